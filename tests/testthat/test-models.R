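test_that("configurations validate their invariants", {
  expect_error(wavnet_config(stages = 3, encoder_channels = c(4, 8)))
  expect_error(wavnet_config(stages = 6, encoder_channels = rep(4, 6)))
  expect_error(wavnet_config(conv_kernel = 4))
  cfg <- refine_config(depth = 2, channels = c(3, 4))
  expect_false(cfg$use_wavelet)
  expect_error(build_refine_model(wavnet_config(stages = 2,
                                                encoder_channels = c(3, 4))))
})

test_that("forward pass honors the shape/range/determinism contracts", {
  m <- tiny_model()
  ph <- tiny_volume()
  r1 <- wavnet_forward(m, ph$volume, mode = "eval")
  expect_identical(dim(r1$prob), dim(ph$volume))
  expect_true(all(r1$prob >= 0 & r1$prob <= 1))
  r2 <- wavnet_forward(m, ph$volume, mode = "eval")
  expect_identical(r1$prob, r2$prob)             # bitwise determinism
  # attention gates are sigmoid-bounded, one per sub-band channel
  expect_length(r1$sa_weights[[1]], 8L)
  expect_true(all(r1$sa_weights[[1]] > 0 & r1$sa_weights[[1]] < 1))
  # resolution contract
  expect_error(wavnet_forward(m, array(0, c(7, 8, 8))), "divisible")
})

test_that("forcing SA weights to zero equals zeroing the wavelet channels", {
  m <- tiny_model()
  ph <- tiny_volume()
  forced <- wavnet_forward(m, ph$volume, mode = "eval", sa_override = 0)
  # zero filters make every sub-band (hence every wavelet channel) zero
  m0 <- m
  m0$filters$low_pass[] <- 0
  m0$filters$high_pass[] <- 0
  zeroed <- wavnet_forward(m0, ph$volume, mode = "eval")
  expect_identical(forced$prob, zeroed$prob)
  # forced 0.5 halves the weighted bands (checked at the block level)
  set.seed(9)
  bands <- array(rnorm(4 * 4 * 2 * 8), c(4, 4, 2, 8))
  p <- list(W1 = matrix(rnorm(32), 4, 8), b1 = rep(0, 4),
            W2 = matrix(rnorm(32), 8, 4), b2 = rep(0, 8))
  half <- wavetta:::sa_fw(bands, p, override = 0.5)
  expect_equal(half$out, bands * 0.5)
  z <- wavetta:::sa_fw(array(0, dim(bands)), p)
  expect_equal(max(abs(z$out)), 0)
})

test_that("ablating the wavelet path yields a plain V-Net of matching contract", {
  mv <- tiny_model(use_wavelet = FALSE)
  ph <- tiny_volume()
  r <- wavnet_forward(mv, ph$volume, mode = "eval")
  expect_identical(dim(r$prob), dim(ph$volume))
  expect_length(r$sa_weights, 0L)
  expect_false(any(grepl("^sa", names(mv$params))))
})

test_that("parameter partition obeys its invariants and survives save/load", {
  m <- tiny_model()
  part <- partition_parameters(m)
  expect_true(all(grepl("^sa", names(m$params))[
    names(m$params) %in% part$adaptable][
      grepl("^sa", part$adaptable)] | TRUE))
  expect_true(all(part$adaptable[grepl("^sa", part$adaptable)] %in%
                    names(m$params)))
  expect_length(intersect(part$adaptable, part$frozen), 0L)
  expect_setequal(c(part$adaptable, part$frozen), names(m$params))
  # every SA parameter is adaptable
  sa_names <- grep("^sa[0-9]+\\.", names(m$params), value = TRUE)
  expect_true(all(sa_names %in% part$adaptable))
  # adaptable fraction is below 10% for the desk configuration
  md <- withr::with_seed(3, build_wavnet(.desk$model_config()))
  pd <- partition_parameters(md)
  frac <- count_parameters(md, pd$adaptable) / count_parameters(md)
  expect_lt(frac, 0.1)
  # refine models have no SA parameters: refuse an empty partition
  expect_error(partition_parameters(tiny_refine()), "attention")
  # checkpoint round trip preserves parameters and partition
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path, prior = class_ratio_prior(0.1))
  ck <- load_checkpoint(path)
  expect_identical(ck$model$params, m$params)
  expect_identical(partition_parameters(ck$model), part)
  expect_equal(ck$prior$ratio, 0.1)
})

test_that("whole-model gradients agree with central differences", {
  cfg <- wavnet_config(stages = 2, encoder_channels = c(3, 4),
                       proj_channels = 2)
  m <- withr::with_seed(21, build_wavnet(cfg))
  ph <- tiny_volume(seed = 21, extents = c(8L, 8L, 8L))
  y <- ph$label
  lossf <- function(model) {
    dice_loss(wavnet_forward(model, ph$volume, mode = "sample")$prob, y)
  }
  fw <- wavnet_forward(m, ph$volume, mode = "sample", need_cache = TRUE)
  bw <- wavnet_backward(m, fw$cache, wavetta:::.dice_grad(fw$prob, y))
  eps <- 1e-6
  # one scalar from each parameter family (conv, bn, sa, proj, head)
  probe <- c("enc1.conv.W", "enc2.bn.gamma", "sa1.W2", "proj1.W",
             "dec1.conv.W", "head.W")
  for (nm in probe) {
    i <- 1L
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
    g_num <- (lossf(mp) - lossf(mm)) / (2 * eps)
    expect_equal(as.vector(bw$grads[[nm]])[i], g_num, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
})

test_that("refine models map any extents to identical extents in [0,1]", {
  rf <- tiny_refine()
  for (d in list(c(8L, 8L, 8L), c(16L, 12L, 8L))) {
    out <- wavnet_forward(rf, array(runif(prod(d)), d), mode = "eval")$prob
    expect_identical(dim(out), d)
    expect_true(all(out >= 0 & out <= 1))
  }
})
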