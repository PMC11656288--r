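# cheap structural tests at tiny scale; the trained desk-scale pipeline is
# exercised in test-acceptance.R

tiny_cfg <- function() wavnet_config(stages = 2L, encoder_channels = c(3L, 4L),
                                     proj_channels = 2L)
tiny_data <- function(n = 4L, extents = c(12L, 12L, 8L)) {
  phs <- lapply(seq_len(n), function(i) {
    generate_phantom(extents, fg_range = c(0.05, 0.25), seed = 400 + i)
  })
  list(volumes = lapply(phs, `[[`, "volume"),
       labels = lapply(phs, `[[`, "label"))
}

test_that("source training reduces the smoothed Dice-loss curve on seeded phantoms", {
  td <- tiny_data(4)
  m <- withr::with_seed(51, build_wavnet(tiny_cfg()))
  fit <- train_source(m, td$volumes, td$labels,
                      source_config(epochs = 50, learning_rate = 0.01,
                                    seed = 51))
  expect_length(fit$history, 50L)
  sm <- stats::filter(fit$history, rep(1 / 5, 5), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1] - 0.1)       # clear overall decrease
  expect_lt(max(diff(sm)), 0.02)               # monotone up to small jitter
  # the prior is the mean per-sample foreground fraction
  expect_equal(fit$prior$ratio,
               mean(vapply(td$labels, mean, numeric(1))))
})

test_that("zero-epoch training returns the initialized model with a prior", {
  td <- tiny_data(2)
  m <- withr::with_seed(52, build_wavnet(tiny_cfg()))
  fit <- train_source(m, td$volumes, td$labels,
                      source_config(epochs = 0, seed = 52))
  expect_identical(fit$model$params, m$params)
  expect_s3_class(fit$prior, "class_ratio_prior")
  expect_length(fit$history, 0L)
})

test_that("seeded training is reproducible run-to-run", {
  td <- tiny_data(2)
  run <- function() {
    m <- withr::with_seed(53, build_wavnet(tiny_cfg()))
    train_source(m, td$volumes, td$labels,
                 source_config(epochs = 5, learning_rate = 0.01,
                               seed = 53))$model$params
  }
  expect_identical(run(), run())
})

test_that("undertrained corpus has schedule x samples pairs in [0,1]", {
  td <- tiny_data(3)
  cfg <- source_config(epochs = 4, learning_rate = 0.01, seed = 54)
  corpus <- generate_undertrained_segmentations(td$volumes, td$labels,
                                                schedule = c(1L, 3L),
                                                config = cfg,
                                                model_config = tiny_cfg())
  expect_length(corpus, 2L * 3L)
  for (pair in corpus) {
    expect_true(all(pair$noisy >= 0 & pair$noisy <= 1))
    expect_identical(dim(pair$noisy), dim(pair$label))
  }
  one <- generate_undertrained_segmentations(td$volumes[1], td$labels[1],
                                             schedule = 1L, config = cfg,
                                             model_config = tiny_cfg())
  expect_length(one, 1L)
  expect_error(generate_undertrained_segmentations(td$volumes, td$labels,
                                                   schedule = c(5L, 10L),
                                                   config = cfg),
               "exceeds")
  expect_error(generate_undertrained_segmentations(td$volumes, td$labels,
                                                   schedule = c(3L, 2L),
                                                   config = cfg),
               "increasing")
})

test_that("refine training reduces reconstruction error and is seeded", {
  td <- tiny_data(3)
  corpus <- lapply(seq_along(td$labels), function(i) {
    list(noisy = array(as.numeric(td$labels[[i]]), dim(td$labels[[i]])),
         label = td$labels[[i]])
  })
  rf0 <- tiny_refine(seed = 55)
  pre <- mean(vapply(corpus, function(p) {
    mean((wavnet_forward(rf0, p$noisy, mode = "eval")$prob - p$label)^2)
  }, numeric(1)))
  fit <- train_refine(rf0, corpus, epochs = 15, learning_rate = 0.05,
                      seed = 55)
  post <- mean(vapply(corpus, function(p) {
    mean((wavnet_forward(fit$model, p$noisy, mode = "eval")$prob -
            p$label)^2)
  }, numeric(1)))
  expect_lt(post, pre)
  fit2 <- train_refine(tiny_refine(seed = 55), corpus, epochs = 15,
                       learning_rate = 0.05, seed = 55)
  expect_identical(fit$model$params, fit2$model$params)
  expect_error(train_refine(rf0, list(), epochs = 1), "empty")
})

test_that("salt-and-pepper + erosion corruption is repaired on held-out pairs", {
  extents <- c(16L, 16L, 8L)
  mk <- function(seed) {
    ph <- generate_phantom(extents, fg_range = c(0.08, 0.25), seed = seed)
    list(noisy = corrupt_segmentation(ph$label, seed = seed + 1000L),
         label = ph$label)
  }
  train <- lapply(1:20, function(i) mk(600 + i))
  held <- lapply(1:10, function(i) mk(700 + i))
  rf <- withr::with_seed(56, build_refine_model(refine_config(depth = 2L,
                                                              channels = c(4L, 8L))))
  fit <- train_refine(rf, train, epochs = 80, learning_rate = 0.2, seed = 56)
  d_noisy <- vapply(held, function(p) {
    dice_coefficient(binarize(p$noisy), p$label)
  }, numeric(1))
  d_ref <- vapply(held, function(p) {
    dice_coefficient(binarize(wavnet_forward(fit$model, p$noisy,
                                             mode = "eval")$prob), p$label)
  }, numeric(1))
  expect_gt(mean(d_ref) - mean(d_noisy), 0)
})

test_that("adaptation freezes what it must and is sample-independent", {
  td <- tiny_data(1)
  m <- withr::with_seed(57, build_wavnet(tiny_cfg()))
  ck <- list(model = m, prior = class_ratio_prior(0.12))
  # iterations = 0 reproduces the eval-mode source prediction exactly
  r0 <- adapt_single_sample(ck, identity, td$volumes[[1]],
                            tta_config(iterations = 0))
  expect_identical(r0$prob,
                   wavnet_forward(m, td$volumes[[1]], mode = "eval")$prob)
  expect_identical(r0$prob, r0$baseline_prob)
  # a short adaptation only moves the adaptable partition
  r <- adapt_single_sample(ck, identity, td$volumes[[1]],
                           tta_config(iterations = 3))
  part <- partition_parameters(m)
  for (nm in part$frozen) {
    expect_identical(r$model$params[[nm]], m$params[[nm]])
  }
  moved <- vapply(part$adaptable, function(nm) {
    max(abs(r$model$params[[nm]] - m$params[[nm]]))
  }, numeric(1))
  expect_gt(max(moved), 0)
  # per-iteration trace recombines to the total at 1e-12
  expect_equal(nrow(r$trace), 3L)
  expect_lt(max(abs(r$trace$L_total -
                      (0.5 * r$trace$L_en + r$trace$L_sh + r$trace$L_re))),
            1e-12)
  # fresh start per sample: re-adapting gives the identical result
  r2 <- adapt_single_sample(ck, identity, td$volumes[[1]],
                            tta_config(iterations = 3))
  expect_identical(r$model$params, r2$model$params)
  expect_identical(r$prob, r2$prob)
})

test_that("an identity refine model makes sh+re coincide with sh", {
  td <- tiny_data(1)
  m <- withr::with_seed(58, build_wavnet(tiny_cfg()))
  ck <- list(model = m, prior = class_ratio_prior(0.12))
  r_sh <- adapt_single_sample(ck, NULL, td$volumes[[1]],
                              tta_config(iterations = 4, ablation = "sh"))
  r_shre <- adapt_single_sample(ck, identity, td$volumes[[1]],
                                tta_config(iterations = 4,
                                           ablation = c("sh", "re")))
  expect_identical(r_sh$prob, r_shre$prob)
  expect_equal(r_shre$trace$L_re, rep(0, 4))
  # the refine term requires a model when enabled
  expect_error(adapt_single_sample(ck, NULL, td$volumes[[1]],
                                   tta_config(iterations = 1)),
               "refine")
})

test_that("adaptation on an all-background volume stays finite", {
  flat <- array(0.3, c(8L, 8L, 8L)) +
    withr::with_seed(59, array(stats::rnorm(512, sd = 0.01), c(8, 8, 8)))
  flat <- pmin(pmax(flat, 0), 1)
  m <- withr::with_seed(59, build_wavnet(tiny_cfg()))
  ck <- list(model = m, prior = class_ratio_prior(0.05))
  r <- adapt_single_sample(ck, identity, flat, tta_config(iterations = 5))
  expect_true(all(is.finite(as.matrix(r$trace))))
})

test_that("run_ablation produces the six-combination table", {
  td <- tiny_data(2)
  m <- withr::with_seed(60, build_wavnet(tiny_cfg()))
  ck <- list(model = m, prior = class_ratio_prior(0.12))
  tab <- run_ablation(ck, identity, td$volumes[1], td$labels[1],
                      config = tta_config(iterations = 1))
  expect_identical(nrow(tab), 6L)
  expect_setequal(tab$combo, c("en", "sh", "re", "en+sh", "sh+re", "total"))
  expect_true(all(tab$dice_mean >= 0 & tab$dice_mean <= 1))
  per <- attr(tab, "per_sample")
  expect_identical(nrow(per), 6L)
})
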