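test_that("filter families satisfy the quadrature-mirror/orthonormality relations", {
  for (fam in c("haar", "db1", "db2", "db3", "db4")) {
    f <- wavelet_filters(fam)
    L <- length(f$low_pass)
    expect_identical(L %% 2L, 0L)
    expect_identical(length(f$high_pass), L)
    # orthonormal QMF: unit energy, sqrt(2) DC gain, derived high-pass
    expect_lt(abs(sum(f$low_pass^2) - 1), 1e-10)
    expect_lt(abs(sum(f$low_pass) - sqrt(2)), 1e-10)
    g_expected <- (-1)^(seq_len(L) - 1) * rev(f$low_pass)
    expect_lt(max(abs(f$high_pass - g_expected)), 1e-10)
    # even-shift orthogonality between the pair
    for (j in seq_len(L / 2 - 1)) {
      expect_lt(abs(sum(f$low_pass[1:(L - 2 * j)] *
                          f$low_pass[(1 + 2 * j):L])), 1e-10)
    }
  }
  expect_error(wavelet_filters("sym9"), "unknown")
})

test_that("single-level transform of a constant annihilates high bands and scales the low band", {
  f <- wavelet_filters("haar")
  cv <- array(0.7, c(8, 8, 8))
  dec <- dwt3d_single_level(cv, f)
  for (b in dec$high) expect_equal(max(abs(b)), 0)
  # per-axis low-pass of a constant multiplies by sqrt(2): direct
  # convolution oracle sum(h) = sqrt(2), applied once per axis
  expect_equal(dec$low, array(2^(3 / 2) * 0.7, c(4, 4, 4)), tolerance = 1e-12)
  # every supported family annihilates constants at every level
  for (fam in c("db2", "db3")) {
    p <- multilevel_dwt(array(1.3, c(16, 16, 16)), 2, wavelet_filters(fam))
    for (n in 1:2) for (b in p$high[[n]]) expect_lt(max(abs(b)), 1e-10)
  }
})

test_that("dwt/idwt round-trips are exact for even and odd extents", {
  set.seed(101)
  for (fam in c("haar", "db2", "db3")) {
    f <- wavelet_filters(fam)
    v <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
    dec <- dwt3d_single_level(v, f)
    expect_identical(length(dec$high), 7L)
    expect_identical(dim(dec$low), c(4L, 4L, 4L))
    expect_lt(max(abs(idwt3d(dec$low, dec$high, f, dim(v)) - v)), 1e-8)
    v2 <- array(rnorm(7 * 6 * 5), c(7, 6, 5))
    dec2 <- dwt3d_single_level(v2, f)
    expect_identical(dim(dec2$low), c(4L, 3L, 3L))  # ceiling halving
    expect_lt(max(abs(idwt3d(dec2$low, dec2$high, f, dim(v2)) - v2)), 1e-8)
  }
  # zero bands reconstruct to the zero volume
  f <- wavelet_filters("db2")
  z <- dwt3d_single_level(array(0, c(6, 6, 6)), f)
  expect_equal(idwt3d(z$low, z$high, f, c(6L, 6L, 6L)),
               array(0, c(6, 6, 6)))
})

test_that("multilevel pyramid has the documented shapes and inverts exactly", {
  set.seed(102)
  f <- wavelet_filters("db2")
  v <- array(rnorm(64 * 64 * 64), c(64, 64, 64))
  p <- multilevel_dwt(v, 4, f)
  expect_identical(dim(p$low[[4]]), c(4L, 4L, 4L))
  for (n in 1:4) {
    expect_identical(dim(p$low[[n]]),
                     as.integer(ceiling(c(64, 64, 64) / 2^n)))
  }
  expect_lt(max(abs(invert_pyramid(p, f) - v)), 1e-8)
  # levels = 1 reproduces the single-level transform exactly
  p1 <- multilevel_dwt(v, 1, f)
  dec <- dwt3d_single_level(v, f)
  expect_identical(p1$low[[1]], dec$low)
  expect_identical(p1$high[[1]], dec$high)
  # odd extents at depth
  v3 <- array(rnorm(13 * 10 * 9), c(13, 10, 9))
  p3 <- multilevel_dwt(v3, 2, f)
  expect_identical(dim(p3$low[[2]]), c(4L, 3L, 3L))
  expect_lt(max(abs(invert_pyramid(p3, f) - v3)), 1e-8)
})

test_that("Parseval energy identity holds for orthonormal filters on even extents", {
  set.seed(103)
  v <- array(rnorm(64 * 64 * 32), c(64, 64, 32))
  for (fam in c("haar", "db2")) {
    p <- multilevel_dwt(v, 4, wavelet_filters(fam))
    expect_lt(abs(pyramid_energy(p) - sum(v^2)) / sum(v^2), 1e-6)
  }
})

test_that("the transform is linear and deterministic with a fixed band ordering", {
  set.seed(104)
  f <- wavelet_filters("db2")
  a <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
  b <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
  d1 <- dwt3d_single_level(2 * a + 3 * b, f)
  da <- dwt3d_single_level(a, f)
  db <- dwt3d_single_level(b, f)
  expect_lt(max(abs(d1$low - 2 * da$low - 3 * db$low)), 1e-10)
  for (nm in names(d1$high)) {
    expect_lt(max(abs(d1$high[[nm]] - 2 * da$high[[nm]] - 3 * db$high[[nm]])),
              1e-10)
  }
  expect_identical(names(d1$high),
                   c("LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  expect_identical(dwt3d_single_level(a, f), dwt3d_single_level(a, f))
})

test_that("infeasible decompositions fail with informative errors", {
  f <- wavelet_filters("db2")
  expect_error(multilevel_dwt(array(0, c(8, 8, 8)), 4, f), "at most 2")
  expect_error(multilevel_dwt(array(0, c(64, 64, 64)), 5, f), "levels")
  expect_error(dwt3d_single_level(array(0, c(2, 8, 8)),
                                  wavelet_filters("db4")), "axis 1")
  dec <- dwt3d_single_level(array(rnorm(64), c(4, 4, 4)), f)
  bad <- dec$high
  bad$HHH <- bad$HHH[1, , , drop = FALSE]
  expect_error(idwt3d(dec$low, bad, f, c(4L, 4L, 4L)), "shape mismatch")
})

test_that("subbands_at_level stacks low + seven detail bands as channels", {
  set.seed(105)
  v <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  p <- multilevel_dwt(v, 2, wavelet_filters("db2"))
  sb <- subbands_at_level(p, 2)
  expect_identical(dim(sb), c(4L, 4L, 2L, 8L))
  expect_equal(sb[, , , 1], p$low[[2]])
  expect_equal(sb[, , , 5], p$high[[2]][["HLL"]])
  expect_error(subbands_at_level(p, 3))
})
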