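#' Orthonormal wavelet analysis filters
#'
#' Returns the 1-D low-pass / high-pass decomposition filter pair for a
#' Daubechies family member. The high-pass filter is derived from the
#' low-pass one by the quadrature-mirror relation
#' \eqn{g_m = (-1)^m h_{L-1-m}} (0-based), so the pair is orthonormal by
#' construction.
#'
#' @param family One of `"haar"`, `"db1"` (synonym of haar), `"db2"`,
#'   `"db3"`, `"db4"`.
#' @return An object of class `wavelet_filters` with elements `low_pass`,
#'   `high_pass` and `family_name`.
#' @export
wavelet_filters <- function(family = "db2") {
  family <- tolower(family)
  h <- switch(family,
    haar = ,
    db1 = rep(1 / sqrt(2), 2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db3 = c(0.3326705529509569, 0.8068915093133388, 0.4598775021193313,
            -0.13501102001039084, -0.08544127388224149, 0.035226291882100656),
    db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
            -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    stop("unknown wavelet family: ", family)
  )
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  structure(list(low_pass = h, high_pass = g, family_name = family),
            class = "wavelet_filters")
}

# pad the first margin of a matrix view to even length by edge replication
.pad_even <- function(m) {
  if (nrow(m) %% 2L == 1L) rbind(m, m[nrow(m), , drop = FALSE]) else m
}

# periodized analysis along the rows of a (N x rest) matrix; N must be even
.dwt_rows <- function(m, h, g) {
  n <- nrow(m)
  half <- n %/% 2L
  lo <- matrix(0, half, ncol(m))
  hi <- matrix(0, half, ncol(m))
  base <- 2L * (seq_len(half) - 1L)
  for (j in seq_along(h)) {
    idx <- (base + (j - 1L)) %% n + 1L
    mj <- m[idx, , drop = FALSE]
    lo <- lo + h[j] * mj
    hi <- hi + g[j] * mj
  }
  list(lo = lo, hi = hi)
}

# adjoint/inverse of .dwt_rows, returning n rows (n even)
.idwt_rows <- function(lo, hi, h, g, n) {
  out <- matrix(0, n, ncol(lo))
  base <- 2L * (seq_len(nrow(lo)) - 1L)
  for (j in seq_along(h)) {
    idx <- (base + (j - 1L)) %% n + 1L
    out[idx, ] <- out[idx, ] + h[j] * lo + g[j] * hi
  }
  out
}

# move `axis` to the front as a matrix, apply f, restore layout with new
# leading extent
.along_axis <- function(x, axis, f) {
  d <- dim(x)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  res <- f(m)
  lapply(res, function(r) {
    arr <- array(r, c(nrow(r), dp[2], dp[3]))
    aperm(arr, order(perm))
  })
}

#' Single-level separable 3D discrete wavelet transform
#'
#' Filters and decimates along each axis in turn (periodized boundary
#' handling; odd extents are edge-padded to even first, and the original
#' extents recorded for exact inversion). Produces the low-pass `LLL` band
#' plus the seven mixed bands in fixed lexicographic order over
#' (axis1, axis2, axis3) in \{L,H\}^3: `LLH, LHL, LHH, HLL, HLH, HHL, HHH`.
#'
#' @param volume 3D numeric array.
#' @param filters A [wavelet_filters()] object.
#' @return A list with `low` (the LLL band), `high` (named list of the seven
#'   detail bands) and `input_shape` (the original extents, needed by
#'   [idwt3d()]).
#' @export
dwt3d_single_level <- function(volume, filters) {
  stopifnot(length(dim(volume)) == 3, inherits(filters, "wavelet_filters"))
  h <- filters$low_pass; g <- filters$high_pass
  L <- length(h)
  d0 <- dim(volume)
  for (ax in 1:3) {
    padded <- d0[ax] + d0[ax] %% 2L
    if (padded < L) {
      stop("decomposition too deep: axis ", ax, " extent ", d0[ax],
           " is smaller than the filter support (", L, ")")
    }
  }
  # sequentially split each axis; bands keyed by their L/H code so far
  bands <- stats::setNames(list(volume), "")
  for (ax in 1:3) {
    nxt <- list()
    nms <- character(0)
    for (ki in seq_along(bands)) {
      res <- .along_axis(bands[[ki]], ax, function(m) {
        .dwt_rows(.pad_even(m), h, g)
      })
      nxt <- c(nxt, list(res$lo, res$hi))
      nms <- c(nms, paste0(names(bands)[ki], c("L", "H")))
    }
    bands <- stats::setNames(nxt, nms)
  }
  ord <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  bands <- bands[ord]
  list(low = bands[["LLL"]], high = bands[ord[-1]], input_shape = d0)
}

#' Inverse of [dwt3d_single_level()]
#'
#' @param low LLL band.
#' @param high Named list of the seven detail bands (order as produced by
#'   the forward transform).
#' @param filters A [wavelet_filters()] object.
#' @param target_shape Integer triple: extents of the volume to reconstruct.
#' @return 3D numeric array of extents `target_shape`.
#' @export
idwt3d <- function(low, high, filters, target_shape) {
  h <- filters$low_pass; g <- filters$high_pass
  target_shape <- as.integer(target_shape)
  ord <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  bands <- c(list(LLL = low), high)[ord]
  exp_half <- as.integer(ceiling(target_shape / 2))
  for (nm in names(bands)) {
    if (!identical(dim(bands[[nm]]), as.integer(exp_half))) {
      stop("shape mismatch: band ", nm, " has extents ",
           paste(dim(bands[[nm]]), collapse = "x"), ", expected ",
           paste(exp_half, collapse = "x"))
    }
  }
  padded <- target_shape + target_shape %% 2L
  # undo the axis splits in reverse order; crop padding only at the end
  for (ax in 3:1) {
    keys <- unique(substring(names(bands), 1L, ax - 1L))
    nxt <- list()
    for (key in keys) {
      nxt[[paste0("k", key)]] <- .merge_axis(bands[[paste0(key, "L")]],
                                             bands[[paste0(key, "H")]],
                                             ax, h, g, padded[ax])
    }
    names(nxt) <- sub("^k", "", names(nxt))
    bands <- nxt
  }
  out <- bands[[1]]
  out[seq_len(target_shape[1]), seq_len(target_shape[2]),
      seq_len(target_shape[3]), drop = FALSE]
}

# inverse split of one axis: lo/hi half-extent arrays -> n-extent array
.merge_axis <- function(lo, hi, ax, h, g, n) {
  perm <- c(ax, setdiff(1:3, ax))
  lop <- aperm(lo, perm)
  hip <- aperm(hi, perm)
  dp <- dim(lop)
  out <- .idwt_rows(matrix(lop, nrow = dp[1]), matrix(hip, nrow = dp[1]),
                    h, g, n)
  dp[1] <- n
  aperm(array(out, dp), order(perm))
}

#' Multilevel 3D wavelet pyramid
#'
#' Recursively decomposes the low-pass band: level-n bands derive from the
#' level-(n-1) low band only, with the input volume as level 0. Each level-n
#' sub-band has extents `ceiling(extent / 2^n)` per axis.
#'
#' @param volume 3D numeric array.
#' @param levels Integer in 1..4.
#' @param filters A [wavelet_filters()] object.
#' @return A `wavelet_pyramid` object: `levels`, per-level `low` and `high`
#'   lists, `input_shape`, and the per-level shapes needed for inversion.
#' @export
multilevel_dwt <- function(volume, levels, filters) {
  stopifnot(length(dim(volume)) == 3)
  if (levels < 1 || levels > 4) stop("levels must be in 1..4")
  d <- dim(volume)
  L <- length(filters$low_pass)
  feasible <- 0L
  dd <- d
  repeat {
    if (any(dd + dd %% 2L < L) || feasible >= 4L) break
    feasible <- feasible + 1L
    dd <- as.integer(ceiling(dd / 2))
  }
  if (levels > feasible) {
    stop("extents ", paste(d, collapse = "x"), " support at most ",
         feasible, " decomposition level(s), requested ", levels)
  }
  low <- vector("list", levels)
  high <- vector("list", levels)
  shapes <- vector("list", levels + 1L)
  shapes[[1]] <- d
  cur <- volume
  for (n in seq_len(levels)) {
    dec <- dwt3d_single_level(cur, filters)
    low[[n]] <- dec$low
    high[[n]] <- dec$high
    cur <- dec$low
    shapes[[n + 1L]] <- dim(dec$low)
  }
  structure(list(levels = levels, low = low, high = high,
                 input_shape = d, level_shapes = shapes,
                 family = filters$family_name),
            class = "wavelet_pyramid")
}

#' Reconstruct the input volume from a wavelet pyramid
#'
#' Test/analysis utility: inverts the recursion of [multilevel_dwt()].
#' @param pyramid A `wavelet_pyramid`.
#' @param filters The filters used to build it.
#' @return 3D numeric array with the pyramid's `input_shape`.
#' @export
invert_pyramid <- function(pyramid, filters) {
  cur <- pyramid$low[[pyramid$levels]]
  for (n in rev(seq_len(pyramid$levels))) {
    cur <- idwt3d(cur, pyramid$high[[n]], filters,
                  as.integer(pyramid$level_shapes[[n]]))
  }
  cur
}

#' Stack the eight level-n sub-bands as channels
#'
#' Fusion helper for the segmenter: returns a (X, Y, Z, 8) array holding the
#' level-n low band followed by the seven detail bands in their fixed order.
#' @param pyramid A `wavelet_pyramid`.
#' @param level Level index (1-based).
#' @return 4D array with 8 channels.
#' @export
subbands_at_level <- function(pyramid, level) {
  stopifnot(level >= 1, level <= pyramid$levels)
  bands <- c(list(pyramid$low[[level]]), pyramid$high[[level]])
  d <- dim(bands[[1]])
  out <- array(0, c(d, 8L))
  for (i in seq_along(bands)) out[, , , i] <- bands[[i]]
  out
}

#' Total energy held in a pyramid
#'
#' Sum of squares of the deepest low band plus all detail bands at all
#' levels; for orthonormal filters and even extents this equals the energy
#' of the input volume (Parseval identity).
#' @param pyramid A `wavelet_pyramid`.
#' @return Scalar.
#' @export
pyramid_energy <- function(pyramid) {
  e <- sum(pyramid$low[[pyramid$levels]]^2)
  for (n in seq_len(pyramid$levels)) {
    e <- e + sum(vapply(pyramid$high[[n]], function(b) sum(b^2), numeric(1)))
  }
  e
}
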