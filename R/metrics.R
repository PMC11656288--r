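#' Binarize a probability map
#' @param prob Probability array.
#' @param threshold Cut-off (default 0.5).
#' @return Integer 0/1 array.
#' @export
binarize <- function(prob, threshold = 0.5) {
  out <- array(0L, dim(prob))
  out[prob > threshold] <- 1L
  out
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#' @param a,b Binary arrays of equal extents.
#' @return Scalar in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("extent mismatch")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

# boundary voxels: foreground with at least one face-adjacent (6-connected)
# background neighbor; voxels touching the volume border count as boundary.
.boundary_coords <- function(mask) {
  d <- dim(mask)
  m <- array(FALSE, d + 2L)
  m[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- mask != 0
  inner <- m[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])]
  nb_all <- m[seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    m[2 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    m[1 + seq_len(d[1]), seq_len(d[2]), 1 + seq_len(d[3])] &
    m[1 + seq_len(d[1]), 2 + seq_len(d[2]), 1 + seq_len(d[3])] &
    m[1 + seq_len(d[1]), 1 + seq_len(d[2]), seq_len(d[3])] &
    m[1 + seq_len(d[1]), 1 + seq_len(d[2]), 2 + seq_len(d[3])]
  which(inner & !nb_all, arr.ind = TRUE)
}

# for each row of P, the minimum Euclidean distance to any row of Q
.min_dists <- function(P, Q, chunk = 4096L) {
  q2 <- rowSums(Q^2)
  out <- numeric(nrow(P))
  for (s in seq(1L, nrow(P), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(P))
    Pc <- P[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Pc^2), q2, "+") - 2 * Pc %*% t(Q)
    d2[d2 < 0] <- 0
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' 95th-percentile Hausdorff distance between two binary masks
#'
#' The 95th percentile of the pooled, bidirectional boundary-to-boundary
#' distances, in millimeters under the given anisotropic voxel spacing.
#' Returns `NA` (with a warning) when either mask is empty -- never a silent
#' zero.
#'
#' @param a,b Binary arrays of equal extents.
#' @param spacing Numeric triple, mm per voxel along each axis.
#' @return Scalar (mm) or `NA_real_`.
#' @export
hd95 <- function(a, b, spacing = c(1, 1, 1)) {
  if (!all(dim(a) == dim(b))) stop("extent mismatch")
  stopifnot(length(spacing) == 3, all(spacing > 0))
  if (sum(a != 0) == 0 || sum(b != 0) == 0) {
    warning("hd95 undefined: at least one mask is empty")
    return(NA_real_)
  }
  A <- .boundary_coords(a)
  B <- .boundary_coords(b)
  A <- A * rep(spacing, each = nrow(A))
  B <- B * rep(spacing, each = nrow(B))
  pooled <- c(.min_dists(A, B), .min_dists(B, A))
  as.numeric(stats::quantile(pooled, 0.95, type = 7, names = FALSE))
}

#' Summarize per-sample metric results
#'
#' Mean and sample standard deviation (n-1 denominator) per metric;
#' undefined (`NA`) HD95 entries are excluded with a logged count.
#'
#' @param per_sample data.frame with columns `dice` and `hd95` (and
#'   optionally a grouping column named `domain`).
#' @return data.frame of mean/sd rows (one per domain if grouped).
#' @export
summarize_metrics <- function(per_sample) {
  stopifnot(nrow(per_sample) >= 1)
  groups <- if ("domain" %in% names(per_sample)) {
    split(per_sample, per_sample$domain)
  } else {
    list(all = per_sample)
  }
  rows <- lapply(names(groups), function(g) {
    df <- groups[[g]]
    hd <- df$hd95
    n_undef <- sum(is.na(hd))
    if (n_undef > 0) {
      message("summarize_metrics: excluding ", n_undef,
              " undefined hd95 value(s) in group '", g, "'")
    }
    hd <- hd[!is.na(hd)]
    data.frame(domain = g, n = nrow(df),
               dice_mean = mean(df$dice),
               dice_sd = if (nrow(df) > 1) stats::sd(df$dice) else 0,
               hd95_mean = if (length(hd)) mean(hd) else NA_real_,
               hd95_sd = if (length(hd) > 1) stats::sd(hd) else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
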