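# Brute-force oracles shared by the metrics unit tests and the acceptance
# suite. Written deliberately naively (explicit loops, all-pairs
# distances), independent of the package internals they check.

.oracle_boundary <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] == 0) next
    nb <- FALSE
    for (o in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                   c(0, 0, -1), c(0, 0, 1))) {
      q <- c(i, j, k) + o
      if (any(q < 1) || any(q > d) || mask[q[1], q[2], q[3]] == 0) {
        nb <- TRUE
        break
      }
    }
    if (nb) out <- rbind(out, c(i, j, k))
  }
  out
}

.oracle_hd95 <- function(a, b, spacing) {
  A <- .oracle_boundary(a)
  B <- .oracle_boundary(b)
  ds <- c()
  for (i in seq_len(nrow(A))) {
    ds <- c(ds, min(sqrt(colSums((t(B) * spacing - A[i, ] * spacing)^2))))
  }
  for (i in seq_len(nrow(B))) {
    ds <- c(ds, min(sqrt(colSums((t(A) * spacing - B[i, ] * spacing)^2))))
  }
  as.numeric(stats::quantile(ds, 0.95, type = 7, names = FALSE))
}

.rand_mask <- function(d, p = 0.3) array(rbinom(prod(d), 1, p), d)
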