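# Objective functions. Probabilities are clamped to [eps, 1-eps] with
# eps = 1e-6 before any logarithm; natural log throughout.

.EPS <- 1e-6

.clamp <- function(p, eps = .EPS) pmin(pmax(p, eps), 1 - eps)

.check_prob <- function(p) {
  if (length(p) == 0) stop("empty probability map")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  invisible(p)
}

#' Class-ratio prior
#'
#' The mean foreground voxel fraction over the source training labels, used
#' as a weak shape prior during adaptation.
#' @param ratio Scalar in (0, 1).
#' @return A `class_ratio_prior` object.
#' @export
class_ratio_prior <- function(ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0 || ratio >= 1) {
    stop("class-ratio prior must be a scalar in (0, 1)")
  }
  structure(list(ratio = as.numeric(ratio)), class = "class_ratio_prior")
}

.prior_ratio <- function(prior) {
  if (inherits(prior, "class_ratio_prior")) prior$ratio else {
    class_ratio_prior(prior)$ratio
  }
}

#' Loss weights for the hybrid adaptation objective
#'
#' Total = lambda1 * entropy + lambda2 * shape + refine (refine weight fixed
#' at 1); defaults (0.5, 1).
#' @param lambda1 Entropy weight (>= 0).
#' @param lambda2 Shape weight (>= 0).
#' @return A `loss_weights` object.
#' @export
loss_weights <- function(lambda1 = 0.5, lambda2 = 1.0) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2), class = "loss_weights")
}

#' Mean binary Shannon entropy of a prediction
#'
#' Per-voxel entropy of the two-class distribution (p, 1-p), averaged over
#' voxels; natural log, so the value lies in [0, log 2].
#' @param prediction Probability array.
#' @return Scalar.
#' @export
entropy_loss <- function(prediction) {
  .check_prob(prediction)
  p <- .clamp(prediction)
  -mean(p * log(p) + (1 - p) * log(1 - p))
}

.entropy_grad <- function(prediction) {
  p <- .clamp(prediction)
  log((1 - p) / p) / length(p)
}

#' Soft foreground class ratio
#'
#' Mean foreground probability over all voxels (kept soft so the shape loss
#' stays differentiable).
#' @param prediction Probability array.
#' @return Scalar in [0, 1].
#' @export
foreground_class_ratio <- function(prediction) {
  .check_prob(prediction)
  mean(prediction)
}

# symmetric KL between Bernoulli(q) and Bernoulli(r), clamped
.sym_bernoulli_kl <- function(q, r) {
  q <- .clamp(q); r <- .clamp(r)
  kl <- function(a, b) a * log(a / b) + (1 - a) * log((1 - a) / (1 - b))
  0.5 * (kl(q, r) + kl(r, q))
}

#' Symmetric shape-aware (class-ratio) loss
#'
#' Treats the predicted soft foreground ratio Fs and the source prior as
#' two-outcome (foreground/background) distributions and returns the
#' symmetrized KL divergence between them: zero iff the ratios agree.
#' @param prediction Probability array.
#' @param prior A [class_ratio_prior()] (or bare scalar in (0,1)).
#' @return Non-negative scalar.
#' @export
shape_aware_loss <- function(prediction, prior) {
  r <- .prior_ratio(prior)
  q <- foreground_class_ratio(prediction)
  .sym_bernoulli_kl(q, r)
}

.shape_grad <- function(prediction, prior) {
  r <- .clamp(.prior_ratio(prior))
  q <- .clamp(mean(prediction))
  dq <- 0.5 * (log(q / r) - log((1 - q) / (1 - r)) - r / q + (1 - r) / (1 - q))
  array(dq / length(prediction), dim(prediction))
}

# run the Refine model (or an identity/function stand-in) on a prediction
.refine_apply <- function(prediction, refine_model, need_cache = FALSE) {
  if (is.function(refine_model)) {
    return(list(prob = refine_model(prediction), cache = NULL, fn = TRUE))
  }
  fw <- wavnet_forward(refine_model, prediction, mode = "eval",
                       need_cache = need_cache)
  list(prob = fw$prob, cache = fw$cache, fn = FALSE)
}

#' Refine reconstruction loss
#'
#' Mean squared error between a prediction and its reconstruction by the
#' (frozen) Refine model. At test time gradients flow into the prediction
#' path only; Refine parameters are never updated.
#' @param prediction Probability array.
#' @param refine_model A `wavnet_model` from [build_refine_model()], or a
#'   plain function mapping an array to an array (e.g. `identity`).
#' @return Non-negative scalar.
#' @export
refine_loss <- function(prediction, refine_model) {
  .check_prob(prediction)
  rf <- .refine_apply(prediction, refine_model)$prob
  if (!all(dim(rf) == dim(prediction))) {
    stop("refine model output extents do not match the prediction")
  }
  mean((rf - prediction)^2)
}

# value + gradient wrt prediction (chain rule through the refine network)
.refine_loss_vg <- function(prediction, refine_model) {
  ra <- .refine_apply(prediction, refine_model, need_cache = TRUE)
  d <- ra$prob - prediction
  N <- length(prediction)
  val <- mean(d^2)
  if (ra$fn) {
    # function stand-ins (identity etc.) are treated as constant maps
    grad <- -(2 / N) * d
  } else {
    bw <- wavnet_backward(refine_model, ra$cache, (2 / N) * d,
                          need_input_grad = TRUE)
    grad <- bw$gx - (2 / N) * d
  }
  list(value = val, grad = grad)
}

#' Hybrid test-time objective
#'
#' Weighted sum of the enabled terms: `lambda1 * entropy + lambda2 * shape +
#' refine`. Returns the total and the per-term breakdown (disabled terms are
#' `NA`).
#' @param prediction Probability array.
#' @param prior A [class_ratio_prior()].
#' @param refine_model Refine model (required when `"re"` is enabled).
#' @param weights A [loss_weights()].
#' @param ablation Character subset of `c("en", "sh", "re")`.
#' @return List with `total` and `terms` (named numeric: en, sh, re).
#' @export
total_loss <- function(prediction, prior, refine_model = NULL,
                       weights = loss_weights(),
                       ablation = c("en", "sh", "re")) {
  if (length(ablation) == 0) stop("at least one loss term must be enabled")
  ablation <- match.arg(ablation, c("en", "sh", "re"), several.ok = TRUE)
  terms <- c(en = NA_real_, sh = NA_real_, re = NA_real_)
  total <- 0
  if ("en" %in% ablation) {
    terms[["en"]] <- entropy_loss(prediction)
    total <- total + weights$lambda1 * terms[["en"]]
  }
  if ("sh" %in% ablation) {
    terms[["sh"]] <- shape_aware_loss(prediction, prior)
    total <- total + weights$lambda2 * terms[["sh"]]
  }
  if ("re" %in% ablation) {
    terms[["re"]] <- refine_loss(prediction, refine_model)
    total <- total + terms[["re"]]
  }
  list(total = total, terms = terms)
}

#' Soft Dice loss for source training
#'
#' `1 - (2 sum(p y) + s) / (sum(p) + sum(y) + s)` with smoothing `s = 1e-5`.
#' @param prediction Probability array.
#' @param label Binary array of identical extents.
#' @param smooth Smoothing constant.
#' @return Scalar in [0, 1].
#' @export
dice_loss <- function(prediction, label, smooth = 1e-5) {
  if (!all(dim(prediction) == dim(label))) stop("extent mismatch")
  num <- 2 * sum(prediction * label) + smooth
  den <- sum(prediction) + sum(label) + smooth
  1 - num / den
}

.dice_grad <- function(prediction, label, smooth = 1e-5) {
  num <- 2 * sum(prediction * label) + smooth
  den <- sum(prediction) + sum(label) + smooth
  -(2 * label * den - num) / den^2
}
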