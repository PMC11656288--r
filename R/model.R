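#' Network configuration for the wavelet-attention segmenter
#'
#' @param stages Number of encoder stages (2..5; the full-scale profile uses
#'   5, the CPU desk profile 3). Wavelet levels fused = `stages - 1`.
#' @param encoder_channels Integer vector of per-stage channel counts,
#'   length `stages`.
#' @param conv_kernel Spatial kernel extent (odd; default 3).
#' @param proj_channels Channel budget the 8 attention-weighted sub-bands are
#'   projected to (1x1x1 conv) before concatenation into the encoder.
#' @param sa_reduction Channel-reduction ratio inside sub-band attention
#'   blocks (default 2).
#' @param use_wavelet Fuse wavelet sub-bands (TRUE) or run as a plain V-Net.
#' @param wavelet_family Filter family for [wavelet_filters()].
#' @param num_classes Only 1 (binary, sigmoid head) is supported.
#' @return A `wavnet_config` list.
#' @export
wavnet_config <- function(stages = 3L, encoder_channels = c(8L, 16L, 32L),
                          conv_kernel = 3L, proj_channels = 4L,
                          sa_reduction = 2L, use_wavelet = TRUE,
                          wavelet_family = "db2", num_classes = 1L) {
  stopifnot(stages >= 2, stages <= 5,
            length(encoder_channels) == stages,
            conv_kernel %% 2 == 1, num_classes == 1L,
            sa_reduction >= 1, proj_channels >= 1)
  structure(list(stages = as.integer(stages),
                 encoder_channels = as.integer(encoder_channels),
                 conv_kernel = as.integer(conv_kernel),
                 proj_channels = as.integer(proj_channels),
                 sa_reduction = as.integer(sa_reduction),
                 use_wavelet = isTRUE(use_wavelet),
                 wavelet_family = wavelet_family,
                 num_classes = 1L),
            class = "wavnet_config")
}

#' Configuration for the Refine reconstruction network
#'
#' An encoder/decoder autoencoder mapping a probability map to a cleaned
#' probability map of identical extents, with a sigmoid head.
#'
#' @param depth Number of encoder stages (default 4, the full-scale profile).
#' @param channels Per-stage channels, length `depth`.
#' @return A `wavnet_config` with wavelet fusion disabled.
#' @export
refine_config <- function(depth = 4L, channels = c(8L, 16L, 32L, 64L)) {
  wavnet_config(stages = depth, encoder_channels = channels,
                use_wavelet = FALSE)
}

.conv_init <- function(fan_in, cout, k, gain = 2) {
  list(W = matrix(stats::rnorm(k^3 * fan_in * cout) * sqrt(gain / (k^3 * fan_in)),
                  nrow = k^3 * fan_in, ncol = cout),
       b = rep(0, cout))
}

.build_vnet <- function(config, filters) {
  S <- config$stages
  ch <- config$encoder_channels
  k <- config$conv_kernel
  pc <- config$proj_channels
  params <- list()
  bn_names <- character(0)
  add_bn <- function(name, C) {
    params[[paste0(name, ".gamma")]] <<- rep(1, C)
    params[[paste0(name, ".beta")]] <<- rep(0, C)
    bn_names <<- c(bn_names, name)
    C
  }
  bn_dims <- integer(0)
  for (n in seq_len(S)) {
    cin <- if (n == 1) 1L else ch[n - 1] + if (config$use_wavelet) pc else 0L
    cv <- .conv_init(cin, ch[n], k)
    params[[paste0("enc", n, ".conv.W")]] <- cv$W
    params[[paste0("enc", n, ".conv.b")]] <- cv$b
    bn_dims <- c(bn_dims, add_bn(paste0("enc", n, ".bn"), ch[n]))
    if (config$use_wavelet && n < S) {
      C <- 8L
      Cr <- max(1L, C %/% config$sa_reduction)
      params[[paste0("sa", n, ".W1")]] <- matrix(stats::rnorm(Cr * C) * sqrt(2 / C), Cr, C)
      params[[paste0("sa", n, ".b1")]] <- rep(0, Cr)
      params[[paste0("sa", n, ".W2")]] <- matrix(stats::rnorm(C * Cr) * sqrt(2 / Cr), C, Cr)
      params[[paste0("sa", n, ".b2")]] <- rep(0, C)
      pj <- .conv_init(C, pc, 1L)
      params[[paste0("proj", n, ".W")]] <- pj$W
      params[[paste0("proj", n, ".b")]] <- pj$b
    }
  }
  for (n in seq_len(S - 1)) {
    cin <- ch[n + 1] + ch[n]
    cv <- .conv_init(cin, ch[n], k)
    params[[paste0("dec", n, ".conv.W")]] <- cv$W
    params[[paste0("dec", n, ".conv.b")]] <- cv$b
    bn_dims <- c(bn_dims, add_bn(paste0("dec", n, ".bn"), ch[n]))
  }
  hd <- .conv_init(ch[1], 1L, 1L, gain = 1)
  params[["head.W"]] <- hd$W
  params[["head.b"]] <- hd$b
  bn_running <- stats::setNames(lapply(bn_dims, function(C) {
    list(mean = rep(0, C), var = rep(1, C))
  }), bn_names)
  structure(list(params = params, config = config, filters = filters,
                 bn_running = bn_running),
            class = "wavnet_model")
}

#' Build the wavelet-attention segmentation model
#'
#' A V-Net-style encoder/decoder with skip connections. At encoder stage
#' n+1 (n = 1..stages-1) the eight level-n wavelet sub-bands of the input
#' volume are gated by a sub-band attention block, projected to
#' `proj_channels` by a 1x1x1 convolution, and channel-concatenated with the
#' pooled spatial features before the stage's convolution. The head is a
#' single-channel sigmoid, so outputs are per-voxel foreground
#' probabilities.
#'
#' Parameter initialization uses the current RNG state; seed it (e.g. with
#' [withr::with_seed()]) for reproducible models.
#'
#' @param config A [wavnet_config()].
#' @param filters Optional [wavelet_filters()]; defaults to the family named
#'   in `config`.
#' @return A `wavnet_model`.
#' @export
build_wavnet <- function(config = wavnet_config(),
                         filters = wavelet_filters(config$wavelet_family)) {
  .build_vnet(config, filters)
}

#' Build the Refine reconstruction model
#'
#' Same backbone as [build_wavnet()] but without wavelet fusion: a plain
#' encoder/decoder autoencoder over probability maps with a sigmoid head.
#'
#' @param config A [refine_config()].
#' @return A `wavnet_model`.
#' @export
build_refine_model <- function(config = refine_config()) {
  stopifnot(!config$use_wavelet)
  .build_vnet(config, wavelet_filters(config$wavelet_family))
}

#' Forward pass
#'
#' @param model A `wavnet_model`.
#' @param x 3D numeric array (intensities in any range; typically [0,1]).
#' @param mode `"eval"` uses running batch-norm statistics; `"sample"` uses
#'   the current volume's statistics (source training and test-time
#'   adaptation).
#' @param update_running Update running BN statistics (source training only).
#' @param sa_override If non-NULL, force every sub-band attention weight to
#'   this value (ablation/testing hook).
#' @param need_cache Keep the activation caches needed by
#'   [wavnet_backward()].
#' @return List with `prob` (3D probability array), `sa_weights` (per-level
#'   gate vectors), `model` (with updated running stats if requested) and,
#'   when `need_cache`, `cache`.
#' @export
wavnet_forward <- function(model, x, mode = c("eval", "sample"),
                           update_running = FALSE, sa_override = NULL,
                           need_cache = FALSE) {
  mode <- match.arg(mode)
  cfg <- model$config
  S <- cfg$stages
  d <- dim(x)
  stopifnot(length(d) == 3)
  if (any(d %% 2^(S - 1) != 0)) {
    stop("input extents ", paste(d, collapse = "x"),
         " must be divisible by ", 2^(S - 1), " for a ", S, "-stage model")
  }
  pyr <- NULL
  if (cfg$use_wavelet) pyr <- multilevel_dwt(x, S - 1L, model$filters)
  p <- model$params
  bnr <- model$bn_running
  cache <- list(enc = vector("list", S), dec = vector("list", S - 1))
  sa_weights <- vector("list", if (cfg$use_wavelet) S - 1 else 0)
  feats <- vector("list", S)
  dim(x) <- c(d, 1L)
  cur <- x
  for (n in seq_len(S)) {
    cc <- list()
    if (n > 1) {
      pl <- avgpool2_fw(cur)
      cc$pool <- pl$cache
      cur <- pl$out
      if (cfg$use_wavelet) {
        bands <- subbands_at_level(pyr, n - 1L)
        if (!all(dim(bands)[1:3] == dim(cur)[1:3])) {
          stop("configuration error: level-", n - 1, " sub-band extents ",
               paste(dim(bands)[1:3], collapse = "x"),
               " do not match stage-", n, " feature extents ",
               paste(dim(cur)[1:3], collapse = "x"))
        }
        sa <- sa_fw(bands, list(W1 = p[[paste0("sa", n - 1, ".W1")]],
                                b1 = p[[paste0("sa", n - 1, ".b1")]],
                                W2 = p[[paste0("sa", n - 1, ".W2")]],
                                b2 = p[[paste0("sa", n - 1, ".b2")]]),
                    override = sa_override)
        sa_weights[[n - 1]] <- sa$weights
        pj <- conv_fw(sa$out, p[[paste0("proj", n - 1, ".W")]],
                      p[[paste0("proj", n - 1, ".b")]], 1L)
        ct <- concat_fw(cur, pj$out)
        cc$sa <- sa$cache; cc$proj <- pj$cache; cc$concat <- ct$cache
        cur <- ct$out
      }
    }
    cv <- conv_fw(cur, p[[paste0("enc", n, ".conv.W")]],
                  p[[paste0("enc", n, ".conv.b")]], cfg$conv_kernel)
    bname <- paste0("enc", n, ".bn")
    bn <- bn_fw(cv$out, p[[paste0(bname, ".gamma")]], p[[paste0(bname, ".beta")]],
                if (mode == "eval") "eval" else "sample",
                bnr[[bname]]$mean, bnr[[bname]]$var,
                update_running = update_running)
    if (update_running) bnr[[bname]] <- list(mean = bn$run_mean, var = bn$run_var)
    rl <- relu_fw(bn$out)
    cc$conv <- cv$cache; cc$bn <- bn$cache; cc$relu <- rl$cache
    cache$enc[[n]] <- cc
    feats[[n]] <- rl$out
    cur <- rl$out
  }
  for (n in rev(seq_len(S - 1))) {
    up <- upsample2_fw(cur)
    ct <- concat_fw(up$out, feats[[n]])
    cv <- conv_fw(ct$out, p[[paste0("dec", n, ".conv.W")]],
                  p[[paste0("dec", n, ".conv.b")]], cfg$conv_kernel)
    bname <- paste0("dec", n, ".bn")
    bn <- bn_fw(cv$out, p[[paste0(bname, ".gamma")]], p[[paste0(bname, ".beta")]],
                if (mode == "eval") "eval" else "sample",
                bnr[[bname]]$mean, bnr[[bname]]$var,
                update_running = update_running)
    if (update_running) bnr[[bname]] <- list(mean = bn$run_mean, var = bn$run_var)
    rl <- relu_fw(bn$out)
    cache$dec[[n]] <- list(up = up$cache, concat = ct$cache, conv = cv$cache,
                           bn = bn$cache, relu = rl$cache)
    cur <- rl$out
  }
  hd <- conv_fw(cur, p[["head.W"]], p[["head.b"]], 1L)
  sg <- sigmoid_fw(hd$out)
  cache$head <- hd$cache
  cache$sig <- sg$cache
  prob <- sg$out
  dim(prob) <- d
  model$bn_running <- bnr
  list(prob = prob, sa_weights = sa_weights, model = model,
       cache = if (need_cache) cache else NULL)
}

#' Backward pass
#'
#' Computes gradients of a scalar loss with respect to every parameter (and
#' optionally the input volume) given the gradient of the loss with respect
#' to the output probability map.
#'
#' @param model The `wavnet_model` used in the forward pass.
#' @param cache Cache returned by [wavnet_forward()] (`need_cache = TRUE`).
#' @param dprob 3D array: dLoss/dProb.
#' @param need_input_grad Also return dLoss/dInput (used to differentiate
#'   through the frozen Refine model at test time).
#' @return List with `grads` (named like `model$params`) and optionally `gx`.
#' @export
wavnet_backward <- function(model, cache, dprob, need_input_grad = FALSE) {
  cfg <- model$config
  S <- cfg$stages
  p <- model$params
  grads <- list()
  d <- dim(dprob)
  dim(dprob) <- c(d, 1L)
  g <- sigmoid_bw(cache$sig, dprob)
  hb <- conv_bw(cache$head, p[["head.W"]], g, need_xgrad = TRUE)
  grads[["head.W"]] <- hb$gW; grads[["head.b"]] <- hb$gb
  gcur <- hb$gx
  feat_grad <- vector("list", S)
  for (n in seq_len(S - 1)) {
    cc <- cache$dec[[n]]
    g <- relu_bw(cc$relu, gcur)
    bb <- bn_bw(cc$bn, g)
    bname <- paste0("dec", n, ".bn")
    grads[[paste0(bname, ".gamma")]] <- bb$dgamma
    grads[[paste0(bname, ".beta")]] <- bb$dbeta
    cb <- conv_bw(cc$conv, p[[paste0("dec", n, ".conv.W")]], bb$gx, TRUE)
    grads[[paste0("dec", n, ".conv.W")]] <- cb$gW
    grads[[paste0("dec", n, ".conv.b")]] <- cb$gb
    sp <- concat_bw(cc$concat, cb$gx)
    feat_grad[[n]] <- sp$gb
    gcur <- upsample2_bw(cc$up, sp$ga)
  }
  feat_grad[[S]] <- gcur
  gx <- NULL
  for (n in rev(seq_len(S))) {
    cc <- cache$enc[[n]]
    g <- relu_bw(cc$relu, feat_grad[[n]])
    bb <- bn_bw(cc$bn, g)
    bname <- paste0("enc", n, ".bn")
    grads[[paste0(bname, ".gamma")]] <- bb$dgamma
    grads[[paste0(bname, ".beta")]] <- bb$dbeta
    need_x <- n > 1 || need_input_grad
    cb <- conv_bw(cc$conv, p[[paste0("enc", n, ".conv.W")]], bb$gx, need_x)
    grads[[paste0("enc", n, ".conv.W")]] <- cb$gW
    grads[[paste0("enc", n, ".conv.b")]] <- cb$gb
    if (n > 1) {
      gin <- cb$gx
      if (cfg$use_wavelet) {
        sp <- concat_bw(cc$concat, gin)
        gin <- sp$ga
        pb <- conv_bw(cc$proj, p[[paste0("proj", n - 1, ".W")]], sp$gb,
                      need_xgrad = TRUE)
        grads[[paste0("proj", n - 1, ".W")]] <- pb$gW
        grads[[paste0("proj", n - 1, ".b")]] <- pb$gb
        sab <- sa_bw(cc$sa, list(W1 = p[[paste0("sa", n - 1, ".W1")]],
                                 b1 = p[[paste0("sa", n - 1, ".b1")]],
                                 W2 = p[[paste0("sa", n - 1, ".W2")]],
                                 b2 = p[[paste0("sa", n - 1, ".b2")]]),
                     pb$gx)
        grads[[paste0("sa", n - 1, ".W1")]] <- sab$dW1
        grads[[paste0("sa", n - 1, ".b1")]] <- sab$db1
        grads[[paste0("sa", n - 1, ".W2")]] <- sab$dW2
        grads[[paste0("sa", n - 1, ".b2")]] <- sab$db2
      }
      pg <- avgpool2_bw(cc$pool, gin)
      feat_grad[[n - 1]] <- feat_grad[[n - 1]] + pg
    } else if (need_input_grad) {
      gx <- cb$gx
      dim(gx) <- d
    }
  }
  list(grads = grads, gx = gx)
}

#' Split parameters into adaptable and frozen sets
#'
#' Adaptable = every sub-band attention parameter plus every batch-norm
#' affine parameter; frozen = everything else. Refuses models without both
#' component kinds (a silent empty partition would disable adaptation).
#'
#' @param model A `wavnet_model` built by [build_wavnet()].
#' @return List with character vectors `adaptable` and `frozen`.
#' @export
partition_parameters <- function(model) {
  nms <- names(model$params)
  sa <- grepl("^sa[0-9]+\\.", nms)
  bn <- grepl("\\.bn\\.(gamma|beta)$", nms)
  if (!any(sa)) stop("model has no sub-band attention parameters; ",
                     "refusing an empty adaptable partition")
  if (!any(bn)) stop("model has no batch-normalization parameters")
  list(adaptable = nms[sa | bn], frozen = nms[!(sa | bn)])
}

#' Count parameters in a model or a named subset
#' @param model A `wavnet_model`.
#' @param names Optional subset of parameter names.
#' @return Integer count of scalar parameters.
#' @export
count_parameters <- function(model, names = NULL) {
  nms <- if (is.null(names)) base::names(model$params) else names
  sum(vapply(model$params[nms], length, integer(1)))
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding parameters, configuration, wavelet family,
#' running BN statistics, the source-domain class-ratio prior (if any) and
#' the parameter partition, under a versioned schema.
#'
#' @param model A `wavnet_model`.
#' @param path File path.
#' @param prior Optional class-ratio prior to store.
#' @param extra Optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, prior = NULL, extra = list()) {
  partition <- tryCatch(partition_parameters(model), error = function(e) NULL)
  obj <- c(list(schema = 1L, params = model$params, config = model$config,
                wavelet_family = model$filters$family_name,
                bn_running = model$bn_running, prior = prior,
                partition = partition), extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return For `load_checkpoint`: list with `model`, `prior` and any extra
#'   fields.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  stopifnot(identical(obj$schema, 1L))
  model <- structure(list(params = obj$params, config = obj$config,
                          filters = wavelet_filters(obj$wavelet_family),
                          bn_running = obj$bn_running),
                     class = "wavnet_model")
  c(list(model = model), obj[setdiff(names(obj),
                                     c("schema", "params", "config",
                                       "wavelet_family", "bn_running"))])
}
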