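#' Source-training configuration
#'
#' @param epochs Training epochs (full-scale profile: 2000; the CPU desk
#'   profile uses ~120 with a proportionally larger learning rate).
#' @param learning_rate SGD learning rate (full-scale profile: 5e-4).
#' @param momentum SGD momentum.
#' @param seed RNG seed for initialization and epoch shuffling.
#' @return A `source_config` list (batch size is always 1).
#' @export
source_config <- function(epochs = 2000L, learning_rate = 5e-4,
                          momentum = 0.9, seed = 0L) {
  stopifnot(epochs >= 0, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), batch_size = 1L,
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "source_config")
}

#' Test-time adaptation configuration
#'
#' @param iterations Gradient steps on the single test sample (default 200;
#'   0 gives the no-adaptation baseline).
#' @param learning_rate SGD learning rate (default 5e-4).
#' @param momentum SGD momentum.
#' @param weights A [loss_weights()].
#' @param ablation Enabled loss terms, subset of `c("en", "sh", "re")`.
#' @param seed RNG seed (adaptation itself is deterministic; kept for
#'   manifest completeness).
#' @return A `tta_config` list.
#' @export
tta_config <- function(iterations = 200L, learning_rate = 5e-4,
                       momentum = 0.9, weights = loss_weights(),
                       ablation = c("en", "sh", "re"), seed = 0L) {
  stopifnot(iterations >= 0)
  ablation <- match.arg(ablation, c("en", "sh", "re"), several.ok = TRUE)
  structure(list(iterations = as.integer(iterations),
                 learning_rate = learning_rate, momentum = momentum,
                 weights = weights, ablation = ablation,
                 seed = as.integer(seed)),
            class = "tta_config")
}

.check_finite <- function(x, what, where) {
  if (any(!is.finite(x))) {
    stop("non-finite ", what, " at ", where, "; aborting")
  }
}

#' Train the segmenter on labeled source volumes
#'
#' Supervised Dice-loss training at batch size 1 with every parameter
#' unfrozen; running batch-norm statistics are accumulated for later
#' eval-mode inference. Also computes the source class-ratio prior as the
#' mean per-sample foreground fraction of the training labels.
#'
#' @param model A `wavnet_model` (its current parameters are the starting
#'   point).
#' @param volumes List of 3D arrays.
#' @param labels List of binary 3D arrays.
#' @param config A [source_config()].
#' @param snapshot_epochs Integer vector; a deep copy of the model is kept
#'   after each listed epoch (used to harvest undertrained models from a
#'   single run).
#' @return List: `model`, `prior` (a [class_ratio_prior()]), `history`
#'   (per-epoch mean Dice loss), `snapshots` (named list of models).
#' @export
train_source <- function(model, volumes, labels, config = source_config(),
                         snapshot_epochs = integer(0)) {
  stopifnot(length(volumes) >= 1, length(volumes) == length(labels))
  prior <- class_ratio_prior(mean(vapply(labels, mean, numeric(1))))
  history <- numeric(0)
  snapshots <- list()
  if (config$epochs > 0) {
    withr::with_seed(config$seed, {
      st <- sgd_state(config$learning_rate, config$momentum)
      for (ep in seq_len(config$epochs)) {
        ord <- sample.int(length(volumes))
        losses <- numeric(length(ord))
        for (ii in seq_along(ord)) {
          i <- ord[ii]
          fw <- wavnet_forward(model, volumes[[i]], mode = "sample",
                               update_running = TRUE, need_cache = TRUE)
          model <- fw$model
          l <- dice_loss(fw$prob, labels[[i]])
          .check_finite(l, "Dice loss", paste0("epoch ", ep, ", sample ", i))
          bw <- wavnet_backward(model, fw$cache, .dice_grad(fw$prob, labels[[i]]))
          up <- sgd_step(model$params, bw$grads, st)
          model$params <- up$params
          st <- up$state
          losses[ii] <- l
        }
        history <- c(history, mean(losses))
        if (ep %in% snapshot_epochs) snapshots[[as.character(ep)]] <- model
      }
    })
  }
  list(model = model, prior = prior, history = history, snapshots = snapshots)
}

#' Generate undertrained segmentations for Refine training
#'
#' Trains early-stopped segmenters and collects their (imperfect)
#' predictions on every source sample, paired with the ground-truth labels.
#' By default the undertrained models are snapshots of one seeded training
#' run; `independent = TRUE` trains one fresh model per stop epoch instead.
#'
#' @param volumes,labels Source training data.
#' @param schedule Strictly increasing stop epochs (default
#'   `c(30, 40, 50, 60, 70, 80)`).
#' @param config A [source_config()]; `config$epochs` must exceed
#'   `max(schedule)` (it bounds the training length the stops are taken
#'   from).
#' @param independent Train separate models per stop epoch.
#' @param model_config [wavnet_config()] used to build the undertrained
#'   models.
#' @return List of `list(noisy, label)` pairs, `length(schedule) *
#'   length(volumes)` of them.
#' @export
generate_undertrained_segmentations <- function(volumes, labels,
                                                schedule = c(30L, 40L, 50L, 60L, 70L, 80L),
                                                config = source_config(),
                                                independent = FALSE,
                                                model_config = wavnet_config()) {
  schedule <- as.integer(schedule)
  if (length(schedule) == 0 || any(diff(schedule) <= 0) || any(schedule < 1)) {
    stop("schedule must be a strictly increasing vector of positive epochs")
  }
  if (max(schedule) >= config$epochs) {
    stop("stop epoch ", max(schedule), " exceeds the training length (",
         config$epochs, " epochs)")
  }
  models <- list()
  if (independent) {
    for (s in schedule) {
      cfg_s <- config
      cfg_s$epochs <- s
      mdl <- withr::with_seed(config$seed + s, build_wavnet(model_config))
      models[[as.character(s)]] <- train_source(mdl, volumes, labels, cfg_s)$model
    }
  } else {
    cfg_s <- config
    cfg_s$epochs <- max(schedule)
    mdl <- withr::with_seed(config$seed, build_wavnet(model_config))
    models <- train_source(mdl, volumes, labels, cfg_s,
                           snapshot_epochs = schedule)$snapshots
  }
  corpus <- list()
  for (s in as.character(schedule)) {
    for (i in seq_along(volumes)) {
      pred <- wavnet_forward(models[[s]], volumes[[i]], mode = "eval")$prob
      corpus[[length(corpus) + 1L]] <- list(noisy = pred, label = labels[[i]],
                                            stop_epoch = as.integer(s))
    }
  }
  corpus
}

#' Train the Refine reconstruction model
#'
#' Minimizes the mean squared error between the Refine output on a corrupted
#' segmentation and the corresponding ground-truth label.
#'
#' @param refine_model A model from [build_refine_model()].
#' @param corpus List of `list(noisy, label)` pairs.
#' @param epochs Training epochs (full-scale profile: 1000).
#' @param learning_rate,momentum SGD settings.
#' @param seed Epoch-shuffle seed.
#' @return List: `model`, `history` (per-epoch mean MSE).
#' @export
train_refine <- function(refine_model, corpus, epochs = 1000L,
                         learning_rate = 5e-4, momentum = 0.9, seed = 0L) {
  if (length(corpus) == 0) stop("empty Refine training corpus")
  history <- numeric(0)
  withr::with_seed(seed, {
    st <- sgd_state(learning_rate, momentum)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(corpus))
      losses <- numeric(length(ord))
      for (ii in seq_along(ord)) {
        pair <- corpus[[ord[ii]]]
        fw <- wavnet_forward(refine_model, pair$noisy, mode = "sample",
                             update_running = TRUE, need_cache = TRUE)
        refine_model <- fw$model
        d <- fw$prob - pair$label
        l <- mean(d^2)
        .check_finite(l, "Refine MSE", paste0("epoch ", ep))
        bw <- wavnet_backward(refine_model, fw$cache, (2 / length(d)) * d)
        up <- sgd_step(refine_model$params, bw$grads, st)
        refine_model$params <- up$params
        st <- up$state
        losses[ii] <- l
      }
      history <- c(history, mean(losses))
    }
  })
  list(model = refine_model, history = history)
}

#' Adapt the segmenter to one unlabeled test volume
#'
#' Starts fresh from the source checkpoint, freezes everything except the
#' sub-band attention and batch-norm affine parameters, and minimizes the
#' hybrid objective for a fixed number of SGD steps on this single sample.
#' Batch-norm layers use the test volume's own statistics during adaptation
#' (running statistics are left untouched); the no-adaptation baseline
#' (`iterations = 0`) is the eval-mode source prediction.
#'
#' @param checkpoint List with `model` and `prior` (as returned by
#'   [train_source()] or [load_checkpoint()]).
#' @param refine_model A trained Refine model (or a function stand-in);
#'   required when `"re"` is enabled. Frozen throughout.
#' @param test_volume 3D array.
#' @param config A [tta_config()].
#' @return List: `model` (adapted), `prob` (final segmentation),
#'   `baseline_prob` (unadapted eval-mode prediction), `trace` (data.frame
#'   iteration / L_en / L_sh / L_re / L_total), `sa_weights`.
#' @export
adapt_single_sample <- function(checkpoint, refine_model = NULL, test_volume,
                                config = tta_config()) {
  model <- checkpoint$model
  prior <- checkpoint$prior
  if ("re" %in% config$ablation && is.null(refine_model)) {
    stop("the refine ('re') term is enabled but no refine model was given")
  }
  baseline <- wavnet_forward(model, test_volume, mode = "eval")$prob
  trace <- data.frame(iteration = integer(0), L_en = numeric(0),
                      L_sh = numeric(0), L_re = numeric(0),
                      L_total = numeric(0))
  if (config$iterations == 0) {
    return(list(model = model, prob = baseline, baseline_prob = baseline,
                trace = trace, sa_weights = NULL))
  }
  part <- partition_parameters(model)
  st <- sgd_state(config$learning_rate, config$momentum)
  w <- config$weights
  ab <- config$ablation
  sa_w <- NULL
  for (it in seq_len(config$iterations)) {
    fw <- wavnet_forward(model, test_volume, mode = "sample", need_cache = TRUE)
    p <- fw$prob
    sa_w <- fw$sa_weights
    terms <- c(en = NA_real_, sh = NA_real_, re = NA_real_)
    total <- 0
    dP <- array(0, dim(p))
    if ("en" %in% ab) {
      terms[["en"]] <- entropy_loss(p)
      total <- total + w$lambda1 * terms[["en"]]
      dP <- dP + w$lambda1 * .entropy_grad(p)
    }
    if ("sh" %in% ab) {
      terms[["sh"]] <- shape_aware_loss(p, prior)
      total <- total + w$lambda2 * terms[["sh"]]
      dP <- dP + w$lambda2 * .shape_grad(p, prior)
    }
    if ("re" %in% ab) {
      vg <- .refine_loss_vg(p, refine_model)
      terms[["re"]] <- vg$value
      total <- total + vg$value
      dP <- dP + vg$grad
    }
    for (nm in names(terms)) {
      if (!is.na(terms[[nm]]) && !is.finite(terms[[nm]])) {
        stop("non-finite loss term '", nm, "' at iteration ", it, "; aborting")
      }
    }
    .check_finite(total, "total loss", paste0("iteration ", it))
    trace <- rbind(trace, data.frame(iteration = it, L_en = terms[["en"]],
                                     L_sh = terms[["sh"]], L_re = terms[["re"]],
                                     L_total = total))
    bw <- wavnet_backward(model, fw$cache, dP)
    up <- sgd_step(model$params, bw$grads, st, names = part$adaptable)
    model$params <- up$params
    st <- up$state
  }
  final <- wavnet_forward(model, test_volume, mode = "sample")$prob
  list(model = model, prob = final, baseline_prob = baseline, trace = trace,
       sa_weights = sa_w)
}

#' Default six loss combinations of the ablation study
#' @return Named list of ablation flag vectors.
#' @export
ablation_combos <- function() {
  list(en = "en", sh = "sh", re = "re",
       `en+sh` = c("en", "sh"), `sh+re` = c("sh", "re"),
       total = c("en", "sh", "re"))
}

#' Run the loss-combination ablation over a test set
#'
#' Adapts every test volume once per loss combination (fresh start each
#' time) and tabulates Dice and HD95 against the labels.
#'
#' @param checkpoint Source checkpoint (`model` + `prior`).
#' @param refine_model Trained Refine model.
#' @param test_volumes,test_labels Lists of target volumes and their labels.
#' @param combos Named list of ablation flag vectors (default the six
#'   standard combinations).
#' @param config Base [tta_config()]; its `ablation` field is overridden per
#'   combination.
#' @param spacing Voxel spacing in mm for HD95.
#' @return `data.frame`: combo, n, dice_mean, dice_sd, hd95_mean, hd95_sd,
#'   plus a `per_sample` attribute with per-volume rows.
#' @export
run_ablation <- function(checkpoint, refine_model, test_volumes, test_labels,
                         combos = ablation_combos(), config = tta_config(),
                         spacing = c(1, 1, 1)) {
  stopifnot(length(test_volumes) == length(test_labels))
  rows <- list()
  per <- list()
  for (cname in names(combos)) {
    cfg <- config
    cfg$ablation <- combos[[cname]]
    dices <- numeric(length(test_volumes))
    hds <- numeric(length(test_volumes))
    for (i in seq_along(test_volumes)) {
      res <- adapt_single_sample(checkpoint, refine_model, test_volumes[[i]], cfg)
      m <- binarize(res$prob)
      dices[i] <- dice_coefficient(m, test_labels[[i]])
      hds[i] <- hd95(m, test_labels[[i]], spacing)
      per[[length(per) + 1L]] <- data.frame(combo = cname, sample = i,
                                            dice = dices[i], hd95 = hds[i])
    }
    rows[[cname]] <- data.frame(combo = cname, n = length(dices),
                                dice_mean = mean(dices),
                                dice_sd = stats::sd(dices),
                                hd95_mean = mean(hds, na.rm = TRUE),
                                hd95_sd = stats::sd(hds[is.finite(hds)]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_sample") <- do.call(rbind, per)
  out
}
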