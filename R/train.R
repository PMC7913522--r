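#' Regression training loss
#'
#' Mean squared error between subjective and objective score vectors,
#' \eqn{L = \frac{1}{N}\sum_n (q^s_n - q^o_n)^2}{L = mean((qs - qo)^2)},
#' optionally scaled by 1/2 (`half = TRUE`), the convention some
#' frameworks use for regression output layers. The factor only rescales
#' gradients, so the plain form is the default.
#'
#' @param qs Subjective scores.
#' @param qo Objective (predicted) scores, same length.
#' @param half Multiply by 1/2?
#' @return Non-negative scalar; zero iff the vectors are equal.
#' @export
mse_loss <- function(qs, qo, half = FALSE) {
  if (length(qs) != length(qo)) stop_mriqa("`qs` and `qo` must have equal length")
  if (!length(qs)) stop_mriqa("empty score vectors")
  l <- mean((qs - qo)^2)
  if (half) l / 2 else l
}

#' Training configuration
#'
#' Stochastic gradient descent with momentum (SGDM). The defaults are the
#' standard fine-tuning recipe for ImageNet-pretrained fusions: learning
#' rate 1e-4, mini-batch 32, 5 epochs; momentum 0.9 is the conventional
#' SGDM value. For tiny randomly initialized backbones a larger learning
#' rate (0.02, calibrated on training-loss descent) is appropriate, as
#' there are no pretrained weights whose preservation would call for a
#' small step size.
#'
#' @param learning_rate Positive step size.
#' @param batch_size Mini-batch size (`>= 1`).
#' @param epochs Number of passes over the (already augmented) training
#'   set (`>= 1`).
#' @param momentum SGDM momentum in `[0, 1)`.
#' @param seed Seed for per-epoch shuffling.
#' @param freeze_backbones If `TRUE`, only the head is updated.
#' @param half_loss Use the half-MSE variant of [mse_loss()].
#' @return A `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 32L,
                            epochs = 5L, momentum = 0.9, seed = 1L,
                            freeze_backbones = FALSE, half_loss = FALSE) {
  if (learning_rate < 0) stop_mriqa("`learning_rate` must be >= 0")
  if (epochs < 1) stop_mriqa("`epochs` must be >= 1")
  if (batch_size < 1) stop_mriqa("`batch_size` must be >= 1")
  if (momentum < 0 || momentum >= 1) stop_mriqa("`momentum` must be in [0, 1)")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), momentum = momentum,
                 seed = as.integer(seed),
                 freeze_backbones = isTRUE(freeze_backbones),
                 half_loss = isTRUE(half_loss)),
            class = "training_config")
}

zero_like_grads <- function(bb) {
  lapply(bb$layers, function(l)
    if (l$type == "conv")
      list(dW = matrix(0, nrow(l$W_mat), ncol(l$W_mat)),
           db = numeric(length(l$b)))
    else NULL)
}

#' Jointly fine-tune a fusion network
#'
#' Minimizes the (half-)MSE between predicted and subjective scores by
#' mini-batch SGDM, back-propagating through the head into every fused
#' backbone (unless `freeze_backbones`). Mini-batch order is reshuffled
#' each epoch from `cfg$seed`. Results are reproducible for a fixed seed,
#' data, and platform.
#'
#' @param net A `fusion_network`.
#' @param train An `mriqa_dataset` (augment beforehand if desired).
#' @param cfg A [training_config()].
#' @return List with the trained `net` and `history`, a `training_history`
#'   holding the per-epoch mean training loss and a config echo.
#' @export
fine_tune <- function(net, train, cfg = training_config()) {
  if (!inherits(net, "fusion_network")) stop_mriqa("`net` must be a fusion_network")
  if (!inherits(train, "mriqa_dataset") || !length(train))
    stop_mriqa("`train` must be a non-empty mriqa_dataset")
  if (!inherits(cfg, "training_config")) stop_mriqa("`cfg` must be a training_config")
  inputs <- as_network_inputs(train)
  n <- length(inputs)
  qs <- unname(dataset_mos(train))
  # Pre-resize once per backbone; this is where any input-size mixing is
  # absorbed, so the training loop only does linear algebra.
  xmats <- lapply(inputs, function(x)
    lapply(net$backbones, function(bb) input_matrix(x, bb)))
  slices <- fusion_slices(net)
  nb <- length(net$backbones)
  lr <- cfg$learning_rate; mom <- cfg$momentum
  vel <- lapply(net$backbones, zero_like_grads)
  vel_head <- list(w = numeric(net$total_feature_width), b = 0)
  epoch_loss <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      sq_err <- numeric(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        bs <- length(idx)
        g_head_w <- numeric(net$total_feature_width); g_head_b <- 0
        g_bb <- if (!cfg$freeze_backbones) lapply(net$backbones, zero_like_grads)
        for (i in idx) {
          fwd <- lapply(seq_len(nb), function(b)
            backbone_forward(net$backbones[[b]], xmats[[i]][[b]],
                             keep_cache = !cfg$freeze_backbones))
          feat <- unlist(lapply(fwd, `[[`, "out"))
          score <- sum(feat * net$head$w) + net$head$b
          err <- score - qs[i]
          sq_err[i] <- err^2
          dscore <- 2 * err / bs
          if (cfg$half_loss) dscore <- dscore / 2
          g_head_w <- g_head_w + dscore * feat
          g_head_b <- g_head_b + dscore
          if (!cfg$freeze_backbones) {
            dfeat <- dscore * net$head$w
            for (b in seq_len(nb)) {
              gr <- backbone_backward(net$backbones[[b]], fwd[[b]]$caches,
                                      dfeat[slices[[b]]])
              for (li in seq_along(gr)) if (!is.null(gr[[li]])) {
                g_bb[[b]][[li]]$dW <- g_bb[[b]][[li]]$dW + gr[[li]]$dW
                g_bb[[b]][[li]]$db <- g_bb[[b]][[li]]$db + gr[[li]]$db
              }
            }
          }
        }
        # SGDM update
        vel_head$w <- mom * vel_head$w - lr * g_head_w
        vel_head$b <- mom * vel_head$b - lr * g_head_b
        net$head$w <- net$head$w + vel_head$w
        net$head$b <- net$head$b + vel_head$b
        if (!cfg$freeze_backbones) {
          for (b in seq_len(nb)) {
            for (li in seq_along(net$backbones[[b]]$layers)) {
              if (is.null(g_bb[[b]][[li]])) next
              vel[[b]][[li]]$dW <- mom * vel[[b]][[li]]$dW - lr * g_bb[[b]][[li]]$dW
              vel[[b]][[li]]$db <- mom * vel[[b]][[li]]$db - lr * g_bb[[b]][[li]]$db
              net$backbones[[b]]$layers[[li]]$W_mat <-
                net$backbones[[b]]$layers[[li]]$W_mat + vel[[b]][[li]]$dW
              net$backbones[[b]]$layers[[li]]$b <-
                net$backbones[[b]]$layers[[li]]$b + vel[[b]][[li]]$db
            }
          }
        }
      }
      l <- mean(sq_err)
      epoch_loss[ep] <- if (cfg$half_loss) l / 2 else l
    }
  })
  history <- structure(list(epoch_loss = epoch_loss, config = cfg),
                       class = "training_history")
  list(net = net, history = history)
}

#' @export
print.training_history <- function(x, ...) {
  cat(sprintf("<training_history> %d epoch(s); mean loss %s\n",
              length(x$epoch_loss),
              paste(signif(x$epoch_loss, 4), collapse = " -> ")))
  invisible(x)
}
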