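# Training protocol: minibatch binary cross-entropy with the ADAM
# optimizer; batch size 64 and 100 epochs by default.

#' Training configuration
#'
#' @param learning_rate ADAM step size (default 1e-3).
#' @param batch_size Graphs per minibatch (default 64).
#' @param epochs Training epochs (default 100).
#' @param beta1,beta2,eps ADAM moment decay rates and stabilizer.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param verbose Print the per-epoch loss.
#' @return List of class `mg_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64L,
                         epochs = 100L, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, seed = 1L, verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 1L)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "mg_train_config")
}

.zeros_like <- function(p) lapply(p, function(x) {
  if (is.list(x)) .zeros_like(x) else x * 0
})

.adam_update <- function(par, grad, m, v, lr_t, beta1, beta2, eps) {
  for (k in seq_along(par)) {
    if (is.list(par[[k]])) {
      upd <- .adam_update(par[[k]], grad[[k]], m[[k]], v[[k]],
                          lr_t, beta1, beta2, eps)
      par[[k]] <- upd$par; m[[k]] <- upd$m; v[[k]] <- upd$v
    } else {
      m[[k]] <- beta1 * m[[k]] + (1 - beta1) * grad[[k]]
      v[[k]] <- beta2 * v[[k]] + (1 - beta2) * grad[[k]]^2
      par[[k]] <- par[[k]] - lr_t * m[[k]] / (sqrt(v[[k]]) + eps)
    }
  }
  list(par = par, m = m, v = v)
}

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the graph classification model
#'
#' Minibatch binary cross-entropy with ADAM. Deterministic for a fixed
#' seed on a fixed platform. Aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param samples List of labelled `mg_graph` training samples.
#' @param config Model architecture from [model_config()].
#' @param train_cfg Protocol from [train_config()].
#' @return A trained `mg_model`; the per-epoch mean training loss is in
#'   attribute/list element `loss_log`.
#' @export
train_model <- function(samples, config = model_config(),
                        train_cfg = train_config()) {
  stopifnot(length(samples) > 0L)
  y_all <- vapply(samples, function(s) as.numeric(s$y), 0)
  if (anyNA(y_all)) stop("all training samples must carry a 0/1 label")
  model <- init_model(config, seed = train_cfg$seed)
  m_st <- .zeros_like(list(layers = model$layers, head = model$head))
  v_st <- .zeros_like(list(layers = model$layers, head = model$head))
  step <- 0L
  loss_log <- numeric(train_cfg$epochs)
  .with_local_seed(train_cfg$seed + 1L, {
    for (ep in seq_len(train_cfg$epochs)) {
      ord <- sample.int(length(samples))
      batches <- batch_graphs(samples[ord], train_cfg$batch_size)
      ep_loss <- 0
      for (b in batches) {
        fwd <- forward_model(model, b, training = TRUE, keep_cache = TRUE)
        loss <- .bce(fwd$p, b$y)
        if (!is.finite(loss)) {
          stop(sprintf("training diverged: non-finite loss at epoch %d", ep))
        }
        ep_loss <- ep_loss + loss * b$n_graphs
        grads <- .model_backward(model, fwd, b$y)
        step <- step + 1L
        lr_t <- train_cfg$learning_rate *
          sqrt(1 - train_cfg$beta2^step) / (1 - train_cfg$beta1^step)
        upd <- .adam_update(list(layers = model$layers, head = model$head),
                            grads, m_st, v_st, lr_t,
                            train_cfg$beta1, train_cfg$beta2, train_cfg$eps)
        model$layers <- upd$par$layers
        model$head <- upd$par$head
        m_st <- upd$m; v_st <- upd$v
        if (config$head == "conv") {
          # batch-norm running statistics (momentum 0.1)
          hc <- fwd$caches$head
          model$bn_stats$mean <- 0.9 * model$bn_stats$mean + 0.1 * hc$mu
          model$bn_stats$var <- 0.9 * model$bn_stats$var +
            0.1 * (hc$sd^2 - 1e-5)
          model$n_updates <- model$n_updates + 1L
        }
      }
      loss_log[ep] <- ep_loss / length(samples)
      if (train_cfg$verbose) {
        message(sprintf("epoch %3d  loss %.5f", ep, loss_log[ep]))
      }
    }
  })
  model$loss_log <- loss_log
  model
}

#' Save / load a trained model
#'
#' The model is serialized with `saveRDS` next to a JSON sidecar recording
#' the architecture configuration.
#'
#' @param model A trained `mg_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- sub("\\.rds$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(unclass(model$config), side, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
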