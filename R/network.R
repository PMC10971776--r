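# The graph classification network: four multi-head graph-attention layers
# with graph normalization, a mean readout over all nodes (both
# disconnected chains), and either a two-layer 1-D convolution head with
# batch normalization and an identity skip connection feeding a sigmoid
# fully-connected classifier, or a plain linear head (the GAT-only
# ablation).
#
# Forward and reverse passes are written directly in vectorized base R:
# per-destination softmax attention is computed with grouped row sums, and
# every layer's analytic gradient is verified against finite differences
# in the test suite.

#' Model configuration
#'
#' @param gat_layers Number of stacked graph-attention layers (default 4).
#' @param attention_heads Attention heads per layer (default 8).
#' @param gat_hidden Per-head hidden width (default 32).
#' @param conv_layers 1-D convolution layers in the head (fixed at 2).
#' @param conv_channels Convolution channels (default 16).
#' @param conv_kernel Odd kernel width (default 3).
#' @param dropout Attention-weight dropout probability (default 0.1).
#' @param use_edge_features Feed bond features into attention (default
#'   TRUE).
#' @param head One of "conv" (full model) or "linear" (GAT-only ablation).
#' @param input_dim Node feature width (default 31).
#' @param edge_dim Edge feature width (default 12).
#' @return List of class `mg_model_config`.
#' @export
model_config <- function(gat_layers = 4L, attention_heads = 8L,
                         gat_hidden = 32L, conv_layers = 2L,
                         conv_channels = 16L, conv_kernel = 3L,
                         dropout = 0.1, use_edge_features = TRUE,
                         head = c("conv", "linear"),
                         input_dim = 31L, edge_dim = 12L) {
  head <- match.arg(head)
  stopifnot(gat_layers >= 1L, attention_heads >= 1L, gat_hidden >= 1L,
            conv_channels >= 1L, conv_kernel %% 2L == 1L,
            dropout >= 0, dropout < 1)
  structure(list(gat_layers = gat_layers, attention_heads = attention_heads,
                 gat_hidden = gat_hidden, conv_layers = conv_layers,
                 conv_channels = conv_channels, conv_kernel = conv_kernel,
                 dropout = dropout, use_edge_features = use_edge_features,
                 head = head, input_dim = input_dim, edge_dim = edge_dim),
            class = "mg_model_config")
}

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize model parameters
#'
#' @param config From [model_config()].
#' @param seed Integer seed for the Glorot-uniform initialization.
#' @return List of class `mg_model` holding parameters, the config, and
#'   batch-norm running statistics.
#' @export
init_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "mg_model_config"))
  .with_local_seed(seed, {
    H <- config$attention_heads; K <- config$gat_hidden; D <- H * K
    layers <- vector("list", config$gat_layers)
    fin <- config$input_dim
    for (l in seq_len(config$gat_layers)) {
      layers[[l]] <- list(
        W = .glorot(fin, D),
        U = .glorot(config$edge_dim, D),
        a_dst = .glorot(D, 1)[, 1],
        a_src = .glorot(D, 1)[, 1],
        a_edge = .glorot(D, 1)[, 1],
        b = numeric(D),
        # the mean-scale starts at 0.5, not 1: with full centering the
        # per-graph mean of every feature is exactly zero, so a mean
        # readout of the final layer would carry no first-moment signal
        gn_gamma = rep(1, D), gn_beta = numeric(D), gn_alpha = rep(0.5, D)
      )
      fin <- D
    }
    ch <- config$conv_channels; k <- config$conv_kernel
    head <- if (config$head == "conv") {
      stopifnot(D %% 2L == 0L)
      list(K1 = .glorot(k, ch), bc1 = numeric(ch),
           bn_gamma = rep(1, ch), bn_beta = numeric(ch),
           K2 = .glorot(k * ch, ch), bc2 = numeric(ch),
           w_fc = .glorot(D %/% 2L * ch, 1), b_fc = 0)
    } else {
      list(w_fc = .glorot(D, 1), b_fc = 0)
    }
    structure(list(config = config, layers = layers, head = head,
                   bn_stats = list(mean = numeric(config$conv_channels),
                                   var = rep(1, config$conv_channels)),
                   n_updates = 0L),
              class = "mg_model")
  })
}

# --- batch preparation -----------------------------------------------------

# Append self-loops (zero edge features) so every node, including isolated
# ones, attends to itself.
.prepare_batch <- function(batch) {
  n <- nrow(batch$x)
  src <- c(batch$edge_index[1, ], seq_len(n))
  dst <- c(batch$edge_index[2, ], seq_len(n))
  ef <- rbind(batch$edge_attr,
              matrix(0, n, ncol(batch$edge_attr)))
  list(x = batch$x, src = src, dst = dst, ef = ef, n = n,
       graph_id = batch$graph_id, n_graphs = batch$n_graphs,
       ng = tabulate(batch$graph_id, batch$n_graphs),
       y = batch$y)
}

.expand_heads <- function(m, heads, per_head) {
  m[, rep(seq_len(heads), each = per_head), drop = FALSE]
}

# --- GAT layer -------------------------------------------------------------

# The attention logits use only per-head scalar projections of the node
# and edge embeddings, so the three attention maps are folded into small
# (F x H) / (edge_dim x H) matrices: per-edge work at full width H*K is
# limited to the message path.
.gat_forward <- function(par, X, pb, config, training, Bmat) {
  H <- config$attention_heads; K <- config$gat_hidden; D <- H * K
  src <- pb$src; dst <- pb$dst; n <- pb$n
  Wh <- X %*% par$W
  W1 <- (par$W * rep(par$a_dst, each = nrow(par$W))) %*% Bmat
  W2 <- (par$W * rep(par$a_src, each = nrow(par$W))) %*% Bmat
  S <- .mg_edge_scores(X %*% W1, X %*% W2, src, dst)
  if (config$use_edge_features) {
    W3 <- (par$U * rep(par$a_edge, each = nrow(par$U))) %*% Bmat
    S <- S + pb$ef %*% W3
  }
  if (anyNA(S)) stop("training diverged: non-finite attention scores")
  lneg <- S < 0
  L <- S
  L[lneg] <- 0.2 * S[lneg]
  A <- .mg_softmax_dst(L, dst, n)
  if (training && config$dropout > 0) {
    mask <- (stats::runif(length(A)) >= config$dropout) / (1 - config$dropout)
    dim(mask) <- dim(A)
    Ad <- A * mask
  } else {
    mask <- NULL
    Ad <- A
  }
  agg <- .mg_aggregate(Wh, Ad, src, dst, K)
  # graph normalization before the ELU activation (a mean readout of a
  # per-graph standardized representation would otherwise be constant)
  gn <- .mg_gn_elu(agg, par$b, pb$graph_id, pb$ng, pb$n_graphs,
                   par$gn_alpha, par$gn_gamma, par$gn_beta)
  list(out = gn$out,
       cache = list(X = X, Wh = Wh, lneg = lneg, A = A,
                    mask = mask, Ad = Ad, out = gn$out, vhat = gn$vhat,
                    mu = gn$mu, sd = gn$sd))
}

.gat_backward <- function(par, cache, dOut, pb, config, Bmat) {
  H <- config$attention_heads; K <- config$gat_hidden; D <- H * K
  src <- pb$src; dst <- pb$dst; n <- pb$n
  # ELU + GraphNorm backward (fused)
  gb <- .mg_gn_elu_bwd(dOut, cache$out, cache$vhat, cache$mu, cache$sd,
                       pb$graph_id, pb$ng, pb$n_graphs,
                       par$gn_alpha, par$gn_gamma)
  d_gamma <- gb$d_gamma; d_beta <- gb$d_beta
  d_alpha <- gb$d_alpha; d_b <- gb$d_b
  # aggregation backward
  ab <- .mg_aggregate_bwd(gb$dAgg, cache$Wh, cache$Ad, src, dst, K)
  dWh <- ab$dWh
  dA <- if (is.null(cache$mask)) ab$dAd else ab$dAd * cache$mask
  # softmax backward (per destination, per head)
  dL <- .mg_softmax_dst_bwd(cache$A, dA, dst, n)
  dS <- dL
  dS[cache$lneg] <- 0.2 * dL[cache$lneg]
  # attention-score backward through the folded projections
  dP_dst <- .group_rowsum(dS, dst, n)
  dP_src <- .group_rowsum(dS, src, n)
  W1 <- (par$W * rep(par$a_dst, each = nrow(par$W))) %*% Bmat
  W2 <- (par$W * rep(par$a_src, each = nrow(par$W))) %*% Bmat
  dW1 <- crossprod(cache$X, dP_dst)
  dW2 <- crossprod(cache$X, dP_src)
  hd <- rep(seq_len(H), each = K)
  a_dst_m <- rep(par$a_dst, each = nrow(par$W))
  a_src_m <- rep(par$a_src, each = nrow(par$W))
  dW <- crossprod(cache$X, dWh) +
    dW1[, hd, drop = FALSE] * a_dst_m + dW2[, hd, drop = FALSE] * a_src_m
  d_a_dst <- colSums(par$W * dW1[, hd, drop = FALSE])
  d_a_src <- colSums(par$W * dW2[, hd, drop = FALSE])
  if (config$use_edge_features) {
    W3 <- (par$U * rep(par$a_edge, each = nrow(par$U))) %*% Bmat
    dW3 <- crossprod(pb$ef, dS)
    dU <- dW3[, hd, drop = FALSE] * rep(par$a_edge, each = nrow(par$U))
    d_a_edge <- colSums(par$U * dW3[, hd, drop = FALSE])
  } else {
    dU <- matrix(0, config$edge_dim, D)
    d_a_edge <- numeric(D)
  }
  dX <- dWh %*% t(par$W) + dP_dst %*% t(W1) + dP_src %*% t(W2)
  list(dX = dX,
       grads = list(W = dW, U = dU, a_dst = d_a_dst, a_src = d_a_src,
                    a_edge = d_a_edge, b = d_b,
                    gn_gamma = d_gamma, gn_beta = d_beta,
                    gn_alpha = d_alpha))
}

# --- readout ---------------------------------------------------------------

#' Mean readout over each graph's nodes
#'
#' @param node_feats Node feature/embedding matrix.
#' @param graph_id Per-node graph membership (1-based).
#' @param n_graphs Number of graphs in the batch.
#' @return `n_graphs x ncol(node_feats)` matrix of per-graph means.
#' @export
readout_mean <- function(node_feats, graph_id, n_graphs) {
  ng <- as.numeric(table(factor(graph_id, levels = seq_len(n_graphs))))
  if (any(ng == 0)) stop("readout of an empty graph")
  .group_rowsum(node_feats, graph_id, n_graphs) / ng
}

# --- convolution head ------------------------------------------------------

.shift_fwd <- function(v, G) c(numeric(G), v[seq_len(length(v) - G)])
.shift_bwd <- function(v, G) c(v[-seq_len(G)], numeric(G))
.shift_fwd_m <- function(m, G) {
  out <- matrix(0, nrow(m), ncol(m))
  out[-seq_len(G), ] <- m[seq_len(nrow(m) - G), ]
  out
}
.shift_bwd_m <- function(m, G) {
  out <- matrix(0, nrow(m), ncol(m))
  out[seq_len(nrow(m) - G), ] <- m[-seq_len(G), ]
  out
}

.conv_head_forward <- function(par, r, model, training) {
  G <- nrow(r); C <- ncol(r)
  v <- as.vector(r)                      # (G*C), column-major: node g, pos t
  Xun <- cbind(.shift_fwd(v, G), v, .shift_bwd(v, G))
  Y1 <- sweep(Xun %*% par$K1, 2, par$bc1, `+`)
  if (training) {
    mu <- colMeans(Y1)
    va <- colMeans(sweep(Y1, 2, mu)^2)
  } else {
    mu <- model$bn_stats$mean
    va <- model$bn_stats$var
  }
  sd <- sqrt(va + 1e-5)
  Yc <- sweep(Y1, 2, mu)
  Yhat <- sweep(Yc, 2, sd, `/`)
  Z0 <- sweep(sweep(Yhat, 2, par$bn_gamma, `*`), 2, par$bn_beta, `+`)
  Z <- pmax(Z0, 0)
  Zun <- cbind(.shift_fwd_m(Z, G), Z, .shift_bwd_m(Z, G))
  Y2 <- sweep(Zun %*% par$K2, 2, par$bc2, `+`)
  Y2s <- Y2 + v                           # identity skip, broadcast over channels
  # average pooling (window 2, stride 2) then a fully-connected sigmoid
  # unit over all pooled channel/position features
  C2 <- C %/% 2L
  pos <- rep(rep(seq_len(C2), each = 2L), each = G)
  pool_id <- rep_len(seq_len(G), G * C) + (pos - 1L) * G
  q <- .group_rowsum(Y2s, pool_id, G * C2) / 2
  qf <- q
  dim(qf) <- c(G, C2 * ncol(Y2s))
  logit <- (qf %*% par$w_fc)[, 1] + par$b_fc
  list(logit = logit,
       cache = list(r = r, v = v, Xun = Xun, Y1 = Y1, mu = mu, sd = sd,
                    Yhat = Yhat, Z0 = Z0, Z = Z, Zun = Zun, qf = qf,
                    G = G, C = C, C2 = C2, pool_id = pool_id,
                    training = training))
}

.conv_head_backward <- function(par, cache, dlogit) {
  G <- cache$G; C <- cache$C; C2 <- cache$C2
  dqf <- matrix(dlogit, G, 1) %*% t(par$w_fc)
  d_wfc <- crossprod(cache$qf, matrix(dlogit, ncol = 1))
  d_bfc <- sum(dlogit)
  ch <- ncol(cache$Z)
  dq <- dqf
  dim(dq) <- c(G * C2, ch)
  dY2s <- dq[cache$pool_id, , drop = FALSE] / 2
  dv <- rowSums(dY2s)                     # skip path
  dY2 <- dY2s
  d_K2 <- crossprod(cache$Zun, dY2)
  d_bc2 <- colSums(dY2)
  dZun <- dY2 %*% t(par$K2)
  ch <- ncol(cache$Z)
  dZ <- dZun[, ch + seq_len(ch), drop = FALSE] +
    .shift_bwd_m(dZun[, seq_len(ch), drop = FALSE], G) +
    .shift_fwd_m(dZun[, 2 * ch + seq_len(ch), drop = FALSE], G)
  dZ0 <- dZ * (cache$Z0 > 0)
  d_bn_gamma <- colSums(dZ0 * cache$Yhat)
  d_bn_beta <- colSums(dZ0)
  dYhat <- sweep(dZ0, 2, par$bn_gamma, `*`)
  if (cache$training) {
    nB <- nrow(dYhat)
    dY1 <- sweep(dYhat, 2, cache$sd, `/`) -
      sweep(matrix(colMeans(dYhat), nB, ncol(dYhat), byrow = TRUE),
            2, cache$sd, `/`) -
      cache$Yhat * matrix(colMeans(dYhat * cache$Yhat), nB, ncol(dYhat),
                          byrow = TRUE) / matrix(cache$sd, nB, ncol(dYhat),
                                                 byrow = TRUE)
  } else {
    dY1 <- sweep(dYhat, 2, cache$sd, `/`)
  }
  d_K1 <- crossprod(cache$Xun, dY1)
  d_bc1 <- colSums(dY1)
  dXun <- dY1 %*% t(par$K1)
  dv <- dv + dXun[, 2] + .shift_bwd(dXun[, 1], G) + .shift_fwd(dXun[, 3], G)
  dr <- matrix(dv, G, C)
  list(dr = dr,
       grads = list(K1 = d_K1, bc1 = d_bc1, bn_gamma = d_bn_gamma,
                    bn_beta = d_bn_beta, K2 = d_K2, bc2 = d_bc2,
                    w_fc = d_wfc, b_fc = d_bfc))
}

.linear_head_forward <- function(par, r) {
  list(logit = (r %*% par$w_fc)[, 1] + par$b_fc,
       cache = list(r = r))
}

.linear_head_backward <- function(par, cache, dlogit) {
  list(dr = matrix(dlogit, ncol = 1) %*% t(par$w_fc),
       grads = list(w_fc = crossprod(cache$r, matrix(dlogit, ncol = 1)),
                    b_fc = sum(dlogit)))
}

# --- full model ------------------------------------------------------------

.head_block_matrix <- function(config) {
  H <- config$attention_heads; K <- config$gat_hidden
  B <- matrix(0, H * K, H)
  B[cbind(seq_len(H * K), rep(seq_len(H), each = K))] <- 1
  B
}

#' Forward pass: per-graph binding probabilities
#'
#' @param model An `mg_model`.
#' @param batch A batch from [collate_batch()].
#' @param training Use training-mode stochasticity (attention dropout,
#'   batch statistics)? Default FALSE: evaluation mode is deterministic.
#' @param keep_cache Keep intermediate activations for the backward pass.
#' @return If `keep_cache` is FALSE, a numeric vector of probabilities in
#'   (0, 1); otherwise a list with `p`, `logit` and `caches`.
#' @export
forward_model <- function(model, batch, training = FALSE,
                          keep_cache = FALSE) {
  config <- model$config
  pb <- .prepare_batch(batch)
  Bmat <- .head_block_matrix(config)
  X <- pb$x
  caches <- vector("list", config$gat_layers)
  for (l in seq_len(config$gat_layers)) {
    fw <- .gat_forward(model$layers[[l]], X, pb, config, training, Bmat)
    X <- fw$out
    caches[[l]] <- fw$cache
  }
  r <- .group_rowsum(X, pb$graph_id, pb$n_graphs) / pb$ng
  if (config$head == "conv") {
    hd <- .conv_head_forward(model$head, r, model, training)
  } else {
    hd <- .linear_head_forward(model$head, r)
  }
  p <- .sigmoid(hd$logit)
  if (!keep_cache) return(p)
  list(p = p, logit = hd$logit,
       caches = list(layers = caches, head = hd$cache, pb = pb, Bmat = Bmat,
                     r = r))
}

# Gradients of mean binary cross-entropy w.r.t. all parameters.
.model_backward <- function(model, fwd, y) {
  config <- model$config
  pb <- fwd$caches$pb
  G <- pb$n_graphs
  dlogit <- (fwd$p - y) / G
  if (config$head == "conv") {
    hb <- .conv_head_backward(model$head, fwd$caches$head, dlogit)
  } else {
    hb <- .linear_head_backward(model$head, fwd$caches$head, dlogit)
  }
  dX <- hb$dr[pb$graph_id, , drop = FALSE] / pb$ng[pb$graph_id]
  layer_grads <- vector("list", config$gat_layers)
  for (l in rev(seq_len(config$gat_layers))) {
    bk <- .gat_backward(model$layers[[l]], fwd$caches$layers[[l]], dX, pb,
                        config, fwd$caches$Bmat)
    dX <- bk$dX
    layer_grads[[l]] <- bk$grads
  }
  list(layers = layer_grads, head = hb$grads)
}

#' Predict binding probabilities for featurized samples
#'
#' Deterministic evaluation-mode forward pass.
#'
#' @param model A trained `mg_model`.
#' @param samples List of `mg_graph` objects (or a single one).
#' @param batch_size Graphs per forward pass.
#' @return Numeric vector of probabilities.
#' @export
predict_model <- function(model, samples, batch_size = 64L) {
  if (inherits(samples, "mg_graph")) samples <- list(samples)
  unlist(lapply(batch_graphs(samples, batch_size), function(b) {
    forward_model(model, b, training = FALSE)
  }), use.names = FALSE)
}
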