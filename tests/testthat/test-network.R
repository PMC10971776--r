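# The analytic backward pass is the core of the trainable model; it is
# verified against central finite differences on a small two-graph batch.

test_that("analytic gradients match finite differences for every parameter", {
  set.seed(301)
  cfg <- model_config(gat_layers = 2, attention_heads = 2, gat_hidden = 3,
                      conv_channels = 2, dropout = 0, head = "conv")
  batch <- collate_batch(list(featurize_pair("GA", "G", 1),
                              featurize_pair("G", "C", 0)))
  model <- init_model(cfg, seed = 7)
  fwd <- forward_model(model, batch, training = TRUE, keep_cache = TRUE)
  grads <- mhcgraph:::.model_backward(model, fwd, batch$y)
  loss_of <- function(m) {
    mhcgraph:::.bce(forward_model(m, batch, training = TRUE,
                                  keep_cache = TRUE)$p, batch$y)
  }
  check_block <- function(get, set, g, label, k = 4) {
    p <- get(model)
    for (i in sample(length(p), min(k, length(p)))) {
      h <- 1e-5
      num <- (loss_of(set(model, replace(p, i, p[i] + h))) -
                loss_of(set(model, replace(p, i, p[i] - h)))) / (2 * h)
      expect_lt(abs(num - g[i]) /
                  max(1e-6, abs(num) + abs(g[i])), 1e-4,
                label = paste(label, i))
    }
  }
  for (l in 1:2) {
    for (nm in names(model$layers[[l]])) {
      check_block(function(m) m$layers[[l]][[nm]],
                  function(m, v) { m$layers[[l]][[nm]][] <- v; m },
                  grads$layers[[l]][[nm]], paste0("layer", l, ":", nm))
    }
  }
  for (nm in names(model$head)) {
    check_block(function(m) m$head[[nm]],
                function(m, v) { m$head[[nm]][] <- v; m },
                grads$head[[nm]], paste0("head:", nm))
  }
})

test_that("gradients also match for the linear-head ablation", {
  set.seed(302)
  cfg <- model_config(gat_layers = 2, attention_heads = 2, gat_hidden = 3,
                      dropout = 0, head = "linear")
  batch <- collate_batch(tiny_samples())
  model <- init_model(cfg, seed = 9)
  fwd <- forward_model(model, batch, training = TRUE, keep_cache = TRUE)
  grads <- mhcgraph:::.model_backward(model, fwd, batch$y)
  loss_of <- function(m) {
    mhcgraph:::.bce(forward_model(m, batch, training = TRUE,
                                  keep_cache = TRUE)$p, batch$y)
  }
  for (nm in c("W", "a_dst", "gn_alpha")) {
    p <- model$layers[[1]][[nm]]
    i <- sample(length(p), 1)
    h <- 1e-5
    bump <- function(delta) {
      m <- model; m$layers[[1]][[nm]][i] <- p[i] + delta; m
    }
    num <- (loss_of(bump(h)) - loss_of(bump(-h))) / (2 * h)
    expect_lt(abs(num - grads$layers[[1]][[nm]][i]) /
                max(1e-6, abs(num) + abs(grads$layers[[1]][[nm]][i])), 1e-4)
  }
})

test_that("attention weights are a proper distribution over in-neighbours", {
  cfg <- model_config(gat_layers = 1, attention_heads = 3, gat_hidden = 2,
                      dropout = 0, head = "linear")
  model <- init_model(cfg, seed = 3)
  batch <- collate_batch(list(featurize_pair("G", "A", 1)))
  pb <- mhcgraph:::.prepare_batch(batch)
  fw <- mhcgraph:::.gat_forward(model$layers[[1]], pb$x, pb, cfg,
                                FALSE, mhcgraph:::.head_block_matrix(cfg))
  A <- fw$cache$A
  expect_true(all(A >= 0))
  sums <- rowsum(A, pb$dst)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
  # an isolated node attends only to its self-loop
  one <- collate_batch(list(structure(list(
    x = matrix(0, 1, 31), edge_index = matrix(integer(0), 2, 0),
    edge_attr = matrix(0, 0, 12), y = 1, n_nodes = 1L),
    class = "mg_graph")))
  pb1 <- mhcgraph:::.prepare_batch(one)
  fw1 <- mhcgraph:::.gat_forward(model$layers[[1]], pb1$x, pb1, cfg,
                                 FALSE, mhcgraph:::.head_block_matrix(cfg))
  expect_equal(as.vector(fw1$cache$A), rep(1, 3))
})

test_that("readout_mean averages per graph and is permutation invariant", {
  x <- rbind(matrix(1, 3, 4) * 2, matrix(1, 2, 4) * 5)
  gid <- c(1, 1, 1, 2, 2)
  r <- readout_mean(x, gid, 2)
  expect_equal(r, rbind(rep(2, 4), rep(5, 4)))
  perm <- c(4, 1, 5, 3, 2)
  expect_equal(readout_mean(x[perm, ], gid[perm], 2), r)
  expect_error(readout_mean(x, c(1, 1, 1, 1, 1), 2), "empty")
})

test_that("evaluation-mode forward is deterministic and invariant to graph order", {
  cfg <- model_config(gat_layers = 2, attention_heads = 2, gat_hidden = 4,
                      conv_channels = 3, head = "conv")
  model <- init_model(cfg, seed = 5)
  model$bn_stats$mean <- runif(3); model$bn_stats$var <- runif(3) + 0.5
  samples <- tiny_samples()
  p1 <- forward_model(model, collate_batch(samples))
  p2 <- forward_model(model, collate_batch(samples))
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  perm <- c(3, 1, 4, 2)
  p3 <- forward_model(model, collate_batch(samples[perm]))
  expect_equal(p3, p1[perm], tolerance = 1e-10)
})

test_that("per-graph output is invariant to atom relabelling", {
  cfg <- model_config(gat_layers = 2, attention_heads = 2, gat_hidden = 4,
                      head = "linear")
  model <- init_model(cfg, seed = 6)
  g <- featurize_pair("AG", "S", 1)
  set.seed(303)
  perm <- sample(g$n_nodes)
  g2 <- g
  inv <- order(perm)  # old atom i becomes new atom perm[i]
  g2$x <- g$x[inv, , drop = FALSE]
  g2$edge_index <- matrix(perm[g$edge_index], nrow = 2)
  p_orig <- forward_model(model, collate_batch(list(g)))
  p_perm <- forward_model(model, collate_batch(list(g2)))
  expect_equal(p_perm, p_orig, tolerance = 1e-10)
})

test_that("a zeroed classifier head outputs exactly 0.5", {
  cfg <- model_config(gat_layers = 1, attention_heads = 2, gat_hidden = 3,
                      conv_channels = 2, head = "conv")
  model <- init_model(cfg, seed = 8)
  model$head$K1[] <- 0; model$head$K2[] <- 0
  model$head$bc1[] <- 0; model$head$bc2[] <- 0
  model$head$w_fc[] <- 0; model$head$b_fc <- 0
  # with zero conv weights the skip path feeds the FC, whose weights are
  # zero, so the logit is exactly the zero bias
  p <- forward_model(model, collate_batch(tiny_samples()))
  expect_identical(unname(p), rep(0.5, 4))
})
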