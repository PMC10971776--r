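# Desk-scale benchmark conditions shared by the acceptance suite and
# documented in the methods vignette: a planted two-anchor binding rule
# over a 4-allele panel with reduced (8-residue) pseudo-sequences,
# 2500 records split 80/20 into 2000 train / 500 test.

benchmark_synth_config <- function() {
  synth_config(n_alleles = 4L, pseudo_length = 8L, n_records = 2500L,
               anchor_positions = c(2L, 9L), binder_fraction = 0.5,
               log10_sd = 0.3, seed = 11L)
}

benchmark_model_config <- function(head = "conv") {
  model_config(gat_layers = 4L, attention_heads = 4L, gat_hidden = 4L,
               conv_channels = 8L, dropout = 0.1, head = head)
}

benchmark_train_config <- function(seed) {
  train_config(epochs = 20L, learning_rate = 3e-3, seed = seed)
}

# Featurized benchmark split, built once per test session.
benchmark_split <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_affinity_dataset(benchmark_synth_config())
      samples <- featurize_records(ds$records, ds$mapping)
      cache <<- split_train_test(samples, 0.8, seed = 1)
    }
    cache
  }
})
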