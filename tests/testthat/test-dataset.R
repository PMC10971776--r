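write_affinity_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

test_that("the 500 nM labelling rule has its step exactly at the threshold", {
  expect_equal(label_ic50(c(499.99, 500, 500.01)), c(1L, 1L, 0L))
  expect_equal(label_ic50(1e-6), 1L)
  expect_equal(label_ic50(5e4), 0L)
})

test_that("affinity tables are parsed, labelled and filtered against the map", {
  mapping <- c("HLA-A*02:01" = paste(rep("A", 34), collapse = ""),
               "HLA-B*07:02" = paste(rep("G", 34), collapse = ""))
  rows <- data.frame(
    allele = c(rep("HLA-A*02:01", 4), rep("HLA-B*07:02", 4),
               rep("HLA-C*99:99", 2)),
    peptide = rep("SIINFEKLM", 10),
    ic50 = c(500, 500.01, 3, 20000, 1, 499, 501, 1000, 5, 5))
  path <- write_affinity_fixture(rows)
  suppressMessages(rec <- read_affinity_table(path, mapping))
  expect_equal(nrow(rec), 8)
  expect_equal(attr(rec, "n_dropped"), 2)
  expect_equal(rec$label, c(1L, 0L, 1L, 0L, 1L, 1L, 0L, 0L))
  # missing column and non-numeric IC50 diagnostics
  bad <- rows; names(bad)[3] <- "affinity"
  expect_error(read_affinity_table(write_affinity_fixture(bad), mapping),
               "missing column")
  bad2 <- rows; bad2$ic50 <- as.character(bad2$ic50); bad2$ic50[3] <- "n/a"
  expect_error(read_affinity_table(write_affinity_fixture(bad2), mapping),
               "row 3")
})

test_that("pseudo-sequence maps enforce the 34-mer convention", {
  path <- tempfile()
  writeLines(c("# comment", paste0("HLA-A*02:01 ", strrep("A", 34)),
               paste0("HLA-B*07:02 ", strrep("G", 34))), path)
  mp <- read_pseudo_map(path)
  expect_equal(unname(nchar(mp)), c(34L, 34L))
  path2 <- tempfile()
  writeLines("HLA-A*02:01 SHORT", path2)
  expect_error(read_pseudo_map(path2), "length")
  expect_silent(read_pseudo_map(path2, expected_length = NULL))
})

test_that("train/test split is an exact, deterministic, seed-sensitive partition", {
  rec <- data.frame(i = 1:1000)
  sp <- split_train_test(rec, 0.8, seed = 7)
  expect_equal(nrow(sp$train), 800)
  expect_equal(nrow(sp$test), 200)
  expect_equal(sort(c(sp$train$i, sp$test$i)), 1:1000)
  sp2 <- split_train_test(rec, 0.8, seed = 7)
  expect_identical(sp$train$i, sp2$train$i)
  sp3 <- split_train_test(rec, 0.8, seed = 8)
  expect_false(identical(sp$train$i, sp3$train$i))
  # the published corpus size splits to the published counts
  n <- 157084
  expect_equal(round(0.8 * n), 125667)
  expect_equal(n - round(0.8 * n), 31417)
  big <- split_train_test(data.frame(i = seq_len(n)), 0.8, seed = 1)
  expect_equal(nrow(big$train), 125667)
  expect_equal(nrow(big$test), 31417)
})

test_that("batching concatenates graphs with valid offsets and unbatching inverts it", {
  samples <- tiny_samples()
  samples <- c(samples, samples, samples)  # 12 graphs
  batches <- batch_graphs(samples, 5)
  expect_equal(vapply(batches, function(b) b$n_graphs, 0L), c(5L, 5L, 2L))
  b1 <- batches[[1]]
  expect_equal(nrow(b1$x), sum(b1$n_nodes_per_graph))
  expect_true(max(b1$edge_index) <= nrow(b1$x))
  expect_equal(length(b1$graph_id), nrow(b1$x))
  # two single-glycine graphs: 20 node rows, membership 10 + 10
  g1 <- featurize_molecule(build_peptide("G"), 0)
  gb <- collate_batch(list(g1, g1))
  expect_equal(nrow(gb$x), 20)
  expect_equal(gb$graph_id, rep(1:2, each = 10))
  round_trip <- unbatch_graphs(b1)
  for (i in seq_along(round_trip)) {
    expect_equal(round_trip[[i]]$x, samples[[i]]$x)
    expect_equal(round_trip[[i]]$edge_index, samples[[i]]$edge_index)
    expect_equal(round_trip[[i]]$edge_attr, samples[[i]]$edge_attr)
    expect_equal(round_trip[[i]]$y, samples[[i]]$y)
  }
})

test_that("dataset serialization round-trips with a manifest", {
  dir <- tempfile()
  samples <- tiny_samples()
  write_dataset(samples, dir, list(seed = 5, train_fraction = 0.8))
  back <- read_dataset(dir)
  expect_equal(length(back$samples), 4)
  expect_equal(back$manifest$seed, 5)
  expect_equal(back$manifest$n_samples, 4)
  expect_equal(back$samples[[1]]$x, samples[[1]]$x)
})
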