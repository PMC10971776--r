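# IEDB-style affinity tables, pseudo-sequence maps, splitting, batching.

#' Read a NetMHCpan-style allele-to-pseudo-sequence map
#'
#' Two whitespace-separated columns (allele name, pseudo-sequence); lines
#' starting with `#` are comments.
#'
#' @param path Path to the map file.
#' @param expected_length Required pseudo-sequence length (default 34, the
#'   number of polymorphic binding-groove residues; set `NULL` to skip the
#'   check, e.g. for reduced-length synthetic maps).
#' @return Named character vector: allele -> pseudo-sequence.
#' @export
read_pseudo_map <- function(path, expected_length = 34L) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("allele", "pseudo"))
  if (!is.null(expected_length)) {
    bad <- nchar(df$pseudo) != expected_length
    if (any(bad)) {
      stop(sprintf("pseudo-sequence for %s has length %d, expected %d",
                   df$allele[which(bad)[1]], nchar(df$pseudo[which(bad)[1]]),
                   expected_length))
    }
  }
  stats::setNames(df$pseudo, df$allele)
}

#' Label an IC50 value with the 500 nM binding rule
#'
#' @param ic50 Positive IC50 values in nM.
#' @param threshold Binding threshold in nM (default 500).
#' @return Integer labels: 1 when `ic50 <= threshold`, else 0.
#' @export
label_ic50 <- function(ic50, threshold = 500) {
  as.integer(ic50 <= threshold)
}

#' Read an IEDB-style quantitative binding-affinity table
#'
#' Parses a CSV with allele, peptide and quantitative IC50 (nM) columns,
#' assigns binary labels with the 500 nM rule, and drops rows whose allele
#' has no pseudo-sequence mapping (with a reported count).
#'
#' @param path Path to the CSV file.
#' @param mapping Named character vector from [read_pseudo_map()], or
#'   `NULL` to keep all rows.
#' @param allele_col,peptide_col,ic50_col Column names in the CSV.
#' @param threshold Binding threshold in nM (default 500).
#' @return `data.frame` with columns allele, peptide, ic50, label; the
#'   number of dropped rows is in attribute `"n_dropped"`.
#' @export
read_affinity_table <- function(path, mapping = NULL,
                                allele_col = "allele",
                                peptide_col = "peptide",
                                ic50_col = "ic50",
                                threshold = 500) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c(allele_col, peptide_col, ic50_col), names(df))
  if (length(miss) > 0L) {
    stop("affinity table is missing column(s): ", paste(miss, collapse = ", "))
  }
  ic50 <- suppressWarnings(as.numeric(df[[ic50_col]]))
  if (anyNA(ic50)) {
    stop("non-numeric IC50 at row ", which(is.na(ic50))[1])
  }
  if (any(ic50 <= 0)) stop("IC50 must be positive at row ", which(ic50 <= 0)[1])
  rec <- data.frame(allele = as.character(df[[allele_col]]),
                    peptide = as.character(df[[peptide_col]]),
                    ic50 = ic50,
                    stringsAsFactors = FALSE)
  rec$label <- label_ic50(rec$ic50, threshold)
  n_dropped <- 0L
  if (!is.null(mapping)) {
    keep <- rec$allele %in% names(mapping)
    n_dropped <- sum(!keep)
    if (n_dropped > 0L) {
      message(n_dropped, " row(s) dropped: allele not in pseudo-sequence map")
    }
    rec <- rec[keep, , drop = FALSE]
    rownames(rec) <- NULL
  }
  attr(rec, "n_dropped") <- n_dropped
  rec
}

#' Random 80/20 train/test split
#'
#' Simple (non-stratified) random partition; the training set size is
#' `round(train_fraction * N)`.
#'
#' @param records A data.frame or list of records.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed controlling the permutation.
#' @return List with elements `train` and `test` of the same type as the
#'   input.
#' @export
split_train_test <- function(records, train_fraction = 0.8, seed = 1L) {
  n <- if (is.data.frame(records)) nrow(records) else length(records)
  if (n == 0L) stop("cannot split an empty record set")
  n_train <- round(train_fraction * n)
  idx <- .with_local_seed(seed, sample.int(n))
  tr <- sort(idx[seq_len(n_train)])
  te <- sort(idx[-seq_len(n_train)])
  if (is.data.frame(records)) {
    list(train = records[tr, , drop = FALSE], test = records[te, , drop = FALSE])
  } else {
    list(train = records[tr], test = records[te])
  }
}

#' Featurize a table of binding records
#'
#' @param records data.frame from [read_affinity_table()] (or the synthetic
#'   generator) with columns allele, peptide, label.
#' @param mapping Named character vector allele -> pseudo-sequence.
#' @return List of `mg_graph` samples (alleles are featurized once and the
#'   chain graphs reused across records).
#' @export
featurize_records <- function(records, mapping) {
  unknown <- setdiff(unique(records$allele), names(mapping))
  if (length(unknown) > 0L) {
    stop("allele(s) missing from mapping: ", paste(unknown, collapse = ", "))
  }
  labels <- if ("label" %in% names(records)) records$label else
    rep(NA_real_, nrow(records))
  lapply(seq_len(nrow(records)), function(i) {
    featurize_pair(mapping[[records$allele[i]]], records$peptide[i],
                   labels[i])
  })
}

#' Collate featurized graphs into minibatches
#'
#' Each batch concatenates the node matrices, offsets the edge indices by
#' cumulative node counts and carries a per-node graph membership vector so
#' a per-graph readout is computable.
#'
#' @param samples List of `mg_graph` objects.
#' @param batch_size Graphs per batch (default 64).
#' @return List of batches; each batch is a list with `x`, `edge_index`,
#'   `edge_attr`, `graph_id` (per node, 1-based within batch), `y`,
#'   `n_graphs`, `n_nodes_per_graph`.
#' @export
batch_graphs <- function(samples, batch_size = 64L) {
  stopifnot(length(samples) > 0L)
  grp <- ceiling(seq_along(samples) / batch_size)
  idx <- split(seq_along(samples), factor(grp, levels = unique(grp)))
  unname(lapply(idx, function(ii) collate_batch(samples[ii])))
}

#' Collate a list of graphs into one batch
#' @param samples List of `mg_graph` objects.
#' @return A single batch (see [batch_graphs()]).
#' @export
collate_batch <- function(samples) {
  sizes <- vapply(samples, function(s) s$n_nodes, 0L)
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  x <- do.call(rbind, lapply(samples, `[[`, "x"))
  ei <- do.call(cbind, Map(function(s, o) s$edge_index + o, samples, offs))
  ea <- do.call(rbind, lapply(samples, `[[`, "edge_attr"))
  list(
    x = x,
    edge_index = ei,
    edge_attr = ea,
    graph_id = rep(seq_along(samples), sizes),
    y = vapply(samples, function(s) as.numeric(s$y), 0),
    n_graphs = length(samples),
    n_nodes_per_graph = sizes
  )
}

#' Split a batch back into per-graph tensors
#'
#' Inverse of [collate_batch()]; used to verify that batching is lossless.
#'
#' @param batch A batch from [collate_batch()].
#' @return List of `mg_graph` objects.
#' @export
unbatch_graphs <- function(batch) {
  sizes <- batch$n_nodes_per_graph
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  lapply(seq_len(batch$n_graphs), function(g) {
    nodes <- which(batch$graph_id == g)
    emask <- batch$edge_index[1, ] %in% nodes
    structure(list(
      x = batch$x[nodes, , drop = FALSE],
      edge_index = batch$edge_index[, emask, drop = FALSE] - offs[g],
      edge_attr = batch$edge_attr[emask, , drop = FALSE],
      y = batch$y[g],
      n_nodes = sizes[g]
    ), class = "mg_graph")
  })
}

#' Write a featurized dataset with a provenance manifest
#'
#' Serializes the samples to `<dir>/samples.rds` and writes
#' `<dir>/manifest.json` recording the seed, split fraction and source
#' checksums.
#'
#' @param samples List of `mg_graph` objects.
#' @param dir Output directory (created if needed).
#' @param manifest Named list of provenance fields to record.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir, manifest = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(samples, file.path(dir, "samples.rds"))
  manifest$n_samples <- length(samples)
  manifest$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$package_version <- as.character(utils::packageVersion("mhcgraph"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a featurized dataset written by [write_dataset()]
#' @param dir Dataset directory.
#' @return List with `samples` and `manifest`.
#' @export
read_dataset <- function(dir) {
  list(samples = readRDS(file.path(dir, "samples.rds")),
       manifest = jsonlite::read_json(file.path(dir, "manifest.json")))
}
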