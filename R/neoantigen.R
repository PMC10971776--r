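# Neoantigen load from missense variants and group comparisons.

#' Enumerate 9-mer windows covering a mutated position
#'
#' All length-9 substrings that lie fully inside the protein and contain
#' the (1-based) mutated position, ordered by start position.
#'
#' @param protein_seq Protein amino-acid sequence.
#' @param mutated_position 1-based position of the missense mutation.
#' @return Character vector of 9-mer peptides (empty, with a warning, when
#'   the sequence is shorter than 9).
#' @export
nine_mer_windows <- function(protein_seq, mutated_position) {
  len <- nchar(protein_seq)
  if (len < 9L) {
    warning("protein shorter than 9 residues: no 9-mer windows")
    return(character(0))
  }
  if (mutated_position < 1L || mutated_position > len) {
    stop("mutated_position outside the sequence")
  }
  starts <- max(1L, mutated_position - 8L):min(mutated_position, len - 8L)
  vapply(starts, function(s) substr(protein_seq, s, s + 8L), "")
}

#' Per-patient neoantigen load
#'
#' Counts (allele, candidate-peptide) pairs whose predicted binding
#' probability reaches the threshold. A peptide predicted to bind two of
#' the patient's alleles counts twice unless `unique_peptides = TRUE`.
#'
#' @param alleles Character vector of the patient's HLA allele names.
#' @param candidates Character vector of candidate 9-mer peptides.
#' @param model A trained model from [train_model()], or any function
#'   `f(mhc_seq, peptide)` returning a binding probability.
#' @param mapping Allele -> pseudo-sequence map. Unmapped alleles are
#'   skipped with a warning.
#' @param threshold Probability threshold (default 0.5).
#' @param unique_peptides Count peptides instead of pairs (default FALSE).
#' @return Integer load.
#' @export
neoantigen_load <- function(alleles, candidates, model, mapping,
                            threshold = 0.5, unique_peptides = FALSE) {
  mapped <- alleles %in% names(mapping)
  if (any(!mapped)) {
    warning("skipping unmapped allele(s): ",
            paste(alleles[!mapped], collapse = ", "))
    alleles <- alleles[mapped]
  }
  if (length(alleles) == 0L || length(candidates) == 0L) return(0L)
  pairs <- expand.grid(allele = alleles, peptide = candidates,
                       stringsAsFactors = FALSE)
  if (is.function(model)) {
    p <- mapply(model, mapping[pairs$allele], pairs$peptide)
  } else {
    samples <- lapply(seq_len(nrow(pairs)), function(i) {
      featurize_pair(mapping[[pairs$allele[i]]], pairs$peptide[i])
    })
    p <- predict_model(model, samples)
  }
  hit <- p >= threshold
  if (unique_peptides) {
    length(unique(pairs$peptide[hit]))
  } else {
    as.integer(sum(hit))
  }
}

#' Median split of neoantigen loads
#'
#' High group: load strictly greater than the cohort median; ties at the
#' median go to the low group.
#'
#' @param loads Numeric vector of per-patient loads.
#' @return Logical vector, `TRUE` for the high-load group.
#' @export
median_split <- function(loads) {
  if (length(loads) < 2L) stop("median split needs at least 2 patients")
  high <- loads > stats::median(loads)
  if (!any(high)) warning("degenerate split: high-load group is empty")
  high
}

#' Mantel-Cox log-rank test between two survival groups
#'
#' Wraps `survival::survdiff` (1 df chi-square). An administrative
#' censoring horizon (e.g. 5-year survival) can be applied first: times are
#' truncated at the horizon and later events become censored.
#'
#' @param time Survival/follow-up times (days).
#' @param event Event indicator (1 = death observed).
#' @param group Two-level group assignment (e.g. from [median_split()]).
#' @param horizon_days Optional administrative censoring horizon.
#' @return List with `statistic` (chi-square), `p_value`, `df`.
#' @export
logrank_test <- function(time, event, group, horizon_days = NULL) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) {
    stop("log-rank test needs exactly two non-empty groups")
  }
  if (!is.null(horizon_days)) {
    event <- ifelse(time > horizon_days, 0L, event)
    time <- pmin(time, horizon_days)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sd$chisq
  list(statistic = unname(stat), df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Two-sided rank-sum comparison of a biomarker score between groups
#'
#' Wilcoxon-Mann-Whitney test via `stats::wilcox.test` (normal
#' approximation without continuity correction, matching the common
#' large-sample convention).
#'
#' @param scores Numeric biomarker scores.
#' @param group Two-level assignment; statistics are reported for the
#'   first level against the second.
#' @return List with `statistic` (Mann-Whitney U for the high/first group)
#'   and `p_value`.
#' @export
score_comparison <- function(scores, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) {
    stop("score comparison needs exactly two non-empty groups")
  }
  lv <- levels(droplevels(group))
  wt <- stats::wilcox.test(scores[group == lv[2]], scores[group == lv[1]],
                           exact = FALSE, correct = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Affinity-to-score transforms used for baseline comparison
#'
#' `t_log(x) = 1 - log(x)/log(50000)` maps an affinity in nM to a score in
#' (0, 1] for x in [1, 50000]; `t_sig(x) = 1/(1 + exp(x))` is the
#' reflected sigmoid applied literally to its argument.
#'
#' @param affinity Positive binding affinity (nM) for `t_log`; any real
#'   for `t_sig`.
#' @return Transformed score.
#' @name baseline_transforms
NULL

#' @rdname baseline_transforms
#' @export
t_log <- function(affinity) {
  if (any(affinity <= 0)) stop("t_log requires positive affinities")
  1 - log(affinity) / log(50000)
}

#' @rdname baseline_transforms
#' @export
t_sig <- function(affinity) 1 / (1 + exp(affinity))

#' Read a patient variant table
#'
#' CSV/TSV with columns patient_id, alleles (semicolon-separated),
#' protein_seq, mut_pos.
#'
#' @param path File path (delimiter inferred from the extension).
#' @return data.frame.
#' @export
read_patient_table <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("patient_id", "alleles", "protein_seq", "mut_pos")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("patient table missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Read a clinical table
#'
#' CSV/TSV with columns patient_id, time_days, event, stromal, immune,
#' estimate.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_clinical_table <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("patient_id", "time_days", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Full neoantigen-load group-comparison analysis
#'
#' Computes per-patient loads with a trained model, splits the cohort at
#' the median load, and runs the overall-survival log-rank test plus
#' rank-sum comparisons for each biomarker score.
#'
#' @param patients data.frame as from [read_patient_table()].
#' @param clinical data.frame as from [read_clinical_table()].
#' @param model Trained model (or scoring function, see
#'   [neoantigen_load()]).
#' @param mapping Allele -> pseudo-sequence map.
#' @param threshold Binding probability threshold (default 0.5).
#' @param horizon_days Optional administrative censoring horizon for the
#'   survival comparison.
#' @return List with `loads` (data.frame patient_id, load, high_group),
#'   `survival` (log-rank result) and `scores` (per-biomarker rank-sum
#'   results).
#' @export
neoantigen_analysis <- function(patients, clinical, model, mapping,
                                threshold = 0.5, horizon_days = NULL) {
  loads <- vapply(seq_len(nrow(patients)), function(i) {
    cands <- nine_mer_windows(patients$protein_seq[i], patients$mut_pos[i])
    neoantigen_load(strsplit(patients$alleles[i], ";")[[1]], cands,
                    model, mapping, threshold)
  }, 0L)
  high <- median_split(loads)
  cl <- clinical[match(patients$patient_id, clinical$patient_id), ]
  surv <- logrank_test(cl$time_days, cl$event, high, horizon_days)
  score_cols <- intersect(c("stromal", "immune", "estimate"), names(cl))
  scores <- lapply(score_cols, function(sc) {
    score_comparison(cl[[sc]], factor(high, levels = c(TRUE, FALSE),
                                      labels = c("high", "low")))
  })
  names(scores) <- score_cols
  list(loads = data.frame(patient_id = patients$patient_id, load = loads,
                          high_group = high, stringsAsFactors = FALSE),
       survival = surv, scores = scores)
}
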