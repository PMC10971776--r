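# Synthetic affinity datasets and patient cohorts with planted ground truth.
#
# The affinity generator emulates an IEDB-style quantitative table: a fixed
# panel of synthetic alleles, each with a pseudo-sequence and one preferred
# residue per peptide anchor position; peptide IC50 is log-normal around
# 50 nM when every anchor matches the allele's preference and around
# 5000 nM otherwise, and labels follow the 500 nM rule. The cohort
# generator emulates the survival application: exponential overall survival
# whose hazard is multiplied by a configured ratio for patients in the
# low-neoantigen-load group, independent censoring, and biomarker scores
# with a configurable group mean shift.

#' Configuration for the synthetic affinity generator
#'
#' @param n_alleles Number of synthetic alleles in the panel.
#' @param pseudo_length Pseudo-sequence length (34 in the NetMHCpan
#'   convention; reducible for desk-scale experiments).
#' @param n_records Number of (allele, peptide, IC50) rows to draw.
#' @param peptide_length Peptide length (MHC class I presents 9-mers).
#' @param anchor_positions Peptide anchor positions carrying the planted
#'   binding rule (default positions 2 and 9, the canonical class I
#'   anchors).
#' @param binder_fraction Target fraction of binding records.
#' @param log10_sd IC50 noise standard deviation on the log10 scale.
#' @param binder_ic50,nonbinder_ic50 Log-normal medians (nM) for anchor
#'   matches and non-matches.
#' @param seed Integer seed.
#' @return A list of class `mg_synth_config`.
#' @export
synth_config <- function(n_alleles = 8L, pseudo_length = 34L,
                         n_records = 1000L, peptide_length = 9L,
                         anchor_positions = c(2L, 9L),
                         binder_fraction = 0.5, log10_sd = 0.3,
                         binder_ic50 = 50, nonbinder_ic50 = 5000,
                         seed = 1L) {
  stopifnot(n_alleles >= 1L, pseudo_length >= 1L, n_records >= 1L,
            peptide_length >= max(anchor_positions),
            binder_fraction > 0, binder_fraction < 1, log10_sd >= 0)
  structure(list(n_alleles = n_alleles, pseudo_length = pseudo_length,
                 n_records = n_records, peptide_length = peptide_length,
                 anchor_positions = as.integer(anchor_positions),
                 binder_fraction = binder_fraction, log10_sd = log10_sd,
                 binder_ic50 = binder_ic50, nonbinder_ic50 = nonbinder_ic50,
                 seed = as.integer(seed)),
            class = "mg_synth_config")
}

.random_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(.AA_CODES, len, replace = TRUE), collapse = "")
  }, "")
}

#' Generate a synthetic affinity dataset with a planted anchor rule
#'
#' @param config From [synth_config()].
#' @return List with `records` (data.frame: allele, peptide, ic50, label),
#'   `mapping` (allele -> pseudo-sequence), and `truth` (anchor positions
#'   and the per-allele preferred residues).
#' @export
generate_affinity_dataset <- function(config) {
  stopifnot(inherits(config, "mg_synth_config"))
  .with_local_seed(config$seed, {
    alleles <- sprintf("SYN-%02d:01", seq_len(config$n_alleles))
    mapping <- stats::setNames(
      .random_seq(config$n_alleles, config$pseudo_length), alleles)
    prefs <- matrix(sample(.AA_CODES, config$n_alleles *
                             length(config$anchor_positions), replace = TRUE),
                    nrow = config$n_alleles,
                    dimnames = list(alleles, NULL))
    n <- config$n_records
    which_allele <- sample(config$n_alleles, n, replace = TRUE)
    planted <- stats::runif(n) < config$binder_fraction
    pep <- matrix(sample(.AA_CODES, n * config$peptide_length, replace = TRUE),
                  nrow = n)
    for (j in seq_along(config$anchor_positions)) {
      pep[planted, config$anchor_positions[j]] <- prefs[which_allele[planted], j]
    }
    match_rule <- rep(TRUE, n)
    for (j in seq_along(config$anchor_positions)) {
      match_rule <- match_rule &
        pep[, config$anchor_positions[j]] == prefs[which_allele, j]
    }
    med <- ifelse(match_rule, config$binder_ic50, config$nonbinder_ic50)
    ic50 <- 10^(log10(med) + stats::rnorm(n, 0, config$log10_sd))
    records <- data.frame(
      allele = alleles[which_allele],
      peptide = apply(pep, 1, paste, collapse = ""),
      ic50 = ic50,
      stringsAsFactors = FALSE
    )
    records$label <- label_ic50(records$ic50)
    list(records = records, mapping = mapping,
         truth = list(anchor_positions = config$anchor_positions,
                      preferred = prefs, anchor_match = match_rule))
  })
}

#' Configuration for the synthetic patient cohort generator
#'
#' @param n_patients Number of patients.
#' @param n_alleles Size of the allele panel patients draw from.
#' @param alleles_per_patient HLA alleles per patient.
#' @param pseudo_length Pseudo-sequence length of panel alleles.
#' @param protein_length Length of each mutated protein fragment.
#' @param anchor_positions Planted anchor positions (as in [synth_config()]).
#' @param baseline_hazard Exponential hazard per day for the
#'   high-neoantigen-load group.
#' @param hazard_ratio_low Hazard multiplier applied to the low-load group
#'   (1 = null; >1 means low load does worse).
#' @param censor_hazard Hazard of independent exponential censoring.
#' @param horizon_days Administrative censoring horizon (default 10 years).
#' @param score_shift Mean shift added to the high-load group's biomarker
#'   scores (stromal, immune, ESTIMATE), in score units (sd = 1).
#' @param neoantigen_rate Probability that a patient's mutation creates a
#'   presented neoantigen: one candidate window gets the anchor-preferred
#'   residues of one of the patient's alleles written in. Without this,
#'   anchor matches in random protein sequence are so rare that nearly
#'   every true load is zero and the median split degenerates.
#' @param panel Optional shared allele panel: a list with `mapping`
#'   (allele -> pseudo-sequence) and `preferred` (allele x anchor matrix of
#'   preferred residues), e.g. taken from the `truth` of
#'   [generate_affinity_dataset()] so that a model trained on that dataset
#'   can be applied to the cohort. When given it overrides `n_alleles` and
#'   `pseudo_length`.
#' @param seed Integer seed.
#' @return A list of class `mg_cohort_config`.
#' @export
cohort_config <- function(n_patients = 200L, n_alleles = 4L,
                          alleles_per_patient = 2L, pseudo_length = 8L,
                          protein_length = 21L, anchor_positions = c(2L, 9L),
                          baseline_hazard = 1 / 2000, hazard_ratio_low = 3,
                          censor_hazard = 1 / 4000, horizon_days = 3650,
                          score_shift = 0.8, neoantigen_rate = 0.5,
                          panel = NULL, seed = 1L) {
  stopifnot(n_patients >= 2L, protein_length >= 9L, baseline_hazard > 0,
            hazard_ratio_low > 0)
  structure(as.list(environment()), class = "mg_cohort_config")
}

#' Generate a synthetic patient cohort with group-dependent survival
#'
#' Each patient carries HLA alleles from a synthetic panel, a mutated
#' protein fragment with a known missense position (whose 9-mer windows are
#' the neoantigen candidates), overall-survival time and event indicator,
#' and three biomarker scores. The planted anchor rule defines a true
#' neoantigen load; patients at or below the median true load have their
#' hazard multiplied by `hazard_ratio_low`, and high-load patients' scores
#' are shifted by `score_shift`.
#'
#' @param config From [cohort_config()].
#' @return List with `patients` (data.frame: patient_id, alleles
#'   (semicolon-separated), protein_seq, mut_pos), `clinical` (data.frame:
#'   patient_id, time_days, event, stromal, immune, estimate), `mapping`,
#'   and `truth` (per-patient true load, group, anchor rule).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "mg_cohort_config"))
  .with_local_seed(config$seed, {
    if (is.null(config$panel)) {
      alleles <- sprintf("SYN-%02d:01", seq_len(config$n_alleles))
      mapping <- stats::setNames(
        .random_seq(config$n_alleles, config$pseudo_length), alleles)
      prefs <- matrix(sample(.AA_CODES, config$n_alleles *
                               length(config$anchor_positions),
                             replace = TRUE),
                      nrow = config$n_alleles,
                      dimnames = list(alleles, NULL))
    } else {
      mapping <- config$panel$mapping
      prefs <- config$panel$preferred
      alleles <- names(mapping)
      stopifnot(nrow(prefs) == length(alleles),
                ncol(prefs) == length(config$anchor_positions))
    }
    n <- config$n_patients
    pat_alleles <- t(vapply(seq_len(n), function(i) {
      sample(alleles, config$alleles_per_patient,
             replace = config$alleles_per_patient > config$n_alleles)
    }, character(config$alleles_per_patient)))
    protein <- .random_seq(n, config$protein_length)
    mut_pos <- sample.int(config$protein_length, n, replace = TRUE)
    planted <- stats::runif(n) < config$neoantigen_rate
    for (i in which(planted)) {
      lo <- max(1L, mut_pos[i] - 8L)
      hi <- min(mut_pos[i], config$protein_length - 8L)
      starts <- lo:hi
      # one to three anchor-matching windows so loads spread beyond 0/1
      k <- sample.int(3L, 1L)
      starts <- starts[sample.int(length(starts), min(k, length(starts)))]
      for (s in starts) {
        al <- sample(pat_alleles[i, ], 1L)
        for (j in seq_along(config$anchor_positions)) {
          at <- s + config$anchor_positions[j] - 1L
          substr(protein[i], at, at) <- prefs[al, j]
        }
      }
    }
    true_load <- vapply(seq_len(n), function(i) {
      wins <- nine_mer_windows(protein[i], mut_pos[i])
      total <- 0L
      for (al in pat_alleles[i, ]) {
        for (w in wins) {
          ok <- TRUE
          for (j in seq_along(config$anchor_positions)) {
            ok <- ok && substr(w, config$anchor_positions[j],
                               config$anchor_positions[j]) == prefs[al, j]
          }
          total <- total + as.integer(ok)
        }
      }
      total
    }, 0L)
    grp_high <- median_split(true_load)
    hz <- config$baseline_hazard *
      ifelse(grp_high, 1, config$hazard_ratio_low)
    t_event <- stats::rexp(n, hz)
    t_cens <- pmin(stats::rexp(n, config$censor_hazard), config$horizon_days)
    time_days <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    scores <- matrix(stats::rnorm(n * 3), n, 3,
                     dimnames = list(NULL, c("stromal", "immune", "estimate")))
    scores[grp_high, ] <- scores[grp_high, ] + config$score_shift
    list(
      patients = data.frame(
        patient_id = sprintf("P%04d", seq_len(n)),
        alleles = apply(pat_alleles, 1, paste, collapse = ";"),
        protein_seq = protein,
        mut_pos = mut_pos,
        stringsAsFactors = FALSE
      ),
      clinical = data.frame(
        patient_id = sprintf("P%04d", seq_len(n)),
        time_days = time_days,
        event = event,
        stromal = scores[, "stromal"],
        immune = scores[, "immune"],
        estimate = scores[, "estimate"],
        stringsAsFactors = FALSE
      ),
      mapping = mapping,
      truth = list(true_load = true_load, high_group = grp_high,
                   preferred = prefs,
                   anchor_positions = config$anchor_positions)
    )
  })
}
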