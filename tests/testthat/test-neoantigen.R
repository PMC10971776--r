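test_that("9-mer window enumeration matches the counting formula exhaustively", {
  w <- nine_mer_windows(strrep("A", 20), 10)
  expect_length(w, 9)
  expect_true(all(nchar(w) == 9))
  expect_length(nine_mer_windows(strrep("A", 9), 5), 1)
  expect_length(nine_mer_windows(strrep("A", 20), 1), 1)
  set.seed(501)
  for (L in 9:30) {
    seq <- paste(sample(AA20, L, replace = TRUE), collapse = "")
    for (p in seq_len(L)) {
      w <- nine_mer_windows(seq, p)
      expect_length(w, min(p, L - 8) - max(1, p - 8) + 1)
      # every window contains the mutated position
      starts <- max(1, p - 8):min(p, L - 8)
      expect_identical(w, vapply(starts, function(s) substr(seq, s, s + 8), ""))
    }
  }
  expect_warning(w0 <- nine_mer_windows("SHORT", 2), "shorter")
  expect_length(w0, 0)
  expect_error(nine_mer_windows(strrep("A", 12), 13), "outside")
})

test_that("neoantigen load counts pairs above threshold, with allele skipping", {
  mapping <- c(X = "GG", Y = "AA")
  always <- function(mhc, pep) 0.9
  never <- function(mhc, pep) 0.1
  cands <- c("AAAAAAAAA", "GGGGGGGGG", "AAAAGAAAA")
  expect_equal(neoantigen_load(c("X", "Y"), cands, always, mapping), 6L)
  expect_equal(neoantigen_load(c("X", "Y"), cands, never, mapping), 0L)
  expect_warning(
    l <- neoantigen_load(c("X", "Z"), cands, always, mapping), "unmapped")
  expect_equal(l, 3L)
  # planted-rule scorer equals a brute-force rule count
  prefs <- list(X = c("A", "G"), Y = c("G", "A"))
  rule <- function(mhc, pep) {
    al <- names(mapping)[match(mhc, mapping)]
    as.numeric(substr(pep, 2, 2) == prefs[[al]][1] &
                 substr(pep, 9, 9) == prefs[[al]][2])
  }
  set.seed(502)
  peps <- vapply(1:30, function(i) {
    paste(sample(c("A", "G"), 9, replace = TRUE), collapse = "")
  }, "")
  brute <- sum(outer(c("X", "Y"), peps, Vectorize(function(al, p) {
    substr(p, 2, 2) == prefs[[al]][1] & substr(p, 9, 9) == prefs[[al]][2]
  })))
  expect_equal(neoantigen_load(c("X", "Y"), peps, rule, mapping), brute)
  # unique-peptide counting collapses multi-allele hits
  expect_equal(neoantigen_load(c("X", "Y"), cands, always, mapping,
                               unique_peptides = TRUE), 3L)
})

test_that("median split sends ties to the low group and is scale invariant", {
  expect_equal(median_split(c(1, 2, 3, 4)), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(median_split(c(1, 2, 2, 5)), c(FALSE, FALSE, FALSE, TRUE))
  expect_warning(all_low <- median_split(c(3, 3, 3)), "degenerate")
  expect_false(any(all_low))
  set.seed(503)
  loads <- rpois(31, 5)
  expect_identical(median_split(loads), median_split(loads * 7 + 1))
  expect_error(median_split(1), "at least 2")
})

test_that("log-rank statistic agrees with a textbook implementation", {
  # fixed 20-subject toy table
  time <- c(5, 8, 12, 13, 18, 23, 26, 27, 30, 42,
            6, 9, 10, 11, 14, 16, 21, 29, 35, 40)
  event <- c(1, 0, 1, 1, 1, 1, 0, 1, 1, 1,
             1, 1, 0, 1, 1, 1, 1, 0, 1, 0)
  group <- rep(c("a", "b"), each = 10)
  res <- logrank_test(time, event, group)
  expect_equal(res$statistic, oracle_logrank(time, event, group),
               tolerance = 1e-6)
  expect_equal(res$p_value,
               pchisq(oracle_logrank(time, event, group), 1, lower.tail = FALSE),
               tolerance = 1e-6)
  # administrative censoring at a horizon truncates later events
  res5 <- logrank_test(time, event, group, horizon_days = 25)
  t2 <- pmin(time, 25); e2 <- ifelse(time > 25, 0, event)
  expect_equal(res5$statistic, oracle_logrank(t2, e2, group),
               tolerance = 1e-6)
  expect_error(logrank_test(time, event, rep("a", 20)), "two")
})

test_that("rank-sum statistic equals brute-force U counting", {
  set.seed(504)
  x <- rnorm(23); y <- rnorm(27, 0.5)
  res <- score_comparison(c(x, y), rep(c("low", "high"), c(23, 27)))
  # statistic reported for the second factor level ("low") vs first
  expect_equal(unname(res$statistic), oracle_u_stat(x, y), tolerance = 1e-9)
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(res$p_value, wt$p.value, tolerance = 1e-9)
  dup <- c(1:10, 1:10)
  resdup <- score_comparison(dup, rep(c("g1", "g2"), each = 10))
  expect_gt(resdup$p_value, 0.95)
})

test_that("baseline affinity transforms match their closed forms", {
  expect_equal(t_log(50000), 0)
  expect_equal(t_log(1), 1)
  expect_equal(t_log(500), 1 - log(500) / log(50000))
  expect_error(t_log(0), "positive")
  expect_equal(t_sig(0), 0.5)
  expect_lt(t_sig(10), t_sig(-10))
})

test_that("cohort analysis wires loads, split and tests together", {
  cc <- cohort_config(n_patients = 40, seed = 11, hazard_ratio_low = 4)
  coh <- generate_cohort(cc)
  # scoring function that reproduces the planted rule exactly
  prefs <- coh$truth$preferred
  ap <- coh$truth$anchor_positions
  rev_map <- stats::setNames(names(coh$mapping), coh$mapping)
  scorer <- function(mhc, pep) {
    al <- rev_map[[mhc]]
    as.numeric(all(vapply(seq_along(ap), function(j) {
      substr(pep, ap[j], ap[j]) == prefs[al, j]
    }, TRUE)))
  }
  res <- neoantigen_analysis(coh$patients, coh$clinical, scorer, coh$mapping)
  expect_equal(res$loads$load, coh$truth$true_load)
  expect_equal(res$loads$high_group, coh$truth$high_group)
  expect_named(res$scores, c("stromal", "immune", "estimate"))
  expect_true(res$survival$p_value >= 0 && res$survival$p_value <= 1)
})
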