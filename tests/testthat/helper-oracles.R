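# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Published molecular formulas of the 20 free amino acids.
KNOWN_AA_FORMULAS <- list(
  A = c(C = 3, H = 7, N = 1, O = 2), R = c(C = 6, H = 14, N = 4, O = 2),
  N = c(C = 4, H = 8, N = 2, O = 3), D = c(C = 4, H = 7, N = 1, O = 4),
  C = c(C = 3, H = 7, N = 1, O = 2, S = 1), E = c(C = 5, H = 9, N = 1, O = 4),
  Q = c(C = 5, H = 10, N = 2, O = 3), G = c(C = 2, H = 5, N = 1, O = 2),
  H = c(C = 6, H = 9, N = 3, O = 2), I = c(C = 6, H = 13, N = 1, O = 2),
  L = c(C = 6, H = 13, N = 1, O = 2), K = c(C = 6, H = 14, N = 2, O = 2),
  M = c(C = 5, H = 11, N = 1, O = 2, S = 1),
  F = c(C = 9, H = 11, N = 1, O = 2), P = c(C = 5, H = 9, N = 1, O = 2),
  S = c(C = 3, H = 7, N = 1, O = 3), T = c(C = 4, H = 9, N = 1, O = 3),
  W = c(C = 11, H = 12, N = 2, O = 2), Y = c(C = 9, H = 11, N = 1, O = 3),
  V = c(C = 5, H = 11, N = 1, O = 2)
)

AA20 <- names(KNOWN_AA_FORMULAS)

# Condensation arithmetic: sum of free-residue formulas minus (n-1) waters.
oracle_peptide_formula <- function(sequence) {
  letters1 <- strsplit(sequence, "")[[1]]
  tot <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (a in letters1) {
    f <- KNOWN_AA_FORMULAS[[a]]
    tot[names(f)] <- tot[names(f)] + f
  }
  tot["H"] <- tot["H"] - 2 * (length(letters1) - 1)
  tot["O"] <- tot["O"] - (length(letters1) - 1)
  tot[tot > 0]
}

# Brute-force AUC: average over all +/- pairs of the comparison outcome.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Rank-based AUC (Mann-Whitney identity); independent of the package and
# fast enough to drive bootstrap resampling.
oracle_fast_auc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(rank(scores)[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Brute-force ring membership: a bond is in a ring iff removing it leaves
# its endpoints connected (cycle test by BFS on the remaining bond list).
oracle_ring_bonds <- function(a1, a2, n_atoms) {
  adj <- function(drop) {
    nb <- vector("list", n_atoms)
    for (k in seq_along(a1)) {
      if (k == drop) next
      nb[[a1[k]]] <- c(nb[[a1[k]]], a2[k])
      nb[[a2[k]]] <- c(nb[[a2[k]]], a1[k])
    }
    nb
  }
  vapply(seq_along(a1), function(k) {
    nb <- adj(k)
    seen <- rep(FALSE, n_atoms)
    queue <- a1[k]; seen[a1[k]] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    seen[a2[k]]
  }, TRUE)
}

# Textbook Mantel-Cox log-rank chi-square for two groups.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  stopifnot(all(g %in% 1:2))
  times <- sort(unique(time[event == 1]))
  o1 <- 0; e1 <- 0; v <- 0
  for (t in times) {
    n_at <- sum(time >= t); n1_at <- sum(time >= t & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1_at / n_at
    if (n_at > 1) {
      v <- v + d * (n1_at / n_at) * (1 - n1_at / n_at) * (n_at - d) / (n_at - 1)
    }
  }
  (o1 - e1)^2 / v
}

# Brute-force Mann-Whitney U (number of (x, y) pairs with x > y, ties 0.5).
oracle_u_stat <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
  u
}

# Small deterministic featurized fixture set for network tests.
tiny_samples <- function() {
  list(featurize_pair("GA", "G", 1), featurize_pair("AC", "S", 0),
       featurize_pair("G", "GG", 1), featurize_pair("S", "A", 0))
}
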