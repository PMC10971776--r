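# Internal helpers.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) saved <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Group sums of matrix rows: returns an n_groups x ncol matrix where row g
# is the sum of rows of `m` with group index g (groups 1..n_groups, all
# rows of the result present even for empty groups).
.group_rowsum <- function(m, group, n_groups) {
  out <- rowsum(m, group)
  if (nrow(out) != n_groups) {
    full <- matrix(0, n_groups, ncol(m))
    full[as.integer(rownames(out)), ] <- out
    return(full)
  }
  dimnames(out) <- NULL
  out
}

.sigmoid <- function(x) 1 / (1 + exp(-x))
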