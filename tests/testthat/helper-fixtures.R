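# Small fixtures built in code, shared across test files.

# deterministic random expression matrix with labels
random_expression <- function(m = 50, n = 10, seed = 1) {
  set.seed(seed)
  expression_matrix(matrix(stats::rexp(m * n), m, n),
                    sprintf("g%03d", seq_len(m)),
                    sprintf("c%03d", seq_len(n)))
}

# tiny 5-type dataset for fast end-to-end style tests
small_dataset <- function(seed = 1, n_types = 5, cells_per_type = 40,
                          m_genes = 600) {
  simulate_labeled_counts(simulation_config(
    n_types = n_types, cells_per_type = cells_per_type,
    m_genes = m_genes, n_universal = 100, markers_per_type = 20,
    seed = seed))
}

# brute-force mHG p-value by enumerating all arrangements of r ones in m
# positions (independent of the DP implementation)
mhg_pvalue_enum <- function(score, m, r) {
  if (r == 0) return(1)
  combs <- utils::combn(m, r)
  hit <- 0
  for (j in seq_len(ncol(combs))) {
    lam <- integer(m)
    lam[combs[, j]] <- 1L
    ks <- cumsum(lam)
    tails <- stats::phyper(ks - 1, r, m - r, seq_len(m), lower.tail = FALSE)
    if (min(tails) <= score) hit <- hit + 1
  }
  hit / ncol(combs)
}

# exact minimum-cost column matching by enumerating permutations (small k)
clue_like_match <- function(err) {
  k <- nrow(err)
  perms <- all_permutations(k)
  costs <- apply(perms, 1, function(p) sum(err[cbind(seq_len(k), p)]^2))
  best <- perms[which.min(costs), ]
  list(row = seq_len(k), col = best)
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1, sub))
    out <- rbind(out, block)
  }
  out
}

# does any archetype's dominant-cell set match the given type with
# majority overlap in both directions?
rare_type_recovered <- function(labels, truth, type_id) {
  rare <- which(truth == type_id)
  for (a in unique(labels)) {
    dom <- which(labels == a)
    inter <- length(intersect(dom, rare))
    if (inter > length(dom) / 2 && inter > length(rare) / 2) return(TRUE)
  }
  FALSE
}
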