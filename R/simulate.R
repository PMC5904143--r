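#' Configuration for the labeled single-cell simulator
#'
#' The generator emulates the structural premise of the similarity
#' kernel: a transcriptome dominated by highly, uniformly expressed
#' universal genes, with each cell type distinguished only by a small set
#' of weakly expressed exclusive markers. Values live on a log-TPM-like
#' continuous scale (zero-truncated Gaussian around each gene's mean),
#' not counts.
#'
#' @param n_types number of cell types.
#' @param cells_per_type integer vector (length `n_types`) of cells per
#'   type; a single number is recycled. Rare types are planted by making
#'   one entry small.
#' @param m_genes total genes.
#' @param n_universal number of universally expressed genes.
#' @param markers_per_type exclusive marker genes per type.
#' @param universal_mean mean expression of universal genes (log-TPM-like
#'   units).
#' @param marker_effect mean expression of a marker in its own type
#'   (markers are silent elsewhere); deliberately weaker than
#'   `universal_mean`.
#' @param noise_sd standard deviation of the expression noise.
#' @param dropout apply one pass of the expression-dependent dropout
#'   model after generation.
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_types = 5, cells_per_type = 100,
                              m_genes = 2000, n_universal = 200,
                              markers_per_type = 20,
                              universal_mean = 4, marker_effect = 2,
                              noise_sd = 0.5, dropout = FALSE, seed = 1) {
  if (length(cells_per_type) == 1)
    cells_per_type <- rep(cells_per_type, n_types)
  if (length(cells_per_type) != n_types)
    stop("cells_per_type must have length n_types")
  cfg <- list(n_types = as.integer(n_types),
              cells_per_type = as.integer(cells_per_type),
              m_genes = as.integer(m_genes),
              n_universal = as.integer(n_universal),
              markers_per_type = as.integer(markers_per_type),
              universal_mean = universal_mean,
              marker_effect = marker_effect,
              noise_sd = noise_sd, dropout = isTRUE(dropout),
              seed = as.integer(seed))
  if (any(unlist(cfg[c("n_types", "cells_per_type", "m_genes")]) <= 0))
    stop("counts must be positive")
  if (cfg$markers_per_type < 0 || cfg$n_universal < 0)
    stop("counts must be non-negative")
  if (cfg$n_universal + cfg$n_types * cfg$markers_per_type > cfg$m_genes)
    stop("universal + marker genes exceed total gene count")
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a labeled expression matrix
#'
#' Universal genes have a high mean in every cell; each type's markers
#' have mean `marker_effect` only in that type's cells; remaining
#' background genes have mean 0. Gaussian noise of sd `noise_sd` is added
#' and values are truncated at zero, giving a sparse non-negative
#' log-scale matrix.
#'
#' @param config a [simulation_config()].
#' @return object of class `labeled_dataset`: list with `X`
#'   (an [expression_matrix()]), `labels` (integer type per cell, 1-based),
#'   `marker_table` (type -> marker gene ids), `universal_genes`, and the
#'   `config`.
#' @export
simulate_labeled_counts <- function(config = simulation_config()) {
  cfg <- config
  set.seed(cfg$seed)
  m <- cfg$m_genes
  n <- sum(cfg$cells_per_type)
  labels <- rep(seq_len(cfg$n_types), cfg$cells_per_type)
  gene_ids <- sprintf("g%04d", seq_len(m))
  cell_ids <- sprintf("c%04d", seq_len(n))
  uni <- seq_len(cfg$n_universal)
  marker_table <- list()
  nxt <- cfg$n_universal
  mu <- matrix(0, m, n)
  mu[uni, ] <- cfg$universal_mean
  for (t in seq_len(cfg$n_types)) {
    idx <- nxt + seq_len(cfg$markers_per_type)
    nxt <- nxt + cfg$markers_per_type
    marker_table[[t]] <- gene_ids[idx]
    if (cfg$markers_per_type > 0)
      mu[idx, labels == t] <- cfg$marker_effect
  }
  names(marker_table) <- paste0("type", seq_len(cfg$n_types))
  X <- pmax(mu + matrix(stats::rnorm(m * n, sd = cfg$noise_sd), m, n), 0)
  X <- expression_matrix(X, gene_ids, cell_ids)
  if (cfg$dropout) X <- apply_dropout(X, seed = cfg$seed + 1L)
  structure(list(X = X, labels = labels, marker_table = marker_table,
                 universal_genes = gene_ids[uni], config = cfg),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset: ", nrow(x$X), " genes x ", ncol(x$X), " cells, ",
      x$config$n_types, " types\n", sep = "")
  invisible(x)
}

#' Expression-dependent dropout
#'
#' Each nonzero entry x is independently zeroed with probability
#' 2^(-6x): weakly expressed transcripts are lost preferentially,
#' strongly expressed ones almost never. Zeros are untouched.
#'
#' @param X non-negative expression matrix.
#' @param seed RNG seed.
#' @return matrix of the same shape and dimnames.
#' @export
apply_dropout <- function(X, seed = 1) {
  cls <- class(X)
  X <- unclass(X)
  set.seed(seed)
  nz <- which(X > 0)
  p <- 2^(-6 * X[nz])
  drop <- stats::runif(length(nz)) < p
  X[nz[drop]] <- 0
  class(X) <- cls
  X
}

#' Repeated dropout passes down to a target density
#'
#' Applies [apply_dropout()] repeatedly until the fraction of retained
#' nonzero entries (relative to the input) falls to `target_density`,
#' or `max_passes` is reached.
#'
#' @param X non-negative expression matrix.
#' @param target_density fraction of the original nonzeros to retain.
#' @param seed RNG seed (incremented per pass).
#' @param max_passes safety cap.
#' @return list with `X` and `density` (retained-nonzero fraction).
#' @export
dropout_series <- function(X, target_density, seed = 1, max_passes = 100L) {
  nz0 <- sum(unclass(X) > 0)
  dens <- 1
  pass <- 0L
  while (dens > target_density && pass < max_passes) {
    pass <- pass + 1L
    X <- apply_dropout(X, seed = seed + pass)
    dens <- sum(unclass(X) > 0) / nz0
  }
  list(X = X, density = dens, passes = pass)
}

#' Simulate a noiseless or near-separable instance
#'
#' Plants k pure columns at known indices; every other column is a random
#' convex combination of the pure columns plus a noise column scaled so
#' its 2-norm is at most `noise_eps`.
#'
#' @param m rows, `k` pure columns, `n` total columns.
#' @param noise_eps maximum column-wise noise norm (0 = exactly
#'   separable).
#' @param seed RNG seed.
#' @return list with `Y` (m x n), `true_indices` (length k) and `H_true`
#'   (k x n column-stochastic, identity block on the pure columns).
#' @export
simulate_separable_instance <- function(m, k, n, noise_eps = 0, seed = 1) {
  if (k > n) stop("k must not exceed n")
  set.seed(seed)
  W <- matrix(stats::runif(m * k), m, k)       # pure columns, a.s. full rank
  true_indices <- sort(sample.int(n, k))
  H <- matrix(0, k, n)
  H[, true_indices] <- diag(k)
  others <- setdiff(seq_len(n), true_indices)
  if (length(others) > 0) {
    mix <- matrix(stats::rexp(k * length(others)), k, length(others))
    mix <- sweep(mix, 2, colSums(mix), "/")
    H[, others] <- mix
  }
  Y <- W %*% H
  if (noise_eps > 0) {
    N <- matrix(stats::rnorm(m * n), m, n)
    nn <- sqrt(colSums(N^2))
    N <- sweep(N, 2, nn, "/") * stats::runif(n, 0, noise_eps)
    Y <- Y + N
  }
  list(Y = Y, true_indices = true_indices, H_true = H)
}

#' Plant TF regulons aligned with a cell type's markers
#'
#' Builds a regulon table in which one TF's targets overlap a chosen
#' type's marker genes by a configurable fraction (the remainder and all
#' other TFs draw targets uniformly from non-marker genes), to drive
#' planted-enrichment tests of the TRN step.
#'
#' @param dataset a `labeled_dataset`.
#' @param focal_type index of the type whose markers seed the focal TF.
#' @param n_targets targets per TF.
#' @param overlap number of the focal TF's targets drawn from the focal
#'   type's markers.
#' @param n_decoy_tfs additional TFs with random targets.
#' @param seed RNG seed.
#' @return a `regulon_set`; the focal TF is named `"TF_A"`, decoys
#'   `"TF_B"`, `"TF_C"`, ...
#' @export
plant_regulons <- function(dataset, focal_type = 1, n_targets = 20,
                           overlap = 15, n_decoy_tfs = 4, seed = 1) {
  set.seed(seed)
  genes <- rownames(dataset$X)
  markers <- dataset$marker_table[[focal_type]]
  if (overlap > length(markers))
    stop("overlap exceeds number of markers of the focal type")
  if (overlap > n_targets) stop("overlap exceeds n_targets")
  nonmark <- setdiff(genes, unlist(dataset$marker_table))
  focal <- c(sample(markers, overlap),
             sample(nonmark, n_targets - overlap))
  reg <- list(TF_A = focal)
  for (i in seq_len(n_decoy_tfs)) {
    reg[[paste0("TF_", LETTERS[i + 1])]] <- sample(nonmark, n_targets)
  }
  regulon_set(reg, provenance = "planted")
}

#' Write the regulon table of a `regulon_set` as TRRUST-style TSV
#'
#' @param regulons a `regulon_set`.
#' @param path output path.
#' @export
write_regulons <- function(regulons, path) {
  rows <- unlist(lapply(names(regulons), function(tf)
    sprintf("%s\t%s\tUnknown\tplanted", tf, regulons[[tf]])))
  writeLines(rows, path)
  invisible(path)
}
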