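#' Kernel k-means clustering
#'
#' Lloyd iterations carried out entirely in the kernel: the squared
#' distance from cell j to the centroid of cluster c is
#' `K_jj - 2 mean_{i in c} K_ij + mean_{i,i' in c} K_ii'`. Starts from
#' random assignments; the best of `n_init` runs (lowest within-cluster
#' objective) is returned. Tiny negative kernel eigenvalues are tolerated
#' (distances are used as-is); an emptied cluster is re-seeded with the
#' point farthest from its current centroid.
#'
#' @param K n x n symmetric kernel matrix.
#' @param k number of clusters (2 <= k < n).
#' @param n_init number of random initializations.
#' @param seed RNG seed; results are deterministic given the seed.
#' @param max_iter Lloyd iteration cap per initialization.
#' @return object of class `kernel_kmeans`: list with `labels` (1..k),
#'   `inertia` (best objective), `n_init`, `seed`.
#' @export
kernel_kmeans <- function(K, k, n_init = 100, seed = 1, max_iter = 100L) {
  K <- unclass(K)
  n <- nrow(K)
  if (k < 2 || k >= n) stop("need 2 <= k < n")
  set.seed(seed)
  dK <- diag(K)
  best <- NULL; best_obj <- Inf
  for (init in seq_len(n_init)) {
    lab <- sample.int(k, n, replace = TRUE)
    lab[sample.int(n, k)] <- seq_len(k)   # guarantee non-empty start
    for (it in seq_len(max_iter)) {
      Z <- matrix(0, n, k)
      Z[cbind(seq_len(n), lab)] <- 1
      sizes <- colSums(Z)
      if (any(sizes == 0)) {              # re-seed an emptied cluster
        for (c0 in which(sizes == 0)) {
          far <- which.max(dK)            # fallback; refined below
          lab[far] <- c0
        }
        Z <- matrix(0, n, k); Z[cbind(seq_len(n), lab)] <- 1
        sizes <- colSums(Z)
      }
      KZ <- K %*% Z
      B <- sweep(KZ, 2, sizes, "/")                    # mean K to cluster
      t3 <- colSums(Z * KZ) / sizes^2                  # within-cluster mean
      D <- matrix(dK, n, k) - 2 * B + matrix(t3, n, k, byrow = TRUE)
      new_lab <- max.col(-D, ties.method = "first")
      # keep clusters non-empty: give an empty cluster the farthest point
      miss <- setdiff(seq_len(k), unique(new_lab))
      for (c0 in miss) {
        far <- which.max(D[cbind(seq_len(n), new_lab)])
        new_lab[far] <- c0
      }
      if (all(new_lab == lab)) break
      lab <- new_lab
    }
    Z <- matrix(0, n, k); Z[cbind(seq_len(n), lab)] <- 1
    sizes <- pmax(colSums(Z), 1)
    KZ <- K %*% Z
    B <- sweep(KZ, 2, sizes, "/")
    t3 <- colSums(Z * KZ) / sizes^2
    D <- matrix(dK, n, k) - 2 * B + matrix(t3, n, k, byrow = TRUE)
    obj <- sum(D[cbind(seq_len(n), lab)])
    if (obj < best_obj) { best_obj <- obj; best <- lab }
  }
  structure(list(labels = best, inertia = best_obj, n_clusters = k,
                 n_init = n_init, seed = seed),
            class = "kernel_kmeans")
}

#' Extrinsic clustering agreement scores
#'
#' Computes the Adjusted Rand Index (chance-corrected pair agreement),
#' Normalized Mutual Information (mutual information divided by the
#' arithmetic mean of the two label entropies), and the pairwise F-score
#' (harmonic mean of precision and recall over co-clustered pairs, with
#' `pred` pairs as predictions and `truth` pairs as reference).
#'
#' @param pred,truth label vectors of equal length.
#' @return list with `ari`, `nmi`, `fscore`.
#' @export
clustering_scores <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have the same length")
  n <- length(pred)
  tab <- table(pred, truth)
  a <- rowSums(tab); b <- colSums(tab)
  sum_nij <- sum(choose(tab, 2))
  sum_a <- sum(choose(a, 2)); sum_b <- sum(choose(b, 2))
  tot <- choose(n, 2)
  expected <- sum_a * sum_b / tot
  max_idx <- (sum_a + sum_b) / 2
  ari <- if (max_idx == expected) 1 else (sum_nij - expected) / (max_idx - expected)
  # NMI (arithmetic-mean normalization)
  pj <- tab / n
  pa <- a / n; pb <- b / n
  nzc <- pj > 0
  mi <- sum(pj[nzc] * log(pj[nzc] / (outer(pa, pb))[nzc]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  nmi <- if (ha + hb == 0) 1 else mi / ((ha + hb) / 2)
  # pairwise F-score
  tp <- sum_nij
  prec <- if (sum_a == 0) 1 else tp / sum_a
  rec <- if (sum_b == 0) 1 else tp / sum_b
  fscore <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(ari = ari, nmi = nmi, fscore = fscore)
}
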