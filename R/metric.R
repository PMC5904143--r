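#' Standardize each cell profile over genes
#'
#' Each column (cell) is z-scored across its m gene entries using the
#' sample (m-1 denominator) standard deviation, so downstream projections
#' operate on comparable profiles regardless of per-cell scale.
#'
#' @param X genes x cells numeric matrix.
#' @return matrix `Z` of the same shape; every column has mean 0 and
#'   sample sd 1.
#' @export
standardize_cells <- function(X) {
  X <- unclass(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  zero <- which(sdv == 0 | !is.finite(sdv))
  if (length(zero) > 0) {
    ids <- colnames(X)[zero]
    if (is.null(ids)) ids <- as.character(zero)
    stop("cell profile has zero variance and cannot be standardized: ",
         paste(utils::head(ids, 5), collapse = ", "))
  }
  sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
}

#' Universal expression signature
#'
#' The mean expression of each gene across all cells is used as a
#' first-order proxy for ubiquitous ("housekeeping") expression; its
#' standardized form is the direction that is later projected out of every
#' cell profile.
#'
#' @param X genes x cells numeric matrix.
#' @return list with `v` (row means) and `z_v` (v standardized over genes,
#'   sample sd).
#' @export
universal_signature <- function(X) {
  X <- unclass(X)
  v <- rowMeans(X)
  s <- stats::sd(v)
  if (s == 0 || !is.finite(s))
    stop("universal signature is constant across genes; cannot standardize")
  list(v = v, z_v = (v - mean(v)) / s)
}

#' Project cell profiles onto the orthogonal complement of the universal
#' signature
#'
#' Applies the rank-one projector `I - z_v z_v^T / ||z_v||^2` to every
#' column of `Z`, removing the component of each standardized cell profile
#' that lies along the universal expression direction.
#'
#' @param Z standardized genes x cells matrix.
#' @param z_v standardized universal signature (length = nrow(Z)).
#' @return the adjusted profile matrix `Zperp`.
#' @export
project_out_universal <- function(Z, z_v) {
  if (length(z_v) != nrow(Z))
    stop("z_v has length ", length(z_v), " but Z has ", nrow(Z), " rows")
  nrm2 <- sum(z_v^2)
  if (nrm2 <= 0) stop("z_v has zero norm")
  Z - tcrossprod(z_v / nrm2, crossprod(Z, z_v))
}

#' Gene specificity via normalized entropy
#'
#' Negative entries of the adjusted profiles are zeroed, rows are
#' normalized to a row-stochastic matrix P, and each gene's uniformity is
#' the normalized Shannon entropy of its row. The normalizer is
#' `log(n_cells)` (the row length), so a gene used uniformly across cells
#' attains u = 1 and a gene positive in a single cell attains u = 0.
#'
#' @param Zperp adjusted genes x cells matrix.
#' @return list with `P` (row-stochastic; all-zero rows left as zeros),
#'   `u` (normalized entropies, `NA` for all-zero rows) and `zero_rows`
#'   (logical flag per gene).
#' @export
gene_specificity <- function(Zperp) {
  pos <- pmax(unclass(Zperp), 0)
  rs <- rowSums(pos)
  zero_rows <- rs == 0
  P <- pos
  P[!zero_rows, ] <- pos[!zero_rows, , drop = FALSE] / rs[!zero_rows]
  n <- ncol(P)
  plogp <- P * log(P)
  plogp[P == 0] <- 0
  u <- -rowSums(plogp) / log(n)
  u[zero_rows] <- NA_real_
  # guard against tiny negative round-off
  u <- pmin(pmax(u, 0), 1)
  list(P = P, u = u, zero_rows = zero_rows)
}

#' Split bimodal entropies and derive gene weights
#'
#' The distribution of gene uniformities is bimodal: a specific-gene mode
#' at low entropy and a universal-gene mode near 1. A two-component
#' Gaussian mixture (unshared variances) is fitted to the finite
#' entropies; the threshold `u_hat` is the equal-density crossing of the
#' two weighted component densities, located between the component means
#' by bisection. Weights are `w_i = u_hat / u_i` after clamping `u_i` to
#' `[u_min, 1]`, so specific genes (u below the threshold) are scaled up
#' and universal genes scaled down. Genes with an all-zero positive
#' projection (u = NA) get weight 1.
#'
#' @param u numeric vector of normalized entropies (NAs allowed).
#' @param u_min lower clamp for u before division; keeps weights finite
#'   for genes positive in a single cell. Callers working from an n-cell
#'   matrix use `1/log(n)`.
#' @return list with `u_hat`, `w`, and the fitted mixture parameters
#'   (`means`, `sds`, `lambdas`).
#' @export
fit_entropy_threshold <- function(u, u_min = 1e-3) {
  uf <- u[is.finite(u)]
  if (length(uf) < 10)
    stop("need at least 10 finite entropy values to fit the mixture")
  # Mclust resolves mclustBIC in the caller's frame; bind it locally so
  # the fit works without attaching mclust
  mclustBIC <- mclust::mclustBIC
  fit <- suppressWarnings(
    mclust::Mclust(uf, G = 2, modelNames = "V", verbose = FALSE)
  )
  if (is.null(fit)) {
    # degenerate data (e.g. near-constant entropies): split at the mean
    u_hat <- mean(uf)
    warning("Gaussian mixture fit failed; using mean entropy as threshold")
    pars <- list(means = c(NA, NA), sds = c(NA, NA), lambdas = c(NA, NA))
  } else {
    mu <- as.numeric(fit$parameters$mean)
    sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
    if (length(sig) == 1) sig <- rep(sig, 2)
    lam <- as.numeric(fit$parameters$pro)
    o <- order(mu)
    mu <- mu[o]; sig <- sig[o]; lam <- lam[o]
    dd <- function(x) lam[1] * stats::dnorm(x, mu[1], sig[1]) -
      lam[2] * stats::dnorm(x, mu[2], sig[2])
    u_hat <- NULL
    if (mu[2] - mu[1] > sqrt(.Machine$double.eps)) {
      f1 <- dd(mu[1]); f2 <- dd(mu[2])
      if (is.finite(f1) && is.finite(f2) && sign(f1) != sign(f2) &&
          f1 != 0 && f2 != 0) {
        u_hat <- stats::uniroot(dd, c(mu[1], mu[2]), tol = 1e-10)$root
      }
    }
    if (is.null(u_hat)) {
      u_hat <- mean(mu)
      warning("no equal-density crossing between component means; ",
              "falling back to their midpoint")
    }
    pars <- list(means = mu, sds = sig, lambdas = lam)
  }
  uc <- pmin(pmax(u, u_min), 1)
  w <- u_hat / uc
  w[!is.finite(u)] <- 1
  c(list(u_hat = u_hat, w = w), pars)
}

#' Weighted dot-product kernel of adjusted profiles
#'
#' Forms `Y = diag(w) Zperp` and returns `K = Y^T Y`, the
#' specificity-weighted inner-product similarity between cells.
#'
#' @param Zperp adjusted genes x cells matrix.
#' @param w positive finite gene weights (length = nrow(Zperp)).
#' @return list with `K` (n x n symmetric PSD) and `Y`.
#' @export
compute_kernel <- function(Zperp, w) {
  if (length(w) != nrow(Zperp))
    stop("weight vector length does not match gene count")
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be finite and positive")
  Y <- unclass(Zperp) * w
  K <- crossprod(Y)
  K <- (K + t(K)) / 2
  list(K = K, Y = Y)
}

#' ACTION cell-similarity kernel
#'
#' End-to-end computation of the cell kernel from a raw expression matrix:
#' per-cell standardization, removal of the universal-expression
#' direction, entropy-based gene weighting, and the weighted dot-product
#' kernel. Expression is used on the scale supplied (no internal log
#' transform); pass the same scale you would cluster on.
#'
#' @param X genes x cells non-negative expression matrix with dimnames
#'   (or an [expression_matrix()]).
#' @return an object of class `action_kernel`: list with `K` (n x n
#'   kernel), `Y` (weighted adjusted profiles), `Zperp`, `z_v`, `u`,
#'   `u_hat`, `w`, `cell_ids`, `gene_ids`.
#' @export
action_kernel <- function(X) {
  X <- expression_matrix(as.matrix(X))
  Z <- standardize_cells(X)
  us <- universal_signature(X)
  Zperp <- project_out_universal(Z, us$z_v)
  gs <- gene_specificity(Zperp)
  u_min <- 1 / log(ncol(X))
  th <- fit_entropy_threshold(gs$u, u_min = u_min)
  kr <- compute_kernel(Zperp, th$w)
  structure(
    list(K = kr$K, Y = kr$Y, Zperp = Zperp, z_v = us$z_v,
         u = gs$u, u_hat = th$u_hat, w = th$w,
         gene_ids = rownames(X), cell_ids = colnames(X)),
    class = "action_kernel")
}

#' @export
print.action_kernel <- function(x, ...) {
  cat("action_kernel: ", length(x$cell_ids), " cells, ",
      length(x$gene_ids), " genes; entropy threshold u_hat = ",
      signif(x$u_hat, 4), "\n", sep = "")
  invisible(x)
}
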