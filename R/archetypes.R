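#' Minimum-volume origin-centered ellipsoid (Khachiyan ascent)
#'
#' Finds the matrix E of the minimum-volume ellipsoid {x : x'Ex <= 1}
#' centered at the origin containing all columns of `P` together with
#' their reflections (the sign-symmetrized set), via barycentric
#' coordinate ascent on the log-det design objective.
#'
#' @param P d x n matrix of points (columns).
#' @param tol relative convergence tolerance on the support condition.
#' @param max_iter iteration cap.
#' @return list with `E` (d x d SPD ellipsoid matrix) and `u` (support
#'   weights over columns).
#' @keywords internal
mve_origin <- function(P, tol = 1e-2, max_iter = 10000L) {
  d <- nrow(P); n <- ncol(P)
  u <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    M <- P %*% (u * t(P))                 # P diag(u) P'
    Minv <- tryCatch(solve(M), error = function(e) NULL)
    if (is.null(Minv)) Minv <- MASS::ginv(M)
    kappa <- colSums(P * (Minv %*% P))    # leverage of each point
    j <- which.max(kappa)
    km <- kappa[j]
    if (km <= d * (1 + tol)) break
    step <- (km - d) / (d * (km - 1))
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  M <- P %*% (u * t(P))
  E <- tryCatch(solve(M), error = function(e) MASS::ginv(M)) / d
  E <- (E + t(E)) / 2
  list(E = E, u = u)
}

#' Precondition adjusted profiles for column selection
#'
#' Reduces the columns of `Y` to `r` dimensions by truncated SVD and then
#' applies a linear transform that maps the minimum-volume origin-centered
#' ellipsoid of the (sign-symmetrized) reduced columns to the unit ball.
#' Preconditioning preserves which columns generate the others (any
#' nonsingular transform does) while improving the conditioning of greedy
#' corner selection.
#'
#' @param Y m x n matrix of profiles (columns = cells).
#' @param r target dimensionality; reduced with a warning if the numeric
#'   rank of `Y` is below `r`.
#' @param mve_tol,mve_max_iter tolerance and cap for the ellipsoid solver.
#' @return list with `Yp` (r x n preconditioned columns), `r` (rank
#'   actually used), `L` (the ellipsoid Cholesky factor applied after the
#'   SVD reduction) and `V`, `d` (right singular vectors / singular
#'   values of the reduction).
#' @export
precondition_profiles <- function(Y, r, mve_tol = 1e-2,
                                  mve_max_iter = 10000L) {
  Y <- unclass(Y)
  if (r > min(dim(Y))) stop("target rank r exceeds min(dim(Y))")
  sv <- svd(Y, nu = 0, nv = min(dim(Y)))
  keep <- sum(sv$d > max(sv$d) * 1e-10)
  if (keep < r) {
    warning("numeric rank ", keep, " below requested r = ", r,
            "; reducing")
    r <- keep
  }
  Yr <- sv$d[seq_len(r)] * t(sv$v[, seq_len(r), drop = FALSE])
  prec <- precondition_reduced(Yr, tol = mve_tol, max_iter = mve_max_iter)
  list(Yp = prec$Yp, r = r, L = prec$L,
       V = sv$v[, seq_len(r), drop = FALSE], d = sv$d[seq_len(r)])
}

# MVE normalization of an already rank-reduced point set (r x n).
# For an origin-centered ellipsoid the symmetrized set {+/-y} yields the
# same design matrix as the original columns, so no explicit reflection
# is needed.
precondition_reduced <- function(Yr, tol = 1e-2, max_iter = 10000L) {
  mve <- mve_origin(Yr, tol = tol, max_iter = max_iter)
  L <- tryCatch(chol(mve$E), error = function(e) {
    eg <- eigen(mve$E, symmetric = TRUE)
    vals <- pmax(eg$values, max(eg$values) * 1e-12)
    chol(eg$vectors %*% (vals * t(eg$vectors)))
  })
  list(Yp = L %*% Yr, L = L)
}

#' Successive projection algorithm (SPA)
#'
#' Greedy selection of k candidate pure columns: repeatedly pick the
#' column with the largest 2-norm, then project all columns onto the
#' orthogonal complement of the pick. Exact recovery is guaranteed for
#' noiseless separable matrices. Ties on the norm break to the lowest
#' column index.
#'
#' @param Yp matrix whose columns are candidate points (typically the
#'   preconditioned profiles).
#' @param k number of columns to select.
#' @return integer vector of selected column indices, in selection order
#'   (may be shorter than `k`, with a warning, if the residual vanishes).
#' @export
spa_select <- function(Yp, k) {
  Yp <- unclass(Yp)
  n <- ncol(Yp)
  if (k > n) stop("k exceeds number of columns")
  R <- Yp
  sel <- integer(0)
  nrm0 <- max(sqrt(colSums(R^2)))
  for (step in seq_len(k)) {
    nrms <- sqrt(colSums(R^2))
    nrms[sel] <- -Inf
    j <- as.integer(which.max(nrms))  # first max = lowest index on ties
    if (!is.finite(nrms[j]) || nrms[j] <= 1e-12 * nrm0) {
      warning("residual numerically zero after ", length(sel),
              " of ", k, " selections")
      break
    }
    sel <- c(sel, j)
    q <- R[, j] / nrms[j]
    R <- R - tcrossprod(q, crossprod(R, q))
  }
  sel
}

#' Oversampling test on the archetype similarity graph
#'
#' Given candidate cells, their pairwise kernel similarities are z-scored;
#' pairs above `z_threshold` become edges of the archetype similarity
#' graph. Each multi-node connected component is tested for excess density
#' against an Erdos-Renyi background whose edge probability is the
#' null edge probability implied by the Gaussian assumption behind the
#' z-threshold, `1 - pnorm(z_threshold)` (0.025 at the default 1.96): a
#' component with c nodes and e edges gets p-value
#' P(Binomial(choose(c,2), p_edge) >= e), Bonferroni-corrected over
#' multi-node components. Oversampling is flagged when any component is
#' significantly dense at 0.05. With fewer than 4 candidates (< 6 pairs)
#' the test is skipped and never flags; zero-variance similarities give
#' all-zero z-scores and no edges.
#'
#' @param K full cell kernel matrix.
#' @param S integer indices of the candidate cells.
#' @param z_threshold edge threshold on z-scored similarities.
#' @param alpha component-density significance level.
#' @param edge_prob ER background edge probability; defaults to
#'   `1 - pnorm(z_threshold)`.
#' @return list with `flagged`, `graph` (igraph object), `z` (named
#'   pairwise z-scores), `component_pvalues`.
#' @export
detect_oversampling <- function(K, S, z_threshold = 1.96, alpha = 0.05,
                                edge_prob = NULL) {
  if (is.null(edge_prob)) edge_prob <- 1 - stats::pnorm(z_threshold)
  k <- length(S)
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  if (k < 4)
    return(list(flagged = FALSE, graph = g, z = numeric(0),
                component_pvalues = numeric(0)))
  sub <- K[S, S, drop = FALSE]
  pairs <- which(upper.tri(sub), arr.ind = TRUE)
  sims <- sub[upper.tri(sub)]
  s <- stats::sd(sims)
  z <- if (s == 0 || !is.finite(s)) rep(0, length(sims))
       else (sims - mean(sims)) / s
  ed <- pairs[z > z_threshold, , drop = FALSE]
  if (nrow(ed) > 0)
    g <- igraph::add_edges(g, as.vector(t(ed)))
  comps <- igraph::components(g)
  pvals <- numeric(0)
  if (nrow(ed) > 0) {
    memb <- comps$membership
    multi <- which(comps$csize >= 2)
    for (ci in multi) {
      nodes <- which(memb == ci)
      e <- sum(memb[ed[, 1]] == ci)
      trials <- choose(length(nodes), 2)
      pvals <- c(pvals, stats::pbinom(e - 1, trials, edge_prob,
                                      lower.tail = FALSE))
    }
  }
  flagged <- length(pvals) > 0 && any(pvals * length(pvals) <= alpha)
  list(flagged = flagged, graph = g, z = z, component_pvalues = pvals)
}

#' Choose the number of archetypes by incremental oversampling monitoring
#'
#' Increases k from `k_min`, at each step selecting k candidate cells with
#' preconditioned SPA and testing the candidate set for oversampling. The
#' chosen k is the last value before the first flagged k; if no k up to
#' `k_max` is flagged, `k_max` is returned with a warning.
#'
#' @param Y weighted adjusted profiles (genes x cells).
#' @param K cell kernel (computed as `crossprod(Y)` if missing).
#' @param k_min,k_max search range.
#' @param z_threshold passed to [detect_oversampling()].
#' @return list with `k_star`, `candidates` (list of index vectors per k),
#'   `flags`, `diagnostics` per k.
#' @export
select_num_archetypes <- function(Y, K = NULL, k_min = 2,
                                  k_max = min(30, ncol(Y) - 1),
                                  z_threshold = 1.96) {
  Y <- unclass(Y)
  n <- ncol(Y)
  if (!(2 <= k_min && k_min < k_max && k_max <= n))
    stop("need 2 <= k_min < k_max <= n")
  if (is.null(K)) K <- crossprod(Y)
  # one spectral decomposition of the kernel serves every k: the reduced
  # r-dim coordinates are d_r * t(v_r)
  r_cap <- min(k_max, n)
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  evals <- pmax(eg$values, 0)
  keep <- sum(evals > max(evals) * 1e-12)
  dsv <- sqrt(evals[seq_len(keep)])
  Vt <- t(eg$vectors[, seq_len(keep), drop = FALSE])
  candidates <- list(); flags <- logical(0); diag_list <- list()
  k_star <- NA_integer_
  for (k in k_min:k_max) {
    r <- min(k, keep)
    Yr <- dsv[seq_len(r)] * Vt[seq_len(r), , drop = FALSE]
    Yp <- precondition_reduced(Yr)$Yp
    S <- spa_select(Yp, k)
    det <- detect_oversampling(K, S, z_threshold = z_threshold)
    candidates[[as.character(k)]] <- S
    flags <- c(flags, det$flagged)
    diag_list[[as.character(k)]] <- det$component_pvalues
    if (det$flagged) {
      k_star <- max(k_min, k - 1L)
      break
    }
  }
  if (is.na(k_star)) {
    warning("no oversampling detected up to k_max = ", k_max,
            "; returning k_max")
    k_star <- k_max
  }
  list(k_star = as.integer(k_star), candidates = candidates,
       flags = flags, diagnostics = diag_list)
}

# Euclidean projection of each column onto the probability simplex
proj_simplex_cols <- function(M) {
  apply(M, 2, function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    theta <- (css[rho] - 1) / rho
    pmax(v - theta, 0)
  })
}

#' Principal convex hull analysis (archetypal analysis)
#'
#' Alternating projected-gradient minimization of ||Y - Y C H||_F over
#' column-stochastic C (n x k) and H (k x n), initialized from candidate
#' pure cells (C = indicator columns). Steps are accepted only when the
#' objective decreases (backtracking with multiplicative step adaptation),
#' so the objective trace is non-increasing by construction. With
#' `delta > 0` the column sums of C may relax into [1-delta, 1+delta],
#' letting archetypes move slightly outside the convex hull of the data.
#'
#' @param Y genes x cells profile matrix.
#' @param init integer vector of k initial candidate column indices.
#' @param k number of archetypes (defaults to `length(init)`).
#' @param delta corner relaxation radius (default 0 = strict convex hull).
#' @param max_iter,tol iteration cap and relative objective tolerance.
#' @return object of class `archetypal_decomposition`: list with `C`, `H`,
#'   `A = Y C`, `k`, `objective_trace` (||Y - YCH||_F per iteration).
#' @export
pcha_fit <- function(Y, init, k = length(init), delta = 0,
                     max_iter = 200L, tol = 1e-6) {
  Y <- unclass(Y)
  n <- ncol(Y)
  if (length(init) != k) stop("init must supply k column indices")
  if (any(init < 1 | init > n)) stop("init indices out of range")
  S <- crossprod(Y)                       # Gram matrix; all updates use it
  trS <- sum(diag(S))
  C <- matrix(0, n, k)
  C[cbind(init, seq_len(k))] <- 1
  # initial H: each candidate cell represents itself exactly, everything
  # else starts uniform; a few projected steps then settle H for fixed C
  H <- matrix(1 / k, k, n)
  H[, init] <- diag(k)

  obj_fun <- function(C, H) {
    SC <- S %*% C
    CtSC <- crossprod(C, SC)
    f2 <- trS - 2 * sum(t(SC) * H) + sum(H * (CtSC %*% H))
    sqrt(max(f2, 0))
  }

  scale_cols_delta <- function(C) {
    if (delta <= 0) return(C)
    cs <- colSums(C)
    tgt <- pmin(pmax(cs, 1 - delta), 1 + delta)
    sweep(C, 2, ifelse(cs > 0, tgt / cs, 1), "*")
  }

  update_block <- function(C, H, which, mu) {
    # one backtracking projected-gradient step on C or H
    f0 <- obj_fun(C, H)
    if (which == "H") {
      SC <- S %*% C
      G <- 2 * (crossprod(C, SC) %*% H - t(SC))
    } else {
      SH <- tcrossprod(S, H)              # n x k  (S H^T)
      G <- 2 * (S %*% C %*% tcrossprod(H) - SH)
    }
    gmax <- max(abs(G))
    if (gmax == 0) return(list(C = C, H = H, mu = mu, f = f0))
    for (try in 1:12) {
      if (which == "H") {
        Hn <- proj_simplex_cols(H - mu * G)
        f1 <- obj_fun(C, Hn)
        if (f1 <= f0) return(list(C = C, H = Hn, mu = mu * 2, f = f1))
      } else {
        Cn <- proj_simplex_cols(C - mu * G)
        Cn <- scale_cols_delta(Cn)
        f1 <- obj_fun(Cn, H)
        if (f1 <= f0) return(list(C = Cn, H = H, mu = mu * 2, f = f1))
      }
      mu <- mu / 2
    }
    list(C = C, H = H, mu = mu, f = f0)
  }

  mu_C <- 1 / max(abs(S)); mu_H <- mu_C
  # settle H for the indicator C first
  for (i in 1:25) {
    st <- update_block(C, H, "H", mu_H)
    H <- st$H; mu_H <- st$mu
  }
  trace <- obj_fun(C, H)
  for (it in seq_len(max_iter)) {
    st <- update_block(C, H, "C", mu_C); C <- st$C; mu_C <- st$mu
    st <- update_block(C, H, "H", mu_H); H <- st$H; mu_H <- st$mu
    f <- st$f
    if (!is.finite(f)) stop("PCHA objective became non-finite at iteration ", it)
    trace <- c(trace, f)
    prev <- trace[length(trace) - 1]
    if (prev - f < tol * max(prev, .Machine$double.eps)) break
  }
  A <- Y %*% C
  rownames(A) <- rownames(Y)
  structure(list(C = C, H = H, A = A, k = k, objective_trace = trace,
                 delta = delta, init = init),
            class = "archetypal_decomposition")
}

#' @export
print.archetypal_decomposition <- function(x, ...) {
  cat("archetypal_decomposition: k = ", x$k, ", ", ncol(x$H),
      " cells; final ||Y - YCH||_F = ",
      signif(utils::tail(x$objective_trace, 1), 5), "\n", sep = "")
  invisible(x)
}

#' Assign each cell to its dominant archetype
#'
#' @param H column-stochastic k x n archetype-contribution matrix.
#' @return integer vector of archetype labels (1..k); ties break to the
#'   lowest archetype index.
#' @export
assign_dominant_archetype <- function(H) {
  apply(unclass(H), 2, which.max)
}

#' Full archetypal decomposition of an expression matrix
#'
#' Convenience pipeline: kernel, automatic selection of the number of
#' archetypes, PCHA refinement from the SPA candidates, and dominant-
#' archetype labels.
#'
#' @param X raw genes x cells expression matrix, or a precomputed
#'   [action_kernel()] object.
#' @param k_min,k_max archetype-number search range.
#' @param delta PCHA corner relaxation (default 0).
#' @param z_threshold oversampling edge threshold.
#' @param k fixed number of archetypes; skips automatic selection.
#' @return object of class `action_decomposition`: the
#'   `archetypal_decomposition` fields plus `k_star`, `labels`,
#'   `cell_ids`, `gene_ids`, `selection` diagnostics and the kernel.
#' @export
action_decompose <- function(X, k_min = 2, k_max = NULL, delta = 0,
                             z_threshold = 1.96, k = NULL) {
  kern <- if (inherits(X, "action_kernel")) X else action_kernel(X)
  n <- length(kern$cell_ids)
  if (is.null(k_max)) k_max <- min(30, n - 1)
  if (is.null(k)) {
    selres <- select_num_archetypes(kern$Y, K = kern$K, k_min = k_min,
                                    k_max = k_max,
                                    z_threshold = z_threshold)
    k_star <- selres$k_star
  } else {
    selres <- NULL
    k_star <- as.integer(k)
  }
  S <- if (!is.null(selres) && !is.null(selres$candidates[[as.character(k_star)]]))
    selres$candidates[[as.character(k_star)]]
  else {
    pc <- precondition_profiles(kern$Y, r = min(k_star, min(dim(kern$Y))))
    spa_select(pc$Yp, k_star)
  }
  fit <- pcha_fit(kern$Y, init = S, k = length(S), delta = delta)
  labels <- assign_dominant_archetype(fit$H)
  structure(
    list(C = fit$C, H = fit$H, A = fit$A, k = fit$k,
         objective_trace = fit$objective_trace, k_star = k_star,
         labels = labels, cell_ids = kern$cell_ids,
         gene_ids = kern$gene_ids, selection = selres, kernel = kern),
    class = "action_decomposition")
}

#' @export
print.action_decomposition <- function(x, ...) {
  cat("action_decomposition: k = ", x$k, " archetypes over ",
      length(x$cell_ids), " cells\n", sep = "")
  invisible(x)
}
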