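#' Residual expression of one archetype
#'
#' The positive part of the archetype matrix is taken, and archetype i is
#' projected onto the orthogonal complement of the span of all other
#' archetypes' positive parts. The projection uses the Moore-Penrose
#' pseudoinverse, so rank-deficient cases (e.g. duplicated archetypes)
#' are handled: a column lying in the span of the others yields a zero
#' residual.
#'
#' @param A genes x k archetype matrix (k >= 2).
#' @param i archetype index to orthogonalize.
#' @return numeric residual-expression vector (length = nrow(A)), named
#'   by gene ids when `A` has rownames.
#' @export
orthogonalize_archetype <- function(A, i) {
  A <- unclass(A)
  k <- ncol(A)
  if (k < 2) stop("need at least 2 archetypes")
  if (i < 1 || i > k) stop("archetype index out of range")
  Ap <- pmax(A, 0)
  a <- Ap[, i]
  B <- Ap[, -i, drop = FALSE]
  coef <- MASS::ginv(B) %*% a
  res <- as.numeric(a - B %*% coef)
  names(res) <- rownames(A)
  res
}

#' Residual expression for all archetypes
#'
#' @param A genes x k archetype matrix.
#' @return genes x k matrix of residual expressions.
#' @export
residual_expression <- function(A) {
  out <- vapply(seq_len(ncol(A)), function(i) orthogonalize_archetype(A, i),
                numeric(nrow(A)))
  rownames(out) <- rownames(A)
  colnames(out) <- colnames(A)
  out
}

#' Rank genes by residual expression
#'
#' Descending order of residual expression; ties break by lexicographic
#' gene id (C-locale radix sort) so rankings are reproducible.
#'
#' @param residual numeric vector of residual expressions.
#' @param gene_ids gene identifiers (defaults to `names(residual)`).
#' @return character vector of gene ids, best-ranked first.
#' @export
rank_genes <- function(residual, gene_ids = names(residual)) {
  if (is.null(gene_ids)) stop("gene ids required")
  if (any(!is.finite(residual))) stop("residual values must be finite")
  gene_ids[order(-residual, gene_ids, method = "radix")]
}

#' Minimum hypergeometric (mHG) score of a ranked binary vector
#'
#' For every cut 1 <= l <= m the hypergeometric upper tail
#' P(X >= k_l) is computed, where k_l is the number of ones among the
#' top l entries, and X follows Hypergeometric(m, r, l) with r the total
#' number of ones. The mHG score is the minimum tail over all cuts;
#' `l_best` is the smallest cut attaining it. An empty target set (r = 0)
#' returns score 1 with l_best 0.
#'
#' @param lambda binary (0/1) vector in ranked order.
#' @return list with `score`, `l_best`, `r`, `m`.
#' @export
mhg_score <- function(lambda) {
  lambda <- as.integer(lambda)
  if (any(lambda != 0L & lambda != 1L)) stop("lambda must be binary")
  m <- length(lambda)
  r <- sum(lambda)
  if (r == 0L) return(list(score = 1, l_best = 0L, r = 0L, m = m))
  ks <- cumsum(lambda)
  tails <- stats::phyper(ks - 1, r, m - r, seq_len(m), lower.tail = FALSE)
  l_best <- which.min(tails)             # first (= smallest) argmin
  list(score = tails[l_best], l_best = as.integer(l_best), r = r, m = m)
}

#' Exact p-value of an mHG score by dynamic programming
#'
#' Computes the probability that a uniformly random arrangement of r ones
#' among m positions attains an mHG score <= `score`, by counting lattice
#' paths that avoid every prefix (l, k) whose hypergeometric tail is
#' already <= `score` (such prefixes certify success, so paths through
#' them are removed and the surviving mass is complemented). Path counts
#' are rescaled when they grow large, so the result is numerically stable
#' for long rankings.
#'
#' @param score observed mHG score (0 < score <= 1).
#' @param m ranking length.
#' @param r number of ones.
#' @return exact p-value in `[score, min(1, m*score)]`.
#' @export
mhg_pvalue_dp <- function(score, m, r) {
  if (r < 0 || r > m) stop("need 0 <= r <= m")
  if (r == 0) return(1)
  # W[j+1] = number of unblocked paths with j ones after i positions
  W <- numeric(r + 1)
  W[1] <- 1
  log_scale <- 0
  for (i in seq_len(m)) {
    jmax <- min(i, r)
    jmin <- max(0L, i - (m - r))
    Wn <- numeric(r + 1)
    js <- jmin:jmax
    Wn[js + 1] <- W[js + 1]
    take <- js[js >= 1]
    if (length(take) > 0)
      Wn[take + 1] <- Wn[take + 1] + W[take]
    # block prefixes whose tail is <= score (same phyper evaluation as
    # mhg_score, so the comparison is float-exact)
    tails <- stats::phyper(js - 1, r, m - r, i, lower.tail = FALSE)
    Wn[js[tails <= score] + 1] <- 0
    W <- Wn
    mx <- max(W)
    if (mx > 1e250) {
      W <- W / mx
      log_scale <- log_scale + log(mx)
    }
  }
  if (W[r + 1] <= 0) return(1)
  surv <- exp(log(W[r + 1]) + log_scale - lchoose(m, r))
  max(0, min(1, 1 - surv))
}

#' Read a TF->target regulon table
#'
#' Tab-separated, TRRUST-style: TF, target, mode, reference. A header row
#' is auto-detected (first field equal to "tf"/"source"/"regulator",
#' case-insensitive). Duplicate TF-target rows are collapsed; regulation
#' modes are retained as attributes but never used in scoring.
#'
#' @param path path to the tab-separated file.
#' @return object of class `regulon_set`: named list mapping TF id to a
#'   character vector of unique target ids, with a `modes` attribute
#'   (data.frame tf/target/mode) and `provenance` attribute (the path).
#' @export
read_regulons <- function(path) {
  if (!file.exists(path)) stop("regulon file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("regulon file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2)
  if (length(bad) > 0)
    stop("regulon file line ", bad[1], " has fewer than 2 fields")
  first <- tolower(fields[[1]][1])
  if (first %in% c("tf", "source", "regulator")) {
    fields <- fields[-1]
    if (length(fields) == 0) stop("regulon file has a header but no data rows")
  }
  tf <- vapply(fields, `[`, character(1), 1)
  tg <- vapply(fields, `[`, character(1), 2)
  mode <- vapply(fields, function(f) if (length(f) >= 3) f[3] else NA_character_,
                 character(1))
  if (any(!nzchar(tf)) || any(!nzchar(tg)))
    stop("regulon file contains empty TF or target ids")
  df <- unique(data.frame(tf = tf, target = tg, mode = mode,
                          stringsAsFactors = FALSE)[, c("tf", "target", "mode")])
  reg <- split(df$target, df$tf)
  reg <- lapply(reg, unique)
  structure(reg, class = "regulon_set",
            modes = unique(df), provenance = path)
}

#' Build a regulon set from a TF -> targets list
#'
#' @param x named list mapping TF ids to character vectors of target ids.
#' @param provenance free-text provenance string.
#' @return a `regulon_set`.
#' @export
regulon_set <- function(x, provenance = "in-memory") {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("regulon list must be named by TF id")
  reg <- lapply(x, function(tg) unique(as.character(tg)))
  structure(reg, class = "regulon_set", provenance = provenance)
}

#' @export
print.regulon_set <- function(x, ...) {
  cat("regulon_set: ", length(x), " TFs, ",
      length(unique(unlist(x))), " distinct targets\n", sep = "")
  invisible(x)
}

#' Archetype-specific transcriptional regulatory network
#'
#' For each archetype, genes are ranked by residual expression, the
#' ranking is restricted to the gene universe (intersection of ranked
#' genes with genes known to the regulon table), and every TF is scored
#' by mHG enrichment of its targets near the top of the list, with an
#' exact DP p-value. TFs passing `alpha` contribute edges to their
#' targets ranked above the optimal cut.
#'
#' @param decomp an `action_decomposition`, or a genes x k archetype
#'   matrix with gene rownames.
#' @param regulons a `regulon_set` (or named TF -> targets list).
#' @param alpha significance level on the mHG p-value (default 0.05; the
#'   strict functional-activity level is 1e-3).
#' @param adjust `"none"` (raw threshold, default) or `"BH"` for
#'   Benjamini-Hochberg adjustment per archetype before thresholding.
#' @return object of class `action_trn`: list with `tf_table` (one row
#'   per archetype x TF: r, m, mhg score, l_best, p-value, adjusted
#'   p-value, significance), `edges` (archetype, tf, target, p_value),
#'   `rankings` (restricted ranked universe per archetype), `alpha`,
#'   `adjust`.
#' @export
build_trn <- function(decomp, regulons, alpha = 0.05,
                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  A <- if (inherits(decomp, "action_decomposition")) {
    M <- decomp$A; rownames(M) <- decomp$gene_ids; M
  } else as.matrix(decomp)
  if (is.null(rownames(A))) stop("archetype matrix must have gene rownames")
  if (!inherits(regulons, "regulon_set")) regulons <- regulon_set(regulons)
  known <- unique(unlist(regulons))
  universe <- intersect(rownames(A), known)
  if (length(universe) == 0)
    stop("no overlap between ranked genes and regulon target genes")
  Aperp <- residual_expression(A)
  k <- ncol(A)
  tf_rows <- list(); edge_rows <- list(); rankings <- list()
  for (arch in seq_len(k)) {
    ranked <- rank_genes(Aperp[, arch], rownames(A))
    ranked_u <- ranked[ranked %in% universe]
    rankings[[arch]] <- ranked_u
    m <- length(ranked_u)
    for (tf in names(regulons)) {
      targets <- intersect(regulons[[tf]], universe)
      if (length(targets) == 0) {
        message("TF ", tf, " has no targets in the gene universe; skipped")
        next
      }
      lambda <- as.integer(ranked_u %in% targets)
      sc <- mhg_score(lambda)
      p <- mhg_pvalue_dp(sc$score, sc$m, sc$r)
      tf_rows[[length(tf_rows) + 1]] <- data.frame(
        archetype = arch, tf = tf, r = sc$r, m = sc$m,
        mhg_score = sc$score, l_best = sc$l_best, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  tf_table <- do.call(rbind, tf_rows)
  if (is.null(tf_table))
    tf_table <- data.frame(archetype = integer(0), tf = character(0),
                           r = integer(0), m = integer(0),
                           mhg_score = numeric(0), l_best = integer(0),
                           p_value = numeric(0))
  tf_table$p_adjusted <- tf_table$p_value
  if (adjust == "BH" && nrow(tf_table) > 0) {
    for (arch in unique(tf_table$archetype)) {
      idx <- tf_table$archetype == arch
      tf_table$p_adjusted[idx] <- stats::p.adjust(tf_table$p_value[idx],
                                                  method = "BH")
    }
  }
  tf_table$significant <- tf_table$p_adjusted <= alpha
  if (nrow(tf_table) > 0) {
    for (ri in which(tf_table$significant)) {
      arch <- tf_table$archetype[ri]
      tf <- tf_table$tf[ri]
      top <- utils::head(rankings[[arch]], tf_table$l_best[ri])
      hits <- intersect(top, regulons[[tf]])
      if (length(hits) > 0)
        edge_rows[[length(edge_rows) + 1]] <- data.frame(
          archetype = arch, tf = tf, target = hits,
          p_value = tf_table$p_value[ri], stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edge_rows) > 0) do.call(rbind, edge_rows)
           else data.frame(archetype = integer(0), tf = character(0),
                           target = character(0), p_value = numeric(0))
  structure(list(tf_table = tf_table, edges = edges, rankings = rankings,
                 residuals = Aperp, alpha = alpha, adjust = adjust),
            class = "action_trn")
}

#' @export
print.action_trn <- function(x, ...) {
  cat("action_trn: ", sum(x$tf_table$significant), " significant TF calls, ",
      nrow(x$edges), " edges across ", length(x$rankings),
      " archetypes (alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' Write a TRN as SIF
#'
#' One line per edge: `TF  regulates  TG`.
#' @param trn an `action_trn`.
#' @param path output file.
#' @export
write_trn_sif <- function(trn, path) {
  lines <- sprintf("%s\tregulates\t%s", trn$edges$tf, trn$edges$target)
  writeLines(lines, path)
  invisible(path)
}

#' Write a TRN as GraphML with node type and edge p-value attributes
#'
#' @param trn an `action_trn`.
#' @param path output file.
#' @export
write_trn_graphml <- function(trn, path) {
  ed <- trn$edges
  tfs <- unique(ed$tf); tgs <- setdiff(unique(ed$target), tfs)
  nodes <- data.frame(name = c(tfs, tgs),
                      type = c(rep("TF", length(tfs)),
                               rep("TG", length(tgs))),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    ed[, c("tf", "target", "p_value")], directed = TRUE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Per-archetype marker table
#'
#' @param trn an `action_trn`.
#' @param archetype archetype index.
#' @param n number of top genes (default all with positive residual).
#' @return data.frame with gene, residual and rank.
#' @export
marker_table <- function(trn, archetype, n = NULL) {
  res <- trn$residuals[, archetype]
  ord <- rank_genes(res, rownames(trn$residuals))
  if (is.null(n)) n <- sum(res > 0)
  top <- utils::head(ord, n)
  data.frame(gene = top, residual = res[top], rank = seq_along(top),
             row.names = NULL, stringsAsFactors = FALSE)
}
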