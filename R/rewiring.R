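#' Fisher transformation of a correlation coefficient
#'
#' Computes `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`. Coefficients at or
#' beyond +/-1 (which occur for perfectly correlated pairs in toy data) are
#' clamped to +/-(1 - 1e-7) with a warning.
#'
#' @param r Numeric vector of correlation coefficients.
#' @return Numeric vector of transformed values.
#' @export
fisher_z <- function(r) {
  eps <- 1e-7
  out_of_range <- abs(r) >= 1
  if (any(out_of_range, na.rm = TRUE)) {
    warning(sum(out_of_range, na.rm = TRUE),
            " correlation(s) with |r| >= 1 clamped to +/-(1 - 1e-7)")
    r <- pmin(pmax(r, -(1 - eps)), 1 - eps)
  }
  atanh(r)
}

#' Rewiring statistic for a gene pair
#'
#' The difference of Fisher-transformed correlations divided by its standard
#' error, `(z_case - z_ctrl) / sqrt(1/(n_case - 3) + 1/(n_ctrl - 3))`. Under
#' no change in correlation the statistic is approximately standard normal.
#'
#' @param z_case,z_ctrl Fisher-transformed correlations per group.
#' @param n_case,n_ctrl Sample counts per group; each must be >= 4 so the
#'   variance terms are positive and finite.
#' @return Numeric vector of rewiring statistics.
#' @export
rewire_statistic <- function(z_case, z_ctrl, n_case, n_ctrl) {
  if (any(n_case < 4L)) stop("case group has fewer than 4 samples")
  if (any(n_ctrl < 4L)) stop("control group has fewer than 4 samples")
  (z_case - z_ctrl) / sqrt(1 / (n_case - 3) + 1 / (n_ctrl - 3))
}

#' Standardize a set of rewiring scores
#'
#' Centers and scales the full edge-score set: `Z_i = (x_i - mu) / sigma`.
#' By default sigma is the population (n-denominator) standard deviation.
#' A degenerate set (sigma = 0, e.g. identical case/control matrices) yields
#' all-zero scores with a warning.
#'
#' @param x Numeric vector of rewiring scores (length >= 2).
#' @param sd_mode `"population"` (default) or `"sample"`.
#' @return Numeric vector of standardized scores.
#' @export
standardize_scores <- function(x, sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  if (length(x) < 2L) stop("need at least 2 scores to standardize")
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (sd_mode == "population") sigma <- sigma * sqrt((length(x) - 1) / length(x))
  if (!is.finite(sigma) || sigma == 0) {
    warning("score set has zero standard deviation; all standardized scores set to 0")
    return(rep(0, length(x)))
  }
  (x - mu) / sigma
}

#' Two-tailed significance and edge scores for standardized rewiring scores
#'
#' Converts each standardized score to a two-tailed normal p-value,
#' `p = 2 * (1 - pnorm(|Z|))`, applies Benjamini-Hochberg adjustment over all
#' edges, retains edges with adjusted p <= `alpha`, and assigns retained
#' edges the score `delta = 1 - adj_p` (monotone in significance, in (0, 1]).
#'
#' @param Z Numeric vector of standardized scores.
#' @param alpha FDR threshold for retaining edges (default 0.05).
#' @return A list with `p`, `adj_p`, `keep` (logical), and `delta`
#'   (`NA` for non-retained edges).
#' @export
edge_significance <- function(Z, alpha = 0.05) {
  if (!length(Z)) stop("empty score vector")
  p <- 2 * stats::pnorm(-abs(Z))
  adj_p <- stats::p.adjust(p, method = "BH")
  keep <- adj_p <= alpha
  delta <- ifelse(keep, 1 - adj_p, NA_real_)
  list(p = p, adj_p = adj_p, keep = keep, delta = delta)
}

#' Remove genes with zero expression variance
#'
#' Genes whose expression shows no variability (standard deviation exactly 0)
#' produce undefined correlations and are removed before network
#' construction. Removed genes are reported via a message.
#'
#' @param x Numeric genes x samples matrix.
#' @return The matrix restricted to variable genes (possibly zero rows).
#' @export
filter_zero_variance <- function(x) {
  if (is.null(rownames(x))) stop("expression matrix must have gene row names")
  v <- apply(x, 1L, stats::var)
  drop <- v == 0 | !is.finite(v)
  if (any(drop)) {
    message(sum(drop), " zero-variance gene(s) removed: ",
            paste(utils::head(rownames(x)[drop], 5L), collapse = ", "),
            if (sum(drop) > 5L) ", ..." else "")
  }
  x[!drop, , drop = FALSE]
}

#' Per-gene differential expression between case and control
#'
#' logFC is the difference of group means (log-scale input assumed,
#' case minus control); the two-sided p-value comes from a Welch two-sample
#' t-test, BH-adjusted over all genes.
#'
#' @param case,control Numeric genes x samples matrices over the same genes.
#' @return A data.frame with columns `gene`, `logFC`, `p`, `adj_p`.
#' @export
differential_expression <- function(case, control) {
  if (ncol(case) < 2L || ncol(control) < 2L) {
    stop("each group needs at least 2 samples for differential expression")
  }
  genes <- rownames(case)
  if (!identical(genes, rownames(control))) {
    stop("case and control must share the same gene universe (same order)")
  }
  n1 <- ncol(case); n2 <- ncol(control)
  m1 <- rowMeans(case); m2 <- rowMeans(control)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((control - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  # constant-in-both-groups genes give 0/0; no evidence of change
  p[!is.finite(tstat)] <- 1
  data.frame(gene = genes, logFC = m1 - m2, p = p,
             adj_p = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the rewired co-expression network
#'
#' Orchestrates the rewiring pipeline: zero-variance filtering in each group,
#' Pearson correlations per group over the common gene universe, an optional
#' minimum-correlation floor, Fisher transformation, the rewiring statistic,
#' standardization over the tested edge set, two-tailed p-values with BH
#' adjustment, and edge scores `delta = 1 - adj_p` for retained edges.
#' Deterministic for fixed inputs.
#'
#' Gene pairs are stored once, with `gene_i < gene_j` under lexicographic
#' gene-ID ordering; self-pairs are never scored.
#'
#' @param case,control Numeric genes x samples matrices (log-scale). Row
#'   names are gene IDs; the universe is the intersection of variable genes.
#' @param alpha Edge FDR threshold (default 0.05).
#' @param r_min Minimum-correlation floor: pairs with
#'   `max(|r_case|, |r_ctrl|) < r_min` are dropped before testing
#'   (default 0.2; 0 disables).
#' @param sd_mode Standardization mode, see [standardize_scores()].
#' @return An object of class `rewired_network`: a list with `edges` (a
#'   data.frame of retained edges with per-edge statistics), `nodes`,
#'   `universe`, `de` (the differential-expression table over the universe),
#'   `n_case`, `n_ctrl`, `n_tested`, and `params`.
#' @export
build_rewired_network <- function(case, control, alpha = 0.05, r_min = 0.2,
                                  sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  if (ncol(case) < 4L || ncol(control) < 4L) {
    stop("each group needs at least 4 samples for the rewiring test")
  }
  case <- filter_zero_variance(case)
  control <- filter_zero_variance(control)
  universe <- sort(intersect(rownames(case), rownames(control)))
  if (length(universe) < 2L) stop("empty universe: fewer than 2 variable genes shared by both groups")
  case <- case[universe, , drop = FALSE]
  control <- control[universe, , drop = FALSE]

  de <- differential_expression(case, control)

  r_case <- stats::cor(t(case))
  r_ctrl <- stats::cor(t(control))
  ut <- which(upper.tri(r_case))
  p_genes <- length(universe)
  i_idx <- row(r_case)[ut]
  j_idx <- col(r_case)[ut]
  rc <- r_case[ut]
  rk <- r_ctrl[ut]

  if (r_min > 0) {
    pass <- pmax(abs(rc), abs(rk)) >= r_min
    i_idx <- i_idx[pass]; j_idx <- j_idx[pass]
    rc <- rc[pass]; rk <- rk[pass]
  }
  n_tested <- length(rc)
  params <- list(alpha = alpha, r_min = r_min, sd_mode = sd_mode,
                 n_case = ncol(case), n_ctrl = ncol(control))
  empty_edges <- data.frame(gene_i = character(), gene_j = character(),
                            r_case = numeric(), r_ctrl = numeric(),
                            z_case = numeric(), z_ctrl = numeric(),
                            rewire = numeric(), Z = numeric(), p = numeric(),
                            adj_p = numeric(), delta = numeric(),
                            stringsAsFactors = FALSE)
  if (n_tested == 0L) {
    return(new_rewired_network(empty_edges, universe, de, n_tested, params))
  }

  zc <- fisher_z(rc)
  zk <- fisher_z(rk)
  stat <- rewire_statistic(zc, zk, ncol(case), ncol(control))
  Z <- if (n_tested >= 2L) standardize_scores(stat, sd_mode) else stat
  sig <- edge_significance(Z, alpha)

  keep <- sig$keep
  edges <- data.frame(gene_i = universe[i_idx[keep]],
                      gene_j = universe[j_idx[keep]],
                      r_case = rc[keep], r_ctrl = rk[keep],
                      z_case = zc[keep], z_ctrl = zk[keep],
                      rewire = stat[keep], Z = Z[keep],
                      p = sig$p[keep], adj_p = sig$adj_p[keep],
                      delta = sig$delta[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$adj_p, edges$gene_i, edges$gene_j), , drop = FALSE]
  rownames(edges) <- NULL
  new_rewired_network(edges, universe, de, n_tested, params)
}

new_rewired_network <- function(edges, universe, de, n_tested, params) {
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$gene_i, edges$gene_j))),
                 universe = universe,
                 de = de,
                 n_case = params$n_case,
                 n_ctrl = params$n_ctrl,
                 n_tested = n_tested,
                 params = params),
            class = "rewired_network")
}

#' @export
print.rewired_network <- function(x, ...) {
  cat("Rewired co-expression network\n",
      "  universe: ", length(x$universe), " genes\n",
      "  tested pairs: ", x$n_tested, "\n",
      "  retained edges (adj p <= ", x$params$alpha, "): ",
      nrow(x$edges), " over ", length(x$nodes), " genes\n", sep = "")
  invisible(x)
}
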