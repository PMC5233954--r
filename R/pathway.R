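#' Map a pathway gene set onto the rewired network
#'
#' Computes the pathway subnetwork quantities used by the alteration scores:
#' `T` (pathway genes present in the universe), `M = T*(T-1)/2` (possible
#' intra-pathway connections), `m` (retained rewired edges with both
#' endpoints in the pathway) with their scores `delta`, and the regulatory
#' rewired edges whose target is a pathway gene, partitioned into local
#' (TF inside the pathway) and global (TF outside).
#'
#' @param net A `rewired_network`.
#' @param reg A `regulatory_rewired` set from [annotate_regulatory()] (or
#'   `NULL` for none).
#' @param gene_set Character vector of pathway gene IDs.
#' @return A list of class `pathway_subnetwork` with fields `T`, `M`, `m`,
#'   `delta` (scores of intra-pathway rewired edges), `t` (distinct DE
#'   targets with >= 1 regulatory rewired edge), `targets` (per-TG table
#'   with `n_edges` and `logFC`), `tfs_local`, `tfs_global`, and
#'   `scoreable` (`FALSE` when `T < 2`).
#' @export
map_pathway <- function(net, reg, gene_set) {
  stopifnot(inherits(net, "rewired_network"))
  gene_set <- unique(gene_set)
  mapped <- intersect(gene_set, net$universe)
  T_n <- length(mapped)
  M <- T_n * (T_n - 1) / 2
  edges <- net$edges
  intra <- edges$gene_i %in% mapped & edges$gene_j %in% mapped
  delta <- edges$delta[intra]

  reg_edges <- if (!is.null(reg) && nrow(reg$edges)) {
    reg$edges[reg$edges$tg %in% mapped, , drop = FALSE]
  } else {
    NULL
  }
  if (!is.null(reg_edges) && nrow(reg_edges)) {
    local <- reg_edges$tf %in% mapped
    agg <- split(reg_edges, reg_edges$tg)
    targets <- data.frame(tg = names(agg),
                          n_edges = vapply(agg, nrow, integer(1L)),
                          logFC = vapply(agg, function(d) d$tg_logFC[1L], numeric(1L)),
                          row.names = NULL, stringsAsFactors = FALSE)
    tfs_local <- sort(unique(reg_edges$tf[local]))
    tfs_global <- sort(unique(reg_edges$tf[!local]))
  } else {
    targets <- data.frame(tg = character(), n_edges = integer(),
                          logFC = numeric(), stringsAsFactors = FALSE)
    tfs_local <- character()
    tfs_global <- character()
  }
  structure(list(T = T_n, M = M, m = sum(intra), delta = delta,
                 genes = mapped, edge_idx = which(intra),
                 t = nrow(targets), targets = targets,
                 tfs_local = tfs_local, tfs_global = tfs_global,
                 scoreable = T_n >= 2L),
            class = "pathway_subnetwork")
}

#' One-sided Fisher's exact test for rewired-gene over-representation
#'
#' Tests whether the pathway gene set is enriched in rewired genes (genes
#' incident to at least one retained rewired edge) against the variance-
#' filtered universe, using the 2x2 table
#' \[pathway&rewired, pathway&not; non-pathway&rewired, non-pathway&not\].
#'
#' @param pathway_genes Pathway genes, restricted to the universe.
#' @param rewired_genes Genes incident to a retained rewired edge (a subset
#'   of the universe).
#' @param universe All genes surviving variance filtering.
#' @return One-sided (over-representation) p-value.
#' @export
enrichment_test <- function(pathway_genes, rewired_genes, universe) {
  if (!length(universe)) stop("empty universe")
  pathway_genes <- intersect(pathway_genes, universe)
  rewired_genes <- intersect(rewired_genes, universe)
  a <- length(intersect(pathway_genes, rewired_genes))
  b <- length(pathway_genes) - a
  c_ <- length(rewired_genes) - a
  d <- length(universe) - a - b - c_
  stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE),
                     alternative = "greater")$p.value
}

#' Rewiring density of a pathway subnetwork
#'
#' `R = sum(delta_i) / M` over the `m` intra-pathway rewired edges; 0 when
#' `m = 0`. Bounded in \[0, 1\].
#'
#' @param sub A `pathway_subnetwork` from [map_pathway()].
#' @return The rewiring density, or `NA` when the pathway is unscoreable
#'   (`M = 0`).
#' @export
rewiring_density <- function(sub) {
  if (sub$M == 0) return(NA_real_)
  if (sub$m == 0L) return(0)
  sum(sub$delta) / sub$M
}

#' Differential regulation score of a pathway
#'
#' The mean absolute expression fold change over the `t` distinct
#' differentially expressed target genes that carry at least one regulatory
#' rewired edge; 0 when `t = 0`. With `weighted = TRUE` the per-target
#' regulatory edge counts `n_j` weight the average:
#' `Dr_w = sum(n_j * |f_j|) / sum(n_j)`.
#'
#' @param sub A `pathway_subnetwork`.
#' @param weighted Use the edge-count weighted variant (default `FALSE`).
#' @return The differential regulation score Dr (>= 0).
#' @export
differential_regulation_score <- function(sub, weighted = FALSE) {
  if (sub$t == 0L) return(0)
  f <- abs(sub$targets$logFC)
  if (weighted) {
    n <- sub$targets$n_edges
    sum(n * f) / sum(n)
  } else {
    mean(f)
  }
}

#' Normalized alteration scores across pathways
#'
#' For every pathway in the scored set `d` (pathways with at least one
#' rewired edge: `m >= 1` intra-pathway rewired edge or `t >= 1` regulatory
#' rewired target), the raw alteration score is `R + Dr`; the normalized
#' alteration score Dy is its z-score over `d` (population standard
#' deviation). Pathways outside `d` receive `NA`. When `|d| = 1` or the raw
#' scores are constant, all members receive `Dy = 0`.
#'
#' @param raw Numeric vector of raw alteration scores (`R + Dr`) per pathway.
#' @param in_d Logical vector: pathway membership in the scored set `d`.
#' @return Numeric vector of Dy scores (`NA` outside `d`).
#' @export
alteration_scores <- function(raw, in_d) {
  stopifnot(length(raw) == length(in_d))
  dy <- rep(NA_real_, length(raw))
  d <- which(in_d)
  if (!length(d)) return(dy)
  dy[d] <- zscore_pop(raw[d])
  dy
}

#' Score a pathway collection against a rewired network
#'
#' Runs [map_pathway()], [enrichment_test()] (BH-adjusted across all tested
#' pathways), [rewiring_density()], [differential_regulation_score()], and
#' [alteration_scores()] over a pathway collection, and classifies pathways:
#' `altered` when enrichment adjusted p <= `enrich_alpha` and `m >= 1`;
#' `diff_regulated` when additionally `Dr > dr_threshold`. Altered pathways
#' are ranked by Dy, descending.
#'
#' @param net A `rewired_network`.
#' @param reg A `regulatory_rewired` set (or `NULL`).
#' @param pathways Named list of gene sets (as from [read_gmt()]).
#' @param enrich_alpha Enrichment FDR threshold (default 0.05).
#' @param dr_threshold Differential-regulation threshold on Dr (default 0.05).
#' @param weighted_dr Use the weighted Dr variant (default `FALSE`).
#' @return A data.frame with one row per pathway: `pathway`, `T`, `M`, `m`,
#'   `t`, `enrich_p`, `enrich_adj_p`, `R`, `Dr`, `raw`, `in_d`, `Dy`,
#'   `altered`, `diff_regulated`, `rank`, `tfs`, `tgs`.
#' @export
score_pathways <- function(net, reg, pathways, enrich_alpha = 0.05,
                           dr_threshold = 0.05, weighted_dr = FALSE) {
  stopifnot(inherits(net, "rewired_network"))
  if (!length(pathways)) stop("empty pathway collection")
  subs <- lapply(pathways, function(gs) map_pathway(net, reg, gs))
  rewired_genes <- net$nodes
  enrich_p <- vapply(subs, function(s) {
    if (!s$scoreable) return(NA_real_)
    enrichment_test(s$genes, rewired_genes, net$universe)
  }, numeric(1L))
  enrich_adj_p <- stats::p.adjust(enrich_p, method = "BH")
  R <- vapply(subs, rewiring_density, numeric(1L))
  Dr <- vapply(subs, differential_regulation_score, numeric(1L),
               weighted = weighted_dr)
  m <- vapply(subs, `[[`, numeric(1L), "m")
  t_n <- vapply(subs, `[[`, numeric(1L), "t")
  raw <- ifelse(is.na(R), 0, R) + Dr
  in_d <- (m >= 1L | t_n >= 1L)
  Dy <- alteration_scores(raw, in_d)
  altered <- !is.na(enrich_adj_p) & enrich_adj_p <= enrich_alpha & m >= 1L
  diff_reg <- altered & Dr > dr_threshold
  res <- data.frame(
    pathway = names(pathways),
    T = vapply(subs, `[[`, numeric(1L), "T"),
    M = vapply(subs, `[[`, numeric(1L), "M"),
    m = m, t = t_n,
    enrich_p = enrich_p, enrich_adj_p = enrich_adj_p,
    R = R, Dr = Dr, raw = raw, in_d = in_d, Dy = Dy,
    altered = altered, diff_regulated = diff_reg,
    tfs = vapply(subs, function(s)
      paste(sort(unique(c(s$tfs_local, s$tfs_global))), collapse = ","),
      character(1L)),
    tgs = vapply(subs, function(s)
      paste(sort(s$targets$tg), collapse = ","), character(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  res$rank <- NA_integer_
  alt <- which(res$altered)
  if (length(alt)) {
    res$rank[alt[order(-res$Dy[alt])]] <- seq_along(alt)
  }
  attr(res, "subnetworks") <- subs
  res
}

#' Permutation significance of pathway alteration scores
#'
#' Permutes the case/control sample labels `B` times (preserving group
#' sizes), recomputes the full pipeline raw alteration score (`R + Dr`) per
#' pathway on each shuffle, and reports the add-one empirical p-value
#' `perm_p = (1 + #\{raw_perm >= raw_obs\}) / (B + 1)`, BH-adjusted across
#' pathways. The raw (pre-normalization) score is used so the null of one
#' pathway does not depend on co-shuffled pathways.
#'
#' @param case,control Expression matrices as in [build_rewired_network()].
#' @param pathways Named list of gene sets.
#' @param grn Regulatory network data.frame (`tf`, `tg`).
#' @param B Number of permutations (>= 1; default 1000).
#' @param seed Optional RNG seed for reproducible shuffles.
#' @param alpha,r_min,sd_mode,de_alpha,de_mode,weighted_dr Pipeline
#'   parameters, as in [build_rewired_network()] and [annotate_regulatory()].
#' @return A data.frame with `pathway`, `raw_obs`, `perm_p`, `perm_adj_p`.
#' @export
permutation_significance <- function(case, control, pathways, grn,
                                     B = 1000L, seed = NULL,
                                     alpha = 0.05, r_min = 0.2,
                                     sd_mode = "population",
                                     de_alpha = 0.05, de_mode = "any",
                                     weighted_dr = FALSE) {
  if (B < 1L) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  raw_scores <- function(case_m, control_m) {
    net <- build_rewired_network(case_m, control_m, alpha = alpha,
                                 r_min = r_min, sd_mode = sd_mode)
    reg <- annotate_regulatory(net, grn, de_alpha = de_alpha, de_mode = de_mode)
    vapply(pathways, function(gs) {
      s <- map_pathway(net, reg, gs)
      R <- rewiring_density(s)
      (if (is.na(R)) 0 else R) +
        differential_regulation_score(s, weighted = weighted_dr)
    }, numeric(1L))
  }
  obs <- raw_scores(case, control)
  pooled <- cbind(case, control)
  n1 <- ncol(case)
  n <- ncol(pooled)
  exceed <- rep(0L, length(pathways))
  for (b in seq_len(B)) {
    idx <- sample.int(n)
    perm <- suppressMessages(suppressWarnings(
      raw_scores(pooled[, idx[seq_len(n1)], drop = FALSE],
                 pooled[, idx[-seq_len(n1)], drop = FALSE])
    ))
    exceed <- exceed + (perm >= obs)
  }
  perm_p <- (1 + exceed) / (B + 1)
  data.frame(pathway = names(pathways), raw_obs = obs, perm_p = perm_p,
             perm_adj_p = stats::p.adjust(perm_p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}
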