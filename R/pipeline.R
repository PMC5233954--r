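#' Run the full altered-pathway analysis pipeline
#'
#' Orchestrates the analysis: variance filtering and rewired-network
#' construction, regulatory overlay, pathway scoring and classification,
#' optional permutation significance, optional random-walk-with-restart
#' disease-gene enrichment, and per-gene prioritization. The analytic
#' pipeline is deterministic; the seed governs only the permutation step.
#'
#' @param case,control Numeric genes x samples expression matrices
#'   (log-scale), as from [read_expression()].
#' @param pathways Named list of pathway gene sets, as from [read_gmt()].
#' @param grn Regulatory network data.frame (`tf`, `tg`), as from
#'   [read_regulatory_network()].
#' @param seeds Optional character vector of disease seed genes.
#' @param alpha Edge FDR threshold (default 0.05).
#' @param r_min Minimum-correlation floor (default 0.2).
#' @param sd_mode Score standardization mode (default `"population"`).
#' @param de_alpha Target differential-expression FDR threshold
#'   (default 0.05).
#' @param de_mode `"any"` or `"up"` (default `"any"`).
#' @param enrich_alpha Pathway enrichment FDR threshold (default 0.05).
#' @param dr_threshold Differential-regulation threshold on Dr
#'   (default 0.05).
#' @param weighted_dr Use the edge-count weighted Dr variant
#'   (default `FALSE`).
#' @param restart RWR restart probability (default 0.75).
#' @param rwr_divisor `"m"` or `"M"`, see [disease_enrichment_score()].
#' @param permutations Number of label permutations (0 = off).
#' @param seed RNG seed recorded in the run parameters and used for the
#'   permutation step.
#' @return An object of class `pathrewire_result`: a list with `network`,
#'   `regulatory`, `pathways_table`, `edges_table`, `genes_table`,
#'   `affinity`, `permutation`, and `params`.
#' @export
run_pipeline <- function(case, control, pathways, grn, seeds = NULL,
                         alpha = 0.05, r_min = 0.2,
                         sd_mode = "population", de_alpha = 0.05,
                         de_mode = "any", enrich_alpha = 0.05,
                         dr_threshold = 0.05, weighted_dr = FALSE,
                         restart = 0.75, rwr_divisor = "m",
                         permutations = 0L, seed = NULL) {
  for (a in c(alpha, de_alpha, enrich_alpha)) {
    if (a <= 0 || a >= 1) stop("significance thresholds must be in (0, 1)")
  }
  net <- build_rewired_network(case, control, alpha = alpha, r_min = r_min,
                               sd_mode = sd_mode)
  reg <- annotate_regulatory(net, grn, de_alpha = de_alpha, de_mode = de_mode)
  ptab <- score_pathways(net, reg, pathways, enrich_alpha = enrich_alpha,
                         dr_threshold = dr_threshold,
                         weighted_dr = weighted_dr)
  subs <- attr(ptab, "subnetworks")

  perm <- NULL
  if (permutations > 0L) {
    perm <- permutation_significance(case, control, pathways, grn,
                                     B = permutations, seed = seed,
                                     alpha = alpha, r_min = r_min,
                                     sd_mode = sd_mode, de_alpha = de_alpha,
                                     de_mode = de_mode,
                                     weighted_dr = weighted_dr)
    ptab$perm_p <- perm$perm_p[match(ptab$pathway, perm$pathway)]
    ptab$perm_adj_p <- perm$perm_adj_p[match(ptab$pathway, perm$pathway)]
  }

  aff <- NULL
  if (!is.null(seeds) && nrow(net$edges)) {
    aff <- rwr(column_normalize(network_adjacency(net)), seeds,
               r_restart = restart)
    ptab$disease_score <- vapply(subs, disease_enrichment_score,
                                 numeric(1L), net = net, aff = aff,
                                 divisor = rwr_divisor)
  }

  edges_table <- net$edges
  if (nrow(edges_table)) {
    key <- paste(edges_table$gene_i, edges_table$gene_j, sep = "\r")
    reg_key <- unique(paste(reg$edges$gene_i, reg$edges$gene_j, sep = "\r"))
    edges_table$regulatory <- key %in% reg_key
    idx <- match(key, paste(reg$edges$gene_i, reg$edges$gene_j, sep = "\r"))
    edges_table$tf <- reg$edges$tf[idx]
    edges_table$tg <- reg$edges$tg[idx]
  } else {
    edges_table$regulatory <- logical()
    edges_table$tf <- character()
    edges_table$tg <- character()
  }

  genes_table <- prioritize_genes(net, aff = aff)

  params <- list(alpha = alpha, r_min = r_min, sd_mode = sd_mode,
                 de_alpha = de_alpha, de_mode = de_mode,
                 enrich_alpha = enrich_alpha, dr_threshold = dr_threshold,
                 weighted_dr = weighted_dr, restart = restart,
                 rwr_divisor = rwr_divisor, permutations = permutations,
                 seed = seed, n_case = ncol(case), n_ctrl = ncol(control),
                 n_universe = length(net$universe),
                 n_tested_pairs = net$n_tested,
                 n_rewired_edges = nrow(net$edges))
  structure(list(network = net, regulatory = reg, pathways_table = ptab,
                 edges_table = edges_table, genes_table = genes_table,
                 affinity = aff, permutation = perm, params = params),
            class = "pathrewire_result")
}

#' @export
print.pathrewire_result <- function(x, ...) {
  cat("pathrewire pipeline result\n",
      "  universe: ", x$params$n_universe, " genes; rewired edges: ",
      x$params$n_rewired_edges, "\n",
      "  pathways scored: ", nrow(x$pathways_table),
      "; altered: ", sum(x$pathways_table$altered),
      "; differentially regulated: ", sum(x$pathways_table$diff_regulated),
      "\n", sep = "")
  invisible(x)
}
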