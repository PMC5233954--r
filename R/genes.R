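#' Node centralities of the rewired network
#'
#' Computes four per-gene centralities on the rewired network: closeness and
#' PageRank (damping 0.85) on the delta-weighted graph, degree as the
#' unweighted incident-edge count, and transitivity as the unweighted local
#' clustering coefficient (0 for nodes of degree < 2). For weighted
#' closeness, edge distance is `1 / delta`, so stronger rewiring means a
#' shorter distance.
#'
#' @param net A `rewired_network` with at least one edge.
#' @param weighted Use delta weights for closeness and PageRank
#'   (default `TRUE`).
#' @return A data.frame with columns `gene`, `degree`, `closeness`,
#'   `transitivity`, `pagerank`.
#' @export
gene_centralities <- function(net, weighted = TRUE) {
  g <- network_igraph(net)
  if (igraph::vcount(g) == 0L) stop("empty rewired network")
  w <- if (weighted) igraph::E(g)$delta else NULL
  cl <- suppressWarnings(
    igraph::closeness(g, weights = if (weighted) 1 / w else NA, mode = "all")
  )
  cl[!is.finite(cl)] <- 0
  tr <- igraph::transitivity(g, type = "local", isolates = "zero")
  tr[!is.finite(tr)] <- 0
  pr <- igraph::page_rank(g, damping = 0.85, weights = w)$vector
  data.frame(gene = igraph::V(g)$name,
             degree = as.numeric(igraph::degree(g)),
             closeness = as.numeric(cl),
             transitivity = as.numeric(tr),
             pagerank = as.numeric(pr),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Composite centrality score
#'
#' Standardizes each of the four centralities across network nodes
#' (population standard deviation; a constant centrality contributes 0) and
#' averages them: `cs = mean(z(closeness), z(transitivity), z(degree),
#' z(pagerank))`. The mean of `cs` over nodes is 0.
#'
#' @param centralities Data.frame from [gene_centralities()].
#' @return The input data.frame with an added `cs` column.
#' @export
composite_centrality <- function(centralities) {
  cols <- c("degree", "closeness", "transitivity", "pagerank")
  stopifnot(all(cols %in% names(centralities)))
  if (nrow(centralities) < 2L) stop("need at least 2 nodes")
  z <- vapply(cols, function(cc) zscore_pop(centralities[[cc]]),
              numeric(nrow(centralities)))
  centralities$cs <- rowMeans(z)
  centralities
}

#' Local rewiring score per gene
#'
#' The sum of edge scores delta over edges incident to each network gene,
#' z-standardized across the network genes. Genes absent from the rewired
#' network carry no score.
#'
#' @param net A `rewired_network` with at least one edge.
#' @return A data.frame with columns `gene`, `incident_delta`,
#'   `local_rewiring`.
#' @export
local_rewiring_score <- function(net) {
  stopifnot(inherits(net, "rewired_network"))
  if (!nrow(net$edges)) stop("empty rewired network")
  raw <- tapply(c(net$edges$delta, net$edges$delta),
                c(net$edges$gene_i, net$edges$gene_j), sum)
  genes <- net$nodes
  raw <- raw[genes]
  data.frame(gene = genes, incident_delta = as.numeric(raw),
             local_rewiring = zscore_pop(as.numeric(raw)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene prioritization table
#'
#' Assembles the per-gene report over the expression universe: differential
#' expression, the four centralities, the composite centrality `cs`, the
#' local rewiring score, and (optionally) the seed affinity. Genes outside
#' the rewired network carry `NA` for network-derived columns.
#'
#' @param net A `rewired_network`.
#' @param aff Optional `affinity_vector` from [rwr()].
#' @param weighted Passed to [gene_centralities()].
#' @return A data.frame with one row per universe gene.
#' @export
prioritize_genes <- function(net, aff = NULL, weighted = TRUE) {
  stopifnot(inherits(net, "rewired_network"))
  out <- net$de
  names(out)[names(out) == "p"] <- "de_p"
  names(out)[names(out) == "adj_p"] <- "de_adj_p"
  if (nrow(net$edges)) {
    cent <- composite_centrality(gene_centralities(net, weighted = weighted))
    lrs <- local_rewiring_score(net)
    out <- merge(out, cent, by = "gene", all.x = TRUE, sort = FALSE)
    out <- merge(out, lrs[, c("gene", "local_rewiring")], by = "gene",
                 all.x = TRUE, sort = FALSE)
  } else {
    out[c("degree", "closeness", "transitivity", "pagerank", "cs",
          "local_rewiring")] <- NA_real_
  }
  out$affinity <- if (!is.null(aff)) {
    unname(aff$affinity[out$gene])
  } else {
    NA_real_
  }
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# igraph view of a rewired network (delta kept as an edge attribute)
network_igraph <- function(net) {
  stopifnot(inherits(net, "rewired_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("gene_i", "gene_j", "delta")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

# population-sd z-score; (numerically) constant input maps to all zeros so
# that floating-point jitter on symmetric graphs is not inflated to +/-1
zscore_pop <- function(x) {
  n <- length(x)
  sigma <- stats::sd(x) * sqrt((n - 1) / n)
  if (!is.finite(sigma) || sigma <= 1e-9 * max(abs(x), 1e-300)) {
    return(rep(0, n))
  }
  (x - mean(x)) / sigma
}
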