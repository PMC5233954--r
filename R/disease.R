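#' Column-normalize a weighted adjacency matrix
#'
#' Divides each nonzero column by its sum, making the matrix column-
#' stochastic over non-isolated nodes (isolated nodes cannot occur in a
#' rewired network, whose nodes all carry at least one edge; zero columns
#' are left zero).
#'
#' @param adjacency Symmetric non-negative weighted adjacency matrix.
#' @return The column-normalized matrix W.
#' @export
column_normalize <- function(adjacency) {
  if (any(adjacency < 0)) stop("adjacency weights must be non-negative")
  cs <- colSums(adjacency)
  nz <- cs > 0
  adjacency[, nz] <- sweep(adjacency[, nz, drop = FALSE], 2L, cs[nz], "/")
  adjacency
}

#' Weighted adjacency matrix of a rewired network
#'
#' Symmetric matrix over the network nodes with entries equal to the edge
#' scores delta.
#'
#' @param net A `rewired_network`.
#' @return A numeric matrix with node names as dimnames.
#' @export
network_adjacency <- function(net) {
  stopifnot(inherits(net, "rewired_network"))
  nodes <- net$nodes
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(net$edges)) {
    i <- match(net$edges$gene_i, nodes)
    j <- match(net$edges$gene_j, nodes)
    A[cbind(i, j)] <- net$edges$delta
    A[cbind(j, i)] <- net$edges$delta
  }
  A
}

#' Random walk with restart over a rewired network
#'
#' Iterates `p <- (1 - r_restart) * W %*% p + r_restart * p0` with `p0`
#' uniform over the mapped seed nodes, until the L1 change falls below
#' `tol`. The fixed point equals the direct linear-system solution
#' `p = r_restart * solve(I - (1 - r_restart) * W) %*% p0`.
#'
#' @param W Column-normalized adjacency matrix (see [column_normalize()])
#'   with node names as dimnames.
#' @param seeds Character vector of seed gene IDs; at least one must map to
#'   the network, otherwise an error lists the unmapped seeds.
#' @param r_restart Restart probability in (0, 1) (default 0.75, the
#'   customary propagation default).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 1000).
#' @return A list of class `affinity_vector` with `affinity` (named numeric
#'   vector summing to 1), `iterations`, `residual`, `r_restart`, and
#'   `seeds_used`.
#' @export
rwr <- function(W, seeds, r_restart = 0.75, tol = 1e-10, max_iter = 1000L) {
  if (r_restart <= 0 || r_restart >= 1) stop("r_restart must be in (0, 1)")
  nodes <- rownames(W)
  if (is.null(nodes)) stop("W must carry node names as dimnames")
  mapped <- intersect(seeds, nodes)
  if (!length(mapped)) {
    stop("no seed maps to the rewired network; unmapped seeds: ",
         paste(seeds, collapse = ", "))
  }
  p0 <- stats::setNames(rep(0, length(nodes)), nodes)
  p0[mapped] <- 1 / length(mapped)
  # mass sitting on a zero column (possible only in hand-built graphs) is
  # redirected to the restart distribution so the walk stays stochastic
  dangling <- colSums(W) == 0
  p <- p0
  resid <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    lost <- sum(p[dangling])
    p_new <- as.vector((1 - r_restart) * (W %*% p + lost * p0)) +
      r_restart * p0
    resid <- sum(abs(p_new - p))
    p <- p_new
    if (resid < tol) break
  }
  structure(list(affinity = stats::setNames(p, nodes), iterations = iter,
                 residual = resid, r_restart = r_restart,
                 seeds_used = mapped),
            class = "affinity_vector")
}

#' Disease-gene enrichment score of a pathway subnetwork
#'
#' Sums the seed-affinity of the two endpoints of every intra-pathway
#' rewired connection and averages over the connections:
#' `score = (1/m) * sum(p_i + p_j)`; 0 when `m = 0`. The divisor `m`
#' (rewired edge count, default) does not penalize pathways for untested
#' pairs; the alternative divisor `M` (all possible intra-pathway pairs) is
#' available.
#'
#' @param sub A `pathway_subnetwork` from [map_pathway()].
#' @param net The `rewired_network` the subnetwork was mapped on.
#' @param aff An `affinity_vector` from [rwr()].
#' @param divisor `"m"` (default) or `"M"`.
#' @return The disease enrichment score.
#' @export
disease_enrichment_score <- function(sub, net, aff, divisor = c("m", "M")) {
  divisor <- match.arg(divisor)
  if (sub$m == 0L) return(0)
  e <- net$edges[sub$edge_idx, , drop = FALSE]
  p <- aff$affinity
  total <- sum(p[e$gene_i] + p[e$gene_j])
  total / switch(divisor, m = sub$m, M = sub$M)
}
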