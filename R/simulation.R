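#' Generate a weighted Barabasi-Albert network
#'
#' Preferential-attachment graph (igraph `sample_pa`, linear preference,
#' undirected) with each edge assigned an interaction strength drawn
#' Uniform(`w_min`, `w_max`), standing for a true correlation strength.
#'
#' @param n Number of nodes (default 2000).
#' @param m_attach Edges attached per incoming node (default 3).
#' @param w_min,w_max Baseline weight range (default 0.2 to 1, so that
#'   replacement by Uniform(0, 1) produces detectable shifts).
#' @param seed Optional RNG seed.
#' @return An igraph graph with vertex names `g0001...` and edge attribute
#'   `weight`.
#' @export
generate_ba_network <- function(n = 2000L, m_attach = 3L, w_min = 0.2,
                                w_max = 1, seed = NULL) {
  if (m_attach < 1L || n <= m_attach) stop("need n > m_attach >= 1")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_pa(n, power = 1, m = m_attach, directed = FALSE)
  igraph::V(g)$name <- sprintf("g%05d", seq_len(n))
  igraph::E(g)$weight <- stats::runif(igraph::ecount(g), w_min, w_max)
  g
}

#' Assign pathway gene sets and truth labels over a simulated network
#'
#' Creates `n_dr` differentially regulated (DR) pathway gene sets of
#' `dr_size` genes, mutually disjoint, plus `n_null` null gene sets with
#' sizes drawn uniformly from `null_size_range`, sampled from a pool of
#' nodes disjoint from the DR genes. A reserve of `n_nonpathway` nodes is
#' kept outside every gene set to supply the regulatory partners.
#'
#' @param graph An igraph graph from [generate_ba_network()].
#' @param n_dr,dr_size,n_null Pathway counts and sizes (defaults 10, 100, 90).
#' @param null_size_range Null gene-set size range (default c(50, 100)).
#' @param n_nonpathway Nodes reserved outside all gene sets (default 300).
#' @param seed Optional RNG seed.
#' @return A list with `pathways` (named list of gene sets; DR sets first),
#'   `labels` (named logical: `TRUE` for DR), and `nonpathway` (reserved
#'   node names).
#' @export
build_pathway_truth <- function(graph, n_dr = 10L, dr_size = 100L,
                                n_null = 90L, null_size_range = c(50L, 100L),
                                n_nonpathway = 300L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- igraph::V(graph)$name
  need <- n_dr * dr_size + n_nonpathway + max(null_size_range)
  if (length(nodes) < need) {
    stop("insufficient nodes: need at least ", need, ", have ", length(nodes))
  }
  shuffled <- sample(nodes)
  dr_genes <- shuffled[seq_len(n_dr * dr_size)]
  dr_sets <- split(dr_genes, rep(seq_len(n_dr), each = dr_size))
  nonpathway <- shuffled[n_dr * dr_size + seq_len(n_nonpathway)]
  null_pool <- shuffled[-seq_len(n_dr * dr_size + n_nonpathway)]
  null_sizes <- sample(seq(null_size_range[1L], null_size_range[2L]),
                       n_null, replace = TRUE)
  null_sets <- lapply(null_sizes, function(k) sample(null_pool, k))
  pathways <- c(stats::setNames(dr_sets, sprintf("DR_%02d", seq_len(n_dr))),
                stats::setNames(null_sets, sprintf("NULL_%02d", seq_len(n_null))))
  labels <- stats::setNames(rep(c(TRUE, FALSE), c(n_dr, n_null)),
                            names(pathways))
  list(pathways = pathways, labels = labels, nonpathway = nonpathway)
}

#' Plant rewiring and regulatory structure into case/control network copies
#'
#' Copies the simulated network into control and case versions. For every DR
#' pathway, at least one intra-pathway edge (added first if the pathway has
#' none) has its case-copy weight replaced by Uniform(0, 1). A proportion
#' `gamma` of each DR pathway's genes (`ceiling(gamma * size)`) additionally
#' gets one edge to a reserved non-pathway gene rewired the same way; those
#' partners are registered as TFs of the pathway genes in a simulated
#' regulatory network, and the targets are stamped as significantly
#' differentially expressed. Null-pathway intra edges are never touched.
#'
#' @param graph igraph graph from [generate_ba_network()].
#' @param truth Output of [build_pathway_truth()].
#' @param gamma Proportion of DR-pathway genes given regulatory rewiring,
#'   in (0, 1].
#' @param w_min,w_max Weight range for edges that must be added (same as the
#'   baseline range).
#' @param seed Optional RNG seed.
#' @return A list with `edges` (data.frame `from`, `to`, `w_ctrl`, `w_case`,
#'   `changed`, `added`), `grn` (data.frame `tf`, `tg` of planted regulatory
#'   pairs), and `de` (simulated differential-expression table over all
#'   nodes: planted targets carry |logFC| ~ Uniform(0.5, 2) with adjusted
#'   p stamped 0.001; all other genes carry logFC ~ Normal(0, 0.1) with
#'   p = 1).
#' @export
inject_rewiring <- function(graph, truth, gamma, w_min = 0.2, w_max = 1,
                            seed = NULL) {
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ed <- igraph::as_data_frame(graph, what = "edges")
  edges <- data.frame(from = ed$from, to = ed$to, w_ctrl = ed$weight,
                      stringsAsFactors = FALSE)
  new_edges <- list()
  dr_sets <- truth$pathways[truth$labels]
  pathway_genes <- unique(unlist(truth$pathways, use.names = FALSE))
  nonpathway <- truth$nonpathway

  # index: node -> incident edge rows (over original edges)
  inc <- split(rep(seq_len(nrow(edges)), 2L), c(edges$from, edges$to))
  other_end <- function(idx, g) ifelse(edges$from[idx] == g,
                                       edges$to[idx], edges$from[idx])
  changed_existing <- integer()
  grn <- list()

  for (pw in dr_sets) {
    in_pw_from <- edges$from %in% pw
    in_pw_to <- edges$to %in% pw
    intra <- which(in_pw_from & in_pw_to)
    if (length(intra)) {
      changed_existing <- c(changed_existing, intra[sample.int(length(intra), 1L)])
    } else {
      pair <- sample(pw, 2L)
      new_edges[[length(new_edges) + 1L]] <-
        data.frame(from = pair[1L], to = pair[2L],
                   w_ctrl = stats::runif(1L, w_min, w_max), changed = TRUE,
                   stringsAsFactors = FALSE)
    }
    n_reg <- ceiling(gamma * length(pw))
    reg_genes <- sample(pw, n_reg)
    for (g in reg_genes) {
      cand <- inc[[g]]
      cand <- cand[other_end(cand, g) %in% nonpathway]
      if (length(cand)) {
        pick <- cand[sample.int(length(cand), 1L)]
        changed_existing <- c(changed_existing, pick)
        partner <- other_end(pick, g)
      } else {
        partner <- sample(nonpathway, 1L)
        new_edges[[length(new_edges) + 1L]] <-
          data.frame(from = partner, to = g,
                     w_ctrl = stats::runif(1L, w_min, w_max), changed = TRUE,
                     stringsAsFactors = FALSE)
      }
      grn[[length(grn) + 1L]] <- c(partner, g)
    }
  }

  edges$changed <- FALSE
  edges$changed[changed_existing] <- TRUE
  edges$added <- FALSE
  if (length(new_edges)) {
    add <- do.call(rbind, new_edges)
    add$added <- TRUE
    edges <- rbind(edges, add[, c("from", "to", "w_ctrl", "changed", "added")])
    message(sum(add$added), " edge(s) added to guarantee planted rewiring")
  }
  edges$w_case <- edges$w_ctrl
  edges$w_case[edges$changed] <- stats::runif(sum(edges$changed), 0, 1)

  grn <- as.data.frame(do.call(rbind, grn), stringsAsFactors = FALSE)
  names(grn) <- c("tf", "tg")
  grn <- grn[!duplicated(grn), , drop = FALSE]

  nodes <- igraph::V(graph)$name
  de <- data.frame(gene = nodes,
                   logFC = stats::rnorm(length(nodes), 0, 0.1),
                   p = 1, adj_p = 1, stringsAsFactors = FALSE)
  tg_idx <- match(unique(grn$tg), de$gene)
  de$logFC[tg_idx] <- stats::runif(length(tg_idx), 0.5, 2)
  de$p[tg_idx] <- 5e-4
  de$adj_p[tg_idx] <- 1e-3
  rownames(edges) <- NULL
  list(edges = edges, grn = grn, de = de)
}

#' Detect rewiring on a pair of simulated weight networks
#'
#' Runs the package's rewiring detection on a case/control pair of weighted
#' networks by treating the edge weights as true correlations and, by
#' default, sampling the observed per-group correlation of each interaction
#' from the Fisher sampling model,
#' `atanh(r_obs) ~ Normal(atanh(r_true), 1/(n - 3))`, with a nominal sample
#' size of `n_sim` per group. The identical statistic, standardization,
#' two-tailed p, and BH steps of [build_rewired_network()] are then applied
#' to the interaction list.
#'
#' @param sim_edges Edge table from [inject_rewiring()] (columns `from`,
#'   `to`, `w_ctrl`, `w_case`).
#' @param de Differential-expression table to attach to the network (e.g.
#'   the simulated one from [inject_rewiring()]).
#' @param n_sim Nominal per-group sample size (default 50).
#' @param noise Sample observed correlations from the Fisher model
#'   (default `TRUE`); `FALSE` uses the weights as observed correlations.
#' @param alpha Edge FDR threshold (default 0.05).
#' @param r_min Minimum-correlation floor on observed correlations
#'   (default 0.2).
#' @param sd_mode Standardization mode (default `"population"`).
#' @param universe Node name vector (defaults to all endpoint names).
#' @return A `rewired_network` over the simulated nodes.
#' @export
detect_rewiring <- function(sim_edges, de, n_sim = 50L, noise = TRUE,
                            alpha = 0.05, r_min = 0.2,
                            sd_mode = "population", universe = NULL) {
  if (n_sim < 4L) stop("n_sim must be >= 4")
  if (is.null(universe)) {
    universe <- sort(unique(c(sim_edges$from, sim_edges$to)))
  }
  z_case <- fisher_z(sim_edges$w_case)
  z_ctrl <- fisher_z(sim_edges$w_ctrl)
  if (noise) {
    se <- sqrt(1 / (n_sim - 3))
    z_case <- z_case + stats::rnorm(length(z_case), 0, se)
    z_ctrl <- z_ctrl + stats::rnorm(length(z_ctrl), 0, se)
  }
  rc <- tanh(z_case)
  rk <- tanh(z_ctrl)
  gi <- pmin(sim_edges$from, sim_edges$to)
  gj <- pmax(sim_edges$from, sim_edges$to)
  keep0 <- rep(TRUE, length(rc))
  if (r_min > 0) keep0 <- pmax(abs(rc), abs(rk)) >= r_min
  params <- list(alpha = alpha, r_min = r_min, sd_mode = sd_mode,
                 n_case = n_sim, n_ctrl = n_sim, noise = noise)
  stat <- rewire_statistic(z_case[keep0], z_ctrl[keep0], n_sim, n_sim)
  if (length(stat) >= 2L) stat_z <- standardize_scores(stat, sd_mode) else stat_z <- stat
  if (!length(stat)) {
    edges <- data.frame(gene_i = character(), gene_j = character(),
                        r_case = numeric(), r_ctrl = numeric(),
                        z_case = numeric(), z_ctrl = numeric(),
                        rewire = numeric(), Z = numeric(), p = numeric(),
                        adj_p = numeric(), delta = numeric(),
                        stringsAsFactors = FALSE)
    return(new_rewired_network(edges, universe, de, 0L, params))
  }
  sig <- edge_significance(stat_z, alpha)
  keep <- sig$keep
  idx <- which(keep0)[keep]
  edges <- data.frame(gene_i = gi[idx], gene_j = gj[idx],
                      r_case = rc[idx], r_ctrl = rk[idx],
                      z_case = z_case[idx], z_ctrl = z_ctrl[idx],
                      rewire = stat[keep], Z = stat_z[keep],
                      p = sig$p[keep], adj_p = sig$adj_p[keep],
                      delta = sig$delta[keep], stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  new_rewired_network(edges, universe, de, length(stat), params)
}

#' Run one simulation scenario of the pathway benchmark
#'
#' For each replicate: a fresh Barabasi-Albert network is generated, pathway
#' truth is assigned, rewiring and regulatory structure is planted at the
#' given `gamma`, rewiring detection runs on the case/control pair, the
#' planted regulatory pairs are overlaid with [annotate_regulatory()], the
#' pathways are scored with [score_pathways()], and the area under the ROC
#' curve of the Dy score against the DR/null truth labels is recorded
#' (pathways without a score rank jointly at the bottom).
#'
#' @param gamma Proportion of DR-pathway genes given regulatory rewiring.
#' @param replicates Number of replicates (default 20).
#' @param n_nodes,m_attach Network size parameters (defaults 2000, 3).
#' @param n_dr,dr_size,n_null,null_size_range,n_nonpathway Pathway truth
#'   parameters, see [build_pathway_truth()].
#' @param n_sim,noise,alpha,r_min Detection parameters, see
#'   [detect_rewiring()].
#' @param seed Optional RNG seed.
#' @return A list with `auroc` (per-replicate values), `mean_auroc`, and
#'   `scores` (long data.frame: `replicate`, `pathway`, `label`, `raw`,
#'   `in_d`, `Dy`).
#' @export
run_scenario <- function(gamma, replicates = 20L, n_nodes = 2000L,
                         m_attach = 3L, n_dr = 10L, dr_size = 100L,
                         n_null = 90L, null_size_range = c(50L, 100L),
                         n_nonpathway = 300L, n_sim = 50L, noise = TRUE,
                         alpha = 0.05, r_min = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aurocs <- numeric(replicates)
  score_tabs <- vector("list", replicates)
  for (rep_i in seq_len(replicates)) {
    g <- generate_ba_network(n_nodes, m_attach)
    truth <- build_pathway_truth(g, n_dr, dr_size, n_null, null_size_range,
                                 n_nonpathway)
    inj <- suppressMessages(inject_rewiring(g, truth, gamma))
    net <- detect_rewiring(inj$edges, inj$de, n_sim = n_sim, noise = noise,
                           alpha = alpha, r_min = r_min)
    reg <- annotate_regulatory(net, inj$grn)
    res <- score_pathways(net, reg, truth$pathways)
    scores <- ifelse(is.na(res$Dy), -Inf, res$Dy)
    labels <- truth$labels[res$pathway]
    aurocs[rep_i] <- auroc(scores, labels)
    score_tabs[[rep_i]] <- data.frame(replicate = rep_i,
                                      pathway = res$pathway,
                                      label = unname(labels),
                                      raw = res$raw, in_d = res$in_d,
                                      Dy = res$Dy, stringsAsFactors = FALSE)
  }
  list(auroc = aurocs, mean_auroc = mean(aurocs),
       scores = do.call(rbind, score_tabs))
}

#' Run the full simulation benchmark over a set of gamma scenarios
#'
#' @param gammas Regulatory-gene proportions (default the benchmark set
#'   `c(0.01, 0.25, 0.50, 0.75, 1.00)`).
#' @param replicates Replicates per scenario (default 20).
#' @param seed Optional RNG seed governing the whole benchmark.
#' @param ... Passed to [run_scenario()].
#' @return A list with `summary` (data.frame `gamma`, `mean_auroc`,
#'   `sd_auroc`, `replicates`) and `auroc` (list of per-replicate vectors,
#'   one per gamma).
#' @export
simulate_benchmark <- function(gammas = c(0.01, 0.25, 0.50, 0.75, 1.00),
                               replicates = 20L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  runs <- lapply(gammas, function(gm)
    run_scenario(gm, replicates = replicates, seed = NULL, ...))
  summary <- data.frame(
    gamma = gammas,
    mean_auroc = vapply(runs, `[[`, numeric(1L), "mean_auroc"),
    sd_auroc = vapply(runs, function(r) stats::sd(r$auroc), numeric(1L)),
    replicates = replicates
  )
  list(summary = summary,
       auroc = stats::setNames(lapply(runs, `[[`, "auroc"),
                               paste0("gamma_", gammas)))
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation with midrank tie handling: the probability that
#' a randomly chosen positive outranks a randomly chosen negative, counting
#' ties as 1/2.
#'
#' @param scores Numeric score vector (may contain `-Inf` for unscored
#'   items).
#' @param labels Logical (or 0/1) truth labels, `TRUE` for positives.
#' @return auROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must be non-missing")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("labels must include both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Generate a synthetic case/control expression pair with planted structure
#'
#' Genes are organized into equicorrelated multivariate-normal modules with
#' a specified within-module correlation per group (so a module with, e.g.,
#' `r_control = 0.8` and `r_case = 0` is a planted rewired module), plus
#' independent noise genes. Planted TF -> TG pairs shift the target's mean
#' by `logFC` in the case group (means do not affect correlations). Samples
#' are columns; values are on a log-like continuous scale.
#'
#' @param modules List of module specifications, each a list with `genes`
#'   (character vector), `r_case`, and `r_control` (within-module
#'   correlations in \[0, 1)); an out-of-range correlation is rejected as an
#'   infeasible (non-positive-definite) target.
#' @param n_noise Number of independent noise genes appended (default 100).
#' @param regulatory Optional data.frame with columns `tf`, `tg`, `logFC`:
#'   each `tg` has its case-group mean shifted by `logFC`.
#' @param n_case,n_control Samples per group (default 50 each).
#' @param seed Optional RNG seed.
#' @return A list with `case`, `control` (genes x samples matrices), and
#'   `truth` (list: `rewired_pairs` data.frame of planted rewired gene
#'   pairs, `de_genes`, `regulatory`, `modules`).
#' @export
generate_expression_pair <- function(modules, n_noise = 100L,
                                     regulatory = NULL, n_case = 50L,
                                     n_control = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (mod in modules) {
    for (r in c(mod$r_case, mod$r_control)) {
      if (r < 0 || r >= 1) {
        stop("infeasible within-module correlation ", r,
             " (equicorrelated target must be in [0, 1))")
      }
    }
  }
  module_genes <- unlist(lapply(modules, `[[`, "genes"), use.names = FALSE)
  if (anyDuplicated(module_genes)) stop("modules must not share genes")
  noise_genes <- if (n_noise > 0L) sprintf("noise%04d", seq_len(n_noise)) else character()
  genes <- c(module_genes, noise_genes)

  sim_group <- function(n_samples, which_r) {
    x <- matrix(stats::rnorm(length(genes) * n_samples), length(genes),
                n_samples, dimnames = list(genes, NULL))
    for (mod in modules) {
      r <- mod[[which_r]]
      if (r > 0) {
        f <- stats::rnorm(n_samples)
        idx <- match(mod$genes, genes)
        x[idx, ] <- sqrt(r) * matrix(f, length(idx), n_samples, byrow = TRUE) +
          sqrt(1 - r) * x[idx, ]
      }
    }
    x
  }
  control <- sim_group(n_control, "r_control")
  case <- sim_group(n_case, "r_case")
  colnames(control) <- sprintf("ctrl%03d", seq_len(n_control))
  colnames(case) <- sprintf("case%03d", seq_len(n_case))
  if (!is.null(regulatory) && nrow(regulatory)) {
    idx <- match(regulatory$tg, genes)
    if (anyNA(idx)) stop("regulatory targets must be simulated genes")
    case[idx, ] <- case[idx, ] + regulatory$logFC
  }
  rewired_pairs <- do.call(rbind, lapply(modules, function(mod) {
    if (mod$r_case == mod$r_control || length(mod$genes) < 2L) return(NULL)
    pairs <- t(utils::combn(sort(mod$genes), 2L))
    data.frame(gene_i = pairs[, 1L], gene_j = pairs[, 2L],
               stringsAsFactors = FALSE)
  }))
  list(case = case, control = control,
       truth = list(rewired_pairs = rewired_pairs,
                    de_genes = if (!is.null(regulatory)) unique(regulatory$tg) else character(),
                    regulatory = regulatory,
                    modules = modules))
}

#' Build a planted end-to-end study: one rewired + regulated pathway among decoys
#'
#' Convenience wrapper around [generate_expression_pair()] producing a
#' complete pipeline input: a planted pathway whose within-module
#' correlation collapses from `r_control` to `r_case` in cases, regulated by
#' one TF (a module member kept outside the pathway gene set) whose targets
#' gain `logFC` in cases, plus `n_decoys` decoy gene sets drawn from the
#' independent noise genes.
#'
#' @param n_decoys Number of decoy gene sets (default 20).
#' @param pathway_size Planted pathway size (default 15).
#' @param r_control,r_case Within-module correlation per group
#'   (defaults 0.9, 0: a tight co-expression module that fully collapses).
#' @param n_targets Number of TF targets with planted differential
#'   expression (default 5, a small regulon).
#' @param logFC Planted case-group mean shift of the targets (default 1.5).
#' @param n_noise Independent noise genes (default 200).
#' @param n_case,n_control Samples per group (default 50 each).
#' @param seed Optional RNG seed.
#' @return A list with `case`, `control`, `pathways` (named list; the
#'   planted pathway is `"PLANTED"`), `grn`, and `truth`.
#' @export
make_planted_study <- function(n_decoys = 20L, pathway_size = 15L,
                               r_control = 0.9, r_case = 0,
                               n_targets = 5L, logFC = 1.5,
                               n_noise = 200L, n_case = 50L,
                               n_control = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pathway_genes <- sprintf("pw%03d", seq_len(pathway_size))
  tf <- "TF001"
  module <- list(genes = c(pathway_genes, tf),
                 r_case = r_case, r_control = r_control)
  targets <- pathway_genes[seq_len(n_targets)]
  regulatory <- data.frame(tf = tf, tg = targets, logFC = logFC,
                           stringsAsFactors = FALSE)
  sim <- generate_expression_pair(list(module), n_noise = n_noise,
                                  regulatory = regulatory,
                                  n_case = n_case, n_control = n_control)
  noise_genes <- setdiff(rownames(sim$case), module$genes)
  decoys <- lapply(seq_len(n_decoys), function(i) sample(noise_genes, pathway_size))
  pathways <- c(list(PLANTED = pathway_genes),
                stats::setNames(decoys, sprintf("DECOY_%02d", seq_len(n_decoys))))
  list(case = sim$case, control = sim$control, pathways = pathways,
       grn = regulatory[, c("tf", "tg")], truth = sim$truth)
}
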