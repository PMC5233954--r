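test_that("BA network generation respects size, weights, and determinism", {
  g <- generate_ba_network(n = 300, m_attach = 2, seed = 20)
  expect_equal(igraph::vcount(g), 300)
  # preferential attachment with m = 2: core edge + 2 per subsequent node
  expect_equal(igraph::ecount(g), 1 + 2 * 298)
  w <- igraph::E(g)$weight
  expect_true(all(w >= 0.2 & w <= 1))
  g2 <- generate_ba_network(n = 300, m_attach = 2, seed = 20)
  expect_identical(igraph::as_edgelist(g2), igraph::as_edgelist(g))
  expect_identical(igraph::E(g2)$weight, w)
  expect_error(generate_ba_network(n = 3, m_attach = 3), "n > m_attach")
})

test_that("pathway truth has the required sizes, labels, and disjointness", {
  g <- generate_ba_network(n = 2000, seed = 21)
  truth <- build_pathway_truth(g, seed = 21)
  expect_length(truth$pathways, 100)
  expect_equal(sum(truth$labels), 10)
  dr <- truth$pathways[truth$labels]
  nulls <- truth$pathways[!truth$labels]
  expect_true(all(lengths(dr) == 100))
  expect_true(all(lengths(nulls) >= 50 & lengths(nulls) <= 100))
  # DR sets mutually disjoint and disjoint from nulls and the reserve
  dr_genes <- unlist(dr, use.names = FALSE)
  expect_equal(anyDuplicated(dr_genes), 0)
  expect_length(intersect(dr_genes, unlist(nulls)), 0)
  expect_length(intersect(truth$nonpathway, c(dr_genes, unlist(nulls))), 0)
  expect_lte(length(unique(c(dr_genes, unlist(nulls)))), 2000)
  expect_error(build_pathway_truth(generate_ba_network(n = 500, seed = 1)),
               "insufficient nodes")
})

test_that("rewiring injection plants the promised structure and spares null pathways", {
  g <- generate_ba_network(n = 2000, seed = 22)
  truth <- build_pathway_truth(g, seed = 22)
  for (gamma in c(0.01, 1)) {
    inj <- suppressMessages(inject_rewiring(g, truth, gamma, seed = 22))
    dr <- truth$pathways[truth$labels]
    # every DR pathway has at least one changed intra-pathway edge
    for (pw in dr) {
      intra <- inj$edges$from %in% pw & inj$edges$to %in% pw
      expect_gte(sum(inj$edges$changed[intra]), 1)
    }
    # regulatory targets per DR pathway = ceiling(gamma * 100)
    per_pw <- vapply(dr, function(pw) length(unique(inj$grn$tg[inj$grn$tg %in% pw])),
                     integer(1))
    expect_equal(unname(per_pw), rep(ceiling(gamma * 100), 10))
    # TFs come from the non-pathway reserve
    expect_true(all(inj$grn$tf %in% truth$nonpathway))
    # null-pathway intra edges identical across copies
    null_genes <- unlist(truth$pathways[!truth$labels], use.names = FALSE)
    intra_null <- inj$edges$from %in% null_genes & inj$edges$to %in% null_genes
    expect_equal(inj$edges$w_case[intra_null], inj$edges$w_ctrl[intra_null])
    # planted targets are stamped significantly DE, others not
    tg <- unique(inj$grn$tg)
    de <- inj$de
    expect_true(all(de$adj_p[de$gene %in% tg] <= 0.01))
    expect_true(all(de$adj_p[!de$gene %in% tg] == 1))
    expect_true(all(abs(de$logFC[de$gene %in% tg]) >= 0.5))
  }
  expect_error(inject_rewiring(g, truth, 0), "gamma")
})

test_that("noise-free detection flags exactly the strongly changed edges and nothing null", {
  g <- generate_ba_network(n = 600, seed = 23)
  truth <- build_pathway_truth(g, n_dr = 2, dr_size = 50, n_null = 5,
                               null_size_range = c(20, 30),
                               n_nonpathway = 100, seed = 23)
  inj <- suppressMessages(inject_rewiring(g, truth, 1, seed = 23))
  net <- detect_rewiring(inj$edges, inj$de, noise = FALSE, r_min = 0)
  key_changed <- with(inj$edges[inj$edges$changed, ],
                      paste(pmin(from, to), pmax(from, to)))
  key_found <- paste(net$edges$gene_i, net$edges$gene_j)
  expect_true(all(key_found %in% key_changed))
})

test_that("auroc matches the all-pairs oracle and handles ties and edge cases", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(5, 4, 1, 0), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  set.seed(24)
  for (i in 1:10) {
    n <- sample(5:200, 1)
    scores <- sample(c(rnorm(n - 3), rep(-Inf, 3)))
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
    expect_equal(auroc(scores, labels), auroc_pairs_oracle(scores, labels),
                 tolerance = 1e-14)
  }
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("scenario runs are deterministic for a fixed seed and separate DR from null", {
  a <- run_scenario(1, replicates = 2, n_nodes = 800, n_dr = 4, dr_size = 60,
                    n_null = 20, null_size_range = c(30, 50),
                    n_nonpathway = 150, seed = 25)
  b <- run_scenario(1, replicates = 2, n_nodes = 800, n_dr = 4, dr_size = 60,
                    n_null = 20, null_size_range = c(30, 50),
                    n_nonpathway = 150, seed = 25)
  expect_identical(a$scores, b$scores)
  expect_identical(a$auroc, b$auroc)
  # at gamma = 1 every DR pathway is scored and dominates the nulls
  s <- a$scores
  expect_true(all(s$in_d[s$label]))
  expect_gt(min(s$raw[s$label]), max(s$raw[!s$label]))
  expect_gt(a$mean_auroc, 0.9)
})

test_that("expression generator plants correlation structure, DE, and honest nulls", {
  mod <- list(genes = sprintf("m%02d", 1:10), r_case = 0, r_control = 0.8)
  sim <- generate_expression_pair(list(mod), n_noise = 50,
                                  regulatory = data.frame(
                                    tf = "m01", tg = c("m02", "m03"),
                                    logFC = 1.5),
                                  seed = 26)
  expect_equal(dim(sim$case), c(60, 50))
  # control within-module correlations near 0.8, case near 0
  rc <- cor(t(sim$control[mod$genes, ]))
  expect_equal(mean(rc[upper.tri(rc)]), 0.8, tolerance = 0.08)
  rk <- cor(t(sim$case[mod$genes, ]))
  expect_lt(abs(mean(rk[upper.tri(rk)])), 0.1)
  # planted logFC recovered
  de <- differential_expression(sim$case, sim$control)
  expect_equal(de$logFC[de$gene == "m02"], 1.5, tolerance = 0.6)
  expect_error(
    generate_expression_pair(list(list(genes = c("a", "b"), r_case = -0.2,
                                       r_control = 0.5))),
    "infeasible")

  # no planted effects: FDR keeps the rewired network empty or nearly so
  null_sim <- generate_expression_pair(list(), n_noise = 80, seed = 27)
  net <- build_rewired_network(null_sim$case, null_sim$control)
  expect_lt(nrow(net$edges), 5)
})

test_that("planted DE targets are recovered with high power at n = 50", {
  set.seed(28)
  hits <- replicate(20, {
    sim <- generate_expression_pair(
      list(), n_noise = 100,
      regulatory = data.frame(tf = "noise0001", tg = "noise0002", logFC = 1.5))
    de <- differential_expression(sim$case, sim$control)
    de$adj_p[de$gene == "noise0002"] <= 0.05
  })
  expect_gte(mean(hits), 0.9)
})
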