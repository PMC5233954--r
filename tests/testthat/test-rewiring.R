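test_that("fisher_z matches the closed form, is odd and increasing, and clamps", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.9), 0.5 * log(19), tolerance = 1e-12)
  expect_equal(fisher_z(0.9), 1.47222, tolerance = 1e-5)
  expect_equal(fisher_z(-0.5), -0.54931, tolerance = 1e-5)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_equal(z1, atanh(1 - 1e-7))
})

test_that("rewire_statistic matches the closed form and is antisymmetric", {
  expect_identical(rewire_statistic(1, 1, 20, 20), 0)
  expect_equal(rewire_statistic(1, 0, 20, 20), 1 / sqrt(2 / 17), tolerance = 1e-12)
  expect_equal(rewire_statistic(1, 0, 20, 20), 2.91548, tolerance = 1e-5)
  expect_equal(rewire_statistic(1, 0, 4, 4), 0.70711, tolerance = 1e-5)
  set.seed(3)
  zc <- rnorm(10); zk <- rnorm(10)
  expect_equal(rewire_statistic(zc, zk, 12, 30),
               -rewire_statistic(zk, zc, 30, 12))
  expect_error(rewire_statistic(1, 0, 3, 20), "case group")
  expect_error(rewire_statistic(1, 0, 20, 3), "control group")
})

test_that("standardize_scores centers and scales with the population sd", {
  expect_warning(z <- standardize_scores(c(1, 1, 1)), "zero standard deviation")
  expect_identical(z, c(0, 0, 0))
  expect_equal(standardize_scores(c(-1, 0, 1)),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  set.seed(4)
  for (n in c(2, 17, 400)) {
    z <- standardize_scores(rnorm(n, mean = 5, sd = 3))
    expect_lt(abs(mean(z)), 1e-12)
    expect_equal(sd(z) * sqrt((n - 1) / n), 1, tolerance = 1e-12)
  }
  x <- rnorm(20)
  expect_equal(standardize_scores(x, sd_mode = "sample"), (x - mean(x)) / sd(x))
  expect_error(standardize_scores(1), "at least 2")
})

test_that("edge significance: two-tailed p, BH agreement with a sort-based oracle, delta", {
  sig <- edge_significance(c(1.95996, 0))
  expect_equal(sig$p[1], 0.05, tolerance = 1e-5)
  expect_equal(edge_significance(rep(1, 4))$adj_p,
               bh_oracle(edge_significance(rep(1, 4))$p))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(5)
  for (n in c(1, 10, 257, 1000)) {
    p <- runif(n)
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-14)
  }
  # delta defined only on retained edges, always above 1 - alpha there
  sig <- edge_significance(c(6, 5, 0.1, 0.2), alpha = 0.05)
  expect_true(all(sig$delta[sig$keep] > 0.95))
  expect_true(all(is.na(sig$delta[!sig$keep])))
  expect_true(all(sig$adj_p >= sig$p))
  expect_error(edge_significance(numeric()), "empty")
})

test_that("zero-variance genes are removed and the degenerate all-constant case errors downstream", {
  x <- toy_matrix(4, 8)
  x["G2", ] <- 7
  expect_message(kept <- filter_zero_variance(x), "1 zero-variance")
  expect_identical(rownames(kept), c("G1", "G3", "G4"))
  expect_identical(filter_zero_variance(x[c("G1", "G3"), ]), x[c("G1", "G3"), ])
  allconst <- matrix(1, 3, 8, dimnames = list(paste0("G", 1:3), paste0("S", 1:8)))
  expect_error(suppressMessages(build_rewired_network(allconst, allconst + 0)),
               "empty universe")
})

test_that("differential expression matches per-gene Welch t-tests and simple arithmetic", {
  set.seed(6)
  case <- toy_matrix(20, 9, seed = 6)
  control <- toy_matrix(20, 14, seed = 7)
  de <- differential_expression(case, control)
  for (g in c(1, 7, 20)) {
    tt <- t.test(case[g, ], control[g, ])
    expect_equal(de$p[g], tt$p.value, tolerance = 1e-12)
    expect_equal(de$logFC[g], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
  expect_equal(de$adj_p, p.adjust(de$p, "BH"))
  # exact shift recovered; identical group means give logFC 0
  shifted <- control[, 1:9] + 1
  colnames(shifted) <- colnames(case)
  de2 <- differential_expression(shifted, control[, 1:9])
  expect_equal(de2$logFC, rep(1, 20), tolerance = 1e-12)
  expect_error(differential_expression(case[, 1, drop = FALSE], control),
               "at least 2 samples")
})

test_that("differential expression p-values are calibrated under the null", {
  set.seed(8)
  n_genes <- 1000
  x <- matrix(rnorm(n_genes * 60), n_genes, 60,
              dimnames = list(paste0("G", 1:n_genes), paste0("S", 1:60)))
  de <- differential_expression(x[, 1:30], x[, 31:60])
  frac <- mean(de$p <= 0.05)
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / n_genes)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("identical matrices yield no rewired edges; planted rewiring is recovered", {
  x <- toy_matrix(10, 20, seed = 9)
  net0 <- suppressMessages(suppressWarnings(build_rewired_network(x, x)))
  expect_equal(nrow(net0$edges), 0)

  sim <- generate_expression_pair(
    list(list(genes = paste0("mod", 1:8), r_case = 0, r_control = 0.9)),
    n_noise = 150, seed = 10)
  net <- build_rewired_network(sim$case, sim$control)
  expect_gt(nrow(net$edges), 0)
  planted <- paste(sim$truth$rewired_pairs$gene_i,
                   sim$truth$rewired_pairs$gene_j)
  found <- paste(net$edges$gene_i, net$edges$gene_j)
  # planted edges dominate the retained set
  expect_gt(mean(found %in% planted), 0.9)
  expect_gt(sum(found %in% planted), 0.5 * length(planted))
})

test_that("swapping case and control retains the same edges with negated statistics", {
  sim <- generate_expression_pair(
    list(list(genes = paste0("mod", 1:6), r_case = 0.1, r_control = 0.85)),
    n_noise = 150, seed = 11)
  a <- build_rewired_network(sim$case, sim$control)
  b <- build_rewired_network(sim$control, sim$case)
  expect_gt(nrow(a$edges), 0)
  key_a <- paste(a$edges$gene_i, a$edges$gene_j)
  key_b <- paste(b$edges$gene_i, b$edges$gene_j)
  expect_setequal(key_a, key_b)
  m <- match(key_a, key_b)
  expect_equal(a$edges$rewire, -b$edges$rewire[m], tolerance = 1e-12)
  expect_equal(a$edges$adj_p, b$edges$adj_p[m], tolerance = 1e-12)
})

test_that("rewiring raw p-values are calibrated under the null (no correlation floor)", {
  set.seed(12)
  n_genes <- 100
  x <- matrix(rnorm(n_genes * 100), n_genes, 100,
              dimnames = list(sprintf("G%03d", 1:n_genes), paste0("S", 1:100)))
  case <- x[, 1:50]; ctrl <- x[, 51:100]
  zc <- fisher_z(cor(t(case))[upper.tri(diag(n_genes))])
  zk <- fisher_z(cor(t(ctrl))[upper.tri(diag(n_genes))])
  stat <- rewire_statistic(zc, zk, 50, 50)
  p <- edge_significance(standardize_scores(stat))$p
  frac <- mean(p <= 0.05)
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / length(p))
  expect_gt(frac, ci[1] - 0.01)  # allowance for pair dependence through shared genes
  expect_lt(frac, ci[2] + 0.01)
  # with FDR control, retained edges are near zero under the null
  net <- build_rewired_network(case, ctrl, r_min = 0)
  expect_lt(nrow(net$edges), 5)
})
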