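test_that("Newick input is parsed and validated", {
  tree <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tree), 3)
  depths <- ape::node.depth.edgelength(tree)
  expect_equal(max(depths[1:3]), 2)
  # write-read identity up to formatting
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tree, f)
  tree2 <- read_newick(f)
  expect_equal(sort(tree2$tip.label), sort(tree$tip.label))
  expect_equal(ape::vcv(tree2)[tree$tip.label, tree$tip.label],
               ape::vcv(tree)[tree$tip.label, tree$tip.label])
  # contract errors
  expect_error(read_newick("((A,B),C);"), "branch lengths")
  expect_error(read_newick("((A:1,A:1):1,C:2);"), "duplicate")
})

test_that("lambda-scaled covariance has the stated structure", {
  tree <- read_newick("((A:1,B:1):1,C:2);")
  C1 <- bm_covariance(tree, 1)
  expect_equal(C1["A", "B"], 1)
  expect_equal(diag(C1), c(A = 2, B = 2, C = 2))
  C0 <- bm_covariance(tree, 0)
  expect_equal(C0[upper.tri(C0)], c(0, 0, 0))
  expect_equal(diag(C0), diag(C1))
  Ch <- bm_covariance(tree, 0.5)
  expect_equal(Ch["A", "B"], 0.5)
  # star tree: diagonal for any lambda
  star <- ape::stree(5, "star"); star$edge.length <- rep(1, 5)
  Cs <- bm_covariance(star, 0.7)
  expect_true(all(Cs[upper.tri(Cs)] == 0))
  # symmetric PSD across admissible lambda
  for (l in c(0, 0.3, 0.8, 1)) {
    C <- bm_covariance(tree, l)
    expect_equal(C, t(C))
    expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
  }
  expect_error(bm_covariance(tree, 1.2), "lambda")
})

test_that("lambda estimation matches a brute-force grid and conventions", {
  tree <- balanced_tree(4)            # 16 tips
  y <- simulate_bm_traits(trait_sim_config(tree, lambda_true = 0.6, seed = 3))
  yv <- setNames(y$trait_1, y$species)
  est <- estimate_lambda(tree, yv)
  g <- oracle_lambda_grid(tree, yv, 1001)
  expect_gte(est$log_likelihood, g$loglik - 1e-9)
  expect_lt(abs(est$log_likelihood - g$loglik), 1e-4)
  expect_lt(abs(est$lambda_hat - g$lambda), 2e-3)
  # optimality over the boundary values
  expect_gte(est$log_likelihood, oracle_lambda_loglik(0, tree, yv) - 1e-9)
  expect_gte(est$log_likelihood, oracle_lambda_loglik(1, tree, yv) - 1e-9)
  # star phylogeny: flat likelihood, lambda 0 by convention
  star <- ape::stree(6, "star"); star$edge.length <- rep(1, 6)
  ys <- setNames(rnorm(6), star$tip.label)
  expect_equal(estimate_lambda(star, ys)$lambda_hat, 0)
  # affine invariance of lambda-hat; sigma2 scales by the slope squared
  e2 <- estimate_lambda(tree, 5 + 2 * yv)
  expect_equal(e2$lambda_hat, est$lambda_hat, tolerance = 1e-5)
  expect_equal(e2$sigma2_hat, 4 * est$sigma2_hat, tolerance = 1e-4)
  # zero-variance trait is rejected
  expect_error(estimate_lambda(tree, setNames(rep(1, 16), tree$tip.label)),
               "variance")
})

test_that("lambda estimate agrees with an independent reference fit", {
  skip_if_not_installed("phytools")
  tree <- balanced_tree(5)            # 32 tips
  # moderate true signal keeps the optimum interior to [0, 1], where the
  # reference (which searches a wider lambda range) is comparable
  y <- simulate_bm_traits(trait_sim_config(tree, lambda_true = 0.5, seed = 11))
  yv <- setNames(y$trait_1, y$species)
  est <- estimate_lambda(tree, yv)
  ref <- phytools::phylosig(tree, yv, method = "lambda")
  expect_equal(est$lambda_hat, ref$lambda, tolerance = 1e-3)
  expect_equal(est$log_likelihood, ref$logL, tolerance = 1e-4)
})

test_that("PGLS reduces correctly and fits exact relations", {
  tree <- balanced_tree(4)
  sim <- simulate_bm_traits(trait_sim_config(tree, seed = 8), n_traits = 2)
  y <- setNames(sim$trait_1, sim$species)
  x <- setNames(sim$trait_2, sim$species)
  # lambda = 0: equals weighted OLS with 1/diag(C) weights
  f0 <- pgls_fit(tree, y, x, lambda = 0)
  C <- ape::vcv(tree)
  wls <- lm(y[rownames(C)] ~ x[rownames(C)], weights = 1 / diag(C))
  expect_equal(f0$coefficients$estimate, unname(coef(wls)), tolerance = 1e-9)
  # exact linear relation: perfect fit, zero residuals
  fy <- pgls_fit(tree, 2 + 3 * x, x, lambda = "ml")
  expect_equal(unname(fy$residuals), rep(0, length(x)), tolerance = 1e-8)
  expect_equal(fy$coefficients$estimate[2], 3, tolerance = 1e-8)
  # rank deficiency is an error
  X2 <- data.frame(a = x[rownames(C)], b = 2 * x[rownames(C)],
                   row.names = rownames(C))
  expect_error(pgls_fit(tree, y, X2), "rank")
  # recovery sanity: known slope within 3 SE
  set.seed(14)
  xr <- setNames(rnorm(length(y)), names(y))
  noise <- simulate_bm_traits(trait_sim_config(tree, sigma2 = 0.5, seed = 15))
  yr <- 1.5 * xr + setNames(noise$trait_1, noise$species)[names(xr)]
  fr <- pgls_fit(tree, yr, xr, lambda = "ml")
  slope <- fr$coefficients[fr$coefficients$term != "(Intercept)", ]
  expect_lt(abs(slope$estimate - 1.5), 3 * slope$se)
})

test_that("clade summaries aggregate trials and delegate comparisons", {
  set.seed(19)
  metrics <- data.frame(
    clade = rep(c("A", "B", "C"), each = 10),
    wf_distance_sl = c(rnorm(10, 100, 10), rnorm(10, 200, 10),
                       rnorm(10, 150, 10)))
  cs <- clade_summaries(metrics)
  # summaries equal a group-by mean oracle, sorted descending
  expect_equal(cs$summary$clade[1], "B")
  for (i in seq_len(nrow(cs$summary))) {
    cl <- cs$summary$clade[i]
    expect_equal(cs$summary$mean[i],
                 mean(metrics$wf_distance_sl[metrics$clade == cl]))
  }
  expect_lt(cs$kruskal$p_value, 0.05)
  expect_equal(nrow(cs$pairwise), 3)
  # single clade: summary only
  one <- clade_summaries(data.frame(clade = "A", wf_distance_sl = rnorm(5, 10)))
  expect_null(one$kruskal)
  # undersized clades are excluded with a warning
  expect_warning(
    clade_summaries(rbind(metrics,
                          data.frame(clade = "D", wf_distance_sl = 1))),
    "excluded")
})
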