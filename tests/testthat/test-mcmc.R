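test_that("posterior sampling recovers the prior under a flat likelihood", {
  tree <- toy_tree()
  pp <- tip_partials(tree, toy_traits(c(NA, NA, NA)), "x")
  pri <- list(gain = prior_exponential(0.001), loss = prior_uniform(0, 2))
  ch <- mcmc_run(model_single_trait(), tree, pp, pri, iterations = 120000,
                 burnin = 10000, thin = 20, seed = 6)
  expect_gt(ch$acceptance, 0)
  expect_lt(ch$acceptance, 1)
  expect_equal(mean(ch$samples[, "gain"]), 0.001, tolerance = 0.15)
  expect_equal(mean(ch$samples[, "loss"]), 1, tolerance = 0.08)
})

test_that("chains are seed-reproducible and seed-consistent", {
  tree <- toy_tree()
  pp <- tip_partials(tree, toy_traits(), "x")
  pri <- list(gain = prior_uniform(0, 10), loss = prior_uniform(0, 10))
  a <- mcmc_run(model_single_trait(), tree, pp, pri, iterations = 30000,
                burnin = 5000, thin = 10, seed = 3)
  b <- mcmc_run(model_single_trait(), tree, pp, pri, iterations = 30000,
                burnin = 5000, thin = 10, seed = 3)
  expect_identical(a$samples, b$samples)
  c_ <- mcmc_run(model_single_trait(), tree, pp, pri, iterations = 30000,
                 burnin = 5000, thin = 10, seed = 4)
  expect_false(identical(a$samples, c_$samples))
  expect_equal(colMeans(a$samples), colMeans(c_$samples), tolerance = 0.5)
})

test_that("constrained nodes never leave the allowed state set", {
  tree <- parse_newick("((A:0.3,B:0.5)node1:0.2,C:0.8);")
  pp <- tip_partials(tree, toy_traits(c(1, 0, 1)), "x")
  pri <- list(gain = prior_uniform(0, 10), loss = prior_uniform(0, 10))
  ch <- mcmc_run(model_single_trait(), tree, pp, pri,
                 constraints = list(node1 = "1"), iterations = 20000,
                 burnin = 2000, thin = 10, seed = 9)
  expect_equal(ancestral_posterior(ch, "node1"), 1)

  expect_error(mcmc_run(model_single_trait(), tree, pp, pri,
                        constraints = list(node1 = character(0)),
                        iterations = 1000, seed = 1),
               "excludes all states")
})

test_that("a symmetric two-tip tree has root posterior one half", {
  tree <- parse_newick("(A:0.6,B:0.6)root;")
  tree$node.label <- "node1"
  tm <- trait_matrix(data.frame(x = c(1L, 0L), row.names = c("A", "B")))
  pp <- tip_partials(tree, tm, "x")
  pri <- list(rate = prior_uniform(0, 5))
  ch <- mcmc_run(model_single_trait(equal_rates = TRUE), tree, pp, pri,
                 iterations = 120000, burnin = 10000, thin = 10, seed = 2)
  expect_equal(ancestral_posterior(ch, "node1"), 0.5, tolerance = 0.02)
})

test_that("posterior density matches grid integration on a one-param toy", {
  # posterior mean of the single rate under an exponential prior, against
  # quadrature on the same product density
  tree <- toy_tree()
  pp <- tip_partials(tree, toy_traits(), "x")
  m <- model_single_trait(equal_rates = TRUE)
  pri <- list(rate = prior_exponential(0.5))
  lik <- function(r) vapply(r, function(x)
    exp(prune_loglik(tree, pp, build_rate_matrix(m, x))), numeric(1))
  num <- stats::integrate(function(r) r * stats::dexp(r, 2) * lik(r), 0, Inf,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(function(r) stats::dexp(r, 2) * lik(r), 0, Inf,
                          rel.tol = 1e-10)$value
  ch <- mcmc_run(m, tree, pp, pri, iterations = 200000, burnin = 10000,
                 thin = 10, seed = 5)
  expect_equal(mean(ch$samples[, "rate"]), num / den, tolerance = 0.03)
})

test_that("stepping stone matches quadrature on one- and two-param toys", {
  tree <- toy_tree()
  pp <- tip_partials(tree, toy_traits(), "x")
  m1 <- model_single_trait(equal_rates = TRUE)
  pri1 <- list(rate = prior_exponential(0.5))
  ss1 <- stepping_stone_logml(m1, tree, pp, pri1, stones = 50,
                              iters_per_stone = 4000, seed = 3)
  expect_equal(ss1$logml, quadrature_logml(m1, tree, pp, pri1),
               tolerance = 0.1)

  m2 <- model_single_trait()
  pri2 <- list(gain = prior_uniform(0, 5), loss = prior_uniform(0, 5))
  ss2 <- stepping_stone_logml(m2, tree, pp, pri2, stones = 50,
                              iters_per_stone = 4000, seed = 4)
  expect_equal(ss2$logml, quadrature_logml(m2, tree, pp, pri2),
               tolerance = 0.1)

  # flat likelihood: the marginal likelihood is exactly the prior mass, 1
  ppa <- tip_partials(tree, toy_traits(c(NA, NA, NA)), "x")
  ssa <- stepping_stone_logml(m2, tree, ppa, pri2, stones = 20,
                              iters_per_stone = 1000, seed = 5)
  expect_equal(ssa$logml, 0, tolerance = 1e-8)
})

test_that("log Bayes factors double the marginal-likelihood difference", {
  expect_equal(log_bayes_factor(-10, -10)$log_bf, 0)
  expect_equal(log_bayes_factor(-100, -102.35)$log_bf, 4.7)
  b <- log_bayes_factor(-10, -13.25)
  expect_equal(b$log_bf, 6.5)
  expect_equal(b$evidence, "strong")
  expect_equal(log_bayes_factor(-1, -1.5)$evidence, "weak")
  expect_equal(log_bayes_factor(-1, -9)$evidence, "very strong")
})

test_that("priors are assigned by the small/large expected-value rule", {
  fit <- structure(list(model = model_single_trait(),
                        estimate = c(gain = 0.002, loss = 0.4)),
                   class = "ml_fit")
  pri <- assign_priors(fit)
  expect_equal(pri$gain$type, "exponential")
  expect_equal(pri$gain$a, 0.001)
  expect_equal(pri$loss$type, "uniform")
  expect_equal(pri$loss$b, 100)
})

test_that("contradictory ancestral hypotheses are rejected", {
  tr <- enac_tree_synthetic()
  tt <- enac_trait_table()
  expect_error(
    run_ancestry_analysis(tr, tt, "PY",
                          hypotheses = "divergent+convergent:node1",
                          stones = 2, iters_per_stone = 50, restarts = 2),
    "contradictory")
})
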