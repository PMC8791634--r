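test_that("likelihood-ratio test follows the chi-square reference", {
  mk_fit <- function(id, np, ll, nests = character(0)) {
    structure(list(model = structure(list(id = id, params = letters[1:np],
                                          nests = nests),
                                     class = "rate_model"),
                   loglik = ll, n_params = np), class = "ml_fit")
  }
  f0 <- mk_fit("independent_pair", 2, -50)
  f1 <- mk_fit("dependent_pair", 4, -50, nests = "independent_pair")
  r <- likelihood_ratio_test(f0, f1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  f1b <- mk_fit("dependent_pair", 4, -50 + 5.991 / 2,
                nests = "independent_pair")
  rb <- likelihood_ratio_test(f0, f1b)
  expect_equal(rb$df, 2)
  expect_equal(rb$p_value, 0.0500, tolerance = 1e-3)  # chi-square tail

  f2 <- mk_fit("independent_habitat", 3, -50)
  expect_error(likelihood_ratio_test(f2, f1b), "does not nest")
  worse <- mk_fit("dependent_pair", 4, -51, nests = "independent_pair")
  expect_error(likelihood_ratio_test(f0, worse), "worse")
})

test_that("ML fitting is seed-deterministic and respects nesting", {
  tree <- simulate_tree(40, seed = 5, total_length = 30)
  m <- model_independent_pair()
  tm <- simulate_traits(tree, m, c(gain = 0.3, loss = 0.5), c("a", "b"),
                        seed = 5)
  pp <- tip_partials(tree, tm, c("a", "b"))
  f1 <- maximize_likelihood(m, tree, pp, restarts = 8, seed = 11)
  f2 <- maximize_likelihood(m, tree, pp, restarts = 8, seed = 11)
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$loglik, f2$loglik)
  expect_lte(f1$loglik, 0)

  fd <- maximize_likelihood(model_dependent_pair(), tree, pp, restarts = 8,
                            seed = 12)
  expect_gte(fd$loglik, f1$loglik - 1e-6)  # nesting inequality
})

test_that("rates are recovered from data simulated at moderate size", {
  tree <- simulate_tree(150, seed = 3, total_length = 120)
  truth <- c(gain = 0.25, loss = 0.6)
  tm <- simulate_traits(tree, model_independent_pair(), truth, c("a", "b"),
                        seed = 3)
  pp <- tip_partials(tree, tm, c("a", "b"))
  fit <- maximize_likelihood(model_independent_pair(), tree, pp,
                             restarts = 10, seed = 4)
  expect_lt(max(abs(log(fit$estimate / truth))), log(1.6))
})

test_that("a flat likelihood surface is flagged", {
  tree <- simulate_tree(30, seed = 8, total_length = 20)
  tm <- trait_matrix(data.frame(
    a = rep(NA_integer_, 30), b = rep(NA_integer_, 30),
    row.names = tree$tip.label))
  pp <- tip_partials(tree, tm, c("a", "b"))
  fit <- maximize_likelihood(model_dependent_pair(), tree, pp, restarts = 12,
                             seed = 2)
  expect_true(fit$flat_likelihood)
  expect_equal(fit$loglik, 0)
})

test_that("likelihood and ML fit agree with an independent Mk implementation", {
  tr <- simulate_tree(15, seed = 3, total_length = 12)
  m <- model_single_trait()
  tm <- simulate_traits(tr, m, c(gain = 0.4, loss = 0.9), "x", seed = 3)
  x <- setNames(factor(tm$x, levels = 0:1), rownames(tm))
  ref <- phytools::fitMk(tr, x, model = "ARD", pi = "equal")
  fit <- maximize_likelihood(m, tr, tip_partials(tr, tm, "x"),
                             restarts = 10, seed = 1)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(sort(unname(fit$estimate)), sort(unname(ref$rates)),
               tolerance = 1e-3)

  # fixed-Q likelihood on the 4-state coevolution space
  m4 <- model_dependent_pair()
  pars <- setNames(c(0.3, 0.9, 0.5, 0.2), m4$params)
  tm4 <- simulate_traits(tr, m4, pars, c("a", "b"), seed = 5)
  x4 <- setNames(factor(paste0(tm4$a, tm4$b), levels = pair_states()),
                 rownames(tm4))
  Q4 <- build_rate_matrix(m4, pars)
  ref4 <- phytools::fitMk(tr, x4, fixedQ = Q4, pi = "equal")
  expect_equal(prune_loglik(tr, tip_partials(tr, tm4, c("a", "b")), Q4),
               as.numeric(stats::logLik(ref4)), tolerance = 1e-8)
})

test_that("the coevolution suite returns one LRT row per pair", {
  tr <- enac_tree_synthetic()
  tt <- enac_trait_table()
  out <- run_coevolution_suite(tr, tt,
                               list(c("site1", "site2")), family = "pair",
                               restarts = 6, seed = 3)
  expect_equal(nrow(out), 1)
  expect_true(out$p_value >= 0 && out$p_value <= 1)
  expect_equal(out$df, 2)
  expect_gte(out$lnL_dependent, out$lnL_independent - 1e-6)
})
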