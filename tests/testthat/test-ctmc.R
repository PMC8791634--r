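test_that("rate matrices place parameters as the model structure dictates", {
  Q <- build_rate_matrix(model_independent_pair(), c(gain = 0.1, loss = 0.2))
  expect_equal(Q["00", "01"], 0.1)
  expect_equal(Q["00", "10"], 0.1)
  expect_equal(Q["11", "01"], 0.2)
  expect_equal(Q["00", "11"], 0)          # dual transition: structural zero
  expect_equal(Q["11", "00"], 0)
  expect_equal(diag(Q)[["00"]], -0.2)
  expect_equal(unname(rowSums(Q)), rep(0, 4))

  expect_equal(build_rate_matrix(model_dependent_pair(), rep(0, 4)),
               matrix(0, 4, 4, dimnames = list(pair_states(), pair_states())))

  # dependent collapses to independent when the split rates are equal
  Qd <- build_rate_matrix(model_dependent_pair(),
                          c(gain_other_absent = 0.3, gain_other_present = 0.3,
                            loss_other_absent = 0.7, loss_other_present = 0.7))
  Qi <- build_rate_matrix(model_independent_pair(), c(gain = 0.3, loss = 0.7))
  expect_equal(Qd, Qi)

  # habitat models: the reverse habitat transition is a structural zero
  Qh <- build_rate_matrix(model_independent_habitat(),
                          c(gain = 1, loss = 2, habitat_gain = 3))
  expect_equal(Qh["01", "00"], 0)
  expect_equal(Qh["11", "10"], 0)
  expect_equal(Qh["00", "01"], 3)

  expect_error(build_rate_matrix(model_independent_pair(), c(gain = 0.1)),
               "parameter")
  expect_error(build_rate_matrix(model_independent_pair(),
                                 c(gain = -1, loss = 1)), ">= 0")
})

test_that("transition matrices are stochastic and satisfy the semigroup law", {
  set.seed(31)
  m <- model_dependent_habitat()
  for (i in 1:20) {
    Q <- build_rate_matrix(m, setNames(runif(5, 0, 4), m$params))
    expect_equal(transition_matrix(Q, 0), diag(4), ignore_attr = TRUE)
    s <- runif(1, 0, 1.5); t <- runif(1, 0, 1.5)
    Pst <- transition_matrix(Q, s + t)
    expect_equal(unname(rowSums(Pst)), rep(1, 4), tolerance = 1e-10)
    expect_true(all(Pst >= 0 & Pst <= 1))
    # Chapman-Kolmogorov
    expect_equal(Pst, transition_matrix(Q, s) %*% transition_matrix(Q, t),
                 tolerance = 1e-9)
  }
  # analytic two-state solution
  a <- 0.7; b <- 0.25; t <- 1.3
  P <- transition_matrix(build_rate_matrix(model_single_trait(),
                                           c(gain = a, loss = b)), t)
  expect_equal(P[1, 2], a / (a + b) * (1 - exp(-(a + b) * t)),
               tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(7)
  for (rep in 1:25) {
    nt <- sample(3:6, 1)
    tree <- simulate_tree(nt, seed = rep)
    m <- if (rep %% 2) model_dependent_pair() else model_dependent_habitat()
    pars <- setNames(runif(length(m$params), 0.05, 3), m$params)
    Q <- build_rate_matrix(m, pars)
    tm <- simulate_traits(tree, m, pars, c("a", "b"), seed = rep)
    pp <- tip_partials(tree, tm, c("a", "b"))
    pp[, sample(nt, 1)] <- 1  # make one tip fully ambiguous
    expect_equal(prune_loglik(tree, pp, Q),
                 brute_force_loglik(tree, pp, Q), tolerance = 1e-10)
  }
})

test_that("pruning handles degenerate inputs exactly", {
  # all-ambiguous tips: total probability 1 for any Q
  tree <- toy_tree()
  pp <- tip_partials(tree, toy_traits(c(NA, NA, NA)), "x")
  Q <- build_rate_matrix(model_single_trait(), c(gain = 2, loss = 5))
  expect_equal(prune_loglik(tree, pp, Q), 0)

  # single tip on a zero branch under a uniform 4-state prior
  tr1 <- parse_newick("(A:0);")
  pp1 <- matrix(c(0, 1, 0, 0, 1, 1, 1, 1), 4, 2,
                dimnames = list(pair_states(), NULL))
  Q4 <- build_rate_matrix(model_independent_pair(), c(gain = 1, loss = 1))
  expect_equal(prune_loglik(tr1, pp1, Q4), log(0.25))

  # zero-length branches everywhere reduce to the root prior mass
  tr0 <- parse_newick("((A:0,B:0):0,C:0);")
  pp0 <- tip_partials(tr0, toy_traits(c(1, 1, 1)), "x")
  Q2 <- build_rate_matrix(model_single_trait(), c(gain = 1, loss = 2))
  expect_equal(prune_loglik(tr0, pp0, Q2), log(0.5))
})

test_that("likelihood is invariant to child order and joint rate/time scaling", {
  tree <- parse_newick("((A:0.4,B:0.6):0.3,(C:0.2,D:0.9):0.5);")
  swapped <- parse_newick("((D:0.9,C:0.2):0.5,(B:0.6,A:0.4):0.3);")
  tm <- trait_matrix(data.frame(x = c(1, 0, 1, 0),
                                row.names = c("A", "B", "C", "D")))
  Q <- build_rate_matrix(model_single_trait(), c(gain = 0.8, loss = 1.7))
  l1 <- prune_loglik(tree, tip_partials(tree, tm, "x"), Q)
  l2 <- prune_loglik(swapped, tip_partials(swapped, tm, "x"), Q)
  expect_equal(l1, l2, tolerance = 1e-12)

  for (c_ in c(0.1, 3, 40)) {
    scaled <- tree
    scaled$edge.length <- scaled$edge.length / c_
    l3 <- prune_loglik(scaled, tip_partials(scaled, tm, "x"), Q * c_)
    expect_equal(l3, l1, tolerance = 1e-10)
  }
})

test_that("node constraints fossilize states and validate their inputs", {
  tree <- parse_newick("((A:0.3,B:0.5)node1:0.2,C:0.8);")
  tm <- toy_traits(c(1, 1, 0))
  pp <- tip_partials(tree, tm, "x")
  Q <- build_rate_matrix(model_single_trait(), c(gain = 0.5, loss = 0.5))
  lu <- prune_loglik(tree, pp, Q)
  ppc <- apply_node_constraints(pp, tree, list(node1 = "1"))
  lc <- prune_loglik(tree, ppc, Q)
  expect_lt(lc, lu)  # constraining removes probability mass
  ppc0 <- apply_node_constraints(pp, tree, list(node1 = "0"))
  # the two constrained likelihoods partition the unconstrained one
  expect_equal(log(exp(lc) + exp(prune_loglik(tree, ppc0, Q))), lu,
               tolerance = 1e-10)

  expect_error(apply_node_constraints(pp, tree, list(nodeX = "1")),
               "no internal node")
  expect_error(apply_node_constraints(pp, tree, list(node1 = c("0", "1"))),
               "strict subset")
  expect_error(apply_node_constraints(pp, tree, list(node1 = "2")),
               "unknown state")
})
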