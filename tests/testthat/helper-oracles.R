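# Independent oracles used across the suite.

# Brute-force tree likelihood: enumerate every assignment of internal-node
# states and sum transition-probability products (feasible for <= 6 tips).
brute_force_loglik <- function(tree, partials, Q, prior = NULL) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  ns <- nrow(Q)
  if (is.null(prior)) prior <- rep(1 / ns, ns)
  P <- lapply(seq_len(nrow(tree$edge)), function(i)
    transition_matrix(Q, tree$edge.length[i]))
  ints <- (nt + 1):nn
  grid <- as.matrix(expand.grid(rep(list(1:ns), length(ints))))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st <- grid[g, ]
    lik <- prior[st[1]]
    for (i in seq_len(nrow(tree$edge))) {
      par <- tree$edge[i, 1]
      chi <- tree$edge[i, 2]
      sp <- st[par - nt]
      lik <- lik * if (chi <= nt) sum(P[[i]][sp, ] * partials[, chi])
        else P[[i]][sp, st[chi - nt]]
    }
    tot <- tot + lik * prod(partials[cbind(st, ints)])
  }
  log(tot)
}

# Quadrature oracle for 1- or 2-parameter marginal likelihoods.
quadrature_logml <- function(model, tree, partials, priors) {
  dens <- function(p, pr) {
    if (pr$type == "uniform") stats::dunif(p, pr$a, pr$b)
    else stats::dexp(p, 1 / pr$a)
  }
  np <- length(model$params)
  lik1 <- function(x) exp(prune_loglik(tree, partials,
                                       build_rate_matrix(model, x)))
  if (np == 1) {
    pr <- priors[[1]]
    up <- if (pr$type == "uniform") pr$b else Inf
    f <- function(v) vapply(v, function(x) lik1(x) * dens(x, pr), numeric(1))
    log(stats::integrate(f, 0, up, rel.tol = 1e-10)$value)
  } else {
    pr1 <- priors[[model$params[1]]]
    pr2 <- priors[[model$params[2]]]
    up1 <- if (pr1$type == "uniform") pr1$b else qexp(1 - 1e-12, 1 / pr1$a)
    up2 <- if (pr2$type == "uniform") pr2$b else qexp(1 - 1e-12, 1 / pr2$a)
    f <- function(a, b) mapply(function(x, y)
      lik1(c(x, y)) * dens(x, pr1) * dens(y, pr2), a, b)
    log(pracma::integral2(f, 0, up1, 0, up2, reltol = 1e-8)$Q)
  }
}

# tiny fixed tree reused by several tests
toy_tree <- function() {
  tr <- parse_newick("((A:0.3,B:0.5):0.2,C:0.8);")
  tr
}

toy_traits <- function(x = c(1, 0, 1)) {
  trait_matrix(data.frame(x = x, row.names = c("A", "B", "C")))
}
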