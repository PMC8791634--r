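#' Parameter priors for MCMC
#'
#' Uniform and exponential priors over non-negative rates.  Following the
#' study's prior-assignment rule, parameters with small expected values get an
#' exponential prior with mean 0.001 and parameters with large expected values
#' get a wide uniform prior; [assign_priors()] applies that rule using
#' maximum-likelihood estimates.
#'
#' @param lower,upper uniform support (0 <= lower < upper).
#' @return a `prior` object.
#' @export
prior_uniform <- function(lower = 0, upper = 100) {
  stopifnot(lower >= 0, upper > lower)
  structure(list(type = "uniform", a = lower, b = upper), class = "prior")
}

#' @rdname prior_uniform
#' @param mean exponential mean (> 0).
#' @export
prior_exponential <- function(mean = 0.001) {
  stopifnot(mean > 0)
  structure(list(type = "exponential", a = mean, b = NA_real_), class = "prior")
}

#' @rdname prior_uniform
#' @param fit an [maximize_likelihood()] fit.
#' @param small_threshold ML estimates below this get the exponential prior.
#' @param exp_mean,uniform_upper prior hyperparameters.
#' @return a named list of priors, one per model parameter.
#' @export
assign_priors <- function(fit, small_threshold = 0.01, exp_mean = 0.001,
                          uniform_upper = 100) {
  stopifnot(inherits(fit, "ml_fit"))
  lapply(setNames(nm = fit$model$params), function(pn) {
    if (fit$estimate[[pn]] < small_threshold) prior_exponential(exp_mean)
    else prior_uniform(0, uniform_upper)
  })
}

prior_columns <- function(priors, params) {
  if (is.null(names(priors))) names(priors) <- params
  missing <- setdiff(params, names(priors))
  if (length(missing)) stop("no prior for parameter(s): ",
                            paste(missing, collapse = ", "))
  priors <- priors[params]
  list(
    type = vapply(priors, function(p) if (p$type == "uniform") 0L else 1L,
                  integer(1)),
    a = vapply(priors, function(p) p$a, numeric(1)),
    b = vapply(priors, function(p) if (is.na(p$b)) 1 else p$b, numeric(1))
  )
}

prior_draw <- function(priors, params) {
  vapply(priors[params], function(p) {
    if (p$type == "uniform") max(runif(1, p$a, p$b), 1e-8)
    else rexp(1, rate = 1 / p$a)
  }, numeric(1))
}

resolve_constraints <- function(constraints, states) {
  if (length(constraints) == 0L) return(list())
  if (anyDuplicated(names(constraints)))
    stop("contradictory constraints: node '",
         names(constraints)[duplicated(names(constraints))][1L],
         "' is constrained more than once")
  constraints
}

#' Posterior MCMC over rate parameters with ancestral reconstruction
#'
#' Metropolis-Hastings sampling of the model's rate parameters, targeting
#' prior x likelihood, with optional node fossilization (constraints zero the
#' disallowed state partials at named internal nodes).  Proposals are
#' multiplicative lognormal on each rate, with step sizes auto-tuned during
#' burn-in toward 20-40% acceptance.  Each retained sample also records a
#' joint draw of all internal-node states, from which ancestral posteriors are
#' read with [ancestral_posterior()].
#'
#' @param model a [rate_model()].
#' @param tree an [ape::phylo] tree with labelled ancestral nodes if
#'   constraints are used.
#' @param partials tip partials from [tip_partials()].
#' @param priors named list of [prior_uniform()]/[prior_exponential()] per
#'   parameter.
#' @param constraints named list node label -> allowed state labels.
#' @param iterations total chain length (default 1,010,000).
#' @param burnin,thin burn-in iterations and thinning interval.
#' @param seed integer seed; chains with identical seeds are identical.
#' @param init optional initial parameter values (default: drawn from the
#'   priors).
#' @param root_prior optional root prior (default uniform).
#' @return an object of class `mcmc_chain`: `samples` (matrix of rates),
#'   `loglik`, `states` (retained-sample states at internal nodes, 1-based
#'   into `model$states`), `acceptance`, plus run metadata.
#' @export
mcmc_run <- function(model, tree, partials, priors, constraints = list(),
                     iterations = 1010000, burnin = 10000, thin = 100,
                     seed = 1, init = NULL, root_prior = NULL) {
  stopifnot(inherits(model, "rate_model"))
  constraints <- resolve_constraints(constraints, model$states)
  partials <- apply_node_constraints(partials, tree, constraints)
  pc <- prior_columns(priors, model$params)
  ns <- length(model$states)
  if (is.null(root_prior)) root_prior <- rep(1 / ns, ns)
  pe <- postorder_edges(tree)
  set.seed(seed)
  if (is.null(init)) init <- prior_draw(priors, model$params)
  res <- .cpp_mcmc(pe$edge, pe$edge_len, partials, model$index, init,
                   pc$type, pc$a, pc$b, root_prior, pe$root, beta = 1,
                   n_iter = as.integer(iterations),
                   burnin = as.integer(burnin), thin = as.integer(thin),
                   step0 = rep(0.6, length(init)), tune = TRUE,
                   sample_states = TRUE, n_tip = pe$n_tip)
  if (res$acceptance <= 0)
    stop("chain accepted no proposals; check priors and starting values")
  colnames(res$samples) <- model$params
  structure(list(model = model, samples = res$samples, loglik = res$loglik,
                 states = res$states, acceptance = res$acceptance,
                 tree = tree, constraints = constraints,
                 iterations = iterations, burnin = burnin, thin = thin,
                 seed = seed),
            class = "mcmc_chain")
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat("MCMC chain: ", x$iterations, " iterations (burn-in ", x$burnin,
      ", thin ", x$thin, "), ", nrow(x$samples), " samples, acceptance ",
      sprintf("%.2f", x$acceptance), "\n", sep = "")
  print(round(colMeans(x$samples), 5))
  invisible(x)
}

#' Posterior probability of a trait at an ancestral node
#'
#' Fraction of retained MCMC samples in which the trait is present at the
#' named node.
#'
#' @param chain an [mcmc_run()] result.
#' @param node a node label (e.g. `"node1"`).
#' @param trait_pos which digit of the state label carries the trait (1 for
#'   single-trait models).
#' @return a probability in `[0, 1]`.
#' @export
ancestral_posterior <- function(chain, node, trait_pos = 1) {
  stopifnot(inherits(chain, "mcmc_chain"))
  nodes <- named_nodes(chain$tree)
  if (!node %in% names(nodes))
    stop("node '", node, "' is not a labelled internal node")
  n_tip <- ape::Ntip(chain$tree)
  col <- nodes[[node]] - n_tip
  st <- chain$model$states[chain$states[, col]]
  mean(substr(st, trait_pos, trait_pos) == "1")
}

#' Stepping-stone log marginal likelihood
#'
#' Estimates the log marginal likelihood by sampling a path of power
#' posteriors `prior x likelihood^beta` and summing the log mean importance
#' ratios between adjacent powers.  The power schedule follows quantiles of a
#' Beta(0.4, 1) distribution (`beta_k = (k/K)^(1/0.4)`), the standard choice
#' concentrating stones near the prior where the integrand changes fastest.
#' Each stone runs a short chain continued from the previous stone's state;
#' the first 10% of each stone's iterations are discarded as within-stone
#' burn-in.
#'
#' @inheritParams mcmc_run
#' @param stones number of stones (powers), default 100.
#' @param iters_per_stone iterations per stone, default 10,000.
#' @param replicates number of independent stepping-stone runs; the reported
#'   `logml` is their mean and `mc_se` the standard error across replicates
#'   (Monte Carlo uncertainty).
#' @return an object of class `marginal_likelihood`: `logml`, `mc_se`,
#'   `replicate_logml`, `stones`, `iters_per_stone`, `betas`, `seed`.
#' @export
stepping_stone_logml <- function(model, tree, partials, priors,
                                 constraints = list(), stones = 100,
                                 iters_per_stone = 10000, seed = 1,
                                 replicates = 1, init = NULL,
                                 root_prior = NULL) {
  stopifnot(inherits(model, "rate_model"), stones >= 1, iters_per_stone >= 10)
  if (replicates > 1) {
    reps <- vapply(seq_len(replicates), function(r)
      stepping_stone_logml(model, tree, partials, priors, constraints,
                           stones, iters_per_stone, seed = seed + 101L * r,
                           replicates = 1, init = init,
                           root_prior = root_prior)$logml,
      numeric(1))
    return(structure(list(logml = mean(reps),
                          mc_se = stats::sd(reps) / sqrt(replicates),
                          replicate_logml = reps, stones = stones,
                          iters_per_stone = iters_per_stone,
                          constraints = constraints, seed = seed),
                     class = "marginal_likelihood"))
  }
  constraints <- resolve_constraints(constraints, model$states)
  partials <- apply_node_constraints(partials, tree, constraints)
  pc <- prior_columns(priors, model$params)
  ns <- length(model$states)
  if (is.null(root_prior)) root_prior <- rep(1 / ns, ns)
  pe <- postorder_edges(tree)
  set.seed(seed)
  if (is.null(init)) init <- prior_draw(priors, model$params)
  betas <- (seq_len(stones) / stones)^(1 / 0.4)  # Beta(0.4, 1) quantiles
  powers <- c(0, betas)                          # sample at beta_0 .. beta_{K-1}
  burn <- max(1L, as.integer(0.1 * iters_per_stone))
  step <- rep(0.6, length(init))
  p_cur <- init
  logml <- 0
  for (k in seq_len(stones)) {
    res <- .cpp_mcmc(pe$edge, pe$edge_len, partials, model$index, p_cur,
                     pc$type, pc$a, pc$b, root_prior, pe$root,
                     beta = powers[k], n_iter = as.integer(iters_per_stone),
                     burnin = burn, thin = 1L, step0 = step, tune = TRUE,
                     sample_states = FALSE, n_tip = pe$n_tip)
    ll <- res$loglik
    if (all(!is.finite(ll)))
      stop("all importance ratios degenerate at stone ", k,
           "; the constrained likelihood may be zero everywhere")
    d <- powers[k + 1] - powers[k]
    m <- max(ll)
    logml <- logml + d * m + log(mean(exp(d * (ll - m))))
    p_cur <- res$params_final
    step <- res$step_final
  }
  if (!is.finite(logml)) stop("stepping-stone estimate is not finite")
  structure(list(logml = logml, mc_se = NA_real_, replicate_logml = logml,
                 stones = stones, iters_per_stone = iters_per_stone,
                 betas = betas, constraints = constraints, seed = seed),
            class = "marginal_likelihood")
}

#' @export
print.marginal_likelihood <- function(x, ...) {
  cat(sprintf("stepping-stone log marginal likelihood: %.4f (%d stones x %d)\n",
              x$logml, x$stones, x$iters_per_stone))
  invisible(x)
}

#' Log Bayes factor between two marginal likelihoods
#'
#' Computed as twice the difference of log marginal likelihoods.  The returned
#' object carries the conventional evidence band: < 2 weak, > 2 positive,
#' 5-10 strong, > 10 very strong evidence for the better model.
#'
#' @param logml_1,logml_2 log marginal likelihoods (numbers or
#'   [stepping_stone_logml()] results).
#' @return a list with `log_bf` (2 x difference, signed toward model 1) and
#'   `evidence` (band label for |log BF|).
#' @export
log_bayes_factor <- function(logml_1, logml_2) {
  v1 <- if (inherits(logml_1, "marginal_likelihood")) logml_1$logml else logml_1
  v2 <- if (inherits(logml_2, "marginal_likelihood")) logml_2$logml else logml_2
  stopifnot(is.finite(v1), is.finite(v2))
  bf <- 2 * (v1 - v2)
  band <- abs(bf)
  evidence <- if (band < 2) "weak" else if (band < 5) "positive"
    else if (band <= 10) "strong" else "very strong"
  list(log_bf = bf, evidence = evidence)
}

#' Ancestral-origin analysis: divergent versus convergent hypotheses
#'
#' Compares stepping-stone marginal likelihoods of ancestral-state hypotheses
#' for one trait at the labelled ancestral nodes `node1`..`node4`:
#' `unconstrained` (nodes free), `divergent` (nodes 1-4 fossilized to carry
#' the trait), and `convergent:nodeK` (node K fossilized to lack the trait).
#' Cleavage sites are analysed within the framework of sites 1 and 2
#' coevolving with each other (the 4-state dependent model, constraining the
#' focal site's digit); the PY motif uses the 2-state single-trait model.
#'
#' @param tree an [ape::phylo] tree with labelled nodes `node1`..`node4`.
#' @param traits a [trait_matrix()].
#' @param trait focal trait name (e.g. `"site1"`, `"site2"`, `"PY"`).
#' @param hypotheses character vector drawn from `"unconstrained"`,
#'   `"divergent"`, `"convergent"` (= node1) or `"convergent:nodeK"`.
#' @param companion for cleavage sites, the other site completing the
#'   coevolving pair; `NULL` for a single-trait analysis.
#' @param priors named list of priors; when `NULL`, assigned from an ML fit by
#'   the small/large expected-value rule (see [assign_priors()]).
#' @param stones,iters_per_stone stepping-stone settings.
#' @param restarts ML restarts used for prior assignment.
#' @param seed integer seed.
#' @return a list with `logml` (data frame per hypothesis), `bf` (matrix of
#'   pairwise log Bayes factors, row minus column), `priors`, and `trait_pos`.
#' @export
run_ancestry_analysis <- function(tree, traits, trait,
                                  hypotheses = c("unconstrained", "divergent",
                                                 "convergent"),
                                  companion = NULL, priors = NULL,
                                  stones = 100, iters_per_stone = 10000,
                                  replicates = 1, restarts = 25, seed = 1) {
  if (is.null(companion)) {
    model <- model_single_trait()
    trait_names <- trait
    trait_pos <- 1L
  } else {
    model <- model_dependent_pair()
    trait_names <- c(trait, companion)
    trait_pos <- 1L
  }
  partials <- tip_partials(tree, traits, trait_names)
  nn <- length(trait_names)
  present <- states_where(trait_pos, TRUE, nn)
  absent <- states_where(trait_pos, FALSE, nn)

  if (is.null(priors)) {
    fit <- maximize_likelihood(model, tree, partials, restarts = restarts,
                               seed = seed)
    priors <- assign_priors(fit)
  }

  parse_hypothesis <- function(h) {
    if (grepl("+", h, fixed = TRUE)) {
      parts <- strsplit(h, "+", fixed = TRUE)[[1]]
      return(do.call(c, lapply(parts, parse_hypothesis)))
    }
    if (h == "unconstrained") return(list())
    if (h == "divergent")
      return(setNames(rep(list(present), 4), paste0("node", 1:4)))
    if (startsWith(h, "convergent")) {
      node <- sub("^convergent:?", "", h)
      if (node == "") node <- "node1"
      return(setNames(list(absent), node))
    }
    stop("unknown hypothesis: ", h)
  }

  rows <- list()
  for (i in seq_along(hypotheses)) {
    h <- hypotheses[i]
    cons <- parse_hypothesis(h)
    ml <- stepping_stone_logml(model, tree, partials, priors,
                               constraints = cons, stones = stones,
                               iters_per_stone = iters_per_stone,
                               replicates = replicates,
                               seed = seed + 37L * i)
    rows[[i]] <- data.frame(hypothesis = h, logml = ml$logml,
                            mc_se = ml$mc_se, stringsAsFactors = FALSE)
  }
  logml <- do.call(rbind, rows)
  bf <- outer(logml$logml, logml$logml, function(a, b) 2 * (a - b))
  dimnames(bf) <- list(logml$hypothesis, logml$hypothesis)
  list(trait = trait, companion = companion, logml = logml, bf = bf,
       priors = priors, trait_pos = trait_pos,
       meta = list(stones = stones, iters_per_stone = iters_per_stone,
                   seed = seed))
}
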