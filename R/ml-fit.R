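#' Maximum-likelihood estimation of trait evolution rates
#'
#' Maximizes the pruning log-likelihood over the model's rate parameters.
#' Optimization runs in log-rate space (rates span orders of magnitude) with
#' box bounds, from `restarts` starting points drawn log-uniformly between the
#' bounds; the best local optimum is reported.  Rates estimated at the lower
#' bound are effectively zero and are reported as such by [summary] methods.
#'
#' @param model a [rate_model()].
#' @param tree an [ape::phylo] tree.
#' @param partials tip partials from [tip_partials()] (possibly constrained).
#' @param restarts number of random restarts (>= 1).
#' @param bounds numeric lower/upper bounds on every rate.
#' @param seed integer seed making the restart draw deterministic.
#' @param root_prior optional root prior (default uniform).
#' @return an object of class `ml_fit`: list with `model`, `estimate` (named
#'   rates), `loglik`, `restarts`, `converged`, `flat_likelihood` (TRUE when
#'   the likelihood surface is flat in some parameters, e.g. rates that are
#'   unidentifiable because a conditioning state is never visited), and
#'   `n_params`.
#' @export
maximize_likelihood <- function(model, tree, partials, restarts = 25,
                                bounds = c(1e-8, 100), seed = 1,
                                root_prior = NULL) {
  stopifnot(inherits(model, "rate_model"), restarts >= 1)
  np <- length(model$params)
  pe <- postorder_edges(tree)
  ns <- nrow(partials)
  if (is.null(root_prior)) root_prior <- rep(1 / ns, ns)
  lb <- log(bounds[1]); ub <- log(bounds[2])

  nll <- function(logp) {
    Q <- build_rate_matrix(model, exp(logp))
    -.cpp_prune_loglik(pe$edge, pe$edge_len, partials, unname(Q),
                       root_prior, pe$root)
  }

  set.seed(seed)
  starts <- matrix(runif(restarts * np, lb, ub), restarts, np)
  best <- NULL
  lls <- rep(NA_real_, restarts)
  pars <- matrix(NA_real_, restarts, np)
  n_conv <- 0L
  for (r in seq_len(restarts)) {
    fit <- tryCatch(
      optim(starts[r, ], nll, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value)) next
    n_conv <- n_conv + 1L
    lls[r] <- -fit$value
    pars[r, ] <- exp(fit$par)
    if (is.null(best) || -fit$value > -best$value) best <- fit
  }
  if (is.null(best))
    stop("optimization failed on all ", restarts, " restarts")

  est <- setNames(exp(best$par), model$params)
  ll <- -best$value
  # flat-likelihood diagnostic: many restarts reach the same lnL while some
  # parameter wanders over orders of magnitude (unidentifiable direction)
  near <- which(is.finite(lls) & lls > ll - 1e-4)
  flat <- FALSE
  if (length(near) >= 3) {
    spread <- apply(log(pmax(pars[near, , drop = FALSE], bounds[1])), 2,
                    function(z) diff(range(z)))
    flat <- any(spread > log(100))
  }
  structure(list(model = model, estimate = est, loglik = ll,
                 restarts = restarts, converged = n_conv > 0L,
                 flat_likelihood = flat, n_params = np,
                 bounds = bounds, seed = seed),
            class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, digits = 4, ...) {
  cat("ML fit of '", x$model$id, "': lnL = ", format(x$loglik, digits = 8),
      "\n", sep = "")
  est <- x$estimate
  est[est <= x$bounds[1] * (1 + 1e-6)] <- 0  # boundary estimates shown as 0
  print(round(est, digits))
  if (x$flat_likelihood) cat("note: likelihood surface flat in some parameters\n")
  invisible(x)
}

#' Likelihood-ratio test of nested trait-evolution models
#'
#' The statistic is twice the difference of the maximized log-likelihoods,
#' referred to a chi-square distribution with degrees of freedom equal to the
#' difference in free-parameter counts.
#'
#' @param fit_null,fit_alt [maximize_likelihood()] fits; `fit_alt`'s model
#'   must nest `fit_null`'s model.
#' @return an object of class `lrt_result`: list with `statistic`, `df`,
#'   `p_value`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "ml_fit"), inherits(fit_alt, "ml_fit"))
  if (!fit_null$model$id %in% fit_alt$model$nests)
    stop("model '", fit_alt$model$id, "' does not nest '",
         fit_null$model$id, "'")
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (stat < -1e-6)
    stop("alternative model fits worse than null beyond optimizer tolerance (",
         format(stat), "); refit with more restarts")
  stat <- max(stat, 0)
  df <- fit_alt$n_params - fit_null$n_params
  if (df <= 0) stop("alternative model has no extra free parameters")
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: 2*dlnL = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Run a suite of pairwise coevolution tests
#'
#' For each trait pair, fits the independent (null) and dependent
#' (alternative) model of the requested family and performs the
#' likelihood-ratio test.  The `pair` family treats both traits as reversible
#' coevolving characters (shared gain/loss rates split by the other's state);
#' the `habitat` family treats the second trait as a one-way conditioning
#' character (e.g. terrestrial status or lungs) whose reverse transition has
#' rate zero.
#'
#' @param tree an [ape::phylo] tree.
#' @param traits a [trait_matrix()].
#' @param pairs list of character 2-vectors `(traitA, traitB)`; in the
#'   `habitat` family `traitB` is the conditioning character.
#' @param family `"pair"` or `"habitat"`.
#' @param restarts,seed,bounds passed to [maximize_likelihood()].
#' @return a data frame with one row per pair: log-likelihoods, LRT statistic,
#'   df and p-value, plus the dependent-model estimates as an attribute
#'   `fits`.
#' @export
run_coevolution_suite <- function(tree, traits, pairs,
                                  family = c("pair", "habitat"),
                                  restarts = 25, seed = 1,
                                  bounds = c(1e-8, 100)) {
  family <- match.arg(family)
  null_model <- switch(family, pair = model_independent_pair(),
                       habitat = model_independent_habitat())
  alt_model <- switch(family, pair = model_dependent_pair(),
                      habitat = model_dependent_habitat())
  rows <- list(); fits <- list()
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    partials <- tip_partials(tree, traits, pr)
    f0 <- maximize_likelihood(null_model, tree, partials, restarts = restarts,
                              seed = seed + i, bounds = bounds)
    f1 <- maximize_likelihood(alt_model, tree, partials, restarts = restarts,
                              seed = seed + 1000 + i, bounds = bounds)
    lrt <- likelihood_ratio_test(f0, f1)
    rows[[i]] <- data.frame(
      trait1 = pr[1], trait2 = pr[2], family = family,
      lnL_independent = f0$loglik, lnL_dependent = f1$loglik,
      statistic = lrt$statistic, df = lrt$df, p_value = lrt$p_value,
      stringsAsFactors = FALSE
    )
    fits[[i]] <- list(independent = f0, dependent = f1)
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  attr(out, "meta") <- list(restarts = restarts, seed = seed,
                            root_prior = "uniform")
  out
}
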