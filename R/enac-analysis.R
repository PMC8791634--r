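#' The full suite of ENaC coevolution likelihood-ratio tests
#'
#' Runs every pairwise coevolution test reported for the ENaC dataset:
#' site 1 versus site 2 (reversible pair family); site 1, site 2, tandem
#' sites and the PY motif each against terrestrial status and against lungs
#' (habitat family, the conditioning character being one-way); and lungs
#' against terrestrial status (habitat family).
#'
#' @param tree an [ape::phylo] tree (e.g. [enac_tree_synthetic()]).
#' @param traits a [trait_matrix()] (e.g. [enac_trait_table()]).
#' @param restarts,seed passed to the ML fits.
#' @return a data frame (see [run_coevolution_suite()]) with all comparisons.
#' @export
enac_lrt_suite <- function(tree, traits, restarts = 25, seed = 1) {
  pair <- run_coevolution_suite(tree, traits, list(c("site1", "site2")),
                                family = "pair", restarts = restarts,
                                seed = seed)
  hab_pairs <- list(
    c("site1", "terrestrial"), c("tandem", "terrestrial"),
    c("site2", "terrestrial"),
    c("site1", "lungs"), c("tandem", "lungs"), c("site2", "lungs"),
    c("PY", "terrestrial"), c("PY", "lungs"),
    c("lungs", "terrestrial")
  )
  hab <- run_coevolution_suite(tree, traits, hab_pairs, family = "habitat",
                               restarts = restarts, seed = seed + 100)
  out <- rbind(pair, hab)
  attr(out, "fits") <- c(attr(pair, "fits"), attr(hab, "fits"))
  rownames(out) <- NULL
  out
}

#' Ancestral-origin analyses for the cleavage sites and the PY motif
#'
#' For each cleavage site (within the framework of the two sites coevolving
#' with each other) compares the unconstrained, divergent (sites present at
#' nodes 1-4) and convergent (site absent at node 1) models; for the PY motif
#' compares unconstrained, divergent and all four single-node convergent
#' models, and reports the node-1..4 presence posteriors from the
#' unconstrained MCMC run.
#'
#' @inheritParams enac_lrt_suite
#' @param stones,iters_per_stone stepping-stone settings.
#' @param mcmc_iterations chain length for the unconstrained PY run.
#' @param replicates independent stepping-stone replicates per hypothesis
#'   (the reported log marginal likelihood is their mean).
#' @return a list with elements `site1`, `site2` (each a
#'   [run_ancestry_analysis()] result), `py` (ditto, plus
#'   `node_posteriors`).
#' @export
enac_ancestry_suite <- function(tree, traits, stones = 100,
                                iters_per_stone = 10000,
                                mcmc_iterations = 1010000, replicates = 3,
                                restarts = 25, seed = 1) {
  site1 <- run_ancestry_analysis(
    tree, traits, "site1", c("unconstrained", "divergent", "convergent"),
    companion = "site2", stones = stones, iters_per_stone = iters_per_stone,
    replicates = replicates, restarts = restarts, seed = seed
  )
  site2 <- run_ancestry_analysis(
    tree, traits, "site2", c("unconstrained", "divergent", "convergent"),
    companion = "site1", stones = stones, iters_per_stone = iters_per_stone,
    replicates = replicates, restarts = restarts, seed = seed + 500
  )
  py <- run_ancestry_analysis(
    tree, traits, "PY",
    c("unconstrained", "divergent", "convergent:node1", "convergent:node2",
      "convergent:node3", "convergent:node4"),
    companion = NULL, stones = stones, iters_per_stone = iters_per_stone,
    replicates = replicates, restarts = restarts, seed = seed + 900
  )
  partials <- tip_partials(tree, traits, "PY")
  chain <- mcmc_run(model_single_trait(), tree, partials, py$priors,
                    iterations = mcmc_iterations, seed = seed + 1300)
  py$node_posteriors <- vapply(paste0("node", 1:4), function(nd)
    ancestral_posterior(chain, nd), numeric(1))
  py$chain <- chain
  list(site1 = site1, site2 = site2, py = py)
}
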