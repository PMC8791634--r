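#' Simulate a random rooted birth-death tree
#'
#' Complete-sampling birth-death simulation (via [ape::rphylo()]) conditioned
#' on the number of extant tips, optionally rescaled so that the total tree
#' length (sum of branch lengths, in expected substitutions) is fixed --
#' useful because the information content of discrete-trait data depends on
#' tree length.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth,death per-lineage rates; `death` must be below `birth`.
#' @param total_length optional total tree length to rescale to.
#' @param seed integer seed; identical seeds give identical trees.
#' @return an [ape::phylo] tree with strictly positive branch lengths.
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, total_length = NULL,
                          seed = 1) {
  stopifnot(n_tips >= 2, birth > 0)
  if (death >= birth)
    stop("death rate must be below birth rate (extinction-dominated ",
         "processes do not reach the requested tip count)")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = death)
  tree$edge.length <- pmax(tree$edge.length, 1e-9)
  if (!is.null(total_length))
    tree$edge.length <- tree$edge.length * total_length / sum(tree$edge.length)
  tree
}

#' Simulate binary traits down a tree under a rate model
#'
#' Exact CTMC simulation: the root state is fixed or drawn from `root_prior`,
#' and each child's state is drawn from the corresponding row of the
#' transition matrix for its branch.  State labels are decomposed into one
#' column per digit, named by `trait_names`.
#'
#' @param tree an [ape::phylo] tree.
#' @param model a [rate_model()].
#' @param params named rates for the model.
#' @param trait_names column names for the emitted traits (one per digit of
#'   the state labels).
#' @param root_state optional fixed root state label; otherwise drawn from
#'   `root_prior` (default uniform).
#' @param seed integer seed.
#' @param root_prior optional root state distribution.
#' @return a [trait_matrix()] with one row per tip; attribute `node_states`
#'   holds the simulated state label of every node (the ground truth).
#' @export
simulate_traits <- function(tree, model, params, trait_names,
                            root_state = NULL, seed = 1, root_prior = NULL) {
  stopifnot(inherits(model, "rate_model"))
  states <- model$states
  ndig <- nchar(states[1])
  stopifnot(length(trait_names) == ndig)
  Q <- build_rate_matrix(model, params)
  set.seed(seed)
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  if (is.null(root_prior)) root_prior <- rep(1 / length(states), length(states))
  st <- integer(n_node)
  st[root] <- if (is.null(root_state)) {
    sample.int(length(states), 1, prob = root_prior)
  } else {
    m <- match(root_state, states)
    if (is.na(m)) stop("unknown root state: ", root_state)
    m
  }
  # transition rows per edge, walking parents before children
  pr <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(pr$edge)))
  Pcache <- list()
  for (i in ord) {
    par <- pr$edge[i, 1]; chi <- pr$edge[i, 2]; t <- pr$edge.length[i]
    key <- format(t, digits = 15)
    P <- Pcache[[key]]
    if (is.null(P)) {
      P <- transition_matrix(Q, t)
      Pcache[[key]] <- P
    }
    st[chi] <- sample.int(length(states), 1, prob = P[st[par], ])
  }
  lab <- states[st[seq_len(n_tip)]]
  out <- as.data.frame(lapply(seq_len(ndig), function(d)
    as.integer(substr(lab, d, d))))
  names(out) <- trait_names
  rownames(out) <- tree$tip.label
  tm <- trait_matrix(out)
  attr(tm, "node_states") <- states[st]
  tm
}

#' Build a motif-implanted alignment fixture with known ground truth
#'
#' Generates an alignment whose background alphabet contains no basic residues
#' (and no tyrosine), so that every polybasic or PY hit a scanner reports must
#' be an implant: truth tables are exact by construction.
#'
#' @param ids sequence identifiers.
#' @param n_col alignment width.
#' @param implants data frame with columns `id`, `motif` (gap-free string) and
#'   `column` (alignment column of the motif's first residue).
#' @param gap_frac fraction of background positions turned into gaps.
#' @param seed integer seed.
#' @return a [protein_alignment()]; attribute `truth` is the implant table
#'   with the motif's last-residue (P1) column added.
#' @export
make_alignment_fixture <- function(ids, n_col, implants =
                                     data.frame(id = character(0),
                                                motif = character(0),
                                                column = integer(0)),
                                   gap_frac = 0.1, seed = 1) {
  background <- c("A", "D", "E", "F", "G", "H", "I", "L", "M", "N",
                  "P", "Q", "S", "T", "V", "W")  # no R/K, no Y
  set.seed(seed)
  mat <- matrix(sample(background, length(ids) * n_col, replace = TRUE),
                nrow = length(ids), dimnames = list(ids, NULL))
  if (gap_frac > 0) {
    gaps <- matrix(runif(length(mat)) < gap_frac, nrow = nrow(mat))
    mat[gaps] <- "-"
  }
  if (nrow(implants)) {
    claimed <- matrix(FALSE, length(ids), n_col, dimnames = list(ids, NULL))
    for (i in seq_len(nrow(implants))) {
      id <- implants$id[i]
      motif <- strsplit(implants$motif[i], "")[[1]]
      cols <- implants$column[i] + seq_along(motif) - 1L
      if (max(cols) > n_col) stop("implant '", implants$motif[i],
                                  "' extends beyond the alignment")
      if (!id %in% ids) stop("implant id not in alignment: ", id)
      if (any(claimed[id, cols]))
        stop("overlapping implants for sequence '", id, "'")
      mat[id, cols] <- motif
      claimed[id, cols] <- TRUE
    }
    implants$p1_column <- implants$column + nchar(implants$motif) - 1L
  }
  aln <- protein_alignment(apply(mat, 1, paste, collapse = ""))
  attr(aln, "truth") <- implants
  aln
}

#' Type-I error / power calibration of the coevolution LRT
#'
#' Simulates `replicates` trait datasets on a tree under a generating model,
#' runs the independent-versus-dependent likelihood-ratio test on each, and
#' reports the rejection rate at level `alpha` with a 95% binomial confidence
#' interval.  With the independent (null) generating model this measures the
#' test's type-I error, which can sit below `alpha` because null rates on the
#' boundary make the chi-square reference conservative; with a strongly
#' dependent generating model it measures power.
#'
#' @param tree an [ape::phylo] tree.
#' @param generating_model,params model and rates traits are simulated under.
#' @param family LRT family, as in [run_coevolution_suite()].
#' @param alpha test level.
#' @param replicates number of simulated datasets (> 0).
#' @param restarts ML restarts per fit (calibration uses fewer than a
#'   production fit since each replicate is refit twice).
#' @param seed integer seed.
#' @return a list with `rejection_rate`, `ci` (95% binomial), `p_values`.
#' @export
lrt_calibration <- function(tree, generating_model, params,
                            family = c("pair", "habitat"), alpha = 0.05,
                            replicates = 100, restarts = 5, seed = 1) {
  family <- match.arg(family)
  if (replicates <= 0) stop("replicates must be positive")
  null_model <- switch(family, pair = model_independent_pair(),
                       habitat = model_independent_habitat())
  alt_model <- switch(family, pair = model_dependent_pair(),
                      habitat = model_dependent_habitat())
  pvals <- rep(NA_real_, replicates)
  for (r in seq_len(replicates)) {
    tm <- simulate_traits(tree, generating_model, params, c("t1", "t2"),
                          seed = seed + r)
    partials <- tip_partials(tree, tm, c("t1", "t2"))
    f0 <- maximize_likelihood(null_model, tree, partials, restarts = restarts,
                              seed = seed + 10000 + r)
    f1 <- maximize_likelihood(alt_model, tree, partials, restarts = restarts,
                              seed = seed + 20000 + r)
    if (f1$loglik < f0$loglik) f1$loglik <- f0$loglik  # boundary-noise guard
    pvals[r] <- likelihood_ratio_test(f0, f1)$p_value
  }
  rej <- mean(pvals < alpha)
  ci <- as.numeric(binom.test(sum(pvals < alpha), replicates)$conf.int)
  list(rejection_rate = rej, ci = ci, p_values = pvals, alpha = alpha)
}
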