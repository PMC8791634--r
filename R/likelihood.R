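#' Tip partial likelihoods for one or two binary traits
#'
#' Builds the per-node state indicator matrix consumed by the pruning
#' likelihood.  Tip columns are 1 for states consistent with the observation
#' and 0 otherwise; an ambiguous (`NA`) trait leaves both of its values
#' allowed, so a tip with every trait ambiguous contributes a column of ones.
#' Internal-node columns start as all-ones and can be restricted with
#' [apply_node_constraints()].
#'
#' For two traits the state labels are `00`, `01`, `10`, `11`, the i-th digit
#' being the i-th trait in `trait_names`.
#'
#' @param tree an [ape::phylo] tree.
#' @param traits a [trait_matrix()] covering every tip.
#' @param trait_names one or two trait (column) names.
#' @return a states-by-nodes numeric matrix with state labels as row names.
#' @export
tip_partials <- function(tree, traits, trait_names) {
  stopifnot(length(trait_names) %in% 1:2)
  missing <- setdiff(trait_names, colnames(traits))
  if (length(missing)) stop("trait(s) not in matrix: ", paste(missing, collapse = ", "))
  cc <- check_consistency(tree, traits)
  if (!cc$consistent)
    stop("tree and trait matrix are inconsistent; missing: ",
         paste(cc$missing_in_traits, collapse = ", "), "; extra: ",
         paste(cc$extra_in_traits, collapse = ", "))
  states <- if (length(trait_names) == 1L) c("0", "1") else pair_states()
  digits <- do.call(rbind, lapply(strsplit(states, ""), as.integer))
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  P <- matrix(1, length(states), n_node, dimnames = list(states, NULL))
  vals <- as.matrix(traits[tree$tip.label, trait_names, drop = FALSE])
  for (i in seq_len(n_tip)) {
    for (s in seq_along(states)) {
      ok <- is.na(vals[i, ]) | vals[i, ] == digits[s, ]
      P[s, i] <- as.numeric(all(ok))
    }
  }
  P
}

#' State labels with a given trait present or absent
#'
#' @param trait_pos which digit of the state label (1 or 2).
#' @param present `TRUE` for states with the trait present.
#' @param n_traits 1 or 2 (size of the joint state space).
#' @return a character vector of state labels.
#' @export
states_where <- function(trait_pos, present = TRUE, n_traits = 2) {
  states <- if (n_traits == 1L) c("0", "1") else pair_states()
  states[substr(states, trait_pos, trait_pos) == (if (present) "1" else "0")]
}

#' Fossilize internal nodes to allowed state sets
#'
#' Implements node constraints ("fossilization") for ancestral-state
#' hypotheses: at each named node, partials for disallowed states are zeroed,
#' so the likelihood only integrates over histories consistent with the
#' hypothesis.
#'
#' @param partials a matrix from [tip_partials()].
#' @param tree the tree the partials were built on (must carry the node
#'   labels referenced by `constraints`; see [named_nodes()]).
#' @param constraints a named list: node label -> character vector of allowed
#'   state labels (a nonempty strict subset of the state space).
#' @return the constrained partials matrix.
#' @export
apply_node_constraints <- function(partials, tree, constraints) {
  if (length(constraints) == 0L) return(partials)
  nodes <- named_nodes(tree)
  states <- rownames(partials)
  for (nm in names(constraints)) {
    if (!nm %in% names(nodes)) stop("no internal node labelled '", nm, "'")
    allowed <- constraints[[nm]]
    if (!all(allowed %in% states))
      stop("unknown state label(s) in constraint '", nm, "'")
    if (length(allowed) == 0L)
      stop("constraint '", nm, "' excludes all states")
    if (length(unique(allowed)) >= length(states))
      stop("constraint '", nm, "' must be a strict subset of the state space")
    mask <- as.numeric(states %in% allowed)
    partials[, nodes[[nm]]] <- partials[, nodes[[nm]]] * mask
    if (all(partials[, nodes[[nm]]] == 0))
      stop("constraint '", nm, "' excludes all states at that node")
  }
  partials
}

postorder_edges <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, edge_len = po$edge.length,
       root = ape::Ntip(tree) + 1L,
       n_tip = ape::Ntip(tree))
}

#' Log-likelihood by Felsenstein pruning
#'
#' Exact likelihood of tip states (and any node constraints encoded in the
#' partials) under a continuous-time Markov model on the tree, computed by
#' the pruning algorithm with per-node numerical rescaling.
#'
#' @param tree an [ape::phylo] tree.
#' @param partials matrix from [tip_partials()] (possibly constrained).
#' @param Q rate matrix from [build_rate_matrix()]; its dimension must match
#'   the partials' state space.
#' @param root_prior prior over root states; default uniform.  Must sum to 1.
#' @return the log-likelihood (a scalar; `-Inf` if the data are impossible).
#' @export
prune_loglik <- function(tree, partials, Q, root_prior = NULL) {
  ns <- nrow(partials)
  if (nrow(Q) != ns) stop("Q dimension does not match state space")
  if (is.null(root_prior)) root_prior <- rep(1 / ns, ns)
  if (length(root_prior) != ns || any(root_prior < 0) ||
      abs(sum(root_prior) - 1) > 1e-8)
    stop("root_prior must be a probability vector over the states")
  if (any(colSums(partials) == 0))
    stop("a partials column has no allowed state")
  pe <- postorder_edges(tree)
  .cpp_prune_loglik(pe$edge, pe$edge_len, partials, unname(Q),
                    root_prior, pe$root)
}
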