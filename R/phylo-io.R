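#' Parse a rooted Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contracts the
#' downstream trait models rely on: a single root, branch lengths on every
#' non-root edge, non-negative branch lengths and unique tip labels.  Trees
#' are used exactly as rooted in the input; no rerooting is ever performed,
#' because the identities of named ancestral nodes depend on the published
#' rooting.
#'
#' Internal node labels of the form `node1`, `node2`, ... are retained and can
#' be resolved to node numbers with [named_nodes()].
#'
#' @param text a Newick string.
#' @return an [ape::phylo] tree.
#' @seealso [read_tree()], [write_newick()]
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree)) {
    stop("malformed Newick string (near character ",
         regexpr("[^();,[:alnum:]_.:[:space:]-]", text)[1L], ")")
  }
  validate_tree(tree)
}

#' Read a rooted Newick tree from a file
#' @param path path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Serialize a tree to Newick
#' @param tree an [ape::phylo] tree.
#' @param path optional path; when `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(tree, path = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree is missing branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  # exactly one root: every node but one appears as a child exactly once
  n_node <- ape::Ntip(tree) + tree$Nnode
  child_count <- tabulate(tree$edge[, 2], nbins = n_node)
  roots <- which(child_count == 0)
  if (length(roots) != 1L || any(child_count > 1L))
    stop("tree is not singly rooted")
  tree$tip.label <- trimws(tree$tip.label)
  tree
}

#' Resolve named internal nodes
#'
#' Returns the node numbers of internal nodes carrying labels (for example the
#' ancestral gene-duplication nodes `node1`..`node4` of the ENaC phylogeny).
#'
#' @param tree an [ape::phylo] tree with (some) internal node labels.
#' @return a named integer vector of node numbers; empty if none are labelled.
#' @export
named_nodes <- function(tree) {
  if (is.null(tree$node.label)) return(setNames(integer(0), character(0)))
  lab <- tree$node.label
  keep <- !is.na(lab) & nzchar(lab)
  setNames(ape::Ntip(tree) + which(keep), lab[keep])
}

#' Construct a binary trait matrix
#'
#' A trait matrix holds one row per tip of an associated tree and one column
#' per named binary trait.  States are `0` (absent), `1` (present) or `NA`
#' (ambiguous: the relevant sequence region was missing).  If columns named
#' `site1`, `site2` and `tandem` are all present, `tandem` must equal
#' `site1 & site2` on every row where the conjunction is determined.
#'
#' @param x a data frame or matrix of 0/1/NA values with taxa as row names.
#' @return an object of class `trait_matrix` (a data frame).
#' @export
trait_matrix <- function(x) {
  x <- as.data.frame(x)
  if (nrow(x) == 0L) stop("trait table has no rows")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("taxa (row names) must be present and unique")
  for (j in seq_along(x)) {
    v <- x[[j]]
    if (is.logical(v)) v <- as.integer(v)
    if (!all(v %in% c(0L, 1L, NA)))
      stop("trait '", names(x)[j], "' contains states other than 0/1/NA")
    x[[j]] <- as.integer(v)
  }
  if (all(c("site1", "site2", "tandem") %in% names(x))) {
    expect <- as.integer(x$site1 == 1L & x$site2 == 1L)
    bad <- which(!is.na(expect) & !is.na(x$tandem) & expect != x$tandem)
    if (length(bad))
      stop("tandem != site1 & site2 for: ", paste(rownames(x)[bad], collapse = ", "))
  }
  rownames(x) <- trimws(rownames(x))
  class(x) <- c("trait_matrix", "data.frame")
  x
}

#' Read a trait table from TSV
#'
#' Expected dialect: a header `taxon<TAB>trait1<TAB>...`, one row per taxon,
#' states encoded `0`, `1` or `?` (ambiguous).
#'
#' @param path path to a TSV file.
#' @return a [trait_matrix()].
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE)
  if (nrow(df) == 0L) stop("trait table has an empty body: ", path)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate taxon in trait table: ",
         paste(unique(df[[1L]][duplicated(df[[1L]])]), collapse = ", "))
  taxa <- trimws(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  for (j in seq_along(df)) {
    v <- trimws(df[[j]])
    bad <- !v %in% c("0", "1", "?")
    if (any(bad))
      stop("unknown state token '", v[bad][1L], "' in trait '", names(df)[j], "'")
    df[[j]] <- as.integer(replace(v, v == "?", NA_character_))
  }
  rownames(df) <- taxa
  trait_matrix(df)
}

#' Write a trait table to TSV
#' @param x a [trait_matrix()].
#' @param path output path.
#' @export
write_trait_table <- function(x, path) {
  stopifnot(inherits(x, "trait_matrix"))
  out <- as.data.frame(lapply(x, function(v) ifelse(is.na(v), "?", as.character(v))))
  out <- cbind(taxon = rownames(x), out)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a protein alignment
#'
#' @param seqs a named character vector of aligned sequences (gap character
#'   `-`); all sequences must have the same number of columns.  Residues are
#'   uppercased on construction.
#' @return an object of class `protein_alignment`: a named character vector
#'   with attribute `n_col`.
#' @export
protein_alignment <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequence ids must be present and unique")
  seqs <- toupper(vapply(seqs, as.character, character(1)))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    off <- names(seqs)[widths != widths[1L]][1L]
    stop("ragged alignment: sequence '", off, "' has ", nchar(seqs[off]),
         " columns, expected ", widths[1L])
  }
  structure(seqs, n_col = unname(widths[1L]), class = "protein_alignment")
}

#' Number of alignment columns
#' @param aln a [protein_alignment()].
#' @export
n_columns <- function(aln) attr(aln, "n_col")

#' Read a gapped protein alignment from FASTA
#' @param path path to a FASTA file.
#' @return a [protein_alignment()].
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  protein_alignment(setNames(unlist(lapply(recs, as.character)), names(recs)))
}

#' Write a protein alignment to FASTA
#' @param aln a [protein_alignment()].
#' @param path output path.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqinr::write.fasta(as.list(unclass(aln)), names = names(aln),
                      file.out = path, nbchar = 70)
  invisible(path)
}

#' Check tree/trait-matrix consistency
#'
#' @param tree an [ape::phylo] tree.
#' @param traits a [trait_matrix()].
#' @return a list with `missing_in_traits` (tips with no trait row),
#'   `extra_in_traits` (trait rows with no tip) and `consistent` (TRUE iff
#'   both are empty).
#' @export
check_consistency <- function(tree, traits) {
  tips <- tree$tip.label
  taxa <- rownames(traits)
  out <- list(
    missing_in_traits = setdiff(tips, taxa),
    extra_in_traits = setdiff(taxa, tips)
  )
  out$consistent <- length(out$missing_in_traits) == 0L &&
    length(out$extra_in_traits) == 0L
  out
}
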