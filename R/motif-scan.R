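aln_chars <- function(aln) strsplit(unclass(aln), "")

#' Map ungapped reference positions to alignment columns
#'
#' Cleavage-site anchors are defined by the P1 residue position (1-based,
#' ungapped) in a reference sequence (e.g. the human alpha or gamma subunit);
#' scanning happens in alignment-column coordinates, the only coordinate
#' system shared across sequences.
#'
#' @param aln a [protein_alignment()].
#' @param reference_id id of the reference row.
#' @param anchors named integer vector: anchor name -> P1 position in
#'   ungapped reference coordinates.  Conventional names are `alpha_site1`,
#'   `alpha_site2`, `gamma_site1`, `gamma_site2_prostasin`.
#' @return a data frame with columns `name`, `p1_ungapped`, `column` and
#'   `p1_residue`.
#' @export
map_anchor_columns <- function(aln, reference_id, anchors) {
  if (!reference_id %in% names(aln))
    stop("reference id not in alignment: ", reference_id)
  ch <- aln_chars(aln)[[match(reference_id, names(aln))]]
  res_cols <- which(ch != "-")
  p1 <- as.integer(anchors)
  if (any(p1 < 1 | p1 > length(res_cols)))
    stop("anchor position out of range for reference '", reference_id,
         "' (", length(res_cols), " residues)")
  data.frame(name = names(anchors), p1_ungapped = p1,
             column = res_cols[p1], p1_residue = ch[res_cols[p1]],
             stringsAsFactors = FALSE)
}

is_basic <- function(x) x %in% c("R", "K")

classify_tract <- function(fourmer, terminal_rule) {
  if (grepl("^R.[RK]R$", fourmer)) return("furin_ideal")
  if (terminal_rule == "R_only") "polybasic_R" else "polybasic_RK"
}

#' Scan for polybasic cleavage tracts near an anchored column
#'
#' For every sequence, examines gap-free 4-mers (the P4-P1 substrate
#' residues, read from the sequence's own ungapped residues) whose P1 residue
#' falls within `window` alignment columns of the anchor's P1 column.  A hit
#' must end in Arg (`R_only`, furin-style) or Arg/Lys (`R_or_K`,
#' prostasin-style) and be either an ideal furin site (`R-X-R/K-R`) or a
#' polybasic tract with at least two basic residues among the four.  At most
#' one hit is reported per sequence: the one whose P1 column is nearest the
#' anchor, ties broken toward the C-terminal side.
#'
#' @param aln a [protein_alignment()].
#' @param anchor_column alignment column of the anchor's P1 residue (from
#'   [map_anchor_columns()]).
#' @param terminal_rule `"R_only"` (furin) or `"R_or_K"` (prostasin).
#' @param window half-width of the scan window in alignment columns.
#' @param anchor_name optional label copied into the output.
#' @return a data frame with one row per sequence: `id`, `hit`, `motif`,
#'   `class`, `p1_column`, `p1_ungapped`, `region_missing` (no residues at
#'   all inside the window, i.e. the region is absent from the available
#'   sequence).
#' @export
find_polybasic_sites <- function(aln, anchor_column,
                                 terminal_rule = c("R_only", "R_or_K"),
                                 window = 5, anchor_name = NA_character_) {
  terminal_rule <- match.arg(terminal_rule)
  stopifnot(window >= 0)
  chs <- aln_chars(aln)
  lo <- anchor_column - window
  hi <- anchor_column + window
  rows <- lapply(seq_along(chs), function(si) {
    ch <- chs[[si]]
    res_cols <- which(ch != "-")
    in_win <- which(res_cols >= lo & res_cols <= hi)
    out <- data.frame(id = names(aln)[si], hit = FALSE, motif = NA_character_,
                      class = NA_character_, p1_column = NA_integer_,
                      p1_ungapped = NA_integer_,
                      region_missing = length(in_win) == 0L,
                      anchor = anchor_name, stringsAsFactors = FALSE)
    cand <- in_win[in_win >= 4L]  # need a full P4..P1 4-mer
    best <- NULL
    for (i in cand) {
      fourmer <- paste(ch[res_cols[(i - 3L):i]], collapse = "")
      p1res <- ch[res_cols[i]]
      term_ok <- if (terminal_rule == "R_only") p1res == "R" else is_basic(p1res)
      if (!term_ok) next
      nb <- sum(is_basic(strsplit(fourmer, "")[[1]]))
      if (!(grepl("^R.[RK]R$", fourmer) || nb >= 2L)) next
      dist <- abs(res_cols[i] - anchor_column)
      if (is.null(best) || dist < best$dist ||
          (dist == best$dist && res_cols[i] > best$col)) {
        best <- list(fourmer = fourmer, col = res_cols[i], dist = dist, i = i)
      }
    }
    if (!is.null(best)) {
      out$hit <- TRUE
      out$motif <- best$fourmer
      out$class <- classify_tract(best$fourmer, terminal_rule)
      out$p1_column <- best$col
      out$p1_ungapped <- best$i
    }
    out
  })
  do.call(rbind, rows)
}

#' Scan C-termini for the PY motif
#'
#' Finds the `L/P-P-X-Y` 4-mer nearest the C-terminus within the last
#' `region` ungapped residues of each sequence.  A sequence whose row is all
#' gaps over the last `tail_cols` alignment columns is flagged as having its
#' C-terminal region missing (ambiguous), rather than motif-absent.
#'
#' @param aln a [protein_alignment()], or a named character vector of (raw or
#'   gapped) sequences.
#' @param region number of C-terminal ungapped residues searched.
#' @param tail_cols alignment columns used to detect a missing C-terminal
#'   region (ignored for raw sequences).
#' @return a data frame with one row per sequence: `id`, `hit`, `motif`,
#'   `region_missing`.
#' @export
find_py_motif <- function(aln, region = 25, tail_cols = 10) {
  is_aln <- inherits(aln, "protein_alignment")
  if (!is_aln) aln <- protein_alignment(aln)
  chs <- aln_chars(aln)
  nc <- n_columns(aln)
  rows <- lapply(seq_along(chs), function(si) {
    ch <- chs[[si]]
    res <- ch[ch != "-"]
    missing_tail <- is_aln && nc > tail_cols &&
      all(ch[(nc - tail_cols + 1L):nc] == "-")
    out <- data.frame(id = names(aln)[si], hit = FALSE, motif = NA_character_,
                      region_missing = missing_tail || length(res) == 0L,
                      stringsAsFactors = FALSE)
    if (length(res) == 0L) return(out)
    tail_seq <- paste(res[max(1L, length(res) - region + 1L):length(res)],
                      collapse = "")
    m <- gregexpr("[LP]P.Y", tail_seq)[[1]]
    if (m[1] != -1L) {
      last <- m[length(m)]
      out$hit <- TRUE
      out$motif <- substr(tail_seq, last, last + 3L)
      out$region_missing <- FALSE
    }
    out
  })
  do.call(rbind, rows)
}

#' Build a trait matrix from motif scans
#'
#' Runs the cleavage-site and PY scans appropriate to each subunit class and
#' assembles the binary trait matrix used by the evolutionary models:
#' * alpha and delta subunits: both sites scanned with the furin rule
#'   (`R_only`) around the alpha-subunit proximal/distal anchors;
#' * beta and gamma subunits: site 1 scanned with the furin rule around the
#'   gamma proximal anchor, site 2 with the prostasin rule (`R_or_K`) around
#'   the gamma distal anchor;
#' * ASIC and other non-ENaC outgroup sequences: trait values follow the
#'   study's explicit assignment -- all treated as marine, sites absent except
#'   ids listed in `asic_site2_present`;
#' * `tandem` is the conjunction of `site1` and `site2`;
#' * a site whose scan window (or C-terminal region, for PY) is missing from
#'   the available sequence is coded ambiguous (`NA`).
#'
#' @param aln a [protein_alignment()].
#' @param seq_map data frame with columns `id`, `species`, `subunit`
#'   (`alpha`, `beta`, `gamma`, `delta`, or an outgroup class such as `ASIC`
#'   or `ENaClike`) covering every sequence.
#' @param habitat data frame with columns `species`, `terrestrial`, `lungs`
#'   (0/1) covering every species in `seq_map`.
#' @param anchors anchor table from [map_anchor_columns()] containing
#'   `alpha_site1`, `alpha_site2`, `gamma_site1`, `gamma_site2_prostasin`.
#' @param asic_site2_present ids of outgroup sequences assigned a site-2
#'   polybasic tract.
#' @param window scan half-width in alignment columns.
#' @return a [trait_matrix()] with traits `site1`, `site2`, `tandem`, `PY`,
#'   `terrestrial`, `lungs`; attribute `hits` holds the per-anchor scan
#'   tables.
#' @export
build_trait_matrix_from_scan <- function(aln, seq_map, habitat, anchors,
                                         asic_site2_present = character(0),
                                         window = 5) {
  need <- c("alpha_site1", "alpha_site2", "gamma_site1",
            "gamma_site2_prostasin")
  if (!all(need %in% anchors$name))
    stop("anchors must include: ", paste(need, collapse = ", "))
  acol <- setNames(anchors$column, anchors$name)
  ids <- names(aln)
  m <- seq_map[match(ids, seq_map$id), ]
  if (anyNA(m$id)) stop("sequence(s) missing from seq_map: ",
                        paste(setdiff(ids, seq_map$id), collapse = ", "))
  h <- habitat[match(m$species, habitat$species), ]
  if (anyNA(h$species))
    stop("species missing from habitat table: ",
         paste(setdiff(m$species, habitat$species), collapse = ", "))

  scans <- list(
    alpha_site1 = find_polybasic_sites(aln, acol[["alpha_site1"]], "R_only",
                                       window, "alpha_site1"),
    alpha_site2 = find_polybasic_sites(aln, acol[["alpha_site2"]], "R_only",
                                       window, "alpha_site2"),
    gamma_site1 = find_polybasic_sites(aln, acol[["gamma_site1"]], "R_only",
                                       window, "gamma_site1"),
    gamma_site2 = find_polybasic_sites(aln, acol[["gamma_site2_prostasin"]],
                                       "R_or_K", window, "gamma_site2"),
    py = find_py_motif(aln)
  )

  site_value <- function(scan_row) {
    if (scan_row$region_missing) NA_integer_ else as.integer(scan_row$hit)
  }

  n <- length(ids)
  site1 <- site2 <- PY <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    sub <- m$subunit[i]
    if (sub %in% c("alpha", "delta")) {
      site1[i] <- site_value(scans$alpha_site1[i, ])
      site2[i] <- site_value(scans$alpha_site2[i, ])
    } else if (sub %in% c("beta", "gamma")) {
      site1[i] <- site_value(scans$gamma_site1[i, ])
      site2[i] <- site_value(scans$gamma_site2[i, ])
    } else {
      site1[i] <- 0L
      site2[i] <- as.integer(ids[i] %in% asic_site2_present)
    }
    PY[i] <- if (sub %in% c("alpha", "beta", "gamma", "delta")) {
      site_value(scans$py[i, ])
    } else 0L
  }
  outgroup <- !m$subunit %in% c("alpha", "beta", "gamma", "delta")
  terrestrial <- ifelse(outgroup, 0L, as.integer(h$terrestrial))
  lungs <- ifelse(outgroup, 0L, as.integer(h$lungs))
  tandem <- as.integer(site1 == 1L & site2 == 1L)

  out <- data.frame(site1 = site1, site2 = site2, tandem = tandem, PY = PY,
                    terrestrial = terrestrial, lungs = lungs)
  rownames(out) <- ids
  tm <- trait_matrix(out)
  attr(tm, "hits") <- scans
  tm
}
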