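#' ENaC study data: motif tables, habitat table, sequence map
#'
#' The per-species cleavage-site 4-mers and C-terminal PY-motif sequences of
#' the vertebrate ENaC subunit dataset, as published.  Encoding: the motif
#' string itself when a tract/motif is present in the aligned region, `"-"`
#' when the region is present but carries no motif, `"?"` when the relevant
#' region is missing from the available sequence.  Species with no sequence
#' for a subunit simply have no row (and no tree tip).
#'
#' @return `enac_site_motifs()`: data frame `species`, `subunit`, `site1`,
#'   `site2` (proximal and distal cleavage-site 4-mers).
#' @export
enac_site_motifs <- function() {
  rows <- function(subunit, species, site1, site2)
    data.frame(species = species, subunit = subunit, site1 = site1,
               site2 = site2, stringsAsFactors = FALSE)
  rbind(
    rows("alpha",
         c("S.Lamprey", "J.Lamprey", "E.Shark", "Ropefish", "Coelacanth",
           "W.Lungfish", "A.Lungfish", "Frog", "Salamander", "Turtle",
           "Chicken", "Cow", "Human"),
         c("-", "-", "?", "-", "RSNR", "-", "-", "RVKR", "RERR", "RSPR",
           "RTSR", "RSRR", "RSRR"),
         c("-", "-", "?", "-", "-", "-", "-", "RVSR", "RVRR", "RHKR",
           "RQKR", "RGVR", "RRAR")),
    rows("delta",
         c("Coelacanth", "Frog", "Turtle", "Chicken", "Cow", "Human"),
         c("-", "-", "-", "-", "-", "-"),
         c("-", "-", "-", "-", "RLQR", "RLQR")),
    rows("beta",
         c("S.Lamprey", "J.Lamprey", "E.Shark", "Ropefish", "Coelacanth",
           "W.Lungfish", "A.Lungfish", "Frog", "Turtle", "Chicken", "Cow",
           "Human"),
         c("-", "-", "-", "-", "KRER", "-", "-", "-", "-", "-", "-", "-"),
         c("-", "-", "-", "-", "-", "-", "-", "-", "-", "-", "-", "-")),
    rows("gamma",
         c("S.Lamprey", "J.Lamprey", "E.Shark", "Ropefish", "Coelacanth",
           "W.Lungfish", "A.Lungfish", "Frog", "Turtle", "Chicken", "Cow",
           "Human"),
         c("-", "-", "-", "RKRR", "-", "-", "RKLR", "RSKR", "KVRR", "KVRR",
           "RKRR", "RKRR"),
         c("-", "-", "RQHR", "NRKR", "VKQR", "-", "RQYR", "KRTR", "NKRK",
           "RKRK", "RKRK", "RKRK"))
  )
}

#' @rdname enac_site_motifs
#' @return `enac_py_motifs()`: data frame `species`, `subunit`, `py` (the
#'   printed C-terminal sequence; it counts as a PY motif only when it
#'   matches `L/P-P-X-Y`).
#' @export
enac_py_motifs <- function() {
  rows <- function(subunit, species, py)
    data.frame(species = species, subunit = subunit, py = py,
               stringsAsFactors = FALSE)
  rbind(
    rows("alpha",
         c("S.Lamprey", "J.Lamprey", "E.Shark", "Ropefish", "Coelacanth",
           "W.Lungfish", "A.Lungfish", "Frog", "Salamander", "Turtle",
           "Chicken", "Cow", "Human"),
         c("PPPSF", "PPDY", "?", "PPPAY", "PPAY", "PPPAY", "PPPAY", "PPPAY",
           "PPPAY", "LPSY", "LPSY", "PPPAY", "PPPAY")),
    rows("delta",
         c("Coelacanth", "Frog", "Turtle", "Chicken", "Cow", "Human"),
         c("?", "-", "-", "-", "-", "-")),
    rows("beta",
         c("S.Lamprey", "J.Lamprey", "E.Shark", "Ropefish", "Coelacanth",
           "W.Lungfish", "A.Lungfish", "Frog", "Turtle", "Chicken", "Cow",
           "Human"),
         c("PPPHY", "PPPHY", "PPPRY", "PPPHY", "PPPNY", "PPPHY", "PPPKY",
           "PPPNY", "PPPNY", "PPPNY", "PPPNY", "PPPNY")),
    rows("gamma",
         c("S.Lamprey", "J.Lamprey", "E.Shark", "Ropefish", "Coelacanth",
           "W.Lungfish", "A.Lungfish", "Frog", "Turtle", "Chicken", "Cow",
           "Human"),
         c("PPPQY", "PPPQY", "PPPNY", "PPPNY", "PPPTY", "PPPQY", "PPPQY",
           "PPPKY", "PPPNY", "PPPNY", "PPPRY", "PPPKY"))
  )
}

#' @rdname enac_site_motifs
#' @return `enac_species_habitat()`: data frame `species`, `terrestrial`,
#'   `lungs` (0/1).  Lungs are scored for the two lungfishes and the ropefish
#'   (which evolved lungs independently) as well as for all terrestrial
#'   vertebrates.
#' @export
enac_species_habitat <- function() {
  terrestrial <- c("Frog", "Salamander", "Turtle", "Chicken", "Cow", "Human")
  lunged <- c(terrestrial, "Ropefish", "W.Lungfish", "A.Lungfish")
  species <- c("S.Lamprey", "J.Lamprey", "E.Shark", "Ropefish", "Coelacanth",
               "W.Lungfish", "A.Lungfish", terrestrial,
               "J.Medaka", "Tunicate", "Lancelet")
  data.frame(species = species,
             terrestrial = as.integer(species %in% terrestrial),
             lungs = as.integer(species %in% lunged),
             stringsAsFactors = FALSE)
}

outgroup_ids <- function() {
  c("Human_ASIC1", "Coelacanth_ASIC1", "J.Medaka_ASIC1",
    "Human_ASIC2", "Coelacanth_ASIC2", "E.Shark_ASIC1",
    "J.Medaka_ENaClike1", "J.Medaka_ENaClike2",
    "Tunicate_ENaClike", "Lancelet_ENaClike")
}

#' @rdname enac_site_motifs
#' @return `enac_sequence_map()`: data frame `id`, `species`, `subunit`
#'   covering all 53 sequences (43 ENaC subunits plus 10 outgroup
#'   ASIC/ENaC-like sequences).
#' @export
enac_sequence_map <- function() {
  sm <- enac_site_motifs()
  enac <- data.frame(id = paste0(sm$species, "_", sm$subunit),
                     species = sm$species, subunit = sm$subunit,
                     stringsAsFactors = FALSE)
  og <- outgroup_ids()
  out <- data.frame(id = og,
                    species = sub("_.*$", "", og),
                    subunit = ifelse(grepl("ASIC", og), "ASIC", "ENaClike"),
                    stringsAsFactors = FALSE)
  rbind(enac, out)
}

matches_py <- function(x) !is.na(x) & grepl("[LP]P.Y", x)

#' Binary trait matrix of the ENaC dataset
#'
#' Trait coding derived directly from the published motif tables: `site1`,
#' `site2` (proximal/distal cleavage tract present), `tandem` (both present),
#' `PY` (C-terminal PY motif present), `terrestrial` and `lungs` (species
#' level).  Missing regions are coded ambiguous (`NA`).  Outgroup (ASIC and
#' ENaC-like) sequences follow the study's explicit assignment: all marine,
#' no cleavage sites except a site-2 tract in coelacanth ASIC2, and no PY
#' motif.
#'
#' @param include_outgroups include the 10 ASIC/ENaC-like rows.
#' @return a [trait_matrix()].
#' @export
enac_trait_table <- function(include_outgroups = TRUE) {
  sm <- enac_site_motifs()
  pm <- enac_py_motifs()
  hb <- enac_species_habitat()
  code_site <- function(x) ifelse(x == "?", NA_integer_,
                                  as.integer(x != "-"))
  id <- paste0(sm$species, "_", sm$subunit)
  py <- pm$py[match(paste0(sm$species, sm$subunit),
                    paste0(pm$species, pm$subunit))]
  site1 <- code_site(sm$site1)
  site2 <- code_site(sm$site2)
  out <- data.frame(
    site1 = site1, site2 = site2,
    tandem = as.integer(site1 == 1L & site2 == 1L),
    PY = ifelse(py == "?", NA_integer_, as.integer(matches_py(py))),
    terrestrial = hb$terrestrial[match(sm$species, hb$species)],
    lungs = hb$lungs[match(sm$species, hb$species)]
  )
  rownames(out) <- id
  if (include_outgroups) {
    og <- outgroup_ids()
    ogdf <- data.frame(site1 = 0L, site2 = as.integer(og == "Coelacanth_ASIC2"),
                       tandem = 0L, PY = 0L, terrestrial = 0L, lungs = 0L,
                       row.names = og)
    out <- rbind(out, ogdf)
  }
  trait_matrix(out)
}

# ---- synthetic stand-in phylogeny ------------------------------------------
# The published 53-sequence ML tree is distributed as a supplementary file and
# is not redistributable here; this is a synthetic stand-in with the topology
# the study describes (six clades; duplication nodes node1..node4; jawless
# fishes basal within each subunit clade) and branch lengths set from rough
# divergence-time reasoning at a protein-typical substitution rate.

enac_clade_rates <- c(alpha = 0.0013, delta = 0.0017, beta = 0.0011,
                      gamma = 0.0012, ASIC = 0.0009, ENaClike = 0.0016,
                      stem = 0.0012)

#' Synthetic stand-in phylogeny of the 53 ENaC-family sequences
#'
#' A rooted, 53-tip tree whose topology follows the study's description of
#' the ENaC gene family: an outgroup clade of ASIC and ENaC-like sequences,
#' and the four ENaC subunit clades arising from three gene duplications at
#' the labelled internal nodes `node1` (beta/gamma versus alpha/delta
#' ancestor), `node2` (beta/gamma duplication), `node3` (ancestral
#' alpha/delta clade) and `node4` (alpha/delta duplication, placed before the
#' coelacanth--tetrapod divergence).  Within each subunit clade, species
#' branch in the accepted vertebrate order with jawless fishes basal.
#'
#' Branch lengths are synthetic: divergence-time differences (in Myr) times a
#' per-clade amino-acid substitution rate.  This tree is a stand-in for the
#' published maximum-likelihood tree, which is only distributed as
#' supplementary material; analyses that depend on the exact published branch
#' lengths will differ quantitatively on this tree.
#'
#' @return an [ape::phylo] tree with node labels `node1`..`node4`.
#' @export
enac_tree_synthetic <- function() {
  tip <- function(name) list(tip = name)
  nd <- function(age, children, label = "") {
    list(age = age, children = children, label = label)
  }
  rate_of <- function(name) {
    suf <- sub("^.*_", "", name)
    if (grepl("^ASIC", suf)) return(enac_clade_rates[["ASIC"]])
    if (grepl("^ENaClike", suf)) return(enac_clade_rates[["ENaClike"]])
    r <- enac_clade_rates[suf]
    if (is.na(r)) enac_clade_rates[["stem"]] else unname(r)
  }
  # species subtree shared by the beta and gamma clades (no salamander)
  species_clade <- function(suffix, crown) {
    t <- function(sp) tip(paste0(sp, "_", suffix))
    nd(crown, list(
      nd(200, list(t("S.Lamprey"), t("J.Lamprey"))),
      nd(460, list(t("E.Shark"), nd(430, list(
        t("Ropefish"),
        nd(420, list(t("Coelacanth"), nd(410, list(
          nd(250, list(t("W.Lungfish"), t("A.Lungfish"))),
          nd(350, list(t("Frog"), nd(310, list(
            nd(260, list(t("Turtle"), t("Chicken"))),
            nd(95, list(t("Cow"), t("Human")))
          ))))
        ))))
      ))))
    ))
  }
  ta <- function(sp) tip(paste0(sp, "_alpha"))
  td <- function(sp) tip(paste0(sp, "_delta"))
  alpha_crown <- nd(420, list(
    ta("Coelacanth"),
    nd(410, list(
      nd(250, list(ta("W.Lungfish"), ta("A.Lungfish"))),
      nd(350, list(
        nd(290, list(ta("Frog"), ta("Salamander"))),
        nd(310, list(
          nd(260, list(ta("Turtle"), ta("Chicken"))),
          nd(95, list(ta("Cow"), ta("Human")))
        ))
      ))
    ))
  ))
  delta_clade <- nd(420, list(
    td("Coelacanth"),
    nd(350, list(td("Frog"), nd(310, list(
      nd(260, list(td("Turtle"), td("Chicken"))),
      nd(95, list(td("Cow"), td("Human")))
    ))))
  ))
  node4 <- nd(440, list(alpha_crown, delta_clade), label = "node4")
  node3 <- nd(560, list(
    nd(200, list(ta("S.Lamprey"), ta("J.Lamprey"))),
    nd(460, list(ta("E.Shark"), nd(450, list(ta("Ropefish"), node4))))
  ), label = "node3")
  node2 <- nd(580, list(species_clade("beta", 550),
                        species_clade("gamma", 550)), label = "node2")
  node1 <- nd(600, list(node2, node3), label = "node1")
  asic <- nd(500, list(
    nd(430, list(nd(420, list(tip("Human_ASIC1"), tip("Coelacanth_ASIC1"))),
                 tip("J.Medaka_ASIC1"))),
    nd(460, list(nd(420, list(tip("Human_ASIC2"), tip("Coelacanth_ASIC2"))),
                 tip("E.Shark_ASIC1")))
  ))
  enac_like <- nd(600, list(
    nd(300, list(tip("J.Medaka_ENaClike1"), tip("J.Medaka_ENaClike2"))),
    nd(550, list(tip("Tunicate_ENaClike"), tip("Lancelet_ENaClike")))
  ))
  outgroups <- nd(620, list(asic, enac_like))
  root <- nd(650, list(node1, outgroups))

  to_newick <- function(node, parent_age) {
    if (!is.null(node$tip)) {
      len <- parent_age * rate_of(node$tip)
      return(sprintf("%s:%.6f", node$tip, len))
    }
    kids <- vapply(node$children, to_newick, character(1),
                   parent_age = node$age)
    # stem rate: rate of the first descendant tip's clade
    first_tip <- function(n) if (!is.null(n$tip)) n$tip else
      first_tip(n$children[[1]])
    len <- (parent_age - node$age) * rate_of(first_tip(node))
    sprintf("(%s)%s:%.6f", paste(kids, collapse = ","), node$label, len)
  }
  kids <- vapply(root$children, to_newick, character(1),
                 parent_age = root$age)
  parse_newick(sprintf("(%s);", paste(kids, collapse = ",")))
}

# ---- synthetic alignment reconstruction ------------------------------------

#' Synthetic alignment reconstruction carrying the published motifs
#'
#' Builds an 80-column protein alignment for the 53 sequences in which the
#' published cleavage-site 4-mers sit at the anchored proximal (P1 = column
#' 20) and distal (P1 = column 45) columns and the published C-terminal
#' sequences end at the final column; regions recorded as missing are
#' rendered as gaps.  The background alphabet contains no basic residues and
#' no tyrosine, so the scanner's hits on this alignment are exactly the
#' published motifs.  The full-length supplementary alignment is not
#' redistributable; this reconstruction preserves precisely the features the
#' motif scanner consumes.
#'
#' @return a [protein_alignment()] of 53 sequences.
#' @export
enac_alignment_synthetic <- function() {
  n_col <- 80L
  p1_site1 <- 20L
  p1_site2 <- 45L
  tail_gap <- 12L
  background <- c("A", "D", "E", "F", "G", "H", "I", "L", "M", "N",
                  "P", "Q", "S", "T", "V", "W")
  bg <- function(row, col)  # deterministic, RNG-free background
    background[(row * 7L + col * 3L) %% length(background) + 1L]

  sm <- enac_site_motifs()
  pm <- enac_py_motifs()
  map <- enac_sequence_map()
  seqs <- character(nrow(map))
  for (i in seq_len(nrow(map))) {
    ch <- vapply(seq_len(n_col), function(j) bg(i, j), character(1))
    si <- match(paste0(map$species[i], map$subunit[i]),
                paste0(sm$species, sm$subunit))
    place <- function(ch, motif, p1) {
      if (is.na(motif) || motif == "-") return(ch)
      if (motif == "?") {  # region missing: gap out the whole scan window
        ch[(p1 - 9L):(p1 + 9L)] <- "-"
        return(ch)
      }
      k <- nchar(motif)
      ch[(p1 - k + 1L):p1] <- strsplit(motif, "")[[1]]
      ch
    }
    if (!is.na(si)) {
      ch <- place(ch, sm$site1[si], p1_site1)
      ch <- place(ch, sm$site2[si], p1_site2)
      pyi <- match(paste0(map$species[i], map$subunit[i]),
                   paste0(pm$species, pm$subunit))
      py <- pm$py[pyi]
      if (py == "?") {
        ch[(n_col - tail_gap + 1L):n_col] <- "-"
      } else if (py != "-") {
        k <- nchar(py)
        ch[(n_col - k + 1L):n_col] <- strsplit(py, "")[[1]]
      }
    } else if (map$id[i] == "Coelacanth_ASIC2") {
      ch <- place(ch, "RTKR", p1_site2)  # the site-2 tract noted for ASIC2
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  protein_alignment(setNames(seqs, map$id))
}

#' Cleavage-site anchors for the synthetic alignment
#'
#' @param aln the alignment the anchors refer to (default the synthetic
#'   reconstruction, whose human reference rows are gap-free with site P1
#'   residues at ungapped positions 20 and 45).
#' @return an anchor table as returned by [map_anchor_columns()].
#' @export
enac_anchors <- function(aln = enac_alignment_synthetic()) {
  rbind(
    map_anchor_columns(aln, "Human_alpha",
                       c(alpha_site1 = 20L, alpha_site2 = 45L)),
    map_anchor_columns(aln, "Human_gamma",
                       c(gamma_site1 = 20L, gamma_site2_prostasin = 45L))
  )
}
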