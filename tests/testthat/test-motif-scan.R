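test_that("anchor mapping converts ungapped positions to columns", {
  aln <- protein_alignment(c(ref = "MARSRRAT", other = "MA--RRAT"))
  a <- map_anchor_columns(aln, "ref", c(s1 = 6L))
  expect_equal(a$column, 6L)
  expect_equal(a$p1_residue, "R")

  aln2 <- protein_alignment(c(ref = "---MARSRRAT", other = "MAAAARRRATT"))
  a2 <- map_anchor_columns(aln2, "ref", c(s1 = 6L))
  expect_equal(a2$column, 9L)  # 3 leading gaps shift the column

  expect_error(map_anchor_columns(aln, "ref", c(s1 = 99L)), "out of range")
  expect_error(map_anchor_columns(aln, "nope", c(s1 = 1L)), "reference id")
})

test_that("polybasic scan finds the published tract classes", {
  # anchor P1 at column 20; motifs implanted ending at P1 columns
  aln <- make_alignment_fixture(
    c("human_g1", "human_g2", "lungfish", "mutant", "glycines"),
    n_col = 40,
    implants = data.frame(
      id = c("human_g1", "human_g2", "lungfish", "mutant"),
      motif = c("RKRR", "RKRK", "RQYR", "AKLA"),
      column = c(17L, 17L, 14L, 17L)),
    gap_frac = 0, seed = 5)
  aln <- protein_alignment(sub("^....", "GGGG",
                               setNames(unclass(aln), names(aln))))
  fur <- find_polybasic_sites(aln, 20, "R_only")
  expect_true(fur[fur$id == "human_g1", "hit"])
  expect_equal(fur[fur$id == "human_g1", "motif"], "RKRR")
  expect_equal(fur[fur$id == "human_g1", "class"], "furin_ideal")
  # RQYR 3 columns from the anchor is inside the +/-5 window
  expect_equal(fur[fur$id == "lungfish", "motif"], "RQYR")
  expect_equal(fur[fur$id == "lungfish", "class"], "polybasic_R")
  # terminal Ala disqualifies; basic-free background has nothing
  expect_false(fur[fur$id == "mutant", "hit"])
  expect_false(fur[fur$id == "glycines", "hit"])
  # RKRK ends in Lys: under the furin rule only its embedded ...RKR 4-mer
  # (one column short of the anchor) qualifies; the prostasin rule takes the
  # full tract at the anchor
  expect_match(fur[fur$id == "human_g2", "motif"], "RKR$")
  expect_equal(fur[fur$id == "human_g2", "p1_column"], 19L)
  pro <- find_polybasic_sites(aln, 20, "R_or_K")
  expect_equal(pro[pro$id == "human_g2", "motif"], "RKRK")
  expect_equal(pro[pro$id == "human_g2", "p1_column"], 20L)
})

test_that("window contract: implants at +/-5 detected, +/-8 not", {
  for (off in c(-8L, -5L, 0L, 5L, 8L)) {
    aln <- make_alignment_fixture("s", n_col = 60,
                                  implants = data.frame(id = "s",
                                                        motif = "RKRR",
                                                        column = 27L + off),
                                  gap_frac = 0, seed = 2)
    sc <- find_polybasic_sites(aln, 30, "R_only")
    expect_identical(sc$hit, abs(off) <= 5L,
                     label = sprintf("offset %d", off))
  }
})

test_that("scan is invariant to all-gap columns outside the window", {
  aln <- make_alignment_fixture(c("a", "b"), n_col = 40,
                                implants = data.frame(id = "a",
                                                      motif = "RRSR",
                                                      column = 17L),
                                gap_frac = 0, seed = 3)
  base <- find_polybasic_sites(aln, 20, "R_only")
  padded <- protein_alignment(vapply(unclass(aln), function(s)
    paste0("-----", s), character(1)))
  shifted <- find_polybasic_sites(padded, 25, "R_only")
  expect_equal(shifted$hit, base$hit)
  expect_equal(shifted$motif, base$motif)
  expect_equal(shifted$p1_column, base$p1_column + 5L)
})

test_that("scanner has perfect precision and recall on implanted fixtures", {
  set.seed(42)
  ids <- sprintf("seq%02d", 1:30)
  with_motif <- sample(ids, 15)
  aln <- make_alignment_fixture(
    ids, n_col = 60,
    implants = data.frame(id = with_motif, motif = "RKSR", column = 27L),
    gap_frac = 0.05, seed = 9)
  sc <- find_polybasic_sites(aln, 30, "R_only")
  called <- sc$id[sc$hit]
  expect_setequal(called, with_motif)  # recall and precision both 1
})

test_that("PY motif scan matches the published C-terminal calls", {
  seqs <- c(human_a = "GGGGSSSSPPPAY", lamprey_a = "GGGGSSSSPPPSF",
            lamprey_j = "GGGGSSSSSPPDY", turtle_a = "GGGGSSSSSLPSY")
  py <- find_py_motif(seqs)
  expect_equal(py[py$id == "human_a", "motif"], "PPAY")
  expect_false(py[py$id == "lamprey_a", "hit"])
  expect_equal(py[py$id == "lamprey_j", "motif"], "PPDY")
  expect_equal(py[py$id == "turtle_a", "motif"], "LPSY")
  # empty sequence region
  empty <- find_py_motif(protein_alignment(c(x = "----", y = "PPAY")))
  expect_true(empty[empty$id == "x", "region_missing"])
  # search region bound: a PY-like 4-mer far from the C-terminus is ignored
  far <- find_py_motif(c(z = paste0("LPAY", strrep("G", 30))))
  expect_false(far$hit)
})

test_that("trait matrix from the synthetic alignment equals the table coding", {
  aln <- enac_alignment_synthetic()
  tm <- build_trait_matrix_from_scan(aln, enac_sequence_map(),
                                     enac_species_habitat(),
                                     enac_anchors(aln),
                                     asic_site2_present = "Coelacanth_ASIC2")
  ref <- enac_trait_table()
  expect_equal(as.data.frame(tm[rownames(ref), ]), as.data.frame(ref),
               ignore_attr = TRUE)
  # spot checks straight from the published tables
  expect_equal(unlist(tm["Frog_gamma", c("site1", "site2", "tandem")],
                      use.names = FALSE), c(1L, 1L, 1L))
  expect_equal(unlist(tm["W.Lungfish_gamma", c("site1", "site2", "tandem")],
                      use.names = FALSE), c(0L, 0L, 0L))
  expect_true(all(is.na(tm["E.Shark_alpha", c("site1", "site2", "PY")])))
  expect_equal(tm["Coelacanth_ASIC2", "site2"], 1L)
  expect_equal(sum(tm[grepl("ASIC|ENaClike", rownames(tm)), "site2"]), 1L)
})

test_that("missing habitat or map entries raise errors naming the gap", {
  aln <- enac_alignment_synthetic()
  map <- enac_sequence_map()
  expect_error(build_trait_matrix_from_scan(aln, map[-1, ],
                                            enac_species_habitat(),
                                            enac_anchors(aln)),
               "missing from seq_map")
  hab <- enac_species_habitat()
  expect_error(build_trait_matrix_from_scan(aln, map,
                                            hab[hab$species != "Human", ],
                                            enac_anchors(aln)),
               "Human")
})
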