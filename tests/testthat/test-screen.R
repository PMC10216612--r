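# Ordered screening rule, extension detection and group classification.

test_that("a canonical GG..QxVxG..PW arrangement passes with all three hits", {
  ann <- screen_protein(demo_positive())
  expect_true(ann$pass)
  expect_equal(ann$hit_gg$start, 6)
  expect_equal(ann$hit_central$start, 50)
  expect_equal(ann$hit_cw$start, 80)
  expect_equal(ann$central_variant, "QVVSG")
  expect_equal(ann$cw_variant, "PW")
  expect_true(ann$hit_gg$start < ann$hit_central$start)
  expect_true(ann$hit_central$start < ann$hit_cw$start)
})

test_that("rejection reasons are specific", {
  # central loop knocked out at a fixed position (V -> A at pattern pos 3)
  ann <- screen_protein(sub("QVVSG", "QVASG", demo_positive()))
  expect_false(ann$pass)
  expect_equal(ann$reason, "missing_central")

  ann <- screen_protein(sub("GG", "GA", demo_positive()))
  expect_equal(ann$reason, "missing_gg")

  ann <- screen_protein(sub("PW", "PV", demo_positive()))
  expect_equal(ann$reason, "missing_cw")

  # central loop present only upstream of the GG
  shuffled <- paste0("M", "QVVSG", "ACDEF", "GG",
                     strrep("ACDEFHIKLMRSTV", 6), "PV", "ACDEF")
  ann <- screen_protein(shuffled)
  expect_equal(ann$reason, "order_violation")

  # spacing out of window
  ann <- screen_protein(paste0("M", "ACDEF", "GG", strrep("ACDEFHIKLMRSTV", 9),
                               "QVVSG", strrep("ACDEF", 5), "PW", "ACDEF"))
  expect_equal(ann$reason, "window_violation")

  ann <- screen_protein("MACDEFGG")
  expect_equal(ann$reason, "too_short")
})

test_that("the C-terminal motif may relax P-W to A-W", {
  ann <- screen_protein(demo_positive(cw = "AW"))
  expect_true(ann$pass)
  expect_equal(ann$cw_variant, "AW")
})

test_that("the signal-peptide end shifts the GG anchor", {
  # a GG inside a 60-residue signal peptide leaves the central loop > 90
  # residues downstream, breaking the spacing window unless it is skipped
  sp <- paste0("MGG", strrep("ACDEFHIKLMRSTV", 4), "A")     # 60 residues
  seqs <- paste0(sp, substring(demo_positive(), 2))
  ann0 <- screen_protein(seqs)
  expect_false(ann0$pass)
  expect_equal(ann0$reason, "window_violation")
  ann <- screen_protein(seqs, signal_peptide_end = 10)
  expect_true(ann$pass)
  expect_equal(ann$hit_gg$start, 65)
})

test_that("extension detection uses the inclusive tail threshold or SNSL", {
  cfg <- screen_config()
  short_tail <- demo_positive(tail = strrep("A", 8))
  ann <- detect_extension(short_tail, screen_protein(short_tail, cfg), cfg)
  expect_false(ann$has_cterm_extension)

  exact_tail <- demo_positive(tail = strrep("A", 50))
  ann <- detect_extension(exact_tail, screen_protein(exact_tail, cfg), cfg)
  expect_true(ann$has_cterm_extension)

  snsl_tail <- demo_positive(tail = paste0(strrep("A", 60), "SNSL", strrep("A", 5)))
  ann <- detect_extension(snsl_tail, screen_protein(snsl_tail, cfg), cfg)
  expect_true(ann$has_cterm_extension)
  expect_false(is.null(ann$hit_snsl))
  expect_true(ann$hit_snsl$start >= ann$hit_cw$end)
})

test_that("group classification follows the helix signatures and extension", {
  cfg <- screen_config()
  classify <- function(aa) {
    ann <- screen_protein(aa, cfg)
    ann <- detect_extension(aa, ann, cfg)
    classify_group(aa, ann, cfg)$group
  }
  a_seq <- demo_positive()  # LARFAVDEHN helix
  expect_equal(classify(a_seq), "A")
  c_seq <- sub("LARFAVDEHN", "IGEFAVDAYN", demo_positive())
  expect_equal(classify(c_seq), "C")
  b_seq <- sub("LARFAVDEHN", "IGRFAVEEHN", demo_positive())
  expect_equal(classify(b_seq), "B")
  # extension alone places a protein in group A even without the A helix
  ext_b <- sub("LARFAVDEHN", "IGRFAVEEHN",
               demo_positive(tail = strrep("A", 55)))
  expect_equal(classify(ext_b), "A")
  # no recognisable helix at all
  none <- sub("LARFAVDEHN", "ACDEFHIKLM", demo_positive())
  expect_equal(classify(none), "unclassified")
})

test_that("the group-B example matches the consensus but neither signature", {
  cons <- compile_pattern("[LVI]-[AGT]-[RKE]-[FY]-[AS]-[VI]-X-[EDQV]-[HYFQ]-N")
  a_sig <- compile_pattern("L-A-R-F-A-V-[DEQ]-E-H-N")
  c_sig <- compile_pattern("I-G-E-F-A-V-D-[EA]-Y-N")
  expect_equal(nrow(scan_motif("IGRFAVEEHN", cons)), 1)
  expect_equal(nrow(scan_motif("IGRFAVEEHN", a_sig)), 0)
  expect_equal(nrow(scan_motif("IGRFAVEEHN", c_sig)), 0)
})

test_that("screen_proteins deduplicates exact sequences and tabulates", {
  prots <- list(protein_record("p1", demo_positive()),
                protein_record("p2", demo_positive()),
                protein_record("p3", sub("GG", "GA", demo_positive())))
  tab <- screen_proteins(prots)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$pass, c(TRUE, FALSE))
  expect_equal(tab$reason[2], "missing_gg")
  expect_false(is.na(tab$mw_da[1]))
  expect_false(is.na(tab$pi[1]))
})
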