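# Seeded generators: determinism, bookkeeping and planted-truth recovery.

test_that("make_transcriptome bookkeeping matches the requested mix", {
  sim <- make_transcriptome(3, n_noise = 10, n_planted = 20,
                            group_mix = c(A = 7, B = 6, C = 7),
                            decoy_spec = c(central_knockout = 2, shuffle = 2))
  expect_equal(sum(sim$truth$class == "cystatin"), 20)
  expect_equal(as.integer(table(sim$truth$group)[c("A", "B", "C")]),
               c(7L, 6L, 7L))
  expect_equal(sum(sim$truth$class == "decoy"), 4)
  expect_equal(sum(sim$truth$class == "noise"), 10)
  expect_equal(length(sim$contigs), nrow(sim$truth))
  expect_setequal(vapply(sim$contigs, `[[`, "", "id"), sim$truth$id)
})

test_that("generators are pure functions of seed and parameters", {
  a <- make_transcriptome(5, n_noise = 5, n_planted = 4,
                          group_mix = c(A = 2, B = 1, C = 1),
                          decoy_spec = c(shuffle = 2))
  b <- make_transcriptome(5, n_noise = 5, n_planted = 4,
                          group_mix = c(A = 2, B = 1, C = 1),
                          decoy_spec = c(shuffle = 2))
  expect_identical(a, b)
  c1 <- simulate_inhibition_series(7, 10, assay_preset("papain"))
  c2 <- simulate_inhibition_series(7, 10, assay_preset("papain"))
  expect_identical(c1, c2)
  e1 <- simulate_erosion_experiment(7, erosion_reference("enamel"), 3)
  e2 <- simulate_erosion_experiment(7, erosion_reference("enamel"), 3)
  expect_identical(e1, e2)
  # FASTA bytes identical on repeat
  d1 <- withr::local_tempfile(); d2 <- withr::local_tempfile()
  write_fasta(a$contigs, d1); write_fasta(b$contigs, d2)
  expect_identical(readLines(d1), readLines(d2))
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(99)
  x1 <- runif(1)
  set.seed(99)
  invisible(make_transcriptome(5, n_noise = 2, n_planted = 2,
                               group_mix = c(A = 1, B = 1, C = 0),
                               decoy_spec = c(shuffle = 1)))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("planted proteins screen positive with their planted labels; decoys fail", {
  sim <- make_transcriptome(13, n_noise = 0, n_planted = 12,
                            group_mix = c(A = 4, B = 4, C = 4),
                            decoy_spec = c(central_knockout = 3, gg_knockout = 3,
                                           cw_knockout = 3, order_violation = 2,
                                           window_violation = 2, shuffle = 3))
  cfg <- screen_config()
  for (r in seq_len(nrow(sim$truth))) {
    aa <- sim$truth$protein[r]
    ann <- screen_protein(aa, cfg)
    if (sim$truth$class[r] == "cystatin") {
      expect_true(ann$pass, info = sim$truth$id[r])
      ann <- classify_group(aa, detect_extension(aa, ann, cfg), cfg)
      expect_equal(ann$group, sim$truth$group[r], info = sim$truth$id[r])
    } else {
      expect_false(ann$pass, info = sim$truth$id[r])
    }
  }
})

test_that("planted contigs carry the planted peptide in some reading frame", {
  sim <- make_transcriptome(17, n_noise = 0, n_planted = 4,
                            group_mix = c(A = 2, B = 1, C = 1),
                            decoy_spec = c(shuffle = 0))
  res <- screen_transcriptome(sim$contigs)
  found <- res$orfs$aa_seq
  for (r in which(sim$truth$class == "cystatin")) {
    expect_true(sim$truth$protein[r] %in% found, info = sim$truth$id[r])
  }
})

test_that("noiseless inhibition series satisfy the competitive model exactly", {
  setup <- assay_preset("cathepsin_B")
  sim <- simulate_inhibition_series(11, 21.94, setup, cv = 0)
  expect_equal(sim$truth$kiapp_nM, 21.94 * (1 + 20 / 23))
  for (rep in sim$series$replicates) {
    expect_equal(rep$vi, rep$v0 / (1 + rep$conc_nM / sim$truth$kiapp_nM),
                 tolerance = 1e-12)
  }
  expect_error(simulate_inhibition_series(1, 10, setup, cv = -0.1), "cv")
  expect_error(simulate_inhibition_series(1, -1, setup))
})

test_that("zero-SD erosion groups plant their means exactly", {
  params <- data.frame(group = c("u", "v"), mean = c(30, 5), sd = c(0, 0))
  sim <- simulate_erosion_experiment(23, params, n_per_group = 4)
  smc <- sample_smc(sim$experiment)
  expect_equal(smc$smc[smc$group == "u"], rep(30, 4), tolerance = 1e-9)
  expect_equal(smc$smc[smc$group == "v"], rep(5, 4), tolerance = 1e-9)
  expect_error(simulate_erosion_experiment(1, transform(params, sd = -1), 4))
})

test_that("the seven-group design reproduces its planted summary statistics", {
  ref <- erosion_reference("enamel")
  sim <- simulate_erosion_experiment(29, ref, n_per_group = 20)
  expect_equal(nrow(sim$truth), 140)
  smc <- sample_smc(sim$experiment)
  obs <- vapply(split(smc$smc, smc$group), mean, 0)
  for (gi in seq_len(nrow(ref))) {
    se <- ref$sd[gi] / sqrt(20)
    expect_lt(abs(obs[[ref$group[gi]]] - ref$mean[gi]), 4 * se)
  }
  # per-sample %SMC equals the planted per-sample truth
  m <- merge(smc, sim$truth, by = "sample_id")
  expect_equal(m$smc, m$planted_smc, tolerance = 1e-9)
})

test_that("generator output passes its consumer's input validation", {
  sim <- make_transcriptome(31, n_noise = 3, n_planted = 2,
                            group_mix = c(A = 1, B = 1, C = 0),
                            decoy_spec = c(shuffle = 1))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(sim$contigs, path)
  expect_silent(read_fasta(path, type = "DNA"))
  er <- simulate_erosion_experiment(31, erosion_reference("dentin"), 3,
                                    tissue = "dentin")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(er$experiment, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_silent(read_indentation_table(p2))
})
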