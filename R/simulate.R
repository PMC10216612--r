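# Seeded generators producing inputs with known (planted) truth for every
# pipeline stage. All generators are pure functions of (seed, parameters):
# the same call reproduces identical output, and no global RNG state leaks.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Filler alphabet for scaffold spacers: the 20 residues minus G, N, Q, W so
# spacer text can never create a spurious GG, QxVxG, [PA]W, SNSL or helix
# consensus (every consensus/signature ends in N).
FILLER_AA <- setdiff(AA_ALPHABET, c("G", "N", "Q", "W"))

rand_aa <- function(n) paste(sample(FILLER_AA, n, replace = TRUE), collapse = "")
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# codon list per amino acid, standard code
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# Uniform-synonymous-codon reverse translation (no codon-usage model; the
# screen operates on translated peptides, so usage bias is irrelevant here).
reverse_translate <- function(aa_seq, codons = codons_by_aa()) {
  chars <- strsplit(aa_seq, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(a) {
    cs <- codons[[a]]
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, ""), collapse = "")
}

# One phytocystatin scaffold for a planted group. Motif layout (residues):
# M + 5 filler + GG + 12 filler + helix(10) + 20 filler + QxVxG + 25 filler +
# [PA]W + tail. Gaps: GG end -> central start = 42 (window 25-90), central
# end -> cw start = 25 (window 15-70).
cystatin_scaffold <- function(group, extended = FALSE, cw = "PW") {
  helix <- switch(group,
    A = paste0("LARFAV", sample(c("D", "E", "Q"), 1), "EHN"),
    C = paste0("IGEFAVD", sample(c("E", "A"), 1), "YN"),
    B = {
      sets <- list(c("L", "V", "I"), c("A", "G", "T"), c("R", "K", "E"),
                   c("F", "Y"), c("A", "S"), c("V", "I"), FILLER_AA,
                   c("E", "D", "Q", "V"), c("H", "Y", "F", "Q"), "N")
      repeat {
        h <- paste(vapply(sets, function(s) sample(s, 1), ""), collapse = "")
        if (!grepl("^LARFAV[DEQ]EHN$", h) && !grepl("^IGEFAVD[EA]YN$", h)) break
      }
      h
    })
  central <- if (extended) "QVVAG" else "QVVSG"
  tail <- if (extended) {
    paste0(rand_aa(25), "SNSL", rand_aa(31))  # SNSL inside a >=50-residue tail
  } else {
    rand_aa(10)
  }
  paste0("M", rand_aa(5), "GG", rand_aa(12), helix, rand_aa(20),
         central, rand_aa(25), cw, tail)
}

# Decoy proteins derived from a scaffold; each type knocks out exactly one
# property of the screen so rejection reasons are interpretable.
decoy_protein <- function(type, config) {
  base <- cystatin_scaffold(sample(c("A", "B", "C"), 1))
  switch(type,
    central_knockout = sub("QVV([AS])G", "QVA\\1G", base),
    gg_knockout = sub("GG", "GA", base),
    cw_knockout = sub("([PA])W", "\\1V", base),
    order_violation = paste0("M", rand_aa(3), "QVVSG", rand_aa(10), "GG",
                             rand_aa(40), "PV", rand_aa(30)),
    window_violation = paste0("M", rand_aa(5), "GG", rand_aa(120), "QVVSG",
                              rand_aa(25), "PW", rand_aa(10)),
    shuffle = {
      chars <- strsplit(substring(base, 2), "", fixed = TRUE)[[1]]
      for (i in 1:100) {
        cand <- paste0("M", paste(sample(chars), collapse = ""))
        if (!screen_protein(cand, config)$pass) return(cand)
      }
      stop("could not produce a failing shuffled decoy")
    })
}

#' Generate a synthetic transcriptome with planted cystatins and decoys
#'
#' Planted cystatins are built from group-specific scaffolds (group A with
#' the LARFAV-[DEQ]-EHN helix, a share of them carrying an SNSL-bearing
#' C-terminal extension; group C with IGEFAVD-[EA]-YN; group B matching the
#' general helix consensus only), reverse-translated with uniform synonymous
#' codons, and embedded between random UTRs on a random strand, with an
#' in-frame stop immediately upstream of the start codon. Decoys cycle
#' through a fixed taxonomy (central-motif knockout, GG knockout, C-terminal
#' knockout, order violation, window violation, shuffled positive); noise
#' contigs are random DNA.
#'
#' @param seed Integer seed.
#' @param n_noise Number of random-DNA contigs.
#' @param n_planted Number of planted cystatin contigs.
#' @param group_mix Named integer vector over `c(A=, B=, C=)` summing to
#'   `n_planted`.
#' @param decoy_spec Named integer vector over the decoy types.
#' @param config [screen_config()] used to verify shuffled decoys fail.
#' @return List with `contigs` (list of [contig()]) and `truth` (data.frame:
#'   `id`, `class` = cystatin/decoy/noise, `group`, `decoy_type`, `extended`,
#'   `protein`).
#' @export
make_transcriptome <- function(seed, n_noise = 430, n_planted = 20,
                               group_mix = NULL,
                               decoy_spec = c(central_knockout = 10,
                                              gg_knockout = 10,
                                              cw_knockout = 10,
                                              order_violation = 5,
                                              window_violation = 5,
                                              shuffle = 10),
                               config = screen_config()) {
  if (is.null(group_mix)) {
    # near-even A/B/C split (A gets any remainder first, matching the
    # 7/6/7 mix at the default 20)
    base <- n_planted %/% 3
    extra <- n_planted %% 3
    group_mix <- c(A = base + (extra >= 1), B = base, C = base + (extra >= 2))
  }
  stopifnot(n_noise >= 0, n_planted >= 0, sum(group_mix) == n_planted)
  with_seed(seed, {
    codons <- codons_by_aa()
    truth <- list()
    contigs <- list()
    embed <- function(aa) {
      dna <- reverse_translate(aa, codons)
      stop_codon <- sample(c("TAA", "TAG", "TGA"), 1)
      utr5 <- paste0(rand_dna(sample(30:60, 1)), "TAA")  # in-frame upstream stop
      utr3 <- rand_dna(sample(20:50, 1))
      full <- paste0(utr5, dna, stop_codon, utr3)
      if (stats::runif(1) < 0.5) reverse_complement(full) else full
    }
    idx <- 1L
    for (g in names(group_mix)) {
      for (i in seq_len(group_mix[[g]])) {
        extended <- g == "A" && i %% 2 == 1  # part of group A is SNSL-extended
        cw <- if (stats::runif(1) < 0.15) "AW" else "PW"
        aa <- cystatin_scaffold(g, extended = extended, cw = cw)
        id <- sprintf("planted_%s_%02d", g, i)
        contigs[[idx]] <- contig(id, embed(aa))
        truth[[idx]] <- data.frame(id = id, class = "cystatin", group = g,
                                   decoy_type = NA_character_,
                                   extended = extended, protein = aa,
                                   stringsAsFactors = FALSE)
        idx <- idx + 1L
      }
    }
    for (ty in names(decoy_spec)) {
      for (i in seq_len(decoy_spec[[ty]])) {
        aa <- decoy_protein(ty, config)
        id <- sprintf("decoy_%s_%02d", ty, i)
        contigs[[idx]] <- contig(id, embed(aa))
        truth[[idx]] <- data.frame(id = id, class = "decoy",
                                   group = NA_character_, decoy_type = ty,
                                   extended = NA, protein = aa,
                                   stringsAsFactors = FALSE)
        idx <- idx + 1L
      }
    }
    for (i in seq_len(n_noise)) {
      id <- sprintf("noise_%04d", i)
      contigs[[idx]] <- contig(id, rand_dna(sample(300:600, 1)))
      truth[[idx]] <- data.frame(id = id, class = "noise",
                                 group = NA_character_,
                                 decoy_type = NA_character_, extended = NA,
                                 protein = NA_character_,
                                 stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
    list(contigs = contigs, truth = do.call(rbind, truth))
  })
}

#' Simulate an inhibitor-titration slope series
#'
#' Slopes follow Vi = V0 / (1 + [I]/Kiapp) with Kiapp = Ki (1 + [S]/Km);
#' multiplicative Gaussian noise with coefficient of variation `cv` is applied
#' to every slope, and each replicate's V0 is drawn around a nominal slope.
#'
#' @param seed Integer seed.
#' @param true_ki_nM Planted Ki, nM (> 0).
#' @param setup An [assay_setup()].
#' @param inhibitor_concs_nM Inhibitor concentrations, nM; defaults to six
#'   points spanning 0.3-10 x Kiapp.
#' @param cv Coefficient of variation of the multiplicative slope noise.
#' @param n_replicates Number of replicates (triplicate by default).
#' @param nominal_v0 Nominal uninhibited slope (fluorescence/min).
#' @return List with `series` (an [inhibition_series()]) and `truth`
#'   (planted Ki and Kiapp).
#' @export
simulate_inhibition_series <- function(seed, true_ki_nM, setup,
                                       inhibitor_concs_nM = NULL,
                                       cv = 0.02, n_replicates = 3,
                                       nominal_v0 = 1000) {
  stopifnot(true_ki_nM > 0)
  if (cv < 0) stop("cv must be non-negative")
  kiapp <- true_ki_nM * (1 + setup$s_uM / setup$km_uM)
  if (is.null(inhibitor_concs_nM)) {
    inhibitor_concs_nM <- kiapp * c(0.3, 0.75, 1.5, 3, 6, 10)
  }
  with_seed(seed, {
    reps <- lapply(seq_len(n_replicates), function(r) {
      noise <- function(n) 1 + cv * stats::rnorm(n)
      v0 <- nominal_v0 * noise(1)
      vi <- v0 / (1 + inhibitor_concs_nM / kiapp) * noise(length(inhibitor_concs_nM))
      inhibition_replicate(v0 = v0, conc_nM = inhibitor_concs_nM,
                           vi = pmax(vi, 1e-9))
    })
    list(series = inhibition_series(setup, reps),
         truth = data.frame(true_ki_nM = true_ki_nM, kiapp_nM = kiapp,
                            cv = cv, n_replicates = n_replicates))
  })
}

#' Simulate a microhardness erosion experiment
#'
#' Baseline readings are drawn around a tissue-typical Knoop hardness; each
#' sample's target %SMC is drawn from its group's planted Normal(mean, SD),
#' indentation-level noise is added to the final readings, and the final
#' readings are then renormalised so the per-sample %SMC equals its target
#' exactly (so SD = 0 plants the group mean exactly).
#'
#' @param seed Integer seed.
#' @param group_params data.frame with `group`, `mean`, `sd` (per-group %SMC),
#'   e.g. [erosion_reference()].
#' @param n_per_group Samples per group (>= 2).
#' @param n_indent Indentations per sample (six by design).
#' @param tissue `"enamel"` or `"dentin"` (sets the baseline hardness scale:
#'   Knoop ~ 330 for enamel, ~ 55 for dentin).
#' @return List with `experiment` (long-format indentation data.frame) and
#'   `truth` (per-sample planted %SMC plus the group parameters).
#' @export
simulate_erosion_experiment <- function(seed, group_params, n_per_group = 20,
                                        n_indent = 6,
                                        tissue = c("enamel", "dentin")) {
  tissue <- match.arg(tissue)
  stopifnot(all(c("group", "mean", "sd") %in% names(group_params)),
            n_per_group >= 2, all(group_params$sd >= 0))
  mu_tissue <- if (tissue == "enamel") 330 else 55
  sd_between <- 0.05 * mu_tissue   # sample-to-sample baseline spread
  sd_indent <- 0.03 * mu_tissue    # indentation repeatability
  with_seed(seed, {
    rows <- list()
    truth <- list()
    k <- 1L
    for (gi in seq_len(nrow(group_params))) {
      g <- group_params$group[gi]
      for (si in seq_len(n_per_group)) {
        sid <- sprintf("%s_%s_s%02d", substr(tissue, 1, 3), gsub("\\s", "", g), si)
        smc <- stats::rnorm(1, group_params$mean[gi], group_params$sd[gi])
        smc <- min(smc, 99)
        mu_sample <- max(stats::rnorm(1, mu_tissue, sd_between), mu_tissue / 2)
        b <- abs(stats::rnorm(n_indent, mu_sample, sd_indent))
        target_final <- mean(b) * (1 - smc / 100)
        f <- abs(stats::rnorm(n_indent, target_final, sd_indent))
        f <- f * target_final / mean(f)  # per-sample %SMC exact
        rows[[k]] <- data.frame(sample_id = sid, tissue = tissue, group = g,
                                indent = seq_len(n_indent),
                                sm_baseline = b, sm_final = f,
                                stringsAsFactors = FALSE)
        truth[[k]] <- data.frame(sample_id = sid, group = g,
                                 planted_smc = smc,
                                 group_mean = group_params$mean[gi],
                                 group_sd = group_params$sd[gi],
                                 stringsAsFactors = FALSE)
        k <- k + 1L
      }
    }
    list(experiment = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}
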