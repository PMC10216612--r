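# Ordered screening rule for phytocystatins and group classification.
#
# A candidate passes when it carries, in order along the chain, the three
# motifs of the tripartite wedge: an N-terminal Gly-Gly dipeptide, the central
# Q-x-V-x-G loop within a spacing window downstream, and a C-terminal [PA]-W
# within a second window. The N-terminal helix consensus and the SNSL legumain
# motif are recorded as diagnostics but never required.

#' Screening configuration
#'
#' @param min_len Minimum protein length considered (residues).
#' @param central_window Allowed gap (residues) between the end of the GG
#'   dipeptide and the start of the central QxVxG loop.
#' @param cw_window Allowed gap between the end of the central loop and the
#'   start of the C-terminal [PA]-W motif.
#' @param min_tail Minimum number of residues after the [PA]-W motif for a
#'   C-terminal extension call (inclusive boundary).
#' @return A list of class `"screen_config"`, including the compiled patterns.
#' @export
screen_config <- function(min_len = 80,
                          central_window = c(25, 90),
                          cw_window = c(15, 70),
                          min_tail = 50) {
  structure(list(
    min_len = min_len,
    central_window = central_window,
    cw_window = cw_window,
    min_tail = min_tail,
    pat_gg = compile_pattern("G-G", "gg"),
    pat_central = compile_pattern("Q-x-V-x-G", "central"),
    pat_cw = compile_pattern("[PA]-W", "cw"),
    pat_helix = compile_pattern(
      "[LVI]-[AGT]-[RKE]-[FY]-[AS]-[VI]-x-[EDQV]-[HYFQ]-N", "consensus_helix"),
    pat_snsl = compile_pattern("S-N-S-L", "snsl"),
    pat_group_a = compile_pattern("L-A-R-F-A-V-[DEQ]-E-H-N", "group_a"),
    pat_group_c = compile_pattern("I-G-E-F-A-V-D-[EA]-Y-N", "group_c")
  ), class = "screen_config")
}

first_hit <- function(hits) if (nrow(hits)) hits[1, , drop = FALSE] else NULL

# Leftmost hit whose start falls in [lo, hi] residues after `after_end`.
hit_in_window <- function(hits, after_end, window) {
  if (!nrow(hits)) return(NULL)
  gap <- hits$start - after_end
  ok <- gap >= window[1] & gap <= window[2]
  if (!any(ok)) return(NULL)
  hits[which(ok)[1], , drop = FALSE]
}

#' Screen one protein for the phytocystatin motif architecture
#'
#' The first GG after the (optional, externally supplied) signal-peptide end
#' anchors the rule; ties among central/C-terminal candidates are broken by
#' the leftmost hit inside its window. Rejection is a value, not an error,
#' with reason one of `missing_gg`, `missing_central`, `missing_cw`,
#' `order_violation`, `window_violation`, `too_short`.
#'
#' @param prot A [protein_record()] or amino-acid string.
#' @param config A [screen_config()].
#' @param signal_peptide_end Optional 0-based index of the last signal-peptide
#'   residue boundary; the GG search starts there.
#' @return A list of class `"cystatin_annotation"` with `pass`, `reason`,
#'   the recorded hits, `central_variant`, `cw_variant`, and placeholders for
#'   extension/group/physchem fields filled by later steps.
#' @export
screen_protein <- function(prot, config = screen_config(),
                           signal_peptide_end = NULL) {
  if (is.character(prot)) prot <- protein_record("query", prot, source = "external")
  aa <- prot$aa_seq
  ann <- structure(list(
    protein_id = prot$id, pass = FALSE, reason = NA_character_,
    hit_gg = NULL, hit_central = NULL, hit_cw = NULL,
    hit_consensus_helix = NULL, hit_snsl = NULL,
    central_variant = NA_character_, cw_variant = NA_character_,
    has_cterm_extension = NA, group = NA_character_,
    mw_da = NA_real_, pi = NA_real_,
    signal_peptide_end = signal_peptide_end
  ), class = "cystatin_annotation")

  if (nchar(aa) < config$min_len) {
    ann$reason <- "too_short"
    return(ann)
  }
  origin <- if (is.null(signal_peptide_end)) 0L else as.integer(signal_peptide_end)

  gg <- scan_motif(prot, config$pat_gg)
  gg <- gg[gg$start >= origin, , drop = FALSE]
  if (!nrow(gg)) {
    ann$reason <- "missing_gg"
    return(ann)
  }
  ann$hit_gg <- gg[1, , drop = FALSE]

  central_all <- scan_motif(prot, config$pat_central)
  if (!nrow(central_all)) {
    ann$reason <- "missing_central"
    return(ann)
  }
  central_down <- central_all[central_all$start >= ann$hit_gg$end, , drop = FALSE]
  if (!nrow(central_down)) {
    ann$reason <- "order_violation"
    return(ann)
  }
  ann$hit_central <- hit_in_window(central_down, ann$hit_gg$end,
                                   config$central_window)
  if (is.null(ann$hit_central)) {
    ann$reason <- "window_violation"
    return(ann)
  }

  cw_all <- scan_motif(prot, config$pat_cw)
  if (!nrow(cw_all)) {
    ann$reason <- "missing_cw"
    return(ann)
  }
  cw_down <- cw_all[cw_all$start >= ann$hit_central$end, , drop = FALSE]
  if (!nrow(cw_down)) {
    ann$reason <- "order_violation"
    return(ann)
  }
  ann$hit_cw <- hit_in_window(cw_down, ann$hit_central$end, config$cw_window)
  if (is.null(ann$hit_cw)) {
    ann$reason <- "window_violation"
    return(ann)
  }

  ann$pass <- TRUE
  ann$central_variant <- ann$hit_central$matched_text
  ann$cw_variant <- paste0(substr(ann$hit_cw$matched_text, 1, 1), "W")
  ann$hit_consensus_helix <- first_hit(scan_motif(prot, config$pat_helix))
  ann$hit_snsl <- first_hit(scan_motif(prot, config$pat_snsl))
  ann
}

#' Detect a C-terminal cystatin-like extension
#'
#' The extension is called when at least `config$min_tail` residues follow the
#' C-terminal [PA]-W motif (boundary inclusive) or when an SNSL legumain
#' motif lies downstream of it.
#'
#' @param prot The screened [protein_record()] or string.
#' @param annotation A passing annotation from [screen_protein()].
#' @param config A [screen_config()].
#' @return The annotation with `has_cterm_extension` (and `hit_snsl`) set.
#' @export
detect_extension <- function(prot, annotation, config = screen_config()) {
  stopifnot(isTRUE(annotation$pass))
  aa <- if (is.character(prot)) prot else prot$aa_seq
  tail_len <- nchar(aa) - annotation$hit_cw$end
  snsl_after <- !is.null(annotation$hit_snsl) &&
    annotation$hit_snsl$start >= annotation$hit_cw$end
  annotation$has_cterm_extension <- tail_len >= config$min_tail || snsl_after
  annotation
}

#' Classify a screened phytocystatin into group A, B or C
#'
#' Group A: the helix region matches L-A-R-F-A-V-[DEQ]-E-H-N, or the protein
#' carries a C-terminal extension. Group C: the helix matches
#' I-G-E-F-A-V-D-[EA]-Y-N. Group B: the general phytocystatin helix consensus
#' matches but neither group signature does. Otherwise unclassified.
#'
#' @param prot The protein (record or string).
#' @param annotation A passing annotation (after [detect_extension()]).
#' @param config A [screen_config()].
#' @return The annotation with `group` set to `"A"`, `"B"`, `"C"` or
#'   `"unclassified"`.
#' @export
classify_group <- function(prot, annotation, config = screen_config()) {
  stopifnot(isTRUE(annotation$pass))
  aa <- if (is.character(prot)) prot else prot$aa_seq
  has_a <- nrow(scan_motif(aa, config$pat_group_a)) > 0
  has_c <- nrow(scan_motif(aa, config$pat_group_c)) > 0
  has_consensus <- nrow(scan_motif(aa, config$pat_helix)) > 0
  annotation$group <-
    if (has_a || isTRUE(annotation$has_cterm_extension)) "A"
    else if (has_c) "C"
    else if (has_consensus) "B"
    else "unclassified"
  annotation
}

#' Screen a set of proteins and tabulate annotations
#'
#' Runs [screen_protein()], [detect_extension()], [classify_group()] and
#' [physchem_properties()] over deduplicated (exact-sequence) proteins.
#'
#' @param proteins List of [protein_record()]s.
#' @param config A [screen_config()].
#' @param dedupe Drop later records with an identical sequence.
#' @return A data.frame, one row per protein, with pass/fail, reason, motif
#'   coordinates, variants, extension flag, group, `mw_da` and `pi`.
#' @export
screen_proteins <- function(proteins, config = screen_config(), dedupe = TRUE) {
  if (dedupe) {
    seqs <- vapply(proteins, `[[`, "", "aa_seq")
    proteins <- proteins[!duplicated(seqs)]
  }
  rows <- lapply(proteins, function(p) {
    ann <- screen_protein(p, config)
    if (ann$pass) {
      ann <- detect_extension(p, ann, config)
      ann <- classify_group(p, ann, config)
      if (!grepl("X", p$aa_seq, fixed = TRUE)) {
        pc <- physchem_properties(p)
        ann$mw_da <- pc[["mw_da"]]
        ann$pi <- pc[["pi"]]
      }
    }
    annotation_row(ann)
  })
  do.call(rbind, rows)
}

annotation_row <- function(ann) {
  coord <- function(h, what) {
    if (is.null(h)) NA_integer_ else as.integer(h[[what]])
  }
  data.frame(
    protein_id = ann$protein_id, pass = ann$pass, reason = ann$reason,
    gg_start = coord(ann$hit_gg, "start"),
    central_start = coord(ann$hit_central, "start"),
    cw_start = coord(ann$hit_cw, "start"),
    central_variant = ann$central_variant, cw_variant = ann$cw_variant,
    has_cterm_extension = if (is.na(ann$has_cterm_extension)) NA
                          else ann$has_cterm_extension,
    snsl = !is.null(ann$hit_snsl),
    group = ann$group, mw_da = ann$mw_da, pi = ann$pi,
    stringsAsFactors = FALSE)
}

empty_annotation_table <- function() {
  data.frame(protein_id = character(), pass = logical(), reason = character(),
             gg_start = integer(), central_start = integer(),
             cw_start = integer(), central_variant = character(),
             cw_variant = character(), has_cterm_extension = logical(),
             snsl = logical(), group = character(), mw_da = numeric(),
             pi = numeric(), stringsAsFactors = FALSE)
}

#' Screen a transcriptome end to end
#'
#' Extracts ORFs from every contig, deduces the proteins and applies the full
#' screening and classification chain. The filter funnel (contigs, ORFs,
#' passes) is available in the result.
#'
#' @param contigs List of [contig()]s.
#' @param config A [screen_config()].
#' @param min_aa Minimum ORF peptide length.
#' @return A list with `orfs` (the [orf_table()]), `annotations` (screening
#'   table; protein ids are `<contig_id>|orf<k>`), and `funnel` counts.
#' @export
screen_transcriptome <- function(contigs, config = screen_config(),
                                 min_aa = config$min_len) {
  orfs <- find_orfs_many(contigs, min_aa = min_aa)
  prots <- lapply(seq_along(orfs), function(i) {
    protein_record(sprintf("%s|orf%d", orfs[[i]]$contig_id, i),
                   orfs[[i]]$aa_seq, source = "orf")
  })
  ann <- if (length(prots)) screen_proteins(prots, config, dedupe = FALSE)
         else empty_annotation_table()
  list(orfs = orf_table(orfs),
       annotations = ann,
       funnel = c(contigs = length(contigs), orfs = length(orfs),
                  passes = if (nrow(ann)) sum(ann$pass) else 0L))
}
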