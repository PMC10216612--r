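# Orchestration: subcommands over the analysis modules with a reproducible
# run manifest. run_pipeline() is an ordinary function returning an exit
# status so it can be tested; inst/scripts/cystkit-cli.R wraps it for shells.

#' Run a pipeline subcommand
#'
#' Subcommands: `simulate` (`--what transcriptome|ki|erosion`), `screen`
#' (contig FASTA in, ORF + annotation tables out), `classify` (protein FASTA
#' in, annotation table out), `tree` (aligned protein FASTA in, Newick +
#' group table out), `ki` (series TSV + assay preset in, estimate JSON out),
#' `erosion` (indentation TSV in, ANOVA/Tukey/letters JSON out). Every run
#' writes `manifest.json` (subcommand, options, package version) next to its
#' outputs; re-running a manifest's command reproduces the outputs
#' byte-identically.
#'
#' @param argv Character vector of arguments, e.g.
#'   `c("screen", "--fasta", "x.fa", "--out-dir", "out")`.
#' @param quiet Suppress the INFO log lines.
#' @return Integer exit status, `0` on success (invisibly).
#' @export
run_pipeline <- function(argv, quiet = FALSE) {
  status <- tryCatch({
    do_run(argv, quiet)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    message(usage_text())
    1L
  })
  invisible(status)
}

usage_text <- function() {
  paste("usage: cystkit <simulate|screen|classify|tree|ki|erosion> [options]",
        "  common options: --out-dir DIR --seed INT", sep = "\n")
}

parse_opts <- function(args, allowed) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!grepl("^--", key)) stop("unexpected argument: ", key)
    name <- sub("^--", "", key)
    if (!name %in% allowed) stop("unknown flag: ", key)
    if (i + 1L > length(args)) stop("missing value for ", key)
    opts[[name]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

log_info <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("INFO  ", fmt), ...))
}

write_manifest <- function(out_dir, subcommand, opts) {
  manifest <- list(tool = "cystkit",
                   version = as.character(utils::packageVersion("cystkit")),
                   subcommand = subcommand, options = opts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

do_run <- function(argv, quiet) {
  if (length(argv) < 1L) stop("no subcommand given")
  sub <- argv[1]
  args <- argv[-1]
  handler <- switch(sub,
                    simulate = cmd_simulate, screen = cmd_screen,
                    classify = cmd_classify, tree = cmd_tree,
                    ki = cmd_ki, erosion = cmd_erosion,
                    stop("unknown subcommand: ", sub))
  handler(args, quiet)
}

out_dir_of <- function(opts) {
  dir <- opts[["out-dir"]] %||% stop("--out-dir is required")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir
}

cmd_simulate <- function(args, quiet) {
  opts <- parse_opts(args, c("what", "seed", "out-dir", "n-noise", "n-planted",
                             "true-ki", "preset", "cv", "tissue",
                             "n-per-group"))
  what <- opts$what %||% stop("--what is required")
  seed <- as.integer(opts$seed %||% 1)
  dir <- out_dir_of(opts)
  if (what == "transcriptome") {
    sim <- make_transcriptome(seed,
                              n_noise = as.integer(opts[["n-noise"]] %||% 430),
                              n_planted = as.integer(opts[["n-planted"]] %||% 20))
    write_fasta(sim$contigs, file.path(dir, "contigs.fasta"))
    write_tsv(sim$truth, file.path(dir, "truth.tsv"))
    log_info(quiet, "wrote %d contigs (%d planted cystatins, %d decoys)",
             length(sim$contigs), sum(sim$truth$class == "cystatin"),
             sum(sim$truth$class == "decoy"))
  } else if (what == "ki") {
    setup <- assay_preset(opts$preset %||% "papain")
    sim <- simulate_inhibition_series(seed,
                                      true_ki_nM = as.numeric(opts[["true-ki"]] %||% 10),
                                      setup = setup,
                                      cv = as.numeric(opts$cv %||% 0.02))
    rows <- do.call(rbind, lapply(seq_along(sim$series$replicates), function(r) {
      rep <- sim$series$replicates[[r]]
      data.frame(replicate_id = r,
                 inhibitor_conc_nM = c(0, rep$conc_nM),
                 slope = c(rep$v0, rep$vi))
    }))
    write_tsv(rows, file.path(dir, "series.tsv"))
    write_tsv(sim$truth, file.path(dir, "truth.tsv"))
    log_info(quiet, "wrote %d replicates for %s", length(sim$series$replicates),
             setup$enzyme)
  } else if (what == "erosion") {
    tissue <- opts$tissue %||% "enamel"
    sim <- simulate_erosion_experiment(seed, erosion_reference(tissue),
                                       n_per_group = as.integer(opts[["n-per-group"]] %||% 20),
                                       tissue = tissue)
    write_tsv(sim$experiment, file.path(dir, "indentations.tsv"))
    write_tsv(sim$truth, file.path(dir, "truth.tsv"))
    log_info(quiet, "wrote %d %s samples", nrow(sim$truth), tissue)
  } else stop("unknown --what: ", what)
  write_manifest(dir, "simulate", opts)
}

cmd_screen <- function(args, quiet) {
  opts <- parse_opts(args, c("fasta", "out-dir", "min-aa"))
  path <- opts$fasta %||% stop("--fasta is required")
  dir <- out_dir_of(opts)
  contigs <- read_fasta(path, type = "DNA")
  res <- screen_transcriptome(contigs,
                              min_aa = as.integer(opts[["min-aa"]] %||% 80))
  write_tsv(res$orfs, file.path(dir, "orfs.tsv"))
  write_tsv(res$annotations, file.path(dir, "annotations.tsv"))
  log_info(quiet, "funnel: %d contigs -> %d ORFs -> %d passes",
           res$funnel["contigs"], res$funnel["orfs"], res$funnel["passes"])
  write_manifest(dir, "screen", opts)
}

cmd_classify <- function(args, quiet) {
  opts <- parse_opts(args, c("fasta", "out-dir"))
  path <- opts$fasta %||% stop("--fasta is required")
  dir <- out_dir_of(opts)
  prots <- read_fasta(path, type = "AA")
  ann <- screen_proteins(prots)
  write_tsv(ann, file.path(dir, "annotations.tsv"))
  log_info(quiet, "%d proteins screened, %d passed", nrow(ann), sum(ann$pass))
  write_manifest(dir, "classify", opts)
}

cmd_tree <- function(args, quiet) {
  opts <- parse_opts(args, c("fasta", "out-dir", "k", "model"))
  path <- opts$fasta %||% stop("--fasta is required")
  k <- as.integer(opts$k %||% 3)
  dir <- out_dir_of(opts)
  prots <- read_fasta(path, type = "AA")
  dm <- pairwise_distance(prots, model = opts$model %||% "p")
  tr <- nj_tree(dm)
  groups <- cut_groups(tr, k)
  ape::write.tree(tr, file.path(dir, "tree.nwk"))
  write_tsv(data.frame(leaf = names(groups), group = unname(groups)),
            file.path(dir, "groups.tsv"))
  log_info(quiet, "%d leaves cut into %d groups", length(groups), k)
  write_manifest(dir, "tree", opts)
}

cmd_ki <- function(args, quiet) {
  opts <- parse_opts(args, c("series", "preset", "out-dir"))
  path <- opts$series %||% stop("--series is required")
  setup <- assay_preset(opts$preset %||% stop("--preset is required"))
  dir <- out_dir_of(opts)
  series <- read_inhibition_series(path, setup)
  est <- estimate_ki(series)
  jsonlite::write_json(unclass(est), file.path(dir, "ki_estimate.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_info(quiet, "%s: Ki = %.4g +/- %.2g nM (Kiapp %.4g nM, n=%d)",
           setup$enzyme, est$ki_mean, est$ki_sd, est$kiapp_mean,
           est$n_replicates)
  write_manifest(dir, "ki", opts)
}

cmd_erosion <- function(args, quiet) {
  opts <- parse_opts(args, c("table", "alpha", "out-dir"))
  path <- opts$table %||% stop("--table is required")
  alpha <- as.numeric(opts$alpha %||% 0.05)
  dir <- out_dir_of(opts)
  exp <- read_indentation_table(path)
  res <- tukey_cld(exp, alpha)
  write_tsv(sample_smc(exp), file.path(dir, "smc.tsv"))
  write_tsv(res$tukey, file.path(dir, "tukey.tsv"))
  write_tsv(data.frame(group = names(res$letters),
                       mean_smc = unname(res$group_means[names(res$letters)]),
                       letters = unname(res$letters)),
            file.path(dir, "letters.tsv"))
  jsonlite::write_json(res[c("f_stat", "df_between", "df_within", "p_value")],
                       file.path(dir, "anova.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_info(quiet, "ANOVA F(%d,%d) = %.3f, p = %.3g", res$df_between,
           res$df_within, res$f_stat, res$p_value)
  write_manifest(dir, "erosion", opts)
}
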