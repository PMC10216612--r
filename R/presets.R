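# Reference constants shipped with the package: assay constants, the
# published Ki matrix for the five maqui cystatins, and the enamel/dentin
# %SMC group summaries used as planted truth in recovery simulations.

#' Published Ki reference table
#'
#' Inhibition constants (nM, mean and SD across triplicate fits) of the five
#' recombinant maqui cystatins against papain, cathepsin L and cathepsin B.
#' Used as planted-truth values in simulation-based recovery tests; the raw
#' slope data behind them are not deposited, so they are inputs here, not
#' outputs.
#'
#' @return data.frame: `inhibitor`, `enzyme` (assay preset name), `ki_nM`,
#'   `ki_sd_nM`.
#' @export
ki_reference <- function() {
  data.frame(
    inhibitor = rep(paste0("MaquiCPI-", 1:5), times = 3),
    enzyme = rep(c("papain", "cathepsin_L", "cathepsin_B"), each = 5),
    ki_nM = c(7.13, 1.42, 3.29, 2.99, 5.05,
              0.34, 0.33, 0.38, 0.57, 1.25,
              35.74, 20.97, 21.94, 876.70, 5470),
    ki_sd_nM = c(1.30, 0.39, 0.58, 0.34, 0.82,
                 0.07, 0.07, 0.08, 0.11, 0.25,
                 0.84, 3.78, 3.01, 53.99, 630),
    stringsAsFactors = FALSE)
}

#' Published %SMC group summaries
#'
#' Per-treatment mean and SD of the percentage surface-microhardness change
#' in the seven-group (n = 20/group) initial-erosion experiment, for enamel
#' and dentin. Used as planted group parameters in
#' [simulate_erosion_experiment()].
#'
#' @param tissue `"enamel"` or `"dentin"`.
#' @return data.frame: `group`, `mean`, `sd`.
#' @export
erosion_reference <- function(tissue = c("enamel", "dentin")) {
  tissue <- match.arg(tissue)
  groups <- c("Control", "Elmex", "CaneCPI-5", "0.1 MaquiCPI-3",
              "0.25 MaquiCPI-3", "0.5 MaquiCPI-3", "1.0 MaquiCPI-3")
  if (tissue == "enamel") {
    data.frame(group = groups,
               mean = c(37.56, 22.30, 19.37, 19.93, 23.72, 2.90, 19.23),
               sd = c(13.98, 10.06, 10.41, 10.26, 9.74, 3.35, 12.01),
               stringsAsFactors = FALSE)
  } else {
    data.frame(group = groups,
               mean = c(38.38, 33.25, 10.49, 14.87, 18.52, 9.76, 35.77),
               sd = c(8.97, 5.62, 5.57, 10.18, 10.33, 10.93, 10.24),
               stringsAsFactors = FALSE)
  }
}
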