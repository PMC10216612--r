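# Tight-binding competitive inhibition constants from slope series.
#
# Model: V0/Vi = 1 + [I]/Kiapp, with the substrate correction
# Ki = Kiapp / (1 + [S]/Km). Units are fixed: [I] and Ki in nM, [S] and Km
# in µM; conversion happens only at parse time.

#' Assay setup
#'
#' @param enzyme Enzyme name.
#' @param e_nM Enzyme concentration, nM.
#' @param s_uM Substrate concentration, µM.
#' @param km_uM Michaelis constant for the substrate, µM.
#' @return A list of class `"assay_setup"`.
#' @export
assay_setup <- function(enzyme, e_nM, s_uM, km_uM) {
  stopifnot(e_nM > 0, s_uM > 0, km_uM > 0)
  structure(list(enzyme = enzyme, e_nM = e_nM, s_uM = s_uM, km_uM = km_uM),
            class = "assay_setup")
}

#' Shipped assay presets
#'
#' Fluorogenic Z-Phe-Arg-AMC assays: papain at 10 nM with 2.5 µM substrate
#' (Km 10 µM), cathepsin B at 1.9 nM with 20 µM substrate (Km 23 µM),
#' cathepsin L at 3.5 nM with 8 µM substrate (Km 2 µM).
#'
#' @param enzyme `"papain"`, `"cathepsin_B"` or `"cathepsin_L"`.
#' @return An [assay_setup()].
#' @export
assay_preset <- function(enzyme = c("papain", "cathepsin_B", "cathepsin_L")) {
  enzyme <- match.arg(enzyme)
  switch(enzyme,
         papain      = assay_setup("papain", e_nM = 10,  s_uM = 2.5, km_uM = 10),
         cathepsin_B = assay_setup("cathepsin_B", e_nM = 1.9, s_uM = 20, km_uM = 23),
         cathepsin_L = assay_setup("cathepsin_L", e_nM = 3.5, s_uM = 8,  km_uM = 2))
}

#' One titration replicate
#'
#' @param v0 Uninhibited slope (fluorescence/min), positive.
#' @param conc_nM Inhibitor concentrations, nM (>= 2 distinct positive values).
#' @param vi Inhibited slopes, same length as `conc_nM`, positive.
#' @return A list of class `"inhibition_replicate"`.
#' @export
inhibition_replicate <- function(v0, conc_nM, vi) {
  stopifnot(v0 > 0, length(conc_nM) == length(vi),
            length(unique(conc_nM[conc_nM > 0])) >= 2, all(conc_nM > 0),
            all(vi > 0))
  structure(list(v0 = v0, conc_nM = as.numeric(conc_nM), vi = as.numeric(vi)),
            class = "inhibition_replicate")
}

#' A replicated titration series with its assay setup
#'
#' @param setup An [assay_setup()].
#' @param replicates List of [inhibition_replicate()]s.
#' @return A list of class `"inhibition_series"`.
#' @export
inhibition_series <- function(setup, replicates) {
  stopifnot(inherits(setup, "assay_setup"), length(replicates) >= 1)
  structure(list(setup = setup, replicates = replicates),
            class = "inhibition_series")
}

#' Fit the apparent inhibition constant for one replicate
#'
#' Unweighted least squares of y = V0/Vi - 1 on [I] through the origin
#' (the model has no free intercept); Kiapp = 1/slope. R^2 is computed on the
#' transformed points. If no point shows inhibition the fit is flagged
#' `no_inhibition` with Kiapp = Inf; apparent activation (Vi > V0 beyond
#' `activation_tol`) raises a warning but the point is retained.
#'
#' @param replicate An [inhibition_replicate()].
#' @param activation_tol Relative tolerance on Vi > V0 before warning.
#' @return List with `kiapp_nM`, `r2`, `slope`, `no_inhibition`.
#' @export
fit_kiapp <- function(replicate, activation_tol = 0.02) {
  y <- replicate$v0 / replicate$vi - 1
  x <- replicate$conc_nM
  if (any(y < -activation_tol)) {
    warning("apparent activation (Vi > V0) in replicate; points retained")
  }
  if (all(y == 0)) {
    return(list(kiapp_nM = Inf, r2 = NA_real_, slope = 0,
                no_inhibition = TRUE))
  }
  slope <- sum(x * y) / sum(x^2)
  ss_res <- sum((y - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(kiapp_nM = 1 / slope, r2 = r2, slope = slope, no_inhibition = FALSE)
}

#' Substrate-competition correction
#'
#' Ki = Kiapp / (1 + [S]/Km); units preserved (nM in, nM out).
#'
#' @param kiapp_nM Apparent inhibition constant, nM.
#' @param setup An [assay_setup()].
#' @return Ki in nM.
#' @export
ki_from_kiapp <- function(kiapp_nM, setup) {
  stopifnot(is.finite(kiapp_nM), kiapp_nM > 0)
  if (setup$km_uM <= 0) stop("Km must be positive")
  kiapp_nM / (1 + setup$s_uM / setup$km_uM)
}

#' Estimate Ki from a replicated series
#'
#' Per-replicate through-origin fits give per-replicate Kiapp and Ki values;
#' the estimate is their mean with the sample (n-1) standard deviation. The
#' tight-binding flag is raised when the mean Kiapp is below ten times the
#' enzyme concentration, where depletion of free inhibitor begins to bias the
#' uncorrected fit.
#'
#' @param series An [inhibition_series()].
#' @return A list of class `"ki_estimate"`: `kiapp_mean`, `kiapp_sd`,
#'   `ki_mean`, `ki_sd` (nM), `n_replicates`, `fit_r2`, `tight_binding_flag`.
#' @export
estimate_ki <- function(series) {
  fits <- lapply(series$replicates, fit_kiapp)
  if (any(vapply(fits, `[[`, TRUE, "no_inhibition"))) {
    stop("no inhibition observed in at least one replicate; Ki is unbounded")
  }
  kiapp <- vapply(fits, `[[`, 0, "kiapp_nM")
  ki <- vapply(kiapp, ki_from_kiapp, 0, setup = series$setup)
  n <- length(kiapp)
  structure(list(
    kiapp_mean = mean(kiapp),
    kiapp_sd = if (n > 1) stats::sd(kiapp) else 0,
    ki_mean = mean(ki),
    ki_sd = if (n > 1) stats::sd(ki) else 0,
    n_replicates = n,
    fit_r2 = vapply(fits, `[[`, 0, "r2"),
    tight_binding_flag = mean(kiapp) < 10 * series$setup$e_nM
  ), class = "ki_estimate")
}

#' Residual enzymatic activity
#'
#' @param v0 Uninhibited slope (> 0).
#' @param vi Inhibited slope.
#' @return `vi/v0`, clipped below at 0.
#' @export
residual_activity <- function(v0, vi) {
  if (any(v0 <= 0)) stop("v0 must be positive")
  pmax(vi / v0, 0)
}

#' Read a titration series from TSV
#'
#' Expected columns: `replicate_id`, `inhibitor_conc_nM`, `slope`; the row(s)
#' with zero inhibitor concentration give each replicate's V0.
#'
#' @param path TSV path.
#' @param setup An [assay_setup()].
#' @return An [inhibition_series()].
#' @export
read_inhibition_series <- function(path, setup) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("replicate_id", "inhibitor_conc_nM", "slope")
  if (!all(need %in% names(tab))) {
    stop("series TSV must have columns: ", paste(need, collapse = ", "))
  }
  reps <- lapply(split(tab, tab$replicate_id), function(df) {
    v0_rows <- df$inhibitor_conc_nM == 0
    if (!any(v0_rows)) stop("replicate without a zero-inhibitor (V0) row")
    inhibition_replicate(v0 = mean(df$slope[v0_rows]),
                         conc_nM = df$inhibitor_conc_nM[!v0_rows],
                         vi = df$slope[!v0_rows])
  })
  inhibition_series(setup, unname(reps))
}
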