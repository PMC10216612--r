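# Surface-microhardness change (%SMC) and the one-way ANOVA / Tukey HSD
# battery with a compact letter display.
#
# An experiment is a long-format data.frame with columns sample_id, tissue,
# group, indent, sm_baseline, sm_final (one row per indentation; six per
# sample by design).

#' Percentage surface-microhardness change for one sample
#'
#' `(mean(baseline) - mean(final)) / mean(baseline) * 100`; positive values
#' mean softening. Invariant under rescaling of all readings by any c > 0.
#'
#' @param sm_baseline Baseline Knoop readings (typically six).
#' @param sm_final Post-treatment Knoop readings.
#' @return %SMC (scalar).
#' @export
percent_smc <- function(sm_baseline, sm_final) {
  b <- mean(sm_baseline)
  if (b <= 0) stop("baseline mean must be positive")
  (b - mean(sm_final)) / b * 100
}

#' Per-sample %SMC table for an experiment
#'
#' @param experiment Long-format indentation data.frame (`sample_id`, `group`,
#'   `sm_baseline`, `sm_final`, optionally `tissue`).
#' @return data.frame with one row per sample: `sample_id`, `group`, `smc`.
#' @export
sample_smc <- function(experiment) {
  stopifnot(all(c("sample_id", "group", "sm_baseline", "sm_final") %in%
                  names(experiment)))
  parts <- split(experiment, experiment$sample_id)
  out <- do.call(rbind, lapply(parts, function(df) {
    data.frame(sample_id = df$sample_id[1], group = df$group[1],
               smc = percent_smc(df$sm_baseline, df$sm_final),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$sample_id), ]
}

#' Normality and homogeneity checks
#'
#' One-sample Kolmogorov–Smirnov test of each group's per-sample %SMC against
#' a normal with that group's mean and SD (note: estimating the parameters
#' from the sample makes plain KS anti-conservative), and Bartlett's test of
#' homogeneity of variances across groups.
#'
#' @param experiment Long-format indentation data.frame, or a [sample_smc()]
#'   table (recognised by its `smc` column).
#' @param alpha Significance level for the flags.
#' @return List with `ks` (per-group data.frame), `bartlett`
#'   (statistic/df/p/flag), and `alpha`.
#' @export
check_assumptions <- function(experiment, alpha = 0.05) {
  smc <- if ("smc" %in% names(experiment)) experiment else sample_smc(experiment)
  groups <- split(smc$smc, smc$group)
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 3))
  ks <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    data.frame(group = g, statistic = unname(kt$statistic),
               p_value = kt$p.value, flagged = kt$p.value < alpha,
               stringsAsFactors = FALSE)
  }))
  vars <- vapply(groups, stats::var, 0)
  if (any(vars == 0)) {
    bart <- list(statistic = NA_real_, df = length(groups) - 1,
                 p_value = NA_real_, flagged = NA,
                 note = "zero within-group variance; Bartlett undefined")
  } else {
    bt <- stats::bartlett.test(smc$smc, factor(smc$group))
    bart <- list(statistic = unname(bt$statistic), df = unname(bt$parameter),
                 p_value = bt$p.value, flagged = bt$p.value < alpha,
                 note = NA_character_)
  }
  list(ks = ks, bartlett = bart, alpha = alpha)
}

#' One-way ANOVA on per-sample %SMC
#'
#' @param experiment Long-format indentation data.frame or [sample_smc()]
#'   table.
#' @return List: `f_stat`, `df_between`, `df_within`, `p_value`, plus the
#'   underlying `aov` fit.
#' @export
one_way_anova <- function(experiment) {
  smc <- if ("smc" %in% names(experiment)) experiment else sample_smc(experiment)
  stopifnot(length(unique(smc$group)) >= 2,
            all(table(smc$group) >= 2))
  if (stats::var(smc$smc) == 0) stop("zero total variance; ANOVA undefined")
  fit <- stats::aov(smc ~ group, data = transform(smc, group = factor(group)))
  tab <- summary(fit)[[1]]
  list(f_stat = tab[["F value"]][1],
       df_between = tab[["Df"]][1], df_within = tab[["Df"]][2],
       p_value = tab[["Pr(>F)"]][1], fit = fit)
}

#' Tukey HSD with a compact letter display
#'
#' All pairwise comparisons via the studentized range (Tukey–Kramer for
#' unequal n), then a compact letter display built by insert-then-absorb:
#' groups sharing a letter are not significantly different at `alpha`.
#' Letters are assigned in order of ascending group mean.
#'
#' @param experiment Long-format indentation data.frame or [sample_smc()]
#'   table.
#' @param alpha Significance level.
#' @return List of class `"anova_result"`: the [one_way_anova()] fields plus
#'   `tukey` (pair, diff, p_adj), `letters` (group -> letter string),
#'   `group_means`, and `assumptions` from [check_assumptions()].
#' @export
tukey_cld <- function(experiment, alpha = 0.05) {
  smc <- if ("smc" %in% names(experiment)) experiment else sample_smc(experiment)
  groups <- sort(unique(smc$group))
  if (length(groups) < 2) stop("need at least 2 groups")
  av <- one_way_anova(smc)
  tk <- stats::TukeyHSD(av$fit, conf.level = 1 - alpha)$group
  # reconstruct pair names from the factor levels (group labels may contain
  # '-', so parsing rownames is unsafe)
  cmb <- utils::combn(groups, 2)
  expected <- paste(cmb[2, ], cmb[1, ], sep = "-")
  if (!identical(rownames(tk), expected)) {
    stop("unexpected TukeyHSD comparison order")
  }
  tukey <- data.frame(group1 = cmb[2, ], group2 = cmb[1, ],
                      diff = tk[, "diff"], p_adj = tk[, "p adj"],
                      stringsAsFactors = FALSE)
  # equal data in all cells: no differences at all
  tukey$p_adj[is.nan(tukey$p_adj) & tukey$diff == 0] <- 1
  means <- vapply(split(smc$smc, smc$group), mean, 0)
  letters <- cld_insert_absorb(groups[order(means[groups])], tukey, alpha)
  structure(c(av[c("f_stat", "df_between", "df_within", "p_value")],
              list(tukey = tukey, letters = letters,
                   group_means = means,
                   assumptions = check_assumptions(smc, alpha),
                   alpha = alpha)),
            class = "anova_result")
}

# Insert-then-absorb compact letter display (Piepho-style). `order_groups` is
# the group sequence in ascending mean order; `tukey` the pairwise table.
cld_insert_absorb <- function(order_groups, tukey, alpha) {
  sig_pair <- function(a, b) {
    row <- (tukey$group1 == a & tukey$group2 == b) |
           (tukey$group1 == b & tukey$group2 == a)
    any(tukey$p_adj[row] < alpha)
  }
  # columns: logical membership vectors over groups
  cols <- list(stats::setNames(rep(TRUE, length(order_groups)), order_groups))
  for (i in seq_along(order_groups)) {
    for (j in seq_len(i - 1L)) {
      a <- order_groups[i]; b <- order_groups[j]
      if (!sig_pair(a, b)) next
      viol <- which(vapply(cols, function(col) col[a] && col[b], TRUE))
      for (v in viol) {
        old <- cols[[v]]
        c1 <- old; c1[a] <- FALSE
        c2 <- old; c2[b] <- FALSE
        cols[[v]] <- c1
        cols[[length(cols) + 1L]] <- c2
      }
      # absorb: drop columns whose membership is a subset of another's
      keep <- rep(TRUE, length(cols))
      for (u in seq_along(cols)) {
        for (w in seq_along(cols)) {
          if (u != w && keep[u] && keep[w] &&
              all(!cols[[u]] | cols[[w]]) && any(cols[[w]] & !cols[[u]])) {
            keep[u] <- FALSE
          }
        }
      }
      cols <- cols[keep]
      cols <- unique(cols)
    }
  }
  # letter columns ordered by their lowest-mean member
  first_member <- vapply(cols, function(col) min(match(names(col)[col],
                                                       order_groups)), 0)
  cols <- cols[order(first_member)]
  out <- stats::setNames(rep("", length(order_groups)), order_groups)
  for (ci in seq_along(cols)) {
    lab <- letters[ci]
    members <- names(cols[[ci]])[cols[[ci]]]
    out[members] <- paste0(out[members], lab)
  }
  out
}

#' Read an indentation table from TSV
#'
#' Columns: `sample_id`, `tissue`, `group`, `indent`, `sm_baseline`,
#' `sm_final`.
#'
#' @param path TSV path.
#' @return Validated long-format data.frame.
#' @export
read_indentation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "group", "indent", "sm_baseline", "sm_final")
  if (!all(need %in% names(tab))) {
    stop("indentation TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$sm_baseline <= 0) || any(tab$sm_final <= 0)) {
    stop("all Knoop readings must be positive")
  }
  tab
}
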