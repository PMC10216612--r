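# %SMC, assumption checks, one-way ANOVA and the Tukey compact letter display.

mk_experiment <- function(values_by_group, n_indent = 6) {
  # builds a long-format table whose per-sample %SMC equal `values_by_group`
  rows <- list()
  k <- 1L
  for (g in names(values_by_group)) {
    for (si in seq_along(values_by_group[[g]])) {
      smc <- values_by_group[[g]][si]
      b <- rep(300, n_indent)
      rows[[k]] <- data.frame(sample_id = sprintf("%s_s%02d", g, si),
                              tissue = "enamel", group = g,
                              indent = seq_len(n_indent),
                              sm_baseline = b,
                              sm_final = b * (1 - smc / 100))
      k <- k + 1L
    }
  }
  do.call(rbind, rows)
}

test_that("percent_smc is the relative drop of the mean reading", {
  expect_equal(percent_smc(rep(350, 6), rep(262.5, 6)), 25.0)
  expect_equal(percent_smc(rep(350, 6), rep(350, 6)), 0.0)
  # scale invariance
  set.seed(141)
  b <- runif(6, 200, 400); f <- runif(6, 150, 350)
  expect_equal(percent_smc(b, f), percent_smc(3.7 * b, 3.7 * f))
  expect_error(percent_smc(rep(0, 6), rep(0, 6)), "positive")
  # bounded above by 100 for non-negative readings; 100 iff final mean is 0
  expect_lte(percent_smc(b, f), 100)
  expect_equal(percent_smc(b, rep(0, 6)), 100)
})

test_that("one-way ANOVA matches the hand sum-of-squares decomposition", {
  exp1 <- mk_experiment(list(g1 = c(1, 2), g2 = c(3, 4)))
  av <- one_way_anova(exp1)
  expect_equal(av$f_stat, 8)  # SSB = 4, SSW = 1, df = (1, 2)
  expect_equal(c(av$df_between, av$df_within), c(1, 2))

  set.seed(151)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    vals <- lapply(seq_len(k), function(g) rnorm(sample(3:8, 1), mean = g))
    names(vals) <- paste0("g", seq_len(k))
    exp_i <- mk_experiment(vals)
    av_i <- one_way_anova(exp_i)
    orc <- oracle_anova_f(unlist(vals), rep(names(vals), lengths(vals)))
    expect_equal(av_i$f_stat, orc$f, tolerance = 1e-10)
    expect_equal(c(av_i$df_between, av_i$df_within), c(orc$dfb, orc$dfw))
  }
})

test_that("with two groups F equals the squared pooled t statistic", {
  set.seed(161)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(10, 0.5)
    exp2 <- mk_experiment(list(a = x, b = y))
    av <- one_way_anova(exp2)
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(av$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("identical group means give F = 0 and all-equal data errors", {
  exp0 <- mk_experiment(list(a = c(1, 3), b = c(3, 1)))
  expect_equal(one_way_anova(exp0)$f_stat, 0)
  expect_error(one_way_anova(mk_experiment(list(a = c(2, 2), b = c(2, 2)))),
               "zero total variance")
})

test_that("assumption checks: Bartlett zero under equal variances, KS flags heavy tails", {
  # identical dispersion in each group -> Bartlett statistic exactly 0
  exp_eq <- mk_experiment(list(a = c(1, 2, 3), b = c(11, 12, 13)))
  rep1 <- check_assumptions(exp_eq)
  expect_equal(rep1$bartlett$statistic, 0, tolerance = 1e-12)

  # zero within-group variance -> Bartlett undefined, flagged as such
  exp_zv <- mk_experiment(list(a = c(2, 2, 2), b = c(5, 5, 5)))
  rep2 <- check_assumptions(exp_zv)
  expect_true(is.na(rep2$bartlett$statistic))
  expect_match(rep2$bartlett$note, "undefined")

  # same-normal groups are rarely flagged; a heavy-tailed group usually is
  set.seed(171)
  normal_flags <- heavy_flags <- logical(40)
  for (s in 1:40) {
    g_norm <- list(a = rnorm(20, 10, 2), b = rnorm(20, 10, 2))
    rn <- check_assumptions(mk_experiment(g_norm))
    normal_flags[s] <- any(rn$ks$flagged)
    g_heavy <- list(a = rnorm(200, 10, 2), b = 10 + 2 * rcauchy(200))
    rh <- check_assumptions(mk_experiment(lapply(g_heavy, function(x) pmin(x, 99))))
    heavy_flags[s] <- rh$ks$flagged[rh$ks$group == "b"]
  }
  expect_lt(mean(normal_flags), 0.2)
  expect_gt(mean(heavy_flags), 0.8)
})

test_that("Tukey letters separate an obvious outlier group", {
  set.seed(181)
  vals <- list(low1 = rnorm(10, 10, 0.1), low2 = rnorm(10, 10.05, 0.1),
               high = rnorm(10, 30, 0.1))
  res <- tukey_cld(mk_experiment(vals))
  expect_equal(unname(res$letters[c("low1", "low2")]), c("a", "a"))
  expect_equal(unname(res$letters["high"]), "b")
})

test_that("identical data in every cell share a single letter", {
  exp_same <- mk_experiment(list(a = c(5, 5, 5), b = c(5, 5, 5), c = c(5, 5, 5)))
  expect_error(tukey_cld(exp_same), "zero total variance")
  # identical distributions but nonzero variance: all groups share a letter
  exp_shared <- mk_experiment(list(a = c(4, 5, 6), b = c(4, 5, 6), c = c(4, 5, 6)))
  res <- tukey_cld(exp_shared)
  expect_true(all(res$letters == "a"))
})

test_that("letters are consistent with the adjusted p values on random data", {
  set.seed(191)
  for (i in 1:15) {
    k <- sample(3:6, 1)
    vals <- lapply(seq_len(k), function(g) rnorm(sample(4:9, 1), sample(0:3, 1)))
    names(vals) <- paste0("g", seq_len(k))
    if (var(unlist(vals)) == 0) next
    res <- tukey_cld(mk_experiment(vals))
    lt <- strsplit(res$letters, "")
    for (r in seq_len(nrow(res$tukey))) {
      shared <- length(intersect(lt[[res$tukey$group1[r]]],
                                 lt[[res$tukey$group2[r]]])) > 0
      expect_equal(shared, res$tukey$p_adj[r] >= res$alpha)
    }
  }
})

test_that("indentation TSV reader validates structure and readings", {
  dir <- withr::local_tempdir()
  exp1 <- mk_experiment(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  path <- file.path(dir, "ind.tsv")
  write.table(exp1, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_indentation_table(path)
  expect_equal(nrow(back), nrow(exp1))
  bad <- exp1; bad$sm_final[1] <- -1
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_indentation_table(path), "positive")
})
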