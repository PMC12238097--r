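# table-level generators used across the statistical tests ----------------

sim_table <- function(seed, n_men = 9, n_women = 11, sd_subj = 1, sd_eps = 1,
                      load_shift = 0, rep_slope = 0,
                      sex_gap = 0, sex_load_gap = 0) {
  withr::with_seed(seed, {
    n <- n_men + n_women
    subj <- sprintf("s%02d", seq_len(n))
    sex <- rep(c("M", "F"), c(n_men, n_women))
    d <- expand.grid(subject_id = subj, load = c(75, 90), repetition = 1:3,
                     stringsAsFactors = FALSE)
    d$sex <- sex[match(d$subject_id, subj)]
    b <- stats::rnorm(n, 0, sd_subj)
    d$y <- b[match(d$subject_id, subj)] +
      load_shift * (d$load == 75) +
      rep_slope * (d$repetition - 2) +
      sex_gap * (d$sex == "F") +
      sex_load_gap * (d$sex == "F") * (d$load == 75) +
      stats::rnorm(nrow(d), 0, sd_eps)
    d
  })
}

test_that("Welch t and average-SD d reproduce the printed height comparison", {
  wt <- welch_t(183.2, 4.5, 9, 169.9, 5.8, 11)
  expect_equal(round(wt$t, 2), 5.77)
  expect_lt(wt$p, 0.001)
  expect_equal(round(cohens_d_avgsd(183.2, 4.5, 169.9, 5.8), 2), 2.58)
})

test_that("Welch t basics: zero at equal means, two-path equality, t.test oracle", {
  expect_equal(welch_t(10, 2, 5, 10, 3, 8)$t, 0)
  withr::with_seed(8, {
    for (i in 1:10) {
      x <- stats::rnorm(5 + i, 1, 2)
      y <- stats::rnorm(9, 0, 1.5)
      two_path <- welch_t_raw(x, y)
      summ <- welch_t(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
      expect_equal(two_path, summ)
      ref <- stats::t.test(x, y)
      expect_equal(two_path$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(two_path$df, unname(ref$parameter), tolerance = 1e-12)
      expect_equal(two_path$p, ref$p.value, tolerance = 1e-12)
      # Satterthwaite df never exceeds the pooled df
      expect_lte(two_path$df, length(x) + length(y) - 2)
    }
  })
})

test_that("Cohen's d: zero at equal means, scale-invariant, pooled variant", {
  expect_equal(cohens_d_avgsd(3, 1, 3, 2), 0)
  d1 <- cohens_d_avgsd(10, 2, 7, 3)
  expect_equal(cohens_d_avgsd(50, 10, 35, 15), d1)  # both groups scaled by 5
  expect_equal(sign(d1), 1)
  expect_equal(sign(cohens_d_avgsd(7, 3, 10, 2)), -1)
  dp <- cohens_d_avgsd(10, 2, 7, 3, denominator = "pooled", n1 = 4, n2 = 6)
  expect_equal(dp, 3 / sqrt((3 * 4 + 5 * 9) / 8))
  expect_error(cohens_d_avgsd(1, 1, 0, 1, denominator = "pooled"), "n1")
})

test_that("a 2-level within factor reduces to the squared paired t", {
  withr::with_seed(13, {
    for (i in 1:5) {
      n <- 6 + i
      d <- expand.grid(subject_id = seq_len(n), load = c("a", "b"))
      d$y <- stats::rnorm(nrow(d))
      fit <- mixed_rm_anova(d, dv = "y", within = "load",
                            subject = "subject_id")
      diffs <- d$y[d$load == "a"] - d$y[d$load == "b"]
      t2 <- (mean(diffs) / (sd(diffs) / sqrt(n)))^2
      expect_equal(tidy(fit)$F, t2, tolerance = 1e-12)
      expect_equal(tidy(fit)$epsilon_gg, 1)
    }
  })
})

test_that("F, epsilon and p match the projection oracle on toy designs", {
  cases <- list(
    list(seed = 1, n = 4, within = c("rep"), between = NULL),
    list(seed = 2, n = 5, within = c("load", "rep"), between = NULL),
    list(seed = 3, n = 6, within = c("load", "rep"), between = "sex",
         sizes = c(3, 3)),
    list(seed = 4, n = 6, within = c("load", "rep"), between = "sex",
         sizes = c(2, 4)),   # unequal groups
    list(seed = 5, n = 6, within = c("rep"), between = "sex", sizes = c(2, 4))
  )
  for (cs in cases) {
    withr::with_seed(cs$seed, {
      grid <- list(subject_id = sprintf("s%d", seq_len(cs$n)))
      if ("load" %in% cs$within) grid$load <- c("l1", "l2")
      grid$rep <- c("r1", "r2", "r3")
      d <- do.call(expand.grid, c(grid, stringsAsFactors = FALSE))
      if (!is.null(cs$between)) {
        sex <- rep(c("M", "F"), cs$sizes)
        d$sex <- sex[match(d$subject_id, sprintf("s%d", seq_len(cs$n)))]
      }
      d$y <- stats::rnorm(nrow(d), sd = 2) +
        as.numeric(factor(d$rep)) * stats::rnorm(cs$n)[
          match(d$subject_id, sprintf("s%d", seq_len(cs$n)))]
    })
    fit <- mixed_rm_anova(d, dv = "y", within = cs$within,
                          between = cs$between, subject = "subject_id")
    got <- tidy(fit)
    want <- oracle_rm_anova(d, dv = "y", within = cs$within,
                            between = cs$between, subject = "subject_id")
    expect_equal(nrow(got), nrow(want))
    for (j in seq_len(nrow(want))) {
      g <- got[got$effect == want$effect[j], ]
      expect_equal(nrow(g), 1)
      expect_equal(g$F, want$F[j], tolerance = 1e-8)
      expect_equal(g$ss_effect, want$ss[j], tolerance = 1e-8)
      expect_equal(g$ss_error, want$ss_err[j], tolerance = 1e-8)
      expect_equal(g$df_num, want$df[j])
      expect_equal(g$df_den, want$df_err[j])
      if (!is.na(want$epsilon[j])) {
        expect_equal(g$epsilon_gg, want$epsilon[j], tolerance = 1e-8)
      }
      expect_equal(g$p_uncorrected, want$p[j], tolerance = 1e-8)
      expect_equal(g$p_gg, want$p_gg[j], tolerance = 1e-8)
    }
  }
})

test_that("the fit agrees with car's repeated-measures Type III analysis", {
  skip_if_not_installed("car")
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  withr::defer(options(op))
  d <- sim_table(17, n_men = 4, n_women = 5, rep_slope = 0.4)
  fit <- mixed_rm_anova(d, dv = "y", within = c("load", "repetition"),
                        between = "sex", subject = "subject_id")
  subj <- sort(unique(d$subject_id))
  cells <- expand.grid(load = c(75, 90), repetition = 1:3)
  Y <- matrix(NA_real_, length(subj), nrow(cells))
  for (i in seq_along(subj)) {
    for (j in seq_len(nrow(cells))) {
      Y[i, j] <- d$y[d$subject_id == subj[i] & d$load == cells$load[j] &
                       d$repetition == cells$repetition[j]]
    }
  }
  sex <- d$sex[match(subj, d$subject_id)]
  mlm <- stats::lm(Y ~ sex, data = data.frame(sex = factor(sex)))
  idata <- data.frame(load = factor(cells$load),
                      repetition = factor(cells$repetition))
  aa <- summary(car::Anova(mlm, idata = idata,
                           idesign = ~load * repetition, type = 3),
                multivariate = FALSE)
  ref_F <- aa$univariate.tests[, "F value"]
  got <- tidy(fit)
  pick <- function(eff) got$F[got$effect == eff]
  expect_equal(pick("sex"), unname(ref_F["sex"]), tolerance = 1e-10)
  expect_equal(pick("load"), unname(ref_F["load"]), tolerance = 1e-10)
  expect_equal(pick("repetition"), unname(ref_F["repetition"]),
               tolerance = 1e-10)
  expect_equal(pick("load:repetition"), unname(ref_F["load:repetition"]),
               tolerance = 1e-10)
  eps_ref <- aa$pval.adjustments[, "GG eps"]
  expect_equal(got$epsilon_gg[got$effect == "repetition"],
               unname(eps_ref["repetition"]), tolerance = 1e-10)
  # Mauchly W agrees with the mlm-based test
  mw <- mauchly_test(
    stats::aggregate(y ~ subject_id + sex + repetition, data = d, FUN = mean),
    dv = "y", within = "repetition", subject = "subject_id", between = "sex")
  expect_equal(mw$W, unname(aa$sphericity.tests["repetition", 1]),
               tolerance = 1e-10)
  expect_equal(mw$p, unname(aa$sphericity.tests["repetition", 2]),
               tolerance = 1e-10)
})

test_that("sums of squares decompose the corrected total (orthogonal designs)", {
  check_decomp <- function(d, within, between = NULL) {
    fit <- mixed_rm_anova(d, dv = "y", within = within, between = between,
                          subject = "subject_id")
    eff <- tidy(fit)
    if (!is.null(between)) {
      win <- eff[eff$effect != between, ]
      lab <- sub(paste0(":", between, "$"), "", win$effect)
      ss_between <- eff$ss_effect[eff$effect == between]
    } else {
      win <- eff
      lab <- win$effect
      ss_between <- 0
    }
    # each within stratum's error counted once (effect and effect:between
    # rows share it), plus the subject stratum
    strata_err <- vapply(split(win$ss_error, lab), function(x) x[1], 0)
    total <- sum((d$y - mean(d$y))^2)
    parts <- sum(win$ss_effect) + ss_between + sum(strata_err) +
      fit$ss_subject
    expect_equal(parts, total, tolerance = 1e-8 * total)
  }
  check_decomp(sim_table(23, n_men = 10, n_women = 10, rep_slope = 0.3),
               within = c("load", "repetition"), between = "sex")
  d2 <- sim_table(24, n_men = 9, n_women = 11)
  d2$sex <- NULL
  check_decomp(d2, within = c("load", "repetition"))
})

test_that("Mauchly: not applicable at 2 levels, calibrated under sphericity, powerful under AR(1)", {
  d2 <- expand.grid(subject_id = 1:8, w = c("a", "b"))
  d2$y <- stats::rnorm(16)
  na_res <- mauchly_test(d2, dv = "y", within = "w", subject = "subject_id")
  expect_false(na_res$applicable)
  expect_true(is.na(na_res$W))

  gen_cov <- function(seed, n, Sigma) {
    withr::with_seed(seed, {
      L <- chol(Sigma)
      Y <- matrix(stats::rnorm(n * 3), n, 3) %*% L
      data.frame(subject_id = rep(seq_len(n), 3),
                 w = rep(c("w1", "w2", "w3"), each = n), y = as.vector(Y))
    })
  }
  # iid levels: W near 1 on average, rejection near alpha
  rej <- 0
  W <- numeric(200)
  for (s in 1:200) {
    m <- mauchly_test(gen_cov(s, 20, diag(3)), dv = "y", within = "w",
                      subject = "subject_id")
    W[s] <- m$W
    rej <- rej + (m$p < 0.05)
  }
  expect_gt(mean(W), 0.75)  # W concentrates near 1 (downward-biased at n=20)
  expect_lt(rej / 200, 0.12)

  # strong AR(1) correlation: rejected in > 80% of seeds at n = 40
  rho <- 0.9
  Sig <- rho^abs(outer(1:3, 1:3, "-"))
  rej2 <- 0
  for (s in 1:200) {
    m <- mauchly_test(gen_cov(5000 + s, 40, Sig), dv = "y", within = "w",
                      subject = "subject_id")
    rej2 <- rej2 + (m$p < 0.05)
  }
  expect_gt(rej2 / 200, 0.8)
})

test_that("epsilon approaches 1 under compound symmetry as n grows", {
  eps_at <- function(n, seed) {
    d <- withr::with_seed(seed, {
      subj <- seq_len(n)
      dd <- expand.grid(subject_id = subj, repetition = 1:3)
      b <- stats::rnorm(n, 0, 1)  # exchangeable: subject intercept + iid
      dd$y <- b[dd$subject_id] + stats::rnorm(nrow(dd))
      dd
    })
    fit <- mixed_rm_anova(d, dv = "y", within = "repetition",
                          subject = "subject_id")
    tidy(fit)$epsilon_gg
  }
  e_small <- mean(vapply(1:40, function(s) eps_at(10, s), 0))
  e_large <- mean(vapply(1:40, function(s) eps_at(400, 100 + s), 0))
  expect_gt(e_large, e_small)
  expect_gt(e_large, 0.97)
  # epsilon always within its theoretical range
  expect_true(all(vapply(1:40, function(s) eps_at(10, s), 0) >= 0.5))
})

test_that("Bonferroni post hocs: pair count, caps, degenerate and powered cases", {
  d <- sim_table(31, rep_slope = 0)
  ph <- bonferroni_posthoc(d, factor = "repetition", dv = "y",
                           subject = "subject_id")
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_bonferroni, pmin(1, 3 * ph$p_raw))
  expect_true(all(ph$p_bonferroni <= 1))

  # identical level values: all p = 1
  d0 <- expand.grid(subject_id = 1:6, repetition = 1:3)
  d0$y <- rep(stats::rnorm(6), 3)
  ph0 <- bonferroni_posthoc(d0, factor = "repetition", dv = "y",
                            subject = "subject_id")
  expect_true(all(ph0$p_bonferroni == 1))
  expect_true(all(ph0$mean_diff == 0))

  # injected decline at repetition 3 (about 1 SD): rep1-vs-rep3 significant
  # in > 80% of seeds at n = 20
  hits <- 0
  for (s in 1:200) {
    dd <- sim_table(4000 + s, sd_subj = 0.5, sd_eps = 1)
    dd$y <- dd$y - (dd$repetition == 3) * 1
    ph <- bonferroni_posthoc(dd, factor = "repetition", dv = "y",
                             subject = "subject_id")
    p13 <- ph$p_bonferroni[ph$level_a == 1 & ph$level_b == 3]
    hits <- hits + (p13 < 0.05)
  }
  expect_gt(hits / 200, 0.8)
})

test_that("estimated marginal means: cell means, equivariance, CI behaviour", {
  # balanced one-factor data: EMM equals the arithmetic cell mean
  d <- withr::with_seed(41, {
    dd <- expand.grid(subject_id = 1:12, repetition = 1:3)
    dd$y <- stats::rnorm(nrow(dd))
    dd
  })
  emm <- estimated_marginal_means(d, by = "repetition", dv = "y",
                                  subject = "subject_id")
  cellmeans <- as.numeric(tapply(d$y, d$repetition, mean))
  expect_equal(emm$estimate, cellmeans, tolerance = 1e-12)
  expect_true(all(emm$ci_low <= emm$estimate & emm$estimate <= emm$ci_high))

  # adding a constant shifts estimates, leaves widths unchanged
  d2 <- d
  d2$y <- d$y + 7
  emm2 <- estimated_marginal_means(d2, by = "repetition", dv = "y",
                                   subject = "subject_id")
  expect_equal(emm2$estimate, emm$estimate + 7, tolerance = 1e-12)
  expect_equal(emm2$ci_high - emm2$ci_low, emm$ci_high - emm$ci_low,
               tolerance = 1e-12)

  # empty cell is an error
  expect_error(
    estimated_marginal_means(d[-1, ], by = "repetition", dv = "y",
                             subject = "subject_id"),
    "empty cell"
  )
})

test_that("EMM contrasts recover an injected sex-by-load pattern", {
  # women exceed men at 75% only; the EMM difference (pooled across
  # repetitions) recovers the injected gap within its joint CI
  true_gap <- 6
  covered <- 0
  for (s in 1:100) {
    d <- sim_table(6000 + s, sd_subj = 2, sd_eps = 1.5,
                   sex_load_gap = true_gap)
    emm <- estimated_marginal_means(d, by = c("sex", "load"), dv = "y",
                                    subject = "subject_id", between = "sex")
    at75 <- emm[emm$load == "75", ]
    gap <- at75$estimate[at75$sex == "F"] - at75$estimate[at75$sex == "M"]
    se <- sqrt(sum(at75$se^2))
    covered <- covered +
      (abs(gap - true_gap) <= stats::qt(0.975, at75$df[1]) * se)
  }
  expect_gte(covered / 100, 0.9)
})

test_that("unbalanced or deficient designs are refused", {
  d <- sim_table(51)
  expect_error(
    mixed_rm_anova(d[-1, ], dv = "y", within = c("load", "repetition"),
                   between = "sex", subject = "subject_id"),
    "balanced"
  )
  d1 <- d[d$load == 75, ]
  expect_error(
    mixed_rm_anova(d1, dv = "y", within = "load", subject = "subject_id"),
    "fewer than 2"
  )
  dupe <- rbind(d, d[1, ])
  expect_error(
    mixed_rm_anova(dupe, dv = "y", within = c("load", "repetition"),
                   subject = "subject_id"),
    "balanced"
  )
  # a subject in two between-groups
  d2 <- d
  d2$sex[d2$subject_id == "s01"][1] <- "F"
  expect_error(
    mixed_rm_anova(d2, dv = "y", within = c("load", "repetition"),
                   between = "sex", subject = "subject_id"),
    "more than one level"
  )
})
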