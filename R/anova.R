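# Mixed repeated-measures ANOVA, implemented from first principles via the
# orthonormal-contrast (univariate split-plot) decomposition:
#
#   * each within effect e with q_e orthonormal contrast columns M_e maps the
#     subjects-by-cells matrix Y to scores Z_e = Y M_e;
#   * the effect is the Type III test of the intercept of Z_e against the
#     between-group design, the effect-by-group interaction the Type III test
#     of the group term, and the error stratum the within-group residual of
#     Z_e (the classical e-by-subject(group) term);
#   * the between effect is tested on the cell-averaged scores Y u with
#     u = 1/sqrt(p), against subject(group);
#   * Greenhouse-Geisser epsilon comes from the pooled within-group
#     covariance S_e of Z_e, epsilon = tr(S)^2 / (q tr(S^2)), and Mauchly's W
#     from det(S) / (tr(S)/q)^q with the chi-square approximation.
#
# Type III (unweighted-means) hypotheses are used throughout, matching how
# general-linear-model software treats unequal group sizes (e.g. 9 men vs 11
# women).

orthonorm_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Reshape a long table into a subjects x within-cells matrix, validating the
# balanced complete design.
rm_design <- function(data, dv, within, between, subject) {
  for (v in c(dv, within, between, subject)) {
    if (!v %in% names(data)) abort(paste0("column '", v, "' not found"))
  }
  if (length(within) < 1 || length(within) > 2) {
    abort("need 1 or 2 within-subject factors")
  }
  if (anyNA(data[[dv]])) abort("missing values in response; no imputation")
  subj <- factor(data[[subject]])
  wlev <- map(within, ~ sort(unique(data[[.x]])))
  names(wlev) <- within
  for (w in within) {
    if (length(wlev[[w]]) < 2) {
      abort(paste0("within factor '", w, "' has fewer than 2 levels"))
    }
  }
  wfac <- map2(within, wlev, ~ factor(data[[.x]], levels = .y))
  cell <- if (length(within) == 1) wfac[[1]] else {
    interaction(wfac[[1]], wfac[[2]], lex.order = FALSE)  # first varies fastest
  }
  p <- prod(lengths(wlev))
  n <- nlevels(subj)
  counts <- table(subj, cell)
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)
    abort(paste0("design is not balanced/complete: subject ",
                 rownames(counts)[bad[1, 1]], ", cell ",
                 colnames(counts)[bad[1, 2]], " has ", counts[bad[1, ]][1],
                 " observations (expected 1); no imputation is performed"))
  }
  Y <- matrix(NA_real_, n, p, dimnames = list(levels(subj), levels(cell)))
  Y[cbind(as.integer(subj), as.integer(cell))] <- data[[dv]]
  group <- NULL
  if (!is.null(between)) {
    g <- tapply(as.character(data[[between]]), subj,
                function(x) unique(x))
    if (any(lengths(g) != 1)) {
      abort(paste0("subject assigned to more than one level of '", between, "'"))
    }
    group <- factor(unlist(g))
    if (nlevels(group) < 2) abort("between factor needs >= 2 levels")
    if (any(table(group) < 2)) {
      abort("each between-group needs >= 2 subjects")
    }
  }
  list(Y = Y, group = group, within = within, wlev = wlev, n = n, p = p)
}

# Type III SS for the intercept and (optionally) the group term of Z ~ 1 + g,
# summed over the columns of Z; plus the residual stratum.
type3_stratum <- function(Z, group) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  q <- ncol(Z)
  if (is.null(group)) {
    zbar <- colMeans(Z)
    ss_int <- n * sum(zbar^2)
    res <- sweep(Z, 2, zbar)
    list(ss_int = ss_int, ss_grp = NA_real_, ss_err = sum(res^2),
         df_grp = 0L, df_err = n - 1L)
  } else {
    G <- nlevels(group)
    X <- stats::model.matrix(~g, data.frame(g = group),
                             contrasts.arg = list(g = "contr.sum"))
    XtXi <- solve(crossprod(X))
    B <- XtXi %*% crossprod(X, Z)           # (G x q) coefficients
    res <- Z - X %*% B
    ss_int <- sum(B[1, ]^2) / XtXi[1, 1]
    Lg <- 2:G
    Vg <- solve(XtXi[Lg, Lg, drop = FALSE])
    ss_grp <- sum(vapply(seq_len(q), function(j) {
      b <- B[Lg, j]
      drop(t(b) %*% Vg %*% b)
    }, 0))
    list(ss_int = ss_int, ss_grp = ss_grp, ss_err = sum(res^2),
         df_grp = (G - 1L), df_err = n - G)
  }
}

pooled_within_cov <- function(Z, group) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (is.null(group)) {
    S <- crossprod(sweep(Z, 2, colMeans(Z)))
    d <- n - 1L
  } else {
    S <- matrix(0, ncol(Z), ncol(Z))
    for (g in levels(group)) {
      Zg <- Z[group == g, , drop = FALSE]
      S <- S + crossprod(sweep(Zg, 2, colMeans(Zg)))
    }
    d <- n - nlevels(group)
  }
  list(S = S / d, df = d)
}

gg_epsilon <- function(S) {
  q <- ncol(S)
  if (q == 1) return(1)
  e <- sum(diag(S))^2 / (q * sum(S * S))
  min(max(e, 1 / q), 1)
}

mauchly_from_cov <- function(S, df_err) {
  q <- ncol(S)
  tr <- sum(diag(S))
  W <- det(S) / (tr / q)^q
  W <- min(max(W, 0), 1)
  f <- (2 * q^2 + q + 2) / (6 * q)
  chi <- -(df_err - f) * log(max(W, .Machine$double.xmin))
  df <- q * (q + 1) / 2 - 1
  list(W = W, chi_sq = chi, df = df,
       p = stats::pchisq(chi, df, lower.tail = FALSE))
}

#' Mixed repeated-measures ANOVA
#'
#' Fits the split-plot general linear model for a fully-crossed
#' repeated-measures design with one or two within-subject factors and an
#' optional between-subjects factor: each within effect (and its interaction
#' with the between factor) is tested against its own effect-by-subject error
#' stratum, the between effect against subject-within-group. Every within
#' effect gets a Greenhouse-Geisser epsilon (from the pooled covariance of
#' its orthonormal contrast scores) and both the uncorrected and
#' GG-corrected p value — the correction is always reported, not gated on
#' Mauchly's test, so results do not depend on an adaptive rule. Effect sizes
#' are partial eta-squared, `SS_effect / (SS_effect + SS_error)`. Mauchly's
#' sphericity test is included for every within effect with at least two
#' contrast dimensions.
#'
#' The design must be complete and balanced within subjects (every subject
#' observed once in every within-cell); anything else is an error — no
#' imputation. Between-group sizes may differ; unweighted-means (Type III)
#' hypotheses are used, as general-linear-model software does.
#'
#' @param data Long-format data frame (e.g. the study table).
#' @param dv Name of the response column.
#' @param within Character vector of 1-2 within-subject factor columns.
#' @param between Optional between-subjects factor column.
#' @param subject Subject identifier column.
#' @return An object of class `eqi_anova`; see [tidy.eqi_anova()] for the
#'   per-effect table and [mauchly_test()] for standalone sphericity tests.
#' @export
#' @examples
#' tab <- expand.grid(subject_id = paste0("s", 1:6), load = c(75, 90),
#'                    repetition = 1:3)
#' tab$y <- rnorm(nrow(tab)) + 2 * (tab$load == 75)
#' fit <- mixed_rm_anova(tab, dv = "y", within = c("load", "repetition"),
#'                       subject = "subject_id")
#' tidy(fit)
mixed_rm_anova <- function(data, dv, within, between = NULL, subject) {
  d <- rm_design(data, dv, within, between, subject)
  Y <- d$Y
  group <- d$group
  k <- lengths(d$wlev)
  nw <- length(d$within)

  # orthonormal basis blocks per factor: averaging vector and contrasts
  u <- map(k, ~ matrix(1 / sqrt(.x), .x, 1))
  C <- map(k, orthonorm_contrasts)

  effects <- list()
  mauchly <- list()

  # between-subjects stratum
  u_all <- if (nw == 1) u[[1]] else kronecker(u[[2]], u[[1]])
  st0 <- type3_stratum(Y %*% u_all, group)
  if (!is.null(group)) {
    effects[[length(effects) + 1]] <- tibble(
      effect = "between",
      F = (st0$ss_grp / st0$df_grp) / (st0$ss_err / st0$df_err),
      df_num = st0$df_grp, df_den = st0$df_err, epsilon_gg = NA_real_,
      ss_effect = st0$ss_grp, ss_error = st0$ss_err
    )
  }
  ss_subject <- st0$ss_err
  df_subject <- st0$df_err

  # within effects: every nonempty subset of the within factors
  subsets <- if (nw == 1) list(1L) else list(1L, 2L, c(1L, 2L))
  for (e in subsets) {
    blocks <- map(seq_len(nw), function(f) if (f %in% e) C[[f]] else u[[f]])
    M <- if (nw == 1) blocks[[1]] else kronecker(blocks[[2]], blocks[[1]])
    q <- ncol(M)
    Z <- Y %*% M
    st <- type3_stratum(Z, group)
    pc <- pooled_within_cov(Z, group)
    eps <- gg_epsilon(pc$S)
    ename <- paste(d$within[e], collapse = ":")
    df1 <- q
    df2 <- q * st$df_err
    effects[[length(effects) + 1]] <- tibble(
      effect = ename,
      F = (st$ss_int / df1) / (st$ss_err / df2),
      df_num = df1, df_den = df2, epsilon_gg = eps,
      ss_effect = st$ss_int, ss_error = st$ss_err
    )
    if (!is.null(group)) {
      dfg1 <- q * st$df_grp
      effects[[length(effects) + 1]] <- tibble(
        effect = paste(ename, "sex_between", sep = ":"),
        F = (st$ss_grp / dfg1) / (st$ss_err / df2),
        df_num = dfg1, df_den = df2, epsilon_gg = eps,
        ss_effect = st$ss_grp, ss_error = st$ss_err
      )
    }
    if (q >= 2) {
      mt <- mauchly_from_cov(pc$S, pc$df)
      mauchly[[length(mauchly) + 1]] <- tibble(
        effect = ename, W = mt$W, chi_sq = mt$chi_sq, df = mt$df, p = mt$p
      )
    }
  }

  eff <- dplyr::bind_rows(effects)
  # rename the between row and interaction labels with the true factor name
  if (!is.null(between)) {
    eff$effect[eff$effect == "between"] <- between
    eff$effect <- sub(":sex_between$", paste0(":", between), eff$effect)
  }
  eff$p_uncorrected <- stats::pf(eff$F, eff$df_num, eff$df_den,
                                 lower.tail = FALSE)
  eps_use <- ifelse(is.na(eff$epsilon_gg), 1, eff$epsilon_gg)
  eff$p_gg <- stats::pf(eff$F, eps_use * eff$df_num, eps_use * eff$df_den,
                        lower.tail = FALSE)
  eff$partial_eta_sq <- eff$ss_effect / (eff$ss_effect + eff$ss_error)
  eff <- eff[, c("effect", "F", "df_num", "df_den", "epsilon_gg",
                 "p_uncorrected", "p_gg", "partial_eta_sq",
                 "ss_effect", "ss_error")]

  structure(
    list(
      effects = eff,
      mauchly = if (length(mauchly)) dplyr::bind_rows(mauchly) else
        tibble(effect = character(), W = double(), chi_sq = double(),
               df = double(), p = double()),
      ss_subject = ss_subject, df_subject = df_subject,
      design = list(dv = dv, within = within, between = between,
                    subject = subject, n_subjects = d$n,
                    within_levels = d$wlev,
                    group_sizes = if (is.null(group)) d$n else table(group)),
      data = as_tibble(data[, c(subject, between, within, dv)])
    ),
    class = "eqi_anova"
  )
}

#' @export
print.eqi_anova <- function(x, ...) {
  des <- x$design
  cat(sprintf("Mixed repeated-measures ANOVA: %s ~ %s%s (n = %d subjects)\n",
              des$dv, paste(des$within, collapse = " * "),
              if (!is.null(des$between)) paste0(" * ", des$between) else "",
              des$n_subjects))
  eff <- x$effects
  eff$F <- round(eff$F, 3)
  eff$epsilon_gg <- round(eff$epsilon_gg, 3)
  eff$p_uncorrected <- signif(eff$p_uncorrected, 3)
  eff$p_gg <- signif(eff$p_gg, 3)
  eff$partial_eta_sq <- round(eff$partial_eta_sq, 3)
  print(as.data.frame(eff[, c("effect", "F", "df_num", "df_den", "epsilon_gg",
                              "p_gg", "partial_eta_sq")]), row.names = FALSE)
  invisible(x)
}

#' Tidy an rm-ANOVA fit
#'
#' @param x An `eqi_anova`.
#' @param ... Unused.
#' @return Tibble with one row per effect: `effect`, `F`, `df_num`, `df_den`,
#'   `epsilon_gg`, `p_uncorrected`, `p_gg`, `partial_eta_sq`, `ss_effect`,
#'   `ss_error`.
#' @export
tidy.eqi_anova <- function(x, ...) {
  x$effects
}

#' @rdname tidy.eqi_anova
#' @return For `glance()`: one-row tibble with design summary.
#' @export
glance.eqi_anova <- function(x, ...) {
  tibble(
    n_subjects = x$design$n_subjects,
    n_within_cells = prod(lengths(x$design$within_levels)),
    n_effects = nrow(x$effects),
    min_p_gg = min(x$effects$p_gg)
  )
}

#' Effect-size plot of an rm-ANOVA fit
#'
#' Partial eta-squared per effect, with the conventional small/medium/large
#' reference lines (0.01, 0.06, 0.14).
#'
#' @param object An `eqi_anova`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eqi_anova <- function(object, ...) {
  eff <- object$effects
  eff$effect <- factor(eff$effect, levels = rev(eff$effect))
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$partial_eta_sq, y = .data$effect)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = c(0.01, 0.06, 0.14), linetype = 3) +
    ggplot2::labs(x = expression(partial ~ eta^2), y = NULL)
}

#' Mauchly's test of sphericity
#'
#' Tests sphericity of a within-subject factor's covariance from the
#' orthonormalised contrast scores: `W = det(S) / (tr(S)/q)^q` with the
#' chi-square approximation on `k(k-1)/2 - 1` degrees of freedom. Covariance
#' is pooled within between-groups when a between factor is given. With two
#' levels sphericity holds trivially and the test is not applicable.
#'
#' @inheritParams mixed_rm_anova
#' @param within A single within-subject factor column (k >= 3 levels).
#' @return Tibble with `effect`, `W`, `chi_sq`, `df`, `p`, `applicable`.
#'   For k = 2 the test statistics are `NA` and `applicable` is `FALSE`.
#' @export
mauchly_test <- function(data, dv, within, subject, between = NULL) {
  stopifnot(length(within) == 1)
  d <- rm_design(data, dv = dv,
                 within = within, between = between, subject = subject)
  k <- lengths(d$wlev)[1]
  if (k < 3) {
    return(tibble(effect = within, W = NA_real_, chi_sq = NA_real_,
                  df = NA_real_, p = NA_real_, applicable = FALSE))
  }
  Z <- d$Y %*% orthonorm_contrasts(k)
  pc <- pooled_within_cov(Z, d$group)
  mt <- mauchly_from_cov(pc$S, pc$df)
  tibble(effect = within, W = mt$W, chi_sq = mt$chi_sq, df = mt$df, p = mt$p,
         applicable = TRUE)
}

#' Bonferroni-corrected pairwise post hoc tests
#'
#' Paired t-tests between every pair of levels of a within-subject factor on
#' subject-level means (the response averaged over all other design cells per
#' subject), with the p value multiplied by the number of pairs and capped at
#' 1. The Bonferroni family is the factor's pairwise comparisons only.
#'
#' @inheritParams mixed_rm_anova
#' @param factor The within-subject factor column to compare.
#' @return Tibble: `level_a`, `level_b`, `mean_diff` (a minus b), `t`, `df`,
#'   `p_raw`, `p_bonferroni`.
#' @export
bonferroni_posthoc <- function(data, factor, dv, subject) {
  for (v in c(factor, dv, subject)) {
    if (!v %in% names(data)) abort(paste0("column '", v, "' not found"))
  }
  lev <- sort(unique(data[[factor]]))
  if (length(lev) < 2) abort("factor needs >= 2 levels")
  subj <- factor(data[[subject]])
  # subject x level means, collapsing any other design factors
  M <- tapply(data[[dv]], list(subj, factor(data[[factor]], levels = lev)),
              mean)
  if (anyNA(M)) abort("each subject needs data at every factor level")
  pairs <- utils::combn(seq_along(lev), 2)
  m <- ncol(pairs)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    dif <- M[, a] - M[, b]
    n <- length(dif)
    se <- stats::sd(dif) / sqrt(n)
    tval <- if (se == 0) 0 else mean(dif) / se
    p <- if (se == 0 && mean(dif) == 0) 1 else
      2 * stats::pt(abs(tval), n - 1, lower.tail = FALSE)
    out[[j]] <- tibble(
      level_a = lev[a], level_b = lev[b], mean_diff = mean(dif),
      t = tval, df = n - 1, p_raw = p, p_bonferroni = min(1, m * p)
    )
  }
  dplyr::bind_rows(out)
}

#' Estimated marginal means with 95% confidence intervals
#'
#' Model-based cell means for a combination of design factors, averaging the
#' response over the pooled (omitted) within-subject factors within each
#' subject first, then over subjects. The standard error of a cell uses the
#' within-group variance of those subject-level scores at that within-level
#' combination, pooled across between-groups (homoscedastic across groups),
#' with `n_subjects - n_groups` degrees of freedom — the multivariate-model
#' covariance, which is exact for balanced within-designs and handles unequal
#' group sizes. Consequently adding a constant to the response shifts every
#' estimate but leaves interval widths unchanged.
#'
#' @inheritParams mixed_rm_anova
#' @param by Character vector of factor columns to keep (may mix within and
#'   between factors); all other within factors are pooled.
#' @param level Confidence level (default 0.95).
#' @return Tibble: one row per `by`-cell with `estimate`, `se`, `df`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
estimated_marginal_means <- function(data, by, dv, subject, between = NULL,
                                     level = 0.95) {
  for (v in c(by, dv, subject, between)) {
    if (!v %in% names(data)) abort(paste0("column '", v, "' not found"))
  }
  subj <- factor(data[[subject]])
  by_between <- if (!is.null(between)) intersect(by, between) else character(0)
  by_within <- setdiff(by, by_between)

  # subject-level scores at each kept within combination (pool the rest)
  if (length(by_within) > 0) {
    wcell <- interaction(lapply(by_within, function(v)
      factor(data[[v]], levels = sort(unique(data[[v]])))), drop = FALSE,
      lex.order = FALSE)
  } else {
    wcell <- factor(rep("(all)", nrow(data)))
  }
  V <- tapply(data[[dv]], list(subj, wcell), mean)
  if (anyNA(V)) abort("empty cell: every subject needs data in every kept cell")

  grp <- if (!is.null(between)) {
    factor(unlist(tapply(as.character(data[[between]]), subj, unique)))
  } else {
    factor(rep("(all)", nlevels(subj)))
  }
  G <- nlevels(grp)
  n_tot <- nlevels(subj)
  df_err <- n_tot - G

  rows <- list()
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    # pooled within-group variance at this within combination
    ssw <- sum(tapply(v, grp, function(x) sum((x - mean(x))^2)))
    s2 <- ssw / df_err
    keep_groups <- if (length(by_between) > 0) levels(grp) else "(all)"
    for (g in keep_groups) {
      vg <- if (g == "(all)") v else v[grp == g]
      est <- mean(vg)
      se <- sqrt(s2 / length(vg))
      tcrit <- stats::qt(1 - (1 - level) / 2, df_err)
      rows[[length(rows) + 1]] <- tibble(
        cell_within = colnames(V)[j],
        cell_between = g,
        estimate = est, se = se, df = df_err,
        ci_low = est - tcrit * se, ci_high = est + tcrit * se,
        n = length(vg)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  # expand the interaction label back into the original columns
  if (length(by_within) > 0) {
    parts <- do.call(rbind, strsplit(out$cell_within, ".", fixed = TRUE))
    for (i in seq_along(by_within)) out[[by_within[i]]] <- parts[, i]
  }
  if (length(by_between) > 0) out[[by_between]] <- out$cell_between
  out$cell_within <- NULL
  out$cell_between <- NULL
  out[, c(by, "estimate", "se", "df", "ci_low", "ci_high", "n")]
}
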