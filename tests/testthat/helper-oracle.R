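# Independent oracles used to verify the implementation.
#
# The rm-ANOVA oracle works by explicit design-matrix projections on
# subject-centred level means: Type III sums of squares are obtained as
# residual-sum-of-squares differences between sum-coded model matrices with
# a term's columns dropped, stratum by stratum. The Greenhouse-Geisser
# oracle computes epsilon from the eigenvalues of the centred (projected)
# pooled covariance. Both are deliberately different computational routes
# from the package implementation (closed-form Type III on orthonormal
# contrast scores; trace formulas).

oracle_rm_anova <- function(data, dv, within, between = NULL, subject) {
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  subj <- factor(data[[subject]])
  wf <- lapply(within, function(w)
    factor(data[[w]], levels = sort(unique(data[[w]]))))
  names(wf) <- within
  k <- vapply(wf, nlevels, 0L)
  n <- nlevels(subj)
  y <- data[[dv]]
  grp <- if (!is.null(between)) {
    factor(unlist(tapply(as.character(data[[between]]), subj, unique)))
  } else NULL
  G <- if (is.null(grp)) 1L else nlevels(grp)
  p_cells <- prod(k)

  rss <- function(X, z) sum(lm.fit(X, z)$residuals^2)
  out <- list()

  # ---- between-subject stratum: subject means, scaled back to long SS
  ybar <- tapply(y, subj, mean)
  if (!is.null(grp)) {
    Xf <- model.matrix(~g, data.frame(g = grp))
    ss_b <- (rss(Xf[, 1, drop = FALSE], ybar) - rss(Xf, ybar)) * p_cells
    ss_s <- rss(Xf, ybar) * p_cells
    out[[length(out) + 1]] <- data.frame(
      effect = "between", ss = ss_b, df = G - 1,
      ss_err = ss_s, df_err = n - G, epsilon = NA_real_
    )
  } else {
    ss_s <- rss(matrix(1, n, 1), ybar) * p_cells
  }

  # pooled within-group covariance of a subjects-x-levels matrix
  pooled_cov <- function(D) {
    if (is.null(grp)) {
      S <- crossprod(scale(D, scale = FALSE)) / (n - 1)
    } else {
      S <- 0
      for (g in levels(grp)) {
        Dg <- D[grp == g, , drop = FALSE]
        S <- S + crossprod(scale(Dg, scale = FALSE))
      }
      S <- S / (n - G)
    }
    S
  }
  eps_eigen <- function(S, proj, q) {
    A <- proj %*% S %*% proj
    lam <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)[seq_len(q)]
    max(min(sum(lam)^2 / (q * sum(lam^2)), 1), 1 / q)
  }
  centering <- function(m) diag(m) - matrix(1 / m, m, m)

  # ---- within main effects
  for (wi in seq_along(within)) {
    w <- within[wi]
    D <- tapply(y, list(subj, wf[[w]]), mean)      # n x k, means over others
    scale_f <- p_cells / k[wi]
    Dc <- D - rowMeans(D)                          # remove subject means
    long <- data.frame(
      d = as.vector(Dc),
      w = factor(rep(colnames(D), each = n), levels = colnames(D))
    )
    if (!is.null(grp)) long$g <- rep(grp, times = k[wi])
    Xf <- if (is.null(grp)) model.matrix(~w, long) else
      model.matrix(~g * w, long)
    asg <- attr(Xf, "assign")
    labs <- attr(terms(if (is.null(grp)) ~w else ~g * w), "term.labels")
    keep_not <- function(lbl) Xf[, asg != match(lbl, labs), drop = FALSE]
    ss_w <- (rss(keep_not("w"), long$d) - rss(Xf, long$d)) * scale_f
    ss_e <- rss(Xf, long$d) * scale_f
    S <- pooled_cov(D)
    eps <- eps_eigen(S, centering(k[wi]), k[wi] - 1)
    out[[length(out) + 1]] <- data.frame(
      effect = w, ss = ss_w, df = k[wi] - 1,
      ss_err = ss_e, df_err = (k[wi] - 1) * (n - G), epsilon = eps
    )
    if (!is.null(grp)) {
      ss_wg <- (rss(keep_not("g:w"), long$d) - rss(Xf, long$d)) * scale_f
      out[[length(out) + 1]] <- data.frame(
        effect = paste0(w, ":", between), ss = ss_wg, df = (k[wi] - 1) * (G - 1),
        ss_err = ss_e, df_err = (k[wi] - 1) * (n - G), epsilon = eps
      )
    }
  }

  # ---- within-within interaction (two within factors)
  if (length(within) == 2) {
    A <- tapply(y, list(subj, wf[[1]], wf[[2]]), mean)  # n x k1 x k2
    m1 <- apply(A, c(1, 2), mean)  # subject x w1
    m2 <- apply(A, c(1, 3), mean)  # subject x w2
    ms <- apply(A, 1, mean)
    Ac <- A
    for (i2 in seq_len(k[2])) {
      Ac[, , i2] <- A[, , i2] - m1 - matrix(m2[, i2] - ms, n, k[1])
    }
    long <- data.frame(
      d = as.vector(Ac),
      w1 = factor(rep(rep(dimnames(A)[[2]], each = n), k[2]),
                  levels = dimnames(A)[[2]]),
      w2 = factor(rep(dimnames(A)[[3]], each = n * k[1]),
                  levels = dimnames(A)[[3]])
    )
    if (!is.null(grp)) long$g <- rep(grp, times = k[1] * k[2])
    Xf <- if (is.null(grp)) model.matrix(~w1 * w2, long) else
      model.matrix(~g * w1 * w2, long)
    asg <- attr(Xf, "assign")
    labs <- attr(terms(if (is.null(grp)) ~w1 * w2 else ~g * w1 * w2),
                 "term.labels")
    keep_not <- function(lbl) Xf[, asg != match(lbl, labs), drop = FALSE]
    q <- (k[1] - 1) * (k[2] - 1)
    ss_int <- rss(keep_not("w1:w2"), long$d) - rss(Xf, long$d)
    ss_e <- rss(Xf, long$d)
    # covariance of the full cell layout (w1 varying fastest) for epsilon
    D_full <- matrix(A, n, k[1] * k[2])
    S <- pooled_cov(D_full)
    proj <- kronecker(centering(k[2]), centering(k[1]))
    eps <- eps_eigen(S, proj, q)
    out[[length(out) + 1]] <- data.frame(
      effect = paste0(within[1], ":", within[2]), ss = ss_int, df = q,
      ss_err = ss_e, df_err = q * (n - G), epsilon = eps
    )
    if (!is.null(grp)) {
      ss_ig <- rss(keep_not("g:w1:w2"), long$d) - rss(Xf, long$d)
      out[[length(out) + 1]] <- data.frame(
        effect = paste0(within[1], ":", within[2], ":", between),
        ss = ss_ig, df = q * (G - 1),
        ss_err = ss_e, df_err = q * (n - G), epsilon = eps
      )
    }
  }

  res <- do.call(rbind, out)
  res$F <- (res$ss / res$df) / (res$ss_err / res$df_err)
  res$p <- pf(res$F, res$df, res$df_err, lower.tail = FALSE)
  eps_use <- ifelse(is.na(res$epsilon), 1, res$epsilon)
  res$p_gg <- pf(res$F, eps_use * res$df, eps_use * res$df_err,
                 lower.tail = FALSE)
  if (!is.null(between)) res$effect[res$effect == "between"] <- between
  res
}

# exhaustive per-sample scans of the segmentation rules -----------------

oracle_onset <- function(trial, window = 0.25, min_drop = 1) {
  a <- trial$angle_deg
  n <- length(a)
  w <- as.integer(round(window * trial_meta(trial)$sampling_rate_hz))
  for (i in seq_len(n)) {
    if (i <= w) next  # no apex before one full window has elapsed
    j <- max(1, i - w):min(n, i + w)
    if (all(a[i] >= a[j]) && min(a[i:n]) <= a[i] - min_drop) return(i)
  }
  NA_integer_
}

oracle_offset <- function(trial, onset, rom_tolerance = 0.5,
                          half_load_fraction = 0.5, debounce = 0.1) {
  m <- trial_meta(trial)
  a <- trial$angle_deg
  tq <- trial$torque_nm
  n <- length(a)
  L <- max(1L, as.integer(ceiling(debounce * m$sampling_rate_hz)))
  thr <- half_load_fraction * m$prescribed_load_nm
  i_rom <- NA_integer_
  i_trq <- NA_integer_
  for (i in (onset + 1L):n) {
    if (is.na(i_rom) && is.finite(m$rom_df_deg) &&
        a[i] <= m$rom_df_deg + rom_tolerance) {
      i_rom <- i
    }
    if (is.na(i_trq) && is.finite(thr) && i + L - 1 <= n &&
        all(tq[i:(i + L - 1)] < thr)) {
      i_trq <- i
    }
    if (!is.na(i_rom) && !is.na(i_trq)) break
  }
  if (is.na(i_rom) && is.na(i_trq)) {
    list(offset_index = n, offset_reason = "open_ended")
  } else if (!is.na(i_rom) && (is.na(i_trq) || i_rom <= i_trq)) {
    list(offset_index = i_rom, offset_reason = "end_of_rom")
  } else {
    list(offset_index = i_trq, offset_reason = "torque_below_half_load")
  }
}
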