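# Statistical layer: one-sample t-tests against chance, mixed / repeated
# measures ANOVA with Greenhouse-Geisser correction, Bonferroni adjustment,
# partial eta squared and observed power.

#' One-sample t-test against a fixed value
#'
#' Two-tailed test of the mean against `mu` (chance = 50% for 2-AFC
#' scores). With zero variance the statistic is reported as signed
#' infinity with p = 0 (or t = 0, p = 1 when the mean equals `mu`).
#'
#' @param values Numeric vector (n >= 2).
#' @param mu Comparison value (default 50).
#' @return Data frame: `t`, `df`, `p`, `mean`, `sd`, `n`, `mu`.
#' @export
one_sample_t <- function(values, mu = 50) {
  n <- length(values)
  if (n < 2) stopf("need at least 2 values")
  m <- mean(values); s <- stats::sd(values)
  if (s == 0) {
    t <- if (m == mu) 0 else sign(m - mu) * Inf
    p <- if (m == mu) 1 else 0
    return(data.frame(t = t, df = n - 1, p = p, mean = m, sd = s, n = n, mu = mu))
  }
  tt <- stats::t.test(values, mu = mu)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, mean = m, sd = s, n = n, mu = mu)
}

#' One-sample t-test from summary statistics
#'
#' `t = (mean - mu) / (sd / sqrt(n))` with an n-1 denominator SD and a
#' two-tailed p from the t distribution; used to recompute published
#' statistics from printed cell means and SDs.
#'
#' @param mean,sd,n Summary statistics.
#' @param mu Comparison value (default 50).
#' @return Data frame as in [one_sample_t()].
#' @export
one_sample_t_summary <- function(mean, sd, n, mu = 50) {
  t <- (mean - mu) / (sd / sqrt(n))
  data.frame(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
             mean = mean, sd = sd, n = n, mu = mu)
}

#' Partial eta squared from an F statistic
#'
#' `F * df1 / (F * df1 + df2)`, identically `SS_effect / (SS_effect +
#' SS_error)`.
#'
#' @param f,df1,df2 F statistic and its degrees of freedom.
#' @return Effect size in \[0, 1\].
#' @export
partial_eta_sq <- function(f, df1, df2) {
  f * df1 / (f * df1 + df2)
}

#' Observed (post hoc) power of an F test
#'
#' Probability that a noncentral F with noncentrality `lambda = F * df1`
#' exceeds the alpha-level critical value — the convention used by common
#' commercial ANOVA software.
#'
#' @param f,df1,df2 Observed F and degrees of freedom.
#' @param alpha Test level (default 0.05).
#' @return Power in \[0, 1\].
#' @export
observed_power <- function(f, df1, df2, alpha = 0.05) {
  crit <- stats::qf(1 - alpha, df1, df2)
  1 - stats::pf(crit, df1, df2, ncp = f * df1)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for each p-value.
#'
#' @param p Raw p-values.
#' @param m Number of comparisons (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < 1) stopf("m must be >= 1")
  pmin(1, m * p)
}

#' Greenhouse-Geisser epsilon
#'
#' Computed from the covariance matrix of the within-factor measures via
#' normalized orthogonal contrasts: with `M = C' S C`,
#' `epsilon = tr(M)^2 / ((k - 1) * tr(M^2))`, clipped to
#' \[1 / (k - 1), 1\]. Factors with fewer than 3 levels trivially satisfy
#' sphericity and return 1.
#'
#' @param S Covariance matrix (k x k) of the k repeated measures.
#' @return Epsilon.
#' @export
gg_epsilon <- function(S) {
  k <- nrow(S)
  if (is.null(k) || k < 3) return(1)
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  M <- t(C) %*% S %*% C
  eps <- sum(diag(M))^2 / ((k - 1) * sum(M^2))
  min(max(eps, 1 / (k - 1)), 1)
}

cell_key <- function(df, cols) do.call(paste, c(df[cols], sep = "."))

reshape_wide <- function(data, dv, subject, within, between) {
  for (col in c(within, between)) data[[col]] <- factor(data[[col]])
  cells <- unique(data[within])
  cells <- cells[do.call(order, cells), , drop = FALSE]
  keys <- cell_key(cells, within)
  data$..cell <- cell_key(data, within)
  subs <- unique(data[c(subject, between)])
  y <- matrix(NA_real_, nrow = nrow(subs), ncol = nrow(cells),
              dimnames = list(subs[[subject]], keys))
  for (i in seq_len(nrow(subs))) {
    rows <- data[data[[subject]] == subs[[subject]][i], ]
    idx <- match(keys, rows$..cell)
    if (anyNA(idx)) {
      stopf("subject %s is missing cell(s): %s", subs[[subject]][i],
            paste(keys[is.na(idx)], collapse = ", "))
    }
    if (anyDuplicated(rows$..cell))
      stopf("subject %s has duplicated cells", subs[[subject]][i])
    y[i, ] <- rows[[dv]][idx]
  }
  list(y = y, cells = cells, subs = subs)
}

#' Mixed (split-plot) ANOVA with Greenhouse-Geisser correction
#'
#' Univariate repeated-measures ANOVA with an optional between-subject
#' factor, Type III sums of squares with sum-to-zero contrasts (so
#' between-group effects test unweighted marginal means under unequal
#' group sizes). The Greenhouse-Geisser epsilon adjusts the p-value of
#' within effects with more than two levels; two-level factors trivially
#' satisfy sphericity (epsilon = 1). Each effect carries partial eta
#' squared and observed power at alpha = 0.05.
#'
#' @param data Long data frame, one row per subject x within-cell.
#' @param dv Name of the response column.
#' @param subject Name of the subject identifier column.
#' @param within Character vector of within-subject factor names.
#' @param between Optional between-subject factor name.
#' @param alpha Level used for the observed-power computation.
#' @return Data frame of class `sl_anova`: `effect`, `ss`, `ss_error`,
#'   `df1`, `df2`, `F`, `epsilon`, `p` (epsilon-adjusted where epsilon
#'   < 1), `p_unadj`, `eta_p2`, `power`.
#' @export
mixed_anova <- function(data, dv, subject, within, between = NULL,
                        alpha = 0.05) {
  rw <- reshape_wide(data, dv, subject, within, between)
  idata <- rw$cells
  for (col in within) idata[[col]] <- factor(idata[[col]])
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  y <- rw$y
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  if (is.null(between)) {
    mod <- stats::lm(y ~ 1)
  } else {
    g <- factor(rw$subs[[between]])
    if (nlevels(g) < 2 || any(table(g) < 2))
      stopf("need >= 2 subjects in each of >= 2 groups")
    mod <- stats::lm(y ~ g)
  }
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  s <- summary(av, multivariate = FALSE)
  ut <- s$univariate.tests
  eff <- rownames(ut)
  keep <- eff != "(Intercept)"
  out <- data.frame(
    effect = gsub("^g($|:)", paste0(between %||% "g", "\\1"), eff[keep]),
    ss = ut[keep, "Sum Sq"], ss_error = ut[keep, "Error SS"],
    df1 = ut[keep, "num Df"], df2 = ut[keep, "den Df"],
    F = ut[keep, "F value"], epsilon = 1,
    p = ut[keep, "Pr(>F)"], p_unadj = ut[keep, "Pr(>F)"],
    stringsAsFactors = FALSE)
  adj <- s$pval.adjustments
  if (!is.null(adj) && nrow(adj) > 0) {
    i <- match(rownames(adj), out$effect)
    # two-level factors trivially satisfy sphericity; car reports NA there
    ok <- !is.na(i) & is.finite(adj[, "GG eps"])
    out$epsilon[i[ok]] <- adj[ok, "GG eps"]
    out$p[i[ok]] <- adj[ok, "Pr(>F[GG])"]
  }
  out$eta_p2 <- partial_eta_sq(out$F, out$df1, out$df2)
  out$power <- observed_power(out$F, out$df1, out$df2, alpha = alpha)
  rownames(out) <- NULL
  class(out) <- c("sl_anova", "data.frame")
  out
}

#' Repeated-measures ANOVA (within-subject factors only)
#'
#' [mixed_anova()] without a between-subject factor.
#'
#' @inheritParams mixed_anova
#' @return An `sl_anova` table.
#' @export
rm_anova <- function(data, dv, subject, within, alpha = 0.05) {
  mixed_anova(data, dv, subject, within, between = NULL, alpha = alpha)
}

#' Bonferroni-adjusted pairwise comparisons of within-factor levels
#'
#' Paired t-tests between all level pairs of one within-subject factor
#' (averaging over any other cells per subject), p-values multiplied by
#' the number of comparisons.
#'
#' @param data Long data frame.
#' @param dv,subject,factor Column names.
#' @return Data frame: `contrast`, `mean_diff`, `t`, `df`, `p_raw`,
#'   `p_adj`.
#' @export
pairwise_bonferroni <- function(data, dv, subject, factor) {
  lv <- unique(data[[factor]])
  agg <- stats::aggregate(data[[dv]],
                          by = list(s = data[[subject]], f = data[[factor]]),
                          FUN = mean)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- agg$x[agg$f == pr[1]][order(agg$s[agg$f == pr[1]])]
    b <- agg$x[agg$f == pr[2]][order(agg$s[agg$f == pr[2]])]
    tt <- stats::t.test(a, b, paired = TRUE)
    data.frame(contrast = paste(pr[1], "-", pr[2]),
               mean_diff = mean(a) - mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni_adjust(out$p_raw, length(pairs))
  out
}
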