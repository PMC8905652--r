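test_that("one-sample t-tests agree with stats::t.test and closed forms", {
  set.seed(1)
  x <- rnorm(15, 55, 12)
  got <- one_sample_t(x, mu = 50)
  ref <- t.test(x, mu = 50)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  expect_equal(got$df, 14)
  expect_equal(one_sample_t(rep(50, 5))$t, 0)
  expect_equal(one_sample_t(rep(50, 5))$p, 1)
  z <- one_sample_t(rep(60, 5))
  expect_equal(z$t, Inf)
  expect_equal(z$p, 0)
})

test_that("published t statistics recompute from the printed cells", {
  # explicit task, n = 21 adults: high-TP and low-TP cells
  t_hi <- one_sample_t_summary(61.4, 20.12, 21, mu = 50)
  t_lo <- one_sample_t_summary(65.5, 20.08, 21, mu = 50)
  expect_lt(abs(t_hi$t - 2.592), 0.02)
  expect_lt(abs(t_lo$t - 3.543), 0.02)
  expect_equal(t_hi$df, 20)
  expect_lt(t_lo$p, 0.01)
})

test_that("repeated-measures ANOVA matches the contrast-score oracle", {
  # 2x2 within design, 4 subjects, hand-enumerable
  d <- expand.grid(subject = paste0("s", 1:4), task = c("implicit", "explicit"),
                   tp_class = c("high", "low"), stringsAsFactors = FALSE)
  set.seed(3)
  d$y <- rnorm(nrow(d), 50, 10) + ifelse(d$task == "explicit", 5, 0)
  got <- rm_anova(d, "y", "subject", within = c("task", "tp_class"))
  ora <- oracle_anova_f(d, "y", "subject", within = c("task", "tp_class"))
  for (eff in names(ora))
    expect_equal(got$F[got$effect == eff], ora[[eff]], tolerance = 1e-9)
  # all factors 2-level: sphericity trivially satisfied
  expect_true(all(got$epsilon == 1))
  expect_equal(got$df1, rep(1, 3))
  expect_equal(got$df2, rep(3, 3))
})

test_that("three-way within ANOVA matches the oracle and is label-symmetric", {
  d <- expand.grid(subject = paste0("s", 1:6), task = c("i", "e"),
                   tp_class = c("h", "l"), half = c("1", "2"),
                   stringsAsFactors = FALSE)
  set.seed(4)
  d$y <- rnorm(nrow(d), 0, 2) + ifelse(d$tp_class == "h", -1.5, 0)
  got <- rm_anova(d, "y", "subject", within = c("task", "tp_class", "half"))
  ora <- oracle_anova_f(d, "y", "subject", within = c("task", "tp_class", "half"))
  for (eff in names(ora))
    expect_equal(got$F[got$effect == eff], ora[[eff]], tolerance = 1e-9)
  # factor order permutation leaves the statistics unchanged
  got2 <- rm_anova(d, "y", "subject", within = c("half", "task", "tp_class"))
  for (eff in got$effect) {
    parts <- sort(strsplit(eff, ":")[[1]])
    match2 <- vapply(got2$effect, function(e)
      identical(sort(strsplit(e, ":")[[1]]), parts), logical(1))
    expect_equal(got2$F[match2], got$F[got$effect == eff], tolerance = 1e-9)
  }
})

test_that("mixed ANOVA with unbalanced groups matches the unweighted oracle", {
  d <- expand.grid(subject = paste0("s", 1:9), task = c("i", "e"),
                   tp_class = c("h", "l"), stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 5, "adults", "children")
  set.seed(5)
  d$y <- rnorm(nrow(d), 50, 8) + ifelse(d$group == "adults", 6, 0)
  got <- mixed_anova(d, "y", "subject", within = c("task", "tp_class"),
                     between = "group")
  ora <- oracle_anova_f(d, "y", "subject", within = c("task", "tp_class"),
                        between = "group")
  for (eff in names(ora)) {
    sel <- got$effect == eff |
      got$effect == paste(rev(strsplit(eff, ":")[[1]]), collapse = ":")
    expect_equal(got$F[sel], ora[[eff]], tolerance = 1e-9)
  }
  # adding a constant changes no F statistic
  d2 <- d; d2$y <- d2$y + 123.4
  got2 <- mixed_anova(d2, "y", "subject", within = c("task", "tp_class"),
                      between = "group")
  expect_equal(got2$F, got$F, tolerance = 1e-9)
  # partial eta squared identity against the SS decomposition
  expect_equal(got$eta_p2, got$ss / (got$ss + got$ss_error), tolerance = 1e-12)
  # missing cell is reported with the offending subject
  expect_error(mixed_anova(d[-1, ], "y", "subject",
                           within = c("task", "tp_class"), between = "group"),
               "missing cell")
})

test_that("Greenhouse-Geisser epsilon follows its defining formula", {
  # compound symmetry -> sphericity holds -> epsilon = 1
  S_cs <- diag(4) * 2 + 1
  expect_equal(gg_epsilon(S_cs), 1)
  expect_equal(gg_epsilon(diag(2)), 1)   # k = 2 trivially spherical
  # a constructed sphericity-violating 3-level covariance
  S <- matrix(c(4, 2.5, 0.5,
                2.5, 3, 1,
                0.5, 1, 1.5), 3, byrow = TRUE)
  expect_equal(gg_epsilon(S), oracle_gg_epsilon(S), tolerance = 1e-12)
  expect_lt(gg_epsilon(S), 1)
  expect_gte(gg_epsilon(S), 1 / 2)       # clipped at 1/(k-1)
})

test_that("the ANOVA applies the GG correction to >2-level within factors", {
  set.seed(8)
  n <- 12
  base <- rnorm(n, 0, 3)
  d <- data.frame(
    subject = rep(paste0("s", 1:n), 3),
    cond = rep(c("a", "b", "c"), each = n),
    y = c(base + rnorm(n, 0, 0.5), base + rnorm(n, 0, 2.5),
          rnorm(n, 0, 1.5)))
  got <- rm_anova(d, "y", "subject", within = "cond")
  y <- matrix(d$y, n)   # subjects x 3 levels
  eps_direct <- gg_epsilon(cov(y))
  expect_equal(got$epsilon[got$effect == "cond"], eps_direct, tolerance = 1e-8)
  expect_lt(got$epsilon[got$effect == "cond"], 1)
  # the reported p equals the F tail at epsilon-scaled degrees of freedom
  row <- got[got$effect == "cond", ]
  expect_equal(row$p, pf(row$F, row$df1 * row$epsilon, row$df2 * row$epsilon,
                         lower.tail = FALSE), tolerance = 1e-8)
})

test_that("effect-size and power conventions reproduce the published values", {
  expect_lt(abs(partial_eta_sq(4.791, 1, 39) - 0.109), 0.001)
  expect_lt(abs(partial_eta_sq(11.979, 1, 39) - 0.235), 0.001)
  expect_equal(partial_eta_sq(0, 1, 39), 0)
  expect_lt(abs(observed_power(4.791, 1, 39) - 0.569), 0.005)
  expect_lt(abs(observed_power(11.979, 1, 39) - 0.921), 0.005)
  expect_gt(observed_power(500, 1, 39), 0.9999)   # power -> 1 for large F
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.6, 3), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.04), 1), c(0.2, 0.04))
  expect_equal(bonferroni_adjust(c(0.01, 0.02)), p.adjust(c(0.01, 0.02), "bonferroni"))
  d <- data.frame(subject = rep(1:6, 2), f = rep(c("x", "y"), each = 6),
                  y = c(rnorm(6), rnorm(6, 2)))
  pw <- pairwise_bonferroni(d, "y", "subject", "f")
  expect_equal(nrow(pw), 1)
  expect_equal(pw$p_adj, pmin(1, pw$p_raw))
})

test_that("ANOVA effect-size estimates are calibrated against a closed form", {
  # paired 2-level within design: F = t^2 with noncentrality sqrt(n) d / s;
  # the mean estimated eta_p^2 over replicates must match the expectation
  # under the noncentral F law, computed by numeric integration
  n <- 12; delta <- 1.2; sd_diff <- 2
  df2 <- n - 1
  ncp <- n * (delta / sd_diff)^2
  expected <- integrate(function(f)
    partial_eta_sq(f, 1, df2) * df(f, 1, df2, ncp = ncp), 0, Inf,
    rel.tol = 1e-9)$value
  set.seed(11)
  est <- replicate(400, {
    diff <- rnorm(n, delta, sd_diff)
    base <- rnorm(n, 0, 3)
    d <- data.frame(subject = rep(seq_len(n), 2),
                    cond = rep(c("a", "b"), each = n),
                    y = c(base + diff / 2, base - diff / 2))
    a <- rm_anova(d, "y", "subject", within = "cond")
    a$eta_p2[a$effect == "cond"]
  })
  expect_lt(abs(mean(est) - expected), 3 * sd(est) / sqrt(length(est)))
})
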