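# Independent oracles used across the suite: everything here is computed
# from definitions (loops, contrast scores, closed forms), never through
# the code paths it checks.

# Brute-force adjacency/count scan of a word sequence, written directly
# against the constraint definitions rather than via audit_word_sequence().
scan_sequence <- function(sq) {
  lex <- attr(sq, "lexicon")
  w <- lex$words
  reps <- attr(sq, "reps_per_block")
  ok <- TRUE
  for (b in unique(sq$block)) {
    ids <- sq$word_id[sq$block == b]
    for (wid in w$id) ok <- ok && sum(ids == wid) == reps
  }
  ids <- sq$word_id
  for (i in seq_len(length(ids) - 1)) {
    a <- ids[i]; b <- ids[i + 1]
    if (a == b) ok <- FALSE
    if (w$syl3[w$id == a] == w$syl1[w$id == b]) ok <- FALSE
  }
  ok
}

# Triple-loop artifact-rejection oracle.
oracle_reject_mask <- function(data, threshold) {
  n_ep <- dim(data)[1]
  keep <- logical(n_ep)
  for (e in seq_len(n_ep)) {
    bad <- FALSE
    for (ch in seq_len(dim(data)[2])) {
      for (s in seq_len(dim(data)[3])) {
        if (abs(data[e, ch, s]) > threshold) bad <- TRUE
      }
    }
    keep[e] <- !bad
  }
  keep
}

# Double-loop ROI/window mean oracle.
oracle_roi_mean <- function(erp, times, channels, electrodes, window) {
  tot <- 0; n <- 0
  for (ch in electrodes) {
    for (s in seq_along(times)) {
      if (times[s] >= window[1] && times[s] <= window[2]) {
        tot <- tot + erp[which(channels == ch), s]
        n <- n + 1
      }
    }
  }
  unname(tot / n)
}

# Contrast-score sums-of-squares oracle for factorial repeated-measures
# designs in which every within factor has 2 levels (optional 2+-group
# between factor). Each within effect (and its interaction with the group)
# reduces to a one-sample / one-way ANOVA on a per-subject contrast score;
# the between main effect to a one-way ANOVA on subject means. Type III /
# unweighted-means solution via sum-to-zero contrasts.
oracle_anova_f <- function(data, dv, subject, within, between = NULL) {
  cells <- unique(data[within])
  cells <- cells[do.call(order, cells), , drop = FALSE]
  key <- function(df) do.call(paste, c(df[within], sep = "."))
  ck <- key(cells)
  subs <- unique(data[c(subject, between)])
  y <- matrix(NA_real_, nrow(subs), nrow(cells))
  for (i in seq_len(nrow(subs))) {
    rows <- data[data[[subject]] == subs[[subject]][i], ]
    y[i, ] <- rows[[dv]][match(ck, key(rows))]
  }
  g <- if (is.null(between)) NULL else factor(subs[[between]])
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  out <- list()
  effects <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, paste, collapse = ":", simplify = FALSE)))
  for (eff in effects) {
    parts <- strsplit(eff, ":")[[1]]
    ct <- rep(1, nrow(cells))
    for (p in parts) {
      lv <- sort(unique(as.character(cells[[p]])))
      ct <- ct * ifelse(as.character(cells[[p]]) == lv[1], 0.5, -0.5)
    }
    sc <- as.vector(y %*% ct)
    if (is.null(g)) {
      tt <- stats::t.test(sc)
      out[[eff]] <- unname(tt$statistic)^2
    } else {
      m <- stats::lm(sc ~ g)
      co <- summary(m)$coefficients
      out[[eff]] <- co["(Intercept)", "t value"]^2
      av <- stats::anova(m)
      out[[paste0(between, ":", eff)]] <- av["g", "F value"]
    }
  }
  if (!is.null(g)) {
    sm <- rowMeans(y)
    av <- stats::anova(stats::lm(sm ~ g))
    out[[between]] <- av["g", "F value"]
  }
  out
}

# Greenhouse-Geisser epsilon straight from its defining formula, with an
# explicitly orthonormalized random contrast basis (independent of the
# helmert basis used by the implementation).
oracle_gg_epsilon <- function(S) {
  k <- nrow(S)
  set.seed(99)
  B <- matrix(rnorm(k * (k - 1)), k)
  B <- sweep(B, 2, colMeans(B))          # orthogonal to the unit vector
  Q <- qr.Q(qr(B))[, seq_len(k - 1)]
  M <- t(Q) %*% S %*% Q
  sum(diag(M))^2 / ((k - 1) * sum(M^2))
}

# A reduced-montage effect spec used by the simulation studies: central
# ROI electrodes plus mastoids, adjustable rate/noise/effects.
calibration_spec <- function(rate = 128, noise_sd = 10, artifact_rate = 0.15,
                             d_tp = 0, d_half = 0, subject_sd = 0.5) {
  spec <- default_effect_spec("adults", noise_sd = noise_sd,
                              artifact_rate = artifact_rate,
                              sample_rate = rate,
                              montage = canonical_rois()$central)
  spec$components$N100$d_task <- 0
  spec$components$N100$d_half <- d_half
  spec$components$N400$d_tp <- d_tp
  spec$components$N400$d_half <- d_half
  spec$subject_sd <- subject_sd
  spec
}

# One simulated experiment through the full pipeline (one task): returns
# the N400 amplitude table for included subjects.
run_erp_experiment <- function(timeline, spec, n_subjects, seed) {
  sims <- simulate_eeg(timeline, spec, n_subjects = n_subjects,
                       task = "implicit", seed = seed)
  rows <- list()
  for (s in seq_along(sims)) {
    pr <- process_subject(sims[[s]]$eeg, sims[[s]]$events, group = "adults")
    if (!isTRUE(as.logical(pr$included))) next
    m <- pr$measures
    m$subject <- paste0("s", s)
    rows[[length(rows) + 1]] <- m
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}
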