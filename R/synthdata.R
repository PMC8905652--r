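# Synthetic behavioural and EEG data with the statistical structure the
# analysis pipeline assumes, so every downstream stage is testable without
# a recording session.

#' Canonical behavioural profile
#'
#' Per (group x task x word-type) cell: the true 2-AFC accuracy and the
#' between-subject standard deviation the simulator is calibrated to, with
#' the analyzed sample sizes (21 adults, 20 children) and 8 trials per
#' word type. The cell means and SDs are the published group-level 2-AFC
#' summaries for this paradigm.
#'
#' @param n_adults,n_children Subjects per group.
#' @return Data frame of class `sl_behavior_profile`.
#' @export
canonical_behavior_profile <- function(n_adults = 21L, n_children = 20L) {
  prof <- data.frame(
    group = rep(c("children", "adults"), each = 4),
    task = rep(rep(c("implicit", "explicit"), each = 2), 2),
    tp_class = rep(c("high", "low"), 4),
    mean_pct = c(50.1, 45.1, 55.7, 52.5,
                 47.1, 58.4, 61.4, 65.5),
    sd_pct   = c(17.17, 19.16, 15.43, 17.54,
                 17.68, 14.46, 20.12, 20.08),
    stringsAsFactors = FALSE)
  prof$n_subjects <- ifelse(prof$group == "adults", n_adults, n_children)
  prof$n_trials <- 8L
  class(prof) <- c("sl_behavior_profile", "data.frame")
  prof
}

# Beta-binomial overdispersion (intra-class correlation) matching a target
# between-subject SD of the percent score; 0 (plain binomial) when the
# target is at or below binomial dispersion.
behavior_dispersion <- function(mean_pct, sd_pct, n_trials = 8L) {
  p <- mean_pct / 100
  v_x <- (sd_pct / (100 / n_trials))^2
  base <- n_trials * p * (1 - p)
  rho <- (v_x / base - 1) / (n_trials - 1)
  pmin(pmax(rho, 0), 0.999)
}

#' Simulate per-subject 2-AFC accuracy tables
#'
#' Each subject x task x word-type score is `100 * correct / n_trials`
#' with `correct` drawn from a beta-binomial whose mean and dispersion are
#' calibrated to the profile cell (plain binomial where the target SD is
#' below binomial dispersion). A Gaussian copula with correlation
#' `subject_rho` links a subject's latent ability across cells, giving the
#' within-subject structure a repeated-measures analysis expects.
#'
#' @param profile An `sl_behavior_profile`.
#' @param seed Integer seed.
#' @param subject_rho Within-subject latent correlation across cells.
#' @return Data frame: `group`, `subject`, `task`, `tp_class`, `correct`,
#'   `score_pct`.
#' @export
simulate_behavior <- function(profile = canonical_behavior_profile(),
                              seed = 1L, subject_rho = 0.5) {
  if (any(profile$mean_pct < 0 | profile$mean_pct > 100))
    stopf("cell accuracies must be in [0, 100]")
  if (subject_rho < 0 || subject_rho >= 1) stopf("subject_rho must be in [0, 1)")
  with_seed(seed, {
    out <- list()
    for (g in unique(profile$group)) {
      cells <- profile[profile$group == g, ]
      n_sub <- cells$n_subjects[1]
      n_tr <- cells$n_trials[1]
      z_sub <- stats::rnorm(n_sub)
      for (i in seq_len(nrow(cells))) {
        p <- cells$mean_pct[i] / 100
        rho <- behavior_dispersion(cells$mean_pct[i], cells$sd_pct[i], n_tr)
        z <- sqrt(subject_rho) * z_sub +
          sqrt(1 - subject_rho) * stats::rnorm(n_sub)
        u <- stats::pnorm(z)
        if (rho > 0) {
          nu <- 1 / rho - 1
          p_i <- stats::qbeta(u, p * nu, (1 - p) * nu)
        } else {
          p_i <- rep(p, n_sub)
        }
        correct <- stats::rbinom(n_sub, n_tr, p_i)
        out[[length(out) + 1]] <- data.frame(
          group = g, subject = paste0(substr(g, 1, 1), seq_len(n_sub)),
          task = cells$task[i], tp_class = cells$tp_class[i],
          correct = correct, score_pct = 100 * correct / n_tr,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate the chirp-detection cover task
#'
#' Bernoulli hits on chirp-flagged syllable tokens and Bernoulli false
#' alarms on unflagged ones.
#'
#' @param chirps An `sl_chirps` flag matrix.
#' @param hit_rate,fa_rate Probabilities in \[0, 1\].
#' @param seed Integer seed.
#' @return List with `hits`, `misses`, `false_alarms`, `n_flags`,
#'   `n_unflagged`, `pct_correct` (hits over flags + false alarms).
#' @export
simulate_chirp_detection <- function(chirps, hit_rate = 0.98, fa_rate = 0.002,
                                     seed = 1L) {
  if (any(c(hit_rate, fa_rate) < 0 | c(hit_rate, fa_rate) > 1))
    stopf("rates must be in [0, 1]")
  flags <- as.vector(chirps)
  with_seed(seed, {
    hits <- sum(stats::rbinom(sum(flags), 1, hit_rate))
    fas <- sum(stats::rbinom(sum(!flags), 1, fa_rate))
    list(hits = hits, misses = sum(flags) - hits, false_alarms = fas,
         n_flags = sum(flags), n_unflagged = sum(!flags),
         pct_correct = 100 * hits / max(1, hits + fas))
  })
}

#' Default EEG effect specification
#'
#' Component templates are negative Gaussian-in-time bumps; the windows and
#' scalp regions are the analysis constants, the magnitudes are simulation
#' parameters. The N100 peaks at 100 ms (25 ms width); the N400 peaks at
#' 400 ms for adults and 450 ms for children, mirroring the later analysis
#' window used for children. Condition effects are additive amplitude
#' deltas (in microvolts; negative = larger deflection) over task, word
#' type and exposure half; subjects get a per-component random amplitude
#' shift. A fraction of word epochs receives a large transient exceeding
#' the +/-100 uV rejection threshold.
#'
#' @param group `"adults"` or `"children"`.
#' @param noise_sd Additive Gaussian noise SD in uV (default 10).
#' @param artifact_rate Fraction of word epochs carrying an artifact.
#' @param sample_rate Sampling rate in Hz (default 512).
#' @param montage Scalp channels to simulate (mastoids are appended).
#' @return List of class `sl_effect_spec`.
#' @export
default_effect_spec <- function(group = c("adults", "children"),
                                noise_sd = 10, artifact_rate = 0.15,
                                sample_rate = 512,
                                montage = standard_montage()) {
  group <- match.arg(group)
  n400_peak <- if (group == "adults") 400 else 450
  channels <- c(montage, "M1", "M2")
  scalp_w <- stats::setNames(rep(1, length(channels)), channels)
  scalp_w[c("M1", "M2")] <- 0
  spec <- list(
    group = group,
    sample_rate = sample_rate,
    channels = channels,
    components = list(
      N100 = list(peak_ms = 100, width_ms = 25, base = -2,
                  d_task = if (group == "adults") -0.5 else 0,
                  d_tp = 0, d_half = -0.5, weights = scalp_w),
      N400 = list(peak_ms = n400_peak, width_ms = 70, base = -1,
                  d_task = if (group == "children") -1 else 0,
                  d_tp = if (group == "adults") -2 else 0,
                  d_half = -0.5, weights = scalp_w)
    ),
    subject_sd = 0.5,
    noise_sd = noise_sd,
    noise_model = "white",
    artifact_rate = artifact_rate,
    artifact_uV = 150,
    pad_ms = 500
  )
  class(spec) <- "sl_effect_spec"
  spec
}

#' The scalp channels the analysis uses
#'
#' Union of the three canonical regions of interest.
#'
#' @return Character vector of electrode names.
#' @export
standard_montage <- function() {
  unique(unlist(canonical_rois(), use.names = FALSE))
}

component_amplitude <- function(comp, task, tp_class, half) {
  comp$base +
    comp$d_task * (task == "explicit") +
    comp$d_tp * (tp_class == "high") +
    comp$d_half * (half == 2)
}

#' Analytic window gain of a component template
#'
#' Mean of the unit-amplitude Gaussian template over the sampled analysis
#' window; converts a window-mean amplitude back into template peak units.
#'
#' @param spec An `sl_effect_spec`.
#' @param component Component name (e.g. `"N400"`).
#' @param window_ms Length-2 analysis window in ms.
#' @return Scalar gain in (0, 1\].
#' @export
template_window_gain <- function(spec, component, window_ms) {
  comp <- spec$components[[component]]
  rate <- spec$sample_rate
  rel <- seq(round(window_ms[1] * rate / 1000), round(window_ms[2] * rate / 1000))
  t_ms <- rel / rate * 1000
  mean(exp(-((t_ms - comp$peak_ms)^2) / (2 * comp$width_ms^2)))
}

#' Simulate continuous EEG for one or more subjects
#'
#' Each word onset of the timeline injects the component templates scaled
#' by the condition amplitude (fixed effects plus a subject random effect),
#' on the template's scalp weighting; Gaussian sensor noise is added
#' everywhere, and a fraction of word epochs receives a transient artifact
#' exceeding the rejection threshold (placed 150-750 ms post-onset so it
#' contaminates exactly one epoch). Deterministic under the seed.
#'
#' @param timeline An `sl_timeline`.
#' @param spec An `sl_effect_spec`.
#' @param n_subjects Number of subjects to simulate.
#' @param task Task label attached to the events (`"implicit"`/`"explicit"`).
#' @param seed Integer seed.
#' @return A list with one element per subject: `list(eeg, events, subject)`
#'   where `eeg` is an `sl_eeg` (channels x samples matrix, `rate`,
#'   `channels`, `units`) and `events` the word-onset table (onsets in ms
#'   within the recording, plus `word_id`, `tp_class`, `block`, `half`,
#'   `task`).
#' @export
simulate_eeg <- function(timeline, spec = default_effect_spec(),
                         n_subjects = 1L, task = "implicit", seed = 1L) {
  bad <- setdiff(unlist(lapply(spec$components, function(c) names(c$weights))),
                 spec$channels)
  if (length(bad) > 0)
    stopf("spatial weights name unknown channels: %s", paste(bad, collapse = ", "))
  rate <- spec$sample_rate
  pad <- spec$pad_ms
  onsets_ms <- timeline$onset[timeline$word_onset] + pad
  ev <- data.frame(
    onset = onsets_ms,
    word_id = timeline$word_id[timeline$word_onset],
    tp_class = timeline$tp_class[timeline$word_onset],
    block = timeline$block[timeline$word_onset],
    half = timeline$half[timeline$word_onset],
    task = task,
    stringsAsFactors = FALSE)
  total_ms <- (attr(timeline, "total_ms") %||% max(timeline$onset + 350)) + 2 * pad
  n_samp <- ceiling(total_ms / 1000 * rate)
  n_ch <- length(spec$channels)
  onset_samp <- round(onsets_ms / 1000 * rate)
  lapply(seq_len(n_subjects), function(s) {
    with_seed(derive_seed(seed, s), {
      data <- matrix(0, nrow = n_ch, ncol = n_samp,
                     dimnames = list(spec$channels, NULL))
      for (cn in names(spec$components)) {
        comp <- spec$components[[cn]]
        re <- stats::rnorm(1, 0, spec$subject_sd)
        half_span <- ceiling(4 * comp$width_ms / 1000 * rate)
        rel <- seq(-half_span, half_span)
        t_ms <- rel / rate * 1000
        tmpl <- exp(-((t_ms)^2) / (2 * comp$width_ms^2))
        peak_shift <- round(comp$peak_ms / 1000 * rate)
        sig <- numeric(n_samp)
        for (e in seq_along(onset_samp)) {
          amp <- component_amplitude(comp, ev$task[e], ev$tp_class[e], ev$half[e]) + re
          idx <- onset_samp[e] + peak_shift + rel
          keep <- idx >= 1 & idx <= n_samp
          sig[idx[keep]] <- sig[idx[keep]] + amp * tmpl[keep]
        }
        w <- numeric(n_ch)
        w[match(names(comp$weights), spec$channels)] <- comp$weights
        data <- data + outer(w, sig)
      }
      if (spec$noise_sd > 0) {
        noise <- matrix(stats::rnorm(n_ch * n_samp, 0, spec$noise_sd),
                        nrow = n_ch)
        if (identical(spec$noise_model, "pink")) {
          noise <- t(apply(noise, 1, shape_pink))
          noise <- noise * (spec$noise_sd / stats::sd(as.vector(noise)))
        }
        data <- data + noise
      }
      if (spec$artifact_rate > 0) {
        n_art <- stats::rbinom(1, length(onset_samp), spec$artifact_rate)
        if (n_art > 0) {
          which_ev <- sample(seq_along(onset_samp), n_art)
          scalp <- which(spec$channels %in% standard_montage())
          for (e in which_ev) {
            ch <- if (length(scalp) == 1) scalp else sample(scalp, 1)
            center_ms <- stats::runif(1, 200, 700)
            sgn <- sample(c(-1, 1), 1)
            c_samp <- onset_samp[e] + round(center_ms / 1000 * rate)
            rel <- seq(-round(0.05 * rate), round(0.05 * rate))
            idx <- c_samp + rel
            keep <- idx >= 1 & idx <= n_samp
            bump <- sgn * spec$artifact_uV *
              exp(-((rel / rate * 1000)^2) / (2 * 25^2))
            data[ch, idx[keep]] <- data[ch, idx[keep]] + bump[keep]
          }
        }
      }
      eeg <- structure(list(data = data, rate = rate, channels = spec$channels,
                            units = "uV"), class = "sl_eeg")
      list(eeg = eeg, events = ev, subject = s)
    })
  })
}

# 1/f amplitude shaping of a white-noise row via FFT
shape_pink <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  freq <- c(1, seq_len(n - 1))
  freq <- pmin(freq, n - freq + 1)
  f <- f / sqrt(freq)
  Re(stats::fft(f, inverse = TRUE)) / n
}
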