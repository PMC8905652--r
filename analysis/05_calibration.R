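#!/usr/bin/env Rscript

# Step 5 — pipeline calibration (reduced-size preview of the checks the
# test suite runs at full replication counts). Two simulation studies over
# the complete simulate -> preprocess -> measure -> ANOVA chain:
#   (a) type-I error with no injected condition effects (target ~0.05),
#   (b) bias of the recovered N400 word-type delta (target < 5%).
# 128 Hz sampling, central-ROI montage, 48-word streams; 100 / 50
# replicates here (the acceptance tests use 500 / 200).

suppressPackageStartupMessages(library(syllastream))
out <- "results/calibration"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec_for <- function(d_tp) {
  spec <- default_effect_spec("adults", noise_sd = 10, artifact_rate = 0.15,
                              sample_rate = 128,
                              montage = canonical_rois()$central)
  spec$components$N100$d_task <- 0
  spec$components$N100$d_half <- 0
  spec$components$N400$d_half <- 0
  spec$components$N400$d_tp <- d_tp
  spec
}
one_rep <- function(timeline, spec, n_subjects, seed) {
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
  do.call(rbind, rows)
}

lex <- canonical_syllabary("A")
sq <- generate_word_sequence(lex, reps_per_block = 1, n_blocks = 6, seed = 1001)
tl <- build_timeline(sq)

null_spec <- spec_for(d_tp = 0)
ps <- vapply(1:100, function(r) {
  m <- one_rep(tl, null_spec, 6, 50000 + r)
  m <- m[m$component == "N400", ]
  a <- rm_anova(m, "amplitude", "subject", within = c("tp_class", "half"))
  a$p[a$effect == "tp_class"]
}, numeric(1))
cat(sprintf("type-I error of the N400 word-type test over 100 null runs: %.3f (nominal 0.05)\n",
            mean(ps < 0.05)))

eff_spec <- spec_for(d_tp = -2)
gain <- template_window_gain(eff_spec, "N400", c(350, 450))
est <- vapply(1:50, function(r) {
  m <- one_rep(tl, eff_spec, 8, 70000 + r)
  m <- m[m$component == "N400", ]
  (mean(m$amplitude[m$tp_class == "high"]) -
      mean(m$amplitude[m$tp_class == "low"])) / gain
}, numeric(1))
cat(sprintf("recovered N400 delta over 50 runs: mean %.3f uV (injected -2), bias %.1f%%\n",
            mean(est), 100 * abs(mean(est) + 2) / 2))

write.csv(data.frame(study = c("type_I", "recovery"),
                     n_replicates = c(100, 50),
                     value = c(mean(ps < 0.05), mean(est))),
          file.path(out, "calibration.csv"), row.names = FALSE)
cat(sprintf("wrote %s\n", out))
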