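#!/usr/bin/env Rscript

# Step 2 — familiarization streams. Generate the constrained pseudo-random
# word sequences for both tasks (implicit = syllabary A, explicit = B),
# audit the constraints with an independent scan, measure boundary and
# token-level transitional probabilities, assign the chirp cover task, and
# write the millisecond event timelines.

suppressPackageStartupMessages(library(syllastream))
out <- "results/stream"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

summary_rows <- list()
for (task in c("implicit", "explicit")) {
  id <- if (task == "implicit") "A" else "B"
  lex <- canonical_syllabary(id)
  sq <- generate_word_sequence(lex, seed = derive_seed(seed, 10L + match(id, c("A", "B"))))
  audit <- audit_word_sequence(sq)
  stopifnot(audit$ok)
  chirps <- assign_chirps(sq, rate = 0.15, seed = derive_seed(seed, 20L))
  tl <- build_timeline(sq, chirps)
  write_events_tsv(tl, file.path(out, sprintf("events_%s.tsv", task)))
  write.csv(token_tp_table(sq), file.path(out, sprintf("token_tp_%s.csv", task)),
            row.names = FALSE)
  hi <- word_boundary_tp(sq, "high"); lo <- word_boundary_tp(sq, "low")
  summary_rows[[task]] <- data.frame(
    task = task, syllabary = id, n_words = nrow(sq),
    boundary_tp_high = hi, boundary_tp_low = lo,
    word_period_ms = attr(tl, "word_period_ms"),
    total_min = attr(tl, "total_ms") / 60000, n_chirps = sum(chirps))
  cat(sprintf(
    "%s stream (syllabary %s): %d words, constraints pass; boundary TP high = %.3f (~1/7), low = %.3f (~1/6); %d chirps; %.1f min\n",
    task, id, nrow(sq), hi, lo, sum(chirps), attr(tl, "total_ms") / 60000))
}
write.csv(do.call(rbind, summary_rows), file.path(out, "stream_summary.csv"),
          row.names = FALSE)

# short audio demonstration (first block of the implicit stream, 16 kHz)
lex <- canonical_syllabary("A")
sq1 <- generate_word_sequence(lex, reps_per_block = 1, n_blocks = 1,
                              seed = derive_seed(seed, 30L))
tl1 <- build_timeline(sq1, assign_chirps(sq1, total = 4, seed = derive_seed(seed, 31L)))
render_wav(tl1, file.path(out, "demo_stream.wav"), sample_rate = 16000)
cat(sprintf("wrote %s (incl. %s)\n", out, "demo_stream.wav"))
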