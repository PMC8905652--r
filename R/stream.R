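# Familiarization-stream generation: constrained pseudo-random word order,
# chirp cover-task assignment, millisecond timeline, TP audits, audio.

#' Generate the constrained pseudo-random word sequence
#'
#' Every word occurs exactly `reps_per_block` times in each of `n_blocks`
#' blocks, with two adjacency constraints enforced everywhere (including
#' across block joins, since the blocks are contiguous audio): the same
#' word never repeats immediately, and a word never follows another whose
#' final syllable equals its own initial syllable (which would locally
#' recreate a within-word bigram at a boundary).
#'
#' @param lex An `sl_lexicon`.
#' @param reps_per_block Word repetitions per block (default 10).
#' @param n_blocks Number of blocks (default 6).
#' @param seed Integer seed; the result is deterministic given it.
#' @param max_restarts Bound on full restarts before giving up.
#' @return Data frame (`pos`, `block`, `word_id`, `tp_class`) of class
#'   `sl_word_sequence`, with the lexicon attached as an attribute.
#' @export
generate_word_sequence <- function(lex, reps_per_block = 10, n_blocks = 6,
                                   seed = 1L, max_restarts = 50L) {
  w <- lex$words
  n_w <- nrow(w)
  legal <- outer(seq_len(n_w), seq_len(n_w), function(i, j)
    i != j & w$syl3[i] != w$syl1[j])
  fill_block <- function(prev) {
    remaining <- rep(reps_per_block, n_w)
    out <- integer(n_w * reps_per_block)
    for (k in seq_along(out)) {
      cand <- which(remaining > 0L & (if (prev == 0L) TRUE else legal[prev, ]))
      if (length(cand) == 0L) return(NULL)
      pick <- if (length(cand) == 1L) cand else
        sample(cand, 1L, prob = remaining[cand])
      out[k] <- pick
      remaining[pick] <- remaining[pick] - 1L
      prev <- pick
    }
    out
  }
  with_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      blocks <- vector("list", n_blocks)
      prev <- 0L
      ok <- TRUE
      for (b in seq_len(n_blocks)) {
        blk <- NULL
        for (try in 1:200) {
          blk <- fill_block(prev)
          if (!is.null(blk)) break
        }
        if (is.null(blk)) { ok <- FALSE; break }
        blocks[[b]] <- blk
        prev <- blk[length(blk)]
      }
      if (ok) {
        idx <- unlist(blocks)
        out <- data.frame(
          pos = seq_along(idx),
          block = rep(seq_len(n_blocks), each = n_w * reps_per_block),
          word_id = w$id[idx],
          tp_class = w$tp_class[idx],
          stringsAsFactors = FALSE)
        class(out) <- c("sl_word_sequence", "data.frame")
        attr(out, "lexicon") <- lex
        attr(out, "reps_per_block") <- reps_per_block
        attr(out, "n_blocks") <- n_blocks
        return(out)
      }
    }
    stopf("sequence constraints unsatisfiable after %d restarts", max_restarts)
  })
}

#' Brute-force audit of a word sequence
#'
#' Re-checks every constraint by direct scanning, independently of the
#' generator: exact per-block word counts, no immediate word repetition,
#' and no cross-boundary syllable repetition (final of one word equal to
#' the initial of the next), including across block joins.
#'
#' @param seq An `sl_word_sequence`.
#' @return List with `ok` (logical) and `problems` (character vector).
#' @export
audit_word_sequence <- function(seq) {
  lex <- attr(seq, "lexicon")
  w <- lex$words
  reps <- attr(seq, "reps_per_block")
  p <- character()
  for (b in unique(seq$block)) {
    cnt <- table(factor(seq$word_id[seq$block == b], levels = w$id))
    if (any(cnt != reps))
      p <- c(p, sprintf("block %s: unequal word counts", b))
  }
  ids <- seq$word_id
  if (any(ids[-1] == ids[-length(ids)]))
    p <- c(p, "immediate word repetition found")
  fin <- w$syl3[match(ids, w$id)]
  ini <- w$syl1[match(ids, w$id)]
  if (any(fin[-length(fin)] == ini[-1]))
    p <- c(p, "cross-boundary syllable repetition found")
  list(ok = length(p) == 0L, problems = p)
}

#' Word-level across-boundary transitional probabilities
#'
#' For each word A of the class, the empirical successor probabilities
#' TP(B | A) = count(A followed by B) / count(A non-final) are averaged
#' (unweighted) over A's *legal* successors — the words the adjacency
#' constraints allow after A — and then averaged over the class. On a
#' default stream this equals 1/7 for high-TP words (7 legal successors)
#' and 1/6 for low-TP words.
#'
#' @param seq An `sl_word_sequence`.
#' @param tp_class `"high"` or `"low"`.
#' @param detail Return per-word summaries as well.
#' @return The class summary probability, or a list when `detail = TRUE`.
#' @export
word_boundary_tp <- function(seq, tp_class = c("high", "low"), detail = FALSE) {
  tp_class <- match.arg(tp_class)
  lex <- attr(seq, "lexicon")
  w <- lex$words
  words_in_class <- w$id[w$tp_class == tp_class]
  if (length(words_in_class) == 0L) stopf("no words of class %s", tp_class)
  ids <- seq$word_id
  per_word <- vapply(words_in_class, function(a) {
    i <- which(ids == a)
    i <- i[i < length(ids)]
    succ <- ids[i + 1L]
    legal <- w$id[w$id != a & w$syl1 != w$syl3[w$id == a]]
    tps <- vapply(legal, function(b) sum(succ == b) / length(succ), numeric(1))
    mean(tps)
  }, numeric(1))
  if (detail) list(summary = mean(per_word), per_word = per_word)
  else mean(per_word)
}

#' Empirical syllable-token transitional probabilities
#'
#' Flattens the stream to its syllable token sequence and tabulates every
#' attested ordered bigram: TP(y | x) = count(x followed by y) / count(x in
#' non-final position). For each antecedent the probabilities over its
#' continuations sum to 1.
#'
#' @param seq An `sl_word_sequence`.
#' @return Data frame with `x`, `y`, `count_xy`, `count_x`, `tp`.
#' @export
token_tp_table <- function(seq) {
  lex <- attr(seq, "lexicon")
  w <- lex$words
  m <- match(seq$word_id, w$id)
  toks <- as.vector(t(cbind(w$syl1[m], w$syl2[m], w$syl3[m])))
  x <- toks[-length(toks)]
  y <- toks[-1]
  tab <- as.data.frame(table(x = x, y = y), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  denom <- table(x)
  tab$count_x <- as.integer(denom[tab$x])
  names(tab)[names(tab) == "Freq"] <- "count_xy"
  tab$tp <- tab$count_xy / tab$count_x
  rownames(tab) <- NULL
  tab[order(tab$x, tab$y), ]
}

#' Assign chirps to syllable tokens
#'
#' Flags `rate` of all syllable tokens (or an explicit `total`) for the
#' chirp cover task, balanced across the 8 words and 3 syllable positions
#' so the chirp carries no segmentation cue. At the defaults (0.15 of
#' 1,440 tokens) this is exactly 9 flags per (word, position) cell; when
#' the total does not divide evenly the remainder is spread round-robin
#' over randomly ordered cells.
#'
#' @param seq An `sl_word_sequence`.
#' @param rate Fraction of syllable tokens to flag (default 0.15).
#' @param total Optional explicit total count, overriding `rate`.
#' @param seed Integer seed.
#' @return Logical matrix (word tokens x 3 positions) of class
#'   `sl_chirps`, with `rate` and `total` attributes.
#' @export
assign_chirps <- function(seq, rate = 0.15, total = NULL, seed = 1L) {
  n_tok <- nrow(seq) * 3L
  if (is.null(total)) {
    if (!is.numeric(rate) || rate <= 0 || rate > 1) stopf("rate must be in (0, 1]")
    total <- round(rate * n_tok)
  }
  total <- as.integer(total)
  if (total < 1L || total > n_tok) stopf("chirp total out of range")
  lex <- attr(seq, "lexicon")
  word_ids <- lex$words$id
  cells <- expand.grid(word = word_ids, posn = 1:3, stringsAsFactors = FALSE)
  with_seed(seed, {
    base <- total %/% nrow(cells)
    rem <- total %% nrow(cells)
    counts <- rep(base, nrow(cells))
    if (rem > 0) counts[sample.int(nrow(cells), rem)] <- base + 1L
    flags <- matrix(FALSE, nrow = nrow(seq), ncol = 3L)
    for (i in seq_len(nrow(cells))) {
      if (counts[i] == 0L) next
      tok <- which(seq$word_id == cells$word[i])
      if (counts[i] > length(tok))
        stopf("cannot place %d chirps on %d tokens of word %s",
              counts[i], length(tok), cells$word[i])
      pick <- if (length(tok) == 1L) tok else sample(tok, counts[i])
      flags[pick, cells$posn[i]] <- TRUE
    }
    structure(flags, class = "sl_chirps", rate = sum(flags) / n_tok,
              total = sum(flags))
  })
}

#' Build the millisecond event timeline
#'
#' One event per syllable token. Each syllable lasts `syl_ms` and is
#' followed by a `gap_ms` silence (three gaps per word), so the word
#' period is `3 * (syl_ms + gap_ms)` = 1,050 ms at the defaults and a
#' default 480-word stream lasts 504,000 ms (8.4 min; 1.4 min per block).
#'
#' @param seq An `sl_word_sequence`.
#' @param chirps An `sl_chirps` matrix (optional; no flags if omitted).
#' @param syl_ms Syllable duration in ms (default 300).
#' @param gap_ms Inter-syllable silence in ms (default 50).
#' @return Data frame of class `sl_timeline` with columns `onset` (ms),
#'   `duration` (ms), `syllable`, `word_id`, `position`, `block`, `half`,
#'   `tp_class`, `chirp`, `word_onset`.
#' @export
build_timeline <- function(seq, chirps = NULL, syl_ms = 300, gap_ms = 50) {
  lex <- attr(seq, "lexicon")
  w <- lex$words
  n_blocks <- attr(seq, "n_blocks") %||% max(seq$block)
  m <- match(seq$word_id, w$id)
  period <- 3 * (syl_ms + gap_ms)
  n <- nrow(seq)
  if (is.null(chirps)) chirps <- matrix(FALSE, nrow = n, ncol = 3L)
  ev <- data.frame(
    onset = rep((seq$pos - 1) * period, each = 3L) +
      (rep(1:3, times = n) - 1L) * (syl_ms + gap_ms),
    duration = syl_ms,
    syllable = as.vector(t(cbind(w$syl1[m], w$syl2[m], w$syl3[m]))),
    word_id = rep(seq$word_id, each = 3L),
    position = rep(1:3, times = n),
    block = rep(seq$block, each = 3L),
    half = rep(ifelse(seq$block <= n_blocks / 2, 1L, 2L), each = 3L),
    tp_class = rep(seq$tp_class, each = 3L),
    chirp = as.vector(t(unclass(chirps)[, , drop = FALSE])),
    word_onset = rep(c(TRUE, FALSE, FALSE), times = n),
    stringsAsFactors = FALSE)
  class(ev) <- c("sl_timeline", "data.frame")
  attr(ev, "syl_ms") <- syl_ms
  attr(ev, "gap_ms") <- gap_ms
  attr(ev, "word_period_ms") <- period
  attr(ev, "total_ms") <- n * period
  attr(ev, "n_blocks") <- n_blocks
  ev
}

#' Write a timeline as a BIDS-style events TSV
#'
#' Onsets and durations in seconds, `trial_type` = word id, plus the
#' syllable-level columns.
#'
#' @param timeline An `sl_timeline`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(timeline, path) {
  out <- data.frame(
    onset = sprintf("%.3f", timeline$onset / 1000),
    duration = sprintf("%.3f", timeline$duration / 1000),
    trial_type = timeline$word_id,
    syllable = timeline$syllable,
    position = timeline$position,
    block = timeline$block,
    half = timeline$half,
    tp_class = timeline$tp_class,
    chirp = as.integer(timeline$chirp),
    word_onset = as.integer(timeline$word_onset),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events TSV written by [write_events_tsv()]
#'
#' @param path Events file.
#' @return An `sl_timeline`-shaped data frame (onsets back in ms).
#' @export
read_events_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  ev <- data.frame(
    onset = x$onset * 1000, duration = x$duration * 1000,
    syllable = x$syllable, word_id = x$trial_type, position = x$position,
    block = x$block, half = x$half, tp_class = x$tp_class,
    chirp = as.logical(x$chirp), word_onset = as.logical(x$word_onset),
    stringsAsFactors = FALSE)
  class(ev) <- c("sl_timeline", "data.frame")
  ev
}

#' Render a timeline as audio
#'
#' Each syllable is a fixed-frequency 300 ms tone (one tone per syllable
#' label, chromatic spacing) with 10 ms cosine ramps; chirp-flagged
#' syllables carry a superimposed 0.1 s sawtooth sweep from 450 to
#' 1,450 Hz; gaps are digital silence. Written as 16-bit mono PCM WAV.
#'
#' @param timeline An `sl_timeline`.
#' @param path Output WAV file, or `NULL` to return samples only.
#' @param sample_rate Samples per second (default 44100).
#' @param amplitude Peak tone amplitude in (0, 1].
#' @return Invisibly, the numeric sample vector.
#' @export
render_wav <- function(timeline, path = NULL, sample_rate = 44100,
                       amplitude = 0.3) {
  total_ms <- attr(timeline, "total_ms") %||%
    (max(timeline$onset + timeline$duration) + (attr(timeline, "gap_ms") %||% 50))
  n <- ceiling(total_ms / 1000 * sample_rate)
  wave <- numeric(n)
  syls <- sort(unique(timeline$syllable))
  freqs <- 220 * 2^((seq_along(syls) - 1) / 12)
  names(freqs) <- syls
  dur_s <- timeline$duration[1] / 1000
  n_syl <- round(dur_s * sample_rate)
  t_syl <- seq_len(n_syl) / sample_rate
  ramp <- pmin(1, pmin(t_syl, dur_s - t_syl) / 0.01)
  chirp_n <- round(0.1 * sample_rate)
  t_ch <- seq_len(chirp_n) / sample_rate
  phase_ch <- 450 * t_ch + (1450 - 450) * t_ch^2 / (2 * 0.1)
  chirp_wave <- (2 * (phase_ch %% 1) - 1) * 0.5 * amplitude
  for (i in seq_len(nrow(timeline))) {
    s0 <- round(timeline$onset[i] / 1000 * sample_rate)
    idx <- s0 + seq_len(n_syl)
    idx <- idx[idx <= n]
    tone <- amplitude * ramp * sin(2 * pi * freqs[timeline$syllable[i]] * t_syl)
    wave[idx] <- wave[idx] + tone[seq_along(idx)]
    if (isTRUE(timeline$chirp[i])) {
      cidx <- s0 + seq_len(chirp_n)
      cidx <- cidx[cidx <= n]
      wave[cidx] <- wave[cidx] + chirp_wave[seq_along(cidx)]
    }
  }
  if (!is.null(path)) write_wav(wave, sample_rate, path)
  invisible(wave)
}

#' Write samples as 16-bit PCM mono WAV
#'
#' @param samples Numeric vector in \[-1, 1\] (clipped otherwise).
#' @param sample_rate Samples per second.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Minimal reader matching [write_wav()], used for round-trip checks.
#'
#' @param path WAV file.
#' @return List with `samples` (numeric in \[-1, 1\]) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wavefmt <- readChar(con, 8)
  if (riff != "RIFF" || wavefmt != "WAVEfmt ") stopf("not a PCM WAV file")
  fmt_len <- readBin(con, integer(), size = 4, endian = "little")
  readBin(con, integer(), size = 2, endian = "little")
  n_chan <- readBin(con, integer(), size = 2, endian = "little")
  rate <- readBin(con, integer(), size = 4, endian = "little")
  readBin(con, integer(), size = 4, endian = "little")
  readBin(con, integer(), size = 2, endian = "little")
  bits <- readBin(con, integer(), size = 2, endian = "little")
  if (fmt_len > 16) readBin(con, raw(), fmt_len - 16)
  readChar(con, 4)
  data_bytes <- readBin(con, integer(), size = 4, endian = "little")
  pcm <- readBin(con, integer(), n = data_bytes / 2L, size = 2, endian = "little")
  if (n_chan != 1L || bits != 16L) stopf("only 16-bit mono supported")
  list(samples = pcm / 32767, sample_rate = rate)
}
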