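# Lexicon construction: trisyllabic high/low transitional-probability word
# sets, zero-TP foils, and 2-AFC trial lists.

CANONICAL_WORDS <- list(
  A = list(
    high = c("tucida", "bupepo", "modego", "bibaca"),
    low  = c("dotige", "tidomi", "migedo", "gemiti"),
    high_foils = c("tumica", "bugego", "modopo", "bitida"),
    low_foils  = c("dobage", "tidemi", "mipedo", "geciti")
  ),
  B = list(
    high = c("todidu", "cegita", "gapabe", "bomaco"),
    low  = c("pitegu", "tepime", "megupi", "gumete"),
    high_foils = c("tomeco", "cegube", "gapita", "botedu"),
    low_foils  = c("pimagu", "tepame", "megipi", "gudite")
  )
)

#' Split a string of consecutive CV syllables
#'
#' Trisyllabic items are plain concatenations of two-character
#' consonant-vowel units, so syllabification is a fixed-width split.
#'
#' @param x Character vector of even-length strings.
#' @return A list of character vectors of syllables.
#' @export
syllabify <- function(x) {
  if (any(nchar(x) %% 2L != 0L)) stopf("all items must have an even number of characters")
  lapply(x, function(w) {
    substring(w, seq(1, nchar(w), by = 2), seq(2, nchar(w), by = 2))
  })
}

syllable_matrix <- function(items) {
  syl <- syllabify(items)
  if (any(lengths(syl) != 3L)) stopf("all items must be trisyllabic")
  m <- do.call(rbind, syl)
  dimnames(m) <- NULL
  m
}

words_df <- function(high, low) {
  m <- syllable_matrix(c(high, low))
  data.frame(
    id = c(high, low),
    tp_class = rep(c("high", "low"), each = 4),
    syl1 = m[, 1], syl2 = m[, 2], syl3 = m[, 3],
    stringsAsFactors = FALSE
  )
}

foils_df <- function(high_foils, low_foils, source_high, source_low) {
  m <- syllable_matrix(c(high_foils, low_foils))
  data.frame(
    id = c(high_foils, low_foils),
    tp_class = rep(c("high", "low"), each = 4),
    syl1 = m[, 1], syl2 = m[, 2], syl3 = m[, 3],
    source_word_id = c(source_high, source_low),
    stringsAsFactors = FALSE
  )
}

word_syllables <- function(df) unique(c(df$syl1, df$syl2, df$syl3))

internal_bigrams <- function(df) {
  c(paste(df$syl1, df$syl2, sep = ">"), paste(df$syl2, df$syl3, sep = ">"))
}

#' Assemble and validate a lexicon
#'
#' A lexicon holds 8 words (4 high-TP, 4 low-TP), 8 foils and the derived
#' 16-syllable inventory with frequency classes (high-TP syllables occur in
#' exactly one word, low-TP syllables in three).
#'
#' @param words Word data frame (`id`, `tp_class`, `syl1..3`).
#' @param foils Foil data frame (adds `source_word_id`).
#' @param syllabary_id `"A"`, `"B"` or `"custom"`.
#' @return An object of class `sl_lexicon`.
#' @export
new_lexicon <- function(words, foils, syllabary_id = "custom") {
  syl <- word_syllables(words)
  counts <- vapply(syl, function(s) {
    sum(words$syl1 == s | words$syl2 == s | words$syl3 == s)
  }, integer(1))
  syllables <- data.frame(
    label = syl,
    freq_class = ifelse(counts == 1L, "high", ifelse(counts == 3L, "low", "bad")),
    n_words = counts,
    stringsAsFactors = FALSE
  )
  lex <- structure(
    list(syllabary_id = syllabary_id, words = words, foils = foils,
         syllables = syllables),
    class = "sl_lexicon"
  )
  problems <- validate_lexicon(lex)
  if (length(problems) > 0)
    stopf("invalid lexicon: %s", paste(problems, collapse = "; "))
  lex
}

#' Check all combinatorial invariants of a lexicon
#'
#' @param lex An `sl_lexicon`.
#' @return Character vector of violated invariants (empty when valid).
#' @export
validate_lexicon <- function(lex) {
  p <- character()
  w <- lex$words; f <- lex$foils; s <- lex$syllables
  if (nrow(w) != 8 || sum(w$tp_class == "high") != 4 || sum(w$tp_class == "low") != 4)
    p <- c(p, "need 4 high + 4 low words")
  if (nrow(s) != 16 || anyDuplicated(s$label))
    p <- c(p, "need 16 distinct syllables")
  if (sum(s$freq_class == "high") != 12 || sum(s$freq_class == "low") != 4)
    p <- c(p, "need 12 high-frequency-class and 4 low-class syllables")
  hi <- w[w$tp_class == "high", ]; lo <- w[w$tp_class == "low", ]
  hi_syl <- unlist(hi[, c("syl1", "syl2", "syl3")], use.names = FALSE)
  lo_syl <- unlist(lo[, c("syl1", "syl2", "syl3")], use.names = FALSE)
  if (anyDuplicated(hi_syl)) p <- c(p, "high-TP words must partition 12 unique syllables")
  low_set <- unique(lo_syl)
  if (length(low_set) != 4) p <- c(p, "low-TP words must use exactly 4 syllables")
  if (length(intersect(hi_syl, lo_syl)) > 0)
    p <- c(p, "high and low word syllable sets must be disjoint")
  # Latin-rectangle design: each low syllable exactly once per position and
  # in exactly 3 of the 4 low words.
  for (pos in c("syl1", "syl2", "syl3")) {
    if (anyDuplicated(lo[[pos]]))
      p <- c(p, sprintf("low syllable repeated at position %s", substring(pos, 4)))
  }
  in3 <- vapply(low_set, function(x)
    sum(lo$syl1 == x | lo$syl2 == x | lo$syl3 == x), integer(1))
  if (length(low_set) == 4 && any(in3 != 3L))
    p <- c(p, "each low syllable must occur in exactly 3 low words")
  wb <- internal_bigrams(w)
  if (anyDuplicated(wb)) p <- c(p, "the 8 internal word bigrams must be distinct")
  # foils
  if (!is.null(f)) {
    if (nrow(f) != 8 || sum(f$tp_class == "high") != 4 || sum(f$tp_class == "low") != 4)
      p <- c(p, "need 4 high + 4 low foils")
    fb <- internal_bigrams(f)
    if (length(intersect(fb, wb)) > 0)
      p <- c(p, "foil internal bigrams must not occur inside any word")
    fs <- unlist(f[, c("syl1", "syl2", "syl3")], use.names = FALSE)
    cnt <- table(factor(fs, levels = s$label))
    bad_hi <- s$label[s$freq_class == "high"][cnt[s$label[s$freq_class == "high"]] != 1L]
    bad_lo <- s$label[s$freq_class == "low"][cnt[s$label[s$freq_class == "low"]] != 3L]
    if (length(bad_hi) > 0 || length(bad_lo) > 0)
      p <- c(p, "foil set must reuse each high syllable once and each low syllable three times")
    # class mixing: high foil = 2 high + 1 low syllable, low foil = 2 low + 1 high
    cls <- matrix(s$freq_class[match(as.vector(as.matrix(f[, c("syl1", "syl2", "syl3")])),
                                     s$label)], nrow = nrow(f))
    n_high <- rowSums(cls == "high")
    if (any(n_high[f$tp_class == "high"] != 2L) || any(n_high[f$tp_class == "low"] != 1L))
      p <- c(p, "foil class composition rule violated (2+1 mixing)")
    # positional occupancy of foil syllables is a subset of word occupancy
    occ <- function(df) unique(c(paste(df$syl1, 1), paste(df$syl2, 2), paste(df$syl3, 3)))
    if (!all(occ(f) %in% occ(w)))
      p <- c(p, "foil syllables must keep positions they occupy in words")
  }
  p
}

#' Load one of the two canonical syllabaries
#'
#' Returns the published 8-word + 8-foil material set for syllabary `"A"`
#' or `"B"`, syllabified as consecutive CV units.
#'
#' @param id `"A"` or `"B"`.
#' @return An `sl_lexicon`.
#' @export
canonical_syllabary <- function(id = c("A", "B")) {
  if (!is.character(id) || length(id) != 1 || !id %in% c("A", "B"))
    stopf("unknown syllabary id: %s (use \"A\" or \"B\")", paste(id, collapse = ","))
  cw <- CANONICAL_WORDS[[id]]
  w <- words_df(cw$high, cw$low)
  # canonical foil sources: the word whose initial syllable the foil keeps
  src <- function(foils) {
    ini <- substring(foils, 1, 2)
    w$id[match(ini, w$syl1)]
  }
  f <- foils_df(cw$high_foils, cw$low_foils, src(cw$high_foils), src(cw$low_foils))
  new_lexicon(w, f, syllabary_id = id)
}

#' Design transitional probability between two syllables
#'
#' TP(y | x) under the design assumption that every word occurs equally
#' often (`tokens_per_word` tokens). The denominator counts every token of
#' `x`, including word-final ones, so internal bigrams of high-TP words
#' score 1, internal bigrams of low-TP words score 1/3, and foil bigrams 0.
#'
#' @param lex An `sl_lexicon`.
#' @param x,y Syllable labels.
#' @param tokens_per_word Word token count assumed for the stream (default 60).
#' @return A probability.
#' @export
design_tp <- function(lex, x, y, tokens_per_word = 60) {
  w <- lex$words
  if (!x %in% lex$syllables$label) stopf("syllable \"%s\" is not in the lexicon", x)
  n_x <- sum(w$syl1 == x) + sum(w$syl2 == x) + sum(w$syl3 == x)
  n_xy <- sum(w$syl1 == x & w$syl2 == y) + sum(w$syl2 == x & w$syl3 == y)
  (n_xy * tokens_per_word) / (n_x * tokens_per_word)
}

#' Table of design transitional probabilities
#'
#' All ordered syllable bigrams attested inside words (plus, optionally,
#' foil-internal bigrams, which have probability 0 by construction), with
#' the supporting design token counts.
#'
#' @inheritParams design_tp
#' @param include_foils Also list foil-internal bigrams (TP 0).
#' @return Data frame with `x`, `y`, `count_xy`, `count_x`, `tp`, `kind`.
#' @export
design_tp_table <- function(lex, tokens_per_word = 60, include_foils = TRUE) {
  w <- lex$words
  big <- rbind(
    data.frame(x = w$syl1, y = w$syl2, cls = w$tp_class, stringsAsFactors = FALSE),
    data.frame(x = w$syl2, y = w$syl3, cls = w$tp_class, stringsAsFactors = FALSE)
  )
  big <- unique(big)
  rows <- lapply(seq_len(nrow(big)), function(i) {
    data.frame(x = big$x[i], y = big$y[i], tp_class = big$cls[i], kind = "word",
               tp = design_tp(lex, big$x[i], big$y[i], tokens_per_word),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (include_foils && !is.null(lex$foils)) {
    f <- lex$foils
    fb <- unique(rbind(
      data.frame(x = f$syl1, y = f$syl2, cls = f$tp_class, stringsAsFactors = FALSE),
      data.frame(x = f$syl2, y = f$syl3, cls = f$tp_class, stringsAsFactors = FALSE)
    ))
    out <- rbind(out, data.frame(
      x = fb$x, y = fb$y, tp_class = fb$cls, kind = "foil",
      tp = vapply(seq_len(nrow(fb)), function(i)
        design_tp(lex, fb$x[i], fb$y[i], tokens_per_word), numeric(1)),
      stringsAsFactors = FALSE))
  }
  n_x <- vapply(out$x, function(s)
    (sum(w$syl1 == s) + sum(w$syl2 == s) + sum(w$syl3 == s)) * tokens_per_word, numeric(1))
  out$count_x <- n_x
  out$count_xy <- round(out$tp * n_x)
  rownames(out) <- NULL
  out
}

random_permutation_avoiding <- function(n, forbidden_cols) {
  # random permutation p with p[i] not in forbidden_cols[[i]], by rejection
  for (try in 1:2000) {
    p <- sample.int(n)
    ok <- all(vapply(seq_len(n), function(i) !(p[i] %in% forbidden_cols[[i]]), logical(1)))
    if (ok) return(p)
  }
  NULL
}

#' Build a lexicon from 16 syllable tokens
#'
#' Partitions the 12 high-class syllables into 4 high-TP words and arranges
#' the 4 low-class syllables into 4 low-TP words forming a Latin-rectangle
#' design (each syllable once per position across the set; each word omits
#' one syllable) with all 8 internal bigrams distinct, then derives foils.
#'
#' @param high_syllables 12 distinct syllable labels.
#' @param low_syllables 4 distinct syllable labels.
#' @param seed Integer seed; identical seeds give identical lexicons.
#' @param syllabary_id Identifier stored on the result.
#' @return An `sl_lexicon`.
#' @export
build_lexicon <- function(high_syllables, low_syllables, seed = 1L,
                          syllabary_id = "custom") {
  toks <- c(high_syllables, low_syllables)
  if (length(high_syllables) != 12 || length(low_syllables) != 4 ||
      anyDuplicated(toks))
    stopf("need 12 + 4 distinct syllable tokens")
  with_seed(seed, {
    hs <- sample(high_syllables)
    high <- vapply(1:4, function(i) paste0(hs[(3 * i - 2):(3 * i)], collapse = ""), character(1))
    low_words <- NULL
    for (attempt in 1:500) {
      c1 <- sample.int(4)
      c2 <- random_permutation_avoiding(4, as.list(c1))
      if (is.null(c2)) next
      c3 <- random_permutation_avoiding(4, Map(c, c1, c2))
      if (is.null(c3)) next
      bg <- c(paste(c1, c2), paste(c2, c3))
      if (anyDuplicated(bg)) next
      low_words <- paste0(low_syllables[c1], low_syllables[c2], low_syllables[c3])
      break
    }
    if (is.null(low_words))
      stopf("could not satisfy the low-word Latin-rectangle/bigram constraints")
    hm <- matrix(hs, ncol = 3, byrow = TRUE)
    w <- data.frame(
      id = c(high, low_words),
      tp_class = rep(c("high", "low"), each = 4),
      syl1 = c(hm[, 1], low_syllables[c1]),
      syl2 = c(hm[, 2], low_syllables[c2]),
      syl3 = c(hm[, 3], low_syllables[c3]),
      stringsAsFactors = FALSE)
    lex <- structure(list(syllabary_id = syllabary_id, words = w, foils = NULL),
                     class = "sl_lexicon")
    f <- build_foils_from_words(w, seed = derive_seed(seed, 101L))
    new_lexicon(w, f, syllabary_id = syllabary_id)
  })
}

build_foils_from_words <- function(w, seed = 1L) {
  hi <- w[w$tp_class == "high", ]; lo <- w[w$tp_class == "low", ]
  with_seed(seed, {
    # low foils: keep initial + final, medial <- a position-2 high syllable
    # (bijection over the 4 high words' medials)
    med <- sample(hi$syl2)
    low_foils <- data.frame(
      id = paste0(lo$syl1, med, lo$syl3), tp_class = "low",
      syl1 = lo$syl1, syl2 = med, syl3 = lo$syl3, source_word_id = lo$id,
      stringsAsFactors = FALSE)
    # high foils: keep initial, medial <- a low syllable (bijection; every low
    # syllable occupies position 2 somewhere by the Latin rectangle), final <-
    # the final of a *different* high word (derangement)
    low_set <- unique(c(lo$syl1, lo$syl2, lo$syl3))
    medl <- sample(low_set)
    der <- random_permutation_avoiding(4, as.list(1:4))
    if (is.null(der)) stopf("could not find a derangement over high-word finals")
    high_foils <- data.frame(
      id = paste0(hi$syl1, medl, hi$syl3[der]), tp_class = "high",
      syl1 = hi$syl1, syl2 = medl, syl3 = hi$syl3[der], source_word_id = hi$id,
      stringsAsFactors = FALSE)
    out <- rbind(high_foils, low_foils)
    rownames(out) <- NULL
    out
  })
}

#' Build zero-TP foils for a lexicon
#'
#' Low foils keep their source word's initial and final syllables and swap
#' the medial for a high syllable attested at position 2; high foils keep
#' the initial, take a low medial, and a final deranged across high words.
#' The resulting foil set reuses each high syllable once and each low
#' syllable three times, and no foil bigram occurs inside any word.
#'
#' @param lex An `sl_lexicon` (its existing foils are ignored).
#' @param seed Integer seed.
#' @return Foil data frame.
#' @export
build_foils <- function(lex, seed = 1L) {
  f <- build_foils_from_words(lex$words, seed = seed)
  chk <- new_lexicon(lex$words, f, syllabary_id = lex$syllabary_id)
  chk$foils
}

#' Build the 16-trial 2-AFC test list
#'
#' Each word is paired with two distinct foils of its own TP class, once per
#' 8-trial block; within each block exactly half of the high-TP and half of
#' the low-TP trials are word-first, with the assignment complemented in the
#' other block. Trial order within block is randomized under the seed.
#'
#' @param lex An `sl_lexicon` with foils.
#' @param seed Integer seed.
#' @return Data frame of 16 trials with timing constants as attributes
#'   (`fixation_ms` 1000, `isi_ms` 500, `timeout_ms` 10000).
#' @export
build_2afc_trials <- function(lex, seed = 1L) {
  w <- lex$words; f <- lex$foils
  with_seed(seed, {
    blocks <- list()
    for (cls in c("high", "low")) {
      wi <- w$id[w$tp_class == cls]
      fi <- f$id[f$tp_class == cls]
      p1 <- sample(fi)
      p2 <- NULL
      repeat {
        p2 <- sample(fi)
        if (all(p2 != p1)) break
      }
      first1 <- sample(1:4, 2)  # word-first in block 1; complement in block 2
      blocks[[cls]] <- list(
        b1 = data.frame(block = 1L, word_id = wi, foil_id = p1, tp_class = cls,
                        order = ifelse(seq_along(wi) %in% first1, "word-first", "foil-first"),
                        stringsAsFactors = FALSE),
        b2 = data.frame(block = 2L, word_id = wi, foil_id = p2, tp_class = cls,
                        order = ifelse(seq_along(wi) %in% first1, "foil-first", "word-first"),
                        stringsAsFactors = FALSE))
    }
    b1 <- rbind(blocks$high$b1, blocks$low$b1)
    b2 <- rbind(blocks$high$b2, blocks$low$b2)
    b1 <- b1[sample.int(nrow(b1)), ]
    b2 <- b2[sample.int(nrow(b2)), ]
    out <- rbind(b1, b2)
    out$trial <- seq_len(nrow(out))
    rownames(out) <- NULL
    out <- out[, c("trial", "block", "word_id", "foil_id", "tp_class", "order")]
    attr(out, "fixation_ms") <- 1000
    attr(out, "isi_ms") <- 500
    attr(out, "timeout_ms") <- 10000
    out
  })
}

#' Rotate syllables across positions to derive counterbalancing lists
#'
#' Produces an alternative material list by cyclically rotating each word's
#' syllable positions; a heuristic stand-in for the unpublished list
#' construction, provided for counterbalancing only.
#'
#' @param lex An `sl_lexicon`.
#' @param k Rotation amount (1 or 2).
#' @return An `sl_lexicon` whose words are position-rotated; foils rebuilt.
#' @export
rotate_lexicon <- function(lex, k = 1L) {
  k <- as.integer(k) %% 3L
  if (k == 0L) return(lex)
  rot <- function(df, perm) {
    cols <- c("syl1", "syl2", "syl3")
    df[, cols] <- df[, cols][, perm]
    df$id <- paste0(df$syl1, df$syl2, df$syl3)
    df
  }
  perms <- if (k == 1L) list(c(3, 1, 2), c(2, 3, 1)) else
    list(c(2, 3, 1), c(3, 1, 2))
  for (perm in perms) {
    w <- rot(lex$words, perm)
    out <- tryCatch({
      f <- build_foils_from_words(w, seed = 1L)
      new_lexicon(w, f, syllabary_id = paste0(lex$syllabary_id, "-rot", k))
    }, error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stopf("no valid position rotation exists for this lexicon")
}

#' Serialize a lexicon to TSV
#'
#' Writes one row per word and foil (`kind`, `id`, `class`, `syl1..3`,
#' `source_word`).
#'
#' @param lex An `sl_lexicon`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lexicon_tsv <- function(lex, path) {
  w <- lex$words; f <- lex$foils
  out <- rbind(
    data.frame(kind = "word", id = w$id, class = w$tp_class,
               syl1 = w$syl1, syl2 = w$syl2, syl3 = w$syl3,
               source_word = NA_character_, stringsAsFactors = FALSE),
    data.frame(kind = "foil", id = f$id, class = f$tp_class,
               syl1 = f$syl1, syl2 = f$syl2, syl3 = f$syl3,
               source_word = f$source_word_id, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.sl_lexicon <- function(x, ...) {
  cat(sprintf("<sl_lexicon %s: %d words (%d high, %d low), %d foils, %d syllables>\n",
              x$syllabary_id, nrow(x$words), sum(x$words$tp_class == "high"),
              sum(x$words$tp_class == "low"),
              if (is.null(x$foils)) 0L else nrow(x$foils), nrow(x$syllables)))
  invisible(x)
}
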