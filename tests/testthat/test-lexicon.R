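test_that("canonical syllabaries match the published material set", {
  a <- canonical_syllabary("A")
  expect_setequal(a$words$id[a$words$tp_class == "high"],
                  c("tucida", "bupepo", "modego", "bibaca"))
  expect_setequal(a$words$id[a$words$tp_class == "low"],
                  c("dotige", "tidomi", "migedo", "gemiti"))
  expect_setequal(a$foils$id,
                  c("tumica", "bugego", "modopo", "bitida",
                    "dobage", "tidemi", "mipedo", "geciti"))
  b <- canonical_syllabary("B")
  expect_setequal(b$words$id[b$words$tp_class == "low"],
                  c("pitegu", "tepime", "megupi", "gumete"))
  expect_setequal(b$words$id[b$words$tp_class == "high"],
                  c("todidu", "cegita", "gapabe", "bomaco"))
  # 16 distinct syllables; the high-frequency (3x) set of A
  expect_length(unique(a$syllables$label), 16)
  expect_setequal(a$syllables$label[a$syllables$freq_class == "low"],
                  c("do", "ti", "ge", "mi"))
  # both canonical sets pass every generator invariant
  expect_length(validate_lexicon(a), 0)
  expect_length(validate_lexicon(b), 0)
  expect_error(canonical_syllabary("C"), "unknown syllabary")
})

test_that("syllabification splits consecutive CV units", {
  expect_equal(syllabify("tucida")[[1]], c("tu", "ci", "da"))
  expect_error(syllabify("tucid"), "even number")
})

test_that("design TPs are 1, 1/3 and 0 for high, low and foil bigrams", {
  for (id in c("A", "B")) {
    lex <- canonical_syllabary(id)
    tab <- design_tp_table(lex)
    expect_equal(unique(tab$tp[tab$kind == "word" & tab$tp_class == "high"]), 1)
    expect_equal(unique(tab$tp[tab$kind == "word" & tab$tp_class == "low"]), 1 / 3)
    expect_true(all(tab$tp[tab$kind == "foil"] == 0))
  }
  a <- canonical_syllabary("A")
  expect_equal(design_tp(a, "tu", "ci"), 1)
  expect_equal(design_tp(a, "do", "ti"), 1 / 3)
  expect_equal(design_tp(a, "do", "ba"), 0)
  expect_error(design_tp(a, "zz", "ti"), "not in the lexicon")
  # denominator: 180 tokens of "do" (3 words x 60), 60 of the bigram
  tab <- design_tp_table(a)
  row <- tab[tab$x == "do" & tab$y == "ti", ]
  expect_equal(row$count_x, 180)
  expect_equal(row$count_xy, 60)
})

test_that("built lexicons satisfy all invariants, deterministically", {
  hi <- paste0(rep(c("ba", "be", "bi", "bo", "bu", "da"), 2),
               rep(1:2, each = 6))
  hi <- sprintf("s%02d", 1:12)
  lo <- c("ka", "ke", "ki", "ko")
  for (seed in 1:8) {
    lex <- build_lexicon(hi, lo, seed = seed)
    expect_length(validate_lexicon(lex), 0)
    lowords <- lex$words[lex$words$tp_class == "low", ]
    # 4x3 positional incidence with one occurrence per (syllable, position)
    for (pos in c("syl1", "syl2", "syl3"))
      expect_setequal(lowords[[pos]], lo)
  }
  expect_identical(build_lexicon(hi, lo, seed = 3),
                   build_lexicon(hi, lo, seed = 3))
  expect_error(build_lexicon(hi[1:5], lo, seed = 1), "12")
})

test_that("exhaustive search confirms the low-word design space is non-empty", {
  # enumerate all (col1, col2, col3) permutation triples with distinct rows
  # and 8 distinct internal bigrams
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (rest in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  P <- perms(1:4)
  n_valid <- 0
  for (c1 in P) for (c2 in P) {
    if (any(c1 == c2)) next
    for (c3 in P) {
      if (any(c3 == c1) || any(c3 == c2)) next
      bg <- c(paste(c1, c2), paste(c2, c3))
      if (!anyDuplicated(bg)) n_valid <- n_valid + 1
    }
  }
  expect_gt(n_valid, 0)
  # and the solver finds one of them
  lex <- build_lexicon(sprintf("s%02d", 1:12), c("ka", "ke", "ki", "ko"), seed = 1)
  expect_length(validate_lexicon(lex), 0)
})

test_that("canonical foils follow the reverse-engineered construction rules", {
  for (id in c("A", "B")) {
    lex <- canonical_syllabary(id)
    w <- lex$words; f <- lex$foils
    lo_f <- f[f$tp_class == "low", ]
    src <- w[match(lo_f$source_word_id, w$id), ]
    # low foils preserve their source word's initial and final syllables
    expect_equal(lo_f$syl1, src$syl1)
    expect_equal(lo_f$syl3, src$syl3)
    # each low syllable occurs exactly 3 times across the 8 foils
    lows <- lex$syllables$label[lex$syllables$freq_class == "low"]
    fs <- unlist(f[, c("syl1", "syl2", "syl3")], use.names = FALSE)
    expect_true(all(table(factor(fs[fs %in% lows], levels = lows)) == 3))
    hi_f <- f[f$tp_class == "high", ]
    src_h <- w[match(hi_f$source_word_id, w$id), ]
    expect_equal(hi_f$syl1, src_h$syl1)       # initial kept
    expect_true(all(hi_f$syl3 != src_h$syl3)) # final deranged
  }
})

test_that("generated foils satisfy the foil invariants over seeds", {
  lex <- canonical_syllabary("A")
  for (seed in 1:6) {
    f <- build_foils(lex, seed = seed)
    chk <- new_lexicon(lex$words, f, "A")   # validator runs inside
    expect_s3_class(chk, "sl_lexicon")
    wb <- c(paste(lex$words$syl1, lex$words$syl2),
            paste(lex$words$syl2, lex$words$syl3))
    fb <- c(paste(f$syl1, f$syl2), paste(f$syl2, f$syl3))
    expect_length(intersect(fb, wb), 0)
    for (i in seq_len(nrow(f)))
      expect_equal(design_tp(lex, f$syl1[i], f$syl2[i]), 0)
  }
  expect_identical(build_foils(lex, seed = 2), build_foils(lex, seed = 2))
})

test_that("2-AFC trial lists satisfy the pairing and counterbalancing rules", {
  lex <- canonical_syllabary("A")
  for (seed in 1:5) {
    tr <- build_2afc_trials(lex, seed = seed)
    expect_equal(nrow(tr), 16)
    # each word appears twice, against two distinct foils, once per block
    for (wid in lex$words$id) {
      rows <- tr[tr$word_id == wid, ]
      expect_equal(nrow(rows), 2)
      expect_length(unique(rows$foil_id), 2)
      expect_setequal(rows$block, 1:2)
    }
    # foils are of the word's own class
    expect_equal(lex$foils$tp_class[match(tr$foil_id, lex$foils$id)],
                 tr$tp_class)
    # per block: exactly 2 high and 2 low words are word-first
    for (b in 1:2) for (cls in c("high", "low")) {
      sel <- tr$block == b & tr$tp_class == cls
      expect_equal(sum(tr$order[sel] == "word-first"), 2)
    }
  }
  expect_identical(build_2afc_trials(lex, seed = 9),
                   build_2afc_trials(lex, seed = 9))
})

test_that("lexicon TSV round-trips the material set", {
  lex <- canonical_syllabary("A")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon_tsv(lex, path)
  x <- read.delim(path)
  expect_equal(nrow(x), 16)
  expect_setequal(x$id[x$kind == "word"], lex$words$id)
  expect_setequal(x$id[x$kind == "foil"], lex$foils$id)
})

test_that("rotated counterbalancing lists remain valid lexicons", {
  lex <- canonical_syllabary("A")
  r1 <- rotate_lexicon(lex, 1)
  expect_length(validate_lexicon(r1), 0)
  expect_setequal(r1$syllables$label, lex$syllables$label)
  expect_false(any(r1$words$id %in% lex$words$id))
})
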