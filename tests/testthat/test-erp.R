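make_eeg <- function(data, rate = 512, channels = NULL) {
  if (is.null(channels)) channels <- rownames(data)
  structure(list(data = data, rate = rate, channels = channels, units = "uV"),
            class = "sl_eeg")
}

test_that("mastoid re-referencing removes the common reference", {
  ch <- c("Cz", "Fz", "M1", "M2")
  d <- matrix(0, 4, 100, dimnames = list(ch, NULL))
  d["Cz", ] <- 5
  eeg <- make_eeg(d)
  # zero mastoids: identity
  expect_equal(rereference_mastoids(eeg)$data, d)
  # after re-referencing the mastoid average is identically zero
  d["M1", ] <- rnorm(100); d["M2", ] <- rnorm(100)
  r <- rereference_mastoids(make_eeg(d))
  expect_equal((r$data["M1", ] + r$data["M2", ]) / 2, rep(0, 100))
  # a common offset on every channel vanishes
  d2 <- matrix(3, 4, 100, dimnames = list(ch, NULL))
  expect_true(all(rereference_mastoids(make_eeg(d2))$data == 0))
  expect_error(rereference_mastoids(make_eeg(d[1:2, , drop = FALSE])),
               "mastoid")
})

test_that("the zero-phase band-pass has the designed magnitude response", {
  rate <- 512
  t <- seq(0, 20, by = 1 / rate)
  mk <- function(f) make_eeg(matrix(sin(2 * pi * f * t), 1,
                                    dimnames = list("Cz", NULL)), rate)
  mid <- function(x) x[round(length(x) * 0.4):round(length(x) * 0.6)]
  y10 <- bandpass_filter(mk(10))$data[1, ]
  expect_lt(abs(max(abs(mid(y10))) - 1), 0.01)       # 10 Hz preserved
  y50 <- bandpass_filter(mk(50))$data[1, ]
  expect_lt(max(abs(mid(y50))), 0.10)                # 50 Hz attenuated
  # forward-backward filtering leaves a symmetric impulse response (up to
  # the slowly decaying high-pass edge transient)
  imp <- numeric(16001); imp[8001] <- 1
  yi <- bandpass_filter(make_eeg(matrix(imp, 1, dimnames = list("Cz", NULL)),
                                 rate))$data[1, ]
  expect_equal(which.max(abs(yi)), 8001)
  expect_lt(max(abs(yi - rev(yi))) / max(abs(yi)), 1e-3)
  expect_error(bandpass_filter(mk(10), high = 300), "invalid")
})

test_that("epoching produces 768-sample baseline-zero epochs at 512 Hz", {
  rate <- 512
  ch <- c("Cz", "M1", "M2")
  n <- rate * 10
  d <- matrix(rnorm(3 * n), 3, dimnames = list(ch, NULL))
  eeg <- make_eeg(d, rate)
  ev <- data.frame(onset = c(1000, 2500, 4000), word_id = "w",
                   tp_class = "high", block = 1, half = 1, task = "implicit")
  ep <- epoch_eeg(eeg, ev)
  expect_equal(dim(ep$data), c(3, 3, round(1.5 * rate)))
  expect_equal(dim(ep$data)[3], 768)
  # post-baseline mean of the -300..0 window is zero by definition
  sel <- ep$times >= -300 & ep$times <= 0
  bl <- apply(ep$data[, , sel], c(1, 2), mean)
  expect_true(all(abs(bl) < 1e-9))
  # events too close to the record edge are dropped with a warning
  ev2 <- rbind(ev, data.frame(onset = 100, word_id = "w", tp_class = "high",
                              block = 1, half = 1, task = "implicit"))
  expect_warning(ep2 <- epoch_eeg(eeg, ev2), "record edge")
  expect_equal(dim(ep2$data)[1], 3)
})

test_that("a full default stream yields 480 epochs per task", {
  lex <- canonical_syllabary("A")
  sq <- generate_word_sequence(lex, seed = 1)
  tl <- build_timeline(sq)
  spec <- calibration_spec(rate = 128, noise_sd = 0, artifact_rate = 0)
  sim <- simulate_eeg(tl, spec, seed = 1)
  ep <- epoch_eeg(sim[[1]]$eeg, sim[[1]]$events)
  expect_equal(dim(ep$data)[1], 480)
  expect_equal(dim(ep$data)[3], round(1.5 * 128))
})

test_that("threshold rejection is strict and matches a brute-force oracle", {
  mk_ep <- function(data) {
    structure(list(data = data, times = seq_len(dim(data)[3]),
                   channels = paste0("c", seq_len(dim(data)[2])),
                   labels = data.frame(task = "implicit",
                                       tp_class = "high", half = 1,
                                       row.names = NULL)[rep(1, dim(data)[1]), ],
                   retained = rep(TRUE, dim(data)[1]), rate = 512),
              class = "sl_epochs")
  }
  d <- array(0, c(3, 2, 10))
  d[1, 1, 5] <- 99.9    # below threshold: retained
  d[2, 2, 7] <- 100.1   # above: rejected
  d[3, 1, 2] <- 100     # exactly at threshold: retained (strict inequality)
  r <- reject_artifacts(mk_ep(d), 100)
  expect_equal(r$retained, c(TRUE, FALSE, TRUE))
  # oracle comparison on 1,000 random epochs
  set.seed(42)
  d2 <- array(rnorm(1000 * 4 * 20, sd = 55), c(1000, 4, 20))
  r2 <- reject_artifacts(mk_ep(d2), 100)
  expect_identical(r2$retained, oracle_reject_mask(d2, 100))
})

test_that("the two-thirds inclusion rule is applied per condition cell", {
  labels <- expand.grid(task = c("implicit", "explicit"),
                        tp_class = c("high", "low"), half = 1:2,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  labels <- labels[rep(seq_len(8), each = 12), ]  # 12 epochs per cell
  ep <- structure(list(data = array(0, c(96, 1, 4)), times = 1:4,
                       channels = "Cz", labels = labels,
                       retained = rep(TRUE, 96), rate = 512),
                  class = "sl_epochs")
  expect_true(include_participant(ep))
  # drop one cell to 50% retention -> excluded
  ep2 <- ep
  first_cell <- which(labels$task == "implicit" & labels$tp_class == "high" &
                        labels$half == 1)
  ep2$retained[first_cell[1:6]] <- FALSE
  inc <- include_participant(ep2)
  expect_false(as.logical(inc))
  expect_match(attr(inc, "reason"), "retention")
  # retaining exactly ceiling(2/3 x 12) = 8 is still included
  ep3 <- ep
  ep3$retained[first_cell[1:4]] <- FALSE
  expect_true(as.logical(include_participant(ep3)))
})

test_that("condition averaging is an arithmetic mean over retained epochs", {
  labels <- data.frame(task = "implicit", tp_class = rep(c("high", "low"), each = 2),
                       half = 1, stringsAsFactors = FALSE)
  d <- array(0, c(4, 2, 5))
  d[1, , ] <- 1; d[2, , ] <- 1          # identical epochs
  d[3, , ] <- 1; d[4, , ] <- -1         # +1 and -1 average to 0
  ep <- structure(list(data = d, times = 1:5, channels = c("a", "b"),
                       labels = labels, retained = rep(TRUE, 4), rate = 512),
                  class = "sl_epochs")
  avg <- condition_erps(ep, by = c("tp_class"))
  expect_true(all(avg$erps[["high"]] == 1))
  expect_true(all(avg$erps[["low"]] == 0))
  # grand average equals mean of means on balanced data
  expect_equal((avg$erps[["high"]] + avg$erps[["low"]]) / 2,
               colMeans(d))
})

test_that("ROI/window means match a brute-force double loop", {
  rois <- canonical_rois()
  expect_length(rois$central, 9)
  expect_true("CPz" %in% rois$central)
  expect_length(rois$frontal, 9)
  expect_length(rois$fronto_central, 9)
  channels <- unique(c(unlist(rois), "M1"))
  times <- seq(-300, 1195, by = 1000 / 512)
  set.seed(7)
  erp <- matrix(rnorm(length(channels) * length(times)), length(channels),
                dimnames = list(channels, NULL))
  for (nm in names(rois)) {
    got <- roi_window_mean(erp, times, channels, rois[[nm]], c(80, 120))
    expect_equal(got, oracle_roi_mean(erp, times, channels, rois[[nm]], c(80, 120)))
  }
  # constant waveform returns the constant
  cst <- matrix(-5, length(channels), length(times), dimnames = list(channels, NULL))
  expect_equal(roi_window_mean(cst, times, channels, rois$central, c(350, 450)), -5)
  expect_error(roi_window_mean(erp, times, channels, c("Cz", "XX9"), c(80, 120)),
               "XX9")
})

test_that("the pipeline is linear in its input up to rejection", {
  lex <- canonical_syllabary("A")
  sq <- generate_word_sequence(lex, reps_per_block = 1, n_blocks = 2, seed = 1)
  tl <- build_timeline(sq)
  spec <- calibration_spec(rate = 128, noise_sd = 3, artifact_rate = 0)
  sim <- simulate_eeg(tl, spec, seed = 9)
  run <- function(eeg) {
    pr <- process_subject(eeg, sim[[1]]$events, group = "adults",
                          reject_uV = NULL)
    pr$measures$amplitude
  }
  a1 <- run(sim[[1]]$eeg)
  eeg3 <- sim[[1]]$eeg
  eeg3$data <- eeg3$data * 3
  expect_equal(run(eeg3), 3 * a1, tolerance = 1e-6)
})

test_that("epoch-then-baseline equals baseline during epoching", {
  lex <- canonical_syllabary("A")
  sq <- generate_word_sequence(lex, reps_per_block = 1, n_blocks = 2, seed = 2)
  tl <- build_timeline(sq)
  spec <- calibration_spec(rate = 128, noise_sd = 5, artifact_rate = 0)
  sim <- simulate_eeg(tl, spec, seed = 3)
  a <- epoch_eeg(sim[[1]]$eeg, sim[[1]]$events)
  b <- apply_baseline(epoch_eeg(sim[[1]]$eeg, sim[[1]]$events, baseline_ms = NULL))
  expect_identical(a$data, b$data)
})
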