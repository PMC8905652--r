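# Orchestration: experiment configuration, validation, and the end-to-end
# reproduce() run (design -> stream -> simulate -> erp -> stats -> report).

#' Default experiment configuration
#'
#' The shipped defaults are the study conditions: canonical syllabary A for
#' the implicit task and B for the explicit task, 60 word repetitions in 6
#' blocks (300 ms syllables, 50 ms gaps), a 15% chirp rate, 21 adults and
#' 20 children, 512 Hz EEG, +/-100 uV rejection with the two-thirds
#' inclusion rule, and alpha = 0.05.
#'
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @return Nested configuration list of class `sl_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    syllabaries = list(implicit = "A", explicit = "B"),
    stream = list(reps_per_block = 10L, n_blocks = 6L, syl_ms = 300,
                  gap_ms = 50, chirp_rate = 0.15, chirp_total = NULL),
    behavior = list(n_adults = 21L, n_children = 20L, subject_rho = 0.5),
    chirp_detection = list(
      adults = list(hit_rate = 0.98, fa_rate = 0.002),
      children = list(hit_rate = 0.92, fa_rate = 0.005)),
    eeg = list(enabled = TRUE, n_adults = 21L, n_children = 20L,
               sample_rate = 512, noise_sd = 10, artifact_rate = 0.15,
               reps_per_block = NULL),
    analysis = list(reject_uV = 100, min_fraction = 2 / 3, alpha = 0.05,
                    windows = list(
                      adults = list(N100 = c(80, 120), N400 = c(350, 450)),
                      children = list(N100 = c(80, 120), N400 = c(400, 500))))
  ), class = "sl_config")
}

#' A scaled-down configuration for demonstrations and simulation studies
#'
#' Same structure and statistical assumptions as [default_config()], with
#' smaller problem sizes in the EEG arm (fewer subjects and word
#' repetitions) so an end-to-end run finishes in seconds.
#'
#' @param seed Master seed.
#' @return An `sl_config`.
#' @export
demo_config <- function(seed = 1L) {
  cfg <- default_config(seed)
  cfg$behavior$n_adults <- 12L
  cfg$behavior$n_children <- 12L
  cfg$eeg$n_adults <- 4L
  cfg$eeg$n_children <- 4L
  cfg$eeg$reps_per_block <- 1L
  cfg
}

#' Read a configuration from YAML
#'
#' @param path YAML file with the [default_config()] structure; missing
#'   entries fall back to the defaults.
#' @return An `sl_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(user$seed %||% 1L)
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        merge_into(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  structure(merge_into(unclass(cfg), user), class = "sl_config")
}

#' Validate a configuration
#'
#' @param config An `sl_config`.
#' @return Character vector of problems; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  p <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  st <- config$stream
  chk(all(unlist(config$syllabaries) %in% c("A", "B")),
      "syllabary ids must be A or B")
  chk(is.numeric(config$seed) && config$seed == round(config$seed),
      "seed must be an integer")
  chk(st$reps_per_block >= 1 && st$n_blocks >= 1, "stream size must be positive")
  chk(st$syl_ms > 0 && st$gap_ms >= 0, "durations must be positive")
  if (!is.null(st$chirp_total)) {
    chk(st$chirp_total >= 1, "chirp total must be >= 1")
  } else {
    chk(st$chirp_rate > 0 && st$chirp_rate <= 1, "chirp rate out of range (0, 1]")
  }
  chk(config$behavior$n_adults >= 2 && config$behavior$n_children >= 2,
      "need at least 2 subjects per group")
  for (g in c("adults", "children")) {
    cd <- config$chirp_detection[[g]]
    chk(all(c(cd$hit_rate, cd$fa_rate) >= 0 & c(cd$hit_rate, cd$fa_rate) <= 1),
        sprintf("%s chirp detection rates out of range", g))
    for (comp in names(config$analysis$windows[[g]])) {
      w <- config$analysis$windows[[g]][[comp]]
      chk(w[1] >= -300 && w[2] <= 1200 && w[1] < w[2],
          sprintf("%s %s window outside the -300..1200 ms epoch", g, comp))
    }
  }
  an <- config$analysis
  chk(an$reject_uV > 0, "rejection threshold must be positive")
  chk(an$min_fraction > 0 && an$min_fraction <= 1,
      "inclusion fraction out of range (0, 1]")
  chk(an$alpha > 0 && an$alpha < 1, "alpha out of range (0, 1)")
  ee <- config$eeg
  chk(ee$sample_rate > 60, "sampling rate must exceed twice the filter band")
  chk(ee$noise_sd >= 0, "noise SD must be non-negative")
  chk(ee$artifact_rate >= 0 && ee$artifact_rate < 1, "artifact rate out of range [0, 1)")
  p
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config), tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

components_for <- function(group, config) {
  comps <- default_components(group)
  for (i in seq_len(nrow(comps))) {
    w <- config$analysis$windows[[group]][[comps$component[i]]]
    if (!is.null(w)) { comps$win_lo[i] <- w[1]; comps$win_hi[i] <- w[2] }
  }
  comps
}

#' Run the full pipeline and collect a report bundle
#'
#' Builds the lexicons and streams for both tasks, audits the design and
#' the generated sequences, simulates behaviour, chirp detection and EEG
#' for both groups, runs the ERP pipeline and the behavioural and ERP
#' statistics, and returns everything in one machine-readable bundle with
#' provenance (config hash, seed, versions). Identical configurations give
#' identical payloads.
#'
#' @param config An `sl_config`.
#' @param out_dir Optional directory to write CSV/JSON outputs to.
#' @param progress Print per-stage messages.
#' @return List of class `sl_report`.
#' @export
reproduce <- function(config = default_config(), out_dir = NULL,
                      progress = FALSE) {
  problems <- validate_config(config)
  if (length(problems) > 0)
    stopf("invalid configuration: %s", paste(problems, collapse = "; "))
  say <- function(...) if (progress) message(sprintf(...))
  seed <- config$seed
  tasks <- c("implicit", "explicit")
  groups <- c("adults", "children")
  st <- config$stream

  ## design + stream per task -------------------------------------------
  say("stage design/stream")
  stream_info <- list()
  for (ti in seq_along(tasks)) {
    task <- tasks[ti]
    lex <- canonical_syllabary(config$syllabaries[[task]])
    sq <- generate_word_sequence(lex, reps_per_block = st$reps_per_block,
                                 n_blocks = st$n_blocks,
                                 seed = derive_seed(seed, 10L + ti))
    audit <- audit_word_sequence(sq)
    chirps <- assign_chirps(sq, rate = st$chirp_rate, total = st$chirp_total,
                            seed = derive_seed(seed, 20L + ti))
    tl <- build_timeline(sq, chirps, syl_ms = st$syl_ms, gap_ms = st$gap_ms)
    dtab <- design_tp_table(lex)
    stream_info[[task]] <- list(
      lexicon = lex, sequence = sq, chirps = chirps, timeline = tl,
      trials_2afc = build_2afc_trials(lex, seed = derive_seed(seed, 30L + ti)),
      audit = list(
        constraints_ok = audit$ok, problems = audit$problems,
        design_tp_high = unique(dtab$tp[dtab$kind == "word" & dtab$tp_class == "high"]),
        design_tp_low = unique(dtab$tp[dtab$kind == "word" & dtab$tp_class == "low"]),
        design_tp_foil_max = max(dtab$tp[dtab$kind == "foil"]),
        boundary_tp_high = word_boundary_tp(sq, "high"),
        boundary_tp_low = word_boundary_tp(sq, "low"),
        token_tp = token_tp_table(sq),
        word_period_ms = attr(tl, "word_period_ms"),
        block_ms = attr(tl, "total_ms") / st$n_blocks,
        total_ms = attr(tl, "total_ms"),
        n_chirps = sum(chirps)))
  }

  ## behaviour ----------------------------------------------------------
  say("stage behavior")
  profile <- canonical_behavior_profile(config$behavior$n_adults,
                                        config$behavior$n_children)
  beh <- simulate_behavior(profile, seed = derive_seed(seed, 40L),
                           subject_rho = config$behavior$subject_rho)
  tt <- do.call(rbind, lapply(split(beh, beh[c("group", "task", "tp_class")]),
    function(d) cbind(group = d$group[1], task = d$task[1],
                      tp_class = d$tp_class[1],
                      one_sample_t(d$score_pct, mu = 50))))
  rownames(tt) <- NULL
  cellm <- stats::aggregate(score_pct ~ group + task + tp_class, beh, mean)
  marg <- list(
    group = stats::setNames(
      vapply(groups, function(g) mean(cellm$score_pct[cellm$group == g]), numeric(1)),
      groups),
    task = stats::setNames(
      vapply(tasks, function(t) mean(cellm$score_pct[cellm$task == t]), numeric(1)),
      tasks))
  beh_anova <- mixed_anova(beh, "score_pct", "subject",
                           within = c("task", "tp_class"), between = "group",
                           alpha = config$analysis$alpha)

  ## chirp detection ----------------------------------------------------
  chirp_det <- list()
  for (g in groups) for (task in tasks) {
    cd <- config$chirp_detection[[g]]
    chirp_det[[paste(g, task, sep = ".")]] <- simulate_chirp_detection(
      stream_info[[task]]$chirps, hit_rate = cd$hit_rate, fa_rate = cd$fa_rate,
      seed = derive_seed(seed, 50L + match(g, groups) * 2L + match(task, tasks)))
  }

  ## EEG ----------------------------------------------------------------
  erp <- NULL
  if (isTRUE(config$eeg$enabled)) {
    say("stage eeg")
    ee <- config$eeg
    erp <- list()
    tl_eeg <- list()
    for (task in tasks) {
      if (!is.null(ee$reps_per_block) &&
          ee$reps_per_block < st$reps_per_block) {
        sq2 <- generate_word_sequence(
          stream_info[[task]]$lexicon, reps_per_block = ee$reps_per_block,
          n_blocks = st$n_blocks, seed = derive_seed(seed, 60L + match(task, tasks)))
        tl_eeg[[task]] <- build_timeline(sq2, syl_ms = st$syl_ms, gap_ms = st$gap_ms)
      } else {
        tl_eeg[[task]] <- stream_info[[task]]$timeline
      }
    }
    for (g in groups) {
      n_sub <- if (g == "adults") ee$n_adults else ee$n_children
      spec <- default_effect_spec(g, noise_sd = ee$noise_sd,
                                  artifact_rate = ee$artifact_rate,
                                  sample_rate = ee$sample_rate)
      comps <- components_for(g, config)
      measures <- list(); inclusion <- list()
      for (s in seq_len(n_sub)) {
        sub_rows <- list(); ok_all <- TRUE
        for (task in tasks) {
          sim <- simulate_eeg(tl_eeg[[task]], spec, n_subjects = 1L, task = task,
                              seed = derive_seed(seed, 1000L + 100L * match(g, groups) +
                                                   10L * match(task, tasks) + s))
          pr <- process_subject(sim[[1]]$eeg, sim[[1]]$events, group = g,
                                reject_uV = config$analysis$reject_uV,
                                min_fraction = config$analysis$min_fraction)
          sub_rows[[task]] <- if (identical(comps, default_components(g)))
            pr$measures else erp_measures(pr$epochs, components = comps)
          ok_all <- ok_all && isTRUE(as.logical(pr$included))
        }
        inclusion[[s]] <- data.frame(group = g, subject = s, included = ok_all,
                                     stringsAsFactors = FALSE)
        if (ok_all) {
          m <- do.call(rbind, sub_rows)
          m$subject <- paste0(substr(g, 1, 1), s)
          measures[[length(measures) + 1]] <- m
        }
      }
      gm <- do.call(rbind, measures)
      anovas <- list()
      for (comp in unique(gm$component)) {
        anovas[[comp]] <- rm_anova(gm[gm$component == comp, ], "amplitude",
                                   "subject", within = c("task", "tp_class", "half"),
                                   alpha = config$analysis$alpha)
      }
      erp[[g]] <- list(measures = gm, anova = anovas,
                       inclusion = do.call(rbind, inclusion),
                       n_included = length(measures))
    }
  }

  bundle <- structure(list(
    audit = lapply(stream_info, function(x) x$audit),
    trials_2afc = lapply(stream_info, function(x) x$trials_2afc),
    behavior = list(table = beh, t_tests = tt, anova = beh_anova,
                    marginals = marg),
    chirp_detection = chirp_det,
    erp = erp,
    provenance = list(config = config, config_hash = config_hash(config),
                      seed = seed,
                      package_version = tryCatch(
                        as.character(utils::packageVersion("syllastream")),
                        error = function(e) "dev"),
                      r_version = R.version.string,
                      timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "sl_report")
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' CSV for the tabular payloads, JSON for the audits and provenance.
#'
#' @param bundle An `sl_report`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  audit <- lapply(bundle$audit, function(a) a[setdiff(names(a), "token_tp")])
  jsonlite::write_json(
    list(audit = audit, chirp_detection = bundle$chirp_detection,
         provenance = bundle$provenance[setdiff(names(bundle$provenance), "config")]),
    file.path(out_dir, "audit.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (task in names(bundle$audit))
    wcsv(bundle$audit[[task]]$token_tp, sprintf("token_tp_%s.csv", task))
  wcsv(bundle$behavior$table, "behavior.csv")
  wcsv(bundle$behavior$t_tests, "behavior_t_tests.csv")
  wcsv(bundle$behavior$anova, "behavior_anova.csv")
  if (!is.null(bundle$erp)) {
    for (g in names(bundle$erp)) {
      wcsv(bundle$erp[[g]]$measures, sprintf("erp_measures_%s.csv", g))
      for (comp in names(bundle$erp[[g]]$anova))
        wcsv(bundle$erp[[g]]$anova[[comp]],
             sprintf("erp_anova_%s_%s.csv", g, comp))
    }
  }
  invisible(out_dir)
}
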