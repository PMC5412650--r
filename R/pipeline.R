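#' End-to-end processing pipeline
#'
#' Orchestrates the full analysis on one session: obtain a recording (from
#' disk or by simulation), detect beats and compute per-beat transit time,
#' heart rate and blood pressure (chest-to-neck, plus the MEG-proximal
#' variant when a MEG channel exists), extract respiration, convert NIRS
#' intensities to hemoglobin concentration changes, and — when hold-onset
#' markers are present — epoch and average every modality over the task
#' windows. All outputs land in `out_dir` as plain text, stamped with the
#' configuration hash so runs are self-describing; the same configuration
#' and seed always reproduce identical numbers.
#'
#' @param config A named list, or path to a YAML/JSON file holding one.
#'   Exactly one of `config$simulation` (arguments for [sim_config()]) or
#'   `config$input` (path for [read_recording()]) must be present. Optional
#'   blocks: `channels` (names for chest/neck/meg/nirs channels), `ptt`
#'   (`lag_window`, `prefilter`, `min_interval`), `respiration` (`cutoff`),
#'   `nirs` (`baseline_window`), `epochs` (`tmin`, `tmax`, `fs_out`,
#'   `marker`), `seed`, `out_dir`.
#' @return Invisibly, a result bundle: list with `recording`, `beats`, `ptt`,
#'   `hr`, `bp`, `bp_meg`, `respiration`, `hemoglobin`, `averages`, `qc`,
#'   `log`, `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a config-file path.", class = "hp_config_error")
  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (has_sim == has_input)
    abort("Exactly one of `simulation` and `input` must be present.", class = "hp_config_error")

  cfg_hash <- rlang::hash(config)
  logline <- character(0)
  say <- function(...) logline <<- c(logline, sprintf(...))
  say("config hash: %s", cfg_hash)

  chn <- utils::modifyList(
    list(chest = "chest", neck = "neck", meg = "meg",
         nirs = c("nirs660", "nirs850")),
    as.list(config$channels %||% list()))
  gt <- NULL
  if (has_sim) {
    sim_args <- as.list(config$simulation)
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    if (!is.null(sim_args$breath_hold_schedule) && isTRUE(sim_args$breath_hold_schedule == "task"))
      sim_args$breath_hold_schedule <- hold_schedule()
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_recording(scfg)
    rec <- sim$recording
    gt <- sim$ground_truth
    say("simulated %g s session, seed %d, %d beats", scfg$duration, scfg$seed,
        length(gt$beat_times$times))
  } else {
    rec <- read_recording(config$input)
    say("read recording %s (%d channels)", config$input, length(rec$channels))
  }

  for (nm in c(chn$chest, chn$neck)) {
    if (!nm %in% names(rec$channels))
      abort(sprintf("Configured channel '%s' not present in the recording.", nm),
            class = "hp_config_error")
  }

  pp <- utils::modifyList(list(lag_window = c(0.02, 0.4), prefilter = c(0.5, 30),
                               min_interval = 0.4),
                          as.list(config$ptt %||% list()))
  acm <- acm_ptt_bp(rec$channels[[chn$chest]], rec$channels[[chn$neck]],
                    lag_window = pp$lag_window, prefilter = pp$prefilter,
                    min_interval = pp$min_interval)
  say("chest-neck: %d beats kept, %d removed by QC, %d transit times",
      length(acm$beats$times), acm$qc$n_removed, nrow(acm$ptt))

  bp_meg <- NULL
  if (chn$meg %in% names(rec$channels)) {
    meg <- meg_ptt_bp(rec$channels[[chn$meg]], rec$channels[[chn$neck]],
                      lag_window = pp$lag_window, prefilter = pp$prefilter,
                      min_interval = pp$min_interval)
    bp_meg <- meg$bp
    say("meg-neck: %d transit times", nrow(meg$ptt))
  }

  rp <- utils::modifyList(list(cutoff = 0.5), as.list(config$respiration %||% list()))
  resp <- extract_respiration(rec$channels[[chn$chest]], cutoff = rp$cutoff)

  hemo <- NULL
  if (all(chn$nirs %in% names(rec$channels))) {
    np <- utils::modifyList(list(baseline_window = c(0, 30)), as.list(config$nirs %||% list()))
    hemo <- nirs_hemoglobin(rec, channels = chn$nirs,
                            baseline_window = np$baseline_window)
    say("nirs: %d hemoglobin samples", nrow(hemo))
  }

  ep <- utils::modifyList(list(tmin = -5, tmax = 80, fs_out = 4, marker = "hold_onset"),
                          as.list(config$epochs %||% list()))
  averages <- list()
  if (ep$marker %in% names(rec$markers)) {
    events <- rec$markers[[ep$marker]]
    per_beat <- list(
      ptt = acm$ptt[, c("beat_time", "ptt")],
      bp = acm$bp[, c("beat_time", "bp")],
      hr = acm$hr[, c("time", "hr")]
    )
    if (!is.null(hemo)) {
      per_beat$hbo <- hemo[, c("time", "hbo")]
      per_beat$hb <- hemo[, c("time", "hb")]
    }
    for (nm in names(per_beat)) {
      es <- baseline_correct(epoch_series(per_beat[[nm]], events,
                                          tmin = ep$tmin, tmax = ep$tmax,
                                          fs_out = ep$fs_out))
      averages[[nm]] <- average_epochs(es)
      say("epochs %s: %d averaged (window %g..%g s)", nm, attr(averages[[nm]], "n"),
          ep$tmin, ep$tmax)
    }
  }

  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(path) {
      writeLines(c(sprintf("# config_hash: %s", cfg_hash),
                   readLines(path)), path)
      files <<- c(files, path)
    }
    beat_tbl <- dplyr::full_join(tibble(beat_time = acm$ptt$beat_time, ptt = acm$ptt$ptt),
                                 tibble(beat_time = acm$bp$beat_time, bp = acm$bp$bp),
                                 by = "beat_time")
    p <- file.path(config$out_dir, "beats.tsv")
    utils::write.table(beat_tbl, p, sep = "\t", row.names = FALSE, quote = FALSE)
    stamp(p)
    p <- file.path(config$out_dir, "hr.tsv")
    utils::write.table(acm$hr, p, sep = "\t", row.names = FALSE, quote = FALSE)
    stamp(p)
    if (!is.null(hemo)) {
      p <- file.path(config$out_dir, "hemoglobin.tsv")
      keep <- seq(1, nrow(hemo), by = max(1L, round((attr(hemo, "fs") %||% 1) / 10)))
      utils::write.table(hemo[keep, ], p, sep = "\t", row.names = FALSE, quote = FALSE)
      stamp(p)
    }
    for (nm in names(averages)) {
      p <- file.path(config$out_dir, sprintf("average_%s.tsv", nm))
      utils::write.table(averages[[nm]], p, sep = "\t", row.names = FALSE, quote = FALSE)
      stamp(p)
    }
    p <- file.path(config$out_dir, "pipeline.log")
    writeLines(logline, p)
    files <- c(files, p)
  }

  invisible(list(recording = rec, ground_truth = gt, beats = acm$beats,
                 ptt = acm$ptt, hr = acm$hr, bp = acm$bp, bp_meg = bp_meg,
                 respiration = resp, hemoglobin = hemo, averages = averages,
                 qc = acm$qc, log = logline, files = files))
}
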