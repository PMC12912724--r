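#' Write / read an event design as TSV
#'
#' Events follow the BIDS-style convention: columns `onset`, `duration`,
#' `direction_deg`, `session`, `trial_type`. Lure trials carry an empty
#' direction. `read_events` validates the table: missing columns are
#' reported by name, onsets must be strictly increasing within a session,
#' and a lure row with a direction raises a validation warning.
#'
#' @param events an [make_event_design()] table.
#' @param file TSV path.
#' @return `read_events` returns a validated `event_design`;
#'   `write_events` returns `file` invisibly.
#' @export
write_events <- function(events, file) {
  utils::write.table(events, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(file)
}

#' @rdname write_events
#' @export
read_events <- function(file) {
  df <- utils::read.delim(file, na.strings = c("n/a", "NA", ""))
  need <- c("onset", "duration", "direction_deg", "session", "trial_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("events TSV is missing column(s): ", paste(miss, collapse = ", "))
  for (s in unique(df$session)) {
    on <- df$onset[df$session == s]
    if (any(diff(on) <= 0)) stop("onsets not strictly increasing within session ", s)
  }
  bad_lure <- df$trial_type == "lure" & !is.na(df$direction_deg)
  if (any(bad_lure)) {
    warning(sum(bad_lure), " lure trial(s) carry a direction value")
  }
  class(df) <- c("event_design", "data.frame")
  df
}

## Series matrices (scans x sessions, or voxels x scans) as TSV.
write_series <- function(series, file) {
  utils::write.table(series, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

read_series <- function(file) {
  as.matrix(utils::read.delim(file, header = FALSE))
}

#' Write a run manifest beside command outputs
#'
#' Every stochastic pipeline run records the command, its configuration
#' snapshot, all seeds, the package version, a timestamp and the output
#' paths, sufficient for bit-identical replay.
#'
#' @param command command name.
#' @param config configuration list (must include any seeds used).
#' @param outputs character vector of output paths.
#' @param file JSON path for the manifest.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(command, config, outputs, file) {
  manifest <- list(command = command,
                   config = config,
                   package = "phasesync",
                   version = as.character(utils::packageVersion("phasesync")),
                   timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
                   outputs = outputs)
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

## Merge user config over defaults, rejecting unknown keys exhaustively.
merge_config <- function(config, defaults, command) {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop(sprintf("invalid config key(s) for '%s': %s", command,
                 paste(unknown, collapse = ", ")))
  }
  defaults[names(config)] <- config
  defaults
}

#' Run a named analysis pipeline
#'
#' Dispatches to the corresponding module pipeline and writes its outputs
#' (TSV tables and JSON results) plus a replayable manifest into `out_dir`.
#' Commands: `"synth"` (event design + direction-tuned voxel series),
#' `"fit-periodicity"` (cross-validated quadrature alignment over candidate
#' folds), `"spectrum"` (fold spectrum + permutation null of a direction
#' table), `"behavior"` (synthetic behavioral vector + spectrum),
#' `"coupling"` (directional amplitude-phase coupling of two signals), and
#' `"simulate-model"` (goal-directed navigation simulation).
#'
#' @param name command name.
#' @param config named list of command settings (see Details); unknown keys
#'   are rejected with an exhaustive message.
#' @param out_dir output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
run_command <- function(name, config = list(), out_dir = ".") {
  commands <- c("synth", "fit-periodicity", "spectrum", "coupling",
                "behavior", "simulate-model")
  if (!name %in% commands) {
    stop("unknown command '", name, "'; available: ", paste(commands, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  if (name == "synth") {
    cfg <- merge_config(config, list(seed = 1, fold = 6, phi_deg = 15,
                                     amplitude = 1, noise_sd = 1), name)
    starts <- sample_ring_starts(seed = child_seed(cfg$seed, 1))
    events <- make_event_design(starts$direction_deg, seed = child_seed(cfg$seed, 2))
    series <- simulate_voxel(events, fold = cfg$fold, phi_deg = cfg$phi_deg,
                             amplitude = cfg$amplitude, noise_sd = cfg$noise_sd,
                             seed = child_seed(cfg$seed, 3))
    write_events(events, p("events.tsv"))
    write_series(series, p("series.tsv"))
    jsonlite::write_json(cfg, p("truth.json"), auto_unbox = TRUE, digits = NA)
    out <- c("events.tsv", "series.tsv", "truth.json")
  } else if (name == "fit-periodicity") {
    cfg <- merge_config(config, list(events = "events.tsv", series = "series.tsv",
                                     folds = 3:7), name)
    events <- read_events(cfg$events)
    series <- read_series(cfg$series)
    fits <- lapply(cfg$folds, function(k) {
      cv <- crossval_alignment(series, events, k)
      list(fold = k, phi_deg = cv$phi_deg, heldout_beta = cv$heldout_beta)
    })
    betas <- vapply(fits, `[[`, numeric(1), "heldout_beta")
    jsonlite::write_json(list(fits = fits,
                              argmax_fold = cfg$folds[which.max(betas)]),
                         p("periodicity.json"), auto_unbox = TRUE, digits = NA)
    out <- "periodicity.json"
  } else if (name == "spectrum") {
    cfg <- merge_config(config, list(table = "bins.tsv", n_perm = 5000, seed = 1), name)
    tab <- utils::read.delim(cfg$table)
    need <- c("direction_bin_deg", "value")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("spectrum table missing column(s): ", paste(miss, collapse = ", "))
    det <- detect_periodicity(tab$value, tab$direction_bin_deg,
                              n_perm = cfg$n_perm, seed = cfg$seed)
    jsonlite::write_json(list(folds = det$spectrum$folds,
                              magnitudes = det$spectrum$magnitudes,
                              uncorrected = det$null$uncorrected,
                              fwe_threshold = det$null$fwe,
                              significant_folds = det$significant_folds,
                              argmax_fold = det$argmax_fold,
                              n_perm = cfg$n_perm, seed = cfg$seed),
                         p("spectrum.json"), auto_unbox = TRUE, digits = NA)
    out <- "spectrum.json"
  } else if (name == "behavior") {
    cfg <- merge_config(config, list(seed = 1, fold = 3, phase_deg = 5,
                                     amplitude = 1, noise_sd = 0.5,
                                     n_perm = 5000), name)
    starts <- sample_ring_starts(seed = child_seed(cfg$seed, 1))
    beh <- simulate_behavior(starts$direction_deg, fold = cfg$fold,
                             phase_deg = cfg$phase_deg, amplitude = cfg$amplitude,
                             noise_sd = cfg$noise_sd, seed = child_seed(cfg$seed, 2))
    rs <- circular_resample(beh$direction_deg, beh$score, 36)
    det <- detect_periodicity(rs$values, rs$directions,
                              n_perm = cfg$n_perm, seed = child_seed(cfg$seed, 3))
    utils::write.table(beh, p("behavior.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(significant_folds = det$significant_folds,
                              argmax_fold = det$argmax_fold,
                              magnitudes = det$spectrum$magnitudes,
                              fwe_threshold = det$null$fwe, seed = cfg$seed),
                         p("behavior_spectrum.json"), auto_unbox = TRUE, digits = NA)
    out <- c("behavior.tsv", "behavior_spectrum.json")
  } else if (name == "coupling") {
    cfg <- merge_config(config, list(fast = "fast.tsv", slow = "slow.tsv",
                                     n_bins = 9), name)
    fast <- utils::read.delim(cfg$fast)
    slow <- utils::read.delim(cfg$slow)
    for (tab in list(fast, slow)) {
      miss <- setdiff(c("direction_deg", "value"), names(tab))
      if (length(miss)) stop("coupling table missing column(s): ", paste(miss, collapse = ", "))
    }
    ca <- coupling_alignment(fast$value, slow$value, n_bins = cfg$n_bins)
    pl <- phase_locking(fast$value, slow$value)
    jsonlite::write_json(list(M = ca$M, M_surrogate = ca$M_surrogate,
                              strength = ca$strength,
                              bin_centers_deg = ca$bin_centers,
                              argmax_bin_center = ca$argmax_bin_center,
                              plv = pl$plv, pli = pl$pli),
                         p("coupling.json"), auto_unbox = TRUE, digits = NA)
    out <- "coupling.json"
  } else { # simulate-model
    cfg <- merge_config(config, list(seed = 1, n_goals = 100, n_starts = 120,
                                     n_perm = 5000, delta_c = 3, dir_amp = 1,
                                     orientation_deg = 15, period = 9), name)
    params <- grid_params(period = cfg$period, orientation_deg = cfg$orientation_deg)
    sim <- run_simulation(n_goals = cfg$n_goals, n_starts = cfg$n_starts,
                          params = params, delta_c = cfg$delta_c,
                          dir_amp = cfg$dir_amp, n_perm = cfg$n_perm,
                          seed = cfg$seed)
    utils::write.table(sim$runs, p("runs.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(list(folds = sim$folds,
                              mean_magnitudes = sim$mean_magnitudes,
                              fwe_threshold = sim$fwe_threshold,
                              significant_folds = sim$significant_folds,
                              argmax_fold = sim$argmax_fold,
                              n_perm = sim$n_perm, seed = cfg$seed),
                         p("model_spectrum.json"), auto_unbox = TRUE, digits = NA)
    out <- c("runs.tsv", "model_spectrum.json")
  }
  write_manifest(name, cfg, out, p(paste0(gsub("-", "_", name), "_manifest.json")))
}
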