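# Batch analysis and reproducible pipeline runs.

# default manual baseline window: the late-diastolic segment immediately
# prior to the systolic upslope (the synthetic waveform's upslope starts
# at phase 0, so "prior" is the end of the cycle).
DEFAULT_MANUAL_WINDOW <- c(0.90, 1.00)

#' Analyse a curve pair with every transit-time method
#'
#' One row per method x baseline combination: time-to-foot under each
#' requested baseline mode, and maximum upslope / time-to-peak (to which
#' baseline correction does not apply).
#'
#' @param pair a [curve_pair()].
#' @param methods transit methods to run.
#' @param baselines baseline modes for TTF.
#' @param manual_window phase window for manual correction.
#' @param smoothing a [smoothing_spec()].
#' @return A data frame with columns `method`, `baseline`, `delta_t_ms`,
#'   `landmark_asc_ms`, `landmark_desc_ms`, `pwv_m_per_s`, `pwv_defined`.
#'   Analysis failures yield `NA` rows flagged `pwv_defined = FALSE`.
#' @export
analyze_pair <- function(pair,
                         methods = c("ttf", "max_upslope", "ttp"),
                         baselines = c("none", "automatic", "manual"),
                         manual_window = DEFAULT_MANUAL_WINDOW,
                         smoothing = smoothing_spec()) {
  stopifnot(inherits(pair, "curve_pair"))
  methods <- match.arg(methods, several.ok = TRUE)
  baselines <- match.arg(baselines, c("none", "automatic", "manual"),
                         several.ok = TRUE)
  combos <- list()
  for (m in methods) {
    modes <- if (m == "ttf") baselines else "none"
    for (b in modes) combos[[length(combos) + 1L]] <- c(m, b)
  }
  rows <- lapply(combos, function(cb) {
    spec <- if (cb[2L] == "manual") {
      baseline_spec("manual", manual_window)
    } else {
      baseline_spec(cb[2L])
    }
    est <- tryCatch(transit_time(pair, cb[1L], spec, smoothing),
                    error = function(e) NULL)
    if (is.null(est)) {
      data.frame(method = cb[1L], baseline = cb[2L], delta_t_ms = NA_real_,
                 landmark_asc_ms = NA_real_, landmark_desc_ms = NA_real_,
                 pwv_m_per_s = NA_real_, pwv_defined = FALSE)
    } else {
      data.frame(method = cb[1L], baseline = cb[2L],
                 delta_t_ms = est$delta_t_ms,
                 landmark_asc_ms = est$landmark_asc_ms,
                 landmark_desc_ms = est$landmark_desc_ms,
                 pwv_m_per_s = est$pwv_m_per_s,
                 pwv_defined = est$pwv_defined)
    }
  })
  do.call(rbind, rows)
}

#' Analyse a synthetic cohort into a tidy results table
#'
#' @param subjects list of `synthetic_subject`s from [generate_cohort()].
#' @inheritParams analyze_pair
#' @return A data frame, one row per subject x method x baseline, with
#'   `subject_id`, `true_pwv_m_per_s`, `delta_d_mm`, `kind` plus the
#'   [analyze_pair()] columns.
#' @export
analyze_cohort <- function(subjects,
                           methods = c("ttf", "max_upslope", "ttp"),
                           baselines = c("none", "automatic", "manual"),
                           manual_window = DEFAULT_MANUAL_WINDOW,
                           smoothing = smoothing_spec()) {
  rows <- lapply(subjects, function(s) {
    stopifnot(inherits(s, "synthetic_subject"))
    res <- analyze_pair(s$pair, methods, baselines, manual_window, smoothing)
    cbind(data.frame(subject_id = s$subject_id,
                     true_pwv_m_per_s = s$true_pwv_m_per_s,
                     delta_d_mm = s$pair$delta_d_mm,
                     kind = s$pair$ascending$kind),
          res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Analyse subjects listed in a manifest CSV
#'
#' The manifest has columns `subject_id`, `asc_path`, `desc_path`,
#' `delta_d_mm`; paths are resolved relative to the manifest's directory
#' unless absolute.
#'
#' @param manifest_path manifest CSV path.
#' @inheritParams analyze_pair
#' @return A tidy results data frame, one row per subject x method x
#'   baseline.
#' @export
analyze_manifest <- function(manifest_path,
                             methods = c("ttf", "max_upslope", "ttp"),
                             baselines = c("none", "automatic", "manual"),
                             manual_window = DEFAULT_MANUAL_WINDOW,
                             smoothing = smoothing_spec()) {
  if (!file.exists(manifest_path)) {
    stop_param("manifest not found: ", manifest_path)
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "asc_path", "desc_path", "delta_d_mm")
  if (!all(need %in% names(man))) {
    stop_param("manifest must have columns ", paste(need, collapse = ", "))
  }
  root <- dirname(normalizePath(manifest_path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(root, p))
  }
  rows <- lapply(seq_len(nrow(man)), function(i) {
    pair <- curve_pair(read_curve(resolve(man$asc_path[i])),
                       read_curve(resolve(man$desc_path[i])),
                       man$delta_d_mm[i])
    res <- analyze_pair(pair, methods, baselines, manual_window, smoothing)
    cbind(data.frame(subject_id = man$subject_id[i],
                     delta_d_mm = man$delta_d_mm[i],
                     kind = pair$ascending$kind),
          res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Deterministic fingerprint of a config (31-based polynomial hash of its
# canonical JSON form); changes iff the config changes.
config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run a reproducible simulate-and-analyse pipeline
#'
#' Validates the config, simulates a cohort, writes each subject's curves
#' as CSV, analyses all subjects with every method/baseline combination,
#' and writes a tidy results table, a per-cell summary, the Bland-Altman
#' agreement between automatic and manual baseline correction (TTF), and a
#' manifest (config, config hash, package version, timestamp).  All
#' randomness flows from `config$seed`; rerunning the same config yields
#' byte-identical artifacts apart from the manifest timestamp.  Subjects
#' with undefined transit time are flagged in the results, not dropped.
#'
#' Config fields (with defaults): `n_subjects` (15), `profile`
#' (`"neonate"`), `pwv_range_m_per_s` (c(2, 10)), `delta_d_mm` (68),
#' `acquisition_frames` (44), `noise_sd` (0), `seed` (1),
#' `manual_window` (c(0.90, 1.00)).
#'
#' @param config named list, see above.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  defaults <- list(n_subjects = 15, profile = "neonate",
                   pwv_range_m_per_s = c(2, 10), delta_d_mm = 68,
                   acquisition_frames = 44, noise_sd = 0, seed = 1,
                   manual_window = DEFAULT_MANUAL_WINDOW)
  if (!is.list(config)) stop_param("`config` must be a named list")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop_param("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  config <- utils::modifyList(defaults, config)
  # validate everything before touching the filesystem
  subjects <- generate_cohort(config$n_subjects, config$profile,
                              config$pwv_range_m_per_s, config$delta_d_mm,
                              config$acquisition_frames, config$noise_sd,
                              config$seed)
  dir.create(file.path(out_dir, "curves"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- list()
  for (s in subjects) {
    pa <- file.path(out_dir, "curves", paste0(s$subject_id, "_asc.csv"))
    pd <- file.path(out_dir, "curves", paste0(s$subject_id, "_desc.csv"))
    write_curve(s$pair$ascending, pa)
    write_curve(s$pair$descending, pd)
    paths[[paste0(s$subject_id, "_asc")]] <- pa
    paths[[paste0(s$subject_id, "_desc")]] <- pd
  }
  results <- analyze_cohort(subjects, manual_window = config$manual_window)
  truth <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    true_pwv_m_per_s = vapply(subjects, `[[`, 0, "true_pwv_m_per_s"))
  paths$results <- file.path(out_dir, "results.csv")
  utils::write.csv(results, paths$results, row.names = FALSE)
  paths$truth <- file.path(out_dir, "true_pwv.csv")
  utils::write.csv(truth, paths$truth, row.names = FALSE)
  paths$summary <- file.path(out_dir, "summary.csv")
  utils::write.csv(summarize_methods(results), paths$summary,
                   row.names = FALSE)
  ttf <- results[results$method == "ttf", ]
  auto <- ttf[ttf$baseline == "automatic", ]
  manu <- ttf[ttf$baseline == "manual", ]
  keep <- is.finite(auto$pwv_m_per_s) & is.finite(manu$pwv_m_per_s)
  paths$agreement <- file.path(out_dir, "agreement_auto_vs_manual.json")
  if (sum(keep) >= 2L) {
    ba <- bland_altman(auto$pwv_m_per_s[keep], manu$pwv_m_per_s[keep])
    jsonlite::write_json(
      list(comparison = "ttf automatic minus manual baseline correction",
           bias = ba$bias, sd = ba$sd, loa_low = ba$loa_low,
           loa_high = ba$loa_high, n = ba$n),
      paths$agreement, auto_unbox = TRUE, digits = NA)
  }
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(config = config,
         config_hash = config_hash(config),
         package = "pwvflow",
         package_version = as.character(utils::packageVersion("pwvflow")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
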