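# On-disk formats: marker TSV (frame label x y z), force TSV (sample fz),
# cohort manifest CSV, run configuration YAML/JSON, report JSON/CSV.
# Units never change on the way through: mm, N, degrees.

force_path_for <- function(path) {
  sub("\\.markers\\.tsv$", ".force.tsv", path)
}

#' Write a marker trial to TSV
#'
#' Writes `<stem>.markers.tsv` (columns `frame label x y z`) and, when
#' force data are present, `<stem>.force.tsv` (columns `sample fz`).
#' Numeric columns are written with enough digits for a lossless
#' round-trip (well below 1e-6 mm).
#'
#' @param trial a [marker_trial()].
#' @param stem output path stem (without extension).
#' @return invisibly, the marker file path.
#' @export
write_marker_trial <- function(trial, stem) {
  mpath <- paste0(stem, ".markers.tsv")
  mk <- trial$markers
  mk$x <- sprintf("%.9g", mk$x); mk$y <- sprintf("%.9g", mk$y)
  mk$z <- sprintf("%.9g", mk$z)
  utils::write.table(mk, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(trial$force)) {
    fr <- trial$force
    fr$fz <- sprintf("%.9g", fr$fz)
    utils::write.table(fr, force_path_for(mpath), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(mpath)
}

#' Read a marker trial from TSV
#'
#' Parses the documented marker TSV dialect, validates every label against
#' the registry (unknown labels are a schema error naming the offenders),
#' checks frame contiguity and per-segment marker counts, and attaches the
#' sibling `.force.tsv` when present. Missing samples stay flagged as `NA`
#' and are never interpolated here.
#'
#' @param path path to a `.markers.tsv` file.
#' @param registry label registry data.frame (`label`, `segment`), e.g.
#'   [foot_marker_registry()].
#' @param kind trial kind; `"walking"` requires the force file.
#' @param trial_id identifier; defaults to the file stem.
#' @return a [marker_trial()].
#' @export
read_marker_trial <- function(path, registry, kind = "walking",
                              trial_id = NULL) {
  if (!file.exists(path)) {
    fk_stop(paste0("no such file: ", path), "footkin_schema_error")
  }
  mk <- utils::read.delim(path, stringsAsFactors = FALSE)
  fpath <- force_path_for(path)
  force <- NULL
  if (file.exists(fpath) && fpath != path) {
    force <- utils::read.delim(fpath, stringsAsFactors = FALSE)
  }
  marker_trial(mk, registry,
               trial_id %||% sub("\\.markers\\.tsv$", "", basename(path)),
               kind, force = force)
}

manifest_columns <- c("id", "ncsp", "rcsp", "ankle_dorsiflexion",
                      "mpj_dorsiflexion", "first_ray", "forefoot", "fpi",
                      "neutral_angle", "standing_path", "stn_path",
                      "walking_paths")

#' Write a synthetic cohort to disk
#'
#' Writes every trial of every participant as marker/force TSV files plus
#' a cohort manifest CSV (one row per participant: the static assessment
#' fields and the relative trial paths, walking paths separated by `;`).
#'
#' @param cohort a marker-level [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  if (!isTRUE(cohort$config$markers)) {
    fk_stop("cohort has no marker trials to write", "footkin_contract_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$participants, function(p) {
    wpaths <- vapply(p$trials, function(tr) {
      basename(write_marker_trial(tr, file.path(dir, tr$trial_id)))
    }, character(1))
    spath <- basename(write_marker_trial(p$standing,
                                         file.path(dir, p$standing$trial_id)))
    npath <- basename(write_marker_trial(p$stn,
                                         file.path(dir, p$stn$trial_id)))
    data.frame(id = p$id, ncsp = p$static$ncsp, rcsp = p$static$rcsp,
               ankle_dorsiflexion = p$static$ankle_dorsiflexion,
               mpj_dorsiflexion = p$static$mpj_dorsiflexion,
               first_ray = p$static$first_ray, forefoot = p$static$forefoot,
               fpi = p$static$fpi, neutral_angle = p$neutral_angle,
               standing_path = spath, stn_path = npath,
               walking_paths = paste(wpaths, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "cohort_manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort manifest
#'
#' Validates the documented manifest CSV: typed static fields, closed
#' category vocabularies and unique participant ids.
#'
#' @param path manifest CSV path.
#' @return data.frame with one row per participant; trial paths are
#'   resolved relative to the manifest's directory.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) {
    fk_stop(paste0("no such file: ", path), "footkin_validation_error")
  }
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_columns, names(mf))
  if (length(missing)) {
    fk_stop(paste0("manifest lacks columns: ",
                   paste(missing, collapse = ", ")),
            "footkin_validation_error")
  }
  if (anyDuplicated(mf$id)) {
    fk_stop("duplicate participant id in manifest",
            "footkin_validation_error")
  }
  bad_fr <- setdiff(unique(mf$first_ray),
                    c("plantarflexed", "normal", "dorsiflexed"))
  bad_ff <- setdiff(unique(mf$forefoot), c("varus", "normal", "valgus"))
  if (length(c(bad_fr, bad_ff))) {
    fk_stop(paste0("out-of-vocabulary categories: ",
                   paste(c(bad_fr, bad_ff), collapse = ", ")),
            "footkin_validation_error")
  }
  for (v in c("ncsp", "rcsp", "ankle_dorsiflexion", "mpj_dorsiflexion",
              "neutral_angle")) {
    if (!is.numeric(mf[[v]])) {
      fk_stop(paste0("manifest column `", v, "` must be numeric"),
              "footkin_validation_error")
    }
  }
  attr(mf, "dir") <- dirname(path)
  mf
}

#' Run configuration
#'
#' Reads/writes the run configuration (YAML or JSON by extension):
#' filter settings, event thresholds and windows, deformity thresholds,
#' statistical options and the seed. Unknown keys are rejected.
#'
#' @param cutoff Butterworth cutoff (Hz).
#' @param filter_boundary `"periodic"` or `"reflect"`.
#' @param force_threshold stance threshold (N).
#' @param midstance_start start of mid-stance as fraction of stance.
#' @param heel_lift_fallback fallback heel-lift fraction of stance.
#' @param alpha significance level.
#' @param min_group_size minimum group size for comparisons.
#' @param equinus_threshold,hallux_threshold,varus_threshold deformity
#'   cut-offs (deg).
#' @param seed optional integer seed.
#' @return list of class `footkin_config`.
#' @export
footkin_config <- function(cutoff = 6, filter_boundary = "periodic",
                           force_threshold = 20, midstance_start = 0.15,
                           heel_lift_fallback = 0.65, alpha = 0.05,
                           min_group_size = 5, equinus_threshold = 10,
                           hallux_threshold = 65, varus_threshold = 0,
                           seed = NULL) {
  structure(list(cutoff = cutoff, filter_boundary = filter_boundary,
                 force_threshold = force_threshold,
                 midstance_start = midstance_start,
                 heel_lift_fallback = heel_lift_fallback, alpha = alpha,
                 min_group_size = min_group_size,
                 equinus_threshold = equinus_threshold,
                 hallux_threshold = hallux_threshold,
                 varus_threshold = varus_threshold, seed = seed),
            class = "footkin_config")
}

#' @rdname footkin_config
#' @param path configuration file path (`.yaml`/`.yml` or `.json`).
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(footkin_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    fk_stop(paste0("unknown config keys: ", paste(unknown, collapse = ", ")),
            "footkin_config_error")
  }
  do.call(footkin_config, vals)
}

#' @rdname footkin_config
#' @param config a `footkin_config` list.
#' @export
write_config <- function(config, path) {
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Write report outputs
#'
#' `write_report_json()` serializes the full machine-readable report;
#' `write_report_csv()` writes the flat comparison/correlation/summary/
#' count tables as CSV files into a directory.
#'
#' @param report a [run_full_analysis()] result.
#' @param path JSON output path.
#' @return invisibly, the written path(s).
#' @export
write_report_json <- function(report, path) {
  tabs <- report_tables(report)
  payload <- list(
    n = report$n,
    deformity_prevalence_pct = as.list(report$deformity_prevalence),
    deformity_counts = tabs$counts,
    cohort_summary = tabs$summary,
    comparisons = tabs$comparisons,
    correlations = tabs$correlations,
    stn = report$stn
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @param dir output directory for the CSV tables.
#' @export
write_report_csv <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- report_tables(report)
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Write a per-participant gait-variable table
#'
#' @param variables data.frame (`id` + six dynamic variables columns).
#' @param path CSV output path.
#' @export
write_variables_csv <- function(variables, path) {
  utils::write.csv(variables, path, row.names = FALSE)
  invisible(path)
}
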