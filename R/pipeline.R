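#' Process one participant's trials into gait variables
#'
#' Calibrates the segment model from the standing reference trial,
#' computes filtered inter-segment angle curves for every walking trial,
#' averages the normalized curves across trials, detects stance (force
#' threshold) and heel lift (plantarflexion-velocity onset) and extracts
#' the six dynamic variables from the mean curves. When a
#' subtalar-neutral standing trial is supplied, its mean frontal rearfoot
#' angle is measured with the same calibration and compared against the
#' mean gait curve.
#'
#' @param standing standing reference [marker_trial()].
#' @param walking list of walking [marker_trial()]s.
#' @param stn optional subtalar-neutral standing trial.
#' @param config a [footkin_config()].
#' @return list with `variables` ([extract_variables()] result), `events`,
#'   `mean_series`, `series` (per trial), `stance_fraction`,
#'   `neutral_angle` and `stn` ([stn_passthrough()] result or `NULL`).
#' @export
process_participant <- function(standing, walking, stn = NULL,
                                config = footkin_config()) {
  cal <- calibrate_segments(standing)
  series <- lapply(walking, compute_joint_angles, calibration = cal,
                   cutoff = config$cutoff,
                   boundary = config$filter_boundary)
  stances <- lapply(walking, function(tr) {
    detect_stance(tr$force, rate = tr$force_rate,
                  threshold = config$force_threshold)
  })
  sfrac <- vapply(seq_along(walking), function(i) {
    (stances[[i]]$toe_off - stances[[i]]$heel_strike) /
      series[[i]]$cycle_duration
  }, numeric(1))
  msd <- mean_across_trials(series)
  stance_fraction <- mean(sfrac)
  hl <- detect_heel_lift(msd$normalized$rearfoot$sagittal, stance_fraction,
                         fallback = config$heel_lift_fallback)
  ev <- gait_events(heel_strike = 0,
                    toe_off = stance_fraction * msd$cycle_duration,
                    heel_lift_stance_frac = hl$stance_frac,
                    cycle_duration = msd$cycle_duration,
                    midstance_start = config$midstance_start)
  vars <- extract_variables(msd, ev)
  neutral <- NULL
  stn_res <- NULL
  if (!is.null(stn)) {
    stn_series <- compute_joint_angles(stn, cal, cutoff = config$cutoff,
                                       boundary = config$filter_boundary)
    neutral <- mean(stn_series$curves$rearfoot$frontal)
    stn_res <- stn_passthrough(neutral, msd$normalized$rearfoot$frontal)
  }
  list(variables = vars, events = ev, mean_series = msd, series = series,
       stance_fraction = stance_fraction, heel_lift = hl,
       neutral_angle = neutral, stn = stn_res)
}

#' Process a whole cohort
#'
#' Runs [process_participant()] for every participant of an in-memory
#' synthetic cohort or an on-disk cohort manifest, collecting the
#' per-participant dynamic-variable table, the static table and the STN
#' results.
#'
#' @param cohort a marker-level [generate_cohort()] result, or the path of
#'   a cohort manifest CSV (see [read_cohort_manifest()]).
#' @param config a [footkin_config()].
#' @param registry label registry used when reading trials from disk.
#' @return list with `variables` (data.frame), `statics` (data.frame),
#'   `stn` (list of [stn_passthrough()] results) and `details` (per
#'   participant).
#' @export
process_cohort <- function(cohort, config = footkin_config(),
                           registry = foot_marker_registry()) {
  if (is.character(cohort)) {
    mf <- read_cohort_manifest(cohort)
    dir <- attr(mf, "dir")
    entries <- lapply(seq_len(nrow(mf)), function(i) {
      walking <- lapply(strsplit(mf$walking_paths[i], ";")[[1]],
                        function(p) {
                          read_marker_trial(file.path(dir, p), registry,
                                            kind = "walking")
                        })
      list(id = mf$id[i],
           standing = read_marker_trial(file.path(dir, mf$standing_path[i]),
                                        registry,
                                        kind = "standing_reference"),
           stn = read_marker_trial(file.path(dir, mf$stn_path[i]), registry,
                                   kind = "stn_standing"),
           walking = walking,
           statics = mf[i, c("id", "ncsp", "rcsp", "ankle_dorsiflexion",
                             "mpj_dorsiflexion", "first_ray", "forefoot",
                             "fpi", "neutral_angle")])
    })
  } else {
    if (!inherits(cohort, "synthetic_cohort") || !cohort$config$markers) {
      fk_stop("`cohort` must be a marker-level synthetic cohort or a manifest path",
              "footkin_contract_error")
    }
    st <- cohort_statics(cohort)
    entries <- lapply(seq_along(cohort$participants), function(i) {
      p <- cohort$participants[[i]]
      list(id = p$id, standing = p$standing, stn = p$stn,
           walking = p$trials, statics = st[i, , drop = FALSE])
    })
  }
  details <- lapply(entries, function(e) {
    res <- process_participant(e$standing, e$walking, stn = e$stn,
                               config = config)
    res$id <- e$id
    res
  })
  variables <- do.call(rbind, lapply(details, function(d) {
    cbind(data.frame(id = d$id, stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(d$variables))))
  }))
  statics <- do.call(rbind, lapply(entries, function(e) e$statics))
  rownames(statics) <- NULL
  stn <- lapply(details, function(d) d$stn)
  list(variables = variables, statics = statics, stn = stn,
       details = details)
}

#' End-to-end synthetic study
#'
#' Generates a cohort, processes every participant's marker trials and
#' runs the full statistical battery: the one-call demonstration of the
#' whole pipeline.
#'
#' @param cohort_cfg a [cohort_config()].
#' @param config a [footkin_config()].
#' @return list with `cohort`, `processed` and `report`.
#' @export
run_study <- function(cohort_cfg = cohort_config(n = 20),
                      config = footkin_config()) {
  cohort <- generate_cohort(cohort_cfg)
  processed <- process_cohort(cohort, config = config)
  report <- run_full_analysis(processed$variables, processed$statics,
                              stn = processed$stn,
                              config = analysis_config(
                                alpha = config$alpha,
                                min_group_size = config$min_group_size,
                                thresholds = deformity_thresholds(
                                  varus = config$varus_threshold,
                                  equinus = config$equinus_threshold,
                                  hallux = config$hallux_threshold)))
  list(cohort = cohort, processed = processed, report = report)
}
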