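canonical_joints <- function(segments) {
  jt <- foot_model()$joints
  jt[jt$proximal %in% c(segments, "leg") & jt$distal %in% segments, ,
     drop = FALSE]
}

#' Calibrate segment coordinate systems from a standing reference trial
#'
#' Builds the leg LCS from the anatomical markers (medial/lateral malleoli
#' and knee margins) and sets every foot-segment LCS parallel to it in the
#' standing pose, which defines 0 degrees for all inter-segment angles.
#' Each segment's time-averaged standing cluster is stored as its tracking
#' reference geometry.
#'
#' @param standing a [marker_trial()] of kind `"standing_reference"`
#'   containing the anatomical markers and all cluster markers.
#' @return object of class `segment_calibration`: list with `leg_rotation`
#'   (standing leg LCS, 3x3), `leg_origin`, `clusters` (named list of
#'   labelled reference matrices) and `joints` (data.frame).
#' @export
calibrate_segments <- function(standing) {
  if (!inherits(standing, "marker_trial")) {
    fk_stop("`standing` must be a marker_trial", "footkin_contract_error")
  }
  reg <- standing$registry
  anat_labels <- c("med_malleolus", "lat_malleolus", "med_knee", "lat_knee")
  have <- reg$label[reg$segment == "anatomical"]
  missing <- setdiff(anat_labels, intersect(have, unique(standing$markers$label)))
  if (length(missing)) {
    fk_stop(paste0("standing trial lacks anatomical markers: ",
                   paste(missing, collapse = ", ")), "footkin_model_error")
  }
  mean_positions <- function(labels) {
    arr <- marker_array(standing, labels)
    m <- apply(arr, c(2, 3), mean, na.rm = TRUE)
    if (!all(is.finite(m))) {
      fk_stop("standing trial has fully-missing markers",
              "footkin_model_error")
    }
    m
  }
  anat <- mean_positions(anat_labels)
  lcs <- build_leg_lcs(anat)
  segs <- setdiff(unique(reg$segment), "anatomical")
  clusters <- lapply(segs, function(s) {
    mean_positions(reg$label[reg$segment == s])
  })
  names(clusters) <- segs
  structure(list(leg_rotation = lcs$rotation, leg_origin = lcs$origin,
                 clusters = clusters, joints = canonical_joints(segs)),
            class = "segment_calibration")
}

#' @export
print.segment_calibration <- function(x, ...) {
  cat("<segment_calibration> ", length(x$clusters), " segments, ",
      nrow(x$joints), " joints\n", sep = "")
  invisible(x)
}

#' Inter-segment angle series
#'
#' Constructor for the container of three-plane angle curves of the five
#' joints. `curves[[joint]][[plane]]` holds degrees per raw frame;
#' `normalized[[joint]][[plane]]` holds the 101-point (0-100% gait cycle)
#' view. Either view may be omitted (`NULL`) when not available.
#'
#' @param curves,normalized nested lists `[[joint]][[plane]]` of numeric
#'   curves (normalized curves must have 101 points).
#' @param cycle_duration gait cycle duration in seconds.
#' @param trial_id identifier.
#' @param rate marker rate (Hz).
#' @param provenance list of processing settings.
#' @return object of class `angle_series`.
#' @export
angle_series <- function(curves = NULL, normalized = NULL,
                         cycle_duration = NA_real_, trial_id = "series",
                         rate = 100, provenance = list()) {
  for (view in list(curves, normalized)) {
    if (is.null(view)) next
    len <- unique(unlist(lapply(view, function(j) vapply(j, length, 1L))))
    if (length(len) != 1L) {
      fk_stop("all joint-plane curves must share one length",
              "footkin_contract_error")
    }
  }
  if (!is.null(normalized)) {
    n <- length(normalized[[1]][[1]])
    if (n != 101L) {
      fk_stop("normalized curves must have 101 samples",
              "footkin_contract_error")
    }
  }
  structure(list(trial_id = trial_id, rate = rate, curves = curves,
                 normalized = normalized, cycle_duration = cycle_duration,
                 provenance = provenance),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  nr <- if (!is.null(x$curves)) length(x$curves[[1]][[1]]) else 0L
  cat("<angle_series '", x$trial_id, "'> ", nr, " raw frames",
      if (!is.null(x$normalized)) ", normalized (101 pts)",
      sprintf(", cycle %.3g s", x$cycle_duration), "\n", sep = "")
  invisible(x)
}

#' @export
plot.angle_series <- function(x, joint = "rearfoot", ...) {
  cur <- x$normalized[[joint]] %||% x$curves[[joint]]
  pct <- seq(0, 100, length.out = length(cur[[1]]))
  graphics::matplot(pct, do.call(cbind, cur), type = "l", lty = 1,
                    xlab = "% gait cycle", ylab = "angle (deg)",
                    main = joint, ...)
  graphics::legend("topleft", legend = names(cur), col = 1:3, lty = 1,
                   bty = "n")
  invisible(x)
}

resample_curve <- function(y, n_out, periodic = TRUE) {
  n <- length(y)
  if (periodic) {
    xs <- c(seq_len(n) - 1L, n) / n
    ys <- c(y, y[1])
  } else {
    xs <- (seq_len(n) - 1L) / (n - 1L)
    ys <- y
  }
  stats::approx(xs, ys, xout = seq(0, 1, length.out = n_out), rule = 2)$y
}

#' Compute inter-segment joint angles for a trial
#'
#' For every frame, estimates each segment's pose by a least-squares rigid
#' fit of its calibrated standing cluster ([fit_rigid_pose()]), forms the
#' distal-relative-to-proximal rotation for the five joint pairs in the
#' standing leg LCS basis, decomposes it with the Cardan x-y-z sequence,
#' low-pass filters each angle curve and derives the 101-point
#' cycle-normalized view. Angles are zero-referenced to the standing trial
#' by construction (all segment LCS are parallel there). Frames on which a
#' needed segment has fewer than 3 complete markers are excluded and
#' recorded in the result.
#'
#' @param trial a [marker_trial()] (walking or standing).
#' @param calibration a [calibrate_segments()] result.
#' @param cutoff Butterworth low-pass cutoff in Hz.
#' @param boundary filter boundary handling; `"periodic"` (default) treats
#'   the trial as one full gait cycle, heel strike to heel strike.
#' @return an [angle_series()] with raw and normalized views; excluded
#'   frame indices are stored in `provenance$excluded_frames`.
#' @export
compute_joint_angles <- function(trial, calibration, cutoff = 6,
                                 boundary = "periodic") {
  if (!inherits(trial, "marker_trial") ||
      !inherits(calibration, "segment_calibration")) {
    fk_stop("need a marker_trial and a segment_calibration",
            "footkin_contract_error")
  }
  jt <- calibration$joints
  segs <- unique(c(jt$proximal, jt$distal))
  miss_seg <- setdiff(segs, c(names(calibration$clusters)))
  if (length(miss_seg)) {
    fk_stop(paste0("calibration lacks segments: ",
                   paste(miss_seg, collapse = ", ")), "footkin_model_error")
  }
  nf <- n_frames(trial)
  R0 <- calibration$leg_rotation
  arrs <- lapply(segs, function(s) {
    marker_array(trial, rownames(calibration$clusters[[s]]))
  })
  names(arrs) <- segs
  # pose per segment per frame
  rots <- lapply(segs, function(s) array(NA_real_, c(3, 3, nf)))
  names(rots) <- segs
  ok_frame <- rep(TRUE, nf)
  for (s in segs) {
    ref <- calibration$clusters[[s]]
    arr <- arrs[[s]]
    for (k in seq_len(nf)) {
      pts <- arr[k, , , drop = TRUE]
      keep <- stats::complete.cases(pts)
      if (sum(keep) < 3L) {
        ok_frame[k] <- FALSE
        next
      }
      fit <- fit_rigid_pose(ref[keep, , drop = FALSE],
                            pts[keep, , drop = FALSE])
      rots[[s]][, , k] <- fit$rotation
    }
  }
  if (!any(ok_frame)) {
    fk_stop("no frame has complete segment clusters", "footkin_model_error")
  }
  if (!all(ok_frame)) {
    fk_warn(sprintf("%d frame(s) excluded for missing segment markers",
                    sum(!ok_frame)), "footkin_missing_frames_warning")
  }
  kept <- which(ok_frame)
  curves <- lapply(seq_len(nrow(jt)), function(i) {
    prox <- jt$proximal[i]; dist <- jt$distal[i]
    ang <- vapply(kept, function(k) {
      Rrel <- t(R0) %*% t(rots[[prox]][, , k]) %*% rots[[dist]][, , k] %*% R0
      cardan_xyz(Rrel)
    }, numeric(3))
    ch <- lapply(1:3, function(p) {
      butterworth_lowpass(ang[p, ], cutoff = cutoff, rate = trial$rate,
                          boundary = boundary)
    })
    names(ch) <- plane_names()
    ch
  })
  names(curves) <- jt$joint
  periodic <- identical(boundary, "periodic")
  normalized <- lapply(curves, function(j) {
    lapply(j, resample_curve, n_out = 101L, periodic = periodic)
  })
  angle_series(curves = curves, normalized = normalized,
               cycle_duration = nf / trial$rate, trial_id = trial$trial_id,
               rate = trial$rate,
               provenance = list(cutoff = cutoff, boundary = boundary,
                                 excluded_frames = which(!ok_frame) - 1L,
                                 meta = trial$meta))
}

#' Re-normalize an angle series to an arbitrary grid
#'
#' @param series an [angle_series()] with raw curves.
#' @param n number of samples of the output grid over the cycle.
#' @return nested list `[[joint]][[plane]]` of length-`n` curves.
#' @export
time_normalize <- function(series, n = 101L) {
  if (is.null(series$curves)) {
    fk_stop("series lacks raw curves to normalize", "footkin_contract_error")
  }
  periodic <- identical(series$provenance$boundary %||% "periodic",
                        "periodic")
  lapply(series$curves, function(j) {
    lapply(j, resample_curve, n_out = n, periodic = periodic)
  })
}

#' Pointwise mean of normalized angle series
#'
#' Averages the 101-point normalized curves of several trials (typically
#' the eight walking trials of one participant) per joint and plane.
#'
#' @param series_list list of [angle_series()] objects, all normalized to
#'   the common 101-point base.
#' @return an [angle_series()] holding the mean normalized curves; the mean
#'   cycle duration is carried over.
#' @export
mean_across_trials <- function(series_list) {
  if (!length(series_list)) {
    fk_stop("need at least one series", "footkin_contract_error")
  }
  if (any(!vapply(series_list, function(s) !is.null(s$normalized),
                  logical(1)))) {
    fk_stop("all series must be normalized to the common 101-point base",
            "footkin_contract_error")
  }
  lens <- unique(vapply(series_list,
                        function(s) length(s$normalized[[1]][[1]]), 1L))
  if (length(lens) != 1L) {
    fk_stop("mixed normalization bases", "footkin_contract_error")
  }
  jts <- names(series_list[[1]]$normalized)
  normalized <- lapply(jts, function(j) {
    ch <- lapply(plane_names(), function(p) {
      rowMeans(vapply(series_list, function(s) s$normalized[[j]][[p]],
                      numeric(lens)))
    })
    names(ch) <- plane_names()
    ch
  })
  names(normalized) <- jts
  angle_series(normalized = normalized,
               cycle_duration = mean(vapply(series_list,
                                            function(s) s$cycle_duration,
                                            1)),
               trial_id = sprintf("mean_of_%d", length(series_list)),
               provenance = list(n_trials = length(series_list)))
}
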