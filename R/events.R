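#' Detect stance from vertical ground-reaction force
#'
#' Finds the longest contiguous run of force samples above `threshold`
#' lasting at least `min_duration`, and returns its first and one-past-last
#' crossing converted to seconds (sample j occurs at j / `rate` s,
#' 0-based).
#'
#' @param force data.frame with columns `sample`, `fz` (newtons), or a
#'   numeric vector of force samples.
#' @param rate force sampling rate in Hz.
#' @param threshold stance threshold in newtons.
#' @param min_duration minimum qualifying run length in seconds (debounce).
#' @return list with `heel_strike` and `toe_off` times in seconds.
#' @export
#' @examples
#' fz <- c(rep(0, 10), rep(600, 400), rep(0, 10))
#' detect_stance(fz, rate = 1500)
detect_stance <- function(force, rate = 1500, threshold = 20,
                          min_duration = 0.2) {
  fz <- if (is.data.frame(force)) force$fz else as.numeric(force)
  if (any(!is.finite(fz)) || any(fz < 0)) {
    fk_stop("force must be finite and non-negative", "footkin_contract_error")
  }
  r <- rle(fz > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values & r$lengths >= min_duration * rate)
  if (!length(qual)) {
    fk_stop("no supra-threshold run long enough for stance",
            "footkin_no_stance_error")
  }
  best <- qual[which.max(r$lengths[qual])]
  list(heel_strike = (starts[best] - 1L) / rate,
       toe_off = ends[best] / rate)
}

#' Detect heel lift from the sagittal rearfoot curve
#'
#' Heel lift is taken as the onset of sustained rearfoot plantarflexion in
#' late stance: the first instant after `after` of stance at which the
#' sagittal angular velocity goes and stays negative for at least
#' `sustain` of stance. If the criterion is never met the configured fixed
#' fallback fraction is returned with a classed warning.
#'
#' @param sagittal rearfoot sagittal curve normalized over the gait cycle
#'   (equally spaced samples spanning 0-100%).
#' @param stance_fraction stance duration as a fraction of the cycle.
#' @param after earliest admissible heel lift, as a fraction of stance.
#' @param sustain required length of the negative-velocity run (fraction
#'   of stance).
#' @param fallback fixed fraction of stance used when detection fails.
#' @return list with `stance_frac` (heel lift as a fraction of stance) and
#'   `method` (`"velocity"` or `"fallback"`).
#' @export
detect_heel_lift <- function(sagittal, stance_fraction, after = 0.4,
                             sustain = 0.05, fallback = 0.65) {
  check_number(stance_fraction, "stance_fraction", min = 1e-6, max = 1)
  ns <- 201L
  st <- seq(0, 1, length.out = ns)
  xs <- seq(0, 1, length.out = length(sagittal))
  y <- stats::approx(xs, sagittal, xout = st * stance_fraction, rule = 2)$y
  v <- diff(y)
  run <- max(1L, as.integer(ceiling(sustain * (ns - 1L))))
  neg <- v < 0
  for (i in which(st[-ns] >= after)) {
    j <- i:min(i + run - 1L, ns - 1L)
    if (length(j) == run && all(neg[j])) {
      return(list(stance_frac = st[i], method = "velocity"))
    }
  }
  fk_warn(sprintf("heel-lift velocity criterion never met; using fixed %g%% of stance",
                  100 * fallback), "footkin_heel_lift_fallback")
  list(stance_frac = fallback, method = "fallback")
}

#' Gait events for one trial
#'
#' Assembles heel strike, heel lift and toe off with the stance sub-phase
#' windows: mid-stance from the foot-flat proxy (`midstance_start` of
#' stance) to heel lift, and propulsion from heel lift to toe off. The
#' windows are conventions (configurable), expressed in percent of stance.
#'
#' @param heel_strike,toe_off stance bounds in seconds (from
#'   [detect_stance()]).
#' @param heel_lift_stance_frac heel lift as a fraction of stance.
#' @param cycle_duration gait cycle duration in seconds.
#' @param midstance_start start of mid-stance as a fraction of stance.
#' @return object of class `gait_events` with times in seconds and windows
#'   in percent of stance.
#' @export
gait_events <- function(heel_strike, toe_off, heel_lift_stance_frac,
                        cycle_duration, midstance_start = 0.15) {
  check_number(heel_strike, "heel_strike", min = 0)
  check_number(toe_off, "toe_off", min = 0)
  check_number(heel_lift_stance_frac, "heel_lift_stance_frac",
               min = 0, max = 1)
  heel_lift <- heel_strike + heel_lift_stance_frac * (toe_off - heel_strike)
  if (!(heel_strike < heel_lift && heel_lift < toe_off)) {
    fk_stop("events must satisfy heel strike < heel lift < toe off",
            "footkin_contract_error")
  }
  midstance <- c(100 * midstance_start, 100 * heel_lift_stance_frac)
  propulsion <- c(100 * heel_lift_stance_frac, 100)
  if (midstance[1] >= midstance[2]) {
    fk_stop("mid-stance window is empty", "footkin_contract_error")
  }
  structure(list(heel_strike = heel_strike, toe_off = toe_off,
                 heel_lift = heel_lift,
                 heel_lift_stance_frac = heel_lift_stance_frac,
                 midstance = midstance, propulsion = propulsion,
                 cycle_duration = cycle_duration),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf(
    "<gait_events> HS %.3f s, HL %.3f s (%.1f%% stance), TO %.3f s; MS %0.f-%0.f%%, prop %0.f-%0.f%% stance\n",
    x$heel_strike, x$heel_lift, 100 * x$heel_lift_stance_frac, x$toe_off,
    x$midstance[1], x$midstance[2], x$propulsion[1], x$propulsion[2]))
  invisible(x)
}

# grid samples inside the window plus the curve values linearly
# interpolated at the window edges (so extrema sitting on a window
# boundary are evaluated at the boundary itself, not at the nearest grid
# sample); extrema are never located at sub-sample resolution.
window_samples <- function(curve, events, window_stance_pct) {
  n <- length(curve)
  u <- seq(0, 1, length.out = n)  # cycle fraction
  hs <- events$heel_strike / events$cycle_duration
  sf <- (events$toe_off - events$heel_strike) / events$cycle_duration
  w <- hs + window_stance_pct / 100 * sf
  idx <- which(u >= w[1] - 1e-9 & u <= w[2] + 1e-9)
  if (!length(idx)) {
    fk_stop("event window contains no samples", "footkin_contract_error")
  }
  edges <- stats::approx(u, curve, xout = pmin(pmax(w, 0), 1), rule = 2)$y
  c(edges[1], curve[idx], edges[2])
}

#' Extract the standard dynamic gait variables
#'
#' Computes the six scalar variables used in the static-vs-dynamic
#' analyses from a cycle-normalized angle series: peak (most negative)
#' rearfoot eversion and peak rearfoot dorsiflexion during mid-stance, the
#' sagittal rearfoot angle at heel lift, the mid-stance sagittal rearfoot
#' range, and the propulsion-phase peak hallux dorsiflexion and peak
#' rearfoot eversion. Peaks are signed extrema of the filtered curves over
#' the named window, taken on the normalized grid without sub-sample
#' interpolation; the heel-lift angle is linearly interpolated at the
#' heel-lift instant.
#'
#' @param series an [angle_series()] with normalized curves.
#' @param events a [gait_events()] consistent with the series' time base.
#' @return object of class `gait_variables`: named numeric vector of the
#'   six variables (degrees) with the events attached as an attribute.
#' @export
extract_variables <- function(series, events) {
  if (is.null(series$normalized)) {
    fk_stop("series must carry normalized curves", "footkin_contract_error")
  }
  if (!inherits(events, "gait_events")) {
    fk_stop("`events` must be gait_events", "footkin_contract_error")
  }
  sag <- series$normalized$rearfoot$sagittal
  frn <- series$normalized$rearfoot$frontal
  hx <- series$normalized$hallux$sagittal
  ms_f <- window_samples(frn, events, events$midstance)
  ms_s <- window_samples(sag, events, events$midstance)
  pr_f <- window_samples(frn, events, events$propulsion)
  pr_h <- window_samples(hx, events, events$propulsion)
  u <- seq(0, 1, length.out = length(sag))
  hl_u <- events$heel_lift / events$cycle_duration
  hl_angle <- stats::approx(u, sag, xout = hl_u, rule = 2)$y
  v <- c(peak_eversion_midstance = min(ms_f),
         peak_dorsiflexion_midstance = max(ms_s),
         sagittal_angle_heel_lift = hl_angle,
         sagittal_range_midstance = max(ms_s) - min(ms_s),
         peak_hallux_dorsiflexion_propulsion = max(pr_h),
         peak_eversion_propulsion = min(pr_f))
  stopifnot(all(v["peak_eversion_midstance"] <= ms_f))  # defn of minimum
  if (!all(is.finite(v)) || v["sagittal_range_midstance"] < 0) {
    fk_stop("extracted variables must be finite with non-negative range",
            "footkin_contract_error")
  }
  structure(v, class = c("gait_variables", "numeric"), events = events)
}
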