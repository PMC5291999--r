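# Harmonic gait waveforms. Every channel is offset + sum_k amp_k *
# cos(2*pi*(k*u - k*phase_k)) over cycle fraction u in [0,1), with <= 4
# harmonics, so curves are exactly periodic and window extrema can be
# recovered by dense scans for oracle tests.

#' Canonical harmonic channel parameters
#'
#' Builds a channel from raised-cosine power bumps
#' `w * ((1 + cos(2*pi*(u - u0)))/2)^p` with power 2 (default, harmonics
#' 1-2) or 4 (narrower, harmonics 1-4); overlapping bumps are merged into a
#' single canonical harmonic series (complex phasor addition), so any
#' number of bumps still yields at most 4 harmonics.
#'
#' @param bumps list of `list(w = weight_deg, u0 = cycle_fraction,
#'   power = 2 or 4)` (`power` optional).
#' @param offset constant offset in degrees.
#' @return list `(offset, amp, phase)`; `amp[k]`/`phase[k]` are the degree
#'   amplitude and cycle-fraction phase of harmonic k.
#' @export
harmonic_channel <- function(bumps = list(), offset = 0) {
  coefs <- list(`2` = c(0.5, 0.125),
                `4` = c(7 / 16, 7 / 32, 1 / 16, 1 / 128))
  consts <- c(`2` = 0.375, `4` = 35 / 128)
  z <- complex(real = rep(0, 4), imaginary = rep(0, 4))
  for (b in bumps) {
    pw <- as.character(b$power %||% 2)
    if (!pw %in% names(coefs)) {
      fk_stop("bump power must be 2 or 4", "footkin_config_error")
    }
    coef <- coefs[[pw]]
    offset <- offset + consts[[pw]] * b$w
    for (k in seq_along(coef)) {
      z[k] <- z[k] + b$w * coef[k] * exp(2i * pi * k * b$u0)
    }
  }
  amp <- Mod(z)
  phase <- ifelse(amp > 0, Arg(z) / (2 * pi * seq_along(z)), 0)
  keep <- which(amp > 0)
  k <- if (length(keep)) max(keep) else 0L
  list(offset = offset, amp = amp[seq_len(k)], phase = phase[seq_len(k)])
}

#' Evaluate a harmonic channel
#'
#' @param params list `(offset, amp, phase)` as from [harmonic_channel()].
#' @param u cycle fractions (any real; evaluation is periodic).
#' @return angle values in degrees.
#' @export
eval_channel <- function(params, u) {
  y <- rep(params$offset %||% 0, length(u))
  amp <- params$amp %||% numeric(0)
  phase <- params$phase %||% rep(0, length(amp))
  for (k in seq_along(amp)) {
    if (amp[k] != 0) y <- y + amp[k] * cos(2 * pi * k * (u - phase[k]))
  }
  y
}

channel_scan <- function(params, lo, hi, n = 20001L) {
  u <- seq(lo, hi, length.out = n)
  y <- eval_channel(params, u)
  list(u = u, y = y,
       min = min(y), u_min = u[which.min(y)],
       max = max(y), u_max = u[which.max(y)])
}

# Solve the weight A of an extra bump at u0 so that the window extremum of
# channel + A*bump equals `target`. Monotone in A, solved by uniroot.
solve_bump_weight <- function(params, u0, target, window,
                              type = c("max", "min"), n = 2001L) {
  type <- match.arg(type)
  u <- seq(window[1], window[2], length.out = n)
  base <- eval_channel(params, u)
  bump <- ((1 + cos(2 * pi * (u - u0))) / 2)^2
  f <- if (type == "max") {
    function(A) max(base + A * bump) - target
  } else {
    function(A) min(base - A * bump) - target
  }
  lim <- max(400, 4 * abs(target) + 4 * max(abs(base)))
  if (f(0) * f(lim) > 0) {
    fk_stop("target extremum unreachable within bump scaling limits",
            "footkin_config_error")
  }
  A <- stats::uniroot(f, c(0, lim), tol = 1e-10)$root
  if (type == "min") A <- -A
  A
}

add_bump <- function(params, w, u0) {
  extra <- harmonic_channel(list(list(w = w, u0 = u0)))
  merge_channels(params, extra)
}

merge_channels <- function(a, b) {
  ka <- length(a$amp %||% numeric(0)); kb <- length(b$amp %||% numeric(0))
  k <- max(ka, kb)
  z <- complex(real = rep(0, max(k, 1)), imaginary = rep(0, max(k, 1)))
  for (i in seq_len(ka)) z[i] <- z[i] + a$amp[i] * exp(2i * pi * i * a$phase[i])
  for (i in seq_len(kb)) z[i] <- z[i] + b$amp[i] * exp(2i * pi * i * b$phase[i])
  amp <- Mod(z)
  phase <- ifelse(amp > 0, Arg(z) / (2 * pi * seq_along(z)), 0)
  list(offset = (a$offset %||% 0) + (b$offset %||% 0),
       amp = amp, phase = phase)
}

#' Default joint waveform parameters
#'
#' Baseline ("rest") harmonic shapes for the 15 joint-plane channels of the
#' five inter-segment joints, emulating the canonical features of
#' multi-segment foot kinematics: an early-stance rearfoot plantarflexion
#' dip and terminal-stance plantarflexion, a mid-stance rearfoot eversion
#' trough with propulsion/swing re-inversion, and a hallux dorsiflexion
#' peak during propulsion. Per-participant compensation magnitudes are
#' added on top of these shapes by [generate_cohort()].
#'
#' @param stance_fraction stance duration as a fraction of the gait cycle.
#' @return nested list `params[[joint]][[plane]]` of harmonic channels.
#' @export
default_joint_params <- function(stance_fraction = 0.62) {
  s <- stance_fraction
  p <- list()
  flat <- harmonic_channel()
  small <- function(w, u0, off = 0, power = 2) {
    harmonic_channel(list(list(w = w, u0 = u0, power = power)), offset = off)
  }
  p$rearfoot <- list(
    # PF dip just after heel strike, deep PF around toe-off; the mid-stance
    # dorsiflexion bump is participant-specific (added by the cohort layer).
    sagittal = merge_channels(small(-3, 0.05 * s), small(-14, 1.06 * s)),
    # narrow re-inversion peak in late propulsion (around 91% of stance);
    # the mid-stance eversion trough is added per person.
    frontal = small(4.5, 0.915 * s, power = 4),
    transverse = small(2, 0.5 * s)
  )
  p$midfoot <- list(
    sagittal = small(3, 0.8 * s), frontal = small(-2, 0.45 * s),
    transverse = small(1.5, 0.6 * s)
  )
  p$medial_forefoot <- list(
    sagittal = small(-4, 0.95 * s), frontal = small(2, 0.7 * s),
    transverse = small(1.5, 0.3 * s)
  )
  p$lateral_forefoot <- list(
    sagittal = small(-3, 0.95 * s), frontal = small(-2, 0.6 * s),
    transverse = small(1.5, 0.5 * s)
  )
  p$hallux <- list(
    # dorsiflexion rises through terminal stance; propulsion peak height is
    # participant-specific (added by the cohort layer).
    sagittal = small(5, 0.9 * s),
    frontal = small(1.5, 0.55 * s), transverse = flat
  )
  p
}

#' Build an angle waveform set
#'
#' Samples the 15 harmonic joint-plane channels over one gait cycle. The
#' object carries the analytic channel parameters, so ground-truth peak
#' values and locations remain retrievable by dense scans of the harmonic
#' form (not of the 100 Hz samples).
#'
#' @param joint_params nested list `params[[joint]][[plane]]`, e.g. from
#'   [default_joint_params()].
#' @param stance_fraction stance fraction of the cycle, must lie in
#'   (0.4, 0.8).
#' @param cycle_duration gait cycle duration in seconds.
#' @param rate marker sampling rate in Hz.
#' @return an object of class `angle_waveforms`: list with `params`,
#'   `curves` (`curves[[joint]][[plane]]`, degrees, one cycle at `rate`),
#'   `stance_fraction`, `cycle_duration`, `rate`, `n_frames`.
#' @export
#' @examples
#' wf <- angle_waveforms()
#' range(wf$curves$rearfoot$frontal)
angle_waveforms <- function(joint_params = default_joint_params(),
                            stance_fraction = 0.62, cycle_duration = 1.1,
                            rate = 100) {
  check_number(stance_fraction, "stance_fraction")
  if (stance_fraction <= 0.4 || stance_fraction >= 0.8) {
    fk_stop("`stance_fraction` must lie in (0.4, 0.8)",
            "footkin_config_error")
  }
  check_number(cycle_duration, "cycle_duration", min = 0.2, max = 5)
  n <- as.integer(round(cycle_duration * rate))
  u <- (seq_len(n) - 1L) / n
  curves <- lapply(joint_names(), function(j) {
    ch <- lapply(plane_names(), function(pl) {
      prm <- joint_params[[j]][[pl]] %||% harmonic_channel()
      if (!all(is.finite(c(prm$offset, prm$amp)))) {
        fk_stop("waveform amplitudes must be finite", "footkin_config_error")
      }
      eval_channel(prm, u)
    })
    names(ch) <- plane_names()
    ch
  })
  names(curves) <- joint_names()
  structure(list(params = joint_params, curves = curves,
                 stance_fraction = stance_fraction,
                 cycle_duration = cycle_duration, rate = rate, n_frames = n),
            class = "angle_waveforms")
}

#' @export
print.angle_waveforms <- function(x, ...) {
  cat("<angle_waveforms> ", x$n_frames, " frames @ ", x$rate, " Hz, cycle ",
      x$cycle_duration, " s, stance ", round(100 * x$stance_fraction, 1),
      "%\n", sep = "")
  invisible(x)
}

#' Ground-truth window extremum of a waveform channel
#'
#' Dense scan (20001 points) of the analytic harmonic channel over a cycle
#' window: the reference against which pipeline-extracted peaks are judged.
#'
#' @param wf an [angle_waveforms()] object.
#' @param joint,plane channel selectors.
#' @param window cycle-fraction window `c(lo, hi)`.
#' @param type `"max"` or `"min"`.
#' @return list `(value, u)`: extremum in degrees and its cycle fraction.
#' @export
waveform_peak <- function(wf, joint, plane, window = c(0, 1),
                          type = c("max", "min")) {
  type <- match.arg(type)
  prm <- wf$params[[joint]][[plane]] %||% harmonic_channel()
  sc <- channel_scan(prm, window[1], window[2])
  if (type == "max") list(value = sc$max, u = sc$u_max)
  else list(value = sc$min, u = sc$u_min)
}

# True heel-lift instant: cycle fraction of the rearfoot sagittal maximum in
# late stance (after 40% of stance), i.e. the onset of sustained
# plantarflexion.
waveform_heel_lift <- function(wf) {
  s <- wf$stance_fraction
  waveform_peak(wf, "rearfoot", "sagittal", c(0.4 * s, s), "max")$u
}

#' Ground-truth gait variables of a waveform set
#'
#' Evaluates the six standard dynamic variables (peak rearfoot eversion and
#' dorsiflexion in mid-stance, sagittal rearfoot angle at heel lift,
#' mid-stance sagittal range, peak hallux dorsiflexion and peak rearfoot
#' eversion during propulsion) directly on the analytic waveforms with the
#' generator's known stance bounds and heel-lift instant.
#'
#' @param wf an [angle_waveforms()] object.
#' @param midstance_start start of the mid-stance window as a fraction of
#'   stance (foot-flat proxy).
#' @return named numeric vector of the six variables (degrees).
#' @export
true_gait_variables <- function(wf, midstance_start = 0.15) {
  s <- wf$stance_fraction
  hl <- waveform_heel_lift(wf)
  ms <- c(midstance_start * s, hl)
  prop <- c(hl, s)
  sag <- wf$params$rearfoot$sagittal
  frn <- wf$params$rearfoot$frontal
  hx <- wf$params$hallux$sagittal
  sag_ms <- channel_scan(sag, ms[1], ms[2])
  c(peak_eversion_midstance = channel_scan(frn, ms[1], ms[2])$min,
    peak_dorsiflexion_midstance = sag_ms$max,
    sagittal_angle_heel_lift = eval_channel(sag, hl),
    sagittal_range_midstance = sag_ms$max - sag_ms$min,
    peak_hallux_dorsiflexion_propulsion =
      channel_scan(hx, prop[1], prop[2])$max,
    peak_eversion_propulsion = channel_scan(frn, prop[1], prop[2])$min)
}
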