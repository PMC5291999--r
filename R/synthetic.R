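# Synthetic motion capture: inverse kinematics of the measurement model.
# Inter-segment Cardan rotations are composed down the segment chain
# leg -> calcaneus -> midfoot -> {medial forefoot -> hallux, lateral
# forefoot}, expressed in the standing leg LCS basis, and applied to the
# built-in cluster geometry; isotropic Gaussian noise is added per marker
# per frame. A smooth double-hump vertical force trace covers stance.

check_cluster_geometry <- function(model) {
  for (s in names(model$segments)) {
    mk <- model$segments[[s]]$markers
    ctr <- sweep(mk, 2, colMeans(mk))
    sv <- svd(ctr)$d
    if (length(sv) < 2L || sv[2] < 1e-6) {
      fk_stop(paste0("marker cluster for segment '", s, "' is collinear"),
              "footkin_geometry_error")
    }
    if (s == "leg" && nrow(mk) < 4L) {
      fk_stop("leg cluster requires 4 markers", "footkin_geometry_error")
    }
    if (nrow(mk) < 3L) {
      fk_stop(paste0("segment '", s, "' requires >= 3 markers"),
              "footkin_geometry_error")
    }
  }
  invisible(model)
}

# chain-ordered segment names (parents before children)
chain_order <- function(model) {
  ord <- character(0)
  remaining <- names(model$segments)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(s) {
      p <- model$segments[[s]]$parent
      is.na(p) || p %in% ord
    }, logical(1))]
    ord <- c(ord, ready)
    remaining <- setdiff(remaining, ready)
  }
  ord
}

# forward kinematics for one frame: named list of per-joint degree triples
# (sagittal, frontal, transverse) -> lab-frame marker matrix
fk_frame <- function(model, angles, R0, leg_tilt = 0, leg_shift = c(0, 0, 0)) {
  segs <- model$segments
  R <- list(); o <- list()
  R$leg <- R0 %*% rot_x(leg_tilt) %*% t(R0)
  o$leg <- segs$leg$origin + leg_shift
  jt <- model$joints
  for (s in chain_order(model)) {
    if (s == "leg") next
    p <- segs[[s]]$parent
    j <- jt$joint[jt$distal == s]
    a <- angles[[j]] %||% c(0, 0, 0)
    Rj <- R0 %*% cardan_compose(a[1], a[2], a[3]) %*% t(R0)
    R[[s]] <- R[[p]] %*% Rj
    o[[s]] <- o[[p]] + drop(R[[p]] %*% (segs[[s]]$origin - segs[[p]]$origin))
  }
  out <- lapply(names(segs), function(s) {
    mk <- segs[[s]]$markers
    t(o[[s]] + R[[s]] %*% t(sweep(mk, 2, segs[[s]]$origin)))
  })
  m <- do.call(rbind, out)
  rownames(m) <- unlist(lapply(segs, function(sg) rownames(sg$markers)))
  m
}

markers_to_df <- function(mats) {
  nf <- length(mats)
  labs <- rownames(mats[[1]])
  data.frame(
    frame = rep(seq_len(nf) - 1L, each = length(labs)),
    label = rep(labs, nf),
    x = unlist(lapply(mats, function(m) m[, 1]), use.names = FALSE),
    y = unlist(lapply(mats, function(m) m[, 2]), use.names = FALSE),
    z = unlist(lapply(mats, function(m) m[, 3]), use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Synthetic vertical ground-reaction force
#'
#' Smooth double-hump force trace: zero exactly outside stance, a two-peak
#' `A * (sin(pi w) + 0.4 sin(3 pi w))` profile over the stance fraction
#' `w`, scaled so the peaks reach about 1.15 body weight.
#'
#' @param cycle_duration gait cycle duration (s).
#' @param stance_fraction stance fraction of the cycle.
#' @param weight body weight in newtons.
#' @param rate force sampling rate (Hz).
#' @param noise_sd additive force noise sd (N), applied inside stance only.
#' @return data.frame `sample`, `fz` (0-based samples).
#' @export
synthetic_force <- function(cycle_duration = 1.1, stance_fraction = 0.62,
                            weight = 700, rate = 1500, noise_sd = 2) {
  n <- as.integer(round(cycle_duration * rate))
  u <- (seq_len(n) - 1L) / (cycle_duration * rate)
  w <- u / stance_fraction
  A <- 1.15 * weight
  fz <- ifelse(w < 1, A * (sin(pi * pmin(w, 1)) + 0.4 * sin(3 * pi * pmin(w, 1))),
               0)
  fz[fz < 0] <- 0
  if (noise_sd > 0) {
    inside <- fz > 0
    fz[inside] <- pmax(0, fz[inside] + stats::rnorm(sum(inside), 0, noise_sd))
  }
  data.frame(sample = seq_len(n) - 1L, fz = fz)
}

#' Generate a synthetic walking trial from angle waveforms
#'
#' Inverts the measurement model: composes the per-frame inter-segment
#' Cardan rotations (x-y-z, in the standing leg LCS basis) down the segment
#' chain, places the built-in marker clusters accordingly, adds isotropic
#' Gaussian marker noise, and attaches a synthetic vertical force trace at
#' `force_rate`. With all-zero waveforms and no noise every frame equals
#' the standing reference configuration.
#'
#' @param waveforms an [angle_waveforms()] object.
#' @param model a [foot_model()]; clusters must be non-collinear.
#' @param noise_sd isotropic marker noise sd in mm.
#' @param seed optional integer seed (bit-reproducible output).
#' @param trial_id trial identifier.
#' @param weight body weight (N) for the force trace.
#' @param force_noise_sd force noise sd (N).
#' @return a [marker_trial()] of kind `"walking"` whose `meta` carries the
#'   generator ground truth (stance fraction, cycle duration, heel-lift
#'   fraction of stance).
#' @export
#' @examples
#' tr <- markers_from_waveforms(angle_waveforms(), noise_sd = 0)
#' tr
markers_from_waveforms <- function(waveforms, model = foot_model(),
                                   noise_sd = 0.5, seed = NULL,
                                   trial_id = "trial", weight = 700,
                                   force_noise_sd = 2) {
  if (!inherits(waveforms, "angle_waveforms")) {
    fk_stop("`waveforms` must be an angle_waveforms object",
            "footkin_contract_error")
  }
  check_cluster_geometry(model)
  if (!is.null(seed)) set.seed(seed)
  R0 <- build_leg_lcs(do.call(rbind, model$anatomical))$rotation
  n <- waveforms$n_frames
  cur <- waveforms$curves
  mats <- lapply(seq_len(n), function(k) {
    ang <- lapply(joint_names(), function(j) {
      c(cur[[j]]$sagittal[k], cur[[j]]$frontal[k], cur[[j]]$transverse[k])
    })
    names(ang) <- joint_names()
    fk_frame(model, ang, R0)
  })
  df <- markers_to_df(mats)
  if (noise_sd > 0) {
    df$x <- df$x + stats::rnorm(nrow(df), 0, noise_sd)
    df$y <- df$y + stats::rnorm(nrow(df), 0, noise_sd)
    df$z <- df$z + stats::rnorm(nrow(df), 0, noise_sd)
  }
  force <- synthetic_force(waveforms$cycle_duration,
                           waveforms$stance_fraction, weight,
                           noise_sd = force_noise_sd)
  reg <- foot_marker_registry(model)
  reg <- reg[reg$segment != "anatomical", , drop = FALSE]
  marker_trial(df, reg, trial_id, "walking", force = force,
               rate = waveforms$rate,
               meta = list(stance_fraction = waveforms$stance_fraction,
                           cycle_duration = waveforms$cycle_duration,
                           heel_lift_stance_frac =
                             waveform_heel_lift(waveforms) /
                             waveforms$stance_fraction))
}

#' Generate a synthetic standing trial
#'
#' Static trial in the standing reference pose. For the subtalar-neutral
#' (STN) standing trial the calcaneus is held rotated in the frontal plane
#' by `rearfoot_frontal` degrees (positive = inverted) relative to relaxed
#' standing; all other joints stay at 0 degrees. The standing reference
#' trial additionally carries the four anatomical calibration markers.
#'
#' @param model a [foot_model()].
#' @param kind `"standing_reference"` or `"stn_standing"`.
#' @param rearfoot_frontal frontal-plane rearfoot angle (deg) of the held
#'   pose; ignored for the standing reference.
#' @param duration trial duration in seconds.
#' @param noise_sd marker noise sd (mm).
#' @param seed optional seed.
#' @param trial_id trial identifier.
#' @return a [marker_trial()].
#' @export
standing_trial <- function(model = foot_model(), kind = "standing_reference",
                           rearfoot_frontal = 0, duration = 1,
                           noise_sd = 0.5, seed = NULL,
                           trial_id = kind) {
  kind <- match.arg(kind, c("standing_reference", "stn_standing"))
  check_cluster_geometry(model)
  if (!is.null(seed)) set.seed(seed)
  R0 <- build_leg_lcs(do.call(rbind, model$anatomical))$rotation
  n <- as.integer(round(duration * 100))
  ang <- stats::setNames(rep(list(c(0, 0, 0)), 5), joint_names())
  if (kind == "stn_standing") {
    ang$rearfoot <- c(0, rearfoot_frontal, 0)
  }
  base <- fk_frame(model, ang, R0)
  if (kind == "standing_reference") {
    anat <- do.call(rbind, model$anatomical)
    colnames(anat) <- c("x", "y", "z")
    base <- rbind(base, anat)
  }
  mats <- rep(list(base), n)
  df <- markers_to_df(mats)
  if (noise_sd > 0) {
    df$x <- df$x + stats::rnorm(nrow(df), 0, noise_sd)
    df$y <- df$y + stats::rnorm(nrow(df), 0, noise_sd)
    df$z <- df$z + stats::rnorm(nrow(df), 0, noise_sd)
  }
  reg <- foot_marker_registry(model)
  if (kind != "standing_reference") {
    reg <- reg[reg$segment != "anatomical", , drop = FALSE]
  }
  marker_trial(df, reg, trial_id, kind, rate = 100,
               meta = list(rearfoot_frontal = rearfoot_frontal))
}
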