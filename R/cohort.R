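# Cohort-level synthesis. Static deformity magnitudes and dynamic
# compensation magnitudes are linked by a Gaussian copula: for each
# deformity pair a bivariate standard normal (z_s, z_d) with correlation
# rho is drawn; the static measure is the z_s-quantile of a two-component
# truncated-normal mixture whose low/high components sit on either side of
# the clinical threshold (so deformity prevalence is exact in
# distribution), and z_d sets the dynamic compensation magnitude that
# parameterizes the participant's waveforms.

qtruncnorm <- function(p, mu, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mu, sd)
  phi <- stats::pnorm(upper, mu, sd)
  stats::qnorm(plo + p * (phi - plo), mu, sd)
}

# quantile of a mixture: mass w_low below `threshold` (low component
# truncated above it), mass 1 - w_low above (high component truncated
# below it). Monotone in u, so copula ranks are preserved.
mixture_quantile <- function(u, w_low, low, high, threshold) {
  ifelse(u <= w_low & w_low > 0,
         qtruncnorm(pmin(u / max(w_low, 1e-12), 1), low$mu, low$sd,
                    upper = threshold),
         qtruncnorm(pmax((u - w_low), 0) / max(1 - w_low, 1e-12),
                    high$mu, high$sd, lower = threshold))
}

#' Default deformity-class effects on the dynamic variables
#'
#' Additive shifts (degrees) applied to a participant's dynamic
#' compensation targets according to their deformity classes. Together
#' with the class-aligned copula shift these reproduce the group
#' contrasts observed in symptom-free cohorts (about -1 deg peak rearfoot
#' dorsiflexion with ankle equinus, about -6 deg propulsion hallux
#' dorsiflexion with a limited 1st MPJ, once the copula contribution is
#' included). Set all to zero for a null cohort.
#'
#' @return named numeric vector of effects.
#' @export
default_group_effects <- function() {
  c(equinus_peak_dorsiflexion = -0.8,
    equinus_peak_eversion = 0.2,
    first_ray_plantarflexed_peak_eversion = -1.7,
    first_ray_dorsiflexed_hallux_dorsiflexion = 0.8,
    forefoot_varus_peak_eversion = 0.5,
    forefoot_valgus_peak_eversion = -0.9,
    hallux_limitation_hallux_dorsiflexion = -5.0)
}

#' Synthetic cohort configuration
#'
#' Study conditions for [generate_cohort()]. Defaults emulate a
#' symptom-free adult cohort: deformity prevalences of 97% rearfoot varus,
#' 87% ankle equinus and 9% hallux limitation; first-ray categories
#' 74/19/7% (plantarflexed/normal/dorsiflexed) and forefoot categories
#' 76/4/20% (varus/normal/valgus); static-dynamic copula correlations of
#' 0.43 (NCSP - mid-stance eversion magnitude), 0.08 (ankle range -
#' mid-stance dorsiflexion) and 0.27 (1st MPJ range - propulsion hallux
#' dorsiflexion); eight walking trials per participant with 0.5 mm marker
#' noise and 0.5 deg inter-trial waveform jitter.
#'
#' Observed static-dynamic correlations combine the copula `rho` with the
#' point-biserial contribution of the threshold group effects: with the
#' defaults the NCSP - mid-stance-eversion pair (no aligned group effect)
#' shows |r| of about 0.43, while the ankle and hallux pairs combine their
#' smaller copula values with the aligned equinus and hallux-limitation
#' effects to totals near 0.2 and 0.4. Between-subject dynamic-variable
#' SDs (3.3-4.9 deg) are sized from published cohort confidence
#' intervals, which keeps most deformity group contrasts statistically
#' unremarkable at n = 100 - as observed in symptom-free cohorts.
#'
#' @param n number of participants (>= 2).
#' @param rho named numeric of copula correlations for the `rearfoot`,
#'   `ankle` and `hallux` pairs (a single unnamed value is recycled); each
#'   must lie in \eqn{[-1, 1]}.
#' @param prevalence named numeric in \eqn{[0, 1]}: `rearfoot_varus`,
#'   `ankle_equinus`, `hallux_limitation`.
#' @param first_ray_probs,forefoot_probs category probabilities (must sum
#'   to 1).
#' @param group_effects named effects vector, see
#'   [default_group_effects()].
#' @param n_trials walking trials per participant.
#' @param marker_noise_sd isotropic marker noise sd (mm).
#' @param jitter_sd inter-trial waveform amplitude jitter sd (deg).
#' @param force_noise_sd force noise sd (N).
#' @param stance_fraction,cycle_duration gait timing of the cohort.
#' @param markers generate marker-level trials (`TRUE`) or only
#'   static/dynamic variables (`FALSE`, for large statistical
#'   simulations).
#' @param seed optional integer seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n = 100,
                          rho = c(rearfoot = 0.43, ankle = 0.08,
                                  hallux = 0.27),
                          prevalence = c(rearfoot_varus = 0.97,
                                         ankle_equinus = 0.87,
                                         hallux_limitation = 0.09),
                          first_ray_probs = c(plantarflexed = 0.74,
                                              normal = 0.19,
                                              dorsiflexed = 0.07),
                          forefoot_probs = c(varus = 0.76, normal = 0.04,
                                             valgus = 0.20),
                          group_effects = default_group_effects(),
                          n_trials = 8, marker_noise_sd = 0.5,
                          jitter_sd = 0.5, force_noise_sd = 2,
                          stance_fraction = 0.62, cycle_duration = 1.1,
                          markers = TRUE, seed = NULL) {
  check_number(n, "n", min = 2)
  if (length(rho) == 1L && is.null(names(rho))) {
    rho <- c(rearfoot = rho, ankle = rho, hallux = rho)
  }
  for (nm in c("rearfoot", "ankle", "hallux")) {
    if (is.na(rho[nm])) {
      fk_stop("`rho` must name rearfoot, ankle and hallux",
              "footkin_config_error")
    }
    check_number(unname(rho[nm]), paste0("rho[", nm, "]"), min = -1, max = 1)
  }
  for (nm in c("rearfoot_varus", "ankle_equinus", "hallux_limitation")) {
    if (is.na(prevalence[nm])) {
      fk_stop("`prevalence` must name rearfoot_varus, ankle_equinus and hallux_limitation",
              "footkin_config_error")
    }
    check_number(unname(prevalence[nm]), paste0("prevalence[", nm, "]"),
                 min = 0, max = 1)
  }
  for (pr in list(first_ray_probs, forefoot_probs)) {
    if (length(pr) != 3L || any(pr < 0) || abs(sum(pr) - 1) > 1e-8) {
      fk_stop("category probabilities must be 3 non-negative values summing to 1",
              "footkin_config_error")
    }
  }
  check_number(n_trials, "n_trials", min = 1)
  check_number(marker_noise_sd, "marker_noise_sd", min = 0)
  check_number(jitter_sd, "jitter_sd", min = 0)
  structure(list(n = as.integer(n), rho = rho, prevalence = prevalence,
                 first_ray_probs = first_ray_probs,
                 forefoot_probs = forefoot_probs,
                 group_effects = group_effects,
                 n_trials = as.integer(n_trials),
                 marker_noise_sd = marker_noise_sd, jitter_sd = jitter_sd,
                 force_noise_sd = force_noise_sd,
                 stance_fraction = stance_fraction,
                 cycle_duration = cycle_duration,
                 markers = isTRUE(markers), seed = seed),
            class = "cohort_config")
}

#' Null cohort configuration for calibration studies
#'
#' A cohort with no static-dynamic coupling (`rho = 0`), no deformity
#' group effects, and balanced class prevalences (so every comparison cell
#' is testable in every replicate). Used to check the empirical type-I
#' error of the statistical battery.
#'
#' @param n number of participants.
#' @param ... further arguments passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
null_cohort_config <- function(n = 100, ...) {
  cohort_config(n = n, rho = c(rearfoot = 0, ankle = 0, hallux = 0),
                prevalence = c(rearfoot_varus = 0.5, ankle_equinus = 0.5,
                               hallux_limitation = 0.5),
                first_ray_probs = c(plantarflexed = 1, normal = 1,
                                    dorsiflexed = 1) / 3,
                forefoot_probs = c(varus = 1, normal = 1, valgus = 1) / 3,
                group_effects = 0 * default_group_effects(),
                markers = FALSE, ...)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> n = ", x$n, ", ", x$n_trials, " trials, markers = ",
      x$markers, "\n  rho: ",
      paste(sprintf("%s %.2f", names(x$rho), x$rho), collapse = ", "),
      "\n  prevalence: ",
      paste(sprintf("%s %.2f", names(x$prevalence), x$prevalence),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# dynamic-variable population parameters (degrees); the SDs are the
# between-subject spreads implied by the 95% CIs of published symptom-free
# cohort summaries (half-width * sqrt(n) / 1.96)
dynamic_pop <- function() {
  list(ever = list(base = -3.3, sd = 3.3),
       df = list(base = 6.6, sd = 4.0),
       hallux = list(base = 45.8, sd = 4.9))
}

# waveform realizability bounds for marker-level synthesis: a mid-stance
# eversion "peak" must undercut the rest curve and the dorsiflexion /
# hallux peaks must exceed it; targets drawn beyond these are clipped and
# the clipped value becomes the ground truth
clip_targets <- function(targets) {
  c(ever = min(unname(targets["ever"]), -0.3),
    df = max(unname(targets["df"]), 0.3),
    hallux = max(unname(targets["hallux"]), 8))
}

sample_category <- function(probs) {
  sample(names(probs), 1L, prob = probs)
}

effect_sum <- function(eff, profile) {
  g <- function(nm) if (is.na(eff[nm])) 0 else unname(eff[nm])
  list(
    ever = g("equinus_peak_eversion") * profile$equinus +
      g("first_ray_plantarflexed_peak_eversion") *
        (profile$first_ray == "plantarflexed") +
      g("forefoot_varus_peak_eversion") * (profile$forefoot == "varus") +
      g("forefoot_valgus_peak_eversion") * (profile$forefoot == "valgus"),
    df = g("equinus_peak_dorsiflexion") * profile$equinus,
    hallux = g("hallux_limitation_hallux_dorsiflexion") * profile$hallux +
      g("first_ray_dorsiflexed_hallux_dorsiflexion") *
        (profile$first_ray == "dorsiflexed")
  )
}

# build one participant's waveforms so the realized window extrema equal
# the dynamic targets exactly
participant_waveforms <- function(targets, stance_fraction, cycle_duration) {
  s <- stance_fraction
  prm <- default_joint_params(s)
  u_df <- 0.73 * s; u_e <- 0.48 * s; u_h <- 0.90 * s
  w_df <- solve_bump_weight(prm$rearfoot$sagittal, u_df, targets["df"],
                            c(0.15 * s, s), "max")
  prm$rearfoot$sagittal <- add_bump(prm$rearfoot$sagittal, w_df, u_df)
  hl <- channel_scan(prm$rearfoot$sagittal, 0.4 * s, s)$u_max
  w_e <- solve_bump_weight(prm$rearfoot$frontal, u_e, targets["ever"],
                           c(0.15 * s, hl), "min")
  prm$rearfoot$frontal <- add_bump(prm$rearfoot$frontal, w_e, u_e)
  w_h <- solve_bump_weight(prm$hallux$sagittal, u_h, targets["hallux"],
                           c(hl, s), "max")
  prm$hallux$sagittal <- add_bump(prm$hallux$sagittal, w_h, u_h)
  list(params = prm, bump_u0 = c(sagittal = u_df, frontal = u_e,
                                 hallux = u_h))
}

jittered_waveforms <- function(base, jitter_sd, stance_fraction,
                               cycle_duration) {
  prm <- base$params
  if (jitter_sd > 0) {
    prm$rearfoot$sagittal <- add_bump(prm$rearfoot$sagittal,
                                      stats::rnorm(1, 0, jitter_sd),
                                      base$bump_u0["sagittal"])
    prm$rearfoot$frontal <- add_bump(prm$rearfoot$frontal,
                                     stats::rnorm(1, 0, jitter_sd),
                                     base$bump_u0["frontal"])
    prm$hallux$sagittal <- add_bump(prm$hallux$sagittal,
                                    stats::rnorm(1, 0, jitter_sd),
                                    base$bump_u0["hallux"])
  }
  angle_waveforms(prm, stance_fraction, cycle_duration)
}

#' Generate a synthetic gait cohort with known ground truth
#'
#' Draws each participant's static assessment and dynamic compensation
#' magnitudes from the configured copula model, builds waveforms whose
#' mid-stance/propulsion extrema equal the dynamic targets exactly, and
#' (when `config$markers` is `TRUE`) synthesizes the walking trials, the
#' standing reference trial and the subtalar-neutral standing trial for
#' every participant. Per-participant trials differ only by marker noise
#' and small waveform amplitude jitter.
#'
#' @param config a [cohort_config()].
#' @param model a [foot_model()].
#' @return object of class `synthetic_cohort`: list with `config` and
#'   `participants`; each participant carries `static`
#'   ([static_assessment()]), `neutral_angle`, `dynamic_magnitudes`
#'   (positive compensation scale), `true_variables` (the six dynamic
#'   variables), and in marker mode `waveforms`, `trials`, `standing`,
#'   `stn` and `truth` (heel-lift/stance ground truth).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 2, markers = FALSE, seed = 1))
#' coh$participants[[1]]$static
generate_cohort <- function(config = cohort_config(), model = foot_model()) {
  if (!inherits(config, "cohort_config")) {
    fk_stop("`config` must be a cohort_config", "footkin_config_error")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  rho <- config$rho[c("rearfoot", "ankle", "hallux")]
  prev <- config$prevalence
  eff <- config$group_effects
  pop <- dynamic_pop()
  s <- config$stance_fraction
  participants <- vector("list", config$n)
  for (i in seq_len(config$n)) {
    zs <- stats::rnorm(3)
    zd <- rho * zs + sqrt(1 - rho^2) * stats::rnorm(3)
    names(zs) <- names(zd) <- c("rearfoot", "ankle", "hallux")
    ncsp <- mixture_quantile(stats::pnorm(zs["rearfoot"]),
                             1 - prev["rearfoot_varus"],
                             list(mu = -2, sd = 1.5),
                             list(mu = 9.2, sd = 3.0), threshold = 0)
    ankle <- mixture_quantile(stats::pnorm(zs["ankle"]),
                              prev["ankle_equinus"],
                              list(mu = 4.8, sd = 2.0),
                              list(mu = 11.9, sd = 1.5), threshold = 10)
    mpj <- mixture_quantile(stats::pnorm(zs["hallux"]),
                            prev["hallux_limitation"],
                            list(mu = 57, sd = 4),
                            list(mu = 78, sd = 7), threshold = 65)
    first_ray <- sample_category(config$first_ray_probs)
    forefoot <- sample_category(config$forefoot_probs)
    rcsp <- stats::rnorm(1, 4.0, 2.5)
    fpi_cat <- sample_category(c(pronated = 0.32, neutral = 0.56,
                                 supinated = 0.12))
    fpi <- round(stats::rnorm(1, c(pronated = 7.7, neutral = 2.6,
                                   supinated = -2.4)[fpi_cat], 1.5))
    static <- static_assessment(ncsp = unname(ncsp), rcsp = rcsp,
                                ankle_dorsiflexion = unname(ankle),
                                mpj_dorsiflexion = unname(mpj),
                                first_ray = first_ray, forefoot = forefoot,
                                fpi = fpi)
    prof <- list(equinus = ankle < 10, hallux = mpj < 65,
                 first_ray = first_ray, forefoot = forefoot)
    ef <- effect_sum(eff, prof)
    targets <- c(
      ever = unname(pop$ever$base - pop$ever$sd * zd["rearfoot"] + ef$ever),
      df = unname(pop$df$base + pop$df$sd * zd["ankle"] + ef$df),
      hallux = unname(pop$hallux$base + pop$hallux$sd * zd["hallux"] +
                        ef$hallux))
    magnitudes <- c(rearfoot = unname(-targets["ever"]),
                    ankle = unname(targets["df"]),
                    hallux = unname(targets["hallux"]))
    neutral <- unname(ncsp) - rcsp
    p <- list(id = sprintf("P%03d", i), static = static,
              neutral_angle = neutral, z = list(static = zs, dynamic = zd),
              dynamic_magnitudes = magnitudes)
    if (config$markers) {
      targets <- clip_targets(targets)
      p$dynamic_magnitudes <- c(rearfoot = unname(-targets["ever"]),
                                ankle = unname(targets["df"]),
                                hallux = unname(targets["hallux"]))
      base <- participant_waveforms(targets, s, config$cycle_duration)
      wf <- angle_waveforms(base$params, s, config$cycle_duration)
      p$waveforms <- wf
      p$true_variables <- true_gait_variables(wf)
      p$truth <- list(
        heel_lift_stance_frac = waveform_heel_lift(wf) / s,
        stance_fraction = s, cycle_duration = config$cycle_duration)
      p$trials <- lapply(seq_len(config$n_trials), function(t) {
        wft <- jittered_waveforms(base, config$jitter_sd, s,
                                  config$cycle_duration)
        markers_from_waveforms(wft, model,
                               noise_sd = config$marker_noise_sd,
                               trial_id = sprintf("%s_W%d", p$id, t),
                               force_noise_sd = config$force_noise_sd)
      })
      p$standing <- standing_trial(model, "standing_reference",
                                   noise_sd = config$marker_noise_sd,
                                   trial_id = paste0(p$id, "_static"))
      p$stn <- standing_trial(model, "stn_standing",
                              rearfoot_frontal = neutral,
                              noise_sd = config$marker_noise_sd,
                              trial_id = paste0(p$id, "_stn"))
    } else {
      p$true_variables <- c(
        peak_eversion_midstance = unname(targets["ever"]),
        peak_dorsiflexion_midstance = unname(targets["df"]),
        sagittal_angle_heel_lift =
          unname(targets["df"]) - abs(stats::rnorm(1, 0.1, 0.05)),
        sagittal_range_midstance =
          unname(targets["df"]) + abs(stats::rnorm(1, 1.3, 0.4)),
        peak_hallux_dorsiflexion_propulsion = unname(targets["hallux"]),
        peak_eversion_propulsion =
          0.5 * unname(targets["ever"]) + stats::rnorm(1, 0.9, 1.5))
    }
    participants[[i]] <- p
  }
  structure(list(config = config, participants = participants),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$participants), " participants",
      if (x$config$markers) sprintf(", %d walking trials each",
                                    x$config$n_trials)
      else " (variables only)", "\n", sep = "")
  invisible(x)
}

#' Static assessment table of a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @return data.frame: one row per participant with the static fields and
#'   the subtalar-neutral standing angle.
#' @export
cohort_statics <- function(cohort) {
  do.call(rbind, lapply(cohort$participants, function(p) {
    data.frame(id = p$id, ncsp = p$static$ncsp, rcsp = p$static$rcsp,
               ankle_dorsiflexion = p$static$ankle_dorsiflexion,
               mpj_dorsiflexion = p$static$mpj_dorsiflexion,
               first_ray = p$static$first_ray, forefoot = p$static$forefoot,
               fpi = p$static$fpi, neutral_angle = p$neutral_angle,
               stringsAsFactors = FALSE)
  }))
}

#' Ground-truth dynamic variable table of a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @return data.frame: one row per participant, six dynamic variables.
#' @export
cohort_true_variables <- function(cohort) {
  do.call(rbind, lapply(cohort$participants, function(p) {
    cbind(data.frame(id = p$id, stringsAsFactors = FALSE),
          as.data.frame(as.list(p$true_variables)))
  }))
}
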