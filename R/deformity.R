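#' Static biomechanical assessment record
#'
#' The five Root-model static measures plus the Foot Posture Index for one
#' (left) foot. Angles are degrees; NCSP/RCSP are frontal-plane calcaneal
#' angles with inversion positive.
#'
#' @param ncsp neutral calcaneal stance position angle (deg, + inverted).
#' @param rcsp relaxed calcaneal stance position angle (deg).
#' @param ankle_dorsiflexion static ankle dorsiflexion range (deg).
#' @param mpj_dorsiflexion maximum 1st MPJ (hallux) dorsiflexion (deg).
#' @param first_ray sagittal first-ray position: `"plantarflexed"`,
#'   `"normal"` or `"dorsiflexed"`.
#' @param forefoot frontal forefoot-to-rearfoot alignment: `"varus"`,
#'   `"normal"` or `"valgus"`.
#' @param fpi Foot Posture Index total score (integer, stored as given).
#' @return object of class `static_assessment`.
#' @export
static_assessment <- function(ncsp, rcsp = NA_real_, ankle_dorsiflexion,
                              mpj_dorsiflexion, first_ray = "normal",
                              forefoot = "normal", fpi = NA_integer_) {
  for (v in list(ncsp = ncsp, ankle_dorsiflexion = ankle_dorsiflexion,
                 mpj_dorsiflexion = mpj_dorsiflexion)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      fk_stop("static angles must be single finite numbers",
              "footkin_validation_error")
    }
  }
  first_ray <- match.arg(first_ray, c("plantarflexed", "normal",
                                      "dorsiflexed"))
  forefoot <- match.arg(forefoot, c("varus", "normal", "valgus"))
  structure(list(ncsp = ncsp, rcsp = rcsp,
                 ankle_dorsiflexion = ankle_dorsiflexion,
                 mpj_dorsiflexion = mpj_dorsiflexion,
                 first_ray = first_ray, forefoot = forefoot,
                 fpi = as.integer(round(fpi))),
            class = "static_assessment")
}

#' @export
print.static_assessment <- function(x, ...) {
  cat(sprintf(
    "<static_assessment> NCSP %.1f, RCSP %s, ankle DF %.1f, 1st MPJ DF %.1f, first ray %s, forefoot %s, FPI %s\n",
    x$ncsp, format(x$rcsp), x$ankle_dorsiflexion, x$mpj_dorsiflexion,
    x$first_ray, x$forefoot, format(x$fpi)))
  invisible(x)
}

#' Deformity classification thresholds
#'
#' The Root-model cut-offs: rearfoot varus when the calcaneus is inverted
#' in NCSP (strictly above `varus`, default 0 deg); ankle equinus when the
#' static ankle dorsiflexion range is strictly below `equinus` (default
#' 10 deg); hallux limitation when maximum 1st MPJ dorsiflexion is strictly
#' below `hallux` (default 65 deg). Values exactly at a threshold classify
#' as normal.
#'
#' @param varus,equinus,hallux thresholds in degrees.
#' @return named list of thresholds.
#' @export
deformity_thresholds <- function(varus = 0, equinus = 10, hallux = 65) {
  list(varus = check_number(varus, "varus"),
       equinus = check_number(equinus, "equinus"),
       hallux = check_number(hallux, "hallux"))
}

#' Classify the five Root-model foot deformities
#'
#' Applies the static classification rules to an assessment record:
#' rearfoot varus (NCSP inverted), ankle equinus (dorsiflexion range below
#' 10 deg), hallux limitation (1st MPJ dorsiflexion below 65 deg), and the
#' pass-through binary/ternary first-ray and forefoot categories. The
#' deformity count (0-5) gives one slot each to the five assessments, with
#' any non-normal first-ray or forefoot category contributing its slot.
#'
#' @param static a [static_assessment()].
#' @param thresholds a [deformity_thresholds()] list.
#' @return object of class `deformity_profile`: list of present/absent
#'   flags with magnitudes, the two categories, and `count`.
#' @export
#' @examples
#' classify_deformities(static_assessment(
#'   ncsp = 9.2, ankle_dorsiflexion = 4.8, mpj_dorsiflexion = 70))
classify_deformities <- function(static,
                                 thresholds = deformity_thresholds()) {
  if (!inherits(static, "static_assessment")) {
    fk_stop("`static` must be a static_assessment", "footkin_validation_error")
  }
  varus <- static$ncsp > thresholds$varus
  equinus <- static$ankle_dorsiflexion < thresholds$equinus
  hallux <- static$mpj_dorsiflexion < thresholds$hallux
  count <- sum(varus, equinus, hallux,
               static$first_ray != "normal", static$forefoot != "normal")
  prof <- structure(list(
    rearfoot_varus = varus, rearfoot_varus_deg = static$ncsp,
    ankle_equinus = equinus, ankle_dorsiflexion_deg = static$ankle_dorsiflexion,
    hallux_limitation = hallux, mpj_dorsiflexion_deg = static$mpj_dorsiflexion,
    first_ray = static$first_ray, forefoot = static$forefoot,
    count = as.integer(count)), class = "deformity_profile")
  stopifnot(prof$count == sum(prof$rearfoot_varus, prof$ankle_equinus,
                              prof$hallux_limitation,
                              prof$first_ray != "normal",
                              prof$forefoot != "normal"))
  prof
}

#' @export
print.deformity_profile <- function(x, ...) {
  lab <- c(if (x$rearfoot_varus) sprintf("rearfoot varus (%.1f deg)",
                                         x$rearfoot_varus_deg),
           if (x$ankle_equinus) sprintf("ankle equinus (%.1f deg DF)",
                                        x$ankle_dorsiflexion_deg),
           if (x$hallux_limitation) sprintf("hallux limitation (%.1f deg)",
                                            x$mpj_dorsiflexion_deg),
           if (x$first_ray != "normal") paste0(x$first_ray, " first ray"),
           if (x$forefoot != "normal") paste0("forefoot ", x$forefoot))
  cat("<deformity_profile> count ", x$count, ": ",
      if (length(lab)) paste(lab, collapse = ", ") else "none", "\n",
      sep = "")
  invisible(x)
}

#' Subtalar-neutral pass-through analysis for one foot
#'
#' Compares the frontal-plane rearfoot angle held in subtalar neutral
#' standing with the frontal rearfoot curve during gait. The foot "passes
#' through" neutral if the curve minus the neutral angle changes sign or
#' touches zero (within `tol`) anywhere in the examined range; the first
#' crossing instant is reported (all crossings are retrievable). Otherwise
#' the minimum absolute difference and the instant of closest approach are
#' reported.
#'
#' @param neutral_angle frontal rearfoot angle in subtalar neutral
#'   standing (deg, + inverted).
#' @param curve frontal rearfoot gait curve, normalized with equally
#'   spaced samples spanning 0-100% of the gait cycle (at least 51
#'   samples).
#' @param tol angular tolerance for "coinciding" (deg).
#' @param stance_fraction optional; when given, the analysis is restricted
#'   to stance (0 to `stance_fraction` of the cycle).
#' @return object of class `stn_result`: `passed`, `crossing_pct` and
#'   `crossings` (percent of gait cycle; populated when passed),
#'   `min_diff` and `closest_pct` (populated when not passed).
#' @export
#' @examples
#' stn_passthrough(5, seq(0, 10, length.out = 101))
stn_passthrough <- function(neutral_angle, curve, tol = 1e-9,
                            stance_fraction = NULL) {
  check_number(neutral_angle, "neutral_angle")
  if (!is.numeric(curve) || length(curve) < 51L || !all(is.finite(curve))) {
    fk_stop("`curve` must be a finite cycle-normalized curve (>= 51 samples)",
            "footkin_contract_error")
  }
  pct <- seq(0, 100, length.out = length(curve))
  if (!is.null(stance_fraction)) {
    keep <- pct <= 100 * stance_fraction + 1e-9
    pct <- pct[keep]; curve <- curve[keep]
  }
  d <- curve - neutral_angle
  crossings <- numeric(0)
  i <- 1L
  while (i <= length(d)) {
    if (abs(d[i]) <= tol) {
      crossings <- c(crossings, pct[i])
      i <- i + 1L
      next
    }
    if (i < length(d) && abs(d[i + 1L]) > tol &&
        sign(d[i]) != sign(d[i + 1L])) {
      w <- d[i] / (d[i] - d[i + 1L])
      crossings <- c(crossings, pct[i] + w * (pct[i + 1L] - pct[i]))
    }
    i <- i + 1L
  }
  if (length(crossings)) {
    res <- list(passed = TRUE, crossing_pct = crossings[1],
                crossings = crossings, min_diff = NA_real_,
                closest_pct = crossings[1], neutral_angle = neutral_angle)
  } else {
    j <- which.min(abs(d))
    res <- list(passed = FALSE, crossing_pct = NA_real_,
                crossings = numeric(0), min_diff = abs(d[j]),
                closest_pct = pct[j], neutral_angle = neutral_angle)
  }
  structure(res, class = "stn_result")
}

#' @export
print.stn_result <- function(x, ...) {
  if (x$passed) {
    cat(sprintf("<stn_result> passed through neutral at %.1f%% of cycle (%d crossing(s))\n",
                x$crossing_pct, length(x$crossings)))
  } else {
    cat(sprintf("<stn_result> did not pass; minimum difference %.2f deg at %.1f%%\n",
                x$min_diff, x$closest_pct))
  }
  invisible(x)
}

#' Cohort summary of subtalar-neutral pass-through results
#'
#' Percent of feet passing through neutral, and the pooled timing summary:
#' the crossing time for passers together with the closest-approach time
#' for non-passers, as a mean with t-based 95% confidence interval (the
#' "passed through or was closest" statistic).
#'
#' @param results list of [stn_passthrough()] results.
#' @param level confidence level.
#' @return list with `n`, `pct_passed`, `mean_pct`, `ci` (percent of gait
#'   cycle).
#' @export
cohort_stn_summary <- function(results, level = 0.95) {
  if (!length(results)) {
    fk_stop("need at least one STN result", "footkin_contract_error")
  }
  passed <- vapply(results, function(r) r$passed, logical(1))
  times <- vapply(results, function(r) {
    if (r$passed) r$crossing_pct else r$closest_pct
  }, numeric(1))
  ci <- ci_mean(times, level = level)
  list(n = length(results), pct_passed = 100 * mean(passed),
       mean_pct = mean(times), ci = ci)
}
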