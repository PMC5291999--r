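test_that("a square force pulse yields exact stance bounds", {
  fz <- rep(0, 4500)
  fz[1501:3000] <- 600  # samples 1500-2999, 0-based
  st <- detect_stance(fz, rate = 1500, threshold = 20)
  expect_equal(st$heel_strike, 1.0)
  expect_equal(st$toe_off, 2.0)
})

test_that("all-zero force is a no-stance error", {
  expect_error(detect_stance(rep(0, 3000)), class = "footkin_no_stance_error")
  expect_error(detect_stance(c(rep(0, 100), rep(100, 50), rep(0, 100))),
               class = "footkin_no_stance_error")  # too short to qualify
})

test_that("stance detection is invariant to force re-scaling", {
  fr <- synthetic_force(noise_sd = 0)
  a <- detect_stance(fr)
  b <- detect_stance(fr$fz * 3.7)
  # re-scaling only moves the threshold crossing along the loading ramp
  expect_lt(abs(a$heel_strike - b$heel_strike), 0.003)
  expect_lt(abs(a$toe_off - b$toe_off), 0.003)
})

test_that("noisy synthetic force bounds are within 10 ms of ground truth", {
  set.seed(70)
  for (i in 1:10) {
    fr <- synthetic_force(cycle_duration = 1.1, stance_fraction = 0.62,
                          noise_sd = 2)
    st <- detect_stance(fr)
    expect_lt(abs(st$heel_strike - 0), 0.010)
    expect_lt(abs(st$toe_off - 0.62 * 1.1), 0.010)
  }
})

test_that("a constructed plantarflexion onset is detected exactly", {
  # stance is the first half of the cycle; flat until 60% stance (30% of
  # cycle, a grid point), then linear plantarflexion
  u <- seq(0, 1, length.out = 101)
  curve <- ifelse(u <= 0.3, 5, 5 - 40 * (u - 0.3))
  hl <- detect_heel_lift(curve, stance_fraction = 0.5)
  expect_equal(hl$stance_frac, 0.6, tolerance = 1e-9)
  expect_identical(hl$method, "velocity")
})

test_that("a monotone dorsiflexing curve falls back with a warning", {
  curve <- seq(0, 10, length.out = 101)
  expect_warning(hl <- detect_heel_lift(curve, stance_fraction = 0.6,
                                        fallback = 0.65),
                 class = "footkin_heel_lift_fallback")
  expect_equal(hl$stance_frac, 0.65)
  expect_identical(hl$method, "fallback")
})

test_that("heel lift on synthetic curves lands within 3% stance of truth", {
  for (targets in list(c(ever = -3, df = 5, hallux = 40),
                       c(ever = -5.5, df = 7.5, hallux = 50))) {
    wf <- demo_waveforms(targets)
    truth <- footkin:::waveform_heel_lift(wf) / wf$stance_fraction
    norm <- lapply(wf$curves$rearfoot, footkin:::resample_curve,
                   n_out = 101L)
    hl <- detect_heel_lift(norm$sagittal, wf$stance_fraction)
    expect_lt(abs(hl$stance_frac - truth), 0.03)
  }
})

test_that("event window invariants are enforced", {
  expect_error(gait_events(0.5, 0.4, 0.6, 1.1),
               class = "footkin_contract_error")
  ev <- gait_events(0, 0.682, 0.65, 1.1)
  expect_lt(ev$heel_strike, ev$heel_lift)
  expect_lt(ev$heel_lift, ev$toe_off)
  expect_equal(ev$midstance, c(15, 65))
  expect_equal(ev$propulsion, c(65, 100))
})

make_series <- function(f_sag, f_frn, f_hx) {
  u <- seq(0, 1, length.out = 101)
  angle_series(normalized = list(
    rearfoot = list(sagittal = f_sag(u), frontal = f_frn(u),
                    transverse = rep(0, 101)),
    hallux = list(sagittal = f_hx(u), frontal = rep(0, 101),
                  transverse = rep(0, 101))),
    cycle_duration = 1.1)
}

test_that("constructed extrema are extracted exactly", {
  ev <- gait_events(0, 0.682, 0.65, 1.1)
  # frontal trough of -4 at 25% cycle (inside mid-stance), constant sagittal
  ser <- make_series(
    f_sag = function(u) rep(2, length(u)),
    f_frn = function(u) -4 * exp(-((u - 0.25) / 0.08)^2),
    f_hx = function(u) 30 * exp(-((u - 0.5) / 0.07)^2))
  v <- extract_variables(ser, ev)
  expect_equal(unname(v["peak_eversion_midstance"]), -4, tolerance = 1e-6)
  expect_equal(unname(v["sagittal_range_midstance"]), 0)
  expect_equal(unname(v["sagittal_angle_heel_lift"]), 2)
})

test_that("variables on harmonic curves match dense brute-force scans", {
  for (targets in list(c(ever = -4.2, df = 6.3, hallux = 46),
                       c(ever = -2.1, df = 4.4, hallux = 38))) {
    wf <- demo_waveforms(targets)
    s <- wf$stance_fraction
    hl_frac <- footkin:::waveform_heel_lift(wf) / s
    norm <- lapply(footkin:::joint_names(), function(j) {
      lapply(wf$curves[[j]], footkin:::resample_curve, n_out = 101L)
    })
    names(norm) <- footkin:::joint_names()
    ser <- angle_series(normalized = norm,
                        cycle_duration = wf$cycle_duration)
    ev <- gait_events(0, s * wf$cycle_duration, hl_frac,
                      wf$cycle_duration)
    v <- extract_variables(ser, ev)
    truth <- true_gait_variables(wf)
    expect_equal(as.numeric(v), unname(truth), tolerance = 0.1,
                 ignore_attr = TRUE)
    expect_lt(max(abs(as.numeric(v) - truth)), 0.1)
  }
})

test_that("extraction is invariant to time-base refinement", {
  wf <- demo_waveforms()
  s <- wf$stance_fraction
  hl_frac <- footkin:::waveform_heel_lift(wf) / s
  ev <- gait_events(0, s * wf$cycle_duration, hl_frac, wf$cycle_duration)
  u101 <- seq(0, 1, length.out = 101)
  u1001 <- seq(0, 1, length.out = 1001)
  v <- lapply(list(u101, u1001), function(u) {
    norm <- lapply(footkin:::joint_names(), function(j) {
      lapply(wf$params[[j]], function(prm) eval_channel(prm, u))
    })
    names(norm) <- footkin:::joint_names()
    ser <- angle_series(curves = norm, cycle_duration = wf$cycle_duration)
    ser$normalized <- norm  # same grid semantics, different density
    extract_variables(ser, ev)
  })
  expect_lt(max(abs(v[[1]] - v[[2]])), 0.05)
})

test_that("an empty window is a contract error", {
  ser <- make_series(function(u) u, function(u) u, function(u) u)
  ev <- gait_events(0, 0.682, 0.65, 1.1)
  ev$midstance <- c(15.0, 15.1)
  expect_error(extract_variables(ser, ev), class = "footkin_contract_error")
})
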