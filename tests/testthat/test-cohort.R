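no_effects <- function(...) {
  cohort_config(..., group_effects = 0 * default_group_effects(),
                markers = FALSE)
}

test_that("uncoupled cohorts show no static-dynamic correlation", {
  coh <- generate_cohort(no_effects(n = 200, rho = 0, seed = 31))
  st <- cohort_statics(coh)
  tv <- cohort_true_variables(coh)
  expect_lt(abs(cor(st$ncsp, tv$peak_eversion_midstance)), 0.15)
  expect_lt(abs(cor(st$ankle_dorsiflexion,
                    tv$peak_dorsiflexion_midstance)), 0.15)
  expect_lt(abs(cor(st$mpj_dorsiflexion,
                    tv$peak_hallux_dorsiflexion_propulsion)), 0.15)
})

test_that("a degenerate copula gives perfect rank correlation", {
  coh <- generate_cohort(no_effects(n = 60, rho = 1, seed = 32))
  st <- cohort_statics(coh)
  mag <- t(vapply(coh$participants, function(p) p$dynamic_magnitudes,
                  numeric(3)))
  expect_equal(cor(st$ncsp, mag[, "rearfoot"], method = "spearman"), 1)
  expect_equal(cor(st$ankle_dorsiflexion, mag[, "ankle"],
                   method = "spearman"), 1)
  expect_equal(cor(st$mpj_dorsiflexion, mag[, "hallux"],
                   method = "spearman"), 1)
})

test_that("prevalence 1 forces every ankle below the equinus threshold", {
  cfg <- cohort_config(n = 50, prevalence = c(rearfoot_varus = 0.97,
                                              ankle_equinus = 1,
                                              hallux_limitation = 0),
                       markers = FALSE, seed = 33)
  st <- cohort_statics(generate_cohort(cfg))
  expect_true(all(st$ankle_dorsiflexion < 10))
  expect_true(all(st$mpj_dorsiflexion >= 65))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(rho = 1.2), class = "footkin_config_error")
  expect_error(cohort_config(prevalence = c(rearfoot_varus = -0.1,
                                            ankle_equinus = 0.5,
                                            hallux_limitation = 0.5)),
               class = "footkin_config_error")
  expect_error(cohort_config(n = 1), class = "footkin_config_error")
  expect_error(cohort_config(marker_noise_sd = -1),
               class = "footkin_config_error")
  expect_error(cohort_config(first_ray_probs = c(0.5, 0.5, 0.5)),
               class = "footkin_config_error")
})

test_that("marker cohorts carry the configured trial count and exact truth", {
  cfg <- cohort_config(n = 2, n_trials = 3, marker_noise_sd = 0,
                       jitter_sd = 0, seed = 34)
  coh <- generate_cohort(cfg)
  p <- coh$participants[[1]]
  expect_length(p$trials, 3L)
  # true variables are consistent with the waveforms they came from
  expect_equal(unname(p$true_variables),
               unname(true_gait_variables(p$waveforms)))
  # and with the dynamic magnitudes that parameterized them
  expect_equal(unname(-p$true_variables["peak_eversion_midstance"]),
               unname(p$dynamic_magnitudes["rearfoot"]), tolerance = 1e-6)
})

test_that("seeded cohorts are reproducible", {
  a <- generate_cohort(cohort_config(n = 2, n_trials = 1, seed = 35))
  b <- generate_cohort(cohort_config(n = 2, n_trials = 1, seed = 35))
  expect_identical(cohort_statics(a), cohort_statics(b))
  expect_identical(a$participants[[1]]$trials[[1]]$markers,
                   b$participants[[1]]$trials[[1]]$markers)
})

test_that("zero-noise pipeline recovers the generating waveforms", {
  cfg <- cohort_config(n = 2, n_trials = 2, marker_noise_sd = 0,
                       jitter_sd = 0, force_noise_sd = 0, seed = 36)
  coh <- generate_cohort(cfg)
  p <- coh$participants[[1]]
  cal <- calibrate_segments(p$standing)
  for (tr in p$trials) {
    ser <- compute_joint_angles(tr, cal)
    for (j in footkin:::joint_names()) {
      for (pl in footkin:::plane_names()) {
        expect_lt(max(abs(ser$curves[[j]][[pl]] -
                            p$waveforms$curves[[j]][[pl]])), 0.01)
      }
    }
  }
})
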