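test_that("calibration zeroes all inter-segment angles on the standing trial", {
  st <- standing_trial(noise_sd = 0)
  cal <- calibrate_segments(st)
  ser <- compute_joint_angles(st, cal)
  for (j in footkin:::joint_names()) {
    for (pl in footkin:::plane_names()) {
      expect_lt(max(abs(ser$curves[[j]][[pl]])), 1e-9)
    }
  }
})

test_that("calibration from a synthetic standing trial reproduces the model", {
  st <- standing_trial(noise_sd = 0)
  cal <- calibrate_segments(st)
  model <- foot_model()
  R0 <- build_leg_lcs(do.call(rbind, model$anatomical))$rotation
  expect_equal(cal$leg_rotation, R0, tolerance = 1e-9)
  for (s in names(cal$clusters)) {
    expect_equal(unname(cal$clusters[[s]][rownames(model$segments[[s]]$markers), ]),
                 unname(model$segments[[s]]$markers), tolerance = 1e-9)
  }
})

test_that("a standing trial without a malleolus marker is a model error", {
  st <- standing_trial(noise_sd = 0)
  st$markers <- st$markers[st$markers$label != "med_malleolus", ]
  st$registry <- st$registry[st$registry$label != "med_malleolus", ]
  expect_error(calibrate_segments(st), regexp = "med_malleolus",
               class = "footkin_model_error")
})

test_that("noisy recovery stays within tolerance with near-zero bias", {
  wf <- demo_waveforms()
  st <- standing_trial(noise_sd = 0.5, seed = 60)
  cal <- calibrate_segments(st)
  set.seed(61)
  errs <- list()
  for (t in 1:4) {
    tr <- markers_from_waveforms(wf, noise_sd = 0.5)
    ser <- compute_joint_angles(tr, cal)
    errs[[t]] <- unlist(lapply(footkin:::joint_names(), function(j) {
      lapply(footkin:::plane_names(), function(pl) {
        ser$curves[[j]][[pl]] - wf$curves[[j]][[pl]]
      })
    }))
  }
  per_channel_rmse <- sqrt(Reduce(`+`, lapply(errs, function(e) e^2)) /
                             length(errs))
  expect_lt(max(per_channel_rmse), 1)          # every sample of every channel
  expect_lt(sqrt(mean(unlist(errs)^2)), 0.5)   # pooled RMSE
  expect_lt(abs(mean(unlist(errs))), 0.1)      # bias
})

test_that("frames with missing segment markers are excluded with a warning", {
  wf <- demo_waveforms()
  tr <- markers_from_waveforms(wf, noise_sd = 0)
  st <- standing_trial(noise_sd = 0)
  cal <- calibrate_segments(st)
  bad <- tr$markers$frame == 5 & grepl("^calcaneus", tr$markers$label)
  tr$markers$x[bad] <- NA
  expect_warning(ser <- compute_joint_angles(tr, cal),
                 class = "footkin_missing_frames_warning")
  expect_equal(ser$provenance$excluded_frames, 5L)
})

test_that("mean across trials is idempotent, linear and matches brute force", {
  wf <- demo_waveforms()
  st <- standing_trial(noise_sd = 0)
  cal <- calibrate_segments(st)
  tr <- markers_from_waveforms(wf, noise_sd = 0)
  ser <- compute_joint_angles(tr, cal)
  m8 <- mean_across_trials(rep(list(ser), 8))
  expect_equal(m8$normalized, ser$normalized, tolerance = 1e-12)
  ser5 <- ser
  ser5$normalized <- lapply(ser$normalized, function(j) {
    lapply(j, function(x) x + 5)
  })
  m2 <- mean_across_trials(list(ser, ser5))
  expect_equal(m2$normalized$rearfoot$sagittal,
               ser$normalized$rearfoot$sagittal + 2.5, tolerance = 1e-12)
  set.seed(62)
  rnd <- lapply(1:3, function(i) {
    s <- ser
    s$normalized <- lapply(s$normalized, function(j) {
      lapply(j, function(x) x + stats::rnorm(length(x)))
    })
    s
  })
  mr <- mean_across_trials(rnd)
  brute <- (rnd[[1]]$normalized$hallux$frontal +
              rnd[[2]]$normalized$hallux$frontal +
              rnd[[3]]$normalized$hallux$frontal) / 3
  expect_equal(mr$normalized$hallux$frontal, brute, tolerance = 1e-12)
})

test_that("mixed normalization bases are a contract error", {
  s1 <- angle_series(normalized = list(rearfoot = list(
    sagittal = rep(0, 101), frontal = rep(0, 101), transverse = rep(0, 101))))
  s2 <- s1
  s2$normalized$rearfoot <- lapply(s2$normalized$rearfoot, function(x) x[1:51])
  expect_error(mean_across_trials(list(s1, s2)),
               class = "footkin_contract_error")
  expect_error(angle_series(normalized = s2$normalized),
               class = "footkin_contract_error")
})

test_that("normalized view has 101 samples and refines consistently", {
  wf <- demo_waveforms()
  tr <- markers_from_waveforms(wf, noise_sd = 0)
  cal <- calibrate_segments(standing_trial(noise_sd = 0))
  ser <- compute_joint_angles(tr, cal)
  expect_length(ser$normalized$rearfoot$frontal, 101L)
  fine <- time_normalize(ser, 1001L)
  expect_length(fine$rearfoot$frontal, 1001L)
  expect_equal(fine$rearfoot$frontal[seq(1, 1001, by = 10)],
               ser$normalized$rearfoot$frontal, tolerance = 1e-9)
})
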