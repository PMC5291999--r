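test_that("zero waveforms and zero noise reproduce the reference pose", {
  wf <- angle_waveforms()  # rest shapes
  zero <- lapply(wf$params, function(j) lapply(j, function(x) harmonic_channel()))
  wfz <- angle_waveforms(zero)
  tr <- markers_from_waveforms(wfz, noise_sd = 0)
  m0 <- footkin:::frame_matrix(tr, 0)
  for (k in c(10, 50, 100)) {
    expect_equal(footkin:::frame_matrix(tr, k), m0, tolerance = 1e-12)
  }
  model <- foot_model()
  rn <- rownames(model$segments$calcaneus$markers)
  expect_equal(unname(m0[rn, ]),
               unname(model$segments$calcaneus$markers), tolerance = 1e-12)
})

test_that("a pure sagittal rearfoot rotation rotates the calcaneus cluster", {
  zero <- lapply(angle_waveforms()$params, function(j) {
    lapply(j, function(x) harmonic_channel())
  })
  zero$rearfoot$sagittal <- list(offset = 10, amp = numeric(0),
                                 phase = numeric(0))  # constant 10 deg
  wf <- angle_waveforms(zero)
  tr <- markers_from_waveforms(wf, noise_sd = 0)
  model <- foot_model()
  R <- cardan_compose(10, 0, 0)
  org <- model$segments$calcaneus$origin
  expect_ref <- t(org + R %*% t(sweep(model$segments$calcaneus$markers, 2,
                                      org)))
  got <- footkin:::frame_matrix(tr, 5)[
    rownames(model$segments$calcaneus$markers), ]
  expect_equal(unname(got), unname(expect_ref), tolerance = 1e-10)
})

test_that("seeded marker synthesis is bit-reproducible", {
  wf <- demo_waveforms()
  a <- markers_from_waveforms(wf, noise_sd = 0.5, seed = 123)
  b <- markers_from_waveforms(wf, noise_sd = 0.5, seed = 123)
  c <- markers_from_waveforms(wf, noise_sd = 0.5, seed = 124)
  expect_identical(a$markers, b$markers)
  expect_false(identical(a$markers, c$markers))
})

test_that("force trace is zero outside stance and supra-threshold within", {
  fr <- synthetic_force(cycle_duration = 1.1, stance_fraction = 0.62,
                        noise_sd = 2)
  t <- fr$sample / 1500
  stance <- t / 1.1 < 0.62
  expect_true(all(fr$fz[!stance] == 0))
  expect_gt(mean(fr$fz[stance] > 20), 0.95)
  expect_true(all(fr$fz >= 0))
})

test_that("collinear clusters are rejected at generation", {
  model <- foot_model()
  model$segments$midfoot$markers <- cbind(1:3, 2 * (1:3), 3 * (1:3))
  rownames(model$segments$midfoot$markers) <- paste0("midfoot_", 1:3)
  expect_error(markers_from_waveforms(demo_waveforms(), model = model,
                                      noise_sd = 0),
               class = "footkin_geometry_error")
})

test_that("STN standing trial holds the configured frontal rearfoot angle", {
  stn <- standing_trial(kind = "stn_standing", rearfoot_frontal = 6.5,
                        noise_sd = 0)
  st <- standing_trial(noise_sd = 0)
  cal <- calibrate_segments(st)
  ser <- compute_joint_angles(stn, cal)
  expect_equal(mean(ser$curves$rearfoot$frontal), 6.5, tolerance = 1e-6)
})
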