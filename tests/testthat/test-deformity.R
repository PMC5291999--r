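test_that("worked static records classify deterministically", {
  equin <- classify_deformities(static_assessment(
    ncsp = 0, ankle_dorsiflexion = 4.8, mpj_dorsiflexion = 70))
  expect_true(equin$ankle_equinus)
  expect_equal(equin$ankle_dorsiflexion_deg, 4.8)

  varus <- classify_deformities(static_assessment(
    ncsp = 9.2, ankle_dorsiflexion = 12, mpj_dorsiflexion = 70))
  expect_true(varus$rearfoot_varus)
  expect_equal(varus$rearfoot_varus_deg, 9.2)

  clean <- classify_deformities(static_assessment(
    ncsp = 0, ankle_dorsiflexion = 11.9, mpj_dorsiflexion = 70,
    first_ray = "normal", forefoot = "normal"))
  expect_equal(clean$count, 0L)
  expect_false(clean$rearfoot_varus)  # exactly vertical calcaneus: no varus
  # repeated classification is byte-identical
  expect_identical(clean, classify_deformities(static_assessment(
    ncsp = 0, ankle_dorsiflexion = 11.9, mpj_dorsiflexion = 70)))
})

test_that("threshold values classify as normal (strict inequalities)", {
  s <- static_assessment(ncsp = 0, ankle_dorsiflexion = 10,
                         mpj_dorsiflexion = 65)
  p <- classify_deformities(s)
  expect_false(p$ankle_equinus)
  expect_false(p$hallux_limitation)
  expect_equal(p$count, 0L)
})

test_that("classification is threshold-monotone", {
  set.seed(80)
  for (i in 1:50) {
    s <- static_assessment(ncsp = runif(1, -5, 15),
                           ankle_dorsiflexion = runif(1, 0, 20),
                           mpj_dorsiflexion = runif(1, 40, 90))
    lo <- classify_deformities(s, deformity_thresholds(equinus = 8))
    hi <- classify_deformities(s, deformity_thresholds(equinus = 12))
    # raising the threshold never converts present -> absent
    expect_true(!lo$ankle_equinus || hi$ankle_equinus)
  }
})

test_that("deformity count equals the sum of indicators on random profiles", {
  set.seed(81)
  for (i in 1:50) {
    s <- static_assessment(
      ncsp = runif(1, -5, 15), ankle_dorsiflexion = runif(1, 0, 20),
      mpj_dorsiflexion = runif(1, 40, 90),
      first_ray = sample(c("plantarflexed", "normal", "dorsiflexed"), 1),
      forefoot = sample(c("varus", "normal", "valgus"), 1))
    p <- classify_deformities(s)
    expect_equal(p$count,
                 sum(p$rearfoot_varus, p$ankle_equinus, p$hallux_limitation,
                     p$first_ray != "normal", p$forefoot != "normal"))
    expect_true(p$count >= 0 && p$count <= 5)
  }
})

test_that("STN pass-through handles the elementary cases", {
  r1 <- stn_passthrough(2, rep(2, 101))
  expect_true(r1$passed)
  expect_equal(r1$crossing_pct, 0)

  r2 <- stn_passthrough(5, seq(0, 10, length.out = 101))
  expect_true(r2$passed)
  expect_equal(r2$crossing_pct, 50)

  r3 <- stn_passthrough(10, 4 * sin(2 * pi * seq(0, 1, length.out = 101)))
  expect_false(r3$passed)
  expect_equal(r3$min_diff, 6, tolerance = 1e-9)
  expect_true(is.na(r3$crossing_pct))
})

test_that("exactly one of crossing time and minimum difference is populated", {
  set.seed(82)
  for (i in 1:50) {
    curve <- raw_harmonic(seq(0, 1, length.out = 101),
                          runif(3, -4, 4), runif(3), runif(1, -2, 2))
    r <- stn_passthrough(runif(1, -8, 8), curve)
    expect_true(xor(is.na(r$crossing_pct), is.na(r$min_diff)))
    expect_true(r$closest_pct >= 0 && r$closest_pct <= 100)
  }
})

test_that("pass-through decisions agree with a brute-force dense scan", {
  set.seed(83)
  pct <- seq(0, 100, length.out = 101)
  dense_u <- seq(0, 100, length.out = 100001)
  for (i in 1:1000) {
    amp <- runif(3, -4, 4); ph <- runif(3); off <- runif(1, -2, 2)
    neutral <- runif(1, -6, 6)
    curve <- raw_harmonic(seq(0, 1, length.out = 101), amp, ph, off)
    r <- stn_passthrough(neutral, curve)
    # brute force: scan a dense linear interpolation of the same curve
    d <- stats::approx(pct, curve - neutral, xout = dense_u)$y
    brute_pass <- min(d) <= 1e-9 && max(d) >= -1e-9
    expect_identical(r$passed, brute_pass)
    if (brute_pass) {
      first <- dense_u[which(abs(d) <= 1e-9 | c(diff(sign(d)) != 0, FALSE))[1]]
      expect_lt(abs(r$crossing_pct - first), 0.01)
    } else {
      expect_lt(abs(r$min_diff - min(abs(d))), 1e-9)
      expect_lt(abs(r$closest_pct - dense_u[which.min(abs(d))]), 0.01)
    }
  }
})

test_that("cohort STN summaries pool passers and non-passers", {
  all_pass <- lapply(1:5, function(i) stn_passthrough(0, rep(0, 101)))
  s <- cohort_stn_summary(all_pass)
  expect_equal(s$pct_passed, 100)

  res <- c(lapply(1:39, function(i) {
    stn_passthrough(5, seq(0, 10, length.out = 101))     # crosses at 50%
  }), lapply(1:61, function(i) {
    stn_passthrough(10, 4 + raw_harmonic(seq(0, 1, length.out = 101),
                                         1, 0.6))        # closest at 60%
  }))
  s2 <- cohort_stn_summary(res)
  expect_equal(s2$pct_passed, 39)
  expect_equal(s2$n, 100)
  expect_equal(s2$mean_pct, 0.39 * 50 + 0.61 * 60, tolerance = 0.01)
  expect_true(s2$ci[1] <= s2$mean_pct && s2$mean_pct <= s2$ci[2])
  expect_error(cohort_stn_summary(list()), class = "footkin_contract_error")
})

test_that("unnormalized curves are a contract error", {
  expect_error(stn_passthrough(1, c(1, 2, 3)),
               class = "footkin_contract_error")
})
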