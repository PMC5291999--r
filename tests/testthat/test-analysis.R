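test_that("the full grid runs every cell on a balanced cohort", {
  coh <- generate_cohort(null_cohort_config(n = 100, seed = 120))
  rep <- run_full_analysis(cohort_true_variables(coh), cohort_statics(coh))
  expect_length(rep$comparisons, 9L)
  expect_length(rep$correlations, 6L)
  expect_true(all(vapply(rep$comparisons, function(cp) {
    !inherits(cp, "skipped_comparison") && isTRUE(cp$tested)
  }, logical(1))))
  expect_equal(rep$n, 100L)
  expect_equal(sum(rep$deformity_counts), 100)
})

test_that("tiny comparator groups are flagged skips, never silent drops", {
  coh <- generate_cohort(cohort_config(n = 60, markers = FALSE, seed = 121))
  rep <- run_full_analysis(cohort_true_variables(coh), cohort_statics(coh))
  expect_length(rep$comparisons, 9L)
  varus_cell <- rep$comparisons[[1]]
  expect_s3_class(varus_cell, "skipped_comparison")
  expect_match(varus_cell$note, "insufficient comparator group")
  tabs <- report_tables(rep)
  expect_equal(nrow(tabs$comparisons), 9L)
  expect_true("skipped" %in% tabs$comparisons$test)
})

test_that("a cohort of two produces summaries with all tests flagged", {
  coh <- generate_cohort(cohort_config(n = 2, markers = FALSE, seed = 122))
  rep <- run_full_analysis(cohort_true_variables(coh), cohort_statics(coh))
  expect_true(all(vapply(rep$comparisons, function(cp) {
    inherits(cp, "skipped_comparison") || !isTRUE(cp$tested)
  }, logical(1))))
  expect_equal(nrow(rep$cohort_summary), 9L)
  expect_true(all(is.finite(rep$cohort_summary$mean)))
})

test_that("an injected equinus effect is detected with high power", {
  eff <- 0 * default_group_effects()
  eff["equinus_peak_dorsiflexion"] <- -5
  hits <- 0L
  for (k in 1:25) {
    cfg <- cohort_config(n = 100, rho = 0,
                         prevalence = c(rearfoot_varus = 0.5,
                                        ankle_equinus = 0.5,
                                        hallux_limitation = 0.5),
                         first_ray_probs = c(plantarflexed = 1, normal = 1,
                                             dorsiflexed = 1) / 3,
                         forefoot_probs = c(varus = 1, normal = 1,
                                            valgus = 1) / 3,
                         group_effects = eff, markers = FALSE,
                         seed = 3000 + k)
    coh <- generate_cohort(cfg)
    rep <- run_full_analysis(cohort_true_variables(coh),
                             cohort_statics(coh))
    cell <- rep$comparisons[[2]]  # equinus / peak dorsiflexion mid-stance
    expect_identical(cell$grouping, "ankle_equinus")
    if (isTRUE(cell$significant)) hits <- hits + 1L
  }
  expect_gt(hits / 25, 0.8)
})

test_that("report JSON and CSV outputs are written", {
  coh <- generate_cohort(null_cohort_config(n = 30, seed = 123))
  rep <- run_full_analysis(cohort_true_variables(coh), cohort_statics(coh))
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "report.json")
  write_report_json(rep, jp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$n, 30)
  expect_equal(nrow(back$comparisons), 9)
  paths <- write_report_csv(rep, dir)
  expect_true(all(file.exists(paths)))
})
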