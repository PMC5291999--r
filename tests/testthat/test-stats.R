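test_that("the normality gate passes normal and rejects bimodal samples", {
  set.seed(90)
  g1 <- normality_gate(rnorm(1000))
  expect_true(g1$parametric)
  mix <- c(rnorm(500, -6, 0.3), rnorm(500, 6, 0.3))
  g2 <- normality_gate(mix)
  expect_false(g2$parametric)
  expect_warning(g3 <- normality_gate(c(1, 2, 3)),
                 class = "footkin_gate_warning")
  expect_false(g3$parametric)
  g4 <- normality_gate(rep(2, 50))
  expect_false(g4$parametric)
  expect_identical(g4$reason, "zero variance")
})

test_that("identical groups give null results", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.8, 3.9, 1.7)
  r <- compare_two_groups(x, x)
  expect_gt(r$p, 0.95)
  expect_equal(r$groups$mean[1], r$groups$mean[2])
  r3 <- compare_three_groups(list(a = x, b = x, c = x))
  expect_gt(r3$p, 0.95)
})

test_that("the t branch matches the textbook pooled-variance formula", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(6, 7, 8, 9, 10)
  gate <- list(structure(list(parametric = TRUE), class = "normality_gate"),
               structure(list(parametric = TRUE), class = "normality_gate"))
  r <- compare_two_groups(a, b, gate = gate)
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_identical(r$test, "t")
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
})

test_that("the ANOVA branch matches the between/within mean-square ratio", {
  set.seed(91)
  g <- list(a = rnorm(12, 0), b = rnorm(12, 2), c = rnorm(12, 0))
  r <- compare_three_groups(g)
  if (r$parametric) {
    y <- unlist(g)
    gm <- mean(y)
    ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, 1))
    ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
    f_hand <- (ssb / 2) / (ssw / (length(y) - 3))
    expect_equal(r$statistic, f_hand, tolerance = 1e-10)
  }
  expect_identical(r$test, "anova_lsd")
  expect_true(!is.null(r$posthoc))
  expect_equal(nrow(r$posthoc), 3L)
})

test_that("the Kruskal-Wallis branch matches the rank formula", {
  g <- list(a = c(1.1, 5.2, 7.3, 11.4), b = c(2.5, 6.6, 9.7, 12.8),
            c = c(3.9, 4.1, 8.2, 10.3))
  gate <- lapply(1:3, function(i) {
    structure(list(parametric = FALSE), class = "normality_gate")
  })
  r <- compare_three_groups(g, gate = gate)
  y <- unlist(g)
  rk <- rank(y)
  n <- length(y)
  ri <- split(rk, rep(names(g), lengths(g)))
  h_hand <- 12 / (n * (n + 1)) *
    sum(vapply(ri, function(v) sum(v)^2 / length(v), 1)) - 3 * (n + 1)
  expect_identical(r$test, "kruskal_wallis_mw_bonferroni")
  expect_equal(r$statistic, h_hand, tolerance = 1e-10)
})

test_that("Bonferroni post-hoc never flags a pair with raw p >= alpha/3", {
  set.seed(92)
  for (i in 1:30) {
    g <- list(a = rexp(8), b = rexp(8) + runif(1, 0, 3), c = rexp(8))
    gate <- lapply(1:3, function(i) {
      structure(list(parametric = FALSE), class = "normality_gate")
    })
    r <- compare_three_groups(g, gate = gate)
    if (!is.null(r$posthoc)) {
      expect_true(all(r$posthoc$p_raw[r$posthoc$significant] < 0.05 / 3))
      expect_true(all(r$posthoc$p_adj >= r$posthoc$p_raw))
    }
  }
})

test_that("confidence intervals contain the sample mean and shrink with n", {
  set.seed(93)
  x <- rnorm(40, 5, 2)
  ci <- ci_mean(x)
  expect_true(ci[1] < mean(x) && mean(x) < ci[2])
  wide <- diff(ci_mean(x[1:10]))
  narrow <- diff(ci_mean(rep(x, 10)))
  expect_lt(narrow, wide)
})

test_that("small groups yield flagged untested results", {
  r <- compare_two_groups(c(1), c(2, 3, 4))
  expect_false(r$tested)
  expect_identical(r$test, "none")
  r3 <- compare_three_groups(list(a = 1, b = c(2, 3), c = c(4, 5)))
  expect_false(r3$tested)
})

test_that("correlations handle exact linearity and degenerate input", {
  x <- c(1, 2.5, 3, 4.2, 5, 6.1, 7, 8.3, 9, 10)
  r1 <- correlate(x, 2 * x + 1)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  r2 <- correlate(x, -x)
  expect_equal(r2$r, -1, tolerance = 1e-12)
  expect_error(correlate(x, rep(2, 10)),
               class = "footkin_undefined_correlation_error")
  expect_error(correlate(c(1, 2), c(3, 4)),
               class = "footkin_contract_error")
})

test_that("the gate routes correlations to Spearman for non-normal data", {
  set.seed(94)
  x <- rexp(60)^3
  y <- x + rexp(60)^3
  r <- correlate(x, y)
  expect_identical(r$method, "spearman")
  g <- list(structure(list(parametric = TRUE), class = "normality_gate"),
            structure(list(parametric = TRUE), class = "normality_gate"))
  r2 <- correlate(x, y, gate = g)
  expect_identical(r2$method, "pearson")
})
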