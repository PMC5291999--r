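#' t-based confidence interval of a mean
#'
#' @param x numeric sample.
#' @param level confidence level.
#' @return `c(lower, upper)`; `NA` when n < 2.
#' @export
ci_mean <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(c(NA_real_, NA_real_))
  se <- stats::sd(x) / sqrt(n)
  q <- stats::qt(1 - (1 - level) / 2, df = n - 1L)
  mean(x) + c(-1, 1) * q * se
}

#' Normality gate for test selection
#'
#' One-sample Kolmogorov-Smirnov test of the sample against a normal
#' distribution with the sample's mean and standard deviation (the
#' parameter-estimation caveat of this variant is noted in the result).
#' The sample is called parametric when p >= `alpha`. Samples with n < 5
#' or zero variance force the nonparametric branch with a classed warning.
#'
#' @param x numeric sample.
#' @param alpha gate level.
#' @return object of class `normality_gate`: list `parametric`,
#'   `statistic`, `p`, `n`, `reason`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 5L) {
    fk_warn("n < 5: forcing nonparametric branch", "footkin_gate_warning")
    return(structure(list(parametric = FALSE, statistic = NA_real_,
                          p = NA_real_, n = n, reason = "n < 5"),
                     class = "normality_gate"))
  }
  s <- stats::sd(x)
  if (s == 0) {
    return(structure(list(parametric = FALSE, statistic = NA_real_,
                          p = NA_real_, n = n, reason = "zero variance"),
                     class = "normality_gate"))
  }
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), s))
  structure(list(parametric = kt$p.value >= alpha,
                 statistic = unname(kt$statistic), p = kt$p.value, n = n,
                 reason = "KS vs fitted normal"),
            class = "normality_gate")
}

group_descriptives <- function(values, labels) {
  data.frame(group = labels,
             n = vapply(values, function(v) sum(is.finite(v)), 1L),
             mean = vapply(values, function(v) mean(v[is.finite(v)]), 1),
             median = vapply(values, function(v) stats::median(v[is.finite(v)]), 1),
             ci_lower = vapply(values, function(v) ci_mean(v)[1], 1),
             ci_upper = vapply(values, function(v) ci_mean(v)[2], 1),
             stringsAsFactors = FALSE)
}

#' Two-group comparison with normality-gated test choice
#'
#' Independent two-sample pooled-variance t-test when both groups pass the
#' normality gate, otherwise a Mann-Whitney (Wilcoxon rank-sum) test.
#' Group means with t-based 95% CIs are always reported. Groups with n < 2
#' yield a descriptive-only result flagged as untested.
#'
#' @param a,b numeric samples of the two groups.
#' @param labels character labels of the groups.
#' @param variable name of the compared variable.
#' @param alpha significance level.
#' @param gate optional list of two [normality_gate()] results; computed
#'   from the data when `NULL`.
#' @return object of class `comparison_result`.
#' @export
compare_two_groups <- function(a, b, labels = c("a", "b"), variable = "",
                               alpha = 0.05, gate = NULL) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  desc <- group_descriptives(list(a, b), labels)
  if (length(a) < 2L || length(b) < 2L) {
    return(structure(list(variable = variable, groups = desc,
                          test = "none", statistic = NA_real_, p = NA_real_,
                          tested = FALSE, reason = "group with n < 2",
                          parametric = NA), class = "comparison_result"))
  }
  if (is.null(gate)) gate <- list(normality_gate(a), normality_gate(b))
  parametric <- gate[[1]]$parametric && gate[[2]]$parametric
  if (parametric) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    test <- "t"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    tt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    test <- "mann_whitney"; statistic <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(variable = variable, groups = desc, test = test,
                 statistic = statistic, p = p, tested = TRUE,
                 parametric = parametric, gate = gate, alpha = alpha,
                 significant = p < alpha),
            class = "comparison_result")
}

#' Three-group comparison with gated omnibus and post-hoc tests
#'
#' One-way ANOVA with Least Significant Difference post-hoc (pairwise t
#' with the pooled within-group mean square, uncorrected — that is the
#' definition of LSD) when every group passes the normality gate;
#' otherwise Kruskal-Wallis with pairwise Mann-Whitney tests at the
#' Bonferroni-corrected level `alpha / 3`. Post-hoc tests run only when
#' the omnibus is significant. Any group with n < 2 skips the omnibus.
#'
#' @param groups named list of three numeric samples.
#' @param variable name of the compared variable.
#' @param alpha significance level.
#' @param gate optional list of three [normality_gate()] results.
#' @return object of class `comparison_result` with a `posthoc`
#'   data.frame (`pair`, `p_raw`, `p_adj`, `significant`).
#' @export
compare_three_groups <- function(groups, variable = "", alpha = 0.05,
                                 gate = NULL) {
  stopifnot(length(groups) == 3L)
  labels <- names(groups) %||% paste0("g", 1:3)
  groups <- lapply(groups, function(v) v[is.finite(v)])
  desc <- group_descriptives(groups, labels)
  if (any(vapply(groups, length, 1L) < 2L)) {
    return(structure(list(variable = variable, groups = desc,
                          test = "none", statistic = NA_real_, p = NA_real_,
                          tested = FALSE, reason = "group with n < 2",
                          parametric = NA, posthoc = NULL),
                     class = "comparison_result"))
  }
  if (is.null(gate)) gate <- lapply(groups, normality_gate)
  parametric <- all(vapply(gate, function(g) g$parametric, logical(1)))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, vapply(groups, length, 1L)), levels = labels)
  pairs <- utils::combn(labels, 2)
  if (parametric) {
    fit <- stats::aov(y ~ g)
    an <- summary(fit)[[1]]
    statistic <- an[["F value"]][1]
    p <- an[["Pr(>F)"]][1]
    test <- "anova_lsd"
    posthoc <- NULL
    if (p < alpha) {
      mse <- an[["Mean Sq"]][2]
      dfe <- an[["Df"]][2]
      pr <- apply(pairs, 2, function(pp) {
        ni <- length(groups[[pp[1]]]); nj <- length(groups[[pp[2]]])
        tstat <- (mean(groups[[pp[1]]]) - mean(groups[[pp[2]]])) /
          sqrt(mse * (1 / ni + 1 / nj))
        2 * stats::pt(-abs(tstat), dfe)
      })
      posthoc <- data.frame(pair = apply(pairs, 2, paste, collapse = " vs "),
                            p_raw = pr, p_adj = pr,
                            significant = pr < alpha,
                            stringsAsFactors = FALSE)
    }
  } else {
    kt <- stats::kruskal.test(y, g)
    statistic <- unname(kt$statistic)
    p <- kt$p.value
    test <- "kruskal_wallis_mw_bonferroni"
    posthoc <- NULL
    if (p < alpha) {
      pr <- apply(pairs, 2, function(pp) {
        suppressWarnings(stats::wilcox.test(groups[[pp[1]]],
                                            groups[[pp[2]]],
                                            exact = FALSE))$p.value
      })
      posthoc <- data.frame(pair = apply(pairs, 2, paste, collapse = " vs "),
                            p_raw = pr, p_adj = pmin(1, 3 * pr),
                            significant = pr < alpha / 3,
                            stringsAsFactors = FALSE)
    }
  }
  structure(list(variable = variable, groups = desc, test = test,
                 statistic = statistic, p = p, tested = TRUE,
                 parametric = parametric, gate = gate, alpha = alpha,
                 significant = p < alpha, posthoc = posthoc),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> ", x$variable, ": ", sep = "")
  if (!isTRUE(x$tested)) {
    cat("not tested (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("%s, statistic %.3f, p = %.4g%s\n", x$test, x$statistic,
                x$p, if (isTRUE(x$significant)) " *" else ""))
  }
  print(x$groups, row.names = FALSE)
  if (!is.null(x$posthoc)) print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' Normality-gated correlation
#'
#' Pearson correlation when both variables pass the normality gate,
#' Spearman otherwise; two-sided p value.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @param pair character pair name `c(static, dynamic)`.
#' @param alpha gate and significance level.
#' @param gate optional list of two [normality_gate()] results.
#' @return object of class `correlation_result`: `pair`, `method`, `r`,
#'   `p`, `n`.
#' @export
correlate <- function(x, y, pair = c("x", "y"), alpha = 0.05, gate = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    fk_stop("need at least 3 complete pairs", "footkin_contract_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    fk_stop("correlation undefined for zero-variance input",
            "footkin_undefined_correlation_error")
  }
  if (is.null(gate)) gate <- list(normality_gate(x), normality_gate(y))
  parametric <- gate[[1]]$parametric && gate[[2]]$parametric
  method <- if (parametric) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  structure(list(pair = pair, method = method, r = unname(ct$estimate),
                 p = ct$p.value, n = length(x),
                 significant = ct$p.value < alpha),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s ~ %s: %s r = %.3f (p = %.4g, n = %d)%s\n",
              x$pair[1], x$pair[2], x$method, x$r, x$p, x$n,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}
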