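#' Analysis configuration
#'
#' @param alpha significance and gate level.
#' @param min_group_size smallest group size admitted to a comparison;
#'   smaller groups make the cell a flagged skip (never a silent drop).
#' @param thresholds deformity thresholds, see [deformity_thresholds()].
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, min_group_size = 5,
                            thresholds = deformity_thresholds()) {
  check_number(alpha, "alpha", min = 0, max = 1)
  check_number(min_group_size, "min_group_size", min = 2)
  structure(list(alpha = alpha, min_group_size = min_group_size,
                 thresholds = thresholds), class = "analysis_config")
}

skipped_cell <- function(variable, grouping, note, sizes = NULL) {
  structure(list(variable = variable, grouping = grouping, skipped = TRUE,
                 note = note, group_sizes = sizes),
            class = "skipped_comparison")
}

#' @export
print.skipped_comparison <- function(x, ...) {
  cat("<skipped_comparison> ", x$grouping, " / ", x$variable, ": ", x$note,
      "\n", sep = "")
  invisible(x)
}

two_group_cell <- function(df, flag, variable, grouping, labels, cfg) {
  a <- df[[variable]][df[[flag]]]
  b <- df[[variable]][!df[[flag]]]
  if (min(length(a), length(b)) < cfg$min_group_size) {
    return(skipped_cell(variable, grouping, "insufficient comparator group",
                        c(length(a), length(b))))
  }
  res <- compare_two_groups(a, b, labels = labels, variable = variable,
                            alpha = cfg$alpha)
  res$grouping <- grouping
  res
}

three_group_cell <- function(df, col, variable, grouping, levels, cfg) {
  groups <- lapply(levels, function(l) df[[variable]][df[[col]] == l])
  names(groups) <- levels
  if (any(vapply(groups, length, 1L) < cfg$min_group_size)) {
    return(skipped_cell(variable, grouping, "insufficient comparator group",
                        vapply(groups, length, 1L)))
  }
  res <- compare_three_groups(groups, variable = variable, alpha = cfg$alpha)
  res$grouping <- grouping
  res
}

#' Run the full static-vs-dynamic statistical battery
#'
#' Executes the standard comparison/correlation grid on a processed
#' cohort: ankle equinus vs none (peak rearfoot dorsiflexion and eversion
#' in mid-stance, sagittal angle at heel lift); limited vs free 1st MPJ
#' dorsiflexion (propulsion hallux dorsiflexion and rearfoot eversion);
#' three-group first-ray and forefoot comparisons; the rearfoot varus
#' comparison (reported as an explicit skip when the comparator group is
#' too small, as in cohorts where nearly every foot is varus); and the six
#' static-dynamic correlations (NCSP with mid-stance eversion; ankle range
#' with mid-stance dorsiflexion, eversion and sagittal range; 1st MPJ
#' range with propulsion hallux dorsiflexion and eversion). Every test is
#' normality-gated (Kolmogorov-Smirnov, per variable within group).
#'
#' @param variables data.frame of dynamic variables: `id` plus the six
#'   columns produced by [extract_variables()].
#' @param statics data.frame of static fields: `id`, `ncsp`,
#'   `ankle_dorsiflexion`, `mpj_dorsiflexion`, `first_ray`, `forefoot`
#'   (e.g. from [cohort_statics()]).
#' @param stn optional list of [stn_passthrough()] results.
#' @param config an [analysis_config()].
#' @return object of class `footkin_report` with elements `comparisons`,
#'   `correlations`, `cohort_summary`, `deformity_counts`,
#'   `deformity_prevalence`, `stn`, `n`.
#' @export
run_full_analysis <- function(variables, statics, stn = NULL,
                              config = analysis_config()) {
  if (!is.data.frame(variables) || !is.data.frame(statics) ||
      nrow(variables) < 2L) {
    fk_stop("need data.frames of >= 2 participants", "footkin_contract_error")
  }
  df <- merge(statics, variables, by = "id")
  thr <- config$thresholds
  df$rearfoot_varus <- df$ncsp > thr$varus
  df$ankle_equinus <- df$ankle_dorsiflexion < thr$equinus
  df$hallux_limitation <- df$mpj_dorsiflexion < thr$hallux
  df$deformity_count <- df$rearfoot_varus + df$ankle_equinus +
    df$hallux_limitation + (df$first_ray != "normal") +
    (df$forefoot != "normal")

  comparisons <- list(
    two_group_cell(df, "rearfoot_varus", "peak_eversion_midstance",
                   "rearfoot_varus", c("varus", "no varus"), config),
    two_group_cell(df, "ankle_equinus", "peak_dorsiflexion_midstance",
                   "ankle_equinus", c("equinus", "no equinus"), config),
    two_group_cell(df, "ankle_equinus", "peak_eversion_midstance",
                   "ankle_equinus", c("equinus", "no equinus"), config),
    two_group_cell(df, "ankle_equinus", "sagittal_angle_heel_lift",
                   "ankle_equinus", c("equinus", "no equinus"), config),
    two_group_cell(df, "hallux_limitation",
                   "peak_hallux_dorsiflexion_propulsion",
                   "hallux_limitation", c("<65 deg", ">=65 deg"), config),
    two_group_cell(df, "hallux_limitation", "peak_eversion_propulsion",
                   "hallux_limitation", c("<65 deg", ">=65 deg"), config),
    three_group_cell(df, "first_ray", "peak_eversion_midstance",
                     "first_ray", c("plantarflexed", "normal", "dorsiflexed"),
                     config),
    three_group_cell(df, "first_ray", "peak_hallux_dorsiflexion_propulsion",
                     "first_ray", c("plantarflexed", "normal", "dorsiflexed"),
                     config),
    three_group_cell(df, "forefoot", "peak_eversion_midstance",
                     "forefoot", c("varus", "normal", "valgus"), config)
  )

  cor_pairs <- list(
    c("ncsp", "peak_eversion_midstance"),
    c("ankle_dorsiflexion", "peak_dorsiflexion_midstance"),
    c("ankle_dorsiflexion", "peak_eversion_midstance"),
    c("ankle_dorsiflexion", "sagittal_range_midstance"),
    c("mpj_dorsiflexion", "peak_hallux_dorsiflexion_propulsion"),
    c("mpj_dorsiflexion", "peak_eversion_propulsion")
  )
  correlations <- lapply(cor_pairs, function(pr) {
    tryCatch(correlate(df[[pr[1]]], df[[pr[2]]], pair = pr,
                       alpha = config$alpha),
             footkin_undefined_correlation_error = function(e) {
               skipped_cell(pr[2], pr[1], conditionMessage(e))
             },
             footkin_contract_error = function(e) {
               skipped_cell(pr[2], pr[1], conditionMessage(e))
             })
  })

  sum_vars <- c("peak_eversion_midstance", "peak_dorsiflexion_midstance",
                "sagittal_angle_heel_lift", "sagittal_range_midstance",
                "peak_hallux_dorsiflexion_propulsion",
                "peak_eversion_propulsion", "ncsp", "ankle_dorsiflexion",
                "mpj_dorsiflexion")
  cohort_summary <- do.call(rbind, lapply(sum_vars, function(v) {
    ci <- ci_mean(df[[v]])
    data.frame(variable = v, n = sum(is.finite(df[[v]])),
               mean = mean(df[[v]], na.rm = TRUE),
               ci_lower = ci[1], ci_upper = ci[2], stringsAsFactors = FALSE)
  }))

  counts <- table(factor(df$deformity_count, levels = 0:5))
  prevalence <- c(
    rearfoot_varus = 100 * mean(df$rearfoot_varus),
    ankle_equinus = 100 * mean(df$ankle_equinus),
    hallux_limitation = 100 * mean(df$hallux_limitation),
    first_ray_plantarflexed = 100 * mean(df$first_ray == "plantarflexed"),
    first_ray_dorsiflexed = 100 * mean(df$first_ray == "dorsiflexed"),
    forefoot_varus = 100 * mean(df$forefoot == "varus"),
    forefoot_valgus = 100 * mean(df$forefoot == "valgus"))

  structure(list(comparisons = comparisons, correlations = correlations,
                 cohort_summary = cohort_summary,
                 deformity_counts = counts,
                 deformity_prevalence = prevalence,
                 stn = if (!is.null(stn)) cohort_stn_summary(stn),
                 n = nrow(df), config = config, data = df),
            class = "footkin_report")
}

#' @export
print.footkin_report <- function(x, ...) {
  cat("<footkin_report> n = ", x$n, "\n\nDeformity prevalence (%):\n",
      sep = "")
  print(round(x$deformity_prevalence, 1))
  cat("\nDeformity count distribution:\n")
  print(x$deformity_counts)
  cat("\nComparisons:\n")
  for (cp in x$comparisons) {
    if (inherits(cp, "skipped_comparison")) {
      cat(sprintf("  %s / %s: skipped (%s)\n", cp$grouping, cp$variable,
                  cp$note))
    } else {
      cat(sprintf("  %s / %s: %s p = %.3g%s\n", cp$grouping, cp$variable,
                  cp$test, cp$p, if (isTRUE(cp$significant)) " *" else ""))
    }
  }
  cat("\nCorrelations:\n")
  for (cr in x$correlations) {
    if (inherits(cr, "skipped_comparison")) {
      cat(sprintf("  %s ~ %s: skipped (%s)\n", cr$grouping, cr$variable,
                  cr$note))
    } else {
      cat(sprintf("  %s ~ %s: %s r = %.2f (p = %.3g)%s\n", cr$pair[1],
                  cr$pair[2], cr$method, cr$r, cr$p,
                  if (isTRUE(cr$significant)) " *" else ""))
    }
  }
  if (!is.null(x$stn)) {
    cat(sprintf("\nSTN: %.0f%% passed through neutral; passed/closest at %.1f%% (%.1f-%.1f) of cycle\n",
                x$stn$pct_passed, x$stn$mean_pct, x$stn$ci[1], x$stn$ci[2]))
  }
  invisible(x)
}

#' Flat tables of a report
#'
#' @param report a [run_full_analysis()] result.
#' @return list of data.frames: `comparisons`, `correlations`, `summary`,
#'   `counts`.
#' @export
report_tables <- function(report) {
  comp <- do.call(rbind, lapply(report$comparisons, function(cp) {
    if (inherits(cp, "skipped_comparison")) {
      data.frame(grouping = cp$grouping, variable = cp$variable,
                 test = "skipped", statistic = NA_real_, p = NA_real_,
                 significant = NA, note = cp$note, stringsAsFactors = FALSE)
    } else {
      data.frame(grouping = cp$grouping, variable = cp$variable,
                 test = cp$test, statistic = cp$statistic, p = cp$p,
                 significant = cp$significant, note = "",
                 stringsAsFactors = FALSE)
    }
  }))
  corr <- do.call(rbind, lapply(report$correlations, function(cr) {
    if (inherits(cr, "skipped_comparison")) {
      data.frame(static = cr$grouping, dynamic = cr$variable,
                 method = "skipped", r = NA_real_, p = NA_real_,
                 n = NA_integer_, stringsAsFactors = FALSE)
    } else {
      data.frame(static = cr$pair[1], dynamic = cr$pair[2],
                 method = cr$method, r = cr$r, p = cr$p, n = cr$n,
                 stringsAsFactors = FALSE)
    }
  }))
  counts <- data.frame(deformity_count = 0:5,
                       feet = as.integer(report$deformity_counts))
  list(comparisons = comp, correlations = corr,
       summary = report$cohort_summary, counts = counts)
}
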