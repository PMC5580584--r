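# The study's statistical stages on a cohort table: group and subgroup
# summaries with pooled totals, baseline ANOVA across age groups, former vs
# current baseline/follow-up comparison, per-age-bin paired t-tests in the
# former group, and Spearman age vs smoking duration. Optional ratings
# matrices yield the ICC reproducibility coefficients.

#' Run the full cohort analysis
#'
#' @param cohort a `cohort_table`.
#' @param alpha significance level (default 0.05, two-sided).
#' @param icc1_ratings optional n x k matrix of repeated GMR sessions by one
#'   examiner, for ICC(1,1).
#' @param icc2_ratings optional n x k matrix of GMR by different examiners,
#'   for ICC(2,1).
#' @return An object of class `gmr_study`: list with `group_summary`,
#'   `subgroup_summary`, `baseline_anova`, `status_comparison`,
#'   `paired_by_age` (former group), `spearman_age_duration`, `icc11`,
#'   `icc21`, `alpha`, `n`.
#' @export
run_study_analysis <- function(cohort, alpha = 0.05,
                               icc1_ratings = NULL, icc2_ratings = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- as.data.frame(cohort)
  df$age_group <- factor(df$age_group, levels = AGE_GROUP_LEVELS)
  df$smoking_status <- factor(df$smoking_status,
                              levels = c("former", "current"))

  msd <- function(v) c(mean = mean(v), sd = stats::sd(v))
  grp_row <- function(sub, label) {
    data.frame(group = label, n = nrow(sub),
               n_male = sum(sub$sex == "male"),
               n_female = sum(sub$sex == "female"),
               age_mean = mean(sub$age), age_sd = stats::sd(sub$age),
               smoking_duration_mean = mean(sub$smoking_duration),
               smoking_duration_sd = stats::sd(sub$smoking_duration),
               gmr_baseline_mean = mean(sub$gmr_baseline),
               gmr_baseline_sd = stats::sd(sub$gmr_baseline),
               followup_mean = mean(sub$followup_period),
               followup_sd = stats::sd(sub$followup_period),
               cessation_mean = if (all(is.na(sub$cessation_duration)))
                 NA_real_ else mean(sub$cessation_duration, na.rm = TRUE),
               cessation_sd = if (all(is.na(sub$cessation_duration)))
                 NA_real_ else stats::sd(sub$cessation_duration, na.rm = TRUE))
  }
  group_summary <- rbind(
    grp_row(df[df$smoking_status == "former", ], "former"),
    grp_row(df[df$smoking_status == "current", ], "current"),
    grp_row(df, "total"))

  # subgroup (status x age bin) summary; empty bins reported with n = 0
  subgroup_summary <- do.call(rbind, lapply(
    levels(df$smoking_status), function(st) {
      do.call(rbind, lapply(AGE_GROUP_LEVELS, function(ag) {
        sub <- df[df$smoking_status == st & df$age_group == ag, ]
        if (!nrow(sub)) {
          return(data.frame(status = st, age_group = ag, n = 0L,
                            n_male = 0L, n_female = 0L,
                            smoking_duration_mean = NA_real_,
                            followup_mean = NA_real_,
                            cessation_mean = NA_real_,
                            gmr_baseline_mean = NA_real_,
                            gmr_followup_mean = NA_real_,
                            gmr_change_mean = NA_real_))
        }
        data.frame(status = st, age_group = ag, n = nrow(sub),
                   n_male = sum(sub$sex == "male"),
                   n_female = sum(sub$sex == "female"),
                   smoking_duration_mean = mean(sub$smoking_duration),
                   followup_mean = mean(sub$followup_period),
                   cessation_mean = if (st == "former")
                     mean(sub$cessation_duration) else NA_real_,
                   gmr_baseline_mean = mean(sub$gmr_baseline),
                   gmr_followup_mean = mean(sub$gmr_followup),
                   gmr_change_mean = mean(sub$gmr_followup -
                                            sub$gmr_baseline))
      }))
    }))
  rownames(subgroup_summary) <- NULL

  # baseline GMR across age groups, all subjects pooled
  bl_groups <- split(df$gmr_baseline, df$age_group)
  bl_groups <- bl_groups[lengths(bl_groups) > 0]
  baseline_anova <- if (length(bl_groups) >= 2 &&
                        sum(lengths(bl_groups)) > length(bl_groups))
    one_way_anova(bl_groups) else NULL

  # former vs current, baseline and follow-up means per bin
  status_comparison <- subgroup_summary[
    , c("status", "age_group", "n", "gmr_baseline_mean",
        "gmr_followup_mean")]

  # per-age-bin paired t-tests in the former group
  paired_by_age <- do.call(rbind, lapply(AGE_GROUP_LEVELS, function(ag) {
    sub <- df[df$smoking_status == "former" & df$age_group == ag, ]
    if (nrow(sub) < 2) {
      return(data.frame(age_group = ag, n = nrow(sub),
                        mean_change = if (nrow(sub)) mean(sub$gmr_followup -
                                                            sub$gmr_baseline)
                        else NA_real_,
                        t = NA_real_, df = NA_real_, p_value = NA_real_,
                        significant = NA))
    }
    tt <- paired_t(sub$gmr_baseline, sub$gmr_followup)
    data.frame(age_group = ag, n = nrow(sub),
               mean_change = mean(sub$gmr_followup - sub$gmr_baseline),
               t = tt$value, df = tt$df, p_value = tt$p_value,
               significant = tt$p_value < alpha)
  }))

  spearman_age_duration <- spearman_rho(df$age, df$smoking_duration)

  structure(list(group_summary = group_summary,
                 subgroup_summary = subgroup_summary,
                 baseline_anova = baseline_anova,
                 status_comparison = status_comparison,
                 paired_by_age = paired_by_age,
                 spearman_age_duration = spearman_age_duration,
                 icc11 = if (!is.null(icc1_ratings))
                   icc(icc1_ratings, "one_way") else NULL,
                 icc21 = if (!is.null(icc2_ratings))
                   icc(icc2_ratings, "two_way") else NULL,
                 alpha = alpha, n = nrow(df)),
            class = "gmr_study")
}

#' @export
print.gmr_study <- function(x, ...) {
  g <- x$group_summary
  cat(sprintf("Cohort analysis of %d subjects (%d former / %d current)\n",
              x$n, g$n[g$group == "former"], g$n[g$group == "current"]))
  cat(sprintf("  baseline GMR: %.1f%% former, %.1f%% current, %.1f%% total\n",
              g$gmr_baseline_mean[1], g$gmr_baseline_mean[2],
              g$gmr_baseline_mean[3]))
  if (!is.null(x$baseline_anova)) {
    cat("  baseline GMR across age groups: ")
    print(x$baseline_anova)
  }
  cat("  age vs smoking duration: ")
  print(x$spearman_age_duration)
  if (!is.null(x$icc11)) { cat("  repeatability: "); print(x$icc11) }
  if (!is.null(x$icc21)) { cat("  between-examiner: "); print(x$icc21) }
  invisible(x)
}

#' @export
summary.gmr_study <- function(object, ...) {
  print(object)
  cat("\nPaired baseline vs follow-up change (former smokers) by age group:\n")
  print(object$paired_by_age, row.names = FALSE, digits = 3)
  invisible(object)
}

#' Plot the study's three standard figures
#'
#' Panel 1: mean baseline GMR by age group (all subjects). Panel 2: mean
#' baseline and follow-up GMR, former vs current smokers. Panel 3: mean GMR
#' change from baseline to follow-up per age group among former smokers.
#'
#' @param x a `gmr_study`.
#' @param which subset of 1:3.
#' @param ... ignored.
#' @export
plot.gmr_study <- function(x, which = 1:3, ...) {
  ss <- x$subgroup_summary
  if (1 %in% which) {
    bl <- stats::aggregate(
      cbind(w = n * gmr_baseline_mean, n = n) ~ age_group, data = ss,
      FUN = sum, na.action = stats::na.omit)
    graphics::barplot(bl$w / bl$n, names.arg = bl$age_group,
                      ylab = "mean baseline GMR (%)", xlab = "age group",
                      col = "grey70", main = "Baseline GMR by age group")
  }
  if (2 %in% which) {
    m <- rbind(
      baseline = tapply(x$status_comparison$gmr_baseline_mean *
                          x$status_comparison$n,
                        x$status_comparison$status, sum, na.rm = TRUE) /
        tapply(x$status_comparison$n, x$status_comparison$status, sum),
      followup = tapply(x$status_comparison$gmr_followup_mean *
                          x$status_comparison$n,
                        x$status_comparison$status, sum, na.rm = TRUE) /
        tapply(x$status_comparison$n, x$status_comparison$status, sum))
    graphics::barplot(m, beside = TRUE, ylab = "mean GMR (%)",
                      legend.text = rownames(m),
                      main = "Baseline vs follow-up by smoking status")
  }
  if (3 %in% which) {
    pa <- x$paired_by_age
    graphics::barplot(pa$mean_change, names.arg = pa$age_group,
                      ylab = "mean GMR change (%)", xlab = "age group",
                      col = ifelse(isTRUE(pa$significant) |
                                     pa$significant %in% TRUE,
                                   "grey40", "grey80"),
                      main = "GMR change under cessation by age group")
    graphics::abline(h = 0)
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' CSV summaries, a JSON file of test results, and PNG figures.
#'
#' @param study a `gmr_study`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_study_report <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, "group_summary.csv")
  f2 <- file.path(dir, "subgroup_summary.csv")
  f3 <- file.path(dir, "paired_by_age.csv")
  utils::write.csv(study$group_summary, f1, row.names = FALSE, na = "")
  utils::write.csv(study$subgroup_summary, f2, row.names = FALSE, na = "")
  utils::write.csv(study$paired_by_age, f3, row.names = FALSE, na = "")
  tst <- list(alpha = study$alpha,
              baseline_anova = unclass(study$baseline_anova),
              spearman_age_duration = unclass(study$spearman_age_duration),
              icc11 = if (!is.null(study$icc11)) unclass(study$icc11),
              icc21 = if (!is.null(study$icc21)) unclass(study$icc21))
  f4 <- file.path(dir, "test_results.json")
  writeLines(jsonlite::toJSON(tst, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), f4)
  figs <- character(0)
  for (i in 1:3) {
    fp <- file.path(dir, sprintf("figure_%d.png", i))
    grDevices::png(fp, width = 640, height = 480)
    try(plot(study, which = i), silent = TRUE)
    grDevices::dev.off()
    figs <- c(figs, fp)
  }
  invisible(c(f1, f2, f3, f4, figs))
}
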