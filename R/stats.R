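# Cohort statistics implemented from closed-form formulas (mean-squares and
# rank arithmetic); the corresponding base-R fitters serve as independent
# oracles in the test suite, never as the implementation.

AGE_GROUP_LEVELS <- c("19-29", "30-39", "40-49", "50-59", ">=60")

#' Classify smoking status
#'
#' Current smoker: more than 100 lifetime cigarettes and smoked in the
#' previous 30 days. Former smoker: more than 100 lifetime cigarettes but not
#' in the previous 30 days. Anything else is ineligible for the study design.
#'
#' @param lifetime_cigarettes numeric vector of lifetime cigarette counts.
#' @param smoked_last_30_days logical vector.
#' @return factor with levels current, former, ineligible.
#' @export
classify_smoking_status <- function(lifetime_cigarettes,
                                    smoked_last_30_days) {
  out <- ifelse(is.na(lifetime_cigarettes) | is.na(smoked_last_30_days),
                "ineligible",
         ifelse(lifetime_cigarettes > 100,
                ifelse(smoked_last_30_days, "current", "former"),
                "ineligible"))
  factor(out, levels = c("current", "former", "ineligible"))
}

#' Assign 10-year age groups
#'
#' Bins 19-29, 30-39, 40-49, 50-59 and >=60 (study range 19-79); ages below
#' 19 are outside the study range and raise an error.
#'
#' @param age numeric vector of ages in years.
#' @return factor with the five age-group levels.
#' @export
assign_age_group <- function(age) {
  if (any(is.na(age)) || any(age < 19))
    stop("age below study range (19)", call. = FALSE)
  cut(age, breaks = c(19, 30, 40, 50, 60, Inf), right = FALSE,
      labels = AGE_GROUP_LEVELS)
}

#' Pooled mean of group means
#'
#' Weighted mean `sum(mean_i n_i) / sum(n_i)`; reproduces a total column from
#' printed subgroup cells.
#'
#' @param means numeric vector of group means.
#' @param n numeric vector of group sizes (all >= 1).
#' @return The pooled mean.
#' @export
pooled_mean <- function(means, n) {
  if (!length(means)) stop("no groups", call. = FALSE)
  stopifnot(length(means) == length(n), all(n >= 1))
  sum(means * n) / sum(n)
}

gmr_test <- function(statistic, value, df, p_value = NA_real_,
                     degenerate = FALSE, estimate = NULL) {
  structure(list(statistic = statistic, value = value, df = df,
                 p_value = p_value, degenerate = degenerate,
                 estimate = estimate),
            class = "gmr_test")
}

#' @export
print.gmr_test <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s = %s (df %s)%s%s\n", x$statistic,
              format(x$value, digits = 4), dfs,
              if (!is.na(x$p_value))
                sprintf(", p = %s", format.pval(x$p_value, digits = 3))
              else "",
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' One-way fixed-effects analysis of variance
#'
#' `F = MS_between / MS_within` with degrees of freedom (g - 1, N - g) and
#' the upper-tail F p-value. With zero within-group variance the F statistic
#' is infinite and flagged degenerate.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   non-empty, total N > number of groups).
#' @return A `gmr_test` with statistic "F".
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, as.numeric)
  g <- length(groups)
  ns <- lengths(groups)
  if (g < 2 || any(ns < 1)) stop(">= 2 non-empty groups required",
                                 call. = FALSE)
  N <- sum(ns)
  if (N <= g) stop("total n must exceed the number of groups", call. = FALSE)
  grand <- sum(unlist(groups)) / N
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- g - 1L
  df2 <- N - g
  msb <- ssb / df1
  msw <- ssw / df2
  if (msw == 0) {
    return(gmr_test("F", if (msb == 0) 0 else Inf, c(df1, df2),
                    p_value = if (msb == 0) 1 else 0, degenerate = TRUE))
  }
  f <- msb / msw
  gmr_test("F", f, c(df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Paired t-test of follow-up against baseline
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = followup - baseline`,
#' df = n - 1, two-sided p from the t distribution. A zero-variance nonzero
#' difference is flagged degenerate (|t| infinite, p = 0).
#'
#' @param baseline,followup numeric vectors of equal length >= 2, paired by
#'   subject.
#' @return A `gmr_test` with statistic "t".
#' @export
paired_t <- function(baseline, followup) {
  stopifnot(length(baseline) == length(followup), length(baseline) >= 2)
  d <- as.numeric(followup) - as.numeric(baseline)
  n <- length(d)
  sdd <- stats::sd(d)
  md <- mean(d)
  if (sdd == 0) {
    if (md == 0) return(gmr_test("t", 0, n - 1L, p_value = 1))
    return(gmr_test("t", sign(md) * Inf, n - 1L, p_value = 0,
                    degenerate = TRUE))
  }
  t <- md / (sdd / sqrt(n))
  gmr_test("t", t, n - 1L, 2 * stats::pt(abs(t), n - 1L, lower.tail = FALSE),
           estimate = md)
}

#' Spearman rank correlation
#'
#' Mid-ranks for ties; rho is the Pearson correlation of the rank vectors;
#' the p-value uses the t approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom
#' (two-sided).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A `gmr_test` with statistic "rho".
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("Spearman rho undefined: zero rank variance", call. = FALSE)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  }
  gmr_test("rho", rho, n - 2L, p)
}

#' Exact permutation p-value for Spearman's rho
#'
#' Full enumeration of the permutation null (two-sided, by |rho|). Intended
#' as a small-sample oracle; practical only for n <= 8.
#'
#' @param x,y numeric vectors of equal length n (3 <= n <= 8).
#' @return The exact two-sided p-value.
#' @export
spearman_exact_p <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3, n <= 8)
  obs <- abs(spearman_rho(x, y)$value)
  perms <- permutations_of(seq_len(n))
  vals <- apply(perms, 1, function(p) abs(spearman_rho(x, y[p])$value))
  mean(vals >= obs - 1e-12)
}

#' @keywords internal
#' @noRd
permutations_of <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- permutations_of(v[-i])
    out[[i]] <- cbind(v[i], rest)
  }
  do.call(rbind, out)
}

#' Intraclass correlation coefficients ICC(1,1) and ICC(2,1)
#'
#' Single-rater coefficients from the classical mean-squares decompositions.
#' One-way (repeatability of one examiner across sessions):
#' `ICC(1,1) = (BMS - WMS) / (BMS + (k - 1) WMS)`. Two-way random effects
#' (stability between examiners):
#' `ICC(2,1) = (BMS - EMS) / (BMS + (k - 1) EMS + k (JMS - EMS) / n)`,
#' with BMS the between-target, WMS the within-target, JMS the
#' between-rater, and EMS the residual mean square.
#'
#' @param ratings complete numeric matrix, n targets (rows) x k raters or
#'   sessions (columns), n >= 2, k >= 2.
#' @param model `"one_way"` for ICC(1,1) or `"two_way"` for ICC(2,1).
#' @return A `gmr_test` with statistic "ICC11" or "ICC21" (no p-value).
#' @export
icc <- function(ratings, model = c("one_way", "two_way")) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2 || anyNA(ratings))
    stop("ratings must be a complete matrix with n >= 2 and k >= 2",
         call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  bms <- ss_rows / (n - 1)
  if (model == "one_way") {
    wms <- (ss_tot - ss_rows) / (n * (k - 1))
    if (bms == 0 && wms == 0)
      stop("ICC undefined for a constant ratings matrix", call. = FALSE)
    val <- (bms - wms) / (bms + (k - 1) * wms)
    return(gmr_test("ICC11", val, c(n - 1L, n * (k - 1L))))
  }
  jms <- ss_cols / (k - 1)
  ems <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  if (bms == 0 && jms == 0 && ems == 0)
    stop("ICC undefined for a constant ratings matrix", call. = FALSE)
  val <- (bms - ems) / (bms + (k - 1) * ems + k * (jms - ems) / n)
  gmr_test("ICC21", val, c(n - 1L, (n - 1L) * (k - 1L)))
}
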