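# Simulated longitudinal smoking-cessation cohorts with the cell structure
# of the reference study: two smoking-status groups x five 10-year age bins,
# baseline and follow-up GMR, and age-dependent fading of pigmentation after
# cessation. Defaults are the reference cohort's printed summary values.

REFERENCE_N_PER_CELL <- rbind(
  former  = c(13, 32, 29, 32, 27),
  current = c(17, 26, 32, 36, 15))
REFERENCE_MALE_PER_CELL <- rbind(
  former  = c(8, 23, 21, 16, 20),
  current = c(11, 18, 19, 23, 8))
AGE_BIN_LO <- c(19, 30, 40, 50, 60)
AGE_BIN_HI <- c(29, 39, 49, 59, 79)

#' Parameters of the cohort simulator
#'
#' Defaults reproduce the reference cohort's structure: 259 subjects in the
#' printed subgroup cells, baseline GMR with mean 26.7 and sd 19.8 (%),
#' smoking onset around age 18, and age-group-dependent fading of
#' pigmentation under cessation. `onset_age_sd` is calibrated so the
#' population Spearman correlation between age and smoking duration is
#' about 0.85 (see the methods vignette).
#'
#' @param n_per_cell 2 x 5 matrix of subject counts (rows former/current,
#'   columns the five age bins).
#' @param male_per_cell 2 x 5 matrix of male counts per cell (<= n_per_cell).
#' @param gmr_mean,gmr_sd baseline GMR moments in percent; the baseline draw
#'   is a truncated normal on \[0, 100\] whose location is solved so its mean
#'   equals `gmr_mean`.
#' @param onset_age_mean,onset_age_sd smoking onset age (years); default
#'   mean 18, sd 10.9 (calibrated).
#' @param fade_rate named vector, per-year multiplicative GMR reduction
#'   under cessation for each age group (in \[0, 1\], smallest for 19-29).
#' @param current_smoker_drift per-year multiplicative GMR change for
#'   continuing smokers (default -0.01, a slight decline).
#' @param followup_mean,followup_sd follow-up period (years) by status.
#' @param cessation_mean per-age-group mean cessation duration (years) for
#'   former smokers; `cessation_sd` its spread. Draws are truncated to
#'   \[0, follow-up\].
#' @param seed RNG seed (default 42).
#' @return A `cohort_gen_params` list.
#' @export
cohort_gen_params <- function(n_per_cell = REFERENCE_N_PER_CELL,
                              male_per_cell = REFERENCE_MALE_PER_CELL,
                              gmr_mean = 26.7, gmr_sd = 19.8,
                              onset_age_mean = 18, onset_age_sd = 10.9,
                              fade_rate = c("19-29" = 0.02, "30-39" = 0.07,
                                            "40-49" = 0.09, "50-59" = 0.11,
                                            ">=60" = 0.13),
                              current_smoker_drift = -0.01,
                              followup_mean = c(former = 4.50,
                                                current = 3.79),
                              followup_sd = c(former = 2.15,
                                              current = 1.17),
                              cessation_mean = c(2.62, 2.75, 3.31, 3.38,
                                                 3.67),
                              cessation_sd = 1.95,
                              seed = 42L) {
  n_per_cell <- as.matrix(n_per_cell)
  male_per_cell <- as.matrix(male_per_cell)
  if (!all(dim(n_per_cell) == c(2, 5)) || !all(dim(male_per_cell) == c(2, 5)))
    stop("n_per_cell and male_per_cell must be 2 x 5 matrices", call. = FALSE)
  if (any(n_per_cell < 0)) stop("negative cell count", call. = FALSE)
  if (any(male_per_cell > n_per_cell))
    stop("male count exceeds cell count", call. = FALSE)
  stopifnot(gmr_sd >= 0, onset_age_sd >= 0, cessation_sd >= 0,
            all(followup_sd >= 0),
            all(fade_rate >= 0), all(fade_rate <= 1),
            length(fade_rate) == 5, length(cessation_mean) == 5)
  rownames(n_per_cell) <- rownames(male_per_cell) <- c("former", "current")
  structure(list(n_per_cell = n_per_cell, male_per_cell = male_per_cell,
                 gmr_mean = gmr_mean, gmr_sd = gmr_sd,
                 onset_age_mean = onset_age_mean,
                 onset_age_sd = onset_age_sd,
                 fade_rate = stats::setNames(fade_rate, AGE_GROUP_LEVELS),
                 current_smoker_drift = current_smoker_drift,
                 followup_mean = followup_mean, followup_sd = followup_sd,
                 cessation_mean = cessation_mean,
                 cessation_sd = cessation_sd,
                 seed = seed),
            class = "cohort_gen_params")
}

#' Map a GMR percentage to a plausible subject-level Hedin grade
#'
#' Monotone thresholds used only to furnish simulated cohort tables with an
#' ordinal companion to GMR (0 iff GMR 0; then (0,10\], (10,25\], (25,50\],
#' >50). Photograph-level grading always uses [classify_hedin()].
#'
#' @param gmr numeric vector of GMR percentages.
#' @return integer vector of grades 0-4.
#' @export
gmr_to_hedin_grade <- function(gmr) {
  stopifnot(all(gmr >= 0), all(gmr <= 100))
  findInterval(gmr, c(-Inf, 1e-12, 10, 25, 50)) - 1L
}

#' Simulate a longitudinal smoking-cessation cohort
#'
#' Per cell: ages uniform on the bin (the open-ended bin uses 60-79);
#' smoking duration is `age - onset_age` truncated to \[0, age - 10\];
#' baseline GMR is a mean-matched truncated normal on \[0, 100\]; the
#' follow-up GMR of a former smoker is
#' `baseline (1 - fade_rate(age group))^cessation_years`, and of a current
#' smoker `baseline (1 + current_smoker_drift)^followup_years`, both clamped
#' to \[0, 100\]. Deterministic for a fixed seed.
#'
#' @param params a [cohort_gen_params()].
#' @return A `cohort_table` (see [cohort_table()]).
#' @export
simulate_cohort <- function(params = cohort_gen_params()) {
  stopifnot(inherits(params, "cohort_gen_params"))
  with_seed(params$seed, {
    mu_gmr <- truncnorm_matched_location(params$gmr_mean, params$gmr_sd,
                                         0, 100)
    rows <- list()
    sid <- 0L
    for (st in c("former", "current")) {
      for (b in 1:5) {
        n <- params$n_per_cell[st, b]
        if (n == 0) next
        age <- sample(AGE_BIN_LO[b]:AGE_BIN_HI[b], n, replace = TRUE)
        onset <- stats::rnorm(n, params$onset_age_mean, params$onset_age_sd)
        duration <- pmin(pmax(age - onset, 0), age - 10)
        gmr0 <- rtruncnorm(n, mu_gmr, params$gmr_sd, 0, 100)
        fup <- rtruncnorm(n, params$followup_mean[st],
                          params$followup_sd[st], 0.1, Inf)
        if (st == "former") {
          cess <- rtruncnorm(n, params$cessation_mean[b],
                             params$cessation_sd, 0, Inf)
          cess <- pmin(cess, fup)
          gmr1 <- gmr0 * (1 - params$fade_rate[b])^cess
        } else {
          cess <- rep(NA_real_, n)
          gmr1 <- gmr0 * (1 + params$current_smoker_drift)^fup
        }
        gmr1 <- pmin(pmax(gmr1, 0), 100)
        nm <- params$male_per_cell[st, b]
        sex <- c(rep("male", nm), rep("female", n - nm))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("S%03d", sid + seq_len(n)),
          age = as.integer(age),
          sex = sex,
          lifetime_cigarettes = pmax(101, round(duration * 365 * 10)),
          smoked_last_30_days = st == "current",
          smoking_duration = duration,
          cessation_duration = cess,
          followup_period = fup,
          gmr_baseline = gmr0,
          gmr_followup = gmr1,
          hedin_baseline = gmr_to_hedin_grade(gmr0),
          hedin_followup = gmr_to_hedin_grade(gmr1))
        sid <- sid + n
      }
    }
    cohort_table(do.call(rbind, rows))
  })
}

#' Hedin grade of a ground-truth site table
#'
#' Definitional alias of [classify_hedin()] so that generator truth and
#' pipeline scoring share a single grade definition.
#'
#' @param truth a ground-truth [site_call_table()].
#' @param grid the matching `site_grid`.
#' @return Integer grade 0-4.
#' @export
hedin_truth_from_sites <- function(truth, grid) {
  classify_hedin(truth, grid)
}
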