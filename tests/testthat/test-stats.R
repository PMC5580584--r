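test_that("smoking status follows the 100-cigarette / 30-day definitions", {
  expect_equal(as.character(classify_smoking_status(120, TRUE)), "current")
  expect_equal(as.character(classify_smoking_status(120, FALSE)), "former")
  expect_equal(as.character(classify_smoking_status(50, FALSE)), "ineligible")
  expect_equal(as.character(classify_smoking_status(100, TRUE)), "ineligible")
  expect_equal(as.character(classify_smoking_status(c(200, 80), c(TRUE, TRUE))),
               c("current", "ineligible"))
})

test_that("age groups use the study's 10-year bins", {
  expect_equal(as.character(assign_age_group(c(19, 29, 30, 45, 59, 60, 79))),
               c("19-29", "19-29", "30-39", "40-49", "50-59", ">=60", ">=60"))
  expect_error(assign_age_group(18), "below study range")
})

test_that("pooled means reproduce printed totals from subgroup cells", {
  expect_equal(round(pooled_mean(c(26.0, 27.5), c(133, 126)), 1), 26.7)
  expect_equal(round(pooled_mean(c(4.50, 3.79), c(133, 126)), 2), 4.15)
  expect_equal(pooled_mean(c(5, 5), c(7, 993)), 5)
  expect_error(pooled_mean(numeric(0), numeric(0)), "no groups")
})

test_that("one-way ANOVA matches hand computation and the lm oracle", {
  a <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(a$value, 3.0)        # SSB = 6, SSW = 6, df (2, 6)
  expect_equal(a$df, c(2, 6))
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$value, 0)
  set.seed(8)
  for (i in 1:10) {
    g <- lapply(seq_len(sample(3:5, 1)),
                function(j) stats::rnorm(sample(4:9, 1), j / 2))
    mine <- one_way_anova(g)
    df <- data.frame(y = unlist(g),
                     grp = factor(rep(seq_along(g), lengths(g))))
    orc <- stats::anova(stats::lm(y ~ grp, df))
    expect_equal(mine$value, orc$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p_value, orc$`Pr(>F)`[1], tolerance = 1e-10)
  }
  # two groups: F is the square of the pooled-variance t statistic
  x <- stats::rnorm(9); y <- stats::rnorm(11, 0.5)
  f2 <- one_way_anova(list(x, y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(f2$value, unname(tt$statistic)^2, tolerance = 1e-10)
  # degenerate within-variance
  dg <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_true(dg$degenerate)
  expect_equal(dg$value, Inf)
  expect_equal(dg$p_value, 0)
})

test_that("paired t matches hand computation, the t.test oracle, and symmetry", {
  r <- paired_t(c(0, 0, 0), c(1, 2, 3))       # d = (1,2,3)
  expect_equal(r$value, 2 / (1 / sqrt(3)))
  expect_equal(round(r$value, 3), 3.464)
  expect_equal(r$df, 2L)
  same <- paired_t(c(3, 1, 4), c(3, 1, 4))
  expect_equal(same$value, 0)
  expect_equal(same$p_value, 1)
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    b <- stats::rnorm(n); f <- b + stats::rnorm(n, 0.3)
    mine <- paired_t(b, f)
    orc <- stats::t.test(f, b, paired = TRUE)
    expect_equal(mine$value, unname(orc$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, orc$p.value, tolerance = 1e-10)
    neg <- paired_t(f, b)
    expect_equal(neg$value, -mine$value)
    expect_equal(neg$p_value, mine$p_value)
  }
  dg <- paired_t(c(1, 2, 3), c(2, 3, 4))      # constant nonzero difference
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 0)
})

test_that("Spearman rho uses mid-ranks and the t approximation", {
  expect_equal(spearman_rho(1:6, c(2, 4, 5, 7, 9, 12))$value, 1)
  expect_equal(spearman_rho(1:6, -(1:6))$value, -1)
  r <- spearman_rho(c(1, 2, 2, 4), c(10, 20, 30, 40))
  expect_equal(round(r$value, 3), 0.949)      # Pearson on mid-ranks
  expect_equal(r$value, 4.5 / sqrt(4.5 * 5))
  set.seed(13)
  for (i in 1:10) {
    n <- sample(6:40, 1)
    x <- sample(1:10, n, replace = TRUE)      # forces ties
    y <- x + stats::rnorm(n, 0, 3)
    mine <- spearman_rho(x, y)
    orc <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                            exact = FALSE))
    expect_equal(mine$value, unname(orc$estimate), tolerance = 1e-10)
    expect_equal(mine$p_value, orc$p.value, tolerance = 1e-10)
  }
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "zero rank variance")
})

test_that("exact permutation p-values agree with the exact distribution", {
  set.seed(41)
  for (i in 1:3) {
    x <- stats::rnorm(6); y <- stats::rnorm(6)
    expect_equal(spearman_exact_p(x, y),
                 stats::cor.test(x, y, method = "spearman",
                                 exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("ICC formulas match the ANOVA mean-squares oracle", {
  # identical columns with non-constant rows: perfect reliability
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc(m, "one_way")$value, 1)
  # permuting targets leaves both coefficients unchanged
  set.seed(17)
  r <- matrix(stats::rnorm(24, 50, 10), 8, 3)
  for (model in c("one_way", "two_way")) {
    v0 <- icc(r, model)$value
    v1 <- icc(r[sample(8), ], model)$value
    expect_equal(v1, v0, tolerance = 1e-12)
  }
  # mean squares from aov() as the independent decomposition
  for (i in 1:5) {
    n <- sample(4:10, 1); k <- sample(2:4, 1)
    ratings <- matrix(stats::rnorm(n * k, 30, 8), n, k)
    long <- data.frame(y = as.vector(ratings),
                       target = factor(rep(seq_len(n), k)),
                       rater = factor(rep(seq_len(k), each = n)))
    ms1 <- stats::anova(stats::lm(y ~ target, long))
    bms <- ms1$`Mean Sq`[1]; wms <- ms1$`Mean Sq`[2]
    expect_equal(icc(ratings, "one_way")$value,
                 (bms - wms) / (bms + (k - 1) * wms), tolerance = 1e-10)
    ms2 <- stats::anova(stats::lm(y ~ target + rater, long))
    bms2 <- ms2$`Mean Sq`[1]; jms <- ms2$`Mean Sq`[2]; ems <- ms2$`Mean Sq`[3]
    expect_equal(icc(ratings, "two_way")$value,
                 (bms2 - ems) / (bms2 + (k - 1) * ems +
                                   k * (jms - ems) / n),
                 tolerance = 1e-10)
  }
  # 4 x 2 fixture against the same decomposition, frozen by hand
  fx <- cbind(c(10, 20, 30, 40), c(12, 18, 33, 41))
  expect_equal(icc(fx, "one_way")$value, 0.986940749698, tolerance = 1e-9)
  expect_equal(icc(fx, "two_way")$value, 0.986937590711, tolerance = 1e-9)
  expect_error(icc(matrix(5, 3, 2), "one_way"), "constant")
})
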