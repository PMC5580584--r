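test_that("GMR is the pigmented percentage at full precision", {
  g <- make_toy_grid(12, 5)  # 60 sites
  r <- compute_gmr(toy_calls(g, rep(c(TRUE, FALSE, FALSE, FALSE), 15)))
  expect_equal(r$gmr, 25.0)
  expect_equal(r$pigmented_count, 15L)
  g117 <- make_toy_grid(13, 9)
  expect_equal(compute_gmr(toy_calls(g117, rep(FALSE, 117)))$gmr, 0)
  expect_equal(compute_gmr(toy_calls(g117, rep(TRUE, 117)))$gmr, 100)
  expect_equal(compute_gmr(toy_calls(make_toy_grid(1, 3),
                                     c(TRUE, FALSE, FALSE)))$gmr,
               100 / 3)
})

test_that("flipping one site raises GMR by exactly 100/n and never lowers it", {
  set.seed(5)
  g <- make_toy_grid(6, 7)
  n <- nrow(g$sites)
  base <- stats::runif(n) < 0.3
  g0 <- compute_gmr(toy_calls(g, base))$gmr
  for (i in sample(which(!base), 5)) {
    flipped <- base
    flipped[i] <- TRUE
    g1 <- compute_gmr(toy_calls(g, flipped))$gmr
    expect_equal(g1 - g0, 100 / n)
  }
})

test_that("Hedin grading follows the component rules on hand-built patterns", {
  g <- make_toy_grid(4, 3)
  pat <- function(...) {
    v <- rep(FALSE, 12)
    v[c(...)] <- TRUE
    v
  }
  # site order: lines 1..4, points 0..2 within each line
  expect_equal(classify_hedin(toy_calls(g, rep(FALSE, 12)), g), 0L)
  expect_equal(classify_hedin(toy_calls(g, rep(TRUE, 12)), g), 4L)
  expect_equal(classify_hedin(toy_calls(g, pat(1)), g), 1L)          # solitary
  expect_equal(classify_hedin(toy_calls(g, pat(1, 12)), g), 1L)      # two units
  expect_equal(classify_hedin(toy_calls(g, pat(1, 6, 12)), g), 2L)   # many units
  expect_equal(classify_hedin(toy_calls(g, pat(1, 4, 7)), g), 3L)    # 3-line ribbon
  expect_equal(classify_hedin(toy_calls(g, pat(1, 4, 7, 10)), g), 4L) # full span
  # hedin = 0 iff gmr = 0, and grading ignores site_id labels
  set.seed(31)
  for (i in 1:20) {
    v <- stats::runif(12) < 0.35
    calls <- toy_calls(g, v)
    h <- classify_hedin(calls, g)
    expect_identical(h == 0L, compute_gmr(calls)$gmr == 0)
    shuf <- calls[sample(nrow(calls)), ]
    relabeled <- site_call_table("toy",
                                 transform(shuf, site_id = sprintf("s%d", 1:12)))
    expect_identical(classify_hedin(relabeled, g), h)
  }
})

test_that("Hedin grading matches the flood-fill oracle on random large grids", {
  set.seed(12)
  for (i in 1:25) {
    g <- make_toy_grid(sample(3:13, 1), sample(3:9, 1))
    calls <- toy_calls(g, stats::runif(nrow(g$sites)) < stats::runif(1))
    expect_identical(classify_hedin(calls, g), hedin_oracle(calls, g))
  }
})

test_that("colour calling uses the window median lightness against the threshold", {
  syn <- render_photograph(params = photo_gen_params(seed = 8, p_site = 0.4))
  pal <- photo_gen_params()$palette
  lab <- gmrscore:::rgb_to_lab(rbind(pal$gingiva, pal$pigment))
  expect_gt(lab[1, 1], 50)   # healthy gingiva well above the default cut
  expect_lt(lab[2, 1], 50)   # melanin well below
  calls <- call_site_pigmentation(syn$photo, syn$grid)
  expect_identical(calls$pigmented, syn$truth$pigmented)
  # a strict threshold below the pigment lightness calls nothing
  none <- call_site_pigmentation(syn$photo, syn$grid,
                                 pigment_call_params(lightness_threshold = 10))
  expect_equal(sum(none$pigmented), 0L)
  # a permissive threshold above the gingiva lightness calls everything
  all_ <- call_site_pigmentation(syn$photo, syn$grid,
                                 pigment_call_params(lightness_threshold = 90))
  expect_equal(sum(all_$pigmented), nrow(all_))
})

test_that("Otsu threshold separates the rendered palette", {
  syn <- render_photograph(params = photo_gen_params(seed = 14, p_site = 0.5))
  thr <- otsu_lightness_threshold(syn$photo)
  pal <- photo_gen_params()$palette
  lab <- gmrscore:::rgb_to_lab(rbind(pal$gingiva, pal$pigment))
  expect_gt(thr, lab[2, 1])
  expect_lt(thr, lab[1, 1])
  calls <- call_site_pigmentation(
    syn$photo, syn$grid, pigment_call_params(lightness_threshold = "otsu"))
  expect_identical(calls$pigmented, syn$truth$pigmented)
})

test_that("gmr() ties the stages together and accepts manual call tables", {
  syn <- render_photograph(params = photo_gen_params(seed = 6, p_site = 0.3))
  fit <- gmr(syn$photo, syn$annotation)
  expect_s3_class(fit, "gmr_result")
  expect_equal(fit$gmr, 100 * sum(syn$truth$pigmented) / nrow(syn$truth))
  expect_equal(fit$hedin, hedin_truth_from_sites(syn$truth, syn$grid))
  expect_output(print(fit), "GMR")
  # manual calls bypass the image entirely (human-estimator workflow)
  manual <- gmr(NULL, syn$annotation, calls = syn$truth)
  expect_equal(manual$gmr, fit$gmr)
  expect_equal(manual$hedin, fit$hedin)
  bad <- syn$truth[-1, ]
  expect_error(gmr(NULL, syn$annotation,
                   calls = site_call_table("synthetic", bad)),
               "does not match")
})
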