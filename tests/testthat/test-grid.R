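test_that("baseline sits one crown length apical to tooth 12's cervical line", {
  ann <- make_fixture_annotation()   # cervical y 210, crown length 64
  expect_equal(build_baseline(ann), 146)
  expect_error(make_fixture_annotation(crown_length = 0), "positive")
  # crown length exceeding the gingival height pushes the baseline off-image
  expect_error(build_baseline(make_fixture_annotation(crown_length = 211)),
               "above the image")
})

test_that("interproximal merging yields 13 lines from 18 candidates", {
  ann <- make_fixture_annotation()
  bl <- build_baseline(ann)
  lines <- build_vertical_lines(ann, bl, merge_tol = 3)
  expect_equal(nrow(lines), 13L)   # 18 candidates minus 5 shared positions
  # brute-force check: pairwise x-distances across merged lines exceed tol
  expect_true(all(diff(sort(lines$x)) > 3))
  # merged interproximal lines carry two sources, outer/central lines one
  expect_equal(sum(lengths(lines$source) == 2), 5L)
  expect_equal(sum(lengths(lines$source) == 1), 8L)
  # coincident interproximal positions merge even at zero tolerance
  expect_equal(nrow(build_vertical_lines(ann, bl, merge_tol = 0)), 13L)
  # with all 18 x positions distinct, zero tolerance keeps all 18
  ann_in <- make_fixture_annotation(inset = 0.5)
  lines0 <- build_vertical_lines(ann_in, build_baseline(ann_in),
                                 merge_tol = 0)
  expect_equal(nrow(lines0), 18L)
  # ... and the default tolerance still merges the 1-px-apart pairs
  expect_equal(nrow(build_vertical_lines(ann_in, build_baseline(ann_in), 3)),
               13L)
  expect_identical(lines$x, sort(lines$x))
})

test_that("a single present tooth yields its three lines", {
  ann <- make_fixture_annotation()
  solo <- landmark_annotation("solo", ann$teeth["12"], 64,
                              ann$attached_gingiva)
  lines <- build_vertical_lines(solo, build_baseline(solo), 3)
  expect_equal(nrow(lines), 3L)
})

test_that("nine points per line separate eight equal parts, endpoints included", {
  ann <- make_fixture_annotation()
  grid_lines <- build_vertical_lines(ann, build_baseline(ann), 3)
  sites <- place_sites(grid_lines)
  expect_equal(nrow(sites), 9L * nrow(grid_lines))
  one <- sites[sites$line_index == 1, ]
  expect_equal(one$y, seq(146, 210, by = 8))
  expect_equal(one$point_index, 0:8)
  # per line: equal spacing and strictly increasing y
  for (li in unique(sites$line_index)) {
    ys <- sites$y[sites$line_index == li]
    expect_true(all(diff(ys) > 0))
    expect_equal(diff(range(diff(ys))), 0)
  }
  # degenerate 8-px line has exactly 1-px spacing
  short <- grid_lines[1, ]
  short$y_bottom <- short$y_top + 8
  expect_equal(diff(place_sites(short)$y), rep(1, 8))
})

test_that("attached-gingiva filtering retains exactly the in-polygon sites", {
  ann <- make_fixture_annotation()           # polygon covers all candidates
  g <- build_site_grid(ann)
  expect_equal(g$retained_count, g$candidate_count)
  expect_equal(g$candidate_count, 117L)
  # polygon top below the baseline row excludes exactly the k = 0 row
  ann2 <- make_fixture_annotation(ag_top = 147)
  g2 <- build_site_grid(ann2)
  expect_equal(g2$retained_count, g2$candidate_count - nrow(g2$lines))
  expect_true(all(g2$sites$point_index > 0))
  # polygon covering nothing is a hard error (GMR undefined)
  expect_error(build_site_grid(make_fixture_annotation(ag_top = 300,
                                                       ag_bottom = 320)),
               "GMR undefined")
})

test_that("retained sites pass independent point-in-polygon checks", {
  ann <- make_fixture_annotation(ag_top = 150, ag_bottom = 203)
  g <- build_site_grid(ann)
  poly <- ann$attached_gingiva
  ray <- gmrscore:::point_in_polygon(g$sites$x, g$sites$y, poly, "raycast")
  wind <- gmrscore:::point_in_polygon(g$sites$x, g$sites$y, poly, "winding")
  expect_true(all(ray))
  expect_true(all(wind))
  # the two methods agree on every candidate, retained or not
  cand <- place_sites(build_vertical_lines(ann, build_baseline(ann), 3))
  r <- gmrscore:::point_in_polygon(cand$x, cand$y, poly, "raycast")
  w <- gmrscore:::point_in_polygon(cand$x, cand$y, poly, "winding")
  expect_identical(r, w)
  pr <- pracma::inpolygon(cand$x, cand$y, poly[, 1], poly[, 2],
                          boundary = TRUE)
  expect_identical(r, pr)
})

test_that("grid construction is invariant under uniform translation", {
  g0 <- build_site_grid(make_fixture_annotation())
  g1 <- build_site_grid(make_fixture_annotation(shift = c(17, -23)))
  expect_equal(g1$retained_count, g0$retained_count)
  expect_equal(g1$candidate_count, g0$candidate_count)
  expect_equal(g1$sites$x, g0$sites$x + 17)
  expect_equal(g1$sites$y, g0$sites$y - 23)
  expect_equal(g1$baseline_y, g0$baseline_y - 23)
})

test_that("cervical interpolation follows a sloped polyline and forbids extrapolation", {
  ann <- make_fixture_annotation()
  # replace tooth 12's cervical line with a sloped polyline
  t12 <- tooth_landmark("12", rbind(c(140, 200), c(240, 220)),
                        mesial_x = 240, central_x = 190, distal_x = 140)
  teeth <- ann$teeth
  teeth[["12"]] <- t12
  ann2 <- landmark_annotation("sloped", teeth, 64, ann$attached_gingiva)
  expect_equal(build_baseline(ann2), 210 - 64)  # midpoint of the slope
  expect_error(gmrscore:::polyline_y_at(t12$cervical_polyline, 250),
               "extrapolation")
})

test_that("grids serialize to JSON and back", {
  g <- build_site_grid(make_fixture_annotation())
  p <- withr::local_tempfile(fileext = ".json")
  write_site_grid(g, p)
  back <- read_site_grid(p)
  expect_equal(back$sites, g$sites)
  expect_equal(back$lines$x, g$lines$x)
  expect_equal(back$retained_count, g$retained_count)
})
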