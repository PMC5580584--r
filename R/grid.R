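# Construction of the GMR measurement lattice from a landmark annotation:
# (1) a horizontal baseline one crown length (tooth 12) apical to the
#     cervical line of the maxillary right lateral incisor;
# (2) vertical lines from the baseline to the cervical line at the mesial,
#     central and distal position of each anterior tooth between the canines,
#     with coincident interproximal lines merged;
# (3) nine points per line separating eight equal parts (both endpoints);
# (4) retention of the points that fall in the attached gingiva.

#' Baseline height of the measurement lattice
#'
#' The baseline is drawn horizontally on the maxillary gingiva, one crown
#' length of the maxillary right lateral incisor (FDI 12) apical to that
#' tooth's cervical line (evaluated at its central vertical-line position).
#' In image coordinates (y downward) apical means smaller y.
#'
#' @param annotation a [landmark_annotation()].
#' @return `baseline_y` in pixels.
#' @export
build_baseline <- function(annotation) {
  stopifnot(inherits(annotation, "landmark_annotation"))
  t12 <- annotation$teeth[["12"]]
  if (is.null(t12)) stop("tooth 12 missing from annotation", call. = FALSE)
  y12 <- polyline_y_at(t12$cervical_polyline, t12$central_x)
  baseline_y <- y12 - annotation$crown_length_12
  if (baseline_y < 0)
    stop("baseline falls above the image (crown length exceeds available ",
         "gingival height)", call. = FALSE)
  baseline_y
}

#' Vertical measurement lines of the lattice
#'
#' One candidate line per present tooth and position (mesial, central,
#' distal); the cervical end (`y_bottom`) is the cervical polyline's y
#' linearly interpolated at the line's x. Candidates whose x differ by at
#' most `merge_tol` are merged (interproximal lines shared by adjacent
#' teeth): merged x is the mean, sources are pooled, and the merged
#' `y_bottom` is the mean of the members' cervical intercepts.
#'
#' @param annotation a [landmark_annotation()].
#' @param baseline_y baseline height from [build_baseline()].
#' @param merge_tol merge tolerance in pixels (default 3).
#' @param exclude_canines drop the canines' (13, 23) own lines, keeping them
#'   only as region bounds (default `FALSE`).
#' @return data.frame of class `vertical_lines`: `line_index`, `x`, `y_top`,
#'   `y_bottom`, and a list-column `source` of "tooth:position" strings.
#' @export
build_vertical_lines <- function(annotation, baseline_y, merge_tol = 3,
                                 exclude_canines = FALSE) {
  stopifnot(inherits(annotation, "landmark_annotation"))
  teeth <- annotation$teeth
  if (exclude_canines) teeth <- teeth[setdiff(names(teeth), c("13", "23"))]
  if (!length(teeth)) stop("no teeth available for lines", call. = FALSE)

  cand_x <- numeric(0); cand_y <- numeric(0); cand_src <- character(0)
  for (t in teeth) {
    xs <- c(mesial = t$mesial_x, central = t$central_x, distal = t$distal_x)
    ys <- polyline_y_at(t$cervical_polyline, xs)
    cand_x <- c(cand_x, xs)
    cand_y <- c(cand_y, ys)
    cand_src <- c(cand_src, paste0(t$tooth_id, ":", names(xs)))
  }
  if (any(cand_y <= baseline_y))
    stop("cervical line at or above the baseline for ",
         paste(cand_src[cand_y <= baseline_y], collapse = ", "),
         " (crown length exceeds gingival height)", call. = FALSE)

  o <- order(cand_x)
  cand_x <- cand_x[o]; cand_y <- cand_y[o]; cand_src <- cand_src[o]
  # greedy chain merge on sorted x
  grp <- integer(length(cand_x))
  g <- 1L
  grp[1] <- g
  for (i in seq_along(cand_x)[-1]) {
    if (cand_x[i] - cand_x[i - 1L] > merge_tol) g <- g + 1L
    grp[i] <- g
  }
  xs <- tapply(cand_x, grp, mean)
  ys <- tapply(cand_y, grp, mean)
  src <- unname(split(cand_src, grp))
  out <- data.frame(line_index = seq_along(xs),
                    x = as.numeric(xs),
                    y_top = baseline_y,
                    y_bottom = as.numeric(ys))
  out$source <- src
  class(out) <- c("vertical_lines", "data.frame")
  out
}

#' Candidate measurement sites on the vertical lines
#'
#' Nine points per line at `y = y_top + k (y_bottom - y_top) / 8`,
#' `k = 0..8`, separating the line into eight equal parts; both endpoints
#' (baseline point and cervical point) are included.
#'
#' @param lines a `vertical_lines` data.frame.
#' @return data.frame with `site_id`, `line_index`, `point_index`, `x`, `y`.
#' @export
place_sites <- function(lines) {
  if (!nrow(lines)) stop("no vertical lines", call. = FALSE)
  if (any(lines$y_top >= lines$y_bottom))
    stop("each line requires y_top < y_bottom", call. = FALSE)
  k <- 0:8
  out <- do.call(rbind, lapply(seq_len(nrow(lines)), function(i) {
    data.frame(site_id = sprintf("L%02d_P%d", lines$line_index[i], k),
               line_index = lines$line_index[i],
               point_index = k,
               x = lines$x[i],
               y = lines$y_top[i] + k * (lines$y_bottom[i] - lines$y_top[i]) / 8)
  }))
  rownames(out) <- NULL
  out
}

#' Restrict candidate sites to the attached gingiva
#'
#' Retains the candidate points lying inside or on the boundary of the
#' annotation's attached-gingiva polygon (boundary counts as inside), in the
#' original order. Measurement is undefined without retained sites.
#'
#' @param candidates data.frame from [place_sites()].
#' @param annotation a [landmark_annotation()].
#' @param lines the `vertical_lines` the candidates were placed on.
#' @param baseline_y baseline height (pixels).
#' @return An object of class `site_grid`: list with `baseline_y`, `lines`,
#'   `sites` (retained), `candidate_count`, `retained_count`.
#' @export
filter_attached_gingiva <- function(candidates, annotation, lines,
                                    baseline_y) {
  inside <- point_in_polygon(candidates$x, candidates$y,
                             annotation$attached_gingiva)
  retained <- candidates[inside, , drop = FALSE]
  rownames(retained) <- NULL
  if (!nrow(retained))
    stop("no candidate site lies in the attached gingiva; GMR undefined",
         call. = FALSE)
  structure(list(image_id = annotation$image_id,
                 baseline_y = baseline_y,
                 lines = lines,
                 sites = retained,
                 candidate_count = nrow(candidates),
                 retained_count = nrow(retained)),
            class = "site_grid")
}

#' Build the full measurement lattice for one annotated photograph
#'
#' Convenience wrapper chaining [build_baseline()], [build_vertical_lines()],
#' [place_sites()] and [filter_attached_gingiva()].
#'
#' @inheritParams build_vertical_lines
#' @return A `site_grid` object.
#' @export
build_site_grid <- function(annotation, merge_tol = 3,
                            exclude_canines = FALSE) {
  baseline_y <- build_baseline(annotation)
  lines <- build_vertical_lines(annotation, baseline_y, merge_tol,
                                exclude_canines)
  candidates <- place_sites(lines)
  filter_attached_gingiva(candidates, annotation, lines, baseline_y)
}

#' @export
print.site_grid <- function(x, ...) {
  cat(sprintf(
    "<site_grid '%s': baseline y = %.1f, %d lines, %d/%d sites retained>\n",
    x$image_id, x$baseline_y, nrow(x$lines), x$retained_count,
    x$candidate_count))
  invisible(x)
}

#' Read / write a site grid (JSON)
#'
#' @param grid a `site_grid`.
#' @param path JSON file path.
#' @export
write_site_grid <- function(grid, path) {
  stopifnot(inherits(grid, "site_grid"))
  lines <- grid$lines
  j <- list(image_id = grid$image_id,
            baseline_y = grid$baseline_y,
            candidate_count = grid$candidate_count,
            retained_count = grid$retained_count,
            lines = lapply(seq_len(nrow(lines)), function(i) list(
              line_index = lines$line_index[i], x = lines$x[i],
              y_top = lines$y_top[i], y_bottom = lines$y_bottom[i],
              source = as.list(lines$source[[i]]))),
            sites = lapply(seq_len(nrow(grid$sites)), function(i)
              as.list(grid$sites[i, ])))
  writeLines(jsonlite::toJSON(j, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_site_grid
#' @export
read_site_grid <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  lines <- data.frame(
    line_index = vapply(j$lines, `[[`, numeric(1), "line_index"),
    x = vapply(j$lines, `[[`, numeric(1), "x"),
    y_top = vapply(j$lines, `[[`, numeric(1), "y_top"),
    y_bottom = vapply(j$lines, `[[`, numeric(1), "y_bottom"))
  lines$source <- lapply(j$lines, function(l) unlist(l$source))
  class(lines) <- c("vertical_lines", "data.frame")
  sites <- do.call(rbind, lapply(j$sites, function(s)
    data.frame(site_id = s$site_id, line_index = s$line_index,
               point_index = s$point_index, x = s$x, y = s$y)))
  structure(list(image_id = j$image_id, baseline_y = j$baseline_y,
                 lines = lines, sites = sites,
                 candidate_count = j$candidate_count,
                 retained_count = j$retained_count),
            class = "site_grid")
}
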