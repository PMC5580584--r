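# Domain types and file I/O: photographs (PNG/JPEG not needed beyond PNG for
# synthetic work), landmark annotations (JSON), site call tables and cohort
# tables (CSV). All pixel coordinates are 0-based, origin at the top-left
# corner, y increasing downward; for the maxillary gingiva the apical
# direction is therefore decreasing y.

ANNOTATION_SCHEMA_VERSION <- "1.0"
ANTERIOR_TEETH <- c("13", "12", "11", "21", "22", "23")

#' Construct an oral photograph object
#'
#' Wraps an H x W x 3 array of 8-bit RGB values (0-255) with an image id.
#'
#' @param pixels numeric array, H x W x 3, values in \[0, 255\].
#' @param image_id character scalar identifying the photograph.
#' @return An object of class `oral_photo` (the pixel array with attributes).
#' @export
oral_photograph <- function(pixels, image_id) {
  stopifnot(is.character(image_id), length(image_id) == 1L)
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  if (d[1] < 64L || d[2] < 64L)
    stop("image must be at least 64 x 64 pixels", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  structure(pixels, image_id = image_id, class = "oral_photo")
}

#' @export
print.oral_photo <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<oral_photo '%s': %d x %d px, 3 channels>\n",
              attr(x, "image_id"), d[2], d[1]))
  invisible(x)
}

#' @rdname oral_photograph
#' @param path file path of a PNG image.
#' @export
read_photograph <- function(path, image_id = NULL) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  if (is.null(image_id))
    image_id <- sub("\\.[^.]*$", "", basename(path))
  oral_photograph(round(a * 255), image_id)
}

#' @rdname oral_photograph
#' @param photo an `oral_photo` object.
#' @export
write_photograph <- function(photo, path) {
  stopifnot(inherits(photo, "oral_photo"))
  png::writePNG(unclass(photo) / 255, path)
  invisible(path)
}

#' Construct a per-tooth landmark
#'
#' A tooth landmark carries the cervical line traced as a polyline and the
#' x-positions of the mesial, central and distal vertical measurement lines.
#'
#' @param tooth_id FDI tooth number, one of "13","12","11","21","22","23".
#' @param cervical_polyline numeric matrix (n >= 2 rows) of (x, y) pixel
#'   coordinates tracing the cervical line.
#' @param mesial_x,central_x,distal_x x-coordinates (pixels) of the three
#'   vertical-line positions; must lie within the polyline's x-range.
#' @return A `tooth_landmark` list.
#' @export
tooth_landmark <- function(tooth_id, cervical_polyline,
                           mesial_x, central_x, distal_x) {
  tooth_id <- as.character(tooth_id)
  if (!tooth_id %in% ANTERIOR_TEETH)
    stop("tooth_id must be one of ", paste(ANTERIOR_TEETH, collapse = ", "),
         call. = FALSE)
  cervical_polyline <- matrix(as.numeric(cervical_polyline), ncol = 2)
  if (nrow(cervical_polyline) < 2L)
    stop("cervical_polyline needs at least 2 points", call. = FALSE)
  xr <- range(cervical_polyline[, 1])
  xs <- c(mesial_x = mesial_x, central_x = central_x, distal_x = distal_x)
  if (any(xs < xr[1] - 1e-9 | xs > xr[2] + 1e-9))
    stop("mesial/central/distal x must lie within the cervical polyline's ",
         "x-range for tooth ", tooth_id, call. = FALSE)
  structure(list(tooth_id = tooth_id,
                 cervical_polyline = cervical_polyline,
                 mesial_x = as.numeric(mesial_x),
                 central_x = as.numeric(central_x),
                 distal_x = as.numeric(distal_x)),
            class = "tooth_landmark")
}

#' Construct a landmark annotation for one photograph
#'
#' @param image_id character id matching the photograph.
#' @param teeth list of [tooth_landmark()] objects (unique tooth ids; tooth 12
#'   must be present, as its crown length anchors the baseline).
#' @param crown_length_12 crown length (pixels) of the maxillary right lateral
#'   incisor (FDI 12); strictly positive.
#' @param attached_gingiva numeric matrix (>= 3 rows) of (x, y) vertices of a
#'   simple polygon bounding the attached gingiva (cervical side to the
#'   mucogingival junction).
#' @return A `landmark_annotation` list.
#' @export
landmark_annotation <- function(image_id, teeth, crown_length_12,
                                attached_gingiva) {
  stopifnot(is.character(image_id), length(image_id) == 1L)
  if (!all(vapply(teeth, inherits, logical(1), "tooth_landmark")))
    stop("teeth must be a list of tooth_landmark objects", call. = FALSE)
  ids <- vapply(teeth, `[[`, character(1), "tooth_id")
  if (anyDuplicated(ids))
    stop("duplicate tooth ids in annotation", call. = FALSE)
  if (!"12" %in% ids)
    stop("tooth 12 is required (its crown length anchors the baseline)",
         call. = FALSE)
  if (!is.numeric(crown_length_12) || length(crown_length_12) != 1L ||
      is.na(crown_length_12) || crown_length_12 <= 0)
    stop("crown_length_12 must be a positive number", call. = FALSE)
  attached_gingiva <- matrix(as.numeric(attached_gingiva), ncol = 2)
  if (nrow(attached_gingiva) < 3L)
    stop("attached_gingiva polygon needs at least 3 vertices", call. = FALSE)
  if (!is_simple_polygon(attached_gingiva))
    stop("attached_gingiva polygon is self-intersecting", call. = FALSE)
  names(teeth) <- ids
  structure(list(image_id = image_id,
                 teeth = teeth,
                 crown_length_12 = as.numeric(crown_length_12),
                 attached_gingiva = attached_gingiva),
            class = "landmark_annotation")
}

#' @export
print.landmark_annotation <- function(x, ...) {
  cat(sprintf("<landmark_annotation '%s': %d teeth (%s), crown_length_12 = %g px>\n",
              x$image_id, length(x$teeth),
              paste(names(x$teeth), collapse = " "), x$crown_length_12))
  invisible(x)
}

#' Read / write a landmark annotation (JSON)
#'
#' One JSON document per photograph, with a `schema_version` field.
#' Coordinates are 0-based pixels, origin top-left, y downward.
#'
#' @param path file path of the JSON annotation.
#' @return [read_annotation()] returns a `landmark_annotation`;
#'   [write_annotation()] invisibly returns `path`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  for (f in c("schema_version", "image_id", "teeth", "crown_length_12",
              "attached_gingiva")) {
    if (is.null(j[[f]]))
      stop("annotation is missing required field '", f, "'", call. = FALSE)
  }
  teeth <- lapply(j$teeth, function(tl) {
    for (f in c("tooth_id", "cervical_polyline", "mesial_x", "central_x",
                "distal_x")) {
      if (is.null(tl[[f]]))
        stop("tooth entry missing field '", f, "'", call. = FALSE)
    }
    poly <- do.call(rbind, lapply(tl$cervical_polyline, unlist))
    tooth_landmark(tl$tooth_id, poly, tl$mesial_x, tl$central_x, tl$distal_x)
  })
  gg <- do.call(rbind, lapply(j$attached_gingiva, unlist))
  landmark_annotation(j$image_id, teeth, j$crown_length_12, gg)
}

#' @rdname read_annotation
#' @param annotation a `landmark_annotation` object.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "landmark_annotation"))
  mat2list <- function(m) unname(lapply(seq_len(nrow(m)),
                                        function(i) as.numeric(m[i, ])))
  j <- list(
    schema_version = ANNOTATION_SCHEMA_VERSION,
    image_id = annotation$image_id,
    crown_length_12 = annotation$crown_length_12,
    teeth = unname(lapply(annotation$teeth, function(t) list(
      tooth_id = t$tooth_id,
      cervical_polyline = mat2list(t$cervical_polyline),
      mesial_x = t$mesial_x, central_x = t$central_x, distal_x = t$distal_x
    ))),
    attached_gingiva = mat2list(annotation$attached_gingiva)
  )
  writeLines(jsonlite::toJSON(j, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path)
  invisible(path)
}

#' Construct a site call table
#'
#' One row per retained measurement site with its lattice indices, pixel
#' position and binary pigmentation call.
#'
#' @param image_id character id of the photograph the calls belong to.
#' @param sites data.frame with columns `site_id`, `line_index`,
#'   `point_index` (0-8), `x`, `y`, `pigmented` (logical).
#' @return A data.frame of class `site_call_table`.
#' @export
site_call_table <- function(image_id, sites) {
  need <- c("site_id", "line_index", "point_index", "x", "y", "pigmented")
  if (!all(need %in% names(sites)))
    stop("sites must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  sites <- as.data.frame(sites)[need]
  if (anyDuplicated(sites$site_id))
    stop("site_id values must be unique", call. = FALSE)
  if (any(sites$point_index < 0 | sites$point_index > 8))
    stop("point_index must lie in [0, 8]", call. = FALSE)
  if (anyDuplicated(sites[c("line_index", "point_index")]))
    stop("(line_index, point_index) pairs must be unique", call. = FALSE)
  if (!is.logical(sites$pigmented) || anyNA(sites$pigmented))
    stop("pigmented must be TRUE/FALSE with no missing values", call. = FALSE)
  rownames(sites) <- NULL
  structure(sites, image_id = image_id,
            class = c("site_call_table", "data.frame"))
}

#' @rdname site_call_table
#' @param path CSV file path.
#' @export
read_site_calls <- function(path, image_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$pigmented <- as.logical(df$pigmented)
  if (is.null(image_id)) {
    image_id <- if ("image_id" %in% names(df)) df$image_id[1]
                else sub("\\.[^.]*$", "", basename(path))
  }
  site_call_table(image_id, df)
}

#' @rdname site_call_table
#' @param calls a `site_call_table`.
#' @export
write_site_calls <- function(calls, path) {
  stopifnot(inherits(calls, "site_call_table"))
  df <- as.data.frame(calls)
  df <- cbind(image_id = attr(calls, "image_id"), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- cohort tables -----------------------------------------------------------

COHORT_RAW_COLUMNS <- c("subject_id", "age", "sex", "lifetime_cigarettes",
                        "smoked_last_30_days", "smoking_duration",
                        "cessation_duration", "followup_period",
                        "gmr_baseline", "gmr_followup",
                        "hedin_baseline", "hedin_followup")

#' Assemble a cohort table from subject records
#'
#' Derives `smoking_status` (current/former; >100 lifetime cigarettes with or
#' without smoking in the previous 30 days) and the 10-year `age_group`
#' (19-29, 30-39, 40-49, 50-59, >=60). Subjects matching neither smoking
#' definition are excluded with a load report, mirroring the exclusion of
#' unusable records at enrolment.
#'
#' @param df data.frame with the raw columns listed in `COHORT_RAW_COLUMNS`.
#' @return A data.frame of class `cohort_table` with derived columns and a
#'   `load_report` attribute (`n_read`, `n_kept`, `n_excluded`, `row_errors`).
#' @export
cohort_table <- function(df) {
  missing_cols <- setdiff(COHORT_RAW_COLUMNS, names(df))
  if (length(missing_cols))
    stop("cohort table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)
  n_read <- nrow(df)
  row_errors <- character(0)

  num_cols <- c("age", "lifetime_cigarettes", "smoking_duration",
                "cessation_duration", "followup_period",
                "gmr_baseline", "gmr_followup",
                "hedin_baseline", "hedin_followup")
  bad <- rep(FALSE, n_read)
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    newly_bad <- !is.na(df[[cc]]) & df[[cc]] != "" & is.na(v)
    if (any(newly_bad)) {
      row_errors <- c(row_errors, sprintf(
        "row %d: non-numeric %s ('%s')", which(newly_bad), cc,
        df[[cc]][newly_bad]))
      bad <- bad | newly_bad
    }
    df[[cc]] <- v
  }
  bad <- bad | is.na(df$age) | df$age < 19
  if (any(is.na(df$age) | df$age < 19)) {
    i <- which(is.na(df$age) | df$age < 19)
    row_errors <- c(row_errors,
                    sprintf("row %d: age missing or below study range", i))
  }
  df$smoked_last_30_days <- as.logical(df$smoked_last_30_days)

  status <- classify_smoking_status(df$lifetime_cigarettes,
                                    df$smoked_last_30_days)
  keep <- !bad & status != "ineligible"
  n_excluded <- sum(!keep)
  out <- df[keep, , drop = FALSE]
  out$smoking_status <- as.character(status[keep])
  out$age_group <- as.character(assign_age_group(out$age))
  rownames(out) <- NULL
  structure(out,
            load_report = list(n_read = n_read, n_kept = nrow(out),
                               n_excluded = n_excluded,
                               row_errors = row_errors),
            class = c("cohort_table", "data.frame"))
}

#' Read / write a cohort table (CSV)
#'
#' @param path CSV path with header; UTF-8, "." decimal separator.
#' @return [read_cohort()] returns a `cohort_table` (with `load_report`
#'   attribute); [write_cohort()] writes the raw columns only (derived columns
#'   are always recomputed on load) and invisibly returns `path`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  ct <- cohort_table(df)
  rep <- attr(ct, "load_report")
  gmr_msg(sprintf("read_cohort: %d read, %d kept, %d excluded",
                  rep$n_read, rep$n_kept, rep$n_excluded))
  ct
}

#' @rdname read_cohort
#' @param cohort a `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)[COHORT_RAW_COLUMNS]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table: %d subjects (%d former / %d current)>\n",
              nrow(x), sum(x$smoking_status == "former"),
              sum(x$smoking_status == "current")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
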