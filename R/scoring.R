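# Pigmentation calling and scoring: binary presence/absence per retained
# lattice site (melanin darkens the tissue, so the decision uses CIELAB
# lightness only), the GMR percentage, and an operationalized Hedin 0-4
# grade built from connected components of pigmented sites on the lattice.

#' Parameters of the automatic pigmentation caller
#'
#' @param window_radius neighbourhood half-width in pixels around a site
#'   (default 2, i.e. a 5 x 5 window; windows are clamped at image edges).
#' @param lightness_threshold CIELAB L* decision threshold (default 50): a
#'   site is called pigmented iff its aggregated L* is at or below this.
#'   Pass `"otsu"` to derive the threshold from the image's own L* histogram
#'   (see [otsu_lightness_threshold()]), for photographs with an unknown
#'   palette.
#' @param aggregation `"median"` (default; robust to anti-aliased edges) or
#'   `"mean"`, applied per RGB channel over the window before conversion.
#' @return A `pigment_call_params` list.
#' @export
pigment_call_params <- function(window_radius = 2,
                                lightness_threshold = 50,
                                aggregation = c("median", "mean")) {
  aggregation <- match.arg(aggregation)
  stopifnot(window_radius >= 0)
  if (!identical(lightness_threshold, "otsu")) {
    stopifnot(is.numeric(lightness_threshold),
              lightness_threshold > 0, lightness_threshold < 100)
  }
  structure(list(window_radius = as.integer(window_radius),
                 lightness_threshold = lightness_threshold,
                 aggregation = aggregation),
            class = "pigment_call_params")
}

#' Otsu threshold on the CIELAB lightness histogram of a photograph
#'
#' Classic between-class-variance maximization over a 256-bin histogram of
#' per-pixel L*, for calling pigmentation when the palette (and hence a fixed
#' L* cut) is unknown.
#'
#' @param photo an `oral_photo`.
#' @param nbins number of histogram bins (default 256).
#' @return Threshold on the L* scale (0-100).
#' @export
otsu_lightness_threshold <- function(photo, nbins = 256) {
  stopifnot(inherits(photo, "oral_photo"))
  px <- matrix(unclass(photo), ncol = 3)
  L <- rgb_to_lab(px)[, 1]
  h <- tabulate(pmin(pmax(floor(L / 100 * nbins) + 1, 1), nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  (k / nbins) * 100
}

#' Call pigmentation at every retained lattice site
#'
#' For each retained site, the RGB pixels in a square window centred on the
#' site (clamped at image edges) are aggregated per channel, converted to
#' CIELAB, and the site is called pigmented iff L* is at or below the
#' threshold. Deterministic.
#'
#' @param photo an `oral_photo`.
#' @param grid a `site_grid`.
#' @param params a [pigment_call_params()].
#' @return A [site_call_table()].
#' @export
call_site_pigmentation <- function(photo, grid,
                                   params = pigment_call_params()) {
  stopifnot(inherits(photo, "oral_photo"), inherits(grid, "site_grid"))
  sites <- grid$sites
  if (is.null(sites) || !nrow(sites)) stop("empty site grid", call. = FALSE)
  H <- dim(photo)[1]; W <- dim(photo)[2]
  r <- params$window_radius
  thr <- params$lightness_threshold
  if (identical(thr, "otsu")) thr <- otsu_lightness_threshold(photo)
  aggfun <- if (params$aggregation == "median") stats::median else mean

  agg <- matrix(NA_real_, nrow(sites), 3)
  for (i in seq_len(nrow(sites))) {
    # 0-based coordinates -> 1-based array indices
    col <- round(sites$x[i]) + 1L
    row <- round(sites$y[i]) + 1L
    rows <- max(1L, row - r):min(H, row + r)
    cols <- max(1L, col - r):min(W, col + r)
    win <- unclass(photo)[rows, cols, , drop = FALSE]
    agg[i, ] <- apply(matrix(win, ncol = 3), 2, aggfun)
  }
  L <- rgb_to_lab(agg)[, 1]
  site_call_table(grid$image_id,
                  cbind(sites, pigmented = L <= thr))
}

#' Compute the GMR percentage from site calls
#'
#' GMR = 100 x (pigmented sites) / (all retained sites), kept at full
#' precision; rounding happens only at presentation.
#'
#' @param calls a [site_call_table()].
#' @return An object of class `gmr_result` with `image_id`,
#'   `pigmented_count`, `retained_count`, `gmr` and (if computed) `hedin`.
#' @export
compute_gmr <- function(calls) {
  stopifnot(inherits(calls, "site_call_table"))
  n <- nrow(calls)
  if (n == 0L) stop("GMR undefined: no retained sites", call. = FALSE)
  k <- sum(calls$pigmented)
  structure(list(image_id = attr(calls, "image_id"),
                 pigmented_count = k,
                 retained_count = n,
                 gmr = 100 * k / n,
                 hedin = NA_integer_),
            class = "gmr_result")
}

#' Operationalized Hedin grade (0-4) from site calls
#'
#' The original descriptors (no pigmentation; solitary units; many units;
#' short ribbons; one continuous ribbon) are mapped onto the measurement
#' lattice: connected components of pigmented sites are formed under
#' 8-neighbourhood adjacency on the (line_index, point_index) lattice, and a
#' component is a "ribbon" iff it spans at least 3 distinct lines. Grades:
#' 0 no pigmented site; 1 one or two components, none a ribbon; 2 more than
#' two components, none a ribbon; 3 at least one ribbon but none spanning
#' every line; 4 some component spans every line of the grid. This is an
#' operationalization for the lattice, not a published rubric.
#'
#' @param calls a [site_call_table()].
#' @param grid the `site_grid` the calls were made on.
#' @return Integer grade in 0-4.
#' @export
classify_hedin <- function(calls, grid) {
  stopifnot(inherits(calls, "site_call_table"), inherits(grid, "site_grid"))
  n_lines <- length(unique(grid$lines$line_index))
  pig <- calls[calls$pigmented, , drop = FALSE]
  if (!nrow(pig)) return(0L)
  comp <- lattice_components(pig$line_index, pig$point_index)
  spans <- tapply(pig$line_index, comp, function(v) length(unique(v)))
  n_comp <- length(spans)
  if (any(spans == n_lines)) return(4L)
  if (any(spans >= 3)) return(3L)
  if (n_comp > 2) return(2L)
  1L
}

# Connected components under 8-neighbourhood on integer lattice coordinates.
# Returns an integer component label per input point (BFS over an index map).
#' @keywords internal
#' @noRd
lattice_components <- function(li, pi) {
  n <- length(li)
  key <- paste(li, pi, sep = ",")
  idx <- seq_len(n)
  names(idx) <- key
  comp <- integer(n)
  cur <- 0L
  offs <- expand.grid(dl = -1:1, dp = -1:1)
  offs <- offs[!(offs$dl == 0 & offs$dp == 0), ]
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[[1]]
      queue <- queue[-1]
      nb_keys <- paste(li[i] + offs$dl, pi[i] + offs$dp, sep = ",")
      nb <- idx[nb_keys]
      nb <- nb[!is.na(nb)]
      nb <- nb[comp[nb] == 0L]
      if (length(nb)) {
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

#' Score one annotated photograph
#'
#' The package's central estimator: builds the measurement lattice from the
#' annotation, calls pigmentation at the retained sites (automatically from
#' image colour, or from a supplied manual call table standing in for a human
#' estimator), and returns the GMR percentage together with the
#' operationalized Hedin grade.
#'
#' @param photo an `oral_photo` (may be `NULL` when `calls` is supplied).
#' @param annotation a [landmark_annotation()].
#' @param calls optional [site_call_table()] of manual calls; bypasses colour
#'   calling.
#' @param params a [pigment_call_params()].
#' @param merge_tol interproximal line-merge tolerance in pixels.
#' @param exclude_canines see [build_vertical_lines()].
#' @return A `gmr_result` with components `image_id`, `pigmented_count`,
#'   `retained_count`, `gmr`, `hedin`, plus the `grid` and per-site `calls`.
#' @examples
#' syn <- render_photograph(params = photo_gen_params(seed = 1))
#' fit <- gmr(syn$photo, syn$annotation)
#' fit
#' @export
gmr <- function(photo, annotation, calls = NULL,
                params = pigment_call_params(), merge_tol = 3,
                exclude_canines = FALSE) {
  grid <- build_site_grid(annotation, merge_tol, exclude_canines)
  if (is.null(calls)) {
    calls <- call_site_pigmentation(photo, grid, params)
  } else {
    stopifnot(inherits(calls, "site_call_table"))
    if (!setequal(calls$site_id, grid$sites$site_id))
      stop("manual call table does not match the grid's retained sites",
           call. = FALSE)
    calls <- calls[match(grid$sites$site_id, calls$site_id), , drop = FALSE]
    rownames(calls) <- NULL
  }
  res <- compute_gmr(calls)
  res$hedin <- classify_hedin(calls, grid)
  res$grid <- grid
  res$calls <- calls
  res
}

#' @export
print.gmr_result <- function(x, ...) {
  cat(sprintf("GMR for '%s': %s%% (%d of %d sites pigmented)",
              x$image_id, format(round_half_up(x$gmr, 1), nsmall = 1),
              x$pigmented_count, x$retained_count))
  if (!is.na(x$hedin)) cat(sprintf(", Hedin grade %d", x$hedin))
  cat("\n")
  invisible(x)
}

#' @export
summary.gmr_result <- function(object, ...) {
  x <- object
  cat("Gingival melanosis record\n")
  cat(sprintf("  image:            %s\n", x$image_id))
  if (!is.null(x$grid)) {
    cat(sprintf("  lattice:          %d lines, %d candidate sites, %d retained\n",
                nrow(x$grid$lines), x$grid$candidate_count,
                x$grid$retained_count))
  }
  cat(sprintf("  pigmented sites:  %d / %d\n", x$pigmented_count,
              x$retained_count))
  cat(sprintf("  GMR:              %s%%\n",
              format(round_half_up(x$gmr, 1), nsmall = 1)))
  if (!is.na(x$hedin)) cat(sprintf("  Hedin grade:      %d\n", x$hedin))
  invisible(x)
}

#' Plot a scored photograph with its lattice overlaid
#'
#' @param x a `gmr_result` from [gmr()].
#' @param photo the `oral_photo` to draw under the overlay (optional; lattice
#'   only if missing).
#' @param ... passed to [graphics::plot()].
#' @export
plot.gmr_result <- function(x, photo = NULL, ...) {
  g <- x$grid
  if (is.null(g)) stop("gmr_result carries no grid to plot", call. = FALSE)
  W <- max(g$sites$x) * 1.05
  H <- max(g$sites$y) * 1.1
  if (!is.null(photo)) {
    H <- dim(photo)[1]; W <- dim(photo)[2]
  }
  graphics::plot(NA, xlim = c(0, W), ylim = c(H, 0), asp = 1,
                 xlab = "x (px)", ylab = "y (px)",
                 main = sprintf("%s: GMR %.1f%%, Hedin %d",
                                x$image_id, x$gmr, x$hedin), ...)
  if (!is.null(photo))
    graphics::rasterImage(unclass(photo) / 255, 0, H, W, 0)
  graphics::abline(h = g$baseline_y, col = "steelblue", lty = 2)
  graphics::segments(g$lines$x, g$lines$y_top, g$lines$x, g$lines$y_bottom,
                     col = "steelblue")
  cl <- ifelse(x$calls$pigmented, "black", "white")
  graphics::points(x$calls$x, x$calls$y, pch = 21, bg = cl, col = "red",
                   cex = 0.9)
  invisible(x)
}
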