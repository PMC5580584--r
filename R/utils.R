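# Internal geometry / numeric helpers shared across the package.

#' @keywords internal
#' @noRd
gmr_msg <- function(..., verbose = getOption("gmrscore.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

# Round half away from zero at `digits` decimal places (presentation rounding;
# base round() rounds half to even).
#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# sRGB (0..255) matrix -> CIELAB. Rows are colors.
#' @keywords internal
#' @noRd
rgb_to_lab <- function(rgb) {
  rgb <- matrix(rgb, ncol = 3)
  grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
}

# Linear interpolation of a polyline's y at query x values.
# Extrapolation beyond the polyline's x-range is an error (tolerance eps).
#' @keywords internal
#' @noRd
polyline_y_at <- function(polyline, x, eps = 1e-9) {
  px <- polyline[, 1]
  py <- polyline[, 2]
  o <- order(px)
  px <- px[o]
  py <- py[o]
  if (any(x < min(px) - eps | x > max(px) + eps)) {
    stop("x outside cervical polyline range; extrapolation is not allowed",
         call. = FALSE)
  }
  x <- pmin(pmax(x, min(px)), max(px))
  stats::approx(px, py, xout = x, ties = mean)$y
}

# Point-in-polygon, boundary counts as inside.
# method = "raycast" (even-odd crossing) or "winding" (winding number);
# the two are kept as genuinely separate code paths so they can cross-check
# each other.
#' @keywords internal
#' @noRd
point_in_polygon <- function(x, y, poly, method = c("raycast", "winding"),
                             eps = 1e-9) {
  method <- match.arg(method)
  vx <- poly[, 1]
  vy <- poly[, 2]
  n <- length(vx)
  jj <- c(n, seq_len(n - 1)) # previous vertex index
  out <- logical(length(x))

  on_boundary <- function(px, py) {
    hit <- FALSE
    for (i in seq_len(n)) {
      x1 <- vx[jj[i]]; y1 <- vy[jj[i]]; x2 <- vx[i]; y2 <- vy[i]
      cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
      if (abs(cross) <= eps * (abs(x2 - x1) + abs(y2 - y1) + 1) &&
          px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
          py >= min(y1, y2) - eps && py <= max(y1, y2) + eps) {
        hit <- TRUE
        break
      }
    }
    hit
  }

  for (k in seq_along(x)) {
    px <- x[k]; py <- y[k]
    if (on_boundary(px, py)) {
      out[k] <- TRUE
      next
    }
    if (method == "raycast") {
      inside <- FALSE
      for (i in seq_len(n)) {
        x1 <- vx[jj[i]]; y1 <- vy[jj[i]]; x2 <- vx[i]; y2 <- vy[i]
        if ((y1 > py) != (y2 > py)) {
          xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
          if (px < xint) inside <- !inside
        }
      }
      out[k] <- inside
    } else {
      wn <- 0L
      for (i in seq_len(n)) {
        x1 <- vx[jj[i]]; y1 <- vy[jj[i]]; x2 <- vx[i]; y2 <- vy[i]
        if (y1 <= py) {
          if (y2 > py &&
              (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1) > 0) wn <- wn + 1L
        } else {
          if (y2 <= py &&
              (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1) < 0) wn <- wn - 1L
        }
      }
      out[k] <- wn != 0L
    }
  }
  out
}

# TRUE if the polygon (matrix of vertices) is simple: no two non-adjacent
# edges intersect. Brute-force segment pair test; polygons here are small.
#' @keywords internal
#' @noRd
is_simple_polygon <- function(poly, eps = 1e-12) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  orient <- function(ax, ay, bx, by, cx, cy) {
    v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    if (abs(v) <= eps) 0 else sign(v)
  }
  intersects <- function(s1, s2) {
    d1 <- orient(s2[1], s2[2], s2[3], s2[4], s1[1], s1[2])
    d2 <- orient(s2[1], s2[2], s2[3], s2[4], s1[3], s1[4])
    d3 <- orient(s1[1], s1[2], s1[3], s1[4], s2[1], s2[2])
    d4 <- orient(s1[1], s1[2], s1[3], s1[4], s2[3], s2[4])
    if (d1 != d2 && d3 != d4) return(TRUE)
    on_seg <- function(ax, ay, bx, by, px, py) {
      orient(ax, ay, bx, by, px, py) == 0 &&
        px >= min(ax, bx) - eps && px <= max(ax, bx) + eps &&
        py >= min(ay, by) - eps && py <= max(ay, by) + eps
    }
    (d1 == 0 && on_seg(s2[1], s2[2], s2[3], s2[4], s1[1], s1[2])) ||
      (d2 == 0 && on_seg(s2[1], s2[2], s2[3], s2[4], s1[3], s1[4])) ||
      (d3 == 0 && on_seg(s1[1], s1[2], s1[3], s1[4], s2[1], s2[2])) ||
      (d4 == 0 && on_seg(s1[1], s1[2], s1[3], s1[4], s2[3], s2[4]))
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adjacent <- (j == i + 1) || (i == 1 && j == n)
      if (adjacent) next
      if (intersects(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

# Exact truncated-normal sampling on [lo, hi] via inverse CDF.
#' @keywords internal
#' @noRd
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  a <- stats::pnorm(lo, mean, sd)
  b <- stats::pnorm(hi, mean, sd)
  stats::qnorm(a + stats::runif(n) * (b - a), mean, sd)
}

# Location mu* such that a Normal(mu*, sd) truncated to [lo, hi] has the
# requested mean. Used so generator parameters are the realized moments.
#' @keywords internal
#' @noRd
truncnorm_matched_location <- function(target_mean, sd, lo, hi) {
  if (sd == 0) return(target_mean)
  if (target_mean <= lo || target_mean >= hi)
    stop("target mean must lie strictly inside the truncation interval",
         call. = FALSE)
  tn_mean <- function(mu) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    # far outside the interval the truncated mean collapses to the bound
    if (z < 1e-12) return(if (mu < lo) lo else hi)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  f <- function(mu) tn_mean(mu) - target_mean
  span <- 3 * sd
  while (f(lo - span) > 0 || f(hi + span) < 0) span <- span * 2
  stats::uniroot(f, lower = lo - span, upper = hi + span, tol = 1e-10)$root
}
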