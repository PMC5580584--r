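# Fixtures built in code: a hand-constructed annotation with known geometry,
# a minimal toy lattice, and independent oracles (flood-fill Hedin grading,
# alternative point-in-polygon).

FDI_SIX <- c("13", "12", "11", "21", "22", "23")

# Six teeth in 100-px slots starting at x = 40; flat per-tooth cervical
# lines; adjacent teeth share interproximal x exactly. With the defaults the
# cervical line of tooth 12 sits at y = 210 and crown length 64 puts the
# baseline at y = 146, so sites fall at y = 146, 154, ..., 210.
make_fixture_annotation <- function(image_id = "fixture",
                                    cervical_y = rep(210, 6),
                                    crown_length = 64,
                                    ag_top = 120, ag_bottom = 210,
                                    shift = c(0, 0), inset = 0) {
  slots <- seq(40, 640, by = 100) + shift[1]
  cervical_y <- cervical_y + shift[2]
  teeth <- lapply(1:6, function(i) {
    x0 <- slots[i] + inset; x1 <- slots[i + 1] - inset
    if (i <= 3) { mes <- x1; dis <- x0 } else { mes <- x0; dis <- x1 }
    tooth_landmark(FDI_SIX[i],
                   rbind(c(slots[i], cervical_y[i]),
                         c(slots[i + 1], cervical_y[i])),
                   mesial_x = mes, central_x = (x0 + x1) / 2, distal_x = dis)
  })
  ag <- rbind(c(20 + shift[1], ag_top + shift[2]),
              c(660 + shift[1], ag_top + shift[2]),
              c(660 + shift[1], ag_bottom + shift[2]),
              c(20 + shift[1], ag_bottom + shift[2]))
  landmark_annotation(image_id, teeth, crown_length, ag)
}

# Minimal lattice with n_lines lines and the first n_points point indices
# retained on each; geometry is nominal (grading only looks at indices).
make_toy_grid <- function(n_lines = 4, n_points = 3, image_id = "toy") {
  lines <- data.frame(line_index = seq_len(n_lines),
                      x = 10 * seq_len(n_lines), y_top = 0, y_bottom = 8)
  lines$source <- as.list(sprintf("t%d", seq_len(n_lines)))
  class(lines) <- c("vertical_lines", "data.frame")
  sites <- expand.grid(point_index = 0:(n_points - 1),
                       line_index = seq_len(n_lines))
  sites <- data.frame(
    site_id = sprintf("L%02d_P%d", sites$line_index, sites$point_index),
    line_index = sites$line_index, point_index = sites$point_index,
    x = 10 * sites$line_index, y = sites$point_index)
  structure(list(image_id = image_id, baseline_y = 0, lines = lines,
                 sites = sites, candidate_count = 9 * n_lines,
                 retained_count = nrow(sites)),
            class = "site_grid")
}

toy_calls <- function(grid, pigmented) {
  site_call_table(grid$image_id, cbind(grid$sites, pigmented = pigmented))
}

# Independent Hedin oracle: matrix flood fill (explicit stack) over the
# (line, point) raster, then the published grading rules applied to the
# component spans.
hedin_oracle <- function(calls, grid) {
  lis <- sort(unique(grid$lines$line_index))
  n_lines <- length(lis)
  m <- matrix(FALSE, n_lines, 9)
  pig <- calls[calls$pigmented, , drop = FALSE]
  if (!nrow(pig)) return(0L)
  for (i in seq_len(nrow(pig)))
    m[match(pig$line_index[i], lis), pig$point_index[i] + 1L] <- TRUE
  lab <- matrix(0L, n_lines, 9)
  cur <- 0L
  for (r0 in seq_len(n_lines)) for (c0 in 1:9) {
    if (!m[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(stack)) {
      rc <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- rc[1] + dr; c <- rc[2] + dc
        if (r >= 1 && r <= n_lines && c >= 1 && c <= 9 &&
            m[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  spans <- vapply(seq_len(cur),
                  function(k) length(unique(which(lab == k, arr.ind = TRUE)[, 1])),
                  integer(1))
  if (any(spans == n_lines)) return(4L)
  if (any(spans >= 3)) return(3L)
  if (cur > 2) return(2L)
  1L
}
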