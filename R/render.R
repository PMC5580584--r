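# Stylized frontal oral photograph generator. The scene is deliberately
# simple: six anterior maxillary teeth between the canines, a gingival band
# up to the mucogingival junction, alveolar mucosa above it, and circular
# melanin patches drawn at ground-truth-pigmented lattice sites. The palette
# guarantees a wide CIELAB lightness margin between healthy and pigmented
# gingiva so that colour calling on the rendered image is exactly separable.

#' Parameters of the synthetic photograph generator
#'
#' @param width,height image size in pixels (default 660 x 440; must be
#'   large enough to place six teeth).
#' @param palette named list of RGB triplets (0-255): `enamel`, `gingiva`
#'   (healthy), `pigment` (melanin patch), `mucosa` (alveolar mucosa),
#'   `background`. The pigment lightness must sit below the healthy-gingiva
#'   lightness by at least `lightness_margin` L* units.
#' @param p_site per-site pigmentation probability in \[0, 1\].
#' @param patch_radius melanin patch radius in pixels (default 3; patches
#'   fully cover the default 5 x 5 calling window without reaching the
#'   neighbouring site's window).
#' @param noise_sd optional flat Gaussian pixel noise sd (default 0).
#' @param lightness_margin required L* separation between healthy and
#'   pigmented gingiva (default 20).
#' @param seed RNG seed driving all random draws of the renderer.
#' @return A `photo_gen_params` list.
#' @export
photo_gen_params <- function(width = 660, height = 440,
                             palette = list(
                               enamel = c(246, 243, 230),
                               gingiva = c(233, 150, 138),
                               pigment = c(92, 62, 58),
                               mucosa = c(200, 108, 102),
                               background = c(35, 32, 38)),
                             p_site = 0.25, patch_radius = 3,
                             noise_sd = 0, lightness_margin = 20,
                             seed = 1L) {
  stopifnot(p_site >= 0, p_site <= 1, patch_radius >= 1, noise_sd >= 0)
  need <- c("enamel", "gingiva", "pigment", "mucosa", "background")
  if (!all(need %in% names(palette)))
    stop("palette must name ", paste(need, collapse = ", "), call. = FALSE)
  L <- rgb_to_lab(rbind(palette$gingiva, palette$pigment))[, 1]
  if (L[2] > L[1] - lightness_margin)
    stop(sprintf(paste0("pigment lightness (L* = %.1f) must lie at least ",
                        "%.0f units below healthy gingiva (L* = %.1f)"),
                 L[2], lightness_margin, L[1]), call. = FALSE)
  if (width < 240 || height < 160)
    stop("image too small to place six teeth", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 palette = palette, p_site = p_site,
                 patch_radius = as.integer(patch_radius),
                 noise_sd = noise_sd, lightness_margin = lightness_margin,
                 seed = seed),
            class = "photo_gen_params")
}

# Scene geometry shared by the renderer and its annotation (all 0-based px).
#' @keywords internal
#' @noRd
photo_scene <- function(params) {
  W <- params$width; H <- params$height
  margin <- round(0.05 * W)
  slot_w <- (W - 2 * margin) / 6
  slot_x <- margin + slot_w * 0:6           # 7 slot boundaries
  cerv0 <- round(0.59 * H)
  cerv_off <- c(-6, -2, 0, 0, -2, -6)       # mild scallop across the arch
  cervical_y <- cerv0 + cerv_off
  crown_length_12 <- round(0.145 * H)
  mgj_y <- round(0.34 * H)                  # mucogingival junction
  mucosa_top <- round(0.18 * H)
  ag_bottom <- min(cervical_y) - 4          # attached gingiva apical of crowns
  list(W = W, H = H, margin = margin, slot_x = slot_x, slot_w = slot_w,
       cervical_y = cervical_y, crown_length_12 = crown_length_12,
       mgj_y = mgj_y, mucosa_top = mucosa_top, ag_bottom = ag_bottom,
       tooth_ids = ANTERIOR_TEETH, tooth_inset = 2)
}

#' @keywords internal
#' @noRd
scene_annotation <- function(scene, image_id) {
  teeth <- vector("list", 6)
  for (i in 1:6) {
    x0 <- scene$slot_x[i]; x1 <- scene$slot_x[i + 1]
    cy <- scene$cervical_y[i]
    # mesial is toward the midline (between slots 3 and 4)
    if (i <= 3) { mes <- x1; dis <- x0 } else { mes <- x0; dis <- x1 }
    teeth[[i]] <- tooth_landmark(scene$tooth_ids[i],
                                 rbind(c(x0, cy), c(x1, cy)),
                                 mesial_x = mes,
                                 central_x = (x0 + x1) / 2,
                                 distal_x = dis)
  }
  ag <- rbind(c(scene$margin - 8, scene$mgj_y),
              c(scene$W - scene$margin + 8, scene$mgj_y),
              c(scene$W - scene$margin + 8, scene$ag_bottom),
              c(scene$margin - 8, scene$ag_bottom))
  landmark_annotation(image_id, teeth, scene$crown_length_12, ag)
}

#' Render a synthetic annotated oral photograph
#'
#' Draws the stylized scene, assigns ground-truth pigmentation to the
#' retained lattice sites (Bernoulli(`p_site`) unless an explicit logical
#' `truth` vector is given), stamps a melanin patch over every pigmented
#' site, and returns the photograph together with its geometrically
#' consistent landmark annotation and the ground-truth call table.
#' Deterministic for a fixed seed.
#'
#' @param truth optional logical vector of per-retained-site ground truth
#'   (recycled if length 1); defaults to Bernoulli(`p_site`) draws.
#' @param params a [photo_gen_params()].
#' @param image_id id stored in all returned objects.
#' @return list with `photo` (`oral_photo`), `annotation`
#'   (`landmark_annotation`), `truth` ([site_call_table()]) and `grid`
#'   (`site_grid`).
#' @export
render_photograph <- function(truth = NULL, params = photo_gen_params(),
                              image_id = "synthetic") {
  stopifnot(inherits(params, "photo_gen_params"))
  scene <- photo_scene(params)
  annotation <- scene_annotation(scene, image_id)
  grid <- build_site_grid(annotation)
  ns <- nrow(grid$sites)

  with_seed(params$seed, {
    if (is.null(truth)) {
      truth_vec <- stats::runif(ns) < params$p_site
    } else {
      truth_vec <- rep_len(as.logical(truth), ns)
    }

    pal <- lapply(params$palette, as.numeric)
    H <- scene$H; W <- scene$W
    img <- array(0, c(H, W, 3))
    fill <- function(img, rows, cols, col) {
      rows <- rows[rows >= 1 & rows <= H]
      cols <- cols[cols >= 1 & cols <= W]
      for (ch in 1:3) img[rows, cols, ch] <- col[ch]
      img
    }
    # paint back-to-front: background, mucosa, gingival band, teeth, patches
    img <- fill(img, 1:H, 1:W, pal$background)
    img <- fill(img, (scene$mucosa_top + 1):(scene$mgj_y), 1:W, pal$mucosa)
    img <- fill(img, (scene$mgj_y + 1):(max(scene$cervical_y) + 14), 1:W,
                pal$gingiva)
    for (i in 1:6) {
      x0 <- round(scene$slot_x[i]) + scene$tooth_inset
      x1 <- round(scene$slot_x[i + 1]) - scene$tooth_inset
      cy <- scene$cervical_y[i]
      img <- fill(img, (cy + 1):H, (x0 + 1):(x1 + 1), pal$enamel)
    }
    # melanin patches over ground-truth-pigmented sites
    r <- params$patch_radius
    offs <- expand.grid(dy = -r:r, dx = -r:r)
    offs <- offs[offs$dx^2 + offs$dy^2 <= r^2 + 1e-9, ]
    for (s in which(truth_vec)) {
      cx <- round(grid$sites$x[s]); cy <- round(grid$sites$y[s])
      rows <- cy + offs$dy + 1L
      cols <- cx + offs$dx + 1L
      ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
      for (ch in 1:3)
        img[cbind(rows[ok], cols[ok], ch)] <- pal$pigment[ch]
    }
    if (params$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, params$noise_sd)
      img <- pmin(pmax(img, 0), 255)
    }

    truth_table <- site_call_table(image_id,
                                   cbind(grid$sites, pigmented = truth_vec))
    list(photo = oral_photograph(img, image_id),
         annotation = annotation,
         truth = truth_table,
         grid = grid)
  })
}
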