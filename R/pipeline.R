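# End-to-end orchestration: synthesize photographs and a cohort, build
# grids, score pigmentation, analyze, and write a run manifest. All stage
# outputs use the package's standard PNG/JSON/CSV formats under fixed file
# names inside the run directory, so a fixed config + seed reproduces
# byte-identical CSV/JSON outputs.

#' Assemble a run configuration
#'
#' @param seed master seed; per-stage seeds are derived from it
#'   deterministically.
#' @param out_dir run directory.
#' @param n_photos number of synthetic photographs (default 6).
#' @param photo a [photo_gen_params()] (its seed field is overridden by the
#'   derived per-photo seeds).
#' @param cohort a [cohort_gen_params()] (idem).
#' @param calls a [pigment_call_params()].
#' @param merge_tol lattice merge tolerance in pixels.
#' @param rater_flip_prob probability that an emulated human estimator flips
#'   a site call in a repeated session (drives the ICC stage; default 0.05).
#' @param alpha significance level of the analysis stage.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 42L, out_dir = "gmr_run", n_photos = 6L,
                       photo = photo_gen_params(),
                       cohort = cohort_gen_params(),
                       calls = pigment_call_params(),
                       merge_tol = 3, rater_flip_prob = 0.05,
                       alpha = 0.05) {
  stopifnot(n_photos >= 1, rater_flip_prob >= 0, rater_flip_prob < 1)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_photos = as.integer(n_photos), photo = photo,
                 cohort = cohort, calls = calls, merge_tol = merge_tol,
                 rater_flip_prob = rater_flip_prob, alpha = alpha),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Any omitted field keeps its [run_config()] default; `photo`, `cohort` and
#' `calls` subsections override individual generator/caller parameters.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("seed", "out_dir", "n_photos",
                                  "merge_tol", "rater_flip_prob", "alpha"))]
  if (!is.null(y$photo)) {
    if (!is.null(y$photo$palette))
      y$photo$palette <- lapply(y$photo$palette, as.numeric)
    args$photo <- do.call(photo_gen_params, y$photo)
  }
  if (!is.null(y$cohort)) {
    for (f in c("n_per_cell", "male_per_cell"))
      if (!is.null(y$cohort[[f]]))
        y$cohort[[f]] <- matrix(unlist(y$cohort[[f]]), nrow = 2,
                                byrow = TRUE)
    args$cohort <- do.call(cohort_gen_params, y$cohort)
  }
  if (!is.null(y$calls)) args$calls <- do.call(pigment_call_params, y$calls)
  do.call(run_config, args)
}

# Emulated estimator session: flip each call independently with prob p.
#' @keywords internal
#' @noRd
flip_calls <- function(truth, p) {
  flips <- stats::runif(length(truth)) < p
  xor(truth, flips)
}

#' Run the pipeline end to end
#'
#' Stages, in order: (1) synthesize `n_photos` annotated photographs (PNG +
#' JSON annotation + ground-truth CSV); (2) build and serialize the site
#' grid per photograph; (3) score pigmentation per photograph (automatic
#' calls; GMR + Hedin), plus two emulated repeated sessions and a second
#' emulated examiner for the ICC reproducibility stage; (4) simulate a
#' cohort and run the study analysis, writing summary CSVs, test JSON and
#' figures. A manifest (JSON) records the config hash, package version and
#' stage outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_end_to_end <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "init"
  manifest_files <- character(0)
  res <- tryCatch({
    # --- stage 1 + 2 + 3: photographs, grids, scores -----------------------
    stage <- "synth_photo"
    per_photo <- vector("list", config$n_photos)
    gmr_auto <- numeric(config$n_photos)
    sessions <- matrix(NA_real_, config$n_photos, 2,
                       dimnames = list(NULL, c("session1", "session2")))
    raters <- matrix(NA_real_, config$n_photos, 2,
                     dimnames = list(NULL, c("raterA", "raterB")))
    # photographs span a range of pigmentation burden around the configured
    # p_site (subjects differ), giving the reproducibility stage genuine
    # between-target variance
    spread <- if (config$n_photos > 1)
      0.4 + 1.2 * (seq_len(config$n_photos) - 1) / (config$n_photos - 1)
    else 1
    for (i in seq_len(config$n_photos)) {
      pp <- config$photo
      pp$p_site <- min(1, config$photo$p_site * spread[i])
      pp$seed <- config$seed * 1000L + i
      id <- sprintf("photo%02d", i)
      syn <- render_photograph(params = pp, image_id = id)
      write_photograph(syn$photo, file.path(out, paste0(id, ".png")))
      write_annotation(syn$annotation,
                       file.path(out, paste0(id, "_annotation.json")))
      write_site_calls(syn$truth, file.path(out, paste0(id, "_truth.csv")))
      stage <- "grid"
      grid <- build_site_grid(syn$annotation, config$merge_tol)
      write_site_grid(grid, file.path(out, paste0(id, "_grid.json")))
      stage <- "score"
      fit <- gmr(syn$photo, syn$annotation, params = config$calls,
                 merge_tol = config$merge_tol)
      write_site_calls(fit$calls, file.path(out, paste0(id, "_calls.csv")))
      gmr_auto[i] <- fit$gmr
      # emulated estimator sessions for the reproducibility stage
      with_seed(config$seed * 1000L + 500L + i, {
        for (s in 1:2) {
          calls_s <- fit$calls
          calls_s$pigmented <- flip_calls(calls_s$pigmented,
                                          config$rater_flip_prob)
          sessions[i, s] <- compute_gmr(calls_s)$gmr
        }
        raters[i, 1] <- sessions[i, 1]
        calls_b <- fit$calls
        calls_b$pigmented <- flip_calls(calls_b$pigmented,
                                        config$rater_flip_prob)
        raters[i, 2] <- compute_gmr(calls_b)$gmr
      })
      per_photo[[i]] <- data.frame(
        image_id = id, retained_count = fit$retained_count,
        pigmented_count = fit$pigmented_count, gmr = fit$gmr,
        hedin = fit$hedin,
        truth_gmr = compute_gmr(syn$truth)$gmr,
        truth_hedin = hedin_truth_from_sites(syn$truth, grid))
      manifest_files <- c(manifest_files,
                          paste0(id, c(".png", "_annotation.json",
                                       "_truth.csv", "_grid.json",
                                       "_calls.csv")))
    }
    photo_scores <- do.call(rbind, per_photo)
    utils::write.csv(photo_scores, file.path(out, "photo_scores.csv"),
                     row.names = FALSE)
    manifest_files <- c(manifest_files, "photo_scores.csv")

    # --- stage 4: cohort + analysis ---------------------------------------
    stage <- "synth_cohort"
    cp <- config$cohort
    cp$seed <- config$seed
    cohort <- simulate_cohort(cp)
    write_cohort(cohort, file.path(out, "cohort.csv"))
    manifest_files <- c(manifest_files, "cohort.csv")
    stage <- "analyze"
    icc_ok <- function(m) {
      config$n_photos >= 2 && !isTRUE(all.equal(stats::var(as.vector(m)), 0))
    }
    study <- run_study_analysis(cohort, alpha = config$alpha,
                                icc1_ratings = if (icc_ok(sessions))
                                  sessions else NULL,
                                icc2_ratings = if (icc_ok(raters))
                                  raters else NULL)
    report_files <- write_study_report(study, file.path(out, "report"))
    manifest_files <- c(manifest_files,
                        file.path("report", basename(report_files)))
    list(photo_scores = photo_scores, cohort = cohort, study = study)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  # --- manifest ----------------------------------------------------------
  cfg_path <- file.path(out, "config.yaml")
  cfg <- config
  cfg$out_dir <- NULL   # run location is not a run parameter
  cfg$photo$palette <- lapply(cfg$photo$palette, as.numeric)
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.matrix(x)) apply(x, 1, as.numeric, simplify = FALSE) else
      unclass(x)), cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("gmrscore")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    files = sort(manifest_files))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out, "manifest.json"))
  invisible(c(res, list(manifest = manifest)))
}
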