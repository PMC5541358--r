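# End-to-end orchestration: load -> preprocess -> profiles -> background ->
# peaks/cylinder -> orientation, driven by a declarative config. Every
# interactive gesture of a GUI workflow (clicked points, slider values)
# appears here as an explicit config value, which is what makes batch
# processing reproducible.

#' Default pipeline configuration
#'
#' Returns the full nested config with every key at its default. A user
#' config (YAML/JSON) is merged over this, so only the keys that differ
#' need to be given. Required keys without defaults: `calibration$peak_pixel`
#' and `calibration$d_nm`, plus either `centre$fixed` or `centre$points`.
#'
#' @return nested list of configuration values.
#' @export
default_config <- function() {
  list(
    centre = list(points = NULL, fixed = NULL),
    calibration = list(peak_pixel = NULL, d_nm = NULL),
    mask = list(ll = -Inf, ul = Inf, ri = 0, rio = Inf),
    background = list(image_path = NULL, scale = 1, fit_radii = NULL),
    preprocess = list(fill_gaps = TRUE),
    profiles = list(radial_bin_px = 1, azimuth_bin_deg = 1),
    peaks = list(meridional_guess_px = NULL, meridional_order = 1L,
                 interfib_guess_px = NULL, window_px = 15),
    cylinder = list(mode = "auto", r_nm = NULL, amplitude = NULL,
                    fit_window_px = 15, epsilon = 1e-3,
                    exclude_half_px = 6),
    orientation = list(r_inner = NULL, r_outer = NULL, keep_harmonics = 12,
                       rotate90 = FALSE))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON, which YAML subsumes) merged over [default_config()] and
#' schema-checked: unknown top-level sections are an error, as are missing
#' calibration values or a missing centre.
#'
#' @param path config file path.
#' @return validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) saxs_io_error(paste0("config not found: ", path))
  user <- yaml::read_yaml(path)
  validate_config(merge_config(default_config(), user), names(user))
}

validate_config <- function(config, user_sections = names(config)) {
  # JSON run-logs store infinite thresholds as strings; coerce them back
  config$mask <- lapply(config$mask, function(x)
    if (is.character(x)) as.numeric(x) else x)
  unknown <- setdiff(user_sections, names(default_config()))
  if (length(unknown))
    saxs_validation_error(paste0("unknown config section(s): ",
                                 paste(unknown, collapse = ", ")))
  cal <- config$calibration
  if (is.null(cal$peak_pixel) || is.null(cal$d_nm))
    saxs_validation_error(
      "config must provide calibration$peak_pixel and calibration$d_nm")
  if (is.null(config$centre$fixed) && is.null(config$centre$points))
    saxs_validation_error("config must provide centre$fixed or centre$points")
  if (!config$cylinder$mode %in% c("auto", "manual"))
    saxs_validation_error("cylinder$mode must be 'auto' or 'manual'")
  if (config$cylinder$mode == "manual" &&
      (is.null(config$cylinder$r_nm) || is.null(config$cylinder$amplitude)))
    saxs_validation_error("cylinder mode 'manual' requires r_nm and amplitude")
  config
}

stage_wrap <- function(stage, source, expr) {
  tryCatch(expr, error = function(e) {
    saxs_abort(sprintf("[%s] %s: %s", stage, source, conditionMessage(e)),
               class(e)[1])
  })
}

#' Process one pattern end-to-end
#'
#' Runs the full reduction: load, centring, negative correction, background
#' image subtraction, threshold masking, symmetry gap filling, radial
#' integration, power-law background fit and subtraction, meridional and
#' interfibrillar peak detection, cylinder-transform fitting, Bessel
#' compensation, structure parameters, and the orientation profile.
#' Failures in the analysis stages (peaks, cylinder, compensation,
#' orientation) degrade to absent fields with a warning; failures in the
#' reduction stages propagate as errors naming the stage and source file.
#'
#' @param config a validated config (see [read_config()],
#'   [default_config()]).
#' @param image_path path to the pattern image, or a [saxs_pattern()].
#' @param out_dir if non-`NULL`, write the orientation CSV, polar-plot PNG
#'   and a JSON run-log of every parameter used into this directory.
#' @return A list of class `saxs_run` with elements `row` (one-row results
#'   data frame), `params` (`structure_params`), `profile`
#'   (background-subtracted radial profile), `orientation`, `centre`,
#'   `calibration`, `cylinder` and `stages_run`.
#' @export
run_single <- function(config, image_path, out_dir = NULL) {
  config <- validate_config(config)
  stages <- character()

  if (inherits(image_path, "saxs_pattern")) {
    p <- image_path; src <- p$source
  } else {
    src <- basename(image_path)
    p <- stage_wrap("load", src, load_pattern(image_path))
  }
  stages <- c(stages, "load")

  centre <- if (!is.null(config$centre$fixed)) as.numeric(config$centre$fixed)
    else stage_wrap("centre", src, {
      fit <- fit_circle(do.call(rbind, lapply(config$centre$points, as.numeric)))
      fit$centre
    })
  stages <- c(stages, "centre")

  cal <- make_calibration(config$calibration$peak_pixel, config$calibration$d_nm)

  p <- correct_negative(p)
  stages <- c(stages, "negative_correction")

  if (!is.null(config$background$image_path)) {
    bg_img <- stage_wrap("background_image", src,
                         load_pattern(config$background$image_path))
    p <- stage_wrap("background_image", src,
                    subtract_background_image(p, bg_img,
                                              config$background$scale))
    stages <- c(stages, "background_image")
  }

  spec <- mask_spec(config$mask$ll, config$mask$ul, config$mask$ri,
                    config$mask$rio)
  p <- apply_mask(p, spec)
  stages <- c(stages, "mask")

  if (isTRUE(config$preprocess$fill_gaps) && !all(p$valid)) {
    p <- stage_wrap("fill_gaps", src, fill_gaps(p, centre))
    stages <- c(stages, "fill_gaps")
  }

  profile <- stage_wrap("radial_profile", src,
                        integrate_radial(p, centre,
                                         bin_px = config$profiles$radial_bin_px))
  stages <- c(stages, "radial_profile")

  bg_fit <- NULL; sub <- profile
  if (!is.null(config$background$fit_radii)) {
    bg_fit <- stage_wrap("background_fit", src,
                         fit_power_law(profile,
                                       as.numeric(config$background$fit_radii)))
    sub <- subtract_power_law(profile, bg_fit)
    stages <- c(stages, "background_fit")
  }

  soft <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      warning(sprintf("[%s] %s: %s", stage, src, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  }

  merid <- if (!is.null(config$peaks$meridional_guess_px))
    soft("meridional_peak",
         find_nearest_peak(sub, config$peaks$meridional_guess_px,
                           config$peaks$window_px))
  interfib <- if (!is.null(config$peaks$interfib_guess_px))
    soft("interfibrillar_peak",
         find_nearest_peak(sub, config$peaks$interfib_guess_px,
                           config$peaks$window_px))

  cyl <- NULL
  if (!is.null(config$cylinder$r_nm)) {
    exclude <- if (!is.null(merid))
      cbind(merid$position_px - config$cylinder$exclude_half_px,
            merid$position_px + config$cylinder$exclude_half_px)
    cyl <- soft("cylinder_fit",
                fit_cylinder_transform(sub, cal, config$cylinder$r_nm,
                                       config$cylinder$amplitude,
                                       mode = config$cylinder$mode,
                                       fit_window_px = config$cylinder$fit_window_px,
                                       exclude_px = exclude))
    if (!is.null(cyl)) stages <- c(stages, "cylinder_fit")
  }

  interfib_comp <- NULL
  if (!is.null(cyl) && !is.null(config$peaks$interfib_guess_px)) {
    interfib_comp <- soft("bessel_compensation", {
      G <- bessel_compensate(sub, cyl, cal, config$cylinder$epsilon)
      find_nearest_peak(G, config$peaks$interfib_guess_px,
                        config$peaks$window_px)
    })
    if (!is.null(interfib_comp)) stages <- c(stages, "bessel_compensation")
  }

  params <- compute_structure_params(cal, merid,
                                     config$peaks$meridional_order,
                                     interfib, interfib_comp, cyl)
  stages <- c(stages, "structure_params")

  orient <- NULL
  if (!is.null(config$orientation$r_inner) &&
      !is.null(config$orientation$r_outer)) {
    orient <- soft("orientation",
                   aligned_scatter(p, centre, config$orientation$r_inner,
                                   config$orientation$r_outer, bg_fit,
                                   config$profiles$azimuth_bin_deg,
                                   config$orientation$keep_harmonics))
    if (!is.null(orient)) stages <- c(stages, "orientation")
  }

  row <- results_row(src, centre, params, stages)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stem <- tools::file_path_sans_ext(src)
    if (!is.null(orient))
      write_polar_plot(orient, file.path(out_dir, paste0(stem, "_polar.png")),
                       rotate90 = isTRUE(config$orientation$rotate90))
    runlog <- list(image = if (is.character(image_path)) image_path else src,
                   config = config, centre = as.numeric(centre),
                   stages_run = stages)
    jsonlite::write_json(runlog,
                         file.path(out_dir, paste0(stem, "_runlog.json")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }

  structure(list(row = row, params = params, profile = sub,
                 orientation = orient, centre = centre, calibration = cal,
                 cylinder = cyl, background = bg_fit, pattern = p,
                 stages_run = stages),
            class = "saxs_run")
}

#' @export
print.saxs_run <- function(x, ...) {
  cat(sprintf("SAXS run: %s  (stages: %s)\n", x$row$source,
              paste(x$stages_run, collapse = " > ")))
  print(x$params)
  invisible(x)
}

#' Re-run a processing job from its JSON run-log
#'
#' The run-log written by [run_single()] captures the image path and every
#' parameter used, so replaying it reproduces the run exactly.
#'
#' @param log_path path to a `*_runlog.json` file.
#' @param out_dir output directory (as in [run_single()]).
#' @return the [run_single()] result.
#' @export
run_from_log <- function(log_path, out_dir = NULL) {
  log <- jsonlite::read_json(log_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  run_single(log$config, log$image, out_dir)
}

#' Batch-process a directory of patterns
#'
#' Processes every TIFF/PNG/JPEG in `image_dir` in lexicographic order with
#' the same parameters (retained background, cylinder-transform and peak
#' settings), accumulating all rows into one common results table. A
#' failing image is recorded and processing continues.
#'
#' @param config pipeline config.
#' @param image_dir directory of images.
#' @param out_dir if non-`NULL`, per-image artifacts and a combined
#'   `results.csv` are written here.
#' @return A results `data.frame` (one row per image, including failed ones
#'   with their error message), with attribute `n_failed`.
#' @export
run_batch <- function(config, image_dir, out_dir = NULL) {
  config <- validate_config(config)
  files <- sort(list.files(image_dir, full.names = TRUE,
                           pattern = "\\.(tif|tiff|png|jpg|jpeg)$",
                           ignore.case = TRUE))
  if (length(files) == 0L)
    saxs_empty_data_error(paste0("no loadable images in ", image_dir))
  rows <- vector("list", length(files))
  n_failed <- 0L
  for (i in seq_along(files)) {
    rows[[i]] <- tryCatch(run_single(config, files[i], out_dir)$row,
                          error = function(e) {
                            n_failed <<- n_failed + 1L
                            message("batch: ", conditionMessage(e))
                            results_row(basename(files[i]),
                                        error = conditionMessage(e))
                          })
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(out, file.path(out_dir, "results.csv"))
  }
  attr(out, "n_failed") <- n_failed
  out
}
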