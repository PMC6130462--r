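# File formats: geometry JSON, reflection-table CSV, panel TIFF, manifest.

node_to_list <- function(node) {
  out <- list(name = node$name, level = node$level,
              d0 = node$frame$d0, dx = node$frame$dx, dy = node$frame$dy)
  if (!is.null(node$panel))
    out$panel <- list(n_fast = node$panel$n_fast, n_slow = node$panel$n_slow,
                      pixel_size = c(node$panel$pixel_size_fast,
                                     node$panel$pixel_size_slow))
  if (length(node$children))
    out$children <- lapply(node$children, node_to_list)
  out
}

list_to_node <- function(x) {
  for (fld in c("name", "level", "d0", "dx", "dy"))
    if (is.null(x[[fld]])) stop("geometry JSON: missing field '", fld, "'")
  if (!is.null(x$children) && !is.list(x$children))
    stop("geometry JSON: malformed children list under '", x$name, "'")
  panel <- NULL
  if (!is.null(x$panel)) {
    p <- x$panel
    for (fld in c("n_fast", "n_slow", "pixel_size"))
      if (is.null(p[[fld]])) stop("geometry JSON: panel missing '", fld,
                                  "' under '", x$name, "'")
    psz <- unlist(p$pixel_size)
    panel <- list(n_fast = as.integer(p$n_fast), n_slow = as.integer(p$n_slow),
                  pixel_size_fast = psz[1],
                  pixel_size_slow = psz[if (length(psz) > 1) 2 else 1])
  }
  new_detector_node(x$name, x$level,
                    frame(d0 = unlist(x$d0), dx = unlist(x$dx),
                          dy = unlist(x$dy)),
                    children = if (is.null(x$children)) list()
                               else lapply(x$children, list_to_node),
                    panel = panel)
}

#' Read and write detector geometry as JSON
#'
#' The schema is a nested object per hierarchy node: `name`, `level`,
#' `d0`, `dx`, `dy`, optional `children` and (leaves only) `panel =
#' {n_fast, n_slow, pixel_size}`.  Writing and re-reading is lossless to
#' full double precision; the reader validates all frame and tree
#' invariants and names the offending field on failure.
#'
#' @param det a [detector()].
#' @param path file path.
#' @return `read_geometry`: a [detector()]; `write_geometry`: `path`,
#'   invisibly.
#' @export
write_geometry <- function(det, path) {
  jsonlite::write_json(node_to_list(det$root), path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  detector(list_to_node(jsonlite::read_json(path, simplifyVector = FALSE)))
}

reflection_columns <- c("image_id", "panel", "h", "k", "l", "x_obs_mm",
                        "y_obs_mm", "var_x", "var_y", "x_calc_mm",
                        "y_calc_mm", "delta_psi_rad", "intensity", "sigma_c",
                        "flags")

#' Read and write reflection tables as CSV
#'
#' Fixed column order `image_id, panel, h, k, l, x_obs_mm, y_obs_mm,
#' var_x, var_y, x_calc_mm, y_calc_mm, delta_psi_rad, intensity, sigma_c,
#' flags` with a mandatory header; missing calculated fields are written
#' empty.  Extra columns are preserved on read with a warning.
#'
#' @param refl data.frame using the package's internal names (`x_obs`,
#'   `x_calc`, `psi`, ...); missing columns are written as NA.
#' @param path file path.
#' @return `read_reflections`: data.frame with internal names.
#' @export
write_reflections <- function(refl, path) {
  map <- c(x_obs_mm = "x_obs", y_obs_mm = "y_obs", x_calc_mm = "x_calc",
           y_calc_mm = "y_calc", delta_psi_rad = "psi")
  out <- data.frame(row.names = seq_len(nrow(refl)))
  for (col in reflection_columns) {
    src <- if (col %in% names(map)) map[[col]] else col
    out[[col]] <- if (src %in% names(refl)) refl[[src]] else NA
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_reflections
#' @export
read_reflections <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(reflection_columns, names(df))
  if (length(miss))
    stop("reflection CSV: missing columns ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), reflection_columns)
  if (length(extra))
    warning("reflection CSV: extra columns preserved: ",
            paste(extra, collapse = ", "))
  names(df)[match(c("x_obs_mm", "y_obs_mm", "x_calc_mm", "y_calc_mm",
                    "delta_psi_rad"), names(df))] <-
    c("x_obs", "y_obs", "x_calc", "y_calc", "psi")
  df
}

#' Write and read a panel image as TIFF
#'
#' 32-bit float TIFF via the `tiff` package (suggested dependency).
#'
#' @param img numeric matrix.
#' @param path file path.
#' @return `read_panel_tiff`: numeric matrix.
#' @export
write_panel_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
  img[!is.finite(img)] <- 0
  tiff::writeTIFF(img / max(img, 1), path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_panel_tiff
#' @export
read_panel_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF input")
  tiff::readTIFF(path)
}

#' Write a simulation manifest
#'
#' Records the full configuration (including the seed) and the injected
#' detector perturbations, so any generated experiment and its recovery
#' score can be reproduced bit-identically.
#'
#' @param bundle an [make_experiment()] bundle.
#' @param path file path.
#' @export
write_manifest <- function(bundle, path) {
  cfg <- unclass(bundle$config)
  jsonlite::write_json(list(config = cfg,
                            perturbations = bundle$manifest),
                       path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Assemble a run configuration
#'
#' Collects the pipeline-level settings with the canonical defaults
#' (psi weight 1e6, fractional-index cutoff 0.3, Tukey k = 1.5, 0.05
#' degree psi window, multi-angle scan 20-70 degrees in 2.5-degree
#' steps), optionally overridden from a YAML file and then by named
#' arguments; an explicit `seed` argument always wins over the file.
#'
#' @param path optional YAML file with any subset of the fields.
#' @param ... named overrides.
#' @return a named list of class `"run_config"`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(seed = 1L, n_images = 50L, engine = "sparse_levmar",
              mode = "expanding", w_psi = 1e6, cutoff = 0.3,
              tukey_k = 1.5, psi_window_deg = 0.05,
              angles_deg = seq(20, 70, by = 2.5), batch_size = 50L,
              n_cycles = 4L)
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read config files")
    over <- yaml::read_yaml(path)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' End-to-end synthetic pipeline
#'
#' Simulate, align quadrants from a virtual powder pattern, assign
#' indices, run reindex-refine cycles, and fit the intensity error models
#' -- the full workflow on synthetic data, driven by one seed.
#'
#' @param seed integer seed.
#' @param n_images images to simulate.
#' @param n_cycles refinement cycles.
#' @param mode protocol mode.
#' @param detector detector arguments (see [sim_config()]); the default
#'   uses reduced panels so the powder-alignment stage stays fast.
#' @param out_dir optional directory for geometry/reflections/manifest
#'   outputs.
#' @param ... passed to [sim_config()].
#' @return list with the bundle, alignment result, cycle report and
#'   recovery score.
#' @export
end_to_end <- function(seed, n_images = 50L, n_cycles = 2L,
                       mode = "expanding",
                       detector = list(distance = 130, asic_fast = 48L,
                                       asic_slow = 44L, pixel = 0.5),
                       out_dir = NULL, ...) {
  cfg <- sim_config(seed = seed, n_images = n_images, detector = detector, ...)
  bundle <- make_experiment(cfg)
  rr <- fixture_ring_radii(seed = seed)
  pw <- render_powder(bundle$true_det, bundle$work_det, ring_radii = rr)
  al <- align_quadrants(pw, bundle$work_det)
  cyc <- run_cycles(al$det, bundle$crystals, bundle$beams, bundle$obs,
                    n_cycles = n_cycles, mode = mode)
  rec <- recovery_errors(bundle$true_det, cyc$det)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_geometry(cyc$det, file.path(out_dir, "refined_geometry.json"))
    write_manifest(bundle, file.path(out_dir, "manifest.json"))
    utils::write.csv(cyc$report, file.path(out_dir, "cycle_report.csv"),
                     row.names = FALSE)
  }
  list(bundle = bundle, alignment = al, cycles = cyc, recovery = rec)
}
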