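# End-to-end pipeline orchestration and headless colour-map export.

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or YAML file) with components:
#' `seed` (integer), `out` (output directory), optional `phantom`
#' (`grid_shape`, `snr`, `radii` per-region cylinder radii in um,
#' `diffusivity`), optional `qsi` (`grid_size`, `interp`, `tensor_mode`),
#' optional `stats` (`reference`, `alpha`), and optional `paths` whose
#' entries must all exist (`dwi`, `scheme` stem, `mask`).
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) config$seed <- 1L
  if (config$seed != round(config$seed)) stop("seed must be an integer", call. = FALSE)
  if (is.null(config$out)) stop("config$out (output directory) required", call. = FALSE)
  ph <- config$phantom
  if (is.null(ph)) ph <- list()
  if (is.null(ph$grid_shape)) ph$grid_shape <- c(16L, 16L, 4L)
  if (is.null(ph$snr)) ph$snr <- 50
  if (is.null(ph$radii)) ph$radii <- c(ta = 30, sol = 25, gas = 40)
  if (is.null(ph$diffusivity)) ph$diffusivity <- 2.0e-3
  config$phantom <- ph
  qs <- config$qsi
  if (is.null(qs)) qs <- list()
  if (is.null(qs$grid_size)) qs$grid_size <- 4096L
  if (is.null(qs$interp)) qs$interp <- "monotone"
  if (is.null(qs$tensor_mode)) qs$tensor_mode <- "squared"
  config$qsi <- qs
  st <- config$stats
  if (is.null(st)) st <- list()
  if (is.null(st$reference)) st$reference <- "control"
  if (is.null(st$alpha)) st$alpha <- 0.05
  if (!(st$alpha > 0 && st$alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  config$stats <- st
  for (p in unlist(config$paths)) {
    if (!file.exists(p)) stop("configured path does not exist: ", p, call. = FALSE)
  }
  config
}

#' Run the full analysis pipeline on a synthetic scan
#'
#' Simulates (or loads) a diffusion-weighted volume, runs the DTI and QSI
#' fits, aggregates muscle ROIs into a subjects table, appends a simulated
#' cohort, computes the group-summary and Spearman-correlation tables, and
#' renders a radial-FWHM colour map. Every product is listed in
#' `manifest.tsv` with an MD5 content hash; reruns with the same seed
#' produce identical hashes.
#'
#' @param config See [validate_config()].
#' @return Invisibly, a tibble manifest (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  scheme <- muscle_protocol()
  ph <- config$phantom
  gs <- as.integer(ph$grid_shape)

  # phantom with one cylinder region per muscle, side by side along x
  nreg <- length(ph$radii)
  regions <- array(0L, dim = gs)
  cuts <- round(seq(0, gs[1], length.out = nreg + 1))
  for (r in seq_len(nreg)) {
    regions[(cuts[r] + 1):cuts[r + 1], , ] <- r
  }
  mixes <- lapply(ph$radii, function(R) {
    list(cylinder_compartment(R, diffusivity = ph$diffusivity))
  })
  spec <- phantom_spec(gs, unname(mixes), scheme,
                       snr = if (identical(ph$snr, "Inf")) Inf else ph$snr,
                       seed = config$seed, regions = regions)
  phant <- generate_phantom(spec)
  write_phantom(phant, file.path(out, "phantom"))

  dti <- dti_fit(phant)
  qsi <- qsi_fit(phant, grid_size = config$qsi$grid_size,
                 interp = config$qsi$interp,
                 tensor_mode = config$qsi$tensor_mode)
  maps <- c(result_maps(dti, gs, "rd"),
            result_maps(qsi, gs, c("radial_fwhm", "flambda1")))
  for (nm in names(maps)) {
    RNifti::writeNifti(RNifti::asNifti(.na_to_zero(maps[[nm]])),
                       file.path(out, paste0(nm, ".nii")))
  }

  labels <- stats::setNames(seq_len(nreg), names(ph$radii))
  subj_img <- roi_summary(maps, regions, labels = labels,
                          subject_id = "phantom")
  write_subjects(subj_img, file.path(out, "subjects_imaging.tsv"))

  cohort <- simulate_cohort(seed = config$seed)
  write_subjects(cohort, file.path(out, "subjects.tsv"))
  vars <- c("smi", "pa", "csa", "rd", "radial_fwhm")
  for (m in unique(cohort$muscle)) {
    cm <- cohort[cohort$muscle == m, ]
    sp <- spearman_matrix(cm, vars)
    utils::write.table(round(sp$rho, 2),
                       file.path(out, paste0("correlation_", m, ".tsv")),
                       sep = "\t", quote = FALSE)
    gsum <- group_summary(cm, c("smi", "radial_fwhm", "rd", "csa"),
                          reference = config$stats$reference,
                          alpha = config$stats$alpha)
    write_subjects(gsum, file.path(out, paste0("groups_", m, ".tsv")))
  }

  export_colormap(maps$radial_fwhm, slice = ceiling(gs[3] / 2),
                  range = c(0, 40),
                  file = file.path(out, "radial_fwhm_map.png"))

  files <- sort(setdiff(list.files(out, recursive = TRUE), "manifest.tsv"))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out, files))))
  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

.na_to_zero <- function(m) { m[!is.finite(m)] <- 0; m }

#' Headless colour-map rendering of a scalar slice
#'
#' Pure function of (map, slice, range, palette): maps values onto a
#' perceptually uniform palette, clips outside `range`, optionally
#' alpha-blends over a grayscale underlay, appends a vertical colour bar,
#' and writes a PNG. Re-rendering the same inputs is byte-identical.
#'
#' @param map 3-D numeric array (or 2-D slice).
#' @param slice Slice index along the third dimension.
#' @param range Length-2 display range `(lo, hi)`, `lo < hi`.
#' @param file Output PNG path.
#' @param underlay Optional volume/slice of the same in-plane shape.
#' @param underlay_alpha Weight of the colour map over the underlay.
#' @param palette Palette name for [grDevices::hcl.colors()].
#' @return Invisibly, the rendered RGB array (rows x cols x 3).
#' @export
export_colormap <- function(map, slice = 1, range, file, underlay = NULL,
                            underlay_alpha = 0.6, palette = "viridis") {
  map <- unclass(map)
  sl <- if (length(dim(map)) == 3) map[, , slice] else map
  if (!is.matrix(sl)) stop("slice is not 2-D", call. = FALSE)
  if (all(!is.finite(sl))) stop("all-invalid slice", call. = FALSE)
  if (!(length(range) == 2 && range[1] < range[2])) {
    stop("range must be (lo, hi) with lo < hi", call. = FALSE)
  }
  cols <- t(grDevices::col2rgb(grDevices::hcl.colors(256, palette))) / 255
  z <- (pmin(pmax(sl, range[1]), range[2]) - range[1]) / diff(range)
  idx <- 1L + as.integer(round(z * 255))
  rgb <- array(0, dim = c(nrow(sl), ncol(sl), 3))
  for (ch in 1:3) {
    v <- cols[idx, ch]
    v[!is.finite(sl)] <- 0.25          # invalid voxels: dark gray
    rgb[, , ch] <- matrix(v, nrow(sl), ncol(sl))
  }
  if (!is.null(underlay)) {
    underlay <- unclass(underlay)
    usl <- if (length(dim(underlay)) == 3) underlay[, , slice] else underlay
    stopifnot(all(dim(usl) == dim(sl)))
    ur <- range(usl[is.finite(usl)])
    ug <- (usl - ur[1]) / max(ur[2] - ur[1], .Machine$double.eps)
    ug[!is.finite(ug)] <- 0
    for (ch in 1:3) {
      rgb[, , ch] <- underlay_alpha * rgb[, , ch] + (1 - underlay_alpha) * ug
    }
  }
  bar <- matrix(rev(seq_len(256)), 256, 12)
  barR <- array(0, dim = c(256, 12, 3))
  for (ch in 1:3) barR[, , ch] <- matrix(cols[bar, ch], 256, 12)
  h <- max(nrow(sl), 256)
  canvas <- array(0, dim = c(h, ncol(sl) + 16, 3))
  canvas[seq_len(nrow(sl)), seq_len(ncol(sl)), ] <- rgb
  canvas[seq_len(256), ncol(sl) + 4 + seq_len(12), ] <- barR
  png::writePNG(canvas, file)
  invisible(canvas)
}
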