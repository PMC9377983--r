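# ROI aggregation: label-mask means, the triplicate + left/right replicate
# averaging scheme, and anatomical cross-sectional area.

#' Mean of a scalar map over one ROI label
#'
#' Arithmetic mean of the finite voxels under `label`; non-finite voxels
#' are excluded and counted.
#'
#' @param map 3-D numeric array (or a map from [result_maps()]).
#' @param mask Integer label array, same shape; 0 = background.
#' @param label Label to aggregate (>= 1).
#' @return A tibble with `label`, `mean`, `n_voxels`, `n_excluded`.
#' @export
roi_mean <- function(map, mask, label) {
  map <- unclass(map); mask <- unclass(mask)
  if (!all(dim(map) == dim(mask))) {
    stop("map and mask shapes differ", call. = FALSE)
  }
  v <- map[mask == label]
  if (!length(v)) stop("empty ROI label: ", label, call. = FALSE)
  ok <- is.finite(v)
  tibble::tibble(label = label, mean = mean(v[ok]),
                 n_voxels = sum(ok), n_excluded = sum(!ok))
}

#' Triplicate and left/right replicate averaging
#'
#' Three replicate measurements per side are averaged, then the two side
#' means are averaged. If one side is missing, the other side's mean is
#' returned with `single_side = TRUE`.
#'
#' @param left,right Numeric vectors of exactly 3 replicate values
#'   (either may be `NULL` for a missing side).
#' @return A tibble with `value` and `single_side`.
#' @export
replicate_average <- function(left = NULL, right = NULL) {
  sides <- list(left = left, right = right)
  sides <- sides[!vapply(sides, is.null, logical(1))]
  if (!length(sides)) stop("at least one side required", call. = FALSE)
  for (s in sides) {
    if (length(s) != 3) stop("exactly 3 replicates per side required", call. = FALSE)
  }
  single <- length(sides) == 1
  if (single) warning("missing side: returning single-side value", call. = FALSE)
  tibble::tibble(value = mean(vapply(sides, mean, numeric(1))),
                 single_side = single)
}

#' Anatomical cross-sectional area of an ROI on one slice
#'
#' Voxel count under the label on the selected axial slice times the
#' in-plane pixel area, converted to cm^2.
#'
#' @param mask Integer label array (3-D) or matrix (single slice).
#' @param label Label to measure.
#' @param pixel_area_mm2 In-plane pixel area, mm^2.
#' @param slice Axial slice index (third dimension) when `mask` is 3-D.
#' @return CSA in cm^2.
#' @export
cross_sectional_area <- function(mask, label, pixel_area_mm2, slice = NULL) {
  mask <- unclass(mask)
  if (length(dim(mask)) == 3) {
    if (is.null(slice)) stop("slice index required for a 3-D mask", call. = FALSE)
    if (slice < 1 || slice > dim(mask)[3]) stop("slice out of bounds", call. = FALSE)
    mask <- mask[, , slice]
  }
  n <- sum(mask == label)
  if (n == 0) stop("empty ROI label on slice: ", label, call. = FALSE)
  n * pixel_area_mm2 / 100
}

#' Resample a label mask onto a map grid (nearest neighbour)
#'
#' ROI masks drawn on a high-resolution anatomical grid are mapped onto
#' the coarser diffusion grid by nearest-neighbour lookup of voxel-centre
#' coordinates (labels must never be interpolated).
#'
#' @param mask Integer label array on the source grid.
#' @param dim_target Target grid dimensions (length 3).
#' @return Integer label array on the target grid; a message reports the
#'   resampling.
#' @export
resample_mask <- function(mask, dim_target) {
  mask <- unclass(mask)
  ds <- dim(mask)
  if (all(ds == dim_target)) return(mask)
  message(sprintf("resampling mask %s -> %s (nearest neighbour)",
                  paste(ds, collapse = "x"),
                  paste(dim_target, collapse = "x")))
  idx <- lapply(1:3, function(a) {
    pmin(ds[a], pmax(1L, round((seq_len(dim_target[a]) - 0.5) *
                                 ds[a] / dim_target[a] + 0.5)))
  })
  mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Per-subject, per-muscle ROI summary of fitted maps
#'
#' Applies [roi_mean()] for every requested muscle label to the RD and
#' radial-FWHM maps and measures CSA on the reference slice, producing one
#' row per muscle. The soleus (crossed-fibre architecture) is flagged
#' `unreliable_crossed_fiber`.
#'
#' @param maps Named list of 3-D maps containing at least `rd` and
#'   `radial_fwhm` (see [result_maps()]).
#' @param mask Integer label array (resampled onto the map grid if shapes
#'   differ).
#' @param labels Named integer vector, e.g. `c(ta = 1, sol = 2, gas = 3)`.
#' @param pixel_area_mm2 In-plane pixel area of the mask grid, mm^2.
#' @param csa_slice Reference slice for CSA (default: middle slice).
#' @param subject_id Identifier copied into the output.
#' @return A tibble: `subject_id`, `muscle`, `rd`, `radial_fwhm`, `csa`,
#'   `n_voxels`, `flag`.
#' @export
roi_summary <- function(maps, mask, labels = c(ta = 1, sol = 2, gas = 3),
                        pixel_area_mm2 = 3.12^2, csa_slice = NULL,
                        subject_id = NA_character_) {
  stopifnot(all(c("rd", "radial_fwhm") %in% names(maps)))
  dim3 <- dim(maps$rd)
  mask <- resample_mask(mask, dim3)
  if (is.null(csa_slice)) csa_slice <- ceiling(dim3[3] / 2)
  purrr::map_dfr(names(labels), function(m) {
    lb <- labels[[m]]
    rd_stat <- roi_mean(maps$rd, mask, lb)
    fw_stat <- roi_mean(maps$radial_fwhm, mask, lb)
    tibble::tibble(
      subject_id = subject_id, muscle = m,
      rd = rd_stat$mean, radial_fwhm = fw_stat$mean,
      csa = cross_sectional_area(mask, lb, pixel_area_mm2, csa_slice),
      n_voxels = rd_stat$n_voxels,
      flag = if (identical(m, "sol")) "unreliable_crossed_fiber" else "ok")
  })
}
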