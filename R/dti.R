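# Conventional diffusion-tensor fit on the b = {0, 800} s/mm^2 subset,
# giving radial diffusivity RD = (lambda2 + lambda3) / 2.

#' Apparent diffusion coefficient from a two-point fit
#'
#' ADC = -ln(S_b / S_0) / b, clamped at zero when the attenuated signal
#' exceeds the reference (noise).
#'
#' @param s0 Unweighted signal (> 0).
#' @param s_b Diffusion-weighted signal.
#' @param b b-value, s/mm^2 (> 0).
#' @return ADC, mm^2/s (vectorized); `NA` where `s0 <= 0` or `s_b <= 0`.
#' @export
adc_per_direction <- function(s0, s_b, b) {
  if (any(b <= 0)) stop("b must be positive", call. = FALSE)
  adc <- -log(s_b / s0) / b
  adc <- pmax(adc, 0)
  adc[s0 <= 0 | s_b <= 0] <- NA_real_
  adc
}

#' Least-squares symmetric-tensor fit to directional measurements
#'
#' Solves g_i' D g_i = y_i in the least-squares sense (exact for six
#' independent directions). Negative eigenvalues are clamped to zero with
#' a warning.
#'
#' @param values Directional measurements (>= 6), e.g. per-direction ADC.
#' @param directions Matrix of unit vectors, one row per measurement;
#'   design matrix must have rank 6.
#' @return A `sym_tensor`.
#' @export
fit_tensor <- function(values, directions) {
  if (length(values) != nrow(as.matrix(directions))) {
    stop("one value per direction required", call. = FALSE)
  }
  if (anyNA(values)) stop("invalid (NA) directional values", call. = FALSE)
  comp <- solve_tensor_ls(directions, values)
  sym_tensor(drop(comp), clamp_negative = TRUE)
}

#' Radial diffusivity of a diffusion tensor
#'
#' RD = (lambda2 + lambda3) / 2, the mean of the two minor eigenvalues.
#'
#' @param tensor A `sym_tensor`.
#' @return RD in the tensor's units (mm^2/s for diffusivity).
#' @export
radial_diffusivity <- function(tensor) {
  stopifnot(inherits(tensor, "sym_tensor"))
  (tensor$values[2] + tensor$values[3]) / 2
}

#' Voxelwise DTI fit of a 4-D diffusion-weighted volume
#'
#' Uses only the b = 0 and `b_dti` shells, per the conventional
#' monoexponential two-point ADC. The b0 estimate is the mean of the b = 0
#' replicates; voxels whose b0 falls below `s0_floor` (default 5x an
#' estimated noise floor) are masked out.
#'
#' @param dwi 4-D array (x, y, z, volume) ordered as
#'   [scheme_measurements()], or the list returned by [generate_phantom()].
#' @param scheme A `gradient_scheme` (taken from `dwi` if a phantom list).
#' @param b_dti b-value of the weighted shell used for the fit (the
#'   closest shell is selected), s/mm^2.
#' @param mask Optional logical/0-1 3-D array of voxels to fit.
#' @param s0_floor Minimum b0 signal; `NULL` for the default rule.
#' @return A tibble, one row per fitted voxel: voxel indices `i, j, k`,
#'   eigenvalues `lambda1..lambda3` (mm^2/s) and `rd`.
#' @examples
#' ph <- generate_phantom(phantom_spec(c(3, 3, 1),
#'   gaussian_compartment(c(1.7, 0.3, 0.2) * 1e-3), muscle_protocol(),
#'   snr = Inf))
#' dti_fit(ph)
#' @export
dti_fit <- function(dwi, scheme = NULL, b_dti = 800, mask = NULL,
                    s0_floor = NULL) {
  x <- .as_dwi(dwi, scheme)
  meas <- scheme_measurements(x$scheme)
  i0 <- meas$volume[meas$b == 0]
  if (!length(i0)) stop("scheme has no b = 0 measurement", call. = FALSE)
  shell_b <- x$scheme$b_values
  s_sel <- which.min(abs(shell_b - b_dti))
  if (shell_b[s_sel] <= 0) stop("no weighted shell available", call. = FALSE)
  b_used <- shell_b[s_sel]
  iw <- meas$volume[meas$shell == s_sel]
  dirs <- x$scheme$directions[meas$direction[match(iw, meas$volume)], ,
                              drop = FALSE]
  assert_design_rank(dirs)

  sig <- matrix(x$dwi, prod(x$dim3), dim(x$dwi)[4])
  s0 <- rowMeans(sig[, i0, drop = FALSE])
  if (is.null(s0_floor)) s0_floor <- 5 * .noise_floor(sig)
  keep <- s0 > s0_floor & s0 > 0
  if (!is.null(mask)) keep <- keep & (as.vector(mask) > 0)
  vox <- which(keep)

  Sb <- sig[vox, iw, drop = FALSE]
  adc <- adc_per_direction(rep(s0[vox], ncol(Sb)), as.vector(Sb),
                           b_used)
  adc <- matrix(adc, length(vox), ncol(Sb))
  comp <- solve_tensor_ls(dirs, t(adc))          # 6 x nvox
  lam <- apply(comp, 2, function(v) {
    ev <- eigen(tensor_from_components(v), symmetric = TRUE,
                only.values = TRUE)$values
    pmax(ev, 0)
  })
  ijk <- arrayInd(vox, x$dim3)
  tibble::tibble(
    voxel = vox, i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    lambda1 = lam[1, ], lambda2 = lam[2, ], lambda3 = lam[3, ],
    rd = (lam[2, ] + lam[3, ]) / 2)
}

# Background-noise floor estimate: a small quantile of all signal values.
.noise_floor <- function(sig) stats::quantile(sig, 0.01, names = FALSE) / 5

# Accept a phantom list, an RNifti image or a plain 4-D array.
.as_dwi <- function(dwi, scheme) {
  if (is.list(dwi) && !is.null(dwi$dwi)) {
    if (is.null(scheme)) scheme <- dwi$scheme
    dwi <- dwi$dwi
  }
  if (is.null(scheme)) stop("a gradient_scheme is required", call. = FALSE)
  dwi <- unclass(dwi)
  if (length(dim(dwi)) != 4) stop("dwi must be a 4-D array", call. = FALSE)
  nvol <- length(scheme$b_values) * nrow(scheme$directions)
  if (dim(dwi)[4] != nvol) {
    stop(sprintf("dwi has %d volumes but the scheme implies %d",
                 dim(dwi)[4], nvol), call. = FALSE)
  }
  list(dwi = dwi, scheme = scheme, dim3 = dim(dwi)[1:3])
}

#' Rebuild 3-D maps from a voxelwise result tibble
#'
#' @param result Tibble from [dti_fit()] or [qsi_fit()].
#' @param dim3 Grid dimensions, length 3.
#' @param columns Which columns to reshape; default all numeric metric
#'   columns.
#' @return Named list of 3-D arrays (`NA` outside fitted voxels).
#' @export
result_maps <- function(result, dim3, columns = NULL) {
  if (is.null(columns)) {
    columns <- setdiff(names(result)[vapply(result, is.numeric, logical(1))],
                       c("voxel", "i", "j", "k"))
  }
  out <- lapply(columns, function(cl) {
    m <- array(NA_real_, dim = dim3)
    m[result$voxel] <- result[[cl]]
    m
  })
  names(out) <- columns
  out
}
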