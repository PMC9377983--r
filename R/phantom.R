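# Synthetic restricted-diffusion phantom: Gaussian-tensor and
# restricted-cylinder compartments under a PGSE protocol, with Rician noise.

#' Gaussian (free-diffusion) tensor compartment
#'
#' Monoexponential compartment E = exp(-b g' D g) with an axially symmetric
#' or general diffusion tensor specified by its eigenvalues and principal
#' axis.
#'
#' @param eigenvalues Length-3, mm^2/s, sorted descending (lambda1 >=
#'   lambda2 >= lambda3 >= 0).
#' @param axis Principal (lambda1) axis, length-3; normalized internally.
#' @param volume_fraction In `[0, 1]`.
#' @return A `compartment_spec`.
#' @export
gaussian_compartment <- function(eigenvalues, axis = c(0, 0, 1),
                                 volume_fraction = 1) {
  stopifnot(length(eigenvalues) == 3)
  if (any(eigenvalues < 0) || is.unsorted(rev(eigenvalues))) {
    stop("eigenvalues must be non-negative and sorted descending", call. = FALSE)
  }
  .check_fraction(volume_fraction)
  structure(list(model = "gaussian_tensor",
                 eigenvalues = as.numeric(eigenvalues),
                 axis = .unit(axis), volume_fraction = volume_fraction),
            class = "compartment_spec")
}

#' Restricted-cylinder compartment
#'
#' Water inside an impermeable cylinder of given radius: free Gaussian
#' diffusion along the axis, restricted diffusion across it modelled with
#' the Gaussian phase distribution (GPD) approximation for finite gradient
#' duration (see [signal_cylinder()]).
#'
#' @param radius Cylinder radius, um, in (0, 200].
#' @param diffusivity Free (axial/intrinsic) diffusivity, mm^2/s.
#' @param axis Cylinder axis, length-3; normalized internally.
#' @param volume_fraction In `[0, 1]`.
#' @return A `compartment_spec`.
#' @export
cylinder_compartment <- function(radius, diffusivity = 2.0e-3,
                                 axis = c(0, 0, 1), volume_fraction = 1) {
  if (!(radius > 0 && radius <= 200)) {
    stop("cylinder radius must be in (0, 200] um", call. = FALSE)
  }
  stopifnot(diffusivity >= 0)
  .check_fraction(volume_fraction)
  structure(list(model = "restricted_cylinder", radius = radius,
                 diffusivity = diffusivity, axis = .unit(axis),
                 volume_fraction = volume_fraction),
            class = "compartment_spec")
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("axis must be non-zero", call. = FALSE)
  v / n
}

.check_fraction <- function(f) {
  if (!(f >= 0 && f <= 1)) stop("volume_fraction must be in [0, 1]", call. = FALSE)
}

#' Normalized Gaussian-compartment signal
#'
#' @param scheme A `gradient_scheme`.
#' @param shell_index Shell (b/q) index into the scheme.
#' @param direction_index Direction index into the scheme.
#' @param tensor A `sym_tensor` (diffusivities, mm^2/s) or a
#'   `compartment_spec` from [gaussian_compartment()].
#' @return E in (0, 1]; E = 1 at b = 0.
#' @export
signal_gaussian <- function(scheme, shell_index, direction_index, tensor) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  b <- scheme$b_values[shell_index]
  g <- scheme$directions[direction_index, ]
  D <- .as_tensor_matrix(tensor)
  if (any(b < 0)) stop("negative b", call. = FALSE)
  if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
    stop("tensor must be positive semidefinite", call. = FALSE)
  }
  exp(-b * drop(g %*% D %*% g))
}

.as_tensor_matrix <- function(tensor) {
  if (inherits(tensor, "sym_tensor")) return(tensor$mat)
  if (inherits(tensor, "compartment_spec")) {
    stopifnot(tensor$model == "gaussian_tensor")
    return(.axial_tensor(tensor$eigenvalues, tensor$axis))
  }
  as.matrix(tensor)
}

# Build a tensor with given eigenvalues, lambda1 along `axis` and the two
# minor eigenvalues in the orthogonal complement.
.axial_tensor <- function(eigenvalues, axis) {
  e1 <- .unit(axis)
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- .unit(ref - sum(ref * e1) * e1)
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  V <- cbind(e1, e2, e3)
  V %*% diag(eigenvalues) %*% t(V)
}

# Roots of J1'(x) = 0 (derivative of the first-order Bessel function),
# eigenmode constants of the GPD cylinder series. Cached after first use.
.gpd_env <- new.env(parent = emptyenv())

bessel_j1prime_roots <- function(n = 40) {
  if (!is.null(.gpd_env$roots) && length(.gpd_env$roots) >= n) {
    return(.gpd_env$roots[seq_len(n)])
  }
  f <- function(x) besselJ(x, 0) - besselJ(x, 1) / x
  roots <- numeric(n); k <- 0; x <- 0.5
  while (k < n) {
    x2 <- x + 0.05
    if (f(x) * f(x2) < 0) {
      k <- k + 1
      roots[k] <- stats::uniroot(f, c(x, x2), tol = 1e-14)$root
    }
    x <- x2
  }
  .gpd_env$roots <- roots
  roots
}

# GPD log-attenuation for diffusion inside an impermeable cylinder,
# gradient perpendicular to the axis (finite-delta PGSE).
# q_perp: m^-1; radius_m, D (m^2/s), big_delta/small_delta (s).
# Series over Bessel-root eigenmodes, truncated at 1e-12 relative.
gpd_ln_attenuation <- function(q_perp, radius_m, D, big_delta, small_delta) {
  if (q_perp == 0 || D == 0) return(0)
  mu <- bessel_j1prime_roots(40)
  am <- mu / radius_m
  a2D <- am^2 * D
  num <- 2 * a2D * small_delta - 2 +
    2 * exp(-a2D * small_delta) + 2 * exp(-a2D * big_delta) -
    exp(-a2D * (big_delta - small_delta)) -
    exp(-a2D * (big_delta + small_delta))
  term <- num / (D^2 * am^6 * (radius_m^2 * am^2 - 1))
  csum <- cumsum(term)
  keep <- which(abs(term) > 1e-12 * abs(csum))
  s <- if (length(keep)) csum[max(keep)] else csum[length(csum)]
  gG <- 2 * pi * q_perp / small_delta  # gamma * G_perp, 1/(m s)
  -2 * gG^2 * s
}

#' Normalized restricted-cylinder signal
#'
#' The signal factorizes into free Gaussian diffusion along the cylinder
#' axis and restricted diffusion across it. The perpendicular factor uses
#' the Gaussian phase distribution (GPD) approximation for finite gradient
#' duration; `mode = "narrow_pulse"` instead uses the narrow-pulse disk
#' diffraction form `|2 J1(2 pi q_perp R) / (2 pi q_perp R)|^2`, useful as
#' an analytic cross-check in the delta -> 0 regime.
#'
#' @inheritParams signal_gaussian
#' @param comp A `compartment_spec` from [cylinder_compartment()].
#' @param mode `"gpd"` (default) or `"narrow_pulse"`.
#' @return E in (0, 1]; E = 1 at b = 0.
#' @export
signal_cylinder <- function(scheme, shell_index, direction_index, comp,
                            mode = c("gpd", "narrow_pulse")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (!identical(comp$model, "restricted_cylinder")) {
    stop("unsupported model tag: ", comp$model, call. = FALSE)
  }
  b <- scheme$b_values[shell_index]
  q <- scheme$q_values[shell_index] * 100           # m^-1
  g <- scheme$directions[direction_index, ]
  cos_t <- sum(g * comp$axis)
  b_par <- b * cos_t^2
  q_perp <- q * sqrt(max(0, 1 - cos_t^2))
  D_si <- comp$diffusivity * 1e-6                   # mm^2/s -> m^2/s
  E_ax <- exp(-b_par * comp$diffusivity)
  E_perp <- if (mode == "gpd") {
    exp(gpd_ln_attenuation(q_perp, comp$radius * 1e-6, D_si,
                           scheme$big_delta / 1000, scheme$small_delta / 1000))
  } else {
    x <- 2 * pi * q_perp * comp$radius * 1e-6
    if (x == 0) 1 else (2 * besselJ(x, 1) / x)^2
  }
  E_ax * E_perp
}

#' Normalized signal of a compartment mixture over the whole scheme
#'
#' Volume-fraction-weighted sum of compartment signals for every
#' (shell, direction) measurement of the scheme.
#'
#' @param scheme A `gradient_scheme`.
#' @param compartments List of `compartment_spec`; fractions must sum to 1.
#' @param mode Passed to [signal_cylinder()].
#' @return Matrix `n_shells x n_directions` of normalized signals.
#' @export
mixture_signal <- function(scheme, compartments, mode = "gpd") {
  if (inherits(compartments, "compartment_spec")) compartments <- list(compartments)
  fr <- vapply(compartments, `[[`, numeric(1), "volume_fraction")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("compartment volume fractions must sum to 1", call. = FALSE)
  }
  ns <- length(scheme$b_values); nd <- nrow(scheme$directions)
  E <- matrix(0, ns, nd)
  for (comp in compartments) {
    Ec <- matrix(0, ns, nd)
    for (s in seq_len(ns)) for (d in seq_len(nd)) {
      Ec[s, d] <- switch(comp$model,
        gaussian_tensor = signal_gaussian(scheme, s, d, comp),
        restricted_cylinder = signal_cylinder(scheme, s, d, comp, mode = mode),
        stop("unsupported model tag: ", comp$model, call. = FALSE))
    }
    E <- E + comp$volume_fraction * Ec
  }
  E
}

#' Phantom specification
#'
#' Describes a synthetic scan: a voxel grid, one compartment mixture per
#' region, the acquisition scheme, the signal-to-noise ratio and the seed.
#'
#' @param grid_shape Length-3 integer voxel grid.
#' @param compartments Either a list of `compartment_spec` (single region
#'   covering the grid) or a list of such lists, one mixture per region
#'   label in `regions`.
#' @param scheme A `gradient_scheme`.
#' @param snr b0 signal divided by the Gaussian noise standard deviation;
#'   `Inf` for noise-free.
#' @param seed Integer RNG seed.
#' @param regions Optional integer array of `grid_shape` assigning each
#'   voxel a mixture index (1-based); 0 = empty voxel.
#' @param s0 Noise-free b0 signal amplitude (arbitrary units).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, compartments, scheme, snr = 50,
                         seed = 1L, regions = NULL, s0 = 1000) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  if (!(snr > 0)) stop("snr must be positive (possibly Inf)", call. = FALSE)
  if (inherits(compartments, "compartment_spec")) {
    compartments <- list(list(compartments))
  } else if (length(compartments) && inherits(compartments[[1]], "compartment_spec")) {
    compartments <- list(compartments)
  }
  for (mix in compartments) {
    fr <- vapply(mix, `[[`, numeric(1), "volume_fraction")
    if (abs(sum(fr) - 1) > 1e-9) {
      stop("per-region compartment volume fractions must sum to 1", call. = FALSE)
    }
  }
  if (is.null(regions)) {
    regions <- array(1L, dim = grid_shape)
  }
  stopifnot(all(dim(regions) == grid_shape))
  if (max(regions) > length(compartments)) {
    stop("regions reference more mixtures than provided", call. = FALSE)
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 compartments = compartments, scheme = scheme,
                 snr = snr, seed = as.integer(seed), regions = regions,
                 s0 = s0),
            class = "phantom_spec")
}

# Ground-truth summaries per mixture. radial_fwhm proxy for Gaussian
# compartments: (sqrt(16 ln2 t_d lambda2) + sqrt(16 ln2 t_d lambda3)) / 2,
# the value the QSI pipeline converges to in the noise-free Gaussian limit.
.mixture_truth <- function(mix, scheme) {
  td <- diffusion_time(scheme)  # ms; diffusivity mm^2/s = um^2/ms
  if (length(mix) == 1 && mix[[1]]$model == "gaussian_tensor") {
    ev <- mix[[1]]$eigenvalues
    rd <- (ev[2] + ev[3]) / 2
    # ev [mm^2/s] * td [ms] * 1e3 -> um^2
    fw <- (sqrt(16 * log(2) * td * ev[2] * 1e3) +
           sqrt(16 * log(2) * td * ev[3] * 1e3)) / 2
    list(rd = rd, radial_fwhm = fw, radius = NA_real_)
  } else if (length(mix) == 1 && mix[[1]]$model == "restricted_cylinder") {
    list(rd = NA_real_, radial_fwhm = NA_real_, radius = mix[[1]]$radius)
  } else {
    list(rd = NA_real_, radial_fwhm = NA_real_, radius = NA_real_)
  }
}

#' Generate a synthetic diffusion-weighted volume
#'
#' Evaluates the noise-free forward model per region, broadcasts it over
#' the voxel grid and applies Rician noise (magnitude of a complex Gaussian
#' with standard deviation `s0 / snr` per channel). Deterministic given the
#' seed.
#'
#' @param spec A `phantom_spec`.
#' @param mode Cylinder signal mode, passed to [mixture_signal()].
#' @return List with `dwi` (4-D array, volumes ordered as in
#'   [scheme_measurements()]), `scheme`, `truth` (tibble of per-voxel
#'   ground truth: true RD, the Gaussian radial-FWHM proxy, true cylinder
#'   radius), `region` (3-D array) and `spec`.
#' @export
generate_phantom <- function(spec, mode = "gpd") {
  stopifnot(inherits(spec, "phantom_spec"))
  scheme <- spec$scheme
  ns <- length(scheme$b_values); nd <- nrow(scheme$directions)
  nvol <- ns * nd
  nvox <- prod(spec$grid_shape)
  sig <- matrix(0, nvox, nvol)   # voxels x volumes, noise-free
  truth <- tibble::tibble(voxel = seq_len(nvox),
                          region = as.integer(spec$regions),
                          true_rd = NA_real_, true_radial_fwhm = NA_real_,
                          true_radius = NA_real_)
  for (r in seq_along(spec$compartments)) {
    idx <- which(truth$region == r)
    if (!length(idx)) next
    E <- mixture_signal(scheme, spec$compartments[[r]], mode = mode)
    sig[idx, ] <- matrix(spec$s0 * as.vector(t(E)), length(idx), nvol,
                         byrow = TRUE)
    tr <- .mixture_truth(spec$compartments[[r]], scheme)
    truth$true_rd[idx] <- tr$rd
    truth$true_radial_fwhm[idx] <- tr$radial_fwhm
    truth$true_radius[idx] <- tr$radius
  }
  if (is.finite(spec$snr)) {
    sigma <- spec$s0 / spec$snr
    set.seed(spec$seed)
    n1 <- matrix(stats::rnorm(nvox * nvol, sd = sigma), nvox, nvol)
    n2 <- matrix(stats::rnorm(nvox * nvol, sd = sigma), nvox, nvol)
    sig <- sqrt((sig + n1)^2 + n2^2)
  }
  dwi <- array(sig, dim = c(spec$grid_shape, nvol))
  list(dwi = dwi, scheme = scheme, truth = truth, region = spec$regions,
       spec = spec)
}

#' Write a phantom to disk as NIfTI + gradient files
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of files written.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dwi_path <- file.path(dir, "dwi.nii")
  RNifti::writeNifti(RNifti::asNifti(phantom$dwi), dwi_path)
  reg_path <- file.path(dir, "region.nii")
  RNifti::writeNifti(RNifti::asNifti(phantom$region + 0), reg_path)
  gpaths <- write_gradient_scheme(phantom$scheme, file.path(dir, "scheme"))
  spec_path <- file.path(dir, "phantom.yaml")
  sp <- phantom$spec
  yaml::write_yaml(list(
    grid_shape = sp$grid_shape, snr = if (is.finite(sp$snr)) sp$snr else "Inf",
    seed = sp$seed, s0 = sp$s0,
    big_delta_ms = sp$scheme$big_delta, small_delta_ms = sp$scheme$small_delta,
    n_regions = length(sp$compartments)), spec_path)
  invisible(c(dwi_path, reg_path, gpaths, spec_path))
}
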