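# Shared fixtures built in code.

protocol <- muscle_protocol()
TD_MS <- 45.6 - 27.9 / 3   # effective diffusion time, ms

# Gaussian-propagator FWHM (um) for diffusivity d (mm^2/s) over TD_MS.
gauss_fwhm <- function(d, td_ms = TD_MS) sqrt(16 * log(2) * d * 1e3 * td_ms)

random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  R * sign(det(R))
}

random_pd_tensor <- function(scale = 1e-3) {
  R <- random_rotation()
  ev <- sort(runif(3, 0.3, 2.2), decreasing = TRUE) * scale
  R %*% diag(ev) %*% t(R)
}

# Brute-force Spearman: mid-ranks + explicit Pearson formula.
spearman_brute <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

gaussian_phantom <- function(eigenvalues, grid = c(2, 2, 1), snr = Inf,
                             axis = c(0, 0, 1), seed = 1) {
  generate_phantom(phantom_spec(
    grid, gaussian_compartment(eigenvalues, axis = axis), protocol,
    snr = snr, seed = seed))
}

cylinder_phantom <- function(radius, grid = c(1, 1, 1), snr = Inf,
                             diffusivity = 2e-3, axis = c(0, 0, 1), seed = 1) {
  generate_phantom(phantom_spec(
    grid, cylinder_compartment(radius, diffusivity, axis = axis), protocol,
    snr = snr, seed = seed))
}
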