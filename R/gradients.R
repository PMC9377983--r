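#' Diffusion weighting from the q-value under pulsed-gradient spin echo
#'
#' For a pulsed-gradient spin-echo (PGSE) sequence the b-value and the
#' q-value are tied by the Stejskal–Tanner relation
#' \deqn{b = (2\pi q)^2 \, (\Delta - \delta/3),}
#' where \eqn{\Delta} is the separation and \eqn{\delta} the duration of the
#' two diffusion gradients, and \eqn{t_d = \Delta - \delta/3} is the
#' effective diffusion time.
#'
#' @param q q-value(s) in cm^-1 (non-negative).
#' @param big_delta Gradient separation \eqn{\Delta} in ms.
#' @param small_delta Gradient duration \eqn{\delta} in ms.
#' @return b-value(s) in s/mm^2, same length as `q`.
#' @examples
#' b_from_q(236.3, 45.6, 27.9)  # ~800 s/mm^2
#' @seealso [q_from_b()], [gradient_scheme()]
#' @export
b_from_q <- function(q, big_delta, small_delta) {
  td <- .check_timing(big_delta, small_delta)
  if (any(q < 0)) stop("q must be non-negative", call. = FALSE)
  q_m <- q * 100                       # cm^-1 -> m^-1
  (2 * pi * q_m)^2 * td * 1e-6         # s/m^2 -> s/mm^2
}

#' Inverse of [b_from_q()]
#'
#' @param b b-value(s) in s/mm^2 (non-negative).
#' @inheritParams b_from_q
#' @return q-value(s) in cm^-1.
#' @export
q_from_b <- function(b, big_delta, small_delta) {
  td <- .check_timing(big_delta, small_delta)
  if (any(b < 0)) stop("b must be non-negative", call. = FALSE)
  sqrt(b * 1e6 / td) / (2 * pi) / 100
}

.check_timing <- function(big_delta, small_delta) {
  if (!is.numeric(big_delta) || !is.numeric(small_delta) ||
      small_delta <= 0 || big_delta <= small_delta / 3) {
    stop("invalid timing: require big_delta > small_delta/3 > 0 (ms)",
         call. = FALSE)
  }
  (big_delta - small_delta / 3) / 1000  # effective diffusion time, s
}

#' Effective diffusion time of a scheme
#'
#' @param scheme A `gradient_scheme`.
#' @return \eqn{t_d = \Delta - \delta/3} in ms.
#' @export
diffusion_time <- function(scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  scheme$big_delta - scheme$small_delta / 3
}

#' Construct and validate a diffusion-encoding protocol
#'
#' A `gradient_scheme` bundles the unique encoding directions, the per-shell
#' b- and q-values and the PGSE timing. Validation enforces unit-norm
#' directions, non-decreasing matched b/q lists, and the Stejskal–Tanner
#' consistency b = (2*pi*q)^2 (Delta - delta/3) for every shell within a
#' relative tolerance.
#'
#' @param directions Numeric matrix, one unit direction per row (n x 3), or
#'   `NULL` for the default six-direction set ([default_directions()]).
#' @param b_values Per-shell b-values, s/mm^2, non-decreasing, first = 0.
#' @param q_values Per-shell q-values, cm^-1, same length as `b_values`.
#' @param big_delta,small_delta PGSE timing, ms.
#' @param b_tol Relative tolerance for the b–q consistency check.
#' @return An object of class `gradient_scheme`.
#' @examples
#' sch <- gradient_scheme(b_values = c(0, 800), q_values = q_from_b(c(0, 800), 45.6, 27.9),
#'                        big_delta = 45.6, small_delta = 27.9)
#' @export
gradient_scheme <- function(directions = NULL, b_values, q_values,
                            big_delta, small_delta, b_tol = 0.01) {
  if (is.null(directions)) directions <- default_directions()
  directions <- as.matrix(directions)
  if (ncol(directions) != 3) stop("directions must be n x 3", call. = FALSE)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("all directions must have unit norm (within 1e-6)", call. = FALSE)
  }
  if (length(b_values) != length(q_values)) {
    stop(sprintf("format error: %d b-values but %d q-values",
                 length(b_values), length(q_values)), call. = FALSE)
  }
  if (is.unsorted(b_values) || is.unsorted(q_values)) {
    stop("b_values and q_values must be non-decreasing", call. = FALSE)
  }
  if (any(b_values < 0) || any(q_values < 0)) {
    stop("b and q must be non-negative", call. = FALSE)
  }
  .check_timing(big_delta, small_delta)
  b_pred <- b_from_q(q_values, big_delta, small_delta)
  rel <- ifelse(b_values > 0, abs(b_pred - b_values) / b_values,
                abs(b_pred))
  bad <- which(rel > b_tol)
  if (length(bad)) {
    stop(sprintf(
      "physics error: shell %d (b = %g s/mm^2, q = %g cm^-1) violates b = (2*pi*q)^2 (Delta - delta/3): predicted b = %.4g",
      bad[1], b_values[bad[1]], q_values[bad[1]], b_pred[bad[1]]),
      call. = FALSE)
  }
  structure(
    list(directions = directions, b_values = as.numeric(b_values),
         q_values = as.numeric(q_values),
         big_delta = big_delta, small_delta = small_delta),
    class = "gradient_scheme")
}

#' The default six-direction encoding set
#'
#' The standard dual-gradient six-direction scheme used for six-axis tensor
#' acquisition: normalized (1,1,0), (1,-1,0), (1,0,1), (1,0,-1), (0,1,1),
#' (0,1,-1). Its design matrix for a symmetric 3x3 tensor has full rank 6.
#'
#' @return A 6 x 3 matrix of unit row vectors.
#' @export
default_directions <- function() {
  d <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
             c(1, 0, -1), c(0, 1, 1), c(0, 1, -1))
  d / sqrt(2)
}

#' The acquisition protocol used throughout the package examples
#'
#' Ten q-shells (b = 0 ... 4000 s/mm^2, q = 0 ... 528.3 cm^-1) with
#' Delta/delta = 45.6/27.9 ms and six encoding directions.
#'
#' @param directions Optional direction matrix; default [default_directions()].
#' @return A `gradient_scheme` with 10 shells.
#' @export
muscle_protocol <- function(directions = NULL) {
  gradient_scheme(
    directions = directions,
    b_values = c(0, 50, 200, 450, 800, 1250, 1800, 2400, 3150, 4000),
    q_values = c(0, 59.1, 118.1, 177.2, 236.3, 295.3, 354.4, 409.2,
                 468.8, 528.3),
    big_delta = 45.6, small_delta = 27.9)
}

#' Read a gradient scheme from bval/qval/bvec text files
#'
#' `path_bval` and `path_qval` each hold one whitespace-separated row of
#' per-shell values (same order); `path_bvec` is an FSL-style 3 x N
#' whitespace table of the unique encoding directions (one column per
#' direction).
#'
#' @param path_bval,path_qval,path_bvec File paths.
#' @param big_delta,small_delta PGSE timing, ms.
#' @return A validated `gradient_scheme`.
#' @export
read_gradient_scheme <- function(path_bval, path_qval, path_bvec,
                                 big_delta, small_delta) {
  for (p in c(path_bval, path_qval, path_bvec)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  bv <- scan(path_bval, quiet = TRUE)
  qv <- scan(path_qval, quiet = TRUE)
  vec <- as.matrix(utils::read.table(path_bvec))
  if (nrow(vec) != 3) stop("bvec must be a 3 x N table", call. = FALSE)
  gradient_scheme(directions = t(vec), b_values = bv, q_values = qv,
                  big_delta = big_delta, small_delta = small_delta)
}

#' Write a scheme to bval/qval/bvec files
#'
#' @param scheme A `gradient_scheme`.
#' @param stem Path stem; writes `<stem>.bval`, `<stem>.qval`, `<stem>.bvec`.
#' @return Invisibly, the three paths written.
#' @export
write_gradient_scheme <- function(scheme, stem) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  paths <- paste0(stem, c(".bval", ".qval", ".bvec"))
  writeLines(paste(scheme$b_values, collapse = " "), paths[1])
  writeLines(paste(scheme$q_values, collapse = " "), paths[2])
  write.table(format(t(scheme$directions), digits = 10), paths[3],
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Expand a scheme into the per-volume measurement table
#'
#' Acquisition order is shell-major: for shell s and direction d the 4-D
#' volume index is `(s - 1) * n_dir + d`. The b = 0 shell is replicated over
#' all directions (unweighted measurements).
#'
#' @param scheme A `gradient_scheme`.
#' @return A tibble with columns `volume`, `shell`, `direction`, `b`, `q`,
#'   `gx`, `gy`, `gz`.
#' @export
scheme_measurements <- function(scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  ns <- length(scheme$b_values); nd <- nrow(scheme$directions)
  shell <- rep(seq_len(ns), each = nd)
  dir <- rep(seq_len(nd), times = ns)
  tibble::tibble(
    volume = seq_len(ns * nd), shell = shell, direction = dir,
    b = scheme$b_values[shell], q = scheme$q_values[shell],
    gx = scheme$directions[dir, 1], gy = scheme$directions[dir, 2],
    gz = scheme$directions[dir, 3])
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf(
    "<gradient_scheme> %d shells x %d directions, Delta/delta = %g/%g ms (t_d = %g ms)\n",
    length(x$b_values), nrow(x$directions), x$big_delta, x$small_delta,
    diffusion_time(x)))
  cat("  b (s/mm^2):", paste(signif(x$b_values, 4), collapse = ", "), "\n")
  cat("  q (cm^-1): ", paste(signif(x$q_values, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as_tibble.gradient_scheme <- function(x, ...) scheme_measurements(x)
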