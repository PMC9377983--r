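# Symmetric 3x3 tensor utilities shared by the DTI fit (diffusivity, mm^2/s)
# and the QSI fit (squared FWHM, um^2). Component vector order is
# (xx, yy, zz, xy, xz, yz).

#' Symmetric tensor with sorted eigen-system
#'
#' @param mat Symmetric 3 x 3 matrix, or a length-6 component vector
#'   (xx, yy, zz, xy, xz, yz).
#' @param clamp_negative Clamp negative eigenvalues to zero (with a
#'   warning), as appropriate for physically non-negative quantities.
#' @return An object of class `sym_tensor`: list with `mat` (3 x 3),
#'   `values` (eigenvalues, descending), `vectors` (columns, orthonormal,
#'   matching `values`).
#' @export
sym_tensor <- function(mat, clamp_negative = FALSE) {
  if (is.numeric(mat) && length(mat) == 6) mat <- tensor_from_components(mat)
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 3, ncol(mat) == 3)
  if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(abs(mat)))) {
    stop("matrix is not symmetric", call. = FALSE)
  }
  mat <- (mat + t(mat)) / 2
  e <- eigen(mat, symmetric = TRUE)  # eigen() returns descending order
  vals <- e$values
  if (clamp_negative && any(vals < 0)) {
    warning(sprintf("clamped %d negative eigenvalue(s) to zero",
                    sum(vals < 0)), call. = FALSE)
    vals <- pmax(vals, 0)
  }
  structure(list(mat = mat, values = vals, vectors = e$vectors),
            class = "sym_tensor")
}

#' @export
print.sym_tensor <- function(x, ...) {
  cat("<sym_tensor> eigenvalues:", paste(signif(x$values, 5), collapse = ", "), "\n")
  invisible(x)
}

tensor_from_components <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

tensor_components <- function(mat) {
  c(mat[1, 1], mat[2, 2], mat[3, 3], mat[1, 2], mat[1, 3], mat[2, 3])
}

# Design matrix for g' T g = y: row i is
# (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)
tensor_design <- function(directions) {
  g <- as.matrix(directions)
  cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
        2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

assert_design_rank <- function(directions) {
  A <- tensor_design(directions)
  if (qr(A)$rank < 6) {
    stop("direction set is rank-deficient for a symmetric tensor fit (need rank 6)",
         call. = FALSE)
  }
  invisible(A)
}

# Least-squares solve of g_i' T g_i = y_i for one or many right-hand sides.
# y: length-n vector or n x m matrix (one column per voxel).
# Returns 6 x m component matrix.
solve_tensor_ls <- function(directions, y) {
  A <- assert_design_rank(directions)
  qr.solve(A, as.matrix(y))
}
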