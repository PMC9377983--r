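# Cohort-level statistics: one-way ANOVA, Dunnett many-to-one comparisons
# against the control group, and Spearman rank-correlation matrices.

#' One-way fixed-effects ANOVA
#'
#' @param data Data frame with one row per subject.
#' @param variable Name of the numeric response column.
#' @param group Name of the grouping column (>= 2 levels, each n >= 2).
#' @return Object of class `qsi_anova` (also a tibble): `variable`,
#'   `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
anova_oneway <- function(data, variable, group = "group") {
  y <- data[[variable]]; g <- factor(data[[group]])
  if (!is.numeric(y)) stop("response must be numeric", call. = FALSE)
  ok <- stats::complete.cases(y, g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    stop("need >= 2 groups with >= 2 subjects each", call. = FALSE)
  }
  wss <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  if (wss == 0) stop("degenerate input: zero within-group variance", call. = FALSE)
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  out <- tibble::tibble(variable = variable,
                        statistic = unname(ft$statistic),
                        df1 = unname(ft$parameter[1]),
                        df2 = unname(ft$parameter[2]),
                        p.value = unname(ft$p.value))
  class(out) <- c("qsi_anova", class(out))
  out
}

#' Dunnett many-to-one comparisons against a reference group
#'
#' Compares every group mean with the reference (control) mean with
#' Dunnett's single-step adjustment based on the multivariate
#' t-distribution. Adjusted p-values are computed by adaptive multivariate-t
#' integration; a fixed RNG seed makes the quasi-Monte-Carlo evaluation
#' reproducible (p-values accurate to ~1e-3).
#'
#' @inheritParams anova_oneway
#' @param reference Reference group level (default `"control"`).
#' @param seed Seed for the multivariate-t evaluation.
#' @return Object of class `qsi_dunnett` (also a tibble): `comparison`,
#'   `estimate` (difference in means), `statistic`, `p.value` (adjusted),
#'   `p.unadjusted`.
#' @export
dunnett_vs_control <- function(data, variable, group = "group",
                               reference = "control", seed = 20220808L) {
  y <- data[[variable]]; g <- factor(data[[group]])
  ok <- stats::complete.cases(y, g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (!reference %in% levels(g)) {
    stop("reference group absent: ", reference, call. = FALSE)
  }
  g <- stats::relevel(g, ref = reference)
  fit <- stats::aov(y ~ g)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  sm <- summary(gl)
  unadj <- summary(gl, test = multcomp::adjusted("none"))
  out <- tibble::tibble(
    comparison = names(sm$test$coefficients),
    estimate = unname(sm$test$coefficients),
    statistic = unname(sm$test$tstat),
    p.value = unname(as.numeric(sm$test$pvalues)),
    p.unadjusted = unname(as.numeric(unadj$test$pvalues)))
  class(out) <- c("qsi_dunnett", class(out))
  out
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Spearman rank-correlation matrix with p-values
#'
#' Rank correlations with mid-ranks for ties, pairwise-complete
#' observations, and asymptotic t-approximation p-values (exact
#' permutation null available for small samples via
#' `exact = TRUE`). Constant columns yield `NA` with a reason.
#'
#' @param data Data frame.
#' @param variables Character vector of numeric column names (>= 2).
#' @param exact Use the exact null distribution where n <= 20 and there
#'   are no ties (as in [stats::cor.test()]).
#' @return Object of class `spearman_matrix`: list with `rho` and `p`
#'   (symmetric matrices, unit diagonal on `rho`), `n` (pairwise counts)
#'   and `notes` (tibble of undefined entries with reasons).
#' @export
spearman_matrix <- function(data, variables, exact = FALSE) {
  stopifnot(length(variables) >= 2, all(variables %in% names(data)))
  k <- length(variables)
  rho <- p <- nmat <- matrix(NA_real_, k, k,
                             dimnames = list(variables, variables))
  diag(rho) <- 1; diag(p) <- 0
  notes <- list()
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    x <- data[[variables[a]]]; y <- data[[variables[b]]]
    ok <- is.finite(x) & is.finite(y)
    nmat[a, b] <- nmat[b, a] <- sum(ok)
    if (sum(ok) < 3) {
      notes[[length(notes) + 1]] <- tibble::tibble(
        var1 = variables[a], var2 = variables[b],
        reason = "fewer than 3 complete observations")
      next
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      notes[[length(notes) + 1]] <- tibble::tibble(
        var1 = variables[a], var2 = variables[b],
        reason = "constant column")
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = exact))
    rho[a, b] <- rho[b, a] <- unname(ct$estimate)
    p[a, b] <- p[b, a] <- ct$p.value
  }
  diag(nmat) <- vapply(variables, function(v) sum(is.finite(data[[v]])),
                       numeric(1))
  structure(list(rho = rho, p = p, n = nmat,
                 notes = dplyr::bind_rows(notes)),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 2, ...) {
  cat("<spearman_matrix> rho (pairwise complete):\n")
  print(round(x$rho, digits))
  if (nrow(x$notes)) {
    cat("undefined entries:\n"); print(x$notes)
  }
  invisible(x)
}

#' @export
as.matrix.spearman_matrix <- function(x, ...) x$rho

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.spearman_matrix <- function(x, ...) {
  vars <- rownames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
                 estimate = x$rho[idx], p.value = x$p[idx],
                 n = x$n[idx])
}

#' @export
tidy.qsi_anova <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.qsi_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 df1 = x$df1, df2 = x$df2)
}

#' @export
tidy.qsi_dunnett <- function(x, ...) tibble::as_tibble(unclass(x))

#' Group summary table (mean +/- SD with Dunnett flags)
#'
#' One row per group and variable: group mean, SD, n, and the Dunnett
#' adjusted p-value of the comparison with the reference group.
#'
#' @inheritParams dunnett_vs_control
#' @param variables Character vector of numeric columns to summarize.
#' @param alpha Significance threshold for the `significant` flag.
#' @return A tibble: `variable`, `group`, `n`, `mean`, `sd`,
#'   `p.dunnett` (`NA` for the reference group), `significant`.
#' @export
group_summary <- function(data, variables, group = "group",
                          reference = "control", alpha = 0.05) {
  purrr::map_dfr(variables, function(v) {
    dn <- dunnett_vs_control(data, v, group = group, reference = reference)
    dn$group <- sub(" - .*$", "", dn$comparison)
    base <- data |>
      dplyr::group_by(group = .data[[group]]) |>
      dplyr::summarise(n = sum(is.finite(.data[[v]])),
                       mean = mean(.data[[v]], na.rm = TRUE),
                       sd = stats::sd(.data[[v]], na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::mutate(variable = v)
    base |>
      dplyr::left_join(dn[, c("group", "p.value")], by = "group") |>
      dplyr::rename(p.dunnett = "p.value") |>
      dplyr::mutate(significant = !is.na(.data$p.dunnett) &
                      .data$p.dunnett < alpha) |>
      dplyr::select("variable", "group", "n", "mean", "sd",
                    "p.dunnett", "significant")
  })
}
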