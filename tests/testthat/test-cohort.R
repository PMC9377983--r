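make_groups <- function(means, n = c(12, 10, 11, 10), sd = 1, seed = 1) {
  set.seed(seed)
  g <- c("control", "distance", "powerlifting", "teenager")
  tibble::tibble(
    group = rep(g, n),
    y = stats::rnorm(sum(n), rep(means, n), sd))
}

test_that("one-way ANOVA has the expected null and identity behavior", {
  # identical group means with nonzero within-variance: F = 0
  d <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                      y = c(-1, 0, 1, -1, 0, 1))
  out <- anova_oneway(d, "y")
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p.value, 1, tolerance = 1e-12)
  # two groups: F equals the square of the pooled t statistic
  d2 <- make_groups(c(0, 1, 0, 0))
  d2 <- d2[d2$group %in% c("control", "distance"), ]
  tt <- stats::t.test(y ~ group, data = d2, var.equal = TRUE)
  expect_equal(anova_oneway(d2, "y")$statistic, unname(tt$statistic)^2,
               tolerance = 1e-9)
  # affine invariance of F
  d3 <- make_groups(c(0, 0.5, 1, 1.5))
  d3b <- dplyr::mutate(d3, y = 3.2 * y - 7)
  expect_equal(anova_oneway(d3, "y")$statistic,
               anova_oneway(d3b, "y")$statistic, tolerance = 1e-9)
  expect_error(anova_oneway(tibble::tibble(group = rep(c("a", "b"), each = 2),
                                           y = c(1, 1, 2, 2)), "y"),
               "degenerate")
  expect_error(anova_oneway(tibble::tibble(group = c("a", "a", "b"),
                                           y = c(1, 2, 3)), "y"),
               ">= 2 groups")
})

test_that("Dunnett comparisons behave under null, shift and monotonicity", {
  # one group shifted by 5 pooled SDs: that comparison significant only
  d <- make_groups(c(0, 0, 5, 0), seed = 4)
  dn <- dunnett_vs_control(d, "y")
  expect_equal(nrow(dn), 3)
  p_shift <- dn$p.value[grepl("powerlifting", dn$comparison)]
  expect_lt(p_shift, 0.001)
  expect_true(all(dn$p.value[!grepl("powerlifting", dn$comparison)] > 0.05))
  # adjusted p >= unadjusted p, always
  expect_true(all(dn$p.value >= dn$p.unadjusted - 1e-12))
  dnull <- make_groups(c(0, 0, 0, 0), seed = 5)
  dn0 <- dunnett_vs_control(dnull, "y")
  expect_true(all(dn0$p.value >= dn0$p.unadjusted - 1e-12))
  expect_error(dunnett_vs_control(d, "y", reference = "elephants"),
               "reference group absent")
})

test_that("Dunnett p-values are reproducible across calls", {
  d <- make_groups(c(0, 0.8, 1.6, -0.5), seed = 6)
  expect_equal(dunnett_vs_control(d, "y")$p.value,
               dunnett_vs_control(d, "y")$p.value)
})

test_that("group separations at the study's sizes are detected with power > 80%", {
  # effect sizes mirroring the published SMI separation:
  # control 7.80, powerlifting 9.64, teenager 6.28, pooled sd ~0.75
  hits_pl <- hits_teen <- logical(120)
  for (i in seq_along(hits_pl)) {
    d <- make_groups(c(7.80, 7.28, 9.64, 6.28), sd = 0.75, seed = 1000 + i)
    dn <- dunnett_vs_control(d, "y")
    hits_pl[i] <- dn$p.value[grepl("powerlifting", dn$comparison)] < 0.05
    hits_teen[i] <- dn$p.value[grepl("teenager", dn$comparison)] < 0.05
  }
  expect_gt(mean(hits_pl), 0.8)
  expect_gt(mean(hits_teen), 0.8)
})

test_that("Spearman matrix handles monotone data, ties and transforms", {
  n <- 25
  set.seed(8)
  x <- sort(rnorm(n))
  d <- tibble::tibble(x = x, up = exp(x), down = -x^3,
                      noisy = x + rnorm(n))
  sp <- spearman_matrix(d, c("x", "up", "down", "noisy"))
  expect_equal(sp$rho["x", "up"], 1)
  expect_equal(sp$rho["x", "down"], -1)
  expect_equal(diag(sp$rho), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(abs(sp$rho) <= 1, na.rm = TRUE))
  # invariance under strictly monotone transforms
  d2 <- dplyr::mutate(d, noisy = qlogis(plogis(noisy)))
  sp2 <- spearman_matrix(d2, c("x", "noisy"))
  expect_equal(sp2$rho["x", "noisy"], sp$rho["x", "noisy"], tolerance = 1e-12)
  # constant column is reported, not computed
  d3 <- tibble::tibble(a = 1:5, b = rep(2, 5))
  sp3 <- spearman_matrix(d3, c("a", "b"))
  expect_true(is.na(sp3$rho["a", "b"]))
  expect_equal(sp3$notes$reason, "constant column")
})

test_that("tied data match a brute-force mid-rank computation exactly", {
  set.seed(12)
  for (i in 1:5) {
    n <- sample(6:12, 1)
    d <- tibble::tibble(x = sample(1:4, n, replace = TRUE),
                        y = sample(1:5, n, replace = TRUE))
    if (sd(d$x) == 0 || sd(d$y) == 0) next
    sp <- spearman_matrix(d, c("x", "y"))
    expect_equal(sp$rho["x", "y"], spearman_brute(d$x, d$y),
                 tolerance = 1e-12)
  }
})

test_that("pairwise-complete deletion drives the n matrix", {
  d <- tibble::tibble(a = c(1, 2, 3, 4, NA), b = c(2, 1, 4, 3, 5),
                      c = c(1, NA, 3, 2, 4))
  sp <- spearman_matrix(d, c("a", "b", "c"))
  expect_equal(sp$n["a", "b"], 4)
  expect_equal(sp$n["a", "c"], 3)
  expect_equal(sp$n["b", "c"], 4)
})

test_that("tidy and glance methods return flat tibbles", {
  d <- make_groups(c(0, 1, 2, 3), seed = 2)
  a <- anova_oneway(d, "y")
  expect_s3_class(tidy(a), "tbl_df")
  expect_named(glance(a), c("statistic", "p.value", "df1", "df2"))
  dn <- dunnett_vs_control(d, "y")
  expect_true(all(c("comparison", "estimate", "p.value") %in%
                    names(tidy(dn))))
  sp <- spearman_matrix(d |> dplyr::mutate(z = y + rnorm(43)), c("y", "z"))
  td <- tidy(sp)
  expect_equal(nrow(td), 1)
  expect_true(all(c("var1", "var2", "estimate", "p.value", "n") %in% names(td)))
})

test_that("the simulated cohort has the study's structure", {
  co <- simulate_cohort(seed = 3)
  expect_equal(nrow(co), 43 * 3)
  expect_equal(sort(unique(co$muscle)), c("gas", "sol", "ta"))
  cnt <- dplyr::count(dplyr::distinct(co, subject_id, group), group)
  expect_equal(cnt$n[match(c("control", "distance", "powerlifting",
                             "teenager"), cnt$group)], c(12, 10, 11, 10))
  expect_true(all(co$radial_fwhm > 0) && all(co$rd > 0))
  # muscularity coupling: radial FWHM rank-correlates positively with SMI
  ta <- co[co$muscle == "ta", ]
  expect_gt(spearman_matrix(ta, c("smi", "radial_fwhm"))$rho[1, 2], 0.3)
  # determinism
  expect_identical(simulate_cohort(seed = 3), co)
})

test_that("group_summary reports means, SDs and Dunnett flags per group", {
  co <- simulate_cohort(seed = 3)
  ta <- co[co$muscle == "ta", ]
  gs <- group_summary(ta, c("smi", "radial_fwhm"))
  expect_equal(nrow(gs), 8)
  expect_true(all(is.na(gs$p.dunnett[gs$group == "control"])))
  expect_true(all(is.finite(gs$p.dunnett[gs$group != "control"])))
  ctrl <- ta$smi[ta$group == "control"]
  expect_equal(gs$mean[gs$variable == "smi" & gs$group == "control"],
               mean(ctrl))
  expect_equal(gs$sd[gs$variable == "smi" & gs$group == "control"],
               sd(ctrl))
})
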