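# Synthetic cohort generator: per-subject records for four groups
# (control, distance, powerlifting, teenager) with published group-level
# body-composition statistics and muscle metrics driven by a shared
# muscularity factor, standing in for the study's (non-deposited)
# per-subject table.

# Group-level body composition (mean, sd): control / distance running /
# powerlifting / teenager, group sizes 12 / 10 / 11 / 10.
.cohort_groups <- function() {
  tibble::tibble(
    group = c("control", "distance", "powerlifting", "teenager"),
    n = c(12L, 10L, 11L, 10L),
    age_mean = c(21.6, 21.4, 27.8, 13.0), age_sd = c(1.1, 1.2, 10.3, 0.4),
    height_mean = c(171.3, 169.5, 166.5, 161.7), height_sd = c(7.2, 4.1, 6.0, 5.6),
    weight_mean = c(64.1, 57.1, 86.5, 49.2), weight_sd = c(9.8, 4.3, 23.4, 6.1),
    fat_mean = c(17.0, 13.5, 24.6, 16.4), fat_sd = c(4.9, 3.4, 9.9, 6.1),
    smi_mean = c(7.80, 7.28, 9.64, 6.28), smi_sd = c(0.73, 0.28, 1.11, 0.63))
}

#' Simulate a per-subject cohort table
#'
#' Generates one record per subject and muscle for the four study groups
#' (group sizes 12/10/11/10). Body composition is drawn from the published
#' group means and SDs; imaging and architecture metrics (CSA, pennation
#' angle, RD, radial FWHM) are driven by each subject's standardized
#' skeletal-muscle-mass index plus independent noise, so that more
#' muscular subjects have larger fibres — reproducing the positive
#' rank-correlation structure between radial FWHM and SMI/CSA/PA without
#' asserting any particular coefficient.
#'
#' @param seed Integer RNG seed.
#' @param muscles Muscle labels to emit (default ta, sol, gas).
#' @return A tibble, one row per subject x muscle: `subject_id`, `group`,
#'   `age`, `height`, `weight`, `percent_fat`, `smi`, `muscle`, `csa`
#'   (cm^2), `pa` (degrees), `rd` (mm^2/s), `radial_fwhm` (um).
#' @export
simulate_cohort <- function(seed = 1L, muscles = c("ta", "sol", "gas")) {
  set.seed(seed)
  gi <- .cohort_groups()
  subj <- purrr::pmap_dfr(gi, function(group, n, age_mean, age_sd,
                                       height_mean, height_sd,
                                       weight_mean, weight_sd,
                                       fat_mean, fat_sd, smi_mean, smi_sd) {
    tibble::tibble(
      group = group,
      age = pmax(12, stats::rnorm(n, age_mean, age_sd)),
      height = stats::rnorm(n, height_mean, height_sd),
      weight = pmax(35, stats::rnorm(n, weight_mean, weight_sd)),
      percent_fat = pmax(4, stats::rnorm(n, fat_mean, fat_sd)),
      smi = pmax(4, stats::rnorm(n, smi_mean, smi_sd)))
  })
  subj$subject_id <- sprintf("S%02d", seq_len(nrow(subj)))
  z <- (subj$smi - mean(subj$smi)) / stats::sd(subj$smi)  # muscularity factor
  ns <- nrow(subj)
  base <- list(           # per-muscle baselines: csa cm^2, pa deg, fwhm um
    ta = list(csa = 10, pa = 10, fwhm = 16),
    sol = list(csa = 13, pa = 22, fwhm = 15),
    gas = list(csa = 11, pa = 18, fwhm = 17))
  purrr::map_dfr(muscles, function(m) {
    b <- base[[m]]
    sol_noise <- if (m == "sol") 2 else 1   # crossed fibres: noisier metrics
    tibble::tibble(
      subject_id = subj$subject_id, group = subj$group,
      age = subj$age, height = subj$height, weight = subj$weight,
      percent_fat = subj$percent_fat, smi = subj$smi,
      muscle = m,
      csa = pmax(2, b$csa * (1 + 0.18 * z) + stats::rnorm(ns, 0, 0.9)),
      pa = pmax(2, b$pa + 1.2 * z + stats::rnorm(ns, 0, 2.2)),
      rd = pmax(5e-4, 1.4e-3 + 6e-5 * z + stats::rnorm(ns, 0, 5e-5)),
      radial_fwhm = pmax(6, b$fwhm + 1.8 * z +
                           stats::rnorm(ns, 0, 1.0 * sol_noise)))
  })
}

#' Write / read a subjects table as TSV
#'
#' @param subjects Tibble from [simulate_cohort()] or [roi_summary()]
#'   joined with body scalars.
#' @param path Output path.
#' @return `write_subjects`: invisibly the path; `read_subjects`: a tibble.
#' @export
write_subjects <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}
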