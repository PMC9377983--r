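test_that("Gaussian compartment signal matches the closed form", {
  iso <- sym_tensor(diag(3) * 1e-3)
  expect_equal(signal_gaussian(protocol, 1, 1, iso), 1.0)
  # b = 800 shell (index 5), isotropic D = 1.0e-3 mm^2/s
  expect_equal(signal_gaussian(protocol, 5, 1, iso), exp(-0.8),
               tolerance = 1e-3)  # scheme b is the printed 800
  # prolate tensor, gradient along the principal axis
  g1 <- protocol$directions[1, ]
  comp <- gaussian_compartment(c(1.7, 0.3, 0.3) * 1e-3, axis = g1)
  expect_equal(signal_gaussian(protocol, 5, 1, comp),
               exp(-protocol$b_values[5] * 1.7e-3), tolerance = 1e-12)
  expect_error(signal_gaussian(protocol, 5, 1, sym_tensor(-diag(3) * 1e-3)),
               "semidefinite")
})

test_that("cylinder signal matches independently computed GPD values", {
  # frozen values from an independent evaluation of the GPD Bessel-root
  # series (scipy.special, 50 modes), gradient fully perpendicular,
  # D = 2.0e-3 mm^2/s, Delta/delta = 45.6/27.9 ms
  frozen <- rbind(
    c(10, 118.1, 0.931342059921), c(10, 236.3, 0.752198074733),
    c(10, 528.3, 0.240910102827), c(30, 118.1, 0.756837931094),
    c(30, 236.3, 0.327794498406), c(30, 528.3, 0.003791123168),
    c(60, 118.1, 0.710537129528), c(60, 236.3, 0.254591753672),
    c(60, 528.3, 0.001071897772))
  sch <- gradient_scheme(directions = rbind(c(1, 0, 0)),
                         b_values = protocol$b_values,
                         q_values = protocol$q_values,
                         big_delta = 45.6, small_delta = 27.9)
  for (r in seq_len(nrow(frozen))) {
    comp <- cylinder_compartment(frozen[r, 1], 2e-3, axis = c(0, 0, 1))
    shell <- match(frozen[r, 2], sch$q_values)
    expect_equal(signal_cylinder(sch, shell, 1, comp), frozen[r, 3],
                 tolerance = 1e-6)
  }
})

test_that("cylinder signal has the right limits and monotonicity", {
  sch <- gradient_scheme(directions = rbind(c(0, 0, 1), c(1, 0, 0)),
                         b_values = protocol$b_values,
                         q_values = protocol$q_values,
                         big_delta = 45.6, small_delta = 27.9)
  comp <- cylinder_compartment(30, 2e-3, axis = c(0, 0, 1))
  # parallel gradient: free axial diffusion
  for (s in c(3, 5, 10)) {
    expect_equal(signal_cylinder(sch, s, 1, comp),
                 exp(-sch$b_values[s] * 2e-3), tolerance = 1e-10)
  }
  # radius -> 0: fully restricted, E -> 1 at every q
  tiny <- cylinder_compartment(0.5, 2e-3, axis = c(0, 0, 1))
  for (s in seq_len(10)) {
    expect_gt(signal_cylinder(sch, s, 2, tiny), 0.999)
  }
  # at fixed perpendicular q > 0, smaller radius attenuates less
  e30 <- signal_cylinder(sch, 5, 2, comp)
  e60 <- signal_cylinder(sch, 5, 2, cylinder_compartment(60, 2e-3))
  expect_gt(e30, e60)
  expect_error(signal_cylinder(sch, 5, 2,
                               structure(list(model = "blob"),
                                         class = "compartment_spec")),
               "unsupported model")
  expect_error(cylinder_compartment(250), "radius")
})

test_that("signals are even in the gradient direction", {
  dirs <- rbind(c(1, 2, 3) / sqrt(14), -c(1, 2, 3) / sqrt(14))
  sch <- gradient_scheme(directions = dirs, b_values = protocol$b_values,
                         q_values = protocol$q_values,
                         big_delta = 45.6, small_delta = 27.9)
  tens <- sym_tensor(random_pd_tensor())
  cyl <- cylinder_compartment(25, 2e-3, axis = c(0, 1, 1) / sqrt(2))
  for (s in c(2, 5, 10)) {
    expect_equal(signal_gaussian(sch, s, 1, tens),
                 signal_gaussian(sch, s, 2, tens))
    expect_equal(signal_cylinder(sch, s, 1, cyl),
                 signal_cylinder(sch, s, 2, cyl))
  }
})

test_that("mixture signal is the volume-fraction-weighted sum", {
  a <- gaussian_compartment(c(2, 2, 2) * 1e-3, volume_fraction = 0.3)
  b <- cylinder_compartment(30, 2e-3, volume_fraction = 0.7)
  Em <- mixture_signal(protocol, list(a, b))
  Ea <- mixture_signal(protocol, list(gaussian_compartment(c(2, 2, 2) * 1e-3)))
  Eb <- mixture_signal(protocol, list(cylinder_compartment(30, 2e-3)))
  expect_equal(Em, 0.3 * Ea + 0.7 * Eb, tolerance = 1e-12)
  expect_error(mixture_signal(protocol, list(a)), "sum to 1")
})

test_that("phantom generation is exact at snr = Inf and deterministic", {
  ph <- gaussian_phantom(c(2, 2, 2) * 1e-3, grid = c(3, 2, 1))
  E <- mixture_signal(protocol, list(gaussian_compartment(c(2, 2, 2) * 1e-3)))
  expect_equal(ph$dwi[1, 1, 1, ], 1000 * as.vector(t(E)), tolerance = 1e-12)
  expect_equal(ph$dwi[3, 2, 1, ], ph$dwi[1, 1, 1, ])  # spatially constant
  p1 <- cylinder_phantom(30, grid = c(4, 4, 1), snr = 50, seed = 7)
  p2 <- cylinder_phantom(30, grid = c(4, 4, 1), snr = 50, seed = 7)
  expect_identical(p1$dwi, p2$dwi)
  p3 <- cylinder_phantom(30, grid = c(4, 4, 1), snr = 50, seed = 8)
  expect_false(identical(p1$dwi, p3$dwi))
})

test_that("pure-noise voxels follow the Rayleigh magnitude law", {
  # region label 0 leaves the forward signal at zero; the magnitudes of
  # those measurements are then Rayleigh with mean sigma * sqrt(pi/2)
  regions <- array(0L, dim = c(14, 14, 1)); regions[1, 1, 1] <- 1L
  spec <- phantom_spec(c(14, 14, 1),
                       list(list(gaussian_compartment(c(2, 2, 2) * 1e-3))),
                       protocol, snr = 50, seed = 11, regions = regions)
  ph <- generate_phantom(spec)
  noise <- as.vector(ph$dwi[, , , ])[as.vector(regions) == 0]
  sigma <- 1000 / 50
  expect_gt(length(noise), 1e4)
  expect_equal(mean(noise), sigma * sqrt(pi / 2), tolerance = 0.02)
})

test_that("phantom ground truth carries the Gaussian radial-FWHM proxy", {
  ph <- gaussian_phantom(c(1.7, 0.9, 0.7) * 1e-3)
  expect_equal(ph$truth$true_rd[1], 0.8e-3)
  expect_equal(ph$truth$true_radial_fwhm[1],
               (gauss_fwhm(0.9e-3) + gauss_fwhm(0.7e-3)) / 2)
  pc <- cylinder_phantom(42)
  expect_equal(pc$truth$true_radius[1], 42)
})

test_that("phantom files land on disk in plain formats", {
  dir <- withr::local_tempdir()
  ph <- gaussian_phantom(c(2, 2, 2) * 1e-3)
  files <- write_phantom(ph, dir)
  expect_true(all(file.exists(files)))
  back <- RNifti::readNifti(file.path(dir, "dwi.nii"))
  expect_equal(dim(back), dim(ph$dwi))
  expect_equal(as.array(back), ph$dwi, ignore_attr = TRUE, tolerance = 1e-6)
})
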