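# Scattering model kernels against closed forms and brute-force transforms.

test_that("sphere kernel matches closed-form values and stays bounded", {
  expect_identical(sphere_amplitude(0), 1)
  expect_equal(sphere_amplitude(pi), 3 / pi^2, tolerance = 1e-12)
  # first positive zero is the root of tan x = x, located independently
  root <- uniroot(function(x) sin(x) - x * cos(x), c(4, 4.6), tol = 1e-12)$root
  expect_equal(root, 4.493409, tolerance = 1e-6)
  expect_lt(abs(sphere_amplitude(root)), 1e-12)
  x <- seq(0, 60, length.out = 4000)
  expect_true(all(abs(sphere_amplitude(x)) <= 1))
  # continuity across the series/exact switch at x = 1e-2
  expect_equal(sphere_amplitude(0.00999999), sphere_amplitude(0.01000001),
               tolerance = 1e-10)
  expect_error(sphere_amplitude(-1))
})

test_that("monodisperse vesicle intensity matches the step-profile transform", {
  dsld <- 6.0e-6
  m <- vesicle_model(R = 300, p = 0, d_L = 40.5,
                     sld_shell = 6.34e-6 + dsld, sld_solvent = 6.34e-6)
  q <- c(0.005, 0.01, 0.05, 0.1, 0.3, 0.5)
  expect_equal(vesicle_intensity_mono(q, m),
               oracle_shell_intensity(q, 300, 40.5, dsld),
               tolerance = 1e-10)
  # q -> 0 limit: scale * dsld^2 * V_shell
  V_shell <- 4 * pi / 3 * (340.5^3 - 300^3)
  expect_equal(vesicle_intensity_mono(1e-7, m), dsld^2 * V_shell,
               tolerance = 1e-8)
})

test_that("zero contrast yields pure background for any geometry", {
  q <- exp(seq(log(0.005), log(0.5), length.out = 50))
  for (pars in list(c(R = 150, d_L = 30), c(R = 300, d_L = 40.5),
                    c(R = 600, d_L = 55))) {
    m <- vesicle_model(R = pars[["R"]], p = 0.25, d_L = pars[["d_L"]],
                       sld_shell = 4.2e-6, sld_solvent = 4.2e-6,
                       background = 0.07)
    expect_equal(vesicle_intensity_poly(q, m), rep(0.07, length(q)),
                 tolerance = 1e-14)
  }
})

test_that("scale multiplies intensity minus background exactly in both models", {
  q <- exp(seq(log(0.01), log(0.5), length.out = 40))
  mv <- neat_vesicle(background = 0.003)
  mv5 <- neat_vesicle(scale = 5, background = 0.003)
  expect_equal(vesicle_intensity_poly(q, mv5) - 0.003,
               5 * (vesicle_intensity_poly(q, mv) - 0.003), tolerance = 1e-13)
  qx <- seq(0.05, 1.3, length.out = 40)
  mb <- neat_bilayer(background = 0.1)
  mb5 <- neat_bilayer(scale = 5, background = 0.1)
  expect_equal(saxs_intensity(qx, mb5) - 0.1,
               5 * (saxs_intensity(qx, mb) - 0.1), tolerance = 1e-13)
})

test_that("Schulz pdf integrates to one with the stated mean and variance", {
  for (par in list(c(300, 0.3), c(250, 0.34), c(600, 0.1))) {
    d <- schulz_dist(par[1], par[2])
    hi <- par[1] * (1 + 15 * par[2])
    m0 <- integrate(function(R) schulz_pdf(R, d), 0, hi, rel.tol = 1e-10)$value
    m1 <- integrate(function(R) R * schulz_pdf(R, d), 0, hi, rel.tol = 1e-10)$value
    m2 <- integrate(function(R) R^2 * schulz_pdf(R, d), 0, hi, rel.tol = 1e-10)$value
    expect_equal(m0, 1, tolerance = 1e-8)
    expect_equal(m1, par[1], tolerance = 1e-8)
    expect_equal(m2 - m1^2, par[1]^2 * par[2]^2, tolerance = 1e-6)
  }
  expect_error(schulz_dist(300, 0), class = "vesiclefit_validation_error")
})

test_that("polydisperse intensity converges to the monodisperse limit as p -> 0", {
  q <- exp(seq(log(0.005), log(0.5), length.out = 60))
  m <- vesicle_model(R = 300, p = 1e-4, d_L = 40.5)
  mono <- vesicle_intensity_mono(q, vesicle_model(R = 300, p = 0, d_L = 40.5))
  expect_equal(vesicle_intensity_poly(q, m), mono, tolerance = 1e-6)
  # p = 0 falls back exactly
  m0 <- vesicle_model(R = 300, p = 0, d_L = 40.5)
  expect_identical(vesicle_intensity_poly(q, m0), mono)
})

test_that("closed-form Schulz average matches dense adaptive quadrature", {
  q <- exp(seq(log(0.005), log(0.5), length.out = 25))
  m <- neat_vesicle()
  dsld <- m$pars[["sld_shell"]] - m$pars[["sld_solvent"]]
  brute <- oracle_poly_intensity(q, 300, 0.3, 40.5, dsld)
  expect_equal(vesicle_intensity_poly(q, m), brute, tolerance = 1e-6)
})

test_that("quadrature path cross-checks the closed form and flags aliasing", {
  q <- exp(seq(log(0.005), log(0.5), length.out = 30))
  m <- vesicle_model(R = 300, p = 0.33, d_L = 40.5)
  exact <- vesicle_intensity_poly(q, m)
  quad <- vesicle_intensity_poly(q, m, n_quad = 512, method = "quadrature",
                                 check_convergence = FALSE)
  expect_equal(quad, exact, tolerance = 1e-3)
  # a 64-node rule cannot resolve the high-q oscillations in R: the doubling
  # criterion must signal rather than return silently wrong values
  expect_error(vesicle_intensity_poly(q, m, n_quad = 64, method = "quadrature"),
               class = "vesiclefit_numerical_error")
  expect_error(vesicle_intensity_poly(q, m, n_quad = 8, method = "quadrature"),
               class = "vesiclefit_validation_error")
})

test_that("low-q pit sits at the vesicle-diameter scale and polydispersity fills it", {
  q <- exp(seq(log(0.005), log(0.05), length.out = 400))
  I0 <- vesicle_intensity_mono(q, vesicle_model(R = 300, p = 0, d_L = 40.5))
  i0 <- first_local_min(I0)
  expect_false(is.na(i0))
  d_out <- 2 * (300 + 40.5)
  expect_lt(abs(2 * pi / q[i0] - d_out) / d_out, 0.15)
  # mild polydispersity keeps the pit but makes it shallower
  Ip <- vesicle_intensity_poly(q, vesicle_model(R = 300, p = 0.05, d_L = 40.5))
  ip <- first_local_min(Ip)
  expect_false(is.na(ip))
  contrast <- function(I) (max(I) - min(I)) / max(I)
  win <- q > 0.006 & q < 0.02
  expect_lt(contrast(Ip[win]), contrast(I0[win]))
  # at the study's p = 0.3 the pit is fully washed out (weakly pronounced
  # in real curves): intensity is monotone over the pit window
  I3 <- vesicle_intensity_poly(q, neat_vesicle())
  expect_true(is.na(first_local_min(I3[win])))
})

test_that("bilayer amplitude is the cosine transform of the density profile", {
  m <- neat_bilayer()
  q <- seq(0, 1.3, length.out = 40)
  num <- oracle_cosine_transform(q, function(z) edp_profile(m, z))
  expect_equal(gaussian_bilayer_amplitude(q, m), num, tolerance = 1e-9)
  # q = 0 equals the profile integral
  p <- m$pars
  expect_equal(gaussian_bilayer_amplitude(0, m),
               sqrt(2 * pi) * (2 * p[["rho_head"]] * p[["sigma_head"]] +
                               p[["rho_tail"]] * p[["sigma_tail"]]),
               tolerance = 1e-13)
})

test_that("suppressing the head groups leaves a pure Gaussian decay", {
  # rho_head = 0 is outside the constructor's domain; evaluate the head-free
  # limit by continuity
  m <- gaussian_bilayer_model(z_H = 18.35, rho_head = 1e-12, rho_tail = -1)
  q <- seq(0.01, 1.3, length.out = 50)
  expect_equal(gaussian_bilayer_amplitude(q, m),
               -sqrt(2 * pi) * 5.8 * exp(-q^2 * 5.8^2 / 2), tolerance = 1e-9)
})

test_that("SAXS intensity floors at the background and zeros follow the amplitude", {
  q <- seq(0.05, 1.3, length.out = 300)
  m <- neat_bilayer(background = 0.02)
  I <- saxs_intensity(q, m)
  expect_true(all(I >= 0.02))
  m0 <- neat_bilayer()
  # a bracketed root of F_b is an intensity zero when background = 0
  Fb <- function(qq) gaussian_bilayer_amplitude(qq, m0)
  r <- uniroot(Fb, c(0.05, 0.3), tol = 1e-14)$root
  expect_lt(saxs_intensity(r, m0), 1e-20)
})

test_that("spherical-shell and flat-sheet branches agree above q = 0.05", {
  q <- exp(seq(log(0.05), log(1.3), length.out = 120))
  m <- neat_bilayer()  # R_ves = 300, sigma_R = 90
  I_flat <- saxs_intensity(q, m, use_vesicle_factor = FALSE)
  I_ves <- saxs_intensity(q, m, use_vesicle_factor = TRUE)
  expect_lt(max(abs(I_flat - I_ves) / I_flat), 0.01)
  # flat branch refuses q below 3/R_ves
  expect_error(saxs_intensity(c(0.004, 0.1), m),
               class = "vesiclefit_validation_error")
  expect_silent(saxs_intensity(c(0.004, 0.1), m, use_vesicle_factor = TRUE))
})

test_that("electron density profile is even with head peaks at +/- z_H", {
  m <- neat_bilayer()
  z <- seq(-40, 40, length.out = 1601)
  rho <- edp_profile(m, z)
  expect_equal(rho, rev(rho), tolerance = 1e-14)
  peaks <- which(diff(sign(diff(rho))) == -2) + 1L
  expect_length(peaks, 2L)
  d_HH_prof <- abs(diff(z[peaks]))
  expect_equal(d_HH_prof, 36.7, tolerance = 0.01)
})

test_that("model constructors reject out-of-domain parameters", {
  expect_error(vesicle_model(R = -1), class = "vesiclefit_validation_error")
  expect_error(vesicle_model(p = 1), class = "vesiclefit_validation_error")
  expect_error(vesicle_model(d_L = 0), class = "vesiclefit_validation_error")
  expect_error(gaussian_bilayer_model(rho_tail = 0.5),
               class = "vesiclefit_validation_error")
  expect_error(gaussian_bilayer_model(z_H = -2),
               class = "vesiclefit_validation_error")
})
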