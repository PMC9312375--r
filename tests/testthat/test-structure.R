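# Derived structural quantities: A_L, leaflet ratio, Schulz FWHM, summaries.

test_that("area per lipid follows A_L = 2 V_L / d_L with propagated error", {
  r <- area_per_lipid(1253, 40.5)
  expect_equal(r$A_L, 2 * 1253 / 40.5, tolerance = 1e-14)
  expect_equal(r$A_L, 61.88, tolerance = 1e-3)
  # linearity
  expect_equal(area_per_lipid(2 * 1253, 40.5)$A_L, 2 * r$A_L, tolerance = 1e-14)
  # propagation with sigma_d = 0
  expect_equal(area_per_lipid(1253, 40.5, sigma_V = 3)$stderr, 2 * 3 / 40.5,
               tolerance = 1e-14)
  expect_error(area_per_lipid(1253, 0), class = "vesiclefit_validation_error")
})

test_that("leaflet number ratio reproduces the printed 300 A value", {
  expect_equal(round(leaflet_number_ratio(300, 40.5), 2), 1.13)
  # mid-surface convention at R = 200 A (documented, see vignette)
  expect_equal(leaflet_number_ratio(200, 40.5), 1.202, tolerance = 1e-3)
  # vanishing bilayer
  expect_equal(leaflet_number_ratio(300, 1e-9), 1, tolerance = 1e-10)
})

test_that("leaflet ratio is monotone in R and d_L", {
  R <- seq(100, 1000, by = 50)
  r_R <- leaflet_number_ratio(R, 40.5)
  expect_true(all(diff(r_R) < 0))
  d <- seq(20, 60, by = 2)
  r_d <- leaflet_number_ratio(300, d)
  expect_true(all(diff(r_d) > 0))
  expect_true(all(r_R > 1) && all(r_d > 1))
})

test_that("Schulz FWHM approaches the Gaussian limit and scales with the mean", {
  d <- schulz_dist(300, 0.02)
  gauss_fwhm <- 2 * sqrt(2 * log(2)) * 0.02 * 300
  expect_lt(abs(schulz_fwhm(d) - gauss_fwhm) / gauss_fwhm, 0.005)
  # scale family: FWHM linear in the mean at fixed p
  f1 <- schulz_fwhm(schulz_dist(250, 0.3))
  f2 <- schulz_fwhm(schulz_dist(500, 0.3))
  expect_equal(f2 / f1, 2, tolerance = 1e-8)
})

test_that("Schulz FWHM matches a dense-grid brute-force search", {
  for (par in list(c(300, 0.3), c(250, 0.34), c(220, 0.15))) {
    d <- schulz_dist(par[1], par[2])
    R <- seq(1e-3, par[1] * 4, length.out = 400000)
    f <- schulz_pdf(R, d)
    above <- R[f >= max(f) / 2]
    brute <- max(above) - min(above)
    expect_lt(abs(schulz_fwhm(d) - brute) / brute, 1e-3)
  }
})

test_that("a polydispersity giving a 200 A FWHM exists near the study mean", {
  # bracketed solve for p at mean = 250 A, as used to summarise the fitted
  # radius distributions
  g <- function(p) schulz_fwhm(schulz_dist(250, p)) - 200
  p_star <- uniroot(g, c(0.05, 0.6), tol = 1e-8)$root
  expect_gt(p_star, 0.05); expect_lt(p_star, 0.6)
  expect_equal(schulz_fwhm(schulz_dist(250, p_star)), 200, tolerance = 1e-6)
})

make_neat_fits <- function(c_ion = 0, d_L = 40.5, z_H = 18.35, seed = NULL,
                           noise = 0) {
  sans <- make_sans_curve(vesicle_model(R = 300, p = 0.3, d_L = d_L),
                          noise = noise, seed = seed, c_ion = c_ion, ion = "Ca")
  saxs <- make_saxs_curve(gaussian_bilayer_model(z_H = z_H), noise = noise,
                          seed = if (is.null(seed)) NULL else seed + 1,
                          c_ion = c_ion, ion = "Ca")
  list(sans = sas_fit(sans, vesicle_model(R = 320, p = 0.3, d_L = d_L + 2)),
       saxs = sas_fit(saxs, gaussian_bilayer_model(z_H = z_H + 2)))
}

test_that("neat ground truth survives the summary round trip", {
  fits <- make_neat_fits()
  v <- 1253 * N_AVOGADRO / (MOLAR_MASS[["POPC"]] * 1e24)
  dens <- density_series(T = 25, rho_disp = 1 / (0.01 * v + 0.99 / 0.997045),
                         rho_buf = 0.997045, w_L = 0.01, c_ion = 0, ion = "Ca")
  vol <- lipid_volume(dens)
  sm <- structural_summary(fits$sans, fits$saxs, vol)
  expect_equal(sm$values[["V_L"]], 1253, tolerance = 1e-8)
  expect_equal(sm$values[["d_L"]], 40.5, tolerance = 1e-4)
  expect_equal(sm$values[["d_HH"]], 36.7, tolerance = 1e-4)
  # algebraic identity holds to machine precision
  expect_equal(sm$values[["A_L"]] * sm$values[["d_L"]] / 2,
               sm$values[["V_L"]], tolerance = 1e-12)
  expect_equal(sm$values[["l_avg"]], sqrt(sm$values[["A_L"]]),
               tolerance = 1e-14)
})

test_that("zero input errors propagate to zero summary errors", {
  fits <- make_neat_fits()
  v <- 1253 * N_AVOGADRO / (MOLAR_MASS[["POPC"]] * 1e24)
  dens <- density_series(T = 25, rho_disp = 1 / (0.01 * v + 0.99 / 0.997045),
                         rho_buf = 0.997045, w_L = 0.01, c_ion = 0, ion = "Ca")
  vol <- lipid_volume(dens, sys_err = 0)
  # noiseless fits carry numerically negligible stderr; force the all-zero case
  fits$sans$stderr[] <- 0; fits$saxs$stderr[] <- 0
  sm <- structural_summary(fits$sans, fits$saxs, vol)
  expect_true(all(sm$errors == 0))
})

test_that("a 0.5 A thickness dip at 50 mM flags d_L but not A_L at 1 sigma", {
  # construct summaries with controlled errors: sigma_d = 0.4 A, sigma_V = 3
  ref_fits <- make_neat_fits(c_ion = 0, noise = 0.02, seed = 301)
  hi_fits <- make_neat_fits(c_ion = 50, d_L = 40.0, z_H = 18.35,
                            noise = 0.02, seed = 401)
  mkvol <- function(c_ion) {
    v <- 1253 * N_AVOGADRO / (MOLAR_MASS[["POPC"]] * 1e24)
    d <- density_series(T = 25, rho_disp = 1 / (0.01 * v + 0.99 / 0.997045),
                        rho_buf = 0.997045, w_L = 0.01, c_ion = c_ion,
                        ion = "Ca")
    lipid_volume(d, sys_err = 3)
  }
  ref_fits$sans$stderr["d_L"] <- 0.2; hi_fits$sans$stderr["d_L"] <- 0.2
  ref <- structural_summary(ref_fits$sans, ref_fits$saxs, mkvol(0))
  sm <- structural_summary(hi_fits$sans, hi_fits$saxs, mkvol(50),
                           reference = ref)
  # combined sigma_d = sqrt(2) * 0.2 = 0.28 < 0.5 dip -> flagged
  expect_true(sm$changed[["d_L"]])
  # volume unchanged within its 3 A^3 band -> not flagged
  expect_false(sm$changed[["V_L"]])
  # the A_L flag follows the propagated-error criterion exactly
  dA <- abs(sm$values[["A_L"]] - ref$values[["A_L"]])
  sA <- sqrt(sm$errors[["A_L"]]^2 + ref$errors[["A_L"]]^2)
  expect_identical(sm$changed[["A_L"]], dA > sA)
})

test_that("mismatched ion tags between techniques are refused", {
  f0 <- make_neat_fits(c_ion = 0)
  f50 <- make_neat_fits(c_ion = 50)
  v <- 1253 * N_AVOGADRO / (MOLAR_MASS[["POPC"]] * 1e24)
  dens <- density_series(T = 25, rho_disp = 1 / (0.01 * v + 0.99 / 0.997045),
                         rho_buf = 0.997045, w_L = 0.01, c_ion = 0, ion = "Ca")
  vol <- lipid_volume(dens)
  expect_error(structural_summary(f0$sans, f50$saxs, vol),
               class = "vesiclefit_validation_error")
})
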