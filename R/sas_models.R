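#' Sphere form-factor kernel
#'
#' The normalised amplitude of a homogeneous sphere,
#' `Phi(x) = 3 (sin x - x cos x) / x^3`, with `Phi(0) = 1` by series
#' expansion (no 0/0 at the origin). `|Phi| <= 1` everywhere.
#'
#' @param x dimensionless `q * R`; >= 0.
#' @return `Phi(x)`, same shape as `x`.
#' @export
sphere_amplitude <- function(x) {
  stopifnot(all(x >= 0))
  out <- numeric(length(x))
  small <- x < 1e-2
  xs <- x[small]
  ## Taylor: 1 - x^2/10 + x^4/280 (next term ~ x^6/15120, < 1e-16 at x = 0.01)
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' Single-shell spherical vesicle model (SANS)
#'
#' Parameters of a spherical vesicle whose bilayer is a single homogeneous
#' shell of thickness `d_L` on an aqueous core of radius `R`. `R` denotes the
#' inner (core) radius; the outer radius is `R + d_L`. Size polydispersity is
#' a Schulz distribution of `R` with relative width `p` (thickness held
#' monodisperse).
#'
#' @param R mean inner (core) radius, A; > 0.
#' @param p Schulz polydispersity sigma_R / R; in [0, 1). `p = 0` means
#'   monodisperse.
#' @param d_L shell (bilayer) thickness, A; > 0.
#' @param sld_shell shell scattering length density, 1/A^2. Default: average
#'   H-lipid bilayer.
#' @param sld_solvent solvent scattering length density, 1/A^2. Default: D2O,
#'   the high-contrast solvent for hydrogenated membranes.
#' @param scale volume-fraction-like intensity prefactor; >= 0.
#' @param background flat incoherent background, intensity units; >= 0.
#' @return object of class `c("vesicle_model", "sas_model")`.
#' @export
vesicle_model <- function(R = 300, p = 0.3, d_L = 40.5,
                          sld_shell = -0.3e-6, sld_solvent = 6.34e-6,
                          scale = 1, background = 0) {
  pars <- c(R = R, p = p, d_L = d_L, sld_shell = sld_shell,
            sld_solvent = sld_solvent, scale = scale, background = background)
  m <- structure(list(pars = pars), class = c("vesicle_model", "sas_model"))
  validate_model(m)
  m
}

#' Symmetric three-Gaussian bilayer model (SAXS)
#'
#' The bilayer's relative electron density profile (solvent subtracted) along
#' the membrane normal `z` is the sum of two positive head-group Gaussians at
#' `+/- z_H` and one negative tail Gaussian at the midplane:
#' `rho(z) = rho_tail exp(-z^2/(2 sigma_tail^2)) +
#'  rho_head [exp(-(z-z_H)^2/(2 sigma_head^2)) + exp(-(z+z_H)^2/(2 sigma_head^2))]`.
#' The head-to-head (phosphorus-phosphorus) distance is `d_HH = 2 z_H`.
#' Gaussian widths default to the fixed fluid-phase values 3.6 A (head) and
#' 5.8 A (tail) at 25 C; the vesicle radius `R_ves` and its width `sigma_R`
#' only enter the optional spherical-shell intensity factor and are held fixed
#' in fits (high-q SAXS is insensitive to them).
#'
#' @param z_H head-group Gaussian centre distance from the midplane, A; > 0.
#' @param sigma_head head Gaussian width, A; > 0.
#' @param sigma_tail tail Gaussian width, A; > 0.
#' @param rho_head head amplitude, relative electron density; > 0.
#' @param rho_tail tail amplitude, relative electron density; < 0.
#' @param scale intensity prefactor; >= 0.
#' @param background flat background; >= 0.
#' @param R_ves fixed vesicle mid-shell radius, A (spherical factor only).
#' @param sigma_R fixed vesicle radius distribution width, A (spherical
#'   factor only).
#' @return object of class `c("gaussian_bilayer_model", "sas_model")`.
#' @export
gaussian_bilayer_model <- function(z_H = 18.35, sigma_head = 3.6,
                                   sigma_tail = 5.8, rho_head = 1,
                                   rho_tail = -1, scale = 1, background = 0,
                                   R_ves = 300, sigma_R = 90) {
  pars <- c(z_H = z_H, sigma_head = sigma_head, sigma_tail = sigma_tail,
            rho_head = rho_head, rho_tail = rho_tail, scale = scale,
            background = background, R_ves = R_ves, sigma_R = sigma_R)
  m <- structure(list(pars = pars),
                 class = c("gaussian_bilayer_model", "sas_model"))
  validate_model(m)
  m
}

## parameter-vector plumbing shared by the fitter -----------------------------

#' @export
coef.sas_model <- function(object, ...) object$pars

set_pars <- function(model, pars) {
  model$pars[names(pars)] <- pars
  model
}

validate_model <- function(model) UseMethod("validate_model")

#' @export
validate_model.vesicle_model <- function(model) {
  p <- model$pars
  if (p[["R"]] <= 0) stop_validation("vesicle model: R must be > 0")
  if (p[["p"]] < 0 || p[["p"]] >= 1)
    stop_validation("vesicle model: p must be in [0, 1)")
  if (p[["d_L"]] <= 0) stop_validation("vesicle model: d_L must be > 0")
  if (p[["scale"]] < 0) stop_validation("vesicle model: scale must be >= 0")
  if (p[["background"]] < 0)
    stop_validation("vesicle model: background must be >= 0")
  invisible(model)
}

#' @export
validate_model.gaussian_bilayer_model <- function(model) {
  p <- model$pars
  if (p[["z_H"]] <= 0) stop_validation("bilayer model: z_H must be > 0")
  if (p[["sigma_head"]] <= 0 || p[["sigma_tail"]] <= 0)
    stop_validation("bilayer model: Gaussian widths must be > 0")
  if (p[["rho_head"]] <= 0)
    stop_validation("bilayer model: rho_head must be > 0")
  if (p[["rho_tail"]] >= 0)
    stop_validation("bilayer model: rho_tail must be < 0")
  if (p[["scale"]] < 0 || p[["background"]] < 0)
    stop_validation("bilayer model: scale and background must be >= 0")
  invisible(model)
}

#' @export
print.sas_model <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  print(signif(x$pars, 6))
  invisible(x)
}

## SANS: monodisperse vesicle --------------------------------------------------

#' Monodisperse single-shell vesicle intensity
#'
#' Scattering amplitude of a spherical shell between radii `R` and
#' `R + d_L` with uniform contrast `dsld = sld_shell - sld_solvent`:
#' `F(q) = (4 pi / 3) dsld [R_out^3 Phi(q R_out) - R^3 Phi(q R)]`.
#' The intensity is normalised per shell volume:
#' `I(q) = scale F(q)^2 / V_shell + background`.
#'
#' @param q momentum transfer, 1/A; all > 0.
#' @param model a [vesicle_model()] (its `p` is ignored here).
#' @return intensity, same length as `q`.
#' @export
vesicle_intensity_mono <- function(q, model) {
  stopifnot(inherits(model, "vesicle_model"), all(q > 0))
  p <- model$pars
  R <- p[["R"]]; d <- p[["d_L"]]
  R_out <- R + d
  if (R_out <= R) stop_validation("invalid model: outer radius <= inner radius")
  dsld <- p[["sld_shell"]] - p[["sld_solvent"]]
  V_shell <- 4 * pi / 3 * (R_out^3 - R^3)
  Fq <- 4 * pi / 3 * dsld *
    (R_out^3 * sphere_amplitude(q * R_out) - R^3 * sphere_amplitude(q * R))
  p[["scale"]] * Fq^2 / V_shell + p[["background"]]
}

## Closed-form Schulz average of the shell form factor.
##
## With u = qR, w = q d_L and g(x) = sin x - x cos x, the amplitude difference
## g(u + w) - g(u) reduces to (A + B u) sin u + (C + D u) cos u with
##   A = cos w - 1 + w sin w,  B = sin w,
##   C = sin w - w cos w,      D = 1 - cos w,
## so E[(g(u+w) - g(u))^2] needs only E[u^m] and E[u^m e^{2iu}] (m = 0, 1, 2),
## which are closed-form gamma moments. This average is exact: the strongly
## oscillatory high-q terms, which defeat generic fixed-grid quadrature, are
## damped analytically by the characteristic function.
vesicle_poly_exact <- function(q, model) {
  p <- model$pars
  dist <- schulz_dist(p[["R"]], p[["p"]])
  d <- p[["d_L"]]
  dsld <- p[["sld_shell"]] - p[["sld_solvent"]]
  w <- q * d
  A <- cos(w) - 1 + w * sin(w)
  B <- sin(w)
  C <- sin(w) - w * cos(w)
  D <- 1 - cos(w)
  m1 <- schulz_moment(1, dist); m2 <- schulz_moment(2, dist)
  u1 <- q * m1; u2 <- q^2 * m2
  M0 <- schulz_cmoment(2 * q, 0, dist)
  M1 <- q   * schulz_cmoment(2 * q, 1, dist)
  M2 <- q^2 * schulz_cmoment(2 * q, 2, dist)
  Edelta2 <-
    0.5 * (A^2 + C^2 + 2 * (A * B + C * D) * u1 + (B^2 + D^2) * u2) +
    0.5 * Re((C^2 - A^2) * M0 + 2 * (C * D - A * B) * M1 + (D^2 - B^2) * M2) +
    Im(A * C * M0 + (A * D + B * C) * M1 + B * D * M2)
  V_mean <- 4 * pi / 3 * (3 * d * m2 + 3 * d^2 * m1 + d^3)
  p[["scale"]] * (4 * pi * dsld)^2 * Edelta2 / (q^6 * V_mean) +
    p[["background"]]
}

## Gauss-Legendre nodes/weights on [a, b] by Golub-Welsch (symmetric
## tridiagonal Jacobi matrix); small n only, used by the quadrature
## cross-check path.
gauss_legendre <- function(n, a, b) {
  if (n == 1L) {
    x <- 0; w <- 2
  } else {
    j <- seq_len(n - 1)
    beta <- j / sqrt(4 * j^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(j, j + 1)] <- beta
    J[cbind(j + 1, j)] <- beta
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1, ]^2
  }
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

vesicle_poly_quadrature <- function(q, model, n_quad, check_convergence = TRUE) {
  p <- model$pars
  dist <- schulz_dist(p[["R"]], p[["p"]])
  sd_R <- dist$p * dist$mean
  lo <- max(1e-6, dist$mean - 5 * sd_R)
  hi <- dist$mean + 8 * sd_R
  eval_at <- function(n) {
    ## composite Gauss-Legendre: 16-node panels, at least ceil(n/16) panels
    n_panel <- max(1L, ceiling(n / 16))
    edges <- seq(lo, hi, length.out = n_panel + 1L)
    num <- numeric(length(q)); Vnum <- 0
    for (i in seq_len(n_panel)) {
      gl <- gauss_legendre(16L, edges[i], edges[i + 1L])
      f <- schulz_pdf(gl$x, dist)
      for (j in seq_along(gl$x)) {
        mj <- model
        mj$pars[["R"]] <- gl$x[j]
        mj$pars[["p"]] <- 0
        mj$pars[["scale"]] <- 1
        mj$pars[["background"]] <- 0
        R_out <- gl$x[j] + p[["d_L"]]
        Vj <- 4 * pi / 3 * (R_out^3 - gl$x[j]^3)
        num <- num + gl$w[j] * f[j] * vesicle_intensity_mono(q, mj) * Vj
        Vnum <- Vnum + gl$w[j] * f[j] * Vj
      }
    }
    num / Vnum
  }
  I1 <- eval_at(n_quad)
  if (check_convergence) {
    I2 <- eval_at(2L * n_quad)
    rel <- max(abs(I1 - I2) / pmax(abs(I2), .Machine$double.xmin))
    if (rel > 1e-3)
      stop_numerical(sprintf(
        "Schulz quadrature not converged: doubling n_quad = %d changes the ",
        n_quad), sprintf("intensity by %.3g (> 0.1%%); increase n_quad", rel))
  }
  p[["scale"]] * I1 + p[["background"]]
}

#' Polydisperse single-shell vesicle intensity
#'
#' Number-weighted Schulz average of [vesicle_intensity_mono()] over the core
#' radius `R` (shell thickness monodisperse), normalised by the equally
#' weighted mean shell volume. The default `method = "exact"` evaluates the
#' average in closed form through the gamma-distribution complex moments
#' `E[R^m e^{2iqR}]`; it is exact for every `q` and costs the same as a single
#' monodisperse evaluation. `method = "quadrature"` integrates numerically
#' with an `n_quad`-node composite Gauss-Legendre rule over
#' `R` in `[max(0, mean - 5 sd), mean + 8 sd]` and signals non-convergence
#' when doubling `n_quad` moves any point by more than 0.1% (at high `q` the
#' integrand oscillates in `R` with period `pi/q`, so low node counts alias);
#' it exists as an independent cross-check of the closed form.
#'
#' @param q momentum transfer grid, 1/A; all > 0.
#' @param model a [vesicle_model()]; `p = 0` falls back to the monodisperse
#'   intensity.
#' @param n_quad quadrature node count (`method = "quadrature"` only); >= 16.
#' @param method `"exact"` (closed form, default) or `"quadrature"`.
#' @param check_convergence for the quadrature path, verify the 0.1% doubling
#'   criterion (default `TRUE`).
#' @return intensity, same length as `q`.
#' @export
vesicle_intensity_poly <- function(q, model, n_quad = 128L,
                                   method = c("exact", "quadrature"),
                                   check_convergence = TRUE) {
  stopifnot(inherits(model, "vesicle_model"), all(q > 0))
  method <- match.arg(method)
  if (model$pars[["p"]] <= 0) return(vesicle_intensity_mono(q, model))
  if (method == "exact") {
    vesicle_poly_exact(q, model)
  } else {
    if (n_quad < 16L) stop_validation("n_quad must be >= 16")
    vesicle_poly_quadrature(q, model, as.integer(n_quad), check_convergence)
  }
}

## SAXS: three-Gaussian bilayer ------------------------------------------------

#' Amplitude of the symmetric three-Gaussian bilayer
#'
#' Analytic cosine transform of the real-space profile:
#' `F_b(q) = sqrt(2 pi) [2 rho_head sigma_head cos(q z_H) exp(-q^2 sigma_head^2 / 2)
#'                      + rho_tail sigma_tail exp(-q^2 sigma_tail^2 / 2)]`.
#' At `q = 0` this equals the integral of the relative electron density
#' profile.
#'
#' @param q momentum transfer, 1/A; >= 0.
#' @param model a [gaussian_bilayer_model()].
#' @return amplitude, same length as `q`.
#' @export
gaussian_bilayer_amplitude <- function(q, model) {
  stopifnot(inherits(model, "gaussian_bilayer_model"), all(q >= 0))
  p <- model$pars
  sqrt(2 * pi) * (
    2 * p[["rho_head"]] * p[["sigma_head"]] * cos(q * p[["z_H"]]) *
      exp(-q^2 * p[["sigma_head"]]^2 / 2) +
    p[["rho_tail"]] * p[["sigma_tail"]] * exp(-q^2 * p[["sigma_tail"]]^2 / 2))
}

## Schulz-averaged thin-shell sphere factor, normalised so that it tends to
## 1/q^2 once the radius distribution washes out the sphere oscillations:
## S(q) = 2 <R^2 sin^2(qR)> / (<R^2> q^2), using the closed-form moments.
thin_shell_factor <- function(q, R_ves, sigma_R) {
  dist <- schulz_dist(R_ves, sigma_R / R_ves)
  m2 <- schulz_moment(2, dist)
  cos_m2 <- Re(schulz_cmoment(2 * q, 2, dist))
  (m2 - cos_m2) / (m2 * q^2)
}

#' SAXS intensity of a vesicle with a three-Gaussian bilayer
#'
#' Default (`use_vesicle_factor = FALSE`): the thin-sheet (separated form
#' factor) approximation for a locally flat bilayer,
#' `I(q) = scale F_b(q)^2 / q^2 + background`, valid for `q >> 1/R_ves`.
#' With `use_vesicle_factor = TRUE` the `1/q^2` term is replaced by the
#' Schulz-averaged thin-shell sphere factor built from the fixed `R_ves` and
#' `sigma_R`; both branches agree closely for `q >= 0.05` 1/A at
#' `R_ves = 300` A.
#'
#' @param q momentum transfer grid, 1/A; all > 0. With the flat-sheet branch,
#'   `q` must not extend below `3 / R_ves` (the approximation fails there).
#' @param model a [gaussian_bilayer_model()].
#' @param use_vesicle_factor use the spherical-shell factor instead of
#'   `1/q^2`.
#' @return intensity, same length as `q`.
#' @export
saxs_intensity <- function(q, model, use_vesicle_factor = FALSE) {
  stopifnot(inherits(model, "gaussian_bilayer_model"), all(q > 0))
  p <- model$pars
  Fb2 <- gaussian_bilayer_amplitude(q, model)^2
  if (use_vesicle_factor) {
    S <- thin_shell_factor(q, p[["R_ves"]], p[["sigma_R"]])
  } else {
    if (min(q) < 3 / p[["R_ves"]])
      stop_validation(sprintf(
        "flat-sheet approximation invalid: q extends below 3/R_ves = %.4g 1/A; ",
        3 / p[["R_ves"]]), "use use_vesicle_factor = TRUE or restrict q")
    S <- 1 / q^2
  }
  p[["scale"]] * Fb2 * S + p[["background"]]
}

#' Relative electron density profile of the three-Gaussian bilayer
#'
#' Evaluates `rho(z)` (solvent-subtracted, even in `z`): two positive
#' head-group peaks at `+/- z_H` and a negative tail trough at the midplane.
#'
#' @param model a [gaussian_bilayer_model()].
#' @param z positions along the bilayer normal, A.
#' @return relative electron density, same length as `z`.
#' @export
edp_profile <- function(model, z) {
  stopifnot(inherits(model, "gaussian_bilayer_model"))
  p <- model$pars
  p[["rho_tail"]] * exp(-z^2 / (2 * p[["sigma_tail"]]^2)) +
    p[["rho_head"]] * (exp(-(z - p[["z_H"]])^2 / (2 * p[["sigma_head"]]^2)) +
                       exp(-(z + p[["z_H"]])^2 / (2 * p[["sigma_head"]]^2)))
}

## generic model evaluation used by the fitter and the generators
model_intensity <- function(model, q, ...) UseMethod("model_intensity")

#' @export
model_intensity.vesicle_model <- function(model, q, ...) {
  vesicle_intensity_poly(q, model, ...)
}

#' @export
model_intensity.gaussian_bilayer_model <- function(model, q,
                                                   use_vesicle_factor = FALSE,
                                                   ...) {
  saxs_intensity(q, model, use_vesicle_factor = use_vesicle_factor)
}

model_probe <- function(model) {
  if (inherits(model, "vesicle_model")) "neutron" else "xray"
}
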