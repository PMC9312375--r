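# Shared fixtures and independent numerical oracles used across test files.
# All fixtures are built in code; nothing is read from disk.

neat_vesicle <- function(...) vesicle_model(R = 300, p = 0.3, d_L = 40.5, ...)
neat_bilayer <- function(...) gaussian_bilayer_model(z_H = 18.35, ...)

# Brute-force radial Fourier transform of the step SLD profile of a
# single shell between R and R + d_L (contrast dsld), intensity per shell
# volume. Independent of the closed-form kernel path.
oracle_shell_intensity <- function(q, R, d_L, dsld) {
  vapply(q, function(qq) {
    Fq <- stats::integrate(function(r) 4 * pi * r^2 * dsld * sin(qq * r) / (qq * r),
                           lower = R, upper = R + d_L, rel.tol = 1e-12)$value
    V <- 4 * pi / 3 * ((R + d_L)^3 - R^3)
    Fq^2 / V
  }, numeric(1))
}

# Dense adaptive quadrature of the Schulz-weighted shell intensity;
# independent of the closed-form gamma-moment path.
oracle_poly_intensity <- function(q, R_mean, p, d_L, dsld) {
  d <- schulz_dist(R_mean, p)
  hi <- R_mean * (1 + 12 * p)
  vapply(q, function(qq) {
    num <- stats::integrate(function(R) {
      Rout <- R + d_L
      Fq <- 4 * pi / 3 * dsld *
        (Rout^3 * sphere_amplitude(qq * Rout) - R^3 * sphere_amplitude(qq * R))
      schulz_pdf(R, d) * Fq^2
    }, lower = 1e-6, upper = hi, rel.tol = 1e-10, subdivisions = 5000L)$value
    den <- stats::integrate(function(R) {
      schulz_pdf(R, d) * 4 * pi / 3 * ((R + d_L)^3 - R^3)
    }, lower = 1e-6, upper = hi, rel.tol = 1e-10, subdivisions = 5000L)$value
    num / den
  }, numeric(1))
}

# Numerical cosine transform of a real-space density profile rho(z).
oracle_cosine_transform <- function(q, rho_fun, z_max = 80) {
  vapply(q, function(qq) {
    stats::integrate(function(z) rho_fun(z) * cos(qq * z),
                     lower = -z_max, upper = z_max, rel.tol = 1e-12)$value
  }, numeric(1))
}

first_local_min <- function(x) {
  i <- which(diff(sign(diff(x))) == 2)
  if (length(i)) i[1] + 1L else NA_integer_
}
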