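#' Default ground-truth table for a divalent-ion titration scenario
#'
#' Encodes the neat-POPC reference state (inner radius 300 A, polydispersity
#' 0.3, bilayer thickness 40.5 A, head-to-head distance 36.7 A, volume per
#' lipid 1253 A^3) and the qualitative titration trends: the mean vesicle
#' radius shrinking from ~300 to ~200 A across 0-50 mM, bilayer thickness and
#' volume flat up to 30 mM with only a <= 0.5 A thickness dip and a few-A^3
#' volume shift at 50 mM.
#'
#' @param concentrations ion concentrations, mM; must include 0.
#' @return data.frame with one row per concentration: `c_ion`, `R`, `p`,
#'   `d_L`, `z_H`, `V_L`.
#' @export
popc_truth <- function(concentrations = c(0, 1, 5, 10, 30, 50)) {
  if (!0 %in% concentrations)
    stop_validation("truth table must include the 0 mM reference")
  cc <- sort(unique(concentrations))
  R <- stats::approx(x = c(0, 1, 5, 10, 30, 50),
                     y = c(300, 290, 270, 250, 220, 200),
                     xout = cc, rule = 2)$y
  d_L <- ifelse(cc > 30, 40.0, 40.5)
  z_H <- ifelse(cc > 30, (36.7 - 0.5) / 2, 36.7 / 2)
  V_L <- ifelse(cc > 30, 1253 + 5, 1253)
  data.frame(c_ion = cc, R = R, p = 0.3, d_L = d_L, z_H = z_H, V_L = V_L)
}

check_noise_seed <- function(noise, seed) {
  if (noise < 0) stop_validation("noise must be >= 0")
  if (noise > 0 && is.null(seed))
    stop_validation("a seed is mandatory for any noisy output")
  if (!is.null(seed)) set.seed(seed)
}

apply_noise <- function(I, noise, model = c("gaussian", "poisson")) {
  model <- match.arg(model)
  ## noise = 0: exact model curve; the sigma column is then a nominal
  ## counting-statistics-like weight, sigma_i = 0.01 sqrt(I_i I_max) (1% at
  ## the curve maximum, growing relatively toward weak high-q points).
  ## Purely relative weights would let the deep high-q thickness fringes
  ## dominate chi2 and carve phase-slip local minima.
  if (noise == 0) return(list(I = I, sigma = 0.01 * sqrt(abs(I) * max(abs(I)))))
  if (model == "gaussian") {
    list(I = I * (1 + stats::rnorm(length(I), 0, noise)),
         sigma = noise * abs(I))
  } else {
    ## Poisson counts scaled so the relative error at the curve maximum is
    ## `noise`; sigma from the observed counts
    n0 <- 1 / noise^2
    counts <- stats::rpois(length(I), I / max(I) * n0)
    scale_back <- max(I) / n0
    list(I = counts * scale_back, sigma = sqrt(pmax(counts, 1)) * scale_back)
  }
}

#' Generate a synthetic SANS vesicle curve with known ground truth
#'
#' Evaluates the polydisperse vesicle model on a logarithmic q grid (default
#' 120 points over 0.005-0.5 1/A, the instrument range for H-lipid vesicles
#' in D2O) and optionally applies multiplicative Gaussian noise,
#' `I_obs = I (1 + eps)`, `eps ~ N(0, noise)`, with the reported sigma column
#' equal to `noise * I`. With `noise = 0` the curve is the exact forward
#' model; the sigma column is then a nominal counting-statistics-like weight
#' `0.01 sqrt(I * max(I))` (1% at the curve maximum), used only to weight
#' fits.
#'
#' @param truth a [vesicle_model()], or a named list/vector of its parameters
#'   (e.g. `list(R = 300, p = 0.3, d_L = 40.5)`).
#' @param n,q_min,q_max log-spaced q grid specification, 1/A.
#' @param noise relative noise level (default 2%); 0 for exact curves.
#' @param seed RNG seed; mandatory when `noise > 0`.
#' @param noise_model `"gaussian"` (multiplicative) or `"poisson"` (scaled
#'   counting statistics).
#' @param c_ion,ion optional sample tags carried on the curve.
#' @return a [scattering_curve()] with `probe = "neutron"`.
#' @export
make_sans_curve <- function(truth = vesicle_model(), n = 120, q_min = 0.005,
                            q_max = 0.5, noise = 0.02, seed = NULL,
                            noise_model = "gaussian",
                            c_ion = NA_real_, ion = "none") {
  model <- as_vesicle_model(truth)
  check_noise_seed(noise, seed)
  q <- exp(seq(log(q_min), log(q_max), length.out = n))
  I <- vesicle_intensity_poly(q, model)
  ns <- apply_noise(I, noise, noise_model)
  scattering_curve(q, ns$I, ns$sigma, probe = "neutron",
                   label = sprintf("synthetic SANS (R=%g, p=%g, d_L=%g)",
                                   model$pars[["R"]], model$pars[["p"]],
                                   model$pars[["d_L"]]),
                   c_ion = c_ion, ion = ion)
}

as_vesicle_model <- function(truth) {
  if (inherits(truth, "vesicle_model")) return(truth)
  do.call(vesicle_model, as.list(truth)[names(as.list(truth)) %in%
          names(formals(vesicle_model))])
}

as_bilayer_model <- function(truth) {
  if (inherits(truth, "gaussian_bilayer_model")) return(truth)
  do.call(gaussian_bilayer_model, as.list(truth)[names(as.list(truth)) %in%
          names(formals(gaussian_bilayer_model))])
}

#' Generate a synthetic SAXS bilayer curve with known ground truth
#'
#' As [make_sans_curve()], using the three-Gaussian bilayer intensity on a
#' log grid over 0.05-1.3 1/A by default (the q window where the flat-sheet
#' approximation and the measured statistics are both reliable). Requesting q
#' below `3/R_ves` with the flat-sheet branch is refused.
#'
#' @inheritParams make_sans_curve
#' @param truth a [gaussian_bilayer_model()] or named list/vector of its
#'   parameters.
#' @param use_vesicle_factor evaluate with the spherical-shell factor instead
#'   of `1/q^2`.
#' @return a [scattering_curve()] with `probe = "xray"`.
#' @export
make_saxs_curve <- function(truth = gaussian_bilayer_model(), n = 180,
                            q_min = 0.05, q_max = 1.3, noise = 0.03,
                            seed = NULL, noise_model = "gaussian",
                            use_vesicle_factor = FALSE,
                            c_ion = NA_real_, ion = "none") {
  model <- as_bilayer_model(truth)
  check_noise_seed(noise, seed)
  q <- exp(seq(log(q_min), log(q_max), length.out = n))
  I <- saxs_intensity(q, model, use_vesicle_factor = use_vesicle_factor)
  ns <- apply_noise(I, noise, noise_model)
  scattering_curve(q, ns$I, ns$sigma, probe = "xray",
                   label = sprintf("synthetic SAXS (z_H=%g)",
                                   model$pars[["z_H"]]),
                   c_ion = c_ion, ion = ion)
}

#' Generate a synthetic densitometric temperature series
#'
#' Builds dispersion/buffer density pairs whose exact inversion through
#' [lipid_volume()] returns `V_L(T) = V_L0 exp(beta (T - T_ref))`: the
#' apparent specific volume is converted back to a dispersion density,
#' `rho_disp = 1 / (w_L v + (1 - w_L)/rho_buf)`. Optional Gaussian noise is
#' added to the dispersion density (g/cm^3 scale, emulating instrument
#' reproducibility).
#'
#' @param V_L0 volume per lipid at `T_ref`, A^3.
#' @param beta thermal volume expansivity, 1/K.
#' @param temps temperatures, degrees C (>= 2 values).
#' @param w_L lipid mass fraction.
#' @param rho_buf buffer density: scalar, vector along `temps`, or
#'   `function(T)`.
#' @param M_L lipid molar mass, g/mol.
#' @param noise density noise sigma, g/cm^3 (e.g. 5e-6 for a vibrating-tube
#'   instrument); 0 for exact values.
#' @param seed RNG seed; mandatory when `noise > 0`.
#' @param T_ref reference temperature, degrees C.
#' @param c_ion,ion sample tags.
#' @return a [density_series()].
#' @export
make_density_series <- function(V_L0 = 1253, beta = 79e-5,
                                temps = c(20, 25, 30), w_L = 0.01,
                                rho_buf = 0.997045,
                                M_L = MOLAR_MASS[["POPC"]],
                                noise = 0, seed = NULL, T_ref = 25,
                                c_ion = 0, ion = "none") {
  if (length(temps) < 2L) stop_validation("need >= 2 temperatures")
  check_noise_seed(noise, seed)
  rb <- if (is.function(rho_buf)) rho_buf(temps) else rep_len(rho_buf, length(temps))
  V_L <- V_L0 * exp(beta * (temps - T_ref))
  v <- V_L * N_AVOGADRO / (M_L * 1e24)        # cm^3/g
  rho_disp <- 1 / (w_L * v + (1 - w_L) / rb)
  if (noise > 0) rho_disp <- rho_disp + stats::rnorm(length(temps), 0, noise)
  density_series(temps, rho_disp, rb, w_L, M_L = M_L, c_ion = c_ion, ion = ion)
}

#' Generate a complete synthetic study with truth manifest
#'
#' Emulates the full experimental campaign for one divalent ion: per
#' concentration a SANS curve, a SAXS curve and a densitometric temperature
#' series, all generated from a ground-truth table and written in the same
#' formats the readers consume, plus a key-value truth manifest. Two runs
#' with the same seed produce byte-identical trees.
#'
#' @param dir output directory.
#' @param ion `"Ca"` or `"Mg"`.
#' @param truth a truth table as from [popc_truth()].
#' @param noise_sans,noise_saxs relative scattering noise (defaults 2% and
#'   3%).
#' @param noise_density density noise, g/cm^3.
#' @param seed RNG seed (mandatory when any noise level is positive).
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, a list with the file `paths` and the `truth` table.
#' @export
make_scenario <- function(dir, ion = c("Ca", "Mg"), truth = popc_truth(),
                          noise_sans = 0.02, noise_saxs = 0.03,
                          noise_density = 5e-6, seed = NULL,
                          overwrite = FALSE) {
  ion <- match.arg(ion)
  noisy <- noise_sans > 0 || noise_saxs > 0 || noise_density > 0
  if (noisy && is.null(seed))
    stop_validation("a seed is mandatory for any noisy output")
  if (dir.exists(dir) && !overwrite)
    stop_validation("output directory exists: ", dir,
                    " (use overwrite = TRUE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ## one seeded generator: per-file streams drawn from the master seed
  sub_seed <- function() if (is.null(seed)) NULL else
    sample.int(.Machine$integer.max - 1L, 1L)

  paths <- character(0)
  dens_all <- NULL
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    tag <- sprintf("%gmM", tr$c_ion)
    sans <- make_sans_curve(list(R = tr$R, p = tr$p, d_L = tr$d_L),
                            noise = noise_sans, seed = sub_seed(),
                            c_ion = tr$c_ion, ion = ion)
    p_sans <- file.path(dir, sprintf("sans_%s_%s.dat", ion, tag))
    write_scattering(sans, p_sans)
    saxs <- make_saxs_curve(list(z_H = tr$z_H), noise = noise_saxs,
                            seed = sub_seed(), c_ion = tr$c_ion, ion = ion)
    p_saxs <- file.path(dir, sprintf("saxs_%s_%s.dat", ion, tag))
    write_scattering(saxs, p_saxs)
    dens <- make_density_series(V_L0 = tr$V_L, noise = noise_density,
                                seed = sub_seed(), c_ion = tr$c_ion,
                                ion = ion)
    dens_all <- rbind(dens_all, as.data.frame(dens))
    paths <- c(paths, p_sans, p_saxs)
  }
  p_dens <- file.path(dir, "density.csv")
  utils::write.csv(dens_all, p_dens, row.names = FALSE, quote = FALSE)
  p_truth <- file.path(dir, "truth.txt")
  lines <- c(sprintf("ion = %s", ion),
             sprintf("seed = %s", if (is.null(seed)) "none" else seed))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    lines <- c(lines, sprintf(
      "conc.%g.%s = %.10g", tr$c_ion,
      c("R", "p", "d_L", "z_H", "V_L"),
      unlist(tr[c("R", "p", "d_L", "z_H", "V_L")])))
  }
  writeLines(lines, p_truth)
  invisible(list(paths = c(paths, p_dens, p_truth), truth = truth))
}

#' Read a key-value truth manifest written by [make_scenario()]
#'
#' @param path manifest path.
#' @return data.frame with the same columns as [popc_truth()].
#' @export
read_truth_manifest <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  conc <- grepl("^conc\\.", keys)
  parts <- strsplit(keys[conc], ".", fixed = TRUE)
  df <- data.frame(
    c_ion = as.numeric(vapply(parts, `[`, "", 2L)),
    param = vapply(parts, `[`, "", 3L),
    value = as.numeric(vals[conc]))
  wide <- stats::reshape(df, idvar = "c_ion", timevar = "param",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide[order(wide$c_ion), c("c_ion", "R", "p", "d_L", "z_H", "V_L")]
}
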