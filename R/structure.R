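#' Area per lipid from volume and bilayer thickness
#'
#' Combines the densitometric volume per lipid with the scattering bilayer
#' thickness: `A_L = 2 V_L / d_L` (two leaflets share the bilayer slab).
#' Uncertainty by first-order propagation:
#' `sigma_A^2 = (2 sigma_V / d_L)^2 + (2 V_L sigma_d / d_L^2)^2`.
#'
#' @param V_L volume per lipid, A^3; > 0.
#' @param d_L bilayer thickness, A; > 0.
#' @param sigma_V,sigma_d 1-sigma uncertainties (default 0).
#' @return list with `A_L` (A^2) and `stderr` (A^2).
#' @export
area_per_lipid <- function(V_L, d_L, sigma_V = 0, sigma_d = 0) {
  stopifnot(V_L > 0, sigma_V >= 0, sigma_d >= 0)
  if (d_L <= 0) stop_validation("d_L must be > 0")
  A <- 2 * V_L / d_L
  err <- sqrt((2 * sigma_V / d_L)^2 + (2 * V_L * sigma_d / d_L^2)^2)
  list(A_L = A, stderr = err)
}

#' Outer-to-inner leaflet lipid-number ratio of a vesicle
#'
#' For a vesicle with inner (core) radius `R_inner` and bilayer thickness
#' `d_L`, the bilayer midplane sits at `R_inner + d_L/2` and each leaflet's
#' mid-surface at `+/- d_L/4` from it. Assuming equal area per lipid in both
#' leaflets, the lipid-number ratio is the squared ratio of the mid-surface
#' radii:
#' `N_out/N_in = ((R_inner + 3 d_L/4) / (R_inner + d_L/4))^2`.
#' The ratio tends to 1 as `d_L/R -> 0` and grows for smaller vesicles.
#'
#' @param R_inner inner radius, A; > 0.
#' @param d_L bilayer thickness, A; > 0.
#' @return dimensionless ratio > 1.
#' @export
leaflet_number_ratio <- function(R_inner, d_L) {
  stopifnot(all(R_inner > 0), all(d_L > 0))
  ((R_inner + 3 * d_L / 4) / (R_inner + d_L / 4))^2
}

#' Assemble fitted and volumetric results into one structural record
#'
#' Joins a SANS vesicle fit (bilayer thickness `d_L`, vesicle radius `R`), a
#' SAXS bilayer fit (head-to-head distance `d_HH = 2 z_H`) and a
#' densitometric volume into the derived quantities: area per lipid
#' `A_L = 2 V_L / d_L`, mean interlipid distance `l = sqrt(A_L)`, with
#' first-order error propagation throughout. When a `reference` summary (the
#' 0 mM record) is supplied, each field whose change from the reference
#' exceeds its propagated 1-sigma error is flagged.
#'
#' @param fit_sans a [sas_fit()] of a [vesicle_model()].
#' @param fit_saxs a [sas_fit()] of a [gaussian_bilayer_model()].
#' @param vol one row of a [lipid_volume()] result (data.frame).
#' @param reference optional `"structural_summary"` to compare against.
#' @param check_tags refuse mismatched `c_ion`/`ion` tags between the inputs
#'   that carry them (default `TRUE`).
#' @return object of class `"structural_summary"`: named `values`, `errors`,
#'   tags, and (with a reference) logical `changed`.
#' @export
structural_summary <- function(fit_sans, fit_saxs, vol, reference = NULL,
                               check_tags = TRUE) {
  stopifnot(inherits(fit_sans, "sas_fit"), inherits(fit_saxs, "sas_fit"))
  if (!inherits(fit_sans$model, "vesicle_model"))
    stop_validation("fit_sans must be a vesicle-model fit")
  if (!inherits(fit_saxs$model, "gaussian_bilayer_model"))
    stop_validation("fit_saxs must be a gaussian-bilayer fit")
  stopifnot(is.data.frame(vol), nrow(vol) == 1L)

  tags <- list(sans = attr(fit_sans$curve, "c_ion"),
               saxs = attr(fit_saxs$curve, "c_ion"),
               vol = vol$c_ion)
  present <- !vapply(tags, function(x) is.null(x) || is.na(x), logical(1))
  if (check_tags && sum(present) > 1L &&
      length(unique(unlist(tags[present]))) > 1L)
    stop_validation("c_ion tag mismatch between SANS/SAXS/volume inputs")
  c_ion <- if (any(present)) unlist(tags[present])[1] else NA_real_

  err_of <- function(fit, par)
    if (par %in% fit$free && is.finite(fit$stderr[[par]]))
      fit$stderr[[par]] else 0

  V_L <- vol$V_L;  sV <- vol$sys_err
  d_L <- fit_sans$params[["d_L"]]; sd_L <- err_of(fit_sans, "d_L")
  R   <- fit_sans$params[["R"]];   sR   <- err_of(fit_sans, "R")
  z_H <- fit_saxs$params[["z_H"]]
  d_HH <- 2 * z_H; sd_HH <- 2 * err_of(fit_saxs, "z_H")
  ap <- area_per_lipid(V_L, d_L, sV, sd_L)
  A_L <- ap$A_L; sA <- ap$stderr
  l_avg <- sqrt(A_L)
  sl <- if (A_L > 0) sA / (2 * sqrt(A_L)) else 0

  values <- c(V_L = V_L, d_L = d_L, d_HH = d_HH, A_L = A_L,
              l_avg = l_avg, R = R)
  errors <- c(V_L = sV, d_L = sd_L, d_HH = sd_HH, A_L = sA,
              l_avg = sl, R = sR)
  out <- structure(list(values = values, errors = errors,
                        c_ion = c_ion, ion = vol$ion[1]),
                   class = "structural_summary")
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "structural_summary"))
    delta <- abs(values - reference$values)
    tol <- sqrt(errors^2 + reference$errors^2)
    out$changed <- delta > tol
    out$reference <- reference$values
  }
  out
}

#' @export
print.structural_summary <- function(x, ...) {
  cat("<structural_summary>")
  if (!is.na(x$c_ion)) cat(sprintf(" %s %g mM", x$ion, x$c_ion))
  cat("\n")
  units <- c(V_L = "A^3", d_L = "A", d_HH = "A", A_L = "A^2",
             l_avg = "A", R = "A")
  for (nm in names(x$values)) {
    flag <- if (!is.null(x$changed) && x$changed[[nm]]) "  * changed vs reference"
            else ""
    cat(sprintf("  %-6s %9.3f +/- %-8.3f %-4s%s\n", nm, x$values[[nm]],
                x$errors[[nm]], units[[nm]], flag))
  }
  invisible(x)
}

#' Flat key-value export of a structural summary
#'
#' @param x a [structural_summary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  stopifnot(inherits(x, "structural_summary"))
  lines <- c(
    sprintf("ion = %s", x$ion),
    sprintf("c_ion = %g", x$c_ion),
    sprintf("%s = %.10g", names(x$values), x$values),
    sprintf("err.%s = %.10g", names(x$errors), x$errors))
  if (!is.null(x$changed))
    lines <- c(lines, sprintf("changed.%s = %s", names(x$changed),
                              tolower(as.character(x$changed))))
  writeLines(lines, path)
  invisible(path)
}
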