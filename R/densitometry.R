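#' Construct a table of densitometric observations
#'
#' Each row is one vibrating-tube densitometer observation: the dispersion
#' (lipid + buffer) density and the matching buffer density at a temperature,
#' together with the lipid mass fraction, plus optional ion tags.
#'
#' @param T temperature, degrees C.
#' @param rho_disp dispersion density, g/cm^3.
#' @param rho_buf buffer density, g/cm^3.
#' @param w_L lipid mass fraction, in (0, 1).
#' @param M_L lipid molar mass, g/mol (default POPC).
#' @param c_ion ion concentration, mM.
#' @param ion `"Ca"`, `"Mg"` or `"none"`.
#' @param warn warn when |rho_disp - rho_buf| exceeds 5% of rho_buf (a
#'   plausibility check for dilute dispersions).
#' @return data.frame of class `"density_series"`.
#' @export
density_series <- function(T, rho_disp, rho_buf, w_L,
                           M_L = MOLAR_MASS[["POPC"]],
                           c_ion = 0, ion = "none", warn = TRUE) {
  n <- length(T)
  df <- data.frame(T = as.numeric(T), rho_disp = as.numeric(rho_disp),
                   rho_buf = as.numeric(rho_buf),
                   w_L = rep_len(as.numeric(w_L), n),
                   M_L = rep_len(as.numeric(M_L), n),
                   c_ion = rep_len(as.numeric(c_ion), n),
                   ion = rep_len(as.character(ion), n))
  if (any(df$w_L <= 0 | df$w_L >= 1))
    stop_validation("w_L must be in (0, 1)")
  if (any(df$rho_disp <= 0) || any(df$rho_buf <= 0))
    stop_validation("densities must be > 0")
  if (warn && any(abs(df$rho_disp - df$rho_buf) > 0.05 * df$rho_buf))
    warning("dispersion and buffer densities differ by more than 5%; ",
            "check units/inputs", call. = FALSE)
  class(df) <- c("density_series", "data.frame")
  df
}

#' Read a density table from CSV/TSV
#'
#' Expects columns `T, rho_disp, rho_buf, w_L` and optionally `M_L, c_ion,
#' ion`; the delimiter is sniffed from the header line (comma or tab/space).
#'
#' @param path file path.
#' @return a [density_series()].
#' @export
read_density_table <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("T", "rho_disp", "rho_buf", "w_L")
  if (!all(need %in% names(df)))
    stop_validation(path, ": missing column(s) ",
                    paste(setdiff(need, names(df)), collapse = ", "))
  density_series(df$T, df$rho_disp, df$rho_buf, df$w_L,
                 M_L = if ("M_L" %in% names(df)) df$M_L else MOLAR_MASS[["POPC"]],
                 c_ion = if ("c_ion" %in% names(df)) df$c_ion else 0,
                 ion = if ("ion" %in% names(df)) df$ion else "none")
}

#' @rdname read_density_table
#' @param series a [density_series()].
#' @export
write_density_table <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Volume per lipid from dispersion and buffer densities
#'
#' The apparent specific volume of the lipid in a dilute dispersion is
#' `v = (1/rho_disp - (1 - w_L)/rho_buf) / w_L` (cm^3/g); the molecular
#' volume follows as `V_L = v * M_L / N_A * 1e24` (A^3). The buffer density
#' is subtracted as measured, with no correction for ion depletion by
#' adsorption onto the bilayer.
#'
#' @param series a [density_series()] (or a data.frame with the same
#'   columns).
#' @param sys_err systematic error per value, A^3; default 3 (midpoint of
#'   the 2-4 A^3 sample-preparation error budget).
#' @return data.frame of class `"volume_result"` with columns `T`, `V_L`
#'   (A^3), `sys_err` (A^3), `c_ion`, `ion`.
#' @export
lipid_volume <- function(series, sys_err = 3) {
  stopifnot(is.data.frame(series), sys_err >= 0)
  v <- (1 / series$rho_disp - (1 - series$w_L) / series$rho_buf) / series$w_L
  if (any(v <= 0))
    stop_validation("unphysical densities: apparent specific volume <= 0")
  V_L <- v * series$M_L / N_AVOGADRO * 1e24
  structure(data.frame(T = series$T, V_L = V_L, sys_err = sys_err,
                       c_ion = series$c_ion, ion = series$ion),
            class = c("volume_result", "data.frame"))
}

#' Thermal volume expansivity from a temperature series
#'
#' `beta = d ln(V_L) / dT`, estimated as the ordinary least-squares slope of
#' `ln V_L` against temperature. The slope is identical whether `T` is in
#' degrees C or K (only the intercept shifts).
#'
#' @param volumes a data.frame with columns `T` (degrees C) and `V_L` (A^3),
#'   at >= 3 distinct temperatures.
#' @return list with `beta` (1/K), `stderr` (1/K) and the underlying `lm`
#'   fit.
#' @export
thermal_expansivity <- function(volumes) {
  stopifnot(is.data.frame(volumes), all(c("T", "V_L") %in% names(volumes)))
  if (length(unique(volumes$T)) < 3L)
    stop_validation("need >= 3 distinct temperatures for the expansivity")
  if (any(volumes$V_L <= 0))
    stop_validation("non-positive V_L in expansivity input")
  fit <- stats::lm(log(V_L) ~ T, data = volumes)
  sm <- summary(fit)$coefficients
  list(beta = unname(sm["T", "Estimate"]),
       stderr = unname(sm["T", "Std. Error"]),
       fit = fit)
}

#' Volume per lipid across an ion-concentration series
#'
#' Computes the mean `V_L` per concentration and tests the no-change
#' criterion: every concentration's `V_L` lying within `+/- sys_err` of the
#' 0 mM reference value (the gray-band criterion used for dilute divalent
#' ions).
#'
#' @param volumes a `"volume_result"` data.frame covering >= 2 concentrations
#'   including 0 mM.
#' @return list with `table` (data.frame `c_ion`, `V_L`, `sys_err`, `n`,
#'   `within_band`), `flat` (logical verdict), and `deviating` (the
#'   concentrations outside the band).
#' @export
volume_vs_concentration <- function(volumes) {
  stopifnot(is.data.frame(volumes), all(c("c_ion", "V_L") %in% names(volumes)))
  concs <- sort(unique(volumes$c_ion))
  if (length(concs) < 2L)
    stop_validation("need >= 2 ion concentrations (including 0 mM)")
  if (!0 %in% concs)
    stop_validation("missing the 0 mM reference concentration")
  agg <- do.call(rbind, lapply(concs, function(cc) {
    sub <- volumes[volumes$c_ion == cc, ]
    data.frame(c_ion = cc, V_L = mean(sub$V_L),
               sys_err = mean(sub$sys_err), n = nrow(sub))
  }))
  ref <- agg$V_L[agg$c_ion == 0]
  band <- agg$sys_err[agg$c_ion == 0]
  agg$within_band <- abs(agg$V_L - ref) <= band
  list(table = agg, flat = all(agg$within_band),
       deviating = agg$c_ion[!agg$within_band])
}
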