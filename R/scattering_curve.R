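#' Construct a 1-D reduced scattering dataset
#'
#' A `scattering_curve` holds a reduced small-angle scattering curve: the
#' momentum-transfer grid `q` (1/A), measured intensities, their 1-sigma
#' uncertainties and a probe tag. Intensities are in instrument units
#' (cm^-1 for calibrated SANS, arbitrary for SAXS); downstream code never
#' relies on absolute calibration because the models carry a free scale.
#'
#' @param q numeric, strictly increasing, all > 0; momentum transfer, 1/A.
#' @param intensity numeric, same length as `q`.
#' @param sigma numeric 1-sigma uncertainties, same length, all > 0.
#' @param probe `"neutron"` or `"xray"`.
#' @param label free-text sample description.
#' @param c_ion optional divalent-ion concentration tag, mM.
#' @param ion optional ion tag: `"Ca"`, `"Mg"` or `"none"`.
#' @return object of class `"scattering_curve"` (a data.frame with columns
#'   `q`, `intensity`, `sigma` and attributes `probe`, `label`, `c_ion`, `ion`).
#' @export
scattering_curve <- function(q, intensity, sigma, probe = c("neutron", "xray"),
                             label = "", c_ion = NA_real_, ion = "none") {
  probe <- match.arg(probe)
  q <- as.numeric(q); intensity <- as.numeric(intensity); sigma <- as.numeric(sigma)
  if (length(q) == 0L)
    stop_validation("empty dataset: no scattering points")
  if (length(intensity) != length(q) || length(sigma) != length(q))
    stop_validation("q, intensity and sigma must have equal length")
  if (anyNA(q) || anyNA(intensity) || anyNA(sigma))
    stop_validation("scattering curve contains NA values")
  if (any(q <= 0))
    stop_validation("all q must be > 0 (first bad point at index ",
                    which(q <= 0)[1], ")")
  if (any(diff(q) <= 0))
    stop_validation("q must be strictly increasing (violated at index ",
                    which(diff(q) <= 0)[1] + 1L, ")")
  if (any(sigma <= 0))
    stop_validation("all sigma must be > 0 (first bad point at index ",
                    which(sigma <= 0)[1], ")")
  structure(data.frame(q = q, intensity = intensity, sigma = sigma),
            probe = probe, label = label, c_ion = c_ion, ion = ion,
            class = c("scattering_curve", "data.frame"))
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %s probe, %d points, q in [%g, %g] 1/A\n",
              attr(x, "probe"), nrow(x), min(x$q), max(x$q)))
  lab <- attr(x, "label")
  if (nzchar(lab)) cat("  label:", lab, "\n")
  if (!is.na(attr(x, "c_ion")))
    cat(sprintf("  ion: %s at %g mM\n", attr(x, "ion"), attr(x, "c_ion")))
  invisible(x)
}

#' Read a 3-column ASCII scattering file
#'
#' Parses the whitespace-delimited dialect used throughout the package:
#' `#`-prefixed header lines followed by rows of `q intensity sigma`.
#' Header lines of the form `# key: value` are recognised for `probe`,
#' `label`, `c_ion` and `ion`. Validation failures report the offending
#' 1-based line number.
#'
#' @param path file path.
#' @param probe probe override; if `NULL`, taken from a `# probe:` header
#'   (default `"neutron"` when absent).
#' @return a [scattering_curve()].
#' @export
read_scattering <- function(path, probe = NULL) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- grepl("^\\s*#", lines) | !nzchar(trimws(lines))
  hdr <- lines[grepl("^\\s*#", lines)]
  meta <- list(probe = "neutron", label = "", c_ion = NA_real_, ion = "none")
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3L && m[2] %in% names(meta)) {
      meta[[m[2]]] <- if (m[2] == "c_ion") as.numeric(m[3]) else trimws(m[3])
    }
  }
  if (!is.null(probe)) meta$probe <- probe
  data_idx <- which(!is_hdr)
  if (length(data_idx) == 0L)
    stop_validation("empty dataset: ", path, " has no data rows")
  rows <- strsplit(trimws(lines[data_idx]), "\\s+")
  ncol_row <- lengths(rows)
  if (any(ncol_row < 3L))
    stop_validation(path, " line ", data_idx[which(ncol_row < 3L)[1]],
                    ": expected 3 columns (q, intensity, sigma)")
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[1:3]), numeric(3)))
  bad <- which(apply(vals, 2, anyNA))
  if (length(bad))
    stop_validation(path, " line ", data_idx[bad[1]], ": non-numeric value")
  q <- vals[1, ]; intensity <- vals[2, ]; sigma <- vals[3, ]
  if (any(sigma <= 0))
    stop_validation(path, " line ", data_idx[which(sigma <= 0)[1]],
                    ": non-positive sigma")
  if (any(diff(q) <= 0))
    stop_validation(path, " line ", data_idx[which(diff(q) <= 0)[1] + 1L],
                    ": q not strictly increasing")
  scattering_curve(q, intensity, sigma, probe = meta$probe, label = meta$label,
                   c_ion = meta$c_ion, ion = meta$ion)
}

#' Write a scattering curve in the 3-column ASCII dialect
#'
#' Emits the same format [read_scattering()] consumes; the round trip is
#' value-identical at full double precision.
#'
#' @param curve a [scattering_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scattering <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  hdr <- c(
    sprintf("# probe: %s", attr(curve, "probe")),
    if (nzchar(attr(curve, "label"))) sprintf("# label: %s", attr(curve, "label")),
    if (!is.na(attr(curve, "c_ion"))) sprintf("# c_ion: %.17g", attr(curve, "c_ion")),
    if (!identical(attr(curve, "ion"), "none")) sprintf("# ion: %s", attr(curve, "ion")),
    "# columns: q[1/A] intensity sigma")
  body <- sprintf("%.17g %.17g %.17g", curve$q, curve$intensity, curve$sigma)
  writeLines(c(hdr, body), path)
  invisible(path)
}
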