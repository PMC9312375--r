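#' Fit a scattering model to a reduced curve by weighted least squares
#'
#' Minimises `chi^2 = sum_i [(I_model(q_i) - I_i) / sigma_i]^2` over the free
#' parameters within box bounds, by Levenberg-Marquardt (via
#' [minpack.lm::nls.lm]). Initial values come from the supplied model object;
#' fixed parameters keep their model values. Parameter uncertainties follow
#' the small-angle-scattering convention: the covariance matrix of the free
#' parameters, `(J' J)^{-1}` with `J` the Jacobian of the weighted residuals,
#' is scaled by the reduced chi-square before taking square roots,
#' `stderr_j = sqrt(cov_jj * chi2_red)`. This makes the quoted errors
#' invariant under a common rescaling of the data uncertainties.
#'
#' @param curve a [scattering_curve()].
#' @param model a [vesicle_model()] or [gaussian_bilayer_model()] holding the
#'   initial parameter values.
#' @param free character vector of free parameter names. Defaults:
#'   `c("R", "d_L", "scale", "background")` for the vesicle model,
#'   `c("z_H", "rho_head", "rho_tail", "scale", "background")` for the
#'   bilayer model (widths and vesicle size fixed, per standard practice).
#' @param lower,upper named numeric vectors of box bounds for (a subset of)
#'   the free parameters; defaults keep each model inside its validity domain.
#' @param q_window length-2 numeric `(q_min, q_max)` restriction; `NULL` uses
#'   the probe default: `c(0.005, 0.5)` 1/A for neutrons, `c(0.05, 1.3)` 1/A
#'   for X-rays.
#' @param max_iter iteration cap for the optimizer.
#' @param check_probe refuse a neutron model on an X-ray curve and vice versa
#'   (default `TRUE`).
#' @param ... passed to the model intensity evaluator (e.g.
#'   `use_vesicle_factor` for the bilayer model).
#' @return object of class `"sas_fit"`: the fitted model, best-fit parameter
#'   vector, scaled standard errors (`NA` where the covariance is singular),
#'   reduced chi-square, covariance matrix, convergence flag and the data
#'   actually fitted. Methods: `print`, `summary`, `coef`, `vcov`, `predict`,
#'   `residuals`, `fitted`, `plot`, `simulate`, plus [profile_uncertainty()].
#' @export
sas_fit <- function(curve, model, free = NULL, lower = NULL, upper = NULL,
                    q_window = NULL, max_iter = 200L, check_probe = TRUE,
                    ...) {
  stopifnot(inherits(curve, "scattering_curve"), inherits(model, "sas_model"))
  if (check_probe && !identical(attr(curve, "probe"), model_probe(model)))
    stop_validation("probe mismatch: curve is tagged '", attr(curve, "probe"),
                    "' but the model expects '", model_probe(model),
                    "' data (set check_probe = FALSE to override)")
  if (is.null(free)) {
    free <- if (inherits(model, "vesicle_model"))
      c("R", "d_L", "scale", "background")
    else c("z_H", "rho_head", "rho_tail", "scale", "background")
  }
  pars <- coef(model)
  if (!all(free %in% names(pars)))
    stop_validation("unknown free parameter(s): ",
                    paste(setdiff(free, names(pars)), collapse = ", "))
  if (length(free) == 0L) stop_validation("at least one parameter must be free")

  defaults <- default_bounds(model)
  lo <- defaults$lower[free]; hi <- defaults$upper[free]
  if (!is.null(lower)) lo[names(lower)[names(lower) %in% free]] <-
      lower[names(lower) %in% free]
  if (!is.null(upper)) hi[names(upper)[names(upper) %in% free]] <-
      upper[names(upper) %in% free]
  init <- pars[free]
  if (any(init < lo | init > hi))
    stop_validation("initial value outside bounds for: ",
                    paste(free[init < lo | init > hi], collapse = ", "))

  if (is.null(q_window)) {
    q_window <- if (model_probe(model) == "neutron") c(0.005, 0.5)
                else c(0.05, 1.3)
  }
  keep <- curve$q >= q_window[1] & curve$q <= q_window[2]
  if (!any(keep)) stop_validation("q_window does not overlap the data")
  q <- curve$q[keep]; I_obs <- curve$intensity[keep]; sig <- curve$sigma[keep]
  n <- length(q); n_free <- length(free)
  if (n <= n_free)
    stop_validation("need more data points (", n, ") than free parameters (",
                    n_free, ")")

  resid_fn <- function(theta) {
    m <- set_pars(model, stats::setNames(theta, free))
    (model_intensity(m, q, ...) - I_obs) / sig
  }
  res <- minpack.lm::nls.lm(
    par = init, lower = lo, upper = hi, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                         ftol = 1e-12, ptol = 1e-12))
  theta <- stats::setNames(res$par, free)
  converged <- res$info %in% c(1, 2, 3, 4)

  chi2 <- sum(resid_fn(theta)^2)
  chi2_red <- chi2 / (n - n_free)

  ## covariance from a central-difference Jacobian of the weighted residuals
  J <- num_jacobian(resid_fn, theta, lower = lo, upper = hi)
  JtJ <- crossprod(J)
  ## invert on the correlation scale so mixed parameter units do not fake a
  ## singular covariance
  cov <- tryCatch({
    d <- sqrt(diag(JtJ))
    if (any(d <= 0)) NULL else {
      Cm <- JtJ / tcrossprod(d)
      if (rcond(Cm) < 1e-10) NULL else solve(Cm) / tcrossprod(d)
    }
  }, error = function(e) NULL)
  if (is.null(cov)) {
    stderr <- stats::setNames(rep(NA_real_, n_free), free)
    cov_out <- matrix(NA_real_, n_free, n_free, dimnames = list(free, free))
    undetermined <- TRUE
  } else {
    stderr <- stats::setNames(sqrt(pmax(diag(cov), 0) * chi2_red), free)
    cov_out <- cov
    dimnames(cov_out) <- list(free, free)
    undetermined <- FALSE
  }

  fitted_model <- set_pars(model, theta)
  structure(list(
    model = fitted_model, free = free,
    params = coef(fitted_model), stderr = stderr,
    chi2 = chi2, chi2_red = chi2_red,
    n_points = n, n_free = n_free,
    covariance = cov_out, undetermined = undetermined,
    converged = converged, optim_info = res$info,
    message = res$message, niter = res$niter,
    lower = lo, upper = hi, q_window = q_window,
    curve = curve, keep = keep,
    data = data.frame(q = q, intensity = I_obs, sigma = sig),
    extra_args = list(...),
    call = match.call()
  ), class = "sas_fit")
}

default_bounds <- function(model) {
  if (inherits(model, "vesicle_model")) {
    list(
      lower = c(R = 10, p = 0, d_L = 5, sld_shell = -1e-6, sld_solvent = -1e-6,
                scale = 0, background = 0),
      upper = c(R = 5000, p = 0.95, d_L = 100, sld_shell = 3e-6,
                sld_solvent = 1e-5, scale = Inf, background = Inf))
  } else {
    list(
      lower = c(z_H = 5, sigma_head = 0.5, sigma_tail = 0.5, rho_head = 1e-6,
                rho_tail = -100, scale = 0, background = 0,
                R_ves = 50, sigma_R = 1),
      upper = c(z_H = 50, sigma_head = 20, sigma_tail = 20, rho_head = 100,
                rho_tail = -1e-6, scale = Inf, background = Inf,
                R_ves = 5000, sigma_R = 1000))
  }
}

## central-difference Jacobian, steps kept inside the box
num_jacobian <- function(fn, theta, lower, upper, rel_step = 1e-6) {
  n <- length(fn(theta)); p <- length(theta)
  J <- matrix(0, n, p)
  for (j in seq_len(p)) {
    h <- rel_step * max(abs(theta[j]), 1e-8)
    up <- theta; up[j] <- min(theta[j] + h, upper[j])
    dn <- theta; dn[j] <- max(theta[j] - h, lower[j])
    denom <- up[j] - dn[j]
    if (denom <= 0) next
    J[, j] <- (fn(up) - fn(dn)) / denom
  }
  J
}

#' @export
coef.sas_fit <- function(object, all = FALSE, ...) {
  if (all) object$params else object$params[object$free]
}

#' @export
vcov.sas_fit <- function(object, ...) object$covariance

#' @export
fitted.sas_fit <- function(object, ...) {
  do.call(model_intensity,
          c(list(object$model, object$data$q), object$extra_args))
}

#' @export
residuals.sas_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  r <- object$data$intensity - fitted(object)
  if (type == "weighted") r / object$data$sigma else r
}

#' @export
predict.sas_fit <- function(object, newdata = NULL, ...) {
  q <- if (is.null(newdata)) object$data$q
       else if (is.data.frame(newdata)) newdata$q
       else as.numeric(newdata)
  do.call(model_intensity, c(list(object$model, q), object$extra_args))
}

#' @export
print.sas_fit <- function(x, ...) {
  cat(sprintf("<sas_fit> %s, %d points in q = [%g, %g] 1/A\n",
              class(x$model)[1], x$n_points, x$q_window[1], x$q_window[2]))
  cat(sprintf("  reduced chi-square: %.4g  (%d free parameters)%s\n",
              x$chi2_red, x$n_free,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- x$params[x$free]
  se <- x$stderr
  se_txt <- ifelse(is.na(se), "undetermined", sprintf("%.4g", se))
  for (i in seq_along(est))
    cat(sprintf("  %-12s %.6g  +/- %s\n", names(est)[i], est[i], se_txt[i]))
  invisible(x)
}

#' @export
summary.sas_fit <- function(object, ...) {
  se <- object$stderr
  tab <- data.frame(
    estimate = object$params[object$free],
    stderr = se,
    row.names = object$free)
  fixed <- setdiff(names(object$params), object$free)
  structure(list(coefficients = tab,
                 fixed = object$params[fixed],
                 chi2 = object$chi2, chi2_red = object$chi2_red,
                 n_points = object$n_points, n_free = object$n_free,
                 converged = object$converged,
                 undetermined = object$undetermined,
                 model_class = class(object$model)[1]),
            class = "summary.sas_fit")
}

#' @export
print.summary.sas_fit <- function(x, ...) {
  cat(sprintf("Weighted least-squares fit of a %s\n", x$model_class))
  cat(sprintf("%d points, %d free parameters, chi2 = %.6g, chi2_red = %.6g\n",
              x$n_points, x$n_free, x$chi2, x$chi2_red))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  if (x$undetermined)
    cat("WARNING: singular covariance; standard errors undetermined\n")
  cat("\nFree parameters (stderr = sqrt(cov_jj * chi2_red)):\n")
  print(signif(x$coefficients, 6))
  cat("\nFixed parameters:\n")
  print(signif(x$fixed, 6))
  invisible(x)
}

#' @export
plot.sas_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  d <- x$data
  graphics::plot(d$q, d$intensity, log = "xy", pch = 16, cex = 0.5,
                 xlab = "q [1/A]", ylab = "I(q)", ...)
  graphics::lines(d$q, fitted(x), col = "red3", lwd = 1.5)
  graphics::plot(d$q, residuals(x), log = "x", pch = 16, cex = 0.5,
                 xlab = "q [1/A]", ylab = "(I - fit)/sigma")
  graphics::abline(h = 0, col = "grey50")
  invisible(x)
}

#' @export
simulate.sas_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sig <- object$data$sigma
  out <- replicate(nsim, stats::rnorm(length(mu), mu, sig))
  colnames(out) <- paste0("sim_", seq_len(nsim))
  data.frame(q = object$data$q, out)
}

#' Profile-likelihood uncertainty interval for one fitted parameter
#'
#' Validates the covariance-based standard errors by chi-square profiling:
#' the parameter is stepped away from its best-fit value, all other free
#' parameters are re-optimised, and the interval is where
#' `chi^2 <= chi2_min + chi2_red` (the `+1` criterion expressed on the scale
#' of the scaled uncertainties, so that a quadratic chi-square surface
#' reproduces `stderr` exactly). A side whose crossing lies beyond the
#' parameter's bound is flagged one-sided.
#'
#' @param fit a converged [sas_fit()].
#' @param param name of one free parameter.
#' @param max_expand search no further than `max_expand` scaled standard
#'   errors from the best fit (beyond that the profile is flagged unbounded).
#' @return list with `lower`, `upper` (NA when that side hit a bound or did
#'   not cross), `estimate`, `stderr`, and flags `at_bound_lower`,
#'   `at_bound_upper`.
#' @export
profile_uncertainty <- function(fit, param, max_expand = 8) {
  stopifnot(inherits(fit, "sas_fit"))
  if (!fit$converged) stop_numerical("fit did not converge; cannot profile")
  if (!param %in% fit$free) stop_validation("'", param, "' is not free in this fit")
  others <- setdiff(fit$free, param)
  est <- fit$params[[param]]
  target <- fit$chi2 + fit$chi2_red
  step <- fit$stderr[[param]]
  if (!is.finite(step) || step <= 0)
    step <- max(abs(est) * 0.01, 1e-6)

  chi2_at <- function(val) {
    m <- set_pars(fit$model, stats::setNames(val, param))
    if (length(others) == 0L) {
      r <- do.call(model_intensity,
                   c(list(m, fit$data$q), fit$extra_args))
      return(sum(((r - fit$data$intensity) / fit$data$sigma)^2))
    }
    refit <- sas_fit(fit$curve, m, free = others,
                     lower = fit$lower[others], upper = fit$upper[others],
                     q_window = fit$q_window, check_probe = FALSE)
    refit$chi2
  }

  side <- function(dir) {
    bound <- if (dir < 0) fit$lower[[param]] else fit$upper[[param]]
    at_bound <- FALSE; crossing <- NA_real_
    prev <- est
    for (k in seq_len(max_expand)) {
      val <- est + dir * k * step
      if ((dir < 0 && val <= bound) || (dir > 0 && val >= bound)) {
        val <- bound; at_bound <- TRUE
      }
      if (chi2_at(val) >= target) {
        crossing <- stats::uniroot(function(v) chi2_at(v) - target,
                                   lower = min(prev, val),
                                   upper = max(prev, val),
                                   tol = abs(step) * 1e-4)$root
        at_bound <- FALSE
        break
      }
      prev <- val
      if (at_bound) break
    }
    if (is.na(crossing) && !at_bound)
      stop_numerical("profile for '", param, "' unbounded within ",
                     max_expand, " stderr steps")
    list(crossing = crossing, at_bound = at_bound)
  }

  lo <- side(-1); hi <- side(+1)
  list(estimate = est, stderr = fit$stderr[[param]],
       lower = lo$crossing, upper = hi$crossing,
       at_bound_lower = lo$at_bound, at_bound_upper = hi$at_bound)
}

#' Write a fit result as a machine-readable key-value report
#'
#' @param fit a [sas_fit()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "sas_fit"))
  kv <- c(
    model = class(fit$model)[1],
    converged = tolower(as.character(fit$converged)),
    n_points = fit$n_points, n_free = fit$n_free,
    chi2 = sprintf("%.10g", fit$chi2),
    chi2_red = sprintf("%.10g", fit$chi2_red),
    q_min = fit$q_window[1], q_max = fit$q_window[2])
  par_lines <- sprintf("param.%s = %.10g", names(fit$params), fit$params)
  err_lines <- sprintf("stderr.%s = %s", fit$free,
                       ifelse(is.na(fit$stderr), "undetermined",
                              sprintf("%.10g", fit$stderr)))
  writeLines(c(sprintf("%s = %s", names(kv), kv), par_lines, err_lines), path)
  invisible(path)
}
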