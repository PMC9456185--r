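#' Fit a phase-solubility diagram
#'
#' Ordinary least-squares line through dissolved guest concentration versus
#' host (cyclodextrin) concentration, the Higuchi-Connors analysis of a
#' phase-solubility experiment. A linear diagram with slope below one is
#' A_L-type and indicates 1:1 host-guest complexation; the intercept estimates
#' the intrinsic guest solubility S0.
#'
#' @param data Data frame with numeric columns `host_conc` and `guest_conc`,
#'   both in molar units (M). One diagram, i.e. one temperature and one
#'   host-guest pair, per call; see [read_solubility_csv()] for grouped input.
#' @param r2_threshold Minimum r-squared for the diagram to be accepted as
#'   linear (A_L). Below it the profile is reported `"nonlinear"` with a
#'   warning. Default 0.98.
#'
#' @return An object of class `hg_ps_fit`: a list with elements `slope`,
#'   `intercept_s0` (M), `r_squared`, `profile` (`"A_L"` or `"nonlinear"`),
#'   `n_points`, and the underlying `lm` fit. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#'
#' @details The slope of a noise-free 1:1 diagram equals
#'   `Kc * S0 / (1 + Kc * S0)` and therefore always lies in (0, 1); a fitted
#'   slope at or above 1 cannot arise from 1:1 complexation and is flagged
#'   `"nonlinear"` (it would make the stability-constant denominator
#'   non-positive).
#'
#' @examples
#' d <- simulate_diagram(s0 = 1e-4, kc = 219, noise_sd = 0)
#' fit <- fit_diagram(d)
#' stability_constant(fit)
#' @seealso [stability_constant()], [simulate_diagram()]
#' @export
fit_diagram <- function(data, r2_threshold = 0.98) {
  check_columns(data, c("host_conc", "guest_conc"), "solubility diagram")
  host <- data$host_conc
  guest <- data$guest_conc
  if (length(host) < 3) {
    hg_abort("A phase-solubility diagram needs at least 3 points.", "input")
  }
  if (any(!is.finite(host)) || any(!is.finite(guest))) {
    hg_abort("Concentrations must be finite numbers.", "input")
  }
  if (any(host < 0) || any(guest < 0)) {
    hg_abort("Concentrations must be non-negative.", "domain")
  }
  if (length(unique(host)) < 2) {
    hg_abort("Host concentrations are all equal; cannot fit a slope.", "input")
  }
  check_number(r2_threshold, "r2_threshold")

  fit <- lm(guest ~ host)
  slope <- unname(coef(fit)[2])
  s0 <- unname(coef(fit)[1])
  # r.squared from summary() is NaN for an exact zero-residual fit with a
  # flat response; guard the degenerate-but-valid constant diagram (Kc = 0)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((guest - mean(guest))^2)
  r2 <- if (ss_tot == 0) {
    as.numeric(ss_res <= 1e-20 * max(sum(guest^2), .Machine$double.xmin))
  } else {
    1 - ss_res / ss_tot
  }

  profile <- if (slope > 0 && slope < 1 && r2 >= r2_threshold) "A_L" else "nonlinear"
  if (profile == "nonlinear" && slope >= 1) {
    warn(sprintf(
      "Fitted slope %.3f >= 1: not A_L-type; the 1:1 stability constant is undefined.",
      slope
    ))
  } else if (profile == "nonlinear" && r2 < r2_threshold) {
    warn(sprintf(
      "r-squared %.4f below linearity threshold %.3f; profile reported as nonlinear.",
      r2, r2_threshold
    ))
  }

  structure(
    list(
      slope = slope,
      intercept_s0 = s0,
      r_squared = r2,
      profile = profile,
      n_points = length(host),
      r2_threshold = r2_threshold,
      fit = fit
    ),
    class = "hg_ps_fit"
  )
}

#' @export
print.hg_ps_fit <- function(x, ...) {
  cat("Phase-solubility fit (", x$profile, ")\n", sep = "")
  cat(sprintf("  slope      = %.6g\n", x$slope))
  cat(sprintf("  S0         = %.6g M\n", x$intercept_s0))
  cat(sprintf("  r-squared  = %.6g  (n = %d)\n", x$r_squared, x$n_points))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hg_ps_fit <- function(x, ...) {
  tibble(
    term = c("slope", "intercept_s0"),
    estimate = c(x$slope, x$intercept_s0),
    std.error = unname(summary(x$fit)$coefficients[c(2, 1), 2])
  )
}

#' @exportS3Method generics::glance
glance.hg_ps_fit <- function(x, ...) {
  tibble(
    slope = x$slope,
    intercept_s0 = x$intercept_s0,
    r_squared = x$r_squared,
    profile = x$profile,
    n_points = x$n_points
  )
}

#' Apparent 1:1 stability constant from a phase-solubility fit
#'
#' Computes `Kc = slope / (S0 * (1 - slope))` from a fitted A_L-type
#' diagram, the apparent equilibrium constant of 1:1 inclusion-complex
#' formation in 1/M.
#'
#' @param fit An `hg_ps_fit` from [fit_diagram()], or a data frame/list with
#'   elements `slope` and `intercept_s0`.
#' @param temperature Optional temperature in kelvin carried into the result,
#'   for assembling a Van't Hoff series.
#'
#' @return A one-row tibble with columns `kc` (1/M), `slope`,
#'   `intercept_s0`, and `temperature` (NA if not supplied).
#'
#' @examples
#' d <- simulate_diagram(s0 = 1e-4, kc = 219, noise_sd = 0)
#' stability_constant(fit_diagram(d))$kc # 219
#' @export
stability_constant <- function(fit, temperature = NA_real_) {
  slope <- fit$slope
  s0 <- fit$intercept_s0
  if (is.null(slope) || is.null(s0)) {
    hg_abort("`fit` must carry `slope` and `intercept_s0`.", "input")
  }
  # a flat (Kc = 0) diagram can fit to a slope of -0 within rounding
  if (slope < 0 && slope > -1e-10) slope <- 0
  if (slope < 0 || slope >= 1) {
    hg_abort(sprintf(
      "slope must lie in [0, 1) for a 1:1 stability constant (got %g).", slope
    ), "domain")
  }
  if (s0 <= 0) {
    hg_abort(sprintf("S0 must be > 0 (got %g M).", s0), "domain")
  }
  tibble(
    kc = slope / (s0 * (1 - slope)),
    slope = slope,
    intercept_s0 = s0,
    temperature = as.numeric(temperature)
  )
}
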