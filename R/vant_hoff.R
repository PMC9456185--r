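#' Van't Hoff fit of stability constants across temperature
#'
#' Ordinary least-squares regression of `ln Kc` on `1/T`. Under the Van't
#' Hoff relation `ln Kc = -dH/(R T) + dS/R`, the slope gives the
#' complexation enthalpy `dH = -R * slope` and the intercept the entropy
#' `dS = R * intercept`.
#'
#' @param data Data frame with numeric columns `temperature` (kelvin) and
#'   `kc` (1/M), one row per temperature.
#' @param gas_constant Gas constant R in kcal/(mol K); default
#'   [hg_gas_constant] (1.985e-3).
#'
#' @return An object of class `hg_vh_fit`: list with `delta_h` (kcal/mol),
#'   `delta_s` (kcal/(mol K)), `r_squared`, `n_points`, `gas_constant` and
#'   the underlying `lm` fit. Has [tidy()], [glance()] and [autoplot()]
#'   methods; pass to [gibbs()] for the free energy at any temperature.
#'
#' @examples
#' kc <- tibble::tibble(
#'   temperature = c(293.15, 303.15, 313.15, 323.15),
#'   kc = c(209, 219, 232, 237)
#' )
#' fit <- vant_hoff_fit(kc)
#' gibbs(fit, 303) # about -3.24 kcal/mol
#' @export
vant_hoff_fit <- function(data, gas_constant = hg_gas_constant) {
  check_columns(data, c("temperature", "kc"), "stability-constant series")
  temp <- data$temperature
  kc <- data$kc
  check_number(gas_constant, "gas_constant", positive = TRUE)
  if (any(!is.finite(temp)) || any(temp <= 0)) {
    hg_abort("Temperatures must be finite and > 0 K.", "domain")
  }
  if (any(!is.finite(kc)) || any(kc <= 0)) {
    hg_abort("All stability constants must be finite and > 0 for ln Kc.", "domain")
  }
  if (length(unique(temp)) < 2) {
    hg_abort("Van't Hoff regression needs at least 2 distinct temperatures.", "input")
  }

  inv_t <- 1 / temp
  log_kc <- log(kc)
  fit <- lm(log_kc ~ inv_t)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((log_kc - mean(log_kc))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot

  structure(
    list(
      delta_h = -gas_constant * slope,
      delta_s = gas_constant * intercept,
      r_squared = r2,
      n_points = length(kc),
      gas_constant = gas_constant,
      fit = fit
    ),
    class = "hg_vh_fit"
  )
}

#' @export
print.hg_vh_fit <- function(x, ...) {
  cat("Van't Hoff fit\n")
  cat(sprintf("  dH = %.4g kcal/mol\n", x$delta_h))
  cat(sprintf("  dS = %.4g kcal/(mol K)\n", x$delta_s))
  cat(sprintf("  r-squared = %.4f  (n = %d)\n", x$r_squared, x$n_points))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hg_vh_fit <- function(x, ...) {
  tibble(
    term = c("delta_h", "delta_s"),
    estimate = c(x$delta_h, x$delta_s),
    std.error = x$gas_constant * unname(summary(x$fit)$coefficients[c(2, 1), 2])
  )
}

#' @exportS3Method generics::glance
glance.hg_vh_fit <- function(x, ...) {
  tibble(
    delta_h = x$delta_h,
    delta_s = x$delta_s,
    r_squared = x$r_squared,
    n_points = x$n_points
  )
}

#' Gibbs free energy of complexation at a temperature
#'
#' `dG = dH - T * dS` from a Van't Hoff fit.
#'
#' @param fit An `hg_vh_fit` from [vant_hoff_fit()], or any list with
#'   numeric `delta_h` (kcal/mol) and `delta_s` (kcal/(mol K)).
#' @param temperature Temperature in kelvin (> 0).
#'
#' @return Gibbs free energy in kcal/mol (numeric scalar).
#' @examples
#' gibbs(list(delta_h = 4.05, delta_s = 6.47 / 303), 303) # -2.42
#' @export
gibbs <- function(fit, temperature) {
  check_number(temperature, "temperature", positive = TRUE)
  dh <- fit$delta_h
  ds <- fit$delta_s
  if (is.null(dh) || is.null(ds)) {
    hg_abort("`fit` must carry `delta_h` and `delta_s`.", "input")
  }
  dh - temperature * ds
}

#' Thermodynamic summary table from a stability-constant series
#'
#' Runs [vant_hoff_fit()] per label and bundles the enthalpy, entropy and
#' Gibbs free energy at a reference temperature into one tibble, the shape
#' in which complexation thermodynamics are reported.
#'
#' @param data Data frame with columns `temperature` (K), `kc` (1/M) and
#'   optionally `label` (one series per label).
#' @param reference_t Reference temperature in kelvin for `t_delta_s` and
#'   `delta_g`; default 303.
#' @param gas_constant R in kcal/(mol K); default [hg_gas_constant].
#'
#' @return A tibble with one row per label: `label`, `delta_h` (kcal/mol),
#'   `delta_s` (kcal/(mol K)), `t_delta_s` (kcal/mol at `reference_t`),
#'   `delta_g` (kcal/mol), `r_squared`, `n_points`, `reference_t`,
#'   `gas_constant`. The identity `delta_g = delta_h - t_delta_s` holds to
#'   machine precision by construction.
#'
#' @examples
#' kc <- tibble::tibble(
#'   temperature = rep(c(293.15, 303.15, 313.15, 323.15), 2),
#'   kc = c(209, 219, 232, 237, 42, 60, 73, 80),
#'   label = rep(c("AA/DMbCD", "AA/bCD"), each = 4)
#' )
#' thermo_table(kc)
#' @export
thermo_table <- function(data, reference_t = 303, gas_constant = hg_gas_constant) {
  check_number(reference_t, "reference_t", positive = TRUE)
  if (!("label" %in% names(data))) data$label <- "series"
  check_columns(data, c("temperature", "kc", "label"), "stability-constant table")

  data |>
    group_by(.data$label) |>
    dplyr::group_modify(function(grp, key) {
      fit <- vant_hoff_fit(grp, gas_constant = gas_constant)
      tibble(
        delta_h = fit$delta_h,
        delta_s = fit$delta_s,
        t_delta_s = reference_t * fit$delta_s,
        delta_g = fit$delta_h - reference_t * fit$delta_s,
        r_squared = fit$r_squared,
        n_points = fit$n_points,
        reference_t = reference_t,
        gas_constant = gas_constant
      )
    }) |>
    ungroup()
}
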