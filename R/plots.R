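#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_abline geom_raster
#'   scale_fill_viridis_c labs theme_minimal geom_smooth facet_wrap
NULL

#' @exportS3Method ggplot2::autoplot
autoplot.hg_ps_fit <- function(object, ...) {
  d <- object$fit$model
  names(d) <- c("guest_conc", "host_conc")
  ggplot(d, aes(x = .data$host_conc * 1e3, y = .data$guest_conc * 1e3)) +
    geom_point() +
    geom_abline(slope = object$slope, intercept = object$intercept_s0 * 1e3) +
    labs(
      x = "host concentration (mM)", y = "dissolved guest (mM)",
      title = sprintf("Phase-solubility diagram (%s)", object$profile),
      subtitle = sprintf("slope = %.4g, S0 = %.3g M, r-squared = %.4f",
                         object$slope, object$intercept_s0, object$r_squared)
    ) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.hg_vh_fit <- function(object, ...) {
  d <- object$fit$model
  names(d) <- c("log_kc", "inv_t")
  ggplot(d, aes(x = .data$inv_t, y = .data$log_kc)) +
    geom_point() +
    geom_abline(slope = unname(coef(object$fit)[2]),
                intercept = unname(coef(object$fit)[1])) +
    labs(
      x = "1 / T (1/K)", y = "ln Kc",
      title = "Van't Hoff plot",
      subtitle = sprintf("dH = %.3g kcal/mol, dS = %.3g kcal/(mol K)",
                         object$delta_h, object$delta_s)
    ) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.hg_fel <- function(object, ...) {
  d <- as_tibble(object)
  ggplot(d[!is.na(d$f), ], aes(x = .data$x, y = .data$y, fill = .data$f)) +
    geom_raster() +
    scale_fill_viridis_c(name = "F (kcal/mol)") +
    labs(x = "d32 O3(n)-O2(n+1) (A)", y = "d44 O4(n)-O4(n+1) (A)",
         title = "Free-energy landscape") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.hg_rdf <- function(object, ...) {
  ggplot(object, aes(x = .data$r, y = .data$g)) +
    geom_line() +
    labs(x = "r (A)", y = "g(r)", title = "Radial distribution function") +
    theme_minimal()
}

#' Plot per-frame descriptor series
#'
#' Line plot of one or more per-frame series (RMSD, Rg, contacts) as
#' returned by [rmsd_series()], [rg_series()] or [contact_series()].
#'
#' @param data Tibble with a `frame` column and one or more value columns.
#' @return A ggplot object.
#' @export
plot_frame_series <- function(data) {
  check_columns(data, "frame", "frame series")
  long <- tidyr::pivot_longer(data, -"frame",
                              names_to = "descriptor", values_to = "value")
  ggplot(long, aes(x = .data$frame, y = .data$value)) +
    geom_line() +
    facet_wrap(~descriptor, scales = "free_y", ncol = 1) +
    labs(x = "frame", y = NULL) +
    theme_minimal()
}
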