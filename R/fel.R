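#' 2D free-energy landscape by Boltzmann inversion
#'
#' Bins two collective variables (here typically the rim distances d32 and
#' d44) on a regular 2D grid and converts the empirical bin probabilities
#' P(x,y) to free energies `F(x,y) = -kB*T * ln P(x,y)`, shifted so the
#' lowest occupied cell sits at zero. Empty cells are masked (NA), not
#' assigned a penalty constant. kB*T is the molar R*T in kcal/mol.
#'
#' @param data Data frame holding the two collective variables, or NULL if
#'   `x`/`y` are numeric vectors.
#' @param x,y Column names (unquoted, tidy-eval) when `data` is a data
#'   frame; otherwise equal-length numeric vectors.
#' @param x_bin,y_bin Bin widths in the variables' units (angstrom for
#'   distances); default 0.1.
#' @param temperature Temperature in kelvin; default 303.
#' @param gas_constant R in kcal/(mol K); default [hg_gas_constant].
#'
#' @return An object of class `hg_fel`: list with `x_edges`, `y_edges`,
#'   `counts` (nx x ny), `f` (free energies, NA-masked, kcal/mol), `kbt`,
#'   `n_samples`. Has [as_tibble()] and [autoplot()] methods.
#'
#' @examples
#' rims <- tibble::tibble(d32 = rnorm(500, 3, 0.2), d44 = rnorm(500, 4.3, 0.2))
#' fel <- fel_2d(rims, d32, d44)
#' min(fel$f, na.rm = TRUE) # 0 by construction
#' @export
fel_2d <- function(data = NULL, x, y, x_bin = 0.1, y_bin = 0.1,
                   temperature = 303, gas_constant = hg_gas_constant) {
  if (is.data.frame(data)) {
    xv <- rlang::eval_tidy(enquo(x), data)
    yv <- rlang::eval_tidy(enquo(y), data)
  } else {
    xv <- x
    yv <- y
  }
  if (length(xv) != length(yv)) {
    hg_abort("x and y samples must have equal length.", "input")
  }
  if (length(xv) == 0) hg_abort("No samples to bin.", "input")
  if (any(!is.finite(xv)) || any(!is.finite(yv))) {
    hg_abort("Samples must be finite.", "input")
  }
  check_number(x_bin, "x_bin", positive = TRUE)
  check_number(y_bin, "y_bin", positive = TRUE)
  check_number(temperature, "temperature", positive = TRUE)

  x_edges <- grid_edges(xv, x_bin)
  y_edges <- grid_edges(yv, y_bin)
  ix <- bin_index(xv, x_edges[1], x_bin, length(x_edges) - 1L)
  iy <- bin_index(yv, y_edges[1], y_bin, length(y_edges) - 1L)
  nx <- length(x_edges) - 1L
  ny <- length(y_edges) - 1L
  counts <- matrix(tabulate(ix + (iy - 1L) * nx, nbins = nx * ny), nx, ny)

  kbt <- gas_constant * temperature
  p <- counts / length(xv)
  f <- -kbt * log(p)
  f[counts == 0] <- NA_real_
  f <- f - min(f, na.rm = TRUE)

  structure(
    list(
      x_edges = x_edges, y_edges = y_edges, counts = counts, f = f,
      kbt = kbt, n_samples = length(xv)
    ),
    class = "hg_fel"
  )
}

# bin edges on a lattice anchored at multiples of `bin`, covering all samples
grid_edges <- function(v, bin) {
  lo <- floor(min(v) / bin) * bin
  hi <- ceiling(max(v) / bin) * bin
  if (hi <= lo) hi <- lo + bin # all samples on one lattice point
  seq(lo, hi, by = bin)
}

bin_index <- function(v, origin, bin, nbins) {
  i <- pmin(pmax(floor((v - origin) / bin) + 1L, 1L), nbins)
  as.integer(i)
}

#' @export
print.hg_fel <- function(x, ...) {
  cat(sprintf(
    "Free-energy landscape: %d x %d bins, %d samples, %d occupied, kB*T = %.4g kcal/mol\n",
    length(x$x_edges) - 1, length(x$y_edges) - 1, x$n_samples,
    sum(x$counts > 0), x$kbt
  ))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.hg_fel <- function(x, ...) {
  fel <- x
  nx <- length(fel$x_edges) - 1L
  ny <- length(fel$y_edges) - 1L
  xc <- (fel$x_edges[-1] + fel$x_edges[-(nx + 1)]) / 2
  yc <- (fel$y_edges[-1] + fel$y_edges[-(ny + 1)]) / 2
  tibble(
    x = rep(xc, times = ny),
    y = rep(yc, each = nx),
    count = as.vector(fel$counts),
    f = as.vector(fel$f)
  )
}

#' Empirical bin probabilities recovered from a free-energy landscape
#'
#' Inverts the Boltzmann transform: `exp(-F/kbt)` over occupied cells,
#' renormalised to sum to one. Up to the normalisation this is exactly the
#' empirical histogram the landscape was built from, which is the
#' self-consistency property of the transform.
#'
#' @param fel An `hg_fel`.
#' @return Matrix of probabilities (NA where masked).
#' @export
fel_probabilities <- function(fel) {
  w <- exp(-fel$f / fel$kbt)
  w / sum(w, na.rm = TRUE)
}
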