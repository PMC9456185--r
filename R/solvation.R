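#' Radial distribution function of solvent around selected atoms
#'
#' Shell histogram of centre-solvent distances, averaged over frames and
#' centres and normalised by the ideal-gas shell expectation
#' `4*pi*r^2*dr*rho`, giving g(r) -> 1 in bulk. Distances use the
#' minimum-image convention when the trajectory carries a box; without a
#' box an explicit `bulk_density` must be supplied.
#'
#' @param traj An `hg_trajectory`.
#' @param centers Integer atom indices of the reference (solute) atoms.
#' @param solvent Integer atom indices of the solvent sites (water oxygens).
#' @param dr Bin width in angstrom; default 0.05.
#' @param r_max Histogram range in angstrom; default 10.
#' @param bulk_density Solvent number density in particles/angstrom^3;
#'   default `length(solvent) / prod(box)`.
#'
#' @return A tibble of class `hg_rdf` with columns `r` (bin centres, A),
#'   `g` and `count` (raw pair counts per bin), carrying attributes
#'   `bulk_density`, `dr`, `r_max`, `n_frames`, `n_centers`.
#' @seealso [first_minimum()], [coordination_number()], [hydration_table()]
#' @export
rdf <- function(traj, centers, solvent, dr = 0.05, r_max = 10,
                bulk_density = NULL) {
  check_number(dr, "dr", positive = TRUE)
  check_number(r_max, "r_max", positive = TRUE)
  if (r_max <= dr) hg_abort("`r_max` must exceed `dr`.", "input")
  if (length(solvent) == 0) hg_abort("Empty solvent selection.", "input")
  if (length(centers) == 0) hg_abort("Empty centre selection.", "input")
  box <- traj$box
  if (is.null(box) && is.null(bulk_density)) {
    hg_abort(
      "RDF normalisation needs a periodic box or an explicit `bulk_density`.",
      "input"
    )
  }
  rho <- bulk_density %||% (length(solvent) / prod(box))

  nb <- as.integer(ceiling(r_max / dr))
  counts <- integer(nb)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    d <- pair_distances(xyz[centers, , drop = FALSE],
                        xyz[solvent, , drop = FALSE], box)
    d <- d[d > 0 & d < r_max]
    counts <- counts + tabulate(as.integer(floor(d / dr)) + 1L, nbins = nb)
  }
  r_centers <- (seq_len(nb) - 0.5) * dr
  shell <- 4 * pi * r_centers^2 * dr * rho * nf * length(centers)
  out <- tibble(r = r_centers, g = counts / shell, count = counts)
  structure(
    out,
    bulk_density = rho, dr = dr, r_max = r_max,
    n_frames = nf, n_centers = length(centers),
    class = c("hg_rdf", class(out))
  )
}

#' First minimum of a radial distribution function
#'
#' Radius of the first local minimum following the first local maximum of
#' the (optionally moving-average smoothed) g(r); the conventional outer
#' edge of the first solvation shell. Returns `NA` with a `"detected"`
#' attribute when the profile shows no maximum-then-minimum pattern (e.g. a
#' buried atom with no solvation peak), mirroring how such atoms are
#' reported as absent in hydration tables.
#'
#' @param profile An `hg_rdf` (or any data frame with `r` and `g`).
#' @param smooth_window Moving-average window in bins (odd; 1 disables);
#'   default 3.
#' @return Radius in angstrom, or `NA_real_` if no first minimum exists.
#' @export
first_minimum <- function(profile, smooth_window = 3) {
  check_columns(profile, c("r", "g"), "RDF profile")
  g <- profile$g
  r <- profile$r
  if (length(g) < 5) hg_abort("Profile needs at least 5 bins.", "input")
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    hg_abort("`smooth_window` must be a positive odd number of bins.", "input")
  }
  gs <- moving_average(g, smooth_window)
  n <- length(gs)
  # first strict local maximum, then first strict local minimum after it
  i_max <- NA_integer_
  for (i in 2:(n - 1)) {
    if (gs[i] > gs[i - 1] && gs[i] >= gs[i + 1]) { i_max <- i; break }
  }
  if (is.na(i_max) || i_max + 1 > n - 1) {
    return(structure(NA_real_, detected = FALSE))
  }
  for (i in seq(i_max + 1, n - 1)) {
    if (gs[i] < gs[i - 1] && gs[i] <= gs[i + 1]) {
      return(structure(r[i], detected = TRUE))
    }
  }
  structure(NA_real_, detected = FALSE)
}

moving_average <- function(x, window) {
  if (window == 1) return(x)
  half <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Coordination number n(r) from a radial distribution function
#'
#' Integrates the RDF, `n(r_cut) = 4*pi*rho * integral_0^r_cut g(r) r^2 dr`
#' (trapezoidal rule on the binned profile), the mean number of solvent
#' molecules within `r_cut` of a centre.
#'
#' @param profile An `hg_rdf`.
#' @param r_cut Integration limit in angstrom, within the profile range.
#' @return One-row tibble with `r_cut` and `n_of_r`.
#' @export
coordination_number <- function(profile, r_cut) {
  check_columns(profile, c("r", "g"), "RDF profile")
  check_number(r_cut, "r_cut", nonneg = TRUE)
  r <- profile$r
  rho <- attr(profile, "bulk_density")
  if (is.null(rho)) hg_abort("Profile lacks a `bulk_density` attribute.", "input")
  if (r_cut > max(r) + attr(profile, "dr") / 2) {
    hg_abort(sprintf("`r_cut` %.3g outside the profile range (max %.3g).",
                     r_cut, max(r)), "domain")
  }
  tibble(r_cut = r_cut, n_of_r = 4 * pi * rho * cum_trapz_at(r, profile$g * r^2, r_cut))
}

# trapezoidal integral of y(x) from 0 to x0, prepending (0, 0) and linearly
# interpolating at x0
cum_trapz_at <- function(x, y, x0) {
  x <- c(0, x)
  y <- c(0, y)
  if (x0 <= 0) return(0)
  keep <- x < x0
  xs <- c(x[keep], x0)
  ys <- c(y[keep], approx(x, y, xout = x0, rule = 2)$y)
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}

#' Hydration table: coordination numbers at the first minimum, across replicates
#'
#' For each labelled solute atom, finds the first minimum of each
#' replicate's RDF, integrates n(r) up to it, and reports the mean and
#' standard error across replicates (SEM = sd/sqrt(n), sample sd). Atoms
#' whose profiles show no first solvation minimum in every replicate are
#' reported as not detected (`n_mean` NA), the "-" entries of a hydration
#' table.
#'
#' @param profiles Tibble with columns `atom` (label), `replicate`, and
#'   `profile` (list column of `hg_rdf` objects), e.g. built with
#'   [tibble::tibble()] over [rdf()] results.
#' @param smooth_window Passed to [first_minimum()]; default 3.
#'
#' @return Tibble with one row per atom: `atom`, `n_replicates`, `detected`,
#'   `r_min_mean` (A), `n_mean`, `n_sem`.
#' @export
hydration_table <- function(profiles, smooth_window = 3) {
  check_columns(profiles, c("atom", "replicate", "profile"), "hydration input")
  profiles |>
    group_by(.data$atom) |>
    dplyr::group_modify(function(grp, key) {
      rmins <- purrr::map_dbl(grp$profile, first_minimum,
                              smooth_window = smooth_window)
      if (any(is.na(rmins))) {
        return(tibble(
          n_replicates = nrow(grp), detected = FALSE,
          r_min_mean = NA_real_, n_mean = NA_real_, n_sem = NA_real_
        ))
      }
      nvals <- purrr::map2_dbl(grp$profile, rmins,
                               function(p, rc) coordination_number(p, rc)$n_of_r)
      nrep <- length(nvals)
      tibble(
        n_replicates = nrep, detected = TRUE,
        r_min_mean = mean(rmins),
        n_mean = mean(nvals),
        n_sem = if (nrep > 1) sd(nvals) / sqrt(nrep) else NA_real_
      )
    }) |>
    ungroup()
}
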