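#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of one structure onto another over a common
#' atom selection, via singular value decomposition of the covariance
#' matrix, constrained to a proper rotation (determinant +1).
#'
#' @param mobile,reference Coordinate matrices (`atoms x 3`, angstrom) of
#'   identical atom count.
#' @param selection Optional integer atom indices used both for the fit and
#'   the RMSD; default all atoms.
#'
#' @return List with `rotation` (3x3, proper), `translation` (length 3),
#'   and `rmsd` (angstrom, the minimised value over the selection). The
#'   superposed mobile coordinates are `mobile %*% t(rotation) + translation`
#'   (row-wise).
#'
#' @details Degenerate selections (fewer than 3 atoms, or all atoms
#'   collinear/coincident, which leave the rotation underdetermined) raise a
#'   degeneracy error rather than returning an arbitrary rotation.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- coerce_coords(mobile, "mobile")
  reference <- coerce_coords(reference, "reference")
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (max(selection) > nrow(mobile) || max(selection) > nrow(reference)) {
    hg_abort("`selection` indexes beyond the coordinate matrices.", "input")
  }
  m <- mobile[selection, , drop = FALSE]
  r <- reference[selection, , drop = FALSE]
  if (nrow(m) != nrow(r)) {
    hg_abort("Selection must have identical length on both structures.", "input")
  }
  if (nrow(m) < 3) {
    hg_abort("Superposition needs at least 3 atoms.", "degenerate")
  }
  cm <- colMeans(m)
  cr <- colMeans(r)
  p <- sweep(m, 2, cm)
  q <- sweep(r, 2, cr)
  # collinear or coincident selections leave rotation about the common axis
  # free: detect via the second singular value of the centred coordinates
  sv_p <- svd(p, nu = 0, nv = 0)$d
  sv_q <- svd(q, nu = 0, nv = 0)$d
  if (sv_p[2] < 1e-8 * max(sv_p, 1e-12) || sv_q[2] < 1e-8 * max(sv_q, 1e-12)) {
    hg_abort("Selection is collinear or coincident; rotation is underdetermined.",
             "degenerate")
  }
  s <- svd(t(p) %*% q)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rotated <- p %*% t(rot)
  rmsd <- sqrt(mean(rowSums((rotated - q)^2)))
  list(
    rotation = rot,
    translation = as.numeric(cr - cm %*% t(rot)),
    rmsd = rmsd
  )
}

coerce_coords <- function(x, name) {
  if (inherits(x, "hg_trajectory")) {
    if (n_frames(x) != 1) {
      hg_abort(sprintf("`%s` must be a single frame.", name), "input")
    }
    return(frame_coords(x, 1))
  }
  x <- as.matrix(x)
  if (ncol(x) != 3 || !is.numeric(x)) {
    hg_abort(sprintf("`%s` must be an atoms x 3 numeric matrix.", name), "input")
  }
  x
}

#' Per-frame superposed RMSD series
#'
#' Root-mean-square deviation of each frame from a reference frame after
#' optimal rigid-body superposition over the selection, the standard
#' stability descriptor of a simulation.
#'
#' @param traj An `hg_trajectory`.
#' @param reference Reference frame index (default 1) or an `atoms x 3`
#'   coordinate matrix.
#' @param selection Integer atom indices; default all atoms.
#'
#' @return Tibble with columns `frame` (1-based) and `rmsd` (angstrom).
#' @export
rmsd_series <- function(traj, reference = 1, selection = NULL) {
  ref <- if (is.numeric(reference) && length(reference) == 1) {
    frame_coords(traj, reference)
  } else {
    coerce_coords(reference, "reference")
  }
  if (!is.null(selection) && length(selection) == 0) {
    hg_abort("Empty atom selection.", "input")
  }
  nf <- n_frames(traj)
  rmsd <- vapply(seq_len(nf), function(f) {
    kabsch_superpose(frame_coords(traj, f), ref, selection)$rmsd
  }, numeric(1))
  tibble(frame = seq_len(nf), rmsd = rmsd)
}

# monoisotopic-ish standard atomic masses for Rg weighting
hg_atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, NA. = 22.990, K = 39.098
)

element_masses <- function(elements) {
  key <- toupper(elements)
  key[key == "NA"] <- "NA."
  m <- hg_atomic_masses[key]
  if (any(is.na(m))) {
    hg_abort(sprintf("No atomic mass for element(s): %s.",
                     paste(unique(elements[is.na(m)]), collapse = ", ")),
             "input")
  }
  unname(m)
}

#' Per-frame radius of gyration
#'
#' Root-mean-square (optionally mass-weighted) distance of the selected
#' atoms from their (mass-weighted) centroid, per frame; measures the
#' compactness of the host or complex.
#'
#' @param traj An `hg_trajectory`.
#' @param selection Integer atom indices; default all atoms.
#' @param masses Optional per-selected-atom masses; default unit masses.
#'   Pass `element_masses_of(topology, selection)` style vectors, or use
#'   `topo` below.
#' @param topo Optional `hg_topology`; when given and `masses` is NULL,
#'   standard atomic masses are looked up from the element column
#'   (mass-weighted Rg, the usual convention).
#'
#' @return Tibble with columns `frame` and `rg` (angstrom).
#' @export
rg_series <- function(traj, selection = NULL, masses = NULL, topo = NULL) {
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  if (length(selection) == 0) hg_abort("Empty atom selection.", "input")
  if (is.null(masses)) {
    masses <- if (is.null(topo)) {
      rep(1, length(selection))
    } else {
      element_masses(topo$atoms$element[selection])
    }
  }
  if (length(masses) != length(selection) || any(masses <= 0)) {
    hg_abort("`masses` must be positive, one per selected atom.", "input")
  }
  w <- masses / sum(masses)
  nf <- n_frames(traj)
  rg <- vapply(seq_len(nf), function(f) {
    xyz <- frame_coords(traj, f)[selection, , drop = FALSE]
    ctr <- colSums(xyz * w)
    sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)))
  }, numeric(1))
  tibble(frame = seq_len(nf), rg = rg)
}

#' Per-frame host-guest atom contacts (total, native, nonnative)
#'
#' Counts inter-group atom pairs within a cutoff in every frame, using the
#' minimum-image convention when the trajectory has a box. A pair is
#' "native" if it is also within the cutoff in the reference frame (the
#' starting pose by default); nonnative = total - native.
#'
#' @param traj An `hg_trajectory`.
#' @param group_a,group_b Disjoint integer atom-index vectors.
#' @param cutoff Distance cutoff in angstrom (> 0); default 4.5, a common
#'   heavy-atom contact convention.
#' @param reference_frame Frame defining native contacts; default 1.
#'
#' @return Tibble with columns `frame`, `total`, `native`, `nonnative`.
#' @export
contact_series <- function(traj, group_a, group_b, cutoff = 4.5,
                           reference_frame = 1) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    hg_abort("Contact groups must be non-empty.", "input")
  }
  if (length(intersect(group_a, group_b)) > 0) {
    hg_abort("Contact groups must be disjoint.", "input")
  }
  check_number(cutoff, "cutoff", positive = TRUE)
  contact_mask <- function(f) {
    xyz <- frame_coords(traj, f)
    pair_distances(xyz[group_a, , drop = FALSE],
                   xyz[group_b, , drop = FALSE],
                   traj$box) <= cutoff
  }
  ref_mask <- contact_mask(reference_frame)
  nf <- n_frames(traj)
  out <- purrr::map(seq_len(nf), function(f) {
    m <- contact_mask(f)
    total <- sum(m)
    native <- sum(m & ref_mask)
    tibble(frame = f, total = total, native = native, nonnative = total - native)
  })
  bind_rows(out)
}

#' Adjacent-unit rim oxygen distances of a macrocyclic host
#'
#' For every frame and glucose unit n, the secondary-rim distance
#' O3(n)-O2(n+1) (`d32`) and the glycosidic distance O4(n)-O4(n+1) (`d44`),
#' with cyclic pairing (unit n_units pairs with unit 1). `d32 <= 3.5` A is
#' conventionally read as a possible intramolecular hydrogen bond across
#' the wider rim.
#'
#' @param traj An `hg_trajectory`.
#' @param topo An `hg_topology` with a complete O2/O3/O4 site map.
#'
#' @return Tibble with columns `frame`, `unit`, `d32`, `d44` (angstrom),
#'   `n_units * n_frames` rows.
#' @export
rim_distances <- function(traj, topo) {
  nu <- topo$n_units
  if (nu < 3) hg_abort("Topology has no macrocyclic host (n_units < 3).", "topology")
  o2 <- vapply(seq_len(nu), function(u) site_index(topo, u, "O2"), integer(1))
  o3 <- vapply(seq_len(nu), function(u) site_index(topo, u, "O3"), integer(1))
  o4 <- vapply(seq_len(nu), function(u) site_index(topo, u, "O4"), integer(1))
  nxt <- c(seq_len(nu)[-1], 1L) # cyclic successor
  nf <- n_frames(traj)
  res <- purrr::map(seq_len(nf), function(f) {
    xyz <- frame_coords(traj, f)
    d32 <- sqrt(rowSums((xyz[o3, , drop = FALSE] - xyz[o2[nxt], , drop = FALSE])^2))
    d44 <- sqrt(rowSums((xyz[o4, , drop = FALSE] - xyz[o4[nxt], , drop = FALSE])^2))
    tibble(frame = f, unit = seq_len(nu), d32 = d32, d44 = d44)
  })
  bind_rows(res)
}

#' Fraction of rim pairs consistent with an intramolecular hydrogen bond
#'
#' Fraction of (frame, unit) observations with secondary-rim distance
#' `d32` at or below the distance criterion.
#'
#' @param rims Tibble from [rim_distances()] (needs a `d32` column).
#' @param threshold Distance criterion in angstrom; default 3.5.
#' @return Fraction in \[0, 1\].
#' @export
hbond_fraction <- function(rims, threshold = 3.5) {
  check_columns(rims, "d32", "rim-distance table")
  check_number(threshold, "threshold", positive = TRUE)
  mean(rims$d32 <= threshold)
}
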