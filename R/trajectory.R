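#' Trajectory and topology containers
#'
#' A trajectory is a stack of coordinate frames (angstrom) with an optional
#' orthorhombic box; a topology labels each atom with a name, element, role
#' (host / guest / solvent) and, for host atoms, a 1-based glucose-unit
#' index. For a macrocyclic host the topology also carries a site map
#' locating the O2, O3 and O4 oxygens of every unit, the atoms behind rim
#' distances and the glycosidic ring.
#'
#' @param coords Numeric array `frames x atoms x 3`, or a single
#'   `atoms x 3` matrix (treated as one frame). Angstrom.
#' @param box Optional orthorhombic box lengths, numeric length 3 (angstrom),
#'   or `NULL` for a non-periodic system.
#'
#' @return `trajectory()` returns an `hg_trajectory` (list with `coords`,
#'   `box`); `topology()` an `hg_topology` (list with `atoms` tibble,
#'   `n_units`, `site_map` tibble).
#' @examples
#' tr <- trajectory(array(rnorm(2 * 5 * 3), c(2, 5, 3)))
#' n_frames(tr)
#' @export
trajectory <- function(coords, box = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    hg_abort("`coords` must be a frames x atoms x 3 array.", "input")
  }
  if (!is.null(box)) {
    if (!is.numeric(box) || length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
      hg_abort("`box` must be 3 positive orthorhombic edge lengths.", "input")
    }
    box <- as.numeric(box)
  }
  structure(list(coords = coords, box = box), class = "hg_trajectory")
}

#' @param atoms Data frame with columns `name`, `element`, `role` (one of
#'   "host", "guest", "solvent") and `unit` (1-based glucose-unit id for host
#'   atoms, NA otherwise).
#' @param require_sites If `TRUE` (default) every host unit must carry
#'   exactly one O2, one O3 and one O4 atom; set `FALSE` for topologies
#'   without a macrocyclic host.
#' @rdname trajectory
#' @export
topology <- function(atoms, require_sites = TRUE) {
  check_columns(atoms, c("name", "element", "role", "unit"), "topology")
  atoms <- as_tibble(atoms)
  bad_role <- setdiff(unique(atoms$role), c("host", "guest", "solvent"))
  if (length(bad_role) > 0) {
    hg_abort(sprintf("Unknown atom role(s): %s.", paste(bad_role, collapse = ", ")),
             "topology")
  }
  host <- atoms[atoms$role == "host", ]
  units <- sort(unique(host$unit[!is.na(host$unit)]))
  n_units <- length(units)
  site_map <- tibble(unit = integer(), site = character(), atom = integer())
  if (n_units > 0) {
    if (!identical(as.integer(units), seq_len(n_units))) {
      hg_abort("Host unit indices must be contiguous 1..n_units.", "topology")
    }
    idx <- which(atoms$role == "host" & atoms$name %in% c("O2", "O3", "O4"))
    site_map <- tibble(
      unit = as.integer(atoms$unit[idx]),
      site = atoms$name[idx],
      atom = as.integer(idx)
    )
    if (require_sites) {
      tally <- table(factor(site_map$unit, levels = units), site_map$site)
      want <- c("O2", "O3", "O4")
      if (!all(want %in% colnames(tally)) || any(tally[, want] != 1)) {
        hg_abort(
          "Every host unit must carry exactly one O2, O3 and O4 site.",
          "topology"
        )
      }
    }
  }
  structure(
    list(atoms = atoms, n_units = n_units, site_map = site_map),
    class = "hg_topology"
  )
}

#' @param x An `hg_trajectory`.
#' @rdname trajectory
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname trajectory
#' @export
n_atoms <- function(x) {
  if (inherits(x, "hg_topology")) nrow(x$atoms) else dim(x$coords)[2]
}

#' @param frame 1-based frame index.
#' @rdname trajectory
#' @export
frame_coords <- function(x, frame) {
  nf <- n_frames(x)
  if (frame < 1 || frame > nf) {
    hg_abort(sprintf("Frame %d outside 1..%d.", frame, nf), "input")
  }
  matrix(x$coords[frame, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' @export
print.hg_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frame(s) x %d atoms%s\n",
              n_frames(x), n_atoms(x),
              if (is.null(x$box)) ", non-periodic"
              else sprintf(", box %.2f x %.2f x %.2f A", x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' @export
print.hg_topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms (%s)%s\n",
              nrow(x$atoms),
              paste(sprintf("%d %s", table(x$atoms$role), names(table(x$atoms$role))),
                    collapse = ", "),
              if (x$n_units > 0) sprintf("; %d host units", x$n_units) else ""))
  invisible(x)
}

#' Atom indices matching a role (and optionally a name) in a topology
#'
#' @param topo An `hg_topology`.
#' @param role One of "host", "guest", "solvent", or NULL for all.
#' @param name Optional atom-name filter (e.g. "O4").
#' @return Integer vector of 1-based atom indices.
#' @export
atom_indices <- function(topo, role = NULL, name = NULL) {
  keep <- rep(TRUE, nrow(topo$atoms))
  if (!is.null(role)) keep <- keep & topo$atoms$role %in% role
  if (!is.null(name)) keep <- keep & topo$atoms$name %in% name
  which(keep)
}

#' Atom index of a labelled site on a given host unit
#'
#' @param topo An `hg_topology`.
#' @param unit 1-based glucose-unit index.
#' @param site "O2", "O3" or "O4".
#' @return Single 1-based atom index.
#' @export
site_index <- function(topo, unit, site) {
  hit <- topo$site_map$atom[topo$site_map$unit == unit & topo$site_map$site == site]
  if (length(hit) != 1) {
    hg_abort(sprintf("Site %s of unit %d missing from site map.", site, unit),
             "topology")
  }
  hit
}

# minimum-image displacement components (orthorhombic box); dx is a numeric
# vector/matrix of raw differences along one axis
min_image <- function(dx, length) {
  if (is.null(length)) dx else dx - length * round(dx / length)
}

# all pairwise distances between two coordinate matrices, minimum image if
# box is non-NULL; returns |A| x |B| matrix
pair_distances <- function(a, b, box = NULL) {
  d2 <- 0
  for (k in 1:3) {
    dd <- outer(a[, k], b[, k], "-")
    dd <- min_image(dd, box[k])
    d2 <- d2 + dd^2
  }
  sqrt(d2)
}
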