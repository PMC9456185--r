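#' Read a phase-solubility CSV
#'
#' Expects columns `host_conc`, `guest_conc`, `temperature`, and optionally
#' `unit` ("M" or "mM"; mM values are converted to M) and `label`. One
#' diagram is one (label, temperature) group; concentrations are returned
#' in M.
#'
#' @param path CSV file path.
#' @return Tibble with columns `host_conc`, `guest_conc` (M),
#'   `temperature`, `label`, ordered by label, temperature, host_conc.
#' @export
read_solubility_csv <- function(path) {
  data <- read_csv_checked(path, c("host_conc", "guest_conc", "temperature"),
                           "solubility CSV")
  require_numeric(data, c("host_conc", "guest_conc", "temperature"),
                  "solubility CSV")
  if (!("label" %in% names(data))) data$label <- "series"
  if ("unit" %in% names(data)) {
    bad <- setdiff(unique(data$unit), c("M", "mM"))
    if (length(bad) > 0) {
      hg_abort(sprintf("Unknown concentration unit(s): %s (use M or mM).",
                       paste(bad, collapse = ", ")), "schema")
    }
    scale <- ifelse(data$unit == "mM", 1e-3, 1)
    data$host_conc <- data$host_conc * scale
    data$guest_conc <- data$guest_conc * scale
    data$unit <- NULL
  }
  data |>
    select("host_conc", "guest_conc", "temperature", "label") |>
    arrange(.data$label, .data$temperature, .data$host_conc)
}

#' Read a stability-constant CSV
#'
#' Expects columns `temperature_K`, `kc_per_M` and optionally `label`; the
#' shape in which Kc-versus-temperature tables are published.
#'
#' @param path CSV file path.
#' @return Tibble with columns `temperature` (K), `kc` (1/M), `label`,
#'   ready for [vant_hoff_fit()] / [thermo_table()].
#' @export
read_kc_csv <- function(path) {
  data <- read_csv_checked(path, c("temperature_K", "kc_per_M"), "Kc CSV")
  require_numeric(data, c("temperature_K", "kc_per_M"), "Kc CSV")
  if (!("label" %in% names(data))) data$label <- "series"
  tibble(
    temperature = data$temperature_K,
    kc = data$kc_per_M,
    label = data$label
  )
}

#' Read per-snapshot MM/PBSA component and entropy CSVs
#'
#' `read_energy_csv()` expects columns `replicate`, `frame`, `e_vdw`,
#' `e_ele`, `g_solv_polar`, `g_solv_nonpolar`; `read_entropy_csv()` expects
#' `replicate`, `t_delta_s`. All energies in kcal/mol.
#'
#' @param path CSV file path.
#' @return Tibble with the validated, typed columns.
#' @export
read_energy_csv <- function(path) {
  cols <- c("replicate", "frame", "e_vdw", "e_ele", "g_solv_polar",
            "g_solv_nonpolar")
  data <- read_csv_checked(path, cols, "energy CSV")
  require_numeric(data, cols, "energy CSV")
  select(data, dplyr::all_of(cols))
}

#' @rdname read_energy_csv
#' @export
read_entropy_csv <- function(path) {
  data <- read_csv_checked(path, c("replicate", "t_delta_s"), "entropy CSV")
  require_numeric(data, c("replicate", "t_delta_s"), "entropy CSV")
  select(data, "replicate", "t_delta_s")
}

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    hg_abort(sprintf("File not found: %s", path), "io")
  }
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) hg_abort(sprintf("%s: cannot parse %s (%s).",
                                         what, path, conditionMessage(e)),
                                 "schema")
  )
  if (nrow(data) == 0 && ncol(data) == 0) {
    hg_abort(sprintf("%s: %s is empty.", what, path), "schema")
  }
  check_columns(data, required, what)
  data
}

require_numeric <- function(data, cols, what) {
  for (cl in cols) {
    v <- data[[cl]]
    if (!is.numeric(v) || any(is.na(v))) {
      hg_abort(sprintf("%s: column `%s` must be numeric with no missing values.",
                       what, cl), "schema")
    }
  }
  invisible(data)
}

#' Read a trajectory from multi-model PDB or XYZ + topology sidecar
#'
#' The PDB dialect honours MODEL/ENDMDL, ATOM/HETATM and CRYST1 records
#' only (others are ignored). Atom roles come from residue names: host
#' residues map unit ids from the residue number, `HOH`/`WAT`/`SOL` are
#' solvent, anything else is guest. For XYZ input a JSON topology sidecar
#' carries names/elements/roles/units per atom and the box.
#'
#' @param path Trajectory file (`.pdb` or `.xyz`).
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @param topology_path JSON sidecar path (required for XYZ; ignored for
#'   PDB).
#' @param host_resnames Residue names treated as macrocyclic host units in
#'   PDB input; default `"GLC"`.
#' @param require_sites Passed to [topology()]; set `FALSE` for systems
#'   without a complete O2/O3/O4 rim.
#'
#' @return List with `trajectory` (`hg_trajectory`) and `topology`
#'   (`hg_topology`).
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz"),
                            topology_path = NULL, host_resnames = "GLC",
                            require_sites = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) hg_abort(sprintf("File not found: %s", path), "io")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", xyz = "xyz",
                     hg_abort(sprintf("Cannot detect format from extension '.%s'.", ext),
                              "input"))
  }
  if (format == "pdb") {
    read_pdb_multimodel(path, host_resnames, require_sites)
  } else {
    if (is.null(topology_path)) {
      hg_abort("XYZ input needs a JSON `topology_path` sidecar.", "input")
    }
    read_xyz_trajectory(path, topology_path, require_sites)
  }
}

read_pdb_multimodel <- function(path, host_resnames, require_sites) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  box <- NULL
  cryst <- which(startsWith(rec, "CRYST1"))
  if (length(cryst) > 0) {
    ln <- lines[cryst[1]]
    box <- as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24), substr(ln, 25, 33)))
    if (any(is.na(box)) || any(box <= 0)) box <- NULL
  }

  model_starts <- which(startsWith(rec, "MODEL "))
  model_ends <- which(startsWith(rec, "ENDMDL"))
  atom_line <- startsWith(rec, "ATOM  ") | startsWith(rec, "HETATM")

  if (length(model_starts) == 0) {
    # single implicit frame
    blocks <- list(which(atom_line))
  } else {
    if (length(model_ends) < length(model_starts)) {
      hg_abort(sprintf(
        "Truncated PDB: MODEL at line %d has no matching ENDMDL.",
        model_starts[length(model_ends) + 1]
      ), "parse")
    }
    blocks <- purrr::map2(model_starts, model_ends, function(s, e) {
      idx <- s:e
      idx[atom_line[idx]]
    })
  }
  if (length(blocks) == 0 || length(blocks[[1]]) == 0) {
    hg_abort(sprintf("No ATOM/HETATM records in %s.", path), "parse")
  }

  n0 <- length(blocks[[1]])
  counts <- vapply(blocks, length, integer(1))
  if (any(counts != n0)) {
    bad <- which(counts != n0)[1]
    hg_abort(sprintf(
      "Inconsistent atom count in frame %d: %d atoms, expected %d.",
      bad, counts[bad], n0
    ), "parse")
  }

  parse_block <- function(idx, frame) {
    ln <- lines[idx]
    x <- as.numeric(substr(ln, 31, 38))
    y <- as.numeric(substr(ln, 39, 46))
    z <- as.numeric(substr(ln, 47, 54))
    if (any(is.na(x)) || any(is.na(y)) || any(is.na(z))) {
      bad_line <- idx[which(is.na(x) | is.na(y) | is.na(z))[1]]
      hg_abort(sprintf("Unparsable coordinates at line %d (frame %d).",
                       bad_line, frame), "parse")
    }
    cbind(x, y, z)
  }

  nf <- length(blocks)
  coords <- array(NA_real_, dim = c(nf, n0, 3))
  for (f in seq_len(nf)) coords[f, , ] <- parse_block(blocks[[f]], f)

  first <- lines[blocks[[1]]]
  name <- trimws(substr(first, 13, 16))
  resname <- trimws(substr(first, 18, 20))
  resid <- suppressWarnings(as.integer(trimws(substr(first, 23, 26))))
  elem <- trimws(substr(first, 77, 78))
  elem[elem == ""] <- substr(gsub("[^A-Za-z].*$", "", name[elem == ""]), 1, 1)
  role <- dplyr::case_when(
    resname %in% host_resnames ~ "host",
    resname %in% c("HOH", "WAT", "SOL") ~ "solvent",
    TRUE ~ "guest"
  )
  unit <- ifelse(role == "host", resid, NA_integer_)
  # renumber host units contiguously in order of appearance
  if (any(role == "host")) {
    u <- unit[role == "host"]
    unit[role == "host"] <- as.integer(factor(u, levels = unique(u)))
  }
  atoms <- tibble(name = name, element = elem, role = role,
                  unit = as.integer(unit))
  list(
    trajectory = trajectory(coords, box = box),
    topology = topology(atoms, require_sites = require_sites)
  )
}

read_xyz_trajectory <- function(path, topology_path, require_sites) {
  lines <- readLines(path)
  if (!file.exists(topology_path)) {
    hg_abort(sprintf("Topology sidecar not found: %s", topology_path), "io")
  }
  meta <- jsonlite::fromJSON(topology_path)
  for (fld in c("name", "element", "role")) {
    if (is.null(meta$atoms[[fld]])) {
      hg_abort(sprintf("Topology sidecar lacks atoms$%s.", fld), "schema")
    }
  }
  atoms <- tibble(
    name = meta$atoms$name,
    element = meta$atoms$element,
    role = meta$atoms$role,
    unit = as.integer(meta$atoms$unit %||% rep(NA_integer_, length(meta$atoms$name)))
  )
  box <- if (!is.null(meta$box)) as.numeric(meta$box) else NULL

  na <- nrow(atoms)
  i <- 1L
  frames <- list()
  f <- 0L
  n_lines <- length(lines)
  while (i <= n_lines && nzchar(trimws(lines[i]))) {
    cnt <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(cnt)) {
      hg_abort(sprintf("Expected an atom count at line %d.", i), "parse")
    }
    if (cnt != na) {
      hg_abort(sprintf("Frame %d declares %d atoms, topology has %d.",
                       f + 1L, cnt, na), "parse")
    }
    if (i + 1L + cnt > n_lines) {
      hg_abort(sprintf("Truncated XYZ: frame %d starting at line %d is incomplete.",
                       f + 1L, i), "parse")
    }
    block <- lines[(i + 2L):(i + 1L + cnt)]
    parts <- strsplit(trimws(block), "\\s+")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(is.na(xyz))) {
      bad <- i + 1L + which(apply(is.na(xyz), 1, any))[1]
      hg_abort(sprintf("Unparsable coordinates at line %d.", bad), "parse")
    }
    f <- f + 1L
    frames[[f]] <- xyz
    i <- i + 2L + cnt
  }
  if (f == 0L) hg_abort(sprintf("No frames in %s.", path), "parse")
  coords <- array(NA_real_, dim = c(f, na, 3))
  for (k in seq_len(f)) coords[k, , ] <- frames[[k]]
  list(
    trajectory = trajectory(coords, box = box),
    topology = topology(atoms, require_sites = require_sites)
  )
}

#' Write a trajectory as multi-model PDB or XYZ + topology sidecar
#'
#' Inverse of [read_trajectory()]: MODEL/ENDMDL blocks with ATOM records
#' (host atoms as residue `GLC` numbered by unit, guest as `LIG`, solvent
#' as `HOH`) and a CRYST1 record when the trajectory has a box. The XYZ
#' writer emits a plain XYZ file plus a JSON sidecar holding
#' names/elements/roles/units and the box.
#'
#' @param traj An `hg_trajectory`.
#' @param topo An `hg_topology`.
#' @param path Output path.
#' @param topology_path Sidecar path for XYZ output; default `path` with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, topo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- topo$atoms
  resname <- dplyr::case_when(
    at$role == "host" ~ "GLC",
    at$role == "solvent" ~ "HOH",
    TRUE ~ "LIG"
  )
  resid <- dplyr::case_when(
    at$role == "host" ~ as.integer(at$unit),
    at$role == "guest" ~ topo$n_units + 1L,
    TRUE ~ topo$n_units + 1L + cumsum(at$role == "solvent")
  )
  if (!is.null(traj$box)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       traj$box[1], traj$box[2], traj$box[3], 90, 90, 90), con)
  }
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL %8d", f), con)
    xyz <- frame_coords(traj, f)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)) %% 100000L, at$name, resname, resid %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3], at$element
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_trajectory_pdb
#' @export
write_trajectory_xyz <- function(traj, topo, path,
                                 topology_path = sub("\\.[^.]*$", ".json", path)) {
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  na <- n_atoms(traj)
  for (f in seq_len(nf)) {
    writeLines(as.character(na), con)
    writeLines(sprintf("frame %d", f), con)
    xyz <- frame_coords(traj, f)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                       topo$atoms$element, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  sidecar <- list(
    atoms = list(
      name = topo$atoms$name, element = topo$atoms$element,
      role = topo$atoms$role, unit = topo$atoms$unit
    ),
    box = traj$box
  )
  jsonlite::write_json(sidecar, topology_path, auto_unbox = FALSE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Write an analysis result as TSV or JSON
#'
#' TSV output has a stable column order and fixed display precision; JSON
#' output round-trips exactly (full precision, `NA`/masked values as
#' `null`). Accepts any data frame, or package result objects with an
#' `as_tibble`/`tidy` representation.
#'
#' @param results Data frame (or `hg_fel` / `hg_mmpbsa` / fit object).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param digits Display digits for TSV floats; default 6. JSON is always
#'   full precision.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json"), digits = 6) {
  format <- match.arg(format)
  tb <- results_as_table(results)
  dir <- dirname(path)
  if (!dir.exists(dir)) hg_abort(sprintf("Directory does not exist: %s", dir), "io")
  if (format == "tsv") {
    out <- tb
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(v) {
      ifelse(is.na(v), "NA", formatC(v, digits = digits, format = "g"))
    })
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    jsonlite::write_json(tb, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", null = "null")
  }
  invisible(path)
}

results_as_table <- function(results) {
  if (is.data.frame(results)) return(as_tibble(results))
  if (inherits(results, "hg_fel")) return(as_tibble(results))
  if (inherits(results, "hg_mmpbsa")) return(results$terms)
  if (inherits(results, c("hg_ps_fit", "hg_vh_fit"))) return(glance(results))
  hg_abort("Don't know how to tabulate this result type.", "input")
}
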