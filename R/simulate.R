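#' Simulate an A_L-type phase-solubility diagram
#'
#' Generates dissolved-guest concentrations from the 1:1 complexation
#' model: `guest = S0 + [Kc*S0 / (1 + Kc*S0)] * host + noise`, with
#' independent Gaussian measurement noise. The noise-free slope is exactly
#' `Kc*S0/(1+Kc*S0)`, so the generator is analytically invertible by
#' [fit_diagram()] + [stability_constant()].
#'
#' @param s0 Intrinsic guest solubility in M (> 0).
#' @param kc 1:1 stability constant in 1/M (>= 0).
#' @param host_concs Host concentrations in M; default 0-10 mM in 2 mM
#'   steps, the usual working range of a cyclodextrin phase-solubility
#'   experiment.
#' @param noise_sd Gaussian noise sd on the guest concentration, in M.
#' @param temperature Temperature (K) recorded in the output; default 303.15.
#' @param label Series label recorded in the output.
#' @param seed Optional integer seed; fixed seed gives identical output.
#'
#' @return Tibble with columns `host_conc`, `guest_conc` (M),
#'   `temperature`, `label`.
#' @export
simulate_diagram <- function(s0, kc, host_concs = seq(0, 0.01, by = 0.002),
                             noise_sd = 0, temperature = 303.15,
                             label = "synthetic", seed = NULL) {
  check_number(s0, "s0", positive = TRUE)
  check_number(kc, "kc", nonneg = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  if (any(host_concs < 0)) hg_abort("Host concentrations must be >= 0.", "domain")
  slope <- kc * s0 / (1 + kc * s0)
  guest <- s0 + slope * host_concs
  if (noise_sd > 0) {
    guest <- guest + with_seed_if(seed, rnorm(length(host_concs), 0, noise_sd))
  }
  tibble(
    host_conc = as.numeric(host_concs),
    guest_conc = guest,
    temperature = temperature,
    label = label
  )
}

#' Simulate a Van't Hoff-consistent stability-constant series
#'
#' Inverse of the Van't Hoff regression: `Kc(T) = exp(-dH/(R*T) + dS/R)`,
#' optionally with Gaussian noise on ln Kc. Noise-free series are exactly
#' log-linear in 1/T and recovered exactly by [vant_hoff_fit()].
#'
#' @param delta_h Complexation enthalpy in kcal/mol.
#' @param delta_s Complexation entropy in kcal/(mol K).
#' @param temps Temperatures in kelvin; default 293.15-323.15 K in 10 K
#'   steps (20-50 C).
#' @param noise_sd_logkc Gaussian noise sd on ln Kc.
#' @param gas_constant R in kcal/(mol K); default [hg_gas_constant].
#' @param label Series label.
#' @param seed Optional integer seed.
#'
#' @return Tibble with columns `temperature` (K), `kc` (1/M), `label`.
#' @export
simulate_vant_hoff <- function(delta_h, delta_s,
                               temps = c(293.15, 303.15, 313.15, 323.15),
                               noise_sd_logkc = 0,
                               gas_constant = hg_gas_constant,
                               label = "synthetic", seed = NULL) {
  check_number(delta_h, "delta_h")
  check_number(delta_s, "delta_s")
  check_number(noise_sd_logkc, "noise_sd_logkc", nonneg = TRUE)
  if (any(temps <= 0)) hg_abort("Temperatures must be > 0 K.", "domain")
  log_kc <- -delta_h / (gas_constant * temps) + delta_s / gas_constant
  if (noise_sd_logkc > 0) {
    log_kc <- log_kc + with_seed_if(seed, rnorm(length(temps), 0, noise_sd_logkc))
  }
  tibble(temperature = as.numeric(temps), kc = exp(log_kc), label = label)
}

#' Simulate a toy macrocycle trajectory with labelled rim sites
#'
#' Builds a geometric (not chemical) seven-unit ring mimicking a
#' beta-cyclodextrin skeleton: glycosidic O4 oxygens on a regular n-gon,
#' per-unit O3 and O2 sites placed so that every O3(n)-O2(n+1) rim pair
#' sits at an exact configured separation, one backbone carbon per unit,
#' optional guest atoms in the cavity, and uniformly distributed
#' non-interacting solvent sites (water oxygens) resampled every frame in
#' a periodic box. Per-frame Gaussian jitter is applied to host and guest
#' atoms. All randomness is deterministic per seed.
#'
#' @param n_frames Number of frames; default 10.
#' @param n_units Glucose units (>= 3); default 7 (beta-cyclodextrin).
#' @param ring_radius Radius of the O4 n-gon in angstrom; default 5.
#' @param o3_o2_sep Constructed O3(n)-O2(n+1) separation in angstrom;
#'   default 3.0 (inside the 3.5 A hydrogen-bond criterion).
#' @param jitter_sd Per-frame Gaussian jitter sd (A) on host/guest atoms;
#'   default 0.
#' @param n_guest Guest atoms placed along the cavity axis; default 0.
#' @param n_waters Solvent sites per frame; default 0.
#' @param box Orthorhombic box lengths (A); required when `n_waters > 0`
#'   and must exceed twice the ring radius.
#' @param seed Optional integer seed.
#'
#' @return List with elements `trajectory` (`hg_trajectory`) and
#'   `topology` (`hg_topology`).
#' @export
simulate_ring_trajectory <- function(n_frames = 10, n_units = 7,
                                     ring_radius = 5, o3_o2_sep = 3.0,
                                     jitter_sd = 0, n_guest = 0,
                                     n_waters = 0, box = NULL, seed = NULL) {
  if (n_units < 3) hg_abort("`n_units` must be >= 3.", "domain")
  check_number(ring_radius, "ring_radius", positive = TRUE)
  check_number(o3_o2_sep, "o3_o2_sep", positive = TRUE)
  check_number(jitter_sd, "jitter_sd", nonneg = TRUE)
  if (n_waters > 0) {
    if (is.null(box)) hg_abort("Solvent requires a periodic box.", "input")
    if (any(box <= 2 * ring_radius)) {
      hg_abort("Box must exceed twice the ring radius.", "domain")
    }
  }

  theta <- 2 * pi * (seq_len(n_units) - 1) / n_units
  # template coordinates, ring centred at the origin in the xy-plane
  o4 <- cbind(ring_radius * cos(theta), ring_radius * sin(theta), 0)
  o3 <- cbind((ring_radius + 1) * cos(theta), (ring_radius + 1) * sin(theta), 1)
  # O2 of unit n+1 sits exactly o3_o2_sep above O3 of unit n (+z), forcing
  # every cyclic rim distance to the configured value
  prv <- c(n_units, seq_len(n_units - 1))
  o2 <- o3[prv, , drop = FALSE] + matrix(rep(c(0, 0, o3_o2_sep), each = n_units), ncol = 3)
  c1 <- cbind(ring_radius * cos(theta), ring_radius * sin(theta), 0.5)

  host_xyz <- do.call(rbind, lapply(seq_len(n_units), function(u) {
    rbind(c1[u, ], o2[u, ], o3[u, ], o4[u, ])
  }))
  host_atoms <- tibble(
    name = rep(c("C1", "O2", "O3", "O4"), n_units),
    element = rep(c("C", "O", "O", "O"), n_units),
    role = "host",
    unit = rep(seq_len(n_units), each = 4)
  )

  guest_xyz <- if (n_guest > 0) {
    cbind(0, 0, seq(-0.5 * (n_guest - 1), 0.5 * (n_guest - 1)) * 0.5)
  } else {
    matrix(numeric(0), ncol = 3)
  }
  guest_atoms <- if (n_guest > 0) {
    tibble(name = paste0("G", seq_len(n_guest)), element = "C",
           role = "guest", unit = NA_integer_)
  } else {
    tibble(name = character(), element = character(),
           role = character(), unit = integer())
  }

  solvent_atoms <- if (n_waters > 0) {
    tibble(name = paste0("OW", seq_len(n_waters)), element = "O",
           role = "solvent", unit = NA_integer_)
  } else {
    tibble(name = character(), element = character(),
           role = character(), unit = integer())
  }

  solute_xyz <- rbind(host_xyz, guest_xyz)
  if (!is.null(box)) {
    solute_xyz <- sweep(solute_xyz, 2, box / 2, "+") # centre in the box
  }
  n_solute <- nrow(solute_xyz)
  n_total <- n_solute + n_waters

  coords <- with_seed_if(seed, {
    arr <- array(NA_real_, dim = c(n_frames, n_total, 3))
    for (f in seq_len(n_frames)) {
      xyz <- solute_xyz
      if (jitter_sd > 0) {
        xyz <- xyz + matrix(rnorm(n_solute * 3, 0, jitter_sd), ncol = 3)
      }
      if (n_waters > 0) {
        wat <- cbind(runif(n_waters, 0, box[1]),
                     runif(n_waters, 0, box[2]),
                     runif(n_waters, 0, box[3]))
        xyz <- rbind(xyz, wat)
      }
      arr[f, , ] <- xyz
    }
    arr
  })

  list(
    trajectory = trajectory(coords, box = box),
    topology = topology(bind_rows(host_atoms, guest_atoms, solvent_atoms))
  )
}

#' Simulate per-snapshot MM/PBSA energy-component tables
#'
#' Draws independent Gaussian rows for the four energy components, for a
#' configurable number of snapshots and replicates, with one entropy term
#' per replicate. Zero sds reproduce the means exactly under
#' [summarize_mmpbsa()].
#'
#' @param means Length-4 numeric: means of `e_vdw`, `e_ele`,
#'   `g_solv_polar`, `g_solv_nonpolar` (kcal/mol).
#' @param sds Length-4 numeric, per-component Gaussian sds (>= 0).
#' @param t_delta_s Entropy term (kcal/mol), scalar (recycled) or one per
#'   replicate.
#' @param n_snapshots Snapshots per replicate; default 100.
#' @param n_replicates Replicates; default 3.
#' @param seed Optional integer seed.
#'
#' @return List with `components` (tibble: `replicate`, `frame`, the four
#'   component columns) and `entropy` (tibble: `replicate`, `t_delta_s`).
#' @export
simulate_energy_table <- function(means, sds, t_delta_s,
                                  n_snapshots = 100, n_replicates = 3,
                                  seed = NULL) {
  if (length(means) != 4 || length(sds) != 4) {
    hg_abort("`means` and `sds` must have length 4.", "input")
  }
  if (any(sds < 0)) hg_abort("`sds` must be >= 0.", "domain")
  if (!(length(t_delta_s) %in% c(1L, n_replicates))) {
    hg_abort("`t_delta_s` must be scalar or one per replicate.", "input")
  }
  tds <- rep(t_delta_s, length.out = n_replicates)
  cols <- c("e_vdw", "e_ele", "g_solv_polar", "g_solv_nonpolar")

  components <- with_seed_if(seed, {
    purrr::map(seq_len(n_replicates), function(r) {
      vals <- purrr::map2(means, sds, function(m, s) {
        if (s == 0) rep(m, n_snapshots) else rnorm(n_snapshots, m, s)
      })
      names(vals) <- cols
      dplyr::bind_cols(
        tibble(replicate = r, frame = seq_len(n_snapshots)),
        as_tibble(vals)
      )
    }) |> bind_rows()
  })

  list(
    components = components,
    entropy = tibble(replicate = seq_len(n_replicates), t_delta_s = tds)
  )
}
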