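test_that("rdf is zero when no solvent lies within range", {
  # one centre, solvent 20 A away, no box: explicit density needed
  coords <- rbind(c(0, 0, 0), c(20, 0, 0))
  tr <- trajectory(coords)
  expect_error(rdf(tr, 1, 2, dr = 0.2, r_max = 8), class = "hg_error_input")
  prof <- rdf(tr, 1, 2, dr = 0.2, r_max = 8, bulk_density = 0.0334)
  expect_true(all(prof$g == 0))
})

test_that("a single fixed pair is normalised by the ideal shell count", {
  box <- c(12, 12, 12)
  dr <- 0.2
  # place the pair at an exact bin centre so the hand normalisation is exact
  d0 <- 2.9
  coords <- rbind(c(6, 6, 6), c(6 + d0, 6, 6))
  tr <- trajectory(coords, box = box)
  prof <- rdf(tr, centers = 1, solvent = 2, dr = dr, r_max = 5)
  rho <- 1 / prod(box)
  hit <- which(prof$count == 1)
  expect_identical(length(hit), 1L)
  expect_equal(prof$r[hit], d0)
  expect_equal(prof$g[hit], 1 / (4 * pi * d0^2 * dr * rho), tolerance = 1e-12)
  expect_true(all(prof$g[-hit] == 0))
})

test_that("uniform random solvent approaches the ideal-gas g(r) = 1", {
  sim <- simulate_ring_trajectory(n_frames = 20, n_guest = 5, n_waters = 2000,
                                  box = c(40, 40, 40), seed = 13)
  prof <- rdf(sim$trajectory,
              centers = atom_indices(sim$topology, "guest"),
              solvent = atom_indices(sim$topology, "solvent"),
              dr = 0.1, r_max = 6)
  band <- prof$g[prof$r >= 2 & prof$r <= 5]
  expect_equal(mean(band), 1, tolerance = 0.05)
})

test_that("histogram conservation: binned counts equal total counted pairs", {
  sim <- simulate_ring_trajectory(n_frames = 3, n_guest = 2, n_waters = 200,
                                  box = c(25, 25, 25), seed = 21)
  centers <- atom_indices(sim$topology, "guest")
  solvent <- atom_indices(sim$topology, "solvent")
  r_max <- 7
  prof <- rdf(sim$trajectory, centers, solvent, dr = 0.05, r_max = r_max)
  direct <- 0L
  for (f in 1:3) {
    xyz <- frame_coords(sim$trajectory, f)
    for (ci in centers) {
      d <- xyz[solvent, , drop = FALSE] - matrix(xyz[ci, ], length(solvent), 3,
                                                 byrow = TRUE)
      d <- d - sweep(round(sweep(d, 2, c(25, 25, 25), "/")), 2, c(25, 25, 25), "*")
      direct <- direct + sum(sqrt(rowSums(d^2)) < r_max)
    }
  }
  expect_identical(sum(prof$count), direct)
})

test_that("first minimum finds the constructed max-then-min pattern", {
  r <- seq(0.1, 6, by = 0.1)
  g <- exp(-((r - 2.8) / 0.3)^2) * 2 + pmin(1, pmax(0, (r - 3.4) / 1.2))
  prof <- make_profile(r, g, rho = 0.033, dr = 0.1)
  expect_equal(as.numeric(first_minimum(prof, smooth_window = 1)), 3.4,
               tolerance = 0.11)

  monotone <- make_profile(r, r / 6, rho = 0.033, dr = 0.1)
  got <- first_minimum(monotone)
  expect_true(is.na(got))
  expect_false(attr(got, "detected"))
})

test_that("smoothed minimum detection equals the exhaustive scan oracle", {
  withr::with_seed(41, {
    for (i in 1:10) {
      r <- seq(0.05, 8, by = 0.05)
      g <- pmax(0, 2.2 * exp(-((r - 2.5) / 0.35)^2) +
                  1 - exp(-(r / 3)^2) + rnorm(length(r), 0, 0.08))
      prof <- make_profile(r, g, rho = 0.033, dr = 0.05)
      got <- as.numeric(first_minimum(prof, smooth_window = 3))
      want <- first_min_oracle(r, g, window = 3)
      expect_equal(got, want)
    }
  })
})

test_that("coordination number integrates the profile correctly", {
  rho <- 0.0334
  r <- seq(0.025, 6, by = 0.05)
  uniform <- make_profile(r, rep(1, length(r)), rho = rho, dr = 0.05)
  expect_equal(coordination_number(uniform, 0)$n_of_r, 0)
  expect_equal(coordination_number(uniform, 3)$n_of_r, 4 / 3 * pi * 27 * rho,
               tolerance = 1e-3)
  expect_error(coordination_number(uniform, 10), class = "hg_error_domain")

  # n(r) nondecreasing in r
  withr::with_seed(43, {
    g <- pmax(0, 1 + rnorm(length(r), 0, 0.3))
    noisy <- make_profile(r, g, rho = rho, dr = 0.05)
    cuts <- seq(0.5, 6, by = 0.25)
    nvals <- vapply(cuts, function(rc) coordination_number(noisy, rc)$n_of_r,
                    numeric(1))
    expect_true(all(diff(nvals) >= -1e-12))
  })
})

test_that("coordination number matches a direct count of nearby solvent", {
  sim <- simulate_ring_trajectory(n_frames = 40, n_guest = 1, n_waters = 600,
                                  box = c(22, 22, 22), seed = 19)
  center <- atom_indices(sim$topology, "guest")
  solvent <- atom_indices(sim$topology, "solvent")
  prof <- rdf(sim$trajectory, center, solvent, dr = 0.05, r_max = 8)
  r_cut <- 5
  got <- coordination_number(prof, r_cut)$n_of_r

  direct <- 0
  for (f in seq_len(n_frames(sim$trajectory))) {
    xyz <- frame_coords(sim$trajectory, f)
    d <- xyz[solvent, , drop = FALSE] - matrix(xyz[center, ], length(solvent), 3,
                                               byrow = TRUE)
    d <- d - sweep(round(sweep(d, 2, sim$trajectory$box, "/")), 2,
                   sim$trajectory$box, "*")
    direct <- direct + sum(sqrt(rowSums(d^2)) <= r_cut)
  }
  direct <- direct / n_frames(sim$trajectory)
  expect_equal(got, direct, tolerance = 0.05)
})

test_that("hydration table aggregates replicates and reports absent minima", {
  r <- seq(0.05, 8, by = 0.05)
  shell <- function(h) pmax(0, h * exp(-((r - 2.5) / 0.3)^2) + 1 - exp(-(r / 4)^2))
  rho <- 0.0334
  profs <- tibble::tibble(
    atom = rep(c("O8", "O_buried"), each = 3),
    replicate = rep(1:3, 2),
    profile = c(
      purrr::map(c(2.0, 2.2, 2.4), function(h) make_profile(r, shell(h), rho, 0.05)),
      purrr::map(1:3, function(i) make_profile(r, 1 - exp(-(r / 4)^2), rho, 0.05))
    )
  )
  tab <- hydration_table(profs)
  expect_identical(nrow(tab), 2L)
  o8 <- tab[tab$atom == "O8", ]
  expect_true(o8$detected)
  buried <- tab[tab$atom == "O_buried", ]
  expect_false(buried$detected)
  expect_true(is.na(buried$n_mean))

  # hand-computed mean/SEM from the per-replicate values
  rmins <- purrr::map_dbl(profs$profile[1:3], first_minimum)
  nvals <- purrr::map2_dbl(profs$profile[1:3], rmins,
                           function(p, rc) coordination_number(p, rc)$n_of_r)
  expect_equal(o8$n_mean, mean(nvals), tolerance = 1e-12)
  expect_equal(o8$n_sem, stats::sd(nvals) / sqrt(3), tolerance = 1e-12)

  # identical replicates have SEM exactly zero
  same <- tibble::tibble(
    atom = "O9", replicate = 1:3,
    profile = purrr::map(1:3, function(i) make_profile(r, shell(2), rho, 0.05))
  )
  expect_equal(hydration_table(same)$n_sem, 0)
})
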