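square_with_lift <- function(lift = 1) {
  rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, lift))
}

test_that("superposing a structure on itself and on rigid copies gives zero RMSD", {
  xyz <- square_with_lift()
  expect_equal(kabsch_superpose(xyz, xyz)$rmsd, 0, tolerance = 1e-12)

  rot90z <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  moved <- xyz %*% t(rot90z) + matrix(5, nrow(xyz), 3)
  res <- kabsch_superpose(moved, xyz)
  expect_lt(res$rmsd, 1e-8)
  expect_equal(det(res$rotation), 1, tolerance = 1e-10)
  # returned transform actually superposes the mobile coordinates
  applied <- moved %*% t(res$rotation) +
    matrix(res$translation, nrow(xyz), 3, byrow = TRUE)
  expect_lt(max(abs(applied - xyz)), 1e-8)
})

test_that("minimised RMSD matches a rotation-search oracle on a bent square", {
  mobile <- square_with_lift(1)
  reference <- square_with_lift(0)
  got <- kabsch_superpose(mobile, reference)$rmsd
  expect_equal(got, rmsd_oracle(mobile, reference), tolerance = 1e-6)
})

test_that("degenerate selections are refused", {
  line <- cbind(0:3, 0, 0)
  expect_error(kabsch_superpose(line, line), class = "hg_error_degenerate")
  expect_error(kabsch_superpose(square_with_lift()[1:2, ], square_with_lift()[1:2, ]),
               class = "hg_error_degenerate")
})

test_that("RMSD is invariant under rigid motion and symmetric in its arguments", {
  withr::with_seed(5, {
    base <- matrix(rnorm(30), ncol = 3)
    jig <- base + matrix(rnorm(30, 0, 0.3), ncol = 3)
    r0 <- kabsch_superpose(jig, base)$rmsd
    for (i in 1:20) {
      rot <- random_rotation()
      shift <- matrix(rnorm(3, 0, 10), nrow(jig), 3, byrow = TRUE)
      r1 <- kabsch_superpose(jig %*% t(rot) + shift, base)$rmsd
      expect_lt(abs(r1 - r0), 1e-8)
    }
    expect_lt(abs(kabsch_superpose(base, jig)$rmsd - r0), 1e-8)
  })
})

test_that("rmsd_series reproduces the frame-wise superposition oracle", {
  sim <- simulate_ring_trajectory(n_frames = 6, jitter_sd = 0.2, seed = 9)
  series <- rmsd_series(sim$trajectory)
  expect_identical(nrow(series), 6L)
  ref <- frame_coords(sim$trajectory, 1)
  for (f in 1:6) {
    expect_equal(series$rmsd[f],
                 kabsch_superpose(frame_coords(sim$trajectory, f), ref)$rmsd,
                 tolerance = 1e-12)
  }
  # identical frames give identically zero RMSD
  still <- simulate_ring_trajectory(n_frames = 4, jitter_sd = 0, seed = 1)
  expect_equal(rmsd_series(still$trajectory)$rmsd, rep(0, 4), tolerance = 1e-10)
})

test_that("radius of gyration handles dumbbells, rings and mass weighting", {
  two <- trajectory(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(rg_series(two)$rg, 1)

  coincident <- trajectory(matrix(1, 4, 3))
  expect_equal(rg_series(coincident)$rg, 0)

  for (k in 3:12) {
    th <- 2 * pi * (seq_len(k) - 1) / k
    ring <- trajectory(cbind(6.5 * cos(th), 6.5 * sin(th), 0))
    expect_equal(rg_series(ring)$rg, 6.5, tolerance = 1e-10)
  }

  # unequal masses: two atoms 4 A apart, masses 1 and 3
  dumb <- trajectory(rbind(c(0, 0, 0), c(4, 0, 0)))
  expect_equal(rg_series(dumb, masses = c(1, 3))$rg, sqrt(3), tolerance = 1e-12)
})

test_that("contact counts match the brute-force all-pairs oracle", {
  # constructed 3x3 configuration
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  b <- rbind(c(0, 0, 1), c(3, 3, 3), c(0.5, 0.5, 0.5))
  tr <- trajectory(rbind(a, b))
  cs <- contact_series(tr, 1:3, 4:6, cutoff = 1.5)
  expect_identical(cs$total, contacts_oracle(a, b, 1.5))

  # random instances, periodic and non-periodic
  withr::with_seed(17, {
    for (i in 1:30) {
      na <- sample(2:50, 1)
      nb <- sample(2:50, 1)
      box <- if (i %% 2 == 0) c(8, 8, 8) else NULL
      pts <- matrix(runif((na + nb) * 3, 0, 8), ncol = 3)
      tr <- trajectory(pts, box = box)
      cutoff <- runif(1, 0.5, 4)
      got <- contact_series(tr, 1:na, na + 1:nb, cutoff = cutoff)
      want <- contacts_oracle(pts[1:na, , drop = FALSE],
                              pts[na + 1:nb, , drop = FALSE], cutoff, box)
      expect_identical(got$total, want)
      expect_identical(got$nonnative, 0L + got$total - got$native)
    }
  })
})

test_that("native contacts are defined by the reference frame", {
  # two frames: atoms together in frame 1 (reference), apart in frame 2
  f1 <- rbind(c(0, 0, 0), c(1, 0, 0))
  f2 <- rbind(c(0, 0, 0), c(9, 0, 0))
  coords <- array(NA_real_, c(2, 2, 3))
  coords[1, , ] <- f1
  coords[2, , ] <- f2
  tr <- trajectory(coords)
  cs <- contact_series(tr, 1, 2, cutoff = 2)
  expect_identical(cs$nonnative[1], 0L) # frame equal to reference
  expect_identical(cs$total[2], 0L)
  expect_error(contact_series(tr, 1:2, 2, cutoff = 2), class = "hg_error_input")
})

test_that("rim distances honour the construction and the cyclic pairing", {
  sim <- simulate_ring_trajectory(n_frames = 3, ring_radius = 5, o3_o2_sep = 3.0,
                                  jitter_sd = 0)
  rims <- rim_distances(sim$trajectory, sim$topology)
  expect_equal(rims$d32, rep(3.0, nrow(rims)), tolerance = 1e-12)
  # O4 sites on a regular heptagon of radius 5: chord length 2 R sin(pi/7)
  expect_equal(rims$d44, rep(2 * 5 * sin(pi / 7), nrow(rims)), tolerance = 1e-12)
  # exactly n_units pairs per frame, including the wrap-around pair (7 -> 1)
  expect_identical(as.integer(table(rims$frame)), rep(7L, 3))
  expect_true(7L %in% rims$unit)
})

test_that("jittered rim distances match direct coordinate arithmetic", {
  sim <- simulate_ring_trajectory(n_frames = 2, jitter_sd = 0.3, seed = 23)
  rims <- rim_distances(sim$trajectory, sim$topology)
  topo <- sim$topology
  for (f in 1:2) {
    xyz <- frame_coords(sim$trajectory, f)
    for (u in 1:7) {
      nxt <- if (u == 7) 1 else u + 1
      d32 <- sqrt(sum((xyz[site_index(topo, u, "O3"), ] -
                         xyz[site_index(topo, nxt, "O2"), ])^2))
      got <- rims$d32[rims$frame == f & rims$unit == u]
      expect_equal(got, d32, tolerance = 1e-12)
    }
  }
})

test_that("hydrogen-bond fraction is a simple threshold count", {
  rims <- tibble::tibble(d32 = c(3.0, 3.0, 4.0, 4.0))
  expect_equal(hbond_fraction(rims), 0.5)
  expect_equal(hbond_fraction(tibble::tibble(d32 = rep(3.0, 5))), 1.0)
  expect_equal(hbond_fraction(tibble::tibble(d32 = rep(4.0, 5))), 0.0)
  # boundary value counts as bonded (criterion is <=)
  expect_equal(hbond_fraction(tibble::tibble(d32 = 3.5)), 1.0)
})
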