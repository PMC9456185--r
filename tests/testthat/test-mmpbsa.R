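published_means <- c(e_vdw = -35.12, e_ele = -17.05,
                  g_solv_polar = 29.69, g_solv_nonpolar = -5.51)

test_that("derived terms follow the component arithmetic", {
  zero <- tibble::tibble(e_vdw = 0, e_ele = 0, g_solv_polar = 0, g_solv_nonpolar = 0)
  dz <- derive_terms(zero)
  expect_equal(unlist(dz[, c("e_mm", "g_solv", "polar_plus_ele", "nonpolar_plus_vdw")]),
               c(e_mm = 0, g_solv = 0, polar_plus_ele = 0, nonpolar_plus_vdw = 0))

  row <- tibble::as_tibble(as.list(published_means))
  dr <- derive_terms(row)
  expect_equal(dr$polar_plus_ele, 12.64)
  expect_equal(dr$g_solv, 24.18)
  expect_equal(dr$e_mm, -52.17)
  expect_equal(dr$nonpolar_plus_vdw, -40.63)

  expect_error(derive_terms(tibble::tibble(e_vdw = 1)), class = "hg_error_schema")
})

test_that("derived columns equal independent recomputation on random rows", {
  withr::with_seed(51, {
    tb <- tibble::tibble(
      e_vdw = rnorm(50, -30, 3), e_ele = rnorm(50, -15, 2),
      g_solv_polar = rnorm(50, 25, 2), g_solv_nonpolar = rnorm(50, -5, 1)
    )
  })
  d <- derive_terms(tb)
  expect_equal(d$e_mm, tb$e_vdw + tb$e_ele, tolerance = 1e-15)
  expect_equal(d$g_solv, tb$g_solv_polar + tb$g_solv_nonpolar, tolerance = 1e-15)
  expect_equal(d$polar_plus_ele, tb$g_solv_polar + tb$e_ele, tolerance = 1e-15)
  expect_equal(d$nonpolar_plus_vdw, tb$g_solv_nonpolar + tb$e_vdw, tolerance = 1e-15)
})

test_that("identical replicates summarise with zero SEM and exact identities", {
  sim <- simulate_energy_table(published_means, sds = rep(0, 4), t_delta_s = -24.12,
                               n_snapshots = 10, n_replicates = 3)
  s <- summarize_mmpbsa(sim$components, sim$entropy)
  expect_equal(s$terms$sem[s$terms$term != "t_delta_s"],
               rep(0, nrow(s$terms) - 1))
  m <- setNames(s$terms$mean, s$terms$term)
  expect_equal(m[["e_mm"]], m[["e_vdw"]] + m[["e_ele"]], tolerance = 1e-12)
  expect_equal(m[["g_solv"]], m[["g_solv_polar"]] + m[["g_solv_nonpolar"]],
               tolerance = 1e-12)
  expect_equal(m[["g_bind"]], m[["e_mm"]] + m[["g_solv"]] - m[["t_delta_s"]],
               tolerance = 1e-12)
})

test_that("assembling the printed component means yields the printed binding energy", {
  sim <- simulate_energy_table(published_means, sds = rep(0, 4), t_delta_s = -24.12,
                               n_snapshots = 1, n_replicates = 3)
  s <- summarize_mmpbsa(sim$components, sim$entropy, g_exp = -3.24)
  expect_equal(s$g_bind, -3.87, tolerance = 1e-9)
  expect_equal(s$delta_vs_exp, -0.63, tolerance = 1e-9)
  expect_equal(compare_experiment(s, -3.24), -0.63, tolerance = 1e-9)
  expect_equal(compare_experiment(s, s$g_bind), 0)
})

test_that("SEM is replicate-order invariant and the mean commutes with derivation", {
  sim <- simulate_energy_table(published_means, sds = c(1, 0.5, 0.8, 0.3),
                               t_delta_s = c(-24.0, -24.2, -24.1),
                               n_snapshots = 40, n_replicates = 3, seed = 6)
  s1 <- summarize_mmpbsa(sim$components, sim$entropy)
  # reorder replicates 3,1,2
  perm <- dplyr::mutate(sim$components,
                        replicate = c(3, 1, 2)[replicate])
  ent_perm <- dplyr::mutate(sim$entropy, replicate = c(3, 1, 2)[replicate])
  s2 <- summarize_mmpbsa(perm, ent_perm)
  expect_equal(s1$terms$sem, s2$terms$sem, tolerance = 1e-12)
  expect_equal(s1$g_bind, s2$g_bind, tolerance = 1e-12)

  # linearity: mean of derived column = derived value of column means
  d <- derive_terms(sim$components)
  expect_equal(mean(d$e_mm), mean(d$e_vdw) + mean(d$e_ele), tolerance = 1e-12)

  # pooled-snapshot SEM mode runs and differs from the replicate mode
  s3 <- summarize_mmpbsa(sim$components, sim$entropy, sem_mode = "snapshot")
  expect_identical(s3$sem_mode, "snapshot")
  expect_false(isTRUE(all.equal(s1$terms$sem[1], s3$terms$sem[1])))
})

test_that("replicate/entropy mismatches are rejected", {
  sim <- simulate_energy_table(published_means, sds = rep(0, 4), t_delta_s = -24,
                               n_snapshots = 2, n_replicates = 3)
  expect_error(
    summarize_mmpbsa(sim$components, sim$entropy[1:2, ]),
    class = "hg_error_input"
  )
})
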