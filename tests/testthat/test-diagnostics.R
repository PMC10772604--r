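test_that("habitat volume equals a naive per-cell oracle on a toy grid", {
  env <- toy_grid()
  tr <- trait_set(8, 0.3, dEdT = 0.025)
  got <- habitat_volume(env, 8, 0.3, 0.025, Phi_max = 1.4,
                        depth_band = c(0, 200))
  oracle <- 0
  for (i in 1:4) for (j in 1:4) for (k in 1:2) {
    phi <- metabolic_index(env$pO2[i, j, k, 1], env$T[i, j, k, 1], tr)
    if (phi >= 1 && phi <= 1.4) oracle <- oracle + env$volume[i, j, k]
  }
  expect_identical(got, oracle)
  expect_gt(got, 0)
})

test_that("habitable, sub-threshold and super-band volumes conserve total", {
  env <- toy_grid()
  p <- habitat_volume(env, 8, 0.3, 0.025, Phi_max = 1.2,
                      depth_band = c(0, 200), parts = TRUE)
  expect_identical(p$habitable + p$sub_threshold + p$super_band, p$total)
  expect_identical(p$total, sum(env$volume))
  # degenerate traits: nothing habitable / everything sub-threshold
  expect_identical(habitat_volume(env, 1e-9, 0, 0, depth_band = c(0, 200)),
                   0)
  expect_error(habitat_volume(env, 8, 0.3, depth_band = c(5000, 6000)),
               "depth")
})

test_that("habitable volume is monotone in A_eco when the band is unbounded", {
  env <- test_env()
  A <- exp(seq(log(0.5), log(100), length.out = 12))
  v <- vapply(A, function(a) habitat_volume(env, a, 0.4, 0.025,
                                            Phi_max = Inf,
                                            depth_band = c(0, 1000)),
              numeric(1))
  expect_true(all(diff(v) >= 0))
})

test_that("trait-grid volumes equal pointwise evaluation and flip with depth", {
  env <- test_env()
  A <- exp(seq(log(2), log(60), length.out = 6))
  E <- seq(-0.4, 1.2, length.out = 5)
  gr <- habitat_volume_grid(env, A, E, dEdT = 0.025, Phi_max = 1.4)
  for (b in 1:2) {
    band <- gr[[b]]$depth_band
    for (ia in c(1, 4)) for (ie in c(2, 5)) {
      expect_identical(gr[[b]]$volume[ia, ie],
                       habitat_volume(env, A[ia], E[ie], 0.025, 1.4, band))
    }
  }
  # at high E the volume-maximising A is larger in the warm shallow band
  # than in the cool deep band
  ie <- 5
  Afine <- exp(seq(log(0.5), log(100), length.out = 30))
  g2 <- habitat_volume_grid(env, Afine, E[ie], dEdT = 0.025,
                            Phi_max = 1.4)
  expect_gt(Afine[which.max(g2[[1]]$volume)],
            Afine[which.max(g2[[2]]$volume)])
})

test_that("edge sensitivities follow the linear formula exactly", {
  f0 <- list(traits = trait_set(5, 0.3, 0), T_C = 2, T_W = 21)
  e0 <- edge_sensitivities(f0)
  expect_equal(e0$E_eco_W, e0$E_eco_C)
  expect_equal(e0$delta_E_eco, 0)
  f1 <- list(traits = trait_set(5, 0.19, 0.05), T_C = 12, T_W = 20)
  e1 <- edge_sensitivities(f1)
  expect_equal(e1$E_eco_W, 0.44)
  expect_equal(e1$delta_E_eco, 0.05 * 8, tolerance = 1e-14)
  # the identity delta = dEdT * (T_W - T_C) holds to machine precision
  set.seed(8)
  for (i in 1:25) {
    tr <- trait_set(runif(1, 1, 50), runif(1, -1, 2), runif(1, 0, 0.12))
    TC <- runif(1, -2, 15); TW <- TC + runif(1, 0, 20)
    e <- edge_sensitivities(list(traits = tr, T_C = TC, T_W = TW))
    expect_lt(abs(e$delta_E_eco - tr$dEdT * (TW - TC)), 1e-13)
  }
})

test_that("phi_max_ratio is the occupied 95th-percentile index", {
  at_thr <- manual_dataset(
    data.frame(T = 15, pO2 = 0.1, label = "presence", weight = 1,
               volume = 1))
  expect_equal(phi_max_ratio(at_thr, trait_set(10, 0, 0)), 1)
  phis <- seq(1, 2, by = 0.1)
  ds <- manual_dataset(
    data.frame(T = 15, pO2 = phis / 10, label = "presence", weight = 1,
               volume = 1))
  expect_equal(phi_max_ratio(ds, trait_set(10, 0, 0)),
               unname(quantile(phis, 0.95, type = 7)))
  expect_gt(phi_max_ratio(ds, trait_set(10, 0, 0)), 1)
})

test_that("E_phicrit derives from trait differences and FAS regressions", {
  expect_equal(e_phicrit(0.19, 0.34), -0.15)
  expect_equal(e_phicrit(0.4, 0.4), 0)
  expect_error(e_phicrit(0.2, 0.3, "spA", "spB"), "mismatch")
  # two-point Arrhenius regression of FAS
  x <- -(1 / kB_test) * (1 / c(283.15, 293.15) - 1 / 288.15)
  expected <- (log(3) - log(4)) / (x[2] - x[1])
  got <- e_phicrit_from_fas(c(4, 3), c(10, 20))
  expect_equal(got, expected)
  expect_lt(got, 0)
  expect_error(e_phicrit_from_fas(4, 10), ">= 2")
})

test_that("latitudinal summaries use species median latitudes", {
  tt <- data.frame(species_id = c("a", "b", "c"),
                   A_eco = c(20, 10, 5), E_eco_ref = c(-0.2, 0.3, 0.8))
  occ <- data.frame(
    species = rep(c("a", "b", "c"), times = c(3, 2, 4)),
    decimalLatitude = c(4, 5, 6, 34, 36, 63, 65, 65, 90))
  ls <- latitudinal_summary(tt, occ, band_width_deg = 30)
  expect_equal(nrow(ls), 3)
  expect_equal(ls$A_eco_median, c(20, 10, 5))  # equatorward increase
  expect_true(all(diff(ls$E_eco_median) > 0))
  # duplicating records of one species never moves the medians
  occ2 <- rbind(occ, occ[occ$species == "b", ])
  expect_equal(latitudinal_summary(tt, occ2, 30)$A_eco_median,
               ls$A_eco_median)
  # single species in a band is that band's median
  expect_equal(ls$n_species, c(1L, 1L, 1L))
})

test_that("KS statistic matches exhaustive enumeration and is symmetric", {
  x <- c(0.1, 0.4, 0.7, 0.9); y <- c(0.2, 0.3, 0.8, 1.5)
  ks <- ks_two_sample(x, y)
  zs <- sort(unique(c(x, y)))
  oracle <- max(vapply(zs, function(z)
    abs(mean(x <= z) - mean(y <= z)), numeric(1)))
  expect_lt(abs(ks$D - oracle), 1e-12)
  expect_equal(ks_two_sample(y, x)$D, ks$D)
  expect_identical(ks_two_sample(x, x)$D, 0)
  expect_identical(ks_two_sample(x, x)$p, 1)
  expect_equal(ks_two_sample(c(0, 1), c(10, 11))$D, 1)
  expect_error(ks_two_sample(numeric(0), y), "non-empty")
})

test_that("KS p-values agree with the reference implementation", {
  set.seed(12)
  x <- rnorm(200); y <- rnorm(200, 0.3)
  ours <- ks_two_sample(x, y)
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  expect_equal(ours$D, unname(ref$statistic))
  expect_lt(abs(ours$p - ref$p.value), 0.02)
  # p decreases as the separation (hence D) grows
  shifts <- c(0, 0.2, 0.5, 1, 2)
  res <- lapply(shifts, function(s) ks_two_sample(x, y + s))
  Ds <- vapply(res, `[[`, numeric(1), "D")
  ps <- vapply(res, `[[`, numeric(1), "p")
  expect_true(all(diff(Ds[order(Ds)]) >= 0))
  expect_true(all(diff(ps[order(Ds)]) <= 0))
})
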