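test_that("F1 score follows its closed form and conventions", {
  expect_equal(f1_score(8, 2, 2), 0.8)
  expect_equal(f1_score(5, 0, 0), 1)
  expect_equal(f1_score(0, 3, 4), 0)
  expect_error(f1_score(0, 0, 0), "undefined")
  expect_error(f1_score(-1, 0, 2), ">= 0")
})

test_that("classifier limits behave as expected", {
  fx <- test_species_dataset()
  ds <- fx$dataset
  everything <- classify(ds, trait_set(1e12, 0, 0))
  expect_equal(everything$FN, 0)
  expect_equal(everything$FP,
               sum(ds$samples$weight[ds$samples$label == "background"]))
  nothing <- classify(ds, trait_set(1e-12, 0, 0))
  expect_equal(nothing$TP, 0)
  expect_equal(nothing$TN, everything$FP)
})

test_that("presence filling the viable region gives F1 = 1 at the truth", {
  env <- test_env()
  tr <- trait_set(8, 0.3, 0.02, species_id = "full")
  phi <- aerotraits:::phi_field(env, tr)
  hab <- which(env$mask & phi >= 1, arr.ind = TRUE)
  occ <- data.frame(species = "full",
                    decimalLatitude = env$lat[hab[, 2]],
                    decimalLongitude = env$lon[hab[, 1]],
                    depth = env$depth[hab[, 3]], month = NA)
  ds <- build_occupancy(occ, env, occupancy_opts(universe = "cells"))
  conf <- classify(ds, tr)
  expect_equal(conf$FN, 0)
  expect_equal(conf$FP, 0)  # unoccupied habitable region is empty
  expect_equal(f1_score(conf$TP, conf$FP, conf$FN), 1)
  # at stricter traits, FP counts exactly the habitable background
  tr_loose <- trait_set(16, 0.3, 0.02)
  phi_loose <- aerotraits:::phi_field(env, tr_loose)
  conf2 <- classify(ds, tr_loose)
  kset <- range(hab[, 3])
  kset <- max(1, kset[1] - 1):min(length(env$depth), kset[2] + 1)
  bghab <- env$mask & phi_loose >= 1 & !(phi >= 1)
  bghab[, , setdiff(seq_along(env$depth), kset)] <- FALSE
  expect_equal(conf2$FP, sum(bghab))
})

test_that("fit recovers a noiseless synthetic species to high skill", {
  fx <- test_species_dataset(A = 8, E = 0.3, D = 0.02, n_presence = 5000,
                             noise = 0)
  fit <- fit_traits(fx$dataset)
  expect_gte(fit$F1, 0.95)
  expect_lt(abs(log(fit$traits$A_eco / 8)), log(1.12))
  expect_lt(abs(fit$traits$E_eco_ref - 0.3), 0.06)
  expect_lt(abs(fit$traits$dEdT - 0.02), 0.012)
  expect_equal(fit$flag, "ok")
  expect_lte(fit$T_C, fit$T_W)
})

test_that("returned traits sit on the near-optimal plateau of the grid", {
  fx <- test_species_dataset(n_presence = 600)
  ds <- fx$dataset
  fit <- fit_traits(ds)
  P <- sum(ds$samples$weight[ds$samples$label == "presence"])
  tol <- 2 / (2 * P)
  ss <- search_spec()
  set.seed(99)
  pts <- expand.grid(A = sample(ss$A_grid, 8), E = sample(ss$E_grid, 8),
                     D = ss$dEdT_grid)
  for (r in seq_len(nrow(pts))) {
    cf <- classify(ds, trait_set(pts$A[r], pts$E[r], pts$D[r]))
    expect_gte(fit$F1 + tol,
               f1_score(cf$TP, cf$FP, cf$FN))
  }
})

test_that("deep non-habitable background does not move the fit", {
  fx <- test_species_dataset(n_presence = 600)
  ds <- fx$dataset
  fit1 <- fit_traits(ds)
  extra <- data.frame(T = c(1, 2, 3), pO2 = c(1e-4, 2e-4, 1e-4),
                      label = "background", weight = 1,
                      volume = 1e12)
  ds2 <- ds
  ds2$samples <- rbind(ds$samples, extra)
  fit2 <- fit_traits(ds2)
  expect_identical(fit1$traits[c("A_eco", "E_eco_ref", "dEdT")],
                   fit2$traits[c("A_eco", "E_eco_ref", "dEdT")])
})

test_that("fitting is deterministic", {
  fx <- test_species_dataset(n_presence = 400)
  f1 <- fit_traits(fx$dataset)
  f2 <- fit_traits(fx$dataset)
  expect_identical(f1, f2)
})

test_that("degenerate datasets are rejected", {
  fx <- test_species_dataset(n_presence = 300)
  ds <- fx$dataset
  ds$samples <- ds$samples[ds$samples$label == "presence", ]
  expect_error(fit_traits(ds), "no background")
})

test_that("empirical lower threshold tracks presence pO2 quantiles", {
  set.seed(4)
  n <- 4000
  pres <- data.frame(T = runif(n, 10, 12), pO2 = runif(n, 0.1, 0.2),
                     volume = 1)
  ds <- manual_dataset(
    data.frame(T = pres$T, pO2 = pres$pO2, label = "presence",
               weight = 1, volume = 1), pres)
  env1 <- empirical_lower_threshold(ds, T_breaks = c(10, 12))
  expect_equal(env1$po2_lower, 0.105, tolerance = 0.01)
  # single sample in a bin returns that sample; empty bins return NA
  one <- manual_dataset(
    data.frame(T = 5, pO2 = 0.17, label = "presence", weight = 1,
               volume = 1))
  e2 <- empirical_lower_threshold(one, T_breaks = c(4, 6, 8))
  expect_equal(e2$po2_lower, c(0.17, NA_real_))
  expect_equal(e2$n_cells, c(1L, 0L))
})

test_that("multi-species driver returns the documented table schema", {
  env <- test_env()
  asm <- simulate_assemblage(env, n_species = 3, n_presence = 200,
                             seed = 17)
  tt <- fit_species_table(asm$occurrences, env)
  expect_setequal(tt$species_id, asm$truth$species_id)
  expect_true(all(c("A_eco", "E_eco_ref", "dEdT", "F1", "TP", "FP", "FN",
                    "TN", "T_C", "T_W", "Phi_max", "n_cells", "flag")
                  %in% names(tt)))
  expect_true(all(tt$F1 >= 0 & tt$F1 <= 1))
  expect_true(all(tt$T_C <= tt$T_W))
})
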