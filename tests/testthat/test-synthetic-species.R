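test_that("noiseless occurrences all fall inside the true habitat band", {
  env <- test_env()
  tr <- trait_set(8, 0.3, 0.02, species_id = "sp_band")
  truth <- species_truth(tr, Phi_max = 1.5, n_presence = 400,
                         noise_rate = 0, seed = 5)
  occ <- simulate_species(env, truth)
  expect_equal(nrow(occ), 400)
  # snap records back to cells and evaluate the true index
  i <- floor((occ$decimalLongitude + 180) / env$resolution_deg) + 1
  j <- floor((occ$decimalLatitude + 90) / env$resolution_deg) + 1
  k <- vapply(occ$depth, function(d) which.min(abs(env$depth - d)),
              integer(1))
  phi <- metabolic_index(env$pO2[cbind(i, j, k, 1)],
                         env$T[cbind(i, j, k, 1)], tr)
  expect_true(all(phi >= 1 & phi <= 1.5))
})

test_that("same seed reproduces the identical record set", {
  env <- test_env()
  truth <- species_truth(trait_set(10, 0.2, 0, species_id = "sp"),
                         seed = 11)
  expect_identical(simulate_species(env, truth),
                   simulate_species(env, truth))
})

test_that("label noise flips the stated fraction out of habitat", {
  env <- test_env()
  tr <- trait_set(8, 0.3, 0.02, species_id = "sp_noise")
  truth <- species_truth(tr, Phi_max = 1.5, n_presence = 2000,
                         noise_rate = 0.05, seed = 9)
  occ <- simulate_species(env, truth)
  i <- floor((occ$decimalLongitude + 180) / env$resolution_deg) + 1
  j <- floor((occ$decimalLatitude + 90) / env$resolution_deg) + 1
  k <- vapply(occ$depth, function(d) which.min(abs(env$depth - d)),
              integer(1))
  phi <- metabolic_index(env$pO2[cbind(i, j, k, 1)],
                         env$T[cbind(i, j, k, 1)], tr)
  out <- mean(!(phi >= 1 & phi <= 1.5))
  ci <- 2.576 * sqrt(0.05 * 0.95 / 2000)  # binomial 99% interval
  expect_gt(out, 0.05 - ci)
  expect_lt(out, 0.05 + ci)
})

test_that("empty habitat raises an error naming the offending traits", {
  env <- test_env()
  truth <- species_truth(trait_set(0.001, 0, 0, species_id = "ghost",
                                   allow_negative_dEdT = TRUE),
                         seed = 1)
  expect_error(simulate_species(env, truth), "empty habitat.*ghost")
})

test_that("sampling frequencies converge to volume weights", {
  env <- make_ocean(resolution_deg = 20, seed = 2)
  tr <- trait_set(8, 0.3, 0.02, species_id = "sp_vw")
  truth <- species_truth(tr, n_presence = 50000, noise_rate = 0, seed = 21)
  occ <- simulate_species(env, truth)
  phi <- aerotraits:::phi_field(env, tr)
  hab <- which(env$mask & phi >= 1)
  # count draws per habitat cell
  dims <- dim(env$volume)
  i <- floor((occ$decimalLongitude + 180) / env$resolution_deg) + 1
  j <- floor((occ$decimalLatitude + 90) / env$resolution_deg) + 1
  k <- vapply(occ$depth, function(d) which.min(abs(env$depth - d)),
              integer(1))
  cell <- (k - 1) * dims[1] * dims[2] + (j - 1) * dims[1] + i
  counts <- table(factor(cell, levels = hab))
  pexp <- env$volume[hab] / sum(env$volume[hab])
  keep <- pexp * 50000 >= 5
  chi <- suppressWarnings(
    stats::chisq.test(as.vector(counts[keep]), p = pexp[keep],
                      rescale.p = TRUE))
  expect_gt(chi$p.value, 0.01)
})

test_that("clade simulation matches its stated covariance", {
  tree <- read_newick(text = "((A:1,B:1):0.5,C:1.5);")
  # sigma2 = 0 pins all tips at the root value
  expect_equal(unname(simulate_clade(tree, 0, 1, root_value = 3.3)),
               rep(3.3, 3))
  # Monte-Carlo covariance against sigma2 * C_lambda
  sigma2 <- 2; lambda <- 0.5
  draws <- t(vapply(1:5000, function(s)
    simulate_clade(tree, sigma2, lambda, 0, seed = s), numeric(3)))
  Cexp <- sigma2 * phylo_covariance(tree, lambda)
  expect_lt(max(abs(stats::cov(draws) - Cexp)) / max(Cexp), 0.05)
  # lambda = 0: off-diagonal covariance indistinguishable from zero
  draws0 <- t(vapply(1:3000, function(s)
    simulate_clade(tree, 1, 0, 0, seed = s), numeric(3)))
  C0 <- stats::cov(draws0)
  expect_lt(max(abs(C0[upper.tri(C0)])), 0.1)
  # non-positive-definite covariance is reported
  bad <- tree; bad$edge.length <- c(-2, 1, 1, 1.5)
  expect_error(simulate_clade(bad, 1, 1), "positive definite")
})

test_that("assemblages carry ground truth and honour determinism", {
  env <- test_env()
  asm <- simulate_assemblage(env, n_species = 4, n_presence = 150,
                             seed = 31)
  expect_equal(nrow(asm$truth), 4)
  expect_equal(sort(unique(asm$occurrences$species)), asm$truth$species_id)
  asm2 <- simulate_assemblage(env, n_species = 4, n_presence = 150,
                              seed = 31)
  expect_identical(asm$occurrences, asm2$occurrences)
})
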