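test_that("Newick round trips preserve the tree", {
  tr <- read_newick(text = "((A,B),C);")
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$Nnode, 2)
  tr2 <- read_newick(text = "((A:1,B:1):0.5,C:1.5);")
  rt <- read_newick(text = write_newick(tr2))
  expect_equal(rt$tip.label, tr2$tip.label)
  expect_identical(rt$edge, tr2$edge)
  expect_equal(rt$edge.length, tr2$edge.length)
  expect_error(read_newick(text = "((A,B,C;"), "")
})

test_that("Grafen heights follow the descendant-tip-count transform", {
  # two tips: unit-depth tree regardless of rho
  t2 <- grafen_branch_lengths(read_newick(text = "(A,B);"), rho = 0.73)
  expect_equal(t2$edge.length, c(1, 1))
  # hand-computed three-tip case
  t3 <- grafen_branch_lengths(read_newick(text = "((A,B),C);"), rho = 0.4)
  h <- 0.5^0.4
  lens <- t3$edge.length[order(t3$edge[, 2])]
  # edges sorted by child: A, B, C tips then internal node
  expect_lt(max(abs(sort(t3$edge.length) -
                      sort(c(1 - h, h, h, 1)))), 1e-12)
  # rho = 1: heights linear in (tips - 1)
  t5 <- read_newick(text = "(((A,B),(C,D)),E);")
  g1 <- grafen_branch_lengths(t5, rho = 1)
  ref <- ape::compute.brlen(t5, method = "Grafen", power = 1)
  expect_equal(g1$edge.length, ref$edge.length)
  # agreement with the reference implementation on a bigger random tree
  set.seed(5)
  big <- ape::rtree(20)
  expect_equal(grafen_branch_lengths(big, 0.4)$edge.length,
               ape::compute.brlen(big, method = "Grafen",
                                  power = 0.4)$edge.length)
  expect_true(all(grafen_branch_lengths(big, 0.25)$edge.length >= 0))
  expect_error(grafen_branch_lengths(big, -1), "rho")
})

test_that("phylogenetic covariance applies the lambda transform", {
  tr <- read_newick(text = "((A:1,B:1):0.5,C:1.5);")
  C1 <- phylo_covariance(tr, 1)
  expect_equal(C1["A", "B"], 0.5)
  expect_equal(C1["A", "A"], 1.5)
  expect_equal(C1, ape::vcv(tr))
  C0 <- phylo_covariance(tr, 0)
  expect_true(all(C0[upper.tri(C0)] == 0))
  expect_equal(diag(C0), diag(C1))
  Ch <- phylo_covariance(tr, 0.5)
  expect_equal(Ch["A", "B"], 0.25)
  expect_error(phylo_covariance(tr, 1.2), "lambda")
})

test_that("lambda ML matches a dense grid oracle on a small tree", {
  set.seed(2)
  tree <- grafen_branch_lengths(ape::rtree(6), rho = 0.4)
  y <- simulate_clade(tree, sigma2 = 1, lambda_true = 0.6, seed = 14)
  fit <- pagel_lambda(tree, y)
  # independent oracle: profile likelihood via solve()/determinant()
  C <- ape::vcv(tree)
  oracle_ll <- function(l) {
    V <- C * l; diag(V) <- diag(C)
    n <- length(y)
    Vi <- solve(V)
    one <- rep(1, n)
    beta <- sum(Vi %*% y) / sum(Vi %*% one)
    r <- y - beta
    s2 <- as.numeric(t(r) %*% Vi %*% r) / n
    ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
    -0.5 * (n * log(2 * pi * s2) + ld + n)
  }
  grid <- seq(0, 1, by = 1e-4)
  ll <- vapply(grid, oracle_ll, numeric(1))
  expect_lt(abs(fit$lambda_hat - grid[which.max(ll)]), 1e-3)
  expect_equal(fit$logL_at_hat, max(ll), tolerance = 1e-6)
  expect_gte(fit$logL_at_hat, fit$logL_at_zero)
  expect_true(fit$p_LRT >= 0 && fit$p_LRT <= 1)
})

test_that("lambda estimates respond to signal and its destruction", {
  set.seed(6)
  tree <- grafen_branch_lengths(ape::rtree(120), rho = 0.4)
  y <- simulate_clade(tree, sigma2 = 2, lambda_true = 1, seed = 3)
  fit <- pagel_lambda(tree, y)
  expect_gte(fit$lambda_hat, 0.8)
  expect_lt(fit$p_LRT, 1e-3)
  yp <- setNames(sample(y), names(y))
  fitp <- pagel_lambda(tree, yp)
  expect_lte(fitp$lambda_hat, 0.3)
})

test_that("lambda is affine-invariant and sigma2 scales quadratically", {
  set.seed(9)
  tree <- grafen_branch_lengths(ape::rtree(40), rho = 0.4)
  y <- simulate_clade(tree, sigma2 = 1.5, lambda_true = 0.7, seed = 4)
  f1 <- pagel_lambda(tree, y)
  f2 <- pagel_lambda(tree, 3 * y + 10)
  expect_equal(f1$lambda_hat, f2$lambda_hat, tolerance = 1e-5)
  expect_equal(f2$sigma2_hat / f1$sigma2_hat, 9, tolerance = 1e-4)
})

test_that("lambda agrees with the phytools reference implementation", {
  skip_if_not_installed("phytools")
  set.seed(13)
  tree <- grafen_branch_lengths(ape::rtree(60), rho = 0.4)
  y <- simulate_clade(tree, sigma2 = 1, lambda_true = 0.5, seed = 8)
  fit <- pagel_lambda(tree, y)
  ref <- phytools::phylosig(tree, y, method = "lambda")
  expect_equal(fit$lambda_hat, ref$lambda, tolerance = 1e-3)
  expect_equal(fit$logL_at_hat, ref$logL, tolerance = 1e-3)
})

test_that("tip matching prunes and small samples error", {
  set.seed(11)
  tree <- grafen_branch_lengths(ape::rtree(10), rho = 0.4)
  y <- simulate_clade(tree, 1, 1, seed = 2)
  expect_message(fit <- pagel_lambda(tree, y[1:7]), "pruning 3")
  expect_equal(fit$n_tips, 7)
  expect_equal(fit$n_pruned, 3)
  expect_error(pagel_lambda(tree, y[1:3]), "at least 4")
  expect_error(pagel_lambda(tree, unname(y)), "named")
})
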