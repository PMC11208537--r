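test_that("polynomial fits recover exact relationships", {
  x <- seq(1, 20, by = 0.5)
  lin <- suppressWarnings(fit_polynomial(x, 2 * x + 1, degree = 1))
  expect_equal(lin$r_squared, 1)
  expect_equal(lin$coefficients[2], 2)
  expect_lt(lin$p_value, 1e-10)

  quad <- suppressWarnings(fit_polynomial(x, -(x - 10)^2, degree = 2))
  expect_equal(quad$vertex_x, 10)
  expect_equal(quad$r_squared, 1)

  expect_error(fit_polynomial(1:3, 1:3, degree = 2), "n >= degree")
  expect_error(fit_polynomial(rep(2, 10), rnorm(10), degree = 1), "degenerate")
})

test_that("Spearman grid is rank-based with midranks and BH adjustment", {
  set.seed(5)
  env <- data.frame(ph = runif(20, 4.5, 6.5), tn = rnorm(20, 2))
  ta <- cbind(mono = exp(env$ph),        # strictly monotone transform of pH
              anti = -env$ph^3,
              noise = rnorm(20))
  g <- spearman_grid(ta, env)
  expect_equal(g$rho[g$taxon == "mono" & g$variable == "ph"], 1)
  expect_equal(g$rho[g$taxon == "anti" & g$variable == "ph"], -1)
  expect_true(all(g$p_adjusted >= g$p - 1e-12))
  # midrank handling on the ties-heavy toy
  g2 <- spearman_grid(cbind(t = c(1, 2, 2, 3)), data.frame(y = c(1, 2, 3, 3)))
  expect_equal(g2$rho, 5 / 6)
  expect_equal(g2$rho, cor(c(1, 2, 2, 3), c(1, 2, 3, 3), method = "spearman"))
  expect_warning(spearman_grid(cbind(k = rep(1, 20)), env), "constant")
})

test_that("Mantel statistic agrees with vegan and honours identities", {
  set.seed(2)
  dA <- as.matrix(dist(matrix(rnorm(36), 12)))
  dB <- as.matrix(dist(matrix(rnorm(36), 12)))
  for (meth in c("pearson", "spearman")) {
    mine <- mantel_test(dA, dB, method = meth, permutations = 199, seed = 9)
    ref <- vegan::mantel(dA, dB, method = meth, permutations = 199)
    expect_equal(mine$r, unname(ref$statistic))
  }
  expect_equal(mantel_test(dA, dA, permutations = 99, seed = 1)$r, 1)
  # spearman is invariant to monotone transforms of a matrix
  expect_equal(mantel_test(dA, exp(dA) + dA^2, method = "spearman",
                           permutations = 99, seed = 1)$r, 1)
  # determinism and the permutation p floor
  m1 <- mantel_test(dA, dB, permutations = 199, seed = 4)
  m2 <- mantel_test(dA, dB, permutations = 199, seed = 4)
  expect_identical(m1, m2)
  expect_gte(m1$p_value, 1 / 200)
  rownames(dB) <- colnames(dB) <- letters[1:12]
  expect_error(mantel_test(dA * 1, dB, permutations = 99), "labels")
})

test_that("partial Mantel behaves algebraically", {
  set.seed(7)
  dA <- as.matrix(dist(matrix(rnorm(45), 15)))
  dB <- as.matrix(dist(matrix(rnorm(45), 15)))
  dC <- as.matrix(dist(matrix(rnorm(45), 15)))
  # conditioning on itself removes everything
  expect_equal(partial_mantel_test(dA, dB, dB, permutations = 99, seed = 1)$r, 0)
  # dB = dA with independent dC: near-perfect partial correlation
  expect_gt(partial_mantel_test(dA, dA, dC, permutations = 99, seed = 1)$r, 0.95)
  # independent dC barely changes the plain Mantel r
  plain <- mantel_test(dA, dB, permutations = 99, seed = 1)$r
  part <- partial_mantel_test(dA, dB, dC, permutations = 99, seed = 1)$r
  expect_lt(abs(plain - part), 0.15)
})

test_that("variation partitioning matches vegan::varpart and sums to one", {
  set.seed(3)
  comm <- matrix(rpois(20 * 15, 8), 20, 15)
  X1 <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  X2 <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "c"))
  vp <- variation_partition(comm, X1, X2)
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-9)
  ref <- vegan::varpart(vegan::decostand(comm, "hellinger"), X1, X2)
  # vegan::varpart orders its individual fractions X1|X2, X2|X1, shared, resid
  expect_equal(unname(vp$fractions[c("a", "c", "b", "residual")]),
               ref$part$indfract$Adj.R.squared, tolerance = 1e-10)
  # affine rescaling of predictors leaves fractions unchanged
  vp2 <- variation_partition(comm, X1 %*% diag(c(10, 0.2)) + 5, X2 * 3 - 1)
  expect_equal(vp2$fractions, vp$fractions, tolerance = 1e-9)
  # duplicated block has no unique fractions
  vp3 <- variation_partition(comm, X1, X1 + matrix(1e-9 * rnorm(40), 20))
  expect_lt(abs(vp3$fractions["a"]), 1e-6)
  expect_lt(abs(vp3$fractions["c"]), 1e-6)
  expect_error(variation_partition(comm, cbind(X1, X1[, 1]), X2),
               "rank-deficient.*X1")
})

test_that("VPA attributes variance to the generating block", {
  set.seed(11)
  n <- 40
  x1 <- matrix(rnorm(n * 2), n, 2)
  x2 <- matrix(rnorm(n * 2), n, 2)
  base <- matrix(rpois(n * 12, 20), n, 12)
  resp <- round(exp(outer(x1[, 1], seq(-1, 1, length.out = 12)) * 1.5) * 20)
  comm <- base + resp
  vp <- variation_partition(comm, x1, x2)
  expect_gt(vp$fractions["a"], 0.5)
  expect_lt(abs(vp$fractions["c"]), 0.05)
})

test_that("random-forest importance ranks the informative predictor first", {
  set.seed(1)
  X <- as.data.frame(matrix(rnorm(200 * 5), 200))
  y <- 3 * X$V1 + rnorm(200, sd = 0.5)
  imp <- forest_importance(X, y, trees = 300, seed = 1)
  expect_equal(imp$variable[imp$rank == 1], "V1")
  expect_setequal(imp$rank, 1:5)
  expect_identical(imp, forest_importance(X, y, trees = 300, seed = 1))
  expect_error(forest_importance(X, rep(1, 200), trees = 300), "constant")
  # duplicated predictors share importance with the original
  X2 <- X; X2$V6 <- X$V1
  imp2 <- forest_importance(X2, y, trees = 300, seed = 1)
  pair <- sum(imp2$importance[imp2$variable %in% c("V1", "V6")])
  single <- imp$importance[imp$variable == "V1"]
  expect_gt(pair, 0.5 * single)
})
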