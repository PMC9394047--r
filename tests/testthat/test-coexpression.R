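test_that("corCor is 1 on identical matrices and matches the brute-force oracle", {
  set.seed(14)
  x <- matrix(rnorm(8 * 10), 8, dimnames = list(sprintf("g%d", 1:8), NULL))
  cc <- corcor(x, x)
  expect_true(all(abs(cc$corcor - 1) < 1e-12))
  # 3-gene x 4-sample worked fixture vs enumeration of Spearman ranks
  f1 <- rbind(g1 = c(1.0, 2.0, 3.0, 4.0),
              g2 = c(2.0, 1.0, 4.0, 3.0),
              g3 = c(4.0, 3.0, 2.0, 1.0))
  f2 <- rbind(g1 = c(1.5, 2.5, 3.0, 2.0),
              g2 = c(3.0, 1.0, 2.0, 4.0),
              g3 = c(2.0, 4.0, 1.0, 3.0))
  got <- corcor(f1, f2)
  expect_equal(got$corcor, oracle_corcor(f1, f2))
  # larger random case against the same oracle
  y1 <- matrix(rnorm(6 * 7), 6, dimnames = list(sprintf("g%d", 1:6), NULL))
  y2 <- matrix(rnorm(6 * 7), 6, dimnames = list(sprintf("g%d", 1:6), NULL))
  expect_equal(corcor(y1, y2)$corcor, oracle_corcor(y1, y2))
})

test_that("corCor is invariant to per-gene monotone transforms", {
  set.seed(15)
  x1 <- matrix(rnorm(6 * 9), 6, dimnames = list(sprintf("g%d", 1:6), NULL))
  x2 <- matrix(rnorm(6 * 9), 6, dimnames = list(sprintf("g%d", 1:6), NULL))
  base <- corcor(x1, x2)$corcor
  warp <- x1
  warp[1, ] <- exp(warp[1, ])
  warp[2, ] <- warp[2, ]^3
  warp[3, ] <- 10 * warp[3, ] - 2
  expect_equal(corcor(warp, x2)$corcor, base)
})

test_that("permuting each gene's samples drives mean corCor to zero", {
  set.seed(16)
  n <- 100; s <- 100
  f <- matrix(rnorm(5 * s), 5, s)
  lam <- runif(n, 0.5, 1) * sample(c(-1, 1), n, TRUE)
  x <- lam * f[rep(1:5, length.out = n), ] + matrix(rnorm(n * s), n, s)
  rownames(x) <- sprintf("g%03d", 1:n)
  xp <- t(apply(x, 1, sample))
  rownames(xp) <- rownames(x)
  cc <- corcor(x, xp)
  expect_lt(abs(mean(cc$corcor, na.rm = TRUE)), 0.05)
})

test_that("constant genes are flagged and excluded from backgrounds", {
  set.seed(17)
  x1 <- matrix(rnorm(5 * 8), 5, dimnames = list(sprintf("g%d", 1:5), NULL))
  x2 <- x1
  x1[2, ] <- 3  # constant in matrix 1
  cc <- corcor(x1, x2)
  expect_true(cc$flagged[2])
  expect_true(is.na(cc$corcor[2]))
  expect_equal(unique(cc$n_background), 3L)  # 4 valid genes minus self
})

test_that("soft connectivity sums |r|^beta off the diagonal", {
  x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8))
  expect_equal(soft_connectivity(x, beta = 6), c(g1 = 1, g2 = 1))
  ortho <- rbind(g1 = c(1, -1, 1, -1), g2 = c(1, 1, -1, -1))
  expect_equal(soft_connectivity(ortho, beta = 6), c(g1 = 0, g2 = 0))
  # 4-gene fixture vs direct summation
  set.seed(18)
  y <- matrix(rnorm(4 * 12), 4, dimnames = list(sprintf("g%d", 1:4), NULL))
  k <- soft_connectivity(y, beta = 3)
  r <- cor(t(y))
  for (i in 1:4)
    expect_equal(unname(k[i]), sum(abs(r[i, -i])^3))
  y[2, ] <- 1
  expect_true(is.na(soft_connectivity(y)["g2"]))
})

test_that("connectivity correlation hits the +/-1 poles and validates input", {
  k <- c(g1 = 1, g2 = 2, g3 = 5, g4 = 3)
  expect_equal(connectivity_correlation(k, k, names(k)), 1)
  expect_equal(connectivity_correlation(k, -k + 10, names(k)), -1)
  expect_error(connectivity_correlation(k, k, c("g1", "g2")), ">= 3")
  expect_error(connectivity_correlation(k, k[1:3], names(k)), "undefined")
})

test_that("preserved modules keep higher connectivity correlation than scrambled", {
  ok <- vapply(1:5, function(s) {
    sim <- generate_paired_expression(
      n_genes = 200, n_tissues = 1, samples_per_tissue = 40,
      frac_diverged = 0, frac_variance_shifted = 0, n_modules = 10,
      frac_modules_scrambled = 0.5, seed = s)
    la <- log2(sim$expr_a$values + 0.25)
    lb <- log2(sim$expr_b$values + 0.25)
    rownames(lb) <- rownames(la)  # align on species-A ids
    ka <- soft_connectivity(la); kb <- soft_connectivity(lb)
    tr <- sim$truth
    r_mod <- vapply(sort(unique(tr$module_of_gene)), function(m)
      connectivity_correlation(ka, kb,
                               names(tr$module_of_gene)[tr$module_of_gene == m]),
      numeric(1))
    scr <- sort(unique(tr$module_of_gene)) %in% tr$scrambled_module_ids
    mean(r_mod[!scr]) > mean(r_mod[scr])
  }, logical(1))
  expect_true(all(ok))
})
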