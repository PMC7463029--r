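test_that("kinship recursion reproduces textbook coefficients", {
  phi <- kinship_matrix(relatives_ped())
  expect_equal(phi["gp1", "gp1"], 0.5)     # outbred self
  expect_equal(phi["gp1", "gp2"], 0)       # unrelated founders
  expect_equal(phi["gp1", "p1"], 0.25)     # parent-offspring
  expect_equal(phi["p1", "p2"], 0.25)      # full sibs
  expect_equal(phi["c1", "c2"], 0.0625)    # first cousins
  expect_equal(phi["c2", "h1"], 0.125)     # half sibs (share p2... via s-)
  expect_equal(phi["p1", "c1"], 0.25)      # parent-offspring again
  expect_equal(phi["gp1", "c1"], 0.125)    # grandparent-grandchild
  expect_true(isSymmetric(unclass(phi)))
})

test_that("half sibs through a shared mother have kinship 1/8", {
  ped <- make_ped(c("m", "f1", "f2", "k1", "k2"),
                  father = c(NA, NA, NA, "f1", "f2"),
                  mother = c(NA, NA, NA, "m", "m"))
  phi <- kinship_matrix(ped)
  expect_equal(phi["k1", "k2"], 0.125)
})

test_that("kinship of a cyclic pedigree errors", {
  ped <- make_ped(c("a", "b"), father = c("b", "a"))
  expect_error(kinship_matrix(ped), "cycle")
})

test_that("2*Phi is positive semi-definite on simulated cohorts", {
  ped <- simulate_pedigrees(10, seed = 61)
  phi <- kinship_matrix(ped)
  ev <- eigen(2 * unclass(phi), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("vc_loglik reduces to iid normals when sigma2_g = 0", {
  set.seed(62)
  ped <- nuclear_ped(3)
  phi <- kinship_matrix(ped)
  y <- rnorm(5, 1, 2)
  ll <- vc_loglik(y, unclass(phi), sigma2_g = 0, sigma2_e = 4, mu = 1)
  expect_equal(ll, sum(dnorm(y, 1, 2, log = TRUE)), tolerance = 1e-10)
})

test_that("vc_loglik matches the dense MVN oracle on a 3x3 family", {
  phi <- matrix(c(0.5, 0.25, 0.25,
                  0.25, 0.5, 0.25,
                  0.25, 0.25, 0.5), 3, 3)
  y <- c(0.3, -1.2, 0.8)
  for (pars in list(c(0.7, 0.5), c(0.2, 1.3))) {
    omega <- 2 * phi * pars[1] + diag(pars[2], 3)
    expect_equal(vc_loglik(y, phi, pars[1], pars[2], mu = 0.1),
                 dense_mvn_ll(y, 0.1, omega), tolerance = 1e-10)
  }
})

test_that("vc_loglik is invariant to relabelling individuals", {
  ped <- simulate_pedigrees(4, seed = 63)
  phi <- unclass(kinship_matrix(ped))
  set.seed(64)
  y <- rnorm(nrow(ped))
  perm <- sample(length(y))
  expect_equal(vc_loglik(y, phi, 0.4, 0.6, mu = 0),
               vc_loglik(y[perm], phi[perm, perm], 0.4, 0.6, mu = 0),
               tolerance = 1e-10)
})

test_that("all-unrelated samples are flagged unidentifiable", {
  set.seed(65)
  n <- 40
  phi <- diag(0.5, n)
  y <- rnorm(n)
  fit <- fit_polygenic(y, phi)
  expect_false(fit$identifiable)
  expect_lt(fit$lrt, 1e-6)
})

test_that("the ML fit matches the dense grid-search oracle (n <= 30)", {
  for (seed in c(71, 72)) {
    ped <- simulate_pedigrees(5, seed = seed)
    ped <- ped[ped$family %in% unique(ped$family)[1:4], ]
    phi <- unclass(kinship_matrix(ped))
    kin <- kinship_matrix(ped)
    y <- simulate_trait(ped, kin, trait_spec(0.5), seed = seed + 100)
    n <- length(y)
    expect_lte(n, 30)
    fit <- fit_polygenic(y, phi, family = ped$family)
    oracle <- grid_ml_oracle(y, 2 * phi)
    expect_gte(fit$loglik_full, oracle$loglik - 1e-4)
    expect_lt(abs(fit$loglik_full - oracle$loglik), 0.05)
  }
})

test_that("the full model never falls below the null and LRT >= 0", {
  ped <- simulate_pedigrees(20, seed = 73)
  kin <- kinship_matrix(ped)
  fam <- setNames(ped$family, ped$id)
  for (h2 in c(0, 0.5)) {
    y <- simulate_trait(ped, kin, trait_spec(h2), seed = 74 + 10 * h2)
    fit <- fit_polygenic(y, kin, family = fam[names(y)])
    expect_gte(fit$loglik_full, fit$loglik_null - 1e-9)
    expect_gte(fit$lrt, 0)
    expect_true(fit$h2 >= 0 && fit$h2 <= 1)
    expect_true(fit$sigma2_g >= 0 && fit$sigma2_e >= 0)
  }
})

test_that("estimates are invariant to rescaling the trait", {
  ped <- simulate_pedigrees(25, seed = 75)
  kin <- kinship_matrix(ped)
  fam <- setNames(ped$family, ped$id)
  y <- simulate_trait(ped, kin, trait_spec(0.4), seed = 76)
  f1 <- fit_polygenic(y, kin, family = fam[names(y)])
  f2 <- fit_polygenic(3 * y, kin, family = fam[names(y)])
  expect_equal(f1$h2, f2$h2, tolerance = 1e-5)
  expect_equal(9 * f1$sigma2_g, f2$sigma2_g, tolerance = 1e-4)
  expect_equal(f1$lrt, f2$lrt, tolerance = 1e-6)
})

test_that("mixture p-values halve the chi-squared tail", {
  ped <- simulate_pedigrees(30, seed = 77)
  kin <- kinship_matrix(ped)
  fam <- setNames(ped$family, ped$id)
  y <- simulate_trait(ped, kin, trait_spec(0.6), seed = 78)
  fit <- fit_polygenic(y, kin, family = fam[names(y)])
  expect_equal(fit$p_value, fit$p_value_chisq1 / 2, tolerance = 1e-12)
})
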