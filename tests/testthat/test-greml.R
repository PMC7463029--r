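test_that("GRM entries match the hand-computed one-SNP example", {
  g <- matrix(c(0L, 2L), 1, 2, dimnames = list("s1", c("a", "b")))
  grm <- compute_grm(g)
  # p = 0.5: off-diagonal (0-1)(2-1)/0.5 = -2; diagonals 1 + 0.5/0.5 = 2
  expect_equal(grm$A["a", "b"], -2)
  expect_equal(grm$A["a", "a"], 2)
  expect_equal(grm$A["b", "b"], 2)
  expect_equal(grm$m, 1)
})

test_that("monomorphic SNPs abort GRM construction", {
  g <- matrix(c(2L, 2L, 2L, 1L, 0L, 1L), 2, 3, byrow = TRUE,
              dimnames = list(c("mono", "ok"), c("a", "b", "c")))
  expect_error(compute_grm(g), "monomorphic")
})

test_that("unrelated founders have near-zero expected relatedness", {
  ped <- make_ped(paste0("f", 1:150), proband = c(TRUE, rep(FALSE, 149)))
  panel <- simulate_snp_panel(10000, seed = 81)
  g <- simulate_genotypes(ped, panel, seed = 82)
  grm <- compute_grm(g)
  off <- grm$A[upper.tri(grm$A)]
  expect_gt(mean(off), -0.01)
  expect_lt(mean(off), 0.01)
  expect_equal(mean(diag(grm$A)), 1, tolerance = 0.05)
})

test_that("full sibs average a realised relationship of one half", {
  peds <- lapply(1:60, function(i) nuclear_ped(2, sprintf("FS%02d", i)))
  ped <- do.call(rbind, peds)
  class(ped) <- c("pedigree", "data.frame")
  panel <- simulate_snp_panel(10000, seed = 83)
  g <- simulate_genotypes(ped, panel, seed = 84)
  grm <- compute_grm(g)
  sibs <- split(ped$id[!ped$founder], ped$family[!ped$founder])
  a_sib <- vapply(sibs, function(s) grm$A[s[1], s[2]], 0)
  expect_equal(mean(a_sib), 0.5, tolerance = 0.03)
})

test_that("realised relatedness regresses on pedigree expectation with slope 1", {
  ped <- simulate_pedigrees(40, seed = 85)
  panel <- simulate_snp_panel(10000, seed = 86)
  g <- simulate_genotypes(ped, panel, seed = 87)
  grm <- compute_grm(g)
  phi <- kinship_matrix(ped)
  off <- upper.tri(grm$A)
  slope <- coef(lm(grm$A[off] ~ I(2 * unclass(phi)[off])))[2]
  expect_equal(unname(slope), 1, tolerance = 0.05)
})

test_that("pairwise-complete counts handle missing dosages", {
  g <- matrix(c(0L, 1L, 2L, NA, 1L, 0L,
                2L, NA, 0L, 1L, 1L, 2L), 2, 6, byrow = TRUE,
              dimnames = list(c("s1", "s2"), paste0("i", 1:6)))
  grm <- compute_grm(g)
  expect_equal(grm$N["i1", "i2"], 1)  # s2 missing for i2
  expect_equal(grm$N["i1", "i3"], 2)
  expect_true(all(grm$N <= grm$m))
})

test_that("A = I makes the variance components unidentifiable", {
  set.seed(88)
  y <- rnorm(80)
  fit <- suppressWarnings(ai_reml(y, diag(80)))
  expect_false(fit$identifiable)
  expect_lt(fit$lrt, 1e-6)
})

test_that("AI-REML matches the dense restricted-likelihood grid oracle", {
  ped <- nuclear_ped(4)
  peds <- lapply(1:5, function(i) nuclear_ped(4, sprintf("F%02d", i)))
  ped <- do.call(rbind, peds)
  class(ped) <- c("pedigree", "data.frame")
  panel <- simulate_snp_panel(3000, seed = 89)
  g <- drop_mono(simulate_genotypes(ped, panel, seed = 90))
  grm <- compute_grm(g)
  kin <- kinship_matrix(ped)
  y <- simulate_trait(ped, kin, trait_spec(0.5), seed = 91)
  expect_lte(length(y), 30)
  fit <- suppressWarnings(ai_reml(y, grm))
  oracle <- grid_reml_oracle(unname(y), grm$A)
  expect_gte(fit$loglik_full, oracle$loglik - 1e-4)
  expect_lt(abs(fit$loglik_full - oracle$loglik), 0.05)
})

test_that("REML is invariant to SNP order and consistent under permutation", {
  ped <- simulate_pedigrees(15, seed = 92)
  panel <- simulate_snp_panel(1000, seed = 93)
  g <- simulate_genotypes(ped, panel, seed = 94)
  kin <- kinship_matrix(ped)
  y <- simulate_trait(ped, kin, trait_spec(0.4), seed = 95)
  set.seed(955)
  grm1 <- compute_grm(g)
  grm2 <- compute_grm(g[sample(nrow(g)), ])
  expect_equal(grm1$A, grm2$A, tolerance = 1e-12)
  f1 <- ai_reml(y, grm1)
  perm <- sample(length(y))
  f2 <- ai_reml(y[perm], grm1)  # ids re-matched through the registry
  expect_equal(f1$h2, f2$h2, tolerance = 1e-6)
  expect_equal(f1$loglik_full, f2$loglik_full, tolerance = 1e-6)
})

test_that("the restricted likelihood never decreases across iterations", {
  ped <- simulate_pedigrees(25, seed = 96)
  panel <- simulate_snp_panel(1500, seed = 97)
  g <- drop_mono(simulate_genotypes(ped, panel, seed = 98))
  kin <- kinship_matrix(ped)
  grm <- compute_grm(g)
  for (h2 in c(0, 0.4, 0.8)) {
    y <- simulate_trait(ped, kin, trait_spec(h2), seed = 99 + 10 * h2)
    fit <- ai_reml(y, grm)
    expect_true(all(diff(fit$trace$loglik) > -1e-8),
                label = sprintf("monotone trace at h2=%.1f", h2))
  }
})

test_that("ML on 2*Phi and REML on the GRM agree on strong signals", {
  ped <- simulate_pedigrees(108, seed = 101)
  panel <- simulate_snp_panel(4000, seed = 102)
  g <- simulate_genotypes(ped, panel, seed = 103)
  kin <- kinship_matrix(ped)
  fam <- setNames(ped$family, ped$id)
  for (h2 in c(0, 0.4, 0.8)) {
    y <- simulate_trait(ped, kin, trait_spec(h2), seed = 104 + 10 * h2)
    yp <- y[ped$phenotyped]
    fit_ml <- fit_polygenic(yp, kin, family = fam[names(yp)])
    # same model with A replaced by the pedigree expectation 2*Phi
    phi2 <- 2 * unclass(kin)[names(yp), names(yp)]
    fit_reml <- suppressWarnings(ai_reml(yp, phi2))
    expect_lt(abs(fit_ml$h2 - fit_reml$h2), 0.1,
              label = sprintf("ML vs REML at h2=%.1f", h2))
  }
})

test_that("MLMA finds a planted causal SNP and skips degenerate ones", {
  ped <- simulate_pedigrees(108, seed = 105)
  panel <- simulate_snp_panel(800, seed = 106)
  g <- simulate_genotypes(ped, panel, seed = 107)
  keep <- ped$id[ped$phenotyped]
  gk <- g[, keep]
  grm <- compute_grm(gk)
  set.seed(108)
  x <- as.numeric(scale(gk[500, ]))
  y <- setNames(x * sqrt(0.2) + rnorm(length(keep), 0, sqrt(0.8)), keep)
  gk[3, ] <- 1L  # constant dosage: zero variance
  expect_warning(res <- mlma_scan(y, gk, grm), "zero-variance")
  expect_equal(res$snp[which.min(res$p)], rownames(gk)[500])
  expect_true(is.na(res$p[3]))
  expect_true(all(res$p > 0 & res$p <= 1, na.rm = TRUE))
  expect_true(all(res$se > 0, na.rm = TRUE))
})
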