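test_that("pedigree generator hits the cohort design and is deterministic", {
  ped <- simulate_pedigrees(108, seed = 1)
  expect_equal(length(unique(ped$family)), 108)
  expect_true(all(tapply(ped$proband, ped$family, sum) == 1))
  # ~341 phenotyped under the default structure, within 15% across seeds
  totals <- vapply(1:5, function(s) {
    sum(simulate_pedigrees(108, seed = s)$phenotyped)
  }, 0)
  expect_true(all(totals > 341 * 0.85 & totals < 341 * 1.15))
  expect_identical(simulate_pedigrees(20, seed = 7),
                   simulate_pedigrees(20, seed = 7))
})

test_that("forced structure yields the forced family size", {
  cfg <- cohort_structure(sibship_sizes = 3, sibship_probs = 1,
                          grandparent_prob = 0)
  ped <- simulate_pedigrees(1, cfg, seed = 1)
  expect_equal(nrow(ped), 5)  # two parents + fixed sibship of 3
  expect_equal(sum(ped$founder), 2)
})

test_that("invalid sibship distributions are rejected", {
  expect_error(cohort_structure(sibship_sizes = c(3, 4),
                                sibship_probs = c(0.5, 0.3)),
               "sum to 1")
  expect_error(cohort_structure(sibship_sizes = c(3, 4),
                                sibship_probs = 0.5),
               "one probability per size")
})

test_that("pedigree invariants are validated", {
  bad <- make_ped(c("a", "b"), father = c(NA, "zzz"))
  expect_error(validate_pedigree(bad), "does not exist")
  loop <- make_ped(c("a", "b"), father = c("b", "a"),
                   mother = c(NA, NA))
  loop$founder <- FALSE
  expect_error(validate_pedigree(loop), "cycle")
})

test_that("gene dropping transmits alleles Mendelianly", {
  ped <- nuclear_ped(3)
  panel <- simulate_snp_panel(50, seed = 1)
  g <- simulate_genotypes(ped, panel, seed = 2)
  # both parents homozygous reference -> all children homozygous reference
  both0 <- g[, 1] == 0 & g[, 2] == 0
  expect_true(all(g[both0, 3:5] == 0))
  both2 <- g[, 1] == 2 & g[, 2] == 2
  expect_true(all(g[both2, 3:5] == 2))
  expect_identical(simulate_genotypes(ped, panel, seed = 9),
                   simulate_genotypes(ped, panel, seed = 9))
})

test_that("founder dosages match the binomial expectation", {
  ped <- make_ped(paste0("f", 1:40), proband = c(TRUE, rep(FALSE, 39)))
  panel <- simulate_snp_panel(10000, seed = 3)
  panel$freq <- rep(0.5, nrow(panel))
  g <- simulate_genotypes(ped, panel, seed = 4)
  expect_equal(mean(g), 1.0, tolerance = 0.02)
  # HWE proportions: heterozygosity ~ 0.5 at p = 0.5
  expect_equal(mean(g == 1), 0.5, tolerance = 0.02)
})

test_that("allele frequencies are conserved through the pedigree", {
  ped <- simulate_pedigrees(60, seed = 11)
  panel <- simulate_snp_panel(400, seed = 12)
  g <- simulate_genotypes(ped, panel, seed = 13)
  p_hat <- allele_freq(g)
  # founder freq vs cohort freq: binomial SE on 2n founder draws plus drift;
  # 3 SE of the whole-cohort estimate bounds the discrepancy
  se <- sqrt(panel$freq * (1 - panel$freq) / (2 * ncol(g)))
  frac_within <- mean(abs(p_hat - panel$freq) < 3 * pmax(se, 0.02))
  expect_gt(frac_within, 0.95)
})

test_that("full-sib dosage correlation matches twice the kinship", {
  # many independent SNPs through one sib pair = Monte-Carlo replicates
  ped <- nuclear_ped(2)
  panel <- simulate_snp_panel(20000, seed = 5)
  panel$freq <- rep(0.5, nrow(panel))
  g <- simulate_genotypes(ped, panel, seed = 6)
  expect_equal(cor(g[, 3], g[, 4]), 0.5, tolerance = 0.02)
})

test_that("covariates reproduce the cohort moments", {
  ped <- simulate_pedigrees(400, seed = 21)  # ~2500 individuals
  cov <- simulate_covariates(ped, seed = 22)
  expect_equal(mean(cov$bmi), 25.88, tolerance = 0.15)
  expect_equal(mean(cov$sbp), 139.71, tolerance = 0.9)
  expect_true(all(cov$age >= 19 & cov$age <= 73))
  expect_true(all(cov$bmi > 0))
  # probands hypertensive by ascertainment; phenotyped prevalence ~ 0.39
  expect_true(all(cov$hypertension[ped$proband] == 1))
  prev <- mean(cov$hypertension[ped$phenotyped])
  expect_equal(prev, 0.39, tolerance = 0.04)
})

test_that("trait spec enforces the variance identity", {
  sp <- trait_spec(h2 = 0.37, total_var = 2.5)
  expect_equal(sp$sigma2_g / (sp$sigma2_g + sp$sigma2_e), 0.37,
               tolerance = 1e-12)
  expect_error(trait_spec(h2 = 1.4), "h2")
})

test_that("simulated traits carry the target genetic variance", {
  ped <- simulate_pedigrees(40, seed = 31)
  kin <- kinship_matrix(ped)
  # h2 = 0: no resemblance between sibs beyond chance
  y0 <- simulate_trait(ped, kin, trait_spec(0), seed = 32)
  sib_pairs <- do.call(rbind, lapply(split(ped, ped$family), function(f) {
    s <- f$id[!f$founder & f$generation == 2]
    if (length(s) >= 2) t(utils::combn(s, 2)) else NULL
  }))
  r0 <- cor(y0[sib_pairs[, 1]], y0[sib_pairs[, 2]])
  expect_lt(abs(r0), 0.15)
  # total variance ~ 1 averaged over replicates
  vars <- vapply(1:60, function(r) {
    var(simulate_trait(ped, kin, trait_spec(0.4, 1), seed = 100 + r))
  }, 0)
  expect_equal(mean(vars), 1, tolerance = 0.05)
  # full-sib correlation at h2 = 0.8 approaches 2*phi*sigma2_g = 0.4
  rs <- vapply(1:80, function(r) {
    y <- simulate_trait(ped, kin, trait_spec(0.8), seed = 200 + r)
    cor(y[sib_pairs[, 1]], y[sib_pairs[, 2]])
  }, 0)
  expect_equal(mean(rs), 0.4, tolerance = 0.05)
})

test_that("flow phantom obeys its profile and is deterministic", {
  prof <- flow_profile(radius_mm = 15, peak_velocity = 1.0, flatten = 2,
                       noise_sd = 0)
  cine <- simulate_flow_series(prof, seed = 1)
  systolic <- cine$frames[[prof$systole_frame]]
  expect_equal(max(systolic), 1.0, tolerance = 1e-6)
  expect_identical(simulate_flow_series(flow_profile(), seed = 3),
                   simulate_flow_series(flow_profile(), seed = 3))
  expect_error(simulate_flow_series(flow_profile(radius_mm = 60)),
               "exceeds")
})

test_that("default cohort phantoms average the calibrated velocities", {
  set.seed(77)
  u_pm <- vapply(1:120, function(i) {
    prof <- flow_profile(
      radius_mm = min(max(rnorm(1, 15.5, 1.7), 8), 19),
      peak_velocity = min(max(rnorm(1, 0.79, 0.10), 0.2), 1.6))
    flow_metrics(simulate_flow_series(prof, seed = i))$u_pm
  }, 0)
  expect_equal(mean(u_pm), 0.450, tolerance = 0.03)
})
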