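test_that("HWE exact test matches hand-enumerated small tables", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_test(0, 2, 0), 1)
  expect_equal(hwe_exact_test(10, 0, 0), 1)  # monomorphic
  expect_equal(hwe_exact_test(0, 0, 7), 1)
  # mid-p is strictly smaller for polymorphic tables
  expect_lt(hwe_exact_test(5, 10, 5, midp = TRUE), hwe_exact_test(5, 10, 5))
})

test_that("HWE exact test agrees with the enumeration oracle", {
  for (n in c(5, 13, 25)) {
    for (n_aa in 0:n) {
      for (n_ab in 0:(n - n_aa)) {
        n_bb <- n - n_aa - n_ab
        expect_equal(hwe_exact_test(n_aa, n_ab, n_bb),
                     hwe_enum_oracle(n_aa, n_ab, n_bb),
                     tolerance = 1e-12,
                     label = sprintf("table (%d,%d,%d)", n_aa, n_ab, n_bb))
      }
    }
  }
})

test_that("HWE rejection rate is nominal for founders in equilibrium", {
  set.seed(42)
  n <- 500
  m <- 1500
  g <- matrix(rbinom(n * m, 2, 0.3), m, n)
  pvals <- apply(g, 1, function(x) {
    hwe_exact_test(sum(x == 2), sum(x == 1), sum(x == 0))
  })
  # exact tests are conservative; rejection should not exceed nominal
  rate <- mean(pvals < 0.05)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / m))
  expect_gt(rate, 0.01)
})

test_that("the crafted 8-SNP fixture retains exactly 4 SNPs", {
  g <- qc_fixture()
  res <- snp_filters(g, qc_thresholds())
  expect_equal(res$counts, c(call_rate = 1, maf = 2, hwe = 1))
  expect_equal(sort(res$kept), paste0("s", 5:8))
})

test_that("disabled thresholds keep every SNP", {
  g <- qc_fixture()
  res <- snp_filters(g, qc_thresholds(snp_call_rate = 0, maf = 0, hwe_p = 0))
  expect_equal(length(res$kept), 8)
})

test_that("boundary conventions: at-threshold values are retained", {
  n <- 100
  g <- matrix(rep(c(0L, 1L), c(90, 10)), 1, n,
              dimnames = list("s1", paste0("i", 1:n)))  # MAF exactly 0.05
  res <- snp_filters(g, qc_thresholds(hwe_p = 0))
  expect_equal(res$kept, "s1")
  # heterozygosity exactly on the window edge is retained ("included")
  set.seed(32)
  gs <- matrix(rbinom(400, 2, 0.5), 20, 20,
               dimnames = list(paste0("s", 1:20), paste0("i", 1:20)))
  het <- colMeans(gs == 1)
  win <- c(min(het), max(het))
  smp <- sample_filters(gs, qc_thresholds(het_window = win))
  expect_equal(length(smp$kept), 20)
})

test_that("sample filters remove no-call individuals and het outliers", {
  ped <- make_ped(paste0("f", 1:60), proband = c(TRUE, rep(FALSE, 59)))
  panel <- simulate_snp_panel(300, seed = 33)
  panel$freq <- rep(0.5, nrow(panel))
  g <- simulate_genotypes(ped, panel, seed = 34)
  g[, 1] <- NA  # individual with no genotypes at all
  smp <- sample_filters(g, qc_thresholds(het_window = c(0.35, 0.65)))
  expect_true("f1" %in% smp$removed$call_rate)
  # founders at p = 0.5 have heterozygosity ~ 0.5: a window far away
  # rejects everyone, which must raise a diagnostic error
  expect_error(sample_filters(g[, -1], qc_thresholds(het_window = c(0.31, 0.33))),
               "excludes every individual")
})

test_that("Mendelian logic flags impossible trios and duos only", {
  ped <- make_ped(c("dad", "mum", "kid"),
                  father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"))
  g <- matrix(c(0L, 0L, 1L,   # AA x AA -> Aa impossible
                0L, 2L, 1L,   # AA x aa -> Aa obligate
                2L, 2L, 2L,   # fine
                0L, 0L, 2L),  # AA x AA -> aa impossible
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("dad", "mum", "kid")))
  mc <- mendel_check(g, ped)
  expect_equal(sort(mc$errors$snp), c("s1", "s4"))
  expect_true(all(is.na(mc$g[c("s1", "s4"), "kid"])))
  # duo: opposite homozygotes are impossible, het parent is not
  ped2 <- make_ped(c("dad", "kid"), father = c(NA, "dad"))
  g2 <- matrix(c(0L, 2L,
                 1L, 2L), nrow = 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("dad", "kid")))
  mc2 <- mendel_check(g2, ped2)
  expect_equal(mc2$errors$snp, "s1")
})

test_that("injected Mendelian errors are exactly the ones flagged", {
  ped <- simulate_pedigrees(30, seed = 41)
  panel <- simulate_snp_panel(300, seed = 42)
  g <- simulate_genotypes(ped, panel, seed = 43)
  expect_equal(mendel_check(g, ped)$n_errors, 0)  # clean by construction
  # corrupt 50 child genotypes to guaranteed-impossible values
  set.seed(44)
  kids <- which(!is.na(ped$father) & ped$generation == 2)
  inj <- data.frame(snp = integer(0), ind = integer(0))
  gg <- g
  while (nrow(inj) < 50) {
    j <- sample(kids, 1)
    i <- sample(nrow(g), 1)
    fa <- g[i, ped$father[j]]
    mo <- g[i, ped$mother[j]]
    if (is.na(fa) || is.na(mo)) next
    lo <- (fa == 2) + (mo == 2)
    hi <- 2 - (fa == 0) - (mo == 0)
    bad_vals <- setdiff(0:2, lo:hi)
    if (!length(bad_vals)) next
    if (any(inj$snp == i & inj$ind == j)) next
    gg[i, j] <- bad_vals[1]
    inj <- rbind(inj, data.frame(snp = i, ind = j))
  }
  mc <- mendel_check(gg, ped)
  got <- paste(mc$errors$snp, mc$errors$child)
  want <- paste(rownames(g)[inj$snp], ped$id[inj$ind])
  expect_setequal(got, want)
  expect_equal(mc$n_errors, 50)
})

test_that("run_qc accounts for every SNP and individual", {
  ped <- simulate_pedigrees(25, seed = 51)
  panel <- simulate_snp_panel(250, seed = 52)
  g <- simulate_genotypes(ped, panel, missing_rate = 0.02, seed = 53)
  rep_ <- run_qc(g, ped)
  st <- rep_$stages$initial
  expect_equal(length(rep_$kept_snps) +
                 sum(vapply(rep_$stages, function(s) sum(s$snp), 0)),
               nrow(g))
  expect_lte(length(rep_$kept_samples), ncol(g))
  # retained matrix is consistent with the registries
  expect_equal(dim(rep_$g), c(length(rep_$kept_snps),
                              length(rep_$kept_samples)))
})
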