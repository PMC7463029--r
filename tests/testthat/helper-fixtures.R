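# Hand-built pedigrees and small generators shared across test files.

# minimal pedigree constructor: father/mother NA for founders
make_ped <- function(id, father = NA, mother = NA, sex = "male",
                     family = "FAM1", proband = NULL, phenotyped = TRUE) {
  n <- length(id)
  founder <- is.na(rep_len(father, n)) & is.na(rep_len(mother, n))
  if (is.null(proband)) proband <- c(TRUE, rep(FALSE, n - 1))
  data.frame(family = rep_len(family, n), id = id,
             father = rep_len(father, n), mother = rep_len(mother, n),
             sex = rep_len(sex, n), founder = founder,
             generation = NA_integer_,
             proband = proband, phenotyped = rep_len(phenotyped, n),
             genotyped = TRUE, stringsAsFactors = FALSE)
}

# nuclear family: two founder parents and k full sibs
nuclear_ped <- function(k = 2, family = "FAM1") {
  ids <- paste0(family, "_", seq_len(2 + k))
  make_ped(ids,
           father = c(NA, NA, rep(ids[1], k)),
           mother = c(NA, NA, rep(ids[2], k)),
           sex = c("male", "female", rep(c("male", "female"), length.out = k)),
           family = family)
}

# three-generation pedigree containing parent-offspring, full sibs,
# half sibs and first cousins:
#   gp1 x gp2 -> p1, p2 (full sibs); p1 x s1 -> c1; p2 x s2 -> c2
#   (c1, c2 first cousins); s1 x p2 -> h1 (half sib of c2)
relatives_ped <- function() {
  id <- c("gp1", "gp2", "p1", "p2", "s1", "s2", "c1", "c2", "h1")
  father <- c(NA, NA, "gp1", "gp1", NA, NA, "p1", "p2", "p2")
  mother <- c(NA, NA, "gp2", "gp2", NA, NA, "s1", "s2", "s1")
  sex <- c("male", "female", "male", "male", "female", "female",
           "male", "female", "male")
  make_ped(id, father, mother, sex)
}

# dense multivariate-normal log-likelihood, used as the independent oracle
# for vc_loglik and the variance-components fits
dense_mvn_ll <- function(y, mu, omega) {
  n <- length(y)
  r <- y - mu
  -0.5 * (n * log(2 * pi) + determinant(omega)$modulus[1] +
            drop(t(r) %*% solve(omega, r)))
}

# brute-force profile ML over a (h2, total variance) grid with the GLS
# mean at each grid point, evaluated densely (independent of the package's
# eigen-based path)
grid_ml_oracle <- function(y, K, h2_grid = seq(0, 0.995, length.out = 200),
                           s2_grid = NULL) {
  if (is.null(s2_grid)) s2_grid <- seq(0.05, 4 * var(y), length.out = 200)
  n <- length(y)
  ones <- rep(1, n)
  best <- -Inf
  best_par <- c(NA, NA)
  for (h2 in h2_grid) {
    S <- h2 * K + (1 - h2) * diag(n)
    Si <- solve(S)
    mu <- drop(t(ones) %*% Si %*% y) / drop(t(ones) %*% Si %*% ones)
    for (s2 in s2_grid) {
      ll <- dense_mvn_ll(y, mu, s2 * S)
      if (ll > best) {
        best <- ll
        best_par <- c(h2, s2)
      }
    }
  }
  list(loglik = best, h2 = best_par[1], s2 = best_par[2])
}

# brute-force restricted likelihood on a grid, dense matrix algebra
grid_reml_oracle <- function(y, A, X = NULL,
                             h2_grid = seq(0.001, 0.999, length.out = 200),
                             s2_grid = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  p <- ncol(X)
  if (is.null(s2_grid)) s2_grid <- seq(0.05, 4 * var(y), length.out = 200)
  best <- -Inf
  best_par <- c(NA, NA)
  for (h2 in h2_grid) {
    for (s2 in s2_grid) {
      V <- s2 * (h2 * A + (1 - h2) * diag(n)) + 1e-8 * diag(n)
      if (inherits(tryCatch(chol(V), error = identity), "error")) next
      Vi <- solve(V)
      XtViX <- t(X) %*% Vi %*% X
      beta <- solve(XtViX, t(X) %*% Vi %*% y)
      r <- y - X %*% beta
      ll <- -0.5 * (determinant(V)$modulus[1] +
                      determinant(XtViX)$modulus[1] +
                      drop(t(r) %*% Vi %*% r) + (n - p) * log(2 * pi))
      if (ll > best) {
        best <- ll
        best_par <- c(h2, s2)
      }
    }
  }
  list(loglik = best, h2 = best_par[1], s2 = best_par[2])
}

# drop SNPs that became monomorphic in a small simulated sample
drop_mono <- function(g) {
  p <- allele_freq(g)
  g[p > 0 & p < 1, , drop = FALSE]
}

# 8-SNP fixture: SNP1 fails call rate (0.95), SNPs 2-3 fail MAF at 0.05,
# SNP4 fails HWE at 1e-8, SNPs 5-8 pass everything.
qc_fixture <- function() {
  n <- 100
  g <- matrix(0L, 8, n, dimnames = list(paste0("s", 1:8),
                                        paste0("i", 1:n)))
  set.seed(31)
  g[1, ] <- rbinom(n, 2, 0.3)
  g[1, 1:10] <- NA                      # call rate 0.90 < 0.95
  g[2, ] <- 0L; g[2, 1:4] <- 1L         # MAF 0.02 < 0.05
  g[3, ] <- 2L; g[3, 1:2] <- 1L         # MAF 0.01 < 0.05
  g[4, ] <- c(rep(0L, 50), rep(2L, 50)) # no hets at p = 0.5: HWE p << 1e-8
  g[5, ] <- rbinom(n, 2, 0.5)
  g[6, ] <- rbinom(n, 2, 0.3)
  g[7, ] <- rbinom(n, 2, 0.4)
  g[8, ] <- rbinom(n, 2, 0.25)
  g
}

# enumeration oracle for the Hardy-Weinberg exact test, written with
# choose() arithmetic (a different route than the package's log-factorial
# implementation)
hwe_enum_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n1 <- 2 * n_aa + n_ab
  nm <- min(n1, 2 * n - n1)
  if (nm == 0) return(1)
  hets <- seq(nm %% 2, nm, by = 2)
  probs <- sapply(hets, function(h) {
    hom_min <- (nm - h) / 2
    hom_maj <- n - h - hom_min
    # multinomial genotype count x 2^h over the allele-count multiset
    exp(lchoose(n, h) + lchoose(n - h, hom_min) + h * log(2) -
          (lchoose(2 * n, nm)))
  })
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, hets)]
  sum(probs[probs <= p_obs * (1 + 1e-10)])
}
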