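#' Specification of a simulated heritable trait
#'
#' Fixes the additive genetic and environmental variances of a quantitative
#' trait. Narrow-sense heritability is `h2 = sigma2_g / (sigma2_g +
#' sigma2_e)`; either supply `h2` together with the total variance, or the
#' two components directly.
#'
#' @param h2 Target narrow-sense heritability in [0, 1].
#' @param total_var Total trait variance (genetic + environmental).
#' @param sigma2_g,sigma2_e Variance components; override `h2`/`total_var`
#'   when both are given.
#' @param beta Named numeric vector of covariate effects added to the trait
#'   (names must match covariate-table columns).
#' @param mode `"kinship"` draws the genetic value from a multivariate
#'   normal with covariance `2*Phi*sigma2_g`; `"causal"` sums effects of
#'   randomly chosen causal SNPs rescaled to `sigma2_g`.
#' @param n_causal Number of causal SNPs in `"causal"` mode.
#'
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(h2 = 0.4, total_var = 1,
                       sigma2_g = NULL, sigma2_e = NULL,
                       beta = NULL, mode = c("kinship", "causal"),
                       n_causal = 100) {
  mode <- match.arg(mode)
  if (is.null(sigma2_g) || is.null(sigma2_e)) {
    stopifnot(h2 >= 0, h2 <= 1, total_var > 0)
    sigma2_g <- h2 * total_var
    sigma2_e <- (1 - h2) * total_var
  }
  stopifnot(sigma2_g >= 0, sigma2_e >= 0, sigma2_g + sigma2_e > 0)
  h2 <- sigma2_g / (sigma2_g + sigma2_e)
  spec <- list(h2 = h2, sigma2_g = sigma2_g, sigma2_e = sigma2_e,
               beta = beta, mode = mode, n_causal = n_causal)
  stopifnot(abs(spec$h2 - sigma2_g / (sigma2_g + sigma2_e)) < 1e-12)
  class(spec) <- "trait_spec"
  spec
}

#' Simulate a quantitative trait with known heritability
#'
#' Generates `y = X beta + g + e` where the polygenic value `g` has
#' covariance `2 Phi sigma2_g` (drawn per family block from the pedigree
#' kinship matrix) or, in causal-SNP mode, is a weighted sum of genotype
#' dosages rescaled to variance `sigma2_g`; `e` is iid Normal(0, sigma2_e).
#'
#' @param ped A `pedigree` data frame.
#' @param kinship Kinship matrix `Phi` over `ped$id` (see
#'   [kinship_matrix()]); required in `"kinship"` mode.
#' @param spec A [trait_spec()].
#' @param covariates Optional `covariate_table` supplying the columns named
#'   in `spec$beta`.
#' @param genotypes Dosage matrix (SNPs x individuals) for `"causal"` mode.
#' @param seed Integer seed.
#'
#' @return Named numeric vector of trait values for every pedigree member.
#' @export
simulate_trait <- function(ped, kinship = NULL, spec = trait_spec(),
                           covariates = NULL, genotypes = NULL, seed = NULL) {
  n <- nrow(ped)
  with_seed(seed, {
    g <- if (spec$mode == "kinship") {
      if (is.null(kinship)) stop("kinship matrix required in kinship mode")
      draw_polygenic(ped, kinship, spec$sigma2_g)
    } else {
      if (is.null(genotypes)) stop("genotypes required in causal mode")
      draw_causal(genotypes, ped$id, spec$sigma2_g, spec$n_causal)
    }
    e <- rnorm(n, 0, sqrt(spec$sigma2_e))
    y <- g + e
    if (!is.null(spec$beta)) {
      if (is.null(covariates)) stop("covariates required when beta is set")
      cv <- covariates[match(ped$id, covariates$id), , drop = FALSE]
      for (nm in names(spec$beta)) {
        y <- y + spec$beta[[nm]] * cv[[nm]]
      }
    }
    names(y) <- ped$id
    y
  })
}

draw_polygenic <- function(ped, kinship, sigma2_g) {
  g <- numeric(nrow(ped))
  if (sigma2_g == 0) return(g)
  kin_ids <- rownames(kinship)
  for (f in unique(ped$family)) {
    ids <- ped$id[ped$family == f]
    K <- 2 * kinship[match(ids, kin_ids), match(ids, kin_ids), drop = FALSE]
    L <- tryCatch(chol(K), error = function(e) {
      ev <- eigen(K, symmetric = TRUE)
      if (min(ev$values) < -1e-8) {
        stop("2*Phi is not positive semi-definite for family ", f)
      }
      # PSD but singular: use the symmetric square root
      v <- pmax(ev$values, 0)
      return(t(ev$vectors %*% (t(ev$vectors) * sqrt(v))))
    })
    z <- rnorm(length(ids))
    g[ped$family == f] <- sqrt(sigma2_g) * drop(t(L) %*% z)
  }
  g
}

draw_causal <- function(genotypes, ids, sigma2_g, n_causal) {
  g <- genotypes[, match(ids, colnames(genotypes)), drop = FALSE]
  m <- nrow(g)
  causal <- sample.int(m, min(n_causal, m))
  b <- rnorm(length(causal))
  gc <- g[causal, , drop = FALSE]
  gc[is.na(gc)] <- 0
  gv <- drop(crossprod(gc, b))
  s <- stats::sd(gv)
  if (s == 0) return(numeric(length(ids)))
  (gv - mean(gv)) / s * sqrt(sigma2_g)
}
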