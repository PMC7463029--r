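#' Simulate a biallelic SNP panel
#'
#' Produces SNP metadata (chromosome, position, alleles) and founder allele
#' frequencies for the alternative allele A1. Positions are strictly
#' increasing within each chromosome; frequencies are drawn uniformly on a
#' configurable open interval so every simulated SNP is polymorphic among
#' founders.
#'
#' @param m Number of SNPs.
#' @param n_chrom Number of autosomes the SNPs are spread across.
#' @param freq_range Range for the founder A1 allele frequency `p_i`.
#' @param seed Integer seed.
#'
#' @return A `data.frame` of class `snp_panel` with columns `snp`, `chrom`,
#'   `pos`, `a1`, `a2`, `freq`.
#' @export
simulate_snp_panel <- function(m, n_chrom = 22, freq_range = c(0.05, 0.5),
                               seed = NULL) {
  stopifnot(m >= 1, freq_range[1] > 0, freq_range[2] < 1)
  with_seed(seed, {
    chrom <- sort(sample.int(n_chrom, m, replace = TRUE))
    pos <- integer(m)
    for (cc in unique(chrom)) {
      k <- sum(chrom == cc)
      pos[chrom == cc] <- cumsum(sample.int(50000L, k, replace = TRUE))
    }
    alleles <- c("A", "C", "G", "T")
    a1 <- sample(alleles, m, replace = TRUE)
    a2 <- vapply(a1, function(a) sample(setdiff(alleles, a), 1L), "")
    panel <- data.frame(snp = sprintf("snp%06d", seq_len(m)),
                        chrom = chrom, pos = pos, a1 = a1, a2 = a2,
                        freq = runif(m, freq_range[1], freq_range[2]),
                        stringsAsFactors = FALSE)
    class(panel) <- c("snp_panel", "data.frame")
    panel
  })
}

#' Gene-drop genotypes through a pedigree
#'
#' Founders receive two independent Bernoulli(`p_i`) allele copies per SNP
#' (Hardy-Weinberg proportions); each non-founder inherits one allele from
#' each parent, chosen uniformly at random per SNP and per meiosis
#' (classical gene dropping). SNPs are transmitted independently (no
#' linkage). Dosage counts copies of the A1 allele.
#'
#' @param ped A `pedigree` data frame ([simulate_pedigrees()]).
#' @param panel A `snp_panel` ([simulate_snp_panel()]).
#' @param missing_rate Fraction of entries set missing completely at random.
#' @param seed Integer seed.
#'
#' @return An integer matrix of dosages in \{0, 1, 2, NA\}, SNPs in rows
#'   (named by `panel$snp`), individuals in columns (named by `ped$id`).
#' @export
simulate_genotypes <- function(ped, panel, missing_rate = 0, seed = NULL) {
  if (nrow(panel) < 1) stop("panel must contain at least one SNP")
  stopifnot(missing_rate >= 0, missing_rate < 1)
  m <- nrow(panel)
  n <- nrow(ped)
  ord <- topo_order(ped$id, ped$father, ped$mother)
  idx <- seq_len(n)
  names(idx) <- ped$id
  with_seed(seed, {
    h1 <- matrix(0L, m, n)  # paternal allele copy
    h2 <- matrix(0L, m, n)  # maternal allele copy
    p <- panel$freq
    for (j in ord) {
      fa <- ped$father[j]
      mo <- ped$mother[j]
      if (is.na(fa) && is.na(mo)) {
        h1[, j] <- rbinom(m, 1L, p)
        h2[, j] <- rbinom(m, 1L, p)
      } else {
        h1[, j] <- if (is.na(fa)) rbinom(m, 1L, p) else
          transmit(h1[, idx[fa]], h2[, idx[fa]])
        h2[, j] <- if (is.na(mo)) rbinom(m, 1L, p) else
          transmit(h1[, idx[mo]], h2[, idx[mo]])
      }
    }
    g <- h1 + h2
    if (missing_rate > 0) {
      g[runif(length(g)) < missing_rate] <- NA_integer_
    }
    dimnames(g) <- list(panel$snp, ped$id)
    g
  })
}

# one meiosis: pick one of the parent's two allele copies per SNP
transmit <- function(a, b) {
  pick <- runif(length(a)) < 0.5
  ifelse(pick, a, b)
}

#' Observed allele frequency of the A1 allele
#'
#' @param g Dosage matrix (SNPs x individuals) with NA for missing.
#' @return Numeric vector of per-SNP sample frequencies.
#' @export
allele_freq <- function(g) {
  rowMeans(g, na.rm = TRUE) / 2
}
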