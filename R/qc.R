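#' Genotype quality-control thresholds
#'
#' PLINK-style thresholds. SNPs are removed when their call rate falls
#' below `snp_call_rate`, their minor allele frequency is strictly below
#' `maf`, or their Hardy-Weinberg exact p-value is strictly below `hwe_p`;
#' individuals are removed when their call rate falls below
#' `sample_call_rate` or their mean heterozygosity lies outside
#' `het_window` (boundaries included, i.e. retained). A two-stage run uses
#' `maf_initial` first (the pre-imputation 1\% filter) and `maf` in the
#' final stage.
#'
#' @param snp_call_rate Minimum per-SNP call rate (default 0.95).
#' @param sample_call_rate Minimum per-individual call rate (default 0.95).
#' @param maf Final-stage minor-allele-frequency minimum (default 0.05).
#' @param maf_initial Initial-stage MAF minimum (default 0.01).
#' @param hwe_p Hardy-Weinberg exact-test p-value minimum (default 1e-8).
#' @param het_window Length-2 inclusive heterozygosity retention window, or
#'   NULL to use mean +/- 3 SD of the observed distribution.
#' @param hwe_founders_only Test HWE in founders only (relatives inflate
#'   rejection rates); set FALSE to use all samples.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_call_rate = 0.95, sample_call_rate = 0.95,
                          maf = 0.05, maf_initial = 0.01, hwe_p = 1e-8,
                          het_window = NULL, hwe_founders_only = TRUE) {
  vals <- c(snp_call_rate, sample_call_rate, maf, maf_initial, hwe_p)
  stopifnot(all(vals >= 0), all(vals <= 1))
  if (!is.null(het_window)) {
    stopifnot(length(het_window) == 2, het_window[1] <= het_window[2])
  }
  structure(list(snp_call_rate = snp_call_rate,
                 sample_call_rate = sample_call_rate,
                 maf = maf, maf_initial = maf_initial, hwe_p = hwe_p,
                 het_window = het_window,
                 hwe_founders_only = hwe_founders_only),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the sum of probabilities of all heterozygote counts whose conditional
#' probability (hypergeometric-type distribution of heterozygotes given
#' allele counts) does not exceed that of the observed configuration.
#' Monomorphic tables return 1. The mid-p variant halves the contribution
#' of the observed configuration.
#'
#' @param n_aa Count of A1/A1 homozygotes.
#' @param n_ab Count of heterozygotes.
#' @param n_bb Count of A2/A2 homozygotes.
#' @param midp Use the mid-p variant.
#' @return Exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(1, 0, 1)  # 1/3
hwe_exact_test <- function(n_aa, n_ab, n_bb, midp = FALSE) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("at least one genotype is required")
  n1 <- 2 * n_aa + n_ab          # copies of allele A1
  nm <- min(n1, 2 * n - n1)      # minor allele count
  if (nm == 0) return(1)         # monomorphic
  hets <- seq(nm %% 2, nm, by = 2)
  # log P(het = h | allele counts), up to a common constant
  lp <- vapply(hets, function(h) {
    hom1 <- (nm - h) / 2
    hom2 <- n - h - hom1
    h * log(2) - lfactorial(hom1) - lfactorial(h) - lfactorial(hom2)
  }, 0)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- match(min(n_ab, nm), hets)
  if (is.na(obs)) stop("inconsistent genotype counts")
  p_obs <- pr[obs]
  p <- sum(pr[pr <= p_obs * (1 + 1e-10)])
  if (midp) p <- p - 0.5 * p_obs
  min(p, 1)
}

#' Per-SNP filters: call rate, MAF, Hardy-Weinberg
#'
#' Applies the SNP-level filters in fixed order: call rate first, then
#' minor allele frequency computed on the currently retained individuals,
#' then the Hardy-Weinberg exact test (in founders only by default).
#' Boundary convention follows PLINK: strict `<` removes, so a SNP exactly
#' at the threshold is kept.
#'
#' @param g Dosage matrix (SNPs x individuals).
#' @param thresholds A [qc_thresholds()] object.
#' @param founder_ids Character vector of founder ids for the HWE test;
#'   defaults to all individuals when NULL or when
#'   `thresholds$hwe_founders_only` is FALSE.
#' @param maf Overrides `thresholds$maf` (used for the two-stage run).
#' @return A list: `kept` (SNP names), `removed` (named list per filter),
#'   `counts` (removed per filter).
#' @export
snp_filters <- function(g, thresholds = qc_thresholds(),
                        founder_ids = NULL, maf = thresholds$maf) {
  stopifnot(nrow(g) > 0, ncol(g) > 0)
  snps <- rownames(g) %||% as.character(seq_len(nrow(g)))
  call_rate <- rowMeans(!is.na(g))
  fail_cr <- call_rate < thresholds$snp_call_rate
  keep <- !fail_cr
  p <- allele_freq(g[keep, , drop = FALSE])
  mafs <- pmin(p, 1 - p)
  fail_maf_sub <- mafs < maf
  fail_maf <- setNames(rep(FALSE, nrow(g)), snps)
  fail_maf[which(keep)[fail_maf_sub]] <- TRUE
  keep <- keep & !fail_maf
  hw_g <- g
  if (thresholds$hwe_founders_only && !is.null(founder_ids)) {
    hw_g <- g[, colnames(g) %in% founder_ids, drop = FALSE]
  }
  fail_hwe <- rep(FALSE, nrow(g))
  for (i in which(keep)) {
    x <- hw_g[i, ]
    x <- x[!is.na(x)]
    if (!length(x)) next
    pv <- hwe_exact_test(sum(x == 2), sum(x == 1), sum(x == 0))
    fail_hwe[i] <- pv < thresholds$hwe_p
  }
  keep <- keep & !fail_hwe
  list(kept = snps[keep],
       removed = list(call_rate = snps[fail_cr],
                      maf = snps[fail_maf],
                      hwe = snps[fail_hwe]),
       counts = c(call_rate = sum(fail_cr), maf = sum(fail_maf),
                  hwe = sum(fail_hwe)))
}

#' Per-individual filters: call rate and heterozygosity window
#'
#' Removes individuals whose genotype call rate over the retained SNPs is
#' below threshold, then individuals whose mean heterozygosity (fraction
#' of non-missing genotypes that are heterozygous) falls outside the
#' retention window. Window boundaries are retained. When no window is
#' configured, mean +/- 3 SD of the observed heterozygosity distribution
#' is used.
#'
#' @param g Dosage matrix after SNP filters (SNPs x individuals).
#' @param thresholds A [qc_thresholds()] object.
#' @return A list: `kept` (ids), `removed` (per filter), `counts`,
#'   `het` (per-individual heterozygosity), `window` (the window applied).
#' @export
sample_filters <- function(g, thresholds = qc_thresholds()) {
  ids <- colnames(g) %||% as.character(seq_len(ncol(g)))
  call_rate <- colMeans(!is.na(g))
  fail_cr <- call_rate < thresholds$sample_call_rate
  het <- colMeans(g == 1, na.rm = TRUE)
  het[is.nan(het)] <- NA_real_
  window <- thresholds$het_window
  if (is.null(window)) {
    mu <- mean(het[!fail_cr], na.rm = TRUE)
    s <- sd(het[!fail_cr], na.rm = TRUE)
    window <- c(mu - 3 * s, mu + 3 * s)
  }
  fail_het <- !fail_cr & (is.na(het) | het < window[1] | het > window[2])
  keep <- !fail_cr & !fail_het
  if (!any(keep)) {
    hist_txt <- paste(utils::capture.output(print(summary(het))),
                      collapse = "\n")
    stop("heterozygosity window [", window[1], ", ", window[2],
         "] excludes every individual; observed distribution:\n", hist_txt)
  }
  list(kept = ids[keep],
       removed = list(call_rate = ids[fail_cr], heterozygosity = ids[fail_het]),
       counts = c(call_rate = sum(fail_cr), heterozygosity = sum(fail_het)),
       het = setNames(het, ids), window = window)
}

#' Mendelian-inconsistency detection
#'
#' Flags genotype configurations impossible under biallelic inheritance in
#' parent-offspring trios and duos: a child must receive exactly one
#' allele from each genotyped parent (a duo is impossible only for
#' opposite homozygotes). Checks are iterated — flagged genotypes are set
#' missing and the scan repeats until no new error appears — which
#' propagates errors through multi-generation pedigrees as an
#' approximation to a full multigenerational check.
#'
#' @param g Dosage matrix (SNPs x individuals).
#' @param ped Pedigree data frame.
#' @return A list: `errors` (data.frame with `snp`, `child`, `father`,
#'   `mother`), `g` (the matrix with flagged genotypes set missing),
#'   `n_errors`.
#' @export
mendel_check <- function(g, ped) {
  ids <- colnames(g)
  err <- list()
  gg <- g
  kids <- which(!is.na(ped$father) | !is.na(ped$mother))
  repeat {
    new_err <- 0L
    for (j in kids) {
      cid <- ped$id[j]
      ci <- match(cid, ids)
      if (is.na(ci)) next
      fi <- match(ped$father[j], ids)
      mi <- match(ped$mother[j], ids)
      cv <- gg[, ci]
      fv <- if (!is.na(fi)) gg[, fi] else rep(NA_integer_, nrow(gg))
      mv <- if (!is.na(mi)) gg[, mi] else rep(NA_integer_, nrow(gg))
      bad <- mendel_impossible(cv, fv, mv)
      if (any(bad)) {
        new_err <- new_err + sum(bad)
        err[[length(err) + 1L]] <- data.frame(
          snp = rownames(gg)[bad], child = cid,
          father = ped$father[j] %||% NA_character_,
          mother = ped$mother[j] %||% NA_character_,
          stringsAsFactors = FALSE)
        gg[bad, ci] <- NA_integer_
      }
    }
    if (new_err == 0L) break
  }
  errors <- if (length(err)) do.call(rbind, err) else
    data.frame(snp = character(0), child = character(0),
               father = character(0), mother = character(0),
               stringsAsFactors = FALSE)
  list(errors = errors, g = gg, n_errors = nrow(errors))
}

# vectorised over SNPs: TRUE where the child's genotype cannot arise from
# the (available) parental genotypes
mendel_impossible <- function(child, father, mother) {
  bad <- rep(FALSE, length(child))
  known_c <- !is.na(child)
  # allele each parent can transmit: dosage 0 -> only 0; 2 -> only 1; 1/NA -> either
  f_min <- ifelse(is.na(father), 0L, ifelse(father == 2L, 1L, 0L))
  f_max <- ifelse(is.na(father), 1L, ifelse(father == 0L, 0L, 1L))
  m_min <- ifelse(is.na(mother), 0L, ifelse(mother == 2L, 1L, 0L))
  m_max <- ifelse(is.na(mother), 1L, ifelse(mother == 0L, 0L, 1L))
  lo <- f_min + m_min
  hi <- f_max + m_max
  bad[known_c] <- child[known_c] < lo[known_c] | child[known_c] > hi[known_c]
  bad
}

#' Run the full quality-control sequence
#'
#' Applies the declared filter order — SNP call rate, MAF, HWE, sample
#' call rate, heterozygosity window, Mendelian check — as a two-stage run
#' mirroring a pre-imputation stage (MAF >= `maf_initial`) followed by the
#' final stage (MAF >= `maf`). Each stage logs per-filter removal counts.
#'
#' @param g Dosage matrix (SNPs x individuals).
#' @param ped Pedigree data frame covering the genotyped individuals.
#' @param thresholds A [qc_thresholds()] object.
#' @param two_stage Run the initial (1\% MAF) stage before the final one.
#' @return A list of class `qc_report`: `g` (filtered matrix with
#'   Mendelian errors blanked), `kept_snps`, `kept_samples`, `stages`
#'   (per-stage counts), `mendel_errors`.
#' @export
run_qc <- function(g, ped, thresholds = qc_thresholds(), two_stage = TRUE) {
  founder_ids <- ped$id[ped$founder]
  stages <- list()
  stage_mafs <- if (two_stage) c(initial = thresholds$maf_initial,
                                 final = thresholds$maf)
                else c(final = thresholds$maf)
  mend <- NULL
  for (sn in names(stage_mafs)) {
    sf <- snp_filters(g, thresholds, founder_ids, maf = stage_mafs[[sn]])
    g <- g[sf$kept, , drop = FALSE]
    smp <- sample_filters(g, thresholds)
    g <- g[, smp$kept, drop = FALSE]
    mend <- mendel_check(g, ped[ped$id %in% smp$kept, , drop = FALSE])
    g <- mend$g
    stages[[sn]] <- list(snp = sf$counts, sample = smp$counts,
                         mendel = mend$n_errors,
                         het_window = smp$window)
  }
  structure(list(g = g, kept_snps = rownames(g), kept_samples = colnames(g),
                 stages = stages, mendel_errors = mend$errors,
                 thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", length(x$kept_snps), "SNPs x",
      length(x$kept_samples), "individuals retained\n")
  for (sn in names(x$stages)) {
    st <- x$stages[[sn]]
    cat(sprintf("  stage %s: snp removals [call_rate %d, maf %d, hwe %d], sample removals [call_rate %d, het %d], mendel errors %d\n",
                sn, st$snp[["call_rate"]], st$snp[["maf"]], st$snp[["hwe"]],
                st$sample[["call_rate"]], st$sample[["heterozygosity"]],
                st$mendel))
  }
  invisible(x)
}
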