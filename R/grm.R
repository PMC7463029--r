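#' Genetic relationship matrix from SNP dosages
#'
#' Realised additive relationships estimated from genotype dosages, using
#' the GCTA conventions: off-diagonal
#' `A_jk = (1/m_jk) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' over the SNPs non-missing in both individuals, and diagonal
#' `A_jj = 1 + (1/m_j) * sum_i (x_ij^2 - (1 + 2 p_i) x_ij + 2 p_i^2) /
#' (2 p_i (1 - p_i))`. Allele frequencies are the sample frequencies.
#' Missingness is handled by pairwise-complete SNP counts, not imputation.
#'
#' @param g Post-QC dosage matrix (SNPs x individuals); every SNP must be
#'   polymorphic.
#' @return A list of class `grm`: `A` (n x n), `N` (pairwise SNP counts),
#'   `ids`, `m` (number of SNPs).
#' @export
compute_grm <- function(g) {
  stopifnot(nrow(g) >= 1, ncol(g) >= 2)
  p <- allele_freq(g)
  mono <- which(!is.finite(p) | p <= 0 | p >= 1)
  if (length(mono)) {
    stop("monomorphic SNP encountered: ",
         paste(head(rownames(g)[mono], 5), collapse = ", "),
         " (QC must remove monomorphic SNPs before GRM construction)")
  }
  denom <- 2 * p * (1 - p)
  w <- (g - 2 * p) / sqrt(denom)
  obs <- !is.na(g)
  w[!obs] <- 0
  num <- crossprod(w)                       # n x n sums of products
  counts <- crossprod(obs * 1)              # pairwise-complete SNP counts
  A <- num / counts
  # GCTA diagonal with the 1 + ... correction
  diag_terms <- (g^2 - (1 + 2 * p) * g + 2 * p^2) / denom
  diag_terms[!obs] <- 0
  m_j <- colSums(obs)
  diag(A) <- 1 + colSums(diag_terms) / m_j
  ids <- colnames(g) %||% as.character(seq_len(ncol(g)))
  dimnames(A) <- list(ids, ids)
  structure(list(A = A, N = counts, ids = ids, m = nrow(g)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d individuals, %d SNPs; mean diagonal %.4f, mean off-diagonal %.5f\n",
              length(x$ids), x$m, mean(diag(x$A)),
              mean(x$A[upper.tri(x$A)])))
  invisible(x)
}
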