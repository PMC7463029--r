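#' Mixed-linear-model association scan
#'
#' Per-SNP association test under the polygenic mixed model: the variance
#' components of `V = A sigma2_g + I sigma2_e` are estimated once under
#' the null (no candidate SNP) by [ai_reml()] and held fixed for every
#' SNP; each SNP effect is then the generalised-least-squares estimate in
#' `y = mu + beta x + g + e`, tested with a Wald chi-squared(1) statistic.
#' SNPs with p below the genome-wide threshold (5e-8) are flagged.
#' Missing dosages are mean-imputed for the scan only; zero-variance SNPs
#' are skipped with NA results.
#'
#' @param y Trait vector (named by individual id).
#' @param g Dosage matrix (SNPs x individuals) covering `names(y)`.
#' @param grm A `grm` object (or relationship matrix) for the polygenic
#'   covariance; may cover a superset of `names(y)`.
#' @param covariates Optional numeric matrix of fixed covariates.
#' @param fit Optional pre-computed null `vc_fit` from [ai_reml()]
#'   (skips re-estimation).
#' @param gw_threshold Genome-wide significance threshold.
#' @return A `data.frame` of class `assoc_result`: `snp`, `beta`, `se`,
#'   `chisq`, `p`, `genome_wide`; attributes `lambda_gc` (genomic-control
#'   inflation factor, median chi-squared / 0.4549) and `fit`.
#' @export
mlma_scan <- function(y, g, grm, covariates = NULL, fit = NULL,
                      gw_threshold = 5e-8) {
  ids <- names(y)
  keep <- is.finite(y)
  y <- y[keep]
  ids <- ids[keep]
  n <- length(y)
  G <- g[, ids, drop = FALSE]
  if (is.null(fit)) {
    X0 <- cbind(intercept = rep(1, n), covariates)
    fit <- ai_reml(y, grm, X = if (is.null(covariates)) NULL else X0)
  }
  A <- if (inherits(grm, "grm")) grm$A else grm
  A <- A[ids, ids, drop = FALSE]
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
  w <- 1 / (fit$sigma2_g * ev$values + fit$sigma2_e)
  U <- ev$vectors
  ty <- drop(crossprod(U, y))
  X0 <- cbind(intercept = rep(1, n), covariates)
  tX0 <- crossprod(U, X0)
  # project the candidate out of the null design under the GLS metric:
  # beta_x = x'My / x'Mx with M = V^-1 - V^-1 X0 (X0'V^-1 X0)^-1 X0'V^-1
  XtVX_inv <- solve(crossprod(tX0, tX0 * w))
  My <- ty * w - (tX0 * w) %*% (XtVX_inv %*% crossprod(tX0, ty * w))
  xmat <- t(G)                      # n x m
  if (anyNA(xmat)) {
    cm <- colMeans(xmat, na.rm = TRUE)
    nas <- which(is.na(xmat), arr.ind = TRUE)
    xmat[nas] <- cm[nas[, 2]]
  }
  txm <- crossprod(U, xmat)          # n x m rotated dosages
  xMy <- drop(crossprod(txm, My))
  # x'Mx = x'V^-1 x - (X0'V^-1 x)' (X0'V^-1 X0)^-1 (X0'V^-1 x)
  xVx <- colSums(txm^2 * w)
  B <- crossprod(tX0, txm * w)       # p x m
  xMx <- xVx - colSums(B * (XtVX_inv %*% B))
  beta <- xMy / xMx
  se <- sqrt(1 / xMx)
  chisq <- beta^2 * xMx
  zero_var <- apply(xmat, 2, function(v) var(v) == 0)
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance SNP(s) skipped")
    beta[zero_var] <- NA
    se[zero_var] <- NA
    chisq[zero_var] <- NA
  }
  p <- pchisq(chisq, 1, lower.tail = FALSE)
  out <- data.frame(snp = rownames(G) %||% as.character(seq_len(nrow(G))),
                    beta = beta, se = se, chisq = chisq, p = p,
                    genome_wide = !is.na(p) & p < gw_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "lambda_gc") <- median(chisq, na.rm = TRUE) /
    stats::qchisq(0.5, 1)
  attr(out, "fit") <- fit
  class(out) <- c("assoc_result", "data.frame")
  out
}
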