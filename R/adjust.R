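#' Stepwise covariate selection for a trait
#'
#' Bidirectional stepwise multiple linear regression: at each step the
#' candidate with the smallest partial-test p-value below `p_enter` is
#' added, then any included covariate whose partial p-value has risen to
#' `p_remove` or above is dropped; the procedure stops when neither move
#' changes the model. Collinear candidates (aliased in the fit) are dropped
#' with a warning.
#'
#' @param y Numeric trait vector.
#' @param candidates `data.frame` of candidate covariates (numeric or 0/1
#'   coded), rows aligned with `y`. Typically age, age^2, sex, BMI,
#'   systolic BP and hypertension status.
#' @param p_enter Entry threshold (covariate enters when partial p <
#'   `p_enter`).
#' @param p_remove Removal threshold (covariate leaves when partial p >=
#'   `p_remove`). The default matches the entry threshold; classical
#'   stepwise software often uses 0.10.
#' @param centre_age When a column named `age` is present and a column
#'   `age2` is derived from it, recompute `age2` from centred age to curb
#'   collinearity between the linear and quadratic terms.
#'
#' @return A list of class `adjustment_model`: `covariates` (in entry
#'   order), `fit` (the final `lm`), `coefficients`, `p_enter`, `p_remove`,
#'   `data` (the candidate columns actually used).
#' @export
stepwise_select <- function(y, candidates, p_enter = 0.05,
                            p_remove = p_enter, centre_age = TRUE) {
  stopifnot(is.data.frame(candidates) || is.null(candidates))
  if (is.null(candidates)) candidates <- data.frame(row.names = seq_along(y))
  if (nrow(candidates) && nrow(candidates) != length(y)) {
    stop("candidates and y must have the same length")
  }
  cand <- candidates
  if (centre_age && all(c("age", "age2") %in% names(cand))) {
    cand$age2 <- (cand$age - mean(cand$age, na.rm = TRUE))^2
  }
  ok <- stats::complete.cases(cand) & is.finite(y)
  if (ncol(cand) > 0 && sum(ok) < 10 * 1) {
    stop("too few complete cases for stepwise selection")
  }
  dat <- cbind(data.frame(.y = y), cand)[ok, , drop = FALSE]
  included <- character(0)
  pool <- names(cand)
  repeat {
    changed <- FALSE
    # forward step: most significant candidate below the entry threshold
    if (length(pool)) {
      pvals <- vapply(pool, function(v) {
        partial_p(dat, c(included, v), v)
      }, 0)
      best <- which.min(pvals)
      if (is.finite(pvals[best]) && pvals[best] < p_enter) {
        included <- c(included, pool[best])
        pool <- pool[-best]
        changed <- TRUE
      }
    }
    # backward step: drop the worst included covariate at/above p_remove
    repeat {
      if (!length(included)) break
      pv <- vapply(included, function(v) partial_p(dat, included, v), 0)
      worst <- which.max(pv)
      if (pv[worst] >= p_remove) {
        pool <- c(pool, included[worst])
        included <- included[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- lm(mk_formula(included), data = dat)
  al <- is.na(coef(fit))
  if (any(al)) {
    bad <- names(coef(fit))[al]
    warning("dropping collinear covariate(s): ", paste(bad, collapse = ", "))
    included <- setdiff(included, bad)
    fit <- lm(mk_formula(included), data = dat)
  }
  structure(list(covariates = included, fit = fit,
                 coefficients = coef(fit),
                 p_enter = p_enter, p_remove = p_remove,
                 complete = ok, data = dat),
            class = "adjustment_model")
}

mk_formula <- function(vars) {
  if (!length(vars)) return(.y ~ 1)
  stats::as.formula(paste(".y ~", paste(sprintf("`%s`", vars), collapse = " + ")))
}

partial_p <- function(dat, model_vars, test_var) {
  fit <- lm(mk_formula(model_vars), data = dat)
  sm <- summary(fit)$coefficients
  row <- match(sprintf("`%s`", test_var), rownames(sm))
  if (is.na(row)) row <- match(test_var, rownames(sm))
  if (is.na(row)) return(Inf)  # aliased: never significant
  sm[row, 4]
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat("adjustment_model: ",
      if (length(x$covariates)) paste(x$covariates, collapse = " + ")
      else "(intercept only)", "\n", sep = "")
  invisible(x)
}

#' Standardised residuals with 3-SD outlier exclusion
#'
#' Takes the residuals of a fitted adjustment model, standardises them to
#' mean 0 and variance 1, and flags individuals whose standardised residual
#' exceeds `sd_limit` in absolute value as excluded. The model is not
#' refitted after exclusion unless `refit = TRUE`, in which case the same
#' covariate set is refitted on the retained individuals and the residuals
#' re-standardised (once).
#'
#' @param y Trait vector the model was fitted on.
#' @param model An `adjustment_model` from [stepwise_select()].
#' @param sd_limit Exclusion threshold in standard deviations.
#' @param refit Refit coefficients on the retained set.
#'
#' @return A list of class `adjusted_trait`: `z` (standardised residuals,
#'   NA where the trait or covariates were missing), `excluded` (logical),
#'   `n_retained`, `model`.
#' @export
adjust_standardize <- function(y, model, sd_limit = 3, refit = FALSE) {
  stopifnot(inherits(model, "adjustment_model"))
  r <- stats::residuals(model$fit)
  s <- sd(r)
  if (s < 1e-12 * max(1, abs(mean(y, na.rm = TRUE)))) {
    stop("residuals have zero variance; cannot standardise")
  }
  z_fit <- (r - mean(r)) / s
  z <- rep(NA_real_, length(y))
  z[model$complete] <- z_fit
  excluded <- !is.na(z) & abs(z) > sd_limit
  if (refit && any(excluded)) {
    complete_idx <- which(model$complete)
    keep_fit <- !excluded[complete_idx]
    fit2 <- lm(mk_formula(model$covariates),
               data = model$data[keep_fit, , drop = FALSE])
    r2 <- stats::residuals(fit2)
    z[] <- NA_real_
    z[complete_idx[keep_fit]] <- (r2 - mean(r2)) / sd(r2)
  }
  structure(list(z = z, excluded = excluded,
                 n_retained = sum(!is.na(z) & !excluded),
                 sd_limit = sd_limit, model = model),
            class = "adjusted_trait")
}

#' @export
print.adjusted_trait <- function(x, ...) {
  cat(sprintf("adjusted_trait: %d retained, %d excluded beyond %.3g SD\n",
              x$n_retained, sum(x$excluded), x$sd_limit))
  invisible(x)
}
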