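#' SNP-based heritability by average-information REML
#'
#' Restricted maximum likelihood for the single-component model
#' `V = A sigma2_g + I sigma2_e` with fixed effects `X` (an intercept by
#' default; the pipeline normally supplies pre-adjusted residuals).
#' Updates use the average-information (AI) algorithm with an EM-REML
#' first step and an EM fallback whenever an AI step would leave the
#' parameter space or decrease the restricted likelihood, so the
#' restricted likelihood is non-decreasing across iterations. The standard
#' error of `h2` comes from the inverse AI matrix by the delta method, and
#' the p-value from a likelihood-ratio test against `sigma2_g = 0` using
#' the boundary 50:50 chi-squared mixture.
#'
#' @param y Trait vector.
#' @param grm A `grm` object (or a bare relationship matrix).
#' @param X Fixed-effect design matrix (defaults to an intercept).
#' @param max_iter Maximum AI iterations.
#' @param tol Convergence tolerance on the change in restricted
#'   log-likelihood.
#' @param ridge Ridge added to the diagonal of `V` before factorisation.
#' @return A list of class `vc_fit` with `method = "AI-REML"`; see
#'   [fit_polygenic()] for the fields, plus `se_sigma2` and `iterations`
#'   and the per-iteration `trace`.
#' @export
ai_reml <- function(y, grm, X = NULL, max_iter = 100, tol = 1e-8,
                    ridge = 1e-8) {
  A <- if (inherits(grm, "grm")) grm$A else grm
  ids <- names(y)
  if (!is.null(ids) && !is.null(rownames(A))) {
    A <- A[ids, ids, drop = FALSE]
  }
  keep <- is.finite(y)
  y <- y[keep]
  A <- A[keep, keep, drop = FALSE]
  n <- length(y)
  if (n < 50) warning("n < 50: REML variance components will be unstable")
  if (is.null(X)) X <- matrix(1, n, 1) else X <- as.matrix(X)[keep, , drop = FALSE]
  p <- ncol(X)
  # one spectral decomposition serves every iteration
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam <- ev$values
  U <- ev$vectors
  ty <- drop(crossprod(U, y))
  tX <- crossprod(U, X)
  identifiable <- diff(range(lam)) > 1e-8
  vy <- var(y)
  theta <- c(g = vy / 2, e = vy / 2)
  floor_v <- 1e-8 * vy

  rl <- function(th) reml_ll(th, lam, ty, tX, ridge)
  ll <- rl(theta)
  trace <- data.frame(iter = 0, sigma2_g = theta[1], sigma2_e = theta[2],
                      loglik = ll, step = "init")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    q <- reml_quantities(theta, lam, ty, tX, ridge)
    # EM-REML on the first iteration, AI afterwards
    if (it == 1) {
      prop <- pmax(theta + theta^2 * (q$yPVPy - q$trPV) / n, floor_v)
      step <- "EM"
    } else {
      delta <- tryCatch(solve(q$AI, q$score), error = function(e) NULL)
      if (is.null(delta)) {
        prop <- pmax(theta + theta^2 * (q$yPVPy - q$trPV) / n, floor_v)
        step <- "EM"
      } else {
        prop <- theta + delta
        step <- "AI"
        if (any(prop < floor_v)) {
          prop <- pmax(theta + theta^2 * (q$yPVPy - q$trPV) / n, floor_v)
          step <- "EM"
        }
      }
    }
    ll_new <- rl(prop)
    if (step == "AI" && ll_new < ll - 1e-10) {  # AI overshoot: EM fallback
      prop <- pmax(theta + theta^2 * (q$yPVPy - q$trPV) / n, floor_v)
      step <- "EM"
      ll_new <- rl(prop)
    }
    trace <- rbind(trace, data.frame(iter = it, sigma2_g = prop[1],
                                     sigma2_e = prop[2], loglik = ll_new,
                                     step = step))
    done <- abs(ll_new - ll) < tol && max(abs(prop - theta)) < sqrt(tol)
    theta <- prop
    ll <- ll_new
    if (done) { converged <- TRUE; break }
  }
  # profile polish: EM crawls when the optimum sits near the h2 = 1
  # boundary, so finish with a one-dimensional search over the variance
  # ratio with the total variance profiled out (only accepted uphill,
  # which preserves the monotone trace)
  pol <- reml_profile_opt(lam, ty, tX)
  if (is.finite(pol$ll)) {
    prop <- pmax(c(pol$h2 * pol$s2t, (1 - pol$h2) * pol$s2t), floor_v)
    ll_pol <- rl(prop)
    if (ll_pol > ll + 1e-9) {
      theta <- prop
      ll <- ll_pol
      converged <- TRUE
      trace <- rbind(trace, data.frame(iter = nrow(trace),
                                       sigma2_g = theta[1],
                                       sigma2_e = theta[2],
                                       loglik = ll, step = "profile"))
    }
  }
  if (!converged && max_iter > 0) {
    warning("AI-REML did not converge in ", max_iter, " iterations")
  }
  q <- reml_quantities(theta, lam, ty, tX, ridge)
  Vth <- tryCatch(solve(q$AI), error = function(e) matrix(NA, 2, 2))
  s2g <- unname(theta[1]); s2e <- unname(theta[2])
  tot <- s2g + s2e
  grad <- c(s2e, -s2g) / tot^2
  se_h2 <- sqrt(max(0, drop(t(grad) %*% Vth %*% grad)))
  # null REML: V = sigma2 I, so sigma2 = RSS / (n - p) from OLS
  qr0 <- qr(X)
  r0 <- qr.resid(qr0, y)
  s20 <- sum(r0^2) / (n - p)
  ll0 <- -0.5 * (n * log(s20) + log(det(crossprod(X) / s20)) +
                   sum(r0^2) / s20 + (n - p) * log(2 * pi))
  lrt <- max(0, 2 * (ll - ll0))
  structure(list(sigma2_g = s2g, sigma2_e = s2e, h2 = s2g / tot,
                 se_h2 = se_h2, se_sigma2 = sqrt(pmax(0, diag(Vth))),
                 loglik_full = ll, loglik_null = ll0, lrt = lrt,
                 p_value = if (lrt <= 0) 1 else
                   0.5 * pchisq(lrt, 1, lower.tail = FALSE),
                 p_value_chisq1 = pchisq(lrt, 1, lower.tail = FALSE),
                 n = n, identifiable = identifiable,
                 converged = converged, iterations = nrow(trace) - 1,
                 trace = trace, eigen = list(lam = lam, U = U),
                 method = "AI-REML"),
            class = "vc_fit")
}

# restricted log-likelihood (with constant) in the eigenbasis of A
reml_ll <- function(theta, lam, ty, tX, ridge) {
  d <- theta[1] * lam + theta[2] + ridge
  if (any(d <= 0)) return(-Inf)
  w <- 1 / d
  XtVX <- crossprod(tX, tX * w)
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, backsolve(ch, crossprod(tX, ty * w),
                                  transpose = TRUE))
  # y'Py = y'V^-1 (y - X beta)
  yPy <- sum(ty * w * (ty - drop(tX %*% beta)))
  n <- length(ty)
  p <- ncol(tX)
  -0.5 * (sum(log(d)) + 2 * sum(log(diag(ch))) + yPy +
            (n - p) * log(2 * pi))
}

# restricted likelihood profiled over the total variance at fixed h2
reml_profile_ll <- function(h2, lam, ty, tX) {
  d0 <- h2 * lam + (1 - h2)
  if (any(d0 <= 0)) return(list(ll = -Inf))
  w <- 1 / d0
  XtSX <- crossprod(tX, tX * w)
  ch <- tryCatch(chol(XtSX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, backsolve(ch, crossprod(tX, ty * w),
                                  transpose = TRUE))
  yPSy <- sum(ty * w * (ty - drop(tX %*% beta)))
  np <- length(ty) - ncol(tX)
  if (yPSy <= 0) return(list(ll = -Inf))
  s2t <- yPSy / np
  ll <- -0.5 * (sum(log(d0)) + 2 * sum(log(diag(ch))) + np * log(s2t) +
                  np + np * log(2 * pi))
  list(ll = ll, s2t = s2t)
}

reml_profile_opt <- function(lam, ty, tX, grid_points = 201) {
  grid <- seq(0, 1 - 1e-7, length.out = grid_points)
  lls <- vapply(grid, function(h) reml_profile_ll(h, lam, ty, tX)$ll, 0)
  best <- which.max(lls)
  if (!is.finite(lls[best])) return(list(ll = -Inf))
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(grid_points, best + 1)]
  opt <- stats::optimize(function(h) reml_profile_ll(h, lam, ty, tX)$ll,
                         c(lo, hi), maximum = TRUE, tol = 1e-10)
  h2 <- if (opt$objective >= lls[best]) opt$maximum else grid[best]
  res <- reml_profile_ll(h2, lam, ty, tX)
  list(ll = res$ll, h2 = h2, s2t = res$s2t)
}

# score, AI matrix and the EM ingredients at the current parameters
reml_quantities <- function(theta, lam, ty, tX, ridge) {
  d <- theta[1] * lam + theta[2] + ridge
  w <- 1 / d
  XtVX <- solve(crossprod(tX, tX * w))
  Pv <- function(v) {  # P %*% v in the eigenbasis
    wv <- v * w
    wv - (tX * w) %*% (XtVX %*% crossprod(tX, wv))
  }
  Py <- Pv(ty)
  APy <- lam * Py           # V_g = A is diagonal (lam) in the eigenbasis
  PAPy <- Pv(APy)
  PPy <- Pv(Py)
  # tr(P V_i) = tr(V^-1 V_i) - tr((X'V^-1 X)^-1 X'V^-1 V_i V^-1 X)
  M_A <- crossprod(tX, tX * (lam * w^2))
  M_I <- crossprod(tX, tX * w^2)
  tr_PA <- sum(lam * w) - sum(XtVX * t(M_A))
  tr_PI <- sum(w) - sum(XtVX * t(M_I))
  yPAPy <- sum(ty * PAPy)
  yPPy <- sum(ty * PPy)
  score <- c(-0.5 * (tr_PA - yPAPy), -0.5 * (tr_PI - yPPy))
  AI <- matrix(0, 2, 2)
  AI[1, 1] <- 0.5 * sum(APy * Pv(APy))
  AI[1, 2] <- AI[2, 1] <- 0.5 * sum(APy * PPy)
  AI[2, 2] <- 0.5 * sum(Py * PPy)
  list(score = score, AI = AI,
       trPV = c(tr_PA, tr_PI), yPVPy = c(yPAPy, yPPy))
}
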