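#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression with convergence metadata and
#' explicit failure modes. Convergence requires both the relative
#' log-likelihood change and the maximum absolute score component to fall
#' below tolerance; a coefficient diverging past `beta_limit` raises a
#' separation error naming the offending term, and a rank-deficient design
#' raises a collinearity error.
#'
#' @param x design matrix (include the intercept column yourself, or use
#'   [model.matrix()]); column names label the coefficients.
#' @param y 0/1 outcome vector.
#' @param tol relative log-likelihood convergence tolerance.
#' @param grad_tol score (gradient) convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @param beta_limit absolute coefficient bound beyond which separation is
#'   declared.
#' @return A list of class `logistic_fit`: `coefficients`, `vcov` (inverse
#'   observed information), `loglik`, `n_iter`, `converged`, `n`.
#' @export
fit_logistic <- function(x, y, tol = 1e-10, grad_tol = 1e-8,
                         max_iter = 100L, beta_limit = 15) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (length(y) != nrow(x)) stop(data_error("x and y dimensions disagree"))
  if (anyNA(x) || anyNA(y)) stop(data_error("design or outcome contains NA"))
  if (!all(y %in% c(0, 1))) stop(data_error("outcome must be 0/1"))
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop(data_error("need more observations than terms"))
  qrx <- qr(x)
  if (qrx$rank < p) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1):p]]
    stop(model_error(paste("singular design; collinear term(s):",
                           paste(dropped, collapse = ", ")),
                     subclass = "ambientgxe_collinearity"))
  }

  beta <- rep(0, p)
  names(beta) <- colnames(x)
  loglik_at <- function(eta) sum(y * eta - log1p(exp(eta)))
  eta <- drop(x %*% beta)
  ll <- loglik_at(eta)
  converged <- FALSE
  iter <- 0L
  info <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, .Machine$double.eps)
    score <- drop(crossprod(x, y - mu))
    info <- crossprod(x * sqrt(w))
    step <- tryCatch(solve(info, score), error = function(e)
      stop(model_error("information matrix singular during IRLS",
                       subclass = "ambientgxe_collinearity")))
    # step-halving safeguards the ascent
    lam <- 1
    repeat {
      cand <- beta + lam * step
      eta_c <- drop(x %*% cand)
      ll_c <- loglik_at(eta_c)
      if (is.finite(ll_c) && (ll_c >= ll - 1e-12 || lam < 1e-4)) break
      lam <- lam / 2
    }
    beta <- cand; eta <- eta_c
    if (any(abs(beta) > beta_limit)) {
      worst <- names(beta)[which.max(abs(beta))]
      stop(model_error(paste0("complete or quasi-complete separation suspected: ",
                              "coefficient for '", worst, "' diverged"),
                       subclass = "ambientgxe_separation"))
    }
    rel <- abs(ll_c - ll) / (abs(ll) + 1e-8)
    ll <- ll_c
    mu <- plogis(eta)
    score <- drop(crossprod(x, y - mu))
    if (rel < tol && max(abs(score)) < grad_tol) {
      converged <- TRUE
      break
    }
  }
  w <- pmax(plogis(eta) * (1 - plogis(eta)), .Machine$double.eps)
  info <- crossprod(x * sqrt(w))
  vc <- solve(info)
  dimnames(vc) <- list(colnames(x), colnames(x))
  structure(list(coefficients = beta, vcov = vc, loglik = ll,
                 n_iter = iter, converged = converged, n = n,
                 max_score = max(abs(score))),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (IRLS): n = %d, logLik = %.4f, %d iteration(s), %s\n",
              x$n, x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(estimate = x$coefficients, se = se,
                    z = x$coefficients / se,
                    p = 2 * pnorm(-abs(x$coefficients / se)))
  print(round(tab, 4))
  invisible(x)
}

#' Odds ratio with Wald confidence interval for a coefficient contrast
#'
#' For contrast vector `c`, reports `OR = exp(c'beta)` with 95% interval
#' `exp(c'beta +/- 1.96 sqrt(c' V c))` and a two-sided normal p-value.
#'
#' @param fit a [fit_logistic()] result.
#' @param contrast numeric vector, or a coefficient name.
#' @param conf_level confidence level (normal multiplier).
#' @return A list of class `effect_estimate`: `or`, `ci_low`, `ci_high`,
#'   `p`, `log_or`, `se`, `contrast`.
#' @export
wald_or <- function(fit, contrast, conf_level = 0.95) {
  b <- fit$coefficients
  if (is.character(contrast)) {
    cv <- as.numeric(names(b) %in% contrast)
    if (sum(cv) != length(contrast))
      stop(data_error("contrast names not all found among coefficients"))
    contrast <- cv
  }
  if (length(contrast) != length(b))
    stop(data_error("contrast length must equal coefficient length"))
  est <- sum(contrast * b)
  if (all(contrast == 0))
    return(structure(list(or = 1, ci_low = 1, ci_high = 1, p = NA_real_,
                          log_or = 0, se = 0, contrast = contrast),
                     class = "effect_estimate"))
  v <- drop(t(contrast) %*% fit$vcov %*% contrast)
  if (v <= 0) stop(model_error("zero-variance contrast"))
  se <- sqrt(v)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(or = exp(est), ci_low = exp(est - zq * se),
                 ci_high = exp(est + zq * se),
                 p = 2 * pnorm(-abs(est / se)),
                 log_or = est, se = se, contrast = contrast),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("OR = %.3f (95%% CI %.3f, %.3f), p = %.4g\n",
              x$or, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

# Likelihood-ratio p-value for dropping one term from a fitted design.
lrt_p <- function(x, y, term) {
  full <- fit_logistic(x, y)
  reduced <- fit_logistic(x[, setdiff(colnames(x), term), drop = FALSE], y)
  stat <- 2 * (full$loglik - reduced$loglik)
  pchisq(max(stat, 0), df = 1L, lower.tail = FALSE)
}
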