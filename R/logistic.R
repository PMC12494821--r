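## Internal logistic-regression engine.
##
## The burden, single-variant and window scans fit tens of thousands of
## logistic models that share one covariate block and differ only in the
## final predictor column, so the engine is a plain IRLS loop on a numeric
## design matrix (no formula interface) with warm starts from the
## covariate-only null fit. Separation or non-convergence falls back to a
## Firth (Jeffreys-prior) penalized fit.

logit_irls <- function(X, y, start = NULL, max_iter = 30L, tol = 1e-8) {
  p <- ncol(X)
  beta <- if (is.null(start)) numeric(p) else start
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    eta[eta > 30] <- 30; eta[eta < -30] <- -30
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    w[w < 1e-12] <- 1e-12
    XtWX <- crossprod(X * sqrt(w))        # dsyrk on the weighted design
    score <- crossprod(X, y - mu)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(list(ok = FALSE))
    beta_new <- beta + drop(backsolve(ch, forwardsolve(t(ch), score)))
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  eta[eta > 30] <- 30; eta[eta < -30] <- -30
  mu <- 1 / (1 + exp(-eta))
  w <- mu * (1 - mu); w[w < 1e-12] <- 1e-12
  ch <- tryCatch(chol(crossprod(X * sqrt(w))), error = function(e) NULL)
  if (is.null(ch)) return(list(ok = FALSE))
  list(ok = TRUE, coef = drop(beta), vcov = chol2inv(ch),
       converged = converged, separated = any(abs(beta) > 15))
}

## Firth-penalized logistic regression: IRLS on the modified score
## U*(beta) = X' (y - mu + h (1/2 - mu)), h = leverage under W.
firth_irls <- function(X, y, max_iter = 80L, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  for (iter in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    XtWX <- crossprod(X * w, X)
    inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(inv)) return(list(ok = FALSE))
    h <- rowSums((X %*% inv) * X) * w
    score <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- drop(inv %*% score)
    ## dampen oversized steps for stability near separation
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol * (1 + max(abs(beta)))) break
  }
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  vcov <- tryCatch(solve(crossprod(X * w, X)), error = function(e) NULL)
  if (is.null(vcov)) return(list(ok = FALSE))
  list(ok = TRUE, coef = beta, vcov = vcov, converged = iter < max_iter,
       separated = FALSE)
}

## Drop aliased columns (rank-deficient design) keeping the leftmost set.
## Returns the column indices retained.
full_rank_columns <- function(X) {
  qr_x <- qr(X)
  sort(qr_x$pivot[seq_len(qr_x$rank)])
}

## Fit outcome ~ covariates (+ optional final predictor column) and return a
## Wald test on the last coefficient. `null_fit` (a logit_irls result on the
## covariate block) provides warm starts.
wald_logistic <- function(predictor, y, covariates, null_fit = NULL,
                          firth_on_failure = TRUE) {
  X <- cbind(covariates, predictor = predictor)
  start <- if (!is.null(null_fit) && null_fit$ok) c(null_fit$coef, 0) else NULL
  fit <- logit_irls(X, y, start = start)
  flag <- "ok"
  if (!fit$ok || !fit$converged || fit$separated) {
    if (firth_on_failure) {
      fit <- firth_irls(X, y)
      flag <- "firth"
    }
    if (!fit$ok) {
      return(list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                  flag = "failed"))
    }
  }
  k <- ncol(X)
  est <- unname(fit$coef[k])
  se <- unname(sqrt(fit$vcov[k, k]))
  z <- est / se
  list(estimate = est, se = se, p = 2 * pnorm(-abs(z)), flag = flag)
}
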