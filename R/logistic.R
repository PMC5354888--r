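# Internal single-covariate logistic fits used for per-region association
# scoring: a tight IRLS maximum-likelihood fit with a likelihood-ratio test
# against the intercept-only model, and a Firth-penalized fallback for
# (quasi-)separated regions where the MLE diverges.

clamp_eta <- function(eta) pmin(pmax(eta, -30), 30)

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

# Maximum-likelihood logistic fit of y ~ 1 + x by IRLS.
irls_logistic <- function(x, y, max_iter = 60, tol = 1e-10) {
  n <- length(y)
  pbar <- mean(y)
  b0 <- qlogis(pmin(pmax(pbar, 1e-6), 1 - 1e-6))
  b1 <- 0
  dev <- binomial_deviance(y, rep(pbar, n))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- clamp_eta(b0 + b1 * x)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    sw <- sum(w); swx <- sum(w * x); swx2 <- sum(w * x * x)
    swz <- sum(w * z); swxz <- sum(w * x * z)
    det <- sw * swx2 - swx * swx
    if (!is.finite(det) || abs(det) < 1e-300) break
    b0_new <- (swx2 * swz - swx * swxz) / det
    b1_new <- (sw * swxz - swx * swz) / det
    dev_new <- binomial_deviance(y, plogis(clamp_eta(b0_new + b1_new * x)))
    moved <- abs(dev_new - dev)
    b0 <- b0_new; b1 <- b1_new; dev <- dev_new
    if (moved < tol) { converged <- TRUE; break }
  }
  list(coef = c(b0, b1), deviance = dev, converged = converged)
}

# Firth-penalized logistic fit; returns the penalized log-likelihood so that
# full and null fits can be compared by a penalized LRT. X is n x p.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  p_dim <- ncol(X)
  beta <- rep(0, p_dim)
  pll <- function(beta) {
    eta <- clamp_eta(drop(X %*% beta))
    pr <- plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-10)
    XtWX <- crossprod(X * sqrt(w))
    ll <- sum(y * eta - log1p(exp(eta)))
    ld <- determinant(XtWX, logarithm = TRUE)$modulus
    ll + 0.5 * as.numeric(ld)
  }
  cur <- pll(beta)
  for (it in seq_len(max_iter)) {
    eta <- clamp_eta(drop(X %*% beta))
    pr <- plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-10)
    Xw <- X * sqrt(w)
    XtWX <- crossprod(Xw)
    XtWX_inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(XtWX_inv)) break
    h <- rowSums((X %*% XtWX_inv) * X) * w
    U <- drop(crossprod(X, y - pr + h * (0.5 - pr)))
    step <- drop(XtWX_inv %*% U)
    # step-halving to guarantee monotone penalized likelihood
    improved <- FALSE
    for (half in 0:12) {
      cand <- beta + step / 2^half
      new <- pll(cand)
      if (is.finite(new) && new >= cur - 1e-12) {
        if (abs(new - cur) < tol && max(abs(step / 2^half)) < 1e-5) {
          beta <- cand; cur <- new
          return(list(coef = beta, pll = cur, converged = TRUE))
        }
        beta <- cand; cur <- new; improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(coef = beta, pll = cur, converged = FALSE)
}

# Likelihood-ratio test of association between a binary outcome and a single
# covariate. Returns the p-value, slope, and whether the Firth fallback was
# engaged (perfect or quasi-separation).
logistic_lrt <- function(x, y) {
  y <- as.numeric(y)
  n <- length(y)
  n1 <- sum(y)
  if (n1 == 0 || n1 == n)
    return(list(p_value = 1, stat = 0, slope = 0, separated = FALSE))
  pbar <- n1 / n
  null_dev <- -2 * (n1 * log(pbar) + (n - n1) * log(1 - pbar))
  fit <- irls_logistic(x, y)
  separated <- !fit$converged || fit$deviance < 1e-6
  if (!separated) {
    stat <- max(null_dev - fit$deviance, 0)
    return(list(p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                stat = stat, slope = fit$coef[2], separated = FALSE))
  }
  X <- cbind(1, x)
  full <- firth_logistic(X, y)
  nullf <- firth_logistic(matrix(1, n, 1), y)
  stat <- max(2 * (full$pll - nullf$pll), 0)
  list(p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       stat = stat, slope = full$coef[2], separated = TRUE)
}

# Closed-form one-way ANOVA F-test of a numeric vector across class labels.
anova_f_test <- function(x, labels) {
  labels <- droplevels(as.factor(labels))
  k <- nlevels(labels)
  n <- length(x)
  means <- tapply(x, labels, mean)
  counts <- tabulate(labels)
  grand <- mean(x)
  ssb <- sum(counts * (means - grand)^2)
  ssw <- sum((x - means[as.integer(labels)])^2)
  df1 <- k - 1; df2 <- n - k
  if (ssw <= 0) {
    if (ssb <= 0) return(list(p_value = 1, stat = 0))
    return(list(p_value = 1e-300, stat = Inf))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(p_value = pf(f, df1, df2, lower.tail = FALSE), stat = f)
}
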