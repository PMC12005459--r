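# Independent oracles, deliberately implemented differently from the package.

# normal-equations solve for d ~ a * ln(x) + b
oracle_logfit <- function(weeks, distances) {
  X <- cbind(log(weeks), 1)
  beta <- solve(t(X) %*% X, t(X) %*% distances)
  list(a = beta[1], b = beta[2])
}

# two-pass RMSE: explicit residual vector, explicit mean
oracle_rmse <- function(pred, act) {
  resid <- numeric(length(pred))
  for (i in seq_along(pred)) resid[i] <- pred[i] - act[i]
  sq <- resid^2
  sqrt(sum(sq) / length(sq))
}

# exhaustive two-tailed signed-rank p value over all 2^n sign assignments
oracle_signrank_p <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(vs >= v_obs), mean(vs <= v_obs)))
}

# OLS coefficients via explicit normal equations
oracle_ols <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  as.numeric(solve(t(Xi) %*% Xi, t(Xi) %*% y))
}
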