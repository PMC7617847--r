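# Independent oracles, implemented from first principles and kept separate
# from the package's computation paths.

# Partial correlation by the residual-regression route: correlate the
# residuals of columns i and j after regressing each on all remaining
# columns.
pcor_residual_route <- function(ts) {
  ts <- as.matrix(ts)
  k <- ncol(ts)
  out <- diag(k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      others <- ts[, -c(i, j), drop = FALSE]
      if (ncol(others) == 0) {
        r <- cor(ts[, i], ts[, j])
      } else {
        ri <- residuals(lm(ts[, i] ~ others))
        rj <- residuals(lm(ts[, j] ~ others))
        r <- cor(ri, rj)
      }
      out[i, j] <- out[j, i] <- r
    }
  }
  dimnames(out) <- list(colnames(ts), colnames(ts))
  out
}

# Cook's distance by the leave-one-out refit definition:
# D_i = sum_j (yhat_j - yhat_j(i))^2 / (p * s^2), with p parameters and
# s^2 the full-fit mean squared error.
cooks_loo <- function(y, x) {
  n <- length(y)
  fit <- lm(y ~ x)
  yhat <- fitted(fit)
  p <- 2
  s2 <- sum(residuals(fit)^2) / (n - p)
  vapply(seq_len(n), function(i) {
    fit_i <- lm(y[-i] ~ x[-i])
    yhat_i <- cbind(1, x) %*% coef(fit_i)
    sum((yhat - yhat_i)^2) / (p * s2)
  }, numeric(1))
}
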