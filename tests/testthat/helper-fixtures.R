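# shared fixture builders; everything is generated in code at test time

# small random regression fixture with named columns
make_regression_fixture <- function(n = 20, p = 5, seed = 1, noise_sd = 0.5,
                                    beta = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(sprintf("m%02d", 1:n),
                                                  sprintf("d%02d", 1:p)))
  if (is.null(beta)) beta <- c(2, -1, rep(0, p - 2))
  y <- 1 + drop(X %*% beta) + rnorm(n, sd = noise_sd)
  list(X = X, y = y, beta = beta)
}

# literal leave-one-out PRESS by refitting n times (independent oracle)
loo_q2_bruteforce <- function(X, y) {
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    fit <- lm.fit(cbind(1, X[-i, , drop = FALSE]), y[-i])
    pred <- sum(c(1, X[i, ]) * fit$coefficients)
    press <- press + (y[i] - pred)^2
  }
  unname(1 - press / sum((y - mean(y))^2))
}

# Pearson correlation from the raw sum formula (oracle independent of cor())
pearson_by_sums <- function(a, b) {
  n <- length(a)
  (n * sum(a * b) - sum(a) * sum(b)) /
    sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
}
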