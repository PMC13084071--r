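## Shared fixtures built in code.

## small planted dataset for regression tests
makePlanted <- function(n = 50, m = 8, k = 3, noiseSd = 0, seed = 11,
                        ...) {
  genQsarDataset(nCompounds = n, mDescriptors = m, kInformative = k,
                 noiseSd = noiseSd, seed = seed, ...)
}

## brute-force leave-one-out PRESS: refit n times with lm()
bruteForcePress <- function(X, y) {
  n <- length(y)
  sum(vapply(seq_len(n), function(i) {
    df <- data.frame(y = y[-i], X[-i, , drop = FALSE])
    fit <- stats::lm(y ~ ., data = df)
    newd <- as.data.frame(X[i, , drop = FALSE])
    (y[i] - stats::predict(fit, newdata = newd))^2
  }, numeric(1)))
}

## direct transcription of the through-origin formulas (independent of
## the package implementation)
oracleThroughOrigin <- function(yo, yp) {
  k <- sum(yo * yp) / sum(yp^2)
  kp <- sum(yo * yp) / sum(yo^2)
  c(r0_2 = 1 - sum((yp - k * yp)^2) / sum((yp - mean(yp))^2),
    r0_prime_2 = 1 - sum((yo - kp * yo)^2) / sum((yo - mean(yo))^2),
    k = k, k_prime = kp)
}

expect_unit_last_digit <- function(computed, printed) {
  ## agreement within one unit in the last printed digit
  dec <- nchar(sub("^[^.]*\\.?", "", sub("[eE].*", "", printed)))
  mant <- as.numeric(sub("[eE].*", "", printed))
  expo <- ifelse(grepl("[eE]", printed),
                 as.numeric(sub(".*[eE]", "", printed)), 0)
  ulp <- 10^(expo - dec)
  expect_lte(abs(computed - as.numeric(printed)), ulp + 1e-12)
}
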