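## Three well-separated Gaussian blobs (centers on orthogonal axes), one per
## class; with sep = 4 and unit noise the Bayes accuracy is ~1.
make_blobs <- function(n, d = 5, seed = 1, sep = 4) {
  withr::with_seed(seed, {
    centers <- matrix(0, 3, d)
    for (k in 1:3) centers[k, (k - 1) %% d + 1] <- sep * if (k <= d) 1 else -1
    y <- sample(1:3, n, replace = TRUE)
    X <- centers[y, , drop = FALSE] + matrix(rnorm(n * d), n, d)
    list(X = X, y = c("positive", "uncertain", "negative")[y])
  })
}

## small hand-specified embedding table
toy_table <- function() {
  embedding_table(matrix(c(1, 0,
                           0, 1,
                           2, 2), 3, 2, byrow = TRUE,
                         dimnames = list(c("a", "b", "c"), NULL)))
}

## independent 2-d multivariate normal density (test oracle)
dmvn2 <- function(x, mean, cov) {
  d <- length(mean)
  ch <- chol(cov)
  z <- backsolve(ch, x - mean, transpose = TRUE)
  exp(-0.5 * sum(z^2) - sum(log(diag(ch))) - d / 2 * log(2 * pi))
}

## KL integrand q(x) log(q(x)/p(x)) for q = N(m, LL^T), p = N(0, I), after
## the substitution x = m + Lz; vectorized the way pracma::quad2d calls it.
kl_integrand <- function(z1, z2, m, L, S) {
  vals <- mapply(function(a, b) {
    x <- m + L %*% c(a, b)
    dmvn2(c(a, b), c(0, 0), diag(2)) *
      (log(dmvn2(x, m, S)) - log(dmvn2(x, c(0, 0), diag(2))))
  }, z1, z2)
  array(vals, dim = dim(as.matrix(z1)))
}
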