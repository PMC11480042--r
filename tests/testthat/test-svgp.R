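test_that("ARD-RBF kernel matches hand-evaluated values and limits", {
  expect_equal(rbf_ard(c(1, 2), c(1, 2), 2.5, c(1, 1)), 2.5)
  ## huge length scales: correlation saturates at the signal variance
  expect_equal(rbf_ard(c(0, 0), c(3, -4), 1.7, c(1e8, 1e8)), 1.7,
               tolerance = 1e-9)
  ## sigma^2 = 1, unit length scales, squared distance 2 -> exp(-1)
  expect_equal(rbf_ard(c(0, 0), c(1, 1), 1, c(1, 1)), exp(-1))
  ## symmetry and the bound k <= sigma^2 on random pairs
  withr::with_seed(2, {
    for (i in 1:10) {
      x <- rnorm(4); y <- rnorm(4); ls <- runif(4, 0.5, 2)
      expect_equal(rbf_ard(x, y, 1.3, ls), rbf_ard(y, x, 1.3, ls))
      expect_lte(rbf_ard(x, y, 1.3, ls), 1.3)
    }
  })
  expect_error(rbf_ard(1, 2, -1, 1), "positive")
})

test_that("KL is zero at the prior and matches the scalar closed form", {
  Z <- matrix(seq(-1, 1, length.out = 3))
  st <- svgp_state(Z)   # m = 0, L = I: q equals the whitened prior
  expect_equal(svgp_kl(st), 0)
  ## q = N(0,1) against prior N(0,2): whitened factor sqrt(1/2), M = 1
  st1 <- svgp_state(matrix(0), signal_variance = 2,
                    m = matrix(0), L = list(matrix(sqrt(0.5))),
                    class_levels = "positive")
  expect_equal(svgp_kl(st1), 0.5 * (log(2) + 0.5 - 1), tolerance = 1e-12)
})

test_that("KL is non-negative on random valid states", {
  withr::with_seed(31, {
    for (i in 1:100) {
      M <- sample(2:5, 1)
      L <- lapply(1:3, function(c) {
        A <- matrix(rnorm(M * M, sd = 0.4), M, M)
        A[upper.tri(A)] <- 0
        diag(A) <- abs(diag(A)) + 0.05
        A
      })
      st <- svgp_state(matrix(rnorm(M * 2), M, 2),
                       m = matrix(rnorm(M * 3), M, 3), L = L)
      expect_gte(svgp_kl(st), 0)
    }
  })
})

test_that("closed-form KL agrees with a 2-d quadrature oracle", {
  skip_if_not_installed("pracma")
  m <- c(0.3, -0.2)
  L <- matrix(c(0.9, 0.4, 0, 1.1), 2, 2)
  S <- L %*% t(L)
  st <- svgp_state(matrix(rnorm(4), 2, 2), m = matrix(m),
                   L = list(L), class_levels = "positive")
  ## substitute x = m + Lz so the integrand carries a standard-normal weight
  quad <- pracma::quad2d(function(z1, z2) kl_integrand(z1, z2, m, L, S),
                         -8, 8, -8, 8, n = 64)
  expect_equal(svgp_kl(st), quad, tolerance = 1e-6)
})

test_that("degenerate ELBO configuration reduces to the plain log likelihood", {
  withr::with_seed(12, {
    Z <- matrix(rnorm(8), 4, 2)
    X <- matrix(rnorm(12), 6, 2)
    y <- c("positive", "uncertain", "negative", "positive", "negative", "uncertain")
    st <- svgp_state(Z, signal_variance = 1.4, length_scales = c(0.9, 1.2),
                     m = matrix(rnorm(12, sd = 0.5), 4, 3))
    ## hand path: whitened marginal means, then log-softmax at the means
    Kmm <- rbf_ard(Z, Z, 1.4, c(0.9, 1.2)) + diag(1e-8, 4)
    A <- forwardsolve(t(chol(Kmm)), rbf_ard(Z, X, 1.4, c(0.9, 1.2)))
    mu <- crossprod(A, st$m)
    yi <- match(y, c("positive", "uncertain", "negative"))
    ll <- sum(mu[cbind(1:6, yi)] - log(rowSums(exp(mu))))
    expect_equal(svgp_elbo(st, X, y, kl_weight = 0, deterministic = TRUE),
                 ll, tolerance = 1e-10)
    ## untrained symmetric state: likelihood term is n * log(1/3) exactly
    st0 <- svgp_state(Z)
    expect_equal(svgp_elbo(st0, X, y, kl_weight = 0, deterministic = TRUE),
                 6 * log(1 / 3))
  })
})

test_that("Monte-Carlo ELBO variance shrinks with the sample count", {
  withr::with_seed(4, {
    Z <- matrix(rnorm(6), 3, 2)
    X <- matrix(rnorm(20), 10, 2)
    y <- rep(c("positive", "uncertain", "negative"), length.out = 10)
    st <- svgp_state(Z, m = matrix(rnorm(9), 3, 3))
    est <- function(mc) vapply(1:40, function(s) svgp_elbo(st, X, y, mc = mc, seed = s),
                               numeric(1))
    v1 <- var(est(1)); v16 <- var(est(16))
    expect_lt(v16, v1 / 4)  # O(1/mc) scaling, asserted loosely
  })
})

test_that("analytic minibatch gradients match finite differences", {
  withr::with_seed(3, {
    n <- 10; d <- 2; M <- 3
    X <- matrix(rnorm(n * d), n, d)
    y <- rep(c("positive", "uncertain", "negative"), length.out = n)
    L <- lapply(1:3, function(i) {
      A <- matrix(rnorm(M * M, sd = 0.2), M, M); A[upper.tri(A)] <- 0
      diag(A) <- abs(diag(A)) + 0.7; A
    })
    st <- svgp_state(matrix(rnorm(M * d), M, d), signal_variance = 1.3,
                     length_scales = c(0.8, 1.3),
                     m = matrix(rnorm(M * 3, sd = 0.5), M, 3), L = L)
    yi <- match(y, st$class_levels)
    gr <- withr::with_seed(42, reportuq:::svgp_elbo_grad(st, X, yi, n, mc = 5))
    f <- function(s) svgp_elbo(s, X, y, n_total = n, mc = 5, seed = 42)
    fd <- function(set, idx) {
      h <- 1e-6
      (f(set(h, idx)) - f(set(-h, idx))) / (2 * h)
    }
    for (i in c(1, 5, 9)) {
      expect_equal(fd(function(h, i) { s <- st; s$m[i] <- s$m[i] + h; s }, i),
                   gr$g_m[i], tolerance = 1e-4)
    }
    expect_equal(fd(function(h, i) { s <- st; s$log_sv <- s$log_sv + h; s }, 1),
                 gr$g_log_sv, tolerance = 1e-4)
    for (i in 1:2) {
      expect_equal(fd(function(h, i) { s <- st; s$log_ls[i] <- s$log_ls[i] + h; s }, i),
                   gr$g_log_ls[i], tolerance = 1e-4)
    }
    expect_equal(fd(function(h, i) { s <- st; s$Lraw[[2]][2, 1] <- s$Lraw[[2]][2, 1] + h; s }, 1),
                 gr$g_Lraw[[2]][2, 1], tolerance = 1e-4)
  })
})

test_that("untrained symmetric state predicts near-uniform probabilities", {
  st <- svgp_state(matrix(rnorm(10), 5, 2), mc_predict = 2000, predict_seed = 8)
  pd <- predict(st, matrix(c(0.3, -1, 2, 0.5), 2, 2))
  expect_true(all(abs(pd$probs - 1 / 3) < 0.02))
  expect_equal(rowSums(pd$probs), c(1, 1), tolerance = 1e-9)
})

test_that("latent variance reverts to the prior far from the inducing set", {
  st <- svgp_state(matrix(seq(-1, 1, length.out = 4)), signal_variance = 1.9,
                   length_scales = 0.5,
                   m = matrix(rnorm(12), 4, 3))
  pd <- predict(st, matrix(50), mc = 10)
  expect_true(all(abs(pd$latent_var - 1.9) < 1e-6))
  ## monotone non-decreasing along a ray leaving the inducing set
  ray <- matrix(seq(1, 6, by = 0.5))
  vr <- predict(st, ray, mc = 2)$latent_var[, 1]
  expect_true(all(diff(vr) >= -1e-10))
})

test_that("fit and predict are reproducible under fixed seeds", {
  blobs <- make_blobs(120, d = 3, seed = 6)
  f1 <- fit_svgp(blobs$X, blobs$y, num_inducing = 10, batch_size = 60,
                 epochs = 3, seed = 5)
  f2 <- fit_svgp(blobs$X, blobs$y, num_inducing = 10, batch_size = 60,
                 epochs = 3, seed = 5)
  expect_identical(f1$m, f2$m)
  expect_identical(f1$training_log, f2$training_log)
  p1 <- predict(f1, blobs$X[1:5, ])
  p2 <- predict(f2, blobs$X[1:5, ])
  expect_identical(p1$probs, p2$probs)
})

test_that("fitting requires every class in the training labels", {
  blobs <- make_blobs(60, d = 2, seed = 7)
  y <- blobs$y
  y[y == "uncertain"] <- "negative"
  expect_error(fit_svgp(blobs$X, y, num_inducing = 5, epochs = 2), "uncertain")
})
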