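#' ARD radial-basis-function kernel
#'
#' \deqn{k(x, x') = \sigma^2 \exp\{-\tfrac12 \sum_d (x_d - x'_d)^2 / \ell_d^2\}}
#' with one length scale per input dimension (automatic relevance
#' determination), so irrelevant dimensions can be down-weighted during
#' hyperparameter optimization.
#'
#' @param x,x2 numeric vectors of equal length, or matrices with one point
#'   per row.
#' @param signal_variance positive scalar \eqn{\sigma^2}.
#' @param length_scales positive vector, one per dimension (a scalar is
#'   recycled).
#' @return scalar (vector inputs) or `nrow(x) x nrow(x2)` matrix.
#' @export
rbf_ard <- function(x, x2, signal_variance = 1, length_scales = 1) {
  if (signal_variance <= 0 || any(length_scales <= 0)) {
    stop("rbf_ard: kernel parameters must be strictly positive")
  }
  vec_in <- !is.matrix(x)
  X1 <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  X2 <- if (is.matrix(x2)) x2 else matrix(x2, nrow = 1)
  if (ncol(X1) != ncol(X2)) stop("rbf_ard: dimension mismatch")
  ls <- rep_len(length_scales, ncol(X1))
  K <- signal_variance * exp(-0.5 * ard_sqdist(X1, X2, ls))
  if (vec_in && !is.matrix(x2)) K[1, 1] else K
}

## scaled squared distances sum_d (x1_d - x2_d)^2 / ls_d^2
ard_sqdist <- function(X1, X2, ls) {
  A <- sweep(X1, 2, ls, "/")
  B <- sweep(X2, 2, ls, "/")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

## actual lower-triangular factor from raw parameterization (log diagonal)
lq_actual <- function(Lraw) {
  L <- Lraw
  L[upper.tri(L)] <- 0
  diag(L) <- exp(diag(Lraw))
  L
}

new_svgp_state <- function(Z, log_sv, log_ls, m, Lraw, class_levels,
                           mc_train = 20L, mc_predict = 100L,
                           predict_seed = 1L, jitter = 1e-8,
                           training_log = NULL, config = list()) {
  structure(list(Z = Z, log_sv = log_sv, log_ls = log_ls, m = m, Lraw = Lraw,
                 class_levels = class_levels, mc_train = mc_train,
                 mc_predict = mc_predict, predict_seed = predict_seed,
                 jitter = jitter, training_log = training_log,
                 config = config),
            class = "svgp")
}

#' KL divergence between the variational posterior and the GP prior
#'
#' The model uses the whitened parameterisation, in which the inducing-value
#' prior is standard normal per latent function and the KL is the closed-form
#' Gaussian expression
#' \eqn{\tfrac12 (\|m\|^2 + \|L\|_F^2 - M - 2\sum_i \log L_{ii})}
#' summed over the C latent functions. Equals the KL between the unwhitened
#' variational distribution and the zero-mean prior with covariance
#' \eqn{K_{MM}}; always non-negative, zero iff the variational distribution
#' equals the prior.
#'
#' @param state an `svgp` state (see [fit_svgp()] or [svgp_state()]).
#' @return non-negative scalar.
#' @export
svgp_kl <- function(state) {
  M <- nrow(state$Z)
  kl <- 0
  for (c in seq_len(ncol(state$m))) {
    L <- lq_actual(state$Lraw[[c]])
    kl <- kl + 0.5 * (sum(state$m[, c]^2) + sum(L^2) - M -
                        2 * sum(diag(state$Lraw[[c]])))
  }
  kl
}

#' Assemble an SVGP state from explicit parameters
#'
#' Mostly useful for testing and for constructing untrained reference states.
#' Variational factors are supplied as actual lower-triangular matrices with
#' positive diagonals.
#'
#' @param Z `M x d` inducing inputs.
#' @param signal_variance,length_scales kernel hyperparameters.
#' @param m `M x C` whitened variational means (default zero).
#' @param L list of C lower-triangular `M x M` factors (default identity).
#' @param class_levels class labels (default the three report classes).
#' @param ... further fields passed to the state (e.g. `mc_predict`).
#' @return an `svgp` state.
#' @export
svgp_state <- function(Z, signal_variance = 1, length_scales = 1,
                       m = NULL, L = NULL, class_levels = CLASS_LEVELS, ...) {
  Z <- as.matrix(Z)
  M <- nrow(Z)
  C <- length(class_levels)
  if (is.null(m)) m <- matrix(0, M, C)
  if (is.null(L)) L <- replicate(C, diag(M), simplify = FALSE)
  Lraw <- lapply(L, function(Li) {
    if (any(diag(Li) <= 0)) stop("variational factors need positive diagonals")
    R <- Li
    diag(R) <- log(diag(Li))
    R[upper.tri(R)] <- 0
    R
  })
  new_svgp_state(Z, log_sv = log(signal_variance),
                 log_ls = log(rep_len(length_scales, ncol(Z))),
                 m = m, Lraw = Lraw, class_levels = class_levels, ...)
}

## latent marginal means and variances at X, plus reusable factors
svgp_marginals <- function(state, X, want_factors = FALSE) {
  if (ncol(X) != ncol(state$Z)) stop("svgp: feature dimension mismatch")
  sv <- exp(state$log_sv)
  ls <- exp(state$log_ls)
  C <- ncol(state$m)
  Kmm0 <- sv * exp(-0.5 * ard_sqdist(state$Z, state$Z, ls))
  Lmm <- chol_jitter(Kmm0, jitter = state$jitter)
  Kmx <- sv * exp(-0.5 * ard_sqdist(state$Z, X, ls))
  A <- forwardsolve(Lmm, Kmx)
  mu <- crossprod(A, state$m)
  vr <- matrix(0, nrow(X), C)
  Ls <- lapply(state$Lraw, lq_actual)
  common <- colSums(A^2)
  for (c in seq_len(C)) {
    vr[, c] <- sv - common + colSums(crossprod(Ls[[c]], A)^2)
  }
  vr <- pmax(vr, 1e-12)
  out <- list(mu = mu, var = vr)
  if (want_factors) {
    out$Kmm0 <- Kmm0; out$Lmm <- Lmm; out$Kmx <- Kmx; out$A <- A; out$Ls <- Ls
    out$sv <- sv; out$ls <- ls
  }
  out
}

#' Minibatch evidence lower bound of the SVGP classifier
#'
#' \deqn{\hat{L} = \frac{N}{|B|} \sum_{i \in B}
#'   \hat{E}_{q}[\log p(y_i | f_i)] - KL(q \| p)}
#' where the expected log softmax likelihood is a reparameterised Monte-Carlo
#' average over `mc` standard-normal draws through the marginal latent
#' Gaussians. With `deterministic = TRUE` the latent is fixed at its mean
#' (zero-variance likelihood), which reduces the first term to the plain
#' log-likelihood sum.
#'
#' @param state an `svgp` state.
#' @param X feature matrix rows for the batch.
#' @param y class labels for the batch.
#' @param n_total full training-set size N (defaults to `nrow(X)`).
#' @param mc Monte-Carlo samples (default `state$mc_train`).
#' @param seed optional seed for the draws.
#' @param kl_weight multiplier on the KL term (1 for the proper bound).
#' @param deterministic if `TRUE`, evaluate the likelihood at the latent
#'   means instead of sampling.
#' @return scalar ELBO estimate.
#' @export
svgp_elbo <- function(state, X, y, n_total = nrow(X), mc = NULL, seed = NULL,
                      kl_weight = 1, deterministic = FALSE) {
  y_int <- as.integer(factor(as.character(y), levels = state$class_levels))
  if (anyNA(y_int)) stop("svgp_elbo: labels outside the model's class set")
  mg <- svgp_marginals(state, X)
  B <- nrow(X); C <- ncol(state$m)
  scale <- n_total / B
  if (deterministic) {
    ll <- sum(mg$mu[cbind(seq_len(B), y_int)] - row_logsumexp(mg$mu))
  } else {
    mc <- if (is.null(mc)) state$mc_train else mc
    draw <- function() {
      tot <- 0
      sd_ <- sqrt(mg$var)
      for (s in seq_len(mc)) {
        f <- mg$mu + sd_ * matrix(stats::rnorm(B * C), B, C)
        tot <- tot + sum(f[cbind(seq_len(B), y_int)] - row_logsumexp(f))
      }
      tot / mc
    }
    ll <- if (is.null(seed)) draw() else with_seed(seed, draw())
  }
  scale * ll - kl_weight * svgp_kl(state)
}

## ELBO value and analytic gradients for one minibatch (softmax likelihood,
## whitened variational parameters, shared ARD kernel). Consumes RNG draws
## from the current stream.
svgp_elbo_grad <- function(state, X, y_int, n_total, mc) {
  mg <- svgp_marginals(state, X, want_factors = TRUE)
  M <- nrow(state$Z); B <- nrow(X); C <- ncol(state$m)
  scale <- n_total / B
  sd_ <- sqrt(mg$var)
  onehot <- matrix(0, B, C); onehot[cbind(seq_len(B), y_int)] <- 1

  ll <- 0
  gbar <- matrix(0, B, C)   # mean_s d loglik / d mu
  wvar <- matrix(0, B, C)   # mean_s d loglik / d var
  for (s in seq_len(mc)) {
    eps <- matrix(stats::rnorm(B * C), B, C)
    f <- mg$mu + sd_ * eps
    ll <- ll + sum(f[cbind(seq_len(B), y_int)] - row_logsumexp(f))
    g <- onehot - row_softmax(f)
    gbar <- gbar + g
    wvar <- wvar + g * eps / (2 * sd_)
  }
  ll <- ll / mc; gbar <- gbar / mc; wvar <- wvar / mc

  A <- mg$A; Ls <- mg$Ls
  ## variational mean gradient (likelihood + KL)
  gm <- scale * (A %*% gbar) - state$m
  ## variational factor gradients
  gLraw <- vector("list", C)
  for (c in seq_len(C)) {
    H <- tcrossprod(sweep(A, 2, wvar[, c], "*"), A)
    gL <- scale * 2 * (H %*% Ls[[c]]) - Ls[[c]]
    diag(gL) <- diag(gL) + 1 / diag(Ls[[c]])
    gL[upper.tri(gL)] <- 0
    diag(gL) <- diag(gL) * diag(Ls[[c]])  # chain rule through log-diagonal
    gLraw[[c]] <- gL
  }

  ## kernel hyperparameter gradients (flow through A and the prior variance)
  G1 <- state$m %*% t(gbar)                       # sum_c m_c gbar_c^T
  wsum <- rowSums(wvar)
  Aws <- sweep(A, 2, wsum, "*")
  SAW <- matrix(0, M, B)
  for (c in seq_len(C)) {
    S_c <- tcrossprod(Ls[[c]])
    SAW <- SAW + S_c %*% sweep(A, 2, wvar[, c], "*")
  }
  hyper_dot <- function(dKmm, dKmx, svdot) {
    Phi <- forwardsolve(mg$Lmm, dKmm)
    Phi <- t(forwardsolve(mg$Lmm, t(Phi)))
    Phi[upper.tri(Phi)] <- 0
    diag(Phi) <- diag(Phi) / 2
    dA <- forwardsolve(mg$Lmm, dKmx) - Phi %*% A
    sum(dA * G1) + svdot * sum(wvar) - 2 * sum(Aws * dA) + 2 * sum(SAW * dA)
  }
  g_log_sv <- scale * hyper_dot(mg$Kmm0, mg$Kmx, mg$sv)
  g_log_ls <- numeric(ncol(X))
  for (i in seq_along(g_log_ls)) {
    dzz <- outer(state$Z[, i], state$Z[, i], "-")^2 / mg$ls[i]^2
    dzx <- outer(state$Z[, i], X[, i], "-")^2 / mg$ls[i]^2
    g_log_ls[i] <- scale * hyper_dot(mg$Kmm0 * dzz, mg$Kmx * dzx, 0)
  }

  list(elbo = scale * ll - svgp_kl(state),
       g_m = gm, g_Lraw = gLraw, g_log_sv = g_log_sv, g_log_ls = g_log_ls)
}

## k-means inducing inputs (deterministic given the active RNG stream)
init_inducing <- function(X, M) {
  Xu <- unique(X)
  if (nrow(Xu) <= M) return(Xu)
  km <- suppressWarnings(stats::kmeans(Xu, centers = M, iter.max = 30, nstart = 1))
  km$centers
}

#' Fit the sparse variational GP multiclass classifier
#'
#' One zero-mean latent GP per class with a shared ARD-RBF kernel, M inducing
#' points fixed at k-means centroids of the training features, a whitened
#' full-covariance Gaussian variational posterior per latent function, and a
#' softmax likelihood whose expectation is estimated by reparameterised
#' Monte-Carlo sampling. Trained stochastically with RMSProp on the
#' minibatch evidence lower bound; variational parameters and kernel
#' hyperparameters are optimized jointly via analytic gradients.
#'
#' @param X `n x d` feature matrix.
#' @param labels length-n class labels; all three classes must be present.
#' @param num_inducing number of inducing points M (capped at n).
#' @param learning_rate RMSProp learning rate.
#' @param epochs passes over the data; `NULL` chooses
#'   `max(2, ceiling(200 / updates_per_epoch))` so small corpora still get a
#'   useful number of updates.
#' @param batch_size minibatch size (capped at n).
#' @param mc_train,mc_predict Monte-Carlo samples for training / prediction.
#' @param seed integer seed controlling initialization, batching and MC draws.
#' @param jitter initial diagonal jitter for Cholesky factorizations.
#' @param rmsprop_decay RMSProp second-moment decay.
#' @param verbose print per-epoch ELBO.
#' @return an `svgp` state; `$training_log` holds the per-epoch mean ELBO.
#' @export
fit_svgp <- function(X, labels, num_inducing = 300, learning_rate = 0.003,
                     epochs = NULL, batch_size = 500, mc_train = 20,
                     mc_predict = 100, seed = 1L, jitter = 1e-8,
                     rmsprop_decay = 0.9, verbose = FALSE) {
  X <- as.matrix(X)
  yf <- as_class_factor(labels)
  if (any(table(yf) == 0)) {
    stop("fit_svgp: class(es) missing from training labels: ",
         paste(levels(yf)[table(yf) == 0], collapse = ", "))
  }
  y_int <- as.integer(yf)
  n <- nrow(X); d <- ncol(X); C <- nlevels(yf)
  batch_size <- min(batch_size, n)
  upd_per_epoch <- ceiling(n / batch_size)
  if (is.null(epochs)) epochs <- max(2, ceiling(200 / upd_per_epoch))

  Z <- with_seed(derive_seed(seed, "inducing"), init_inducing(X, min(num_inducing, n)))
  M <- nrow(Z)
  state <- new_svgp_state(
    Z = Z, log_sv = 0,
    log_ls = log(pmax(apply(X, 2, stats::sd), 1e-6) * sqrt(d)),
    m = matrix(0, M, C),
    Lraw = replicate(C, matrix(0, M, M), simplify = FALSE),
    class_levels = levels(yf), mc_train = mc_train, mc_predict = mc_predict,
    predict_seed = derive_seed(seed, "predict"), jitter = jitter,
    config = list(num_inducing = num_inducing, learning_rate = learning_rate,
                  epochs = epochs, batch_size = batch_size, seed = seed))

  ## RMSProp caches
  r_m <- matrix(0, M, C)
  r_L <- replicate(C, matrix(0, M, M), simplify = FALSE)
  r_sv <- 0; r_ls <- numeric(d)
  eps0 <- 1e-8
  step <- function(g, r) learning_rate * g / (sqrt(r) + eps0)

  log_elbo <- numeric(epochs)
  with_seed(derive_seed(seed, "train"), {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      acc <- 0
      for (b in seq_len(upd_per_epoch)) {
        idx <- perm[((b - 1) * batch_size + 1):min(b * batch_size, n)]
        gr <- svgp_elbo_grad(state, X[idx, , drop = FALSE], y_int[idx], n, mc_train)
        if (!all(is.finite(gr$elbo), is.finite(gr$g_m), is.finite(gr$g_log_sv),
                 is.finite(gr$g_log_ls))) {
          stop("fit_svgp: non-finite ELBO/gradient at epoch ", ep, ", batch ", b,
               " (log_sv=", signif(state$log_sv, 4), ")")
        }
        acc <- acc + gr$elbo
        r_m <- rmsprop_decay * r_m + (1 - rmsprop_decay) * gr$g_m^2
        state$m <- state$m + step(gr$g_m, r_m)
        for (c in seq_len(C)) {
          r_L[[c]] <- rmsprop_decay * r_L[[c]] + (1 - rmsprop_decay) * gr$g_Lraw[[c]]^2
          state$Lraw[[c]] <- state$Lraw[[c]] + step(gr$g_Lraw[[c]], r_L[[c]])
        }
        r_sv <- rmsprop_decay * r_sv + (1 - rmsprop_decay) * gr$g_log_sv^2
        state$log_sv <- state$log_sv + step(gr$g_log_sv, r_sv)
        r_ls <- rmsprop_decay * r_ls + (1 - rmsprop_decay) * gr$g_log_ls^2
        state$log_ls <- state$log_ls + step(gr$g_log_ls, r_ls)
      }
      log_elbo[ep] <- acc / upd_per_epoch
      if (verbose) message("epoch ", ep, ": mean ELBO ", signif(log_elbo[ep], 6))
    }
  })
  state$training_log <- data.frame(epoch = seq_len(epochs), elbo = log_elbo)
  state
}

#' Predictive distribution of a fitted SVGP
#'
#' Latent means and variances come from the standard sparse predictive
#' equations; class probabilities are the Monte-Carlo expectation of the
#' softmax over the marginal latent Gaussians, with a fixed prediction seed
#' so repeated calls agree.
#'
#' @param object an `svgp` state.
#' @param X feature matrix (same dimension as training).
#' @param mc Monte-Carlo samples (default `object$mc_predict`).
#' @param seed seed for the draws (default `object$predict_seed`).
#' @param ... unused.
#' @return a `predictive_distribution`: list with `probs` (`n x C`, rows on
#'   the simplex), `latent_mean`, `latent_var`.
#' @export
predict.svgp <- function(object, X, mc = NULL, seed = NULL, ...) {
  X <- as.matrix(X)
  mg <- svgp_marginals(object, X)
  mc <- if (is.null(mc)) object$mc_predict else mc
  seed <- if (is.null(seed)) object$predict_seed else seed
  B <- nrow(X); C <- ncol(object$m)
  sd_ <- sqrt(mg$var)
  P <- with_seed(seed, {
    acc <- matrix(0, B, C)
    for (s in seq_len(mc)) {
      acc <- acc + row_softmax(mg$mu + sd_ * matrix(stats::rnorm(B * C), B, C))
    }
    acc / mc
  })
  colnames(P) <- object$class_levels
  colnames(mg$mu) <- colnames(mg$var) <- object$class_levels
  structure(list(probs = P, latent_mean = mg$mu, latent_var = mg$var),
            class = "predictive_distribution")
}

#' Optimal sparse-GP variational solution under a Gaussian likelihood
#'
#' For a single latent function with Gaussian observation noise the optimal
#' whitened variational parameters are available in closed form:
#' \eqn{S = (I + A A^\top / \sigma_n^2)^{-1}}, \eqn{m = S A y / \sigma_n^2}
#' with \eqn{A = L_{MM}^{-1} K_{MX}}. With the inducing inputs placed at the
#' training inputs the resulting ELBO collapses to the exact GP log marginal
#' likelihood, which [svgp_elbo_gaussian()] exposes for verification.
#'
#' @param X `n x d` inputs.
#' @param y numeric targets.
#' @param signal_variance,length_scales kernel hyperparameters.
#' @param noise_variance Gaussian observation-noise variance.
#' @param Z inducing inputs (default: the training inputs).
#' @param jitter Cholesky jitter.
#' @return list with the whitened optimum (`m`, `S`, `L`), the factors used,
#'   and the inputs.
#' @export
svgp_gaussian_optimal <- function(X, y, signal_variance, length_scales,
                                  noise_variance, Z = X, jitter = 1e-10) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  ls <- rep_len(length_scales, ncol(X))
  Kmm <- rbf_ard(Z, Z, signal_variance, ls)
  Lmm <- chol_jitter(Kmm, jitter = jitter)
  A <- forwardsolve(Lmm, rbf_ard(Z, X, signal_variance, ls))
  S <- solve(diag(nrow(Z)) + tcrossprod(A) / noise_variance)
  S <- (S + t(S)) / 2
  m <- S %*% A %*% y / noise_variance
  list(m = drop(m), S = S, L = chol_jitter(S, jitter = 1e-12), A = A,
       Lmm = Lmm, X = X, Z = Z, signal_variance = signal_variance,
       length_scales = ls, noise_variance = noise_variance)
}

#' Gaussian-likelihood ELBO of a whitened sparse-GP solution
#'
#' Analytic (no Monte Carlo): the expected Gaussian log likelihood minus the
#' whitened KL,
#' \deqn{\sum_i \log N(y_i; \mu_i, \sigma_n^2) - \frac{v_i}{2\sigma_n^2}
#'   - KL(q \| p).}
#'
#' @param sol output of [svgp_gaussian_optimal()] (or any list with the same
#'   fields).
#' @param y numeric targets.
#' @return scalar ELBO.
#' @export
svgp_elbo_gaussian <- function(sol, y) {
  A <- sol$A
  mu <- drop(crossprod(A, sol$m))
  vr <- sol$signal_variance - colSums(A^2) + colSums((crossprod(sol$L, A))^2)
  sn2 <- sol$noise_variance
  ell <- sum(stats::dnorm(y, mu, sqrt(sn2), log = TRUE)) - sum(vr) / (2 * sn2)
  kl <- 0.5 * (sum(sol$m^2) + sum(diag(sol$S)) - nrow(sol$S) -
                 determinant(sol$S, logarithm = TRUE)$modulus[1])
  ell - kl
}
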