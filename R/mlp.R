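## Multilayer perceptron with batch normalization, written with explicit
## forward/backward passes: the backward pass also yields the loss gradient
## with respect to the inputs, which fast-gradient-sign adversarial training
## needs and which off-the-shelf R fitters do not expose.

BN_EPS <- 1e-5

mlp_init <- function(d_in, hidden, d_out) {
  sizes <- c(d_in, hidden, d_out)
  L <- length(sizes) - 1L
  params <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    params[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[l + 1]),
      b = numeric(sizes[l + 1]))
    if (l < L) {  # batch norm on hidden layers
      params[[l]]$gamma <- rep(1, sizes[l + 1])
      params[[l]]$beta <- numeric(sizes[l + 1])
      params[[l]]$run_mean <- numeric(sizes[l + 1])
      params[[l]]$run_var <- rep(1, sizes[l + 1])
    }
  }
  list(params = params, n_layers = L, sizes = sizes)
}

mlp_forward <- function(net, X, training = TRUE, update_running = FALSE,
                        momentum = 0.9) {
  L <- net$n_layers
  cache <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    p <- net$params[[l]]
    Z <- H %*% p$W
    Z <- sweep(Z, 2, p$b, "+")
    if (l < L) {
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(Z^2) - mu^2
        if (update_running) {
          net$params[[l]]$run_mean <- momentum * p$run_mean + (1 - momentum) * mu
          net$params[[l]]$run_var <- momentum * p$run_var + (1 - momentum) * v
        }
      } else {
        mu <- p$run_mean
        v <- p$run_var
      }
      xhat <- sweep(sweep(Z, 2, mu, "-"), 2, sqrt(v + BN_EPS), "/")
      A <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
      out <- pmax(A, 0)
      cache[[l]] <- list(input = H, xhat = xhat, v = v, act = out)
      H <- out
    } else {
      cache[[l]] <- list(input = H)
      H <- Z
    }
  }
  list(logits = H, cache = cache, net = net)
}

## mean softmax cross-entropy and gradients for all parameters plus inputs
mlp_backward <- function(net, fwd, y_int) {
  B <- nrow(fwd$logits)
  L <- net$n_layers
  P <- row_softmax(fwd$logits)
  loss <- -mean(log(pmax(P[cbind(seq_len(B), y_int)], 1e-300)))
  onehot <- matrix(0, B, ncol(P)); onehot[cbind(seq_len(B), y_int)] <- 1
  delta <- (P - onehot) / B
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    p <- net$params[[l]]
    cc <- fwd$cache[[l]]
    if (l < L) {
      ## through ReLU then batch norm
      delta <- delta * (cc$act > 0)
      dgamma <- colSums(delta * cc$xhat)
      dbeta <- colSums(delta)
      dxhat <- sweep(delta, 2, p$gamma, "*")
      inv_sd <- 1 / sqrt(cc$v + BN_EPS)
      dZ <- sweep(dxhat -
                    matrix(colMeans(dxhat), B, ncol(dxhat), byrow = TRUE) -
                    cc$xhat * matrix(colMeans(dxhat * cc$xhat), B, ncol(dxhat),
                                     byrow = TRUE),
                  2, inv_sd, "*")
      grads[[l]] <- list(W = crossprod(cc$input, dZ), b = colSums(dZ),
                         gamma = dgamma, beta = dbeta)
      delta <- tcrossprod(dZ, p$W)
    } else {
      grads[[l]] <- list(W = crossprod(cc$input, delta), b = colSums(delta))
      delta <- tcrossprod(delta, p$W)
    }
  }
  list(loss = loss, grads = grads, dX = delta)
}

#' Fast gradient sign method perturbation
#'
#' Returns `x + epsilon * sign(loss_gradient)` with `sign(0) = 0`. `epsilon`
#' may be a scalar or a per-feature vector (recycled across the columns of a
#' matrix input).
#'
#' @param x numeric vector, or matrix with one example per row.
#' @param loss_gradient gradient of the loss with respect to `x`, same shape.
#' @param epsilon non-negative scalar or per-feature vector.
#' @return perturbed input, same shape as `x`.
#' @export
fgsm_perturb <- function(x, loss_gradient, epsilon) {
  if (any(epsilon < 0)) stop("fgsm_perturb: epsilon must be non-negative")
  s <- sign(loss_gradient)
  if (is.matrix(x)) {
    x + sweep(s, 2, rep_len(epsilon, ncol(x)), "*")
  } else {
    x + rep_len(epsilon, length(x)) * s
  }
}

adam_update <- function(param, grad, state, lr, t, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^t)
  vhat <- state$v / (1 - b2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

train_mlp_member <- function(X, y_int, n_classes, hidden, lr, epochs,
                             batch_size, epsilon, member_seed) {
  n <- nrow(X)
  with_seed(member_seed, {
    net <- mlp_init(ncol(X), hidden, n_classes)
    opt <- lapply(net$params, function(p) {
      lapply(p[intersect(names(p), c("W", "b", "gamma", "beta"))],
             function(q) list(m = q * 0, v = q * 0))
    })
    t_step <- 0L
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      nb <- ceiling(n / batch_size)
      for (b in seq_len(nb)) {
        idx <- perm[((b - 1) * batch_size + 1):min(b * batch_size, n)]
        Xb <- X[idx, , drop = FALSE]; yb <- y_int[idx]
        fwd <- mlp_forward(net, Xb, training = TRUE, update_running = TRUE)
        net <- fwd$net
        bw_c <- mlp_backward(net, fwd, yb)
        Xa <- fgsm_perturb(Xb, bw_c$dX, epsilon)
        fwd_a <- mlp_forward(net, Xa, training = TRUE, update_running = FALSE)
        bw_a <- mlp_backward(net, fwd_a, yb)
        loss <- (bw_c$loss + bw_a$loss) / 2
        if (!is.finite(loss)) {
          stop("fit_ensemble: member with seed ", member_seed,
               " diverged (non-finite loss at epoch ", ep, ")")
        }
        t_step <- t_step + 1L
        for (l in seq_len(net$n_layers)) {
          for (nm in names(opt[[l]])) {
            g <- (bw_c$grads[[l]][[nm]] + bw_a$grads[[l]][[nm]]) / 2
            up <- adam_update(net$params[[l]][[nm]], g, opt[[l]][[nm]], lr, t_step)
            net$params[[l]][[nm]] <- up$param
            opt[[l]][[nm]] <- up$state
          }
        }
      }
    }
    net
  })
}

#' Fit a deep ensemble of adversarially trained MLPs
#'
#' `n_members` multilayer perceptrons (three hidden layers of
#' `hidden_units` units with batch normalization by default) are trained
#' independently from distinct member seeds with Adam on softmax
#' cross-entropy; each minibatch loss averages the clean batch and its fast
#' gradient sign method (FGSM) perturbation. The ensemble's predictive
#' distribution is the arithmetic mean of the member distributions.
#'
#' @param X `n x d` feature matrix.
#' @param labels length-n class labels (all three classes required).
#' @param n_members ensemble size (at least 2).
#' @param hidden_units,n_hidden hidden-layer width and count.
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs per member.
#' @param batch_size minibatch size.
#' @param adversarial_epsilon FGSM step; default `0.01 *` the per-feature
#'   interquartile range of the training features, scaling the perturbation
#'   to the input range.
#' @param member_seeds optional distinct integer seeds, one per member.
#' @param seed global seed from which member seeds are derived when not given.
#' @return object of class `deep_ensemble`.
#' @export
fit_ensemble <- function(X, labels, n_members = 5, hidden_units = 200,
                         n_hidden = 3, learning_rate = 3e-3, epochs = 10,
                         batch_size = 100, adversarial_epsilon = NULL,
                         member_seeds = NULL, seed = 1L) {
  X <- as.matrix(X)
  yf <- as_class_factor(labels)
  if (any(table(yf) == 0)) {
    stop("fit_ensemble: class(es) missing from training labels: ",
         paste(levels(yf)[table(yf) == 0], collapse = ", "))
  }
  if (n_members < 2) stop("fit_ensemble: n_members must be at least 2")
  if (is.null(member_seeds)) {
    member_seeds <- vapply(seq_len(n_members),
                           function(i) derive_seed(seed, paste0("member:", i)),
                           integer(1))
  }
  if (anyDuplicated(member_seeds)) stop("fit_ensemble: member seeds must be distinct")
  if (is.null(adversarial_epsilon)) {
    iqr <- apply(X, 2, stats::IQR)
    adversarial_epsilon <- 0.01 * iqr
  }
  members <- lapply(member_seeds, function(ms) {
    train_mlp_member(X, as.integer(yf), nlevels(yf),
                     rep(hidden_units, n_hidden), learning_rate, epochs,
                     min(batch_size, nrow(X)), adversarial_epsilon, ms)
  })
  structure(list(members = members, member_seeds = member_seeds,
                 class_levels = levels(yf),
                 config = list(n_members = n_members,
                               hidden_units = hidden_units,
                               n_hidden = n_hidden,
                               learning_rate = learning_rate,
                               epochs = epochs, batch_size = batch_size,
                               adversarial_epsilon = adversarial_epsilon)),
            class = "deep_ensemble")
}

#' Ensemble predictive distribution
#'
#' @param model a `deep_ensemble`.
#' @param X feature matrix.
#' @param return_members if `TRUE`, also return each member's probability
#'   matrix (used e.g. to verify the Jensen relation between ensemble and
#'   member NLPP).
#' @return a `predictive_distribution` (with `$member_probs` when requested).
#' @export
predict_ensemble <- function(model, X, return_members = FALSE) {
  stopifnot(inherits(model, "deep_ensemble"))
  X <- as.matrix(X)
  member_probs <- lapply(model$members, function(net) {
    row_softmax(mlp_forward(net, X, training = FALSE)$logits)
  })
  P <- Reduce(`+`, member_probs) / length(member_probs)
  colnames(P) <- model$class_levels
  out <- structure(list(probs = P), class = "predictive_distribution")
  if (return_members) out$member_probs <- member_probs
  out
}

#' @export
predict.deep_ensemble <- function(object, X, ...) predict_ensemble(object, X, ...)
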