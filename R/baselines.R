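## one-vs-rest isotonic calibration map fitted on (raw score, indicator)
## pairs; returns a monotone interpolator plus its knots for inspection.
fit_isotonic_map <- function(score, indicator) {
  o <- order(score)
  iso <- stats::isoreg(score[o], indicator[o])
  xs <- score[o]
  ys <- iso$yf
  ## collapse duplicate scores to a single knot (isoreg fit is constant there)
  kx <- unique(xs)
  ky <- as.numeric(tapply(ys, match(xs, kx), mean))
  if (length(kx) == 1) {
    f <- function(s) rep(ky, length(s))
  } else {
    f <- stats::approxfun(kx, ky, method = "linear", rule = 2)
  }
  list(map = f, knots = data.frame(x = kx, y = ky))
}

#' Fit the calibrated random-forest baseline
#'
#' A probability forest (300 trees, maximum depth 40 by default) trained on
#' the primary labels, followed by per-class one-vs-rest isotonic regression
#' fitted on a calibration set disjoint from training (the validation split
#' in the pipeline), with the calibrated scores renormalized to the simplex.
#' A class absent from the calibration set keeps its raw scores (identity
#' map) with a warning.
#'
#' @param X training feature matrix.
#' @param labels training class labels.
#' @param cal_X,cal_labels calibration features and labels (disjoint from
#'   training).
#' @param n_trees,max_depth forest size and depth cap.
#' @param seed integer seed.
#' @return object of class `rf_calibrated`.
#' @export
fit_forest <- function(X, labels, cal_X, cal_labels,
                       n_trees = 300, max_depth = 40, seed = 1L) {
  stopifnot(n_trees >= 1, max_depth >= 1)
  yf <- as_class_factor(labels)
  df <- data.frame(y = yf, as.data.frame(X))
  forest <- ranger::ranger(y ~ ., data = df, num.trees = n_trees,
                           max.depth = max_depth, probability = TRUE,
                           seed = derive_seed(seed, "forest"),
                           num.threads = 1)
  raw_cal <- stats::predict(forest, data = as.data.frame(cal_X))$predictions
  raw_cal <- raw_cal[, CLASS_LEVELS, drop = FALSE]
  calf <- as_class_factor(cal_labels)
  maps <- vector("list", length(CLASS_LEVELS))
  names(maps) <- CLASS_LEVELS
  for (cl in CLASS_LEVELS) {
    if (!any(calf == cl)) {
      warning("fit_forest: class '", cl,
              "' absent from calibration set; using identity map")
      maps[[cl]] <- list(map = identity, knots = NULL)
    } else {
      maps[[cl]] <- fit_isotonic_map(raw_cal[, cl], as.numeric(calf == cl))
    }
  }
  structure(list(forest = forest, maps = maps, class_levels = CLASS_LEVELS,
                 config = list(n_trees = n_trees, max_depth = max_depth,
                               calibration = "isotonic", seed = seed)),
            class = "rf_calibrated")
}

## apply per-class maps and renormalize; degenerate all-zero rows -> uniform
calibrate_probs <- function(raw, maps) {
  out <- raw
  for (cl in colnames(raw)) {
    out[, cl] <- pmax(maps[[cl]]$map(raw[, cl]), 0)
  }
  z <- rowSums(out)
  bad <- z <= 0
  if (any(bad)) out[bad, ] <- 1 / ncol(out)
  out[!bad, ] <- out[!bad, , drop = FALSE] / z[!bad]
  out
}

#' Predictive distribution of the calibrated forest
#'
#' @param model an `rf_calibrated`.
#' @param X feature matrix.
#' @param calibrated if `FALSE`, return the raw forest class frequencies.
#' @return a `predictive_distribution`.
#' @export
predict_forest <- function(model, X, calibrated = TRUE) {
  stopifnot(inherits(model, "rf_calibrated"))
  raw <- stats::predict(model$forest, data = as.data.frame(as.matrix(X)))$predictions
  raw <- raw[, model$class_levels, drop = FALSE]
  P <- if (calibrated) calibrate_probs(raw, model$maps) else raw
  structure(list(probs = P), class = "predictive_distribution")
}

#' @export
predict.rf_calibrated <- function(object, X, ...) predict_forest(object, X, ...)
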