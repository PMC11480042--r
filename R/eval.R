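PROB_FLOOR <- 1e-12

get_probs <- function(probs) {
  if (inherits(probs, "predictive_distribution")) probs <- probs$probs
  probs <- as.matrix(probs)
  assert_simplex_rows(probs)
  probs
}

#' Argmax class predictions from a probability matrix
#'
#' Ties are broken toward the lower class index (positive < uncertain <
#' negative) and counted via the `"n_ties"` attribute.
#'
#' @param probs `n x 3` simplex rows (or a `predictive_distribution`).
#' @return character vector of predicted classes.
#' @export
predicted_classes <- function(probs) {
  P <- get_probs(probs)
  idx <- apply(P, 1L, which.max)  # which.max takes the first (lowest) index
  n_ties <- sum(apply(P, 1L, function(r) sum(r == max(r)) > 1))
  if (n_ties > 0) message("predicted_classes: ", n_ties, " argmax tie(s), broken toward the lower class index")
  out <- CLASS_LEVELS[idx]
  attr(out, "n_ties") <- n_ties
  out
}

#' Classification accuracy
#'
#' Fraction of rows whose argmax class equals the truth.
#'
#' @param probs `n x 3` simplex rows.
#' @param truth length-n class labels.
#' @return real in `[0, 1]`.
#' @export
accuracy <- function(probs, truth) {
  P <- get_probs(probs)
  truth <- as.character(truth)
  if (nrow(P) != length(truth)) stop("accuracy: length mismatch")
  if (nrow(P) == 0) stop("accuracy: empty input")
  mean(predicted_classes(P) == truth)
}

#' Negative log predictive probability
#'
#' \deqn{NLPP = -\frac1n \sum_i \ln \max(p_i(y_i), 10^{-12})}
#' (natural log; the floor keeps degenerate predictions finite, and its use
#' is reported via a message).
#'
#' @param probs `n x 3` simplex rows.
#' @param truth length-n class labels.
#' @return non-negative real.
#' @export
nlpp <- function(probs, truth) {
  P <- get_probs(probs)
  truth <- as.character(truth)
  if (nrow(P) != length(truth)) stop("nlpp: length mismatch")
  if (nrow(P) == 0) stop("nlpp: empty input")
  idx <- match(truth, CLASS_LEVELS)
  if (anyNA(idx)) stop("nlpp: unknown truth label")
  p <- P[cbind(seq_len(nrow(P)), idx)]
  n_floor <- sum(p < PROB_FLOOR)
  if (n_floor > 0) message("nlpp: probability floor applied to ", n_floor, " row(s)")
  mean(-log(pmax(p, PROB_FLOOR)))
}

#' Mean maximum predicted confidence level
#'
#' Mean over rows of the largest class probability; lies in `[1/3, 1]` for
#' three classes. An empty input yields `NA_real_` (an explicit
#' undefined-marker, mirroring how empty groups are reported downstream).
#'
#' @param probs `n x 3` simplex rows.
#' @return real in `[1/3, 1]`, or `NA_real_` for an empty set.
#' @export
mmpcl <- function(probs) {
  if (inherits(probs, "predictive_distribution")) probs <- probs$probs
  probs <- as.matrix(probs)
  if (nrow(probs) == 0) return(NA_real_)
  assert_simplex_rows(probs)
  mean(apply(probs, 1L, max))
}

#' Group-wise MMPCL for false negatives and true positives of one class
#'
#' For `class_c` (positive or uncertain — the negative class is ignored in
#' the asymmetric-risk analysis): the FN group contains rows whose truth is
#' `class_c` but whose prediction is not; the TP group contains rows with
#' truth = prediction = `class_c`. MMPCL is computed within each group;
#' empty groups are reported as `NA` with their count, never silently
#' dropped.
#'
#' @param probs `n x 3` simplex rows.
#' @param truth length-n true labels.
#' @param predicted length-n predicted labels (defaults to the argmax of
#'   `probs`).
#' @param class_c `"positive"` or `"uncertain"`.
#' @return data.frame with columns `group` (`FN`, `TP`), `mmpcl`, `n`.
#' @export
groupwise_mmpcl <- function(probs, truth, predicted = NULL, class_c) {
  stopifnot(class_c %in% c("positive", "uncertain"))
  P <- get_probs(probs)
  truth <- as.character(truth)
  if (is.null(predicted)) predicted <- predicted_classes(P)
  predicted <- as.character(predicted)
  fn <- truth == class_c & predicted != class_c
  tp <- truth == class_c & predicted == class_c
  val <- function(sel) if (any(sel)) mmpcl(P[sel, , drop = FALSE]) else NA_real_
  data.frame(group = c("FN", "TP"),
             mmpcl = c(val(fn), val(tp)),
             n = c(sum(fn), sum(tp)),
             stringsAsFactors = FALSE)
}

#' Reliability analysis and expected calibration error
#'
#' Bins predictions by maximum probability into `n_bins` equal-width bins on
#' `[0, 1]` and compares within-bin mean confidence with within-bin accuracy;
#' \deqn{ECE = \sum_b \frac{n_b}{n} |acc_b - conf_b|.}
#'
#' @param probs `n x 3` simplex rows.
#' @param truth length-n class labels.
#' @param n_bins number of equal-width bins (default 10).
#' @return list with `table` (per-bin counts, confidence, accuracy) and
#'   `ece`.
#' @export
reliability_analysis <- function(probs, truth, n_bins = 10) {
  P <- get_probs(probs)
  truth <- as.character(truth)
  if (nrow(P) < n_bins) stop("reliability_analysis: need at least n_bins rows")
  conf <- apply(P, 1L, max)
  correct <- predicted_classes(P) == truth
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(conf, edges, rightmost.closed = TRUE), 1L), n_bins)
  tab <- data.frame(bin = seq_len(n_bins),
                    lower = edges[-(n_bins + 1)], upper = edges[-1],
                    n = 0L, confidence = NA_real_, accuracy = NA_real_)
  for (b in seq_len(n_bins)) {
    sel <- bin == b
    tab$n[b] <- sum(sel)
    if (any(sel)) {
      tab$confidence[b] <- mean(conf[sel])
      tab$accuracy[b] <- mean(correct[sel])
    }
  }
  nz <- tab$n > 0
  ece <- sum(tab$n[nz] / nrow(P) * abs(tab$accuracy[nz] - tab$confidence[nz]))
  list(table = tab, ece = ece)
}

#' Aggregate per-repeat, per-variant predictions into an evaluation report
#'
#' `runs` is a list with one element per split repetition; each element is a
#' named list of test variants, and each variant is a list with `probs`
#' (simplex rows) and `truth` (labels). Per-variant accuracy, NLPP and MMPCL
#' are computed per repeat and averaged; group-wise FN/TP MMPCL is computed
#' for the positive and uncertain classes. Headline values are arithmetic
#' means over repeats; every raw per-repeat value is retained. Group-wise
#' means average the repeats in which the group is non-empty (the reported
#' `n` is the total group count; a group empty in every repeat stays `NA`).
#'
#' @param runs list of repeats as described above.
#' @return object of class `eval_report` with `summary`, `groupwise`, and
#'   `per_repeat`.
#' @export
evaluate_run <- function(runs) {
  stopifnot(length(runs) >= 1)
  variants <- names(runs[[1]])
  if (is.null(variants) || any(!nzchar(variants))) {
    stop("evaluate_run: variants must be named")
  }
  for (r in seq_along(runs)) {
    missing <- setdiff(variants, names(runs[[r]]))
    if (length(missing) > 0) {
      stop("evaluate_run: repeat ", r, " is missing variant(s): ",
           paste(missing, collapse = ", "))
    }
  }
  per_repeat <- list()
  for (r in seq_along(runs)) {
    for (v in variants) {
      entry <- runs[[r]][[v]]
      P <- get_probs(entry$probs)
      truth <- as.character(entry$truth)
      if (nrow(P) == 0) {
        metrics <- data.frame(repeat_id = r, variant = v, n = 0L,
                              accuracy = NA_real_, nlpp = NA_real_,
                              mmpcl = NA_real_)
        gw <- NULL
      } else {
        pred <- predicted_classes(P)
        metrics <- data.frame(repeat_id = r, variant = v, n = nrow(P),
                              accuracy = accuracy(P, truth),
                              nlpp = nlpp(P, truth),
                              mmpcl = mmpcl(P))
        gw <- do.call(rbind, lapply(c("positive", "uncertain"), function(cl) {
          g <- groupwise_mmpcl(P, truth, pred, cl)
          g$class <- cl; g$repeat_id <- r; g$variant <- v
          g
        }))
      }
      per_repeat[[length(per_repeat) + 1L]] <- list(metrics = metrics, groupwise = gw)
    }
  }
  metrics_all <- do.call(rbind, lapply(per_repeat, `[[`, "metrics"))
  gw_all <- do.call(rbind, Filter(Negate(is.null),
                                  lapply(per_repeat, `[[`, "groupwise")))
  summary <- do.call(rbind, lapply(variants, function(v) {
    m <- metrics_all[metrics_all$variant == v, ]
    data.frame(variant = v, n_repeats = nrow(m), n = mean(m$n),
               accuracy = mean(m$accuracy), nlpp = mean(m$nlpp),
               mmpcl = mean(m$mmpcl), stringsAsFactors = FALSE)
  }))
  groupwise <- NULL
  if (!is.null(gw_all)) {
    combos <- unique(gw_all[, c("variant", "class", "group")])
    groupwise <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      sel <- gw_all$variant == combos$variant[i] &
        gw_all$class == combos$class[i] & gw_all$group == combos$group[i]
      g <- gw_all[sel, ]
      data.frame(variant = combos$variant[i], class = combos$class[i],
                 group = combos$group[i],
                 mmpcl = if (all(is.na(g$mmpcl))) NA_real_ else mean(g$mmpcl, na.rm = TRUE),
                 n = sum(g$n), stringsAsFactors = FALSE)
    }))
  }
  structure(list(summary = summary, groupwise = groupwise,
                 per_repeat = list(metrics = metrics_all, groupwise = gw_all),
                 n_repeats = length(runs)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report (", x$n_repeats, " repeat(s))\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param report an `eval_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, na = "null")
  invisible(path)
}

#' Read an evaluation report written by [write_report()]
#' @param path JSON file.
#' @return an `eval_report`.
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$summary <- as.data.frame(obj$summary)
  if (!is.null(obj$groupwise)) obj$groupwise <- as.data.frame(obj$groupwise)
  structure(obj, class = "eval_report")
}
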