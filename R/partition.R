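## largest-remainder allocation of `total` across weights
largest_remainder <- function(weights, total) {
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Stratifies by the primary (training-target) label with largest-remainder
#' rounding of the per-class validation and test counts, so split class
#' proportions track the corpus within one report per class. Deterministic
#' for a fixed seed.
#'
#' @param corpus a `labelled_corpus`.
#' @param val_fraction,test_fraction held-out fractions (default 0.10 each).
#' @param seed integer seed.
#' @return object of class `split_plan` with disjoint `train_ids`, `val_ids`,
#'   `test_ids` covering the corpus.
#' @export
make_split <- function(corpus, val_fraction = 0.10, test_fraction = 0.10, seed) {
  stopifnot(inherits(corpus, "labelled_corpus"),
            val_fraction > 0, test_fraction > 0,
            val_fraction + test_fraction < 1)
  r <- corpus$reports
  counts <- table(factor(r$primary_label, levels = CLASS_LEVELS))
  small <- names(counts)[counts < 10]
  if (length(small) > 0) {
    stop("too few reports to stratify class(es): ", paste(small, collapse = ", "))
  }
  n <- nrow(r)
  n_test_c <- largest_remainder(as.numeric(counts), round(test_fraction * n))
  n_val_c <- largest_remainder(as.numeric(counts), round(val_fraction * n))
  with_seed(seed, {
    train <- val <- test <- character(0)
    for (k in seq_along(CLASS_LEVELS)) {
      ids <- r$report_id[r$primary_label == CLASS_LEVELS[k]]
      ids <- sample(ids)
      test <- c(test, ids[seq_len(n_test_c[k])])
      val <- c(val, ids[n_test_c[k] + seq_len(n_val_c[k])])
      train <- c(train, ids[-seq_len(n_test_c[k] + n_val_c[k])])
    }
    structure(list(train_ids = sort(train), val_ids = sort(val),
                   test_ids = sort(test),
                   val_fraction = val_fraction, test_fraction = test_fraction,
                   seed = seed),
              class = "split_plan")
  })
}

#' Build the consistent and inconsistent test-set variants
#'
#' Within the test partition: reports where the two labellers agree form the
#' consistent pool (truth = the shared label); reports where they disagree
#' form one id set evaluated twice — against the secondary labels
#' (`NegINCONSTest` role) and against the primary labels (`CheXINCONSTest`
#' role). A consistent subsample of the same cardinality as the inconsistent
#' set is drawn uniformly without replacement for size-matched comparison.
#'
#' @param corpus a `labelled_corpus`.
#' @param split a `split_plan`.
#' @param seed integer seed for the consistent subsample.
#' @return object of class `test_variants`: id vectors `cons_ids`,
#'   `cons_subsample_ids`, `incons_ids` and named truth vectors `cons_truth`,
#'   `neg_incons_truth`, `chex_incons_truth`.
#' @export
make_test_variants <- function(corpus, split, seed) {
  stopifnot(inherits(corpus, "labelled_corpus"), inherits(split, "split_plan"))
  r <- corpus$reports
  te <- r[match(split$test_ids, r$report_id), ]
  agree <- te$primary_label == te$secondary_label
  cons_ids <- te$report_id[agree]
  incons_ids <- te$report_id[!agree]
  cons_truth <- stats::setNames(te$primary_label[agree], cons_ids)
  if (length(incons_ids) == 0) {
    warning("make_test_variants: no inconsistent reports in the test set; ",
            "inconsistent variants are empty")
    sub_ids <- character(0)
  } else {
    sub_ids <- with_seed(seed, sort(sample(cons_ids, min(length(incons_ids),
                                                         length(cons_ids)))))
  }
  structure(list(
    cons_ids = cons_ids,
    cons_subsample_ids = sub_ids,
    incons_ids = incons_ids,
    cons_truth = cons_truth,
    cons_subsample_truth = cons_truth[sub_ids],
    neg_incons_truth = stats::setNames(te$secondary_label[!agree], incons_ids),
    chex_incons_truth = stats::setNames(te$primary_label[!agree], incons_ids),
    seed = seed
  ), class = "test_variants")
}
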