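#' Default token lexicon for the synthetic report generator
#'
#' Four token groups mirror the lexical cues rule-based radiology-report
#' labellers key on: affirmative disease mentions, negation cues, hedging
#' terms, and neutral filler. The lists are small on purpose: class signal in
#' the mean-pooled features comes from group frequencies, not from individual
#' word identity.
#'
#' @return named list with character vectors `affirmative`, `negation`,
#'   `hedging`, `filler`.
#' @export
default_vocab <- function() {
  list(
    affirmative = c("edema", "oedema", "congestion", "opacities", "effusions",
                    "consolidation", "engorgement", "haziness"),
    negation    = c("no", "without", "absent", "resolved", "clear"),
    hedging     = c("possible", "probable", "likely", "may", "suggest",
                    "borderline", "questionable", "equivocal"),
    filler      = c("the", "is", "are", "chest", "radiograph", "portable",
                    "view", "comparison", "prior", "stable", "unchanged",
                    "heart", "size", "normal", "lungs", "pleural",
                    "silhouette", "contour", "mediastinal", "tube", "line",
                    "position", "interval", "again", "seen", "noted", "right",
                    "left", "bilateral", "lower", "upper", "lobe", "findings",
                    "impression", "exam", "study", "patient", "overall",
                    "limits", "within")
  )
}

#' Severity model governing synthetic corpus generation
#'
#' Each report carries a latent severity \eqn{s \sim U(0,1)} mapped to the
#' three ordered classes (negative < uncertain < positive) by two thresholds
#' placed to reproduce `class_proportions`. Documents whose severity lies
#' within `boundary_width` of a threshold are "borderline"; a subset of these
#' receives deliberately ambiguous token patterns on which the two labeller
#' rules disagree, so that the overall disagreement fraction matches
#' `disagreement_rate`.
#'
#' Defaults emulate the consistent-partition class counts
#' 26,455 / 11,781 / 25,246 (positive / uncertain / negative), a ~4 percent
#' labeller-disagreement rate, and a mean document length of 43.5 tokens.
#'
#' @param class_proportions length-3 numeric on the simplex, ordered
#'   (positive, uncertain, negative).
#' @param boundary_width half-width (in severity units) of the borderline
#'   band around each class threshold.
#' @param disagreement_rate target fraction of documents on which the two
#'   labellers disagree.
#' @param mean_doc_length mean token count (Poisson, truncated at 3).
#' @param vocab_spec token lexicon, see [default_vocab()].
#' @return object of class `severity_model`.
#' @export
severity_model <- function(class_proportions = c(26455, 11781, 25246) / 63482,
                           boundary_width = 0.025,
                           disagreement_rate = 0.04,
                           mean_doc_length = 43.5,
                           vocab_spec = default_vocab()) {
  stopifnot(length(class_proportions) == 3, all(class_proportions > 0),
            abs(sum(class_proportions) - 1) <= 1e-9,
            boundary_width >= 0, disagreement_rate >= 0,
            mean_doc_length > 0)
  for (grp in c("affirmative", "negation", "hedging", "filler")) {
    if (length(vocab_spec[[grp]]) == 0) stop("empty token group: ", grp)
  }
  names(class_proportions) <- CLASS_LEVELS
  ## severity axis runs negative -> uncertain -> positive
  t_neg_unc <- unname(class_proportions["negative"])
  t_unc_pos <- unname(class_proportions["negative"] + class_proportions["uncertain"])
  structure(list(
    class_proportions = class_proportions,
    boundary_width = boundary_width,
    disagreement_rate = disagreement_rate,
    mean_doc_length = mean_doc_length,
    vocab_spec = vocab_spec,
    thresholds = c(neg_unc = t_neg_unc, unc_pos = t_unc_pos)
  ), class = "severity_model")
}

#' Deterministic rule labeller
#'
#' A labeller is a pure function of the token list: it counts hedging tokens
#' and affirmative tokens, with any affirmative token occurring at most
#' `negation_scope` tokens after a negation cue neutralized. Verdict order:
#' `uncertain` if the hedging count reaches `hedging_threshold`, else
#' `positive` if any non-neutralized affirmative token remains, else
#' `negative`. A lower `hedging_threshold` / wider `negation_scope` makes a
#' labeller more conservative (more "uncertain", fewer "positive" verdicts);
#' `conservativeness` records that bias on a 0-1 scale for diagnostics.
#'
#' @param hedging_threshold non-negative integer.
#' @param negation_scope non-negative integer window.
#' @param conservativeness real in `[0, 1]`.
#' @param vocab token lexicon the rule keys on, see [default_vocab()].
#' @return object of class `labeller_rule`.
#' @export
labeller_rule <- function(hedging_threshold, negation_scope,
                          conservativeness = 0.5, vocab = default_vocab()) {
  stopifnot(hedging_threshold >= 0, negation_scope >= 0,
            conservativeness >= 0, conservativeness <= 1)
  structure(list(hedging_threshold = as.integer(hedging_threshold),
                 negation_scope = as.integer(negation_scope),
                 conservativeness = conservativeness,
                 vocab = vocab),
            class = "labeller_rule")
}

#' Default primary (more conservative) labeller rule
#' @return a `labeller_rule`.
#' @export
primary_rule <- function() labeller_rule(2L, 2L, conservativeness = 0.8)

#' Default secondary (less conservative) labeller rule
#' @return a `labeller_rule`.
#' @export
secondary_rule <- function() labeller_rule(3L, 1L, conservativeness = 0.2)

#' Apply a labeller rule to a token list
#'
#' @param rule a [labeller_rule()].
#' @param tokens non-empty character vector.
#' @return one of `"positive"`, `"uncertain"`, `"negative"`.
#' @export
apply_labeller <- function(rule, tokens) {
  stopifnot(inherits(rule, "labeller_rule"))
  if (length(tokens) == 0) stop("apply_labeller: empty token list")
  v <- rule$vocab
  n_hedge <- sum(tokens %in% v$hedging)
  if (n_hedge >= rule$hedging_threshold) return("uncertain")
  aff_pos <- which(tokens %in% v$affirmative)
  if (length(aff_pos) > 0 && rule$negation_scope > 0) {
    neg_pos <- which(tokens %in% v$negation)
    if (length(neg_pos) > 0) {
      neutral <- vapply(aff_pos, function(i) {
        any(neg_pos >= i - rule$negation_scope & neg_pos < i)
      }, logical(1))
      aff_pos <- aff_pos[!neutral]
    }
  }
  if (length(aff_pos) > 0) "positive" else "negative"
}

severity_class <- function(s, thresholds) {
  ifelse(s < thresholds["neg_unc"], "negative",
         ifelse(s < thresholds["unc_pos"], "uncertain", "positive"))
}

## which ambiguous patterns the given rule pair can realize, with the
## qualitative mix observed between a conservative and a lenient labeller:
## mostly (uncertain, negative), some (negative, positive) via negation-scope
## differences, a little (uncertain, positive).
feasible_patterns <- function(rp, rs) {
  pats <- list()
  if (rp$hedging_threshold < rs$hedging_threshold &&
      rp$negation_scope >= 1 && rs$negation_scope >= 1) {
    pats$unc_neg <- 0.70
    pats$unc_pos <- 0.12
  }
  if (rp$negation_scope > rs$negation_scope) {
    pats$neg_pos <- 0.18
  }
  pats
}

## token material for one report; returns a list of "elements", each a
## character vector kept contiguous under shuffling (negation units).
signal_elements <- function(kind, s, model, rp, rs) {
  v <- model$vocab_spec
  th <- model$thresholds
  pick <- function(grp, k = 1L) sample(v[[grp]], k, replace = TRUE)
  els <- list()
  add <- function(x) els[[length(els) + 1L]] <<- x
  if (kind == "unc_neg") {
    ## hedge count between the two thresholds; adjacent negated mention
    for (i in seq_len(rs$hedging_threshold - 1L)) add(pick("hedging"))
    add(c(pick("negation"), pick("affirmative")))
  } else if (kind == "unc_pos") {
    for (i in seq_len(rs$hedging_threshold - 1L)) add(pick("hedging"))
    add(pick("affirmative"))
  } else if (kind == "neg_pos") {
    ## gap defeats the secondary's narrow negation scope only
    if (min(rp$hedging_threshold, rs$hedging_threshold) > 1L &&
        stats::runif(1) < 0.3) add(pick("hedging"))
    add(c(pick("negation"), pick("filler", rs$negation_scope), pick("affirmative")))
  } else if (kind == "positive") {
    rel <- (s - th["unc_pos"]) / (1 - th["unc_pos"])
    n_aff <- 1L + stats::rpois(1L, 2 * rel)
    for (i in seq_len(n_aff)) add(pick("affirmative"))
    if (stats::runif(1) < 0.4 * (1 - rel)) add(pick("hedging"))
  } else if (kind == "uncertain") {
    n_h <- max(rp$hedging_threshold, rs$hedging_threshold) + stats::rpois(1L, 1)
    for (i in seq_len(n_h)) add(pick("hedging"))
    if (stats::runif(1) < 0.5) add(pick("affirmative"))
  } else if (kind == "negative") {
    rel <- (th["neg_unc"] - s) / th["neg_unc"]
    if (stats::runif(1) < 0.7) add(c(pick("negation"), pick("affirmative")))
    n_extra <- stats::rpois(1L, 0.5)
    for (i in seq_len(n_extra)) add(pick("negation"))
    if (stats::runif(1) < 0.3 * (1 - rel)) add(pick("hedging"))
  } else stop("unknown pattern kind: ", kind)
  els
}

#' Generate a synthetic dual-labelled report corpus
#'
#' Draws a latent severity per report, emits class-conditional token material
#' (signal tokens plus neutral filler, total length Poisson with the model's
#' mean, truncated at 3), and labels every report by actually running both
#' deterministic rules on the tokens. Ambiguous token patterns — the only
#' source of labeller disagreement — are assigned only to documents whose
#' severity falls within `boundary_width` of a class threshold, at a rate
#' calibrated so the corpus-level disagreement fraction approaches the
#' model's `disagreement_rate`.
#'
#' @param model a [severity_model()].
#' @param rule_primary,rule_secondary [labeller_rule()] objects; the primary
#'   rule plays the conservative-labeller role.
#' @param n number of reports.
#' @param seed integer seed; regeneration with the same arguments is
#'   bit-identical.
#' @return object of class `labelled_corpus`: a list with `reports`
#'   (data.frame with `report_id`, `tokens` list-column, `severity`,
#'   `primary_label`, `secondary_label`) and `meta`.
#' @export
generate_corpus <- function(model = severity_model(),
                            rule_primary = primary_rule(),
                            rule_secondary = secondary_rule(),
                            n, seed) {
  stopifnot(inherits(model, "severity_model"), n >= 1)
  if (rule_primary$conservativeness < rule_secondary$conservativeness &&
      rule_primary$hedging_threshold > rule_secondary$hedging_threshold) {
    warning("primary rule declared less conservative but has the lower bar for 'uncertain'")
  }
  th <- model$thresholds
  bw <- model$boundary_width
  ## borderline probability mass (bands clipped to [0,1], overlap merged)
  band <- function(c0) c(max(0, c0 - bw), min(1, c0 + bw))
  b1 <- band(th[["neg_unc"]]); b2 <- band(th[["unc_pos"]])
  p_border <- (b1[2] - b1[1]) + (b2[2] - b2[1]) - max(0, min(b1[2], b2[2]) - max(b1[1], b2[1]))
  if (model$disagreement_rate > 0) {
    if (p_border <= 0) {
      stop("unreachable disagreement_rate ", model$disagreement_rate,
           ": boundary_width ", bw, " leaves no borderline documents")
    }
    p_amb <- model$disagreement_rate / p_border
    if (p_amb > 1) {
      stop("unreachable disagreement_rate ", model$disagreement_rate,
           " given boundary_width ", bw,
           " (borderline mass ", signif(p_border, 3), ")")
    }
    pats <- feasible_patterns(rule_primary, rule_secondary)
    if (length(pats) == 0) {
      stop("unreachable disagreement_rate ", model$disagreement_rate,
           ": the two labeller rules cannot disagree on any token pattern")
    }
    pat_names <- names(pats)
    pat_w <- unlist(pats) / sum(unlist(pats))
  } else {
    p_amb <- 0
  }

  with_seed(seed, {
    severity <- stats::runif(n)
    tokens <- vector("list", n)
    primary <- character(n)
    secondary <- character(n)
    for (i in seq_len(n)) {
      s <- severity[i]
      borderline <- (abs(s - th[["neg_unc"]]) <= bw) || (abs(s - th[["unc_pos"]]) <= bw)
      ambiguous <- borderline && p_amb > 0 && stats::runif(1) < p_amb
      kind <- if (ambiguous) {
        sample(pat_names, 1L, prob = pat_w)
      } else {
        severity_class(s, th)
      }
      els <- signal_elements(kind, s, model, rule_primary, rule_secondary)
      n_sig <- sum(lengths(els))
      len <- max(3L, stats::rpois(1L, model$mean_doc_length), n_sig)
      n_fill <- len - n_sig
      if (n_fill > 0) {
        fillers <- sample(model$vocab_spec$filler, n_fill, replace = TRUE)
        for (f in fillers) els[[length(els) + 1L]] <- f
      }
      toks <- unlist(els[sample.int(length(els))], use.names = FALSE)
      tokens[[i]] <- toks
      primary[i] <- apply_labeller(rule_primary, toks)
      secondary[i] <- apply_labeller(rule_secondary, toks)
    }
    reports <- data.frame(report_id = sprintf("r%06d", seq_len(n)),
                          severity = severity,
                          primary_label = primary,
                          secondary_label = secondary,
                          stringsAsFactors = FALSE)
    reports$tokens <- tokens
    structure(list(reports = reports,
                   meta = list(n = n, seed = seed,
                               model = model,
                               rule_primary = rule_primary,
                               rule_secondary = rule_secondary)),
              class = "labelled_corpus")
  })
}

#' Summary statistics of a labelled corpus
#'
#' @param corpus a `labelled_corpus`.
#' @return list with `n`, per-labeller class proportions, exact
#'   `disagreement_rate`, and `mean_tokens`.
#' @export
corpus_stats <- function(corpus) {
  stopifnot(inherits(corpus, "labelled_corpus"))
  r <- corpus$reports
  if (nrow(r) == 0) stop("corpus_stats: empty corpus")
  prop <- function(lab) {
    tab <- table(factor(lab, levels = CLASS_LEVELS))
    stats::setNames(as.numeric(tab) / length(lab), CLASS_LEVELS)
  }
  list(n = nrow(r),
       primary_proportions = prop(r$primary_label),
       secondary_proportions = prop(r$secondary_label),
       disagreement_rate = mean(r$primary_label != r$secondary_label),
       mean_tokens = mean(lengths(r$tokens)))
}

#' @export
print.labelled_corpus <- function(x, ...) {
  st <- corpus_stats(x)
  cat("labelled_corpus:", st$n, "reports,",
      sprintf("disagreement %.3f,", st$disagreement_rate),
      sprintf("mean length %.1f tokens\n", st$mean_tokens))
  invisible(x)
}

#' Write a corpus as JSON-lines
#'
#' One UTF-8 JSON object per line with fields `report_id`, `tokens`,
#' `severity`, `primary_label`, `secondary_label`.
#'
#' @param corpus a `labelled_corpus`.
#' @param path output file.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "labelled_corpus"))
  r <- corpus$reports
  lines <- vapply(seq_len(nrow(r)), function(i) {
    jsonlite::toJSON(list(report_id = r$report_id[i],
                          tokens = r$tokens[[i]],
                          severity = r$severity[i],
                          primary_label = r$primary_label[i],
                          secondary_label = r$secondary_label[i]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON-lines corpus
#'
#' @param path corpus file written by [write_corpus()] (or any file in the
#'   same dialect; `severity` is optional).
#' @return a `labelled_corpus`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  if (n == 0) stop("read_corpus: empty file ", path)
  tokens <- vector("list", n)
  report_id <- character(n); severity <- rep(NA_real_, n)
  primary <- character(n); secondary <- character(n)
  for (i in seq_len(n)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("read_corpus: malformed JSON on line ", i))
    for (f in c("report_id", "tokens", "primary_label", "secondary_label")) {
      if (is.null(rec[[f]])) stop("read_corpus: missing field '", f, "' on line ", i)
    }
    if (!(rec$primary_label %in% CLASS_LEVELS) ||
        !(rec$secondary_label %in% CLASS_LEVELS)) {
      stop("read_corpus: invalid label on line ", i)
    }
    if (length(rec$tokens) == 0) stop("read_corpus: empty token list on line ", i)
    report_id[i] <- rec$report_id
    tokens[[i]] <- as.character(rec$tokens)
    severity[i] <- if (is.null(rec$severity)) NA_real_ else rec$severity
    primary[i] <- rec$primary_label
    secondary[i] <- rec$secondary_label
  }
  reports <- data.frame(report_id = report_id, severity = severity,
                        primary_label = primary, secondary_label = secondary,
                        stringsAsFactors = FALSE)
  reports$tokens <- tokens
  structure(list(reports = reports, meta = list(n = n, source = path)),
            class = "labelled_corpus")
}
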