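#' Build a fully resolved experiment configuration
#'
#' Everything a run needs is carried in one serializable list: corpus
#' parameters, embedding dimensionality, split fractions and repeat count,
#' the model roster with per-model settings, and the single global seed from
#' which every stage seed is derived. Unspecified entries take the package
#' defaults shown below.
#'
#' @param seed global integer seed.
#' @param n corpus size.
#' @param models character subset of `c("gp", "rf", "ens")`.
#' @param repeats number of repeated train/validation/test splits averaged
#'   in the report.
#' @param ... overrides for any other top-level or per-model field; per-model
#'   settings are nested lists `gp`, `rf`, `ens`.
#' @return a named list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L, n = 10000, models = c("gp", "rf", "ens"),
                              repeats = 2, ...) {
  defaults <- list(
    seed = seed, n = n, models = models, repeats = repeats,
    disagreement_rate = 0.04, boundary_width = 0.025,
    mean_doc_length = 43.5,
    class_proportions = c(26455, 11781, 25246) / 63482,
    embedding_dim = 32,
    val_fraction = 0.10, test_fraction = 0.10,
    write_artifacts = TRUE,
    gp = list(num_inducing = 96, learning_rate = 0.003, epochs = NULL,
              batch_size = 500, mc_train = 20, mc_predict = 100),
    rf = list(n_trees = 300, max_depth = 40),
    ens = list(n_members = 5, hidden_units = 200, n_hidden = 3,
               learning_rate = 3e-3, epochs = 10, batch_size = 100)
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0) stop("experiment_config: unknown field(s): ",
                            paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  cfg$models <- match.arg(cfg$models, c("gp", "rf", "ens"), several.ok = TRUE)
  structure(cfg, class = "experiment_config")
}

#' The desk-scale analog of the full study protocol
#'
#' 10,000 synthetic reports with ~4 percent boundary-localized labeller
#' disagreement, two repeated splits, and all three models.
#'
#' @param seed global seed.
#' @param ... overrides passed to [experiment_config()].
#' @return an `experiment_config`.
#' @export
paper_analog_config <- function(seed = 1L, ...) {
  experiment_config(seed = seed, n = 10000, repeats = 2, ...)
}

fit_one_model <- function(model, Xtr, ytr, Xval, yval, cfg, fit_seed) {
  switch(model,
    gp = fit_svgp(Xtr, ytr,
                  num_inducing = cfg$gp$num_inducing,
                  learning_rate = cfg$gp$learning_rate,
                  epochs = cfg$gp$epochs, batch_size = cfg$gp$batch_size,
                  mc_train = cfg$gp$mc_train, mc_predict = cfg$gp$mc_predict,
                  seed = fit_seed),
    rf = fit_forest(Xtr, ytr, Xval, yval,
                    n_trees = cfg$rf$n_trees, max_depth = cfg$rf$max_depth,
                    seed = fit_seed),
    ens = fit_ensemble(Xtr, ytr,
                       n_members = cfg$ens$n_members,
                       hidden_units = cfg$ens$hidden_units,
                       n_hidden = cfg$ens$n_hidden,
                       learning_rate = cfg$ens$learning_rate,
                       epochs = cfg$ens$epochs,
                       batch_size = cfg$ens$batch_size,
                       seed = fit_seed),
    stop("unknown model: ", model))
}

predict_any <- function(model_obj, X) {
  if (inherits(model_obj, "svgp")) predict.svgp(model_obj, X)
  else if (inherits(model_obj, "rf_calibrated")) predict_forest(model_obj, X)
  else predict_ensemble(model_obj, X)
}

#' Run an end-to-end experiment
#'
#' Executes generate -> featurize -> split (x repeats) -> train (x models)
#' -> evaluate, with every stage seed derived from the global seed, and
#' returns one [evaluate_run()] report per model plus the run manifest.
#' The evaluated variants are `NegINCONSTest` (truth = secondary labels),
#' `CheXINCONSTest` (truth = primary labels on the same ids), `CONSTest`
#' (consistent subsample size-matched to the inconsistent set), and
#' `CONSFull` (the full consistent test partition, used for the group-wise
#' FN/TP analysis where the subsample would be too small).
#'
#' With `out_dir` set, the resolved manifest is written before any
#' computation and all artifacts (corpus, embeddings, features, splits,
#' per-model reports, combined summary tables) are written beneath it;
#' re-running the same manifest reproduces all files bit-identically.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory.
#' @return list with `reports` (per model), `tables` (`table1` accuracy/NLPP
#'   per variant; `table2` group-wise MMPCL), `corpus_stats`, `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  cfg <- config
  seeds <- list(corpus = derive_seed(cfg$seed, "corpus"),
                embeddings = derive_seed(cfg$seed, "embeddings"))
  for (r in seq_len(cfg$repeats)) {
    seeds[[paste0("split_", r)]] <- derive_seed(cfg$seed, paste0("split:", r))
    seeds[[paste0("variants_", r)]] <- derive_seed(cfg$seed, paste0("variants:", r))
    for (m in cfg$models) {
      seeds[[paste0(m, "_", r)]] <- derive_seed(cfg$seed, paste0(m, ":", r))
    }
  }
  manifest <- list(package = "reportuq",
                   version = as.character(utils::packageVersion("reportuq")),
                   config = unclass(cfg), derived_seeds = seeds)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  model <- severity_model(class_proportions = cfg$class_proportions,
                          boundary_width = cfg$boundary_width,
                          disagreement_rate = cfg$disagreement_rate,
                          mean_doc_length = cfg$mean_doc_length)
  corpus <- generate_corpus(model, primary_rule(), secondary_rule(),
                            n = cfg$n, seed = seeds$corpus)
  stats_ <- corpus_stats(corpus)
  table <- synthetic_embeddings(model$vocab_spec, dimension = cfg$embedding_dim,
                                seed = seeds$embeddings)
  X <- featurize_corpus(corpus, table)
  labs <- stats::setNames(corpus$reports$primary_label, corpus$reports$report_id)

  if (!is.null(out_dir) && isTRUE(cfg$write_artifacts)) {
    write_corpus(corpus, file.path(out_dir, "corpus.jsonl"))
    write_embeddings(table, file.path(out_dir, "embeddings.vec"))
    write_features(X, file.path(out_dir, "features.csv"))
    jsonlite::write_json(stats_, file.path(out_dir, "corpus_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  runs <- stats::setNames(vector("list", length(cfg$models)), cfg$models)
  for (m in cfg$models) runs[[m]] <- vector("list", cfg$repeats)
  for (r in seq_len(cfg$repeats)) {
    split <- make_split(corpus, cfg$val_fraction, cfg$test_fraction,
                        seed = seeds[[paste0("split_", r)]])
    variants <- make_test_variants(corpus, split,
                                   seed = seeds[[paste0("variants_", r)]])
    if (!is.null(out_dir) && isTRUE(cfg$write_artifacts)) {
      jsonlite::write_json(unclass(split),
                           file.path(out_dir, sprintf("split_%d.json", r)),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    Xtr <- X[split$train_ids, , drop = FALSE]
    Xval <- X[split$val_ids, , drop = FALSE]
    for (m in cfg$models) {
      fitted <- fit_one_model(m, Xtr, labs[split$train_ids],
                              Xval, labs[split$val_ids], cfg,
                              seeds[[paste0(m, "_", r)]])
      variant_sets <- list(
        NegINCONSTest = list(ids = variants$incons_ids,
                             truth = variants$neg_incons_truth),
        CheXINCONSTest = list(ids = variants$incons_ids,
                              truth = variants$chex_incons_truth),
        CONSTest = list(ids = variants$cons_subsample_ids,
                        truth = variants$cons_subsample_truth),
        CONSFull = list(ids = variants$cons_ids,
                        truth = variants$cons_truth))
      runs[[m]][[r]] <- lapply(variant_sets, function(vs) {
        if (length(vs$ids) == 0) {
          return(list(probs = matrix(numeric(0), 0, 3), truth = character(0)))
        }
        pd <- predict_any(fitted, X[vs$ids, , drop = FALSE])
        list(probs = pd$probs, truth = unname(vs$truth[vs$ids]))
      })
    }
  }

  reports <- lapply(runs, evaluate_run)
  table1 <- do.call(rbind, lapply(names(reports), function(m) {
    s <- reports[[m]]$summary
    s <- s[s$variant %in% c("NegINCONSTest", "CheXINCONSTest", "CONSTest"), ]
    cbind(model = m, s)
  }))
  table2 <- do.call(rbind, lapply(names(reports), function(m) {
    g <- reports[[m]]$groupwise
    if (is.null(g)) return(NULL)
    g <- g[g$variant %in% c("NegINCONSTest", "CONSFull"), ]
    cbind(model = m, g)
  }))

  if (!is.null(out_dir)) {
    for (m in names(reports)) {
      write_report(reports[[m]], file.path(out_dir, sprintf("report_%s.json", m)))
    }
    utils::write.csv(table1, file.path(out_dir, "table1.csv"), row.names = FALSE)
    if (!is.null(table2)) {
      utils::write.csv(table2, file.path(out_dir, "table2.csv"), row.names = FALSE)
    }
  }
  list(reports = reports, tables = list(table1 = table1, table2 = table2),
       corpus_stats = stats_, manifest = manifest)
}

#' Re-run an experiment from its manifest
#'
#' Reads the resolved configuration out of a `manifest.json` written by
#' [run_experiment()] and executes the identical run; with the same package
#' version all deterministic outputs are reproduced bit-identically.
#'
#' @param path path to a manifest JSON file.
#' @param out_dir optional output directory for the re-run.
#' @return the [run_experiment()] result.
#' @export
run_from_manifest <- function(path, out_dir = NULL) {
  man <- jsonlite::fromJSON(path)
  cfg <- man$config
  cfg$models <- as.character(cfg$models)
  cfg$class_proportions <- as.numeric(cfg$class_proportions)
  ## JSON serializes the auto-epochs NULL as an empty object; restore it
  if (!is.null(cfg$gp) && length(cfg$gp$epochs) == 0) cfg$gp$epochs <- NULL
  cfg <- do.call(experiment_config, cfg)
  run_experiment(cfg, out_dir = out_dir)
}
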