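#' Construct an embedding table
#'
#' @param vectors numeric matrix, one row per token, with token rownames.
#' @return object of class `embedding_table`.
#' @export
embedding_table <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors),
            !is.null(rownames(vectors)), ncol(vectors) >= 1)
  if (anyDuplicated(rownames(vectors))) stop("duplicate tokens in embedding table")
  if (any(!is.finite(vectors))) stop("non-finite entries in embedding table")
  structure(list(vectors = vectors, dimension = ncol(vectors)),
            class = "embedding_table")
}

#' Synthetic token-embedding fixture table
#'
#' Per-token vectors are drawn once from a fixed-seed isotropic Gaussian
#' (scale `1/sqrt(dimension)`), and the three class-indicative token groups
#' (affirmative, negation, hedging) receive mean offsets along three mutually
#' orthogonal directions so that mean-pooled documents carry learnable class
#' signal. Stands in for pretrained biomedical word vectors; any table in
#' word2vec text format can be used instead via [read_embeddings()].
#'
#' @param vocab token lexicon, see [default_vocab()].
#' @param dimension embedding dimensionality.
#' @param offset magnitude of the group mean offsets.
#' @param seed integer seed (fixed default so the fixture is stable).
#' @return an `embedding_table`.
#' @export
synthetic_embeddings <- function(vocab = default_vocab(), dimension = 32,
                                 offset = 2, seed = 104729L) {
  stopifnot(dimension >= 3)
  tokens <- unique(unlist(vocab, use.names = FALSE))
  with_seed(seed, {
    vec <- matrix(stats::rnorm(length(tokens) * dimension, sd = 1 / sqrt(dimension)),
                  nrow = length(tokens), dimnames = list(tokens, NULL))
    dirs <- qr.Q(qr(matrix(stats::rnorm(dimension * 3), dimension, 3)))
    shift <- function(group, j) {
      idx <- rownames(vec) %in% vocab[[group]]
      vec[idx, ] <<- vec[idx, , drop = FALSE] +
        matrix(offset * dirs[, j], sum(idx), dimension, byrow = TRUE)
    }
    shift("affirmative", 1); shift("negation", 2); shift("hedging", 3)
    embedding_table(vec)
  })
}

#' Write an embedding table in word2vec text format
#'
#' First line `"<vocab_size> <dimension>"`, then one `token v1 ... vd` line
#' per token, values printed with 17 significant digits so a round-trip
#' reproduces them exactly.
#'
#' @param table an `embedding_table`.
#' @param path output file.
#' @export
write_embeddings <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  v <- table$vectors
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(v), ncol(v)), con)
  for (i in seq_len(nrow(v))) {
    writeLines(paste(rownames(v)[i],
                     paste(sprintf("%.17g", v[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a word2vec text-format embedding table
#'
#' @param path file in word2vec text format.
#' @return an `embedding_table`.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2) stop("read_embeddings: malformed header line")
  nv <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) != nv) stop("read_embeddings: header promises ", nv,
                               " vectors, found ", length(body))
  vec <- matrix(NA_real_, nv, d)
  toks <- character(nv)
  for (i in seq_len(nv)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(parts) != d + 1) {
      stop("read_embeddings: line ", i + 1, " has ", length(parts) - 1,
           " values, expected ", d)
    }
    toks[i] <- parts[1]
    vec[i, ] <- as.numeric(parts[-1])
  }
  rownames(vec) <- toks
  embedding_table(vec)
}

#' Clean raw text or tokens into the canonical token stream
#'
#' Lower-cases, splits on whitespace, and removes punctuation by splitting
#' tokens at any non-alphanumeric character (Unicode-aware). Idempotent:
#' re-applying to its own output is a no-op.
#'
#' @param x a character vector (raw text and/or tokens).
#' @return character vector of clean tokens, order preserved. May be empty if
#'   nothing alphanumeric survives; downstream pooling flags that case.
#' @export
preprocess <- function(x) {
  if (is.null(x)) stop("preprocess: null input")
  if (length(x) == 0) return(character(0))
  parts <- unlist(strsplit(tolower(x), "[^\\p{L}\\p{N}]+", perl = TRUE),
                  use.names = FALSE)
  parts[nzchar(parts)]
}

#' Mean-pooled embedding of a token list
#'
#' Arithmetic mean of the vectors of in-vocabulary tokens; out-of-vocabulary
#' tokens are skipped (the mean renormalizes over the in-vocabulary count).
#' A document with no in-vocabulary token maps to the zero vector and the
#' event is reported via a message.
#'
#' @param tokens character vector.
#' @param table an `embedding_table`.
#' @return numeric vector of length `table$dimension`.
#' @export
mean_pool_embed <- function(tokens, table) {
  stopifnot(inherits(table, "embedding_table"))
  iv <- tokens[tokens %in% rownames(table$vectors)]
  if (length(iv) == 0) {
    message("mean_pool_embed: no in-vocabulary tokens; emitting zero vector")
    return(numeric(table$dimension))
  }
  colMeans(table$vectors[iv, , drop = FALSE])
}

#' Featurize a corpus into a fixed-length matrix
#'
#' Row i is the mean-pooled embedding of report i's tokens; rownames carry
#' the report ids. The latent severity field, if present, is never consulted:
#' features are a function of tokens and the table only.
#'
#' @param corpus a `labelled_corpus`.
#' @param table an `embedding_table`.
#' @param clean if `TRUE`, run [preprocess()] on each token list first
#'   (generated corpora are already clean).
#' @return numeric matrix `n x d` with `report_id` rownames.
#' @export
featurize_corpus <- function(corpus, table, clean = FALSE) {
  stopifnot(inherits(corpus, "labelled_corpus"), inherits(table, "embedding_table"))
  r <- corpus$reports
  if (nrow(r) == 0) stop("featurize_corpus: empty corpus")
  vocab_hit <- rownames(table$vectors)
  X <- matrix(0, nrow(r), table$dimension,
              dimnames = list(r$report_id, NULL))
  n_empty <- 0L
  for (i in seq_len(nrow(r))) {
    toks <- r$tokens[[i]]
    if (clean) toks <- preprocess(toks)
    iv <- toks[toks %in% vocab_hit]
    if (length(iv) == 0) {
      n_empty <- n_empty + 1L
    } else {
      X[i, ] <- colMeans(table$vectors[iv, , drop = FALSE])
    }
  }
  if (n_empty > 0) {
    message("featurize_corpus: ", n_empty,
            " report(s) had no in-vocabulary tokens (zero vector emitted)")
  }
  if (any(!is.finite(X))) stop("featurize_corpus: non-finite feature values")
  X
}

#' Write a feature matrix as CSV (with report ids)
#' @param X feature matrix with report-id rownames.
#' @param path output file.
#' @export
write_features <- function(X, path) {
  vals <- matrix(sprintf("%.17g", X), nrow(X), ncol(X))
  header <- paste(c("report_id", paste0("f", seq_len(ncol(X)))), collapse = ",")
  rows <- vapply(seq_len(nrow(X)), function(i) {
    paste(c(rownames(X)[i], vals[i, ]), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#' @param path CSV file.
#' @return numeric matrix with report-id rownames.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$report_id
  storage.mode(X) <- "double"
  X
}
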