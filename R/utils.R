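#' @keywords internal
"_PACKAGE"

CLASS_LEVELS <- c("positive", "uncertain", "negative")

#' Derive a stage-specific RNG seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its seed from the global seed
#' plus a stage tag, so a single integer plus the run manifest reproduces a
#' whole experiment. The derived seed always lies in `[1, 2^31 - 2]`.
#'
#' @param seed integer global seed.
#' @param tag character stage tag, e.g. `"corpus"`, `"split:1"`.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(tag), length(tag) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- (abs(as.numeric(seed)) %% m)
  for (code in utf8ToInt(tag)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Cholesky factorization with an escalating jitter ladder
#'
#' Attempts `chol()` on a symmetric matrix, adding `jitter` to the diagonal
#' and multiplying it by 10 on each failure, up to `max_tries` attempts.
#' Failures and the jitter finally used are reported via a message so
#' numerically delicate runs leave a trace in the log.
#'
#' @param mat symmetric matrix.
#' @param jitter initial diagonal jitter.
#' @param max_tries maximum number of escalations.
#' @return lower-triangular factor `L` with `mat ~= L %*% t(L)`.
#' @keywords internal
chol_jitter <- function(mat, jitter = 1e-8, max_tries = 6L) {
  d <- nrow(mat)
  for (k in seq_len(max_tries)) {
    L <- tryCatch(t(chol(mat + diag(jitter, d))), error = function(e) NULL)
    if (!is.null(L)) {
      if (k > 1L) message("chol_jitter: succeeded with jitter ", signif(jitter, 3))
      return(L)
    }
    jitter <- jitter * 10
  }
  stop("Cholesky failed after jitter escalation to ", signif(jitter, 3),
       "; matrix may not be positive definite (dim ", d, ").")
}

## log-sum-exp over rows of a matrix
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

row_softmax <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

assert_simplex_rows <- function(probs, tol = 1e-6) {
  if (any(!is.finite(probs)) || any(probs < -tol) ||
      any(abs(rowSums(probs) - 1) > tol)) {
    stop("probability rows must lie on the simplex (tolerance ", tol, ")")
  }
  invisible(TRUE)
}

as_class_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  bad <- setdiff(unique(labels), CLASS_LEVELS)
  if (length(bad) > 0) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  }
  factor(labels, levels = CLASS_LEVELS)
}
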