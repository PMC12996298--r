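#' Derive a named sub-stream seed
#'
#' Every stochastic stage draws from its own sub-stream derived from a parent
#' seed and a stage name, so changing one configuration knob does not
#' reshuffle unrelated draws. The derivation is a small deterministic hash
#' kept below 2^31 so it is always a valid R integer seed.
#'
#' @param seed integer parent seed.
#' @param name character sub-stream name.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1, prime
  h <- abs(as.numeric(seed)) %% m
  for (k in utf8ToInt(paste(name, collapse = "/"))) {
    h <- (h * 131 + k) %% m
  }
  as.integer(h)
}

#' Evaluate an expression under a local RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' package internals never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  force(seed) # evaluate caller draws before snapshotting the RNG state
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Polynomial rolling hash of strings into [0, 2^31 - 2]; memoised over the
# unique values of x. Deterministic across platforms (pure integer arithmetic
# on UTF-8 code points, exact in doubles).
hash_strings <- function(x) {
  ux <- unique(x)
  m <- 2147483647
  hu <- vapply(ux, function(s) {
    h <- 7
    for (k in utf8ToInt(s)) h <- (h * 131 + k) %% m
    h
  }, numeric(1), USE.NAMES = FALSE)
  hu[match(x, ux)]
}

# Row-wise L2 normalisation; zero rows stay zero.
l2_normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

# Cosine distance between the rows of a and the rows of b (both matrices).
cosine_dist <- function(a, b) {
  a <- l2_normalize_rows(a)
  b <- l2_normalize_rows(b)
  d <- 1 - tcrossprod(a, b)
  pmin(pmax(d, 0), 2)
}

mae <- function(y, yhat) mean(abs(y - yhat))

rsq <- function(y, yhat) {
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    return(if (ss_res == 0) 1 else -Inf)
  }
  1 - ss_res / ss_tot
}

#' Hash an R object into a short fingerprint
#'
#' Used for fold-plan and configuration provenance.
#'
#' @param x any R object.
#' @return a character hash.
#' @export
object_hash <- function(x) rlang::hash(x)
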