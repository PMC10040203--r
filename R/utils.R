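#' @importFrom stats aggregate coef cor cor.test lm logLik pchisq pnorm qnorm
#'   rbinom rnorm runif sd setNames t.test uniroot var
#' @importFrom utils packageVersion read.delim write.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Standard error of the mean from a standard deviation
#'
#' @param sd Sample standard deviation (n - 1 denominator).
#' @param n Number of observations.
#' @return `sd / sqrt(n)`.
#' @export
sem <- function(sd, n) {
  stopifnot(is.numeric(sd), is.numeric(n), all(n >= 1))
  sd / sqrt(n)
}

# 32-bit FNV-1a over a string; used to derive reproducible RNG substreams
# and config hashes without external dependencies.
fnv1a <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(x))) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# Independent substream per (seed, tag): one generator never perturbs another.
derive_seed <- function(seed, tag) {
  as.integer((seed * 48271 + fnv1a(tag)) %% 2147483629)
}

config_hash <- function(x) {
  sprintf("%08x", fnv1a(paste(deparse(x), collapse = "\n")))
}

abort_config <- function(msg) {
  stop(errorCondition(msg, class = c("ambinorm_config_error", "error")))
}

check_probability_vector <- function(p, what = "probability vector") {
  if (!is.numeric(p) || length(p) < 1 || anyNA(p) || any(p < 0)) {
    abort_config(sprintf("%s must be non-negative and free of NA", what))
  }
  if (abs(sum(p) - 1) > 1e-12) {
    abort_config(sprintf("%s must sum to 1 (got %.15f)", what, sum(p)))
  }
  invisible(p)
}

check_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort_config(sprintf("%s must be an integer >= %d", what, min))
  }
  as.integer(x)
}

check_rate <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort_config(sprintf("%s must lie in [0, 1]", what))
  }
  x
}

#' Ambiguity condition labels
#'
#' The four-level ambiguity factor used throughout: homonyms (unrelated
#' meanings), irregular (metaphorical) polysemes, regular (metonymic)
#' polysemes, and unambiguous words. Alphabetical order puts `Homonym`
#' first, so default treatment coding uses it as the reference level.
#'
#' @return Character vector of the four condition labels.
#' @export
ambiguity_conditions <- function() {
  c("Homonym", "IrregularPolyseme", "RegularPolyseme", "Unambiguous")
}
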