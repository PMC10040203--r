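#' Remove items whose anaphor is a multiword expression
#'
#' Masked-token surprisal is defined for a single-token anaphor, so items
#' whose anaphoric expression contains internal whitespace (e.g. "a lot")
#' are dropped before the encoder analysis. Idempotent.
#'
#' @param items Zeugma item tibble with an `anaphor_text` column.
#' @return Retained items, with attribute `n_removed`.
#' @export
filter_multiword_anaphors <- function(items) {
  multi <- grepl("\\s", trimws(items$anaphor_text))
  kept <- items[!multi, ]
  attr(kept, "n_removed") <- sum(multi)
  kept
}

#' Span embedding by subtoken averaging
#'
#' A word split into several subword pieces is represented by the
#' unweighted mean of the piece vectors covering its character span; a
#' single-piece span returns that piece's vector unchanged.
#'
#' @param vectors Matrix (subtokens x dim) of one layer's vectors.
#' @param alignment Tokenization tibble with 0-based half-open `start`,
#'   `end` character offsets per subtoken.
#' @param span Numeric `c(start, end)`, 0-based half-open.
#' @return Numeric vector of length `dim`.
#' @export
span_embedding <- function(vectors, alignment, span) {
  stopifnot(length(span) == 2, span[1] < span[2])
  idx <- which(alignment$start < span[2] & alignment$end > span[1])
  if (length(idx) == 0) {
    stop(errorCondition(
      sprintf("span [%d, %d) maps to no subtokens", span[1], span[2]),
      class = c("ambinorm_alignment_error", "error")))
  }
  colMeans(vectors[idx, , drop = FALSE])
}

#' Cosine distance
#'
#' `1 - (u . v) / (|u| |v|)`: 0 for identical directions, 1 for orthogonal
#' vectors, 2 for antipodal ones. Invariant to positive rescaling of
#' either argument.
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return The cosine distance in `[0, 2]`.
#' @export
cosine_distance <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine distance undefined for a zero vector")
  d <- 1 - sum(u * v) / (nu * nv)
  min(max(d, 0), 2) # clip floating-point excursions outside [0, 2]
}

#' Masked-anaphor surprisal
#'
#' The anaphoric expression is masked and the encoder supplies the
#' probability of the attested anaphor in that slot; surprisal is its
#' negative logarithm (natural log by default; `base = 2` gives bits).
#'
#' @param encoder An encoder implementing the contextual-encoder
#'   interface (see [make_toy_encoder()]).
#' @param item One-row zeugma item tibble.
#' @param base Logarithm base (default `exp(1)`).
#' @return Surprisal `s >= 0`; `s = 0` iff the probability is 1.
#' @export
anaphor_surprisal <- function(encoder, item, base = exp(1)) {
  stopifnot(nrow(item) == 1)
  p <- encoder$masked_probability(item$sentence,
                                  c(item$anaphor_start, item$anaphor_end),
                                  item$anaphor_text)
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p > 1) {
    stop(errorCondition(
      sprintf("encoder returned an invalid probability: %s", format(p)),
      class = c("ambinorm_encoder_contract_error", "error")))
  }
  -log(p) / log(base)
}

#' Per-item encoder metrics
#'
#' For every item, the cosine distance between the target-word and anaphor
#' span embeddings at each layer, and the masked-anaphor surprisal.
#' Multiword anaphors must have been filtered first (an item whose anaphor
#' spans multiple words is an error here).
#'
#' @param encoder Encoder implementing the contextual-encoder interface.
#' @param items Zeugma item tibble (single-word anaphors).
#' @param base Logarithm base for surprisal.
#' @return List with `cosine` (tibble `item`, `layer`, `d_cos`),
#'   `surprisal` (tibble `item`, `s`), and `meta` (encoder name, layer
#'   count `L`, dimension `d`, log base, and the number of items whose
#'   target span needed subtoken averaging).
#' @export
item_metrics <- function(encoder, items, base = exp(1)) {
  if (any(grepl("\\s", trimws(items$anaphor_text)))) {
    stop("multiword anaphors present; apply filter_multiword_anaphors() first")
  }
  n_layers <- encoder$n_layers
  cos_rows <- vector("list", nrow(items))
  s <- numeric(nrow(items))
  n_averaged <- 0L
  for (i in seq_len(nrow(items))) {
    it <- items[i, ]
    toks <- encoder$tokenize(it$sentence)
    layers <- encoder$layer_vectors(it$sentence)
    tspan <- c(it$target_start, it$target_end)
    aspan <- c(it$anaphor_start, it$anaphor_end)
    if (sum(toks$start < tspan[2] & toks$end > tspan[1]) > 1) {
      n_averaged <- n_averaged + 1L
    }
    d <- vapply(seq_len(n_layers), function(l) {
      cosine_distance(span_embedding(layers[[l]], toks, tspan),
                      span_embedding(layers[[l]], toks, aspan))
    }, numeric(1))
    cos_rows[[i]] <- tibble::tibble(item = it$item,
                                    layer = seq_len(n_layers),
                                    d_cos = d)
    s[i] <- anaphor_surprisal(encoder, it, base = base)
  }
  list(cosine = dplyr::bind_rows(cos_rows),
       surprisal = tibble::tibble(item = items$item, s = s),
       meta = list(encoder = encoder$name %||% "unknown",
                   n_layers = n_layers, dim = encoder$dim,
                   log_base = base, n_target_averaged = n_averaged))
}

#' Layer-wise correlation between cosine distance and human similarity
#'
#' Pearson product-moment correlation per layer between the items' cosine
#' distances and their mean human similarity ratings, with a 95%
#' confidence interval from the Fisher z transform, and the layer whose
#' correlation is strongest in magnitude.
#'
#' @param cosine Tibble `item`, `layer`, `d_cos` (from [item_metrics()]).
#' @param item_means Tibble `item`, `mean` (human item means).
#' @return List with `by_layer` (tibble `layer`, `n`, `r`, `ci_lower`,
#'   `ci_upper`) and `strongest_layer` (layer index of max `|r|`). Layers
#'   with zero variance in either variable get `NA` with a warning.
#' @export
layer_correlations <- function(cosine, item_means) {
  dat <- dplyr::inner_join(cosine, item_means[, c("item", "mean")],
                           by = "item")
  rows <- lapply(split(dat, dat$layer), function(d) {
    if (nrow(d) < 4) stop("need at least 4 paired observations per layer")
    if (sd(d$d_cos) == 0 || sd(d$mean) == 0) {
      warning("zero variance at layer ", d$layer[1], "; r undefined")
      return(tibble::tibble(layer = d$layer[1], n = nrow(d), r = NA_real_,
                            ci_lower = NA_real_, ci_upper = NA_real_))
    }
    ct <- cor.test(d$d_cos, d$mean, method = "pearson")
    tibble::tibble(layer = d$layer[1], n = nrow(d),
                   r = unname(ct$estimate),
                   ci_lower = ct$conf.int[1], ci_upper = ct$conf.int[2])
  })
  by_layer <- dplyr::arrange(dplyr::bind_rows(rows), .data$layer)
  strongest <- if (all(is.na(by_layer$r))) NA_integer_ else
    by_layer$layer[which.max(abs(by_layer$r))]
  list(by_layer = by_layer, strongest_layer = strongest)
}
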