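#' Deterministic toy contextual encoder
#'
#' A test double for a pretrained bidirectional transformer, exposing the
#' contextual-encoder interface used by the metric functions: `tokenize`,
#' `layer_vectors`, and `masked_probability`. Token vectors are seeded unit
#' Gaussian directions derived by hashing (token, layer, seed), so the
#' encoder is fully deterministic and needs no stored weights. For
#' sentences belonging to `items`, the anaphor vector at layer `l` is a
#' spherical interpolation between the target word's span embedding `t`
#' and a planted orthogonal distractor `u`:
#' `a = cos(phi) t + sin(phi) u` with
#' `phi = (1 - blend) * (pi / 2) * (l / L)`, where `blend` is the item's
#' planted `true_similarity`. Cosine distance between target and anaphor
#' is therefore `1 - cos(phi)`: strictly decreasing in the planted
#' similarity, zero at `blend = 1`, and with the widest dynamic range at
#' the final layer. The masked probability of the anaphor token is
#' `0.02 + 0.96 * blend`, strictly increasing in the planted similarity.
#'
#' @param items Zeugma item tibble (see [generate_zeugma_items()]); its
#'   sentences get planted anaphor geometry. `NULL` gives a plain static
#'   encoder.
#' @param n_layers Number of layers `L` (default 12).
#' @param dim Vector dimension `d` (default 768).
#' @param seed Integer seed.
#' @param vocab Extra words to admit beyond those in `items` sentences.
#' @param subword_threshold Words longer than this many characters are
#'   deterministically split into two subword pieces (default 8).
#' @return An object of class `toy_encoder` implementing the encoder
#'   interface; see Details.
#' @details The returned object is a list with fields `name`, `n_layers`,
#'   `dim`, and functions:
#'   \describe{
#'     \item{`tokenize(sentence)`}{tibble with `token`, `word_index`,
#'       `start`, `end` (0-based half-open character offsets); subword
#'       continuation pieces are prefixed `##` and the pieces of a word
#'       partition its character range exactly.}
#'     \item{`layer_vectors(sentence)`}{list of `n_layers` matrices
#'       (subtokens x dim), layer 1 first.}
#'     \item{`masked_probability(sentence, span, candidate)`}{probability
#'       in (0, 1] of `candidate` at the masked character `span`
#'       (`c(start, end)`, 0-based half-open).}
#'   }
#'   Tokens outside the vocabulary raise an error of class
#'   `ambinorm_oov_error`.
#' @export
make_toy_encoder <- function(items = NULL,
                             n_layers = 12L,
                             dim = 768L,
                             seed = 1L,
                             vocab = NULL,
                             subword_threshold = 8L) {
  n_layers <- check_count(n_layers, "n_layers")
  dim <- check_count(dim, "dim", min = 2L)
  if (!is.null(items)) {
    stopifnot(all(c("item", "sentence", "target_start", "target_end",
                    "anaphor_start", "anaphor_end", "true_similarity")
                  %in% names(items)))
    if (any(items$true_similarity < 0 | items$true_similarity > 1)) {
      abort_config("true_similarity must lie in [0, 1]")
    }
  }
  seed <- as.integer(seed)

  item_words <- if (is.null(items)) character(0) else
    unlist(strsplit(tolower(items$sentence), " +"), use.names = FALSE)
  vocabulary <- unique(c(tolower(vocab %||% character(0)), item_words, "."))
  item_by_sentence <- if (is.null(items)) list() else
    split(items, items$sentence)

  split_word <- function(w) {
    if (nchar(w) <= subword_threshold) return(w)
    head_len <- ceiling(nchar(w) / 2)
    c(substr(w, 1, head_len), paste0("##", substr(w, head_len + 1, nchar(w))))
  }

  tokenize <- function(sentence) {
    words <- strsplit(sentence, " +")[[1]]
    words <- words[nzchar(words)]
    oov <- setdiff(tolower(words), vocabulary)
    if (length(oov) > 0) {
      stop(errorCondition(
        paste("out-of-vocabulary token(s):", paste(oov, collapse = ", ")),
        class = c("ambinorm_oov_error", "error")))
    }
    # recover 0-based character offsets of each word
    starts <- integer(length(words))
    offset <- 0L
    for (i in seq_along(words)) {
      at <- regexpr(words[i], substr(sentence, offset + 1, nchar(sentence)),
                    fixed = TRUE)
      starts[i] <- offset + as.integer(at) - 1L
      offset <- starts[i] + nchar(words[i])
    }
    out <- list()
    for (i in seq_along(words)) {
      pieces <- split_word(tolower(words[i]))
      lens <- nchar(sub("^##", "", pieces))
      piece_start <- starts[i] + cumsum(c(0L, lens[-length(lens)]))
      out[[i]] <- tibble::tibble(token = pieces,
                                 word_index = i,
                                 start = as.integer(piece_start),
                                 end = as.integer(piece_start + lens))
    }
    dplyr::bind_rows(out)
  }

  vec_cache <- new.env(parent = emptyenv())
  token_vector <- function(token, layer) {
    key <- sprintf("%s|%d", token, layer)
    hit <- vec_cache[[key]]
    if (!is.null(hit)) return(hit)
    h <- derive_seed(seed, sprintf("tok|%s|%d", token, layer))
    v <- withr::with_seed(h, rnorm(dim))
    v <- v / sqrt(sum(v^2))
    vec_cache[[key]] <- v
    v
  }

  distractor_vector <- function(item, layer) {
    h <- derive_seed(seed, sprintf("distractor|%s|%d", item, layer))
    withr::with_seed(h, rnorm(dim))
  }

  layer_vectors <- function(sentence) {
    toks <- tokenize(sentence)
    it <- item_by_sentence[[sentence]]
    lapply(seq_len(n_layers), function(l) {
      m <- t(vapply(toks$token, token_vector, numeric(dim), layer = l))
      rownames(m) <- NULL
      if (!is.null(it)) {
        it1 <- it[1, ]
        t_idx <- which(toks$start < it1$target_end &
                         toks$end > it1$target_start)
        a_idx <- which(toks$start < it1$anaphor_end &
                         toks$end > it1$anaphor_start)
        tvec <- colMeans(m[t_idx, , drop = FALSE])
        tvec <- tvec / sqrt(sum(tvec^2))
        u <- distractor_vector(it1$item, l)
        u <- u - sum(u * tvec) * tvec
        u <- u / sqrt(sum(u^2))
        phi <- (1 - it1$true_similarity) * (pi / 2) * (l / n_layers)
        avec <- cos(phi) * tvec + sin(phi) * u
        m[a_idx, ] <- matrix(avec, nrow = length(a_idx), ncol = dim,
                             byrow = TRUE)
        # target subtokens collapse onto their mean direction so the span
        # embedding equals tvec exactly and blend = 1 gives distance 0
        m[t_idx, ] <- matrix(tvec, nrow = length(t_idx), ncol = dim,
                             byrow = TRUE)
      }
      m
    })
  }

  masked_probability <- function(sentence, span, candidate) {
    stopifnot(length(span) == 2, span[1] < span[2])
    it <- item_by_sentence[[sentence]]
    if (!is.null(it) &&
        span[1] == it$anaphor_start[1] && span[2] == it$anaphor_end[1] &&
        tolower(candidate) == tolower(it$anaphor_text[1])) {
      return(0.02 + 0.96 * it$true_similarity[1])
    }
    h <- derive_seed(seed, sprintf("mask|%s|%d|%d|%s", sentence,
                                   span[1], span[2], tolower(candidate)))
    withr::with_seed(h, runif(1, 1e-4, 0.05))
  }

  structure(
    list(name = sprintf("toy-encoder(dim=%d,layers=%d,seed=%d)",
                        dim, n_layers, seed),
         n_layers = n_layers,
         dim = dim,
         tokenize = tokenize,
         layer_vectors = layer_vectors,
         masked_probability = masked_probability),
    class = "toy_encoder"
  )
}
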