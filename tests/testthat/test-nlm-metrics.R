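make_items <- function(blends, anaphor = "one") {
  n <- length(blends)
  z <- generate_zeugma_items(ceiling(n / 4), multiword_fraction = 0, seed = 21)
  z <- z[seq_len(n), ]
  z$true_similarity <- blends
  z
}

test_that("the multiword-anaphor filter drops whitespace anaphors only", {
  items <- tibble::tibble(
    item = sprintf("i%03d", 1:318),
    anaphor_text = c(rep("one", 310), "it", "that", "some", "them",
                     rep("a lot", 4)))
  kept <- filter_multiword_anaphors(items)
  expect_identical(nrow(kept), 314L)
  expect_identical(attr(kept, "n_removed"), 4L)
  expect_true("one" %in% kept$anaphor_text)
  expect_false("a lot" %in% kept$anaphor_text)
  # idempotent
  again <- filter_multiword_anaphors(kept)
  expect_identical(again$item, kept$item)
  expect_identical(attr(again, "n_removed"), 0L)
})

test_that("span embeddings average the covering subtokens", {
  vectors <- rbind(c(0, 0), c(2, 4), c(9, 9))
  alignment <- tibble::tibble(start = c(0L, 3L, 8L), end = c(2L, 7L, 10L))
  expect_equal(span_embedding(vectors, alignment, c(0, 7)), c(1, 2))
  expect_equal(span_embedding(vectors, alignment, c(3, 7)), c(2, 4))
  expect_error(span_embedding(vectors, alignment, c(7, 8)),
               class = "ambinorm_alignment_error")
})

test_that("cosine distance has the expected geometry", {
  expect_equal(cosine_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 0), c(-1, 0)), 2)
  expect_equal(cosine_distance(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(cosine_distance(c(0, 0), c(1, 0)), "zero vector")
})

test_that("cosine distance is symmetric and scale-invariant", {
  withr::with_seed(3, {
    for (i in 1:25) {
      u <- rnorm(10); v <- rnorm(10)
      d <- cosine_distance(u, v)
      expect_gte(d, 0); expect_lte(d, 2)
      expect_equal(d, cosine_distance(v, u), tolerance = 1e-12)
      expect_equal(d, cosine_distance(3.7 * u, 0.01 * v), tolerance = 1e-9)
    }
  })
})

test_that("surprisal is the negative log probability in the chosen base", {
  stub <- function(p) list(n_layers = 1L, dim = 2L,
                           masked_probability = function(...) p)
  it <- tibble::tibble(item = "x", sentence = "a b", anaphor_start = 2L,
                       anaphor_end = 3L, anaphor_text = "b")
  expect_equal(anaphor_surprisal(stub(1), it), 0)
  expect_equal(anaphor_surprisal(stub(0.5), it), log(2), tolerance = 1e-12)
  expect_equal(anaphor_surprisal(stub(0.5), it, base = 2), 1,
               tolerance = 1e-12)
  # base change: s_e = ln(2) * s_2
  for (p in c(0.9, 0.31, 0.004)) {
    expect_equal(anaphor_surprisal(stub(p), it),
                 log(2) * anaphor_surprisal(stub(p), it, base = 2),
                 tolerance = 1e-12)
  }
  expect_error(anaphor_surprisal(stub(0), it),
               class = "ambinorm_encoder_contract_error")
  expect_error(anaphor_surprisal(stub(1.2), it),
               class = "ambinorm_encoder_contract_error")
})

test_that("the toy encoder is deterministic and rejects unknown tokens", {
  z <- generate_zeugma_items(2, seed = 7)
  e1 <- make_toy_encoder(z, n_layers = 3, dim = 12, seed = 5)
  e2 <- make_toy_encoder(z, n_layers = 3, dim = 12, seed = 5)
  expect_identical(e1$layer_vectors(z$sentence[1]),
                   e2$layer_vectors(z$sentence[1]))
  expect_identical(e1$masked_probability(z$sentence[1],
                                         c(z$anaphor_start[1],
                                           z$anaphor_end[1]),
                                         z$anaphor_text[1]),
                   e2$masked_probability(z$sentence[1],
                                         c(z$anaphor_start[1],
                                           z$anaphor_end[1]),
                                         z$anaphor_text[1]))
  expect_error(e1$tokenize("the unseenword ."),
               class = "ambinorm_oov_error")
})

test_that("tokenization partitions each word's characters exactly", {
  z <- generate_zeugma_items(4, seed = 7) # includes a long split target
  enc <- make_toy_encoder(z, n_layers = 2, dim = 8, seed = 1)
  for (s in z$sentence) {
    toks <- enc$tokenize(s)
    expect_true(any(grepl("^##", toks$token)) ||
                  all(nchar(toks$token) <= 8))
    for (w in unique(toks$word_index)) {
      pieces <- toks[toks$word_index == w, ]
      expect_identical(pieces$start[-1], pieces$end[-nrow(pieces)])
      covered <- substr(s, pieces$start[1] + 1, pieces$end[nrow(pieces)])
      expect_identical(tolower(covered),
                       paste(sub("^##", "", pieces$token), collapse = ""))
    }
  }
})

test_that("planted similarity drives encoder geometry monotonically", {
  blends <- c(0, 0.25, 0.5, 0.75, 1)
  items <- make_items(blends)
  enc <- make_toy_encoder(items, n_layers = 4, dim = 24, seed = 9)
  m <- item_metrics(enc, items)
  final <- m$cosine$d_cos[m$cosine$layer == 4]
  expect_true(all(diff(final) < 0)) # strictly decreasing in sense blend
  # identical meaning: distance 0 in every layer
  sat <- m$cosine[m$cosine$item == items$item[5], ]
  expect_true(all(abs(sat$d_cos) < 1e-9))
  # surprisal decreases as the planted similarity rises
  expect_true(all(diff(m$surprisal$s) < 0))
})

test_that("item metrics report subtoken averaging and reject multiword anaphors", {
  z <- generate_zeugma_items(4, multiword_fraction = 0.5, seed = 19)
  expect_error(item_metrics(make_toy_encoder(z, n_layers = 2, dim = 8,
                                             seed = 1), z),
               "multiword anaphors present")
  kept <- filter_multiword_anaphors(z)
  enc <- make_toy_encoder(kept, n_layers = 2, dim = 8, seed = 1)
  m <- item_metrics(enc, kept)
  expect_identical(m$meta$n_target_averaged,
                   sum(nchar(sub(" .*", "",
                                 substr(kept$sentence, kept$target_start + 1,
                                        kept$target_end))) > 8))
  expect_true(all(m$cosine$d_cos >= 0 & m$cosine$d_cos <= 2))
  expect_true(all(m$surprisal$s >= 0))
})

test_that("layer correlations match a direct product-moment oracle", {
  means <- tibble::tibble(item = sprintf("i%d", 1:6),
                          mean = c(1.2, 2.5, 3.1, 4.8, 5.5, 6.4))
  cosine <- tibble::tibble(item = rep(means$item, 2),
                           layer = rep(1:2, each = 6),
                           d_cos = c(0.9, 0.7, 0.8, 0.4, 0.3, 0.1,
                                     -means$mean / 10))
  out <- layer_correlations(cosine, means)
  r_oracle <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(out$by_layer$r[1],
               r_oracle(cosine$d_cos[1:6], means$mean), tolerance = 1e-12)
  expect_equal(out$by_layer$r[2], -1, tolerance = 1e-12)
  expect_identical(out$strongest_layer, 2L)
  # Fisher-z interval brackets r and is inside [-1, 1]
  expect_true(all(out$by_layer$ci_lower <= out$by_layer$r &
                    out$by_layer$r <= out$by_layer$ci_upper))

  flat <- cosine
  flat$d_cos[flat$layer == 1] <- 0.5
  expect_warning(out2 <- layer_correlations(flat, means), "zero variance")
  expect_true(is.na(out2$by_layer$r[1]))
})
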