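#' Generate synthetic zeugma sentences with marked spans
#'
#' Builds items of the shape used for zeugma similarity norming: two
#' clauses joined by a conjunction, a single uppercase target word in the
#' first clause, and an anaphoric referring expression (usually "one") in
#' the second. Words are symbolic tokens, not real English. Character
#' offsets are 0-based and half-open. Each item carries a planted
#' `true_similarity` in `[0, 1]` — the ground-truth meaning similarity of
#' the target's two senses — drawn per condition so that `1 + 6 *
#' true_similarity` follows the condition's 1-7 rating distribution.
#'
#' @param n_per_condition Items per ambiguity condition.
#' @param multiword_fraction Probability that an item's anaphor is the
#'   multiword expression "a lot" (default 0), used to exercise the
#'   multiword-anaphor exclusion filter.
#' @param seed Integer seed.
#' @param condition_means,condition_item_sds Per-condition mean and SD of
#'   the similarity distribution on the 1-7 scale (defaults as in
#'   [rating_study_config()]).
#' @return A tibble with columns `item`, `sentence`, `target_start`,
#'   `target_end`, `anaphor_start`, `anaphor_end`, `anaphor_text`,
#'   `condition`, `true_similarity`. Span substrings always equal the
#'   recorded texts.
#' @export
generate_zeugma_items <- function(n_per_condition,
                                  multiword_fraction = 0,
                                  seed = 1L,
                                  condition_means = c(Homonym = 1.63,
                                                      IrregularPolyseme = 2.57,
                                                      RegularPolyseme = 4.96,
                                                      Unambiguous = 6.28),
                                  condition_item_sds = c(Homonym = 0.33,
                                                         IrregularPolyseme = 1.14,
                                                         RegularPolyseme = 1.27,
                                                         Unambiguous = 0.44)) {
  n_per_condition <- check_count(n_per_condition, "n_per_condition")
  check_rate(multiword_fraction, "multiword_fraction")
  withr::with_seed(derive_seed(seed, "zeugma"), {
    conds <- ambiguity_conditions()
    n <- 4L * n_per_condition
    condition <- rep(conds, each = n_per_condition)
    item <- sprintf("Z%03d", seq_len(n))
    # every 8th target is long enough to be split into subword pieces, so a
    # minority of sentences exercises span averaging
    target <- ifelse(seq_len(n) %% 8L == 0L,
                     sprintf("targetlongform%03d", seq_len(n)),
                     sprintf("targ%03d", seq_len(n)))
    subj1 <- sprintf("agent%02d", sample.int(40, n, replace = TRUE))
    subj2 <- sprintf("patient%02d", sample.int(40, n, replace = TRUE))
    verb1 <- sprintf("verbed%02d", sample.int(20, n, replace = TRUE))
    verb2 <- sprintf("saw%02d", sample.int(20, n, replace = TRUE))
    multi <- runif(n) < multiword_fraction
    # mostly "one", with enough variety that the anaphor grouping factor
    # has several levels; multiword items get "a lot"
    single <- sample(c("one", "one", "one", "it", "that", "some", "them"),
                     n, replace = TRUE)
    anaphor <- ifelse(multi, "a lot", single)

    sentence <- sprintf("the %s %s the %s and the %s %s %s .",
                        subj1, verb1, target, subj2, verb2, anaphor)
    locate <- function(s, txt) {
      start <- as.integer(regexpr(txt, s, fixed = TRUE)) - 1L
      c(start, start + nchar(txt))
    }
    tspan <- t(mapply(locate, sentence, target))
    aspan <- t(vapply(seq_len(n), function(i) {
      # anaphor is always the token(s) before the final " ."
      end <- nchar(sentence[i]) - 2L
      c(end - nchar(anaphor[i]), end)
    }, integer(2)))

    true_mean <- clamp(rnorm(n,
                             mean = condition_means[condition],
                             sd = condition_item_sds[condition]),
                       1, 7)
    tibble::tibble(
      item = item,
      sentence = sentence,
      target_start = as.integer(tspan[, 1]),
      target_end = as.integer(tspan[, 2]),
      anaphor_start = as.integer(aspan[, 1]),
      anaphor_end = as.integer(aspan[, 2]),
      anaphor_text = anaphor,
      condition = condition,
      true_similarity = (true_mean - 1) / 6
    )
  })
}
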