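#' Configuration for a simulated free-association dominance norming study
#'
#' Describes a study in which each participant types two free associates to
#' each ambiguous word, and two raters classify every response against the
#' word's candidate senses. Latent per-word sense mixtures are either
#' supplied or drawn with the dominant-sense proportion uniform on
#' (0.5, 1), a maximally uninformative prior over how biased a two-sense
#' word can be.
#'
#' @param n_words Number of stimulus words.
#' @param n_participants Number of norming participants.
#' @param responses_per_participant Free associates requested per word
#'   (default 2: a first and a second response).
#' @param true_sense_probs Optional list (length `n_words`) of probability
#'   vectors over each word's 2-5 latent senses. When `NULL`, each word
#'   gets two senses with the dominant proportion drawn uniformly on
#'   (0.5, 1).
#' @param rater_coverage Probability that a response is labeled by both
#'   raters rather than one (default 0.757).
#' @param rater_agreement Probability that the second rater's label matches
#'   the first rater's (default 0.949); disagreements pick uniformly among
#'   the word's other senses.
#' @param seed Integer seed; the study is fully reproducible given the
#'   config.
#' @return An `associate_study_config` list.
#' @export
associate_study_config <- function(n_words,
                                   n_participants,
                                   responses_per_participant = 2L,
                                   true_sense_probs = NULL,
                                   rater_coverage = 0.757,
                                   rater_agreement = 0.949,
                                   seed = 1L) {
  n_words <- check_count(n_words, "n_words")
  n_participants <- check_count(n_participants, "n_participants")
  responses_per_participant <- check_count(responses_per_participant,
                                           "responses_per_participant")
  check_rate(rater_coverage, "rater_coverage")
  check_rate(rater_agreement, "rater_agreement")
  if (!is.null(true_sense_probs)) {
    if (!is.list(true_sense_probs) || length(true_sense_probs) != n_words) {
      abort_config("true_sense_probs must be a list with one vector per word")
    }
    for (p in true_sense_probs) {
      check_probability_vector(p, "per-word sense probability vector")
      if (length(p) < 2 || length(p) > 5) {
        abort_config("each word must have between 2 and 5 latent senses")
      }
    }
  }
  structure(
    list(n_words = n_words,
         n_participants = n_participants,
         responses_per_participant = responses_per_participant,
         true_sense_probs = true_sense_probs,
         rater_coverage = rater_coverage,
         rater_agreement = rater_agreement,
         seed = as.integer(seed)),
    class = "associate_study_config"
  )
}

#' Simulate a free-association study with dual-rater sense classification
#'
#' Every participant contributes exactly `responses_per_participant`
#' responses per word; each response's latent sense is an independent draw
#' from the word's sense mixture. Rater 1 labels every response with its
#' true sense; with probability `rater_coverage` rater 2 also labels it,
#' agreeing with rater 1 with probability `rater_agreement` and otherwise
#' picking uniformly among the word's other senses. Response strings are
#' symbolic tokens tied to the latent sense, not real English associates.
#'
#' @param config An [associate_study_config()].
#' @return A list with tibbles `associates` (participant_id, word, slot,
#'   response_text), `assignments` (rater_id, participant_id, word, slot,
#'   label), `truth` (participant_id, word, slot, true_sense), and
#'   `sense_probs` (word, sense, prob) recording the mixtures actually
#'   used.
#' @export
simulate_associate_study <- function(config) {
  stopifnot(inherits(config, "associate_study_config"))
  withr::with_seed(derive_seed(config$seed, "associates"), {
    words <- sprintf("W%03d", seq_len(config$n_words))
    probs <- config$true_sense_probs
    if (is.null(probs)) {
      p1 <- runif(config$n_words, 0.5, 1)
      probs <- lapply(p1, function(p) c(p, 1 - p))
    }
    names(probs) <- words

    participants <- sprintf("P%03d", seq_len(config$n_participants))
    grid <- expand.grid(slot = seq_len(config$responses_per_participant),
                        word = words,
                        participant_id = participants,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    n <- nrow(grid)
    k_word <- vapply(probs, length, integer(1))
    true_sense <- integer(n)
    for (w in words) {
      idx <- grid$word == w
      true_sense[idx] <- sample.int(length(probs[[w]]), sum(idx),
                                    replace = TRUE, prob = probs[[w]])
    }
    associates <- tibble::tibble(
      participant_id = grid$participant_id,
      word = grid$word,
      slot = as.integer(grid$slot),
      response_text = sprintf("assoc_%s_s%d_%s", grid$word, true_sense,
                              grid$participant_id)
    )
    truth <- tibble::tibble(
      participant_id = grid$participant_id,
      word = grid$word,
      slot = as.integer(grid$slot),
      true_sense = true_sense
    )

    r1 <- tibble::tibble(
      rater_id = "R1",
      participant_id = grid$participant_id,
      word = grid$word,
      slot = as.integer(grid$slot),
      label = true_sense
    )
    covered <- runif(n) < config$rater_coverage
    agree <- runif(n) < config$rater_agreement
    k_here <- k_word[grid$word]
    other <- vapply(seq_len(n), function(i) {
      cand <- setdiff(seq_len(k_here[i]), true_sense[i])
      if (length(cand) == 1) cand else sample(cand, 1)
    }, integer(1))
    r2_label <- ifelse(agree, true_sense, other)
    r2 <- tibble::tibble(
      rater_id = "R2",
      participant_id = grid$participant_id[covered],
      word = grid$word[covered],
      slot = as.integer(grid$slot[covered]),
      label = r2_label[covered]
    )
    assignments <- dplyr::arrange(dplyr::bind_rows(r1, r2),
                                  .data$word, .data$participant_id,
                                  .data$slot, .data$rater_id)

    sense_probs <- tibble::tibble(
      word = rep(words, k_word),
      sense = unlist(lapply(k_word, seq_len), use.names = FALSE),
      prob = unlist(probs, use.names = FALSE)
    )
    list(associates = associates, assignments = assignments,
         truth = truth, sense_probs = sense_probs)
  })
}
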