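#' Sense label conventions
#'
#' Rater assignments carry an integer `label`: a sense index in `1..K`, or
#' `0`, the sentinel for responses judged to match multiple,
#' undifferentiable, or none of the word's candidate senses ("OTHER").
#'
#' @name sense-labels
NULL

OTHER_LABEL <- 0L

#' Tally rater sense assignments for one word
#'
#' Each rater's label counts as one rating: a response labeled by both
#' raters contributes two ratings, and when the raters disagree each label
#' is counted toward its own sense. OTHER labels are excluded from both
#' the counts and the denominator, which is the total number of ratings
#' aligned with any of the word's selected senses.
#'
#' @param assignments Tibble of rater assignments for a single word, with
#'   columns `rater_id`, `participant_id`, `word`, `slot`, `label` (see
#'   [sense-labels]).
#' @param n_senses Number of candidate senses `K` (2-5).
#' @return A `sense_tally`: list with `word`, `counts` (length `K`),
#'   `total_classified`, and `percentages` (counts / total_classified).
#' @export
tally_sense_assignments <- function(assignments, n_senses) {
  n_senses <- check_count(n_senses, "n_senses", min = 2L)
  if (n_senses > 5L) abort_config("n_senses must be between 2 and 5")
  word <- unique(assignments$word)
  if (length(word) != 1) {
    stop("assignments must all refer to a single word")
  }
  lab <- assignments$label
  if (any(lab < 0 | lab > n_senses)) {
    stop("labels must be 0 (OTHER) or a sense index in 1..n_senses")
  }
  counts <- tabulate(lab[lab != OTHER_LABEL], nbins = n_senses)
  total <- sum(counts)
  if (total == 0) {
    stop(errorCondition(
      sprintf("no classified ratings for word %s; skip it", word),
      class = c("ambinorm_empty_tally", "error")))
  }
  structure(
    list(word = word,
         counts = counts,
         total_classified = total,
         percentages = counts / total),
    class = "sense_tally"
  )
}

#' Meaning/sense dominance score
#'
#' The dominance of an ambiguous word's most frequent meaning over its
#' second most frequent one: `D = (p1 - p2) / p1`, where `p1 >= p2` are
#' the proportions of classified associates aligned with the top two
#' senses. `D = 0` for perfectly balanced meanings and `D = 1` when one
#' sense is completely dominant. Words at or below the `cutoff` (default
#' 0.75, the conventional boundary for calling an ambiguous word
#' meaning-balanced) are flagged `balanced`.
#'
#' @param x A `sense_tally` from [tally_sense_assignments()], or the
#'   numeric proportion `p1` of the most frequent sense.
#' @param ... Passed to methods.
#' @return A one-row tibble with `word`, `top1`, `top2`, `p1`, `p2`,
#'   `score`, `n_responses`, `balanced` (the numeric method leaves `word`,
#'   `top1`, `top2`, `n_responses` as `NA`).
#' @export
dominance_score <- function(x, ...) UseMethod("dominance_score")

#' @rdname dominance_score
#' @param p2 Proportion of the second most frequent sense (numeric method).
#' @param cutoff Balance cutoff on `D` (default 0.75).
#' @export
dominance_score.numeric <- function(x, p2, cutoff = 0.75, ...) {
  p1 <- x
  stopifnot(length(p1) == 1, length(p2) == 1)
  if (is.na(p1) || is.na(p2) || p1 < 0 || p2 < 0 || p2 > p1 || p1 > 1) {
    stop("need proportions with 0 <= p2 <= p1 <= 1")
  }
  if (p1 == 0) stop("p1 = 0: dominance undefined")
  score <- (p1 - p2) / p1
  tibble::tibble(word = NA_character_, top1 = NA_integer_, top2 = NA_integer_,
                 p1 = p1, p2 = p2, score = score,
                 n_responses = NA_integer_, balanced = score <= cutoff)
}

#' @rdname dominance_score
#' @export
dominance_score.sense_tally <- function(x, cutoff = 0.75, ...) {
  ord <- order(-x$percentages, seq_along(x$percentages)) # ties: lowest index
  top1 <- ord[1]; top2 <- ord[2]
  p1 <- x$percentages[top1]; p2 <- x$percentages[top2]
  if (p1 == 0) stop("p1 = 0: dominance undefined")
  out <- dominance_score(p1, p2, cutoff = cutoff)
  out$word <- x$word
  out$top1 <- as.integer(top1)
  out$top2 <- as.integer(top2)
  out$n_responses <- as.integer(x$total_classified)
  out
}

#' Dominance table for a whole associate study
#'
#' Tallies every word's assignments and computes its dominance record.
#' Words with no classified ratings (all labels OTHER) are skipped and
#' reported, mirroring the practice of rejecting unratable items.
#'
#' @param assignments Assignment tibble covering many words.
#' @param n_senses Either a single `K` for every word or a named vector
#'   `word -> K`.
#' @param cutoff Balance cutoff (default 0.75).
#' @return A tibble of dominance records (one row per retained word) with
#'   attribute `skipped`: character vector of words with empty tallies.
#' @export
dominance_table <- function(assignments, n_senses, cutoff = 0.75) {
  words <- sort(unique(assignments$word))
  k_of <- function(w) {
    if (length(n_senses) == 1 && is.null(names(n_senses))) n_senses
    else n_senses[[w]]
  }
  rows <- list(); skipped <- character(0)
  by_word <- split(assignments, assignments$word)
  for (w in words) {
    rec <- tryCatch(
      dominance_score(tally_sense_assignments(by_word[[w]], k_of(w)),
                      cutoff = cutoff),
      ambinorm_empty_tally = function(e) NULL)
    if (is.null(rec)) skipped <- c(skipped, w) else rows[[w]] <- rec
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Interrater reliability of sense assignments
#'
#' Coverage is the proportion of responses labeled by both raters (the
#' remainder being labeled by a single rater); consistency is the
#' proportion of both-labeled responses on which the raters gave the same
#' non-OTHER sense. Defined for exactly two raters.
#'
#' @param assignments Assignment tibble (any number of words).
#' @return List with `coverage`, `consistency`, `n_responses`,
#'   `n_both_labeled`. `consistency` is `NA` (with a warning) when no
#'   response was labeled by both raters.
#' @export
interrater_reliability <- function(assignments) {
  raters <- unique(assignments$rater_id)
  if (length(raters) > 2) {
    stop("interrater reliability is defined for two raters, got ",
         length(raters))
  }
  key <- paste(assignments$participant_id, assignments$word,
               assignments$slot, sep = "\r")
  by_rec <- split(assignments$label, key)
  n_raters <- lengths(by_rec)
  if (any(n_raters > 2)) stop("a record has more than one label per rater")
  both <- by_rec[n_raters == 2]
  coverage <- length(both) / length(by_rec)
  if (length(both) == 0) {
    warning("no response labeled by both raters; consistency undefined")
    consistency <- NA_real_
  } else {
    match_ok <- vapply(both, function(l)
      l[1] == l[2] && l[1] != OTHER_LABEL, logical(1))
    consistency <- mean(match_ok)
  }
  list(coverage = coverage, consistency = consistency,
       n_responses = length(by_rec), n_both_labeled = length(both))
}

#' Consensus sense per response
#'
#' Resolves each response to a single sense: the shared label when both
#' raters agree on a sense, the sense when only one rater assigned one (an
#' OTHER from the second rater does not override a sense from the first),
#' and unresolved (`NA`) when the raters disagree on two different senses
#' or no sense was assigned.
#'
#' @param assignments Assignment tibble.
#' @return Tibble with `participant_id`, `word`, `slot`, `sense`
#'   (integer or `NA`).
#' @export
resolve_consensus_labels <- function(assignments) {
  resolved <- dplyr::summarise(
    dplyr::group_by(assignments, .data$participant_id, .data$word,
                    .data$slot),
    sense = {
      senses <- unique(.data$label[.data$label != OTHER_LABEL])
      if (length(senses) == 1) senses else NA_integer_
    },
    .groups = "drop")
  resolved
}

#' First/second response meaning consistency
#'
#' For each (participant, word) pair of first and second responses, asks
#' whether both resolved to the same sense — the "doubling down" tendency
#' of free-association respondents. Pairs in which either response is
#' unresolved (OTHER or rater disagreement) are dropped.
#'
#' @param resolved Output of [resolve_consensus_labels()] (columns
#'   `participant_id`, `word`, `slot`, `sense`).
#' @return List with `same` (proportion of pairs resolving to one sense),
#'   `different` (`1 - same`), and `n_pairs`.
#' @export
response_meaning_consistency <- function(resolved) {
  ok <- resolved[!is.na(resolved$sense), ]
  pairs <- dplyr::summarise(
    dplyr::group_by(ok, .data$participant_id, .data$word),
    complete = dplyr::n() == 2,
    same = dplyr::n() == 2 && length(unique(.data$sense)) == 1,
    .groups = "drop")
  pairs <- pairs[pairs$complete, ]
  if (nrow(pairs) == 0) {
    stop(errorCondition("no valid first/second response pairs",
                        class = c("ambinorm_no_pairs", "error")))
  }
  same <- mean(pairs$same)
  list(same = same, different = 1 - same, n_pairs = nrow(pairs))
}
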