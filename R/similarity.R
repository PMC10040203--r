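#' Exclude flat or incomplete raters from a similarity norming
#'
#' A participant is excluded as "flat" when the absolute difference
#' between their mean rating of Homonym items and of Unambiguous items is
#' at most `flat_threshold`: the two anchor conditions are expected to sit
#' at opposite ends of the similarity scale, so a small spread marks a
#' rater who gave similar ratings regardless of item type. Participants
#' who rated fewer than `completeness` of the items are excluded as
#' incomplete, and participants with no ratings in either anchor condition
#' as having insufficient anchor data.
#'
#' @param ratings Tibble with `participant_id`, `item`, `rating`.
#' @param items Tibble with `item`, `condition`.
#' @param flat_threshold Maximum anchor-condition spread to call a rater
#'   flat (default 0.5).
#' @param completeness Minimum fraction of items a participant must have
#'   rated (default 0.8).
#' @return List with `kept` (character vector of participant ids) and
#'   `excluded` (tibble `participant_id`, `reason` in
#'   `{"flat", "incomplete", "insufficient anchor data"}`).
#' @export
exclude_participants <- function(ratings, items, flat_threshold = 0.5,
                                 completeness = 0.8) {
  missing_cond <- setdiff(unique(ratings$item), items$item)
  if (length(missing_cond) > 0) {
    stop("rated items without a condition label: ",
         paste(utils::head(missing_cond, 5), collapse = ", "))
  }
  dat <- dplyr::left_join(ratings, items[, c("item", "condition")],
                          by = "item")
  n_items <- length(unique(items$item))
  per <- dplyr::summarise(
    dplyr::group_by(dat, .data$participant_id),
    n_rated = dplyr::n_distinct(.data$item),
    hom = mean(.data$rating[.data$condition == "Homonym"]),
    unamb = mean(.data$rating[.data$condition == "Unambiguous"]),
    .groups = "drop")
  reason <- rep(NA_character_, nrow(per))
  reason[per$n_rated < completeness * n_items] <- "incomplete"
  anchorless <- is.na(per$hom) | is.na(per$unamb)
  reason[is.na(reason) & anchorless] <- "insufficient anchor data"
  flat <- !anchorless & abs(per$hom - per$unamb) <= flat_threshold
  reason[is.na(reason) & flat] <- "flat"
  excluded <- tibble::tibble(participant_id = per$participant_id,
                             reason = reason)[!is.na(reason), ]
  list(kept = per$participant_id[is.na(reason)], excluded = excluded)
}

#' Apply an item exclusion list
#'
#' @param items Item tibble with `item`, `condition`.
#' @param exclude Character vector of item ids to drop (e.g. items later
#'   found to be mis-designed).
#' @return The retained items, with attribute `condition_counts` (named
#'   integer vector of retained items per condition). Excluding an unknown
#'   item is an error; emptying a condition raises a warning.
#' @export
exclude_items <- function(items, exclude = character(0)) {
  unknown <- setdiff(exclude, items$item)
  if (length(unknown) > 0) {
    stop("exclusion list names unknown item(s): ",
         paste(unknown, collapse = ", "))
  }
  kept <- items[!items$item %in% exclude, ]
  counts <- table(factor(kept$condition, levels = ambiguity_conditions()))
  counts <- setNames(as.integer(counts), names(counts))
  if (any(counts == 0)) {
    warning("condition(s) with no retained items: ",
            paste(names(counts)[counts == 0], collapse = ", "))
  }
  attr(kept, "condition_counts") <- counts
  kept
}

#' Per-item similarity statistics
#'
#' Mean, sample SD (n - 1 denominator) and SEM (`SD / sqrt(n)`) of the
#' ratings each item received from the kept participants.
#'
#' @param ratings Tibble with `participant_id`, `item`, `rating` (already
#'   filtered to kept participants).
#' @param items Item tibble with `item`, `condition`; only these items are
#'   summarised.
#' @return Tibble `item`, `condition`, `n`, `mean`, `sd`, `sem`; `sd` and
#'   `sem` are `NA` when an item has fewer than 2 ratings (with a
#'   warning).
#' @export
item_statistics <- function(ratings, items) {
  dat <- dplyr::inner_join(ratings, items[, c("item", "condition")],
                           by = "item")
  out <- dplyr::summarise(
    dplyr::group_by(dat, .data$item, .data$condition),
    n = dplyr::n(),
    mean = mean(.data$rating),
    sd = sd(.data$rating),
    .groups = "drop")
  out$sd[out$n < 2] <- NA_real_
  out$sem <- sem(out$sd, out$n)
  if (any(out$n < 2)) {
    warning(sum(out$n < 2), " item(s) with fewer than 2 ratings: SD/SEM undefined")
  }
  out
}

#' Condition-level statistics and pairwise comparisons
#'
#' Summarises item means by ambiguity condition (mean and SD computed
#' across item means, not pooled ratings) and runs all six pairwise
#' two-sided Welch t tests on the item means, Bonferroni-adjusted for the
#' six comparisons.
#'
#' @param item_stats Output of [item_statistics()].
#' @param alpha Significance level for the reported flags (default 0.01).
#' @return List with `conditions` (tibble `condition`, `n_items`, `mean`,
#'   `sd`) and `tests` (tibble `condition_a`, `condition_b`, `t`, `df`,
#'   `p_raw`, `p_adjusted`, `significant`). Pairs involving a condition
#'   with fewer than 2 items get `NA` statistics.
#' @export
condition_statistics <- function(item_stats, alpha = 0.01) {
  conds <- ambiguity_conditions()
  summary <- dplyr::summarise(
    dplyr::group_by(item_stats, .data$condition),
    n_items = dplyr::n(),
    sd = sd(.data$mean),
    mean = mean(.data$mean),
    .groups = "drop")
  summary <- summary[, c("condition", "n_items", "mean", "sd")]
  summary <- summary[order(match(summary$condition, conds)), ]

  pairs <- utils::combn(conds[conds %in% summary$condition], 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- item_stats$mean[item_stats$condition == pairs[1, j]]
    b <- item_stats$mean[item_stats$condition == pairs[2, j]]
    if (length(a) < 2 || length(b) < 2) {
      warning("fewer than 2 items in a condition; test ",
              pairs[1, j], " vs ", pairs[2, j], " not computed")
      return(tibble::tibble(condition_a = pairs[1, j],
                            condition_b = pairs[2, j],
                            t = NA_real_, df = NA_real_, p_raw = NA_real_))
    }
    tt <- t.test(a, b, var.equal = FALSE)
    tibble::tibble(condition_a = pairs[1, j], condition_b = pairs[2, j],
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_raw = tt$p.value)
  })
  tests <- dplyr::bind_rows(rows)
  tests$p_adjusted <- bonferroni_adjust(tests$p_raw, m)
  tests$significant <- !is.na(tests$p_adjusted) & tests$p_adjusted < alpha
  list(conditions = summary, tests = tests)
}

#' Leave-one-out inter-annotator agreement
#'
#' For each participant, the Spearman rank correlation (average ranks for
#' ties) between that participant's ratings and the mean rating given to
#' the same items by all remaining participants. Items the participant
#' rated but nobody else did are dropped; participants left with fewer
#' than `min_items` usable items get an undefined rho and are excluded
#' from the summary with a warning.
#'
#' @param ratings Tibble with `participant_id`, `item`, `rating`.
#' @param min_items Minimum usable items per participant (default 3).
#' @return List with `per_participant` (tibble `participant_id`, `rho`,
#'   `n_items`) and `summary` (`mean`, `sd`, `median`, `min`, `max`,
#'   `n`).
#' @export
loo_agreement <- function(ratings, min_items = 3L) {
  participants <- unique(ratings$participant_id)
  if (length(participants) < 3) {
    stop("leave-one-out agreement needs at least 3 participants")
  }
  # item totals let the leave-one-out mean be computed in one pass
  totals <- dplyr::summarise(
    dplyr::group_by(ratings, .data$item),
    total = sum(.data$rating), n = dplyr::n(), .groups = "drop")
  dat <- dplyr::left_join(ratings, totals, by = "item")
  loo_mean <- (dat$total - dat$rating) / (dat$n - 1)
  usable <- dat$n >= 2
  rho_tbl <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(participant_id = dat$participant_id[usable],
                                   own = dat$rating[usable],
                                   others = loo_mean[usable]),
                    .data$participant_id),
    rho = if (dplyr::n() >= min_items)
      suppressWarnings(cor(.data$own, .data$others, method = "spearman"))
    else NA_real_,
    n_items = dplyr::n(),
    .groups = "drop")
  if (anyNA(rho_tbl$rho)) {
    warning(sum(is.na(rho_tbl$rho)),
            " participant(s) with undefined rho excluded from the summary")
  }
  rho <- rho_tbl$rho[!is.na(rho_tbl$rho)]
  list(per_participant = rho_tbl,
       summary = list(mean = mean(rho), sd = sd(rho),
                      median = stats::median(rho),
                      min = min(rho), max = max(rho), n = length(rho)))
}
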