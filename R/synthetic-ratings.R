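#' Configuration for a simulated zeugma similarity-rating study
#'
#' Describes a norming study in which participants rate the meaning
#' similarity of a target word and its anaphor on a 1-7 Likert scale, with
#' items in four ambiguity conditions. Default condition means and
#' across-item SDs are the observed condition statistics of the human
#' norms this generator emulates: Homonym 1.63 (0.33), IrregularPolyseme
#' 2.57 (1.14), RegularPolyseme 4.96 (1.27), Unambiguous 6.28 (0.44).
#'
#' @param condition_means Named numeric vector: target mean of item means
#'   per condition, on the 1-7 scale.
#' @param condition_item_sds Named numeric vector: SD of item means per
#'   condition.
#' @param within_item_sd Latent rating-noise SD around each item's mean
#'   (default 1.2, of the order of the within-item SDs reported for
#'   individual items).
#' @param items_per_condition Items per condition (default 80).
#' @param n_participants Raters, each rating every item (default 88).
#' @param n_flat_raters Planted uncooperative raters who give one constant
#'   rating to every item (default 0); these should be caught by the
#'   participant exclusion rule.
#' @param seed Integer seed.
#' @return A `rating_study_config` list.
#' @export
rating_study_config <- function(condition_means = c(Homonym = 1.63,
                                                    IrregularPolyseme = 2.57,
                                                    RegularPolyseme = 4.96,
                                                    Unambiguous = 6.28),
                                condition_item_sds = c(Homonym = 0.33,
                                                       IrregularPolyseme = 1.14,
                                                       RegularPolyseme = 1.27,
                                                       Unambiguous = 0.44),
                                within_item_sd = 1.2,
                                items_per_condition = 80L,
                                n_participants = 88L,
                                n_flat_raters = 0L,
                                seed = 1L) {
  conds <- ambiguity_conditions()
  if (!all(conds %in% names(condition_means)) ||
      !all(conds %in% names(condition_item_sds))) {
    abort_config("condition_means and condition_item_sds must name all four conditions")
  }
  if (any(condition_means < 1) || any(condition_means > 7)) {
    abort_config("condition means must lie within the 1-7 scale")
  }
  if (any(condition_item_sds < 0) || within_item_sd < 0) {
    abort_config("standard deviations must be non-negative")
  }
  items_per_condition <- check_count(items_per_condition, "items_per_condition")
  n_participants <- check_count(n_participants, "n_participants")
  n_flat_raters <- check_count(n_flat_raters, "n_flat_raters", min = 0L)
  if (n_flat_raters > n_participants) {
    abort_config("n_flat_raters cannot exceed n_participants")
  }
  structure(
    list(condition_means = condition_means[conds],
         condition_item_sds = condition_item_sds[conds],
         within_item_sd = within_item_sd,
         items_per_condition = items_per_condition,
         n_participants = n_participants,
         n_flat_raters = n_flat_raters,
         seed = as.integer(seed)),
    class = "rating_study_config"
  )
}

# Latent Gaussian mean whose rounded-and-clamped 1..7 rating has the target
# expectation. Rounding to a bounded scale pulls means toward the middle;
# solving for the latent mean keeps the simple Gaussian generative model
# while making recovered item means unbiased.
calibrate_latent_mean <- function(target, sigma) {
  if (sigma == 0) return(target)
  # E[Y] = 7 - sum_{k=1..6} P(Y <= k) for Y supported on 1..7
  expected <- function(mu) {
    p_le <- pnorm((1:6 + 0.5 - mu) / sigma) # P(Y <= k), k = 1..6
    7 - sum(p_le)
  }
  target <- clamp(target, 1 + 1e-9, 7 - 1e-9)
  uniroot(function(mu) expected(mu) - target,
          lower = 1 - 12 * sigma, upper = 7 + 12 * sigma,
          tol = 1e-10)$root
}

#' Simulate a similarity-rating study
#'
#' Item true means are drawn per condition from the configured
#' mean/SD (clamped to the 1-7 scale); each rating is a Gaussian draw
#' around the item's mean, rounded to the nearest integer and clamped to
#' 1..7. The latent Gaussian mean is calibrated so the expected observed
#' rating equals the item's true mean despite rounding and clamping.
#' Planted flat raters give a single constant rating (drawn once from
#' 3..5) to every item.
#'
#' @param config A [rating_study_config()].
#' @param items Optional item table (tibble with `item`, `condition`, and
#'   `true_similarity` in `[0, 1]`), e.g. from [generate_zeugma_items()];
#'   item true means are then `1 + 6 * true_similarity` instead of fresh
#'   condition draws, tying ratings to the planted sense similarity.
#' @return A list with tibbles `ratings` (participant_id, item, rating),
#'   `items` (item, condition, true_mean), and `flat_raters` (the planted
#'   participant ids).
#' @export
simulate_rating_study <- function(config, items = NULL) {
  stopifnot(inherits(config, "rating_study_config"))
  withr::with_seed(derive_seed(config$seed, "ratings"), {
    conds <- ambiguity_conditions()
    if (is.null(items)) {
      item_tbl <- tibble::tibble(
        item = sprintf("item_%03d",
                       seq_len(4L * config$items_per_condition)),
        condition = rep(conds, each = config$items_per_condition)
      )
      item_tbl$true_mean <- clamp(
        rnorm(nrow(item_tbl),
              mean = config$condition_means[item_tbl$condition],
              sd = config$condition_item_sds[item_tbl$condition]),
        1, 7)
    } else {
      stopifnot(all(c("item", "condition", "true_similarity") %in% names(items)))
      item_tbl <- tibble::tibble(item = items$item,
                                 condition = items$condition,
                                 true_mean = 1 + 6 * items$true_similarity)
    }

    mu <- vapply(item_tbl$true_mean, calibrate_latent_mean,
                 numeric(1), sigma = config$within_item_sd)
    participants <- sprintf("S%03d", seq_len(config$n_participants))
    flat <- participants[seq_len(config$n_flat_raters)]

    n_items <- nrow(item_tbl)
    ratings <- tibble::tibble(
      participant_id = rep(participants, each = n_items),
      item = rep(item_tbl$item, times = config$n_participants),
      rating = as.integer(clamp(round(
        rnorm(n_items * config$n_participants,
              mean = rep(mu, times = config$n_participants),
              sd = config$within_item_sd)), 1, 7))
    )
    if (length(flat) > 0) {
      flat_values <- sample(3:5, length(flat), replace = TRUE)
      names(flat_values) <- flat
      is_flat <- ratings$participant_id %in% flat
      ratings$rating[is_flat] <- flat_values[ratings$participant_id[is_flat]]
    }
    list(ratings = ratings, items = item_tbl, flat_raters = flat)
  })
}
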