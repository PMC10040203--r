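#' Specification of a linear mixed model for the metric analyses
#'
#' Models relate an encoder metric or the human similarity means to the
#' ambiguity condition and to each other, with a random intercept for the
#' anaphoric expression. Condition enters as a treatment-coded factor
#' whose reference level is the alphabetically first one (Homonym).
#'
#' @param response One of `"surprisal"`, `"cosine_distance"`,
#'   `"mean_similarity"` (or any column of the analysis table).
#' @param fixed_effects Character vector of fixed-effect terms (possibly
#'   empty for an intercept-only model).
#' @param random_intercept Grouping factor for the random intercept
#'   (default `"anaphor"`).
#' @return A `model_spec` list.
#' @export
model_spec <- function(response,
                       fixed_effects = character(0),
                       random_intercept = "anaphor") {
  if (response %in% fixed_effects) {
    abort_config("the response cannot also be a fixed effect")
  }
  structure(list(response = response,
                 fixed_effects = fixed_effects,
                 random_intercept = random_intercept),
            class = "model_spec")
}

spec_formula <- function(spec) {
  rhs <- if (length(spec$fixed_effects) == 0) "1" else
    paste(spec$fixed_effects, collapse = " + ")
  stats::as.formula(sprintf("%s ~ %s + (1 | %s)",
                            spec$response, rhs, spec$random_intercept))
}

#' Fit a linear mixed model by maximum likelihood
#'
#' Fits `response ~ fixed effects + (1 | group)` with lme4 under ML (not
#' REML), so that likelihood-ratio tests between nested fixed-effect
#' structures are valid. Factor predictors use R's default treatment
#' coding (alphabetical reference level). A singular fit (zero estimated
#' group variance) is kept, with a warning; in that limit the fixed
#' effects coincide with ordinary least squares.
#'
#' @param spec A [model_spec()].
#' @param data Data frame with complete cases for all model variables; the
#'   grouping factor needs at least 2 levels.
#' @return An `ambinorm_fit`: list with `model` (the merMod), `spec`,
#'   `formula`, `loglik`, `n_fixed` (fixed-effect parameter count),
#'   `coefficients`, `singular`, `n_obs`.
#' @export
fit_mixed_model <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- c(spec$response, spec$fixed_effects, spec$random_intercept)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    stop("data lacks model variable(s): ", paste(missing_vars, collapse = ", "))
  }
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), ,
               drop = FALSE]
  if (length(unique(data[[spec$random_intercept]])) < 2) {
    stop("grouping factor must have at least 2 levels")
  }
  fml <- spec_formula(spec)
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = data, REML = FALSE),
    message = function(m) invokeRestart("muffleMessage"))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("singular fit: random-intercept variance estimated at zero",
            call. = FALSE)
  }
  structure(
    list(model = fit,
         spec = spec,
         formula = fml,
         loglik = as.numeric(logLik(fit)),
         n_fixed = length(lme4::fixef(fit)),
         coefficients = lme4::fixef(fit),
         singular = singular,
         n_obs = nrow(data)),
    class = "ambinorm_fit"
  )
}

#' Likelihood-ratio test between nested mixed models
#'
#' `chi2 = 2 (loglik_full - loglik_reduced)` (floored at zero against
#' optimizer noise), with degrees of freedom equal to the difference in
#' fixed-effect parameter counts (a 4-level condition factor contributes
#' 3), referred to the upper tail of the chi-square distribution. Both
#' fits must be ML fits of the same response on the same rows, with the
#' reduced model's fixed effects a subset of the full model's (identical
#' sets give the degenerate self-comparison: chi2 0, df 0, p 1).
#'
#' @param full,reduced `ambinorm_fit` objects from [fit_mixed_model()].
#' @return Tibble `chi2`, `df`, `p_raw`, `loglik_full`, `loglik_reduced`
#'   (one row).
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "ambinorm_fit"), inherits(reduced, "ambinorm_fit"))
  if (full$spec$response != reduced$spec$response ||
      full$spec$random_intercept != reduced$spec$random_intercept) {
    stop("models are not nested: response or random structure differs")
  }
  if (!all(reduced$spec$fixed_effects %in% full$spec$fixed_effects)) {
    stop("reduced fixed effects must be a subset of the full model's")
  }
  if (full$n_obs != reduced$n_obs) {
    stop("models were fitted on different numbers of rows")
  }
  df <- full$n_fixed - reduced$n_fixed
  chi2 <- 2 * (full$loglik - reduced$loglik)
  if (chi2 < -1e-6) {
    warning("full model loglik below reduced; chi2 floored at 0")
  }
  chi2 <- max(chi2, 0)
  # identical fixed effects (df 0) is the degenerate self-comparison: p = 1
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  tibble::tibble(chi2 = chi2, df = df,
                 p_raw = p,
                 loglik_full = full$loglik,
                 loglik_reduced = reduced$loglik)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` for a family of `m` comparisons (here
#' typically `m = 2`, for the two encoder-derived metrics testing the same
#' hypothesis). Order-preserving, never below the raw p.
#'
#' @param p Numeric vector of raw p values in `[0, 1]` (`NA` passed
#'   through).
#' @param m Family size.
#' @return Adjusted p values.
#' @export
bonferroni_adjust <- function(p, m) {
  m <- check_count(m, "family size m")
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]")
  }
  pmin(1, m * p)
}

#' Merge items, human means, and encoder metrics into one analysis table
#'
#' @param item_stats Item statistics ([item_statistics()]); supplies
#'   `mean_similarity`.
#' @param metrics Output of [item_metrics()].
#' @param items Zeugma item tibble; supplies `condition` and the anaphor
#'   grouping factor.
#' @param layer Which layer's cosine distance to carry (default: the final
#'   layer).
#' @return Tibble `item`, `condition`, `anaphor`, `mean_similarity`,
#'   `surprisal`, `cosine_distance`.
#' @export
assemble_analysis_table <- function(item_stats, metrics, items,
                                    layer = NULL) {
  layer <- layer %||% max(metrics$cosine$layer)
  d <- metrics$cosine[metrics$cosine$layer == layer,
                      c("item", "d_cos")]
  out <- dplyr::inner_join(
    dplyr::inner_join(
      tibble::tibble(item = items$item,
                     condition = items$condition,
                     anaphor = items$anaphor_text),
      tibble::tibble(item = item_stats$item,
                     mean_similarity = item_stats$mean),
      by = "item"),
    dplyr::inner_join(metrics$surprisal, d, by = "item"),
    by = "item")
  names(out)[names(out) == "s"] <- "surprisal"
  names(out)[names(out) == "d_cos"] <- "cosine_distance"
  out
}

#' The nested model comparisons of the metric analysis
#'
#' Runs the two families of likelihood-ratio tests relating the encoder
#' metrics, condition, and human similarity, each Bonferroni-adjusted for
#' the two metrics:
#' \enumerate{
#'   \item Does condition explain each metric? `surprisal ~ condition`
#'     vs. intercept-only, and the same for `cosine_distance` (df 3).
#'   \item Does each metric explain human similarity beyond condition?
#'     `mean_similarity ~ condition + metric` vs.
#'     `mean_similarity ~ condition` (df 1).
#' }
#' All models carry a random intercept for the anaphor.
#'
#' @param data Analysis table from [assemble_analysis_table()].
#' @return Tibble with one row per comparison: `family`, `response`,
#'   `tested`, `chi2`, `df`, `p_raw`, `p_adjusted`.
#' @export
run_model_comparisons <- function(data) {
  one <- function(family, response, tested, keep) {
    full <- fit_mixed_model(model_spec(response, c(keep, tested)), data)
    red <- fit_mixed_model(model_spec(response, keep), data)
    cmp <- likelihood_ratio_test(full, red)
    tibble::tibble(family = family, response = response, tested = tested,
                   chi2 = cmp$chi2, df = cmp$df, p_raw = cmp$p_raw)
  }
  fam1 <- dplyr::bind_rows(
    one("metric_by_condition", "surprisal", "condition", character(0)),
    one("metric_by_condition", "cosine_distance", "condition", character(0)))
  fam2 <- dplyr::bind_rows(
    one("similarity_beyond_condition", "mean_similarity", "surprisal",
        "condition"),
    one("similarity_beyond_condition", "mean_similarity", "cosine_distance",
        "condition"))
  out <- dplyr::bind_rows(fam1, fam2)
  out$p_adjusted <- stats::ave(out$p_raw, out$family,
                               FUN = function(p) bonferroni_adjust(p, 2))
  out
}
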