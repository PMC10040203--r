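# Small in-code fixtures shared across test files.

# assignment rows for one word: `labels` is a list of per-response label
# pairs; NA in the second position means rater 2 did not label the response
make_assignments <- function(word, labels) {
  rows <- lapply(seq_along(labels), function(i) {
    l <- labels[[i]]
    out <- tibble::tibble(rater_id = "R1",
                          participant_id = sprintf("P%02d", i),
                          word = word, slot = 1L, label = as.integer(l[1]))
    if (length(l) > 1 && !is.na(l[2])) {
      out <- rbind(out, tibble::tibble(rater_id = "R2",
                                       participant_id = sprintf("P%02d", i),
                                       word = word, slot = 1L,
                                       label = as.integer(l[2])))
    }
    out
  })
  dplyr::bind_rows(rows)
}

make_rating_fixture <- function(mat, items = NULL) {
  # mat: participants x items matrix of ratings
  n_p <- nrow(mat); n_i <- ncol(mat)
  ids <- sprintf("S%02d", seq_len(n_p))
  its <- colnames(mat) %||% sprintf("item_%02d", seq_len(n_i))
  tibble::tibble(participant_id = rep(ids, each = n_i),
                 item = rep(its, times = n_p),
                 rating = as.integer(t(mat)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a 320-item design table: 80 items per condition, Homonym first
design_320 <- function() {
  tibble::tibble(
    item = sprintf("item_%03d", 1:320),
    condition = rep(ambinorm::ambiguity_conditions(), each = 80))
}

# data whose groups are exact copies of one block, so the group-effect
# variance is estimated at zero and the mixed model's fixed effects must
# collapse onto ordinary least squares
ols_limit_data <- function(seed = 31, n_groups = 5, per_group = 12) {
  withr::with_seed(seed, {
    cond <- rep(ambinorm::ambiguity_conditions(), length.out = per_group)
    x <- rnorm(per_group)
    y <- 2 + 0.5 * x + c(Homonym = 0, IrregularPolyseme = 1,
                         RegularPolyseme = 2, Unambiguous = 3)[cond] +
      rnorm(per_group, sd = 0.4)
    block <- data.frame(y = y, x = x, condition = cond)
    d <- block[rep(seq_len(per_group), n_groups), ]
    d$anaphor <- factor(rep(sprintf("g%d", seq_len(n_groups)),
                            each = per_group))
    rownames(d) <- NULL
    d
  })
}

# simulated-null LRT p-values, computed once and cached for the session:
# response depends on a random anaphor-group intercept but not on the
# tested predictor x
.null_lrt_cache <- new.env(parent = emptyenv())
null_lrt_pvalues <- function(n_reps = 1000, seed = 20260101) {
  key <- sprintf("r%d_s%d", n_reps, seed)
  hit <- .null_lrt_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      g <- factor(rep(1:10, each = 5))
      d <- data.frame(
        y = rnorm(10)[as.integer(g)] * 0.8 + rnorm(50),
        x = rnorm(50),
        anaphor = g)
      full <- suppressWarnings(
        ambinorm::fit_mixed_model(ambinorm::model_spec("y", "x"), d))
      red <- suppressWarnings(
        ambinorm::fit_mixed_model(ambinorm::model_spec("y", character(0)), d))
      ambinorm::likelihood_ratio_test(full, red)$p_raw
    }, numeric(1))
  })
  .null_lrt_cache[[key]] <- p
  p
}
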