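test_that("flat raters are excluded on the anchor-condition spread", {
  items <- tibble::tibble(item = c("h1", "h2", "u1", "u2"),
                          condition = c("Homonym", "Homonym",
                                        "Unambiguous", "Unambiguous"))
  mat <- rbind(c(4, 4, 4, 4),   # flat: spread 0
               c(2, 1, 6, 7),   # spread 5 -> kept
               c(1, 2, 2, 1))   # spread 0 -> flat
  colnames(mat) <- items$item
  ratings <- make_rating_fixture(mat)
  out <- exclude_participants(ratings, items, completeness = 0)
  expect_identical(out$kept, "S02")
  expect_identical(sort(out$excluded$participant_id), c("S01", "S03"))
  expect_true(all(out$excluded$reason == "flat"))
})

test_that("anchorless and incomplete participants get distinct reasons", {
  items <- tibble::tibble(item = c("h1", "u1", "r1"),
                          condition = c("Homonym", "Unambiguous",
                                        "RegularPolyseme"))
  ratings <- tibble::tibble(
    participant_id = c("A", "A", "A", "B"),
    item = c("h1", "u1", "r1", "r1"),
    rating = c(1L, 7L, 4L, 4L))
  out <- exclude_participants(ratings, items, completeness = 0.9)
  expect_identical(out$kept, "A")
  expect_identical(out$excluded$reason, "incomplete")

  out2 <- exclude_participants(ratings, items, completeness = 0)
  expect_identical(out2$excluded$participant_id, "B")
  expect_identical(out2$excluded$reason, "insufficient anchor data")

  bad <- rbind(ratings, tibble::tibble(participant_id = "A",
                                       item = "zzz", rating = 4L))
  expect_error(exclude_participants(bad, items), "without a condition")
})

test_that("item exclusions reproduce the design counts", {
  items <- design_320()
  kept <- exclude_items(items, c("item_001", "item_002"))
  counts <- attr(kept, "condition_counts")
  expect_identical(nrow(kept), 318L)
  expect_identical(unname(counts),
                   c(78L, 80L, 80L, 80L))

  expect_identical(exclude_items(items)$item, items$item)
  expect_error(exclude_items(items, "nope"), "unknown item")
  small <- items[items$item %in% sprintf("item_%03d", 1:81), ]
  expect_warning(exclude_items(small, sprintf("item_%03d", 1:80)),
                 "no retained items")
})

test_that("item statistics use sample SD and SEM = SD / sqrt(n)", {
  items <- tibble::tibble(item = c("a", "b"),
                          condition = c("Homonym", "Unambiguous"))
  ratings <- tibble::tibble(
    participant_id = rep(c("S1", "S2", "S3"), 2),
    item = rep(c("a", "b"), each = 3),
    rating = c(1L, 2L, 3L, 5L, 5L, 5L))
  st <- item_statistics(ratings, items)
  a <- st[st$item == "a", ]
  expect_equal(a$mean, 2)
  expect_equal(a$sd, 1)
  expect_equal(a$sem, 1 / sqrt(3))
  b <- st[st$item == "b", ]
  expect_equal(b$sd, 0)
  expect_equal(b$sem, 0)
  expect_equal(st$sem * sqrt(st$n), st$sd, tolerance = 1e-12)

  lone <- ratings[c(1, 4), ]
  expect_warning(st2 <- item_statistics(lone, items), "fewer than 2")
  expect_true(all(is.na(st2$sd)))
})

test_that("condition tests are Welch t tests with Bonferroni adjustment", {
  st <- tibble::tibble(
    item = sprintf("i%02d", 1:12),
    condition = rep(ambiguity_conditions(), each = 3),
    n = 10L,
    mean = c(1, 2, 3, 1, 2, 3, 5, 6, 7, 5, 6, 7),
    sd = 1, sem = 1 / sqrt(10))
  out <- condition_statistics(st)
  # identical item-mean vectors: t = 0, adjusted p capped at 1
  hi <- out$tests[out$tests$condition_a == "Homonym" &
                    out$tests$condition_b == "IrregularPolyseme", ]
  expect_equal(hi$t, 0)
  expect_equal(hi$p_adjusted, 1)
  # hand-derived Welch statistic for {1,2,3} vs {5,6,7}
  hr <- out$tests[out$tests$condition_a == "Homonym" &
                    out$tests$condition_b == "RegularPolyseme", ]
  se <- sqrt(1 / 3 + 1 / 3) # both sample variances are 1, n = 3
  expect_equal(hr$t, (2 - 6) / se, tolerance = 1e-12)
  expect_equal(hr$df, 4, tolerance = 1e-9)
  expect_true(all(out$tests$p_adjusted >= out$tests$p_raw, na.rm = TRUE))
  expect_true(all(out$tests$p_adjusted <= 1, na.rm = TRUE))
  # condition means lie within the range of their item means
  expect_true(all(out$conditions$mean >= c(1, 1, 5, 5) &
                    out$conditions$mean <= c(3, 3, 7, 7)))
})

test_that("cloned raters have perfect leave-one-out agreement", {
  mat <- rbind(c(1, 3, 5, 7), c(1, 3, 5, 7), c(1, 3, 5, 7))
  ag <- loo_agreement(make_rating_fixture(mat))
  expect_true(all(ag$per_participant$rho == 1))
  expect_equal(ag$summary$mean, 1)
})

test_that("leave-one-out rho matches a brute-force rank oracle", {
  mat <- rbind(c(1, 2, 3, 4),
               c(2, 1, 4, 3),
               c(7, 5, 6, 1))
  ratings <- make_rating_fixture(mat)
  ag <- loo_agreement(ratings)
  # oracle: explicit leave-one-out means and Pearson on average ranks
  spearman <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  for (i in 1:3) {
    others <- colMeans(mat[-i, , drop = FALSE])
    oracle <- spearman(mat[i, ], others)
    got <- ag$per_participant$rho[ag$per_participant$participant_id ==
                                    sprintf("S%02d", i)]
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("rho is invariant under strictly monotone transforms", {
  withr::with_seed(13, {
    mat <- matrix(sample(1:7, 5 * 8, replace = TRUE), nrow = 5)
    base <- loo_agreement(make_rating_fixture(mat))$per_participant
    warped <- make_rating_fixture(mat)
    one <- warped$participant_id == "S01"
    # strictly increasing transform of participant S01's ratings only
    warped$rating[one] <- warped$rating[one]^2 + 3L
    trans <- loo_agreement(warped)$per_participant
    expect_equal(trans$rho[trans$participant_id == "S01"],
                 base$rho[base$participant_id == "S01"], tolerance = 1e-12)
  })
})

test_that("participants with too few usable items are reported undefined", {
  ratings <- dplyr::bind_rows(
    make_rating_fixture(rbind(c(1, 2, 3, 4), c(2, 3, 4, 5), c(3, 4, 5, 6))),
    tibble::tibble(participant_id = "S99", item = c("item_01", "item_02"),
                   rating = c(1L, 2L)))
  expect_warning(ag <- loo_agreement(ratings), "undefined rho")
  expect_true(is.na(ag$per_participant$rho[
    ag$per_participant$participant_id == "S99"]))
  expect_identical(ag$summary$n, 3L)
  expect_error(loo_agreement(make_rating_fixture(rbind(c(1, 2), c(2, 1)))),
               "at least 3 participants")
})

test_that("duplicating a participant cannot decrease their agreement", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      mat <- matrix(sample(1:7, 4 * 6, replace = TRUE), nrow = 4)
      if (sd(mat[1, ]) == 0) next
      base <- loo_agreement(make_rating_fixture(mat))$per_participant
      dup <- rbind(mat, mat[1, ])
      with_dup <- loo_agreement(make_rating_fixture(dup))$per_participant
      r0 <- base$rho[base$participant_id == "S01"]
      r1 <- with_dup$rho[with_dup$participant_id == "S01"]
      expect_gte(r1, r0 - 1e-9)
    }
  })
})
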