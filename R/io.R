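## Table schemas, TSV and JSONL round-trips, and input validation.
## TSV (not CSV) throughout: stimulus sentences contain commas. UTF-8, with
## BOM and CRLF tolerated on input.

table_schemas <- list(
  associates = list(cols = c("participant_id", "word", "slot", "response"),
                    ints = "slot"),
  assignments = list(cols = c("rater_id", "participant_id", "word", "slot",
                              "label"),
                     ints = c("slot", "label")),
  ratings = list(cols = c("participant_id", "item", "rating"),
                 ints = "rating"),
  items = list(cols = c("item", "condition"), ints = character(0))
)

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(txt) > 0) {
    txt[1] <- sub("^\ufeff", "", txt[1]) # strip UTF-8 BOM
  }
  txt <- sub("\r$", "", txt) # tolerate CRLF line endings
  read.delim(text = paste(txt, collapse = "\n"),
             stringsAsFactors = FALSE, colClasses = "character")
}

#' Read and validate a norming table
#'
#' Reads one of the documented TSV layouts, coercing and validating each
#' row. Malformed rows (uncoercible integers, ratings outside 1-7,
#' response slots other than 1/2, empty identifiers) are collected into a
#' rejection report with row numbers; the read aborts when more than
#' `max_malformed` of rows are rejected.
#'
#' @param path TSV file path (UTF-8; BOM and CRLF tolerated).
#' @param schema One of `"associates"`, `"assignments"`, `"ratings"`,
#'   `"items"`.
#' @param max_malformed Maximum tolerated fraction of malformed rows
#'   (default 0.05).
#' @return A tibble of valid rows with attribute `rejected`: tibble
#'   `row`, `reason`.
#' @export
read_norming_table <- function(path, schema, max_malformed = 0.05) {
  sch <- table_schemas[[schema]]
  if (is.null(sch)) stop("unknown schema: ", schema)
  raw <- read_tsv_raw(path)
  missing_cols <- setdiff(sch$cols, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: header lacks column(s) %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[, sch$cols, drop = FALSE]
  reasons <- rep(NA_character_, nrow(raw))
  for (col in sch$ints) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- is.na(v) & !is.na(raw[[col]])
    reasons[bad & is.na(reasons)] <- sprintf("%s not an integer", col)
    raw[[col]] <- v
  }
  if (schema == "ratings") {
    bad <- !is.na(raw$rating) & (raw$rating < 1 | raw$rating > 7)
    reasons[bad & is.na(reasons)] <- "rating outside 1-7"
  }
  if (schema == "associates") {
    bad <- !is.na(raw$slot) & !(raw$slot %in% c(1L, 2L))
    reasons[bad & is.na(reasons)] <- "slot must be 1 or 2"
  }
  id_cols <- setdiff(sch$cols, sch$ints)
  for (col in id_cols) {
    bad <- is.na(raw[[col]]) | !nzchar(raw[[col]])
    reasons[bad & is.na(reasons)] <- sprintf("empty %s", col)
  }
  rejected <- tibble::tibble(row = which(!is.na(reasons)),
                             reason = reasons[!is.na(reasons)])
  if (nrow(raw) > 0 && nrow(rejected) / nrow(raw) > max_malformed) {
    stop(sprintf("%s: %d of %d rows malformed (> %.0f%% tolerated)",
                 path, nrow(rejected), nrow(raw), 100 * max_malformed))
  }
  out <- tibble::as_tibble(raw[is.na(reasons), , drop = FALSE])
  attr(out, "rejected") <- rejected
  out
}

#' Write a table as TSV
#'
#' UTF-8, tab-separated, no quoting, no row names: the layout
#' [read_norming_table()] reads back.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write and read zeugma items as JSONL
#'
#' One JSON object per line with fields `item`, `sentence`, `target_span`,
#' `anaphor_span` (0-based half-open `[start, end)` pairs),
#' `anaphor_text`, `condition`, and `true_similarity` when present.
#'
#' @param items Zeugma item tibble ([generate_zeugma_items()] layout).
#' @param path File path.
#' @return `path` invisibly (write); the item tibble (read).
#' @export
write_zeugma_jsonl <- function(items, path) {
  lines <- vapply(seq_len(nrow(items)), function(i) {
    it <- items[i, ]
    obj <- list(item = it$item, sentence = it$sentence,
                target_span = c(it$target_start, it$target_end),
                anaphor_span = c(it$anaphor_start, it$anaphor_end),
                anaphor_text = it$anaphor_text,
                condition = it$condition)
    if ("true_similarity" %in% names(items)) {
      obj$true_similarity <- it$true_similarity
    }
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_zeugma_jsonl
#' @export
read_zeugma_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    tibble::tibble(item = o$item, sentence = o$sentence,
                   target_start = as.integer(o$target_span[1]),
                   target_end = as.integer(o$target_span[2]),
                   anaphor_start = as.integer(o$anaphor_span[1]),
                   anaphor_end = as.integer(o$anaphor_span[2]),
                   anaphor_text = o$anaphor_text,
                   condition = o$condition,
                   true_similarity = o$true_similarity %||% NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  bad <- substr(out$sentence, out$anaphor_start + 1, out$anaphor_end) !=
    out$anaphor_text
  if (any(bad)) {
    stop("anaphor span does not match anaphor text for item(s): ",
         paste(out$item[bad], collapse = ", "))
  }
  out
}
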