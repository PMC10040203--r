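#' Configuration of a full simulated norming-and-analysis run
#'
#' @param seed Master seed; every stage derives its own substream from it.
#' @param n_words,n_participants_assoc Size of the simulated
#'   free-association dominance study.
#' @param items_per_condition,n_participants_rating,n_flat_raters Size of
#'   the simulated similarity-rating study.
#' @param multiword_fraction Fraction of zeugma items given a multiword
#'   anaphor.
#' @param dominance_cutoff Balance cutoff on the dominance score.
#' @param flat_threshold,completeness Participant-exclusion parameters.
#' @param n_layers,dim Toy-encoder geometry.
#' @param log_base Logarithm base for surprisal.
#' @param alpha Significance level for reported flags.
#' @return A `run_config` list (with its hash under `$hash`).
#' @export
run_config <- function(seed = 1L,
                       n_words = 40L,
                       n_participants_assoc = 30L,
                       items_per_condition = 20L,
                       n_participants_rating = 30L,
                       n_flat_raters = 0L,
                       multiword_fraction = 0.02,
                       dominance_cutoff = 0.75,
                       flat_threshold = 0.5,
                       completeness = 0.8,
                       n_layers = 12L,
                       dim = 64L,
                       log_base = exp(1),
                       alpha = 0.01) {
  cfg <- list(seed = as.integer(seed),
              n_words = check_count(n_words, "n_words"),
              n_participants_assoc = check_count(n_participants_assoc,
                                                 "n_participants_assoc"),
              items_per_condition = check_count(items_per_condition,
                                                "items_per_condition"),
              n_participants_rating = check_count(n_participants_rating,
                                                  "n_participants_rating"),
              n_flat_raters = check_count(n_flat_raters, "n_flat_raters",
                                          min = 0L),
              multiword_fraction = check_rate(multiword_fraction,
                                              "multiword_fraction"),
              dominance_cutoff = check_rate(dominance_cutoff,
                                            "dominance_cutoff"),
              flat_threshold = flat_threshold,
              completeness = check_rate(completeness, "completeness"),
              n_layers = check_count(n_layers, "n_layers"),
              dim = check_count(dim, "dim", min = 2L),
              log_base = log_base,
              alpha = check_rate(alpha, "alpha"))
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full simulated pipeline
#'
#' simulate -> dominance -> similarity -> encoder metrics -> model
#' comparisons, writing every table, report, and a manifest (config hash,
#' seed, package version) into one output directory. Deterministic given
#' the config: re-running with the same config and directory reproduces
#' every artifact byte for byte. If a stage fails, earlier outputs are
#' kept and a `failure.json` manifest records the stage and message.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory; default a new directory named by the
#'   config hash under `tempdir()`.
#' @return List with `dir` and the in-memory stage results; on partial
#'   failure, list with `dir`, `failed_stage`, `error`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% file.path(tempdir(),
                                    paste0("ambinorm-run-", config$hash))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "ambinorm",
                   version = as.character(packageVersion("ambinorm")),
                   seed = config$seed,
                   config_hash = config$hash,
                   config = unclass(config))
  results <- list()
  stage <- "simulate"
  tryCatch({
    assoc <- simulate_associate_study(associate_study_config(
      n_words = config$n_words,
      n_participants = config$n_participants_assoc,
      seed = config$seed))
    zeugma <- generate_zeugma_items(config$items_per_condition,
                                    multiword_fraction = config$multiword_fraction,
                                    seed = config$seed)
    rating <- simulate_rating_study(
      rating_study_config(items_per_condition = config$items_per_condition,
                          n_participants = config$n_participants_rating,
                          n_flat_raters = config$n_flat_raters,
                          seed = config$seed),
      items = zeugma)
    write_tsv(assoc$associates, file.path(out_dir, "associates.tsv"))
    write_tsv(assoc$assignments, file.path(out_dir, "assignments.tsv"))
    write_tsv(rating$ratings, file.path(out_dir, "ratings.tsv"))
    write_tsv(rating$items, file.path(out_dir, "items.tsv"))
    write_zeugma_jsonl(zeugma, file.path(out_dir, "zeugma.jsonl"))

    stage <- "dominance"
    n_senses <- table(assoc$sense_probs$word)
    n_senses <- setNames(as.integer(n_senses), names(n_senses))
    dom <- dominance_table(assoc$assignments, n_senses,
                           cutoff = config$dominance_cutoff)
    irr <- interrater_reliability(assoc$assignments)
    consist <- response_meaning_consistency(
      resolve_consensus_labels(assoc$assignments))
    write_tsv(dom, file.path(out_dir, "dominance.tsv"))
    write_json(list(interrater = irr, response_consistency = consist,
                    skipped_words = attr(dom, "skipped")),
               file.path(out_dir, "dominance_summary.json"))

    stage <- "similarity"
    excl <- exclude_participants(rating$ratings, rating$items,
                                 flat_threshold = config$flat_threshold,
                                 completeness = config$completeness)
    kept_ratings <- rating$ratings[
      rating$ratings$participant_id %in% excl$kept, ]
    stats <- item_statistics(kept_ratings, rating$items)
    cond <- condition_statistics(stats, alpha = config$alpha)
    agreement <- loo_agreement(kept_ratings)
    write_tsv(stats, file.path(out_dir, "item_stats.tsv"))
    write_tsv(excl$excluded, file.path(out_dir, "excluded_participants.tsv"))
    write_json(list(conditions = cond$conditions, tests = cond$tests,
                    agreement = agreement$summary),
               file.path(out_dir, "similarity_summary.json"))

    stage <- "nlm"
    retained <- filter_multiword_anaphors(zeugma)
    encoder <- make_toy_encoder(retained, n_layers = config$n_layers,
                                dim = config$dim, seed = config$seed)
    metrics <- item_metrics(encoder, retained, base = config$log_base)
    corr <- layer_correlations(metrics$cosine, stats)
    write_tsv(metrics$cosine, file.path(out_dir, "metrics_cosine.tsv"))
    write_tsv(metrics$surprisal, file.path(out_dir, "metrics_surprisal.tsv"))
    write_tsv(corr$by_layer, file.path(out_dir, "layer_correlations.tsv"))
    write_json(c(metrics$meta,
                 list(n_multiword_removed = attr(retained, "n_removed"),
                      strongest_layer = corr$strongest_layer)),
               file.path(out_dir, "nlm_manifest.json"))

    stage <- "compare"
    analysis <- assemble_analysis_table(stats, metrics, retained)
    comparisons <- run_model_comparisons(analysis)
    write_tsv(analysis, file.path(out_dir, "analysis_table.tsv"))
    write_json(comparisons, file.path(out_dir, "comparisons.json"))

    write_json(manifest, file.path(out_dir, "manifest.json"))
    results <- list(dir = out_dir, dominance = dom, interrater = irr,
                    exclusions = excl, item_stats = stats,
                    condition_stats = cond, agreement = agreement,
                    metrics = metrics, layer_correlations = corr,
                    comparisons = comparisons)
    results
  }, error = function(e) {
    write_json(c(manifest, list(failed_stage = stage,
                                error = conditionMessage(e))),
               file.path(out_dir, "failure.json"))
    list(dir = out_dir, failed_stage = stage, error = conditionMessage(e))
  })
}
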