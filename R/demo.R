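#' Stream configuration for the end-to-end demo
#'
#' A 60-day stream at 50 posts/day with a mid-stream changepoint raising
#' the positive share among polar (positive/negative) posts from 0.5 to
#' 0.7 while the neutral share stays at one third — the kind of abrupt
#' sentiment shift the trend index is meant to surface.
#'
#' @param seed Stream seed.
#' @return A [stream_config()].
#' @export
demo_stream_config <- function(seed = 42) {
  cfg <- al_fixture_config(seed = seed, n_posts = 3000, duration_days = 60)
  inject_changepoint(cfg, time_days = 30,
                     new_weights = c(positive = 0.7 * 2 / 3,
                                     negative = 0.3 * 2 / 3,
                                     neutral = 1 / 3))
}

#' Run the full pipeline end to end on synthetic data
#'
#' Generates a stream with a mid-stream sentiment shift, runs the active
#' learning loop (budget 300 consensus labels from five simulated
#' annotators), filters and annotates the whole stream with the final
#' model, and computes the trend report. All artifacts are plain text and
#' byte-identical across reruns with the same seed.
#'
#' Artifacts written to `out_dir`: `stream.jsonl`, `al_history.csv`,
#' `processed.jsonl`, `trends.csv`, `model/` and `report.json`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for the run.
#' @param budget Consensus-label budget for the learning loop.
#' @return The report, invisibly (a named list).
#' @export
run_demo <- function(out_dir, seed = 42, budget = 300) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- demo_stream_config(seed)
  posts <- generate_stream(scfg)
  write_posts(posts, file.path(out_dir, "stream.jsonl"))

  annotators <- lapply(1:5, function(k) {
    simulated_annotator(paste0("u", k), accuracy = 0.9,
                        seed = seed * 1000L + k)
  })
  al <- active_learning_loop(
    posts, annotators,
    al_config(strategy = "uncertainty", budget = budget,
              rng_seed = seed * 7L + 13L))
  utils::write.csv(al$history, file.path(out_dir, "al_history.csv"),
                   row.names = FALSE)
  save_model(al$model, file.path(out_dir, "model"))

  pcfg <- pipeline_config(keyword_filter(scfg$keyword_tokens))
  processed <- list()
  for (p in posts) {
    res <- process_post(p, al$model, pcfg)
    if (res$eligible) processed[[length(processed) + 1L]] <- res$post
  }
  write_posts(processed, file.path(out_dir, "processed.jsonl"))

  tcfg <- trend_config(source = "predicted")
  series <- trend_report(processed, tcfg,
                         csv_path = file.path(out_dir, "trends.csv"))

  cp_time <- scfg$start_time + 30 * 86400
  def <- !is.na(series$index)
  report <- list(
    seed = seed,
    n_posts = length(posts),
    n_processed = length(processed),
    labels_used = max(al$history$labels_used),
    final_accuracy = al$history$accuracy[nrow(al$history)],
    initial_accuracy = al$history$accuracy[1],
    model_version = al$model$version,
    mean_index_before = mean(series$index[def & series$bins < cp_time]),
    mean_index_after = mean(series$index[def & series$bins >= cp_time]))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
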