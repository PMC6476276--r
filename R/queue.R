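#' Configure the labeling priority queue
#'
#' The queue keeps a bounded pool of recent posts prioritized for human
#' labeling. Priority blends label uncertainty against recency:
#' `lambda * U + (1 - lambda) * exp(-age / tau)`, housing the
#' exploration/exploitation trade-off between uncertain and timely posts.
#'
#' @param max_size Maximum queue size (default 100).
#' @param n_consensus Distinct annotators required before a post retires to
#'   the consensus stage (default 3).
#' @param lambda_uncertainty Blend weight in \[0, 1\] on uncertainty
#'   (default 0.5); 1 is pure uncertainty sampling.
#' @param tau_recency Recency decay time constant in seconds
#'   (default 86400, one day).
#' @return A list of class `"queue_config"`.
#' @export
queue_config <- function(max_size = 100, n_consensus = 3,
                         lambda_uncertainty = 0.5, tau_recency = 86400) {
  assert_that(max_size >= 1, "max_size must be positive")
  assert_that(n_consensus >= 1, "n_consensus must be positive")
  assert_that(lambda_uncertainty >= 0 && lambda_uncertainty <= 1,
              "lambda_uncertainty must be in [0,1]")
  assert_that(tau_recency > 0, "tau_recency must be positive")
  structure(list(max_size = as.integer(max_size),
                 n_consensus = as.integer(n_consensus),
                 lambda_uncertainty = lambda_uncertainty,
                 tau_recency = tau_recency),
            class = "queue_config")
}

#' Priority score of a queue item
#'
#' `lambda * uncertainty + (1 - lambda) * exp(-age / tau)`: monotone
#' increasing in uncertainty, decreasing in age, and always in \[0, 1\].
#'
#' @param uncertainty Label uncertainty in \[0, 1\].
#' @param age_seconds Non-negative age in seconds.
#' @param config A [queue_config()].
#' @return Score in \[0, 1\].
#' @export
priority_score <- function(uncertainty, age_seconds, config) {
  assert_that(all(uncertainty >= 0 & uncertainty <= 1),
              "uncertainty must be in [0,1]")
  assert_that(all(age_seconds >= 0), "age must be non-negative")
  lam <- config$lambda_uncertainty
  lam * uncertainty + (1 - lam) * exp(-age_seconds / config$tau_recency)
}

#' Create an empty queue state
#'
#' The queue contract is single-writer: operations take a state and return
#' the updated state. Retired post ids accumulate in `$completed`, the feed
#' of the consensus stage.
#'
#' @param config A [queue_config()].
#' @return A list of class `"queue_state"`.
#' @export
queue_state <- function(config = queue_config()) {
  structure(list(config = config, items = list(), completed = character(0)),
            class = "queue_state")
}

#' Create a queue item
#'
#' @param post_id Post id.
#' @param base_uncertainty Label uncertainty in \[0, 1\] at prediction time.
#' @param enqueued_at Epoch seconds.
#' @return A list of class `"queue_item"`.
#' @export
queue_item <- function(post_id, base_uncertainty, enqueued_at) {
  assert_that(base_uncertainty >= 0 && base_uncertainty <= 1,
              "base_uncertainty must be in [0,1]")
  structure(list(post_id = as.character(post_id),
                 base_uncertainty = base_uncertainty,
                 enqueued_at = as.numeric(enqueued_at),
                 users_done = character(0), retired = FALSE),
            class = "queue_item")
}

item_scores <- function(state, now) {
  if (!length(state$items)) return(numeric(0))
  u <- vapply(state$items, `[[`, 0, "base_uncertainty")
  at <- vapply(state$items, `[[`, 0, "enqueued_at")
  priority_score(u, pmax(now - at, 0), state$config)
}

#' Add an item to the bounded queue
#'
#' When the queue is full, the item with the lowest priority score —
#' recomputed at `now`, so recency decay is honored — is evicted to make
#' room; if the entrant itself scores lowest it is not added. Ties on the
#' eviction side go to the older item, then lexicographic post id.
#'
#' @param item A [queue_item()].
#' @param state A [queue_state()].
#' @param now Epoch seconds.
#' @return The updated state.
#' @export
enqueue <- function(item, state, now) {
  assert_that(inherits(item, "queue_item"), "item must be a queue_item")
  assert_that(!item$retired, "cannot enqueue a retired item")
  assert_that(is.null(state$items[[item$post_id]]),
              paste0("duplicate post_id in queue: ", item$post_id))
  if (length(state$items) >= state$config$max_size) {
    scores <- item_scores(state, now)
    entrant <- priority_score(item$base_uncertainty,
                              max(now - item$enqueued_at, 0), state$config)
    at <- vapply(state$items, `[[`, 0, "enqueued_at")
    ord <- order(scores, at, names(state$items))  # worst first: low score, then oldest
    worst <- ord[1]
    if (entrant <= scores[worst]) return(state)  # entrant is the lowest
    state$items[[worst]] <- NULL
  }
  state$items[[item$post_id]] <- item
  state
}

#' Next item for an annotator
#'
#' The highest-current-priority non-retired item the user has not yet
#' labeled; ties broken by newer `enqueued_at`, then lexicographic post id.
#' `NULL` when no eligible item exists — a user never sees the same post
#' twice.
#'
#' @param user_id Annotator id.
#' @param state A [queue_state()].
#' @param now Epoch seconds.
#' @return A [queue_item()] or `NULL`.
#' @export
next_for_user <- function(user_id, state, now) {
  if (!length(state$items)) return(NULL)
  elig <- !vapply(state$items, function(it) {
    it$retired || user_id %in% it$users_done
  }, NA)
  if (!any(elig)) return(NULL)
  scores <- item_scores(state, now)[elig]
  items <- state$items[elig]
  at <- vapply(items, `[[`, 0, "enqueued_at")
  ord <- order(-scores, -at, names(items))
  items[[ord[1]]]
}

#' Record a completed labeling of a post by a user
#'
#' Only called after the user successfully finishes the question sequence;
#' abandoned sequences leave no trace. When the item reaches `n_consensus`
#' distinct users it is retired, removed from the queue, and its post id is
#' emitted to `state$completed` for the consensus stage.
#'
#' @param user_id Annotator id.
#' @param post_id Post id; must be present in the queue.
#' @param state A [queue_state()].
#' @return The updated state.
#' @export
record_done <- function(user_id, post_id, state) {
  it <- state$items[[post_id]]
  assert_that(!is.null(it), paste0("unknown queue item: ", post_id))
  assert_that(!user_id %in% it$users_done,
              paste0("user ", user_id, " already labeled post ", post_id))
  it$users_done <- c(it$users_done, user_id)
  if (length(it$users_done) >= state$config$n_consensus) {
    it$retired <- TRUE
    state$items[[post_id]] <- NULL
    state$completed <- c(state$completed, post_id)
  } else {
    state$items[[post_id]] <- it
  }
  state
}
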