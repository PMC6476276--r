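#' Construct a post record
#'
#' A post is a timestamped short text with optional latent true class
#' (synthetic data only) and optional prediction metadata attached by the
#' processing pipeline. Unknown fields read from disk are carried through
#' untouched in `extra`.
#'
#' @param post_id Unique string id.
#' @param timestamp UTC epoch seconds (integer-valued).
#' @param text Post text.
#' @param true_class,predicted_class Optional class labels.
#' @param class_probs Optional named probability vector over classes
#'   (non-negative, sums to 1 within 1e-9; `predicted_class` must be an
#'   argmax of it).
#' @param priority Optional priority score in \[0, 1\].
#' @param extra Named list of passthrough fields.
#' @return A list of class `"ss_post"`.
#' @export
post <- function(post_id, timestamp, text, true_class = NULL,
                 predicted_class = NULL, class_probs = NULL,
                 priority = NULL, extra = list()) {
  p <- structure(
    list(post_id = as.character(post_id),
         timestamp = as.numeric(timestamp),
         text = as.character(text),
         true_class = true_class, predicted_class = predicted_class,
         class_probs = class_probs, priority = priority, extra = extra),
    class = "ss_post")
  validate_post(p)
  p
}

validate_post <- function(p) {
  assert_that(is.character(p$post_id) && nzchar(p$post_id),
              "post_id must be a non-empty string")
  assert_that(is.numeric(p$timestamp) && length(p$timestamp) == 1 &&
                p$timestamp == floor(p$timestamp),
              paste0("timestamp must be integer epoch seconds (post ",
                     p$post_id, ")"))
  assert_that(is.character(p$text) && length(p$text) == 1,
              paste0("text must be a single string (post ", p$post_id, ")"))
  if (!is.null(p$class_probs)) {
    check_prob_vector(p$class_probs,
                      what = paste0("class_probs of post ", p$post_id))
    if (!is.null(p$predicted_class)) {
      mx <- names(p$class_probs)[p$class_probs >=
                                   max(p$class_probs) - 1e-12]
      assert_that(p$predicted_class %in% mx,
                  paste0("predicted_class is not an argmax of class_probs (post ",
                         p$post_id, ")"))
    }
  }
  if (!is.null(p$priority)) {
    assert_that(p$priority >= 0 && p$priority <= 1,
                paste0("priority out of [0,1] (post ", p$post_id, ")"))
  }
  invisible(TRUE)
}

ss_known_fields <- c("post_id", "timestamp", "text", "true_class",
                     "predicted_class", "class_probs", "priority")

#' Read a stream of posts from a JSONL file
#'
#' One JSON object per line with at least `post_id`, `timestamp`, `text`.
#' Unknown fields are preserved in the post's `extra` passthrough map.
#' Posts are returned in file order.
#'
#' @param path Path to a JSONL file (UTF-8, one object per line).
#' @return List of posts (see [post()]).
#' @export
read_posts <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  seen <- new.env(parent = emptyenv())
  posts <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e)
                      stop("malformed JSON on line ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    for (f in c("post_id", "timestamp", "text")) {
      if (is.null(obj[[f]])) {
        stop("line ", i, ": missing required field '", f, "'", call. = FALSE)
      }
    }
    if (exists(obj$post_id, envir = seen, inherits = FALSE)) {
      stop("duplicate post_id '", obj$post_id, "' on line ", i, call. = FALSE)
    }
    assign(obj$post_id, TRUE, envir = seen)
    probs <- obj$class_probs
    if (!is.null(probs)) probs <- unlist(probs)
    extra <- obj[setdiff(names(obj), ss_known_fields)]
    posts[[i]] <- post(obj$post_id, obj$timestamp, obj$text,
                       true_class = obj$true_class,
                       predicted_class = obj$predicted_class,
                       class_probs = probs, priority = obj$priority,
                       extra = extra)
  }
  posts
}

post_to_json <- function(p) {
  obj <- list(post_id = p$post_id, timestamp = p$timestamp, text = p$text)
  for (f in c("true_class", "predicted_class", "class_probs", "priority")) {
    if (!is.null(p[[f]])) obj[[f]] <- p[[f]]
  }
  if (!is.null(obj$class_probs)) {
    obj$class_probs <- as.list(obj$class_probs)  # keep class names in JSON
  }
  if (length(p$extra)) obj <- c(obj, p$extra[order(names(p$extra))])
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Write posts to a JSONL file
#'
#' One JSON object per line, keys in canonical order (known fields first,
#' passthrough fields alphabetically); output is deterministic, so
#' `write_posts(read_posts(f))` is byte-identical to `f` for canonically
#' formatted files.
#'
#' @param posts List of posts.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path) {
  lapply(posts, validate_post)
  ids <- vapply(posts, `[[`, "", "post_id")
  dup <- ids[duplicated(ids)]
  assert_that(length(dup) == 0,
              paste0("duplicate post_id: ", paste(unique(dup), collapse = ", ")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (p in posts) {
    writeLines(post_to_json(p), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

annotation_fields <- c("user_id", "post_id", "question_id", "answer_id",
                       "timestamp")

check_annotation_dups <- function(df) {
  key <- paste(df$user_id, df$post_id, df$question_id, sep = "\r")
  d <- which(duplicated(key))
  if (length(d)) {
    stop("duplicate annotation for (user_id=", df$user_id[d[1]],
         ", post_id=", df$post_id[d[1]],
         ", question_id=", df$question_id[d[1]], ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read annotations from CSV or JSONL
#'
#' An annotation is one (user, post, question, answer) row, the atomic
#' labeling event. The triple (user_id, post_id, question_id) must be unique.
#'
#' @param path CSV file with header
#'   `user_id,post_id,question_id,answer_id,timestamp`, or JSONL with the
#'   same fields.
#' @return data.frame of annotations, in file order.
#' @export
read_annotations <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(trimws(first), "{")) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    rows <- lapply(lines, function(l) {
      as.data.frame(jsonlite::fromJSON(l)[annotation_fields])
    })
    df <- do.call(rbind, rows) %||%
      stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 5)),
                      annotation_fields)
  } else {
    df <- utils::read.csv(path, colClasses = c(
      user_id = "character", post_id = "character",
      question_id = "character", answer_id = "character",
      timestamp = "numeric"))
  }
  missing <- setdiff(annotation_fields, names(df))
  assert_that(length(missing) == 0,
              paste0("annotation file missing fields: ",
                     paste(missing, collapse = ", ")))
  df <- df[annotation_fields]
  check_annotation_dups(df)
  df
}

#' Write annotations to CSV
#'
#' @param annotations data.frame with the five annotation fields.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  missing <- setdiff(annotation_fields, names(annotations))
  assert_that(length(missing) == 0,
              paste0("annotations missing fields: ",
                     paste(missing, collapse = ", ")))
  check_annotation_dups(annotations)
  utils::write.csv(annotations[annotation_fields], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Construct a consensus-labeled training example
#'
#' Materializes the consensus outcome for one post: the winning label, the
#' number of contributing annotators, and the agreement fraction
#' (winning votes / annotators). Agreement must exceed 0.5 unless the label
#' is "unresolved".
#'
#' @param post_id,text Post identity and text.
#' @param label Consensus class label.
#' @param n_annotators Number of contributing annotators.
#' @param agreement Winning-vote fraction in \[0, 1\].
#' @return A list of class `"labeled_example"`.
#' @export
labeled_example <- function(post_id, text, label, n_annotators, agreement) {
  assert_that(n_annotators >= 1, "n_annotators must be positive")
  assert_that(agreement >= 0 && agreement <= 1, "agreement out of [0,1]")
  if (label != "unresolved") {
    assert_that(agreement > 0.5,
                "agreement must exceed 0.5 for a resolved label")
  }
  structure(list(post_id = post_id, text = text, label = label,
                 n_annotators = n_annotators, agreement = agreement),
            class = "labeled_example")
}
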