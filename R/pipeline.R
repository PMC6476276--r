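#' Tokenize post text
#'
#' Lowercases, replaces URLs by the token `<url>` and @-mentions by
#' `<user>`, then splits on any run of characters that are neither letters
#' nor digits, dropping empty tokens.
#'
#' @param text A single string.
#' @return Character vector of tokens (possibly empty).
#' @export
preprocess <- function(text) {
  assert_that(is.character(text) && length(text) == 1, "text must be one string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  s <- tolower(text)
  m <- gregexpr("https?://\\S+|www\\.\\S+|@\\w+|[\\p{L}\\p{N}]+", s,
                perl = TRUE)[[1]]
  if (m[1] == -1) return(character(0))
  toks <- regmatches(s, list(m))[[1]]
  toks[grepl("^(https?://|www\\.)", toks)] <- "<url>"
  toks[startsWith(toks, "@")] <- "<user>"
  toks
}

#' Construct a keyword filter
#'
#' @param keywords Non-empty character vector; keywords must not contain
#'   whitespace. Matching is case-insensitive.
#' @param match_fields Post fields to match against (default `"text"`).
#' @param substring_match If `TRUE`, a keyword matches anywhere inside the
#'   lowercased text; by default a keyword must exactly equal a token
#'   (so "vaccines" does not match keyword "vaccine").
#' @return A list of class `"keyword_filter"`.
#' @export
keyword_filter <- function(keywords, match_fields = "text",
                           substring_match = FALSE) {
  keywords <- tolower(trimws(keywords))
  keywords <- keywords[nzchar(keywords)]
  assert_that(length(keywords) > 0, "keywords must be non-empty")
  assert_that(!any(grepl("\\s", keywords)),
              "keywords must not contain whitespace")
  structure(list(keywords = keywords, match_fields = match_fields,
                 substring_match = isTRUE(substring_match)),
            class = "keyword_filter")
}

#' Read a keyword list from a plain-text file
#'
#' One keyword per line; `#` starts a comment; blank lines are ignored.
#'
#' @param path File path.
#' @param ... Passed to [keyword_filter()].
#' @return A [keyword_filter()].
#' @export
read_keywords <- function(path, ...) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  keyword_filter(lines[nzchar(lines)], ...)
}

#' Test whether a text matches a keyword filter
#'
#' True iff at least one keyword equals (case-insensitively) at least one
#' token of the tokenized text; with `substring_match` enabled, substring
#' semantics on the lowercased raw text.
#'
#' @param text A single string (empty text never matches).
#' @param filter A [keyword_filter()].
#' @return Logical scalar.
#' @export
keyword_match <- function(text, filter) {
  assert_that(inherits(filter, "keyword_filter"), "filter must be a keyword_filter")
  if (is.na(text) || !nzchar(text)) return(FALSE)
  if (filter$substring_match) {
    s <- tolower(text)
    return(any(vapply(filter$keywords, grepl, NA, x = s, fixed = TRUE)))
  }
  any(filter$keywords %in% preprocess(text))
}

#' Configure the processing pipeline
#'
#' @param filter A [keyword_filter()].
#' @param classes Label set the classifier is trained on.
#' @param queue_config A [queue_config()] used to compute the priority
#'   attached to queue-eligible posts.
#' @param uncertainty_method Passed to [uncertainty()].
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(filter, classes = default_classes(),
                            queue_config = sentistream::queue_config(),
                            uncertainty_method = "least_confidence") {
  assert_that(inherits(filter, "keyword_filter"), "filter must be a keyword_filter")
  structure(list(filter = filter, classes = classes,
                 queue_config = queue_config,
                 uncertainty_method = uncertainty_method),
            class = "pipeline_config")
}

#' Process one incoming post
#'
#' Applies the keyword filter; non-matching posts are returned unchanged
#' with a `FALSE` queue-eligible flag (they stay in the raw store but are
#' never queued). Matching posts get prediction metadata attached:
#' `class_probs`, `predicted_class`, and a labeling `priority` computed
#' from the model's uncertainty and the post's age at `now`. Text and
#' timestamp are never mutated, and reprocessing yields identical metadata
#' given the same model and evaluation time.
#'
#' @param p A post.
#' @param model A trained [train_bow()] model over `config$classes`.
#' @param config A [pipeline_config()].
#' @param now Evaluation time, epoch seconds (default: the post timestamp).
#' @return `list(post = <post>, eligible = <logical>)`.
#' @export
process_post <- function(p, model, config, now = p$timestamp) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  assert_that(identical(model$classes, config$classes),
              "model class set does not match pipeline configuration")
  fields <- config$filter$match_fields
  hit <- any(vapply(fields, function(f) {
    v <- if (f == "text") p$text else p$extra[[f]]
    !is.null(v) && keyword_match(v, config$filter)
  }, NA))
  if (!hit) return(list(post = p, eligible = FALSE))
  probs <- predict_proba(model, p$text)
  p$class_probs <- probs
  p$predicted_class <- names(probs)[which.max(probs)]
  u <- uncertainty(probs, config$uncertainty_method)
  age <- now - p$timestamp
  p$priority <- priority_score(u, max(age, 0), config$queue_config)
  list(post = p, eligible = TRUE)
}
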