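SEQ_END <- "END"

#' Construct a question sequence
#'
#' A question sequence is a directed acyclic graph of annotation questions:
#' each answer to a question selects the next question (or `END`), so
#' follow-up questions depend on previous answers — e.g. a relevance
#' question routes irrelevant posts straight to `END`, skipping the
#' sentiment question. Answers may carry a class-label tag; a user's class
#' vote is the tag of the last tagged answer on their path.
#'
#' @param questions Named list: `question_id -> list(text, answers)` where
#'   `answers` is a named list `answer_id -> list(text = ..., label = <tag
#'   or NULL>, next = <question_id or "END">)`.
#' @param start The first question id.
#' @return A list of class `"question_sequence"`.
#' @seealso [read_question_sequence()] for the on-disk YAML form,
#'   [validate_sequence()].
#' @export
question_sequence <- function(questions, start) {
  seq <- structure(list(questions = questions, start = start),
                   class = "question_sequence")
  bad <- validate_sequence(seq)
  assert_that(length(bad) == 0,
              paste0("invalid question sequence: ", paste(bad, collapse = "; ")))
  seq
}

#' Validate a question sequence
#'
#' Reports (as data, not errors) cycles, answers without a transition,
#' transitions to unknown questions, questions unreachable from the start,
#' and an unreachable `END`.
#'
#' @param seq A question-sequence structure (possibly invalid).
#' @return Character vector of violations; empty means valid.
#' @export
validate_sequence <- function(seq) {
  v <- character(0)
  qs <- seq$questions
  if (is.null(qs[[seq$start]])) {
    return(paste0("start question '", seq$start, "' not defined"))
  }
  adj <- list()
  for (qid in names(qs)) {
    ans <- qs[[qid]]$answers
    if (!length(ans)) v <- c(v, paste0("question '", qid, "' has no answers"))
    for (aid in names(ans)) {
      nxt <- ans[[aid]][["next"]]
      if (is.null(nxt)) {
        v <- c(v, paste0("missing transition for (", qid, ", ", aid, ")"))
      } else if (nxt != SEQ_END && is.null(qs[[nxt]])) {
        v <- c(v, paste0("transition (", qid, ", ", aid,
                         ") targets unknown question '", nxt, "'"))
      } else if (nxt != SEQ_END) {
        adj[[qid]] <- c(adj[[qid]], nxt)
      }
    }
  }
  # cycle detection: iterative DFS with colors
  color <- stats::setNames(rep(0L, length(qs)), names(qs))  # 0 new 1 open 2 done
  has_cycle <- FALSE
  visit <- function(u) {
    stack <- list(list(node = u, i = 1L))
    color[[u]] <<- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      nbrs <- unique(adj[[top$node]])
      if (top$i <= length(nbrs)) {
        w <- nbrs[top$i]
        stack[[length(stack)]]$i <- top$i + 1L
        if (color[[w]] == 1L) has_cycle <<- TRUE
        else if (color[[w]] == 0L) {
          color[[w]] <<- 1L
          stack[[length(stack) + 1L]] <- list(node = w, i = 1L)
        }
      } else {
        color[[top$node]] <<- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  for (qid in names(qs)) if (color[[qid]] == 0L) visit(qid)
  if (has_cycle) v <- c(v, "cycle detected among question transitions")
  # reachability from start
  reach <- character(0)
  frontier <- seq$start
  while (length(frontier)) {
    reach <- union(reach, frontier)
    frontier <- setdiff(unique(unlist(adj[frontier])), reach)
  }
  unreach <- setdiff(names(qs), reach)
  if (length(unreach)) {
    v <- c(v, paste0("unreachable question(s): ", paste(unreach, collapse = ", ")))
  }
  end_ok <- any(vapply(reach, function(qid) {
    any(vapply(qs[[qid]]$answers, function(a)
      identical(a[["next"]], SEQ_END), NA))
  }, NA))
  if (!isTRUE(end_ok)) v <- c(v, "END not reachable from start")
  v
}

#' Transition to the next question
#'
#' @param seq A [question_sequence()].
#' @param current Current question id.
#' @param answer Answer id given; the pair must have a transition.
#' @return The next question id, or `"END"`.
#' @export
next_question <- function(seq, current, answer) {
  q <- seq$questions[[current]]
  assert_that(!is.null(q), paste0("unknown question: ", current))
  a <- q$answers[[answer]]
  assert_that(!is.null(a),
              paste0("unknown answer '", answer, "' for question '", current, "'"))
  a[["next"]]
}

#' Run one user through a question sequence
#'
#' Every answered question yields one annotation row (user, post, question,
#' answer). If `answer_fn` returns an answer the current question does not
#' have, the run is aborted: `completed` is `FALSE` and no annotations are
#' emitted — only successfully finished sequences count, so the caller
#' invokes [record_done()] only on completion.
#'
#' @param seq A [question_sequence()].
#' @param p The post being labeled.
#' @param answer_fn Function `question_id -> answer_id`.
#' @param user_id Annotator id.
#' @param timestamp Annotation time, epoch seconds.
#' @return `list(run = list(user_id, post_id, path, completed),
#'   annotations = data.frame)`.
#' @export
run_sequence <- function(seq, p, answer_fn, user_id,
                         timestamp = p$timestamp) {
  qid <- seq$start
  path <- list()
  rows <- list()
  for (step in seq_len(length(seq$questions))) {
    ans <- answer_fn(qid)
    if (is.null(ans) || is.null(seq$questions[[qid]]$answers[[ans]])) {
      return(list(
        run = list(user_id = user_id, post_id = p$post_id,
                   path = path, completed = FALSE),
        annotations = empty_annotations()))
    }
    path[[length(path) + 1L]] <- c(question_id = qid, answer_id = ans)
    rows[[length(rows) + 1L]] <- data.frame(
      user_id = user_id, post_id = p$post_id, question_id = qid,
      answer_id = ans, timestamp = timestamp, stringsAsFactors = FALSE)
    qid <- next_question(seq, qid, ans)
    if (qid == SEQ_END) {
      return(list(
        run = list(user_id = user_id, post_id = p$post_id,
                   path = path, completed = TRUE),
        annotations = do.call(rbind, rows)))
    }
  }
  stop("sequence did not reach END within the number of questions ",
       "(cycle?)", call. = FALSE)
}

empty_annotations <- function() {
  data.frame(user_id = character(0), post_id = character(0),
             question_id = character(0), answer_id = character(0),
             timestamp = numeric(0), stringsAsFactors = FALSE)
}

#' Answer function for a simulated annotator
#'
#' Routes a simulated annotator through a sequence: at the first question
#' offering answers tagged with the annotator's classes, the annotator's
#' perceived class is drawn (via [annotate_simulated()]) and the matching
#' answer chosen; questions without such tags take the first untagged
#' answer (e.g. "relevant" on a relevance question).
#'
#' @param annotator A [simulated_annotator()].
#' @param seq A [question_sequence()].
#' @param true_class The post's latent class.
#' @return Function `question_id -> answer_id` for [run_sequence()].
#' @export
simulated_answer_fn <- function(annotator, seq, true_class) {
  env <- new.env(parent = emptyenv())
  env$perceived <- NULL
  function(qid) {
    answers <- seq$questions[[qid]]$answers
    tags <- vapply(answers, function(a) a$label %||% NA_character_, "")
    if (any(tags %in% annotator$classes)) {
      if (is.null(env$perceived)) {
        env$perceived <- annotate_simulated(annotator, true_class)
      }
      hit <- which(tags == env$perceived)
      if (length(hit)) return(names(answers)[hit[1]])
    }
    untagged <- which(is.na(tags))
    if (length(untagged)) return(names(answers)[untagged[1]])
    names(answers)[1]
  }
}

user_vote <- function(rows, seq) {
  tag <- "irrelevant"
  for (i in seq_len(nrow(rows))) {
    a <- seq$questions[[rows$question_id[i]]]$answers[[rows$answer_id[i]]]
    if (!is.null(a$label)) tag <- a$label
  }
  tag
}

#' Aggregate one post's annotations into a consensus label
#'
#' Each contributing user must have completed the sequence; a user's vote
#' is the class tag of the last tagged answer on their path (users routed
#' to `END` before any tagged answer vote "irrelevant"). The consensus
#' label is the strict-majority class (> half the users); without a strict
#' majority the label is the tie policy's, by default "unresolved", which
#' is excluded from classifier training.
#'
#' @param annotations data.frame of annotation rows for one post, completed
#'   users only.
#' @param seq The [question_sequence()] that produced them.
#' @param n_consensus Required number of distinct users.
#' @param tie_policy Only `"unresolved"` is supported.
#' @param text The post text (carried into the training example).
#' @return A [labeled_example()].
#' @export
consensus_label <- function(annotations, seq, n_consensus = 3,
                            tie_policy = "unresolved", text = "") {
  tie_policy <- match.arg(tie_policy, "unresolved")
  pid <- unique(annotations$post_id)
  assert_that(length(pid) == 1, "annotations must concern exactly one post")
  users <- unique(annotations$user_id)
  if (length(users) < n_consensus) {
    stop("consensus not reached for post ", pid, ": ", length(users),
         " of ", n_consensus, " required annotators", call. = FALSE)
  }
  votes <- vapply(users, function(u) {
    user_vote(annotations[annotations$user_id == u, , drop = FALSE], seq)
  }, "")
  tab <- table(votes)
  top <- max(tab)
  n <- length(users)
  if (top > n / 2) {
    label <- names(tab)[which.max(tab)]
    agreement <- top / n
  } else {
    label <- "unresolved"
    agreement <- top / n
  }
  labeled_example(pid, text, label, n, agreement)
}

#' Read a question sequence from a YAML file
#'
#' Schema: top-level `start` and a `questions` list; each question has
#' `id`, `text` and an `answers` list of `{id, text, label (optional class
#' tag), next (question id or END)}`. Validated at load.
#'
#' @param path YAML file path.
#' @return A [question_sequence()].
#' @export
read_question_sequence <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  y <- yaml::read_yaml(path)
  assert_that(!is.null(y$start) && length(y$questions) > 0,
              "sequence file must define 'start' and 'questions'")
  qs <- list()
  for (q in y$questions) {
    answers <- list()
    for (a in q$answers) {
      answers[[a$id]] <- list(text = a$text %||% a$id,
                              label = a$label,
                              "next" = a[["next"]])
    }
    qs[[q$id]] <- list(text = q$text %||% q$id, answers = answers)
  }
  question_sequence(qs, y$start)
}

#' The default two-step relevance/sentiment sequence
#'
#' Question 1 asks whether the post is relevant: the "irrelevant" answer is
#' tagged and goes straight to `END`; the "relevant" answer leads to the
#' sentiment question, whose answers are tagged with the three sentiment
#' classes.
#'
#' @param classes Sentiment classes (default [default_classes()]).
#' @return A [question_sequence()].
#' @export
default_question_sequence <- function(classes = default_classes()) {
  sent_answers <- stats::setNames(lapply(classes, function(cl) {
    list(text = cl, label = cl, "next" = SEQ_END)
  }), paste0("a2_", seq_along(classes)))
  question_sequence(
    questions = list(
      Q1 = list(
        text = "Is this post relevant to vaccinations?",
        answers = list(
          a1_1 = list(text = "relevant", label = NULL, "next" = "Q2"),
          a1_2 = list(text = "irrelevant", label = "irrelevant",
                      "next" = SEQ_END))),
      Q2 = list(
        text = "What sentiment toward vaccinations does this post express?",
        answers = sent_answers)),
    start = "Q1")
}
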