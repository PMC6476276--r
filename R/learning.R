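tokenize_with_bigrams <- function(text) {
  toks <- preprocess(text)
  if (length(toks) >= 2) {
    toks <- c(toks, paste(toks[-length(toks)], toks[-1], sep = "_"))
  }
  toks
}

# Sparse document-term count matrix over a fixed vocabulary.
# token_lists: list of character vectors (already tokenized).
dtm_from_tokens <- function(token_lists, vocab) {
  n <- length(token_lists)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (d in seq_len(n)) {
    idx <- vocab[token_lists[[d]]]
    idx <- idx[!is.na(idx)]
    if (!length(idx)) next
    tab <- table(idx)
    ii <- c(ii, rep.int(d, length(tab)))
    jj <- c(jj, as.integer(names(tab)))
    xx <- c(xx, as.numeric(tab))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, length(vocab)))
}

build_vocab <- function(token_lists, min_df = 2) {
  df <- table(unlist(lapply(token_lists, unique)))
  keep <- sort(names(df)[df >= min_df])
  stats::setNames(seq_along(keep), keep)
}

#' Train the baseline bag-of-words classifier
#'
#' Multinomial logistic regression with L2 (ridge) regularization on
#' unigram + bigram token counts, the fast-retraining baseline behind the
#' active learning loop. Examples labeled "unresolved" or "irrelevant" (or
#' anything outside `classes`) are excluded. Deterministic: the fit has no
#' random component.
#'
#' @param examples List of [labeled_example()]s (or a data.frame with
#'   `text` and `label` columns).
#' @param classes Ordered label set to train on.
#' @param lambda Ridge penalty (per-observation scale, as in glmnet).
#' @param min_df Minimum document frequency for a token to enter the
#'   vocabulary.
#' @param prev_version Version counter to increment (0 for a fresh model).
#' @return A list of class `"bow_model"` with the vocabulary, a
#'   features-by-classes weight matrix, per-class biases, and metadata.
#' @export
train_bow <- function(examples, classes = default_classes(), lambda = 0.01,
                      min_df = 2, prev_version = 0L) {
  if (is.data.frame(examples)) {
    texts <- examples$text; labels <- examples$label
  } else {
    texts <- vapply(examples, `[[`, "", "text")
    labels <- vapply(examples, `[[`, "", "label")
  }
  keep <- labels %in% classes
  texts <- texts[keep]; labels <- labels[keep]
  missing <- setdiff(classes, unique(labels))
  if (length(missing)) {
    stop("no training examples for class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  token_lists <- lapply(texts, tokenize_with_bigrams)
  vocab <- build_vocab(token_lists, min_df = min_df)
  assert_that(length(vocab) >= 2, "vocabulary too small to train on")
  x <- dtm_from_tokens(token_lists, vocab)
  y <- factor(labels, levels = classes)
  # short decreasing path down to the target lambda stabilizes convergence
  lam_path <- unique(c(lambda * c(100, 10, 2), lambda))
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                        lambda = lam_path, standardize = FALSE,
                        thresh = 1e-12, maxit = 1e6)
  cf <- stats::coef(fit, s = lambda)
  weights <- do.call(cbind, lapply(cf, function(m) as.numeric(m[-1, 1])))
  bias <- vapply(cf, function(m) m[1, 1], 0)
  colnames(weights) <- classes
  rownames(weights) <- names(vocab)
  names(bias) <- classes
  structure(list(vocabulary = vocab, weights = weights, bias = bias,
                 classes = classes, lambda = lambda, min_df = min_df,
                 trained_on = length(texts),
                 version = as.integer(prev_version) + 1L),
            class = "bow_model")
}

softmax_rows <- function(scores) {
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

#' Predict class probabilities for texts
#'
#' Softmax over linear scores on the model's unigram+bigram count features.
#' Out-of-vocabulary tokens are ignored; a text with no in-vocabulary
#' tokens (including empty text) gets the bias-only softmax, the model's
#' prior.
#'
#' @param model A [train_bow()] model.
#' @param texts Character vector, or a list of pre-tokenized texts (as
#'   produced internally; used by the loop to avoid re-tokenizing).
#' @return Matrix `length(texts)` x classes of probabilities, rows summing
#'   to 1.
#' @export
predict_proba_many <- function(model, texts) {
  token_lists <- if (is.list(texts)) texts else lapply(texts, tokenize_with_bigrams)
  x <- dtm_from_tokens(token_lists, model$vocabulary)
  scores <- as.matrix(x %*% model$weights)
  scores <- sweep(scores, 2, model$bias, `+`)
  p <- softmax_rows(scores)
  colnames(p) <- model$classes
  p
}

#' @rdname predict_proba_many
#' @param text A single string.
#' @return `predict_proba` returns one named probability vector.
#' @export
predict_proba <- function(model, text) {
  p <- predict_proba_many(model, list(tokenize_with_bigrams(text)))
  stats::setNames(as.numeric(p[1, ]), model$classes)
}

#' Label uncertainty of a probability vector
#'
#' `least_confidence` is `1 - max(p)`; `entropy` is the Shannon entropy
#' normalized by `log(K)` so both lie in \[0, 1\] (0 for a one-hot vector,
#' maximal for the uniform vector).
#'
#' @param probs Probability vector (non-negative, sums to 1).
#' @param method `"least_confidence"` (default) or `"entropy"`.
#' @return Uncertainty in \[0, 1\].
#' @export
uncertainty <- function(probs, method = c("least_confidence", "entropy")) {
  method <- match.arg(method)
  check_prob_vector(probs, tol = 1e-6, what = "probs")
  if (method == "least_confidence") {
    1 - max(probs)
  } else {
    p <- probs[probs > 0]
    -sum(p * log(p)) / log(length(probs))
  }
}

#' Micro-averaged precision and recall
#'
#' Pools true/false positives and false negatives over all classes. For
#' single-label multiclass predictions micro-precision, micro-recall and
#' accuracy coincide.
#'
#' @param truth,predicted Equal-length vectors of class labels.
#' @return List with `micro_precision`, `micro_recall`, `accuracy`, and a
#'   `per_class` data.frame of per-class precision/recall.
#' @export
evaluate_micro <- function(truth, predicted) {
  assert_that(length(truth) > 0, "empty test set")
  assert_that(length(truth) == length(predicted),
              "truth and predicted must have equal length")
  classes <- sort(unique(c(truth, predicted)))
  tp <- fp <- fn <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    tp[cl] <- sum(predicted == cl & truth == cl)
    fp[cl] <- sum(predicted == cl & truth != cl)
    fn[cl] <- sum(predicted != cl & truth == cl)
  }
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  list(micro_precision = sum(tp) / (sum(tp) + sum(fp)),
       micro_recall = sum(tp) / (sum(tp) + sum(fn)),
       accuracy = mean(predicted == truth),
       per_class = data.frame(class = classes, precision = as.numeric(prec),
                              recall = as.numeric(rec)))
}

#' Save / load a model directory
#'
#' The directory holds `vocabulary.json` (token -> column index),
#' `weights.csv` (sparse triplets feature,class,weight plus the biases) and
#' `metadata.json` (classes, version, hyperparameters) — portable plain
#' text.
#'
#' @param model A [train_bow()] model.
#' @param dir Directory path (created if needed).
#' @return `dir` (for `save_model`) / the model (for `load_model`).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(as.list(model$vocabulary),
                       file.path(dir, "vocabulary.json"), auto_unbox = TRUE)
  nz <- which(model$weights != 0, arr.ind = TRUE)
  wdf <- data.frame(feature = rownames(model$weights)[nz[, 1]],
                    class = colnames(model$weights)[nz[, 2]],
                    weight = model$weights[nz])
  bdf <- data.frame(feature = "<bias>", class = model$classes,
                    weight = as.numeric(model$bias))
  utils::write.csv(rbind(bdf, wdf), file.path(dir, "weights.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(classes = model$classes, version = model$version,
         lambda = model$lambda, min_df = model$min_df,
         trained_on = model$trained_on),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  voc <- unlist(jsonlite::read_json(file.path(dir, "vocabulary.json"),
                                    simplifyVector = TRUE))
  voc <- stats::setNames(as.integer(voc), names(voc))
  w <- utils::read.csv(file.path(dir, "weights.csv"),
                       colClasses = c("character", "character", "numeric"))
  weights <- matrix(0, length(voc), length(meta$classes),
                    dimnames = list(names(voc), meta$classes))
  rows <- w[w$feature != "<bias>", ]
  weights[cbind(rows$feature, rows$class)] <- rows$weight
  brows <- w[w$feature == "<bias>", ]
  bias <- stats::setNames(brows$weight, brows$class)[meta$classes]
  structure(list(vocabulary = voc, weights = weights, bias = bias,
                 classes = meta$classes, lambda = meta$lambda,
                 min_df = meta$min_df, trained_on = meta$trained_on,
                 version = meta$version),
            class = "bow_model")
}
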