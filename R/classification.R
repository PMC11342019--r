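#' Split a labelled story set into train/validation/test
#'
#' Stratified by label and deterministic given the seed. Overall split sizes
#' follow the ratios exactly (largest-remainder rounding); the default
#' 8:1:1 ratio reproduces the 8000/1000/1000 design of a 10 000-story
#' labelled set.
#'
#' @param labels List of [gold_label()] objects (or a list of
#'   `list(story_id, eligible)`).
#' @param ratios Length-3 proportions summing to 1.
#' @param seed Integer seed.
#' @return A `dataset_split`: list with tibbles `train`, `validation`,
#'   `test`, each with columns `story_id`, `label`.
#' @export
split_dataset <- function(labels, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-8) abort("`ratios` must sum to 1.")
  if (length(ratios) != 3) abort("`ratios` must have length 3.")
  df <- tibble::tibble(
    story_id = vapply(labels, `[[`, character(1), "story_id"),
    label = ifelse(vapply(labels, `[[`, logical(1), "eligible"),
                   "eligible", "ineligible"))
  n <- nrow(df)
  targets <- largest_remainder(n * ratios)
  assign_split <- withr::with_seed(seed, {
    out <- integer(n)
    for (cls in unique(df$label)) {
      idx <- sample(which(df$label == cls))
      alloc <- largest_remainder(length(idx) * ratios)
      out[idx] <- rep(1:3, times = alloc)
    }
    # Repair per-class rounding so overall sizes hit the exact targets.
    sizes <- tabulate(out, 3)
    while (any(sizes != targets)) {
      over <- which(sizes > targets)[1]
      under <- which(sizes < targets)[1]
      mv <- which(out == over)[1]
      out[mv] <- under
      sizes <- tabulate(out, 3)
    }
    out
  })
  split_names <- c("train", "validation", "test")
  res <- lapply(1:3, function(k) df[assign_split == k, ])
  names(res) <- split_names
  for (k in split_names) {
    if (nrow(res[[k]]) > 0 && length(unique(res[[k]]$label)) < 2 &&
        length(unique(df$label)) == 2) {
      warn(sprintf("Split '%s' contains a single class.", k))
    }
  }
  structure(res, class = "dataset_split")
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- x - fl
  k <- as.integer(round(sum(x)) - sum(fl))
  if (k > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(k)]
    fl[add] <- fl[add] + 1
  }
  as.integer(fl)
}

tokenize_doc <- function(text) {
  toks <- stringr::str_split_1(
    stringr::str_squish(stringr::str_replace_all(tolower(text),
                                                 "[^a-z0-9]+", " ")), " ")
  toks[nzchar(toks)]
}

doc_term_matrix <- function(texts, vocab = NULL, ngram = 1) {
  tok_lists <- lapply(texts, function(t) {
    toks <- tokenize_doc(t)
    if (ngram >= 2 && length(toks) >= 2) {
      toks <- c(toks, paste(toks[-length(toks)], toks[-1], sep = "_"))
    }
    toks
  })
  if (is.null(vocab)) vocab <- sort(unique(unlist(tok_lists)))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (d in seq_along(tok_lists)) {
    tab <- table(factor(tok_lists[[d]], levels = vocab))
    nz <- which(tab > 0)
    ii <- c(ii, rep(d, length(nz)))
    jj <- c(jj, nz)
    xx <- c(xx, as.numeric(tab[nz]))
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(texts), length(vocab)))
  colnames(m) <- vocab
  list(matrix = m, vocab = vocab)
}

#' Train the eligible-story classifier
#'
#' The default model is a bag-of-n-grams document-term matrix with a
#' ridge-regularised logistic regression (fit with \pkg{glmnet}); it is
#' deterministic, desk-scale and replaceable. Any model honouring the
#' `predict(story) -> label, score` contract (for example a fine-tuned
#' transformer) can be plugged in behind the same interface.
#'
#' @param split A [split_dataset()] result; training uses `split$train`.
#' @param stories Corpus (list of [media_story()]) covering the split ids.
#' @param model_spec `list(ngram, lambda)`; `ngram` 1 or 2, `lambda` ridge
#'   penalty.
#' @return A `story_classifier` object usable with
#'   [predict.story_classifier()].
#' @export
train_classifier <- function(split, stories,
                             model_spec = list(ngram = 1, lambda = 1e-3)) {
  train <- split$train
  if (nrow(train) == 0) abort("Training split is empty.")
  if (length(unique(train$label)) < 2) {
    abort("Training data contain a single class; both classes are required.")
  }
  ids <- vapply(stories, `[[`, character(1), "story_id")
  idx <- match(train$story_id, ids)
  if (anyNA(idx)) abort("Some training story_ids are missing from `stories`.")
  texts <- vapply(stories[idx], story_text, character(1))
  dtm <- doc_term_matrix(texts, ngram = model_spec$ngram %||% 1)
  y <- as.integer(train$label == "eligible")
  lambda <- model_spec$lambda %||% 1e-3
  fit <- glmnet::glmnet(dtm$matrix, y, family = "binomial", alpha = 0,
                        lambda = c(lambda * 10, lambda),
                        standardize = FALSE)
  structure(list(fit = fit, lambda = lambda, vocab = dtm$vocab,
                 ngram = model_spec$ngram %||% 1),
            class = "story_classifier")
}

#' Predict story eligibility
#'
#' @param object A `story_classifier`.
#' @param stories List of [media_story()] objects.
#' @param ... Unused.
#' @return A tibble with `story_id`, `label` (`"eligible"`/`"ineligible"`)
#'   and `score` (posterior probability of eligibility).
#' @export
predict.story_classifier <- function(object, stories, ...) {
  texts <- vapply(stories, story_text, character(1))
  dtm <- doc_term_matrix(texts, vocab = object$vocab, ngram = object$ngram)
  p <- as.numeric(stats::predict(object$fit, newx = dtm$matrix,
                                 s = object$lambda, type = "response"))
  tibble::tibble(
    story_id = vapply(stories, `[[`, character(1), "story_id"),
    label = ifelse(p >= 0.5, "eligible", "ineligible"),
    score = p)
}

#' Classification metric suite
#'
#' Computes the platform's evaluation metrics with "eligible" as the
#' positive class: accuracy, support-weighted average precision, positive-
#' class precision, support-weighted recall, specificity, false positive
#' rate, and support-weighted F1 (the weighted mean of per-class F1 scores).
#' In the binary case support-weighted recall is structurally identical to
#' accuracy, which is the averaging convention that makes a published
#' metric table internally consistent. Undefined ratios (zero denominators)
#' are reported as 0.
#'
#' @param predictions,truth Equal-length label vectors
#'   (`"eligible"`/`"ineligible"`, or logical eligibility).
#' @param positive Positive-class label.
#' @return A `metrics_report` list: `accuracy`, `precision_average`,
#'   `precision_positive`, `recall`, `specificity`, `false_positive_rate`,
#'   `f1`, and `confusion` (named TP/FP/FN/TN counts).
#' @export
compute_classification_metrics <- function(predictions, truth,
                                           positive = "eligible") {
  as_lab <- function(x) {
    if (is.logical(x)) ifelse(x, positive, paste0("not_", positive)) else
      as.character(x)
  }
  predictions <- as_lab(predictions)
  truth <- as_lab(truth)
  if (length(predictions) != length(truth) || length(truth) == 0) {
    abort("`predictions` and `truth` must be non-empty and equal length.")
  }
  tp <- sum(predictions == positive & truth == positive)
  fp <- sum(predictions == positive & truth != positive)
  fn <- sum(predictions != positive & truth == positive)
  tn <- sum(predictions != positive & truth != positive)
  n <- tp + fp + fn + tn
  safe <- function(num, den) if (den == 0) 0 else num / den
  prec_pos <- safe(tp, tp + fp)
  prec_neg <- safe(tn, tn + fn)
  rec_pos <- safe(tp, tp + fn)
  rec_neg <- safe(tn, tn + fp)
  supp_pos <- tp + fn
  supp_neg <- tn + fp
  f1_pos <- safe(2 * prec_pos * rec_pos, prec_pos + rec_pos)
  f1_neg <- safe(2 * prec_neg * rec_neg, prec_neg + rec_neg)
  fpr <- safe(fp, fp + tn)
  structure(list(
    accuracy = (tp + tn) / n,
    precision_average = (supp_pos * prec_pos + supp_neg * prec_neg) / n,
    precision_positive = prec_pos,
    recall = (supp_pos * rec_pos + supp_neg * rec_neg) / n,
    specificity = 1 - fpr,
    false_positive_rate = fpr,
    f1 = (supp_pos * f1_pos + supp_neg * f1_neg) / n,
    confusion = c(TP = tp, FP = fp, FN = fn, TN = tn)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Classification metrics (positive = eligible)\n")
  for (m in c("accuracy", "precision_average", "precision_positive",
              "recall", "specificity", "false_positive_rate", "f1")) {
    cat(sprintf("  %-20s %6.4f\n", m, x[[m]]))
  }
  cat(sprintf("  confusion: TP=%d FP=%d FN=%d TN=%d\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["FN"],
              x$confusion["TN"]))
  invisible(x)
}
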