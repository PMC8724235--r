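## Multiclass classifier evaluation over the six-emotion label set, plus a
## desk-scale lexicon baseline so the pipeline runs end to end without a
## trained neural model (any classifier emitting one of the six labels per
## message plugs into the same evaluation).

#' Confusion matrix over the six emotion labels
#'
#' Rows are true labels, columns predicted labels, in the fixed
#' [emotion_levels()] order.
#'
#' @param truth,predicted equal-length character vectors of labels.
#' @return 6 x 6 integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted differ in length", call. = FALSE)
  }
  assert_emotion(truth, "true")
  assert_emotion(predicted, "predicted")
  cm <- table(factor(truth, levels = EMOTIONS),
              factor(predicted, levels = EMOTIONS))
  cm <- matrix(as.integer(cm), 6L, 6L, dimnames = list(true = EMOTIONS,
                                                       predicted = EMOTIONS))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Row-normalize a confusion matrix
#'
#' @param cm a [confusion_matrix()].
#' @return Matrix whose non-empty rows sum to 1; the diagonal equals
#'   per-class recall.
#' @export
row_normalize <- function(cm) {
  rs <- rowSums(cm)
  out <- unclass(cm) / ifelse(rs > 0, rs, 1)
  out[rs == 0, ] <- NA_real_
  out
}

#' F1 score from precision and recall
#'
#' `F = 2 P R / (P + R)`, defined as 0 when `P + R = 0`.  Vectorized.
#'
#' @param precision,recall numeric in `[0, 1]`.
#' @return Numeric F1 values.
#' @export
#' @examples
#' f1_score(0.729, 0.813)
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Per-class precision, recall and F1 plus overall accuracy
#'
#' One-vs-rest reduction per class: `tp` is the diagonal entry, `fp` the
#' rest of the column, `fn` the rest of the row.  Accuracy is the standard
#' multiclass `trace / total`.  A class with no predicted (or no true)
#' positives gets precision (or recall) 0 with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return List with `per_class` (data.frame `class`, `precision`,
#'   `recall`, `f1`) and `accuracy`.
#' @export
class_metrics <- function(cm) {
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  if (any(tp + fp == 0)) {
    warning(sprintf("no predicted positives for class(es): %s; precision set to 0",
                    paste(EMOTIONS[tp + fp == 0], collapse = ", ")))
  }
  if (any(tp + fn == 0)) {
    warning(sprintf("no true positives for class(es): %s; recall set to 0",
                    paste(EMOTIONS[tp + fn == 0], collapse = ", ")))
  }
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  list(per_class = data.frame(class = EMOTIONS,
                              precision = as.numeric(precision),
                              recall = as.numeric(recall),
                              f1 = f1_score(as.numeric(precision),
                                            as.numeric(recall)),
                              row.names = NULL),
       accuracy = sum(tp) / total)
}

#' Default keyword lexicon matched to the synthetic vocabularies
#'
#' Maps every core token of [default_vocab()] to its emotion; shared
#' stopwords are unmapped.
#'
#' @inheritParams default_vocab
#' @return Named list (by emotion) of character keyword vectors.
#' @export
default_lexicon <- function(n_core = 15L) {
  stats::setNames(lapply(EMOTIONS, function(emo) {
    sprintf("%s_core%02d", emo, seq_len(n_core))
  }), EMOTIONS)
}

#' Keyword-lexicon emotion classifier
#'
#' Desk-scale baseline: each message is labeled with the emotion whose
#' keywords match the most tokens; `neutral` when nothing matches; ties are
#' broken by the fixed label order of [emotion_levels()].
#'
#' @param tokens a character vector (one message) or a list of character
#'   vectors (many messages).
#' @param lexicon named list mapping each emotion to its keyword vector.
#' @return Character label(s).
#' @export
lexicon_classifier <- function(tokens, lexicon = default_lexicon()) {
  assert_emotion(names(lexicon), "lexicon")
  if (is.character(tokens)) tokens <- list(tokens)
  # token -> emotion lookup; a token mapped by several emotions counts for each
  vapply(tokens, function(tk) {
    hits <- vapply(EMOTIONS, function(emo) {
      kw <- lexicon[[emo]]
      if (is.null(kw)) 0L else sum(tk %in% kw)
    }, integer(1))
    if (all(hits == 0L)) "neutral" else EMOTIONS[which.max(hits)]
  }, character(1))
}
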