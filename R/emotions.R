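#' The closed six-emotion label set
#'
#' Every message carries exactly one of these labels; the order is fixed and
#' is also the tie-break precedence used by [lexicon_classifier()].
#'
#' @return Character vector of the six emotion labels.
#' @export
#' @examples
#' emotion_levels()
emotion_levels <- function() {
  c("happy", "angry", "sad", "fear", "surprise", "neutral")
}

# internal shorthand
EMOTIONS <- c("happy", "angry", "sad", "fear", "surprise", "neutral")

assert_emotion <- function(x, what = "emotion") {
  bad <- setdiff(unique(as.character(x)), EMOTIONS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s label(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# one-hot row for a label
emotion_onehot <- function(label) {
  as.numeric(EMOTIONS == label)
}
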