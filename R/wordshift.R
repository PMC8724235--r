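## Shannon-entropy word shifts between two token corpora.
##
## The entropy of a corpus's empirical word distribution measures how
## unpredictable (topically rich) it is; the shift decomposes the entropy
## difference between two corpora into signed per-word contributions.
## Base-2 logarithms throughout; results are in bits.

# p * log2(1/p) with the convention 0 * log(1/0) = 0
plogp <- function(p) ifelse(p > 0, -p * log2(p), 0)

#' Empirical token distribution of a corpus
#'
#' @param tokens character vector of tokens (the corpus).
#' @return Named probability vector (token -> relative frequency) with
#'   attribute `n_tokens`; raw frequencies, no smoothing.
#' @export
corpus_distribution <- function(tokens) {
  if (length(tokens) == 0L) stop("empty corpus", call. = FALSE)
  tab <- table(tokens)
  p <- as.numeric(tab) / length(tokens)
  structure(stats::setNames(p, names(tab)), n_tokens = length(tokens))
}

#' Shannon entropy of a token distribution, in bits
#'
#' `H(P) = sum_tau p_tau log2(1 / p_tau)`.
#'
#' @param dist a named probability vector (as [corpus_distribution()]) or a
#'   raw character token vector, which is tabulated first.
#' @return Entropy in bits.
#' @export
#' @examples
#' shannon_entropy(c(a = 0.25, b = 0.25, c = 0.25, d = 0.25))  # 2 bits
shannon_entropy <- function(dist) {
  if (is.character(dist)) dist <- corpus_distribution(dist)
  if (length(dist) == 0L) stop("empty corpus", call. = FALSE)
  check_prob_vector(as.numeric(dist), "dist")
  sum(plogp(as.numeric(dist)))
}

#' Shannon-entropy word shift between two corpora
#'
#' Builds the empirical distributions of both corpora over their union
#' vocabulary and decomposes the entropy difference `H2 - H1` into per-word
#' contributions `delta_H = p2 log2(1/p2) - p1 log2(1/p1)` (zero terms for
#' out-of-support words).  The contributions sum exactly to `H2 - H1`.
#'
#' @param corpus1,corpus2 character token vectors; corpus 1 is the
#'   reference stratum.
#' @return Object of class `word_shift`: list with entropies `H1`, `H2`,
#'   `delta_H = H2 - H1`, and `table`, a data.frame
#'   `(token, p1, p2, delta)` ranked by `|delta|` descending with
#'   lexicographic tie-break.
#' @export
entropy_shift <- function(corpus1, corpus2) {
  if (length(corpus1) == 0L || length(corpus2) == 0L) {
    stop("empty corpus", call. = FALSE)
  }
  d1 <- corpus_distribution(corpus1)
  d2 <- corpus_distribution(corpus2)
  vocab <- sort(union(names(d1), names(d2)))
  p1 <- ifelse(vocab %in% names(d1), d1[vocab], 0)
  p2 <- ifelse(vocab %in% names(d2), d2[vocab], 0)
  p1[is.na(p1)] <- 0; p2[is.na(p2)] <- 0
  delta <- plogp(p2) - plogp(p1)
  tab <- data.frame(token = vocab, p1 = as.numeric(p1), p2 = as.numeric(p2),
                    delta = as.numeric(delta), stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$delta), tab$token), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(H1 = sum(plogp(p1)), H2 = sum(plogp(p2)),
                 delta_H = sum(delta), table = tab),
            class = "word_shift")
}

#' @export
print.word_shift <- function(x, k = 10L, ...) {
  cat(sprintf("word_shift: H1 = %.4f bits, H2 = %.4f bits, delta = %+.4f bits\n",
              x$H1, x$H2, x$delta_H))
  top <- utils::head(x$table, k)
  bar <- function(d) {
    len <- round(20 * abs(d) / max(abs(top$delta), .Machine$double.eps))
    paste0(ifelse(d >= 0, "+", "-"), strrep("=", len))
  }
  for (i in seq_len(nrow(top))) {
    cat(sprintf("%3d %-20s %+8.5f %s\n", top$rank[i], top$token[i],
                top$delta[i], bar(top$delta[i])))
  }
  invisible(x)
}

#' Proportion shift between two corpora
#'
#' The simple companion diagnostic: per-token difference of relative
#' frequencies `p2 - p1`, ranked by absolute magnitude.  The differences
#' sum to zero over the union vocabulary.
#'
#' @inheritParams entropy_shift
#' @return data.frame `(token, p1, p2, diff, rank)` ranked by `|diff|`.
#' @export
proportion_shift <- function(corpus1, corpus2) {
  if (length(corpus1) == 0L || length(corpus2) == 0L) {
    stop("empty corpus", call. = FALSE)
  }
  d1 <- corpus_distribution(corpus1)
  d2 <- corpus_distribution(corpus2)
  vocab <- sort(union(names(d1), names(d2)))
  p1 <- ifelse(vocab %in% names(d1), d1[vocab], 0); p1[is.na(p1)] <- 0
  p2 <- ifelse(vocab %in% names(d2), d2[vocab], 0); p2[is.na(p2)] <- 0
  tab <- data.frame(token = vocab, p1 = as.numeric(p1), p2 = as.numeric(p2),
                    diff = as.numeric(p2 - p1), stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$diff), tab$token), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Top contributing tokens of a word shift
#'
#' @param shift an [entropy_shift()] result.
#' @param k number of tokens; ties on `|delta|` are already resolved
#'   lexicographically in the ranking.
#' @return The first `k` rows of the ranked contribution table.
#' @export
top_contributors <- function(shift, k) {
  stopifnot(inherits(shift, "word_shift"))
  if (k <= 0) stop("k must be positive", call. = FALSE)
  utils::head(shift$table, k)
}
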