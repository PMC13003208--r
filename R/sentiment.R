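#' Split a token vector into fixed-size chunks
#'
#' Consecutive, non-overlapping chunks of `chunk_size` tokens; every chunk
#' is full except possibly the last, and concatenating the chunks restores
#' the input. Mirrors the fixed 128-token input window of transformer
#' sentiment models, whose truncation bias the chunk-and-average scheme is
#' designed to remove.
#'
#' @param tokens non-empty character vector.
#' @param chunk_size tokens per chunk (default 128).
#' @return list of character vectors.
#' @export
chunk_tokens <- function(tokens, chunk_size = 128) {
  if (chunk_size < 1) stop("chunk_size must be at least 1")
  n <- length(tokens)
  if (n == 0) stop("cannot chunk an empty token vector")
  unname(split(tokens, (seq_len(n) - 1) %/% chunk_size))
}

#' Deterministic lexicon sentiment scorer
#'
#' The reference scorer backend: with n+ positive-lexicon and n- negative-
#' lexicon tokens in a chunk, the polarity score is
#' `s = (n+ - n-) / (n+ + n- + smoothing)` and the positive probability is
#' `(1 + s) / 2` (0.5 when no polarity token occurs). Distinct smoothing
#' constants give genuinely distinct ensemble members.
#'
#' @param pos_lexicon,neg_lexicon disjoint token sets.
#' @param smoothing additive constant in the denominator (default 1).
#' @param name scorer name used in outputs.
#' @return a `sentiment_scorer`: list with `name` and `score(tokens)`
#'   returning `c(p_pos, p_neg)` summing to one.
#' @export
lexicon_scorer <- function(pos_lexicon, neg_lexicon, smoothing = 1,
                           name = paste0("lexicon_s", smoothing)) {
  if (length(intersect(pos_lexicon, neg_lexicon)) > 0)
    stop("pos_lexicon and neg_lexicon must be disjoint")
  force(smoothing)
  structure(list(
    name = name,
    score = function(tokens) {
      np <- sum(tokens %in% pos_lexicon)
      nn <- sum(tokens %in% neg_lexicon)
      s <- (np - nn) / (np + nn + smoothing)
      p_pos <- (1 + s) / 2
      c(p_pos = p_pos, p_neg = 1 - p_pos)
    }), class = "sentiment_scorer")
}

#' Read a one-token-per-line lexicon file
#'
#' @param path plain-text file, one token per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return character vector of tokens.
#' @export
read_lexicon <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Document-level score of one scorer
#'
#' Tokenizes, chunks, scores each chunk, and averages the chunk
#' probabilities with equal weight (optionally weighting by chunk length).
#' The average of distributions is again a distribution.
#'
#' @param scorer a `sentiment_scorer`.
#' @param text one document (character scalar) or a pre-tokenized
#'   character vector.
#' @param chunk_size tokens per chunk.
#' @param weight_by_length if `TRUE`, chunks contribute proportionally to
#'   their token counts instead of equally.
#' @return named numeric `c(p_pos, p_neg, n_chunks)`.
#' @export
score_document <- function(scorer, text, chunk_size = 128,
                           weight_by_length = FALSE) {
  tokens <- if (length(text) == 1 && !is.null(text)) tokenize(text)[[1]] else text
  if (length(tokens) == 0) stop("document is empty after tokenization")
  chunks <- chunk_tokens(tokens, chunk_size)
  probs <- matrix(NA_real_, length(chunks), 2)
  for (i in seq_along(chunks)) {
    p <- tryCatch(scorer$score(chunks[[i]]), error = function(e)
      stop("scorer '", scorer$name, "' failed on chunk ", i, ": ",
           conditionMessage(e), call. = FALSE))
    probs[i, ] <- p
  }
  w <- if (weight_by_length) lengths(chunks) / length(tokens)
       else rep(1 / length(chunks), length(chunks))
  c(p_pos = sum(probs[, 1] * w), p_neg = sum(probs[, 2] * w),
    n_chunks = length(chunks))
}

#' Bagging ensemble of document scores
#'
#' Averages the per-scorer document-level positive and negative
#' probabilities and takes the label with the higher average; an exact tie
#' is labelled positive (documented, deterministic rule).
#'
#' @param doc_scores matrix or data frame with columns `p_pos`, `p_neg`,
#'   one row per scorer (at least one).
#' @return list with `p_pos`, `p_neg`, `label`.
#' @export
ensemble <- function(doc_scores) {
  doc_scores <- as.data.frame(doc_scores)
  if (nrow(doc_scores) == 0) stop("ensemble needs at least one scorer output")
  p_pos <- mean(doc_scores$p_pos)
  p_neg <- mean(doc_scores$p_neg)
  list(p_pos = p_pos, p_neg = p_neg,
       label = if (p_pos >= p_neg) "positive" else "negative")
}

#' Classify the questions and/or top answers of a corpus
#'
#' Runs tokenize, chunk, per-scorer scoring, chunk averaging and the
#' bagging ensemble over the requested targets. The answer target uses each
#' record's most upvoted answer ([top_answers()]). Documents empty after
#' tokenization are excluded and counted in the `excluded` attribute.
#'
#' @param corpus a [qa_corpus()] (answered records).
#' @param scorers list of `sentiment_scorer`s (the reference setup uses two
#'   lexicon scorers with different smoothing).
#' @param target `"questions"`, `"answers"`, or `"both"`.
#' @param chunk_size tokens per chunk.
#' @param weight_by_length passed to [score_document()].
#' @return tibble with `record_id`, `target`, one `p_pos_<scorer>` column
#'   per scorer, `p_pos`, `p_neg`, `label`, `n_chunks`; attribute
#'   `excluded` lists skipped record ids.
#' @export
classify_corpus <- function(corpus, scorers, target = c("answers", "questions", "both"),
                            chunk_size = 128, weight_by_length = FALSE) {
  target <- match.arg(target)
  corpus <- qa_corpus(corpus)
  if (length(scorers) == 0) stop("need at least one scorer")
  jobs <- list()
  if (target %in% c("questions", "both"))
    jobs$question <- stats::setNames(corpus$question_text, corpus$record_id)
  if (target %in% c("answers", "both")) {
    ta <- top_answers(corpus)
    jobs$answer <- stats::setNames(ta$answer_text, ta$record_id)
  }
  excluded <- character()
  out <- list()
  for (tgt in names(jobs)) {
    texts <- jobs[[tgt]]
    toks <- tokenize(texts)
    empty <- lengths(toks) == 0
    if (any(empty)) excluded <- c(excluded, paste0(tgt, ":", names(texts)[empty]))
    keep <- which(!empty)
    rows <- lapply(keep, function(i) {
      per <- t(vapply(scorers, score_document, numeric(3), text = toks[[i]],
                      chunk_size = chunk_size,
                      weight_by_length = weight_by_length))
      ens <- ensemble(data.frame(p_pos = per[, "p_pos"], p_neg = per[, "p_neg"]))
      row <- tibble::tibble(record_id = names(texts)[i], target = tgt,
                            p_pos = ens$p_pos, p_neg = ens$p_neg,
                            label = ens$label, n_chunks = per[1, "n_chunks"])
      for (s in seq_along(scorers))
        row[[paste0("p_pos_", scorers[[s]]$name)]] <- per[s, "p_pos"]
      row
    })
    out[[tgt]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  if (length(excluded) > 0)
    message(length(excluded), " empty document(s) excluded from sentiment scoring")
  attr(res, "excluded") <- excluded
  res
}

#' Accuracy of predicted labels against gold labels
#'
#' @param predicted tibble with `record_id` and `label`.
#' @param gold tibble with `record_id` and a gold label column (second
#'   column, or `gold_col`).
#' @param gold_col name of the gold label column.
#' @return list with `accuracy`, `n_match`, `n_total`.
#' @export
evaluate_accuracy <- function(predicted, gold, gold_col = NULL) {
  gold_col <- gold_col %||% setdiff(names(gold), "record_id")[1]
  common <- intersect(predicted$record_id, gold$record_id)
  if (length(common) == 0) stop("predicted and gold label sets share no record_id")
  p <- predicted$label[match(common, predicted$record_id)]
  g <- gold[[gold_col]][match(common, gold$record_id)]
  n_match <- sum(p == g)
  list(accuracy = n_match / length(common), n_match = n_match,
       n_total = length(common))
}
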