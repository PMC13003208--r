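POS <- sprintf("good%02d", 1:5)
NEG <- sprintf("bad%02d", 1:5)
ref_scorer <- function(smoothing = 1) lexicon_scorer(POS, NEG, smoothing)

test_that("chunking is exact, ordered, and reconstructs the input", {
  toks <- sprintf("w%03d", 1:300)
  ch <- chunk_tokens(toks, 128)
  expect_equal(lengths(ch), c(128L, 128L, 44L))
  expect_identical(unlist(ch), toks)
  expect_equal(lengths(chunk_tokens(sprintf("w%d", 1:128), 128)), 128L)
  expect_equal(lengths(chunk_tokens("one", 128)), 1L)
  expect_error(chunk_tokens(character(), 128), "empty")
  # property: reconstruction holds across random lengths and chunk sizes
  set.seed(4)
  for (i in 1:20) {
    n <- sample(1:500, 1)
    cs <- sample(1:130, 1)
    ch <- chunk_tokens(as.character(seq_len(n)), cs)
    expect_identical(unlist(ch), as.character(seq_len(n)))
    expect_true(all(lengths(ch)[-length(ch)] == cs))
  }
})

test_that("the lexicon scorer follows its smoothed polarity formula", {
  s <- ref_scorer()
  expect_equal(s$score(c("plain", "words")), c(p_pos = 0.5, p_neg = 0.5))
  expect_equal(s$score(c(POS[1:3]))[["p_pos"]], 0.875)  # s = 3/4
  expect_equal(s$score(c(POS[1], NEG[1]))[["p_pos"]], 0.5)
  # probabilities always conserve mass
  set.seed(9)
  for (i in 1:25) {
    chunk <- sample(c(POS, NEG, letters), sample(1:40, 1), replace = TRUE)
    p <- s$score(chunk)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    # monotonicity: one more positive token never lowers p_pos
    expect_gte(s$score(c(chunk, POS[1]))[["p_pos"]], p[["p_pos"]])
  }
  expect_error(lexicon_scorer(c("x"), c("x")), "disjoint")
})

test_that("document scores average chunks equally and are chunk-order invariant", {
  # scorer whose chunk scores we control through marker tokens
  marker <- lexicon_scorer("up", "down", smoothing = 0.25)
  doc <- c(rep("up", 128), rep("down", 128))
  out <- score_document(marker, doc, chunk_size = 128)
  # first chunk is all-positive, second all-negative: means cancel to 0.5
  expect_equal(out[["p_pos"]], 0.5)
  expect_equal(out[["n_chunks"]], 2)

  # single-chunk document: document score equals the chunk score
  one <- score_document(marker, c("up", "x"), chunk_size = 128)
  expect_equal(one[["p_pos"]], marker$score(c("up", "x"))[["p_pos"]])

  # permutation invariance of the unweighted mean over chunks
  set.seed(2)
  toks <- sample(c("up", "down", "x"), 300, replace = TRUE)
  chunks <- chunk_tokens(toks, 50)
  base <- score_document(marker, toks, chunk_size = 50)[["p_pos"]]
  for (i in 1:5) {
    shuf <- unlist(chunks[sample(length(chunks))])
    expect_equal(score_document(marker, shuf, chunk_size = 50)[["p_pos"]], base)
  }
  expect_error(score_document(marker, "   "), "empty")
})

test_that("mean-of-chunk-probabilities matches a hand-computed mixed document", {
  # chunk p_pos values 0.9, 0.5, 0.1 must average to 0.5; emulate with a
  # scorer reading a count marker
  fake <- structure(list(name = "fixed", score = function(tokens) {
    p <- as.numeric(tokens[1])
    c(p_pos = p, p_neg = 1 - p)
  }), class = "sentiment_scorer")
  doc <- c("0.9", rep("x", 1), "0.5", rep("x", 1), "0.1", "x")
  expect_equal(score_document(fake, doc, chunk_size = 2)[["p_pos"]], 0.5)
})

test_that("the bagging ensemble averages probabilities and breaks ties positive", {
  expect_equal(ensemble(data.frame(p_pos = c(0.8, 0.6), p_neg = c(0.2, 0.4))),
               list(p_pos = 0.7, p_neg = 0.3, label = "positive"))
  expect_equal(ensemble(data.frame(p_pos = c(0.2, 0.4), p_neg = c(0.8, 0.6)))$label,
               "negative")
  expect_equal(ensemble(data.frame(p_pos = c(0.5, 0.5), p_neg = c(0.5, 0.5)))$label,
               "positive")
  expect_error(ensemble(data.frame(p_pos = numeric(), p_neg = numeric())),
               "at least one")
})

test_that("corpus classification composes chunking, scoring and bagging", {
  n <- 12
  corpus <- qa_corpus(tibble::tibble(
    record_id = sprintf("r%02d", 1:n), platform = "p",
    question_text = rep(paste(POS[1:3], collapse = " "), n),
    question_timestamp = as.Date("2020-07-01") + 1:n,
    url = NA_character_,
    answers = replicate(n, make_answers(5, texts = paste(POS, collapse = " ")),
                        simplify = FALSE)))
  res <- classify_corpus(corpus, list(ref_scorer(1), ref_scorer(2)), "both")
  expect_true(all(res$label == "positive"))
  expect_equal(nrow(res), 2 * n)
  expect_prob_rows(cbind(res$p_pos, res$p_neg), tol = 1e-9)

  # an ensemble of identical scorers equals the single scorer's labels
  dual <- classify_corpus(corpus, list(ref_scorer(1), ref_scorer(1)), "answers")
  single <- classify_corpus(corpus, list(ref_scorer(1)), "answers")
  expect_equal(dual$label, single$label)
  expect_equal(dual$p_pos, single$p_pos)
})

test_that("accuracy evaluation reports matches over totals", {
  ids <- sprintf("r%03d", 1:50)
  gold <- tibble::tibble(record_id = ids,
                         label = rep(c("positive", "negative"), 25))
  pred <- gold
  pred$label[1:17] <- ifelse(pred$label[1:17] == "positive", "negative", "positive")
  out <- evaluate_accuracy(pred, gold)
  expect_equal(out$accuracy, 0.66)
  expect_equal(out$n_match, 33)

  pred2 <- gold
  pred2$label[1:14] <- ifelse(pred2$label[1:14] == "positive", "negative", "positive")
  expect_equal(evaluate_accuracy(pred2, gold)$accuracy, 0.72)

  expect_equal(evaluate_accuracy(gold, gold)$accuracy, 1.0)
  other <- tibble::tibble(record_id = "zzz", label = "positive")
  expect_error(evaluate_accuracy(other, gold), "share no record_id")
})
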