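# Fixture builders shared across test files. All corpora are built in code;
# nothing is read from disk except files the tests themselves write.

make_answers <- function(upvotes, texts = NULL, timestamps = NULL) {
  n <- length(upvotes)
  tibble::tibble(
    answer_text = texts %||% sprintf("answer number %d", seq_len(n)),
    upvotes = as.integer(upvotes),
    answer_timestamp = if (is.null(timestamps)) as.Date(rep(NA, n))
                       else as.Date(timestamps))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# n records, first n_unanswered have no answers; keyword "vaccine" planted
# in the questions of `keyword_in_question` and the answers of
# `keyword_in_answer` (indices).
make_fixture_corpus <- function(n = 10, n_unanswered = 0,
                                keyword_in_question = integer(),
                                keyword_in_answer = integer()) {
  answers <- lapply(seq_len(n), function(i) {
    if (i <= n_unanswered) return(make_answers(integer()))
    a <- make_answers(c(3, 9, 1)[seq_len(1 + i %% 3)])
    if (i %in% keyword_in_answer)
      a$answer_text[1] <- "yes the VACCINE rollout helped"
    a
  })
  q <- sprintf("question about topic %d please advise", seq_len(n))
  q[keyword_in_question] <- sprintf("are vaccines safe, case %d?",
                                    keyword_in_question)
  qa_corpus(tibble::tibble(
    record_id = sprintf("r%03d", seq_len(n)),
    platform = "quora",
    question_text = q,
    question_timestamp = as.Date("2020-07-01") + seq_len(n),
    url = ifelse(seq_len(n) %% 2 == 0, sprintf("http://x/%d", seq_len(n)),
                 NA_character_),
    answers = answers))
}

# a fast, small generator config for tests
tiny_gen_config <- function(...) {
  defaults <- list(n_records = 60, n_topics = 2, vocab_size_per_topic = 20,
                   shared_vocab_size = 0, doc_length_range = c(10, 40),
                   answers_per_record_range = c(1, 3), seed = 42L)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

expect_prob_rows <- function(m, tol = 1e-8) {
  expect_true(all(abs(rowSums(m) - 1) < tol))
}

# best label-permutation accuracy from a confusion matrix (clusters x truth);
# exhaustive over permutations, fine for <= 7 topics
best_permutation_accuracy <- function(conf) {
  k <- nrow(conf)
  stopifnot(k == ncol(conf), k <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  max(vapply(perms(seq_len(k)), function(p)
    sum(conf[cbind(seq_len(k), p)]), numeric(1))) / sum(conf)
}
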