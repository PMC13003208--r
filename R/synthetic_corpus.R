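#' Configuration for the synthetic Q&A corpus generator
#'
#' The generator plants the statistical structure the analysis pipeline is
#' designed to recover: topics with private vocabularies, per-topic question
#' sentiment mixtures, question-to-answer sentiment coupling, and
#' month-resolved answer sentiment rates that can cross the 50% majority
#' line. Tokens are abstract symbols (no natural-language realism).
#'
#' Defaults emulate one platform's corpus in the motivating study: 3952
#' question-answer records over June 27, 2020 to June 27, 2021, five topics,
#' and a handful of answers per question with a unique most-upvoted answer.
#'
#' @param n_records number of question records.
#' @param n_topics number of planted topics.
#' @param vocab_size_per_topic private vocabulary size of each topic.
#' @param shared_vocab_size size of the topic-neutral shared vocabulary.
#' @param shared_mass probability that a content token is drawn from the
#'   shared vocabulary rather than the topic's private one.
#' @param topic_weights probability vector over topics (default uniform).
#' @param doc_length_range inclusive integer range for document lengths;
#'   the default reaches past 128 tokens so sentiment chunking is exercised.
#' @param pos_lexicon,neg_lexicon disjoint polarity token sets.
#' @param injection_rate per-token probability of replacing a content token
#'   with a polarity token of the document's sentiment (at least one is
#'   always injected).
#' @param pi_t per-topic probability that a question is positive (recycled
#'   to `n_topics`).
#' @param rho probability that the answer sentiment agrees with the question
#'   sentiment; used only when `month_pos_rate` is `NULL`.
#' @param month_pos_rate optional named vector mapping months (`"YYYY-MM"`)
#'   to the answer-positive probability, planting temporal structure; when
#'   given it overrides `rho` and records are spread over exactly these
#'   months.
#' @param date_range length-2 `Date` (or ISO string) vector delimiting
#'   question timestamps.
#' @param answers_per_record_range inclusive integer range for answers per
#'   record.
#' @param platform platform label stamped on the records.
#' @param seed integer seed; the corpus is fully reproducible given the
#'   config.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n_records = 3952,
                             n_topics = 5,
                             vocab_size_per_topic = 60,
                             shared_vocab_size = 40,
                             shared_mass = 0.2,
                             topic_weights = NULL,
                             doc_length_range = c(20, 400),
                             pos_lexicon = sprintf("goodtok%02d", 1:15),
                             neg_lexicon = sprintf("badtok%02d", 1:15),
                             injection_rate = 0.1,
                             pi_t = 0.5,
                             rho = 0.8,
                             month_pos_rate = NULL,
                             date_range = c("2020-06-27", "2021-06-27"),
                             answers_per_record_range = c(1, 5),
                             platform = "synthetic",
                             seed = 1L) {
  topic_weights <- topic_weights %||% rep(1 / n_topics, n_topics)
  cfg <- list(n_records = as.integer(n_records), n_topics = as.integer(n_topics),
              vocab_size_per_topic = as.integer(vocab_size_per_topic),
              shared_vocab_size = as.integer(shared_vocab_size),
              shared_mass = shared_mass, topic_weights = topic_weights,
              doc_length_range = as.integer(doc_length_range),
              pos_lexicon = pos_lexicon, neg_lexicon = neg_lexicon,
              injection_rate = injection_rate,
              pi_t = rep_len(pi_t, n_topics), rho = rho,
              month_pos_rate = month_pos_rate,
              date_range = as.Date(date_range),
              answers_per_record_range = as.integer(answers_per_record_range),
              platform = platform, seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  if (abs(sum(cfg$topic_weights) - 1) > 1e-9)
    stop("topic_weights must sum to 1")
  if (length(cfg$topic_weights) != cfg$n_topics)
    stop("topic_weights must have length n_topics")
  if (length(intersect(cfg$pos_lexicon, cfg$neg_lexicon)) > 0)
    stop("pos_lexicon and neg_lexicon must be disjoint")
  probs <- c(cfg$shared_mass, cfg$injection_rate, cfg$pi_t, cfg$rho,
             cfg$month_pos_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (cfg$injection_rate > 0 &&
      (length(cfg$pos_lexicon) == 0 || length(cfg$neg_lexicon) == 0))
    stop("nonzero injection_rate requires non-empty polarity lexicons")
  if (diff(cfg$date_range) < 0) stop("date_range must be increasing")
  if (cfg$doc_length_range[1] < 1 || diff(cfg$doc_length_range) < 0)
    stop("invalid doc_length_range")
  if (cfg$answers_per_record_range[1] < 1 ||
      diff(cfg$answers_per_record_range) < 0)
    stop("invalid answers_per_record_range")
  invisible(cfg)
}

month_key <- function(dates) format(dates, "%Y-%m")

# all dates of calendar month "YYYY-MM" clipped to [from, to]
month_dates <- function(key, from, to) {
  first <- as.Date(paste0(key, "-01"))
  last <- seq(first, by = "month", length.out = 2)[2] - 1
  seq(max(first, from), min(last, to), by = "day")
}

#' Generate a synthetic Q&A corpus with ground truth
#'
#' See [generator_config()] for the planted structure. Every record carries
#' one designated gold answer whose upvote count strictly exceeds all other
#' answers of the record and whose text expresses the record's true answer
#' sentiment; remaining answers are sentiment-neutral filler.
#'
#' @param config a [generator_config()].
#' @return list with `corpus` (a [qa_corpus()]) and `truth` (tibble with
#'   `record_id`, `true_topic`, `true_question_sentiment`,
#'   `true_answer_sentiment`, `true_month`).
#' @export
generate_corpus <- function(config) {
  validate_generator_config(config)
  cfg <- config
  # tokens survive tokenize() unchanged: lowercase alphanumerics only
  topic_vocab <- lapply(seq_len(cfg$n_topics), function(t)
    sprintf("topic%dword%03d", t, seq_len(cfg$vocab_size_per_topic)))
  shared_vocab <- if (cfg$shared_vocab_size > 0)
    sprintf("sharedword%03d", seq_len(cfg$shared_vocab_size)) else character()

  months <- if (!is.null(cfg$month_pos_rate)) {
    sort(names(cfg$month_pos_rate))
  } else {
    sort(unique(month_key(seq(cfg$date_range[1], cfg$date_range[2], by = "day"))))
  }
  mdates <- lapply(months, month_dates, from = cfg$date_range[1],
                   to = cfg$date_range[2])
  if (any(vapply(mdates, length, integer(1)) == 0))
    stop("month_pos_rate names a month with no dates inside date_range")

  withr::with_seed(cfg$seed, {
    n <- cfg$n_records
    topic <- sample.int(cfg$n_topics, n, replace = TRUE, prob = cfg$topic_weights)
    mi <- sample.int(length(months), n, replace = TRUE)
    q_date <- as.Date(vapply(mi, function(i)
      as.character(sample(as.character(mdates[[i]]), 1)), character(1)))
    q_pos <- stats::runif(n) < cfg$pi_t[topic]
    a_pos <- if (!is.null(cfg$month_pos_rate)) {
      stats::runif(n) < unname(cfg$month_pos_rate[months[mi]])
    } else {
      agree <- stats::runif(n) < cfg$rho
      ifelse(agree, q_pos, !q_pos)
    }

    make_doc <- function(t, sentiment = NULL) {
      len <- sample(seq(cfg$doc_length_range[1], cfg$doc_length_range[2]), 1)
      use_shared <- length(shared_vocab) > 0 &
        stats::runif(len) < cfg$shared_mass
      toks <- character(len)
      n_sh <- sum(use_shared)
      if (n_sh > 0) toks[use_shared] <- sample(shared_vocab, n_sh, replace = TRUE)
      toks[!use_shared] <- sample(topic_vocab[[t]], len - n_sh, replace = TRUE)
      if (!is.null(sentiment) && cfg$injection_rate > 0) {
        lex <- if (sentiment) cfg$pos_lexicon else cfg$neg_lexicon
        inj <- stats::runif(len) < cfg$injection_rate
        if (!any(inj)) inj[sample.int(len, 1)] <- TRUE
        toks[inj] <- sample(lex, sum(inj), replace = TRUE)
      }
      paste(toks, collapse = " ")
    }

    q_text <- character(n)
    answers <- vector("list", n)
    for (i in seq_len(n)) {
      n_ans <- sample(seq(cfg$answers_per_record_range[1],
                          cfg$answers_per_record_range[2]), 1)
      gold <- sample.int(n_ans, 1)
      other_up <- if (n_ans > 1) sample(0:5, n_ans - 1, replace = TRUE) else integer()
      upvotes <- integer(n_ans)
      if (n_ans > 1) upvotes[-gold] <- other_up
      # strict upvote margin so the gold answer is the unique top answer
      upvotes[gold] <- (if (n_ans > 1) max(other_up) else 0L) + sample(1:3, 1)
      texts <- character(n_ans)
      for (j in seq_len(n_ans))
        texts[j] <- if (j == gold) make_doc(topic[i], a_pos[i]) else make_doc(topic[i])
      q_text[i] <- make_doc(topic[i], q_pos[i])
      answers[[i]] <- tibble::new_tibble(list(
        answer_text = texts, upvotes = upvotes,
        answer_timestamp = q_date[i] + sample(0:20, n_ans, replace = TRUE)),
        nrow = n_ans)
    }
    corpus <- qa_corpus(tibble::tibble(
      record_id = sprintf("rec%05d", seq_len(n)), platform = cfg$platform,
      question_text = q_text, question_timestamp = q_date,
      url = NA_character_, answers = answers))
    truth <- tibble::tibble(
      record_id = corpus$record_id, true_topic = topic,
      true_question_sentiment = ifelse(q_pos, "positive", "negative"),
      true_answer_sentiment = ifelse(a_pos, "positive", "negative"),
      true_month = months[mi])
    list(corpus = corpus, truth = truth)
  })
}

#' Number of majority crossovers planted in a generator config
#'
#' Counts the consecutive-month pairs at which the planted answer-positive
#' rate crosses 0.5. A rate of exactly 0.5 carries the previous month's
#' majority sign (a leading 0.5 counts as positive), matching the rule
#' [count_crossovers()] applies to observed shares.
#'
#' @param config a [generator_config()] with `month_pos_rate` defined on at
#'   least two months, or a named/plain numeric vector of monthly rates.
#' @return integer crossover count.
#' @export
planted_crossover_count <- function(config) {
  rates <- if (inherits(config, "generator_config")) {
    if (is.null(config$month_pos_rate))
      stop("config has no month_pos_rate")
    config$month_pos_rate[sort(names(config$month_pos_rate))]
  } else as.numeric(config)
  if (length(rates) < 2)
    stop("need rates for at least 2 consecutive months")
  s <- majority_signs(rates)
  sum(s[-1] != s[-length(s)])
}

# +1 / -1 majority sign per entry; exact 0.5 carries the previous sign,
# a leading 0.5 is treated as positive.
majority_signs <- function(shares) {
  s <- sign(shares - 0.5)
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- if (i == 1) 1 else s[i - 1]
  s
}
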