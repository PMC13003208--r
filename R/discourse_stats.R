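#' Topic proportion table
#'
#' Counts records per merged topic label and reports the percentage of the
#' corpus, integer-rounded (half up) for display; exact fractions are kept
#' in `share`. Rows are sorted by decreasing count (ties by label).
#'
#' @param labels tibble with `record_id` and `label`, one row per record;
#'   an `NA` label is an error.
#' @param label_order optional ordering of labels for the output.
#' @return tibble with `label`, `n`, `share`, `pct` (integer percent).
#' @export
topic_table <- function(labels, label_order = NULL) {
  if (anyNA(labels$label)) stop("every record must be labeled")
  N <- nrow(labels)
  tab <- dplyr::count(labels, .data$label, name = "n")
  if (!is.null(label_order)) {
    missing_lab <- setdiff(label_order, tab$label)
    if (length(missing_lab) > 0)
      tab <- dplyr::bind_rows(tab, tibble::tibble(label = missing_lab, n = 0L))
  }
  tab <- tab[order(-tab$n, tab$label), ]
  tab$share <- tab$n / N
  tab$pct <- round_half_up(100 * tab$share, 0)
  stopifnot(sum(tab$n) == N)
  tab
}

#' Per-topic sentiment proportions
#'
#' Joins answer sentiment labels with topic labels and reports per-topic
#' positive/negative counts, exact shares, and display percentages at two
#' decimals (half-up).
#'
#' @param sentiments tibble with `record_id` and `label` in
#'   `{"positive","negative"}` (e.g. [classify_corpus()] output filtered to
#'   one target).
#' @param topics tibble with `record_id` and `label` (merged topic).
#' @return tibble with `topic`, `n`, `n_pos`, `n_neg`, `pos_share`,
#'   `pct_pos`, `pct_neg`.
#' @export
sentiment_proportions <- function(sentiments, topics) {
  df <- dplyr::inner_join(
    dplyr::select(sentiments, "record_id", sentiment = "label"),
    dplyr::select(topics, "record_id", topic = "label"), by = "record_id")
  out <- dplyr::summarise(dplyr::group_by(df, .data$topic),
                          n = dplyr::n(),
                          n_pos = sum(.data$sentiment == "positive"),
                          n_neg = sum(.data$sentiment == "negative"),
                          .groups = "drop")
  out$pos_share <- out$n_pos / out$n
  out$pct_pos <- round_half_up(100 * out$n_pos / out$n, 2)
  out$pct_neg <- round_half_up(100 * out$n_neg / out$n, 2)
  out[order(-out$n, out$topic), ]
}

#' Question-answer sentiment pair cross-tabulation per topic
#'
#' For each topic, counts the four ordered (question sentiment, answer
#' sentiment) pairs — PP, PN, NP, NN — with percentages of the topic's row
#' total at two decimals (half-up).
#'
#' @param question_sentiments,answer_sentiments tibbles with `record_id`
#'   and `label`; every record must appear in both (a missing label is an
#'   error naming the record).
#' @param topics tibble with `record_id` and `label` (merged topic).
#' @return tibble with `topic`, `n`, counts `pp`, `pn`, `np`, `nn` and
#'   percentages `pct_pp`, `pct_pn`, `pct_np`, `pct_nn`.
#' @export
pair_crosstab <- function(question_sentiments, answer_sentiments, topics) {
  q <- dplyr::select(question_sentiments, "record_id", q = "label")
  a <- dplyr::select(answer_sentiments, "record_id", a = "label")
  missing_q <- setdiff(topics$record_id, q$record_id)
  missing_a <- setdiff(topics$record_id, a$record_id)
  if (length(missing_q) > 0)
    stop("record(s) without a question sentiment label: ",
         paste(head(missing_q, 5), collapse = ", "))
  if (length(missing_a) > 0)
    stop("record(s) without an answer sentiment label: ",
         paste(head(missing_a, 5), collapse = ", "))
  df <- dplyr::inner_join(dplyr::inner_join(q, a, by = "record_id"),
                          dplyr::select(topics, "record_id", topic = "label"),
                          by = "record_id")
  out <- dplyr::summarise(dplyr::group_by(df, .data$topic),
                          n = dplyr::n(),
                          pp = sum(.data$q == "positive" & .data$a == "positive"),
                          pn = sum(.data$q == "positive" & .data$a == "negative"),
                          np = sum(.data$q == "negative" & .data$a == "positive"),
                          nn = sum(.data$q == "negative" & .data$a == "negative"),
                          .groups = "drop")
  for (cell in c("pp", "pn", "np", "nn"))
    out[[paste0("pct_", cell)]] <- round_half_up(100 * out[[cell]] / out$n, 2)
  stopifnot(all(out$pp + out$pn + out$np + out$nn == out$n))
  out[order(-out$n, out$topic), ]
}

#' Consistency of the pair table with the sentiment marginals
#'
#' Checks, per topic, that the pair-table column sums reproduce the answer
#' sentiment counts (`pp + np = n_pos`, `pn + nn = n_neg`) and, when
#' question proportions are supplied, the question marginals
#' (`pp + pn` and `np + nn`). Failures are returned as data, not raised.
#'
#' @param pair_table output of [pair_crosstab()].
#' @param answer_props output of [sentiment_proportions()] for answers.
#' @param question_props optional, the same for questions.
#' @return tibble of per-topic checks with columns `topic`, `check`,
#'   `expected`, `observed`, `pass`; attribute `pass` gives the overall
#'   verdict.
#' @export
marginal_check <- function(pair_table, answer_props, question_props = NULL) {
  rows <- list()
  add <- function(topic, check, expected, observed)
    tibble::tibble(topic = topic, check = check, expected = expected,
                   observed = observed, pass = expected == observed)
  for (i in seq_len(nrow(pair_table))) {
    t <- pair_table$topic[i]
    ai <- match(t, answer_props$topic)
    if (!is.na(ai)) {
      rows[[length(rows) + 1]] <- add(t, "answer_positive",
        answer_props$n_pos[ai], pair_table$pp[i] + pair_table$np[i])
      rows[[length(rows) + 1]] <- add(t, "answer_negative",
        answer_props$n_neg[ai], pair_table$pn[i] + pair_table$nn[i])
    }
    if (!is.null(question_props)) {
      qi <- match(t, question_props$topic)
      if (!is.na(qi)) {
        rows[[length(rows) + 1]] <- add(t, "question_positive",
          question_props$n_pos[qi], pair_table$pp[i] + pair_table$pn[i])
        rows[[length(rows) + 1]] <- add(t, "question_negative",
          question_props$n_neg[qi], pair_table$np[i] + pair_table$nn[i])
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "pass") <- all(out$pass)
  out
}

#' Bin a timestamp into an analysis month
#'
#' Returns the calendar month (`"YYYY-MM"`) of each timestamp, except that
#' a leading partial month covering at most `merge_threshold_days` days of
#' the analysis window is merged into the following month (e.g. a window
#' starting June 27 folds June's four days into July). Timestamps outside
#' the window are an error.
#'
#' @param dates `Date` vector (or ISO strings).
#' @param window_start,window_end analysis window bounds (`Date`).
#' @param merge_threshold_days maximal length of a leading partial month
#'   that gets merged forward (default 7).
#' @return character vector of month keys.
#' @export
month_bin <- function(dates, window_start, window_end, merge_threshold_days = 7) {
  dates <- as.Date(dates)
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  if (any(dates < window_start | dates > window_end, na.rm = TRUE))
    stop("timestamp(s) outside the analysis window")
  key <- month_key(dates)
  first_month <- month_key(window_start)
  next_first <- seq(as.Date(paste0(first_month, "-01")), by = "month",
                    length.out = 2)[2]
  lead_days <- as.integer(next_first - window_start)
  if (lead_days <= merge_threshold_days && window_end >= next_first)
    key[key == first_month] <- month_key(next_first)
  key
}

#' Monthly sentiment series per topic
#'
#' Aggregates answer sentiment labels into contiguous month bins over the
#' analysis window (leading partial month merged per [month_bin()]). For
#' each topic and month, positive/negative counts and the positive share;
#' months with no records carry an `NA` share (skipped by crossover
#' counting, never imputed).
#'
#' @param sentiments tibble with `record_id` and `label`
#'   (positive/negative) for answers.
#' @param topics tibble with `record_id` and `label` (merged topic).
#' @param timestamps tibble with `record_id` and `question_timestamp`
#'   (`Date`), e.g. the corpus columns.
#' @param window_start,window_end analysis window (defaults: observed range).
#' @param merge_threshold_days see [month_bin()].
#' @return tibble with `topic`, `month`, `n_pos`, `n_neg`, `pos_share`,
#'   contiguous in `month` within each topic.
#' @export
monthly_series <- function(sentiments, topics, timestamps,
                           window_start = NULL, window_end = NULL,
                           merge_threshold_days = 7) {
  df <- dplyr::inner_join(
    dplyr::select(sentiments, "record_id", sentiment = "label"),
    dplyr::select(topics, "record_id", topic = "label"), by = "record_id")
  df <- dplyr::inner_join(df,
    dplyr::select(timestamps, "record_id", "question_timestamp"),
    by = "record_id")
  window_start <- as.Date(window_start %||% min(df$question_timestamp))
  window_end <- as.Date(window_end %||% max(df$question_timestamp))
  df$month <- month_bin(df$question_timestamp, window_start, window_end,
                        merge_threshold_days)
  all_months <- sort(unique(month_bin(
    seq(window_start, window_end, by = "day"),
    window_start, window_end, merge_threshold_days)))
  out <- list()
  for (t in sort(unique(df$topic))) {
    sub <- df[df$topic == t, ]
    n_pos <- vapply(all_months, function(m)
      sum(sub$month == m & sub$sentiment == "positive"), integer(1),
      USE.NAMES = FALSE)
    n_neg <- vapply(all_months, function(m)
      sum(sub$month == m & sub$sentiment == "negative"), integer(1),
      USE.NAMES = FALSE)
    tot <- n_pos + n_neg
    out[[t]] <- tibble::tibble(topic = t, month = all_months,
                               n_pos = n_pos, n_neg = n_neg,
                               pos_share = ifelse(tot > 0, n_pos / tot, NA_real_))
  }
  dplyr::bind_rows(out)
}

#' Count positive/negative majority crossovers in a monthly series
#'
#' Each non-null month gets a majority sign from `sign(pos_share - 0.5)`;
#' an exact 0.5 carries the previous month's sign (a leading 0.5 counts as
#' positive). A crossover is a consecutive pair of non-null months with
#' strictly opposite signs. Requires at least two non-null months.
#'
#' @param series one topic's rows of [monthly_series()] (or a numeric
#'   vector of shares in month order; `NA` months are skipped).
#' @return integer crossover count.
#' @export
count_crossovers <- function(series) {
  shares <- if (is.data.frame(series)) series$pos_share else as.numeric(series)
  shares <- shares[!is.na(shares)]
  if (length(shares) < 2)
    stop("need at least 2 non-null months to count crossovers")
  s <- majority_signs(shares)
  sum(s[-1] != s[-length(s)])
}

#' Longest dominance streak of one polarity
#'
#' The longest run of consecutive months in which the polarity's share is
#' strictly above one half (for `"negative"`, the negative share
#' `1 - pos_share`). Null months break runs. Ties go to the earliest run.
#'
#' @param series one topic's rows of [monthly_series()].
#' @param polarity `"positive"` or `"negative"`.
#' @return list with `length` and `start_month` (`NA` if no dominant
#'   month).
#' @export
dominance_streak <- function(series, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  shares <- series$pos_share
  months <- if (!is.null(series$month)) series$month else as.character(seq_along(shares))
  dom <- !is.na(shares) &
    (if (polarity == "positive") shares > 0.5 else shares < 0.5)
  best_len <- 0L; best_start <- NA_character_
  run <- 0L
  for (i in seq_along(dom)) {
    run <- if (dom[i]) run + 1L else 0L
    if (run > best_len) {
      best_len <- run
      best_start <- months[i - run + 1L]
    }
  }
  list(length = best_len, start_month = best_start)
}
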