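lab_tbl <- function(labels) {
  tibble::tibble(record_id = sprintf("r%04d", seq_along(labels)), label = labels)
}

test_that("topic tables count, share and percent with conservation", {
  labels <- lab_tbl(rep(c("A", "B", "C"), c(50, 30, 20)))
  tab <- topic_table(labels)
  expect_equal(sum(tab$n), 100)
  expect_equal(tab$pct, c(50, 30, 20))
  expect_equal(sum(tab$share), 1)

  one <- topic_table(lab_tbl(rep("only", 7)))
  expect_equal(one$pct, 100)
  expect_error(topic_table(lab_tbl(c("A", NA))), "labeled")
})

test_that("sentiment proportions report exact counts and 2-decimal shares", {
  n <- 40
  sent <- lab_tbl(rep(c("positive", "negative"), c(30, 10)))
  topics <- lab_tbl(rep("T", n))
  out <- sentiment_proportions(sent, topics)
  expect_equal(out$n_pos, 30)
  expect_equal(out$pct_pos, 75)
  expect_equal(out$pct_pos + out$pct_neg, 100)

  all_pos <- sentiment_proportions(lab_tbl(rep("positive", 5)),
                                   lab_tbl(rep("T", 5)))
  expect_equal(all_pos$n_neg, 0)
  expect_equal(all_pos$pct_pos, 100)
})

test_that("pair cross-tabulation conserves row totals and names missing records", {
  q <- lab_tbl(c(rep("positive", 6), rep("negative", 4)))
  a <- lab_tbl(c(rep("positive", 3), rep("negative", 3),
                 rep("positive", 2), rep("negative", 2)))
  topics <- lab_tbl(rep("T", 10))
  pt <- pair_crosstab(q, a, topics)
  expect_equal(unlist(pt[, c("pp", "pn", "np", "nn")], use.names = FALSE),
               c(3L, 3L, 2L, 2L))
  expect_equal(pt$pp + pt$pn + pt$np + pt$nn, pt$n)
  expect_equal(pt$pct_pp, 30)

  allpp <- pair_crosstab(lab_tbl(rep("positive", 4)),
                         lab_tbl(rep("positive", 4)), lab_tbl(rep("T", 4)))
  expect_equal(c(allpp$pp, allpp$pn, allpp$np, allpp$nn), c(4L, 0L, 0L, 0L))
  expect_equal(allpp$pct_pp, 100)

  expect_error(pair_crosstab(q[-1, ], a, topics), "question sentiment.*r0001")
})

test_that("marginal check passes on self-generated data and flags discrepancies", {
  set.seed(31)
  n <- 200
  q <- lab_tbl(sample(c("positive", "negative"), n, replace = TRUE))
  a <- lab_tbl(sample(c("positive", "negative"), n, replace = TRUE))
  topics <- lab_tbl(sample(c("T1", "T2", "T3"), n, replace = TRUE))
  pt <- pair_crosstab(q, a, topics)
  pa <- sentiment_proportions(a, topics)
  pq <- sentiment_proportions(q, topics)
  chk <- marginal_check(pt, pa, pq)
  expect_true(attr(chk, "pass"))
  expect_true(all(chk$pass))

  broken <- pa
  broken$n_pos[1] <- broken$n_pos[1] + 1L
  chk2 <- marginal_check(pt, broken, pq)
  expect_false(attr(chk2, "pass"))
  expect_equal(sum(!chk2$pass), 1)
})

test_that("month binning merges a short leading partial month forward", {
  expect_equal(month_bin(as.Date("2020-06-28"), "2020-06-27", "2021-06-27"),
               "2020-07")
  expect_equal(month_bin(as.Date("2020-08-15"), "2020-06-27", "2021-06-27"),
               "2020-08")
  # window starting on the 1st: nothing to merge
  expect_equal(month_bin(as.Date("2020-07-01"), "2020-07-01", "2021-06-27"),
               "2020-07")
  # a long leading partial month stays separate
  expect_equal(month_bin(as.Date("2020-06-15"), "2020-06-10", "2021-06-27"),
               "2020-06")
  expect_error(month_bin(as.Date("2021-07-01"), "2020-06-27", "2021-06-27"),
               "outside")
})

test_that("monthly series are contiguous, null months excluded from crossovers", {
  sent <- lab_tbl(c("positive", "positive", "positive", "negative"))
  topics <- lab_tbl(rep("T", 4))
  ts <- tibble::tibble(record_id = sprintf("r%04d", 1:4),
                       question_timestamp = as.Date(c("2020-08-03", "2020-08-10",
                                                      "2020-08-21", "2020-08-28")))
  out <- monthly_series(sent, topics, ts, "2020-08-01", "2020-10-31")
  expect_equal(out$month, c("2020-08", "2020-09", "2020-10"))
  expect_equal(out$pos_share[1], 0.75)
  expect_true(all(is.na(out$pos_share[2:3])))
  expect_error(count_crossovers(out), "at least 2 non-null")
})

test_that("planted monthly rates are recovered within binomial error", {
  rates <- c("2020-07" = 0.9, "2020-08" = 0.2, "2020-09" = 0.7)
  g <- generate_corpus(generator_config(
    n_records = 600, n_topics = 2, vocab_size_per_topic = 15,
    doc_length_range = c(10, 30), month_pos_rate = rates,
    date_range = c("2020-07-01", "2020-09-30"), seed = 17))
  truth <- g$truth
  sent <- tibble::tibble(record_id = truth$record_id,
                         label = truth$true_answer_sentiment)
  topics <- tibble::tibble(record_id = truth$record_id, label = "all")
  out <- monthly_series(sent, topics,
                        g$corpus[, c("record_id", "question_timestamp")],
                        "2020-07-01", "2020-09-30")
  for (i in seq_len(nrow(out))) {
    n <- out$n_pos[i] + out$n_neg[i]
    r <- rates[out$month[i]]
    expect_lt(abs(out$pos_share[i] - r), 3 * sqrt(r * (1 - r) / n) + 1e-9)
  }
})

test_that("crossover counting applies the 0.5-carry rule and its bounds", {
  expect_equal(count_crossovers(c(0.6, 0.4, 0.6, 0.4)), 3)
  expect_equal(count_crossovers(c(0.7, 0.7, 0.7)), 0)
  expect_equal(count_crossovers(c(0.6, 0.5, 0.4)), 1)
  expect_equal(count_crossovers(c(0.6, NA, 0.4)), 1)  # null month skipped
  expect_error(count_crossovers(c(0.7, NA)), "at least 2 non-null")
  # property: 0 <= crossovers <= non-null months - 1; monotone series <= 1
  set.seed(6)
  for (i in 1:20) {
    shares <- runif(sample(2:12, 1))
    cc <- count_crossovers(shares)
    expect_gte(cc, 0)
    expect_lte(cc, length(shares) - 1)
    expect_lte(count_crossovers(sort(shares)), 1)
  }
})

test_that("dominance streaks find the longest strict-majority run, earliest on ties", {
  s <- tibble::tibble(topic = "T",
                      month = sprintf("2020-%02d", 1:4),
                      pos_share = c(0.6, 0.7, 0.4, 0.8))
  out <- dominance_streak(s, "positive")
  expect_equal(out$length, 2L)
  expect_equal(out$start_month, "2020-01")

  all_pos <- s
  all_pos$pos_share <- c(0.6, 0.7, 0.9, 0.8)
  expect_equal(dominance_streak(all_pos, "positive")$length, 4L)
  expect_equal(dominance_streak(all_pos, "negative")$length, 0L)
  expect_true(is.na(dominance_streak(all_pos, "negative")$start_month))

  # exactly 0.5 is not a strict majority for either polarity
  half <- s
  half$pos_share <- c(0.5, 0.6, 0.5, 0.4)
  expect_equal(dominance_streak(half, "positive")$length, 1L)
  expect_equal(dominance_streak(half, "negative")$length, 1L)

  # ties in run length resolve to the earliest run
  tie <- s
  tie$pos_share <- c(0.6, 0.4, 0.7, 0.3)
  expect_equal(dominance_streak(tie, "positive")$start_month, "2020-01")
})

test_that("a planted 4-month positive block is recovered exactly", {
  rates <- c("2020-07" = 0.3, "2020-08" = 0.9, "2020-09" = 0.9,
             "2020-10" = 0.9, "2020-11" = 0.9, "2020-12" = 0.3)
  g <- generate_corpus(generator_config(
    n_records = 1200, n_topics = 2, vocab_size_per_topic = 15,
    doc_length_range = c(10, 30), month_pos_rate = rates,
    date_range = c("2020-07-01", "2020-12-31"), seed = 29))
  sent <- tibble::tibble(record_id = g$truth$record_id,
                         label = g$truth$true_answer_sentiment)
  topics <- tibble::tibble(record_id = g$truth$record_id, label = "all")
  out <- monthly_series(sent, topics,
                        g$corpus[, c("record_id", "question_timestamp")],
                        "2020-07-01", "2020-12-31")
  streak <- dominance_streak(out, "positive")
  expect_equal(streak$length, 4L)
  expect_equal(streak$start_month, "2020-08")
})
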