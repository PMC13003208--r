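test_that("K = 1 degenerates to smoothed corpus frequencies and unit theta", {
  docs <- list(d1 = c("a", "b", "a"), d2 = c("b", "c"))
  m <- fit_lda(docs, K = 1, n_iter = 5, seed = 1)
  expect_equal(dim(m$theta), c(2L, 1L))
  expect_equal(unname(m$theta[, 1]), c(1, 1))
  counts <- c(a = 2, b = 2, c = 1)
  expected_phi <- (counts + m$beta) / (sum(counts) + 3 * m$beta)
  expect_equal(m$phi[1, ], expected_phi)
})

test_that("disjoint-vocabulary topics separate and runs are seed-deterministic", {
  vocab_a <- sprintf("alpha%02d", 1:10)
  vocab_b <- sprintf("beta%02d", 1:10)
  set.seed(3)
  docs <- c(
    lapply(1:10, function(i) sample(vocab_a, 50, replace = TRUE)),
    lapply(1:10, function(i) sample(vocab_b, 50, replace = TRUE)))
  names(docs) <- sprintf("d%02d", 1:20)
  m <- fit_lda(docs, K = 2, n_iter = 200, seed = 5)
  expect_prob_rows(m$phi)
  expect_prob_rows(m$theta)
  # each topic's keywords come from exactly one planted vocabulary
  for (k in 1:2) {
    kw <- m$keywords[[k]]
    expect_true(all(kw %in% vocab_a) || all(kw %in% vocab_b))
  }
  expect_true(!setequal(m$keywords[[1]], m$keywords[[2]]))
  # argmax(theta) recovers the split up to label permutation
  lab <- apply(m$theta, 1, which.max)
  expect_true(length(unique(lab[1:10])) == 1 && length(unique(lab[11:20])) == 1
              && lab[1] != lab[20])
  # determinism
  m2 <- fit_lda(docs, K = 2, n_iter = 200, seed = 5)
  expect_identical(m$phi, m2$phi)
  expect_identical(m$theta, m2$theta)
})

test_that("empty documents are excluded with a warning, not a crash", {
  docs <- list(good = c("a", "b"), bad = character(), ok = c("b", "c"))
  expect_warning(m <- fit_lda(docs, K = 1, n_iter = 5, seed = 1), "bad")
  expect_equal(m$doc_ids, c("good", "ok"))
  expect_equal(m$excluded, "bad")
})

test_that("UMass coherence matches hand-counted co-document frequencies", {
  # oracle: count document frequencies directly
  docs <- list(c("a", "b", "x"), c("b", "a"), c("c", "x"))
  # D(b) = 2, D(a, b) = 2 -> pair (a, b): log((2 + 1) / 2)
  expect_equal(coherence_score(c("a", "b"), docs), log(3 / 2))

  # keywords that never co-occur, D(w_j) = 5 -> log(1 / 5)
  docs2 <- c(replicate(5, c("b", "filler"), simplify = FALSE), list("a"))
  expect_equal(coherence_score(c("a", "b"), docs2), log(1 / 5))

  # three keywords: independent pairwise enumeration oracle
  docs3 <- list(c("a", "b", "c"), c("a", "c"), c("b", "c"), c("a"))
  kw <- c("c", "a", "b")
  oracle <- 0
  for (j in 2:3) for (i in 1:(j - 1)) {
    dj <- sum(vapply(docs3, function(d) kw[j] %in% d, logical(1)))
    co <- sum(vapply(docs3, function(d) kw[i] %in% d && kw[j] %in% d, logical(1)))
    oracle <- oracle + log((co + 1) / dj)
  }
  expect_equal(coherence_score(kw, docs3), oracle)
  # determinism and the keyword-absent floor
  expect_equal(coherence_score(kw, docs3), coherence_score(kw, docs3))
  expect_warning(s <- coherence_score(c("a", "zzz"), docs3), "zzz")
  expect_equal(s, log(1 / 4))
})

test_that("select_k returns the argmax with ties to the smallest K", {
  docs <- replicate(8, c("a", "b", "a", "b"), simplify = FALSE)
  # singleton candidate list
  expect_equal(select_k(docs, 2, n_iter = 20, seed = 1, M = 2)$K, 2L)
  # both tokens co-occur in every document, so every topic's 2-keyword list
  # scores identically for any K: the tie must resolve to the smallest K
  sel <- select_k(docs, c(4, 2), n_iter = 20, seed = 1, M = 2)
  expect_equal(length(unique(sel$table$mean_coherence)), 1)
  expect_equal(sel$K, 2L)
  expect_named(sel$table, c("K", "mean_coherence"))
  expect_equal(nrow(sel$table), 2)
})

test_that("keyword extraction ranks by phi with lexicographic ties", {
  model <- list(K = 2L,
                phi = rbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.3, 0.3, 0.3)),
                vocab = c("x", "c", "a", "b"))
  colnames(model$phi) <- model$vocab
  expect_equal(extract_keywords(model, 1)[[1]], "x")
  # ties among equal-phi tokens resolve lexicographically
  expect_equal(extract_keywords(model, 3)[[2]], c("a", "b", "c"))
  # M = V gives a full permutation of the vocabulary
  expect_setequal(extract_keywords(model, 4)[[1]], model$vocab)
  expect_error(extract_keywords(model, 5), "M must lie")
})

test_that("merged labels take the maximal summed theta mass with label-order ties", {
  model <- list(K = 2L, theta = rbind(c(0.6, 0.4)), doc_ids = "d1",
                keywords = list(c("k1"), c("k2")))
  mm <- merge_map(c("A", "B"))
  expect_equal(merge_topics(model, mm)$labels$label, "A")

  model3 <- list(K = 3L, theta = rbind(c(0.3, 0.3, 0.4)), doc_ids = "d1",
                 keywords = list("k1", "k2", "k3"))
  mm3 <- merge_map(c("A", "A", "B"))
  out <- merge_topics(model3, mm3)
  expect_equal(out$labels$label, "A")  # 0.6 summed beats 0.4
  expect_equal(out$labels$mass, 0.6)
  expect_setequal(out$keyword_pools$A, c("k1", "k2"))

  # both raw topics on one label: every document gets it
  mm_one <- merge_map(c("A", "A"))
  expect_equal(merge_topics(model, mm_one)$labels$label, "A")

  # exact tie resolves by label order
  model_tie <- list(K = 2L, theta = rbind(c(0.5, 0.5)), doc_ids = "d1",
                    keywords = list("k1", "k2"))
  expect_equal(merge_topics(model_tie, merge_map(c("B", "A"),
                                                 labels = c("B", "A")))$labels$label, "B")

  expect_error(merge_topics(model3, mm), "total on raw topics 1..3")
})

test_that("relabeling raw topics with a consistent permutation leaves merged labels unchanged", {
  g <- generate_corpus(tiny_gen_config())
  docs <- tokenize(g$corpus$question_text)
  names(docs) <- g$corpus$record_id
  m <- fit_lda(docs, 4, n_iter = 100, seed = 9)
  mm <- merge_map(c("A", "A", "B", "B"))
  base <- merge_topics(m, mm)$labels

  perm <- c(3L, 1L, 4L, 2L)
  m_perm <- m
  m_perm$theta <- m$theta[, perm]
  m_perm$phi <- m$phi[perm, ]
  m_perm$keywords <- m$keywords[perm]
  mm_perm <- merge_map(mm$mapping[perm], labels = mm$labels)
  expect_identical(merge_topics(m_perm, mm_perm)$labels, base)
})
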