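#' Fit LDA by collapsed Gibbs sampling
#'
#' Standard Latent Dirichlet Allocation with symmetric Dirichlet priors,
#' estimated by collapsed Gibbs sampling. Topic-word (`phi`, K x V) and
#' document-topic (`theta`, D x K) distributions are computed from the
#' final sampler state with Dirichlet smoothing, so every row sums to one.
#' Documents that are empty after tokenization are excluded with a warning
#' and appear in `excluded`.
#'
#' @param docs list of token character vectors (or a character vector of
#'   raw documents, which is passed through [tokenize()]).
#' @param K number of topics.
#' @param alpha document-topic concentration; default `50 / K`.
#' @param beta topic-word concentration; default 0.01.
#' @param n_iter number of Gibbs sweeps (default 1000).
#' @param seed integer seed; the sampler uses its own generator, so results
#'   are reproducible regardless of R's RNG state.
#' @param n_starts number of independent restarts (chain seeds derived from
#'   `seed`); the final state with the highest collapsed joint log
#'   probability is kept. Collapsed Gibbs chains can trap in modes where
#'   two true topics merge, so a handful of restarts makes the fit robust;
#'   1 disables restarting.
#' @param M number of keywords extracted per topic (default 10).
#' @param keep_samples if `TRUE`, also return the per-sweep token
#'   assignment trace after `burnin` sweeps (for diagnostics on small
#'   problems).
#' @param burnin sweeps discarded from the trace when `keep_samples`.
#' @return a `topic_model` list: `K`, `phi`, `theta`, `alpha`, `beta`,
#'   `vocab`, `keywords` (per-topic ranked token lists), `doc_ids`,
#'   `excluded`, `seed`, and optionally `samples`.
#' @export
fit_lda <- function(docs, K, alpha = NULL, beta = 0.01, n_iter = 1000,
                    seed = 1L, n_starts = 3, M = 10, keep_samples = FALSE,
                    burnin = 0L) {
  if (K < 1) stop("K must be at least 1")
  if (is.character(docs)) docs <- tokenize(docs)
  ids <- names(docs) %||% as.character(seq_along(docs))
  lens <- lengths(docs)
  excluded <- ids[lens == 0]
  if (length(excluded) > 0) {
    warning(length(excluded), " document(s) empty after tokenization excluded: ",
            paste(head(excluded, 5), collapse = ", "))
    docs <- docs[lens > 0]
    ids <- ids[lens > 0]
  }
  if (length(docs) == 0) stop("no non-empty documents to fit")
  alpha <- alpha %||% (50 / K)
  vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  docs_int <- lapply(docs, function(x) match(x, vocab) - 1L)
  if (keep_samples) n_starts <- 1  # a trace only makes sense for one chain
  fit <- NULL
  best_seed <- as.integer(seed)
  for (r in seq_len(max(1, n_starts))) {
    chain_seed <- derive_seed(seed, r - 1L)
    cand <- lda_gibbs_cpp(docs_int, length(vocab), as.integer(K), alpha, beta,
                          as.integer(n_iter), as.integer(burnin),
                          chain_seed, keep_samples)
    if (is.null(fit) || cand$log_posterior > fit$log_posterior) {
      fit <- cand
      best_seed <- chain_seed
    }
  }
  phi <- fit$phi
  colnames(phi) <- vocab
  theta <- fit$theta
  rownames(theta) <- ids
  model <- list(K = as.integer(K), phi = phi, theta = theta, alpha = alpha,
                beta = beta, vocab = vocab, doc_ids = ids,
                excluded = excluded, seed = as.integer(seed),
                chain_seed = best_seed, log_posterior = fit$log_posterior,
                n_iter = as.integer(n_iter))
  model$keywords <- extract_keywords(model, min(M, length(vocab)))
  if (keep_samples) model$samples <- fit$samples
  class(model) <- "topic_model"
  model
}

#' @export
print.topic_model <- function(x, ...) {
  cat("LDA topic model: K =", x$K, ", V =", length(x$vocab),
      ", D =", nrow(x$theta), "\n")
  for (k in seq_len(x$K))
    cat(sprintf("  topic %d: %s\n", k,
                paste(head(x$keywords[[k]], 8), collapse = " ")))
  invisible(x)
}

#' Top keywords per topic
#'
#' Ranks each topic's tokens by topic-word probability; ties are broken by
#' lexicographic token order so the ranking is deterministic.
#'
#' @param model a `topic_model` from [fit_lda()].
#' @param M keywords per topic, between 1 and the vocabulary size.
#' @return list of `K` ranked character vectors.
#' @export
extract_keywords <- function(model, M = 10) {
  V <- length(model$vocab)
  if (M < 1 || M > V) stop("M must lie in [1, vocabulary size]")
  lapply(seq_len(model$K), function(k) {
    ord <- order(-model$phi[k, ], model$vocab)
    model$vocab[ord[seq_len(M)]]
  })
}

#' UMass topic coherence
#'
#' For ranked keywords w_1..w_M, sums `log((D(w_i, w_j) + 1) / D(w_j))`
#' over ordered pairs i < j, where D counts documents containing a word or
#' word pair. Higher (closer to zero) is more coherent. A keyword absent
#' from every document contributes the smoothed floor `log(1 / n_docs)`
#' for each of its pairs, with a warning.
#'
#' @param topic_keywords character vector of at least two ranked keywords.
#' @param docs list of token vectors (or character vector of documents).
#' @return the coherence score (a non-positive number).
#' @export
coherence_score <- function(topic_keywords, docs) {
  if (length(topic_keywords) < 2) stop("need at least 2 keywords")
  if (is.character(docs)) docs <- tokenize(docs)
  if (length(docs) == 0) stop("docs must be non-empty")
  n_docs <- length(docs)
  present <- lapply(topic_keywords, function(w)
    vapply(docs, function(d) w %in% d, logical(1)))
  df <- vapply(present, sum, numeric(1))
  if (any(df == 0))
    warning("keyword(s) absent from all documents: ",
            paste(topic_keywords[df == 0], collapse = ", "))
  score <- 0
  M <- length(topic_keywords)
  for (j in 2:M) {
    for (i in 1:(j - 1)) {
      if (df[j] == 0) {
        score <- score + log(1 / n_docs)
      } else {
        co <- sum(present[[i]] & present[[j]])
        score <- score + log((co + 1) / df[j])
      }
    }
  }
  score
}

#' Choose the number of topics by mean coherence
#'
#' Fits one model per candidate K, scores the mean UMass coherence of the
#' topics' top-`M` keyword lists, and returns the K with the highest mean
#' coherence (ties go to the smallest K). The per-K table is returned for
#' inspection; no claim is made that the planted K always wins.
#'
#' @param docs list of token vectors or character vector of documents.
#' @param candidate_Ks non-empty integer vector of K values to try.
#' @param M keywords per topic used in scoring.
#' @param seed integer seed (each K is fitted with the same seed).
#' @inheritParams fit_lda
#' @return list with `K` (chosen), `table` (tibble of K, mean_coherence)
#'   and `models` (the fitted models, named by K).
#' @export
select_k <- function(docs, candidate_Ks, alpha = NULL, beta = 0.01,
                     n_iter = 200, seed = 1L, n_starts = 1, M = 10) {
  if (length(candidate_Ks) == 0) stop("candidate_Ks must be non-empty")
  if (is.character(docs)) docs <- tokenize(docs)
  models <- lapply(candidate_Ks, function(K)
    fit_lda(docs, K, alpha = alpha, beta = beta, n_iter = n_iter,
            seed = seed, n_starts = n_starts,
            M = min(M, length(unique(unlist(docs))))))
  names(models) <- as.character(candidate_Ks)
  mean_coh <- vapply(models, function(m)
    mean(vapply(m$keywords, coherence_score, numeric(1), docs = docs)),
    numeric(1))
  tab <- tibble::tibble(K = as.integer(candidate_Ks), mean_coherence = unname(mean_coh))
  ord <- order(-tab$mean_coherence, tab$K)
  list(K = tab$K[ord[1]], table = tab, models = models)
}

#' Merge map from raw topics to display labels
#'
#' Encodes the human-curated grouping of raw LDA topics into a small set of
#' interpretable labels. `mapping` must cover every raw topic `1..K`
#' exactly once; `labels` fixes the display order used for deterministic
#' tie-breaking.
#'
#' @param mapping character vector of length K: `mapping[k]` is the merged
#'   label of raw topic k.
#' @param labels optional ordered label names (default: order of first
#'   appearance in `mapping`).
#' @return a `merge_map` list with elements `mapping` and `labels`.
#' @export
merge_map <- function(mapping, labels = NULL) {
  mapping <- as.character(mapping)
  labels <- labels %||% unique(mapping)
  if (!all(mapping %in% labels))
    stop("mapping uses label(s) not in labels: ",
         paste(setdiff(mapping, labels), collapse = ", "))
  if (!all(labels %in% mapping))
    stop("label(s) with no raw topic: ", paste(setdiff(labels, mapping), collapse = ", "))
  structure(list(mapping = mapping, labels = labels), class = "merge_map")
}

#' Read a merge map from a YAML or JSON config file
#'
#' The file holds `mapping` (raw topic index, 1-based, to label; either a
#' list keyed by index or an ordered array) and optionally `labels` (display
#' order).
#'
#' @param path config file path (`.yaml`, `.yml` or `.json`).
#' @return a [merge_map()].
#' @export
read_merge_map <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  m <- obj$mapping
  if (is.list(m) && !is.null(names(m))) {
    idx <- as.integer(names(m))
    if (anyNA(idx) || !setequal(idx, seq_along(m)))
      stop("merge map mapping must cover raw topics 1..K; missing: ",
           paste(setdiff(seq_along(m), idx), collapse = ", "))
    m <- unlist(m)[order(idx)]
  }
  merge_map(as.character(m), labels = obj$labels)
}

#' Merge raw topics into configured labels
#'
#' Each document receives the merged label whose member raw topics carry
#' the maximal summed document-topic mass (ties broken by the merge map's
#' label order). Keyword pools are the union of member topics' ranked
#' keyword lists, deduplicated in rank order.
#'
#' @param model a `topic_model`.
#' @param mm a [merge_map()] total on `1..K`.
#' @return list with `labels` (tibble `record_id`, `label`, `mass`) and
#'   `keyword_pools` (named list of character vectors).
#' @export
merge_topics <- function(model, mm) {
  if (length(mm$mapping) != model$K)
    stop("merge map must be total on raw topics 1..", model$K,
         "; it has length ", length(mm$mapping))
  mass <- sapply(mm$labels, function(lab)
    rowSums(model$theta[, mm$mapping == lab, drop = FALSE]))
  if (is.null(dim(mass))) mass <- matrix(mass, nrow = 1, dimnames = list(NULL, mm$labels))
  best <- apply(mass, 1, which.max)  # which.max takes the first (= label order) on ties
  labels <- tibble::tibble(record_id = model$doc_ids,
                           label = mm$labels[best],
                           mass = mass[cbind(seq_len(nrow(mass)), best)])
  pools <- lapply(mm$labels, function(lab) {
    member <- which(mm$mapping == lab)
    ranks <- do.call(rbind, lapply(member, function(k)
      data.frame(tok = model$keywords[[k]], rank = seq_along(model$keywords[[k]]))))
    ranks <- ranks[order(ranks$rank, ranks$tok), ]
    unique(ranks$tok)
  })
  names(pools) <- mm$labels
  list(labels = labels, keyword_pools = pools)
}
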