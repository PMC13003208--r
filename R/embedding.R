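#' Build a shared word/document embedding space
#'
#' Deterministic reference construction: a symmetric windowed word-word
#' co-occurrence matrix is transformed to positive pointwise mutual
#' information (PPMI) and factored by truncated SVD. Word vectors are the
#' left singular vectors scaled by the singular values; a document vector
#' is the length-normalized mean of its tokens' word vectors, so words and
#' documents live in one space and are comparable by cosine similarity.
#' Each singular vector's sign is fixed (largest-magnitude component made
#' positive) so outputs are bit-stable.
#'
#' @param docs named list of token vectors (names become document ids) or
#'   a character vector of raw documents.
#' @param d embedding dimension (>= 2; the corpus must have at least `d`
#'   distinct tokens).
#' @param window symmetric co-occurrence window (default 5 tokens each
#'   side).
#' @return an `embedding_space` list: `word_vectors` (V x d, rownames are
#'   tokens), `doc_vectors` (D x d, rownames are doc ids), `d`, `window`.
#'   Tokens with no co-occurrences get zero vectors (with a message), as do
#'   documents none of whose tokens have vectors.
#' @export
build_embedding <- function(docs, d = 50, window = 5) {
  if (d < 2) stop("embedding dimension d must be at least 2")
  if (is.character(docs)) docs <- tokenize(docs)
  ids <- names(docs) %||% as.character(seq_along(docs))
  vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  V <- length(vocab)
  if (V < d) stop("corpus has ", V, " distinct tokens; need at least d = ", d)

  flat <- lapply(docs, function(doc) {
    n <- length(doc)
    if (n < 2) return(integer())
    idx <- match(doc, vocab)
    unlist(lapply(seq_len(min(window, n - 1)), function(o) {
      i <- idx[1:(n - o)]
      j <- idx[(1 + o):n]
      # both directions of each within-window pair
      c((j - 1L) * V + i, (i - 1L) * V + j)
    }), use.names = FALSE)
  })
  C <- matrix(tabulate(unlist(flat, use.names = FALSE), nbins = V * V),
              V, V, dimnames = list(vocab, vocab))
  total <- sum(C)
  if (total == 0) stop("no co-occurrences in corpus; cannot build embedding")
  rs <- rowSums(C)
  iso <- rs == 0
  if (any(iso))
    message(sum(iso), " token(s) with no co-occurrences get zero vectors: ",
            paste(head(vocab[iso], 5), collapse = ", "))
  P <- C * total
  P <- P / outer(pmax(rs, 1), pmax(rs, 1))
  ppmi <- matrix(0, V, V, dimnames = dimnames(C))
  pos <- C > 0
  ppmi[pos] <- pmax(0, log(P[pos]))

  sv <- svd(ppmi, nu = d, nv = 0)
  U <- sv$u
  for (j in seq_len(d)) {
    if (U[which.max(abs(U[, j])), j] < 0) U[, j] <- -U[, j]
  }
  W <- U %*% diag(sv$d[seq_len(d)], d)
  rownames(W) <- vocab
  W[iso, ] <- 0

  doc_vecs <- t(vapply(docs, function(toks) {
    v <- colMeans(W[match(toks, vocab), , drop = FALSE])
    nv <- sqrt(sum(v^2))
    if (nv > 0) v / nv else v
  }, numeric(d)))
  rownames(doc_vecs) <- ids
  structure(list(word_vectors = W, doc_vectors = doc_vecs,
                 d = as.integer(d), window = as.integer(window)),
            class = "embedding_space")
}

#' Centroid topic vector of a set of documents
#'
#' The topic vector of a merged topic is the arithmetic mean of the
#' embedding vectors of the documents assigned to it. An all-zero centroid
#' is flagged degenerate (attribute `degenerate`); cosine operations
#' against a degenerate centroid refuse to run.
#'
#' @param doc_vectors matrix of member document vectors (rows).
#' @return the centroid vector with attribute `degenerate`.
#' @export
topic_vector <- function(doc_vectors) {
  if (is.null(dim(doc_vectors))) doc_vectors <- matrix(doc_vectors, nrow = 1)
  if (nrow(doc_vectors) == 0)
    stop("a merged topic with no member documents is a configuration failure")
  v <- colMeans(doc_vectors)
  attr(v, "degenerate") <- all(abs(v) < 1e-12)
  v
}

#' Topic vectors for every merged label
#'
#' @param space an `embedding_space` from [build_embedding()].
#' @param labels tibble with `record_id` and `label` (merged label per
#'   document, e.g. from [merge_topics()]); `record_id`s must match the
#'   space's document ids.
#' @param label_order optional label ordering for the output rows.
#' @return matrix (one row per label) with attribute `degenerate` (logical
#'   per label).
#' @export
topic_vectors <- function(space, labels, label_order = NULL) {
  label_order <- label_order %||% unique(labels$label)
  rows <- lapply(label_order, function(lab) {
    ids <- labels$record_id[labels$label == lab]
    topic_vector(space$doc_vectors[rownames(space$doc_vectors) %in% ids, , drop = FALSE])
  })
  m <- do.call(rbind, rows)
  rownames(m) <- label_order
  attr(m, "degenerate") <- vapply(rows, attr, logical(1), "degenerate")
  m
}

#' Keywords semantically closest to a topic vector
#'
#' Ranks a candidate keyword pool (typically the merged topic's LDA
#' keyword pool, which acts as a coarse topical filter) by cosine
#' similarity to the topic centroid and returns the top `J`. Ties are
#' broken lexicographically; candidates without a word vector are skipped
#' with a warning.
#'
#' @param tvec topic centroid from [topic_vector()].
#' @param candidates character vector of candidate keywords (non-empty).
#' @param word_vectors word vector matrix (rownames are tokens).
#' @param J number of keywords to return.
#' @return tibble with `token` and `similarity`, at most `J` rows.
#' @export
characterize_topic <- function(tvec, candidates, word_vectors, J = 10) {
  if (length(candidates) == 0) stop("candidate keyword pool is empty")
  if (isTRUE(attr(tvec, "degenerate")))
    stop("topic vector is degenerate (zero); cannot rank by cosine")
  known <- candidates %in% rownames(word_vectors)
  if (any(!known))
    warning("candidate(s) without a word vector skipped: ",
            paste(candidates[!known], collapse = ", "))
  cand <- candidates[known]
  sims <- cosine_to_rows(as.numeric(tvec),
                         word_vectors[cand, , drop = FALSE])
  keep <- !is.na(sims)
  cand <- cand[keep]; sims <- sims[keep]
  ord <- order(-sims, cand)
  n <- min(J, length(cand))
  tibble::tibble(token = cand[ord[seq_len(n)]],
                 similarity = sims[ord[seq_len(n)]])
}

#' Assign documents to the nearest topic vector
#'
#' Optional refinement pass: each document gets the merged label whose
#' centroid has maximal cosine similarity to its document vector (ties go
#' to the earlier label in row order). Documents with degenerate (zero)
#' vectors are assigned the most frequent label among the non-degenerate
#' assignments, with a message. Degenerate topic centroids are excluded
#' with a warning.
#'
#' @param doc_vectors D x d matrix (rownames are record ids).
#' @param tvecs label-by-dimension matrix from [topic_vectors()].
#' @return tibble with `record_id`, `label`, `similarity`.
#' @export
assign_documents <- function(doc_vectors, tvecs) {
  degen <- attr(tvecs, "degenerate") %||% rep(FALSE, nrow(tvecs))
  if (any(degen)) {
    warning("degenerate topic vector(s) excluded from assignment: ",
            paste(rownames(tvecs)[degen], collapse = ", "))
    tvecs <- tvecs[!degen, , drop = FALSE]
  }
  if (nrow(tvecs) == 0) stop("no non-degenerate topic vectors to assign against")
  labs <- rownames(tvecs)
  sims <- matrix(NA_real_, nrow(doc_vectors), nrow(tvecs))
  for (i in seq_len(nrow(doc_vectors)))
    sims[i, ] <- cosine_to_rows(doc_vectors[i, ], tvecs)
  bad <- apply(sims, 1, function(s) all(is.na(s)))
  best <- integer(nrow(doc_vectors))
  best[!bad] <- apply(sims[!bad, , drop = FALSE], 1, which.max)
  out <- tibble::tibble(record_id = rownames(doc_vectors),
                        label = NA_character_, similarity = NA_real_)
  out$label[!bad] <- labs[best[!bad]]
  out$similarity[!bad] <- sims[cbind(which(!bad), best[!bad])]
  if (any(bad)) {
    if (all(bad)) stop("every document vector is degenerate")
    fallback <- names(which.max(table(out$label[!bad])))
    message(sum(bad), " degenerate document vector(s) assigned the most ",
            "frequent label '", fallback, "'")
    out$label[bad] <- fallback
  }
  out
}
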