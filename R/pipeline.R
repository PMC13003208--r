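#' Resolved run configuration
#'
#' Collects every tunable of the end-to-end pipeline with recorded
#' defaults. The resolved configuration is serialized alongside the
#' outputs of every run so results are fully auditable. Exactly one of
#' `input` (a corpus file) or `generator` (a [generator_config()]) feeds
#' the run; with neither, a default synthetic corpus is generated.
#'
#' @param input optional path to a JSONL/CSV corpus.
#' @param format corpus file format for [read_corpus()].
#' @param generator optional [generator_config()] for synthetic input.
#' @param keyword_forms optional keyword filter substrings (`NULL` skips
#'   the filter); `search_answers` controls whether answers are searched.
#' @param search_answers see [filter_by_keyword()].
#' @param sample_n optional subsample size ([sample_match()]).
#' @param stopwords optional stop list for [tokenize()].
#' @param lda list of LDA settings: exactly one of `K` or `candidate_Ks`,
#'   plus `alpha` (default 50/K), `beta`, `n_iter`, `M` keywords per topic.
#' @param merge_map a [merge_map()], a path to a YAML/JSON merge map, or
#'   `NULL` for the identity merge (one label per raw topic; only valid
#'   with a fixed `K`). Required when `candidate_Ks` is given.
#' @param embedding_dim,window embedding settings ([build_embedding()]).
#' @param refine if `TRUE`, document labels are re-assigned by cosine to
#'   the topic centroids ([assign_documents()]); default keeps the merged
#'   LDA labels.
#' @param pos_lexicon,neg_lexicon polarity lexica (token vectors or paths
#'   to one-token-per-line files) for the reference scorers; defaults
#'   follow [generator_config()] so synthetic runs are self-contained.
#' @param scorer_smoothings smoothing constants, one lexicon scorer per
#'   entry (two members give the two-model bagging setup).
#' @param chunk_size,weight_by_length see [score_document()].
#' @param window_start,window_end,merge_threshold_days temporal analysis
#'   settings ([monthly_series()]); window defaults to the observed range.
#' @param out_dir output directory.
#' @param seed global integer seed; stage seeds are derived from it.
#' @return a validated `run_config` list.
#' @export
run_config <- function(input = NULL, format = "auto", generator = NULL,
                       keyword_forms = NULL, search_answers = TRUE,
                       sample_n = NULL, stopwords = NULL,
                       lda = list(), merge_map = NULL,
                       embedding_dim = 25, window = 5, refine = FALSE,
                       pos_lexicon = NULL, neg_lexicon = NULL,
                       scorer_smoothings = c(1, 2),
                       chunk_size = 128, weight_by_length = FALSE,
                       window_start = NULL, window_end = NULL,
                       merge_threshold_days = 7,
                       out_dir = "qadiscourse_run", seed = 1L) {
  lda <- utils::modifyList(list(K = NULL, candidate_Ks = NULL, alpha = NULL,
                                beta = 0.01, n_iter = 1000, n_starts = 3,
                                M = 10), lda)
  cfg <- list(input = input, format = format, generator = generator,
              keyword_forms = keyword_forms, search_answers = search_answers,
              sample_n = sample_n, stopwords = stopwords, lda = lda,
              merge_map = merge_map, embedding_dim = embedding_dim,
              window = window, refine = refine,
              pos_lexicon = pos_lexicon, neg_lexicon = neg_lexicon,
              scorer_smoothings = scorer_smoothings, chunk_size = chunk_size,
              weight_by_length = weight_by_length,
              window_start = window_start, window_end = window_end,
              merge_threshold_days = merge_threshold_days,
              out_dir = out_dir, seed = as.integer(seed))
  if (is.null(cfg$input) && is.null(cfg$generator))
    cfg$generator <- generator_config(seed = derive_seed(cfg$seed, 11L))
  if (!is.null(cfg$input) && !is.null(cfg$generator))
    stop("config error: give either input or generator, not both")
  if (is.null(cfg$lda$K) && is.null(cfg$lda$candidate_Ks)) {
    cfg$lda$K <- if (!is.null(cfg$generator)) cfg$generator$n_topics else
      stop("config error: lda$K or lda$candidate_Ks required with file input")
  }
  if (!is.null(cfg$lda$candidate_Ks) && is.null(cfg$merge_map))
    stop("config error: merge_map is required when lda$candidate_Ks is given ",
         "(the chosen K is not known in advance)")
  if (is.null(cfg$pos_lexicon))
    cfg$pos_lexicon <- if (!is.null(cfg$generator)) cfg$generator$pos_lexicon
      else stop("config error: pos_lexicon required with file input")
  if (is.null(cfg$neg_lexicon))
    cfg$neg_lexicon <- if (!is.null(cfg$generator)) cfg$generator$neg_lexicon
      else stop("config error: neg_lexicon required with file input")
  if (is.character(cfg$pos_lexicon) && length(cfg$pos_lexicon) == 1 &&
      file.exists(cfg$pos_lexicon)) cfg$pos_lexicon <- read_lexicon(cfg$pos_lexicon)
  if (is.character(cfg$neg_lexicon) && length(cfg$neg_lexicon) == 1 &&
      file.exists(cfg$neg_lexicon)) cfg$neg_lexicon <- read_lexicon(cfg$neg_lexicon)
  if (is.character(cfg$merge_map)) cfg$merge_map <- read_merge_map(cfg$merge_map)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML or JSON
#'
#' The file holds the [run_config()] arguments by name; a `generator` entry
#' is passed through [generator_config()]. Command-line overrides (e.g. a
#' global seed) can be supplied via `...`.
#'
#' @param path config file (`.yaml`, `.yml` or `.json`).
#' @param ... overrides merged over the file's values.
#' @return a [run_config()].
#' @export
run_config_from_file <- function(path, ...) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE) else yaml::read_yaml(path)
  obj <- utils::modifyList(obj, list(...))
  if (!is.null(obj$generator)) obj$generator <- do.call(generator_config, obj$generator)
  do.call(run_config, obj)
}

stage_path <- function(out_dir, file) file.path(out_dir, file)

require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing upstream artifact '", path, "'; run the ", producer,
         " stage first")
  path
}

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

#' Pipeline stages
#'
#' Each stage runs one module over the artifacts of the previous stages in
#' `out_dir`, so chained stages are byte-for-byte equivalent to
#' [run_pipeline()]. `stage_generate` writes `corpus.jsonl`,
#' `ground_truth.csv` and `generator_config.json`; `stage_ingest` reads the
#' input corpus (or the generated one), applies the preprocessing funnel
#' and writes `corpus_filtered.jsonl` plus `filter_report.json`;
#' `stage_topics` writes `topic_labels.csv`, `topic_keywords.csv` and
#' (when selecting K) `coherence.csv`; `stage_sentiment` writes
#' `sentiment.csv`; `stage_pairs` writes `topic_table.csv`,
#' `sentiment_proportions.csv`, `pair_table.csv` and `marginal_check.csv`;
#' `stage_temporal` writes `monthly_series.csv` and `stats.json`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (defaults to `config$out_dir`).
#' @return each stage invisibly returns its main in-memory result.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_generate <- function(config, out_dir = config$out_dir) {
  if (is.null(config$generator)) stop("config has no generator")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_corpus(config$generator)
  write_corpus(gen$corpus, stage_path(out_dir, "corpus.jsonl"))
  utils::write.csv(gen$truth, stage_path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  gcfg <- config$generator
  gcfg$date_range <- format(gcfg$date_range, "%Y-%m-%d")
  write_json_stable(unclass(gcfg), stage_path(out_dir, "generator_config.json"))
  invisible(gen)
}

#' @rdname pipeline_stages
#' @export
stage_ingest <- function(config, out_dir = config$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- if (!is.null(config$input)) {
    read_corpus(config$input, config$format)
  } else {
    read_corpus(require_artifact(stage_path(out_dir, "corpus.jsonl"), "generate"))
  }
  pre <- preprocess_corpus(corpus, keyword_forms = config$keyword_forms,
                           search_answers = config$search_answers,
                           sample_n = config$sample_n,
                           seed = derive_seed(config$seed, 1L))
  write_corpus(pre$corpus, stage_path(out_dir, "corpus_filtered.jsonl"))
  write_json_stable(as.list(pre$report), stage_path(out_dir, "filter_report.json"))
  invisible(pre)
}

read_filtered <- function(out_dir) {
  read_corpus(require_artifact(stage_path(out_dir, "corpus_filtered.jsonl"),
                               "ingest"))
}

#' @rdname pipeline_stages
#' @export
stage_topics <- function(config, out_dir = config$out_dir) {
  corpus <- read_filtered(out_dir)
  docs <- tokenize(corpus$question_text, config$stopwords)
  names(docs) <- corpus$record_id
  lda_seed <- derive_seed(config$seed, 2L)
  if (!is.null(config$lda$candidate_Ks)) {
    sel <- select_k(docs, config$lda$candidate_Ks, alpha = config$lda$alpha,
                    beta = config$lda$beta, n_iter = config$lda$n_iter,
                    seed = lda_seed, n_starts = config$lda$n_starts,
                    M = config$lda$M)
    utils::write.csv(sel$table, stage_path(out_dir, "coherence.csv"),
                     row.names = FALSE)
    model <- sel$models[[as.character(sel$K)]]
  } else {
    model <- fit_lda(docs, config$lda$K, alpha = config$lda$alpha,
                     beta = config$lda$beta, n_iter = config$lda$n_iter,
                     seed = lda_seed, n_starts = config$lda$n_starts,
                     M = config$lda$M)
  }
  mm <- config$merge_map %||%
    merge_map(sprintf("topic_%02d", seq_len(model$K)))
  merged <- merge_topics(model, mm)
  space <- build_embedding(docs, d = config$embedding_dim,
                           window = config$window)
  # a merged label can lose every document when a raw topic collapses in
  # the sampler; such labels have no centroid and drop out of the space
  present <- mm$labels[mm$labels %in% unique(merged$labels$label)]
  if (length(present) < length(mm$labels))
    warning("merged label(s) with no documents skipped: ",
            paste(setdiff(mm$labels, present), collapse = ", "))
  tvecs <- topic_vectors(space, merged$labels, label_order = present)
  labels <- if (isTRUE(config$refine)) {
    assign_documents(space$doc_vectors, tvecs)
  } else {
    tibble::tibble(record_id = merged$labels$record_id,
                   label = merged$labels$label,
                   similarity = merged$labels$mass)
  }
  kw <- dplyr::bind_rows(lapply(present, function(lab) {
    if (isTRUE(attr(tvecs, "degenerate")[match(lab, rownames(tvecs))]))
      return(NULL)
    ch <- characterize_topic(tvecs[lab, ], merged$keyword_pools[[lab]],
                             space$word_vectors, J = config$lda$M)
    tibble::tibble(label = lab, rank = seq_len(nrow(ch)), token = ch$token,
                   similarity = ch$similarity)
  }))
  utils::write.csv(labels, stage_path(out_dir, "topic_labels.csv"),
                   row.names = FALSE)
  utils::write.csv(kw, stage_path(out_dir, "topic_keywords.csv"),
                   row.names = FALSE)
  invisible(list(model = model, merge_map = mm, merged = merged,
                 space = space, topic_vectors = tvecs, labels = labels,
                 keywords = kw))
}

#' @rdname pipeline_stages
#' @export
stage_sentiment <- function(config, out_dir = config$out_dir) {
  corpus <- read_filtered(out_dir)
  scorers <- lapply(config$scorer_smoothings, function(s)
    lexicon_scorer(config$pos_lexicon, config$neg_lexicon, smoothing = s))
  res <- classify_corpus(corpus, scorers, target = "both",
                         chunk_size = config$chunk_size,
                         weight_by_length = config$weight_by_length)
  utils::write.csv(res, stage_path(out_dir, "sentiment.csv"), row.names = FALSE)
  invisible(res)
}

read_stage_csv <- function(out_dir, file, producer) {
  utils::read.csv(require_artifact(stage_path(out_dir, file), producer),
                  stringsAsFactors = FALSE)
}

#' @rdname pipeline_stages
#' @export
stage_pairs <- function(config, out_dir = config$out_dir) {
  labels <- tibble::as_tibble(read_stage_csv(out_dir, "topic_labels.csv", "topics"))
  sent <- tibble::as_tibble(read_stage_csv(out_dir, "sentiment.csv", "sentiment"))
  qs <- sent[sent$target == "question", ]
  as_ <- sent[sent$target == "answer", ]
  ttab <- topic_table(labels)
  props_a <- sentiment_proportions(as_, labels)
  props_q <- sentiment_proportions(qs, labels)
  pairs <- pair_crosstab(qs, as_, labels)
  check <- marginal_check(pairs, props_a, props_q)
  utils::write.csv(ttab, stage_path(out_dir, "topic_table.csv"), row.names = FALSE)
  utils::write.csv(props_a, stage_path(out_dir, "sentiment_proportions.csv"),
                   row.names = FALSE)
  utils::write.csv(pairs, stage_path(out_dir, "pair_table.csv"), row.names = FALSE)
  utils::write.csv(check, stage_path(out_dir, "marginal_check.csv"),
                   row.names = FALSE)
  if (!isTRUE(attr(check, "pass")))
    warning("marginal check failed; see marginal_check.csv")
  invisible(list(topic_table = ttab, answer_props = props_a,
                 question_props = props_q, pair_table = pairs, check = check))
}

#' @rdname pipeline_stages
#' @export
stage_temporal <- function(config, out_dir = config$out_dir) {
  labels <- tibble::as_tibble(read_stage_csv(out_dir, "topic_labels.csv", "topics"))
  sent <- tibble::as_tibble(read_stage_csv(out_dir, "sentiment.csv", "sentiment"))
  corpus <- read_filtered(out_dir)
  series <- monthly_series(sent[sent$target == "answer", ], labels,
                           corpus[, c("record_id", "question_timestamp")],
                           window_start = config$window_start,
                           window_end = config$window_end,
                           merge_threshold_days = config$merge_threshold_days)
  stats <- lapply(split(series, series$topic), function(s) {
    nn <- sum(!is.na(s$pos_share))
    list(crossovers = if (nn >= 2) count_crossovers(s) else NULL,
         positive_streak = dominance_streak(s, "positive"),
         negative_streak = dominance_streak(s, "negative"))
  })
  utils::write.csv(series, stage_path(out_dir, "monthly_series.csv"),
                   row.names = FALSE)
  write_json_stable(stats, stage_path(out_dir, "stats.json"))
  invisible(list(series = series, stats = stats))
}

serializable_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$generator)) {
    cfg$generator <- unclass(cfg$generator)
    cfg$generator$date_range <- format(cfg$generator$date_range, "%Y-%m-%d")
  }
  if (!is.null(cfg$merge_map)) cfg$merge_map <- unclass(cfg$merge_map)
  cfg
}

#' Run the full pipeline
#'
#' Executes corpus generation (or ingestion), preprocessing, topic
#' categorization, sentiment classification, cross-tabulation, and
#' temporal analysis, writing every module's artifacts plus the resolved
#' configuration (`config.json`) and a run manifest (`manifest.json`,
#' written last, recording per-stage record counts and wall times; on
#' failure it names the failing stage and partial outputs are retained).
#' Identical config and seed give byte-identical result tables.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (defaults to `config$out_dir`).
#' @return invisible list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_json_stable(serializable_config(config), stage_path(out_dir, "config.json"))
  manifest <- list(config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("qadiscourse")),
                   seed = config$seed, stages = list())
  results <- list()
  stages <- c(if (is.null(config$input)) "generate",
              "ingest", "topics", "sentiment", "pairs", "temporal")
  for (st in stages) {
    t0 <- Sys.time()
    res <- tryCatch(
      switch(st,
             generate = stage_generate(config, out_dir),
             ingest = stage_ingest(config, out_dir),
             topics = stage_topics(config, out_dir),
             sentiment = stage_sentiment(config, out_dir),
             pairs = stage_pairs(config, out_dir),
             temporal = stage_temporal(config, out_dir)),
      error = function(e) e)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      manifest$stages[[st]] <- list(status = "failed", seconds = elapsed,
                                    error = conditionMessage(res))
      manifest$failed_stage <- st
      write_json_stable(manifest, stage_path(out_dir, "manifest.json"))
      stop("pipeline stage '", st, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    n_records <- stage_record_count(st, res)
    manifest$stages[[st]] <- list(status = "ok", seconds = elapsed,
                                  n_records = n_records)
    results[[st]] <- res
  }
  if (!is.null(results$ingest))
    manifest$filter_report <- as.list(results$ingest$report)
  write_json_stable(manifest, stage_path(out_dir, "manifest.json"))
  invisible(c(results, list(manifest = manifest)))
}

stage_record_count <- function(stage, res) {
  switch(stage,
         generate = nrow(res$corpus),
         ingest = nrow(res$corpus),
         topics = nrow(res$labels),
         sentiment = nrow(res),
         pairs = sum(res$topic_table$n),
         temporal = nrow(res$series),
         NA_integer_)
}

config_hash <- function(config) {
  # order-stable structural fingerprint; good enough to tie a manifest to
  # its config without a digest dependency
  s <- jsonlite::toJSON(serializable_config(config), auto_unbox = TRUE,
                        digits = NA, null = "null")
  sum(utf8ToInt(as.character(s)) * (seq_len(nchar(as.character(s))) %% 97 + 1)) %% 2147483647
}
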