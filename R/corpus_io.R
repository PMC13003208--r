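#' Q&A corpus objects
#'
#' A corpus is a tibble with one row per question record and columns
#' `record_id` (unique string), `platform`, `question_text`,
#' `question_timestamp` (a `Date`), `url` (optional, `NA` allowed) and
#' `answers`, a list column in which each element is a data frame with
#' columns `answer_text`, `upvotes` (non-negative integer) and
#' `answer_timestamp` (`Date`, `NA` allowed). `qa_corpus()` validates and
#' stamps the class.
#'
#' @param x a data frame with the columns above.
#' @return a validated `qa_corpus` tibble.
#' @export
qa_corpus <- function(x) {
  req <- c("record_id", "platform", "question_text", "question_timestamp", "answers")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop("corpus is missing required column(s): ", paste(miss, collapse = ", "))
  x <- tibble::as_tibble(x)
  if (!"url" %in% names(x)) x$url <- NA_character_
  x <- x[, c("record_id", "platform", "question_text", "question_timestamp",
             "url", "answers")]
  if (anyDuplicated(x$record_id))
    stop("record_id values must be unique within a corpus; duplicated: ",
         paste(unique(x$record_id[duplicated(x$record_id)]), collapse = ", "))
  if (!inherits(x$question_timestamp, "Date"))
    x$question_timestamp <- parse_iso_date(x$question_timestamp, "question_timestamp")
  if (anyNA(x$question_timestamp))
    stop("question_timestamp contains unparseable dates")
  x$answers <- lapply(x$answers, validate_answers)
  class(x) <- c("qa_corpus", class(tibble::tibble()))
  x
}

parse_iso_date <- function(x, what) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(as.character(x)))
  if (length(bad) > 0)
    stop("unparseable ", what, " (expect ISO-8601 YYYY-MM-DD) at position(s): ",
         paste(head(bad, 5), collapse = ", "))
  d
}

validate_answers <- function(a) {
  if (is.null(a) || (is.data.frame(a) && nrow(a) == 0)) {
    return(tibble::tibble(answer_text = character(), upvotes = integer(),
                          answer_timestamp = as.Date(character())))
  }
  a <- tibble::as_tibble(a)
  if (!all(c("answer_text", "upvotes") %in% names(a)))
    stop("each answer needs answer_text and upvotes")
  if (!"answer_timestamp" %in% names(a)) a$answer_timestamp <- as.Date(NA)
  if (!inherits(a$answer_timestamp, "Date"))
    a$answer_timestamp <- parse_iso_date(a$answer_timestamp, "answer_timestamp")
  a$upvotes <- as.integer(a$upvotes)
  if (anyNA(a$upvotes) || any(a$upvotes < 0))
    stop("upvotes must be non-negative integers")
  a[, c("answer_text", "upvotes", "answer_timestamp")]
}

#' Read a Q&A corpus from JSONL or CSV
#'
#' JSONL holds one record object per line with keys `record_id`, `platform`,
#' `question_text`, `question_timestamp` (ISO-8601 date), optional `url`,
#' and `answers` (array of objects with `answer_text`, `upvotes`, optional
#' `answer_timestamp`). CSV holds one row per answer with the record-level
#' fields repeated; a record with no answers occupies one row with empty
#' answer fields. Input order is preserved. A missing required field or an
#' unparseable date is a schema error naming the offending line.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @return a [qa_corpus()] tibble.
#' @seealso [write_corpus()] for the bit-stable writer.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (format == "jsonl") read_corpus_jsonl(path) else read_corpus_csv(path)
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty corpus file: ", path)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyDataFrame = TRUE),
                    error = function(e) stop("line ", i, ": invalid JSON (",
                                             conditionMessage(e), ")", call. = FALSE))
    for (f in c("record_id", "platform", "question_text", "question_timestamp")) {
      if (is.null(obj[[f]]))
        stop("line ", i, ": missing required field '", f, "'", call. = FALSE)
    }
    ans <- obj$answers
    if (is.null(ans) || length(ans) == 0) {
      ans <- NULL
    } else if (!is.data.frame(ans)) {
      ans <- do.call(rbind, lapply(ans, function(a) as.data.frame(a, stringsAsFactors = FALSE)))
    }
    recs[[i]] <- tibble::tibble(
      record_id = as.character(obj$record_id),
      platform = as.character(obj$platform),
      question_text = as.character(obj$question_text),
      question_timestamp = as.character(obj$question_timestamp),
      url = as.character(obj$url %||% NA_character_),
      answers = list(ans)
    )
  }
  qa_corpus(dplyr::bind_rows(recs))
}

read_corpus_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  req <- c("record_id", "platform", "question_text", "question_timestamp",
           "answer_text", "upvotes")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("CSV corpus is missing required column(s): ", paste(miss, collapse = ", "))
  if (!"url" %in% names(df)) df$url <- NA_character_
  if (!"answer_timestamp" %in% names(df)) df$answer_timestamp <- NA_character_
  ids <- unique(df$record_id)
  recs <- lapply(ids, function(id) {
    rows <- df[df$record_id == id, , drop = FALSE]
    has_ans <- nzchar(rows$answer_text) & !is.na(rows$answer_text)
    ans <- if (any(has_ans)) {
      tibble::tibble(answer_text = rows$answer_text[has_ans],
                     upvotes = as.integer(rows$upvotes[has_ans]),
                     answer_timestamp = parse_iso_date(
                       ifelse(nzchar(rows$answer_timestamp[has_ans]),
                              rows$answer_timestamp[has_ans], NA),
                       "answer_timestamp"))
    } else NULL
    tibble::tibble(record_id = id, platform = rows$platform[1],
                   question_text = rows$question_text[1],
                   question_timestamp = rows$question_timestamp[1],
                   url = ifelse(nzchar(rows$url[1]), rows$url[1], NA_character_),
                   answers = list(ans))
  })
  qa_corpus(dplyr::bind_rows(recs))
}

#' Write a Q&A corpus bit-stably
#'
#' Emits the JSONL or CSV schema read by [read_corpus()] with sorted object
#' keys and fixed formatting, so that identical corpora serialize to
#' byte-identical files (round-trip tested).
#'
#' @param corpus a [qa_corpus()].
#' @param path output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  corpus <- qa_corpus(corpus)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      a <- corpus$answers[[i]]
      ans <- lapply(seq_len(nrow(a)), function(j) {
        o <- list(answer_text = a$answer_text[j], upvotes = a$upvotes[j])
        if (!is.na(a$answer_timestamp[j]))
          o$answer_timestamp <- format(a$answer_timestamp[j], "%Y-%m-%d")
        o[sort(names(o))]
      })
      o <- list(answers = ans, platform = corpus$platform[i],
                question_text = corpus$question_text[i],
                question_timestamp = format(corpus$question_timestamp[i], "%Y-%m-%d"),
                record_id = corpus$record_id[i])
      if (!is.na(corpus$url[i])) o$url <- corpus$url[i]
      as.character(jsonlite::toJSON(o[sort(names(o))], auto_unbox = TRUE))
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    rows <- lapply(seq_len(nrow(corpus)), function(i) {
      a <- corpus$answers[[i]]
      base <- tibble::tibble(record_id = corpus$record_id[i],
                             platform = corpus$platform[i],
                             question_text = corpus$question_text[i],
                             question_timestamp = format(corpus$question_timestamp[i], "%Y-%m-%d"),
                             url = ifelse(is.na(corpus$url[i]), "", corpus$url[i]))
      if (nrow(a) == 0) {
        base$answer_text <- ""
        base$upvotes <- NA_integer_
        base$answer_timestamp <- ""
        base
      } else {
        dplyr::bind_cols(base[rep(1, nrow(a)), ],
                         tibble::tibble(answer_text = a$answer_text,
                                        upvotes = a$upvotes,
                                        answer_timestamp = ifelse(is.na(a$answer_timestamp), "",
                                                                  format(a$answer_timestamp, "%Y-%m-%d"))))
      }
    })
    utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Keep records mentioning a keyword
#'
#' A record is kept iff its question text (and, by default, any of its
#' answer texts) contains at least one of the given forms as a
#' case-insensitive substring — so the form `"vaccine"` also matches
#' "vaccines", "vaccinee" and other words containing it.
#'
#' @param corpus a [qa_corpus()].
#' @param keyword_forms non-empty character vector of substrings.
#' @param search_answers also search answer texts (default `TRUE`).
#' @return the filtered corpus.
#' @export
filter_by_keyword <- function(corpus, keyword_forms, search_answers = TRUE) {
  if (length(keyword_forms) == 0 || all(!nzchar(keyword_forms)))
    stop("keyword_forms must be a non-empty set of substrings")
  corpus <- qa_corpus(corpus)
  hit_any <- function(text) {
    text <- tolower(text)
    out <- rep(FALSE, length(text))
    for (f in keyword_forms)
      out <- out | grepl(tolower(f), text, fixed = TRUE)
    out
  }
  keep <- hit_any(corpus$question_text)
  if (search_answers) {
    ans_hit <- vapply(corpus$answers, function(a)
      nrow(a) > 0 && any(hit_any(a$answer_text)), logical(1))
    keep <- keep | ans_hit
  }
  corpus[keep, ]
}

#' Drop records with no answers
#'
#' @param corpus a [qa_corpus()].
#' @return the corpus restricted to records with at least one answer.
#' @export
drop_unanswered <- function(corpus) {
  corpus <- qa_corpus(corpus)
  corpus[vapply(corpus$answers, nrow, integer(1)) > 0, ]
}

#' Select the most upvoted answer of a record
#'
#' Ties on upvotes are broken by earliest answer timestamp (missing
#' timestamps sort last), then by position in the answer list, so the
#' selection is deterministic.
#'
#' @param answers the answers data frame of one record (columns
#'   `answer_text`, `upvotes`, `answer_timestamp`).
#' @return the selected one-row answer data frame.
#' @export
select_top_answer <- function(answers) {
  if (is.null(answers) || nrow(answers) == 0)
    stop("select_top_answer requires at least one answer")
  ts <- as.numeric(answers$answer_timestamp)
  ts[is.na(ts)] <- Inf
  ord <- order(-answers$upvotes, ts, seq_len(nrow(answers)))
  answers[ord[1], , drop = FALSE]
}

#' Top answer of every record
#'
#' @param corpus a [qa_corpus()] with every record answered.
#' @return tibble with `record_id`, `answer_text`, `upvotes`,
#'   `answer_timestamp` (one row per record).
#' @export
top_answers <- function(corpus) {
  corpus <- drop_unanswered(corpus)
  picked <- dplyr::bind_rows(lapply(corpus$answers, select_top_answer))
  dplyr::bind_cols(tibble::tibble(record_id = corpus$record_id), picked)
}

#' Random subsample of a corpus
#'
#' Uniform sampling without replacement of exactly `n` records,
#' reproducible given `seed`; the result is sorted by question timestamp
#' (ties by record id) so downstream outputs are order-stable.
#'
#' @param corpus a [qa_corpus()].
#' @param n sample size; must not exceed the corpus size.
#' @param seed integer seed.
#' @return the sampled corpus.
#' @export
sample_match <- function(corpus, n, seed) {
  corpus <- qa_corpus(corpus)
  if (n > nrow(corpus))
    stop("cannot sample ", n, " records from a corpus of ", nrow(corpus))
  idx <- withr::with_seed(as.integer(seed), sample.int(nrow(corpus), n))
  out <- corpus[sort(idx), ]
  out[order(out$question_timestamp, out$record_id), ]
}

#' Run the preprocessing funnel
#'
#' Applies, in order: keyword filter (if `keyword_forms` given), the
#' answered-only filter, and random subsampling to `sample_n` (if given),
#' and returns the funnel report alongside the corpus. Counts in the
#' report are weakly decreasing by construction.
#'
#' @param corpus a [qa_corpus()].
#' @param keyword_forms optional character vector for [filter_by_keyword()].
#' @param search_answers passed to [filter_by_keyword()].
#' @param sample_n optional target size for [sample_match()].
#' @param seed integer seed used for sampling (recorded in the report).
#' @return list with elements `corpus` and `report` (a one-row tibble with
#'   `n_input`, `n_after_keyword`, `n_after_answered`, `n_after_sampling`,
#'   `seed`).
#' @export
preprocess_corpus <- function(corpus, keyword_forms = NULL, search_answers = TRUE,
                              sample_n = NULL, seed = 1L) {
  corpus <- qa_corpus(corpus)
  n_input <- nrow(corpus)
  if (!is.null(keyword_forms))
    corpus <- filter_by_keyword(corpus, keyword_forms, search_answers)
  n_kw <- nrow(corpus)
  corpus <- drop_unanswered(corpus)
  n_ans <- nrow(corpus)
  if (!is.null(sample_n)) corpus <- sample_match(corpus, sample_n, seed)
  n_samp <- nrow(corpus)
  report <- tibble::tibble(n_input = n_input, n_after_keyword = n_kw,
                           n_after_answered = n_ans, n_after_sampling = n_samp,
                           seed = as.integer(seed))
  stopifnot(n_input >= n_kw, n_kw >= n_ans, n_ans >= n_samp)
  list(corpus = corpus, report = report)
}
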