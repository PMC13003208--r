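`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero at a fixed number of decimals
#'
#' Display rounding for report tables. Unlike [base::round()], which rounds
#' half to even, values exactly halfway round up in magnitude (the convention
#' used for printed percentages throughout the reporting functions).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.345), c(0, 0, 2))
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # small epsilon guards against 51.525 stored as 51.52499999...
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Tokenize text
#'
#' Lowercases and splits on any run of non-alphanumeric characters. No
#' stemming and no stop-word removal by default; an optional stop list drops
#' exact tokens after splitting.
#'
#' @param text character vector of documents.
#' @param stopwords optional character vector of tokens to drop.
#' @return list of character vectors, one per document (empty documents give
#'   zero-length vectors).
#' @examples
#' tokenize("Are vaccines safe?")
#' @export
tokenize <- function(text, stopwords = NULL) {
  toks <- strsplit(tolower(text), "[^\\p{L}\\p{N}]+", perl = TRUE)
  toks <- lapply(toks, function(x) x[nzchar(x)])
  if (!is.null(stopwords)) toks <- lapply(toks, function(x) x[!x %in% stopwords])
  toks
}

# Cosine similarity between a vector and the rows of a matrix.
# Degenerate (all-zero) inputs yield NA rather than NaN noise.
cosine_to_rows <- function(v, m) {
  nv <- sqrt(sum(v^2))
  nm <- sqrt(rowSums(m^2))
  if (nv == 0) return(rep(NA_real_, nrow(m)))
  s <- as.numeric(m %*% v) / unname(nv * nm)
  s[nm == 0] <- NA_real_
  s
}

# Derive a stage seed from the global run seed; keeps results independent
# across stages while remaining a valid 32-bit integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
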