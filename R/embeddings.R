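#' Default English stopword list
#'
#' A small list of high-frequency function words removed before indexing
#' and distance computation. Kept deliberately short: aggressive stopword
#' removal would strip the emotional vocabulary this corpus runs on.
#'
#' @return Character vector of lowercase tokens.
#' @export
default_stopwords <- function() {
  c("a", "an", "the", "and", "or", "but", "if", "then", "than", "so",
    "of", "to", "in", "on", "at", "by", "for", "with", "about", "as",
    "is", "am", "are", "was", "were", "be", "been", "being",
    "i", "im", "me", "my", "we", "you", "your", "it", "its", "this",
    "that", "these", "those", "do", "does", "did", "have", "has", "had",
    "not", "no", "dont", "cant", "will", "would", "can", "could",
    "just", "really", "very", "s", "t", "m", "re", "ve", "ll", "d")
}

#' Tokenize text into lowercase word tokens
#'
#' Unicode-aware: tokens are maximal runs of letters; digits and
#' punctuation are separators (so "I'm" yields "i", "m"). Tokens are
#' lowercased, stopwords dropped, order and duplicates preserved.
#'
#' @param text Character scalar.
#' @param stopwords Character vector of tokens to remove.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(text, stopwords = default_stopwords()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) return(character())
  toks <- regmatches(text, gregexpr("\\p{L}+", text, perl = TRUE))[[1]]
  toks <- tolower(toks)
  toks[!(toks %in% stopwords)]
}

#' Construct an embedding table
#'
#' @param vectors Numeric matrix, one row per token, with unique rownames.
#' @return An `embedding_table` object with fields `dimension` and
#'   `vectors`.
#' @export
embedding_table <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors),
            !is.null(rownames(vectors)))
  if (anyDuplicated(rownames(vectors)))
    stop("duplicate token(s) in embedding table")
  structure(list(dimension = ncol(vectors), vectors = vectors),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("Embedding table: %d tokens, dimension %d\n",
              nrow(x$vectors), x$dimension))
  invisible(x)
}

#' Load word embeddings in word2vec text format
#'
#' The format is a header line `"<vocab_size> <dimension>"` followed by one
#' line per token: the token then `dimension` floats, space-separated.
#'
#' @param path Path to the embedding file.
#' @return An [embedding_table()].
#' @export
load_word2vec_text <- function(path) {
  if (!file.exists(path)) stop(sprintf("embedding file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1L) stop("empty embedding file")
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(header) != 2L)
    stop("line 1: header must be \"vocab_size dimension\"")
  vocab_size <- as.integer(header[[1]]); dim <- as.integer(header[[2]])
  if (is.na(vocab_size) || is.na(dim) || vocab_size < 1L || dim < 1L)
    stop("line 1: invalid header values")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != vocab_size)
    stop(sprintf("header declares %d tokens but file has %d rows",
                 vocab_size, length(body)))
  tokens <- character(vocab_size)
  mat <- matrix(NA_real_, vocab_size, dim)
  for (k in seq_len(vocab_size)) {
    parts <- strsplit(trimws(body[[k]]), "\\s+")[[1]]
    if (length(parts) != dim + 1L)
      stop(sprintf("line %d: expected token plus %d floats, found %d fields",
                   k + 1L, dim, length(parts)))
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals))
      stop(sprintf("line %d: non-numeric vector component", k + 1L))
    tokens[k] <- parts[[1]]
    mat[k, ] <- vals
  }
  dup <- tokens[duplicated(tokens)]
  if (length(dup))
    stop(sprintf("duplicate token(s): %s", paste(unique(dup), collapse = ", ")))
  rownames(mat) <- tokens
  embedding_table(mat)
}

#' Write word embeddings in word2vec text format
#'
#' @param emb An [embedding_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_word2vec_text <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(emb$vectors), emb$dimension), con,
             useBytes = TRUE)
  rows <- apply(emb$vectors, 1L, function(v)
    paste(formatC(v, format = "g", digits = 17), collapse = " "))
  writeLines(paste(rownames(emb$vectors), rows), con, useBytes = TRUE)
  invisible(path)
}

#' Euclidean ground distance between two embedded tokens
#'
#' @param emb An [embedding_table()].
#' @param t1,t2 Tokens present in the table.
#' @return Non-negative Euclidean distance between the word vectors.
#' @export
word_distance <- function(emb, t1, t2) {
  v <- emb$vectors
  for (t in c(t1, t2)) {
    if (!t %in% rownames(v)) stop(sprintf("token not in embedding table: %s", t))
  }
  sqrt(sum((v[t1, ] - v[t2, ])^2))
}

#' Normalized bag-of-words document
#'
#' Drops out-of-vocabulary tokens and normalizes the remaining counts to a
#' probability mass summing to one — the operand of Word Mover's Distance.
#' A document left empty after OOV removal is a structured signal, not an
#' error: retrieval treats it as unmatchable.
#'
#' @param tokens Character vector of tokens (duplicates meaningful).
#' @param emb An [embedding_table()].
#' @return An `nbow_doc` with `weights` (named numeric, sums to 1) and
#'   `vocab_hits` (number of in-vocabulary token occurrences), or a
#'   zero-length-weights `nbow_doc` when nothing survives.
#' @export
nbow <- function(tokens, emb) {
  stopifnot(is.character(tokens))
  known <- tokens[tokens %in% rownames(emb$vectors)]
  if (length(known) == 0L) {
    return(structure(list(weights = numeric(0), vocab_hits = 0L),
                     class = "nbow_doc"))
  }
  counts <- table(known)
  w <- as.numeric(counts) / length(known)
  names(w) <- names(counts)
  structure(list(weights = w, vocab_hits = length(known)), class = "nbow_doc")
}

#' Test whether an nBOW document is empty
#' @param doc An `nbow_doc`.
#' @return `TRUE` when no in-vocabulary mass remains.
#' @export
is_empty_doc <- function(doc) {
  length(doc$weights) == 0L
}
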