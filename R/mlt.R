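#' Build an inverted index over the retrievable corpus
#'
#' Indexes the post text of each corpus record: term postings with
#' within-post frequencies, document frequencies, and precomputed tf-idf
#' document norms used for cosine-style candidate scoring. Posts whose text
#' tokenizes to nothing are left out of the index (they can never match a
#' disjunctive query).
#'
#' @param records Named list of `corpus_record`s from [filter_corpus()].
#' @param stopwords Stopword list passed to [tokenize()].
#' @return An `inverted_index` with fields `N`, `postings`
#'   (term -> named integer vector of term frequencies keyed by post_id),
#'   `df`, `doc_norms`, and `stopwords`.
#' @export
build_index <- function(records, stopwords = default_stopwords()) {
  stopifnot(length(records) >= 1L)
  toks <- lapply(records, function(r) tokenize(r$text, stopwords))
  names(toks) <- vapply(records, `[[`, character(1), "post_id")
  toks <- toks[lengths(toks) > 0L]
  if (length(toks) == 0L) stop("every post tokenized to an empty document")

  N <- length(toks)
  tfs <- lapply(toks, function(tt) table(tt))
  term_v <- unlist(lapply(tfs, names), use.names = FALSE)
  tf_v <- as.integer(unlist(lapply(tfs, as.integer), use.names = FALSE))
  pid_v <- rep(names(tfs), times = lengths(tfs))
  names(tf_v) <- pid_v
  plist <- split(tf_v, term_v)
  terms <- names(plist)
  df <- vapply(plist, length, integer(1))

  idf_vals <- log((N + 1) / (df + 1)) + 1
  norms <- numeric(N); names(norms) <- names(toks)
  for (term in terms) {
    p <- plist[[term]]
    norms[names(p)] <- norms[names(p)] + (p * idf_vals[[term]])^2
  }
  norms <- sqrt(norms)

  structure(list(N = N, postings = plist, df = df, doc_norms = norms,
                 stopwords = stopwords),
            class = "inverted_index")
}

#' @export
print.inverted_index <- function(x, ...) {
  cat(sprintf("Inverted index: %d posts, %d terms\n", x$N, length(x$df)))
  invisible(x)
}

#' Smoothed inverse document frequency
#'
#' `idf(t) = ln((N + 1) / (df_t + 1)) + 1`: strictly decreasing in the
#' document frequency, strictly positive, and equal to 1 for a term present
#' in every document.
#'
#' @param index An `inverted_index`.
#' @param term Indexed term.
#' @return Positive idf weight.
#' @export
idf <- function(index, term) {
  d <- index$df[term]
  if (is.na(d)) stop(sprintf("term not indexed: %s", term))
  unname(log((index$N + 1) / (d + 1)) + 1)
}

#' Select the most discriminative query terms
#'
#' Weights each indexed query term by query term frequency times idf and
#' keeps the top `max_query_terms` — the "more like this" term selection.
#' Ties in weight break lexicographically on the term.
#'
#' @param index An `inverted_index`.
#' @param query_tokens Tokenized incoming post.
#' @param max_query_terms Maximum number of terms to keep.
#' @return An `mlt_query`: data frame of `term`, `weight`, sorted by weight
#'   descending. Zero rows when no query token is indexed.
#' @export
select_query_terms <- function(index, query_tokens, max_query_terms = 25L) {
  stopifnot(max_query_terms >= 1L)
  query_tokens <- query_tokens[query_tokens %in% names(index$df)]
  if (length(query_tokens) == 0L) {
    q <- data.frame(term = character(), weight = numeric(),
                    stringsAsFactors = FALSE)
    class(q) <- c("mlt_query", class(q))
    return(q)
  }
  tf <- table(query_tokens)
  terms <- names(tf)
  w <- as.numeric(tf) * vapply(terms, function(t) idf(index, t), numeric(1))
  ord <- order(-w, terms)
  keep <- ord[seq_len(min(max_query_terms, length(ord)))]
  q <- data.frame(term = terms[keep], weight = w[keep],
                  stringsAsFactors = FALSE)
  rownames(q) <- NULL
  class(q) <- c("mlt_query", class(q))
  q
}

#' Score candidates with a disjunctive more-like-this query
#'
#' A post scores if it shares at least one query term:
#' `score(p) = sum_t weight(t) * tf_p(t) * idf(t) / doc_norm(p)`,
#' a cosine-style normalization that avoids a long-post bias. The top
#' `pool_size` hits are returned, sorted by score descending with ties
#' broken by `post_id` ascending.
#'
#' @param index An `inverted_index`.
#' @param query An `mlt_query` from [select_query_terms()].
#' @param pool_size Maximum number of candidates.
#' @return Data frame of `post_id`, `score`; zero rows for an empty query.
#' @export
mlt_candidates <- function(index, query, pool_size = 50L) {
  stopifnot(pool_size >= 1L)
  if (nrow(query) == 0L) {
    return(data.frame(post_id = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  ids_list <- vector("list", nrow(query))
  contrib_list <- vector("list", nrow(query))
  for (k in seq_len(nrow(query))) {
    term <- query$term[k]
    p <- index$postings[[term]]
    if (is.null(p)) next
    ids_list[[k]] <- names(p)
    contrib_list[[k]] <- unname(query$weight[k] * p * idf(index, term))
  }
  all_ids <- unlist(ids_list)
  if (length(all_ids) == 0L) {
    return(data.frame(post_id = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  agg <- rowsum(unlist(contrib_list), group = all_ids)
  scores <- agg[, 1L] / index$doc_norms[rownames(agg)]
  ids <- rownames(agg)
  ord <- order(-scores, ids)
  keep <- ord[seq_len(min(pool_size, length(ord)))]
  data.frame(post_id = ids[keep], score = unname(scores[keep]),
             stringsAsFactors = FALSE)
}

#' Persist an inverted index as JSON
#'
#' @param index An `inverted_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index_json <- function(index, path) {
  obj <- list(N = index$N,
              postings = lapply(index$postings, as.list),
              df = as.list(index$df),
              doc_norms = as.list(index$doc_norms),
              stopwords = index$stopwords)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an inverted index persisted by [write_index_json()]
#'
#' @param path Path to the JSON artifact.
#' @return An `inverted_index`.
#' @export
read_index_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  postings <- lapply(obj$postings, function(p)
    vapply(p, function(x) as.integer(x), integer(1)))
  structure(list(N = as.integer(obj$N),
                 postings = postings,
                 df = vapply(obj$df, as.integer, integer(1)),
                 doc_norms = vapply(obj$doc_norms, as.numeric, numeric(1)),
                 stopwords = unlist(obj$stopwords)),
            class = "inverted_index")
}
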