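#' Bot framing messages
#'
#' The fixed strings shown to a user before a retrieved or relayed
#' response is delivered: the preliminary deployment's agent framing, and
#' the controlled framing experiment's agent and peer variants.
#'
#' @return Named list with elements `agent_preliminary`,
#'   `experiment_agent`, `experiment_peer`.
#' @export
framing_messages <- function() {
  list(
    agent_preliminary =
      "While you wait for responses, I may have an idea that might help…",
    experiment_agent = paste0(
      "While you wait for responses, maybe I can help… ",
      "I'm just a robot and I'm still learning, but here's a thought."),
    experiment_peer = "Someone replied to your post. Let’s check it out."
  )
}

#' Calibrate the WMD acceptance threshold to a coverage target
#'
#' Sets the threshold tau to the lower empirical q-quantile of best-match
#' WMD scores over a calibration stream: the `ceiling(q * n)`-th smallest
#' score. The fraction of calibration scores at or below tau is then at
#' least `q` and minimal among admissible cut points, so roughly a
#' fraction `q` of comparable incoming posts will be answered (the
#' deployed system targeted about 10%). Calibration posts that could not
#' be scored at all (no candidates, empty document) should enter as `Inf`
#' so that coverage is measured over the whole stream.
#'
#' With `coverage_target = 0` the threshold is placed below the smallest
#' observed score (and may be negative): nothing matches.
#'
#' @param best_scores Numeric vector; one best-over-corpus WMD per
#'   calibration post (`Inf` allowed for unscorable posts).
#' @param coverage_target Target match fraction q in `[0, 1]`.
#' @return A `threshold_config`: list with `tau`, `coverage_target`,
#'   `calibrated_on` (sample size).
#' @export
calibrate_threshold <- function(best_scores, coverage_target = 0.10) {
  stopifnot(length(best_scores) >= 1L, !anyNA(best_scores),
            coverage_target >= 0, coverage_target <= 1)
  n <- length(best_scores)
  k <- ceiling(coverage_target * n)
  sorted <- sort(best_scores)
  tau <- if (k == 0L) min(sorted[1L], 0) - 1 else sorted[k]
  structure(list(tau = tau, coverage_target = coverage_target,
                 calibrated_on = n),
            class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat(sprintf(
    "WMD threshold: tau = %.6g (coverage target %.1f%%, calibrated on %d posts)\n",
    x$tau, 100 * x$coverage_target, x$calibrated_on))
  invisible(x)
}

#' Assemble a retrieval engine
#'
#' Bundles the filtered corpus records, the inverted index built over
#' them, per-post nBOW documents, the embedding table, and the engine
#' parameters into one object that [retrieve_response()] and
#' [calibrate_engine()] operate on.
#'
#' @param records Named list of `corpus_record`s from [filter_corpus()].
#' @param emb An [embedding_table()].
#' @param max_query_terms,pool_size More-like-this parameters.
#' @param stopwords Tokenizer stopword list.
#' @param threshold Optional `threshold_config`; may be attached later via
#'   [calibrate_engine()].
#' @param framing Framing message attached to delivered responses.
#' @return A `retrieval_engine`.
#' @export
retrieval_engine <- function(records, emb,
                             max_query_terms = 25L, pool_size = 50L,
                             stopwords = default_stopwords(),
                             threshold = NULL,
                             framing = framing_messages()$agent_preliminary) {
  index <- build_index(records, stopwords)
  docs <- lapply(records, function(r) nbow(tokenize(r$text, stopwords), emb))
  names(docs) <- names(records)
  docs <- docs[names(index$doc_norms)]
  structure(list(records = records, index = index, docs = docs, emb = emb,
                 max_query_terms = as.integer(max_query_terms),
                 pool_size = as.integer(pool_size),
                 stopwords = stopwords, threshold = threshold,
                 framing = framing),
            class = "retrieval_engine")
}

#' @export
print.retrieval_engine <- function(x, ...) {
  cat(sprintf("Retrieval engine: %d records, %d indexed posts%s\n",
              length(x$records), x$index$N,
              if (is.null(x$threshold)) ", uncalibrated"
              else sprintf(", tau = %.4g", x$threshold$tau)))
  invisible(x)
}

# Best exact-WMD match for one incoming text, before any threshold gate.
# Returns list(post_id, wmd) or list(reason = <code>) when no stage yields
# anything.
engine_best_match <- function(engine, text) {
  tokens <- tokenize(text, engine$stopwords)
  qdoc <- nbow(tokens, engine$emb)
  query <- select_query_terms(engine$index, tokens, engine$max_query_terms)
  if (nrow(query) == 0L) return(list(reason = "empty_query"))
  if (is_empty_doc(qdoc)) return(list(reason = "empty_document"))
  cand <- mlt_candidates(engine$index, query, engine$pool_size)
  if (nrow(cand) == 0L) return(list(reason = "no_candidates"))
  ranked <- prune_and_rank(qdoc, engine$docs[cand$post_id], engine$emb,
                           top_m = 1L)
  if (nrow(ranked) == 0L) return(list(reason = "no_candidates"))
  list(post_id = ranked$post_id[1L], wmd = ranked$wmd[1L])
}

#' Calibrate an engine's threshold on a stream of posts
#'
#' Scores every calibration post against the corpus (best exact WMD;
#' `Inf` when unscorable) and installs the quantile threshold from
#' [calibrate_threshold()].
#'
#' @param engine A `retrieval_engine`.
#' @param texts Character vector of calibration posts.
#' @param coverage_target Target match fraction q.
#' @return The engine with `threshold` set; the score vector is attached
#'   as attribute `"calibration_scores"` of the threshold.
#' @export
calibrate_engine <- function(engine, texts, coverage_target = 0.10) {
  stopifnot(length(texts) >= 1L)
  scores <- vapply(texts, function(tx) {
    m <- engine_best_match(engine, tx)
    if (is.null(m$wmd)) Inf else m$wmd
  }, numeric(1), USE.NAMES = FALSE)
  th <- calibrate_threshold(scores, coverage_target)
  attr(th, "calibration_scores") <- scores
  engine$threshold <- th
  engine
}

#' Pick the most favorable retained response of a record
#'
#' Preference order good, then ok, then unrated (bad-rated responses never
#' survive filtering); ties break on the smallest `response_id` so
#' selection is deterministic.
#'
#' @param record A `corpus_record` with at least one retained response.
#' @return One-row data frame with `response_id`, `text`, `rating`.
#' @export
select_favorable_response <- function(record) {
  rr <- record$responses
  if (is.null(rr) || nrow(rr) == 0L)
    stop(sprintf("record %s has no retained responses", record$post_id))
  pref <- match(rr$rating, c("good", "ok"))
  pref[is.na(pref)] <- 3L
  pick <- order(pref, rr$response_id)[1L]
  rr[pick, , drop = FALSE]
}

#' Retrieve a repurposable archived response for an incoming post
#'
#' Runs the full pipeline: tokenize, select top tf-idf query terms, pull
#' a disjunctive more-like-this candidate pool, rerank the pool by exact
#' WMD with lower-bound pruning, gate the best match on the calibrated
#' threshold (inclusive), and select the matched post's most favorably
#' rated response.
#'
#' @param engine A calibrated `retrieval_engine`.
#' @param text Incoming post text.
#' @return A `retrieval_result`: list with `matched`; on a match also
#'   `post_id`, `response_id`, `response_text`, `best_wmd`; otherwise a
#'   `reason` code (`empty_query`, `empty_document`, `no_candidates`,
#'   `above_threshold`) and `best_wmd` when one was computed. Always
#'   carries `framing_message`.
#' @export
retrieve_response <- function(engine, text) {
  if (is.null(engine$threshold))
    stop("engine has no threshold: run calibrate_engine() first")
  m <- engine_best_match(engine, text)
  res <- if (!is.null(m$reason)) {
    list(matched = FALSE, reason = m$reason)
  } else if (m$wmd > engine$threshold$tau) {
    list(matched = FALSE, reason = "above_threshold", best_wmd = m$wmd)
  } else {
    resp <- select_favorable_response(engine$records[[m$post_id]])
    list(matched = TRUE, post_id = m$post_id,
         response_id = resp$response_id, response_text = resp$text,
         best_wmd = m$wmd)
  }
  res$framing_message <- engine$framing
  structure(res, class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  if (x$matched) {
    cat(sprintf("Matched post %s (WMD %.4f), response %s\n",
                x$post_id, x$best_wmd, x$response_id))
  } else {
    cat(sprintf("No match (%s)\n", x$reason))
  }
  invisible(x)
}
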