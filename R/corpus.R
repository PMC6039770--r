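#' Corpus configuration
#'
#' Limits and filter settings for assembling a retrievable post/response
#' corpus. Platform posts are capped at 950 characters and responses at 600;
#' responses soliciting contact on outside messengers are excluded from
#' reuse, as are quarantined and bad-rated ones.
#'
#' @param post_limit Maximum post length in Unicode code points (after
#'   trimming leading/trailing whitespace).
#' @param response_limit Maximum response length, same counting rule.
#' @param solicitation_patterns Character vector of lowercase words whose
#'   whole-word, case-insensitive occurrence marks a response as a
#'   solicitation to move the conversation off-platform.
#' @return A list of class `corpus_config`.
#' @export
corpus_config <- function(post_limit = 950L,
                          response_limit = 600L,
                          solicitation_patterns = c("kik", "instagram")) {
  stopifnot(post_limit > 0, response_limit > 0,
            length(solicitation_patterns) >= 1)
  structure(list(post_limit = as.integer(post_limit),
                 response_limit = as.integer(response_limit),
                 solicitation_patterns = tolower(solicitation_patterns)),
            class = "corpus_config")
}

#' Validate a text against a character limit
#'
#' A text is acceptable when it is non-empty after trimming leading and
#' trailing whitespace and its trimmed length, counted in Unicode code
#' points, does not exceed `limit`.
#'
#' @param text Character scalar.
#' @param limit Positive integer limit.
#' @return `TRUE` or `FALSE`.
#' @export
validate_text <- function(text, limit) {
  stopifnot(is.character(text), length(text) == 1L, limit > 0)
  if (is.na(text)) return(FALSE)
  trimmed <- trimws(text)
  nchar(trimmed, type = "chars") > 0L && nchar(trimmed, type = "chars") <= limit
}

#' Flag solicitations to chat on other platforms
#'
#' Case-insensitive whole-word match of any pattern inside the text.
#' Substrings embedded in longer words do not match ("kicked" does not
#' trigger the "kik" pattern).
#'
#' @param text Character scalar.
#' @param patterns Character vector of lowercase words.
#' @return `TRUE` if any pattern occurs as a whole word.
#' @export
solicitation_flag <- function(text,
                              patterns = corpus_config()$solicitation_patterns) {
  stopifnot(is.character(text), length(text) == 1L, length(patterns) >= 1)
  if (is.na(text)) return(FALSE)
  any(vapply(patterns, function(p) {
    grepl(paste0("\\b", p, "\\b"), text, ignore.case = TRUE, perl = TRUE)
  }, logical(1)))
}

new_filter_report <- function(n_input, bad, quarantined, solicitation,
                              overlimit, retained) {
  structure(list(n_input_responses = n_input,
                 n_removed_bad = bad,
                 n_removed_quarantined = quarantined,
                 n_removed_solicitation = solicitation,
                 n_removed_overlimit = overlimit,
                 n_retained = retained),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Corpus filter report\n")
  cat(sprintf("  input responses : %d\n", x$n_input_responses))
  cat(sprintf("  removed quarantined : %d\n", x$n_removed_quarantined))
  cat(sprintf("  removed bad-rated   : %d\n", x$n_removed_bad))
  cat(sprintf("  removed solicitation: %d\n", x$n_removed_solicitation))
  cat(sprintf("  removed over-limit  : %d\n", x$n_removed_overlimit))
  cat(sprintf("  retained            : %d\n", x$n_retained))
  invisible(x)
}

RATING_LEVELS <- c("good", "ok", "bad")

check_ratings <- function(rating) {
  bad <- !is.na(rating) & !(rating %in% RATING_LEVELS)
  if (any(bad)) {
    stop(sprintf("unknown rating value(s): %s",
                 paste(unique(rating[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(rating)
}

#' Filter a raw corpus down to its retrievable records
#'
#' Applies the eligibility rules for response reuse, removing each response
#' for the first rule it violates, in fixed precedence order:
#' quarantined, then bad-rated, then solicitation, then over-limit (a
#' response whose own text fails validation, or whose parent post's text
#' fails the post limit, is counted here). Unrated responses are retained.
#' Posts left with no eligible response are dropped: a post that can never
#' supply a response has no place in the index.
#'
#' @param posts Data frame with columns `post_id`, `text` (and optionally
#'   `created_at`).
#' @param responses Data frame with columns `response_id`, `post_id`,
#'   `text`, and optionally `rating` (`"good"`, `"ok"`, `"bad"`, or `NA`)
#'   and `quarantined` (logical).
#' @param config A [corpus_config()].
#' @return A list with `records` (a named list of `corpus_record` objects,
#'   keyed and ordered by `post_id`; each has `post_id`, `text`, and a
#'   `responses` data frame) and `report` (a `filter_report`).
#' @export
filter_corpus <- function(posts, responses, config = corpus_config()) {
  stopifnot(is.data.frame(posts), is.data.frame(responses))
  if (anyDuplicated(posts$post_id)) stop("duplicate post_id in posts")
  if (nrow(responses) > 0 && anyDuplicated(responses$response_id))
    stop("duplicate response_id in responses")
  if (is.null(responses$rating)) responses$rating <- NA_character_
  if (is.null(responses$quarantined)) responses$quarantined <- FALSE
  responses$quarantined[is.na(responses$quarantined)] <- FALSE
  check_ratings(responses$rating)

  dangling <- !(responses$post_id %in% posts$post_id)
  if (any(dangling)) {
    stop(sprintf("response(s) reference unknown post_id: %s",
                 paste(responses$response_id[dangling], collapse = ", ")),
         call. = FALSE)
  }

  n <- nrow(responses)
  post_ok <- vapply(posts$text, validate_text, logical(1),
                    limit = config$post_limit)
  names(post_ok) <- posts$post_id

  removal <- character(n)  # "" = retained
  for (k in seq_len(n)) {
    r <- responses[k, ]
    removal[k] <-
      if (isTRUE(r$quarantined)) "quarantined"
      else if (!is.na(r$rating) && r$rating == "bad") "bad"
      else if (solicitation_flag(r$text, config$solicitation_patterns)) "solicitation"
      else if (!validate_text(r$text, config$response_limit) ||
               !post_ok[[r$post_id]]) "overlimit"
      else ""
  }

  keep <- removal == ""
  report <- new_filter_report(
    n_input = n,
    bad = sum(removal == "bad"),
    quarantined = sum(removal == "quarantined"),
    solicitation = sum(removal == "solicitation"),
    overlimit = sum(removal == "overlimit"),
    retained = sum(keep)
  )

  kept <- responses[keep, , drop = FALSE]
  live_ids <- posts$post_id[post_ok[posts$post_id] &
                              posts$post_id %in% kept$post_id]
  live_ids <- sort(live_ids)
  records <- lapply(live_ids, function(pid) {
    rr <- kept[kept$post_id == pid, c("response_id", "text", "rating"),
               drop = FALSE]
    rr <- rr[order(rr$response_id), , drop = FALSE]
    rownames(rr) <- NULL
    structure(list(post_id = pid,
                   text = posts$text[match(pid, posts$post_id)],
                   responses = rr),
              class = "corpus_record")
  })
  names(records) <- live_ids
  list(records = records, report = report)
}

#' Read a post/response corpus from JSONL
#'
#' One JSON object per line; `"type"` is either `"post"` (fields `post_id`,
#' `text`, optional `created_at`) or `"response"` (fields `response_id`,
#' `post_id`, `text`, optional `rating` and `quarantined`).
#'
#' @param path Path to a UTF-8 JSONL file.
#' @return A list with data frames `posts` and `responses`.
#' @export
read_corpus_jsonl <- function(path) {
  if (!file.exists(path)) stop(sprintf("corpus file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  posts <- list(); resps <- list()
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) {
                      stop(sprintf("malformed JSON at line %d: %s",
                                   i, conditionMessage(e)), call. = FALSE)
                    })
    type <- obj$type
    if (is.null(type) || !type %in% c("post", "response"))
      stop(sprintf("line %d: missing or unknown \"type\"", i), call. = FALSE)
    if (is.null(obj$text))
      stop(sprintf("line %d: missing \"text\" field", i), call. = FALSE)
    if (type == "post") {
      if (is.null(obj$post_id))
        stop(sprintf("line %d: post missing \"post_id\"", i), call. = FALSE)
      posts[[length(posts) + 1L]] <- data.frame(
        post_id = obj$post_id, text = obj$text,
        created_at = if (is.null(obj$created_at)) NA_character_ else obj$created_at,
        stringsAsFactors = FALSE)
    } else {
      if (is.null(obj$response_id) || is.null(obj$post_id))
        stop(sprintf("line %d: response missing \"response_id\" or \"post_id\"", i),
             call. = FALSE)
      rating <- if (is.null(obj$rating)) NA_character_ else obj$rating
      if (!is.na(rating) && !rating %in% RATING_LEVELS)
        stop(sprintf("line %d: unknown rating \"%s\"", i, rating), call. = FALSE)
      resps[[length(resps) + 1L]] <- data.frame(
        response_id = obj$response_id, post_id = obj$post_id, text = obj$text,
        rating = rating,
        quarantined = isTRUE(obj$quarantined),
        stringsAsFactors = FALSE)
    }
  }
  empty_posts <- data.frame(post_id = character(), text = character(),
                            created_at = character(), stringsAsFactors = FALSE)
  empty_resps <- data.frame(response_id = character(), post_id = character(),
                            text = character(), rating = character(),
                            quarantined = logical(), stringsAsFactors = FALSE)
  list(posts = if (length(posts)) do.call(rbind, posts) else empty_posts,
       responses = if (length(resps)) do.call(rbind, resps) else empty_resps)
}

#' Write a post/response corpus to JSONL
#'
#' Inverse of [read_corpus_jsonl()]: posts first, then responses, one JSON
#' object per line, UTF-8 with LF line endings. Optional fields that are
#' `NA` are omitted so a round trip is field-for-field lossless.
#'
#' @param posts,responses Data frames as returned by [read_corpus_jsonl()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(posts, responses, path) {
  check_ratings(responses$rating)
  con <- file(path, open = "wb")
  on.exit(close(con))
  emit <- function(obj) {
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA),
               con, useBytes = TRUE)
  }
  for (k in seq_len(nrow(posts))) {
    obj <- list(type = "post", post_id = posts$post_id[k],
                text = posts$text[k])
    if (!is.null(posts$created_at) && !is.na(posts$created_at[k]))
      obj$created_at <- posts$created_at[k]
    emit(obj)
  }
  for (k in seq_len(nrow(responses))) {
    obj <- list(type = "response", response_id = responses$response_id[k],
                post_id = responses$post_id[k], text = responses$text[k])
    if (!is.null(responses$rating) && !is.na(responses$rating[k]))
      obj$rating <- responses$rating[k]
    if (isTRUE(responses$quarantined[k])) obj$quarantined <- TRUE
    emit(obj)
  }
  invisible(path)
}
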