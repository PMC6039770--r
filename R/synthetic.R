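#' Configuration for the synthetic corpus generator
#'
#' Seeded generators emulating the structure of a short-form peer-support
#' corpus: topic-clustered vocabulary and embeddings, template posts well
#' under the 950-character post limit, several rated responses per post
#' (about 4.7 on average, matching the archived corpus's response/post
#' ratio), a good/ok/bad rating mix that skews favorable for on-topic
#' responses, contamination (solicitations, quarantined content, bad
#' ratings) at configurable rates, and gendered pronouns on a fraction of
#' posts with a known mismatch rate for the pronoun diagnostic.
#'
#' @param seed Integer master seed; every substream derives from it.
#' @param n_topics Number of topic clusters.
#' @param n_posts Number of archived posts.
#' @param response_lambda Responses per post are `1 + Poisson(response_lambda)`.
#' @param embedding_dimension Embedding dimensionality.
#' @param topic_separation Distance scale between topic centroids.
#' @param within_spread Per-coordinate standard deviation around a
#'   centroid (within-topic spread).
#' @param vocab_per_topic,n_filler Vocabulary sizes for topic-specific and
#'   shared filler words.
#' @param rating_noise Probability that a response is off-topic (such
#'   responses are rated bad).
#' @param solicitation_rate,bad_rate,quarantine_rate Contamination rates.
#' @param gendered_fraction Fraction of posts that gender their subject.
#' @param mismatch_rate Probability that a response to a gendered post
#'   genders it the wrong way.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_topics = 10L,
                             n_posts = 2000L,
                             response_lambda = 3.7,
                             embedding_dimension = 32L,
                             topic_separation = 10,
                             within_spread = 1,
                             vocab_per_topic = 40L,
                             n_filler = 30L,
                             rating_noise = 0.10,
                             solicitation_rate = 0.02,
                             bad_rate = 0.05,
                             quarantine_rate = 0.02,
                             gendered_fraction = 0.30,
                             mismatch_rate = 0.05) {
  rates <- c(rating_noise, solicitation_rate, bad_rate, quarantine_rate,
             gendered_fraction, mismatch_rate)
  stopifnot(n_topics >= 1L, n_posts >= 1L, embedding_dimension >= 2L,
            topic_separation > 0, within_spread > 0,
            all(rates >= 0), all(rates <= 1))
  structure(as.list(environment()), class = "generator_config")
}

# Purely alphabetic synthetic tokens: the tokenizer treats digits as
# separators, so indices are spelled with letters ("topicab", "wordcd").
letter_code <- function(i) {
  vapply(i, function(k) {
    k <- k - 1L
    code <- ""
    repeat {
      code <- paste0(letters[k %% 26L + 1L], code)
      k <- k %/% 26L - 1L
      if (k < 0L) break
    }
    code
  }, character(1))
}

topic_vocab <- function(config) {
  lapply(seq_len(config$n_topics), function(z)
    paste0("topic", letter_code(z), "word",
           letter_code(seq_len(config$vocab_per_topic))))
}

filler_vocab <- function(n_filler) {
  paste0("filler", letter_code(seq_len(n_filler)))
}

GENDER_VOCAB <- list(
  masculine = c("he", "him", "his", "guy", "boyfriend", "brother"),
  feminine = c("she", "her", "hers", "girl", "girlfriend", "sister")
)

#' Generate a topic-clustered synthetic embedding table
#'
#' Topic words are drawn around random centroids separated on the
#' `topic_separation` scale; shared filler words sit near the origin; a
#' small gendered vocabulary forms two narrow clusters slightly offset
#' from the origin, so that a wrongly gendered response costs a little
#' WMD but not much — mirroring how gender terms behave in real
#' embeddings.
#'
#' @param config A [generator_config()].
#' @return An [embedding_table()].
#' @export
generate_embeddings <- function(config) {
  rng <- local_rng(substream_seed(config$seed, "embeddings"))
  on.exit(rng())
  d <- config$embedding_dimension
  centroids <- matrix(stats::rnorm(config$n_topics * d), config$n_topics, d)
  centroids <- centroids / sqrt(rowSums(centroids^2)) * config$topic_separation

  vocab <- topic_vocab(config)
  rows <- list()
  for (z in seq_len(config$n_topics)) {
    mat <- matrix(stats::rnorm(length(vocab[[z]]) * d,
                               sd = config$within_spread),
                  ncol = d, byrow = TRUE)
    mat <- sweep(mat, 2L, centroids[z, ], "+")
    rownames(mat) <- vocab[[z]]
    rows[[length(rows) + 1L]] <- mat
  }
  fmat <- matrix(stats::rnorm(config$n_filler * d, sd = config$within_spread),
                 ncol = d)
  rownames(fmat) <- filler_vocab(config$n_filler)
  rows[[length(rows) + 1L]] <- fmat
  gdir <- stats::rnorm(d); gdir <- gdir / sqrt(sum(gdir^2))
  for (g in names(GENDER_VOCAB)) {
    off <- if (g == "masculine") 1 else -1
    gm <- matrix(stats::rnorm(length(GENDER_VOCAB[[g]]) * d, sd = 0.3),
                 ncol = d)
    gm <- sweep(gm, 2L, off * gdir, "+")
    rownames(gm) <- GENDER_VOCAB[[g]]
    rows[[length(rows) + 1L]] <- gm
  }
  embedding_table(do.call(rbind, rows))
}

# One synthetic post body: topic words plus filler, optionally gendered.
compose_text <- function(topic_words, gender = NA_character_,
                         n_filler = 30L) {
  n_topic <- sample(4:9, 1L)
  n_fill <- sample(2:4, 1L)
  words <- c(sample(topic_words, n_topic, replace = TRUE),
             filler_vocab(n_filler)[sample.int(n_filler, n_fill,
                                               replace = TRUE)])
  words <- sample(words)
  if (!is.na(gender))
    words <- c(words, sample(GENDER_VOCAB[[gender]], 2L))
  paste(words, collapse = " ")
}

#' Generate a synthetic post/response corpus
#'
#' Emulates the archived corpus's post-response structure: each post gets
#' one or more single-shot responses, mostly on-topic and favorably
#' rated; a `rating_noise` fraction of responses are off-topic and rated
#' bad; contamination (quarantined responses, solicitation phrases,
#' additional bad ratings) is injected at the configured rates. Gendered
#' posts receive responses echoing their gender except for a known
#' `mismatch_rate`. All texts respect the platform character limits by
#' construction.
#'
#' @param config A [generator_config()].
#' @param path Optional path; when given the corpus is also written as
#'   JSONL via [write_corpus_jsonl()].
#' @return List with data frames `posts` (including generator ground-truth
#'   columns `topic`, `gender`) and `responses` (including `topic` and
#'   `mismatched`).
#' @export
generate_corpus <- function(config, path = NULL) {
  rng <- local_rng(substream_seed(config$seed, "corpus"))
  on.exit(rng())
  vocab <- topic_vocab(config)
  n <- config$n_posts

  topic <- sample.int(config$n_topics, n, replace = TRUE)
  gender <- ifelse(stats::runif(n) < config$gendered_fraction,
                   sample(c("masculine", "feminine"), n, replace = TRUE),
                   NA_character_)
  posts <- data.frame(
    post_id = sprintf("p%06d", seq_len(n)),
    text = vapply(seq_len(n), function(i)
      compose_text(vocab[[topic[i]]], gender[i], config$n_filler), character(1)),
    created_at = NA_character_,
    topic = topic, gender = gender,
    stringsAsFactors = FALSE)

  resps <- vector("list", n)
  for (i in seq_len(n)) {
    k <- 1L + stats::rpois(1L, config$response_lambda)
    off_topic <- stats::runif(k) < config$rating_noise
    r_topic <- ifelse(off_topic,
                      1L + (topic[i] - 1L + sample.int(config$n_topics - 1L,
                                                       k, replace = TRUE)) %%
                        config$n_topics,
                      topic[i])
    if (config$n_topics == 1L) r_topic <- rep(topic[i], k)
    rating <- character(k)
    for (j in seq_len(k)) {
      rating[j] <- if (off_topic[j] && config$n_topics > 1L) "bad"
        else if (stats::runif(1L) < config$bad_rate) "bad"
        else sample(c("good", "ok", NA_character_), 1L,
                    prob = c(0.60, 0.25, 0.15))
    }
    mism <- if (is.na(gender[i])) rep(FALSE, k)
      else stats::runif(k) < config$mismatch_rate
    r_gender <- rep(NA_character_, k)
    if (!is.na(gender[i])) {
      r_gender <- ifelse(mism,
                         ifelse(gender[i] == "masculine", "feminine",
                                "masculine"),
                         gender[i])
    }
    text <- vapply(seq_len(k), function(j)
      compose_text(vocab[[r_topic[j]]], r_gender[j], config$n_filler), character(1))
    sol <- stats::runif(k) < config$solicitation_rate
    text[sol] <- paste(text[sol], "hmu on kik")
    resps[[i]] <- data.frame(
      response_id = sprintf("r%06d_%02d", i, seq_len(k)),
      post_id = posts$post_id[i],
      text = text, rating = rating,
      quarantined = stats::runif(k) < config$quarantine_rate,
      topic = r_topic, mismatched = mism,
      stringsAsFactors = FALSE)
  }
  responses <- do.call(rbind, resps)
  rownames(responses) <- NULL
  if (!is.null(path)) write_corpus_jsonl(posts, responses, path)
  list(posts = posts, responses = responses)
}

#' Generate a stream of incoming posts
#'
#' Same generative process and topic mixture as archived posts, drawn
#' from an independent substream so calibration and evaluation streams
#' never overlap the corpus (or each other, given distinct `stream`
#' labels).
#'
#' @param config A [generator_config()].
#' @param n Number of incoming posts.
#' @param stream Substream label; different labels give independent
#'   streams under the same master seed.
#' @return Data frame with `text` and ground-truth `topic`, `gender`.
#' @export
generate_incoming <- function(config, n, stream = "incoming") {
  rng <- local_rng(substream_seed(config$seed, paste0("stream:", stream)))
  on.exit(rng())
  if (n == 0L) {
    return(data.frame(text = character(), topic = integer(),
                      gender = character(), stringsAsFactors = FALSE))
  }
  vocab <- topic_vocab(config)
  topic <- sample.int(config$n_topics, n, replace = TRUE)
  gender <- ifelse(stats::runif(n) < config$gendered_fraction,
                   sample(c("masculine", "feminine"), n, replace = TRUE),
                   NA_character_)
  data.frame(
    text = vapply(seq_len(n), function(i)
      compose_text(vocab[[topic[i]]], gender[i], config$n_filler), character(1)),
    topic = topic, gender = gender, stringsAsFactors = FALSE)
}
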