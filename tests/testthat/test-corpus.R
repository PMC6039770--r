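test_that("text validation enforces trimmed length within the platform limits", {
  expect_true(validate_text(strrep("x", 950), 950))
  expect_false(validate_text(strrep("x", 951), 950))
  expect_true(validate_text(strrep("y", 600), 600))
  expect_false(validate_text(strrep("y", 601), 600))
  expect_false(validate_text("   ", 600))
  expect_false(validate_text("", 950))
  # trimming happens before counting
  expect_true(validate_text(paste0("  ", strrep("x", 950), "  "), 950))
  # code points, not bytes
  expect_true(validate_text(strrep("é", 950), 950))
  expect_false(validate_text(strrep("é", 951), 950))
})

test_that("solicitation matching is whole-word and case-insensitive", {
  expect_true(solicitation_flag("message me on kik!"))
  expect_true(solicitation_flag("DM me on Instagram"))
  expect_true(solicitation_flag("KIK me"))
  expect_false(solicitation_flag("I felt kicked out"))
  expect_false(solicitation_flag("we had a picnic"))
  expect_true(solicitation_flag("find me on snapchat", patterns = "snapchat"))
  expect_false(solicitation_flag("no contact info here"))
})

test_that("filter_corpus applies eligibility rules and reconciles its report", {
  posts <- data.frame(post_id = "p1", text = "feeling low today",
                      stringsAsFactors = FALSE)
  resp <- data.frame(
    response_id = c("r1", "r2"),
    post_id = "p1",
    text = c("it gets better", "that is dumb"),
    rating = c("good", "bad"),
    quarantined = FALSE, stringsAsFactors = FALSE)
  out <- filter_corpus(posts, resp)
  expect_length(out$records, 1L)
  expect_equal(out$records[["p1"]]$responses$response_id, "r1")
  expect_equal(out$report$n_removed_bad, 1L)
  expect_equal(out$report$n_retained, 1L)

  # a post whose only response is quarantined yields nothing retrievable
  resp2 <- data.frame(response_id = "r1", post_id = "p1",
                      text = "whatever", rating = "good",
                      quarantined = TRUE, stringsAsFactors = FALSE)
  out2 <- filter_corpus(posts, resp2)
  expect_length(out2$records, 0L)
  expect_equal(out2$report$n_removed_quarantined, 1L)

  # removal reasons counted in precedence order, one reason per response
  resp3 <- data.frame(
    response_id = c("r1", "r2", "r3"),
    post_id = "p1",
    text = c(strrep("a", 601), "hmu on kik", strrep("b", 100)),
    rating = c(NA, NA, "good"),
    quarantined = FALSE, stringsAsFactors = FALSE)
  out3 <- filter_corpus(posts, resp3)
  expect_equal(out3$report$n_removed_overlimit, 1L)
  expect_equal(out3$report$n_removed_solicitation, 1L)
  expect_equal(out3$report$n_retained, 1L)
  expect_equal(out3$records[["p1"]]$responses$response_id, "r3")
})

test_that("each response is removed for the first violated rule only", {
  posts <- data.frame(post_id = "p1", text = "ok", stringsAsFactors = FALSE)
  # violates every rule at once; precedence says quarantined wins
  resp <- data.frame(response_id = "r1", post_id = "p1",
                     text = paste("kik", strrep("x", 601)),
                     rating = "bad", quarantined = TRUE,
                     stringsAsFactors = FALSE)
  rep1 <- filter_corpus(posts, resp)$report
  expect_equal(rep1$n_removed_quarantined, 1L)
  expect_equal(rep1$n_removed_bad + rep1$n_removed_solicitation +
                 rep1$n_removed_overlimit, 0L)
  # without quarantine, bad rating wins over solicitation and length
  resp$quarantined <- FALSE
  rep2 <- filter_corpus(posts, resp)$report
  expect_equal(rep2$n_removed_bad, 1L)
  expect_equal(rep2$n_removed_solicitation + rep2$n_removed_overlimit, 0L)
})

test_that("dangling responses raise an error naming the offender", {
  posts <- data.frame(post_id = "p1", text = "hello", stringsAsFactors = FALSE)
  resp <- data.frame(response_id = "r9", post_id = "nope", text = "hi",
                     rating = NA_character_, quarantined = FALSE,
                     stringsAsFactors = FALSE)
  expect_error(filter_corpus(posts, resp), "r9")
})

test_that("filtering is idempotent and conserves counts on random corpora", {
  set.seed(401)
  for (rep in 1:5) {
    cfg <- generator_config(seed = 500L + rep, n_posts = 40L, n_topics = 3L,
                            solicitation_rate = 0.1, bad_rate = 0.2,
                            quarantine_rate = 0.1)
    corp <- generate_corpus(cfg)
    out <- filter_corpus(corp$posts, corp$responses)
    r <- out$report
    expect_equal(r$n_input_responses,
                 r$n_retained + r$n_removed_bad + r$n_removed_quarantined +
                   r$n_removed_solicitation + r$n_removed_overlimit)
    # no retained response is bad-rated or over-limit
    for (rec in out$records) {
      expect_false(any(rec$responses$rating %in% "bad"))
      expect_true(all(vapply(rec$responses$text, validate_text, logical(1),
                             limit = 600L)))
    }
    # idempotence: re-filter the surviving rows; nothing more is removed
    kept_ids <- unlist(lapply(out$records, function(x) x$responses$response_id))
    again <- filter_corpus(
      corp$posts[corp$posts$post_id %in% names(out$records), , drop = FALSE],
      corp$responses[corp$responses$response_id %in% kept_ids, , drop = FALSE])
    expect_equal(again$report$n_retained, r$n_retained)
    expect_equal(again$report$n_input_responses, r$n_retained)
    expect_equal(names(again$records), names(out$records))
  }
})

test_that("corpus JSONL round-trips losslessly", {
  posts <- data.frame(post_id = c("p1", "p2"),
                      text = c("first post — unicode é", "second"),
                      created_at = c("2016-08-15T12:00:00Z", NA),
                      stringsAsFactors = FALSE)
  resp <- data.frame(response_id = c("r1", "r2"), post_id = c("p1", "p2"),
                     text = c("a reply", "another"),
                     rating = c("good", NA), quarantined = c(FALSE, TRUE),
                     stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".jsonl")
  write_corpus_jsonl(posts, resp, path)
  back <- read_corpus_jsonl(path)
  expect_equal(back$posts, posts)
  expect_equal(back$responses, resp)
})

test_that("malformed corpus lines are rejected with their line number", {
  path <- tempfile(fileext = ".jsonl")
  writeLines(c('{"type":"post","post_id":"p1","text":"hello"}',
               '{"type":"post","post_id":"p2"}'), path)
  expect_error(read_corpus_jsonl(path), "line 2")

  writeLines(c('{"type":"post","post_id":"p1","text":"hello"}',
               'not json at all'), path)
  expect_error(read_corpus_jsonl(path), "line 2")

  writeLines(c('{"type":"post","post_id":"p1","text":"x"}',
               '{"type":"response","response_id":"r1","post_id":"p1","text":"y","rating":"great"}'),
             path)
  expect_error(read_corpus_jsonl(path), "great")
})
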