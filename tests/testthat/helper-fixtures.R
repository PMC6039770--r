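# Shared fixture builders and independent oracles. Everything is built in
# code at test time; no stored data.

# --- tiny hand corpus -------------------------------------------------------

# Three-topic toy embedding on recognizable words; axis-aligned clusters.
toy_embeddings <- function() {
  v <- rbind(
    exam    = c(10, 0, 0),
    test    = c(10.5, 0, 0),
    study   = c(9.5, 0.5, 0),
    stress  = c(9.8, -0.5, 0),
    dog     = c(0, 10, 0),
    cat     = c(0.5, 10.2, 0),
    pet     = c(-0.3, 9.7, 0),
    lonely  = c(0, 0, 10),
    alone   = c(0.2, 0, 10.3),
    sad     = c(-0.2, 0.4, 9.8),
    feeling = c(0.1, 0.1, 0.2),
    today   = c(-0.1, 0.2, 0)
  )
  embedding_table(v)
}

toy_posts <- function() {
  data.frame(
    post_id = c("post-exam", "post-pet", "post-lonely"),
    text = c("exam stress study today",
             "dog cat pet feeling",
             "lonely alone sad today"),
    stringsAsFactors = FALSE)
}

toy_responses <- function() {
  data.frame(
    response_id = c("resp-exam-1", "resp-exam-2", "resp-pet-1",
                    "resp-lonely-1"),
    post_id = c("post-exam", "post-exam", "post-pet", "post-lonely"),
    text = c("study feeling today", "exam feeling", "pet feeling today",
             "feeling today alone"),
    rating = c("good", "ok", "good", NA),
    quarantined = FALSE,
    stringsAsFactors = FALSE)
}

toy_engine <- function(...) {
  filt <- filter_corpus(toy_posts(), toy_responses())
  retrieval_engine(filt$records, toy_embeddings(), ...)
}

# --- random instances -------------------------------------------------------

random_embeddings <- function(n_tokens, dim = 4L) {
  m <- matrix(stats::rnorm(n_tokens * dim), n_tokens, dim)
  rownames(m) <- paste0("w", seq_len(n_tokens))
  embedding_table(m)
}

random_nbow <- function(emb, max_tokens = 6L) {
  vocab <- rownames(emb$vectors)
  k <- sample.int(min(max_tokens, length(vocab)), 1L)
  toks <- sample(vocab, k)
  w <- stats::runif(k)
  structure(list(weights = stats::setNames(w / sum(w), toks)[order(toks)],
                 vocab_hits = k),
            class = "nbow_doc")
}

# --- independent oracles ----------------------------------------------------

# scipy (HiGHS) solves the same instances as plain LPs; one batched call.
oracle_transport_batch <- function(problems) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  stopifnot(nzchar(py))
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  jsonlite::write_json(problems, fin, digits = NA, auto_unbox = TRUE)
  status <- system2(py, c(shQuote(test_path("oracle_transport.py")),
                          shQuote(fin), shQuote(fout)))
  stopifnot(status == 0L)
  as.numeric(jsonlite::read_json(fout, simplifyVector = TRUE))
}

# WMD instance -> oracle problem description
wmd_problem <- function(a, b, emb) {
  A <- emb$vectors[names(a$weights), , drop = FALSE]
  B <- emb$vectors[names(b$weights), , drop = FALSE]
  C <- sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") -
                   2 * tcrossprod(A, B), 0))
  list(n = length(a$weights), m = length(b$weights),
       d1 = unname(a$weights), d2 = unname(b$weights),
       C = as.vector(t(C)))
}

# Dense tf-idf/cosine reference ranking, written independently of the
# inverted-index path: full document-term matrix, same idf dialect.
dense_mlt_ranking <- function(texts, ids, query_text) {
  toks <- lapply(texts, tokenize)
  qtok <- tokenize(query_text)
  vocab <- sort(unique(unlist(toks)))
  N <- length(texts)
  tf <- sapply(vocab, function(t) vapply(toks, function(d) sum(d == t),
                                         numeric(1)))
  tf <- matrix(tf, nrow = N)
  df <- colSums(tf > 0)
  idf_v <- log((N + 1) / (df + 1)) + 1
  W <- sweep(tf, 2L, idf_v, "*")
  norms <- sqrt(rowSums(W^2))
  qtf <- vapply(vocab, function(t) sum(qtok == t), numeric(1))
  qw <- qtf * idf_v
  scores <- as.vector(W %*% qw) / norms
  shared <- as.vector((tf > 0) %*% (qtf > 0)) > 0
  keep <- which(shared & scores > 0)
  keep[order(-scores[keep], ids[keep])]
}
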