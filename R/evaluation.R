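#' Summarize a vector of three-point ratings
#'
#' @param ratings Character vector of `"good"`, `"ok"`, `"bad"`.
#' @return List with `n_good`, `n_ok`, `n_bad`, and `proportions` (named,
#'   summing to 1; omitted for empty input).
#' @export
rating_distribution <- function(ratings) {
  check_ratings(ratings)
  if (anyNA(ratings)) stop("NA rating in distribution input")
  n <- c(good = sum(ratings == "good"),
         ok = sum(ratings == "ok"),
         bad = sum(ratings == "bad"))
  out <- list(n_good = unname(n[["good"]]), n_ok = unname(n[["ok"]]),
              n_bad = unname(n[["bad"]]))
  if (length(ratings) > 0L) out$proportions <- n / length(ratings)
  out
}

# Half-up rounding: R's round() is round-half-even, which cannot
# reproduce conventionally reported percentages.
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Percentage of a count over a total, half-up rounded
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#' @param digits Decimal places to keep (half-up).
#' @return Percentage on the 0-100 scale.
#' @export
rate_pct <- function(numerator, denominator, digits = 2L) {
  if (denominator <= 0) stop("rate over an empty total is undefined")
  round_half_up(100 * numerator / denominator, digits)
}

#' Acceptable-response rate
#'
#' The percentage of responses rated ok or good, half-up rounded to two
#' decimals — the headline acceptability figure of the rating scale.
#'
#' @param n_good,n_ok,n_bad Non-negative counts.
#' @return Percentage on the 0-100 scale, two decimals.
#' @export
acceptable_rate <- function(n_good, n_ok, n_bad) {
  total <- n_good + n_ok + n_bad
  if (total <= 0) stop("acceptable_rate of zero ratings is undefined")
  rate_pct(n_good + n_ok, total, digits = 2L)
}

#' Build a conditions-by-ratings contingency table
#'
#' @param counts Named list or matrix: one row per condition, columns
#'   `good`, `ok`, `bad` (a 2-column table is also accepted for collapsed
#'   scales).
#' @return A `rating_table` (integer matrix with dimnames).
#' @export
rating_table <- function(counts) {
  m <- if (is.matrix(counts)) counts else do.call(rbind, counts)
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("negative count in rating table")
  if (is.null(rownames(m))) rownames(m) <- paste0("condition", seq_len(nrow(m)))
  structure(m, class = c("rating_table", "matrix"))
}

#' Chi-square test of homogeneity on a rating table
#'
#' Expected counts are `row_total * column_total / grand_total`; the
#' statistic is `sum((O - E)^2 / E)` on `(r - 1)(c - 1)` degrees of
#' freedom with an upper-tail p-value. No continuity correction is
#' applied.
#'
#' @param table A [rating_table()] or plain count matrix.
#' @return List with `statistic`, `dof`, `p_value`, `expected`.
#' @export
chi_square_homogeneity <- function(table) {
  O <- unclass(table)
  storage.mode(O) <- "double"
  rt <- rowSums(O); ct <- colSums(O); g <- sum(O)
  if (any(rt == 0))
    stop(sprintf("degenerate row(s) with zero total: %s",
                 paste(rownames(O)[rt == 0], collapse = ", ")))
  if (any(ct == 0))
    stop(sprintf("degenerate column(s) with zero total: %s",
                 paste(colnames(O)[ct == 0], collapse = ", ")))
  E <- outer(rt, ct) / g
  stat <- sum((O - E)^2 / E)
  dof <- (nrow(O) - 1L) * (ncol(O) - 1L)
  list(statistic = stat, dof = dof,
       p_value = stats::pchisq(stat, dof, lower.tail = FALSE),
       expected = E)
}

#' Randomized assignment of users to experiment arms
#'
#' Independent seeded Bernoulli draws per user; the framing experiment
#' allotted 1/3 of users to the experimental condition and 2/3 to
#' control.
#'
#' @param user_ids Vector of user identifiers.
#' @param p_experimental Probability of the experimental arm.
#' @param seed Integer seed; identical seeds reproduce the assignment.
#' @return Named character vector, values `"control"` / `"experimental"`.
#' @export
assign_arms <- function(user_ids, p_experimental = 1 / 3, seed = 1L) {
  stopifnot(p_experimental >= 0, p_experimental <= 1)
  rng <- local_rng(seed)
  on.exit(rng())
  arms <- ifelse(stats::runif(length(user_ids)) < p_experimental,
                 "experimental", "control")
  stats::setNames(arms, user_ids)
}

GENDER_TERMS <- list(
  masculine = c("he", "him", "his", "himself", "guy", "guys", "boy", "boys",
                "man", "men", "boyfriend", "male", "mr", "sir", "dude",
                "brother", "father", "dad", "son", "husband"),
  feminine = c("she", "her", "hers", "herself", "girl", "girls", "woman",
               "women", "girlfriend", "female", "mrs", "ms", "lady",
               "sister", "mother", "mom", "daughter", "wife")
)

text_genders <- function(text) {
  toks <- tolower(regmatches(text, gregexpr("\\p{L}+", text,
                                            perl = TRUE))[[1]])
  c(masculine = any(toks %in% GENDER_TERMS$masculine),
    feminine = any(toks %in% GENDER_TERMS$feminine))
}

#' Flag a gender-pronoun mismatch between a post and a response
#'
#' Diagnostic heuristic for the retrieval failure mode in which a reused
#' response genders the poster's situation wrongly: flags when the
#' incoming post mentions exactly one gender (its subject) and the
#' response uses any term of the opposite gender. It is a flag for audit
#' only — it never filters retrieval output — and deliberately over-flags
#' responders who gender themselves.
#'
#' @param incoming_text,response_text Character scalars.
#' @return `TRUE` when an opposite-gender reference is present.
#' @export
pronoun_mismatch_flag <- function(incoming_text, response_text) {
  post <- text_genders(incoming_text)
  if (sum(post) != 1L) return(FALSE)
  resp <- text_genders(response_text)
  opposite <- if (post[["masculine"]]) "feminine" else "masculine"
  unname(resp[[opposite]])
}

#' Full evaluation report for per-condition ratings
#'
#' @param ratings Data frame with columns `condition` and `rating`.
#' @return List with per-condition counts, proportions and acceptable
#'   rates, plus the chi-square homogeneity test across conditions (the
#'   test is omitted for a single condition).
#' @export
evaluation_report <- function(ratings) {
  stopifnot(is.data.frame(ratings),
            all(c("condition", "rating") %in% names(ratings)))
  check_ratings(ratings$rating)
  conds <- sort(unique(ratings$condition))
  per <- lapply(conds, function(cc) {
    d <- rating_distribution(ratings$rating[ratings$condition == cc])
    d$acceptable_rate <- acceptable_rate(d$n_good, d$n_ok, d$n_bad)
    d$proportions <- as.list(d$proportions)
    d
  })
  names(per) <- conds
  out <- list(conditions = per)
  if (length(conds) >= 2L) {
    counts <- t(vapply(per, function(d)
      c(good = d$n_good, ok = d$n_ok, bad = d$n_bad), numeric(3)))
    tab <- rating_table(counts[, colSums(counts) > 0, drop = FALSE])
    chi <- chi_square_homogeneity(tab)
    out$chi_square <- list(statistic = chi$statistic, dof = chi$dof,
                           p_value = chi$p_value)
  }
  out
}
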