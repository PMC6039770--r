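stop_empty_doc <- function() {
  stop(structure(class = c("peerecho_empty_doc", "error", "condition"),
                 list(message = "empty document: no in-vocabulary mass",
                      call = NULL)))
}

doc_matrix <- function(doc, emb) {
  emb$vectors[names(doc$weights), , drop = FALSE]
}

# Pairwise Euclidean distances between the rows of A and the rows of B.
cross_distances <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Exact Word Mover's Distance between two nBOW documents
#'
#' Solves the transportation linear program that moves the source
#' document's word mass onto the target's at minimum total cost, where the
#' cost of moving mass between two words is the Euclidean distance between
#' their embedding vectors. The returned objective is the WMD; the flow
#' matrix is the optimal plan.
#'
#' Two documents with identical weight mappings short-circuit to a
#' zero-cost diagonal plan without invoking the solver.
#'
#' @param a,b `nbow_doc` objects (see [nbow()]).
#' @param emb An [embedding_table()] covering both documents' tokens.
#' @return A `transport_plan`: list with `flow` (matrix, source tokens in
#'   rows, target tokens in columns), `objective` (the WMD),
#'   `source_weights`, `target_weights`.
#' @export
wmd_exact <- function(a, b, emb) {
  if (is_empty_doc(a) || is_empty_doc(b)) stop_empty_doc()
  wa <- a$weights; wb <- b$weights
  if (length(wa) == length(wb) && all(names(wa) == names(wb)) &&
      all(abs(wa - wb) < 1e-15)) {
    flow <- diag(wa, nrow = length(wa))
    dimnames(flow) <- list(names(wa), names(wa))
    return(structure(list(flow = flow, objective = 0,
                          source_weights = wa, target_weights = wb),
                     class = "transport_plan"))
  }
  C <- cross_distances(doc_matrix(a, emb), doc_matrix(b, emb))
  out <- transport_optimal(wa, wb, C)
  flow <- out$flow
  dimnames(flow) <- list(names(wa), names(wb))
  structure(list(flow = flow, objective = out$objective,
                 source_weights = wa, target_weights = wb),
            class = "transport_plan")
}

#' @export
print.transport_plan <- function(x, ...) {
  cat(sprintf("Transport plan: %d x %d words, objective (WMD) = %.6f\n",
              nrow(x$flow), ncol(x$flow), x$objective))
  invisible(x)
}

#' Word Centroid Distance lower bound
#'
#' Euclidean distance between the two documents' mass-weighted embedding
#' centroids. By Jensen's inequality this never exceeds the exact WMD,
#' and it is cheap enough to screen every candidate.
#'
#' @inheritParams wmd_exact
#' @return Non-negative lower bound on `wmd_exact(a, b, emb)$objective`.
#' @export
wcd_lower_bound <- function(a, b, emb) {
  if (is_empty_doc(a) || is_empty_doc(b)) stop_empty_doc()
  ca <- colSums(doc_matrix(a, emb) * a$weights)
  cb <- colSums(doc_matrix(b, emb) * b$weights)
  sqrt(sum((ca - cb)^2))
}

#' Relaxed Word Mover's Distance lower bound
#'
#' Drops one side's marginal constraints of the transport program: each
#' source word ships its whole mass to its nearest target word (and
#' symmetrically for the other relaxation). The maximum of the two
#' one-sided optima is a lower bound on the WMD that is usually — though
#' not always — tighter than the centroid bound; the two bounds are not
#' mutually ordered.
#'
#' @inheritParams wmd_exact
#' @return Non-negative lower bound on the WMD.
#' @export
rwmd_lower_bound <- function(a, b, emb) {
  if (is_empty_doc(a) || is_empty_doc(b)) stop_empty_doc()
  C <- cross_distances(doc_matrix(a, emb), doc_matrix(b, emb))
  one_sided_ab <- sum(a$weights * apply(C, 1L, min))
  one_sided_ba <- sum(b$weights * apply(C, 2L, min))
  max(one_sided_ab, one_sided_ba)
}

#' Rank candidates by exact WMD with lower-bound pruning
#'
#' Produces exactly the `top_m` candidates by exact WMD (ties broken by
#' `post_id` ascending) while skipping exact solves wherever a cheap lower
#' bound already exceeds the current m-th best distance: candidates are
#' visited in order of their centroid bound, screened by the relaxed
#' bound, and only survivors are solved exactly. The result is identical —
#' set and order — to exhaustively solving every candidate.
#'
#' Candidates whose document is empty are dropped.
#'
#' @param query An `nbow_doc`.
#' @param candidates Named list of `nbow_doc`s, keyed by post_id.
#' @param emb An [embedding_table()].
#' @param top_m Number of matches to return.
#' @return Data frame `post_id`, `wmd`, `bound_used` (always `"exact"` for
#'   returned rows), sorted by `wmd` then `post_id`. The `"audit"`
#'   attribute records, per screened candidate, whether it was solved
#'   exactly or pruned by which bound.
#' @export
prune_and_rank <- function(query, candidates, emb, top_m = 1L) {
  stopifnot(top_m >= 1L)
  if (is_empty_doc(query)) stop_empty_doc()
  candidates <- candidates[!vapply(candidates, is_empty_doc, logical(1))]
  if (length(candidates) == 0L) {
    res <- data.frame(post_id = character(), wmd = numeric(),
                      bound_used = character(), stringsAsFactors = FALSE)
    attr(res, "audit") <- data.frame(post_id = character(),
                                     outcome = character(),
                                     stringsAsFactors = FALSE)
    return(res)
  }
  ids <- names(candidates)
  wcd <- vapply(ids, function(pid)
    wcd_lower_bound(query, candidates[[pid]], emb), numeric(1))
  visit <- ids[order(wcd, ids)]

  best_id <- character(0); best_wmd <- numeric(0)
  outcome <- setNames(character(length(ids)), ids)
  kth <- function() {
    if (length(best_wmd) < top_m) Inf else
      sort(best_wmd, partial = top_m)[top_m]
  }
  margin <- 1e-12
  for (pid in visit) {
    cut <- kth()
    if (wcd[[pid]] > cut + margin) {
      outcome[pid] <- "pruned-by-wcd"
      next
    }
    rb <- rwmd_lower_bound(query, candidates[[pid]], emb)
    if (rb > cut + margin) {
      outcome[pid] <- "pruned-by-rwmd"
      next
    }
    w <- wmd_exact(query, candidates[[pid]], emb)$objective
    outcome[pid] <- "exact"
    best_id <- c(best_id, pid); best_wmd <- c(best_wmd, w)
    if (length(best_wmd) > top_m) {
      ord <- order(best_wmd, best_id)
      # keep enough to resolve ties at the boundary exactly
      keep <- ord[seq_len(top_m)]
      extra <- ord[-seq_len(top_m)]
      extra <- extra[best_wmd[extra] <= best_wmd[ord[top_m]] + margin]
      keep <- c(keep, extra)
      best_id <- best_id[keep]; best_wmd <- best_wmd[keep]
    }
  }
  ord <- order(best_wmd, best_id)
  keep <- ord[seq_len(min(top_m, length(ord)))]
  res <- data.frame(post_id = best_id[keep], wmd = best_wmd[keep],
                    bound_used = rep("exact", length(keep)),
                    stringsAsFactors = FALSE)
  attr(res, "audit") <- data.frame(post_id = ids,
                                   outcome = unname(outcome[ids]),
                                   stringsAsFactors = FALSE)
  res
}
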