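# Exact solver for the balanced transportation problem
#
#   minimize sum_ij T_ij * cost_ij
#   s.t.     rowSums(T) = supply, colSums(T) = demand, T >= 0
#
# via the classical transportation simplex (northwest-corner start,
# u/v potentials, cycle pivots). Documents are short, so instances are
# tiny (rarely beyond 40 x 40); a dense tableau-free primal method is
# both exact and fast here. If the pivot loop ever hits its iteration
# cap (pathological degeneracy), we fall back to a two-phase LP solve.

solve_transport <- function(supply, demand, cost, max_iter = NULL) {
  n <- length(supply); m <- length(demand)
  stopifnot(n >= 1L, m >= 1L, is.matrix(cost),
            nrow(cost) == n, ncol(cost) == m,
            all(supply > 0), all(demand > 0))
  if (abs(sum(supply) - sum(demand)) > 1e-9)
    stop("unbalanced transport problem: supply and demand totals differ")

  if (n == 1L) {
    flow <- matrix(demand, 1L, m)
    return(list(flow = flow, objective = sum(demand * cost[1L, ]),
                status = "optimal"))
  }
  if (m == 1L) {
    flow <- matrix(supply, n, 1L)
    return(list(flow = flow, objective = sum(supply * cost[, 1L]),
                status = "optimal"))
  }
  if (is.null(max_iter)) max_iter <- 200L * (n + m) + 1000L

  # --- northwest-corner initial basis: exactly n + m - 1 cells ---
  a <- supply; b <- demand
  nb <- n + m - 1L
  bi <- integer(nb); bj <- integer(nb); bf <- numeric(nb)
  i <- 1L; j <- 1L
  for (k in seq_len(nb)) {
    t <- min(a[i], b[j])
    bi[k] <- i; bj[k] <- j; bf[k] <- t
    a[i] <- a[i] - t; b[j] <- b[j] - t
    if (k == nb) break
    if (a[i] <= b[j] && i < n) i <- i + 1L else j <- j + 1L
  }

  tol <- 1e-10 * (1 + max(abs(cost)))
  status <- "iteration_limit"

  for (iter in seq_len(max_iter)) {
    # --- potentials from the basis tree ---
    u <- rep(NA_real_, n); v <- rep(NA_real_, m)
    u[bi[1L]] <- 0
    remaining <- seq_len(nb)
    while (length(remaining) > 0L) {
      progressed <- FALSE
      drop_k <- logical(length(remaining))
      for (q in seq_along(remaining)) {
        k <- remaining[q]
        if (!is.na(u[bi[k]]) && is.na(v[bj[k]])) {
          v[bj[k]] <- cost[bi[k], bj[k]] - u[bi[k]]
          drop_k[q] <- TRUE; progressed <- TRUE
        } else if (is.na(u[bi[k]]) && !is.na(v[bj[k]])) {
          u[bi[k]] <- cost[bi[k], bj[k]] - v[bj[k]]
          drop_k[q] <- TRUE; progressed <- TRUE
        } else if (!is.na(u[bi[k]]) && !is.na(v[bj[k]])) {
          drop_k[q] <- TRUE
        }
      }
      remaining <- remaining[!drop_k]
      if (!progressed && length(remaining) > 0L)
        stop("internal error: transport basis is not a spanning tree")
    }

    # --- entering cell: most negative reduced cost ---
    red <- cost - outer(u, v, "+")
    ent <- which.min(red)
    if (red[ent] >= -tol) { status <- "optimal"; break }
    ei <- (ent - 1L) %% n + 1L
    ej <- (ent - 1L) %/% n + 1L

    # --- cycle: path row ei -> col ej through basic cells (DFS) ---
    path <- transport_find_path(bi, bj, n, m, ei, ej)
    if (is.null(path))
      stop("internal error: no pivot cycle found")
    minus <- path[seq(1L, length(path), by = 2L)]
    theta <- min(bf[minus])
    leave <- minus[which.min(bf[minus])]
    plus <- if (length(path) >= 2L) path[seq(2L, length(path), by = 2L)] else integer(0)
    bf[minus] <- bf[minus] - theta
    bf[plus] <- bf[plus] + theta
    bi[leave] <- ei; bj[leave] <- ej; bf[leave] <- theta
  }

  if (status != "optimal")
    return(list(flow = NULL, objective = NA_real_, status = status))

  flow <- matrix(0, n, m)
  flow[cbind(bi, bj)] <- flow[cbind(bi, bj)] + bf
  list(flow = flow, objective = sum(bf * cost[cbind(bi, bj)]),
       status = "optimal")
}

# Path from row node `ei` to column node `ej` through basic cells,
# alternating row -> col -> row ... steps; returns the basic-cell indices
# along the path (odd positions leave a row, even positions leave a col).
transport_find_path <- function(bi, bj, n, m, ei, ej) {
  by_row <- split(seq_along(bi), bi)
  by_col <- split(seq_along(bj), bj)
  # iterative DFS; state: current node (row if positive, col if negative),
  # cells used so far
  stack <- list(list(node = ei, is_row = TRUE, cells = integer(0)))
  seen_rows <- logical(n); seen_cols <- logical(m)
  seen_rows[ei] <- TRUE
  while (length(stack) > 0L) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (st$is_row) {
      for (k in by_row[[as.character(st$node)]]) {
        cc <- bj[k]
        if (seen_cols[cc]) next
        cells <- c(st$cells, k)
        if (cc == ej) return(cells)
        seen_cols[cc] <- TRUE
        stack[[length(stack) + 1L]] <- list(node = cc, is_row = FALSE,
                                            cells = cells)
      }
    } else {
      for (k in by_col[[as.character(st$node)]]) {
        rr <- bi[k]
        if (seen_rows[rr]) next
        seen_rows[rr] <- TRUE
        stack[[length(stack) + 1L]] <- list(node = rr, is_row = TRUE,
                                            cells = c(st$cells, k))
      }
    }
  }
  NULL
}

# Two-phase LP fallback (boot::simplex) for the rare instance the primal
# pivot loop refuses to finish. Same contract as solve_transport.
solve_transport_lp <- function(supply, demand, cost) {
  n <- length(supply); m <- length(demand)
  if (n == 1L)
    return(list(flow = matrix(demand, 1L, m),
                objective = sum(demand * cost[1L, ]), status = "optimal"))
  if (m == 1L)
    return(list(flow = matrix(supply, n, 1L),
                objective = sum(supply * cost[, 1L]), status = "optimal"))
  nv <- n * m
  A3 <- matrix(0, n + m, nv)
  for (j in seq_len(m)) for (i in seq_len(n)) {
    k <- (j - 1L) * n + i
    A3[i, k] <- 1
    A3[n + j, k] <- 1
  }
  b3 <- c(supply, demand)
  A3 <- A3[-(n + m), , drop = FALSE]
  b3 <- b3[-(n + m)]
  s <- boot::simplex(a = as.vector(cost), A3 = A3, b3 = b3, maxi = FALSE)
  if (s$solved != 1) stop("LP fallback failed to solve transport problem")
  list(flow = matrix(unname(s$soln), n, m), objective = unname(s$value),
       status = "optimal")
}

# Public-ish entry used by wmd_exact: try the fast path, fall back to LP.
transport_optimal <- function(supply, demand, cost) {
  out <- solve_transport(supply, demand, cost)
  if (out$status != "optimal") out <- solve_transport_lp(supply, demand, cost)
  out
}
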