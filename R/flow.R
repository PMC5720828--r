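# Minimum-cost flow machinery.
#
# The constrained path cover is solved as a min-weight min-flow circulation
# with lower bounds. Lower bounds are removed by the standard excess/deficit
# transformation, leaving an ordinary min-cost max-flow problem solved by
# successive shortest augmenting paths (Bellman-Ford on the residual
# network; residual arcs carry negated costs). Networks here are tiny (tens
# of nodes), so a plain R implementation is adequate.

# Internal arc-list representation: parallel vectors; arcs are stored in
# forward/backward pairs so that arc i's residual partner is xor(i-1,1)+1.
.mcmf_new <- function(n_nodes) {
  env <- new.env(parent = emptyenv())
  env$n <- n_nodes
  env$from <- integer(0)
  env$to <- integer(0)
  env$cap <- numeric(0)
  env$cost <- numeric(0)
  env$adj <- vector("list", n_nodes)
  env
}

.mcmf_add_arc <- function(env, from, to, cap, cost) {
  i <- length(env$to) + 1L
  env$from <- c(env$from, from, to)
  env$to <- c(env$to, to, from)
  env$cap <- c(env$cap, cap, 0)
  env$cost <- c(env$cost, cost, -cost)
  env$adj[[from]] <- c(env$adj[[from]], i)
  env$adj[[to]] <- c(env$adj[[to]], i + 1L)
  i  # index of the forward arc
}

# Successive shortest paths; returns total flow pushed from s to t.
.mcmf_run <- function(env, s, t) {
  total <- 0
  repeat {
    # Bellman-Ford (queue-based) over the residual network.
    dist <- rep(Inf, env$n)
    pre_arc <- integer(env$n)
    dist[s] <- 0
    in_queue <- logical(env$n)
    queue <- s
    in_queue[s] <- TRUE
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]; in_queue[u] <- FALSE
      for (ai in env$adj[[u]]) {
        if (env$cap[ai] <= 1e-9) next
        v <- env$to[ai]
        nd <- dist[u] + env$cost[ai]
        if (nd < dist[v] - 1e-9) {
          dist[v] <- nd
          pre_arc[v] <- ai
          if (!in_queue[v]) { queue <- c(queue, v); in_queue[v] <- TRUE }
        }
      }
    }
    if (!is.finite(dist[t])) break
    # Bottleneck along the shortest path.
    push <- Inf
    v <- t
    while (v != s) {
      ai <- pre_arc[v]
      push <- min(push, env$cap[ai])
      v <- env$from[ai]
    }
    v <- t
    while (v != s) {
      ai <- pre_arc[v]
      env$cap[ai] <- env$cap[ai] - push
      rev <- if (ai %% 2L == 1L) ai + 1L else ai - 1L
      env$cap[rev] <- env$cap[rev] + push
      v <- env$from[ai]
    }
    total <- total + push
  }
  total
}

# Flow on forward arc i = residual capacity accumulated on its partner.
.mcmf_flow <- function(env, i) env$cap[i + 1L]

#' Min-weight min-flow circulation with lower bounds
#'
#' Computes an integral circulation satisfying `lower(e) <= f(e) <= upper(e)`
#' and flow conservation at every node, minimizing first the flow on the
#' designated circulation arc and, among those, the total cost
#' `sum(cost(e) * f(e))`. The lexicographic objective is realized in a
#' single min-cost-flow solve by pricing the circulation arc above any
#' achievable total arc cost.
#'
#' @param arcs `data.frame` with columns `tail`, `head`, `lower`, `upper`,
#'   `cost` (node ids 1..n; `upper` may be `Inf`).
#' @param n_nodes Number of nodes.
#' @param circ Row index of the circulation arc in `arcs`.
#' @return `arcs` with an added integer `flow` column.
#' @export
min_cost_circulation <- function(arcs, n_nodes, circ) {
  m <- nrow(arcs)
  l1 <- sum(arcs$lower > 0)
  cap_inf <- max(1, l1)
  upper <- pmin(arcs$upper, pmax(cap_inf, arcs$lower))
  big_m <- 1 + sum(abs(arcs$cost[-circ]) * upper[-circ])
  cost <- arcs$cost
  cost[circ] <- big_m

  # Excess/deficit reduction of lower bounds.
  excess <- numeric(n_nodes)
  env <- .mcmf_new(n_nodes + 2L)
  S <- n_nodes + 1L; T <- n_nodes + 2L
  fwd <- integer(m)
  for (i in seq_len(m)) {
    lo <- arcs$lower[i]
    fwd[i] <- .mcmf_add_arc(env, arcs$tail[i], arcs$head[i], upper[i] - lo, cost[i])
    if (lo > 0) {
      excess[arcs$head[i]] <- excess[arcs$head[i]] + lo
      excess[arcs$tail[i]] <- excess[arcs$tail[i]] - lo
    }
  }
  need <- 0
  for (v in seq_len(n_nodes)) {
    if (excess[v] > 0) {
      .mcmf_add_arc(env, S, v, excess[v], 0)
      need <- need + excess[v]
    } else if (excess[v] < 0) {
      .mcmf_add_arc(env, v, T, -excess[v], 0)
    }
  }
  pushed <- .mcmf_run(env, S, T)
  if (pushed < need - 1e-6) {
    bad <- which(arcs$lower > 0)
    stop("infeasible flow network: lower bounds cannot be satisfied (",
         "check constrained arc(s) ",
         paste(arcs$tail[bad], "->", arcs$head[bad], collapse = ", "), ")")
  }
  arcs$flow <- round(vapply(fwd, function(i) .mcmf_flow(env, i), 0) + arcs$lower)
  arcs
}
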