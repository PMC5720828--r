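# Independent oracles: deliberately naive re-implementations used to verify
# the package's optimized code paths.

# Walk a CIGAR string position by position (M/D advance reference and
# aligned; N advances reference only). Independent of GenomicAlignments.
oracle_cigar_walk <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  ref <- pos
  blocks <- list()
  cur_start <- NA_integer_
  introns <- list()
  for (op in ops) {
    n <- as.integer(sub("[A-Z=]$", "", op))
    code <- sub("^[0-9]+", "", op)
    if (code %in% c("M", "=", "X", "D")) {
      if (is.na(cur_start)) cur_start <- ref
      ref <- ref + n
    } else if (code == "N") {
      blocks[[length(blocks) + 1L]] <- c(cur_start, ref - 1L)
      introns[[length(introns) + 1L]] <- c(ref, ref + n - 1L)
      cur_start <- NA_integer_
      ref <- ref + n
    }
    # I/S/H/P do not consume reference
  }
  if (!is.na(cur_start)) blocks[[length(blocks) + 1L]] <- c(cur_start, ref - 1L)
  list(blocks = do.call(rbind, blocks),
       introns = if (length(introns)) do.call(rbind, introns) else
         matrix(integer(0), ncol = 2L))
}

# Per-base coverage by explicit counting.
oracle_coverage <- function(block_list, from, to) {
  cov <- integer(to - from + 1L)
  for (b in block_list) {
    for (i in seq_len(nrow(b))) {
      lo <- max(b[i, 1L], from); hi <- min(b[i, 2L], to)
      if (lo <= hi) {
        idx <- (lo - from + 1L):(hi - from + 1L)
        cov[idx] <- cov[idx] + 1L
      }
    }
  }
  cov
}

# Brute-force subexon cutting: per-base membership, split at every
# donor/acceptor boundary.
oracle_cut <- function(prim, introns) {
  bases <- unlist(apply(prim, 1L, function(r) r[1L]:r[2L], simplify = FALSE))
  bases <- sort(unique(bases))
  cut_after <- sort(unique(c(introns$start - 1L, introns$end)))
  pieces <- list()
  cur <- bases[1L]
  for (i in seq_along(bases)[-1L]) {
    if (bases[i] != bases[i - 1L] + 1L || (bases[i - 1L] %in% cut_after)) {
      pieces[[length(pieces) + 1L]] <- c(cur, bases[i - 1L])
      cur <- bases[i]
    }
  }
  pieces[[length(pieces) + 1L]] <- c(cur, bases[length(bases)])
  do.call(rbind, pieces)
}

# Brute-force placement counting: per-base subexon lookup over every start.
oracle_placements <- function(path, chain, subexons, t, read_len,
                              single_end = FALSE) {
  widths <- subexons$width[chain]
  lab <- rep(chain, widths)      # transcript position -> subexon id
  L <- length(lab)
  if (t > L) return(0L)
  if (!single_end && t < 2L * read_len) return(0L)
  count <- 0L
  for (p in seq_len(L - t + 1L)) {
    touched <- if (single_end) lab[p:(p + t - 1L)] else
      lab[c(p:(p + read_len - 1L), (p + t - read_len):(p + t - 1L))]
    if (setequal(unique(touched), path)) count <- count + 1L
  }
  count
}

# --- Exhaustive constrained-path-cover oracle -------------------------------

# All (s,t)-paths of a splicing_graph as subexon chains.
oracle_all_paths <- function(graph) {
  ed <- graph$edges
  n <- nrow(graph$subexons)
  adj <- lapply(0:(n + 1L), function(v) ed$to[ed$from == v])
  res <- list()
  walk <- function(chain, v) {
    if (v == n + 1L) {
      res[[length(res) + 1L]] <<- chain
      return(invisible(NULL))
    }
    for (w in adj[[v + 1L]]) walk(c(chain, if (w <= n) w else integer(0)), w)
  }
  walk(integer(0), 0L)
  res
}

chain_has_sub <- function(chain, sub) {
  if (length(sub) > length(chain)) return(FALSE)
  for (s in seq_len(length(chain) - length(sub) + 1L)) {
    if (identical(as.integer(chain[s:(s + length(sub) - 1L)]), as.integer(sub)))
      return(TRUE)
  }
  FALSE
}

path_cost <- function(chain, graph) {
  ed <- graph$edges
  cost <- 0
  for (i in seq_len(length(chain) - 1L)) {
    j <- which(ed$from == chain[i] & ed$to == chain[i + 1L] &
                 ed$kind != "artificial")
    cost <- cost + ed$cost[j[1L]]
  }
  cost
}

# Minimum number of (s,t)-paths covering all nodes, all real edges, and all
# subpath constraints; among minimum-cardinality covers, the minimum total
# cost. Exhaustive search over subsets of the path set.
oracle_cmpc <- function(graph, constraints) {
  paths <- oracle_all_paths(graph)
  P <- length(paths)
  n <- nrow(graph$subexons)
  ed <- graph$edges[graph$edges$kind != "artificial", , drop = FALSE]
  edge_keys <- paste(ed$from, ed$to)
  covers_nodes <- lapply(paths, function(ch) unique(ch))
  covers_edges <- lapply(paths, function(ch) {
    if (length(ch) < 2L) return(character(0))
    paste(ch[-length(ch)], ch[-1L])
  })
  sat_cons <- lapply(paths, function(ch) {
    vapply(constraints, function(cs) chain_has_sub(ch, cs), TRUE)
  })
  costs <- vapply(paths, path_cost, 0, graph = graph)
  for (k in seq_len(P)) {
    best <- NULL
    for (idx in utils::combn(P, k, simplify = FALSE)) {
      nodes_ok <- length(unique(unlist(covers_nodes[idx]))) == n
      if (!nodes_ok) next
      edges_ok <- all(edge_keys %in% unlist(covers_edges[idx]))
      if (!edges_ok) next
      cons_ok <- if (length(constraints)) {
        all(Reduce(`|`, sat_cons[idx]))
      } else TRUE
      if (!cons_ok) next
      total <- sum(costs[idx])
      if (is.null(best) || total < best) best <- total
    }
    if (!is.null(best)) return(list(k = k, cost = best))
  }
  stop("no feasible cover (oracle)")
}

# Random DAG wrapped as a splicing_graph, with artificial source/target.
random_dag_graph <- function(seed, max_nodes = 8L, edge_p = 0.4) {
  set.seed(seed)
  n <- sample(4:max_nodes, 1L)
  e <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (runif(1) < edge_p) e[[length(e) + 1L]] <- c(i, j)
    }
  }
  # guarantee a spine so every node has a neighbour
  for (i in seq_len(n - 1L)) {
    if (!any(vapply(e, function(x) x[1L] == i, TRUE))) {
      e[[length(e) + 1L]] <- c(i, i + 1L)
    }
  }
  e <- unique(e)
  em <- do.call(rbind, e)
  em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  sub <- data.frame(id = seq_len(n),
                    start = seq(1L, by = 200L, length.out = n),
                    end = seq(1L, by = 200L, length.out = n) + 99L)
  sub$width <- 100L
  edges <- data.frame(from = as.integer(em[, 1L]), to = as.integer(em[, 2L]),
                      weight = sample(0:9, nrow(em), replace = TRUE),
                      kind = "intron")
  no_in <- setdiff(seq_len(n), edges$to)
  no_out <- setdiff(seq_len(n), edges$from)
  edges <- rbind(edges,
                 data.frame(from = 0L, to = no_in, weight = 0, kind = "artificial"),
                 data.frame(from = as.integer(no_out), to = n + 1L, weight = 0,
                            kind = "artificial"))
  g <- structure(list(chrom = "chrT", strand = "+", unstranded = FALSE,
                      subexons = sub, edges = edges),
                 class = "splicing_graph")
  transform_weights(g)
}

# Random multi-node constraints realizable in the graph (walks along edges).
random_constraints <- function(graph, n_cons, seed) {
  set.seed(seed)
  ed <- graph$edges[graph$edges$kind != "artificial", , drop = FALSE]
  n <- nrow(graph$subexons)
  adj <- lapply(seq_len(n), function(v) ed$to[ed$from == v])
  cons <- list()
  tries <- 0L
  while (length(cons) < n_cons && tries < 50L) {
    tries <- tries + 1L
    v <- sample.int(n, 1L)
    chain <- v
    for (step in 1:2) {
      nxt <- adj[[chain[length(chain)]]]
      if (!length(nxt)) break
      chain <- c(chain, if (length(nxt) == 1L) nxt else sample(nxt, 1L))
    }
    if (length(chain) >= 3L) cons[[length(cons) + 1L]] <- as.integer(chain)
  }
  unique(cons)
}

# Validity of a cover against the original graph and constraints.
expect_valid_cover <- function(cover, graph, constraints) {
  n <- nrow(graph$subexons)
  ed <- graph$edges[graph$edges$kind != "artificial", , drop = FALSE]
  covered_nodes <- unique(unlist(cover$paths))
  expect_setequal(covered_nodes, seq_len(n))
  edge_cov <- unlist(lapply(cover$paths, function(ch) {
    if (length(ch) < 2L) return(character(0))
    paste(ch[-length(ch)], ch[-1L])
  }))
  expect_true(all(paste(ed$from, ed$to) %in% edge_cov))
  for (cs in constraints) {
    expect_true(any(vapply(cover$paths, function(ch) chain_has_sub(ch, cs), TRUE)))
  }
  for (ch in cover$paths) {
    expect_true(all(paste(ch[-length(ch)], ch[-1L]) %in% paste(ed$from, ed$to)))
  }
}

# Full solve: graph + read constraints -> cover (implementation under test).
solve_cmpc <- function(graph, constraints) {
  p_sub <- grow_and_dedup(constraints, graph)
  net <- min_flow_circulation(transform_network(graph, p_sub))
  cover <- decompose_flow(net)
  cover$min_flow <- net$min_flow
  cover$expanded_cost <- sum(vapply(cover$paths, path_cost, 0, graph = graph))
  cover
}
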