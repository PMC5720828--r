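# Constrained minimum path cover on the splicing graph.
#
# An assembled transcript is an (s,t)-path through the splicing graph. The
# cover must touch every subexon, every edge, and contain every subpath
# constraint derived from read-pairs whose unsequenced insert spans
# non-adjacent subexons. The cover of minimum cardinality and, among those,
# minimum total cost is found by a min-weight min-flow circulation.

#' Subpath constraints from read-pairs
#'
#' Every read-pair is reduced to the ordered chain of subexons its aligned
#' bases touch. When two consecutive touched subexons are not adjacent in the
#' graph and the gap is the unsequenced insert between the mates, the
#' intermediate chain is inferred by enumerating all graph chains between the
#' two subexons and keeping those whose implied fragment length lies within
#' `frag_range`; the chain is filled in only if exactly one candidate
#' survives, otherwise the pair emits no constraint. Chains of three or more
#' subexons are returned (two-subexon chains duplicate plain edges, which
#' enter the constraint set separately).
#'
#' @param locus A `locus` object.
#' @param graph The `splicing_graph` of the locus.
#' @param frag_range Numeric length-2: plausible fragment-length bounds used
#'   to prune candidate chains (default no pruning).
#' @return A list of integer subexon-id chains (deduplicated).
#' @export
constraints_from_readpairs <- function(locus, graph, frag_range = c(0, Inf)) {
  sub <- graph$subexons
  n <- nrow(sub)
  if (n < 3L) return(list())
  real <- graph$edges[graph$edges$kind != "artificial", , drop = FALSE]
  adj <- lapply(seq_len(n), function(i) real$to[real$from == i])

  sub_ir <- IRanges::IRanges(sub$start, sub$end)
  rp <- locus$read_pairs
  out <- list()
  for (i in seq_len(nrow(rp))) {
    chain <- .pair_chain(rp[i, , drop = FALSE], sub, sub_ir, adj, frag_range)
    if (!is.null(chain) && length(chain) >= 3L) out[[length(out) + 1L]] <- chain
  }
  unique(out)
}

# Observed subexon chain of one pair, with unique interior fill; NULL if the
# pair is unassignable or ambiguous.
.pair_chain <- function(rp, sub, sub_ir, adj, frag_range) {
  blocks <- rp$blocks[[1L]]
  bl_ir <- IRanges::IRanges(blocks[, 1L], blocks[, 2L])
  hits <- IRanges::findOverlaps(bl_ir, sub_ir)
  if (length(hits) == 0L) return(NULL)
  # cond.2: every aligned base must fall inside the subexon set.
  cov <- IRanges::intersect(bl_ir, sub_ir)
  if (sum(BiocGenerics::width(cov)) != sum(BiocGenerics::width(bl_ir))) return(NULL)
  ids <- sort(unique(S4Vectors::subjectHits(hits)))
  if (length(ids) < 2L) return(NULL)

  # Genomic interval of the unsequenced insert (between the two mates).
  b1 <- rp$r1_blocks[[1L]]; b2 <- rp$r2_blocks[[1L]]
  mate_gap <- if (!is.null(b2) && min(b2[, 1L]) > max(b1[, 2L]) + 1L) {
    c(max(b1[, 2L]) + 1L, min(b2[, 1L]) - 1L)
  } else NULL

  chain <- ids[1L]
  for (k in seq_len(length(ids) - 1L)) {
    a <- ids[k]; b <- ids[k + 1L]
    if (b %in% adj[[a]]) {
      chain <- c(chain, b)
      next
    }
    # Non-adjacent: only an unsequenced insert spanning the gap justifies a
    # fill; a skip with no surviving intron edge makes the pair unusable.
    if (is.null(mate_gap) ||
        !(sub$end[a] >= mate_gap[1L] - 1L && sub$start[b] <= mate_gap[2L] + 1L)) {
      return(NULL)
    }
    cands <- .enumerate_chains(a, b, adj, limit = 64L)
    if (length(cands) == 0L) return(NULL)
    g1 <- min(rp$blocks[[1L]][, 1L]); g2 <- max(rp$blocks[[1L]][, 2L])
    ok <- vapply(cands, function(ch) {
      t_imp <- sum(pmax(0L, pmin(sub$end[ch], g2) - pmax(sub$start[ch], g1) + 1L))
      t_imp >= frag_range[1L] && t_imp <= frag_range[2L]
    }, TRUE)
    if (sum(ok) != 1L) return(NULL)
    fill <- cands[ok][[1L]]
    chain <- c(chain, fill[-1L])
  }
  chain
}

# All chains from a to b along graph edges (DFS; empty beyond `limit`).
.enumerate_chains <- function(a, b, adj, limit = 64L) {
  res <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == b) {
      res[[length(res) + 1L]] <<- path
      return(length(res) <= limit)
    }
    for (w in adj[[v]]) {
      if (w > b) next
      if (!walk(c(path, w))) return(FALSE)
    }
    TRUE
  }
  walk(a)
  if (length(res) > limit) list() else res
}

#' Grow the constraint set and drop contained constraints
#'
#' Every real edge of the graph enters the constraint set as a two-node
#' chain; duplicates are removed, any constraint that appears as a
#' consecutive subchain of another constraint is dropped, and multi-node
#' constraints that overlap by at least one shared edge (one's suffix is the
#' other's prefix) are glued into their union. The merge preserves
#' optimality: when two surviving constraints share an edge, suffixes of the
#' two covering paths can be exchanged at the end of the overlap without
#' changing the edge multiset, so some minimum-cost minimum-cardinality
#' cover has one path containing the union; representing the pair by
#' separate shortcut arcs would instead force two flow units through the
#' overlap, since a path cannot traverse two shortcut arcs whose spans
#' overlap. Constraints meeting only at a node need no merge: their arcs
#' chain consecutively.
#'
#' @param constraints List of integer chains from
#'   [constraints_from_readpairs()].
#' @param graph A `splicing_graph`.
#' @return Deduplicated list of integer chains (the constraint set).
#' @export
grow_and_dedup <- function(constraints, graph) {
  real <- graph$edges[graph$edges$kind != "artificial", , drop = FALSE]
  p_sub <- c(lapply(constraints, as.integer),
             lapply(seq_len(nrow(real)), function(i) c(real$from[i], real$to[i])))
  p_sub <- unique(lapply(p_sub, as.integer))
  drop_contained <- function(chains) {
    keep <- vapply(seq_along(chains), function(i) {
      !any(vapply(seq_along(chains), function(j) {
        i != j && .chain_contained(chains[[i]], chains[[j]])
      }, TRUE))
    }, TRUE)
    chains[keep]
  }
  p_sub <- drop_contained(p_sub)
  # Glue overlapping constraints (suffix of one = prefix of another).
  repeat {
    merged <- FALSE
    for (i in seq_along(p_sub)) {
      for (j in seq_along(p_sub)) {
        if (i == j) next
        a <- p_sub[[i]]; b <- p_sub[[j]]
        pos <- match(b[1L], a)
        if (is.na(pos)) next
        k <- length(a) - pos + 1L
        if (k < 2L) next          # single-node overlap: consecutive arcs chain
        if (k >= length(b)) next  # b would be contained (already handled)
        if (!identical(a[pos:length(a)], b[seq_len(k)])) next
        p_sub[[i]] <- c(a, b[-seq_len(k)])
        p_sub[[j]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  drop_contained(unique(p_sub))
}

# Is chain `a` a consecutive subchain of `b`?
.chain_contained <- function(a, b) {
  if (length(a) >= length(b)) return(FALSE)
  for (s in seq_len(length(b) - length(a) + 1L)) {
    if (identical(a, b[s:(s + length(a) - 1L)])) return(TRUE)
  }
  FALSE
}

#' Transform graph and constraints into a circulation network
#'
#' Applies the path-cover reduction: every subexon `v` is split into
#' `v_in -> v_out` with lower bound 1 (each node must be covered); graph
#' edges run between split halves with lower bound 1 when the edge is itself
#' a constraint and 0 otherwise; each multi-node constraint whose endpoints
#' are `u` and `v` adds a shortcut arc `u_out -> v_in` with lower bound 1 and
#' cost equal to the summed cost of the chain it replaces; artificial
#' source/target arcs have lower bound 0; a circulation arc closes the cycle
#' from target to source.
#'
#' @param graph A `splicing_graph` with costs (see [transform_weights()]).
#' @param p_sub Constraint set from [grow_and_dedup()].
#' @return A `flow_network`: `list(arcs, n_nodes, circ, n_sub, node_in,
#'   node_out)`; `arcs` carries an `expand` list-column mapping shortcut arcs
#'   back to their subexon chains.
#' @export
transform_network <- function(graph, p_sub) {
  sub <- graph$subexons
  n <- nrow(sub)
  stopifnot(n >= 1L)
  ed <- graph$edges
  if (is.null(ed$cost)) stop("call transform_weights() before transform_network()")
  node_in <- function(v) v
  node_out <- function(v) v + n
  s_id <- 2L * n + 1L
  t_id <- 2L * n + 2L

  edge_cost <- function(u, v) {
    i <- which(ed$from == u & ed$to == v & ed$kind != "artificial")
    if (length(i) == 0L) stop("constraint uses missing edge ", u, "->", v)
    ed$cost[i[1L]]
  }
  edge_chains <- Filter(function(p) length(p) == 2L, p_sub)
  edge_keys <- vapply(edge_chains, paste, "", collapse = ",")

  arcs <- list()
  add <- function(tail, head, lower, upper, cost, kind, expand = NULL) {
    arcs[[length(arcs) + 1L]] <<- list(tail = as.integer(tail),
                                       head = as.integer(head), lower = lower,
                                       upper = upper, cost = cost, kind = kind,
                                       expand = expand)
  }
  # A node interior to a multi-node constraint is necessarily covered by the
  # expansion of that constraint's shortcut arc (lower bound 1), so its own
  # coverage bound can be relaxed; forcing it would instead demand a second,
  # redundant path through the original edges the shortcut replaces.
  interior <- unique(unlist(lapply(Filter(function(p) length(p) > 2L, p_sub),
                                   function(p) p[-c(1L, length(p))])))
  for (v in seq_len(n)) {
    add(node_in(v), node_out(v), if (v %in% interior) 0 else 1, Inf, 0,
        "node", c(v))
  }
  for (i in seq_len(nrow(ed))) {
    u <- ed$from[i]; v <- ed$to[i]
    if (ed$kind[i] == "artificial") {
      if (u == 0L) add(s_id, node_in(v), 0, Inf, 0, "artificial")
      else add(node_out(u), t_id, 0, Inf, 0, "artificial")
    } else {
      lower <- as.integer(paste(u, v, sep = ",") %in% edge_keys)
      add(node_out(u), node_in(v), lower, Inf, ed$cost[i], "edge", c(u, v))
    }
  }
  for (p in Filter(function(p) length(p) > 2L, p_sub)) {
    cost <- sum(vapply(seq_len(length(p) - 1L),
                       function(k) edge_cost(p[k], p[k + 1L]), 0))
    add(node_out(p[1L]), node_in(p[length(p)]), 1, Inf, cost, "shortcut", p)
  }
  add(t_id, s_id, 0, Inf, 0, "circulation")

  df <- data.frame(tail = vapply(arcs, `[[`, 1L, "tail"),
                   head = vapply(arcs, `[[`, 1L, "head"),
                   lower = vapply(arcs, `[[`, 1, "lower"),
                   upper = vapply(arcs, `[[`, 1, "upper"),
                   cost = vapply(arcs, `[[`, 1, "cost"),
                   kind = vapply(arcs, `[[`, "", "kind"))
  df$expand <- lapply(arcs, `[[`, "expand")
  structure(list(arcs = df, n_nodes = t_id, circ = which(df$kind == "circulation"),
                 n_sub = n, s_id = s_id, t_id = t_id),
            class = "flow_network")
}

#' Solve the minimum-flow circulation of a network
#'
#' @param network A `flow_network` from [transform_network()].
#' @return The network with integral flows; element `min_flow` holds the flow
#'   on the circulation arc (the number of transcripts) and `cover_cost` the
#'   total cost over non-circulation arcs.
#' @export
min_flow_circulation <- function(network) {
  arcs <- min_cost_circulation(network$arcs, network$n_nodes, network$circ)
  network$arcs <- arcs
  network$min_flow <- arcs$flow[network$circ]
  network$cover_cost <- sum(arcs$cost[-network$circ] * arcs$flow[-network$circ])
  network
}

#' Greedy decomposition of the circulation into unit paths
#'
#' Extracts exactly `min_flow` source-to-target paths: from each node the arc
#' with the largest remaining flow is taken (ties broken toward the lowest
#' head subexon id), one unit is subtracted along the walk, and the expanded
#' subexon chain is recorded. After the last extraction all non-circulation
#' flow must be exhausted.
#'
#' @param network A solved `flow_network` (see [min_flow_circulation()]).
#' @return A `path_cover`: `list(paths, total_cost)` where `paths` is a list
#'   of integer subexon-id chains.
#' @export
decompose_flow <- function(network) {
  arcs <- network$arcs
  flow <- arcs$flow
  flow[network$circ] <- 0
  n_paths <- network$min_flow
  paths <- vector("list", n_paths)
  for (p in seq_len(n_paths)) {
    v <- network$s_id
    chain <- integer(0)
    while (v != network$t_id) {
      cand <- which(arcs$tail == v & flow > 0)
      if (length(cand) == 0L) stop("flow decomposition stuck at node ", v,
                                   ": conservation violated")
      cand <- cand[order(-flow[cand], arcs$head[cand])]
      ai <- cand[1L]
      ex <- arcs$expand[[ai]]
      if (!is.null(ex)) {
        chain <- c(chain, if (length(chain) && length(ex) &&
                              chain[length(chain)] == ex[1L]) ex[-1L] else ex)
      }
      flow[ai] <- flow[ai] - 1
      v <- arcs$head[ai]
    }
    paths[[p]] <- unique(chain)
  }
  if (any(flow > 1e-9)) stop("nonzero residual flow after ", n_paths,
                             " path extractions")
  structure(list(paths = paths, total_cost = network$cover_cost),
            class = "path_cover")
}

#' Assembled transcripts from a path cover
#'
#' Re-expands each covering path to genomic structure: consecutive
#' genomically adjacent subexons merge into exons, and gaps between
#' non-adjacent subexons in the chain become annotated introns.
#'
#' @param cover A `path_cover`.
#' @param graph The `splicing_graph` the cover was computed on.
#' @param locus_id Character scalar used to form transcript ids.
#' @return A `data.frame` with columns `transcript_id`, `chrom`, `strand`,
#'   `unstranded` and list-columns `exons` (start/end matrices), `introns`
#'   and `chain` (subexon ids).
#' @export
cover_to_transcripts <- function(cover, graph, locus_id = "locus1") {
  sub <- graph$subexons
  rows <- lapply(seq_along(cover$paths), function(i) {
    chain <- cover$paths[[i]]
    st <- sub$start[chain]; en <- sub$end[chain]
    new_exon <- c(TRUE, st[-1L] != en[-length(en)] + 1L)
    grp <- cumsum(new_exon)
    exons <- cbind(start = tapply(st, grp, min), end = tapply(en, grp, max))
    rownames(exons) <- NULL
    introns <- if (nrow(exons) > 1L) {
      cbind(start = exons[-nrow(exons), 2L] + 1L, end = exons[-1L, 1L] - 1L)
    } else matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
    list(exons = exons, introns = introns, chain = chain)
  })
  df <- data.frame(
    transcript_id = paste0(locus_id, ".", seq_along(rows)),
    chrom = graph$chrom, strand = graph$strand,
    unstranded = graph$unstranded, stringsAsFactors = FALSE)
  df$exons <- lapply(rows, `[[`, "exons")
  df$introns <- lapply(rows, `[[`, "introns")
  df$chain <- lapply(rows, `[[`, "chain")
  df
}

#' Assemble one locus end to end
#'
#' Convenience wrapper running graph construction, constraint extraction and
#' the constrained path cover for a single locus.
#'
#' @param locus A `locus` object.
#' @param read_len Read length in bp (for the intron filters).
#' @param params A [run_config()]-style list of tuning parameters.
#' @param locus_id Transcript id prefix.
#' @return As [cover_to_transcripts()], or `NULL` for an empty locus.
#' @export
assemble_locus <- function(locus, read_len, params = run_config(), locus_id = "locus1") {
  graph <- locus_graph(locus, read_len, params)
  if (is.null(graph) || nrow(graph$subexons) == 0L) return(NULL)
  cons <- constraints_from_readpairs(locus, graph, frag_range = params$frag_range)
  p_sub <- grow_and_dedup(cons, graph)
  net <- transform_network(graph, p_sub)
  net <- min_flow_circulation(net)
  cover <- decompose_flow(net)
  cover_to_transcripts(cover, graph, locus_id)
}

#' Build the filtered, weighted, cost-transformed graph of a locus
#'
#' @inheritParams assemble_locus
#' @return A `splicing_graph`, or `NULL` if the locus has no covered bases.
#' @export
locus_graph <- function(locus, read_len, params = run_config()) {
  prof <- coverage_profile(locus)
  prim <- primitive_exons(prof)
  if (nrow(prim) == 0L) return(NULL)
  introns <- collect_introns(locus, s = params$overhang)
  if (nrow(introns)) {
    introns <- introns[introns$end - introns$start + 1L <= params$max_intron, ,
                       drop = FALSE]
  }
  kept <- filter_introns(introns, read_len = read_len, s = params$overhang,
                         alpha = params$alpha)
  sub <- cut_subexons(prim, kept)
  g <- build_splicing_graph(sub, kept, locus, overlap_bp = params$overlap_bp)
  transform_weights(g)
}
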