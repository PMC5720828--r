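# Splicing-graph construction: coverage -> primitive exons; junctions ->
# introns; intron filters; subexon cutting; weighted DAG with artificial
# source (id 0) and target (id n+1).

#' Per-base coverage of a locus
#'
#' Coverage at a position is the number of aligned read blocks overlapping
#' it; unsequenced inserts and skipped introns contribute nothing.
#'
#' @param locus A `locus` object from [cluster_loci()].
#' @return A list with `start` (genomic offset) and `cov` (integer-`Rle`
#'   coverage over `[start, end]`).
#' @export
coverage_profile <- function(locus) {
  blocks <- do.call(rbind, locus$read_pairs$blocks)
  width <- locus$end - locus$start + 1L
  if (is.null(blocks) || nrow(blocks) == 0L) {
    return(list(start = locus$start, cov = S4Vectors::Rle(0L, width)))
  }
  ir <- IRanges::IRanges(start = blocks[, 1L] - locus$start + 1L,
                         end = blocks[, 2L] - locus$start + 1L)
  list(start = locus$start, cov = IRanges::coverage(ir, width = width))
}

#' Primitive exons from a coverage profile
#'
#' A primitive exon is a maximal run of positions with coverage greater than
#' zero.
#'
#' @param profile Output of [coverage_profile()].
#' @return A two-column matrix of genomic `start`/`end` intervals.
#' @export
primitive_exons <- function(profile) {
  ir <- IRanges::ranges(IRanges::slice(profile$cov, lower = 1L))
  m <- cbind(start = BiocGenerics::start(ir) + profile$start - 1L,
             end = BiocGenerics::end(ir) + profile$start - 1L)
  m[order(m[, 1L]), , drop = FALSE]
}

#' Collect introns from junction alignments
#'
#' One intron per distinct skipped interval, tallying the number of junction
#' reads (each mate carrying the skip counts once), the number of uniquely
#' aligned junction reads, and the number of small-overhang reads — junction
#' reads whose aligned segment on either side of the junction is at most `s`
#' bases.
#'
#' @param locus A `locus` object.
#' @param s Small-overhang distance in bp (default 6).
#' @return A `data.frame` with columns `start`, `end`, `total`, `unique`,
#'   `small_overhang`.
#' @export
collect_introns <- function(locus, s = 6L) {
  rp <- locus$read_pairs
  key <- character(); tot <- uni <- sm <- integer()
  tally <- new.env(parent = emptyenv())
  add <- function(a, b, is_unique, small) {
    k <- paste0(a, ":", b)
    cur <- tally[[k]]
    if (is.null(cur)) cur <- c(0L, 0L, 0L)
    tally[[k]] <- cur + c(1L, as.integer(is_unique), as.integer(small))
  }
  for (i in seq_len(nrow(rp))) {
    for (mate in list(rp$r1_blocks[[i]], rp$r2_blocks[[i]])) {
      if (is.null(mate) || nrow(mate) < 2L) next
      for (j in seq_len(nrow(mate) - 1L)) {
        a <- mate[j, 2L] + 1L
        b <- mate[j + 1L, 1L] - 1L
        left <- mate[j, 2L] - mate[j, 1L] + 1L
        right <- mate[j + 1L, 2L] - mate[j + 1L, 1L] + 1L
        add(a, b, rp$is_unique[i], min(left, right) <= s)
      }
    }
  }
  keys <- ls(tally)
  if (!length(keys)) {
    return(data.frame(start = integer(), end = integer(), total = integer(),
                      unique = integer(), small_overhang = integer()))
  }
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  vals <- do.call(rbind, lapply(keys, function(k) tally[[k]]))
  df <- data.frame(start = as.integer(parts[, 1L]), end = as.integer(parts[, 2L]),
                   total = vals[, 1L], unique = vals[, 2L], small_overhang = vals[, 3L])
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Small-overhang rejection threshold
#'
#' Under uniform read placement a junction read lands within `s` bases of the
#' junction on either side with probability `p = 2s / (l - 1)` (`l` = read
#' length), so the small-overhang count among `n` junction reads is
#' Bin(`n`, `p`). An intron is rejected when the observed count exceeds the
#' one-sided upper `1 - alpha` quantile; for `n > 100` the normal
#' approximation N(`np`, `np(1-p)`) is used.
#'
#' @param n Total junction reads supporting the intron.
#' @param read_len Read length `l` in bp.
#' @param s Small-overhang distance in bp.
#' @param alpha Significance level of the one-sided test.
#' @return The largest small-overhang count still accepted.
#' @export
small_overhang_threshold <- function(n, read_len, s = 6L, alpha = 0.001) {
  stopifnot(read_len > s)
  p <- 2 * s / (read_len - 1)
  if (n <= 100L) {
    qbinom(1 - alpha, n, p)
  } else {
    qnorm(1 - alpha, mean = n * p, sd = sqrt(n * p * (1 - p)))
  }
}

#' Filter putative introns
#'
#' Discards an intron when any of the following applies: (1) more than 70%
#' of its supporting junction reads are not uniquely aligned; (2) it overlaps
#' another intron whose expression (total junction reads) is more than twenty
#' times larger, i.e. its own expression is below 5% of the maximum
#' overlapping intron; (3) its small-overhang count exceeds the binomial
#' threshold of [small_overhang_threshold()]. All three rules are evaluated
#' against the unfiltered input set, so the outcome is order independent.
#'
#' @param introns Output of [collect_introns()].
#' @param read_len Read length in bp.
#' @param s Small-overhang distance in bp.
#' @param alpha Significance level for the small-overhang test.
#' @param max_multi_frac Maximum tolerated fraction of non-unique support.
#' @param min_overlap_frac Minimum expression relative to the strongest
#'   overlapping intron.
#' @return The kept subset of `introns`; dropped rows and their reasons are
#'   attached as attribute `"dropped"`.
#' @export
filter_introns <- function(introns, read_len, s = 6L, alpha = 0.001,
                           max_multi_frac = 0.7, min_overlap_frac = 0.05) {
  n <- nrow(introns)
  if (n == 0L) return(introns)
  drop <- character(n)

  multi_frac <- (introns$total - introns$unique) / introns$total
  drop[multi_frac > max_multi_frac] <- "multi_mapped"

  ir <- IRanges::IRanges(introns$start, introns$end)
  hits <- IRanges::findOverlaps(ir, ir)
  hits <- hits[S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)]
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    max_other <- tapply(introns$total[S4Vectors::subjectHits(hits)], qh, max)
    idx <- as.integer(names(max_other))
    low <- idx[introns$total[idx] < min_overlap_frac * max_other]
    drop[low[drop[low] == ""]] <- "overlap_low_expression"
  }

  thr <- vapply(introns$total, small_overhang_threshold, 0,
                read_len = read_len, s = s, alpha = alpha)
  bad <- introns$small_overhang > thr
  drop[bad & drop == ""] <- "small_overhang"

  kept <- introns[drop == "", , drop = FALSE]
  dropped <- introns[drop != "", , drop = FALSE]
  dropped$reason <- drop[drop != ""]
  attr(kept, "dropped") <- dropped
  rownames(kept) <- NULL
  kept
}

#' Cut primitive exons into subexons
#'
#' Each primitive exon is split at every kept-intron boundary falling
#' strictly inside it (after the last exonic base before a donor, and after
#' an acceptor's last intronic base), so that every resulting piece is either
#' fully contained in or fully excluded from any transcript. Covered pieces
#' are kept even when they lie inside an overlapping intron (retained or
#' alternative-boundary introns); uncovered intron interiors are never part
#' of a primitive exon in the first place. Intron boundaries falling outside
#' all primitive exons are ignored with a warning.
#'
#' @param prim Two-column matrix of primitive exon intervals.
#' @param introns Kept introns (`data.frame` with `start`, `end`).
#' @return A `data.frame` of subexons with columns `id`, `start`, `end`,
#'   `width`, ordered and numbered by genomic start.
#' @export
cut_subexons <- function(prim, introns) {
  if (is.null(prim) || nrow(prim) == 0L) {
    return(data.frame(id = integer(), start = integer(), end = integer(),
                      width = integer()))
  }
  # A donor at intron start a ends an exonic piece at a-1; an acceptor at
  # intron end b starts the next exonic piece at b+1. "Cut after" positions:
  cuts <- integer(0)
  if (nrow(introns)) {
    prim_ir <- IRanges::IRanges(prim[, 1L], prim[, 2L])
    for (i in seq_len(nrow(introns))) {
      a <- introns$start[i]; b <- introns$end[i]
      donor_in <- any(prim[, 1L] <= a - 1L & prim[, 2L] >= a - 1L)
      accept_in <- any(prim[, 1L] <= b + 1L & prim[, 2L] >= b + 1L)
      if (!donor_in && !accept_in) {
        warning("intron boundary [", a, ",", b, "] outside all primitive exons; ignored")
        next
      }
      cuts <- c(cuts, a - 1L, b)
    }
  }
  cuts <- sort(unique(cuts))
  rows <- list()
  for (i in seq_len(nrow(prim))) {
    a <- prim[i, 1L]; b <- prim[i, 2L]
    inner <- cuts[cuts >= a & cuts < b]
    starts <- c(a, inner + 1L)
    ends <- c(inner, b)
    rows[[i]] <- cbind(starts, ends)
  }
  m <- do.call(rbind, rows)
  m <- m[order(m[, 1L]), , drop = FALSE]
  data.frame(id = seq_len(nrow(m)), start = m[, 1L], end = m[, 2L],
             width = m[, 2L] - m[, 1L] + 1L)
}

#' Build the weighted splicing graph of a locus
#'
#' Nodes are the subexons (ids 1..n in genomic order) plus an artificial
#' source (0) and target (n+1). Genomically adjacent subexons are joined by a
#' non-intron edge weighted by the number of read-pairs with a contiguous
#' aligned block spanning the boundary by at least `overlap_bp` bases on each
#' side. Each kept intron becomes an intron edge between the subexon ending
#' at its donor and the subexon starting after its acceptor, weighted by the
#' total junction read count. The source connects to every subexon without an
#' incoming edge and the target collects every subexon without an outgoing
#' edge.
#'
#' @param subexons Output of [cut_subexons()].
#' @param introns Kept introns.
#' @param locus The `locus` the graph describes.
#' @param overlap_bp Minimum overlap into each subexon for non-intron edge
#'   support (default 6).
#' @return A `splicing_graph`: `list(chrom, strand, unstranded, subexons,
#'   edges)` where `edges` has columns `from`, `to`, `weight`, `kind`.
#' @export
build_splicing_graph <- function(subexons, introns, locus, overlap_bp = 6L) {
  n <- nrow(subexons)
  g <- structure(list(chrom = locus$chrom, strand = locus$strand,
                      unstranded = isTRUE(locus$unstranded),
                      subexons = subexons,
                      edges = data.frame(from = integer(), to = integer(),
                                         weight = numeric(), kind = character())),
                 class = "splicing_graph")
  if (n == 0L) return(g)

  # Mean coverage per subexon.
  prof <- coverage_profile(locus)
  cov <- as.integer(prof$cov)
  idx <- function(p) p - prof$start + 1L
  subexons$mean_cov <- vapply(seq_len(n), function(i) {
    mean(cov[idx(subexons$start[i]):idx(subexons$end[i])])
  }, 0)

  edges <- list()
  blocks_all <- locus$read_pairs$blocks
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (subexons$end[i] + 1L != subexons$start[i + 1L]) next
      bnd <- subexons$end[i]
      w <- sum(vapply(blocks_all, function(b) {
        any(b[, 1L] <= bnd - (overlap_bp - 1L) & b[, 2L] >= bnd + overlap_bp)
      }, TRUE))
      edges[[length(edges) + 1L]] <- data.frame(
        from = i, to = i + 1L, weight = w, kind = "non-intron")
    }
  }
  if (nrow(introns)) {
    for (i in seq_len(nrow(introns))) {
      from <- which(subexons$end == introns$start[i] - 1L)
      to <- which(subexons$start == introns$end[i] + 1L)
      if (length(from) != 1L || length(to) != 1L) {
        warning("intron [", introns$start[i], ",", introns$end[i],
                "] has no flanking subexons; skipped")
        next
      }
      edges[[length(edges) + 1L]] <- data.frame(
        from = from, to = to, weight = introns$total[i], kind = "intron")
    }
  }
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = integer(), to = integer(), weight = numeric(), kind = character())
  stopifnot(all(ed$from < ed$to))  # DAG by construction

  no_in <- setdiff(seq_len(n), ed$to)
  no_out <- setdiff(seq_len(n), ed$from)
  art <- rbind(
    data.frame(from = 0L, to = no_in, weight = 0, kind = "artificial"),
    data.frame(from = no_out, to = n + 1L, weight = 0, kind = "artificial"))
  ed <- rbind(ed, art)
  ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  rownames(ed) <- NULL
  g$subexons <- subexons
  g$edges <- ed
  g
}

#' Transform edge weights into nonnegative costs
#'
#' Read support is evidence for an edge, but the path-cover optimization
#' minimizes total cost, so weights are negated and shifted by the maximum
#' weight in the locus: `cost(e) = W_max - w(e)`. Heavily supported edges
#' become cheap; artificial edges cost nothing.
#'
#' @param graph A `splicing_graph`.
#' @return The graph with a `cost` column added to `edges`.
#' @export
transform_weights <- function(graph) {
  ed <- graph$edges
  if (nrow(ed) == 0L) {
    ed$cost <- numeric(0)
    graph$edges <- ed
    return(graph)
  }
  real <- ed$kind != "artificial"
  wmax <- if (any(real)) max(ed$weight[real]) else 0
  ed$cost <- ifelse(real, wmax - ed$weight, 0)
  graph$edges <- ed
  graph
}
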