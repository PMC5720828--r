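# Read-pair simulation on toy multi-isoform genes. The simulator emits
# alignment coordinates directly (the pipeline consumes alignments, not raw
# sequence), writing valid coordinate-sorted SAM with splice skips and
# transcription-strand tags on junction reads.

#' Construct a toy gene
#'
#' Subexons are laid left to right with the given intron gaps between
#' consecutive subexons (a gap of 0 makes them genomically adjacent).
#' Isoforms are chains over the subexons; molar proportions `eta` describe
#' the transcript mixture.
#'
#' @param subexon_widths Integer widths (bp).
#' @param gaps Integer gaps between consecutive subexons
#'   (length `length(subexon_widths) - 1`).
#' @param chains List of integer isoform chains.
#' @param eta Molar proportions (summing to 1).
#' @param chrom,strand,start Genomic placement.
#' @return A `toy_gene`: `list(chrom, strand, subexons, isoforms, eta, pi)`;
#'   `pi` are the fragment-level proportions `l_k eta_k / sum l_j eta_j`.
#' @export
make_toy_gene <- function(subexon_widths, gaps = rep(0L, length(subexon_widths) - 1L),
                          chains, eta, chrom = "chrT", strand = "+",
                          start = 101L) {
  m <- length(subexon_widths)
  stopifnot(length(gaps) == m - 1L, abs(sum(eta) - 1) < 1e-8,
            length(eta) == length(chains))
  starts <- integer(m); ends <- integer(m)
  pos <- start
  for (i in seq_len(m)) {
    starts[i] <- pos
    ends[i] <- pos + subexon_widths[i] - 1L
    pos <- ends[i] + 1L + if (i < m) gaps[i] else 0L
  }
  sub <- data.frame(id = seq_len(m), start = starts, end = ends,
                    width = subexon_widths)
  iso <- isoforms_from_chains(chains, sub)
  pi <- iso$lengths * eta
  structure(list(chrom = chrom, strand = strand, subexons = sub,
                 isoforms = iso, eta = eta, pi = pi / sum(pi)),
            class = "toy_gene")
}

#' The three-subexon exon-skipping toy gene
#'
#' Subexon widths 100, 60 and 100 bp; the inclusion isoform uses all three
#' (260 bp) and the skipping isoform omits the middle one (200 bp). This is
#' the canonical scene for placement counting: a 175 bp fragment with 50 bp
#' sequenced ends realizes the path touching only the outer subexons from 16
#' start positions on the inclusion isoform and 26 on the skipping isoform.
#'
#' @param eta Molar proportions of (inclusion, skipping).
#' @param gaps Genomic gaps flanking the middle subexon (defaults place all
#'   three subexons adjacently, so skipping implies a spliced junction over
#'   the middle subexon).
#' @return A `toy_gene`.
#' @export
toy_skipping_gene <- function(eta = c(0.5, 0.5), gaps = c(0L, 0L)) {
  make_toy_gene(c(100L, 60L, 100L), gaps = gaps,
                chains = list(c(1L, 2L, 3L), c(1L, 3L)), eta = eta)
}

# Map a transcript-coordinate interval [x, y] on an isoform chain to genomic
# blocks (two-column matrix).
.tx_to_genome <- function(x, y, chain, subexons) {
  w <- subexons$width[chain]
  bnd <- cumsum(w)
  off <- c(0L, bnd[-length(bnd)])
  rows <- list()
  for (i in seq_along(chain)) {
    lo <- max(x, off[i] + 1L); hi <- min(y, bnd[i])
    if (lo > hi) next
    gstart <- subexons$start[chain[i]] + (lo - off[i] - 1L)
    gend <- subexons$start[chain[i]] + (hi - off[i] - 1L)
    rows[[length(rows) + 1L]] <- c(gstart, gend)
  }
  m <- do.call(rbind, rows)
  # merge blocks that abut genomically (adjacent subexons)
  if (nrow(m) > 1L) {
    keep <- list(m[1L, ])
    for (i in 2L:nrow(m)) {
      last <- keep[[length(keep)]]
      if (m[i, 1L] == last[2L] + 1L) {
        keep[[length(keep)]][2L] <- m[i, 2L]
      } else {
        keep[[length(keep) + 1L]] <- m[i, ]
      }
    }
    m <- do.call(rbind, keep)
  }
  colnames(m) <- c("start", "end")
  m
}

.blocks_to_cigar <- function(blocks) {
  parts <- character(0)
  for (i in seq_len(nrow(blocks))) {
    if (i > 1L) {
      parts <- c(parts, paste0(blocks[i, 1L] - blocks[i - 1L, 2L] - 1L, "N"))
    }
    parts <- c(parts, paste0(blocks[i, 2L] - blocks[i, 1L] + 1L, "M"))
  }
  paste(parts, collapse = "")
}

#' Simulate read-pairs from a toy gene
#'
#' Fragments are drawn isoform by isoform with probability proportional to
#' `l_k * eta_k`, fragment length from `fld` (truncated to the isoform
#' length), and 5' start uniform over feasible positions. Mates of
#' `read_len` bp are emitted at both fragment ends with correct CIGARs
#' (match/skip) and a transcription-strand tag on junction reads. Isoforms
#' shorter than the smallest feasible fragment are excluded with a warning.
#' Deterministic given `seed`.
#'
#' @param gene A `toy_gene`.
#' @param n Number of read-pairs.
#' @param fld A `frag_dist`.
#' @param read_len Read length (bp).
#' @param seed Integer seed (required).
#' @param single_end Emit single reads instead of pairs.
#' @param prefix Query-name prefix.
#' @return `list(records, origin, frag_len, gene)` where `records` is a
#'   data.frame of SAM fields and `origin` the true isoform index per pair.
#' @export
simulate_read_pairs <- function(gene, n, fld, read_len = 50L, seed,
                                single_end = FALSE, prefix = "sim") {
  stopifnot(!missing(seed))
  set.seed(seed)
  iso <- gene$isoforms
  K <- length(iso$chains)
  min_frag <- if (single_end) read_len else
    max(2L * read_len, min(fld$lengths[fld$probs > 0]))
  usable <- iso$lengths >= min_frag
  if (!all(usable)) {
    warning("excluding ", sum(!usable), " isoform(s) shorter than the minimum fragment")
  }
  w <- gene$pi * usable
  if (sum(w) == 0) stop("no isoform can carry a fragment of the given length")
  w <- w / sum(w)

  origin <- sample.int(K, n, replace = TRUE, prob = w)
  # Fragment lengths drawn per isoform group (truncated support), starts
  # uniform over feasible positions; all vectorized.
  frag_len <- integer(n)
  start_p <- integer(n)
  for (k in unique(origin)) {
    idx <- which(origin == k)
    lk <- iso$lengths[k]
    ok <- which(fld$probs > 0 & fld$lengths <= lk &
                  fld$lengths >= (if (single_end) read_len else 2L * read_len))
    frag_len[idx] <- if (single_end) read_len else
      fld$lengths[ok[sample.int(length(ok), length(idx), replace = TRUE,
                                prob = fld$probs[ok])]]
    start_p[idx] <- 1L + floor(runif(length(idx)) * (lk - frag_len[idx] + 1L))
  }
  n_rec <- if (single_end) n else 2L * n
  qname_v <- character(n_rec); flag_v <- integer(n_rec); pos_v <- integer(n_rec)
  cigar_v <- character(n_rec); pnext_v <- integer(n_rec); tlen_v <- integer(n_rec)
  ri <- 0L
  emit <- function(qname, flag, blocks, mate) {
    ri <<- ri + 1L
    qname_v[ri] <<- qname; flag_v[ri] <<- flag; pos_v[ri] <<- blocks[1L, 1L]
    cigar_v[ri] <<- .blocks_to_cigar(blocks)
    if (is.null(mate)) {
      pnext_v[ri] <<- 0L; tlen_v[ri] <<- 0L
    } else {
      pnext_v[ri] <<- mate[1L, 1L]
      lo <- min(blocks[1L, 1L], mate[1L, 1L])
      hi <- max(blocks[nrow(blocks), 2L], mate[nrow(mate), 2L])
      tlen_v[ri] <<- if (blocks[1L, 1L] <= mate[1L, 1L]) hi - lo + 1L else
        -(hi - lo + 1L)
    }
  }
  for (i in seq_len(n)) {
    chain <- iso$chains[[origin[i]]]
    p <- start_p[i]; t <- frag_len[i]
    qname <- sprintf("%s%06d", prefix, i)
    if (single_end) {
      emit(qname, 0L, .tx_to_genome(p, p + read_len - 1L, chain, gene$subexons), NULL)
    } else {
      b1 <- .tx_to_genome(p, p + read_len - 1L, chain, gene$subexons)
      b2 <- .tx_to_genome(p + t - read_len, p + t - 1L, chain, gene$subexons)
      emit(qname, 99L, b1, b2)
      emit(qname, 147L, b2, b1)
    }
  }
  if (ri == 0L) {
    df <- data.frame(qname = character(), flag = integer(), rname = character(),
                     pos = integer(), mapq = integer(), cigar = character(),
                     rnext = character(), pnext = integer(), tlen = integer(),
                     seq = character(), qual = character(), tags = character(),
                     stringsAsFactors = FALSE)
    return(list(records = df, origin = origin, frag_len = frag_len, gene = gene))
  }
  spliced <- grepl("N", cigar_v, fixed = TRUE)
  df <- data.frame(qname = qname_v, flag = flag_v, rname = gene$chrom,
                   pos = pos_v, mapq = 60L, cigar = cigar_v,
                   rnext = ifelse(single_end, "*", "="), pnext = pnext_v,
                   tlen = tlen_v, seq = "*", qual = "*",
                   tags = paste0("NH:i:1",
                                 ifelse(spliced, paste0("\tXS:A:", gene$strand), "")),
                   stringsAsFactors = FALSE)[seq_len(ri), , drop = FALSE]
  if (single_end) df$rnext <- "*"
  df <- df[order(df$pos, df$qname, df$flag), , drop = FALSE]
  rownames(df) <- NULL
  list(records = df, origin = origin, frag_len = frag_len, gene = gene)
}

#' Write simulated records as SAM text
#'
#' @param sim Output of [simulate_read_pairs()] (or a compatible `records`
#'   data.frame via `sim = list(records = df, gene = gene)`).
#' @param path Output path (`.sam`).
#' @param seq_len Reference length for the header (defaults to span + 500).
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim, path, seq_len = NULL) {
  df <- sim$records
  gene <- sim$gene
  if (is.null(seq_len)) {
    seq_len <- if (nrow(df)) max(gene$subexons$end) + 500L else 1000L
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", gene$chrom, "\tLN:", seq_len))
  lines <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    lines[i] <- paste(df$qname[i], df$flag[i], df$rname[i], df$pos[i],
                      df$mapq[i], df$cigar[i], df$rnext[i], df$pnext[i],
                      df$tlen[i], df$seq[i], df$qual[i], df$tags[i],
                      sep = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Materialize simulated records as a read-pair table
#'
#' Builds the same `read_pairs` data frame [read_alignments()] would return
#' after a SAM round trip, directly from simulated records. Convenient for
#' large simulation studies; the SAM writer/reader path is exercised
#' separately.
#'
#' @param sim Output of [simulate_read_pairs()].
#' @return A `read_pairs` data frame.
#' @export
as_read_pairs <- function(sim) {
  df <- sim$records
  gene <- sim$gene
  if (nrow(df) == 0L) return(.empty_read_pairs())
  paired <- any(df$flag != 0L)
  first <- df[df$flag %in% c(0L, 99L), , drop = FALSE]
  # Vectorized block extraction: flatten the per-record ranges once instead
  # of dispatching on each element.
  cig_blocks <- function(cigar, pos) {
    irl <- GenomicAlignments::extractAlignmentRangesOnReference(
      cigar, pos = pos, drop.D.ranges = FALSE)
    nb <- S4Vectors::elementNROWS(irl)
    flat <- unlist(irl, use.names = FALSE)
    st <- split(BiocGenerics::start(flat), rep.int(seq_along(nb), nb))
    en <- split(BiocGenerics::end(flat), rep.int(seq_along(nb), nb))
    mapply(function(s, e) cbind(start = s, end = e), st, en, SIMPLIFY = FALSE)
  }
  gaps_of <- function(m) {
    if (nrow(m) < 2L) return(NULL)
    cbind(start = m[-nrow(m), 2L] + 1L, end = m[-1L, 1L] - 1L)
  }
  empty_introns <- matrix(integer(0), ncol = 2L,
                          dimnames = list(NULL, c("start", "end")))
  b1 <- cig_blocks(first$cigar, first$pos)
  if (paired) {
    second <- df[df$flag == 147L, , drop = FALSE]
    b2 <- cig_blocks(second$cigar, second$pos)[match(first$qname, second$qname)]
    n <- length(b1)
    comb_l <- vector("list", n)
    intr_l <- vector("list", n)
    for (i in seq_len(n)) {
      m1 <- b1[[i]]; m2 <- b2[[i]]
      if (m1[nrow(m1), 2L] + 1L < m2[1L, 1L]) {
        comb <- rbind(m1, m2)               # disjoint mates: fast path
      } else {
        comb <- rbind(m1, m2)
        comb <- comb[order(comb[, 1L]), , drop = FALSE]
        keep <- 1L
        for (r in 2L:nrow(comb)) {
          if (comb[r, 1L] <= comb[keep, 2L] + 1L) {
            comb[keep, 2L] <- max(comb[keep, 2L], comb[r, 2L])
          } else {
            keep <- keep + 1L
            comb[keep, ] <- comb[r, ]
          }
        }
        comb <- comb[seq_len(keep), , drop = FALSE]
      }
      comb_l[[i]] <- comb
      ir <- rbind(gaps_of(m1), gaps_of(m2))
      intr_l[[i]] <- if (is.null(ir)) empty_introns else
        unique(ir[order(ir[, 1L]), , drop = FALSE])
    }
    spliced <- grepl("N", first$cigar, fixed = TRUE) |
      grepl("N", second$cigar[match(first$qname, second$qname)], fixed = TRUE)
    res <- data.frame(qname = first$qname, chrom = gene$chrom,
                      strand = ifelse(spliced, gene$strand, "*"),
                      strand_conflict = FALSE,
                      start = vapply(comb_l, function(m) m[1L, 1L], 1L),
                      end = vapply(comb_l, function(m) m[nrow(m), 2L], 1L),
                      is_unique = TRUE, stringsAsFactors = FALSE)
    res$r1_blocks <- b1
    res$r2_blocks <- b2
    res$blocks <- comb_l
    res$introns <- intr_l
  } else {
    intr_l <- lapply(b1, function(m) {
      g <- gaps_of(m)
      if (is.null(g)) empty_introns else g
    })
    res <- data.frame(qname = first$qname, chrom = gene$chrom,
                      strand = ifelse(grepl("N", first$cigar, fixed = TRUE),
                                      gene$strand, "*"),
                      strand_conflict = FALSE,
                      start = vapply(b1, function(m) m[1L, 1L], 1L),
                      end = vapply(b1, function(m) m[nrow(m), 2L], 1L),
                      is_unique = TRUE, stringsAsFactors = FALSE)
    res$r1_blocks <- b1
    res$r2_blocks <- rep(list(NULL), nrow(res))
    res$blocks <- b1
    res$introns <- intr_l
  }
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("read_pairs", "data.frame")
  res
}

#' Random multi-isoform toy gene
#'
#' Builds a gene with `n_isoforms` distinguishable isoforms over
#' `n_isoforms + 2` subexons: the full chain plus chains each skipping a
#' distinct interior subexon (classic exon-skipping events). Subexon widths
#' are drawn between 80 and 250 bp, intron gaps between 100 and 300 bp, and
#' molar proportions from a symmetric Dirichlet floored at 0.08.
#'
#' @param n_isoforms Number of isoforms (2-4 covers the intended range).
#' @param seed Integer seed.
#' @return A `toy_gene`.
#' @export
random_toy_gene <- function(n_isoforms, seed) {
  set.seed(seed)
  m <- n_isoforms + 2L
  widths <- sample(80:250, m, replace = TRUE)
  gaps <- sample(100:300, m - 1L, replace = TRUE)
  chains <- c(list(seq_len(m)),
              lapply(seq_len(n_isoforms - 1L) + 1L,
                     function(drop) setdiff(seq_len(m), drop)))
  eta <- rgamma(n_isoforms, 1)
  eta <- pmax(eta / sum(eta), 0.08)
  eta <- eta / sum(eta)
  make_toy_gene(widths, gaps, chains, eta)
}
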