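#' @import methods
#' @importFrom stats qbinom qnorm dnorm rnorm cor var setNames runif
#' @importFrom utils head tail write.table read.delim
NULL

# Flag bits used when screening SAM/BAM records.
.FLAG_PAIRED <- 0x1L
.FLAG_UNMAPPED <- 0x4L
.FLAG_MATE_UNMAPPED <- 0x8L
.FLAG_REVERSE <- 0x10L
.FLAG_MATE_REVERSE <- 0x20L
.FLAG_FIRST <- 0x40L
.FLAG_LAST <- 0x80L
.FLAG_SECONDARY <- 0x100L
.FLAG_SUPPLEMENTARY <- 0x800L

.has_flag <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

#' Read spliced alignments into read-pairs
#'
#' Parses a coordinate-sorted SAM or BAM file and reduces each properly mated
#' paired-end alignment (or each single-end alignment) to its genomic
#' footprint: the aligned blocks of both mates, the introns implied by skip
#' (`N`) operations, the transcription strand suggested by the aligner's
#' splice-site tag (`XS`), and a uniqueness flag derived from the hit-count
#' tag (`NH`). Coordinates are 1-based closed throughout, matching the SAM
#' convention.
#'
#' Unmapped, secondary and supplementary records are skipped. Mates are
#' joined by query name; paired records whose mate is missing or unmapped are
#' dropped. Single-end records yield degenerate read-pairs whose second mate
#' is absent.
#'
#' @param path Path to a SAM (`.sam`) or BAM file, coordinate sorted.
#' @param region Optional `GRanges` (length 1) retaining only read-pairs whose
#'   fragment span overlaps it.
#' @return A `data.frame` of class `read_pairs`, one row per read-pair, with
#'   columns `qname`, `chrom`, `strand` (`"+"`, `"-"` or `"*"`),
#'   `strand_conflict`, `start`/`end` (fragment span), `is_unique`, and
#'   list-columns `r1_blocks`, `r2_blocks` (two-column start/end matrices;
#'   `r2_blocks` is `NULL` for single-end), `blocks` (both mates merged,
#'   disjoint and sorted) and `introns`.
#' @export
read_alignments <- function(path, region = NULL) {
  stopifnot(file.exists(path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = c("XS", "NH"))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0L) {
    return(.empty_read_pairs())
  }
  flag <- as.integer(res$flag)
  mapped <- !.has_flag(flag, .FLAG_UNMAPPED)
  # Coordinate-order check on mapped records, per reference run.
  .check_sorted(res$rname[mapped], res$pos[mapped], res$qname[mapped])
  keep <- mapped & !.has_flag(flag, .FLAG_SECONDARY) & !.has_flag(flag, .FLAG_SUPPLEMENTARY)
  if (!any(keep)) return(.empty_read_pairs())

  qname <- res$qname[keep]
  flag <- flag[keep]
  rname <- as.character(res$rname)[keep]
  pos <- res$pos[keep]
  cigar <- res$cigar[keep]
  xs <- res$tag$XS[keep]
  nh <- res$tag$NH[keep]
  if (is.null(xs)) xs <- rep(NA_character_, length(qname))
  if (is.null(nh)) nh <- rep(NA_integer_, length(qname))

  block_list <- GenomicAlignments::extractAlignmentRangesOnReference(
    cigar, pos = pos, drop.D.ranges = FALSE)
  intron_list <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = "N")
  if (!any(S4Vectors::elementNROWS(intron_list) > 0L)) {
    warning("no spliced alignment found in ", basename(path))
  }

  paired <- .has_flag(flag, .FLAG_PAIRED)
  rp <- .pair_records(qname, flag, rname, pos, xs, nh, block_list, intron_list, paired)
  if (!is.null(region)) {
    stopifnot(length(region) == 1L)
    keep_rp <- rp$chrom == as.character(GenomicRanges::seqnames(region)) &
      rp$start <= GenomicRanges::end(region) & rp$end >= GenomicRanges::start(region)
    rp <- rp[keep_rp, , drop = FALSE]
  }
  rp
}

.empty_read_pairs <- function() {
  df <- data.frame(qname = character(), chrom = character(), strand = character(),
                   strand_conflict = logical(), start = integer(), end = integer(),
                   is_unique = logical(), stringsAsFactors = FALSE)
  df$r1_blocks <- list()
  df$r2_blocks <- list()
  df$blocks <- list()
  df$introns <- list()
  class(df) <- c("read_pairs", "data.frame")
  df
}

.check_sorted <- function(rname, pos, qname) {
  if (length(pos) < 2L) return(invisible(TRUE))
  rname <- as.character(rname)
  same <- rname[-1L] == rname[-length(rname)]
  bad <- which(same & pos[-1L] < pos[-length(pos)])
  if (length(bad)) {
    stop("input is not coordinate-sorted: record '", qname[bad[1L] + 1L],
         "' at ", rname[bad[1L] + 1L], ":", pos[bad[1L] + 1L],
         " follows position ", pos[bad[1L]])
  }
  invisible(TRUE)
}

.ranges_to_matrix <- function(ir) {
  cbind(start = BiocGenerics::start(ir), end = BiocGenerics::end(ir))
}

#' Combine the transcription-strand tags of the two mates
#'
#' Junction reads typically carry an `XS` tag giving the transcription strand
#' inferred from splice-site dinucleotides. A read-pair's strand is the tag
#' found on either mate; mates carrying conflicting tags are flagged and the
#' strand is reported unknown (`"*"`).
#'
#' @param tag1,tag2 `XS` tag values of the two mates (`NA` if absent).
#' @return A list with elements `strand` and `conflict`.
#' @export
infer_strand <- function(tag1, tag2 = NA_character_) {
  tags <- c(tag1, tag2)
  tags <- tags[!is.na(tags) & tags %in% c("+", "-")]
  tags <- unique(tags)
  if (length(tags) == 0L) return(list(strand = "*", conflict = FALSE))
  if (length(tags) > 1L) return(list(strand = "*", conflict = TRUE))
  list(strand = tags, conflict = FALSE)
}

.pair_records <- function(qname, flag, rname, pos, xs, nh, block_list, intron_list, paired) {
  is_uni <- is.na(nh) | nh == 1L
  rows <- list()
  # Single-end records: one degenerate read-pair each.
  se_idx <- which(!paired)
  for (i in se_idx) {
    b <- .ranges_to_matrix(block_list[[i]])
    ir <- .ranges_to_matrix(intron_list[[i]])
    st <- infer_strand(xs[i])
    rows[[length(rows) + 1L]] <- list(
      qname = qname[i], chrom = rname[i], strand = st$strand,
      strand_conflict = st$conflict, start = min(b[, 1L]), end = max(b[, 2L]),
      is_unique = is_uni[i], r1_blocks = b, r2_blocks = NULL,
      blocks = b, introns = ir)
  }
  pe_idx <- which(paired & !.has_flag(flag, .FLAG_MATE_UNMAPPED))
  if (length(pe_idx)) {
    grp <- split(pe_idx, qname[pe_idx])
    for (g in grp) {
      if (length(g) != 2L) next  # mate missing: not properly mated
      g <- g[order(pos[g])]
      i <- g[1L]; j <- g[2L]
      if (rname[i] != rname[j]) next
      b1 <- .ranges_to_matrix(block_list[[i]])
      b2 <- .ranges_to_matrix(block_list[[j]])
      comb <- IRanges::reduce(IRanges::IRanges(
        start = c(b1[, 1L], b2[, 1L]), end = c(b1[, 2L], b2[, 2L])))
      ir1 <- .ranges_to_matrix(intron_list[[i]])
      ir2 <- .ranges_to_matrix(intron_list[[j]])
      ir <- unique(rbind(ir1, ir2))
      ir <- ir[order(ir[, 1L]), , drop = FALSE]
      st <- infer_strand(xs[i], xs[j])
      rows[[length(rows) + 1L]] <- list(
        qname = qname[i], chrom = rname[i], strand = st$strand,
        strand_conflict = st$conflict,
        start = min(b1[, 1L]), end = max(b2[, 2L]),
        is_unique = is_uni[i] && is_uni[j],
        r1_blocks = b1, r2_blocks = b2,
        blocks = .ranges_to_matrix(comb), introns = ir)
    }
  }
  if (!length(rows)) return(.empty_read_pairs())
  df <- data.frame(
    qname = vapply(rows, `[[`, "", "qname"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    strand_conflict = vapply(rows, `[[`, TRUE, "strand_conflict"),
    start = vapply(rows, `[[`, 1L, "start"),
    end = vapply(rows, `[[`, 1L, "end"),
    is_unique = vapply(rows, `[[`, TRUE, "is_unique"),
    stringsAsFactors = FALSE)
  df$r1_blocks <- lapply(rows, `[[`, "r1_blocks")
  df$r2_blocks <- lapply(rows, `[[`, "r2_blocks")
  df$blocks <- lapply(rows, `[[`, "blocks")
  df$introns <- lapply(rows, `[[`, "introns")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("read_pairs", "data.frame")
  df
}

#' Oriented 4-tuple of a read-pair
#'
#' Returns the genomic positions of the upstream and downstream reads' 5' and
#' 3' ends (`u5`, `u3`, `d5`, `d3`) in transcription direction. For unknown
#' strand the plus orientation is used.
#'
#' @param rp A one-row subset of a `read_pairs` data frame.
#' @export
read_pair_tuple <- function(rp) {
  b1 <- rp$r1_blocks[[1L]]
  b2 <- rp$r2_blocks[[1L]]
  if (is.null(b2)) b2 <- b1
  s1 <- c(min(b1[, 1L]), max(b1[, 2L]))
  s2 <- c(min(b2[, 1L]), max(b2[, 2L]))
  if (identical(rp$strand, "-")) {
    c(u5 = s2[2L], u3 = s2[1L], d5 = s1[2L], d3 = s1[1L])
  } else {
    c(u5 = s1[1L], u3 = s1[2L], d5 = s2[1L], d3 = s2[2L])
  }
}

#' Are two read-pairs compatible?
#'
#' Two read-pairs are incompatible when they imply two different introns that
#' overlap each other: no single isoform can generate both. Read-pairs
#' without introns, or sharing identical introns, are compatible.
#'
#' @param r1,r2 One-row subsets of a `read_pairs` data frame (same locus).
#' @return `TRUE` if the two read-pairs can arise from the same transcript.
#' @export
are_compatible <- function(r1, r2) {
  i1 <- if (is.data.frame(r1)) r1$introns[[1L]] else r1
  i2 <- if (is.data.frame(r2)) r2$introns[[1L]] else r2
  if (is.null(i1) || is.null(i2) || nrow(i1) == 0L || nrow(i2) == 0L) return(TRUE)
  for (a in seq_len(nrow(i1))) {
    for (b in seq_len(nrow(i2))) {
      same <- i1[a, 1L] == i2[b, 1L] && i1[a, 2L] == i2[b, 2L]
      overlap <- i1[a, 1L] <= i2[b, 2L] && i2[b, 1L] <= i1[a, 2L]
      if (overlap && !same) return(FALSE)
    }
  }
  TRUE
}

#' Cluster read-pairs into loci
#'
#' Consecutive read-pairs whose fragment spans are separated by more than
#' `max_gap` bases of zero coverage start a new locus; a gap of exactly
#' `max_gap` keeps them together. Within a positional cluster, read-pairs
#' carrying conflicting transcription-strand tags are separated into one
#' locus per strand; untagged pairs are assigned to the strand with more
#' tagged support (ties and fully untagged clusters go to `"+"`, flagged as
#' unstranded).
#'
#' @param rp A `read_pairs` data frame (coordinate sorted).
#' @param max_gap Maximum zero-coverage gap (bp) bridged within one locus.
#' @return A list of `locus` objects: `list(chrom, start, end, strand,
#'   unstranded, read_pairs)`.
#' @export
cluster_loci <- function(rp, max_gap = 50L) {
  if (nrow(rp) == 0L) return(list())
  out <- list()
  for (chr in unique(rp$chrom)) {
    sub <- rp[rp$chrom == chr, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    run_end <- cummax(sub$end)
    new_cluster <- c(TRUE, sub$start[-1L] - run_end[-nrow(sub)] - 1L > max_gap)
    cl <- cumsum(new_cluster)
    for (k in unique(cl)) {
      part <- sub[cl == k, , drop = FALSE]
      out <- c(out, .split_cluster_by_strand(part))
    }
  }
  out
}

.split_cluster_by_strand <- function(part) {
  tags <- part$strand[part$strand %in% c("+", "-")]
  make_locus <- function(df, strand, unstranded) {
    structure(list(chrom = df$chrom[1L], start = min(df$start), end = max(df$end),
                   strand = strand, unstranded = unstranded, read_pairs = df),
              class = "locus")
  }
  if (length(unique(tags)) <= 1L) {
    strand <- if (length(tags)) tags[1L] else "+"
    return(list(make_locus(part, strand, length(tags) == 0L)))
  }
  # Both strands present: split tagged pairs, untagged follow the majority.
  major <- names(sort(table(tags), decreasing = TRUE))[1L]
  assign <- ifelse(part$strand %in% c("+", "-"), part$strand, major)
  lapply(c("+", "-"), function(s) {
    df <- part[assign == s, , drop = FALSE]
    make_locus(df, s, FALSE)
  })
}
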