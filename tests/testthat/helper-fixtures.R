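# Shared fixture builders: hand-written SAM files and in-memory loci.

write_sam_lines <- function(records, path, chrom = "chrT", len = 100000L) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", chrom, "\tLN:", len))
  writeLines(c(header, records), path)
  path
}

# One SAM line from components; unspecified fields get neutral values.
sam_line <- function(qname, flag, pos, cigar, chrom = "chrT", mapq = 60L,
                     rnext = "*", pnext = 0L, tlen = 0L, tags = "NH:i:1") {
  paste(qname, flag, chrom, pos, mapq, cigar, rnext, pnext, tlen, "*", "*",
        tags, sep = "\t")
}

# A proper pair (both mates forward-block CIGARs).
sam_pair <- function(qname, pos1, cigar1, pos2, cigar2, tags1 = "NH:i:1",
                     tags2 = "NH:i:1", chrom = "chrT") {
  c(sam_line(qname, 99L, pos1, cigar1, chrom, rnext = "=", pnext = pos2, tags = tags1),
    sam_line(qname, 147L, pos2, cigar2, chrom, rnext = "=", pnext = pos1, tags = tags2))
}

# Build a minimal read_pairs row directly (bypassing SAM) for unit tests.
make_rp <- function(blocks1, blocks2 = NULL, strand = "*", is_unique = TRUE,
                    qname = "q", chrom = "chrT") {
  b1 <- matrix(blocks1, ncol = 2L, byrow = TRUE,
               dimnames = list(NULL, c("start", "end")))
  b2 <- if (!is.null(blocks2)) {
    matrix(blocks2, ncol = 2L, byrow = TRUE,
           dimnames = list(NULL, c("start", "end")))
  } else NULL
  all_b <- rbind(b1, b2)
  all_b <- all_b[order(all_b[, 1L]), , drop = FALSE]
  intr <- function(m) {
    if (is.null(m) || nrow(m) < 2L) return(NULL)
    cbind(start = m[-nrow(m), 2L] + 1L, end = m[-1L, 1L] - 1L)
  }
  introns <- unique(rbind(intr(b1), intr(b2)))
  if (is.null(introns)) {
    introns <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  }
  df <- data.frame(qname = qname, chrom = chrom, strand = strand,
                   strand_conflict = FALSE, start = min(all_b[, 1L]),
                   end = max(all_b[, 2L]), is_unique = is_unique,
                   stringsAsFactors = FALSE)
  df$r1_blocks <- list(b1)
  df$r2_blocks <- list(b2)
  df$blocks <- list(all_b)
  df$introns <- list(introns)
  class(df) <- c("read_pairs", "data.frame")
  df
}

make_locus <- function(rp_list, strand = "+") {
  df <- do.call(rbind, rp_list)
  class(df) <- c("read_pairs", "data.frame")
  structure(list(chrom = df$chrom[1L], start = min(df$start),
                 end = max(df$end), strand = strand, unstranded = FALSE,
                 read_pairs = df),
            class = "locus")
}

# Standard two-isoform simulation scene used across tests: exon skipping
# with junction coverage for both isoforms.
sim_skipping_scene <- function(n = 1500L, eta = c(0.6, 0.4), seed = 7L) {
  gene <- toy_skipping_gene(eta = eta, gaps = c(150L, 150L))
  fld <- frag_dist_empirical(setNames(rep(0.25, 4), c(110, 130, 150, 170)))
  sim <- simulate_read_pairs(gene, n, fld, read_len = 50L, seed = seed)
  list(gene = gene, fld = fld, sim = sim)
}
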