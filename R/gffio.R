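# GFF3 input/output via rtracklayer.

#' Write transcripts to GFF3
#'
#' Emits gene, transcript and exon features with `ID`/`Parent` links;
#' abundance columns (`FPKM`, `TPM`, `frac`) present in the table are
#' attached as transcript attributes.
#'
#' @param transcripts Transcript table with columns `transcript_id`, `chrom`,
#'   `strand` and list-column `exons`; optional `gene_id`, `FPKM`, `TPM`,
#'   `frac`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_gff3 <- function(transcripts, path) {
  if (nrow(transcripts) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  tx <- transcripts
  if (is.null(tx$gene_id)) tx$gene_id <- sub("\\.[0-9]+$", "", tx$transcript_id)
  tx_start <- vapply(tx$exons, function(m) min(m[, 1L]), 1L)
  tx_end <- vapply(tx$exons, function(m) max(m[, 2L]), 1L)

  genes <- unique(tx$gene_id)
  g_rows <- lapply(genes, function(g) {
    i <- tx$gene_id == g
    data.frame(chrom = tx$chrom[which(i)[1L]], start = min(tx_start[i]),
               end = max(tx_end[i]), strand = tx$strand[which(i)[1L]],
               type = "gene", ID = g, Parent = NA_character_,
               stringsAsFactors = FALSE)
  })
  t_rows <- lapply(seq_len(nrow(tx)), function(i) {
    data.frame(chrom = tx$chrom[i], start = tx_start[i], end = tx_end[i],
               strand = tx$strand[i], type = "transcript",
               ID = tx$transcript_id[i], Parent = tx$gene_id[i],
               stringsAsFactors = FALSE)
  })
  e_rows <- lapply(seq_len(nrow(tx)), function(i) {
    m <- tx$exons[[i]]
    data.frame(chrom = tx$chrom[i], start = m[, 1L], end = m[, 2L],
               strand = tx$strand[i], type = "exon",
               ID = paste0(tx$transcript_id[i], ".exon", seq_len(nrow(m))),
               Parent = tx$transcript_id[i], stringsAsFactors = FALSE)
  })
  feat <- do.call(rbind, c(g_rows, t_rows, e_rows))
  gr <- GenomicRanges::GRanges(
    seqnames = feat$chrom,
    ranges = IRanges::IRanges(feat$start, feat$end),
    strand = feat$strand)
  S4Vectors::mcols(gr)$type <- feat$type
  S4Vectors::mcols(gr)$ID <- feat$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(feat$Parent), "", feat$Parent)
  for (col in c("FPKM", "TPM", "frac")) {
    if (!is.null(tx[[col]])) {
      v <- rep(NA_character_, length(gr))
      is_tx <- feat$type == "transcript"
      v[is_tx] <- sprintf("%.6f", tx[[col]][match(feat$ID[is_tx], tx$transcript_id)])
      S4Vectors::mcols(gr)[[col]] <- v
    }
  }
  # Order: gene, then its transcripts, then exons, by coordinate.
  ord <- order(feat$chrom, feat$start,
               match(feat$type, c("gene", "transcript", "exon")), feat$ID)
  gr <- gr[ord]
  empty_parent <- S4Vectors::mcols(gr)$Parent == ""
  S4Vectors::mcols(gr)$Parent <- ifelse(empty_parent, NA_character_,
                                        S4Vectors::mcols(gr)$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read transcripts from GFF3/GTF
#'
#' @param path Annotation path.
#' @return Transcript table with `transcript_id`, `gene_id`, `chrom`,
#'   `strand` and list-columns `exons` and `introns`.
#' @export
read_transcripts_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  is_exon <- tolower(as.character(md$type)) == "exon"
  ex <- gr[is_exon]
  exm <- S4Vectors::mcols(ex)
  parent <- if (!is.null(exm$Parent)) {
    vapply(as.list(exm$Parent), function(p) if (length(p)) p[[1L]] else NA_character_, "")
  } else if (!is.null(exm$transcript_id)) {
    as.character(exm$transcript_id)
  } else stop("exon features carry neither Parent nor transcript_id")

  tx_meta <- gr[tolower(as.character(md$type)) %in%
                  c("transcript", "mrna", "mRNA")]
  tid_of <- function(x) {
    m <- S4Vectors::mcols(x)
    if (!is.null(m$ID)) as.character(m$ID) else as.character(m$transcript_id)
  }
  gene_of <- setNames(rep(NA_character_, length(tx_meta)), tid_of(tx_meta))
  mtx <- S4Vectors::mcols(tx_meta)
  if (!is.null(mtx$Parent)) {
    gene_of[] <- vapply(as.list(mtx$Parent),
                        function(p) if (length(p)) p[[1L]] else NA_character_, "")
  } else if (!is.null(mtx$gene_id)) {
    gene_of[] <- as.character(mtx$gene_id)
  }

  ids <- unique(parent)
  rows <- lapply(ids, function(id) {
    sub <- ex[parent == id]
    sub <- sub[order(BiocGenerics::start(sub))]
    m <- cbind(start = BiocGenerics::start(sub), end = BiocGenerics::end(sub))
    introns <- if (nrow(m) > 1L) {
      cbind(start = m[-nrow(m), 2L] + 1L, end = m[-1L, 1L] - 1L)
    } else matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
    list(chrom = as.character(GenomicRanges::seqnames(sub))[1L],
         strand = as.character(BiocGenerics::strand(sub))[1L],
         exons = m, introns = introns)
  })
  df <- data.frame(
    transcript_id = ids,
    gene_id = ifelse(is.na(gene_of[ids]) | !(ids %in% names(gene_of)),
                     ids, gene_of[ids]),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "+"
  df$exons <- lapply(rows, `[[`, "exons")
  df$introns <- lapply(rows, `[[`, "introns")
  rownames(df) <- NULL
  df
}
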