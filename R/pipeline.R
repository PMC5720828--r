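# End-to-end pipeline: assemble + quantify, or quantify only against an
# annotation. Loci are processed independently in deterministic order; the
# whole pipeline is deterministic given input and configuration.

#' Pipeline configuration
#'
#' @param mode `"assemble"` (assemble then quantify) or `"quant"`
#'   (quantification only; requires `annotation`).
#' @param max_intron Maximum intron length in bp; longer skips are dropped
#'   before filtering (default 300000).
#' @param overhang Small-overhang distance `s` in bp (default 6).
#' @param overlap_bp Minimum overlap into each subexon for non-intron edge
#'   support (default 6).
#' @param alpha Significance level of the small-overhang intron filter
#'   (default 0.001).
#' @param max_gap Locus clustering gap in bp (default 50).
#' @param tol,max_iter EM convergence controls.
#' @param frag_mean,frag_sd Gaussian fragment-length fallback (bp), required
#'   for single-end input or when no single-isoform region exists.
#' @param frag_range Fragment-length bounds used to resolve paired-gap
#'   subpath constraints (default derived from the fragment distribution).
#' @param read_len Read length in bp; inferred from the alignments when
#'   `NULL`.
#' @param seed Integer seed applied before processing (the pipeline itself
#'   draws no random numbers; the seed guards any future stochastic step).
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("assemble", "quant"), max_intron = 300000L,
                       overhang = 6L, overlap_bp = 6L, alpha = 0.001,
                       max_gap = 50L, tol = 1e-6, max_iter = 1000L,
                       frag_mean = NULL, frag_sd = NULL, frag_range = c(0, Inf),
                       read_len = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(max_intron > 0, overhang > 0, overlap_bp > 0, alpha > 0,
            max_gap >= 0, tol > 0, max_iter > 0)
  list(mode = mode, max_intron = max_intron, overhang = overhang,
       overlap_bp = overlap_bp, alpha = alpha, max_gap = max_gap, tol = tol,
       max_iter = max_iter, frag_mean = frag_mean, frag_sd = frag_sd,
       frag_range = frag_range, read_len = read_len, seed = seed)
}

.infer_read_len <- function(rp) {
  w <- unlist(lapply(c(rp$r1_blocks, Filter(Negate(is.null), rp$r2_blocks)),
                     function(b) sum(b[, 2L] - b[, 1L] + 1L)))
  as.integer(names(sort(table(w), decreasing = TRUE))[1L])
}

#' Run the full pipeline
#'
#' Reads alignments, learns the fragment-length distribution, clusters
#' loci, assembles transcripts (or loads them from an annotation), and
#' estimates abundances, writing a GFF3 with `FPKM`, `TPM` and `frac`
#' attributes plus a mirror TSV.
#'
#' @param bam Path to a coordinate-sorted SAM/BAM file.
#' @param out Output GFF3 path (a `.tsv` sibling is written alongside).
#' @param annotation GFF3/GTF path (required in `"quant"` mode).
#' @param config A [run_config()] list.
#' @return The transcript table with abundances, invisibly.
#' @export
run_pipeline <- function(bam, out, annotation = NULL,
                         config = run_config()) {
  set.seed(config$seed)
  if (config$mode == "quant" && is.null(annotation)) {
    stop("quantification-only mode requires an annotation GFF")
  }
  rp <- read_alignments(bam)
  if (nrow(rp) == 0L) {
    message("no usable alignments; writing empty output")
    writeLines("##gff-version 3", out)
    return(invisible(NULL))
  }
  single_end <- all(vapply(rp$r2_blocks, is.null, TRUE))
  read_len <- if (is.null(config$read_len)) .infer_read_len(rp) else config$read_len

  fld <- if (!single_end) learn_fragment_dist(rp, max_gap = config$max_gap) else NULL
  if (is.null(fld)) {
    if (is.null(config$frag_mean) || is.null(config$frag_sd)) {
      stop("no single-isoform region to learn the fragment distribution from; ",
           "supply frag_mean and frag_sd")
    }
    fld <- frag_dist_gaussian(config$frag_mean, config$frag_sd,
                              read_len = if (single_end) NULL else read_len)
  }
  frag_range <- config$frag_range
  if (!all(is.finite(frag_range))) {
    frag_range <- range(fld$lengths[fld$probs > 1e-6])
  }
  params <- config
  params$frag_range <- frag_range

  n_total <- nrow(rp)
  results <- list()
  if (config$mode == "assemble") {
    loci <- cluster_loci(rp, max_gap = config$max_gap)
    message(length(loci), " loci")
    for (li in seq_along(loci)) {
      loc <- loci[[li]]
      locus_id <- sprintf("locus%04d", li)
      tx <- tryCatch(assemble_locus(loc, read_len, params, locus_id),
                     error = function(e) {
                       warning("locus ", locus_id, " skipped: ", conditionMessage(e))
                       NULL
                     })
      if (is.null(tx) || nrow(tx) == 0L) next
      graph <- locus_graph(loc, read_len, params)
      iso <- isoforms_from_chains(tx$chain, graph$subexons, ids = tx$transcript_id)
      q <- quantify_locus(iso, loc$read_pairs, fld, read_len,
                          single_end = single_end, n_total_mapped = n_total,
                          tol = config$tol, max_iter = config$max_iter)
      results[[length(results) + 1L]] <- .merge_quant(tx, q, locus_id)
    }
  } else {
    ann <- read_transcripts_gff3(annotation)
    groups <- .annotation_loci(ann)
    message(length(groups), " annotated loci")
    for (li in seq_along(groups)) {
      idx <- groups[[li]]
      locus_id <- sprintf("locus%04d", li)
      sub_ann <- ann[idx, , drop = FALSE]
      iso <- isoforms_from_exons(sub_ann$exons, ids = sub_ann$transcript_id)
      span <- c(min(vapply(sub_ann$exons, function(m) min(m[, 1L]), 1L)),
                max(vapply(sub_ann$exons, function(m) max(m[, 2L]), 1L)))
      sel <- rp$chrom == sub_ann$chrom[1L] & rp$start <= span[2L] & rp$end >= span[1L]
      if (!any(sel)) next
      q <- quantify_locus(iso, rp[sel, , drop = FALSE], fld, read_len,
                          single_end = single_end, n_total_mapped = n_total,
                          tol = config$tol, max_iter = config$max_iter)
      if (is.null(q)) next
      tx <- sub_ann
      tx$chain <- iso$chains
      results[[length(results) + 1L]] <- .merge_quant(tx, q, locus_id)
    }
  }
  if (!length(results)) {
    message("no transcripts; writing empty output")
    writeLines("##gff-version 3", out)
    return(invisible(NULL))
  }
  all_tx <- do.call(rbind, results)
  all_tx <- finalize_tpm(all_tx)
  write_transcripts_gff3(all_tx, out)
  tsv <- sub("\\.gff3?$", ".tsv", out)
  if (tsv == out) tsv <- paste0(out, ".tsv")
  write.table(all_tx[, c("transcript_id", "gene_id", "chrom", "strand",
                         "frac", "eta", "assigned", "FPKM", "TPM")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(all_tx)
}

.merge_quant <- function(tx, q, locus_id) {
  ab <- q$abundance
  m <- match(tx$transcript_id, ab$transcript_id)
  tx$gene_id <- locus_id
  tx$frac <- ab$frac[m]
  tx$eta <- ab$eta[m]
  tx$assigned <- ab$assigned[m]
  tx$FPKM <- ab$FPKM[m]
  tx$tpm_rate <- ab$tpm_rate[m]
  message(locus_id, ": ", nrow(tx), " transcript(s), ",
          q$em$n_iter, " EM iteration(s)")
  tx
}

# Group annotation transcripts into loci of mutually overlapping spans.
.annotation_loci <- function(ann) {
  spans <- data.frame(
    chrom = ann$chrom,
    start = vapply(ann$exons, function(m) min(m[, 1L]), 1L),
    end = vapply(ann$exons, function(m) max(m[, 2L]), 1L))
  groups <- list()
  for (chr in unique(spans$chrom)) {
    idx <- which(spans$chrom == chr)
    idx <- idx[order(spans$start[idx])]
    cur <- idx[1L]; cur_end <- spans$end[idx[1L]]
    for (i in idx[-1L]) {
      if (spans$start[i] <= cur_end) {
        cur <- c(cur, i); cur_end <- max(cur_end, spans$end[i])
      } else {
        groups[[length(groups) + 1L]] <- cur
        cur <- i; cur_end <- spans$end[i]
      }
    }
    groups[[length(groups) + 1L]] <- cur
  }
  groups
}

#' Assemble and quantify
#' @param bam,out,config See [run_pipeline()].
#' @export
assemble <- function(bam, out, config = run_config(mode = "assemble")) {
  config$mode <- "assemble"
  run_pipeline(bam, out, config = config)
}

#' Quantify against an annotation
#' @param bam,gff,out,config See [run_pipeline()].
#' @export
quantify <- function(bam, gff, out, config = run_config(mode = "quant")) {
  config$mode <- "quant"
  run_pipeline(bam, out, annotation = gff, config = config)
}
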