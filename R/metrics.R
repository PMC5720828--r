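# Evaluation statistics: proportionality correlation, Spearman correlation,
# mean absolute relative difference, and transcript-level intron-chain
# matching.

#' Proportionality correlation of two expression vectors
#'
#' `rho_p = 2 Cov(log(x+1), log(y+1)) / (Var(log(x+1)) + Var(log(y+1)))`.
#' Values are incremented by one before the log transform so zeros stay
#' finite. Equals 1 iff the two log vectors differ by a constant and have
#' equal variance; never exceeds 1.
#'
#' @param x,y Nonnegative expression vectors (e.g. FPKM), equal length >= 2.
#' @return The proportionality correlation.
#' @export
proportionality_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("need at least two paired values")
  lx <- log(x + 1); ly <- log(y + 1)
  denom <- var(lx) + var(ly)
  if (denom == 0) stop("zero total variance: proportionality undefined")
  2 * cov(lx, ly) / denom
}

#' @importFrom stats cov
NULL

#' Mean absolute relative difference
#'
#' `ARD_i = |x_i - y_i| / (0.5 |x_i + y_i|)`, defined as 0 when both values
#' are 0; bounded in `[0, 2]`. MARD is the mean over transcripts.
#'
#' @param x,y Nonnegative vectors of equal length.
#' @param summarize If `FALSE`, return the per-transcript ARD vector.
#' @return MARD (or the ARD vector).
#' @export
mard <- function(x, y, summarize = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  denom <- 0.5 * abs(x + y)
  ard <- ifelse(denom == 0, 0, abs(x - y) / denom)
  if (summarize) mean(ard) else ard
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (delegated to
#' [stats::cor()]).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Spearman's rho.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (var(x) == 0 || var(y) == 0) stop("constant vector: rank correlation undefined")
  cor(x, y, method = "spearman")
}

#' Harmonic mean of recall and precision
#' @param recall,precision Values in `[0, 1]`.
#' @export
f1_score <- function(recall, precision) {
  if (recall + precision == 0) return(0)
  2 * recall * precision / (recall + precision)
}

.intron_chain_key <- function(chrom, strand, introns) {
  if (is.null(introns) || nrow(introns) == 0L) return(NA_character_)
  paste0(chrom, strand, ":",
         paste(introns[, 1L], introns[, 2L], sep = "-", collapse = ","))
}

#' Transcript-level intron-chain matching
#'
#' A predicted multi-exon transcript is correct when its ordered set of
#' introns equals some reference transcript's introns exactly; differences
#' confined to the first and last exon boundaries are ignored. Mono-exon
#' transcripts match by exon overlap on the same strand. Recall is
#' correct/|reference| and precision correct/|predicted|.
#'
#' @param predicted,reference Transcript tables with columns `chrom`,
#'   `strand` and list-columns `exons` and `introns` (as produced by
#'   [cover_to_transcripts()] or [read_transcripts_gff3()]).
#' @return `list(recall, precision, f1, n_correct, matched)`; `matched` is a
#'   logical vector over predictions.
#' @export
match_intron_chains <- function(predicted, reference) {
  ref_keys <- vapply(seq_len(nrow(reference)), function(i) {
    .intron_chain_key(reference$chrom[i], reference$strand[i],
                      reference$introns[[i]])
  }, "")
  ref_mono <- which(is.na(ref_keys))
  matched <- logical(nrow(predicted))
  for (i in seq_len(nrow(predicted))) {
    key <- .intron_chain_key(predicted$chrom[i], predicted$strand[i],
                             predicted$introns[[i]])
    if (!is.na(key)) {
      matched[i] <- key %in% ref_keys
    } else if (length(ref_mono)) {
      ex <- predicted$exons[[i]]
      matched[i] <- any(vapply(ref_mono, function(j) {
        rx <- reference$exons[[j]]
        reference$chrom[j] == predicted$chrom[i] &&
          reference$strand[j] == predicted$strand[i] &&
          rx[1L, 1L] <= ex[1L, 2L] && ex[1L, 1L] <= rx[1L, 2L]
      }, TRUE))
    }
  }
  # Each reference transcript is credited at most once.
  pred_keys <- vapply(seq_len(nrow(predicted)), function(i) {
    .intron_chain_key(predicted$chrom[i], predicted$strand[i],
                      predicted$introns[[i]])
  }, "")
  correct_refs <- sum(!is.na(ref_keys) & ref_keys %in% pred_keys[matched]) +
    sum(vapply(ref_mono, function(j) {
      rx <- reference$exons[[j]]
      any(matched & is.na(pred_keys) &
            predicted$chrom == reference$chrom[j] &
            predicted$strand == reference$strand[j] &
            vapply(predicted$exons, function(ex) {
              rx[1L, 1L] <= ex[1L, 2L] && ex[1L, 1L] <= rx[1L, 2L]
            }, TRUE))
    }, TRUE))
  recall <- if (nrow(reference)) correct_refs / nrow(reference) else NA_real_
  precision <- if (nrow(predicted)) sum(matched) / nrow(predicted) else NA_real_
  list(recall = recall, precision = precision,
       f1 = f1_score(recall, precision), n_correct = sum(matched),
       matched = matched)
}
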