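# Quantification: collapse read-pairs to subexon-path counts, build the
# isoform/path compatibility matrix, initialize the conditional
# probabilities from feasible fragment placements, and run the latent-class
# EM to estimate isoform proportions, FPKM and TPM.

#' Construct an isoform set over a subexon table
#'
#' @param chains List of integer subexon-id chains (strictly increasing).
#' @param subexons Subexon table (`id`, `start`, `end`, `width`).
#' @param ids Optional character transcript ids.
#' @return An `isoform_set`: `list(chains, lengths, ids, exons)`.
#' @export
isoforms_from_chains <- function(chains, subexons, ids = NULL) {
  stopifnot(all(vapply(chains, function(ch) all(diff(ch) > 0L), TRUE)))
  if (is.null(ids)) ids <- paste0("iso", seq_along(chains))
  exons <- lapply(chains, function(ch) {
    st <- subexons$start[ch]; en <- subexons$end[ch]
    grp <- cumsum(c(TRUE, st[-1L] != en[-length(en)] + 1L))
    m <- cbind(start = tapply(st, grp, min), end = tapply(en, grp, max))
    rownames(m) <- NULL
    m
  })
  lengths <- vapply(chains, function(ch) sum(subexons$width[ch]), 0)
  structure(list(chains = chains, lengths = lengths, ids = ids, exons = exons,
                 subexons = subexons),
            class = "isoform_set")
}

#' Subexons and chains induced by an annotation
#'
#' Reduces a set of (possibly overlapping) isoforms to a splicing-graph
#' segmentation: exons are cut at every internal exon boundary of any
#' isoform, and each isoform becomes a chain over the resulting subexons.
#' This is the quantification-only entry point when transcripts come from a
#' GFF3 annotation rather than from assembly.
#'
#' @param exon_list List of two-column exon matrices, one per isoform.
#' @param ids Optional transcript ids.
#' @return An `isoform_set` whose `subexons` element is the induced table.
#' @export
isoforms_from_exons <- function(exon_list, ids = NULL) {
  all_ir <- IRanges::IRanges(
    start = unlist(lapply(exon_list, function(m) m[, 1L])),
    end = unlist(lapply(exon_list, function(m) m[, 2L])))
  pieces <- IRanges::disjoin(all_ir)
  pieces <- pieces[order(BiocGenerics::start(pieces))]
  sub <- data.frame(id = seq_along(pieces),
                    start = BiocGenerics::start(pieces),
                    end = BiocGenerics::end(pieces))
  sub$width <- sub$end - sub$start + 1L
  chains <- lapply(exon_list, function(m) {
    hits <- IRanges::findOverlaps(pieces, IRanges::IRanges(m[, 1L], m[, 2L]),
                                  type = "within")
    sort(unique(S4Vectors::queryHits(hits)))
  })
  isoforms_from_chains(chains, sub, ids)
}

#' Assign read-pairs to subexon paths
#'
#' A read-pair belongs to the subexon path consisting of exactly the
#' subexons its aligned bases touch, provided every aligned base falls
#' inside some subexon; pairs with aligned bases outside all subexons (for
#' example overhanging into an intron) are unassignable (`NA`).
#'
#' @param rp A `read_pairs` data frame.
#' @param subexons Subexon table.
#' @return Character vector of path keys (ids joined by `"-"`), `NA` for
#'   unassignable pairs.
#' @export
assign_paths <- function(rp, subexons) {
  n <- nrow(rp)
  if (n == 0L) return(character(0))
  nb <- vapply(rp$blocks, nrow, 1L)
  blocks <- do.call(rbind, rp$blocks)
  pair_of_block <- rep(seq_len(n), nb)
  bl_ir <- IRanges::IRanges(blocks[, 1L], blocks[, 2L])
  sub_ir <- IRanges::IRanges(subexons$start, subexons$end)
  ov <- IRanges::findOverlaps(bl_ir, sub_ir)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  cov_w <- pmin(blocks[qh, 2L], subexons$end[sh]) -
    pmax(blocks[qh, 1L], subexons$start[sh]) + 1L
  cov_per_block <- rep(0L, length(bl_ir))
  agg <- tapply(cov_w, qh, sum)
  cov_per_block[as.integer(names(agg))] <- as.integer(agg)
  block_ok <- cov_per_block == BiocGenerics::width(bl_ir)
  pair_ok <- as.logical(tapply(block_ok, pair_of_block, all))

  keys <- rep(NA_character_, n)
  touched <- split(subexons$id[sh], pair_of_block[qh])
  for (nm in names(touched)) {
    i <- as.integer(nm)
    if (isTRUE(pair_ok[as.character(i)]) || isTRUE(pair_ok[i])) {
      keys[i] <- paste(sort(unique(touched[[nm]])), collapse = "-")
    }
  }
  keys
}

#' Collapse read-pairs into subexon-path counts
#'
#' @param rp A `read_pairs` data frame.
#' @param subexons Subexon table.
#' @return A `data.frame` with list-column `path` (integer subexon ids) and
#'   `count`; the number of unassignable pairs is attached as attribute
#'   `"unassigned"`.
#' @export
collapse_counts <- function(rp, subexons) {
  keys <- assign_paths(rp, subexons)
  tab <- table(keys, useNA = "no")
  df <- data.frame(key = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$path <- lapply(strsplit(df$key, "-", fixed = TRUE), as.integer)
  ord <- order(vapply(df$path, `[`, 1L, 1L),
               vapply(df$path, function(p) p[length(p)], 1L))
  df <- df[ord, c("key", "path", "count")]
  rownames(df) <- NULL
  attr(df, "unassigned") <- sum(is.na(keys))
  df
}

# Number of 5' start positions on an isoform at which a fragment of length t
# (two sequenced ends of read_len bp, or a single read) induces exactly the
# target index set. Vectorized over all start positions.
.placements_vec <- function(chain_widths, target_idx, t, read_len,
                            single_end = FALSE) {
  m <- length(chain_widths)
  bnd <- cumsum(chain_widths)
  L <- bnd[m]
  if (t > L) return(0L)
  if (!single_end && t < 2L * read_len) return(0L)
  tsize <- length(target_idx)
  ind <- integer(m); ind[target_idx] <- 1L
  pre <- c(0L, cumsum(ind))
  p <- seq_len(L - t + 1L)
  if (single_end) {
    a <- findInterval(p - 1L, bnd) + 1L
    b <- findInterval(p + t - 2L, bnd) + 1L
    covered <- pre[b + 1L] - pre[a]
    usize <- b - a + 1L
    return(sum(covered == tsize & usize == tsize))
  }
  a1 <- findInterval(p - 1L, bnd) + 1L
  b1 <- findInterval(p + read_len - 2L, bnd) + 1L
  a2 <- findInterval(p + t - read_len - 1L, bnd) + 1L
  b2 <- findInterval(p + t - 2L, bnd) + 1L
  ovl <- ifelse(a2 <= b1, b1 - a2 + 1L, 0L)
  covered <- (pre[b1 + 1L] - pre[a1]) + (pre[b2 + 1L] - pre[a2]) -
    ifelse(a2 <= b1, pre[b1 + 1L] - pre[a2], 0L)
  usize <- (b1 - a1 + 1L) + (b2 - a2 + 1L) - ovl
  sum(covered == tsize & usize == tsize)
}

#' Count feasible fragment placements
#'
#' Enumerates the 5' start positions on isoform `k` at which a fragment of
#' total length `t` — two `read_len` bp sequenced ends with an unsequenced
#' interior (or a single read in single-end mode) — touches exactly the
#' subexons of path `l`, with every interior subexon of the isoform between
#' them bridged by the unsequenced gap.
#'
#' @param path Integer subexon ids of the path.
#' @param chain Integer subexon ids of the isoform.
#' @param subexons Subexon table supplying widths.
#' @param t Fragment length (bp).
#' @param read_len Read length (bp).
#' @param single_end Logical; treat the fragment as a single sequenced read.
#' @return Integer placement count (`n_klt`).
#' @export
count_placements <- function(path, chain, subexons, t, read_len,
                             single_end = FALSE) {
  idx <- match(path, chain)
  if (anyNA(idx)) return(0L)
  widths <- subexons$width[chain]
  .placements_vec(widths, idx, t, read_len, single_end)
}

#' Empirical fragment-length distribution
#'
#' @param lengths Integer fragment lengths (one per observed fragment), or a
#'   named numeric vector of probabilities (names are lengths).
#' @return A `frag_dist` object: `list(type, lengths, probs, mean, sd)`.
#' @export
frag_dist_empirical <- function(lengths) {
  if (!is.null(names(lengths))) {
    len <- as.integer(names(lengths)); pr <- as.numeric(lengths)
  } else {
    tab <- table(lengths)
    len <- as.integer(names(tab)); pr <- as.numeric(tab)
  }
  pr <- pr / sum(pr)
  mu <- sum(len * pr)
  structure(list(type = "empirical", lengths = len, probs = pr, mean = mu,
                 sd = sqrt(sum(pr * (len - mu)^2))),
            class = "frag_dist")
}

#' Discretized Gaussian fragment-length distribution
#'
#' Fallback when no empirical distribution can be learned (for example for
#' single-end input): a Gaussian with user-supplied mean and standard
#' deviation, discretized on integers and truncated to
#' `[min_len, max_len]`.
#'
#' @param mean,sd Gaussian parameters in bp.
#' @param min_len,max_len Truncation bounds (bp); `min_len` defaults to
#'   twice the read length when supplied via `read_len`.
#' @param read_len Optional read length used for the default `min_len`.
#' @return A `frag_dist` object.
#' @export
frag_dist_gaussian <- function(mean, sd, min_len = NULL, max_len = NULL,
                               read_len = NULL) {
  if (is.null(min_len)) {
    min_len <- if (!is.null(read_len)) 2L * read_len else
      max(1L, floor(mean - 4 * sd))
  }
  if (is.null(max_len)) max_len <- ceiling(mean + 4 * sd)
  len <- seq.int(min_len, max_len)
  pr <- dnorm(len, mean, sd)
  if (sum(pr) <= 0) stop("degenerate Gaussian fragment distribution")
  pr <- pr / sum(pr)
  structure(list(type = "gaussian", lengths = len, probs = pr, mean = mean,
                 sd = sd), class = "frag_dist")
}

#' Learn the fragment-length distribution from alignments
#'
#' Pools read-pairs from loci longer than `min_span` bp showing no
#' alternative splicing (no two overlapping introns); the fragment length of
#' a pair is its genomic span minus any intron it straddles. If no such
#' region exists (or for single-end input) a user Gaussian must be supplied
#' downstream.
#'
#' @param rp A `read_pairs` data frame.
#' @param min_span Minimum locus span in bp (default 2000).
#' @param max_gap Locus clustering gap.
#' @return A `frag_dist`, or `NULL` when no qualifying pair exists.
#' @export
learn_fragment_dist <- function(rp, min_span = 2000L, max_gap = 50L) {
  paired <- !vapply(rp$r2_blocks, is.null, TRUE)
  if (!any(paired)) return(NULL)
  loci <- cluster_loci(rp[paired, , drop = FALSE], max_gap = max_gap)
  lens <- integer(0)
  for (loc in loci) {
    if (loc$end - loc$start + 1L < min_span) next
    introns <- collect_introns(loc)
    if (nrow(introns) > 1L) {
      ir <- IRanges::IRanges(introns$start, introns$end)
      self <- IRanges::findOverlaps(ir, ir)
      if (length(self) > length(ir)) next  # overlapping introns: alt splicing
    }
    sub <- loc$read_pairs
    for (i in seq_len(nrow(sub))) {
      span <- sub$end[i] - sub$start[i] + 1L
      if (nrow(introns)) {
        inside <- introns$start > sub$start[i] & introns$end < sub$end[i]
        if (any(inside)) {
          # subtract introns straddled by the pair (spliced-out sequence)
          blocks <- sub$blocks[[i]]
          for (j in which(inside)) {
            hit_block <- any(blocks[, 1L] <= introns$end[j] &
                             blocks[, 2L] >= introns$start[j])
            if (!hit_block) span <- span - (introns$end[j] - introns$start[j] + 1L)
          }
        }
      }
      lens <- c(lens, span)
    }
  }
  if (!length(lens)) return(NULL)
  frag_dist_empirical(lens)
}

#' Compatibility matrix between isoforms and subexon paths
#'
#' `C[k, l] = 1` when isoform `k` can generate subexon path `l`: the path is
#' a subsequence of the isoform's chain and at least one fragment length
#' with positive probability admits a placement realizing exactly that path.
#'
#' @param isoforms An `isoform_set`.
#' @param paths List of integer subexon-id paths.
#' @param fld A `frag_dist`.
#' @param read_len Read length (bp).
#' @param single_end Logical.
#' @return Binary matrix with one row per isoform, one column per path.
#' @export
compat_matrix <- function(isoforms, paths, fld, read_len, single_end = FALSE) {
  K <- length(isoforms$chains); L <- length(paths)
  C <- matrix(0L, K, L, dimnames = list(isoforms$ids, NULL))
  support <- fld$lengths[fld$probs > 0]
  support <- support[order(-fld$probs[fld$probs > 0])]
  for (k in seq_len(K)) {
    chain <- isoforms$chains[[k]]
    for (l in seq_len(L)) {
      if (!all(paths[[l]] %in% chain)) next
      for (t in support) {
        if (count_placements(paths[[l]], chain, isoforms$subexons, t,
                             read_len, single_end) > 0L) {
          C[k, l] <- 1L
          break
        }
      }
    }
  }
  C
}

#' Initialize the latent-class parameters
#'
#' Class probabilities start uniform. The conditional probability that a
#' fragment from isoform `k` realizes path `l` starts at the total sample
#' rate of all potential placements, observed or not:
#' `sum_t q(t) * n_klt / (l_k - t + 1)`, then each isoform's row is
#' normalized over the observed paths so the one-trial multinomial is well
#' defined. Isoforms unable to generate any observed path are removed with a
#' warning.
#'
#' @param isoforms An `isoform_set`.
#' @param paths List of observed paths.
#' @param fld A `frag_dist`.
#' @param read_len Read length (bp).
#' @param single_end Logical.
#' @return `list(pi0, theta0, theta_raw, C, keep)` where `keep` indexes the
#'   surviving isoforms.
#' @export
init_params <- function(isoforms, paths, fld, read_len, single_end = FALSE) {
  K <- length(isoforms$chains); L <- length(paths)
  support <- fld$lengths[fld$probs > 0]
  q <- fld$probs[fld$probs > 0]
  raw <- matrix(0, K, L, dimnames = list(isoforms$ids, NULL))
  for (k in seq_len(K)) {
    chain <- isoforms$chains[[k]]
    lk <- isoforms$lengths[k]
    for (l in seq_len(L)) {
      if (!all(paths[[l]] %in% chain)) next
      val <- 0
      for (j in seq_along(support)) {
        t <- support[j]
        if (t > lk) next
        nklt <- count_placements(paths[[l]], chain, isoforms$subexons, t,
                                 read_len, single_end)
        if (nklt > 0L) val <- val + q[j] * nklt / (lk - t + 1)
      }
      raw[k, l] <- val
    }
  }
  keep <- which(rowSums(raw) > 0)
  if (length(keep) < K) {
    warning("removing ", K - length(keep),
            " isoform(s) that cannot generate any observed path")
  }
  raw <- raw[keep, , drop = FALSE]
  theta0 <- raw / rowSums(raw)
  pi0 <- rep(1 / length(keep), length(keep))
  list(pi0 = pi0, theta0 = theta0, theta_raw = raw,
       C = (raw > 0) * 1L, keep = keep)
}

#' Latent-class EM for isoform abundances
#'
#' Maximizes the mixture likelihood of the collapsed subexon-path counts
#' over the class probabilities `pi` and conditional path probabilities
#' `theta`. E-step: responsibilities
#' `n_hat[k,l] = n_l * pi_k * theta_kl / sum_k' pi_k' theta_k'l`; M-step:
#' `pi_k = sum_l n_hat[k,l] / n`, `theta_kl = n_hat[k,l] / sum_l n_hat[k,l]`.
#' Iterates until the relative log-likelihood change falls below `tol`.
#'
#' Because every isoform's conditional probabilities are free parameters,
#' the likelihood is maximized on a ridge: once the class proportions exceed
#' the mass of the paths exclusive to each isoform, the conditionals can
#' reproduce the observed counts exactly for many values of `pi`. Jointly
#' updating both parameter blocks from the start therefore freezes `pi`
#' wherever the first E-step happens to land. The default `"staged"`
#' schedule resolves this: `pi` is first estimated with `theta` held at its
#' placement-based initialization — an identifiable mixture with known
#' components, consistent under the uniform-fragment model — and the joint
#' updates are released only afterwards to absorb departures from
#' uniformity. `schedule = "joint"` gives the plain simultaneous updates.
#'
#' @param counts Integer path counts `n_l`.
#' @param C Binary compatibility matrix (rows = isoforms).
#' @param pi0,theta0 Initial parameters (see [init_params()]).
#' @param tol Relative log-likelihood tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 1000) per phase.
#' @param schedule `"staged"` (default) or `"joint"`, see Details.
#' @return An `em_state`: `list(pi, theta, resp, loglik, loglik_trace,
#'   n_iter, converged, excluded_paths)`.
#' @export
em_run <- function(counts, C, pi0, theta0, tol = 1e-6, max_iter = 1000L,
                   schedule = c("staged", "joint")) {
  schedule <- match.arg(schedule)
  stopifnot(length(counts) == ncol(theta0), length(pi0) == nrow(theta0))
  n <- sum(counts)
  stopifnot(n > 0)
  # Paths incompatible with every isoform cannot enter the likelihood.
  denom0 <- as.numeric(pi0 %*% theta0)
  excluded <- which(denom0 <= 0)
  if (length(excluded)) {
    warning(length(excluded), " path(s) incompatible with all isoforms excluded")
    counts <- counts[-excluded]
    theta0 <- theta0[, -excluded, drop = FALSE]
    theta0 <- theta0 / rowSums(theta0)
    C <- C[, -excluded, drop = FALSE]
    n <- sum(counts)
  }
  pi <- pi0; theta <- theta0
  trace <- numeric(0)
  converged <- FALSE
  resp <- NULL
  phases <- if (schedule == "staged") c(FALSE, TRUE) else TRUE
  for (update_theta in phases) {
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      joint <- theta * pi                   # K x L, rows scaled by pi_k
      denom <- pmax(colSums(joint), 1e-300)
      resp <- sweep(joint, 2L, denom, "/")
      resp <- sweep(resp, 2L, counts, "*")  # n_hat[k, l]
      ll <- sum(counts * log(denom))
      trace <- c(trace, ll)
      pi <- rowSums(resp) / n
      if (update_theta) {
        row_tot <- rowSums(resp)
        theta <- resp / ifelse(row_tot > 0, row_tot, 1)
      }
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-12)) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
    }
  }
  structure(list(pi = pi, theta = theta, resp = resp, loglik = trace[length(trace)],
                 loglik_trace = trace, n_iter = length(trace),
                 converged = converged, excluded_paths = excluded),
            class = "em_state")
}

#' Convert class probabilities into abundance measures
#'
#' Fragment-level class probabilities `pi` relate to molar proportions by
#' `pi_k ~ l_k * eta_k`; inverting gives
#' `eta_k = (pi_k / l_k) / sum_j (pi_j / l_j)`. FPKM uses the fragments
#' assigned to the isoform, its length in kb and the library size in
#' millions; the `tpm_rate` column (`assigned / l_k`) is normalized to TPM
#' across all transcripts of a sample by [finalize_tpm()].
#'
#' @param pi Estimated class probabilities.
#' @param lengths Isoform lengths in bp.
#' @param n_locus Assignable fragments at this locus.
#' @param n_total_mapped Mapped fragments in the sample.
#' @param ids Transcript ids.
#' @param effective_length Optional effective lengths to use in place of
#'   `lengths` for the eta/FPKM denominators (off by default).
#' @return A `data.frame` with `transcript_id`, `frac` (pi), `eta`,
#'   `assigned`, `FPKM`, `tpm_rate`.
#' @export
abundances <- function(pi, lengths, n_locus, n_total_mapped,
                       ids = names(pi), effective_length = NULL) {
  stopifnot(abs(sum(pi) - 1) < 1e-6)
  l <- if (is.null(effective_length)) lengths else effective_length
  eta <- (pi / l) / sum(pi / l)
  assigned <- pi * n_locus
  fpkm <- assigned * 1e9 / (l * n_total_mapped)
  data.frame(transcript_id = if (is.null(ids)) paste0("iso", seq_along(pi)) else ids,
             frac = pi, eta = eta, assigned = assigned, FPKM = fpkm,
             tpm_rate = assigned / l, stringsAsFactors = FALSE)
}

#' Normalize per-transcript rates to TPM across a sample
#'
#' @param ab An abundance table (possibly concatenated across loci) with a
#'   `tpm_rate` column.
#' @return The table with a `TPM` column summing to one million.
#' @export
finalize_tpm <- function(ab) {
  total <- sum(ab$tpm_rate)
  ab$TPM <- if (total > 0) ab$tpm_rate * 1e6 / total else 0
  ab
}

#' Quantify one locus against a set of isoforms
#'
#' Runs path assignment, collapsing, compatibility, initialization and EM
#' for a single locus.
#'
#' @param isoforms An `isoform_set`.
#' @param rp `read_pairs` of the locus.
#' @param fld A `frag_dist`.
#' @param read_len Read length (bp).
#' @param single_end Logical.
#' @param n_total_mapped Mapped fragments in the sample (defaults to the
#'   locus count, for single-locus use).
#' @param tol,max_iter EM controls.
#' @return `list(abundance, em, counts, C, isoforms)`; `abundance` rows are
#'   zero-filled for isoforms removed during initialization.
#' @export
quantify_locus <- function(isoforms, rp, fld, read_len, single_end = FALSE,
                           n_total_mapped = NULL, tol = 1e-6, max_iter = 1000L) {
  cc <- collapse_counts(rp, isoforms$subexons)
  if (nrow(cc) == 0L) return(NULL)
  ini <- init_params(isoforms, cc$path, fld, read_len, single_end)
  em <- em_run(cc$count, ini$C, ini$pi0, ini$theta0, tol = tol,
               max_iter = max_iter)
  n_locus <- sum(cc$count)
  if (is.null(n_total_mapped)) n_total_mapped <- n_locus
  kept_ids <- isoforms$ids[ini$keep]
  ab <- abundances(em$pi, isoforms$lengths[ini$keep], n_locus, n_total_mapped,
                   ids = kept_ids)
  if (length(ini$keep) < length(isoforms$ids)) {
    removed <- setdiff(isoforms$ids, kept_ids)
    zero <- data.frame(transcript_id = removed, frac = 0, eta = 0, assigned = 0,
                       FPKM = 0, tpm_rate = 0, stringsAsFactors = FALSE)
    ab <- rbind(ab, zero)
    ab <- ab[match(isoforms$ids, ab$transcript_id), , drop = FALSE]
    rownames(ab) <- NULL
  }
  list(abundance = ab, em = em, counts = cc, C = ini$C, init = ini,
       isoforms = isoforms)
}
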