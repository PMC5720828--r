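fig_gene <- toy_skipping_gene()
fig_iso <- fig_gene$isoforms

test_that("placement counts on the skipping gene match the worked example", {
  t1 <- count_placements(c(1L, 3L), fig_iso$chains[[1]], fig_gene$subexons,
                         175L, 50L)
  t2 <- count_placements(c(1L, 3L), fig_iso$chains[[2]], fig_gene$subexons,
                         175L, 50L)
  expect_equal(t1, 16L)
  expect_equal(t2, 26L)
  # on the skip isoform the path is the whole transcript: closed form l - t + 1
  expect_equal(t2, 200L - 175L + 1L)
})

test_that("placement counting agrees with brute-force enumeration on random scenes", {
  set.seed(99)
  for (rep in 1:15) {
    m <- sample(2:5, 1)
    widths <- sample(30:150, m, replace = TRUE)
    sub <- data.frame(id = seq_len(m), start = cumsum(c(1L, head(widths, -1))),
                      width = widths)
    sub$end <- sub$start + widths - 1L
    chain <- seq_len(m)
    r <- sample(20:40, 1)
    t <- sample((2 * r):(2 * r + 150), 1)
    path <- sort(sample(m, sample(1:m, 1)))
    got <- count_placements(path, chain, sub, t, r)
    ref <- oracle_placements(path, chain, sub, t, r)
    expect_equal(got, ref, info = paste("rep", rep))
    # single-end agreement too
    got_se <- count_placements(path, chain, sub, r, r, single_end = TRUE)
    ref_se <- oracle_placements(path, chain, sub, r, r, single_end = TRUE)
    expect_equal(got_se, ref_se)
  }
})

test_that("fragments shorter than two reads admit no paired placement", {
  expect_equal(count_placements(c(1L, 3L), fig_iso$chains[[1]],
                                fig_gene$subexons, 80L, 50L), 0L)
})

test_that("path assignment follows sequenced bases only and rejects intronic overhang", {
  sub <- fig_gene$subexons  # [101,200],[201,260],[261,360]
  # mates in s1 and s3, insert over s2 -> path {1,3}
  rp13 <- make_rp(c(110, 159), c(290, 339))
  expect_equal(assign_paths(rp13, sub), "1-3")
  # unspliced pair inside s1
  rp1 <- make_rp(c(120, 169), c(140, 189))
  expect_equal(assign_paths(rp1, sub), "1")
  # aligned bases outside any subexon are unassignable
  rp_out <- make_rp(c(380, 429))
  expect_true(is.na(assign_paths(rp_out, sub)))
  # junction read touching s1 and s3 via skip
  rp_skip <- make_rp(c(161, 200, 261, 270))
  expect_equal(assign_paths(rp_skip, sub), "1-3")
})

test_that("collapsing preserves totals and respects the 2^w - 1 bound", {
  scene <- sim_skipping_scene(n = 600L, seed = 21L)
  rp <- as_read_pairs(scene$sim)
  loc <- cluster_loci(rp)[[1]]
  g <- locus_graph(loc, 50L, run_config())
  cc <- collapse_counts(loc$read_pairs, g$subexons)
  expect_equal(sum(cc$count) + attr(cc, "unassigned"), nrow(rp))
  expect_equal(attr(cc, "unassigned"), 0L)
  w <- nrow(g$subexons)
  expect_lte(nrow(cc), 2^w - 1)
  # identical footprints collapse to one path
  many <- do.call(rbind, lapply(1:50, function(i)
    make_rp(c(110, 159), c(290, 339), qname = paste0("q", i))))
  class(many) <- c("read_pairs", "data.frame")
  cc2 <- collapse_counts(many, fig_gene$subexons)
  expect_equal(nrow(cc2), 1L)
  expect_equal(cc2$count, 50L)
})

test_that("compatibility requires a feasible bridging placement, not just a subsequence", {
  fld175 <- frag_dist_empirical(setNames(1, "175"))
  C <- compat_matrix(fig_iso, list(c(1L, 3L)), fld175, 50L)
  expect_equal(unname(C[, 1]), c(1L, 1L))  # both isoforms contain {s1,s3}
  # with a middle subexon too long for the insert the inclusion isoform drops out
  wide <- make_toy_gene(c(100L, 300L, 100L), chains = list(1:3, c(1L, 3L)),
                        eta = c(0.5, 0.5))
  C2 <- compat_matrix(wide$isoforms, list(c(1L, 3L)), fld175, 50L)
  expect_equal(unname(C2[, 1]), c(0L, 1L))
  # a path using a subexon the isoform lacks is incompatible; a 150 bp
  # fragment fits path {s2,s3} on the inclusion isoform but never on the skip
  fld150 <- frag_dist_empirical(setNames(1, "150"))
  C3 <- compat_matrix(fig_iso, list(c(2L, 3L)), fld150, 50L)
  expect_equal(unname(C3[, 1]), c(1L, 0L))
  # and with the long fragment even the inclusion isoform cannot realize it
  C4 <- compat_matrix(fig_iso, list(c(2L, 3L)), fld175, 50L)
  expect_equal(unname(C4[, 1]), c(0L, 0L))
})

test_that("fragment distributions normalize and truncate correctly", {
  emp <- frag_dist_empirical(c(200L, 200L, 200L))
  expect_equal(emp$lengths, 200L)
  expect_equal(emp$probs, 1)
  mix <- frag_dist_empirical(c(100L, 100L, 200L, 300L))
  expect_equal(sum(mix$probs), 1)
  expect_equal(mix$probs[mix$lengths == 100L], 0.5)
  gs <- frag_dist_gaussian(300, 50, read_len = 50L)
  expect_equal(sum(gs$probs), 1)
  expect_gte(min(gs$lengths), 100L)
})

test_that("the fragment distribution is learned from single-isoform regions", {
  # one long unspliced locus (> 2 kb): spans are recovered exactly
  pairs <- lapply(1:30, function(i) {
    start <- 100L + 97L * i
    make_rp(c(start, start + 49L), c(start + 150L, start + 199L),
            qname = paste0("f", i))
  })
  rp <- do.call(rbind, pairs)
  class(rp) <- c("read_pairs", "data.frame")
  fld <- learn_fragment_dist(rp, min_span = 2000L)
  expect_equal(fld$lengths, 200L)
  expect_equal(fld$probs, 1)
  # a short locus is not used
  rp_short <- rp[1:2, ]
  class(rp_short) <- c("read_pairs", "data.frame")
  expect_null(learn_fragment_dist(rp_short, min_span = 2000L))
})

test_that("theta initialization matches the sample-rate formula on the worked example", {
  fld175 <- frag_dist_empirical(setNames(1, "175"))
  ini <- init_params(fig_iso, list(c(1L, 3L)), fld175, 50L)
  # inclusion isoform: 16 placements over 260 - 175 + 1 = 86 potential starts
  expect_equal(unname(ini$theta_raw["iso1", 1]), 16 / 86)
  expect_equal(unname(ini$theta_raw["iso2", 1]), 26 / 26)
  expect_equal(ini$pi0, c(0.5, 0.5))
  # rows normalize over observed paths
  expect_equal(unname(rowSums(ini$theta0)), c(1, 1))
})

test_that("isoforms unable to generate any observed path are removed", {
  fld175 <- frag_dist_empirical(setNames(1, "175"))
  wide <- make_toy_gene(c(100L, 300L, 100L), chains = list(1:3, c(1L, 3L)),
                        eta = c(0.5, 0.5))
  expect_warning(
    ini <- init_params(wide$isoforms, list(c(1L, 3L)), fld175, 50L),
    "cannot generate")
  expect_equal(unname(ini$keep), 2L)
})

test_that("EM has the expected fixed points and a monotone likelihood", {
  # K = 1 collapses immediately
  em1 <- em_run(c(10L, 5L), matrix(1L, 1, 2), 1,
                matrix(c(0.6, 0.4), 1, 2))
  expect_equal(em1$pi, 1)
  # symmetric two-isoform problem stays at (0.5, 0.5)
  C <- matrix(c(1L, 0L, 0L, 1L, 1L, 1L), nrow = 2)
  theta0 <- rbind(c(0.4, 0, 0.6), c(0, 0.4, 0.6))
  em2 <- em_run(c(100L, 100L, 40L), C, c(0.5, 0.5), theta0)
  expect_equal(em2$pi, c(0.5, 0.5), tolerance = 1e-9)
  expect_true(all(diff(em2$loglik_trace) >= -1e-9))
  # invariants of the returned state
  expect_equal(sum(em2$pi), 1)
  expect_equal(unname(rowSums(em2$theta)), c(1, 1), tolerance = 1e-12)
})

test_that("a path incompatible with every isoform is excluded with a warning", {
  C <- matrix(c(1L, 0L), 1, 2)
  theta0 <- matrix(c(1, 0), 1, 2)
  expect_warning(em <- em_run(c(10L, 3L), C, 1, theta0), "incompatible")
  expect_equal(em$excluded_paths, 2L)
  expect_equal(em$pi, 1)
})

test_that("collapsed and per-pair data give identical estimates", {
  scene <- sim_skipping_scene(n = 800L, seed = 31L)
  loc <- cluster_loci(as_read_pairs(scene$sim))[[1]]
  iso <- scene$gene$isoforms
  cc <- collapse_counts(loc$read_pairs, scene$gene$subexons)
  ini <- init_params(iso, cc$path, scene$fld, 50L)
  # un-collapsed: every pair is its own observation; the induced start is
  # the collapsed theta split uniformly over the copies of each path; both
  # runs take the same fixed number of steps for a direct trajectory
  # comparison
  em_col <- em_run(cc$count, ini$C, ini$pi0, ini$theta0,
                   tol = 0, max_iter = 100L)
  path_of_pair <- rep(seq_len(nrow(cc)), cc$count)
  theta_un <- ini$theta0[, path_of_pair, drop = FALSE] /
    rep(cc$count[path_of_pair], each = nrow(ini$theta0))
  C_un <- ini$C[, path_of_pair, drop = FALSE]
  em_un <- em_run(rep(1L, length(path_of_pair)), C_un, ini$pi0, theta_un,
                  tol = 0, max_iter = 100L)
  expect_lt(max(abs(em_col$pi - em_un$pi)), 1e-8)
  expect_true(all(diff(em_un$loglik_trace) >= -1e-9))
})

test_that("abundance conversion inverts the length weighting", {
  ab <- abundances(c(0.5, 0.5), c(1000, 2000), n_locus = 100,
                   n_total_mapped = 1e6, ids = c("a", "b"))
  expect_equal(ab$eta, c(2 / 3, 1 / 3))
  # equal lengths: eta equals pi
  ab2 <- abundances(c(0.3, 0.7), c(500, 500), 10, 1e6, c("a", "b"))
  expect_equal(ab2$eta, c(0.3, 0.7))
  # FPKM definition
  expect_equal(ab$FPKM[1], 50 * 1e9 / (1000 * 1e6))
  # TPM sums to one million over a sample
  tpm <- finalize_tpm(rbind(ab, ab2))
  expect_equal(sum(tpm$TPM), 1e6)
})

test_that("simulated proportions are recovered by the full quantification stack", {
  scene <- sim_skipping_scene(n = 10000L, eta = c(0.7, 0.3), seed = 77L)
  # compare against fragment-level truth pi = l * eta (normalized)
  loc <- cluster_loci(as_read_pairs(scene$sim))[[1]]
  q <- quantify_locus(scene$gene$isoforms, loc$read_pairs, scene$fld, 50L)
  expect_lt(max(abs(q$em$pi - scene$gene$pi)), 0.02)
  expect_lt(max(abs(q$abundance$eta - scene$gene$eta)), 0.02)
})
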