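test_that("coverage counts overlapping blocks and ignores introns and inserts", {
  loc <- make_locus(list(make_rp(c(1, 50)),
                         make_rp(c(10, 40)),
                         make_rp(c(20, 30)),
                         make_rp(c(60, 79, 121, 140))))  # intron [80,120]
  prof <- coverage_profile(loc)
  cov <- as.integer(prof$cov)
  ref <- oracle_coverage(loc$read_pairs$blocks, loc$start, loc$end)
  expect_equal(cov, ref)
  expect_equal(cov[25 - loc$start + 1], 3L)
  expect_true(all(cov[(80:120) - loc$start + 1] == 0L))
})

test_that("primitive exons are maximal covered runs", {
  loc <- make_locus(list(make_rp(c(1, 100)), make_rp(c(201, 300))))
  prim <- primitive_exons(coverage_profile(loc))
  expect_equal(unname(prim), cbind(c(1L, 201L), c(100L, 300L)))
  # single covered base
  loc1 <- make_locus(list(make_rp(c(5, 5))))
  expect_equal(unname(primitive_exons(coverage_profile(loc1))), cbind(5L, 5L))
})

test_that("intron tallies count junction reads, uniqueness and small overhangs", {
  pairs <- c(lapply(1:3, function(i) make_rp(c(50, 100, 201, 250), qname = paste0("u", i))),
             lapply(1:2, function(i) make_rp(c(60, 100, 201, 260), qname = paste0("m", i),
                                             is_unique = FALSE)),
             list(make_rp(c(97, 100, 201, 246), qname = "small")))  # 4 bp overhang
  loc <- make_locus(pairs)
  introns <- collect_introns(loc, s = 6L)
  expect_equal(nrow(introns), 1L)
  expect_equal(introns$total, 6L)
  expect_equal(introns$unique, 4L)
  expect_equal(introns$small_overhang, 1L)

  # two distinct skips give two introns
  loc2 <- make_locus(list(make_rp(c(1, 50, 151, 200)),
                          make_rp(c(1, 60, 171, 220))))
  expect_equal(nrow(collect_introns(loc2)), 2L)
})

test_that("the multi-mapping filter triggers strictly above 70% non-unique support", {
  base <- data.frame(start = c(100L, 500L), end = c(200L, 600L),
                     small_overhang = c(0L, 0L))
  at_boundary <- cbind(base, total = c(10L, 10L), unique = c(3L, 2L))
  kept <- filter_introns(at_boundary[, c("start", "end", "total", "unique",
                                         "small_overhang")],
                         read_len = 100L)
  # 70% non-unique is tolerated, 80% is not
  expect_equal(kept$start, 100L)
  expect_equal(attr(kept, "dropped")$reason, "multi_mapped")
})

test_that("a weak intron overlapped by a strong one is removed at the 5% rule", {
  introns <- data.frame(start = c(100L, 150L), end = c(300L, 250L),
                        total = c(100L, 4L), unique = c(100L, 4L),
                        small_overhang = c(0L, 0L))
  kept <- filter_introns(introns, read_len = 100L)
  expect_equal(kept$total, 100L)
  expect_equal(attr(kept, "dropped")$reason, "overlap_low_expression")
  # at exactly 5% it survives
  introns$total[2] <- 5L
  kept2 <- filter_introns(introns, read_len = 100L)
  expect_equal(nrow(kept2), 2L)
})

test_that("the small-overhang cut matches the exact binomial quantile", {
  n <- 50L; l <- 100L; s <- 6L; alpha <- 0.001
  p <- 2 * s / (l - 1)
  expect_equal(p, 12 / 99)
  thr <- small_overhang_threshold(n, l, s, alpha)
  # independent check: smallest c with P(X <= c) >= 1 - alpha
  cdf <- cumsum(dbinom(0:n, n, p))
  expect_equal(thr, which(cdf >= 1 - alpha)[1] - 1)
  mk <- function(so) data.frame(start = 100L, end = 200L, total = n,
                                unique = n, small_overhang = as.integer(so))
  expect_equal(nrow(filter_introns(mk(thr), read_len = l, s = s, alpha = alpha)), 1L)
  expect_equal(nrow(filter_introns(mk(thr + 1), read_len = l, s = s, alpha = alpha)), 0L)
})

test_that("the normal approximation agrees with the exact binomial near n = 100", {
  l <- 100L; s <- 6L; alpha <- 0.001
  p <- 2 * s / (l - 1)
  for (n in c(101L, 110L, 150L)) {
    thr_norm <- small_overhang_threshold(n, l, s, alpha)
    thr_exact <- qbinom(1 - alpha, n, p)
    counts <- 0:n
    dec_norm <- counts > thr_norm
    dec_exact <- counts > thr_exact
    disagree <- counts[dec_norm != dec_exact]
    expect_true(all(abs(disagree - thr_exact) <= 1),
                info = paste("n =", n))
  }
})

test_that("subexon cutting splits at donor/acceptor boundaries", {
  prim <- cbind(1L, 300L)
  introns <- data.frame(start = 101L, end = 200L)
  sub <- cut_subexons(prim, introns)
  expect_equal(sub$start, c(1L, 101L, 201L))
  expect_equal(sub$end, c(100L, 200L, 300L))
  # no introns: subexons are the primitive exons
  sub0 <- cut_subexons(cbind(c(1L, 500L), c(100L, 700L)),
                       data.frame(start = integer(), end = integer()))
  expect_equal(sub0$start, c(1L, 500L))
  expect_equal(sub0$id, 1:2)
})

test_that("overlapping introns cut at every boundary, matching a brute-force partition", {
  prim <- cbind(1L, 300L)
  introns <- data.frame(start = c(101L, 151L), end = c(200L, 260L))
  sub <- cut_subexons(prim, introns)
  ref <- oracle_cut(prim, introns)
  expect_equal(cbind(sub$start, sub$end), unname(ref))
  # the alternative-acceptor piece [201,260] must survive as its own subexon
  expect_true(any(sub$start == 201L & sub$end == 260L))
  # randomized agreement with the brute-force oracle
  set.seed(42)
  for (rep in 1:20) {
    pr <- cbind(c(1L, 401L), c(350L, 600L))
    k <- sample(1:3, 1)
    st <- sort(sample(20:340, k))
    en <- pmin(st + sample(30:150, k, replace = TRUE), 580L)
    ints <- data.frame(start = st, end = en)
    keep <- ints$end > ints$start
    ints <- ints[keep, , drop = FALSE]
    got <- suppressWarnings(cut_subexons(pr, ints))
    ref <- oracle_cut(pr, ints)
    expect_equal(cbind(got$start, got$end), unname(ref))
  }
})

test_that("out-of-range intron boundaries are ignored with a warning", {
  prim <- cbind(1L, 100L)
  introns <- data.frame(start = 500L, end = 600L)
  expect_warning(sub <- cut_subexons(prim, introns), "outside all primitive")
  expect_equal(nrow(sub), 1L)
})

test_that("graph edges carry adjacency and junction weights and the graph is a DAG", {
  # two adjacent subexons + one skipped: reads across the boundary and a junction
  pairs <- c(lapply(1:4, function(i) make_rp(c(90 + i, 150 + i), qname = paste0("adj", i))),
             list(make_rp(c(98, 100, 201, 248), qname = "thin")),  # 3 bp in left subexon
             lapply(1:3, function(i) make_rp(c(60 + i, 100, 201, 240 + i),
                                             qname = paste0("jx", i))))
  loc <- make_locus(pairs)
  prof <- coverage_profile(loc)
  prim <- primitive_exons(prof)
  introns <- collect_introns(loc)
  kept <- filter_introns(introns, read_len = 50L)
  sub <- cut_subexons(prim, kept)
  g <- build_splicing_graph(sub, kept, loc)
  real <- g$edges[g$edges$kind != "artificial", ]
  nonintron <- real[real$kind == "non-intron", ]
  # 4 reads span >= 6 bp on both sides; the 3 bp overhang does not count
  expect_equal(nonintron$weight, 4)
  intron_e <- real[real$kind == "intron", ]
  expect_equal(intron_e$weight, 4)   # thin + 3 junction reads
  expect_true(all(real$from < real$to))
  # source feeds in-degree-0 nodes, target drains out-degree-0 nodes
  expect_true(any(g$edges$from == 0))
  expect_true(any(g$edges$to == nrow(sub) + 1))
})

test_that("single-subexon loci produce the trivial source-target graph", {
  loc <- make_locus(list(make_rp(c(1, 80))))
  g <- locus_graph(loc, read_len = 50L, params = run_config())
  expect_equal(nrow(g$subexons), 1L)
  expect_equal(g$edges$kind, c("artificial", "artificial"))
})

test_that("cost transform negates and shifts by the maximum weight", {
  ex <- example_cmpc_graph(weights = c("1-2" = 2, "1-3" = 5, "2-4" = 9))
  ed <- ex$graph$edges
  real <- ed[ed$kind != "artificial", ]
  expect_equal(real$cost[real$from == 1 & real$to == 2], 7)
  expect_equal(real$cost[real$from == 1 & real$to == 3], 4)
  expect_equal(real$cost[real$from == 2 & real$to == 4], 0)
  expect_true(all(ed$cost[ed$kind == "artificial"] == 0))
  expect_true(all(ed$cost >= 0))
})

test_that("subexons partition the covered bases of the locus", {
  scene <- sim_skipping_scene(n = 800L, seed = 3L)
  loc <- cluster_loci(as_read_pairs(scene$sim))[[1]]
  g <- locus_graph(loc, 50L, run_config())
  prim <- primitive_exons(coverage_profile(loc))
  covered <- sum(prim[, 2] - prim[, 1] + 1L)
  expect_equal(sum(g$subexons$width), covered)
  # disjoint and ordered
  expect_true(all(diff(g$subexons$start) > 0))
  expect_true(all(g$subexons$start[-1] > g$subexons$end[-nrow(g$subexons)]))
})
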