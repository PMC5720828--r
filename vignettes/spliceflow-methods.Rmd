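---
title: "Models and methods in spliceflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in spliceflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

spliceflow reconstructs transcripts from spliced RNA-Seq alignments and
estimates their abundances without a gene annotation. This vignette explains
the two models the package implements — a constrained minimum path cover for
assembly and a latent class model for quantification — together with the
numerical choices, tunable parameters and known limitations a user should be
aware of.

## From alignments to splicing graphs

Input is a coordinate-sorted SAM/BAM file. Each properly mated pair is
reduced to its genomic footprint: the aligned blocks of both mates, the
introns implied by `N` skip operations, the transcription strand suggested
by the aligner's `XS` tag on junction reads, and a uniqueness flag from the
`NH` hit-count tag (primary alignment with hit count absent or 1).
Coordinates are 1-based and closed throughout, matching SAM and GFF;
conversions happen only at file boundaries. Read-pairs separated by more
than `max_gap` (default 50 bp) of zero coverage start a new locus; clusters
containing junction tags of both signs are split by strand, and fully
untagged loci are assembled on the plus strand and flagged as unstranded.

Within a locus, a *primitive exon* is a maximal run of covered positions,
and an intron is a distinct skipped interval. Spurious junction calls are
removed by three filters, applied independently to the unfiltered set so
the outcome does not depend on evaluation order:

1. more than 70% of the supporting junction reads are not uniquely aligned;
2. the intron overlaps another intron carrying more than twenty times its
   expression (below 5% of the strongest overlapping intron);
3. the count of *small-overhang* reads — junction reads aligned with at most
   `s` bases (default 6) on one side of the junction — exceeds the upper
   `1 - alpha` quantile (default `alpha` 0.001) of Bin(n, p) with
   `p = 2s/(l - 1)`, `n` the junction read total and `l` the read length;
   for `n > 100` the normal approximation N(np, np(1-p)) is used. Under
   uniform read placement small overhangs are rare, so an excess marks a
   spurious junction; the rejection direction and level are the package's
   choice, as only the expectation is prescribed by the underlying model.

Kept introns cut the primitive exons into *subexons* at every donor and
acceptor boundary falling strictly inside them. Every covered piece is
retained: a piece inside an overlapping intron's interior (an alternative
splice-site or retained-intron segment) is genuine sequence of some isoform
whenever it is covered, and coverage — not intron membership — is what
separates exonic from intronic bases here. Subexons are numbered in genomic
order and become the nodes of the splicing graph; genomically adjacent
subexons are joined by a non-intron edge weighted by the number of
read-pairs whose contiguous aligned block spans the boundary by at least
`overlap_bp` bases (default 6) on each side, and each intron contributes an
edge weighted by its junction read count. A block-spanning rule is used
rather than any pair-level overlap because a mate gap across a boundary does
not certify that the two subexons are consecutive in a transcript. An
artificial source feeds every subexon without incoming edges and an
artificial target drains every subexon without outgoing edges. Because the
optimization minimizes cost while read support is evidence, weights are
negated and shifted by the locus maximum: `cost(e) = W_max - w(e)`.

Graphs are always built left-to-right in genomic coordinates; a transcript
is a source-target path in either transcription direction, and the strand
is carried to the output rather than into the graph orientation.

## Assembly as a constrained minimum path cover

A transcript corresponds to a source-to-target path. The assembly asks for
the smallest set of such paths that covers every subexon and every edge and
contains every *subpath constraint* — an ordered chain of subexons that must
appear consecutively in some transcript — and, among covers of minimum
cardinality, one of minimum total cost.

Constraints arise from read-pairs. The chain of subexons touched by a
pair's sequenced bases is direct evidence; when two consecutively touched
subexons are not adjacent in the graph and the gap is the unsequenced
insert, the package enumerates all graph chains between them and keeps those
whose implied fragment length falls within the plausible range (taken from
the fragment-length distribution). The interior is filled in only when
exactly one candidate survives; ambiguous pairs contribute no constraint,
because a wrong constraint forces a wrong transcript while a dropped one
only loses evidence. Chains of three or more subexons enter the constraint
set; junction reads spanning three subexons are treated identically to
insert-bridged chains.

The cover is computed by a reduction to a minimum-cost circulation:

* every edge joins the constraint set as a two-node chain, duplicates and
  chains contained consecutively in longer chains are dropped;
* multi-node constraints overlapping by a shared edge (one's suffix is the
  other's prefix, two or more common nodes) are glued into their union.
  This step is needed for optimality: each multi-node constraint becomes a
  single *shortcut arc*, and a path cannot traverse two shortcut arcs whose
  spans overlap, although one real path contains both chains. A
  suffix-exchange argument shows the glue is safe — given two paths covering
  the two constraints, swapping their tails at the end of the overlap
  produces paths with the same edge multiset, one of which contains the
  union, so some optimal cover satisfies the merged chain. Constraints
  meeting at a single node need no merge, as their arcs chain consecutively.
* each subexon v is split into `v_in -> v_out` with lower bound 1 (node
  coverage), except nodes interior to a multi-node constraint, whose
  coverage is already guaranteed by the mandatory unit on the shortcut arc
  and its re-expansion;
* edges that remain constraints get lower bound 1, edges absorbed into
  longer constraints get lower bound 0, each multi-node constraint becomes
  a shortcut arc with lower bound 1 and cost equal to the chain it
  replaces, and a circulation arc closes the cycle from target to source.

The lexicographic objective — fewest paths first, least cost second — is
realized in a single solve by pricing the circulation arc strictly above
any achievable total arc cost. Lower bounds are removed by the standard
excess/deficit transformation and the result is an ordinary min-cost
max-flow, solved by successive shortest augmenting paths (Bellman-Ford on
the residual network). All costs are integral counts, flows are integral,
and the networks are tiny (tens of nodes per locus), so the plain
implementation is exact and fast. The circulation is then decomposed into
unit paths greedily: from each node the arc with the largest remaining flow
is taken, ties broken toward the lowest subexon id, and one unit is
subtracted per extracted path, so the number of paths equals the flow on
the circulation arc. Shortcut arcs are re-expanded, adjacent subexons are
merged into exons, and each path becomes an assembled transcript.

On small instances the whole procedure is verifiable: the test suite
enumerates every source-target path of random DAGs (up to 8 nodes, up to 3
constraints) and confirms that the computed cover matches the exhaustive
minimum in both cardinality and cost.

## Quantification with a latent class model

For quantification, read-pairs are collapsed to *subexon paths*: the
ordered set of subexons a pair's sequenced bases touch. A pair belongs to a
path only if every aligned base lies inside some subexon; pairs overhanging
into filtered regions are set aside. For `w` subexons there are at most
`2^w - 1` paths regardless of the number of isoforms, which is what makes
the model cheap. The observed path counts `n_l` are sufficient statistics:
the mixture likelihood factorizes over paths, and the test suite checks
that collapsed and per-pair runs return identical estimates.

The generative model: a fragment comes from isoform k with probability
`pi_k` (proportional to molar proportion times length, `pi_k ~ l_k eta_k`),
and conditional on k realizes path l with probability `theta_kl`, a
one-trial multinomial over the observed paths of the locus. The
compatibility matrix `C_kl` marks which isoform can generate which path:
the path must be a subsequence of the isoform's chain *and* at least one
fragment length with positive probability must admit a placement realizing
exactly that path — a 175 bp fragment cannot, for example, produce the
outer-subexon path on an isoform whose middle subexon is longer than the
unsequenced insert.

`theta` is initialized from placement counting. `n_klt` is the number of
5' start positions on isoform k at which a fragment of length t (two
sequenced ends of `read_len` bases around an unsequenced interior) induces
exactly path l; the raw value `sum_t q(t) n_klt / (l_k - t + 1)` sums the
sample rates of all potential placements, observed or not, and rows are
then normalized over the observed paths so the conditional multinomial is
well defined (the raw rows deliberately carry mass on unobserved paths).
Placement counting is vectorized over start positions but remains an exact
enumeration; the tests compare it against a per-base brute-force count and
against the worked three-subexon example (16 placements on the 260 bp
inclusion isoform, 26 on the 200 bp skip isoform, for t = 175 and 50 bp
reads).

The fragment-length distribution `q` is learned empirically from loci
longer than 2 kb without overlapping introns (no alternative splice
sites); the fragment length of a pair there is its genomic span minus any
straddled intron. When no such region exists, or for single-end data, a
user-supplied Gaussian (`frag_mean`, `frag_sd`) is discretized on integers
and truncated below at twice the read length. In single-end mode the
fragment is the read itself.

### The EM schedule

The E- and M-steps are the standard latent-class updates: responsibilities
`n_hat_kl = n_l pi_k theta_kl / sum_k' pi_k' theta_k'l`, then
`pi_k = sum_l n_hat_kl / n` and `theta_kl = n_hat_kl / sum_l n_hat_kl`.
Iteration stops when the relative log-likelihood change drops below `tol`
(default 1e-6, cap 1000 iterations per phase); the log-likelihood is
asserted non-decreasing in every test fixture.

One property of this model deserves emphasis: because every `theta_kl` is
free, the likelihood is maximized on a ridge. Once each `pi_k` exceeds the
mass of the paths exclusive to isoform k, the conditionals can reproduce
the observed counts exactly for a continuum of `pi` values, and jointly
updating both blocks from the start freezes `pi` wherever the first E-step
lands — near its uniform initialization, not near the truth. spliceflow
therefore runs a staged schedule by default: `pi` is first estimated with
`theta` held at its placement-based initialization, which is an
identifiable finite mixture with known components and is consistent when
fragments are placed uniformly; the joint updates are then released so
`theta` can absorb real departures from uniformity (positional bias along
transcripts). Both phases are EM steps on the same likelihood, so
monotonicity is preserved. The plain simultaneous updates remain available
via `em_run(schedule = "joint")`. In seeded simulations (2-4 isoforms,
10,000 pairs), the staged schedule recovers the true class proportions to
a mean absolute error below 0.02, while the joint schedule can stall more
than 0.2 away from the truth.

From `pi` the package reports molar proportions
`eta_k = (pi_k / l_k) / sum_j (pi_j / l_j)`, assigned fragment counts
`pi_k * n`, FPKM (assigned fragments per kilobase of transcript per million
mapped fragments), and TPM normalized across all transcripts of the
sample. Plain isoform length is used in these conversions, matching the
`pi ~ l * eta` relation of the model; an effective-length correction can be
supplied through the `effective_length` argument of `abundances()` but is
off by default.

In quantification-only mode the isoforms come from a GFF3/GTF annotation
instead of the assembler: overlapping transcripts are reduced to a
splicing-graph segmentation by cutting their exons at every internal
boundary, each transcript becomes a chain over the resulting subexons, and
the identical collapsing/EM machinery runs.

## The simulator and what it does and does not emulate

`simulate_read_pairs()` draws fragments exactly from the generative model:
isoform with probability proportional to `l_k eta_k`, fragment length from
a given distribution truncated to the isoform, start uniform among feasible
positions, and mates written as valid coordinate-sorted SAM with skip
operations and transcription-strand tags on junction reads. Alignment
coordinates are generated directly — no sequences, errors or quality values
— because the method consumes alignments, not raw reads. Consequently,
passing tests demonstrate correctness of the graph, cover and EM machinery
under the model's own assumptions; they do not exercise alignment
artifacts, positional or GC bias, or multi-mapping ambiguity beyond the
uniqueness flags. `random_toy_gene()` builds recovery scenes with
`n_isoforms + 2` subexons (the full chain plus distinct exon-skipping
chains), subexon widths of 80-250 bp, intron gaps of 100-300 bp and
Dirichlet proportions floored at 0.08 — sizes chosen so junctions are well
covered at the simulated depths while keeping each scene well under a
second of work. Every stochastic entry point takes an explicit seed, and
the pipeline is byte-deterministic given input and configuration.

Test and simulation problem sizes — loci of a few hundred to ten thousand
pairs, DAGs of up to eight nodes for the exhaustive comparisons, twenty
recovery replicates — are the package's chosen desk-scale study conditions:
large enough for Monte-Carlo error around 0.005 on a proportion, small
enough that exhaustive oracles stay feasible.

## Worked example network

`example_cmpc_graph()` ships the package's reference network for the path
cover: eight subexons with two alternative starts (1-2, 1-3) rejoining at
subexon 4, a three-way branch (4-5/6/7) reconverging at subexon 8, and one
paired-gap constraint {2,4,7}. Its minimum cover takes exactly three
transcripts. Note that the edge 3-4 is essential to that optimum: without
it, the unit of flow forced through 1-3 cannot rejoin subexon 8 and a
fourth path becomes unavoidable. Edge costs in this fixture are synthetic
unit values; the minimum flow and the decomposition count are independent
of the cost assignment.

## Evaluation metrics

For benchmarking, the package implements the proportionality correlation
`2 Cov(log(x+1), log(y+1)) / (Var(log(x+1)) + Var(log(y+1)))`, Spearman
correlation (average ranks on ties, via `stats::cor`), the mean absolute
relative difference `ARD_i = |x_i - y_i| / (0.5 |x_i + y_i|)` (defined as 0
at 0/0, bounded by [0, 2]), and transcript-level intron-chain matching:
a multi-exon prediction is correct when its ordered intron set equals a
reference transcript's exactly, differences confined to the terminal exon
boundaries being ignored; mono-exon transcripts match by same-strand exon
overlap, a tolerance the package defines since no standard exists.

## Known limitations

* Transcription start and end sites are taken from coverage boundaries;
  alternative promoters and polyadenylation sites that require read-depth
  change-point models are out of scope.
* Sequencing-bias correction is limited to what the free per-path
  conditionals absorb; no hexamer or GC model is fitted.
* Multi-mapped pairs count toward coverage and edge weights with weight 1;
  only the intron uniqueness filter consults the hit-count tag.
* Loci are processed independently and in order; the implementation is
  single-threaded (per-locus independence makes parallelism possible but it
  is not required for correctness).
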