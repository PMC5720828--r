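# A hand-built worked example used in documentation and tests.

#' Worked-example splicing graph with a paired-gap constraint
#'
#' An eight-subexon splicing graph whose topology exercises every part of
#' the constrained path cover: two alternative starts (1 -> 2, 1 -> 3)
#' rejoining at subexon 4, a three-way branch (4 -> 5/6/7) reconverging at
#' subexon 8, and a single paired-gap subpath constraint \{2, 4, 7\} from a
#' read-pair whose unsequenced insert bridges subexons 2 and 7 through 4.
#' The constrained minimum path cover of this graph needs exactly three
#' transcripts.
#'
#' @param weights Optional named numeric vector of edge weights
#'   (names `"u-v"`); defaults to unit weights, making all costs equal.
#' @return `list(graph, constraint)`: a `splicing_graph` (costs already
#'   transformed) and the integer constraint chain.
#' @export
example_cmpc_graph <- function(weights = NULL) {
  # Arbitrary disjoint subexon intervals; only the topology matters here.
  sub <- data.frame(id = 1:8,
                    start = seq(1L, by = 200L, length.out = 8L),
                    end = seq(1L, by = 200L, length.out = 8L) + 99L)
  sub$width <- sub$end - sub$start + 1L
  e <- rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4), c(4, 5), c(4, 6), c(4, 7),
             c(5, 8), c(6, 8), c(7, 8))
  w <- rep(1, nrow(e))
  if (!is.null(weights)) {
    key <- paste(e[, 1], e[, 2], sep = "-")
    hit <- match(key, names(weights))
    w[!is.na(hit)] <- weights[hit[!is.na(hit)]]
  }
  edges <- data.frame(from = as.integer(e[, 1]), to = as.integer(e[, 2]),
                      weight = w, kind = "intron")
  edges <- rbind(edges,
                 data.frame(from = 0L, to = 1L, weight = 0, kind = "artificial"),
                 data.frame(from = 8L, to = 9L, weight = 0, kind = "artificial"))
  g <- structure(list(chrom = "chrT", strand = "+", unstranded = FALSE,
                      subexons = sub, edges = edges),
                 class = "splicing_graph")
  g <- transform_weights(g)
  list(graph = g, constraint = c(2L, 4L, 7L))
}
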