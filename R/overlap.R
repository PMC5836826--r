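#' Count shared bands between two fingerprints
#'
#' Greedy leftmost matching on the two sorted band lists: a pair matches iff
#' the absolute difference is at most `t`, and each band is used at most once.
#' For sorted lists with a symmetric tolerance the greedy result equals the
#' maximum bipartite matching, and the count is symmetric in its arguments.
#'
#' @param a,b Sorted integer band vectors.
#' @param t Tolerance in encoded scale units.
#' @return Integer shared-band count.
#' @export
shared_bands <- function(a, b, t = 0L) {
  stopifnot(!is.unsorted(a), !is.unsorted(b), t >= 0)
  .sb_pair(as.integer(a), as.integer(b), as.integer(t))
}

#' Sulston overlap probability
#'
#' Probability that two clones with `nl` and `nh` bands (`nl <= nh`) share at
#' least `s` bands by chance when bands fall independently on a scale of `G`
#' distinguishable values with match tolerance `t`: each band of the smaller
#' clone matches some band of the larger with probability
#' `q = 1 - (1 - p)^nh`, `p = (2t + 1)/G`, and the score is the upper binomial
#' tail `P(X >= s)` for `X ~ Binomial(nl, q)`. Tails far below the double
#' floor are available on the log10 scale.
#'
#' @param nl,nh Band counts of the smaller and larger clone.
#' @param s Observed shared-band count, `0 <= s <= nl`.
#' @param params A [match_params()] supplying `tolerance` and `gel_space`.
#' @param log10p If `TRUE`, return log10 of the score (computed in log space,
#'   exact for tails below 1e-300).
#' @return The score (probability, or its log10).
#' @export
sulston_score <- function(nl, nh, s, params = match_params(),
                          log10p = FALSE) {
  if (any(s > nl)) stop("shared count s cannot exceed the smaller band count")
  stopifnot(all(nl <= nh), all(s >= 0))
  p <- (2 * params$tolerance + 1) / params$gel_space
  q <- 1 - (1 - p)^nh
  if (log10p)
    pbinom(s - 1, nl, q, lower.tail = FALSE, log.p = TRUE) / log(10)
  else
    pbinom(s - 1, nl, q, lower.tail = FALSE)
}

# inclusive significance rule: score <= cutoff is significant (fixed
# convention used by every cutoff comparison in the package)
is_significant <- function(score, cutoff) score <= cutoff

#' Build the significant-overlap network
#'
#' Computes shared-band counts for all clone pairs (with a band-range
#' prefilter that can only skip pairs sharing no band) and keeps edges whose
#' Sulston score is at or below `network_cutoff`. Scores are also stored on
#' the log10 scale so that overlaps far below double precision remain
#' comparable.
#'
#' @param fps Named list of sorted integer band vectors (quality-filtered).
#' @param params A [match_params()].
#' @param compat_slack Near-significant overlaps within this many decades
#'   above the cutoff are retained separately as compatibility edges: they
#'   never create contigs but count as "these clones may overlap" when the
#'   linear-topology test looks for contradictions, which keeps borderline
#'   real overlaps from masquerading as conflicts.
#' @return An object of class `overlap_graph`: list with `nodes` (clone ids),
#'   `edges` (data.frame `a/b/shared/score/log10_score`), `compat_edges`
#'   (same columns) and `params`.
#' @export
overlap_network <- function(fps, params = match_params(), compat_slack = 5) {
  nodes <- names(fps)
  stopifnot(!is.null(nodes), !anyDuplicated(nodes))
  nb <- lengths(fps)
  pr <- .sb_allpairs(lapply(fps, as.integer), params$tolerance, 1L)
  empty <- data.frame(a = character(0), b = character(0),
                      shared = integer(0), score = numeric(0),
                      log10_score = numeric(0))
  edges <- compat <- empty
  if (nrow(pr)) {
    nl <- pmin(nb[pr$i], nb[pr$j])
    nh <- pmax(nb[pr$i], nb[pr$j])
    lg <- sulston_score(nl, nh, pr$shared, params, log10p = TRUE)
    cut <- log10(params$network_cutoff)
    keep <- lg <= cut
    near <- !keep & lg <= cut + compat_slack
    edges <- data.frame(a = nodes[pr$i[keep]], b = nodes[pr$j[keep]],
                        shared = pr$shared[keep],
                        score = 10^lg[keep], log10_score = lg[keep])
    compat <- data.frame(a = nodes[pr$i[near]], b = nodes[pr$j[near]],
                         shared = pr$shared[near],
                         score = 10^lg[near], log10_score = lg[near])
  }
  structure(list(nodes = nodes, edges = edges, compat_edges = compat,
                 band_counts = nb, params = params),
            class = "overlap_graph")
}

#' @export
print.overlap_graph <- function(x, ...) {
  cat("Significant-overlap network:", length(x$nodes), "clones,",
      nrow(x$edges), "edges at cutoff", format(x$params$network_cutoff),
      "\n")
  invisible(x)
}

#' Flag promiscuous (repeat-driven) clones
#'
#' A clone is excluded when its number of highly significant overlaps (score
#' strictly below `promiscuity_score`) exceeds `promiscuity_degree`: such
#' connectivity is the signature of repeat-derived fingerprints.
#'
#' @param graph An `overlap_graph`.
#' @param params A [match_params()].
#' @return Character vector of excluded clone ids.
#' @export
flag_promiscuous <- function(graph, params = graph$params) {
  e <- graph$edges
  hot <- e$score < params$promiscuity_score
  deg <- table(c(e$a[hot], e$b[hot]))
  sort(names(deg)[deg > params$promiscuity_degree])
}

# drop clones and/or edges from an overlap_graph
drop_from_graph <- function(graph, clones = character(0), edge_idx = integer(0)) {
  if (length(edge_idx))
    graph$edges <- graph$edges[-edge_idx, , drop = FALSE]
  if (length(clones)) {
    graph$nodes <- setdiff(graph$nodes, clones)
    keep <- !(graph$edges$a %in% clones | graph$edges$b %in% clones)
    graph$edges <- graph$edges[keep, , drop = FALSE]
    keep2 <- !(graph$compat_edges$a %in% clones |
                 graph$compat_edges$b %in% clones)
    graph$compat_edges <- graph$compat_edges[keep2, , drop = FALSE]
    graph$band_counts <- graph$band_counts[graph$nodes]
  }
  rownames(graph$edges) <- NULL
  graph
}

# igraph view of an overlap_graph (weights = -log10 score)
as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = graph$nodes))
  igraph::E(g)$weight <- pmax(-graph$edges$log10_score, 1e-9)
  igraph::E(g)$score <- graph$edges$score
  g
}
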