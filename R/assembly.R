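# --- component utilities -----------------------------------------------------

graph_components <- function(graph) {
  g <- as_igraph(graph)
  cm <- igraph::components(g)
  split(igraph::V(g)$name, cm$membership)
}

component_edges <- function(graph, nodes) {
  e <- graph$edges
  e[e$a %in% nodes & e$b %in% nodes, , drop = FALSE]
}

component_compat <- function(graph, nodes) {
  e <- graph$compat_edges
  if (is.null(e)) return(NULL)
  e[e$a %in% nodes & e$b %in% nodes, , drop = FALSE]
}

# matrices for a component: significant adjacency (adj), compatibility
# adjacency (adjc = significant + near-significant) and -log10-score weights
component_matrices <- function(nodes, edges, compat = NULL) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  w <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    ia <- match(edges$a, nodes); ib <- match(edges$b, nodes)
    wt <- pmax(-edges$log10_score, 1e-9)
    adj[cbind(ia, ib)] <- TRUE; adj[cbind(ib, ia)] <- TRUE
    w[cbind(ia, ib)] <- wt; w[cbind(ib, ia)] <- wt
  }
  adjc <- adj
  if (!is.null(compat) && nrow(compat)) {
    ia <- match(compat$a, nodes); ib <- match(compat$b, nodes)
    ok <- !is.na(ia) & !is.na(ib)
    adjc[cbind(ia[ok], ib[ok])] <- TRUE
    adjc[cbind(ib[ok], ia[ok])] <- TRUE
  }
  list(adj = adj, adjc = adjc, w = w)
}

# --- ordering ----------------------------------------------------------------

# greedy end-extension path: seed at the strongest edge, repeatedly attach the
# unplaced clone with the most significant overlap to either end, then insert
# any leftovers next to their strongest placed neighbour
greedy_path_order <- function(nodes, w) {
  n <- length(nodes)
  if (n == 1) return(1L)
  seed <- which(w == max(w), arr.ind = TRUE)
  seed <- seed[order(seed[, 1], seed[, 2]), , drop = FALSE][1, ]
  path <- c(seed[1], seed[2])
  placed <- rep(FALSE, n); placed[path] <- TRUE
  repeat {
    l <- path[1]; r <- path[length(path)]
    wl <- ifelse(placed, -Inf, w[l, ]); wr <- ifelse(placed, -Inf, w[r, ])
    bl <- which.max(wl); br <- which.max(wr)
    if (wl[bl] <= 0 && wr[br] <= 0) break
    if (wl[bl] >= wr[br]) { path <- c(bl, path); placed[bl] <- TRUE }
    else { path <- c(path, br); placed[br] <- TRUE }
  }
  left <- which(!placed)
  # insertion phase, strongest-attached first
  while (length(left)) {
    best <- vapply(left, function(i) max(w[i, path]), numeric(1))
    i <- left[which.max(best)]
    nb <- path[which.max(w[i, path])]
    k <- match(nb, path)
    # side chosen by the stronger of the two order-neighbours of nb
    wl <- if (k > 1) w[i, path[k - 1]] else -1
    wr <- if (k < length(path)) w[i, path[k + 1]] else -1
    at <- if (wl >= wr) k else k + 1L
    path <- append(path, i, after = at - 1L)
    left <- setdiff(left, i)
  }
  path
}

# weighted barycenter sweeps: each clone moves to the weighted mean position
# of its neighbours; keeps the permutation, a standard seriation refinement
barycenter_sweeps <- function(ord, w, sweeps = 3L) {
  for (s in seq_len(sweeps)) {
    pos <- numeric(length(ord)); pos[ord] <- seq_along(ord)
    newpos <- vapply(seq_along(pos), function(i) {
      wi <- w[i, ]
      if (sum(wi) == 0) pos[i] else sum(wi * pos) / sum(wi)
    }, numeric(1))
    ord <- order(newpos, seq_along(newpos))
  }
  ord
}

# spectral seriation: order by the Fiedler vector of the weighted Laplacian
spectral_order <- function(w) {
  n <- nrow(w)
  if (n <= 2) return(seq_len(n))
  d <- rowSums(w)
  lap <- diag(d) - w
  ev <- eigen(lap, symmetric = TRUE)
  f <- ev$vectors[, n - 1]
  order(f, seq_len(n))
}

# Interval-consistency violations of an ordering. Clone inserts are
# intervals; in an interval model ordered by start position, an overlap
# between clones i < j implies that every clone k between them also overlaps
# the left endpoint i (the right endpoint need not be reached by a short k).
# The orientation of a contig is unknown, so the anchor direction is chosen
# globally as whichever of the two gives fewer conflicts. Missing edges are
# tested against the compatibility adjacency (significant + near-significant
# overlaps), while constraints are generated from significant edges only.
# Consecutive order positions must additionally be joined by a compatible
# edge. Returns the violation count.
order_violations <- function(ord, adj, adjc = adj) {
  .viol_count(as.integer(ord), adj, adjc)
}

# clones implicated in at least one violation (as step endpoint, spanning-edge
# endpoint, or unconnected intermediate), under the better anchor direction
violation_clones <- function(ord, adj, adjc = adj) {
  .viol_clones(as.integer(ord), adj, adjc)
}

# best ordering of a connected component: greedy end-extension refined by
# barycenter sweeps; if violations remain, spectral seriation is tried and
# the order with fewer violations wins
order_component <- function(nodes, edges, compat = NULL) {
  if (length(nodes) == 1) return(nodes)
  m <- component_matrices(nodes, edges, compat)
  cand <- list(greedy_path_order(nodes, m$w))
  cand[[2]] <- barycenter_sweeps(cand[[1]], m$w)
  v <- vapply(cand, order_violations, integer(1), adj = m$adj,
              adjc = m$adjc)
  if (min(v) > 0) {
    cand[[3]] <- spectral_order(m$w)
    cand[[4]] <- barycenter_sweeps(cand[[3]], m$w)
    v <- vapply(cand, order_violations, integer(1), adj = m$adj,
                adjc = m$adjc)
  }
  nodes[cand[[which.min(v)]]]
}

# linearity test of a connected component under the greedy ordering search
component_is_linear <- function(nodes, edges, compat = NULL) {
  if (length(nodes) <= 2) return(TRUE)
  ord <- order_component(nodes, edges, compat)
  m <- component_matrices(nodes, edges, compat)
  order_violations(match(ord, nodes), m$adj, m$adjc) == 0
}

# total violations of a node set that may be disconnected: each connected
# piece is scored separately under the restriction of the given order (step
# constraints do not apply across pieces)
viol_partition <- function(nodes, edges, compat, full_ord) {
  if (length(nodes) <= 2) return(0L)
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = nodes))
  cm <- igraph::components(g)
  tot <- 0L
  for (p in split(igraph::V(g)$name, cm$membership)) {
    if (length(p) <= 2) next
    ordp <- full_ord[full_ord %in% p]
    ep <- edges[edges$a %in% p & edges$b %in% p, , drop = FALSE]
    cpp <- if (is.null(compat)) NULL else
      compat[compat$a %in% p & compat$b %in% p, , drop = FALSE]
    m <- component_matrices(p, ep, cpp)
    tot <- tot + order_violations(match(ordp, p), m$adj, m$adjc)
  }
  tot
}

# Remove conflict clones from a component until every remaining connected
# piece orders linearly. Candidates are the clones implicated in violations
# plus their neighbours (restricted to `eligible`); each candidate's removal
# is scored by the residual violation count under the current order, the best
# is removed, and the piece is re-ordered. Returns the removed clone ids;
# pieces with no eligible candidate are left as they are (the caller rechecks
# linearity).
resolve_nonlinear <- function(nodes, edges, compat = NULL, eligible = nodes) {
  removed <- character(0)
  queue <- list(nodes)
  while (length(queue)) {
    nd <- queue[[1]]; queue <- queue[-1]
    if (length(nd) <= 2) next
    ed <- edges[edges$a %in% nd & edges$b %in% nd, , drop = FALSE]
    cp <- if (is.null(compat)) NULL else
      compat[compat$a %in% nd & compat$b %in% nd, , drop = FALSE]
    repeat {
      ord <- order_component(nd, ed, cp)
      m <- component_matrices(nd, ed, cp)
      iord <- match(ord, nd)
      v0 <- order_violations(iord, m$adj, m$adjc)
      if (v0 == 0) break
      invol <- violation_clones(iord, m$adj, m$adjc)
      cand_i <- sort(unique(c(invol, which(rowSums(m$adj[, invol,
                                                         drop = FALSE]) > 0))))
      cand <- intersect(nd[cand_i], eligible)
      if (!length(cand)) break
      # score each candidate by the violations left (per connected piece)
      # in the current order without it
      resid <- vapply(cand, function(cl) {
        ndk <- nd[nd != cl]
        edk <- ed[ed$a != cl & ed$b != cl, , drop = FALSE]
        cpk <- if (is.null(cp)) NULL else
          cp[cp$a != cl & cp$b != cl, , drop = FALSE]
        viol_partition(ndk, edk, cpk, ord[ord != cl])
      }, integer(1))
      victim <- cand[order(resid, cand)][1]
      removed <- c(removed, victim)
      nd <- setdiff(nd, victim)
      ed <- ed[ed$a != victim & ed$b != victim, , drop = FALSE]
      if (!is.null(cp))
        cp <- cp[cp$a != victim & cp$b != victim, , drop = FALSE]
      if (length(nd) <= 2) break
      # removal can split the piece: re-queue the components
      g <- igraph::graph_from_data_frame(ed[, c("a", "b")], directed = FALSE,
                                         vertices = data.frame(name = nd))
      cm <- igraph::components(g)
      if (cm$no > 1) {
        queue <- c(queue, split(igraph::V(g)$name, cm$membership))
        break
      }
    }
  }
  removed
}

# --- staged exclusion --------------------------------------------------------

#' Staged exclusion of questionable overlaps and clones
#'
#' Cleans the significant-overlap network in four logged stages before contig
#' construction: (1) overlaps weaker than `q_overlap_cutoff` are dropped;
#' (2) within the subnetwork of overlaps at or below `q_clone_cutoff`, clones
#' whose removal resolves linear-topology conflicts are excluded
#' (questionable clones); (3) components that still fail the linearity test
#' have their weaker edges (score above `split_cutoff`) removed, splitting
#' large groups of highly overlapping clones, and residual conflict clones
#' are excluded at that stricter level; (4) promiscuous clones (more than
#' `promiscuity_degree` overlaps below `promiscuity_score`) are excluded.
#' Already-linear components pass every stage untouched.
#'
#' @param graph An `overlap_graph`.
#' @param params A [match_params()].
#' @return List with the cleaned `graph`, `excluded_clones`
#'   (data.frame `clone_id/stage`) and `excluded_edges`
#'   (data.frame `a/b/score/stage`).
#' @export
exclude_q <- function(graph, params = graph$params) {
  clone_log <- data.frame(clone_id = character(0), stage = character(0))
  edge_log <- data.frame(a = character(0), b = character(0),
                         score = numeric(0), stage = character(0))
  demote_edges <- function(graph, idx, stage) {
    # excluded overlaps stay available as compatibility evidence
    ed <- graph$edges[idx, , drop = FALSE]
    edge_log <<- rbind(edge_log,
                       data.frame(a = ed$a, b = ed$b, score = ed$score,
                                  stage = stage))
    graph$compat_edges <- rbind(graph$compat_edges, ed)
    drop_from_graph(graph, edge_idx = idx)
  }
  # stage 1: questionable overlaps
  weak <- which(!is_significant(graph$edges$score, params$q_overlap_cutoff))
  if (length(weak)) graph <- demote_edges(graph, weak, "q_overlap")
  # stage 2: questionable clones — removal restricted to clones tied into
  # the network at q_clone_cutoff strength (weakly attached clones are not
  # judged at this stage)
  for (nd in graph_components(graph)) {
    if (length(nd) < 3) next
    ed <- component_edges(graph, nd)
    strong <- is_significant(ed$score, params$q_clone_cutoff)
    elig <- unique(c(ed$a[strong], ed$b[strong]))
    rm <- resolve_nonlinear(nd, ed, component_compat(graph, nd),
                            eligible = elig)
    if (length(rm)) {
      clone_log <- rbind(clone_log,
                         data.frame(clone_id = rm, stage = "q_clone"))
      graph <- drop_from_graph(graph, clones = rm)
    }
  }
  # stage 3: split remaining non-linear groups at the stricter cutoff
  for (nd in graph_components(graph)) {
    nd <- intersect(nd, graph$nodes)
    if (length(nd) < 3) next
    ed <- component_edges(graph, nd)
    if (component_is_linear(nd, ed, component_compat(graph, nd))) next
    weak <- which(!is_significant(ed$score, params$split_cutoff))
    if (length(weak)) {
      idx <- match(paste(ed$a[weak], ed$b[weak], sep = "\r"),
                   paste(graph$edges$a, graph$edges$b, sep = "\r"))
      graph <- demote_edges(graph, idx, "split")
    }
    for (nd2 in graph_components_of(graph, nd)) {
      if (length(nd2) < 3) next
      ed2 <- component_edges(graph, nd2)
      cp2 <- component_compat(graph, nd2)
      if (component_is_linear(nd2, ed2, cp2)) next
      rm <- resolve_nonlinear(nd2, ed2, cp2)
      if (length(rm)) {
        clone_log <- rbind(clone_log,
                           data.frame(clone_id = rm, stage = "split"))
        graph <- drop_from_graph(graph, clones = rm)
      }
    }
  }
  # stage 4: promiscuous clones
  prom <- flag_promiscuous(graph, params)
  if (length(prom)) {
    clone_log <- rbind(clone_log,
                       data.frame(clone_id = prom, stage = "promiscuous"))
    graph <- drop_from_graph(graph, clones = prom)
  }
  rownames(clone_log) <- rownames(edge_log) <- NULL
  list(graph = graph, excluded_clones = clone_log, excluded_edges = edge_log)
}

# components of the subgraph induced by `nodes` under graph's current edges
graph_components_of <- function(graph, nodes) {
  ed <- component_edges(graph, nodes)
  g <- igraph::graph_from_data_frame(ed[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = nodes))
  cm <- igraph::components(g)
  split(igraph::V(g)$name, cm$membership)
}

# --- contig construction -----------------------------------------------------

#' Build linear-topology contigs from a cleaned overlap network
#'
#' Connected components passing the linearity test become contigs, with clone
#' order found by greedy end-extension maximising overlap significance and
#' refined so that adjacent order positions are connected by edges (falling
#' back to spectral seriation when refinement leaves conflicts). Components
#' still failing the test have residual conflict clones removed (logged) and
#' are re-split. Contigs are classified reliable (at least
#' `min_reliable_clones` members) or questionable (2 to
#' `min_reliable_clones - 1`); singletons are reported separately. Contig ids
#' are assigned in decreasing estimated-size order; orientation of a contig
#' is arbitrary (reported up to reversal).
#'
#' @param cleaned An `overlap_graph`, normally the `graph` element of
#'   [exclude_q()] output.
#' @param fps Named list of band vectors covering every clone in the graph.
#' @param aparams An [assembly_params()].
#' @param mparams A [match_params()] (for the band-match tolerance).
#' @return An object of class `contig_set`: list with `contigs` (data.frame
#'   `contig_id/n_clones/consensus_bands/est_kb/reliability/depth`),
#'   `clone_order` (named list), `singletons` and `removed` (residual
#'   topology exclusions, data.frame `clone_id/stage`).
#' @export
build_contigs <- function(cleaned, fps, aparams = assembly_params(),
                          mparams = cleaned$params) {
  orders <- list()
  singles <- character(0)
  removed <- character(0)
  for (nd in graph_components(cleaned)) {
    if (length(nd) == 1) { singles <- c(singles, nd); next }
    ed <- component_edges(cleaned, nd)
    cp <- component_compat(cleaned, nd)
    pieces <- list(nd)
    if (!component_is_linear(nd, ed, cp)) {
      rm <- resolve_nonlinear(nd, ed, cp)
      removed <- c(removed, rm)
      nd2 <- setdiff(nd, rm)
      sub <- drop_from_graph(cleaned, clones = rm)
      pieces <- if (length(nd2)) graph_components_of(sub, nd2) else list()
    }
    for (p in pieces) {
      if (length(p) == 1) { singles <- c(singles, p); next }
      orders[[length(orders) + 1]] <-
        order_component(p, component_edges(cleaned, p),
                        component_compat(cleaned, p))
    }
  }
  t <- mparams$tolerance
  cb <- vapply(orders, consensus_band_count, integer(1), fps = fps, t = t)
  est <- estimate_length(cb, aparams)
  n_cl <- lengths(orders)
  o <- order(-est, -n_cl)
  orders <- orders[o]; cb <- cb[o]; est <- est[o]; n_cl <- n_cl[o]
  ids <- sprintf("ctg%d", seq_along(orders))
  names(orders) <- ids
  contigs <- data.frame(
    contig_id = ids, n_clones = n_cl, consensus_bands = cb, est_kb = est,
    reliability = ifelse(n_cl >= aparams$min_reliable_clones,
                         "reliable", "questionable"),
    depth = vapply(seq_along(ids), function(i)
      contig_depth(n_cl[i], est[i], aparams), numeric(1)))
  rownames(contigs) <- NULL
  structure(list(contigs = contigs, clone_order = orders,
                 singletons = sort(singles),
                 removed = data.frame(clone_id = removed,
                                      stage = rep("topology",
                                                  length(removed)))),
            class = "contig_set")
}

#' Consensus band count of an ordered contig
#'
#' Bands of adjacent clones are matched within the tolerance; matched bands
#' chain across the contig, and the consensus count is the number of chains.
#' Because each band matches at most one band in the next clone, the chains
#' form a forest and the count equals total bands minus total adjacent
#' matches.
#'
#' @param order Ordered clone ids.
#' @param fps Named list of band vectors.
#' @param t Match tolerance.
#' @return Integer consensus band count.
#' @export
consensus_band_count <- function(order, fps, t = 0L) {
  b <- fps[order]
  total <- sum(lengths(b))
  if (length(b) < 2) return(as.integer(total))
  matches <- sum(vapply(seq_len(length(b) - 1), function(i)
    .sb_pair(as.integer(b[[i]]), as.integer(b[[i + 1]]), as.integer(t)),
    integer(1)))
  as.integer(total - matches)
}

#' Estimated contig length from consensus bands
#'
#' @param count Consensus band count (vectorised).
#' @param params An [assembly_params()] (1.2 kb per consensus band).
#' @return Estimated length in kb; linear in the count.
#' @export
estimate_length <- function(count, params = assembly_params()) {
  count * params$band_to_kb
}

#' Contig assembly depth
#'
#' Calculated contig length (clones times the mean insert size) divided by
#' the estimated contig length.
#'
#' @param n_clones Number of clones in the contig.
#' @param est_kb Estimated contig length (kb).
#' @param params An [assembly_params()].
#' @return Depth in fold coverage.
#' @export
contig_depth <- function(n_clones, est_kb, params = assembly_params()) {
  if (any(est_kb <= 0)) stop("estimated contig length must be positive")
  n_clones * params$mean_insert_kb / est_kb
}

# --- minimal tiling path -----------------------------------------------------

#' Select a minimal tiling path through an ordered contig
#'
#' Greedy left-to-right selection: from the current MTP clone, the farthest
#' clone in contig order whose overlap with it satisfies the mode's
#' constraints becomes the next MTP clone; the first and last clones are
#' always included. LTC mode requires the pairwise Sulston score at or below
#' `mtp_cutoff`; FPC mode requires score at or below `fpc_mtp$min_overlap`,
#' at least `fpc_mtp$min_shared` shared bands, and at least
#' `fpc_mtp$min_dist_bands` bands of new material in the next clone. When no
#' clone satisfies the constraints the immediate neighbour is taken and a
#' warning recorded.
#'
#' @param order Ordered clone ids of one contig.
#' @param fps Named list of band vectors.
#' @param mparams A [match_params()].
#' @param aparams An [assembly_params()] (FPC-mode constants).
#' @param mode `"ltc"` or `"fpc"`.
#' @return Character vector of MTP clone ids (attribute `warnings` lists
#'   forced-neighbour fallbacks).
#' @export
select_mtp <- function(order, fps, mparams = match_params(),
                       aparams = assembly_params(), mode = c("ltc", "fpc")) {
  mode <- match.arg(mode)
  n <- length(order)
  if (n <= 1) return(order)
  b <- lapply(fps[order], as.integer)
  t <- mparams$tolerance
  ok_pair <- function(i, j) {
    s <- .sb_pair(b[[i]], b[[j]], t)
    nl <- min(length(b[[i]]), length(b[[j]]))
    nh <- max(length(b[[i]]), length(b[[j]]))
    if (s > nl) s <- nl
    sc <- sulston_score(nl, nh, s, mparams, log10p = TRUE)
    if (mode == "ltc") {
      is_significant(sc, log10(mparams$mtp_cutoff))
    } else {
      is_significant(sc, log10(aparams$fpc_mtp$min_overlap)) &&
        s >= aparams$fpc_mtp$min_shared &&
        (length(b[[j]]) - s) >= aparams$fpc_mtp$min_dist_bands
    }
  }
  mtp <- 1L
  warnings <- character(0)
  cur <- 1L
  while (cur < n) {
    nxt <- NA_integer_
    for (j in n:(cur + 1L)) {
      if (ok_pair(cur, j)) { nxt <- j; break }
    }
    if (is.na(nxt)) {
      nxt <- cur + 1L
      warnings <- c(warnings, sprintf(
        "no clone satisfies MTP constraints after %s; forced neighbour %s",
        order[cur], order[nxt]))
    }
    mtp <- c(mtp, nxt)
    cur <- nxt
  }
  structure(order[mtp], warnings = warnings)
}
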