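# terminal clones of each contig (first and last in order)
contig_terminals <- function(contig_set) {
  lapply(contig_set$clone_order, function(o) c(o[1], o[length(o)]))
}

#' Merge contigs end-to-end into scaffolds
#'
#' Two contigs are merged when their terminal clones are joined by a single
#' linking clone (a singleton with significant overlaps to a terminal clone
#' of each contig), by a single significant terminal-terminal overlap that
#' was removed during staged exclusion, or when the same marker hits a
#' terminal clone of each contig (validation rule a). A contig end with more
#' than one merge partner is a conflict: no merge is made and the conflict is
#' logged. Junction evidence is recorded for every adjacent contig pair.
#'
#' @param contig_set A `contig_set` from [build_contigs()].
#' @param graph The original (pre-exclusion) `overlap_graph`.
#' @param marker_hits data.frame `marker_id/clone_id` of marker-positive
#'   clones.
#' @param params A [match_params()].
#' @return An object of class `scaffold_set`: list with `scaffolds` (each a
#'   list of ordered `contigs` and a `junctions` data.frame
#'   `left/right/evidence/detail`) and `conflicts` (data.frame).
#' @export
merge_scaffolds <- function(contig_set, graph,
                            marker_hits = data.frame(marker_id = character(0),
                                                     clone_id = character(0)),
                            params = graph$params) {
  terms <- contig_terminals(contig_set)
  ids <- names(terms)
  clone2ctg <- rep(names(contig_set$clone_order),
                   lengths(contig_set$clone_order))
  names(clone2ctg) <- unlist(contig_set$clone_order, use.names = FALSE)
  term_clones <- unlist(terms, use.names = FALSE)
  # junction evidence is by construction weaker than contig-internal proof:
  # a clone overlap strong enough for the network would have fused the
  # contigs already, so links draw on significant plus near-significant
  # (compatibility) overlaps, including overlaps demoted during staged
  # exclusion
  e <- rbind(graph$edges, graph$compat_edges)

  links <- data.frame(c1 = character(0), c2 = character(0),
                      evidence = character(0), detail = character(0))
  add_link <- function(c1, c2, evidence, detail) {
    if (c1 == c2) return()
    k <- sort(c(c1, c2))
    links[nrow(links) + 1L, ] <<- c(k[1], k[2], evidence, detail)
  }

  # single linking clone: a singleton touching terminal clones of two contigs
  for (s in contig_set$singletons) {
    nb <- unique(c(e$b[e$a == s], e$a[e$b == s]))
    nb <- nb[nb %in% term_clones]
    ctgs <- unique(clone2ctg[nb])
    ctgs <- ctgs[!is.na(ctgs)]
    if (length(ctgs) == 2)
      add_link(ctgs[1], ctgs[2], "single-clone", s)
  }
  # single terminal-terminal overlap (removed during exclusion, hence the
  # contigs stayed separate)
  tt <- e[e$a %in% term_clones & e$b %in% term_clones, , drop = FALSE]
  if (nrow(tt)) {
    ca <- clone2ctg[tt$a]; cb <- clone2ctg[tt$b]
    for (r in which(!is.na(ca) & !is.na(cb) & ca != cb))
      add_link(ca[r], cb[r], "single-overlap",
               paste(tt$a[r], tt$b[r], sep = "~"))
  }
  # rule (a): the same marker at the ends of two contigs
  mh <- marker_hits[marker_hits$clone_id %in% term_clones, , drop = FALSE]
  if (nrow(mh)) {
    for (m in unique(mh$marker_id)) {
      ctgs <- unique(clone2ctg[mh$clone_id[mh$marker_id == m]])
      ctgs <- ctgs[!is.na(ctgs)]
      if (length(ctgs) == 2) add_link(ctgs[1], ctgs[2], "marker", m)
    }
  }
  links <- unique(links)

  # conflict resolution: a contig appearing in links to 3+ partners, or a
  # marker hitting terminals of 3+ contigs, blocks those merges
  conflicts <- data.frame(contig = character(0), detail = character(0))
  mh_all <- marker_hits[marker_hits$clone_id %in% term_clones, , drop = FALSE]
  for (m in unique(mh_all$marker_id)) {
    ctgs <- unique(clone2ctg[mh_all$clone_id[mh_all$marker_id == m]])
    ctgs <- ctgs[!is.na(ctgs)]
    if (length(ctgs) > 2)
      conflicts <- rbind(conflicts, data.frame(
        contig = paste(sort(ctgs), collapse = ","),
        detail = paste0("marker ", m, " hits terminals of ",
                        length(ctgs), " contigs")))
  }
  deg <- table(c(links$c1, links$c2))
  over <- names(deg)[deg > 2]  # a linear contig has at most two ends
  if (length(over)) {
    for (ct in over)
      conflicts <- rbind(conflicts, data.frame(
        contig = ct, detail = "more than two merge partners"))
    links <- links[!(links$c1 %in% over | links$c2 %in% over), , drop = FALSE]
  }
  # drop markers with >2 terminal contigs from links
  if (nrow(conflicts)) {
    bad_m <- unique(mh_all$marker_id[vapply(mh_all$marker_id, function(m) {
      ctgs <- unique(clone2ctg[mh_all$clone_id[mh_all$marker_id == m]])
      length(ctgs[!is.na(ctgs)]) > 2
    }, logical(1))])
    links <- links[!(links$evidence == "marker" &
                       links$detail %in% bad_m), , drop = FALSE]
  }

  # chain contigs through accepted links
  g <- igraph::graph_from_data_frame(
    links[, c("c1", "c2")], directed = FALSE,
    vertices = data.frame(name = ids))
  cm <- igraph::components(g)
  scaffolds <- lapply(split(ids, cm$membership[ids]), function(ct) {
    if (length(ct) == 1)
      return(list(contigs = ct,
                  junctions = data.frame(left = character(0),
                                         right = character(0),
                                         evidence = character(0),
                                         detail = character(0))))
    sub <- links[links$c1 %in% ct & links$c2 %in% ct, , drop = FALSE]
    # order the chain from one end
    deg <- table(c(sub$c1, sub$c2))
    start <- sort(names(deg)[deg == 1])[1]
    if (is.na(start)) start <- sort(ct)[1]  # cyclic, arbitrary break
    ordered <- start
    repeat {
      cur <- ordered[length(ordered)]
      nb <- setdiff(c(sub$c2[sub$c1 == cur], sub$c1[sub$c2 == cur]), ordered)
      if (!length(nb)) break
      ordered <- c(ordered, nb[1])
    }
    jn <- do.call(rbind, lapply(seq_len(length(ordered) - 1), function(i) {
      k <- sort(c(ordered[i], ordered[i + 1]))
      row <- sub[sub$c1 == k[1] & sub$c2 == k[2], , drop = FALSE][1, ]
      data.frame(left = ordered[i], right = ordered[i + 1],
                 evidence = row$evidence, detail = row$detail)
    }))
    list(contigs = ordered, junctions = jn)
  })
  names(scaffolds) <- sprintf("scf%d", seq_along(scaffolds))
  structure(list(scaffolds = scaffolds, links = links,
                 conflicts = conflicts),
            class = "scaffold_set")
}

#' Validate scaffolds against marker and genetic-map evidence
#'
#' Applies three marker-based validation rules: (b) a marker present in a
#' group of mutually overlapping clones inside one contig and in a single
#' clone elsewhere flags that single clone as presumably chimeric; (c) a
#' marker present in two or more internal overlapping groups flags the marker
#' as non-unique; (d) two markers in one scaffold separated by more than
#' `cm_threshold` on the genetic map flag the scaffold for splitting, applied
#' (when `apply_splits`) at the weakest junction between them (junction
#' evidence ranked marker > single-clone > single-overlap).
#'
#' @param scaffold_set A `scaffold_set`.
#' @param contig_set The underlying `contig_set`.
#' @param graph The cleaned `overlap_graph` (to test mutual overlap).
#' @param marker_hits data.frame `marker_id/clone_id`.
#' @param genetic_map data.frame `marker_id/cm` for the mapped subset.
#' @param cm_threshold Genetic distance (cM) beyond which co-scaffold markers
#'   are inconsistent.
#' @param apply_splits Split flagged scaffolds at the weakest junction.
#' @return List with `flags` (data.frame `rule/subject/marker/detail`) and
#'   `scaffolds` (possibly split).
#' @export
validate_scaffolds <- function(scaffold_set, contig_set, graph, marker_hits,
                               genetic_map = data.frame(marker_id = character(0),
                                                        cm = numeric(0)),
                               cm_threshold = 10, apply_splits = FALSE) {
  flags <- data.frame(rule = character(0), subject = character(0),
                      marker = character(0), detail = character(0))
  clone2ctg <- rep(names(contig_set$clone_order),
                   lengths(contig_set$clone_order))
  names(clone2ctg) <- unlist(contig_set$clone_order, use.names = FALSE)
  e <- graph$edges
  connected <- function(x, y)
    any((e$a == x & e$b == y) | (e$a == y & e$b == x))

  for (m in unique(marker_hits$marker_id)) {
    cl <- marker_hits$clone_id[marker_hits$marker_id == m]
    ctg <- clone2ctg[cl]
    groups <- list(); isolated <- character(0)
    for (ct in unique(ctg[!is.na(ctg)])) {
      members <- cl[!is.na(ctg) & ctg == ct]
      if (length(members) >= 2) {
        # mutually overlapping = pairwise connected in the cleaned network
        pairs <- utils::combn(members, 2)
        mutual <- all(vapply(seq_len(ncol(pairs)), function(k)
          connected(pairs[1, k], pairs[2, k]), logical(1)))
        if (mutual) groups[[length(groups) + 1]] <- members
        else isolated <- c(isolated, members)
      } else isolated <- c(isolated, members)
    }
    if (length(groups) >= 2)
      flags <- rbind(flags, data.frame(
        rule = "c", subject = m, marker = m,
        detail = sprintf("marker in %d internal groups", length(groups))))
    if (length(groups) == 1 && length(isolated))
      for (s in isolated)
        flags <- rbind(flags, data.frame(
          rule = "b", subject = s, marker = m,
          detail = "single distant hit beside an internal overlapping group"))
  }

  # rule (d): genetic-map distance within scaffolds
  ev_rank <- c("single-overlap" = 1, "single-clone" = 2, marker = 3)
  out_scaffolds <- list()
  for (sn in names(scaffold_set$scaffolds)) {
    sc <- scaffold_set$scaffolds[[sn]]
    mk <- unique(marker_hits[clone2ctg[marker_hits$clone_id] %in% sc$contigs,
                             "marker_id"])
    cm <- genetic_map$cm[match(mk, genetic_map$marker_id)]
    mk <- mk[!is.na(cm)]; cm <- cm[!is.na(cm)]
    split_here <- FALSE
    if (length(cm) >= 2 && diff(range(cm)) > cm_threshold) {
      pair <- c(mk[which.min(cm)], mk[which.max(cm)])
      flags <- rbind(flags, data.frame(
        rule = "d", subject = sn, marker = paste(pair, collapse = ","),
        detail = sprintf("markers %.1f cM apart (> %.1f)",
                         diff(range(cm)), cm_threshold)))
      split_here <- apply_splits && nrow(sc$junctions) > 0
    }
    if (split_here) {
      jr <- ev_rank[sc$junctions$evidence]
      cut <- which.min(jr)  # weakest junction between the markers
      left <- sc$contigs[seq_len(cut)]
      right <- sc$contigs[(cut + 1):length(sc$contigs)]
      out_scaffolds[[paste0(sn, "a")]] <-
        list(contigs = left,
             junctions = sc$junctions[seq_len(cut - 1), , drop = FALSE])
      out_scaffolds[[paste0(sn, "b")]] <-
        list(contigs = right,
             junctions = sc$junctions[setdiff(seq_len(nrow(sc$junctions)),
                                              seq_len(cut)), , drop = FALSE])
    } else out_scaffolds[[sn]] <- sc
  }
  rownames(flags) <- NULL
  list(flags = flags, scaffolds = out_scaffolds)
}
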