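#' Deletion-bin table of a chromosome arm
#'
#' Ordered bins as fraction intervals of the arm, half-open except the
#' terminal bin which is closed at 1.0. The default table reproduces the
#' 5BS deletion-line bins; note that bins 5BS8 and 5BS1 overlap on
#' 0.67--0.71 as printed in the source map, so assignment in that zone
#' returns both.
#'
#' @param name,start,end Bin names and fraction intervals.
#' @return data.frame `name/start/end` of class `bin_table`.
#' @export
bin_table <- function(name = c("C-5BS3", "5BS3", "5BS2", "5BS4", "5BS8",
                               "5BS1", "5BS5", "5BS6"),
                      start = c(0, 0.41, 0.42, 0.43, 0.56, 0.67, 0.71, 0.81),
                      end = c(0.41, 0.42, 0.43, 0.56, 0.71, 0.71, 0.81, 1.00)) {
  stopifnot(length(name) == length(start), length(start) == length(end),
            all(start >= 0), all(end <= 1), all(start < end))
  structure(data.frame(name = name, start = start, end = end),
            class = c("bin_table", "data.frame"))
}

#' Assign a fractional arm position to deletion bins
#'
#' Returns every bin whose half-open interval contains the fraction; the
#' terminal bin (ending at 1.0) is closed on the right. Bins may overlap, in
#' which case all containing bins are returned.
#'
#' @param fraction Position as a fraction of the arm, in `[0, 1]`.
#' @param bins A [bin_table()].
#' @return Character vector of bin names.
#' @export
assign_bins <- function(fraction, bins = bin_table()) {
  stopifnot(fraction >= 0, fraction <= 1)
  hit <- fraction >= bins$start &
    (fraction < bins$end | (bins$end == 1 & fraction <= 1))
  bins$name[hit]
}

#' Pool layout of a plated BAC library
#'
#' Builds plate pools (one per 384-well plate) and row/column pools per plate
#' from the plate coordinates of a `clone_set`. Every clone belongs to
#' exactly one plate, one row and one column pool.
#'
#' @param clones A `clone_set`.
#' @return An object of class `pool_layout`: list with `plate`, `row` and
#'   `col` pool memberships (named by pool id, each a character vector of
#'   clone ids).
#' @export
pool_layout <- function(clones) {
  stopifnot(inherits(clones, "clone_set"))
  plate_id <- sprintf("P%03d", clones$plate)
  row_id <- sprintf("P%03d-R%s", clones$plate, clones$row)
  col_id <- sprintf("P%03d-C%02d", clones$plate, clones$col)
  structure(list(
    plate = split(clones$clone_id, plate_id),
    row = split(clones$clone_id, row_id),
    col = split(clones$clone_id, col_id),
    wells = data.frame(clone_id = clones$clone_id, plate = clones$plate,
                       row = clones$row, col = clones$col)),
    class = "pool_layout")
}

#' Screen pooled library DNA with PCR markers
#'
#' A clone is marker-positive iff its interval contains the marker locus (on
#' the target chromosome). Positive plate, row and column pools are computed
#' per marker and deconvolved by intersection: within a positive plate, the
#' candidate wells are the cross of positive rows and positive columns. A
#' plate with two or more positive rows and two or more positive columns is
#' ambiguous: its candidates are reported but not confirmed.
#'
#' @param markers data.frame `id/pos` of marker loci (bp on the target).
#' @param clones A `clone_set`.
#' @param layout A [pool_layout()]; computed from `clones` when missing.
#' @return Named list per marker: `pools` (positive pool ids), `hits`
#'   (confirmed clone ids), `candidates` (clone ids in ambiguous plates) and
#'   `ambiguous` (logical).
#' @export
screen_pools <- function(markers, clones, layout = pool_layout(clones)) {
  stopifnot(inherits(clones, "clone_set"))
  out <- vector("list", nrow(markers))
  names(out) <- markers$id
  for (k in seq_len(nrow(markers))) {
    pos <- markers$pos[k]
    positive <- clones$clone_id[clones$source == "target" &
                                  clones$start <= pos & pos < clones$end]
    pools <- c(
      names(layout$plate)[vapply(layout$plate, function(p)
        any(p %in% positive), logical(1))],
      names(layout$row)[vapply(layout$row, function(p)
        any(p %in% positive), logical(1))],
      names(layout$col)[vapply(layout$col, function(p)
        any(p %in% positive), logical(1))])
    hits <- character(0); cands <- character(0); amb <- FALSE
    w <- layout$wells[layout$wells$clone_id %in% positive, , drop = FALSE]
    for (pl in unique(w$plate)) {
      rows <- unique(w$row[w$plate == pl])
      cols <- unique(w$col[w$plate == pl])
      cell <- layout$wells[layout$wells$plate == pl &
                             layout$wells$row %in% rows &
                             layout$wells$col %in% cols, "clone_id"]
      if (length(rows) >= 2 && length(cols) >= 2) {
        amb <- TRUE
        cands <- c(cands, cell)
      } else hits <- c(hits, cell)
    }
    out[[k]] <- list(pools = sort(pools), hits = sort(hits),
                     candidates = sort(cands), ambiguous = amb)
  }
  out
}

#' Direct marker-to-clone hit table
#'
#' Ground-truth interval containment, used for scaffold merging and
#' validation independently of the pooling assay.
#'
#' @param markers data.frame `id/pos`.
#' @param clones A `clone_set`.
#' @return data.frame `marker_id/clone_id`.
#' @export
marker_clone_hits <- function(markers, clones) {
  out <- lapply(seq_len(nrow(markers)), function(k) {
    pos <- markers$pos[k]
    hit <- clones$clone_id[clones$source == "target" &
                             clones$start <= pos & pos < clones$end]
    if (length(hit)) data.frame(marker_id = markers$id[k], clone_id = hit)
    else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(marker_id = character(0),
                               clone_id = character(0))
  else out
}

#' Anchor clones and contigs to a reference by fingerprint comparison
#'
#' Each clone fingerprint is compared with every reference-window fingerprint
#' by shared bands and Sulston score; the best-scoring window at or below the
#' network cutoff (ties broken by leftmost window start) anchors the clone. A
#' contig anchors at the median window midpoint of its anchored clones; with
#' two or more anchored clones it also receives an orientation (sign of the
#' order-versus-position correlation), and contigs anchored by three or more
#' clones with mutually consistent positions (span below twice the estimated
#' length) are marked key contigs.
#'
#' @param clone_fps Named list of band vectors (typically MTP clones).
#' @param window_fps Output of [fingerprint_windows()].
#' @param params A [match_params()].
#' @param contig_set Optional `contig_set` to summarise contig-level anchors.
#' @return List with `clones` (data.frame
#'   `clone_id/window/start/end/shared/log10_score`) and, when `contig_set`
#'   is given, `contigs` (data.frame
#'   `contig_id/position/n_anchored/orientation/key`).
#' @export
anchor_by_reference <- function(clone_fps, window_fps,
                                params = match_params(),
                                contig_set = NULL) {
  wins <- attr(window_fps, "windows")
  stopifnot(!is.null(wins))
  nb_c <- lengths(clone_fps); nb_w <- lengths(window_fps)
  sh <- .sb_cross(lapply(clone_fps, as.integer),
                  lapply(window_fps, as.integer), params$tolerance)
  nl <- outer(nb_c, nb_w, pmin); nh <- outer(nb_c, nb_w, pmax)
  lg <- matrix(sulston_score(as.vector(nl), as.vector(nh), as.vector(sh),
                             params, log10p = TRUE),
               nrow = length(clone_fps))
  recs <- NULL
  best_lg <- apply(lg, 1, min)
  ok <- which(best_lg <= log10(params$network_cutoff))
  if (length(ok)) {
    bw <- vapply(ok, function(i) {
      cand <- which(lg[i, ] == best_lg[i])
      cand[which.min(wins$start[cand])]  # leftmost window on ties
    }, integer(1))
    recs <- data.frame(clone_id = names(clone_fps)[ok],
                       window = wins$id[bw],
                       start = wins$start[bw], end = wins$end[bw],
                       shared = sh[cbind(ok, bw)],
                       log10_score = best_lg[ok])
  } else {
    recs <- data.frame(clone_id = character(0), window = character(0),
                       start = integer(0), end = integer(0),
                       shared = integer(0), log10_score = numeric(0))
  }
  out <- list(clones = recs)
  if (!is.null(contig_set)) {
    mids <- (recs$start + recs$end) / 2
    names(mids) <- recs$clone_id
    ctg <- lapply(names(contig_set$clone_order), function(id) {
      ord <- contig_set$clone_order[[id]]
      anch <- ord[ord %in% names(mids)]
      if (!length(anch)) return(NULL)
      pos <- mids[anch]
      ori <- if (length(anch) >= 2 && length(unique(pos)) > 1 &&
                 length(unique(match(anch, ord))) > 1) {
        r <- suppressWarnings(cor(match(anch, ord), pos,
                                  method = "spearman"))
        if (is.na(r) || r == 0) 0L else as.integer(sign(r))
      } else 0L
      est <- contig_set$contigs$est_kb[contig_set$contigs$contig_id == id]
      key <- length(anch) >= 3 &&
        diff(range(pos)) / 1000 < 2 * est
      data.frame(contig_id = id, position = median(pos),
                 n_anchored = length(anch), orientation = ori, key = key)
    })
    out$contigs <- do.call(rbind, ctg)
    if (is.null(out$contigs))
      out$contigs <- data.frame(contig_id = character(0),
                                position = numeric(0),
                                n_anchored = integer(0),
                                orientation = integer(0), key = logical(0))
  }
  out
}

#' Staged anchoring coverage accounting
#'
#' Each contig is counted once, at the earliest stage that anchors it;
#' cumulative anchored kb and the integer percentage of the arm are reported
#' per stage, so `cumulative(k) = cumulative(k-1) + increment(k)`.
#'
#' @param stage Integer vector (1, 2 or 3; `NA` = never anchored), the
#'   earliest anchoring stage per contig, parallel to `est_kb` — or, if
#'   `est_kb` is missing, a numeric vector of per-stage increment kb.
#' @param est_kb Estimated contig lengths (kb).
#' @param chrom_kb Chromosome arm length (kb).
#' @return data.frame `stage/increment_kb/cumulative_kb/percent`.
#' @export
staged_coverage <- function(stage, est_kb = NULL, chrom_kb) {
  if (is.null(est_kb)) {
    inc <- as.numeric(stage)
  } else {
    stopifnot(length(stage) == length(est_kb))
    inc <- vapply(1:3, function(k)
      sum(est_kb[!is.na(stage) & stage == k]), numeric(1))
  }
  cum <- cumsum(inc)
  data.frame(stage = seq_along(inc), increment_kb = inc,
             cumulative_kb = cum,
             percent = vapply(cum, percent_of, numeric(1),
                              total = chrom_kb, digits = 0))
}
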