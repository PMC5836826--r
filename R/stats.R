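#' Percentage with half-up rounding
#'
#' @param x Numerator.
#' @param total Denominator.
#' @param digits Decimal digits (0 for the integer percentages used in
#'   coverage reporting, 1 for fingerprint-yield style percentages).
#' @return `x / total * 100`, rounded half-up.
#' @export
percent_of <- function(x, total, digits = 0) {
  if (total <= 0) stop("total must be positive")
  round_half_up(x / total * 100, digits)
}

#' Fold ratio rounded to one decimal
#'
#' @param a,b Numerator and denominator.
#' @return `a / b` rounded half-up to one decimal, the convention used for
#'   fold-change comparisons between assemblies.
#' @export
fold_ratio <- function(a, b) round_half_up(a / b, 1)

#' N50 and L50 of a set of contig lengths
#'
#' Lengths are sorted in decreasing order; N50 is the length of the first
#' contig at which the cumulative sum reaches at least half the total, and
#' L50 is its 1-based rank.
#'
#' @param lengths Positive contig lengths (kb).
#' @return List with `n50` and `l50`.
#' @export
n50_l50 <- function(lengths) {
  if (!length(lengths)) stop("empty length list")
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  i <- which(cumsum(s) >= sum(s) / 2)[1]
  list(n50 = s[i], l50 = i)
}

#' Chromosome coverage percentage
#'
#' @param total_kb Summed estimated contig length (kb).
#' @param chrom_kb Chromosome arm length (kb).
#' @return Integer-rounded percentage (half-up).
#' @export
coverage_percent <- function(total_kb, chrom_kb) {
  stopifnot(chrom_kb > 0)
  percent_of(total_kb, chrom_kb, digits = 0)
}

#' Assembly depth report
#'
#' Mean assembly depth is the calculated assembly length (clones times the
#' mean insert size) divided by the estimated assembly length; contigs whose
#' own depth exceeds `k` times the mean are flagged as outliers (repeat
#' candidates).
#'
#' @param contigs Contig table with columns `contig_id`, `n_clones`,
#'   `est_kb`, `depth`.
#' @param params An [assembly_params()].
#' @param k Outlier multiplier (default 1.5).
#' @return List with `mean_depth` (one decimal), `depths` and `outliers`.
#' @export
depth_report <- function(contigs, params = assembly_params(), k = 1.5) {
  stopifnot(nrow(contigs) > 0)
  mean_depth <- sum(contigs$n_clones * params$mean_insert_kb) /
    sum(contigs$est_kb)
  out <- contigs[contigs$depth > k * mean_depth, , drop = FALSE]
  list(mean_depth = round_half_up(mean_depth, 1),
       depths = contigs[, c("contig_id", "est_kb", "depth")],
       outliers = out[, c("contig_id", "est_kb", "depth")])
}

# size-class group boundaries in kb (lower edges; first group is everything
# below the second edge); labels follow the canonical unscaled ranges
.SIZE_GROUPS <- c(0, 1000, 3500, 10000)
.SIZE_LABELS <- c("200-999", "1000-3499", "3500-9999", ">=10000")

#' Contig size-class and positional distribution
#'
#' Classifies contigs into four size groups (200--999, 1000--3499,
#' 3500--9999 and >= 10,000 kb at `scale = 1`; the first group absorbs
#' anything smaller) and tallies them over six equal chromosome intervals by
#' anchor midpoint. Contigs without an anchored position are counted in an
#' `unplaced` column. A length histogram with 500-kb bins below 8,000 kb and
#' 1,000-kb bins above is included.
#'
#' @param contigs Contig table with columns `contig_id` and `est_kb`.
#' @param anchors_bp Named numeric of anchor midpoints (bp) for the anchored
#'   subset of `contigs$contig_id`.
#' @param chrom_length_bp Chromosome length in bp.
#' @param scale Scale factor applied to all group and histogram boundaries
#'   (desk-scale simulations use contigs roughly one order of magnitude
#'   smaller than a 290-Mb arm).
#' @return An object of class `size_class_report`: list with `groups`
#'   (per-contig group), `table` (6 intervals + unplaced, by group) and
#'   `histogram`.
#' @export
size_class_report <- function(contigs, anchors_bp, chrom_length_bp,
                              scale = 1) {
  breaks <- c(.SIZE_GROUPS * scale, Inf)
  grp <- cut(contigs$est_kb, breaks = breaks, labels = .SIZE_LABELS,
             right = FALSE, include.lowest = TRUE)
  iv_breaks <- chrom_length_bp * (0:6) / 6
  mid <- anchors_bp[match(contigs$contig_id, names(anchors_bp))]
  interval <- findInterval(mid, iv_breaks, rightmost.closed = TRUE)
  interval[is.na(interval)] <- 0L  # unplaced
  tab <- matrix(0L, nrow = 4, ncol = 7,
                dimnames = list(.SIZE_LABELS,
                                c(paste0("interval", 1:6), "unplaced")))
  for (i in seq_len(nrow(contigs))) {
    col <- if (interval[i] == 0) 7L else interval[i]
    tab[as.integer(grp[i]), col] <- tab[as.integer(grp[i]), col] + 1L
  }
  hbr <- unique(c(seq(0, 8000, by = 500) * scale,
                  seq(8000, max(9000, ceiling(max(contigs$est_kb) /
                                                (1000 * scale)) * 1000),
                      by = 1000) * scale))
  hist_counts <- table(cut(contigs$est_kb, breaks = c(hbr, Inf),
                           right = FALSE))
  structure(list(groups = data.frame(contig_id = contigs$contig_id,
                                     est_kb = contigs$est_kb,
                                     group = grp,
                                     interval = ifelse(interval == 0,
                                                       "unplaced",
                                                       paste0("interval",
                                                              interval))),
                 table = tab, histogram = hist_counts, scale = scale),
            class = "size_class_report")
}

#' Assembly summary statistics
#'
#' Table-style summary of a physical map: clone and contig counts, estimated
#' total length, chromosome coverage, N50/L50 over reliable contigs (those
#' with more than 5 clones, following the convention that the headline
#' statistics are computed from reliable contigs only), maximum contig size,
#' mean depth and MTP size.
#'
#' @param map A `phys_map` from [assemble_physical_map()].
#' @param chrom_kb Chromosome arm length (kb) for the coverage percentage.
#' @param n_fingerprints_total Optional total fingerprint count before quality
#'   filtering, to report the useful-fingerprint percentage.
#' @return List of class `assembly_stats`.
#' @export
assembly_stats <- function(map, chrom_kb, n_fingerprints_total = NULL) {
  ct <- map$contigs
  rel <- ct[ct$reliability == "reliable", , drop = FALSE]
  nn <- if (nrow(rel)) n50_l50(rel$est_kb) else list(n50 = NA_real_,
                                                     l50 = NA_integer_)
  res <- list(
    useful_fingerprint_pct = if (!is.null(n_fingerprints_total))
      percent_of(map$n_fingerprints, n_fingerprints_total, 1) else NA_real_,
    n_clones_in_contigs = sum(ct$n_clones),
    n_singletons = length(map$singletons),
    n_contigs = nrow(ct),
    n_reliable = nrow(rel),
    total_est_kb = sum(ct$est_kb),
    reliable_est_kb = sum(rel$est_kb),
    coverage_pct = coverage_percent(sum(ct$est_kb), chrom_kb),
    reliable_coverage_pct = coverage_percent(sum(rel$est_kb), chrom_kb),
    n50_kb = nn$n50, l50 = nn$l50,
    max_contig_kb = max(ct$est_kb),
    mean_depth = depth_report(ct, map$assembly_params)$mean_depth,
    mtp_size = sum(lengths(map$mtp)))
  class(res) <- "assembly_stats"
  res
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Physical map assembly statistics\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
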