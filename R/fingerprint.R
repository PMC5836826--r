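#' Locate restriction sites of the five HICF enzymes
#'
#' Scans the given strand for every occurrence of each recognition sequence
#' (the four labeled 6-cutters plus HaeIII). Overlapping occurrences are all
#' reported; `N` never matches. Positions are 0-based offsets of the site
#' start.
#'
#' @param sequence Nucleotide string over A, C, G, T, N.
#' @param params An [hicf_params()].
#' @return Named list (enzyme -> sorted integer positions).
#' @export
digest_sites <- function(sequence, params = hicf_params()) {
  pats <- c(params$labeled_enzymes, params$cutter)
  if (nchar(sequence) == 0)
    return(lapply(pats, function(p) integer(0)))
  subj <- Biostrings::DNAString(sequence)
  lapply(pats, function(p) {
    m <- Biostrings::matchPattern(p, subj, fixed = TRUE)
    Biostrings::start(m) - 1L
  })
}

#' Encode a labeled band on the one-dimensional scale
#'
#' A raw fragment length is retained only within the sizing window (50--500 bp
#' by default); retained lengths are multiplied by 30 and offset by 0, 15,000,
#' 30,000 or 45,000 for BamHI, EcoRI, XbaI and XhoI respectively, so the four
#' enzyme channels occupy disjoint intervals of a single integer scale.
#'
#' @param enzyme Labeled enzyme name.
#' @param raw_len Raw fragment length in bp.
#' @param params An [hicf_params()].
#' @return Encoded integer value, or `NA_integer_` if the length is rejected.
#' @export
encode_band <- function(enzyme, raw_len, params = hicf_params()) {
  if (!enzyme %in% names(params$offsets))
    stop("unknown labeled enzyme: ", enzyme)
  stopifnot(raw_len >= 0)
  if (raw_len < params$min_raw_len || raw_len > params$max_raw_len)
    return(NA_integer_)
  as.integer(raw_len) * params$scale_multiplier + params$offsets[[enzyme]]
}

# shared band builder: from per-enzyme site positions and a sequence length,
# compute the encoded bands of the complete five-enzyme digest.
# Fragment borders are the site start positions (plus the sequence ends, which
# are unlabeled). A fragment yields one band iff at least one border is a
# labeled-enzyme site and the raw length passes the sizing window. When both
# borders are labeled the band is labeled by the lower-priority enzyme in the
# fixed order BamHI < EcoRI < XbaI < XhoI (one band, no double counting).
bands_from_sites <- function(sites, seq_len, params) {
  enz_names <- names(params$labeled_enzymes)
  list_lab <- match(names(sites), enz_names)  # NA for the unlabeled cutter
  pos <- c(unlist(sites, use.names = FALSE), 0L, seq_len)
  lab <- c(rep(list_lab, lengths(sites)), NA_integer_, NA_integer_)
  o <- order(pos, lab, na.last = TRUE)
  pos <- pos[o]; lab <- lab[o]
  # collapse duplicate border positions, keeping the best (lowest) label;
  # after ordering, the first occurrence of a position carries that label
  if (anyDuplicated(pos)) {
    keep <- !duplicated(pos)
    pos <- pos[keep]; lab <- lab[keep]
  }
  n <- length(pos)
  if (n < 2) return(integer(0))
  raw <- pos[-1] - pos[-n]
  ll <- lab[-n]; rl <- lab[-1]
  band_lab <- pmin(ll, rl, na.rm = TRUE)          # lower-priority enzyme wins
  band_lab[is.na(ll) & is.na(rl)] <- NA_integer_  # unlabeled fragments
  ok <- !is.na(band_lab) & raw >= params$min_raw_len & raw <= params$max_raw_len
  vals <- as.integer(raw[ok]) * params$scale_multiplier +
    unname(params$offsets[band_lab[ok]])
  sort(vals)
}

#' In silico HICF fingerprint of one sequence
#'
#' Computes the complete five-enzyme digest (all site positions merged) and
#' encodes every labeled, size-window fragment as a band on the
#' one-dimensional scale. Duplicate encoded values are kept as a multiset,
#' as capillary profiles report repeated peaks. The function is pure: the
#' same sequence always yields the same bands.
#'
#' @param sequence Nucleotide string.
#' @param id Owner identifier (clone or window).
#' @param params An [hicf_params()].
#' @return An object of class `fingerprint`: list with `id`, sorted integer
#'   `bands`, and `band_count`.
#' @export
hicf_fingerprint <- function(sequence, id = "seq", params = hicf_params()) {
  sites <- digest_sites(sequence, params)
  bands <- bands_from_sites(sites, nchar(sequence), params)
  structure(list(id = id, bands = bands, band_count = length(bands)),
            class = "fingerprint")
}

#' Fingerprint a set of sequences
#'
#' Vectorised equivalent of [hicf_fingerprint()] for clone libraries: scans
#' all sequences per enzyme in one pass.
#'
#' @param seqs Named character vector of sequences.
#' @param params An [hicf_params()].
#' @return Named list of sorted integer band vectors.
#' @export
fingerprint_set <- function(seqs, params = hicf_params()) {
  if (!length(seqs)) return(structure(list(), names = character(0)))
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  subj <- Biostrings::DNAStringSet(seqs)
  pats <- c(params$labeled_enzymes, params$cutter)
  hits <- lapply(pats, function(p)
    Biostrings::vmatchPattern(p, subj, fixed = TRUE))
  out <- vector("list", length(seqs))
  names(out) <- names(seqs)
  lens <- nchar(seqs)
  for (i in seq_along(seqs)) {
    sites <- lapply(hits, function(h) Biostrings::start(h[[i]]) - 1L)
    out[[i]] <- bands_from_sites(sites, lens[[i]], params)
  }
  out
}

#' Band-count quality filter
#'
#' Retains fingerprints whose band count lies within the inclusive quality
#' window (18--207 by default); the partition is exhaustive and disjoint.
#'
#' @param fps Named list of band vectors (or list of `fingerprint` objects).
#' @param params An [hicf_params()].
#' @return List with `retained` and `rejected` band lists and a `summary`
#'   data.frame of counts and the retained percentage (one decimal).
#' @export
quality_filter <- function(fps, params = hicf_params()) {
  if (length(fps) && inherits(fps[[1]], "fingerprint")) {
    nm <- vapply(fps, `[[`, "", "id")
    fps <- lapply(fps, `[[`, "bands")
    names(fps) <- nm
  }
  counts <- lengths(fps)
  keep <- counts >= params$quality_min_bands &
    counts <= params$quality_max_bands
  list(retained = fps[keep], rejected = fps[!keep],
       summary = data.frame(
         n_total = length(fps), n_retained = sum(keep),
         pct_retained = percent_of(sum(keep), length(fps), digits = 1)))
}

#' Fingerprint sliding windows of a reference pseudomolecule
#'
#' Splits the reference into BAC-sized windows (100 kb, 50 kb step by
#' default): windows start at multiples of the step while fitting inside the
#' sequence, plus a final window ending exactly at the sequence end when the
#' tail would otherwise be uncovered. Each window is fingerprinted with
#' [hicf_fingerprint()].
#'
#' @param reference Nucleotide string, at least one window long.
#' @param params An [hicf_params()].
#' @return Named list of band vectors with attribute `windows`, a data.frame
#'   `id/start/end` of 0-based half-open window intervals.
#' @export
fingerprint_windows <- function(reference, params = hicf_params()) {
  L <- nchar(reference)
  W <- params$window_size
  if (L < W) stop("reference shorter than one window (", W, " bp)")
  starts <- seq(0L, L - W, by = params$window_step)
  if (max(starts) + W < L) starts <- c(starts, L - W)
  ids <- sprintf("win_%09d_%09d", starts, starts + W)
  seqs <- substring(reference, starts + 1, starts + W)
  names(seqs) <- ids
  fps <- fingerprint_set(seqs, params)
  attr(fps, "windows") <- data.frame(id = ids, start = starts,
                                     end = starts + W)
  fps
}
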