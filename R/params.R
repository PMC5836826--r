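#' HICF fingerprinting parameters
#'
#' Parameters of the in silico HICF SNaPshot digest: the four fluorescently
#' labeled 6-cutters, the unlabeled frequent cutter HaeIII, the sizing window
#' for raw fragment lengths, and the encoding that places every band on a
#' single one-dimensional integer scale (raw length times 30 plus a per-enzyme
#' offset). With the defaults the encoded scale spans 1,500 to 60,000 and the
#' four enzyme channels never overlap.
#'
#' @param min_raw_len,max_raw_len Raw fragment length window (bp) retained as
#'   bands; fragments outside 50--500 bp are invisible to the sizing assay.
#' @param scale_multiplier Multiplier applied to raw lengths before offsetting.
#' @param offsets Named integer vector of per-enzyme offsets, in the fixed
#'   enzyme order BamHI, EcoRI, XbaI, XhoI.
#' @param quality_min_bands,quality_max_bands Band-count window for the
#'   fingerprint quality filter (inclusive).
#' @param window_size,window_step Window length and step (bp) used when
#'   fingerprinting a reference pseudomolecule in BAC-sized pieces.
#' @return An object of class `hicf_params`.
#' @export
hicf_params <- function(min_raw_len = 50L, max_raw_len = 500L,
                        scale_multiplier = 30L,
                        offsets = c(BamHI = 0L, EcoRI = 15000L,
                                    XbaI = 30000L, XhoI = 45000L),
                        quality_min_bands = 18L, quality_max_bands = 207L,
                        window_size = 100000L, window_step = 50000L) {
  stopifnot(min_raw_len > 0, max_raw_len > min_raw_len, scale_multiplier > 0,
            window_step > 0, window_size >= window_step,
            quality_min_bands <= quality_max_bands)
  enz <- c(BamHI = "GGATCC", EcoRI = "GAATTC", XbaI = "TCTAGA", XhoI = "CTCGAG")
  if (!identical(names(offsets), names(enz)))
    stop("offsets must be named BamHI, EcoRI, XbaI, XhoI in that order")
  if (any(diff(offsets) <= 0)) stop("offsets must be strictly increasing")
  structure(list(
    labeled_enzymes = enz,
    cutter = c(HaeIII = "GGCC"),
    offsets = vapply(offsets, as.integer, integer(1)),
    min_raw_len = as.integer(min_raw_len),
    max_raw_len = as.integer(max_raw_len),
    scale_multiplier = as.integer(scale_multiplier),
    quality_min_bands = as.integer(quality_min_bands),
    quality_max_bands = as.integer(quality_max_bands),
    window_size = as.integer(window_size),
    window_step = as.integer(window_step)
  ), class = "hicf_params")
}

#' Overlap scoring and network parameters
#'
#' Tolerance-aware band matching and Sulston-score network thresholds. The
#' per-band chance match probability is p = (2t+1)/G, so exact integer matching
#' (t = 0) stays well defined. All cutoff comparisons are inclusive: a score
#' equal to the cutoff is significant. `gel_space` defaults to 60,000, the
#' size of the encoded one-dimensional band scale.
#'
#' @param tolerance Band match tolerance t, in encoded scale units.
#' @param gel_space Number of distinguishable band values G.
#' @param network_cutoff Sulston score at or below which an overlap enters the
#'   assembly network.
#' @param q_overlap_cutoff,q_clone_cutoff,split_cutoff Staged exclusion cutoffs
#'   for questionable overlaps, questionable clones, and splitting of large
#'   highly overlapping clone groups.
#' @param promiscuity_score,promiscuity_degree A clone with more than
#'   `promiscuity_degree` overlaps scoring strictly below `promiscuity_score`
#'   is excluded as repeat-driven.
#' @param mtp_cutoff Sulston cutoff required between adjacent minimal tiling
#'   path clones (within `mtp_cutoff_range`).
#' @param mtp_cutoff_range,mtp_shared_fraction Documented operating range of
#'   the MTP cutoff and the approximate shared-band fraction it corresponds to.
#' @return An object of class `match_params`.
#' @export
match_params <- function(tolerance = 0L, gel_space = 60000L,
                         network_cutoff = 1e-15,
                         q_overlap_cutoff = 1e-15,
                         q_clone_cutoff = 1e-25,
                         split_cutoff = 1e-30,
                         promiscuity_score = 1e-50,
                         promiscuity_degree = 500L,
                         mtp_cutoff = 1e-15,
                         mtp_cutoff_range = c(1e-15, 1e-33),
                         mtp_shared_fraction = c(0.30, 0.50)) {
  stopifnot(tolerance >= 0, gel_space > 2 * tolerance)
  cuts <- c(network_cutoff, q_overlap_cutoff, q_clone_cutoff, split_cutoff,
            promiscuity_score, mtp_cutoff)
  if (any(cuts <= 0) || any(cuts >= 1)) stop("all cutoffs must lie in (0, 1)")
  structure(list(
    tolerance = as.integer(tolerance), gel_space = as.integer(gel_space),
    network_cutoff = network_cutoff, q_overlap_cutoff = q_overlap_cutoff,
    q_clone_cutoff = q_clone_cutoff, split_cutoff = split_cutoff,
    promiscuity_score = promiscuity_score,
    promiscuity_degree = as.integer(promiscuity_degree),
    mtp_cutoff = mtp_cutoff, mtp_cutoff_range = mtp_cutoff_range,
    mtp_shared_fraction = mtp_shared_fraction
  ), class = "match_params")
}

#' Match parameters calibrated to in silico integer fingerprints
#'
#' The gel space G is the number of distinguishable band values a chance
#' match can fall on. For capillary in vitro fingerprints the encoded
#' one-dimensional scale (60,000 units) is appropriate, but purely in silico
#' fingerprints carry integer raw lengths, so only
#' `(max_raw_len - min_raw_len + 1)` values exist per labeled-enzyme channel
#' (451 x 4 = 1,804 with the defaults). Scoring in silico data against
#' G = 60,000 underestimates chance matching by more than an order of
#' magnitude and floods the network with spurious edges; this constructor
#' sets `gel_space` to the actual alphabet size.
#'
#' @param hparams An [hicf_params()].
#' @param ... Passed to [match_params()].
#' @return A [match_params()] with `gel_space` equal to the in silico band
#'   alphabet size.
#' @export
match_params_insilico <- function(hparams = hicf_params(), ...) {
  g <- (hparams$max_raw_len - hparams$min_raw_len + 1L) *
    length(hparams$labeled_enzymes)
  match_params(gel_space = g, ...)
}

#' Contig assembly parameters
#'
#' Constants used to turn consensus band counts into physical lengths and to
#' classify contig reliability, plus the FPC-style MTP parameter set kept as an
#' alternative selection mode.
#'
#' @param mean_insert_kb Average BAC insert size in kb.
#' @param band_to_kb Average consensus band length in kb; estimated contig
#'   length is consensus bands times this value.
#' @param min_reliable_clones Minimum clone count for a reliable contig;
#'   contigs of 2 to `min_reliable_clones - 1` clones are questionable.
#' @param fpc_mtp List with `min_overlap` (Sulston cutoff), `min_shared`
#'   (shared bands between adjacent MTP clones) and `min_dist_bands` (minimum
#'   new bands contributed by the next MTP clone) for FPC-mode MTP selection.
#' @return An object of class `assembly_params`.
#' @export
assembly_params <- function(mean_insert_kb = 122, band_to_kb = 1.2,
                            min_reliable_clones = 6L,
                            fpc_mtp = list(min_overlap = 1e-30,
                                           min_dist_bands = 30L,
                                           min_shared = 12L)) {
  stopifnot(mean_insert_kb > 0, band_to_kb > 0, min_reliable_clones >= 2,
            fpc_mtp$min_overlap > 0, fpc_mtp$min_dist_bands > 0,
            fpc_mtp$min_shared > 0)
  structure(list(mean_insert_kb = mean_insert_kb, band_to_kb = band_to_kb,
                 min_reliable_clones = as.integer(min_reliable_clones),
                 fpc_mtp = fpc_mtp),
            class = "assembly_params")
}

#' Simulation configuration
#'
#' Study conditions for the synthetic chromosome arm and BAC library: a
#' GC-matched random sequence with tandem-repeat heterochromatin blocks, SSR
#' and ISBP marker loci, a HindIII partial-digest size-selected clone library
#' at a given fold coverage, flow-sorting contamination from a non-homologous
#' decoy chromosome, a fingerprint quality dropout fraction, and the
#' substitution rate of the diverged reference pseudomolecule.
#'
#' @param chromosome_length Arm length in bp.
#' @param gc_fraction GC content of the random backbone.
#' @param repeat_blocks List of `list(start_fraction, end_fraction, unit)`
#'   tandem arrays written as exact copies of `unit`.
#' @param marker_density Named numeric, markers per Mb by type.
#' @param library_coverage Fold coverage of the clone library.
#' @param insert_min,insert_max,insert_mean Size-selection window and mean
#'   insert size in bp.
#' @param contamination_fraction Fraction of clones drawn from the decoy.
#' @param quality_dropout Fraction of clones given corrupted fingerprints
#'   (band count pushed outside the quality window).
#' @param divergence_rate Per-bp substitution rate of the homologous reference.
#' @param seed Integer seed; all simulation randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(chromosome_length = 10000000L, gc_fraction = 0.46,
                       repeat_blocks = list(),
                       marker_density = c(SSR = 2, ISBP = 5),
                       library_coverage = 10,
                       insert_min = 100000L, insert_max = 200000L,
                       insert_mean = 122000L,
                       contamination_fraction = 0.10,
                       quality_dropout = 0.15,
                       divergence_rate = 0.01,
                       seed = 1L) {
  stopifnot(chromosome_length > 0, gc_fraction > 0, gc_fraction < 1,
            library_coverage > 0,
            insert_min <= insert_mean, insert_mean <= insert_max,
            contamination_fraction >= 0, contamination_fraction < 1,
            quality_dropout >= 0, quality_dropout < 1,
            divergence_rate >= 0, divergence_rate < 1)
  if (length(repeat_blocks)) {
    iv <- t(vapply(repeat_blocks, function(b)
      c(b$start_fraction, b$end_fraction), numeric(2)))
    if (any(iv < 0) || any(iv > 1) || any(iv[, 1] >= iv[, 2]))
      stop("repeat block fractions must be increasing intervals within [0, 1]")
    o <- order(iv[, 1])
    if (nrow(iv) > 1 && any(iv[o, 1][-1] < iv[o, 2][-nrow(iv)]))
      stop("repeat blocks must not overlap")
  }
  structure(list(chromosome_length = as.integer(chromosome_length),
                 gc_fraction = gc_fraction, repeat_blocks = repeat_blocks,
                 marker_density = marker_density,
                 library_coverage = library_coverage,
                 insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max),
                 insert_mean = as.integer(insert_mean),
                 contamination_fraction = contamination_fraction,
                 quality_dropout = quality_dropout,
                 divergence_rate = divergence_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}
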