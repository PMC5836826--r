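#' Generate a synthetic chromosome arm
#'
#' Builds a random nucleotide sequence at the configured GC content, overwrites
#' the configured tandem-repeat blocks with exact copies of their unit
#' sequence, and places SSR/ISBP marker loci uniformly outside repeat blocks.
#' The number of loci per type is `round(density * length_in_Mb)`. All
#' coordinates are 0-based, half-open.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_chromosome`: list with `sequence`
#'   (character scalar), `repeat_annotations` (data.frame start/end/class),
#'   `marker_loci` (data.frame id/type/pos) and `length`.
#' @export
generate_chromosome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$chromosome_length
  gc <- config$gc_fraction
  bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  rep_ann <- data.frame(start = integer(0), end = integer(0),
                        class = character(0))
  for (b in config$repeat_blocks) {
    s <- as.integer(floor(b$start_fraction * n))
    e <- as.integer(floor(b$end_fraction * n))
    unit <- strsplit(b$unit, "")[[1]]
    bases[(s + 1):e] <- rep_len(unit, e - s)
    rep_ann <- rbind(rep_ann,
                     data.frame(start = s, end = e, class = "tandem"))
  }
  in_repeat <- rep(FALSE, n)
  if (nrow(rep_ann))
    for (k in seq_len(nrow(rep_ann)))
      in_repeat[(rep_ann$start[k] + 1):rep_ann$end[k]] <- TRUE
  free_pos <- which(!in_repeat) - 1L  # 0-based positions outside repeats
  loci <- data.frame(id = character(0), type = character(0), pos = integer(0))
  for (ty in names(config$marker_density)) {
    k <- round(config$marker_density[[ty]] * n / 1e6)
    if (k > 0) {
      pos <- sort(sample(free_pos, k))
      loci <- rbind(loci, data.frame(
        id = sprintf("%s_%03d", ty, seq_len(k)), type = ty, pos = pos))
    }
  }
  rownames(loci) <- NULL
  structure(list(sequence = paste(bases, collapse = ""),
                 repeat_annotations = rep_ann,
                 marker_loci = loci, length = n),
            class = "synthetic_chromosome")
}

#' Mutate a chromosome into a diverged homologous reference
#'
#' Substitutes each base independently with probability `rate` to one of the
#' three other bases, emulating a homologous reference pseudomolecule from a
#' related genome (about one substitution per 100 bp at the default rate).
#' Annotations and marker loci are preserved.
#'
#' @param chrom A `synthetic_chromosome`.
#' @param rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed for the substitution draw.
#' @return A `synthetic_chromosome` with the mutated sequence.
#' @export
mutate_reference <- function(chrom, rate, seed = 1L) {
  stopifnot(inherits(chrom, "synthetic_chromosome"), rate >= 0, rate < 1)
  if (rate == 0) return(chrom)
  set.seed(seed)
  bases <- strsplit(chrom$sequence, "")[[1]]
  hit <- which(runif(length(bases)) < rate)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    pick <- ceiling(runif(length(hit)) * 3)
    bases[hit] <- vapply(seq_along(hit),
                         function(k) alt[[bases[hit[k]]]][pick[k]], "")
  }
  out <- chrom
  out$sequence <- paste(bases, collapse = "")
  out
}

#' Construct a tandem-repeat unit sequence
#'
#' Builds a repeat unit free of all five fingerprint-enzyme recognition sites
#' (BamHI, EcoRI, XbaI, XhoI, HaeIII) — also across the junction when the
#' unit is tandemly repeated — so that clones inside the repeat block carry
#' almost no bands and fail the fingerprint quality floor, emulating
#' heterochromatic tandem-repeat arrays. With `with_hindiii` the unit
#' contains one AAGCTT site, keeping the block cloneable (clones are sampled
#' there but rejected by the quality filter); without it the block is
#' unmappable, like a simple GAA expansion.
#'
#' @param length Unit length in bp.
#' @param with_hindiii Include one HindIII site in the unit.
#' @param seed Integer seed.
#' @param params An [hicf_params()] (forbidden motifs).
#' @return Character scalar unit sequence.
#' @export
repeat_unit <- function(length = 360L, with_hindiii = TRUE, seed = 1L,
                        params = hicf_params()) {
  stopifnot(length >= 20)
  set.seed(seed)
  forbidden <- unname(c(params$labeled_enzymes, params$cutter))
  repeat {
    # AT-rich backbone, as in heterochromatic satellite arrays
    unit <- paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
                         prob = c(0.4, 0.4, 0.1, 0.1)), collapse = "")
    if (with_hindiii)
      substr(unit, 8, 13) <- "AAGCTT"
    doubled <- paste0(unit, unit)
    if (any(vapply(forbidden, function(m) grepl(m, doubled, fixed = TRUE),
                   logical(1)))) next
    n_h <- sum(gregexpr("AAGCTT", doubled, fixed = TRUE)[[1]] > 0)
    if (n_h == (if (with_hindiii) 2L else 0L)) break
  }
  unit
}

hindiii_sites <- function(sequence) {
  m <- Biostrings::matchPattern("AAGCTT", Biostrings::DNAString(sequence))
  Biostrings::start(m) - 1L  # 0-based
}

# plate layout constants: 384-well plates, 16 rows x 24 columns
.PLATE_ROWS <- LETTERS[1:16]
.PLATE_COLS <- 1:24

#' Simulate a BAC library by HindIII partial digest with size selection
#'
#' Clone inserts start and end at HindIII (AAGCTT) recognition sites: a start
#' site is drawn uniformly among sites that admit a partner site within the
#' size-selection window, and the partner closest to the mean insert size is
#' taken, reproducing size selection without modelling digestion kinetics. A
#' `contamination_fraction` share of clones is drawn from the non-homologous
#' decoy chromosome (flow-sorting impurity). Clones are assigned to 384-well
#' plates (16 rows x 24 columns) in library order.
#'
#' @param chrom Target `synthetic_chromosome`.
#' @param decoy Decoy `synthetic_chromosome` (non-homologous contaminant).
#' @param config A [sim_config()]; clone count is
#'   `round(chromosome_length * library_coverage / insert_mean)`.
#' @param seed Integer seed; defaults to `config$seed + 1`.
#' @return An object of class `clone_set`: data.frame with columns
#'   `clone_id, source, start, end, plate, row, col` (coordinates 0-based
#'   half-open on the source sequence, site-to-site-end inclusive of both
#'   AAGCTT sites).
#' @export
simulate_bac_library <- function(chrom, decoy, config,
                                 seed = config$seed + 1L) {
  stopifnot(inherits(chrom, "synthetic_chromosome"),
            inherits(decoy, "synthetic_chromosome"),
            inherits(config, "sim_config"))
  set.seed(seed)
  n_clones <- round(config$chromosome_length * config$library_coverage /
                      config$insert_mean)
  n_decoy <- round(n_clones * config$contamination_fraction)
  n_target <- n_clones - n_decoy

  draw <- function(sites, n, label) {
    if (length(sites) < 2 && n > 0)
      stop("sequence has too few HindIII sites to build clones")
    # allowed starts: sites with a partner giving an insert in the window
    # (insert spans site start to partner site end, hence the +6)
    lo <- config$insert_min - 6L
    hi <- config$insert_max - 6L
    # for each start site, the in-window partner closest to the mean insert:
    # with sorted sites it is one of the two sites bracketing the target
    target <- sites + config$insert_mean - 6L
    j <- findInterval(target, sites)
    pick <- function(idx) {
      v <- rep(NA_integer_, length(sites))
      okx <- idx >= 1 & idx <= length(sites)
      v[okx] <- sites[idx[okx]]
      v[!is.na(v) & (v < sites + lo | v > sites + hi)] <- NA_integer_
      v
    }
    below <- pick(j); above <- pick(j + 1L)
    d_b <- abs(below - target); d_a <- abs(above - target)
    ends_all <- ifelse(!is.na(below) & (is.na(above) | d_b <= d_a),
                       below, above)
    ok <- !is.na(ends_all)
    if (!any(ok)) {
      warning("no HindIII site pair within the size-selection window (",
              label, "): region unmappable")
      return(data.frame(start = integer(0), end = integer(0)))
    }
    idx <- sample(which(ok), n, replace = TRUE)
    data.frame(start = sites[idx], end = ends_all[idx] + 6L)
  }

  tgt <- draw(hindiii_sites(chrom$sequence), n_target, "target")
  dcy <- draw(hindiii_sites(decoy$sequence), n_decoy, "decoy")
  clones <- rbind(
    if (nrow(tgt)) cbind(source = "target", tgt) else NULL,
    if (nrow(dcy)) cbind(source = "decoy", dcy) else NULL)
  # shuffle before plating so plates mix genomic positions and sources
  clones <- clones[sample(nrow(clones)), , drop = FALSE]
  k <- nrow(clones)
  well <- seq_len(k) - 1L
  clones$clone_id <- sprintf("bac_%05d", seq_len(k))
  clones$plate <- well %/% 384L + 1L
  clones$row <- .PLATE_ROWS[(well %% 384L) %/% 24L + 1L]
  clones$col <- (well %% 24L) + 1L
  rownames(clones) <- NULL
  structure(clones[, c("clone_id", "source", "start", "end",
                       "plate", "row", "col")],
            class = c("clone_set", "data.frame"))
}

#' Extract clone insert sequences
#'
#' @param chrom,decoy The source `synthetic_chromosome` objects.
#' @param clones A `clone_set`.
#' @return Named character vector of insert sequences.
#' @export
clone_sequences <- function(chrom, decoy, clones) {
  stopifnot(inherits(clones, "clone_set"))
  out <- character(nrow(clones))
  tgt <- clones$source == "target"
  if (any(tgt))
    out[tgt] <- substring(chrom$sequence, clones$start[tgt] + 1,
                          clones$end[tgt])
  if (any(!tgt))
    out[!tgt] <- substring(decoy$sequence, clones$start[!tgt] + 1,
                           clones$end[!tgt])
  names(out) <- clones$clone_id
  out
}

#' Corrupt a fraction of fingerprints to emulate quality dropout
#'
#' The quality filter acts on band counts only, so corrupted clones are
#' modelled by randomly deleting or duplicating bands until the count leaves
#' the quality window.
#'
#' @param fps Named list of sorted integer band vectors.
#' @param fraction Fraction of fingerprints to corrupt.
#' @param params An [hicf_params()] providing the quality window.
#' @param seed Integer seed.
#' @return The band list with the selected fingerprints corrupted.
#' @export
corrupt_fingerprints <- function(fps, fraction, params = hicf_params(),
                                 seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0 || !length(fps)) return(fps)
  set.seed(seed)
  k <- round(length(fps) * fraction)
  if (k == 0) return(fps)
  victims <- sample(seq_along(fps), k)
  for (i in victims) {
    b <- fps[[i]]
    if (!length(b)) next  # already below the quality floor
    if (runif(1) < 0.5 || length(b) < 2) {
      # duplicate random bands until above the quality ceiling
      while (length(b) <= params$quality_max_bands)
        b <- c(b, sample(b, min(length(b), 40), replace = TRUE))
    } else {
      # delete bands down to below the quality floor
      b <- sample(b, min(length(b), params$quality_min_bands - 1L))
    }
    fps[[i]] <- sort(as.integer(b))
  }
  fps
}
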