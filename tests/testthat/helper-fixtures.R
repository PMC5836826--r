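# Shared simulation fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# clean mid-scale library: 2 Mb, 10x, no contamination or dropout
clean_sim <- function() fixture("clean_sim", function() {
  cfg <- sim_config(chromosome_length = 2e6, library_coverage = 10,
                    contamination_fraction = 0, quality_dropout = 0,
                    marker_density = c(SSR = 3, ISBP = 6), seed = 7)
  chrom <- generate_chromosome(cfg)
  decoy <- generate_chromosome(sim_config(chromosome_length = 2e6,
                                          seed = 99))
  clones <- simulate_bac_library(chrom, decoy, cfg)
  fps <- fingerprint_set(clone_sequences(chrom, decoy, clones))
  qf <- quality_filter(fps)
  mp <- match_params_insilico()
  map <- assemble_physical_map(qf$retained, mp)
  list(cfg = cfg, chrom = chrom, decoy = decoy, clones = clones,
       fps = fps, qf = qf, mp = mp, map = map)
})

# clean acceptance-scale library: 5 Mb, 10x
clean_sim5 <- function() fixture("clean_sim5", function() {
  cfg <- sim_config(chromosome_length = 5e6, library_coverage = 10,
                    contamination_fraction = 0, quality_dropout = 0,
                    seed = 11)
  chrom <- generate_chromosome(cfg)
  decoy <- generate_chromosome(sim_config(chromosome_length = 5e6,
                                          seed = 99))
  clones <- simulate_bac_library(chrom, decoy, cfg)
  fps <- fingerprint_set(clone_sequences(chrom, decoy, clones))
  qf <- quality_filter(fps)
  mp <- match_params_insilico()
  map <- assemble_physical_map(qf$retained, mp)
  list(cfg = cfg, chrom = chrom, decoy = decoy, clones = clones,
       fps = fps, qf = qf, mp = mp, map = map)
})

clone_midpoints <- function(clones) {
  mid <- (clones$start + clones$end) / 2
  names(mid) <- clones$clone_id
  mid
}

# truth-coordinate coverage (bp) of a set of clone ids
clone_union_bp <- function(ids, clones) {
  i <- match(ids, clones$clone_id)
  interval_union(clones$start[i], clones$end[i])
}
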