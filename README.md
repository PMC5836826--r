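# physmapr

Desk-scale construction and evaluation of BAC physical maps from
high-information-content (HICF SNaPshot) restriction fingerprints.

Physical maps order bacterial artificial chromosome (BAC) clones along a
chromosome by the statistical similarity of their restriction fingerprints,
and were the backbone of clone-by-clone sequencing of large cereal genomes:
a flow-sorted chromosome arm is cloned into a ~100–200 kb insert library,
each clone is digested with five enzymes and its fragment "bands" sized, and
clones whose band sets overlap far beyond chance are assembled into ordered
contigs from which a minimal tiling path (MTP) is picked for sequencing.
physmapr re-implements that computation for anyone who wants to study,
teach, or stress-test the method: it simulates the whole experiment on
synthetic chromosomes with known ground truth, so every stage is verifiable.

The statistical core is the Sulston overlap score. Two clones with
`nl <= nh` bands on a scale of `G` distinguishable values, matched with
tolerance `t`, share at least `s` bands by chance with probability

    p = (2t + 1) / G,  q = 1 - (1 - p)^nh,  score = P(X >= s),  X ~ Bin(nl, q)

Overlaps at or below 1e-15 form a network; questionable overlaps and clones
are excluded in logged stages (cutoffs 1e-15 / 1e-25 / 1e-30, plus clones
with more than 500 overlaps below 1e-50); components passing a
linear-topology test become contigs whose length is consensus bands × 1.2 kb;
MTPs are chosen greedily under overlap constraints; and contigs are anchored
by pooled PCR marker screening, deletion bins, and Sulston-score comparison
with in silico fingerprints of 100-kb windows of a diverged reference
pseudomolecule.

## Worked example

Simulate a 2-Mb chromosome arm at 10× clone coverage with 5% flow-sort
contamination and 10% fingerprint dropout, then assemble:

```r
library(physmapr)
cfg <- sim_config(chromosome_length = 2e6, library_coverage = 10,
                  contamination_fraction = 0.05, quality_dropout = 0.1,
                  seed = 42)
chrom  <- generate_chromosome(cfg)
decoy  <- generate_chromosome(sim_config(chromosome_length = 2e6, seed = 142))
clones <- simulate_bac_library(chrom, decoy, cfg)
fps    <- fingerprint_set(clone_sequences(chrom, decoy, clones))
fps    <- corrupt_fingerprints(fps, cfg$quality_dropout, seed = 43)
qf     <- quality_filter(fps)
qf$summary
#>   n_total n_retained pct_retained
#> 1     164        148         90.2

map <- assemble_physical_map(qf$retained, match_params_insilico())
map
#> Physical map: 148 fingerprints -> 3 contigs ( 1 reliable ), 4 singletons
#>   total estimated length: 3179 kb; MTP size: 31 clones

summary(map, chrom_kb = 2000, n_fingerprints_total = length(fps))
#> Physical map assembly statistics
#>   useful_fingerprint_pct   90.2
#>   n_clones_in_contigs      144
#>   n_contigs                3
#>   n_reliable               1
#>   coverage_pct             159
#>   n50_kb                   2706
#>   l50                      1
#>   mean_depth               5.5
#>   mtp_size                 31
```

Reading the numbers: 148 of 164 fingerprints survive the 18–207 band quality
filter (the corrupted 10% fail it); the contaminating decoy clones share no
bands with anything and end up among the singletons; one reliable contig of
~2.7 Mb estimated length covers the arm. The estimated length exceeds the
true 2 Mb because clone-end fragments contribute private bands to the
consensus — the same inflation the estimated-coverage statistics of real
HICF maps show — and assembly depth correspondingly reads ~5.5× for this
effective ~9× retained library. `match_params_insilico()` scores with the
gel space of integer in silico bands (1,804 distinguishable values); see the
methods vignette (`vignettes/physical-mapping.Rmd`) for why that matters.

`run_pipeline()` wraps the full chain (simulation → fingerprints → network →
contigs → MTP → three-stage anchoring → statistics) and writes FASTA/BED/TSV
artifacts, a bands file, JSON statistics and a manifest into an output
directory. A thin command-line front end with subcommands
(`simulate`, `fingerprint`, `overlap`, `assemble`, `mtp`, `stats`,
`coverage`, `run`) is installed at `inst/scripts/physmap.R`.

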