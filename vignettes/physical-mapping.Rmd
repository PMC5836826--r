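---
title: "BAC physical mapping from HICF fingerprints: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BAC physical mapping from HICF fingerprints: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physmapr)
```

physmapr re-implements, at desk scale, the computation behind a BAC-based
physical map of a flow-sorted wheat chromosome arm: in silico
high-information-content (HICF SNaPshot) fingerprinting, Sulston-score
overlap networks, linear-topology contig assembly with staged exclusion of
questionable clones, minimal tiling path (MTP) selection, three-way contig
anchoring, and assembly statistics. Every stage can be exercised end-to-end
on synthetic chromosomes where the ground truth is known, so the pipeline is
testable without any external data.

## The fingerprint model

A clone's fingerprint is the multiset of its restriction "bands". The in
silico digest uses five enzymes: four labeled 6-cutters (BamHI `GGATCC`,
EcoRI `GAATTC`, XbaI `TCTAGA`, XhoI `CTCGAG`) and the unlabeled 4-cutter
HaeIII (`GGCC`). Fragment borders are the merged site start positions of all
five enzymes plus the sequence ends. A fragment becomes a band iff at least
one border is a labeled-enzyme site and its raw length lies in the sizing
window 50–500 bp. Bands are encoded on a one-dimensional integer scale:

```
value = raw_length * 30 + offset,  offset = 0 / 15,000 / 30,000 / 45,000
                                   for BamHI / EcoRI / XbaI / XhoI
```

so the four channels occupy the disjoint intervals 1,500–15,000,
16,500–30,000, 31,500–45,000 and 46,500–60,000 (verified exhaustively in the
tests). Three decisions close gaps the sizing rules leave open:

* A fragment with **both** ends at labeled sites emits **one** band, labeled
  by the first enzyme in the fixed order BamHI < EcoRI < XbaI < XhoI. The
  alternative (two bands) would double-count fragments; the choice is a
  convention, not a physical claim.
* HaeIII–HaeIII fragments emit no band: SNaPshot labels only the four
  6-cutter ends.
* Duplicate encoded values are kept as a multiset, as capillary profiles
  report repeated peaks.

Only fingerprints with 18–207 bands (inclusive) are used, the quality window
applied to the real library. Random 100-kb sequence at GC 0.46 yields about
105–140 bands, comfortably inside the window, so the simulation operates in
the same quality regime.

## The Sulston score and the gel space G

Two clones with `nl <= nh` bands sharing `s` bands are scored by the upper
binomial tail

```
p = (2t + 1) / G,   q = 1 - (1 - p)^nh,   score = P(X >= s),  X ~ Bin(nl, q)
```

with `t` the match tolerance and `G` the number of distinguishable band
values. `p = (2t+1)/G` rather than `2t/G` keeps exact integer matching
(`t = 0`) well defined. All cutoff comparisons are inclusive (`score <=
cutoff` is significant), and tails far below the double floor are carried on
the log10 scale so that extremely strong overlaps remain comparable.

`G` deserves care. For capillary in vitro data the encoded scale
(60,000 units) is the natural choice and is the `match_params()` default.
Purely in silico fingerprints, however, take integer raw lengths, so only
451 values exist per labeled channel — 1,804 distinguishable values in
total. Two unrelated 140-band clones then share about 11 bands by chance,
while the G = 60,000 model predicts 0.3; scoring in silico data against
60,000 turns roughly a third of unrelated clone pairs into "significant"
overlaps and no meaningful map survives. `match_params_insilico()` therefore
sets `G` to the actual alphabet size, and every simulation-driven path in
the package uses it. This is a calibration of the null model to the data
type, not a tuning knob: the exact gel length used on the real data set is
unreported, and results are parameterized on `G`.

The binomial tail treats the `nl` bands as independent. A Monte-Carlo
band-placement experiment (bands placed uniformly on `G` slots, greedy
matching) agrees with the formula within Monte-Carlo error at `s = 1`; at
deeper `s` the true tail is measurably lighter because matching uses each
band at most once, so the analytic score slightly overstates chance
agreement — a conservative bias for significance testing. The agreement
check at `s = 1` for (nl, nh, G) = (5, 5, 100) and (10, 20, 1000) runs in
the acceptance suite.

Greedy leftmost matching of two sorted band lists equals the maximum
bipartite matching under a symmetric tolerance; the test suite verifies
greedy == exhaustive on random cases.

## Network cleaning and linear-topology contigs

Significant overlaps (score at or below 1e-15) form the assembly network.
Cleaning proceeds in four logged stages before contigs are read off:

1. **Q-overlaps**: edges weaker than the Q-overlap cutoff (1e-15) are
   dropped — demoted, not forgotten (see below).
2. **Q-clones** (cutoff 1e-25): within each non-linear component, clones
   whose removal resolves the topology conflicts are excluded greedily;
   only clones tied into the network at Q-clone strength are judged here.
3. **Splitting** (cutoff 1e-30): components still non-linear lose their
   weaker edges, splitting large groups of highly overlapping clones, and
   residual conflict clones are removed at that stricter level.
4. **Promiscuous clones**: more than 500 overlaps below 1e-50 is the
   signature of repeat-derived fingerprints; such clones are excluded.

The linearity test is the interval-graph ordering property: clone inserts
are intervals, and in an ordering by position an overlap between clones
`i < j` forces every clone between them to overlap the **order-left**
endpoint `i` (a short intermediate clone need not reach `j`). Because a
contig's orientation is unknown, the anchor direction is chosen globally as
whichever of the two gives fewer conflicts; consecutive order positions must
additionally be joined by an edge. A naive rule demanding intermediates
overlap *both* endpoints is false for variable-length inserts and
over-excludes clones — discovering that was the main correction during
development, and the exhaustive-ordering oracle in the tests guards it.

Near-significant overlaps (within five decades above the cutoff) are kept
separately as *compatibility* edges. They never create contigs, but they
count as "these clones may overlap" when the linearity test looks for
contradictions. Without this, real overlaps sitting just above the cutoff
masquerade as conflicts and trigger spurious Q-clone exclusions; five
decades spans the score jitter of borderline true overlaps at the
simulation's band counts and adds no false conflicts in the clean-library
tests.

Clone order within a contig comes from greedy end-extension (seeded at the
strongest edge, extending whichever end has the most significant unplaced
neighbour, then inserting leftovers next to their strongest neighbour),
refined by weighted barycenter sweeps; if conflicts remain, spectral
seriation by the Fiedler vector of the weighted Laplacian is tried and the
order with fewer violations wins. On clean 10x simulations the recovered
order correlates with the true clone midpoints at |Spearman| > 0.999.
Components that still fail linearity after all staged exclusions have
residual conflict clones removed by the same greedy machinery (logged as
stage `topology`) rather than being split at articulation vertices — on a
linear path every internal vertex is an articulation point, so literal
articulation splitting would shatter valid contigs.

Contig lengths are estimated as consensus bands × 1.2 kb. Consensus bands
are counted by matching bands of adjacent clones in contig order and
chaining the matches; because each band matches at most one band in the next
clone, the chains form a forest and the count is simply total bands minus
total adjacent matches. Contigs with at least 6 clones are *reliable*,
2–5 clones *questionable*. Depth is clones × 122 kb / estimated length.
Note the estimate runs 1.3–1.5× above the true span on simulations: clone-end
fragments create per-clone private bands, and adjacent-only matching cannot
merge them — the same mechanism that pushes the real LTC map's estimated
coverage above 100%. Assembly depth correspondingly reads below the nominal
library coverage (about 7× for a 10× clean library), which is the regime the
depth checks in the tests assert.

## MTP selection

LTC mode walks each contig left to right: from the current MTP clone, the
farthest clone in contig order whose pairwise score is at or below the MTP
cutoff (default 1e-15, within the documented 1e-15–1e-33 operating range
that corresponds to roughly 30–50% shared bands) becomes the next MTP
clone; the first and last clones are always included. FPC mode instead
requires score ≤ 1e-30, at least 12 shared bands, and at least 30 bands of
new material in the chosen clone. When nothing satisfies the constraints the
immediate neighbour is taken and a warning recorded. On simulations the MTP
spans ≥ 95% of its contig's clone union with roughly a 6-fold clone
reduction.

## Scaffolds and marker validation

Contigs merge end-to-end into scaffolds through evidence that is by
construction weaker than contig-internal proof: a single linking clone with
(near-)significant overlaps to a terminal clone of each contig, a single
terminal–terminal overlap, or the same marker hitting terminal clones of two
contigs (rule a). An end with more than one merge partner, or a marker
hitting terminals of three or more contigs, is a conflict: no merge, logged.
Marker validation then applies: (b) a marker in an internal overlapping
group plus one isolated distant clone flags that clone as presumably
chimeric; (c) a marker in two or more internal groups is non-unique; (d) two
markers of one scaffold separated by more than 10 cM on the genetic map flag
the scaffold for splitting at its weakest junction (evidence ranked marker >
single-clone > single-overlap). The 10 cM default quantifies "considerable
distance" on a map where typical marker spacing is a few cM; it is a
parameter.

## Anchoring

Three staged evidence types place contigs on the chromosome, each contig
counted at the earliest stage that anchors it:

1. **Pooled marker screening.** The library sits in 384-well plates (16
   rows × 24 columns); plate pools plus per-plate row and column pools are
   screened in silico (a clone is positive iff its interval contains the
   marker locus). Deconvolution intersects plate × row × column; a plate
   with ≥ 2 positive rows and ≥ 2 positive columns is ambiguous and returns
   candidates instead of hits, so confirmed hits are always sound.
2. **External marker positions** (deletion-bin or synteny-derived evidence,
   supplied as a table). Deletion bins are fraction intervals of the arm;
   assignment returns every containing bin — the printed 5BS bin table has
   two bins overlapping on 0.67–0.71, and both are reported in that zone
   rather than silently resolving a possible typo in the source table.
3. **In silico fingerprinting of a reference pseudomolecule**, split into
   100-kb windows at 50-kb steps (plus a flush final window). Each MTP clone
   anchors to its best-scoring window at or below the network cutoff, ties
   broken by leftmost window start. A contig's position is the median window
   midpoint of its anchored clones (no summary rule is standard; the median
   resists single mis-anchored clones), its orientation the sign
   of the order-versus-position correlation, and contigs with ≥ 3 anchored,
   mutually consistent clones (span < 2× estimated length) are *key
   contigs*.

With an undiverged reference, ≥ 95% of MTP clones anchor within 100 kb of
their true midpoint. At one substitution per 100 bp — the divergence of the
homologous reference this emulates — band survival is still high (a band
needs both 6-bp border sites intact, about 0.99^12 ≈ 89% per band), so the
anchored fraction stays near 1 across the divergence grid 0–0.02; the tests
assert positivity and monotone non-increase rather than a strict decline,
which a plateau at full anchoring would falsify.

## The synthetic-data generator

`sim_config()` encodes the study conditions: a 10-Mb arm (desk-scale
stand-in for the 290-Mb arm) of GC 0.46 random sequence; tandem-repeat
heterochromatin blocks written as exact unit copies; SSR and ISBP marker
loci placed uniformly outside repeats (2 and 5 per Mb — enough markers for
pooled screening at desk scale, with ISBP the more numerous class as in the
real marker sets); a HindIII partial-digest library at 10× coverage with
inserts of 100–200 kb drawn to the site pair nearest 122 kb (reproducing
size selection without digestion kinetics); 10% contamination from an
independent random decoy chromosome of equal GC (flow-sorting contaminants
are non-homologous); 15% fingerprint-quality dropout, modelled by pushing
band counts outside the 18–207 window since that is all the filter sees; and
a diverged reference at 0.01 substitutions per bp. Clone starts are drawn
uniformly over *allowed sites*, so a repeat unit for block experiments
should carry HindIII at roughly background density (one site per ~3.6 kb;
`repeat_unit(length = 3600)`) — a site-dense unit would oversample the block
relative to its DNA mass. `repeat_unit()` builds units free of all five
fingerprint-enzyme sites, including across tandem junctions, so block-internal
clones carry almost no bands and fail the quality floor, which is how
heterochromatin depresses fingerprint yield in the real library.

What the generator does **not** emulate: realistic transposable-element
landscapes, sizing noise and dye artifacts of capillary electrophoresis
(band values are exact integers), chimeric ligation products, cloning bias
beyond HindIII site availability, and biological divergence structure
(substitutions are iid). Passing the recovery tests therefore shows the
algorithms are correct under the stated statistical model, not that the
pipeline is robust to every artifact of real capillary data — tolerance
`t > 0` exists for that but is untested against real noise here.

## Problem sizes and determinism

The shipped checks use a 2-Mb/10× library (~164 clones) for unit-level
recovery, 5 Mb/10× (~410 clones) for coverage, ordering, MTP-span and
anchoring properties, and a 10-Mb/10× contaminated run with one subtelomeric
repeat block for the end-to-end pattern of short contigs in the repeat
region; together they run in about a minute. All randomness flows from
integer seeds in the configuration objects; reruns are byte-identical, which
the pipeline tests assert on the output files themselves.

## Known limitations

* The linearity search is heuristic (greedy + barycenter + spectral); it is
  verified against exhaustive ordering only for small components, and a
  pathological component could in principle be misclassified as non-linear
  and lose a clone to stage-`topology` exclusion.
* Consensus band counting matches adjacent clones only, so estimated
  lengths inflate by the per-clone boundary-band count; cross-clone chain
  merging (a CB-map-style consensus) is out of scope.
* FPC's stepwise merge/DQer protocol is not reproduced; FPC appears only as
  an MTP parameter set and as printed comparison numbers.
* Scores below ~1e-320 underflow to zero on the probability scale; ranking
  uses the log10 scale throughout, so this is cosmetic in the edge tables.
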