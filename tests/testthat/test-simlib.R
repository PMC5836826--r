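test_that("chromosome generation writes repeat blocks, places markers outside them, and is deterministic", {
  cfg <- sim_config(chromosome_length = 1e6, gc_fraction = 0.46,
                    repeat_blocks = list(list(start_fraction = 0.81,
                                              end_fraction = 1.00,
                                              unit = "GAA")),
                    marker_density = c(SSR = 5, ISBP = 10), seed = 3)
  ch <- generate_chromosome(cfg)
  expect_equal(nchar(ch$sequence), 1e6)
  expect_equal(ch$repeat_annotations,
               data.frame(start = 810000L, end = 1000000L, class = "tandem"))
  # block is exact tandem copies of the unit
  block <- substring(ch$sequence, 810001, 810001 + 29)
  expect_equal(block, paste(rep("GAA", 10), collapse = ""))
  # marker counts follow round(density * Mb); all loci outside the block
  expect_equal(sum(ch$marker_loci$type == "SSR"), 5)
  expect_equal(sum(ch$marker_loci$type == "ISBP"), 10)
  expect_true(all(ch$marker_loci$pos < 810000))
  expect_true(all(ch$marker_loci$pos >= 0 & ch$marker_loci$pos < 1e6))
  # determinism
  ch2 <- generate_chromosome(cfg)
  expect_identical(ch$sequence, ch2$sequence)
  expect_identical(ch$marker_loci, ch2$marker_loci)
  # overlapping repeat blocks are rejected
  expect_error(sim_config(repeat_blocks = list(
    list(start_fraction = 0.1, end_fraction = 0.5, unit = "GAA"),
    list(start_fraction = 0.4, end_fraction = 0.6, unit = "TTC"))),
    "overlap")
})

test_that("reference mutation follows the per-base substitution model", {
  cfg <- sim_config(chromosome_length = 10000, marker_density = c(SSR = 0),
                    seed = 5)
  ch <- generate_chromosome(cfg)
  expect_identical(mutate_reference(ch, 0)$sequence, ch$sequence)
  mut <- mutate_reference(ch, 0.01, seed = 2)
  a <- strsplit(ch$sequence, "")[[1]]
  b <- strsplit(mut$sequence, "")[[1]]
  d <- sum(a != b)
  # binomial oracle: 10,000 x 0.01 = 100 +/- 3*sqrt(99)
  expect_lt(abs(d - 100), 3 * sqrt(10000 * 0.01 * 0.99))
  # substituted bases are always different from the original
  expect_true(all(b[a != b] %in% c("A", "C", "G", "T")))
  expect_identical(mut$repeat_annotations, ch$repeat_annotations)
  expect_error(mutate_reference(ch, 1.2))
})

test_that("simulated BAC clones start and end at HindIII sites within the size selection window", {
  fx <- clean_sim()
  clones <- fx$clones
  n_exp <- round(2e6 * 10 / 122000)
  expect_equal(nrow(clones), n_exp)
  len <- clones$end - clones$start
  expect_true(all(len >= fx$cfg$insert_min & len <= fx$cfg$insert_max))
  # both termini carry the HindIII recognition sequence
  left <- substring(fx$chrom$sequence, clones$start + 1, clones$start + 6)
  right <- substring(fx$chrom$sequence, clones$end - 5, clones$end)
  expect_true(all(left == "AAGCTT"))
  expect_true(all(right == "AAGCTT"))
  # plate layout: unique wells, 384 per plate, valid rows/columns
  well <- paste(clones$plate, clones$row, clones$col)
  expect_false(anyDuplicated(well) > 0)
  expect_true(all(clones$row %in% LETTERS[1:16]))
  expect_true(all(clones$col %in% 1:24))
  expect_true(all(table(clones$plate)[-length(table(clones$plate))] == 384))
})

test_that("contamination draws the expected share of clones from the decoy", {
  cfg <- sim_config(chromosome_length = 1e6, library_coverage = 12.2,
                    contamination_fraction = 0.1, seed = 21)
  chrom <- generate_chromosome(cfg)
  decoy <- generate_chromosome(sim_config(chromosome_length = 1e6,
                                          seed = 55))
  clones <- simulate_bac_library(chrom, decoy, cfg)
  expect_equal(nrow(clones), 100)
  expect_equal(sum(clones$source == "decoy"), 10)
  # decoy termini lie on the decoy sequence
  d <- clones[clones$source == "decoy", ]
  expect_true(all(substring(decoy$sequence, d$start + 1, d$start + 6) ==
                    "AAGCTT"))
  # determinism: same config and seed reproduce the clone table exactly
  expect_identical(clones, simulate_bac_library(chrom, decoy, cfg))
})

test_that("target clone starts are approximately uniform over mappable positions", {
  cfg <- sim_config(chromosome_length = 2e6, library_coverage = 305,
                    contamination_fraction = 0, seed = 13)
  chrom <- generate_chromosome(cfg)
  decoy <- generate_chromosome(sim_config(chromosome_length = 1e6,
                                          seed = 56))
  clones <- simulate_bac_library(chrom, decoy, cfg)
  expect_gte(nrow(clones), 5000)
  # uniform over mappable start positions: expected bin mass follows the
  # HindIII site density, not base pairs
  lim <- 2e6 - 2e5
  sites <- gregexpr("AAGCTT", chrom$sequence, fixed = TRUE)[[1]] - 1L
  sites <- sites[sites <= lim]
  st <- clones$start[clones$start <= lim]
  breaks <- seq(0, lim, length.out = 11)
  obs <- table(cut(st, breaks, include.lowest = TRUE))
  pr <- as.numeric(table(cut(sites, breaks, include.lowest = TRUE)))
  p <- suppressWarnings(stats::chisq.test(obs, p = pr / sum(pr)))$p.value
  expect_gt(p, 0.001)
})

test_that("repeat units are cloneable but invisible to the fingerprint enzymes", {
  unit <- repeat_unit(length = 360, with_hindiii = TRUE, seed = 3)
  doubled <- paste0(unit, unit)
  for (m in c("GGATCC", "GAATTC", "TCTAGA", "CTCGAG", "GGCC"))
    expect_false(grepl(m, doubled, fixed = TRUE))
  expect_equal(sum(gregexpr("AAGCTT", doubled, fixed = TRUE)[[1]] > 0), 2)
  no_h <- repeat_unit(length = 200, with_hindiii = FALSE, seed = 4)
  expect_false(grepl("AAGCTT", paste0(no_h, no_h), fixed = TRUE))
  # a clone fully inside such an array fails the quality floor
  array_seq <- paste(rep(unit, 400), collapse = "")
  fp <- hicf_fingerprint(substring(array_seq, 1, 122000), "rep")
  expect_lt(fp$band_count, 18)
})

test_that("quality dropout corrupts band counts out of the quality window", {
  fx <- clean_sim()
  fps <- fx$fps[1:40]
  out <- corrupt_fingerprints(fps, 0.25, seed = 9)
  counts <- lengths(out)
  bad <- counts < 18 | counts > 207
  expect_equal(sum(bad), 10)
  expect_identical(out[!bad], fps[!bad])
})
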