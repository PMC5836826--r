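test_that("deletion-bin assignment returns every containing bin", {
  expect_equal(assign_bins(0.90), "5BS6")
  expect_equal(assign_bins(0.30), "C-5BS3")
  expect_setequal(assign_bins(0.69), c("5BS8", "5BS1"))
  expect_equal(assign_bins(1.0), "5BS6")   # terminal bin closed at 1
  expect_equal(assign_bins(0.41), "5BS3")  # half-open boundaries
  expect_error(assign_bins(1.2))
})

make_plated_clones <- function(df) {
  df$source <- "target"
  structure(df[, c("clone_id", "source", "start", "end",
                   "plate", "row", "col")],
            class = c("clone_set", "data.frame"))
}

test_that("pool screening deconvolves plate x row x column intersections", {
  clones <- make_plated_clones(data.frame(
    clone_id = c("c1", "c2", "c3", "c4"),
    start = c(0, 5000, 20000, 40000),
    end = c(10000, 15000, 30000, 50000),
    plate = c(2L, 2L, 2L, 3L),
    row = c("B", "D", "F", "A"),
    col = c(3L, 1L, 9L, 1L)))
  mk <- data.frame(id = c("m_unique", "m_pair", "m_none"),
                   pos = c(25000, 7000, 999999))
  scr <- screen_pools(mk, clones)
  # single positive clone: plate, row and column pools identify it
  expect_setequal(scr$m_unique$pools, c("P002", "P002-RF", "P002-C09"))
  expect_equal(scr$m_unique$hits, "c3")
  expect_false(scr$m_unique$ambiguous)
  # two positives in one plate on different rows AND columns: 2x2 ambiguity
  expect_true(scr$m_pair$ambiguous)
  expect_setequal(scr$m_pair$candidates, c("c1", "c2"))
  expect_length(scr$m_pair$hits, 0)
  # marker hitting no clone: empty but valid
  expect_length(scr$m_none$hits, 0)
  expect_length(scr$m_none$pools, 0)
})

test_that("confirmed pool hits always contain the marker locus", {
  fx <- clean_sim()
  mk <- fx$chrom$marker_loci
  scr <- screen_pools(data.frame(id = mk$id, pos = mk$pos), fx$clones)
  for (m in names(scr)) {
    pos <- mk$pos[mk$id == m]
    for (cl in scr[[m]]$hits) {
      i <- match(cl, fx$clones$clone_id)
      expect_true(fx$clones$start[i] <= pos && pos < fx$clones$end[i])
    }
  }
})

test_that("reference windows self-anchor with minimal scores", {
  set.seed(41)
  ref <- paste(sample(c("A", "C", "G", "T"), 4e5, TRUE,
                      prob = c(.27, .23, .23, .27)), collapse = "")
  wf <- fingerprint_windows(ref)
  an <- anchor_by_reference(wf, wf, match_params_insilico())
  iv <- attr(wf, "windows")
  expect_equal(nrow(an$clones), nrow(iv))
  expect_equal(an$clones$start, iv$start[match(an$clones$clone_id, iv$id)])
})

test_that("decoy clones do not anchor to the target reference", {
  fx <- clean_sim()
  decoy_clone <- substring(fx$decoy$sequence, 100001, 222000)
  dfp <- list(dec = hicf_fingerprint(decoy_clone)$bands)
  wf <- fingerprint_windows(substring(fx$chrom$sequence, 1, 1e6))
  an <- anchor_by_reference(dfp, wf, match_params_insilico())
  expect_equal(nrow(an$clones), 0)
})

test_that("staged coverage accounting is cumulative and integer-rounded", {
  cov <- staged_coverage(c(131447, 54527, 103922), chrom_kb = 290000)
  expect_equal(cov$cumulative_kb, c(131447, 185974, 289896))
  expect_equal(cov$percent, c(45, 64, 100))
  # additivity from per-contig stages
  st <- c(1, 2, 1, NA, 3, 2)
  kb <- c(100, 200, 300, 400, 500, 600)
  cc <- staged_coverage(st, kb, chrom_kb = 2000)
  expect_equal(cc$increment_kb, c(400, 800, 500))
  expect_equal(cc$cumulative_kb, cumsum(cc$increment_kb))
  expect_equal(cc$percent, c(20, 60, 85))
})
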