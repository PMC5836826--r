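test_that("digest_sites finds every recognition site on the given strand", {
  s <- digest_sites("AAGGATCCAA")
  expect_equal(s$BamHI, 2L)
  expect_equal(s$HaeIII, integer(0))
  s <- digest_sites("GGCCGGCC")
  expect_equal(s$HaeIII, c(0L, 4L))
  s <- digest_sites("")
  expect_true(all(lengths(s) == 0))
  # N never matches
  expect_equal(digest_sites("GGNTCCGGATCC")$BamHI, 6L)
})

test_that("band encoding multiplies by 30 and offsets per enzyme channel", {
  expect_equal(encode_band("BamHI", 200), 6000L)
  expect_equal(encode_band("EcoRI", 100), 18000L)
  expect_equal(encode_band("XhoI", 500), 60000L)
  expect_true(is.na(encode_band("XbaI", 49)))
  expect_true(is.na(encode_band("BamHI", 501)))
  expect_error(encode_band("HindIII", 100), "unknown")
})

test_that("fingerprints contain exactly the labeled size-window fragments", {
  at <- function(n) paste(rep("AT", ceiling(n / 2)), collapse = "")
  # one BamHI site, one HaeIII site 200 bp downstream, nothing else:
  # the BamHI-HaeIII fragment is the only band (200 x 30 + 0 = 6000); the
  # 30 bp leading fragment is below the sizing window and the trailing
  # HaeIII-end fragment is unlabeled
  s <- paste0(substring(at(30), 1, 30), "GGATCC", substring(at(194), 1, 194),
              "GGCC", substring(at(400), 1, 400))
  fp <- hicf_fingerprint(s, "toy")
  expect_equal(fp$bands, 6000L)
  expect_equal(fp$band_count, 1L)
  # no labeled-enzyme site at all: no bands even with HaeIII present
  fp0 <- hicf_fingerprint(paste0(at(100), "GGCC", at(100), "GGCC", at(100)))
  expect_equal(fp0$bands, integer(0))
  # purity: identical input gives identical bands
  expect_identical(hicf_fingerprint(s)$bands, hicf_fingerprint(s)$bands)
})

test_that("a long labeled-site-free spacer makes fingerprints additive over concatenation", {
  at_pad <- paste(rep("AT", 255), collapse = "")  # 510 bp site-free pad
  set.seed(31)
  core <- function() paste(sample(c("A", "C", "G", "T"), 3000, TRUE,
                                  prob = c(.27, .23, .23, .27)),
                           collapse = "")
  a <- paste0(at_pad, core(), at_pad)
  b <- paste0(at_pad, core(), at_pad)
  spacer <- paste(rep("AT", 300), collapse = "")
  joint <- hicf_fingerprint(paste0(a, spacer, b))$bands
  parts <- sort(c(hicf_fingerprint(a)$bands, hicf_fingerprint(b)$bands))
  expect_equal(joint, parts)
})

test_that("both-labeled-end fragments emit one band labeled by the lower-priority enzyme", {
  pad <- paste(rep("AT", 20), collapse = "")  # 40 bp, below the size window
  # XhoI site 100 bp before a BamHI site: single band in the BamHI channel
  s <- paste0(pad, "CTCGAG", paste(rep("AT", 47), collapse = ""),
              "GGATCC", pad)
  fp <- hicf_fingerprint(s)
  expect_equal(fp$bands, 3000L)
  expect_false(any(fp$bands == 100 * 30 + 45000))
})

test_that("duplicate encoded values are kept as a multiset", {
  at <- paste(rep("AT", 60), collapse = "")
  piece <- paste0("GGATCC", substring(at, 1, 94))  # 100 bp BamHI fragments
  s <- paste0(at, piece, piece, piece, "GGATCC", at)
  fp <- hicf_fingerprint(s)
  expect_equal(sum(fp$bands == 3000), 3)
})

test_that("the quality filter retains 18-207 bands inclusively and partitions exhaustively", {
  fps <- list(a = seq_len(17) * 30L + 1500L, b = seq_len(18) * 30L + 1500L,
              c = seq_len(207) * 30L + 1500L, d = seq_len(208) * 30L + 1500L)
  qf <- quality_filter(fps)
  expect_equal(names(qf$retained), c("b", "c"))
  expect_equal(names(qf$rejected), c("a", "d"))
  expect_equal(qf$summary$n_total, 4)
  expect_equal(qf$summary$pct_retained, 50)
  expect_length(intersect(names(qf$retained), names(qf$rejected)), 0)
})

test_that("random 100 kb sequences at GC 0.46 fingerprint inside the quality window", {
  set.seed(8)
  counts <- vapply(1:5, function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 1e5, TRUE,
                      prob = c(.27, .23, .23, .27)), collapse = "")
    hicf_fingerprint(s)$band_count
  }, integer(1))
  expect_true(all(counts >= 18 & counts <= 207))
})

test_that("reference windows tile at the step size with a flush final window", {
  hp <- hicf_params(window_size = 1000, window_step = 500,
                    quality_min_bands = 1, quality_max_bands = 1000)
  set.seed(12)
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  w <- fingerprint_windows(mk(10000), hp)
  iv <- attr(w, "windows")
  expect_equal(nrow(iv), 19)
  expect_equal(iv$start[1], 0)
  expect_equal(c(iv$start[19], iv$end[19]), c(9000, 10000))
  w1 <- fingerprint_windows(mk(1000), hp)
  expect_equal(nrow(attr(w1, "windows")), 1)
  w2 <- fingerprint_windows(mk(1300), hp)
  expect_equal(attr(w2, "windows")$start, c(0, 300))
  expect_equal(attr(w2, "windows")$end, c(1000, 1300))
  expect_error(fingerprint_windows(mk(900), hp), "shorter")
})
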