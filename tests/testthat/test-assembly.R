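# synthetic "slot" clones: clone covering slots [s, s+39] shares 40 - |ds|
# bands with a clone 'ds' slots away, giving an interval-like overlap graph

chain_fps <- function(n, step = 8, width = 40) {
  fps <- lapply(seq_len(n) - 1, function(i)
    slots_to_bands(seq(i * step, i * step + width - 1)))
  names(fps) <- sprintf("c%02d", seq_len(n))
  fps
}

test_that("staged exclusion leaves a linear chain untouched (idempotence)", {
  fps <- chain_fps(8)
  net <- overlap_network(fps, match_params())
  res <- exclude_q(net)
  expect_equal(nrow(res$excluded_clones), 0)
  expect_equal(nrow(res$excluded_edges), 0)
  expect_identical(res$graph$edges, net$edges)
})

test_that("a star hub is excluded as a questionable clone", {
  hub <- slots_to_bands(0:199)
  leaves <- lapply(0:9, function(i)
    slots_to_bands(c(i * 20 + 0:19, 10000 + i * 100 + 0:19)))
  fps <- c(list(hub = hub), setNames(leaves, sprintf("leaf%02d", 0:9)))
  net <- overlap_network(fps, match_params())
  # sanity: hub overlaps every leaf, leaves do not overlap each other
  expect_equal(nrow(net$edges), 10)
  res <- exclude_q(net)
  expect_true("hub" %in% res$excluded_clones$clone_id)
  expect_equal(res$excluded_clones$stage[
    res$excluded_clones$clone_id == "hub"], "q_clone")
  expect_false(any(sprintf("leaf%02d", 0:9) %in%
                     res$excluded_clones$clone_id))
})

test_that("the greedy linearity test agrees with an exhaustive ordering search on small graphs", {
  set.seed(23)
  n_checked <- 0
  for (rep in 1:25) {
    n <- sample(4:7, 1)
    start <- sort(runif(n, 0, 250))
    len <- runif(n, 80, 120)
    fps <- lapply(seq_len(n), function(i)
      slots_to_bands(seq(floor(start[i]), floor(start[i] + len[i]))))
    names(fps) <- sprintf("v%d", seq_len(n))
    net <- overlap_network(fps, match_params())
    comps <- physmapr:::graph_components(net)
    for (nd in comps) {
      if (length(nd) < 3 || length(nd) > 7) next
      ed <- physmapr:::component_edges(net, nd)
      cp <- physmapr:::component_compat(net, nd)
      expect_equal(physmapr:::component_is_linear(nd, ed, cp),
                   exhaustive_linear(nd, ed, cp))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 5)
})

test_that("contigs reproduce the simulated clone order up to reversal", {
  # clones at 0, 60, 120, 180 kb with interval-model band sharing
  fps <- lapply(c(0, 60, 120, 180), function(s)
    slots_to_bands(seq(s, s + 121)))
  names(fps) <- sprintf("p%03d", c(0, 60, 120, 180))
  net <- overlap_network(fps, match_params())
  cs <- build_contigs(exclude_q(net)$graph, fps)
  expect_equal(nrow(cs$contigs), 1)
  ord <- cs$clone_order[[1]]
  expect_true(identical(ord, names(fps)) || identical(ord, rev(names(fps))))
})

test_that("contig reliability is determined solely by clone count", {
  two <- chain_fps(2)
  net2 <- overlap_network(two, match_params())
  cs2 <- build_contigs(exclude_q(net2)$graph, two)
  expect_equal(cs2$contigs$n_clones, 2)
  expect_equal(cs2$contigs$reliability, "questionable")
  six <- chain_fps(6)
  cs6 <- build_contigs(exclude_q(overlap_network(six,
                                                 match_params()))$graph, six)
  expect_equal(cs6$contigs$reliability, "reliable")
})

test_that("consensus band counting merges matched chains across adjacent clones", {
  one <- list(a = slots_to_bands(1:100))
  expect_equal(consensus_band_count("a", one), 100)
  expect_equal(estimate_length(consensus_band_count("a", one)), 120)
  twin <- list(a = slots_to_bands(1:100), b = slots_to_bands(1:100))
  expect_equal(consensus_band_count(c("a", "b"), twin), 100)
  # forced by the 1.2 kb/band rule
  expect_equal(estimate_length(2565), 3078)
  # linearity of the estimate
  expect_equal(estimate_length(7 + 13), estimate_length(7) + estimate_length(13))
})

test_that("contig depth is calculated length over estimated length", {
  expect_equal(contig_depth(10, 1220), 1)
  expect_equal(contig_depth(10, 122), 10)
  expect_error(contig_depth(10, 0), "positive")
})

test_that("MTP selection skips redundant intermediate clones", {
  # clones at 0, 60, 122, 180, 244 kb with 140 kb inserts: clone pairs two
  # steps apart still overlap significantly, so the tiling path takes
  # every other clone
  pos <- c(0, 60, 122, 180, 244)
  fps <- lapply(pos, function(s) slots_to_bands(seq(s, s + 139)))
  names(fps) <- sprintf("p%03d", pos)
  net <- overlap_network(fps, match_params())
  cs <- build_contigs(exclude_q(net)$graph, fps)
  ord <- cs$clone_order[[1]]
  mtp <- select_mtp(ord, fps, match_params())
  expect_equal(sort(mtp), c("p000", "p122", "p244"))
  expect_length(attr(mtp, "warnings"), 0)
  # single-clone contig: the MTP is that clone
  expect_equal(select_mtp("p000", fps), "p000")
})

test_that("FPC-mode MTP forces consecutive clones when shared bands stay under 12", {
  # middle clone sees only 11 of each terminal clone's bands
  fps <- list(a = slots_to_bands(0:10), b = slots_to_bands(0:39),
              c = slots_to_bands(29:39))
  net <- overlap_network(fps, match_params())
  cs <- build_contigs(exclude_q(net)$graph, fps)
  ord <- cs$clone_order[[1]]
  mtp <- select_mtp(ord, fps, match_params(), mode = "fpc")
  expect_equal(length(mtp), 3)
  expect_gt(length(attr(mtp, "warnings")), 0)
})

test_that("assembly conserves clones across contigs, singletons and exclusions", {
  fx <- clean_sim()
  map <- fx$map
  n_in <- length(fx$qf$retained)
  n_out <- sum(map$contigs$n_clones) + length(map$singletons) +
    nrow(map$exclusions$clones)
  expect_equal(n_out, n_in)
  # every excluded clone carries its stage label
  expect_true(all(map$exclusions$clones$stage %in%
                    c("q_clone", "split", "promiscuous", "topology")))
  # contig ids are assigned in decreasing estimated size
  expect_false(is.unsorted(rev(map$contigs$est_kb)))
})

test_that("a 10x clean simulation assembles at plausible depth", {
  fx <- clean_sim()
  dr <- depth_report(fx$map$contigs)
  expect_gt(dr$mean_depth, 5)
  expect_lt(dr$mean_depth, 12)
})
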