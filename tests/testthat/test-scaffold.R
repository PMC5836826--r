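# two separated chains plus configurable extras, as slot fingerprints
two_contig_setup <- function(extra = list()) {
  fps <- c(
    setNames(lapply(0:3, function(i) slots_to_bands(i * 8 + 0:39)),
             sprintf("a%d", 0:3)),
    setNames(lapply(0:3, function(i) slots_to_bands(2000 + i * 8 + 0:39)),
             sprintf("b%d", 0:3)),
    extra)
  net <- overlap_network(fps, match_params())
  cs <- build_contigs(exclude_q(net)$graph, fps)
  list(fps = fps, net = net, cs = cs)
}

test_that("a shared terminal marker merges two scaffolds (rule a)", {
  s <- two_contig_setup()
  expect_equal(nrow(s$cs$contigs), 2)
  terms <- physmapr:::contig_terminals(s$cs)
  mh <- data.frame(marker_id = "M1",
                   clone_id = c(terms[[1]][2], terms[[2]][1]))
  sc <- merge_scaffolds(s$cs, s$net, mh)
  merged <- sc$scaffolds[lengths(lapply(sc$scaffolds, `[[`,
                                        "contigs")) == 2]
  expect_length(merged, 1)
  expect_equal(merged[[1]]$junctions$evidence, "marker")
  expect_equal(merged[[1]]$junctions$detail, "M1")
})

test_that("a single linking clone merges two contigs with recorded evidence", {
  # linker shares a few bands with the right end of chain A and the left end
  # of chain B: too weak to join the contigs in the network, but recorded as
  # a near-significant overlap usable as junction evidence
  link <- list(link = slots_to_bands(c(58:63, 2000:2005, 7000:7027)))
  s <- two_contig_setup(link)
  expect_equal(nrow(s$cs$contigs), 2)
  expect_true("link" %in% s$cs$singletons)
  sc <- merge_scaffolds(s$cs, s$net)
  merged <- sc$scaffolds[lengths(lapply(sc$scaffolds, `[[`,
                                        "contigs")) == 2]
  expect_length(merged, 1)
  expect_equal(merged[[1]]$junctions$evidence, "single-clone")
  expect_equal(merged[[1]]$junctions$detail, "link")
})

test_that("a marker on terminals of three contigs is a conflict, not a merge", {
  extra <- setNames(lapply(0:3, function(i)
    slots_to_bands(5000 + i * 8 + 0:39)), sprintf("c%d", 0:3))
  s <- two_contig_setup(extra)
  expect_equal(nrow(s$cs$contigs), 3)
  terms <- physmapr:::contig_terminals(s$cs)
  mh <- data.frame(marker_id = "M1",
                   clone_id = vapply(terms, `[`, "", 1))
  sc <- merge_scaffolds(s$cs, s$net, mh)
  expect_true(all(lengths(lapply(sc$scaffolds, `[[`, "contigs")) == 1))
  expect_gt(nrow(sc$conflicts), 0)
})

test_that("marker validation flags chimeras, non-unique markers and map inconsistencies", {
  s <- two_contig_setup()
  cs <- s$cs
  ord1 <- cs$clone_order[[1]]; ord2 <- cs$clone_order[[2]]
  graph <- exclude_q(s$net)$graph
  # rule b: marker in an internal overlapping pair of one contig and in a
  # single clone of the other
  mh_b <- data.frame(marker_id = "Mb",
                     clone_id = c(ord1[2], ord1[3], ord2[1]))
  v <- validate_scaffolds(merge_scaffolds(cs, s$net), cs, graph, mh_b)
  fb <- v$flags[v$flags$rule == "b", ]
  expect_equal(fb$subject, ord2[1])
  # rule c: marker in overlapping groups of both contigs
  mh_c <- data.frame(marker_id = "Mc",
                     clone_id = c(ord1[1], ord1[2], ord2[1], ord2[2]))
  v <- validate_scaffolds(merge_scaffolds(cs, s$net), cs, graph, mh_c)
  expect_equal(v$flags$rule, "c")
  # rule d: two markers in one scaffold far apart on the genetic map
  terms <- physmapr:::contig_terminals(cs)
  mh_d <- data.frame(marker_id = c("M1", "M1", "Md1", "Md2"),
                     clone_id = c(terms[[1]][2], terms[[2]][1],
                                  ord1[1], ord2[2]))
  gm <- data.frame(marker_id = c("Md1", "Md2"), cm = c(3, 40))
  sc <- merge_scaffolds(cs, s$net, mh_d[mh_d$marker_id == "M1", ])
  v <- validate_scaffolds(sc, cs, graph, mh_d, gm, cm_threshold = 10,
                          apply_splits = TRUE)
  fd <- v$flags[v$flags$rule == "d", ]
  expect_equal(nrow(fd), 1)
  expect_match(fd$detail, "37.0 cM")
  # the flagged scaffold was split at its only junction
  expect_gt(length(v$scaffolds), length(sc$scaffolds))
})
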