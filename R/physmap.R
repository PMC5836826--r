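#' Assemble a physical map from quality-filtered fingerprints
#'
#' The central constructor: builds the significant-overlap network, applies
#' staged questionable-overlap/clone exclusion, constructs linear-topology
#' contigs with consensus band counts, estimated lengths, reliability classes
#' and depths, and selects a minimal tiling path per contig.
#'
#' @param fps Named list of sorted integer band vectors (quality-filtered).
#' @param mparams A [match_params()].
#' @param aparams An [assembly_params()].
#' @param mtp_mode `"ltc"` (default) or `"fpc"`.
#' @return An object of class `phys_map`: list with `contigs`, `clone_order`,
#'   `singletons`, `mtp` (named list of MTP clone ids per contig),
#'   `exclusions` (clone and edge logs), `network` (original graph), `graph`
#'   (cleaned graph), parameter objects and `n_fingerprints`.
#' @export
assemble_physical_map <- function(fps, mparams = match_params(),
                                  aparams = assembly_params(),
                                  mtp_mode = "ltc") {
  net <- overlap_network(fps, mparams)
  cleaned <- exclude_q(net, mparams)
  cs <- build_contigs(cleaned$graph, fps, aparams, mparams)
  exclusions <- list(
    clones = rbind(cleaned$excluded_clones, cs$removed),
    edges = cleaned$excluded_edges)
  mtp <- lapply(cs$clone_order, select_mtp, fps = fps, mparams = mparams,
                aparams = aparams, mode = mtp_mode)
  structure(list(contigs = cs$contigs, clone_order = cs$clone_order,
                 singletons = cs$singletons, mtp = mtp,
                 exclusions = exclusions, network = net,
                 graph = cleaned$graph,
                 match_params = mparams, assembly_params = aparams,
                 n_fingerprints = length(fps)),
            class = "phys_map")
}

#' @export
print.phys_map <- function(x, ...) {
  rel <- sum(x$contigs$reliability == "reliable")
  cat("Physical map:", x$n_fingerprints, "fingerprints ->",
      nrow(x$contigs), "contigs (", rel, "reliable ),",
      length(x$singletons), "singletons\n")
  cat("  total estimated length:",
      format(round(sum(x$contigs$est_kb))), "kb; MTP size:",
      sum(lengths(x$mtp)), "clones\n")
  invisible(x)
}

#' @export
summary.phys_map <- function(object, chrom_kb = NULL,
                             n_fingerprints_total = NULL, ...) {
  if (is.null(chrom_kb))
    chrom_kb <- sum(object$contigs$est_kb)  # coverage of itself = 100%
  assembly_stats(object, chrom_kb, n_fingerprints_total)
}

#' Plot a physical map
#'
#' Two base-graphics panels: contig depth against estimated length (repeat
#' contigs stand out above the mean line) and the contig length histogram.
#'
#' @param x A `phys_map`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.phys_map <- function(x, ...) {
  ct <- x$contigs
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(ct$est_kb, ct$depth, log = "x",
                 xlab = "estimated contig length (kb)",
                 ylab = "depth (fold)", pch = 19, cex = 0.7, ...)
  md <- sum(ct$n_clones * x$assembly_params$mean_insert_kb) / sum(ct$est_kb)
  graphics::abline(h = md, lty = 2)
  graphics::hist(ct$est_kb, breaks = 20, main = "",
                 xlab = "estimated contig length (kb)")
  invisible(x)
}

#' Run the full desk-scale pipeline
#'
#' Orchestrates simulate -> fingerprint -> quality filter -> overlap ->
#' assemble -> MTP -> anchor (pooled markers, deletion bins, reference
#' windows) -> statistics, writing every artifact plus a JSON manifest to
#' `outdir`. Deterministic for a fixed config seed. When
#' `config$divergence_rate` is `NA` no reference is built and anchoring is
#' limited to marker/bin evidence (noted in the manifest).
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param hparams,mparams,aparams Stage parameter objects.
#' @param external_marker_fraction Fraction of marker loci treated as
#'   external-evidence markers (positions supplied from outside the pooled
#'   screen, the stage-2 analogue of synteny-derived markers).
#' @param size_class_scale Scale factor for the size-class report boundaries.
#' @return Invisibly, a list with the `phys_map`, anchoring tables, stats and
#'   file paths.
#' @export
run_pipeline <- function(config = sim_config(), outdir = tempfile("physmap_"),
                         hparams = hicf_params(),
                         mparams = match_params_insilico(hparams),
                         aparams = assembly_params(),
                         external_marker_fraction = 0.3,
                         size_class_scale = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, paste0(...))

  # simulate
  chrom <- generate_chromosome(config)
  set.seed(config$seed + 17L)
  decoy <- local({
    cfg2 <- config
    cfg2$seed <- config$seed + 101L
    cfg2$repeat_blocks <- list()
    cfg2$marker_density <- c(SSR = 0, ISBP = 0)
    generate_chromosome(cfg2)
  })
  clones <- simulate_bac_library(chrom, decoy, config)
  write_fasta(c(chrom = chrom$sequence), p("chromosome.fa"))
  write_fasta(c(decoy = decoy$sequence), p("decoy.fa"))
  write_bed(chrom$repeat_annotations, "chrom", p("repeats.bed"))
  write_tsv(chrom$marker_loci, p("markers.tsv"))
  write_tsv(as.data.frame(clones), p("clones.tsv"))

  # fingerprint + quality filter (with dropout corruption)
  fps_all <- fingerprint_set(clone_sequences(chrom, decoy, clones), hparams)
  fps_all <- corrupt_fingerprints(fps_all, config$quality_dropout, hparams,
                                  seed = config$seed + 2L)
  qf <- quality_filter(fps_all, hparams)
  write_bands(qf$retained, p("bands.txt"))

  # assemble
  map <- assemble_physical_map(qf$retained, mparams, aparams)
  write_tsv(cbind(map$contigs,
                  clone_order = vapply(map$clone_order, paste,
                                       "", collapse = ",")),
            p("contigs.tsv"))
  write_tsv(data.frame(contig_id = rep(names(map$mtp), lengths(map$mtp)),
                       clone_id = unlist(map$mtp, use.names = FALSE)),
            p("mtp.tsv"))
  write_tsv(map$network$edges, p("edges.tsv"))

  # anchoring stage 1: pooled marker screening
  mk <- chrom$marker_loci
  set.seed(config$seed + 3L)
  n_ext <- round(nrow(mk) * external_marker_fraction)
  ext_idx <- if (n_ext > 0) sort(sample(nrow(mk), n_ext)) else integer(0)
  screened <- mk[setdiff(seq_len(nrow(mk)), ext_idx), , drop = FALSE]
  external <- mk[ext_idx, , drop = FALSE]
  scr <- screen_pools(screened, clones)
  hits1 <- data.frame(marker_id = rep(names(scr), lengths(lapply(scr, `[[`,
                                                                 "hits"))),
                      clone_id = unlist(lapply(scr, `[[`, "hits"),
                                        use.names = FALSE))
  clone2ctg <- rep(names(map$clone_order), lengths(map$clone_order))
  names(clone2ctg) <- unlist(map$clone_order, use.names = FALSE)
  stage_of <- rep(NA_integer_, nrow(map$contigs))
  names(stage_of) <- map$contigs$contig_id
  pos_of <- rep(NA_real_, nrow(map$contigs))
  names(pos_of) <- map$contigs$contig_id
  if (nrow(hits1)) {
    h <- hits1[hits1$clone_id %in% names(clone2ctg), , drop = FALSE]
    for (r in seq_len(nrow(h))) {
      ct <- clone2ctg[h$clone_id[r]]
      if (is.na(stage_of[ct])) {
        stage_of[ct] <- 1L
        pos_of[ct] <- screened$pos[screened$id == h$marker_id[r]]
      }
    }
  }
  # stage 2: external markers with known positions (synteny-style evidence)
  if (nrow(external)) {
    hits2 <- marker_clone_hits(data.frame(id = external$id,
                                          pos = external$pos), clones)
    h <- hits2[hits2$clone_id %in% names(clone2ctg), , drop = FALSE]
    for (r in seq_len(nrow(h))) {
      ct <- clone2ctg[h$clone_id[r]]
      if (is.na(stage_of[ct])) {
        stage_of[ct] <- 2L
        pos_of[ct] <- external$pos[external$id == h$marker_id[r]]
      }
    }
  }
  # stage 3: in silico fingerprinting of the diverged reference
  have_ref <- !is.na(config$divergence_rate)
  anchors3 <- NULL
  if (have_ref) {
    ref <- mutate_reference(chrom, config$divergence_rate,
                            seed = config$seed + 4L)
    write_fasta(c(reference = ref$sequence), p("reference.fa"))
    wfps <- fingerprint_windows(ref$sequence, hparams)
    mtp_ids <- unlist(map$mtp, use.names = FALSE)
    anchors3 <- anchor_by_reference(qf$retained[mtp_ids], wfps, mparams,
                                    contig_set = map)
    for (r in seq_len(nrow(anchors3$contigs))) {
      ct <- anchors3$contigs$contig_id[r]
      if (is.na(stage_of[ct])) {
        stage_of[ct] <- 3L
        pos_of[ct] <- anchors3$contigs$position[r]
      }
    }
  }
  anchored <- !is.na(stage_of)
  agp <- data.frame(object = "chrom",
                    object_beg = ifelse(anchored, round(pos_of), NA),
                    object_end = ifelse(anchored, round(pos_of), NA),
                    part_number = seq_along(stage_of),
                    component_type = "contig",
                    component_id = names(stage_of),
                    evidence = c("marker", "marker", "reference-window",
                                 "unplaced")[ifelse(anchored, stage_of, 4L)],
                    stage = stage_of)
  write_tsv(agp, p("anchors.tsv"))

  chrom_kb <- config$chromosome_length / 1000
  cov <- staged_coverage(stage_of, map$contigs$est_kb, chrom_kb = chrom_kb)
  st <- assembly_stats(map, chrom_kb, n_fingerprints_total = length(fps_all))
  scr_rep <- size_class_report(map$contigs, pos_of[anchored],
                               config$chromosome_length,
                               scale = size_class_scale)
  jsonlite::write_json(list(stats = unclass(st), staged_coverage = cov),
                       p("stats.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("physmapr")),
    config = unclass(config)[setdiff(names(config), "repeat_blocks")],
    n_repeat_blocks = length(config$repeat_blocks),
    reference_built = have_ref,
    counts = list(clones = nrow(clones), fingerprints = length(fps_all),
                  retained = length(qf$retained),
                  edges = nrow(map$network$edges),
                  contigs = nrow(map$contigs),
                  singletons = length(map$singletons),
                  excluded_clones = nrow(map$exclusions$clones),
                  mtp = sum(lengths(map$mtp)),
                  anchored_contigs = sum(anchored)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(map = map, chromosome = chrom, clones = clones,
                 quality = qf, stage_of = stage_of, anchor_pos = pos_of,
                 anchors3 = anchors3, staged_coverage = cov, stats = st,
                 size_classes = scr_rep, outdir = outdir))
}
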