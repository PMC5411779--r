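#' Run the full assembly-pair evaluation pipeline
#'
#' Orchestrates the stages end-to-end from a single declarative
#' configuration: simulate a two-version assembly pair with reads and
#' candidate sites, write every input in its standard interchange format
#' (FASTA, AGP, PAF, SAM, VCF, BED, TSV), then run each analysis stage
#' from those files — collapse/expansion classification, read-pair
#' movement, candidate-base validation, and variant coverage/remap
#' transitions — and write per-stage tables plus a machine-readable
#' `summary.json` that records every resolved parameter, the stage
#' results, and truth-versus-called concordance. Identical configuration
#' and seed give a byte-identical summary.
#'
#' @param config a configuration list, or path to a YAML file with the
#'   same structure (see `inst/extdata/fixture_config.yaml`): top-level
#'   `seed`, a `sim` block of [sim_config()] fields, `events` (list of
#'   `kind` plus constructor arguments), `sites` (`n_sites`, `depth`,
#'   `read_length`), and `params` (`min_non_n_fraction`, `min_mapq`,
#'   `snv_cutoff`, `indel_cutoff`, `min_depth`, `merge_distance`, `top_k`).
#' @param outdir output directory (created if needed).
#' @return The summary list, invisibly; side effect: `inputs/` and
#'   `results/` trees plus `summary.json` under `outdir`.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- resolve_pipeline_config(config)
  dir.create(file.path(outdir, "inputs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "results"), recursive = TRUE, showWarnings = FALSE)

  paths <- stage_simulate(config, file.path(outdir, "inputs"))
  ce <- stage_collapse_expand(paths, config, file.path(outdir, "results"))
  mv <- stage_read_movement(paths, config, file.path(outdir, "results"))
  bv <- stage_base_validation(paths, config, file.path(outdir, "results"))
  tr <- stage_variant_transition(paths, config, file.path(outdir, "results"))

  summary <- list(
    schema_version = "1.0",
    seed = config$seed,
    parameters = config$params,
    sim = config$sim,
    events = config$events,
    collapse_expand = ce,
    read_movement = mv,
    base_validation = bv,
    variant_transition = tr
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}

resolve_pipeline_config <- function(config) {
  defaults <- list(
    seed = 1L,
    sim = list(),
    events = list(),
    sites = list(n_sites = 200L, depth = 30L, read_length = 100L),
    params = list(min_non_n_fraction = 0.5, min_mapq = 20L,
                  snv_cutoff = 0.90, indel_cutoff = 0.70, min_depth = 1L,
                  merge_distance = 100000L, top_k = 10L,
                  minicontig_flank = 60L)
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      for (f in setdiff(names(defaults[[nm]]), names(config[[nm]]))) {
        config[[nm]][[f]] <- defaults[[nm]][[f]]
      }
    }
  }
  config
}

events_from_config <- function(event_list) {
  lapply(event_list, function(e) {
    kind <- e$kind
    e$kind <- NULL
    ctor <- switch(kind,
                   false_duplication = ev_false_duplication,
                   collapse = ev_collapse,
                   gap_closure = ev_gap_closure,
                   inversion = ev_inversion,
                   base_error = ev_base_error,
                   retile = ev_retile,
                   centromere_model = ev_centromere_model,
                   alt_locus = ev_alt_locus,
                   stop("unknown event kind: ", kind))
    do.call(ctor, e)
  })
}

write_label_bed <- function(track_gr, path) {
  gr <- track_gr
  names(gr) <- gr$label
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

write_bed <- function(gr, path) {
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

read_bed_gr <- function(path) {
  if (file.size(path) == 0L) return(GenomicRanges::GRanges())
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::granges(gr, use.mcols = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname run_pipeline
#' @param outdir output directory for the stage.
#' @export
stage_simulate <- function(config, outdir) {
  sim_args <- config$sim
  sim_args$seed <- config$seed
  cfg <- do.call(sim_config, sim_args)
  pair <- simulate_assembly_pair(cfg, events_from_config(config$events))
  reads <- simulate_reads(pair)
  sites <- plant_candidate_sites(pair, config$sites$n_sites)
  contigs <- build_minicontigs(pair$A$seq, sites,
                               flank = config$params$minicontig_flank)
  site_reads <- simulate_site_reads(pair$A$seq, sites,
                                    depth = config$sites$depth,
                                    read_length = config$sites$read_length,
                                    seed = cfg$seed + 3L)
  p <- function(...) file.path(outdir, ...)
  Biostrings::writeXStringSet(pair$A$seq, p("A.fa"))
  Biostrings::writeXStringSet(pair$B$seq, p("B.fa"))
  write_agp(pair$A$agp, p("A.agp"))
  write_agp(pair$B$agp, p("B.agp"))
  write_paf(pair$truth$blocks, p("blocks.paf"))
  a_lens <- stats::setNames(Biostrings::width(pair$A$seq), names(pair$A$seq))
  b_lens <- stats::setNames(Biostrings::width(pair$B$seq), names(pair$B$seq))
  bp_lens <- b_lens[pair$B$primary]
  write_sam(reads$truth$A, a_lens, p("reads_vs_A.sam"))
  write_sam(reads$truth$B_primary, bp_lens, p("reads_vs_B_primary.sam"))
  write_sam(reads$truth$B_full, b_lens, p("reads_vs_B_full.sam"))
  write_pair_fastq(reads, p("reads"))
  write_sites(sites, p("candidate_sites.vcf"), contigs = a_lens)
  Biostrings::writeXStringSet(contigs$contigs, p("minicontigs.fa"))
  write_tsv(contigs$windows, p("minicontig_windows.tsv"))
  write_sam(site_reads, a_lens, p("site_reads_vs_A.sam"))
  write_bed(pair$truth$newseq_B, p("new_sequence_B.bed"))
  write_bed(pair$truth$cen_B, p("centromeres_B.bed"))
  write_label_bed(pair$truth$labels_A, p("truth_labels_A.bed"))
  write_label_bed(pair$truth$labels_B, p("truth_labels_B.bed"))
  write_tsv(pair$truth$roles, p("roles.tsv"))
  truth_sites <- sites
  class(truth_sites) <- "data.frame"
  write_tsv(truth_sites, p("truth_sites.tsv"))
  manifest <- list(
    note = paste("synthetic fixture: all distributional choices are",
                 "simulator design, recorded in the package vignette"),
    events = pair$events[, c("event_id", "kind", "chrom", "start", "end",
                             "obj2", "start2", "end2", "dest", "divergence")],
    n_read_pairs = reads$n_pairs,
    n_candidate_sites = nrow(sites))
  jsonlite::write_json(manifest, p("truth_manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  list(dir = outdir, pair = pair, reads = reads, sites = sites,
       contigs = contigs, site_reads = site_reads,
       a_lens = a_lens, b_lens = b_lens)
}

#' @rdname run_pipeline
#' @param paths stage-one handle (list with `dir`).
#' @export
stage_collapse_expand <- function(paths, config, outdir) {
  p <- function(...) file.path(paths$dir, ...)
  blocks <- read_paf(p("blocks.paf"))
  seqA <- Biostrings::readDNAStringSet(p("A.fa"))
  seqB <- Biostrings::readDNAStringSet(p("B.fa"))
  agpA <- read_agp(p("A.agp"))
  agpB <- read_agp(p("B.agp"))
  out <- list()
  for (side in c("A", "B")) {
    seqs <- if (side == "A") seqA else seqB
    agp <- if (side == "A") agpA else agpB
    blk <- if (side == "A") blocks else invert_blocks(blocks)
    lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
    regions <- ungapped_regions(seqs, agp,
                                min_non_n_fraction = config$params$min_non_n_fraction)
    track <- label_bases(blk, lens)
    summ <- summarize_labels(track, regions, k = config$params$top_k)
    write_tsv(summ$lengths, file.path(outdir,
                                      paste0("labels_", side, ".tsv")))
    write_tsv(summ$top, file.path(outdir, paste0("top_regions_", side, ".tsv")))
    totals <- tapply(summ$lengths$bases, summ$lengths$label, sum)
    out[[side]] <- list(kept_bases = summ$kept_bases,
                        bases = as.list(totals))
  }
  # truth concordance on labeled lengths inside kept regions
  truth_tr <- read_bed_gr_labels(p("truth_labels_A.bed"))
  regionsA <- ungapped_regions(seqA, agpA,
                               min_non_n_fraction = config$params$min_non_n_fraction)
  truth_len <- truth_label_lengths(truth_tr, regionsA)
  out$truth_concordance_A <- list(
    truth_bases = as.list(truth_len),
    match = identical(lapply(truth_len, as.integer),
                      lapply(out$A$bases[names(truth_len)], as.integer)))
  out
}

read_bed_gr_labels <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- GenomicRanges::granges(gr, use.mcols = FALSE)
  out$label <- gr$name
  out
}

truth_label_lengths <- function(truth_gr, regions) {
  out <- c(COLLAPSED = 0L, EXPANDED = 0L, UNIQUE = 0L, UNALIGNED = 0L)
  for (lb in names(out)) {
    sub <- truth_gr[truth_gr$label == lb]
    if (length(sub) == 0L) next
    inter <- suppressWarnings(GenomicRanges::intersect(sub, regions))
    out[[lb]] <- sum(GenomicRanges::width(inter))
  }
  as.list(out)
}

#' @rdname run_pipeline
#' @export
stage_read_movement <- function(paths, config, outdir) {
  p <- function(...) file.path(paths$dir, ...)
  agpA <- read_agp(p("A.agp"))
  agpB <- read_agp(p("B.agp"))
  pa <- read_placements(p("reads_vs_A.sam"))
  pb <- read_placements(p("reads_vs_B_primary.sam"))
  pf <- read_placements(p("reads_vs_B_full.sam"))
  roles <- utils::read.table(p("roles.tsv"), header = TRUE,
                             stringsAsFactors = FALSE)
  rolesB <- roles[roles$assembly == "B", c("seq_id", "role")]
  cen <- read_bed_gr(p("centromeres_B.bed"))
  newseq <- read_bed_gr(p("new_sequence_B.bed"))

  regions <- unchanged_regions(agpA, agpB)
  eligible <- select_unique_pairs(pa, regions,
                                  min_mapq = config$params$min_mapq)
  mv <- detect_moved_pairs(eligible, pa, pb, agpA, agpB,
                           min_mapq = config$params$min_mapq)
  rec <- classify_movement(mv$records, rolesB, cen)
  pairings <- component_pairings(rec)
  rs <- rescue_stats(pa, pb, pf, newseq)
  write_tsv(rec, file.path(outdir, "moved_reads.tsv"))
  write_tsv(pairings, file.path(outdir, "component_pairings.tsv"))
  cat_tab <- table(factor(rec$category,
                          levels = c("ON", "ONCEN", "OFF", "OFFCEN",
                                     "TOSCAF", "UNCEN")))
  write_tsv(as.data.frame(cat_tab, responseName = "reads"),
            file.path(outdir, "movement_categories.tsv"))

  truth <- truth_read_stats(paths$pair, paths$reads,
                            min_mapq = config$params$min_mapq)
  tkey <- paste0(truth$categories$read_id, "/", truth$categories$mate)
  okey <- paste0(rec$read_id, "/", rec$mate)
  agree <- identical(sort(tkey), sort(okey)) &&
    all(rec$category[match(tkey, okey)] == truth$categories$category)
  list(
    n_unchanged_regions = nrow(regions),
    n_eligible = mv$n_eligible, n_moved = mv$n_moved,
    fraction_moved = mv$fraction_moved,
    fraction_moved_also_unique_in_B = mv$fraction_moved_also_unique_in_B,
    categories = as.list(stats::setNames(as.integer(cat_tab),
                                         names(cat_tab))),
    rescue = rs,
    truth_concordance = list(
      fraction_moved_truth = truth$fraction_moved,
      categories_match = agree,
      rescue_truth = truth$rescue)
  )
}

#' @rdname run_pipeline
#' @export
stage_base_validation <- function(paths, config, outdir) {
  p <- function(...) file.path(paths$dir, ...)
  sites <- read_sites(p("candidate_sites.vcf"), fasta = p("A.fa"))
  truth_sites <- utils::read.table(p("truth_sites.tsv"), header = TRUE,
                                   stringsAsFactors = FALSE)
  sites$in_source <- truth_sites$in_source[match(sites$site_id,
                                                 truth_sites$site_id)]
  tallies <- pileup_tally(p("site_reads_vs_A.sam"), sites,
                          min_mapq = config$params$min_mapq,
                          seqlens = paths$a_lens)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    cl <- classify_site(tallies[[i]],
                        snv_cutoff = config$params$snv_cutoff,
                        indel_cutoff = config$params$indel_cutoff,
                        min_depth = config$params$min_depth)
    dec <- decide_update(cl, sites$type[i], sites$in_source[i])
    data.frame(site_id = sites$site_id[i], type = sites$type[i],
               depth = tallies[[i]]$depth,
               majority_fraction = cl$majority_fraction,
               call = cl$call, decision = dec$decision, reason = dec$reason,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  write_tsv(tab, file.path(outdir, "site_decisions.tsv"))
  upd <- sites[tab$decision == "APPLY_UPDATE", , drop = FALSE]
  write_sites(upd, file.path(outdir, "applied_updates.vcf"),
              contigs = paths$a_lens)

  contigs <- paths$contigs
  windows <- contigs$windows
  seqA <- paths$pair$A$seq
  n_pass <- 0L
  for (i in seq_len(nrow(sites))) {
    w <- windows[windows$site_id == sites$site_id[i], ]
    win <- as.character(Biostrings::subseq(seqA[[w$seq_id]], w$start, w$end))
    v <- validate_minicontig(contigs$contigs[[sites$site_id[i]]], win,
                             sites$pos[i] - w$start + 1L,
                             sites$ref[i], sites$alt[i], sites$type[i])
    n_pass <- n_pass + v$pass
  }
  truth_geno <- truth_sites$genotype[match(sites$site_id,
                                           truth_sites$site_id)]
  list(
    n_sites = nrow(sites),
    calls = as.list(table(tab$call)),
    decisions = as.list(table(tab$decision)),
    genotype_concordance = mean(tab$call == truth_geno),
    minicontig_pass_rate = n_pass / nrow(sites)
  )
}

#' @rdname run_pipeline
#' @export
stage_variant_transition <- function(paths, config, outdir) {
  p <- function(...) file.path(paths$dir, ...)
  sites <- read_sites(p("candidate_sites.vcf"))
  blocks <- read_paf(p("blocks.paf"))
  roles <- utils::read.table(p("roles.tsv"), header = TRUE,
                             stringsAsFactors = FALSE)
  rolesB <- roles[roles$assembly == "B", c("seq_id", "role")]
  pa <- read_placements(p("reads_vs_A.sam"))
  pb <- read_placements(p("reads_vs_B_primary.sam"))

  status_a <- site_coverage(pa, sites, min_mapq = config$params$min_mapq,
                            seqlens = paths$a_lens)
  rm <- remap_sites(sites, blocks, rolesB)
  tp <- transition_placements(rm)
  tp <- tp[!is.na(tp$pos), , drop = FALSE]
  b_sites <- data.frame(seq_id = tp$seq_id, pos = tp$pos, site_id = tp$site_id,
                        stringsAsFactors = FALSE)
  status_b <- site_coverage(pb, b_sites, min_mapq = config$params$min_mapq)
  tr <- coverage_transition(status_a, rm, status_b,
                            merge_distance = config$params$merge_distance)
  tab <- data.frame(
    site_id = status_a$site_id,
    status_A = status_a$status,
    remapped = !rm$sites$unmapped,
    ambiguous = rm$sites$ambiguous,
    status_B = status_b$status[match(status_a$site_id, status_b$site_id)],
    stringsAsFactors = FALSE)
  write_tsv(tab, file.path(outdir, "coverage_transition.tsv"))
  write_tsv(rm$placements, file.path(outdir, "remap_placements.tsv"))
  list(
    n_sites = nrow(sites),
    n_ambiguous = sum(rm$sites$ambiguous),
    n_unmapped = sum(rm$sites$unmapped),
    n_gained = tr$n_gained, n_lost = tr$n_lost,
    n_gained_groups = tr$n_gained_groups, n_lost_groups = tr$n_lost_groups
  )
}
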