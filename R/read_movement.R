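#' Regions whose underlying component is unchanged between versions
#'
#' For every component accession.version placed in both AGPs with the same
#' orientation, intersects the two placements in component coordinates and
#' maps the intersection into both object coordinate systems. Orientation
#' mismatches are excluded; a component span placed more than once within
#' one assembly is an error (ambiguous provenance). These paired intervals
#' define the "unchanged sequence" to which read-movement analysis is
#' restricted.
#'
#' @param agpA,agpB `agp` data.frames of the two versions.
#' @return A `data.frame` of class `unchanged_regions`, sorted by A
#'   coordinates, with columns `component_id`, `comp_start`, `comp_end`
#'   (intersection in component coordinates), `seq_A`, `start_A`, `end_A`,
#'   `seq_B`, `start_B`, `end_B`, `orientation`.
#' @export
unchanged_regions <- function(agpA, agpB) {
  compA <- agpA[!agpA$component_type %in% c("N", "U"), ]
  compB <- agpB[!agpB$component_type %in% c("N", "U"), ]
  check_dup <- function(comp, label) {
    for (id in unique(comp$component_id[duplicated(comp$component_id)])) {
      rows <- comp[comp$component_id == id, ]
      ir <- IRanges::IRanges(rows$component_beg, rows$component_end)
      if (any(IRanges::coverage(ir) > 1L)) {
        stop("component ", id, " has overlapping placements in assembly ",
             label, " (ambiguous provenance)")
      }
    }
  }
  check_dup(compA, "A")
  check_dup(compB, "B")
  shared <- intersect(compA$component_id, compB$component_id)
  out <- list()
  for (id in shared) {
    ra <- compA[compA$component_id == id, ]
    rb <- compB[compB$component_id == id, ]
    for (i in seq_len(nrow(ra))) {
      for (j in seq_len(nrow(rb))) {
        if (ra$orientation[i] != rb$orientation[j]) next
        cs <- max(ra$component_beg[i], rb$component_beg[j])
        ce <- min(ra$component_end[i], rb$component_end[j])
        if (cs > ce) next
        proj <- function(r, cs, ce) {
          if (r$orientation == "+") {
            c(r$object_beg + (cs - r$component_beg),
              r$object_beg + (ce - r$component_beg))
          } else {
            c(r$object_beg + (r$component_end - ce),
              r$object_beg + (r$component_end - cs))
          }
        }
        pa <- proj(ra[i, ], cs, ce)
        pb <- proj(rb[j, ], cs, ce)
        out[[length(out) + 1L]] <- data.frame(
          component_id = id, comp_start = cs, comp_end = ce,
          seq_A = ra$object[i], start_A = pa[1L], end_A = pa[2L],
          seq_B = rb$object[j], start_B = pb[1L], end_B = pb[2L],
          orientation = ra$orientation[i], stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(component_id = character(), comp_start = integer(),
               comp_end = integer(), seq_A = character(), start_A = integer(),
               end_A = integer(), seq_B = character(), start_B = integer(),
               end_B = integer(), orientation = character(),
               stringsAsFactors = FALSE)
  res <- res[order(res$seq_A, res$start_A), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("unchanged_regions", "data.frame")
  res
}

#' Select uniquely mapped read pairs inside unchanged regions
#'
#' A pair is eligible when both mates are mapped, primary, have
#' MAPQ >= `min_mapq` (unique mapping is operationalized as primary +
#' MAPQ threshold), and both aligned spans lie fully inside unchanged
#' regions on A.
#'
#' @param placements_a `read_placements` versus assembly A.
#' @param regions an `unchanged_regions` data.frame.
#' @param min_mapq MAPQ threshold (default 20).
#' @param primary_only restrict to primary placements (default TRUE).
#' @return Character vector of eligible read ids.
#' @export
select_unique_pairs <- function(placements_a, regions, min_mapq = 20L,
                                primary_only = TRUE) {
  p <- placements_a
  if (primary_only) p <- p[p$primary | !p$mapped, , drop = FALSE]
  # containment is evaluated against the union of unchanged intervals: a
  # span crossing two adjacent unchanged components is still unchanged
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    regions$seq_A, IRanges::IRanges(regions$start_A, regions$end_A)))
  ok <- p$mapped & p$mapq >= min_mapq &
    span_within(p$seq_id, p$pos, p$end, gr, p$mapped)
  by_pair <- split(ok, p$read_id)
  n_mates <- vapply(by_pair, length, 1L)
  if (any(n_mates > 2L)) {
    stop("read(s) with more than two primary records: ",
         paste(utils::head(names(by_pair)[n_mates > 2L]), collapse = ", "))
  }
  sort(names(by_pair)[vapply(by_pair, function(x) length(x) == 2L && all(x),
                             TRUE)])
}

#' Detect read pairs that move between assembly versions
#'
#' A pair moves when at least one mate's primary B placement midpoint lies
#' on a component accession.version different from the component under its
#' A placement midpoint (a version bump counts as a change). Reports the
#' moved fraction over eligible pairs and the fraction of moved pairs that
#' are also uniquely mapped on B (both mates mapped, primary,
#' MAPQ >= `min_mapq`).
#'
#' @param eligible character vector of eligible read ids from
#'   [select_unique_pairs()].
#' @param placements_a,placements_b `read_placements` versus A and B.
#' @param agpA,agpB the two component maps.
#' @param min_mapq MAPQ threshold for B-side uniqueness.
#' @return A list: `records` (data.frame `read_id`, `mate`, `seq_A`,
#'   `pos_A`, `end_A`, `component_A`, `seq_B`, `pos_B`, `end_B`,
#'   `component_B`, `read_moved` — one row per mate of each moved pair
#'   with a mapped B placement), `moved_ids`, `n_eligible`, `n_moved`,
#'   `fraction_moved`, `fraction_moved_also_unique_in_B`.
#' @export
detect_moved_pairs <- function(eligible, placements_a, placements_b,
                               agpA, agpB, min_mapq = 20L) {
  pa <- placements_a[placements_a$read_id %in% eligible &
                       (placements_a$primary | !placements_a$mapped), ,
                     drop = FALSE]
  pb <- placements_b[placements_b$read_id %in% eligible &
                       (placements_b$primary | !placements_b$mapped), ,
                     drop = FALSE]
  key_a <- paste0(pa$read_id, "/", pa$mate)
  key_b <- paste0(pb$read_id, "/", pb$mate)
  missing <- setdiff(key_a, key_b)
  if (length(missing) > 0L) {
    stop("no B placement for eligible read(s): ",
         paste(utils::head(missing), collapse = ", "))
  }
  pb <- pb[match(key_a, key_b), , drop = FALSE]
  mid_a <- (pa$pos + pa$end) %/% 2L
  mid_b <- (pb$pos + pb$end) %/% 2L
  comp_a <- component_at(agpA, pa$seq_id, mid_a)
  comp_b <- rep(NA_character_, nrow(pb))
  bm <- pb$mapped
  comp_b[bm] <- component_at(agpB, pb$seq_id[bm], mid_b[bm])
  read_moved <- bm & !is.na(comp_a) & !is.na(comp_b) & comp_a != comp_b
  moved_ids <- sort(unique(pa$read_id[read_moved]))
  n_eligible <- length(eligible)
  n_moved <- length(moved_ids)

  ok_b <- pb$mapped & pb$mapq >= min_mapq
  by_b <- split(ok_b, pb$read_id)
  uniq_b <- names(by_b)[vapply(by_b, function(x) length(x) == 2L && all(x),
                               TRUE)]
  n_also <- length(intersect(moved_ids, uniq_b))

  keep <- pa$read_id %in% moved_ids & pb$mapped
  records <- data.frame(
    read_id = pa$read_id[keep], mate = pa$mate[keep],
    seq_A = pa$seq_id[keep], pos_A = pa$pos[keep], end_A = pa$end[keep],
    component_A = comp_a[keep],
    seq_B = pb$seq_id[keep], pos_B = pb$pos[keep], end_B = pb$end[keep],
    component_B = comp_b[keep],
    read_moved = read_moved[keep],
    stringsAsFactors = FALSE)
  list(records = records, moved_ids = moved_ids,
       n_eligible = n_eligible, n_moved = n_moved,
       fraction_moved = if (n_eligible > 0L) n_moved / n_eligible else NA_real_,
       fraction_moved_also_unique_in_B =
         if (n_moved > 0L) n_also / n_moved else NA_real_)
}

#' Classify moved reads into the six-way destination taxonomy
#'
#' Each read of a moved pair with a mapped B placement gets exactly one
#' category from its destination: `ON`/`ONCEN` — noncentromeric or
#' centromeric sequence on the same chromosome; `OFF`/`OFFCEN` — on a
#' different chromosome; `TOSCAF` — a noncentromeric unlocalized or
#' unplaced scaffold; `UNCEN` — an unplaced scaffold carrying
#' centromere-associated annotation. "Centromeric" means any overlap of
#' the aligned span with a centromere interval; a scaffold is
#' centromere-associated when it carries any centromere annotation.
#'
#' @param records the `records` data.frame from [detect_moved_pairs()].
#' @param roles data.frame `seq_id`, `role` (role in
#'   `chromosome`, `unlocalized`, `unplaced`, `alternate`) covering every
#'   destination sequence.
#' @param centromeres [GenomicRanges::GRanges] of centromere intervals on B.
#' @return `records` with a `category` column appended.
#' @export
classify_movement <- function(records, roles, centromeres) {
  if (nrow(records) == 0L) {
    records$category <- character(0L)
    return(records)
  }
  role <- roles$role[match(records$seq_B, roles$seq_id)]
  if (anyNA(role)) {
    stop("no role for destination sequence(s): ",
         paste(unique(records$seq_B[is.na(role)]), collapse = ", "))
  }
  cen_objs <- unique(as.character(GenomicRanges::seqnames(centromeres)))
  over_cen <- span_overlaps_any(records$seq_B, records$pos_B, records$end_B,
                                centromeres)
  scaf <- role %in% c("unlocalized", "unplaced")
  records$category <- ifelse(
    scaf,
    ifelse(records$seq_B %in% cen_objs, "UNCEN", "TOSCAF"),
    ifelse(records$seq_B == records$seq_A,
           ifelse(over_cen, "ONCEN", "ON"),
           ifelse(over_cen, "OFFCEN", "OFF")))
  records
}

#' Unmapped-read rescue statistics across assembly versions
#'
#' Read-level (not pair-level) fractions: of the reads unmapped on A, how
#' many map to the B primary units; of the reads still unmapped on the B
#' primary units, how many map to the full B assembly (alternate loci
#' included); and how many rescued reads land in annotated new-sequence
#' intervals. Zero denominators yield `NA` (undefined), never zero.
#'
#' @param placements_a,placements_b_primary,placements_b_full
#'   `read_placements` for the same read universe.
#' @param new_sequence [GenomicRanges::GRanges] of new-sequence intervals
#'   on B.
#' @return A list: `n_a_unmapped`, `frac_a_unmapped_mapped_b_primary`,
#'   `frac_rescued_in_new_sequence`, `n_bp_unmapped`,
#'   `frac_bp_unmapped_mapped_b_full`.
#' @export
rescue_stats <- function(placements_a, placements_b_primary,
                         placements_b_full, new_sequence = GenomicRanges::GRanges()) {
  key <- function(p) sort(paste0(p$read_id, "/", p$mate))
  ka <- key(placements_a)
  if (!identical(ka, key(placements_b_primary)) ||
      !identical(ka, key(placements_b_full))) {
    stop("the three placement sets do not cover the same reads")
  }
  align <- function(p) p[order(paste0(p$read_id, "/", p$mate)), , drop = FALSE]
  A <- align(placements_a)
  Bp <- align(placements_b_primary)
  Bf <- align(placements_b_full)
  a_un <- !A$mapped
  n_a_un <- sum(a_un)
  resc <- a_un & Bp$mapped
  frac1 <- if (n_a_un > 0L) sum(resc) / n_a_un else NA_real_
  in_new <- span_overlaps_any(Bp$seq_id[resc], Bp$pos[resc], Bp$end[resc],
                              new_sequence)
  frac_new <- if (sum(resc) > 0L) mean(in_new) else NA_real_
  bp_un <- !Bp$mapped
  n_bp_un <- sum(bp_un)
  frac2 <- if (n_bp_un > 0L) sum(bp_un & Bf$mapped) / n_bp_un else NA_real_
  list(n_a_unmapped = n_a_un,
       frac_a_unmapped_mapped_b_primary = frac1,
       frac_rescued_in_new_sequence = frac_new,
       n_bp_unmapped = n_bp_un,
       frac_bp_unmapped_mapped_b_full = frac2)
}

#' Source/destination component pairings of moved reads
#'
#' Exact contingency counts of (A component, B component) over moved reads
#' with a mapped B placement, sorted by decreasing count with
#' lexicographic tie-break. Counts sum to the number of such reads.
#'
#' @param records the (classified or not) moved-read records.
#' @return data.frame `component_A`, `component_B`, `n`.
#' @export
component_pairings <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(component_A = character(), component_B = character(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  tab <- stats::aggregate(list(n = rep(1L, nrow(records))),
                          by = list(component_A = records$component_A,
                                    component_B = records$component_B),
                          FUN = sum)
  tab <- tab[order(-tab$n, tab$component_A, tab$component_B), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
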