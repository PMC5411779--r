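# Truth-level movement and rescue statistics, computed from the
# simulator's internal bookkeeping (component tables and truth
# placements), independently of the AGP/SAM analysis path.

# component accession.version under positions, from the simulator's
# internal per-object component tables
truth_comp_b <- function(cmaps, seq_id, pos) {
  out <- rep(NA_character_, length(seq_id))
  for (nm in unique(seq_id[!is.na(seq_id)])) {
    rows <- cmaps$bmap[[nm]]
    idx <- which(seq_id == nm)
    j <- findInterval(pos[idx], rows$start)
    ok <- j >= 1L & pos[idx] <= rows$end[pmax(j, 1L)]
    out[idx[ok]] <- paste0(rows$acc[j[ok]], ".", rows$ver[j[ok]])
  }
  out
}

truth_comp_a <- function(cmaps, seq_id, pos) {
  agp <- cmaps$agpA
  comp <- agp[!agp$component_type %in% c("N", "U"), ]
  out <- rep(NA_character_, length(seq_id))
  for (nm in unique(seq_id[!is.na(seq_id)])) {
    rows <- comp[comp$object == nm, ]
    rows <- rows[order(rows$object_beg), ]
    idx <- which(seq_id == nm)
    j <- findInterval(pos[idx], rows$object_beg)
    ok <- j >= 1L & pos[idx] <= rows$object_end[pmax(j, 1L)]
    out[idx[ok]] <- rows$component_id[j[ok]]
  }
  out
}

#' Truth movement, category and rescue expectations for simulated reads
#'
#' Recomputes, from the simulator's internal truth bundle only, the
#' quantities that the read-movement analysis derives from AGP/SAM inputs:
#' the eligible read-pair set (both mates truth-mapped on A, primary,
#' MAPQ >= `min_mapq`, spans inside truth unchanged regions), the moved
#' subset (a mate's B placement midpoint falls on a different component
#' accession.version than its A placement midpoint), per-read destination
#' categories, and the read-level rescue fractions.
#'
#' @param pair an `asm_pair`.
#' @param reads a `sim_reads` from [simulate_reads()].
#' @param min_mapq uniqueness threshold (default 20).
#' @return A list: `n_eligible`, `n_moved`, `fraction_moved`,
#'   `fraction_moved_also_unique_in_B`, `categories` (data.frame `read_id`,
#'   `mate`, `category`), and `rescue` (list `n_a_unmapped`,
#'   `frac_a_unmapped_mapped_b_primary`, `frac_rescued_in_new_sequence`,
#'   `n_bp_unmapped`, `frac_bp_unmapped_mapped_b_full`).
#' @export
truth_read_stats <- function(pair, reads, min_mapq = 20L) {
  A <- reads$truth$A
  Bp <- reads$truth$B_primary
  Bf <- reads$truth$B_full
  cm <- pair$truth$cmaps

  ugr <- GenomicRanges::GRanges(pair$truth$unchanged$aobj,
                                IRanges::IRanges(pair$truth$unchanged$astart,
                                                 pair$truth$unchanged$aend))
  ok_a <- A$mapped & A$primary & A$mapq >= min_mapq &
    span_within(A$seq_id, A$pos, A$end, ugr, A$mapped)
  by_pair <- split(ok_a, A$read_id)
  eligible_ids <- names(by_pair)[vapply(by_pair, function(x) {
    length(x) == 2L && all(x)
  }, TRUE)]
  n_eligible <- length(eligible_ids)

  el <- A$read_id %in% eligible_ids
  midA <- (A$pos + A$end) %/% 2L
  midB <- (Bp$pos + Bp$end) %/% 2L
  compA <- rep(NA_character_, nrow(A))
  compB <- rep(NA_character_, nrow(A))
  compA[el] <- truth_comp_a(cm, A$seq_id[el], midA[el])
  bel <- el & Bp$mapped
  compB[bel] <- truth_comp_b(cm, Bp$seq_id[bel], midB[bel])
  read_moved <- el & Bp$mapped & !is.na(compA) & !is.na(compB) & compA != compB
  moved_ids <- unique(A$read_id[read_moved])
  n_moved <- length(moved_ids)

  # categories for reads of moved pairs with a mapped B placement
  mv <- which(A$read_id %in% moved_ids & Bp$mapped)
  cat_v <- character(length(mv))
  if (length(mv) > 0L) {
    roleB <- pair$truth$roles[pair$truth$roles$assembly == "B", ]
    role <- roleB$role[match(Bp$seq_id[mv], roleB$seq_id)]
    cen <- pair$truth$cen_B
    cen_objs <- unique(as.character(GenomicRanges::seqnames(cen)))
    over_cen <- span_overlaps_any(Bp$seq_id[mv], Bp$pos[mv], Bp$end[mv], cen)
    same_chr <- Bp$seq_id[mv] == A$seq_id[mv]
    cat_v <- ifelse(role %in% c("unplaced", "unlocalized"),
                    ifelse(Bp$seq_id[mv] %in% cen_objs, "UNCEN", "TOSCAF"),
                    ifelse(same_chr,
                           ifelse(over_cen, "ONCEN", "ON"),
                           ifelse(over_cen, "OFFCEN", "OFF")))
  }
  categories <- data.frame(read_id = A$read_id[mv], mate = A$mate[mv],
                           category = cat_v, stringsAsFactors = FALSE)

  # "also uniquely mapped on B": both mates mapped, primary, MAPQ >= cutoff
  ok_b <- Bp$mapped & Bp$primary & Bp$mapq >= min_mapq
  by_pair_b <- split(ok_b, Bp$read_id)
  uniq_b_ids <- names(by_pair_b)[vapply(by_pair_b, function(x) {
    length(x) == 2L && all(x)
  }, TRUE)]
  n_moved_uniq_b <- length(intersect(moved_ids, uniq_b_ids))

  # read-level rescue
  a_un <- !A$mapped
  n_a_un <- sum(a_un)
  resc <- a_un & Bp$mapped
  frac1 <- if (n_a_un > 0L) sum(resc) / n_a_un else NA_real_
  in_new <- span_overlaps_any(Bp$seq_id[resc], Bp$pos[resc], Bp$end[resc],
                              pair$truth$newseq_B)
  frac_new <- if (sum(resc) > 0L) mean(in_new) else NA_real_
  bp_un <- !Bp$mapped
  n_bp_un <- sum(bp_un)
  frac2 <- if (n_bp_un > 0L) sum(bp_un & Bf$mapped) / n_bp_un else NA_real_

  list(
    n_eligible = n_eligible,
    n_moved = n_moved,
    fraction_moved = if (n_eligible > 0L) n_moved / n_eligible else NA_real_,
    fraction_moved_also_unique_in_B =
      if (n_moved > 0L) n_moved_uniq_b / n_moved else NA_real_,
    categories = categories,
    rescue = list(
      n_a_unmapped = n_a_un,
      frac_a_unmapped_mapped_b_primary = frac1,
      frac_rescued_in_new_sequence = frac_new,
      n_bp_unmapped = n_bp_un,
      frac_bp_unmapped_mapped_b_full = frac2
    )
  )
}

span_overlaps_any <- function(seq_id, start, end, gr) {
  if (length(seq_id) == 0L) return(logical(0L))
  if (length(gr) == 0L) return(rep(FALSE, length(seq_id)))
  q <- GenomicRanges::GRanges(seq_id, IRanges::IRanges(start, end))
  suppressWarnings(IRanges::overlapsAny(q, gr))
}
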