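#' MAPQ-filtered coverage status at variant sites
#'
#' Counts, per site, the primary mapped alignments with
#' MAPQ >= `min_mapq` whose span overlaps the site position, and reports
#' each site as `COVERED` (depth >= 1) or `ZERO`.
#'
#' @param alignments path to SAM/BAM or a `read_placements` data.frame.
#' @param sites a `variant_sites` data.frame.
#' @param min_mapq MAPQ threshold (default 20).
#' @param seqlens optional named sequence lengths; sites beyond a
#'   sequence end raise an error.
#' @return data.frame `site_id`, `seq_id`, `pos`, `depth`, `status`.
#' @export
site_coverage <- function(alignments, sites, min_mapq = 20L, seqlens = NULL) {
  if (is.character(alignments)) alignments <- read_placements(alignments)
  if (!is.null(seqlens)) {
    over <- sites$pos > seqlens[sites$seq_id]
    if (any(over)) {
      stop("site(s) beyond contig end: ",
           paste(sites$site_id[over], collapse = ", "))
    }
  }
  p <- alignments[alignments$mapped & alignments$primary &
                    alignments$mapq >= min_mapq, , drop = FALSE]
  sgr <- GenomicRanges::GRanges(sites$seq_id,
                                IRanges::IRanges(sites$pos, sites$pos))
  depth <- if (nrow(p) == 0L) rep(0L, nrow(sites)) else {
    rgr <- GenomicRanges::GRanges(p$seq_id, IRanges::IRanges(p$pos, p$end))
    suppressWarnings(GenomicRanges::countOverlaps(sgr, rgr))
  }
  data.frame(site_id = sites$site_id, seq_id = sites$seq_id, pos = sites$pos,
             depth = as.integer(depth),
             status = ifelse(depth >= 1L, "COVERED", "ZERO"),
             stringsAsFactors = FALSE)
}

#' Remap variant sites through alignment blocks
#'
#' Projects each site position (indels by their anchor base) through every
#' alignment block containing it, deduplicates placements at exact
#' (sequence, position, strand), and flags a site ambiguous when two or
#' more distinct placements fall on primary-assembly sequences
#' (alternate-locus placements are reported but excluded from the
#' ambiguity count). Unprojectable sites are reported unmapped, not
#' errored.
#'
#' @param sites a `variant_sites` data.frame on the blocks' query assembly.
#' @param blocks an `alignment_blocks` data.frame oriented source to
#'   target.
#' @param roles data.frame `seq_id`, `role`; target sequences with role
#'   `"alternate"` are excluded from the ambiguity count.
#' @return A list of class `remap_results`: `placements` (data.frame
#'   `site_id`, `seq_id`, `pos`, `strand`, `pass_class`, `primary_unit`)
#'   and `sites` (data.frame `site_id`, `n_placements`,
#'   `n_primary_placements`, `ambiguous`, `unmapped`).
#' @export
remap_sites <- function(sites, blocks, roles = NULL) {
  rows <- list()
  for (b in seq_len(nrow(blocks))) {
    blk <- blocks[b, ]
    idx <- which(sites$seq_id == blk$qname & sites$pos >= blk$qstart &
                   sites$pos <= blk$qend)
    if (length(idx) == 0L) next
    tpos <- project_coordinate(blk, sites$pos[idx])
    got <- !is.na(tpos)
    if (!any(got)) next
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = sites$site_id[idx[got]], seq_id = blk$tname,
      pos = tpos[got], strand = blk$strand,
      pass_class = blk$pass_class, stringsAsFactors = FALSE)
  }
  pl <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(site_id = character(), seq_id = character(), pos = integer(),
               strand = character(), pass_class = character(),
               stringsAsFactors = FALSE)
  pl <- pl[!duplicated(pl[, c("site_id", "seq_id", "pos", "strand")]), ,
           drop = FALSE]
  pl$primary_unit <- if (is.null(roles)) {
    rep(TRUE, nrow(pl))
  } else {
    role <- roles$role[match(pl$seq_id, roles$seq_id)]
    is.na(role) | role != "alternate"
  }
  n_pl <- table(factor(pl$site_id, levels = sites$site_id))
  n_pr <- table(factor(pl$site_id[pl$primary_unit], levels = sites$site_id))
  res <- data.frame(
    site_id = sites$site_id,
    n_placements = as.integer(n_pl),
    n_primary_placements = as.integer(n_pr),
    ambiguous = as.integer(n_pr) >= 2L,
    unmapped = as.integer(n_pl) == 0L,
    stringsAsFactors = FALSE)
  structure(list(placements = pl, sites = res), class = "remap_results")
}

#' Preferred remap placement per site for coverage transitions
#'
#' The remapping service's primary placement of a site is its reciprocal
#' best-hit placement when one exists; nonreciprocal placements are used
#' only for sites with no reciprocal placement. A site with two or more
#' distinct placements at the preferred tier, or none at all, has no
#' usable transition placement (`NA` position).
#'
#' @param remaps a `remap_results` from [remap_sites()].
#' @return data.frame `site_id`, `seq_id`, `pos` (`NA` when unusable).
#' @export
transition_placements <- function(remaps) {
  pl <- remaps$placements[remaps$placements$primary_unit, , drop = FALSE]
  ids <- remaps$sites$site_id
  seq_id <- rep(NA_character_, length(ids))
  pos <- rep(NA_integer_, length(ids))
  for (k in seq_along(ids)) {
    sub <- pl[pl$site_id == ids[k], , drop = FALSE]
    pref <- sub[sub$pass_class == "RECIPROCAL", , drop = FALSE]
    if (nrow(pref) == 0L) pref <- sub
    pref <- pref[!duplicated(pref[, c("seq_id", "pos")]), , drop = FALSE]
    if (nrow(pref) == 1L) {
      seq_id[k] <- pref$seq_id
      pos[k] <- pref$pos
    }
  }
  data.frame(site_id = ids, seq_id = seq_id, pos = pos,
             stringsAsFactors = FALSE)
}

#' Coverage transitions between assembly versions
#'
#' Combines per-site coverage on A, the remapping of each site to B, and
#' coverage at the remapped B positions into gained/lost site lists:
#' `gained` sites have zero MAPQ-filtered coverage on A, remap uniquely,
#' and are covered on B; `lost` sites are covered on A and zero on B.
#' Sites on the same sequence within `merge_distance` are merged into
#' region groups by single linkage; both site counts and group counts are
#' reported. The gained and lost lists are disjoint by construction.
#'
#' @param status_a coverage of the sites on A ([site_coverage()]).
#' @param remaps a `remap_results` for the same sites, A to B.
#' @param status_b coverage evaluated at the remapped B positions; its
#'   `site_id` column must cover every uniquely remapped site.
#' @param merge_distance grouping distance in bases (default 100,000).
#' @return A list of class `transition_report`: `gained`, `lost`
#'   (data.frames `site_id`, `seq_id`, `pos`, `group`), `n_gained`,
#'   `n_lost`, `n_gained_groups`, `n_lost_groups`.
#' @export
coverage_transition <- function(status_a, remaps, status_b,
                                merge_distance = 100000L) {
  tp <- transition_placements(remaps)
  usable <- tp$site_id[!is.na(tp$pos)]
  need <- intersect(status_a$site_id, usable)
  missing <- setdiff(need, status_b$site_id)
  if (length(missing) > 0L) {
    stop("no B coverage status for remapped site(s): ",
         paste(utils::head(missing), collapse = ", "))
  }
  a <- status_a[match(need, status_a$site_id), ]
  b <- status_b[match(need, status_b$site_id), ]
  gained_ids <- need[a$status == "ZERO" & b$status == "COVERED"]
  lost_ids <- need[a$status == "COVERED" & b$status == "ZERO"]
  group_sites <- function(ids) {
    sub <- status_a[match(ids, status_a$site_id),
                    c("site_id", "seq_id", "pos")]
    sub <- sub[order(sub$seq_id, sub$pos), , drop = FALSE]
    if (nrow(sub) == 0L) {
      sub$group <- integer(0L)
      return(sub)
    }
    new_grp <- c(TRUE, diff(sub$pos) > merge_distance |
                   sub$seq_id[-1L] != sub$seq_id[-nrow(sub)])
    sub$group <- cumsum(new_grp)
    rownames(sub) <- NULL
    sub
  }
  gained <- group_sites(gained_ids)
  lost <- group_sites(lost_ids)
  structure(list(
    gained = gained, lost = lost,
    n_gained = nrow(gained), n_lost = nrow(lost),
    n_gained_groups = if (nrow(gained) > 0L) max(gained$group) else 0L,
    n_lost_groups = if (nrow(lost) > 0L) max(lost$group) else 0L
  ), class = "transition_report")
}
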