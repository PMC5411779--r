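# AGP component maps for the simulated pair.
#
# Both versions share a baseline tile grid of components per chromosome;
# curation events replace spans with new accessions (gap closures,
# centromere models), bump accession versions (retiling, base updates), or
# add version-specific components (false-duplication copies, scaffolds,
# alternate loci). A carries version 1 everywhere; re-finished components
# appear in B with a bumped version.

tile_grid <- function(config, ci, L) {
  starts <- seq(1L, L, by = config$component_length)
  ends <- pmin(starts + config$component_length - 1L, L)
  data.frame(start = starts, end = ends,
             acc = sprintf("SIM%02dT%03d", ci, seq_along(starts)),
             stringsAsFactors = FALSE)
}

# split rows of a per-chromosome component table around [s, e] and insert
# a single new-accession row covering [s, e]
split_rows <- function(rows, s, e, newacc) {
  out <- list()
  for (j in seq_len(nrow(rows))) {
    r <- rows[j, ]
    if (r$end < s || r$start > e) { out[[length(out) + 1L]] <- r; next }
    if (r$start < s) {
      left <- r; left$end <- s - 1L
      left$cend <- left$cbeg + (left$end - left$start)
      out[[length(out) + 1L]] <- left
    }
    if (r$end > e) {
      right <- r
      right$cbeg <- r$cbeg + (e + 1L - r$start)
      right$start <- e + 1L
      right$cend <- right$cbeg + (right$end - right$start)
      out[[length(out) + 1L]] <- right
    }
  }
  ins <- data.frame(start = s, end = e, acc = newacc, ver = 1L,
                    cbeg = 1L, cend = e - s + 1L, stringsAsFactors = FALSE)
  res <- rbind(do.call(rbind, out), ins)
  res[order(res$start), , drop = FALSE]
}

component_maps <- function(config, ev, chrom_names, donor, b_lens, pieces) {
  n_new <- 0L
  bmap <- list()      # per B chromosome: start,end,acc,ver,cbeg,cend
  tiles <- list()
  bumped <- list()    # per chromosome: bumped tile accessions
  for (ci in seq_along(chrom_names)) {
    nm <- chrom_names[ci]
    tg <- tile_grid(config, ci, config$chromosome_length)
    tiles[[nm]] <- tg
    rows <- data.frame(start = tg$start, end = tg$end, acc = tg$acc,
                       ver = 1L, cbeg = 1L, cend = tg$end - tg$start + 1L,
                       stringsAsFactors = FALSE)
    for (i in which(ev$chrom == nm &
                      ev$kind %in% c("GAP_CLOSURE", "CENTROMERE_MODEL"))) {
      n_new <- n_new + 1L
      rows <- split_rows(rows, ev$start[i], ev$end[i],
                         sprintf("SIMN%04d", n_new))
    }
    bump_acc <- character()
    for (i in which(ev$chrom == nm & ev$kind %in% c("RETILE", "BASE_ERROR"))) {
      hit <- tg$acc[tg$end >= ev$start[i] & tg$start <= ev$end[i]]
      bump_acc <- union(bump_acc, hit)
    }
    rows$ver[rows$acc %in% bump_acc] <- 2L
    bumped[[nm]] <- bump_acc
    bmap[[nm]] <- rows
  }

  # B AGP: chromosomes + scaffolds + alternate locus, no gap rows
  agp_rows <- list()
  for (nm in chrom_names) {
    r <- bmap[[nm]]
    agp_rows[[nm]] <- data.frame(
      object = nm, object_beg = r$start, object_end = r$end,
      part_number = seq_len(nrow(r)), component_type = "W",
      component_id = paste0(r$acc, ".", r$ver),
      component_beg = r$cbeg, component_end = r$cend, orientation = "+",
      gap_length = NA_integer_, gap_type = NA_character_,
      linkage = NA_character_, stringsAsFactors = FALSE)
  }
  n_scaf <- 0L
  scaf_names <- names(donor$scaf_seqs)
  for (scaf in scaf_names) {
    n_scaf <- n_scaf + 1L
    len <- nchar(donor$scaf_seqs[[scaf]])
    acc <- sprintf("SIMS%02d", n_scaf)
    agp_rows[[scaf]] <- data.frame(
      object = scaf, object_beg = 1L, object_end = len, part_number = 1L,
      component_type = "W", component_id = paste0(acc, ".1"),
      component_beg = 1L, component_end = len, orientation = "+",
      gap_length = NA_integer_, gap_type = NA_character_,
      linkage = NA_character_, stringsAsFactors = FALSE)
    bmap[[scaf]] <- data.frame(start = 1L, end = len, acc = acc, ver = 1L,
                               cbeg = 1L, cend = len)
  }
  if (!is.null(donor$alt_name)) {
    len <- nchar(donor$alt_seq)
    agp_rows[[donor$alt_name]] <- data.frame(
      object = donor$alt_name, object_beg = 1L, object_end = len,
      part_number = 1L, component_type = "W", component_id = "SIMA01.1",
      component_beg = 1L, component_end = len, orientation = "+",
      gap_length = NA_integer_, gap_type = NA_character_,
      linkage = NA_character_, stringsAsFactors = FALSE)
    bmap[[donor$alt_name]] <- data.frame(start = 1L, end = len, acc = "SIMA01",
                                         ver = 1L, cbeg = 1L, cend = len)
  }
  agpB <- do.call(rbind, unname(agp_rows))
  rownames(agpB) <- NULL
  class(agpB) <- c("agp", "data.frame")

  # A AGP from the piece lists; A components are always version 1
  amap <- list()
  a_rows <- list()
  for (ci in seq_along(chrom_names)) {
    nm <- chrom_names[ci]
    tg <- tiles[[nm]]
    df <- pieces[[nm]]
    rows <- list()
    for (j in seq_len(nrow(df))) {
      p <- df[j, ]
      if (p$type == "gap") {
        rows[[length(rows) + 1L]] <- data.frame(
          object = nm, object_beg = p$astart, object_end = p$aend,
          part_number = NA_integer_, component_type = "N",
          component_id = NA_character_, component_beg = NA_integer_,
          component_end = NA_integer_, orientation = NA_character_,
          gap_length = p$aend - p$astart + 1L, gap_type = "contig",
          linkage = "no", stringsAsFactors = FALSE)
      } else if (p$type == "dup") {
        rows[[length(rows) + 1L]] <- data.frame(
          object = nm, object_beg = p$astart, object_end = p$aend,
          part_number = NA_integer_, component_type = "W",
          component_id = sprintf("SIMF%04d.1", p$event_id),
          component_beg = 1L, component_end = p$aend - p$astart + 1L,
          orientation = "+", gap_length = NA_integer_,
          gap_type = NA_character_, linkage = NA_character_,
          stringsAsFactors = FALSE)
      } else {
        hit <- which(tg$end >= p$dstart & tg$start <= p$dend)
        os <- pmax(tg$start[hit], p$dstart)
        oe <- pmin(tg$end[hit], p$dend)
        if (p$strand == "+") {
          ab <- p$astart + (os - p$dstart)
          ae <- p$astart + (oe - p$dstart)
        } else {
          ab <- p$astart + (p$dend - oe)
          ae <- p$astart + (p$dend - os)
          ord <- order(ab)
          hit <- hit[ord]; os <- os[ord]; oe <- oe[ord]
          ab <- sort(ab); ae <- sort(ae)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          object = nm, object_beg = ab, object_end = ae,
          part_number = NA_integer_, component_type = "W",
          component_id = paste0(tg$acc[hit], ".1"),
          component_beg = os - tg$start[hit] + 1L,
          component_end = oe - tg$start[hit] + 1L,
          orientation = p$strand, gap_length = NA_integer_,
          gap_type = NA_character_, linkage = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    chrom_rows <- do.call(rbind, rows)
    chrom_rows <- chrom_rows[order(chrom_rows$object_beg), , drop = FALSE]
    chrom_rows$part_number <- seq_len(nrow(chrom_rows))
    a_rows[[nm]] <- chrom_rows
    amap[[nm]] <- chrom_rows
  }
  agpA <- do.call(rbind, unname(a_rows))
  rownames(agpA) <- NULL
  class(agpA) <- c("agp", "data.frame")

  # component library attribution (source clone library vs other)
  all_acc <- unique(c(unlist(lapply(bmap, function(r) r$acc)),
                      sub("\\.\\d+$", "", agpA$component_id[!is.na(agpA$component_id)])))
  all_acc <- sort(all_acc)
  lib <- ifelse(stats::runif(length(all_acc)) < config$source_library_fraction,
                "source", "other")
  names(lib) <- all_acc

  list(agpA = agpA, agpB = agpB, bmap = bmap, tiles = tiles,
       bumped = bumped, library = lib)
}
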