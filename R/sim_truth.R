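# Truth bundle for the simulated pair: alignment blocks, per-base labels,
# unchanged regions, annotations, ambiguous-placement regions, and the
# B-to-A read projection map.

# map a donor interval lying inside a single '+' run piece to A coordinates
donor_to_a <- function(pieces, chrom, s, e) {
  df <- pieces[[chrom]]
  j <- which(df$type == "run" & df$strand == "+" & df$dstart <= s & df$dend >= e)
  if (length(j) != 1L) {
    stop("donor interval ", chrom, ":", s, "-", e,
         " is not contained in one forward run piece")
  }
  c(df$astart[j] + (s - df$dstart[j]), df$astart[j] + (e - df$dstart[j]))
}

build_truth <- function(config, ev, donor, pieces, cmaps,
                        a_lens, b_lens, chrom_names, sat) {
  f <- SIM_SCAF_FLANK

  # --- truth alignment blocks (A as query) -------------------------------
  qn <- character(); qs <- integer(); qe <- integer()
  tn <- character(); ts <- integer(); te <- integer()
  st <- character(); pc <- character()
  add <- function(qname, qstart, qend, tname, tstart, tend, strand, pass) {
    qn <<- c(qn, qname); qs <<- c(qs, qstart); qe <<- c(qe, qend)
    tn <<- c(tn, tname); ts <<- c(ts, tstart); te <<- c(te, tend)
    st <<- c(st, strand); pc <<- c(pc, pass)
  }
  for (nm in chrom_names) {
    df <- pieces[[nm]]
    for (j in seq_len(nrow(df))) {
      p <- df[j, ]
      if (p$type == "run") {
        add(nm, p$astart, p$aend, nm, p$dstart, p$dend, p$strand, "RECIPROCAL")
      } else if (p$type == "dup") {
        add(nm, p$astart, p$aend, nm, ev$start[p$event_id], ev$end[p$event_id],
            "+", "NONRECIPROCAL")
      }
    }
  }
  for (i in which(ev$kind == "COLLAPSE")) {
    a <- donor_to_a(pieces, ev$chrom[i], ev$start[i], ev$end[i])
    add(ev$chrom[i], a[1L], a[2L], ev$obj2[i], ev$start2[i], ev$end2[i],
        "+", "NONRECIPROCAL")
  }
  alt_i <- which(ev$kind == "ALT_LOCUS")
  for (i in alt_i) {
    fl <- ev$flank[i]; nov <- ev$novel_length[i]
    aL <- donor_to_a(pieces, ev$chrom[i], ev$start[i], ev$start[i] + fl - 1L)
    aR <- donor_to_a(pieces, ev$chrom[i], ev$start[i] + fl, ev$end[i])
    add(ev$chrom[i], aL[1L], aL[2L], donor$alt_name, 1L, fl, "+", "NONRECIPROCAL")
    add(ev$chrom[i], aR[1L], aR[2L], donor$alt_name, fl + nov + 1L,
        fl + nov + fl, "+", "NONRECIPROCAL")
  }
  blocks <- make_blocks(qn, qs, qe, tn, ts, te, st, pc,
                        qlen = unname(a_lens[qn]), tlen = unname(b_lens[tn]))

  # --- per-base truth labels --------------------------------------------
  overlay_track <- function(lens, default, overlays) {
    lvls <- names(lens)
    out <- list()
    for (nm in names(lens)) {
      base <- GenomicRanges::GRanges(factor(nm, levels = lvls),
                                     IRanges::IRanges(1L, lens[[nm]]))
      ov <- overlays[overlays$obj == nm, , drop = FALSE]
      if (nrow(ov) == 0L) {
        base$label <- default[[nm]]
        out[[nm]] <- base
        next
      }
      ogr <- GenomicRanges::GRanges(factor(rep(nm, nrow(ov)), levels = lvls),
                                    IRanges::IRanges(ov$start, ov$end),
                                    label = ov$label)
      rest <- BiocGenerics::setdiff(base, ogr)
      if (length(rest) > 0L) rest$label <- default[[nm]]
      gr <- BiocGenerics::sort(c(ogr, rest))
      out[[nm]] <- gr
    }
    res <- unname(out)
    do.call(c, res)
  }
  no_overlays <- data.frame(obj = character(), start = integer(),
                            end = integer(), label = character(),
                            stringsAsFactors = FALSE)
  ovA <- no_overlays
  for (nm in chrom_names) {
    df <- pieces[[nm]]
    g <- df[df$type == "gap", , drop = FALSE]
    if (nrow(g) > 0L) {
      ovA <- rbind(ovA, data.frame(obj = nm, start = g$astart, end = g$aend,
                                   label = "UNALIGNED"))
    }
    d <- df[df$type == "dup", , drop = FALSE]
    if (nrow(d) > 0L) {
      ovA <- rbind(ovA, data.frame(obj = nm, start = d$astart, end = d$aend,
                                   label = "EXPANDED"))
    }
  }
  for (i in which(ev$kind == "COLLAPSE")) {
    a <- donor_to_a(pieces, ev$chrom[i], ev$start[i], ev$end[i])
    ovA <- rbind(ovA, data.frame(obj = ev$chrom[i], start = a[1L], end = a[2L],
                                 label = "COLLAPSED"))
  }
  for (i in alt_i) {
    fl <- ev$flank[i]
    aL <- donor_to_a(pieces, ev$chrom[i], ev$start[i], ev$start[i] + fl - 1L)
    aR <- donor_to_a(pieces, ev$chrom[i], ev$start[i] + fl, ev$end[i])
    ovA <- rbind(ovA, data.frame(obj = ev$chrom[i],
                                 start = c(aL[1L], aR[1L]),
                                 end = c(aL[2L], aR[2L]), label = "COLLAPSED"))
  }
  defaultsA <- stats::setNames(rep("UNIQUE", length(a_lens)), names(a_lens))
  labels_A <- overlay_track(a_lens, defaultsA, ovA)

  ovB <- no_overlays
  for (i in seq_len(nrow(ev))) {
    k <- ev$kind[i]
    if (k == "FALSE_DUPLICATION") {
      ovB <- rbind(ovB, data.frame(obj = ev$chrom[i], start = ev$start[i],
                                   end = ev$end[i], label = "COLLAPSED"))
    } else if (k == "COLLAPSE") {
      ovB <- rbind(ovB, data.frame(obj = ev$obj2[i], start = ev$start2[i],
                                   end = ev$end2[i], label = "EXPANDED"))
    } else if (k %in% c("GAP_CLOSURE", "CENTROMERE_MODEL")) {
      ovB <- rbind(ovB, data.frame(obj = ev$chrom[i], start = ev$start[i],
                                   end = ev$end[i], label = "UNALIGNED"))
    } else if (k == "ALT_LOCUS") {
      fl <- ev$flank[i]; nov <- ev$novel_length[i]
      ovB <- rbind(ovB, data.frame(obj = donor$alt_name,
                                   start = c(1L, fl + nov + 1L),
                                   end = c(fl, fl + nov + fl),
                                   label = "EXPANDED"))
    }
  }
  defaultsB <- stats::setNames(
    ifelse(names(b_lens) %in% chrom_names, "UNIQUE", "UNALIGNED"),
    names(b_lens))
  labels_B <- overlay_track(b_lens, defaultsB, ovB)

  # --- unchanged regions (same component accession.version both sides) ---
  unchanged <- list()
  for (nm in chrom_names) {
    df <- pieces[[nm]]
    runs <- df[df$type == "run" & df$strand == "+", , drop = FALSE]
    if (nrow(runs) == 0L) next
    run_ir <- IRanges::IRanges(runs$dstart, runs$dend)
    bump_acc <- cmaps$bumped[[nm]]
    tg <- cmaps$tiles[[nm]]
    # subtract bumped tiles and replaced (new-accession) spans
    excl <- IRanges::IRanges()
    if (length(bump_acc) > 0L) {
      bt <- tg[tg$acc %in% bump_acc, , drop = FALSE]
      excl <- c(excl, IRanges::IRanges(bt$start, bt$end))
    }
    keep <- BiocGenerics::setdiff(run_ir, excl)
    if (length(keep) == 0L) next
    hits <- IRanges::findOverlaps(keep, run_ir)
    ks <- IRanges::start(keep)[S4Vectors::queryHits(hits)]
    ke <- IRanges::end(keep)[S4Vectors::queryHits(hits)]
    ri <- S4Vectors::subjectHits(hits)
    astart <- runs$astart[ri] + (ks - runs$dstart[ri])
    aend <- runs$astart[ri] + (ke - runs$dstart[ri])
    unchanged[[nm]] <- data.frame(
      dobj = nm, dstart = ks, dend = ke,
      aobj = nm, astart = astart, aend = aend, stringsAsFactors = FALSE)
  }
  unchanged <- if (length(unchanged) > 0L) {
    u <- do.call(rbind, unname(unchanged)); rownames(u) <- NULL; u
  } else {
    data.frame(dobj = character(), dstart = integer(), dend = integer(),
               aobj = character(), astart = integer(), aend = integer())
  }

  # --- annotations -------------------------------------------------------
  new_rows <- no_overlays[, c("obj", "start", "end")]
  cen_rows <- new_rows
  for (i in seq_len(nrow(ev))) {
    k <- ev$kind[i]
    if (k %in% c("GAP_CLOSURE", "CENTROMERE_MODEL")) {
      new_rows <- rbind(new_rows, data.frame(obj = ev$chrom[i],
                                             start = ev$start[i],
                                             end = ev$end[i]))
    } else if (k == "COLLAPSE" && !is.na(ev$scaffold[i])) {
      len <- nchar(donor$scaf_seqs[[ev$scaffold[i]]])
      new_rows <- rbind(new_rows,
                        data.frame(obj = ev$scaffold[i],
                                   start = c(1L, ev$end2[i] + 1L),
                                   end = c(f, len)))
      if (identical(ev$dest[i], "scaffold_cen")) {
        cen_rows <- rbind(cen_rows,
                          data.frame(obj = ev$scaffold[i],
                                     start = ev$end2[i] + 1L,
                                     end = ev$end2[i] + SIM_SAT_CHUNK))
      }
    } else if (k == "ALT_LOCUS") {
      fl <- ev$flank[i]
      new_rows <- rbind(new_rows, data.frame(obj = donor$alt_name,
                                             start = fl + 1L,
                                             end = fl + ev$novel_length[i]))
    }
  }
  if (!is.null(sat)) {
    peri <- ev[ev$kind == "COLLAPSE" &
                 !is.na(ev$dest) &
                 ev$dest %in% c("same_pericen", "other_pericen"), , drop = FALSE]
    cen_end <- max(c(sat[["end"]], peri$end2))
    cen_rows <- rbind(cen_rows, data.frame(obj = chrom_names[1L],
                                           start = sat[["start"]],
                                           end = cen_end))
  }
  to_gr <- function(rows) {
    if (nrow(rows) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(rows$obj, IRanges::IRanges(rows$start, rows$end))
  }
  newseq_B <- to_gr(new_rows)
  cen_B <- to_gr(cen_rows)

  # --- ambiguous-placement (MAPQ 0) regions -----------------------------
  lowA <- new_rows[0L, ]; lowB <- new_rows[0L, ]
  for (i in seq_len(nrow(ev))) {
    k <- ev$kind[i]
    if (k == "FALSE_DUPLICATION" && ev$divergence[i] == 0) {
      a1 <- donor_to_a(pieces, ev$chrom[i], ev$start[i], ev$end[i])
      dp <- pieces[[ev$chrom[i]]]
      dj <- which(dp$type == "dup" & dp$event_id == i)
      lowA <- rbind(lowA, data.frame(obj = ev$chrom[i],
                                     start = c(a1[1L], dp$astart[dj]),
                                     end = c(a1[2L], dp$aend[dj])))
    } else if (k == "COLLAPSE" && ev$divergence[i] == 0) {
      lowB <- rbind(lowB,
                    data.frame(obj = c(ev$chrom[i], ev$obj2[i]),
                               start = c(ev$start[i], ev$start2[i]),
                               end = c(ev$end[i], ev$end2[i])))
    } else if (k == "CENTROMERE_MODEL") {
      lowB <- rbind(lowB, data.frame(obj = ev$chrom[i], start = ev$start[i],
                                     end = ev$end[i]))
    } else if (k == "COLLAPSE" && identical(ev$dest[i], "scaffold_cen")) {
      lowB <- rbind(lowB, data.frame(obj = ev$scaffold[i],
                                     start = ev$end2[i] + 1L,
                                     end = ev$end2[i] + SIM_SAT_CHUNK))
    }
  }
  sd <- donor$segdups
  if (!is.null(sd) && config$segdup_divergence == 0) {
    both <- data.frame(obj = c(sd$chrom1, sd$chrom2),
                       start = c(sd$start1, sd$start2),
                       end = c(sd$end1, sd$end2))
    lowB <- rbind(lowB, both)
    for (j in seq_len(nrow(both))) {
      a <- donor_to_a(pieces, both$obj[j], both$start[j], both$end[j])
      lowA <- rbind(lowA, data.frame(obj = both$obj[j], start = a[1L], end = a[2L]))
    }
  }

  # --- B-to-A read projection map ---------------------------------------
  maps <- list()
  for (nm in chrom_names) {
    df <- pieces[[nm]]
    r <- df[df$type == "run", , drop = FALSE]
    if (nrow(r) > 0L) {
      maps[[length(maps) + 1L]] <- data.frame(
        bobj = nm, bstart = r$dstart, bend = r$dend,
        aobj = nm, astart = r$astart, aend = r$aend, strand = r$strand,
        stringsAsFactors = FALSE)
    }
  }
  for (i in which(ev$kind == "COLLAPSE")) {
    a <- donor_to_a(pieces, ev$chrom[i], ev$start[i], ev$end[i])
    maps[[length(maps) + 1L]] <- data.frame(
      bobj = ev$obj2[i], bstart = ev$start2[i], bend = ev$end2[i],
      aobj = ev$chrom[i], astart = a[1L], aend = a[2L], strand = "+",
      stringsAsFactors = FALSE)
  }
  for (i in alt_i) {
    fl <- ev$flank[i]; nov <- ev$novel_length[i]
    aL <- donor_to_a(pieces, ev$chrom[i], ev$start[i], ev$start[i] + fl - 1L)
    aR <- donor_to_a(pieces, ev$chrom[i], ev$start[i] + fl, ev$end[i])
    maps[[length(maps) + 1L]] <- data.frame(
      bobj = donor$alt_name, bstart = c(1L, fl + nov + 1L),
      bend = c(fl, fl + nov + fl),
      aobj = ev$chrom[i], astart = c(aL[1L], aR[1L]),
      aend = c(aL[2L], aR[2L]), strand = "+", stringsAsFactors = FALSE)
  }
  b2a <- do.call(rbind, maps)
  rownames(b2a) <- NULL

  roles <- rbind(
    data.frame(assembly = "A", seq_id = names(a_lens), role = "chromosome",
               stringsAsFactors = FALSE),
    data.frame(assembly = "B", seq_id = names(b_lens),
               role = ifelse(names(b_lens) %in% chrom_names, "chromosome",
                             ifelse(names(b_lens) %in% names(donor$scaf_seqs),
                                    "unplaced", "alternate")),
               stringsAsFactors = FALSE))

  list(blocks = blocks, labels_A = labels_A, labels_B = labels_B,
       unchanged = unchanged, newseq_B = newseq_B, cen_B = cen_B,
       lowmapq_A = to_gr(lowA), lowmapq_B = to_gr(lowB),
       b2a = b2a, roles = roles, library = cmaps$library,
       cmaps = cmaps)
}
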