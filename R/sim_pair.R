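# Two-version assembly-pair simulation.
#
# Assembly A plays the older version (it carries the implanted defects);
# assembly B plays the curated update and shares its chromosome
# coordinates with the donor. All randomness flows through the single
# stream seeded in simulate_assembly_pair().

SIM_MARGIN <- 30000L     # unused flank at chromosome ends
SIM_SPACING <- 20000L    # minimum distance between implanted features
SIM_SCAF_FLANK <- 5000L  # unique flank on simulated unplaced scaffolds
SIM_SAT_CHUNK <- 5000L   # satellite-associated chunk on *_cen scaffolds

#' Simulate a two-version assembly pair with ground truth
#'
#' Builds a donor genome, applies the given curation events, and returns
#' both assembly versions (FASTA-ready sequences plus AGP component maps)
#' together with a truth bundle: truth alignment blocks between A and B
#' (reciprocal and nonreciprocal), per-base region labels
#' (collapsed/expanded/unique/unaligned) for each assembly, unchanged-region
#' pairs, new-sequence and centromere annotations, ambiguous-placement
#' (MAPQ 0) regions, sequence roles, and the B-to-A read projection map.
#'
#' With an empty event list the two assemblies are byte-identical and the
#' truth alignment is one reciprocal block per chromosome.
#'
#' @param config a [sim_config()].
#' @param events list of [sim_events] (may be empty).
#' @return A list of class `asm_pair` with elements `config`, `A` (list
#'   `seq`, `agp`), `B` (list `seq` over the full assembly, `agp`,
#'   `primary` = primary-unit sequence names), `truth` (see above), and
#'   `events` (the resolved event table).
#' @export
simulate_assembly_pair <- function(config, events = list()) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(events, "sim_event")) events <- list(events)
  set.seed(config$seed)
  ev <- layout_events(config, events)
  donor <- build_donor_sequences(config, ev)
  ev <- donor$ev
  build_pair(config, donor, ev)
}

# -- deterministic, RNG-free locus allocation ----------------------------

layout_events <- function(config, events) {
  n_ev <- length(events)
  L <- config$chromosome_length
  nC <- config$n_chromosomes
  chrom_names <- paste0("chr", seq_len(nC))

  needs_sat <- any(vapply(events, function(e) {
    e$kind == "CENTROMERE_MODEL" ||
      (e$kind == "COLLAPSE" && e$dest %in% c("same_pericen", "other_pericen",
                                             "scaffold_cen"))
  }, TRUE))
  sat_len <- config$satellite_monomer_length * config$satellite_copy_count
  sat_start <- if (needs_sat) as.integer(floor(0.45 * L)) else NA_integer_
  sat_end <- if (needs_sat) sat_start + sat_len - 1L else NA_integer_
  if (needs_sat && (sat_end > L - SIM_MARGIN || sat_start < SIM_MARGIN)) {
    stop("satellite array does not fit on the chromosome")
  }
  pericen_lens <- vapply(events, function(e) {
    if (e$kind == "COLLAPSE" && e$dest %in% c("same_pericen", "other_pericen"))
      e$length else 0L
  }, 1L)
  pericen_total <- sum(pericen_lens + ifelse(pericen_lens > 0L, SIM_SPACING, 0L))
  if (needs_sat && sat_end + pericen_total > L - SIM_MARGIN) {
    stop("pericentromeric features exceed chromosome length")
  }
  zone <- if (needs_sat) {
    c(sat_start - SIM_SPACING, sat_end + pericen_total + SIM_SPACING)
  } else NULL

  cursors <- rep(SIM_MARGIN + 1L, nC)
  allocate <- function(ci, len) {
    cur <- cursors[ci]
    if (ci == 1L && !is.null(zone) &&
        cur + len - 1L >= zone[1L] && cur <= zone[2L]) {
      cur <- zone[2L] + 1L
    }
    if (cur + len - 1L > L - SIM_MARGIN) {
      stop("requested features exceed chromosome length on ", chrom_names[ci])
    }
    cursors[ci] <<- cur + len + SIM_SPACING - 1L + 1L
    c(cur, cur + len - 1L)
  }
  pericen_cursor <- if (needs_sat) sat_end + 1L else NA_integer_
  allocate_pericen <- function(len) {
    s <- pericen_cursor
    pericen_cursor <<- pericen_cursor + len + SIM_SPACING
    c(s, s + len - 1L)
  }

  rr <- 0L
  next_chrom <- function() { rr <<- rr %% nC + 1L; rr }

  rows <- vector("list", n_ev)
  n_scaf <- 0L
  for (i in seq_along(events)) {
    e <- events[[i]]
    row <- list(event_id = i, kind = e$kind, length = e$length,
                divergence = if (is.null(e$divergence)) NA_real_ else e$divergence,
                dest = if (is.null(e$dest)) NA_character_ else e$dest,
                novel_length = if (is.null(e$novel_length)) NA_integer_ else e$novel_length,
                flank = if (is.null(e$flank)) NA_integer_ else e$flank,
                obj2 = NA_character_, start2 = NA_integer_, end2 = NA_integer_,
                scaffold = NA_character_)
    if (e$kind == "CENTROMERE_MODEL") {
      if (!needs_sat) stop("internal: satellite layout missing")
      row$chrom <- chrom_names[1L]
      row$start <- sat_start; row$end <- sat_end
      row$length <- sat_len
    } else if (e$kind == "COLLAPSE") {
      ci <- if (!is.na(e$chrom)) e$chrom else
        switch(e$dest,
               same_pericen = 1L,
               other_pericen = if (nC >= 2L) 2L else
                 stop("other_pericen needs at least two chromosomes"),
               next_chrom())
      loc <- allocate(ci, e$length)
      row$chrom <- chrom_names[ci]; row$start <- loc[1L]; row$end <- loc[2L]
      if (e$dest == "same_arm") {
        # the second copy must sit on a different baseline component than
        # the first, or its reads cannot register as moved
        tl <- config$component_length
        cursors[ci] <- as.integer(((cursors[ci] - 1L) %/% tl + 1L) * tl + 1L)
        loc2 <- allocate(ci, e$length)
        row$obj2 <- chrom_names[ci]
      } else if (e$dest == "other_arm") {
        if (nC < 2L) stop("other_arm needs at least two chromosomes")
        ci2 <- ci %% nC + 1L
        loc2 <- allocate(ci2, e$length)
        row$obj2 <- chrom_names[ci2]
      } else if (e$dest %in% c("same_pericen", "other_pericen")) {
        loc2 <- allocate_pericen(e$length)
        row$obj2 <- chrom_names[1L]
      } else { # scaffold, scaffold_cen
        n_scaf <- n_scaf + 1L
        scaf <- sprintf("scaf%02d", n_scaf)
        row$scaffold <- scaf
        row$obj2 <- scaf
        off <- SIM_SCAF_FLANK
        loc2 <- c(off + 1L, off + e$length)
      }
      row$start2 <- loc2[1L]; row$end2 <- loc2[2L]
    } else {
      ci <- if (!is.na(e$chrom)) e$chrom else next_chrom()
      loc <- allocate(ci, e$length)
      row$chrom <- chrom_names[ci]; row$start <- loc[1L]; row$end <- loc[2L]
    }
    rows[[i]] <- row
  }
  ev <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  if (is.null(ev)) {
    ev <- data.frame(event_id = integer(), kind = character(),
                     length = integer(), divergence = numeric(),
                     dest = character(), novel_length = integer(),
                     flank = integer(), obj2 = character(),
                     start2 = integer(), end2 = integer(),
                     scaffold = character(), chrom = character(),
                     start = integer(), end = integer(),
                     stringsAsFactors = FALSE)
  }
  # background segdup pairs share the allocator
  sd_rows <- list()
  if (config$segdup_count > 0L) {
    for (k in seq_len(config$segdup_count)) {
      c1 <- next_chrom(); c2 <- next_chrom()
      l1 <- allocate(c1, config$segdup_length)
      l2 <- allocate(c2, config$segdup_length)
      sd_rows[[k]] <- data.frame(
        pair = k, chrom1 = chrom_names[c1], start1 = l1[1L], end1 = l1[2L],
        chrom2 = chrom_names[c2], start2 = l2[1L], end2 = l2[2L],
        stringsAsFactors = FALSE)
    }
  }
  attr(ev, "segdups") <- if (length(sd_rows) > 0L) do.call(rbind, sd_rows) else NULL
  attr(ev, "satellite") <- if (needs_sat) {
    c(start = sat_start, end = sat_end)
  } else NULL
  attr(ev, "chrom_names") <- chrom_names
  ev
}

# -- donor sequence construction (consumes RNG in fixed order) -----------

build_donor_sequences <- function(config, ev) {
  chrom_names <- attr(ev, "chrom_names")
  L <- config$chromosome_length
  seqs <- list()
  for (nm in chrom_names) {
    seqs[[nm]] <- random_dna(L, config$gc_fraction)
  }
  sat <- attr(ev, "satellite")
  sat_seq <- NULL
  if (!is.null(sat)) {
    monomer <- random_dna(config$satellite_monomer_length, config$gc_fraction)
    copies <- vapply(seq_len(config$satellite_copy_count), function(i) {
      mutate_seq(monomer, config$satellite_divergence)
    }, "")
    sat_seq <- paste(copies, collapse = "")
    substr(seqs[[chrom_names[1L]]], sat[["start"]], sat[["end"]]) <- sat_seq
  }
  # event-derived donor edits, in event order
  ev$err_base <- rep(NA_character_, nrow(ev))
  dupseqs <- vector("list", nrow(ev))
  scaf_seqs <- list()
  alt_seq <- NULL; alt_name <- NULL
  for (i in seq_len(nrow(ev))) {
    kind <- ev$kind[i]
    if (kind == "COLLAPSE") {
      copy1 <- substr(seqs[[ev$chrom[i]]], ev$start[i], ev$end[i])
      copy2 <- mutate_seq(copy1, ev$divergence[i])
      if (!is.na(ev$scaffold[i])) {
        cen <- identical(ev$dest[i], "scaffold_cen")
        chunk <- if (cen) substr(sat_seq, 1L, SIM_SAT_CHUNK) else ""
        scaf_seqs[[ev$scaffold[i]]] <-
          paste0(random_dna(SIM_SCAF_FLANK, config$gc_fraction), copy2, chunk,
                 random_dna(SIM_SCAF_FLANK, config$gc_fraction))
      } else {
        substr(seqs[[ev$obj2[i]]], ev$start2[i], ev$end2[i]) <- copy2
      }
    } else if (kind == "FALSE_DUPLICATION") {
      src <- substr(seqs[[ev$chrom[i]]], ev$start[i], ev$end[i])
      dupseqs[[i]] <- mutate_seq(src, ev$divergence[i])
    } else if (kind == "BASE_ERROR") {
      ref <- substr(seqs[[ev$chrom[i]]], ev$start[i], ev$start[i])
      ev$err_base[i] <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    } else if (kind == "ALT_LOCUS") {
      alt_name <- "alt1"
      f <- ev$flank[i]
      anchor <- substr(seqs[[ev$chrom[i]]], ev$start[i], ev$end[i])
      alt_seq <- paste0(substr(anchor, 1L, f),
                        random_dna(ev$novel_length[i], config$gc_fraction),
                        substr(anchor, f + 1L, 2L * f))
    }
  }
  sd <- attr(ev, "segdups")
  if (!is.null(sd)) {
    for (k in seq_len(nrow(sd))) {
      src <- substr(seqs[[sd$chrom1[k]]], sd$start1[k], sd$end1[k])
      substr(seqs[[sd$chrom2[k]]], sd$start2[k], sd$end2[k]) <-
        mutate_seq(src, config$segdup_divergence)
    }
  }
  list(chrom_seqs = seqs, scaf_seqs = scaf_seqs, alt_seq = alt_seq,
       alt_name = alt_name, sat_seq = sat_seq,
       dupseqs = dupseqs, segdups = sd, ev = ev)
}

# -- assembly derivation --------------------------------------------------

build_pair <- function(config, donor, ev) {
  chrom_names <- attr(ev, "chrom_names")
  L <- config$chromosome_length
  sat <- attr(ev, "satellite")

  # --- A piece lists -----------------------------------------------------
  pieces <- list()  # per chromosome: df type,dstart,dend,strand,event_id
  for (ci in seq_along(chrom_names)) {
    nm <- chrom_names[ci]
    special <- data.frame(start = integer(), end = integer(),
                          type = character(), event_id = integer(),
                          stringsAsFactors = FALSE)
    extra_breaks <- integer()
    for (i in seq_len(nrow(ev))) {
      k <- ev$kind[i]
      if (k == "COLLAPSE" && !is.na(ev$obj2[i]) && ev$obj2[i] == nm &&
          is.na(ev$scaffold[i])) {
        special <- rbind(special, data.frame(start = ev$start2[i],
                                             end = ev$end2[i], type = "del",
                                             event_id = i))
      }
      if (ev$chrom[i] == nm) {
        if (k %in% c("GAP_CLOSURE", "CENTROMERE_MODEL")) {
          special <- rbind(special, data.frame(start = ev$start[i],
                                               end = ev$end[i], type = "gap",
                                               event_id = i))
        } else if (k == "INVERSION") {
          special <- rbind(special, data.frame(start = ev$start[i],
                                               end = ev$end[i], type = "inv",
                                               event_id = i))
        } else if (k == "FALSE_DUPLICATION") {
          extra_breaks <- c(extra_breaks, ev$end[i])
        }
      }
    }
    special <- special[order(special$start), , drop = FALSE]
    if (nrow(special) > 1L &&
        any(special$start[-1L] <= special$end[-nrow(special)])) {
      stop("overlapping events on ", nm)
    }
    if (nrow(special) > 0L && any(special$end > L)) {
      stop("event extends past chromosome end on ", nm)
    }
    brk <- sort(unique(c(0L, special$start - 1L, special$end, extra_breaks, L)))
    brk <- brk[brk >= 0L & brk <= L]
    pc <- list()
    for (j in seq_len(length(brk) - 1L)) {
      s <- brk[j] + 1L; e <- brk[j + 1L]
      hit <- which(special$start <= s & special$end >= e)
      if (length(hit) == 1L) {
        ty <- special$type[hit]
        eid <- special$event_id[hit]
        if (ty == "del") next
        pc[[length(pc) + 1L]] <- data.frame(
          type = ifelse(ty == "gap", "gap", "run"),
          dstart = s, dend = e,
          strand = ifelse(ty == "inv", "-", "+"),
          event_id = eid, stringsAsFactors = FALSE)
      } else {
        pc[[length(pc) + 1L]] <- data.frame(
          type = "run", dstart = s, dend = e, strand = "+",
          event_id = NA_integer_, stringsAsFactors = FALSE)
      }
      # false duplication copies insert right after their donor locus
      dupi <- which(ev$kind == "FALSE_DUPLICATION" & ev$chrom == nm &
                      ev$end == e)
      for (i in dupi) {
        pc[[length(pc) + 1L]] <- data.frame(
          type = "dup", dstart = ev$start[i], dend = ev$end[i], strand = "+",
          event_id = i, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, pc)
    w <- ifelse(df$type == "gap", config$default_gap_length,
                df$dend - df$dstart + 1L)
    df$astart <- cumsum(c(1L, w[-length(w)]))
    df$aend <- df$astart + w - 1L
    pieces[[nm]] <- df
  }

  # --- A sequences -------------------------------------------------------
  a_seqs <- list()
  for (nm in chrom_names) {
    df <- pieces[[nm]]
    parts <- character(nrow(df))
    for (j in seq_len(nrow(df))) {
      if (df$type[j] == "gap") {
        parts[j] <- strrep("N", config$default_gap_length)
      } else if (df$type[j] == "dup") {
        parts[j] <- donor$dupseqs[[df$event_id[j]]]
      } else if (df$strand[j] == "-") {
        parts[j] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(substr(donor$chrom_seqs[[nm]],
                                       df$dstart[j], df$dend[j]))))
      } else {
        parts[j] <- substr(donor$chrom_seqs[[nm]], df$dstart[j], df$dend[j])
      }
    }
    a_seqs[[nm]] <- paste(parts, collapse = "")
    # implant base errors (A side carries the erroneous base)
    for (i in which(ev$kind == "BASE_ERROR" & ev$chrom == nm)) {
      p <- ev$start[i]
      pj <- which(df$type == "run" & df$strand == "+" &
                    df$dstart <= p & df$dend >= p)
      if (length(pj) != 1L) stop("base error locus lost during derivation")
      ap <- df$astart[pj] + (p - df$dstart[pj])
      substr(a_seqs[[nm]], ap, ap) <- ev$err_base[i]
    }
  }

  # --- B objects ---------------------------------------------------------
  b_seqs <- donor$chrom_seqs
  for (scaf in names(donor$scaf_seqs)) b_seqs[[scaf]] <- donor$scaf_seqs[[scaf]]
  if (!is.null(donor$alt_name)) b_seqs[[donor$alt_name]] <- donor$alt_seq
  b_lens <- vapply(b_seqs, nchar, 1L)
  a_lens <- vapply(a_seqs, nchar, 1L)
  primary <- setdiff(names(b_seqs), donor$alt_name)

  # --- component maps ----------------------------------------------------
  cmaps <- component_maps(config, ev, chrom_names, donor, b_lens, pieces)

  # --- truth bundle ------------------------------------------------------
  truth <- build_truth(config, ev, donor, pieces, cmaps,
                       a_lens, b_lens, chrom_names, sat)

  structure(list(
    config = config,
    A = list(seq = as_dss(a_seqs), agp = cmaps$agpA),
    B = list(seq = as_dss(b_seqs), agp = cmaps$agpB, primary = primary),
    truth = truth,
    events = ev,
    pieces = pieces
  ), class = "asm_pair")
}

as_dss <- function(seq_list) {
  Biostrings::DNAStringSet(unlist(seq_list))
}
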