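#' Simulate paired-end reads with truth placements
#'
#' Draws read pairs from the full B assembly (the curated version carries
#' every simulated locus, including B-only copies, new sequence and the
#' alternate locus) at the configured depth, insert-size law (normal,
#' truncated below at the read length) and per-base substitution error
#' rate, and derives three truth placement sets per read:
#'
#' * versus the full B assembly — the source locus;
#' * versus the B primary units — identical, except that reads from the
#'   alternate-locus scaffold place on its chromosomal anchor (flanks) or
#'   are unmapped (novel core);
#' * versus A — the source span projected through the truth alignment map;
#'   reads whose span is not fully contained in one mapped interval
#'   (new sequence, satellite, scaffold flanks) are truth-unmapped on A.
#'
#' Placements wholly inside a region with two effectively identical copies
#' in the respective assembly get MAPQ 0; all other placements MAPQ 60.
#' A configured fraction of pairs is replaced by random contaminant
#' sequence, truth-unmapped everywhere.
#'
#' @param pair an `asm_pair` from [simulate_assembly_pair()].
#' @param seed seed for the read stream (default: config seed + 1).
#' @return A list of class `sim_reads`: `reads` (data.frame `read_id`,
#'   `mate`, `seq` as sequenced), and `truth` — a list of three
#'   `read_placements` data.frames (`A`, `B_primary`, `B_full`), each with
#'   `strand` and `seq` columns suitable for [write_sam()].
#' @export
simulate_reads <- function(pair, seed = pair$config$seed + 1L) {
  cfg <- pair$config
  set.seed(seed)
  b_lens <- Biostrings::width(pair$B$seq)
  names(b_lens) <- names(pair$B$seq)
  G <- sum(b_lens)
  rl <- cfg$read_length
  n_pairs <- max(1L, as.integer(round(cfg$depth * G / (2 * rl))))

  obj <- sample(names(b_lens), n_pairs, replace = TRUE, prob = b_lens)
  frag <- as.integer(round(stats::rnorm(n_pairs, cfg$insert_mean, cfg$insert_sd)))
  frag <- pmax(frag, rl)
  frag <- pmin(frag, b_lens[obj])
  fs <- 1L + as.integer(floor(stats::runif(n_pairs) * (b_lens[obj] - frag + 1)))
  fe <- fs + frag - 1L
  ori <- sample(c(TRUE, FALSE), n_pairs, replace = TRUE)

  m_start <- cbind(ifelse(ori, fs, fe - rl + 1L), ifelse(ori, fe - rl + 1L, fs))
  m_strand <- cbind(ifelse(ori, "+", "-"), ifelse(ori, "-", "+"))

  n_contam <- as.integer(round(cfg$contaminant_fraction * n_pairs))
  contam <- rep(FALSE, n_pairs)
  if (n_contam > 0L) contam[sample.int(n_pairs, n_contam)] <- TRUE

  read_id <- sprintf("sim%07d", seq_len(n_pairs))

  # per-mate sequences in reference orientation, then flip '-' mates
  extract_seqs <- function(starts) {
    seqs <- character(n_pairs)
    for (nm in unique(obj)) {
      idx <- which(obj == nm & !contam)
      if (length(idx) == 0L) next
      v <- Biostrings::Views(pair$B$seq[[nm]], start = starts[idx],
                             width = rl)
      seqs[idx] <- as.character(v)
    }
    seqs
  }
  seq1 <- extract_seqs(m_start[, 1L])
  seq2 <- extract_seqs(m_start[, 2L])
  flip <- function(seqs, strands) {
    idx <- which(strands == "-" & !contam)
    if (length(idx) > 0L) {
      seqs[idx] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[idx])))
    }
    seqs
  }
  seq1 <- flip(seq1, m_strand[, 1L])
  seq2 <- flip(seq2, m_strand[, 2L])
  if (n_contam > 0L) {
    for (i in which(contam)) {
      seq1[i] <- random_dna(rl, 0.5)
      seq2[i] <- random_dna(rl, 0.5)
    }
  }
  seq1 <- add_read_errors(seq1, cfg$per_base_error_rate)
  seq2 <- add_read_errors(seq2, cfg$per_base_error_rate)

  long <- data.frame(
    read_id = rep(read_id, 2L),
    mate = rep(c(1L, 2L), each = n_pairs),
    seq_id = rep(obj, 2L),
    pos = c(m_start[, 1L], m_start[, 2L]),
    strand = c(m_strand[, 1L], m_strand[, 2L]),
    contam = rep(contam, 2L),
    seq = c(seq1, seq2),
    stringsAsFactors = FALSE
  )
  long$end <- long$pos + rl - 1L

  truth_full <- placements_b_full(long, pair)
  truth_primary <- placements_b_primary(long, pair)
  truth_a <- placements_a(long, pair)

  structure(list(
    reads = long[, c("read_id", "mate", "seq")],
    n_pairs = n_pairs,
    truth = list(A = truth_a, B_primary = truth_primary, B_full = truth_full)
  ), class = "sim_reads")
}

add_read_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  for (i in seq_along(seqs)) {
    k <- stats::rbinom(1L, nchar(seqs[i]), rate)
    if (k > 0L) seqs[i] <- mutate_at(seqs[i], sample.int(nchar(seqs[i]), k))
  }
  seqs
}

mutate_at <- function(seq, idx) {
  alphabet <- c("A", "C", "G", "T")
  for (i in idx) {
    substr(seq, i, i) <- sample(setdiff(alphabet, substr(seq, i, i)), 1L)
  }
  seq
}

span_within <- function(seq_id, start, end, gr, mapped = NULL) {
  if (length(gr) == 0L) return(rep(FALSE, length(seq_id)))
  ok <- if (is.null(mapped)) !is.na(seq_id) else mapped & !is.na(seq_id)
  res <- rep(FALSE, length(seq_id))
  if (!any(ok)) return(res)
  q <- GenomicRanges::GRanges(seq_id[ok], IRanges::IRanges(start[ok], end[ok]))
  hit <- suppressWarnings(IRanges::overlapsAny(q, gr, type = "within"))
  res[ok] <- hit
  res
}

placement_frame <- function(long, seq_id, pos, end, strand, mapped, mapq) {
  df <- data.frame(
    read_id = long$read_id, mate = long$mate,
    seq_id = ifelse(mapped, seq_id, NA_character_),
    pos = ifelse(mapped, pos, NA_integer_),
    end = ifelse(mapped, end, NA_integer_),
    mapq = ifelse(mapped, mapq, 0L),
    mapped = mapped, primary = TRUE,
    strand = ifelse(mapped, strand, "+"),
    seq = long$seq,
    stringsAsFactors = FALSE
  )
  class(df) <- c("read_placements", "data.frame")
  df
}

placements_b_full <- function(long, pair) {
  mapped <- !long$contam
  low <- span_within(long$seq_id, long$pos, long$end, pair$truth$lowmapq_B,
                     mapped)
  placement_frame(long, long$seq_id, long$pos, long$end, long$strand,
                  mapped, ifelse(low, 0L, 60L))
}

placements_b_primary <- function(long, pair) {
  alt_name <- setdiff(names(pair$B$seq), pair$B$primary)
  seq_id <- long$seq_id; pos <- long$pos; end <- long$end
  mapped <- !long$contam
  if (length(alt_name) == 1L) {
    ev <- pair$events
    i <- which(ev$kind == "ALT_LOCUS")[1L]
    fl <- ev$flank[i]; nov <- ev$novel_length[i]
    on_alt <- long$seq_id == alt_name & !long$contam
    in_L <- on_alt & long$end <= fl
    in_R <- on_alt & long$pos >= fl + nov + 1L
    mapped[on_alt & !(in_L | in_R)] <- FALSE
    seq_id[in_L | in_R] <- ev$chrom[i]
    pos[in_L] <- ev$start[i] + (long$pos[in_L] - 1L)
    end[in_L] <- pos[in_L] + (long$end[in_L] - long$pos[in_L])
    pos[in_R] <- ev$start[i] + fl + (long$pos[in_R] - (fl + nov + 1L))
    end[in_R] <- pos[in_R] + (long$end[in_R] - long$pos[in_R])
  }
  low <- span_within(seq_id, pos, end, pair$truth$lowmapq_B, mapped)
  placement_frame(long, seq_id, pos, end, long$strand, mapped,
                  ifelse(low, 0L, 60L))
}

placements_a <- function(long, pair) {
  b2a <- pair$truth$b2a
  map_gr <- GenomicRanges::GRanges(b2a$bobj,
                                   IRanges::IRanges(b2a$bstart, b2a$bend))
  ok <- !long$contam
  q <- GenomicRanges::GRanges(long$seq_id[ok],
                              IRanges::IRanges(long$pos[ok], long$end[ok]))
  hit <- suppressWarnings(GenomicRanges::findOverlaps(q, map_gr, type = "within",
                                                     select = "first"))
  idx_ok <- which(ok)
  mapped <- rep(FALSE, nrow(long))
  seq_id <- rep(NA_character_, nrow(long))
  pos <- rep(NA_integer_, nrow(long))
  end <- rep(NA_integer_, nrow(long))
  strand <- rep("+", nrow(long))
  got <- !is.na(hit)
  ri <- hit[got]
  gi <- idx_ok[got]
  fwd <- b2a$strand[ri] == "+"
  seq_id[gi] <- b2a$aobj[ri]
  pos[gi] <- ifelse(fwd, b2a$astart[ri] + (long$pos[gi] - b2a$bstart[ri]),
                    b2a$aend[ri] - (long$end[gi] - b2a$bstart[ri]))
  end[gi] <- ifelse(fwd, b2a$astart[ri] + (long$end[gi] - b2a$bstart[ri]),
                    b2a$aend[ri] - (long$pos[gi] - b2a$bstart[ri]))
  strand[gi] <- ifelse(fwd, long$strand[gi],
                       ifelse(long$strand[gi] == "+", "-", "+"))
  mapped[gi] <- TRUE
  low <- span_within(seq_id, pos, end, pair$truth$lowmapq_A, mapped)
  placement_frame(long, seq_id, pos, end, strand, mapped,
                  ifelse(low, 0L, 60L))
}

#' Write simulated reads as paired FASTQ
#'
#' @param reads a `sim_reads` object.
#' @param prefix output prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return character vector of the two paths, invisibly.
#' @export
write_pair_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, "_", 1:2, ".fastq")
  for (m in 1:2) {
    sub <- reads$reads[reads$reads$mate == m, ]
    dss <- Biostrings::DNAStringSet(sub$seq)
    names(dss) <- sub$read_id
    q <- Biostrings::BStringSet(vapply(nchar(sub$seq), strrep, "", x = "I"))
    Biostrings::writeXStringSet(dss, paths[m], format = "fastq",
                                qualities = q)
  }
  invisible(paths)
}
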