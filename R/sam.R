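#' Read paired-end read placements from SAM/BAM
#'
#' Extracts the placement contract used throughout the package from a
#' SAM or BAM file via Rsamtools: one row per alignment record with the
#' read id, mate, leftmost position, aligned reference span, MAPQ, and
#' mapped/primary flags. Unmapped records are retained (with `NA`
#' coordinates) because unmapped-read rescue statistics need them.
#'
#' Plain-text SAM input is converted to a temporary coordinate-sorted BAM
#' with [Rsamtools::asBam()] before reading.
#'
#' @param path path to a `.sam` or `.bam` file.
#' @return A `data.frame` of class `read_placements` with columns
#'   `read_id`, `mate` (1 or 2), `seq_id`, `pos` (1-based leftmost),
#'   `end` (aligned span end), `mapq`, `mapped`, `primary`.
#' @export
read_placements <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar")
  )
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  flag <- res$flag
  mate <- ifelse(bitwAnd(flag, 0x40L) != 0L, 1L,
                 ifelse(bitwAnd(flag, 0x80L) != 0L, 2L, 1L))
  mapped <- bitwAnd(flag, 0x4L) == 0L
  primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  width <- rep(NA_integer_, length(flag))
  has_cig <- mapped & !is.na(res$cigar)
  if (any(has_cig)) {
    width[has_cig] <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[has_cig])
  }
  df <- data.frame(
    read_id = res$qname,
    mate = mate,
    seq_id = ifelse(mapped, as.character(res$rname), NA_character_),
    pos = ifelse(mapped, res$pos, NA_integer_),
    end = ifelse(mapped, res$pos + width - 1L, NA_integer_),
    mapq = ifelse(mapped, res$mapq, 0L),
    mapped = mapped,
    primary = primary,
    stringsAsFactors = FALSE
  )
  dup <- df[df$primary & df$mapped, c("read_id", "mate")]
  if (anyDuplicated(dup)) {
    d <- dup[duplicated(dup), , drop = FALSE]
    stop("multiple primary placements for read(s): ",
         paste(unique(paste0(d$read_id, "/", d$mate)), collapse = ", "))
  }
  class(df) <- c("read_placements", "data.frame")
  df
}

#' Write read placements as a SAM file
#'
#' Writes the minimal SAM representation of a placement table (fixture
#' output of the simulator): `@HD`/`@SQ` header from a sequence dictionary
#' and one record per placement. Mapped records need read sequences;
#' unmapped mates are written with flag 0x4 and `*` fields.
#'
#' @param placements a `read_placements` data.frame; mapped rows must also
#'   carry `strand` (`"+"`/`"-"`) and all rows a `seq` column with the read
#'   bases (as sequenced, forward orientation).
#' @param seqinfo named integer vector of target sequence lengths.
#' @param path output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(placements, seqinfo, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(seqinfo), "\tLN:", as.integer(seqinfo)))
  p <- placements
  n <- nrow(p)
  paired <- any(p$mate == 2L)
  strand <- if ("strand" %in% names(p)) p$strand else rep("+", n)
  if (paired) {
    mate1 <- p$mate == 1L
    flag <- rep(1L, n)                             # paired
    flag <- flag + ifelse(mate1, 0x40L, 0x80L)
    flag <- flag + ifelse(p$mapped, 0L, 0x4L)
    key <- paste0(p$read_id, "/", ifelse(mate1, 2L, 1L))
    self_key <- paste0(p$read_id, "/", p$mate)
    mate_mapped <- p$mapped[match(key, self_key)]
    mate_mapped[is.na(mate_mapped)] <- FALSE
    flag <- flag + ifelse(mate_mapped, 0L, 0x8L)
    flag <- flag + ifelse(p$mapped & strand == "-", 0x10L, 0L)
    mate_strand <- strand[match(key, self_key)]
    flag <- flag + ifelse(mate_mapped & !is.na(mate_strand) & mate_strand == "-",
                          0x20L, 0L)
  } else {
    flag <- ifelse(p$mapped, 0L, 0x4L) + ifelse(p$mapped & strand == "-", 0x10L, 0L)
  }
  seq <- if ("seq" %in% names(p)) p$seq else strrep("N", 1L)
  # SAM stores the sequence as aligned: reverse-complement minus-strand reads
  rc <- p$mapped & strand == "-"
  if (any(rc)) {
    seq[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seq[rc])))
  }
  cigar <- if ("cigar" %in% names(p)) {
    ifelse(p$mapped, p$cigar, "*")
  } else {
    ifelse(p$mapped, paste0(nchar(seq), "M"), "*")
  }
  qual <- vapply(nchar(seq), function(k) strrep("I", k), "")
  rec <- paste(p$read_id, flag,
               ifelse(p$mapped, p$seq_id, "*"),
               ifelse(p$mapped, p$pos, 0L),
               ifelse(p$mapped, p$mapq, 0L),
               cigar, "*", 0L, 0L, seq, qual, sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}
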