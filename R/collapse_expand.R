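#' Candidate ungapped regions of an assembly sequence
#'
#' Splits each sequence into maximal inter-gap segments and keeps a segment
#' only if its non-N base fraction strictly exceeds `min_non_n_fraction`
#' (default 0.5, i.e. regions comprised of >50% non-N bases). Gap
#' separators come from the AGP gap rows when an AGP is supplied;
#' otherwise runs of `N` in the sequence are used as separators.
#'
#' @param seqs a [Biostrings::DNAStringSet] of assembly sequences.
#' @param agp optional `agp` data.frame for the same assembly; its object
#'   spans must match the sequence lengths.
#' @param min_non_n_fraction strict lower bound on the kept non-N fraction,
#'   in `[0, 1)`.
#' @return A [GenomicRanges::GRanges] of kept regions (1-based inclusive).
#' @export
ungapped_regions <- function(seqs, agp = NULL, min_non_n_fraction = 0.5) {
  stopifnot(min_non_n_fraction >= 0, min_non_n_fraction < 1)
  lens <- Biostrings::width(seqs)
  names(lens) <- names(seqs)
  if (!is.null(agp)) {
    spans <- tapply(agp$object_end, agp$object, max)
    common <- intersect(names(spans), names(lens))
    if (length(common) == 0L && nrow(agp) > 0L) {
      stop("AGP and FASTA share no sequence names")
    }
    bad <- common[spans[common] != lens[common]]
    if (length(bad) > 0L) {
      stop("AGP span and sequence length disagree for: ",
           paste(bad, collapse = ", "))
    }
    gaps <- agp_gaps(agp)
  } else {
    gaps <- n_runs(seqs)
  }
  out <- list()
  for (nm in names(seqs)) {
    g <- gaps[as.character(GenomicRanges::seqnames(gaps)) == nm]
    segs <- IRanges::gaps(IRanges::reduce(GenomicRanges::ranges(g)),
                          start = 1L, end = lens[[nm]])
    if (length(segs) == 0L) next
    frac <- non_n_fraction(seqs[[nm]], segs)
    keep <- segs[frac > min_non_n_fraction]
    if (length(keep) > 0L) {
      out[[nm]] <- GenomicRanges::GRanges(factor(rep(nm, length(keep)),
                                                 levels = names(seqs)), keep)
    }
  }
  if (length(out) == 0L) return(GenomicRanges::GRanges())
  do.call(c, unname(out))
}

n_runs <- function(seqs) {
  out <- list()
  for (nm in names(seqs)) {
    m <- Biostrings::matchPattern("N", seqs[[nm]])
    r <- IRanges::reduce(IRanges::ranges(m))
    if (length(r) > 0L) {
      out[[nm]] <- GenomicRanges::GRanges(factor(rep(nm, length(r)),
                                                 levels = names(seqs)), r)
    }
  }
  if (length(out) == 0L) return(GenomicRanges::GRanges())
  do.call(c, unname(out))
}

non_n_fraction <- function(seq, segs) {
  v <- Biostrings::Views(seq, segs)
  nN <- Biostrings::letterFrequency(v, "N")[, 1L]
  1 - nN / IRanges::width(segs)
}

#' Per-base collapse/expansion labels from best-hit alignment blocks
#'
#' Classifies every base of the focal assembly by the pass classes of the
#' alignment segments covering it: bases covered by at least one reciprocal
#' and at least one nonreciprocal best-hit segment are `COLLAPSED` (a
#' duplicate copy is missing from the focal assembly); bases covered only
#' by nonreciprocal segments are `EXPANDED` (extra sequence relative to the
#' other assembly); bases covered only by reciprocal segments are `UNIQUE`;
#' uncovered bases are `UNALIGNED`. Coverage is computed at segment
#' (post-CIGAR) resolution, not whole-block envelopes, so indel gaps inside
#' blocks do not inflate labels.
#'
#' @param blocks an `alignment_blocks` data.frame oriented with the focal
#'   assembly as query (use [invert_blocks()] for the other side).
#' @param seqlens named integer vector of focal sequence lengths.
#' @return A named list (one element per focal sequence) of
#'   [S4Vectors::Rle] factor labels over `[1, length]`, an object of class
#'   `label_track`.
#' @export
label_bases <- function(blocks, seqlens) {
  if (nrow(blocks) > 0L) {
    unknown <- setdiff(unique(blocks$qname), names(seqlens))
    if (length(unknown) > 0L) {
      stop("blocks reference unknown focal sequence(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  labels <- c("COLLAPSED", "EXPANDED", "UNIQUE", "UNALIGNED")
  seg_ranges <- function(pass) {
    idx <- which(blocks$pass_class == pass)
    if (length(idx) == 0L) {
      return(GenomicRanges::GRanges(seqnames = factor(levels = names(seqlens)),
                                    ranges = IRanges::IRanges()))
    }
    segs <- do.call(rbind, blocks$segments[idx])
    qn <- rep(blocks$qname[idx],
              vapply(blocks$segments[idx], nrow, 1L))
    GenomicRanges::GRanges(factor(qn, levels = names(seqlens)),
                           IRanges::IRanges(segs$qstart, segs$qend))
  }
  rec <- seg_ranges("RECIPROCAL")
  non <- seg_ranges("NONRECIPROCAL")
  out <- list()
  for (nm in names(seqlens)) {
    L <- as.integer(seqlens[[nm]])
    covr <- label_cov(rec, nm, L)
    covn <- label_cov(non, nm, L)
    lab <- ifelse(covr & covn, "COLLAPSED",
                  ifelse(covn, "EXPANDED", ifelse(covr, "UNIQUE", "UNALIGNED")))
    out[[nm]] <- S4Vectors::Rle(factor(lab, levels = labels))
  }
  class(out) <- "label_track"
  out
}

label_cov <- function(gr, nm, L) {
  sub <- gr[as.character(GenomicRanges::seqnames(gr)) == nm]
  cov <- IRanges::coverage(GenomicRanges::ranges(sub), width = L)
  as.vector(cov > 0L)
}

#' Summarize a label track over kept regions
#'
#' Counts, per sequence and label, the number of bases inside the kept
#' ungapped regions, and reports the `k` largest labeled intervals per
#' label (ties broken by sequence name, then start).
#'
#' @param track a `label_track` from [label_bases()].
#' @param regions kept regions from [ungapped_regions()]; labels are only
#'   counted inside them.
#' @param k number of largest intervals to report per label.
#' @return A list with `lengths` (data.frame `seq_id`, `label`, `bases`),
#'   `top` (data.frame `label`, `seq_id`, `start`, `end`, `bases`), and
#'   `kept_bases` (total kept-region length); labels always sum to
#'   `kept_bases`.
#' @export
summarize_labels <- function(track, regions, k = 10L) {
  labels <- c("COLLAPSED", "EXPANDED", "UNIQUE", "UNALIGNED")
  len_rows <- list()
  ivl_rows <- list()
  for (nm in names(track)) {
    rle <- track[[nm]]
    keep <- regions[as.character(GenomicRanges::seqnames(regions)) == nm]
    if (length(keep) == 0L) {
      len_rows[[nm]] <- data.frame(seq_id = nm, label = labels, bases = 0L)
      next
    }
    mask <- IRanges::coverage(GenomicRanges::ranges(keep),
                              width = length(rle)) > 0L
    counts <- integer(length(labels)); names(counts) <- labels
    vals <- S4Vectors::runValue(rle)
    ir <- IRanges::IRanges(start = S4Vectors::start(rle), end = S4Vectors::end(rle))
    # per-run intersection with kept mask
    kept_ir <- as(mask, "IRanges")  # ranges where TRUE
    ov <- IRanges::findOverlaps(ir, kept_ir)
    if (length(ov) > 0L) {
      qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
      inter_start <- pmax(IRanges::start(ir)[qi], IRanges::start(kept_ir)[si])
      inter_end <- pmin(IRanges::end(ir)[qi], IRanges::end(kept_ir)[si])
      w <- inter_end - inter_start + 1L
      lab <- as.character(vals)[qi]
      agg <- tapply(w, lab, sum)
      counts[names(agg)] <- as.integer(agg)
      ivl_rows[[nm]] <- data.frame(seq_id = nm, label = lab,
                                   start = inter_start, end = inter_end,
                                   bases = w, stringsAsFactors = FALSE)
    }
    len_rows[[nm]] <- data.frame(seq_id = nm, label = labels,
                                 bases = as.integer(counts))
  }
  lengths_df <- do.call(rbind, unname(len_rows))
  rownames(lengths_df) <- NULL
  ivls <- if (length(ivl_rows) > 0L) do.call(rbind, unname(ivl_rows)) else
    data.frame(seq_id = character(), label = character(), start = integer(),
               end = integer(), bases = integer())
  top <- do.call(rbind, lapply(labels, function(lb) {
    sub <- ivls[ivls$label == lb, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    ord <- order(-sub$bases, sub$seq_id, sub$start)
    utils::head(sub[ord, c("label", "seq_id", "start", "end", "bases")], k)
  }))
  if (is.null(top)) {
    top <- data.frame(label = character(), seq_id = character(),
                      start = integer(), end = integer(), bases = integer())
  }
  rownames(top) <- NULL
  list(lengths = lengths_df, top = top,
       kept_bases = sum(GenomicRanges::width(regions)))
}
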