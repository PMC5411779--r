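#' Tally alleles at candidate sites from a MAPQ-filtered pileup
#'
#' Counts, per candidate site, the allele shown by each primary mapped
#' alignment with MAPQ >= `min_mapq`. SNV sites count the aligned base at
#' the position, with deletions spanning the site counted as a distinct
#' `"del"` allele; insertion and deletion sites count presence or absence
#' of the left-anchored event at the position (VCF convention): a read
#' shows `"alt"` when it carries an insertion immediately after the anchor
#' (respectively a deletion of the following bases) of the expected
#' length, `"ref"` when it aligns across the junction without the event,
#' and the observed indel string otherwise. Secondary and supplementary
#' alignments are excluded.
#'
#' @param alignments path to a SAM/BAM file against the sites' assembly,
#'   or a `read_placements` data.frame carrying `seq` and `cigar` columns.
#' @param sites a `variant_sites` data.frame.
#' @param min_mapq MAPQ threshold (default 20).
#' @param fasta optional assembly FASTA path; when given, site REF alleles
#'   are validated against it.
#' @param seqlens optional named lengths of the assembly sequences; sites
#'   beyond a sequence end raise an error.
#' @return A list of class `allele_tallies`: one element per site with
#'   `site_id`, `counts` (named integer), `depth`, `multi_allelic`,
#'   `unexpected_allele`.
#' @export
pileup_tally <- function(alignments, sites, min_mapq = 20L, fasta = NULL,
                         seqlens = NULL) {
  if (is.character(alignments)) {
    alignments <- read_placements_with_seq(alignments)
  }
  if (!is.null(fasta)) check_site_refs(sites, fasta)
  if (!is.null(seqlens)) {
    over <- sites$pos + nchar(sites$ref) - 1L > seqlens[sites$seq_id]
    if (any(over)) {
      stop("site(s) beyond contig end: ",
           paste(sites$site_id[over], collapse = ", "))
    }
  }
  p <- alignments[alignments$mapped & alignments$primary &
                    alignments$mapq >= min_mapq, , drop = FALSE]
  if (!"cigar" %in% names(p)) p$cigar <- paste0(nchar(p$seq), "M")
  sgr <- GenomicRanges::GRanges(sites$seq_id,
                                IRanges::IRanges(sites$pos, sites$pos))
  rgr <- GenomicRanges::GRanges(p$seq_id, IRanges::IRanges(p$pos, p$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(sgr, rgr))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)

  # pre-exploded CIGARs for the reads involved
  uread <- unique(sh)
  ops_list <- GenomicAlignments::explodeCigarOps(p$cigar[uread])
  len_list <- GenomicAlignments::explodeCigarOpLengths(p$cigar[uread])
  read_idx <- match(sh, uread)

  tallies <- lapply(seq_len(nrow(sites)), function(i) {
    list(site_id = sites$site_id[i], counts = integer(0L), depth = 0L,
         multi_allelic = FALSE, unexpected_allele = FALSE)
  })
  names(tallies) <- sites$site_id

  for (k in seq_along(qh)) {
    si <- qh[k]; ri <- sh[k]
    allele <- read_allele(ops_list[[read_idx[k]]], len_list[[read_idx[k]]],
                          p$pos[ri], p$seq[ri], sites$pos[si],
                          sites$type[si], sites$ref[si], sites$alt[si])
    if (is.na(allele)) next
    cts <- tallies[[si]]$counts
    cts[allele] <- if (allele %in% names(cts)) cts[[allele]] + 1L else 1L
    tallies[[si]]$counts <- cts
  }
  for (i in seq_along(tallies)) {
    cts <- tallies[[i]]$counts
    tallies[[i]]$depth <- sum(cts)
    tallies[[i]]$multi_allelic <- length(cts) > 2L
    expected <- if (sites$type[i] == "SNV") c(sites$ref[i], sites$alt[i])
                else c("ref", "alt")
    tallies[[i]]$unexpected_allele <- any(!names(cts) %in% expected)
    tallies[[i]]$type <- sites$type[i]
    tallies[[i]]$ref <- sites$ref[i]
    tallies[[i]]$alt <- sites$alt[i]
  }
  class(tallies) <- "allele_tallies"
  tallies
}

# allele shown by one read at one site; NA when uninformative
read_allele <- function(ops, lens, read_pos, read_seq, site_pos, type,
                        ref, alt) {
  rcur <- read_pos   # next reference base consumed
  qcur <- 1L         # next read base consumed
  n_ops <- length(ops)
  if (type == "SNV") {
    for (j in seq_len(n_ops)) {
      op <- ops[j]; ln <- lens[j]
      if (op %in% c("M", "=", "X")) {
        if (site_pos < rcur + ln && site_pos >= rcur) {
          return(substr(read_seq, qcur + (site_pos - rcur),
                        qcur + (site_pos - rcur)))
        }
        rcur <- rcur + ln; qcur <- qcur + ln
      } else if (op == "D" || op == "N") {
        if (site_pos < rcur + ln && site_pos >= rcur) return("del")
        rcur <- rcur + ln
      } else if (op %in% c("I", "S")) {
        qcur <- qcur + ln
      }
    }
    return(NA_character_)
  }
  # indel sites: the event sits between site_pos and site_pos + 1 (INS) or
  # removes bases starting at site_pos + 1 (DEL); a read is informative
  # only if it aligns across the anchor junction
  exp_len <- abs(nchar(alt) - nchar(ref))
  for (j in seq_len(n_ops)) {
    op <- ops[j]; ln <- lens[j]
    if (op %in% c("M", "=", "X")) {
      if (site_pos >= rcur && site_pos < rcur + ln) {
        # anchor aligned; inspect what follows
        if (site_pos < rcur + ln - 1L) {
          # next reference base aligned in the same op: no event here
          return(if (type == "DEL") "ref" else {
            "ref"
          })
        }
        # anchor is the last base of this op: the next op decides
        if (j == n_ops) return(NA_character_)
        nxt <- ops[j + 1L]; nln <- lens[j + 1L]
        if (type == "INS") {
          if (nxt == "I") return(if (nln == exp_len) "alt"
                                 else paste0("ins", nln))
          if (nxt %in% c("M", "=", "X")) return("ref")
          if (nxt == "D") return(paste0("del", nln))
          return(NA_character_)
        } else { # DEL
          if (nxt == "D") return(if (nln == exp_len) "alt"
                                 else paste0("del", nln))
          if (nxt %in% c("M", "=", "X")) return("ref")
          if (nxt == "I") return(paste0("ins", nln))
          return(NA_character_)
        }
      }
      rcur <- rcur + ln; qcur <- qcur + ln
    } else if (op == "D" || op == "N") {
      if (site_pos >= rcur && site_pos < rcur + ln) return(NA_character_)
      rcur <- rcur + ln
    } else if (op %in% c("I", "S")) {
      qcur <- qcur + ln
    }
  }
  NA_character_
}

read_placements_with_seq <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")))[[1L]]
  flag <- res$flag
  mapped <- bitwAnd(flag, 0x4L) == 0L
  width <- rep(NA_integer_, length(flag))
  has <- mapped & !is.na(res$cigar)
  width[has] <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[has])
  df <- data.frame(
    read_id = res$qname,
    mate = ifelse(bitwAnd(flag, 0x80L) != 0L, 2L, 1L),
    seq_id = ifelse(mapped, as.character(res$rname), NA_character_),
    pos = ifelse(mapped, res$pos, NA_integer_),
    end = ifelse(mapped, res$pos + width - 1L, NA_integer_),
    mapq = ifelse(mapped, res$mapq, 0L),
    mapped = mapped,
    primary = bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L,
    cigar = res$cigar,
    seq = as.character(res$seq),
    stringsAsFactors = FALSE)
  class(df) <- c("read_placements", "data.frame")
  df
}

#' Classify a candidate site from its allele tally
#'
#' The majority-allele fraction is compared to the homozygosity cutoff
#' (90% for SNVs, 70% for indels; a boundary fraction counts as
#' homozygous): at or above the cutoff the call is homozygous for the
#' majority allele (`HOM_REF` or `HOM_ALT`), below it `HET`. Sites with
#' more than two alleles at an SNV, or any allele outside the expected
#' \{ref, alt\} set, are `REVIEW`. Depth below `min_depth` is `NO_DATA`.
#'
#' @param tally one element of an `allele_tallies` list.
#' @param snv_cutoff,indel_cutoff homozygosity cutoffs.
#' @param min_depth minimum counted depth.
#' @return A list: `call` (`HOM_REF`, `HET`, `HOM_ALT`, `REVIEW`,
#'   `NO_DATA`) and `majority_fraction`.
#' @export
classify_site <- function(tally, snv_cutoff = 0.90, indel_cutoff = 0.70,
                          min_depth = 1L) {
  stopifnot(snv_cutoff > 0.5, snv_cutoff < 1, indel_cutoff > 0.5,
            indel_cutoff < 1)
  if (tally$depth < min_depth) {
    return(list(call = "NO_DATA", majority_fraction = NA_real_))
  }
  cts <- tally$counts
  frac <- max(cts) / tally$depth
  if ((tally$type == "SNV" && tally$multi_allelic) || tally$unexpected_allele) {
    return(list(call = "REVIEW", majority_fraction = frac))
  }
  cutoff <- if (tally$type == "SNV") snv_cutoff else indel_cutoff
  maj <- names(cts)[which.max(cts)]
  ref_name <- if (tally$type == "SNV") tally$ref else "ref"
  call <- if (frac >= cutoff) {
    if (identical(maj, ref_name)) "HOM_REF" else "HOM_ALT"
  } else "HET"
  list(call = call, majority_fraction = frac)
}

#' Decide whether to update a candidate reference base
#'
#' Deterministic policy: `HOM_ALT` confirms the candidate error and yields
#' `APPLY_UPDATE`; `HOM_REF` refutes it (`RETAIN_REFERENCE`); a
#' heterozygous call inside a source-library component means the
#' reference base is a real allele of the source haplotype and is
#' retained; indel sites that are not homozygous-alternate, `REVIEW`
#' classifications, heterozygous calls outside the source library, and
#' `NO_DATA` all go to `MANUAL_REVIEW`.
#'
#' @param classification result of [classify_site()].
#' @param site_type `"SNV"`, `"INS"` or `"DEL"`.
#' @param in_source_library_component logical: does the site lie in a
#'   component from the source clone library?
#' @return A list: `decision` (`APPLY_UPDATE`, `RETAIN_REFERENCE`,
#'   `MANUAL_REVIEW`) and `reason`.
#' @export
decide_update <- function(classification, site_type,
                          in_source_library_component) {
  call <- classification$call
  if (call == "HOM_ALT") {
    return(list(decision = "APPLY_UPDATE", reason = "hom_alt_confirmed"))
  }
  if (site_type %in% c("INS", "DEL")) {
    # all nonhomozygous-alternate indel calls are reviewed
    if (call == "HOM_REF") {
      return(list(decision = "RETAIN_REFERENCE", reason = "candidate_refuted"))
    }
    return(list(decision = "MANUAL_REVIEW", reason = "indel_not_hom_alt"))
  }
  switch(call,
         HOM_REF = list(decision = "RETAIN_REFERENCE",
                        reason = "candidate_refuted"),
         HET = if (isTRUE(in_source_library_component)) {
           list(decision = "RETAIN_REFERENCE",
                reason = "het_in_source_haplotype")
         } else {
           list(decision = "MANUAL_REVIEW", reason = "het_outside_source")
         },
         REVIEW = list(decision = "MANUAL_REVIEW", reason = "ambiguous_alleles"),
         NO_DATA = list(decision = "MANUAL_REVIEW", reason = "no_coverage"))
}

#' Validate a replacement mini-contig against its reference window
#'
#' Aligns the contig to the reference window with an end-free (overlap)
#' global alignment (match 1, mismatch -2, gap open -4, gap extend -1)
#' and lists every difference in window coordinates. The contig passes
#' when the difference set is exactly the expected alternate allele at the
#' target site; indel differences are left-normalized before comparison.
#'
#' @param contig contig sequence (character or [Biostrings::DNAString]).
#' @param window reference window sequence.
#' @param site_offset 1-based position of the site within the window.
#' @param ref,alt the site's REF and ALT alleles (VCF convention).
#' @param type `"SNV"`, `"INS"` or `"DEL"`.
#' @return A list: `pass` (logical), `differences` (data.frame `pos`
#'   in window coordinates, `kind`, `ref`, `alt`).
#' @export
validate_minicontig <- function(contig, window, site_offset, ref, alt, type) {
  contig <- as.character(contig); window <- as.character(window)
  aln <- Biostrings::pairwiseAlignment(
    pattern = contig, subject = window, type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 1)
  alp <- as.character(Biostrings::alignedPattern(aln))
  als <- as.character(Biostrings::alignedSubject(aln))
  aligned_contig <- sum(strsplit(alp, "")[[1L]] != "-")
  if (aligned_contig < 0.8 * nchar(contig)) {
    stop("contig aligns with less than 80% of its length inside the window")
  }
  diffs <- alignment_differences(alp, als,
                                 Biostrings::start(Biostrings::subject(aln)))
  diffs <- normalize_differences(diffs, window)
  expected <- expected_difference(site_offset, ref, alt, type, window)
  pass <- nrow(diffs) == nrow(expected) &&
    nrow(merge(diffs, expected)) == nrow(expected)
  list(pass = pass, differences = diffs)
}

# walk aligned strings; returns left-normalized differences in subject
# (window) coordinates
alignment_differences <- function(alp, als, subject_start) {
  pc <- strsplit(alp, "")[[1L]]
  sc <- strsplit(als, "")[[1L]]
  spos <- subject_start - 1L
  out <- list()
  i <- 1L
  n <- length(pc)
  while (i <= n) {
    if (sc[i] != "-" ) spos <- spos + 1L
    if (pc[i] == "-") {            # deletion relative to window
      j <- i
      del <- character()
      while (j <= n && pc[j] == "-") { del <- c(del, sc[j]); j <- j + 1L }
      out[[length(out) + 1L]] <- data.frame(
        pos = spos, kind = "DEL", ref = paste(del, collapse = ""), alt = "",
        stringsAsFactors = FALSE)
      spos <- spos + length(del) - 1L
      i <- j
    } else if (sc[i] == "-") {     # insertion relative to window
      j <- i
      ins <- character()
      while (j <= n && sc[j] == "-") { ins <- c(ins, pc[j]); j <- j + 1L }
      out[[length(out) + 1L]] <- data.frame(
        pos = spos, kind = "INS", ref = "", alt = paste(ins, collapse = ""),
        stringsAsFactors = FALSE)
      i <- j
    } else {
      if (pc[i] != sc[i]) {
        out[[length(out) + 1L]] <- data.frame(
          pos = spos, kind = "SNV", ref = sc[i], alt = pc[i],
          stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(pos = integer(), kind = character(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# shift observed indels left through identical preceding bases so
# equivalent placements compare equal to the canonical expected event
normalize_differences <- function(d, window) {
  if (nrow(d) == 0L) return(d)
  rows <- lapply(seq_len(nrow(d)), function(r) {
    if (d$kind[r] == "INS") {
      canonical_indel(d$pos[r], "INS", "", d$alt[r], window)
    } else if (d$kind[r] == "DEL") {
      canonical_indel(d$pos[r] - 1L, "DEL", d$ref[r], "", window)
    } else {
      d[r, , drop = FALSE]
    }
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

expected_difference <- function(site_offset, ref, alt, type, window) {
  if (type == "SNV") {
    data.frame(pos = site_offset, kind = "SNV", ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  } else if (type == "INS") {
    ins <- substr(alt, 2L, nchar(alt))
    canonical_indel(site_offset, "INS", "", ins, window)
  } else {
    del <- substr(ref, 2L, nchar(ref))
    canonical_indel(site_offset, "DEL", del, "", window)
  }
}

# the aligner may place an indel anywhere within a repeat run; canonicalize
# the expected event to the leftmost equivalent placement, which is also
# where a left-shifting aligner reports it. Both observed and expected go
# through the same shift so comparison is placement-invariant.
canonical_indel <- function(anchor, kind, ref, alt, window) {
  seqs <- if (kind == "INS") alt else ref
  pos <- anchor + 1L  # first affected/inserted base position in the window
  # shift left while the base before the event equals the last event base
  while (pos > 1L) {
    prev <- substr(window, pos - 1L, pos - 1L)
    last <- substr(seqs, nchar(seqs), nchar(seqs))
    if (prev != last) break
    seqs <- paste0(last, substr(seqs, 1L, nchar(seqs) - 1L))
    pos <- pos - 1L
  }
  if (kind == "INS") {
    data.frame(pos = pos - 1L, kind = "INS", ref = "", alt = seqs,
               stringsAsFactors = FALSE)
  } else {
    data.frame(pos = pos, kind = "DEL", ref = seqs, alt = "",
               stringsAsFactors = FALSE)
  }
}
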