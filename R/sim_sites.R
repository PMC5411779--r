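#' Plant candidate reference-error sites on assembly A
#'
#' Chooses well-separated positions on A inside truth-unchanged, ungapped
#' sequence, assigns each a site type (SNV, insertion or deletion, VCF
#' left-anchored convention) and a truth genotype of the underlying sample
#' (`HOM_REF`: the candidate is refuted, the reference base is real;
#' `HET`: the sample carries both alleles; `HOM_ALT`: the reference base
#' is a bona fide error), and records whether the containing component
#' belongs to the source clone library (which drives the
#' retain-heterozygous update rule).
#'
#' @param pair an `asm_pair`.
#' @param n_sites number of sites.
#' @param type_mix named numeric proportions over `SNV`, `INS`, `DEL`.
#' @param genotype_mix named numeric proportions over `HOM_REF`, `HET`,
#'   `HOM_ALT`.
#' @param flank minimum clearance (bases) between a site and region edges
#'   or neighbouring sites; also the mini-contig flank.
#' @param seed seed (default: config seed + 2).
#' @return A `data.frame` of class `candidate_sites` (also
#'   `variant_sites`): `seq_id`, `pos`, `site_id`, `ref`, `alt`, `type`,
#'   `genotype`, `in_source`.
#' @export
plant_candidate_sites <- function(pair, n_sites,
                                  type_mix = c(SNV = 0.8, INS = 0.1, DEL = 0.1),
                                  genotype_mix = c(HOM_REF = 0.2, HET = 0.4,
                                                   HOM_ALT = 0.4),
                                  flank = 60L,
                                  seed = pair$config$seed + 2L) {
  set.seed(seed)
  u <- pair$truth$unchanged
  spacing <- 2L * flank + 40L
  pool_obj <- character(); pool_pos <- integer()
  for (j in seq_len(nrow(u))) {
    lo <- u$astart[j] + flank + 10L
    hi <- u$aend[j] - flank - 10L
    if (hi < lo) next
    p <- seq.int(lo, hi, by = spacing)
    pool_obj <- c(pool_obj, rep(u$aobj[j], length(p)))
    pool_pos <- c(pool_pos, p)
  }
  if (length(pool_pos) < n_sites) {
    stop("n_sites (", n_sites, ") exceeds available candidate positions (",
         length(pool_pos), ")")
  }
  pick <- sort(sample.int(length(pool_pos), n_sites))
  seq_id <- pool_obj[pick]; pos <- pool_pos[pick]

  mix_assign <- function(mix, n) {
    mix <- mix / sum(mix)
    counts <- floor(mix * n)
    rem <- n - sum(counts)
    if (rem > 0L) {
      extra <- order(mix * n - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    sample(rep(names(mix), counts))
  }
  type <- mix_assign(type_mix, n_sites)
  genotype <- mix_assign(genotype_mix, n_sites)

  aseq <- pair$A$seq
  ref <- character(n_sites); alt <- character(n_sites)
  alphabet <- c("A", "C", "G", "T")
  for (i in seq_len(n_sites)) {
    base <- as.character(Biostrings::subseq(aseq[[seq_id[i]]], pos[i], pos[i]))
    if (type[i] == "SNV") {
      ref[i] <- base
      alt[i] <- sample(setdiff(alphabet, base), 1L)
    } else if (type[i] == "INS") {
      ilen <- sample(1:3, 1L)
      ref[i] <- base
      alt[i] <- paste0(base, paste(sample(alphabet, ilen, replace = TRUE),
                                   collapse = ""))
    } else {
      dlen <- sample(1:3, 1L)
      ref[i] <- as.character(Biostrings::subseq(aseq[[seq_id[i]]], pos[i],
                                                pos[i] + dlen))
      alt[i] <- base
    }
  }
  comp <- component_at(pair$truth$cmaps$agpA, seq_id, pos)
  acc <- sub("\\.\\d+$", "", comp)
  in_source <- unname(pair$truth$library[acc] == "source")

  df <- data.frame(seq_id = seq_id, pos = pos,
                   site_id = sprintf("site%05d", seq_len(n_sites)),
                   ref = ref, alt = alt, type = type, genotype = genotype,
                   in_source = in_source, stringsAsFactors = FALSE)
  class(df) <- c("candidate_sites", "variant_sites", "data.frame")
  df
}

#' Build single-edit replacement mini-contigs for candidate sites
#'
#' For each site, extracts the reference window `pos - flank` to
#' `pos + nchar(ref) - 1 + flank` from assembly A and substitutes the
#' alternate allele at the site, producing a contig that differs from the
#' window only at the target site.
#'
#' @param seqs assembly A sequences ([Biostrings::DNAStringSet]).
#' @param sites a `candidate_sites` / `variant_sites` data.frame.
#' @param flank window flank in bases.
#' @return A list: `contigs` (named [Biostrings::DNAStringSet]) and
#'   `windows` (data.frame `site_id`, `seq_id`, `start`, `end`).
#' @export
build_minicontigs <- function(seqs, sites, flank = 60L) {
  n <- nrow(sites)
  contigs <- character(n)
  ws <- integer(n); we <- integer(n)
  for (i in seq_len(n)) {
    s <- seqs[[sites$seq_id[i]]]
    rlen <- nchar(sites$ref[i])
    ws[i] <- max(1L, sites$pos[i] - flank)
    we[i] <- min(length(s), sites$pos[i] + rlen - 1L + flank)
    win <- as.character(Biostrings::subseq(s, ws[i], we[i]))
    off <- sites$pos[i] - ws[i]  # 0-based offset of the site in the window
    contigs[i] <- paste0(substr(win, 1L, off), sites$alt[i],
                         substr(win, off + rlen + 1L, nchar(win)))
  }
  dss <- Biostrings::DNAStringSet(contigs)
  names(dss) <- sites$site_id
  list(contigs = dss,
       windows = data.frame(site_id = sites$site_id, seq_id = sites$seq_id,
                            start = ws, end = we, stringsAsFactors = FALSE))
}

#' Simulate genotype-consistent reads over candidate sites
#'
#' Generates, per site, `depth` reads spanning the site against assembly
#' A. Each read is drawn from the reference or the alternate haplotype
#' according to the site's truth genotype (`HET` reads are alternate with
#' probability 0.5). Alternate-haplotype reads at indel sites carry the
#' event in their CIGAR. Substitution errors are applied at `error` per
#' base.
#'
#' @param seqs assembly A sequences.
#' @param sites a `candidate_sites` data.frame (needs `genotype`).
#' @param depth reads per site.
#' @param read_length read length.
#' @param error per-base substitution error rate.
#' @param mapq MAPQ assigned to every read.
#' @param seed seed.
#' @return A `read_placements` data.frame with `strand`, `seq` and `cigar`
#'   columns, suitable for [write_sam()].
#' @export
simulate_site_reads <- function(seqs, sites, depth = 30L, read_length = 100L,
                                error = 0, mapq = 60L, seed = 1L) {
  set.seed(seed)
  margin <- 5L
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- seqs[[sites$seq_id[i]]]
    type <- sites$type[i]
    rlen <- nchar(sites$ref[i]); alen <- nchar(sites$alt[i])
    extent <- switch(type, SNV = 0L, INS = alen - rlen, DEL = rlen - alen)
    pos <- sites$pos[i]
    o_max <- read_length - margin - extent - 1L
    o <- margin + sample.int(o_max - margin + 1L, depth, replace = TRUE) - 1L
    start <- pos - o
    is_alt <- switch(sites$genotype[i],
                     HOM_REF = rep(FALSE, depth),
                     HOM_ALT = rep(TRUE, depth),
                     HET = stats::runif(depth) < 0.5)
    seq <- character(depth); cigar <- character(depth)
    for (r in seq_len(depth)) {
      a <- o[r] + 1L  # bases up to and including the anchor
      if (!is_alt[r] || type == "SNV") {
        seq[r] <- as.character(Biostrings::subseq(s, start[r],
                                                  start[r] + read_length - 1L))
        cigar[r] <- paste0(read_length, "M")
        if (is_alt[r]) {
          substr(seq[r], a, a) <- sites$alt[i]
        }
      } else if (type == "INS") {
        ins <- substr(sites$alt[i], 2L, alen)
        b <- read_length - a - nchar(ins)
        seq[r] <- paste0(
          as.character(Biostrings::subseq(s, start[r], pos)),
          ins,
          as.character(Biostrings::subseq(s, pos + 1L, pos + b)))
        cigar[r] <- paste0(a, "M", nchar(ins), "I", b, "M")
      } else { # DEL
        dlen <- rlen - 1L
        b <- read_length - a
        seq[r] <- paste0(
          as.character(Biostrings::subseq(s, start[r], pos)),
          as.character(Biostrings::subseq(s, pos + dlen + 1L, pos + dlen + b)))
        cigar[r] <- paste0(a, "M", dlen, "D", b, "M")
      }
    }
    seq <- add_read_errors(seq, error)
    rows[[i]] <- data.frame(
      read_id = paste0(sites$site_id[i], "_r", seq_len(depth)),
      mate = 1L, seq_id = sites$seq_id[i], pos = start,
      end = start + read_length - 1L +
        ifelse(is_alt & type == "DEL", rlen - alen, 0L) -
        ifelse(is_alt & type == "INS", alen - rlen, 0L),
      mapq = mapq, mapped = TRUE, primary = TRUE, strand = "+",
      seq = seq, cigar = cigar, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  class(df) <- c("read_placements", "data.frame")
  df
}
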