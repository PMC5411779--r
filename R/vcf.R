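#' Read candidate variant sites from VCF
#'
#' Loads a VCF 4.x of candidate sites via VariantAnnotation and returns the
#' compact site table used by the validation and coverage modules. The site
#' type is inferred from allele lengths: equal-length single-base alleles
#' are SNVs; longer ALT than REF is an insertion, shorter a deletion
#' (left-anchored on the preceding base, VCF convention). Multi-allelic
#' records are rejected — candidate reference-error sites carry one
#' asserted alternate allele.
#'
#' @param path path to a VCF file.
#' @param fasta optional path to the assembly FASTA; when given, each
#'   site's REF allele is checked against the assembly bases and a
#'   mismatch raises an error.
#' @return A `data.frame` of class `variant_sites` with columns `seq_id`,
#'   `pos` (1-based), `site_id`, `ref`, `alt`, `type` (`"SNV"`, `"INS"`,
#'   `"DEL"`).
#' @export
read_sites <- function(path, fasta = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "asm")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt) != 1L)) {
    stop("multi-allelic VCF records are not supported for candidate sites")
  }
  df <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    site_id = names(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(alt)),
    stringsAsFactors = FALSE
  )
  df$type <- site_type(df$ref, df$alt)
  if (!is.null(fasta)) check_site_refs(df, fasta)
  class(df) <- c("variant_sites", "data.frame")
  df
}

site_type <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
         ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
}

check_site_refs <- function(sites, fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  for (i in seq_len(nrow(sites))) {
    s <- sites$seq_id[i]
    if (!s %in% names(seqs)) stop("site sequence ", s, " absent from FASTA")
    end <- sites$pos[i] + nchar(sites$ref[i]) - 1L
    if (end > length(seqs[[s]])) {
      stop("site ", sites$site_id[i], " extends past the end of ", s)
    }
    obs <- as.character(Biostrings::subseq(seqs[[s]], sites$pos[i], end))
    if (!identical(obs, sites$ref[i])) {
      stop("site ", sites$site_id[i], " REF allele '", sites$ref[i],
           "' disagrees with assembly base(s) '", obs, "'")
    }
  }
  invisible(sites)
}

#' Write candidate variant sites as VCF
#'
#' Minimal VCF 4.2 writer for the package's own site tables (candidate
#' sites, update sets, remap annotations). Round-trips through
#' [read_sites()].
#'
#' @param sites a `variant_sites` data.frame.
#' @param path output path.
#' @param contigs optional named integer vector of contig lengths for the
#'   header.
#' @param info optional character vector (same length as `sites` rows) of
#'   preformatted INFO fields; defaults to `.`.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path, contigs = NULL, info = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=asmeval")
  if (!is.null(contigs)) {
    hdr <- c(hdr, paste0("##contig=<ID=", names(contigs),
                         ",length=", as.integer(contigs), ">"))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (is.null(info)) info <- rep(".", nrow(sites))
  ord <- order(sites$seq_id, sites$pos)
  rec <- paste(sites$seq_id, sites$pos, sites$site_id, sites$ref, sites$alt,
               ".", ".", info, sep = "\t")[ord]
  writeLines(c(hdr, rec), path)
  invisible(path)
}
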