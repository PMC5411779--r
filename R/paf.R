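#' Read best-hit alignment blocks from a PAF table
#'
#' Parses a PAF file of assembly-assembly best-hit alignment blocks. Each
#' record must carry a reciprocity tag `rc:A:R` (reciprocal best hit, first
#' alignment pass) or `rc:A:N` (nonreciprocal best hit, second pass); records
#' without the tag, or with an unknown value, are rejected. An optional
#' `cg:Z:` CIGAR tag (ops `M`, `=`, `X`, `I`, `D`) is expanded into ordered
#' co-linear ungapped segments; records without a CIGAR become
#' single-segment ungapped blocks (and must then have equal query and
#' target span lengths).
#'
#' PAF coordinates (0-based, half-open) are converted to the package's
#' internal 1-based inclusive convention at this boundary. For `-` strand
#' blocks the CIGAR is walked with the query ascending from its start and
#' the target descending from its end, so the first query base of a segment
#' pairs with the highest target base of that segment.
#'
#' @param path path to a PAF file.
#' @return A `data.frame` of class `alignment_blocks`, one row per block,
#'   with columns `qname`, `qlen`, `qstart`, `qend`, `strand`, `tname`,
#'   `tlen`, `tstart`, `tend`, `pass_class` (`"RECIPROCAL"` or
#'   `"NONRECIPROCAL"`) and a list column `segments` of per-block
#'   data.frames (`qstart`, `qend`, `tstart`, `tend`, all 1-based
#'   inclusive, equal lengths per segment).
#' @seealso [project_coordinate()], [invert_blocks()], [write_paf()]
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_blocks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 12L)) {
    stop("PAF line ", which(lengths(fields) < 12L)[1L],
         " has fewer than 12 columns")
  }
  get <- function(i) vapply(fields, `[`, "", i)
  tagval <- function(x, prefix) {
    hit <- x[startsWith(x, prefix)]
    if (length(hit) == 0L) NA_character_ else sub(prefix, "", hit[1L], fixed = TRUE)
  }
  rc <- vapply(fields, tagval, "", prefix = "rc:A:")
  if (anyNA(rc)) {
    stop("PAF line ", which(is.na(rc))[1L], " lacks the rc:A: reciprocity tag")
  }
  if (any(!rc %in% c("R", "N"))) {
    stop("unknown reciprocity value '", rc[!rc %in% c("R", "N")][1L],
         "' (expected R or N)")
  }
  cg <- vapply(fields, tagval, "", prefix = "cg:Z:")
  strand <- get(5L)
  if (any(!strand %in% c("+", "-"))) stop("PAF strand must be + or -")
  blocks <- data.frame(
    qname = get(1L), qlen = as.integer(get(2L)),
    qstart = as.integer(get(3L)) + 1L, qend = as.integer(get(4L)),
    strand = strand,
    tname = get(6L), tlen = as.integer(get(7L)),
    tstart = as.integer(get(8L)) + 1L, tend = as.integer(get(9L)),
    pass_class = ifelse(rc == "R", "RECIPROCAL", "NONRECIPROCAL"),
    stringsAsFactors = FALSE
  )
  blocks$segments <- lapply(seq_len(nrow(blocks)), function(i) {
    cigar_segments(cg[i], blocks$qstart[i], blocks$qend[i],
                   blocks$tstart[i], blocks$tend[i], blocks$strand[i])
  })
  class(blocks) <- c("alignment_blocks", "data.frame")
  blocks
}

empty_blocks <- function() {
  b <- data.frame(
    qname = character(), qlen = integer(), qstart = integer(),
    qend = integer(), strand = character(), tname = character(),
    tlen = integer(), tstart = integer(), tend = integer(),
    pass_class = character(), stringsAsFactors = FALSE
  )
  b$segments <- list()
  class(b) <- c("alignment_blocks", "data.frame")
  b
}

# Expand a CIGAR into ungapped segments pairing query and target intervals.
# M/=/X consume both sides; I consumes query only; D consumes target only.
cigar_segments <- function(cigar, qstart, qend, tstart, tend, strand) {
  qspan <- qend - qstart + 1L
  tspan <- tend - tstart + 1L
  if (is.na(cigar) || !nzchar(cigar)) {
    if (qspan != tspan) {
      stop("block without CIGAR has unequal query (", qspan,
           ") and target (", tspan, ") spans")
    }
    return(data.frame(qstart = qstart, qend = qend,
                      tstart = tstart, tend = tend))
  }
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (sum(nchar(ops)) != nchar(cigar)) stop("malformed CIGAR: ", cigar)
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  if (any(!op %in% c("M", "=", "X", "I", "D"))) {
    stop("unsupported CIGAR op in: ", cigar)
  }
  qcur <- qstart
  tcur <- if (strand == "+") tstart else tend
  segs <- vector("list", length(op))
  # merge consecutive both-consuming ops into one segment
  open_q <- NA_integer_; open_t <- NA_integer_
  nseg <- 0L
  close_seg <- function() {
    if (!is.na(open_q)) {
      nseg <<- nseg + 1L
      if (strand == "+") {
        segs[[nseg]] <<- c(open_q, qcur - 1L, open_t, tcur - 1L)
      } else {
        segs[[nseg]] <<- c(open_q, qcur - 1L, tcur + 1L, open_t)
      }
      open_q <<- NA_integer_; open_t <<- NA_integer_
    }
  }
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X")) {
      if (is.na(open_q)) { open_q <- qcur; open_t <- tcur }
      qcur <- qcur + len[i]
      tcur <- if (strand == "+") tcur + len[i] else tcur - len[i]
    } else if (op[i] == "I") {
      close_seg()
      qcur <- qcur + len[i]
    } else { # D
      close_seg()
      tcur <- if (strand == "+") tcur + len[i] else tcur - len[i]
    }
  }
  close_seg()
  if (qcur - 1L != qend) {
    stop("CIGAR query consumption (", qcur - qstart,
         ") inconsistent with query span (", qspan, ")")
  }
  tok <- if (strand == "+") tcur - 1L == tend else tcur + 1L == tstart
  if (!tok) {
    stop("CIGAR target consumption inconsistent with target span (",
         tspan, ")")
  }
  m <- do.call(rbind, segs[seq_len(nseg)])
  data.frame(qstart = m[, 1L], qend = m[, 2L], tstart = m[, 3L], tend = m[, 4L])
}

#' Write alignment blocks as PAF
#'
#' Emits one PAF record per block with the `rc:A:` reciprocity tag and a
#' `cg:Z:` CIGAR reconstructed from the block's segments (match runs with
#' `I`/`D` between them). Round-trips through [read_paf()].
#'
#' @param blocks an `alignment_blocks` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(blocks, path) {
  lines <- vapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    segs <- b$segments[[1L]]
    cig <- segments_to_cigar(segs, b$strand)
    paste(b$qname, b$qlen, b$qstart - 1L, b$qend, b$strand,
          b$tname, b$tlen, b$tstart - 1L, b$tend,
          sum(segs$qend - segs$qstart + 1L),
          b$qend - b$qstart + 1L, 60L,
          paste0("rc:A:", ifelse(b$pass_class == "RECIPROCAL", "R", "N")),
          paste0("cg:Z:", cig),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

segments_to_cigar <- function(segs, strand) {
  n <- nrow(segs)
  out <- character(0L)
  for (i in seq_len(n)) {
    out <- c(out, paste0(segs$qend[i] - segs$qstart[i] + 1L, "M"))
    if (i < n) {
      qi <- segs$qstart[i + 1L] - segs$qend[i] - 1L
      ti <- if (strand == "+") segs$tstart[i + 1L] - segs$tend[i] - 1L
            else segs$tstart[i] - segs$tend[i + 1L] - 1L
      if (qi > 0L) out <- c(out, paste0(qi, "I"))
      if (ti > 0L) out <- c(out, paste0(ti, "D"))
    }
  }
  paste(out, collapse = "")
}

#' Project a query coordinate through an alignment block
#'
#' Strand-aware linear projection of a 1-based query position onto the
#' target through the block's ungapped segments. On `-` strand blocks the
#' target offset decreases as the query offset increases. Over the aligned
#' (non-indel) positions of a block this projection is a bijection.
#'
#' @param block one row of an `alignment_blocks` data.frame (or a list with
#'   fields `strand` and `segments`).
#' @param pos 1-based query position(s).
#' @return Integer vector of target positions; `NA` where `pos` is
#'   unprojectable (inside a query-only insertion between segments, or
#'   outside the block). Malformed blocks raise errors instead.
#' @export
project_coordinate <- function(block, pos) {
  segs <- if (is.data.frame(block$segments)) block$segments else block$segments[[1L]]
  strand <- block$strand[[1L]]
  out <- rep(NA_integer_, length(pos))
  for (j in seq_len(nrow(segs))) {
    inside <- !is.na(pos) & pos >= segs$qstart[j] & pos <= segs$qend[j]
    if (any(inside)) {
      off <- pos[inside] - segs$qstart[j]
      out[inside] <- if (strand == "+") segs$tstart[j] + off
                     else segs$tend[j] - off
    }
  }
  out
}

#' Swap the query and target sides of alignment blocks
#'
#' Re-orients blocks so that the former target assembly becomes the query,
#' preserving the pass class and per-segment pairing. Projecting a position
#' through a block and then through its inversion is the identity on every
#' aligned base.
#'
#' @param blocks an `alignment_blocks` data.frame.
#' @return The inverted `alignment_blocks`.
#' @export
invert_blocks <- function(blocks) {
  inv <- blocks
  inv$qname <- blocks$tname; inv$qlen <- blocks$tlen
  inv$qstart <- blocks$tstart; inv$qend <- blocks$tend
  inv$tname <- blocks$qname; inv$tlen <- blocks$qlen
  inv$tstart <- blocks$qstart; inv$tend <- blocks$qend
  inv$segments <- lapply(seq_len(nrow(blocks)), function(i) {
    s <- blocks$segments[[i]]
    out <- data.frame(qstart = s$tstart, qend = s$tend,
                      tstart = s$qstart, tend = s$qend)
    if (blocks$strand[i] == "-") out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  class(inv) <- c("alignment_blocks", "data.frame")
  inv
}

#' Construct alignment blocks programmatically
#'
#' Convenience constructor used by the simulator and in tests: builds an
#' `alignment_blocks` data.frame from parallel vectors, each block a single
#' ungapped segment (query and target spans must be equal length).
#'
#' @param qname,qstart,qend query sequence name and 1-based inclusive span.
#' @param tname,tstart,tend target sequence name and span.
#' @param strand `"+"` or `"-"` per block.
#' @param pass_class `"RECIPROCAL"` or `"NONRECIPROCAL"` per block.
#' @param qlen,tlen sequence lengths (default: span ends).
#' @return An `alignment_blocks` data.frame.
#' @export
make_blocks <- function(qname, qstart, qend, tname, tstart, tend,
                        strand = "+", pass_class = "RECIPROCAL",
                        qlen = NULL, tlen = NULL) {
  n <- length(qname)
  b <- data.frame(
    qname = qname, qlen = if (is.null(qlen)) as.integer(qend) else as.integer(qlen),
    qstart = as.integer(qstart), qend = as.integer(qend),
    strand = rep_len(strand, n),
    tname = tname, tlen = if (is.null(tlen)) as.integer(tend) else as.integer(tlen),
    tstart = as.integer(tstart), tend = as.integer(tend),
    pass_class = rep_len(pass_class, n),
    stringsAsFactors = FALSE
  )
  if (any(b$qend - b$qstart != b$tend - b$tstart)) {
    stop("single-segment blocks must have equal query and target spans")
  }
  b$segments <- lapply(seq_len(n), function(i) {
    data.frame(qstart = b$qstart[i], qend = b$qend[i],
               tstart = b$tstart[i], tend = b$tend[i])
  })
  class(b) <- c("alignment_blocks", "data.frame")
  b
}
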