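#' Read an AGP v2.0 component map
#'
#' Parses an AGP file describing how assembled objects (chromosomes,
#' scaffolds) are built from ordered components and gaps. Component rows
#' carry accession.version provenance; gap rows carry a length and a
#' spanned/unspanned kind. All coordinates are kept in the AGP convention
#' (1-based, inclusive), which is also the package's internal convention.
#'
#' Structural invariants are enforced: rows of one object must be
#' contiguous, non-overlapping and ordered by part number, and the object
#' span of a component row must have the same length as its component span.
#'
#' @param path path to an AGP v2.0 file (plain text; `#` comments allowed).
#' @return A `data.frame` of class `agp` with one row per AGP line and
#'   columns `object`, `object_beg`, `object_end`, `part_number`,
#'   `component_type`, `component_id`, `component_beg`, `component_end`,
#'   `orientation`, `gap_length`, `gap_type`, `linkage`. Gap rows have `NA`
#'   component fields; component rows have `NA` gap fields.
#' @seealso [write_agp()], [agp_gaps()], [unchanged_regions()]
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_agp())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    stop("AGP line ", which(nf < 8L)[1L], " has fewer than 8 columns")
  }
  get <- function(i) vapply(fields, function(x) if (length(x) >= i) x[i] else NA_character_, "")
  c5 <- get(5L)
  is_gap <- c5 %in% c("N", "U")
  df <- data.frame(
    object = get(1L),
    object_beg = as.integer(get(2L)),
    object_end = as.integer(get(3L)),
    part_number = as.integer(get(4L)),
    component_type = c5,
    component_id = ifelse(is_gap, NA_character_, get(6L)),
    component_beg = ifelse(is_gap, NA, suppressWarnings(as.integer(get(7L)))),
    component_end = ifelse(is_gap, NA, suppressWarnings(as.integer(get(8L)))),
    orientation = ifelse(is_gap, NA_character_, get(9L)),
    gap_length = ifelse(is_gap, suppressWarnings(as.integer(get(6L))), NA_integer_),
    gap_type = ifelse(is_gap, get(7L), NA_character_),
    linkage = ifelse(is_gap, get(8L), NA_character_),
    stringsAsFactors = FALSE
  )
  validate_agp(df)
  class(df) <- c("agp", "data.frame")
  df
}

empty_agp <- function() {
  df <- data.frame(
    object = character(), object_beg = integer(), object_end = integer(),
    part_number = integer(), component_type = character(),
    component_id = character(), component_beg = integer(),
    component_end = integer(), orientation = character(),
    gap_length = integer(), gap_type = character(), linkage = character(),
    stringsAsFactors = FALSE
  )
  class(df) <- c("agp", "data.frame")
  df
}

validate_agp <- function(df) {
  if (any(is.na(df$object_beg)) || any(is.na(df$object_end))) {
    stop("AGP object coordinates must be integers")
  }
  if (any(df$object_beg > df$object_end)) {
    bad <- which(df$object_beg > df$object_end)[1L]
    stop("AGP object span inverted for object ", df$object[bad],
         " part ", df$part_number[bad])
  }
  is_gap <- df$component_type %in% c("N", "U")
  if (any(!is_gap)) {
    comp <- df[!is_gap, ]
    if (any(is.na(comp$component_beg)) || any(is.na(comp$component_end))) {
      stop("AGP component rows must carry integer component coordinates")
    }
    if (any(!comp$orientation %in% c("+", "-"))) {
      bad <- comp[!comp$orientation %in% c("+", "-"), ]
      stop("AGP component row has unsupported orientation '",
           bad$orientation[1L], "' (object ", bad$object[1L],
           " part ", bad$part_number[1L], ")")
    }
    olen <- comp$object_end - comp$object_beg + 1L
    clen <- comp$component_end - comp$component_beg + 1L
    if (any(olen != clen)) {
      bad <- which(olen != clen)[1L]
      stop("AGP object span length != component span length for object ",
           comp$object[bad], " part ", comp$part_number[bad])
    }
  }
  if (any(is_gap)) {
    gaps <- df[is_gap, ]
    if (any(is.na(gaps$gap_length)) || any(gaps$gap_length < 1L)) {
      stop("AGP gap rows must have gap_length >= 1")
    }
  }
  for (obj in unique(df$object)) {
    rows <- df[df$object == obj, ]
    ord <- order(rows$part_number)
    rows <- rows[ord, ]
    if (any(diff(rows$part_number) != 1L) || rows$part_number[1L] != 1L) {
      stop("AGP part numbers for object ", obj, " are not 1..n")
    }
    if (rows$object_beg[1L] != 1L) {
      stop("AGP object ", obj, " does not start at base 1 (part ",
           rows$part_number[1L], ")")
    }
    if (nrow(rows) > 1L) {
      gap_ok <- rows$object_beg[-1L] == rows$object_end[-nrow(rows)] + 1L
      if (any(!gap_ok)) {
        bad <- which(!gap_ok)[1L] + 1L
        stop("AGP rows for object ", obj,
             " are not contiguous/non-overlapping at part ",
             rows$part_number[bad])
      }
    }
  }
  invisible(df)
}

#' Write an AGP v2.0 component map
#'
#' Inverse of [read_agp()]: `read_agp(write_agp(x, f))` reproduces `x` on
#' all fields.
#'
#' @param agp an `agp` data.frame as returned by [read_agp()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  is_gap <- agp$component_type %in% c("N", "U")
  c6 <- ifelse(is_gap, as.character(agp$gap_length), agp$component_id)
  c7 <- ifelse(is_gap, agp$gap_type, as.character(agp$component_beg))
  c8 <- ifelse(is_gap, agp$linkage, as.character(agp$component_end))
  c9 <- ifelse(is_gap, "na", agp$orientation)
  lines <- paste(agp$object, agp$object_beg, agp$object_end, agp$part_number,
                 agp$component_type, c6, c7, c8, c9, sep = "\t")
  writeLines(c("##agp-version\t2.0", lines), path)
  invisible(path)
}

#' Gap intervals of an AGP
#'
#' @param agp an `agp` data.frame.
#' @return A [GenomicRanges::GRanges] of the gap rows (1-based, inclusive),
#'   with metadata columns `gap_type` and `linkage`.
#' @export
agp_gaps <- function(agp) {
  g <- agp[agp$component_type %in% c("N", "U"), ]
  GenomicRanges::GRanges(
    seqnames = g$object,
    ranges = IRanges::IRanges(start = g$object_beg, end = g$object_end),
    gap_type = g$gap_type, linkage = g$linkage
  )
}

#' Component at object positions
#'
#' Looks up the AGP component accession.version under each (object,
#' position) query. Positions falling in gap rows or outside any row
#' return `NA`.
#'
#' @param agp an `agp` data.frame.
#' @param seq_id character vector of object names.
#' @param pos integer vector of 1-based positions, recycled with `seq_id`.
#' @return character vector of component ids.
#' @export
component_at <- function(agp, seq_id, pos) {
  n <- max(length(seq_id), length(pos))
  seq_id <- rep_len(seq_id, n)
  pos <- rep_len(pos, n)
  comp <- agp[!agp$component_type %in% c("N", "U"), ]
  q <- GenomicRanges::GRanges(seq_id, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(comp$object,
                              IRanges::IRanges(comp$object_beg, comp$object_end))
  hits <- GenomicRanges::findOverlaps(q, s, select = "first")
  comp$component_id[hits]
}
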