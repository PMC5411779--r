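#' Simulator configuration
#'
#' Parameters of the two-version assembly-pair simulator. One global
#' integer seed drives all randomness through a single generator stream,
#' so an identical configuration yields byte-identical outputs.
#'
#' The defaults emulate a clone-based reference pair at desk scale: 0.41
#' GC, alpha-satellite-like 171-bp monomers, and the 50-kbp convention for
#' gaps of unknown size, so that downstream length accounting can
#' distinguish the gap convention from real missing sequence.
#'
#' @param n_chromosomes number of donor chromosomes.
#' @param chromosome_length length of each donor chromosome (bases).
#' @param gc_fraction expected GC fraction of random donor sequence.
#' @param segdup_count,segdup_length,segdup_divergence background segmental
#'   duplication pairs implanted in the donor (count per genome, length in
#'   bases, per-copy substitution divergence).
#' @param satellite_monomer_length,satellite_copy_count,satellite_divergence
#'   the satellite array: a tandem repeat of `satellite_copy_count` copies
#'   of a `satellite_monomer_length`-bp monomer, each copy carrying
#'   `satellite_divergence` substitution divergence (default 5%, enough to
#'   make per-copy alignment ambiguous).
#' @param default_gap_length written length of gaps of unknown size
#'   (default 50,000 bases, the reference convention).
#' @param component_length tile length of the baseline AGP component grid.
#' @param read_length,insert_mean,insert_sd paired-end read geometry;
#'   insert sizes are drawn from Normal(`insert_mean`, `insert_sd`)
#'   truncated below at `read_length`.
#' @param per_base_error_rate substitution error rate per sequenced base,
#'   in `[0, 0.1)`.
#' @param depth fold sequencing coverage of the read simulator.
#' @param contaminant_fraction fraction of read pairs replaced by random
#'   sequence unmappable on any assembly (adapter/contaminant emulation).
#' @param source_library_fraction fraction of baseline components attributed
#'   to the source clone library whose haplotype the reference preserves
#'   (drives the retain-heterozygous rule downstream).
#' @param seed integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chromosome_length = 1000000L,
                       gc_fraction = 0.41,
                       segdup_count = 0L,
                       segdup_length = 20000L,
                       segdup_divergence = 0.02,
                       satellite_monomer_length = 171L,
                       satellite_copy_count = 100L,
                       satellite_divergence = 0.05,
                       default_gap_length = 50000L,
                       component_length = 100000L,
                       read_length = 150L,
                       insert_mean = 450L,
                       insert_sd = 50L,
                       per_base_error_rate = 0,
                       depth = 30,
                       contaminant_fraction = 0,
                       source_library_fraction = 0.7,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    gc_fraction = gc_fraction,
    segdup_count = as.integer(segdup_count),
    segdup_length = as.integer(segdup_length),
    segdup_divergence = segdup_divergence,
    satellite_monomer_length = as.integer(satellite_monomer_length),
    satellite_copy_count = as.integer(satellite_copy_count),
    satellite_divergence = satellite_divergence,
    default_gap_length = as.integer(default_gap_length),
    component_length = as.integer(component_length),
    read_length = as.integer(read_length),
    insert_mean = as.integer(insert_mean),
    insert_sd = as.numeric(insert_sd),
    per_base_error_rate = per_base_error_rate,
    depth = depth,
    contaminant_fraction = contaminant_fraction,
    source_library_fraction = source_library_fraction,
    seed = as.integer(seed)
  )
  lens <- c("chromosome_length", "segdup_length", "satellite_monomer_length",
            "default_gap_length", "component_length", "read_length",
            "insert_mean")
  for (f in lens) {
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L) stop("config field ", f, " must be positive")
  }
  if (cfg$n_chromosomes < 1L) stop("need at least one chromosome")
  if (cfg$per_base_error_rate < 0 || cfg$per_base_error_rate >= 0.1) {
    stop("per_base_error_rate must be in [0, 0.1)")
  }
  if (cfg$gc_fraction <= 0 || cfg$gc_fraction >= 1) stop("gc_fraction must be in (0,1)")
  if (cfg$depth <= 0) stop("depth must be positive")
  if (cfg$insert_mean < cfg$read_length) stop("insert_mean must be >= read_length")
  if (cfg$contaminant_fraction < 0 || cfg$contaminant_fraction >= 1) {
    stop("contaminant_fraction must be in [0,1)")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Curation events for the simulator
#'
#' Constructors for the implanted curation events that differentiate the
#' two assembly versions. Assembly A plays the older version (it carries
#' the defects); assembly B plays the curated update. Event loci are
#' allocated deterministically and non-overlappingly on the donor by
#' [simulate_assembly_pair()]; a `chrom` index can pin an event to a donor
#' chromosome.
#'
#' * `ev_false_duplication(length, divergence)` — A carries a near-identical
#'   extra copy of a donor locus (a false duplication); B carries one copy.
#'   With `divergence = 0` the copies are unresolvable at read scale and
#'   placements inside them get MAPQ 0 on A.
#' * `ev_collapse(length, divergence, dest)` — the donor (and B) carry two
#'   copies of a locus; A collapsed them into one. `dest` places the
#'   B-only copy: `"same_arm"`, `"other_arm"`, `"same_pericen"`,
#'   `"other_pericen"` (adjacent to the satellite array, inside the
#'   centromere annotation), `"scaffold"` or `"scaffold_cen"` (an unplaced
#'   scaffold, the latter carrying satellite-associated sequence). Reads
#'   truly from the B-only copy place on the retained copy in A and on
#'   their own copy in B — the genome-scale mechanism by which read pairs
#'   move between reference versions. With `divergence = 0` the B copies are
#'   unresolvable and get MAPQ 0 on B.
#' * `ev_gap_closure(length)` — A represents the locus as an N gap written
#'   at the default gap convention length; B carries the `length` real
#'   bases (new sequence).
#' * `ev_centromere_model()` — A has a centromeric N gap; B carries the
#'   satellite array model (new sequence, centromere-annotated, MAPQ 0).
#' * `ev_inversion(length)` — A carries the locus inverted relative to B.
#' * `ev_base_error()` — A carries a single erroneous base; B's component
#'   is re-finished (version bump).
#' * `ev_retile(length)` — the region's tiling path was replaced: B records
#'   new component accession.versions over the span without sequence change.
#' * `ev_alt_locus(novel_length, flank)` — B's full assembly gains an
#'   alternate-locus scaffold: two `flank`-bp anchors copied from a donor
#'   locus around a `novel_length`-bp novel core absent from both primary
#'   units.
#'
#' @param length event length in donor bases.
#' @param divergence substitution divergence between copies.
#' @param dest placement of the B-only copy (`ev_collapse`).
#' @param novel_length,flank alternate-locus geometry (`ev_alt_locus`).
#' @param chrom optional donor chromosome index.
#' @return A list of class `sim_event`.
#' @name sim_events
NULL

new_event <- function(kind, length, chrom = NULL, ...) {
  ev <- list(kind = kind, length = as.integer(length),
             chrom = if (is.null(chrom)) NA_integer_ else as.integer(chrom),
             ...)
  if (ev$length < 1L) stop("event length must be positive")
  class(ev) <- "sim_event"
  ev
}

#' @rdname sim_events
#' @export
ev_false_duplication <- function(length = 20000L, divergence = 0, chrom = NULL) {
  new_event("FALSE_DUPLICATION", length, chrom, divergence = divergence)
}

#' @rdname sim_events
#' @export
ev_collapse <- function(length = 20000L, divergence = 0.02,
                        dest = c("same_arm", "other_arm", "same_pericen",
                                 "other_pericen", "scaffold", "scaffold_cen"),
                        chrom = NULL) {
  dest <- match.arg(dest)
  new_event("COLLAPSE", length, chrom, divergence = divergence, dest = dest)
}

#' @rdname sim_events
#' @export
ev_gap_closure <- function(length = 6000L, chrom = NULL) {
  new_event("GAP_CLOSURE", length, chrom)
}

#' @rdname sim_events
#' @export
ev_centromere_model <- function() {
  new_event("CENTROMERE_MODEL", 1L, 1L)  # length resolved from satellite config
}

#' @rdname sim_events
#' @export
ev_inversion <- function(length = 30000L, chrom = NULL) {
  new_event("INVERSION", length, chrom)
}

#' @rdname sim_events
#' @export
ev_base_error <- function(chrom = NULL) {
  new_event("BASE_ERROR", 1L, chrom)
}

#' @rdname sim_events
#' @export
ev_retile <- function(length = 50000L, chrom = NULL) {
  new_event("RETILE", length, chrom)
}

#' @rdname sim_events
#' @export
ev_alt_locus <- function(novel_length = 10000L, flank = 5000L, chrom = NULL) {
  new_event("ALT_LOCUS", as.integer(2L * flank), chrom,
            novel_length = as.integer(novel_length), flank = as.integer(flank))
}

# -- low-level sequence helpers ------------------------------------------

random_dna <- function(n, gc) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# substitution-only mutation: preserves length
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  idx <- sample.int(n, k)
  alphabet <- c("A", "C", "G", "T")
  for (i in idx) {
    chars[i] <- sample(setdiff(alphabet, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}
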