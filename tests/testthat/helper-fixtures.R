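# Shared simulated fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# rich scenario exercising every event kind and movement destination
movement_events <- function() {
  list(
    ev_false_duplication(20000, divergence = 0),
    ev_collapse(15000, divergence = 0.02, dest = "same_arm"),
    ev_collapse(12000, divergence = 0.02, dest = "other_arm"),
    ev_collapse(10000, divergence = 0.02, dest = "same_pericen"),
    ev_collapse(10000, divergence = 0, dest = "other_pericen"),
    ev_collapse(12000, divergence = 0.02, dest = "scaffold"),
    ev_collapse(12000, divergence = 0.02, dest = "scaffold_cen"),
    ev_gap_closure(6000),
    ev_inversion(30000),
    ev_base_error(),
    ev_retile(50000),
    ev_centromere_model(),
    ev_alt_locus(novel_length = 8000, flank = 3000)
  )
}

movement_pair <- function() {
  fixture("movement_pair", function() {
    cfg <- sim_config(n_chromosomes = 2, chromosome_length = 1000000,
                      depth = 3, contaminant_fraction = 0.005, seed = 11)
    simulate_assembly_pair(cfg, movement_events())
  })
}

movement_reads <- function() {
  fixture("movement_reads", function() simulate_reads(movement_pair()))
}

# plain pair with no events (identity case)
plain_pair <- function() {
  fixture("plain_pair", function() {
    simulate_assembly_pair(
      sim_config(n_chromosomes = 2, chromosome_length = 300000, seed = 4),
      list())
  })
}

seqlens_of <- function(dss) stats::setNames(Biostrings::width(dss), names(dss))

mk_tally <- function(counts, type = "SNV", ref = "A", alt = "G") {
  list(site_id = "s", counts = counts, depth = sum(counts),
       multi_allelic = length(counts) > 2L,
       unexpected_allele = any(!names(counts) %in%
                                 if (type == "SNV") c(ref, alt)
                               else c("ref", "alt")),
       type = type, ref = ref, alt = alt)
}
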