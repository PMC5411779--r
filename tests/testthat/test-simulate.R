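test_that("config invariants are enforced", {
  expect_error(sim_config(per_base_error_rate = 0.2), "error_rate")
  expect_error(sim_config(chromosome_length = 0), "positive")
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(insert_mean = 100, read_length = 150), "insert_mean")
})

test_that("identical seed gives byte-identical assemblies and reads", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 200000, depth = 2,
                    seed = 99)
  evs <- list(ev_collapse(10000, dest = "same_arm"), ev_gap_closure(3000))
  p1 <- simulate_assembly_pair(cfg, evs)
  p2 <- simulate_assembly_pair(cfg, evs)
  expect_identical(as.character(p1$A$seq), as.character(p2$A$seq))
  expect_identical(as.character(p1$B$seq), as.character(p2$B$seq))
  expect_identical(p1$A$agp, p2$A$agp)
  r1 <- simulate_reads(p1)
  r2 <- simulate_reads(p2)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth$A, r2$truth$A)
})

test_that("no events gives identical assemblies and one reciprocal block per chromosome", {
  p <- plain_pair()
  expect_identical(as.character(p$A$seq),
                   as.character(p$B$seq[p$B$primary]))
  expect_equal(nrow(p$truth$blocks), 2L)
  expect_true(all(p$truth$blocks$pass_class == "RECIPROCAL"))
  expect_equal(p$truth$blocks$qend - p$truth$blocks$qstart + 1L,
               unname(Biostrings::width(p$A$seq)))
})

test_that("realized GC is within the binomial tolerance at 1 Mb", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 1000000,
                    gc_fraction = 0.41, seed = 21)
  p <- simulate_assembly_pair(cfg, list())
  gc <- Biostrings::letterFrequency(p$A$seq[[1]], "GC", as.prob = TRUE)[1]
  # 3 binomial SD at n = 1e6, p = 0.41 is ~0.0015, well under the 0.02 budget
  expect_lt(abs(gc - 0.41), 0.02)
})

test_that("gap closure writes the default 50-kbp gap in A over real sequence in B", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 300000, seed = 13)
  p <- simulate_assembly_pair(cfg, list(ev_gap_closure(6000)))
  ev <- p$events
  agp_gap <- p$A$agp[p$A$agp$component_type == "N", ]
  expect_equal(nrow(agp_gap), 1L)
  expect_equal(agp_gap$gap_length, 50000L)
  # ungapped length difference at the locus equals the missing sequence
  a_ungapped <- sum(Biostrings::width(p$A$seq)) -
    sum(Biostrings::letterFrequency(p$A$seq, "N"))
  b_ungapped <- sum(Biostrings::width(p$B$seq[p$B$primary]))
  expect_equal(b_ungapped - a_ungapped, 6000L)
  # the B span is new sequence with a fresh component accession
  newacc <- p$B$agp$component_id[p$B$agp$object_beg == ev$start &
                                   p$B$agp$object_end == ev$end]
  expect_match(newacc, "^SIMN")
})

test_that("satellite array and centromere model have the configured geometry", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 300000,
                    satellite_monomer_length = 171, satellite_copy_count = 100,
                    seed = 5)
  p <- simulate_assembly_pair(cfg, list(ev_centromere_model()))
  ev <- p$events
  expect_equal(ev$end - ev$start + 1L, 171L * 100L)
  # A carries an N gap, B carries the satellite
  cen <- p$truth$cen_B
  expect_equal(sum(GenomicRanges::width(cen)), 17100L)
  asq <- as.character(p$A$seq[[1]])
  expect_true(grepl("N", asq, fixed = TRUE))
  expect_false(grepl("N", as.character(p$B$seq[[1]]), fixed = TRUE))
  # tandem monomers diverge by about the configured 5%
  arr <- Biostrings::subseq(p$B$seq[[1]], ev$start, ev$end)
  m1 <- as.character(Biostrings::subseq(arr, 1, 171))
  m2 <- as.character(Biostrings::subseq(arr, 172, 342))
  mm <- sum(strsplit(m1, "")[[1]] != strsplit(m2, "")[[1]])
  expect_gt(mm, 0)
  expect_lt(mm / 171, 0.25)
})

test_that("false duplication and collapse produce the definitional truth labels", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_length = 400000, seed = 17)
  p <- simulate_assembly_pair(cfg, list(
    ev_false_duplication(20000, divergence = 0.01),
    ev_collapse(15000, divergence = 0.02, dest = "other_arm")))
  la <- p$truth$labels_A
  lb <- p$truth$labels_B
  expect_equal(sum(GenomicRanges::width(la[la$label == "EXPANDED"])), 20000L)
  expect_equal(sum(GenomicRanges::width(la[la$label == "COLLAPSED"])), 15000L)
  expect_equal(sum(GenomicRanges::width(lb[lb$label == "COLLAPSED"])), 20000L)
  expect_equal(sum(GenomicRanges::width(lb[lb$label == "EXPANDED"])), 15000L)
  # labels partition each assembly
  expect_equal(sum(GenomicRanges::width(la)), sum(Biostrings::width(p$A$seq)))
  expect_equal(sum(GenomicRanges::width(lb)), sum(Biostrings::width(p$B$seq)))
})

test_that("truth-unique bases project through truth blocks and back to themselves", {
  withr::local_seed(31)
  p <- movement_pair()
  blocks <- p$truth$blocks
  inv <- invert_blocks(blocks)
  la <- p$truth$labels_A
  uni <- la[la$label == "UNIQUE"]
  for (k in sample(length(uni), min(25, length(uni)))) {
    nm <- as.character(GenomicRanges::seqnames(uni))[k]
    pos <- as.integer(round((GenomicRanges::start(uni)[k] +
                               GenomicRanges::end(uni)[k]) / 2))
    hit <- which(blocks$qname == nm & blocks$qstart <= pos &
                   blocks$qend >= pos & blocks$pass_class == "RECIPROCAL")
    expect_equal(length(hit), 1L)
    tpos <- project_coordinate(blocks[hit, ], pos)
    back <- project_coordinate(inv[hit, ], tpos)
    expect_equal(back, pos)
  }
})

test_that("read pair count follows depth within Poisson tolerance and reads match sources", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 1000000,
                    depth = 30, read_length = 150, seed = 23)
  p <- simulate_assembly_pair(cfg, list())
  rd <- simulate_reads(p)
  expected <- 30 * 1e6 / (2 * 150)
  expect_lt(abs(rd$n_pairs - expected), 3 * sqrt(expected) + 1)
  # error rate 0: every truth-placed read equals the reference substring
  Bf <- rd$truth$B_full
  withr::local_seed(1)
  for (i in sample(which(Bf$mapped), 100)) {
    refseq <- as.character(Biostrings::subseq(p$B$seq[[Bf$seq_id[i]]],
                                              Bf$pos[i], Bf$end[i]))
    readseq <- Bf$seq[i]
    if (Bf$strand[i] == "-") {
      readseq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(readseq)))
    }
    expect_identical(readseq, refseq)
  }
})

test_that("gap-closure reads are truth-unmapped on A and mapped on B", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 300000, depth = 5,
                    seed = 29)
  p <- simulate_assembly_pair(cfg, list(ev_gap_closure(6000)))
  rd <- simulate_reads(p)
  ev <- p$events
  A <- rd$truth$A; Bp <- rd$truth$B_primary
  inside <- Bp$mapped & Bp$pos >= ev$start & Bp$end <= ev$end
  expect_gt(sum(inside), 10)
  expect_true(all(!A$mapped[inside]))
  expect_true(all(Bp$mapped[inside]))
})

test_that("candidate sites have consistent alleles, genotypes and mini-contigs", {
  p <- movement_pair()
  sites <- plant_candidate_sites(p, 150)
  expect_equal(nrow(sites), 150L)
  expect_setequal(unique(sites$type), c("SNV", "INS", "DEL"))
  expect_setequal(unique(sites$genotype), c("HOM_REF", "HET", "HOM_ALT"))
  # ref alleles match assembly A
  for (i in seq_len(nrow(sites))) {
    obs <- as.character(Biostrings::subseq(
      p$A$seq[[sites$seq_id[i]]], sites$pos[i],
      sites$pos[i] + nchar(sites$ref[i]) - 1L))
    expect_identical(obs, sites$ref[i])
  }
  mc <- build_minicontigs(p$A$seq, sites)
  # each contig differs from its window exactly at the site, by construction
  for (i in sample(nrow(sites), 20)) {
    w <- mc$windows[i, ]
    win <- as.character(Biostrings::subseq(p$A$seq[[w$seq_id]], w$start, w$end))
    ctg <- as.character(mc$contigs[[i]])
    off <- sites$pos[i] - w$start
    expect_identical(substr(ctg, 1, off), substr(win, 1, off))
    expect_identical(substr(ctg, off + 1, off + nchar(sites$alt[i])),
                     sites$alt[i])
  }
  expect_error(plant_candidate_sites(p, 1e6), "exceeds")
})

test_that("layout rejects features that do not fit and overlapping events", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 100000, seed = 1)
  expect_error(
    simulate_assembly_pair(cfg, list(ev_retile(95000))),
    "exceed")
})
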