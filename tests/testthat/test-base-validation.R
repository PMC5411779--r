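test_that("pileup counts only primary MAPQ-passing reads and honors site types", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGTTGCAAT", 120)))
  sites <- data.frame(seq_id = "chr1", pos = c(300L, 501L, 702L),
                      site_id = c("snv", "ins", "del"),
                      ref = c(substr(as.character(seqs[[1]]), 300, 300),
                              substr(as.character(seqs[[1]]), 501, 501),
                              substr(as.character(seqs[[1]]), 702, 704)),
                      alt = NA, stringsAsFactors = FALSE)
  sites$alt <- c("G", paste0(sites$ref[2], "TT"), substr(sites$ref[3], 1, 1))
  sites$type <- c("SNV", "INS", "DEL")
  sites$genotype <- c("HET", "HOM_ALT", "HOM_REF")
  rd <- simulate_site_reads(seqs, sites, depth = 40, read_length = 80,
                            seed = 9)
  # push one read below the MAPQ threshold: it must not be counted
  rd$mapq[1] <- 10L
  tf <- withr::local_tempfile(fileext = ".sam")
  write_sam(rd, c(chr1 = 1200L), tf)
  tl <- pileup_tally(tf, sites, min_mapq = 20L)
  expect_equal(tl[["snv"]]$depth, 39L)
  expect_setequal(names(tl[["snv"]]$counts), c(sites$ref[1], "G"))
  expect_equal(names(tl[["ins"]]$counts), "alt")
  expect_equal(tl[["ins"]]$counts[["alt"]], 40L)
  expect_equal(names(tl[["del"]]$counts), "ref")
  # no overlapping reads: NO_DATA-bound tally with depth 0
  far <- data.frame(seq_id = "chr1", pos = 1190L, site_id = "far",
                    ref = substr(as.character(seqs[[1]]), 1190, 1190),
                    alt = "A", type = "SNV", stringsAsFactors = FALSE)
  tl2 <- pileup_tally(tf, far, min_mapq = 20L)
  expect_equal(tl2[["far"]]$depth, 0L)
  expect_equal(classify_site(tl2[["far"]])$call, "NO_DATA")
  # site beyond the contig end is an error
  off <- far; off$pos <- 2000L; off$site_id <- "off"
  expect_error(pileup_tally(tf, off, seqlens = c(chr1 = 1200L)), "contig end")
})

test_that("deletions spanning an SNV site count as a distinct del allele", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGTTGCAAT", 30)))
  base <- substr(as.character(seqs[[1]]), 100, 100)
  rd <- data.frame(read_id = c("a", "b"), mate = 1L, seq_id = "chr1",
                   pos = c(61L, 61L), end = c(140L, 143L), mapq = 60L,
                   mapped = TRUE, primary = TRUE, strand = "+",
                   seq = c(substr(as.character(seqs[[1]]), 61, 140),
                           paste0(substr(as.character(seqs[[1]]), 61, 97),
                                  substr(as.character(seqs[[1]]), 101, 143))),
                   cigar = c("80M", "37M3D43M"), stringsAsFactors = FALSE)
  sites <- data.frame(seq_id = "chr1", pos = 100L, site_id = "s",
                      ref = base, alt = "T", type = "SNV",
                      stringsAsFactors = FALSE)
  tl <- pileup_tally(rd, sites)
  expect_setequal(names(tl[["s"]]$counts), c(base, "del"))
  expect_true(tl[["s"]]$unexpected_allele)
  expect_equal(classify_site(tl[["s"]])$call, "REVIEW")
})

test_that("classification applies the 90%/70% cutoffs with >= boundary semantics", {
  t1 <- mk_tally(c(A = 28L, G = 2L))          # 0.933
  expect_equal(classify_site(t1)$call, "HOM_REF")
  t2 <- mk_tally(c(A = 15L, G = 15L))
  expect_equal(classify_site(t2)$call, "HET")
  t3 <- mk_tally(c(A = 10L, G = 10L, T = 5L))
  expect_equal(classify_site(t3)$call, "REVIEW")
  t4 <- mk_tally(c(A = 27L, G = 3L))          # exactly 0.90: homozygous
  expect_equal(classify_site(t4)$call, "HOM_REF")
  expect_equal(classify_site(t4)$majority_fraction, 0.9)
  t5 <- mk_tally(c(G = 29L, A = 1L))
  expect_equal(classify_site(t5)$call, "HOM_ALT")
  # indels use the 70% cutoff on ref/alt presence counts
  t6 <- mk_tally(c(ref = 8L, alt = 22L), type = "INS")  # 0.733 >= 0.70
  expect_equal(classify_site(t6)$call, "HOM_ALT")
  t7 <- mk_tally(c(ref = 10L, alt = 20L), type = "INS") # 0.667 < 0.70
  expect_equal(classify_site(t7)$call, "HET")
})

test_that("update decisions implement the retain-heterozygous policy", {
  het <- list(call = "HET", majority_fraction = 0.6)
  hom_alt <- list(call = "HOM_ALT", majority_fraction = 1)
  hom_ref <- list(call = "HOM_REF", majority_fraction = 1)
  expect_equal(decide_update(het, "SNV", TRUE)$decision, "RETAIN_REFERENCE")
  expect_equal(decide_update(het, "SNV", TRUE)$reason,
               "het_in_source_haplotype")
  expect_equal(decide_update(hom_alt, "SNV", TRUE)$decision, "APPLY_UPDATE")
  expect_equal(decide_update(hom_ref, "SNV", FALSE)$decision,
               "RETAIN_REFERENCE")
  expect_equal(decide_update(het, "INS", TRUE)$decision, "MANUAL_REVIEW")
  expect_equal(decide_update(het, "SNV", FALSE)$decision, "MANUAL_REVIEW")
  expect_equal(decide_update(list(call = "REVIEW"), "SNV", TRUE)$decision,
               "MANUAL_REVIEW")
  expect_equal(decide_update(list(call = "NO_DATA"), "DEL", TRUE)$decision,
               "MANUAL_REVIEW")
  # pure function: identical inputs, identical outputs
  expect_identical(decide_update(het, "SNV", TRUE),
                   decide_update(het, "SNV", TRUE))
})

test_that("HET pileups at depth 40 show alt fractions within 3 binomial SD", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGTTGCAAT", 2000)))
  pos <- seq(500L, 19000L, by = 400L)
  sites <- data.frame(
    seq_id = "chr1", pos = pos, site_id = sprintf("h%03d", seq_along(pos)),
    ref = vapply(pos, function(p) substr(as.character(seqs[[1]]), p, p), ""),
    alt = NA_character_, type = "SNV", genotype = "HET",
    stringsAsFactors = FALSE)
  sites$alt <- ifelse(sites$ref == "A", "G", "A")
  rd <- simulate_site_reads(seqs, sites, depth = 40, read_length = 80,
                            seed = 33)
  tl <- pileup_tally(rd, sites)
  fracs <- vapply(sites$site_id, function(id) {
    cts <- tl[[id]]$counts
    alt <- sites$alt[sites$site_id == id]
    (if (alt %in% names(cts)) cts[[alt]] else 0L) / tl[[id]]$depth
  }, 1)
  # mean alt fraction over ~47 sites: binomial SD of the mean
  sd_mean <- sqrt(0.25 / 40 / length(fracs))
  expect_lt(abs(mean(fracs) - 0.5), 3 * sd_mean)
})

test_that("mini-contig validation passes single edits and reports extra ones", {
  win <- strrep("ACGTTGCAAT", 12)
  # SNV
  ctg <- win; substr(ctg, 61, 61) <- "C"  # ref at 61 is A
  v <- validate_minicontig(ctg, win, 61L, "A", "C", "SNV")
  expect_true(v$pass)
  expect_equal(nrow(v$differences), 1L)
  # an extra planted mismatch fails with both differences listed
  ctg2 <- ctg; substr(ctg2, 30, 30) <- "G"  # window base 30 is T
  v2 <- validate_minicontig(ctg2, win, 61L, "A", "C", "SNV")
  expect_false(v2$pass)
  expect_equal(nrow(v2$differences), 2L)
  # hand-checked 60-base deletion toy: contig lacking one base aligns with
  # a single 1-base deletion at the site
  win3 <- paste0(strrep("ACGTT", 6), "G", strrep("CATGA", 6))
  ctg3 <- paste0(strrep("ACGTT", 6), strrep("CATGA", 6))
  v3 <- validate_minicontig(ctg3, win3, 30L, paste0("T", "G"), "T", "DEL")
  expect_true(v3$pass)
  expect_equal(v3$differences$kind, "DEL")
  # insertion case
  win4 <- paste0(strrep("ACGTT", 6), strrep("CATGA", 6))
  ctg4 <- paste0(strrep("ACGTT", 6), "GGC", strrep("CATGA", 6))
  v4 <- validate_minicontig(ctg4, win4, 30L, "T", "TGGC", "INS")
  expect_true(v4$pass)
  # unalignable contig errors distinctly
  expect_error(validate_minicontig(strrep("GATC", 30), win, 61L, "A", "C",
                                   "SNV"),
               "80%")
})
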