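test_that("AGP parsing distinguishes component and gap rows and validates structure", {
  tf <- withr::local_tempfile(fileext = ".agp")
  writeLines(c("# comment",
               "chr1\t1\t1000\t1\tW\tCMP1.1\t1\t1000\t+",
               "chr1\t1001\t51000\t2\tN\t50000\tcontig\tno",
               "chr1\t51001\t52000\t3\tW\tCMP2.1\t1\t1000\t-"), tf)
  agp <- read_agp(tf)
  expect_s3_class(agp, "agp")
  expect_equal(agp$component_type, c("W", "N", "W"))
  expect_equal(agp$component_id[1], "CMP1.1")
  expect_equal(agp$object_end[1] - agp$object_beg[1] + 1L, 1000L)
  expect_equal(agp$gap_length[2], 50000L)
  expect_equal(agp$orientation[3], "-")
  gaps <- agp_gaps(agp)
  expect_equal(GenomicRanges::start(gaps), 1001L)
  expect_equal(GenomicRanges::end(gaps), 51000L)
})

test_that("AGP structural violations are rejected with object and part named", {
  tf <- withr::local_tempfile(fileext = ".agp")
  writeLines(c("chr1\t1\t600\t1\tW\tC1.1\t1\t600\t+",
               "chr1\t500\t900\t2\tW\tC2.1\t1\t401\t+"), tf)
  expect_error(read_agp(tf), "chr1.*part 2|contiguous")
  writeLines(c("chr1\t1\t600\t1\tW\tC1.1\t1\t500\t+"), tf)
  expect_error(read_agp(tf), "length")
})

test_that("AGP round-trips through write_agp on all fields", {
  agp <- movement_pair()$A$agp
  tf <- withr::local_tempfile(fileext = ".agp")
  write_agp(agp, tf)
  back <- read_agp(tf)
  rownames(back) <- rownames(agp) <- NULL
  expect_identical(back, agp)
})

test_that("PAF records need the reciprocity tag and expand CIGARs to segments", {
  tf <- withr::local_tempfile(fileext = ".paf")
  writeLines(c(
    paste("q1", 200, 0, 100, "+", "t1", 300, 50, 150, 100, 100, 60,
          "rc:A:R", sep = "\t"),
    paste("q1", 200, 0, 100, "+", "t1", 300, 0, 90, 90, 100, 60,
          "rc:A:N", "cg:Z:50=10I40=", sep = "\t")), tf)
  b <- read_paf(tf)
  expect_equal(b$pass_class, c("RECIPROCAL", "NONRECIPROCAL"))
  expect_equal(nrow(b$segments[[1]]), 1L)
  # 50=10I40= : two target-side segments separated by a query-only insertion
  expect_equal(b$segments[[2]],
               data.frame(qstart = c(1L, 61L), qend = c(50L, 100L),
                          tstart = c(1L, 51L), tend = c(50L, 90L)))

  writeLines(paste("q1", 200, 0, 100, "+", "t1", 300, 50, 150, 100, 100, 60,
                   sep = "\t"), tf)
  expect_error(read_paf(tf), "rc:A")
  writeLines(paste("q1", 200, 0, 100, "+", "t1", 300, 50, 150, 100, 100, 60,
                   "rc:A:Q", sep = "\t"), tf)
  expect_error(read_paf(tf), "reciprocity")
  writeLines(paste("q1", 200, 0, 100, "+", "t1", 300, 50, 150, 100, 100, 60,
                   "rc:A:R", "cg:Z:90=", sep = "\t"), tf)
  expect_error(read_paf(tf), "inconsisten")
})

test_that("projection is strand-aware, refuses insertions, and matches brute force", {
  b <- make_blocks("q", 1, 100, "t", 201, 300)
  expect_equal(project_coordinate(b[1, ], 1L), 201L)
  bm <- make_blocks("q", 1, 100, "t", 201, 300, strand = "-")
  expect_equal(project_coordinate(bm[1, ], 1L), 300L)
  # brute-force enumeration over all 100 positions: monotone reversal
  om <- oracle_projection(bm[1, ])
  expect_equal(project_coordinate(bm[1, ], 1:100), unname(om[as.character(1:100)]))
  expect_true(all(diff(project_coordinate(bm[1, ], 1:100)) == -1L))
  # insertion gap and outside positions are unprojectable, not errors
  tf <- withr::local_tempfile(fileext = ".paf")
  writeLines(paste("q1", 200, 0, 100, "+", "t1", 300, 0, 90, 90, 100, 60,
                   "rc:A:R", "cg:Z:50=10I40=", sep = "\t"), tf)
  big <- read_paf(tf)
  expect_true(is.na(project_coordinate(big[1, ], 55L)))
  expect_true(is.na(project_coordinate(big[1, ], 150L)))
})

test_that("projection through a block and its inverse is the identity (property)", {
  withr::local_seed(42)
  lens <- c(q1 = 50000L, q2 = 40000L)
  tlens <- c(t1 = 60000L, t2 = 30000L)
  blocks <- random_blocks(lens, 40, tlens)
  inv <- invert_blocks(blocks)
  for (i in seq_len(nrow(blocks))) {
    segs <- blocks$segments[[i]]
    qpos <- unlist(lapply(seq_len(nrow(segs)),
                          function(j) segs$qstart[j]:segs$qend[j]))
    qpos <- sample(qpos, min(200, length(qpos)))
    fwd <- project_coordinate(blocks[i, ], qpos)
    expect_false(anyNA(fwd))
    expect_equal(project_coordinate(inv[i, ], fwd), qpos)
    # bijection onto the aligned target positions
    expect_equal(length(unique(fwd)), length(qpos))
  }
})

test_that("PAF round-trips through write_paf including multi-segment blocks", {
  withr::local_seed(7)
  lens <- c(q1 = 50000L)
  blocks <- random_blocks(lens, 20, c(t1 = 50000L))
  tf <- withr::local_tempfile(fileext = ".paf")
  write_paf(blocks, tf)
  back <- read_paf(tf)
  expect_equal(back$segments, blocks$segments)
  expect_equal(back$pass_class, blocks$pass_class)
  expect_equal(back$qstart, blocks$qstart)
  expect_equal(back$tend, blocks$tend)
})

test_that("SAM round-trip via Rsamtools preserves the placement contract", {
  pl <- data.frame(
    read_id = c("r1", "r1", "r2", "r2"),
    mate = c(1L, 2L, 1L, 2L),
    seq_id = c("chr1", "chr1", "chr1", NA),
    pos = c(101L, 501L, 201L, NA),
    end = c(150L, 550L, 250L, NA),
    mapq = c(60L, 20L, 5L, 0L),
    mapped = c(TRUE, TRUE, TRUE, FALSE),
    primary = TRUE,
    strand = c("+", "-", "+", "+"),
    seq = strrep("ACGTT", 10),
    stringsAsFactors = FALSE)
  tf <- withr::local_tempfile(fileext = ".sam")
  write_sam(pl, c(chr1 = 1000L), tf)
  back <- read_placements(tf)
  back <- back[order(back$read_id, back$mate), ]
  expect_equal(back$read_id, pl$read_id)
  expect_equal(back$mapped, pl$mapped)
  expect_equal(back$pos, pl$pos)
  expect_equal(back$end, pl$end)
  expect_equal(back$mapq, pl$mapq)
})

test_that("VCF sites round-trip and REF alleles are checked against FASTA", {
  sites <- data.frame(
    seq_id = "chr1", pos = c(10L, 20L, 30L),
    site_id = c("s1", "s2", "s3"),
    ref = c("A", "C", "CGT"), alt = c("G", "CTT", "C"),
    stringsAsFactors = FALSE)
  sites$type <- c("SNV", "INS", "DEL")
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_sites(sites, tf, contigs = c(chr1 = 100L))
  back <- read_sites(tf)
  expect_equal(back$type, c("SNV", "INS", "DEL"))
  expect_equal(back$ref, sites$ref)
  expect_equal(back$alt, sites$alt)

  fa <- withr::local_tempfile(fileext = ".fa")
  seq <- paste(rep("ACGTACGTAC", 10), collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(chr1 = seq)), fa)
  expect_error(read_sites(tf, fasta = fa), "disagrees")
})
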