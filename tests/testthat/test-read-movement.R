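make_agp_rows <- function(object, object_beg, object_end, component_id,
                          component_beg, orientation = "+") {
  n <- length(object)
  df <- data.frame(
    object = object, object_beg = as.integer(object_beg),
    object_end = as.integer(object_end),
    part_number = stats::ave(seq_len(n), object, FUN = seq_along),
    component_type = "W", component_id = component_id,
    component_beg = as.integer(component_beg),
    component_end = as.integer(component_beg + (object_end - object_beg)),
    orientation = orientation, gap_length = NA_integer_,
    gap_type = NA_character_, linkage = NA_character_,
    stringsAsFactors = FALSE)
  class(df) <- c("agp", "data.frame")
  df
}

test_that("unchanged regions intersect shared components in component coordinates", {
  # identical placements: one pair covering the full component
  a <- make_agp_rows("chr1", 1, 100000, "C1.1", 1)
  b <- make_agp_rows("chr1", 1, 100000, "C1.1", 1)
  u <- unchanged_regions(a, b)
  expect_equal(nrow(u), 1L)
  expect_equal(u$start_A, 1L)
  expect_equal(u$end_B, 100000L)

  # orientation mismatch: excluded
  b2 <- make_agp_rows("chr1", 1, 100000, "C1.1", 1, orientation = "-")
  expect_equal(nrow(unchanged_regions(a, b2)), 0L)

  # partial overlap in component coordinates, offset placements
  a3 <- make_agp_rows("chr1", 1, 100000, "C1.1", 1)
  b3 <- make_agp_rows("chr2", 1, 100000, "C1.1", 50001)
  u3 <- unchanged_regions(a3, b3)
  expect_equal(u3$comp_start, 50001L)
  expect_equal(u3$comp_end, 100000L)
  expect_equal(u3$start_A, 50001L)
  expect_equal(u3$end_A, 100000L)
  expect_equal(u3$start_B, 1L)
  expect_equal(u3$end_B, 50000L)
  # brute-force check: component base 60000 sits at A 60000 and B 9999+1
  expect_equal(u3$start_B + (60000 - u3$comp_start), 10000)

  # duplicate placement of one component span is ambiguous provenance
  a4 <- make_agp_rows(c("chr1", "chr1"), c(1, 100001), c(100000, 200000),
                      c("C1.1", "C1.1"), c(1, 1))
  expect_error(unchanged_regions(a4, b), "ambiguous")
})

test_that("a version bump makes a component changed", {
  a <- make_agp_rows("chr1", 1, 100000, "C1.1", 1)
  b <- make_agp_rows("chr1", 1, 100000, "C1.2", 1)
  expect_equal(nrow(unchanged_regions(a, b)), 0L)
})

test_that("pair eligibility needs both mates unique and fully inside unchanged regions", {
  regions <- data.frame(component_id = "C1.1", comp_start = 1L,
                        comp_end = 10000L, seq_A = "chr1", start_A = 1001L,
                        end_A = 11000L, seq_B = "chr1", start_B = 1001L,
                        end_B = 11000L, orientation = "+",
                        stringsAsFactors = FALSE)
  mk <- function(id, pos1, pos2, mq1 = 60L, mq2 = 60L) {
    data.frame(read_id = id, mate = 1:2, seq_id = "chr1",
               pos = c(pos1, pos2), end = c(pos1, pos2) + 99L,
               mapq = c(mq1, mq2), mapped = TRUE, primary = TRUE,
               stringsAsFactors = FALSE)
  }
  pl <- rbind(mk("good", 2000, 2400),
              mk("lowq", 3000, 3400, mq2 = 5L),
              mk("straddle", 10950, 10500))
  expect_equal(select_unique_pairs(pl, regions), "good")
  # threshold is configurable
  expect_setequal(select_unique_pairs(pl, regions, min_mapq = 5L),
                  c("good", "lowq"))
})

test_that("moved pairs are detected by component change with midpoint assignment", {
  agpA <- make_agp_rows(rep("chr1", 2), c(1, 100001), c(100000, 200000),
                        c("C1.1", "C2.1"), 1)
  agpB <- make_agp_rows(rep("chr1", 2), c(1, 100001), c(100000, 200000),
                        c("C1.1", "C3.1"), 1)
  mk <- function(id, posA, posB) {
    list(
      A = data.frame(read_id = id, mate = 1:2, seq_id = "chr1",
                     pos = posA, end = posA + 99L, mapq = 60L, mapped = TRUE,
                     primary = TRUE, stringsAsFactors = FALSE),
      B = data.frame(read_id = id, mate = 1:2, seq_id = "chr1",
                     pos = posB, end = posB + 99L, mapq = 60L, mapped = TRUE,
                     primary = TRUE, stringsAsFactors = FALSE))
  }
  same <- mk("same", c(2000, 2400), c(2000, 2400))
  moved <- mk("moved", c(3000, 3400), c(3000, 150000))
  pa <- rbind(same$A, moved$A)
  pb <- rbind(same$B, moved$B)
  mv <- detect_moved_pairs(c("moved", "same"), pa, pb, agpA, agpB)
  expect_equal(mv$moved_ids, "moved")
  expect_equal(mv$fraction_moved, 0.5)
  expect_equal(nrow(mv$records), 2L)  # both mates of the moved pair
  # a missing B record for an eligible read is an error naming the read
  expect_error(detect_moved_pairs(c("moved", "same"), pa,
                                  pb[pb$read_id != "moved", ], agpA, agpB),
               "moved")
})

test_that("the six destination categories follow roles and centromere overlap", {
  roles <- data.frame(seq_id = c("chr1", "chr2", "scafU", "scafC"),
                      role = c("chromosome", "chromosome", "unplaced",
                               "unplaced"),
                      stringsAsFactors = FALSE)
  cen <- GenomicRanges::GRanges(c("chr1", "chr2", "scafC"),
                                IRanges::IRanges(c(5000, 5000, 1),
                                                 c(6000, 6000, 1000)))
  rec <- data.frame(
    read_id = paste0("r", 1:6), mate = 1L,
    seq_A = "chr1", pos_A = 1L, end_A = 100L, component_A = "X.1",
    seq_B = c("chr1", "chr1", "chr2", "chr2", "scafU", "scafC"),
    pos_B = c(100L, 5500L, 100L, 5500L, 10L, 2000L),
    end_B = c(199L, 5599L, 199L, 5599L, 109L, 2099L),
    component_B = "Y.1", read_moved = TRUE, stringsAsFactors = FALSE)
  out <- classify_movement(rec, roles, cen)
  expect_equal(out$category,
               c("ON", "ONCEN", "OFF", "OFFCEN", "TOSCAF", "UNCEN"))
  rec$seq_B[1] <- "mystery"
  expect_error(classify_movement(rec, roles, cen), "role")
})

test_that("rescue fractions are read-level and undefined-safe", {
  mk <- function(mapped) {
    data.frame(read_id = paste0("r", seq_along(mapped)), mate = 1L,
               seq_id = ifelse(mapped, "chr1", NA), pos = 1L, end = 100L,
               mapq = 60L, mapped = mapped, primary = TRUE,
               stringsAsFactors = FALSE)
  }
  all_mapped <- mk(rep(TRUE, 4))
  r <- rescue_stats(all_mapped, all_mapped, all_mapped)
  expect_true(is.na(r$frac_a_unmapped_mapped_b_primary))
  expect_true(is.na(r$frac_bp_unmapped_mapped_b_full))
  r2 <- rescue_stats(mk(c(FALSE, FALSE, TRUE, TRUE)),
                     mk(c(TRUE, FALSE, TRUE, TRUE)),
                     mk(c(TRUE, TRUE, TRUE, TRUE)),
                     GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200)))
  expect_equal(r2$frac_a_unmapped_mapped_b_primary, 0.5)
  expect_equal(r2$frac_rescued_in_new_sequence, 1)
  expect_equal(r2$frac_bp_unmapped_mapped_b_full, 1)
  bad <- mk(TRUE)
  expect_error(rescue_stats(all_mapped, bad, all_mapped), "same reads")
})

test_that("component pairings are exact counts with lexicographic ties", {
  rec <- data.frame(component_A = c("A.1", "A.1", "B.1", "B.1"),
                    component_B = c("X.1", "X.1", "Y.1", "Y.1"),
                    stringsAsFactors = FALSE)
  cp <- component_pairings(rec)
  expect_equal(cp$n, c(2L, 2L))
  expect_equal(cp$component_A, c("A.1", "B.1"))
  expect_equal(sum(cp$n), nrow(rec))
})

test_that("fraction_moved is invariant under permutation of read order", {
  p <- movement_pair()
  rd <- movement_reads()
  regions <- unchanged_regions(p$A$agp, p$B$agp)
  pa <- rd$truth$A
  pb <- rd$truth$B_primary
  eligible <- select_unique_pairs(pa, regions)
  mv1 <- detect_moved_pairs(eligible, pa, pb, p$A$agp, p$B$agp)
  withr::local_seed(3)
  perm <- sample(nrow(pa))
  mv2 <- detect_moved_pairs(eligible, pa[perm, ], pb[sample(nrow(pb)), ],
                            p$A$agp, p$B$agp)
  expect_equal(mv1$fraction_moved, mv2$fraction_moved)
  expect_equal(mv1$moved_ids, mv2$moved_ids)
})
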