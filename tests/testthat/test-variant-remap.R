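mk_sites <- function(seq_id, pos) {
  data.frame(seq_id = seq_id, pos = as.integer(pos),
             site_id = sprintf("v%03d", seq_along(pos)),
             ref = "A", alt = "G", type = "SNV", stringsAsFactors = FALSE)
}

mk_reads <- function(seq_id, pos, mapq = 60L) {
  data.frame(read_id = sprintf("r%03d", seq_along(pos)), mate = 1L,
             seq_id = seq_id, pos = as.integer(pos),
             end = as.integer(pos) + 99L, mapq = mapq, mapped = TRUE,
             primary = TRUE, stringsAsFactors = FALSE)
}

test_that("site coverage applies the MAPQ 20 rule", {
  sites <- mk_sites("chr1", c(150, 500))
  reads <- rbind(mk_reads("chr1", c(100, 120), mapq = 60L),
                 mk_reads("chr1", c(450, 460, 470), mapq = 0L))
  cov <- site_coverage(reads, sites)
  expect_equal(cov$depth, c(2L, 0L))
  expect_equal(cov$status, c("COVERED", "ZERO"))
  expect_error(site_coverage(reads, mk_sites("chr1", 5000),
                             seqlens = c(chr1 = 1000L)),
               "contig end")
})

test_that("remapping flags multi-placement sites as ambiguous, alternates excluded", {
  blocks <- rbind(
    make_blocks("chr1", 101, 1100, "b_chr1", 201, 1200,
                pass_class = "RECIPROCAL"),
    make_blocks("chr1", 101, 1100, "b_chr2", 5001, 6000,
                pass_class = "NONRECIPROCAL"),
    make_blocks("chr1", 2001, 2500, "b_alt", 1, 500,
                pass_class = "NONRECIPROCAL"),
    make_blocks("chr1", 2001, 2500, "b_chr1", 9001, 9500,
                pass_class = "RECIPROCAL"))
  roles <- data.frame(seq_id = c("b_chr1", "b_chr2", "b_alt"),
                      role = c("chromosome", "chromosome", "alternate"),
                      stringsAsFactors = FALSE)
  sites <- mk_sites("chr1", c(500, 2200, 9999))
  rm <- remap_sites(sites, blocks, roles)
  # site 1: two primary placements on different chromosomes -> ambiguous
  expect_true(rm$sites$ambiguous[1])
  expect_equal(rm$sites$n_placements[1], 2L)
  # site 2: one primary + one alternate placement -> not ambiguous
  expect_false(rm$sites$ambiguous[2])
  expect_equal(rm$sites$n_placements[2], 2L)
  expect_equal(rm$sites$n_primary_placements[2], 1L)
  # site 3: no block -> unmapped, not an error
  expect_true(rm$sites$unmapped[3])
})

test_that("remap round-trip through reciprocal blocks is the identity", {
  withr::local_seed(77)
  lens <- c(chr1 = 100000L)
  blocks <- random_blocks(lens, 20, c(b1 = 100000L, b2 = 80000L))
  blocks$pass_class <- "RECIPROCAL"
  inv <- invert_blocks(blocks)
  for (i in seq_len(nrow(blocks))) {
    segs <- blocks$segments[[i]]
    pos <- unlist(lapply(seq_len(nrow(segs)),
                         function(j) segs$qstart[j]:segs$qend[j]))
    pos <- sample(pos, min(50, length(pos)))
    sites <- mk_sites("chr1", pos)
    fwd <- remap_sites(sites, blocks[i, ])
    expect_false(any(fwd$sites$unmapped))
    back_sites <- data.frame(seq_id = fwd$placements$seq_id,
                             pos = fwd$placements$pos,
                             site_id = fwd$placements$site_id,
                             stringsAsFactors = FALSE)
    back <- remap_sites(back_sites, inv[i, ])
    got <- back$placements[match(sites$site_id, back$placements$site_id), ]
    expect_equal(got$pos, sites$pos)
    expect_true(all(got$seq_id == "chr1"))
  }
})

test_that("ambiguity is monotone: adding blocks never un-flags a site", {
  blocks1 <- make_blocks("chr1", 101, 1100, "b1", 201, 1200,
                         pass_class = "RECIPROCAL")
  blocks2 <- rbind(blocks1,
                   make_blocks("chr1", 101, 1100, "b2", 1, 1000,
                               pass_class = "NONRECIPROCAL"))
  blocks3 <- rbind(blocks2,
                   make_blocks("chr1", 101, 1100, "b3", 1, 1000,
                               pass_class = "NONRECIPROCAL"))
  sites <- mk_sites("chr1", 500)
  a1 <- remap_sites(sites, blocks1)$sites$ambiguous
  a2 <- remap_sites(sites, blocks2)$sites$ambiguous
  a3 <- remap_sites(sites, blocks3)$sites$ambiguous
  expect_equal(c(a1, a2, a3), c(FALSE, TRUE, TRUE))
})

test_that("coverage transitions form gained/lost lists with region grouping", {
  sites <- mk_sites("chr1", c(1000, 11000, 300000, 500000))
  status_a <- data.frame(site_id = sites$site_id, seq_id = sites$seq_id,
                         pos = sites$pos,
                         depth = c(0L, 0L, 5L, 5L),
                         status = c("ZERO", "ZERO", "COVERED", "COVERED"),
                         stringsAsFactors = FALSE)
  blocks <- make_blocks("chr1", 1, 600000, "b1", 1, 600000,
                        pass_class = "RECIPROCAL")
  rm <- remap_sites(sites, blocks)
  status_b <- data.frame(site_id = sites$site_id,
                         status = c("COVERED", "COVERED", "ZERO", "COVERED"),
                         stringsAsFactors = FALSE)
  tr <- coverage_transition(status_a, rm, status_b, merge_distance = 100000L)
  expect_equal(tr$gained$site_id, c("v001", "v002"))
  expect_equal(tr$n_gained_groups, 1L)  # 10 kb apart, one group
  expect_equal(tr$lost$site_id, "v003")
  expect_equal(tr$n_lost_groups, 1L)
  expect_length(intersect(tr$gained$site_id, tr$lost$site_id), 0L)
  # missing B status for a needed site is an error
  expect_error(coverage_transition(status_a, rm, status_b[1:2, ]), "v003")
  # stability under input order permutation
  perm <- c(3L, 1L, 4L, 2L)
  tr2 <- coverage_transition(status_a[perm, ], rm, status_b[perm, ])
  expect_equal(tr2$gained$site_id, tr$gained$site_id)
  expect_equal(tr2$lost$site_id, tr$lost$site_id)
})

test_that("transition placements prefer the reciprocal best-hit placement", {
  blocks <- rbind(
    make_blocks("chr1", 101, 1100, "b1", 201, 1200, pass_class = "RECIPROCAL"),
    make_blocks("chr1", 101, 1100, "b2", 1, 1000,
                pass_class = "NONRECIPROCAL"))
  sites <- mk_sites("chr1", 500)
  tp <- transition_placements(remap_sites(sites, blocks))
  expect_equal(tp$seq_id, "b1")
  expect_equal(tp$pos, 600L)
})
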