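# Independent brute-force oracles: explicit per-base arrays, no interval
# arithmetic shared with the implementation.

# per-base collapse/expansion labels from marking every segment base
oracle_labels <- function(blocks, seqlens) {
  rec <- lapply(seqlens, function(L) logical(L))
  non <- lapply(seqlens, function(L) logical(L))
  for (i in seq_len(nrow(blocks))) {
    segs <- blocks$segments[[i]]
    nm <- blocks$qname[i]
    for (j in seq_len(nrow(segs))) {
      idx <- segs$qstart[j]:segs$qend[j]
      if (blocks$pass_class[i] == "RECIPROCAL") rec[[nm]][idx] <- TRUE
      else non[[nm]][idx] <- TRUE
    }
  }
  lapply(stats::setNames(names(seqlens), names(seqlens)), function(nm) {
    ifelse(rec[[nm]] & non[[nm]], "COLLAPSED",
           ifelse(non[[nm]], "EXPANDED",
                  ifelse(rec[[nm]], "UNIQUE", "UNALIGNED")))
  })
}

# label lengths inside kept regions, counted base by base
oracle_label_lengths <- function(olabels, regions) {
  out <- c(COLLAPSED = 0L, EXPANDED = 0L, UNIQUE = 0L, UNALIGNED = 0L)
  for (k in seq_along(regions)) {
    nm <- as.character(GenomicRanges::seqnames(regions))[k]
    idx <- GenomicRanges::start(regions)[k]:GenomicRanges::end(regions)[k]
    tab <- table(olabels[[nm]][idx])
    out[names(tab)] <- out[names(tab)] + as.integer(tab)
  }
  out
}

# enumerate the full per-base projection map of a block
oracle_projection <- function(block) {
  segs <- if (is.data.frame(block$segments)) block$segments else block$segments[[1]]
  strand <- block$strand[[1]]
  out <- integer(0)
  for (j in seq_len(nrow(segs))) {
    q <- segs$qstart[j]:segs$qend[j]
    t <- if (strand == "+") segs$tstart[j]:segs$tend[j]
         else segs$tend[j]:segs$tstart[j]
    out[as.character(q)] <- t
  }
  out
}

# random multi-segment alignment blocks over given sequence lengths
random_blocks <- function(seqlens, n, tlens) {
  rows <- lapply(seq_len(n), function(i) {
    qn <- sample(names(seqlens), 1)
    tn <- sample(names(tlens), 1)
    nseg <- sample(1:3, 1)
    strand <- sample(c("+", "-"), 1)
    pass <- sample(c("RECIPROCAL", "NONRECIPROCAL"), 1)
    widths <- sample(50:2000, nseg, replace = TRUE)
    qgaps <- if (nseg > 1) sample(0:200, nseg - 1, replace = TRUE) else integer(0)
    tgaps <- if (nseg > 1) sample(0:200, nseg - 1, replace = TRUE) else integer(0)
    qspan <- sum(widths) + sum(qgaps)
    tspan <- sum(widths) + sum(tgaps)
    if (qspan >= seqlens[[qn]] || tspan >= tlens[[tn]]) return(NULL)
    qstart <- sample.int(seqlens[[qn]] - qspan, 1)
    tstart <- sample.int(tlens[[tn]] - tspan, 1)
    qs <- qstart + cumsum(c(0L, widths[-nseg] + qgaps))
    qe <- qs + widths - 1L
    if (strand == "+") {
      ts <- tstart + cumsum(c(0L, widths[-nseg] + tgaps))
      te <- ts + widths - 1L
    } else {
      # first query segment pairs with the highest target coordinates
      te_first <- tstart + tspan - 1L
      te <- te_first - cumsum(c(0L, widths[-nseg] + tgaps))
      ts <- te - widths + 1L
    }
    b <- data.frame(qname = qn, qlen = seqlens[[qn]], qstart = qstart,
                    qend = qstart + qspan - 1L, strand = strand, tname = tn,
                    tlen = tlens[[tn]], tstart = tstart,
                    tend = tstart + tspan - 1L, pass_class = pass,
                    stringsAsFactors = FALSE)
    b$segments <- list(data.frame(qstart = qs, qend = qe,
                                  tstart = ts, tend = te))
    b
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(asmeval:::empty_blocks())
  out <- do.call(rbind, rows)
  class(out) <- c("alignment_blocks", "data.frame")
  out
}
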