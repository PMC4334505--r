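# helper: build a segment GRanges and matching probe GRanges from a spec of
# (start, end, level, nProbes)
make_segments <- function(spec, strand = "+") {
  probes <- list()
  segs <- list()
  pid <- 0L
  for (i in seq_len(nrow(spec))) {
    n <- spec$n[i]
    starts <- round(seq(spec$start[i], spec$end[i] - 9, length.out = n))
    ids <- paste0("p", pid + seq_len(n))
    pid <- pid + n
    probes[[i]] <- data.frame(start = starts, level = spec$level[i],
                              id = ids)
    segs[[i]] <- data.frame(start = spec$start[i], end = spec$end[i],
                            level = spec$level[i], n = n,
                            ids = I(list(ids)))
  }
  pdf <- do.call(rbind, probes)
  pgr <- GenomicRanges::GRanges("chrI",
                                IRanges::IRanges(pdf$start, width = 10),
                                strand = strand)
  pgr$ratio <- pdf$level
  pgr$unique <- TRUE
  pgr$probe_id <- pdf$id
  sdf <- do.call(rbind, segs)
  sgr <- GenomicRanges::GRanges("chrI",
                                IRanges::IRanges(sdf$start, sdf$end),
                                strand = strand)
  sgr$level <- sdf$level
  sgr$n_probes <- sdf$n
  sgr$n_probes_unique <- sdf$n
  sgr$probe_ids <- IRanges::CharacterList(sdf$ids)
  list(segments = sgr, ratios = pgr)
}

test_that("overexpression calls join by gap and enforce probe support", {
  # two segments above 2-fold separated by a 30-nt gap join into one
  x <- make_segments(data.frame(start = c(100, 330), end = c(300, 530),
                                level = c(1.2, 1.5), n = c(12, 12)))
  joined <- callOverexpressed(x$segments, x$ratios)
  expect_length(joined, 1L)
  expect_equal(GenomicRanges::start(joined), 100L)
  expect_equal(GenomicRanges::end(joined), 530L)

  # a 60-nt gap keeps them apart
  y <- make_segments(data.frame(start = c(100, 360), end = c(300, 560),
                                level = c(1.2, 1.5), n = c(12, 12)))
  expect_length(callOverexpressed(y$segments, y$ratios), 2L)

  # 11 unique probes dropped, 12 kept
  z11 <- make_segments(data.frame(start = 100, end = 300, level = 1.5,
                                  n = 11))
  expect_length(callOverexpressed(z11$segments, z11$ratios), 0L)
  z12 <- make_segments(data.frame(start = 100, end = 300, level = 1.5,
                                  n = 12))
  expect_length(callOverexpressed(z12$segments, z12$ratios), 1L)

  # segments at or below 2-fold never enter
  low <- make_segments(data.frame(start = 100, end = 300, level = 1.0,
                                  n = 12))
  expect_length(callOverexpressed(low$segments, low$ratios), 0L)
})

test_that("joining is independent of segment order", {
  x <- make_segments(data.frame(start = c(100, 330, 700),
                                end = c(300, 530, 900),
                                level = c(1.2, 1.5, 2.0),
                                n = c(12, 12, 12)))
  shuffled <- x$segments[c(3, 1, 2)]
  a <- callOverexpressed(x$segments, x$ratios)
  b <- callOverexpressed(shuffled, x$ratios)
  expect_equal(GenomicRanges::start(a), GenomicRanges::start(b))
  expect_equal(GenomicRanges::end(a), GenomicRanges::end(b))
})

test_that("the cleaved-region cutoff reproduces the hand-computed MAD rule", {
  lv <- c(-0.6, -0.2, 0.0, 0.1, 0.3)
  x <- make_segments(data.frame(
    start = c(100, 600, 1100, 1600, 2100),
    end = c(400, 900, 1400, 1900, 2400),
    level = lv, n = 12))
  calls <- callCleaved(x$segments, x$ratios)
  # median 0, unscaled MAD 0.2, cutoff -0.392: only the -0.6 segment
  expect_equal(S4Vectors::metadata(calls)$cutoff, -0.392)
  expect_length(calls, 1L)
  expect_equal(calls$level, -0.6)

  # all levels equal: MAD 0, nothing strictly below the cutoff
  eq <- make_segments(data.frame(
    start = c(100, 600, 1100), end = c(400, 900, 1400),
    level = -0.3, n = 12))
  expect_length(callCleaved(eq$segments, eq$ratios), 0L)

  expect_error(callCleaved(x$segments[1:2], x$ratios), ">= 3 segments")
})

test_that("cleaved regions respect the 125-nt width rule", {
  mk <- function(width) {
    make_segments(data.frame(
      start = c(100, 600, 1100, 1600, 2100),
      end = c(100 + width - 1, 900, 1400, 1900, 2400),
      level = c(-0.6, -0.2, 0.0, 0.1, 0.3), n = 12))
  }
  x120 <- mk(120)
  expect_length(callCleaved(x120$segments, x120$ratios), 0L)
  x125 <- mk(125)
  expect_length(callCleaved(x125$segments, x125$ratios), 1L)
})

test_that("the cleavage cutoff is location- and scale-equivariant", {
  lv <- c(-0.6, -0.2, 0.0, 0.1, 0.3)
  base <- make_segments(data.frame(
    start = c(100, 600, 1100, 1600, 2100),
    end = c(400, 900, 1400, 1900, 2400), level = lv, n = 12))
  c0 <- S4Vectors::metadata(callCleaved(base$segments,
                                        base$ratios))$cutoff
  shifted <- base
  shifted$segments$level <- lv + 0.7
  shifted$ratios$ratio <- shifted$ratios$ratio + 0.7
  c1 <- S4Vectors::metadata(callCleaved(shifted$segments,
                                        shifted$ratios))$cutoff
  expect_equal(c1, c0 + 0.7)
  scaled <- base
  scaled$segments$level <- lv * 3
  scaled$ratios$ratio <- scaled$ratios$ratio * 3
  c3 <- S4Vectors::metadata(callCleaved(scaled$segments,
                                        scaled$ratios))$cutoff
  expect_equal(c3, c0 * 3)
})

test_that("loop association applies the boundary-window rule", {
  regions <- GenomicRanges::GRanges(
    "chrI", IRanges::IRanges(c(1000, 5000), c(1500, 5500)),
    strand = "+")
  hits <- GenomicRanges::GRanges("chrI", IRanges::IRanges(1000, 1035),
                                 strand = "+")
  hits$score <- 0.9
  res <- associateLoops(regions, hits)
  expect_true(res$associated[1])   # hit at the 5' boundary
  expect_false(res$associated[2])  # no hit within the window
  expect_equal(res$fraction, 0.5)

  # opposite-strand hits never associate
  minusHits <- hits
  GenomicRanges::strand(minusHits) <- "-"
  expect_equal(associateLoops(regions, minusHits)$fraction, 0)
})

test_that("cleavage sites planted at loops all associate", {
  set.seed(47)
  b <- simGenome(30000, seed = 47)
  positions <- c(5000, 15000, 25000)
  for (p in positions) b <- plantLoop(b, p, "AGUU")
  pl <- plantedLoops(b$manifest)
  # regions starting at each planted cleavage site
  regions <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(pl$fragment_end, pl$fragment_end + 400),
    strand = "+")
  scan <- scanGenome(b$genome, defaultScoringModel())
  res <- associateLoops(regions, scan$hits)
  expect_equal(res$fraction, 1)
})
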