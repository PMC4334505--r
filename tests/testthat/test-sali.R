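test_that("adapter trimming matches a brute-force overlap scan", {
  expect_equal(unname(trimAdapter(c(r = "ACGTACGTX"), "ACGTACGT")), "X")
  expect_equal(unname(trimAdapter(c(r = "TTTTGGGG"), "ACGCACGC")),
               "TTTTGGGG")

  # one mismatch in a 10-nt overlap trims at rate 0.1, not at rate 0
  adapter <- "GGCCAATTGC"
  read <- paste0("GGCCAATAGC", "TTTTTTTT")  # mismatch at overlap pos 8
  expect_equal(unname(trimAdapter(c(r = read), adapter, 0.1)),
               "TTTTTTTT")
  expect_equal(unname(trimAdapter(c(r = read), adapter, 0)), read)

  # brute-force oracle over random reads
  oracle_trim <- function(r, a, rate) {
    best <- 0
    for (L in seq_len(min(nchar(a), nchar(r)))) {
      suff <- substr(a, nchar(a) - L + 1, nchar(a))
      pref <- substr(r, 1, L)
      mm <- sum(strsplit(suff, "")[[1]] != strsplit(pref, "")[[1]])
      if (mm <= floor(rate * L)) best <- L
    }
    substr(r, best + 1, nchar(r))
  }
  set.seed(3)
  a <- "CGACAGGTTCAG"
  for (t in 1:30) {
    r <- paste(sample(c("A", "C", "G", "T"), sample(10:40, 1),
                      replace = TRUE), collapse = "")
    if (t %% 2 == 0) r <- paste0(substr(a, sample(1:12, 1), 12), r)
    expect_equal(unname(trimAdapter(setNames(r, "x"), a, 0.1)),
                 oracle_trim(r, a, 0.1))
  }
})

test_that("length filtering keeps the documented boundary", {
  reads <- setNames(c(strrep("A", 15), strrep("C", 16), strrep("G", 30)),
                    c("a", "b", "c"))
  kept <- filterLengths(reads)
  expect_equal(names(kept), c("b", "c"))
  expect_length(filterLengths(character()), 0L)
})

test_that("unique exact mapping places, discards and windows correctly", {
  set.seed(13)
  b <- simGenome(5000, seed = 13)
  g <- b$genome
  s <- as.character(g[[1]])
  # a read present once
  r35 <- substr(s, 1000, 1034)
  m <- mapUnique(setNames(r35, "u1"), g)
  expect_length(m$placed, 1L)
  expect_equal(GenomicRanges::start(m$placed), 1000L)
  expect_equal(as.character(GenomicRanges::strand(m$placed)), "+")

  # minus-strand placement
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", r35), "")[[1]]),
              collapse = "")
  m2 <- mapUnique(setNames(rc, "u2"), g)
  expect_equal(GenomicRanges::start(m2$placed), 1000L)
  expect_equal(as.character(GenomicRanges::strand(m2$placed)), "-")

  # a duplicated sequence is discarded
  dup <- paste0(substr(s, 1, 2400), substr(s, 2000, 2035),
                substr(s, 2500, 5000))
  gdup <- Biostrings::DNAStringSet(setNames(dup, "chrS"))
  planted <- substr(s, 2000, 2035)
  m3 <- mapUnique(setNames(planted, "d1"), gdup)
  expect_length(m3$placed, 0L)
  expect_equal(m3$discarded, planted)

  # 31- and 39-nt placed reads fall outside the clustering window
  r31 <- substr(s, 3000, 3030)
  r39 <- substr(s, 3200, 3238)
  r32 <- substr(s, 3400, 3431)
  r38 <- substr(s, 3600, 3637)
  m4 <- mapUnique(setNames(c(r31, r39, r32, r38), paste0("x", 1:4)), g)
  expect_equal(sort(nchar(m4$placed$sequence)), c(32L, 38L))
  expect_equal(sort(nchar(m4$outside$sequence)), c(31L, 39L))
})

test_that("cluster enrichment applies the treated/control count rule", {
  mk <- function(seqs, counts) {
    gr <- GenomicRanges::GRanges("chrS",
                                 IRanges::IRanges(seq(100, by = 100,
                                                      length.out =
                                                        length(seqs)),
                                                  width = nchar(seqs)),
                                 strand = "+")
    gr$sequence <- seqs
    gr$count <- counts
    gr
  }
  seqs <- vapply(1:3, function(i)
    paste(rep(c("A", "C", "G", "T")[i], 35), collapse = ""),
    character(1))
  treated <- mk(seqs, c(14L, 13L, 100L))
  control <- mk(seqs[3], 1L)
  enr <- enrichClusters(treated, control)
  expect_length(enr, 1L)
  expect_equal(enr$count_treated, 14L)
  expect_equal(enr$count_control, 0L)
  # relaxing the control tolerance admits the 100/1 cluster
  enr2 <- enrichClusters(treated, control, maxControlCount = 1L)
  expect_length(enr2, 2L)
})

test_that("cluster merging follows the shorter-member overlap rule", {
  mk <- function(starts, ends, counts = 20L) {
    gr <- GenomicRanges::GRanges("chrS", IRanges::IRanges(starts, ends),
                                 strand = "+")
    gr$sequence <- vapply(ends - starts + 1, function(w)
      paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
            collapse = ""), character(1))
    gr$count_treated <- counts
    gr$count_control <- 0L
    gr
  }
  set.seed(5)
  # overlap 25 of shorter 35 (~71%): merged
  m1 <- mergeClusters(mk(c(100, 110), c(134, 144)))
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$start, 100L)
  expect_equal(m1$end, 144L)
  # overlap 17 of 35 (~49%): not merged
  m2 <- mergeClusters(mk(c(100, 118), c(134, 152)))
  expect_equal(nrow(m2), 2L)
  # disjoint clusters unchanged
  m3 <- mergeClusters(mk(c(100, 500), c(134, 534)))
  expect_equal(nrow(m3), 2L)

  # count conservation and order independence
  cl <- mk(c(100, 110, 120, 500), c(134, 144, 154, 534),
           counts = c(20L, 15L, 30L, 14L))
  a <- mergeClusters(cl)
  b <- mergeClusters(cl[c(3, 1, 4, 2)])
  expect_equal(sum(a$total_count), sum(cl$count_treated))
  expect_equal(a[order(a$start), ], b[order(b$start), ],
               ignore_attr = TRUE)
  # idempotence: merged spans do not merge further
  expect_equal(nrow(mergeClusters(cl)), 2L)
})

test_that("the SALI pipeline recovers planted fragments end to end", {
  exp <- make_sali_experiment(seed = 61, copies = 20)
  res <- saliPipeline(exp$reads$treated, exp$reads$control,
                      exp$bundle$genome, adapter = exp$reads$adapter)
  man <- exp$reads$manifest
  expect_equal(nrow(res$merged), length(man))
  for (i in seq_along(man)) {
    hit <- res$merged$start == GenomicRanges::start(man)[i] &
      res$merged$end == GenomicRanges::end(man)[i]
    expect_true(any(hit), info = paste("fragment", i))
  }
  # stage counts monotone non-increasing
  st <- res$stages
  expect_true(st$input["treated"] >= st$length_filtered["treated"])
  expect_true(st$length_filtered["treated"] >=
                st$uniquely_placed_in_window["treated"])

  # a 13-copy fragment is not reported
  lo <- simSali(exp$bundle, fragmentCounts = 13L, backgroundN = 100,
                seed = 99)
  resLo <- saliPipeline(lo$treated, lo$control, exp$bundle$genome,
                        adapter = lo$adapter)
  expect_equal(nrow(resLo$merged), 0L)

  # background-only genome yields zero enriched clusters
  bgOnly <- simSali(simGenome(20000, seed = 71), fragmentCounts = 0L,
                    backgroundN = 300, seed = 72)
  resBg <- saliPipeline(bgOnly$treated, bgOnly$control,
                        simGenome(20000, seed = 71)$genome,
                        adapter = bgOnly$adapter)
  expect_equal(nrow(resBg$merged), 0L)
})
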