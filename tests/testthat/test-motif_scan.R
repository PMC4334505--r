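test_that("enumeration matches the brute-force window oracle", {
  set.seed(17)
  for (t in 1:8) {
    s <- paste(sample(c("A", "C", "G", "T"),
                      sample(200:800, 1), replace = TRUE),
               collapse = "")
    cand <- enumerateCandidates(s, strand = "+")
    expect_equal(sort(cand$loop_start), sort(oracle_enumerate(s)),
                 info = paste("case", t))
  }
})

test_that("degenerate sequences yield no candidates", {
  polyA <- paste(rep("A", 1000), collapse = "")
  expect_length(enumerateCandidates(polyA), 0L)
})

test_that("a planted canonical loop is enumerated at the planted interval", {
  set.seed(23)
  b <- simGenome(4000, seed = 23)
  b <- plantLoop(b, 1500, "AGUU", stemLen = 16)
  pl <- plantedLoops(b$manifest)
  cand <- enumerateCandidates(b$genome)
  hit <- cand[cand$loop_start == pl$loop_start &
                as.character(GenomicRanges::strand(cand)) == "+"]
  expect_length(hit, 1L)
  expect_equal(hit$downstream_bp, 16L)  # full stem window paired
  expect_equal(hit$loop_seq, "AGUU")
  expect_lt(hit$dG, -10)
})

test_that("scanning the reverse complement mirrors the hit set", {
  b <- simGenome(20000, seed = 29)
  g <- b$genome
  n <- nchar(as.character(g[[1]]))
  rc <- Biostrings::reverseComplement(g)
  names(rc) <- names(g)
  c1 <- enumerateCandidates(g)
  c2 <- enumerateCandidates(rc)
  # mirror the coordinates of the reverse-complement scan
  mirrored <- sort(data.frame(
    start = n - GenomicRanges::end(c2) + 1L,
    strand = ifelse(as.character(GenomicRanges::strand(c2)) == "+",
                    "-", "+"))$start)
  expect_equal(sort(GenomicRanges::start(c1)), mirrored)
  expect_equal(length(c1), length(c2))
})

test_that("training learns degenerate positions and permutes equivariantly", {
  subs <- makeSubstrateTable(16, seed = 4)
  # force loop position 1 to A everywhere
  substr(subs$sequence, subs$loop_start, subs$loop_start) <- "A"
  uni <- c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)
  m <- trainModel(subs, backgroundFreqs = uni)
  expect_equal(unname(which.max(m@loopWeights[, 1])), 1L)  # A maximal

  # relabeling bases under a symmetric background permutes the learned
  # loop weights identically
  swap <- function(s) chartr("AC", "CA", s)
  subs2 <- subs
  subs2$sequence <- swap(subs$sequence)
  m2 <- trainModel(subs2, backgroundFreqs = uni)
  expect_equal(m2@loopWeights["A", ], m@loopWeights["C", ])
  expect_equal(m2@loopWeights["C", ], m@loopWeights["A", ])
  expect_equal(m2@loopWeights["G", ], m@loopWeights["G", ])

  expect_error(trainModel(subs[1:9, ]), ">= 10 substrates")
})

test_that("training on the shipped fixture set reproduces the AGDU consensus", {
  subs <- readSubstrateTable(system.file("extdata",
                                         "substrates_synthetic.tsv",
                                         package = "Rnt1Scan"))
  expect_equal(loopConsensus(subs), "AGDU")
})

test_that("self-similarity is exact and scores respect the hard disqualifier", {
  # perfect-stem substrates: the enumerated frame equals the training frame
  set.seed(6)
  mkPerfect <- function(i) {
    arm3 <- paste(Rnt1Scan:::drawArm(16), collapse = "")
    paste0(Rnt1Scan:::reverseComplement2(arm3), "AG",
           sample(c("AT", "GT", "TT"), 1), arm3)
  }
  subs <- data.frame(name = paste0("s", 1:12), group = "x",
                     sequence = chartr("T", "U", vapply(1:12, mkPerfect,
                                                        character(1))),
                     loop_start = 17L, loop_len = 4L,
                     stringsAsFactors = FALSE)
  m <- trainModel(subs)
  cand <- enumerateCandidates(subs$sequence[1], strand = "+")
  cand <- cand[cand$loop_start == subs$loop_start[1]]
  sc <- scoreCandidates(cand, m)
  expect_equal(sc$raw_similarity, 1)

  # property: no candidate with downstream_bp < 3 ever receives a score,
  # and all scores lie in [0, 1]
  b <- simGenome(30000, seed = 31)$genome
  all <- scoreCandidates(enumerateCandidates(b), m)
  expect_true(all(is.na(all$score[all$downstream_bp < 3])))
  ok <- !is.na(all$score)
  expect_true(all(all$score[ok] >= 0 & all$score[ok] <= 1))
})

test_that("hit sets are nested under increasing cutoff", {
  m <- defaultScoringModel()
  b <- simGenome(150000, seed = 37)$genome
  scan <- scanGenome(b, m, cutoff = 0.80)
  s80 <- scan$hits
  s85 <- s80[s80$score >= 0.85]
  s90 <- s80[s80$score >= 0.90]
  full85 <- scanGenome(b, m, cutoff = 0.85)$hits
  expect_equal(GenomicRanges::start(full85), GenomicRanges::start(s85))
  expect_gte(length(s80), length(s85))
  expect_gte(length(s85), length(s90))
  # cutoff above 1 leaves nothing
  expect_length(scanGenome(b, m, cutoff = 0.999999)$hits, 0L)
})

test_that("planted high-tier loops are recovered by a genome scan", {
  set.seed(43)
  b <- simGenome(60000, seed = 43)
  for (pos in c(10000, 30000, 50000))
    b <- plantLoop(b, pos, "AGUU", stemLen = 16)
  m <- defaultScoringModel()
  scan <- scanGenome(b$genome, m)
  pl <- plantedLoops(b$manifest)
  for (i in seq_along(pl))
    expect_true(any(IRanges::overlapsAny(scan$hits, pl[i])),
                info = paste("planted loop", i))
})

test_that("hit spacing arithmetic handles normal and degenerate cases", {
  expect_equal(hitDensity(10, 40000), 4.0)
  expect_equal(hitDensity(0, 40000), Inf)
  expect_error(hitDensity(3, 0), "positive")
})

test_that("hit annotation follows the category precedence", {
  ann <- GenomicRanges::GRanges(
    "chrI",
    IRanges::IRanges(c(100, 300, 300, 700), c(200, 400, 400, 800)),
    strand = c("+", "+", "+", "-"))
  ann$type <- c("gene", "snoRNA", "gene", "gene")
  ann$Name <- c("G1", "SNR1", "G2", "G3")
  hits <- GenomicRanges::GRanges(
    "chrI",
    IRanges::IRanges(c(150, 350, 750, 900), width = 10),
    strand = "+")
  hits$score <- 0.9
  out <- annotateHits(hits, ann)
  expect_equal(out$category,
               c("PCG-sense", "ncRNA", "antisense", "intergenic"))
})

test_that("calibration meets its constraints on the shipped defaults", {
  m <- defaultScoringModel()
  subs <- readSubstrateTable(system.file("extdata",
                                         "substrates_synthetic.tsv",
                                         package = "Rnt1Scan"))
  s <- scoreSubstrates(m, subs)
  expect_gte(mean(s >= 0.85, na.rm = TRUE), 0.8)
  rep <- attr(m, "calibration")
  expect_true(is.data.frame(rep) && nrow(rep) >= 1)
})
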