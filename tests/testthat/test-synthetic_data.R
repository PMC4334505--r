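test_that("random genomes are seeded, composition-matched and reproducible", {
  b1 <- simGenome(1000, seed = 5)
  b2 <- simGenome(1000, seed = 5)
  expect_equal(as.character(b1$genome), as.character(b2$genome))

  uni <- rep(1 / 16, 16)
  names(uni) <- names(Rnt1Scan:::YEAST_DINUC)
  g <- simGenome(1000, uni, seed = 2)$genome
  s <- as.character(g[[1]])
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  expect_lt(abs(gc - 0.5), 0.05)

  big <- simGenome(1e6, seed = 3)$genome
  ch <- strsplit(as.character(big[[1]]), "")[[1]]
  gcBig <- mean(ch %in% c("G", "C"))
  expect_lt(abs(gcBig - 0.38), 0.01)
  # dinucleotide convergence
  di <- table(paste0(head(ch, -1), tail(ch, -1))) / (length(ch) - 1)
  expect_lt(max(abs(di[names(Rnt1Scan:::YEAST_DINUC)] -
                      Rnt1Scan:::YEAST_DINUC)), 0.01)

  bad <- uni; bad[1] <- -0.01; bad[2] <- bad[2] + 0.02
  expect_error(simGenome(100, bad, seed = 1), "nonnegative")
})

test_that("planted loops fold into the intended hairpin and class", {
  set.seed(9)
  b <- simGenome(3000, seed = 9)
  b <- plantLoop(b, 1000, "AGUU", stemLen = 16)
  pl <- plantedLoops(b$manifest)
  expect_length(pl, 1L)
  insert <- substr(as.character(b$genome[[1]]),
                   GenomicRanges::start(pl), GenomicRanges::end(pl))
  fr <- foldRNA(insert)
  tl <- terminalLoops(fr)
  expect_equal(nrow(tl), 1L)
  expect_equal(tl$seq, "AGUU")
  expect_equal(classifyLoop(fr), "G2_NGNN")

  # the archetypal A1-loop AAGU extends into the AHNN category
  b2 <- plantLoop(simGenome(3000, seed = 10), 1000, "AAGU")
  insert2 <- substr(as.character(b2$genome[[1]]),
                    GenomicRanges::start(plantedLoops(b2$manifest)),
                    GenomicRanges::end(plantedLoops(b2$manifest)))
  expect_equal(classifyLoop(foldRNA(insert2)), "AHNN")

  expect_error(plantLoop(b, 500, "AG"), "loop length")
  expect_error(plantLoop(b, 500, "AGUUAGG"), "loop length")
})

test_that("simulated probes recover abundance, fold change and dG bias", {
  g <- make_transcribed_genome(genomeLen = 20000, nTx = 4, seed = 7)
  ab <- setNames(rep(4, 4), names(g$transcripts))
  # degenerate noise: intensity equals abundance exactly
  p0 <- simProbes(g$bundle$genome, g$transcripts,
                  list(s1 = ab), noiseSd = 0, dGbiasCoeff = 0,
                  background = 1, seed = 1)
  i0 <- intensities(p0)[, "s1"]
  inTx <- IRanges::overlapsAny(
    SummarizedExperiment::rowRanges(p0), g$transcripts,
    type = "within", ignore.strand = FALSE)
  expect_true(all(i0[inTx] == 4))     # transcript abundance
  expect_true(all(i0[!inTx] == 1))    # background outside transcripts

  # fold change 2 shows as probe-wise log2 ratio 1 inside the transcript
  p2 <- simProbes(g$bundle$genome, g$transcripts,
                  list(wt = ab, mut = ab * c(2, 1, 1, 1)),
                  noiseSd = 0, seed = 1)
  gr <- SummarizedExperiment::rowRanges(p2)
  tx1 <- g$transcripts[1]
  in1 <- IRanges::overlapsAny(gr, tx1, type = "within",
                              ignore.strand = FALSE) &
    as.character(GenomicRanges::strand(gr)) ==
      as.character(GenomicRanges::strand(tx1))
  ratio <- log2(intensities(p2)[, "mut"] / intensities(p2)[, "wt"])
  expect_equal(mean(ratio[in1]), 1, tolerance = 1e-9)

  # injected hybridization bias is recovered by regression on background
  pb <- simProbes(g$bundle$genome, g$transcripts, list(s1 = ab),
                  noiseSd = 0.05, dGbiasCoeff = 0.08, seed = 2)
  bgP <- !IRanges::overlapsAny(SummarizedExperiment::rowRanges(pb),
                               g$transcripts, ignore.strand = TRUE)
  fit <- lm(log2(intensities(pb)[bgP, "s1"]) ~
              SummarizedExperiment::rowRanges(pb)$hyb_dG[bgP])
  expect_equal(unname(coef(fit)[2]), 0.08, tolerance = 0.01)
})

test_that("Cut-and-Chip simulation attenuates only downstream probes", {
  exp0 <- make_cutchip_experiment(seed = 41, cleaveIdx = 1L,
                                  efficiency = 0, noiseSd = 0)
  i <- intensities(exp0$probes)
  expect_equal(i[, "treated"], i[, "untreated"])

  exp5 <- make_cutchip_experiment(seed = 41, cleaveIdx = 1L,
                                  efficiency = 0.5, noiseSd = 0)
  i5 <- intensities(exp5$probes)
  ratio <- log2(i5[, "treated"] / i5[, "untreated"])
  gr <- SummarizedExperiment::rowRanges(exp5$probes)
  site <- exp5$sites[1]
  tx <- exp5$transcripts[1]
  down <- as.character(GenomicRanges::strand(gr)) ==
    as.character(GenomicRanges::strand(site)) &
    GenomicRanges::start(gr) >= GenomicRanges::end(site) &
    GenomicRanges::end(gr) <= GenomicRanges::end(tx)
  expect_equal(unname(ratio[down]), rep(-1, sum(down)))
  expect_true(all(ratio[!down] == 0))

  # a site outside any transcript is rejected
  orphan <- GenomicRanges::GRanges("chrS", IRanges::IRanges(5, 5),
                                   strand = "+")
  orphan$efficiency <- 0.5
  expect_error(simCutChip(exp0$probes, orphan, exp0$transcripts,
                          baseSample = "base"),
               "outside any transcript")
})

test_that("simulated qPCR drives the upregulation caller as planted", {
  q0 <- simQpcr(c(G1 = 1), replicateSd = 0, nReps = 3, seed = 1)
  calls0 <- callUpregulated(q0)
  expect_false(calls0$upregulated)

  # power at 2-fold: simulated replicates recover the call
  hits <- vapply(1:20, function(i) {
    q <- simQpcr(c(G1 = 2), replicateSd = 0.05, nReps = 3, seed = i)
    callUpregulated(q)$upregulated
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # 1.1-fold sits under the 1.2 gate regardless of significance
  q11 <- simQpcr(c(G1 = 1.1), replicateSd = 0.01, nReps = 6, seed = 2)
  expect_false(callUpregulated(q11)$upregulated)
})

test_that("generator manifests locate every planted feature", {
  exp <- make_sali_experiment(seed = 51, copies = 15)
  pl <- plantedLoops(exp$bundle$manifest)
  expect_equal(length(pl), length(exp$loops))
  g <- as.character(exp$bundle$genome[[1]])
  for (i in seq_along(pl)) {
    insert <- substr(g, GenomicRanges::start(pl)[i],
                     GenomicRanges::end(pl)[i])
    loop <- pl$loop_seq[i]
    expect_equal(substr(insert, 20, 19 + nchar(loop)),
                 chartr("U", "T", loop))
  }
  # same seed twice: identical reads
  r1 <- simSali(exp$bundle, fragmentCounts = 15, seed = 77)
  r2 <- simSali(exp$bundle, fragmentCounts = 15, seed = 77)
  expect_identical(r1$treated, r2$treated)
  expect_identical(r1$control, r2$control)
})
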