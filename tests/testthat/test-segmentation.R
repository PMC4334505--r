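test_that("hybridization energies order by GC content and are RC-symmetric", {
  expect_lt(probeDG("GCGCGCGCGC"), probeDG("AAAAAAAAAA"))
  set.seed(2)
  for (t in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
               collapse = "")
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                collapse = "")
    expect_equal(probeDG(s), probeDG(rc))
  }
  expect_error(probeDG("ACGX"), "non-nucleotide")
})

test_that("a hand-summed stack decomposition matches probeDG", {
  # GATTAC = GA + AT + TT + TA + AC
  expected <- -1.30 + -0.88 + -1.00 + -0.58 + -1.44
  expect_equal(probeDG("GATTAC"), expected)
})

test_that("probe correction removes the 5% tail and nulls the slope", {
  g <- make_transcribed_genome(genomeLen = 10000, nTx = 2, seed = 13)
  ab <- setNames(rep(4, 2), names(g$transcripts))
  p <- simProbes(g$bundle$genome, g$transcripts, list(s1 = ab),
                 noiseSd = 0.1, dGbiasCoeff = 0.08, seed = 3)
  n0 <- nrow(p)
  corrected <- correctProbes(p)
  expect_equal(nrow(corrected), n0 - floor(0.05 * n0))
  dG <- SummarizedExperiment::rowRanges(corrected)$hyb_dG
  y <- log2(intensities(corrected)[, "s1"])
  slope <- unname(coef(lm(y ~ dG))[2])
  expect_lt(abs(slope), 1e-6)
  # the removed tail is the strongest-hybridizing (most negative) one
  expect_gt(min(dG), min(SummarizedExperiment::rowRanges(p)$hyb_dG))

  small <- p[1:10, ]
  expect_error(correctProbes(small), ">= 20 probes")
})

test_that("normalization methods agree on identity and planted fold change", {
  exp <- make_expression_experiment(seed = 19, noiseSd = 0,
                                    dGbiasCoeff = 0)
  ann <- expression_annotation(exp$transcripts)
  refs <- names(exp$folds)[exp$folds == 1][1:3]

  # identical samples: all ratios zero under every method
  probes <- exp$probes
  intens <- intensities(probes)
  same <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = cbind(a = intens[, "wildtype"],
                                    b = intens[, "wildtype"])),
    rowRanges = SummarizedExperiment::rowRanges(probes))
  same <- new("ProbeSet", same)
  for (meth in c("reference_genes", "intergenic", "combined")) {
    r <- normalizeProbes(same, meth, mutant = "b", wildtype = "a",
                         annotation = ann, referenceGenes = refs)
    expect_true(all(abs(r$ratio) < 1e-9), info = meth)
  }
  rv <- normalizeProbes(same, "vsn_robust", mutant = "b", wildtype = "a")
  expect_lt(max(abs(rv$ratio)), 0.02)

  # a global 2x gain on one sample is removed exactly by reference genes
  gained <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = cbind(a = intens[, "wildtype"],
                                    b = 2 * intens[, "mutant"])),
    rowRanges = SummarizedExperiment::rowRanges(probes))
  gained <- new("ProbeSet", gained)
  r0 <- normalizeProbes(probes, "reference_genes", mutant = "mutant",
                        wildtype = "wildtype", annotation = ann,
                        referenceGenes = refs)
  r2 <- normalizeProbes(gained, "reference_genes", mutant = "b",
                        wildtype = "a", annotation = ann,
                        referenceGenes = refs)
  expect_equal(r2$ratio, r0$ratio, tolerance = 1e-9)

  # planted fold changes come back as log2(fold) under all methods
  up <- exp$transcripts[exp$upIdx]
  plantedLog2 <- unname(log2(exp$folds[exp$upIdx][1]))
  for (meth in c("reference_genes", "intergenic", "combined")) {
    r <- normalizeProbes(probes, meth, mutant = "mutant",
                         wildtype = "wildtype", annotation = ann,
                         referenceGenes = refs)
    inUp <- IRanges::overlapsAny(r, up, type = "within",
                                 ignore.strand = FALSE)
    expect_equal(mean(r$ratio[inUp]), plantedLog2, tolerance = 0.1,
                 info = meth)
  }
})

test_that("segmentation is exact, BIC-selected and shift invariant", {
  expect_error(segmentSeries(1), ">= 2 values")
  expect_error(segmentSeries(c(1, NA, 3)), "non-finite")

  const <- segmentSeries(rep(2.5, 40))
  expect_equal(const$n_segments, 1L)
  expect_length(const$changepoints, 0L)

  step <- segmentSeries(c(rep(0, 50), rep(1, 50)))
  expect_equal(step$n_segments, 2L)
  expect_equal(step$changepoints, 51L)
  expect_equal(step$levels, c(0, 1))

  # DP equals exhaustive search over boundary placements
  set.seed(7)
  for (t in 1:25) {
    n <- sample(6:30, 1)
    x <- rnorm(n) + rep(c(0, 3), each = ceiling(n / 2))[1:n]
    dp <- Rnt1Scan:::.segment_dp_cpp(x, 4)
    for (S in 1:4)
      expect_equal(dp$rss[S], oracle_seg_rss(x, S), tolerance = 1e-8)
    # RSS non-increasing in S
    expect_true(all(diff(dp$rss) <= 1e-12))
  }

  # shift invariance
  x <- c(rnorm(30), rnorm(30, 4))
  s1 <- segmentSeries(x)
  s2 <- segmentSeries(x + 7)
  expect_equal(s2$changepoints, s1$changepoints)
  expect_equal(s2$levels, s1$levels + 7)
})

test_that("genomic segmentation respects contig and strand tracks", {
  gr <- GenomicRanges::GRanges(
    rep("chrI", 40),
    IRanges::IRanges(seq(1, by = 10, length.out = 40), width = 9),
    strand = rep(c("+", "-"), each = 20))
  gr$ratio <- c(rep(0, 10), rep(2, 10), rep(1, 20))
  gr$unique <- TRUE
  gr$probe_id <- paste0("p", 1:40)
  segs <- segmentProbes(gr)
  plus <- segs[as.character(GenomicRanges::strand(segs)) == "+"]
  minus <- segs[as.character(GenomicRanges::strand(segs)) == "-"]
  expect_length(plus, 2L)
  expect_length(minus, 1L)
  expect_equal(sort(plus$level), c(0, 2))
  expect_equal(minus$level, 1)
  # level is recomputable as the member median
  for (i in seq_along(segs)) {
    mem <- gr[gr$probe_id %in% unlist(segs$probe_ids[i])]
    expect_equal(segs$level[i], median(mem$ratio))
  }
})
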