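# Shared builders for synthetic experiments used across test files.

# genome with evenly spaced same-length transcripts on alternating strands
make_transcribed_genome <- function(genomeLen = 40000L, nTx = 10L,
                                    txLen = 1500L, seed = 11L) {
  bundle <- simGenome(genomeLen, seed = seed)
  gap <- floor((genomeLen - nTx * txLen) / (nTx + 1L))
  starts <- gap + (seq_len(nTx) - 1L) * (txLen + gap)
  tx <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(starts, width = txLen),
    strand = rep(c("+", "-"), length.out = nTx))
  names(tx) <- sprintf("T%02d", seq_len(nTx))
  list(bundle = bundle, transcripts = tx)
}

# expression experiment: some transcripts 2-fold up in the mutant
make_expression_experiment <- function(seed = 11L, nTx = 10L,
                                       upIdx = c(2L, 5L, 8L),
                                       noiseSd = 0.25,
                                       dGbiasCoeff = 0.03) {
  g <- make_transcribed_genome(nTx = nTx, seed = seed)
  folds <- rep(1, nTx)
  folds[upIdx] <- 2.5
  names(folds) <- names(g$transcripts)
  wtAb <- setNames(rep(8, nTx), names(g$transcripts))
  samples <- list(wildtype = wtAb, mutant = wtAb * folds)
  probes <- simProbes(g$bundle$genome, g$transcripts, samples,
                      step = 8L, probeLen = 25L,
                      dGbiasCoeff = dGbiasCoeff, noiseSd = noiseSd,
                      seed = seed + 1L)
  list(genome = g$bundle$genome, transcripts = g$transcripts,
       probes = probes, folds = folds, upIdx = upIdx)
}

expression_annotation <- function(transcripts) {
  ann <- transcripts
  ann$type <- "gene"
  ann$Name <- names(transcripts)
  ann
}

# run the expression caller end to end, return calls + recovery stats
run_expression_pipeline <- function(exp, maxSegments = 25L) {
  ann <- expression_annotation(exp$transcripts)
  refs <- names(exp$folds)[exp$folds == 1][1:3]
  probes <- correctProbes(exp$probes)
  ratios <- normalizeProbes(probes, "reference_genes",
                            mutant = "mutant", wildtype = "wildtype",
                            annotation = ann, referenceGenes = refs)
  segs <- segmentProbes(ratios, maxSegments = maxSegments)
  calls <- callOverexpressed(segs, ratios, annotation = ann)
  planted <- exp$transcripts[exp$upIdx]
  recovered <- vapply(seq_along(planted), function(i)
    any(IRanges::overlapsAny(calls, planted[i])), logical(1))
  fp <- calls[!IRanges::overlapsAny(calls, planted)]
  list(calls = calls, sensitivity = mean(recovered),
       n_false = length(fp), segs = segs, ratios = ratios)
}

# Cut-and-Chip experiment: cleavage sites planted inside transcripts
make_cutchip_experiment <- function(seed = 21L, nTx = 10L,
                                    cleaveIdx = c(1L, 3L, 5L, 7L),
                                    efficiency = 0.8,
                                    frag3 = 700L,
                                    shortIdx = integer(),
                                    shortFrag = 40L,
                                    noiseSd = 0.2) {
  g <- make_transcribed_genome(nTx = nTx, seed = seed)
  tx <- g$transcripts
  ab <- setNames(rep(8, nTx), names(tx))
  probes <- simProbes(g$bundle$genome, tx, list(base = ab),
                      step = 8L, probeLen = 25L, noiseSd = noiseSd,
                      seed = seed + 1L)
  mkSite <- function(i, frag) {
    minus <- as.character(GenomicRanges::strand(tx)[i]) == "-"
    pos <- if (minus) GenomicRanges::start(tx)[i] + frag
           else GenomicRanges::end(tx)[i] - frag
    GenomicRanges::GRanges("chrS", IRanges::IRanges(pos, pos),
                           strand = GenomicRanges::strand(tx)[i])
  }
  sites <- do.call(c, c(lapply(cleaveIdx, mkSite, frag = frag3),
                        lapply(shortIdx, mkSite, frag = shortFrag)))
  sites$efficiency <- efficiency
  sites$planted_frag <- c(rep(frag3, length(cleaveIdx)),
                          rep(shortFrag, length(shortIdx)))
  probes <- simCutChip(probes, sites, tx, baseSample = "base")
  list(genome = g$bundle$genome, transcripts = tx, probes = probes,
       sites = sites, cleaveIdx = cleaveIdx, shortIdx = shortIdx)
}

run_cutchip_pipeline <- function(exp, maxSegments = 25L) {
  ann <- expression_annotation(exp$transcripts)
  probes <- correctProbes(exp$probes)
  uncut <- setdiff(names(exp$transcripts),
                   names(exp$transcripts)[c(exp$cleaveIdx, exp$shortIdx)])
  ratios <- normalizeProbes(probes, "reference_genes",
                            mutant = "treated", wildtype = "untreated",
                            annotation = ann,
                            referenceGenes = uncut[1:3])
  segs <- segmentProbes(ratios, maxSegments = maxSegments)
  calls <- callCleaved(segs, ratios, annotation = ann)
  degradedSpan <- function(i) {
    site <- exp$sites[i]
    tx <- exp$transcripts[IRanges::overlapsAny(exp$transcripts, site) &
      as.character(GenomicRanges::strand(exp$transcripts)) ==
        as.character(GenomicRanges::strand(site))][1]
    if (as.character(GenomicRanges::strand(site)) == "-")
      GenomicRanges::GRanges("chrS", IRanges::IRanges(
        GenomicRanges::start(tx), GenomicRanges::start(site)))
    else
      GenomicRanges::GRanges("chrS", IRanges::IRanges(
        GenomicRanges::start(site), GenomicRanges::end(tx)))
  }
  recovered <- vapply(seq_along(exp$sites), function(i)
    any(IRanges::overlapsAny(calls, degradedSpan(i),
                             ignore.strand = TRUE)), logical(1))
  list(calls = calls, recovered = recovered, segs = segs,
       ratios = ratios)
}

# SALI experiment: loops of several classes planted in a genome
make_sali_experiment <- function(seed = 31L, copies = 20L,
                                 loops = c("AGUU", "AGGU", "AGAU", "UGUU",
                                           "AAGU", "AACU", "AGA", "CGAAU"),
                                 backgroundN = 200L) {
  bundle <- simGenome(30000L, seed = seed)
  positions <- seq(2000L, by = 3000L, length.out = length(loops))
  set.seed(seed + 1L)
  for (i in seq_along(loops))
    bundle <- plantLoop(bundle, positions[i], loops[i], stemLen = 16L)
  reads <- simSali(bundle, fragmentCounts = copies,
                   backgroundN = backgroundN, seed = seed + 2L)
  list(bundle = bundle, reads = reads, loops = loops)
}
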