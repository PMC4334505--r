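# Yeast-like dinucleotide frequencies used as the generator default: base
# marginals A/T = 0.31, C/G = 0.19 (GC = 0.38) with AA/TT enrichment and
# CG/GC suppression relative to independence, keeping the marginals exact so
# the chain's stationary composition matches the target GC.
YEAST_DINUC <- local({
  p <- c(A = 0.31, C = 0.19, G = 0.19, T = 0.31)
  f <- as.vector(outer(p, p))
  names(f) <- as.vector(outer(names(p), names(p), paste0))
  d <- 0.012; e <- 0.004
  f["AA"] <- f["AA"] + d; f["TT"] <- f["TT"] + d
  f["AT"] <- f["AT"] - d; f["TA"] <- f["TA"] - d
  f["CC"] <- f["CC"] + e; f["GG"] <- f["GG"] + e
  f["CG"] <- f["CG"] - e; f["GC"] <- f["GC"] - e
  f / sum(f)
})

# Shared arm profile of the synthetic substrate family (3' arm, 5'->3' from
# the loop outward). Real Rnt1p substrates carry positional preferences in
# the stem boxes (initial binding/positioning, binding stability, middle and
# cleavage efficiency boxes); the generator emulates that with a fixed
# preferred base per position so trained positional weights carry signal and
# planted high-tier loops fall inside the trained family. The loop-distal
# positions are G/C-rich for fold stability.
SUBSTRATE_ARM_PROFILE <- c("A", "T", "C", "A", "G", "A", "A", "T",
                           "C", "T", "A", "G", "G", "C", "G", "C")

# draw a 3' (downstream) arm from the family profile
drawArm <- function(stemLen, strength = 0.7) {
  vapply(seq_len(stemLen), function(p) {
    pref <- SUBSTRATE_ARM_PROFILE[min(p, length(SUBSTRATE_ARM_PROFILE))]
    others <- setdiff(c("A", "C", "G", "T"), pref)
    sample(c(pref, others), 1L,
           prob = c(strength, rep((1 - strength) / 3, 3L)))
  }, character(1))
}

emptyManifest <- function(seed) {
  new("TruthManifest",
      plantedLoops = GRanges(),
      foldChanges = setNames(numeric(), character()),
      cleavageSites = GRanges(),
      seed = as.integer(seed))
}

#' Generate a random genome with first-order Markov structure
#'
#' Draws a sequence whose dinucleotide frequencies converge to the supplied
#' 16-entry target as the length grows. The default target is yeast-like
#' (GC about 0.38).
#'
#' @param length sequence length in nucleotides.
#' @param dinucleotideFreqs named 16-entry frequency vector (names AA..TT)
#'   summing to 1.
#' @param seed integer seed.
#' @param contig contig name (default "chrS").
#' @return list with `genome` (DNAStringSet) and `manifest` (an empty
#'   [TruthManifest-class] carrying the seed).
#' @export
simGenome <- function(length, dinucleotideFreqs = YEAST_DINUC, seed,
                      contig = "chrS") {
  f <- dinucleotideFreqs
  if (length(f) != 16L || is.null(names(f)))
    stopf("dinucleotideFreqs must be a named 16-entry vector")
  if (any(f < 0)) stopf("dinucleotide frequencies must be nonnegative")
  if (abs(sum(f) - 1) > 1e-9) stopf("dinucleotide frequencies must sum to 1")
  bases <- c("A", "C", "G", "T")
  M <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (a in bases) for (b in bases) M[a, b] <- f[paste0(a, b)]
  init <- rowSums(M)
  trans <- M / pmax(init, 1e-12)
  seq <- withSeed(seed, {
    u <- runif(length)
    idx <- integer(length)
    cum0 <- cumsum(init / sum(init))
    cumT <- t(apply(trans, 1L, cumsum))
    idx[1L] <- findInterval(u[1L], cum0) + 1L
    for (i in seq_len(length - 1L) + 1L)
      idx[i] <- findInterval(u[i], cumT[idx[i - 1L], ]) + 1L
    paste(bases[idx], collapse = "")
  })
  genome <- Biostrings::DNAStringSet(setNames(seq, contig))
  list(genome = genome, manifest = emptyManifest(seed))
}

#' Plant a stem-loop into a synthetic genome
#'
#' Overwrites the genome at `position` with a constructed stem-loop: a
#' reverse-complement stem of `stemLen` base pairs (with optional mismatch
#' positions, counted from the loop) capped by `loopSeq` and closed by a
#' 3-bp G-C clamp at the stem base. The arm sequence is drawn from the
#' current RNG stream, so plant order and the caller's seed determine the
#' construct. The manifest records the planted interval, loop class and
#' the internal-fragment span between the scissile positions (15 nt beyond
#' each end of the loop).
#'
#' @param bundle list(genome, manifest) as returned by [simGenome()].
#' @param position 1-based position where the construct starts.
#' @param loopSeq terminal loop sequence, length 3-6.
#' @param stemLen stem length in base pairs, clamp excluded (default 16).
#' @param mismatches stem positions (1 = adjacent to the loop) forced
#'   unpaired on the 3' arm.
#' @param contig contig name (defaults to the first).
#' @param tier intended score tier: "high" draws the arm from the synthetic
#'   substrate family profile (the distribution the shipped fixture set and
#'   the default model are built from); "random" draws a uniform arm.
#' @return the updated bundle.
#' @export
plantLoop <- function(bundle, position, loopSeq, stemLen = 16L,
                      mismatches = integer(), contig = NULL,
                      tier = c("high", "random")) {
  tier <- match.arg(tier)
  loopSeq <- toRNA(loopSeq)
  if (nchar(loopSeq) < 3L || nchar(loopSeq) > 6L)
    stopf("loop length must be 3-6 nt (got %d)", nchar(loopSeq))
  genome <- bundle$genome
  if (is.null(contig)) contig <- names(genome)[1L]
  s <- as.character(genome[[contig]])
  a3chars <- if (tier == "high") drawArm(stemLen)
             else sample(c("A", "C", "G", "T"), stemLen, replace = TRUE)
  arm3 <- paste(a3chars, collapse = "")            # loop-proximal first
  arm5 <- reverseComplement2(arm3)                 # 5' arm, loop-distal first
  if (length(mismatches)) {
    # break pairing on the 3' arm at the given loop-relative positions
    a3 <- a3chars
    for (p in mismatches) {
      if (p < 1L || p > stemLen) stopf("mismatch position out of stem")
      partner <- strsplit(arm5, "")[[1L]][stemLen - p + 1L]
      bad <- setdiff(c("A", "C", "G", "T"),
                     c(chartr("ACGT", "TGCA", partner), partner))
      a3[p] <- sample(bad, 1L)
    }
    arm3 <- paste(a3, collapse = "")
  }
  construct <- paste0("GGC", arm5, toDNA(loopSeq), arm3, "GCC")
  len <- nchar(construct)
  if (position < 1L || position + len - 1L > nchar(s))
    stopf("construct does not fit in the genome at position %d", position)
  substr(s, position, position + len - 1L) <- construct
  genome[[contig]] <- Biostrings::DNAString(s)

  loopStart <- position + 3L + stemLen
  loopEnd <- loopStart + nchar(loopSeq) - 1L
  gr <- GRanges(contig, IRanges(position, position + len - 1L),
                strand = "+")
  gr$loop_class <- classifyLoopSeq(loopSeq)
  gr$loop_seq <- loopSeq
  gr$tier <- tier
  gr$loop_start <- loopStart
  gr$fragment_start <- loopStart - 15L
  gr$fragment_end <- loopEnd + 15L
  man <- bundle$manifest
  man@plantedLoops <- c(man@plantedLoops, gr)
  list(genome = genome, manifest = man)
}

#' Synthetic stand-in for a curated substrate stem-loop table
#'
#' Generates canonical G2-loop substrates (AGNN-type tetraloops on mostly
#' paired stems) in the style of the published substrate catalogue: loop
#' position 1 is A in 90 percent of substrates, position 2 always G,
#' position 3 drawn from A/G/U and position 4 mostly U, on 14-16 bp stems;
#' substrates labelled ncRNA carry unpaired positions near the scissile
#' phosphates and the middle stem.
#'
#' @param n number of substrates (default 24).
#' @param seed integer seed.
#' @return data.frame with the [readSubstrateTable()] schema.
#' @export
makeSubstrateTable <- function(n = 24L, seed = 1L) {
  # balanced loop design: position 1 mostly A, position 2 always G,
  # position 3 cycling through A/G/U, position 4 mostly U -- the catalogue
  # consensus AGDU by construction
  pos1 <- rep(c(rep("A", 7L), "C"), length.out = n)
  pos3 <- rep(c("A", "G", "U"), length.out = n)
  pos4 <- rep(c(rep("U", 5L), "C"), length.out = n)
  withSeed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      group <- if (i %% 5 %in% c(1, 2, 3)) "ncRNA" else "PCG"
      loop <- paste0(pos1[i], "G", pos3[i], pos4[i])
      stemLen <- sample(14:16, 1L)
      a3chars <- drawArm(stemLen)
      arm3 <- paste(a3chars, collapse = "")
      arm5 <- reverseComplement2(arm3)
      mism <- integer()
      if (group == "ncRNA") {
        # unpaired cleavage region and middle stem, as in processing signals
        if (runif(1) < 0.7) mism <- c(mism, sample(14:min(15, stemLen), 1L))
        if (runif(1) < 0.5) mism <- c(mism, sample(7:8, 1L))
      } else if (runif(1) < 0.3) {
        mism <- sample(5:10, 1L)
      }
      mism <- mism[mism <= stemLen]
      if (length(mism)) {
        a3 <- strsplit(arm3, "")[[1L]]
        arm5chars <- strsplit(arm5, "")[[1L]]
        for (p in mism) {
          partner <- arm5chars[stemLen - p + 1L]
          bad <- setdiff(c("A", "C", "G", "T"),
                         c(chartr("ACGT", "TGCA", partner), partner))
          a3[p] <- sample(bad, 1L)
        }
        arm3 <- paste(a3, collapse = "")
      }
      seqn <- toRNA(paste0(arm5, toDNA(loop), arm3))
      data.frame(name = sprintf("SYN%02d", i), group = group,
                 sequence = seqn, loop_start = stemLen + 1L,
                 loop_len = 4L, class = "G2_NGNN",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate tiling-array probe intensities
#'
#' Tiles each contig on both strands with probes of `probeLen` every `step`
#' nucleotides. Probe intensity is transcript abundance times a
#' hybridization-energy bias term times lognormal noise:
#' intensity = abundance x 2^(dGbiasCoeff x hyb_dG) x 2^N(0, noiseSd).
#' Probes outside any transcript see the background abundance.
#'
#' @param genome DNAStringSet.
#' @param transcripts GRanges of transcripts; names (or a `Name` column)
#'   identify them.
#' @param samples named list: sample name to a named vector of transcript
#'   abundances (linear scale).
#' @param step tiling step in nt (default 8).
#' @param probeLen probe length (default 25).
#' @param dGbiasCoeff log2-intensity slope per kcal/mol of hybridization
#'   energy (default 0 = unbiased).
#' @param noiseSd lognormal noise sd in log2 units (default 0).
#' @param background abundance outside transcripts (default 1).
#' @param seed integer seed.
#' @return a [ProbeSet-class] with `hyb_dG` populated.
#' @export
simProbes <- function(genome, transcripts, samples, step = 8L,
                      probeLen = 25L, dGbiasCoeff = 0, noiseSd = 0,
                      background = 1, seed = 1L) {
  if (step < 1L) stopf("step must be >= 1")
  txNames <- names(transcripts)
  if (is.null(txNames)) txNames <- transcripts$Name
  if (is.null(txNames)) stopf("transcripts must be named")
  rows <- list()
  for (contig in names(genome)) {
    s <- as.character(genome[[contig]])
    n <- nchar(s)
    if (probeLen > n) stopf("probeLen exceeds contig length")
    starts <- seq(1L, n - probeLen + 1L, by = step)
    fwd <- substring(s, starts, starts + probeLen - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = contig, start = starts, end = starts + probeLen - 1L,
      strand = "+", sequence = fwd, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = contig, start = starts, end = starts + probeLen - 1L,
      strand = "-", sequence = reverseComplement2(fwd),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GRanges(df$contig, IRanges(df$start, df$end), strand = df$strand)
  dG <- probeDG(df$sequence)

  # per-probe abundance per sample: background outside transcripts,
  # transcript abundance where the probe lies inside one (same strand)
  abmat <- matrix(background, nrow = length(gr), ncol = length(samples),
                  dimnames = list(NULL, names(samples)))
  ov <- GenomicRanges::findOverlaps(gr, transcripts, type = "within")
  for (sn in names(samples)) {
    ab <- samples[[sn]]
    txAb <- ab[txNames[S4Vectors::subjectHits(ov)]]
    txAb[is.na(txAb)] <- background
    q <- S4Vectors::queryHits(ov)
    agg <- tapply(txAb, q, sum)
    abmat[as.integer(names(agg)), sn] <- as.numeric(agg)
  }
  intens <- withSeed(seed, {
    noise <- matrix(rnorm(length(abmat), 0, max(noiseSd, 0)),
                    nrow = nrow(abmat))
    abmat * 2^(dGbiasCoeff * dG) * 2^noise
  })
  mcols(gr) <- DataFrame(
    probe_id = sprintf("p%06d", seq_along(gr)),
    sequence = df$sequence,
    unique = TRUE,
    hyb_dG = dG)
  rownames(intens) <- gr$probe_id
  new("ProbeSet",
      SummarizedExperiment(assays = list(intensity = intens),
                           rowRanges = gr))
}

#' Simulate a Cut-and-Chip treated/untreated sample pair
#'
#' Emulates in vitro cleavage followed by Xrn1p degradation of the 3' end
#' product: in the treated sample, probes downstream of each cleavage site
#' (toward the transcript 3' end, within the host transcript and on its
#' strand) are attenuated by (1 - efficiency); the untreated sample is an
#' unmodified copy.
#'
#' @param probes a [ProbeSet-class].
#' @param sites GRanges of cleavage sites with an `efficiency` metadata
#'   column in [0, 1].
#' @param transcripts GRanges of host transcripts.
#' @param baseSample name of the sample column to duplicate.
#' @param treated,untreated names of the new columns.
#' @return a [ProbeSet-class] with the two added sample columns; the
#'   realized 3'-fragment lengths are in attribute `"frag3_len"`.
#' @export
simCutChip <- function(probes, sites, transcripts,
                       baseSample = colnames(probes)[1L],
                       treated = "treated", untreated = "untreated") {
  intens <- intensities(probes)
  base <- intens[, baseSample]
  trt <- base
  gr <- rowRanges(probes)
  eff <- sites$efficiency
  if (is.null(eff)) stopf("sites need an 'efficiency' metadata column")
  frag <- integer(length(sites))
  for (i in seq_along(sites)) {
    site <- sites[i]
    host <- transcripts[IRanges::overlapsAny(transcripts, site,
                                             ignore.strand = FALSE) &
                        as.character(strand(transcripts)) ==
                          as.character(strand(site))]
    if (length(host) == 0L)
      stopf("cleavage site %d lies outside any transcript", i)
    host <- host[1L]
    minus <- as.character(strand(host)) == "-"
    frag[i] <- if (minus) start(site) - start(host)
               else end(host) - end(site)
    sameTrack <- as.character(seqnames(gr)) ==
      as.character(seqnames(site)) &
      as.character(strand(gr)) == as.character(strand(site))
    downstream <- if (minus)
      sameTrack & end(gr) <= start(site) & start(gr) >= start(host)
    else
      sameTrack & start(gr) >= end(site) & end(gr) <= end(host)
    trt[downstream] <- trt[downstream] * (1 - eff[i])
  }
  intens <- cbind(intens, matrix(c(trt, base), ncol = 2,
                                 dimnames = list(NULL,
                                                 c(treated, untreated))))
  out <- new("ProbeSet",
             SummarizedExperiment(assays = list(intensity = intens),
                                  rowRanges = gr))
  attr(out, "frag3_len") <- frag
  out
}

DEFAULT_ADAPTER <- "CGACAGGTTCAG"

#' Simulate a SALI read set
#'
#' The treated file holds N identical copies of each planted internal
#' cleavage fragment (the sequence between the two scissile positions)
#' with the 5' adapter prepended, plus background small-RNA reads; the
#' control file holds the background reads only (the same reads appear in
#' both files).
#'
#' @param bundle list(genome, manifest) with planted loops (their
#'   `fragment_start` / `fragment_end` define the internal fragments), or a
#'   genome DNAStringSet plus explicit `fragments` GRanges.
#' @param fragmentCounts integer vector (recycled) of copies per fragment,
#'   or a function(n) drawing them.
#' @param backgroundN number of background reads (default 300).
#' @param backgroundLen length range of background reads (default
#'   c(20, 60)).
#' @param adapter 5' adapter sequence (default a fixed 12-mer).
#' @param seed integer seed.
#' @param fragments optional explicit GRanges of internal fragments.
#' @return list with `treated` and `control` named read vectors, `adapter`,
#'   and `manifest` (cleavage sites with the emitted copy numbers).
#' @export
simSali <- function(bundle, fragmentCounts = 20L, backgroundN = 300L,
                    backgroundLen = c(20L, 60L),
                    adapter = DEFAULT_ADAPTER, seed = 1L,
                    fragments = NULL) {
  if (is.list(bundle) && !is.null(bundle$genome)) {
    genome <- bundle$genome
    if (is.null(fragments)) {
      pl <- plantedLoops(bundle$manifest)
      if (length(pl))
        fragments <- GRanges(seqnames(pl),
                             IRanges(pl$fragment_start, pl$fragment_end),
                             strand = strand(pl))
      else fragments <- GRanges()
    }
  } else {
    genome <- bundle
    if (is.null(fragments)) fragments <- GRanges()
  }
  withSeed(seed, {
    nFrag <- length(fragments)
    counts <- if (is.function(fragmentCounts)) fragmentCounts(nFrag)
              else rep_len(fragmentCounts, max(nFrag, 1L))[seq_len(nFrag)]
    treated <- character()
    if (nFrag > 0L) {
      fragSeq <- vapply(seq_len(nFrag), function(i) {
        s <- substr(as.character(genome[[as.character(
          seqnames(fragments)[i])]]),
          start(fragments)[i], end(fragments)[i])
        if (as.character(strand(fragments)[i]) == "-")
          s <- reverseComplement2(s)
        s
      }, character(1))
      treated <- unlist(lapply(seq_len(nFrag), function(i)
        rep(paste0(adapter, fragSeq[i]), counts[i])))
    }
    bg <- character()
    if (backgroundN > 0L) {
      contigs <- names(genome)
      lens <- nchar(as.character(genome))
      bg <- vapply(seq_len(backgroundN), function(i) {
        ct <- sample(seq_along(contigs), 1L)
        L <- sample(backgroundLen[1L]:backgroundLen[2L], 1L)
        p <- sample(max(lens[ct] - L, 1L), 1L)
        s <- substr(as.character(genome[[ct]]), p, p + L - 1L)
        if (runif(1) < 0.5) s <- reverseComplement2(s)
        paste0(adapter, s)
      }, character(1))
    }
    treatedAll <- c(treated, bg)
    if (length(treatedAll))
      names(treatedAll) <- sprintf("t%05d", seq_along(treatedAll))
    control <- bg
    if (length(control))
      names(control) <- sprintf("c%05d", seq_along(control))
    man <- fragments
    if (nFrag > 0L) man$copies <- counts
    list(treated = treatedAll, control = control, adapter = adapter,
         manifest = man)
  })
}

#' Simulate a qPCR Ct table
#'
#' Ct values are generated so that 2^(mean dCt wild-type - mean dCt mutant)
#' has expectation equal to the planted fold change, with independent
#' normal replicate noise.
#'
#' @param trueFolds named numeric vector of planted linear fold changes
#'   (mutant over wild-type) per gene.
#' @param replicateSd replicate noise sd in Ct cycles (default 0.1).
#' @param nReps replicates per genotype (default 3, the minimum the caller
#'   accepts).
#' @param condition condition label (default "standard").
#' @param seed integer seed.
#' @return a qPCR data.frame in the [readQpcrTable()] schema.
#' @export
simQpcr <- function(trueFolds, replicateSd = 0.1, nReps = 3L,
                    condition = "standard", seed = 1L) {
  if (nReps < 3L) stopf("need nReps >= 3")
  withSeed(seed, {
    rows <- list()
    for (g in names(trueFolds)) {
      dctWt <- 8
      dctMut <- dctWt - log2(trueFolds[[g]])
      for (geno in c("wild-type", "mutant")) {
        dct <- if (geno == "wild-type") dctWt else dctMut
        for (r in seq_len(nReps)) {
          ctRef <- 15 + rnorm(1, 0, replicateSd)
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, condition = condition, genotype = geno,
            replicate = r,
            ct_target = ctRef + dct + rnorm(1, 0, replicateSd),
            ct_reference = ctRef, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
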