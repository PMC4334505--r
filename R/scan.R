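# Model frame geometry: 52 positions, tetraloop at 25-28, stems filling
# 24..9 (upstream) and 29..44 (downstream) outward from the loop. The
# scissile phosphates sit at positions 9/10 and 43/44, the middle stem at
# 15/16 and 37/38.
FRAME_LEN <- 52L
LOOP_POS <- 25:28
UP_STEM <- 24:9
DOWN_STEM <- 29:44
DEFAULT_BOXES <- list(
  IBPB = c(21:24, 29:32),
  BSB = c(17:20, 33:36),
  MB = c(13:16, 37:40),
  CEB = c(9:12, 41:44)
)
CLEAVAGE_OFFSETS <- c(9L, 10L, 43L, 44L)

#' Enumerate G2 stem-loop candidates in a sequence
#'
#' Every 4-nt window with G at loop position 2 (NGNN) whose flanks can form
#' at least `minStem` Watson-Crick or G-U pairs over a window of `stemSpan`
#' stem positions per arm (greedy pairing from the loop outward, allowing
#' up to `maxBulge` bulged nucleotides per arm) yields a candidate.
#' Candidates carry the count of consecutive pairs immediately downstream
#' of the loop (`downstream_bp`), the folding free energy of the enumerated
#' hairpin, and a `wobble_proximal` flag when a G-U pair occupies one of
#' the first two stem positions next to the loop.
#'
#' @param sequence a character string, DNAString/RNAString, or a named
#'   DNAStringSet (one entry per contig).
#' @param strand "both" (default), "+" or "-".
#' @param stemSpan stem window per arm (default 16).
#' @param maxBulge maximum bulged nucleotides per arm (default 2).
#' @param minStem minimum pairs required for candidacy (default 3).
#' @return GRanges of candidates with metadata columns `loop_seq`, `frame`,
#'   `pairing`, `downstream_bp`, `n_paired`, `dG` and `wobble_proximal`.
#' @export
enumerateCandidates <- function(sequence, strand = c("both", "+", "-"),
                                stemSpan = 16L, maxBulge = 2L,
                                minStem = 3L) {
  strand <- match.arg(strand)
  seqs <- asContigList(sequence)
  out <- list()
  for (contig in names(seqs)) {
    s <- seqs[[contig]]
    n <- nchar(s)
    if (strand %in% c("both", "+")) {
      df <- .enumerate_candidates_cpp(s, stemSpan, maxBulge, minStem)
      if (nrow(df))
        out[[length(out) + 1L]] <- candidateGRanges(df, contig, "+", n)
    }
    if (strand %in% c("both", "-")) {
      df <- .enumerate_candidates_cpp(reverseComplement2(s), stemSpan,
                                      maxBulge, minStem)
      if (nrow(df)) {
        # map minus-strand coordinates back to the forward reference
        tmp <- df
        tmp$start <- n - df$end + 1L
        tmp$end <- n - df$start + 1L
        tmp$loop_start <- n - (df$loop_start + 3L) + 1L
        out[[length(out) + 1L]] <- candidateGRanges(tmp, contig, "-", n)
      }
    }
  }
  if (!length(out)) {
    gr <- GRanges()
    return(gr)
  }
  sort(do.call(c, out), ignore.strand = TRUE)
}

candidateGRanges <- function(df, contig, strand, contigLen) {
  gr <- GRanges(contig, IRanges(df$start, df$end), strand = strand,
                seqlengths = setNames(contigLen, contig))
  gr$loop_start <- df$loop_start
  gr$loop_seq <- toRNA(df$loop_seq)
  gr$frame <- df$frame
  gr$pairing <- df$pairing
  gr$downstream_bp <- df$downstream_bp
  gr$n_paired <- df$n_paired
  gr$dG <- df$dG
  gr$wobble_proximal <- as.logical(df$wobble_proximal)
  gr
}

asContigList <- function(sequence) {
  if (is(sequence, "XStringSet")) {
    s <- as.character(sequence)
    if (is.null(names(s))) names(s) <- paste0("contig_", seq_along(s))
    return(as.list(toupper(chartr("U", "T", s))))
  }
  if (is(sequence, "XString"))
    return(list(seq1 = toupper(chartr("U", "T", as.character(sequence)))))
  s <- toupper(chartr("U", "T", as.character(sequence)))
  if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
  as.list(s)
}

#' Train a scoring model from a substrate table
#'
#' Positional log-odds are log2 of the (pseudocounted) base frequency at
#' each model-frame position over the background frequency; pairing weights
#' are the observed per-position pairing fractions of the folded
#' substrates. When per-position conservation fractions are supplied they
#' modulate the positional weights; otherwise the conservation term is
#' disabled and its mass is carried by the remaining components.
#'
#' @param substrates data.frame from [readSubstrateTable()] (>= 10 rows).
#' @param backgroundFreqs numeric(4) background base frequencies (A, C, G,
#'   U); defaults to yeast-like frequencies at GC 0.38.
#' @param conservation optional numeric(52) per-position conservation
#'   fractions in [0, 1] from user-supplied orthologous alignments.
#' @param componentWeights starting component weights (sequence, structure,
#'   similarity).
#' @param pseudocount Laplace pseudocount for positional frequencies.
#' @param cutoff score cutoff stored in the model (default 0.85).
#' @return a [ScoringModel-class].
#' @export
trainModel <- function(substrates,
                       backgroundFreqs = c(A = 0.31, C = 0.19, G = 0.19,
                                           U = 0.31),
                       conservation = NULL,
                       componentWeights = c(sequence = 0.40,
                                            structure = 0.35,
                                            similarity = 0.25),
                       pseudocount = 0.5, cutoff = 0.85) {
  if (nrow(substrates) < 10L)
    stopf(paste("need >= 10 substrates to train (have %d);",
                "see makeSubstrateTable() for a synthetic fixture set"),
          nrow(substrates))
  backgroundFreqs <- backgroundFreqs / sum(backgroundFreqs)
  frames <- vapply(seq_len(nrow(substrates)), function(i)
    substrateFrame(substrates$sequence[i], substrates$loop_start[i],
                   substrates$loop_len[i]),
    character(1))
  fm <- do.call(rbind, strsplit(frames, ""))

  logOdds <- function(colIdx) {
    vapply(colIdx, function(p) {
      obs <- fm[, p]
      obs <- obs[obs != "N"]
      if (length(obs) < 3L) return(rep(NA_real_, 4L))
      cnt <- table(factor(obs, levels = BASES))
      fr <- (as.numeric(cnt) + pseudocount) /
        (length(obs) + 4 * pseudocount)
      log2(fr / backgroundFreqs)
    }, numeric(4))
  }

  lw <- logOdds(LOOP_POS)
  colnames(lw) <- NULL
  rownames(lw) <- BASES
  bw <- matrix(NA_real_, 4L, FRAME_LEN, dimnames = list(BASES, NULL))
  boxPos <- sort(unlist(DEFAULT_BOXES))
  bw[, boxPos] <- logOdds(boxPos)
  if (!is.null(conservation)) {
    if (length(conservation) != FRAME_LEN)
      stopf("conservation must have length %d", FRAME_LEN)
    bw <- sweep(bw, 2L, conservation, `*`)
    lw <- sweep(lw, 2L, conservation[LOOP_POS], `*`)
  }

  # pairing fractions from the folded substrates
  pairedMat <- t(vapply(seq_len(nrow(substrates)), function(i)
    substratePairingVector(substrates$sequence[i],
                           substrates$loop_start[i],
                           substrates$loop_len[i]),
    numeric(FRAME_LEN)))
  pw <- colMeans(pairedMat, na.rm = TRUE)
  pw[is.nan(pw)] <- NA_real_
  pw[LOOP_POS] <- NA_real_

  # raw log-odds range achievable over the scored positions (positions with
  # too few observations carry no weight and contribute nothing)
  scored <- cbind(lw, bw[, boxPos])
  lo <- sum(apply(scored, 2L, function(col)
    if (all(is.na(col))) 0 else min(col, na.rm = TRUE)))
  hi <- sum(apply(scored, 2L, function(col)
    if (all(is.na(col))) 0 else max(col, na.rm = TRUE)))

  new("ScoringModel",
      loopWeights = lw, boxWeights = bw, boxes = DEFAULT_BOXES,
      pairingWeights = unname(pw),
      componentWeights = componentWeights / sum(componentWeights),
      conservationEnabled = !is.null(conservation),
      cutoff = cutoff, cleavageOffsets = CLEAVAGE_OFFSETS,
      substrateFrames = frames, seqRange = c(lo, hi),
      scoreShift = 0, scoreScale = 1,
      backgroundFreqs = unname(backgroundFreqs))
}

# place a substrate into the 52-position model frame: loop left-anchored at
# position 25, upstream arm right-aligned ending at 24, downstream arm from
# 25 + loop_len; N elsewhere
substrateFrame <- function(sequence, loopStart, loopLen) {
  sequence <- toRNA(sequence)
  ch <- strsplit(sequence, "")[[1L]]
  fr <- rep("N", FRAME_LEN)
  lp <- 25L
  for (k in seq_len(min(loopLen, FRAME_LEN - lp + 1L)))
    fr[lp + k - 1L] <- ch[loopStart + k - 1L]
  up <- rev(seq_len(loopStart - 1L))
  for (k in seq_along(up)) {
    pos <- 24L - k + 1L
    if (pos < 1L) break
    fr[pos] <- ch[up[k]]
  }
  down <- seq(loopStart + loopLen, length(ch))
  if (loopStart + loopLen <= length(ch)) {
    for (k in seq_along(down)) {
      pos <- 24L + loopLen + k
      if (pos > FRAME_LEN) break
      fr[pos] <- ch[down[k]]
    }
  }
  paste(fr, collapse = "")
}

substratePairingVector <- function(sequence, loopStart, loopLen) {
  fold <- foldRNA(sequence)
  db <- strsplit(fold@structure, "")[[1L]]
  paired <- db != "."
  pv <- rep(NA_real_, FRAME_LEN)
  for (k in seq_len(loopStart - 1L)) {
    pos <- 24L - k + 1L
    if (pos < 1L) break
    pv[pos] <- as.numeric(paired[loopStart - k])
  }
  down <- seq(loopStart + loopLen, nchar(sequence))
  if (loopStart + loopLen <= nchar(sequence)) {
    for (k in seq_along(down)) {
      pos <- 24L + loopLen + k
      if (pos > FRAME_LEN) break
      pv[pos] <- as.numeric(paired[down[k]])
    }
  }
  pv
}

#' Score enumerated candidates under a model
#'
#' The sequence component is the min-max-normalized positional log-odds sum
#' over the loop and box positions; the structure component combines the
#' agreement between the observed pairing and the model's pairing
#' probabilities with a stability term mapping the hairpin free energy
#' through a logistic centered at -10 kcal/mol; the similarity component is
#' the best normalized global-alignment score against the training
#' substrates (+1 match, -1 mismatch, -2 gap, normalized by self-score).
#' The final score is the component-weighted sum, clipped to [0, 1], and is
#' absent (NA) for candidates with fewer than 3 consecutive pairs
#' immediately downstream of the loop.
#'
#' @param candidates GRanges from [enumerateCandidates()].
#' @param model a [ScoringModel-class].
#' @return the candidates with added metadata columns `c_sequence`,
#'   `c_structure`, `c_similarity` (calibrated components), the raw
#'   components `raw_sequence` / `raw_structure` / `raw_similarity`, and
#'   `score`.
#' @export
scoreCandidates <- function(candidates, model) {
  n <- length(candidates)
  if (n == 0L) {
    for (col in c("c_sequence", "c_structure", "c_similarity", "score"))
      mcols(candidates)[[col]] <- numeric(0)
    return(candidates)
  }
  if (any(nchar(candidates$frame) != FRAME_LEN))
    stopf("candidate frame length does not match the model frame")
  fm <- do.call(rbind, strsplit(candidates$frame, ""))
  baseIdx <- matrix(match(fm, BASES), nrow = n)   # NA for N

  W <- model@boxWeights
  W[, LOOP_POS] <- model@loopWeights
  raw <- numeric(n)
  for (p in seq_len(FRAME_LEN)) {
    wp <- W[, p]
    if (all(is.na(wp))) next
    v <- wp[baseIdx[, p]]
    v[is.na(v)] <- 0
    raw <- raw + v
  }
  cseq <- clip01((raw - model@seqRange[1L]) /
                   max(model@seqRange[2L] - model@seqRange[1L], 1e-9))

  pm <- do.call(rbind, strsplit(candidates$pairing, ""))
  pobs <- matrix(NA_real_, n, FRAME_LEN)
  pobs[pm == "1"] <- 1
  pobs[pm == "0"] <- 0
  pw <- model@pairingWeights
  diff <- abs(sweep(pobs, 2L, pw, `-`))
  agree <- 1 - rowMeans(diff, na.rm = TRUE)
  agree[is.nan(agree)] <- 0.5
  stability <- plogis(-(candidates$dG + 10) / 2)
  cstr <- 0.5 * agree + 0.5 * stability

  stemRegion <- function(x) substr(x, min(UP_STEM), max(DOWN_STEM))
  csim <- .nw_best_cpp(stemRegion(candidates$frame),
                       stemRegion(model@substrateFrames), 1, -1, -2)

  w <- model@componentWeights
  cal <- function(x) clip01(model@scoreShift + model@scoreScale * x)
  comps <- cbind(sequence = cal(cseq), structure = cal(cstr),
                 similarity = cal(csim))
  score <- clip01(as.numeric(comps %*% w[colnames(comps)]))
  score[candidates$downstream_bp < 3L] <- NA_real_

  candidates$raw_sequence <- cseq
  candidates$raw_structure <- cstr
  candidates$raw_similarity <- csim
  candidates$c_sequence <- comps[, "sequence"]
  candidates$c_structure <- comps[, "structure"]
  candidates$c_similarity <- comps[, "similarity"]
  candidates$score <- score
  candidates
}

#' Scan a genome for high-scoring G2 stem-loops
#'
#' Enumerates candidates on both strands, scores them, and reports the
#' hits at or above the cutoff sorted by coordinate, together with summary
#' counts and the hit density.
#'
#' @param genome DNAStringSet or path to a FASTA file.
#' @param model a [ScoringModel-class].
#' @param cutoff score cutoff; defaults to the model's.
#' @param strand strands to scan (default "both").
#' @return list with `hits` (GRanges with scores), `candidates` (all scored
#'   candidates) and `summary` (n_candidates, n_hits, scanned_nt,
#'   spacing_kb).
#' @export
scanGenome <- function(genome, model, cutoff = NULL,
                       strand = "both") {
  if (is.character(genome) && length(genome) == 1L &&
      file.exists(genome))
    genome <- readGenome(genome)
  if (is.null(cutoff)) cutoff <- model@cutoff
  cand <- enumerateCandidates(genome, strand = strand)
  cand <- scoreCandidates(cand, model)
  hits <- cand[!is.na(cand$score) & cand$score >= cutoff]
  totalNt <- if (is(genome, "XStringSet")) sum(nchar(as.character(genome)))
             else sum(nchar(genome))
  scanned <- totalNt * (if (strand == "both") 2L else 1L)
  list(hits = hits, candidates = cand,
       summary = list(n_candidates = length(cand),
                      n_hits = length(hits),
                      scanned_nt = scanned,
                      spacing_kb = hitDensity(length(hits), scanned)))
}

#' Mean spacing between hits
#'
#' @param hits number of hits, or a GRanges of hits.
#' @param scannedNt total scanned nucleotides (both-strand total for a
#'   both-strand scan).
#' @return kb of scanned sequence per hit; `Inf` for zero hits.
#' @export
hitDensity <- function(hits, scannedNt) {
  n <- if (is(hits, "GRanges")) length(hits) else as.numeric(hits)
  if (scannedNt <= 0) stopf("scannedNt must be positive")
  if (n == 0) return(Inf)
  scannedNt / n / 1000
}

NCRNA_TYPES <- c("ncRNA", "snoRNA", "snRNA", "rRNA", "tRNA", "ncRNA_gene",
                 "snoRNA_gene", "snRNA_gene", "rRNA_gene", "tRNA_gene")
LTR_TYPES <- c("LTR", "long_terminal_repeat", "LTR_retrotransposon")

#' Annotate scan hits by overlapping feature class
#'
#' Each hit is assigned one category with precedence ncRNA > PCG-sense >
#' LTR > antisense > intergenic: sense overlap with a non-coding RNA gene
#' wins over sense overlap with a protein-coding gene, LTR elements are
#' checked on either strand, an antisense call requires an opposite-strand
#' gene with no same-strand feature, and hits overlapping nothing are
#' intergenic.
#'
#' @param hits GRanges of hits.
#' @param annotation GRanges with a `type` metadata column (gene / mRNA =
#'   protein coding; ncRNA-like and LTR-like types recognized by name).
#' @return the hits with a `category` column; the category fractions are in
#'   attribute `"fractions"`.
#' @export
annotateHits <- function(hits, annotation) {
  type <- as.character(annotation$type)
  isNc <- type %in% NCRNA_TYPES
  isLtr <- type %in% LTR_TYPES
  isPcg <- !isNc & !isLtr
  cat <- vapply(seq_along(hits), function(i) {
    h <- hits[i]
    ov <- IRanges::overlapsAny(annotation, h, ignore.strand = TRUE)
    if (!any(ov)) return("intergenic")
    same <- ov & as.character(strand(annotation)) ==
      as.character(strand(h))
    if (any(same & isNc)) return("ncRNA")
    if (any(same & isPcg)) return("PCG-sense")
    if (any(ov & isLtr)) return("LTR")
    if (any(ov & !isLtr)) return("antisense")
    "intergenic"
  }, character(1))
  hits$category <- cat
  lev <- c("PCG-sense", "antisense", "intergenic", "ncRNA", "LTR")
  attr(hits, "fractions") <-
    table(factor(cat, levels = lev)) / max(length(cat), 1L)
  hits
}

#' Score curated substrates under a model
#'
#' Scores each substrate's own stem-loop: candidates are enumerated within
#' the substrate sequence and the candidate at the annotated loop is
#' scored.
#'
#' @param model a [ScoringModel-class].
#' @param substrates data.frame from [readSubstrateTable()].
#' @return numeric vector of scores (NA where the substrate yields no
#'   scorable candidate, mirroring "no score" calls).
#' @export
scoreSubstrates <- function(model, substrates) {
  vapply(seq_len(nrow(substrates)), function(i) {
    cand <- enumerateCandidates(substrates$sequence[i], strand = "+")
    if (length(cand) == 0L) return(NA_real_)
    cand <- cand[cand$loop_start == substrates$loop_start[i]]
    if (length(cand) == 0L) return(NA_real_)
    cand <- scoreCandidates(cand, model)
    cand$score[1L]
  }, numeric(1))
}

#' Calibrate component weights and score normalization
#'
#' Fixes the model's free parameters against two constraints: a target
#' fraction of curated/fixture substrates must score at or above the
#' cutoff, and the hit density on background (random, dinucleotide-matched)
#' sequence must fall inside a declared band. A grid search over the
#' component-weight simplex is combined, for each weight choice, with an
#' affine score normalization placing the background score quantile that
#' corresponds to the band's target density at the cutoff; candidates are
#' then re-scored exactly and the constraints verified.
#'
#' @param model a [ScoringModel-class].
#' @param substrates fixture substrate data.frame.
#' @param background DNAStringSet of background sequence (both strands are
#'   scanned).
#' @param minSensitivity target fraction of substrates at or above the
#'   cutoff (default 0.8).
#' @param densityBand acceptable kb-per-hit band on the background
#'   (default c(1.5, 6)).
#' @param targetDensity kb-per-hit aimed at inside the band (default 3).
#' @param gridStep weight grid step (default 0.1).
#' @return the calibrated [ScoringModel-class]; the calibration report is
#'   in attribute `"calibration"`.
#' @export
calibrateModel <- function(model, substrates, background,
                           minSensitivity = 0.8,
                           densityBand = c(1.5, 6), targetDensity = 3,
                           gridStep = 0.1) {
  cutoff <- model@cutoff
  bgCand <- enumerateCandidates(background, strand = "both")
  bgCand <- scoreCandidates(bgCand, stripCalibration(model))
  bgCand <- bgCand[!is.na(bgCand$score)]
  scannedNt <- 2 * sum(nchar(as.character(background)))
  targetHits <- scannedNt / (targetDensity * 1000)
  pHit <- min(0.5, targetHits / max(length(bgCand), 1L))

  base <- stripCalibration(model)
  # leave-one-out similarity: a training substrate always matches itself
  # exactly, which says nothing about how an unseen substrate of the same
  # family scores; anchoring the calibration on held-out components keeps
  # the cutoff meaningful for novel loops
  fixRaw <- rawSubstrateComponents(base, substrates, loo = TRUE)

  grid <- weightGrid(gridStep)
  results <- list()
  for (gi in seq_len(nrow(grid))) {
    w <- unlist(grid[gi, ])
    rBg <- as.numeric(cbind(bgCand$raw_sequence, bgCand$raw_structure,
                            bgCand$raw_similarity) %*% w)
    rFix <- as.numeric(fixRaw %*% w)
    rFix <- rFix[!is.na(rFix)]
    if (!length(rFix)) next
    qBg <- quantile(rBg, 1 - pHit, names = FALSE)
    qFix <- quantile(rFix, 1 - minSensitivity, names = FALSE)
    if (qFix <= qBg) next
    b <- (0.92 - cutoff) / (qFix - qBg)
    a <- cutoff - b * qBg
    # exact re-evaluation under per-component clipping (no re-alignment:
    # raw components are affine-transformed and clipped, then combined)
    calScore <- function(rawMat) {
      comps <- clip01(a + b * rawMat)
      clip01(as.numeric(comps %*% w))
    }
    sFix <- calScore(fixRaw)
    sens <- mean(sFix >= cutoff, na.rm = TRUE)
    bgMat <- cbind(bgCand$raw_sequence, bgCand$raw_structure,
                   bgCand$raw_similarity)
    nHits <- sum(calScore(bgMat) >= cutoff, na.rm = TRUE)
    dens <- hitDensity(nHits, scannedNt)
    results[[length(results) + 1L]] <- data.frame(
      w_sequence = w[1L], w_structure = w[2L], w_similarity = w[3L],
      shift = a, scale = b, sensitivity = sens, density_kb = dens)
  }
  if (!length(results))
    stopf("calibration infeasible: no weight choice separates substrates from background")
  rep <- do.call(rbind, results)
  ok <- rep$sensitivity >= minSensitivity &
    is.finite(rep$density_kb) &
    rep$density_kb >= densityBand[1L] & rep$density_kb <= densityBand[2L]
  if (!any(ok)) {
    best <- rep[order(-rep$sensitivity,
                      abs(log(rep$density_kb / targetDensity))), ][1L, ]
    stopf(paste("calibration constraints infeasible;",
                "best achieved sensitivity %.2f at density %.2f kb/hit"),
          best$sensitivity, best$density_kb)
  }
  sel <- rep[ok, ]
  sel <- sel[order(-sel$sensitivity,
                   abs(log(sel$density_kb / targetDensity))), ][1L, ]
  out <- stripCalibration(model)
  out@componentWeights <- c(sequence = sel$w_sequence,
                            structure = sel$w_structure,
                            similarity = sel$w_similarity)
  out@scoreShift <- sel$shift
  out@scoreScale <- sel$scale
  attr(out, "calibration") <- rep
  out
}

stripCalibration <- function(model) {
  model@scoreShift <- 0
  model@scoreScale <- 1
  model
}

rawSubstrateComponents <- function(model, substrates, loo = FALSE) {
  t(vapply(seq_len(nrow(substrates)), function(i) {
    cand <- enumerateCandidates(substrates$sequence[i], strand = "+")
    if (length(cand)) {
      cand <- cand[cand$loop_start == substrates$loop_start[i]]
      if (length(cand)) {
        mi <- model
        if (loo && length(model@substrateFrames) > 1L)
          mi@substrateFrames <- model@substrateFrames[-i]
        cand <- scoreCandidates(cand, mi)
        if (!is.na(cand$score[1L]))
          return(c(cand$raw_sequence[1L], cand$raw_structure[1L],
                   cand$raw_similarity[1L]))
      }
    }
    c(NA_real_, NA_real_, NA_real_)
  }, numeric(3)))
}

weightGrid <- function(step) {
  v <- seq(step, 1 - 2 * step, by = step)
  g <- expand.grid(w1 = v, w2 = v)
  g <- g[g$w1 + g$w2 < 1 - step / 2, , drop = FALSE]
  data.frame(w1 = g$w1, w2 = g$w2, w3 = 1 - g$w1 - g$w2)
}

# cache for the default model (deterministic: fixed fixture set and seed)
.rnt1cache <- new.env(parent = emptyenv())

#' The package's default calibrated scoring model
#'
#' Trains on the shipped synthetic substrate fixture set and calibrates the
#' component weights and score normalization against a seeded yeast-like
#' random background so that at least 80 percent of the fixture substrates
#' score at or above 0.85 while the background hit density stays in the
#' 1.5-6 kb-per-hit band. Deterministic; the result is cached for the
#' session.
#'
#' @param backgroundKb kilobases of calibration background (default 300).
#' @return a [ScoringModel-class].
#' @export
defaultScoringModel <- function(backgroundKb = 300) {
  key <- paste0("default_", backgroundKb)
  if (!is.null(.rnt1cache[[key]])) return(.rnt1cache[[key]])
  subs <- readSubstrateTable(system.file("extdata",
                                         "substrates_synthetic.tsv",
                                         package = "Rnt1Scan"))
  model <- trainModel(subs)
  bg <- simGenome(backgroundKb * 1000, seed = 20150213)$genome
  model <- calibrateModel(model, subs, bg)
  .rnt1cache[[key]] <- model
  model
}
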