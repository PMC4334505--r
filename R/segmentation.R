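# Dinucleotide stacking free energies for DNA duplex hybridization
# (unified nearest-neighbor parameters, kcal/mol at 37 C). The table is
# reverse-complement symmetric, so a probe and its complement get the same
# predicted duplex energy.
DNA_STACK_DG <- c(
  AA = -1.00, AT = -0.88, TA = -0.58, CA = -1.45, GT = -1.44,
  CT = -1.28, GA = -1.30, CG = -2.17, GC = -2.24, GG = -1.84,
  TT = -1.00, TG = -1.45, AC = -1.44, AG = -1.28, TC = -1.30, CC = -1.84
)

#' Predicted hybridization free energy of a probe
#'
#' Nearest-neighbor duplex free energy summed over the dinucleotide stacks
#' of the probe sequence. More G/C-rich probes give more negative values;
#' a probe and its reverse complement have equal energy.
#'
#' @param sequence character vector of probe sequences (ACGT/U).
#' @return numeric vector, kcal/mol.
#' @export
probeDG <- function(sequence) {
  sequence <- toDNA(sequence)
  if (any(!grepl("^[ACGT]+$", sequence)))
    stopf("non-nucleotide character in probe sequence")
  vapply(sequence, function(s) {
    n <- nchar(s)
    if (n < 2L) return(0)
    di <- substring(s, seq_len(n - 1L), seq_len(n - 1L) + 1L)
    sum(DNA_STACK_DG[di])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Hybridization-energy correction of probe intensities
#'
#' Removes the probes with the strongest predicted hybridization (most
#' negative delta-G; these G/C-rich probes saturate) and residualizes the
#' remaining log2 intensities against delta-G per sample, so that the
#' post-fit slope is zero and the mean is unchanged.
#'
#' @param probes a [ProbeSet-class]; `hyb_dG` is computed from the probe
#'   sequences when absent.
#' @param removeFraction fraction of probes removed from the strong-
#'   hybridization tail (default 0.05).
#' @param strongestTail if TRUE (default) "top hybridization" is read as the
#'   most negative delta-G; FALSE selects the least negative tail instead.
#' @return a corrected [ProbeSet-class] with the tail probes removed.
#' @export
correctProbes <- function(probes, removeFraction = 0.05,
                          strongestTail = TRUE) {
  n <- nrow(probes)
  if (n < 20L)
    stopf("need >= 20 probes for the %.0f%% tail removal (have %d)",
          100 * removeFraction, n)
  gr <- rowRanges(probes)
  dG <- gr$hyb_dG
  if (is.null(dG)) dG <- probeDG(gr$sequence)
  nRemove <- floor(n * removeFraction)
  ord <- order(dG, decreasing = !strongestTail)
  drop <- ord[seq_len(nRemove)]
  keep <- setdiff(seq_len(n), drop)
  probes <- probes[keep, ]
  dG <- dG[keep]
  intens <- intensities(probes)
  for (s in seq_len(ncol(intens))) {
    y <- log2(pmax(intens[, s], 1e-12))
    slope <- coef(lm(y ~ dG))[2L]
    y2 <- y - slope * (dG - mean(dG))
    intens[, s] <- 2^y2
  }
  se <- SummarizedExperiment(assays = list(intensity = intens),
                             rowRanges = {
                               g <- rowRanges(probes); g$hyb_dG <- dG; g
                             })
  new("ProbeSet", se)
}

#' Per-probe log2 ratios with a choice of normalization
#'
#' Computes the probe-wise log2 ratio of a mutant over a wild-type sample
#' under one of four normalizations: `reference_genes` subtracts the median
#' ratio of probes in a list of unaffected genes; `intergenic` subtracts
#' the median ratio of probes overlapping no annotated feature, after
#' excluding the 5 percent most affected of them; `combined` uses the union
#' of both reference sets; `vsn_robust` fits a robust affine generalized-log
#' calibration between the two samples by least-trimmed squares (trimming
#' quantile 0.5) and returns calibrated glog ratios.
#'
#' @param probes a [ProbeSet-class].
#' @param method one of "reference_genes", "intergenic", "combined",
#'   "vsn_robust".
#' @param mutant,wildtype sample (column) names.
#' @param annotation GRanges annotation (genes); required for the
#'   reference-gene and intergenic methods.
#' @param referenceGenes character vector of unaffected gene names matched
#'   against `annotation$Name` / `annotation$ID`.
#' @param excludeFraction fraction of the most affected intergenic probes
#'   excluded before taking the reference median (default 0.05).
#' @param ltsQuantile trimming quantile of the robust calibration
#'   (default 0.5).
#' @param absentGenes optional gene names known to be absent (auxotrophic
#'   deletions); each sample is floor-anchored so these genes take the
#'   minimum of its scale.
#' @return GRanges mirroring the probe positions with metadata columns
#'   `ratio` (log2 mutant/wild-type), `unique` and `probe_id`.
#' @export
normalizeProbes <- function(probes, method = c("reference_genes",
                                               "intergenic", "combined",
                                               "vsn_robust"),
                            mutant, wildtype, annotation = NULL,
                            referenceGenes = NULL,
                            excludeFraction = 0.05, ltsQuantile = 0.5,
                            absentGenes = NULL) {
  method <- match.arg(method)
  intens <- intensities(probes)
  if (!all(c(mutant, wildtype) %in% colnames(intens)))
    stopf("sample columns %s / %s not found", mutant, wildtype)
  gr <- rowRanges(probes)
  lmut <- log2(pmax(intens[, mutant], 1e-12))
  lwt <- log2(pmax(intens[, wildtype], 1e-12))

  if (!is.null(absentGenes) && !is.null(annotation)) {
    idx <- probesInGenes(gr, annotation, absentGenes)
    if (length(idx)) {
      lmut <- anchorFloor(lmut, idx)
      lwt <- anchorFloor(lwt, idx)
    }
  }

  ratio <- lmut - lwt
  refIdx <- integer()
  if (method %in% c("reference_genes", "combined")) {
    if (is.null(annotation) || is.null(referenceGenes))
      stopf("method '%s' needs annotation and referenceGenes", method)
    refIdx <- probesInGenes(gr, annotation, referenceGenes)
  }
  if (method %in% c("intergenic", "combined")) {
    if (is.null(annotation))
      stopf("method '%s' needs annotation", method)
    ig <- which(!IRanges::overlapsAny(gr, annotation, ignore.strand = TRUE))
    if (length(ig)) {
      nEx <- floor(length(ig) * excludeFraction)
      if (nEx > 0) {
        ord <- ig[order(abs(ratio[ig]), decreasing = TRUE)]
        ig <- setdiff(ig, ord[seq_len(nEx)])
      }
    }
    refIdx <- union(refIdx, ig)
  }

  if (method == "vsn_robust") {
    ratio <- glogCalibratedRatio(intens[, wildtype], intens[, mutant],
                                 ltsQuantile)
  } else {
    if (!length(refIdx))
      stopf("empty reference probe set after exclusions")
    ratio <- ratio - median(ratio[refIdx])
  }

  out <- granges(gr)
  out$probe_id <- gr$probe_id
  out$unique <- gr$unique
  out$ratio <- unname(ratio)
  out
}

probesInGenes <- function(gr, annotation, genes) {
  nm <- annotation$Name
  if (is.null(nm)) nm <- annotation$ID
  if (is.null(nm)) nm <- names(annotation)
  feats <- annotation[!is.na(nm) & nm %in% genes]
  which(IRanges::overlapsAny(gr, feats, ignore.strand = TRUE))
}

anchorFloor <- function(lx, idx) {
  shift <- median(lx[idx]) - min(lx)
  lx[idx] <- lx[idx] - shift
  lx
}

# robust affine + generalized-log calibration between two samples:
# h(x) = asinh((x - a) / b); (a, b) fitted by iterated least-trimmed squares
glogCalibratedRatio <- function(xref, x, ltsQuantile = 0.5) {
  href <- asinh(xref)
  fitfun <- function(par, keep) {
    a <- par[1L]; b <- exp(par[2L])
    h <- asinh((x[keep] - a) / b)
    sum((h - href[keep])^2)
  }
  keep <- seq_along(x)
  par <- c(0, 0)
  for (it in 1:4) {
    opt <- optim(par, fitfun, keep = keep, method = "Nelder-Mead")
    par <- opt$par
    a <- par[1L]; b <- exp(par[2L])
    res <- (asinh((x - a) / b) - href)^2
    keep <- order(res)[seq_len(max(10L, floor(length(x) * ltsQuantile)))]
  }
  a <- par[1L]; b <- exp(par[2L])
  (asinh((x - a) / b) - href) / log(2)
}

#' Exact piecewise-constant segmentation with BIC model selection
#'
#' For every segment count S up to `maxSegments` the boundary placement
#' minimizing the residual sum of squares of the piecewise-constant fit is
#' found by dynamic programming (exact, not heuristic). S is then selected
#' by the Bayesian Information Criterion n*ln(RSS/n) + p*ln(n) with
#' p = 2S - 1 parameters (S means, S - 1 boundaries). The fitted DP
#' objective uses segment means; the reported segment `level` is the median
#' of the member values.
#'
#' @param values numeric vector ordered by coordinate.
#' @param maxSegments maximum number of segments considered (default 10).
#' @param bicParams function(S) giving the BIC parameter count; default
#'   2S - 1.
#' @return a list with `n_segments`, `changepoints` (indices of the first
#'   value of segments 2..S), `starts`, `ends`, `levels` (medians), `rss`
#'   and the full `rss_by_s` / `bic_by_s` traces.
#' @export
segmentSeries <- function(values, maxSegments = 10L,
                          bicParams = function(S) 2 * S - 1) {
  if (length(values) < 2L) stopf("need >= 2 values to segment")
  if (any(!is.finite(values))) stopf("non-finite values in series")
  maxSegments <- max(1L, min(as.integer(maxSegments), length(values)))
  dp <- .segment_dp_cpp(as.numeric(values), maxSegments)
  n <- length(values)
  rss <- pmax(dp$rss, 1e-12)
  bic <- n * log(rss / n) + vapply(seq_along(rss), function(S)
    bicParams(S) * log(n), numeric(1))
  S <- which.min(bic)
  starts <- dp$starts[[S]]
  ends <- c(starts[-1L] - 1L, n)
  levels <- vapply(seq_len(S), function(k)
    median(values[starts[k]:ends[k]]), numeric(1))
  list(n_segments = S,
       changepoints = if (S > 1L) starts[-1L] else integer(),
       starts = starts, ends = ends, levels = levels,
       rss = dp$rss[S], rss_by_s = dp$rss, bic_by_s = bic)
}

#' Segment per-probe values along the genome
#'
#' Probes are split into one ordered track per contig and strand, each
#' track is segmented with [segmentSeries()], and the resulting segments
#' are returned as genomic intervals.
#'
#' @param ratios GRanges from [normalizeProbes()] (metadata columns
#'   `ratio`, `unique`, `probe_id`).
#' @param maxSegments maximum segments per track.
#' @return GRanges of segments with metadata columns `level` (median of
#'   member probe values), `n_probes`, `n_probes_unique` and `probe_ids`.
#' @export
segmentProbes <- function(ratios, maxSegments = 10L) {
  key <- paste(as.character(seqnames(ratios)),
               as.character(strand(ratios)))
  pieces <- lapply(split(seq_along(ratios), key), function(idx) {
    idx <- idx[order(start(ratios)[idx])]
    v <- ratios$ratio[idx]
    if (length(v) < 2L) {
      return(data.frame(contig = as.character(seqnames(ratios))[idx[1L]],
                        strand = as.character(strand(ratios))[idx[1L]],
                        start = start(ratios)[idx[1L]],
                        end = end(ratios)[idx[1L]],
                        level = v[1L], n_probes = 1L,
                        n_probes_unique = sum(ratios$unique[idx]),
                        probe_ids = I(list(ratios$probe_id[idx])),
                        stringsAsFactors = FALSE))
    }
    seg <- segmentSeries(v, maxSegments)
    do.call(rbind, lapply(seq_len(seg$n_segments), function(k) {
      mem <- idx[seg$starts[k]:seg$ends[k]]
      data.frame(contig = as.character(seqnames(ratios))[mem[1L]],
                 strand = as.character(strand(ratios))[mem[1L]],
                 start = min(start(ratios)[mem]),
                 end = max(end(ratios)[mem]),
                 level = seg$levels[k],
                 n_probes = length(mem),
                 n_probes_unique = sum(ratios$unique[mem]),
                 probe_ids = I(list(ratios$probe_id[mem])),
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, pieces)
  gr <- GRanges(df$contig, IRanges(df$start, df$end), strand = df$strand)
  gr$level <- df$level
  gr$n_probes <- df$n_probes
  gr$n_probes_unique <- df$n_probes_unique
  gr$probe_ids <- IRanges::CharacterList(df$probe_ids)
  sort(gr, ignore.strand = TRUE)
}
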