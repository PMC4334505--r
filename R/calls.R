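#' Call overexpressed regions from expression segments
#'
#' Keeps segments whose level exceeds the log2 fold-change threshold
#' (default 1, i.e. 2-fold), joins neighboring kept segments on the same
#' strand separated by less than `joinGap` nucleotides, recomputes each
#' joined region's level as the median over the member probes, and drops
#' regions supported by fewer than `minUniqueProbes` uniquely matching
#' probes.
#'
#' @param segments GRanges from [segmentProbes()] (log2 levels).
#' @param ratios the probe-level GRanges the segments were computed from
#'   (used to recompute joined levels over member probes).
#' @param minLevel minimum segment level in log2 units (default 1).
#' @param joinGap join gap in nucleotides (default 48; strict "less than").
#' @param minUniqueProbes minimum uniquely matching probes per joined
#'   region (default 12).
#' @param annotation optional GRanges; overlapping feature names are
#'   attached.
#' @return GRanges of overexpressed regions with metadata columns `level`,
#'   `n_probes`, `n_probes_unique` and (when annotated) `genes`.
#' @export
callOverexpressed <- function(segments, ratios, minLevel = 1,
                              joinGap = 48L, minUniqueProbes = 12L,
                              annotation = NULL) {
  kept <- segments[segments$level > minLevel]
  out <- joinSegments(kept, ratios, joinGap)
  out <- out[out$n_probes_unique >= minUniqueProbes]
  if (!is.null(annotation)) out <- attachGenes(out, annotation)
  out
}

#' Call cleaved regions (Cut and Chip) from difference segments
#'
#' Operates on segments of the per-probe log2 ratio treated / untreated.
#' Segments with fewer than `minUniqueProbes` unique probes are removed
#' first; the cutoff is then the median segment level minus `k` times the
#' median absolute deviation (MAD, unscaled by default), segments strictly
#' below the cutoff are kept, neighbors closer than `joinGap` nt are
#' grouped, and grouped regions shorter than `minWidth` nt are dropped.
#'
#' @param segments GRanges from [segmentProbes()] on log2(treated /
#'   untreated) ratios.
#' @param ratios probe-level GRanges used to recompute grouped levels.
#' @param k cutoff multiplier (default 1.96).
#' @param joinGap grouping gap in nucleotides (default 48).
#' @param minWidth minimum region width in nucleotides (default 125).
#' @param minUniqueProbes minimum unique probes per segment (default 12).
#' @param scaledMad use the 1.4826 consistency-scaled MAD instead of the
#'   unscaled one (default FALSE).
#' @param annotation optional GRanges; overlapping feature names are
#'   attached.
#' @return GRanges of cleaved regions; the cutoff used is stored in
#'   `metadata(...)$cutoff`.
#' @export
callCleaved <- function(segments, ratios, k = 1.96, joinGap = 48L,
                        minWidth = 125L, minUniqueProbes = 12L,
                        scaledMad = FALSE, annotation = NULL) {
  segments <- segments[segments$n_probes_unique >= minUniqueProbes]
  if (length(segments) < 3L)
    stopf("need >= 3 segments for a MAD-based cutoff (have %d)",
          length(segments))
  lev <- segments$level
  madv <- mad(lev, constant = if (scaledMad) 1.4826 else 1)
  cutoff <- median(lev) - k * madv
  kept <- segments[segments$level < cutoff]
  out <- joinSegments(kept, ratios, joinGap)
  out <- out[width(out) >= minWidth]
  if (!is.null(annotation)) out <- attachGenes(out, annotation)
  metadata(out)$cutoff <- cutoff
  out
}

# join/group neighboring segments on the same contig and strand separated by
# less than joinGap nt; levels recomputed as the median over member probes
joinSegments <- function(segments, ratios, joinGap) {
  if (length(segments) == 0L) return(segments)
  segments <- sort(segments, ignore.strand = TRUE)
  key <- paste(as.character(seqnames(segments)),
               as.character(strand(segments)))
  groups <- integer(length(segments))
  g <- 0L
  lastEnd <- -Inf
  for (i in seq_along(segments)) {
    newTrack <- i == 1L || key[i] != key[i - 1L]
    gap <- start(segments)[i] - lastEnd - 1L
    if (newTrack || gap >= joinGap) {
      g <- g + 1L
      lastEnd <- end(segments)[i]
    } else {
      lastEnd <- max(lastEnd, end(segments)[i])
    }
    groups[i] <- g
  }
  pieces <- lapply(split(seq_along(segments), groups), function(idx) {
    ids <- unlist(segments$probe_ids[idx])
    mem <- which(ratios$probe_id %in% ids)
    data.frame(contig = as.character(seqnames(segments))[idx[1L]],
               strand = as.character(strand(segments))[idx[1L]],
               start = min(start(segments)[idx]),
               end = max(end(segments)[idx]),
               level = median(ratios$ratio[mem]),
               n_probes = length(mem),
               n_probes_unique = sum(ratios$unique[mem]),
               probe_ids = I(list(ids)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  gr <- GRanges(df$contig, IRanges(df$start, df$end), strand = df$strand)
  gr$level <- df$level
  gr$n_probes <- df$n_probes
  gr$n_probes_unique <- df$n_probes_unique
  gr$probe_ids <- IRanges::CharacterList(df$probe_ids)
  sort(gr, ignore.strand = TRUE)
}

attachGenes <- function(gr, annotation) {
  nm <- annotation$Name
  if (is.null(nm)) nm <- annotation$ID
  if (is.null(nm)) nm <- paste0("feature_", seq_along(annotation))
  hits <- GenomicRanges::findOverlaps(gr, annotation, ignore.strand = TRUE)
  genes <- rep(list(character()), length(gr))
  sp <- split(nm[S4Vectors::subjectHits(hits)],
              S4Vectors::queryHits(hits))
  for (q in names(sp)) genes[[as.integer(q)]] <- unique(sp[[q]])
  gr$genes <- IRanges::CharacterList(genes)
  gr
}

#' Fraction of cleaved regions with a loop motif near a boundary
#'
#' A region is motif-associated when any scan hit at or above the model
#' cutoff lies within `window` nucleotides of either region boundary on the
#' region's strand.
#'
#' @param regions GRanges of cleaved regions.
#' @param hits GRanges of loop hits from [scanGenome()] (with a `score`
#'   column).
#' @param window boundary window in nucleotides (default 100).
#' @param cutoff minimum hit score (default 0.85).
#' @return list with `fraction`, logical vector `associated`, and `n`.
#' @export
associateLoops <- function(regions, hits, window = 100L, cutoff = 0.85) {
  if (!is.null(hits$score)) hits <- hits[hits$score >= cutoff]
  associated <- vapply(seq_along(regions), function(i) {
    r <- regions[i]
    same <- hits[as.character(strand(hits)) ==
                   as.character(strand(r)) &
                 as.character(seqnames(hits)) ==
                   as.character(seqnames(r))]
    if (length(same) == 0L) return(FALSE)
    d5 <- pmin(abs(start(same) - start(r)), abs(end(same) - start(r)))
    d3 <- pmin(abs(start(same) - end(r)), abs(end(same) - end(r)))
    inside <- start(same) <= end(r) & end(same) >= start(r)
    any(d5 <= window | d3 <= window | inside)
  }, logical(1))
  list(fraction = if (length(regions)) mean(associated) else NA_real_,
       associated = associated, n = length(regions))
}
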