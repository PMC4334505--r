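#' Trim a 5' adapter from reads
#'
#' Removes the longest read prefix matching a suffix of the adapter,
#' allowing mismatches at a rate up to `maxErrorRate` of the overlap
#' length. Reads without an adapter match pass through unchanged.
#'
#' @param reads named character vector of read sequences.
#' @param adapter adapter sequence (non-empty).
#' @param maxErrorRate maximum mismatch rate in the adapter overlap
#'   (default 0.1).
#' @return the trimmed reads (names preserved).
#' @export
trimAdapter <- function(reads, adapter, maxErrorRate = 0.1) {
  if (nchar(adapter) == 0L) stopf("adapter must be non-empty")
  adapter <- toupper(adapter)
  aLen <- nchar(adapter)
  aChars <- strsplit(adapter, "")[[1L]]
  vapply(reads, function(r) {
    r <- toupper(r)
    best <- 0L
    maxL <- min(aLen, nchar(r))
    for (L in seq_len(maxL)) {
      suff <- aChars[(aLen - L + 1L):aLen]
      pref <- strsplit(substr(r, 1L, L), "")[[1L]]
      if (sum(suff != pref) <= floor(maxErrorRate * L)) best <- L
    }
    substr(r, best + 1L, nchar(r))
  }, character(1))
}

#' Remove short reads
#'
#' @param reads named character vector.
#' @param minLen minimum length kept (default 16).
#' @return the reads of length >= minLen.
#' @export
filterLengths <- function(reads, minLen = 16L) {
  reads[nchar(reads) >= minLen]
}

#' Place reads by unique exact match
#'
#' A read is placed if and only if it has exactly one exact match in the
#' genome across both strands; reads with zero or multiple matches are
#' discarded. After placement only reads in the `lenWindow` length range
#' proceed to clustering.
#'
#' @param reads named character vector.
#' @param genome DNAStringSet.
#' @param lenWindow length window retained for clustering (default
#'   c(32, 38)).
#' @return list with `placed` (GRanges with `sequence` and `count`, one
#'   range per distinct read sequence within the window), `discarded`
#'   (sequences with 0 or >1 matches) and `outside` (uniquely placed but
#'   outside the window).
#' @export
mapUnique <- function(reads, genome, lenWindow = c(32L, 38L)) {
  if (length(reads) == 0L)
    return(list(placed = GRanges(), discarded = character(),
                outside = GRanges()))
  tab <- table(toupper(reads))
  seqs <- names(tab)
  hits <- lapply(seqs, function(s) exactMatches(s, genome))
  nHit <- vapply(hits, nrow, integer(1))
  unique1 <- nHit == 1L
  discarded <- seqs[!unique1]
  if (!any(unique1)) {
    return(list(placed = GRanges(), discarded = discarded,
                outside = GRanges()))
  }
  hdf <- do.call(rbind, hits[unique1])
  gr <- GRanges(hdf$contig, IRanges(hdf$start, hdf$end),
                strand = hdf$strand)
  gr$sequence <- seqs[unique1]
  gr$count <- as.integer(tab[unique1])
  inWin <- nchar(gr$sequence) >= lenWindow[1L] &
    nchar(gr$sequence) <= lenWindow[2L]
  list(placed = gr[inWin], discarded = discarded, outside = gr[!inWin])
}

# all exact matches of one sequence on both strands of a genome
exactMatches <- function(s, genome) {
  out <- list()
  pat <- Biostrings::DNAString(toDNA(s))
  rcp <- Biostrings::reverseComplement(pat)
  for (contig in names(genome)) {
    subj <- genome[[contig]]
    fwd <- Biostrings::matchPattern(pat, subj)
    if (length(fwd))
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, start = Biostrings::start(fwd),
        end = Biostrings::end(fwd), strand = "+",
        stringsAsFactors = FALSE)
    rev <- Biostrings::matchPattern(rcp, subj)
    if (length(rev))
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, start = Biostrings::start(rev),
        end = Biostrings::end(rev), strand = "-",
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Identify enriched identical-read clusters
#'
#' A cluster (all identical placed reads) is enriched when its treated
#' count reaches `minCount` and its control count does not exceed
#' `maxControlCount` (default 0: found in the cleaved and not the control
#' sample).
#'
#' @param placedTreated GRanges from [mapUnique()] on the treated reads.
#' @param placedControl GRanges from [mapUnique()] on the control reads.
#' @param minCount minimum treated count (default 14).
#' @param maxControlCount maximum tolerated control count (default 0).
#' @return GRanges of enriched clusters with `sequence`, `count_treated`
#'   and `count_control`.
#' @export
enrichClusters <- function(placedTreated, placedControl, minCount = 14L,
                           maxControlCount = 0L) {
  if (length(placedTreated) == 0L) {
    gr <- GRanges()
    return(gr)
  }
  ctrl <- setNames(
    if (length(placedControl)) placedControl$count else integer(),
    if (length(placedControl)) placedControl$sequence else character())
  cc <- ctrl[placedTreated$sequence]
  cc[is.na(cc)] <- 0L
  gr <- placedTreated
  gr$count_treated <- gr$count
  gr$count_control <- as.integer(cc)
  gr$count <- NULL
  gr[gr$count_treated >= minCount & gr$count_control <= maxControlCount]
}

#' Merge overlapping enriched clusters
#'
#' Two clusters merge when their overlap exceeds `minOverlap` of the
#' shorter cluster's length (strict "over 50 percent" by default), on the
#' same strand; merging is transitive. The representative of a merged
#' cluster is its longest member sequence.
#'
#' @param clusters GRanges from [enrichClusters()].
#' @param minOverlap overlap fraction threshold (default 0.5, strict).
#' @param annotation optional GRanges; overlapping transcript names are
#'   attached.
#' @return data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `n_members`, `total_count`, `representative` and (if annotated)
#'   `transcript`.
#' @export
mergeClusters <- function(clusters, minOverlap = 0.5, annotation = NULL) {
  n <- length(clusters)
  if (n == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_members = integer(), total_count = integer(),
                      representative = character(),
                      stringsAsFactors = FALSE))
  }
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (as.character(seqnames(clusters)[i]) !=
          as.character(seqnames(clusters)[j])) next
      if (as.character(strand(clusters)[i]) !=
          as.character(strand(clusters)[j])) next
      ov <- min(end(clusters)[i], end(clusters)[j]) -
        max(start(clusters)[i], start(clusters)[j]) + 1L
      shorter <- min(width(clusters)[i], width(clusters)[j])
      if (ov > minOverlap * shorter) {
        ri <- findRoot(i); rj <- findRoot(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), findRoot, integer(1))
  pieces <- lapply(split(seq_len(n), root), function(idx) {
    seqs <- clusters$sequence[idx]
    # deterministic representative: longest, ties broken lexicographically
    seqs <- seqs[order(-nchar(seqs), seqs)]
    data.frame(contig = as.character(seqnames(clusters)[idx[1L]]),
               start = min(start(clusters)[idx]),
               end = max(end(clusters)[idx]),
               strand = as.character(strand(clusters)[idx[1L]]),
               n_members = length(idx),
               total_count = sum(clusters$count_treated[idx]),
               representative = seqs[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[order(out$contig, out$start), , drop = FALSE]
  if (!is.null(annotation)) {
    nm <- annotation$Name
    if (is.null(nm)) nm <- annotation$ID
    out$transcript <- vapply(seq_len(nrow(out)), function(i) {
      gr <- GRanges(out$contig[i], IRanges(out$start[i], out$end[i]),
                    strand = out$strand[i])
      ov <- IRanges::overlapsAny(annotation, gr, ignore.strand = TRUE)
      if (any(ov)) paste(unique(nm[ov]), collapse = ",") else ""
    }, character(1))
  }
  out
}

#' Run the full SALI pipeline
#'
#' Adapter trimming, length filtering, unique exact mapping with the
#' 32-38 nt clustering window, identical-read cluster enrichment against
#' the control, and overlap merging.
#'
#' @param treated,control named read vectors (or FASTQ paths).
#' @param genome DNAStringSet or FASTA path.
#' @param adapter 5' adapter sequence.
#' @param minLen minimum read length after trimming (default 16).
#' @param minCount cluster enrichment threshold (default 14).
#' @param maxControlCount tolerated control count (default 0).
#' @param annotation optional GRanges for transcript assignment.
#' @return list with `merged` (data.frame), `clusters` (GRanges),
#'   `stages` (read counts surviving each stage).
#' @export
saliPipeline <- function(treated, control, genome,
                         adapter = DEFAULT_ADAPTER, minLen = 16L,
                         minCount = 14L, maxControlCount = 0L,
                         annotation = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- readGenome(genome)
  if (is.character(treated) && length(treated) == 1L &&
      file.exists(treated))
    treated <- readReads(treated)
  if (is.character(control) && length(control) == 1L &&
      file.exists(control))
    control <- readReads(control)
  stage <- function(tr, co) c(treated = length(tr), control = length(co))
  stages <- list(input = stage(treated, control))
  tTrim <- trimAdapter(treated, adapter)
  cTrim <- trimAdapter(control, adapter)
  tLen <- filterLengths(tTrim, minLen)
  cLen <- filterLengths(cTrim, minLen)
  stages$length_filtered <- stage(tLen, cLen)
  mT <- mapUnique(tLen, genome)
  mC <- mapUnique(cLen, genome)
  stages$uniquely_placed_in_window <- c(
    treated = sum(mT$placed$count), control = sum(mC$placed$count))
  clusters <- enrichClusters(mT$placed, mC$placed, minCount,
                             maxControlCount)
  merged <- mergeClusters(clusters, annotation = annotation)
  list(merged = merged, clusters = clusters, stages = stages)
}
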