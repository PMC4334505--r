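#' Read a genome or sequence set from FASTA
#'
#' Sequences are uppercased; both T and U alphabets are accepted and
#' preserved as given.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] (T alphabet) when the file contains
#'   no U, otherwise an [Biostrings::RNAStringSet].
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(Biostrings::DNAStringSet())
  hdr <- grepl("^>", lines)
  if (!hdr[1L])
    stopf("malformed FASTA: line 1 of %s does not start with '>'", path)
  bad <- which(!hdr & !grepl("^[ACGTUNacgtun]*$", lines))
  if (length(bad))
    stopf("malformed FASTA: invalid sequence characters at line %d of %s",
          bad[1L], path)
  grp <- cumsum(hdr)
  names <- sub("^>\\s*", "", lines[hdr])
  names <- sub("\\s.*$", "", names)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  seqs <- seqs[as.character(seq_along(names))]
  seqs[is.na(seqs)] <- ""
  hasU <- any(grepl("U", seqs))
  if (hasU)
    Biostrings::RNAStringSet(setNames(chartr("T", "U", seqs), names))
  else
    Biostrings::DNAStringSet(setNames(seqs, names))
}

#' Write sequences to FASTA
#'
#' @param seqs a named XStringSet or named character vector.
#' @param path output path.
#' @param width line width.
#' @export
writeGenome <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) {
    if (any(grepl("U", toupper(seqs))))
      seqs <- Biostrings::RNAStringSet(toupper(seqs))
    else
      seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

PROBE_META_COLS <- c("probe_id", "contig", "start", "end", "strand",
                     "sequence", "unique")

#' Read a tiling-array probe table
#'
#' The TSV schema is the package's ingestion point for tiling-array data
#' (raw CEL processing is out of scope): header columns `probe_id`,
#' `contig`, `start`, `end` (1-based inclusive coordinates), `strand`,
#' `sequence`, `unique`, followed by one numeric intensity column per
#' sample. Sample columns are auto-discovered.
#'
#' @param path path to the TSV file.
#' @return a [ProbeSet-class].
#' @export
readProbeTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(PROBE_META_COLS, colnames(df))
  if (length(miss))
    stopf("probe table %s is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  sampleCols <- setdiff(colnames(df), PROBE_META_COLS)
  if (!length(sampleCols))
    stopf("probe table %s has no sample intensity columns", path)
  probeSetFromDf(df, sampleCols)
}

probeSetFromDf <- function(df, sampleCols) {
  if (any(df$start > df$end))
    stopf("probe interval with start > end (probe %s)",
          df$probe_id[which(df$start > df$end)[1L]])
  intens <- as.matrix(df[, sampleCols, drop = FALSE])
  if (any(!is.finite(intens)) || any(intens < 0))
    stopf("probe intensities must be finite and nonnegative")
  gr <- GRanges(df$contig,
                IRanges(start = df$start, end = df$end),
                strand = df$strand)
  mcols(gr) <- DataFrame(probe_id = df$probe_id,
                         sequence = toupper(df$sequence),
                         unique = as.logical(df$unique))
  if ("hyb_dG" %in% colnames(df)) mcols(gr)$hyb_dG <- df$hyb_dG
  rownames(intens) <- df$probe_id
  se <- SummarizedExperiment(assays = list(intensity = intens),
                             rowRanges = gr)
  new("ProbeSet", se)
}

#' Write a ProbeSet to the probe-table TSV schema
#'
#' @param probes a [ProbeSet-class].
#' @param path output path.
#' @export
writeProbeTable <- function(probes, path) {
  gr <- rowRanges(probes)
  df <- data.frame(probe_id = gr$probe_id,
                   contig = as.character(seqnames(gr)),
                   start = start(gr), end = end(gr),
                   strand = as.character(strand(gr)),
                   sequence = gr$sequence,
                   unique = gr$unique,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(gr$hyb_dG)) df$hyb_dG <- gr$hyb_dG
  df <- cbind(df, as.data.frame(intensities(probes), check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' TSV columns: `gene`, `condition`, `genotype` (wild-type / mutant),
#' `replicate`, `ct_target`, `ct_reference`. The reference gene is ACT1 by
#' convention; Ct values must be positive.
#'
#' @param path path to the TSV file.
#' @return a data.frame.
#' @export
readQpcrTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "condition", "genotype", "replicate",
            "ct_target", "ct_reference")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stopf("qPCR table %s is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  if (any(df$ct_target <= 0) || any(df$ct_reference <= 0))
    stopf("Ct values must be positive")
  if (!all(df$genotype %in% c("wild-type", "mutant")))
    stopf("genotype must be 'wild-type' or 'mutant'")
  df
}

#' Write hits or regions to BED6
#'
#' Output is 0-based half-open per the BED convention; the score column
#' carries `round(1000 * score)`.
#'
#' @param gr a GRanges with metadata columns `name` (optional) and `score`
#'   in [0, 1].
#' @param path output path.
#' @param contigLengths optional named vector of contig lengths used to
#'   validate coordinates.
#' @export
writeBedHits <- function(gr, path, contigLengths = NULL) {
  if (!is.null(contigLengths)) {
    lens <- contigLengths[as.character(seqnames(gr))]
    if (any(is.na(lens)) || any(end(gr) > lens) || any(start(gr) < 1))
      stopf("interval out of range of declared contig lengths")
  }
  score <- if (!is.null(gr$score)) gr$score else 0
  name <- if (!is.null(gr$name)) gr$name else
    paste0("hit_", seq_along(gr))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   chromStart = start(gr) - 1L,
                   chromEnd = end(gr),
                   name = name,
                   score = round(1000 * score),
                   strand = as.character(strand(gr)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file into a GRanges
#'
#' BED 0-based half-open coordinates are converted to the internal 1-based
#' closed convention; the 0-1000 score column is rescaled to [0, 1].
#'
#' @param path path to the BED file.
#' @return GRanges with metadata columns `name` and `score`.
#' @export
readBedHits <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stopf("expected BED6: %s", path)
  gr <- GRanges(df[[1L]], IRanges(df[[2L]] + 1L, df[[3L]]),
                strand = df[[6L]])
  gr$name <- df[[4L]]
  gr$score <- df[[5L]] / 1000
  gr
}

#' Read genome annotation from GFF3
#'
#' Parsed as 1-based inclusive (the GFF convention, which is also the
#' internal GRanges convention).
#'
#' @param path path to the GFF3 file.
#' @param featureTypes optional character vector restricting feature types.
#' @return GRanges with metadata columns `type`, `ID` and `Name` when
#'   present.
#' @export
readAnnotation <- function(path, featureTypes = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(featureTypes)) gr <- gr[gr$type %in% featureTypes]
  gr
}

#' Write genome annotation to GFF3
#'
#' @param gr GRanges with a `type` metadata column.
#' @param path output path.
#' @export
writeAnnotation <- function(gr, path) {
  if (is.null(gr$type)) gr$type <- "gene"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read reads from FASTQ
#'
#' @param path path to a FASTQ file (Sanger qualities; qualities are not
#'   used downstream).
#' @return a named character vector of read sequences (uppercase, DNA
#'   alphabet).
#' @export
readReads <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(character())
  if (length(lines) %% 4L != 0L)
    stopf("malformed FASTQ (%d lines): %s", length(lines), path)
  ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  ids <- sub("\\s.*$", "", ids)
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  setNames(seqs, ids)
}

#' Write reads to FASTQ (constant Sanger quality)
#'
#' @param reads named character vector of read sequences.
#' @param path output path.
#' @export
writeReads <- function(reads, path) {
  if (is.null(names(reads)))
    names(reads) <- paste0("read_", seq_along(reads))
  qual <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  out <- as.vector(rbind(paste0("@", names(reads)), unname(reads),
                         "+", qual))
  writeLines(out, path)
  invisible(path)
}

#' Read a curated substrate stem-loop table
#'
#' TSV columns: `name`, `group` (e.g. ncRNA / PCG), `sequence` (full
#' stem-loop, 5' to 3'), `loop_start` (1-based position of the first loop
#' nucleotide within `sequence`) and `loop_len`.
#'
#' @param path path to the TSV file.
#' @return a data.frame.
#' @export
readSubstrateTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "group", "sequence", "loop_start", "loop_len")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stopf("substrate table %s is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  df$sequence <- toRNA(df$sequence)
  bad <- df$loop_start < 1 |
    df$loop_start + df$loop_len - 1 > nchar(df$sequence)
  if (any(bad))
    stopf("substrate %s: loop outside sequence", df$name[which(bad)[1L]])
  df
}

#' Serialize a ScoringModel to JSON
#' @param model a [ScoringModel-class].
#' @param path output path.
#' @export
writeScoringModel <- function(model, path) {
  obj <- list(
    loopWeights = model@loopWeights,
    boxWeights = model@boxWeights,
    boxes = model@boxes,
    pairingWeights = model@pairingWeights,
    componentWeights = as.list(model@componentWeights),
    conservationEnabled = model@conservationEnabled,
    cutoff = model@cutoff,
    cleavageOffsets = model@cleavageOffsets,
    substrateFrames = model@substrateFrames,
    seqRange = model@seqRange,
    scoreShift = model@scoreShift,
    scoreScale = model@scoreScale,
    backgroundFreqs = model@backgroundFreqs
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Deserialize a ScoringModel from JSON
#' @param path path written by [writeScoringModel()].
#' @return a [ScoringModel-class].
#' @export
readScoringModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asMat <- function(x, nr, nc) {
    m <- if (is.matrix(x)) x else matrix(as.numeric(x), nr, nc, byrow = TRUE)
    storage.mode(m) <- "double"
    dimnames(m) <- list(BASES, NULL)
    m
  }
  lw <- asMat(obj$loopWeights, 4, 4)
  bw <- asMat(obj$boxWeights, 4, 52)
  new("ScoringModel",
      loopWeights = lw, boxWeights = bw,
      boxes = lapply(obj$boxes, as.integer),
      pairingWeights = as.numeric(obj$pairingWeights),
      componentWeights = unlist(obj$componentWeights),
      conservationEnabled = as.logical(obj$conservationEnabled),
      cutoff = as.numeric(obj$cutoff),
      cleavageOffsets = as.integer(obj$cleavageOffsets),
      substrateFrames = as.character(obj$substrateFrames),
      seqRange = as.numeric(obj$seqRange),
      scoreShift = as.numeric(obj$scoreShift),
      scoreScale = as.numeric(obj$scoreScale),
      backgroundFreqs = as.numeric(obj$backgroundFreqs))
}
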