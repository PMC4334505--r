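#' Fold an RNA sequence to its minimum-free-energy structure
#'
#' Zuker-style dynamic programming over a bundled simplified
#' nearest-neighbor parameter table (stacking energies, hairpin-length
#' penalties, interior/bulge and multiloop terms). Watson-Crick pairs, G-U
#' wobble pairs and non-canonical A-C pairs (with a +1.0 kcal/mol
#' destabilizing surcharge per pair) are permitted; pseudoknots are not.
#' The minimal hairpin loop is 3 nt.
#'
#' @param sequence a single RNA or DNA sequence (T is read as U); length
#'   >= 8.
#' @return a [FoldResult-class].
#' @examples
#' fr <- foldRNA("GGGGAAAACCCC")
#' foldEnergy(fr)
#' terminalLoops(fr)
#' @export
foldRNA <- function(sequence) {
  sequence <- toRNA(as.character(sequence))
  if (nchar(sequence) < 8L)
    stopf("sequence too short to fold (length %d < 8)", nchar(sequence))
  if (!grepl("^[ACGU]+$", sequence))
    stopf("invalid character in sequence (expect ACGU/T)")
  res <- .fold_mfe_cpp(sequence)
  dG <- if (res$dG > 0) 0 else res$dG  # empty structure always available
  new("FoldResult",
      sequence = sequence,
      structure = res$structure,
      dG = dG,
      terminalLoops = extractTerminalLoops(sequence, res$partner))
}

# hairpin loops with the stack depth of their closing stems, from a partner
# vector (1-based, NA = unpaired)
extractTerminalLoops <- function(sequence, partner) {
  n <- length(partner)
  out <- data.frame(start = integer(), end = integer(),
                    seq = character(), stem_bp = integer(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    j <- partner[i]
    if (is.na(j) || j <= i) next
    inner <- seq(i + 1L, j - 1L)
    if (length(inner) && all(is.na(partner[inner]))) {
      # hairpin closed by (i, j); stem depth = consecutive stacked pairs
      depth <- 0L
      a <- i; b <- j
      while (a >= 1L && b <= n && !is.na(partner[a]) && partner[a] == b) {
        depth <- depth + 1L
        a <- a - 1L; b <- b + 1L
      }
      out <- rbind(out, data.frame(
        start = i + 1L, end = j - 1L,
        seq = substr(sequence, i + 1L, j - 1L),
        stem_bp = depth, stringsAsFactors = FALSE))
    }
  }
  out
}

LOOP_CLASSES <- c("G2_NGNN", "AHNN", "BHNN", "TRILOOP", "PENTALOOP",
                  "HEXALOOP", "OTHER")

#' Classify the terminal loop of a folded structure
#'
#' Uses the terminal loop of the longest stem. Loop size 3 is a TRILOOP, 5 a
#' PENTALOOP, 6 a HEXALOOP. Tetraloops partition exactly by sequence: G at
#' loop position 2 is the canonical G2-loop (G2_NGNN); otherwise A at loop
#' position 1 gives AHNN; anything else is BHNN (IUPAC H = not G, B = not
#' A). Unfolded sequences and loops larger than 6 nt are OTHER.
#'
#' @param fold a [FoldResult-class], or a loop sequence given directly as a
#'   character string.
#' @return one of G2_NGNN, AHNN, BHNN, TRILOOP, PENTALOOP, HEXALOOP, OTHER.
#' @export
classifyLoop <- function(fold) {
  if (is.character(fold)) return(classifyLoopSeq(fold))
  tl <- terminalLoops(fold)
  if (nrow(tl) == 0L) return("OTHER")
  best <- tl[order(-tl$stem_bp, tl$start), , drop = FALSE][1L, ]
  classifyLoopSeq(best$seq)
}

classifyLoopSeq <- function(loopSeq) {
  loopSeq <- toRNA(loopSeq)
  n <- nchar(loopSeq)
  if (n == 3L) return("TRILOOP")
  if (n == 5L) return("PENTALOOP")
  if (n == 6L) return("HEXALOOP")
  if (n != 4L) return("OTHER")
  b <- strsplit(loopSeq, "")[[1L]]
  if (b[2L] == "G") return("G2_NGNN")
  if (b[1L] == "A") return("AHNN")
  "BHNN"
}

#' Fold and classify SALI cleavage products
#'
#' Folds the representative sequence (the longest member) of each merged
#' read cluster, classifies its terminal loop, and tabulates the class
#' distribution.
#'
#' @param representatives character vector of representative sequences (or a
#'   merged-cluster data.frame from [mergeClusters()] with a
#'   `representative` column).
#' @return a data.frame with columns `class`, `count` and `fraction`,
#'   covering every loop class (zero counts included), plus per-input
#'   classifications in attribute `"classes"`.
#' @export
classifyProducts <- function(representatives) {
  if (is.data.frame(representatives))
    representatives <- representatives$representative
  if (length(representatives) == 0L) {
    return(data.frame(class = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  cls <- vapply(representatives, function(s) {
    f <- foldRNA(s)
    if (f@dG >= 0) "OTHER" else classifyLoop(f)
  }, character(1), USE.NAMES = FALSE)
  counts <- table(factor(cls, levels = LOOP_CLASSES))
  out <- data.frame(class = names(counts),
                    count = as.integer(counts),
                    fraction = as.integer(counts) / length(cls),
                    stringsAsFactors = FALSE)
  attr(out, "classes") <- cls
  out
}
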