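#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges granges seqnames strand start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowRanges colData
NULL

#' Scoring model for G2-loop stem-loop candidates
#'
#' Positional log-odds weights for the tetraloop and the four stem boxes
#' (initial binding and positioning box, binding stability box, middle box,
#' cleavage efficiency box), per-position expected pairing probabilities, and
#' the component weights combining the sequence, structure and similarity
#' components into a final score in [0, 1]. The model frame is a 52-position
#' stem-loop with the tetraloop at positions 25-28 and the scissile
#' phosphates at positions 9/10 and 43/44.
#'
#' @slot loopWeights 4 x 4 matrix of log2 odds (rows A, C, G, U; columns loop
#'   positions 1-4).
#' @slot boxWeights 4 x 52 matrix of log2 odds over the model frame; NA
#'   outside the modeled boxes.
#' @slot boxes named list of frame positions belonging to each box.
#' @slot pairingWeights numeric(52), expected pairing probability per frame
#'   position (NA outside the stems).
#' @slot componentWeights named nonnegative weights (sequence, structure,
#'   similarity) summing to one.
#' @slot conservationEnabled logical; TRUE when per-position conservation
#'   fractions were supplied at training.
#' @slot cutoff score cutoff used by [scanGenome()], default 0.85.
#' @slot cleavageOffsets frame positions of the scissile phosphates.
#' @slot substrateFrames character vector of training-substrate frame
#'   sequences used by the similarity component.
#' @slot seqRange numeric(2); raw log-odds sums mapped to 0 and 1 by the
#'   sequence component.
#' @slot scoreShift,scoreScale calibrated affine transform applied to each
#'   component (see [calibrateModel()]).
#' @slot backgroundFreqs numeric(4) background base frequencies (A, C, G, U).
#' @export
setClass("ScoringModel",
  representation(
    loopWeights = "matrix",
    boxWeights = "matrix",
    boxes = "list",
    pairingWeights = "numeric",
    componentWeights = "numeric",
    conservationEnabled = "logical",
    cutoff = "numeric",
    cleavageOffsets = "integer",
    substrateFrames = "character",
    seqRange = "numeric",
    scoreShift = "numeric",
    scoreScale = "numeric",
    backgroundFreqs = "numeric"
  )
)

setValidity("ScoringModel", function(object) {
  w <- object@componentWeights
  msg <- character()
  if (length(w) != 3L || is.null(names(w)) ||
      !setequal(names(w), c("sequence", "structure", "similarity")))
    msg <- c(msg, "componentWeights must be named sequence/structure/similarity")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-6)
    msg <- c(msg, "componentWeights must be nonnegative and sum to 1")
  if (object@cutoff <= 0 || object@cutoff >= 1)
    msg <- c(msg, "cutoff must lie in (0, 1)")
  if (!identical(dim(object@loopWeights), c(4L, 4L)))
    msg <- c(msg, "loopWeights must be 4 x 4")
  if (!identical(dim(object@boxWeights), c(4L, 52L)))
    msg <- c(msg, "boxWeights must be 4 x 52")
  if (length(object@pairingWeights) != 52L)
    msg <- c(msg, "pairingWeights must have length 52")
  if (length(msg)) msg else TRUE
})

#' Ground truth emitted by the synthetic-data generators
#'
#' Records every feature planted into a synthetic genome so that recovery
#' tests can compare pipeline calls against a known answer.
#'
#' @slot plantedLoops GRanges of planted stem-loops with metadata columns
#'   `loop_class`, `loop_seq` and `tier`.
#' @slot foldChanges named numeric vector of planted expression fold changes
#'   (linear scale) per transcript.
#' @slot cleavageSites GRanges of planted cleavage sites (the span between
#'   the two scissile positions) with metadata columns `efficiency` and
#'   `frag3_len`.
#' @slot seed integer seed used by the generator.
#' @export
setClass("TruthManifest",
  representation(
    plantedLoops = "GRanges",
    foldChanges = "numeric",
    cleavageSites = "GRanges",
    seed = "integer"
  )
)

setValidity("TruthManifest", function(object) {
  msg <- character()
  eff <- object@cleavageSites$efficiency
  if (length(eff) && (any(eff < 0) || any(eff > 1)))
    msg <- c(msg, "cleavage efficiencies must lie in [0, 1]")
  if (length(object@foldChanges) && any(object@foldChanges <= 0))
    msg <- c(msg, "fold changes must be positive")
  if (length(msg)) msg else TRUE
})

#' Tiling-array probe container
#'
#' A RangedSummarizedExperiment holding one row per probe: genomic position
#' (`rowRanges`), probe sequence, uniqueness flag and predicted hybridization
#' free energy in `rowData`, and one linear-scale intensity column per sample
#' in the `intensity` assay.
#'
#' @export
setClass("ProbeSet", contains = "RangedSummarizedExperiment")

setValidity("ProbeSet", function(object) {
  msg <- character()
  rd <- rowData(object)
  need <- c("probe_id", "sequence", "unique")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("missing rowData column(s): ",
                         paste(miss, collapse = ", ")))
  if (!"intensity" %in% names(assays(object)))
    msg <- c(msg, "missing 'intensity' assay")
  else if (any(assay(object, "intensity") < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be nonnegative")
  if ("sequence" %in% colnames(rd) &&
      any(nchar(rd$sequence) != width(rowRanges(object))))
    msg <- c(msg, "probe sequence length must equal interval width")
  if (length(msg)) msg else TRUE
})

#' Predicted RNA secondary structure
#'
#' Result of [foldRNA()]: the minimum-free-energy structure in dot-bracket
#' notation, its free energy, and the extracted terminal (hairpin) loops.
#'
#' @slot sequence RNA sequence (U alphabet).
#' @slot structure dot-bracket string of the same length.
#' @slot dG free energy of the structure, kcal/mol.
#' @slot terminalLoops data.frame of hairpin loops with columns `start`,
#'   `end`, `seq` and `stem_bp` (consecutive closing stack depth).
#' @export
setClass("FoldResult",
  representation(
    sequence = "character",
    structure = "character",
    dG = "numeric",
    terminalLoops = "data.frame"
  )
)

setValidity("FoldResult", function(object) {
  msg <- character()
  if (nchar(object@sequence) != nchar(object@structure))
    msg <- c(msg, "sequence and structure lengths differ")
  db <- strsplit(object@structure, "")[[1]]
  if (sum(db == "(") != sum(db == ")"))
    msg <- c(msg, "unbalanced brackets")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScoringModel", function(object) {
  w <- object@componentWeights
  cat("ScoringModel (52-position G2 stem-loop frame)\n")
  cat(sprintf("  component weights: sequence %.3f, structure %.3f, similarity %.3f\n",
              w["sequence"], w["structure"], w["similarity"]))
  cat(sprintf("  cutoff: %.2f | conservation: %s | training substrates: %d\n",
              object@cutoff,
              if (object@conservationEnabled) "on" else "off",
              length(object@substrateFrames)))
})

setMethod("show", "TruthManifest", function(object) {
  cat("TruthManifest\n")
  cat(sprintf("  planted loops: %d | fold changes: %d | cleavage sites: %d | seed: %d\n",
              length(object@plantedLoops), length(object@foldChanges),
              length(object@cleavageSites), object@seed))
})

setMethod("show", "FoldResult", function(object) {
  cat("FoldResult  dG =", sprintf("%.2f kcal/mol", object@dG), "\n")
  cat(" ", object@sequence, "\n")
  cat(" ", object@structure, "\n")
  nl <- nrow(object@terminalLoops)
  if (nl > 0)
    cat(sprintf("  %d terminal loop(s): %s\n", nl,
                paste(object@terminalLoops$seq, collapse = ", ")))
})

#' @rdname ScoringModel-class
#' @param object a ScoringModel
#' @export
setGeneric("componentWeights", function(object)
  standardGeneric("componentWeights"))

#' @rdname ScoringModel-class
#' @export
setMethod("componentWeights", "ScoringModel", function(object)
  object@componentWeights)

#' @rdname ScoringModel-class
#' @export
setGeneric("scoreCutoff", function(object) standardGeneric("scoreCutoff"))

#' @rdname ScoringModel-class
#' @export
setMethod("scoreCutoff", "ScoringModel", function(object) object@cutoff)

#' @rdname TruthManifest-class
#' @param object a TruthManifest
#' @export
setGeneric("plantedLoops", function(object) standardGeneric("plantedLoops"))

#' @rdname TruthManifest-class
#' @export
setMethod("plantedLoops", "TruthManifest", function(object)
  object@plantedLoops)

#' @rdname TruthManifest-class
#' @export
setGeneric("cleavageSites", function(object) standardGeneric("cleavageSites"))

#' @rdname TruthManifest-class
#' @export
setMethod("cleavageSites", "TruthManifest", function(object)
  object@cleavageSites)

#' @rdname TruthManifest-class
#' @export
setGeneric("foldChanges", function(object) standardGeneric("foldChanges"))

#' @rdname TruthManifest-class
#' @export
setMethod("foldChanges", "TruthManifest", function(object)
  object@foldChanges)

#' @rdname ProbeSet-class
#' @param object a ProbeSet
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname ProbeSet-class
#' @export
setMethod("intensities", "ProbeSet", function(object)
  assay(object, "intensity"))

#' @rdname ProbeSet-class
#' @export
setGeneric("probeSequences", function(object)
  standardGeneric("probeSequences"))

#' @rdname ProbeSet-class
#' @export
setMethod("probeSequences", "ProbeSet", function(object)
  rowData(object)$sequence)

#' @rdname FoldResult-class
#' @param object a FoldResult
#' @export
setGeneric("terminalLoops", function(object) standardGeneric("terminalLoops"))

#' @rdname FoldResult-class
#' @export
setMethod("terminalLoops", "FoldResult", function(object)
  object@terminalLoops)

#' @rdname FoldResult-class
#' @export
setGeneric("foldEnergy", function(object) standardGeneric("foldEnergy"))

#' @rdname FoldResult-class
#' @export
setMethod("foldEnergy", "FoldResult", function(object) object@dG)
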