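#' Proportion estimate with a binomial confidence interval
#'
#' @param successes,n counts with 0 <= successes <= n, n >= 1.
#' @param ciMethod "clopper-pearson" (exact, default) or "wilson".
#' @param level confidence level (default 0.95).
#' @param digits rounding of the reported percent (default 0).
#' @return list with `percent`, `ci` (percent scale) and the inputs.
#' @export
proportionEstimate <- function(successes, n,
                               ciMethod = c("clopper-pearson", "wilson"),
                               level = 0.95, digits = 0) {
  ciMethod <- match.arg(ciMethod)
  if (n < 1) stopf("n must be >= 1")
  if (successes < 0 || successes > n)
    stopf("successes must lie in [0, n]")
  p <- successes / n
  if (ciMethod == "clopper-pearson") {
    ci <- as.numeric(binom.test(successes, n,
                                conf.level = level)$conf.int)
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    den <- 1 + z^2 / n
    center <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    ci <- c(center - half, center + half)
  }
  list(percent = round(100 * p, digits), ci = 100 * clip01(ci),
       successes = successes, n = n, method = ciMethod)
}

#' Array-vs-qPCR concordance
#'
#' Spearman rank correlation (average ranks on ties) between paired array
#' and qPCR log2 fold changes, plus the directional concordance at
#' 2-fold: among pairs with array log2 > 1, the fraction with qPCR fold
#' > 2.
#'
#' @param arrayLog2,qpcrLog2 paired finite log2 fold changes.
#' @return list with `rho`, `p`, `n`, `concordance_percent` and
#'   `n_twofold`.
#' @export
concordance <- function(arrayLog2, qpcrLog2) {
  ok <- is.finite(arrayLog2) & is.finite(qpcrLog2)
  arrayLog2 <- arrayLog2[ok]
  qpcrLog2 <- qpcrLog2[ok]
  if (length(arrayLog2) < 3L) stopf("need >= 3 pairs")
  ct <- suppressWarnings(
    stats::cor.test(arrayLog2, qpcrLog2, method = "spearman"))
  up <- arrayLog2 > 1
  conc <- if (any(up)) 100 * mean(qpcrLog2[up] > 1) else NA_real_
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(arrayLog2),
       concordance_percent = conc, n_twofold = sum(up))
}

#' Call upregulated genes from a qPCR table
#'
#' Per gene and condition, the replicate dCt is ct_target minus
#' ct_reference; the fold change is 2^(mean dCt wild-type - mean dCt
#' mutant), and a gene is upregulated when the fold exceeds
#' `foldThreshold` and a one-tailed two-sample t-test (mutant dCt below
#' wild-type dCt) gives p below `alpha`.
#'
#' @param qpcr data.frame in the [readQpcrTable()] schema (>= 3
#'   replicates per genotype).
#' @param foldThreshold linear fold-change gate (default 1.2).
#' @param alpha t-test significance gate (default 0.01).
#' @return data.frame with one row per gene x condition (`fold`, `p`,
#'   `upregulated`); the any-condition union summary is in attribute
#'   `"summary"`.
#' @export
callUpregulated <- function(qpcr, foldThreshold = 1.2, alpha = 0.01) {
  qpcr$dct <- qpcr$ct_target - qpcr$ct_reference
  combos <- unique(qpcr[, c("gene", "condition")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    g <- combos$gene[i]; cond <- combos$condition[i]
    sub <- qpcr[qpcr$gene == g & qpcr$condition == cond, ]
    wt <- sub$dct[sub$genotype == "wild-type"]
    mut <- sub$dct[sub$genotype == "mutant"]
    if (length(wt) < 3L || length(mut) < 3L)
      stopf("gene %s / condition %s: need >= 3 replicates per genotype",
            g, cond)
    fold <- 2^(mean(wt) - mean(mut))
    p <- if (stats::sd(c(wt, mut)) < 1e-12) 1 else
      t.test(wt, mut, alternative = "greater")$p.value
    data.frame(gene = g, condition = cond, fold = fold, p = p,
               upregulated = fold > foldThreshold & p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  anyUp <- tapply(out$upregulated, out$gene, any)
  attr(out, "summary") <- list(
    genes = length(anyUp),
    upregulated_any_condition = sum(anyUp),
    percent_upregulated = 100 * mean(anyUp))
  out
}

#' Match predicted cleavage products against in vivo 5'-phosphate ends
#'
#' A 3'-end cleavage product matches when any detected 5'-P site lies
#' within the first `window` nucleotides of the product's 5' end on the
#' same strand.
#'
#' @param products GRanges of 3'-end cleavage products (their 5' ends are
#'   the predicted scissile positions).
#' @param sites GRanges of in vivo 5'-P positions (width-1 ranges).
#' @param window match window in nucleotides (default 5).
#' @return list with `fraction`, logical `matched` and `n`.
#' @export
matchRaceEnds <- function(products, sites, window = 5L) {
  matched <- vapply(seq_along(products), function(i) {
    p <- products[i]
    minus <- as.character(strand(p)) == "-"
    lo <- if (minus) end(p) - window + 1L else start(p)
    hi <- if (minus) end(p) else start(p) + window - 1L
    same <- sites[as.character(seqnames(sites)) ==
                    as.character(seqnames(p)) &
                  as.character(strand(sites)) ==
                    as.character(strand(p))]
    any(start(same) >= lo & start(same) <= hi)
  }, logical(1))
  list(fraction = if (length(products)) mean(matched) else NA_real_,
       matched = matched, n = length(products))
}

#' Compare detection methods against known substrates
#'
#' Computes the per-method fraction of known substrates detected, the
#' cardinality of every Venn region over the call sets, and per-method
#' quartile summaries of the best loop score per detected target.
#'
#' @param callSets named list of character vectors of gene identifiers
#'   (one per method).
#' @param known character vector of known substrate identifiers.
#' @param geneScores optional named numeric vector of best loop score per
#'   gene.
#' @return list with `detection_rates`, `venn` (named region counts),
#'   `union_size` and `score_summary` (per-method quartiles, when scores
#'   are given).
#' @export
compareMethods <- function(callSets, known = character(),
                           geneScores = NULL) {
  methods <- names(callSets)
  callSets <- lapply(callSets, unique)
  rates <- vapply(callSets, function(s)
    if (length(known)) mean(known %in% s) else NA_real_, numeric(1))
  all <- unique(unlist(callSets))
  membership <- vapply(callSets, function(s) all %in% s,
                       logical(length(all)))
  if (length(all) == 1L) membership <- matrix(membership, nrow = 1L,
                                              dimnames = list(NULL,
                                                              methods))
  region <- apply(membership, 1L, function(m)
    paste(methods[m], collapse = "&"))
  venn <- table(region)
  scoreSummary <- NULL
  if (!is.null(geneScores)) {
    scoreSummary <- lapply(callSets, function(s) {
      v <- geneScores[intersect(s, names(geneScores))]
      if (!length(v)) return(NULL)
      quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = TRUE)
    })
  }
  list(detection_rates = rates,
       venn = as.list(venn),
       union_size = length(all),
       score_summary = scoreSummary)
}
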