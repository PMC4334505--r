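#' Position-wise sequence and pairing statistics over a substrate group
#'
#' Substrates are anchored at the loop in the 52-position model frame. Per
#' position and base, a Fisher exact test compares the observed base count
#' (base vs not-base) against counts expected from the background
#' frequencies scaled to the group size; pairing is tested per position by
#' a chi-squared goodness-of-fit against the background pairing rate. Both
#' test families are Bonferroni-adjusted over positions x tests.
#'
#' @param substrates data.frame in the [readSubstrateTable()] schema
#'   (>= 5 rows).
#' @param backgroundFreqs numeric(4) background base frequencies
#'   (A, C, G, U).
#' @param backgroundPairingRate expected pairing fraction under the null
#'   (default 0.5).
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with one row per frame position: base counts,
#'   pairing counts, Bonferroni-adjusted per-base Fisher p-values
#'   (`p_A`..`p_U`), adjusted `chi2_p`, and `significant_seq` /
#'   `significant_pairing` flags.
#' @export
positionTests <- function(substrates,
                          backgroundFreqs = c(A = 0.31, C = 0.19,
                                              G = 0.19, U = 0.31),
                          backgroundPairingRate = 0.5, alpha = 0.05) {
  if (nrow(substrates) < 5L)
    stopf("need a group of >= 5 substrates (have %d)", nrow(substrates))
  backgroundFreqs <- backgroundFreqs / sum(backgroundFreqs)
  frames <- vapply(seq_len(nrow(substrates)), function(i)
    substrateFrame(substrates$sequence[i], substrates$loop_start[i],
                   substrates$loop_len[i]), character(1))
  fm <- do.call(rbind, strsplit(frames, ""))
  pm <- t(vapply(seq_len(nrow(substrates)), function(i)
    substratePairingVector(substrates$sequence[i],
                           substrates$loop_start[i],
                           substrates$loop_len[i]),
    numeric(FRAME_LEN)))

  rows <- lapply(seq_len(FRAME_LEN), function(p) {
    obs <- fm[, p]
    obs <- obs[obs != "N"]
    n <- length(obs)
    cnt <- as.integer(table(factor(obs, levels = BASES)))
    names(cnt) <- BASES
    pvals <- rep(NA_real_, 4L)
    names(pvals) <- BASES
    if (n >= 1L) {
      for (b in seq_along(BASES)) {
        expB <- round(n * backgroundFreqs[b])
        tab <- matrix(c(cnt[b], n - cnt[b], expB, n - expB), nrow = 2L)
        pvals[b] <- fisher.test(tab)$p.value
      }
    }
    pv <- pm[, p]
    pv <- pv[!is.na(pv)]
    chi <- NA_real_
    if (length(pv) >= 1L) {
      paired <- sum(pv)
      chi <- suppressWarnings(
        chisq.test(c(paired, length(pv) - paired),
                   p = c(backgroundPairingRate,
                         1 - backgroundPairingRate))$p.value)
    }
    data.frame(position = p, n = n,
               A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]],
               U = cnt[["U"]],
               n_paired = if (length(pv)) sum(pv) else NA_integer_,
               n_unpaired = if (length(pv)) length(pv) - sum(pv)
                            else NA_integer_,
               p_A = pvals[["A"]], p_C = pvals[["C"]],
               p_G = pvals[["G"]], p_U = pvals[["U"]],
               chi2_p = chi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  mFisher <- sum(!is.na(as.matrix(out[, c("p_A", "p_C", "p_G", "p_U")])))
  mChi <- sum(!is.na(out$chi2_p))
  for (col in c("p_A", "p_C", "p_G", "p_U"))
    out[[col]] <- pmin(1, out[[col]] * mFisher)
  out$chi2_p <- pmin(1, out$chi2_p * mChi)
  out$significant_seq <- apply(
    out[, c("p_A", "p_C", "p_G", "p_U")], 1L,
    function(x) any(!is.na(x) & x < alpha))
  out$significant_pairing <- !is.na(out$chi2_p) & out$chi2_p < alpha
  out
}

#' IUPAC consensus of the loop
#'
#' Per loop position, the minimal IUPAC code covering every base whose
#' frequency reaches `threshold`. With `gate = TRUE`, positions lacking a
#' significant base enrichment (per [positionTests()]) fall back to N.
#'
#' @param substrates substrate data.frame (tetraloop positions are read
#'   from the model frame).
#' @param threshold minimum base frequency entering the code (default
#'   0.2).
#' @param gate require positional significance (default FALSE).
#' @param stats optional precomputed [positionTests()] output (required
#'   when `gate = TRUE`).
#' @return the consensus string (one code per loop position).
#' @export
loopConsensus <- function(substrates, threshold = 0.2, gate = FALSE,
                          stats = NULL) {
  frames <- vapply(seq_len(nrow(substrates)), function(i)
    substrateFrame(substrates$sequence[i], substrates$loop_start[i],
                   substrates$loop_len[i]), character(1))
  fm <- do.call(rbind, strsplit(frames, ""))
  loopLen <- max(substrates$loop_len)
  codes <- vapply(seq_len(loopLen), function(k) {
    p <- LOOP_POS[1L] + k - 1L
    obs <- fm[, p]
    obs <- obs[obs != "N"]
    if (!length(obs)) return("N")
    if (gate) {
      if (is.null(stats)) stopf("gate = TRUE needs positionTests() output")
      if (!stats$significant_seq[stats$position == p]) return("N")
    }
    fr <- table(factor(obs, levels = BASES)) / length(obs)
    iupacCode(BASES[fr >= threshold])
  }, character(1))
  paste(codes, collapse = "")
}

#' Percent-paired profile per substrate group
#'
#' Fraction of substrates with a base pair at each model-frame position,
#' per named group, from the folded structures.
#'
#' @param groups named list of substrate data.frames.
#' @return matrix positions x groups of paired fractions (NA where no
#'   substrate covers a position); differences at the scissile and middle-
#'   stem positions (9, 10, 15, 16, 43, 44) are in attribute
#'   `"key_positions"`.
#' @export
percentPairedProfile <- function(groups) {
  prof <- vapply(groups, function(df) {
    pm <- t(vapply(seq_len(nrow(df)), function(i)
      substratePairingVector(df$sequence[i], df$loop_start[i],
                             df$loop_len[i]),
      numeric(FRAME_LEN)))
    colMeans(pm, na.rm = TRUE)
  }, numeric(FRAME_LEN))
  prof[is.nan(prof)] <- NA_real_
  key <- c(9L, 10L, 15L, 16L, 43L, 44L)
  attr(prof, "key_positions") <- prof[key, , drop = FALSE]
  prof
}

#' Median folding free energy per substrate group
#'
#' @param groups named list of substrate data.frames (or of character
#'   vectors of sequences).
#' @return named numeric vector of median dG (kcal/mol) per group.
#' @export
groupDG <- function(groups) {
  vapply(groups, function(g) {
    seqs <- if (is.data.frame(g)) g$sequence else g
    if (!length(seqs)) stopf("empty substrate group")
    median(vapply(seqs, function(s) foldRNA(s)@dG, numeric(1)))
  }, numeric(1))
}
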