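# Independent oracles used by the module and acceptance tests. These mirror
# the documented model definitions in plain R and must stay independent of
# the compiled implementations they check.

# ---- folding energy model (R reimplementation) ------------------------------
.oracle_pairs <- c(CG = 1, GC = 2, GU = 3, UG = 4, AU = 5, UA = 6,
                   AC = 7, CA = 8)
.oracle_stack <- matrix(c(
  -3.3, -3.4, -2.1, -1.4, -2.1, -2.1,
  -2.4, -3.3, -2.5, -1.5, -2.2, -2.4,
  -1.4, -1.5, -0.5,  1.3, -0.6, -1.0,
  -2.1, -2.5, -0.7, -0.5, -1.4, -1.3,
  -2.1, -2.4, -1.4, -0.6, -0.9, -1.3,
  -2.4, -2.1, -1.3, -1.0, -1.0, -1.3), 6, 6, byrow = TRUE)

oracle_pair_code <- function(a, b) {
  idx <- .oracle_pairs[paste0(a, b)]
  if (is.na(idx)) NA_integer_ else unname(idx)
}

oracle_hairpin <- function(u) {
  H <- c(5.4, 5.6, 5.7, 5.4, 6.0, 6.4, 6.8)
  if (u < 3) return(Inf)
  if (u <= 9) return(H[u - 2])
  6.8 + 1.08 * log(u / 9)
}

oracle_energy <- function(seqChars, pairs) {
  n <- length(seqChars)
  partner <- rep(NA_integer_, n)
  for (p in pairs) { partner[p[1]] <- p[2]; partner[p[2]] <- p[1] }
  e <- 0
  for (p in pairs) {
    i <- p[1]; j <- p[2]
    pc <- oracle_pair_code(seqChars[i], seqChars[j])
    if (pc >= 7) e <- e + 1.0
    k <- i + 1; unp <- 0; branches <- 0; inner <- NULL
    while (k < j) {
      if (!is.na(partner[k]) && partner[k] > k && partner[k] < j) {
        branches <- branches + 1
        if (branches == 1) inner <- c(k, partner[k])
        k <- partner[k] + 1
      } else {
        if (is.na(partner[k])) unp <- unp + 1
        k <- k + 1
      }
    }
    if (branches == 0) {
      e <- e + oracle_hairpin(unp)
    } else if (branches == 1) {
      if (unp == 0) {
        pin <- oracle_pair_code(seqChars[inner[1]], seqChars[inner[2]])
        e <- e + if (pc >= 7 || pin >= 7) -0.5 else .oracle_stack[pc, pin]
      } else {
        e <- e + 1.6 + 0.4 * unp
      }
    } else {
      e <- e + 3.4 + 0.1 * unp + 0.4 * branches
    }
  }
  e
}

oracle_enum_structs <- function(seqChars, i, j) {
  if (j - i < 4) return(list(list()))
  out <- oracle_enum_structs(seqChars, i, j - 1)
  for (k in i:(j - 4)) {
    if (is.na(oracle_pair_code(seqChars[k], seqChars[j]))) next
    left <- if (k - 1 >= i) oracle_enum_structs(seqChars, i, k - 1)
            else list(list())
    right <- oracle_enum_structs(seqChars, k + 1, j - 1)
    for (L in left) for (R in right)
      out[[length(out) + 1]] <- c(L, R, list(c(k, j)))
  }
  out
}

oracle_mfe <- function(s) {
  ch <- strsplit(s, "")[[1]]
  structs <- oracle_enum_structs(ch, 1, length(ch))
  min(0, min(vapply(structs, function(p) oracle_energy(ch, p),
                    numeric(1))))
}

# ---- exhaustive segmentation ------------------------------------------------
oracle_seg_rss <- function(x, S) {
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  if (S == 1) return(sse(x))
  best <- Inf
  combs <- utils::combn(n - 1, S - 1)
  for (c in seq_len(ncol(combs))) {
    b <- c(0, combs[, c], n)
    rss <- sum(vapply(seq_len(S), function(k)
      sse(x[(b[k] + 1):b[k + 1]]), numeric(1)))
    if (rss < best) best <- rss
  }
  best
}

# ---- brute-force stem-loop enumeration --------------------------------------
# mirrors the documented candidate definition: NGNN loop; greedy pairing from
# the loop outward over a 16-step window with up to 2 bulges per arm; a run
# of >= 3 consecutive pairs required for candidacy
oracle_enumerate <- function(seq, stemSpan = 16L, maxBulge = 2L,
                             minStem = 3L) {
  ch <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  pairOK <- function(a, b) {
    p <- paste0(a, b)
    p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  n <- length(ch)
  loops <- integer()
  for (i in seq_len(max(n - 3L, 0L))) {
    if (ch[i + 1L] != "G") next
    if (any(!ch[i:(i + 3L)] %in% c("A", "C", "G", "T"))) next
    u <- i - 1L; d <- i + 4L
    bu <- 0L; bd <- 0L
    run <- 0L; bestRun <- 0L
    for (s in seq_len(stemSpan)) {
      if (u < 1L && d > n) break
      a <- if (u >= 1L) ch[u] else NA
      b <- if (d <= n) ch[d] else NA
      paired <- FALSE
      if (!is.na(a) && !is.na(b) && pairOK(a, b)) {
        paired <- TRUE
        u <- u - 1L; d <- d + 1L
      } else {
        aU <- if (u - 1L >= 1L) ch[u - 1L] else NA
        bD <- if (d + 1L <= n) ch[d + 1L] else NA
        if (bu < maxBulge && !is.na(aU) && !is.na(b) && pairOK(aU, b)) {
          bu <- bu + 1L; paired <- TRUE
          u <- u - 2L; d <- d + 1L
        } else if (bd < maxBulge && !is.na(a) && !is.na(bD) &&
                   pairOK(a, bD)) {
          bd <- bd + 1L; paired <- TRUE
          u <- u - 1L; d <- d + 2L
        } else {
          u <- u - 1L; d <- d + 1L
        }
      }
      if (paired) { run <- run + 1L; bestRun <- max(bestRun, run) }
      else run <- 0L
    }
    if (bestRun >= minStem) loops <- c(loops, i)
  }
  loops
}

# ---- Spearman rank correlation ----------------------------------------------
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
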