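#' @useDynLib Rnt1Scan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median mad quantile coef lm rnorm runif setNames
#'   fisher.test chisq.test p.adjust t.test cor binom.test plogis optim
#' @importFrom utils read.delim write.table head tail
NULL

BASES <- c("A", "C", "G", "U")

# IUPAC code table: code -> sorted base set (RNA alphabet)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"),
  H = c("A", "C", "U"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "U")
)

# minimal IUPAC code covering a base set
iupacCode <- function(bases) {
  bases <- sort(unique(bases))
  for (code in names(IUPAC_SETS)) {
    s <- IUPAC_SETS[[code]]
    if (length(s) == length(bases) && all(s == bases)) return(code)
  }
  "N"
}

# does base match an IUPAC code?
iupacMatches <- function(base, code) {
  base %in% IUPAC_SETS[[code]]
}

toRNA <- function(x) chartr("Tt", "Uu", toupper(x))
toDNA <- function(x) chartr("Uu", "Tt", toupper(x))

# reverse complement of a character sequence, preserving T/U convention
reverseComplement2 <- function(x) {
  isRNA <- grepl("U", toupper(x))
  out <- vapply(strsplit(toupper(chartr("U", "T", x)), ""), function(ch) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(unname(comp[ch])), collapse = "")
  }, character(1))
  ifelse(isRNA, chartr("T", "U", out), out)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# canonical pair test over single characters (RNA or DNA letters)
isPairedBase <- function(a, b, wobble = TRUE) {
  a <- toRNA(a); b <- toRNA(b)
  p <- paste0(a, b)
  wc <- c("AU", "UA", "GC", "CG")
  gu <- c("GU", "UG")
  p %in% c(wc, if (wobble) gu)
}

# stop with a consistent message style
stopf <- function(...) stop(sprintf(...), call. = FALSE)

# seeded RNG scope helper: evaluates expr under a local seed without
# disturbing the caller's RNG stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
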