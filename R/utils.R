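## Shared internal helpers and package-wide constants.

## 20 canonical amino acids plus 'X' (unknown / assembly-gap placeholder).
.AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

## The seven canonical spidroin classes, named for their producing glands.
.SPIDROIN_CLASSES <- c("AcSp", "AgSp", "FLAG", "MaSp", "MiSp", "PySp", "TuSp")

## Wildcard symbols permitted in motif descriptions: 'x' matches any residue;
## 'z' marks a second, independent wildcard position in one description.
.WILDCARDS <- c("x", "z")

#' Round half away from zero
#'
#' Percentages in sharing summaries are printed to one decimal with
#' conventional half-up rounding (base \code{round} rounds half to even).
#' @param x numeric vector (non-negative in all package uses).
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @keywords internal
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## Extract residues [start, end) from a sequence string (0-based half-open).
sliceResidues <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

## Derive a stream-specific 32-bit seed from a master seed and an offset, so
## that independent generator components consume independent random streams.
deriveSeed <- function(seed, offset) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 +
                as.numeric(offset) * 40503 + 97) %% 2147483647)
}

## Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Leftmost-greedy non-overlapping match starts (1-based) of `pattern` in
## `subject`. Fixed patterns use literal matching; wildcard patterns are
## translated to a regular expression first.
nonOverlappingMatches <- function(pattern, subject) {
  if (nchar(pattern) == 0L || nchar(subject) < nchar(pattern)) return(integer(0))
  if (grepl("[xz]", pattern)) {
    m <- gregexpr(wildcardToRegex(pattern), subject, perl = TRUE)[[1L]]
  } else {
    m <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  }
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

## Translate a motif description to a literal regex ('x'/'z' -> any residue).
wildcardToRegex <- function(pattern) {
  chartr("xz", "..", pattern)
}

## Validate a residue string; returns NULL or the 1-based offending position.
badResiduePosition <- function(seq, allowWildcards = FALSE) {
  alphabet <- paste0(.AA_LETTERS, collapse = "")
  if (allowWildcards) alphabet <- paste0(alphabet, "xz")
  pos <- regexpr(sprintf("[^%s]", alphabet), seq)
  if (pos == -1L) NULL else as.integer(pos)
}

## Draw one element of v (immune to sample()'s scalar expansion).
sampleOne <- function(v) {
  if (length(v) == 1L) v else sample(v, 1L)
}

## Stable deterministic string ordering (byte/C collation, locale-independent).
orderStrings <- function(...) {
  order(..., method = "radix")
}
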