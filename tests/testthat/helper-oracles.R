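## Independent oracles used to cross-check the package implementations.
## These are deliberately naive (dynamic programming, while-loop scans,
## direct enumeration) and share no code with the package internals.

## Smith-Waterman local alignment with affine gaps (gap of length L costs
## open + L * ext), full dynamic programming over three states.
swOracle <- function(a, b, mat, gapOpen = 11, gapExt = 1) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A)
  m <- length(B)
  M <- matrix(0, n + 1L, m + 1L)
  X <- matrix(-Inf, n + 1L, m + 1L)   # gap in b (vertical)
  Y <- matrix(-Inf, n + 1L, m + 1L)   # gap in a (horizontal)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      X[i, j] <- max(M[i - 1L, j] - gapOpen - gapExt, X[i - 1L, j] - gapExt)
      Y[i, j] <- max(M[i, j - 1L] - gapOpen - gapExt, Y[i, j - 1L] - gapExt)
      sub <- mat[A[i - 1L], B[j - 1L]]
      M[i, j] <- max(0, max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                            Y[i - 1L, j - 1L]) + sub)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

## Leftmost-greedy non-overlapping starts of a literal pattern (while loop).
naiveGreedyStarts <- function(pattern, s) {
  starts <- integer(0)
  i <- 1L
  lp <- nchar(pattern)
  while (i + lp - 1L <= nchar(s)) {
    if (substr(s, i, i + lp - 1L) == pattern) {
      starts <- c(starts, i)
      i <- i + lp
    } else {
      i <- i + 1L
    }
  }
  starts
}

## As above but honoring 'x'/'z' wildcard positions by per-character compare.
naiveWildcardStarts <- function(pattern, s) {
  pc <- strsplit(pattern, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  lp <- length(pc)
  starts <- integer(0)
  i <- 1L
  while (i + lp - 1L <= length(sc)) {
    window <- sc[i:(i + lp - 1L)]
    if (all(pc %in% c("x", "z") | pc == window)) {
      starts <- c(starts, i)
      i <- i + lp
    } else {
      i <- i + 1L
    }
  }
  starts
}

## Brute-force repeated-substring discovery over small cores: enumerate every
## substring in the length bounds, count greedy non-overlapping occurrences,
## then apply the same right-maximality and subsumption pruning rules as the
## catalog definition, all with direct scans.
discoveryOracle <- function(cores, minLen = 4L, maxLen = 8L, minTotal = 3L) {
  subs <- unique(unlist(lapply(unname(cores), function(s) {
    n <- nchar(s)
    unlist(lapply(seq.int(minLen, maxLen), function(l) {
      if (n < l) character(0) else substring(s, 1:(n - l + 1L), l:n)
    }))
  })))
  if (length(subs) == 0) return(character(0))
  occOf <- function(p) {
    do.call(rbind, lapply(names(cores), function(g) {
      st <- naiveGreedyStarts(p, cores[[g]])
      if (length(st) == 0) NULL else data.frame(gene = g, start = st)
    }))
  }
  occs <- lapply(subs, occOf)
  names(occs) <- subs
  counts <- vapply(occs, function(o) if (is.null(o)) 0L else nrow(o), integer(1))
  keep <- subs[counts >= minTotal]
  if (length(keep) == 0) return(character(0))
  ## right-maximality
  rightMax <- vapply(keep, function(p) {
    if (nchar(p) >= maxLen) return(TRUE)
    o <- occs[[p]]
    follow <- vapply(seq_len(nrow(o)), function(k) {
      s <- cores[[o$gene[k]]]
      pos <- o$start[k] + nchar(p)
      if (pos > nchar(s)) "" else substr(s, pos, pos)
    }, character(1))
    if (any(follow == "") || length(unique(follow)) > 1L) return(TRUE)
    ext <- paste0(p, follow[1L])
    extCount <- sum(vapply(cores, function(s) length(naiveGreedyStarts(ext, s)),
                           integer(1)))
    extCount < minTotal
  }, logical(1))
  keep <- keep[rightMax]
  ## subsumption
  drop <- vapply(keep, function(p) {
    op <- occs[[p]]
    for (q in keep) {
      if (nchar(q) <= nchar(p) || nrow(occs[[q]]) != nrow(op)) next
      if (!grepl(p, q, fixed = TRUE)) next
      oq <- occs[[q]]
      inside <- all(vapply(seq_len(nrow(op)), function(k) {
        any(oq$gene == op$gene[k] & oq$start <= op$start[k] &
              oq$start + nchar(q) >= op$start[k] + nchar(p))
      }, logical(1)))
      if (inside) return(TRUE)
    }
    FALSE
  }, logical(1))
  sort(keep[!drop], method = "radix")
}

## Exhaustive cassette enumeration on one gene's occurrence list: walk the
## start-sorted, non-overlapping adjacency chains directly and emit windows.
chainOracle <- function(occ, maxGap = 20L, minComp = 2L, maxComp = 6L) {
  occ <- occ[order(occ$start, -(occ$end - occ$start), occ$feature_id), ,
             drop = FALSE]
  chains <- list()
  current <- NULL
  for (i in seq_len(nrow(occ))) {
    if (is.null(current)) {
      current <- occ[i, , drop = FALSE]
      next
    }
    lastEnd <- current$end[nrow(current)]
    if (occ$start[i] < lastEnd) next
    if (occ$start[i] - lastEnd <= maxGap) {
      current <- rbind(current, occ[i, , drop = FALSE])
    } else {
      chains[[length(chains) + 1L]] <- current
      current <- occ[i, , drop = FALSE]
    }
  }
  if (!is.null(current)) chains[[length(chains) + 1L]] <- current
  windows <- list()
  for (ch in chains) {
    while (nrow(ch) >= minComp) {
      k <- min(maxComp, nrow(ch))
      windows[[length(windows) + 1L]] <- ch[seq_len(k), , drop = FALSE]
      ch <- ch[-seq_len(k), , drop = FALSE]
    }
  }
  windows
}

## Random occurrence list on one synthetic gene for fuzzing cassette logic.
randomOccurrenceList <- function(n, seed, geneLen = 400L, species = "Cdar",
                                 gene = "g1", nVariants = 5L) {
  set.seed(seed)
  lens <- sample(4:9, nVariants, replace = TRUE)
  starts <- sort(sample.int(geneLen - 10L, n))
  v <- sample.int(nVariants, n, replace = TRUE)
  data.frame(species = species, gene_id = gene, feature_kind = "motif",
             feature_id = sprintf("M%04d", v), start = starts,
             end = starts + lens[v], stringsAsFactors = FALSE)
}

## Small literal SpidroinSet for IO / screening tests.
toySet <- function(seqs, species = "Cdar") {
  SpidroinSet(seqs, species = species)
}

## A compact screening library built from the default grammar's templates.
toyLibrary <- function(grammar = defaultGrammar()) {
  DomainLibrary(c(ntd_masp = grammar@ntd, ctd_masp = grammar@ctd),
                domainKind = c("NTD", "CTD"),
                classLabel = c("MaSp", "MaSp"))
}

## Random residue string over the canonical alphabet.
randomResidues <- function(n, seed) {
  set.seed(seed)
  paste0(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n, replace = TRUE),
         collapse = "")
}
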