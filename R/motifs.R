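## Repeat-motif discovery and painting on spidroin cores.
##
## Terminal domains are masked with a hard 100-residue cutoff; repeated
## substrings of 4-41 residues are enumerated deterministically from the
## masked cores, pruned for right-maximality and subsumption, painted back
## as leftmost-greedy non-overlapping occurrences, organized into residue
## composition groups / similarity sub-groups, and collapsed into wildcard
## descriptions.

#' Mask spidroin terminal domains
#'
#' The repetitive core of a spidroin is what remains after a hard cutoff of
#' \code{cutoff} residues at each terminus: span
#' \code{[min(cutoff, L), max(L - cutoff, min(cutoff, L)))} for a gene of
#' length L (0-based half-open; empty when the sequence is shorter than two
#' terminal windows).
#'
#' @param x a \link{SpidroinSet}.
#' @param cutoff terminal window size in residues.
#' @return data.frame: gene_id, start, end.
#' @examples
#' ss <- SpidroinSet(c(g = strrep("A", 300)), species = "Cdar")
#' maskTerminalDomains(ss)  # core [100, 200)
#' @export
maskTerminalDomains <- function(x, cutoff = 100L) {
  stopifnot(methods::is(x, "SpidroinSet"))
  L <- nchar(residues(x))
  start <- pmin.int(as.integer(cutoff), L)
  end <- pmax.int(L - as.integer(cutoff), start)
  data.frame(gene_id = geneIds(x), start = start, end = end,
             row.names = NULL, stringsAsFactors = FALSE)
}

## Extract the core residue strings named by gene; empty cores are dropped.
coreStrings <- function(x, coreSpans) {
  seqs <- residues(x)
  idx <- match(coreSpans$gene_id, names(seqs))
  cores <- substr(seqs[idx], coreSpans$start + 1L, coreSpans$end)
  names(cores) <- coreSpans$gene_id
  cores[nchar(cores) > 0L]
}

## Total leftmost-greedy non-overlapping occurrence count of a literal
## pattern across a set of core strings.
.totalGreedyCount <- function(pattern, cores) {
  sum(vapply(cores, function(s) length(nonOverlappingMatches(pattern, s)),
             integer(1)))
}

## Greedy occurrence list of a literal pattern: data.frame(gene, start) with
## starts 1-based within the core string.
.greedyOccurrences <- function(pattern, cores) {
  rows <- lapply(names(cores), function(g) {
    s <- nonOverlappingMatches(pattern, cores[[g]])
    if (length(s) == 0) NULL else data.frame(gene = g, start = s,
                                             stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(data.frame(gene = character(0), start = integer(0)))))
}

#' Discover repetitive motif variants in spidroin cores
#'
#' Enumerates repeated substrings of the masked cores within the length
#' bounds, keeps those whose leftmost-greedy non-overlapping occurrence total
#' across all cores reaches \code{minTotalOccurrences}, and prunes the result:
#' a pattern all of whose occurrences are followed by one identical residue is
#' dropped in favor of its one-residue extension when that extension still
#' meets the occurrence threshold (right-maximality), and a pattern contained
#' in a longer catalog pattern with the identical occurrence set (equal count,
#' every occurrence inside an occurrence of the longer pattern) is dropped
#' (subsumption). Variant ids are assigned deterministically by decreasing
#' length, then lexicographic pattern.
#'
#' @param x a \link{SpidroinSet}.
#' @param coreSpans core spans from \link{maskTerminalDomains}; computed with
#'   the default cutoff when omitted.
#' @param minLen,maxLen inclusive motif length bounds (residues).
#' @param minTotalOccurrences minimum non-overlapping occurrence total across
#'   all cores.
#' @param excludeGenes gene ids left out of the analysis entirely (for
#'   deliberate exclusions from a catalog run).
#' @return a \link{MotifCatalog}.
#' @export
discoverMotifs <- function(x, coreSpans = NULL, minLen = 4L, maxLen = 41L,
                           minTotalOccurrences = 3L,
                           excludeGenes = character(0)) {
  stopifnot(methods::is(x, "SpidroinSet"))
  if (minLen < 1L) stop("minLen must be at least 1")
  if (maxLen < minLen) stop("maxLen must be >= minLen")
  if (is.null(coreSpans)) coreSpans <- maskTerminalDomains(x)
  coreSpans <- coreSpans[!coreSpans$gene_id %in% excludeGenes, , drop = FALSE]
  cores <- coreStrings(x, coreSpans)
  empty <- MotifCatalog(data.frame(variant_id = character(0),
                                   pattern = character(0),
                                   stringsAsFactors = FALSE))
  if (length(cores) == 0) return(empty)

  ## Candidate repeated substrings: tally all windows per length; the
  ## overlapping window count bounds the greedy count from above, so it is a
  ## safe pre-filter before the exact greedy recount.
  candidates <- character(0)
  for (len in seq.int(minLen, min(maxLen, max(nchar(cores))))) {
    subs <- unlist(lapply(cores, function(s) {
      n <- nchar(s)
      if (n < len) return(character(0))
      substring(s, 1:(n - len + 1L), len:n)
    }), use.names = FALSE)
    tab <- table(subs)
    candidates <- c(candidates, names(tab)[tab >= minTotalOccurrences])
  }
  if (length(candidates) == 0) return(empty)

  occs <- lapply(candidates, .greedyOccurrences, cores = cores)
  names(occs) <- candidates
  counts <- vapply(occs, nrow, integer(1))
  keep <- counts >= minTotalOccurrences
  candidates <- candidates[keep]
  occs <- occs[keep]
  counts <- counts[keep]
  if (length(candidates) == 0) return(empty)

  ## Right-maximality pruning.
  rightMax <- vapply(candidates, function(p) {
    len <- nchar(p)
    if (len >= maxLen) return(TRUE)
    oc <- occs[[p]]
    follow <- substr(cores[oc$gene], oc$start + len, oc$start + len)
    if (any(follow == "")) return(TRUE)      # some occurrence ends its core
    if (length(unique(follow)) > 1L) return(TRUE)
    ext <- paste0(p, follow[1L])
    .totalGreedyCount(ext, cores) < minTotalOccurrences
  }, logical(1))
  candidates <- candidates[rightMax]
  occs <- occs[rightMax]
  counts <- counts[rightMax]
  if (length(candidates) == 0) return(empty)

  ## Subsumption pruning: identical occurrence set under containment.
  lens <- nchar(candidates)
  drop <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    p <- candidates[i]
    lp <- lens[i]
    js <- which(lens > lp & counts == counts[i])
    for (j in js) {
      if (!grepl(p, candidates[j], fixed = TRUE)) next
      q <- candidates[j]
      lq <- lens[j]
      oq <- occs[[q]]
      op <- occs[[p]]
      contained <- vapply(seq_len(nrow(op)), function(k) {
        sel <- oq$gene == op$gene[k] & oq$start <= op$start[k] &
          (oq$start + lq) >= (op$start[k] + lp)
        any(sel)
      }, logical(1))
      if (all(contained)) { drop[i] <- TRUE; break }
    }
  }
  candidates <- candidates[!drop]
  counts <- counts[!drop]
  if (length(candidates) == 0) return(empty)

  ord <- orderStrings(-nchar(candidates), candidates)
  candidates <- candidates[ord]
  counts <- counts[ord]
  MotifCatalog(data.frame(
    variant_id = sprintf("M%04d", seq_along(candidates)),
    pattern = candidates,
    length = nchar(candidates),
    n_occurrences = as.integer(counts),
    stringsAsFactors = FALSE))
}

#' Paint catalog motifs onto spidroin cores
#'
#' Locates, for every catalog variant, its leftmost-greedy non-overlapping
#' matches (exact or wildcard) within each gene's core span. Occurrences of
#' the same variant never overlap each other; occurrences of different
#' variants may. Output rows are ordered by species, gene, start, then longer
#' variant first.
#'
#' @param x a \link{SpidroinSet}.
#' @param catalog a \link{MotifCatalog}; an empty catalog yields no
#'   occurrences.
#' @param coreSpans core spans from \link{maskTerminalDomains}; computed with
#'   the default cutoff when omitted.
#' @param excludeGenes gene ids left out of painting entirely.
#' @return occurrence data.frame (see \link{occurrenceTable}), coordinates on
#'   the full-length gene.
#' @export
paintSequences <- function(x, catalog, coreSpans = NULL,
                           excludeGenes = character(0)) {
  stopifnot(methods::is(x, "SpidroinSet"), methods::is(catalog, "MotifCatalog"))
  if (is.null(coreSpans)) coreSpans <- maskTerminalDomains(x)
  coreSpans <- coreSpans[!coreSpans$gene_id %in% excludeGenes, , drop = FALSE]
  cores <- coreStrings(x, coreSpans)
  species <- speciesTags(x)
  offsets <- stats::setNames(coreSpans$start, coreSpans$gene_id)
  pats <- motifPatterns(catalog)
  rows <- list()
  for (v in names(pats)) {
    len <- nchar(pats[[v]])
    for (g in names(cores)) {
      starts <- nonOverlappingMatches(pats[[v]], cores[[g]])
      if (length(starts) == 0) next
      s0 <- offsets[[g]] + starts - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        species = species[[g]], gene_id = g, feature_kind = "motif",
        feature_id = v, start = s0, end = s0 + len,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(occurrenceTable())
  }
  out <- do.call(rbind, rows)
  len <- out$end - out$start
  out <- out[orderStrings(out$species, out$gene_id, out$start, -len,
                          out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  validateOccurrences(out, genes = x)
}

#' Per-gene fraction of residues covered by motif occurrences
#'
#' @param x a \link{SpidroinSet}.
#' @param occurrences motif occurrence table (see \link{paintSequences}).
#' @return named numeric vector in [0, 1] per gene.
#' @export
motifCoverage <- function(x, occurrences) {
  stopifnot(methods::is(x, "SpidroinSet"))
  lens <- nchar(residues(x))
  vapply(geneIds(x), function(g) {
    o <- occurrences[occurrences$gene_id == g, , drop = FALSE]
    if (nrow(o) == 0) return(0)
    covered <- logical(lens[[g]])
    for (k in seq_len(nrow(o))) {
      covered[(o$start[k] + 1L):o$end[k]] <- TRUE
    }
    sum(covered) / lens[[g]]
  }, numeric(1))
}

## Fixed, documented residue-composition classes used for motif grouping
## (checked in order; wildcard positions are excluded from the denominator).
.compositionClass <- function(pattern) {
  chars <- strsplit(gsub("[xz]", "", pattern), "")[[1L]]
  if (length(chars) == 0) return("other")
  f <- table(factor(chars, levels = setdiff(.AA_LETTERS, "X"))) / length(chars)
  if (f[["A"]] >= 0.75) return("poly_A")
  if (f[["G"]] + f[["A"]] >= 0.80 && f[["G"]] > 0 && f[["A"]] > 0) return("GA_like")
  if (f[["G"]] >= 0.35) return("gly_rich")
  if (f[["S"]] + f[["T"]] + f[["V"]] >= 0.50) return("ser_thr_val_rich")
  if (f[["Q"]] + f[["P"]] >= 0.50) return("gln_pro_rich")
  "other"
}

## Single-linkage clusters under normalized edit distance <= threshold.
## Returns an integer cluster id per pattern, numbered deterministically by
## each cluster's lexicographically smallest member.
.editClusters <- function(patterns, threshold) {
  n <- length(patterns)
  if (n == 1L) return(1L)
  d <- utils::adist(patterns) / outer(nchar(patterns), nchar(patterns), pmax)
  h <- stats::hclust(stats::as.dist(d), method = "single")
  cl <- stats::cutree(h, h = threshold + 1e-9)
  reps <- vapply(split(patterns, cl), function(p) sort(p, method = "radix")[1L],
                 character(1))
  newId <- stats::setNames(seq_along(reps), names(reps)[orderStrings(reps)])
  unname(newId[as.character(cl)])
}

#' Organize motif variants into groups and sub-groups
#'
#' Variants are grouped by a fixed list of residue-composition classes
#' (poly-A, GA-dinucleotide-like, glycine-rich, Ser/Thr/Val-rich,
#' Gln/Pro-rich, checked in that order); variants matching none of the named
#' classes are clustered by single-linkage on normalized edit distance (at
#' most \code{editThreshold}), clusters of two or more forming sequence
#' groups and remaining singletons staying \code{"unassigned"}. Within each
#' group, sub-groups are the single-linkage edit-distance clusters at the
#' same threshold. The result is a partition: every variant belongs to
#' exactly one group or is unassigned.
#'
#' @param catalog a \link{MotifCatalog}.
#' @param editThreshold normalized edit-distance threshold (edits per residue
#'   of the longer pattern).
#' @return list with \code{catalog} (variants annotated with group_id and
#'   subgroup_id) and \code{groups} (data.frame: group_id, composition_class,
#'   n_variants, description).
#' @export
groupMotifs <- function(catalog, editThreshold = 0.25) {
  stopifnot(methods::is(catalog, "MotifCatalog"))
  v <- variantTable(catalog)
  if (nrow(v) == 0) stop("catalog must not be empty")
  comp <- vapply(v$pattern, .compositionClass, character(1), USE.NAMES = FALSE)
  v$group_id <- comp
  ## sequence-similarity groups among composition-class "other" members
  others <- which(comp == "other")
  if (length(others) > 0) {
    cl <- .editClusters(v$pattern[others], editThreshold)
    sizes <- table(cl)
    seqIds <- sprintf("seq_%02d", cl)
    v$group_id[others] <- ifelse(sizes[as.character(cl)] >= 2L, seqIds,
                                 "unassigned")
  }
  ## sub-groups within each group
  v$subgroup_id <- NA_character_
  for (g in unique(v$group_id)) {
    if (g == "unassigned") next
    idx <- which(v$group_id == g)
    cl <- .editClusters(v$pattern[idx], editThreshold)
    v$subgroup_id[idx] <- sprintf("%s.%d", g, cl)
  }
  grouped <- v[v$group_id != "unassigned", , drop = FALSE]
  groups <- do.call(rbind, lapply(
    sort(unique(grouped$group_id), method = "radix"), function(g) {
      m <- grouped[grouped$group_id == g, , drop = FALSE]
      occ <- m$n_occurrences
      occ[is.na(occ)] <- 0L
      rep_pat <- m$pattern[orderStrings(-occ, m$pattern)][1L]
      data.frame(group_id = g,
                 composition_class = if (startsWith(g, "seq_")) "other" else g,
                 n_variants = nrow(m), description = rep_pat,
                 stringsAsFactors = FALSE)
    }))
  if (is.null(groups)) {
    groups <- data.frame(group_id = character(0), composition_class = character(0),
                         n_variants = integer(0), description = character(0),
                         stringsAsFactors = FALSE)
  }
  list(catalog = MotifCatalog(v), groups = groups)
}

## Merge two equal-length descriptions differing at <= 1 position; returns
## the merged description or NULL. A new wildcard position is written 'x',
## or 'z' when 'x' is already in use elsewhere in the description (at most
## two independent wildcard positions per description).
.mergePair <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NULL)
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  diff <- which(ca != cb)
  if (length(diff) == 0L) return(a)
  if (length(diff) > 1L) return(NULL)
  pos <- diff
  merged <- ca
  if (ca[pos] %in% .WILDCARDS) {
    merged[pos] <- ca[pos]
  } else if (cb[pos] %in% .WILDCARDS) {
    merged[pos] <- cb[pos]
  } else {
    free <- setdiff(.WILDCARDS, ca[-pos])
    if (length(free) == 0L) return(NULL)
    merged[pos] <- free[1L]
  }
  paste0(merged, collapse = "")
}

## Relabel wildcards so 'x' is always the left-most wildcard position and
## 'z' the second (the conventional printed order).
.normalizeWildcards <- function(desc) {
  chars <- strsplit(desc, "")[[1L]]
  w <- which(chars %in% .WILDCARDS)
  if (length(w) > 0L) chars[w] <- .WILDCARDS[seq_along(w)]
  paste0(chars, collapse = "")
}

#' Collapse motif descriptions into wildcard forms
#'
#' Equal-length descriptions differing at a single position merge into one
#' description with a wildcard at the differing position ('x', or 'z' for a
#' second independent wildcard; 'x' always names the left-most wildcard),
#' repeated to a fixpoint; collapsing is idempotent and never increases the
#' description count.
#'
#' @param patterns character vector of motif patterns/descriptions.
#' @return sorted character vector of collapsed descriptions.
#' @examples
#' collapsePatterns(c("APGPQ", "GPGPQ", "SPGPQ"))  # "xPGPQ"
#' @export
collapsePatterns <- function(patterns) {
  descs <- sort(unique(patterns), method = "radix")
  repeat {
    mergedAny <- FALSE
    n <- length(descs)
    if (n < 2L) break
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        m <- .mergePair(descs[i], descs[j])
        if (!is.null(m)) {
          m <- .normalizeWildcards(m)
          descs <- sort(unique(c(descs[-c(i, j)], m)), method = "radix")
          mergedAny <- TRUE
          break
        }
      }
      if (mergedAny) break
    }
    if (!mergedAny) break
  }
  descs
}

#' Collapse variant descriptions within sub-groups
#'
#' Applies \link{collapsePatterns} within every motif sub-group of a grouped
#' catalog; unassigned variants keep their own description. The number of
#' rows returned is the "descriptions after collapse" tally.
#'
#' @param grouped result of \link{groupMotifs} (or a grouped
#'   \link{MotifCatalog}).
#' @return data.frame: group_id, subgroup_id, description.
#' @export
collapseVariantDescriptions <- function(grouped) {
  catalog <- if (methods::is(grouped, "MotifCatalog")) grouped else grouped$catalog
  v <- variantTable(catalog)
  rows <- list()
  assigned <- v[v$group_id != "unassigned", , drop = FALSE]
  for (sg in sort(unique(assigned$subgroup_id), method = "radix")) {
    m <- assigned[assigned$subgroup_id == sg, , drop = FALSE]
    for (d in collapsePatterns(m$pattern)) {
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = m$group_id[1L], subgroup_id = sg, description = d,
        stringsAsFactors = FALSE)
    }
  }
  un <- v[v$group_id == "unassigned", , drop = FALSE]
  for (k in seq_len(nrow(un))) {
    rows[[length(rows) + 1L]] <- data.frame(
      group_id = "unassigned", subgroup_id = NA_character_,
      description = un$pattern[k], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(data.frame(group_id = character(0),
                                                subgroup_id = character(0),
                                                description = character(0),
                                                stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}
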