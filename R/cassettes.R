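## Higher-order repeat (cassette) detection: ordered runs of 2-6 adjacent
## motif occurrences with inter-motif gaps of at most 20 residues, tallied
## into cassette types, grouped via their component motif groups, and curated
## against gap/terminal-domain constraints.

## Build per-gene adjacency chains of non-overlapping motif occurrences with
## successive gaps <= maxGap, then segment each chain into non-overlapping
## windows, longest-first leftmost-first, of at most maxComponents members.
.chainWindows <- function(occ, maxGap, minComponents, maxComponents) {
  ord <- orderStrings(occ$start, -(occ$end - occ$start), occ$feature_id)
  occ <- occ[ord, , drop = FALSE]
  chains <- list()
  cur <- integer(0)
  lastEnd <- -1L
  for (i in seq_len(nrow(occ))) {
    if (length(cur) == 0L) {
      cur <- i; lastEnd <- occ$end[i]; next
    }
    if (occ$start[i] < lastEnd) next          # overlapping occurrence: chains never share residues
    gap <- occ$start[i] - lastEnd
    if (gap <= maxGap) {
      cur <- c(cur, i); lastEnd <- occ$end[i]
    } else {
      chains[[length(chains) + 1L]] <- cur
      cur <- i; lastEnd <- occ$end[i]
    }
  }
  if (length(cur) > 0L) chains[[length(chains) + 1L]] <- cur
  windows <- list()
  for (chain in chains) {
    while (length(chain) >= minComponents) {
      k <- min(maxComponents, length(chain))
      windows[[length(windows) + 1L]] <- occ[chain[seq_len(k)], , drop = FALSE]
      chain <- chain[-seq_len(k)]
    }
  }
  windows
}

#' Detect cassettes from motif occurrences
#'
#' Per gene, motif occurrences are chained whenever successive (non-
#' overlapping) occurrences are separated by at most \code{maxGap} residues;
#' each maximal chain is segmented, longest-window-first and leftmost-first,
#' into candidate cassettes of \code{minComponents} to \code{maxComponents}
#' ordered motif components (a trailing window shorter than
#' \code{minComponents} is discarded). A component tuple becomes a cassette
#' type only when its occurrence total across the whole dataset reaches
#' \code{minTypeSupport} -- the operational reading of "enriched across
#' spidroins". Detection is deterministic given its inputs, and cassette
#' occurrences never share a motif occurrence.
#'
#' @param occurrences motif occurrence table (see \link{paintSequences}).
#' @param maxGap maximum inter-component gap (residues).
#' @param minComponents,maxComponents component count bounds (2-6 by default);
#'   \code{minComponents} below 2 is an error.
#' @param minTypeSupport minimum dataset-wide occurrence count per type.
#' @param catalog optional \link{MotifCatalog} used to render type
#'   descriptions (component patterns joined with "_" at junctions where any
#'   observed gap is positive).
#' @return list with \code{types} (cassette_id, components, n_components,
#'   support, description) and \code{occurrences} (occurrence rows plus
#'   component ids/starts and inter-component gaps).
#' @export
detectCassettes <- function(occurrences, maxGap = 20L, minComponents = 2L,
                            maxComponents = 6L, minTypeSupport = 2L,
                            catalog = NULL) {
  if (minComponents < 2L) stop("minComponents must be at least 2")
  if (maxComponents < minComponents) stop("maxComponents must be >= minComponents")
  occurrences <- validateOccurrences(occurrences)
  emptyTypes <- data.frame(cassette_id = character(0), components = character(0),
                           n_components = integer(0), support = integer(0),
                           description = character(0), stringsAsFactors = FALSE)
  emptyOcc <- data.frame(species = character(0), gene_id = character(0),
                         feature_kind = character(0), feature_id = character(0),
                         start = integer(0), end = integer(0),
                         components = character(0), component_starts = character(0),
                         gaps = character(0), stringsAsFactors = FALSE)
  if (nrow(occurrences) == 0) return(list(types = emptyTypes, occurrences = emptyOcc))

  keys <- unique(occurrences[, c("species", "gene_id")])
  cand <- list()
  for (r in seq_len(nrow(keys))) {
    occ <- occurrences[occurrences$species == keys$species[r] &
                       occurrences$gene_id == keys$gene_id[r], , drop = FALSE]
    for (w in .chainWindows(occ, maxGap, minComponents, maxComponents)) {
      gaps <- if (nrow(w) > 1L) w$start[-1L] - w$end[-nrow(w)] else integer(0)
      cand[[length(cand) + 1L]] <- data.frame(
        species = keys$species[r], gene_id = keys$gene_id[r],
        tuple = paste(w$feature_id, collapse = "+"),
        start = w$start[1L], end = w$end[nrow(w)],
        n_components = nrow(w),
        component_starts = paste(w$start, collapse = ","),
        gaps = paste(gaps, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0) return(list(types = emptyTypes, occurrences = emptyOcc))
  cand <- do.call(rbind, cand)
  support <- table(cand$tuple)
  keepTuples <- names(support)[support >= minTypeSupport]
  cand <- cand[cand$tuple %in% keepTuples, , drop = FALSE]
  if (nrow(cand) == 0) return(list(types = emptyTypes, occurrences = emptyOcc))

  tup <- unique(cand$tuple)
  ncomp <- lengths(strsplit(tup, "+", fixed = TRUE))
  ord <- orderStrings(-ncomp, tup)
  tup <- tup[ord]
  ncomp <- ncomp[ord]
  ids <- stats::setNames(sprintf("C%04d", seq_along(tup)), tup)
  types <- data.frame(
    cassette_id = unname(ids), components = tup, n_components = as.integer(ncomp),
    support = as.integer(support[tup]),
    description = vapply(tup, function(tt) {
      .cassetteDescription(tt, cand, catalog)
    }, character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)

  occOut <- data.frame(
    species = cand$species, gene_id = cand$gene_id,
    feature_kind = "cassette", feature_id = unname(ids[cand$tuple]),
    start = cand$start, end = cand$end,
    components = cand$tuple, component_starts = cand$component_starts,
    gaps = cand$gaps, stringsAsFactors = FALSE)
  occOut <- occOut[orderStrings(occOut$species, occOut$gene_id, occOut$start,
                                occOut$feature_id), , drop = FALSE]
  rownames(occOut) <- NULL
  list(types = types, occurrences = occOut)
}

## Render a cassette type description: component patterns (or variant ids
## when no catalog is given) joined with '_' at junctions where any observed
## occurrence has a positive gap.
.cassetteDescription <- function(tuple, cand, catalog) {
  comps <- strsplit(tuple, "+", fixed = TRUE)[[1L]]
  labels <- if (!is.null(catalog)) {
    pats <- motifPatterns(catalog)
    ifelse(comps %in% names(pats), unname(pats[comps]), comps)
  } else {
    comps
  }
  if (length(comps) == 1L) return(labels)
  gapRows <- strsplit(cand$gaps[cand$tuple == tuple], ",", fixed = TRUE)
  gapMat <- do.call(rbind, lapply(gapRows, as.integer))
  joiners <- ifelse(apply(gapMat > 0L, 2L, any), "_", "")
  out <- labels[1L]
  for (k in seq_len(length(labels) - 1L)) {
    out <- paste0(out, joiners[k], labels[k + 1L])
  }
  out
}

#' Group cassette types by their component motif groups
#'
#' Cassette types whose ordered component tuples map to the same ordered
#' tuple of motif groups share a cassette group. Group descriptions join the
#' components' collapsed motif descriptions with "_" at junctions where any
#' observed inter-component gap is positive. Component tuples of different
#' lengths never share a group, and the grouping partitions the types.
#'
#' @param types cassette types from \link{detectCassettes}.
#' @param occurrences cassette occurrences from \link{detectCassettes}.
#' @param groupedMotifs result of \link{groupMotifs}.
#' @return list with \code{types} (annotated with group_id) and
#'   \code{groups} (group_id, component_groups, description, n_types).
#' @export
groupCassettes <- function(types, occurrences, groupedMotifs) {
  if (nrow(types) == 0) stop("types must not be empty")
  v <- variantTable(groupedMotifs$catalog)
  vGroup <- stats::setNames(v$group_id, v$variant_id)
  vDesc <- .variantCollapsedDescriptions(groupedMotifs$catalog)
  compList <- strsplit(types$components, "+", fixed = TRUE)
  groupTuple <- vapply(compList, function(comps) {
    paste(ifelse(comps %in% names(vGroup), unname(vGroup[comps]), "unassigned"),
          collapse = "+")
  }, character(1))
  tuples <- sort(unique(groupTuple), method = "radix")
  gids <- stats::setNames(sprintf("CG%03d", seq_along(tuples)), tuples)
  types$group_id <- unname(gids[groupTuple])

  groups <- do.call(rbind, lapply(tuples, function(tt) {
    members <- which(groupTuple == tt)
    ## description from the first (deterministically ordered) member type,
    ## with components rendered as collapsed motif descriptions
    m <- members[orderStrings(types$components[members])][1L]
    comps <- compList[[m]]
    labels <- ifelse(comps %in% names(vDesc), unname(vDesc[comps]), comps)
    gapRows <- strsplit(occurrences$gaps[occurrences$feature_id ==
                                           types$cassette_id[m]], ",",
                        fixed = TRUE)
    gapMat <- do.call(rbind, lapply(gapRows, as.integer))
    joiners <- if (is.null(gapMat)) {
      rep("", length(labels) - 1L)
    } else {
      ifelse(apply(gapMat > 0L, 2L, any), "_", "")
    }
    desc <- labels[1L]
    for (k in seq_len(length(labels) - 1L)) desc <- paste0(desc, joiners[k], labels[k + 1L])
    data.frame(group_id = unname(gids[tt]), component_groups = tt,
               description = desc, n_types = length(members),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  list(types = types, groups = groups)
}

## Map each variant to the collapsed description of its sub-group that it
## matches (its own pattern when unassigned or unmatched).
.variantCollapsedDescriptions <- function(catalog) {
  v <- variantTable(catalog)
  out <- stats::setNames(v$pattern, v$variant_id)
  assigned <- v[!is.na(v$subgroup_id), , drop = FALSE]
  for (sg in unique(assigned$subgroup_id)) {
    m <- assigned[assigned$subgroup_id == sg, , drop = FALSE]
    descs <- collapsePatterns(m$pattern)
    for (k in seq_len(nrow(m))) {
      hit <- descs[nchar(descs) == nchar(m$pattern[k]) &
                     vapply(descs, function(d) {
                       grepl(sprintf("^%s$", wildcardToRegex(d)), m$pattern[k],
                             perl = TRUE)
                     }, logical(1))]
      if (length(hit) > 0) out[[m$variant_id[k]]] <- hit[1L]
    }
  }
  out
}

#' Curate cassettes against gap and terminal-domain constraints
#'
#' Removes cassette occurrences that exhibit an inter-component gap above
#' \code{maxGap} or that extend outside their gene's repetitive core span,
#' then removes cassette types whose remaining support falls below
#' \code{minTypeSupport} (together with their surviving occurrences).
#' Retained plus removed occurrences always account for every input
#' occurrence.
#'
#' @param types,occurrences output of \link{detectCassettes}.
#' @param coreSpans core spans from \link{maskTerminalDomains}.
#' @param maxGap maximum tolerated inter-component gap (residues).
#' @param minTypeSupport minimum post-curation support per type.
#' @return list with \code{types}, \code{occurrences}, and
#'   \code{removedOccurrences}.
#' @export
curateCassettes <- function(types, occurrences, coreSpans, maxGap = 20L,
                            minTypeSupport = 2L) {
  if (nrow(occurrences) == 0) {
    return(list(types = types[0, , drop = FALSE], occurrences = occurrences,
                removedOccurrences = occurrences))
  }
  coreStart <- stats::setNames(coreSpans$start, coreSpans$gene_id)
  coreEnd <- stats::setNames(coreSpans$end, coreSpans$gene_id)
  badGap <- vapply(strsplit(occurrences$gaps, ",", fixed = TRUE), function(g) {
    g <- suppressWarnings(as.integer(g))
    any(!is.na(g) & g > maxGap)
  }, logical(1))
  cs <- coreStart[occurrences$gene_id]
  ce <- coreEnd[occurrences$gene_id]
  outsideCore <- is.na(cs) | occurrences$start < cs | occurrences$end > ce
  removed <- badGap | outsideCore
  kept <- occurrences[!removed, , drop = FALSE]
  support <- table(kept$feature_id)
  keepTypes <- types$cassette_id %in% names(support)[support >= minTypeSupport]
  dropIds <- types$cassette_id[!keepTypes]
  removed <- removed | occurrences$feature_id %in% dropIds
  kept <- occurrences[!removed, , drop = FALSE]
  rownames(kept) <- NULL
  out <- occurrences[removed, , drop = FALSE]
  rownames(out) <- NULL
  keptTypes <- types[keepTypes, , drop = FALSE]
  keptTypes$support <- as.integer(table(kept$feature_id)[keptTypes$cassette_id])
  rownames(keptTypes) <- NULL
  list(types = keptTypes, occurrences = kept, removedOccurrences = out)
}
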