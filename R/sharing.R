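## Cross-species sharing tallies for motif and cassette catalogs: the machine
## twin of a two-species repeat-sharing summary table, per-species origin
## breakdowns, and top-k frequency rankings. Type identity across species is
## feature-id (pattern) equality after wildcard collapse -- collapse first,
## then compare -- so both species must be painted with a shared catalog.

## Build a SharingSummary from raw counts; percentages are always recomputed
## here (rounded half-up to one decimal), never stored free-floating.
.makeSharingSummary <- function(featureKind, speciesA, speciesB,
                                privateA, privateB, shared,
                                occurrencesA, occurrencesB,
                                nGenesA, nGenesB) {
  total <- privateA + privateB + shared
  pct <- function(n, d) if (d == 0) 0 else roundHalfUp(100 * n / d, 1L)
  new("SharingSummary",
      featureKind = featureKind, speciesA = speciesA, speciesB = speciesB,
      totalTypes = as.integer(total),
      privateA = as.integer(privateA), privateB = as.integer(privateB),
      shared = as.integer(shared),
      occurrencesA = as.integer(occurrencesA),
      occurrencesB = as.integer(occurrencesB),
      nGenesA = as.integer(nGenesA), nGenesB = as.integer(nGenesB),
      pctPrivateA = pct(privateA, total), pctPrivateB = pct(privateB, total),
      pctShared = pct(shared, total),
      pctOccurrencesA = pct(occurrencesA, occurrencesA + occurrencesB))
}

#' Summarize cross-species feature sharing
#'
#' A feature type is shared when it has at least one occurrence in each
#' species, otherwise private to the species carrying it. Percentages of
#' types are taken over the total type count and the occurrence percentage
#' over total occurrences, each rounded half-up to one decimal. Swapping the
#' two input tables swaps the A/B fields exactly.
#'
#' @param occurrencesA,occurrencesB occurrence tables for the two species
#'   (each carrying a single species tag; the two tags must differ).
#' @param featureKind "motif" or "cassette".
#' @return a \link[=SharingSummary-class]{SharingSummary}.
#' @export
summarizeSharing <- function(occurrencesA, occurrencesB,
                             featureKind = c("motif", "cassette")) {
  featureKind <- match.arg(featureKind)
  spA <- unique(occurrencesA$species)
  spB <- unique(occurrencesB$species)
  if (length(spA) > 1 || length(spB) > 1)
    stop("each occurrence table must carry a single species tag")
  if (length(spA) == 0) spA <- "A"
  if (length(spB) == 0) spB <- "B"
  if (any(spA %in% spB))
    stop("the two occurrence tables must carry distinct species tags")
  typesA <- unique(occurrencesA$feature_id)
  typesB <- unique(occurrencesB$feature_id)
  shared <- length(intersect(typesA, typesB))
  .makeSharingSummary(featureKind, spA, spB,
                      privateA = length(typesA) - shared,
                      privateB = length(typesB) - shared,
                      shared = shared,
                      occurrencesA = nrow(occurrencesA),
                      occurrencesB = nrow(occurrencesB),
                      nGenesA = length(unique(occurrencesA$gene_id)),
                      nGenesB = length(unique(occurrencesB$gene_id)))
}

#' Sharing summary arithmetic from tallied counts
#'
#' Recomputes the derived percentages of a sharing summary from its raw
#' counts (for instance counts tallied from a published summary table),
#' using the same rounding convention as \link{summarizeSharing}.
#'
#' @param privateA,privateB,shared type counts.
#' @param occurrencesA,occurrencesB occurrence totals.
#' @param nGenesA,nGenesB genes per species.
#' @param speciesA,speciesB species tags.
#' @param featureKind "motif" or "cassette".
#' @return a \link[=SharingSummary-class]{SharingSummary}.
#' @export
sharingFromCounts <- function(privateA, privateB, shared,
                              occurrencesA, occurrencesB,
                              nGenesA = NA_integer_, nGenesB = NA_integer_,
                              speciesA = "A", speciesB = "B",
                              featureKind = c("motif", "cassette")) {
  featureKind <- match.arg(featureKind)
  .makeSharingSummary(featureKind, speciesA, speciesB, privateA, privateB,
                      shared, occurrencesA, occurrencesB, nGenesA, nGenesB)
}

#' Percentages of a SharingSummary as a numeric vector
#'
#' @param x a \link[=SharingSummary-class]{SharingSummary}.
#' @return named numeric vector: pct_private_a, pct_private_b, pct_shared,
#'   pct_occurrences_a.
#' @export
sharingPercentages <- function(x) {
  stopifnot(methods::is(x, "SharingSummary"))
  c(pct_private_a = x@pctPrivateA, pct_private_b = x@pctPrivateB,
    pct_shared = x@pctShared, pct_occurrences_a = x@pctOccurrencesA)
}

#' Origin breakdown of private feature types
#'
#' For each species, splits its private types into those originating from a
#' single gene, those shared across genes all of one silk class, and those
#' shared across classes; the three counts always account for every private
#' type. The single-gene percentage is reported over the species' private
#' types, rounded half-up to one decimal.
#'
#' @param occurrencesA,occurrencesB occurrence tables for the two species.
#' @param classLabels named character vector: silk class (or "unclassified")
#'   per gene id appearing in the tables.
#' @return data.frame with one row per species: species, private_types,
#'   single_gene_private_types, pct_single_gene, within_class_shared,
#'   across_class_shared.
#' @export
originBreakdown <- function(occurrencesA, occurrencesB, classLabels) {
  typesA <- unique(occurrencesA$feature_id)
  typesB <- unique(occurrencesB$feature_id)
  sharedTypes <- intersect(typesA, typesB)
  oneSpecies <- function(occ, own, speciesTag) {
    priv <- setdiff(own, sharedTypes)
    single <- 0L; within <- 0L; across <- 0L
    for (ft in priv) {
      genes <- unique(occ$gene_id[occ$feature_id == ft])
      if (length(genes) == 1L) {
        single <- single + 1L
      } else {
        cls <- unique(classLabels[genes])
        if (length(cls) == 1L && !anyNA(cls)) within <- within + 1L
        else across <- across + 1L
      }
    }
    data.frame(species = speciesTag, private_types = length(priv),
               single_gene_private_types = single,
               pct_single_gene = if (length(priv) == 0) 0 else
                 roundHalfUp(100 * single / length(priv), 1L),
               within_class_shared = within, across_class_shared = across,
               stringsAsFactors = FALSE)
  }
  spA <- if (nrow(occurrencesA) > 0) occurrencesA$species[1L] else "A"
  spB <- if (nrow(occurrencesB) > 0) occurrencesB$species[1L] else "B"
  out <- rbind(oneSpecies(occurrencesA, typesA, spA),
               oneSpecies(occurrencesB, typesB, spB))
  rownames(out) <- NULL
  out
}

#' @rdname originBreakdown
#' @param private_types,single_gene_private_types,within_class_shared,across_class_shared
#'   tallied counts for one species (must satisfy single + within + across =
#'   private).
#' @param species species tag.
#' @return \code{originFromCounts}: a one-row data.frame in the same shape.
#' @export
originFromCounts <- function(private_types, single_gene_private_types,
                             within_class_shared = NA_integer_,
                             across_class_shared = NA_integer_,
                             species = "A") {
  if (!is.na(within_class_shared) && !is.na(across_class_shared) &&
      single_gene_private_types + within_class_shared + across_class_shared !=
        private_types) {
    stop("single-gene + within-class + across-class must equal private types")
  }
  data.frame(species = species, private_types = as.integer(private_types),
             single_gene_private_types = as.integer(single_gene_private_types),
             pct_single_gene = if (private_types == 0) 0 else
               roundHalfUp(100 * single_gene_private_types / private_types, 1L),
             within_class_shared = as.integer(within_class_shared),
             across_class_shared = as.integer(across_class_shared),
             stringsAsFactors = FALSE)
}

#' Rank the most frequently observed motifs
#'
#' Ranks feature types by total occurrence count (ties broken by
#' lexicographic feature id) within three panels: private to species A,
#' private to species B, and shared. Shared types are annotated with the
#' dominant silk class of the genes using them in each species and flagged
#' when those dominant classes differ (cross-class usage).
#'
#' @param occurrencesA,occurrencesB occurrence tables for the two species.
#' @param k panel size (top-k); must be positive.
#' @param classLabels optional named class vector per gene id, enabling the
#'   class annotation of the shared panel.
#' @return list with data.frames \code{privateA}, \code{privateB},
#'   \code{shared} (feature_id, n_occurrences, and for shared: class_a,
#'   class_b, cross_class).
#' @export
rankTopMotifs <- function(occurrencesA, occurrencesB, k = 15L,
                          classLabels = NULL) {
  if (k <= 0) stop("k must be positive")
  typesA <- unique(occurrencesA$feature_id)
  typesB <- unique(occurrencesB$feature_id)
  sharedTypes <- intersect(typesA, typesB)
  countIn <- function(occ, types) {
    vapply(types, function(ft) sum(occ$feature_id == ft), integer(1))
  }
  rank <- function(types, n) {
    ord <- orderStrings(-n, types)
    take <- utils::head(ord, k)
    data.frame(feature_id = types[take], n_occurrences = n[take],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  privA <- setdiff(typesA, sharedTypes)
  privB <- setdiff(typesB, sharedTypes)
  out <- list(
    privateA = rank(privA, countIn(occurrencesA, privA)),
    privateB = rank(privB, countIn(occurrencesB, privB)),
    shared = rank(sharedTypes,
                  countIn(occurrencesA, sharedTypes) +
                    countIn(occurrencesB, sharedTypes)))
  if (!is.null(classLabels) && nrow(out$shared) > 0) {
    dominantClass <- function(ft, occ) {
      genes <- occ$gene_id[occ$feature_id == ft]
      cls <- classLabels[genes]
      cls <- cls[!is.na(cls)]
      if (length(cls) == 0) return(NA_character_)
      tab <- table(cls)
      sort(names(tab)[tab == max(tab)], method = "radix")[1L]
    }
    out$shared$class_a <- vapply(out$shared$feature_id, dominantClass,
                                 character(1), occ = occurrencesA,
                                 USE.NAMES = FALSE)
    out$shared$class_b <- vapply(out$shared$feature_id, dominantClass,
                                 character(1), occ = occurrencesB,
                                 USE.NAMES = FALSE)
    out$shared$cross_class <- !is.na(out$shared$class_a) &
      !is.na(out$shared$class_b) & out$shared$class_a != out$shared$class_b
  }
  out
}
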