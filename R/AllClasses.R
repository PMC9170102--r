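#' SpidroinSet: translated spidroin / spidroin-like proteins
#'
#' Container for a set of translated spidroin or spidroin-like gene products.
#' Sequences are held as a \link[Biostrings]{AAStringSet} named by gene id,
#' with a species tag and an optional silk-class label per gene. Residues are
#' restricted to the 20 canonical amino acids plus \code{X}; \code{X} runs
#' double as assembly-gap placeholders. The pair (species, gene id) must be
#' unique so that two-species joint analyses keep provenance unambiguous.
#'
#' @slot sequences \link[Biostrings]{AAStringSet}, names are gene ids.
#' @slot speciesTag character vector, one species tag per gene (e.g. "Cdar").
#' @slot classLabel character vector, one silk-class label per gene; one of
#'   AcSp, AgSp, FLAG, MaSp, MiSp, PySp, TuSp, "SpL", or "unclassified".
#'
#' @param sequences named character vector or \code{AAStringSet} of residues.
#' @param species species tag(s), recycled to the number of genes.
#' @param classLabel optional class label(s), recycled; default "unclassified".
#' @param x a \code{SpidroinSet}.
#' @return \code{SpidroinSet()} returns a validated \code{SpidroinSet}.
#'
#' @examples
#' ss <- SpidroinSet(c(gA = "MAFASAAAA", gB = "GPGPQGPS"), species = "Cdar")
#' geneIds(ss)
#' residues(ss)
#' @aliases geneIds speciesTags classLabels residues nGenes
#' @export SpidroinSet
#' @exportClass SpidroinSet
setClass("SpidroinSet",
  representation(
    sequences = "AAStringSet",
    speciesTag = "character",
    classLabel = "character"
  )
)

setValidity("SpidroinSet", function(object) {
  n <- length(object@sequences)
  ids <- names(object@sequences)
  if (n > 0 && (is.null(ids) || any(ids == "")))
    return("all sequences must be named by gene id")
  if (length(object@speciesTag) != n) return("speciesTag must have one entry per gene")
  if (length(object@classLabel) != n) return("classLabel must have one entry per gene")
  if (n == 0) return(TRUE)
  if (any(BiocGenerics::width(object@sequences) == 0L))
    return("residue strings must be non-empty")
  af <- Biostrings::alphabetFrequency(object@sequences)
  disallowed <- setdiff(colnames(af), .AA_LETTERS)
  bad <- rowSums(af[, disallowed, drop = FALSE]) > 0
  if (any(bad))
    return(sprintf("gene '%s' contains residues outside the allowed alphabet",
                   ids[which(bad)[1L]]))
  key <- paste(object@speciesTag, ids, sep = "\r")
  if (anyDuplicated(key))
    return(sprintf("duplicated (species, gene_id): '%s'",
                   ids[which(duplicated(key))[1L]]))
  TRUE
})

SpidroinSet <- function(sequences, species, classLabel = "unclassified") {
  if (!methods::is(sequences, "AAStringSet")) {
    nm <- names(sequences)
    sequences <- Biostrings::AAStringSet(toupper(as.character(sequences)))
    names(sequences) <- nm
  }
  n <- length(sequences)
  new("SpidroinSet",
      sequences = sequences,
      speciesTag = rep_len(as.character(species), n),
      classLabel = rep_len(as.character(classLabel), n))
}

#' @rdname SpidroinSet
#' @export
setMethod("geneIds", "SpidroinSet", function(x) names(x@sequences))

#' @rdname SpidroinSet
#' @export
setMethod("speciesTags", "SpidroinSet", function(x) {
  stats::setNames(x@speciesTag, names(x@sequences))
})

#' @rdname SpidroinSet
#' @export
setMethod("classLabels", "SpidroinSet", function(x) {
  stats::setNames(x@classLabel, names(x@sequences))
})

#' @rdname SpidroinSet
#' @export
setMethod("residues", "SpidroinSet", function(x) {
  stats::setNames(as.character(x@sequences), names(x@sequences))
})

#' @rdname SpidroinSet
#' @export
setMethod("nGenes", "SpidroinSet", function(x) length(x@sequences))

#' @rdname SpidroinSet
#' @export
setMethod("length", "SpidroinSet", function(x) length(x@sequences))

#' @rdname SpidroinSet
#' @param i index (gene ids, logical, or integer positions).
#' @export
setMethod("[", "SpidroinSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  new("SpidroinSet",
      sequences = x@sequences[i],
      speciesTag = x@speciesTag[i],
      classLabel = x@classLabel[i])
})

setMethod("show", "SpidroinSet", function(object) {
  cat(sprintf("SpidroinSet with %d gene(s) [species: %s]\n",
              length(object@sequences),
              paste(unique(object@speciesTag), collapse = ", ")))
  if (length(object@sequences) > 0) {
    head <- utils::head(seq_along(object@sequences), 5L)
    for (i in head) {
      cat(sprintf("  %-18s %6d aa  %s\n",
                  names(object@sequences)[i],
                  BiocGenerics::width(object@sequences)[i],
                  object@classLabel[i]))
    }
    if (length(object@sequences) > 5L) cat("  ...\n")
  }
  invisible(NULL)
})

#' Combine two SpidroinSets into a joint dataset
#'
#' The pair (species, gene id) must stay unique across the joint set, which is
#' what permits mixing two species (same gene ids, different species tags).
#'
#' @param x,y \code{SpidroinSet} objects.
#' @return a joint \code{SpidroinSet}.
#' @export
combineSpidroinSets <- function(x, y) {
  stopifnot(methods::is(x, "SpidroinSet"), methods::is(y, "SpidroinSet"))
  new("SpidroinSet",
      sequences = c(x@sequences, y@sequences),
      speciesTag = c(x@speciesTag, y@speciesTag),
      classLabel = c(x@classLabel, y@classLabel))
}

#' DomainLibrary: curated spidroin terminal-domain references
#'
#' Reference library of conserved spidroin N-terminal (NTD) and C-terminal
#' (CTD) domains with silk-class labels, used as subjects for the local
#' homology screen. Every entry must carry one of the seven canonical class
#' labels.
#'
#' @slot sequences \link[Biostrings]{AAStringSet}, names are domain ids.
#' @slot domainKind character, "NTD" or "CTD" per entry.
#' @slot classLabel character, one canonical class per entry.
#'
#' @param sequences named character vector or \code{AAStringSet}.
#' @param domainKind "NTD"/"CTD" per entry.
#' @param classLabel canonical class per entry.
#' @param x a \code{DomainLibrary}.
#' @aliases domainKinds
#' @export DomainLibrary
#' @exportClass DomainLibrary
setClass("DomainLibrary",
  representation(
    sequences = "AAStringSet",
    domainKind = "character",
    classLabel = "character"
  )
)

setValidity("DomainLibrary", function(object) {
  n <- length(object@sequences)
  if (n == 0) return("domain library must not be empty")
  if (is.null(names(object@sequences)) || any(names(object@sequences) == ""))
    return("all library entries must be named")
  if (length(object@domainKind) != n || length(object@classLabel) != n)
    return("domainKind and classLabel must have one entry per sequence")
  if (!all(object@domainKind %in% c("NTD", "CTD")))
    return("domainKind must be 'NTD' or 'CTD'")
  if (!all(object@classLabel %in% .SPIDROIN_CLASSES))
    return(sprintf("classLabel must be one of: %s",
                   paste(.SPIDROIN_CLASSES, collapse = ", ")))
  TRUE
})

DomainLibrary <- function(sequences, domainKind, classLabel) {
  if (!methods::is(sequences, "AAStringSet")) {
    nm <- names(sequences)
    sequences <- Biostrings::AAStringSet(toupper(as.character(sequences)))
    names(sequences) <- nm
  }
  n <- length(sequences)
  new("DomainLibrary",
      sequences = sequences,
      domainKind = rep_len(as.character(domainKind), n),
      classLabel = rep_len(as.character(classLabel), n))
}

#' @rdname DomainLibrary
#' @export
setMethod("domainKinds", "DomainLibrary", function(x) {
  stats::setNames(x@domainKind, names(x@sequences))
})

#' @rdname DomainLibrary
#' @export
setMethod("classLabels", "DomainLibrary", function(x) {
  stats::setNames(x@classLabel, names(x@sequences))
})

#' @rdname DomainLibrary
#' @export
setMethod("residues", "DomainLibrary", function(x) {
  stats::setNames(as.character(x@sequences), names(x@sequences))
})

setMethod("show", "DomainLibrary", function(object) {
  cat(sprintf("DomainLibrary with %d entries (%d NTD, %d CTD)\n",
              length(object@sequences),
              sum(object@domainKind == "NTD"),
              sum(object@domainKind == "CTD")))
  invisible(NULL)
})

#' MotifCatalog: repetitive motif variants of spidroin cores
#'
#' Catalog of unique repetitive motif variants (4-41 residues; positions may
#' be the wildcards \code{x}/\code{z} meaning any residue, at a density of at
#' most one wildcard per two positions). Variants may be organized into motif
#' groups (by residue composition) and sub-groups (by sequence similarity);
#' ungroupable variants carry group id \code{"unassigned"}.
#'
#' @slot variants data.frame with columns \code{variant_id}, \code{pattern},
#'   \code{length}, \code{n_occurrences}, \code{group_id}, \code{subgroup_id}.
#'
#' @param variants the variant data.frame (missing grouping columns are
#'   initialized to "unassigned"/NA).
#' @param x a \code{MotifCatalog}.
#' @aliases variantTable variantIds motifPatterns
#' @export MotifCatalog
#' @exportClass MotifCatalog
setClass("MotifCatalog", representation(variants = "data.frame"))

setValidity("MotifCatalog", function(object) {
  v <- object@variants
  need <- c("variant_id", "pattern", "length", "n_occurrences",
            "group_id", "subgroup_id")
  if (!all(need %in% names(v)))
    return(sprintf("variants must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(v) == 0) return(TRUE)
  if (anyDuplicated(v$variant_id)) return("variant_id must be unique")
  len <- nchar(v$pattern)
  if (any(len < 4L | len > 41L))
    return("motif patterns must be 4-41 residues long")
  for (i in seq_len(nrow(v))) {
    if (!is.null(badResiduePosition(v$pattern[i], allowWildcards = TRUE)))
      return(sprintf("pattern '%s' contains an illegal character", v$pattern[i]))
  }
  nwild <- nchar(gsub("[^xz]", "", v$pattern))
  if (any(nwild / len > 0.5))
    return("wildcard density must not exceed 50% of pattern positions")
  TRUE
})

MotifCatalog <- function(variants) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  n <- nrow(variants)
  if (!"length" %in% names(variants)) variants$length <- nchar(variants$pattern)
  if (!"n_occurrences" %in% names(variants))
    variants$n_occurrences <- rep_len(NA_integer_, n)
  if (!"group_id" %in% names(variants))
    variants$group_id <- rep_len("unassigned", n)
  if (!"subgroup_id" %in% names(variants))
    variants$subgroup_id <- rep_len(NA_character_, n)
  rownames(variants) <- NULL
  new("MotifCatalog", variants = variants)
}

#' @rdname MotifCatalog
#' @export
setMethod("variantTable", "MotifCatalog", function(x) x@variants)

#' @rdname MotifCatalog
#' @export
setMethod("variantIds", "MotifCatalog", function(x) x@variants$variant_id)

#' @rdname MotifCatalog
#' @export
setMethod("motifPatterns", "MotifCatalog", function(x) {
  stats::setNames(x@variants$pattern, x@variants$variant_id)
})

#' @rdname MotifCatalog
#' @export
setMethod("length", "MotifCatalog", function(x) nrow(x@variants))

setMethod("show", "MotifCatalog", function(object) {
  v <- object@variants
  cat(sprintf("MotifCatalog with %d variant(s)", nrow(v)))
  if (nrow(v) > 0) {
    cat(sprintf(" (lengths %d-%d; %d grouped)",
                min(v$length), max(v$length), sum(v$group_id != "unassigned")))
  }
  cat("\n")
  invisible(NULL)
})

#' SharingSummary: cross-species motif/cassette sharing tallies
#'
#' Machine twin of a two-species repeat-sharing summary table: counts of
#' feature types private to each species or shared, the occurrence split, and
#' the derived percentages (rounded half-up to one decimal, recomputed from
#' counts rather than stored free-floating).
#'
#' @slot featureKind "motif" or "cassette".
#' @slot speciesA,speciesB species tags.
#' @slot totalTypes,privateA,privateB,shared type counts.
#' @slot occurrencesA,occurrencesB occurrence totals per species.
#' @slot nGenesA,nGenesB number of genes carrying occurrences per species.
#' @slot pctPrivateA,pctPrivateB,pctShared,pctOccurrencesA derived percentages.
#' @export
setClass("SharingSummary",
  representation(
    featureKind = "character",
    speciesA = "character", speciesB = "character",
    totalTypes = "integer",
    privateA = "integer", privateB = "integer", shared = "integer",
    occurrencesA = "integer", occurrencesB = "integer",
    nGenesA = "integer", nGenesB = "integer",
    pctPrivateA = "numeric", pctPrivateB = "numeric",
    pctShared = "numeric", pctOccurrencesA = "numeric"
  )
)

setValidity("SharingSummary", function(object) {
  if (object@privateA + object@privateB + object@shared != object@totalTypes)
    return("privateA + privateB + shared must equal totalTypes")
  if (any(c(object@privateA, object@privateB, object@shared,
            object@occurrencesA, object@occurrencesB) < 0))
    return("counts must be non-negative")
  TRUE
})

setMethod("show", "SharingSummary", function(object) {
  cat(sprintf("%s sharing summary: %s vs %s\n",
              object@featureKind, object@speciesA, object@speciesB))
  cat(sprintf("  Types detected                  %6d\n", object@totalTypes))
  cat(sprintf("  Private to %-8s             %6d (%.1f%%)\n",
              object@speciesA, object@privateA, object@pctPrivateA))
  cat(sprintf("  Private to %-8s             %6d (%.1f%%)\n",
              object@speciesB, object@privateB, object@pctPrivateB))
  cat(sprintf("  Shared                          %6d (%.1f%%)\n",
              object@shared, object@pctShared))
  cat(sprintf("  Occurrences %s / %s     %6d / %d (%.1f%% in %s)\n",
              object@speciesA, object@speciesB,
              object@occurrencesA, object@occurrencesB,
              object@pctOccurrencesA, object@speciesA))
  invisible(NULL)
})

#' SpidroinGrammar: generative model for synthetic spidroins
#'
#' A spidroin-like protein is emulated as a conserved ~100-aa N-terminal
#' domain (containing a MAFAS-like anchor), a repetitive core built by
#' concatenating cassette instances (ordered tuples of 2-6 pool motifs with
#' short inter-motif spacers), and a conserved ~100-aa C-terminal domain.
#' Consecutive cassette instances are separated by longer spacers (by default
#' above the 20-residue adjacency limit) so that planted cassettes stay
#' distinct higher-order units.
#'
#' @slot ntd,ctd terminal-domain template residue strings (~100 aa).
#' @slot motifPool motif patterns, lengths 4-41.
#' @slot cassetteTemplates list of integer vectors (2-6 pool indices each).
#' @slot spacerRange inclusive range of intra-cassette spacer lengths (<= 20).
#' @slot interCassetteRange inclusive range of between-cassette spacer lengths.
#' @slot repeatsPerGene inclusive range of cassette instances per gene.
#' @slot background named numeric: residue sampling weights for spacers.
#' @slot classLabel silk-class label recorded as ground truth.
#' @export
setClass("SpidroinGrammar",
  representation(
    ntd = "character", ctd = "character",
    motifPool = "character",
    cassetteTemplates = "list",
    spacerRange = "integer",
    interCassetteRange = "integer",
    repeatsPerGene = "integer",
    background = "numeric",
    classLabel = "character"
  )
)

setValidity("SpidroinGrammar", function(object) {
  if (!grepl("MAFAS", object@ntd, fixed = TRUE))
    return("ntd template must contain the MAFAS anchor")
  len <- nchar(object@motifPool)
  if (length(object@motifPool) == 0 || any(len < 4L | len > 41L))
    return("motif pool patterns must be 4-41 residues long")
  sizes <- lengths(object@cassetteTemplates)
  if (length(object@cassetteTemplates) == 0 || any(sizes < 2L | sizes > 6L))
    return("cassette templates must have 2-6 components")
  idx <- unlist(object@cassetteTemplates)
  if (any(idx < 1L | idx > length(object@motifPool)))
    return("cassette template indices must point into the motif pool")
  if (length(object@spacerRange) != 2L || object@spacerRange[1L] < 0L ||
      object@spacerRange[2L] > 20L || diff(object@spacerRange) < 0L)
    return("spacerRange must be an increasing pair within [0, 20]")
  if (length(object@interCassetteRange) != 2L ||
      object@interCassetteRange[1L] < 0L || diff(object@interCassetteRange) < 0L)
    return("interCassetteRange must be an increasing pair of non-negatives")
  if (length(object@repeatsPerGene) != 2L || object@repeatsPerGene[1L] < 0L ||
      diff(object@repeatsPerGene) < 0L)
    return("repeatsPerGene must be an increasing pair of non-negatives")
  if (is.null(names(object@background)) || any(object@background < 0) ||
      sum(object@background) <= 0)
    return("background must be a named, non-negative weight vector")
  if (!all(names(object@background) %in% setdiff(.AA_LETTERS, "X")))
    return("background residues must be canonical amino acids")
  TRUE
})
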