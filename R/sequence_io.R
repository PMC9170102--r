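## On-disk artifacts: protein FASTA, terminal-domain libraries, occurrence
## tables, and qPCR Ct tables. All coordinates on disk are 0-based half-open,
## matching the in-memory convention; 1-based closed display coordinates add
## exactly (+1, 0).

#' Read translated spidroin proteins from FASTA
#'
#' The first whitespace-delimited header token becomes the gene id (the
#' remainder is retained as a free-text description attribute); sequences are
#' uppercased and trailing \code{*} stop symbols are stripped. The species tag
#' is caller-supplied, never inferred from headers, so joint two-species
#' datasets keep explicit provenance.
#'
#' @param path FASTA file path.
#' @param species species tag applied to every record (e.g. "Cdar").
#' @return a \link{SpidroinSet}; an empty file yields an empty set.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">gA", "MAFASAAAA", ">gB", "GPGPQGPS"), f)
#' readProteinFasta(f, species = "Cdar")
#' @export
readProteinFasta <- function(path, species) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, ">"))) {
    return(SpidroinSet(Biostrings::AAStringSet(), species = character(0)))
  }
  ## validate residues from the raw text first: the FASTA reader silently
  ## drops invalid one-letter codes, which would mask the error contract
  hdr <- which(startsWith(lines, ">"))
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    if (bounds[k + 1L] - 1L < hdr[k] + 1L) next
    body <- lines[seq.int(hdr[k] + 1L, bounds[k + 1L] - 1L)]
    rawSeq <- sub("\\*+$", "", toupper(paste0(body, collapse = "")))
    pos <- badResiduePosition(rawSeq)
    if (!is.null(pos)) {
      id <- sub("\\s.*$", "", sub("^>", "", lines[hdr[k]]))
      stop(sprintf("illegal residue '%s' in gene '%s' at position %d",
                   substr(rawSeq, pos, pos), id, pos))
    }
  }
  raw <- Biostrings::readAAStringSet(path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(raw))
  seqs <- sub("\\*+$", "", seqs)
  for (i in seq_along(seqs)) {
    pos <- badResiduePosition(seqs[i])
    if (!is.null(pos)) {
      stop(sprintf("illegal residue '%s' in gene '%s' at position %d",
                   substr(seqs[i], pos, pos), ids[i], pos))
    }
  }
  names(seqs) <- ids
  out <- SpidroinSet(seqs, species = species)
  attr(out@sequences, "description") <- desc
  out
}

#' Write a SpidroinSet to FASTA
#'
#' @param x a \link{SpidroinSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeProteinFasta <- function(x, path) {
  stopifnot(methods::is(x, "SpidroinSet"))
  Biostrings::writeXStringSet(x@sequences, path)
  invisible(path)
}

#' Read a terminal-domain reference library
#'
#' The library is a FASTA of conserved NTD/CTD reference sequences plus a
#' tab-separated label table with columns \code{domain_id}, \code{domain_kind}
#' (NTD/CTD) and \code{class_label} (one of the seven canonical classes).
#'
#' @param fastaPath FASTA of reference domain sequences.
#' @param labelPath TSV with one row per FASTA entry.
#' @return a \link{DomainLibrary}.
#' @export
readDomainLibrary <- function(fastaPath, labelPath) {
  raw <- Biostrings::readAAStringSet(fastaPath)
  names(raw) <- sub("\\s.*$", "", names(raw))
  labels <- utils::read.delim(labelPath, stringsAsFactors = FALSE)
  need <- c("domain_id", "domain_kind", "class_label")
  missing <- setdiff(need, names(labels))
  if (length(missing) > 0) {
    stop(sprintf("label table is missing column(s) %s; expected schema: %s",
                 paste(missing, collapse = ", "), paste(need, collapse = ", ")))
  }
  idx <- match(names(raw), labels$domain_id)
  if (anyNA(idx)) {
    stop(sprintf("no label row for domain '%s'", names(raw)[which(is.na(idx))[1L]]))
  }
  DomainLibrary(toupper(as.character(raw)),
                domainKind = labels$domain_kind[idx],
                classLabel = labels$class_label[idx])
}

.OCC_COLUMNS <- c("species", "gene_id", "feature_kind", "feature_id",
                  "start", "end")

#' Construct / validate an occurrence table
#'
#' An occurrence table records located motif or cassette instances, one row
#' per occurrence, with 0-based half-open residue coordinates. When a
#' \link{SpidroinSet} is supplied, coordinates are checked against gene
#' lengths.
#'
#' @param species,gene_id,feature_kind,feature_id,start,end column vectors
#'   (recycled); \code{feature_kind} is "motif" or "cassette".
#' @param x a data.frame with the occurrence-table columns.
#' @param genes optional \link{SpidroinSet} for coordinate bounds checking.
#' @return a validated occurrence data.frame.
#' @export
occurrenceTable <- function(species = character(0), gene_id = character(0),
                            feature_kind = character(0),
                            feature_id = character(0),
                            start = integer(0), end = integer(0)) {
  validateOccurrences(data.frame(
    species = as.character(species), gene_id = as.character(gene_id),
    feature_kind = as.character(feature_kind),
    feature_id = as.character(feature_id),
    start = as.integer(start), end = as.integer(end),
    stringsAsFactors = FALSE))
}

#' @rdname occurrenceTable
#' @export
validateOccurrences <- function(x, genes = NULL) {
  missing <- setdiff(.OCC_COLUMNS, names(x))
  if (length(missing) > 0) {
    stop(sprintf("occurrence table is missing column(s) %s; expected schema: %s",
                 paste(missing, collapse = ", "),
                 paste(.OCC_COLUMNS, collapse = ", ")))
  }
  x <- x[, .OCC_COLUMNS, drop = FALSE]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  bad <- which(x$start < 0L | x$start >= x$end)
  if (length(bad) > 0) {
    stop(sprintf("row %d (%s %s [%d,%d)): coordinates must satisfy 0 <= start < end",
                 bad[1L], x$gene_id[bad[1L]], x$feature_id[bad[1L]],
                 x$start[bad[1L]], x$end[bad[1L]]))
  }
  if (!all(x$feature_kind %in% c("motif", "cassette"))) {
    stop("feature_kind must be 'motif' or 'cassette'")
  }
  if (!is.null(genes)) {
    lens <- nchar(residues(genes))
    glen <- lens[x$gene_id]
    bad <- which(is.na(glen) | x$end > glen)
    if (length(bad) > 0) {
      stop(sprintf("row %d: occurrence [%d,%d) of %s exceeds gene '%s' bounds",
                   bad[1L], x$start[bad[1L]], x$end[bad[1L]],
                   x$feature_id[bad[1L]], x$gene_id[bad[1L]]))
    }
  }
  rownames(x) <- NULL
  x
}

## Deterministic occurrence-table row order used for all on-disk output.
sortOccurrences <- function(x) {
  x <- x[orderStrings(x$species, x$gene_id, x$start, x$feature_id), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Write / read an occurrence table (TSV)
#'
#' Rows are written tab-separated with a header in a deterministic order
#' (species, gene id, start, feature id) regardless of input order; reading a
#' written table reproduces its rows exactly.
#'
#' @param x an occurrence data.frame (see \link{occurrenceTable}).
#' @param path TSV file path.
#' @param genes optional \link{SpidroinSet} for bounds checking before writing.
#' @return \code{writeOccurrenceTable} returns \code{path} invisibly;
#'   \code{readOccurrenceTable} returns the occurrence data.frame.
#' @export
writeOccurrenceTable <- function(x, path, genes = NULL) {
  x <- sortOccurrences(validateOccurrences(x, genes = genes))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOccurrenceTable
#' @export
readOccurrenceTable <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in intersect(c("species", "gene_id", "feature_kind", "feature_id"),
                        names(x))) {
    x[[col]] <- as.character(x[[col]])
  }
  validateOccurrences(x)
}

#' Convert occurrence coordinates for human-readable display
#'
#' Internal coordinates are 0-based half-open; display coordinates are
#' 1-based closed, i.e. exactly (start + 1, end).
#'
#' @param x an occurrence data.frame.
#' @return the table with \code{start}/\code{end} replaced by 1-based closed
#'   \code{start1}/\code{end1}.
#' @export
toDisplayCoordinates <- function(x) {
  x <- validateOccurrences(x)
  x$start1 <- x$start + 1L
  x$end1 <- x$end
  x$start <- NULL
  x$end <- NULL
  x
}

.CT_COLUMNS <- c("sample", "tissue", "target", "replicate", "ct")

#' Read a qPCR Ct table
#'
#' Expects a tab-separated table with columns \code{sample}, \code{tissue},
#' \code{target}, \code{replicate}, \code{ct} and optionally \code{is_nrt}
#' (no-reverse-transcriptase control wells). "Undetermined" or empty Ct
#' entries are parsed as censored values: \code{ct} is set to
#' \code{maxCycles} and \code{censored} is \code{TRUE}; censored values are
#' never used to impute a numeric relative quantity downstream.
#'
#' @param path TSV file path.
#' @param maxCycles censoring limit for undetermined wells (cycles).
#' @return data.frame with columns sample, tissue, target, replicate, ct,
#'   censored, is_nrt.
#' @export
readCtTable <- function(path, maxCycles = 40) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(.CT_COLUMNS, names(x))
  if (length(missing) > 0) {
    stop(sprintf("Ct table is missing column(s) %s; expected schema: %s",
                 paste(missing, collapse = ", "),
                 paste(c(.CT_COLUMNS, "[is_nrt]"), collapse = ", ")))
  }
  ct_raw <- trimws(x$ct)
  censored <- ct_raw == "" | toupper(ct_raw) == "UNDETERMINED" | is.na(ct_raw)
  ct <- suppressWarnings(as.numeric(ct_raw))
  if (any(!censored & is.na(ct))) {
    bad <- which(!censored & is.na(ct))[1L]
    stop(sprintf("row %d: Ct value '%s' is neither numeric nor 'Undetermined'",
                 bad, ct_raw[bad]))
  }
  ct[censored] <- maxCycles
  out <- data.frame(sample = x$sample, tissue = x$tissue, target = x$target,
                    replicate = as.integer(x$replicate), ct = ct,
                    censored = censored, stringsAsFactors = FALSE)
  out$is_nrt <- if ("is_nrt" %in% names(x)) {
    as.logical(x$is_nrt)
  } else {
    FALSE
  }
  out
}

#' Write a qPCR Ct table
#'
#' Censored wells are written back as "Undetermined" so the written file
#' round-trips through \link{readCtTable}.
#'
#' @param x a Ct data.frame as returned by \link{readCtTable} or
#'   \link{generateCtTable}.
#' @param path TSV file path.
#' @return \code{path}, invisibly.
#' @export
writeCtTable <- function(x, path) {
  out <- x[, intersect(c(.CT_COLUMNS, "is_nrt"), names(x)), drop = FALSE]
  out$ct <- as.character(out$ct)
  if ("censored" %in% names(x)) out$ct[x$censored] <- "Undetermined"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
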