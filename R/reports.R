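## Paper-shaped report assembly: a sharing-summary table, top-k motif
## listings per panel, and a targets-by-tissues relative-expression matrix,
## built from the upstream modules' tables. Every number in the bundle is
## recomputed from the referenced inputs; rendering is pure (same inputs,
## identical bytes).

#' Assemble a report bundle from upstream tables
#'
#' Inputs may be file paths (read with the package readers, so schema
#' violations raise errors naming the file and expected columns) or
#' in-memory tables of the same shapes. Percentages are re-derived from
#' counts, never copied.
#'
#' @param occurrencesA,occurrencesB motif occurrence tables or TSV paths.
#' @param ct optional Ct table (or TSV path) for the expression matrix.
#' @param classLabels optional named class vector per gene, or a TSV path
#'   with columns gene_id, class_label.
#' @param k top-k panel size.
#' @param reference,calibrator qPCR reference target and calibrator tissue.
#' @param seed seed recorded in the run metadata.
#' @return a report bundle: list with \code{sharing}, \code{origin},
#'   \code{topMotifs}, \code{expression} (targets x tissues rq matrix or
#'   NULL), and \code{metadata}.
#' @export
buildReport <- function(occurrencesA, occurrencesB, ct = NULL,
                        classLabels = NULL, k = 15L,
                        reference = "RPL13a", calibrator = "legs",
                        seed = NA_integer_) {
  readOcc <- function(x, label) {
    if (is.character(x) && length(x) == 1L) {
      tryCatch(readOccurrenceTable(x), error = function(e) {
        stop(sprintf("%s ('%s'): %s", label, x, conditionMessage(e)))
      })
    } else {
      validateOccurrences(x)
    }
  }
  occA <- readOcc(occurrencesA, "occurrencesA")
  occB <- readOcc(occurrencesB, "occurrencesB")
  if (is.character(classLabels) && length(classLabels) == 1L &&
      file.exists(classLabels)) {
    lab <- utils::read.delim(classLabels, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "class_label") %in% names(lab))) {
      stop(sprintf("class label table '%s' must have columns gene_id, class_label",
                   classLabels))
    }
    classLabels <- stats::setNames(lab$class_label, lab$gene_id)
  }
  sharing <- summarizeSharing(occA, occB, featureKind = "motif")
  origin <- originBreakdown(occA, occB,
                            classLabels = if (is.null(classLabels)) {
                              character(0)
                            } else classLabels)
  top <- rankTopMotifs(occA, occB, k = k, classLabels = classLabels)
  expression <- NULL
  if (!is.null(ct)) {
    if (is.character(ct) && length(ct) == 1L) ct <- readCtTable(ct)
    rq <- relativeQuantities(ct, reference = reference,
                             calibrator = calibrator)
    targets <- sort(unique(rq$target), method = "radix")
    tissues <- sort(unique(rq$tissue), method = "radix")
    expression <- matrix(NA_real_, length(targets), length(tissues),
                         dimnames = list(targets, tissues))
    for (i in seq_len(nrow(rq))) {
      expression[rq$target[i], rq$tissue[i]] <- rq$rq[i]
    }
  }
  list(sharing = sharing, origin = origin, topMotifs = top,
       expression = expression,
       metadata = list(seed = seed, k = k, reference = reference,
                       calibrator = calibrator,
                       package_version = as.character(
                         utils::packageVersion("silkmotifs"))))
}

#' Render a report bundle as plain text
#'
#' @param bundle result of \link{buildReport}.
#' @return character vector of report lines (deterministic).
#' @export
renderReportText <- function(bundle) {
  s <- bundle$sharing
  lines <- c(
    "Spidroin repeat motif sharing summary",
    sprintf("  Motif types detected: %d", s@totalTypes),
    sprintf("  Private to %s: %d (%.1f%%)", s@speciesA, s@privateA, s@pctPrivateA),
    sprintf("  Private to %s: %d (%.1f%%)", s@speciesB, s@privateB, s@pctPrivateB),
    sprintf("  Shared: %d (%.1f%%)", s@shared, s@pctShared),
    sprintf("  Occurrences %s / %s: %d / %d (%.1f%% in %s)",
            s@speciesA, s@speciesB, s@occurrencesA, s@occurrencesB,
            s@pctOccurrencesA, s@speciesA))
  for (i in seq_len(nrow(bundle$origin))) {
    o <- bundle$origin[i, ]
    lines <- c(lines, sprintf(
      "  %s private types from a single gene: %d of %d (%.1f%%)",
      o$species, o$single_gene_private_types, o$private_types,
      o$pct_single_gene))
  }
  panel <- function(name, df) {
    c(sprintf("Top %d %s", bundle$metadata$k, name),
      if (nrow(df) == 0) "  (none)" else
        sprintf("  %-24s %6d", df$feature_id, df$n_occurrences))
  }
  lines <- c(lines,
             panel(sprintf("motifs private to %s", s@speciesA),
                   bundle$topMotifs$privateA),
             panel(sprintf("motifs private to %s", s@speciesB),
                   bundle$topMotifs$privateB),
             panel("shared motifs", bundle$topMotifs$shared))
  if (!is.null(bundle$expression)) {
    lines <- c(lines, "Relative expression (rq, 2^-ddCt)",
               paste0("  target\t", paste(colnames(bundle$expression),
                                          collapse = "\t")))
    for (tg in rownames(bundle$expression)) {
      lines <- c(lines, paste0("  ", tg, "\t",
                               paste(sprintf("%.4g", bundle$expression[tg, ]),
                                     collapse = "\t")))
    }
  }
  lines
}

#' Write a report bundle to a directory
#'
#' Writes \code{sharing.tsv}, \code{origin.tsv}, the three top-k panels,
#' \code{expression.tsv} (when present), and the rendered \code{report.txt}.
#'
#' @param bundle result of \link{buildReport}.
#' @param dir output directory (created when absent).
#' @return \code{dir}, invisibly.
#' @export
writeReport <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- bundle$sharing
  sharingDf <- data.frame(
    metric = c("total_types", "private_a", "private_b", "shared",
               "pct_private_a", "pct_private_b", "pct_shared",
               "occurrences_a", "occurrences_b", "pct_occurrences_a"),
    value = c(s@totalTypes, s@privateA, s@privateB, s@shared,
              s@pctPrivateA, s@pctPrivateB, s@pctShared,
              s@occurrencesA, s@occurrencesB, s@pctOccurrencesA),
    stringsAsFactors = FALSE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(sharingDf, "sharing.tsv")
  w(bundle$origin, "origin.tsv")
  w(bundle$topMotifs$privateA, "top_motifs_private_a.tsv")
  w(bundle$topMotifs$privateB, "top_motifs_private_b.tsv")
  w(bundle$topMotifs$shared, "top_motifs_shared.tsv")
  if (!is.null(bundle$expression)) {
    em <- data.frame(target = rownames(bundle$expression),
                     bundle$expression, check.names = FALSE,
                     stringsAsFactors = FALSE)
    w(em, "expression.tsv")
  }
  writeLines(renderReportText(bundle), file.path(dir, "report.txt"))
  invisible(dir)
}
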