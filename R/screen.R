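## Spidroin candidate screening: local homology of query proteins to curated
## terminal-domain references, signature-motif annotation, fragment
## categorization, and silk-class assignment.

## Karlin-Altschul parameters for BLOSUM62 with affine gap open 11 / extend 1
## (the standard gapped protein-search regime). E = K * m * n * exp(-lambda*S),
## with m the query (region) length and n the summed library length.
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Local homology search against a terminal-domain library
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps, open 11 / extend 1)
#' of each query against each library entry, with a Karlin-Altschul
#' expectation value computed over the summed library length. Hits with
#' E-value above \code{eThreshold} are discarded; per query at most one best
#' NTD and one best CTD hit is reported (highest score, ties broken by lowest
#' E-value, then lexicographic reference id). Because spidroin terminal
#' domains are ~100 aa and repetitive cores alignment-bait, queries longer
#' than 300 aa are searched only within their first \code{terminalRegion}
#' residues for NTD references and their last \code{terminalRegion} residues
#' for CTD references.
#'
#' @param queries a \link{SpidroinSet}.
#' @param library a \link{DomainLibrary}.
#' @param eThreshold E-value retention threshold (expectation units).
#' @param terminalRegion residues searched at each end for long queries.
#' @return data.frame of best hits: gene_id, domain_kind, start, end (0-based
#'   half-open on the query), reference_id, class_label, score, evalue.
#' @examples
#' lib <- DomainLibrary(c(ref = strrep("MAFASGQNT", 11)),
#'                      domainKind = "NTD", classLabel = "MaSp")
#' qs <- SpidroinSet(c(g1 = strrep("MAFASGQNT", 11)), species = "Cdar")
#' localHomologySearch(qs, lib)
#' @export
localHomologySearch <- function(queries, library, eThreshold = 1e-6,
                                terminalRegion = 150L) {
  stopifnot(methods::is(queries, "SpidroinSet"))
  if (!methods::is(library, "DomainLibrary")) stop("library must be a DomainLibrary")
  if (nGenes(queries) == 0) stop("at least one query sequence is required")
  mat <- .blosum62()
  dbLen <- sum(BiocGenerics::width(library@sequences))
  refSeqs <- residues(library)
  refKinds <- domainKinds(library)
  refClasses <- classLabels(library)
  seqs <- residues(queries)
  rows <- list()
  for (g in names(seqs)) {
    q <- seqs[[g]]
    L <- nchar(q)
    best <- list(NTD = NULL, CTD = NULL)
    for (r in names(refSeqs)) {
      kind <- refKinds[[r]]
      if (L > 300L) {
        if (kind == "NTD") {
          region <- substr(q, 1L, terminalRegion)
          offset <- 0L
        } else {
          region <- substr(q, L - terminalRegion + 1L, L)
          offset <- L - terminalRegion
        }
      } else {
        region <- q
        offset <- 0L
      }
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(region), Biostrings::AAString(refSeqs[[r]]),
        type = "local", substitutionMatrix = mat,
        gapOpening = 11, gapExtension = 1)
      s <- BiocGenerics::score(aln)
      ev <- .KA_K * nchar(region) * dbLen * exp(-.KA_LAMBDA * s)
      if (ev > eThreshold) next
      pat <- Biostrings::pattern(aln)
      hit <- data.frame(
        gene_id = g, domain_kind = kind,
        start = BiocGenerics::start(pat) - 1L + offset,
        end = BiocGenerics::end(pat) + offset,
        reference_id = r, class_label = refClasses[[r]],
        score = s, evalue = ev, stringsAsFactors = FALSE)
      cur <- best[[kind]]
      if (is.null(cur) ||
          hit$score > cur$score ||
          (hit$score == cur$score && hit$evalue < cur$evalue) ||
          (hit$score == cur$score && hit$evalue == cur$evalue &&
           hit$reference_id < cur$reference_id)) {
        best[[kind]] <- hit
      }
    }
    rows <- c(rows, Filter(Negate(is.null), best))
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), domain_kind = character(0),
                      start = integer(0), end = integer(0),
                      reference_id = character(0), class_label = character(0),
                      score = numeric(0), evalue = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate spidroin signature motifs
#'
#' Reports, per gene: whether the MAFAS anchor occurs with its start inside
#' the N-terminal window; the number of non-overlapping GPGQQ repeats; and a
#' summary of maximal poly-alanine runs of length >= \code{minPolyA}.
#'
#' @param x a \link{SpidroinSet}.
#' @param ntdWindow N-terminal window (residues) within which MAFAS counts.
#' @param minPolyA minimum poly-A run length reported.
#' @return data.frame: gene_id, mafas_present, gpgqq_count, polya_run_count,
#'   max_polya_length.
#' @seealso \link{polyAlanineRuns} for run coordinates.
#' @export
detectSignatures <- function(x, ntdWindow = 100L, minPolyA = 4L) {
  stopifnot(methods::is(x, "SpidroinSet"))
  seqs <- residues(x)
  runs <- polyAlanineRuns(x, minLength = minPolyA)
  out <- data.frame(gene_id = names(seqs), stringsAsFactors = FALSE)
  out$mafas_present <- vapply(seqs, function(s) {
    pos <- regexpr("MAFAS", s, fixed = TRUE)
    pos != -1L && (pos - 1L) < ntdWindow
  }, logical(1), USE.NAMES = FALSE)
  out$gpgqq_count <- vapply(seqs, function(s) {
    length(nonOverlappingMatches("GPGQQ", s))
  }, integer(1), USE.NAMES = FALSE)
  out$polya_run_count <- vapply(names(seqs), function(g) {
    sum(runs$gene_id == g)
  }, integer(1), USE.NAMES = FALSE)
  out$max_polya_length <- vapply(names(seqs), function(g) {
    r <- runs$length[runs$gene_id == g]
    if (length(r) == 0) 0L else max(r)
  }, integer(1), USE.NAMES = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname detectSignatures
#' @param minLength minimum run length (residues).
#' @return \code{polyAlanineRuns}: data.frame gene_id, start (0-based), length.
#' @export
polyAlanineRuns <- function(x, minLength = 4L) {
  stopifnot(methods::is(x, "SpidroinSet"))
  seqs <- residues(x)
  rows <- lapply(names(seqs), function(g) {
    r <- rle(strsplit(seqs[[g]], "")[[1L]] == "A")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths >= minLength
    if (!any(keep)) return(NULL)
    data.frame(gene_id = g, start = starts[keep], length = r$lengths[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(gene_id = character(0),
                                                start = integer(0),
                                                length = integer(0)))))
  rownames(out) <- NULL
  out
}

#' Detect internal assembly-gap evidence
#'
#' Assembly gaps in translated gene models surface as runs of \code{X}
#' residues; a run of at least \code{minRun} X's strictly inside the sequence
#' counts as internal-gap evidence.
#'
#' @param x a \link{SpidroinSet}.
#' @param minRun minimum X-run length counted as a gap.
#' @return named logical vector per gene.
#' @export
detectAssemblyGaps <- function(x, minRun = 10L) {
  stopifnot(methods::is(x, "SpidroinSet"))
  vapply(residues(x), function(s) {
    grepl(sprintf("X{%d,}", minRun), s)
  }, logical(1))
}

.FRAGMENT_CATEGORIES <- c("complete", "internal_gap", "five_prime_end",
                          "three_prime_end", "repetitive")

#' Categorize spidroin fragments
#'
#' Assigns each candidate exactly one of five fragment categories from its
#' terminal-domain hits and gap evidence: \code{complete} (NTD and CTD, no
#' internal gap), \code{internal_gap} (both termini with gap evidence),
#' \code{five_prime_end} (NTD only), \code{three_prime_end} (CTD only), and
#' \code{repetitive} (neither terminus; repeats-only sequence). The
#' repetitive call is supported by at least 3 GPGQQ repeats, a poly-A run of
#' >= 6 residues, or >= 30 percent of residues covered by catalog motifs when
#' a painted coverage fraction is supplied; candidates with neither terminal
#' domain fall into this residual category, with the evidence recorded in the
#' \code{repetitive_evidence} column.
#'
#' @param x a \link{SpidroinSet}.
#' @param hits terminal-domain hits from \link{localHomologySearch}.
#' @param gapEvidence named logical per gene (see \link{detectAssemblyGaps});
#'   missing genes default to FALSE.
#' @param signatures optional signature table from \link{detectSignatures}
#'   (computed on the fly when absent).
#' @param motifCoverage optional named numeric per gene: fraction of residues
#'   covered by catalog motif occurrences.
#' @return data.frame: gene_id, category, repetitive_evidence.
#' @export
categorizeFragments <- function(x, hits, gapEvidence = NULL,
                                signatures = NULL, motifCoverage = NULL) {
  stopifnot(methods::is(x, "SpidroinSet"))
  ids <- geneIds(x)
  if (is.null(signatures)) signatures <- detectSignatures(x)
  if (is.null(gapEvidence)) gapEvidence <- stats::setNames(rep(FALSE, length(ids)), ids)
  out <- data.frame(gene_id = ids, category = NA_character_,
                    repetitive_evidence = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    g <- ids[i]
    h <- hits[hits$gene_id == g, , drop = FALSE]
    hasNTD <- any(h$domain_kind == "NTD")
    hasCTD <- any(h$domain_kind == "CTD")
    gap <- isTRUE(gapEvidence[[g]])
    sig <- signatures[signatures$gene_id == g, , drop = FALSE]
    cov <- if (!is.null(motifCoverage) && g %in% names(motifCoverage)) {
      motifCoverage[[g]]
    } else {
      0
    }
    repEvidence <- (nrow(sig) > 0 &&
                    (sig$gpgqq_count >= 3L || sig$max_polya_length >= 6L)) ||
                   cov >= 0.30
    out$repetitive_evidence[i] <- repEvidence
    out$category[i] <- if (hasNTD && hasCTD) {
      if (gap) "internal_gap" else "complete"
    } else if (hasNTD) {
      "five_prime_end"
    } else if (hasCTD) {
      "three_prime_end"
    } else {
      "repetitive"
    }
  }
  out
}

#' Assign a silk class to one gene
#'
#' Combines the available lines of evidence with precedence: concordant
#' N-/C-terminal homology outranks internal motif votes, which outrank
#' gland-expression rank. Conflicting NTD/CTD labels with no tiebreaking
#' evidence yield \code{"unclassified"} with the (conflicting) evidence still
#' recorded; a gene with no evidence at all is \code{"unclassified"} with an
#' empty evidence set.
#'
#' @param geneId gene identifier.
#' @param hits terminal-domain hits (rows for other genes are ignored).
#' @param motifClassVotes optional named integer vector: votes per class from
#'   internal repetitive motifs shared with classified genes.
#' @param expressionClass optional class label implied by the silk gland with
#'   the highest relative expression (see \link{rankGlands}).
#' @return list with \code{gene_id}, \code{class_label}, \code{evidence}
#'   (character subset of ntd_homology, ctd_homology, internal_motifs,
#'   expression).
#' @export
assignClass <- function(geneId, hits, motifClassVotes = NULL,
                        expressionClass = NULL) {
  h <- hits[hits$gene_id == geneId, , drop = FALSE]
  ntd <- h$class_label[h$domain_kind == "NTD"]
  ctd <- h$class_label[h$domain_kind == "CTD"]
  evidence <- character(0)
  if (length(ntd) > 0) evidence <- c(evidence, "ntd_homology")
  if (length(ctd) > 0) evidence <- c(evidence, "ctd_homology")
  motifLabel <- NULL
  if (!is.null(motifClassVotes) && length(motifClassVotes) > 0 &&
      sum(motifClassVotes) > 0) {
    top <- names(motifClassVotes)[motifClassVotes == max(motifClassVotes)]
    motifLabel <- sort(top)[1L]
    evidence <- c(evidence, "internal_motifs")
  }
  if (!is.null(expressionClass) && !is.na(expressionClass)) {
    evidence <- c(evidence, "expression")
  }
  label <- if (length(ntd) > 0 && length(ctd) > 0) {
    if (ntd[1L] == ctd[1L]) {
      ntd[1L]
    } else if (!is.null(motifLabel)) {
      motifLabel
    } else if ("expression" %in% evidence) {
      expressionClass
    } else {
      "unclassified"
    }
  } else if (length(ntd) > 0) {
    ntd[1L]
  } else if (length(ctd) > 0) {
    ctd[1L]
  } else if (!is.null(motifLabel)) {
    motifLabel
  } else if ("expression" %in% evidence) {
    expressionClass
  } else {
    "unclassified"
  }
  list(gene_id = geneId, class_label = label, evidence = evidence)
}

#' Map a silk-gland tissue to its namesake spidroin class
#'
#' Expression evidence for class assignment comes from the gland with the
#' highest relative expression; this maps the standard tissue-panel names to
#' the silk class named for that gland. Tissues without a one-to-one class
#' (the combined aciniform/piriform isolate, non-silk tissues) map to
#' \code{NA}.
#'
#' @param tissue character vector of tissue names (e.g. "MA", "FL",
#'   "tubuliform").
#' @return character vector of class labels or NA.
#' @export
glandToClass <- function(tissue) {
  map <- c(MA = "MaSp", MI = "MiSp", FL = "FLAG", AG = "AgSp",
           tubuliform = "TuSp")
  unname(map[tissue])
}
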