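## Synthetic spidroin datasets with full ground truth: sequences built from a
## motif/cassette grammar, paired two-species catalogs with a planted sharing
## fraction, fragment truncations, and qPCR Ct tables. Random streams are
## derived per component from one master seed, so identical seeds give
## byte-identical outputs and changing one grammar knob perturbs only its own
## stream.
##
## Spacer residues are drawn from an alphabet disjoint from the motif-pool
## alphabet. This is a deliberate idealization: planted motif occurrences are
## then the unique ground truth (no spurious or junction-spanning matches),
## which is what makes exact-recovery testing of painting and cassette
## detection meaningful.

#' Construct a spidroin grammar
#'
#' @param ntd,ctd terminal-domain templates (NTD must contain "MAFAS").
#' @param motifPool motif patterns (4-41 residues each).
#' @param cassetteTemplates list of integer vectors of 2-6 pool indices.
#' @param spacerRange intra-cassette spacer length range, within [0, 20].
#' @param interCassetteRange between-cassette spacer length range (defaults
#'   exceed the 20-residue adjacency limit so planted cassettes stay distinct).
#' @param repeatsPerGene range of cassette instances per gene.
#' @param background named residue weights for spacer sampling.
#' @param classLabel ground-truth silk class of generated genes.
#' @return a validated \link[=SpidroinGrammar-class]{SpidroinGrammar}.
#' @export
spidroinGrammar <- function(ntd, ctd, motifPool, cassetteTemplates,
                            spacerRange = c(1L, 6L),
                            interCassetteRange = c(21L, 25L),
                            repeatsPerGene = c(4L, 8L),
                            background = NULL,
                            classLabel = "MaSp") {
  if (is.null(background)) {
    background <- stats::setNames(rep(1, 6), c("N", "K", "R", "H", "F", "M"))
  }
  new("SpidroinGrammar",
      ntd = ntd, ctd = ctd, motifPool = motifPool,
      cassetteTemplates = lapply(cassetteTemplates, as.integer),
      spacerRange = as.integer(spacerRange),
      interCassetteRange = as.integer(interCassetteRange),
      repeatsPerGene = as.integer(repeatsPerGene),
      background = background, classLabel = classLabel)
}

#' Default spidroin grammar
#'
#' A realistic fixture built from motifs of the silk literature: the tandem
#' unit GPGPQGPS, the GPGQQ signature, a poly-alanine tract, glycine-rich
#' motifs ([GGP]3, GYGGQ, GGSGGGL), a Ser/Val/Thr-rich spacer-like motif, and
#' an aggregate-type DT.SY.TGEY-like motif. Templates are 3-component
#' cassettes; every template carries at least one GPGQQ or poly-A component
#' so repeats-only fragments keep detectable signatures.
#'
#' @param classLabel silk class recorded as ground truth.
#' @return a \link[=SpidroinGrammar-class]{SpidroinGrammar}.
#' @export
defaultGrammar <- function(classLabel = "MaSp") {
  ## fixed, non-repetitive 100-aa templates: a periodic template would act as
  ## an alignment decoy against repetitive cores
  ntd <- paste0("MAFASLNPMYDFYPHQHVMNPVQWMYKRIIQELWVCFCGPVDCTCNWSLCEC",
                "CSVCQHLWFCEHHSAAIMKYTWDKYTSQPALRHKRMANQKWIGWWSAG")
  ctd <- paste0("YTKHCNGYEMQLPMMDQLSWMMMRFHTWMRCIGCPYHMVRMKGGMHGNGFLA",
                "PCRNQQVIQDLESISVGAYMLINTHLYASCHPKKNRQMPVFNWGTFTV")
  pool <- c("GPGPQGPS", "GPGQQ", "AAAAAAA", "GGPGGPGGP", "GYGGQ",
            "GGSGGGL", "SVSVVSTTIS", "DTASYLTGEY")
  templates <- list(c(1L, 2L, 1L), c(3L, 1L, 2L), c(4L, 5L, 2L),
                    c(7L, 3L, 1L), c(6L, 5L, 3L), c(8L, 2L, 6L))
  spidroinGrammar(ntd, ctd, pool, templates, classLabel = classLabel)
}

#' Ground-truth motif catalog of a grammar
#'
#' The grammar's motif pool as a \link{MotifCatalog}, with variant ids
#' assigned by the same deterministic convention as \link{discoverMotifs}
#' (length descending, then lexicographic pattern), so planted occurrences
#' and painted occurrences share ids.
#'
#' @param grammar a \link[=SpidroinGrammar-class]{SpidroinGrammar}, or a
#'   character vector of patterns.
#' @return a \link{MotifCatalog}.
#' @export
groundTruthCatalog <- function(grammar) {
  pats <- if (methods::is(grammar, "SpidroinGrammar")) grammar@motifPool else grammar
  pats <- unique(pats)
  ord <- orderStrings(-nchar(pats), pats)
  pats <- pats[ord]
  MotifCatalog(data.frame(variant_id = sprintf("M%04d", seq_along(pats)),
                          pattern = pats, stringsAsFactors = FALSE))
}

#' Generate one synthetic spidroin with ground truth
#'
#' The sequence is NTD + a concatenation of cassette instances (template
#' motifs separated by sampled intra-cassette spacers, instances separated by
#' longer inter-cassette spacers) + CTD. Every planted occurrence is recorded
#' with 0-based half-open coordinates consistent with the generated sequence.
#' Deterministic given the seed.
#'
#' @param grammar a \link[=SpidroinGrammar-class]{SpidroinGrammar}.
#' @param seed master seed for this gene.
#' @param geneId,species identifiers for the generated record.
#' @param nRepeats optional fixed number of cassette instances (overrides the
#'   grammar range; 0 yields NTD + CTD with no planted occurrences).
#' @param templateStart optional 1-based template cycling offset; templates
#'   are used round-robin from this offset (seed-derived when omitted), which
#'   guarantees template coverage across a generated gene set.
#' @return list with \code{record} (a one-gene \link{SpidroinSet}),
#'   \code{motifOccurrences} and \code{cassetteOccurrences} (planted ground
#'   truth; motif feature ids follow \link{groundTruthCatalog}), and
#'   \code{ntdLength}/\code{ctdLength}.
#' @export
generateSpidroin <- function(grammar, seed, geneId = "syn_001",
                             species = "SynA", nRepeats = NULL,
                             templateStart = NULL) {
  stopifnot(methods::is(grammar, "SpidroinGrammar"))
  methods::validObject(grammar)
  catalog <- groundTruthCatalog(grammar)
  pats <- motifPatterns(catalog)
  poolIds <- stats::setNames(names(pats)[match(grammar@motifPool, pats)],
                             NULL)
  nTpl <- length(grammar@cassetteTemplates)
  if (is.null(nRepeats)) {
    nRepeats <- withSeed(deriveSeed(seed, 1L), {
      r <- grammar@repeatsPerGene
      if (r[1L] == r[2L]) r[1L] else sample(seq.int(r[1L], r[2L]), 1L)
    })
  }
  if (is.null(templateStart)) {
    templateStart <- withSeed(deriveSeed(seed, 2L), sample.int(nTpl, 1L))
  }
  tplIdx <- if (nRepeats > 0) {
    ((templateStart - 1L + seq_len(nRepeats) - 1L) %% nTpl) + 1L
  } else {
    integer(0)
  }
  nIntra <- sum(pmax(lengths(grammar@cassetteTemplates[tplIdx]) - 1L, 0L))
  nInter <- max(nRepeats - 1L, 0L)
  spacerLens <- withSeed(deriveSeed(seed, 3L), {
    intra <- if (nIntra > 0) {
      s <- grammar@spacerRange
      if (s[1L] == s[2L]) rep(s[1L], nIntra) else sample(seq.int(s[1L], s[2L]), nIntra, replace = TRUE)
    } else integer(0)
    inter <- if (nInter > 0) {
      s <- grammar@interCassetteRange
      if (s[1L] == s[2L]) rep(s[1L], nInter) else sample(seq.int(s[1L], s[2L]), nInter, replace = TRUE)
    } else integer(0)
    list(intra = as.integer(intra), inter = as.integer(inter))
  })
  totalSpacer <- sum(spacerLens$intra) + sum(spacerLens$inter)
  spacerChars <- withSeed(deriveSeed(seed, 4L), {
    if (totalSpacer > 0) {
      sample(names(grammar@background), totalSpacer, replace = TRUE,
             prob = grammar@background)
    } else character(0)
  })
  takeSpacer <- local({
    used <- 0L
    function(n) {
      if (n == 0L) return("")
      out <- paste0(spacerChars[(used + 1L):(used + n)], collapse = "")
      used <<- used + n
      out
    }
  })

  pieces <- list(grammar@ntd)
  pos <- nchar(grammar@ntd)
  motifRows <- list()
  cassetteRows <- list()
  iIntra <- 0L
  for (ci in seq_len(nRepeats)) {
    tpl <- grammar@cassetteTemplates[[tplIdx[ci]]]
    cstart <- pos
    gaps <- integer(0)
    for (j in seq_along(tpl)) {
      pat <- grammar@motifPool[tpl[j]]
      pieces[[length(pieces) + 1L]] <- pat
      motifRows[[length(motifRows) + 1L]] <- data.frame(
        species = species, gene_id = geneId, feature_kind = "motif",
        feature_id = poolIds[tpl[j]], start = pos, end = pos + nchar(pat),
        stringsAsFactors = FALSE)
      pos <- pos + nchar(pat)
      if (j < length(tpl)) {
        iIntra <- iIntra + 1L
        l <- spacerLens$intra[iIntra]
        pieces[[length(pieces) + 1L]] <- takeSpacer(l)
        gaps <- c(gaps, l)
        pos <- pos + l
      }
    }
    cassetteRows[[length(cassetteRows) + 1L]] <- data.frame(
      species = species, gene_id = geneId, feature_kind = "cassette",
      feature_id = paste(poolIds[tpl], collapse = "+"),
      start = cstart, end = pos,
      gaps = paste(gaps, collapse = ","), template = tplIdx[ci],
      stringsAsFactors = FALSE)
    if (ci < nRepeats) {
      l <- spacerLens$inter[ci]
      pieces[[length(pieces) + 1L]] <- takeSpacer(l)
      pos <- pos + l
    }
  }
  pieces[[length(pieces) + 1L]] <- grammar@ctd
  seq <- paste0(unlist(pieces), collapse = "")
  record <- SpidroinSet(stats::setNames(seq, geneId), species = species,
                        classLabel = grammar@classLabel)
  emptyOcc <- occurrenceTable()
  list(record = record,
       motifOccurrences = if (length(motifRows) > 0) {
         do.call(rbind, motifRows)
       } else emptyOcc,
       cassetteOccurrences = if (length(cassetteRows) > 0) {
         do.call(rbind, cassetteRows)
       } else {
         cbind(emptyOcc, data.frame(gaps = character(0), template = integer(0)))
       },
       ntdLength = nchar(grammar@ntd), ctdLength = nchar(grammar@ctd))
}

#' Generate a set of synthetic spidroins
#'
#' Genes are generated independently from per-gene derived seeds; template
#' cycling offsets advance across genes so that all cassette templates are
#' covered whenever enough instances are drawn.
#'
#' @param grammar a \link[=SpidroinGrammar-class]{SpidroinGrammar}.
#' @param nGenes number of genes (>= 1).
#' @param seed master seed.
#' @param species species tag.
#' @param prefix gene-id prefix.
#' @return list with \code{set} (a \link{SpidroinSet}),
#'   \code{motifOccurrences}, \code{cassetteOccurrences}.
#' @export
generateSpidroinSet <- function(grammar, nGenes, seed, species = "SynA",
                                prefix = "syn") {
  if (nGenes < 1) stop("nGenes must be at least 1")
  nTpl <- length(grammar@cassetteTemplates)
  recs <- vector("list", nGenes)
  offset <- withSeed(deriveSeed(seed, 5L), sample.int(nTpl, 1L))
  instances <- 0L
  for (i in seq_len(nGenes)) {
    recs[[i]] <- generateSpidroin(
      grammar, seed = deriveSeed(seed, 100L + i),
      geneId = sprintf("%s_%03d", prefix, i), species = species,
      templateStart = ((offset - 1L + instances) %% nTpl) + 1L)
    instances <- instances + nrow(recs[[i]]$cassetteOccurrences)
  }
  set <- recs[[1L]]$record
  for (i in seq_len(nGenes)[-1L]) set <- combineSpidroinSets(set, recs[[i]]$record)
  list(set = set,
       motifOccurrences = do.call(rbind, lapply(recs, `[[`, "motifOccurrences")),
       cassetteOccurrences = do.call(rbind, lapply(recs, `[[`, "cassetteOccurrences")))
}

#' Generate a paired two-species dataset with a planted sharing fraction
#'
#' A universe of \code{nMotifTypes} distinct, mutually non-substring motif
#' patterns is drawn; each type is shared between the two species with
#' probability \code{sharedFraction} and otherwise assigned alternately to
#' one species. Each species' genes are generated from its own pool with
#' 3-component cassette templates cycling through the pool, so every pool
#' type is planted. The realized shared-type fraction is binomial around the
#' planted value.
#'
#' @param sharedFraction probability a motif type occurs in both species.
#' @param nGenes genes per species (>= 1).
#' @param seed master seed.
#' @param nMotifTypes size of the motif-type universe.
#' @param grammarA,grammarB optional grammars supplying terminal-domain
#'   templates and spacer settings (motif pools and cassette templates are
#'   replaced by the drawn ones); defaults to \link{defaultGrammar}.
#' @param speciesA,speciesB species tags.
#' @return list with \code{setA}/\code{setB}, planted occurrence tables
#'   \code{occurrencesA}/\code{occurrencesB} (ids from the joint catalog),
#'   the joint \code{catalog}, and \code{truth} (pools, shared patterns,
#'   planted and realized shared fractions).
#' @export
generateTwoSpecies <- function(sharedFraction, nGenes, seed,
                               nMotifTypes = 200L,
                               grammarA = defaultGrammar("MaSp"),
                               grammarB = defaultGrammar("MaSp"),
                               speciesA = "Cdar", speciesB = "Tcla") {
  if (sharedFraction < 0 || sharedFraction > 1)
    stop("sharedFraction must be within [0, 1]")
  if (nGenes < 1) stop("nGenes must be at least 1")
  universe <- .randomMotifUniverse(nMotifTypes, deriveSeed(seed, 11L))
  assign <- withSeed(deriveSeed(seed, 12L),
                     stats::runif(nMotifTypes) < sharedFraction)
  privates <- which(!assign)
  toA <- privates[seq_along(privates) %% 2L == 1L]
  poolA <- universe[sort(c(which(assign), toA))]
  poolB <- universe[sort(c(which(assign), setdiff(privates, toA)))]
  ## degenerate corners: a species must keep a non-empty pool
  if (length(poolA) == 0) poolA <- universe[1L]
  if (length(poolB) == 0) poolB <- universe[min(2L, length(universe))]
  mkGrammar <- function(base, pool) {
    m <- length(pool)
    templates <- lapply(seq_len(ceiling(m / 3)), function(i) {
      ((3L * (i - 1L) + 0:2) %% m) + 1L
    })
    spidroinGrammar(base@ntd, base@ctd, pool, templates,
                    spacerRange = base@spacerRange,
                    interCassetteRange = base@interCassetteRange,
                    repeatsPerGene = base@repeatsPerGene,
                    background = base@background,
                    classLabel = base@classLabel)
  }
  gA <- mkGrammar(grammarA, poolA)
  gB <- mkGrammar(grammarB, poolB)
  genA <- generateSpidroinSet(gA, nGenes, deriveSeed(seed, 21L),
                              species = speciesA, prefix = "cda")
  genB <- generateSpidroinSet(gB, nGenes, deriveSeed(seed, 22L),
                              species = speciesB, prefix = "tcl")
  catalog <- groundTruthCatalog(universe)
  ## remap planted ids (per-species catalogs) to the joint catalog
  remap <- function(gen, pool) {
    own <- motifPatterns(groundTruthCatalog(pool))
    joint <- motifPatterns(catalog)
    jointId <- stats::setNames(names(joint), joint)
    occ <- gen$motifOccurrences
    occ$feature_id <- unname(jointId[own[occ$feature_id]])
    occ
  }
  shared <- universe[assign]
  realized <- length(shared) / length(universe)
  list(setA = genA$set, setB = genB$set,
       occurrencesA = remap(genA, poolA), occurrencesB = remap(genB, poolB),
       catalog = catalog,
       truth = list(poolA = poolA, poolB = poolB, sharedPatterns = shared,
                    plantedSharedFraction = sharedFraction,
                    realizedSharedFraction = realized))
}

## Draw n distinct, mutually non-substring motif patterns (lengths 5-10)
## over a 9-letter motif alphabet disjoint from the spacer alphabet.
.randomMotifUniverse <- function(n, seed) {
  alphabet <- c("G", "P", "Q", "S", "A", "Y", "T", "V", "L")
  withSeed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 100L * n) stop("failed to draw a non-substring motif universe")
      len <- sample(5:10, 1L)
      cand <- paste0(sample(alphabet, len, replace = TRUE), collapse = "")
      clash <- any(vapply(out, function(p) {
        grepl(cand, p, fixed = TRUE) || grepl(p, cand, fixed = TRUE)
      }, logical(1)))
      if (!clash) out <- c(out, cand)
    }
    out
  })
}

#' Truncate a synthetic spidroin into a known fragment category
#'
#' Produces the record a fragmented assembly would yield, together with the
#' fragment category it should be assigned: \code{five_prime} removes the
#' CTD-bearing suffix, \code{three_prime} removes the NTD-bearing prefix,
#' \code{internal_gap} obscures an internal run (>= 10 residues) with X while
#' keeping both termini, and \code{repetitive} keeps a core-only middle
#' slice. Truncation points are sampled at least 50 residues clear of the
#' terminal windows.
#'
#' @param gen result of \link{generateSpidroin}.
#' @param mode one of "five_prime", "three_prime", "internal_gap",
#'   "repetitive".
#' @param seed seed for truncation-point sampling.
#' @return list with \code{record} (modified one-gene \link{SpidroinSet}),
#'   \code{expected} (the expected fragment category label), and
#'   \code{gapEvidence}.
#' @export
truncateForFragments <- function(gen, mode = c("five_prime", "three_prime",
                                               "internal_gap", "repetitive"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  seqs <- residues(gen$record)
  geneId <- names(seqs)
  s <- seqs[[1L]]
  L <- nchar(s)
  nt <- gen$ntdLength
  ctStart <- L - gen$ctdLength
  margin <- 50L
  lo <- nt + margin
  hi <- ctStart - margin
  if (hi - lo < 20L)
    stop(sprintf("sequence too short to truncate in mode '%s'", mode))
  species <- speciesTags(gen$record)[[1L]]
  cls <- classLabels(gen$record)[[1L]]
  mk <- function(newSeq, suffix) {
    SpidroinSet(stats::setNames(newSeq, paste0(geneId, suffix)),
                species = species, classLabel = cls)
  }
  withSeed(deriveSeed(seed, 31L), {
    if (mode == "five_prime") {
      cut <- sampleOne(seq.int(lo, hi))
      list(record = mk(substr(s, 1L, cut), "_5p"),
           expected = "five_prime_end", gapEvidence = FALSE)
    } else if (mode == "three_prime") {
      cut <- sampleOne(seq.int(lo, hi))
      list(record = mk(substr(s, cut + 1L, L), "_3p"),
           expected = "three_prime_end", gapEvidence = FALSE)
    } else if (mode == "internal_gap") {
      run <- sampleOne(10:25)
      if (hi - lo <= run) stop("core too short for an internal gap")
      p <- sampleOne(seq.int(lo, hi - run))
      gapped <- paste0(substr(s, 1L, p), strrep("X", run),
                       substr(s, p + run + 1L, L))
      list(record = mk(gapped, "_gap"), expected = "internal_gap",
           gapEvidence = TRUE)
    } else {
      width <- min(hi - lo, 250L)
      start <- sampleOne(seq.int(lo, hi - width))
      list(record = mk(substr(s, start + 1L, start + width), "_rep"),
           expected = "repetitive", gapEvidence = FALSE)
    }
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' Per target and tissue, replicate Ct values are drawn as
#' \code{baseCt - log2(foldChange) + Normal(0, noiseSd)}; the reference gene
#' is constant across tissues up to the same noise. The calibrator tissue
#' (fold 1) is appended when missing from the fold-change matrix.
#'
#' @param foldChange numeric matrix, targets in rows and tissues in columns
#'   (dimnames required); all entries positive.
#' @param noiseSd replicate noise standard deviation (cycles), >= 0.
#' @param seed master seed.
#' @param nReplicates replicates per well group.
#' @param baseCt nominal target Ct at fold 1 (cycles).
#' @param referenceCt nominal reference-gene Ct (cycles).
#' @param reference,calibrator reference target and calibrator tissue names.
#' @param sample sample identifier.
#' @return a Ct data.frame compatible with \link{relativeQuantities}.
#' @export
generateCtTable <- function(foldChange, noiseSd = 0.2, seed = 1L,
                            nReplicates = 3L, baseCt = 24, referenceCt = 18,
                            reference = "RPL13a", calibrator = "legs",
                            sample = "S1") {
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  if (is.null(dimnames(foldChange)) || is.null(rownames(foldChange)) ||
      is.null(colnames(foldChange)))
    stop("foldChange must have target row names and tissue column names")
  if (any(foldChange <= 0)) stop("fold changes must be positive")
  if (!calibrator %in% colnames(foldChange)) {
    foldChange <- cbind(foldChange,
                        matrix(1, nrow(foldChange), 1L,
                               dimnames = list(NULL, calibrator)))
  }
  targets <- c(rownames(foldChange), reference)
  tissues <- colnames(foldChange)
  grid <- expand.grid(replicate = seq_len(nReplicates), tissue = tissues,
                      target = targets, stringsAsFactors = FALSE)
  mu <- vapply(seq_len(nrow(grid)), function(i) {
    if (grid$target[i] == reference) {
      referenceCt
    } else {
      baseCt - log2(foldChange[grid$target[i], grid$tissue[i]])
    }
  }, numeric(1))
  noise <- withSeed(deriveSeed(seed, 41L), stats::rnorm(nrow(grid), 0, noiseSd))
  data.frame(sample = sample, tissue = grid$tissue, target = grid$target,
             replicate = grid$replicate, ct = mu + noise,
             censored = FALSE, is_nrt = FALSE, stringsAsFactors = FALSE)
}
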