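test_that("a query identical to a library domain self-hits below threshold", {
  lib <- toyLibrary()
  q <- toySet(stats::setNames(defaultGrammar()@ntd, "query1"))
  hits <- localHomologySearch(q, lib)
  expect_equal(nrow(hits[hits$domain_kind == "NTD", ]), 1L)
  ntd <- hits[hits$domain_kind == "NTD", ]
  expect_equal(ntd$start, 0L)
  expect_equal(ntd$end, 100L)
  expect_equal(ntd$class_label, "MaSp")
  expect_lt(ntd$evalue, 1e-6)
})

test_that("local alignment scores match a full dynamic-programming oracle", {
  mat <- silkmotifs:::.blosum62()
  set.seed(202)
  for (rep in 1:12) {
    a <- randomResidues(10L, 3000 + rep)
    b <- if (rep %% 3 == 0) a else randomResidues(10L, 4000 + rep)
    expected <- swOracle(a, b, mat)
    got <- BiocGenerics::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1))
    expect_equal(got, expected, info = sprintf("pair %d", rep))
  }
})

test_that("masked (all-X) queries produce no hits and empty library errors", {
  lib <- toyLibrary()
  q <- toySet(c(masked = strrep("X", 50)))
  expect_equal(nrow(localHomologySearch(q, lib)), 0L)
  expect_error(localHomologySearch(q, "not a library"), "DomainLibrary")
  expect_error(DomainLibrary(character(0), character(0), character(0)),
               "empty")
})

test_that("lowering the E-value threshold never adds hits", {
  g <- defaultGrammar()
  lib <- toyLibrary(g)
  gen <- generateSpidroin(g, seed = 5, geneId = "gM", species = "Cdar")
  thresholds <- c(1e-2, 1e-6, 1e-20, 1e-80)
  nhits <- vapply(thresholds, function(th) {
    nrow(localHomologySearch(gen$record, lib, eThreshold = th))
  }, integer(1))
  expect_true(all(diff(nhits) <= 0))
})

test_that("signature detection finds MAFAS, GPGQQ repeats, and poly-A runs", {
  ss <- toySet(c(anchored = paste0("MAFASGG", strrep("Q", 100)),
                 late = paste0(strrep("Q", 120), "MAFAS"),
                 polya = "AAAAA",
                 gp = strrep("GPGQQ", 4)))
  sig <- detectSignatures(ss)
  expect_equal(sig$mafas_present, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(sig$gpgqq_count[sig$gene_id == "gp"], 4L)
  runs <- polyAlanineRuns(ss)
  expect_equal(runs[runs$gene_id == "polya", c("start", "length")],
               data.frame(start = 0L, length = 5L), ignore_attr = TRUE)
})

test_that("GPGQQ counting equals a naive non-overlapping scan on random input", {
  for (seed in 1:6) {
    set.seed(seed)
    pieces <- sample(c("GPGQQ", "GPG", "QQ", "A", randomResidues(7, seed)),
                     120, replace = TRUE)
    s <- paste0(pieces, collapse = "")
    s <- substr(s, 1, 500)
    ss <- toySet(stats::setNames(s, "r"))
    expect_equal(detectSignatures(ss)$gpgqq_count,
                 length(naiveGreedyStarts("GPGQQ", s)))
  }
})

test_that("fragment categories follow the five-way definition", {
  hits <- data.frame(gene_id = c("g1", "g1", "g2"),
                     domain_kind = c("NTD", "CTD", "CTD"),
                     start = 0L, end = 10L, reference_id = "r",
                     class_label = "MaSp", score = 500, evalue = 1e-60,
                     stringsAsFactors = FALSE)
  ss <- toySet(c(g1 = strrep("GPGQQ", 10), g2 = strrep("GPGQQ", 10)))
  cats <- categorizeFragments(ss, hits)
  expect_equal(cats$category[cats$gene_id == "g1"], "complete")
  expect_equal(cats$category[cats$gene_id == "g2"], "three_prime_end")
  cats2 <- categorizeFragments(ss, hits,
                               gapEvidence = c(g1 = TRUE, g2 = FALSE))
  expect_equal(cats2$category[cats2$gene_id == "g1"], "internal_gap")
  noHits <- hits[0, ]
  cats3 <- categorizeFragments(ss, noHits)
  expect_equal(unique(cats3$category), "repetitive")
  expect_true(all(cats3$repetitive_evidence))
})

test_that("synthetic truncations are categorized perfectly outside terminal windows", {
  g <- defaultGrammar()
  lib <- toyLibrary(g)
  cat <- groundTruthCatalog(g)
  modes <- c("five_prime", "three_prime", "internal_gap", "repetitive")
  n <- 0L
  ok <- 0L
  for (i in 1:10) {
    gen <- generateSpidroin(g, seed = 500 + i, geneId = sprintf("g%d", i),
                            species = "Cdar")
    for (m in modes) {
      tr <- truncateForFragments(gen, m, seed = i)
      hits <- localHomologySearch(tr$record, lib)
      span <- data.frame(gene_id = geneIds(tr$record), start = 0L,
                         end = nchar(residues(tr$record)))
      cov <- motifCoverage(tr$record, paintSequences(tr$record, cat, span))
      got <- categorizeFragments(
        tr$record, hits,
        gapEvidence = stats::setNames(tr$gapEvidence, geneIds(tr$record)),
        motifCoverage = cov)
      n <- n + 1L
      ok <- ok + as.integer(got$category == tr$expected)
    }
  }
  expect_equal(ok, n)
})

test_that("class assignment follows evidence precedence and conflict rules", {
  mk <- function(kinds, labels) {
    n <- length(kinds)
    data.frame(gene_id = rep("g", n), domain_kind = kinds,
               start = rep(0L, n), end = rep(10L, n),
               reference_id = rep("r", n), class_label = labels,
               score = rep(500, n), evalue = rep(1e-50, n),
               stringsAsFactors = FALSE)
  }
  concordant <- assignClass("g", mk(c("NTD", "CTD"), c("FLAG", "FLAG")))
  expect_equal(concordant$class_label, "FLAG")
  expect_setequal(concordant$evidence, c("ntd_homology", "ctd_homology"))

  none <- assignClass("g", mk(character(0), character(0)))
  expect_equal(none$class_label, "unclassified")
  expect_length(none$evidence, 0L)

  conflict <- assignClass("g", mk(c("NTD", "CTD"), c("MaSp", "FLAG")))
  expect_equal(conflict$class_label, "unclassified")
  expect_setequal(conflict$evidence, c("ntd_homology", "ctd_homology"))
  tiebreak <- assignClass("g", mk(c("NTD", "CTD"), c("MaSp", "FLAG")),
                          motifClassVotes = c(MaSp = 3L, FLAG = 1L))
  expect_equal(tiebreak$class_label, "MaSp")

  expr_only <- assignClass("g", mk(character(0), character(0)),
                           expressionClass = "AgSp")
  expect_equal(expr_only$class_label, "AgSp")
  expect_equal(expr_only$evidence, "expression")
})

test_that("gland names map to their namesake classes for expression evidence", {
  expect_equal(glandToClass(c("MA", "FL", "tubuliform")),
               c("MaSp", "FLAG", "TuSp"))
  expect_true(is.na(glandToClass("other_silk")))
  ## top-gland expression feeds assignClass as an evidence source
  rq <- data.frame(sample = "S1", tissue = c("MA", "FL"), target = "spl",
                   rq = c(1, 9), quantifiable = TRUE)
  top <- attr(rankGlands(rq), "top")
  got <- assignClass("spl", data.frame(gene_id = character(0),
                                       domain_kind = character(0),
                                       class_label = character(0)),
                     expressionClass = glandToClass(top))
  expect_equal(got$class_label, "FLAG")
  expect_equal(got$evidence, "expression")
})

test_that("a synthetic MaSp-template gene recovers its class", {
  g <- defaultGrammar("MaSp")
  lib <- toyLibrary(g)
  gen <- generateSpidroin(g, seed = 77, geneId = "gC", species = "Cdar")
  hits <- localHomologySearch(gen$record, lib)
  expect_equal(assignClass("gC", hits)$class_label, "MaSp")
})
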