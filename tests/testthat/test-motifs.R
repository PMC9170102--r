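test_that("terminal masking produces the documented core spans", {
  ss <- toySet(c(long = randomResidues(300, 1),
                 short = randomResidues(150, 2),
                 edge = randomResidues(201, 3)))
  cs <- maskTerminalDomains(ss)
  expect_equal(cs$start, c(100L, 100L, 100L))
  expect_equal(cs$end, c(200L, 100L, 101L))   # short: empty; edge: one residue
  expect_true(all(cs$start <= cs$end))
})

test_that("tandem-repeat cores yield the tandem unit among discovered variants", {
  core <- strrep("GPGPQGPS", 20)
  ss <- toySet(stats::setNames(paste0(randomResidues(100, 4), core,
                                      randomResidues(100, 5)), "tandem"))
  cat <- discoverMotifs(ss)
  expect_true("GPGPQGPS" %in% motifPatterns(cat))
})

test_that("repetition-free cores yield an empty catalog", {
  ## 20 distinct residues: no 4-mer can repeat
  ss <- toySet(stats::setNames(
    paste0(strrep("M", 100), "ACDEFGHIKLNPQRSTVWYM", strrep("W", 100)), "flat"))
  span <- data.frame(gene_id = "flat", start = 100L, end = 120L)
  expect_equal(length(discoverMotifs(ss, span)), 0L)
})

test_that("discovery equals the brute-force substring oracle on random cores", {
  for (seed in 1:6) {
    set.seed(seed)
    ## short cores with planted repetition so candidates exist
    unit <- paste0(sample(c("G", "P", "Q", "A", "S"), 5, TRUE), collapse = "")
    cores <- vapply(1:3, function(i) {
      paste0(randomResidues(15, seed * 10 + i), unit,
             randomResidues(10, seed * 20 + i), unit,
             randomResidues(sample(5:20, 1), seed * 30 + i))
    }, character(1))
    names(cores) <- sprintf("g%d", 1:3)
    full <- vapply(cores, function(s) paste0(strrep("M", 100), s,
                                             strrep("W", 100)), character(1))
    ss <- toySet(full)
    spans <- data.frame(gene_id = names(cores), start = 100L,
                        end = 100L + nchar(cores))
    got <- sort(unname(motifPatterns(discoverMotifs(ss, spans, minLen = 4,
                                                    maxLen = 8))),
                method = "radix")
    expect_equal(got, discoveryOracle(cores, 4L, 8L, 3L),
                 info = sprintf("seed %d", seed))
  }
})

test_that("excluded genes contribute neither to discovery nor painting", {
  g <- defaultGrammar()
  gen <- generateSpidroinSet(g, nGenes = 3, seed = 55)
  drop <- geneIds(gen$set)[1]
  occ <- paintSequences(gen$set, groundTruthCatalog(g), excludeGenes = drop)
  expect_false(drop %in% occ$gene_id)
  full <- discoverMotifs(gen$set)
  reduced <- discoverMotifs(gen$set, excludeGenes = drop)
  expect_lte(sum(variantTable(reduced)$n_occurrences),
             sum(variantTable(full)$n_occurrences))
})

test_that("raising the occurrence threshold never enlarges the catalog", {
  g <- defaultGrammar()
  gen <- generateSpidroinSet(g, nGenes = 3, seed = 8)
  sizes <- vapply(c(2L, 3L, 5L, 8L), function(m) {
    length(discoverMotifs(gen$set, minTotalOccurrences = m))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("painting places tandem GPGPQ copies at 5-residue intervals", {
  core <- strrep("GPGPQ", 3)
  ss <- toySet(stats::setNames(paste0(strrep("M", 100), core,
                                      strrep("W", 100)), "t"))
  cat <- MotifCatalog(data.frame(variant_id = "M0001", pattern = "GPGPQ"))
  occ <- paintSequences(ss, cat)
  expect_equal(occ$start, c(100L, 105L, 110L))
  expect_equal(occ$end - occ$start, rep(5L, 3))
  ## empty catalog paints nothing
  expect_equal(nrow(paintSequences(ss, MotifCatalog(
    data.frame(variant_id = character(0), pattern = character(0))))), 0L)
})

test_that("painting equals a sliding-window oracle, wildcards included", {
  for (seed in 1:6) {
    set.seed(seed)
    cores <- vapply(1:2, function(i) {
      paste0(sample(c("G", "P", "Q", "A", "S", "Y"), 120, TRUE), collapse = "")
    }, character(1))
    names(cores) <- c("g1", "g2")
    full <- vapply(cores, function(s) paste0(strrep("M", 100), s,
                                             strrep("W", 100)), character(1))
    ss <- toySet(full)
    spans <- data.frame(gene_id = names(cores), start = 100L,
                        end = 100L + nchar(cores))
    pats <- c("GPGQ", "xPGQ", "QQxz", "GAGA", "PQSx")
    cat <- MotifCatalog(data.frame(variant_id = sprintf("M%04d", 1:5),
                                   pattern = pats))
    got <- paintSequences(ss, cat, spans)
    expected <- do.call(rbind, lapply(seq_along(pats), function(v) {
      do.call(rbind, lapply(names(cores), function(g) {
        st <- naiveWildcardStarts(pats[v], cores[[g]])
        if (length(st) == 0) return(NULL)
        data.frame(gene_id = g, feature_id = sprintf("M%04d", v),
                   start = 100L + st - 1L)
      }))
    }))
    gotKey <- sort(paste(got$gene_id, got$feature_id, got$start))
    expKey <- if (is.null(expected)) character(0) else
      sort(paste(expected$gene_id, expected$feature_id, expected$start))
    expect_equal(gotKey, expKey, info = sprintf("seed %d", seed))
  }
})

test_that("no painted occurrence intersects a masked terminal window", {
  g <- defaultGrammar()
  gen <- generateSpidroinSet(g, nGenes = 4, seed = 21)
  spans <- maskTerminalDomains(gen$set)
  occ <- paintSequences(gen$set, discoverMotifs(gen$set, spans), spans)
  lims <- merge(occ, spans, by = "gene_id", suffixes = c("", "_core"))
  expect_true(all(lims$start >= lims$start_core & lims$end <= lims$end_core))
  ## per-variant occurrences within one gene never overlap
  byVariant <- split(occ, paste(occ$gene_id, occ$feature_id))
  overlaps <- vapply(byVariant, function(o) {
    o <- o[order(o$start), ]
    nrow(o) > 1 && any(o$start[-1] < o$end[-nrow(o)])
  }, logical(1))
  expect_false(any(overlaps))
})

test_that("grouping is a partition with composition-driven membership", {
  cat <- MotifCatalog(data.frame(
    variant_id = sprintf("M%04d", 1:6),
    pattern = c("GYGGQ", "GGYG", "AAAAAAA", "SVSVVSTT", "WHKFMNDE", "CCCW")))
  grp <- groupMotifs(cat)
  v <- variantTable(grp$catalog)
  ## glycine-rich motifs co-group regardless of edit distance
  expect_equal(v$group_id[v$pattern == "GYGGQ"],
               v$group_id[v$pattern == "GGYG"])
  expect_equal(v$group_id[v$pattern == "AAAAAAA"], "poly_A")
  expect_equal(v$group_id[v$pattern == "SVSVVSTT"], "ser_thr_val_rich")
  ## dissimilar leftovers are unassigned, and every variant has one home
  expect_equal(v$group_id[v$pattern == "CCCW"], "unassigned")
  expect_true(all(table(v$variant_id) == 1L))
  expect_false(any(is.na(v$group_id)))
})

test_that("identical patterns land in the same group and subgroup", {
  cat <- MotifCatalog(data.frame(variant_id = c("M0001", "M0002"),
                                 pattern = c("WHKFMNDE", "WHKFMNDE")))
  v <- variantTable(groupMotifs(cat)$catalog)
  expect_equal(v$group_id[1], v$group_id[2])
  expect_equal(v$subgroup_id[1], v$subgroup_id[2])
})

test_that("wildcard collapse merges single-position families to a fixpoint", {
  expect_equal(collapsePatterns(c("APGPQ", "GPGPQ", "SPGPQ")), "xPGPQ")
  expect_equal(collapsePatterns("GGSGGGL"), "GGSGGGL")
  ## two independent wildcard positions use x then z
  expect_equal(collapsePatterns(c("DTASYATGEY", "DTCSYATGEY",
                                  "DTASYCTGEY", "DTCSYCTGEY")),
               "DTxSYzTGEY")
  ## idempotence
  for (seed in 1:4) {
    set.seed(seed)
    pats <- replicate(6, paste0(sample(c("G", "P", "Q", "A"), 5, TRUE),
                                collapse = ""))
    once <- collapsePatterns(pats)
    expect_equal(collapsePatterns(once), once)
    expect_lte(length(once), length(unique(pats)))
  }
})

test_that("collapsed description count never exceeds the variant count", {
  g <- defaultGrammar()
  gen <- generateSpidroinSet(g, nGenes = 4, seed = 31)
  cat <- discoverMotifs(gen$set)
  grp <- groupMotifs(cat)
  collapsed <- collapseVariantDescriptions(grp)
  expect_lte(nrow(collapsed), length(cat))
  expect_true(all(nchar(collapsed$description) >= 4L))
})

test_that("occurrence totals are conserved between catalog and table", {
  g <- defaultGrammar()
  gen <- generateSpidroinSet(g, nGenes = 3, seed = 13)
  spans <- maskTerminalDomains(gen$set)
  cat <- discoverMotifs(gen$set, spans)
  occ <- paintSequences(gen$set, cat, spans)
  perVariant <- table(occ$feature_id)
  expect_equal(sum(perVariant), nrow(occ))
  ## every catalog variant that was discovered has >= the discovery threshold
  expect_true(all(variantTable(cat)$n_occurrences >= 3L))
})
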