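mkOcc <- function(starts, ends, ids, gene = "g1", species = "Cdar") {
  data.frame(species = species, gene_id = gene, feature_kind = "motif",
             feature_id = ids, start = as.integer(starts),
             end = as.integer(ends), stringsAsFactors = FALSE)
}

test_that("the 20-residue gap boundary separates cassette from no cassette", {
  at20 <- rbind(mkOcc(c(0, 25), c(5, 30), c("M0001", "M0002")),
                mkOcc(c(100, 125), c(105, 130), c("M0001", "M0002"),
                      gene = "g2"))
  det <- detectCassettes(at20, maxGap = 20)
  expect_equal(nrow(det$occurrences), 2L)
  expect_equal(det$types$n_components, 2L)

  at21 <- rbind(mkOcc(c(0, 26), c(5, 31), c("M0001", "M0002")),
                mkOcc(c(100, 126), c(105, 131), c("M0001", "M0002"),
                      gene = "g2"))
  expect_equal(nrow(detectCassettes(at21, maxGap = 20)$occurrences), 0L)
  expect_error(detectCassettes(at20, minComponents = 1L), "at least 2")
})

test_that("a repeated poly-A + GPGPQ adjacency becomes a cassette type", {
  cat <- MotifCatalog(data.frame(variant_id = c("M0001", "M0002"),
                                 pattern = c("AAAAAAA", "GPGPQ")))
  occ <- rbind(mkOcc(c(0, 7), c(7, 12), c("M0001", "M0002")),
               mkOcc(c(50, 57), c(57, 62), c("M0001", "M0002")))
  det <- detectCassettes(occ, catalog = cat)
  expect_equal(det$types$components, "M0001+M0002")
  expect_equal(det$types$support, 2L)
  expect_equal(det$types$description, "AAAAAAAGPGPQ")   # gap 0: no spacer mark
})

test_that("descriptions mark spacer junctions with an underscore", {
  occ <- rbind(mkOcc(c(0, 10), c(5, 15), c("M0001", "M0002")),
               mkOcc(c(50, 60), c(55, 65), c("M0001", "M0002")))
  cat <- MotifCatalog(data.frame(variant_id = c("M0001", "M0002"),
                                 pattern = c("GGXGG", "GGAGG")))
  det <- detectCassettes(occ, catalog = cat)
  expect_equal(det$types$description, "GGXGG_GGAGG")
})

test_that("detection equals an exhaustive chain-enumeration oracle", {
  for (seed in 1:8) {
    occ <- randomOccurrenceList(n = sample(5:30, 1), seed = 900 + seed)
    det <- detectCassettes(occ, minTypeSupport = 1L)
    windows <- chainOracle(occ)
    expKeys <- sort(vapply(windows, function(w) {
      paste(w$start[1], w$end[nrow(w)], paste(w$feature_id, collapse = "+"))
    }, character(1)))
    gotKeys <- sort(paste(det$occurrences$start, det$occurrences$end,
                          det$occurrences$components))
    expect_equal(gotKeys, expKeys, info = sprintf("seed %d", seed))
  }
})

test_that("relaxing the gap limit never silences a cassette-bearing gene", {
  ## merging chains under a larger gap can fuse two cassettes into one, so
  ## the occurrence count itself is not monotone; what is monotone is the
  ## set of genes carrying at least one cassette
  for (seed in 1:5) {
    genes <- lapply(1:4, function(k) {
      randomOccurrenceList(n = sample(4:12, 1), seed = seed * 50 + k,
                           gene = sprintf("g%d", k))
    })
    occ <- do.call(rbind, genes)
    withCassette <- lapply(c(5L, 10L, 20L, 40L), function(g) {
      unique(detectCassettes(occ, maxGap = g,
                             minTypeSupport = 1L)$occurrences$gene_id)
    })
    for (i in seq_len(length(withCassette) - 1L)) {
      expect_true(all(withCassette[[i]] %in% withCassette[[i + 1L]]),
                  info = sprintf("seed %d step %d", seed, i))
    }
  }
})

test_that("cassette components reference existing motif occurrences, unshared", {
  g <- defaultGrammar()
  gen <- generateSpidroinSet(g, nGenes = 4, seed = 44)
  painted <- paintSequences(gen$set, groundTruthCatalog(g))
  det <- detectCassettes(painted)
  motifKeys <- paste(det$occurrences$gene_id, det$occurrences$component_starts)
  for (i in seq_len(nrow(det$occurrences))) {
    starts <- as.integer(strsplit(det$occurrences$component_starts[i],
                                  ",")[[1]])
    comps <- strsplit(det$occurrences$components[i], "+", fixed = TRUE)[[1]]
    for (k in seq_along(starts)) {
      expect_true(any(painted$gene_id == det$occurrences$gene_id[i] &
                        painted$feature_id == comps[k] &
                        painted$start == starts[k]))
    }
  }
  ## no motif occurrence serves two cassettes
  usage <- unlist(lapply(seq_len(nrow(det$occurrences)), function(i) {
    paste(det$occurrences$gene_id[i],
          strsplit(det$occurrences$component_starts[i], ",")[[1]])
  }))
  expect_false(any(duplicated(usage)))
})

test_that("cassette grouping partitions types by component group tuples", {
  cat <- MotifCatalog(data.frame(variant_id = c("M0001", "M0002", "M0003"),
                                 pattern = c("APGPQ", "SPGPQ", "AAAAAAA")))
  grp <- groupMotifs(cat)
  occ <- rbind(mkOcc(c(0, 10), c(5, 15), c("M0001", "M0001")),
               mkOcc(c(40, 50), c(45, 55), c("M0001", "M0001")),
               mkOcc(c(100, 110), c(105, 115), c("M0002", "M0001")),
               mkOcc(c(140, 150), c(145, 155), c("M0002", "M0001")),
               mkOcc(c(200, 210), c(207, 215), c("M0003", "M0001")),
               mkOcc(c(240, 250), c(247, 255), c("M0003", "M0001")))
  det <- detectCassettes(occ, catalog = cat)
  cg <- groupCassettes(det$types, det$occurrences, grp)
  expect_equal(length(unique(cg$types$group_id)),
               nrow(cg$groups))
  ## co-grouped components (APGPQ / SPGPQ are both Gln/Pro-rich) share a group
  t1 <- cg$types$group_id[cg$types$components == "M0001+M0001"]
  t2 <- cg$types$group_id[cg$types$components == "M0002+M0001"]
  t3 <- cg$types$group_id[cg$types$components == "M0003+M0001"]
  expect_equal(t1, t2)
  expect_false(t1 == t3)
  ## partition: every type in exactly one group
  expect_equal(sum(cg$groups$n_types), nrow(cg$types))
})

test_that("curation accounts for every occurrence and enforces support", {
  spans <- data.frame(gene_id = c("g1", "g2"), start = 0L, end = 60L)
  occ <- rbind(mkOcc(c(0, 10), c(5, 15), c("M0001", "M0002")),
               mkOcc(c(40, 50), c(45, 55), c("M0001", "M0002")),
               mkOcc(c(50, 58), c(55, 63), c("M0001", "M0002"), gene = "g2"))
  det <- detectCassettes(occ, minTypeSupport = 2L)
  expect_equal(nrow(det$occurrences), 3L)
  cur <- curateCassettes(det$types, det$occurrences, spans)
  ## the g2 occurrence straddles the core end and is removed
  expect_equal(nrow(cur$occurrences) + nrow(cur$removedOccurrences),
               nrow(det$occurrences))
  expect_false("g2" %in% cur$occurrences$gene_id)
  expect_equal(cur$types$support, 2L)

  ## a type at minimum support losing one occurrence disappears entirely
  spans2 <- data.frame(gene_id = c("g1", "g2"), start = 0L, end = 20L)
  cur2 <- curateCassettes(det$types, det$occurrences, spans2)
  expect_equal(nrow(cur2$types), 0L)
  expect_equal(nrow(cur2$occurrences), 0L)
  expect_equal(nrow(cur2$removedOccurrences), 3L)
})

test_that("planted cassettes are recovered completely from painted motifs", {
  g <- defaultGrammar()
  gen <- generateSpidroinSet(g, nGenes = 5, seed = 99)
  painted <- paintSequences(gen$set, groundTruthCatalog(g))
  det <- detectCassettes(painted)
  planted <- gen$cassetteOccurrences
  plantedKeys <- paste(planted$gene_id, planted$start, planted$end,
                       planted$feature_id)
  detKeys <- paste(det$occurrences$gene_id, det$occurrences$start,
                   det$occurrences$end, det$occurrences$components)
  expect_true(all(plantedKeys %in% detKeys))
  expect_equal(nrow(det$occurrences), nrow(planted))
})
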