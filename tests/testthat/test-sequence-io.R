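test_that("protein FASTA parsing handles empty, plain, and decorated input", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_equal(nGenes(readProteinFasta(empty, species = "Cdar")), 0L)

  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">gA", "MAFASAAAA", ">gB some description", "gpgpqgps*"), f)
  ss <- readProteinFasta(f, species = "Cdar")
  expect_equal(geneIds(ss), c("gA", "gB"))
  expect_equal(unname(residues(ss)), c("MAFASAAAA", "GPGPQGPS"))
  expect_equal(unname(speciesTags(ss)), c("Cdar", "Cdar"))

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">gC", "MAFA8AA"), bad)
  expect_error(readProteinFasta(bad, species = "Cdar"), "gC.*position 5")
})

test_that("FASTA write-then-read round-trips randomized record sets", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(1:6, 1)
    seqs <- vapply(seq_len(n), function(i) randomResidues(sample(20:200, 1),
                                                          seed * 100 + i),
                   character(1))
    names(seqs) <- sprintf("gene_%d_%d", seed, seq_len(n))
    ss <- toySet(seqs)
    f <- withr::local_tempfile(fileext = ".fasta")
    writeProteinFasta(ss, f)
    back <- readProteinFasta(f, species = "Cdar")
    expect_equal(residues(back), residues(ss))
    expect_equal(geneIds(back), geneIds(ss))
  }
})

test_that("SpidroinSet enforces residue alphabet and id uniqueness", {
  expect_error(SpidroinSet(c(g1 = "MAFAB"), species = "Cdar"), "alphabet")
  expect_error(SpidroinSet(c(g1 = "MAFAS", g1 = "GPGQQ"), species = "Cdar"),
               "duplicated")
  ## same gene id under two species tags is a valid joint dataset
  joint <- combineSpidroinSets(SpidroinSet(c(g1 = "MAFAS"), species = "Cdar"),
                               SpidroinSet(c(g1 = "MAFAS"), species = "Tcla"))
  expect_equal(nGenes(joint), 2L)
})

test_that("occurrence tables round-trip exactly and sort deterministically", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeOccurrenceTable(occurrenceTable(), f)
  expect_equal(nrow(readOccurrenceTable(f)), 0L)

  tab <- occurrenceTable(
    species = c("Tcla", "Cdar", "Cdar"),
    gene_id = c("gB", "gA", "gA"),
    feature_kind = "motif",
    feature_id = c("M0002", "M0002", "M0001"),
    start = c(10L, 30L, 5L), end = c(15L, 35L, 9L))
  writeOccurrenceTable(tab, f)
  back <- readOccurrenceTable(f)
  expect_equal(back$gene_id, c("gA", "gA", "gB"))
  expect_equal(back$start, c(5L, 30L, 10L))
  ## permuting rows does not change the written file
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeOccurrenceTable(tab[c(3, 1, 2), ], f2)
  expect_identical(readLines(f), readLines(f2))

  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(1:20, 1)
    starts <- sample.int(500, n)
    tab <- occurrenceTable(species = sample(c("Cdar", "Tcla"), n, TRUE),
                           gene_id = sample(sprintf("g%d", 1:4), n, TRUE),
                           feature_kind = sample(c("motif", "cassette"), n, TRUE),
                           feature_id = sprintf("M%04d", sample.int(9, n, TRUE)),
                           start = starts, end = starts + sample.int(30, n, TRUE))
    f3 <- withr::local_tempfile(fileext = ".tsv")
    writeOccurrenceTable(tab, f3)
    back <- readOccurrenceTable(f3)
    ## write-read is idempotent byte-for-byte, and no row is lost
    f4 <- withr::local_tempfile(fileext = ".tsv")
    writeOccurrenceTable(back, f4)
    expect_identical(readLines(f3), readLines(f4))
    expect_setequal(do.call(paste, back), do.call(paste, tab))
  }
})

test_that("occurrence validation rejects bad coordinates, naming the row", {
  tab <- data.frame(species = "Cdar", gene_id = "gA", feature_kind = "motif",
                    feature_id = "M0001", start = 5L, end = 5L)
  expect_error(validateOccurrences(tab), "start < end")
  tab$end <- 50L
  genes <- toySet(c(gA = "MAFASAAAA"))
  expect_error(validateOccurrences(tab, genes = genes), "exceeds gene 'gA'")
  expect_error(validateOccurrences(tab[, -1]), "missing column")
})

test_that("display coordinates are 1-based closed, adding exactly (+1, 0)", {
  tab <- occurrenceTable(species = "Cdar", gene_id = "g", feature_kind = "motif",
                         feature_id = "M0001", start = 0L, end = 5L)
  disp <- toDisplayCoordinates(tab)
  expect_equal(disp$start1, 1L)
  expect_equal(disp$end1, 5L)
})

test_that("Ct tables parse censored wells and group replicates stably", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\ttissue\ttarget\treplicate\tct",
               "S1\tMA\tMaSp1\t1\t20.0",
               "S1\tMA\tMaSp1\t2\t20.5",
               "S1\tMA\tMaSp1\t3\t21.0",
               "S1\tFL\tMaSp1\t1\tUndetermined",
               "S1\tFL\tMaSp1\t2\t"), f)
  ct <- readCtTable(f)
  expect_equal(sum(ct$censored), 2L)
  agg <- aggregateReplicates(ct)
  expect_equal(agg$mean_ct[agg$tissue == "MA"], 20.5)
  expect_true(agg$censored[agg$tissue == "FL"])

  ## shuffled input rows yield identical grouped records
  shuffled <- ct[sample(nrow(ct)), ]
  expect_equal(aggregateReplicates(shuffled), agg)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\ttissue\ttarget\tct", "S1\tMA\tMaSp1\t20"), bad)
  expect_error(readCtTable(bad), "expected schema")
})

test_that("Ct tables round-trip through write/read including censoring", {
  fc <- matrix(c(4, 1), 1, 2, dimnames = list("t1", c("MA", "legs")))
  ct <- generateCtTable(fc, noiseSd = 0.3, seed = 11)
  ct$censored[1] <- TRUE
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCtTable(ct, f)
  back <- readCtTable(f)
  expect_equal(back$censored, ct$censored)
  expect_equal(back$ct[!back$censored], ct$ct[!ct$censored], tolerance = 1e-12)
})
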