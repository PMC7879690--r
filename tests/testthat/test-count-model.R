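test_that("count tables default to column-sum totals and round-trip through TSV", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig_id\tL1\tL2", "c1\t1\t2", "c2\t3\t4"), tsv)
  tcs <- readCountTable(tsv)
  expect_identical(unname(libraryTotals(tcs)), c(4, 6))
  expect_identical(rownames(tcs), c("c1", "c2"))

  sim <- simulateAbscissionExperiment(nGenes = c(az_specific_up = 5,
                                                 null = 5), seed = 3)
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("counts.tsv", "totals.tsv", "lengths.tsv",
                            "samples.tsv"))
  writeCountTable(sim$natural, paths[1], totalsPath = paths[2],
                  lengthsPath = paths[3], samplePath = paths[4])
  back <- readCountTable(paths[1], totalsPath = paths[2],
                         lengthsPath = paths[3], samplePath = paths[4])
  expect_identical(counts(back), counts(sim$natural))
  expect_identical(libraryTotals(back), libraryTotals(sim$natural))
  expect_identical(transcriptLengths(back), transcriptLengths(sim$natural))

  # byte-level idempotence of re-serialization
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeCountTable(back, p2)
  expect_identical(readLines(p2), readLines(paths[1]))
})

test_that("malformed count files and invalid tables are rejected", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig_id\tL1", "c1\t-1"), bad)
  expect_error(readCountTable(bad), "c1.*L1")
  writeLines(c("contig_id\tL1", "c1\t1.5"), bad)
  expect_error(readCountTable(bad), "not a non-negative integer")
  writeLines(c("contig_id\tL1", "c1\t1", "c1\t2"), bad)
  expect_error(readCountTable(bad), "duplicate contig id")

  m <- matrix(5L, 2, 2, dimnames = list(c("a", "b"), c("L1", "L2")))
  expect_error(TagCountSet(m, libraryTotals = c(L1 = 3, L2 = 20)),
               ">= column sums")
  expect_error(TagCountSet(m, lengths = c(a = 0L, b = 100L)),
               "lengths")
  expect_error(TagCountSet(matrix(5L, 2, 2,
                                  dimnames = list(c("a", "b"),
                                                  c("L1", "L1")))),
               "duplicate library")
})

test_that("rpkm follows count*1e9/(length*total), is depth-scale invariant, and conserves abundance", {
  m <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "L1"))
  tcs <- TagCountSet(m, libraryTotals = c(L1 = 1e6),
                     lengths = c(g1 = 1000L, g2 = 500L))
  expect_equal(rpkm(tcs, "g1", "L1"), 10)
  expect_equal(rpkm(tcs, "g2", "L1"), 0)

  sim <- simulateAbscissionExperiment(nGenes = c(az_specific_up = 10,
                                                 null = 20), seed = 11)
  nat <- sim$natural
  # scale invariance: multiplying counts and totals by 7 leaves RPKM fixed
  scaled <- TagCountSet(counts(nat) * 7L, libraryTotals = libraryTotals(nat) * 7,
                        lengths = transcriptLengths(nat),
                        sampleData = as.data.frame(colData(nat)))
  expect_equal(rpkm(scaled), rpkm(nat), tolerance = 1e-12)

  # conservation: sum(rpkm * length) = 1e9 * colsum / total per library
  r <- rpkm(nat)
  len <- as.numeric(transcriptLengths(nat))
  lhs <- colSums(r * len)
  rhs <- 1e9 * colSums(counts(nat)) / libraryTotals(nat)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  selfnorm <- TagCountSet(counts(nat), lengths = transcriptLengths(nat))
  expect_equal(unname(colSums(rpkm(selfnorm) * len)), rep(1e9, 3),
               tolerance = 1e-12)
  expect_error(rpkm(TagCountSet(m)), "lengths")
})

test_that("expression profiles are ordered by time or stage and need >= 2 libraries", {
  sim <- simulateAbscissionExperiment(nGenes = c(az_specific_up = 3,
                                                 null = 3), seed = 5)
  pe <- expressionProfile(sim$ethylene, "gene0001", tissue = "AZ",
                          treatment = "ethylene", stageDap = 150)
  expect_named(pe, c("0h", "3h", "6h", "9h", "12h"))
  cpmv <- countsPerMillion(sim$ethylene)["gene0001",
                                         paste0("AZ150_", c(0, 3, 6, 9, 12),
                                                "h")]
  expect_equal(unname(pe), unname(cpmv))

  pn <- expressionProfile(sim$natural, "gene0001", tissue = "AZ",
                          treatment = "field")
  expect_named(pn, c("30DAP", "120DAP", "160DAP"))
  expect_equal(unname(pn),
               unname(rpkm(sim$natural)["gene0001", ]))

  expect_error(expressionProfile(sim$ethylene, "gene0001", tissue = "M",
                                 treatment = "ethylene", stageDap = 150),
               "at least 2")
})
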