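test_that("stage 1 retains genes the exact test calls against the 0 h control", {
  az150 <- rbind(induced = c(5L, 5L, 5L, 5L, 200L),
                 steady = c(50L, 50L, 50L, 50L, 55L),
                 silent = c(0L, 0L, 0L, 0L, 0L))
  x <- make_ethylene_set(az150, total = 1e5)
  s1 <- stage1EthyleneDegs(x)
  expect_identical(s1$degs, "induced")

  # adjusted p at 12 h agrees with the summation oracle times the family size
  row <- s1$tests[s1$tests$contig_id == "induced" & s1$tests$time_h == 12, ]
  expect_equal(row$p_adj,
               min(1, 3 * ac_pvalue_sum(5, 200, 1e5, 1e5)),
               tolerance = 1e-10)
  expect_lt(row$p_adj, 0.01)
  row2 <- s1$tests[s1$tests$contig_id == "steady" & s1$tests$time_h == 12, ]
  expect_gt(row2$p_adj, 0.5)

  # missing 0 h control is an error
  x0 <- x[, colnames(x) != "AZ150_0h"]
  expect_error(stage1EthyleneDegs(x0), "0 h control")

  # an empty table yields an empty DEG set, not an error
  empty <- x[integer(0), ]
  s1e <- stage1EthyleneDegs(empty)
  expect_identical(s1e$degs, character(0))
  expect_identical(nrow(s1e$tests), 0L)
})

test_that("stage 2 requires significance against both comparator tissues in one direction", {
  # az_only differs from both comparators at 6 h; p_only matches AZ30
  az150 <- rbind(az_only = c(5L, 5L, 300L, 5L, 5L),
                 p_only = c(5L, 5L, 300L, 5L, 5L))
  az30 <- rbind(az_only = c(5L, 5L, 4L, 5L),
                p_only = c(5L, 5L, 300L, 5L))
  p150 <- rbind(az_only = c(5L, 5L, 5L, 5L),
                p_only = c(5L, 5L, 5L, 5L))
  x <- make_ethylene_set(az150, az30, p150, total = 1e5)
  s2 <- stage2TissueFilter(c("az_only", "p_only"), x)
  expect_identical(s2$candidates, "az_only")
  expect_identical(stage2TissueFilter(character(0), x)$candidates,
                   character(0))
})

test_that("stage 4 keeps candidates whose natural profile moves the same way", {
  nat <- make_natural_set(rbind(up_good = c(1L, 2L, 40L),
                                up_flat = c(10L, 11L, 9L),
                                dn_good = c(50L, 40L, 2L)))
  dirs <- data.frame(contig_id = c("up_good", "up_flat", "dn_good"),
                     direction = c("up", "up", "down"),
                     net = c(5, 5, -5))
  s4 <- stage4Concordance(c("up_good", "up_flat", "dn_good"), dirs, nat)
  expect_identical(s4$finalUp, "up_good")
  expect_identical(s4$finalDown, "dn_good")
  expect_identical(
    s4$naturalCalls$natural_direction,
    c("up", "flat", "down"))

  # transient candidates need a non-flat natural call matching their net sign
  dirs$direction <- "transient"
  s4t <- stage4Concordance(c("up_good", "up_flat", "dn_good"), dirs, nat)
  expect_identical(s4t$finalUp, "up_good")
  expect_identical(s4t$finalDown, "dn_good")

  # candidates absent from the natural table are excluded but logged
  expect_message(
    s4m <- stage4Concordance(c("up_good", "ghost"),
                             rbind(dirs[1, ],
                                   data.frame(contig_id = "ghost",
                                              direction = "up", net = 1)),
                             nat),
    "absent")
  expect_false("ghost" %in% s4m$finalUp)
  expect_false(s4m$naturalCalls$resolved[2])
})

test_that("planted AZ-specific genes at decisive depth are recovered and shared responders are not", {
  sim <- simulateAbscissionExperiment(
    nGenes = c(az_specific_up = 20, null = 30), libraryTotal = 1e8,
    seed = 2)
  res <- runScreen(sim$ethylene, sim$natural)
  planted <- sim$truth$contig_id[sim$truth$label == "az_specific_up"]
  expect_setequal(finalUp(res), planted)
  expect_length(finalDown(res), 0)

  shared <- simulateAbscissionExperiment(
    nGenes = c(shared_responsive = 30), libraryTotal = 1e8, seed = 2)
  res_sh <- runScreen(shared$ethylene, shared$natural)
  expect_length(finalUp(res_sh), 0)
  expect_length(finalDown(res_sh), 0)
})

test_that("the funnel nests and grows monotonically with alpha", {
  for (seed in 1:3) {
    sim <- simulateAbscissionExperiment(
      nGenes = c(az_specific_up = 10, az_specific_down = 10,
                 az_transient = 10, shared_responsive = 10,
                 natural_discordant = 10, null = 40), seed = seed)
    res <- runScreen(sim$ethylene, sim$natural)
    expect_true(all(stage2Candidates(res) %in% stage1Degs(res)))
    expect_true(all(c(finalUp(res), finalDown(res)) %in%
                      stage2Candidates(res)))
    expect_length(intersect(finalUp(res), finalDown(res)), 0)

    loose <- runScreen(sim$ethylene, sim$natural,
                       ScreenConfig(alpha = 0.05))
    expect_true(all(stage1Degs(res) %in% stage1Degs(loose)))
    expect_true(all(stage2Candidates(res) %in% stage2Candidates(loose)))
  }
})

test_that("identical inputs produce byte-identical reports", {
  sim <- simulateAbscissionExperiment(
    nGenes = c(az_specific_up = 10, null = 20), seed = 9)
  res1 <- runScreen(sim$ethylene, sim$natural)
  res2 <- runScreen(sim$ethylene, sim$natural)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ann <- setNames(rep(c("metabolism", "stress"), 15),
                  sim$truth$contig_id)
  writeScreenResult(res1, d1, annotation = ann)
  writeScreenResult(res2, d2, annotation = ann)
  files <- list.files(d1)
  expect_true(length(files) >= 5)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("functional-class tallies count final candidates with an unknown fallback", {
  ann <- c(a = "metabolism", b = "metabolism", c = "stress")
  expect_identical(summarizeClasses(c("a", "b", "c"), ann),
                   c(metabolism = 2L, stress = 1L))
  expect_identical(summarizeClasses(character(0), ann),
                   setNames(integer(0), character(0)))
  tal <- summarizeClasses(c("a", "b", "c", "x", "y"), ann)
  expect_identical(tal[["unknown"]], 2L)
})
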