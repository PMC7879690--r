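test_that("generation is seeded, reproducible, and leaves the caller's RNG intact", {
  s1 <- simulateAbscissionExperiment(nGenes = c(az_specific_up = 5,
                                                null = 5), seed = 4)
  s2 <- simulateAbscissionExperiment(nGenes = c(az_specific_up = 5,
                                                null = 5), seed = 4)
  expect_identical(counts(s1$ethylene), counts(s2$ethylene))
  expect_identical(counts(s1$natural), counts(s2$natural))
  expect_identical(transcriptLengths(s1$natural),
                   transcriptLengths(s2$natural))
  s3 <- simulateAbscissionExperiment(nGenes = c(az_specific_up = 5,
                                                null = 5), seed = 5)
  expect_false(identical(counts(s1$ethylene), counts(s3$ethylene)))
  expect_error(simulateAbscissionExperiment(nGenes = c(null = 5)),
               "seed")

  set.seed(99); before <- .Random.seed
  simulateAbscissionExperiment(nGenes = c(null = 5), seed = 1)
  expect_identical(.Random.seed, before)
})

test_that("labels, abundances and design cells follow the configuration", {
  ng <- c(az_specific_up = 7, az_specific_down = 3, az_transient = 4,
          shared_responsive = 2, natural_discordant = 5, null = 6)
  sim <- simulateAbscissionExperiment(nGenes = ng, seed = 8)
  expect_identical(unname(c(table(sim$truth$label)[names(ng)])),
                   unname(as.integer(ng)))
  expect_true(all(sim$truth$pi > 0))
  len <- transcriptLengths(sim$natural)
  expect_true(all(len >= 500 & len <= 3000))

  cd <- as.data.frame(SummarizedExperiment::colData(sim$ethylene))
  expect_equal(sum(cd$tissue == "AZ" & cd$stage_dap == 150), 5)
  expect_equal(sum(cd$tissue == "AZ" & cd$stage_dap == 30), 4)
  expect_equal(sum(cd$tissue == "P"), 4)
  expect_identical(colnames(sim$natural),
                   c("AZ_30DAP", "AZ_120DAP", "AZ_160DAP"))
  expect_error(simulateAbscissionExperiment(nGenes = c(weird = 3),
                                            seed = 1), "labels")
  expect_error(simulateAbscissionExperiment(nGenes = c(null = 3),
                                            libraryTotal = 100, seed = 1),
               "1e4")
})

test_that("column sums concentrate around their expected totals", {
  sim <- simulateAbscissionExperiment(seed = 12)
  for (arm in c("ethylene", "natural")) {
    exp_tot <- colSums(sim$expected[[arm]])
    obs_tot <- colSums(counts(sim[[arm]]))
    expect_true(all(abs(obs_tot - exp_tot) <= 4 * sqrt(exp_tot)))
  }
})

test_that("planted fold trajectories scale expected and sampled counts", {
  ng <- c(az_specific_up = 30)
  one <- simulateAbscissionExperiment(nGenes = ng, seed = 1)
  mu <- one$expected$ethylene
  expect_equal(mu[, "AZ150_12h"], 8 * mu[, "AZ150_0h"], tolerance = 1e-12)
  expect_equal(mu[, "AZ150_6h"], 8 * mu[, "AZ150_0h"], tolerance = 1e-12)
  expect_equal(mu[, "AZ150_3h"], sqrt(8) * mu[, "AZ150_0h"],
               tolerance = 1e-12)
  expect_equal(mu[, "AZ30_9h"], mu[, "AZ30_0h"], tolerance = 1e-12)
  expect_equal(one$expected$natural[, "AZ_160DAP"],
               8 * one$expected$natural[, "AZ_30DAP"], tolerance = 1e-12)

  # sampled 12 h counts match their Poisson means within 3 SE over 200 draws
  draws <- vapply(1:200, function(s) {
    sim <- simulateAbscissionExperiment(nGenes = ng, seed = 1000 + s)
    c(obs = sum(counts(sim$ethylene)[, "AZ150_12h"]),
      mu = sum(sim$expected$ethylene[, "AZ150_12h"]))
  }, numeric(2))
  se <- sqrt(sum(draws["mu", ])) / 200   # Poisson: var(obs | mu) = mu
  expect_lt(abs(mean(draws["obs", ] - draws["mu", ])), 3 * se)
})

test_that("a fold-1 design is statistically null for the exact test", {
  sim <- simulateAbscissionExperiment(
    nGenes = c(az_specific_up = 500, shared_responsive = 500, null = 1000),
    fold = 1, seed = 6)
  cnt <- counts(sim$ethylene)
  tot <- libraryTotals(sim$ethylene)
  pv <- unlist(lapply(paste0("AZ150_", c(3, 6, 9, 12), "h"), function(l)
    acPvalue(cnt[, "AZ150_0h"], cnt[, l], tot[["AZ150_0h"]], tot[[l]])))
  expect_lte(mean(pv <= 0.05), 0.06)
})

test_that("dilution-series generation follows the standard-curve model", {
  s <- generateDilutionSeries(2, noiseSd = 0, seed = 1)
  mean_cq <- tapply(s$cq, s$dilution_factor, mean)
  expect_equal(as.numeric(diff(mean_cq)), rep(log2(5), 4),
               tolerance = 1e-10)
  s2 <- generateDilutionSeries(2, noiseSd = 0.3, seed = 2)
  s3 <- generateDilutionSeries(2, noiseSd = 0.3, seed = 2)
  expect_identical(s2, s3)
  expect_error(generateDilutionSeries(1, seed = 1), "\\(1, 2.5\\]")
  expect_error(generateDilutionSeries(2, noiseSd = 0.1), "seed")
})
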