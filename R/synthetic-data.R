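.LABELS <- c("az_specific_up", "az_specific_down", "az_transient",
             "shared_responsive", "natural_discordant", "null")

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Simulate a multi-scale abscission count experiment with planted effects
#'
#' Generates the two arms of the screen design — an ethylene arm (ripe-AZ
#' series at 0, 3, 6, 9, 12 h plus immature-AZ and ripe-pedicel comparator
#' series at 0, 3, 6, 9 h) and a natural arm (field AZ libraries at 30, 120
#' and 160 days after pollination, with transcript lengths) — together with
#' per-gene ground-truth labels for recovery testing.
#'
#' Counts are drawn independently per library as
#' `Poisson(total * pi_g * f_gl)` (the sampling model the Audic-Claverie
#' test assumes; the libraries are unreplicated so no overdispersion is
#' estimable, but `dispersion > 0` switches to negative-binomial noise for
#' robustness experiments). Base proportions `pi_g` are log-normal. The
#' fold trajectory `f_gl` depends on the label:
#' \describe{
#'   \item{az_specific_up / az_specific_down}{saturating ramp
#'     `fold^(min(t, 6)/6)` (reciprocal for down) in the ripe-AZ ethylene
#'     series only — full induction from 6 h, before the 9 h onset of cell
#'     separation — with a concordant 160 DAP effect in the natural arm.}
#'   \item{az_transient}{single-peak response in the ripe AZ (peak at 3 h
#'     for odd genes, 6 h for even), natural arm flat.}
#'   \item{shared_responsive}{the up ramp applied identically in all three
#'     ethylene tissues; natural arm flat.}
#'   \item{natural_discordant}{ripe-AZ-specific ramp (up for odd genes,
#'     down for even) but a flat natural profile.}
#'   \item{null}{flat everywhere.}
#' }
#'
#' @param nGenes named integer vector of genes per label (subset of
#'   `az_specific_up`, `az_specific_down`, `az_transient`,
#'   `shared_responsive`, `natural_discordant`, `null`); default 50 each.
#' @param libraryTotal total mapped reads per library (>= 1e4; default
#'   1e6). The modelled contigs are a subset of the library, so column sums
#'   are far below this total.
#' @param fold fold change at full induction (>= 1; default 8).
#' @param abundanceMeanlog,abundanceSdlog log-normal parameters of the base
#'   proportions (defaults `log(1e-5)` and 1.5, spanning rare to abundant
#'   tags).
#' @param dispersion negative-binomial dispersion (0 = Poisson, the
#'   default).
#' @param lengthRange transcript length range in bp, drawn uniformly
#'   (default 500-3000).
#' @param seed mandatory integer seed (reproducibility contract); the
#'   caller's RNG state is restored on exit.
#' @return list with `ethylene` and `natural` ([TagCountSet-class]s, the
#'   natural one carrying transcript lengths), `truth` (data.frame:
#'   `contig_id`, `label`, `pi`, `fold`) and `expected` (list of expected
#'   count matrices for both arms).
#' @examples
#' sim <- simulateAbscissionExperiment(nGenes = c(null = 10), seed = 7)
#' sim$ethylene
#' @export
simulateAbscissionExperiment <- function(nGenes = stats::setNames(
                                           rep(50L, 6L), .LABELS),
                                         libraryTotal = 1e6, fold = 8,
                                         abundanceMeanlog = log(1e-5),
                                         abundanceSdlog = 1.5,
                                         dispersion = 0,
                                         lengthRange = c(500L, 3000L),
                                         seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required (reproducibility contract)")
  if (is.null(names(nGenes)) || !all(names(nGenes) %in% .LABELS))
    stop("nGenes must be named with labels among: ",
         paste(.LABELS, collapse = ", "))
  if (libraryTotal < 1e4) stop("library totals must be >= 1e4")
  if (fold < 1) stop("fold must be >= 1")
  eth_times <- c(0, 3, 6, 9, 12)
  cmp_times <- c(0, 3, 6, 9)
  labels <- rep(names(nGenes), times = nGenes)
  n <- length(labels)
  ids <- sprintf("gene%04d", seq_len(n))

  design_eth <- rbind(
    data.frame(tissue = "AZ", stage_dap = 150, time_h = eth_times),
    data.frame(tissue = "AZ", stage_dap = 30, time_h = cmp_times),
    data.frame(tissue = "P", stage_dap = 150, time_h = cmp_times))
  design_eth$treatment <- "ethylene"
  design_eth$library_id <- sprintf("%s%d_%gh", design_eth$tissue,
                                   design_eth$stage_dap, design_eth$time_h)
  design_nat <- data.frame(tissue = "AZ", stage_dap = c(30, 120, 160),
                           time_h = NA_real_, treatment = "field",
                           library_id = c("AZ_30DAP", "AZ_120DAP",
                                          "AZ_160DAP"))

  ramp <- function(t) pmin(t, 6) / 6          # full induction from 6 h
  peak3 <- c(0, 1, 0.5, 0, 0)
  peak6 <- c(0, 0.5, 1, 0.5, 0)
  idx_in_label <- stats::ave(seq_len(n), labels, FUN = seq_along)

  # log2-fold weight of gene g in ethylene library l
  eth_w <- matrix(0, n, nrow(design_eth))
  for (l in seq_len(nrow(design_eth))) {
    tis <- design_eth$tissue[l]; stg <- design_eth$stage_dap[l]
    t <- design_eth$time_h[l]
    az150 <- tis == "AZ" && stg == 150
    for (lab in unique(labels)) {
      g <- which(labels == lab)
      w <- switch(lab,
        az_specific_up = if (az150) ramp(t) else 0,
        az_specific_down = if (az150) -ramp(t) else 0,
        az_transient = if (az150)
          ifelse(idx_in_label[g] %% 2 == 1,
                 peak3[match(t, eth_times)],
                 peak6[match(t, eth_times)]) else 0,
        shared_responsive = ramp(t),
        natural_discordant = if (az150)
          ifelse(idx_in_label[g] %% 2 == 1, ramp(t), -ramp(t)) else 0,
        0)
      eth_w[g, l] <- w
    }
  }
  nat_w <- matrix(0, n, 3L)
  ripe <- 3L  # 160 DAP column
  nat_w[labels == "az_specific_up", ripe] <- 1
  nat_w[labels == "az_specific_down", ripe] <- -1

  .with_seed(seed, {
    pi0 <- stats::rlnorm(n, abundanceMeanlog, abundanceSdlog)
    lengths <- sample(seq(lengthRange[1L], lengthRange[2L]), n,
                      replace = TRUE)
    draw <- function(mu) {
      if (dispersion > 0)
        stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      else stats::rpois(length(mu), mu)
    }
    mu_eth <- libraryTotal * pi0 * fold^eth_w
    mu_nat <- libraryTotal * pi0 * fold^nat_w
    cnt_eth <- matrix(draw(mu_eth), n, dimnames =
                        list(ids, design_eth$library_id))
    cnt_nat <- matrix(draw(mu_nat), n, dimnames =
                        list(ids, design_nat$library_id))
  })

  eth <- TagCountSet(cnt_eth,
                     libraryTotals = rep(libraryTotal, nrow(design_eth)),
                     sampleData = design_eth)
  nat <- TagCountSet(cnt_nat,
                     libraryTotals = rep(libraryTotal, nrow(design_nat)),
                     lengths = stats::setNames(lengths, ids),
                     sampleData = design_nat)
  truth <- data.frame(contig_id = ids, label = labels, pi = pi0,
                      fold = fold, stringsAsFactors = FALSE)
  list(ethylene = eth, natural = nat, truth = truth,
       expected = list(ethylene = `dimnames<-`(mu_eth, dimnames(cnt_eth)),
                       natural = `dimnames<-`(mu_nat, dimnames(cnt_nat))))
}

#' Simulate a qPCR serial-dilution series
#'
#' Generates Cq values following the standard-curve model
#' `Cq(d) = cq0 + log(d)/log(E) + Normal(0, noiseSd)` for a primer with
#' true per-cycle amplification factor `E`.
#'
#' @param efficiency true amplification factor per cycle, in (1, 2.5].
#' @param cq0 Cq of the undiluted (factor 1) template (default 20).
#' @param noiseSd Gaussian Cq noise standard deviation (default 0).
#' @param dilutionFactors dilution levels (default 5, 25, 125, 625, 3125).
#' @param replicates technical replicates per level (default 3).
#' @param seed mandatory integer seed; caller's RNG state is restored.
#' @return data.frame with columns `dilution_factor`, `replicate`, `cq`.
#' @examples
#' s <- generateDilutionSeries(2, seed = 1)
#' diff(tapply(s$cq, s$dilution_factor, mean))  # log2(5) per 5-fold step
#' @export
generateDilutionSeries <- function(efficiency, cq0 = 20, noiseSd = 0,
                                   dilutionFactors = c(5, 25, 125, 625,
                                                       3125),
                                   replicates = 3L, seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required (reproducibility contract)")
  if (!is.finite(efficiency) || efficiency <= 1 || efficiency > 2.5)
    stop("efficiency must lie in (1, 2.5]")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  grid <- expand.grid(replicate = seq_len(replicates),
                      dilution_factor = dilutionFactors)
  .with_seed(seed, {
    cq <- cq0 + log(grid$dilution_factor) / log(efficiency) +
      stats::rnorm(nrow(grid), 0, noiseSd)
  })
  data.frame(dilution_factor = grid$dilution_factor,
             replicate = grid$replicate, cq = cq)
}
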