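#' Primer amplification efficiency from a serial-dilution standard curve
#'
#' Fits the least-squares slope of mean Cq (quantification cycle) versus
#' `log10` relative template amount (`1/dilution_factor`) and converts it to
#' the per-cycle amplification factor `E = 10^(-1/slope)` (2.0 = perfect
#' doubling). Technical replicates at the same dilution are averaged before
#' fitting. The estimate is invariant to adding a constant to all Cq values
#' (only the slope matters).
#'
#' @param dilutionFactor positive dilution factors, one per Cq observation
#'   (e.g. 5, 25, 125, 625, 3125); at least 3 distinct levels.
#' @param cq finite positive Cq values.
#' @return list with `slope` (cycles per log10 template) and `efficiency`
#'   (amplification factor per cycle).
#' @examples
#' d <- c(5, 25, 125, 625, 3125)
#' primerEfficiency(d, 20 + log2(d))$efficiency  # 2: perfect doubling
#' @export
primerEfficiency <- function(dilutionFactor, cq) {
  if (length(dilutionFactor) != length(cq))
    stop("dilutionFactor and cq must have the same length")
  if (any(!is.finite(dilutionFactor)) || any(dilutionFactor <= 0))
    stop("dilution factors must be positive")
  if (any(!is.finite(cq)) || any(cq <= 0))
    stop("Cq values must be finite and positive")
  if (length(unique(dilutionFactor)) < 3L)
    stop("at least 3 distinct dilution levels are required")
  mean_cq <- tapply(cq, dilutionFactor, mean)
  log_amount <- log10(1 / as.numeric(names(mean_cq)))
  fit <- stats::lm(mean_cq ~ log_amount)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop("invalid dilution series: Cq does not increase with dilution (slope ",
         format(slope), ")")
  list(slope = slope, efficiency = 10^(-1 / slope))
}

#' Primer retention gate
#'
#' Retains primers whose amplification efficiency lies in the inclusive
#' band `[1.8, 2.0]` (near-perfect doubling per cycle).
#'
#' @param efficiency positive amplification factor(s) per cycle.
#' @return logical vector.
#' @examples
#' efficiencyGate(c(1.79, 1.8, 1.9, 2.0, 2.01))
#' @export
efficiencyGate <- function(efficiency) {
  if (any(!is.finite(efficiency)) || any(efficiency <= 0))
    stop("efficiency must be positive")
  efficiency >= 1.8 & efficiency <= 2.0
}

#' Batch primer-efficiency table
#'
#' Applies [primerEfficiency()] and [efficiencyGate()] per primer to a tidy
#' dilution-series table.
#'
#' @param series data.frame with columns `primer_id`, `dilution_factor`,
#'   `cq` (and optionally `replicate`).
#' @return data.frame with columns `primer_id`, `slope`, `efficiency`,
#'   `pass`.
#' @export
primerEfficiencyTable <- function(series) {
  need <- c("primer_id", "dilution_factor", "cq")
  if (!all(need %in% colnames(series)))
    stop("series must have columns ", paste(need, collapse = ", "))
  ids <- unique(series$primer_id)
  rows <- lapply(ids, function(id) {
    sub <- series[series$primer_id == id, ]
    fit <- primerEfficiency(sub$dilution_factor, sub$cq)
    data.frame(primer_id = id, slope = fit$slope,
               efficiency = fit$efficiency,
               pass = efficiencyGate(fit$efficiency))
  })
  do.call(rbind, rows)
}

#' Read a dilution-series table
#'
#' TSV with columns `primer_id`, `dilution_factor`, `replicate`, `cq`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readDilutionSeries <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Opposite-profile concordance check for the non-shedding genotype
#'
#' Genes that drive abscission are expected to show an *altered* profile in
#' the abscission zone of a non-shedding genotype. Both profiles are
#' normalized to peak 1 ([normalizeToPeak()]); the ripe-stage (last) values
#' are then compared. For an abscission-`up` gene the non-shedding ripe
#' value must fall below `threshold` times the shedding ripe value to count
#' as a `match`; for a `down` gene it must exceed the shedding ripe value
#' divided by `threshold`.
#'
#' @param shedding,nonshedding non-negative profiles over the same ordered
#'   conditions, each with a positive maximum.
#' @param direction `"up"` or `"down"`: the gene's direction during
#'   abscission.
#' @param threshold attenuation threshold in (0, 1); default 0.5.
#' @return `"match"` or `"mismatch"`.
#' @examples
#' oppositeProfileCheck(c(0.1, 0.4, 1), c(1, 0.6, 0.05), "up")  # match
#' @export
oppositeProfileCheck <- function(shedding, nonshedding,
                                 direction = c("up", "down"),
                                 threshold = 0.5) {
  direction <- match.arg(direction)
  if (length(shedding) != length(nonshedding))
    stop("profiles must have the same condition ordering and length")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  sh <- normalizeToPeak(shedding)
  ns <- normalizeToPeak(nonshedding)
  ripe_sh <- sh[length(sh)]
  ripe_ns <- ns[length(ns)]
  ok <- if (direction == "up") ripe_ns < threshold * ripe_sh
        else ripe_ns > ripe_sh / threshold
  if (ok) "match" else "mismatch"
}
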