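# Independent oracles and fixture builders shared across the suite.

# Direct term-by-term summation oracle for the two-sided exact test.
# Terms come from dnbinom (the algebraically identical closed form),
# independent of the package's lgamma/pbeta route. Tail cutoff 1e-15.
ac_pvalue_sum <- function(x, y, n1, n2, cutoff = 1e-15) {
  if (x == 0 && y == 0) return(1)  # zero-zero tie convention: no evidence
  p <- n1 / (n1 + n2)
  p_le <- sum(dnbinom(0:y, size = x + 1, prob = p))
  p_ge <- 0
  k <- y
  mode <- floor((x + 1) * (1 - p) / p) + 1
  repeat {
    term <- dnbinom(k, size = x + 1, prob = p)
    p_ge <- p_ge + term
    k <- k + 1
    if (k > mode && term < cutoff) break
  }
  min(1, 2 * min(p_le, p_ge))
}

# Ethylene-arm fixture: AZ150 at 0,3,6,9,12 h plus AZ30/P150 at 0,3,6,9 h.
# az150: genes x 5 matrix; az30, p150: genes x 4 (default: constant baseline).
make_ethylene_set <- function(az150, az30 = NULL, p150 = NULL,
                              total = 1e5) {
  n <- nrow(az150)
  if (is.null(az30)) az30 <- az150[, 1:4, drop = FALSE]
  if (is.null(p150)) p150 <- az150[, 1:4, drop = FALSE]
  cnt <- cbind(az150, az30, p150)
  storage.mode(cnt) <- "integer"
  eth5 <- c(0, 3, 6, 9, 12); eth4 <- c(0, 3, 6, 9)
  sheet <- data.frame(
    library_id = c(paste0("AZ150_", eth5, "h"), paste0("AZ30_", eth4, "h"),
                   paste0("P150_", eth4, "h")),
    tissue = rep(c("AZ", "AZ", "P"), c(5, 4, 4)),
    stage_dap = rep(c(150, 30, 150), c(5, 4, 4)),
    treatment = "ethylene",
    time_h = c(eth5, eth4, eth4))
  colnames(cnt) <- sheet$library_id
  rownames(cnt) <- rownames(az150)
  TagCountSet(cnt, libraryTotals = rep(total, ncol(cnt)),
              sampleData = sheet)
}

# Natural-arm fixture with RPKM equal to the supplied values:
# lengths 1000 bp and totals 1e6 make RPKM equal the count.
make_natural_set <- function(rpkm_values) {
  cnt <- as.matrix(rpkm_values)
  storage.mode(cnt) <- "integer"
  colnames(cnt) <- c("AZ_30DAP", "AZ_120DAP", "AZ_160DAP")
  sheet <- data.frame(library_id = colnames(cnt), tissue = "AZ",
                      stage_dap = c(30, 120, 160), treatment = "field",
                      time_h = NA_real_)
  TagCountSet(cnt, libraryTotals = rep(1e6, 3),
              lengths = setNames(rep(1000L, nrow(cnt)), rownames(cnt)),
              sampleData = sheet)
}
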