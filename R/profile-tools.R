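#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of per-contig expression profiles with distance
#' `1 - Pearson correlation` and average linkage, cut into `k` clusters.
#' Correlation distance makes the partition invariant to per-profile affine
#' rescaling (`c * profile + b`, `c > 0`), so no prior per-gene
#' standardization is needed. Zero-variance (constant) profiles, for which
#' correlation is undefined, are set aside in a reject class before
#' clustering and reported in the `degenerate` slot (with a message).
#'
#' When profiles span exactly the five canonical ethylene time points
#' (0, 3, 6, 9, 12 h) the rule-based shape class of each contig
#' ([classifyShape()]) is recorded alongside the partition.
#'
#' @param profiles numeric matrix, one row per contig (rownames required),
#'   columns ordered by time; at least 2 columns.
#' @param k number of clusters, between 1 and the number of clusterable
#'   (non-degenerate) contigs.
#' @return a [ClusterAssignment-class].
#' @examples
#' m <- rbind(up = c(1, 2, 4, 8, 16), dn = c(16, 8, 4, 2, 1))
#' clusterLabels(hcaCluster(m, k = 2))  # antipodal profiles separate
#' @export
hcaCluster <- function(profiles, k) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    stop("profiles must have contig ids as rownames")
  if (ncol(profiles) < 2L)
    stop("profiles must have at least 2 time points")
  sds <- apply(profiles, 1L, stats::sd)
  degen <- rownames(profiles)[sds == 0]
  if (length(degen))
    message(length(degen), " zero-variance profile(s) set aside: ",
            paste(utils::head(degen, 5L), collapse = ", "),
            if (length(degen) > 5L) ", ..." else "")
  keep <- profiles[sds > 0, , drop = FALSE]
  if (k < 1L || k > nrow(keep))
    stop("k must be between 1 and the number of clusterable contigs (",
         nrow(keep), ")")
  d <- stats::as.dist(1 - stats::cor(t(keep)))
  tree <- stats::hclust(d, method = "average")
  cl <- stats::cutree(tree, k = k)
  shape <- if (ncol(profiles) == 5L)
    vapply(rownames(keep), function(id) classifyShape(keep[id, ]),
           character(1))
  else stats::setNames(rep(NA_character_, nrow(keep)), rownames(keep))
  new("ClusterAssignment", assignments = cl, tree = tree, k = as.integer(k),
      degenerate = degen, shape = shape)
}

#' @describeIn hcaCluster extract the named cluster-index vector.
#' @param x a `ClusterAssignment`.
#' @export
clusterLabels <- function(x) {
  stopifnot(is(x, "ClusterAssignment"))
  x@assignments
}

#' @describeIn hcaCluster extract the per-contig shape classes.
#' @export
shapeClasses <- function(x) {
  stopifnot(is(x, "ClusterAssignment"))
  x@shape
}

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d contigs in %d clusters",
              length(object@assignments), object@k))
  if (length(object@degenerate))
    cat(sprintf(" (+%d degenerate)", length(object@degenerate)))
  cat("\n  sizes:", paste(tabulate(object@assignments, object@k),
                          collapse = ", "), "\n")
})

#' Rule-based shape classification of an ethylene time-course profile
#'
#' Classifies a five-point profile over 0, 3, 6, 9, 12 h of ethylene
#' treatment into the four canonical response classes: `A` sustained
#' induction (non-decreasing with final > initial), `D` repression
#' (non-increasing with final < initial), `B` transient with a strict peak
#' at 3 h, `C` transient with a strict peak at 6 h; anything else —
#' including constant profiles and tied maxima at 3 h and 6 h — is
#' `"other"`. Monotone classes take precedence over peak classes.
#'
#' @param profile numeric vector of length 5 (abundances at 0, 3, 6, 9,
#'   12 h).
#' @return one of `"A"`, `"B"`, `"C"`, `"D"`, `"other"`.
#' @examples
#' classifyShape(c(1, 2, 4, 8, 16))  # "A"
#' classifyShape(c(1, 10, 2, 1, 1))  # "B"
#' @export
classifyShape <- function(profile) {
  if (length(profile) != 5L || any(!is.finite(profile)))
    stop("profile must be a finite numeric vector of length 5 (0,3,6,9,12 h)")
  d <- diff(profile)
  if (all(d == 0)) return("other")
  if (all(d >= 0) && profile[5L] > profile[1L]) return("A")
  if (all(d <= 0) && profile[5L] < profile[1L]) return("D")
  if (profile[2L] > max(profile[-2L])) return("B")
  if (profile[3L] > max(profile[-3L])) return("C")
  "other"
}

#' Normalize a profile to its peak
#'
#' Divides every value by the profile maximum so the highest point equals 1
#' (the convention used for peak-normalized heat-map comparison of
#' profiles). Idempotent; undefined (an error) for all-zero profiles.
#'
#' @param profile non-negative numeric vector with `max(profile) > 0`.
#' @return profile scaled so its maximum is exactly 1.
#' @examples
#' normalizeToPeak(c(2, 4, 8))  # 0.25 0.50 1.00
#' @export
normalizeToPeak <- function(profile) {
  if (any(!is.finite(profile)) || any(profile < 0))
    stop("profile must be finite and non-negative")
  m <- max(profile)
  if (m <= 0) stop("normalization undefined for an all-zero profile")
  profile / m
}

#' Direction call on a natural ripening profile
#'
#' Compares abundance in the abscising ripe stage (160 DAP) against the
#' maximum of the earlier, non-abscising stages (30 and 120 DAP). With fold
#' threshold `f` and a pseudo-abundance floor `eps` added to both sides to
#' tame zeros: `up` when `r160 + eps >= f * (max(r30, r120) + eps)`, `down`
#' when `r160 + eps <= (max(r30, r120) + eps) / f`, otherwise `flat`.
#'
#' @param r30,r120,r160 non-negative abundances (RPKM) at 30, 120 and
#'   160 days after pollination; vectorized.
#' @param fold fold-change threshold, `> 1` (default 2).
#' @param floor pseudo-abundance floor (default 0.1 RPKM).
#' @return character vector in `{"up", "down", "flat"}`.
#' @examples
#' naturalDirection(1, 2, 40)   # "up"
#' naturalDirection(10, 11, 9)  # "flat"
#' @export
naturalDirection <- function(r30, r120, r160, fold = 2, floor = 0.1) {
  vals <- c(r30, r120, r160)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("abundances must be finite and non-negative")
  if (fold <= 1) stop("fold threshold must be > 1")
  ref <- pmax(r30, r120) + floor
  hi <- r160 + floor
  ifelse(hi >= fold * ref, "up", ifelse(hi <= ref / fold, "down", "flat"))
}
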