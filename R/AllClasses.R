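#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
NULL

.TISSUES <- c("AZ", "P", "M")
.TREATMENTS <- c("ethylene", "field")

#' TagCountSet: tag-count libraries with design metadata
#'
#' An S4 container for unreplicated tag-count sequencing libraries, extending
#' [SummarizedExperiment::SummarizedExperiment]. The `"counts"` assay holds
#' non-negative integer read counts (contigs x libraries). Library totals
#' (total mapped reads, which may exceed the column sums when reads map to
#' contigs filtered out upstream) live in `colData()$library_total`; optional
#' transcript lengths in base pairs live in `rowData()$length_bp`. The sample
#' sheet binding each library to its tissue (`AZ`, `P` or `M`), developmental
#' stage in days after pollination, treatment (`ethylene` or `field`) and
#' ethylene time point in hours is carried in `colData()` columns `tissue`,
#' `stage_dap`, `treatment` and `time_h` (`time_h` is `NA` for field
#' libraries).
#'
#' @slot .. inherited from `SummarizedExperiment`; no additional slots.
#' @seealso [TagCountSet()] for construction, [readCountTable()] for file
#'   input, [rpkm()], [countsPerMillion()], [expressionProfile()].
#' @exportClass TagCountSet
setClass("TagCountSet", contains = "SummarizedExperiment")

.validTagCountSet <- function(object) {
  msg <- character(0)
  if (!"counts" %in% assayNames(object))
    return("assay 'counts' is required")
  m <- assay(object, "counts")
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    msg <- c(msg, "counts must have contig ids as rownames and library ids as colnames")
  if (anyDuplicated(rownames(m)))
    msg <- c(msg, "duplicate contig ids")
  if (anyDuplicated(colnames(m)))
    msg <- c(msg, "duplicate library ids")
  if (any(!is.finite(m)) || any(m < 0) || any(m != floor(m)))
    msg <- c(msg, "counts must be finite non-negative integers")
  cd <- colData(object)
  if (!"library_total" %in% colnames(cd)) {
    msg <- c(msg, "colData column 'library_total' is required")
  } else {
    tot <- cd$library_total
    if (any(!is.finite(tot)) || any(tot < 1) || any(tot != floor(tot)))
      msg <- c(msg, "library totals must be positive integers")
    else if (any(tot < colSums(m)))
      msg <- c(msg, "library totals must be >= column sums of counts")
  }
  rd <- rowData(object)
  if ("length_bp" %in% colnames(rd)) {
    len <- rd$length_bp
    if (any(is.na(len)) || any(len < 1) || any(len != floor(len)))
      msg <- c(msg, "transcript lengths must be integers >= 1 for every contig")
  }
  cd_design <- intersect(c("tissue", "stage_dap", "treatment", "time_h"),
                         colnames(cd))
  if (length(cd_design) == 4L) {
    if (!all(cd$tissue %in% .TISSUES))
      msg <- c(msg, sprintf("tissue must be one of %s",
                            paste(.TISSUES, collapse = ", ")))
    if (!all(cd$treatment %in% .TREATMENTS))
      msg <- c(msg, sprintf("treatment must be one of %s",
                            paste(.TREATMENTS, collapse = ", ")))
    eth <- cd$treatment == "ethylene"
    if (any(eth) && any(is.na(cd$time_h[eth])))
      msg <- c(msg, "ethylene libraries must have time_h set")
    if (any(!eth) && any(!is.na(cd$time_h[!eth])))
      msg <- c(msg, "field libraries must not have time_h set")
    key <- paste(cd$tissue, cd$stage_dap, cd$treatment, cd$time_h, sep = "/")
    if (anyDuplicated(key))
      msg <- c(msg, "design cells (tissue, stage_dap, treatment, time_h) must be unique")
  } else if (length(cd_design) > 0L) {
    msg <- c(msg, "sample metadata must provide all of tissue, stage_dap, treatment, time_h (or none)")
  }
  if (length(msg)) msg else TRUE
}

setValidity("TagCountSet", .validTagCountSet)

#' Screen configuration
#'
#' Thresholds and design constants of the four-step screen.
#'
#' @slot alpha significance threshold on Bonferroni-adjusted p-values
#'   (default 0.01).
#' @slot minTimepoints minimum number of significant ethylene time points for
#'   stage-1 retention (default 1).
#' @slot ethyleneTimes ethylene treatment time points (hours) used in the
#'   stage-1 ripe-AZ time course (default 0, 3, 6, 9, 12).
#' @slot sharedTimes time points shared with the comparator tissues and used
#'   in stage 2 (default 0, 3, 6, 9; the comparators' series stops at 9 h).
#' @slot naturalFoldThreshold fold change defining an up/down call on the
#'   natural ripening profile (default 2).
#' @slot requireSameDirection if `TRUE` (default) a stage-2 candidate must
#'   differ from both comparator tissues in the same direction.
#' @slot pseudoFloor pseudo-abundance added before natural fold ratios to
#'   tame zeros (default 0.1, RPKM units).
#' @slot ripeStage,immatureStage stages (days after pollination) of the ripe
#'   and immature fruit used in the ethylene arm (defaults 150 and 30).
#' @seealso [ScreenConfig()], [runScreen()]
#' @exportClass ScreenConfig
setClass("ScreenConfig",
  representation(alpha = "numeric", minTimepoints = "integer",
                 ethyleneTimes = "numeric", sharedTimes = "numeric",
                 naturalFoldThreshold = "numeric",
                 requireSameDirection = "logical", pseudoFloor = "numeric",
                 ripeStage = "numeric", immatureStage = "numeric"),
  prototype(alpha = 0.01, minTimepoints = 1L,
            ethyleneTimes = c(0, 3, 6, 9, 12), sharedTimes = c(0, 3, 6, 9),
            naturalFoldThreshold = 2, requireSameDirection = TRUE,
            pseudoFloor = 0.1, ripeStage = 150, immatureStage = 30))

setValidity("ScreenConfig", function(object) {
  msg <- character(0)
  if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
      object@alpha <= 0 || object@alpha > 1)
    msg <- c(msg, "alpha must be a single value in (0, 1]")
  if (object@minTimepoints < 1L)
    msg <- c(msg, "minTimepoints must be >= 1")
  if (length(object@naturalFoldThreshold) != 1L ||
      object@naturalFoldThreshold <= 1)
    msg <- c(msg, "naturalFoldThreshold must be > 1")
  if (object@pseudoFloor < 0)
    msg <- c(msg, "pseudoFloor must be >= 0")
  if (!0 %in% object@ethyleneTimes)
    msg <- c(msg, "ethyleneTimes must include the 0 h control")
  if (length(msg)) msg else TRUE
})

#' Screen result
#'
#' Nested contig sets surviving the screen stages, with a per-test audit
#' trail. Invariants enforced by the class: `finalUp`/`finalDown` are
#' disjoint and nest inside `stage2Candidates`, which nest inside
#' `stage1Degs`.
#'
#' @slot stage1Degs contigs significant in the ripe-AZ ethylene time course.
#' @slot stage2Candidates stage-1 contigs that are AZ150-specific versus both
#'   comparator tissues.
#' @slot finalUp,finalDown contigs concordantly up/down in both ethylene and
#'   natural abscission.
#' @slot directions per-candidate ethylene direction (`up`, `down`,
#'   `transient`) used at stage 4.
#' @slot audit one row per two-library test performed (contig, comparison,
#'   x, y, N1, N2, p_raw, p_adj, direction).
#' @slot naturalCalls per-candidate natural-profile abundances and direction
#'   calls (including unresolvable candidates, flagged `resolved = FALSE`).
#' @slot config the [ScreenConfig-class] used.
#' @seealso [runScreen()], accessors [stage1Degs()], [stage2Candidates()],
#'   [finalUp()], [finalDown()], [screenAudit()]
#' @exportClass ScreenResult
setClass("ScreenResult",
  representation(stage1Degs = "character", stage2Candidates = "character",
                 finalUp = "character", finalDown = "character",
                 directions = "character", audit = "data.frame",
                 naturalCalls = "data.frame", config = "ScreenConfig"))

setValidity("ScreenResult", function(object) {
  msg <- character(0)
  if (!all(object@stage2Candidates %in% object@stage1Degs))
    msg <- c(msg, "stage2Candidates must be a subset of stage1Degs")
  fin <- c(object@finalUp, object@finalDown)
  if (!all(fin %in% object@stage2Candidates))
    msg <- c(msg, "final sets must be subsets of stage2Candidates")
  if (length(intersect(object@finalUp, object@finalDown)))
    msg <- c(msg, "finalUp and finalDown must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Hierarchical clustering assignment of expression profiles
#'
#' @slot assignments named integer vector, contig to cluster index (1..k).
#' @slot tree the `hclust` merge tree (average linkage on correlation
#'   distance).
#' @slot k number of clusters the tree was cut into.
#' @slot degenerate contigs with zero-variance profiles, set aside before
#'   clustering (correlation distance undefined).
#' @slot shape per-contig rule-based shape class (`A`, `B`, `C`, `D` or
#'   `other`) when the profiles span the canonical five ethylene time
#'   points, otherwise `NA`.
#' @seealso [hcaCluster()], [classifyShape()]
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  representation(assignments = "integer", tree = "ANY", k = "integer",
                 degenerate = "character", shape = "character"))

setValidity("ClusterAssignment", function(object) {
  msg <- character(0)
  if (is.null(names(object@assignments)))
    msg <- c(msg, "assignments must be named by contig")
  if (anyDuplicated(c(names(object@assignments), object@degenerate)))
    msg <- c(msg, "every contig must be assigned exactly once")
  if (length(object@assignments) &&
      length(unique(object@assignments)) != object@k)
    msg <- c(msg, "number of clusters must equal the requested k")
  if (length(msg)) msg else TRUE
})
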