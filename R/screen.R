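#' Create a screen configuration
#'
#' @param alpha significance threshold on Bonferroni-adjusted p-values
#'   (default 0.01).
#' @param minTimepoints minimum number of significant ethylene time points
#'   for stage-1 retention (default 1).
#' @param ethyleneTimes ripe-AZ ethylene time course, hours (default
#'   0, 3, 6, 9, 12; must include 0).
#' @param sharedTimes time points at which the comparator tissues are
#'   compared in stage 2 (default 0, 3, 6, 9).
#' @param naturalFoldThreshold fold change defining an up/down call on the
#'   natural ripening profile (default 2, must be > 1).
#' @param requireSameDirection require the ripe AZ to differ from both
#'   comparator tissues in the same direction (default `TRUE`).
#' @param pseudoFloor pseudo-abundance added before natural fold ratios
#'   (default 0.1 RPKM).
#' @param ripeStage,immatureStage stages (days after pollination) of the
#'   ripe and immature fruit in the ethylene arm (defaults 150, 30).
#' @return a validated [ScreenConfig-class].
#' @export
ScreenConfig <- function(alpha = 0.01, minTimepoints = 1L,
                         ethyleneTimes = c(0, 3, 6, 9, 12),
                         sharedTimes = c(0, 3, 6, 9),
                         naturalFoldThreshold = 2,
                         requireSameDirection = TRUE, pseudoFloor = 0.1,
                         ripeStage = 150, immatureStage = 30) {
  new("ScreenConfig", alpha = alpha,
      minTimepoints = as.integer(minTimepoints),
      ethyleneTimes = ethyleneTimes, sharedTimes = sharedTimes,
      naturalFoldThreshold = naturalFoldThreshold,
      requireSameDirection = requireSameDirection, pseudoFloor = pseudoFloor,
      ripeStage = ripeStage, immatureStage = immatureStage)
}

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig\n",
      sprintf("  alpha = %g (Bonferroni-adjusted), minTimepoints = %d\n",
              object@alpha, object@minTimepoints),
      sprintf("  ethylene times: %s h; shared times: %s h\n",
              paste(object@ethyleneTimes, collapse = ","),
              paste(object@sharedTimes, collapse = ",")),
      sprintf("  natural fold threshold = %g (floor %g), same direction = %s\n",
              object@naturalFoldThreshold, object@pseudoFloor,
              object@requireSameDirection), sep = "")
})

.lib_for <- function(x, tissue, stage, treatment, time = NULL) {
  cd <- colData(x)
  sel <- cd$tissue == tissue & cd$stage_dap == stage &
    cd$treatment == treatment
  if (!is.null(time)) sel <- sel & !is.na(cd$time_h) & cd$time_h == time
  colnames(x)[sel]
}

.check_design <- function(x) {
  need <- c("tissue", "stage_dap", "treatment", "time_h")
  if (!all(need %in% colnames(colData(x))))
    stop("count set lacks sample metadata (tissue, stage_dap, treatment, time_h)")
}

#' Stage 1: ethylene time-course differential expression in the ripe AZ
#'
#' Tests every contig at each treated ethylene time point against the
#' untreated 0 h ripe-AZ library with the exact Audic-Claverie test
#' ([acPvalue()]), Bonferroni-adjusted within each pairwise comparison
#' (family size = number of contigs). A contig is a stage-1 DEG when its
#' adjusted p-value is `<= alpha` at `>= minTimepoints` time points.
#'
#' @param x ethylene-arm [TagCountSet-class] (must contain the ripe-AZ 0 h
#'   control library).
#' @param cfg a [ScreenConfig-class].
#' @return list with `degs` (character vector of retained contigs) and
#'   `tests` (audit data.frame, one row per contig x time point).
#' @export
stage1EthyleneDegs <- function(x, cfg = ScreenConfig()) {
  .check_design(x)
  lib0 <- .lib_for(x, "AZ", cfg@ripeStage, "ethylene", 0)
  if (length(lib0) != 1L)
    stop("missing ripe-AZ ethylene 0 h control library")
  cd <- colData(x)
  avail <- cd$time_h[cd$tissue == "AZ" & cd$stage_dap == cfg@ripeStage &
                       cd$treatment == "ethylene"]
  times <- intersect(setdiff(cfg@ethyleneTimes, 0), avail)
  if (!length(times))
    stop("no treated ripe-AZ ethylene libraries at the configured time points")
  if (nrow(x) == 0L)
    return(list(degs = character(0), tests = .empty_audit()))
  cnt <- counts(x)
  tot <- libraryTotals(x)
  tests <- do.call(rbind, lapply(times, function(t) {
    libt <- .lib_for(x, "AZ", cfg@ripeStage, "ethylene", t)
    tab <- acTest(cnt[, lib0], cnt[, libt], tot[[lib0]], tot[[libt]],
                  contigIds = rownames(x), m = nrow(x))
    tab$comparison <- sprintf("AZ%g_%gh_vs_0h", cfg@ripeStage, t)
    tab$time_h <- t
    tab
  }))
  nsig <- tapply(tests$p_adj <= cfg@alpha, tests$contig_id, sum)
  degs <- rownames(x)[rownames(x) %in%
                        names(nsig)[nsig >= cfg@minTimepoints]]
  list(degs = degs, tests = tests)
}

#' Stage 2: between-tissue specificity filter
#'
#' A stage-1 DEG is retained when there exists a shared time point at which
#' the ripe AZ differs significantly (Bonferroni-adjusted Audic-Claverie
#' p `<= alpha`, family size = number of DEGs tested) from *both* the
#' immature-fruit AZ and the ripe-fruit pedicel — and, when
#' `requireSameDirection` is set, in the same direction versus both
#' (a gene higher than one comparator but lower than the other is not
#' tissue-specific).
#'
#' @param degs character vector of stage-1 DEG contig ids (or the list
#'   returned by [stage1EthyleneDegs()]).
#' @inheritParams stage1EthyleneDegs
#' @return list with `candidates` (retained contigs) and `tests` (audit
#'   data.frame, one row per contig x time point x comparator).
#' @export
stage2TissueFilter <- function(degs, x, cfg = ScreenConfig()) {
  .check_design(x)
  if (is.list(degs)) degs <- degs$degs
  if (!length(degs)) return(list(candidates = character(0),
                                 tests = .empty_audit()))
  comparators <- list(
    AZ30 = c("AZ", cfg@immatureStage),
    P150 = c("P", cfg@ripeStage))
  shared <- Filter(function(t) {
    length(.lib_for(x, "AZ", cfg@ripeStage, "ethylene", t)) == 1L &&
      all(vapply(comparators, function(cc)
        length(.lib_for(x, cc[1L], as.numeric(cc[2L]), "ethylene", t)) == 1L,
        logical(1)))
  }, cfg@sharedTimes)
  if (!length(shared))
    stop("comparator tissues are missing at every shared time point")
  cnt <- counts(x)
  tot <- libraryTotals(x)
  m <- length(degs)
  tests <- do.call(rbind, lapply(shared, function(t) {
    liby <- .lib_for(x, "AZ", cfg@ripeStage, "ethylene", t)
    do.call(rbind, lapply(names(comparators), function(nm) {
      cc <- comparators[[nm]]
      libx <- .lib_for(x, cc[1L], as.numeric(cc[2L]), "ethylene", t)
      tab <- acTest(cnt[degs, libx], cnt[degs, liby],
                    tot[[libx]], tot[[liby]], contigIds = degs, m = m)
      tab$comparison <- sprintf("AZ%g_vs_%s_%gh", cfg@ripeStage, nm, t)
      tab$time_h <- t
      tab$comparator <- nm
      tab
    }))
  }))
  keep <- vapply(degs, function(id) {
    sub <- tests[tests$contig_id == id, ]
    any(vapply(shared, function(t) {
      tt <- sub[sub$time_h == t, ]
      ok <- all(tt$p_adj <= cfg@alpha)
      if (cfg@requireSameDirection)
        ok <- ok && length(unique(tt$direction)) == 1L &&
          tt$direction[1L] != "none"
      ok
    }, logical(1)))
  }, logical(1))
  list(candidates = degs[keep], tests = tests)
}

.empty_audit <- function() {
  data.frame(contig_id = character(0), x = integer(0), y = integer(0),
             N1 = numeric(0), N2 = numeric(0), p_raw = numeric(0),
             p_adj = numeric(0), direction = character(0),
             comparison = character(0), time_h = numeric(0),
             stringsAsFactors = FALSE)
}

#' Ethylene response direction of each contig
#'
#' Derives the per-contig ethylene direction consumed by
#' [stage4Concordance()] from the ripe-AZ time-course profile (counts per
#' million), via the rule-based shape classifier ([classifyShape()]) when
#' the profile spans the five canonical time points: class `A` maps to
#' `up`, `D` to `down`, and `B`, `C` and `other` to `transient` (later
#' resolved by the sign of the net 0 h to last-time-point change). The net
#' change is recorded for that resolution.
#'
#' @inheritParams stage1EthyleneDegs
#' @param contigs contig ids to classify.
#' @return data.frame with columns `contig_id`, `shape`, `direction`
#'   (`up`/`down`/`transient`) and `net` (last minus 0 h abundance).
#' @export
ethyleneDirections <- function(x, contigs, cfg = ScreenConfig()) {
  .check_design(x)
  cpmm <- countsPerMillion(x)
  cd <- colData(x)
  sel <- cd$tissue == "AZ" & cd$stage_dap == cfg@ripeStage &
    cd$treatment == "ethylene" & cd$time_h %in% cfg@ethyleneTimes
  libs <- colnames(x)[sel][order(cd$time_h[sel])]
  if (length(libs) < 2L) stop("ripe-AZ ethylene series not found")
  prof <- cpmm[contigs, libs, drop = FALSE]
  shape <- if (length(libs) == 5L)
    apply(prof, 1L, classifyShape) else rep("other", length(contigs))
  dir <- ifelse(shape == "A", "up", ifelse(shape == "D", "down", "transient"))
  data.frame(contig_id = contigs, shape = shape, direction = dir,
             net = prof[, length(libs)] - prof[, 1L],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stage 4: concordance with natural abscission
#'
#' Intersects the ethylene-responsive, AZ-specific candidates with the
#' natural ripening time course. Each candidate's natural direction is
#' called from its RPKM profile at 30, 120 and 160 days after pollination
#' ([naturalDirection()]). `up` candidates enter `finalUp` when the natural
#' direction is also `up`; `down` candidates enter `finalDown` analogously.
#' `transient` candidates enter a final set only when their natural
#' direction is non-flat and matches the sign of their net ethylene change.
#' Candidates absent from the natural table are recorded as unresolvable
#' and excluded.
#'
#' @param candidates character vector of stage-2 candidate contig ids.
#' @param directions data.frame from [ethyleneDirections()] (columns
#'   `contig_id`, `direction`, `net`).
#' @param natural natural-arm [TagCountSet-class] (field libraries at 30,
#'   120 and 160 DAP; RPKM used when transcript lengths are present).
#' @param cfg a [ScreenConfig-class].
#' @return list with `finalUp`, `finalDown` and `naturalCalls` (per-contig
#'   abundances, direction call and `resolved` flag).
#' @export
stage4Concordance <- function(candidates, directions, natural,
                              cfg = ScreenConfig()) {
  .check_design(natural)
  if (!length(candidates))
    return(list(finalUp = character(0), finalDown = character(0),
                naturalCalls = data.frame()))
  dmap <- stats::setNames(directions$direction, directions$contig_id)
  nmap <- stats::setNames(directions$net, directions$contig_id)
  if (!all(candidates %in% names(dmap)))
    stop("ethylene directions missing for some candidates")
  abund <- if (hasLengths(natural)) rpkm(natural) else
    countsPerMillion(natural)
  cd <- colData(natural)
  stage_lib <- function(s) {
    lib <- colnames(natural)[cd$tissue == "AZ" & cd$treatment == "field" &
                               cd$stage_dap == s]
    if (length(lib) != 1L)
      stop("natural AZ field library at ", s, " DAP not found")
    lib
  }
  libs <- vapply(c(30, 120, 160), stage_lib, character(1))
  resolved <- candidates %in% rownames(natural)
  if (any(!resolved))
    message(sum(!resolved),
            " candidate(s) absent from the natural table; excluded: ",
            paste(utils::head(candidates[!resolved], 5L), collapse = ", "))
  calls <- data.frame(contig_id = candidates, resolved = resolved,
                      rpkm30 = NA_real_, rpkm120 = NA_real_,
                      rpkm160 = NA_real_,
                      natural_direction = NA_character_,
                      ethylene_direction = unname(dmap[candidates]),
                      stringsAsFactors = FALSE)
  ok <- which(resolved)
  if (length(ok)) {
    ids <- candidates[ok]
    calls$rpkm30[ok] <- abund[ids, libs[1L]]
    calls$rpkm120[ok] <- abund[ids, libs[2L]]
    calls$rpkm160[ok] <- abund[ids, libs[3L]]
    calls$natural_direction[ok] <- naturalDirection(
      calls$rpkm30[ok], calls$rpkm120[ok], calls$rpkm160[ok],
      fold = cfg@naturalFoldThreshold, floor = cfg@pseudoFloor)
  }
  ed <- calls$ethylene_direction
  nd <- calls$natural_direction
  net <- unname(nmap[candidates])
  in_up <- resolved & nd == "up" &
    (ed == "up" | (ed == "transient" & net > 0))
  in_down <- resolved & nd == "down" &
    (ed == "down" | (ed == "transient" & net < 0))
  list(finalUp = candidates[which(in_up)],
       finalDown = candidates[which(in_down)],
       naturalCalls = calls)
}

#' Run the full four-step screen
#'
#' Composes the stages: (1) ethylene time-course differential expression in
#' the ripe-fruit AZ versus the 0 h control; (2) between-tissue specificity
#' versus immature-fruit AZ and ripe-fruit pedicel; (3) ethylene direction
#' classification of each candidate's profile; (4) concordance with the
#' natural ripening time course. Identical inputs and configuration yield
#' identical results (and byte-identical reports via
#' [writeScreenResult()]).
#'
#' @param ethylene ethylene-arm [TagCountSet-class] (ripe AZ time course
#'   plus comparator tissues).
#' @param natural natural-arm [TagCountSet-class] (field AZ at 30, 120,
#'   160 DAP, with transcript lengths for RPKM).
#' @param cfg a [ScreenConfig-class].
#' @return a [ScreenResult-class].
#' @examples
#' sim <- simulateAbscissionExperiment(
#'   nGenes = c(az_specific_up = 5, null = 20), seed = 1)
#' res <- runScreen(sim$ethylene, sim$natural)
#' res
#' @export
runScreen <- function(ethylene, natural, cfg = ScreenConfig()) {
  s1 <- stage1EthyleneDegs(ethylene, cfg)
  s2 <- stage2TissueFilter(s1$degs, ethylene, cfg)
  dirs <- if (length(s2$candidates))
    ethyleneDirections(ethylene, s2$candidates, cfg)
  else data.frame(contig_id = character(0), shape = character(0),
                  direction = character(0), net = numeric(0))
  s4 <- stage4Concordance(s2$candidates, dirs, natural, cfg)
  audit1 <- s1$tests
  audit1$comparator <- "AZ150_0h"
  audit <- rbind(audit1[, c("contig_id", "comparison", "time_h", "comparator",
                            "x", "y", "N1", "N2", "p_raw", "p_adj",
                            "direction")],
                 if (nrow(s2$tests))
                   s2$tests[, c("contig_id", "comparison", "time_h",
                                "comparator", "x", "y", "N1", "N2", "p_raw",
                                "p_adj", "direction")])
  rownames(audit) <- NULL
  new("ScreenResult", stage1Degs = s1$degs, stage2Candidates = s2$candidates,
      finalUp = s4$finalUp, finalDown = s4$finalDown,
      directions = stats::setNames(dirs$direction, dirs$contig_id),
      audit = audit,
      naturalCalls = if (length(s2$candidates)) s4$naturalCalls else
        data.frame(), config = cfg)
}

#' @rdname ScreenResult-accessors
#' @name ScreenResult-accessors
#' @title Accessors for screen results
#' @param x a [ScreenResult-class].
#' @return character vectors of contig ids; `screenAudit()` returns the
#'   audit data.frame (one row per two-library test performed).
#' @export
stage1Degs <- function(x) { stopifnot(is(x, "ScreenResult")); x@stage1Degs }

#' @rdname ScreenResult-accessors
#' @export
stage2Candidates <- function(x) {
  stopifnot(is(x, "ScreenResult")); x@stage2Candidates
}

#' @rdname ScreenResult-accessors
#' @export
finalUp <- function(x) { stopifnot(is(x, "ScreenResult")); x@finalUp }

#' @rdname ScreenResult-accessors
#' @export
finalDown <- function(x) { stopifnot(is(x, "ScreenResult")); x@finalDown }

#' @rdname ScreenResult-accessors
#' @export
screenAudit <- function(x) { stopifnot(is(x, "ScreenResult")); x@audit }

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult (four-step screen)\n",
      sprintf("  stage 1 ethylene DEGs:      %d\n",
              length(object@stage1Degs)),
      sprintf("  stage 2 AZ-specific:        %d\n",
              length(object@stage2Candidates)),
      sprintf("  final (natural-concordant): %d up, %d down\n",
              length(object@finalUp), length(object@finalDown)), sep = "")
})

#' Tally final candidates by functional class
#'
#' @param x a [ScreenResult-class] (the union of the final up and down sets
#'   is tallied) or a character vector of contig ids.
#' @param annotation named character vector mapping contig id to functional
#'   class; contigs absent from the map are tallied as `"unknown"`.
#' @return named integer vector of class counts, decreasing.
#' @examples
#' summarizeClasses(c("a", "b", "c"),
#'                  c(a = "metabolism", b = "metabolism", c = "stress"))
#' @export
summarizeClasses <- function(x, annotation) {
  contigs <- if (is(x, "ScreenResult")) c(x@finalUp, x@finalDown) else x
  if (!length(contigs)) return(stats::setNames(integer(0), character(0)))
  cls <- annotation[contigs]
  cls[is.na(cls)] <- "unknown"
  tab <- table(cls)
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts[order(-counts, names(counts))]
}

#' Write a screen report
#'
#' Serializes a [ScreenResult-class] into a directory of TSV files:
#' `stage1_degs.tsv`, `stage2_candidates.tsv`, `final_up.tsv`,
#' `final_down.tsv`, `audit.tsv` (one row per test: contig, comparison,
#' x, y, N1, N2, p_raw, p_adj, direction), `natural_calls.tsv`, and —
#' when an annotation map is given — `class_summary.tsv`. Output is
#' deterministic: identical results produce byte-identical files.
#'
#' @param x a [ScreenResult-class].
#' @param dir output directory (created if needed).
#' @param annotation optional named character map contig -> functional
#'   class.
#' @return invisibly, the directory path.
#' @export
writeScreenResult <- function(x, dir, annotation = NULL) {
  stopifnot(is(x, "ScreenResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, file)
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  w(data.frame(contig_id = x@stage1Degs), "stage1_degs.tsv")
  w(data.frame(contig_id = x@stage2Candidates), "stage2_candidates.tsv")
  w(data.frame(contig_id = x@finalUp), "final_up.tsv")
  w(data.frame(contig_id = x@finalDown), "final_down.tsv")
  w(x@audit, "audit.tsv")
  if (nrow(x@naturalCalls)) w(x@naturalCalls, "natural_calls.tsv")
  if (!is.null(annotation)) {
    tal <- summarizeClasses(x, annotation)
    w(data.frame(class = names(tal), n = as.integer(tal)),
      "class_summary.tsv")
  }
  invisible(dir)
}
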