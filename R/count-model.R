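#' Construct a TagCountSet
#'
#' @param counts integer matrix of read counts, contigs as rownames and
#'   libraries as colnames.
#' @param libraryTotals total mapped reads per library. Defaults to the
#'   column sums of `counts`; supply explicitly when library totals include
#'   reads mapped to contigs absent from the table (must then be >= the
#'   column sums).
#' @param lengths optional integer transcript lengths (bp), one per contig,
#'   named or in row order. Required for [rpkm()].
#' @param sampleData optional data.frame with one row per library and columns
#'   `tissue`, `stage_dap`, `treatment`, `time_h` (rownames or a
#'   `library_id` column identify the library).
#' @return a validated [TagCountSet-class].
#' @examples
#' m <- matrix(c(1L, 3L, 2L, 4L), 2, dimnames = list(c("c1", "c2"), c("L1", "L2")))
#' tcs <- TagCountSet(m)
#' libraryTotals(tcs)  # column sums: 4, 6
#' @export
TagCountSet <- function(counts, libraryTotals = NULL, lengths = NULL,
                        sampleData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(libraryTotals))
    libraryTotals <- colSums(counts)
  if (!is.null(names(libraryTotals)))
    libraryTotals <- libraryTotals[colnames(counts)]
  cd <- DataFrame(library_total = as.numeric(libraryTotals),
                  row.names = colnames(counts))
  if (!is.null(sampleData)) {
    sampleData <- as.data.frame(sampleData)
    if ("library_id" %in% colnames(sampleData)) {
      rownames(sampleData) <- sampleData$library_id
      sampleData$library_id <- NULL
    }
    miss <- setdiff(colnames(counts), rownames(sampleData))
    if (length(miss))
      stop("sample sheet is missing libraries: ", paste(miss, collapse = ", "))
    extra <- setdiff(rownames(sampleData), colnames(counts))
    if (length(extra))
      stop("sample sheet has libraries absent from the count table: ",
           paste(extra, collapse = ", "))
    sampleData <- sampleData[colnames(counts), , drop = FALSE]
    # totals come from libraryTotals only; a stray column must not override
    for (col in setdiff(colnames(sampleData), "library_total"))
      cd[[col]] <- sampleData[[col]]
  }
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(lengths)) {
    if (!is.null(names(lengths))) {
      miss <- setdiff(rownames(counts), names(lengths))
      if (length(miss))
        stop("lengths are missing for contigs: ", paste(miss, collapse = ", "))
      lengths <- lengths[rownames(counts)]
    }
    rd$length_bp <- as.integer(lengths)
  }
  se <- SummarizedExperiment(assays = SimpleList(counts = counts),
                             colData = cd, rowData = rd)
  new("TagCountSet", se)
}

#' @describeIn TagCountSet read counts matrix.
#' @param object,x a `TagCountSet`.
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "TagCountSet", function(object) assay(object, "counts"))

#' Library totals and transcript lengths
#'
#' `libraryTotals()` returns the total mapped reads per library;
#' `transcriptLengths()` returns transcript lengths in bp (or `NULL` when
#' none were supplied); `hasLengths()` tests for their presence.
#'
#' @param x a [TagCountSet-class].
#' @return named numeric (totals), named integer or `NULL` (lengths), or a
#'   logical scalar.
#' @export
libraryTotals <- function(x) {
  stopifnot(is(x, "TagCountSet"))
  structure(colData(x)$library_total, names = colnames(x))
}

#' @rdname libraryTotals
#' @export
transcriptLengths <- function(x) {
  stopifnot(is(x, "TagCountSet"))
  if (!hasLengths(x)) return(NULL)
  structure(rowData(x)$length_bp, names = rownames(x))
}

#' @rdname libraryTotals
#' @export
hasLengths <- function(x) {
  stopifnot(is(x, "TagCountSet"))
  "length_bp" %in% colnames(rowData(x))
}

setMethod("show", "TagCountSet", function(object) {
  cat(sprintf("TagCountSet: %d contigs x %d libraries\n",
              nrow(object), ncol(object)))
  cat(sprintf("  library totals: %s\n",
              paste(format(libraryTotals(object), trim = TRUE,
                           scientific = FALSE), collapse = ", ")))
  cat(sprintf("  transcript lengths: %s\n",
              if (hasLengths(object)) "present" else "absent"))
  if ("tissue" %in% colnames(colData(object))) {
    cd <- colData(object)
    cells <- paste0(cd$tissue, cd$stage_dap, "/", cd$treatment,
                    ifelse(is.na(cd$time_h), "", paste0("@", cd$time_h, "h")))
    cat("  design: ", paste(cells, collapse = " "), "\n", sep = "")
  }
})

.parse_count_cells <- function(df, path) {
  for (j in seq_along(df)) {
    cells <- trimws(df[[j]])
    bad <- !grepl("^[0-9]+$", cells)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf(
        "%s: cell '%s' at contig '%s', library '%s' is not a non-negative integer",
        path, cells[i], rownames(df)[i], colnames(df)[j]))
    }
    df[[j]] <- as.integer(cells)
  }
  df
}

#' Read and write tag-count tables
#'
#' The count-matrix format is UTF-8 tab-separated text with header
#' `contig_id<TAB>lib1<TAB>lib2...` and integer cells. An optional totals
#' file is two-column TSV `library_id<TAB>total`; a lengths file is
#' two-column TSV `contig_id<TAB>length_bp`; a sample sheet is TSV with
#' columns `library_id`, `tissue`, `stage_dap`, `treatment`, `time_h`
#' (empty `time_h` for field libraries).
#'
#' @param path count-matrix TSV.
#' @param totalsPath,lengthsPath,samplePath optional companion files.
#' @return [readCountTable()] returns a validated [TagCountSet-class];
#'   [writeCountTable()] invisibly returns `path`.
#' @export
readCountTable <- function(path, totalsPath = NULL, lengthsPath = NULL,
                           samplePath = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop(path, ": expected a contig_id column plus at least one library column")
  ids <- trimws(df[[1L]])
  if (anyDuplicated(ids))
    stop(path, ": duplicate contig id '", ids[duplicated(ids)][1L], "'")
  df <- df[, -1L, drop = FALSE]
  rownames(df) <- ids
  df <- .parse_count_cells(df, path)
  counts <- as.matrix(df)
  totals <- NULL
  if (!is.null(totalsPath)) {
    tt <- utils::read.delim(totalsPath, header = TRUE)
    totals <- stats::setNames(as.numeric(tt[[2L]]), tt[[1L]])
  }
  lengths <- NULL
  if (!is.null(lengthsPath)) {
    lt <- utils::read.delim(lengthsPath, header = TRUE)
    lengths <- stats::setNames(as.integer(lt[[2L]]), lt[[1L]])
  }
  sheet <- NULL
  if (!is.null(samplePath)) {
    sheet <- utils::read.delim(samplePath,
                               colClasses = c(time_h = "numeric"))
  }
  TagCountSet(counts, libraryTotals = totals, lengths = lengths,
              sampleData = sheet)
}

#' @rdname readCountTable
#' @param x a [TagCountSet-class] to serialize.
#' @export
writeCountTable <- function(x, path, totalsPath = NULL, lengthsPath = NULL,
                            samplePath = NULL) {
  stopifnot(is(x, "TagCountSet"))
  df <- data.frame(contig_id = rownames(x), counts(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(totalsPath))
    utils::write.table(
      data.frame(library_id = colnames(x), total = libraryTotals(x)),
      totalsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(lengthsPath)) {
    if (!hasLengths(x)) stop("no transcript lengths to write")
    utils::write.table(
      data.frame(contig_id = rownames(x), length_bp = transcriptLengths(x)),
      lengthsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(samplePath)) {
    cd <- as.data.frame(colData(x))
    need <- c("tissue", "stage_dap", "treatment", "time_h")
    if (!all(need %in% colnames(cd))) stop("no sample metadata to write")
    utils::write.table(
      data.frame(library_id = colnames(x), cd[, need]),
      samplePath, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Abundance normalization
#'
#' `rpkm()` computes reads per kilobase of transcript per million mapped
#' reads, `count * 1e9 / (length_bp * library_total)`; it requires transcript
#' lengths. `countsPerMillion()` computes `count * 1e6 / library_total` and
#' needs no lengths (the view used for the ethylene tag-count arm).
#'
#' When totals are the column sums, `sum(rpkm * length_bp)` equals `1e9`
#' exactly in each library (abundance conservation).
#'
#' @param x a [TagCountSet-class].
#' @param contig,library optional single ids to extract one value; when
#'   omitted the full matrix is returned.
#' @return numeric matrix (or scalar when both ids are given).
#' @examples
#' m <- matrix(10L, 1, 1, dimnames = list("c1", "L1"))
#' tcs <- TagCountSet(m, libraryTotals = c(L1 = 1e6), lengths = c(c1 = 1000L))
#' rpkm(tcs, "c1", "L1")  # 10
#' @export
rpkm <- function(x, contig = NULL, library = NULL) {
  stopifnot(is(x, "TagCountSet"))
  if (!hasLengths(x))
    stop("rpkm requires transcript lengths; none are present")
  tot <- libraryTotals(x)
  if (any(tot <= 0)) stop("library totals must be positive")
  r <- counts(x) * 1e9 /
    outer(as.numeric(transcriptLengths(x)), as.numeric(tot))
  dimnames(r) <- dimnames(counts(x))
  .maybe_extract(r, contig, library)
}

#' @rdname rpkm
#' @export
countsPerMillion <- function(x, contig = NULL, library = NULL) {
  stopifnot(is(x, "TagCountSet"))
  tot <- libraryTotals(x)
  if (any(tot <= 0)) stop("library totals must be positive")
  r <- sweep(counts(x), 2L, tot, "/") * 1e6
  .maybe_extract(r, contig, library)
}

.maybe_extract <- function(r, contig, library) {
  if (!is.null(contig) && !all(contig %in% rownames(r)))
    stop("unknown contig: ", paste(setdiff(contig, rownames(r)), collapse = ", "))
  if (!is.null(library) && !all(library %in% colnames(r)))
    stop("unknown library: ", paste(setdiff(library, colnames(r)), collapse = ", "))
  if (!is.null(contig) && !is.null(library)) return(unname(r[contig, library]))
  if (!is.null(contig)) return(r[contig, ])
  if (!is.null(library)) return(r[, library])
  r
}

#' Ordered per-condition expression profile of one contig
#'
#' Assembles the abundance vector of one contig across the libraries matching
#' a design selector, ordered by ethylene time (hours) for ethylene libraries
#' or by stage (days after pollination) for field libraries. Abundances are
#' RPKM when transcript lengths are present, otherwise counts per million.
#'
#' @param x a [TagCountSet-class] with sample metadata.
#' @param contig contig id.
#' @param tissue,treatment design selector; `stageDap` may be omitted for
#'   field libraries (the profile then runs across stages).
#' @param stageDap stage selector (required for ethylene profiles).
#' @return named numeric vector (names are `"<t>h"` or `"<s>DAP"`).
#' @export
expressionProfile <- function(x, contig, tissue, treatment, stageDap = NULL) {
  stopifnot(is(x, "TagCountSet"))
  cd <- colData(x)
  need <- c("tissue", "stage_dap", "treatment", "time_h")
  if (!all(need %in% colnames(cd)))
    stop("expressionProfile requires sample metadata (tissue, stage_dap, treatment, time_h)")
  sel <- cd$tissue == tissue & cd$treatment == treatment
  if (!is.null(stageDap)) sel <- sel & cd$stage_dap == stageDap
  if (sum(sel) < 2L)
    stop(sprintf("selector %s/%s%s matches %d libraries; at least 2 required",
                 tissue, treatment,
                 if (is.null(stageDap)) "" else paste0("/", stageDap),
                 sum(sel)))
  libs <- colnames(x)[sel]
  if (treatment == "ethylene") {
    ord <- order(cd$time_h[sel])
    nms <- paste0(cd$time_h[sel][ord], "h")
  } else {
    ord <- order(cd$stage_dap[sel])
    nms <- paste0(cd$stage_dap[sel][ord], "DAP")
  }
  libs <- libs[ord]
  vals <- if (hasLengths(x)) rpkm(x)[contig, libs] else
    countsPerMillion(x)[contig, libs]
  stats::setNames(as.numeric(vals), nms)
}
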