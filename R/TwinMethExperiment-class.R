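#' Container for twin-cohort CpG methylation data
#'
#' `TwinMethExperiment` extends
#' [SummarizedExperiment::RangedSummarizedExperiment] for CpG methylation
#' beta-values measured on monozygotic (MZ) twin pairs. Rows are single CpG
#' sites (width-1 [GenomicRanges::GRanges], 1-based coordinates, sorted by
#' chromosome and position); columns are individuals. The `"beta"` assay is
#' mandatory; an integer `"coverage"` assay and, after [betaToM()], an `"M"`
#' assay are optional. `colData` carries the per-individual design table:
#' `individual_id`, `pair_id`, `twin_index` (1 or 2), and optionally `sex`
#' (`"F"`/`"M"`), `age_years`, repeated blood-pressure readings
#' `sbp1..sbp3`/`dbp1..dbp3`, `bmi`, `tg`, `fbg` and `case_status`.
#'
#' The validity method enforces the pairwise design: every `pair_id` occurs
#' exactly twice with twin indices 1 and 2, co-twins share their age, and
#' beta-values lie in \[0, 1\] where observed.
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment].
#' @export
setClass("TwinMethExperiment", contains = "RangedSummarizedExperiment")

.validTwinMeth <- function(object) {
  msg <- character(0)
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- SummarizedExperiment::assay(object, "beta")
    if (any(b < 0 | b > 1, na.rm = TRUE))
      msg <- c(msg, "beta-values must lie in [0, 1]")
  }
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr) && any(GenomicRanges::width(rr) != 1L))
    msg <- c(msg, "rows must be single CpG sites (width 1)")
  if (length(rr) > 1L &&
      !identical(GenomicRanges::order(rr), seq_along(rr)))
    msg <- c(msg, "CpGs must be sorted by (chrom, pos)")
  cd <- SummarizedExperiment::colData(object)
  need <- c("individual_id", "pair_id", "twin_index")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  } else if (ncol(object)) {
    tab <- table(cd$pair_id)
    if (any(tab != 2L)) {
      bad <- names(tab)[tab != 2L]
      msg <- c(msg, paste0("pair(s) without exactly two members: ",
                           paste(bad, collapse = ", ")))
    } else {
      idx <- split(as.integer(cd$twin_index), as.character(cd$pair_id))
      if (!all(vapply(idx, function(i) setequal(i, 1:2), logical(1))))
        msg <- c(msg, "each pair must carry twin_index 1 and 2")
      if ("age_years" %in% colnames(cd)) {
        ages <- split(cd$age_years, as.character(cd$pair_id))
        same <- vapply(ages, function(a)
          all(is.na(a)) || isTRUE(abs(diff(a)) < 1e-8), logical(1))
        if (!all(same)) msg <- c(msg, "co-twins must share age_years")
      }
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("TwinMethExperiment", .validTwinMeth)

#' Construct a TwinMethExperiment
#'
#' @param beta numeric matrix of methylation beta-values, CpGs x individuals;
#'   `NA` marks missing observations.
#' @param chrom character vector of chromosome names, one per CpG.
#' @param pos integer vector of 1-based CpG positions.
#' @param cohort data.frame (or DataFrame) of per-individual phenotypes with at
#'   least `individual_id`, `pair_id`, `twin_index`; row order must match the
#'   columns of `beta` (matched by `individual_id` against `colnames(beta)`
#'   when both are present).
#' @param coverage optional non-negative integer matrix of read depth, same
#'   shape as `beta`.
#' @param metadata optional list stored as object metadata.
#' @return a [TwinMethExperiment-class] with CpGs sorted by (chrom, pos).
#' @examples
#' sim <- simulateTwinCohort(simScenario("null", n_pairs = 5, n_cpgs = 20))
#' sim
#' @export
TwinMethExperiment <- function(beta, chrom, pos, cohort, coverage = NULL,
                               metadata = list()) {
  beta <- as.matrix(beta)
  if (length(chrom) != nrow(beta) || length(pos) != nrow(beta))
    stop("chrom/pos must have one entry per row of 'beta'")
  cohort <- S4Vectors::DataFrame(cohort)
  if (nrow(cohort) != ncol(beta))
    stop("'cohort' must have one row per column of 'beta'")
  if (!is.null(colnames(beta)) && "individual_id" %in% colnames(cohort)) {
    if (!setequal(colnames(beta), cohort$individual_id))
      stop("colnames(beta) do not match cohort$individual_id")
    cohort <- cohort[match(colnames(beta), cohort$individual_id), , drop = FALSE]
  }
  rownames(cohort) <- cohort$individual_id
  rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(as.integer(pos), width = 1L))
  assays <- list(beta = beta)
  if (!is.null(coverage)) {
    coverage <- as.matrix(coverage)
    stopifnot(all(dim(coverage) == dim(beta)))
    assays$coverage <- coverage
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowRanges = rr, colData = cohort, metadata = metadata)
  o <- GenomicRanges::order(SummarizedExperiment::rowRanges(se))
  se <- se[o, ]
  methods::new("TwinMethExperiment", se)
}

#' @describeIn TwinMethExperiment beta-value assay
#' @param x,object a `TwinMethExperiment`
#' @export
betaValues <- function(x) SummarizedExperiment::assay(x, "beta")

#' @describeIn TwinMethExperiment M-value assay (present after [betaToM()])
#' @export
mValues <- function(x) {
  if (!"M" %in% SummarizedExperiment::assayNames(x))
    stop("no 'M' assay: run betaToM() first")
  SummarizedExperiment::assay(x, "M")
}

#' @describeIn TwinMethExperiment coverage assay or NULL
#' @export
coverageValues <- function(x) {
  if (!"coverage" %in% SummarizedExperiment::assayNames(x)) return(NULL)
  SummarizedExperiment::assay(x, "coverage")
}

#' @describeIn TwinMethExperiment per-individual design table as a data.frame
#' @export
cohortData <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn TwinMethExperiment per-CpG simulation truth (`NULL` for real data)
#' @export
truthData <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"is_signal" %in% colnames(rd)) return(NULL)
  as.data.frame(rd[, intersect(c("is_signal", "true_effect", "true_direction"),
                               colnames(rd)), drop = FALSE])
}

#' @describeIn TwinMethExperiment simulated cell-fraction matrix (`NULL` for real data)
#' @export
cellFractions <- function(x) S4Vectors::metadata(x)$cell_fractions

setMethod("show", "TwinMethExperiment", function(object) {
  methods::callNextMethod()
  cd <- SummarizedExperiment::colData(object)
  if ("pair_id" %in% colnames(cd))
    cat("twin pairs:", length(unique(cd$pair_id)), "\n")
  ts <- truthData(object)
  if (!is.null(ts))
    cat("simulated truth: ", sum(ts$is_signal), " signal CpG(s)\n", sep = "")
})
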