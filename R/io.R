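# Plain-text interchange formats: methylation TSV (chrom, pos, one column per
# individual), phenotype CSV, truth TSV. Coordinates are 1-based in all of them.

#' Write / read the methylation matrix TSV
#'
#' Columns: `chrom`, `pos` (1-based) and one beta-value column per individual.
#'
#' @param se a [TwinMethExperiment-class].
#' @param path file path.
#' @export
writeMethylationTsv <- function(se, path) {
  rr <- SummarizedExperiment::rowRanges(se)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                   pos = GenomicRanges::start(rr),
                   betaValues(se), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMethylationTsv
#' @return `readMethylationTsv`: list with `beta`, `chrom`, `pos`.
#' @export
readMethylationTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("chrom", "pos") %in% colnames(df)))
  beta <- as.matrix(df[, setdiff(colnames(df), c("chrom", "pos")), drop = FALSE])
  list(beta = beta, chrom = df$chrom, pos = as.integer(df$pos))
}

#' Write / read the phenotype CSV
#' @param x a [TwinMethExperiment-class] or cohort data.frame.
#' @param path file path.
#' @export
writePhenotypeCsv <- function(x, path) {
  cd <- if (methods::is(x, "TwinMethExperiment")) cohortData(x) else x
  utils::write.csv(cd, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePhenotypeCsv
#' @export
readPhenotypeCsv <- function(path) {
  cd <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "pair_id", "twin_index")
  if (!all(need %in% colnames(cd)))
    stop("phenotype CSV must contain: ", paste(need, collapse = ", "))
  cd
}

#' Write the per-CpG simulation truth as TSV
#' @param se a simulated [TwinMethExperiment-class].
#' @param path file path.
#' @export
writeTruthTsv <- function(se, path) {
  ts <- truthData(se)
  if (is.null(ts)) stop("object carries no simulation truth")
  rr <- SummarizedExperiment::rowRanges(se)
  df <- cbind(chrom = as.character(GenomicRanges::seqnames(rr)),
              pos = GenomicRanges::start(rr), ts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a TwinMethExperiment from the standard input files
#' @param methylation path to the methylation TSV.
#' @param phenotype path to the phenotype CSV.
#' @return a [TwinMethExperiment-class].
#' @export
readTwinData <- function(methylation, phenotype) {
  m <- readMethylationTsv(methylation)
  cd <- readPhenotypeCsv(phenotype)
  cd <- cd[match(colnames(m$beta), cd$individual_id), , drop = FALSE]
  TwinMethExperiment(m$beta, m$chrom, m$pos, cd)
}
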