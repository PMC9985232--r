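# Nearest-gene annotation from user-supplied gene models, candidate-CpG
# case-control validation, and the intra-pair partial correlations used in the
# power argument.

#' Read gene models from BED or GFF3
#'
#' BED input (0-based half-open) is converted to 1-based inclusive on read by
#' the importer; GFF3 is taken as is, keeping `type == "gene"` records when a
#' type column is present. The gene symbol is taken from the first available
#' of `symbol`, `gene_name`, `Name`, `name`, `ID`.
#'
#' @param path file path (`.bed`, `.gff`, `.gff3`).
#' @return [GenomicRanges::GRanges] with a `symbol` column (and `ensembl_id`
#'   when present in the source).
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% colnames(mc) && any(mc$type == "gene"))
    gr <- gr[mc$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  sym_col <- intersect(c("symbol", "gene_name", "Name", "name", "ID"),
                       colnames(mc))[1]
  if (is.na(sym_col)) stop("no gene symbol column found in ", path)
  sym <- as.character(mc[[sym_col]])
  keep <- S4Vectors::DataFrame(symbol = sym)
  if ("ensembl_id" %in% colnames(mc)) keep$ensembl_id <- mc$ensembl_id
  S4Vectors::mcols(gr) <- keep
  gr
}

#' Nearest gene(s) for CpG positions
#'
#' Distance 0 when the CpG lies inside a gene body; CpGs inside several
#' overlapping genes, or exactly equidistant from two genes, report all of
#' them (semicolon-joined, gene-list order independent). A chromosome without
#' genes yields `NA`. No search radius is imposed; the distance is reported so
#' users can filter.
#'
#' @param cpgs [GenomicRanges::GRanges] of CpG sites (width 1) or EWAS rows.
#' @param genes [readGeneModels()] output.
#' @return data.frame with `symbols` (";"-joined or `NA`) and `distance` (bp,
#'   `NA` when no gene on the chromosome).
#' @export
nearestGene <- function(cpgs, genes) {
  symbols <- rep(NA_character_, length(cpgs))
  distance <- rep(NA_real_, length(cpgs))
  for (i in seq_along(cpgs)) {
    d <- suppressWarnings(GenomicRanges::distance(cpgs[i], genes))
    if (all(is.na(d))) next
    dmin <- min(d, na.rm = TRUE)
    hits <- which(!is.na(d) & d == dmin)
    sym <- sort(unique(genes$symbol[hits]))
    symbols[i] <- paste(sym, collapse = ";")
    distance[i] <- dmin
  }
  data.frame(symbols = symbols, distance = distance, stringsAsFactors = FALSE)
}

#' Annotate EWAS rows with their nearest gene(s)
#' @param rows [runEwas()] output.
#' @param genes [readGeneModels()] output.
#' @return `rows` with `gene_symbols` and `gene_distance` filled in.
#' @export
annotateNearestGene <- function(rows, genes) {
  ann <- nearestGene(rows, genes)
  rows$gene_symbols <- ann$symbols
  rows$gene_distance <- ann$distance
  rows
}

#' Two-sided Wilcoxon rank-sum test for case-control methylation
#'
#' Exact distribution when the smaller group has at most 8 observations and
#' the pooled values are tie-free; normal approximation with continuity
#' correction otherwise. Identical pooled values give p = 1. Being a rank
#' statistic, the p-value is invariant to strictly monotone transforms.
#'
#' @param case_values,control_values numeric vectors (each n >= 1).
#' @return two-sided p-value.
#' @export
wilcoxonCaseControl <- function(case_values, control_values) {
  case_values <- case_values[!is.na(case_values)]
  control_values <- control_values[!is.na(control_values)]
  if (!length(case_values) || !length(control_values))
    stop("each group needs at least one value")
  pooled <- c(case_values, control_values)
  if (length(unique(pooled)) == 1L) return(1)
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- min(length(case_values), length(control_values)) <= 8L && !ties
  stats::wilcox.test(case_values, control_values, exact = use_exact,
                     correct = TRUE)$p.value
}

#' Logistic case-control association of a CpG
#'
#' Maximum-likelihood log-odds of case status per methylation unit, with a
#' Wald p-value, adjusting for the supplied covariates (BMI, TG, FBG in the
#' standard design). Constant covariates are dropped with a warning; perfect
#' separation is flagged and no estimate returned.
#'
#' @param methylation numeric methylation values.
#' @param case_status logical / 0-1 vector.
#' @param covariates optional data.frame or matrix of adjustment covariates.
#' @return list with `beta`, `se`, `p`, `flag` (`"ok"`, `"separation"`).
#' @export
logisticAssoc <- function(methylation, case_status, covariates = NULL) {
  case_status <- as.integer(case_status)
  if (length(unique(case_status[!is.na(case_status)])) < 2L)
    stop("both outcome classes must be present")
  df <- data.frame(y = case_status, meth = methylation)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) > 1L,
                   logical(1))
    if (any(!keep))
      warning("dropping constant covariate(s): ",
              paste(names(covariates)[!keep], collapse = ", "))
    df <- cbind(df, covariates[, keep, drop = FALSE])
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, flag = "separation"))
  cf <- summary(fit)$coefficients["meth", ]
  list(beta = unname(cf[1]), se = unname(cf[2]), p = unname(cf[4]), flag = "ok")
}

#' Validate candidate CpGs in a case-control sample
#'
#' Per CpG: two-sided Wilcoxon rank-sum p, covariate-adjusted logistic
#' log-odds and p, and the methylation direction in cases (`hyper` when the
#' case median exceeds the control median, `hypo` when below, `NA` on a tie).
#'
#' @param beta_matrix CpGs x individuals methylation matrix.
#' @param case_status logical vector, one per individual.
#' @param covariates optional per-individual covariate data.frame (BMI, TG,
#'   FBG).
#' @return data.frame, one row per CpG.
#' @export
validateCpgs <- function(beta_matrix, case_status, covariates = NULL) {
  beta_matrix <- as.matrix(beta_matrix)
  case_status <- as.logical(case_status)
  out <- lapply(seq_len(nrow(beta_matrix)), function(i) {
    v <- beta_matrix[i, ]
    wp <- wilcoxonCaseControl(v[case_status], v[!case_status])
    la <- tryCatch(logisticAssoc(v, case_status, covariates),
                   error = function(e) list(beta = NA, se = NA, p = NA,
                                            flag = "error"))
    dmed <- stats::median(v[case_status], na.rm = TRUE) -
            stats::median(v[!case_status], na.rm = TRUE)
    data.frame(cpg = rownames(beta_matrix)[i] %||% as.character(i),
               wilcoxon_p = wp, logistic_beta = la$beta, logistic_p = la$p,
               direction = if (isTRUE(dmed > 0)) "hyper"
                           else if (isTRUE(dmed < 0)) "hypo" else NA_character_,
               flag = la$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Intra-pair partial correlation between blood pressure and methylation
#'
#' For each requested CpG, forms per-pair differences (twin 1 minus twin 2,
#' fixed ordering) of derived blood pressure and of the CpG M-value, then
#' correlates the two difference vectors after residualizing both on the
#' pair-level covariates (age and, when variable, sex; co-twins share both).
#' With no covariates this is the plain Pearson correlation of differences.
#' Flipping the twin ordering of one variable flips the sign; the magnitude
#' is what the power argument uses.
#'
#' @param se a [TwinMethExperiment-class] with `"M"` assay and derived BP.
#' @param trait `"SBP"` or `"DBP"`.
#' @param cpgs row indices (or names) of the CpGs to test; default all rows.
#' @param covariates character vector among `"age"`, `"sex"`; empty for the
#'   unadjusted correlation.
#' @return named numeric vector of partial correlations.
#' @export
intrapairPartialCorrelation <- function(se, trait = c("SBP", "DBP"),
                                        cpgs = NULL,
                                        covariates = c("age", "sex")) {
  trait <- match.arg(trait)
  cd <- cohortData(se)
  bp <- cd[[.traitColumn(trait)]]
  if (is.null(bp)) stop("run deriveBP() first")
  M <- mValues(se)
  if (is.null(cpgs)) cpgs <- seq_len(nrow(M))
  o1 <- which(cd$twin_index == 1L); o2 <- which(cd$twin_index == 2L)
  o2 <- o2[match(cd$pair_id[o1], cd$pair_id[o2])]
  dbp <- bp[o1] - bp[o2]
  Zp <- cbind(age = cd$age_years[o1], sex = .sexNumeric(cd$sex[o1]))
  Zp <- Zp[, intersect(covariates, colnames(Zp)), drop = FALSE]
  vapply(cpgs, function(ci) {
    dm <- M[ci, o1] - M[ci, o2]
    ok <- !is.na(dm) & !is.na(dbp) & stats::complete.cases(Zp)
    if (sum(ok) < 4L) stop("fewer than 4 complete discordant pairs")
    if (ncol(Zp) == 0L) return(stats::cor(dbp[ok], dm[ok]))
    Zo <- Zp[ok, , drop = FALSE]
    keep <- apply(Zo, 2, function(v) stats::sd(v) > 0)
    if (!any(keep)) return(stats::cor(dbp[ok], dm[ok]))
    Zo <- cbind(1, Zo[, keep, drop = FALSE])
    r1 <- stats::lm.fit(Zo, dbp[ok])$residuals
    r2 <- stats::lm.fit(Zo, dm[ok])$residuals
    stats::cor(r1, r2)
  }, numeric(1), USE.NAMES = !is.null(names(cpgs)))
}
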