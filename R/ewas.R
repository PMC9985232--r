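# Epigenome-wide association: per-CpG marginal GEE of M-values against blood
# pressure with pair clusters, BH FDR, tiered significance.

.traitColumn <- function(trait) paste0(tolower(trait), "_derived")

.sexNumeric <- function(sex) as.numeric(sex == "M")

# Assemble the per-individual covariate block: BP, age, sex, cell components.
.ewasDesign <- function(cd, trait, components) {
  col <- .traitColumn(trait)
  if (!col %in% colnames(cd)) stop("run deriveBP() first: no ", col, " column")
  Z <- cbind(bp = cd[[col]], age = cd$age_years, sex = .sexNumeric(cd$sex))
  if (!is.null(components)) {
    comp <- if (inherits(components, "CellComponents")) components$components
            else as.matrix(components)
    comp <- comp[match(cd$individual_id, rownames(comp)), , drop = FALSE]
    Z <- cbind(Z, comp)
  }
  rownames(Z) <- cd$individual_id
  Z
}

#' Per-CpG GEE association between methylation and blood pressure
#'
#' Fits the marginal model `M ~ BP + age + sex + components` (default
#' orientation, methylation as outcome) or `BP ~ M + age + sex + components`
#' with an exchangeable working correlation within twin pairs and sandwich
#' standard errors, and returns the Wald test of the association coefficient.
#'
#' @param m named numeric vector of M-values, one per individual.
#' @param cohort cohort data.frame with derived blood pressure (see
#'   [deriveBP()]), `age_years` and `sex`.
#' @param trait `"SBP"` or `"DBP"`.
#' @param components optional [refactorComponents()] output (or matrix) of
#'   cell-type covariates.
#' @param orientation `"m_outcome"` regresses M on BP (the default; cell
#'   composition confounds methylation); `"bp_outcome"` reverses it.
#' @param corstr working correlation for the pair clusters.
#' @param min_pairs minimum complete pairs required (default 10); below it the
#'   CpG is flagged and not fitted.
#' @return list with `coefficient`, `robust_se`, `p`, `n_pairs`, `flag`
#'   (`"ok"`, `"too_few_pairs"` or `"singular"`).
#' @export
fitGeeCpg <- function(m, cohort, trait = c("SBP", "DBP"), components = NULL,
                      orientation = c("m_outcome", "bp_outcome"),
                      corstr = c("exchangeable", "independence"),
                      min_pairs = 10L) {
  trait <- match.arg(trait); orientation <- match.arg(orientation)
  corstr <- match.arg(corstr)
  Z <- .ewasDesign(cohort, trait, components)
  if (!is.null(names(m))) m <- m[match(cohort$individual_id, names(m))]
  ok <- stats::complete.cases(Z) & !is.na(m)
  pid <- as.character(cohort$pair_id)[ok]
  n_pairs <- sum(table(pid) == 2L)
  if (n_pairs < min_pairs)
    return(list(coefficient = NA_real_, robust_se = NA_real_, p = NA_real_,
                n_pairs = n_pairs, flag = "too_few_pairs"))
  if (orientation == "m_outcome") {
    y <- m[ok]; X <- cbind(intercept = 1, Z[ok, , drop = FALSE])
  } else {
    y <- Z[ok, "bp"]
    X <- cbind(intercept = 1, m = m[ok], Z[ok, -1, drop = FALSE])
  }
  fit <- tryCatch(geeFit(y, X, pid, corstr = corstr), error = function(e) NULL)
  if (is.null(fit))
    return(list(coefficient = NA_real_, robust_se = NA_real_, p = NA_real_,
                n_pairs = n_pairs, flag = "singular"))
  j <- 2L  # association coefficient: bp (m_outcome) or m (bp_outcome)
  list(coefficient = unname(fit$coefficients[j]),
       robust_se = unname(fit$robust_se[j]), p = unname(fit$p_value[j]),
       n_pairs = n_pairs, flag = "ok")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment, order-preserving with the input;
#' `NA`s propagate.
#'
#' @param p_values vector of p-values in (0, 1].
#' @export
bhFdr <- function(p_values) {
  if (!length(p_values)) stop("empty p-value vector")
  stats::p.adjust(p_values, method = "BH")
}

#' Assign significance tiers to EWAS rows
#'
#' First matching tier wins: `genomewide` if FDR q < 0.05; else `suggestive`
#' if p < 1e-6; else `weaker_than_suggestive` if p < 1e-5; else `top` if
#' p < 1e-4; else `ns`.
#'
#' @param p_value,fdr_q numeric vectors.
#' @return character vector of tiers (`NA` where p is `NA`).
#' @export
classifyTiers <- function(p_value, fdr_q) {
  stopifnot(length(p_value) == length(fdr_q))
  tier <- rep(NA_character_, length(p_value))
  ok <- !is.na(p_value) & !is.na(fdr_q)
  tier[ok] <- ifelse(fdr_q[ok] < 0.05, "genomewide",
              ifelse(p_value[ok] < 1e-6, "suggestive",
              ifelse(p_value[ok] < 1e-5, "weaker_than_suggestive",
              ifelse(p_value[ok] < 1e-4, "top", "ns"))))
  tier
}

#' Run the epigenome-wide association scan
#'
#' Maps [fitGeeCpg()] over every CpG, applies [bhFdr()] over the successfully
#' fitted CpGs and [classifyTiers()], and returns one row per input CpG sorted
#' by ascending p (ties and flagged rows in (chrom, pos) order, flagged rows
#' last).
#'
#' @param se a [TwinMethExperiment-class] with an `"M"` assay ([betaToM()]).
#' @inheritParams fitGeeCpg
#' @return a [GenomicRanges::GRanges] with metadata columns `coefficient`,
#'   `robust_se`, `p_value`, `fdr_q`, `tier`, `gene_symbols` (NA until
#'   [annotateNearestGene()]), `n_pairs`, `flag`.
#' @export
runEwas <- function(se, trait = c("SBP", "DBP"), components = NULL,
                    orientation = c("m_outcome", "bp_outcome"),
                    corstr = c("exchangeable", "independence"),
                    min_pairs = 10L) {
  trait <- match.arg(trait); orientation <- match.arg(orientation)
  corstr <- match.arg(corstr)
  M <- mValues(se)
  cd <- cohortData(se)
  Z <- .ewasDesign(cd, trait, components)
  base_ok <- stats::complete.cases(Z)
  nC <- nrow(M)
  coefficient <- robust_se <- p_value <- rep(NA_real_, nC)
  n_pairs <- integer(nC); flag <- character(nC)

  # fast path when a CpG is complete: design, cluster split and cross-products
  # are shared across CpGs in the m_outcome orientation
  pid_all <- as.character(cd$pair_id)
  X_full <- cbind(intercept = 1, Z)
  ok_full <- base_ok
  ix_full <- .geeIndex(pid_all[ok_full])
  n_pairs_full <- ix_full$n_clusters - length(ix_full$s)

  for (i in seq_len(nC)) {
    m <- M[i, ]
    ok <- ok_full & !is.na(m)
    if (orientation == "m_outcome" && identical(unname(ok), unname(ok_full))) {
      if (n_pairs_full < min_pairs) {
        n_pairs[i] <- n_pairs_full; flag[i] <- "too_few_pairs"; next
      }
      res <- tryCatch(.geeCore(m[ok_full], X_full[ok_full, , drop = FALSE],
                               ix_full$a, ix_full$b, ix_full$s, corstr),
                      error = function(e) NULL)
      n_pairs[i] <- n_pairs_full
      if (is.null(res)) { flag[i] <- "singular"; next }
      se2 <- res$vcov[2, 2]
      coefficient[i] <- res$beta[2]; robust_se[i] <- sqrt(se2)
      p_value[i] <- 2 * stats::pnorm(-abs(res$beta[2] / sqrt(se2)))
      flag[i] <- "ok"
    } else {
      r <- fitGeeCpg(stats::setNames(m, cd$individual_id), cd, trait,
                     components, orientation, corstr, min_pairs)
      coefficient[i] <- r$coefficient; robust_se[i] <- r$robust_se
      p_value[i] <- r$p; n_pairs[i] <- r$n_pairs; flag[i] <- r$flag
    }
  }

  fdr_q <- rep(NA_real_, nC)
  fitted <- !is.na(p_value)
  if (any(fitted)) fdr_q[fitted] <- bhFdr(p_value[fitted])
  rows <- GenomicRanges::granges(SummarizedExperiment::rowRanges(se))
  S4Vectors::mcols(rows) <- S4Vectors::DataFrame(
    coefficient = coefficient, robust_se = robust_se, p_value = p_value,
    fdr_q = fdr_q, tier = classifyTiers(p_value, fdr_q),
    gene_symbols = NA_character_, n_pairs = n_pairs, flag = flag)
  # stable sort: ascending p, NA last, ties already in (chrom, pos) order
  rows[order(p_value, na.last = TRUE)]
}

#' Select top CpGs of an EWAS
#'
#' Top CpGs are those with association p below `p_cut` (default 1e-4),
#' regardless of tier label.
#'
#' @param rows [runEwas()] output.
#' @param p_cut p-value cutoff.
#' @export
topCpgs <- function(rows, p_cut = 1e-4) {
  rows[!is.na(rows$p_value) & rows$p_value < p_cut]
}

#' Write the EWAS table (Table-1 style TSV)
#' @param rows [runEwas()] output.
#' @param path file path.
#' @export
writeEwasTsv <- function(rows, path) {
  df <- data.frame(chromosome = as.character(GenomicRanges::seqnames(rows)),
                   position_bp = GenomicRanges::start(rows),
                   coefficient = rows$coefficient, p_value = rows$p_value,
                   FDR = rows$fdr_q,
                   gene_symbols = ifelse(is.na(rows$gene_symbols), "NA",
                                         rows$gene_symbols),
                   tier = rows$tier)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
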