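#' Derive mean blood pressure and apply the 3-SD outlier rule
#'
#' The per-individual blood pressure used by every downstream analysis is the
#' arithmetic mean of the three repeated readings. Derived values further than
#' three standard deviations from the cohort mean of the derived trait are set
#' to missing. The rule is applied to the derived mean (not the single
#' readings), per trait, across all individuals.
#'
#' @param x a [TwinMethExperiment-class] or a cohort `data.frame` with columns
#'   `sbp1..sbp3` / `dbp1..dbp3`.
#' @param trait `"SBP"` or `"DBP"`.
#' @return `x` with a `sbp_derived` / `dbp_derived` column added.
#' @examples
#' co <- data.frame(individual_id = c("a", "b"), pair_id = "p", twin_index = 1:2,
#'                  sbp1 = c(120, 118), sbp2 = c(124, 120), sbp3 = c(122, 119))
#' deriveBP(co, "SBP")$sbp_derived
#' @export
deriveBP <- function(x, trait = c("SBP", "DBP")) {
  trait <- match.arg(trait)
  if (methods::is(x, "TwinMethExperiment")) {
    cd <- deriveBP(cohortData(x), trait)
    SummarizedExperiment::colData(x) <- S4Vectors::DataFrame(cd, row.names = cd$individual_id)
    return(x)
  }
  pre <- tolower(trait)
  cols <- paste0(pre, 1:3)
  if (!all(cols %in% colnames(x)))
    stop("need three readings: columns ", paste(cols, collapse = ", "))
  readings <- as.matrix(x[, cols])
  n_ok <- rowSums(!is.na(readings))
  if (any(n_ok < 3L)) {
    bad <- x$individual_id[n_ok < 3L]
    warning("fewer than three ", trait, " readings; record(s) rejected: ",
            paste(bad, collapse = ", "))
  }
  derived <- ifelse(n_ok == 3L, rowMeans(readings), NA_real_)
  mu <- mean(derived, na.rm = TRUE)
  s <- stats::sd(derived, na.rm = TRUE)
  out <- if (is.na(s) || s == 0) rep(FALSE, length(derived))
         else !is.na(derived) & abs(derived - mu) > 3 * s
  derived[out] <- NA_real_
  if (any(out))
    message(sum(out), " derived ", trait, " value(s) beyond mean +/- 3 SD set missing")
  x[[paste0(pre, "_derived")]] <- derived
  x
}

#' Keep blood-pressure-discordant twin pairs
#'
#' Retains exactly the pairs whose absolute intra-pair difference in derived
#' blood pressure meets the discordance threshold (inclusive): default
#' 2 mmHg for SBP and 1 mmHg for DBP. Pairs with a missing derived value in
#' either co-twin are dropped, since the pairwise design needs both members.
#' The median and 95% range of |difference| over the kept pairs are reported
#' via `message()` and attached as attribute `"discordance"`.
#'
#' @inheritParams deriveBP
#' @param min_diff discordance threshold in mmHg.
#' @return the filtered object, same class as `x`.
#' @export
selectDiscordantPairs <- function(x, trait = c("SBP", "DBP"),
                                  min_diff = if (match.arg(trait) == "SBP") 2 else 1) {
  trait <- match.arg(trait)
  if (min_diff <= 0) stop("min_diff must be positive")
  cd <- if (methods::is(x, "TwinMethExperiment")) cohortData(x) else x
  col <- paste0(tolower(trait), "_derived")
  if (!col %in% colnames(cd)) stop("run deriveBP() first: no ", col, " column")
  tab <- table(cd$pair_id)
  if (any(tab != 2L))
    stop("unpaired individual(s) in pair(s): ",
         paste(names(tab)[tab != 2L], collapse = ", "))
  sp <- split(cd[[col]], as.character(cd$pair_id))
  diffs <- vapply(sp, function(v) abs(v[1] - v[2]), numeric(1))
  keep_pairs <- names(diffs)[!is.na(diffs) & diffs >= min_diff]
  kept <- abs(diffs[keep_pairs])
  rep_stats <- c(median = stats::median(kept),
                 lo95 = unname(stats::quantile(kept, 0.025)),
                 hi95 = unname(stats::quantile(kept, 0.975)))
  message("kept ", length(keep_pairs), "/", length(diffs), " ", trait,
          "-discordant pairs (median |d|=", round(rep_stats[1], 1),
          ", 95% range ", round(rep_stats[2], 1), "-", round(rep_stats[3], 1), ")")
  keep <- cd$pair_id %in% keep_pairs
  out <- if (methods::is(x, "TwinMethExperiment")) x[, keep] else x[keep, , drop = FALSE]
  attr(out, "discordance") <- rep_stats
  out
}

#' Cap read coverage at a per-sample quantile
#'
#' Coverage values above each sample's `quantile` (default the 90th
#' percentile) are replaced by that percentile value; beta-values are left
#' untouched. Capping is per sample, following the convention of smoothing
#' pipelines for bisulfite data.
#'
#' @param se a [TwinMethExperiment-class] with a coverage assay.
#' @param quantile cap quantile in (0, 1).
#' @export
capCoverage <- function(se, quantile = 0.9) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  cov <- coverageValues(se)
  if (is.null(cov)) stop("no coverage assay present")
  caps <- apply(cov, 2, stats::quantile, probs = quantile, na.rm = TRUE)
  capped <- pmin(cov, matrix(caps, nrow(cov), ncol(cov), byrow = TRUE))
  SummarizedExperiment::assay(se, "coverage") <- capped
  se
}

#' Drop CpGs failing quality control
#'
#' Removes CpGs whose mean beta-value (over non-missing observations) is below
#' `min_mean_beta`, or that have strictly more than `max_missing` missing
#' observations. Counts removed per rule are stored in
#' `metadata(se)$qc_report`.
#'
#' @param se a [TwinMethExperiment-class].
#' @param min_mean_beta minimum mean methylation level (default 0.01).
#' @param max_missing maximum tolerated missing observations per CpG
#'   (default 10; the rule is strict, 10 missing is kept).
#' @export
qcFilterCpgs <- function(se, min_mean_beta = 0.01, max_missing = 10L) {
  b <- betaValues(se)
  mean_beta <- rowMeans(b, na.rm = TRUE)
  n_miss <- rowSums(is.na(b))
  low <- !is.na(mean_beta) & mean_beta < min_mean_beta
  low[is.nan(mean_beta)] <- TRUE            # all-missing CpG has no signal
  many <- n_miss > max_missing
  drop <- low | many
  report <- c(n_input = nrow(se), n_low_beta = sum(low), n_many_missing = sum(many),
              n_dropped = sum(drop), n_kept = sum(!drop))
  if (all(drop)) warning("all CpGs removed by QC")
  out <- se[!drop, ]
  S4Vectors::metadata(out)$qc_report <- report
  out
}

#' Transform beta-values to M-values
#'
#' M = log2(beta / (1 - beta)), the standard logit2 M-value. Beta-values are
#' clipped to `clip` beforehand so boundary values stay finite; missingness
#' propagates. The transform is strictly increasing and antisymmetric about
#' beta = 0.5.
#'
#' @param se a [TwinMethExperiment-class].
#' @param clip two clip bounds inside (0, 1).
#' @return `se` with an `"M"` assay added.
#' @export
betaToM <- function(se, clip = c(0.001, 0.999)) {
  stopifnot(length(clip) == 2, clip[1] > 0, clip[2] < 1, clip[1] < clip[2])
  b <- betaValues(se)
  if (any(b < 0 | b > 1, na.rm = TRUE)) stop("beta-values outside [0, 1]")
  b <- pmin(pmax(b, clip[1]), clip[2])
  SummarizedExperiment::assays(se)$M <- log2(b / (1 - b))
  se
}
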