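# ICE FALCON: Inference about Causation through Examination of Familial
# Confounding. For a twin pair, three GEE models are compared:
#   M1  y_self ~ x_self              -> beta_self
#   M2  y_self ~ x_cotwin            -> beta_cotwin
#   M3  y_self ~ x_self + x_cotwin   -> beta'_self, beta'_cotwin
# Causation in the modeled direction attenuates the co-twin coefficient much
# more than the self coefficient once the self exposure is in the model;
# familial confounding attenuates both alike.

#' Reshape a twin cohort to ICE FALCON pair-long format
#'
#' Produces two rows per pair; in each row one twin serves as "self" with the
#' co-twin's exposure alongside, so every individual appears once as self.
#'
#' @param cohort cohort data.frame (two rows per `pair_id`).
#' @param x,y named per-individual exposure / outcome vectors (names are
#'   `individual_id`s) or unnamed vectors aligned with `cohort` rows.
#' @return data.frame with `pair_id`, `self_id`, `y_self`, `x_self`,
#'   `x_cotwin`, `age_years`, `sex`; rows of a pair are adjacent.
#' @export
reshapePairs <- function(cohort, x, y) {
  ids <- cohort$individual_id
  if (!is.null(names(x))) x <- x[match(ids, names(x))]
  if (!is.null(names(y))) y <- y[match(ids, names(y))]
  if (anyNA(x) || anyNA(y)) {
    bad_pairs <- unique(cohort$pair_id[is.na(x) | is.na(y)])
    stop("incomplete pair(s): ", paste(bad_pairs, collapse = ", "))
  }
  idx <- split(seq_along(ids), as.character(cohort$pair_id))
  if (any(lengths(idx) != 2L))
    stop("every pair_id must appear exactly twice")
  self <- unlist(lapply(idx, function(i) c(i[1], i[2])), use.names = FALSE)
  cotwin <- unlist(lapply(idx, function(i) c(i[2], i[1])), use.names = FALSE)
  data.frame(pair_id = cohort$pair_id[self], self_id = ids[self],
             y_self = y[self], x_self = x[self], x_cotwin = x[cotwin],
             age_years = cohort$age_years[self], sex = cohort$sex[self],
             row.names = NULL, stringsAsFactors = FALSE)
}

# fit the three models on given row indices of the pair-long table; returns
# the two coefficient changes (and optionally all four coefficients)
.iceChanges <- function(y, xs, xc, Z, pid, full = FALSE) {
  f1 <- .geeQuick(y, cbind(1, xs, Z), pid)
  f2 <- .geeQuick(y, cbind(1, xc, Z), pid)
  f3 <- .geeQuick(y, cbind(1, xs, xc, Z), pid)
  out <- c(self_change = f1$beta[2] - f3$beta[2],
           cotwin_change = f2$beta[2] - f3$beta[3])
  if (full)
    list(changes = out, beta_self = f1$beta[2], beta_cotwin = f2$beta[2],
         beta_self_full = f3$beta[2], beta_cotwin_full = f3$beta[3],
         se = c(f1 = sqrt(f1$vcov[2, 2]), f2 = sqrt(f2$vcov[2, 2])))
  else out
}

# minimal GEE call on a pair-long table whose rows come pair-adjacent
.geeQuick <- function(y, X, pid) {
  n <- length(y)
  a <- seq(1L, n, by = 2L); b <- seq(2L, n, by = 2L)
  .geeCore(y, X, a, b, integer(0), "exchangeable")
}

#' Fit ICE FALCON for one exposure/outcome pair
#'
#' Fits the marginal and joint GEE models (pair clusters, exchangeable working
#' correlation, age and sex plus any extra covariates), computes the self and
#' co-twin coefficient changes, and assesses them by a pair-level
#' nonparametric bootstrap: pairs are resampled with replacement, the changes
#' recomputed, and two-sided normal-approximation p-values formed from the
#' bootstrap standard errors. The change ratio
#' `|cotwin_change| / |self_change|` is reported only when the co-twin change
#' is significant at `alpha`; verdicts follow [classifyCausality()].
#'
#' @param table a [reshapePairs()] data.frame.
#' @param direction `"meth_to_bp"` (x is methylation) or `"bp_to_meth"`.
#' @param covariates optional numeric matrix of extra per-self-row covariates
#'   (e.g. cell components), aligned with `table` rows.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param ratio_threshold,alpha verdict parameters, see [classifyCausality()].
#' @return object of class `IceFalconFit` with the six coefficients, the two
#'   changes with bootstrap p-values, `ratio` (NA when undefined), `verdict`
#'   and a `flag` (`"ok"` or `"degenerate_bootstrap"`).
#' @export
iceFalconFit <- function(table, direction = c("meth_to_bp", "bp_to_meth"),
                         covariates = NULL, n_boot = 1000L, seed = NULL,
                         ratio_threshold = 1.5, alpha = 0.05) {
  direction <- match.arg(direction)
  P <- length(unique(table$pair_id))
  if (P < 20L) stop("need at least 20 complete pairs, got ", P)
  if (nrow(table) != 2L * P) stop("table must have two rows per pair")
  if (!is.null(seed)) set.seed(seed)
  Z <- cbind(age = table$age_years, sex = .sexNumeric(table$sex))
  if (!is.null(covariates)) Z <- cbind(Z, as.matrix(covariates))
  y <- table$y_self; xs <- table$x_self; xc <- table$x_cotwin
  obs <- .iceChanges(y, xs, xc, Z, table$pair_id, full = TRUE)

  pair_rows <- matrix(seq_len(2L * P), nrow = 2L)   # rows come pair-adjacent
  boots <- matrix(NA_real_, n_boot, 2L)
  for (bi in seq_len(n_boot)) {
    rows <- as.vector(pair_rows[, sample.int(P, P, replace = TRUE)])
    boots[bi, ] <- tryCatch(
      .iceChanges(y[rows], xs[rows], xc[rows], Z[rows, , drop = FALSE], NULL),
      error = function(e) c(NA_real_, NA_real_))
  }
  bsd <- apply(boots, 2, stats::sd, na.rm = TRUE)
  flag <- "ok"
  if (any(!is.finite(bsd)) || any(bsd == 0)) {
    flag <- "degenerate_bootstrap"
    p_changes <- c(NA_real_, NA_real_)
  } else {
    p_changes <- 2 * stats::pnorm(-abs(obs$changes / bsd))
  }
  ratio_raw <- abs(obs$changes[["cotwin_change"]]) / abs(obs$changes[["self_change"]])
  fit <- structure(list(
    direction = direction,
    beta_self = obs$beta_self, beta_cotwin = obs$beta_cotwin,
    beta_self_full = obs$beta_self_full, beta_cotwin_full = obs$beta_cotwin_full,
    self_change = obs$changes[["self_change"]],
    cotwin_change = obs$changes[["cotwin_change"]],
    p_self_change = p_changes[1], p_cotwin_change = p_changes[2],
    ratio_raw = ratio_raw,
    ratio = if (!is.na(p_changes[2]) && p_changes[2] < alpha) ratio_raw else NA_real_,
    n_pairs = P, n_boot = n_boot, flag = flag), class = "IceFalconFit")
  fit$verdict <- classifyCausality(fit, ratio_threshold = ratio_threshold,
                                   alpha = alpha)
  fit
}

#' @export
print.IceFalconFit <- function(x, ...) {
  cat("ICE FALCON [", x$direction, "], ", x$n_pairs, " pairs\n",
      "  self change:   ", signif(x$self_change, 4), " (p=",
      signif(x$p_self_change, 3), ")\n",
      "  cotwin change: ", signif(x$cotwin_change, 4), " (p=",
      signif(x$p_cotwin_change, 3), ")\n",
      "  ratio: ", ifelse(is.na(x$ratio), "-", signif(x$ratio, 4)),
      "   verdict: ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' Verdict from an ICE FALCON fit
#'
#' A significant co-twin change (`p_cotwin_change < alpha`) with change ratio
#' above `ratio_threshold` supports causation in the modeled direction; a
#' significant co-twin change with similar self and co-twin changes (ratio at
#' or below the threshold) supports familial confounding; anything else is
#' inconclusive and the ratio is left unreported.
#'
#' @param fit an [iceFalconFit()] result (or compatible list).
#' @param ratio_threshold causal ratio cutoff (default 1.5).
#' @param alpha significance level for the co-twin change.
#' @return `"causal"`, `"familial_confounding"` or `"inconclusive"`.
#' @export
classifyCausality <- function(fit, ratio_threshold = 1.5, alpha = 0.05) {
  p <- fit$p_cotwin_change
  ratio <- fit$ratio_raw %||% fit$ratio
  if (is.na(p) || is.na(ratio) || p >= alpha) return("inconclusive")
  if (ratio > ratio_threshold) "causal" else "familial_confounding"
}

#' Bidirectional ICE FALCON over the top EWAS CpGs
#'
#' For every top CpG fits both causal directions: methylation to blood
#' pressure (y = BP, x = M, covariates age + sex) and blood pressure to
#' methylation (y = M, x = BP, covariates age + sex + cell components).
#' Pairs with a missing M-value at a CpG are dropped for that CpG.
#'
#' @param se a [TwinMethExperiment-class] with `"M"` assay and derived BP.
#' @param trait `"SBP"` or `"DBP"`.
#' @param top_rows [topCpgs()] output (any GRanges subset of EWAS rows).
#' @param components optional cell components for the bp_to_meth direction.
#' @param n_boot,ratio_threshold,alpha see [iceFalconFit()].
#' @param seed integer; per-fit seeds are derived from it, so results are
#'   reproducible.
#' @return data.frame mirroring the causal-inference table: one row per CpG
#'   and direction.
#' @export
runIceFalcon <- function(se, trait = c("SBP", "DBP"), top_rows,
                         components = NULL, n_boot = 1000L, seed = 1L,
                         ratio_threshold = 1.5, alpha = 0.05) {
  trait <- match.arg(trait)
  cd <- cohortData(se)
  bp <- cd[[.traitColumn(trait)]]
  if (is.null(bp)) stop("run deriveBP() first")
  M <- mValues(se)
  rr <- SummarizedExperiment::rowRanges(se)
  key <- paste(GenomicRanges::seqnames(rr), GenomicRanges::start(rr))
  comp <- if (is.null(components)) NULL
          else if (inherits(components, "CellComponents")) components$components
          else as.matrix(components)
  out <- list(); k <- 0L
  for (i in seq_along(top_rows)) {
    ri <- match(paste(as.character(GenomicRanges::seqnames(top_rows))[i],
                      GenomicRanges::start(top_rows)[i]), key)
    m <- M[ri, ]
    keep_pair <- !(cd$pair_id %in% cd$pair_id[is.na(m) | is.na(bp)])
    sub <- cd[keep_pair, , drop = FALSE]
    for (dir in c("meth_to_bp", "bp_to_meth")) {
      k <- k + 1L
      tb <- if (dir == "meth_to_bp")
        reshapePairs(sub, x = m[keep_pair], y = bp[keep_pair])
      else reshapePairs(sub, x = bp[keep_pair], y = m[keep_pair])
      covar <- NULL
      if (dir == "bp_to_meth" && !is.null(comp))
        covar <- comp[match(tb$self_id, rownames(comp)), , drop = FALSE]
      fit <- tryCatch(
        iceFalconFit(tb, dir, covariates = covar, n_boot = n_boot,
                     seed = seed + 7L * k, ratio_threshold = ratio_threshold,
                     alpha = alpha),
        error = function(e) NULL)
      row <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(top_rows))[i],
        pos = GenomicRanges::start(top_rows)[i],
        gene = if (!is.null(top_rows$gene_symbols)) top_rows$gene_symbols[i]
               else NA_character_,
        direction = dir, stringsAsFactors = FALSE)
      if (is.null(fit)) {
        row <- cbind(row, beta_self = NA, beta_cotwin = NA, beta_self_full = NA,
                     beta_cotwin_full = NA, self_change = NA, p_self_change = NA,
                     cotwin_change = NA, p_cotwin_change = NA, ratio = NA,
                     verdict = "inconclusive", flag = "fit_failed")
      } else {
        row <- cbind(row, beta_self = fit$beta_self,
                     beta_cotwin = fit$beta_cotwin,
                     beta_self_full = fit$beta_self_full,
                     beta_cotwin_full = fit$beta_cotwin_full,
                     self_change = fit$self_change,
                     p_self_change = fit$p_self_change,
                     cotwin_change = fit$cotwin_change,
                     p_cotwin_change = fit$p_cotwin_change,
                     ratio = fit$ratio, verdict = fit$verdict, flag = fit$flag)
      }
      out[[k]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write the causal-inference table (Table-3 style TSV)
#' @param df [runIceFalcon()] output.
#' @param path file path.
#' @export
writeIceFalconTsv <- function(df, path) {
  df$ratio <- ifelse(is.na(df$ratio), "-", formatC(df$ratio, digits = 3, format = "f"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
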