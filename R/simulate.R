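#' Define a twin-cohort simulation scenario
#'
#' A scenario fixes the causal structure and the statistical moments of a
#' synthetic MZ-twin methylation study. Four causal structures are supported:
#' \describe{
#'   \item{`"null"`}{no methylation--blood-pressure association at all; every
#'     CpG is a null CpG.}
#'   \item{`"meth_causal"`}{the mean of the signal-CpG methylation latents
#'     drives systolic blood pressure with slope `causal_effect`
#'     (mmHg per M-value unit).}
#'   \item{`"bp_causal"`}{the arrow is reversed: blood pressure shifts the
#'     signal-CpG M-values by `causal_effect` (M-units per mmHg).}
#'   \item{`"confounded"`}{no causal arrow (`causal_effect` forced to 0) but
#'     signal CpGs and blood pressure both load on the shared familial factor.}
#' }
#'
#' Each pair draws a standard-normal familial factor representing the combined
#' genetic and shared-environment background of the co-twins. Signal-CpG
#' M-value latents have standard deviation `familial_load_m` and within-pair
#' correlation `intra_pair_rho`; null CpGs get the same marginal structure from
#' pair-private factors that are independent of blood pressure. Observed
#' beta-values are a Dirichlet-weighted mixture over `n_cell_types`
#' Beta(0.4, 0.4) cell-type basis methylomes, shifted by the latent M-values,
#' perturbed by truncated Gaussian noise (sd `beta_noise_sd`) and clipped to
#' (0.001, 0.999).
#'
#' Default moments were calibrated to the cohort this design emulates:
#' unique-environment SBP noise of 16 mmHg plus a familial loading of 8 mmHg
#' gives a total SBP sd near 20 mmHg and a median intra-pair |dSBP| of
#' 15--18 mmHg after discordance selection; `intra_pair_rho = 0.6` mirrors a
#' blood-pressure heritability of about 0.6.
#'
#' @param name one of `"null"`, `"meth_causal"`, `"bp_causal"`, `"confounded"`.
#' @param n_pairs number of MZ pairs.
#' @param n_cpgs total number of CpG sites.
#' @param n_signal_cpgs number of signal CpGs (ignored under `"null"`).
#' @param causal_effect causal slope; mmHg per M-unit for `"meth_causal"`,
#'   M-units per mmHg for `"bp_causal"`. Defaults: 15, 0.05, otherwise 0.
#' @param familial_load_m sd (M-units) of the signal/null CpG latent.
#' @param familial_load_bp familial loading on SBP (mmHg).
#' @param intra_pair_rho within-pair correlation of the CpG latents, in \[0,1).
#' @param n_cell_types,dirichlet_alpha cell-mixture dimension and Dirichlet
#'   concentration (recycled to `n_cell_types`).
#' @param cell_bp_effect mmHg shift of SBP per unit deviation of the first
#'   cell-type fraction from its expectation; 0 disables the cell-composition
#'   confound.
#' @param bp_noise_sd unique-environment SBP noise sd (mmHg).
#' @param beta_noise_sd technical noise sd on the beta scale.
#' @param missing_rate per-entry probability that a beta-value is missing.
#' @param seed integer seed; all randomness derives from it.
#' @return a `SimScenario` (validated list).
#' @export
simScenario <- function(name = c("null", "meth_causal", "bp_causal", "confounded"),
                        n_pairs = 60L, n_cpgs = 2000L,
                        n_signal_cpgs = min(10L, n_cpgs),
                        causal_effect = NULL,
                        familial_load_m = 1, familial_load_bp = 8,
                        intra_pair_rho = 0.6,
                        n_cell_types = 5L, dirichlet_alpha = c(12, 6, 4, 2, 1),
                        cell_bp_effect = 0,
                        bp_noise_sd = 16, beta_noise_sd = 0.02,
                        missing_rate = 0, seed = 1L) {
  name <- match.arg(name)
  if (is.null(causal_effect))
    causal_effect <- switch(name, meth_causal = 15, bp_causal = 0.02, 0)
  if (name %in% c("null", "confounded")) causal_effect <- 0
  sc <- list(name = name, n_pairs = as.integer(n_pairs),
             n_cpgs = as.integer(n_cpgs),
             n_signal_cpgs = as.integer(n_signal_cpgs),
             causal_effect = causal_effect,
             familial_load_m = familial_load_m,
             familial_load_bp = familial_load_bp,
             intra_pair_rho = intra_pair_rho,
             n_cell_types = as.integer(n_cell_types),
             dirichlet_alpha = rep_len(dirichlet_alpha, n_cell_types),
             cell_bp_effect = cell_bp_effect,
             bp_noise_sd = bp_noise_sd, beta_noise_sd = beta_noise_sd,
             missing_rate = missing_rate, seed = as.integer(seed))
  if (sc$n_pairs <= 0L || sc$n_cpgs <= 0L)
    stop("n_pairs and n_cpgs must be positive")
  if (sc$n_signal_cpgs < 0L || sc$n_signal_cpgs > sc$n_cpgs)
    stop("n_signal_cpgs must lie in [0, n_cpgs]")
  if (sc$intra_pair_rho < 0 || sc$intra_pair_rho >= 1)
    stop("intra_pair_rho must lie in [0, 1)")
  if (!all(is.finite(c(sc$familial_load_m, sc$familial_load_bp, sc$causal_effect))))
    stop("loadings and causal_effect must be finite")
  if (any(sc$dirichlet_alpha <= 0)) stop("dirichlet_alpha must be positive")
  if (sc$missing_rate < 0 || sc$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  class(sc) <- "SimScenario"
  sc
}

#' @export
print.SimScenario <- function(x, ...) {
  cat("SimScenario <", x$name, ">: ", x$n_pairs, " pairs, ", x$n_cpgs,
      " CpGs (", x$n_signal_cpgs, " signal), causal_effect=", x$causal_effect,
      ", rho=", x$intra_pair_rho, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate an MZ twin methylation cohort
#'
#' Draws a complete synthetic study from a [simScenario()]: a phenotype table
#' (three repeated SBP/DBP readings per individual, age, sex, BMI, TG, FBG,
#' hypertension case status) and a CpG beta-value matrix with cell-type mixture
#' structure and coverage, plus the per-CpG simulation truth.
#'
#' @param scenario a [simScenario()].
#' @return a [TwinMethExperiment-class]; `rowData` holds the truth
#'   (`is_signal`, `true_effect`, `true_direction`), metadata holds the
#'   scenario, the `cell_fractions` simplex (individuals x cell types) and the
#'   noise-free latent M matrix `latent_m` used by calibration tests.
#' @examples
#' se <- simulateTwinCohort(simScenario("meth_causal", n_pairs = 20, n_cpgs = 50))
#' dim(betaValues(se))
#' @export
simulateTwinCohort <- function(scenario) {
  stopifnot(inherits(scenario, "SimScenario"))
  sc <- scenario
  set.seed(sc$seed)
  P <- sc$n_pairs; N <- 2L * P; C <- sc$n_cpgs
  S <- if (sc$name == "null") 0L else sc$n_signal_cpgs
  rho <- sc$intra_pair_rho; lam <- sc$familial_load_m

  pair_id <- sprintf("P%04d", seq_len(P))
  individual_id <- sprintf("I%04d", seq_len(N))
  pair_of <- rep(seq_len(P), each = 2L)
  twin_index <- rep(1:2, P)

  age <- pmin(pmax(round(stats::rnorm(P, 52, 7)), 30), 80)
  sex <- ifelse(stats::rbinom(P, 1, 0.5) == 1L, "M", "F")
  Ff <- stats::rnorm(P)                      # shared familial factor per pair

  # CpG coordinates: one chromosome, realistic irregular spacing
  pos <- 10000L + cumsum(sample(20:1500, C, replace = TRUE))
  chrom <- rep("chr1", C)
  signal_idx <- if (S > 0L) sort(sample.int(C, S)) else integer(0)

  # latent M-value structure: sd lam, within-pair correlation rho
  latent <- matrix(0, C, N)
  a <- sqrt(rho); b <- sqrt(1 - rho)
  if (S > 0L) {
    e_sig <- matrix(stats::rnorm(S * N), S, N)
    if (sc$name == "bp_causal") {
      # reversed arrow: methylation's familial correlation comes from
      # CpG-private pair factors; its only link to BP is the causal term
      # added below, so the scenario isolates direction recovery
      Gs <- matrix(stats::rnorm(S * P), S, P)
      latent[signal_idx, ] <- lam * (a * Gs[, pair_of, drop = FALSE] + b * e_sig)
    } else {
      latent[signal_idx, ] <- lam * (a * matrix(Ff[pair_of], S, N, byrow = TRUE) +
                                     b * e_sig)
    }
  }
  null_idx <- setdiff(seq_len(C), signal_idx)
  if (length(null_idx)) {
    G <- matrix(stats::rnorm(length(null_idx) * P), length(null_idx), P)
    e0 <- matrix(stats::rnorm(length(null_idx) * N), length(null_idx), N)
    latent[null_idx, ] <- lam * (a * G[, pair_of, drop = FALSE] + b * e0)
  }

  # cell mixture
  W <- .rdirichlet(N, sc$dirichlet_alpha)            # N x K simplex
  rownames(W) <- individual_id
  cell_dev <- sc$cell_bp_effect *
    (W[, 1] - sc$dirichlet_alpha[1] / sum(sc$dirichlet_alpha))

  base_bp <- 128 + 0.4 * (age[pair_of] - 52) + 5 * (sex[pair_of] == "M")
  eps <- stats::rnorm(N, 0, sc$bp_noise_sd)
  fam_bp <- sc$familial_load_bp * Ff[pair_of]

  if (sc$name == "bp_causal") {
    sbp <- base_bp + fam_bp + cell_dev + eps
    if (S > 0L)
      latent[signal_idx, ] <- latent[signal_idx, , drop = FALSE] +
        sc$causal_effect * matrix(sbp - 128, S, N, byrow = TRUE)
  } else {
    mbar <- if (S > 0L) colMeans(latent[signal_idx, , drop = FALSE]) else 0
    sbp <- base_bp + sc$causal_effect * mbar + fam_bp + cell_dev + eps
  }
  dbp <- 80 + 0.4 * (sbp - 128) + stats::rnorm(N, 0, 6)

  readings <- function(x) vapply(1:3, function(k) x + stats::rnorm(N, 0, 3),
                                 numeric(N))
  sbp_r <- readings(sbp); dbp_r <- readings(dbp)

  # observed beta: cell mixture baseline shifted by the latent on the M scale.
  # Null CpGs draw bimodal Beta(0.4, 0.4) basis methylomes (CpGs are mostly
  # near-un/methylated); signal CpGs draw centred Beta(5, 5) basis profiles --
  # trait-associated CpGs are intermediate-methylation variable sites, and a
  # latent shift at beta ~ 0/1 would vanish in the bounded beta scale.
  B <- matrix(stats::rbeta(C * sc$n_cell_types, 0.4, 0.4), C, sc$n_cell_types)
  if (S > 0L)
    B[signal_idx, ] <- stats::rbeta(S * sc$n_cell_types, 5, 5)
  beta0 <- pmin(pmax(B %*% t(W), 0.001), 0.999)
  m_obs <- log2(beta0 / (1 - beta0)) + latent
  beta <- stats::plogis(m_obs * log(2))
  beta <- beta + stats::rnorm(C * N, 0, sc$beta_noise_sd)
  beta <- pmin(pmax(beta, 0.001), 0.999)
  if (sc$missing_rate > 0)
    beta[stats::runif(C * N) < sc$missing_rate] <- NA_real_
  colnames(beta) <- individual_id
  rownames(beta) <- sprintf("cpg%05d", seq_len(C))
  coverage <- matrix(stats::rnbinom(C * N, mu = 30, size = 3) + 1L, C, N,
                     dimnames = dimnames(beta))

  cohort <- data.frame(
    individual_id = individual_id, pair_id = pair_id[pair_of],
    twin_index = twin_index, sex = sex[pair_of], age_years = age[pair_of],
    sbp1 = sbp_r[, 1], sbp2 = sbp_r[, 2], sbp3 = sbp_r[, 3],
    dbp1 = dbp_r[, 1], dbp2 = dbp_r[, 2], dbp3 = dbp_r[, 3],
    bmi = round(stats::rnorm(N, 24, 3), 1),
    tg = round(stats::rlnorm(N, log(1.3), 0.4), 2),
    fbg = round(stats::rnorm(N, 5.2, 0.8), 2),
    case_status = sbp >= 140 | dbp >= 90,
    stringsAsFactors = FALSE)

  se <- TwinMethExperiment(beta, chrom, pos, cohort, coverage = coverage,
                           metadata = list(scenario = sc, cell_fractions = W))
  o <- order(pos)   # rows were built in position order already; keep aligned
  truth <- S4Vectors::DataFrame(
    is_signal = seq_len(C) %in% signal_idx,
    true_effect = ifelse(seq_len(C) %in% signal_idx, sc$causal_effect, 0),
    true_direction = ifelse(seq_len(C) %in% signal_idx,
                            switch(sc$name, meth_causal = "meth_to_bp",
                                   bp_causal = "bp_to_meth",
                                   confounded = "confounded", "none"), "none"))
  SummarizedExperiment::rowData(se) <- truth[o, , drop = FALSE]
  S4Vectors::metadata(se)$latent_m <- latent[o, , drop = FALSE]
  se
}

#' Implant a differentially methylated region into a simulated cohort
#'
#' Inserts `n_probes` consecutive CpGs spaced `spacing_bp` apart whose
#' M-values carry a shared blood-pressure-associated shift of `effect`
#' M-units per SBP standard deviation, a per-pair latent term shared by all
#' implanted probes (which makes neighbours spatially correlated), and
#' probe-level noise. Used as the ground-truth fixture for the DMR caller.
#'
#' @param se a [TwinMethExperiment-class] (typically from
#'   [simulateTwinCohort()]).
#' @param chrom,start_bp location of the first implanted probe.
#' @param n_probes,spacing_bp region geometry.
#' @param effect M-value shift per SBP standard deviation; 0 implants inert
#'   probes.
#' @return the experiment with the probes inserted (rows re-sorted by
#'   position); the implanted interval is appended to
#'   `metadata(se)$implanted_regions`.
#' @export
implantDmr <- function(se, chrom, start_bp, n_probes, spacing_bp, effect) {
  stopifnot(methods::is(se, "TwinMethExperiment"))
  if (n_probes < 2L || spacing_bp <= 0L) stop("need >= 2 probes, positive spacing")
  new_pos <- as.integer(start_bp + spacing_bp * (seq_len(n_probes) - 1L))
  reg <- GenomicRanges::GRanges(chrom, IRanges::IRanges(min(new_pos), max(new_pos)))
  prev <- S4Vectors::metadata(se)$implanted_regions
  if (!is.null(prev) && length(GenomicRanges::findOverlaps(reg, prev)) > 0)
    stop("implanted region overlaps an existing implanted region")

  cd <- cohortData(se)
  sbp <- rowMeans(cbind(cd$sbp1, cd$sbp2, cd$sbp3))
  z <- as.vector(scale(sbp))
  pid <- as.integer(factor(cd$pair_id, levels = unique(cd$pair_id)))
  g <- stats::rnorm(max(pid), 0, 0.3)[pid]        # pair latent shared by probes
  N <- ncol(se)
  m_new <- matrix(effect * z + g, n_probes, N, byrow = TRUE) +
    matrix(stats::rnorm(n_probes * N, 0, 0.3), n_probes, N)
  beta_new <- pmin(pmax(stats::plogis(m_new * log(2)), 0.001), 0.999)
  colnames(beta_new) <- colnames(se)
  rownames(beta_new) <- sprintf("dmr_%s_%d", chrom, new_pos)

  beta <- rbind(betaValues(se), beta_new)
  cov_old <- coverageValues(se)
  coverage <- if (is.null(cov_old)) NULL else
    rbind(cov_old, matrix(30L, n_probes, N, dimnames = dimnames(beta_new)))
  rr <- SummarizedExperiment::rowRanges(se)
  chrom_all <- c(as.character(GenomicRanges::seqnames(rr)), rep(chrom, n_probes))
  pos_all <- c(GenomicRanges::start(rr), new_pos)

  md <- S4Vectors::metadata(se)
  md$implanted_regions <- if (is.null(prev)) reg else c(prev, reg)
  md$latent_m <- NULL
  out <- TwinMethExperiment(beta, chrom_all, pos_all, cohortData(se),
                            coverage = coverage, metadata = md)
  truth <- S4Vectors::DataFrame(
    is_signal = c(SummarizedExperiment::rowData(se)$is_signal %||% rep(FALSE, nrow(se)),
                  rep(effect != 0, n_probes)),
    true_effect = c(SummarizedExperiment::rowData(se)$true_effect %||% rep(0, nrow(se)),
                    rep(effect, n_probes)),
    true_direction = c(SummarizedExperiment::rowData(se)$true_direction %||% rep("none", nrow(se)),
                       rep(if (effect != 0) "dmr" else "none", n_probes)))
  rr_tmp <- GenomicRanges::GRanges(chrom_all, IRanges::IRanges(pos_all, width = 1L))
  o <- GenomicRanges::order(rr_tmp)   # same ordering the constructor applies
  SummarizedExperiment::rowData(out) <- truth[o, , drop = FALSE]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
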