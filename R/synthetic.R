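# Synthetic cohort generator. Emulates the statistical structure the pipeline
# assumes: three cohorts (ASD / SIB / NEU) of correlated, positive, skewed
# metabolite profiles; a planted mean shift on a small set of variables
# separating ASD from NEU on the standardized latent scale; SIB means placed
# at NEU + lambda * (ASD - NEU) with lambda small (siblings are NEU-like);
# exact recomputed ratio columns (so the real panel's collinearity is
# present); and a noisy nonlinear link from a planted variable subset to a
# bounded adaptive-behavior score.
#
# Marginals are lognormal: latent z ~ N(mean, Sigma) per cohort with
# unit-variance exchangeable-block correlation, observed x = exp(mu + s * z).
# Shifts are specified on the latent standardized scale, so for a single
# planted variable with shift delta the population C-statistic is
# Phi(delta / sqrt(2)) (monotone transforms preserve it).

# Plausible baseline concentrations (central tendency, study-like units).
.default_baselines <- c(
  "Methionine" = 25, "SAM" = 85, "SAH" = 20, "% DNA methylation" = 4,
  "8-OHG" = 0.06, "Adenosine" = 0.25, "Homocysteine" = 7, "Cysteine" = 200,
  "Glu.-Cys." = 2.5, "Cys.-Gly." = 40, "tGSH" = 7.5, "fGSH" = 2,
  "GSSG" = 0.25, "Chlorotyrosine" = 0.03, "Nitrotyrosine" = 0.04,
  "Tyrosine" = 60, "Tryptophane" = 50, "fCystine" = 25, "fCysteine" = 15,
  "% oxidized glutathione" = 7)

# Pathway blocks for the exchangeable correlation structure (base variables).
.default_blocks <- list(
  methylation = c("Methionine", "SAM", "SAH", "Adenosine", "Homocysteine"),
  dna_oxidation = c("% DNA methylation", "8-OHG"),
  glutathione = c("Cysteine", "Glu.-Cys.", "Cys.-Gly.", "tGSH", "fGSH",
                  "GSSG", "% oxidized glutathione"),
  tyrosine = c("Chlorotyrosine", "Nitrotyrosine", "Tyrosine", "Tryptophane"),
  cystine = c("fCystine", "fCysteine"))

#' Default planted variable sets of the synthetic generator
#' @return List with \code{classification} (5 base variables carrying the
#'   ASD-vs-NEU shift) and \code{regression} (5 base variables driving the
#'   behavior-score link; overlaps classification in 8-OHG).
#' @export
planted_defaults <- function() {
  list(
    classification = c("% DNA methylation", "8-OHG", "Glu.-Cys.",
                       "Chlorotyrosine", "% oxidized glutathione"),
    regression = c("8-OHG", "GSSG", "Nitrotyrosine", "Tyrosine", "fCysteine"))
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults mirror the study design: cohort sizes 83/47/76, the full
#' 24-variable panel, five planted classification variables with latent shift
#' 1.75 each (joint separation ~ sqrt(5) * 1.75 under independence, i.e. a
#' near-saturated C-statistic), SIB mixing 0.15, within-block correlation
#' 0.3, lognormal coefficient of variation 0.3, and a logistic
#' metabolite-to-Vineland link with one interaction, noise sd 4 score points,
#' range clipped to [46, 106], recorded for ~66% of ASD samples.
#'
#' @param n_asd,n_sib,n_neu cohort sizes.
#' @param panel panel variables (default full 24; a reduced panel keeps only
#'   ratio variables whose components survive).
#' @param delta named numeric vector of latent standardized mean shifts
#'   (ASD vs NEU) on base variables.
#' @param sib_mixing lambda in [0,1]: SIB latent mean = lambda * delta.
#' @param rho within-block exchangeable correlation.
#' @param cv lognormal coefficient of variation of each base variable.
#' @param regression_variables base variables driving the Vineland link.
#' @param vineland_noise_sd score-scale noise sd.
#' @param vineland_range bounds for clipping (default c(46, 106)).
#' @param vineland_fraction fraction of ASD samples given a score.
#' @param seed integer RNG seed.
#' @return A \code{synthetic_config} list, validated.
#' @export
synthetic_config <- function(n_asd = 83L, n_sib = 47L, n_neu = 76L,
                             panel = metabolite_panel(),
                             delta = NULL,
                             sib_mixing = 0.15,
                             rho = 0.3,
                             cv = 0.3,
                             regression_variables = NULL,
                             vineland_noise_sd = 4,
                             vineland_range = c(46, 106),
                             vineland_fraction = 55 / 83,
                             seed = 1L) {
  base <- panel_base_variables(panel)
  if (is.null(delta)) {
    planted <- intersect(planted_defaults()$classification, base)
    delta <- stats::setNames(rep(1.75, length(planted)), planted)
  }
  if (is.null(regression_variables))
    regression_variables <- intersect(planted_defaults()$regression, base)
  stopifnot(n_asd >= 0, n_sib >= 0, n_neu >= 0,
            sib_mixing >= 0, sib_mixing <= 1,
            rho > -1, rho < 1, cv > 0,
            vineland_range[1L] < vineland_range[2L])
  if (!all(names(delta) %in% base))
    stop("delta names must be base (non-ratio) panel variables")
  if (!all(regression_variables %in% base))
    stop("regression variables must be base panel variables")
  structure(list(
    n_asd = as.integer(n_asd), n_sib = as.integer(n_sib),
    n_neu = as.integer(n_neu), panel = panel, delta = delta,
    sib_mixing = sib_mixing, rho = rho, cv = cv,
    regression_variables = regression_variables,
    vineland_noise_sd = vineland_noise_sd,
    vineland_range = vineland_range,
    vineland_fraction = vineland_fraction,
    seed = as.integer(seed)), class = "synthetic_config")
}

# Exchangeable-block correlation matrix over the given base variables.
.block_correlation <- function(base, rho) {
  p <- length(base)
  R <- diag(p)
  dimnames(R) <- list(base, base)
  for (blk in .default_blocks) {
    idx <- which(base %in% blk)
    if (length(idx) > 1L) R[idx, idx] <- rho
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("invalid correlation structure: not positive definite")
  R
}

# Latent -> observed lognormal transform parameters per base variable.
.lognormal_params <- function(base, cv) {
  s <- sqrt(log(1 + cv^2))
  baselines <- .default_baselines[base]
  baselines[is.na(baselines)] <- 1
  list(mu = log(baselines), s = rep(s, length(base)))
}

#' Generate the three synthetic cohorts
#'
#' Draws correlated Gaussian latent vectors per cohort (NEU mean 0, ASD mean
#' \code{delta}, SIB mean \code{sib_mixing * delta}), exponentiates to
#' lognormal observed scale, and recomputes every ratio variable exactly from
#' its components. Fully reproducible from \code{cfg$seed}.
#'
#' @param cfg a \code{synthetic_config}.
#' @return List with \code{dataset} (a \code{focm_dataset}, provenance
#'   "synthetic") and \code{ground_truth} (planted variables, shifts, latent
#'   transform parameters, link description).
#' @export
generate_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  base <- panel_base_variables(cfg$panel)
  R <- .block_correlation(base, cfg$rho)
  L <- chol(R)
  lp <- .lognormal_params(base, cfg$cv)

  delta_full <- stats::setNames(rep(0, length(base)), base)
  delta_full[names(cfg$delta)] <- cfg$delta

  set.seed(cfg$seed)
  draw <- function(n, shift) {
    Z <- matrix(stats::rnorm(n * length(base)), nrow = n,
                ncol = length(base)) %*% L
    Z <- sweep(Z, 2L, shift, "+")
    colnames(Z) <- base
    Z
  }
  Z <- rbind(draw(cfg$n_asd, delta_full),
             draw(cfg$n_sib, cfg$sib_mixing * delta_full),
             draw(cfg$n_neu, 0 * delta_full))
  cohort <- rep(c("ASD", "SIB", "NEU"), c(cfg$n_asd, cfg$n_sib, cfg$n_neu))

  X <- exp(sweep(sweep(Z, 2L, lp$s, "*"), 2L, lp$mu, "+"))
  data <- as.data.frame(X, check.names = FALSE, optional = TRUE)
  for (ratio in intersect(names(panel_ratios()), cfg$panel)) {
    comp <- panel_ratios()[[ratio]]
    if (!all(comp %in% base)) next
    data[[ratio]] <- data[[comp[1L]]] / data[[comp[2L]]]
  }
  data <- data[, intersect(cfg$panel, colnames(data)), drop = FALSE]

  gt <- list(
    planted_classification_variables = names(cfg$delta),
    planted_regression_variables = cfg$regression_variables,
    delta = cfg$delta, sib_mixing = cfg$sib_mixing,
    lognormal = lp, base_variables = base,
    link = list(type = "logistic+interaction",
                noise_sd = cfg$vineland_noise_sd,
                range = cfg$vineland_range))
  ds <- new_focm_dataset(data, cohort,
                         panel = colnames(data),
                         provenance = list(source = "synthetic",
                                           seed = cfg$seed))
  list(dataset = ds, ground_truth = gt)
}

# Latent standardized value of a base variable recovered from observed scale.
.latent_of <- function(ds, gt, variable) {
  i <- match(variable, gt$base_variables)
  (log(ds$data[[variable]]) - gt$lognormal$mu[[i]]) / gt$lognormal$s[[i]]
}

#' Attach synthetic Vineland scores to the ASD cohort
#'
#' Computes a smooth nonlinear behavior score from the planted regression
#' variables: a scaled logistic of a linear index of their latent
#' standardized values plus one pairwise interaction, with higher metabolic
#' dysfunction mapping to lower adaptive behavior, plus Gaussian noise,
#' clipped to the configured range. Scores are assigned to a seeded random
#' subset of ASD samples (\code{vineland_fraction}).
#'
#' @param ds dataset from \code{\link{generate_cohorts}}.
#' @param cfg the same \code{synthetic_config}.
#' @param gt the matching ground truth (for latent-scale recovery).
#' @return The dataset with \code{vineland} filled in for the selected ASD
#'   samples; the realized link is recorded in \code{provenance}.
#' @export
attach_vineland <- function(ds, cfg, gt) {
  if (!any(ds$cohort == "ASD")) stop("dataset has no ASD cohort")
  vars <- cfg$regression_variables
  missing_v <- setdiff(vars, ds$panel)
  if (length(missing_v))
    stop("link variable(s) absent from panel: ",
         paste(missing_v, collapse = ", "))
  Zl <- vapply(vars, function(v) .latent_of(ds, gt, v),
               numeric(nrow(ds$data)))
  coefs <- c(0.8, -0.6, 0.5, -0.4, 0.3)[seq_along(vars)]
  eta <- drop(Zl %*% coefs)
  if (length(vars) >= 2L) eta <- eta + 0.5 * Zl[, 1L] * Zl[, 2L]

  lo <- cfg$vineland_range[1L]; hi <- cfg$vineland_range[2L]
  set.seed(cfg$seed + 104729L) # distinct stream from the cohort draw
  asd_idx <- which(ds$cohort == "ASD")
  n_score <- round(cfg$vineland_fraction * length(asd_idx))
  scored <- sort(sample(asd_idx, n_score))
  y <- lo + (hi - lo) * stats::plogis(-eta[scored])
  if (cfg$vineland_noise_sd > 0)
    y <- y + stats::rnorm(n_score, sd = cfg$vineland_noise_sd)
  ds$vineland[scored] <- pmin(hi, pmax(lo, y))
  ds$provenance$vineland_link <- list(variables = vars, coefs = coefs,
                                      interaction = 0.5,
                                      noise_sd = cfg$vineland_noise_sd,
                                      range = c(lo, hi))
  ds
}

#' Generate a complete synthetic dataset (cohorts + behavior scores)
#' @param cfg a \code{synthetic_config} (default: study-mimicking defaults).
#' @return List with \code{dataset} and \code{ground_truth}.
#' @export
synthetic_dataset <- function(cfg = synthetic_config()) {
  g <- generate_cohorts(cfg)
  g$dataset <- attach_vineland(g$dataset, cfg, g$ground_truth)
  g
}
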