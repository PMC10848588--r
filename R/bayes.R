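#' MCMC chain configuration
#'
#' @param n_iterations total Gibbs iterations (default 21000).
#' @param burn_in iterations discarded (default 1000).
#' @param thin keep every `thin`-th post-burn-in iteration (default 10).
#' @param seed integer seed.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 21000L, burn_in = 1000L, thin = 10L,
                        seed = 1L) {
  if (burn_in >= n_iterations) stop("burn_in must be smaller than n_iterations")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)), class = "mcmc_config")
}

#' Bayesian marker-effect model specification
#'
#' Five prior families on SNP effects:
#' * `B` — spike at zero with probability `1 - pi`, scaled t otherwise
#'   (implemented by per-marker variance augmentation).
#' * `Cpi` — spike / normal mixture, `pi` estimated with a uniform prior
#'   unless fixed.
#' * `N` — nested mixture: a window-level inclusion indicator over
#'   non-overlapping genomic windows gates `Cpi`-style per-marker
#'   indicators inside each window.
#' * `S` — normal effects whose variance scales with
#'   `(2 p (1-p))^S`; `S` is sampled by a random-walk Metropolis step.
#' * `R` — mixture of four normals with variances
#'   `gamma_k * sigma2`, `gamma = (0, 0.01, 0.1, 1)`, Dirichlet(1,1,1,1)
#'   weights.
#'
#' Throughout, `pi` is the prior probability of a NON-zero effect.
#'
#' @param family `"B"`, `"Cpi"`, `"N"`, `"S"` or `"R"`.
#' @param pi `NULL` to estimate (uniform prior) or a fixed value in `[0, 1]`.
#' @param window_bp window width for family `N` (default 200000).
#' @param gamma variance-class multipliers for family `R`
#'   (non-negative, ascending, first element 0).
#' @param s_prior_sd prior SD of the MAF-coupling exponent for `S`
#'   (default 1).
#' @param df_t degrees of freedom of the scaled t for `B` (default 4).
#' @return an object of class `bayes_spec`.
#' @export
bayes_spec <- function(family = c("B", "Cpi", "N", "S", "R"), pi = NULL,
                       window_bp = 200000, gamma = c(0, 0.01, 0.1, 1),
                       s_prior_sd = 1, df_t = 4) {
  family <- match.arg(family)
  if (!is.null(pi) && (pi < 0 || pi > 1)) stop("fixed pi must lie in [0, 1]")
  if (gamma[1] != 0 || any(diff(gamma) < 0) || any(gamma < 0)) {
    stop("gamma must be non-negative ascending with gamma[1] = 0")
  }
  if (window_bp <= 0) stop("window_bp must be > 0")
  structure(list(family = family, pi = pi, window_bp = window_bp,
                 gamma = gamma, s_prior_sd = s_prior_sd, df_t = df_t),
            class = "bayes_spec")
}

## Non-overlapping windows tiled from each chromosome's first marker bp.
bayes_windows <- function(map, window_bp) {
  win <- integer(nrow(map))
  nxt <- 0L
  for (ch in unique(map$chrom)) {
    j <- which(map$chrom == ch)
    tile <- floor((map$bp[j] - min(map$bp[j])) / window_bp)
    win[j] <- nxt + match(tile, sort(unique(tile)))
    nxt <- max(win[j])
  }
  win
}

#' Run a Bayesian marker-effect Gibbs sampler
#'
#' Single-site Gibbs over marker effects with family-specific full
#' conditionals; fixed effects are sampled under a flat prior and the
#' variance components from scaled inverse chi-square conditionals.
#' Genotypes are centred (not standardized) by training allele
#' frequencies before sampling.
#'
#' @param genotypes a [genotype_matrix()] (QC'd).
#' @param phenotypes data.frame with `id`, the trait, and fixed-effect
#'   factors; rows with `NA` trait values are ignored for training.
#' @param trait trait column name (default `"trait"`).
#' @param fixed_factors fixed-effect factor columns.
#' @param model a [bayes_spec()].
#' @param mcmc an [mcmc_config()].
#' @return an object of class `posterior_summary`: per-marker
#'   `effect_means` and `inclusion_prob`, `beta_means`, thinned chains
#'   (`pi_samples`, `S_samples`, `component_weight_samples`,
#'   `sigma_a2_samples`, `sigma_e2_samples`), per-individual `gebv` for
#'   every genotyped individual, and the `centering_freqs` used.
#' @export
run_sampler <- function(genotypes, phenotypes, trait = "trait",
                        fixed_factors = c("sex", "feed_room"),
                        model = bayes_spec("Cpi"), mcmc = mcmc_config()) {
  ids <- rownames(genotypes$codes)
  obs <- phenotypes[!is.na(phenotypes[[trait]]) & phenotypes$id %in% ids, , drop = FALSE]
  if (nrow(obs) < 1) stop("no phenotyped genotyped individuals")
  y <- obs[[trait]]
  if (sd(y) == 0) stop("constant phenotype: nothing to fit")
  gtrain <- genotypes[obs$id, ]
  p_train <- allele_freq(gtrain)
  p_train[is.nan(p_train)] <- 0
  Ztrain <- sweep(gtrain$codes, 2, 2 * p_train)
  Ztrain[is.na(Ztrain)] <- 0
  X <- design_matrix(obs, fixed_factors)
  wS <- pmax(2 * p_train * (1 - p_train), 1e-4)
  win <- bayes_windows(genotypes$map, model$window_bp)
  n_empty <- sum(!(seq_len(max(win)) %in% win))
  if (model$family == "N" && n_empty > 0) {
    message(n_empty, " empty window(s) skipped")
  }
  out <- with_seed(mcmc$seed, {
    .bayes_mcmc_cpp(Ztrain, X, y, model$family,
                    mcmc$n_iterations, mcmc$burn_in, mcmc$thin,
                    if (is.null(model$pi)) -1 else model$pi,
                    model$gamma, as.integer(win), wS,
                    model$s_prior_sd, 0.3, model$df_t)
  })
  eff <- drop(out$effect_means)
  names(eff) <- genotypes$map$marker
  gebv <- gebv_from_effects(genotypes, eff, p_train)
  ## split-chain stationarity check on the genetic variance
  sa2 <- drop(out$sigma_a2_samples)
  half <- length(sa2) %/% 2
  if (half >= 10) {
    m1 <- mean(sa2[seq_len(half)]); m2 <- mean(sa2[(half + 1):(2 * half)])
    s <- sd(sa2)
    if (s > 0 && abs(m1 - m2) / s > 1) {
      warning("split-chain diagnostic on sigma_a2 suggests non-stationarity ",
              "(half-chain means differ by > 1 SD); consider a longer chain")
    }
  }
  structure(list(
    effect_means = eff,
    inclusion_prob = setNames(drop(out$inclusion_prob), genotypes$map$marker),
    beta_means = setNames(drop(out$beta_means), colnames(X)),
    pi_samples = drop(out$pi_samples),
    S_samples = drop(out$S_samples),
    component_weight_samples = out$component_weight_samples,
    sigma_a2_samples = sa2,
    sigma_e2_samples = drop(out$sigma_e2_samples),
    gebv = gebv,
    centering_freqs = p_train,
    model = model, mcmc = mcmc, n_kept = out$n_kept
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("posterior_summary: Bayes%s, %d retained samples\n",
              x$model$family, x$n_kept))
  cat(sprintf("  mean |effect| %.4g; mean inclusion %.3f; mean sigma_a2 %.4g\n",
              mean(abs(x$effect_means)), mean(x$inclusion_prob),
              mean(x$sigma_a2_samples)))
  invisible(x)
}

#' Genomic values from marker effects
#'
#' `GEBV = (M - 2p) %*% effects` with `p` the centring (training-set)
#' frequencies.
#'
#' @param genotypes a [genotype_matrix()].
#' @param effect_means named per-marker effect vector, aligned to the
#'   marker map.
#' @param centering_freqs per-marker allele frequencies used for centring.
#' @return named numeric vector of genetic values, one per individual.
#' @export
gebv_from_effects <- function(genotypes, effect_means, centering_freqs) {
  if (length(effect_means) != ncol(genotypes$codes)) {
    stop("effect vector length does not match the marker map")
  }
  if (!is.null(names(effect_means)) &&
      !identical(names(effect_means), genotypes$map$marker)) {
    stop("effect vector names do not match the marker map")
  }
  Z <- sweep(genotypes$codes, 2, 2 * centering_freqs)
  Z[is.na(Z)] <- 0
  drop(Z %*% effect_means)
}
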