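#' Assign individuals to cross-validation folds
#'
#' Seeded uniform partition into `k` folds whose sizes differ by at most
#' one (941 ids at `k = 5` give fold sizes 189/188/188/188/188, i.e. a
#' 753-or-752/188-or-189 train/validation division).
#'
#' @param ids character vector of individual ids.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return an object of class `cv_scheme`: list with `fold` (named
#'   integer vector), `k` and `seed`.
#' @export
make_folds <- function(ids, k = 5L, seed = 1L) {
  n <- length(ids)
  if (k > n) stop("k (", k, ") exceeds the number of ids (", n, ")")
  fold <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  structure(list(fold = setNames(fold, ids), k = k, seed = seed),
            class = "cv_scheme")
}

#' Adjusted phenotypes for validation
#'
#' `y* = y - X beta_hat`, with the fixed effects estimated once on the
#' full data jointly with a polygenic term (so the estimate is not biased
#' by genetic structure). The polygenic term uses the supplied
#' relationship matrix.
#'
#' @param phenotypes data.frame with `id`, the trait, fixed-effect
#'   factors.
#' @param trait trait column name.
#' @param fixed_factors fixed-effect factor columns.
#' @param K relationship matrix covering the phenotyped ids (e.g. G for
#'   the genotyped set); a `relationship_matrix` or plain matrix.
#' @param varcomp optional `variance_components` (estimated by REML when
#'   omitted).
#' @return named numeric vector of adjusted values for all phenotyped ids.
#' @export
adjusted_phenotype <- function(phenotypes, trait = "trait",
                               fixed_factors = c("sex", "feed_room"),
                               K, varcomp = NULL) {
  obs <- phenotypes[!is.na(phenotypes[[trait]]), , drop = FALSE]
  V <- if (inherits(K, "relationship_matrix")) K$values else K
  miss <- setdiff(obs$id, rownames(V))
  if (length(miss)) stop("relationship matrix lacks phenotyped id(s): ",
                         paste(head(miss, 5), collapse = ", "))
  y <- obs[[trait]]
  X <- design_matrix(obs, fixed_factors)
  K_obs <- V[obs$id, obs$id, drop = FALSE]
  if (is.null(varcomp)) varcomp <- estimate_reml(y, X, K_obs)
  ## GLS fixed-effect solutions under the fitted covariance
  Vy <- varcomp$sigma_a2 * K_obs + varcomp$sigma_e2 * diag(nrow(K_obs))
  Vinv_X <- solve(Vy, X)
  beta <- solve(crossprod(X, Vinv_X), crossprod(Vinv_X, y))
  setNames(drop(y - X %*% beta), obs$id)
}

#' Cross-validated prediction reliability
#'
#' Per-fold squared Pearson correlation between predictions and adjusted
#' phenotypes in the validation fold, and their mean.
#'
#' @param predictions named numeric vector of predicted (G)EBVs covering
#'   all validation ids.
#' @param adjusted named numeric vector of adjusted phenotypes.
#' @param scheme a [make_folds()] scheme over the validation ids.
#' @param model_kind,trait optional labels stored in the result.
#' @return an object of class `reliability_result`: `per_fold_r2`
#'   (length `k`), `mean_r2`, `model_kind`, `trait`.
#' @export
reliability <- function(predictions, adjusted, scheme,
                        model_kind = NA_character_, trait = NA_character_) {
  ids <- names(scheme$fold)
  missing_pred <- setdiff(ids, names(predictions))
  if (length(missing_pred)) {
    stop("no prediction for validation id(s): ",
         paste(head(missing_pred, 5), collapse = ", "))
  }
  degenerate <- integer(0)
  per_fold <- vapply(seq_len(scheme$k), function(f) {
    v <- ids[scheme$fold == f]
    pr <- predictions[v]; ad <- adjusted[v]
    if (sd(pr) == 0 || sd(ad) == 0) {
      degenerate <<- c(degenerate, f)
      return(0)
    }
    cor(pr, ad)^2
  }, numeric(1))
  if (length(degenerate)) {
    warning("zero-variance predictions or targets in fold(s) ",
            paste(degenerate, collapse = ", "), "; r2 recorded as 0")
  }
  structure(list(per_fold_r2 = per_fold, mean_r2 = mean(per_fold),
                 model_kind = model_kind, trait = trait),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("reliability (%s%s): mean r2 = %.3f [%s]\n",
              ifelse(is.na(x$model_kind), "model", x$model_kind),
              ifelse(is.na(x$trait), "", paste0(", ", x$trait)),
              x$mean_r2, paste(sprintf("%.3f", x$per_fold_r2), collapse = " ")))
  invisible(x)
}

#' Fivefold cross-validated reliability for one model
#'
#' For each fold, validation phenotypes are masked (set `NA`) inside the
#' model fit — the individuals stay in the relationship structure so they
#' receive predictions — variance components are re-estimated on each
#' training fold, and the validation predictions are scored against
#' adjusted phenotypes from the full data.
#'
#' @param model_kind `"pedigree_blup"`, `"gblup"`, `"ssgblup"`, or
#'   `"bayes"`.
#' @param phenotypes data.frame with `id`, the trait, fixed-effect
#'   factors.
#' @param scheme a [make_folds()] over the genotyped-and-phenotyped ids
#'   (created internally when `NULL`, using `seed`).
#' @param trait,fixed_factors passed through to the fitting routines.
#' @param ped,genotypes,genotyped_ids,g_reg passed to [fit_model()].
#' @param bayes_model,mcmc for `model_kind = "bayes"`: a [bayes_spec()]
#'   and [mcmc_config()].
#' @param adjusted optional precomputed adjusted phenotypes (named
#'   vector); computed internally when `NULL`.
#' @param seed seed for fold assignment when `scheme` is `NULL`.
#' @return a `reliability_result` with the per-fold predictions attached
#'   as attribute `"predictions"`.
#' @export
cv_reliability <- function(model_kind, phenotypes, scheme = NULL,
                           trait = "trait", fixed_factors = c("sex", "feed_room"),
                           ped = NULL, genotypes = NULL, genotyped_ids = NULL,
                           g_reg = 0.99, bayes_model = NULL, mcmc = NULL,
                           adjusted = NULL, seed = 1L) {
  is_bayes <- identical(model_kind, "bayes")
  if (is_bayes && is.null(bayes_model)) stop("bayes CV needs a bayes_spec")
  geno_ids <- if (!is.null(genotypes)) rownames(genotypes$codes) else character(0)
  pheno_ids <- phenotypes$id[!is.na(phenotypes[[trait]])]
  cv_ids <- if (length(geno_ids)) intersect(pheno_ids, geno_ids) else pheno_ids
  if (is.null(scheme)) scheme <- make_folds(cv_ids, seed = seed)
  if (is.null(adjusted)) {
    K_adj <- if (!is.null(genotypes)) {
      gsub <- genotypes[intersect(rownames(genotypes$codes), pheno_ids), ]
      build_G(gsub)$values
    } else build_A(ped)$values
    keep <- intersect(pheno_ids, rownames(K_adj))
    adjusted <- adjusted_phenotype(phenotypes[phenotypes$id %in% keep, , drop = FALSE],
                                   trait, fixed_factors, K_adj)
  }
  preds <- numeric(0)
  for (f in seq_len(scheme$k)) {
    val_ids <- names(scheme$fold)[scheme$fold == f]
    ph <- phenotypes
    ph[[trait]][ph$id %in% val_ids] <- NA
    if (is_bayes) {
      mc <- if (is.null(mcmc)) mcmc_config(seed = scheme$seed + f) else
        mcmc_config(mcmc$n_iterations, mcmc$burn_in, mcmc$thin, mcmc$seed + f)
      ps <- run_sampler(genotypes, ph, trait, fixed_factors, bayes_model, mc)
      pf <- ps$gebv[val_ids]
    } else {
      fit <- fit_model(model_kind, ph, trait, fixed_factors, ped = ped,
                       genotypes = genotypes, genotyped_ids = genotyped_ids,
                       g_reg = g_reg)
      pf <- fit$breeding_values[val_ids]
    }
    preds <- c(preds, pf)
  }
  rel <- reliability(preds, adjusted, scheme,
                     model_kind = if (is_bayes) paste0("Bayes", bayes_model$family)
                                  else model_kind,
                     trait = trait)
  attr(rel, "predictions") <- preds
  rel
}

#' Paired comparison of two models across traits
#'
#' Two-sided paired t-test on per-trait reliabilities.
#'
#' @param rel_a,rel_b numeric vectors of mean reliabilities, one entry per
#'   trait, in the same trait order (names checked when present).
#' @return list with `mean_diff` (a minus b), `t`, `df`, `p_value`.
#' @export
compare_models <- function(rel_a, rel_b) {
  if (length(rel_a) != length(rel_b) || length(rel_a) < 2) {
    stop("need reliabilities for the same >= 2 traits under both models")
  }
  if (!is.null(names(rel_a)) && !is.null(names(rel_b)) &&
      !identical(names(rel_a), names(rel_b))) {
    stop("trait names differ between the two models")
  }
  d <- rel_a - rel_b
  n <- length(d)
  if (sd(d) <= 1e-10 * (abs(mean(d)) + max(abs(d)) + 1e-300)) {
    if (all(abs(d) <= 1e-12)) {
      return(list(mean_diff = 0, t = 0, df = n - 1, p_value = 1))
    }
    message("zero variance of paired differences with non-zero mean; p -> 0")
    return(list(mean_diff = mean(d), t = sign(mean(d)) * Inf, df = n - 1,
                p_value = 0))
  }
  tt <- t.test(rel_a, rel_b, paired = TRUE)
  list(mean_diff = mean(d), t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value)
}

#' Marker-density permutation experiment
#'
#' For each density and repeat: subsample markers, rebuild G, run
#' fivefold GBLUP cross-validation, and record the mean reliability.
#' The fold assignment is shared across densities and repeats (one seed
#' stream) while marker subsampling uses an independent stream, so the
#' curves are comparable. Predictive capability is each density's mean
#' reliability divided by that of the largest density.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes data.frame with `id`, the trait, fixed-effect
#'   factors.
#' @param densities marker counts to test (capped at the available
#'   number; default the standard 0.5K-500K grid scaled to the panel).
#' @param repeats random subsamples per density (default 30).
#' @param trait,fixed_factors,g_reg passed through.
#' @param seed base seed: folds use `seed`, subsamples use an offset
#'   stream.
#' @return an object of class `density_curve`: data.frame `results`
#'   (density, repeat, mean_r2), `summary` (density, mean_r2,
#'   capability).
#' @export
density_experiment <- function(genotypes, phenotypes,
                               densities = NULL, repeats = 30L,
                               trait = "trait",
                               fixed_factors = c("sex", "feed_room"),
                               g_reg = 0.99, seed = 1L) {
  if (repeats < 1) stop("repeats must be >= 1")
  m <- ncol(genotypes$codes)
  if (is.null(densities)) {
    grid <- c(500, 1000, 3000, 5000, 10000, 50000, 100000, 500000)
    if (max(grid) > m) grid <- unique(pmin(grid, m))
    densities <- grid[grid <= m]
  }
  if (max(densities) > m) stop("largest density exceeds available markers")
  densities <- sort(unique(densities))
  pheno_ids <- phenotypes$id[!is.na(phenotypes[[trait]])]
  cv_ids <- intersect(pheno_ids, rownames(genotypes$codes))
  scheme <- make_folds(cv_ids, seed = seed)
  gsub_all <- genotypes[intersect(rownames(genotypes$codes), pheno_ids), ]
  adjusted <- adjusted_phenotype(phenotypes[phenotypes$id %in% rownames(gsub_all$codes), ],
                                 trait, fixed_factors, build_G(gsub_all)$values)
  res <- expand.grid(density = densities, rep = seq_len(repeats))
  res$mean_r2 <- NA_real_
  for (i in seq_len(nrow(res))) {
    d <- res$density[i]
    sub_seed <- seed + 10000L + 1000L * res$rep[i] + match(d, densities)
    gsub <- if (d == m) genotypes else subsample_markers(genotypes, d, seed = sub_seed)
    rel <- cv_reliability("gblup", phenotypes, scheme = scheme, trait = trait,
                          fixed_factors = fixed_factors, genotypes = gsub,
                          g_reg = g_reg, adjusted = adjusted)
    res$mean_r2[i] <- rel$mean_r2
  }
  smry <- aggregate(mean_r2 ~ density, data = res, FUN = mean)
  smry$capability <- smry$mean_r2 / smry$mean_r2[which.max(smry$density)]
  structure(list(results = res, summary = smry, scheme = scheme),
            class = "density_curve")
}

#' @export
print.density_curve <- function(x, ...) {
  cat("density_curve:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
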