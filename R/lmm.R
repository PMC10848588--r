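#' Build a fixed-effect design matrix
#'
#' Intercept plus full-rank dummy coding (first level as reference) for
#' the categorical factors named in `factors`, taken from `data`.
#'
#' @param data data.frame with one row per observation.
#' @param factors character vector of factor column names (may be empty).
#' @return numeric design matrix with `nrow(data)` rows.
#' @export
design_matrix <- function(data, factors = c("sex", "feed_room")) {
  factors <- intersect(factors, names(data))
  if (!length(factors)) {
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  }
  for (f in factors) data[[f]] <- factor(data[[f]])
  ## drop constant factors (single level) so X stays full rank
  factors <- factors[vapply(data[factors], function(x) nlevels(x) > 1, logical(1))]
  if (!length(factors)) {
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  }
  fml <- as.formula(paste("~", paste(factors, collapse = " + ")))
  model.matrix(fml, data)
}

## Restricted log-likelihood of y ~ N(Xb, sa2*K + se2*I), computed on the
## eigenrotated scale. `ev` is eigen(K); yt, Xt are rotated y and X.
reml_loglik_rotated <- function(sa2, se2, d, yt, Xt) {
  v <- sa2 * d + se2
  if (any(v <= 0)) return(-Inf)
  vinv <- 1 / v
  XtV <- Xt * vinv
  B <- crossprod(XtV, Xt)
  Binv <- solve(B)
  py <- vinv * yt - XtV %*% (Binv %*% crossprod(XtV, yt))
  ypy <- sum(yt * py)
  ld_B <- determinant(B, logarithm = TRUE)$modulus
  -0.5 * (sum(log(v)) + as.numeric(ld_B) + ypy)
}

#' Restricted log-likelihood at a given heritability
#'
#' Profiles the total variance analytically at a fixed ratio
#' `h2 = sa2/(sa2+se2)`, returning the restricted log-likelihood. Useful
#' for grid checks of the REML optimum.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix.
#' @param K relationship matrix (`relationship_matrix` or plain matrix)
#'   for the observations.
#' @param h2 heritability at which to evaluate, in (0, 1).
#' @return the restricted log-likelihood (same constant convention as
#'   [estimate_reml()]).
#' @export
reml_profile_loglik <- function(y, X, K, h2) {
  V <- if (inherits(K, "relationship_matrix")) K$values else K
  ev <- eigen(V, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  yt <- drop(crossprod(ev$vectors, y))
  Xt <- crossprod(ev$vectors, X)
  n <- length(y); p <- ncol(X)
  ## maximize over total variance s2 with V0 = h2*K + (1-h2)*I fixed
  v0 <- h2 * d + (1 - h2)
  vinv <- 1 / v0
  XtV <- Xt * vinv
  B <- crossprod(XtV, Xt)
  py <- vinv * yt - XtV %*% (solve(B) %*% crossprod(XtV, yt))
  s2 <- sum(yt * py) / (n - p)
  reml_loglik_rotated(h2 * s2, (1 - h2) * s2, d, yt, Xt)
}

#' REML variance components by average information
#'
#' Fits the single-trait animal model `y = Xb + a + e`,
#' `a ~ N(0, K sa2)`, `e ~ N(0, I se2)` by average-information REML,
#' computed on the eigenrotated scale (one eigendecomposition of K, then
#' all iterations are O(n)). When an AI step proposes an out-of-bounds
#' variance, an EM-style multiplicative update is taken instead.
#'
#' @param y response vector (no missing values).
#' @param X fixed-effect design matrix, full column rank.
#' @param K relationship matrix for the observations (symmetric PSD).
#' @param tol convergence tolerance on the relative parameter change
#'   (default 1e-8).
#' @param max_iter maximum iterations (default 200).
#' @return an object of class `variance_components`: list with
#'   `sigma_a2`, `sigma_e2`, `h2`, `se_h2`, `loglik`, `n_iterations`,
#'   `converged`, and the iteration `trace`.
#' @export
estimate_reml <- function(y, X, K, tol = 1e-8, max_iter = 200L) {
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("X is not of full column rank")
  if (n < ncol(X) + 2) stop("need at least rank(X) + 2 observations")
  V <- if (inherits(K, "relationship_matrix")) K$values else K
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) < -1e-6 * max(abs(ev$values))) {
    stop("K is not positive semidefinite (min eigenvalue ",
         signif(min(ev$values), 3), ")")
  }
  d <- pmax(ev$values, 0)
  U <- ev$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  vary <- var(y)
  lower <- 1e-8 * vary
  sa2 <- se2 <- vary / 2
  trace <- matrix(NA_real_, max_iter, 3,
                  dimnames = list(NULL, c("sigma_a2", "sigma_e2", "loglik")))
  converged <- FALSE
  AI <- diag(2)
  for (it in seq_len(max_iter)) {
    v <- sa2 * d + se2
    vinv <- 1 / v
    XtV <- Xt * vinv
    B <- crossprod(XtV, Xt)
    Binv <- solve(B)
    W <- XtV %*% Binv           # n x p
    py <- vinv * yt - W %*% crossprod(XtV, yt)
    py <- drop(py)
    ## diag of P on the rotated scale
    Pdiag <- vinv - rowSums((XtV %*% Binv) * XtV)
    trP_K <- sum(d * Pdiag)
    trP_I <- sum(Pdiag)
    Kpy <- d * py               # dV/dsa2 = diag(d)
    Ipy <- py
    score_a <- -0.5 * (trP_K - sum(py * Kpy))
    score_e <- -0.5 * (trP_I - sum(py * Ipy))
    ## P applied to a vector on the rotated scale
    Pv <- function(x) vinv * x - drop(W %*% crossprod(XtV, x))
    PKpy <- Pv(Kpy); PIpy <- Pv(Ipy)
    AI <- 0.5 * matrix(c(sum(Kpy * PKpy), sum(Kpy * PIpy),
                         sum(Kpy * PIpy), sum(Ipy * PIpy)), 2, 2)
    step <- tryCatch(solve(AI, c(score_a, score_e)), error = function(e) NULL)
    new_a <- if (!is.null(step)) sa2 + step[1] else NaN
    new_e <- if (!is.null(step)) se2 + step[2] else NaN
    ## EM-flavoured multiplicative updates (always positive) serve as the
    ## fallback when an AI proposal is unusable or out of bounds
    em_ratio_a <- sum(py * Kpy) / max(trP_K, 1e-12)
    em_ratio_e <- sum(py * Ipy) / max(trP_I, 1e-12)
    fix_bound <- function(new, cur, em_ratio) {
      if (is.finite(new) && new >= lower) return(new)
      if (em_ratio >= 1) return(cur * em_ratio)  # score points inward: EM step
      lower                                      # optimum at the boundary: jump
    }
    new_a <- fix_bound(new_a, sa2, em_ratio_a)
    new_e <- fix_bound(new_e, se2, em_ratio_e)
    ch_a <- abs(new_a - sa2)
    ch_e <- abs(new_e - se2)
    ## a parameter staying at the boundary with an outward score has converged
    if (new_a <= lower && sa2 <= lower && score_a < 0) ch_a <- 0
    if (new_e <= lower && se2 <= lower && score_e < 0) ch_e <- 0
    rel <- max(ch_a, ch_e) / max(sa2 + se2, 1e-12)
    sa2 <- new_a; se2 <- new_e
    trace[it, ] <- c(sa2, se2, reml_loglik_rotated(sa2, se2, d, yt, Xt))
    if (rel < tol) { converged <- TRUE; break }
  }
  n_iter <- if (converged) it else max_iter
  if (!converged) {
    cond <- structure(
      class = c("reml_nonconvergence", "error", "condition"),
      list(message = paste("REML did not converge in", max_iter, "iterations"),
           call = sys.call(), trace = trace))
    stop(cond)
  }
  h2 <- sa2 / (sa2 + se2)
  se_h2 <- tryCatch({
    Ainv <- solve(AI)
    grad <- c(se2, -sa2) / (sa2 + se2)^2
    sqrt(drop(t(grad) %*% Ainv %*% grad))
  }, error = function(e) NA_real_)
  structure(list(sigma_a2 = sa2, sigma_e2 = se2, h2 = h2, se_h2 = se_h2,
                 loglik = reml_loglik_rotated(sa2, se2, d, yt, Xt),
                 n_iterations = n_iter, converged = converged,
                 trace = trace[seq_len(n_iter), , drop = FALSE]),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("sigma_a2 = %.4g, sigma_e2 = %.4g\n", x$sigma_a2, x$sigma_e2))
  cat(sprintf("h2 = %.3f (SE %.3f), restricted logLik %.3f, %d iterations\n",
              x$h2, x$se_h2, x$loglik, x$n_iterations))
  invisible(x)
}

#' Solve Henderson's mixed-model equations
#'
#' Joint solutions for fixed effects and breeding values in
#' `y = Xb + Za + e`, `a ~ N(0, K sa2)`. Individuals present in `K` but
#' without phenotype rows in `Z` receive predictions through their
#' relationships — this is what makes single-step evaluation and
#' cross-validation masking work.
#'
#' @param y response vector (observations only).
#' @param X fixed-effect design matrix (rows = observations).
#' @param Z incidence matrix mapping observations to the individuals
#'   indexing `K` (rows = observations, columns = individuals).
#' @param K_inv inverse relationship matrix (`relationship_matrix` or
#'   plain matrix) over all individuals.
#' @param varcomp a `variance_components` object (or list with
#'   `sigma_a2`, `sigma_e2`).
#' @return an object of class `model_fit`: list with `beta_hat`,
#'   `breeding_values` (named by the ids of `K_inv`), and `varcomp`.
#' @export
solve_mme <- function(y, X, Z, K_inv, varcomp) {
  Ki <- if (inherits(K_inv, "relationship_matrix")) K_inv$values else K_inv
  lambda <- varcomp$sigma_e2 / varcomp$sigma_a2
  if (!is.finite(lambda) || lambda <= 0) stop("lambda = se2/sa2 must be finite and > 0")
  X <- as.matrix(X); Z <- as.matrix(Z)
  p <- ncol(X); q <- ncol(Z)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * Ki))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- tryCatch(solve(C, rhs), error = function(e) {
    r <- qr(C)$rank
    stop("singular mixed-model coefficient matrix (rank ", r, " of ",
         nrow(C), ")")
  })
  beta <- sol[seq_len(p)]
  names(beta) <- colnames(X)
  a <- sol[p + seq_len(q)]
  names(a) <- colnames(Z)
  structure(list(beta_hat = beta, breeding_values = a, varcomp = varcomp),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("model_fit:", if (!is.null(x$model_kind)) x$model_kind else "",
      length(x$breeding_values), "breeding values\n")
  cat("  fixed effects:", paste(sprintf("%s=%.3g", names(x$beta_hat), x$beta_hat),
                                collapse = ", "), "\n")
  if (!is.null(x$varcomp$h2)) cat(sprintf("  h2 = %.3f\n", x$varcomp$h2))
  invisible(x)
}

#' Fit a pedigree BLUP, GBLUP or single-step GBLUP model
#'
#' One code path for the three evaluations: the model kind selects the
#' relationship structure (A from the pedigree, VanRaden G from the
#' genotypes, or the single-step blend H), REML estimates the variance
#' components on the phenotyped individuals, and Henderson's equations
#' produce solutions for every individual in the relationship matrix.
#' Phenotype rows with `NA` trait values are treated as unphenotyped
#' (masked) but still receive predictions.
#'
#' @param model_kind `"pedigree_blup"`, `"gblup"` or `"ssgblup"`.
#' @param phenotypes data.frame with columns `id`, the trait, and any
#'   fixed-effect factors.
#' @param trait trait column name (default `"trait"`).
#' @param fixed_factors fixed-effect factor columns (default
#'   `c("sex", "feed_room")`; absent columns are ignored).
#' @param ped a [pedigree()] (required for `pedigree_blup`, `ssgblup`).
#' @param genotypes a [genotype_matrix()] (required for `gblup`,
#'   `ssgblup`).
#' @param genotyped_ids ids of the genotyped set for `ssgblup`
#'   (default: all rows of `genotypes`).
#' @param g_reg blending weight on G before inversion (default 0.99;
#'   1 = no regularization).
#' @param varcomp optional `variance_components` to use instead of
#'   re-estimating by REML.
#' @return a `model_fit` with `breeding_values` over the full
#'   relationship-matrix id set, plus `varcomp` and `model_kind`.
#' @export
fit_model <- function(model_kind = c("pedigree_blup", "gblup", "ssgblup"),
                      phenotypes, trait = "trait",
                      fixed_factors = c("sex", "feed_room"),
                      ped = NULL, genotypes = NULL, genotyped_ids = NULL,
                      g_reg = 0.99, varcomp = NULL) {
  model_kind <- match.arg(model_kind)
  if (model_kind %in% c("pedigree_blup", "ssgblup") && is.null(ped)) {
    stop(model_kind, " requires a pedigree")
  }
  if (model_kind %in% c("gblup", "ssgblup") && is.null(genotypes)) {
    stop(model_kind, " requires genotypes")
  }
  if (model_kind == "ssgblup" && is.null(genotyped_ids)) {
    genotyped_ids <- rownames(genotypes$codes)
  }
  if (model_kind == "ssgblup" && length(genotyped_ids) == 0) {
    model_struct <- "A"   # no genotyped block: single-step reduces to A
  } else {
    model_struct <- switch(model_kind, pedigree_blup = "A", gblup = "G", ssgblup = "H")
  }
  if (model_struct == "A") {
    K <- build_A(ped)$values
    K_inv <- chol_solve(K)
  } else if (model_struct == "G") {
    G <- build_G(genotypes)$values
    Greg <- g_reg * G + (1 - g_reg) * diag(nrow(G))
    dimnames(Greg) <- dimnames(G)
    K <- Greg
    K_inv <- chol_solve(Greg)
  } else {
    A <- build_A(ped)$values
    A_inv <- chol_solve(A)
    gg <- genotypes[genotyped_ids, ]
    G <- build_G(gg)$values
    Greg <- g_reg * G + (1 - g_reg) * diag(nrow(G))
    dimnames(Greg) <- dimnames(G)
    G_inv <- chol_solve(Greg)
    A22 <- A[genotyped_ids, genotyped_ids, drop = FALSE]
    A22_inv <- chol_solve(A22)
    H_inv <- build_H_inv(A_inv, G_inv, A22_inv, genotyped_ids)$values
    K_inv <- H_inv
    K <- chol_solve(H_inv)
  }
  ids <- rownames(K_inv)
  obs <- phenotypes[!is.na(phenotypes[[trait]]) & phenotypes$id %in% ids, , drop = FALSE]
  if (nrow(obs) < 3) stop("too few phenotyped individuals in the relationship matrix")
  y <- obs[[trait]]
  X <- design_matrix(obs, fixed_factors)
  if (is.null(varcomp)) {
    K_obs <- K[obs$id, obs$id, drop = FALSE]
    varcomp <- estimate_reml(y, X, K_obs)
  }
  Z <- matrix(0, nrow(obs), length(ids), dimnames = list(NULL, ids))
  Z[cbind(seq_len(nrow(obs)), match(obs$id, ids))] <- 1
  fit <- solve_mme(y, X, Z, K_inv, varcomp)
  fit$model_kind <- model_kind
  fit
}
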