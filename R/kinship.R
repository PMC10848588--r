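#' Numerator relationship matrix from a pedigree
#'
#' Tabular method: rows are filled in topological order, with
#' `a(i,i) = 1 + 0.5 a(s,d)` so the diagonal carries inbreeding.
#'
#' @param ped a [pedigree()] (re-ordered internally if needed).
#' @return a `relationship_matrix` of kind `"A"`, indexed by pedigree id.
#' @export
build_A <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped$id, ped$sire, ped$dam)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  s <- idx[ped$sire]; d <- idx[ped$dam]
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(si)) row <- row + 0.5 * A[si, j]
      if (!is.na(di)) row <- row + 0.5 * A[di, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) 0.5 * A[si, di] else 0
  }
  relationship_matrix(A, kind = "A")
}

relationship_matrix <- function(values, kind, regularization = 0) {
  stopifnot(nrow(values) == ncol(values))
  structure(list(values = values, kind = kind, regularization = regularization),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix kind=%s, %d x %d, mean diag %.3f",
              x$kind, nrow(x$values), ncol(x$values), mean(diag(x$values))), "\n")
  if (x$regularization > 0) cat("  regularization:", x$regularization, "\n")
  invisible(x)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = ZZ' / (2 * sum p_i (1 - p_i))` where `Z = M - 2p` and `p` is the
#' observed counted-allele frequency in the genotyped set. Missing calls
#' are mean-imputed (`2p`) at construction time only. Monomorphic markers
#' contribute zero to the numerator and are excluded from the denominator.
#'
#' @param g a [genotype_matrix()].
#' @param freqs optional allele frequencies to centre with (e.g. training
#'   frequencies); default observed frequencies.
#' @return a `relationship_matrix` of kind `"G"` over the genotyped ids.
#' @export
build_G <- function(g, freqs = NULL) {
  if (nrow(g$codes) < 2) stop("build_G needs at least two individuals")
  p <- if (is.null(freqs)) allele_freq(g) else freqs
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic markers: G is undefined")
  M <- g$codes[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(M, 2, 2 * p)
  Z[is.na(Z)] <- 0  # mean imputation after centring
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  relationship_matrix(G, kind = "G")
}

#' Regularize and invert a genomic relationship matrix
#'
#' `G* = w G + (1 - w) I` before inversion; `w = 1` inverts the raw G.
#'
#' @param G a `relationship_matrix` of kind `"G"` (or a plain matrix).
#' @param weight blending weight on G, default 0.99.
#' @return a `relationship_matrix` of kind `"G_inv"`.
#' @export
invert_G <- function(G, weight = 0.99) {
  V <- if (inherits(G, "relationship_matrix")) G$values else G
  Vr <- weight * V + (1 - weight) * diag(nrow(V))
  dimnames(Vr) <- dimnames(V)
  relationship_matrix(chol_solve(Vr), kind = "G_inv", regularization = 1 - weight)
}

## Symmetric positive-definite inverse via Cholesky; falls back to solve().
chol_solve <- function(V) {
  out <- tryCatch(chol2inv(chol(V)), error = function(e) solve(V))
  dimnames(out) <- dimnames(V)
  out
}

#' Single-step blended inverse relationship matrix
#'
#' `H^-1 = A^-1 + [[0, 0], [0, G^-1 - A22^-1]]`, with the addition applied
#' on the genotyped block only. Row/column order follows `A^-1`.
#'
#' @param A_inv inverse numerator relationship matrix (all individuals).
#' @param G_inv inverse genomic relationship matrix (genotyped individuals).
#' @param A22_inv inverse of the pedigree relationship block for the
#'   genotyped individuals.
#' @param genotyped_ids ids of the genotyped block (may be empty, in which
#'   case `H^-1 = A^-1`).
#' @return a `relationship_matrix` of kind `"H_inv"`.
#' @export
build_H_inv <- function(A_inv, G_inv, A22_inv, genotyped_ids) {
  Ai <- if (inherits(A_inv, "relationship_matrix")) A_inv$values else A_inv
  H <- Ai
  if (length(genotyped_ids)) {
    missing_ids <- setdiff(genotyped_ids, rownames(Ai))
    if (length(missing_ids)) {
      stop("genotyped id(s) absent from pedigree: ",
           paste(head(missing_ids, 5), collapse = ", "))
    }
    Gi <- if (inherits(G_inv, "relationship_matrix")) G_inv$values else G_inv
    A22i <- if (inherits(A22_inv, "relationship_matrix")) A22_inv$values else A22_inv
    Gi <- Gi[genotyped_ids, genotyped_ids, drop = FALSE]
    A22i <- A22i[genotyped_ids, genotyped_ids, drop = FALSE]
    H[genotyped_ids, genotyped_ids] <- H[genotyped_ids, genotyped_ids] + Gi - A22i
  }
  reg <- if (inherits(G_inv, "relationship_matrix")) G_inv$regularization else 0
  relationship_matrix(H, kind = "H_inv", regularization = reg)
}

#' Write a relationship matrix as labelled delimited text
#'
#' @param K a `relationship_matrix`.
#' @param path output path.
#' @export
write_relmatrix <- function(K, path) {
  V <- if (inherits(K, "relationship_matrix")) K$values else K
  write.table(data.frame(id = rownames(V), V, check.names = FALSE),
              path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
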