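#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test obtained by full enumeration of the heterozygote
#' count conditional on the observed allele counts. The p-value sums the
#' probabilities of all configurations whose conditional probability does
#' not exceed that of the observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative).
#' @return the exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("zero total genotype count")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  ## heterozygote count has the parity of the rare-allele count
  het <- seq(rare %% 2, rare, by = 2)
  ## log P(n_Aa = h | allele counts) up to a constant:
  ##   n! / (nAA! nAa! naa!) * 2^nAa / [ (2n)! / (nA! na!) ]
  hom_rare <- (rare - het) / 2
  hom_common <- (n - het - hom_rare)
  logp <- lfactorial(n) - lfactorial(het) - lfactorial(hom_rare) -
    lfactorial(hom_common) + het * log(2)
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)
  obs <- which(het == n_Aa)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

#' Marker quality control
#'
#' Removes markers failing any of the standard filters, applied in the
#' fixed order (non-autosome, call rate, MAF, Hardy-Weinberg). Each
#' dropped marker is attributed to the first filter it fails, making the
#' removal report deterministic.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (markers with MAF strictly
#'   below are removed). Default 0.05.
#' @param call_rate_min minimum proportion of non-missing calls. Default 0.90.
#' @param hwe_p_min minimum exact Hardy-Weinberg p-value. Default 1e-6.
#'   Set to `NULL` or 0 to disable.
#' @param autosomes_only drop markers on non-autosomal chromosomes
#'   (labels in `c("X","Y","Z","W","MT")`, case-insensitive, or with an
#'   `"chrX"`-style suffix). Default TRUE.
#' @return list with elements `genotypes` (filtered [genotype_matrix()])
#'   and `report` (a `qc_report`).
#' @export
qc_filter <- function(g, maf_min = 0.05, call_rate_min = 0.90,
                      hwe_p_min = 1e-6, autosomes_only = TRUE) {
  m <- ncol(g$codes)
  chrom <- toupper(sub("^CHR", "", toupper(g$map$chrom)))
  non_auto <- chrom %in% c("X", "Y", "Z", "W", "M", "MT")
  call_rate <- colMeans(!is.na(g$codes))
  p <- allele_freq(g)
  mafv <- pmin(p, 1 - p)
  mafv[is.nan(mafv)] <- 0
  hwe_p <- rep(1, m)
  use_hwe <- !is.null(hwe_p_min) && hwe_p_min > 0
  if (use_hwe) {
    for (j in seq_len(m)) {
      cj <- g$codes[, j]
      n2 <- sum(cj == 2L, na.rm = TRUE)
      n1 <- sum(cj == 1L, na.rm = TRUE)
      n0 <- sum(cj == 0L, na.rm = TRUE)
      if (n0 + n1 + n2 > 0) hwe_p[j] <- hwe_exact_test(n2, n1, n0)
    }
  }
  fail_auto <- autosomes_only & non_auto
  fail_call <- call_rate < call_rate_min
  fail_maf <- mafv < maf_min
  fail_hwe <- use_hwe & hwe_p < hwe_p_min
  reason <- rep(NA_character_, m)
  reason[fail_hwe] <- "hwe"
  reason[fail_maf] <- "maf"
  reason[fail_call] <- "call_rate"
  reason[fail_auto] <- "non_autosome"   # first-failing filter wins
  keep <- is.na(reason)
  if (!any(keep)) {
    dominating <- names(sort(table(reason), decreasing = TRUE))[1]
    stop("all ", m, " markers removed by QC (dominating filter: ", dominating, ")")
  }
  report <- structure(list(
    n_markers_in = m,
    n_markers_out = sum(keep),
    removals = c(non_autosome = sum(reason == "non_autosome", na.rm = TRUE),
                 call_rate = sum(reason == "call_rate", na.rm = TRUE),
                 maf = sum(reason == "maf", na.rm = TRUE),
                 hwe = sum(reason == "hwe", na.rm = TRUE)),
    per_marker = data.frame(marker = g$map$marker, maf = mafv,
                            call_rate = call_rate, hwe_p = hwe_p,
                            removed = !keep, reason = reason,
                            stringsAsFactors = FALSE)
  ), class = "qc_report")
  list(genotypes = g[, keep], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("marker QC:", x$n_markers_in, "in,", x$n_markers_out, "out\n")
  cat("  removed:", paste(names(x$removals), x$removals, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a QC report as delimited text
#'
#' @param report a `qc_report` from [qc_filter()].
#' @param path output path for the per-marker table.
#' @export
write_qc_report <- function(report, path) {
  write.table(report$per_marker, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Randomly subsample markers
#'
#' Uniform subset without replacement; marker-map order is preserved.
#'
#' @param g a [genotype_matrix()].
#' @param target_count number of markers to keep.
#' @param seed integer seed.
#' @return a [genotype_matrix()] with `target_count` markers.
#' @export
subsample_markers <- function(g, target_count, seed = 1L) {
  m <- ncol(g$codes)
  if (target_count > m) stop("target_count (", target_count, ") exceeds available markers (", m, ")")
  if (target_count < 1) stop("target_count must be >= 1")
  if (target_count == m) return(g)
  keep <- sort(with_seed(seed, sample.int(m, target_count)))
  g[, keep]
}

## Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
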