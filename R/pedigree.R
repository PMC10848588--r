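#' Construct a pedigree
#'
#' Ordered (id, sire, dam) triples. Unknown parents are `NA`. On
#' construction the records are topologically ordered (parents before
#' offspring); a cyclic pedigree is rejected with the offending id.
#'
#' @param id character vector of unique individual ids.
#' @param sire,dam parent ids (`NA` or `"0"` for unknown).
#' @param generation optional integer generation labels.
#' @return An object of class `pedigree`: a data.frame with columns
#'   `id`, `sire`, `dam` (and `generation` if given), parents ordered
#'   before offspring.
#' @export
pedigree <- function(id, sire = NA, dam = NA, generation = NULL) {
  id <- as.character(id)
  n <- length(id)
  sire <- as.character(rep_len(sire, n)); dam <- as.character(rep_len(dam, n))
  sire[sire %in% "0"] <- NA; dam[dam %in% "0"] <- NA
  if (anyDuplicated(id)) stop("pedigree ids must be unique: ", id[duplicated(id)][1])
  unknown_parents <- setdiff(c(sire, dam), c(id, NA))
  if (length(unknown_parents)) {
    stop("parent id(s) not present in pedigree: ",
         paste(head(unknown_parents, 5), collapse = ", "))
  }
  df <- data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
  if (!is.null(generation)) df$generation <- generation
  df <- topo_sort_pedigree(df)
  structure(df, class = c("pedigree", "data.frame"))
}

## Kahn's algorithm; errors on a cycle naming an individual inside it.
topo_sort_pedigree <- function(df) {
  n <- nrow(df)
  idx <- seq_len(n)
  names(idx) <- df$id
  s <- idx[df$sire]; d <- idx[df$dam]  # NA where unknown
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(s[i], d[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) < n) {
    bad <- df$id[setdiff(seq_len(n), order)][1]
    stop("pedigree contains a cycle involving individual ", bad)
  }
  df[order, , drop = FALSE]
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(is.na(x$sire) & is.na(x$dam))
  cat("pedigree:", nrow(x), "individuals (", founders, "founders )\n")
  NextMethod()
}

#' Check genotypes against a pedigree for Mendelian consistency
#'
#' A trio is impossible when a parent is homozygous and the offspring is
#' homozygous for the opposite allele at some marker, or when both parents
#' are homozygous and the offspring code is incompatible with their
#' transmitted alleles.
#'
#' @param g a [genotype_matrix()].
#' @param ped a [pedigree()].
#' @return integer count of (trio, marker) Mendelian violations among
#'   individuals that are genotyped.
#' @export
check_mendelian <- function(g, ped) {
  ids <- rownames(g$codes)
  viol <- 0L
  for (i in seq_len(nrow(ped))) {
    o <- ped$id[i]
    if (!(o %in% ids)) next
    go <- g$codes[o, ]
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (is.na(p) || !(p %in% ids)) next
      gp <- g$codes[p, ]
      ## parent hom 0 -> offspring cannot be 2 (and vice versa)
      viol <- viol + sum(gp == 0L & go == 2L, na.rm = TRUE) +
        sum(gp == 2L & go == 0L, na.rm = TRUE)
    }
    s <- ped$sire[i]; d <- ped$dam[i]
    if (!is.na(s) && !is.na(d) && s %in% ids && d %in% ids) {
      gs <- g$codes[s, ]; gd <- g$codes[d, ]
      ## both parents homozygous: offspring code is determined
      det <- !is.na(gs) & !is.na(gd) & !is.na(go) & gs %% 2L == 0L & gd %% 2L == 0L
      viol <- viol + sum(det & go != (gs + gd) / 2L)
      ## one hom x one het cases are covered by the single-parent rule above
    }
  }
  viol
}
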