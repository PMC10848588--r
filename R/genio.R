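#' Construct a genotype matrix object
#'
#' Container for biallelic genotype codes together with the marker map.
#' Codes count copies of the counted allele (0, 1, 2) with `NA` for a
#' missing call.
#'
#' @param codes integer matrix, individuals in rows, markers in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param individual_ids character vector of unique individual identifiers.
#' @param marker_map data.frame with columns `marker`, `chrom`, `bp`,
#'   `allele1`, `allele2`. Positions must be strictly increasing within a
#'   chromosome.
#' @param counted_allele which allele the codes count: `"allele2"`
#'   (the default, ALT/A1-style counting) or `"allele1"`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `codes`, `map` and `counted_allele`.
#' @export
genotype_matrix <- function(codes, individual_ids = rownames(codes),
                            marker_map = NULL,
                            counted_allele = "allele2") {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  n <- nrow(codes); m <- ncol(codes)
  if (m < 1L || n < 1L) stop("genotype matrix must have at least one individual and one marker")
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n))
  individual_ids <- as.character(individual_ids)
  if (anyDuplicated(individual_ids)) stop("individual ids must be unique")
  if (length(individual_ids) != n) stop("individual_ids length does not match rows of codes")
  if (is.null(marker_map)) {
    marker_map <- data.frame(
      marker = if (!is.null(colnames(codes))) colnames(codes) else paste0("snp", seq_len(m)),
      chrom = "1", bp = seq_len(m),
      allele1 = "A", allele2 = "B",
      stringsAsFactors = FALSE
    )
  }
  marker_map <- as.data.frame(marker_map, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "bp", "allele1", "allele2")
  if (!all(need %in% names(marker_map))) {
    stop("marker_map must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(marker_map) != m) stop("marker_map rows do not match columns of codes")
  marker_map$chrom <- as.character(marker_map$chrom)
  marker_map$bp <- as.numeric(marker_map$bp)
  for (ch in unique(marker_map$chrom)) {
    bp <- marker_map$bp[marker_map$chrom == ch]
    if (any(diff(bp) <= 0)) stop("bp positions must be strictly increasing within chromosome ", ch)
  }
  bad <- codes[!is.na(codes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  counted_allele <- match.arg(counted_allele, c("allele2", "allele1"))
  dimnames(codes) <- list(individual_ids, marker_map$marker)
  structure(list(codes = codes, map = marker_map, counted_allele = counted_allele),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$codes), "individuals x", ncol(x$codes), "markers\n")
  cat("  chromosomes:", paste(unique(x$map$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$codes))
  cat(sprintf("  missing rate: %.4f; counted allele: %s\n", miss, x$counted_allele))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i individual index (ids, logical or integer).
#' @param j marker index.
#' @param ... ignored.
#' @return a `genotype_matrix` restricted to the selected rows/columns.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$codes))
  if (missing(j)) j <- seq_len(ncol(x$codes))
  codes <- x$codes[i, j, drop = FALSE]
  genotype_matrix(codes, rownames(codes), x$map[j, , drop = FALSE],
                  counted_allele = x$counted_allele)
}

#' Per-marker allele frequency of the counted allele
#'
#' Computed on non-missing calls only.
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector of frequencies, one per marker (NaN if all calls
#'   at a marker are missing).
#' @export
allele_freq <- function(g) {
  colMeans(g$codes, na.rm = TRUE) / 2
}

#' Per-marker minor allele frequency
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector, `pmin(p, 1 - p)` of the counted-allele frequency.
#' @export
maf <- function(g) {
  p <- allele_freq(g)
  pmin(p, 1 - p)
}

## ---------------------------------------------------------------------------
## PLINK bed/bim/fam

#' Write genotypes as a PLINK bed/bim/fam triple
#'
#' Writes a SNP-major v1.00 `.bed` with the standard two-bit encoding
#' (00 = two copies of allele1, 10 = heterozygote, 11 = zero copies,
#' 01 = missing). The counted allele is written as A1 (allele1 column of
#' the `.bim`) so that a round trip preserves codes exactly.
#'
#' @param g a [genotype_matrix()].
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` are created.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  counted <- if (g$counted_allele == "allele2") g$map$allele2 else g$map$allele1
  other <- if (g$counted_allele == "allele2") g$map$allele1 else g$map$allele2
  bim <- data.frame(chrom = g$map$chrom, marker = g$map$marker, cm = 0,
                    bp = as.integer(g$map$bp), a1 = counted, a2 = other)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  ids <- rownames(g$codes)
  fam <- data.frame(fid = ids, iid = ids, father = 0, mother = 0, sex = 0, pheno = -9)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  n <- nrow(g$codes); m <- ncol(g$codes)
  ## two-bit codes per individual, packed 4 per byte, low bits first
  lookup <- c(`2` = 0L, `1` = 2L, `0` = 3L)  # copies of A1 -> bit pair
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  npad <- 4L * ceiling(n / 4L)
  for (j in seq_len(m)) {
    cj <- g$codes[, j]
    bits <- integer(npad)
    bits[seq_len(n)] <- ifelse(is.na(cj), 1L, lookup[as.character(cj)])
    bits[seq_len(npad) > n] <- 1L  # pad with missing
    mat <- matrix(bits, nrow = 4L)
    bytes <- as.integer(mat[1, ] + mat[2, ] * 4L + mat[3, ] * 16L + mat[4, ] * 64L)
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

read_bim <- function(path) {
  bim <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "marker", "cm", "bp", "a1", "a2"))
  bim
}

read_plink_bed <- function(prefix) {
  bim <- read_bim(paste0(prefix, ".bim"))
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = 3 + m * ceiling(n / 4) + 4)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file (bad magic bytes): ", prefix, ".bed")
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major (v1.00) bed files are supported")
  body <- raw[-(1:3)]
  bytes_per_marker <- ceiling(n / 4)
  if (length(body) != m * bytes_per_marker) {
    stop(sprintf("bed file size mismatch: expected %d data bytes for %d individuals x %d markers, found %d",
                 m * bytes_per_marker, n, m, length(body)))
  }
  ints <- as.integer(body)
  ## unpack all two-bit fields at once
  pairs <- rbind(ints %% 4L, (ints %/% 4L) %% 4L, (ints %/% 16L) %% 4L, ints %/% 64L)
  decode <- c(2L, NA_integer_, 1L, 0L)  # bitpair 0,1,2,3 -> copies of A1
  codes <- matrix(decode[pairs + 1L], nrow = 4L * bytes_per_marker)[seq_len(n), , drop = FALSE]
  list(codes = codes, bim = bim, fam = fam)
}

#' Read genotypes from PLINK bed/bim/fam or VCF
#'
#' @param path for `format = "plink_bed"`, the file prefix (without
#'   extension); for `format = "vcf"`, the VCF file path.
#' @param format `"plink_bed"` or `"vcf"`.
#' @return a [genotype_matrix()]. PLINK codes count the A1 allele; VCF
#'   codes count the ALT allele. Multi-allelic VCF records are skipped
#'   with a message.
#' @export
read_genotypes <- function(path, format = c("plink_bed", "vcf")) {
  format <- match.arg(format)
  if (format == "plink_bed") {
    parts <- read_plink_bed(path)
    map <- data.frame(marker = parts$bim$marker, chrom = as.character(parts$bim$chrom),
                      bp = parts$bim$bp, allele1 = parts$bim$a2, allele2 = parts$bim$a1,
                      stringsAsFactors = FALSE)
    ## counted allele = A1, stored in the allele2 slot so counting is "allele2"
    genotype_matrix(parts$codes, parts$fam[[2]], map, counted_allele = "allele2")
  } else {
    read_vcf_genotypes(path)
  }
}

## ---------------------------------------------------------------------------
## VCF

#' Write genotypes as VCF 4.2 (GT field only)
#'
#' @param g a [genotype_matrix()].
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  ref <- if (g$counted_allele == "allele2") g$map$allele1 else g$map$allele2
  alt <- if (g$counted_allele == "allele2") g$map$allele2 else g$map$allele1
  ids <- rownames(g$codes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=gskit",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  gt_map <- c("0/0", "0/1", "1/1")
  codes <- g$codes
  for (j in seq_len(ncol(codes))) {
    cj <- codes[, j]
    gt <- ifelse(is.na(cj), "./.", gt_map[cj + 1L])
    writeLines(paste(c(g$map$chrom[j], format(g$map$bp[j], scientific = FALSE),
                       g$map$marker[j], ref[j], alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  biallelic <- !grepl(",", alt) & alt != "." & !grepl(",", fix[, "REF"])
  n_skip <- sum(!biallelic)
  if (n_skip > 0) {
    message(n_skip, " non-biallelic VCF record(s) skipped")
  }
  if (!any(biallelic)) stop("no biallelic records in VCF: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  ## count ALT alleles from the GT string; any missing allele -> NA
  codes <- t(apply(gt, 1, function(row) {
    row <- gsub("\\|", "/", row)
    out <- rep(NA_integer_, length(row))
    known <- !is.na(row) & !grepl("\\.", row)
    parts <- strsplit(row[known], "/", fixed = TRUE)
    out[known] <- vapply(parts, function(p) sum(as.integer(p)), integer(1))
    out
  }))
  codes <- t(codes)  # individuals x markers
  ids <- colnames(gt)
  mk <- fix[, "ID"]
  mk[is.na(mk) | mk == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(mk) | mk == "."]
  map <- data.frame(marker = mk, chrom = fix[, "CHROM"], bp = as.numeric(fix[, "POS"]),
                    allele1 = fix[, "REF"], allele2 = alt[biallelic],
                    stringsAsFactors = FALSE)
  genotype_matrix(codes, ids, map, counted_allele = "allele2")
}

## ---------------------------------------------------------------------------
## Pedigree and phenotype tables

#' Read / write a three-column pedigree file
#'
#' Delimited text with columns id, sire, dam; `0` denotes an unknown parent.
#'
#' @param path file path.
#' @return `read_pedigree()` returns a [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("id", "sire", "dam")
  df$sire[df$sire %in% "0"] <- NA
  df$dam[df$dam %in% "0"] <- NA
  pedigree(df$id, df$sire, df$dam)
}

#' @param ped a [pedigree()].
#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' Tab-delimited with an `id` column, trait columns, and categorical
#' fixed-effect columns (e.g. `sex`, `feed_room`). Missing values as `NA`.
#'
#' @param path file path.
#' @return `read_phenotypes()` returns a data.frame.
#' @export
read_phenotypes <- function(path) {
  read.table(path, header = TRUE, stringsAsFactors = FALSE, sep = "\t")
}

#' @param pheno phenotype data.frame.
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(pheno, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
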