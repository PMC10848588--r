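## Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## Small polygenic study: 200 F2, 600 markers on 3 chromosomes, h2 = 0.5.
fix_small_study <- function() {
  cached("small_study", sim_study(n_f2 = 200, m_total = 600, n_chromosomes = 3,
                                  h2 = 0.5, n_f1 = 30, seed = 101))
}

## Tiny genotype matrix built by hand.
fix_tiny_geno <- function(codes, chrom = NULL) {
  m <- ncol(codes)
  map <- data.frame(marker = paste0("m", seq_len(m)),
                    chrom = if (is.null(chrom)) rep("1", m) else chrom,
                    bp = seq(1000, by = 1000, length.out = m),
                    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  genotype_matrix(codes, paste0("i", seq_len(nrow(codes))), map)
}

## Monte-Carlo oracle for the numerator relationship matrix: drop unique
## founder alleles down the pedigree many times; realized additive
## relationship = mean IBD allele sharing / 2 (diagonal: 1 + realized F).
gene_drop_A_oracle <- function(ped, ndrops = 10000L, seed = 99) {
  set.seed(seed)
  n <- nrow(ped)
  al1 <- matrix(0L, n, ndrops); al2 <- matrix(0L, n, ndrops)
  rownames(al1) <- rownames(al2) <- ped$id
  nxt <- 0L
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (is.na(s)) {
      al1[i, ] <- nxt + 1L; nxt <- nxt + 1L
    } else {
      pick <- runif(ndrops) < 0.5
      al1[i, ] <- ifelse(pick, al1[s, ], al2[s, ])
    }
    if (is.na(d)) {
      al2[i, ] <- nxt + 1L; nxt <- nxt + 1L
    } else {
      pick <- runif(ndrops) < 0.5
      al2[i, ] <- ifelse(pick, al1[d, ], al2[d, ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        A[i, i] <- mean(2 + 2 * (al1[i, ] == al2[i, ])) / 2
      } else {
        A[i, j] <- mean((al1[i, ] == al1[j, ]) + (al1[i, ] == al2[j, ]) +
                        (al2[i, ] == al1[j, ]) + (al2[i, ] == al2[j, ])) / 2
      }
    }
  }
  A
}

## Independent exact-HWE oracle via the Levene/Haldane recurrence.
hwe_recurrence_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa; na <- 2 * naa + nAa
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  probs[1] <- 1
  if (length(hets) > 1) {
    for (k in 2:length(hets)) {
      h <- hets[k - 1]
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      probs[k] <- probs[k - 1] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- which(hets == nAa)
  sum(probs[probs <= probs[obs] * (1 + 1e-12)])
}

## Genotypes of n unrelated individuals in HWE at the given frequencies.
sim_hwe_geno <- function(n, p, seed = 1) {
  set.seed(seed)
  codes <- vapply(p, function(pj) rbinom(n, 2, pj), numeric(n))
  fix_tiny_geno(matrix(as.integer(codes), n, length(p)))
}
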