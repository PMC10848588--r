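#' Founder-population specification
#'
#' Parameters for simulating divergent founder lines of a cross. Markers
#' are laid out evenly along each chromosome; linkage disequilibrium is
#' induced by a first-order autoregressive latent process along each
#' haplotype whose correlation decays as `exp(-ld_decay_rate * distance_bp)`.
#'
#' @param n_founders_per_line founders in each line.
#' @param n_chromosomes number of autosomes.
#' @param markers_per_chromosome markers per chromosome.
#' @param chromosome_length_bp chromosome length in base pairs.
#' @param maf_low,maf_high bounds in (0, 0.5] for the per-line allele
#'   frequency draw.
#' @param ld_decay_rate per-bp decay of the latent haplotype correlation
#'   (0 = complete correlation along the chromosome; large = linkage
#'   equilibrium). Default 2e-6.
#' @param n_lines number of founder lines (default 2).
#' @param line_divergence probability that the two lines sit on opposite
#'   sides of 0.5 at a marker (default 0.5); ignored with one line.
#' @param seed integer seed.
#' @return an object of class `founder_spec`.
#' @export
founder_spec <- function(n_founders_per_line = 30, n_chromosomes = 5,
                         markers_per_chromosome = 400,
                         chromosome_length_bp = 5e7,
                         maf_low = 0.1, maf_high = 0.5,
                         ld_decay_rate = 2e-6, n_lines = 2,
                         line_divergence = 0.5, seed = 1L) {
  stopifnot(n_founders_per_line >= 1, n_chromosomes >= 1,
            markers_per_chromosome >= 1, chromosome_length_bp >= 1)
  if (!(maf_low > 0 && maf_high <= 0.5 && maf_low <= maf_high)) {
    stop("need 0 < maf_low <= maf_high <= 0.5")
  }
  if (ld_decay_rate < 0) stop("ld_decay_rate must be >= 0")
  structure(as.list(environment()), class = "founder_spec")
}

marker_layout <- function(spec) {
  bp <- round(seq(1, spec$chromosome_length_bp,
                  length.out = spec$markers_per_chromosome))
  bp <- bp + seq_len(spec$markers_per_chromosome) - 1  # enforce strict increase
  data.frame(
    marker = paste0("snp", rep(seq_len(spec$n_chromosomes), each = spec$markers_per_chromosome),
                    "_", rep(seq_len(spec$markers_per_chromosome), spec$n_chromosomes)),
    chrom = as.character(rep(seq_len(spec$n_chromosomes), each = spec$markers_per_chromosome)),
    bp = rep(bp, spec$n_chromosomes),
    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE
  )
}

## One haplotype per row: latent Gaussian AR(1) along each chromosome,
## thresholded at qnorm(p_j) so the marginal allele frequency is exact.
sim_haplotypes <- function(n_hap, p, map, ld_decay_rate) {
  m <- length(p)
  thr <- qnorm(p)
  z <- matrix(rnorm(n_hap * m), n_hap, m)
  for (ch in unique(map$chrom)) {
    j <- which(map$chrom == ch)
    if (length(j) < 2) next
    rho <- exp(-ld_decay_rate * diff(map$bp[j]))
    for (k in 2:length(j)) {
      z[, j[k]] <- rho[k - 1] * z[, j[k - 1]] +
        sqrt(1 - rho[k - 1]^2) * z[, j[k]]
    }
  }
  ## allele 1 where the latent value falls below the frequency threshold
  (z < matrix(thr, n_hap, m, byrow = TRUE)) * 1L
}

#' Simulate founder lines
#'
#' Generates two (or `n_lines`) founder lines with line-divergent allele
#' frequencies and within-chromosome LD. Haplotypes are stored in the
#' result so gene dropping can recombine them later.
#'
#' @param spec a [founder_spec()].
#' @return a [genotype_matrix()] with extra fields `haplotypes` (a
#'   `2n x m` 0/1 matrix, rows `2i-1`, `2i` belonging to individual `i`)
#'   and `line` (line label per individual).
#' @export
sim_founders <- function(spec) {
  stopifnot(inherits(spec, "founder_spec"))
  map <- marker_layout(spec)
  m <- nrow(map)
  with_seed(spec$seed, {
    p_line <- matrix(runif(m * spec$n_lines, spec$maf_low, spec$maf_high),
                     m, spec$n_lines)
    if (spec$n_lines >= 2) {
      ## divergence: the later lines carry the complementary allele at a
      ## random subset of markers
      for (l in 2:spec$n_lines) {
        flip <- runif(m) < spec$line_divergence
        p_line[flip, l] <- 1 - p_line[flip, l]
      }
    }
    haps <- vector("list", spec$n_lines)
    for (l in seq_len(spec$n_lines)) {
      haps[[l]] <- sim_haplotypes(2L * spec$n_founders_per_line, p_line[, l],
                                  map, spec$ld_decay_rate)
    }
    H <- do.call(rbind, haps)
    n <- spec$n_lines * spec$n_founders_per_line
    codes <- H[seq(1, 2 * n, by = 2), , drop = FALSE] +
      H[seq(2, 2 * n, by = 2), , drop = FALSE]
    ids <- paste0("L", rep(seq_len(spec$n_lines), each = spec$n_founders_per_line),
                  "_", rep(seq_len(spec$n_founders_per_line), spec$n_lines))
    g <- genotype_matrix(codes, ids, map)
    g$haplotypes <- H
    rownames(g$haplotypes) <- paste0(rep(ids, each = 2), c(".1", ".2"))
    g$line <- rep(seq_len(spec$n_lines), each = spec$n_founders_per_line)
    g
  })
}

## Meiosis: recombine an individual's two haplotypes into one gamete.
## Crossover points are a Poisson process along each chromosome at
## `recomb_rate_per_bp` (default 1 cM/Mb = 1e-8 per bp).
make_gamete <- function(hap1, hap2, map, recomb_rate_per_bp) {
  gam <- integer(length(hap1))
  for (ch in unique(map$chrom)) {
    j <- which(map$chrom == ch)
    bp <- map$bp[j]
    L <- max(bp)
    current <- sample.int(2L, 1L)  # which haplotype starts the chromosome
    if (recomb_rate_per_bp > 0) {
      n_xo <- rpois(1, recomb_rate_per_bp * L)
      xo <- sort(runif(n_xo, 0, L))
    } else xo <- numeric(0)
    src <- (current - 1L + findInterval(bp, xo)) %% 2L + 1L
    gam[j] <- ifelse(src == 1L, hap1[j], hap2[j])
  }
  gam
}

#' Simulate an F2 cross from two founder lines
#'
#' F1 individuals are produced by line-1 x line-2 matings; F2 individuals
#' by matings between distinct F1s. Genotypes come from gene dropping with
#' recombination (Poisson crossover process along each chromosome); the
#' pedigree records all matings.
#'
#' @param founders result of [sim_founders()] (two or more lines).
#' @param n_f1 number of F1 individuals.
#' @param n_f2 number of F2 individuals.
#' @param recomb_rate_per_bp crossovers per bp per meiosis
#'   (default `1e-8`, i.e. 1 cM/Mb).
#' @param seed integer seed.
#' @return list with `pedigree` (a [pedigree()] with a `generation`
#'   column: 0 founders, 1 F1, 2 F2) and `genotypes` (a
#'   [genotype_matrix()] for all individuals, haplotypes retained).
#' @export
sim_cross <- function(founders, n_f1, n_f2, recomb_rate_per_bp = 1e-8, seed = 1L) {
  if (is.null(founders$haplotypes) || is.null(founders$line)) {
    stop("founders must come from sim_founders() (haplotypes required)")
  }
  if (max(founders$line) < 2) stop("an F2 cross needs two founder lines")
  if (n_f1 < 2 && n_f2 > 0) stop("F2 requested but fewer than two F1 individuals")
  map <- founders$map
  f_ids <- rownames(founders$codes)
  line1 <- f_ids[founders$line == 1]
  line2 <- f_ids[founders$line == 2]
  with_seed(seed, {
    hap <- founders$haplotypes
    hap_of <- function(id) list(hap[paste0(id, ".1"), ], hap[paste0(id, ".2"), ])
    all_ids <- f_ids
    sire <- rep(NA_character_, length(f_ids)); dam <- rep(NA_character_, length(f_ids))
    gen <- rep(0L, length(f_ids))
    new_hap <- list()
    breed <- function(s_id, d_id) {
      hs <- hap_of(s_id); hd <- hap_of(d_id)
      rbind(make_gamete(hs[[1]], hs[[2]], map, recomb_rate_per_bp),
            make_gamete(hd[[1]], hd[[2]], map, recomb_rate_per_bp))
    }
    ## F1: random line-1 sire x line-2 dam
    f1_ids <- paste0("F1_", seq_len(n_f1))
    for (k in seq_len(n_f1)) {
      s <- sample(line1, 1); d <- sample(line2, 1)
      hk <- breed(s, d)
      rownames(hk) <- paste0(f1_ids[k], c(".1", ".2"))
      new_hap[[length(new_hap) + 1L]] <- hk
      all_ids <- c(all_ids, f1_ids[k]); sire <- c(sire, s); dam <- c(dam, d)
      gen <- c(gen, 1L)
    }
    hap <- rbind(hap, do.call(rbind, new_hap))
    new_hap <- list()
    ## F2: random pairs of distinct F1s
    f2_ids <- if (n_f2 > 0) paste0("F2_", seq_len(n_f2)) else character(0)
    for (k in seq_len(n_f2)) {
      pair <- sample(f1_ids, 2)
      hk <- breed(pair[1], pair[2])
      rownames(hk) <- paste0(f2_ids[k], c(".1", ".2"))
      new_hap[[length(new_hap) + 1L]] <- hk
      all_ids <- c(all_ids, f2_ids[k]); sire <- c(sire, pair[1]); dam <- c(dam, pair[2])
      gen <- c(gen, 2L)
    }
    if (length(new_hap)) hap <- rbind(hap, do.call(rbind, new_hap))
    n <- length(all_ids)
    codes <- hap[2 * seq_len(n) - 1L, , drop = FALSE] + hap[2 * seq_len(n), , drop = FALSE]
    g <- genotype_matrix(codes, all_ids, map)
    g$haplotypes <- hap
    ped <- pedigree(all_ids, sire, dam, generation = gen)
    list(pedigree = ped, genotypes = g)
  })
}

#' Trait-architecture specification
#'
#' The five architectures mirror the prior families of the Bayesian
#' marker-effect models, so each sampler can be exercised on data matching
#' its own assumptions.
#'
#' @param kind one of `"polygenic"`, `"sparse_t"`, `"normal_mixture_pi"`,
#'   `"maf_coupled_S"`, `"four_component_R"`.
#' @param n_qtl number of causal markers for `sparse_t`.
#' @param pi proportion of markers with non-zero effect
#'   (`normal_mixture_pi`, `maf_coupled_S`).
#' @param S MAF-coupling exponent (`maf_coupled_S` only): per-marker effect
#'   variance is scaled by `(2 p (1-p))^S`.
#' @param component_weights simplex of four proportions for
#'   `four_component_R` (variance classes 0, 0.01, 0.1, 1).
#' @param df_t degrees of freedom of the scaled t for `sparse_t` (default 4).
#' @param h2_target target narrow-sense heritability in `[0, 1]`.
#' @return an object of class `trait_architecture`.
#' @export
trait_architecture <- function(kind = c("polygenic", "sparse_t", "normal_mixture_pi",
                                        "maf_coupled_S", "four_component_R"),
                               n_qtl = 10, pi = 0.05, S = 0,
                               component_weights = c(0.95, 0.03, 0.015, 0.005),
                               df_t = 4, h2_target = 0.5) {
  kind <- match.arg(kind)
  if (pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
  if (h2_target < 0 || h2_target > 1) stop("h2_target must lie in [0, 1]")
  if (abs(sum(component_weights) - 1) > 1e-8 || any(component_weights < 0)) {
    stop("component_weights must be a simplex of four non-negative proportions")
  }
  if (length(component_weights) != 4) stop("component_weights must have length 4")
  structure(list(kind = kind, n_qtl = n_qtl, pi = pi, S = S,
                 component_weights = component_weights, df_t = df_t,
                 h2_target = h2_target), class = "trait_architecture")
}

#' Simulate marker effects under a trait architecture
#'
#' @param arch a [trait_architecture()].
#' @param g a [genotype_matrix()] (supplies marker count and, for the
#'   MAF-coupled architecture, allele frequencies).
#' @param seed integer seed.
#' @return numeric vector of per-marker allele-substitution effects.
#' @export
sim_effects <- function(arch, g, seed = 1L) {
  m <- ncol(g$codes)
  if (arch$h2_target > 0) {
    if (arch$kind %in% c("normal_mixture_pi", "maf_coupled_S") && arch$pi == 0) {
      stop("pi = 0 admits no genetic variance yet h2_target > 0")
    }
    if (arch$kind == "sparse_t" && arch$n_qtl == 0) {
      stop("n_qtl = 0 admits no genetic variance yet h2_target > 0")
    }
    if (arch$kind == "four_component_R" && arch$component_weights[1] >= 1) {
      stop("all-null component weights admit no genetic variance yet h2_target > 0")
    }
  }
  with_seed(seed, {
    eff <- numeric(m)
    switch(arch$kind,
      polygenic = {
        eff <- rnorm(m)
      },
      sparse_t = {
        if (arch$n_qtl > 0) {
          qtl <- sample.int(m, min(arch$n_qtl, m))
          ## scaled t via normal with inverse-chi-square variance
          v <- arch$df_t / rchisq(length(qtl), df = arch$df_t)
          eff[qtl] <- rnorm(length(qtl), 0, sqrt(v))
        }
      },
      normal_mixture_pi = {
        nz <- runif(m) < arch$pi
        eff[nz] <- rnorm(sum(nz))
      },
      maf_coupled_S = {
        p <- allele_freq(g)
        p[is.nan(p) | p <= 0 | p >= 1] <- 0.5
        w <- (2 * p * (1 - p))^arch$S
        nz <- runif(m) < arch$pi
        eff[nz] <- rnorm(sum(nz), 0, sqrt(w[nz]))
      },
      four_component_R = {
        gamma <- c(0, 0.01, 0.1, 1)
        comp <- sample.int(4, m, replace = TRUE, prob = arch$component_weights)
        nz <- comp > 1L
        eff[nz] <- rnorm(sum(nz), 0, sqrt(gamma[comp[nz]]))
      }
    )
    eff
  })
}

#' Fixed-effect specification for simulated phenotypes
#'
#' Additive shifts on two categorical factors.
#'
#' @param sex_shift additive shift for the second sex level (trait units).
#' @param room_shifts numeric vector of shifts, one per feed room; length
#'   gives the number of rooms.
#' @return an object of class `fixed_effect_spec`.
#' @export
fixed_effect_spec <- function(sex_shift = 0, room_shifts = c(0, 0)) {
  structure(list(sex_shift = sex_shift, room_shifts = room_shifts),
            class = "fixed_effect_spec")
}

#' Simulate phenotypes from genotypes and marker effects
#'
#' Genetic values are `g = Z u` with `Z` the centred genotype codes.
#' Residual variance is scaled to the *realized* genetic variance,
#' `var(g) (1 - h2) / h2`, so the sample-level heritability matches the
#' target sharply at moderate n. Sex and feed room are assigned uniformly
#' at random and enter as additive shifts.
#'
#' @param g a [genotype_matrix()].
#' @param effects per-marker effect vector from [sim_effects()].
#' @param h2_target target heritability in `[0, 1)`.
#' @param fixed_spec a [fixed_effect_spec()].
#' @param seed integer seed.
#' @param trait_name column name for the trait (default `"trait"`).
#' @return a data.frame with columns `id`, the trait, `sex`, `feed_room`,
#'   and the true genetic value `tbv` (for validation only).
#' @export
sim_phenotypes <- function(g, effects, h2_target = 0.5,
                           fixed_spec = fixed_effect_spec(), seed = 1L,
                           trait_name = "trait") {
  if (h2_target < 0 || h2_target >= 1) stop("h2_target must lie in [0, 1)")
  if (all(effects == 0) && h2_target > 0) {
    stop("all-zero effects admit no genetic variance yet h2_target > 0")
  }
  n <- nrow(g$codes)
  p <- allele_freq(g)
  Z <- sweep(g$codes, 2, 2 * p)
  Z[is.na(Z)] <- 0
  gv <- drop(Z %*% effects)
  with_seed(seed, {
    var_g <- var(gv)
    if (h2_target == 0) {
      gv <- gv * 0
      sigma_e2 <- 1
    } else if (var_g == 0) {
      sigma_e2 <- 1
    } else {
      sigma_e2 <- var_g * (1 - h2_target) / h2_target
    }
    e <- rnorm(n, 0, sqrt(sigma_e2))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    n_rooms <- length(fixed_spec$room_shifts)
    room <- sample(seq_len(n_rooms), n, replace = TRUE)
    y <- gv + e + ifelse(sex == "M", fixed_spec$sex_shift, 0) +
      fixed_spec$room_shifts[room]
    out <- data.frame(id = rownames(g$codes), y = y, sex = sex,
                      feed_room = paste0("room", room), tbv = gv,
                      stringsAsFactors = FALSE)
    names(out)[2] <- trait_name
    out
  })
}

#' Derived growth and breast-morphology traits
#'
#' Average daily gain between two weigh days uses the day-count divisor
#' `(end - start + 1)`; breast-muscle volume is the product
#' `KL x BMW x BMT`.
#'
#' @param weights data.frame of body weights with columns `id` and one
#'   `bw_<day>` column per weigh day, or a named numeric vector for a
#'   single animal (`bw_1`, `bw_19`, ...). Missing later weights give a
#'   missing derived trait.
#' @param intervals list of `c(start_day, end_day)` pairs for ADG traits.
#' @param morphology optional data.frame with columns `id`, `KL`, `BMW`,
#'   `BMT` (cm); adds a `BMV` column (cm^3).
#' @return data.frame with one `adg_<a>_<b>` column per interval and, if
#'   morphology was given, a `BMV` column.
#' @export
derive_traits <- function(weights, intervals = list(c(1, 19), c(1, 28), c(1, 56),
                                                    c(19, 56), c(28, 56)),
                          morphology = NULL) {
  if (is.numeric(weights) && !is.data.frame(weights)) {
    weights <- as.data.frame(c(list(id = "ind1"), as.list(weights)))
  }
  out <- data.frame(id = weights$id, stringsAsFactors = FALSE)
  for (iv in intervals) {
    a <- iv[1]; b <- iv[2]
    if (b <= a) stop("ADG interval must have end day > start day (got ", a, "-", b, ")")
    ca <- paste0("bw_", a); cb <- paste0("bw_", b)
    if (!all(c(ca, cb) %in% names(weights))) {
      stop("weights table lacks column ", ca, " or ", cb)
    }
    if (any(weights[[ca]] < 0, na.rm = TRUE) || any(weights[[cb]] < 0, na.rm = TRUE)) {
      stop("body weights must be non-negative")
    }
    out[[paste0("adg_", a, "_", b)]] <- (weights[[cb]] - weights[[ca]]) / (b - a + 1)
  }
  if (!is.null(morphology)) {
    bmv <- morphology$KL * morphology$BMW * morphology$BMT
    out <- merge(out, data.frame(id = morphology$id, BMV = bmv), by = "id",
                 all.x = TRUE, sort = FALSE)
  }
  out
}

#' Simulate a complete miniature study
#'
#' One call produces everything the downstream evaluation needs: an F2
#' cross of two divergent founder lines, a pedigree, genotypes for a
#' subset of individuals ("genotyped" set), and a phenotype table with
#' sex and feed-room fixed effects.
#'
#' @param n_f2 F2 individuals (default 600).
#' @param m_total total markers (default 2000 over `n_chromosomes`).
#' @param n_chromosomes autosomes (default 5).
#' @param h2 target heritability (default 0.5).
#' @param arch a [trait_architecture()] (default polygenic at `h2`).
#' @param prop_genotyped proportion of phenotyped F2s that are genotyped
#'   (default 1).
#' @param n_f1 F1 individuals (default 60).
#' @param sex_shift,room_shifts fixed-effect shifts
#'   (defaults 100 and c(0, 20, 40)).
#' @param ld_decay_rate founder LD decay per bp (default 2e-6).
#' @param seed integer seed.
#' @return list with `pedigree`, `genotypes` (all individuals),
#'   `genotyped_ids`, `phenotypes` (F2 individuals only), `effects`
#'   (true marker effects) and `h2`.
#' @export
sim_study <- function(n_f2 = 600, m_total = 2000, n_chromosomes = 5,
                      h2 = 0.5, arch = NULL, prop_genotyped = 1,
                      n_f1 = 60, sex_shift = 100, room_shifts = c(0, 20, 40),
                      ld_decay_rate = 2e-6, seed = 1L) {
  if (is.null(arch)) arch <- trait_architecture("polygenic", h2_target = h2)
  spec <- founder_spec(n_founders_per_line = 30, n_chromosomes = n_chromosomes,
                       markers_per_chromosome = ceiling(m_total / n_chromosomes),
                       ld_decay_rate = ld_decay_rate, seed = seed)
  fnd <- sim_founders(spec)
  cross <- sim_cross(fnd, n_f1 = n_f1, n_f2 = n_f2, seed = seed + 1L)
  g <- cross$genotypes
  f2_ids <- cross$pedigree$id[cross$pedigree$generation == 2L]
  eff <- sim_effects(arch, g[f2_ids, ], seed = seed + 2L)
  pheno <- sim_phenotypes(g[f2_ids, ], eff, h2_target = h2,
                          fixed_spec = fixed_effect_spec(sex_shift, room_shifts),
                          seed = seed + 3L)
  n_geno <- round(prop_genotyped * length(f2_ids))
  genotyped_ids <- sort(with_seed(seed + 4L, sample(f2_ids, n_geno)))
  list(pedigree = cross$pedigree, genotypes = g, genotyped_ids = genotyped_ids,
       phenotypes = pheno, effects = eff, h2 = h2)
}

#' Write a simulated study to disk
#'
#' Emits the complete miniature study as standard files: PLINK bed/bim/fam
#' and VCF genotypes for the genotyped set, a delimited pedigree
#' (0 = unknown parent) and a delimited phenotype table.
#'
#' @param study result of [sim_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gg <- study$genotypes[study$genotyped_ids, ]
  write_plink(gg, file.path(dir, "genotypes"))
  write_vcf(gg, file.path(dir, "genotypes.vcf"))
  write_pedigree(study$pedigree, file.path(dir, "pedigree.txt"))
  write_phenotypes(study$phenotypes[setdiff(names(study$phenotypes), "tbv")],
                   file.path(dir, "phenotypes.txt"))
  invisible(dir)
}
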