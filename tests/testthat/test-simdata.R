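test_that("founder simulation is seed-deterministic and honours frequency bounds", {
  spec <- founder_spec(n_founders_per_line = 100, n_chromosomes = 2,
                       markers_per_chromosome = 250, seed = 11)
  g1 <- sim_founders(spec)
  g2 <- sim_founders(spec)
  expect_identical(g1$codes, g2$codes)

  ## forced frequency: maf bounds collapsed at 0.5, one line
  spec5 <- founder_spec(n_founders_per_line = 300, n_chromosomes = 1,
                        markers_per_chromosome = 200, maf_low = 0.5,
                        maf_high = 0.5, n_lines = 1, seed = 3)
  g5 <- sim_founders(spec5)
  expect_equal(mean(allele_freq(g5)), 0.5, tolerance = 0.02)
})

test_that("large LD decay gives near-independent markers; small decay gives LD", {
  base <- function(rate, seed) {
    sim_founders(founder_spec(n_founders_per_line = 250, n_chromosomes = 1,
                              markers_per_chromosome = 60,
                              chromosome_length_bp = 6e6,
                              maf_low = 0.3, maf_high = 0.5, n_lines = 1,
                              ld_decay_rate = rate, seed = seed))
  }
  mean_adj_r2 <- function(g) {
    r <- diag(cor(g$codes)[-1, -ncol(g$codes)])  # adjacent-marker correlations
    mean(r^2)
  }
  ## independence limit
  r2_indep <- mean(vapply(1:3, function(s) mean_adj_r2(base(1, s)), numeric(1)))
  expect_lt(r2_indep, 0.02)
  ## strong LD regime clearly above it
  r2_ld <- mean(vapply(1:3, function(s) mean_adj_r2(base(1e-7, s)), numeric(1)))
  expect_gt(r2_ld, 0.3)
})

test_that("gene dropping respects Mendelian transmission and the no-recombination limit", {
  st <- fix_small_study()
  expect_identical(check_mendelian(st$genotypes, st$pedigree), 0L)

  ## zero recombination: each F2 chromosome is an unrecombined parental haplotype
  fnd <- sim_founders(founder_spec(n_founders_per_line = 5, n_chromosomes = 2,
                                   markers_per_chromosome = 50, seed = 4))
  cr <- sim_cross(fnd, n_f1 = 4, n_f2 = 10, recomb_rate_per_bp = 0, seed = 9)
  hap <- cr$genotypes$haplotypes
  map <- cr$genotypes$map
  ped <- cr$pedigree
  for (i in which(ped$generation == 2L)[1:5]) {
    for (which_h in 1:2) {
      child_h <- hap[paste0(ped$id[i], ".", which_h), ]
      par <- if (which_h == 1) ped$sire[i] else ped$dam[i]
      for (ch in unique(map$chrom)) {
        j <- map$chrom == ch
        match1 <- identical(child_h[j], hap[paste0(par, ".1"), j])
        match2 <- identical(child_h[j], hap[paste0(par, ".2"), j])
        expect_true(match1 || match2)
      }
    }
  }
})

test_that("parent-offspring genomic relationship matches the transmission expectation", {
  ## over transmission, E[G(o,s) | parents] = 0.5 (G(s,s) + G(s,d));
  ## oracle: average the ratio over replicate simulations
  rel_ratio <- vapply(1:10, function(s) {
    fnd <- sim_founders(founder_spec(n_founders_per_line = 20, n_chromosomes = 3,
                                     markers_per_chromosome = 150, seed = s))
    cr <- sim_cross(fnd, n_f1 = 10, n_f2 = 40, seed = s + 100)
    G <- build_G(cr$genotypes)$values
    ped <- cr$pedigree
    f2 <- ped[ped$generation == 2L, ]
    po <- mean(G[cbind(f2$id, f2$sire)])
    expected <- mean(0.5 * (G[cbind(f2$sire, f2$sire)] +
                            G[cbind(f2$sire, f2$dam)]))
    po / expected
  }, numeric(1))
  expect_equal(mean(rel_ratio), 1, tolerance = 0.1)
})

test_that("sim_cross rejects an F2 request without enough F1s", {
  fnd <- sim_founders(founder_spec(n_founders_per_line = 4, n_chromosomes = 1,
                                   markers_per_chromosome = 20, seed = 1))
  expect_error(sim_cross(fnd, n_f1 = 1, n_f2 = 5), "fewer than two F1")
})

test_that("marker-effect architectures have the advertised structure", {
  st <- fix_small_study()
  g <- st$genotypes[st$genotyped_ids, ]
  m <- ncol(g$codes)

  ## empty models
  arch0 <- trait_architecture("normal_mixture_pi", pi = 0, h2_target = 0)
  expect_true(all(sim_effects(arch0, g, seed = 1) == 0))
  archR0 <- trait_architecture("four_component_R",
                               component_weights = c(1, 0, 0, 0), h2_target = 0)
  expect_true(all(sim_effects(archR0, g, seed = 1) == 0))

  ## rejected degenerate requests
  expect_error(sim_effects(trait_architecture("normal_mixture_pi", pi = 0,
                                              h2_target = 0.5), g),
               "no genetic variance")
  expect_error(sim_effects(trait_architecture("four_component_R",
                                              component_weights = c(1, 0, 0, 0),
                                              h2_target = 0.5), g),
               "no genetic variance")

  ## sparse architecture concentrates variance in the QTL
  archs <- trait_architecture("sparse_t", n_qtl = 10)
  effs <- sim_effects(archs, g, seed = 5)
  expect_identical(sum(effs != 0), 10L)

  ## S = 0 decouples effect size from MAF (replicate correlation oracle)
  archS <- trait_architecture("maf_coupled_S", pi = 1, S = 0)
  cors <- vapply(1:100, function(s) {
    e <- sim_effects(archS, g, seed = s)
    cor(abs(e), maf(g))
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.02)
  ## strong negative coupling when S < 0 (rarer alleles, larger effects)
  archSneg <- trait_architecture("maf_coupled_S", pi = 1, S = -1)
  cors_neg <- vapply(1:20, function(s) {
    e <- sim_effects(archSneg, g, seed = s)
    cor(abs(e), maf(g))
  }, numeric(1))
  expect_lt(mean(cors_neg), -0.1)
})

test_that("architecture contrast: sparse traits concentrate genetic variance, polygenic traits spread it", {
  st <- cached("arch_contrast_study",
               sim_study(n_f2 = 200, m_total = 2000, n_chromosomes = 5,
                         n_f1 = 30, seed = 77))
  g <- st$genotypes[st$genotyped_ids, ]
  p <- allele_freq(g)
  Z <- sweep(g$codes, 2, 2 * p)
  var_share_top10 <- function(eff) {
    per_marker <- apply(Z, 2, var) * eff^2  # marginal variance per marker
    top <- order(abs(eff), decreasing = TRUE)[1:10]
    sum(per_marker[top]) / sum(per_marker)
  }
  eff_sparse <- sim_effects(trait_architecture("sparse_t", n_qtl = 10), g, seed = 1)
  eff_poly <- sim_effects(trait_architecture("polygenic"), g, seed = 1)
  expect_gt(var_share_top10(eff_sparse), 0.99)
  expect_lt(var_share_top10(eff_poly), 0.05)
})

test_that("simulated phenotypes hit the target heritability and fixed effects", {
  st <- fix_small_study()
  g <- st$genotypes[st$genotyped_ids, ]

  ## null heritability: phenotype independent of genotype
  eff <- sim_effects(trait_architecture("polygenic"), g, seed = 2)
  ph0 <- sim_phenotypes(g, eff, h2_target = 0, seed = 3)
  expect_true(all(ph0$tbv == 0))

  ## forced sex shift
  ph <- sim_phenotypes(g, eff, h2_target = 0.3,
                       fixed_spec = fixed_effect_spec(sex_shift = 100), seed = 4)
  shift <- mean(ph$trait[ph$sex == "M"]) - mean(ph$trait[ph$sex == "F"])
  expect_equal(shift, 100, tolerance = 15)

  ## rejected degenerate input
  expect_error(sim_phenotypes(g, numeric(ncol(g$codes)), h2_target = 0.5),
               "no genetic variance")

  ## realized heritability across replicates (residual scaled to realized var(g))
  h2_real <- vapply(1:50, function(s) {
    ph <- sim_phenotypes(g, eff, h2_target = 0.4, seed = s)
    var(ph$tbv) / var(ph$trait)
  }, numeric(1))
  expect_lt(abs(mean(h2_real) - 0.4), 0.03)
})

test_that("derived traits follow the growth and morphology formulas", {
  ## day-count divisor: gain from day 1 to day 19 is averaged over 19 days
  expect_equal(derive_traits(c(bw_1 = 45.7, bw_19 = 680.1),
                             intervals = list(c(1, 19)))$adg_1_19,
               33.4, tolerance = 0.05)
  expect_equal(derive_traits(c(bw_1 = 45.7, bw_28 = 1149.4),
                             intervals = list(c(1, 28)))$adg_1_28,
               39.4, tolerance = 0.05)

  ## unit-cube morphology product
  morph <- data.frame(id = "ind1", KL = 10, BMW = 10, BMT = 1)
  out <- derive_traits(data.frame(id = "ind1", bw_1 = 45, bw_56 = 1900),
                       intervals = list(c(1, 56)), morphology = morph)
  expect_equal(out$BMV, 100)

  ## missing later weight propagates; reversed interval rejected
  out2 <- derive_traits(data.frame(id = c("a", "b"), bw_1 = c(45, 46),
                                   bw_56 = c(NA, 1900)),
                        intervals = list(c(1, 56)))
  expect_true(is.na(out2$adg_1_56[1]) && !is.na(out2$adg_1_56[2]))
  expect_error(derive_traits(c(bw_1 = 45, bw_19 = 600),
                             intervals = list(c(19, 1))), "end day")
})

test_that("the miniature study writer emits a consistent file set", {
  st <- cached("tiny_write_study",
               sim_study(n_f2 = 30, m_total = 60, n_chromosomes = 2,
                         n_f1 = 8, seed = 5))
  td <- withr::local_tempdir()
  write_study(st, td)
  g <- read_genotypes(file.path(td, "genotypes"), "plink_bed")
  expect_identical(unname(g$codes),
                   unname(st$genotypes[st$genotyped_ids, ]$codes))
  ped <- read_pedigree(file.path(td, "pedigree.txt"))
  expect_identical(ped$id, st$pedigree$id)
  ph <- read_phenotypes(file.path(td, "phenotypes.txt"))
  expect_identical(ph$id, st$phenotypes$id)
  expect_equal(ph$trait, st$phenotypes$trait)
})
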