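## Small data so even the default 21,000-iteration protocol is fast.
fix_bayes_data <- function() {
  cached("bayes_small", {
    st <- sim_study(n_f2 = 150, m_total = 400, n_chromosomes = 2,
                    n_f1 = 20, seed = 202)
    list(g = st$genotypes[st$genotyped_ids, ], ph = st$phenotypes, st = st)
  })
}

test_that("chain bookkeeping: the default protocol retains exactly 2000 samples", {
  expect_error(mcmc_config(1000, 2000), "burn_in")
  expect_error(mcmc_config(1000, 100, 0), "thin")
  cfg <- mcmc_config()  # 21000 / 1000 / 10
  expect_identical((cfg$n_iterations - cfg$burn_in) %/% cfg$thin, 2000L)

  ## tiny data keeps the full default protocol cheap
  set.seed(1)
  g <- sim_hwe_geno(40, runif(25, 0.2, 0.8), seed = 14)
  eff <- sim_effects(trait_architecture("polygenic"), g, seed = 2)
  ph <- sim_phenotypes(g, eff, h2_target = 0.5, seed = 3)
  ps <- run_sampler(g, ph, model = bayes_spec("Cpi"), mcmc = mcmc_config(seed = 4))
  expect_identical(ps$n_kept, 2000L)
  expect_identical(length(ps$pi_samples), 2000L)
  expect_true(all(ps$inclusion_prob >= 0 & ps$inclusion_prob <= 1))
})

test_that("samplers are deterministic under a fixed seed", {
  d <- fix_bayes_data()
  cfg <- mcmc_config(600, 100, 5, seed = 31)
  for (fam in c("Cpi", "B", "N", "S", "R")) {
    p1 <- run_sampler(d$g, d$ph, model = bayes_spec(fam), mcmc = cfg)
    p2 <- run_sampler(d$g, d$ph, model = bayes_spec(fam), mcmc = cfg)
    expect_identical(p1$effect_means, p2$effect_means, label = fam)
    expect_identical(p1$sigma_a2_samples, p2$sigma_a2_samples, label = fam)
    expect_identical(p1$gebv, p2$gebv, label = fam)
  }
})

test_that("BayesCpi with pi fixed at 1 reproduces GBLUP (ridge equivalence)", {
  d <- fix_bayes_data()
  ps <- run_sampler(d$g, d$ph, model = bayes_spec("Cpi", pi = 1),
                    mcmc = mcmc_config(2100, 100, 1, seed = 9))
  fit <- fit_model("gblup", d$ph, genotypes = d$g)
  ids <- d$ph$id
  expect_gt(cor(ps$gebv[ids], fit$breeding_values[ids]), 0.98)
})

test_that("pure-noise phenotypes shrink marker effects toward zero", {
  ## n must comfortably exceed m for the likelihood to separate noise from
  ## signal; paired-simulation oracle on shared genotypes
  big <- cached("bayes_big", {
    st <- sim_study(n_f2 = 500, m_total = 400, n_chromosomes = 2,
                    n_f1 = 40, seed = 202)
    st$genotypes[st$genotyped_ids, ]
  })
  cfg <- mcmc_config(4200, 200, 2, seed = 17)
  eff <- sim_effects(trait_architecture("polygenic"), big, seed = 5)
  ph_sig <- sim_phenotypes(big, eff, h2_target = 0.5, seed = 6)
  ph_noise <- ph_sig
  set.seed(7)
  ph_noise$trait <- rnorm(nrow(ph_noise), mean(ph_sig$trait), sd(ph_sig$trait))
  ps_sig <- run_sampler(big, ph_sig, model = bayes_spec("Cpi"), mcmc = cfg)
  ps_noise <- run_sampler(big, ph_noise, model = bayes_spec("Cpi"), mcmc = cfg)
  expect_lt(mean(abs(ps_noise$effect_means)), 0.05 * sd(ps_sig$effect_means))
  expect_error(run_sampler(big, transform(ph_sig, trait = 1)), "constant phenotype")
})

test_that("posterior effect size is monotone in simulated heritability", {
  d <- fix_bayes_data()
  g <- d$g
  eff <- sim_effects(trait_architecture("polygenic"), g, seed = 11)
  cfg <- mcmc_config(2100, 100, 1, seed = 23)
  mean_abs <- vapply(c(0.05, 0.2, 0.5), function(h2) {
    ph <- sim_phenotypes(g, eff, h2_target = h2, seed = 12)
    ## rescale so the phenotypic variance is comparable across h2 levels
    ph$trait <- ph$trait / sd(ph$trait)
    mean(abs(run_sampler(g, ph, model = bayes_spec("Cpi"), mcmc = cfg)$effect_means))
  }, numeric(1))
  expect_true(all(diff(mean_abs) > 0))
})

test_that("GEBV computation follows the centred-genotype hand calculation", {
  g <- fix_tiny_geno(matrix(c(0L, 1L, 2L), 3, 1))
  expect_equal(unname(gebv_from_effects(g, c(m1 = 1), 0.5)), c(-1, 0, 1))
  expect_equal(unname(gebv_from_effects(g, c(m1 = 0), 0.5)), c(0, 0, 0))
  expect_error(gebv_from_effects(g, c(1, 2)), "marker map")
  expect_error(gebv_from_effects(g, c(wrong = 1)), "names")
})

test_that("adding a constant to phenotypes moves only the intercept", {
  d <- fix_bayes_data()
  cfg <- mcmc_config(800, 100, 2, seed = 41)
  p1 <- run_sampler(d$g, d$ph, model = bayes_spec("Cpi"), mcmc = cfg)
  ph2 <- d$ph
  ph2$trait <- ph2$trait + 500
  p2 <- run_sampler(d$g, ph2, model = bayes_spec("Cpi"), mcmc = cfg)
  expect_equal(p2$gebv, p1$gebv, tolerance = 1e-8)
  expect_equal(unname(p2$beta_means["(Intercept)"] - p1$beta_means["(Intercept)"]),
               500, tolerance = 1e-6)
})

test_that("the BayesS exponent chain recovers its prior when no markers are in the model", {
  ## with pi fixed at 0 the likelihood carries no information about S, so
  ## the Metropolis-within-Gibbs chain must sample the N(0, 1) prior
  d <- fix_bayes_data()
  ## the genetic-variance chain is degenerate at zero here, so the
  ## split-chain stationarity warning is expected noise
  ps <- suppressWarnings(
    run_sampler(d$g, d$ph, model = bayes_spec("S", pi = 0),
                mcmc = mcmc_config(21000, 1000, 10, seed = 53)))
  s <- ps$S_samples[seq(1, length(ps$S_samples), by = 10)]  # decorrelate
  expect_gt(stats::ks.test(s, "pnorm", 0, 1)$p.value, 0.01)
  expect_lt(abs(mean(ps$S_samples)), 0.2)
})

test_that("BayesN windows tile each chromosome without overlap", {
  d <- fix_bayes_data()
  map <- d$g$map
  win <- gskit:::bayes_windows(map, 2e5)
  ## every marker assigned; window ids contiguous from 1
  expect_true(all(sort(unique(win)) == seq_len(max(win))))
  ## windows never span chromosomes and never exceed the tile width
  for (w in unique(win)) {
    j <- win == w
    expect_identical(length(unique(map$chrom[j])), 1L)
    expect_lt(max(map$bp[j]) - min(map$bp[j]), 2e5)
  }
  ## a window wider than the chromosome collapses to one window per chromosome
  win1 <- gskit:::bayes_windows(map, 1e9)
  expect_identical(max(win1), length(unique(map$chrom)))

  ## the nested sampler still behaves like a marker-effect model there
  ps <- run_sampler(d$g, d$ph, model = bayes_spec("N", window_bp = 1e9),
                    mcmc = mcmc_config(2100, 100, 1, seed = 61))
  fit <- fit_model("gblup", d$ph, genotypes = d$g)
  expect_gt(cor(ps$gebv[d$ph$id], fit$breeding_values[d$ph$id]), 0.9)
})

test_that("BayesR absorbs almost no variance from pure-noise phenotypes", {
  d <- fix_bayes_data()
  ph <- d$ph
  set.seed(71)
  ph$trait <- rnorm(nrow(ph))
  ps <- run_sampler(d$g, ph, model = bayes_spec("R"),
                    mcmc = mcmc_config(2100, 100, 1, seed = 72))
  ## fitted genetic values capture only a sliver of the (pure-noise) variance
  expect_lt(var(ps$gebv[ph$id]) / var(ph$trait), 0.1)
  ## weight chain stays a simplex
  expect_equal(rowSums(ps$component_weight_samples),
               rep(1, nrow(ps$component_weight_samples)), tolerance = 1e-12)
})

test_that("sparse architectures put the major QTL at the top of the inclusion ranking", {
  ## the scaled-t architecture concentrates genetic variance in few QTL;
  ## only QTL with a sizeable variance share are statistically detectable,
  ## and LD means a tagging neighbour may stand in for the QTL itself
  found <- 0L; total <- 0L
  for (s in 1:4) {
    st <- sim_study(n_f2 = 250, m_total = 500, n_chromosomes = 2, n_f1 = 30,
                    arch = trait_architecture("sparse_t", n_qtl = 5),
                    seed = 400 + s)
    g <- st$genotypes[st$genotyped_ids, ]
    p <- allele_freq(g)
    Z <- sweep(g$codes, 2, 2 * p)
    vshare <- apply(Z, 2, var) * st$effects^2
    vshare <- vshare / sum(vshare)
    big <- which(st$effects != 0 & vshare > 0.2)
    ps <- run_sampler(g, st$phenotypes, model = bayes_spec("B"),
                      mcmc = mcmc_config(2100, 100, 1, seed = s))
    top <- order(ps$inclusion_prob, decreasing = TRUE)[1:25]  # top 5%
    r2 <- cor(Z)^2
    found <- found + sum(vapply(big, function(q)
      (q %in% top) || max(r2[q, top]) >= 0.5, logical(1)))
    total <- total + length(big)
  }
  expect_gt(found / total, 0.7)
})
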