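test_that("simulated genotypes are deterministic and pedigree-structured", {
  cfg <- simulation_config(n_pedigrees = 3, n_sites = 150, seed = 42)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$calls, g2$calls)
  expect_identical(g1$sites$pos, g2$sites$pos)
  expect_true(all(diff(g1$sites$pos) > 0))
  expect_equal(length(unique(g1$individuals$pedigree)), 3L)
  # another seed gives different data
  g3 <- simulate_genotypes(simulation_config(n_pedigrees = 3, n_sites = 150,
                                             seed = 43))
  expect_false(identical(g1$calls, g3$calls))
})

test_that("founder allele frequencies track the configured MAF", {
  cfg <- simulation_config(n_pedigrees = 400, pedigree_couples = 0,
                           n_sites = 60, seed = 7)
  g <- simulate_genotypes(cfg)           # 800 founders
  maf_cfg <- attr(g, "true_maf")
  founders <- g$calls                    # couples: everyone is a founder
  freq <- colMeans(founders) / 2
  n_chr <- 2 * nrow(founders)
  se <- sqrt(maf_cfg * (1 - maf_cfg) / n_chr)
  expect_true(all(abs(freq - maf_cfg) < 4 * se + 1e-9))
  # rare fraction near configured 0.3
  expect_lt(abs(mean(maf_cfg < 0.05) - 0.3), 0.12)
})

test_that("gene dropping produces full-sib allele sharing near kinship 1/4", {
  cfg <- simulation_config(n_pedigrees = 30, pedigree_couples = 1,
                           children_range = c(2, 2), n_sites = 400,
                           seed = 11)
  g <- simulate_genotypes(cfg)
  st <- simulate_pedigree_structure(cfg)
  sib1 <- st$id[st$generation == 3 & grepl("_1$", st$id)]
  sib2 <- st$id[st$generation == 3 & grepl("_2$", st$id)]
  # kinship from dosages standardized by the generating allele frequency:
  # E[z1 * z2] = 2 * kinship = 1/2 for full sibs
  p <- attr(g, "true_maf")
  common <- p >= 0.05
  z <- sweep(g$calls[, common], 2, 2 * p[common]) /
    rep(sqrt(2 * p[common] * (1 - p[common])), each = nrow(g$calls))
  phi2 <- vapply(seq_along(sib1), function(i) {
    mean(z[sib1[i], ] * z[sib2[i], ])
  }, numeric(1))
  expect_lt(abs(mean(phi2) - 0.5), 0.08)
})

test_that("a zero-MAF site is homozygous reference for everyone", {
  cfg <- simulation_config(n_pedigrees = 2, n_sites = 50,
                           rare_maf_range = c(0, 0), rare_fraction = 1,
                           seed = 3)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$calls == 0L))
})

test_that("the trait stream is deterministic, normal and genotype-independent", {
  q1a <- simulate_q1(500, 10, 2, seed = 5)
  expect_identical(q1a, simulate_q1(500, 10, 2, seed = 5))
  big <- simulate_q1(100000, 10, 2, seed = 6)
  expect_lt(abs(mean(big) - 10), 4 * 2 / sqrt(100000))
  tiny_sd <- simulate_q1(10, 3, 1e-12, seed = 1)
  expect_equal(tiny_sd, rep(3, 10), tolerance = 1e-9)
  # independence of the genotype stream: same base seed, negligible correlation
  cfg <- simulation_config(n_pedigrees = 100, pedigree_couples = 0,
                           n_sites = 200, seed = 5)
  g <- simulate_genotypes(cfg)
  q1 <- simulate_q1(nrow(g$calls), 10, 2, seed = 5)
  cors <- abs(apply(g$calls, 2, function(col) {
    if (var(col) == 0) return(0)
    cor(col, q1)
  }))
  expect_lt(mean(cors > 2 / sqrt(nrow(g$calls))), 0.1)
})

test_that("implantation follows the logistic model and spares outside sites", {
  cfg <- simulation_config(n_pedigrees = 50, pedigree_couples = 0,
                           n_sites = 200, seed = 9)
  g <- simulate_genotypes(cfg)
  pos <- g$sites$pos
  region_lo <- pos[80]; region_hi <- pos[120]
  # b1 = 0: replacement probability identical for everyone
  m0 <- implant_model(b0 = 0.5, b1 = 0, q1 = rnorm(nrow(g$calls)),
                      chrom = "1", start_bp = region_lo, end_bp = region_hi)
  expect_equal(unique(m0$p_rep), plogis(0.5))
  # printed-grid evaluation: logistic(-25 + 0.3*50) = logistic(-10)
  m1 <- implant_model(-25, 0.3, 50, "1", region_lo, region_hi)
  expect_equal(m1$p_rep, plogis(-10))
  expect_equal(m1$p_rep, 4.5397868702434395e-05, tolerance = 1e-12)

  q1 <- simulate_q1(nrow(g$calls), 10, 2, seed = 10)
  model <- implant_model(-10, 1, q1, "1", region_lo, region_hi)
  out <- implant_hd(g, model, seed = 10)
  replaced <- attr(out, "replaced")
  expect_gt(sum(replaced), 0)
  in_reg <- pos >= region_lo & pos <= region_hi
  # replaced individuals: indicator identically 1 across the region
  ind <- homozygosity_indicator(out)
  expect_true(all(ind[replaced, in_reg] == 1L))
  # untouched outside the region, and untouched individuals unchanged
  expect_identical(out$calls[, !in_reg], g$calls[, !in_reg])
  expect_identical(out$calls[!replaced, ], g$calls[!replaced, ])
  # empty region errors
  expect_error(implant_hd(g, implant_model(-10, 1, q1, "1", 1, 2)),
               "no sites")
})

test_that("implantation is reproducible and monotone in the trait", {
  cfg <- simulation_config(n_pedigrees = 40, pedigree_couples = 0,
                           n_sites = 100, seed = 13)
  g <- simulate_genotypes(cfg)
  q1 <- simulate_q1(nrow(g$calls), 10, 2, seed = 13)
  model <- implant_model(-10, 1, q1, "1", g$sites$pos[40], g$sites$pos[60])
  o1 <- implant_hd(g, model, seed = 3)
  o2 <- implant_hd(g, model, seed = 3)
  expect_identical(o1$calls, o2$calls)
  # carriers have systematically larger trait values
  rep1 <- attr(o1, "replaced")
  expect_gt(mean(q1[rep1]), mean(q1[!rep1]))
})

test_that("region selection by rare-variant percentile spans the spectrum", {
  cfg <- simulation_config(n_pedigrees = 40, pedigree_couples = 0,
                           n_sites = 500, seed = 17)
  g <- simulate_genotypes(cfg)
  regions <- select_rv_percentile_regions(g, width_sites = 50)
  expect_equal(nrow(regions), 3L)
  expect_true(all(regions$end_bp > regions$start_bp))
  expect_true(all(diff(regions$rare_fraction) >= 0))
})

test_that("small type-I and power experiments behave as expected", {
  cfg <- simulation_config(n_pedigrees = 8, pedigree_couples = 2,
                           n_sites = 400, seed = 19)
  r <- type1_experiment(cfg, n_replicates = 8,
                        spec = window_spec(anchor_stride = 10))
  expect_true(all(r$per_replicate >= 0 & r$per_replicate <= 1))
  expect_lte(r$rate, 0.05 + 3 * max(r$mc_se, 0.02))
  # determinism of the whole experiment
  r2 <- type1_experiment(cfg, n_replicates = 8,
                         spec = window_spec(anchor_stride = 10))
  expect_identical(r$per_replicate, r2$per_replicate)

  cfg2 <- simulation_config(n_pedigrees = 60, pedigree_couples = 0,
                            n_sites = 400, seed = 23)
  pw <- power_experiment(cfg2, data.frame(b0 = -10, b1 = 1),
                         n_replicates = 5,
                         spec = window_spec(anchor_stride = 10))
  expect_equal(pw$results$power, 1)
  # near-zero replacement probability: no real signal
  pw0 <- power_experiment(cfg2, data.frame(b0 = -40, b1 = 0.3),
                          n_replicates = 5,
                          spec = window_spec(anchor_stride = 10))
  expect_lte(pw0$results$power, 0.4)
})

test_that("strong implanted regions are recovered within one window width", {
  cfg <- simulation_config(n_pedigrees = 100, pedigree_couples = 0,
                           n_sites = 500, seed = 29)
  g <- simulate_genotypes(cfg)
  pos <- g$sites$pos
  start <- pos[200]; end <- pos[300]
  q1 <- simulate_q1(nrow(g$calls), 10, 2, seed = 29)
  model <- implant_model(-10, 1, q1, "1", start, end)
  gi <- implant_hd(g, model, seed = 29)
  spec <- window_spec(anchor_stride = 5)
  prof <- estimate_profile(g = gi, spec = spec)
  covars <- hdscan:::simulate_covariates(29, g$individuals$id)
  pheno <- data.frame(id = g$individuals$id, ped = g$individuals$pedigree,
                      age = covars$age, sex = covars$sex, q1 = q1)
  res <- gee_association(prof, response_spec("q1"), pheno)
  sig <- significant_regions(res, 0.05)
  expect_gte(nrow(sig), 1L)
  best <- sig[which.min(sig$min_p_adjusted), ]
  # one window spans 5% of 500 sites = 25 sites; allow that much slack
  win_bp <- max(diff(pos)) * 25
  expect_lt(abs(best$start_bp - start), win_bp)
  expect_lt(abs(best$end_bp - end), win_bp)
})
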