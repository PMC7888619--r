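# Synthetic trio generator: reproducibility, Mendelian behavior, disease
# model, ascertainment and the experiment drivers.

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(n_trios = 30, n_snps = 6, seed = 101, beta0 = 0,
                    ascertain = FALSE)
  p1 <- simulate_parents(cfg)
  p2 <- simulate_parents(cfg)
  expect_identical(p1, p2)
  o1 <- simulate_offspring(p1, seed = 55)
  o2 <- simulate_offspring(p2, seed = 55)
  expect_identical(o1, o2)
  d1 <- simulate_twas_dataset(cfg)
  d2 <- simulate_twas_dataset(cfg)
  expect_identical(d1$geno$hap1, d2$geno$hap1)
  expect_identical(d1$status, d2$status)
  # different seed, different data
  cfg2 <- sim_config(n_trios = 30, n_snps = 6, seed = 102, beta0 = 0,
                     ascertain = FALSE)
  expect_false(identical(simulate_parents(cfg2)$F1, p1$F1))
})

test_that("config validation enforces ranges and a mandatory seed", {
  expect_error(sim_config(n_trios = 10), "seed")
  expect_error(sim_config(maf = 0, seed = 1), "MAF")
  expect_error(sim_config(maf = 0.7, seed = 1), "MAF")
  expect_error(sim_config(n_trios = 0, seed = 1))
  expect_error(sim_config(noise_sigma2 = -1, seed = 1))
})

test_that("allele frequencies and transmission match Mendelian expectations", {
  cfg <- sim_config(n_trios = 4000, n_snps = 2, maf = 0.5, seed = 103,
                    beta0 = 0, ascertain = FALSE)
  par <- simulate_parents(cfg)
  # mean parental dosage ~ 2 * maf within 3 SE
  dos <- par$F1[, 1] + par$F2[, 1]
  se <- sqrt(2 * 0.5 * 0.5 / 4000)
  expect_lt(abs(mean(dos) - 1), 3 * se)
  # each of the 4 transmission configurations occurs ~ 1/4 of the time
  off <- simulate_offspring(par, seed = 9)
  counts <- tabulate(off$config_index, 4)
  expect_gt(chisq.test(counts)$p.value, 0.001)
  # homozygous parents transmit deterministically
  cfg1 <- sim_config(n_trios = 5, n_snps = 3, maf = 0.5, seed = 104,
                     beta0 = 0, ascertain = FALSE)
  parh <- simulate_parents(cfg1)
  parh$F2 <- parh$F1; parh$M2 <- parh$M1
  offh <- simulate_offspring(parh, seed = 1)
  expect_equal(offh$hap1, parh$F1)
  expect_equal(offh$hap2, parh$M1)
})

test_that("logistic disease model honours both modes and the stated prevalences", {
  expect_equal(round(plogis(2.25), 1), 0.9)
  expect_equal(plogis(-2.5), 1 / (1 + exp(2.5)))
  # threshold mode: beta1 = 0 and beta0 < 0 means nobody is affected
  expect_equal(simulate_disease(rnorm(50), beta0 = -0.1, beta1 = 0,
                                mode = "threshold"), rep(0L, 50))
  # threshold mode is deterministic in beta0 + beta1 * G
  G <- c(-2, -0.5, 0.5, 2)
  expect_equal(simulate_disease(G, beta0 = 0, beta1 = 1,
                                mode = "threshold"),
               as.integer(G > 0))
  # bernoulli mode hits the expected rate
  st <- simulate_disease(rep(0, 20000), beta0 = -2.5, beta1 = 1,
                         seed = 7)
  expect_lt(abs(mean(st) - plogis(-2.5)), 3 * sqrt(0.07 * 0.93 / 20000))
})

test_that("ascertained datasets contain only affected probands and respect the retry cap", {
  ds <- simulate_twas_dataset(sim_config(n_trios = 40, beta0 = -1,
                                         beta1 = 0.3, seed = 105))
  expect_true(all(ds$status == 1L))
  expect_true(all(ds$fam$phenotype[seq_len(40)] == 2L))
  expect_equal(length(ds$exposures$proband), 40L)
  expect_error(
    simulate_twas_dataset(sim_config(n_trios = 50, beta0 = -30,
                                     beta1 = 0, seed = 106),
                          max_batches = 3),
    "increase beta0")
})

test_that("simulated probands always pass the Mendelian consistency check", {
  ds <- simulate_twas_dataset(sim_config(n_trios = 25, beta0 = 0,
                                         ascertain = FALSE, seed = 107))
  sets <- lapply(seq_len(25), function(i)
    pseudo_siblings(ds$geno, ds$trios[i, ]))
  rep <- check_mendelian_consistency(sets)
  expect_equal(sum(!rep$consistent), 0L)
  # the simulator's config_index identifies the matching configuration
  for (i in seq_len(10))
    expect_equal(sets[[i]]$configs[ds$exposures$config_index[i], ],
                 sets[[i]]$proband)
})

test_that("status shuffling preserves each family's member multiset", {
  ds <- simulate_twas_dataset(sim_config(n_trios = 50, beta0 = 0,
                                         ascertain = FALSE, seed = 108))
  ms <- sim_matched_sets(ds, standardize = FALSE)
  sh <- shuffle_status(ms$case, ms$ctrl, seed = 5)
  for (i in seq_len(50))
    expect_equal(sort(c(sh$case[i], sh$ctrl[i, ])),
                 sort(c(ms$case[i], ms$ctrl[i, ])))
  sh2 <- shuffle_status(ms$case, ms$ctrl, seed = 5)
  expect_identical(sh, sh2)
})

test_that("noise-robustness driver returns a power value per grid point", {
  ds <- simulate_twas_dataset(sim_config(n_trios = 120, beta0 = -1,
                                         beta1 = 0.8, noise_sigma2 = 0,
                                         seed = 109))
  nr <- noise_robustness_experiment(ds, sigma2_grid = c(0.05, 0.5),
                                    n_reps = 10, seed = 2)
  expect_equal(nr$sigma2, c(0.05, 0.5))
  expect_true(all(nr$power >= 0 & nr$power <= 1))
  nr2 <- noise_robustness_experiment(ds, sigma2_grid = c(0.05, 0.5),
                                     n_reps = 10, seed = 2)
  expect_identical(nr, nr2)
})

test_that("power driver reports all designs and flags degenerate replicates", {
  pw <- power_comparison(beta0 = -2.5, beta1_grid = c(0, 0.5),
                         n_trios = 200, n_reps = 8, seed = 3)
  expect_equal(sort(unique(pw$design)), c("1sib", "3sib", "parent"))
  expect_equal(nrow(pw), 6L)
  expect_true(all(pw$power >= 0 & pw$power <= 1))
  expect_true(all(pw$mean_n_affected > 0))
  # beta0 so low that no replicate has affected trios
  pw0 <- power_comparison(beta0 = -30, beta1_grid = 0.5, n_trios = 50,
                          n_reps = 4, seed = 3)
  expect_true(all(pw0$n_zero_affected == 4L))
  expect_true(all(pw0$power == 0))
})

test_that("weight normalization gives unit-variance imputed expression", {
  ds <- simulate_twas_dataset(sim_config(n_trios = 20000, n_snps = 12,
                                         seed = 110, beta0 = 0,
                                         ascertain = FALSE))
  expect_lt(abs(sd(ds$exposures$proband) - 1), 0.03)
})
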