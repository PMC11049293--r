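test_that("simulation dimensions and determinism match the configuration", {
  cfg <- simulation_config(n_proteins = 30, seed = 7)
  sim1 <- simulate_experiment(cfg)
  sim2 <- simulate_experiment(cfg)
  expect_identical(sim1$quant$mat, sim2$quant$mat)
  expect_identical(sim1$spectra, sim2$spectra)
  expect_identical(sim1$truth, sim2$truth)
  expect_equal(dim(sim1$quant), c(30L, 16L))

  full <- simulate_experiment(simulation_config(seed = 1, missing_rate = 0))
  expect_equal(dim(full$quant), c(2554L, 16L))
})

test_that("a global-null configuration plants no effects and yields ~5% false positives", {
  cfg <- simulation_config(n_proteins = 400, frac_interaction = 0,
                           frac_main_genotype = 0, frac_main_treatment = 0,
                           missing_rate = 0, seed = 5)
  sim <- simulate_experiment(cfg)
  expect_false(any(sim$truth$interaction_true))
  expect_false(any(sim$truth$main_genotype_true))
  st <- fit_factorial_anova(sim$quant)
  rate <- mean(st$p_interaction < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("planted cell means are realized in the simulated matrix", {
  cfg <- simulation_config(n_proteins = 200, frac_interaction = 0.5,
                           missing_rate = 0, seed = 9)
  sim <- simulate_experiment(cfg)
  d <- sim$design
  for (g in c("EW", "TW", "TF")) {
    cols <- d$sample_id[d$group == g]
    emp <- rowMeans(sim$quant$mat[, cols])
    mu <- sim$truth[[paste0("mu_", g)]]
    bound <- 3 * cfg$sigma_log2 / sqrt(4)
    expect_gt(mean(abs(emp - mu) <= bound), 0.98)
  }
  # rescue directionality splits ~50/50
  dir <- sim$truth$direction[sim$truth$interaction_true]
  expect_true(abs(mean(dir == "down") - 0.5) < 0.15)
  down <- sim$truth$interaction_true & sim$truth$direction == "down"
  expect_true(all(sim$truth$mu_TW[down] < sim$truth$mu_EW[down]))
  expect_true(all(sim$truth$mu_TF[down] == sim$truth$mu_EW[down]))
})

test_that("impurity mixing is the exact inverse of correction", {
  sim <- small_sim(20)
  ch <- tmt16_channels()
  P <- purity_matrix(synthetic_impurities())
  expect_true(all(colSums(P) <= 1 + 1e-12))

  mixed <- mix_impurities(sim$spectra, P)
  back <- impurity_correct(mixed, P)
  orig <- as.matrix(sim$spectra[, ch])
  expect_lt(max(abs(as.matrix(back[, ch]) - orig) / (abs(orig) + 1)), 1e-10)

  # identity purity is a no-op
  I_ <- purity_matrix(tibble::tibble(channel = ch, minus2 = 0, minus1 = 0,
                                     plus1 = 0, plus2 = 0))
  expect_equal(as.matrix(mix_impurities(sim$spectra, I_)[, ch]), orig)

  # hand-computed 2-channel leak: true (100, 0), 10% of ch1 into ch2
  toy <- tibble::tibble(spectrum_id = "s1", protein_ids = "P1",
                        A = 100, B = 0)
  P2 <- structure(matrix(c(0.9, 0.1, 0, 1), 2, 2,
                         dimnames = list(c("A", "B"), c("A", "B"))),
                  class = c("purity_matrix", "matrix", "array"))
  obs <- mix_impurities(toy, P2)
  expect_equal(unlist(obs[, c("A", "B")]), c(A = 90, B = 10))
  expect_equal(unlist(impurity_correct(obs, P2)[, c("A", "B")]),
               c(A = 100, B = 0))
})

test_that("missingness injection hits the requested rate and is reproducible", {
  qm <- random_quant(2554, seed = 2)
  out <- inject_missingness(qm, 0.1, seed = 3)
  n_missing <- sum(is.na(out$mat))
  expected <- 0.1 * length(out$mat)
  bound <- qnorm(0.995) * sqrt(length(out$mat) * 0.1 * 0.9)
  expect_lt(abs(n_missing - expected), bound)
  expect_identical(is.na(inject_missingness(qm, 0.1, seed = 3)$mat),
                   is.na(out$mat))
  expect_identical(inject_missingness(qm, 0)$mat, qm$mat)
  expect_error(inject_missingness(qm, 1), "rate")
})

test_that("gene-set simulation respects sizes, enrichment and the seed", {
  sim <- small_sim(100, frac_interaction = 0.3)
  gs1 <- simulate_gene_sets(sim$truth, n_sets = 12, size_range = c(5, 20),
                            enrichment_spec = c(set001 = "interaction_true"),
                            seed = 4)
  gs2 <- simulate_gene_sets(sim$truth, n_sets = 12, size_range = c(5, 20),
                            enrichment_spec = c(set001 = "interaction_true"),
                            seed = 4)
  expect_identical(gs1, gs2)
  expect_true(all(lengths(gs1$members) >= 5 & lengths(gs1$members) <= 20))
  planted <- gs1$members[[which(gs1$name == "set001")]]
  truth_frac <- mean(planted %in% sim$truth$protein_id[sim$truth$interaction_true])
  expect_gte(truth_frac, 0.8)
  expect_error(simulate_gene_sets(sim$truth, size_range = c(5, 1000)),
               "size_range")
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(simulation_config(frac_interaction = 1.2), "proportion")
  expect_error(simulation_config(n_per_group = 1), "n_per_group")
  expect_error(simulation_config(sigma_log2 = -1), "sigma")
  expect_error(simulation_config(missing_rate = 1), "proportion|missing")
})
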