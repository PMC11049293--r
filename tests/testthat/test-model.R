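test_that("missing-value filter keeps proteins with at most one absent sample", {
  qm <- random_quant(5, seed = 41)
  nm <- c(0, 1, 1, 2, 3)
  for (i in seq_len(5)) if (nm[i] > 0) qm$mat[i, seq_len(nm[i])] <- NA
  f1 <- filter_missing(qm, 1)
  expect_equal(attr(f1, "n_retained"), 3L)
  expect_equal(attr(f1, "n_dropped"), 2L)
  f0 <- filter_missing(qm, 0)
  expect_equal(rownames(f0$mat), rownames(qm$mat)[nm == 0])
})

test_that("factorial ANOVA matches an independent normal-equations oracle", {
  d <- design_2x2()
  set.seed(42)
  for (rep in 1:50) {
    y <- rnorm(16, 10, runif(1, 0.1, 2))
    m <- matrix(y, 1, dimnames = list("P1", d$sample_id))
    st <- fit_factorial_anova(quant_matrix(m, d))
    orc <- anova_oracle(y, d)
    expect_equal(st$f_genotype, orc["F", "genotype"], tolerance = 1e-10)
    expect_equal(st$p_genotype, orc["p", "genotype"], tolerance = 1e-10)
    expect_equal(st$f_treatment, orc["F", "treatment"], tolerance = 1e-10)
    expect_equal(st$f_interaction, orc["F", "interaction"], tolerance = 1e-10)
    expect_equal(st$p_interaction, orc["p", "interaction"], tolerance = 1e-10)
    expect_equal(st$df_resid, 12)
  }
})

test_that("a planted interaction of 1 log2 unit at sigma 0.1 is highly significant", {
  d <- design_2x2()
  set.seed(43)
  mu <- c(EW = 0, EF = 0, TW = 0, TF = 1)
  y <- mu[d$group] + rnorm(16, 0, 0.1)
  m <- matrix(y, 1, dimnames = list("P1", d$sample_id))
  st <- fit_factorial_anova(quant_matrix(m, d))
  expect_lt(st$p_interaction, 0.001)
})

test_that("proteins with one missing value are fitted unbalanced, empty cells flagged", {
  d <- design_2x2()
  set.seed(44)
  m <- matrix(rnorm(3 * 16, 10), 3, dimnames = list(c("A", "B", "C"), d$sample_id))
  m[2, d$sample_id[d$group == "TW"][1]] <- NA          # one missing
  m[3, d$sample_id[d$group == "TW"][1:3]] <- NA        # cell with 1 obs left
  st <- fit_factorial_anova(quant_matrix(m, d))
  expect_equal(st$flag, c("ok", "ok", "inestimable"))
  expect_equal(st$df_resid[2], 11)
  # unbalanced fit agrees with a direct lm / type-II computation
  ok <- !is.na(m[2, ])
  dat <- data.frame(y = m[2, ok],
                    genotype = d$genotype[ok], treatment = d$treatment[ok])
  a2 <- car::Anova(lm(y ~ genotype * treatment, dat), type = 2)
  expect_equal(st$p_interaction[2], a2["genotype:treatment", "Pr(>F)"],
               tolerance = 1e-12)
  # zero-variance protein gets p = 1 and a flag
  m2 <- matrix(7, 1, 16, dimnames = list("Z", d$sample_id))
  stz <- fit_factorial_anova(quant_matrix(m2, d))
  expect_equal(stz$flag, "zero_variance")
  expect_equal(stz$p_interaction, 1)
})

test_that("summary-statistics contrasts reproduce printed worked examples", {
  # trisomic-water vs trisomic-fluoxetine, SEM interpretation, n = 4
  ap2a1 <- group_contrast(10.92, 0.08, 4, 11.55, 0.07, 4, "TW", "TF")
  expect_equal(ap2a1$df, 6)
  expect_equal(round(ap2a1$p, 3), 0.001)
  expect_equal(ap2a1$t, 5.927, tolerance = 1e-3)
  clta <- group_contrast(12.08, 0.11, 4, 13.24, 0.09, 4, "TW", "TF")
  expect_equal(round(clta$p, 4), 0.0002)
  # identical means give t = 0, p = 1, pi = 0
  null <- group_contrast(10, 0.1, 4, 10, 0.1, 4)
  expect_equal(null$t, 0)
  expect_equal(null$p, 1)
  expect_equal(null$pi_score, 0)
})

test_that("contrast from raw data equals contrast from its summary statistics", {
  sim <- small_sim(25, seed = 45, missing_rate = 0)
  st <- fit_factorial_anova(sim$quant)
  con <- contrast_all(st, "TW", "TF")
  for (i in c(1, 7, 20)) {
    y <- sim$quant$mat[st$protein_id[i], ]
    tw <- y[sim$design$group == "TW"]; tf <- y[sim$design$group == "TF"]
    direct <- group_contrast(mean(tw), sd(tw) / 2, 4, mean(tf), sd(tf) / 2, 4)
    expect_equal(con$log2_fc[i], unname(direct$log2_fc), tolerance = 1e-12)
    expect_equal(con$p[i], unname(direct$p), tolerance = 1e-12)
  }
})

test_that("pi score follows the stated formula and its symmetries", {
  expect_equal(pi_score(3, 1), 0)
  expect_equal(pi_score(1, 0.1), 1)
  expect_equal(pi_score(-8.61, 0.001), -25.83)
  expect_equal(pi_score(2, 0.01), -pi_score(-2, 0.01))
  expect_error(pi_score(1, 0), "p must")
})

test_that("interaction selection uses strict inequality and orders by p", {
  st <- tibble::tibble(protein_id = c("A", "B", "C", "D"),
                       p_interaction = c(0.2, 0.01, 0.05, 0.049),
                       q_interaction = c(0.3, 0.04, 0.1, 0.1))
  sel <- select_interaction(st, 0.05)
  expect_equal(sel$protein_id, c("B", "D"))
  expect_equal(attr(sel, "n_selected"), 2L)
  selq <- select_interaction(st, 0.05, use_q = TRUE)
  expect_equal(selq$protein_id, "B")
})
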