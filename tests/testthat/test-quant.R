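test_that("iterative normalization removes constructed offsets and is idempotent", {
  set.seed(21)
  d <- design_2x2()
  base <- matrix(rnorm(50 * 16, 10, 0.5), 50)
  offsets <- rep(c(1, -1, 0.5, 0), 4)
  shifted <- sweep(base, 2, offsets, `+`)
  mk <- function(m) {
    dplyr::bind_cols(
      tibble::tibble(spectrum_id = sprintf("s%02d", 1:50),
                     protein_ids = sprintf("P%02d", 1:50)),
      tibble::as_tibble(`colnames<-`(2 ^ m, d$channel)))
  }
  norm <- iterative_normalize(mk(shifted))
  expect_true(attr(norm, "converged"))
  L <- log2(as.matrix(norm[, d$channel]))
  med <- apply(L, 2, median)
  expect_lt(max(med) - min(med), 1e-6)
  rmed <- apply(L, 1, median)
  expect_lt(max(rmed) - min(rmed), 1e-6)
  # already balanced input is a fixed point; re-running changes nothing
  norm2 <- iterative_normalize(norm)
  expect_equal(log2(as.matrix(norm2[, d$channel])), L, tolerance = 1e-6)

  expect_error(iterative_normalize(mk(shifted) |>
                                     dplyr::mutate(`126` = -1)), "positive")
})

test_that("preprocessing prunes shared spectra, logs intensities and weights by total", {
  d <- design_2x2()
  set.seed(8)
  intens <- matrix(2 ^ rnorm(10 * 16, 10), 10)
  colnames(intens) <- d$channel
  tab <- dplyr::bind_cols(
    tibble::tibble(spectrum_id = sprintf("s%02d", 1:10),
                   protein_ids = c(rep("P1", 4), rep("P2", 3),
                                   rep("P1;P2", 3))),
    tibble::as_tibble(intens))
  out <- preprocess_spectra(tab)
  expect_equal(nrow(out), 7)
  expect_equal(attr(out, "n_pruned_shared"), 3)
  expect_equal(as.matrix(out[, d$channel]), log2(intens[1:7, ]),
               ignore_attr = TRUE)
  expect_true(all(is.finite(out$weight) & out$weight > 0))
  # weights non-decreasing in total intensity
  tot <- rowSums(intens[1:7, ])
  expect_equal(order(out$weight), order(tot))

  # an intensity of 8 becomes a log2 value of 3
  tab$`126`[1] <- 8
  out2 <- preprocess_spectra(tab)
  expect_equal(out2$`126`[1], 3)

  # non-positive intensities become missing and are counted
  tab$`127N`[2] <- 0
  out3 <- preprocess_spectra(tab)
  expect_true(is.na(out3$`127N`[2]))
  expect_equal(attr(out3, "n_nonpositive"), 1)
})

test_that("weighted-median rollup follows the lower-value convention", {
  expect_equal(weighted_median(c(10, 11, 12)), 11)
  expect_equal(weighted_median(c(10, 12), c(3, 1)), 10)
  expect_equal(weighted_median(c(12, 10), c(1, 3)), 10)
  expect_equal(weighted_median(5), 5)
  expect_true(is.na(weighted_median(NA_real_)))

  d <- design_2x2()
  tab <- dplyr::bind_cols(
    tibble::tibble(spectrum_id = c("s1", "s2", "s3"),
                   protein_ids = "P1", weight = 1),
    tibble::as_tibble(`colnames<-`(matrix(rep(c(10, 11, 12), 16),
                                          3, 16), d$channel)))
  qm <- rollup_proteins(tab, d)
  expect_true(all(qm$mat["P1", ] == 11))
  # single spectrum: rollup equals the spectrum
  qm1 <- rollup_proteins(tab[1, ], d)
  expect_true(all(qm1$mat["P1", ] == 10))
})

test_that("spectrum medians reproduce the protein matrix up to noise", {
  sim <- small_sim(30, seed = 13, missing_rate = 0, frac_shared_spectra = 0)
  sp <- preprocess_spectra(sim$spectra)
  qm <- rollup_proteins(sp, sim$design)
  common <- intersect(rownames(qm$mat), rownames(sim$quant$mat))
  err <- abs(qm$mat[common, ] - sim$quant$mat[common, ])
  # median of k spectra with 0.5 log2 ionization offsets: generous bound
  expect_gt(mean(err < 1), 0.95)
})

test_that("permutation DE is exact for 4 vs 4 and calibrated under the null", {
  qm <- random_quant(300, seed = 31)
  de <- permutation_de(qm, "TW", "TF")
  expect_true(attr(de, "exhaustive"))
  expect_equal(attr(de, "n_splits"), 70)
  # p-values are multiples of 1/70, minimum 2/70
  expect_true(all(abs(de$p * 70 - round(de$p * 70)) < 1e-9))
  expect_gte(min(de$p), 2 / 70 - 1e-12)
  # discrete-uniform null: each achievable level k/70 equally likely
  expect_lt(abs(mean(de$p < 0.05) - 2 / 70), 3 * sqrt((2 / 70) * (68 / 70) / 300))

  # constant data: all permuted stats equal, p = 1
  d <- design_2x2()
  cm <- matrix(5, 4, 16, dimnames = list(paste0("C", 1:4), d$sample_id))
  de0 <- permutation_de(quant_matrix(cm, d), "TW", "TF")
  expect_true(all(de0$p == 1))

  expect_error(permutation_de(qm, "TW", "XX"), "unknown group")
})

test_that("BH adjustment matches the step-up oracle on all small subsets", {
  p_pool <- c(0.01, 0.02, 0.03, 0.04, 0.2, 0.5, 0.9, 1)
  for (k in 1:8) {
    sub <- utils::combn(p_pool, k)
    for (j in seq_len(ncol(sub))) {
      p <- sub[, j]
      expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
    }
  }
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})
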