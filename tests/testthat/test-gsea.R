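test_that("protein ranking is descending with deterministic tie-breaks", {
  model <- structure(list(
    loadings = matrix(c(0.5, -0.2, 0.9), 3, 1,
                      dimnames = list(c("A", "B", "C"), "PC1")),
    n_components = 1L), class = "pc_model")
  r <- rank_proteins(model, "pc_loading", component = 1)
  expect_equal(r$protein_id, c("C", "A", "B"))

  con <- tibble::tibble(protein_id = c("X", "Y", "Z", "T"),
                        log2_fc = c(2, 1, 2, -1), p = c(0.01, 0.1, 0.01, 0.5))
  rs <- rank_proteins(con, "signed_logp")
  expect_equal(rs$metric[1], 4)
  expect_equal(rs$protein_id[1:2], c("X", "Z"))  # tie broken lexicographically
  expect_equal(rank_proteins(con, "signed_logp")$protein_id, rs$protein_id)
})

test_that("enrichment score matches hand-enumerated and brute-force oracles", {
  ranked <- tibble::tibble(protein_id = c("A", "B", "C", "D", "E"),
                           metric = c(5, 4, 3, 2, 1))
  top2 <- enrichment_score(ranked, c("A", "B"), weight_exponent = 0)
  expect_equal(top2$es, 1.0)
  bottom2 <- enrichment_score(ranked, c("D", "E"), weight_exponent = 0)
  expect_equal(bottom2$es, -1.0)
  # running sum ends at zero by construction
  expect_lt(abs(top2$running_sum[5]), 1e-12)

  set.seed(61)
  for (rep in 1:30) {
    N <- sample(4:10, 1)
    ids <- LETTERS[1:N]
    metric <- sort(rnorm(N, 0, 2), decreasing = TRUE)
    k <- sample(1:(N - 1), 1)
    gs <- sample(ids, k)
    for (w in c(0, 1)) {
      mine <- enrichment_score(tibble::tibble(protein_id = ids, metric = metric),
                               gs, w)
      expect_equal(mine$es, es_oracle(ids, metric, gs, w), tolerance = 1e-12)
      expect_lte(abs(mine$es), 1)
      expect_lt(abs(mine$running_sum[N]), 1e-12)
    }
  }

  # reversing the list negates the unweighted ES
  rev_ranked <- ranked[5:1, ]
  es_f <- enrichment_score(ranked, c("A", "C"), 0)$es
  es_r <- enrichment_score(rev_ranked, c("A", "C"), 0)$es
  expect_equal(es_f, -es_r)

  expect_error(enrichment_score(ranked, ranked$protein_id), "whole universe")
  expect_error(enrichment_score(ranked, "ZZZ"), "intersect")
})

test_that("enrichment score agrees with an external GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(62)
  ids <- sprintf("P%02d", 1:40)
  metric <- sort(rnorm(40, 0, 2), decreasing = TRUE)
  ranked <- tibble::tibble(protein_id = ids, metric = metric)
  stats_named <- stats::setNames(metric, ids)
  for (rep in 1:10) {
    gs <- sample(ids, sample(3:15, 1))
    mine <- enrichment_score(ranked, gs, weight_exponent = 1)$es
    ref <- fgsea::calcGseaStat(stats_named, selectedStats = which(ids %in% gs),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("permutation GSEA recovers a planted set and stays calibrated on nulls", {
  sim <- small_sim(300, seed = 63, frac_interaction = 0.2, missing_rate = 0)
  st <- fit_factorial_anova(sim$quant)
  ranked <- rank_proteins(contrast_all(st, "TW", "TF"), "signed_logp")

  gs <- simulate_gene_sets(sim$truth, n_sets = 20, size_range = c(10, 40),
                           enrichment_spec = c(set001 = "interaction_down_true"),
                           seed = 64)
  res <- run_gsea(ranked, gs, n_perm = 1000, seed = 65)
  planted <- res[res$name == "set001", ]
  expect_lt(planted$q, 0.05)
  expect_gte(abs(planted$nes), sort(abs(res$nes), decreasing = TRUE)[2])
  expect_equal(sign(planted$es), sign(planted$nes))
  # determinism
  res2 <- run_gsea(ranked, gs, n_perm = 1000, seed = 65)
  expect_equal(res$nes, res2$nes)
  # BH monotone in p rank
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))

  # null collection on a random ranking: (almost) nothing at q < 0.25
  set.seed(66)
  null_ranked <- ranked
  null_ranked$metric <- sort(rnorm(nrow(ranked)), decreasing = TRUE)
  gs0 <- simulate_gene_sets(sim$truth, n_sets = 20, size_range = c(10, 40),
                            seed = 67)
  res0 <- run_gsea(null_ranked, gs0, n_perm = 200, seed = 68)
  expect_lte(sum(res0$q < 0.25), 1)
})

test_that("sets below the minimum size or outside the universe are skipped", {
  ranked <- tibble::tibble(protein_id = sprintf("P%02d", 1:30),
                           metric = 30:1)
  coll <- tibble::tibble(name = c("big", "small", "alien"),
                         description = "",
                         members = list(sprintf("P%02d", 1:10),
                                        c("P01", "P02"),
                                        c("Q1", "Q2", "Q3", "Q4", "Q5")))
  res <- run_gsea(ranked, coll, n_perm = 100, seed = 69)
  expect_equal(res$name, "big")
  expect_setequal(attr(res, "skipped"), c("small", "alien"))
})
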