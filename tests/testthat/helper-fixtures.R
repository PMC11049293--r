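# shared fixtures and independent oracles used across test files

small_sim <- function(n = 40, seed = 11, ...) {
  simulate_experiment(simulation_config(n_proteins = n, seed = seed, ...))
}

random_quant <- function(n_proteins, seed = 1, sigma = 1) {
  set.seed(seed)
  d <- design_2x2()
  m <- matrix(rnorm(n_proteins * 16, 10, sigma), n_proteins,
              dimnames = list(sprintf("P%03d", seq_len(n_proteins)),
                              d$sample_id))
  quant_matrix(m, d)
}

# independent least-squares oracle for the balanced two-way ANOVA:
# normal-equations fit of the full model and of each reduced model,
# F from the residual-sum-of-squares drop (type-II).
anova_oracle <- function(y, design) {
  g <- ifelse(design$genotype == "trisomic", 1, -1)
  t_ <- ifelse(design$treatment == "fluoxetine", 1, -1)
  X_full <- cbind(1, g, t_, g * t_)
  rss <- function(X) {
    beta <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta) ^ 2)
  }
  rss_full <- rss(X_full)
  df_res <- length(y) - ncol(X_full)
  out <- sapply(2:4, function(j) {
    drop <- rss(X_full[, -j, drop = FALSE]) - rss_full
    F_ <- drop / (rss_full / df_res)
    c(F = F_, p = pf(F_, 1, df_res, lower.tail = FALSE))
  })
  colnames(out) <- c("genotype", "treatment", "interaction")
  out
}

# brute-force running-sum GSEA oracle: literal walk down the list
es_oracle <- function(ids, metric, gene_set, w_exp = 0) {
  N <- length(ids)
  hit <- ids %in% gene_set
  k <- sum(hit)
  w <- abs(metric) ^ w_exp
  nr <- sum(w[hit])
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) {
      if (nr == 0) 1 / k else w[i] / nr
    } else {
      -1 / (N - k)
    }
    if (abs(run) > abs(best) + 1e-12) best <- run  # ties keep the earliest

  }
  best
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
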