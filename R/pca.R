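#' Principal component analysis of a protein quantity matrix by NIPALS
#'
#' Samples are the observations and proteins the variables: the
#' protein-by-sample matrix is transposed, each protein is
#' mean-centered (no unit-variance scaling), and components are
#' extracted one at a time by NIPALS iteration, which tolerates missing
#' cells by computing each regression over the observed entries only.
#' On complete data the result agrees with the singular value
#' decomposition up to component sign.
#'
#' @param qm A [quant_matrix()]; all-missing proteins must be filtered
#'   out first.
#' @param n_components Number of components to retain (default 7).
#' @param tol NIPALS convergence tolerance on the score vector.
#' @param max_iter Iteration cap per component.
#' @return Object of class `pc_model`: `scores` (sample x component),
#'   `loadings` (protein x component), `variance_fraction` (R2X per
#'   component), `r2x_cum`, `design`, `n_components`.
#' @export
fit_pca <- function(qm, n_components = 7, tol = 1e-9, max_iter = 500) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (nrow(qm$mat) < 2 || ncol(qm$mat) < 2) {
    stop("need at least 2 proteins and 2 samples", call. = FALSE)
  }
  if (any(rowSums(!is.na(qm$mat)) == 0)) {
    stop("all-missing protein present; filter first", call. = FALSE)
  }
  X <- t(qm$mat)                               # samples x proteins
  X <- sweep(X, 2, colMeans(X, na.rm = TRUE))  # center each protein
  n_max <- min(dim(X)) - 0L
  if (n_components > n_max) {
    warning("n_components truncated to ", n_max)
    n_components <- n_max
  }
  ss_total <- sum(X ^ 2, na.rm = TRUE)
  n_samp <- nrow(X); n_prot <- ncol(X)
  scores <- matrix(0, n_samp, n_components)
  loadings <- matrix(0, n_prot, n_components)
  varfrac <- numeric(n_components)
  R <- X
  obs <- !is.na(R)
  R0 <- R; R0[!obs] <- 0
  for (a in seq_len(n_components)) {
    # deterministic start: column with maximal variance
    v <- apply(R, 2, stats::var, na.rm = TRUE)
    t_vec <- R0[, which.max(v)]
    for (it in seq_len(max_iter)) {
      # p_j = sum_i(t_i x_ij) / sum_i(t_i^2) over observed cells
      num_p <- crossprod(R0, t_vec)
      den_p <- crossprod(obs, t_vec ^ 2)
      p_vec <- as.vector(num_p / den_p)
      p_vec[!is.finite(p_vec)] <- 0
      p_vec <- p_vec / sqrt(sum(p_vec ^ 2))
      num_t <- R0 %*% p_vec
      den_t <- obs %*% (p_vec ^ 2)
      t_new <- as.vector(num_t / den_t)
      t_new[!is.finite(t_new)] <- 0
      if (sqrt(sum((t_new - t_vec) ^ 2)) < tol * sqrt(sum(t_new ^ 2))) {
        t_vec <- t_new
        break
      }
      t_vec <- t_new
    }
    fitted <- tcrossprod(t_vec, p_vec)
    varfrac[a] <- sum((fitted[obs]) ^ 2) / ss_total
    R[obs] <- R[obs] - fitted[obs]
    R0 <- R; R0[!obs] <- 0
    scores[, a] <- t_vec
    loadings[, a] <- p_vec
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(n_components)))
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = varfrac,
                 r2x_cum = cumsum(varfrac),
                 design = qm$design,
                 n_components = n_components),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat("<pc_model> ", nrow(x$loadings), " proteins, ", nrow(x$scores),
      " samples, ", x$n_components, " components; cumulative R2X = ",
      round(x$r2x_cum[x$n_components], 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy pc_model
#' @export
tidy.pc_model <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$n_components),
    variance_fraction = x$variance_fraction,
    r2x_cum = x$r2x_cum
  )
}

#' @method glance pc_model
#' @export
glance.pc_model <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 r2x = x$r2x_cum[x$n_components])
}

#' Test each principal component against the factorial design
#'
#' For every retained component the sample scores are fitted by a
#' two-way ANOVA `score ~ genotype * treatment`, giving p-values for
#' the genotype effect, the treatment effect and their interaction.
#'
#' @param model A [fit_pca()] model.
#' @param alpha Significance threshold used for the per-effect flags.
#' @return Tibble: `component`, `variance_fraction`, `p_genotype`,
#'   `p_treatment`, `p_interaction`, matching `sig_*` flags, and
#'   `degenerate` (zero-variance scores).
#' @export
test_pc_design <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "pc_model"))
  design <- model$design
  purrr::map_dfr(seq_len(model$n_components), function(a) {
    sc <- model$scores[design$sample_id, a]
    if (stats::var(sc) <= 1e-300) {
      return(tibble::tibble(component = a,
                            variance_fraction = model$variance_fraction[a],
                            p_genotype = NA_real_, p_treatment = NA_real_,
                            p_interaction = NA_real_,
                            sig_genotype = FALSE, sig_treatment = FALSE,
                            sig_interaction = FALSE, degenerate = TRUE))
    }
    ba <- balanced_anova_rows(matrix(sc, 1), design)
    tibble::tibble(component = a,
                   variance_fraction = model$variance_fraction[a],
                   p_genotype = ba$p[1, "genotype"],
                   p_treatment = ba$p[1, "treatment"],
                   p_interaction = ba$p[1, "interaction"],
                   sig_genotype = ba$p[1, "genotype"] < alpha,
                   sig_treatment = ba$p[1, "treatment"] < alpha,
                   sig_interaction = ba$p[1, "interaction"] < alpha,
                   degenerate = FALSE)
  })
}

#' Randomization-based FDR for PC-design associations
#'
#' Estimates how many of the significant component-effect associations
#' found by [test_pc_design()] would arise by chance. The sample labels
#' (columns) are permuted `n_rand` times and the PCA + ANOVA pipeline
#' is re-run on each randomized matrix. Discoveries are the observed
#' component-effect pairs with p below `alpha`; the null count of a
#' randomization is the number of its pairs with p at or below the
#' largest observed discovery p-value (i.e. associations at least as
#' strong as the weakest discovery). The FDR estimate is the mean null
#' count divided by the number of discoveries, clamped to [0, 1]. A
#' cell-wise shuffle of the whole matrix is available as an alternative
#' randomization scheme.
#'
#' @param qm A [quant_matrix()].
#' @param n_components Components to retain.
#' @param n_rand Number of randomizations (>= 20).
#' @param alpha Per-test significance threshold when counting
#'   discoveries.
#' @param seed Integer seed.
#' @param scheme `"labels"` (permute sample labels, default) or
#'   `"cells"` (shuffle all cells).
#' @return List of class `pc_fdr`: `fdr` (pair-based estimate),
#'   `fdr_component` (denominator = components with any significant
#'   effect), `observed` ([test_pc_design()] table), `n_observed`,
#'   `mean_null`, `no_discoveries` flag, `n_rand`.
#' @export
randomization_fdr <- function(qm, n_components = 7, n_rand = 200,
                              alpha = 0.05, seed = 1L,
                              scheme = c("labels", "cells")) {
  stopifnot(inherits(qm, "quant_matrix"))
  scheme <- match.arg(scheme)
  if (n_rand < 20) stop("n_rand must be >= 20", call. = FALSE)
  observed <- test_pc_design(fit_pca(qm, n_components), alpha = alpha)
  p_mat <- as.matrix(observed[, c("p_genotype", "p_treatment",
                                  "p_interaction")])
  sig_mat <- !is.na(p_mat) & p_mat < alpha
  n_obs_pairs <- sum(sig_mat)
  n_obs_comp <- sum(rowSums(sig_mat) > 0)
  p_thresh <- if (n_obs_pairs > 0) max(p_mat[sig_mat]) else alpha
  set.seed(as.integer(seed))
  null_pairs <- integer(n_rand)
  null_comp <- integer(n_rand)
  for (r in seq_len(n_rand)) {
    qr_ <- qm
    if (scheme == "labels") {
      perm <- sample.int(ncol(qm$mat))
      qr_$mat <- qm$mat[, perm, drop = FALSE]
      colnames(qr_$mat) <- colnames(qm$mat)
    } else {
      v <- as.vector(qm$mat)
      qr_$mat <- matrix(sample(v), nrow(qm$mat),
                        dimnames = dimnames(qm$mat))
    }
    tst <- test_pc_design(fit_pca(qr_, n_components), alpha = alpha)
    pm <- as.matrix(tst[, c("p_genotype", "p_treatment", "p_interaction")])
    hit <- !is.na(pm) & pm <= p_thresh
    null_pairs[r] <- sum(hit)
    null_comp[r] <- sum(rowSums(hit) > 0)
  }
  no_disc <- n_obs_pairs == 0
  fdr_pairs <- if (no_disc) 0 else min(mean(null_pairs) / n_obs_pairs, 1)
  fdr_comp <- if (n_obs_comp == 0) 0 else min(mean(null_comp) / n_obs_comp, 1)
  structure(list(fdr = fdr_pairs, fdr_component = fdr_comp,
                 observed = observed, n_observed = n_obs_pairs,
                 mean_null = mean(null_pairs),
                 no_discoveries = no_disc, n_rand = n_rand),
            class = "pc_fdr")
}

#' @export
print.pc_fdr <- function(x, ...) {
  if (x$no_discoveries) {
    cat("<pc_fdr> no significant component-effect pairs observed\n")
  } else {
    cat("<pc_fdr> ", x$n_observed, " significant pairs; estimated FDR = ",
        signif(x$fdr, 3), " (", x$n_rand, " randomizations)\n", sep = "")
  }
  invisible(x)
}
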