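#' Filter proteins by missing-value count
#'
#' Retains proteins quantified in all but at most `max_missing` samples.
#' With the default of 1 this reproduces the usual rule of eliminating
#' proteins not quantified in more than one sample before factorial
#' modeling.
#'
#' @param qm A [quant_matrix()].
#' @param max_missing Maximum tolerated missing cells per protein.
#' @return Filtered [quant_matrix()] with attributes `n_retained` and
#'   `n_dropped`.
#' @export
filter_missing <- function(qm, max_missing = 1) {
  stopifnot(inherits(qm, "quant_matrix"))
  keep <- rowSums(is.na(qm$mat)) <= max_missing
  out <- qm
  out$mat <- qm$mat[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# closed-form balanced two-way ANOVA for complete rows, fully vectorised:
# with +/-1 contrast coding the three effect columns are orthogonal, so
# type-I, type-II and type-III sums of squares coincide.
balanced_anova_rows <- function(Y, design) {
  g <- ifelse(design$genotype == "trisomic", 1, -1)
  t_ <- ifelse(design$treatment == "fluoxetine", 1, -1)
  contrasts <- cbind(genotype = g, treatment = t_, interaction = g * t_)
  N <- ncol(Y)
  ss_eff <- sapply(colnames(contrasts), function(e) {
    cc <- contrasts[, e]
    (Y %*% cc)[, 1] ^ 2 / sum(cc ^ 2)
  })
  if (is.null(dim(ss_eff))) ss_eff <- matrix(ss_eff, nrow = 1,
                                             dimnames = list(NULL, colnames(contrasts)))
  grand <- rowMeans(Y)
  ss_tot <- rowSums((Y - grand) ^ 2)
  ss_res <- ss_tot - rowSums(ss_eff)
  ss_res <- pmax(ss_res, 0)
  df_res <- N - 4L
  ms_res <- ss_res / df_res
  F_ <- ss_eff / ms_res
  p <- stats::pf(F_, 1, df_res, lower.tail = FALSE)
  zero_var <- ms_res <= 1e-300
  p[zero_var, ] <- 1
  F_[zero_var, ] <- NA_real_
  list(F_ = F_, p = p, df_res = df_res, zero_var = zero_var)
}

# type-II ANOVA for a single protein with missing cells
unbalanced_anova_row <- function(y, design) {
  ok <- !is.na(y)
  dat <- data.frame(y = y[ok],
                    genotype = factor(design$genotype[ok], .genotype_levels),
                    treatment = factor(design$treatment[ok], .treatment_levels))
  cells <- table(dat$genotype, dat$treatment)
  if (any(cells < 2)) return(NULL)
  if (stats::var(dat$y) <= 1e-300) {
    return(list(F_ = c(NA, NA, NA), p = c(1, 1, 1),
                df_res = sum(ok) - 4L, zero_var = TRUE))
  }
  fit <- stats::lm(y ~ genotype * treatment, data = dat)
  a2 <- car::Anova(fit, type = 2)
  rn <- rownames(a2)
  pick <- function(term) {
    i <- match(term, rn)
    c(F_ = a2$`F value`[i], p = a2$`Pr(>F)`[i])
  }
  g <- pick("genotype"); t_ <- pick("treatment"); i_ <- pick("genotype:treatment")
  list(F_ = c(g["F_"], t_["F_"], i_["F_"]),
       p = c(g["p"], t_["p"], i_["p"]),
       df_res = fit$df.residual, zero_var = FALSE)
}

#' Per-protein two-way factorial ANOVA
#'
#' Fits, for every protein, the two-way ANOVA
#' `log2 quantity ~ genotype * treatment` and reports F and p for the
#' genotype (condition) effect, the treatment effect, and their
#' interaction, together with cell means and standard errors.
#' Benjamini-Hochberg q-values are computed across proteins separately
#' within each effect family.
#'
#' Complete balanced rows use a closed-form orthogonal-contrast fit
#' (vectorised across proteins). Rows with missing cells are fitted by
#' least squares with type-II sums of squares, provided every design
#' cell retains at least two observations; otherwise the protein is
#' flagged inestimable. Zero-variance proteins get p = 1 and a flag.
#'
#' @param qm A [quant_matrix()] (typically after [filter_missing()]).
#' @return Tibble with one row per protein: F/p/q per effect
#'   (`f_genotype`, `p_genotype`, `q_genotype`, ... `_treatment`,
#'   `_interaction`), per-cell `mean_*` and `sem_*` (EW/EF/TW/TF),
#'   `n_obs`, `df_resid`, `flag` (`"ok"`, `"zero_variance"`,
#'   `"inestimable"`).
#' @export
fit_factorial_anova <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  design <- qm$design
  Y <- qm$mat
  n <- nrow(Y)
  res <- tibble::tibble(
    protein_id = rownames(Y),
    f_genotype = NA_real_, p_genotype = NA_real_,
    f_treatment = NA_real_, p_treatment = NA_real_,
    f_interaction = NA_real_, p_interaction = NA_real_,
    df_resid = NA_real_, n_obs = rowSums(!is.na(Y)),
    flag = "ok"
  )
  complete <- rowSums(is.na(Y)) == 0
  if (any(complete)) {
    ba <- balanced_anova_rows(Y[complete, , drop = FALSE], design)
    res$f_genotype[complete] <- ba$F_[, "genotype"]
    res$p_genotype[complete] <- ba$p[, "genotype"]
    res$f_treatment[complete] <- ba$F_[, "treatment"]
    res$p_treatment[complete] <- ba$p[, "treatment"]
    res$f_interaction[complete] <- ba$F_[, "interaction"]
    res$p_interaction[complete] <- ba$p[, "interaction"]
    res$df_resid[complete] <- ba$df_res
    res$flag[complete][ba$zero_var] <- "zero_variance"
  }
  for (i in which(!complete)) {
    fit <- unbalanced_anova_row(Y[i, ], design)
    if (is.null(fit)) {
      res$flag[i] <- "inestimable"
      next
    }
    res$f_genotype[i] <- fit$F_[1]; res$p_genotype[i] <- fit$p[1]
    res$f_treatment[i] <- fit$F_[2]; res$p_treatment[i] <- fit$p[2]
    res$f_interaction[i] <- fit$F_[3]; res$p_interaction[i] <- fit$p[3]
    res$df_resid[i] <- fit$df_res
    if (isTRUE(fit$zero_var)) res$flag[i] <- "zero_variance"
  }
  for (grp in .group_levels) {
    cols <- design$sample_id[design$group == grp]
    sub <- Y[, cols, drop = FALSE]
    k <- rowSums(!is.na(sub))
    res[[paste0("mean_", grp)]] <- rowMeans(sub, na.rm = TRUE)
    v <- apply(sub, 1, stats::var, na.rm = TRUE)
    res[[paste0("sem_", grp)]] <- sqrt(v / k)
    res[[paste0("n_", grp)]] <- k
  }
  for (eff in c("genotype", "treatment", "interaction")) {
    res[[paste0("q_", eff)]] <- stats::p.adjust(res[[paste0("p_", eff)]],
                                                method = "BH")
  }
  res
}

#' Two-group contrast from summary statistics
#'
#' Pooled two-sample t-test computed directly from group means, SEMs
#' and sizes — usable both on fitted cell summaries and on published
#' summary values. For equal group sizes the standard error of the
#' difference is `sqrt(sem_a^2 + sem_b^2)` with `df = 2n - 2`; for
#' unequal sizes Welch-Satterthwaite degrees of freedom are used. The
#' log2 fold change is `mean_b - mean_a` and the pi score is
#' `log2FC * -log10(p)`.
#'
#' @param mean_a,sem_a,n_a Summary statistics of the reference group.
#' @param mean_b,sem_b,n_b Summary statistics of the comparison group.
#' @param group_a,group_b Labels carried into the output.
#' @return One-row tibble: `group_a`, `group_b`, `log2_fc`, `se_diff`,
#'   `t`, `df`, `p`, `pi_score`.
#' @examples
#' # trisomic-water vs trisomic-fluoxetine from printed summaries
#' group_contrast(10.92, 0.08, 4, 11.55, 0.07, 4, "TW", "TF")
#' @export
group_contrast <- function(mean_a, sem_a, n_a, mean_b, sem_b, n_b,
                           group_a = "A", group_b = "B") {
  if (n_a < 2 || n_b < 2) stop("need n >= 2 per group", call. = FALSE)
  if (sem_a < 0 || sem_b < 0) stop("SEMs must be >= 0", call. = FALSE)
  diff <- mean_b - mean_a
  se <- sqrt(sem_a ^ 2 + sem_b ^ 2)
  if (se == 0) {
    t_ <- if (diff == 0) 0 else Inf * sign(diff)
    df <- n_a + n_b - 2
    p <- if (diff == 0) 1 else 0
  } else if (n_a == n_b) {
    t_ <- diff / se
    df <- 2 * n_a - 2
    p <- 2 * stats::pt(-abs(t_), df)
  } else {
    t_ <- diff / se
    df <- se ^ 4 / (sem_a ^ 4 / (n_a - 1) + sem_b ^ 4 / (n_b - 1))
    p <- 2 * stats::pt(-abs(t_), df)
  }
  tibble::tibble(group_a = group_a, group_b = group_b,
                 log2_fc = diff, se_diff = se, t = t_, df = df, p = p,
                 pi_score = pi_score(diff, max(p, .Machine$double.xmin)))
}

#' Pairwise group contrasts for all proteins
#'
#' Applies [group_contrast()] to the fitted cell summaries of every
#' protein, with Benjamini-Hochberg adjustment across proteins.
#'
#' @param stats Output of [fit_factorial_anova()].
#' @param group_a,group_b Design cell labels.
#' @return Tibble: `protein_id`, `log2_fc`, `t`, `df`, `p`, `q`,
#'   `pi_score`, sorted as input.
#' @export
contrast_all <- function(stats, group_a, group_b) {
  ma <- stats[[paste0("mean_", group_a)]]
  sa <- stats[[paste0("sem_", group_a)]]
  na_ <- stats[[paste0("n_", group_a)]]
  mb <- stats[[paste0("mean_", group_b)]]
  sb <- stats[[paste0("sem_", group_b)]]
  nb_ <- stats[[paste0("n_", group_b)]]
  if (is.null(ma) || is.null(mb)) stop("unknown group label", call. = FALSE)
  rows <- purrr::pmap(list(ma, sa, na_, mb, sb, nb_), function(a, s1, k1, b, s2, k2) {
    if (is.na(a) || is.na(b) || k1 < 2 || k2 < 2) {
      tibble::tibble(log2_fc = NA_real_, t = NA_real_, df = NA_real_,
                     p = NA_real_, pi_score = NA_real_)
    } else {
      gc <- group_contrast(a, s1, k1, b, s2, k2, group_a, group_b)
      gc[, c("log2_fc", "t", "df", "p", "pi_score")]
    }
  })
  out <- dplyr::bind_cols(tibble::tibble(protein_id = stats$protein_id),
                          dplyr::bind_rows(rows))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("protein_id", "log2_fc", "t", "df", "p", "q", "pi_score")]
}

#' Pi score: effect size times significance
#'
#' Combines biological relevance and statistical significance of a
#' protein into one ranking statistic: `log2FC * -log10(p)`. Its sign
#' follows the fold change and it is zero exactly when p = 1 or the
#' fold change is zero.
#'
#' @param log2fc Log2 fold change.
#' @param p P-value in (0, 1]; p = 0 is an error — use an add-one
#'   permutation p or a floor.
#' @return Numeric pi score (vectorised).
#' @export
pi_score <- function(log2fc, p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    stop("p must lie in (0, 1]", call. = FALSE)
  }
  log2fc * (-log10(p))
}

#' Select proteins with a significant interaction
#'
#' Applies the nominal decision rule `interaction p < alpha` (strict
#' inequality) and returns the selected proteins ordered by p.
#'
#' @param stats Output of [fit_factorial_anova()].
#' @param alpha Nominal threshold (default 0.05).
#' @param use_q Select on the BH q-value instead of the nominal p.
#' @return Tibble of selected rows ordered by interaction p, with
#'   attribute `n_selected`.
#' @export
select_interaction <- function(stats, alpha = 0.05, use_q = FALSE) {
  crit <- if (use_q) stats$q_interaction else stats$p_interaction
  keep <- !is.na(crit) & crit < alpha
  out <- stats[keep, , drop = FALSE]
  out <- out[order(out$p_interaction), , drop = FALSE]
  attr(out, "n_selected") <- nrow(out)
  out
}
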