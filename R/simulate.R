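#' Simulation configuration for a synthetic factorial TMT experiment
#'
#' Collects and validates the parameters of the synthetic-data
#' generator. Defaults emulate a 16-channel TMTpro study of a 2x2
#' genotype-by-treatment design with four replicates per cell and a
#' proteome of 2554 proteins, of which 5% carry a genotype-by-treatment
#' "rescue" interaction of 1 log2 unit against residual noise of
#' 0.25 log2 units.
#'
#' @param n_proteins Number of simulated proteins.
#' @param n_per_group Replicates per design cell.
#' @param frac_interaction Fraction of proteins with a planted
#'   genotype-by-treatment interaction.
#' @param frac_main_genotype,frac_main_treatment Fractions of the
#'   remaining proteins with a planted main effect only.
#' @param effect_size_log2 Interaction magnitude (log2 units).
#' @param main_effect_log2 Main-effect magnitude (log2 units).
#' @param sigma_log2 Residual (between-replicate) SD in log2 units.
#' @param baseline_log2_range Range the per-protein baseline abundances
#'   are drawn from (uniform).
#' @param spectra_per_protein Mean number of quantified spectra per
#'   protein (counts are `1 + Poisson(spectra_per_protein - 1)`).
#' @param sigma_spectrum_log2 Spectrum-level measurement SD around the
#'   protein quantity (log2 units).
#' @param frac_shared_spectra Fraction of spectra additionally assigned
#'   to a second protein (removed later by pruning).
#' @param missing_rate Per-cell missingness probability.
#' @param seed Integer seed; a fixed seed makes all outputs
#'   bit-identical across runs.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 2554,
                              n_per_group = 4,
                              frac_interaction = 0.05,
                              frac_main_genotype = 0.10,
                              frac_main_treatment = 0.10,
                              effect_size_log2 = 1.0,
                              main_effect_log2 = 0.5,
                              sigma_log2 = 0.25,
                              baseline_log2_range = c(8, 14),
                              spectra_per_protein = 4,
                              sigma_spectrum_log2 = 0.1,
                              frac_shared_spectra = 0.05,
                              missing_rate = 0.05,
                              seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_per_group = as.integer(n_per_group),
              frac_interaction = frac_interaction,
              frac_main_genotype = frac_main_genotype,
              frac_main_treatment = frac_main_treatment,
              effect_size_log2 = effect_size_log2,
              main_effect_log2 = main_effect_log2,
              sigma_log2 = sigma_log2,
              baseline_log2_range = baseline_log2_range,
              spectra_per_protein = spectra_per_protein,
              sigma_spectrum_log2 = sigma_spectrum_log2,
              frac_shared_spectra = frac_shared_spectra,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  props <- c("frac_interaction", "frac_main_genotype", "frac_main_treatment",
             "frac_shared_spectra", "missing_rate")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop(p, " must be a proportion in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$missing_rate >= 1) stop("missing_rate must be < 1", call. = FALSE)
  if (cfg$n_proteins < 1 || cfg$n_per_group < 2) {
    stop("need n_proteins >= 1 and n_per_group >= 2", call. = FALSE)
  }
  for (p in c("effect_size_log2", "main_effect_log2", "sigma_log2")) {
    if (!is.finite(cfg[[p]])) stop(p, " must be finite", call. = FALSE)
  }
  if (cfg$sigma_log2 < 0) stop("sigma_log2 must be >= 0", call. = FALSE)
  if (length(cfg$baseline_log2_range) != 2 ||
      diff(cfg$baseline_log2_range) < 0) {
    stop("baseline_log2_range must be an increasing interval", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

# Cell means for every protein given its planted effect class.
# Interaction proteins follow the "rescue" pattern: the trisomic-water
# cell is shifted by +/- effect from the euploid baseline and the
# trisomic-fluoxetine cell is pulled back to baseline, mirroring
# down-in-TW/restored-by-TF and up-in-TW/suppressed-by-TF proteins.
simulate_truth <- function(cfg) {
  n <- cfg$n_proteins
  protein_id <- sprintf("P%04d", seq_len(n))
  baseline <- stats::runif(n, cfg$baseline_log2_range[1], cfg$baseline_log2_range[2])

  n_int <- round(cfg$frac_interaction * n)
  idx <- sample.int(n)
  int_idx <- idx[seq_len(n_int)]
  rest <- idx[-seq_len(n_int)]
  n_g <- round(cfg$frac_main_genotype * n)
  n_t <- round(cfg$frac_main_treatment * n)
  g_idx <- rest[seq_len(min(n_g, length(rest)))]
  rest2 <- setdiff(rest, g_idx)
  t_idx <- rest2[seq_len(min(n_t, length(rest2)))]

  mu <- matrix(baseline, n, 4, dimnames = list(protein_id, .group_levels))
  direction <- rep(NA_character_, n)
  if (n_int > 0) {
    d <- rep(c(-1, 1), length.out = n_int)[sample.int(n_int)]
    direction[int_idx] <- ifelse(d < 0, "down", "up")
    mu[int_idx, "TW"] <- baseline[int_idx] + d * cfg$effect_size_log2
  }
  if (length(g_idx)) {
    sg <- sample(c(-1, 1), length(g_idx), replace = TRUE)
    mu[g_idx, c("TW", "TF")] <- mu[g_idx, c("TW", "TF")] + sg * cfg$main_effect_log2
  }
  if (length(t_idx)) {
    st <- sample(c(-1, 1), length(t_idx), replace = TRUE)
    mu[t_idx, c("EF", "TF")] <- mu[t_idx, c("EF", "TF")] + st * cfg$main_effect_log2
  }

  # flags derived from the realized cell-mean pattern
  int_c <- (mu[, "TF"] - mu[, "TW"]) - (mu[, "EF"] - mu[, "EW"])
  gen_c <- (mu[, "TW"] + mu[, "TF"]) / 2 - (mu[, "EW"] + mu[, "EF"]) / 2
  trt_c <- (mu[, "EF"] + mu[, "TF"]) / 2 - (mu[, "EW"] + mu[, "TW"]) / 2
  tol <- 1e-12
  interaction_true <- abs(int_c) > tol
  tibble::tibble(
    protein_id = protein_id,
    interaction_true = interaction_true,
    interaction_down_true = interaction_true & direction %in% "down",
    interaction_up_true = interaction_true & direction %in% "up",
    main_genotype_true = abs(gen_c) > tol,
    main_treatment_true = abs(trt_c) > tol,
    direction = direction,
    mu_EW = mu[, "EW"], mu_EF = mu[, "EF"],
    mu_TW = mu[, "TW"], mu_TF = mu[, "TF"]
  )
}

#' Simulate a factorial TMT experiment
#'
#' Generates (i) a protein-by-sample log2 quantity matrix with planted
#' genotype, treatment and interaction effects plus Gaussian residual
#' noise and sporadic missingness, (ii) a spectrum-level reporter-ion
#' intensity table whose per-protein, per-sample log2 median equals the
#' matrix entry up to spectrum noise, and (iii) the ground truth of
#' which proteins carry which effects.
#'
#' Interaction proteins split evenly between "down in trisomic-water,
#' restored by fluoxetine" and "up in trisomic-water, suppressed by
#' fluoxetine" patterns.
#'
#' @param config A [simulation_config()].
#' @return List of class `tmt_simulation`: `spectra` (tibble),
#'   `quant` ([quant_matrix()]), `truth` (tibble), `design`, `config`.
#' @examples
#' sim <- simulate_experiment(simulation_config(n_proteins = 50, seed = 1))
#' dim(sim$quant)
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  design <- design_2x2(config$n_per_group)
  truth <- simulate_truth(config)
  n <- config$n_proteins

  mu_cells <- as.matrix(truth[, paste0("mu_", .group_levels)])
  colnames(mu_cells) <- .group_levels
  q <- mu_cells[, design$group, drop = FALSE] +
    matrix(stats::rnorm(n * nrow(design), 0, config$sigma_log2), n)
  dimnames(q) <- list(truth$protein_id, design$sample_id)

  # spectrum layer built around the (pre-missingness) quantity matrix
  k <- 1L + stats::rpois(n, max(config$spectra_per_protein - 1, 0))
  prot_of <- rep(seq_len(n), k)
  n_spec <- length(prot_of)
  delta <- stats::rnorm(n_spec, 0, 0.5)   # per-spectrum ionization offset
  vals <- q[prot_of, , drop = FALSE] + delta +
    matrix(stats::rnorm(n_spec * nrow(design), 0, config$sigma_spectrum_log2),
           n_spec)
  intens <- 2 ^ vals
  colnames(intens) <- design$channel

  protein_ids <- truth$protein_id[prot_of]
  shared <- stats::runif(n_spec) < config$frac_shared_spectra
  if (any(shared) && n > 1) {
    other <- vapply(prot_of[shared], function(i) {
      sample(truth$protein_id[-i], 1)
    }, character(1))
    protein_ids[shared] <- paste(protein_ids[shared], other, sep = ";")
  }
  spectra <- dplyr::bind_cols(
    tibble::tibble(spectrum_id = sprintf("S%06d", seq_len(n_spec)),
                   protein_ids = protein_ids),
    tibble::as_tibble(intens)
  )

  qm <- quant_matrix(q, design)
  if (config$missing_rate > 0) {
    qm <- inject_missingness(qm, config$missing_rate,
                             seed = config$seed + 1000L)
  }
  structure(list(spectra = spectra, quant = qm, truth = truth,
                 design = design, config = config),
            class = "tmt_simulation")
}

#' @export
print.tmt_simulation <- function(x, ...) {
  cat("<tmt_simulation> ", x$config$n_proteins, " proteins, ",
      nrow(x$design), " samples, ", nrow(x$spectra), " spectra; ",
      sum(x$truth$interaction_true), " interaction-true proteins\n", sep = "")
  invisible(x)
}

#' Forward-mix reporter intensities through a purity matrix
#'
#' Applies the isotope-impurity leakage model to clean reporter
#' intensities: each observed channel receives contributions from its
#' neighbours according to the purity matrix. This is the forward model
#' that [impurity_correct()] inverts; mixing followed by correction
#' recovers the input to numerical precision.
#'
#' @param spectra Spectrum tibble (intensity scale) with channel
#'   columns.
#' @param purity A [purity_matrix()] whose dimnames match the channel
#'   columns.
#' @return Spectrum tibble with mixed intensities.
#' @export
mix_impurities <- function(spectra, purity) {
  ch <- colnames(purity)
  if (!all(ch %in% names(spectra)) ||
      length(ch) != length(channel_cols(spectra))) {
    stop("channel columns do not match the purity matrix", call. = FALSE)
  }
  if (any(colSums(purity) > 1 + 1e-12)) {
    stop("purity matrix column sums must be <= 1", call. = FALSE)
  }
  M <- as.matrix(spectra[, ch])
  spectra[, ch] <- M %*% t(unclass(purity))
  spectra
}

#' Inject missing values into a quantity matrix
#'
#' Marks cells of the matrix as missing, either completely at random
#' (each cell independently with probability `rate`) or preferentially
#' at low intensity (`mechanism = "mnar"`: the per-cell probability
#' follows a logistic curve in the centered log2 quantity, scaled so the
#' expected overall rate is `rate`).
#'
#' @param qm A [quant_matrix()].
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed for the mask.
#' @param mechanism `"mcar"` (default) or `"mnar"`.
#' @return The matrix with additional `NA` cells.
#' @export
inject_missingness <- function(qm, rate, seed = 1L, mechanism = c("mcar", "mnar")) {
  stopifnot(inherits(qm, "quant_matrix"))
  mechanism <- match.arg(mechanism)
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("rate must be in [0, 1)", call. = FALSE)
  }
  if (rate == 0) return(qm)
  set.seed(as.integer(seed))
  m <- qm$mat
  if (mechanism == "mcar") {
    mask <- matrix(stats::runif(length(m)) < rate, nrow(m))
  } else {
    z <- scale(as.vector(m))[, 1]
    w <- stats::plogis(-z)            # low-abundance cells more likely missing
    p <- pmin(rate * w / mean(w, na.rm = TRUE), 0.99)
    mask <- matrix(stats::runif(length(m)) < p, nrow(m))
  }
  m[mask] <- NA_real_
  qm$mat <- m
  qm
}

#' Simulate a gene-set collection with planted enrichment
#'
#' Draws gene sets from the simulated protein universe. Sets named in
#' `enrichment_spec` oversample proteins carrying the mapped truth flag
#' (e.g. `interaction_true`); all other sets are uniform draws, giving a
#' null background for enrichment calibration.
#'
#' @param truth Ground-truth tibble from [simulate_experiment()].
#' @param n_sets Number of sets.
#' @param size_range Integer interval of set sizes.
#' @param enrichment_spec Named character vector mapping a set name
#'   (must be one of the generated `set%03d` names) to a logical truth
#'   column of `truth`.
#' @param enriched_fraction Fraction of an enriched set drawn from
#'   flag-true proteins (default 0.9).
#' @param seed Integer seed.
#' @return Gene-set tibble: `name`, `description`, `members` (list
#'   column), `enriched` flag.
#' @export
simulate_gene_sets <- function(truth, n_sets = 50, size_range = c(10, 80),
                               enrichment_spec = character(),
                               enriched_fraction = 0.9, seed = 1L) {
  universe <- truth$protein_id
  if (min(size_range) < 2 || max(size_range) > length(universe)) {
    stop("size_range must lie within [2, n_proteins]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  names_ <- sprintf("set%03d", seq_len(n_sets))
  bad <- setdiff(names(enrichment_spec), names_)
  if (length(bad)) stop("enrichment_spec names not generated: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  sizes <- sample(seq(size_range[1], size_range[2]), n_sets, replace = TRUE)
  members <- vector("list", n_sets)
  enriched <- names_ %in% names(enrichment_spec)
  for (i in seq_len(n_sets)) {
    if (enriched[i]) {
      flag <- enrichment_spec[[names_[i]]]
      if (!flag %in% names(truth) || !is.logical(truth[[flag]])) {
        stop("unknown truth flag: ", flag, call. = FALSE)
      }
      pool_true <- universe[truth[[flag]]]
      n_true <- min(round(enriched_fraction * sizes[i]), length(pool_true))
      rest <- sizes[i] - n_true
      members[[i]] <- sample(c(sample(pool_true, n_true),
                               sample(setdiff(universe, pool_true), rest)))
    } else {
      members[[i]] <- sample(universe, sizes[i])
    }
  }
  tibble::tibble(name = names_,
                 description = ifelse(enriched, "planted", "uniform"),
                 members = members,
                 enriched = enriched)
}
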