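#' @keywords internal
channel_cols <- function(spectra) {
  setdiff(names(spectra), c("spectrum_id", "protein_ids", "weight"))
}

#' Correct reporter intensities for isotope impurities
#'
#' Inverts the channel leakage encoded by a purity matrix: for each
#' spectrum the linear system `P %*% x = observed` is solved for the
#' true intensities `x`. Negative solutions (possible with noisy data)
#' are clamped to zero; the number of clamped cells is attached as the
#' `n_clamped` attribute.
#'
#' @param spectra Spectrum tibble (intensity scale).
#' @param purity A [purity_matrix()]; must be full rank and match the
#'   channel columns.
#' @return Spectrum tibble with corrected intensities.
#' @export
impurity_correct <- function(spectra, purity) {
  ch <- colnames(purity)
  if (!all(ch %in% names(spectra)) ||
      length(ch) != length(channel_cols(spectra))) {
    stop("channel columns do not match the purity matrix", call. = FALSE)
  }
  P <- unclass(purity)
  if (qr(P)$rank < ncol(P)) stop("purity matrix is singular", call. = FALSE)
  M <- as.matrix(spectra[, ch])
  X <- t(solve(P, t(M)))
  n_clamped <- sum(X < 0, na.rm = TRUE)
  X[X < 0] <- 0
  spectra[, ch] <- X
  attr(spectra, "n_clamped") <- n_clamped
  spectra
}

#' Iterative median normalization of reporter intensities
#'
#' Alternately removes per-sample (column) and per-spectrum (row) median
#' offsets in the log2 domain until the largest adjustment falls below
#' `tol`. Offsets are taken relative to the median of medians, so the
#' overall intensity scale is preserved. At convergence all sample
#' medians are equal and all spectrum medians are equal (within `tol`).
#'
#' @param spectra Spectrum tibble on the intensity scale (values must be
#'   positive where present).
#' @param tol Convergence tolerance on the log2 scale.
#' @param max_iter Iteration cap.
#' @return Normalized spectrum tibble (intensity scale), with attributes
#'   `iterations` and `converged`.
#' @export
iterative_normalize <- function(spectra, tol = 1e-8, max_iter = 500) {
  ch <- channel_cols(spectra)
  M <- as.matrix(spectra[, ch])
  if (any(M <= 0, na.rm = TRUE)) {
    stop("intensities must be positive for normalization", call. = FALSE)
  }
  col_ok <- colSums(!is.na(M)) > 0
  if (!all(col_ok)) stop("sample with no observed intensities: ",
                         ch[!col_ok][1], call. = FALSE)
  row_ok <- rowSums(!is.na(M)) > 0
  if (!all(row_ok)) stop("spectrum with no observed intensities: ",
                         spectra$spectrum_id[!row_ok][1], call. = FALSE)
  L <- log2(M)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cmed <- apply(L, 2, stats::median, na.rm = TRUE)
    cadj <- cmed - stats::median(cmed)
    L <- sweep(L, 2, cadj)
    rmed <- apply(L, 1, stats::median, na.rm = TRUE)
    radj <- rmed - stats::median(rmed)
    L <- sweep(L, 1, radj)
    delta <- max(abs(c(cadj, radj)))
    if (delta < tol || iter >= max_iter) break
  }
  spectra[, ch] <- 2 ^ L
  attr(spectra, "iterations") <- iter
  attr(spectra, "converged") <- delta < tol
  spectra
}

#' Log-transform, prune and weight spectra
#'
#' Prepares a spectrum table for protein rollup: intensities are
#' log2-transformed (non-positive values become missing and are
#' counted), spectra matched to more than one protein are removed, and
#' each spectrum receives an intensity weight
#' `w = I_total / (I_total + c)` with `c` the 10th percentile of total
#' spectrum intensities, so low-intensity (noisier) spectra are
#' down-weighted. The weight function is a documented stand-in for
#' proprietary adaptive weighting schemes and can be replaced via
#' `weight_fun`.
#'
#' @param spectra Spectrum tibble on the intensity scale.
#' @param weight_fun Optional function of the vector of total spectrum
#'   intensities returning positive weights.
#' @return Spectrum tibble with log2 channel values and a `weight`
#'   column; attributes `n_pruned_shared` and `n_nonpositive`.
#' @export
preprocess_spectra <- function(spectra, weight_fun = NULL) {
  ch <- channel_cols(spectra)
  shared <- grepl(";", spectra$protein_ids, fixed = TRUE)
  n_pruned <- sum(shared)
  spectra <- spectra[!shared, , drop = FALSE]
  M <- as.matrix(spectra[, ch])
  nonpos <- !is.na(M) & M <= 0
  M[nonpos] <- NA_real_
  total <- rowSums(M, na.rm = TRUE)
  if (is.null(weight_fun)) {
    c0 <- stats::quantile(total, 0.10, names = FALSE)
    weight_fun <- function(tot) tot / (tot + c0)
  }
  w <- weight_fun(total)
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be finite and positive", call. = FALSE)
  }
  spectra[, ch] <- log2(M)
  spectra$weight <- w
  attr(spectra, "n_pruned_shared") <- n_pruned
  attr(spectra, "n_nonpositive") <- sum(nonpos)
  spectra
}

#' Weighted median
#'
#' Smallest value whose cumulative weight reaches half the total
#' weight; ties resolve toward the lower value.
#'
#' @param x Numeric values.
#' @param w Positive weights (default equal).
#' @return The weighted median, or `NA` if no observed values.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  ok <- !is.na(x)
  x <- x[ok]; w <- w[ok]
  if (!length(x)) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1]]
}

#' Roll spectra up to protein quantities
#'
#' Summarizes preprocessed (log2, pruned, weighted) spectra to a
#' protein-by-sample matrix: each entry is the weighted median of the
#' protein's spectrum values in that sample; cells with no observed
#' spectra are missing. Channel columns are mapped to samples via the
#' design's `channel` column.
#'
#' @param spectra Output of [preprocess_spectra()].
#' @param design Design tibble with `channel` and `sample_id`.
#' @return A [quant_matrix()] with a `spectrum_counts` attribute
#'   (tibble of per-protein spectrum counts).
#' @export
rollup_proteins <- function(spectra, design) {
  design <- validate_design(design)
  ch <- channel_cols(spectra)
  if (!setequal(ch, design$channel)) {
    stop("spectrum channels and design channels differ", call. = FALSE)
  }
  if (is.null(spectra$weight)) spectra$weight <- 1
  prots <- sort(unique(spectra$protein_ids))
  mat <- matrix(NA_real_, length(prots), nrow(design),
                dimnames = list(prots, design$sample_id))
  if (nrow(spectra)) {
    split_idx <- split(seq_len(nrow(spectra)), spectra$protein_ids)
    V <- as.matrix(spectra[, design$channel])  # columns in design order
    w_all <- spectra$weight
    for (p in names(split_idx)) {
      rows <- split_idx[[p]]
      for (j in seq_along(design$sample_id)) {
        mat[p, j] <- weighted_median(V[rows, j], w_all[rows])
      }
    }
  }
  qm <- quant_matrix(mat, design)
  counts <- dplyr::count(spectra, .data$protein_ids, name = "n_spectra")
  attr(qm, "spectrum_counts") <- tibble::tibble(
    protein_id = counts$protein_ids, n_spectra = counts$n_spectra)
  qm
}

#' Permutation test for differential expression between two groups
#'
#' Per protein, the statistic is the difference of group means of log2
#' quantities. The null distribution is built by permuting the group
#' labels: exhaustively over all distinct splits when their number is at
#' most `exhaustive_cap`, otherwise by `n_perm` Monte-Carlo draws (with
#' the add-one convention so p is never zero). Two-sided p-values are
#' adjusted across proteins by Benjamini-Hochberg.
#'
#' With 4 vs 4 samples the 70 label splits are enumerated, so p-values
#' are multiples of 1/70 with minimum 2/70.
#'
#' @param qm A [quant_matrix()].
#' @param group_a,group_b Design cell labels (e.g. `"TW"`, `"TF"`).
#' @param n_perm Monte-Carlo permutations when enumeration is too large.
#' @param alpha Unadjusted significance level for the decision flag.
#' @param seed Seed for Monte-Carlo permutations.
#' @param exhaustive_cap Enumerate exhaustively when the number of
#'   distinct splits is at most this.
#' @return Tibble: `protein_id`, `mean_a`, `mean_b`, `log2_fc`
#'   (`mean_b - mean_a`), `p`, `q`, `significant_unadjusted`,
#'   `significant_bh`; attribute `n_splits` records the null size.
#' @export
permutation_de <- function(qm, group_a, group_b, n_perm = 10000,
                           alpha = 0.05, seed = 1L, exhaustive_cap = 20000) {
  stopifnot(inherits(qm, "quant_matrix"))
  for (g in c(group_a, group_b)) {
    if (!g %in% qm$design$group) stop("unknown group label: ", g, call. = FALSE)
  }
  ia <- which(qm$design$group == group_a)
  ib <- which(qm$design$group == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  sub <- qm$mat[, c(ia, ib), drop = FALSE]
  na <- length(ia); nb <- length(ib); ntot <- na + nb
  obs <- rowMeans(sub[, seq_len(na), drop = FALSE], na.rm = TRUE) -
    rowMeans(sub[, na + seq_len(nb), drop = FALSE], na.rm = TRUE)

  n_splits <- choose(ntot, na)
  exhaustive <- n_splits <= exhaustive_cap
  if (exhaustive) {
    combs <- utils::combn(ntot, na)
  } else {
    set.seed(as.integer(seed))
    combs <- replicate(n_perm, sample.int(ntot, na))
  }
  nperm_used <- ncol(combs)
  count_ge <- integer(nrow(sub))
  obs_abs <- abs(obs)
  for (j in seq_len(nperm_used)) {
    sel <- combs[, j]
    stat <- rowMeans(sub[, sel, drop = FALSE], na.rm = TRUE) -
      rowMeans(sub[, -sel, drop = FALSE], na.rm = TRUE)
    count_ge <- count_ge + (abs(stat) >= obs_abs - 1e-12)
  }
  p <- if (exhaustive) count_ge / nperm_used else (count_ge + 1) / (nperm_used + 1)
  p <- pmin(p, 1)
  q <- stats::p.adjust(p, method = "BH")
  out <- tibble::tibble(
    protein_id = rownames(sub),
    mean_a = rowMeans(sub[, seq_len(na), drop = FALSE], na.rm = TRUE),
    mean_b = rowMeans(sub[, na + seq_len(nb), drop = FALSE], na.rm = TRUE),
    log2_fc = -obs,
    p = p, q = q,
    significant_unadjusted = p < alpha,
    significant_bh = q < alpha
  )
  attr(out, "n_splits") <- nperm_used
  attr(out, "exhaustive") <- exhaustive
  out
}
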