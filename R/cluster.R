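#' Standard-scale each protein
#'
#' Centers every protein row to mean zero and scales it to variance one
#' using the population (divide-by-n) variance. Missing cells propagate
#' unchanged; zero-variance proteins are an error.
#'
#' @param qm A [quant_matrix()].
#' @return Scaled [quant_matrix()].
#' @export
standard_scale <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  m <- qm$mat
  mu <- rowMeans(m, na.rm = TRUE)
  n_obs <- rowSums(!is.na(m))
  if (any(n_obs < 2)) {
    stop("protein with < 2 observed values: ",
         rownames(m)[n_obs < 2][1], call. = FALSE)
  }
  centered <- m - mu
  sd_pop <- sqrt(rowSums(centered ^ 2, na.rm = TRUE) / n_obs)
  if (any(sd_pop == 0)) {
    stop("zero-variance protein: ", rownames(m)[sd_pop == 0][1], call. = FALSE)
  }
  qm$mat <- centered / sd_pop
  qm
}

#' Hierarchical clustering of proteins by correlation distance
#'
#' Distance between proteins is one minus their Pearson correlation
#' across samples (pairwise-complete observations); agglomeration uses
#' Ward's criterion on squared dissimilarities with square-root heights
#' (the `ward.D2` convention). Merge heights are non-decreasing.
#'
#' @param qm A [quant_matrix()], typically [standard_scale()]d.
#' @return An `hclust` tree with protein labels.
#' @export
correlation_ward_tree <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  m <- qm$mat
  if (nrow(m) < 2) stop("need at least 2 proteins", call. = FALSE)
  r <- stats::cor(t(m), use = "pairwise.complete.obs")
  if (any(is.na(r))) {
    bad <- which(is.na(r), arr.ind = TRUE)[1, ]
    stop("undefined correlation between ", rownames(m)[bad[1]], " and ",
         rownames(m)[bad[2]], call. = FALSE)
  }
  d <- stats::as.dist(1 - r)
  stats::hclust(d, method = "ward.D2")
}

#' Cut the cluster tree at its first branch
#'
#' Splits the dendrogram into the two subtrees of the root. When a
#' design is given, labels are oriented as in the interaction heatmap
#' convention: "cut1" is the cluster whose proteins are on average
#' lower in trisomic-fluoxetine than trisomic-water samples (scaled
#' TF mean minus TW mean negative), "cut2" the other.
#'
#' @param tree `hclust` tree from [correlation_ward_tree()].
#' @param qm Optional scaled [quant_matrix()] used to orient the
#'   labels; without it the split keeps arbitrary orientation
#'   (cluster of leaf 1 = cut1).
#' @return Tibble `protein_id`, `cluster` (`"cut1"`/`"cut2"`).
#' @export
cut_first_branch <- function(tree, qm = NULL) {
  stopifnot(inherits(tree, "hclust"))
  if (length(tree$labels) < 2) stop("need at least 2 leaves", call. = FALSE)
  k2 <- stats::cutree(tree, k = 2)
  lab <- rep("cut2", length(k2))
  if (!is.null(qm)) {
    design <- qm$design
    tf <- design$sample_id[design$group == "TF"]
    tw <- design$sample_id[design$group == "TW"]
    delta <- vapply(1:2, function(cl) {
      rows <- names(k2)[k2 == cl]
      mean(qm$mat[rows, tf], na.rm = TRUE) - mean(qm$mat[rows, tw], na.rm = TRUE)
    }, numeric(1))
    cut1 <- which.min(delta)
  } else {
    cut1 <- k2[1]
  }
  lab[k2 == cut1] <- "cut1"
  tibble::tibble(protein_id = names(k2), cluster = lab)
}

#' Confidence-ellipse parameters for grouped score plots
#'
#' For each sample group, the bivariate-normal 95% confidence ellipse
#' of two score columns: center, axes (from the eigendecomposition of
#' the covariance scaled by the chi-square 2-df quantile) and angle.
#'
#' @param model A `pc_model`.
#' @param components Pair of component indices (default PC3 vs PC4).
#' @param level Confidence level.
#' @return Tibble per group: `group`, centers, semi-axes `a` and `b`,
#'   `angle_rad`, `degenerate` flag (singular covariance).
#' @export
score_ellipses <- function(model, components = c(3, 4), level = 0.95) {
  stopifnot(inherits(model, "pc_model"))
  design <- model$design
  q <- stats::qchisq(level, df = 2)
  purrr::map_dfr(unique(design$group), function(g) {
    rows <- design$sample_id[design$group == g]
    S <- model$scores[rows, components, drop = FALSE]
    ctr <- colMeans(S)
    V <- stats::cov(S)
    ev <- eigen(V, symmetric = TRUE)
    degen <- any(ev$values <= 1e-12)
    tibble::tibble(group = g, center_x = ctr[1], center_y = ctr[2],
                   a = sqrt(max(ev$values[1], 0) * q),
                   b = sqrt(max(ev$values[2], 0) * q),
                   angle_rad = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
                   degenerate = degen)
  })
}

#' Plot-ready data bundles for the standard figures
#'
#' Collects the data behind the three standard displays: the PC score
#' plot with per-group 95% confidence ellipses, the interaction heatmap
#' (scaled matrix in dendrogram leaf order with cluster labels, sample
#' columns in design order), and per-protein, per-group boxplot
#' five-number summaries (type-7 quantiles).
#'
#' @param qm Quantity matrix of the interaction-selected proteins
#'   (unscaled log2 values for the boxplots).
#' @param model A `pc_model` for the score plot.
#' @param components Score-plot components.
#' @return List with tibbles `scores`, `ellipses`, `heatmap` (long
#'   form, rows ordered by `row_order`), `cluster_assignment`,
#'   `boxplots`.
#' @export
export_plot_data <- function(qm, model, components = c(3, 4)) {
  stopifnot(inherits(qm, "quant_matrix"), inherits(model, "pc_model"))
  design <- qm$design
  scores <- tibble::tibble(
    sample_id = rownames(model$scores),
    x = model$scores[, components[1]],
    y = model$scores[, components[2]]
  )
  scores <- dplyr::left_join(scores,
                             design[, c("sample_id", "group")], by = "sample_id")

  scaled <- standard_scale(qm)
  tree <- correlation_ward_tree(scaled)
  assign <- cut_first_branch(tree, scaled)
  leaf_order <- tree$labels[tree$order]
  heat <- tidy(scaled)
  heat$row_order <- match(heat$protein_id, leaf_order)
  heat <- dplyr::left_join(heat, assign, by = "protein_id")

  box <- tidy(qm) |>
    dplyr::group_by(.data$protein_id, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      lower_whisker = min(.data$log2_quantity),
      q1 = stats::quantile(.data$log2_quantity, 0.25, type = 7, names = FALSE),
      median = stats::median(.data$log2_quantity),
      q3 = stats::quantile(.data$log2_quantity, 0.75, type = 7, names = FALSE),
      upper_whisker = max(.data$log2_quantity),
      .groups = "drop"
    )
  list(scores = scores, ellipses = score_ellipses(model, components),
       heatmap = heat, cluster_assignment = assign, boxplots = box,
       tree = tree)
}
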