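#' Protein-by-sample quantity matrix
#'
#' The central analysis container: a numeric matrix of log2 protein
#' quantities (rows = proteins, columns = samples; `NA` = not
#' quantified) bound to the factorial design of its samples. Most
#' downstream functions — the missing-value filter, per-protein ANOVA,
#' PCA, clustering — consume this object.
#'
#' @param mat Numeric matrix, rownames = protein identifiers, colnames =
#'   sample identifiers.
#' @param design Design tibble (see [design_2x2()]); its `sample_id` set
#'   must equal the matrix columns.
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(mat, design) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("mat must be a numeric matrix",
                                                call. = FALSE)
  if (is.null(rownames(mat))) stop("mat needs protein rownames", call. = FALSE)
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate protein identifiers: ",
         paste(utils::head(unique(rownames(mat)[duplicated(rownames(mat))]), 5),
               collapse = ", "), call. = FALSE)
  }
  design <- validate_design(design)
  if (is.null(colnames(mat))) stop("mat needs sample colnames", call. = FALSE)
  if (!setequal(colnames(mat), design$sample_id)) {
    stop("matrix samples and design sample_id differ", call. = FALSE)
  }
  mat <- mat[, design$sample_id, drop = FALSE]
  if (any(is.infinite(mat))) stop("non-finite quantities present", call. = FALSE)
  structure(list(mat = mat, design = design), class = "quant_matrix")
}

#' @export
dim.quant_matrix <- function(x) dim(x$mat)

#' @export
print.quant_matrix <- function(x, ...) {
  cat("<quant_matrix> ", nrow(x$mat), " proteins x ", ncol(x$mat), " samples; ",
      sum(is.na(x$mat)), " missing cells\n", sep = "")
  invisible(x)
}

#' Per-protein missing-value counts
#'
#' @param qm A [quant_matrix()].
#' @return Tibble with `protein_id` and `n_missing`.
#' @export
missing_counts <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  tibble::tibble(protein_id = rownames(qm$mat),
                 n_missing = rowSums(is.na(qm$mat)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a quantity matrix into long form
#'
#' @param x A [quant_matrix()].
#' @param ... Unused.
#' @return Long tibble: `protein_id`, `sample_id`, `genotype`,
#'   `treatment`, `group`, `log2_quantity` (missing cells dropped).
#' @method tidy quant_matrix
#' @export
tidy.quant_matrix <- function(x, ...) {
  long <- tibble::tibble(
    protein_id = rep(rownames(x$mat), times = ncol(x$mat)),
    sample_id = rep(colnames(x$mat), each = nrow(x$mat)),
    log2_quantity = as.vector(x$mat)
  )
  long <- dplyr::filter(long, !is.na(.data$log2_quantity))
  dplyr::left_join(long, x$design[, c("sample_id", "genotype", "treatment", "group")],
                   by = "sample_id")[, c("protein_id", "sample_id", "genotype",
                                         "treatment", "group", "log2_quantity")]
}

#' @method glance quant_matrix
#' @export
glance.quant_matrix <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$mat),
    n_samples = ncol(x$mat),
    n_missing = sum(is.na(x$mat)),
    missing_fraction = mean(is.na(x$mat))
  )
}

#' Read / write a protein quantity TSV
#'
#' Plain-text exchange format for [quant_matrix()]: a TSV whose first
#' column is `protein_id` and remaining columns are one per sample,
#' holding log2 quantities with empty cells for missing values.
#' `write_quant_tsv()` then `read_quant_tsv()` round-trips losslessly.
#'
#' @param path File path.
#' @param design Design tibble whose `sample_id` set must match the
#'   sample columns of the file.
#' @return A [quant_matrix()].
#' @export
read_quant_tsv <- function(path, design) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(tab)[1] != "protein_id") {
    stop("first column of a quant TSV must be protein_id", call. = FALSE)
  }
  ids <- as.character(tab$protein_id)
  if (anyDuplicated(ids)) {
    stop("duplicated protein row: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- ids
  quant_matrix(mat, design)
}

#' @rdname read_quant_tsv
#' @param qm A [quant_matrix()].
#' @export
write_quant_tsv <- function(qm, path) {
  stopifnot(inherits(qm, "quant_matrix"))
  tab <- tibble::as_tibble(qm$mat)
  tab <- dplyr::bind_cols(tibble::tibble(protein_id = rownames(qm$mat)), tab)
  readr::write_tsv(tab, path)
  invisible(path)
}
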