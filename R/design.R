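#' TMTpro 16plex reporter channel names
#'
#' The sixteen reporter channels of a TMTpro 16plex labelling kit, in
#' mass order. Used as default channel labels throughout the package.
#'
#' @return Character vector of length 16.
#' @export
tmt16_channels <- function() {
  c("126", "127N", "127C", "128N", "128C", "129N", "129C", "130N",
    "130C", "131N", "131C", "132N", "132C", "133N", "133C", "134N")
}

.genotype_levels <- c("euploid", "trisomic")
.treatment_levels <- c("water", "fluoxetine")
.group_levels <- c("EW", "EF", "TW", "TF")

group_code <- function(genotype, treatment) {
  paste0(ifelse(genotype == "trisomic", "T", "E"),
         ifelse(treatment == "fluoxetine", "F", "W"))
}

#' Construct a balanced 2x2 factorial design
#'
#' Builds the sample sheet for a genotype-by-treatment factorial
#' experiment (euploid/trisomic crossed with water/fluoxetine) with
#' `n_per_group` biological replicates per cell, each replicate assigned
#' to one reporter channel. The four cells are coded EW, EF, TW, TF.
#'
#' @param n_per_group Replicates per design cell (default 4, the
#'   16-channel full-plex layout).
#' @param channels Reporter channel labels; defaults to the TMTpro
#'   16plex channels when `4 * n_per_group == 16`, otherwise
#'   `"ch01"..`.
#' @return A tibble with columns `sample_id`, `channel`, `genotype`,
#'   `treatment`, `group` — one row per sample.
#' @examples
#' design_2x2()
#' @export
design_2x2 <- function(n_per_group = 4, channels = NULL) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  n <- 4L * as.integer(n_per_group)
  if (is.null(channels)) {
    channels <- if (n == 16L) tmt16_channels() else sprintf("ch%02d", seq_len(n))
  }
  if (length(channels) != n) {
    stop("need ", n, " channels, got ", length(channels), call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    genotype = .genotype_levels,
    treatment = .treatment_levels,
    rep = seq_len(n_per_group)
  )
  tibble::tibble(
    sample_id = paste0(group_code(grid$genotype, grid$treatment), grid$rep),
    channel = channels,
    genotype = grid$genotype,
    treatment = grid$treatment,
    group = group_code(grid$genotype, grid$treatment)
  )
}

validate_design <- function(design) {
  need <- c("sample_id", "genotype", "treatment")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_g <- setdiff(unique(design$genotype), .genotype_levels)
  if (length(bad_g)) stop("unknown genotype level: ", paste(bad_g, collapse = ", "),
                          call. = FALSE)
  bad_t <- setdiff(unique(design$treatment), .treatment_levels)
  if (length(bad_t)) stop("unknown treatment level: ", paste(bad_t, collapse = ", "),
                          call. = FALSE)
  if (!("group" %in% names(design))) {
    design$group <- group_code(design$genotype, design$treatment)
  }
  empty <- setdiff(.group_levels, unique(design$group))
  if (length(empty)) stop("empty design cells: ", paste(empty, collapse = ", "),
                          call. = FALSE)
  design
}

#' Read / write a sample sheet
#'
#' The sample sheet is a CSV with one row per channel and columns
#' `sample_id`, `channel`, `genotype`, `treatment`. Factor levels are
#' validated (`genotype` in euploid/trisomic, `treatment` in
#' water/fluoxetine) and the derived `group` column (EW/EF/TW/TF) is
#' added.
#'
#' @param path File path.
#' @return `read_sample_sheet()` returns the validated design tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  validate_design(tibble::as_tibble(sheet))
}

#' @rdname read_sample_sheet
#' @param design A design tibble, e.g. from [design_2x2()].
#' @export
write_sample_sheet <- function(design, path) {
  readr::write_csv(design[, c("sample_id", "channel", "genotype", "treatment")],
                   path)
  invisible(path)
}
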