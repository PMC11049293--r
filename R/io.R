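#' Read / write gene sets in GMT format
#'
#' GMT is the tab-separated gene-set exchange format: one set per line
#' as `name TAB description TAB member1 TAB member2 ...`. Lines with
#' fewer than three fields or duplicated set names are errors naming
#' the offending line.
#'
#' @param path File path.
#' @return `read_gmt()` returns a gene-set tibble (`name`,
#'   `description`, `members` list column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1], ": fewer than 3 fields", call. = FALSE)
  }
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    stop("duplicate set name: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  tibble::tibble(
    name = nm,
    description = vapply(parts, `[[`, character(1), 2),
    members = lapply(parts, function(x) x[-(1:2)])
  )
}

#' @rdname read_gmt
#' @param collection Gene-set tibble.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(
    list(collection$name, collection$description, collection$members),
    function(n, d, m) paste(c(n, d, m), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a spectrum table TSV
#'
#' Columns: `spectrum_id`, `protein_ids` (semicolon-joined for shared
#' spectra), then one intensity column per channel.
#'
#' @param path File path.
#' @return A spectrum tibble.
#' @export
read_spectra_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("spectrum_id", "protein_ids")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("spectrum TSV lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tab$spectrum_id <- as.character(tab$spectrum_id)
  tab$protein_ids <- as.character(tab$protein_ids)
  tibble::as_tibble(tab)
}

#' @rdname read_spectra_tsv
#' @param spectra Spectrum tibble.
#' @export
write_spectra_tsv <- function(spectra, path) {
  readr::write_tsv(spectra, path)
  invisible(path)
}

#' Down syndrome risk-marker panel
#'
#' The default marker panel used by [marker_presence()]: eleven
#' trisomy-associated proteins whose presence in a synaptic proteome
#' indicates that the preparation captured the expected compartment.
#'
#' @return Character vector of protein symbols.
#' @export
ds_risk_markers <- function() {
  readLines(system.file("extdata", "ds_risk_markers.txt",
                        package = "tmtfactorial"))
}

#' Marker presence report
#'
#' Checks which of a panel of marker proteins are quantified in the
#' matrix and reports per-group mean log2 quantities for those present.
#'
#' @param qm A [quant_matrix()].
#' @param markers Character vector of protein identifiers; defaults to
#'   the eleven-protein trisomy risk panel.
#' @return Tibble: `marker`, `present`, and `mean_EW`/`mean_EF`/
#'   `mean_TW`/`mean_TF` (NA when absent).
#' @export
marker_presence <- function(qm, markers = ds_risk_markers()) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (!length(markers)) {
    return(tibble::tibble(marker = character(), present = logical(),
                          mean_EW = numeric(), mean_EF = numeric(),
                          mean_TW = numeric(), mean_TF = numeric()))
  }
  design <- qm$design
  purrr::map_dfr(markers, function(m) {
    present <- m %in% rownames(qm$mat)
    means <- rep(NA_real_, 4)
    names(means) <- .group_levels
    if (present) {
      for (g in .group_levels) {
        cols <- design$sample_id[design$group == g]
        means[g] <- mean(qm$mat[m, cols], na.rm = TRUE)
      }
    }
    tibble::tibble(marker = m, present = present,
                   mean_EW = means["EW"], mean_EF = means["EF"],
                   mean_TW = means["TW"], mean_TF = means["TF"])
  })
}

#' Direction concordance against expected regulation arrows
#'
#' Compares the signs of estimated log2 fold changes with an
#' expectation table of regulation directions (up/down arrows) for two
#' contrasts: trisomic-water vs euploid-water, and trisomic-fluoxetine
#' vs trisomic-water. Proteins absent from the contrast tables are
#' counted as untested.
#'
#' @param tw_vs_ew,tf_vs_tw Contrast tibbles (from [contrast_all()])
#'   with `protein_id` and `log2_fc`; fold changes oriented as
#'   second-named group minus first (TW - EW, TF - TW).
#' @param expectations Tibble with `protein_id`, `tw_vs_ew`,
#'   `tf_vs_tw`, each `"up"` or `"down"`; defaults to the packaged
#'   rescue-pattern table.
#' @return List: `per_protein` tibble with `concordant_tw_ew`,
#'   `concordant_tf_tw` (NA = untested), and `summary` tibble with the
#'   overall concordance fraction (`NA` when no protein testable).
#' @export
direction_concordance <- function(tw_vs_ew, tf_vs_tw,
                                  expectations = rescue_expectations()) {
  if (!nrow(expectations)) {
    return(list(per_protein = tibble::tibble(),
                summary = tibble::tibble(n_tested = 0L, n_untested = 0L,
                                         concordance = NA_real_)))
  }
  arrow_sign <- function(x) ifelse(x == "up", 1, -1)
  per <- expectations
  per$fc_tw_ew <- tw_vs_ew$log2_fc[match(per$protein_id, tw_vs_ew$protein_id)]
  per$fc_tf_tw <- tf_vs_tw$log2_fc[match(per$protein_id, tf_vs_tw$protein_id)]
  per$concordant_tw_ew <- sign(per$fc_tw_ew) == arrow_sign(per$tw_vs_ew)
  per$concordant_tf_tw <- sign(per$fc_tf_tw) == arrow_sign(per$tf_vs_tw)
  tested <- !is.na(per$concordant_tw_ew) & !is.na(per$concordant_tf_tw)
  conc <- if (any(tested)) {
    mean(c(per$concordant_tw_ew[tested], per$concordant_tf_tw[tested]))
  } else NA_real_
  list(per_protein = tibble::as_tibble(per),
       summary = tibble::tibble(n_tested = sum(tested),
                                n_untested = sum(!tested),
                                concordance = conc))
}

#' Expected regulation directions for rescue proteins
#'
#' The packaged expectation table of regulation arrows for proteins
#' reported as dysregulated in trisomic-water samples and rescued by
#' fluoxetine: `"down"`/`"up"` per contrast (TW vs EW, then TF vs TW).
#'
#' @return Tibble `protein_id`, `tw_vs_ew`, `tf_vs_tw`.
#' @export
rescue_expectations <- function() {
  readr::read_tsv(system.file("extdata", "rescue_expectations.tsv",
                              package = "tmtfactorial"),
                  show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' Write ground truth / stats bundles
#'
#' @param truth Ground-truth tibble.
#' @param path JSON output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, na = "null")
  invisible(path)
}
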