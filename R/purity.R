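#' Expand per-channel isotope impurities to a purity matrix
#'
#' Isobaric reporter labels carry isotopic impurities that shift a
#' fraction of each channel's signal into the channels -2, -1, +1 and +2
#' positions away (channels taken in mass order). This function expands
#' a per-channel impurity table into the square channel-by-channel
#' purity matrix `P` with columns = true channel and rows = observed
#' channel, so that `observed = P %*% true`. Signal leaking outside the
#' plex is lost, hence column sums may be below 1.
#'
#' @param impurities Data frame with columns `channel`, `minus2`,
#'   `minus1`, `plus1`, `plus2` (percentages, one row per channel in
#'   mass order).
#' @return Numeric matrix with dimnames = channels; class
#'   `purity_matrix`.
#' @seealso [impurity_correct()], [mix_impurities()]
#' @export
purity_matrix <- function(impurities) {
  need <- c("channel", "minus2", "minus1", "plus1", "plus2")
  miss <- setdiff(need, names(impurities))
  if (length(miss)) stop("impurity table lacks: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  ch <- as.character(impurities$channel)
  n <- length(ch)
  frac <- as.matrix(impurities[, c("minus2", "minus1", "plus1", "plus2")]) / 100
  if (any(frac < 0) || any(rowSums(frac) >= 1)) {
    stop("impurity percentages must be >= 0 and sum to < 100 per channel",
         call. = FALSE)
  }
  P <- matrix(0, n, n, dimnames = list(ch, ch))
  offsets <- c(-2L, -1L, 1L, 2L)
  for (j in seq_len(n)) {
    P[j, j] <- 1 - sum(frac[j, ])
    for (k in seq_along(offsets)) {
      i <- j + offsets[k]
      if (i >= 1 && i <= n) P[i, j] <- frac[j, k]
    }
  }
  structure(P, class = c("purity_matrix", "matrix", "array"))
}

#' @rdname purity_matrix
#' @param path CSV with the five impurity columns.
#' @export
read_purity_csv <- function(path) {
  purity_matrix(readr::read_csv(path, show_col_types = FALSE))
}

#' A synthetic TMTpro 16plex purity specification
#'
#' Plausible impurity percentages for a 16-channel kit, used by the
#' simulator and examples. These are synthetic values, not any vendor
#' lot's certificate.
#'
#' @return Impurity tibble suitable for [purity_matrix()].
#' @export
synthetic_impurities <- function() {
  ch <- tmt16_channels()
  n <- length(ch)
  tibble::tibble(
    channel = ch,
    minus2 = rep(0.2, n),
    minus1 = seq(0.5, 2.0, length.out = n),
    plus1 = seq(4.5, 1.5, length.out = n),
    plus2 = rep(0.3, n)
  )
}
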