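#' Build a ranked protein list
#'
#' Orders proteins by a ranking metric, descending. Two sources are
#' supported: the loadings of a chosen principal component
#' (`source = "pc_loading"`), or the signed significance metric
#' `-log10(p) * log2FC` of a group contrast (`source = "signed_logp"`,
#' computed with [pi_score()]). Ties are broken by protein identifier
#' so the order is deterministic; proteins with a missing metric are
#' excluded and counted in the `n_excluded` attribute.
#'
#' @param x A `pc_model` (for `pc_loading`) or a contrast tibble with
#'   `protein_id`, `log2_fc` and `p` columns (for `signed_logp`).
#' @param source Ranking source tag.
#' @param component Component index when ranking by loadings.
#' @return Tibble `protein_id`, `metric` in descending metric order,
#'   with attribute `source`.
#' @export
rank_proteins <- function(x, source = c("pc_loading", "signed_logp"),
                          component = 3) {
  source <- match.arg(source)
  if (source == "pc_loading") {
    stopifnot(inherits(x, "pc_model"))
    if (component > x$n_components) stop("component not retained", call. = FALSE)
    metric <- x$loadings[, component]
    out <- tibble::tibble(protein_id = rownames(x$loadings), metric = metric)
  } else {
    stopifnot(all(c("protein_id", "log2_fc", "p") %in% names(x)))
    out <- tibble::tibble(protein_id = x$protein_id,
                          metric = pi_score(x$log2_fc, pmax(x$p, 1e-300)))
  }
  n0 <- nrow(out)
  out <- out[is.finite(out$metric), , drop = FALSE]
  out <- out[order(-out$metric, out$protein_id), , drop = FALSE]
  attr(out, "source") <- source
  attr(out, "n_excluded") <- n0 - nrow(out)
  out
}

# ES for hits at (sorted) positions `pos` in a list of length N with
# |metric|^w weights `wts`. Extrema of the running sum occur just
# before and just after each hit, so only 2k candidates are scanned.
es_from_positions <- function(pos, wts, N) {
  k <- length(pos)
  miss_step <- 1 / (N - k)
  nr <- sum(wts)
  if (nr == 0) wts <- rep(1 / k, k) else wts <- wts / nr
  cum_hit <- cumsum(wts)
  after <- cum_hit - (pos - seq_len(k)) * miss_step
  before <- c(0, cum_hit[-k]) - (pos - 1 - (seq_len(k) - 1)) * miss_step
  cand <- as.vector(rbind(before, after))   # walk order
  # |max|-ties resolve to the earliest extremum along the walk
  cand[which(abs(cand) >= max(abs(cand)) - 1e-12)[1]]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic preranked GSEA running sum: walking down the ranked list,
#' hits increment by `|metric|^weight_exponent` (normalized over the
#' set's hits) and misses decrement by `1/(N - N_hits)`; the enrichment
#' score is the signed maximum deviation from zero.
#'
#' @param ranked Ranked tibble from [rank_proteins()] (or any tibble
#'   with `protein_id` and `metric` in rank order).
#' @param gene_set Character vector of protein identifiers.
#' @param weight_exponent Metric weight (0 = unweighted KS, 1 =
#'   classic weighted; default 1).
#' @return List: `es`, `running_sum` (length-N profile), `hits`
#'   (positions), `n_hits`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  N <- nrow(ranked)
  hit <- ranked$protein_id %in% gene_set
  k <- sum(hit)
  if (k == 0) stop("gene set does not intersect the ranked universe",
                   call. = FALSE)
  if (k == N) stop("gene set covers the whole universe", call. = FALSE)
  w <- abs(ranked$metric) ^ weight_exponent
  nr <- sum(w[hit])
  inc <- if (nr == 0) rep(1 / k, N) else w / nr
  steps <- ifelse(hit, inc, -1 / (N - k))
  rs <- cumsum(steps)
  es <- rs[which(abs(rs) >= max(abs(rs)) - 1e-12)[1]]
  list(es = es, running_sum = rs, hits = which(hit), n_hits = k)
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the weighted-KS enrichment score of every set, builds a
#' null distribution per set size from gene-label permutations (random
#' sets of matched size drawn from the ranked universe), normalizes the
#' ES by the mean absolute null ES of the same sign (NES), derives an
#' add-one permutation p-value from the same-sign null tail, and
#' adjusts p across sets by Benjamini-Hochberg. Results are ordered by
#' NES.
#'
#' @param ranked Ranked tibble from [rank_proteins()].
#' @param collection Gene-set tibble (`name`, `members` list column),
#'   e.g. from [simulate_gene_sets()] or [read_gmt()].
#' @param n_perm Number of permutations (>= 100).
#' @param weight_exponent Passed to the ES.
#' @param min_size Sets with fewer than this many members in the
#'   universe are skipped (reported in the `skipped` attribute).
#' @param seed Integer seed.
#' @return Tibble ordered by decreasing NES: `name`, `size`, `es`,
#'   `nes`, `p`, `q`, `leading_edge` (list column), `flag`.
#' @export
run_gsea <- function(ranked, collection, n_perm = 1000, weight_exponent = 1,
                     min_size = 5, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  set.seed(as.integer(seed))
  N <- nrow(ranked)
  ids <- ranked$protein_id
  w <- abs(ranked$metric) ^ weight_exponent

  sets <- purrr::map(collection$members, ~ intersect(.x, ids))
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes < N
  skipped <- collection$name[!keep]

  # shared null: per permutation draw positions for each distinct size
  distinct_sizes <- sort(unique(sizes[keep]))
  null_es <- purrr::map(distinct_sizes, function(k) {
    vapply(seq_len(n_perm), function(i) {
      pos <- sort(sample.int(N, k))
      es_from_positions(pos, w[pos], N)
    }, numeric(1))
  })
  names(null_es) <- as.character(distinct_sizes)

  rows <- purrr::map(which(keep), function(i) {
    hit <- ids %in% sets[[i]]
    pos <- which(hit)
    es <- es_from_positions(pos, w[pos], N)
    null_ <- null_es[[as.character(sizes[i])]]
    same <- null_[sign(null_) == sign(es)]
    flag <- "ok"
    if (length(same) == 0) {
      nes <- sign(es) * Inf
      p <- 1 / (n_perm + 1)
      flag <- "no_same_sign_null"
    } else {
      nes <- es / mean(abs(same))
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    }
    # leading edge: hits at or before the running-sum extremum
    prof <- enrichment_score(ranked, sets[[i]], weight_exponent)
    peak <- which(abs(prof$running_sum) >=
                    max(abs(prof$running_sum)) - 1e-12)[1]
    le <- if (es >= 0) ids[intersect(pos, seq_len(peak))] else
      ids[intersect(pos, seq(peak, N))]
    tibble::tibble(name = collection$name[i], size = sizes[i],
                   es = es, nes = nes, p = p,
                   leading_edge = list(le), flag = flag)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(-out$nes), c("name", "size", "es", "nes", "p", "q",
                                "leading_edge", "flag")]
  attr(out, "skipped") <- skipped
  out
}
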