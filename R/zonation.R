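#' Stress zonation: bin-mean scores, tissue-wide quantiles, composition
#'
#' Implements the zonation logic for spatial stress maps: cells are binned on
#' the 50-um grid, each bin's mean score over its resident cells is computed,
#' every cell inherits its bin's mean, quantile cut points are taken over all
#' cells pooled (across conditions), and each cell state's percentage
#' distribution over the quantiles is reported (Q1 low to Q4 high stress).
#'
#' Quantile intervals are left-closed with ties resolved into the lower
#' quantile: a cell's label is 1 + the number of cut points strictly below
#' its inherited score, so a degenerate all-equal score vector places every
#' cell in Q1.
#'
#' @param cells data frame with columns `cell_id, x, y, score, state`.
#' @param bin_size grid edge in um (default 50).
#' @param n_quantiles number of quantile zones (default 4).
#' @param min_bin_cells bins with fewer resident cells are dropped and their
#'   cells reported as unzoned (default 1 = keep all).
#' @param origin optional grid anchor, as in [bin_transcripts()].
#' @return object of class `zonation_result`: list with `cells` (input plus
#'   `bin_mean`, `quantile` where `NA` = unzoned), `cuts`, `bin_scores`
#'   (`ix, iy, mean_score, n_cells`), `composition` (state x quantile
#'   percentage matrix, rows summing to 100) and `n_unzoned`.
#' @export
quantile_zonation <- function(cells, bin_size = 50, n_quantiles = 4,
                              min_bin_cells = 1, origin = NULL) {
  if (n_quantiles < 2) .stopf("n_quantiles must be >= 2")
  need <- c("cell_id", "x", "y", "score", "state")
  if (!all(need %in% names(cells)))
    .stopf("cells must contain columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(cells$score))) .stopf("non-finite scores")
  if (is.null(origin)) {
    origin <- c(floor(min(cells$x) / bin_size) * bin_size,
                floor(min(cells$y) / bin_size) * bin_size)
  }
  ix <- floor((cells$x - origin[1]) / bin_size)
  iy <- floor((cells$y - origin[2]) / bin_size)
  key <- paste(ix, iy, sep = "_")
  bin_mean <- tapply(cells$score, key, mean)
  bin_n <- tapply(cells$score, key, length)
  cells$bin_mean <- as.numeric(bin_mean[key])
  zoned <- as.numeric(bin_n[key]) >= min_bin_cells

  cuts <- stats::quantile(cells$bin_mean[zoned],
                          probs = seq_len(n_quantiles - 1) / n_quantiles,
                          type = 7, names = FALSE)
  lab <- rep(NA_integer_, nrow(cells))
  lab[zoned] <- 1L + findInterval(cells$bin_mean[zoned], cuts,
                                  left.open = TRUE)
  cells$quantile <- lab

  ukey <- !duplicated(key)
  bin_scores <- data.frame(ix = ix[ukey], iy = iy[ukey],
                           mean_score = as.numeric(bin_mean[key[ukey]]),
                           n_cells = as.numeric(bin_n[key[ukey]]))

  st <- factor(cells$state[zoned])
  qf <- factor(lab[zoned], levels = seq_len(n_quantiles))
  tab <- table(st, qf)
  composition <- 100 * sweep(unclass(tab), 1, pmax(rowSums(tab), 1), "/")
  colnames(composition) <- paste0("Q", seq_len(n_quantiles))

  structure(list(cells = cells, cuts = cuts, bin_scores = bin_scores,
                 composition = composition, n_unzoned = sum(!zoned),
                 bin_size = bin_size, origin = origin),
            class = "zonation_result")
}

#' @export
print.zonation_result <- function(x, ...) {
  cat(sprintf("zonation_result: %d cells (%d unzoned), %d bins, %d states\n",
              nrow(x$cells), x$n_unzoned, nrow(x$bin_scores),
              nrow(x$composition)))
  invisible(x)
}

#' Write zonation outputs as TSV
#' @param zon a `zonation_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_zonation <- function(zon, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(zon$bin_scores, file.path(dir, "bin_scores.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  comp <- data.frame(state = rownames(zon$composition), zon$composition,
                     check.names = FALSE)
  utils::write.table(comp, file.path(dir, "zonation_composition.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
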