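#' Adipocyte areas from boundary pixel masks
#'
#' Area = pixel count x pixel area; centroid = mean of pixel centers. Objects
#' outside the open adipocyte gate (`area_min`, `area_max`) um2 are excluded
#' (an object of exactly 1,000 or 25,000 um2 is removed).
#'
#' @param cells a boundary-cell [segmented_object_set()].
#' @param pixel_area pixel area in um2 (default `pixel_size^2` of the set).
#' @param area_min,area_max open gate bounds in um2.
#' @return data frame of class `area_table`: `object_id, area, x, y`.
#' @export
compute_areas <- function(cells, pixel_area = NULL,
                          area_min = 1000, area_max = 25000) {
  stopifnot(inherits(cells, "segmented_object_set"))
  if (cells$kind != "boundary_cell") .stopf("boundary-cell object set required")
  if (is.null(pixel_area)) pixel_area <- cells$pixel_size^2
  if (pixel_area <= 0) .stopf("pixel_area must be > 0")
  ps <- sqrt(pixel_area)
  pix <- cells$pixels
  npx <- tapply(pix$px, pix$object_id, length)
  cx <- tapply((pix$px + 0.5) * ps, pix$object_id, mean)
  cy <- tapply((pix$py + 0.5) * ps, pix$object_id, mean)
  out <- data.frame(object_id = names(npx),
                    area = as.numeric(npx) * pixel_area,
                    x = as.numeric(cx), y = as.numeric(cy),
                    stringsAsFactors = FALSE)
  out <- out[out$area > area_min & out$area < area_max, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("area_table", "data.frame")
  out
}

#' Spearman correlation of gene expression with adipocyte area
#'
#' For every gene and stratum (each condition separately plus all conditions
#' combined), computes the Spearman correlation between per-cell normalized
#' expression and adipocyte area via [spearman_rho()]. A gene is selected
#' when its p-value falls below `selection_p` in at least `min_hits` of the
#' computed correlations (i.e. in more than one, by default). Selected genes
#' are ranked high-to-low by the combined-stratum correlation.
#'
#' @param mat a boundary-mode `cell_count_matrix` (per-cell proportions).
#' @param areas an `area_table`; matrix cells must be a subset of it.
#' @param strata optional per-cell condition labels (defaults to
#'   `mat$meta$condition`; a single stratum named `"all"` if absent).
#' @param selection_p selection p-value threshold (default 1e-5).
#' @param min_hits minimum number of sub-threshold correlations (default 2).
#' @param min_n strata with fewer cells are skipped with a warning (default 5).
#' @return data frame of class `size_correlation`: one row per gene x
#'   stratum with `gene, stratum, rho, p, n, selected, rank` (`rank` is a
#'   permutation of `1..n_selected` on combined-stratum rows, `NA`
#'   otherwise).
#' @export
gene_area_correlation <- function(mat, areas, strata = NULL,
                                  selection_p = 1e-5, min_hits = 2,
                                  min_n = 5) {
  stopifnot(inherits(mat, "cell_count_matrix"))
  if (!all(mat$cells %in% areas$object_id))
    .stopf("matrix contains cells without area measurements")
  area_of <- areas$area[match(mat$cells, areas$object_id)]
  if (is.null(strata)) {
    strata <- if (!is.null(mat$meta$condition)) mat$meta$condition
              else rep("all", length(mat$cells))
  }
  expr <- as.matrix(mat$normalized)
  stratum_sets <- c(
    stats::setNames(lapply(sort(unique(strata)), function(s) strata == s),
                    sort(unique(strata))),
    list(combined = rep(TRUE, length(strata))))
  if (length(stratum_sets) == 2 && names(stratum_sets)[1] == "all")
    stratum_sets <- stratum_sets["combined"]

  rows <- list()
  for (sn in names(stratum_sets)) {
    sel <- stratum_sets[[sn]]
    if (sum(sel) < min_n) {
      .warnf("skipping stratum '%s': n = %d < %d", sn, sum(sel), min_n)
      next
    }
    a <- area_of[sel]
    for (g in mat$genes) {
      e <- expr[sel, g]
      r <- spearman_rho(e, a)
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, stratum = sn,
        rho = r$rho, p = r$p, n = r$n, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  hits <- tapply(!is.na(res$p) & res$p < selection_p, res$gene, sum)
  res$selected <- as.logical(hits[res$gene] >= min_hits)

  res$rank <- NA_integer_
  comb <- res$stratum == "combined" & res$selected & !is.na(res$rho)
  if (any(comb)) {
    ord <- order(-res$rho[comb], res$gene[comb])
    res$rank[which(comb)[ord]] <- seq_len(sum(comb))
  }
  class(res) <- c("size_correlation", "data.frame")
  res
}
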