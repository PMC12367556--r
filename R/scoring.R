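#' Control-matched gene-set scoring
#'
#' Scores a gene set against expression-matched control genes, the scheme used
#' for metabolic, stress and senescence signatures: (1) each gene's mean
#' ln-normalized expression over all cells is computed; (2) all panel genes
#' are partitioned into `n_expression_bins` equal-frequency strata by that
#' mean; (3) for every target gene, `control_size` control genes are drawn
#' uniformly without replacement from its stratum (target genes excluded;
#' with replacement plus a warning when the stratum is too small); (4) the
#' per-cell score is the mean ln expression over target genes minus the mean
#' over the pooled control genes. Deterministic given `seed`.
#'
#' @param mat a `cell_count_matrix` with the `ln` layer.
#' @param gene_set character vector of target genes; genes absent from the
#'   panel are dropped with a warning.
#' @param control_size controls drawn per target gene (default 50).
#' @param n_expression_bins number of expression strata (default 25).
#' @param seed RNG seed for the control draw.
#' @return object of class `gene_set_score`: list with `score` (named
#'   per-cell vector), `gene_set`, `control_genes`, `control_size`,
#'   `n_expression_bins`, `seed`.
#' @export
score_gene_set <- function(mat, gene_set, control_size = 50,
                           n_expression_bins = 25, seed = 1L) {
  stopifnot(inherits(mat, "cell_count_matrix"))
  genes <- mat$genes
  missing <- setdiff(gene_set, genes)
  if (length(missing))
    .warnf("dropping %d gene(s) absent from the panel: %s", length(missing),
           paste(utils::head(missing, 5), collapse = ", "))
  targets <- intersect(gene_set, genes)
  if (length(targets) == 0) .stopf("gene set empty after intersection with panel")
  ln <- mat$ln
  gmean <- Matrix::colMeans(ln)
  nb <- min(n_expression_bins, length(genes))
  # average ranks keep genes with identical means in the same stratum
  stratum <- ceiling(nb * rank(gmean, ties.method = "average") / length(genes))
  stratum <- pmin(pmax(stratum, 1L), nb)
  names(stratum) <- genes

  controls <- with_seed(seed, {
    unlist(lapply(targets, function(g) {
      pool <- genes[stratum == stratum[g]]
      pool <- setdiff(pool, targets)
      if (length(pool) == 0) return(character(0))
      if (length(pool) < control_size) {
        .warnf("control pool for stratum of '%s' has %d genes (< %d); sampling with replacement",
               g, length(pool), control_size)
        sample(pool, control_size, replace = TRUE)
      } else {
        sample(pool, control_size)
      }
    }), use.names = FALSE)
  })
  controls <- unique(controls)
  t_mean <- Matrix::rowMeans(ln[, targets, drop = FALSE])
  c_mean <- if (length(controls) > 0)
    Matrix::rowMeans(ln[, controls, drop = FALSE]) else 0
  score <- as.numeric(t_mean - c_mean)
  names(score) <- mat$cells
  structure(list(score = score, gene_set = targets, control_genes = controls,
                 control_size = control_size,
                 n_expression_bins = n_expression_bins, seed = seed),
            class = "gene_set_score")
}

#' @export
print.gene_set_score <- function(x, ...) {
  cat(sprintf("gene_set_score: %d cells, %d target genes, %d control genes\n",
              length(x$score), length(x$gene_set), length(x$control_genes)))
  invisible(x)
}

#' Tissue stress map from bin-level gene-set scores
#'
#' Attaches a per-bin stress value to a [bin_transcripts()] grid. The default
#' transform is `log1p_clipped`: scores are clipped below at zero and mapped
#' through `log(1 + s)`, giving a non-negative "logged score" suitable for
#' tissue maps; `identity` keeps raw scores.
#'
#' @param score a `gene_set_score` computed on [bin_grid_as_matrix()] output
#'   (cell ids are bin keys `"ix_iy"`).
#' @param grid the `bin_grid` the score refers to.
#' @param transform `"log1p_clipped"` or `"identity"`.
#' @return the grid with a `stress` column added to `grid$bins` (`NA` for
#'   unscored bins) and attribute `stress_transform`.
#' @export
stress_map <- function(score, grid, transform = c("log1p_clipped", "identity")) {
  transform <- match.arg(transform)
  stopifnot(inherits(score, "gene_set_score"), inherits(grid, "bin_grid"))
  if (length(score$score) == 0) .stopf("no kept bins to map")
  val <- switch(transform,
                log1p_clipped = log1p(pmax(score$score, 0)),
                identity = score$score)
  key <- paste(grid$bins$ix, grid$bins$iy, sep = "_")
  grid$bins$stress <- val[match(key, names(score$score))]
  attr(grid, "stress_transform") <- transform
  grid
}

#' Marker-positivity fractions with rank-test comparisons
#'
#' A cell is positive when its raw count for `gene` is at least
#' `threshold_counts`. Fractions are computed per sample within each group
#' (e.g. condition), then compared by two-sided Wilcoxon tests: rank-sum for
#' unpaired group pairs, signed-rank for pairs listed in `paired`, with
#' Benjamini-Hochberg adjustment across the reported comparisons.
#'
#' @param mat a `cell_count_matrix`; `mat$meta` must contain `sample` and the
#'   `group` column.
#' @param gene marker gene (e.g. CDKN1A / p21).
#' @param threshold_counts minimum raw count for positivity (default 1).
#' @param group name of the grouping column in `mat$meta` (default
#'   `"condition"`).
#' @param paired list of group pairs to compare with the paired signed-rank
#'   test; samples are matched by the `donor` metadata column.
#' @return object of class `positivity_result`: list with `positive`
#'   (per-cell logical), `fractions` (sample x group data frame) and
#'   `comparisons` (group pair, test, p, p_adj).
#' @export
call_positive_fraction <- function(mat, gene, threshold_counts = 1,
                                   group = "condition", paired = list()) {
  stopifnot(inherits(mat, "cell_count_matrix"))
  if (!gene %in% mat$genes) .stopf("gene absent from panel: %s", gene)
  if (is.null(mat$meta) || !all(c("sample", group) %in% names(mat$meta)))
    .stopf("metadata must contain 'sample' and '%s'", group)
  pos <- as.numeric(mat$counts[, gene]) >= threshold_counts
  md <- mat$meta
  frac <- stats::aggregate(pos, by = list(sample = md$sample,
                                          group = md[[group]]), FUN = mean)
  names(frac)[3] <- "fraction"
  if (!is.null(md$donor))
    frac$donor <- md$donor[match(frac$sample, md$sample)]

  groups <- unique(frac$group)
  pairs <- if (length(groups) >= 2)
    utils::combn(sort(as.character(groups)), 2, simplify = FALSE) else list()
  comp <- list()
  for (pr in pairs) {
    a <- frac[frac$group == pr[1], ]
    b <- frac[frac$group == pr[2], ]
    if (nrow(a) < 2 || nrow(b) < 2) {
      .warnf("skipping %s-%s: fewer than 2 samples in a group", pr[1], pr[2])
      next
    }
    is_paired <- any(vapply(paired, function(p) setequal(p, pr), logical(1)))
    if (is_paired) {
      if (is.null(frac$donor)) .stopf("paired comparison requires a 'donor' column")
      shared <- intersect(a$donor, b$donor)
      av <- a$fraction[match(shared, a$donor)]
      bv <- b$fraction[match(shared, b$donor)]
      p <- suppressWarnings(stats::wilcox.test(av, bv, paired = TRUE)$p.value)
    } else {
      p <- suppressWarnings(stats::wilcox.test(a$fraction, b$fraction)$p.value)
    }
    comp[[length(comp) + 1]] <- data.frame(
      group_a = pr[1], group_b = pr[2],
      test = if (is_paired) "wilcoxon_paired" else "wilcoxon_unpaired",
      p = p, stringsAsFactors = FALSE)
  }
  comparisons <- if (length(comp)) do.call(rbind, comp) else
    data.frame(group_a = character(0), group_b = character(0),
               test = character(0), p = numeric(0))
  comparisons$p_adj <- if (nrow(comparisons)) bh_adjust(comparisons$p) else numeric(0)
  structure(list(positive = stats::setNames(pos, mat$cells),
                 fractions = frac, comparisons = comparisons,
                 gene = gene, threshold_counts = threshold_counts),
            class = "positivity_result")
}
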