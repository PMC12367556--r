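#' Read a transcript table in the Xenium CSV dialect
#'
#' Required columns: `transcript_id`, `feature_name`, `x_location`,
#' `y_location`, `qv`. Optional columns (`cell_id`, `overlaps_nucleus`,
#' `z_location`) are carried through when present. Column names are
#' standardised to `transcript_id, gene, x, y, qv`.
#'
#' @param path CSV file.
#' @return data frame of class `transcript_table`.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) .stopf("transcript file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("transcript_id", "feature_name", "x_location", "y_location", "qv")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    .stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad))
      .stopf("non-numeric value in column '%s' at row %d", col, bad[1])
    v
  }
  out <- data.frame(transcript_id = raw$transcript_id,
                    gene = raw$feature_name,
                    x = num("x_location"), y = num("y_location"),
                    qv = num("qv"), stringsAsFactors = FALSE)
  if ("cell_id" %in% names(raw)) out$cell_id <- raw$cell_id
  if ("overlaps_nucleus" %in% names(raw))
    out$overlaps_nucleus <- as.integer(raw$overlaps_nucleus)
  if (any(!is.finite(out$x)) || any(!is.finite(out$y)))
    .stopf("non-finite coordinates in transcript table")
  if (any(out$gene == "")) .stopf("empty gene name in transcript table")
  class(out) <- c("transcript_table", "data.frame")
  out
}

#' Filter transcripts by decoding quality
#'
#' Keeps transcripts whose quality value is strictly greater than the
#' threshold (a QV of exactly 35 is removed at the default threshold),
#' preserving input order. The number removed is recorded in the
#' `filter_log` attribute.
#'
#' @param transcripts a `transcript_table`.
#' @param qv_threshold quality cutoff (default 35).
#' @return filtered `transcript_table` with attribute
#'   `filter_log = list(n_in, n_removed, qv_threshold)`.
#' @export
filter_transcripts <- function(transcripts, qv_threshold = 35) {
  keep <- transcripts$qv > qv_threshold
  out <- transcripts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- list(n_in = nrow(transcripts),
                                  n_removed = sum(!keep),
                                  qv_threshold = qv_threshold)
  class(out) <- c("transcript_table", "data.frame")
  out
}

#' @rdname filter_transcripts
#' @param path CSV file in the Xenium dialect.
#' @export
load_and_filter_transcripts <- function(path, qv_threshold = 35) {
  filter_transcripts(read_transcripts(path), qv_threshold)
}

#' Segmentation-free binning of transcripts onto a square grid
#'
#' Tessellates the field into `bin_size`-um half-open square bins
#' `[x0 + i s, x0 + (i+1) s) x [y0 + j s, y0 + (j+1) s)` and counts
#' transcripts per bin and per gene. Bins containing strictly more than
#' `min_count` transcripts are flagged `kept`. The grid origin defaults to
#' the minimum retained coordinate floored to a multiple of `bin_size`, which
#' makes the tessellation deterministic and shift-stable per sample.
#'
#' @param transcripts a (filtered) `transcript_table`.
#' @param bin_size bin edge in um (default 50).
#' @param min_count minimum transcripts per kept bin (strict; default 10).
#' @param origin optional `c(x0, y0)` grid anchor.
#' @return object of class `bin_grid`: list with `origin`, `bin_size`,
#'   `bins` (data frame `ix, iy, x_center, y_center, total, kept`), sparse
#'   `counts` (bins x genes) and `genes`.
#' @export
bin_transcripts <- function(transcripts, bin_size = 50, min_count = 10,
                            origin = NULL) {
  if (bin_size <= 0) .stopf("bin_size must be > 0")
  n <- nrow(transcripts)
  if (is.null(origin)) {
    origin <- if (n == 0) c(0, 0) else
      c(floor(min(transcripts$x) / bin_size) * bin_size,
        floor(min(transcripts$y) / bin_size) * bin_size)
  }
  ix <- floor((transcripts$x - origin[1]) / bin_size)
  iy <- floor((transcripts$y - origin[2]) / bin_size)
  key <- paste(ix, iy, sep = "_")
  ukey <- unique(key)
  bi <- match(key, ukey)
  genes <- sort(unique(transcripts$gene))
  if (n > 0) {
    counts <- Matrix::sparseMatrix(i = bi, j = match(transcripts$gene, genes),
                                   x = 1,
                                   dims = c(length(ukey), length(genes)),
                                   dimnames = list(ukey, genes))
  } else {
    counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(0, 0))
  }
  first <- match(ukey, key)
  bins <- data.frame(
    ix = ix[first], iy = iy[first],
    total = if (n > 0) as.numeric(Matrix::rowSums(counts)) else numeric(0),
    stringsAsFactors = FALSE
  )
  bins$x_center <- origin[1] + (bins$ix + 0.5) * bin_size
  bins$y_center <- origin[2] + (bins$iy + 0.5) * bin_size
  bins$kept <- bins$total > min_count
  bins <- bins[, c("ix", "iy", "x_center", "y_center", "total", "kept")]
  structure(list(origin = origin, bin_size = bin_size, min_count = min_count,
                 bins = bins, counts = counts, genes = genes),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d bins of %g um (%d kept), %d genes\n",
              nrow(x$bins), x$bin_size, sum(x$bins$kept), length(x$genes)))
  invisible(x)
}

#' Write a bin grid as TSV
#'
#' One row per bin: indices, centers, total, kept flag, then one column per
#' requested gene.
#'
#' @param grid a `bin_grid`.
#' @param path output file.
#' @param genes optional gene columns to append (e.g. `c("AREG", "CXCL2")`).
#' @return `path`, invisibly.
#' @export
write_bin_grid <- function(grid, path, genes = NULL) {
  out <- grid$bins
  for (g in genes) {
    if (!g %in% grid$genes) .stopf("gene not present in grid: %s", g)
    out[[g]] <- as.numeric(grid$counts[, g])
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a bin grid into a count-matrix object for gene-set scoring
#'
#' Kept bins become the "cells" of a [build_count_matrix()]-style container
#' so that bin-level gene-set scores (tissue stress maps) reuse the cell-level
#' scoring machinery.
#'
#' @param grid a `bin_grid`.
#' @param normalize_target per-bin total after normalization (default 1,
#'   i.e. proportions).
#' @param kept_only score only bins that passed the transcript-count gate.
#' @return a `cell_count_matrix` whose cells are bin keys `"ix_iy"`.
#' @export
bin_grid_as_matrix <- function(grid, normalize_target = 1, kept_only = TRUE) {
  sel <- if (kept_only) grid$bins$kept else rep(TRUE, nrow(grid$bins))
  if (!any(sel)) .stopf("no kept bins")
  counts <- grid$counts[sel, , drop = FALSE]
  totals <- Matrix::rowSums(counts)
  sf <- ifelse(totals > 0, normalize_target / totals, 0)
  normalized <- methods::as(Matrix::Diagonal(x = sf) %*% counts, "CsparseMatrix")
  dimnames(normalized) <- dimnames(counts)
  ln <- normalized
  ln@x <- log1p(ln@x)
  structure(list(counts = counts, normalized = normalized, ln = ln,
                 cells = rownames(counts), genes = colnames(counts),
                 meta = data.frame(cell_id = rownames(counts),
                                   total = as.numeric(totals),
                                   ix = grid$bins$ix[sel],
                                   iy = grid$bins$iy[sel],
                                   stringsAsFactors = FALSE),
                 min_transcripts = grid$min_count,
                 normalize_target = normalize_target),
            class = "cell_count_matrix")
}
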