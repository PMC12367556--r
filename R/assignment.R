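#' Container for segmented objects (nuclei or boundary-segmented cells)
#'
#' @param ids character object identifiers (unique).
#' @param kind `"nucleus"` or `"boundary_cell"`.
#' @param centroids two-column matrix of centroid coordinates (um).
#' @param polygons optional list of two-column vertex matrices (nuclei).
#' @param pixels data frame `object_id, px, py` of integer pixel indices
#'   (boundary cells); pixel i covers
#'   `[px * pixel_size, (px + 1) * pixel_size)` and its point coordinate is
#'   the pixel center.
#' @param pixel_size pixel edge length in um (required with `pixels`).
#' @return object of class `segmented_object_set`; boundary sets carry
#'   `areas` = pixel count x pixel area (um2).
#' @export
segmented_object_set <- function(ids, kind = c("nucleus", "boundary_cell"),
                                 centroids, polygons = NULL, pixels = NULL,
                                 pixel_size = NULL) {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) .stopf("object ids must be unique")
  centroids <- matrix(as.numeric(centroids), ncol = 2,
                      dimnames = list(NULL, c("x", "y")))
  if (nrow(centroids) != length(ids)) .stopf("one centroid per object required")
  areas <- NULL
  if (kind == "boundary_cell") {
    if (is.null(pixels)) .stopf("boundary cells require a pixel table")
    if (is.null(pixel_size) || pixel_size <= 0)
      .stopf("pixel size not set (must be > 0)")
    pixels$object_id <- as.character(pixels$object_id)
    if (length(ids)) {
      npx <- table(factor(pixels$object_id, levels = ids))
      if (any(npx == 0)) .stopf("pixel lists must be non-empty for every object")
      areas <- as.numeric(npx) * pixel_size^2
    } else {
      areas <- numeric(0)
    }
  }
  structure(list(ids = ids, kind = kind, centroids = centroids,
                 polygons = polygons, pixels = pixels,
                 pixel_size = pixel_size, areas = areas),
            class = "segmented_object_set")
}

#' @export
print.segmented_object_set <- function(x, ...) {
  cat(sprintf("segmented_object_set: %d %s objects\n", length(x$ids), x$kind))
  invisible(x)
}

# Bucketed candidate pairs between points and objects with per-object reach.
# Returns a data.table (pi = point row, oi = object row).
.candidate_pairs <- function(x, y, ox, oy, reach, max_dist) {
  B <- max(2 * (max(reach, 0) + max_dist), 10)
  pts <- data.table::data.table(pi = seq_along(x),
                                bx = floor(x / B), by = floor(y / B))
  off <- data.table::CJ(dx = -1:1, dy = -1:1)
  obj <- data.table::data.table(oi = seq_along(ox),
                                obx = floor(ox / B), oby = floor(oy / B))
  obj <- obj[, {
    data.table::data.table(oi = rep(oi, each = 9),
                           bx = rep(obx, each = 9) + rep(off$dx, length(oi)),
                           by = rep(oby, each = 9) + rep(off$dy, length(oi)))
  }]
  data.table::setkey(obj, bx, by)
  data.table::setkey(pts, bx, by)
  m <- obj[pts, on = c("bx", "by"), nomatch = NULL, allow.cartesian = TRUE]
  m[, c("bx", "by") := NULL]
  m
}

#' Assign transcripts to the nearest nucleus within a distance cutoff
#'
#' Each transcript is assigned to the single nearest nucleus whose geometry
#' (polygon when available, else centroid) lies within `max_dist` um — the
#' nucleus-segmentation quantification mode. Distance is 0 for transcripts
#' inside a nucleus polygon; "within" is read inclusively (distance
#' `<= max_dist`). Ties are broken toward the lexicographically smaller object
#' id. Transcripts with no nucleus in range are left unassigned. A bucketed
#' spatial index accelerates the search; results are identical to the
#' all-pairs scan.
#'
#' @param transcripts a transcript table (see [read_transcripts()]).
#' @param nuclei a nucleus [segmented_object_set()].
#' @param max_dist assignment radius in um (default 2).
#' @return data frame of class `assignment_table`:
#'   `transcript_id, object_id, distance, mode`, plus an attribute
#'   `distance_convention` (`"polygon"` or `"centroid"`).
#' @export
assign_to_nuclei <- function(transcripts, nuclei, max_dist = 2) {
  stopifnot(inherits(nuclei, "segmented_object_set"))
  if (max_dist < 0) .stopf("max_dist must be >= 0")
  tx <- transcripts$x; ty <- transcripts$y
  empty <- data.frame(transcript_id = character(0), object_id = character(0),
                      distance = numeric(0), mode = character(0),
                      stringsAsFactors = FALSE)
  use_poly <- !is.null(nuclei$polygons)
  if (length(nuclei$ids) == 0 || length(tx) == 0) {
    return(structure(empty, class = c("assignment_table", "data.frame"),
                     distance_convention = if (use_poly) "polygon" else "centroid"))
  }
  reach <- if (use_poly) {
    max(vapply(seq_along(nuclei$ids), function(i) {
      p <- nuclei$polygons[[i]]
      sqrt(max((p[, 1] - nuclei$centroids[i, 1])^2 +
                 (p[, 2] - nuclei$centroids[i, 2])^2))
    }, numeric(1)))
  } else 0
  cand <- .candidate_pairs(tx, ty, nuclei$centroids[, 1], nuclei$centroids[, 2],
                           reach, max_dist)
  # centroid prefilter, then exact geometry distance per nucleus
  cand[, d_cent := sqrt((tx[pi] - nuclei$centroids[oi, 1])^2 +
                          (ty[pi] - nuclei$centroids[oi, 2])^2)]
  cand <- cand[d_cent <= reach + max_dist + 1e-9]
  if (nrow(cand) == 0) {
    return(structure(empty, class = c("assignment_table", "data.frame"),
                     distance_convention = if (use_poly) "polygon" else "centroid"))
  }
  if (use_poly) {
    cand[, dist := {
      p <- nuclei$polygons[[oi[1]]]
      dist_points_polygon(tx[pi], ty[pi], p[, 1], p[, 2])
    }, by = oi]
  } else {
    cand[, dist := d_cent]
  }
  cand <- cand[dist <= max_dist + 1e-12]
  if (nrow(cand) == 0) {
    return(structure(empty, class = c("assignment_table", "data.frame"),
                     distance_convention = if (use_poly) "polygon" else "centroid"))
  }
  cand[, object_id := nuclei$ids[oi]]
  data.table::setorder(cand, pi, dist, object_id)
  best <- cand[, .SD[1], by = pi]
  out <- data.frame(transcript_id = transcripts$transcript_id[best$pi],
                    object_id = best$object_id,
                    distance = best$dist,
                    mode = "nucleus", stringsAsFactors = FALSE)
  structure(out, class = c("assignment_table", "data.frame"),
            distance_convention = if (use_poly) "polygon" else "centroid")
}

#' Assign transcripts to boundary-segmented adipocytes
#'
#' The boundary-segmentation quantification mode: objects outside the
#' adipocyte area gate (strictly greater than `area_min` and strictly less
#' than `area_max` um2) are removed first, as are transcripts listed in
#' `exclude` (transcripts already captured by non-adipocyte nuclei). A
#' transcript whose containing pixel belongs to an object's footprint is
#' assigned to that object at distance 0; otherwise it is assigned to every
#' object whose nearest pixel center lies within `max_dist` um
#' (multi-assignment on cell boundaries is deliberate).
#'
#' @param transcripts transcript table.
#' @param cells boundary-cell [segmented_object_set()].
#' @param max_dist assignment radius in um (default 2).
#' @param exclude optional `assignment_table` of transcripts to drop before
#'   assignment (pass the nucleus-mode assignments to non-adipocyte objects).
#' @param area_min,area_max adipocyte area gate in um2 (strict inequalities).
#' @return `assignment_table` data frame (possibly several rows per
#'   transcript).
#' @export
assign_to_boundaries <- function(transcripts, cells, max_dist = 2,
                                 exclude = NULL,
                                 area_min = 1000, area_max = 25000) {
  stopifnot(inherits(cells, "segmented_object_set"))
  if (cells$kind != "boundary_cell") .stopf("boundary-cell object set required")
  if (is.null(cells$pixel_size)) .stopf("pixel size not set")
  if (max_dist < 0) .stopf("max_dist must be >= 0")

  keep_ids <- cells$ids[cells$areas > area_min & cells$areas < area_max]
  tr <- transcripts
  if (!is.null(exclude) && nrow(exclude) > 0) {
    tr <- tr[!(tr$transcript_id %in% exclude$transcript_id), , drop = FALSE]
  }
  empty <- structure(
    data.frame(transcript_id = character(0), object_id = character(0),
               distance = numeric(0), mode = character(0),
               stringsAsFactors = FALSE),
    class = c("assignment_table", "data.frame"))
  if (length(keep_ids) == 0 || nrow(tr) == 0) return(empty)

  ps <- cells$pixel_size
  pix <- data.table::as.data.table(cells$pixels)
  pix <- pix[object_id %in% keep_ids]
  txd <- data.table::data.table(ti = seq_len(nrow(tr)), x = tr$x, y = tr$y)

  # containment: the pixel holding the transcript belongs to the footprint
  txd[, `:=`(px = floor(x / ps), py = floor(y / ps))]
  inside <- pix[txd, on = c("px", "py"), nomatch = NULL, allow.cartesian = TRUE]
  inside_tab <- inside[, .(ti, object_id, dist = 0)]

  # proximity: nearest pixel center within max_dist, all such objects.
  # Only footprint-perimeter pixels can be nearest to an outside point
  # (an interior pixel always has a 4-neighbor strictly closer), so the
  # search is restricted to them; containment above covers inside points.
  has_nb <- rep(TRUE, nrow(pix))
  for (sh in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    shifted <- pix[, .(object_id, px = px + sh[1], py = py + sh[2])]
    has_nb <- has_nb & !is.na(
      shifted[pix, on = c("object_id", "px", "py"), which = TRUE])
  }
  perim <- pix[!has_nb]
  B <- max(4 * ps, 2 * max_dist, 8)
  txd[, `:=`(bx = floor(x / B), by = floor(y / B))]
  pix <- perim
  pix[, `:=`(cx = (px + 0.5) * ps, cy = (py + 0.5) * ps)]
  pix[, `:=`(bx = floor(cx / B), by = floor(cy / B))]
  off <- data.table::CJ(dx = -1:1, dy = -1:1)
  cand <- off[, {
    p2 <- data.table::copy(txd)[, `:=`(bx = bx + dx, by = by + dy)]
    pix[p2, on = c("bx", "by"), nomatch = NULL, allow.cartesian = TRUE,
        .(ti, object_id, d2 = (cx - i.x)^2 + (cy - i.y)^2)]
  }, by = .(dx, dy)]
  cand <- cand[d2 <= (max_dist + 1e-12)^2]
  near_tab <- cand[, .(dist = sqrt(min(d2))), by = .(ti, object_id)]

  inside_ti <- unique(inside_tab$ti)
  near_tab <- near_tab[!(ti %in% inside_ti)]
  res <- rbind(inside_tab[, .(ti, object_id, dist)],
               near_tab[, .(ti, object_id, dist)])
  res <- unique(res, by = c("ti", "object_id"))
  data.table::setorder(res, ti, dist, object_id)
  out <- data.frame(transcript_id = tr$transcript_id[res$ti],
                    object_id = res$object_id,
                    distance = res$dist,
                    mode = "boundary", stringsAsFactors = FALSE)
  structure(out, class = c("assignment_table", "data.frame"))
}

#' Build a cell x gene count matrix from a transcript assignment
#'
#' Multi-assigned transcripts contribute a full count to every assigned
#' object. Cells with total counts less than or equal to `min_transcripts`
#' are removed (more than 40 transcripts are required in nucleus mode;
#' boundary mode keeps everything by default). Two derived layers are
#' populated: `normalized` (per-cell counts rescaled to `normalize_target`
#' total) and `ln` (natural log of 1 + normalized).
#'
#' @param assign an `assignment_table`.
#' @param transcripts the transcript table the assignment refers to.
#' @param min_transcripts minimum per-cell total (strict; default 40).
#' @param normalize_target per-cell total after normalization (default
#'   10000, the single-nucleus convention; use 1 for per-cell proportions in
#'   boundary mode).
#' @param genes optional gene universe (defaults to genes present in
#'   `transcripts`); assigned transcripts with genes outside it are an error.
#' @param meta optional per-cell metadata data frame with a `cell_id` column
#'   (state, sample, condition, area ...), joined onto the kept cells.
#' @return object of class `cell_count_matrix`: list with sparse `counts`,
#'   dense-on-demand `normalized` and `ln` layers (dgCMatrix), `cells`,
#'   `genes`, `meta` and the filter parameters.
#' @export
build_count_matrix <- function(assign, transcripts, min_transcripts = 40,
                               normalize_target = 1e4, genes = NULL,
                               meta = NULL) {
  if (min_transcripts < 0) .stopf("min_transcripts must be >= 0")
  if (normalize_target <= 0) .stopf("normalize_target must be > 0")
  if (is.null(genes)) genes <- sort(unique(transcripts$gene))
  gene_of <- transcripts$gene[match(assign$transcript_id,
                                    transcripts$transcript_id)]
  if (anyNA(gene_of)) .stopf("assignment refers to unknown transcripts")
  if (!all(gene_of %in% genes))
    .stopf("gene absent from panel: %s",
           paste(utils::head(setdiff(gene_of, genes), 3), collapse = ", "))
  cells <- sort(unique(assign$object_id))
  if (length(cells) == 0) {
    .warnf("all cells filtered: empty count matrix")
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(0, length(genes)),
                              dimnames = list(NULL, genes))
    return(structure(list(counts = m, normalized = m, ln = m,
                          cells = character(0), genes = genes,
                          meta = NULL, min_transcripts = min_transcripts,
                          normalize_target = normalize_target),
                     class = "cell_count_matrix"))
  }
  i <- match(assign$object_id, cells)
  j <- match(gene_of, genes)
  counts <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                 dims = c(length(cells), length(genes)),
                                 dimnames = list(cells, genes))
  totals <- Matrix::rowSums(counts)
  keep <- totals > min_transcripts
  if (!any(keep)) .warnf("all cells filtered: empty count matrix")
  counts <- counts[keep, , drop = FALSE]
  totals <- totals[keep]
  sf <- ifelse(totals > 0, normalize_target / totals, 0)
  normalized <- Matrix::Diagonal(x = sf) %*% counts
  normalized <- methods::as(normalized, "CsparseMatrix")
  dimnames(normalized) <- dimnames(counts)
  ln <- normalized
  ln@x <- log1p(ln@x)
  md <- data.frame(cell_id = rownames(counts), total = totals,
                   stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    md <- merge(md, meta, by = "cell_id", all.x = TRUE, sort = FALSE)
    md <- md[match(rownames(counts), md$cell_id), , drop = FALSE]
    rownames(md) <- NULL
  }
  structure(list(counts = counts, normalized = normalized, ln = ln,
                 cells = rownames(counts), genes = genes, meta = md,
                 min_transcripts = min_transcripts,
                 normalize_target = normalize_target),
            class = "cell_count_matrix")
}

#' @export
print.cell_count_matrix <- function(x, ...) {
  cat(sprintf("cell_count_matrix: %d cells x %d genes (target total %g)\n",
              length(x$cells), length(x$genes), x$normalize_target))
  invisible(x)
}

#' Write a count matrix as Matrix Market with sidecars
#'
#' Emits `matrix.mtx` (genes x cells, integer counts), `features.tsv` and
#' `barcodes.tsv` in the conventional layout, plus `metadata.tsv`.
#'
#' @param mat a `cell_count_matrix`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(mat, dir) {
  stopifnot(inherits(mat, "cell_count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::t(mat$counts), file.path(dir, "matrix.mtx"))
  writeLines(mat$genes, file.path(dir, "features.tsv"))
  writeLines(mat$cells, file.path(dir, "barcodes.tsv"))
  if (!is.null(mat$meta))
    utils::write.table(mat$meta, file.path(dir, "metadata.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write an assignment table as TSV
#' @param assign an `assignment_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assign, path) {
  utils::write.table(assign, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
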