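#' Neighborhood composition within a radius
#'
#' For every cell, counts the neighboring cells (distance strictly positive
#' and at most `radius`, self excluded) of each cell state within the same
#' sample, then expresses each cell as the percentage of neighbors in each
#' state. This percentage normalization removes the cell-density bias between
#' lean and obese tissue (lean fields hold roughly twice the neighbors within
#' 300 um) so that niche clustering reflects composition, not density.
#'
#' @param cells data frame with `cell_id, x, y, state` and optionally
#'   `sample` (neighbor search is restricted within sample).
#' @param radius neighborhood radius in um (default 300, chosen to span
#'   adipocytes).
#' @return object of class `neighborhood_matrix`: list with `pct` (cells x
#'   states percentage matrix; rows with neighbors sum to 100),
#'   `n_neighbors`, `states`, `cells` and `radius`. Zero-neighbor rows are
#'   flagged via `n_neighbors == 0` and hold zeros.
#' @export
neighborhood_composition <- function(cells, radius = 300) {
  if (radius <= 0) .stopf("radius must be > 0")
  need <- c("cell_id", "x", "y", "state")
  if (!all(need %in% names(cells)))
    .stopf("cells must contain columns: %s", paste(need, collapse = ", "))
  if (is.null(cells$sample)) cells$sample <- "s1"
  states <- sort(unique(cells$state))
  n <- nrow(cells)
  counts <- matrix(0, n, length(states), dimnames = list(cells$cell_id, states))
  onehot <- outer(cells$state, states, `==`) * 1
  for (s in unique(cells$sample)) {
    idx <- which(cells$sample == s)
    xs <- cells$x[idx]; ys <- cells$y[idx]
    block <- 512L
    for (b0 in seq(1, length(idx), by = block)) {
      b <- b0:min(b0 + block - 1L, length(idx))
      d2 <- outer(xs[b], xs, `-`)^2 + outer(ys[b], ys, `-`)^2
      adj <- d2 <= radius^2
      adj[cbind(seq_along(b), b)] <- FALSE  # self-exclusion
      counts[idx[b], ] <- adj %*% onehot[idx, , drop = FALSE]
    }
  }
  nn <- rowSums(counts)
  pct <- 100 * counts / pmax(nn, 1)
  structure(list(pct = pct, n_neighbors = nn, states = states,
                 cells = cells, radius = radius),
            class = "neighborhood_matrix")
}

#' @export
print.neighborhood_matrix <- function(x, ...) {
  cat(sprintf("neighborhood_matrix: %d cells x %d states (radius %g um, %d zero-neighbor)\n",
              nrow(x$pct), length(x$states), x$radius, sum(x$n_neighbors == 0)))
  invisible(x)
}

# k nearest neighbors on rows of X by Euclidean distance (brute force in
# blocks); returns an edge list matrix.
.knn_edges <- function(X, k) {
  n <- nrow(X)
  k <- min(k, n - 1)
  sq <- rowSums(X^2)
  edges <- matrix(0L, n * k, 2)
  block <- 512L
  pos <- 0L
  for (b0 in seq(1, n, by = block)) {
    b <- b0:min(b0 + block - 1L, n)
    d2 <- outer(sq[b], sq, `+`) - 2 * X[b, , drop = FALSE] %*% t(X)
    d2[cbind(seq_along(b), b)] <- Inf
    nb <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
    edges[pos + seq_len(length(b) * k), ] <-
      cbind(rep(b, each = k), as.integer(t(nb)))
    pos <- pos + length(b) * k
  }
  edges
}

#' Cluster cells into niches from neighborhood compositions
#'
#' Builds a k-nearest-neighbor graph on the composition vectors (optionally
#' centered per sample to absorb batch shifts), runs Leiden community
#' detection at the given resolution, then iteratively merges cluster pairs
#' whose mean composition vectors lie within `merge_tau` Jensen-Shannon
#' distance — absorbing near-duplicate clusters driven by small fluctuations —
#' and logs every merge. Zero-neighbor cells are excluded from clustering.
#'
#' @param neigh a `neighborhood_matrix`.
#' @param k_neighbors graph degree (default 45; large relative to local
#'   composition noise so spatial gradients do not fragment into spurious
#'   communities).
#' @param resolution Leiden resolution (default 0.5).
#' @param merge_tau Jensen-Shannon merge threshold (default 0.05; 0 disables
#'   merging).
#' @param batch_key metadata column for per-sample centering (e.g.
#'   `"sample"`), or `NULL`.
#' @param seed RNG seed for Leiden.
#' @return object of class `niche_assignment`: list with `labels` (data frame
#'   `cell_id, niche`), `summary` (niche x state mean composition), `scaled`
#'   (summary scaled per state by its maximum across niches, in \[0, 1\]),
#'   and `merge_log`.
#' @export
cluster_niches <- function(neigh, k_neighbors = 45, resolution = 0.5,
                           merge_tau = 0.05, batch_key = NULL, seed = 1L) {
  stopifnot(inherits(neigh, "neighborhood_matrix"))
  use <- neigh$n_neighbors > 0
  if (!any(use)) .stopf("all rows have zero neighbors")
  X <- neigh$pct[use, , drop = FALSE]
  if (any(!is.finite(X))) .stopf("non-finite composition values")
  if (nrow(X) < 2) .stopf("need at least 2 clustered cells")
  Xc <- X
  if (!is.null(batch_key)) {
    bk <- neigh$cells[[batch_key]][use]
    if (is.null(bk)) .stopf("batch_key column '%s' not found", batch_key)
    for (s in unique(bk)) {
      i <- bk == s
      Xc[i, ] <- scale(Xc[i, , drop = FALSE], center = TRUE, scale = FALSE)
    }
  }
  edges <- .knn_edges(Xc, k_neighbors)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  cl <- with_seed(seed,
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution, n_iterations = 10))
  memb <- igraph::membership(cl)

  # iterative merge of near-identical mean compositions
  merge_log <- list()
  repeat {
    ids <- sort(unique(memb))
    if (length(ids) < 2) break
    centers <- t(vapply(ids, function(cid)
      colMeans(X[memb == cid, , drop = FALSE]), numeric(ncol(X))))
    best <- NULL; best_d <- Inf
    for (a in seq_along(ids)) for (b in seq_len(a - 1)) {
      d <- js_distance(centers[a, ] / 100, centers[b, ] / 100)
      if (d < best_d) { best_d <- d; best <- c(ids[b], ids[a]) }
    }
    if (best_d >= merge_tau) break
    memb[memb == best[2]] <- best[1]
    merge_log[[length(merge_log) + 1]] <-
      list(from = best[2], into = best[1], js_distance = best_d)
  }

  # relabel by decreasing size
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(paste0("N", seq_along(sizes)), names(sizes))
  niche <- unname(relab[as.character(memb)])
  labels <- data.frame(cell_id = rownames(X), niche = niche,
                       stringsAsFactors = FALSE)
  niches <- sort(unique(niche))
  summary <- t(vapply(niches, function(nm)
    colMeans(X[niche == nm, , drop = FALSE]), numeric(ncol(X))))
  rownames(summary) <- niches
  scaled <- sweep(summary, 2, pmax(apply(summary, 2, max), 1e-12), "/")
  structure(list(labels = labels, summary = summary, scaled = scaled,
                 merge_log = merge_log, resolution = resolution,
                 merge_tau = merge_tau, seed = seed),
            class = "niche_assignment")
}

#' @export
print.niche_assignment <- function(x, ...) {
  cat(sprintf("niche_assignment: %d cells in %d niches (%d merges)\n",
              nrow(x$labels), nrow(x$summary), length(x$merge_log)))
  invisible(x)
}

#' Cell-cell colocalization enrichment by label permutation
#'
#' Counts state-pair adjacencies (cell pairs within `radius` um, within
#' sample) and compares each observed pair count to a null obtained by
#' shuffling state labels over the fixed cell positions within each sample.
#' Enrichment is reported as `z = (obs - mean_null) / sd_null` together with
#' the one-sided empirical p-value `(1 + #{null >= obs}) / (1 + n_perm)`.
#'
#' @param cells data frame with `cell_id, x, y, state` and optional `sample`.
#' @param radius contact radius in um (default 30, cell-contact scale).
#' @param n_permutations permutation count (default 1000; < 100 warns).
#' @param seed RNG seed.
#' @return object of class `colocalization_result`: list with symmetric
#'   matrices `z`, `p`, `observed`, plus `sd_zero` flags for degenerate
#'   pairs, `radius`, `n_permutations`, `seed`.
#' @export
colocalization_enrichment <- function(cells, radius = 30,
                                      n_permutations = 1000, seed = 1L) {
  if (radius <= 0) .stopf("radius must be > 0")
  if (n_permutations < 100) .warnf("fewer than 100 permutations; p-values are coarse")
  if (is.null(cells$sample)) cells$sample <- "s1"
  states <- sort(unique(cells$state))
  S <- length(states)
  if (S < 2) .stopf("need at least 2 states")
  si <- match(cells$state, states)

  # neighbor pair list (i < j), within sample
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (s in unique(cells$sample)) {
    idx <- which(cells$sample == s)
    if (length(idx) < 2) next
    d2 <- outer(cells$x[idx], cells$x[idx], `-`)^2 +
      outer(cells$y[idx], cells$y[idx], `-`)^2
    hit <- which(d2 <= radius^2 & upper.tri(d2), arr.ind = TRUE)
    pairs_i <- c(pairs_i, idx[hit[, 1]])
    pairs_j <- c(pairs_j, idx[hit[, 2]])
  }

  pair_index <- function(lab) {
    a <- pmin(lab[pairs_i], lab[pairs_j])
    b <- pmax(lab[pairs_i], lab[pairs_j])
    (a - 1L) * S + b
  }
  count_pairs <- function(lab) tabulate(pair_index(lab), nbins = S * S)

  obs <- count_pairs(si)
  null_mat <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) {
      lab <- si
      for (s in unique(cells$sample)) {
        idx <- which(cells$sample == s)
        lab[idx] <- si[sample(idx)]
      }
      count_pairs(lab)
    }, numeric(S * S))
  })
  mu <- rowMeans(null_mat)
  sdv <- apply(null_mat, 1, stats::sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
  pv <- (1 + rowSums(null_mat >= matrix(obs, S * S, n_permutations))) /
    (1 + n_permutations)

  to_mat <- function(v) {
    m <- matrix(NA_real_, S, S, dimnames = list(states, states))
    for (a in seq_len(S)) for (b in a:S) {
      m[a, b] <- m[b, a] <- v[(a - 1L) * S + b]
    }
    m
  }
  structure(list(z = to_mat(z), p = to_mat(pv), observed = to_mat(obs),
                 sd_zero = to_mat(as.numeric(sdv == 0)) > 0,
                 radius = radius, n_permutations = n_permutations,
                 seed = seed, states = states),
            class = "colocalization_result")
}

#' Write niche outputs as TSV
#' @param niches a `niche_assignment`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_niches <- function(niches, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(niches$labels, file.path(dir, "niche_labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  summ <- data.frame(niche = rownames(niches$summary), niches$summary,
                     check.names = FALSE)
  utils::write.table(summ, file.path(dir, "niche_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
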