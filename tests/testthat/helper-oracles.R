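# Independent brute-force oracles and small fixture builders. These are kept
# deliberately naive (nested loops, full enumeration) so they share no code
# path with the package implementations they check.

# distance from one point to a polygon: min over edges, 0 if inside
bf_point_polygon_dist <- function(x, y, poly) {
  n <- nrow(poly)
  # even-odd ray crossing
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > y) != (poly[j, 2] > y) &&
        x < (poly[j, 1] - poly[i, 1]) * (y - poly[i, 2]) /
          (poly[j, 2] - poly[i, 2]) + poly[i, 1]) inside <- !inside
    j <- i
  }
  if (inside) return(0)
  dmin <- Inf
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]; x2 <- poly[i, 1]; y2 <- poly[i, 2]
    l2 <- (x2 - x1)^2 + (y2 - y1)^2
    t <- if (l2 == 0) 0 else
      max(0, min(1, ((x - x1) * (x2 - x1) + (y - y1) * (y2 - y1)) / l2))
    d <- sqrt((x - (x1 + t * (x2 - x1)))^2 + (y - (y1 + t * (y2 - y1)))^2)
    dmin <- min(dmin, d)
    j <- i
  }
  dmin
}

# exhaustive nearest-nucleus assignment
bf_assign_nuclei <- function(transcripts, nuclei, max_dist = 2) {
  out <- list()
  for (t in seq_len(nrow(transcripts))) {
    best_id <- NA_character_; best_d <- Inf
    for (o in seq_along(nuclei$ids)) {
      d <- if (!is.null(nuclei$polygons)) {
        bf_point_polygon_dist(transcripts$x[t], transcripts$y[t],
                              nuclei$polygons[[o]])
      } else {
        sqrt((transcripts$x[t] - nuclei$centroids[o, 1])^2 +
               (transcripts$y[t] - nuclei$centroids[o, 2])^2)
      }
      if (d < best_d - 1e-12 ||
          (abs(d - best_d) <= 1e-12 && nuclei$ids[o] < best_id)) {
        best_d <- d; best_id <- nuclei$ids[o]
      }
    }
    if (best_d <= max_dist + 1e-12) {
      out[[length(out) + 1]] <- data.frame(
        transcript_id = transcripts$transcript_id[t],
        object_id = best_id, distance = best_d, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(transcript_id = character(0), object_id = character(0),
               distance = numeric(0))
}

# exhaustive boundary assignment over every pixel of every retained object
bf_assign_boundaries <- function(transcripts, cells, max_dist = 2,
                                 area_min = 1000, area_max = 25000) {
  ps <- cells$pixel_size
  keep <- cells$ids[cells$areas > area_min & cells$areas < area_max]
  out <- list()
  for (t in seq_len(nrow(transcripts))) {
    x <- transcripts$x[t]; y <- transcripts$y[t]
    tpx <- floor(x / ps); tpy <- floor(y / ps)
    holders <- character(0); dists <- numeric(0)
    for (oid in keep) {
      pp <- cells$pixels[cells$pixels$object_id == oid, , drop = FALSE]
      if (any(pp$px == tpx & pp$py == tpy)) {
        holders <- c(holders, oid); dists <- c(dists, 0)
      }
    }
    if (length(holders) == 0) {
      for (oid in keep) {
        pp <- cells$pixels[cells$pixels$object_id == oid, , drop = FALSE]
        d <- sqrt(min(((pp$px + 0.5) * ps - x)^2 + ((pp$py + 0.5) * ps - y)^2))
        if (d <= max_dist + 1e-12) {
          holders <- c(holders, oid); dists <- c(dists, d)
        }
      }
    }
    for (i in seq_along(holders)) {
      out[[length(out) + 1]] <- data.frame(
        transcript_id = transcripts$transcript_id[t],
        object_id = holders[i], distance = dists[i], stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(transcript_id = character(0), object_id = character(0),
               distance = numeric(0))
}

# exhaustive pairwise neighborhood composition
bf_neighborhood <- function(cells, radius) {
  states <- sort(unique(cells$state))
  n <- nrow(cells)
  pct <- matrix(0, n, length(states), dimnames = list(cells$cell_id, states))
  nn <- numeric(n)
  smp <- if (is.null(cells$sample)) rep("s1", n) else cells$sample
  for (i in seq_len(n)) {
    cnt <- setNames(numeric(length(states)), states)
    for (j in seq_len(n)) {
      if (i == j || smp[i] != smp[j]) next
      d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
      if (d <= radius) cnt[cells$state[j]] <- cnt[cells$state[j]] + 1
    }
    nn[i] <- sum(cnt)
    if (nn[i] > 0) pct[i, ] <- 100 * cnt / nn[i]
  }
  list(pct = pct, n_neighbors = nn)
}

# two-sided minlike binomial p by explicit enumeration of all 2^n sequences
bf_binom_enum <- function(k, n, p0 = 0.5) {
  seq_p <- numeric(n + 1)  # total probability of sequences with j successes
  for (s in 0:(2^n - 1)) {
    j <- sum(bitwAnd(bitwShiftR(s, 0:(n - 1)), 1L))
    seq_p[j + 1] <- seq_p[j + 1] + p0^j * (1 - p0)^(n - j)
  }
  sum(seq_p[seq_p <= seq_p[k + 1] * (1 + 1e-9)])
}

# fixture: random transcript table in standardized form
rand_transcripts <- function(n, width = 100, height = 100, genes = c("g1", "g2"),
                             qv_range = c(20, 45)) {
  data.frame(
    transcript_id = sprintf("t%04d", seq_len(n)),
    gene = sample(genes, n, replace = TRUE),
    x = runif(n, 0, width), y = runif(n, 0, height),
    qv = runif(n, qv_range[1], qv_range[2]),
    stringsAsFactors = FALSE)
}

# fixture: random convex-ish nucleus polygons (irregular 5..9-gons)
rand_nuclei <- function(n_obj, width = 100, height = 100, r_range = c(2, 6)) {
  polys <- list()
  cx <- runif(n_obj, 0, width); cy <- runif(n_obj, 0, height)
  for (i in seq_len(n_obj)) {
    k <- sample(5:9, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    r <- runif(k, r_range[1], r_range[2])
    polys[[i]] <- cbind(x = cx[i] + r * cos(ang), y = cy[i] + r * sin(ang))
  }
  segmented_object_set(sprintf("n%03d", seq_len(n_obj)), "nucleus",
                       centroids = cbind(cx, cy), polygons = polys)
}

# fixture: random pixel-blob boundary objects with areas inside the gate
rand_boundary_cells <- function(n_obj, width = 300, height = 300,
                                pixel_size = 1) {
  pix <- list()
  cx <- runif(n_obj, 30, width - 30); cy <- runif(n_obj, 30, height - 30)
  for (i in seq_len(n_obj)) {
    # union of 2-3 offset discs, radius chosen to land inside the area gate
    r0 <- runif(1, 19, 26)
    ps <- list(c(0, 0))
    for (e in seq_len(sample(1:2, 1))) ps[[e + 1]] <- runif(2, -8, 8)
    cells <- unique(do.call(rbind, lapply(ps, function(off) {
      gx <- floor((cx[i] + off[1] - r0)):ceiling((cx[i] + off[1] + r0))
      gy <- floor((cy[i] + off[2] - r0)):ceiling((cy[i] + off[2] + r0))
      g <- expand.grid(px = gx, py = gy)
      g[(g$px + 0.5 - cx[i] - off[1])^2 + (g$py + 0.5 - cy[i] - off[2])^2
        <= r0^2, ]
    })))
    pix[[i]] <- data.frame(object_id = sprintf("b%03d", i), cells)
  }
  segmented_object_set(sprintf("b%03d", seq_len(n_obj)), "boundary_cell",
                       centroids = cbind(cx, cy),
                       pixels = do.call(rbind, pix), pixel_size = pixel_size)
}

# canonical sorted representation of an assignment for comparison
assign_key <- function(a) {
  if (nrow(a) == 0) return(character(0))
  sort(paste(a$transcript_id, a$object_id, sep = "|"))
}

# minimal gene panel for tests that do not exercise expression
tiny_panel <- function() {
  states <- tissue_states()
  rates <- matrix(0.2, length(states), 2,
                  dimnames = list(states, c("gA", "gB")))
  list(rates = rates, stress_genes = character(0), ad_stress_base = 0)
}

# adipocyte-only niche layout for size-coupling fixtures
adipocyte_layout <- function() {
  list(list(name = "adipocyte", xfrac = c(0, 1),
            composition = c(AD = 1, APC = 0, ASC = 0, LAM = 0, TRM = 0,
                            ECart = 0, ECven = 0, Tcell = 0)))
}
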