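# Internal geometry and bookkeeping helpers shared across modules.

# Evaluate a function with a locally seeded RNG, restoring global state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Squared distance from points (px, py) to segment (x1,y1)-(x2,y2), vectorised
# over points.
.dist2_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return((px - x1)^2 + (py - y1)^2)
  t <- ((px - x1) * dx + (py - y1) * dy) / l2
  t <- pmin(1, pmax(0, t))
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

# Even-odd rule point-in-polygon test, vectorised over points.
.points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Distance from points to a closed polygon: 0 inside, else distance to the
# nearest edge.
dist_points_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  stopifnot(n >= 3, length(vy) == n)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    d2 <- pmin(d2, .dist2_point_segment(px, py, vx[j], vy[j], vx[i], vy[i]))
    j <- i
  }
  d <- sqrt(d2)
  d[.points_in_polygon(px, py, vx, vy)] <- 0
  d
}

# Jensen-Shannon distance (base-2 logs, so bounded by 1) between two
# probability vectors.
js_distance <- function(p, q) {
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  sqrt(max(0, 0.5 * kl(p, m) + 0.5 * kl(q, m)))
}

# Format numerics at full round-trip precision for text serialisation.
.num17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
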