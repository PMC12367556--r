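# build a cell_count_matrix directly from a dense count matrix
mat_from_counts <- function(m, target = 1e4, meta = NULL) {
  assign <- data.frame(
    transcript_id = sprintf("t%06d", seq_len(sum(m))),
    object_id = rep(rep(rownames(m), ncol(m)), as.vector(m)),
    distance = 0, mode = "test")
  tr <- data.frame(transcript_id = assign$transcript_id,
                   gene = rep(rep(colnames(m), each = nrow(m)), as.vector(m)),
                   x = 0, y = 0, qv = 40)
  build_count_matrix(assign, tr, min_transcripts = 0,
                     normalize_target = target, genes = colnames(m),
                     meta = meta)
}

test_that("identical constant expression gives zero scores by symmetry", {
  set.seed(50)
  m <- matrix(5L, nrow = 20, ncol = 30,
              dimnames = list(sprintf("c%02d", 1:20), sprintf("g%02d", 1:30)))
  mat <- mat_from_counts(m)
  sc <- suppressWarnings(score_gene_set(mat, c("g01", "g02"),
                                        control_size = 5, seed = 1))
  expect_equal(unname(sc$score), rep(0, 20), tolerance = 1e-12)
})

test_that("scoring is deterministic given a seed", {
  set.seed(51)
  m <- matrix(rpois(40 * 60, 3), nrow = 40,
              dimnames = list(sprintf("c%02d", 1:40), sprintf("g%02d", 1:60)))
  mat <- mat_from_counts(m)
  s1 <- suppressWarnings(score_gene_set(mat, c("g01", "g05"), seed = 9))
  s2 <- suppressWarnings(score_gene_set(mat, c("g01", "g05"), seed = 9))
  expect_identical(s1$score, s2$score)
  expect_identical(s1$control_genes, s2$control_genes)
  s3 <- suppressWarnings(score_gene_set(mat, c("g01", "g05"), seed = 10))
  expect_false(identical(s1$control_genes, s3$control_genes))
})

test_that("a planted ln-expression shift is recovered as the mean score", {
  # targets shifted by +delta over an otherwise homogeneous stratum:
  # score should average delta across cells, over many control draws
  delta <- 0.4
  n_genes <- 120
  n_cells <- 60
  set.seed(52)
  base <- matrix(rnorm(n_cells * n_genes, 0, 0.05), n_cells, n_genes,
                 dimnames = list(sprintf("c%03d", 1:n_cells),
                                 sprintf("g%03d", 1:n_genes)))
  targets <- c("g001", "g002", "g003")
  base[, targets] <- base[, targets] + delta
  mat <- list(ln = Matrix::Matrix(base, sparse = TRUE),
              genes = colnames(base), cells = rownames(base))
  class(mat) <- "cell_count_matrix"
  means <- vapply(1:20, function(s) {
    mean(score_gene_set(mat, targets, control_size = 30,
                        n_expression_bins = 1, seed = s)$score)
  }, numeric(1))
  expect_lt(abs(mean(means) - delta), 0.05)
})

test_that("scores are invariant in expectation to a global expression shift", {
  set.seed(53)
  base <- matrix(rnorm(30 * 80), 30, 80,
                 dimnames = list(sprintf("c%02d", 1:30), sprintf("g%02d", 1:80)))
  mk <- function(m) structure(list(ln = Matrix::Matrix(m, sparse = TRUE),
                                   genes = colnames(m), cells = rownames(m)),
                              class = "cell_count_matrix")
  sa <- sapply(1:15, function(s)
    mean(score_gene_set(mk(base), c("g01", "g02"), control_size = 20,
                        seed = s)$score))
  sb <- sapply(1:15, function(s)
    mean(score_gene_set(mk(base + 2), c("g01", "g02"), control_size = 20,
                        seed = s)$score))
  expect_lt(abs(mean(sa) - mean(sb)), 1e-9)  # shift preserves strata and ln diffs
})

test_that("missing target genes are dropped with a warning, empty set errors", {
  m <- matrix(1L, 5, 10, dimnames = list(paste0("c", 1:5), paste0("g", 1:10)))
  mat <- mat_from_counts(m)
  expect_warning(score_gene_set(mat, c("g1", "nope"), control_size = 2),
                 "absent")
  expect_error(suppressWarnings(score_gene_set(mat, "nope")), "empty")
})

test_that("stress map applies the clipped log transform", {
  set.seed(54)
  tab <- rand_transcripts(600, width = 200, height = 200)
  grid <- bin_transcripts(tab, min_count = 10)
  bm <- bin_grid_as_matrix(grid)
  sc <- suppressWarnings(score_gene_set(bm, "g1", control_size = 1, seed = 1))
  sm <- stress_map(sc, grid)
  key <- paste(sm$bins$ix, sm$bins$iy, sep = "_")
  scored <- key %in% names(sc$score)
  expect_equal(sm$bins$stress[scored],
               unname(log1p(pmax(sc$score[key[scored]], 0))))
  expect_true(all(is.na(sm$bins$stress[!scored])))
  # closed-form anchors
  sc$score[] <- 0
  sm0 <- stress_map(sc, grid)
  expect_true(all(sm0$bins$stress[scored] == 0))
  sc$score[] <- 1
  sm1 <- stress_map(sc, grid)
  expect_equal(unique(sm1$bins$stress[scored]), log(2), tolerance = 1e-12)
  # identity transform passes scores through unchanged
  smi <- stress_map(sc, grid, transform = "identity")
  expect_equal(unique(smi$bins$stress[scored]), 1)
})

test_that("a planted high-stress disc lights up the stress map", {
  cfg <- tissue_config("lean", field_size = c(2400, 800), n_cells = 480,
                       seed = 55,
                       stress_region = list(cx = 2160, cy = 400, r = 250,
                                            fold = 6))
  tis <- generate_tissue(cfg)
  dir <- tempfile()
  write_bundle(tis, dir)
  tr <- load_and_filter_transcripts(file.path(dir, "transcripts.csv"))
  grid <- bin_transcripts(tr)
  sc <- suppressWarnings(
    score_gene_set(bin_grid_as_matrix(grid),
                   default_gene_panel()$stress_genes, seed = 1))
  sm <- stress_map(sc, grid)
  b <- sm$bins[!is.na(sm$bins$stress), ]
  inside <- (b$x_center - 2160)^2 + (b$y_center - 400)^2 <= 250^2
  p <- stats::wilcox.test(b$stress[inside], b$stress[!inside],
                          alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("positivity fractions count cells at the threshold correctly", {
  m <- matrix(0L, 10, 2, dimnames = list(sprintf("c%02d", 1:10), c("CDKN1A", "x")))
  m[1:3, "CDKN1A"] <- 1L
  m[, "x"] <- 5L  # keep totals positive
  meta <- data.frame(cell_id = rownames(m), sample = "s1", condition = "OB")
  mat <- mat_from_counts(m, meta = meta)
  pr <- call_positive_fraction(mat, "CDKN1A")
  expect_equal(pr$fractions$fraction, 0.3)
  # all-zero marker
  m2 <- m; m2[, "CDKN1A"] <- 0L
  pr2 <- call_positive_fraction(mat_from_counts(m2, meta = meta), "CDKN1A")
  expect_equal(pr2$fractions$fraction, 0)
  expect_error(call_positive_fraction(mat, "absent"), "absent")
})

test_that("raising the positivity threshold never raises a fraction", {
  set.seed(56)
  m <- matrix(rpois(200, 1), 20, 10,
              dimnames = list(sprintf("c%02d", 1:20), sprintf("g%02d", 1:10)))
  m[, 1] <- m[, 1] + 1L
  meta <- data.frame(cell_id = rownames(m),
                     sample = rep(c("s1", "s2"), each = 10),
                     condition = rep(c("LN", "OB"), each = 10))
  mat <- mat_from_counts(m, meta = meta)
  f <- sapply(1:4, function(th)
    mean(call_positive_fraction(mat, "g01", th)$fractions$fraction))
  expect_true(all(diff(f) <= 0))
})

test_that("paired planted positivity difference is detected with high power", {
  # planted 0.40 (OB) vs 0.05 (WL), 10 paired samples, 60 cells each
  set.seed(57)
  rejected <- replicate(100, {
    fr_ob <- rbinom(10, 60, 0.40) / 60
    fr_wl <- rbinom(10, 60, 0.05) / 60
    p <- stats::wilcox.test(fr_ob, fr_wl, paired = TRUE)$p.value
    bh_adjust(p) < 0.05
  })
  expect_gte(mean(rejected), 0.95)
})

test_that("comparisons hold the FDR under a global null", {
  set.seed(58)
  n_rep <- 300
  hits <- replicate(n_rep, {
    p <- sapply(1:3, function(i)
      stats::wilcox.test(runif(8), runif(8))$p.value)
    sum(bh_adjust(p) < 0.05)
  })
  expect_lte(mean(hits > 0), 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})

test_that("wilcoxon machinery runs through the result container", {
  set.seed(59)
  n <- 120
  m <- matrix(rpois(n * 4, 2), n, 4,
              dimnames = list(sprintf("c%03d", 1:n), paste0("g", 1:4)))
  meta <- data.frame(cell_id = rownames(m),
                     sample = rep(sprintf("s%02d", 1:12), each = 10),
                     condition = rep(c("LN", "OB", "WL"), each = 40),
                     donor = rep(c(sprintf("d%02d", 1:4),
                                   sprintf("p%02d", 1:4),
                                   sprintf("p%02d", 1:4)), each = 10))
  mat <- mat_from_counts(m, meta = meta)
  pr <- call_positive_fraction(mat, "g1", paired = list(c("OB", "WL")))
  expect_equal(nrow(pr$comparisons), 3)
  expect_equal(pr$comparisons$test[pr$comparisons$group_a == "OB" &
                                     pr$comparisons$group_b == "WL"],
               "wilcoxon_paired")
  expect_true(all(pr$comparisons$p_adj >= pr$comparisons$p - 1e-12))
})
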