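test_that("nucleus assignment honors the closed 2-um convention", {
  # square nucleus with right edge at x = 10
  poly <- cbind(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  nuc <- segmented_object_set("n1", "nucleus", centroids = cbind(5, 5),
                              polygons = list(poly))
  tr <- data.frame(transcript_id = c("in", "at2", "beyond"),
                   gene = "g", x = c(5, 12, 12.01), y = 5, qv = 40)
  a <- assign_to_nuclei(tr, nuc, max_dist = 2)
  expect_setequal(a$transcript_id, c("in", "at2"))
  expect_equal(a$distance[a$transcript_id == "in"], 0)
  expect_equal(a$distance[a$transcript_id == "at2"], 2)
})

test_that("nucleus assignment equals the exhaustive scan on random fields", {
  set.seed(101)
  for (rep in 1:12) {
    tr <- rand_transcripts(sample(100:500, 1), width = 80, height = 80)
    nuc <- rand_nuclei(sample(5:20, 1), width = 80, height = 80)
    got <- assign_to_nuclei(tr, nuc, max_dist = 2)
    ref <- bf_assign_nuclei(tr, nuc, max_dist = 2)
    expect_equal(assign_key(got), assign_key(ref))
    o <- order(got$transcript_id)
    ro <- order(ref$transcript_id)
    expect_equal(got$distance[o], ref$distance[ro], tolerance = 1e-9)
  }
})

test_that("empty nucleus set leaves all transcripts unassigned without error", {
  tr <- rand_transcripts(10)
  nuc <- segmented_object_set(character(0), "nucleus",
                              centroids = matrix(numeric(0), ncol = 2))
  a <- assign_to_nuclei(tr, nuc)
  expect_equal(nrow(a), 0)
  expect_error(assign_to_nuclei(tr, nuc, max_dist = -1), "max_dist")
})

test_that("nucleus ties break toward the smaller object id", {
  polys <- list(cbind(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2)),
                cbind(x = c(4, 6, 6, 4), y = c(0, 0, 2, 2)))
  nuc <- segmented_object_set(c("n2", "n1"), "nucleus",
                              centroids = cbind(c(1, 5), c(1, 1)),
                              polygons = polys)
  tr <- data.frame(transcript_id = "t", gene = "g", x = 3, y = 1, qv = 40)
  a <- assign_to_nuclei(tr, nuc)
  expect_equal(a$object_id, "n1")
})

test_that("boundary area gate is strict at 1,000 and 25,000 um2", {
  mk_block <- function(id, n_pix, x0) {
    side <- ceiling(sqrt(n_pix))
    g <- expand.grid(px = x0 + seq_len(side), py = seq_len(side))[seq_len(n_pix), ]
    data.frame(object_id = id, g)
  }
  pix <- rbind(mk_block("a1000", 1000, 0), mk_block("b1001", 1001, 200),
               mk_block("c25000", 25000, 400), mk_block("d24999", 24999, 800))
  cells <- segmented_object_set(c("a1000", "b1001", "c25000", "d24999"),
                                "boundary_cell",
                                centroids = cbind(c(16, 216, 479, 879),
                                                  c(16, 16, 79, 79)),
                                pixels = pix, pixel_size = 1)
  # one transcript inside each block
  tr <- data.frame(transcript_id = paste0("t", 1:4), gene = "g",
                   x = c(5.5, 205.5, 405.5, 805.5), y = 5.5, qv = 40)
  a <- assign_to_boundaries(tr, cells)
  expect_setequal(unique(a$object_id), c("b1001", "d24999"))
})

test_that("boundary assignment is plural: equidistant objects both receive", {
  # two 40x40 blocks separated by a 3-um gap; transcript centered in the gap
  g1 <- expand.grid(px = 0:39, py = 0:39)
  g2 <- expand.grid(px = 43:82, py = 0:39)
  pix <- rbind(data.frame(object_id = "L", g1), data.frame(object_id = "R", g2))
  cells <- segmented_object_set(c("L", "R"), "boundary_cell",
                                centroids = cbind(c(20, 63), c(20, 20)),
                                pixels = pix, pixel_size = 1)
  tr <- data.frame(transcript_id = "t", gene = "g", x = 41.5, y = 20.5, qv = 40)
  a <- assign_to_boundaries(tr, cells)
  expect_setequal(a$object_id, c("L", "R"))
  expect_equal(a$distance, c(2, 2), tolerance = 1e-9)
})

test_that("boundary assignment equals the all-pixel exhaustive scan", {
  set.seed(202)
  for (rep in 1:8) {
    cells <- rand_boundary_cells(sample(3:6, 1))
    tr <- rand_transcripts(sample(100:300, 1), width = 300, height = 300)
    got <- assign_to_boundaries(tr, cells)
    ref <- bf_assign_boundaries(tr, cells)
    expect_equal(assign_key(got), assign_key(ref))
    o <- order(got$transcript_id, got$object_id)
    ro <- order(ref$transcript_id, ref$object_id)
    expect_equal(got$distance[o], ref$distance[ro], tolerance = 1e-9)
  }
})

test_that("excluded transcripts are dropped before boundary assignment", {
  set.seed(9)
  cells <- rand_boundary_cells(2)
  # one transcript planted at each object centroid: both assign by containment
  tr <- data.frame(transcript_id = c("tA", "tB"), gene = "g",
                   x = cells$centroids[, 1], y = cells$centroids[, 2], qv = 40)
  a0 <- assign_to_boundaries(tr, cells)
  expect_setequal(a0$transcript_id, c("tA", "tB"))
  a1 <- assign_to_boundaries(tr, cells,
                             exclude = data.frame(transcript_id = "tA"))
  expect_equal(unique(a1$transcript_id), "tB")
})

test_that("enlarging max_dist never unassigns a transcript", {
  set.seed(301)
  tr <- rand_transcripts(300, width = 80, height = 80)
  nuc <- rand_nuclei(10, width = 80, height = 80)
  a2 <- assign_to_nuclei(tr, nuc, max_dist = 2)
  a5 <- assign_to_nuclei(tr, nuc, max_dist = 5)
  expect_true(all(a2$transcript_id %in% a5$transcript_id))
  cells <- rand_boundary_cells(4)
  trb <- rand_transcripts(200, width = 300, height = 300)
  b2 <- assign_to_boundaries(trb, cells, max_dist = 2)
  b5 <- assign_to_boundaries(trb, cells, max_dist = 5)
  expect_true(all(paste(b2$transcript_id, b2$object_id) %in%
                    paste(b5$transcript_id, b5$object_id)))
})

test_that("cell QC is strict at more-than-40 transcripts", {
  mk_assign <- function(n) data.frame(
    transcript_id = sprintf("t%03d", seq_len(n)), object_id = "c1",
    distance = 0, mode = "nucleus")
  mk_tr <- function(n) data.frame(
    transcript_id = sprintf("t%03d", seq_len(n)), gene = "g1",
    x = 0, y = 0, qv = 40)
  m40 <- suppressWarnings(build_count_matrix(mk_assign(40), mk_tr(40),
                                             min_transcripts = 40))
  m41 <- build_count_matrix(mk_assign(41), mk_tr(41), min_transcripts = 40)
  expect_equal(length(m40$cells), 0)
  expect_equal(length(m41$cells), 1)
})

test_that("normalization is proportional scaling to the target total", {
  assign <- data.frame(transcript_id = sprintf("t%d", 1:4), object_id = "c1",
                       distance = 0, mode = "nucleus")
  tr <- data.frame(transcript_id = sprintf("t%d", 1:4),
                   gene = c("geneA", "geneA", "geneA", "geneB"),
                   x = 0, y = 0, qv = 40)
  m <- build_count_matrix(assign, tr, min_transcripts = 0,
                          normalize_target = 1e4)
  expect_equal(as.numeric(m$normalized["c1", c("geneA", "geneB")]),
               c(7500, 2500))
  expect_equal(as.numeric(m$ln["c1", "geneA"]), log1p(7500))
})

test_that("normalized rows sum to the target and counts are conserved", {
  set.seed(77)
  n <- 500
  tr <- rand_transcripts(n, genes = c("a", "b", "c", "d"))
  assign <- data.frame(transcript_id = tr$transcript_id,
                       object_id = sample(sprintf("c%d", 1:12), n, TRUE),
                       distance = 0, mode = "nucleus")
  m <- build_count_matrix(assign, tr, min_transcripts = 5,
                          normalize_target = 1e4)
  expect_true(all(abs(Matrix::rowSums(m$normalized) - 1e4) < 1e-9))
  # conservation: matrix total = uniquely assigned transcripts in kept cells
  kept <- assign$object_id %in% m$cells
  expect_equal(sum(m$counts), sum(kept))
  # multi-assigned transcripts count once per object
  assign2 <- rbind(assign, transform(assign[1, ], object_id = "extra"))
  m2 <- build_count_matrix(assign2, tr, min_transcripts = 0)
  expect_equal(sum(m2$counts), nrow(assign2))
})

test_that("unknown genes in the assignment are an error", {
  assign <- data.frame(transcript_id = "t1", object_id = "c1",
                       distance = 0, mode = "nucleus")
  tr <- data.frame(transcript_id = "t1", gene = "odd", x = 0, y = 0, qv = 40)
  expect_error(build_count_matrix(assign, tr, genes = c("a", "b")),
               "gene absent")
})
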