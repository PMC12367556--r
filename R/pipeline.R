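#' Declarative pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its published
#' default: QV cutoff 35 (strict), 50-um bins kept above 10 transcripts,
#' 2-um assignment radius, nuclei kept above 40 transcripts, adipocyte area
#' gate (1,000, 25,000) um2, 300-um niche radius, control size 50, selection
#' p 1e-5. Unknown keys passed via `...` raise an error rather than being
#' silently ignored.
#'
#' @param condition synthetic-tissue condition for the simulate stage.
#' @param n_cells,field_size optional overrides for the simulate stage
#'   (defaults: the generator's per-condition values).
#' @param qv_threshold,bin_size,bin_min,assign_radius,cell_min,area_min,area_max,niche_radius,coloc_radius,control_size,n_expression_bins,selection_p,merge_tau,resolution,k_neighbors,n_permutations pipeline thresholds (see module documentation).
#' @param stress_genes gene set for stress scoring (default: the generator's
#'   planted stress set).
#' @param stages character vector of stages to run, in dependency order, out
#'   of `simulate, qc, assign, score, zonate, niches, sizecorr`.
#' @param seed integer master seed.
#' @param input_dir directory holding a tissue bundle when `simulate` is
#'   disabled.
#' @param ... unknown keys are rejected.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(condition = "lean",
                            qv_threshold = 35, bin_size = 50, bin_min = 10,
                            assign_radius = 2, cell_min = 40,
                            area_min = 1000, area_max = 25000,
                            niche_radius = 300, coloc_radius = 30,
                            control_size = 50, n_expression_bins = 25,
                            selection_p = 1e-5, merge_tau = 0.05,
                            resolution = 0.5, k_neighbors = 45,
                            n_permutations = 1000,
                            stress_genes = default_gene_panel()$stress_genes,
                            stages = c("simulate", "qc", "assign", "score",
                                       "zonate", "niches", "sizecorr"),
                            seed = 1L, input_dir = NULL,
                            n_cells = NULL, field_size = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    .stopf("unknown config key(s): %s", paste(names(extra), collapse = ", "))
  cfg <- list(condition = condition, qv_threshold = qv_threshold,
              bin_size = bin_size, bin_min = bin_min,
              assign_radius = assign_radius, cell_min = cell_min,
              area_min = area_min, area_max = area_max,
              niche_radius = niche_radius, coloc_radius = coloc_radius,
              control_size = control_size,
              n_expression_bins = n_expression_bins,
              selection_p = selection_p, merge_tau = merge_tau,
              resolution = resolution, k_neighbors = k_neighbors,
              n_permutations = n_permutations, stress_genes = stress_genes,
              stages = stages, seed = as.integer(seed),
              input_dir = input_dir, n_cells = n_cells,
              field_size = field_size)
  for (k in c("qv_threshold", "bin_size", "assign_radius", "niche_radius",
              "coloc_radius", "control_size", "selection_p"))
    if (cfg[[k]] <= 0 && k != "qv_threshold")
      .stopf("config key '%s' must be positive", k)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return a `pipeline_config` (read) or `path` invisibly (write).
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.manifest <- function(dir, stage, params, files) {
  hashes <- tools::md5sum(file.path(dir, files))
  jsonlite::write_json(
    list(stage = stage, params = params,
         files = as.list(stats::setNames(unname(hashes), files))),
    file.path(dir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, digits = NA)
}

#' Run the spatial analysis pipeline
#'
#' Executes the enabled stages in dependency order: simulate (synthetic
#' tissue) -> qc (QV filter + 50-um binning) -> assign (both assignment
#' modes and count matrices) -> score (stress scores + tissue map) ->
#' zonate -> niches (+ colocalization) -> sizecorr. Each stage writes its
#' outputs and a manifest with parameters and file hashes into `out_dir`;
#' rerunning with an identical config reproduces the outputs bit for bit.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created).
#' @return named list of in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_pipeline_config(config, file.path(out_dir, "config_resolved.yaml"))
  res <- list()
  log <- function(...) message(sprintf(...))
  stages <- config$stages

  if ("simulate" %in% stages) {
    targs <- list(condition = config$condition, seed = config$seed)
    if (!is.null(config$n_cells)) targs$n_cells <- config$n_cells
    if (!is.null(config$field_size)) targs$field_size <- config$field_size
    tissue <- generate_tissue(do.call(tissue_config, targs))
    bdir <- file.path(out_dir, "bundle")
    write_bundle(tissue, bdir)
    log("simulate: %d cells, %d transcripts", nrow(tissue$truth),
        nrow(tissue$transcripts))
    .manifest(out_dir, "simulate", list(seed = config$seed),
              file.path("bundle", "transcripts.csv"))
  } else {
    if (is.null(config$input_dir))
      .stopf("stage dependency missing: no simulate stage and no input_dir")
    tissue <- read_bundle(config$input_dir)
  }
  res$tissue <- tissue

  if ("qc" %in% stages) {
    tr <- filter_transcripts(
      read_transcripts(file.path(if ("simulate" %in% stages)
        file.path(out_dir, "bundle") else config$input_dir,
        "transcripts.csv")),
      config$qv_threshold)
    fl <- attr(tr, "filter_log")
    log("qc: %d in, %d removed at QV <= %g, %d retained",
        fl$n_in, fl$n_removed, fl$qv_threshold, nrow(tr))
    grid <- bin_transcripts(tr, config$bin_size, config$bin_min)
    write_bin_grid(grid, file.path(out_dir, "bin_grid.tsv"))
    .manifest(out_dir, "qc", list(qv_threshold = config$qv_threshold,
                                  bin_size = config$bin_size,
                                  bin_min = config$bin_min), "bin_grid.tsv")
    res$transcripts <- tr
    res$grid <- grid
  }

  if ("assign" %in% stages) {
    if (is.null(res$transcripts)) .stopf("stage dependency missing: qc")
    tr <- res$transcripts
    nuc_assign <- assign_to_nuclei(tr, tissue$nuclei, config$assign_radius)
    truth_state <- tissue$truth$state[match(nuc_assign$object_id,
                                            tissue$truth$cell_id)]
    non_ad <- nuc_assign[!is.na(truth_state) & truth_state != "AD", ,
                         drop = FALSE]
    bnd_assign <- assign_to_boundaries(tr, tissue$boundaries,
                                       config$assign_radius, exclude = non_ad,
                                       area_min = config$area_min,
                                       area_max = config$area_max)
    meta <- data.frame(cell_id = tissue$truth$cell_id,
                       state = tissue$truth$state,
                       sample = paste0(tissue$meta$condition, "_1"),
                       condition = tissue$meta$condition,
                       area = tissue$truth$area, stringsAsFactors = FALSE)
    nuc_mat <- build_count_matrix(nuc_assign, tr,
                                  min_transcripts = config$cell_min,
                                  normalize_target = 1e4, meta = meta)
    bnd_mat <- build_count_matrix(bnd_assign, tr, min_transcripts = 0,
                                  normalize_target = 1, meta = meta)
    log("assign: %d nuclei kept (> %d transcripts), %d adipocytes",
        length(nuc_mat$cells), config$cell_min, length(bnd_mat$cells))
    write_count_matrix(nuc_mat, file.path(out_dir, "matrix_nucleus"))
    write_count_matrix(bnd_mat, file.path(out_dir, "matrix_boundary"))
    write_assignment(nuc_assign, file.path(out_dir, "assign_nucleus.tsv"))
    write_assignment(bnd_assign, file.path(out_dir, "assign_boundary.tsv"))
    .manifest(out_dir, "assign",
              list(assign_radius = config$assign_radius,
                   cell_min = config$cell_min),
              c("assign_nucleus.tsv", "assign_boundary.tsv"))
    res$nuc_mat <- nuc_mat
    res$bnd_mat <- bnd_mat
  }

  if ("score" %in% stages) {
    if (is.null(res$grid) || is.null(res$nuc_mat))
      .stopf("stage dependency missing: assign")
    bmat <- bin_grid_as_matrix(res$grid)
    bscore <- score_gene_set(bmat, config$stress_genes,
                             control_size = config$control_size,
                             n_expression_bins = config$n_expression_bins,
                             seed = config$seed)
    smap <- stress_map(bscore, res$grid)
    cscore <- score_gene_set(res$nuc_mat, config$stress_genes,
                             control_size = config$control_size,
                             n_expression_bins = config$n_expression_bins,
                             seed = config$seed)
    utils::write.table(
      data.frame(bin_id = names(bscore$score), score = bscore$score,
                 stress = log1p(pmax(bscore$score, 0))),
      file.path(out_dir, "bin_scores.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    log("score: mean bin stress %.4f", mean(log1p(pmax(bscore$score, 0))))
    .manifest(out_dir, "score", list(control_size = config$control_size),
              "bin_scores.tsv")
    res$bin_score <- bscore
    res$stress_grid <- smap
    res$cell_score <- cscore
  }

  if ("zonate" %in% stages) {
    if (is.null(res$cell_score)) .stopf("stage dependency missing: score")
    md <- res$nuc_mat$meta
    cd <- data.frame(cell_id = md$cell_id,
                     x = tissue$truth$x[match(md$cell_id, tissue$truth$cell_id)],
                     y = tissue$truth$y[match(md$cell_id, tissue$truth$cell_id)],
                     score = res$cell_score$score[md$cell_id],
                     state = md$state, stringsAsFactors = FALSE)
    zon <- quantile_zonation(cd, bin_size = config$bin_size)
    write_zonation(zon, out_dir)
    .manifest(out_dir, "zonate", list(bin_size = config$bin_size),
              c("bin_scores.tsv", "zonation_composition.tsv"))
    res$zonation <- zon
  }

  if ("niches" %in% stages) {
    cd <- data.frame(cell_id = tissue$truth$cell_id, x = tissue$truth$x,
                     y = tissue$truth$y, state = tissue$truth$state,
                     sample = paste0(tissue$meta$condition, "_1"),
                     stringsAsFactors = FALSE)
    neigh <- neighborhood_composition(cd, radius = config$niche_radius)
    nas <- cluster_niches(neigh, k_neighbors = config$k_neighbors,
                          resolution = config$resolution,
                          merge_tau = config$merge_tau, seed = config$seed)
    coloc <- colocalization_enrichment(cd, radius = config$coloc_radius,
                                       n_permutations = config$n_permutations,
                                       seed = config$seed)
    write_niches(nas, out_dir)
    utils::write.table(
      data.frame(state = rownames(coloc$z), coloc$z, check.names = FALSE),
      file.path(out_dir, "colocalization_z.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    log("niches: %d niches over %d cells", nrow(nas$summary), nrow(nas$labels))
    .manifest(out_dir, "niches",
              list(niche_radius = config$niche_radius,
                   resolution = config$resolution,
                   merge_tau = config$merge_tau),
              c("niche_labels.tsv", "niche_summary.tsv"))
    res$neigh <- neigh
    res$niches <- nas
    res$coloc <- coloc
  }

  if ("sizecorr" %in% stages) {
    if (is.null(res$bnd_mat)) .stopf("stage dependency missing: assign")
    areas <- compute_areas(tissue$boundaries, area_min = config$area_min,
                           area_max = config$area_max)
    keep <- res$bnd_mat$cells %in% areas$object_id
    bm <- res$bnd_mat
    bm$counts <- bm$counts[keep, , drop = FALSE]
    bm$normalized <- bm$normalized[keep, , drop = FALSE]
    bm$ln <- bm$ln[keep, , drop = FALSE]
    bm$cells <- bm$cells[keep]
    bm$meta <- bm$meta[keep, , drop = FALSE]
    sc <- gene_area_correlation(bm, areas, selection_p = config$selection_p)
    utils::write.table(sc, file.path(out_dir, "size_correlation.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    log("sizecorr: %d genes selected",
        length(unique(sc$gene[sc$selected])))
    .manifest(out_dir, "sizecorr", list(selection_p = config$selection_p),
              "size_correlation.tsv")
    res$size_correlation <- sc
  }

  invisible(res)
}
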