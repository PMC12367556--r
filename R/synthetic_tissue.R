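#' Default cell states and niche layout for synthetic adipose tissue
#'
#' The generator emulates subcutaneous adipose tissue as seen by an
#' imaging-based in situ platform: large adipocytes (AD), adipocyte precursors
#' (APC), multipotent stromal cells (ASC), lipid-associated and tissue-resident
#' macrophages (LAM, TRM), arterial and venous endothelium (ECart, ECven) and
#' T cells. Five spatial niches (adipocyte, stem, arterial, venous, stress) are
#' planted as vertical bands with distinct state compositions.
#'
#' @return character vector of state names.
#' @export
tissue_states <- function() {
  c("AD", "APC", "ASC", "LAM", "TRM", "ECart", "ECven", "Tcell")
}

.default_niche_compositions <- function() {
  s <- tissue_states()
  comp <- rbind(
    adipocyte = c(AD = .60, APC = .08, ASC = .05, LAM = .04, TRM = .10,
                  ECart = .03, ECven = .05, Tcell = .05),
    stem      = c(AD = .15, APC = .20, ASC = .40, LAM = .02, TRM = .13,
                  ECart = .03, ECven = .04, Tcell = .03),
    arterial  = c(AD = .15, APC = .15, ASC = .05, LAM = .03, TRM = .07,
                  ECart = .40, ECven = .08, Tcell = .07),
    venous    = c(AD = .12, APC = .05, ASC = .05, LAM = .10, TRM = .08,
                  ECart = .05, ECven = .40, Tcell = .15),
    stress    = c(AD = .20, APC = .15, ASC = .03, LAM = .28, TRM = .06,
                  ECart = .03, ECven = .05, Tcell = .20)
  )
  comp[, s, drop = FALSE]
}

#' @rdname tissue_states
#' @export
default_niche_layout <- function() {
  comp <- .default_niche_compositions()
  nm <- rownames(comp)
  lapply(seq_along(nm), function(i) {
    lo <- (i - 1) / length(nm)
    hi <- i / length(nm)
    list(name = nm[i], xfrac = c(lo, hi), composition = comp[i, ])
  })
}

#' Default gene panel with per-state expression rates
#'
#' One hundred genes: five markers per state (high in their own state,
#' near-silent elsewhere), twelve housekeeping genes expressed uniformly,
#' eight stress genes, and forty filler genes spanning a log-spaced range of
#' expression rates so that expression-matched control strata are populated
#' across the whole dynamic range. Stress-gene rates in adipocytes are
#' modulated per cell by a latent stress level coupled to adipocyte area
#' (see [tissue_config()]); the per-gene adipocyte base rate is high enough
#' that Poisson counting noise only mildly attenuates the planted rank
#' correlation at the single-gene level.
#'
#' @return list with `rates` (state x gene mean-count matrix),
#'   `stress_genes`, and `ad_stress_base` (per-gene adipocyte stress rate
#'   that the per-cell coupling factor multiplies).
#' @export
default_gene_panel <- function() {
  states <- tissue_states()
  marker_genes <- unlist(lapply(states, function(s) paste0(s, "m", 1:5)))
  hk_genes <- paste0("HK", 1:12)
  stress_genes <- paste0("SG", 1:8)
  filler_genes <- sprintf("F%02d", 1:40)
  genes <- c(marker_genes, hk_genes, stress_genes, filler_genes)
  rates <- matrix(0.05, nrow = length(states), ncol = length(genes),
                  dimnames = list(states, genes))
  for (s in states) rates[s, paste0(s, "m", 1:5)] <- 16
  rates[, hk_genes] <- 1
  rates[, stress_genes] <- 0.4 # broad low-level stress expression
  rates["AD", stress_genes] <- 12 # per-gene base; scaled per cell by area coupling
  rates[, filler_genes] <- rep(exp(seq(log(0.05), log(4), length.out = 40)),
                               each = length(states))
  list(rates = rates, stress_genes = stress_genes, ad_stress_base = 12)
}

#' Configuration for the synthetic tissue generator
#'
#' Defaults define the study conditions the generator emulates: lean tissue
#' has adipocytes of ~40 um median diameter; obesity doubles the diameter and,
#' because fewer cells then fit per unit area, halves the cell density, which
#' reproduces the roughly two-fold difference in 300-um neighbor counts
#' between lean and obese tissue. Weight loss sits in between. Stress-gene
#' expression in adipocytes is coupled to cell area through a Gaussian copula
#' with target Spearman correlation `rho_target`. A configurable fraction of
#' transcripts carries low decoding quality (QV mixture: high ~ N(40, 2),
#' low ~ N(25, 5)), and background transcripts with no source cell are
#' scattered uniformly.
#'
#' @param condition one of `"lean"`, `"obese"`, `"weight_loss"`.
#' @param field_size width and height of the tissue field in um.
#' @param n_cells total cell count; `NULL` derives it from a reference density
#'   of 2e-4 cells/um2 at 40 um diameter, scaled by 40/median-diameter.
#' @param diameter_meanlog,diameter_sdlog log-normal adipocyte diameter
#'   parameters (um); `NULL` meanlog uses the per-condition default
#'   (log 40 lean, log 80 obese, log 50 weight loss).
#' @param niche_layout list of planted niches, each
#'   `list(name, xfrac = c(lo, hi), composition = named state vector)`.
#' @param gene_panel as returned by [default_gene_panel()].
#' @param rho_target target Spearman correlation between adipocyte area and
#'   stress-gene expression rate.
#' @param stress_tau log-normal dispersion of the per-cell stress factor.
#' @param f_lowqv fraction of transcripts drawn from the low-QV component.
#' @param background_rate background transcripts per um2.
#' @param pixel_size boundary-mask pixel size in um.
#' @param loc_sigma transcript localization noise (Gaussian sd, um).
#' @param peri_fraction fraction of adipocyte transcripts placed perinuclearly
#'   (the rest spread over the whole cell disc).
#' @param stress_region optional planted high-stress disc,
#'   `list(cx, cy, r, fold)`: stress-gene rates of every cell inside are
#'   multiplied by `fold`.
#' @param seed integer seed; generation is bit-for-bit reproducible.
#' @return object of class `tissue_config`.
#' @export
tissue_config <- function(condition = c("lean", "obese", "weight_loss"),
                          field_size = c(6000, 1000),
                          n_cells = NULL,
                          diameter_meanlog = NULL,
                          diameter_sdlog = 0.2,
                          niche_layout = default_niche_layout(),
                          gene_panel = default_gene_panel(),
                          rho_target = 0.5,
                          stress_tau = 0.8,
                          f_lowqv = 0.15,
                          background_rate = 1e-5,
                          pixel_size = 1,
                          loc_sigma = 0.5,
                          peri_fraction = 0.5,
                          stress_region = NULL,
                          seed = 1L) {
  condition <- match.arg(condition)
  if (is.null(diameter_meanlog)) {
    diameter_meanlog <- switch(condition,
                               lean = log(40), obese = log(80),
                               weight_loss = log(50))
  }
  if (any(field_size <= 0) || length(field_size) != 2)
    .stopf("field_size must be two positive lengths")
  if (exp(diameter_meanlog) <= 0) .stopf("diameter distribution must be positive")
  if (pixel_size <= 0) .stopf("pixel_size must be > 0")
  if (f_lowqv < 0 || f_lowqv > 1) .stopf("f_lowqv must be in [0, 1]")
  if (length(gene_panel$rates) == 0 || ncol(gene_panel$rates) == 0)
    .stopf("gene panel must contain at least one gene")
  for (nl in niche_layout) {
    if (abs(sum(nl$composition) - 1) > 1e-8)
      .stopf("niche '%s' composition must sum to 1", nl$name)
    if (any(nl$composition < 0)) .stopf("niche compositions must be non-negative")
  }
  if (is.null(n_cells)) {
    n_cells <- round(2e-4 * (40 / exp(diameter_meanlog)) *
                       field_size[1] * field_size[2])
  }
  if (n_cells < 0) .stopf("n_cells must be >= 0")
  structure(list(
    condition = condition, field_size = field_size, n_cells = n_cells,
    diameter_meanlog = diameter_meanlog, diameter_sdlog = diameter_sdlog,
    niche_layout = niche_layout, gene_panel = gene_panel,
    rho_target = rho_target, stress_tau = stress_tau, f_lowqv = f_lowqv,
    background_rate = background_rate, pixel_size = pixel_size,
    loc_sigma = loc_sigma, peri_fraction = peri_fraction,
    stress_region = stress_region, seed = as.integer(seed)
  ), class = "tissue_config")
}

# Regular 12-gon approximating a nucleus of radius r at (cx, cy).
.nucleus_polygon <- function(cx, cy, r = 4) {
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

# Rasterise a disc: integer pixel indices whose centers fall inside.
.rasterize_disc <- function(cx, cy, r, pixel_size) {
  lo_x <- floor((cx - r) / pixel_size)
  hi_x <- floor((cx + r) / pixel_size)
  lo_y <- floor((cy - r) / pixel_size)
  hi_y <- floor((cy + r) / pixel_size)
  px <- rep(lo_x:hi_x, times = hi_y - lo_y + 1)
  py <- rep(lo_y:hi_y, each = hi_x - lo_x + 1)
  cxp <- (px + 0.5) * pixel_size
  cyp <- (py + 0.5) * pixel_size
  keep <- (cxp - cx)^2 + (cyp - cy)^2 <= r^2
  cbind(px = px[keep], py = py[keep])
}

#' Generate a synthetic adipose tissue sample with planted ground truth
#'
#' Places cells niche-by-niche without nucleus overlap, renders adipocytes as
#' pixelated disc boundaries, draws per-cell transcript counts from per-state
#' rates (adipocyte stress genes coupled to area), positions transcripts with
#' localization noise, attaches a two-component QV mixture and adds uniform
#' background transcripts. Deterministic given `(config, seed)`.
#'
#' @param config a [tissue_config()].
#' @return object of class `synthetic_tissue`: list with `transcripts`
#'   (Xenium-style table), `nuclei` and `boundaries`
#'   ([segmented_object_set()]s), `truth` (per-cell state, niche, area) and
#'   `meta` (condition, field size, planted low-QV transcript count).
#' @export
generate_tissue <- function(config) {
  stopifnot(inherits(config, "tissue_config"))
  with_seed(config$seed, .generate_tissue_impl(config))
}

.generate_tissue_impl <- function(cfg) {
  W <- cfg$field_size[1]; H <- cfg$field_size[2]
  nuc_r <- 4; small_r <- 5.5
  layout <- cfg$niche_layout
  states <- rownames(cfg$gene_panel$rates)

  # --- allocate cells to niches and states ---------------------------------
  widths <- vapply(layout, function(l) diff(l$xfrac), numeric(1))
  n_per_niche <- round(cfg$n_cells * widths / sum(widths))
  cell_state <- character(0); cell_niche <- character(0)
  for (i in seq_along(layout)) {
    comp <- layout[[i]]$composition[states]
    comp[is.na(comp)] <- 0
    comp <- comp / sum(comp)
    if (n_per_niche[i] > 0) {
      # exact largest-remainder allocation: the planted composition is the
      # configured one, not a multinomial draw from it
      cnt <- floor(n_per_niche[i] * comp)
      rem <- n_per_niche[i] - sum(cnt)
      if (rem > 0) {
        frac <- n_per_niche[i] * comp - cnt
        add <- order(frac, decreasing = TRUE)[seq_len(rem)]
        cnt[add] <- cnt[add] + 1
      }
      st <- sample(rep(states, cnt))
      cell_state <- c(cell_state, st)
      cell_niche <- c(cell_niche, rep(layout[[i]]$name, n_per_niche[i]))
    }
  }
  n <- length(cell_state)
  is_ad <- cell_state == "AD"
  radius <- rep(small_r, n)
  if (any(is_ad)) {
    d <- stats::rlnorm(sum(is_ad), cfg$diameter_meanlog, cfg$diameter_sdlog)
    d <- pmin(pmax(d, 15), 176)  # keep within the plausible adipocyte range
    radius[is_ad] <- d / 2
  }
  if (sum(pi * radius[is_ad]^2) > 0.55 * W * H)
    .stopf("infeasible packing: adipocyte area exceeds 55%% of the field")

  # --- place cells (largest first within each niche) -----------------------
  ord <- order(match(cell_niche, vapply(layout, `[[`, "", "name")), -radius)
  x <- numeric(n); y <- numeric(n)
  px_placed <- numeric(0); py_placed <- numeric(0)
  pr_placed <- numeric(0); pad_placed <- logical(0)
  for (k in ord) {
    li <- layout[[match(cell_niche[k], vapply(layout, `[[`, "", "name"))]]
    xlo <- li$xfrac[1] * W; xhi <- li$xfrac[2] * W
    r <- radius[k]
    ok <- FALSE
    for (att in 1:300) {
      cx <- stats::runif(1, min(xlo + r, xhi), max(xlo, xhi - r))
      cy <- stats::runif(1, min(r, H), max(0, H - r))
      if (length(px_placed)) {
        dd <- sqrt((px_placed - cx)^2 + (py_placed - cy)^2)
        minsep <- rep(2 * nuc_r + 1, length(dd))
        if (is_ad[k]) {
          minsep[pad_placed] <- 0.8 * (pr_placed[pad_placed] + r)
        } else {
          minsep[pad_placed] <- pmax(minsep[pad_placed], pr_placed[pad_placed] + 2)
        }
        if (any(dd < minsep)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) .stopf("infeasible packing: could not place cell after 300 attempts")
    x[k] <- cx; y[k] <- cy
    px_placed <- c(px_placed, cx); py_placed <- c(py_placed, cy)
    pr_placed <- c(pr_placed, r); pad_placed <- c(pad_placed, is_ad[k])
  }

  cell_id <- sprintf("c%05d", seq_len(n))

  # --- geometry: nuclei polygons and adipocyte boundary pixels -------------
  polygons <- lapply(seq_len(n), function(i) .nucleus_polygon(x[i], y[i], nuc_r))
  nuclei <- segmented_object_set(cell_id, "nucleus",
                                 centroids = cbind(x = x, y = y),
                                 polygons = polygons)
  ad_idx <- which(is_ad)
  if (length(ad_idx)) {
    pix_list <- lapply(ad_idx, function(i) {
      p <- .rasterize_disc(x[i], y[i], radius[i], cfg$pixel_size)
      data.frame(object_id = cell_id[i], px = p[, 1], py = p[, 2],
                 stringsAsFactors = FALSE)
    })
    pixels <- do.call(rbind, pix_list)
  } else {
    pixels <- data.frame(object_id = character(0), px = integer(0), py = integer(0))
  }
  boundaries <- segmented_object_set(cell_id[ad_idx], "boundary_cell",
                                     centroids = cbind(x = x[ad_idx], y = y[ad_idx]),
                                     pixels = pixels, pixel_size = cfg$pixel_size)

  area <- pi * radius^2
  if (length(ad_idx)) area[ad_idx] <- boundaries$areas[match(cell_id[ad_idx],
                                                             boundaries$ids)]

  # --- per-cell stress coupling (adipocytes, Gaussian copula on area rank) --
  stress_factor <- rep(1, n)
  if (length(ad_idx) >= 2) {
    r_cop <- 2 * sin(pi * cfg$rho_target / 6)
    za <- stats::qnorm((rank(radius[ad_idx], ties.method = "first") - 0.5) /
                         length(ad_idx))
    g <- r_cop * za + sqrt(max(0, 1 - r_cop^2)) * stats::rnorm(length(ad_idx))
    tau <- cfg$stress_tau
    stress_factor[ad_idx] <- exp(tau * g - tau^2 / 2)
  }

  # --- transcripts ---------------------------------------------------------
  rates <- cfg$gene_panel$rates
  genes <- colnames(rates)
  sg <- intersect(cfg$gene_panel$stress_genes, genes)
  lam <- rates[cell_state, , drop = FALSE]
  lam[, sg] <- lam[, sg] * stress_factor
  if (!is.null(cfg$stress_region)) {
    sr <- cfg$stress_region
    inside <- (x - sr$cx)^2 + (y - sr$cy)^2 <= sr$r^2
    lam[inside, sg] <- lam[inside, sg] * sr$fold
  }
  counts <- matrix(stats::rpois(length(lam), lam), nrow = n)
  per_cell <- rowSums(counts)

  tx_cell <- rep(seq_len(n), per_cell)
  tx_gene <- unlist(lapply(seq_len(n), function(i)
    rep(genes, counts[i, ])), use.names = FALSE)
  ntx <- length(tx_cell)
  if (ntx > 0) {
    peri <- !is_ad[tx_cell] | stats::runif(ntx) < cfg$peri_fraction
    rmax <- ifelse(peri, small_r, radius[tx_cell])
    rr <- rmax * sqrt(stats::runif(ntx))
    th <- stats::runif(ntx, 0, 2 * pi)
    tx <- x[tx_cell] + rr * cos(th) + stats::rnorm(ntx, 0, cfg$loc_sigma)
    ty <- y[tx_cell] + rr * sin(th) + stats::rnorm(ntx, 0, cfg$loc_sigma)
    tx <- pmin(pmax(tx, 0), W); ty <- pmin(pmax(ty, 0), H)
  } else {
    tx <- numeric(0); ty <- numeric(0)
  }

  n_bg <- stats::rpois(1, cfg$background_rate * W * H)
  if (n_bg > 0) {
    bg_gene <- sample(genes, n_bg, replace = TRUE)
    bx <- stats::runif(n_bg, 0, W); by <- stats::runif(n_bg, 0, H)
  } else {
    bg_gene <- character(0); bx <- numeric(0); by <- numeric(0)
  }

  all_gene <- c(tx_gene, bg_gene)
  all_x <- c(tx, bx); all_y <- c(ty, by)
  all_cell <- c(cell_id[tx_cell], rep("UNASSIGNED", n_bg))
  ntot <- length(all_gene)
  low <- stats::runif(ntot) < cfg$f_lowqv
  qv <- ifelse(low, stats::rnorm(ntot, 25, 5), stats::rnorm(ntot, 40, 2))
  qv <- pmax(qv, 0)
  ovl <- rep(0L, ntot)
  if (ntx > 0) {
    ovl[seq_len(ntx)] <- as.integer(
      (tx - x[tx_cell])^2 + (ty - y[tx_cell])^2 <= nuc_r^2)
  }

  transcripts <- data.frame(
    transcript_id = sprintf("t%07d", seq_len(ntot)),
    cell_id = all_cell,
    overlaps_nucleus = ovl,
    feature_name = all_gene,
    x_location = all_x,
    y_location = all_y,
    z_location = rep(0, ntot),
    qv = qv,
    stringsAsFactors = FALSE
  )

  truth <- data.frame(cell_id = cell_id, state = cell_state, niche = cell_niche,
                      area = area, x = x, y = y, radius = radius,
                      is_adipocyte = is_ad, stringsAsFactors = FALSE)

  structure(list(
    transcripts = transcripts, nuclei = nuclei, boundaries = boundaries,
    truth = truth,
    meta = list(condition = cfg$condition, field_size = cfg$field_size,
                pixel_size = cfg$pixel_size, seed = cfg$seed,
                n_lowqv = sum(qv <= 35), n_background = n_bg,
                states = states)
  ), class = "synthetic_tissue")
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf("Synthetic adipose tissue (%s): %d cells, %d transcripts (%d background)\n",
              x$meta$condition, nrow(x$truth), nrow(x$transcripts),
              x$meta$n_background))
  invisible(x)
}

#' Write / read a synthetic tissue bundle as plain-text files
#'
#' Emits the transcript table in the Xenium CSV dialect plus nucleus, boundary
#' pixel and ground-truth tables. Numeric columns are serialised at full
#' round-trip precision so that `read_bundle(write_bundle(t))` reproduces the
#' in-memory tables exactly.
#'
#' @param tissue a `synthetic_tissue`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(tissue, dir) {
  stopifnot(inherits(tissue, "synthetic_tissue"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) .stopf("cannot create directory '%s'", dir)
  }
  tr <- tissue$transcripts
  tr$x_location <- .num17(tr$x_location)
  tr$y_location <- .num17(tr$y_location)
  tr$qv <- .num17(tr$qv)
  utils::write.csv(tr, file.path(dir, "transcripts.csv"),
                   row.names = FALSE, quote = FALSE)

  nuc <- tissue$nuclei
  poly_str <- vapply(seq_along(nuc$ids), function(i) {
    p <- nuc$polygons[[i]]
    paste(paste(.num17(p[, 1]), .num17(p[, 2]), sep = ":"), collapse = ";")
  }, character(1))
  if (length(nuc$ids) == 0) poly_str <- character(0)
  nuc_df <- data.frame(nucleus_id = nuc$ids,
                       x = .num17(nuc$centroids[, 1]),
                       y = .num17(nuc$centroids[, 2]),
                       polygon = poly_str, stringsAsFactors = FALSE)
  utils::write.csv(nuc_df, file.path(dir, "nuclei.csv"),
                   row.names = FALSE, quote = FALSE)

  utils::write.csv(tissue$boundaries$pixels, file.path(dir, "boundary_pixels.csv"),
                   row.names = FALSE, quote = FALSE)

  tw <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           row.names = FALSE, quote = FALSE)
  tw(tissue$truth[, c("cell_id", "state")], "truth_states.tsv")
  tw(tissue$truth[, c("cell_id", "niche")], "truth_niches.tsv")
  ta <- tissue$truth[, c("cell_id", "area")]
  ta$area <- .num17(ta$area)
  tw(ta, "truth_areas.tsv")
  tr_full <- tissue$truth
  for (cc in c("area", "x", "y", "radius")) tr_full[[cc]] <- .num17(tr_full[[cc]])
  tw(tr_full, "truth_cells.tsv")

  jsonlite::write_json(tissue$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  need <- c("transcripts.csv", "nuclei.csv", "boundary_pixels.csv",
            "truth_cells.tsv", "meta.json")
  for (f in need) if (!file.exists(file.path(dir, f)))
    .stopf("bundle file missing: %s", f)
  tr <- utils::read.csv(file.path(dir, "transcripts.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = c(transcript_id = "character",
                                       cell_id = "character",
                                       feature_name = "character"))
  tr$overlaps_nucleus <- as.integer(tr$overlaps_nucleus)
  tr$z_location <- as.numeric(tr$z_location)
  tr$x_location <- as.numeric(tr$x_location)
  tr$y_location <- as.numeric(tr$y_location)
  tr$qv <- as.numeric(tr$qv)
  nuc_df <- utils::read.csv(file.path(dir, "nuclei.csv"),
                            stringsAsFactors = FALSE,
                            colClasses = c(nucleus_id = "character",
                                           polygon = "character"))
  polygons <- lapply(nuc_df$polygon, function(s) {
    if (is.na(s) || s == "") return(NULL)
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    m <- do.call(rbind, lapply(parts, as.numeric))
    colnames(m) <- c("x", "y")
    m
  })
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  nuclei <- segmented_object_set(nuc_df$nucleus_id, "nucleus",
                                 centroids = cbind(x = nuc_df$x, y = nuc_df$y),
                                 polygons = if (length(polygons)) polygons else NULL)
  pix <- utils::read.csv(file.path(dir, "boundary_pixels.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(object_id = "character"))
  truth <- utils::read.delim(file.path(dir, "truth_cells.tsv"),
                             stringsAsFactors = FALSE,
                             colClasses = c(cell_id = "character",
                                            state = "character",
                                            niche = "character"))
  ad_ids <- truth$cell_id[truth$is_adipocyte]
  cent <- cbind(x = truth$x[truth$is_adipocyte], y = truth$y[truth$is_adipocyte])
  boundaries <- segmented_object_set(ad_ids, "boundary_cell", centroids = cent,
                                     pixels = pix, pixel_size = meta$pixel_size)
  structure(list(transcripts = tr, nuclei = nuclei, boundaries = boundaries,
                 truth = truth, meta = meta),
            class = "synthetic_tissue")
}
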