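## ---------------------------------------------------------------------------
## Synthetic Visium-like data: tissue geometry, gene programs, activation
## fields, negative-binomial counts and a paired plaque-like image.
## ---------------------------------------------------------------------------

REGIONS <- c("cortex_outer", "cortex_inner", "hippocampus", "WM",
             "thalamus", "striatum", "border")
GM_REGIONS <- c("cortex_outer", "cortex_inner", "hippocampus",
                "thalamus", "striatum")

#' DAM / DAA / microglial signature gene sets
#'
#' Marker panels used throughout the package: the 8-gene disease-associated
#' microglia (DAM) set, the 7-gene disease-associated astrocyte (DAA) set, and
#' the 28-gene microglial panel (homeostatic plus reactive markers) used for
#' trajectory inference.
#'
#' @return character vector of gene symbols
#' @export
dam_genes <- function() c("Lpl", "Cst7", "Axl", "Itgax", "Spp1", "Cd9", "Ccl6", "Csf1")

#' @rdname dam_genes
#' @export
daa_genes <- function() c("Ggta1", "Gsn", "Osmr", "Vim", "Serpina3n", "Ctsb", "Gfap")

#' @rdname dam_genes
#' @export
microglial_panel <- function() {
  c("Hexb", "Cst3", "Cx3cr1", "Ctsd", "Csf1r", "Ctss", "Sparc", "Tmsb4x",
    "P2ry12", "C1qa", "C1qb", "Tmem119", "Tyrobp", "Ctsb", "Apoe", "B2m",
    "Fth1", "Lyz2", "Trem2", "Axl", "Cst7", "Ctsl", "Lpl", "Cd9", "Csf1",
    "Ccl6", "Itgax", "Timp2")
}

## reactive (disease-responsive) vs homeostatic split of the panel used by the
## generator to encode an activation axis
reactive_panel <- function() {
  c("Tyrobp", "Apoe", "B2m", "Fth1", "Lyz2", "Trem2", "Axl", "Cst7",
    "Ctsl", "Lpl", "Cd9", "Csf1", "Ccl6", "Itgax", "Ctsd", "Ctsb")
}
homeostatic_panel <- function() setdiff(microglial_panel(), reactive_panel())

#' Tissue design: hex lattice plus anatomical region layout
#'
#' Describes a rectangular offset (hex-like) lattice of spots and a parametric
#' band layout assigning each grid position to one anatomical region:
#' GM cortex layers, hippocampus, WM, thalamus, striatum, and an optional
#' 1-spot border/meninges ring around the section. The WM region is a
#' connected horizontal band.
#'
#' @param n_rows,n_cols grid dimensions (each >= 2)
#' @param spacing centre-to-centre spot spacing in pixels
#' @param layout named list mapping region name to 0-based row indices; the
#'   default carves horizontal bands covering all rows
#' @param border_ring if TRUE the outermost ring of spots is relabelled
#'   `"border"`
#' @return object of class `tissue_design`
#' @export
tissue_design <- function(n_rows = 50, n_cols = 40, spacing = 10,
                          layout = NULL, border_ring = TRUE) {
  if (n_rows < 2 || n_cols < 2) stopf("n_rows and n_cols must be >= 2")
  if (is.null(layout)) {
    fr <- c(cortex_outer = 0.18, cortex_inner = 0.17, hippocampus = 0.15,
            WM = 0.12, thalamus = 0.20, striatum = 0.18)
    edges <- round(cumsum(fr) * n_rows)
    starts <- c(0L, utils::head(edges, -1))
    layout <- mapply(function(a, b) seq.int(a, b - 1L), starts, edges,
                     SIMPLIFY = FALSE)
    names(layout) <- names(fr)
    layout[[length(layout)]] <- seq.int(starts[length(starts)], n_rows - 1L)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, spacing = spacing,
                 layout = layout, border_ring = border_ring),
            class = "tissue_design")
}

#' Build the spot table for a tissue design
#'
#' Lays out `n_rows * n_cols` spots on an offset lattice (odd rows shifted by
#' half a spacing, emulating Visium hex packing), assigns region labels from
#' the design and computes both array indices and pixel coordinates
#' (x right, y down, 0-based frame).
#'
#' @param design a `tissue_design`
#' @return data.frame with columns `barcode`, `array_row`, `array_col`,
#'   `x_px`, `y_px`, `region`
#' @export
build_tissue <- function(design) {
  stopifnot(inherits(design, "tissue_design"))
  rows <- rep(seq_len(design$n_rows) - 1L, each = design$n_cols)
  cols <- rep(seq_len(design$n_cols) - 1L, times = design$n_rows)
  region <- rep(NA_character_, length(rows))
  for (nm in names(design$layout))
    region[rows %in% design$layout[[nm]]] <- nm
  if (anyNA(region)) stopf("layout does not cover row(s): %s",
                           paste(unique(rows[is.na(region)]), collapse = ", "))
  if (design$border_ring) {
    ring <- rows == 0L | rows == design$n_rows - 1L |
      cols == 0L | cols == design$n_cols - 1L
    region[ring] <- "border"
  }
  for (nm in c(names(design$layout), if (design$border_ring) "border"))
    if (!any(region == nm)) stopf("region '%s' has zero spots", nm)
  data.frame(
    barcode = sprintf("SPOT%05d", seq_along(rows)),
    array_row = rows, array_col = cols,
    x_px = (cols + 0.5 * (rows %% 2) + 1) * design$spacing,
    y_px = (rows + 1) * design$spacing * sqrt(3) / 2,
    region = region, stringsAsFactors = FALSE)
}

#' A negative-binomial gene expression program
#'
#' Each program names a gene subset, per-gene baseline negative-binomial means
#' (the mean at activation 0) and a multiplicative `fold` reached at
#' activation 1: the expected count of gene g in spot s is
#' `baseline_g * fold^activation_s` (before library-size scaling), with
#' NB dispersion `size` (variance = m + m^2/size).
#'
#' @param name program name
#' @param genes character vector of gene symbols (non-empty)
#' @param baseline_mean per-gene baseline mean (recycled)
#' @param fold multiplicative effect at activation 1 (> 0)
#' @param dispersion NB size parameter (> 0)
#' @return object of class `gene_program`
#' @export
gene_program <- function(name, genes, baseline_mean, fold = 1, dispersion = 2) {
  if (!length(genes)) stopf("program '%s': empty gene set", name)
  if (fold <= 0) stopf("program '%s': fold must be > 0", name)
  if (dispersion <= 0) stopf("program '%s': dispersion must be > 0", name)
  structure(list(name = name, genes = genes,
                 baseline_mean = rep_len(baseline_mean, length(genes)),
                 fold = fold, dispersion = dispersion),
            class = "gene_program")
}

#' Disease activation field
#'
#' Per-(region-class, genotype, age) activation levels in [0, 1] encoding the
#' WM-early / GM-late activation pattern: WM activation is positive already in
#' the 3-month AD brain, GM activation appears only at 7 months, WT tissue is
#' inactive except for a constant border (meninges / BAM-like) baseline shared
#' by all mice. Activation is monotone in age for AD spots within a region.
#'
#' @param wm_3m,gm_3m,wm_7m,gm_7m AD activation in WM / GM at 3 and 7 months
#' @param border_all border-region activation in every mouse
#' @return object of class `activation_field`
#' @export
activation_field <- function(wm_3m = 0.8, gm_3m = 0, wm_7m = 1.0, gm_7m = 0.8,
                             border_all = 0.4) {
  lv <- c(wm_3m = wm_3m, gm_3m = gm_3m, wm_7m = wm_7m, gm_7m = gm_7m,
          border_all = border_all)
  if (any(lv < 0 | lv > 1)) stopf("activation levels must lie in [0, 1]")
  if (wm_7m < wm_3m || gm_7m < gm_3m)
    stopf("activation must be monotone in age within a region")
  structure(as.list(lv), class = "activation_field")
}

#' Evaluate an activation field over spots
#'
#' @param field an `activation_field`
#' @param region per-spot region label
#' @param genotype per-spot genotype (`"WT"`/`"AD"`)
#' @param age per-spot age (`"3M"`/`"7M"`)
#' @return numeric vector of per-spot activation in [0, 1]
#' @export
activation_at <- function(field, region, genotype, age) {
  a <- numeric(length(region))
  a[region == "border"] <- field$border_all
  ad <- genotype == "AD"
  a[ad & region == "WM" & age == "3M"] <- field$wm_3m
  a[ad & region == "WM" & age == "7M"] <- field$wm_7m
  a[ad & region %in% GM_REGIONS & age == "3M"] <- field$gm_3m
  a[ad & region %in% GM_REGIONS & age == "7M"] <- field$gm_7m
  a
}

#' Simulate NB counts for one sample
#'
#' Expected count of gene g in spot s is
#' `baseline_g * prod_p fold_p ^ activation[s, p]` over the programs p
#' containing g, optionally scaled by a per-spot lognormal library-size factor
#' (mean 1), then drawn from a negative binomial with the program's dispersion.
#'
#' @param spot_table output of [build_tissue()] (or any data.frame with a
#'   `barcode` column)
#' @param programs list of [gene_program()]s; together they must cover every
#'   gene exactly once for the baseline (later programs may re-target genes
#'   with `fold`, whose effects multiply)
#' @param activation spots x programs matrix (values in [0, 1]) with columns
#'   named after programs; programs absent from the columns get activation 0
#' @param lib_factor_sd sd of the per-spot log-normal library factor (0 = none)
#' @param seed integer RNG seed; identical seeds give bit-identical counts
#' @return sparse gene x spot integer matrix with a `"mu"` attribute holding
#'   the expected-count matrix
#' @export
simulate_counts <- function(spot_table, programs, activation = NULL,
                            lib_factor_sd = 0, seed = 1) {
  set.seed(seed)
  genes <- unique(unlist(lapply(programs, `[[`, "genes")))
  n_g <- length(genes); n_s <- nrow(spot_table)
  baseline <- stats::setNames(rep(NA_real_, n_g), genes)
  size <- stats::setNames(rep(2, n_g), genes)
  log_mu <- matrix(0, n_g, n_s, dimnames = list(genes, spot_table$barcode))
  for (p in programs) {
    idx <- match(p$genes, genes)
    base_known <- !is.na(baseline[idx])
    baseline[idx[!base_known]] <- p$baseline_mean[!base_known]
    size[idx] <- p$dispersion
    a <- if (!is.null(activation) && p$name %in% colnames(activation))
      activation[, p$name] else 0
    if (p$fold != 1 && any(a != 0))
      log_mu[idx, ] <- log_mu[idx, ] +
        matrix(log(p$fold) * a, length(idx), n_s, byrow = TRUE)
  }
  log_mu <- log_mu + log(baseline)
  if (lib_factor_sd > 0) {
    lf <- stats::rnorm(n_s, -lib_factor_sd^2 / 2, lib_factor_sd)
    log_mu <- sweep(log_mu, 2, lf, "+")
  }
  mu <- exp(log_mu)
  if (any(!is.finite(mu))) stopf("non-finite expected counts")
  counts <- matrix(stats::rnbinom(n_g * n_s, mu = mu, size = size), n_g, n_s,
                   dimnames = dimnames(mu))
  out <- as_csparse(counts)
  attr(out, "mu") <- mu
  out
}

## draw baselines and assemble the study's default program set
study_programs <- function(genes, region_markers, dam_fold = 2, daa_fold = 2,
                           region_fold = 4, homeostatic_fold = 0.6,
                           dispersion = 6) {
  named <- unique(c(dam_genes(), daa_genes(), microglial_panel()))
  baseline <- stats::setNames(
    pmin(exp(stats::rnorm(length(genes), 0.2, 1)), 60), genes)
  ## signature genes span expression levels (so binned controls are drawn
  ## from unrelated genes), but stay well detected
  baseline[named] <- pmin(pmax(exp(stats::rnorm(length(named), 1.2, 0.6)),
                               3), 25)
  progs <- list(gene_program("background", genes, baseline[genes],
                             fold = 1, dispersion = dispersion))
  for (nm in names(region_markers))
    progs <- c(progs, list(gene_program(
      paste0("region_", nm), region_markers[[nm]],
      baseline[region_markers[[nm]]], fold = region_fold,
      dispersion = dispersion)))
  progs <- c(progs, list(
    gene_program("DAM", union(dam_genes(), reactive_panel()), 5,
                 fold = dam_fold, dispersion = dispersion),
    gene_program("DAA", daa_genes(), 5, fold = daa_fold,
                 dispersion = dispersion),
    gene_program("homeostatic", homeostatic_panel(), 5,
                 fold = homeostatic_fold, dispersion = dispersion)))
  progs
}

#' Simulate the full 2 x 2 x 2 study
#'
#' Generates the study's default synthetic dataset: 8 coronal-section samples
#' ({WT, AD} x {3M, 7M} x {rep1, rep2}) sharing one tissue design, one gene
#' universe with fixed baselines, region marker programs (distinct markers per
#' anatomical region) and DAM / DAA / homeostatic-microglia activation
#' programs driven by the WM-early / GM-late [activation_field()]. The default
#' size is 2,000 spots per sample and 2,500 genes.
#'
#' @param seed master RNG seed; every draw derives from it
#' @param n_rows,n_cols,spacing tissue grid (see [tissue_design()])
#' @param n_genes size of the gene universe (named signature genes included)
#' @param samples character vector of sample names to generate, each of the
#'   form `"<WT|AD>_<3M|7M>_r<k>"`; default is the full 8-sample design
#' @param field an [activation_field()]
#' @param dam_fold,daa_fold spike folds of the DAM / DAA programs at
#'   activation 1
#' @param homeostatic_fold fold of the homeostatic-microglia program at
#'   activation 1 (< 1: homeostatic genes fall as activation rises)
#' @param region_fold fold of the per-region marker programs
#' @param n_region_markers marker genes per region
#' @param dispersion NB size parameter
#' @param lib_factor_sd per-spot log-normal library factor sd
#' @return a `spot_dataset` with a `truth` element: per-spot `region` and
#'   `activation` (the DAM-program activation level), `spiked_genes` (the
#'   DAM-program genes), `daa_genes`, `region_markers`, and `driver_gene`
#' @export
simulate_study <- function(seed = 1, n_rows = 50, n_cols = 40, spacing = 10,
                           n_genes = 2500,
                           samples = c("WT_3M_r1", "WT_3M_r2", "WT_7M_r1",
                                       "WT_7M_r2", "AD_3M_r1", "AD_3M_r2",
                                       "AD_7M_r1", "AD_7M_r2"),
                           field = activation_field(), dam_fold = 2,
                           daa_fold = 2, region_fold = 4,
                           homeostatic_fold = 0.6,
                           n_region_markers = 40, dispersion = 6,
                           lib_factor_sd = 0.2) {
  set.seed(seed)
  named <- unique(c(dam_genes(), daa_genes(), microglial_panel()))
  if (n_genes < length(named) + 7 * n_region_markers)
    stopf("n_genes too small: need >= %d", length(named) + 7 * n_region_markers)
  genes <- c(named, sprintf("Gene%05d", seq_len(n_genes - length(named))))
  free <- setdiff(genes, named)
  design <- tissue_design(n_rows, n_cols, spacing)
  tissue <- build_tissue(design)
  region_markers <- stats::setNames(lapply(seq_along(REGIONS), function(i)
    free[seq.int((i - 1) * n_region_markers + 1, i * n_region_markers)]),
    REGIONS)
  progs <- study_programs(genes, region_markers, dam_fold = dam_fold,
                          daa_fold = daa_fold, region_fold = region_fold,
                          homeostatic_fold = homeostatic_fold,
                          dispersion = dispersion)
  sample_seeds <- sample.int(.Machine$integer.max, length(samples))
  parts <- vector("list", length(samples))
  truth_act <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    sm <- strsplit(samples[i], "_", fixed = TRUE)[[1]]
    genotype <- sm[1]; age <- sm[2]
    act_dis <- activation_at(field, tissue$region, genotype, age)
    activation <- cbind(
      vapply(REGIONS, function(r) as.numeric(tissue$region == r),
             numeric(nrow(tissue))),
      DAM = act_dis, DAA = act_dis, homeostatic = act_dis)
    colnames(activation)[seq_along(REGIONS)] <- paste0("region_", REGIONS)
    counts <- simulate_counts(tissue, progs, activation,
                              lib_factor_sd = lib_factor_sd,
                              seed = sample_seeds[i])
    attr(counts, "mu") <- NULL
    pos <- data.frame(barcode = tissue$barcode, in_tissue = 1L,
                      array_row = tissue$array_row,
                      array_col = tissue$array_col,
                      y_px = tissue$y_px, x_px = tissue$x_px)
    meta <- data.frame(barcode = tissue$barcode, sample = samples[i],
                       genotype = genotype, age = age,
                       region = tissue$region)
    parts[[i]] <- spot_dataset(counts, pos, meta)
    truth_act[[i]] <- act_dis
  }
  merged <- merge_samples(stats::setNames(parts, samples))
  merged$truth <- list(region = merged$meta$region,
                       activation = unlist(truth_act, use.names = FALSE),
                       spiked_genes = union(dam_genes(), reactive_panel()),
                       daa_genes = daa_genes(),
                       region_markers = region_markers,
                       driver_gene = "Cst7")
  merged
}

#' Simulate a single section with plaque-like focal activation
#'
#' One AD-7M-like sample in which a designated driver gene follows a smooth
#' focal intensity field (a sum of Gaussian plaque-like foci over the section)
#' rather than the region-block field, for testing the image-registration and
#' image-latent association stages. All other genes are either flat background
#' or weakly coupled bystanders.
#'
#' @param seed RNG seed
#' @param n_rows,n_cols,spacing tissue grid
#' @param n_genes gene universe size (driver plus background)
#' @param driver_fold fold of the driver gene at field value 1 (plaque-induced
#'   genes are strongly induced near plaques)
#' @param driver_baseline baseline NB mean of the driver gene
#' @param n_bystanders number of genes weakly coupled (fold 1.3) to the field
#' @param n_foci number of Gaussian foci in the field
#' @param dispersion NB size parameter
#' @return a `spot_dataset` with `truth$field` (per-spot field value in [0,1])
#'   and `truth$driver_gene`
#' @export
simulate_plaque_sample <- function(seed = 1, n_rows = 25, n_cols = 20,
                                   spacing = 12, n_genes = 500,
                                   driver_fold = 6, driver_baseline = 20,
                                   n_bystanders = 20, n_foci = 8,
                                   dispersion = 12) {
  set.seed(seed)
  design <- tissue_design(n_rows, n_cols, spacing, border_ring = FALSE,
                          layout = list(all = seq_len(n_rows) - 1L))
  tissue <- build_tissue(design)
  n_s <- nrow(tissue)
  cx <- stats::runif(n_foci, min(tissue$x_px), max(tissue$x_px))
  cy <- stats::runif(n_foci, min(tissue$y_px), max(tissue$y_px))
  sg <- stats::runif(n_foci, 2, 4) * spacing
  f <- rowSums(vapply(seq_len(n_foci), function(k)
    exp(-((tissue$x_px - cx[k])^2 + (tissue$y_px - cy[k])^2) / (2 * sg[k]^2)),
    numeric(n_s)))
  f <- f / max(f)
  genes <- c("Driver", sprintf("Gene%04d", seq_len(n_genes - 1)))
  bystanders <- genes[1 + seq_len(n_bystanders)]
  baseline <- stats::setNames(pmin(exp(stats::rnorm(n_genes, 0.2, 1)), 60), genes)
  baseline["Driver"] <- driver_baseline
  progs <- list(
    gene_program("background", genes, baseline[genes], fold = 1,
                 dispersion = dispersion),
    gene_program("driver", "Driver", driver_baseline, fold = driver_fold,
                 dispersion = dispersion),
    gene_program("bystander", bystanders, baseline[bystanders], fold = 1.3,
                 dispersion = dispersion))
  activation <- cbind(driver = f, bystander = f)
  counts <- simulate_counts(tissue, progs, activation, seed = seed + 1L)
  attr(counts, "mu") <- NULL
  pos <- data.frame(barcode = tissue$barcode, in_tissue = 1L,
                    array_row = tissue$array_row, array_col = tissue$array_col,
                    y_px = tissue$y_px, x_px = tissue$x_px)
  meta <- data.frame(barcode = tissue$barcode, sample = "AD_7M_r1",
                     genotype = "AD", age = "7M", region = tissue$region)
  out <- spot_dataset(counts, pos, meta)
  out$truth <- list(field = f, driver_gene = "Driver")
  out
}

#' Simulate a continuous microglial activation gradient
#'
#' Benchmark dataset for trajectory inference: each spot carries a latent
#' activation level in [0, 1] laid out as a smooth spatial gradient; reactive
#' panel genes scale as `fold^a`, homeostatic panel genes as
#' `homeostatic_fold^a`, and spots whose (noisy) activation exceeds a
#' threshold are labelled as the late disease group (AD, 7M), the rest as WT.
#'
#' @param seed RNG seed
#' @param n_rows,n_cols,spacing tissue grid (`n_rows * n_cols` spots)
#' @param n_bg_genes flat background genes added to the 28-gene panel
#' @param fold reactive-gene fold at activation 1
#' @param homeostatic_fold homeostatic-gene fold at activation 1 (< 1)
#' @param baseline_panel baseline NB mean of the panel genes (multi-cell
#'   spots pool counts, so core microglial genes sit in the tens per spot)
#' @param dispersion NB size parameter
#' @return a `spot_dataset` with `truth$activation` (the latent gradient)
#' @export
simulate_activation_gradient <- function(seed = 1, n_rows = 25, n_cols = 20,
                                         spacing = 12, n_bg_genes = 100,
                                         fold = 5, homeostatic_fold = 0.3,
                                         baseline_panel = 50, dispersion = 8) {
  set.seed(seed)
  design <- tissue_design(n_rows, n_cols, spacing, border_ring = FALSE,
                          layout = list(all = seq_len(n_rows) - 1L))
  tissue <- build_tissue(design)
  n_s <- nrow(tissue)
  a <- (tissue$x_px + tissue$y_px - min(tissue$x_px) - min(tissue$y_px))
  a <- a / max(a)
  a <- pmin(pmax(a + stats::rnorm(n_s, 0, 0.05), 0), 1)
  late <- (a + stats::rnorm(n_s, 0, 0.15)) > 0.6
  genes <- c(microglial_panel(), sprintf("Gene%04d", seq_len(n_bg_genes)))
  baseline <- stats::setNames(pmin(exp(stats::rnorm(length(genes), 0.2, 1)), 60),
                              genes)
  baseline[microglial_panel()] <- baseline_panel
  progs <- list(
    gene_program("background", genes, baseline[genes], fold = 1,
                 dispersion = dispersion),
    gene_program("reactive", reactive_panel(), baseline_panel, fold = fold,
                 dispersion = dispersion),
    gene_program("homeostatic", homeostatic_panel(), baseline_panel,
                 fold = homeostatic_fold, dispersion = dispersion))
  activation <- cbind(reactive = a, homeostatic = a)
  counts <- simulate_counts(tissue, progs, activation, seed = seed + 1L)
  attr(counts, "mu") <- NULL
  pos <- data.frame(barcode = tissue$barcode, in_tissue = 1L,
                    array_row = tissue$array_row, array_col = tissue$array_col,
                    y_px = tissue$y_px, x_px = tissue$x_px)
  meta <- data.frame(barcode = tissue$barcode,
                     sample = ifelse(late, "AD_7M_r1", "WT_3M_r1"),
                     genotype = ifelse(late, "AD", "WT"),
                     age = ifelse(late, "7M", "3M"))
  out <- spot_dataset(counts, pos, meta)
  out$truth <- list(activation = a, late = late)
  out
}

#' Render a plaque-like fluorescence image from a driver gene
#'
#' Splats each spot's driver-gene log-expression onto a pixel canvas and
#' divides by the same splat of a unit amplitude (a Gaussian kernel-regression
#' estimate), so that pixel intensity tracks the local mean driver expression
#' rather than the local spot density — a fluorescence image is a continuous
#' intensity field, not a spot-count field. The result is rescaled to [0, 1],
#' optionally deranged by a known transform (mapping reference-frame
#' coordinates to deranged-image coordinates), and Gaussian read noise is
#' added and clipped to [0, 1]. Landmark pairs relating the two frames are
#' returned for registration scoring.
#'
#' @param dataset a `spot_dataset` (must be non-empty)
#' @param driver_gene gene symbol present in the dataset
#' @param img_dim c(height, width) of the canvas in pixels
#' @param psf_sigma Gaussian PSF sigma in pixels (> 0)
#' @param noise_sd Gaussian read-noise sd (applied to the output image)
#' @param derange optional transform (see [tf_rigid()], [tf_affine()],
#'   [tf_chain()]) mapping reference coordinates to deranged coordinates
#' @param seed RNG seed for the noise
#' @return list with `image` (the deranged, noisy float image in [0, 1]),
#'   `reference` (the clean undisturbed image), `spot_px` (n x 2 matrix of
#'   spot centres in reference-image pixels), `landmarks` (data.frame
#'   `fixed_x`, `fixed_y`, `moving_x`, `moving_y`), and `spot_transform`
#'   (affine mapping dataset pixel coordinates into the reference image)
#' @export
render_plaque_image <- function(dataset, driver_gene, img_dim = c(256, 256),
                                psf_sigma = 8, noise_sd = 0.02,
                                derange = NULL, seed = 1) {
  if (ncol(dataset$counts) == 0) stopf("empty dataset")
  if (psf_sigma <= 0) stopf("psf_sigma must be > 0")
  if (!driver_gene %in% rownames(dataset$counts))
    stopf("driver gene '%s' not in dataset", driver_gene)
  set.seed(seed)
  h <- img_dim[1]; w <- img_dim[2]
  x <- dataset$positions$x_px; y <- dataset$positions$y_px
  margin <- 24
  sc <- min((w - 1 - 2 * margin) / max(diff(range(x)), 1),
            (h - 1 - 2 * margin) / max(diff(range(y)), 1))
  ox <- margin - sc * min(x); oy <- margin - sc * min(y)
  spot_tf <- tf_affine(diag(c(sc, sc)), c(ox, oy))
  px <- sc * x + ox; py <- sc * y + oy
  amp <- log1p(as.numeric(dataset$counts[driver_gene, ]))
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  ij <- cbind(pmin(pmax(round(py), 0), h - 1) + 1,
              pmin(pmax(round(px), 0), w - 1) + 1)
  for (k in seq_along(amp)) {
    num[ij[k, 1], ij[k, 2]] <- num[ij[k, 1], ij[k, 2]] + amp[k]
    den[ij[k, 1], ij[k, 2]] <- den[ij[k, 1], ij[k, 2]] + 1
  }
  num <- EBImage::gblur(num, sigma = psf_sigma)
  den <- EBImage::gblur(den, sigma = psf_sigma)
  img <- matrix(0, h, w)
  inside <- den > max(den) * 0.05  # outside the tissue the estimate is undefined
  img[inside] <- num[inside] / den[inside]
  ## fluorescence-like contrast: the in-tissue baseline is dim, foci bright
  if (any(inside) && max(img) > 0) {
    bg <- stats::quantile(img[inside], 0.10)
    img[inside] <- pmax(img[inside] - bg, 0)
    if (max(img) > 0) img <- img / max(img)
  }
  reference <- img
  lm_fixed <- cbind(
    x = c(margin, w - 1 - margin, margin, w - 1 - margin, (w - 1) / 2),
    y = c(margin, margin, h - 1 - margin, h - 1 - margin, (h - 1) / 2))
  if (!is.null(derange)) {
    out <- warp_image(reference, invert_transform(derange), c(h, w))
    lm_moving <- apply_transform(derange, lm_fixed)
  } else {
    out <- reference
    lm_moving <- lm_fixed
  }
  if (noise_sd > 0)
    out <- pmin(pmax(out + matrix(stats::rnorm(h * w, 0, noise_sd), h, w), 0), 1)
  list(image = out, reference = reference,
       spot_px = cbind(x = px, y = py),
       landmarks = data.frame(fixed_x = lm_fixed[, 1], fixed_y = lm_fixed[, 2],
                              moving_x = lm_moving[, 1],
                              moving_y = lm_moving[, 2]),
       spot_transform = spot_tf)
}
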