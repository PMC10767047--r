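test_that("build_tissue lays out the grid and honours explicit region bands", {
  tis <- build_tissue(tissue_design(10, 10, border_ring = FALSE,
                                    layout = list(all = 0:9)))
  expect_identical(nrow(tis), 100L)

  des <- tissue_design(10, 8, border_ring = FALSE,
                       layout = list(top = 0:3, WM = 4:5, bottom = 6:9))
  tis <- build_tissue(des)
  expect_identical(sum(tis$region == "WM"), 2L * 8L)
  ## deterministic construction: identical tables on repeated calls
  expect_identical(tis, build_tissue(des))
})

test_that("degenerate geometry errors name the empty region", {
  des <- tissue_design(6, 6, border_ring = TRUE,
                       layout = list(a = 0:0, b = 1:4, c = 5:5))
  ## rows 0 and 5 are swallowed by the border ring
  expect_error(build_tissue(des), "'a'")
})

test_that("default design yields every region non-empty and a connected WM band", {
  tis <- build_tissue(tissue_design(30, 20))
  expect_setequal(unique(tis$region),
                  c("cortex_outer", "cortex_inner", "hippocampus", "WM",
                    "thalamus", "striatum", "border"))
  wm_rows <- sort(unique(tis$array_row[tis$region == "WM"]))
  expect_identical(wm_rows, seq(min(wm_rows), max(wm_rows)))
})

test_that("simulate_counts follows the NB parameterization", {
  tis <- build_tissue(tissue_design(100, 100, border_ring = FALSE,
                                    layout = list(all = 0:99)))
  progs <- list(gene_program("p", "g1", baseline_mean = 5, fold = 2,
                             dispersion = 2))
  act <- cbind(p = rep(1, nrow(tis)))
  cnt <- simulate_counts(tis, progs, act, seed = 42)
  ## law of large numbers on the stated NB mean 5 * 2^1 = 10 over 10,000 spots
  expect_lt(abs(mean(cnt["g1", ]) - 10) / 10, 0.05)
  ## variance m + m^2/size = 10 + 50 = 60 within 15%
  expect_lt(abs(var(as.numeric(cnt["g1", ])) - 60) / 60, 0.15)
})

test_that("simulate_counts is bit-identical under a fixed seed", {
  tis <- build_tissue(tissue_design(5, 5, border_ring = FALSE,
                                    layout = list(all = 0:4)))
  progs <- list(gene_program("p", c("g1", "g2"), c(3, 7)))
  a <- simulate_counts(tis, progs, seed = 9)
  b <- simulate_counts(tis, progs, seed = 9)
  expect_identical(as.matrix(a), as.matrix(b))
})

test_that("fold = 1 gives identical expected counts regardless of activation", {
  tis <- build_tissue(tissue_design(4, 4, border_ring = FALSE,
                                    layout = list(all = 0:3)))
  progs <- list(gene_program("p", "g1", 5, fold = 1))
  act <- cbind(p = c(rep(1, 8), rep(0, 8)))
  cnt <- simulate_counts(tis, progs, act, seed = 1)
  mu <- attr(cnt, "mu")
  expect_equal(max(abs(mu - 5)), 0, tolerance = 1e-12)
})

test_that("spiked genes have larger expected means in activated spots", {
  tis <- build_tissue(tissue_design(4, 4, border_ring = FALSE,
                                    layout = list(all = 0:3)))
  progs <- list(gene_program("p", "g1", 5, fold = 3))
  act <- cbind(p = c(rep(1, 8), rep(0, 8)))
  mu <- attr(simulate_counts(tis, progs, act, seed = 1), "mu")
  expect_true(all(mu["g1", 1:8] > mu["g1", 9:16]))
})

test_that("the full study generator is seed-deterministic and truth-aligned", {
  a <- simulate_study(seed = 3, n_rows = 10, n_cols = 8, n_genes = 200,
                      n_region_markers = 8,
                      samples = c("WT_3M_r1", "AD_3M_r1"))
  b <- simulate_study(seed = 3, n_rows = 10, n_cols = 8, n_genes = 200,
                      n_region_markers = 8,
                      samples = c("WT_3M_r1", "AD_3M_r1"))
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(length(a$truth$region), ncol(a$counts))
  expect_identical(length(a$truth$activation), ncol(a$counts))
  ## WT spots carry zero disease activation outside the border
  wt <- a$meta$genotype == "WT" & a$truth$region != "border"
  expect_true(all(a$truth$activation[wt] == 0))
  ## AD 3M activation present in WM, absent in GM
  ad_wm <- a$meta$genotype == "AD" & a$truth$region == "WM"
  ad_gm <- a$meta$genotype == "AD" &
    a$truth$region %in% c("cortex_outer", "thalamus", "striatum")
  expect_true(all(a$truth$activation[ad_wm] > 0))
  expect_true(all(a$truth$activation[ad_gm] == 0))
})

test_that("activation fields respect range and age monotonicity", {
  expect_error(activation_field(wm_3m = 1.2), "\\[0, 1\\]")
  expect_error(activation_field(wm_3m = 0.9, wm_7m = 0.5), "monotone")
  f <- activation_field()
  expect_gte(f$wm_7m, f$wm_3m)
  a3 <- activation_at(f, "WM", "AD", "3M")
  a7 <- activation_at(f, "WM", "AD", "7M")
  expect_gte(a7, a3)
})

test_that("rendered plaque image is monotone in driver expression at spot centres", {
  ## well-separated spots so the PSF does not mix neighbours
  counts <- matrix(c(0L, 2L, 7L, 20L, 55L, 148L), nrow = 1,
                   dimnames = list("Driver", sprintf("s%d", 1:6)))
  pos <- data.frame(barcode = colnames(counts), in_tissue = 1L,
                    array_row = 0L, array_col = 0:5,
                    y_px = 50, x_px = seq(10, 260, by = 50))
  meta <- data.frame(barcode = colnames(counts), sample = "s", genotype = "AD",
                     age = "7M")
  ds <- spot_dataset(counts, pos, meta)
  r <- render_plaque_image(ds, "Driver", img_dim = c(128, 512), psf_sigma = 2,
                           noise_sd = 0)
  vals <- interp_bilinear(r$reference, r$spot_px[, 1], r$spot_px[, 2])
  expect_true(all(diff(vals) > 0))
})

test_that("an all-zero driver gives background noise only", {
  counts <- matrix(0L, 2, 4, dimnames = list(c("Driver", "g2"), paste0("s", 1:4)))
  counts["g2", ] <- 1L
  ds <- helper_tiny_dataset(counts, n_spots = 4)
  r <- render_plaque_image(ds, "Driver", img_dim = c(64, 64), noise_sd = 0.01,
                           seed = 1)
  expect_lt(max(r$reference), 1e-12)
  expect_lt(max(abs(r$image)), 0.06)  # pure clipped read noise
})

test_that("a pure translation derangement shifts every landmark by exactly it", {
  ds <- simulate_plaque_sample(seed = 1, n_rows = 8, n_cols = 8, n_genes = 30,
                               n_bystanders = 5)
  r <- render_plaque_image(ds, "Driver", derange = tf_translation(5, 3),
                           noise_sd = 0, seed = 1)
  expect_equal(r$landmarks$moving_x - r$landmarks$fixed_x, rep(5, 5))
  expect_equal(r$landmarks$moving_y - r$landmarks$fixed_y, rep(3, 5))
})

test_that("render errors on empty dataset and unknown driver", {
  ds <- helper_tiny_dataset()
  expect_error(render_plaque_image(ds, "nope"), "driver")
  empty <- subset_spots(ds, integer(0))
  expect_error(render_plaque_image(empty, "g1"), "empty")
})
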