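test_that("stack projection flattens as specified", {
  m <- matrix(runif(12), 3, 4)
  expect_identical(project_stack(m, "max"), m)
  st <- array(c(1, 0, 0, 0, 0, 0, 2, 0), c(2, 2, 2))
  expect_equal(project_stack(st, "max"), matrix(c(1, 0, 2, 0), 2, 2))
  expect_equal(project_stack(st, "sum"), matrix(c(1, 0, 2, 0), 2, 2))
  # sum-projection dominates max-projection pixelwise for non-negative input
  for (s in 1:5) {
    set.seed(s)
    st <- array(runif(3 * 4 * 5), c(3, 4, 5))
    expect_true(all(project_stack(st, "sum") >= project_stack(st, "max")))
  }
  expect_error(project_stack(st, "median"))
})

test_that("thresholding zeroes sub-threshold pixels", {
  g <- matrix(c(1, 6, 10, 2), 2, 2)
  out <- apply_threshold(g, list("fixed", value = 5))
  expect_equal(out$grid, matrix(c(0, 6, 10, 0), 2, 2))
  expect_equal(out$threshold, 5)
  z <- matrix(0, 4, 4)
  outz <- apply_threshold(z, "otsu")
  expect_equal(outz$grid, z)
  expect_false(any(outz$mask))
})

test_that("otsu separates a two-level image and matches the exhaustive scan", {
  set.seed(7)
  v <- c(rep(10, 900), rep(100, 100))
  thr <- otsu_threshold(v)
  expect_gt(thr, 10)
  expect_lt(thr, 100)
  # random continuous images: exhaustive scan oracle agrees exactly
  for (s in 1:5) {
    set.seed(s)
    img <- c(rlnorm(500, 0, 1), rlnorm(60, 3, 0.3))
    expect_identical(otsu_threshold(img), oracle_otsu(img))
  }
  expect_warning(otsu_threshold(c(0, 5, 5, 5)), "constant")
})

test_that("MTOC detection finds the spot with a lexicographic tie rule", {
  g <- matrix(0, 64, 64)
  g[12, 40] <- 7
  mask <- matrix(TRUE, 64, 64)
  expect_equal(unname(detect_mtoc(g, mask, smooth_sigma_px = 0)), c(12, 40))
  g2 <- matrix(0, 8, 8)
  g2[3, 7] <- 1
  g2[5, 2] <- 1
  expect_equal(unname(detect_mtoc(g2, matrix(TRUE, 8, 8),
                                  smooth_sigma_px = 0)), c(3, 7))
  expect_error(detect_mtoc(matrix(0, 4, 4), matrix(TRUE, 4, 4)),
               "no MTOC signal")
})

test_that("MTOC detection recovers planted positions within 2 px", {
  for (s in 0:19) {
    f <- generate_field(field_sim_params(
      field_shape = c(128, 128), n_cells = 1, cell_radius_um = 3,
      n_lysosomes_per_cell = 10, psf_sigma_um = 0.3,
      noise = list("gaussian", sd = 0.02), seed = s
    ))
    q <- quantify_field(f, quant_config(min_cells_per_field = 1L))
    err <- sqrt((q$mtoc_row - f$truth$cells$mtoc_row)^2 +
                  (q$mtoc_col - f$truth$cells$mtoc_col)^2)
    expect_lt(err, 2)
  }
})

test_that("circular ROI mask follows the centre-in pixel rule", {
  shape <- c(101, 101)
  m <- circular_roi_mask(c(51, 51), 2, 0.1, shape)
  # brute-force pixel enumeration
  cnt <- 0L
  for (r in 1:101) {
    for (c in 1:101) {
      if (((r - 51)^2 + (c - 51)^2) * 0.01 <= 4) cnt <- cnt + 1L
    }
  }
  expect_identical(sum(m), cnt)
  expect_true(m[51, 71])   # exactly on the boundary: included
  expect_false(m[51, 72])
  # radius below half a pixel: centre pixel only
  m1 <- circular_roi_mask(c(10, 10), 0.04, 0.1, c(20, 20))
  expect_identical(sum(m1), 1L)
  expect_true(m1[10, 10])
  # corner centre: quarter disc
  mc <- circular_roi_mask(c(1, 1), 2, 0.1, shape)
  expect_lt(abs(sum(mc) / cnt - 0.25), 0.05)
  expect_error(circular_roi_mask(c(0, 5), 2, 0.1, shape), "outside")
})

test_that("cell ratio hits the 0/1 extremes and recovers planted mass", {
  px <- 0.1
  lyso <- matrix(0, 80, 80)
  mtoc <- matrix(0, 80, 80)
  mtoc[40, 40] <- 10
  mask <- matrix(TRUE, 80, 80)
  fld <- function(l) list(channels = list(lysosome = l, mtoc = mtoc),
                          pixel_size_um = px)
  all_in <- lyso
  all_in[38:42, 38:42] <- 1
  q <- quantify_cell(fld(all_in), mask, cfg_noiseless())
  expect_equal(q$ratio, 1)
  all_out <- lyso
  all_out[70:75, 70:75] <- 1
  q <- quantify_cell(fld(all_out), mask, cfg_noiseless())
  expect_equal(q$ratio, 0)
  # planted 30% of punctum mass within 2 um of the MTOC
  f <- generate_field(field_sim_params(
    field_shape = c(224, 224), n_cells = 1, cell_radius_um = 7,
    n_lysosomes_per_cell = 400, perinuclear_fraction = 0.25,
    perinuclear_sigma_um = 0.5, psf_sigma_um = 0.15, seed = 2
  ))
  q <- quantify_field(f, cfg_noiseless())
  expect_lt(abs(q$ratio - f$truth$cells$planted_fraction), 0.015)
})

test_that("field quantification flags low cell counts and aggregates", {
  f <- small_field(seed = 31, n_cells = 3L)
  cfg <- quant_config(threshold = list("fixed", value = 0),
                      min_cells_per_field = 10L)
  q <- quantify_field(f, cfg)
  expect_identical(nrow(q), 3L)
  expect_true(attr(q, "low_cell_count"))
  cfg3 <- cfg_noiseless()
  q3 <- quantify_field(f, cfg3)
  expect_false(attr(q3, "low_cell_count"))
  # per-field aggregate equals the intensity-weighted mean of cell ratios
  qa <- quantify_field(f, quant_config(threshold = list("fixed", value = 0),
                                       aggregation = "per_field",
                                       min_cells_per_field = 3L))
  expect_equal(qa$ratio,
               sum(q3$ratio * q3$cell_intensity) / sum(q3$cell_intensity))
  expect_error(quantify_field(f, cfg, cell_labels = NULL), "mask")
})

test_that("ratios stay in [0,1], grow with ROI radius, and ignore intensity scale", {
  f <- small_field(seed = 17, perinuclear_fraction = 0.5)
  radii <- c(0.5, 1, 2, 3, 5)
  prev <- rep(0, 3)
  for (r in radii) {
    q <- quantify_field(f, quant_config(roi_radius_um = r,
                                        threshold = list("fixed", value = 0),
                                        min_cells_per_field = 3L))
    expect_true(all(q$ratio >= 0 & q$ratio <= 1))
    expect_true(all(q$ratio >= prev - 1e-12))
    prev <- q$ratio
  }
  # scaling the lysosome channel by k leaves every ratio unchanged
  for (k in c(0.2, 7)) {
    f2 <- f
    f2$channels$lysosome <- f$channels$lysosome * k
    q1 <- quantify_field(f, quant_config(threshold = list("fixed", value = 1e-4),
                                         min_cells_per_field = 3L))
    q2 <- quantify_field(f2, quant_config(threshold = list("fixed", value = 1e-4 * k),
                                          min_cells_per_field = 3L))
    expect_equal(q1$ratio, q2$ratio)
    qo1 <- quantify_field(f, quant_config(min_cells_per_field = 3L))
    qo2 <- quantify_field(f2, quant_config(min_cells_per_field = 3L))
    expect_equal(qo1$ratio, qo2$ratio)
  }
})

test_that("mean ratio increases strictly with the planted perinuclear fraction", {
  fractions <- c(0.2, 0.5, 0.8)
  means <- vapply(fractions, function(fr) {
    ratios <- unlist(lapply(1:4, function(s) {
      quantify_field(small_field(seed = 100 * s + round(100 * fr),
                                 perinuclear_fraction = fr, n_cells = 2L,
                                 shape = c(160L, 160L)),
                     cfg_noiseless())$ratio
    }))
    mean(ratios)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("clustering values are the ratio relative to the control mean", {
  d <- data.frame(group = c("ctrl", "ctrl", "treated"),
                  ratio = c(0.2, 0.4, 0.6))
  cv <- clustering_values(d, "ctrl")
  expect_equal(cv$clustering_value, c(2 / 3, 4 / 3, 2), tolerance = 1e-12)
  expect_identical(mean(cv$clustering_value[cv$group == "ctrl"]), 1)
  set.seed(4)
  d2 <- data.frame(group = rep(c("a", "b"), each = 200),
                   ratio = runif(400, 0.2, 0.6))
  cv2 <- clustering_values(d2, "a")
  expect_lt(abs(mean(cv2$clustering_value[cv2$group == "b"]) - 1), 0.1)
  expect_error(clustering_values(d, "absent"), "control")
  expect_error(clustering_values(data.frame(group = "c", ratio = 0), "c"),
               "zero")
})
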