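test_that("field generation is a pure function of params and seed", {
  p <- field_sim_params(field_shape = c(176, 176), n_cells = 2,
                        cell_radius_um = 3, n_lysosomes_per_cell = 20,
                        seed = 42)
  f1 <- generate_field(p)
  f2 <- generate_field(p)
  expect_identical(f1$channels, f2$channels)
  expect_identical(f1$truth$cells, f2$truth$cells)
  expect_identical(f1$truth$lysosomes, f2$truth$lysosomes)
})

test_that("fully perinuclear placement puts all punctum mass in a 2 um ROI", {
  f <- generate_field(field_sim_params(
    field_shape = c(160, 160), n_cells = 2, cell_radius_um = 3,
    n_lysosomes_per_cell = 50, perinuclear_fraction = 1,
    perinuclear_sigma_um = 0.3, psf_sigma_um = 0, seed = 5
  ))
  # sigma = 0.3 um against a 2 um ROI: all draws fall within 6.7 sigma
  expect_equal(f$truth$cells$planted_fraction, c(1, 1))
})

test_that("uniform placement matches a Monte Carlo cytoplasm-overlap estimate", {
  f <- generate_field(field_sim_params(
    field_shape = c(256, 256), n_cells = 1, cell_radius_um = 8,
    n_lysosomes_per_cell = 1e5, perinuclear_fraction = 0,
    psf_sigma_um = 0, seed = 0
  ))
  cl <- f$truth$cells
  # independent rejection sampler over the same ellipse geometry
  set.seed(1)
  rot <- matrix(c(cos(cl$theta), sin(cl$theta),
                  -sin(cl$theta), cos(cl$theta)), 2, 2)
  n <- 1e5
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < n) {
    cand <- cbind(runif(n, -cl$semi_major_px, cl$semi_major_px),
                  runif(n, -cl$semi_minor_px, cl$semi_minor_px))
    e <- (cand[, 1] / cl$semi_major_px)^2 + (cand[, 2] / cl$semi_minor_px)^2
    en <- (cand[, 1] / (0.45 * cl$semi_major_px))^2 +
      (cand[, 2] / (0.45 * cl$semi_minor_px))^2
    keep <- e <= 1 & en > 1
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts <- pts[seq_len(n), ]
  abs_pts <- t(rot %*% t(pts)) +
    matrix(c(cl$center_row, cl$center_col), n, 2, byrow = TRUE)
  d2 <- (abs_pts[, 1] - cl$mtoc_row)^2 + (abs_pts[, 2] - cl$mtoc_col)^2
  expected <- mean(d2 <= 20^2)  # 2 um ROI at 0.1 um/px
  se <- sqrt(expected * (1 - expected) / n) * sqrt(2)
  expect_lt(abs(cl$planted_fraction - expected), 4 * se + 1e-6)
})

test_that("rendered lysosome intensity is conserved before noise", {
  f <- small_field(seed = 9)
  total <- sum(f$channels$lysosome)
  expect_lt(abs(total + f$truth$clipped_intensity - 3 * 40) / (3 * 40),
            0.005)
})

test_that("stored planted fraction is exactly reproducible from positions", {
  f <- small_field(seed = 13, perinuclear_fraction = 0.4)
  expect_identical(planted_roi_fraction(f), f$truth$cells$planted_fraction)
})

test_that("each MTOC lies inside its own cell mask and cells are disjoint", {
  f <- small_field(seed = 21, n_cells = 3L)
  lab <- f$truth$cell_labels
  for (i in seq_len(nrow(f$truth$cells))) {
    r <- round(f$truth$cells$mtoc_row[i])
    c <- round(f$truth$cells$mtoc_col[i])
    expect_identical(lab[r, c], i)
  }
  # nucleus pixels sit inside the same cell's mask
  nuc <- f$truth$nucleus_labels
  expect_true(all(lab[nuc > 0] == nuc[nuc > 0]))
})

test_that("impossible geometry is rejected", {
  expect_error(
    generate_field(field_sim_params(field_shape = c(64, 64), n_cells = 4,
                                    cell_radius_um = 3, seed = 1)),
    "overlap|too large"
  )
  expect_error(field_sim_params(pixel_size_um = 0), "pixel_size_um|is_number")
  expect_error(field_sim_params(perinuclear_fraction = 1.2), "fraction")
})

test_that("noise models preserve non-negativity and change only intensities", {
  pg <- field_sim_params(field_shape = c(96, 96), n_cells = 1,
                         cell_radius_um = 2.5, n_lysosomes_per_cell = 15,
                         background_level = 0.01,
                         noise = list("gaussian", sd = 0.05), seed = 3)
  fg <- generate_field(pg)
  expect_true(all(fg$channels$lysosome >= 0))
  pp <- field_sim_params(field_shape = c(96, 96), n_cells = 1,
                         cell_radius_um = 2.5, n_lysosomes_per_cell = 15,
                         background_level = 0.01,
                         noise = list("poisson", photons_per_unit = 500),
                         seed = 3)
  fp <- generate_field(pp)
  expect_true(all(fp$channels$lysosome >= 0))
  # truth is computed pre-noise: identical to the noiseless run
  pn <- field_sim_params(field_shape = c(96, 96), n_cells = 1,
                         cell_radius_um = 2.5, n_lysosomes_per_cell = 15,
                         background_level = 0.01, noise = "none", seed = 3)
  fn <- generate_field(pn)
  expect_identical(fg$truth$cells, fn$truth$cells)
})
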