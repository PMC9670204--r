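#' Parameters for the synthetic fluorescence field generator
#'
#' Bundles and validates everything [generate_field()] needs to render a
#' multichannel field of non-overlapping cells with planted lysosome puncta,
#' one microtubule-organising centre (MTOC) spot per cell, and a nucleus
#' channel.  Defaults emulate a confocal set-up at 0.1 micrometre pixels.
#'
#' @param field_shape integer vector `(rows, cols)` in pixels.
#' @param pixel_size_um physical pixel size, micrometres per pixel (> 0).
#' @param n_cells number of cells to place (non-overlapping ellipses).
#' @param cell_radius_um semi-major axis of the cell ellipse, micrometres.
#' @param n_lysosomes_per_cell puncta planted per cell.
#' @param perinuclear_fraction probability, in `[0, 1]`, that a punctum is
#'   drawn from the perinuclear cluster around the MTOC rather than
#'   uniformly over the cytoplasm (cell minus nucleus).
#' @param perinuclear_sigma_um isotropic Gaussian spread of the perinuclear
#'   cluster, micrometres.
#' @param mtoc_offset_um distance of the MTOC from the nucleus edge,
#'   micrometres (clamped so the MTOC always stays inside the cell).
#' @param psf_sigma_um Gaussian point-spread width used to render puncta and
#'   the MTOC spot; 0 renders each punctum into its nearest pixel.
#' @param background_level constant background added to every channel.
#' @param noise noise model: `"none"`, `list("gaussian", sd = )`, or
#'   `list("poisson", photons_per_unit = )`.  Gaussian noise is additive and
#'   clipped at zero; Poisson noise draws counts at
#'   `intensity * photons_per_unit` and rescales back.
#' @param z_planes number of z planes (>= 1).  Puncta are assigned a plane
#'   uniformly at random; the MTOC sits on the middle plane.
#' @param mtoc_amplitude total integrated intensity of the MTOC spot.
#' @param nucleus_scale nucleus semi-axes as a fraction of the cell's.
#' @param seed integer seed; together with the parameters it fully
#'   determines the output.
#' @return An object of class `field_sim_params`.
#' @seealso [generate_field()]
#' @export
field_sim_params <- function(field_shape = c(1024L, 1024L),
                             pixel_size_um = 0.1,
                             n_cells = 10L,
                             cell_radius_um = 8,
                             n_lysosomes_per_cell = 60L,
                             perinuclear_fraction = 0.5,
                             perinuclear_sigma_um = 1,
                             mtoc_offset_um = 0.5,
                             psf_sigma_um = 0.2,
                             background_level = 0,
                             noise = "none",
                             z_planes = 1L,
                             mtoc_amplitude = 100,
                             nucleus_scale = 0.45,
                             seed = 1L) {
  stopifnot(
    length(field_shape) == 2L, all(field_shape >= 16),
    is_number(pixel_size_um), is_count(n_cells),
    is_number(cell_radius_um), cell_radius_um > 0,
    is_count(n_lysosomes_per_cell, min = 0L),
    is_number(perinuclear_fraction),
    is_number(perinuclear_sigma_um), perinuclear_sigma_um > 0,
    is_number(mtoc_offset_um), mtoc_offset_um >= 0,
    is_number(psf_sigma_um), psf_sigma_um >= 0,
    is_number(background_level), background_level >= 0,
    is_count(z_planes), is_number(mtoc_amplitude), mtoc_amplitude > 0,
    is_number(nucleus_scale), nucleus_scale > 0, nucleus_scale < 1,
    is_count(seed, min = 0L)
  )
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (perinuclear_fraction < 0 || perinuclear_fraction > 1) {
    stop("perinuclear_fraction must lie in [0, 1]")
  }
  noise <- normalize_noise_model(noise)
  structure(
    list(
      field_shape = as.integer(field_shape), pixel_size_um = pixel_size_um,
      n_cells = as.integer(n_cells), cell_radius_um = cell_radius_um,
      n_lysosomes_per_cell = as.integer(n_lysosomes_per_cell),
      perinuclear_fraction = perinuclear_fraction,
      perinuclear_sigma_um = perinuclear_sigma_um,
      mtoc_offset_um = mtoc_offset_um, psf_sigma_um = psf_sigma_um,
      background_level = background_level, noise = noise,
      z_planes = as.integer(z_planes), mtoc_amplitude = mtoc_amplitude,
      nucleus_scale = nucleus_scale, seed = as.integer(seed)
    ),
    class = "field_sim_params"
  )
}

#' @noRd
normalize_noise_model <- function(noise) {
  if (is.character(noise) && length(noise) == 1L) noise <- list(noise)
  type <- noise[[1L]]
  if (!type %in% c("none", "gaussian", "poisson")) {
    stop("noise model must be one of 'none', 'gaussian', 'poisson'")
  }
  if (type == "gaussian") {
    sd <- noise$sd %||% noise[[2L]]
    stopifnot(is_number(sd), sd >= 0)
    list(type = "gaussian", sd = sd)
  } else if (type == "poisson") {
    ppu <- noise$photons_per_unit %||% 1000
    stopifnot(is_number(ppu), ppu > 0)
    list(type = "poisson", photons_per_unit = ppu)
  } else {
    list(type = "none")
  }
}

#' Generate a synthetic multichannel fluorescence field with ground truth
#'
#' Places `n_cells` non-overlapping elliptical cells (uniform random
#' orientation, concentric elliptical nucleus), plants one MTOC per cell
#' just outside the nucleus, and scatters lysosome puncta: with probability
#' `perinuclear_fraction` a punctum is drawn from an isotropic Gaussian of
#' width `perinuclear_sigma_um` centred on the MTOC, otherwise uniformly
#' over the cytoplasm (inside the cell, outside the nucleus).  Puncta are
#' rendered as unit-integral Gaussians of width `psf_sigma_um`; the MTOC as
#' a single bright Gaussian spot; noise is applied last.
#'
#' The returned truth records continuous (pre-render) punctum and MTOC
#' positions and, per cell, the planted fraction of punctum mass within
#' `truth_roi_radius_um` of the MTOC, computed from the noiseless pre-blur
#' positions.
#'
#' @param params a [field_sim_params()] object.
#' @param field_id identifier stored with the field.
#' @param truth_roi_radius_um radius (micrometres) at which the planted
#'   in-ROI fraction is evaluated and stored in the truth table.
#' @return An object of class `synthetic_field`: a list with `channels`
#'   (named intensity grids `lysosome`, `mtoc`, `nucleus`; matrices, or
#'   3-D arrays when `z_planes > 1`), `pixel_size_um`, `field_id`, `params`,
#'   and `truth` (cell/nucleus label matrices, per-cell table with MTOC
#'   position and planted ROI fraction, per-punctum table, and the total
#'   punctum intensity clipped at the field border).
#' @examples
#' p <- field_sim_params(field_shape = c(192, 192), n_cells = 3,
#'                       cell_radius_um = 3, n_lysosomes_per_cell = 30,
#'                       perinuclear_fraction = 0.8, seed = 7)
#' fld <- generate_field(p)
#' fld$truth$cells$planted_fraction
#' @export
generate_field <- function(params, field_id = "field_1",
                           truth_roi_radius_um = 2) {
  stopifnot(inherits(params, "field_sim_params"))
  px <- params$pixel_size_um
  nr <- params$field_shape[1L]
  nc <- params$field_shape[2L]
  a_px <- params$cell_radius_um / px

  geom <- with_seed(
    derive_seed(params$seed, 0L, stream = 1L),
    place_cells(nr, nc, params$n_cells, a_px, params$nucleus_scale,
                params$mtoc_offset_um / px)
  )

  cell_labels <- matrix(0L, nr, nc)
  nucleus_labels <- matrix(0L, nr, nc)
  for (i in seq_len(params$n_cells)) {
    g <- geom[[i]]
    cell_labels <- paint_ellipse(cell_labels, g$center, g$a, g$b, g$theta, i)
    nucleus_labels <- paint_ellipse(nucleus_labels, g$center,
                                    g$a * params$nucleus_scale,
                                    g$b * params$nucleus_scale, g$theta, i)
  }

  # puncta: per-cell sub-streams so cell i's draw is independent of n_cells
  sig_peri <- params$perinuclear_sigma_um / px
  lys <- vector("list", params$n_cells)
  for (i in seq_len(params$n_cells)) {
    g <- geom[[i]]
    lys[[i]] <- with_seed(
      derive_seed(params$seed, i, stream = 2L),
      sample_puncta(params$n_lysosomes_per_cell, params$perinuclear_fraction,
                    g, sig_peri, params$nucleus_scale, params$z_planes)
    )
    lys[[i]]$cell_id <- rep.int(i, nrow(lys[[i]]))
  }
  lysosomes <- do.call(rbind, lys)

  dims <- c(nr, nc, params$z_planes)
  sig_psf <- params$psf_sigma_um / px
  lyso_ch <- array(0, dims)
  clipped <- 0
  if (nrow(lysosomes)) {
    for (j in seq_len(nrow(lysosomes))) {
      res <- add_gaussian_spot(lyso_ch[, , lysosomes$z[j]],
                               lysosomes$row[j], lysosomes$col[j], sig_psf)
      lyso_ch[, , lysosomes$z[j]] <- res$grid
      clipped <- clipped + res$clipped
    }
  }
  if (clipped > 1e-9 * max(1, nrow(lysosomes))) {
    message(sprintf("generate_field: %.4g punctum intensity units clipped at the field border", clipped))
  }

  mtoc_ch <- array(0, dims)
  z_mid <- (params$z_planes + 1L) %/% 2L
  sig_mtoc <- max(sig_psf, 1)
  for (i in seq_len(params$n_cells)) {
    g <- geom[[i]]
    res <- add_gaussian_spot(mtoc_ch[, , z_mid], g$mtoc[1L], g$mtoc[2L],
                             sig_mtoc, mass = params$mtoc_amplitude)
    mtoc_ch[, , z_mid] <- res$grid
  }

  nuc_ch <- array(rep(as.numeric(nucleus_labels > 0L), params$z_planes), dims)

  channels <- list(lysosome = lyso_ch, mtoc = mtoc_ch, nucleus = nuc_ch)
  channels <- lapply(channels, function(ch) ch + params$background_level)
  channels <- with_seed(
    derive_seed(params$seed, 0L, stream = 3L),
    lapply(channels, apply_noise, model = params$noise)
  )
  if (params$z_planes == 1L) {
    channels <- lapply(channels, function(ch) array(ch, c(nr, nc)))
  }

  cells <- data.frame(
    cell_id = seq_len(params$n_cells),
    center_row = vapply(geom, function(g) g$center[1L], 0),
    center_col = vapply(geom, function(g) g$center[2L], 0),
    semi_major_px = vapply(geom, function(g) g$a, 0),
    semi_minor_px = vapply(geom, function(g) g$b, 0),
    theta = vapply(geom, function(g) g$theta, 0),
    mtoc_row = vapply(geom, function(g) g$mtoc[1L], 0),
    mtoc_col = vapply(geom, function(g) g$mtoc[2L], 0)
  )
  cells$planted_fraction <- planted_fraction_by_cell(
    cells, lysosomes, truth_roi_radius_um / px
  )

  structure(
    list(
      channels = channels, pixel_size_um = px, field_id = field_id,
      params = params,
      truth = list(
        cell_labels = cell_labels, nucleus_labels = nucleus_labels,
        cells = cells, lysosomes = lysosomes,
        roi_radius_um = truth_roi_radius_um, clipped_intensity = clipped
      )
    ),
    class = "synthetic_field"
  )
}

#' @export
print.synthetic_field <- function(x, ...) {
  d <- dim(x$channels$lysosome)
  cat(sprintf(
    "<synthetic_field '%s'> %d x %d px (%.3g um/px), %d z-plane(s), %d cells, %d puncta\n",
    x$field_id, nrow(x$truth$cell_labels), ncol(x$truth$cell_labels),
    x$pixel_size_um, if (length(d) == 3L) d[3L] else 1L,
    nrow(x$truth$cells), nrow(x$truth$lysosomes)
  ))
  invisible(x)
}

#' Recompute the planted in-ROI fraction from stored punctum positions
#'
#' Each punctum carries unit mass at its continuous planted position; the
#' fraction is the share of a cell's puncta lying within `roi_radius_um`
#' of that cell's true MTOC position.  Used to check truth consistency and
#' to evaluate alternative ROI radii without re-simulating.
#'
#' @param field a `synthetic_field`.
#' @param roi_radius_um ROI radius in micrometres; defaults to the radius
#'   stored in the field's truth.
#' @return numeric vector of per-cell fractions, ordered by `cell_id`.
#' @export
planted_roi_fraction <- function(field, roi_radius_um = NULL) {
  stopifnot(inherits(field, "synthetic_field"))
  r_um <- roi_radius_um %||% field$truth$roi_radius_um
  planted_fraction_by_cell(field$truth$cells, field$truth$lysosomes,
                           r_um / field$pixel_size_um)
}

#' @noRd
planted_fraction_by_cell <- function(cells, lysosomes, radius_px) {
  vapply(seq_len(nrow(cells)), function(i) {
    p <- lysosomes[lysosomes$cell_id == cells$cell_id[i], , drop = FALSE]
    if (!nrow(p)) return(NA_real_)
    d2 <- (p$row - cells$mtoc_row[i])^2 + (p$col - cells$mtoc_col[i])^2
    mean(d2 <= radius_px^2)
  }, 0)
}

# --- geometry internals -----------------------------------------------------

#' Place non-overlapping elliptical cells; error after 1000 attempts/cell.
#' @noRd
place_cells <- function(nr, nc, n_cells, a_px, nucleus_scale, offset_px) {
  margin <- a_px + 1
  if (2 * margin >= nr || 2 * margin >= nc) {
    stop("cell radius too large for the field")
  }
  geom <- vector("list", n_cells)
  centers <- matrix(0, 0, 2)
  radii <- numeric(0)
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (attempt in seq_len(1000L)) {
      ctr <- c(stats::runif(1, margin, nr - margin),
               stats::runif(1, margin, nc - margin))
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums((centers - rep(ctr, each = nrow(centers)))^2)) >
              radii + a_px + 1)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("could not place cell %d without overlap after 1000 attempts", i))
    }
    aspect <- stats::runif(1, 0.65, 1)
    theta <- stats::runif(1, 0, pi)
    b_px <- a_px * aspect
    # MTOC: step from the nucleus edge outward along a random radial
    # direction; clamp to the midpoint between nucleus and cell edge so it
    # always stays strictly inside the cell.
    t_ang <- stats::runif(1, 0, 2 * pi)
    edge <- nucleus_scale * c(a_px * cos(t_ang), b_px * sin(t_ang))
    d_nuc <- sqrt(sum(edge^2))
    u <- edge / d_nuc
    d_cell <- 1 / sqrt((u[1L] / a_px)^2 + (u[2L] / b_px)^2)
    d_mtoc <- min(d_nuc + offset_px, (d_nuc + d_cell) / 2)
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    mtoc <- ctr + as.numeric(rot %*% (u * d_mtoc))
    geom[[i]] <- list(center = ctr, a = a_px, b = b_px, theta = theta,
                      mtoc = mtoc)
    centers <- rbind(centers, ctr)
    radii <- c(radii, a_px)
  }
  geom
}

#' @noRd
paint_ellipse <- function(labels, center, a, b, theta, value) {
  nr <- nrow(labels)
  nc <- ncol(labels)
  r0 <- max(1L, floor(center[1L] - a))
  r1 <- min(nr, ceiling(center[1L] + a))
  c0 <- max(1L, floor(center[2L] - a))
  c1 <- min(nc, ceiling(center[2L] + a))
  rows <- r0:r1
  cols <- c0:c1
  dr <- outer(rows - center[1L], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - center[2L])
  xf <- cos(theta) * dr + sin(theta) * dc
  yf <- -sin(theta) * dr + cos(theta) * dc
  inside <- (xf / a)^2 + (yf / b)^2 <= 1
  block <- labels[rows, cols]
  block[inside] <- value
  labels[rows, cols] <- block
  labels
}

#' Sample punctum positions for one cell (continuous pixel coordinates).
#' @noRd
sample_puncta <- function(n, peri_fraction, g, sigma_px, nucleus_scale,
                          z_planes) {
  rot <- matrix(c(cos(g$theta), sin(g$theta), -sin(g$theta), cos(g$theta)),
                2, 2)
  peri <- stats::runif(n) < peri_fraction
  pos <- matrix(0, n, 2)
  for (j in seq_len(n)) {
    if (peri[j]) {
      pos[j, ] <- g$mtoc + sigma_px * stats::rnorm(2)
    } else {
      repeat {
        f <- c(stats::runif(1, -g$a, g$a), stats::runif(1, -g$b, g$b))
        e <- (f[1L] / g$a)^2 + (f[2L] / g$b)^2
        en <- (f[1L] / (g$a * nucleus_scale))^2 +
          (f[2L] / (g$b * nucleus_scale))^2
        if (e <= 1 && en > 1) break
      }
      pos[j, ] <- g$center + as.numeric(rot %*% f)
    }
  }
  data.frame(
    row = pos[, 1L], col = pos[, 2L],
    z = if (z_planes > 1L) sample.int(z_planes, n, replace = TRUE)
        else rep.int(1L, n),
    perinuclear = peri
  )
}

# --- rendering internals ----------------------------------------------------

#' Add one Gaussian spot of integrated intensity `mass` at a continuous
#' (row, col); the discrete kernel is normalised to unit sum before
#' clipping at the field border, so `clipped` is exactly the mass lost.
#' @noRd
add_gaussian_spot <- function(grid, row, col, sigma_px, mass = 1) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  if (sigma_px <= 0) {
    r <- round(row)
    c <- round(col)
    if (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      grid[r, c] <- grid[r, c] + mass
      return(list(grid = grid, clipped = 0))
    }
    return(list(grid = grid, clipped = mass))
  }
  rad <- max(1L, as.integer(ceiling(4 * sigma_px)))
  rows <- (round(row) - rad):(round(row) + rad)
  cols <- (round(col) - rad):(round(col) + rad)
  kr <- exp(-(rows - row)^2 / (2 * sigma_px^2))
  kc <- exp(-(cols - col)^2 / (2 * sigma_px^2))
  kern <- outer(kr, kc)
  kern <- kern * (mass / sum(kern))
  rkeep <- rows >= 1 & rows <= nr
  ckeep <- cols >= 1 & cols <= nc
  sub <- kern[rkeep, ckeep, drop = FALSE]
  grid[rows[rkeep], cols[ckeep]] <- grid[rows[rkeep], cols[ckeep]] + sub
  list(grid = grid, clipped = mass - sum(sub))
}

#' @noRd
apply_noise <- function(ch, model) {
  if (model$type == "none") return(ch)
  if (model$type == "gaussian") {
    if (model$sd == 0) return(ch)
    out <- ch + stats::rnorm(length(ch), sd = model$sd)
    return(array(pmax(out, 0), dim(ch)))
  }
  ppu <- model$photons_per_unit
  array(stats::rpois(length(ch), lambda = as.numeric(ch) * ppu) / ppu,
        dim(ch))
}
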