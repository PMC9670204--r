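# Independent brute-force oracles used across tests.  These deliberately
# re-derive each quantity by the most literal method available (pixel
# scans, offset-by-offset convolution, exhaustive histogram scans) so they
# share no code path with the package implementation.

# Full 2-D convolution with a truncated-normalised Gaussian kernel,
# accumulated offset by offset with replicate (clamped-index) padding.
oracle_smooth <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  rad <- max(1L, as.integer(ceiling(4 * sigma_px)))
  off <- (-rad):rad
  k1 <- exp(-off^2 / (2 * sigma_px^2))
  k1 <- k1 / sum(k1)
  nr <- nrow(mat)
  nc <- ncol(mat)
  out <- matrix(0, nr, nc)
  for (i in seq_along(off)) {
    ri <- pmin(pmax(seq_len(nr) + off[i], 1L), nr)
    for (j in seq_along(off)) {
      cj <- pmin(pmax(seq_len(nc) + off[j], 1L), nc)
      out <- out + k1[i] * k1[j] * mat[ri, cj]
    }
  }
  out
}

# Exhaustive 256-bin Otsu scan on the nonzero histogram: loops over every
# candidate edge and recomputes both class moments from the counts.
oracle_otsu <- function(x) {
  v <- as.numeric(x)
  v <- v[v > 0]
  lo <- min(v)
  hi <- max(v)
  if (lo == hi) return(lo)
  edges <- seq(lo, hi, length.out = 257L)
  mids <- (edges[-257] + edges[-1]) / 2
  w <- (hi - lo) / 256
  # left-open bins (e_{j-1}, e_j]; the minimum lands in bin 1
  bin <- pmin(256L, pmax(1L, as.integer(ceiling((v - lo) / w))))
  counts <- tabulate(bin, 256L)
  best <- -Inf
  best_edge <- NA_real_
  for (split in 1:255) {
    w0 <- sum(counts[1:split])
    w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:split] * mids[1:split]) / w0
    mu1 <- sum(counts[(split + 1):256] * mids[(split + 1):256]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best) {
      best <- bcv
      best_edge <- edges[split + 1L]
    }
  }
  best_edge
}

# Literal pixel-scan quantification of one cell: threshold by comparison,
# MTOC by row-major argmax of the oracle-smoothed channel, ROI membership
# by per-pixel squared distance.  Returns the ROI/whole-cell ratio.
oracle_cell_ratio <- function(lyso, mtoc, cell_mask, pixel_size_um,
                              roi_radius_um = 2, smooth_sigma_px = 2,
                              threshold = NULL) {
  thr <- threshold
  if (is.null(thr)) thr <- oracle_otsu(lyso)
  lt <- lyso
  lt[lt < thr] <- 0
  sm <- oracle_smooth(mtoc, smooth_sigma_px)
  best <- -Inf
  pos <- c(NA, NA)
  for (r in seq_len(nrow(sm))) {
    row_vals <- ifelse(cell_mask[r, ], sm[r, ], -Inf)
    c <- which.max(row_vals)
    if (row_vals[c] > best) {  # strict: earlier rows win ties (row-major)
      best <- row_vals[c]
      pos <- c(r, c)
    }
  }
  r2 <- (roi_radius_um / pixel_size_um)^2
  roi_sum <- 0
  cell_sum <- 0
  cols <- seq_len(ncol(lt))
  for (r in seq_len(nrow(lt))) {
    inc <- cell_mask[r, ]
    cell_sum <- cell_sum + sum(lt[r, inc])
    in_roi <- inc & ((r - pos[1])^2 + (cols - pos[2])^2 <= r2)
    roi_sum <- roi_sum + sum(lt[r, in_roi])
  }
  roi_sum / cell_sum
}

# Small standard field used by several image tests.
small_field <- function(seed, perinuclear_fraction = 0.8, n_cells = 3L,
                        shape = c(192L, 192L), noise = "none",
                        background = 0) {
  generate_field(field_sim_params(
    field_shape = shape, n_cells = n_cells, cell_radius_um = 3,
    n_lysosomes_per_cell = 40, perinuclear_fraction = perinuclear_fraction,
    perinuclear_sigma_um = 0.5, psf_sigma_um = 0.2,
    background_level = background, noise = noise, seed = seed
  ))
}

# Fixed-zero threshold config: appropriate for noiseless zero-background
# renders, where no background elimination is needed.
cfg_noiseless <- function(...) {
  quant_config(threshold = list("fixed", value = 0),
               min_cells_per_field = 3L, ...)
}
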