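#' Configuration for lysosomal-clustering quantification
#'
#' @param roi_radius_um radius of the circular region of interest centred on
#'   the MTOC, micrometres.  The study's protocol uses 2 micrometres.
#' @param projection how z-stacks are flattened: `"max"` (maximum-intensity,
#'   the puncta convention) or `"sum"`.
#' @param threshold background-elimination rule applied to the lysosome
#'   channel before intensities are summed: `"otsu"` (Otsu's criterion on
#'   the nonzero-intensity histogram, 256 bins) or `list("fixed", value =)`.
#' @param mtoc_smooth_sigma_um Gaussian smoothing applied to the MTOC
#'   channel before locating the spot maximum, micrometres.
#' @param min_cells_per_field fields with fewer usable cells are flagged
#'   (the protocol calls for more than 10 cells per field).
#' @param aggregation `"per_cell"` (one ratio per cell, the default) or
#'   `"per_field"` (summed ROI over summed whole-cell intensity).
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(roi_radius_um = 2,
                         projection = c("max", "sum"),
                         threshold = "otsu",
                         mtoc_smooth_sigma_um = 0.2,
                         min_cells_per_field = 10L,
                         aggregation = c("per_cell", "per_field")) {
  stopifnot(is_number(roi_radius_um), roi_radius_um > 0,
            is_number(mtoc_smooth_sigma_um), mtoc_smooth_sigma_um >= 0,
            is_count(min_cells_per_field, min = 0L))
  projection <- match.arg(projection)
  aggregation <- match.arg(aggregation)
  threshold <- normalize_threshold(threshold)
  structure(
    list(roi_radius_um = roi_radius_um, projection = projection,
         threshold = threshold, mtoc_smooth_sigma_um = mtoc_smooth_sigma_um,
         min_cells_per_field = as.integer(min_cells_per_field),
         aggregation = aggregation),
    class = "quant_config"
  )
}

#' @noRd
normalize_threshold <- function(threshold) {
  if (is.character(threshold) && length(threshold) == 1L) {
    threshold <- list(threshold)
  }
  method <- threshold[[1L]]
  if (identical(method, "otsu")) return(list(method = "otsu"))
  if (identical(method, "fixed")) {
    v <- threshold$value %||% threshold[[2L]]
    stopifnot(is_number(v))
    return(list(method = "fixed", value = v))
  }
  stop("threshold method must be 'otsu' or list('fixed', value = )")
}

#' Flatten a z-stack to a single plane
#'
#' @param stack matrix (returned unchanged) or 3-D array indexed
#'   `[row, col, z]`.
#' @param method `"max"` for per-pixel maximum across z, `"sum"` for the sum.
#' @return a matrix.
#' @export
project_stack <- function(stack, method = c("max", "sum")) {
  method <- match.arg(method)
  d <- dim(stack)
  if (length(d) == 2L) return(stack)
  if (length(d) != 3L) stop("stack must be a matrix or a 3-D array")
  if (d[3L] == 1L) return(matrix(stack[, , 1L], d[1L], d[2L]))
  out <- stack[, , 1L]
  for (z in 2L:d[3L]) {
    out <- if (method == "max") pmax(out, stack[, , z]) else out + stack[, , z]
  }
  out
}

#' Otsu threshold on the nonzero-intensity histogram
#'
#' 256 equal-width bins span the nonzero intensity range; the returned
#' threshold is the bin edge maximising the between-class variance of the
#' nonzero pixels (smallest edge on ties).  Zero pixels are treated as
#' already-eliminated background and excluded from the histogram.
#'
#' @param x numeric vector/matrix of non-negative intensities.
#' @return the threshold value; pixels strictly below it are background.
#' @export
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  v <- v[v > 0]
  if (!length(v)) stop("otsu_threshold: no nonzero pixels")
  lo <- min(v)
  hi <- max(v)
  if (lo == hi) {
    warning("otsu_threshold: constant nonzero intensity; all pixels kept as foreground")
    return(lo)
  }
  edges <- seq(lo, hi, length.out = 257L)
  # left-open uniform bins (e_{j-1}, e_j]; the minimum falls into bin 1
  width <- (hi - lo) / 256
  bin <- pmin(256L, pmax(1L, as.integer(ceiling((v - lo) / width))))
  counts <- tabulate(bin, nbins = 256L)
  # candidate thresholds: interior edges; class 0 = bins below the edge
  n <- length(v)
  w0 <- cumsum(counts)[1:255]
  mids <- (edges[1:256] + edges[2:257]) / 2
  s0 <- cumsum(counts * mids)[1:255]
  total <- sum(counts * mids)
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 255)
  mu0 <- s0[valid] / w0[valid]
  mu1 <- (total - s0[valid]) / w1[valid]
  bcv[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  edges[which.max(bcv) + 1L]
}

#' Zero sub-threshold pixels
#'
#' @param grid non-negative intensity matrix.
#' @param method `"otsu"` (see [otsu_threshold()]) or `list("fixed", value=)`.
#' @return list with the masked `grid` (pixels `< threshold` set to 0), the
#'   logical foreground `mask`, and the `threshold` used.
#' @export
apply_threshold <- function(grid, method = "otsu") {
  method <- normalize_threshold(method)
  if (any(grid < 0)) stop("apply_threshold: negative intensities")
  if (method$method == "fixed") {
    thr <- method$value
  } else {
    if (all(grid == 0)) {
      return(list(grid = grid, mask = grid > 0, threshold = Inf))
    }
    thr <- otsu_threshold(grid)
  }
  mask <- grid >= thr
  out <- grid
  out[!mask] <- 0
  list(grid = out, mask = mask, threshold = thr)
}

#' Locate the MTOC spot within a cell
#'
#' The MTOC channel is Gaussian-smoothed and the position of the global
#' maximum inside the cell mask is returned; ties are broken by the
#' lexicographically smallest (row, col).
#'
#' @param mtoc_channel 2-D intensity grid (project stacks first).
#' @param cell_mask logical matrix, `TRUE` inside the cell.
#' @param smooth_sigma_px smoothing width in pixels (0 = none).
#' @return integer `(row, col)` of the spot.
#' @export
detect_mtoc <- function(mtoc_channel, cell_mask, smooth_sigma_px = 2) {
  stopifnot(identical(dim(mtoc_channel), dim(cell_mask)), any(cell_mask))
  if (all(mtoc_channel[cell_mask] == 0)) {
    stop("detect_mtoc: no MTOC signal within the cell mask")
  }
  sm <- smooth_gaussian(mtoc_channel, smooth_sigma_px)
  sm[!cell_mask] <- -Inf
  # column-major which.min of (-sm) would tie-break by column first; we need
  # row-major lexicographic (smallest row, then col), so scan explicitly
  mx <- max(sm)
  hits <- which(sm == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  c(row = hits[1L, 1L], col = hits[1L, 2L])
}

#' Circular region-of-interest pixel mask
#'
#' A pixel belongs to the ROI iff its centre lies within `radius_um` of the
#' centre pixel: `((r - r0)^2 + (c - c0)^2) * pixel_size_um^2 <= radius_um^2`.
#' The mask is clipped at the image borders.
#'
#' @param center `(row, col)` pixel position (may be fractional).
#' @param radius_um ROI radius, micrometres (> 0).
#' @param pixel_size_um micrometres per pixel.
#' @param shape `(rows, cols)` of the image.
#' @return logical matrix of the given shape.
#' @export
circular_roi_mask <- function(center, radius_um, pixel_size_um, shape) {
  stopifnot(is_number(radius_um), radius_um > 0,
            is_number(pixel_size_um), pixel_size_um > 0)
  if (center[1L] < 1 || center[1L] > shape[1L] ||
      center[2L] < 1 || center[2L] > shape[2L]) {
    stop("circular_roi_mask: center lies outside the image")
  }
  r_px2 <- (radius_um / pixel_size_um)^2
  dr2 <- (seq_len(shape[1L]) - center[1L])^2
  dc2 <- (seq_len(shape[2L]) - center[2L])^2
  outer(dr2, dc2, `+`) <= r_px2
}

#' Quantify one cell: ROI over whole-cell lysosome intensity
#'
#' Implements the clustering readout: after projection and background
#' thresholding, the lysosome-marker intensity inside the circular ROI
#' centred on the detected MTOC is summed and divided by the summed
#' intensity over the whole cell.
#'
#' @param field list with `channels` (named grids including `lysosome` and
#'   `mtoc`) and `pixel_size_um`; e.g. a `synthetic_field` or the value of
#'   [read_field_tiff()].
#' @param cell_mask logical matrix selecting the cell's pixels.
#' @param config a [quant_config()].
#' @param cell_id,field_id identifiers copied into the result.
#' @return one-row data.frame: `field_id`, `cell_id`, `mtoc_row`,
#'   `mtoc_col`, `roi_intensity`, `cell_intensity`, `ratio`; or `NULL`
#'   (with a message) when the thresholded cell has zero intensity.
#' @export
quantify_cell <- function(field, cell_mask, config = quant_config(),
                          cell_id = 1L, field_id = field$field_id %||% "field") {
  stopifnot(inherits(config, "quant_config"))
  lyso <- project_stack(field$channels$lysosome, config$projection)
  lyso <- apply_threshold(lyso, config$threshold)$grid
  mtoc <- project_stack(field$channels$mtoc, config$projection)
  quantify_cell_prepared(lyso, mtoc, cell_mask, field$pixel_size_um, config,
                         cell_id, field_id)
}

#' @noRd
quantify_cell_prepared <- function(lyso, mtoc, cell_mask, pixel_size_um,
                                   config, cell_id, field_id) {
  cell_sum <- sum(lyso[cell_mask])
  if (cell_sum <= 0) {
    message(sprintf("cell %s skipped: zero thresholded lysosome intensity",
                    cell_id))
    return(NULL)
  }
  pos <- detect_mtoc(mtoc, cell_mask,
                     config$mtoc_smooth_sigma_um / pixel_size_um)
  roi <- circular_roi_mask(pos, config$roi_radius_um, pixel_size_um,
                           dim(lyso))
  roi_sum <- sum(lyso[roi & cell_mask])
  data.frame(field_id = field_id, cell_id = cell_id,
             mtoc_row = unname(pos[1L]), mtoc_col = unname(pos[2L]),
             roi_intensity = roi_sum, cell_intensity = cell_sum,
             ratio = roi_sum / cell_sum)
}

#' Quantify every cell of a field
#'
#' Projection and thresholding are performed once per field, then each
#' labelled cell is quantified with [quantify_cell()] semantics.  Fields
#' with fewer usable cells than `config$min_cells_per_field` are flagged
#' (attribute `low_cell_count`); their cells are still returned.
#'
#' @param field as in [quantify_cell()].
#' @param config a [quant_config()].
#' @param cell_labels integer label matrix (0 = background); defaults to
#'   the truth labels of a `synthetic_field`.
#' @return data.frame with one row per usable cell (see [quantify_cell()]),
#'   with attributes `low_cell_count` (logical) and `skipped_cells`
#'   (integer ids).  With `aggregation = "per_field"` a single row with
#'   `cell_id = NA` holding the field-level summed-intensity ratio.
#' @export
quantify_field <- function(field, config = quant_config(),
                           cell_labels = field$truth$cell_labels) {
  stopifnot(inherits(config, "quant_config"))
  if (is.null(cell_labels)) {
    stop("quantify_field: no cell masks supplied (cell_labels is NULL)")
  }
  lyso <- project_stack(field$channels$lysosome, config$projection)
  lyso <- apply_threshold(lyso, config$threshold)$grid
  mtoc <- project_stack(field$channels$mtoc, config$projection)
  ids <- sort(unique(cell_labels[cell_labels > 0L]))
  rows <- list()
  skipped <- integer(0)
  for (id in ids) {
    q <- quantify_cell_prepared(lyso, mtoc, cell_labels == id,
                                field$pixel_size_um, config, id,
                                field$field_id %||% "field")
    if (is.null(q)) skipped <- c(skipped, id) else rows[[length(rows) + 1L]] <- q
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(field_id = character(0), cell_id = integer(0),
               mtoc_row = integer(0), mtoc_col = integer(0),
               roi_intensity = numeric(0), cell_intensity = numeric(0),
               ratio = numeric(0))
  if (config$aggregation == "per_field" && nrow(out)) {
    out <- data.frame(field_id = out$field_id[1L], cell_id = NA_integer_,
                      mtoc_row = NA_integer_, mtoc_col = NA_integer_,
                      roi_intensity = sum(out$roi_intensity),
                      cell_intensity = sum(out$cell_intensity),
                      ratio = sum(out$roi_intensity) / sum(out$cell_intensity))
  }
  attr(out, "low_cell_count") <- length(rows) < config$min_cells_per_field
  attr(out, "skipped_cells") <- skipped
  out
}

#' Control-normalised lysosomal clustering values
#'
#' The clustering value of an observation is its ROI/whole-cell ratio
#' divided by the mean ratio of the control group, so the control group's
#' mean clustering value is 1 exactly.
#'
#' @param quants data.frame with a grouping column and a ratio column, e.g.
#'   row-bound [quantify_field()] results with a `group` column added.
#' @param control_label group label of the control.
#' @param group_col,ratio_col column names.
#' @return the input data.frame with a `clustering_value` column appended.
#' @examples
#' d <- data.frame(group = c("ctrl", "ctrl", "treated"),
#'                 ratio = c(0.2, 0.4, 0.6))
#' clustering_values(d, "ctrl")$clustering_value  # 0.667 1.333 2.0
#' @export
clustering_values <- function(quants, control_label, group_col = "group",
                              ratio_col = "ratio") {
  stopifnot(is.data.frame(quants),
            all(c(group_col, ratio_col) %in% names(quants)))
  g <- quants[[group_col]]
  if (!any(g == control_label)) stop("control group is empty")
  m <- mean(quants[[ratio_col]][g == control_label])
  if (m == 0) stop("control group mean ratio is zero")
  quants$clustering_value <- quants[[ratio_col]] / m
  quants
}
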