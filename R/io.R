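# File-format adapters: multichannel TIFF + JSON sidecar for fields,
# long-format CSV for traces and peptide tables, CSV manifests for outputs.

#' Write a multichannel field as TIFF plus JSON sidecar
#'
#' Planes are stored channel-major (all z of channel 1, then channel 2, ...)
#' as 16-bit samples scaled by the global intensity maximum, which is
#' recorded in the sidecar (`<path>.json`) together with pixel size,
#' channel names, z-plane count and, for synthetic fields, the ground
#' truth tables.  Cell/nucleus label images, when present, go to separate
#' 16-bit label TIFFs `<path stem>_cells.tif` / `<path stem>_nuclei.tif`.
#'
#' @param field a `synthetic_field` or any list with `channels` (named
#'   grids) and `pixel_size_um`.
#' @param path output TIFF path.
#' @param write_labels also write truth label images when available.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path, write_labels = TRUE) {
  chs <- field$channels
  stopifnot(length(chs) >= 1L, !is.null(names(chs)))
  planes <- list()
  z_planes <- 1L
  for (nm in names(chs)) {
    ch <- chs[[nm]]
    d <- dim(ch)
    if (length(d) == 3L) {
      z_planes <- d[3L]
      for (z in seq_len(d[3L])) planes <- c(planes, list(ch[, , z]))
    } else {
      planes <- c(planes, list(ch))
    }
  }
  m <- max(1e-12, vapply(planes, max, 0))
  # integer-valued data within the 16-bit range are stored on the exact
  # 16-bit lattice, making the round trip lossless
  all_int <- all(vapply(planes, function(p) all(p == round(p)), TRUE))
  if (all_int && m <= 65535) m <- 65535
  tiff::writeTIFF(lapply(planes, function(p) p / m), path,
                  bits.per.sample = 16L)
  sidecar <- list(
    pixel_size_um = field$pixel_size_um,
    channel_names = names(chs),
    z_planes = z_planes,
    intensity_max = m,
    field_id = field$field_id %||% basename(path)
  )
  if (!is.null(field$truth)) {
    sidecar$truth <- list(
      cells = field$truth$cells,
      lysosomes = field$truth$lysosomes,
      roi_radius_um = field$truth$roi_radius_um,
      clipped_intensity = field$truth$clipped_intensity
    )
    if (write_labels) {
      stem <- sub("\\.tiff?$", "", path)
      write_label_tiff(field$truth$cell_labels, paste0(stem, "_cells.tif"))
      write_label_tiff(field$truth$nucleus_labels,
                       paste0(stem, "_nuclei.tif"))
      sidecar$cell_labels_file <- paste0(basename(stem), "_cells.tif")
      sidecar$nucleus_labels_file <- paste0(basename(stem), "_nuclei.tif")
    }
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a multichannel field TIFF (+ sidecar) back into a field object
#'
#' @param path TIFF path written by [write_field_tiff()] or compatible.
#' @param sidecar_path JSON sidecar path (default `<path>.json`); may be
#'   `NULL` when `pixel_size_um` and `channel_names` are given explicitly.
#' @param pixel_size_um,channel_names overrides when no sidecar exists.
#' @return list with `channels`, `pixel_size_um`, `field_id`, and `truth`
#'   (with `cell_labels` re-read from the label TIFF when recorded).
#' @export
read_field_tiff <- function(path, sidecar_path = paste0(path, ".json"),
                            pixel_size_um = NULL, channel_names = NULL) {
  planes <- tiff::readTIFF(path, all = TRUE)
  side <- if (!is.null(sidecar_path) && file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  }
  pixel_size_um <- pixel_size_um %||% side$pixel_size_um
  channel_names <- channel_names %||% side$channel_names
  if (is.null(pixel_size_um)) {
    stop("missing pixel_size_um: supply a sidecar or the argument")
  }
  if (is.null(channel_names)) {
    stop("missing channel_names: supply a sidecar or the argument")
  }
  z_planes <- side$z_planes %||% 1L
  if (length(planes) != length(channel_names) * z_planes) {
    stop(sprintf("channel-name mismatch: %d planes but %d channels x %d z",
                 length(planes), length(channel_names), z_planes))
  }
  m <- side$intensity_max %||% 1
  channels <- list()
  for (i in seq_along(channel_names)) {
    idx <- (i - 1L) * z_planes + seq_len(z_planes)
    ch <- if (z_planes == 1L) planes[[idx]] * m else {
      arr <- array(0, c(dim(planes[[idx[1L]]]), z_planes))
      for (z in seq_len(z_planes)) arr[, , z] <- planes[[idx[z]]] * m
      arr
    }
    channels[[channel_names[i]]] <- ch
  }
  truth <- side$truth
  if (!is.null(side$cell_labels_file)) {
    truth$cell_labels <- read_label_tiff(
      file.path(dirname(path), side$cell_labels_file))
  }
  if (!is.null(side$nucleus_labels_file)) {
    truth$nucleus_labels <- read_label_tiff(
      file.path(dirname(path), side$nucleus_labels_file))
  }
  list(channels = channels, pixel_size_um = pixel_size_um,
       field_id = side$field_id %||% basename(path), truth = truth)
}

#' @rdname read_field_tiff
#' @param labels integer label matrix (0 = background, <= 65535).
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(max(labels) <= 65535L)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname read_field_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

# --- CSV adapters -----------------------------------------------------------

#' @noRd
read_table_checked <- function(path, required, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", basename(path),
                 paste(miss, collapse = ", ")))
  }
  d
}

#' Report rows violating a predicate, by data line number (header = line 1).
#' @noRd
reject_rows <- function(d, bad, path, why) {
  if (any(bad)) {
    stop(sprintf("%s: %s at line(s) %s", basename(path), why,
                 paste(which(bad) + 1L, collapse = ", ")))
  }
}

#' Read dual-excitation calcium traces from long-format CSV
#'
#' Expects columns `cell_id`, `time_s`, `F340`, `F380` (case-insensitive).
#' Rows with negative fluorescence or missing values are rejected with
#' their line numbers; each cell's time grid must be uniform within
#' `dt_tol` relative tolerance.
#'
#' @param path CSV path.
#' @param dt_tol relative tolerance on sampling-step uniformity.
#' @return list of `calcium_trace` objects.
#' @export
read_trace_csv <- function(path, dt_tol = 1e-6) {
  d <- read_table_checked(path, c("cell_id", "time_s", "f340", "f380"))
  reject_rows(d, !stats::complete.cases(d[c("time_s", "f340", "f380")]),
              path, "missing value")
  reject_rows(d, d$f340 < 0 | d$f380 < 0, path, "negative fluorescence")
  lapply(split(d, d$cell_id), function(dc) {
    dc <- dc[order(dc$time_s), , drop = FALSE]
    dt <- diff(dc$time_s)
    if (length(dt) && diff(range(dt)) > dt_tol * max(abs(dt))) {
      stop(sprintf("%s: non-uniform time steps for cell %s", basename(path),
                   dc$cell_id[1L]))
    }
    structure(list(cell_id = as.character(dc$cell_id[1L]),
                   time_s = dc$time_s, F340 = dc$f340, F380 = dc$f380,
                   ratio = compute_ratio(dc$f340, dc$f380)),
              class = "calcium_trace")
  })
}

#' @rdname read_trace_csv
#' @param traces list of `calcium_trace` objects.
#' @export
write_trace_csv <- function(traces, path) {
  d <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(cell_id = tr$cell_id, time_s = tr$time_s,
               F340 = tr$F340, F380 = tr$F380)
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format peptide peak-area table
#'
#' Expects columns `peptide_id`, `is_phospho`, `sample_id`, `condition`,
#' `area` (case-insensitive; `sequence` and `phospho_site` optional).
#' Negative areas and duplicate (peptide, sample) rows are rejected with
#' line numbers.  Tab-separated files are detected from a `.tsv` extension.
#'
#' @param path CSV/TSV path.
#' @return data.frame suitable for [normalize_peptides()].
#' @export
read_peptide_csv <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- read_table_checked(path, c("peptide_id", "is_phospho", "sample_id",
                                  "condition", "area"), sep = sep)
  d$is_phospho <- as.logical(d$is_phospho)
  reject_rows(d, is.na(d$is_phospho), path, "unreadable is_phospho flag")
  reject_rows(d, !is.na(d$area) & d$area < 0, path, "negative area")
  reject_rows(d, duplicated(paste(d$peptide_id, d$sample_id)), path,
              "duplicate (peptide_id, sample_id)")
  d
}

#' Read a grouped scalar table (columns `group`, `value`)
#'
#' @param path CSV path.
#' @return data.frame with `group` and `value`.
#' @export
read_groups_csv <- function(path) {
  d <- read_table_checked(path, c("group", "value"))
  reject_rows(d, is.na(d$value), path, "missing value")
  d
}

#' Write result tables and a content-hash manifest
#'
#' Each table is written as `<name>.csv` under `dir`; `manifest.csv` lists
#' every artifact with its size and MD5 content hash, so identical runs
#' produce identical manifests and any content change is visible.
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_results <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- data.frame(
    file = basename(files),
    bytes = file.size(files),
    md5 = unname(tools::md5sum(files))
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# --- run configuration ------------------------------------------------------

#' Read a YAML run configuration with strict key checking
#'
#' Recognised top-level blocks: `seed`, `output_dir`, `log_level`,
#' `image_sim`, `quant`, `trace_sim`, `peptide_sim`, `groups`.  Unknown
#' keys are rejected rather than silently ignored.
#'
#' @param path YAML file.
#' @return named list of configuration blocks.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "output_dir", "log_level", "image_sim", "quant",
             "trace_sim", "peptide_sim", "groups")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}

#' @rdname read_run_config
#' @param cfg configuration list.
#' @param dir directory in which to persist the resolved configuration
#'   (written as `run_config.yaml`, so every run's outputs sit next to the
#'   exact configuration that produced them).
#' @export
write_resolved_config <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, "run_config.yaml")
  yaml::write_yaml(cfg, f)
  invisible(f)
}
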