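#' Construct a single Raman spectrum
#'
#' A spectrum is a vector of intensities on a wavenumber grid, tagged with the
#' cell it was measured from, its class label, and (optionally) its pixel
#' position in a Raman map.
#'
#' @param grid Numeric vector of wavenumbers in cm^-1; strictly increasing,
#'   all within \[100, 6000\], length >= 2.
#' @param intensities Numeric vector, one finite value per grid point.
#'   Negative values are allowed (baseline-corrected spectra dip below zero).
#' @param cell_id Opaque cell identifier (coerced to character).
#' @param class_label Class label (coerced to character), or `NA`.
#' @param pixel Optional integer `c(x, y)` map coordinate (0-based).
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(grid, intensities, cell_id = NA_character_,
                           class_label = NA_character_, pixel = NULL) {
  grid <- validate_grid(grid)
  intensities <- as.numeric(intensities)
  if (length(intensities) != length(grid)) {
    stop("intensities length (", length(intensities),
         ") does not match grid length (", length(grid), ")", call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop("all intensities must be finite", call. = FALSE)
  }
  if (!is.null(pixel)) {
    pixel <- as.integer(pixel)
    if (length(pixel) != 2L || anyNA(pixel)) {
      stop("pixel must be an integer (x, y) pair", call. = FALSE)
    }
  }
  structure(
    list(grid = grid, intensities = intensities,
         cell_id = as.character(cell_id),
         class_label = as.character(class_label), pixel = pixel),
    class = "raman_spectrum"
  )
}

#' Validate a wavenumber grid
#'
#' @param grid Numeric vector of wavenumbers in cm^-1.
#' @return The grid as a plain numeric vector, invisibly validated:
#'   strictly increasing, inside \[100, 6000\], length >= 2.
#' @keywords internal
validate_grid <- function(grid) {
  grid <- as.numeric(grid)
  if (length(grid) < 2L) {
    stop("wavenumber grid must have at least 2 points", call. = FALSE)
  }
  if (anyNA(grid) || !all(is.finite(grid))) {
    stop("wavenumber grid must be finite", call. = FALSE)
  }
  if (any(diff(grid) <= 0)) {
    stop("wavenumber grid must be strictly increasing", call. = FALSE)
  }
  if (grid[1L] < 100 || grid[length(grid)] > 6000) {
    stop("wavenumbers must lie within [100, 6000] cm^-1", call. = FALSE)
  }
  grid
}

#' Construct a spectral dataset
#'
#' The central container of the pipeline: a matrix of spectra (rows) on a
#' shared wavenumber grid (columns), with one class label and one cell id per
#' spectrum, and an explicit class order.
#'
#' @param grid Wavenumber grid (cm^-1), strictly increasing.
#' @param intensities Numeric matrix, `n_spectra x n_wavenumbers`, all finite.
#' @param labels Character vector of class labels, one per row; every label
#'   must appear in `class_order`.
#' @param cell_ids Character vector of cell identifiers, one per row.
#' @param class_order Character vector declaring the ordered class set.
#'   Defaults to the sorted unique labels.
#' @param pixels Optional data.frame with integer columns `x`, `y` (0-based
#'   map coordinates), one row per spectrum.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(grid, intensities, labels, cell_ids,
                             class_order = NULL, pixels = NULL) {
  grid <- validate_grid(grid)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  n <- nrow(intensities)
  if (ncol(intensities) != length(grid)) {
    stop("intensity matrix has ", ncol(intensities),
         " columns but grid has ", length(grid), " points", call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop("all intensities must be finite", call. = FALSE)
  }
  labels <- as.character(labels)
  cell_ids <- as.character(cell_ids)
  if (length(labels) != n || length(cell_ids) != n) {
    stop("labels (", length(labels), ") and cell_ids (", length(cell_ids),
         ") must each have one entry per spectrum (", n, ")", call. = FALSE)
  }
  if (is.null(class_order)) class_order <- sort(unique(labels))
  class_order <- as.character(class_order)
  if (anyDuplicated(class_order)) {
    stop("class_order contains duplicates", call. = FALSE)
  }
  bad <- setdiff(unique(labels), class_order)
  if (length(bad)) {
    stop("labels not in class_order: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(pixels)) {
    pixels <- as.data.frame(pixels)
    if (!all(c("x", "y") %in% names(pixels)) || nrow(pixels) != n) {
      stop("pixels must be a data.frame with columns x, y and one row per spectrum",
           call. = FALSE)
    }
    pixels <- data.frame(x = as.integer(pixels$x), y = as.integer(pixels$y))
  }
  if (is.null(rownames(intensities))) {
    rownames(intensities) <- sprintf("spec_%04d", seq_len(n))
  }
  structure(
    list(grid = grid, intensities = intensities, labels = labels,
         cell_ids = cell_ids, class_order = class_order, pixels = pixels),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("<spectral_dataset> ", nrow(x$intensities), " spectra x ",
      length(x$grid), " wavenumbers (",
      format(x$grid[1]), "-", format(x$grid[length(x$grid)]), " cm^-1)\n",
      sep = "")
  tab <- table(factor(x$labels, levels = x$class_order))
  for (k in x$class_order) {
    cat("  ", k, ": ", tab[[k]], " spectra / ",
        length(unique(x$cell_ids[x$labels == k])), " cells\n", sep = "")
  }
  invisible(x)
}

#' Number of spectra in a dataset
#' @param dataset A `spectral_dataset`.
#' @return Integer row count.
#' @export
n_spectra <- function(dataset) nrow(dataset$intensities)

#' Subset a spectral dataset by row
#'
#' Keeps grid and class order, subsets spectra, labels, cell ids and pixels
#' consistently.
#'
#' @param dataset A `spectral_dataset`.
#' @param idx Integer or logical row index.
#' @return A `spectral_dataset`.
#' @export
subset_rows <- function(dataset, idx) {
  spectral_dataset(
    grid = dataset$grid,
    intensities = dataset$intensities[idx, , drop = FALSE],
    labels = dataset$labels[idx],
    cell_ids = dataset$cell_ids[idx],
    class_order = dataset$class_order,
    pixels = if (!is.null(dataset$pixels)) dataset$pixels[idx, , drop = FALSE]
  )
}

#' Extract one spectrum from a dataset
#' @param dataset A `spectral_dataset`.
#' @param i Row index.
#' @return A `raman_spectrum`.
#' @export
get_spectrum <- function(dataset, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= n_spectra(dataset))
  raman_spectrum(
    grid = dataset$grid,
    intensities = dataset$intensities[i, ],
    cell_id = dataset$cell_ids[i],
    class_label = dataset$labels[i],
    pixel = if (!is.null(dataset$pixels)) unlist(dataset$pixels[i, c("x", "y")])
  )
}

#' Crop a dataset to a wavenumber window
#'
#' Retains exactly the grid points with `lo <= w <= hi` (closed interval), as
#' used for the fingerprint (400-2000 cm^-1) and high-wavenumber
#' (2800-4000 cm^-1) windows. Labels and cell ids are unchanged.
#'
#' @param dataset A `spectral_dataset`.
#' @param lo,hi Window bounds in cm^-1, `lo < hi`.
#' @return A `spectral_dataset` on the cropped grid.
#' @export
crop_range <- function(dataset, lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi) {
    stop("crop_range requires lo < hi", call. = FALSE)
  }
  keep <- dataset$grid >= lo & dataset$grid <= hi
  if (!any(keep)) {
    stop("crop_range: no grid points in [", lo, ", ", hi, "]", call. = FALSE)
  }
  spectral_dataset(
    grid = dataset$grid[keep],
    intensities = dataset$intensities[, keep, drop = FALSE],
    labels = dataset$labels,
    cell_ids = dataset$cell_ids,
    class_order = dataset$class_order,
    pixels = dataset$pixels
  )
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_meta.csv")
}

#' Write a spectral dataset to delimited text
#'
#' Two on-disk layouts are supported. `wide`: a purely numeric CSV whose first
#' column is `wavenumber` and remaining columns are one spectrum each, plus a
#' metadata sidecar `<stem>_meta.csv` with columns
#' `spectrum_id, label, cell_id` (and `x, y` when map coordinates exist).
#' `long_map`: one row per (pixel, wavenumber) with columns
#' `cell_id, x, y, wavenumber_cm1, intensity`, plus the same sidecar (labels
#' are carried by the sidecar in both layouts).
#'
#' @param dataset A `spectral_dataset`.
#' @param path Output CSV path; the sidecar is written next to it.
#' @param format `"wide"` or `"long_map"`.
#' @return Invisibly, the paths written (`data`, `meta`).
#' @export
write_dataset <- function(dataset, path, format = c("wide", "long_map")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "spectral_dataset"))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("cannot write dataset: directory does not exist: ", dir, call. = FALSE)
  }
  n <- n_spectra(dataset)
  ids <- rownames(dataset$intensities)
  px <- dataset$pixels
  if (is.null(px)) {
    # long_map needs coordinates; lay spectra on a line when none were recorded
    px_eff <- data.frame(x = seq_len(n) - 1L, y = rep(0L, n))
  } else {
    px_eff <- px
  }
  meta <- data.frame(spectrum_id = ids, label = dataset$labels,
                     cell_id = dataset$cell_ids,
                     x = px_eff$x, y = px_eff$y,
                     stringsAsFactors = FALSE)
  if (format == "wide") {
    wide <- data.table::data.table(wavenumber = dataset$grid)
    mat <- t(dataset$intensities)
    colnames(mat) <- ids
    wide <- cbind(wide, data.table::as.data.table(mat))
    data.table::fwrite(wide, path)
  } else {
    long <- data.table::data.table(
      cell_id = rep(dataset$cell_ids, each = length(dataset$grid)),
      x = rep(px_eff$x, each = length(dataset$grid)),
      y = rep(px_eff$y, each = length(dataset$grid)),
      wavenumber_cm1 = rep(dataset$grid, times = n),
      intensity = as.vector(t(dataset$intensities))
    )
    data.table::fwrite(long, path)
  }
  data.table::fwrite(meta, sidecar_path(path))
  invisible(list(data = path, meta = sidecar_path(path)))
}

#' Read a spectral dataset from delimited text
#'
#' Inverse of [write_dataset()]. For the `wide` layout the grid is taken from
#' the `wavenumber` column and labels/cell ids from the sidecar; a grid stored
#' in descending order is reordered ascending (intensities reordered
#' consistently). For `long_map`, spectra are identified by the
#' `(cell_id, x, y)` triple and labels come from the sidecar.
#'
#' @param path CSV path written by [write_dataset()] (sidecar expected at
#'   `<stem>_meta.csv`).
#' @param format `"wide"` or `"long_map"`.
#' @param class_order Optional explicit class order; defaults to sorted
#'   unique labels.
#' @return A `spectral_dataset`.
#' @export
read_dataset <- function(path, format = c("wide", "long_map"),
                         class_order = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  mpath <- sidecar_path(path)
  if (!file.exists(mpath)) {
    stop("metadata sidecar not found: ", mpath, call. = FALSE)
  }
  meta <- data.table::fread(mpath, colClasses = list(
    character = c("spectrum_id", "label", "cell_id")))
  if (!all(c("spectrum_id", "label", "cell_id") %in% names(meta))) {
    stop("metadata sidecar must have columns spectrum_id, label, cell_id",
         call. = FALSE)
  }
  if (anyNA(meta$label) || any(meta$label == "")) {
    stop("metadata error: label missing for some spectra", call. = FALSE)
  }
  if (format == "wide") {
    dat <- data.table::fread(path)
    if (!"wavenumber" %in% names(dat)) {
      stop("format error: wide file has no 'wavenumber' column", call. = FALSE)
    }
    spec_cols <- setdiff(names(dat), "wavenumber")
    for (cn in spec_cols) {
      col <- dat[[cn]]
      if (!is.numeric(col)) {
        bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
        stop("parse error: non-numeric intensity in column '", cn,
             "' at row ", bad, call. = FALSE)
      }
    }
    grid <- dat$wavenumber
    mat <- t(as.matrix(dat[, spec_cols, with = FALSE]))
    if (any(diff(grid) < 0)) {           # descending input: reorder ascending
      ord <- order(grid)
      grid <- grid[ord]
      mat <- mat[, ord, drop = FALSE]
    }
    idx <- match(spec_cols, meta$spectrum_id)
    if (anyNA(idx)) {
      stop("metadata error: label missing for spectra: ",
           paste(spec_cols[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    meta <- meta[idx, ]
    rownames(mat) <- spec_cols
  } else {
    long <- data.table::fread(path, colClasses = list(character = "cell_id"))
    need <- c("cell_id", "x", "y", "wavenumber_cm1", "intensity")
    miss <- setdiff(need, names(long))
    if (length(miss)) {
      stop("format error: long_map file lacks column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (!is.numeric(long$intensity)) {
      bad <- which(is.na(suppressWarnings(as.numeric(long$intensity))))[1L]
      stop("parse error: non-numeric intensity at row ", bad, call. = FALSE)
    }
    if (!is.numeric(long$wavenumber_cm1)) {
      stop("format error: wavenumber_cm1 column is not numeric", call. = FALSE)
    }
    grid <- sort(unique(long$wavenumber_cm1))
    key <- paste(long$cell_id, long$x, long$y, sep = "\r")
    ukey <- unique(key)
    widx <- match(long$wavenumber_cm1, grid)
    sidx <- match(key, ukey)
    mat <- matrix(NA_real_, nrow = length(ukey), ncol = length(grid))
    mat[cbind(sidx, widx)] <- long$intensity
    if (anyNA(mat)) {
      stop("format error: long_map is not a complete grid per spectrum",
           call. = FALSE)
    }
    first <- !duplicated(key)
    px <- data.frame(x = long$x[first], y = long$y[first])
    cid <- long$cell_id[first]
    # match spectra to sidecar rows by (cell_id, x, y)
    mkey <- paste(meta$cell_id, meta$x, meta$y, sep = "\r")
    idx <- match(ukey, mkey)
    if (anyNA(idx)) {
      stop("metadata error: label missing for ", sum(is.na(idx)),
           " spectra", call. = FALSE)
    }
    meta <- meta[idx, ]
    rownames(mat) <- meta$spectrum_id
    out <- spectral_dataset(grid, mat, meta$label, cid,
                            class_order = class_order, pixels = px)
    return(out)
  }
  pixels <- if (all(c("x", "y") %in% names(meta))) {
    data.frame(x = meta$x, y = meta$y)
  }
  spectral_dataset(grid, mat, meta$label, meta$cell_id,
                   class_order = class_order, pixels = pixels)
}
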