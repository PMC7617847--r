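#' Load a label atlas
#'
#' Reads an integer label volume and its lookup table (CSV with columns
#' `roi_type`, `hemisphere`, `label`) and validates them: labels must be
#' unique positive integers, every (ROI type, hemisphere) pair must map to
#' exactly one label, and the 12 ROI types must match [roi_types()].
#' Labels listed in the table but absent from the volume produce a warning;
#' labels present in the volume but not in the table are treated as
#' background.
#'
#' @param label_image Path to a NIfTI label volume, or a 3D array.
#' @param label_table Path to the lookup CSV, or a data frame.
#' @return A list of class `label_atlas` with `volume`, `table`,
#'   `roi_types`.
#' @export
load_atlas <- function(label_image, label_table) {
  vol <- if (is.character(label_image)) {
    as.array(RNifti::readNifti(label_image))
  } else {
    label_image
  }
  if (max(abs(vol - round(vol))) > 0) {
    stop("label volume must contain integers only")
  }
  vol <- array(as.integer(round(vol)), dim(vol))
  tab <- if (is.character(label_table)) {
    read.csv(label_table, stringsAsFactors = FALSE)
  } else {
    as.data.frame(label_table)
  }
  req <- c("roi_type", "hemisphere", "label")
  if (!all(req %in% names(tab))) {
    stop("label table needs columns ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(tab$label)) {
    stop("duplicate label ids in label table: ",
         paste(unique(tab$label[duplicated(tab$label)]), collapse = ", "))
  }
  if (any(tab$label <= 0)) stop("labels must be positive integers")
  key <- paste(tab$roi_type, tab$hemisphere)
  if (anyDuplicated(key)) {
    stop("duplicated (roi_type, hemisphere) rows in label table")
  }
  if (!setequal(unique(tab$roi_type), roi_types())) {
    stop("label table must cover exactly the 12 pain-connectome ROI types")
  }
  present <- unique(as.vector(vol))
  missing <- setdiff(tab$label, present)
  if (length(missing) > 0) {
    miss_rows <- tab[tab$label %in% missing, ]
    warning("labels in table but absent from volume: ",
            paste(sprintf("%s_%s (%d)", miss_rows$roi_type,
                          miss_rows$hemisphere, miss_rows$label),
                  collapse = ", "))
  }
  structure(list(volume = vol, table = as_tibble(tab),
                 roi_types = roi_types()),
            class = "label_atlas")
}

#' Extract gray-matter ROI mean time series
#'
#' For each (ROI type, hemisphere) column, averages the BOLD series over
#' the voxels whose label matches and whose gray-matter mask value exceeds
#' `gm_threshold` (unweighted mean, matching an analysis that averages
#' across gray-matter voxels without partial-volume weighting). Grids must
#' match exactly; no resampling is performed here.
#'
#' @param bold Path to a 4D NIfTI image, or a 4D array.
#' @param atlas A [load_atlas()] result.
#' @param gm_mask Path to a 3D NIfTI mask, or a 3D array. Binary masks
#'   (0/1) and probabilistic maps both work with the default threshold.
#' @param min_voxels Minimum eligible voxels per ROI (default 1); fewer is
#'   an error naming the ROI.
#' @param gm_threshold Strict lower bound on the mask value (default 0.5).
#' @param subject_id Identifier stored with the matrix.
#' @return A list of class `roi_timeseries` with `id`, `matrix` (`T x 24`,
#'   [ts_column_names()] columns) and `voxel_counts` (named integer
#'   vector).
#' @export
extract_roi_timeseries <- function(bold, atlas, gm_mask, min_voxels = 1L,
                                   gm_threshold = 0.5, subject_id = "s1") {
  stopifnot(inherits(atlas, "label_atlas"))
  if (min_voxels < 1L) stop("min_voxels must be >= 1")
  bold_arr <- if (is.character(bold)) as.array(RNifti::readNifti(bold)) else bold
  gm_arr <- if (is.character(gm_mask)) as.array(RNifti::readNifti(gm_mask)) else gm_mask
  if (length(dim(bold_arr)) != 4L) stop("bold must be a 4D image")
  sp <- dim(bold_arr)[1:3]
  if (!identical(as.integer(sp), as.integer(dim(atlas$volume))) ||
      !identical(as.integer(sp), as.integer(dim(gm_arr)))) {
    stop("bold, atlas and gray-matter mask must share the same voxel grid")
  }
  T_len <- dim(bold_arr)[4]
  if (T_len < 50L) stop("time series too short (need >= 50 volumes)")
  nvox <- prod(sp)
  flat <- matrix(bold_arr, nvox, T_len)
  lab_v <- as.vector(atlas$volume)
  gm_ok <- as.vector(gm_arr) > gm_threshold

  tab <- atlas$table
  cols <- ts_column_names()
  out <- matrix(NA_real_, T_len, length(cols), dimnames = list(NULL, cols))
  counts <- setNames(integer(length(cols)), cols)
  for (cn in cols) {
    parts <- strsplit(cn, "_(?=[LR]$)", perl = TRUE)[[1]]
    row <- tab[tab$roi_type == parts[1] & tab$hemisphere == parts[2], ]
    vox <- which(lab_v == row$label & gm_ok)
    if (length(vox) < min_voxels) {
      stop("ROI ", cn, " has ", length(vox),
           " eligible gray-matter voxel(s); need at least ", min_voxels)
    }
    counts[cn] <- length(vox)
    out[, cn] <- if (length(vox) == 1L) flat[vox, ] else colMeans(flat[vox, , drop = FALSE])
  }
  structure(list(id = subject_id, matrix = out, voxel_counts = counts),
            class = "roi_timeseries")
}

#' Write an extracted ROI time-series matrix
#'
#' Writes the `T x 24` matrix as CSV plus a JSON sidecar of voxel counts.
#'
#' @param ts A [extract_roi_timeseries()] result.
#' @param path CSV output path (sidecar gets extension `.json`).
#' @return Invisibly, the two paths.
#' @export
write_roi_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  write.csv(as.data.frame(ts$matrix), path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(as.list(ts$voxel_counts), side, auto_unbox = TRUE)
  invisible(c(path, side))
}
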