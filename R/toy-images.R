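#' Lay out a toy voxel atlas for the 24 bilateral ROIs
#'
#' Assigns each of the 24 (ROI type, hemisphere) labels a disjoint set of
#' voxels in a small 3D grid, for use with [render_toy_images()] when
#' testing extraction.
#'
#' @param voxels_per_roi Voxels per label (default 2).
#' @return A list of class `atlas_layout` with `dims` (3D grid) and
#'   `table` (tibble: `roi_type`, `hemisphere`, `label`, `voxels` list of
#'   linear voxel indices).
#' @export
toy_atlas_layout <- function(voxels_per_roi = 2L) {
  n_lab <- 24L
  need <- n_lab * voxels_per_roi
  nx <- ceiling(need^(1 / 3))
  dims <- c(nx, nx, ceiling(need / nx^2) + 1L)
  vox <- seq_len(need)
  tab <- tibble(
    roi_type = rep(roi_types(), times = 2),
    hemisphere = rep(hemispheres(), each = 12),
    label = seq_len(n_lab),
    voxels = split(vox, rep(seq_len(n_lab), each = voxels_per_roi))
  )
  structure(list(dims = as.integer(dims), table = tab),
            class = "atlas_layout")
}

#' Render a subject as toy NIfTI images
#'
#' Writes a 4D BOLD image, an integer label volume and a binary gray-matter
#' mask in which every voxel of a region carries that region's simulated
#' time series (plus optional i.i.d. voxel noise). The fixture is the
#' round-trip partner of [extract_roi_timeseries()].
#'
#' @param subject A [simulate_subject()] record.
#' @param layout An [toy_atlas_layout()]; voxel sets must be disjoint.
#' @param dir Output directory.
#' @param voxel_noise_sd SD of voxel-level Gaussian noise (default 0).
#' @param non_gm_labels Labels whose voxels are marked non-gray-matter in
#'   the mask (useful to provoke the empty-ROI error downstream).
#' @param seed Seed for the voxel noise.
#' @return A list with paths `bold`, `labels`, `gm_mask`, `label_table`.
#' @export
render_toy_images <- function(subject, layout, dir,
                              voxel_noise_sd = 0, non_gm_labels = integer(),
                              seed = 1L) {
  stopifnot(inherits(subject, "subject_record"),
            inherits(layout, "atlas_layout"))
  tab <- layout$table
  all_vox <- unlist(tab$voxels)
  if (anyDuplicated(all_vox)) stop("overlapping labels in atlas layout")
  if (any(lengths(tab$voxels) < 1L)) stop("every label needs >= 1 voxel")
  dims <- layout$dims
  nvox <- prod(dims)
  if (max(all_vox) > nvox) stop("layout voxels exceed grid")

  T_len <- nrow(subject$timeseries)
  label_vol <- array(0L, dims)
  gm_vol <- array(0, dims)
  bold <- array(0, c(dims, T_len))
  flat <- matrix(0, nvox, T_len)

  set.seed(seed)
  for (i in seq_len(nrow(tab))) {
    col <- paste0(tab$roi_type[i], "_", tab$hemisphere[i])
    series <- subject$timeseries[, col]
    for (v in tab$voxels[[i]]) {
      noise <- if (voxel_noise_sd > 0) rnorm(T_len, 0, voxel_noise_sd) else 0
      flat[v, ] <- series + noise
      label_vol[v] <- tab$label[i]
      gm_vol[v] <- if (tab$label[i] %in% non_gm_labels) 0 else 1
    }
  }
  bold[] <- flat  # linear voxel index is the leading dimension

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    bold = file.path(dir, "bold.nii.gz"),
    labels = file.path(dir, "labels.nii.gz"),
    gm_mask = file.path(dir, "gm.nii.gz"),
    label_table = file.path(dir, "labels.csv")
  )
  RNifti::writeNifti(bold, paths$bold)
  RNifti::writeNifti(label_vol, paths$labels)
  RNifti::writeNifti(gm_vol, paths$gm_mask)
  write.csv(tab[, c("roi_type", "hemisphere", "label")],
            paths$label_table, row.names = FALSE)
  paths
}
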