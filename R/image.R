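#' 3D image volume with voxel-to-world geometry
#'
#' The basic container used throughout the pipeline: a 3D scalar array plus a
#' 4x4 affine mapping 0-based voxel indices to world coordinates in mm
#' (RAS+ convention, as NIfTI). Intensities are held as double precision
#' regardless of on-disk storage type.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-index-to-world matrix (mm). If `NULL`, a diagonal
#'   affine is built from `voxel_size` with the origin at voxel (0,0,0).
#' @param voxel_size length-3 positive voxel spacing in mm; ignored when
#'   `affine` is given.
#' @return An object of class `mm_image`.
#' @export
image_volume <- function(data, affine = NULL, voxel_size = c(1, 1, 1)) {
  if (length(dim(data)) != 3L)
    stop("image data must be 3-dimensional, got ", length(dim(data)),
         " dimensions", call. = FALSE)
  if (is.null(affine)) {
    stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
    affine <- diag(c(voxel_size, 1))
  }
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, affine = affine), class = "mm_image")
}

#' @export
print.mm_image <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_size(x)
  cat(sprintf("<mm_image> %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel spacing of an image in mm
#'
#' Derived from the column norms of the affine.
#' @param img an `mm_image`, `mm_mask` or `mm_labels` object.
#' @return numeric length-3.
#' @export
voxel_size <- function(img) {
  sqrt(colSums(img$affine[1:3, 1:3]^2))
}

#' Voxel volume in mm^3
#' @param img an image-like object.
#' @export
voxel_volume <- function(img) prod(voxel_size(img))

#' Binary mask on an image grid
#'
#' @param data 3D logical (or 0/1) array.
#' @param affine 4x4 voxel-to-world matrix.
#' @return An object of class `mm_mask` (also an `mm_image`).
#' @export
binary_mask <- function(data, affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("mask data must be 3-dimensional", call. = FALSE)
  arr <- array(as.logical(data), dim(data))
  if (anyNA(arr)) stop("mask contains NA", call. = FALSE)
  img <- image_volume(array(as.double(arr), dim(arr)), affine)
  structure(list(data = arr, affine = img$affine),
            class = c("mm_mask", "mm_image"))
}

#' Integer label map with a label dictionary
#'
#' Label 0 is reserved for background; every nonzero label id present in the
#' array must be named in `label_names`.
#'
#' @param data 3D non-negative integer array.
#' @param label_names named character vector or id->name mapping
#'   (names are ids as characters) covering every nonzero id.
#' @param affine 4x4 voxel-to-world matrix.
#' @export
label_map <- function(data, label_names = NULL, affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("label data must be 3-dimensional", call. = FALSE)
  arr <- array(as.integer(round(data)), dim(data))
  if (any(arr < 0L)) stop("labels must be non-negative", call. = FALSE)
  ids <- sort(unique(arr[arr > 0L]))
  if (is.null(label_names))
    label_names <- setNames(paste0("region_", ids), ids)
  missing <- setdiff(as.character(ids), names(label_names))
  if (length(missing))
    stop("label ids without names: ", paste(missing, collapse = ", "),
         call. = FALSE)
  img <- image_volume(array(as.double(arr), dim(arr)), affine)
  structure(list(data = arr, affine = img$affine, label_names = label_names),
            class = c("mm_labels", "mm_image"))
}

# sform/qform reader preference: sform when set, else qform
#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An `mm_image`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, file has ", length(dim(arr)),
         " dimensions: ", path, call. = FALSE)
  hdr <- RNifti::niftiHeader(nii)
  if (hdr$sform_code > 0) {
    aff <- rbind(hdr$srow_x, hdr$srow_y, hdr$srow_z, c(0, 0, 0, 1))
  } else {
    aff <- unname(RNifti::xform(nii))
    aff <- rbind(aff[1:3, , drop = FALSE], c(0, 0, 0, 1))
  }
  arr <- array(as.double(arr), dim(arr))  # plain array, no NIfTI attributes
  image_volume(arr, affine = aff)
}

#' Write a volume, mask or label map as NIfTI-1
#'
#' Images are stored as float32, masks as uint8 and label maps as uint16.
#'
#' @param img object to write.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype override the on-disk datatype (RNifti name).
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path, datatype = NULL) {
  if (is.null(datatype)) {
    datatype <- if (inherits(img, "mm_mask")) "uint8"
    else if (inherits(img, "mm_labels")) "uint16"
    else "double"
  }
  arr <- img$data
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
  nii <- RNifti::asNifti(arr)
  sf <- structure(img$affine, code = 2L)
  RNifti::sform(nii) <- sf
  RNifti::qform(nii) <- sf
  RNifti::writeNifti(nii, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI-1 file as a binary mask
#' @param path file path.
#' @export
read_mask <- function(path) {
  img <- read_volume(path)
  binary_mask(img$data != 0, img$affine)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  hw <- max(1L, ceiling(5 * sigma_vox))
  x <- (-hw):hw
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

smooth_array <- function(arr, sigma_vox) {
  dm <- dim(arr)
  sigma_vox <- rep(sigma_vox, length.out = 3)
  out <- as.double(arr)
  for (ax in 0:2) {
    sig <- sigma_vox[ax + 1]
    if (sig <= 0) next
    if (sig > 3) {
      # three-pass box filter: O(n) Gaussian approximation for wide kernels
      r <- max(1L, as.integer(round(sqrt(sig^2 * 12 / 3 + 1) / 2 - 0.5)))
      for (p in 1:3) out <- cpp_box1(out, dm, r, ax)
    } else {
      k <- gaussian_kernel_1d(sig)
      if (length(k) > 1) out <- cpp_conv1(out, dm, k, ax)
    }
  }
  array(out, dm)
}

#' Gaussian smoothing of an image
#'
#' Separable Gaussian convolution with the kernel width given as full width
#' at half maximum in mm (sigma = fwhm / (2 sqrt(2 ln 2)) per axis, converted
#' to voxels through the voxel spacing). Boundaries are mirror-padded, which
#' conserves the mean near edges better than zero padding.
#'
#' @param img an `mm_image`.
#' @param fwhm_mm non-negative kernel FWHM in mm (scalar or length 3).
#' @return smoothed `mm_image` on the same grid.
#' @export
gaussian_smooth <- function(img, fwhm_mm) {
  if (any(fwhm_mm < 0)) stop("fwhm must be non-negative", call. = FALSE)
  fwhm_mm <- rep(fwhm_mm, length.out = 3)
  if (all(fwhm_mm == 0)) return(img)
  sig <- fwhm_to_sigma(fwhm_mm) / voxel_size(img)
  image_volume(smooth_array(img$data, sig), img$affine)
}

#' Dilate (or erode) a binary mask by a Euclidean ball
#'
#' Uses an exact Euclidean distance transform, so the structuring element is
#' the discrete ball of the given voxel radius (isotropic growth on isotropic
#' grids). Dilation is clipped at the grid boundary.
#'
#' @param mask an `mm_mask`.
#' @param radius_voxels non-negative radius in voxels.
#' @return dilated `mm_mask`.
#' @export
dilate_mask <- function(mask, radius_voxels) {
  if (radius_voxels < 0) stop("radius must be non-negative", call. = FALSE)
  if (radius_voxels == 0 || !any(mask$data)) return(mask)
  d2 <- cpp_edt_sq(as.logical(mask$data), dim(mask$data), c(1, 1, 1))
  out <- array(d2 <= radius_voxels^2 + 1e-9, dim(mask$data))
  binary_mask(out, mask$affine)
}

#' Erode a binary mask by a Euclidean ball
#' @inheritParams dilate_mask
#' @export
erode_mask <- function(mask, radius_voxels) {
  if (radius_voxels < 0) stop("radius must be non-negative", call. = FALSE)
  if (radius_voxels == 0) return(mask)
  d2 <- cpp_edt_sq(!mask$data, dim(mask$data), c(1, 1, 1))
  out <- array(mask$data & d2 > radius_voxels^2 + 1e-9, dim(mask$data))
  binary_mask(out, mask$affine)
}

#' Signal- and contrast-to-noise ratio of a scan
#'
#' SNR is the mean signal over the brain divided by the standard deviation of
#' intensities in a pure-noise region; CNR is the difference between
#' probability-weighted GM and WM mean intensities divided by the same noise
#' standard deviation.
#'
#' @param img the image.
#' @param tissues a [tissue_probability_maps()] object on the same grid, with
#'   at least `GM` and `WM` classes.
#' @param noise_mask `mm_mask` of background voxels free of any object signal.
#' @return a one-row tibble with columns `snr`, `cnr`, `noise_sd`,
#'   `gm_mean`, `wm_mean`, `signal_mean`.
#' @export
compute_snr_cnr <- function(img, tissues, noise_mask) {
  if (!any(noise_mask$data)) stop("noise mask is empty", call. = FALSE)
  noise_sd <- sd(img$data[noise_mask$data])
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("noise standard deviation is zero; noise region is degenerate",
         call. = FALSE)
  pg <- tissues$classes$GM
  pw <- tissues$classes$WM
  brain <- brain_probability(tissues)
  wsum <- sum(brain)
  signal_mean <- sum(img$data * brain) / wsum
  gm_mean <- sum(img$data * pg) / sum(pg)
  wm_mean <- sum(img$data * pw) / sum(pw)
  tibble::tibble(
    snr = signal_mean / noise_sd,
    cnr = (gm_mean - wm_mean) / noise_sd,
    noise_sd = noise_sd,
    gm_mean = gm_mean,
    wm_mean = wm_mean,
    signal_mean = signal_mean
  )
}

#' Scale volume measurements for gradient calibration
#'
#' Applies a phantom-based gradient calibration factor to a table of volume
#' measurements. The factor may be given on the linear scale (applied cubed)
#' or directly on the volumetric scale.
#'
#' @param volumes a data frame of volume measurements; every numeric column
#'   except those named in `exclude` is scaled.
#' @param factor positive scaling factor.
#' @param mode `"volumetric"` (multiply by `factor`) or `"linear"`
#'   (multiply by `factor^3`).
#' @param exclude character vector of column names left untouched.
#' @return tibble with scaled volumes.
#' @export
scale_volume_measurements <- function(volumes, factor,
                                      mode = c("volumetric", "linear"),
                                      exclude = character()) {
  mode <- match.arg(mode)
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("factor must be a positive scalar", call. = FALSE)
  mult <- if (mode == "linear") factor^3 else factor
  out <- tibble::as_tibble(volumes)
  for (nm in names(out)) {
    if (nm %in% exclude) next
    if (is.numeric(out[[nm]])) out[[nm]] <- out[[nm]] * mult
  }
  out
}

# world <-> voxel helpers -----------------------------------------------------

#' Convert 0-based voxel indices to world mm coordinates
#' @param img image supplying the affine.
#' @param ijk n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates.
#' @export
voxel_to_world <- function(img, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  t(img$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' Convert world mm coordinates to 0-based voxel indices
#' @inheritParams voxel_to_world
#' @param xyz n x 3 matrix of world coordinates.
#' @export
world_to_voxel <- function(img, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  t(solve(img$affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

# 0-based voxel index grid of an image, n x 3 (cached per dim)
voxel_grid <- function(dm) {
  key <- paste(dm, collapse = "x")
  g <- .mm_env[[key]]
  if (is.null(g)) {
    g <- cbind(
      rep.int(seq_len(dm[1]) - 1, times = dm[2] * dm[3]),
      rep.int(rep(seq_len(dm[2]) - 1, each = dm[1]), times = dm[3]),
      rep(seq_len(dm[3]) - 1, each = dm[1] * dm[2])
    )
    if (length(.mm_env) > 20) rm(list = ls(.mm_env), envir = .mm_env)
    .mm_env[[key]] <- g
  }
  g
}

# world coordinates of every voxel centre, n x 3
world_grid <- function(img) {
  voxel_to_world(img, voxel_grid(dim(img$data)))
}

#' Intensity centroid in world coordinates
#' @param img image volume.
#' @return length-3 world mm coordinates of the intensity-weighted centroid.
#' @export
intensity_centroid <- function(img) {
  w <- as.double(img$data)
  tot <- sum(w)
  if (tot <= 0) stop("image has no intensity mass", call. = FALSE)
  dm <- dim(img$data)
  ix <- seq_len(dm[1]) - 1; iy <- seq_len(dm[2]) - 1; iz <- seq_len(dm[3]) - 1
  m <- array(w, dm)
  cx <- sum(rowSums(m, dims = 1) * ix) / tot
  my <- apply(m, 2, sum)
  cy <- sum(my * iy) / tot
  mz <- apply(m, 3, sum)
  cz <- sum(mz * iz) / tot
  drop(voxel_to_world(img, c(cx, cy, cz)))
}
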