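#' Rigid and affine transform helpers
#'
#' Transforms are 4x4 homogeneous matrices acting on world coordinates (mm).
#' A rigid transform has a proper orthogonal 3x3 block (det +1).
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 mm translation.
#' @return 4x4 homogeneous matrix of class `mm_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthogonal", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be proper (det +1)", call. = FALSE)
  m <- diag(4)
  m[1:3, 1:3] <- rotation
  m[1:3, 4] <- translation
  structure(m, class = c("mm_transform", "matrix", "array"))
}

as_transform <- function(m) {
  m <- unname(as.matrix(m))
  stopifnot(all(dim(m) == c(4, 4)))
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row of a homogeneous transform must be (0,0,0,1)",
         call. = FALSE)
  structure(m, class = c("mm_transform", "matrix", "array"))
}

#' Elementary rotations (radians)
#' @param theta angle in radians.
#' @name elementary-rotations
NULL

#' @rdname elementary-rotations
#' @export
rot_x <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  rbind(c(1, 0, 0), c(0, c_, -s_), c(0, s_, c_))
}

#' @rdname elementary-rotations
#' @export
rot_y <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  rbind(c(c_, 0, s_), c(0, 1, 0), c(-s_, 0, c_))
}

#' @rdname elementary-rotations
#' @export
rot_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  rbind(c(c_, -s_, 0), c(s_, c_, 0), c(0, 0, 1))
}

#' Compose Euler angles into a rotation matrix (Rz Ry Rx order)
#' @param angles length-3 radians (about x, y, z).
#' @export
euler_rotation <- function(angles) {
  rot_z(angles[3]) %*% rot_y(angles[2]) %*% rot_x(angles[1])
}

#' Rotation about an arbitrary world centre
#'
#' @param rotation 3x3 rotation.
#' @param centre world point left fixed by the transform.
#' @param translation extra translation applied after rotation.
#' @export
rotation_about <- function(rotation, centre, translation = c(0, 0, 0)) {
  rigid_transform(rotation, as.numeric(centre) -
                    as.numeric(rotation %*% centre) + translation)
}

#' Geodesic angle between two rotations, in degrees
#' @param r1,r2 3x3 rotation matrices (or 4x4 transforms).
#' @export
geodesic_angle <- function(r1, r2 = diag(3)) {
  if (all(dim(r1) == c(4, 4))) r1 <- r1[1:3, 1:3]
  if (all(dim(r2) == c(4, 4))) r2 <- r2[1:3, 1:3]
  r <- crossprod(r2, r1)
  ct <- (sum(diag(r)) - 1) / 2
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Apply a homogeneous transform to points
#' @param m 4x4 matrix.
#' @param pts n x 3 matrix.
#' @export
apply_transform <- function(m, pts) {
  pts <- matrix(pts, ncol = 3)
  t(m %*% rbind(t(pts), 1))[, 1:3, drop = FALSE]
}

#' Principal matrix logarithm / exponential of a homogeneous transform
#'
#' Used for the log-Euclidean halfway transform: the halfway of `A` is
#' `expm(0.5 logm(A))`. Fails (with an informative error) when `A` has
#' non-positive real eigenvalues, where the principal log is undefined.
#'
#' @param m 4x4 homogeneous matrix.
#' @return 4x4 matrix.
#' @export
transform_log <- function(m) {
  ev <- eigen(m, only.values = TRUE)$values
  if (any(Re(ev) <= 0 & abs(Im(ev)) < 1e-12))
    stop("matrix log undefined: non-positive real eigenvalue", call. = FALSE)
  re <- pracma::logm(unname(as.matrix(m)))
  Re(re)
}

#' @rdname transform_log
#' @export
transform_exp <- function(m) {
  Re(pracma::expm(unname(as.matrix(m))))
}

#' Halfway (square root) of a transform in the log-Euclidean sense
#' @param m 4x4 homogeneous matrix.
#' @export
halfway_transform <- function(m) {
  as_transform(transform_exp(0.5 * transform_log(m)))
}

# ---------------------------------------------------------------------------

#' Resample an image onto a target grid through a world-space transform
#'
#' The returned image lives on the grid of `target` (an image, or a list with
#' `dim` and `affine`). Voxel values are pulled from `img`: for each target
#' voxel centre x (world mm), the output value is `img(transform %*% x)`.
#' To resample an image "moved by T", pass `transform = solve(T)`.
#'
#' @param img source image.
#' @param target image (or list with `dim`, `affine`) defining the output
#'   grid; defaults to the source grid.
#' @param transform 4x4 world-to-world pull-back matrix (target world ->
#'   source world). Default identity.
#' @param method `"cubic"` (default for images), `"linear"` or `"nearest"`.
#' @param fill out-of-field value.
#' @return resampled `mm_image` (masks and labels keep their class and use
#'   nearest-neighbour interpolation).
#' @export
resample_volume <- function(img, target = NULL, transform = diag(4),
                            method = NULL, fill = 0) {
  is_mask <- inherits(img, "mm_mask")
  is_lab <- inherits(img, "mm_labels")
  if (is.null(method)) method <- if (is_mask || is_lab) "nearest" else "cubic"
  mcode <- switch(method, nearest = 0L, linear = 1L, cubic = 3L,
                  stop("unknown method ", method))
  if (is.null(target)) target <- img
  tdim <- if (is.null(target$dim)) dim(target$data) else as.integer(target$dim)
  taff <- target$affine
  # target voxel -> target world -> source world -> source voxel
  m <- solve(img$affine) %*% transform %*% taff
  g <- voxel_grid(tdim)
  co <- tcrossprod(m[1:3, 1:3], g)
  co <- co + m[1:3, 4]
  src <- if (is_mask) array(as.double(img$data), dim(img$data))
         else if (is_lab) array(as.double(img$data), dim(img$data))
         else img$data
  vals <- cpp_sample(as.double(src), dim(src), co[1, ], co[2, ], co[3, ],
                     mcode, fill)
  arr <- array(vals, tdim)
  if (is_mask) return(binary_mask(arr > 0.5, taff))
  if (is_lab) return(label_map(arr, img$label_names, taff))
  image_volume(arr, taff)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Downsample an image by an integer factor (with anti-alias smoothing)
#' @param img image.
#' @param factor integer >= 1.
#' @export
downsample_volume <- function(img, factor = 2L) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(img)
  sm <- gaussian_smooth(img, fwhm_mm = voxel_size(img) * factor * 0.8)
  dm <- dim(img$data)
  nd <- pmax(1L, dm %/% factor)
  aff <- img$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * factor
  resample_volume(sm, target = list(dim = nd, affine = aff),
                  method = "linear")
}

#' Reflect an image in a sagittal plane
#'
#' Samples the image at x-mirrored world coordinates about the plane
#' `x = plane_x` (world mm). Reflection is used only for symmetry scoring,
#' never applied to a subject.
#'
#' @param img image.
#' @param plane_x world x of the mirror plane; default the intensity centroid.
#' @export
reflect_x <- function(img, plane_x = NULL) {
  if (is.null(plane_x)) plane_x <- intensity_centroid(img)[1]
  m <- diag(4)
  m[1, 1] <- -1
  m[1, 4] <- 2 * plane_x
  resample_volume(img, transform = m, method = "linear")
}
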