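# Piecewise-linear intensity standardisation: 11 histogram landmarks at
# percentiles {1, 10, 20, ..., 90, 99} are mapped image-by-image onto a
# trained standard scale so that similar intensities represent equivalent
# anatomy across a cohort (a prerequisite for unbiased group-wise averaging).

LANDMARK_PERCENTILES <- c(1, seq(10, 90, by = 10), 99)

#' Histogram landmarks of an image
#'
#' Empirical percentiles (linear interpolation between order statistics) of
#' the intensities within a mask, at the 11 landmark percentiles
#' 1, 10, 20, ..., 90, 99.
#'
#' @param img image.
#' @param mask `mm_mask`; typically the dilated brain mask. `NULL` uses all
#'   voxels.
#' @return object of class `mm_landmarks` with `percentiles`, `values`,
#'   `source_mask` (descriptor string).
#' @export
compute_landmarks <- function(img, mask = NULL) {
  x <- if (is.null(mask)) as.double(img$data) else img$data[mask$data]
  if (!length(x)) stop("mask is empty", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("constant intensities: landmarks are degenerate", call. = FALSE)
  v <- quantile(x, probs = LANDMARK_PERCENTILES / 100, names = FALSE,
                type = 7)
  structure(list(percentiles = LANDMARK_PERCENTILES, values = v,
                 source_mask = if (is.null(mask)) "whole image" else "mask"),
            class = "mm_landmarks")
}

# map landmark values affinely so (pc1, pc99) -> (0, 1)
map_unit <- function(values) {
  lo <- values[1]; hi <- values[length(values)]
  (values - lo) / (hi - lo)
}

#' Train a standard intensity scale from cohort landmark profiles
#'
#' Each profile is first mapped affinely so its (pc1, pc99) land on the
#' standard range, then the per-landmark mean across profiles defines the
#' standard scale.
#'
#' @param profiles list of [compute_landmarks()] results.
#' @param range standard range for (pc1, pc99); default (0, 1).
#' @return object of class `mm_standard_scale` with `percentiles`,
#'   `target_values`, `range`.
#' @export
train_standard_scale <- function(profiles, range = c(0, 1)) {
  stopifnot(length(profiles) >= 1)
  mapped <- vapply(profiles, function(p)
    range[1] + map_unit(p$values) * diff(range),
    numeric(length(LANDMARK_PERCENTILES)))
  target <- rowMeans(mapped)
  if (any(diff(target) < 0))
    stop("mean landmark profile is non-monotone: pathological inputs",
         call. = FALSE)
  if (any(diff(target) == 0))
    target <- target + seq_along(target) * 1e-12  # guard strictness
  structure(list(percentiles = LANDMARK_PERCENTILES, target_values = target,
                 range = range), class = "mm_standard_scale")
}

#' Standardise an image onto the standard intensity scale
#'
#' Piecewise-linear mapping of intensities between successive landmark
#' pairs, with linear extrapolation beyond pc1 and pc99 (using the slope of
#' the outermost segments). The mapping is monotone non-decreasing, so
#' intensity rank order is preserved.
#'
#' @param img image.
#' @param profile this image's [compute_landmarks()].
#' @param scale a trained [train_standard_scale()].
#' @return standardised `mm_image`.
#' @export
standardise <- function(img, profile, scale) {
  if (length(profile$values) != length(scale$target_values))
    stop("landmark count mismatch between profile and scale", call. = FALSE)
  xs <- profile$values
  ys <- scale$target_values
  # collapse duplicate source landmarks (flat histogram stretches)
  keep <- c(TRUE, diff(xs) > 0)
  xs <- xs[keep]; ys <- ys[keep]
  x <- as.double(img$data)
  if (length(xs) < 2) {
    out <- rep(ys[1], length(x))
  } else {
    out <- approx(xs, ys, xout = x, rule = 2)$y
    lo <- x < xs[1]
    if (any(lo)) {
      sl <- (ys[2] - ys[1]) / (xs[2] - xs[1])
      out[lo] <- ys[1] + (x[lo] - xs[1]) * sl
    }
    n <- length(xs)
    hiv <- x > xs[n]
    if (any(hiv)) {
      sl <- (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1])
      out[hiv] <- ys[n] + (x[hiv] - xs[n]) * sl
    }
  }
  image_volume(array(out, dim(img$data)), img$affine)
}

# standardise an image against a scale trained only on itself (0-1 range);
# used before foreground modelling in extraction
standardise_self <- function(img, mask = NULL) {
  lm <- compute_landmarks(img, mask)
  sc <- train_standard_scale(list(lm))
  standardise(img, lm, sc)
}

#' Standardise a cohort of images
#'
#' Computes per-image landmarks (within the per-image masks when given),
#' trains the standard scale on all profiles, and maps every image.
#'
#' @param imgs list of images.
#' @param masks optional list of masks (same length).
#' @return list with `images` (standardised), `scale`, `profiles`.
#' @export
standardise_cohort <- function(imgs, masks = NULL) {
  profiles <- lapply(seq_along(imgs), function(i)
    compute_landmarks(imgs[[i]], if (is.null(masks)) NULL else masks[[i]]))
  scale <- train_standard_scale(profiles)
  images <- lapply(seq_along(imgs), function(i)
    standardise(imgs[[i]], profiles[[i]], scale))
  list(images = images, scale = scale, profiles = profiles)
}
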