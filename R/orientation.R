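# Orientation to standard RAS space. Mouse brains are elongated
# antero-posteriorly (AP > RL, IS) and approximately mirror-symmetric about
# the mid-sagittal plane; both properties are exploited: principal axes of
# the intensity inertia tensor align AP with y, a roll search plus rigid
# refinement against the image's own reflection aligns the mid-sagittal
# plane, and 180-degree candidates are disambiguated against a reference.

#' Principal axes of the intensity inertia tensor
#'
#' The inertia tensor is computed from intensity-weighted second central
#' moments in world mm about the intensity centroid (intensity weights, not
#' a binary mask: the stage runs before masking on background-suppressed
#' standardised intensities). The antero-posterior axis is the eigenvector
#' with the smallest eigenvalue.
#'
#' @param img image with positive total intensity.
#' @param degeneracy_ratio flag the axes as degenerate when the ratio of the
#'   two smallest eigenvalues is below this.
#' @param background_level intensities below this carry no inertia weight.
#' @return list with `eigenvalues` (descending), `eigenvectors` (columns,
#'   matching order), `centroid` (world mm), `degenerate` (logical).
#' @export
inertia_principal_axes <- function(img, degeneracy_ratio = 1.05,
                                   background_level = 0) {
  w <- as.double(img$data) - background_level
  w[w < 0] <- 0
  tot <- sum(w)
  if (tot <= 0) stop("image has no intensity mass", call. = FALSE)
  xyz <- world_grid(img)
  ctr <- colSums(xyz * w) / tot
  d <- sweep(xyz, 2, ctr)
  # inertia tensor I = sum w (|d|^2 I3 - d d^T)
  xx <- sum(w * d[, 1]^2); yy <- sum(w * d[, 2]^2); zz <- sum(w * d[, 3]^2)
  xy <- sum(w * d[, 1] * d[, 2]); xz <- sum(w * d[, 1] * d[, 3])
  yz <- sum(w * d[, 2] * d[, 3])
  inertia <- matrix(c(yy + zz, -xy, -xz,
                      -xy, xx + zz, -yz,
                      -xz, -yz, xx + yy), 3, 3) / tot
  e <- eigen(inertia, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  ev <- e$values[ord]
  vec <- e$vectors[, ord, drop = FALSE]
  degen <- ev[2] / ev[3] < degeneracy_ratio
  if (degen)
    warning("principal axes nearly degenerate (eigenvalue ratio ",
            format(ev[2] / ev[3], digits = 4), ")", call. = FALSE)
  list(eigenvalues = ev, eigenvectors = vec, centroid = ctr,
       degenerate = degen)
}

# rotation (world) taking the principal axes onto the grid axes:
# smallest-eigenvalue axis -> y (AP), largest -> z (IS), middle -> x (RL)
axes_to_standard_rotation <- function(axes) {
  v_ap <- axes$eigenvectors[, 3]  # smallest eigenvalue
  v_is <- axes$eigenvectors[, 1]  # largest eigenvalue
  v_rl <- axes$eigenvectors[, 2]
  r <- rbind(v_rl, v_ap, v_is)    # rows: world axes x,y,z in brain frame
  # fix signs for a proper rotation with a stable convention
  for (i in 1:3) if (r[i, i] < 0) r[i, ] <- -r[i, ]
  if (det(r) < 0) r[3, ] <- -r[3, ]
  # re-orthonormalise (numerical hygiene)
  s <- svd(r)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) { s$u[, 3] <- -s$u[, 3]; r <- s$u %*% t(s$v) }
  r
}

#' Align the intensity long axis with the y axis
#'
#' Rotates the image (about its intensity centroid) so the principal axes
#' land on the grid axes, with the long (AP) axis parallel to y. The
#' returned transform maps output world coordinates to input world
#' coordinates (pull-back), and is always a proper rotation.
#'
#' @param img image.
#' @param resample produce the resampled image (cubic interpolation).
#' @param background_level intensities below this carry no inertia weight.
#' @return list with `image`, `transform` (4x4), `rotation` (3x3).
#' @export
align_long_axis <- function(img, resample = TRUE, background_level = 0.1) {
  axes <- inertia_principal_axes(img, background_level = background_level)
  if (axes$degenerate)
    stop("degenerate principal axes; cannot orient", call. = FALSE)
  r <- axes_to_standard_rotation(axes)
  # pull-back: output world x -> input world r^T x (rotation about centroid)
  trans <- rotation_about(t(r), axes$centroid)
  out <- if (resample) resample_volume(img, transform = trans) else NULL
  list(image = out, transform = as_transform(trans), rotation = r)
}

#' Mid-sagittal symmetry score
#'
#' Pearson correlation between the image and its reflection in the plane
#' x = (intensity centroid x), over voxels where either image exceeds the
#' background level.
#'
#' @param img image.
#' @param background_level intensities at or below this are background.
#' @param plane_x world x of the reflection plane (default: centroid).
#' @return Pearson r in `[-1, 1]`.
#' @export
symmetry_score <- function(img, background_level = 0.1, plane_x = NULL) {
  if (diff(range(img$data)) == 0)
    stop("constant image: symmetry score undefined", call. = FALSE)
  ref <- reflect_x(img, plane_x)
  a <- as.double(img$data); b <- as.double(ref$data)
  sel <- a > background_level | b > background_level
  if (sum(sel) < 10) sel <- rep(TRUE, length(a))
  stats::cor(a[sel], b[sel])
}

#' Search rolls about y for the most mirror-symmetric pose
#'
#' Evaluates the symmetry score at `n_rolls` equally spaced roll angles in
#' [0, 360) degrees and returns the best (ties to the smallest angle).
#'
#' @param img axis-aligned image.
#' @param n_rolls number of candidate rolls (default 14).
#' @param background_level passed to [symmetry_score()].
#' @param downsample evaluate at this downsampling factor for speed.
#' @return list with `best_roll_deg`, `best_r`, `angles_deg`, `scores`.
#' @export
roll_search <- function(img, n_rolls = 14L, background_level = 0.1,
                        downsample = 2L, refine = TRUE) {
  if (n_rolls < 2) stop("need at least 2 rolls", call. = FALSE)
  angles <- seq(0, 360, length.out = n_rolls + 1)[seq_len(n_rolls)]
  ctr <- intensity_centroid(img)
  small <- if (downsample > 1) downsample_volume(img, downsample) else img
  score_at <- function(a) {
    trans <- rotation_about(rot_y(a * pi / 180), ctr)
    rolled <- resample_volume(small, transform = trans, method = "linear")
    symmetry_score(rolled, background_level)
  }
  scores <- vapply(angles, score_at, numeric(1))
  best <- which(scores >= max(scores) - 1e-12)[1]
  best_a <- angles[best]
  best_r <- scores[best]
  if (refine) {
    # the r landscape can peak between the coarse rolls: refine the top
    # few basins with a local 1-D search (ties keep the smallest angle)
    spacing <- 360 / n_rolls
    top <- utils::head(order(-scores, angles), 3)
    for (b in top) {
      opt <- stats::optimize(function(a) -score_at(a),
                             interval = angles[b] + c(-1, 1) * spacing,
                             tol = 0.25)
      if (-opt$objective > best_r + 1e-9) {
        best_r <- -opt$objective
        best_a <- opt$minimum %% 360
      }
    }
  }
  list(best_roll_deg = best_a, best_r = best_r,
       angles_deg = angles, scores = scores)
}

#' Rigid refinement through the halfway transform to the reflection
#'
#' Rigidly registers the image to its own mid-sagittal reflection, yielding
#' an affine A; resampling through the log-Euclidean half of A (the
#' principal matrix square root) symmetrises the pose. If the matrix log is
#' undefined the refinement is skipped with a warning.
#'
#' @param img approximately symmetric image (after [roll_search()]).
#' @param background_level passed to [symmetry_score()].
#' @return list with `image`, `transform` (the half transform, pull-back),
#'   `A` (full registration transform), `refined` (logical).
#' @export
rigid_refine_halfway <- function(img, background_level = 0.1) {
  ref <- reflect_x(img)
  reg <- register(ref, img, model = "rigid", similarity = "pearson",
                  levels = c(2, 1), cycles = c(3, 1), symmetric = FALSE)
  a <- reg$transform
  half <- tryCatch(halfway_transform(a), error = function(e) {
    warning("halfway transform unavailable (", conditionMessage(e),
            "); refinement skipped", call. = FALSE)
    NULL
  })
  if (is.null(half))
    return(list(image = img, transform = as_transform(diag(4)), A = a,
                refined = FALSE))
  # the symmetrising pull-back is the inverse half under this registration
  # convention (mirror plane contains the rotation axis); both signs are
  # evaluated and the one improving symmetry kept
  pre <- symmetry_score(img, background_level)
  cands <- list(solve(half), half)
  outs <- lapply(cands, function(h) resample_volume(img, transform = h))
  posts <- vapply(outs, symmetry_score, numeric(1), background_level)
  b <- which.max(posts)
  if (posts[b] < pre - 1e-6)
    return(list(image = img, transform = as_transform(diag(4)), A = a,
                refined = FALSE))
  list(image = outs[[b]], transform = as_transform(cands[[b]]), A = a,
       refined = TRUE)
}

ORIENTATION_CANDIDATES <- list(
  RAS = diag(3), LAI = rot_y(pi), LPS = rot_z(pi), RPI = rot_x(pi))

#' Disambiguate the four 180-degree orientation candidates
#'
#' Principal axes leave a four-fold ambiguity (RAS, LAI, LPS, RPI, all
#' proper rotations). Each candidate is rigidly registered to a correctly
#' oriented reference and the candidate with the highest Pearson r wins.
#'
#' @param img axis-aligned, symmetrised image.
#' @param reference correctly oriented (RAS) image.
#' @param refine_registration rigidly register each candidate to the
#'   reference before scoring (more robust, slower).
#' @param ambiguity_margin error if the two best scores differ by less.
#' @return list with `code`, `transform` (pull-back, including the
#'   registration refinement when enabled), `score`, `scores`.
#' @export
disambiguate_orientation <- function(img, reference,
                                     refine_registration = TRUE,
                                     ambiguity_margin = 0.01) {
  ctr <- intensity_centroid(img)
  small_ref <- if (max(voxel_size(reference)) < 0.9 * max(voxel_size(img)))
    downsample_volume(reference, 2L) else reference
  res <- lapply(names(ORIENTATION_CANDIDATES), function(code) {
    rot <- ORIENTATION_CANDIDATES[[code]]
    trans <- rotation_about(t(rot), ctr)   # pull-back of applying rot
    cand <- resample_volume(img, transform = trans, method = "linear")
    if (refine_registration) {
      lev <- if (min(dim(img$data)) >= 40) c(2) else c(1)
      reg <- register(cand, small_ref, model = "rigid",
                      similarity = "pearson", levels = lev,
                      cycles = c(2), symmetric = FALSE)
      score <- reg$score
      total <- trans %*% reg$transform
    } else {
      samp <- resample_volume(cand, target = small_ref, method = "linear")
      score <- similarity_pearson(as.double(samp$data),
                                  as.double(small_ref$data))
      total <- trans
    }
    list(code = code, transform = total, score = score)
  })
  scores <- vapply(res, `[[`, numeric(1), "score")
  ord <- order(-scores)
  if (max(scores) - min(scores) < ambiguity_margin)
    stop("orientation ambiguous: all candidates score within ",
         ambiguity_margin, " (no usable AP/IS asymmetry)", call. = FALSE)
  best <- res[[ord[1]]]
  list(code = best$code, transform = as_transform(best$transform),
       score = best$score, scores = setNames(scores, names(ORIENTATION_CANDIDATES)))
}

#' Orient an image to standard RAS space
#'
#' Full composition: principal-axis alignment, roll search about y,
#' rigid refinement through the halfway transform to the reflection, and
#' 180-degree candidate disambiguation against a reference. The stage
#' transforms are composed and the image is resampled once (a single
#' interpolation pass).
#'
#' @param img image to orient.
#' @param reference correctly oriented reference image.
#' @param n_rolls roll candidates (default 14).
#' @param background_level background intensity level for symmetry scoring.
#' @return list of class `mm_orientation`: `image` (oriented), `transform`
#'   (pull-back: standard world -> original world), `code`, `stages`
#'   (per-stage transforms), `symmetry_r`.
#' @export
orient_to_standard <- function(img, reference, n_rolls = 14L,
                               background_level = 0.1, resample = TRUE) {
  # stage decisions are made on a half-resolution working copy (transforms
  # are world-space, so resolution-independent); the subject is resampled
  # once, at full resolution, through the composed transform. Small grids
  # are used as-is.
  ds <- if (min(dim(img$data)) > 64) 2L else 1L
  work <- downsample_volume(img, ds)
  ref_small <- downsample_volume(reference,
                                 if (min(dim(reference$data)) > 64) 2L else 1L)
  st1 <- align_long_axis(work, resample = FALSE,
                         background_level = background_level)
  aligned <- resample_volume(work, transform = st1$transform,
                             method = "linear")
  rs <- roll_search(aligned, n_rolls = n_rolls,
                    background_level = background_level, downsample = 1L)
  ctr <- intensity_centroid(aligned)
  roll_trans <- rotation_about(rot_y(rs$best_roll_deg * pi / 180), ctr)
  rolled <- resample_volume(aligned, transform = roll_trans,
                            method = "linear")
  st3 <- rigid_refine_halfway(rolled, background_level)
  st4 <- disambiguate_orientation(st3$image, ref_small)
  total <- st1$transform %*% roll_trans %*% st3$transform %*% st4$transform
  # final polish: one rigid registration of the composed pose to the
  # reference, so the single resampling is as accurate as possible
  polish <- register(work, ref_small, model = "rigid",
                     similarity = "pearson", init = total,
                     levels = c(2, 1), cycles = c(2, 1), ls_tol = 0.015,
                     symmetric = FALSE)
  total <- polish$transform
  # the oriented image lives on the reference grid (standard space)
  oriented <- if (resample)
    resample_volume(img, target = reference, transform = total) else NULL
  structure(list(
    image = oriented, transform = as_transform(total), code = st4$code,
    stages = list(axes = st1$transform, roll = as_transform(roll_trans),
                  refine = st3$transform, flip = st4$transform),
    symmetry_r = if (resample) symmetry_score(oriented, background_level)
                 else polish$score
  ), class = "mm_orientation")
}
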