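# Group-wise registration orchestration, simplified locally-ranked label
# fusion, deformation Jacobians and their integration over regions, and
# tissue-map propagation into the common space.

#' Deformation field on the average-space grid
#'
#' Per-voxel 3-vector displacement in world mm, mapping average-space
#' points to subject-space points: T(x) = x + u(x).
#'
#' @param displacement 4D array (nx, ny, nz, 3) of mm displacements.
#' @param affine 4x4 voxel-to-world matrix of the average grid.
#' @export
deformation_field <- function(displacement, affine) {
  stopifnot(length(dim(displacement)) == 4L, dim(displacement)[4] == 3L)
  if (!all(is.finite(displacement)))
    stop("displacement field contains non-finite values", call. = FALSE)
  structure(list(displacement = displacement,
                 affine = unname(as.matrix(affine))),
            class = "mm_defield")
}

#' Zero deformation field on a grid
#' @param grid list with `dim` and `affine` (or an image).
#' @export
identity_field <- function(grid) {
  dm <- if (is.null(grid$dim)) dim(grid$data) else grid$dim
  deformation_field(array(0, c(dm, 3)), grid$affine)
}

#' Jacobian-determinant map of a deformation field
#'
#' J_det from central finite differences (one-sided at the grid boundary) of
#' the mapping x + u(x) in world mm. Voxels with non-positive determinant
#' are counted and their log flagged as NA.
#'
#' @param field [deformation_field()].
#' @return object of class `mm_jacobian` with `values`, `log_values`,
#'   `affine`, `n_nonpositive`.
#' @export
jacobian_map <- function(field) {
  u <- field$displacement
  dm <- dim(u)[1:3]
  vs <- sqrt(colSums(field$affine[1:3, 1:3]^2))
  jac <- array(0, c(dm, 3, 3))
  for (comp in 1:3) {
    g <- array_gradient(u[, , , comp], spacing = vs)
    for (ax in 1:3) jac[, , , comp, ax] <- g[[ax]]
  }
  # det(I + Du)
  a11 <- 1 + jac[, , , 1, 1]; a12 <- jac[, , , 1, 2]; a13 <- jac[, , , 1, 3]
  a21 <- jac[, , , 2, 1]; a22 <- 1 + jac[, , , 2, 2]; a23 <- jac[, , , 2, 3]
  a31 <- jac[, , , 3, 1]; a32 <- jac[, , , 3, 2]; a33 <- 1 + jac[, , , 3, 3]
  det <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  jacobian_map_from_values(det, field$affine)
}

#' Wrap precomputed Jacobian-determinant values
#'
#' @param values 3D array of determinants.
#' @param affine grid affine.
#' @export
jacobian_map_from_values <- function(values, affine) {
  npos <- sum(values <= 0)
  lv <- array(NA_real_, dim(values))
  ok <- values > 0
  lv[ok] <- log(values[ok])
  structure(list(values = values, log_values = lv,
                 affine = unname(as.matrix(affine)),
                 n_nonpositive = npos),
            class = "mm_jacobian")
}

#' Integrate Jacobian determinants over parcellation regions
#'
#' volume(region) = voxel volume x sum of J_det over the region's voxels in
#' average space, i.e. the subject-space volume of the region.
#'
#' @param jac `mm_jacobian` on the average grid.
#' @param labels `mm_labels` on the same grid.
#' @param voxel_volume_mm3 override the grid voxel volume.
#' @return tibble with columns `region_id`, `region`, `volume_mm3`.
#' @export
integrate_regional_volumes <- function(jac, labels, voxel_volume_mm3 = NULL) {
  stopifnot(all(dim(jac$values) == dim(labels$data)))
  vv <- voxel_volume_mm3 %||% voxel_volume(labels)
  ids <- sort(unique(labels$data[labels$data > 0L]))
  if (!length(ids)) stop("label map has no regions", call. = FALSE)
  sums <- vapply(ids, function(id) sum(jac$values[labels$data == id]),
                 numeric(1))
  tibble::tibble(
    region_id = as.integer(ids),
    region = unname(unlist(labels$label_names[as.character(ids)])),
    volume_mm3 = vv * sums
  )
}

# sample a 3D array through a deformation field (pull-back, linear)
sample_through_field <- function(arr, field, method = 1L) {
  dm <- dim(arr)
  g <- voxel_grid(dm)
  xyz <- voxel_to_world(field, g)
  u <- matrix(field$displacement, ncol = 3)
  pts <- xyz + u
  vox <- world_to_voxel(field, pts)
  array(cpp_sample(as.double(arr), dm, vox[, 1], vox[, 2], vox[, 3],
                   method, 0), dm)
}

#' Propagate tissue probability maps to the average space
#'
#' Trilinear resampling of each class map through the deformation field
#' (unmodulated), renormalisation to per-voxel sum 1, then Gaussian
#' smoothing (default FWHM 0.16 mm).
#'
#' @param tpms subject-space `mm_tpm` (on the average grid's world frame).
#' @param field average-to-subject [deformation_field()].
#' @param smooth_fwhm_mm smoothing applied after propagation.
#' @return `mm_tpm` in average space.
#' @export
propagate_tissue_maps <- function(tpms, field, smooth_fwhm_mm = 0.16) {
  cls <- lapply(tpms$classes, function(a) sample_through_field(a, field))
  tot <- Reduce(`+`, cls)
  tot[tot <= 1e-6] <- 1
  cls <- lapply(cls, function(a) pmin(pmax(a / tot, 0), 1))
  if (smooth_fwhm_mm > 0) {
    vs <- sqrt(colSums(field$affine[1:3, 1:3]^2))
    sig <- fwhm_to_sigma(smooth_fwhm_mm) / vs
    cls <- lapply(cls, function(a) smooth_array(a, sig))
  }
  tissue_probability_maps(cls, field$affine, normalise = TRUE)
}

#' Group-wise registration to an evolving average
#'
#' Iterative register-to-current-average with a voxel-wise mean update. The
#' default schedule is 1 symmetric rigid round, 9 symmetric affine rounds
#' and 15 nonrigid rounds; the initial target is drawn from the cohort by a
#' seeded RNG. Inputs should be intensity-standardised so no single image's
#' noise or intensity extremes dominates the average.
#'
#' @param cohort list of `mm_image` on a common grid.
#' @param schedule named integer vector `c(rigid=, affine=, nonrigid=)`.
#' @param seed integer seed (initial target selection).
#' @param backend registration backend name.
#' @param levels pyramid levels for the linear registrations.
#' @param cp_spacing_vox,bending_weight,iter_nonrigid FFD parameters.
#' @return object of class `mm_groupwise`: `average_image`, `per_subject`
#'   (list with `affine_transform`, `field`, `resampled`), `schedule_log`
#'   (tibble: round, model, mean_score), `initial_target`.
#' @export
groupwise_average <- function(cohort,
                              schedule = c(rigid = 1, affine = 9,
                                           nonrigid = 15),
                              seed = 0L, backend = "builtin",
                              levels = c(4, 2),
                              cp_spacing_vox = 5, bending_weight = 0.005,
                              iter_nonrigid = 30) {
  n <- length(cohort)
  if (n < 2) stop("need a cohort of at least 2 images", call. = FALSE)
  dm <- dim(cohort[[1]]$data)
  for (im in cohort) stopifnot(all(dim(im$data) == dm))
  set.seed(seed)
  target_idx <- sample.int(n, 1)
  average <- cohort[[target_idx]]
  aff_t <- replicate(n, diag(4), simplify = FALSE)
  fields <- replicate(n, NULL, simplify = FALSE)
  resampled <- cohort
  models <- rep(names(schedule), times = schedule)
  log_rows <- vector("list", length(models))
  for (rd in seq_along(models)) {
    model <- models[rd]
    scores <- numeric(n)
    for (i in seq_len(n)) {
      if (model %in% c("rigid", "affine")) {
        reg <- register(cohort[[i]], average, model = model,
                        backend = backend, init = aff_t[[i]],
                        levels = levels)
        aff_t[[i]] <- reg$transform
        resampled[[i]] <- reg$resampled
        scores[i] <- reg$score
      } else {
        reg <- register(cohort[[i]], average, model = "nonrigid",
                        backend = backend, init = aff_t[[i]],
                        cp_spacing_vox = cp_spacing_vox,
                        bending_weight = bending_weight,
                        iter_nonrigid = iter_nonrigid)
        fields[[i]] <- reg$transform
        resampled[[i]] <- reg$resampled
        scores[i] <- reg$score
      }
    }
    avg_arr <- Reduce(`+`, lapply(resampled, `[[`, "data")) / n
    average <- image_volume(avg_arr, average$affine)
    log_rows[[rd]] <- tibble::tibble(round = rd, model = model,
                                     mean_score = mean(scores))
  }
  per_subject <- lapply(seq_len(n), function(i) {
    list(affine_transform = as_transform(aff_t[[i]]),
         field = fields[[i]] %||% identity_field(average),
         resampled = resampled[[i]])
  })
  structure(list(average_image = average, per_subject = per_subject,
                 schedule_log = dplyr::bind_rows(log_rows),
                 initial_target = target_idx, schedule = schedule),
            class = "mm_groupwise")
}

#' Jacobian maps of a group-wise result
#'
#' One Jacobian-determinant map per subject. When `compose_affine` is TRUE
#' (the default) the determinant of the affine linear part multiplies the
#' nonrigid determinant, so overall size differences are retained (as when
#' regional volumes are measured by Jacobian integration); with FALSE only
#' the nonrigid component is analysed.
#'
#' @param gw `mm_groupwise`.
#' @param compose_affine include the affine determinant.
#' @return list of `mm_jacobian`.
#' @export
groupwise_jacobians <- function(gw, compose_affine = TRUE) {
  lapply(gw$per_subject, function(ps) {
    j <- jacobian_map(ps$field)
    if (compose_affine) {
      da <- det(ps$affine_transform[1:3, 1:3])
      j <- jacobian_map_from_values(j$values * da, j$affine)
    }
    j
  })
}

# Gaussian-window local statistics (means over a window) for local NCC
local_ncc <- function(a, t, sigma_vox, eps = 1e-6) {
  ga <- smooth_array(a, sigma_vox)
  gt <- smooth_array(t, sigma_vox)
  va <- smooth_array(a * a, sigma_vox) - ga^2
  vt <- smooth_array(t * t, sigma_vox) - gt^2
  cv <- smooth_array(a * t, sigma_vox) - ga * gt
  cv / sqrt(pmax(va, 0) * pmax(vt, 0) + eps)
}

#' Locally-ranked multi-atlas label fusion
#'
#' A documented simplification of similarity-ranked fusion: at each voxel
#' the atlases are ranked by local normalised cross-correlation with the
#' target (Gaussian window), and the top-k vote, weighted by similarity,
#' decides the label (ties to the lowest label id). Atlases must already be
#' registered and resampled to the target grid (use [register()]), or pass
#' `register_atlases = TRUE` for an affine pre-alignment here.
#'
#' @param target target image.
#' @param atlases list of atlas entries, each `list(image=, labels=)`, on
#'   the target grid (unless `register_atlases`).
#' @param k number of top-ranked atlases voting per voxel.
#' @param window_mm Gaussian window sigma in mm.
#' @param register_atlases affinely register each atlas to the target first.
#' @return fused `mm_labels` on the target grid.
#' @export
fuse_labels <- function(target, atlases, k = 5L, window_mm = 0.6,
                        register_atlases = FALSE) {
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  a_n <- length(atlases)
  k <- min(k, a_n)
  if (register_atlases) {
    atlases <- lapply(atlases, function(at) {
      reg <- register(at$image, target, model = "affine")
      labs <- resample_volume(at$labels, target = target,
                              transform = reg$transform)
      list(image = reg$resampled, labels = labs)
    })
  }
  dm <- dim(target$data)
  sig <- window_mm / voxel_size(target)
  wts <- lapply(atlases, function(at)
    local_ncc(at$image$data, target$data, sig))
  labs <- lapply(atlases, function(at) at$labels$data)
  all_ids <- sort(unique(unlist(lapply(labs, function(l) unique(as.integer(l))))))
  score <- lapply(all_ids, function(id) array(0, dm))
  names(score) <- as.character(all_ids)
  remaining <- lapply(wts, function(w) w)
  for (pass in seq_len(k)) {
    # row-wise max over remaining atlases
    best_w <- Reduce(pmax, remaining)
    taken <- array(FALSE, dm)
    for (a in seq_len(a_n)) {
      sel <- !taken & (remaining[[a]] >= best_w - 1e-12) &
        is.finite(remaining[[a]]) & remaining[[a]] > -Inf
      if (!any(sel)) next
      w <- pmax(wts[[a]], 0)
      for (id in all_ids) {
        hit <- sel & (labs[[a]] == id)
        if (any(hit)) {
          key <- as.character(id)
          score[[key]][hit] <- score[[key]][hit] + w[hit]
        }
      }
      remaining[[a]][sel] <- -Inf
      taken <- taken | sel
    }
  }
  out <- array(all_ids[1], dm)
  best_s <- score[[1]]
  if (length(all_ids) > 1) {
    for (j in 2:length(all_ids)) {
      better <- score[[j]] > best_s + 1e-12   # ties keep the lower id
      out[better] <- all_ids[j]
      best_s <- pmax(best_s, score[[j]])
    }
  }
  nm <- list()
  for (at in atlases) nm <- c(nm, at$labels$label_names)
  nm <- nm[!duplicated(names(nm))]
  label_map(out, unlist(nm), target$affine)
}
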