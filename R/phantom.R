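# Synthetic brain phantoms with complete ground truth.
#
# A phantom "brain" is a multi-compartment ellipsoid: a grey-matter shell
# around a white-matter core, two dorsal ventricles (vCSF), an anterior
# "olfactory bulb" protrusion that breaks antero-posterior symmetry (the
# dorsal ventricles break inferior-superior symmetry), an external CSF gap
# and a bright skull shell. The antero-posterior semi-axis is strictly the
# longest, matching the assumption the orientation stage relies on, and the
# phantom is mirror-symmetric about its mid-sagittal plane.

#' Specification of a synthetic brain phantom
#'
#' Defaults describe the desk-scale unit-test phantom: a 96 x 128 x 96 grid
#' of 0.04 mm isotropic voxels holding a miniature brain (semi-axes
#' 1.35 x 2.05 x 1.15 mm), imaged at SNR 15 with Gaussian noise and no bias
#' field. All stochastic elements consume `seed` only.
#'
#' @param grid_dim integer length-3 grid size.
#' @param voxel_mm isotropic voxel size in mm.
#' @param semi_axes brain ellipsoid semi-axes (RL, AP, IS) in mm; AP must be
#'   strictly largest.
#' @param gm_thickness grey-matter shell thickness in mm.
#' @param ventricle_fraction target ventricular volume as a fraction of brain
#'   volume, in (0, 1).
#' @param bulb_radius radius (mm) of the anterior bulb protrusion; 0 disables.
#' @param ventral_scale scale of the inferior (z < 0) semi-axis relative to
#'   the superior one: < 1 flattens the ventral side (strong IS asymmetry,
#'   as a brain resting flat), 1 gives a plain ellipsoid.
#' @param ap_taper linear taper of the RL/IS width towards the anterior end
#'   (narrow frontal pole, wide posterior; strong AP asymmetry).
#' @param skull logical; add a skull shell.
#' @param skull_gap,skull_thickness external CSF gap and skull shell
#'   thickness in mm.
#' @param intensities named list of class mean intensities
#'   (bg, csf, gm, wm, skull, marker, holder) on a nominal 0-1 scale.
#' @param snr requested signal-to-noise ratio (mean brain signal over noise
#'   standard deviation); ignored if `noise_sd` is given.
#' @param noise_sd explicit noise standard deviation (intensity units).
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param bias_amplitude peak multiplicative bias-field deviation from 1
#'   (0 disables); `bias_scale_mm` sets its smoothness.
#' @param bias_scale_mm spatial scale of the bias field.
#' @param pv_fwhm_mm partial-volume blurring applied to the noise-free
#'   intensity map (0 = crisp compartments).
#' @param pose 4x4 rigid transform placing the canonical phantom in world
#'   space (canonical -> world).
#' @param centre_mm world position of the phantom centre (applied before
#'   `pose`).
#' @param seed integer RNG seed.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(96L, 128L, 96L), voxel_mm = 0.04,
                         semi_axes = c(1.35, 2.05, 1.15),
                         gm_thickness = 0.3,
                         ventricle_fraction = 0.02,
                         bulb_radius = 0.6, ventral_scale = 0.72,
                         ap_taper = 0.14,
                         skull = TRUE, skull_gap = 0.08,
                         skull_thickness = 0.12,
                         intensities = list(bg = 0.05, csf = 0.28, gm = 0.75,
                                            wm = 0.48, skull = 0.38,
                                            marker = 0.92, holder = 0.07),
                         snr = 15, noise_sd = NULL,
                         noise_model = c("gaussian", "rician"),
                         bias_amplitude = 0, bias_scale_mm = 2,
                         pv_fwhm_mm = 0,
                         pose = diag(4), centre_mm = c(0, 0, 0),
                         seed = 0L) {
  stopifnot(all(semi_axes > 0), voxel_mm > 0)
  if (semi_axes[2] <= max(semi_axes[c(1, 3)]))
    stop("the AP (second) semi-axis must be strictly largest", call. = FALSE)
  if (ventricle_fraction <= 0 || ventricle_fraction >= 1)
    stop("ventricle_fraction must be in (0, 1)", call. = FALSE)
  structure(list(
    grid_dim = as.integer(grid_dim), voxel_mm = voxel_mm,
    semi_axes = semi_axes, gm_thickness = gm_thickness,
    ventricle_fraction = ventricle_fraction, bulb_radius = bulb_radius,
    ventral_scale = ventral_scale, ap_taper = ap_taper,
    skull = skull, skull_gap = skull_gap, skull_thickness = skull_thickness,
    intensities = intensities, snr = snr, noise_sd = noise_sd,
    noise_model = match.arg(noise_model),
    bias_amplitude = bias_amplitude, bias_scale_mm = bias_scale_mm,
    pv_fwhm_mm = pv_fwhm_mm, pose = unname(as.matrix(pose)),
    centre_mm = centre_mm, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# class ids used in ground truth
PHANTOM_CLASSES <- c("BG", "GM", "WM", "eCSF", "vCSF", "SKULL")

# Evaluate compartment membership at world coordinates (n x 3).
# Returns integer class codes (index into PHANTOM_CLASSES) and toy
# parcellation labels.
phantom_membership <- function(spec, xyz) {
  m <- solve(spec$pose)
  cc <- apply_transform(m, xyz)
  cc <- cc - matrix(spec$centre_mm, nrow(cc), 3, byrow = TRUE)
  a <- spec$semi_axes
  vsc <- spec$ventral_scale %||% 1
  ell <- function(s, centre = c(0, 0, 0)) {
    (cc[, 1] - centre[1])^2 / s[1]^2 + (cc[, 2] - centre[2])^2 / s[2]^2 +
      (cc[, 3] - centre[3])^2 / s[3]^2
  }
  # centred shells use a flattened inferior semi-axis (ventral_scale) and
  # an anterior taper (narrow frontal end, wide posterior)
  tpr <- spec$ap_taper %||% 0.14
  ell0 <- function(s) {
    sz <- ifelse(cc[, 3] < 0, s[3] * vsc, s[3])
    wy <- 1 - tpr * pmax(-1, pmin(1, cc[, 2] / s[2]))
    cc[, 1]^2 / (s[1] * wy)^2 + cc[, 2]^2 / s[2]^2 + cc[, 3]^2 / (sz * wy)^2
  }
  brain_ell <- ell0(a) <= 1
  bulb <- rep(FALSE, nrow(cc))
  if (spec$bulb_radius > 0) {
    bc <- c(0, a[2] - 0.4 * spec$bulb_radius, 0)
    bulb <- (cc[, 1] - bc[1])^2 + (cc[, 2] - bc[2])^2 +
      (cc[, 3] - bc[3])^2 <= spec$bulb_radius^2
  }
  inner <- pmax(a - spec$gm_thickness, 0.05)
  core <- ell0(inner) <= 1
  # ventricles: two dorsal ellipsoids sized to the requested volume fraction
  vb <- (4 / 3) * pi * prod(a) * (1 + vsc) / 2 * (1 + tpr^2 / 5) +
    (2 / 3) * pi * spec$bulb_radius^3
  vshape <- c(0.16, 0.42, 0.16)  # base semi-axes, scaled
  vtarget <- spec$ventricle_fraction * vb / 2
  lam <- (vtarget / ((4 / 3) * pi * prod(vshape)))^(1 / 3)
  vs <- vshape * lam
  vcent <- list(c(0.42 * inner[1], 0.35 * inner[2], 0.45 * inner[3]),
                c(-0.42 * inner[1], 0.35 * inner[2], 0.45 * inner[3]))
  vent <- ell(vs, vcent[[1]]) <= 1 | ell(vs, vcent[[2]]) <= 1
  skull_in <- a + spec$skull_gap
  skull_out <- skull_in + spec$skull_thickness
  cls <- rep(1L, nrow(cc))                       # BG
  if (spec$skull) {
    cls[ell0(skull_out) <= 1] <- 6L              # SKULL
    cls[ell0(skull_in) <= 1] <- 4L               # eCSF gap
  }
  cls[brain_ell | bulb] <- 2L                    # GM shell (plus bulb)
  cls[core] <- 3L                                # WM core
  cls[vent & core] <- 5L                         # vCSF
  # toy parcellation: bulb, 4 GM quadrants, WM core, ventricles
  lab <- integer(nrow(cc))
  gm <- cls == 2L
  lab[gm & cc[, 1] >= 0 & cc[, 2] >= 0] <- 2L
  lab[gm & cc[, 1] < 0 & cc[, 2] >= 0] <- 3L
  lab[gm & cc[, 1] >= 0 & cc[, 2] < 0] <- 4L
  lab[gm & cc[, 1] < 0 & cc[, 2] < 0] <- 5L
  lab[gm & bulb & !brain_ell] <- 1L
  lab[cls == 3L] <- 6L
  lab[cls == 5L] <- 7L
  list(class = cls, label = lab,
       analytic = list(brain_volume = vb,
                       ventricle_volume = 2 * (4 / 3) * pi * prod(vs)))
}

PHANTOM_LABEL_NAMES <- c(`1` = "olfactory bulb",
                         `2` = "cortex right anterior",
                         `3` = "cortex left anterior",
                         `4` = "cortex right posterior",
                         `5` = "cortex left posterior",
                         `6` = "white matter core",
                         `7` = "ventricles")

phantom_intensity <- function(spec, cls) {
  iv <- spec$intensities
  lut <- c(iv$bg, iv$gm, iv$wm, iv$csf, iv$csf, iv$skull)
  lut[cls]
}

# random smooth multiplicative bias field on a grid (vectorised, low-order
# polynomials in normalised coordinates)
phantom_bias <- function(spec, xyz, rng_ok = TRUE) {
  if (spec$bias_amplitude <= 0) return(rep(1, nrow(xyz)))
  u <- sweep(xyz, 2, apply(xyz, 2, mean))
  u <- sweep(u, 2, pmax(apply(abs(u), 2, max), 1e-9), "/")
  co <- matrix(rnorm(3 * 9, sd = 1), 3)
  f <- rep(0, nrow(xyz))
  for (p in 1:3) {
    f <- f + co[p, 1] * u[, 1]^p + co[p, 2] * u[, 2]^p + co[p, 3] * u[, 3]^p +
      co[p, 4] * u[, 1] * u[, 2] + co[p, 5] * u[, 2] * u[, 3] +
      co[p, 6] * u[, 1] * u[, 3] + co[p, 7] * u[, 1]^p * u[, 2] +
      co[p, 8] * u[, 2]^p * u[, 3] + co[p, 9] * u[, 3]^p * u[, 1]
  }
  f <- f / max(abs(f))
  1 + spec$bias_amplitude * f
}

phantom_affine <- function(grid_dim, voxel_mm) {
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- -voxel_mm * (grid_dim - 1) / 2
  aff
}

#' Generate a synthetic brain with ground truth
#'
#' Deterministic for a fixed seed. Returns the noisy image together with
#' exact ground-truth tissue probability maps (hard memberships), a toy
#' 7-region parcellation, the object mask (all non-background material,
#' i.e. brain plus CSF gap plus skull), the brain mask (GM+WM+vCSF) and
#' analytic compartment volumes.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `image`, `tpms`, `labels`, `brain_mask`,
#'   `object_mask`, `pose`, `spec`, `analytic` and `noise_sd`.
#' @export
make_brain <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  aff <- phantom_affine(spec$grid_dim, spec$voxel_mm)
  grid_img <- image_volume(array(0, spec$grid_dim), aff)
  xyz <- world_grid(grid_img)
  dm <- spec$grid_dim
  # evaluate compartments only inside the phantom's bounding sphere
  ctr <- as.numeric(spec$pose[1:3, 4])
  rmax <- max(spec$semi_axes) + spec$skull_gap + spec$skull_thickness +
    spec$bulb_radius + 2 * spec$voxel_mm
  near <- which((xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 +
                  (xyz[, 3] - ctr[3])^2 <= rmax^2)
  mem_n <- phantom_membership(spec, xyz[near, , drop = FALSE])
  cls_full <- rep(1L, nrow(xyz)); cls_full[near] <- mem_n$class
  lab_full <- integer(nrow(xyz)); lab_full[near] <- mem_n$label
  mem <- list(class = cls_full, label = lab_full, analytic = mem_n$analytic)
  inten <- phantom_intensity(spec, mem$class)
  bias <- phantom_bias(spec, xyz)
  clean <- inten * bias
  clean_arr <- array(clean, dm)
  if (spec$pv_fwhm_mm > 0)
    clean_arr <- smooth_array(clean_arr,
                              rep(fwhm_to_sigma(spec$pv_fwhm_mm) /
                                    spec$voxel_mm, 3))
  # noise scaled to the requested whole-brain SNR
  brain_cls <- mem$class %in% c(2L, 3L, 5L)
  mean_signal <- mean(inten[brain_cls])
  nsd <- spec$noise_sd %||% (mean_signal / spec$snr)
  n1 <- array(rnorm(prod(dm), sd = nsd), dm)
  if (spec$noise_model == "rician") {
    n2 <- array(rnorm(prod(dm), sd = nsd), dm)
    img_arr <- sqrt((clean_arr + n1)^2 + n2^2)
  } else {
    img_arr <- clean_arr + n1
  }
  classes <- lapply(seq_along(PHANTOM_CLASSES), function(i)
    array(as.double(mem$class == i), dm))
  names(classes) <- PHANTOM_CLASSES
  # skull counts as background in the 5-class tissue model
  classes$BG <- classes$BG + classes$SKULL
  classes$SKULL <- NULL
  tpms <- tissue_probability_maps(classes, aff)
  labels <- label_map(array(mem$label, dm), PHANTOM_LABEL_NAMES, aff)
  list(
    image = image_volume(img_arr, aff),
    tpms = tpms,
    labels = labels,
    brain_mask = binary_mask(array(mem$class %in% c(2L, 3L, 5L), dm), aff),
    object_mask = binary_mask(array(mem$class != 1L, dm), aff),
    pose = spec$pose,
    spec = spec,
    analytic = mem$analytic,
    noise_sd = nsd
  )
}

#' Specification of a multi-subject scene
#'
#' Emulates a multi-brain acquisition: several phantom brains packed inside
#' a low-signal holder with hyperintense agarose identification markers of
#' different lengths, surrounded by signal-free embedding fluid.
#'
#' @param subjects list of [phantom_spec()]s (their `pose` fields place them
#'   in the scene).
#' @param n_subjects convenience: build this many default subjects at poses
#'   rolled about the scene y axis (used when `subjects` is `NULL`).
#' @param voxel_mm scene voxel size (mm).
#' @param fov_mm length-3 field of view (mm).
#' @param holder add the low-signal holder walls.
#' @param markers add identification markers.
#' @param seed integer seed controlling subject poses and noise.
#' @param snr scene signal-to-noise ratio.
#' @export
scene_spec <- function(subjects = NULL, n_subjects = 3, voxel_mm = 0.18,
                       fov_mm = c(31, 17, 31), holder = TRUE,
                       markers = TRUE, seed = 0L, snr = 15,
                       subject_scale = 3.3) {
  s <- subject_scale
  if (is.null(subjects)) {
    set.seed(seed)
    ang <- c(90, 210, 330, 30, 150, 270)[seq_len(n_subjects)] * pi / 180
    subjects <- lapply(seq_len(n_subjects), function(i) {
      pos <- 2.55 * s * c(cos(ang[i]), 0, sin(ang[i]))
      roll <- runif(1, 0, 2 * pi)
      pose <- rigid_transform(rot_y(roll), pos)
      phantom_spec(pose = pose, seed = seed + i, snr = snr,
                   semi_axes = s * c(1.35, 2.05, 1.15),
                   gm_thickness = s * 0.3, bulb_radius = s * 0.42,
                   skull_gap = s * 0.08, skull_thickness = s * 0.12)
    })
  }
  structure(list(subjects = subjects, voxel_mm = voxel_mm, fov_mm = fov_mm,
                 holder = holder, markers = markers, seed = as.integer(seed),
                 snr = snr, subject_scale = s),
            class = "scene_spec")
}

#' Generate a multi-subject scene with per-subject ground truth
#'
#' @param spec a [scene_spec()].
#' @return list with `image`, `truth` (per-subject list of `object_mask`,
#'   `brain_mask`, `centre_world`, `volume_mm3`) and `spec`. Errors if any
#'   two subject hulls touch or overlap.
#' @export
make_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed + 1000L)
  dm <- as.integer(round(spec$fov_mm / spec$voxel_mm))
  aff <- phantom_affine(dm, spec$voxel_mm)
  grid_img <- image_volume(array(0, dm), aff)
  xyz <- world_grid(grid_img)
  iv <- spec$subjects[[1]]$intensities
  s <- spec$subject_scale %||% 1
  inten <- rep(iv$bg, nrow(xyz))
  rad <- sqrt(xyz[, 1]^2 + xyz[, 3]^2)
  if (spec$holder) {
    tube <- rad >= 4.25 * s & rad <= 4.25 * s + 0.6
    th <- atan2(xyz[, 3], xyz[, 1])
    wall_ang <- c(30, 150, 270) * pi / 180
    wall <- rep(FALSE, nrow(xyz))
    for (w in wall_ang) {
      d <- abs(rad * sin(th - w))
      wall <- wall | (d <= 0.3 & rad <= 4.3 * s & rad >= 1.1 * s &
                        cos(th - w) > 0)
    }
    inten[tube | wall] <- iv$holder
  }
  truth <- vector("list", length(spec$subjects))
  occupied <- rep(0L, nrow(xyz))
  for (i in seq_along(spec$subjects)) {
    ps <- spec$subjects[[i]]
    ctr <- as.numeric(ps$pose[1:3, 4])
    rmax <- max(ps$semi_axes) + ps$skull_gap + ps$skull_thickness +
      ps$bulb_radius + 2 * spec$voxel_mm
    near <- which((xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 +
                    (xyz[, 3] - ctr[3])^2 <= rmax^2)
    mem <- phantom_membership(ps, xyz[near, , drop = FALSE])
    obj_n <- mem$class != 1L
    inten[near[obj_n]] <- phantom_intensity(ps, mem$class[obj_n])
    obj <- rep(FALSE, nrow(xyz)); obj[near] <- obj_n
    brn <- rep(FALSE, nrow(xyz)); brn[near] <- mem$class %in% c(2L, 3L, 5L)
    occupied <- occupied + as.integer(obj)
    truth[[i]] <- list(
      object_mask = binary_mask(array(obj, dm), aff),
      brain_mask = binary_mask(array(brn, dm), aff),
      centre_world = ctr,
      volume_mm3 = sum(obj) * spec$voxel_mm^3
    )
  }
  if (any(occupied > 1L))
    stop("subject hulls overlap; adjust poses or field of view",
         call. = FALSE)
  # adjacency check (no face-touching between subjects)
  if (spec$markers) {
    mang <- c(30, 150, 270) * pi / 180
    mlen <- s * c(0.4, 0.7, 1.0)
    for (i in seq_len(min(3L, length(spec$subjects)))) {
      mc <- 3.45 * s * c(cos(mang[i]), 0, sin(mang[i]))
      inmark <- (xyz[, 1] - mc[1])^2 + (xyz[, 3] - mc[3])^2 <= (0.18 * s)^2 &
        abs(xyz[, 2]) <= mlen[i] / 2
      inten[inmark] <- iv$marker
    }
  }
  mean_signal <- mean(inten[occupied > 0L])
  nsd <- mean_signal / spec$snr
  img_arr <- array(inten, dm) + array(rnorm(prod(dm), sd = nsd), dm)
  list(image = image_volume(img_arr, aff), truth = truth, spec = spec,
       noise_sd = nsd)
}

#' Generate a cohort of analytic Jacobian maps with a regional volume effect
#'
#' Builds the inputs the voxel-wise statistics stage consumes, with exact
#' ground truth: each subject carries a Jacobian-determinant map on a shared
#' "group average" grid. Subjects in the mutant group receive a uniform
#' volumetric expansion `effect_factor` inside a spherical region (with a
#' thin smooth transition shell about 2 voxels wide); all subjects receive a
#' smooth multiplicative log-normal Jacobian noise field emulating
#' registration imprecision (log sd `logj_noise_sd`, correlation length
#' `logj_noise_fwhm_mm`). Covariates (age, cohort, TIV) are drawn per
#' subject; an optional global `tiv_scale` difference can be injected in the
#' mutant group.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param effect_factor volumetric scale factor of the mutant region
#'   (1 = null cohort).
#' @param grid_dim,voxel_mm analysis grid (default 64^3 at 0.04 mm).
#' @param region_centre,region_radius sphere defining the affected region
#'   (mm, in world coordinates).
#' @param logj_noise_sd standard deviation of the smooth log-Jacobian noise.
#' @param logj_noise_fwhm_mm smoothness of the noise field.
#' @param tiv_scale multiplicative TIV excess of the mutant group.
#' @param seed integer seed.
#' @return list with `covariates` (tibble: subject, genotype, age_months,
#'   cohort, tiv_mm3), `jacobians` (list of [jacobian_map_from_values()]
#'   results), `region_mask`, `brain_mask` and `grid` (dim + affine).
#' @export
make_cohort <- function(n_per_group = 10, effect_factor = 1.15,
                        grid_dim = c(64L, 64L, 64L), voxel_mm = 0.04,
                        region_centre = c(0.35, 0.3, 0),
                        region_radius = 0.35,
                        logj_noise_sd = 0.05, logj_noise_fwhm_mm = 0.12,
                        tiv_scale = 1, seed = 0L) {
  if (n_per_group < 2) stop("need at least 2 subjects per group", call. = FALSE)
  if (effect_factor <= 0 || tiv_scale <= 0)
    stop("scale factors must be positive", call. = FALSE)
  set.seed(seed)
  dm <- as.integer(grid_dim)
  aff <- phantom_affine(dm, voxel_mm)
  grid_img <- image_volume(array(0, dm), aff)
  xyz <- world_grid(grid_img)
  half_fov <- voxel_mm * (dm - 1) / 2
  ba <- half_fov * c(0.82, 0.92, 0.75)
  brain <- (xyz[, 1] / ba[1])^2 + (xyz[, 2] / ba[2])^2 +
    (xyz[, 3] / ba[3])^2 <= 1
  brain_mask <- binary_mask(array(brain, dm), aff)
  r <- sqrt(rowSums(sweep(xyz, 2, region_centre)^2))
  region <- r <= region_radius
  region_mask <- binary_mask(array(region, dm), aff)
  shell_w <- 2 * voxel_mm
  # smooth radial profile: ln f in the core, 0 at and beyond the region
  # boundary, cosine ramp in a thin shell just inside the boundary
  ramp <- pmin(1, pmax(0, (region_radius - r) / shell_w))
  ramp <- 0.5 - 0.5 * cos(pi * ramp)
  base_logj <- log(effect_factor) * ramp
  n <- 2L * n_per_group
  genotype <- rep(c("WT", "Tc1"), each = n_per_group)
  cohort <- rep(rep(1:2, length.out = n_per_group), 2)
  age <- ifelse(cohort == 1, 4.5, 15) + rnorm(n, sd = 0.2)
  tiv <- rnorm(n, mean = 469.5, sd = 15.3)
  tiv[genotype == "Tc1"] <- tiv[genotype == "Tc1"] * tiv_scale
  sig_vox <- fwhm_to_sigma(logj_noise_fwhm_mm) / voxel_mm
  jacobians <- vector("list", n)
  for (i in seq_len(n)) {
    noise <- array(rnorm(prod(dm)), dm)
    noise <- smooth_array(noise, rep(sig_vox, 3))
    noise <- noise / sd(noise) * logj_noise_sd
    lj <- noise + if (genotype[i] == "Tc1") array(base_logj, dm) else 0
    jacobians[[i]] <- jacobian_map_from_values(array(exp(lj), dm), aff)
  }
  covariates <- tibble::tibble(
    subject = sprintf("subj_%02d", seq_len(n)),
    genotype = genotype, age_months = age, cohort = cohort, tiv_mm3 = tiv
  )
  list(covariates = covariates, jacobians = jacobians,
       region_mask = region_mask, brain_mask = brain_mask,
       grid = list(dim = dm, affine = aff),
       true_logj = array(base_logj, dm))
}
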