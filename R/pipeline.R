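# End-to-end pipeline driver: extract -> orient -> standardise -> mask ->
# segment -> groupwise -> parcellate -> TBM statistics, with a resolved
# configuration record and per-stage artifacts.

#' Pipeline configuration
#'
#' Collects all stage parameters with their defaults. Unknown keys are
#' rejected. Any subset can be overridden; the resolved configuration is
#' stored with every pipeline result.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    n_subjects = 3L,
    expected_volume_mm3 = NULL,
    extract_fwhm_mm = 0.2,
    foreground_threshold = 0.5,
    crop_margin_voxels = 4L,
    n_rolls = 14L,
    background_level = 0.1,
    rim_voxels = 10L,
    nuc_dilate_voxels = 5L,
    mrf_strength = 0.25,
    relax_factor = 0.25,
    relax_sigma_mm = 0.5,
    schedule = c(rigid = 1, affine = 9, nonrigid = 15),
    backend = "builtin",
    cp_spacing_vox = 5,
    bending_weight = 0.005,
    fusion_k = 5L,
    fusion_window_mm = 0.6,
    logjac_fwhm_mm = 0.16,
    q_fdr = 0.05,
    compose_affine = TRUE,
    seed = 0L,
    stages = c(extract = TRUE, orient = TRUE, standardise = TRUE,
               mask = TRUE, segment = TRUE, groupwise = TRUE,
               parcellate = TRUE, stats = TRUE),
    out_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = "pipeline_config")
}

#' Bias-correction hook
#'
#' Intensity non-uniformity correction is delegated to an external tool;
#' this hook resolves the mask it should operate in (the brain mask dilated
#' by `nuc_dilate_voxels`, default 5) and applies a user-supplied correction
#' function, or returns the image unchanged.
#'
#' @param img image.
#' @param brain_mask `mm_mask`.
#' @param correct_fn optional `function(img, mask)` performing the
#'   correction.
#' @param nuc_dilate_voxels dilation radius for the correction mask.
#' @return list with `image` (corrected or original) and `mask` (the
#'   dilated mask the correction is restricted to).
#' @export
nonuniformity_hook <- function(img, brain_mask, correct_fn = NULL,
                               nuc_dilate_voxels = 5L) {
  m <- dilate_mask(brain_mask, nuc_dilate_voxels)
  out <- if (is.null(correct_fn)) img else correct_fn(img, m)
  list(image = out, mask = m)
}

# segment one subject given registered atlas label maps
segment_subject <- function(img, brain_mask, atlas_labels, class_table,
                            cfg, seed = 0L) {
  emc <- em_config(mrf_strength = cfg$mrf_strength,
                   relax_factor = cfg$relax_factor,
                   relax_sigma_mm = cfg$relax_sigma_mm)
  rim <- rim_segment(img, brain_mask, rim_voxels = cfg$rim_voxels,
                     cfg = emc, seed = seed)
  priors <- build_tissue_priors(atlas_labels, class_table, rim = rim)
  refit <- vcsf_refit(img, priors$classes$vCSF, seed = seed)
  if (isTRUE(refit$refitted)) {
    cls <- priors$classes
    w <- cls$vCSF
    cls$vCSF <- refit$vCSF * w
    cls$GM <- cls$GM + refit$GM * w
    cls$WM <- cls$WM + refit$WM * w
    priors <- tissue_probability_maps(cls, priors$affine, normalise = TRUE)
  }
  post <- em_mrf_segment(img, priors, cfg = emc, seed = seed)
  list(tpms = post, volumes = compute_volumes(post), rim = rim,
       priors = priors)
}

#' Run the full pipeline on in-memory inputs
#'
#' Executes the stage order extract, orient, standardise, mask (label
#' fusion), segment, groupwise, parcellate, statistics. Stages can be
#' disabled through the configuration (supplying suitably prepared inputs
#' instead). All stages are deterministic given the configuration seed.
#'
#' @param scenes list of multi-subject `mm_image` scenes (or single-subject
#'   images when extraction is disabled).
#' @param reference correctly oriented reference image (orientation stage).
#' @param atlases list of atlas entries `list(image=, labels=)` used for
#'   masking/parcellation; the first entry's labels feed the tissue priors.
#' @param class_table a [tissue_class_table()].
#' @param covariates covariate table with one row per extracted subject
#'   (subject, genotype, age_months, cohort; TIV is filled from
#'   segmentation).
#' @param config a [pipeline_config()].
#' @return list of class `mm_pipeline` with per-stage results, the volume
#'   table, the statistical map (when run) and the resolved config.
#' @export
run_pipeline <- function(scenes, reference = NULL, atlases = NULL,
                         class_table = tissue_class_table(),
                         covariates = NULL, config = pipeline_config()) {
  cfg <- config
  stages <- cfg$stages
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  stamp <- function(name, t0) {
    log[[length(log) + 1]] <<- tibble::tibble(stage = name,
                                              seconds = tic() - t0)
  }

  # 1. extraction
  t0 <- tic()
  subjects <- list()
  if (isTRUE(stages[["extract"]])) {
    if (is.null(cfg$expected_volume_mm3))
      stop("expected_volume_mm3 required for extraction", call. = FALSE)
    for (sc in scenes) {
      ex <- extract_all(sc, n = cfg$n_subjects,
                        expected_volume_mm3 = cfg$expected_volume_mm3,
                        fwhm_mm = cfg$extract_fwhm_mm,
                        threshold = cfg$foreground_threshold,
                        margin_voxels = cfg$crop_margin_voxels,
                        seed = cfg$seed)
      subjects <- c(subjects, ex$subjects)
    }
  } else subjects <- scenes
  stamp("extract", t0)

  # 2. orientation
  t0 <- tic()
  orientations <- NULL
  if (isTRUE(stages[["orient"]])) {
    if (is.null(reference)) stop("reference image required", call. = FALSE)
    orientations <- lapply(subjects, orient_to_standard, reference = reference,
                           n_rolls = cfg$n_rolls,
                           background_level = cfg$background_level)
    subjects <- lapply(orientations, `[[`, "image")
  }
  stamp("orient", t0)

  # resample onto the reference grid so downstream stages share a grid
  if (!is.null(reference))
    subjects <- lapply(subjects, resample_volume, target = reference)

  # 3. intensity standardisation (landmarks within rough foreground masks:
  # background and out-of-field fill would otherwise dominate the
  # percentile landmarks)
  t0 <- tic()
  if (isTRUE(stages[["standardise"]])) {
    rough_masks <- lapply(subjects, function(s) {
      gmm <- fit_gmm_1d(as.double(s$data), k = 2L, seed = cfg$seed)
      fp <- foreground_probability(s, gmm)
      dilate_mask(binary_mask(fp$data >= 0.5, s$affine), 5)
    })
    std <- standardise_cohort(subjects, masks = rough_masks)
  } else std <- list(images = subjects, scale = NULL)
  subjects <- std$images
  stamp("standardise", t0)

  # 4. masking by label fusion
  t0 <- tic()
  masks <- NULL
  atlas_on_subject <- vector("list", length(subjects))
  if (isTRUE(stages[["mask"]])) {
    if (is.null(atlases)) stop("atlas database required for masking",
                               call. = FALSE)
    masks <- vector("list", length(subjects))
    for (i in seq_along(subjects)) {
      regd <- lapply(atlases, function(at) {
        reg <- register(at$image, subjects[[i]], model = "affine")
        list(image = reg$resampled,
             labels = resample_volume(at$labels, target = subjects[[i]],
                                      transform = reg$transform))
      })
      atlas_on_subject[[i]] <- regd
      fused <- fuse_labels(subjects[[i]], regd, k = cfg$fusion_k,
                           window_mm = cfg$fusion_window_mm)
      masks[[i]] <- binary_mask(fused$data > 0L, fused$affine)
    }
  }
  stamp("mask", t0)

  # 5. segmentation
  t0 <- tic()
  segs <- NULL
  volumes <- NULL
  if (isTRUE(stages[["segment"]])) {
    if (is.null(masks)) stop("segmentation requires masks", call. = FALSE)
    segs <- lapply(seq_along(subjects), function(i)
      segment_subject(subjects[[i]], masks[[i]],
                      lapply(atlas_on_subject[[i]], `[[`, "labels"),
                      class_table, cfg, seed = cfg$seed + i))
    volumes <- dplyr::bind_rows(lapply(seq_along(segs), function(i)
      dplyr::mutate(segs[[i]]$volumes,
                    subject = sprintf("subject_%02d", i),
                    .before = 1)))
  }
  stamp("segment", t0)

  # 6. group-wise registration
  t0 <- tic()
  gw <- NULL
  if (isTRUE(stages[["groupwise"]])) {
    gw <- groupwise_average(subjects, schedule = cfg$schedule,
                            seed = cfg$seed, backend = cfg$backend,
                            cp_spacing_vox = cfg$cp_spacing_vox,
                            bending_weight = cfg$bending_weight)
  }
  stamp("groupwise", t0)

  # 7. parcellation of the average + regional volumes
  t0 <- tic()
  parcellation <- NULL
  regional <- NULL
  if (isTRUE(stages[["parcellate"]]) && !is.null(gw)) {
    parcellation <- fuse_labels(gw$average_image, atlases,
                                k = cfg$fusion_k,
                                window_mm = cfg$fusion_window_mm,
                                register_atlases = TRUE)
    jacs <- groupwise_jacobians(gw, compose_affine = cfg$compose_affine)
    regional <- dplyr::bind_rows(lapply(seq_along(jacs), function(i)
      dplyr::mutate(
        integrate_regional_volumes(jacs[[i]], parcellation),
        subject = sprintf("subject_%02d", i), .before = 1)))
  }
  stamp("parcellate", t0)

  # 8. statistics
  t0 <- tic()
  statmap <- NULL
  if (isTRUE(stages[["stats"]]) && !is.null(gw) && !is.null(covariates)) {
    cov <- covariates
    if (!"tiv_mm3" %in% names(cov) && !is.null(volumes))
      cov$tiv_mm3 <- volumes$TIV
    amask <- if (!is.null(masks)) {
      # intersection of propagated masks, on the average grid
      binary_mask(Reduce(`+`, lapply(seq_along(masks), function(i)
        as.double(resample_volume(masks[[i]],
                                  target = gw$average_image)$data))) >
          length(masks) / 2, gw$average_image$affine)
    } else binary_mask(array(TRUE, dim(gw$average_image$data)),
                       gw$average_image$affine)
    jacs <- groupwise_jacobians(gw, compose_affine = cfg$compose_affine)
    statmap <- run_tbm(jacs, cov, amask, q = cfg$q_fdr,
                       fwhm_mm = cfg$logjac_fwhm_mm)
  }
  stamp("stats", t0)

  out <- structure(list(
    subjects = subjects, orientations = orientations,
    standard_scale = std$scale, masks = masks, segmentations = segs,
    volumes = volumes, groupwise = gw, parcellation = parcellation,
    regional_volumes = regional, statmap = statmap,
    stage_log = dplyr::bind_rows(log), config = cfg
  ), class = "mm_pipeline")
  if (!is.null(cfg$out_dir)) save_pipeline(out, cfg$out_dir)
  out
}

# write principal artifacts as NIfTI/CSV/JSON under out_dir
save_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  cfg$stages <- as.list(cfg$stages)
  cfg$schedule <- as.list(cfg$schedule)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(res$subjects))
    write_volume(res$subjects[[i]],
                 file.path(out_dir, sprintf("subject_%02d.nii.gz", i)))
  if (!is.null(res$volumes))
    write.csv(res$volumes, file.path(out_dir, "volumes.csv"),
              row.names = FALSE)
  if (!is.null(res$regional_volumes))
    write.csv(res$regional_volumes,
              file.path(out_dir, "regional_volumes.csv"), row.names = FALSE)
  if (!is.null(res$groupwise))
    write_volume(res$groupwise$average_image,
                 file.path(out_dir, "average.nii.gz"))
  if (!is.null(res$statmap)) {
    write_volume(image_volume(replace(res$statmap$t_values,
                                      is.na(res$statmap$t_values), 0),
                              res$statmap$affine),
                 file.path(out_dir, "tbm_t.nii.gz"))
    write_volume(res$statmap$fdr_mask, file.path(out_dir, "tbm_fdr_mask.nii.gz"))
  }
  invisible(out_dir)
}
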