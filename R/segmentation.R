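# Tissue segmentation: subject-specific priors built from registered atlas
# labels, a prior-free EM over a rim region to keep extra-cranial material
# out of the brain classes, an EM-MRF main stage with prior relaxation, and
# a post-hoc refit within the ventricular CSF support (fixed ex vivo
# ventricles are largely collapsed, so the atlas vCSF prior is too generous).

#' Tissue probability maps
#'
#' A set of per-class probability volumes on a shared grid. Per-voxel class
#' probabilities must sum to 1 (within 1e-6).
#'
#' @param classes named list of 3D arrays (same dim), e.g.
#'   `GM`, `WM`, `eCSF`, `vCSF`, `BG`.
#' @param affine shared 4x4 voxel-to-world matrix.
#' @param normalise divide by the per-voxel sum instead of erroring on
#'   non-normalised input.
#' @return object of class `mm_tpm`.
#' @export
tissue_probability_maps <- function(classes, affine, normalise = FALSE) {
  stopifnot(is.list(classes), length(classes) >= 1, !is.null(names(classes)))
  dm <- dim(classes[[1]])
  for (cl in classes) stopifnot(all(dim(cl) == dm))
  tot <- Reduce(`+`, classes)
  if (normalise) {
    tot[tot <= 0] <- 1
    classes <- lapply(classes, function(a) a / tot)
  } else if (max(abs(tot - 1)) > 1e-6) {
    stop("class probabilities must sum to 1 per voxel (max deviation ",
         format(max(abs(tot - 1))), ")", call. = FALSE)
  }
  rng <- range(unlist(lapply(classes, range)))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("class probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(classes = classes, affine = unname(as.matrix(affine))),
            class = "mm_tpm")
}

#' @export
print.mm_tpm <- function(x, ...) {
  cat("<mm_tpm> classes:", paste(names(x$classes), collapse = ", "), "\n")
  invisible(x)
}

# probability of being brain tissue (GM + WM + vCSF)
brain_probability <- function(tpms) {
  cls <- intersect(c("GM", "WM", "vCSF"), names(tpms$classes))
  Reduce(`+`, tpms$classes[cls])
}

#' Tissue class table mapping parcellation labels to tissue classes
#'
#' Mirrors the manual binary classification of atlas structure labels into
#' CSF (ventricular), GM, WM or GM/WM mixture; mixture labels contribute a
#' 50/50 split to the GM and WM priors by default. Labels may also be
#' explicitly excluded.
#'
#' @param mapping data frame with columns `label_name` and `class`
#'   (`"CSF"`, `"GM"`, `"WM"`, `"GM/WM mixture"` or `"excluded"`). If `NULL`
#'   the packaged table (modelled on a 39-label mouse brain atlas) is used.
#' @param mixture_split length-2 fractions (GM, WM) summing to 1.
#' @return tibble of class `tissue_class_table`.
#' @export
tissue_class_table <- function(mapping = NULL, mixture_split = c(0.5, 0.5)) {
  if (abs(sum(mixture_split) - 1) > 1e-9)
    stop("mixture_split fractions must sum to 1", call. = FALSE)
  if (is.null(mapping)) {
    path <- system.file("extdata", "tissue_class_table.csv",
                        package = "multimorph", mustWork = TRUE)
    mapping <- read.csv(path, stringsAsFactors = FALSE)
  }
  mapping <- tibble::as_tibble(mapping)
  stopifnot(all(c("label_name", "class") %in% names(mapping)))
  ok <- c("CSF", "GM", "WM", "GM/WM mixture", "excluded")
  bad <- setdiff(unique(mapping$class), ok)
  if (length(bad))
    stop("unknown tissue classes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  attr(mapping, "mixture_split") <- mixture_split
  class(mapping) <- c("tissue_class_table", class(mapping))
  mapping
}

#' Build subject-specific tissue priors from registered atlas labels
#'
#' Each atlas votes per voxel for the tissue class of its (already resampled)
#' structure label; mixture labels contribute the mixture split to GM and WM,
#' ventricular CSF labels vote for vCSF. The eCSF prior is taken from a rim
#' segmentation when supplied. BG fills the remainder.
#'
#' @param atlas_labels list of `mm_labels`, all on the subject grid.
#' @param table a [tissue_class_table()].
#' @param rim optional `mm_tpm` from [rim_segment()] supplying the eCSF
#'   prior outside the voted tissue.
#' @return `mm_tpm` with classes GM, WM, eCSF, vCSF, BG.
#' @export
build_tissue_priors <- function(atlas_labels, table, rim = NULL) {
  stopifnot(length(atlas_labels) >= 1)
  if (!inherits(table, "tissue_class_table")) table <- tissue_class_table(table)
  split <- attr(table, "mixture_split")
  dm <- dim(atlas_labels[[1]]$data)
  aff <- atlas_labels[[1]]$affine
  acc <- list(GM = array(0, dm), WM = array(0, dm), vCSF = array(0, dm))
  for (lm in atlas_labels) {
    stopifnot(all(dim(lm$data) == dm))
    ids <- sort(unique(lm$data[lm$data > 0L]))
    cls_by_id <- vapply(ids, function(id) {
      nm <- lm$label_names[[as.character(id)]]
      row <- table$class[table$label_name == nm]
      if (!length(row))
        stop("atlas label not present in the tissue class table: ", nm,
             call. = FALSE)
      row[1]
    }, character(1))
    for (j in seq_along(ids)) {
      sel <- lm$data == ids[j]
      cl <- cls_by_id[j]
      if (cl == "GM") acc$GM[sel] <- acc$GM[sel] + 1
      else if (cl == "WM") acc$WM[sel] <- acc$WM[sel] + 1
      else if (cl == "CSF") acc$vCSF[sel] <- acc$vCSF[sel] + 1
      else if (cl == "GM/WM mixture") {
        acc$GM[sel] <- acc$GM[sel] + split[1]
        acc$WM[sel] <- acc$WM[sel] + split[2]
      } # excluded labels vote for nothing
    }
  }
  n <- length(atlas_labels)
  acc <- lapply(acc, function(a) a / n)
  tissue <- acc$GM + acc$WM + acc$vCSF
  ecsf <- array(0, dm)
  if (!is.null(rim) && !is.null(rim$classes$eCSF))
    ecsf <- rim$classes$eCSF * pmax(0, 1 - tissue)
  bg <- pmax(0, 1 - tissue - ecsf)
  tissue_probability_maps(
    list(GM = acc$GM, WM = acc$WM, eCSF = ecsf, vCSF = acc$vCSF, BG = bg),
    aff, normalise = TRUE)
}

#' Mirror-augment an atlas
#'
#' Doubles an atlas database by reflecting image and labels in the
#' mid-sagittal plane (the central x plane of the grid); label names that
#' distinguish sides have "left"/"right" swapped.
#'
#' @param atlas list with elements `image` (`mm_image`) and `labels`
#'   (`mm_labels`), in RAS with the mid-sagittal plane at the grid centre.
#' @return list of the same shape, reflected.
#' @export
mirror_augment <- function(atlas) {
  flip <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  img <- image_volume(flip(atlas$image$data), atlas$image$affine)
  nm <- atlas$labels$label_names
  swapped <- vapply(nm, function(s) {
    if (grepl("left", s, ignore.case = TRUE))
      sub("left", "right", s, ignore.case = TRUE)
    else if (grepl("right", s, ignore.case = TRUE))
      sub("right", "left", s, ignore.case = TRUE)
    else s
  }, character(1))
  names(swapped) <- names(nm)
  lab <- label_map(flip(atlas$labels$data), swapped, atlas$labels$affine)
  list(image = img, labels = lab)
}

#' EM configuration
#'
#' @param mrf_strength Potts coupling of the mean-field Markov-random-field
#'   term over the 6-neighbourhood (0 disables).
#' @param relax_factor per-iteration relaxation of the priors toward the
#'   smoothed posteriors, in `[0, 1]`.
#' @param relax_sigma_mm Gaussian kernel standard deviation (mm) used to
#'   smooth the posteriors before relaxation.
#' @param max_iter iteration cap.
#' @param tol relative log-likelihood convergence tolerance.
#' @export
em_config <- function(mrf_strength = 0.25, relax_factor = 0.25,
                      relax_sigma_mm = 0.5, max_iter = 30, tol = 1e-5) {
  stopifnot(mrf_strength >= 0, relax_factor >= 0, relax_factor <= 1,
            relax_sigma_mm > 0)
  structure(list(mrf_strength = mrf_strength, relax_factor = relax_factor,
                 relax_sigma_mm = relax_sigma_mm, max_iter = max_iter,
                 tol = tol), class = "em_config")
}

# sum of the 6-neighbour values of a 3D array (zero outside the grid)
neighbour_sum <- function(a) {
  dm <- dim(a)
  out <- array(0, dm)
  out[-dm[1], , ] <- out[-dm[1], , ] + a[-1, , ]
  out[-1, , ] <- out[-1, , ] + a[-dm[1], , ]
  out[, -dm[2], ] <- out[, -dm[2], ] + a[, -1, ]
  out[, -1, ] <- out[, -1, ] + a[, -dm[2], ]
  out[, , -dm[3]] <- out[, , -dm[3]] + a[, , -1]
  out[, , -1] <- out[, , -1] + a[, , -dm[3]]
  out
}

#' EM-MRF tissue classification
#'
#' Gaussian intensity model per class, expectation-maximisation with a
#' mean-field Potts Markov-random-field term over the 6-neighbourhood, and
#' per-iteration relaxation of the priors toward the Gaussian-smoothed
#' current posteriors (applied from iteration 2), which prevents overt atlas
#' bias. With `mrf_strength = 0` and `relax_factor = 0` the scheme reduces
#' to plain prior-weighted Gaussian-mixture EM.
#'
#' @param img intensity-standardised image.
#' @param priors `mm_tpm` of (normalised) class priors on the image grid.
#' @param cfg an [em_config()].
#' @param seed integer seed (initialisation is deterministic; the seed guards
#'   any stochastic extension and is recorded in the result).
#' @param support optional `mm_mask` restricting the classification; outside
#'   it the priors are returned unchanged.
#' @return `mm_tpm` of posteriors, with attributes `means`, `sds`,
#'   `log_likelihood` (per-iteration trace) and `iterations`.
#' @export
em_mrf_segment <- function(img, priors, cfg = em_config(), seed = 0L,
                           support = NULL) {
  set.seed(seed)
  dm <- dim(img$data)
  cls <- names(priors$classes)
  K <- length(cls)
  sup <- if (is.null(support)) array(TRUE, dm) else support$data
  y <- img$data[sup]
  nv <- length(y)
  if (nv < 10 * K) stop("support too small for EM", call. = FALSE)
  if (!all(is.finite(y)))
    stop("non-finite intensities in the EM support", call. = FALSE)
  vfloor <- max(1e-6 * var(y), 1e-12)  # guard near-constant supports
  prior <- lapply(priors$classes, function(a) pmax(a[sup], 1e-7))
  tot <- Reduce(`+`, prior)
  prior <- lapply(prior, function(p) p / tot)
  # moment initialisation from the priors
  mu <- vapply(prior, function(p) sum(p * y) / sum(p), numeric(1))
  s2 <- vapply(seq_len(K), function(k)
    max(vfloor, sum(prior[[k]] * (y - mu[k])^2) / sum(prior[[k]])),
    numeric(1))
  if (max(mu) - min(mu) < 1e-8 && K > 1) {
    # flat priors: spread initial means evenly over the robust intensity
    # range (quantiles would all land in the dominant background class)
    qs <- quantile(y, probs = c(0.01, 0.99), names = FALSE)
    mu <- seq(qs[1], qs[2], length.out = K)
    s2 <- rep(max(vfloor, (diff(qs) / (2 * K))^2), K)
  }
  q <- prior
  sig_vox <- cfg$relax_sigma_mm / voxel_size(img)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  it <- 0
  warn_empty <- character(0)
  full <- function(vals) { a <- array(0, dm); a[sup] <- vals; a }
  repeat {
    it <- it + 1
    # E step (mean-field MRF)
    dens <- vector("list", K)
    for (k in seq_len(K)) {
      lg <- log(prior[[k]]) - 0.5 * log(2 * pi * s2[k]) -
        (y - mu[k])^2 / (2 * s2[k])
      if (cfg$mrf_strength > 0)
        lg <- lg + cfg$mrf_strength * neighbour_sum(full(q[[k]]))[sup]
      dens[[k]] <- lg
    }
    mx <- Reduce(pmax, dens)
    ex <- lapply(dens, function(d) exp(d - mx))
    sm <- Reduce(`+`, ex)
    q <- lapply(ex, function(e) e / sm)
    ll <- sum(mx + log(sm))
    ll_trace <- c(ll_trace, ll)
    # M step
    for (k in seq_len(K)) {
      wk <- sum(q[[k]])
      if (wk < 10) {
        warn_empty <- union(warn_empty, cls[k])
        s2[k] <- max(s2[k], vfloor)
        next
      }
      mu[k] <- sum(q[[k]] * y) / wk
      s2[k] <- max(vfloor, sum(q[[k]] * (y - mu[k])^2) / wk)
    }
    # prior relaxation (from iteration 2)
    if (cfg$relax_factor > 0 && it >= 2) {
      sq <- lapply(q, function(v) smooth_array(full(v), sig_vox)[sup])
      prior <- lapply(seq_len(K), function(k)
        pmax((1 - cfg$relax_factor) * prior[[k]] +
               cfg$relax_factor * sq[[k]], 1e-7))
      tot <- Reduce(`+`, prior)
      prior <- lapply(prior, function(p) p / tot)
    }
    if (it >= cfg$max_iter) break
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < cfg$tol * abs(ll_old)) break
    ll_old <- ll
  }
  if (length(warn_empty))
    warning("near-empty class(es), variance floored: ",
            paste(warn_empty, collapse = ", "), call. = FALSE)
  out <- vector("list", K)
  names(out) <- cls
  for (k in seq_len(K)) {
    a <- priors$classes[[k]]
    a[sup] <- q[[k]]
    out[[k]] <- a
  }
  res <- tissue_probability_maps(out, priors$affine, normalise = TRUE)
  attr(res, "means") <- setNames(mu, cls)
  attr(res, "sds") <- setNames(sqrt(s2), cls)
  attr(res, "log_likelihood") <- ll_trace
  attr(res, "iterations") <- it
  res
}

#' Prior-free rim classification around the brain
#'
#' Dilates the brain mask by `rim_voxels` and runs a prior-free (flat-prior)
#' EM within the dilated region, classifying voxels into BG, WM, GM and
#' external CSF. This keeps extra-cranial material, meninges and skull out
#' of the brain classes and prevents cortical-surface partial-volume voxels
#' from being mistaken for WM.
#'
#' @param img intensity-standardised image.
#' @param brain_mask `mm_mask` of the brain.
#' @param rim_voxels dilation radius in voxels.
#' @param cfg an [em_config()]; the MRF and relaxation defaults apply.
#' @param seed integer seed.
#' @return `mm_tpm` with classes BG, WM, GM, eCSF over the dilated region
#'   (BG probability 1 outside it).
#' @export
rim_segment <- function(img, brain_mask, rim_voxels = 10,
                        cfg = em_config(), seed = 0L) {
  sup <- dilate_mask(brain_mask, rim_voxels)
  dm <- dim(img$data)
  flat <- array(0.25, dm)
  pri <- tissue_probability_maps(
    list(BG = flat, WM = flat, GM = flat, eCSF = flat),
    img$affine, normalise = TRUE)
  post <- em_mrf_segment(img, pri, cfg = cfg, seed = seed, support = sup)
  # order classes by their fitted mean intensity: BG darkest, then eCSF,
  # WM, GM brightest (ex vivo contrast; the caller can relabel if needed)
  mu <- attr(post, "means")
  ord <- order(mu)
  mapping <- names(mu)[ord]
  out <- list(BG = post$classes[[mapping[0 + 1]]],
              eCSF = post$classes[[mapping[1 + 1]]],
              WM = post$classes[[mapping[2 + 1]]],
              GM = post$classes[[mapping[3 + 1]]])
  # rename according to intensity rank, keep probabilities
  out$BG[!sup$data] <- 1
  out$eCSF[!sup$data] <- 0
  out$WM[!sup$data] <- 0
  out$GM[!sup$data] <- 0
  res <- tissue_probability_maps(out, img$affine, normalise = TRUE)
  attr(res, "means") <- mu[ord]
  attr(res, "support") <- sup
  res
}

#' Post-hoc refit within the ventricular CSF support
#'
#' Ex vivo ventricles largely collapse, so an atlas-derived vCSF prior
#' typically covers tissue. Runs a 3-class prior-free EM (GM, WM, vCSF)
#' restricted to the vCSF prior support and returns the refitted
#' posteriors; classes are assigned by fitted mean intensity
#' (vCSF darkest, GM brightest).
#'
#' @param img intensity-standardised image.
#' @param vcsf_prior 3D probability array (or `mm_image`) of the vCSF prior.
#' @param support_threshold prior level defining the support.
#' @param min_support below this many support voxels the refit is skipped
#'   (with a warning) and the prior returned unchanged.
#' @param seed integer seed.
#' @return list with 3D arrays `GM`, `WM`, `vCSF` (probabilities on the
#'   support, zero elsewhere) and logical `refitted`.
#' @export
vcsf_refit <- function(img, vcsf_prior, support_threshold = 0.5,
                       min_support = 30, seed = 0L) {
  pr <- if (inherits(vcsf_prior, "mm_image")) vcsf_prior$data else vcsf_prior
  dm <- dim(img$data)
  sup_arr <- pr >= support_threshold
  if (sum(sup_arr) < min_support) {
    warning("vCSF support too small (", sum(sup_arr),
            " voxels); refit skipped", call. = FALSE)
    return(list(GM = array(0, dm), WM = array(0, dm), vCSF = pr,
                refitted = FALSE))
  }
  sup <- binary_mask(sup_arr, img$affine)
  flat <- array(1 / 3, dm)
  pri <- tissue_probability_maps(list(vCSF = flat, WM = flat, GM = flat),
                                 img$affine, normalise = TRUE)
  cfg <- em_config(mrf_strength = 0, relax_factor = 0)
  post <- em_mrf_segment(img, pri, cfg = cfg, seed = seed, support = sup)
  mu <- attr(post, "means")
  sds <- attr(post, "sds")
  # homogeneity check: EM on a single-tissue region splits the noise into
  # pseudo-classes whose mean spread stays within a few within-class SDs;
  # genuine GM/WM/CSF contrast separates far more widely
  if (diff(range(mu)) < 5 * mean(sds)) {
    # homogeneous support (no evidence of tissue classes): the region is
    # all fluid, keep the prior
    return(list(GM = array(0, dm), WM = array(0, dm),
                vCSF = pmin(pr, 1) * 1, refitted = FALSE))
  }
  ord <- order(mu)  # darkest -> vCSF, mid -> WM, brightest -> GM
  res <- list(vCSF = post$classes[[ord[1]]] * sup_arr,
              WM = post$classes[[ord[2]]] * sup_arr,
              GM = post$classes[[ord[3]]] * sup_arr,
              refitted = TRUE)
  res
}

#' Tissue and intracranial volumes from probability maps
#'
#' Class volume is the voxel volume times the summed class probability.
#' TIV = GM + WM + eCSF + vCSF; BV = GM + WM (CSF excluded).
#'
#' @param tpms `mm_tpm` with classes GM, WM, eCSF, vCSF (BG ignored).
#' @param voxel_volume_mm3 voxel volume in mm^3; defaults to the TPM grid's.
#' @return one-row tibble with columns GM, WM, eCSF, vCSF, BV, TIV (mm^3).
#' @export
compute_volumes <- function(tpms, voxel_volume_mm3 = NULL) {
  vv <- voxel_volume_mm3 %||% voxel_volume(tpms)
  get <- function(cl) if (is.null(tpms$classes[[cl]])) 0 else
    vv * sum(tpms$classes[[cl]])
  gm <- get("GM"); wm <- get("WM"); ec <- get("eCSF"); vc <- get("vCSF")
  tibble::tibble(GM = gm, WM = wm, eCSF = ec, vCSF = vc,
                 BV = gm + wm, TIV = gm + wm + ec + vc)
}
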