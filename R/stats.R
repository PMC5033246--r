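# Mass-univariate statistics: the general linear model
#   Y = b1 P(mut) + b2 P(WT) + b3 Age + b4 Cohort + b5 TIV + e
# fitted per voxel on log-Jacobian maps (TBM; TIV included to reveal
# differences independent of overall volume) or propagated tissue maps
# (unmodulated VBM; TIV omitted), with contrasts on the genotype columns,
# two-tailed t tests, and Benjamini-Hochberg FDR control at q = 0.05.
# Volume tables are tested with Welch t-tests and Bonferroni correction.

#' Build the morphometry design matrix
#'
#' Columns: P(mut), P(WT) (complementary group indicators), Age, Cohort and,
#' for TBM, TIV. Age and TIV are mean-centred so the group coefficients are
#' interpretable (this does not change the contrast t values).
#'
#' @param covariates data frame with columns `genotype` (two levels; the
#'   non-reference level is the mutant), `age_months`, `cohort` and
#'   `tiv_mm3`.
#' @param include_tiv include the TIV column (TRUE for TBM, FALSE for VBM).
#' @param reference_genotype the control level (default "WT").
#' @return matrix with rownames from `covariates$subject` when present.
#' @export
design_matrix <- function(covariates, include_tiv = TRUE,
                          reference_genotype = "WT") {
  stopifnot(all(c("genotype", "age_months", "cohort") %in% names(covariates)))
  geno <- as.character(covariates$genotype)
  lev <- unique(geno)
  if (length(lev) != 2)
    stop("exactly two genotypes required, got: ",
         paste(lev, collapse = ", "), call. = FALSE)
  mut <- setdiff(lev, reference_genotype)
  if (length(mut) != 1)
    stop("reference genotype ", reference_genotype, " not found",
         call. = FALSE)
  p_mut <- as.numeric(geno == mut)
  coh <- covariates$cohort
  if (!is.numeric(coh)) coh <- as.numeric(factor(coh))
  coh <- as.numeric(coh == max(coh))
  x <- cbind(
    p_mut = p_mut,
    p_wt = 1 - p_mut,
    age = covariates$age_months - mean(covariates$age_months),
    cohort = coh
  )
  if (include_tiv) {
    stopifnot("tiv_mm3" %in% names(covariates))
    if (any(covariates$tiv_mm3 <= 0))
      stop("TIV must be positive", call. = FALSE)
    x <- cbind(x, tiv = covariates$tiv_mm3 - mean(covariates$tiv_mm3))
  }
  if ("subject" %in% names(covariates)) rownames(x) <- covariates$subject
  if (qr(x)$rank < ncol(x))
    stop("design matrix is rank deficient", call. = FALSE)
  x
}

#' Log-transform and smooth Jacobian maps into a TBM response
#'
#' Natural log of the Jacobian determinant followed by Gaussian smoothing
#' (default FWHM 0.16 mm, i.e. 4 voxels at 0.04 mm), which accounts for
#' residual registration imprecision and renders values more normally
#' distributed.
#'
#' @param jac an `mm_jacobian`.
#' @param fwhm_mm smoothing kernel.
#' @param mask optional analysis mask; non-positive determinants inside it
#'   are an error.
#' @return `mm_image` response volume.
#' @export
prepare_tbm_response <- function(jac, fwhm_mm = 0.16, mask = NULL) {
  bad <- jac$values <= 0
  if (!is.null(mask)) bad <- bad & mask$data
  if (any(bad))
    stop(sum(bad), " non-positive Jacobian determinant(s) inside the ",
         "analysis mask", call. = FALSE)
  lv <- jac$log_values
  lv[!is.finite(lv)] <- 0
  img <- image_volume(lv, jac$affine)
  gaussian_smooth(img, fwhm_mm)
}

#' Voxel-wise general linear model with a t contrast
#'
#' Ordinary least squares at every voxel inside the mask;
#' t = c'b / sqrt(s2 c'(X'X)^-1 c) with n - rank(X) residual degrees of
#' freedom and two-tailed p values. Computation is restricted to the mask to
#' limit the multiple-testing problem.
#'
#' @param responses list of per-subject response `mm_image`s (or 3D arrays)
#'   on a common grid.
#' @param design design matrix (subjects x columns).
#' @param contrast numeric contrast vector (length = ncol(design)).
#' @param mask `mm_mask` restricting the analysis.
#' @param q FDR level for the significance mask.
#' @return object of class `mm_statmap`: `t_values`, `p_values` (3D arrays,
#'   NA outside the mask), `fdr_mask` (`mm_mask`), `q`, `df`, `beta`
#'   (contrast effect array), `mask`.
#' @export
fit_glm_voxelwise <- function(responses, design, contrast, mask, q = 0.05) {
  n <- length(responses)
  stopifnot(nrow(design) == n, length(contrast) == ncol(design))
  if (!any(mask$data)) stop("analysis mask is empty", call. = FALSE)
  rk <- qr(design)$rank
  if (rk < ncol(design)) stop("design matrix is rank deficient", call. = FALSE)
  if (n <= ncol(design) + 1)
    stop("need more subjects than design columns + 1", call. = FALSE)
  sel <- which(mask$data)
  y <- matrix(unlist(lapply(responses, function(r) {
    arr <- if (inherits(r, "mm_image")) r$data else
      if (inherits(r, "mm_jacobian")) r$log_values else r
    as.double(arr[sel])
  })), nrow = n, byrow = TRUE)  # n x nvox
  xtx_inv <- solve(crossprod(design))
  beta <- xtx_inv %*% crossprod(design, y)          # p x nvox
  resid <- y - design %*% beta
  df <- n - rk
  sigma2 <- colSums(resid^2) / df
  cb <- as.numeric(crossprod(contrast, beta))
  se <- sqrt(sigma2 * as.numeric(t(contrast) %*% xtx_inv %*% contrast))
  tval <- cb / se
  tval[se == 0] <- 0
  pval <- 2 * pt(-abs(tval), df = df)
  dm <- dim(mask$data)
  tv <- array(NA_real_, dm); tv[sel] <- tval
  pv <- array(NA_real_, dm); pv[sel] <- pval
  bv <- array(NA_real_, dm); bv[sel] <- cb
  sig <- fdr_correct(pval, q = q)
  fm <- array(FALSE, dm); fm[sel] <- sig
  structure(list(t_values = tv, p_values = pv, beta = bv,
                 fdr_mask = binary_mask(fm, mask$affine), q = q, df = df,
                 mask = mask, contrast = contrast,
                 affine = mask$affine),
            class = "mm_statmap")
}

#' @export
print.mm_statmap <- function(x, ...) {
  n <- sum(!is.na(x$t_values))
  cat(sprintf(
    "<mm_statmap> %d voxels tested, df = %d, %d significant at FDR q = %g\n",
    n, x$df, sum(x$fdr_mask$data), x$q))
  invisible(x)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up procedure: find the largest i with p_(i) <= i q / m and declare
#' all p values up to p_(i) significant.
#'
#' @param p_values numeric vector of p values in `[0, 1]` (NAs allowed,
#'   never significant).
#' @param q FDR level.
#' @return logical vector of the same length.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  out <- rep(FALSE, length(p_values))
  ok <- which(!is.na(p_values))
  if (!length(ok)) return(out)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stop("p values must be in [0, 1]", call. = FALSE)
  out[ok] <- p.adjust(p, method = "BH") <= q
  out
}

#' Group tests on tissue and regional volume tables
#'
#' Welch (unequal-variance) two-tailed t-tests per measure, on absolute
#' volumes and, when requested, volumes normalised to each subject's TIV;
#' Bonferroni correction multiplies p by the number of measures (capped
#' at 1).
#'
#' @param table data frame with a `genotype` column, a `tiv_mm3` column
#'   (needed for normalisation) and one numeric column per measure.
#' @param normalise_to_tiv also test TIV-normalised volumes.
#' @param correction `"bonferroni"` or `"none"`.
#' @param reference_genotype control level.
#' @return tibble: measure, normalised, mean_wt, mean_mut, sd_wt, sd_mut,
#'   t, p, p_adjusted.
#' @export
volume_group_tests <- function(table, normalise_to_tiv = TRUE,
                               correction = c("bonferroni", "none"),
                               reference_genotype = "WT") {
  correction <- match.arg(correction)
  stopifnot("genotype" %in% names(table))
  geno <- as.character(table$genotype)
  lev <- unique(geno)
  if (length(lev) != 2) stop("need exactly two genotypes", call. = FALSE)
  mut <- setdiff(lev, reference_genotype)
  if (min(table(geno)) < 2)
    stop("each group needs at least 2 subjects", call. = FALSE)
  skip <- c("subject", "genotype", "age_months", "cohort")
  measures <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                      skip)
  rows <- list()
  variants <- if (normalise_to_tiv) c(FALSE, TRUE) else FALSE
  for (norm in variants) {
    for (m in measures) {
      v <- table[[m]]
      if (norm) {
        if (!"tiv_mm3" %in% names(table))
          stop("tiv_mm3 column required for normalisation", call. = FALSE)
        if (m == "tiv_mm3") next
        v <- v / table$tiv_mm3
      }
      a <- v[geno == reference_genotype]
      b <- v[geno == mut]
      tt <- t.test(b, a, var.equal = FALSE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        measure = m, normalised = norm,
        mean_wt = mean(a), mean_mut = mean(b),
        sd_wt = sd(a), sd_mut = sd(b),
        t = unname(tt$statistic), p = tt$p.value
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  n_tests <- nrow(out)
  out$p_adjusted <- if (correction == "bonferroni")
    pmin(1, out$p * n_tests) else out$p
  out
}

#' Tensor-based morphometry
#'
#' Log-transforms and smooths each subject's Jacobian map, builds the TBM
#' design (with TIV), and fits the voxel-wise GLM for the mutant-vs-control
#' contrast (positive t: mutant locally larger).
#'
#' @param jacobians list of `mm_jacobian` (one per subject, matching the
#'   covariate rows), e.g. from [groupwise_jacobians()] or [make_cohort()].
#' @param covariates covariate table (see [design_matrix()]).
#' @param mask analysis brain mask.
#' @param q FDR level.
#' @param fwhm_mm response smoothing.
#' @return `mm_statmap`.
#' @export
run_tbm <- function(jacobians, covariates, mask, q = 0.05, fwhm_mm = 0.16) {
  responses <- lapply(jacobians, prepare_tbm_response, fwhm_mm = fwhm_mm,
                      mask = mask)
  x <- design_matrix(covariates, include_tiv = TRUE)
  contrast <- c(1, -1, rep(0, ncol(x) - 2))
  fit_glm_voxelwise(responses, x, contrast, mask, q = q)
}

#' Voxel-based morphometry on propagated tissue maps
#'
#' Unmodulated VBM: the response is the (already propagated and smoothed)
#' tissue probability of one class per subject; the TIV covariate is
#' omitted from the design.
#'
#' @param tpms_list list of average-space `mm_tpm` (one per subject).
#' @param class_name tissue class to analyse (e.g. "GM").
#' @param covariates covariate table.
#' @param mask analysis mask.
#' @param q FDR level.
#' @return `mm_statmap`.
#' @export
run_vbm <- function(tpms_list, class_name, covariates, mask, q = 0.05) {
  responses <- lapply(tpms_list, function(tp) {
    arr <- tp$classes[[class_name]]
    if (is.null(arr)) stop("class not present: ", class_name, call. = FALSE)
    image_volume(arr, tp$affine)
  })
  x <- design_matrix(covariates, include_tiv = FALSE)
  contrast <- c(1, -1, rep(0, ncol(x) - 2))
  fit_glm_voxelwise(responses, x, contrast, mask, q = q)
}

#' Summarise significant clusters by parcellation region
#'
#' @param statmap `mm_statmap`.
#' @param labels `mm_labels` on the same grid.
#' @return tibble: region_id, region, n_voxels, n_positive, n_negative.
#' @export
cluster_summary <- function(statmap, labels) {
  sig <- statmap$fdr_mask$data
  ids <- sort(unique(labels$data[labels$data > 0L]))
  rows <- lapply(ids, function(id) {
    m <- sig & labels$data == id
    tibble::tibble(
      region_id = as.integer(id),
      region = labels$label_names[[as.character(id)]],
      n_voxels = sum(m),
      n_positive = sum(m & statmap$t_values > 0, na.rm = TRUE),
      n_negative = sum(m & statmap$t_values < 0, na.rm = TRUE))
  })
  dplyr::bind_rows(rows)
}

#' Tidy a statistical map into a voxel table
#'
#' @param x `mm_statmap`.
#' @param significant_only keep only FDR-significant voxels.
#' @param ... unused.
#' @return tibble: i, j, k (0-based voxel), x, y, z (world mm), t, p,
#'   significant.
#' @export
tidy.mm_statmap <- function(x, significant_only = TRUE, ...) {
  sel <- if (significant_only) which(x$fdr_mask$data) else
    which(!is.na(x$t_values))
  dm <- dim(x$t_values)
  ijk <- cbind((sel - 1) %% dm[1],
               ((sel - 1) %/% dm[1]) %% dm[2],
               (sel - 1) %/% (dm[1] * dm[2]))
  xyz <- apply_transform(rbind(cbind(x$affine[1:3, 1:3], x$affine[1:3, 4]),
                               c(0, 0, 0, 1)), ijk)
  tvals <- x$t_values[sel]
  pvals <- x$p_values[sel]
  sig <- x$fdr_mask$data[sel]
  tibble::tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 t = tvals, p = pvals, significant = sig)
}

#' Glance at a statistical map
#' @param x `mm_statmap`.
#' @param ... unused.
#' @return one-row tibble: n_tested, n_significant, df, q, min_p, max_abs_t.
#' @export
glance.mm_statmap <- function(x, ...) {
  tibble::tibble(
    n_tested = sum(!is.na(x$t_values)),
    n_significant = sum(x$fdr_mask$data),
    df = x$df, q = x$q,
    min_p = suppressWarnings(min(x$p_values, na.rm = TRUE)),
    max_abs_t = suppressWarnings(max(abs(x$t_values), na.rm = TRUE)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
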