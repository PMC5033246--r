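# Tissue priors, EM-MRF classification, rim modelling, vCSF refit, volumes.

phantom_table <- function() {
  tissue_class_table(tibble::tibble(
    label_name = unname(multimorph:::PHANTOM_LABEL_NAMES),
    class = c("GM", "GM", "GM", "GM", "GM", "WM", "CSF")))
}

test_that("tissue priors average atlas votes; mixtures split 50/50", {
  dm <- c(6, 6, 6)
  aff <- diag(4)
  nm <- c(`1` = "cortex general", `2` = "corpus callosum", `3` = "thalamus",
          `4` = "lateral ventricles")
  l1 <- array(0L, dm); l1[1:3, , ] <- 1L; l1[4, , ] <- 2L; l1[5, , ] <- 3L
  l1[6, , ] <- 4L
  l2 <- array(0L, dm); l2[1:3, , ] <- 1L; l2[4, , ] <- 1L; l2[5, , ] <- 3L
  l2[6, , ] <- 4L
  lm1 <- label_map(l1, nm, aff); lm2 <- label_map(l2, nm, aff)
  pri <- build_tissue_priors(list(lm1), tissue_class_table())
  expect_equal(pri$classes$GM[1, 1, 1], 1)                 # pure GM vote
  expect_equal(pri$classes$GM[5, 1, 1], 0.5)               # mixture label
  expect_equal(pri$classes$WM[5, 1, 1], 0.5)
  expect_equal(pri$classes$vCSF[6, 1, 1], 1)
  pri2 <- build_tissue_priors(list(lm1, lm2), tissue_class_table())
  expect_equal(pri2$classes$GM[4, 1, 1], 0.5)              # GM vs WM vote
  expect_equal(pri2$classes$WM[4, 1, 1], 0.5)
  expect_equal(pri2$classes$BG[1, 6, 6], 0)                # labelled voxel
  bad <- label_map(array(c(1L, rep(0L, 215)), dm), c(`1` = "no such label"),
                   aff)
  expect_error(build_tissue_priors(list(bad), tissue_class_table()),
               "not present")
})

test_that("mirror augmentation is an involution and swaps sides", {
  ph <- make_brain(small_spec(seed = 61))
  nm <- ph$labels$label_names
  nm[["2"]] <- "cortex right anterior"
  atlas <- list(image = ph$image,
                labels = label_map(ph$labels$data, nm, ph$labels$affine))
  m1 <- mirror_augment(atlas)
  expect_equal(m1$labels$label_names[["2"]], "cortex left anterior")
  m2 <- mirror_augment(m1)
  expect_identical(m2$image$data, atlas$image$data)
  expect_identical(m2$labels$data, atlas$labels$data)
  # voxel counts of symmetric labels unchanged
  expect_equal(sum(m1$labels$data == 6L), sum(atlas$labels$data == 6L))
  # a landmark reflects to the mirrored world x (within a voxel)
  idx <- which(atlas$labels$data == 7L)[1]
  dm <- dim(atlas$labels$data)
  ijk <- c((idx - 1) %% dm[1], ((idx - 1) %/% dm[1]) %% dm[2],
           (idx - 1) %/% (dm[1] * dm[2]))
  w <- voxel_to_world(atlas$labels, ijk)
  mirr_ijk <- c(dm[1] - 1 - ijk[1], ijk[2], ijk[3])
  expect_true(m1$labels$data[mirr_ijk[1] + 1, mirr_ijk[2] + 1,
                             mirr_ijk[3] + 1] == 7L)
  wm <- voxel_to_world(m1$labels, mirr_ijk)
  expect_equal(abs(wm[1]), abs(w[1]), tolerance = 0.04 + 1e-9)
})

test_that("EM-MRF separates well-separated classes with flat priors", {
  ph <- make_brain(small_spec(seed = 62, snr = 40))
  flat <- array(0.25, dim(ph$image$data))
  pri <- tissue_probability_maps(list(BG = flat, vCSF = flat, WM = flat,
                                      GM = flat), ph$image$affine,
                                 normalise = TRUE)
  post <- em_mrf_segment(ph$image, pri, em_config(max_iter = 20), seed = 0)
  for (cl in c("GM", "WM")) {
    expect_gt(dice(ph$tpms$classes[[cl]] > 0.5, post$classes[[cl]] > 0.5),
              0.99)
  }
  ll <- attr(post, "log_likelihood")
  expect_true(all(diff(ll) > -1e-6 * abs(ll[1])))
})

test_that("single-class EM returns sample moments and unit posterior", {
  set.seed(63)
  img <- image_volume(array(rnorm(16^3, 5, 2), c(16, 16, 16)),
                      diag(c(0.1, 0.1, 0.1, 1)))
  pri <- tissue_probability_maps(list(ALL = array(1, dim(img$data))),
                                 img$affine)
  post <- em_mrf_segment(img, pri, em_config(mrf_strength = 0,
                                             relax_factor = 0), seed = 0)
  expect_true(all(post$classes$ALL == 1))
  expect_equal(unname(attr(post, "means")), mean(img$data),
               tolerance = 1e-6)
  expect_equal(unname(attr(post, "sds")),
               sd(img$data) * sqrt((16^3 - 1) / 16^3), tolerance = 1e-3)
})

test_that("without MRF and relaxation the scheme is plain prior-weighted EM", {
  # independent oracle: direct dense EM implementation on a 32^3 phantom
  ph <- make_brain(small_spec(seed = 64, grid_dim = c(32L, 44L, 32L),
                              snr = 12))
  y <- as.double(ph$image$data)
  pri_arr <- lapply(c("BG", "GM", "WM", "vCSF"), function(cl)
    pmax(as.double(ph$tpms$classes[[cl]]), 1e-7))
  tot <- Reduce(`+`, pri_arr)
  pri_arr <- lapply(pri_arr, function(p) p / tot)
  mu <- vapply(pri_arr, function(p) sum(p * y) / sum(p), numeric(1))
  s2 <- vapply(seq_along(pri_arr), function(k)
    sum(pri_arr[[k]] * (y - mu[k])^2) / sum(pri_arr[[k]]), numeric(1))
  for (it in 1:40) {
    dens <- vapply(seq_along(mu), function(k)
      pri_arr[[k]] * dnorm(y, mu[k], sqrt(s2[k])), numeric(length(y)))
    r <- dens / pmax(rowSums(dens), 1e-300)
    for (k in seq_along(mu)) {
      mu[k] <- sum(r[, k] * y) / sum(r[, k])
      s2[k] <- max(sum(r[, k] * (y - mu[k])^2) / sum(r[, k]),
                   1e-6 * var(y))
    }
  }
  pri <- tissue_probability_maps(
    setNames(lapply(pri_arr, function(p) array(p, dim(ph$image$data))),
             c("BG", "GM", "WM", "vCSF")), ph$image$affine,
    normalise = TRUE)
  post <- em_mrf_segment(ph$image, pri,
                         em_config(mrf_strength = 0, relax_factor = 0,
                                   max_iter = 40, tol = 0), seed = 0)
  expect_equal(sort(unname(attr(post, "means"))), sort(mu),
               tolerance = 1e-3)
  expect_equal(max(abs(post$classes$GM -
                         array(r[, 2], dim(ph$image$data)))), 0,
               tolerance = 0.02)
})

test_that("the MRF removes isolated misclassifications", {
  ph <- make_brain(small_spec(seed = 65, snr = 6))  # noisy phantom
  flat <- array(0.25, dim(ph$image$data))
  pri <- tissue_probability_maps(list(BG = flat, vCSF = flat, WM = flat,
                                      GM = flat), ph$image$affine,
                                 normalise = TRUE)
  post0 <- em_mrf_segment(ph$image, pri,
                          em_config(mrf_strength = 0, relax_factor = 0,
                                    max_iter = 15), seed = 0)
  post1 <- em_mrf_segment(ph$image, pri,
                          em_config(mrf_strength = 0.25, relax_factor = 0,
                                    max_iter = 15), seed = 0)
  err0 <- sum((post0$classes$GM > 0.5) != (ph$tpms$classes$GM > 0.5))
  err1 <- sum((post1$classes$GM > 0.5) != (ph$tpms$classes$GM > 0.5))
  expect_lt(err1, err0)
})

test_that("rim EM keeps a bright skull shell out of the brain classes", {
  ph <- make_brain(small_spec(seed = 66, skull = TRUE,
                              grid_dim = c(56L, 72L, 56L)))
  img <- multimorph:::standardise_self(ph$image)
  rim <- rim_segment(img, ph$brain_mask, rim_voxels = 5,
                     cfg = em_config(max_iter = 15))
  sup <- attr(rim, "support")
  # coverage: the support is exactly the dilated mask
  expect_identical(sup$data, dilate_mask(ph$brain_mask, 5)$data)
  # with no external material, far outside is BG
  expect_true(all(rim$classes$BG[!sup$data] == 1))
  # skull voxels must not be GM or WM
  skull <- ph$object_mask$data & !dilate_mask(binary_mask(
    ph$tpms$classes$GM + ph$tpms$classes$WM + ph$tpms$classes$vCSF > 0.5,
    ph$image$affine), 1)$data
  skull <- skull & sup$data
  gmwm <- rim$classes$GM[skull] + rim$classes$WM[skull]
  expect_lt(mean(gmwm), 0.15)
})

test_that("vCSF refit shrinks a collapsed-ventricle prior, keeps pure CSF", {
  ph <- make_brain(small_spec(seed = 67))
  img <- ph$image
  # collapsed ventricles: prior support mostly over tissue
  sup <- dilate_mask(binary_mask(ph$tpms$classes$vCSF > 0.5, img$affine), 3)
  prior <- array(0, dim(img$data)); prior[sup$data] <- 1
  refit <- vcsf_refit(img, prior, seed = 0)
  expect_true(refit$refitted)
  expect_lt(sum(refit$vCSF), sum(prior))
  tot <- refit$GM + refit$WM + refit$vCSF
  expect_equal(range(tot[sup$data]), c(1, 1), tolerance = 1e-6)
  # pure-CSF support: vCSF retained
  vent_only <- array(0, dim(img$data))
  vent_only[ph$tpms$classes$vCSF > 0.5] <- 1
  if (sum(vent_only) >= 30) {
    r2 <- vcsf_refit(img, vent_only, seed = 0)
    expect_gt(sum(r2$vCSF) / sum(vent_only), 0.85)
  }
  # tiny support is skipped with a warning
  tiny <- array(0, dim(img$data)); tiny[1:2, 1, 1] <- 1
  expect_warning(r3 <- vcsf_refit(img, tiny), "skipped")
  expect_false(r3$refitted)
})

test_that("volumes follow the additive intracranial-volume identity", {
  dm <- c(10, 10, 10)
  vv <- 0.04^3
  cls <- list(GM = array(0, dm), WM = array(0, dm), eCSF = array(0, dm),
              vCSF = array(0, dm), BG = array(1, dm))
  zero <- compute_volumes(tissue_probability_maps(cls, diag(c(rep(0.04, 3),
                                                              1))))
  expect_true(all(zero[1, ] == 0 | names(zero) == "BG"))
  cls$GM[1:10, 1:10, 1:10] <- 1; cls$BG <- 1 - cls$GM
  v <- compute_volumes(tissue_probability_maps(cls, diag(c(rep(0.04, 3), 1))))
  expect_equal(v$GM, 1000 * vv, tolerance = 1e-12)
  ph <- make_brain(small_spec(seed = 68))
  pv <- compute_volumes(ph$tpms)
  expect_equal(pv$TIV, pv$GM + pv$WM + pv$eCSF + pv$vCSF, tolerance = 1e-9)
  expect_equal(pv$BV, pv$GM + pv$WM, tolerance = 1e-12)
})

test_that("published group means are internally consistent", {
  ref <- reference_volume_summary()
  wt <- derive_volume_arithmetic(ref, "WT")
  get <- function(g, m) ref$mean_mm3[ref$genotype == g & ref$measure == m]
  # BV equals the sum of the printed GM and WM means
  expect_equal(wt$bv_mm3, get("WT", "BV"), tolerance = 0.005)
  # TIV equals BV + vCSF + eCSF
  expect_equal(wt$tiv_mm3, get("WT", "TIV"), tolerance = 0.005)
  expect_equal(wt$bv_tiv_pct, 93.8, tolerance = 0.05)
  tc <- derive_volume_arithmetic(ref, "Tc1")
  expect_equal(tc$bv_tiv_pct, 93.8, tolerance = 0.05)
})
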