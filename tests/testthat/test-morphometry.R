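# Registration contract, group-wise averaging, label fusion, Jacobians,
# regional integration and tissue-map propagation.

test_that("registration: identity, translation recovery, symmetry", {
  ph <- make_brain(small_spec(seed = 71, snr = 40))
  img <- ph$image
  reg0 <- register(img, img, model = "rigid", levels = c(2), cycles = c(2))
  expect_lt(geodesic_angle(reg0$transform[1:3, 1:3]), 0.5)
  expect_lt(max(abs(reg0$transform[1:3, 4])), 0.02)
  # translation recovery within 0.05 mm: resampling through tr moves the
  # content by tr^-1, so the registration must return tr^-1
  tr <- rigid_transform(diag(3), c(0.12, -0.08, 0.1))
  moved <- resample_volume(img, transform = tr)
  reg <- register(moved, img, model = "rigid", levels = c(2, 1),
                  cycles = c(3, 2), ls_tol = 0.01)
  expect_equal(reg$transform[1:3, 4], -c(0.12, -0.08, 0.1),
               tolerance = 0.05 / 0.1)
  expect_lt(geodesic_angle(reg$transform[1:3, 1:3]), 1)
  # symmetric property: A->B and B->A are mutually inverse
  regf <- register(moved, img, model = "rigid", levels = c(2), cycles = c(3))
  regb <- register(img, moved, model = "rigid", levels = c(2), cycles = c(3))
  comp <- regf$transform %*% regb$transform
  expect_lt(max(abs(comp[1:3, 4])), 0.04 * 2)  # ~0.1 voxel mean displacement
  expect_lt(geodesic_angle(comp[1:3, 1:3]), 1)
  expect_error(register(img, img, backend = "external"), "backend")
})

test_that("deformation fields validate and Jacobians match closed forms", {
  dm <- c(20, 20, 20)
  aff <- diag(c(0.1, 0.1, 0.1, 1))
  expect_error(deformation_field(array(NA_real_, c(dm, 3)), aff),
               "non-finite")
  # zero displacement: J = 1, log 0
  f0 <- identity_field(list(dim = dm, affine = aff))
  j0 <- jacobian_map(f0)
  expect_equal(range(j0$values), c(1, 1), tolerance = 1e-12)
  expect_equal(range(j0$log_values), c(0, 0), tolerance = 1e-12)
  # pure translation: J = 1
  ft <- deformation_field(array(rep(c(0.5, -0.3, 0.2), each = prod(dm)),
                                c(dm, 3)), aff)
  expect_equal(range(jacobian_map(ft)$values), c(1, 1), tolerance = 1e-9)
  # uniform scaling u = (s-1) x with s = 1.1: J = 1.331 in the interior
  img <- image_volume(array(0, dm), aff)
  xyz <- voxel_to_world(img, multimorph:::voxel_grid(dm))
  fs <- deformation_field(array(0.1 * xyz, c(dm, 3)), aff)
  js <- jacobian_map(fs)
  core <- 3:18
  expect_equal(range(js$values[core, core, core]), rep(1.1^3, 2),
               tolerance = 1e-6)
  expect_equal(js$log_values[5, 5, 5], 3 * log(1.1), tolerance = 1e-6)
  # general affine: J = det(M) everywhere in the interior
  m <- matrix(c(1.05, 0.02, 0, 0.01, 0.95, 0.03, 0, -0.02, 1.1), 3, 3)
  u <- xyz %*% t(m) - xyz
  ja <- jacobian_map(deformation_field(array(u, c(dm, 3)), aff))
  expect_equal(range(ja$values[core, core, core]), rep(det(m), 2),
               tolerance = 1e-4)
  # non-positive determinants are flagged, not logged
  uc <- array(0, c(dm, 3)); uc[, , , 1] <- -2 * xyz[, 1]
  jc <- jacobian_map(deformation_field(uc, aff))
  expect_gt(jc$n_nonpositive, 0)
  expect_true(all(is.na(jc$log_values[jc$values <= 0])))
})

test_that("regional integration: identity field gives label-count volumes", {
  ph <- make_brain(small_spec(seed = 72))
  f0 <- identity_field(ph$image)
  j0 <- jacobian_map(f0)
  tab <- integrate_regional_volumes(j0, ph$labels)
  vv <- voxel_volume(ph$labels)
  counts <- tabulate(ph$labels$data[ph$labels$data > 0])
  expect_equal(tab$volume_mm3, counts[tab$region_id] * vv,
               tolerance = 1e-9)
  # conservation: total region volume + background equals the grid volume
  total <- sum(tab$volume_mm3) + sum(ph$labels$data == 0) * vv
  expect_equal(total, prod(dim(ph$labels$data)) * vv, tolerance = 1e-9)
  expect_error(integrate_regional_volumes(
    j0, label_map(array(0L, dim(ph$labels$data)), character(0),
                  ph$labels$affine)), "no regions")
})

test_that("tissue maps propagate with unit sum and conserved mass", {
  ph <- make_brain(small_spec(seed = 73))
  f0 <- identity_field(ph$image)
  out0 <- propagate_tissue_maps(ph$tpms, f0, smooth_fwhm_mm = 0)
  expect_equal(out0$classes$GM, ph$tpms$classes$GM, tolerance = 1e-9)
  # volume-preserving translation field: GM mass conserved within 2%
  dm <- dim(ph$image$data)
  ft <- deformation_field(array(rep(c(0.05, 0.02, -0.03),
                                    each = prod(dm)), c(dm, 3)),
                          ph$image$affine)
  out <- propagate_tissue_maps(ph$tpms, ft, smooth_fwhm_mm = 0.16)
  tot <- Reduce(`+`, out$classes)
  expect_equal(range(tot), c(1, 1), tolerance = 1e-6)
  expect_true(all(unlist(lapply(out$classes, range)) >= -1e-9) &&
                all(unlist(lapply(out$classes, range)) <= 1 + 1e-9))
  expect_equal(sum(out$classes$GM), sum(ph$tpms$classes$GM),
               tolerance = 0.02 * sum(ph$tpms$classes$GM))
})

test_that("label fusion: unanimity exact, k = 1 takes the best atlas", {
  ph <- make_brain(small_spec(seed = 74))
  img <- ph$image
  atlases <- lapply(1:3, function(i)
    list(image = make_brain(small_spec(seed = 74 + i))$image,
         labels = ph$labels))
  for (k in c(1, 3)) {
    fl <- fuse_labels(img, atlases, k = k)
    expect_identical(fl$data, ph$labels$data)
  }
  expect_error(fuse_labels(img, atlases, k = 0), "at least 1")
  # 2 corrupted atlases lose to 3 correct ones where corruption hurts NCC
  wrong <- ph$labels$data
  wrong[ph$labels$data == 6L] <- 2L
  bad_img <- image_volume(img$data * (1 - 0.8 * (ph$labels$data == 6L)),
                          img$affine)
  atl5 <- c(atlases,
            lapply(1:2, function(i) list(image = bad_img,
                                         labels = label_map(
                                           wrong, ph$labels$label_names,
                                           ph$labels$affine))))
  fl5 <- fuse_labels(img, atl5, k = 3)
  wm_voxels <- ph$labels$data == 6L
  expect_gt(mean(fl5$data[wm_voxels] == 6L), 0.95)
})

test_that("group-wise averaging: trivial cohort, sharpness, default schedule", {
  ph <- make_brain(small_spec(seed = 75, snr = 40,
                              grid_dim = c(32L, 44L, 32L)))
  cohort <- list(ph$image, ph$image, ph$image)
  gw <- groupwise_average(cohort, schedule = c(rigid = 1, affine = 1,
                                               nonrigid = 1), seed = 0)
  expect_equal(gw$average_image$data, ph$image$data, tolerance = 0.02)
  for (ps in gw$per_subject) {
    expect_lt(geodesic_angle(ps$affine_transform[1:3, 1:3]), 1)
    expect_lt(max(abs(ps$field$displacement)), 0.05)
  }
  # displaced copies: the average is sharper than the naive mean
  set.seed(76)
  cohort2 <- lapply(1:3, function(i) {
    pose <- rigid_transform(euler_rotation(runif(3, -0.08, 0.08)),
                            runif(3, -0.05, 0.05))
    make_brain(small_spec(seed = 75, snr = 40, pose = pose,
                          grid_dim = c(32L, 44L, 32L)))$image
  })
  gw2 <- groupwise_average(cohort2, schedule = c(rigid = 1, affine = 2,
                                                 nonrigid = 1), seed = 0)
  ge <- function(a) {
    g <- multimorph:::array_gradient(a)
    mean(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
  }
  naive <- Reduce(`+`, lapply(cohort2, `[[`, "data")) / 3
  expect_gt(ge(gw2$average_image$data), ge(naive))
  # the default schedule expands to exactly 1 + 9 + 15 rounds
  tiny <- lapply(1:2, function(i)
    downsample_volume(cohort2[[i]], 2L))
  gw3 <- groupwise_average(tiny, seed = 1, iter_nonrigid = 3,
                           levels = c(2))
  expect_equal(nrow(gw3$schedule_log), 25L)
  expect_equal(as.vector(table(gw3$schedule_log$model)[c("rigid", "affine",
                                                         "nonrigid")]),
               c(1L, 9L, 15L))
  expect_error(groupwise_average(cohort2[1]), "at least 2")
})
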