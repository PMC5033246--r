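# Foreground mixture modelling, connected components, convex hulls and
# subject selection.

test_that("2-component GMM recovers a well-separated mixture", {
  set.seed(11)
  n <- 50000
  z <- runif(n) < 0.5
  x <- ifelse(z, rnorm(n, 0.80, 0.02), rnorm(n, 0.10, 0.02))
  fit <- fit_gmm_1d(x, k = 2, seed = 0)
  expect_equal(fit$means, c(0.10, 0.80), tolerance = 0.01)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 0.02)
  expect_true(all(diff(fit$means) > 0))
  # deterministic under a fixed seed
  fit2 <- fit_gmm_1d(x, k = 2, seed = 0)
  expect_identical(fit$means, fit2$means)
  # cross-check against an independent mixture implementation
  suppressPackageStartupMessages(library(mclust))
  mc <- mclust::Mclust(sample(x, 20000), G = 2, modelNames = "V",
                       verbose = FALSE)
  expect_equal(sort(as.numeric(mc$parameters$mean)), fit$means,
               tolerance = 0.02)
})

test_that("single-component fit equals sample moments; edge cases error", {
  set.seed(2)
  x <- rnorm(500, 3, 2)
  fit <- fit_gmm_1d(x, k = 1)
  expect_equal(fit$means, mean(x), tolerance = 1e-9)
  expect_equal(fit$variances, var(x) * 499 / 500, tolerance = 1e-9)
  expect_error(fit_gmm_1d(rep(1, 100), k = 2), "degenerate")
  expect_error(fit_gmm_1d(rnorm(15), k = 2), "10")
})

test_that("unbalanced mixture weights are recovered", {
  set.seed(12)
  n <- 50000
  z <- runif(n) < 0.1
  x <- ifelse(z, rnorm(n, 0.8, 0.03), rnorm(n, 0.1, 0.03))
  fit <- fit_gmm_1d(x, k = 2, seed = 0)
  expect_equal(fit$weights, c(0.9, 0.1), tolerance = 0.02)
})

test_that("foreground posterior equals the direct Bayes-rule evaluation", {
  gmm <- structure(list(n_components = 2L, weights = c(0.6, 0.4),
                        means = c(0.1, 0.7), variances = c(0.02^2, 0.05^2)),
                   class = "mm_gmm")
  set.seed(3)
  img <- image_volume(array(runif(5^3), c(5, 5, 5)))
  p <- foreground_probability(img, gmm)
  x <- as.double(img$data)
  num <- 0.4 * dnorm(x, 0.7, 0.05)
  den <- num + 0.6 * dnorm(x, 0.1, 0.02)
  expect_equal(as.double(p$data), num / den, tolerance = 1e-12)
  # limit behaviour and the equal-posterior point
  at_mean <- image_volume(array(0.7, c(2, 2, 2)))
  expect_true(all(foreground_probability(at_mean, gmm)$data > 0.999))
  sym <- structure(list(n_components = 2L, weights = c(0.5, 0.5),
                        means = c(0, 1), variances = c(0.01, 0.01)),
                   class = "mm_gmm")
  mid <- image_volume(array(0.5, c(2, 2, 2)))
  expect_equal(as.double(foreground_probability(mid, sym)$data),
               rep(0.5, 8), tolerance = 1e-12)
  one <- fit_gmm_1d(rnorm(100), k = 1)
  expect_error(foreground_probability(img, one), "2 components")
})

test_that("6-connected components: labelling, ordering, connectivity rule", {
  dm <- c(20, 20, 20)
  empty <- connected_components(binary_mask(array(FALSE, dm)))
  expect_equal(sum(empty$data), 0)
  expect_length(empty$label_names, 0)
  # two voxels sharing only an edge are separate components
  diag2 <- binary_mask(array(FALSE, dm))
  diag2$data[5, 5, 5] <- TRUE
  diag2$data[6, 6, 5] <- TRUE
  expect_equal(max(connected_components(diag2)$data), 2L)
  # three disjoint spheres, labelled in decreasing size order
  m <- array(FALSE, dm)
  cs <- list(c(4, 4, 4), c(14, 5, 5), c(9, 13, 13))
  rs <- c(2, 3, 4)
  for (i in 1:3) m <- m | rasterise_sphere(dm, cs[[i]], rs[i])
  labs <- connected_components(binary_mask(m))
  counts <- tabulate(labs$data[labs$data > 0])
  expect_length(counts, 3)
  oracle <- vapply(1:3, function(i) sum(rasterise_sphere(dm, cs[[i]], rs[i])),
                   numeric(1))
  expect_equal(sort(counts, decreasing = TRUE), sort(oracle,
                                                     decreasing = TRUE))
  expect_true(all(diff(counts) <= 0))  # label 1 is the largest
})

test_that("convex hull: convex input unchanged, shell filled, superset", {
  dm <- c(20, 20, 20)
  cub <- array(FALSE, dm); cub[5:12, 6:14, 4:10] <- TRUE
  h <- convex_hull_mask(binary_mask(cub))
  expect_identical(unname(h$data), cub)
  # hollow shell -> solid sphere (against the brute-force rasterisation)
  solid <- rasterise_sphere(dm, c(9, 9, 9), 6)
  inner <- rasterise_sphere(dm, c(9, 9, 9), 4.5)
  shell <- solid & !inner
  hs <- convex_hull_mask(binary_mask(shell))
  expect_true(all(hs$data[shell]))                   # superset of input
  expect_true(all(hs$data[solid] | !solid[solid]))   # covers the solid
  disagree <- sum(xor(hs$data, solid))
  expect_lt(disagree / sum(solid), 0.005)            # rasterisation fringe
  # degenerate input falls back to the bounding box
  line <- array(FALSE, dm); line[3:9, 7, 7] <- TRUE
  hl <- convex_hull_mask(binary_mask(line))
  expect_true(all(hl$data[line]))
  expect_error(convex_hull_mask(binary_mask(array(FALSE, dm))), "empty")
})

test_that("subject selection by volume proximity with stated tie-breaks", {
  dm <- c(40, 24, 24)
  aff <- diag(c(0.1, 0.1, 0.1, 1))
  m <- array(FALSE, dm)
  m <- m | rasterise_sphere(dm, c(6, 11, 11), 4)     # ~ brain-sized
  m <- m | rasterise_sphere(dm, c(19, 11, 11), 4.2)  # ~ brain-sized
  m <- m | rasterise_sphere(dm, c(32, 11, 11), 1.5)  # marker
  labs <- connected_components(binary_mask(m, aff))
  vv <- voxel_volume(labs)
  expected <- sum(rasterise_sphere(dm, c(6, 11, 11), 4)) * vv
  sel <- select_subjects(labs, n = 2, expected_volume_mm3 = expected)
  expect_length(sel, 2)
  vols <- vapply(sel, `[[`, numeric(1), "volume_mm3")
  expect_true(all(vols > 10 * pi * 1.5^3 / 3 * vv))  # marker excluded
  # n equal to candidate count returns everything
  sel3 <- select_subjects(labs, n = 3, expected_volume_mm3 = expected,
                          min_fraction = 0)
  expect_length(sel3, 3)
  expect_error(select_subjects(labs, n = 4, expected_volume_mm3 = expected),
               "candidate")
  # equidistant volumes: the larger is preferred
  m2 <- array(FALSE, dm)
  m2[2:4, 2:4, 2:4] <- TRUE          # 27 voxels
  m2[30:34, 18:22, 18:22] <- TRUE    # 125 voxels
  labs2 <- connected_components(binary_mask(m2, aff))
  mid <- (27 + 125) / 2 * vv
  pick <- select_subjects(labs2, n = 1, expected_volume_mm3 = mid,
                          min_fraction = 0)
  expect_gt(pick[[1]]$volume_mm3, 100 * vv)
})

test_that("cropping preserves world coordinates and voxel values", {
  set.seed(4)
  img <- image_volume(array(rnorm(30^3), c(30, 30, 30)),
                      diag(c(0.1, 0.1, 0.1, 1)))
  hull <- binary_mask(rasterise_sphere(c(30, 30, 30), c(14, 14, 14), 5),
                      img$affine)
  obj <- list(hull_mask = hull)
  crop0 <- crop_subject(img, obj, margin_voxels = 0)
  expect_equal(dim(crop0$data), rep(11L, 3))  # sphere extent 2r+1
  # world coordinate of a retained voxel unchanged
  w_orig <- voxel_to_world(img, c(14, 14, 14))
  w_crop <- voxel_to_world(crop0, c(14, 14, 14) - 9)
  expect_equal(w_orig, w_crop, tolerance = 1e-9)
  # values identical on overlap after re-embedding
  crop2 <- crop_subject(img, obj, margin_voxels = 2)
  expect_identical(crop2$data[3, 3, 3], img$data[10, 10, 10])
  expect_error(crop_subject(img, obj, -1), "non-negative")
})

test_that("extraction of a single-subject scene and intensity invariance", {
  sc <- make_scene(scene_spec(n_subjects = 1, fov_mm = c(18, 17, 18),
                              holder = FALSE, seed = 5))
  expected <- sc$truth[[1]]$volume_mm3
  ex <- extract_all(sc$image, n = 1, expected_volume_mm3 = expected)
  expect_length(ex$subjects, 1)
  expect_gt(dice(ex$objects[[1]]$hull_mask, sc$truth[[1]]$object_mask), 0.9)
  # invariance to a global affine intensity rescaling of the input
  resc <- image_volume(3.7 * sc$image$data + 11, sc$image$affine)
  ex2 <- extract_all(resc, n = 1, expected_volume_mm3 = expected)
  expect_equal(ex2$objects[[1]]$volume_mm3, ex$objects[[1]]$volume_mm3,
               tolerance = 0.02)
  expect_identical(dim(ex2$subjects[[1]]$data), dim(ex$subjects[[1]]$data))
})
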