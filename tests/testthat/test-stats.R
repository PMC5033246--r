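# Design construction, voxel-wise GLM, FDR, volume tests, TBM/VBM drivers.

toy_covariates <- function(n_per_group = 5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  tibble::tibble(
    subject = sprintf("s%02d", 1:n),
    genotype = rep(c("WT", "Tc1"), each = n_per_group),
    age_months = rnorm(n, 10, 1),
    cohort = rep_len(1:2, n),
    tiv_mm3 = rnorm(n, 470, 15))
}

test_that("the design has 5 columns for TBM, 4 for VBM, and is validated", {
  cov <- toy_covariates()
  x_tbm <- design_matrix(cov, include_tiv = TRUE)
  x_vbm <- design_matrix(cov, include_tiv = FALSE)
  expect_equal(ncol(x_tbm), 5)
  expect_equal(ncol(x_vbm), 4)
  expect_true(all(x_tbm[, "p_mut"] + x_tbm[, "p_wt"] == 1))
  expect_equal(mean(x_tbm[, "age"]), 0, tolerance = 1e-12)
  expect_equal(mean(x_tbm[, "tiv"]), 0, tolerance = 1e-9)
  bad <- cov; bad$genotype <- "WT"
  expect_error(design_matrix(bad), "two genotypes")
  bad2 <- cov; bad2$tiv_mm3 <- -1
  expect_error(design_matrix(bad2), "positive")
})

test_that("TBM response: log then smooth, with closed-form cases", {
  dm <- c(12, 12, 12)
  aff <- diag(c(0.04, 0.04, 0.04, 1))
  j1 <- jacobian_map_from_values(array(1, dm), aff)
  expect_equal(range(prepare_tbm_response(j1)$data), c(0, 0),
               tolerance = 1e-12)
  je <- jacobian_map_from_values(array(exp(1), dm), aff)
  expect_equal(range(prepare_tbm_response(je)$data), c(1, 1),
               tolerance = 1e-9)
  # piecewise field equals a direct log-then-convolve oracle
  set.seed(81)
  vals <- array(exp(rnorm(prod(dm), 0, 0.1)), dm)
  jp <- jacobian_map_from_values(vals, aff)
  got <- prepare_tbm_response(jp, fwhm_mm = 0.16)
  oracle <- gaussian_smooth(image_volume(log(vals), aff), 0.16)
  expect_equal(got$data, oracle$data, tolerance = 1e-6)
  # non-positive determinants inside the mask are an error
  bad <- vals; bad[5, 5, 5] <- -1
  jb <- jacobian_map_from_values(bad, aff)
  mask <- binary_mask(array(TRUE, dm), aff)
  expect_error(prepare_tbm_response(jb, mask = mask), "non-positive")
})

test_that("voxelwise GLM matches a hand-computed OLS t at a single voxel", {
  set.seed(82)
  cov <- toy_covariates()
  x <- design_matrix(cov, include_tiv = TRUE)
  y <- rnorm(10)
  dm <- c(1, 1, 1)
  responses <- lapply(y, function(v) array(v, dm))
  mask <- binary_mask(array(TRUE, dm))
  contrast <- c(1, -1, 0, 0, 0)
  smap <- fit_glm_voxelwise(responses, x, contrast, mask)
  beta <- solve(crossprod(x)) %*% crossprod(x, y)
  res <- y - x %*% beta
  df <- 10 - qr(x)$rank
  s2 <- sum(res^2) / df
  t_oracle <- as.numeric(t(contrast) %*% beta) /
    sqrt(s2 * as.numeric(t(contrast) %*% solve(crossprod(x)) %*% contrast))
  expect_equal(smap$t_values[1, 1, 1], t_oracle, tolerance = 1e-9)
  expect_equal(smap$p_values[1, 1, 1], 2 * pt(-abs(t_oracle), df),
               tolerance = 1e-12)
  expect_equal(smap$df, df)
})

test_that("GLM residuals are orthogonal to the design, t antisymmetric", {
  set.seed(83)
  cov <- toy_covariates(6)
  x <- design_matrix(cov)
  dm <- c(5, 4, 3)
  responses <- lapply(1:12, function(i) array(rnorm(prod(dm)), dm))
  mask <- binary_mask(array(TRUE, dm))
  c1 <- c(1, -1, 0, 0, 0)
  s1 <- fit_glm_voxelwise(responses, x, c1, mask)
  s2 <- fit_glm_voxelwise(responses, x, -c1, mask)
  expect_equal(s1$t_values, -s2$t_values, tolerance = 1e-12)
  expect_equal(s1$p_values, s2$p_values, tolerance = 1e-12)
  # residual orthogonality at an arbitrary voxel
  y <- vapply(responses, function(r) r[2, 3, 1], numeric(1))
  beta <- solve(crossprod(x)) %*% crossprod(x, y)
  expect_lt(max(abs(crossprod(x, y - x %*% beta))), 1e-8)
  # rank-deficient design errors
  xr <- cbind(x, dup = x[, 1])
  expect_error(fit_glm_voxelwise(responses, xr, c(c1, 0), mask),
               "rank deficient")
})

test_that("group-difference contrast recovers a known effect", {
  set.seed(84)
  hits <- 0
  for (rep in 1:20) {
    cov <- toy_covariates(8, seed = rep)
    x <- design_matrix(cov)
    delta <- 0.5
    y <- rnorm(16) + delta * x[, "p_mut"]
    responses <- lapply(y, function(v) array(v, c(1, 1, 1)))
    smap <- fit_glm_voxelwise(responses, x, c(1, -1, 0, 0, 0),
                              binary_mask(array(TRUE, c(1, 1, 1))))
    beta_hat <- smap$beta[1, 1, 1]
    se <- beta_hat / smap$t_values[1, 1, 1]
    if (abs(beta_hat - delta) <= 2 * se) hits <- hits + 1
  }
  expect_gte(hits, 16)  # ~95% coverage over 20 replicates
})

test_that("BH step-up matches the hand oracle and is monotone in q", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(fdr_correct(p, 0.05), rep(TRUE, 4))  # p_(4) <= 4 q / 4
  expect_equal(fdr_correct(rep(1, 5), 0.05), rep(FALSE, 5))
  p2 <- c(0.001, 0.012, 0.04, 0.2, 0.9)
  # hand step-up: largest i with p_(i) <= i q / m
  m <- 5; q <- 0.05
  thr <- max(c(0, which(sort(p2) <= seq_len(m) * q / m)))
  oracle <- p2 <= (if (thr == 0) -1 else sort(p2)[thr])
  expect_equal(fdr_correct(p2, q), oracle)
  set.seed(85)
  p3 <- runif(2000)^1.5
  m1 <- fdr_correct(p3, 0.01); m2 <- fdr_correct(p3, 0.1)
  expect_true(all(m2[m1]))
  expect_error(fdr_correct(c(0.5, 2)), "0, 1")
  expect_equal(fdr_correct(numeric(0)), logical(0))
})

test_that("BH controls the realised FDR in a uniform-null simulation", {
  set.seed(86)
  reps <- 500; m <- 1e4
  fdp <- vapply(seq_len(reps), function(i) {
    p <- runif(m)
    sig <- fdr_correct(p, 0.05)
    if (!any(sig)) 0 else 1  # all discoveries are false under the null
  }, numeric(1))
  expect_lte(mean(fdp), 0.05 + 0.02)
})

test_that("volume group tests: Welch oracle, Bonferroni, TIV normalisation", {
  set.seed(87)
  tab <- tibble::tibble(
    genotype = rep(c("WT", "Tc1"), each = 6),
    tiv_mm3 = c(rnorm(6, 470, 10), rnorm(6, 530, 12)))
  tab$GM <- 0.67 * tab$tiv_mm3 + rnorm(12, 0, 1)
  res <- volume_group_tests(tab)
  # hand-computed Welch test on the absolute GM volumes
  a <- tab$GM[tab$genotype == "WT"]; b <- tab$GM[tab$genotype == "Tc1"]
  tt <- t.test(b, a)
  row <- res[res$measure == "GM" & !res$normalised, ]
  expect_equal(row$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(row$p, tt$p.value, tolerance = 1e-12)
  expect_equal(row$p_adjusted, min(1, tt$p.value * nrow(res)),
               tolerance = 1e-12)
  # a pure-TIV group difference disappears after normalising to TIV
  rown <- res[res$measure == "GM" & res$normalised, ]
  expect_gt(rown$p_adjusted, 0.5)
  # identical groups: all adjusted p = 1
  tab2 <- tibble::tibble(genotype = rep(c("WT", "Tc1"), each = 4),
                         tiv_mm3 = rep(c(470, 480, 460, 475), 2),
                         GM = rep(c(300, 310, 295, 305), 2))
  res2 <- volume_group_tests(tab2)
  expect_true(all(res2$p_adjusted == 1))
  expect_error(volume_group_tests(tab2[c(1, 5:8), ]), "at least 2")
})

test_that("TBM detects a regional effect and VBM omits the TIV column", {
  co <- make_cohort(n_per_group = 8, effect_factor = 1.15,
                    grid_dim = c(40L, 40L, 40L), seed = 3)
  sm <- run_tbm(co$jacobians, co$covariates, co$brain_mask)
  expect_gt(dice(sm$fdr_mask$data, co$region_mask$data), 0.4)
  # discoveries essentially contained in the dilated true region: the
  # fraction outside is bounded by the FDR level plus sampling slack
  dil <- dilate_mask(co$region_mask, 2)$data
  expect_lte(sum(sm$fdr_mask$data & !dil) / max(1, sum(sm$fdr_mask$data)),
             0.08)
  expect_s3_class(glance(sm), "tbl_df")
  td <- tidy(sm)
  expect_true(all(td$significant))
  expect_equal(nrow(td), sum(sm$fdr_mask$data))
  # VBM path: propagated tissue maps, 4-column design
  ph <- make_brain(small_spec(seed = 88, grid_dim = c(32L, 44L, 32L)))
  tpms_list <- lapply(1:10, function(i) {
    noise <- array(rnorm(prod(dim(ph$image$data)), 0, 0.01),
                   dim(ph$image$data))
    gm <- pmin(pmax(ph$tpms$classes$GM + noise, 0), 1)
    tissue_probability_maps(list(GM = gm, BG = 1 - gm), ph$image$affine)
  })
  cov <- toy_covariates(5)
  mask <- binary_mask(ph$tpms$classes$GM + ph$tpms$classes$WM > 0.5,
                      ph$image$affine)
  vb <- run_vbm(tpms_list, "GM", cov, mask)
  expect_equal(sum(vb$fdr_mask$data), 0)  # null: nothing significant
  expect_error(run_vbm(tpms_list, "WM", cov, mask), "not present")
})

test_that("cluster summary localises significant voxels by region", {
  co <- make_cohort(n_per_group = 8, effect_factor = 1.2,
                    grid_dim = c(40L, 40L, 40L), seed = 4)
  sm <- run_tbm(co$jacobians, co$covariates, co$brain_mask)
  labs <- label_map(array(1L + (co$region_mask$data * 1L),
                          dim(co$region_mask$data)),
                    c(`1` = "background tissue", `2` = "affected region"),
                    co$region_mask$affine)
  cs <- cluster_summary(sm, labs)
  expect_gt(cs$n_voxels[cs$region == "affected region"],
            cs$n_voxels[cs$region == "background tissue"])
  expect_true(all(cs$n_positive[cs$region == "affected region"] >
                    cs$n_negative[cs$region == "affected region"]))
})
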