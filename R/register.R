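# Built-in image registration: rigid/affine by a Powell-style direction-set
# search over NMI or Pearson correlation, and a coarse cubic B-spline
# free-form deformation refined by gradient descent on SSD with a bending
# penalty. Adequate for desk-scale phantoms; production-scale nonrigid
# registration is expected to come from an external backend through the
# same contract.

#' Pearson correlation similarity between two intensity vectors
#' @param a,b numeric vectors of equal length.
#' @export
similarity_pearson <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 10 || sd(a) == 0 || sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Normalised mutual information between two intensity vectors
#'
#' Joint 32-bin histogram estimate; NMI = (H(A) + H(B)) / H(A,B).
#' @param a,b numeric vectors of equal length.
#' @param bins histogram bins per channel.
#' @export
similarity_nmi <- function(a, b, bins = 32L) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 10) return(1)
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) return(1)
  ia <- pmin(bins, 1L + floor((a - ra[1]) / diff(ra) * bins))
  ib <- pmin(bins, 1L + floor((b - rb[1]) / diff(rb) * bins))
  jh <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  p <- jh / sum(jh)
  pa <- rowSums(matrix(p, bins))
  pb <- colSums(matrix(p, bins))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hj <- ent(p)
  if (hj == 0) return(2)
  (ent(pa) + ent(pb)) / hj
}

# Powell-style direction-set minimiser with bounded Brent line searches.
powell_optim <- function(fn, par, scale, cycles = 3, tol = 1e-6,
                         ls_tol = 0.02) {
  n <- length(par)
  f0 <- fn(par)
  for (cy in seq_len(cycles)) {
    f_start <- f0
    for (d in seq_len(n)) {
      ls <- stats::optimize(function(s) {
        p <- par; p[d] <- p[d] + s * scale[d]; fn(p)
      }, interval = c(-1, 1), tol = ls_tol)
      if (ls$objective < f0 - 1e-12) {
        par[d] <- par[d] + ls$minimum * scale[d]
        f0 <- ls$objective
      }
    }
    scale <- scale * 0.5
    if (f_start - f0 < tol * (abs(f_start) + tol)) break
  }
  list(par = par, value = f0)
}

rigid_params_to_transform <- function(p, centre) {
  rotation_about(euler_rotation(p[1:3]), centre, p[4:6])
}

affine_params_to_transform <- function(p, centre) {
  lin <- matrix(p[1:9], 3, 3)
  m <- diag(4)
  m[1:3, 1:3] <- lin
  m[1:3, 4] <- as.numeric(centre) - lin %*% centre + p[10:12]
  as_transform(m)
}

# score a candidate world transform T (fixed world -> moving world)
registration_score <- function(moving, fixed, trans, metric, symmetric) {
  res <- resample_volume(moving, target = fixed, transform = trans,
                         method = "linear")
  s <- metric(as.double(res$data), as.double(fixed$data))
  if (symmetric) {
    res2 <- resample_volume(fixed, target = moving, transform = solve(trans),
                            method = "linear")
    s <- (s + metric(as.double(res2$data), as.double(moving$data))) / 2
  }
  s
}

#' Register a moving image to a fixed image
#'
#' Built-in backend: rigid (6 DOF) and affine (12 DOF) models optimised by a
#' Powell-style direction-set search over normalised mutual information
#' (32-bin joint histogram) or Pearson correlation, in a symmetric
#' formulation (the score averages moving-to-fixed and fixed-to-moving).
#' The nonrigid model is a coarse cubic B-spline free-form deformation
#' (default control-point spacing 5 voxels, bending-energy weight 0.005)
#' refined by gradient descent on intensity SSD, suitable for
#' intensity-standardised images.
#'
#' @param moving,fixed `mm_image` objects.
#' @param model `"rigid"`, `"affine"` or `"nonrigid"`.
#' @param backend backend name; only `"builtin"` ships with the package. The
#'   argument defines the contract point where an external registration tool
#'   can be substituted.
#' @param similarity `"nmi"` (default) or `"pearson"` for the linear models.
#' @param init optional 4x4 initial transform (fixed world -> moving world).
#' @param levels integer downsampling factors, coarse to fine.
#' @param symmetric use the symmetric (inverse-consistent) score.
#' @param multi_start optional list of 3x3 rotations tried as extra starting
#'   points for the rigid model.
#' @param cp_spacing_vox control-point spacing (voxels) for the FFD.
#' @param bending_weight relative bending-energy penalty weight for the FFD.
#' @param iter_nonrigid gradient-descent iterations per level for the FFD.
#' @return a list of class `mm_registration` with elements `transform`
#'   (4x4 matrix mapping fixed world to moving world; for `"nonrigid"`, a
#'   [deformation_field()]), `resampled` (moving resampled on the fixed
#'   grid), `score`, `model`, and `converged`.
#' @export
register <- function(moving, fixed, model = c("rigid", "affine", "nonrigid"),
                     backend = "builtin",
                     similarity = c("nmi", "pearson"),
                     init = NULL, levels = c(4, 2), symmetric = TRUE,
                     multi_start = NULL, cycles = NULL, ls_tol = 0.03,
                     cp_spacing_vox = 5, bending_weight = 0.005,
                     iter_nonrigid = 30) {
  model <- match.arg(model)
  similarity <- match.arg(similarity)
  if (backend != "builtin")
    stop("unknown registration backend: ", backend, call. = FALSE)
  # overlap check
  cf <- voxel_to_world(fixed, (dim(fixed$data) - 1) / 2)
  cm <- voxel_to_world(moving, (dim(moving$data) - 1) / 2)
  ext <- sum(dim(fixed$data) * voxel_size(fixed)) +
    sum(dim(moving$data) * voxel_size(moving))
  if (sqrt(sum((cf - cm)^2)) > ext)
    stop("fields of view do not overlap in world space", call. = FALSE)
  if (model == "nonrigid")
    return(register_ffd(moving, fixed, init = init,
                        cp_spacing_vox = cp_spacing_vox,
                        bending_weight = bending_weight,
                        iter = iter_nonrigid))
  metric <- if (similarity == "nmi") similarity_nmi else similarity_pearson
  centre <- as.numeric(cf)
  vs <- min(voxel_size(fixed))
  if (is.null(init)) {
    # centroid pre-alignment: local optimisation cannot traverse offsets
    # larger than its search range
    off <- tryCatch(intensity_centroid(moving) - intensity_centroid(fixed),
                    error = function(e) c(0, 0, 0))
    init <- rigid_transform(diag(3), off)
  }
  starts <- list(diag(3))
  if (!is.null(multi_start)) starts <- c(starts, multi_start)

  if (is.null(cycles)) cycles <- rep(3, length(levels))
  cycles <- rep(cycles, length.out = length(levels))

  fit_level <- function(mv, fx, par, p2t, scale, n_cycles) {
    fn <- function(p) {
      tr <- init %*% p2t(p, centre)
      -registration_score(mv, fx, tr, metric, symmetric)
    }
    powell_optim(fn, par, scale, cycles = n_cycles, ls_tol = ls_tol)
  }

  pyramids <- lapply(levels, function(l) {
    list(m = downsample_volume(moving, l), f = downsample_volume(fixed, l))
  })

  if (model == "rigid") {
    best <- NULL
    for (st in starts) {
      p <- c(rotation_angles(st), 0, 0, 0)
      for (li in seq_along(pyramids)) {
        lev <- pyramids[[li]]
        sc <- c(rep(0.3 / li, 3), rep(5 * vs * levels[li], 3))
        res <- fit_level(lev$m, lev$f, p, rigid_params_to_transform, sc,
                         cycles[li])
        p <- res$par
      }
      if (is.null(best) || res$value < best$value) best <- list(par = p, value = res$value)
    }
    trans <- init %*% rigid_params_to_transform(best$par, centre)
    score <- -best$value
  } else {
    # affine: initialise from rigid
    rg <- register(moving, fixed, model = "rigid", similarity = similarity,
                   init = init, levels = levels, symmetric = symmetric,
                   multi_start = multi_start, cycles = cycles,
                   ls_tol = ls_tol)
    p <- c(as.numeric(rg$transform[1:3, 1:3]), rep(0, 3))
    r_lin <- rg$transform[1:3, 1:3]
    r_tr <- rg$transform[1:3, 4]
    p2t <- function(q, centre) {
      lin <- matrix(q[1:9], 3, 3)
      m <- diag(4)
      m[1:3, 1:3] <- lin
      m[1:3, 4] <- r_tr + (r_lin - lin) %*% centre + q[10:12]
      as_transform(m)
    }
    for (li in seq_along(pyramids)) {
      lev <- pyramids[[li]]
      sc <- c(rep(0.1 / li, 9), rep(3 * vs * levels[li], 3))
      fn <- function(q) -registration_score(lev$m, lev$f, p2t(q, centre),
                                            metric, symmetric)
      res <- powell_optim(fn, p, sc, cycles = cycles[li], ls_tol = ls_tol)
      p <- res$par
    }
    trans <- p2t(p, centre)
    score <- -res$value
  }
  resampled <- resample_volume(moving, target = fixed, transform = trans)
  structure(list(transform = as_transform(trans), resampled = resampled,
                 score = score, model = model, converged = TRUE),
            class = "mm_registration")
}

# Euler angles (x,y,z convention matching euler_rotation) from a rotation
rotation_angles <- function(r) {
  # r = Rz Ry Rx
  sy <- -r[3, 1]
  sy <- pmin(1, pmax(-1, sy))
  y <- asin(sy)
  if (abs(cos(y)) > 1e-8) {
    x <- atan2(r[3, 2], r[3, 3])
    z <- atan2(r[2, 1], r[1, 1])
  } else {
    x <- atan2(-r[2, 3], r[2, 2])
    z <- 0
  }
  c(x, y, z)
}

# --- nonrigid: coarse cubic B-spline FFD -----------------------------------

array_gradient <- function(arr, spacing = c(1, 1, 1)) {
  dm <- dim(arr)
  g <- vector("list", 3)
  for (ax in 1:3) {
    ip <- im <- arr
    idx_hi <- c(2:dm[ax], dm[ax])
    idx_lo <- c(1, 1:(dm[ax] - 1))
    if (ax == 1) { ip <- arr[idx_hi, , , drop = FALSE]; im <- arr[idx_lo, , , drop = FALSE] }
    if (ax == 2) { ip <- arr[, idx_hi, , drop = FALSE]; im <- arr[, idx_lo, , drop = FALSE] }
    if (ax == 3) { ip <- arr[, , idx_hi, drop = FALSE]; im <- arr[, , idx_lo, drop = FALSE] }
    denom <- array(2 * spacing[ax], dm)
    # one-sided at boundaries
    if (ax == 1) { denom[1, , ] <- spacing[ax]; denom[dm[1], , ] <- spacing[ax] }
    if (ax == 2) { denom[, 1, ] <- spacing[ax]; denom[, dm[2], ] <- spacing[ax] }
    if (ax == 3) { denom[, , 1] <- spacing[ax]; denom[, , dm[3]] <- spacing[ax] }
    g[[ax]] <- (ip - im) / denom
  }
  g
}

second_diff_penalty <- function(cp, cpdim) {
  # discrete bending approximation: squared second differences of the
  # control lattice along each axis, plus its gradient
  ncp <- prod(cpdim)
  g <- numeric(length(cp))
  val <- 0
  cpa <- array(cp, c(cpdim, 3))
  ga <- array(0, c(cpdim, 3))
  for (comp in 1:3) {
    a <- cpa[, , , comp]
    for (ax in 1:3) {
      n <- cpdim[ax]
      if (n < 3) next
      idx0 <- 1:(n - 2); idx1 <- 2:(n - 1); idx2 <- 3:n
      if (ax == 1) d2 <- a[idx2, , , drop = FALSE] - 2 * a[idx1, , , drop = FALSE] + a[idx0, , , drop = FALSE]
      if (ax == 2) d2 <- a[, idx2, , drop = FALSE] - 2 * a[, idx1, , drop = FALSE] + a[, idx0, , drop = FALSE]
      if (ax == 3) d2 <- a[, , idx2, drop = FALSE] - 2 * a[, , idx1, drop = FALSE] + a[, , idx0, drop = FALSE]
      val <- val + sum(d2^2)
      gb <- array(0, cpdim)
      if (ax == 1) {
        gb[idx2, , ] <- gb[idx2, , ] + 2 * d2
        gb[idx1, , ] <- gb[idx1, , ] - 4 * d2
        gb[idx0, , ] <- gb[idx0, , ] + 2 * d2
      } else if (ax == 2) {
        gb[, idx2, ] <- gb[, idx2, ] + 2 * d2
        gb[, idx1, ] <- gb[, idx1, ] - 4 * d2
        gb[, idx0, ] <- gb[, idx0, ] + 2 * d2
      } else {
        gb[, , idx2] <- gb[, , idx2] + 2 * d2
        gb[, , idx1] <- gb[, , idx1] - 4 * d2
        gb[, , idx0] <- gb[, , idx0] + 2 * d2
      }
      ga[, , , comp] <- ga[, , , comp] + gb
    }
  }
  list(value = val / ncp, grad = as.numeric(ga) / ncp)
}

register_ffd <- function(moving, fixed, init = NULL, cp_spacing_vox = 5,
                         bending_weight = 0.005, iter = 30) {
  # bring moving onto the fixed grid first (through init if given)
  mv <- resample_volume(moving, target = fixed,
                        transform = init %||% diag(4), method = "linear")
  dm <- dim(fixed$data)
  vs <- voxel_size(fixed)
  sp <- cp_spacing_vox
  cpdim <- as.integer(ceiling((dm - 1) / sp) + 3)
  cp <- numeric(prod(cpdim) * 3)
  f <- as.double(fixed$data)
  m0 <- mv$data
  grad_m <- array_gradient(m0)
  g <- voxel_grid(dm)
  nvox <- prod(dm)

  cost_grad <- function(cp) {
    disp <- cpp_ffd_disp(cp, cpdim, dm, sp)
    xi <- g[, 1] + disp[1:nvox]
    yi <- g[, 2] + disp[nvox + 1:nvox]
    zi <- g[, 3] + disp[2 * nvox + 1:nvox]
    mval <- cpp_sample(as.double(m0), dm, xi, yi, zi, 1L, 0)
    resid <- mval - f
    ssd <- mean(resid^2)
    gx <- cpp_sample(as.double(grad_m[[1]]), dm, xi, yi, zi, 1L, 0)
    gy <- cpp_sample(as.double(grad_m[[2]]), dm, xi, yi, zi, 1L, 0)
    gz <- cpp_sample(as.double(grad_m[[3]]), dm, xi, yi, zi, 1L, 0)
    fld <- c(resid * gx, resid * gy, resid * gz) * (2 / nvox)
    gcp <- cpp_ffd_grad(fld, dm, cpdim, sp)
    pen <- second_diff_penalty(cp, cpdim)
    list(value = (1 - bending_weight) * ssd + bending_weight * pen$value,
         grad = (1 - bending_weight) * as.numeric(gcp) +
           bending_weight * pen$grad,
         ssd = ssd)
  }

  # L-BFGS with the analytic gradient; fn/gr share one evaluation cache
  cache <- new.env(parent = emptyenv())
  cache$key <- NULL
  eval_cached <- function(p) {
    if (!identical(p, cache$key)) {
      cache$val <- cost_grad(p)
      cache$key <- p
    }
    cache$val
  }
  opt <- stats::optim(cp, fn = function(p) eval_cached(p)$value,
                      gr = function(p) eval_cached(p)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = iter, factr = 1e10))
  cp <- opt$par
  cg <- cost_grad(cp)
  converged <- opt$convergence == 0
  disp <- cpp_ffd_disp(cp, cpdim, dm, sp)
  # voxel-unit displacements -> world mm through the affine linear part
  dispm <- matrix(disp, ncol = 3)
  world_disp <- dispm %*% t(fixed$affine[1:3, 1:3])
  fieldarr <- array(world_disp, c(dm, 3))
  field <- deformation_field(fieldarr, fixed$affine)
  xi <- g[, 1] + disp[1:nvox]
  yi <- g[, 2] + disp[nvox + 1:nvox]
  zi <- g[, 3] + disp[2 * nvox + 1:nvox]
  res <- array(cpp_sample(as.double(m0), dm, xi, yi, zi, 3L, 0), dm)
  structure(list(transform = field, resampled = image_volume(res, fixed$affine),
                 score = -cg$ssd, model = "nonrigid", converged = converged,
                 init = init %||% diag(4), control_points = cp,
                 cp_dim = cpdim, cp_spacing = sp),
            class = "mm_registration")
}
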