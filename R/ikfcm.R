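#' Mask-aware neighborhood mean filter
#'
#' For every voxel, the mean intensity of its `(2p+1)^d` box neighborhood
#' excluding the central voxel, with mirror reflection at image borders.
#' Out-of-mask neighbors are dropped from the average; a voxel with no
#' in-mask neighbor falls back to its own intensity.  This is the local
#' spatial information injected into the improved algorithm's updates.
#'
#' @param image A [gray_image] (or numeric array).
#' @param radius Neighborhood radius `p >= 1`.
#' @return Numeric array of neighborhood means, same shape as the image.
#' @export
neighborhood_mean <- function(image, radius = 1) {
  image <- as_gray_image(image)
  radius <- as.integer(radius)
  if (radius < 1) ik_stop("neighborhood radius must be >= 1", "usage")
  x <- image$intensities
  msk <- image_mask(image)
  d <- dim(x)
  xm <- x
  xm[!msk] <- 0
  acc <- array(0, d)
  cnt <- array(0, d)
  offs <- box_offsets(length(d), radius, drop_center = TRUE)
  idx_base <- lapply(d, seq_len)
  for (r in seq_len(nrow(offs))) {
    idxs <- mapply(function(base, off, n) reflect_index(base + off, n),
                   idx_base, offs[r, ], d, SIMPLIFY = FALSE)
    sx <- do.call(`[`, c(list(xm), idxs, list(drop = FALSE)))
    sm <- do.call(`[`, c(list(msk), idxs, list(drop = FALSE)))
    acc <- acc + as.numeric(sx)
    cnt <- cnt + as.numeric(sm)
  }
  out <- acc / pmax(cnt, 1)
  out[cnt == 0] <- x[cnt == 0]
  dim(out) <- d
  out
}

#' Gaussian-kernel-induced squared distance
#'
#' Squared distance between two intensities after the implicit feature map
#' of a Gaussian kernel: `2 (1 - K(m, a))` with
#' `K(m, a) = exp(-(m - a)^2 / delta^2)`.  Bounded in `[0, 2)`, which is
#' what makes the kernelized memberships robust to outlying intensities.
#'
#' @param m,a Numeric intensities (vectorized).
#' @param delta Kernel width `delta > 0`.
#' @return Non-negative kernel-induced squared distance(s).
#' @export
kernel_distance_sq <- function(m, a, delta) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0) {
    ik_stop("kernel width delta must be a positive scalar", "usage")
  }
  # -2*expm1(-u) = 2*(1 - exp(-u)), accurate also for u near 0
  -2 * expm1(-((m - a)^2) / delta^2)
}

#' Spatially regularized center update
#'
#' Center update of the improved algorithm:
#' `a_x = sum_y b_xy^l (m_y + theta * mbar_y) / ((1 + theta) sum_y b_xy^l)`,
#' where `mbar` is the neighborhood-mean image.  With `theta = 0` this is
#' exactly the classical FCM center update.
#'
#' @inheritParams fcm_cost
#' @param nbr Neighborhood-mean array from [neighborhood_mean()] (same
#'   shape as the image), or a numeric vector over in-mask voxels.
#' @param theta Spatial constraint weight `theta >= 0`.
#' @return Numeric vector of updated centers.
#' @export
update_centers_spatial <- function(image, nbr, membership, fuzzifier = 2,
                                   theta = 0.5) {
  if (theta < 0) ik_stop("theta must be >= 0", "usage")
  m <- masked_values(image)
  mb <- masked_nbr(nbr, image, length(m))
  check_membership_dims(membership, nrow(membership), length(m))
  W <- membership^fuzzifier
  rs <- rowSums(W)
  if (any(rs == 0)) {
    ik_stop("degenerate cluster: a membership row is identically zero",
            "numeric")
  }
  as.numeric((W %*% (m + theta * mb)) / ((1 + theta) * rs))
}

masked_nbr <- function(nbr, image, n) {
  image <- as_gray_image(image)
  if (!is.null(dim(nbr)) && identical(dim(nbr), dim(image$intensities))) {
    mb <- if (is.null(image$mask)) as.numeric(nbr) else as.numeric(nbr[image$mask])
  } else {
    mb <- as.numeric(nbr)
  }
  if (length(mb) != n) ik_stop("neighborhood image does not match image", "data")
  mb
}

#' Kernel-spatial membership update
#'
#' Membership update of the improved algorithm.  Each voxel/cluster pair is
#' scored by `D_xy = d_k(m_y, a_x) + theta * d_k(mbar_y, a_x)` with the
#' kernel-induced distance [kernel_distance_sq()], and
#' `b_xy = D_xy^{-1/(l-1)} / sum_g D_gy^{-1/(l-1)}`.  Voxels with `D = 0`
#' for one or more clusters get the zero-distance clusters' memberships
#' split equally.
#'
#' @inheritParams update_centers_spatial
#' @param centers Numeric vector of distinct cluster centers.
#' @param delta Kernel width `> 0`.
#' @return `f x n` membership matrix with unit column sums.
#' @export
update_membership_kernel <- function(image, nbr, centers, fuzzifier = 2,
                                     theta = 0.5, delta = 1) {
  if (theta < 0) ik_stop("theta must be >= 0", "usage")
  centers <- as.numeric(centers)
  if (anyDuplicated(centers)) {
    ik_stop("cluster centers are not distinct", "numeric")
  }
  m <- masked_values(image)
  n <- length(m)
  mb <- masked_nbr(nbr, image, n)
  f <- length(centers)
  D <- outer(centers, m, function(a, v) kernel_distance_sq(v, a, delta)) +
    theta * outer(centers, mb, function(a, v) kernel_distance_sq(v, a, delta))
  zero <- D == 0
  w <- D^(-1 / (fuzzifier - 1))
  B <- sweep(w, 2, colSums(w), "/")
  sing <- which(colSums(zero) > 0)
  for (j in sing) {
    z <- zero[, j]
    B[, j] <- z / sum(z)
  }
  B
}

#' Hesitation-degree correction of a membership matrix
#'
#' Sharpens each voxel's memberships using its hesitation degree `pi_y`
#' from the intuitionistic fuzzification: with winner
#' `e = argmax_x b_xy`, non-winner memberships are scaled to
#' `pi_y * b_xy` and the winner absorbs the remainder,
#' `b_ey = 1 - pi_y * sum_{x != e} b_xy`.  Columns still sum to 1 exactly,
#' the winner's membership never decreases, and the argmax is preserved;
#' `pi = 1` leaves a column unchanged, `pi = 0` makes it crisp.
#'
#' @param membership `f x n` membership matrix with unit column sums.
#' @param hesitation Numeric vector of hesitation degrees in `[0, 1]`, one
#'   per voxel (column).
#' @return Corrected membership matrix.
#' @export
hesitation_correct <- function(membership, hesitation) {
  B <- membership
  pi_y <- as.numeric(hesitation)
  if (length(pi_y) != ncol(B)) {
    ik_stop("one hesitation value per voxel is required", "data")
  }
  if (any(!is.finite(pi_y)) || any(pi_y < 0 | pi_y > 1)) {
    ik_stop("hesitation degrees must lie in [0, 1]", "data")
  }
  e <- max.col(t(B), ties.method = "first")
  idx <- cbind(e, seq_len(ncol(B)))
  others <- colSums(B) - B[idx]
  out <- sweep(B, 2, pi_y, "*")
  out[idx] <- 1 - pi_y * others
  out
}

#' Fit the improved intuitionistic kernel-spatial fuzzy C-means
#'
#' The full improved pipeline: (1) min-max normalization and
#' intuitionistic fuzzification of the image, whose membership component
#' becomes the working intensity and whose hesitation component drives the
#' correction step; (2) neighborhood-mean image; (3) alternating
#' spatially regularized center updates ([update_centers_spatial()]) and
#' kernel-spatial membership updates ([update_membership_kernel()]);
#' (4) hesitation correction of the membership matrix each iteration;
#' (5) termination on the maximum absolute membership change;
#' (6) max-membership defuzzification.
#'
#' @inheritParams fit_fcm
#' @param theta Spatial constraint weight (default 0.25; larger values
#'   smooth more aggressively and can erode structures one voxel thick).
#' @param delta Gaussian kernel width in working-intensity units (the
#'   working intensities always lie in `[0, 1]`).  Default 0.2: larger
#'   than typical within-tissue spread, small enough that distances to
#'   far-away tissues saturate, which is what suppresses outliers.
#'   `"auto"` uses the standard deviation of the in-mask working
#'   intensities instead (a between-class scale; saturates more).
#' @param radius Neighborhood radius `p` (default 1, a 3x3 or 3x3x3 box).
#' @param hesitation When the hesitation correction is applied: every
#'   iteration (`"each"`, default), once after convergence (`"final"`), or
#'   not at all (`"none"`, the bare kernel-spatial scheme).
#' @param kernel_weighted_centers If `TRUE`, centers are updated with
#'   kernel weights (fully kernelized variant); default `FALSE` uses the
#'   plain spatially regularized update.
#' @return An object of class `c("ikfcm_fit", "fcm_fit")` with the
#'   membership matrix, centers in the working (fuzzified) intensity space,
#'   centers mapped back to the original gray range
#'   (`centers_intensity`), the crisp label array (`labels`, 0 = outside
#'   mask), iteration count and run parameters.
#' @examples
#' ph <- make_phantom(shape = c(32, 32), sigma = 0.01, seed = 2)
#' fit <- fit_ikfcm(ph$image, clusters = 4, seed = 1)
#' fit$centers_intensity
#' @export
fit_ikfcm <- function(image, clusters, fuzzifier = 2, theta = 0.25,
                      delta = 0.2, radius = 1, tol = 1e-4,
                      max_iter = 300, seed = 1,
                      init = c("random", "quantile"),
                      hesitation = c("each", "final", "none"),
                      kernel_weighted_centers = FALSE) {
  init <- match.arg(init)
  hesitation <- match.arg(hesitation)
  image <- as_gray_image(image)
  f <- as.integer(clusters)
  if (f < 2) ik_stop("clusters must be >= 2", "usage")
  if (fuzzifier <= 1) ik_stop("fuzzifier must be > 1", "usage")
  if (theta < 0) ik_stop("theta must be >= 0", "usage")
  if (tol <= 0 || max_iter < 1) ik_stop("invalid tol/max_iter", "usage")

  rng <- range(masked_values(image))
  b0 <- normalize_gray(image)
  ifs <- intuitionistic_fuzzify(b0)
  work <- gray_image(ifs$membership, image$voxel_size, image$mask)
  mbar <- neighborhood_mean(work, radius)

  m <- masked_values(work)
  if (length(unique(m)) < f) {
    ik_stop("fewer distinct in-mask intensities than clusters", "data")
  }
  msk <- image$mask
  pi_y <- if (is.null(msk)) as.numeric(ifs$hesitation) else
    as.numeric(ifs$hesitation[msk])
  if (identical(delta, "auto")) delta <- stats::sd(m)
  if (!is.numeric(delta) || delta <= 0) {
    ik_stop("delta must be positive (or \"auto\")", "usage")
  }

  B <- init_membership(m, f, seed, init, fuzzifier)
  A <- centers_step(work, mbar, B, fuzzifier, theta, delta,
                    kernel_weighted_centers)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    B_new <- update_membership_kernel(work, mbar, A, fuzzifier, theta, delta)
    if (hesitation == "each") B_new <- hesitation_correct(B_new, pi_y)
    A <- centers_step(work, mbar, B_new, fuzzifier, theta, delta,
                      kernel_weighted_centers)
    shift <- max(abs(B_new - B))
    B <- B_new
    if (shift < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (hesitation == "final") B <- hesitation_correct(B, pi_y)

  ord <- order(A)
  A <- A[ord]
  B <- B[ord, , drop = FALSE]
  fit <- structure(
    list(membership = B,
         centers = A,
         centers_intensity = as.numeric(ifs_defuzzify(pmin(pmax(A, 0), 1), rng)),
         n_iter = iter,
         converged = converged,
         fuzzifier = fuzzifier,
         data = m,
         hesitation_degrees = pi_y,
         dim = dim(image$intensities),
         mask = msk,
         voxel_size = image$voxel_size,
         gray_range = rng,
         seed = seed,
         algorithm = "ikfcm",
         params = list(clusters = f, fuzzifier = fuzzifier, theta = theta,
                       delta = delta, radius = radius, tol = tol,
                       max_iter = max_iter, seed = seed, init = init,
                       hesitation = hesitation,
                       kernel_weighted_centers = kernel_weighted_centers)),
    class = c("ikfcm_fit", "fcm_fit")
  )
  fit$labels <- defuzzify(fit)
  fit
}

# One center update, plain (the default) or fully kernelized.
centers_step <- function(work, mbar, B, fuzzifier, theta, delta,
                         kernel_weighted) {
  if (!kernel_weighted) {
    return(update_centers_spatial(work, mbar, B, fuzzifier, theta))
  }
  m <- masked_values(work)
  mb <- masked_nbr(mbar, work, length(m))
  W <- B^fuzzifier
  f <- nrow(B)
  a <- numeric(f)
  # Kernel weights are evaluated at the plain-update center (one fixed-point
  # step), the usual KFCM linearization.
  a0 <- update_centers_spatial(work, mbar, B, fuzzifier, theta)
  for (x in seq_len(f)) {
    k1 <- exp(-((m - a0[x])^2) / delta^2)
    k2 <- exp(-((mb - a0[x])^2) / delta^2)
    num <- sum(W[x, ] * (k1 * m + theta * k2 * mb))
    den <- sum(W[x, ] * (k1 + theta * k2))
    if (den == 0) ik_stop("degenerate cluster in kernel-weighted update",
                          "numeric")
    a[x] <- num / den
  }
  a
}

`%||%` <- function(a, b) if (is.null(a)) b else a
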