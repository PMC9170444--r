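#' Fuzzy C-means cost function
#'
#' The FCM objective: the membership-weighted sum of squared Euclidean
#' distances from every in-mask voxel to every cluster center,
#' \deqn{E = \sum_{x=1}^{f} \sum_{y=1}^{n} b_{xy}^{\,l} \, \|m_y - a_x\|^2.}
#'
#' @param image A [gray_image] (or numeric array/vector).
#' @param membership Numeric `f x n` matrix of membership degrees; columns
#'   (voxels) must sum to 1.
#' @param centers Numeric vector of `f` cluster center intensities.
#' @param fuzzifier Weighting exponent `l > 1` controlling membership
#'   softness (default 2).
#' @return Non-negative scalar cost.
#' @export
fcm_cost <- function(image, membership, centers, fuzzifier = 2) {
  m <- masked_values(image)
  check_membership_dims(membership, length(centers), length(m))
  r2 <- outer(as.numeric(centers), m, function(a, v) (v - a)^2)
  sum(membership^fuzzifier * r2)
}

check_membership_dims <- function(B, f, n) {
  if (!is.matrix(B) || nrow(B) != f || ncol(B) != n) {
    ik_stop("membership matrix dimensions do not match centers/image", "data")
  }
  invisible(TRUE)
}

#' Center update of classical FCM
#'
#' Weighted mean of the voxel intensities under memberships raised to the
#' fuzzifier: `a_x = sum_y b_xy^l m_y / sum_y b_xy^l`.
#'
#' @inheritParams fcm_cost
#' @return Numeric vector of updated centers, each within the intensity
#'   range of the image.
#' @export
update_centers <- function(image, membership, fuzzifier = 2) {
  m <- masked_values(image)
  check_membership_dims(membership, nrow(membership), length(m))
  W <- membership^fuzzifier
  rs <- rowSums(W)
  if (any(rs == 0)) {
    ik_stop("degenerate cluster: a membership row is identically zero",
            "numeric")
  }
  as.numeric((W %*% m) / rs)
}

#' Membership update of classical FCM
#'
#' For voxels not coinciding with any center,
#' `b_xy = [sum_g (r_xy / r_gy)^{2/(l-1)}]^{-1}` with `r_xy = |m_y - a_x|`.
#' A voxel equal to one or more centers (a singular point) gets membership
#' `1/|T_y|` on the coinciding centers and 0 elsewhere.
#'
#' @inheritParams fcm_cost
#' @return `f x n` membership matrix; every column sums to 1.
#' @export
update_membership <- function(image, centers, fuzzifier = 2) {
  m <- masked_values(image)
  centers <- as.numeric(centers)
  if (anyDuplicated(centers)) {
    ik_stop("cluster centers are not distinct", "numeric")
  }
  f <- length(centers)
  r2 <- outer(centers, m, function(a, v) (v - a)^2)
  zero <- r2 == 0
  w <- r2^(-1 / (fuzzifier - 1))
  B <- sweep(w, 2, colSums(w), "/")
  sing <- which(colSums(zero) > 0)
  for (j in sing) {
    z <- zero[, j]
    B[, j] <- z / sum(z)
  }
  B
}

#' Fit classical fuzzy C-means to an image
#'
#' Alternates [update_centers()] and [update_membership()] from a seeded
#' initialization until the largest center shift falls below `tol` or
#' `max_iter` iterations have run.  Centers are returned sorted ascending so
#' that label `k` is the `k`-th darkest tissue, stable across runs.
#'
#' @inheritParams fcm_cost
#' @param clusters Number of clusters `f >= 2`.
#' @param tol Convergence threshold on the maximum absolute center change.
#' @param max_iter Maximum number of iterations.
#' @param seed Integer seed for the random initialization.
#' @param init `"random"` (seeded uniform membership matrix, column
#'   normalized) or `"quantile"` (centers at evenly spaced intensity
#'   quantiles, deterministic).
#' @return An object of class `fcm_fit`: membership matrix over in-mask
#'   voxels, sorted centers, iteration count, cost trace, convergence flag,
#'   and the data needed to defuzzify back into image space.
#' @seealso [defuzzify()], [fit_ikfcm()]
#' @examples
#' img <- gray_image(c(rnorm(50, 0, .1), rnorm(50, 10, .1)))
#' fit <- fit_fcm(img, clusters = 2, seed = 1)
#' fit$centers
#' @export
fit_fcm <- function(image, clusters, fuzzifier = 2, tol = 1e-4,
                    max_iter = 300, seed = 1,
                    init = c("random", "quantile")) {
  init <- match.arg(init)
  image <- as_gray_image(image)
  m <- masked_values(image)
  n <- length(m)
  f <- as.integer(clusters)
  if (f < 2) ik_stop("clusters must be >= 2", "usage")
  if (fuzzifier <= 1) ik_stop("fuzzifier must be > 1", "usage")
  if (tol <= 0 || max_iter < 1) ik_stop("invalid tol/max_iter", "usage")
  if (length(unique(m)) < f) {
    ik_stop("fewer distinct in-mask intensities than clusters", "data")
  }

  B <- init_membership(m, f, seed, init, fuzzifier)
  A <- update_centers(image, B, fuzzifier)
  trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    B <- update_membership(image, A, fuzzifier)
    A_new <- update_centers(image, B, fuzzifier)
    trace[iter] <- fcm_cost(image, B, A_new, fuzzifier)
    shift <- max(abs(A_new - A))
    A <- A_new
    if (shift < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }

  ord <- order(A)
  structure(
    list(membership = B[ord, , drop = FALSE],
         centers = A[ord],
         n_iter = iter,
         cost = trace,
         converged = converged,
         fuzzifier = fuzzifier,
         data = m,
         dim = dim(image$intensities),
         mask = image$mask,
         voxel_size = image$voxel_size,
         seed = seed,
         algorithm = "fcm",
         params = list(clusters = f, fuzzifier = fuzzifier, tol = tol,
                       max_iter = max_iter, seed = seed, init = init)),
    class = "fcm_fit"
  )
}

# Seeded initialization of the partition matrix.
init_membership <- function(m, f, seed, init, fuzzifier) {
  n <- length(m)
  if (init == "random") {
    B <- with_seed(seed, matrix(stats::runif(f * n), f, n))
    sweep(B, 2, colSums(B), "/")
  } else {
    # quantiles of the distinct intensity levels: identical to data
    # quantiles for continuous data, non-degenerate on piecewise-constant
    # images where one plateau dominates the distribution
    a0 <- as.numeric(stats::quantile(unique(m), probs = (seq_len(f) - 0.5) / f))
    if (anyDuplicated(a0)) {
      ik_stop("quantile initialization produced coincident centers", "numeric")
    }
    update_membership(m, a0, fuzzifier)
  }
}

#' Crisp labels by maximum membership
#'
#' Assigns each voxel the cluster of its largest membership degree, ties
#' broken toward the lowest cluster index.  Labels are `1..f` inside the
#' mask and 0 (background sentinel) outside.
#'
#' @param x An `fcm_fit`/`ikfcm_fit` object, or an `f x n` membership
#'   matrix.
#' @param shape Integer vector, shape of the output label array (matrix
#'   input only).
#' @param mask Optional logical array selecting the voxels the columns of
#'   `x` refer to (matrix input only).
#' @param ... Unused.
#' @return Integer label array (or vector when no shape is available).
#' @export
defuzzify <- function(x, ...) UseMethod("defuzzify")

#' @rdname defuzzify
#' @export
defuzzify.matrix <- function(x, shape = NULL, mask = NULL, ...) {
  lab <- max.col(t(x), ties.method = "first")
  if (is.null(shape)) return(as.integer(lab))
  out <- array(0L, shape)
  if (is.null(mask)) {
    out[] <- as.integer(lab)
  } else {
    out[mask] <- as.integer(lab)
  }
  out
}

#' @rdname defuzzify
#' @export
defuzzify.fcm_fit <- function(x, ...) {
  defuzzify.matrix(x$membership, shape = x$dim, mask = x$mask)
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat("<", x$algorithm, " fit> ", length(x$centers), " clusters, ",
      ncol(x$membership), " voxels, ", x$n_iter, " iterations (",
      if (isTRUE(x$converged)) "converged" else "max_iter reached", ")\n",
      sep = "")
  cat("  centers:", format(x$centers, digits = 6), "\n")
  invisible(x)
}
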