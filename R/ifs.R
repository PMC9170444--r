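#' Min-max normalization of image gray levels
#'
#' Rescales intensities to `[0, 1]` using the extrema of the in-mask
#' voxels: `b0 = (m - m_min) / (m_max - m_min)`.  Out-of-mask voxels are
#' clipped into `[0, 1]` so the result is a valid fuzzification input
#' everywhere; only in-mask values take part in any later computation.
#'
#' @param image A [gray_image] (or numeric array).
#' @return Numeric array in `[0, 1]`, same shape as the input.
#' @export
normalize_gray <- function(image) {
  image <- as_gray_image(image)
  m <- masked_values(image)
  rng <- range(m)
  if (diff(rng) == 0) {
    ik_stop("constant image: gray-level range is degenerate", "data")
  }
  b0 <- (image$intensities - rng[1]) / (rng[2] - rng[1])
  b0[b0 < 0] <- 0
  b0[b0 > 1] <- 1
  b0
}

#' Intuitionistic fuzzification of a normalized image
#'
#' Maps each normalized gray level `b0` to an intuitionistic fuzzy triplet:
#' membership `b = b0^2`, non-membership `a = (1 - b0)^2`, and hesitation
#' `pi = 2 b0 (1 - b0)`.  The three degrees sum to 1 identically; the
#' hesitation is largest (0.5) at mid-gray and vanishes at the extremes,
#' quantifying how ambiguous a voxel's brightness is.
#'
#' @param b0 Numeric array with values in `[0, 1]` (see [normalize_gray()]).
#' @return An object of class `ifs_image` with fields `membership`,
#'   `nonmembership` and `hesitation`, all the same shape as `b0`.
#' @export
intuitionistic_fuzzify <- function(b0) {
  if (!is.numeric(b0) || any(!is.finite(b0)) || any(b0 < 0 | b0 > 1)) {
    ik_stop("fuzzification input must lie in [0, 1]", "data")
  }
  structure(
    list(membership = b0^2,
         nonmembership = (1 - b0)^2,
         hesitation = 2 * b0 * (1 - b0)),
    class = "ifs_image"
  )
}

#' Map intuitionistic memberships back to gray levels
#'
#' Inverts the fuzzification generator composed with min-max normalization:
#' `m = m_min + sqrt(b) * (m_max - m_min)`.
#'
#' @param ifs An `ifs_image`, or a numeric array of membership values in
#'   `[0, 1]`.
#' @param range Length-2 numeric, the original gray bounds
#'   `c(m_min, m_max)`.
#' @return Numeric array of gray levels.
#' @export
ifs_defuzzify <- function(ifs, range) {
  b <- if (inherits(ifs, "ifs_image")) ifs$membership else ifs
  if (any(b < 0 | b > 1)) ik_stop("membership values outside [0, 1]", "data")
  if (length(range) != 2 || range[2] < range[1]) {
    ik_stop("range must be c(m_min, m_max)", "usage")
  }
  range[1] + sqrt(b) * (range[2] - range[1])
}

#' @export
print.ifs_image <- function(x, ...) {
  cat("<ifs_image> ", paste(dim(x$membership), collapse = " x "),
      " voxels; mean hesitation ",
      format(mean(x$hesitation), digits = 4), "\n", sep = "")
  invisible(x)
}
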