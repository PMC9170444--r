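#' Grayscale image container
#'
#' A lightweight container for a scalar-intensity MR image: an intensity
#' array (1-, 2- or 3-D), the physical voxel size per axis, and an optional
#' binary brain mask.  All clustering routines operate on the set of in-mask
#' voxels only; out-of-mask voxels carry no weight in any update.
#'
#' @param intensities Numeric array (vector, matrix or 3-D array) of finite
#'   intensity values, arbitrary units.
#' @param voxel_size Numeric vector, physical extent of one voxel along each
#'   axis in millimetres.  Recycled to the number of axes if scalar.
#' @param mask Optional logical array of the same shape; `TRUE` marks
#'   in-brain voxels.  `NULL` means all voxels are used.
#' @return An object of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(rnorm(64), 8, 8))
#' dim(img$intensities)
#' @export
gray_image <- function(intensities, voxel_size = NULL, mask = NULL) {
  if (is.null(dim(intensities))) {
    intensities <- array(as.numeric(intensities), dim = length(intensities))
  }
  d <- dim(intensities)
  if (length(d) < 1L || length(d) > 3L) {
    ik_stop("intensities must have 1, 2 or 3 axes", "data")
  }
  if (!all(is.finite(intensities))) {
    ik_stop("intensities must be finite", "data")
  }
  if (is.null(voxel_size)) voxel_size <- rep(1, length(d))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, length(d))
  if (length(voxel_size) != length(d) || any(voxel_size <= 0)) {
    ik_stop("voxel_size must be positive, one value per axis", "data")
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask), d)) {
      ik_stop("mask shape does not match intensities", "data")
    }
    mask <- array(as.logical(mask), d)
    if (!any(mask)) ik_stop("mask has no TRUE voxel", "data")
  }
  structure(
    list(intensities = array(as.numeric(intensities), d),
         voxel_size = as.numeric(voxel_size),
         mask = mask),
    class = "gray_image"
  )
}

#' Coerce to a gray_image
#'
#' Plain numeric vectors, matrices and arrays are wrapped with unit voxel
#' size and no mask; `gray_image` objects pass through unchanged.
#'
#' @param x Object to coerce.
#' @return A `gray_image`.
#' @export
as_gray_image <- function(x) {
  if (inherits(x, "gray_image")) return(x)
  if (is.numeric(x)) return(gray_image(x))
  ik_stop("cannot coerce object to gray_image", "data")
}

# Logical mask of the image (all TRUE when no mask is set).
image_mask <- function(img) {
  if (is.null(img$mask)) array(TRUE, dim(img$intensities)) else img$mask
}

# In-mask intensities as a plain numeric vector (the pixel set the
# clustering cost is summed over).
masked_values <- function(img) {
  img <- as_gray_image(img)
  if (is.null(img$mask)) as.numeric(img$intensities)
  else as.numeric(img$intensities[img$mask])
}

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat("<gray_image> ", paste(d, collapse = " x "),
      " voxels, voxel size ", paste(x$voxel_size, collapse = " x "), " mm\n",
      sep = "")
  if (!is.null(x$mask)) {
    cat("  mask: ", sum(x$mask), " in-brain voxels\n", sep = "")
  }
  rng <- range(masked_values(x))
  cat("  intensity range: [", rng[1], ", ", rng[2], "]\n", sep = "")
  invisible(x)
}
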