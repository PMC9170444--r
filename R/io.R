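#' Read a NIfTI volume as a gray_image
#'
#' Reads a NIfTI-1 file (`.nii` / `.nii.gz`); intensities and per-axis
#' voxel sizes come from the header.  2-D images are accepted as single
#' slices.
#'
#' @param path Path to the NIfTI file.
#' @param mask Optional path to a binary-mask NIfTI of the same shape.
#' @return A [gray_image].
#' @export
read_volume <- function(path, mask = NULL) {
  if (!is.character(path) || !file.exists(path)) {
    ik_stop(paste0("input file not found: ", path), "usage")
  }
  nii <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) {
    ik_stop(paste0("not a readable NIfTI file (", path, "): ",
                   conditionMessage(e)), "data")
  })
  arr <- as.array(nii)
  d <- dim(arr)
  # drop trailing singleton dims (e.g. 3-D files holding one slice)
  while (length(d) > 2 && d[length(d)] == 1) {
    d <- d[-length(d)]
    dim(arr) <- d
  }
  if (length(d) > 3) ik_stop("only 2-D or 3-D volumes are supported", "data")
  vox <- RNifti::pixdim(nii)[seq_along(d)]
  if (any(!is.finite(vox)) || any(vox <= 0)) vox <- rep(1, length(d))
  msk <- NULL
  if (!is.null(mask)) {
    mimg <- read_volume(mask)
    if (!identical(dim(mimg$intensities), d)) {
      ik_stop("mask shape does not match image", "data")
    }
    msk <- mimg$intensities != 0
  }
  gray_image(arr, vox, msk)
}

#' Write an array or gray_image as a NIfTI volume
#'
#' Voxel sizes are stored in the header.  Integer data (label maps) are
#' written as int32, floating point as float64, so round-trips preserve
#' values exactly.
#'
#' @param x A [gray_image] or a numeric/integer array (2-, 3- or 4-D; a
#'   4th axis holds per-cluster membership volumes).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel extent per axis in mm (taken from a
#'   `gray_image` input when omitted).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size = NULL) {
  if (inherits(x, "gray_image")) {
    if (is.null(voxel_size)) voxel_size <- x$voxel_size
    x <- x$intensities
  }
  d <- dim(x)
  if (is.null(voxel_size)) voxel_size <- rep(1, length(d))
  dt <- if (is.integer(x) || all(x == round(x))) "int32" else "double"
  nii <- RNifti::asNifti(x)
  RNifti::pixdim(nii) <- rep_len(voxel_size, length(d))
  RNifti::writeNifti(nii, path, datatype = dt)
  invisible(path)
}

#' Extract a brain mask by thresholding and morphology
#'
#' Foreground by Otsu (default) or fixed-fraction thresholding of the
#' intensity range, restriction to the largest connected component
#' (6-connectivity in 3-D, 4-connectivity in 2-D), then binary closing
#' with a box structuring element — the standard scalp/skull removal step
#' before tissue clustering.  Deterministic.
#'
#' @param image A [gray_image] (or numeric array).
#' @param threshold `"otsu"` or a number in (0, 1): the fraction of the
#'   intensity range above the minimum.
#' @param radius Closing radius in voxels (0 = no closing).
#' @return Logical mask array, a single connected component (up to
#'   closing).
#' @export
extract_brain_mask <- function(image, threshold = "otsu", radius = 1) {
  image <- as_gray_image(image)
  x <- image$intensities
  rng <- range(x)
  if (diff(rng) == 0) ik_stop("constant image: no foreground", "data")
  th <- if (identical(threshold, "otsu")) {
    otsu_threshold(as.numeric(x))
  } else {
    if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
      ik_stop("threshold must be \"otsu\" or a fraction in (0, 1)", "usage")
    }
    rng[1] + threshold * diff(rng)
  }
  fg <- x > th
  if (!any(fg)) ik_stop("empty foreground after thresholding", "data")
  fg <- largest_component(fg)
  if (radius >= 1) fg <- binary_closing(fg, as.integer(radius))
  fg
}

# Otsu's threshold on a 256-bin histogram: maximize between-class variance.
otsu_threshold <- function(v, bins = 256L) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), nbins = bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, bins)
  bc[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  mids[which.max(bc)]
}

# Largest face-connected component of a logical array.
largest_component <- function(fg) {
  d <- dim(fg)
  idx <- which(fg)
  if (length(idx) == 1) return(fg)
  co <- arrayInd(idx, d)
  strides <- cumprod(c(1, d[-length(d)]))
  edges <- NULL
  for (k in seq_along(d)) {
    ok <- co[, k] < d[k]
    nb <- idx[ok] + strides[k]
    keep <- fg[nb]
    if (any(keep)) {
      edges <- rbind(edges, cbind(match(idx[ok][keep], idx),
                                  match(nb[keep], idx)))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  keep <- comp$membership == which.max(comp$csize)
  out <- array(FALSE, d)
  out[idx[keep]] <- TRUE
  out
}

# Binary closing (dilation then erosion) with a (2r+1)^d box.
binary_closing <- function(x, radius) {
  offs <- box_offsets(length(dim(x)), radius, drop_center = FALSE)
  dil <- array(FALSE, dim(x))
  for (r in seq_len(nrow(offs))) {
    dil <- dil | shift_fill(x, offs[r, ], FALSE)
  }
  ero <- array(TRUE, dim(x))
  for (r in seq_len(nrow(offs))) {
    ero <- ero & shift_fill(dil, offs[r, ], TRUE)
  }
  ero
}
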