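#' Tissue specification for the spin-echo phantom
#'
#' Relaxation times and spin density of one tissue class, the parameters
#' entering the spin-echo signal model.
#'
#' @param name Tissue name (e.g. `"CSF"`, `"GM"`, `"WM"`, `"tumor"`).
#' @param t1 Longitudinal relaxation time, ms (`> 0`).
#' @param t2 Transverse relaxation time, ms (`> 0`).
#' @param density Spin-density weight (arbitrary units, `>= 0`).
#' @return A `tissue_spec` object.
#' @export
tissue_spec <- function(name, t1, t2, density = 1) {
  if (t1 <= 0 || t2 <= 0 || density < 0) {
    ik_stop("tissue parameters must satisfy t1 > 0, t2 > 0, density >= 0",
            "data")
  }
  structure(list(name = as.character(name), t1 = t1, t2 = t2,
                 density = density),
            class = "tissue_spec")
}

#' Default tissue table
#'
#' Literature-typical 3T relaxation times for cerebrospinal fluid, gray
#' matter, white matter and a tumor-like lesion, unit spin density.
#'
#' @return Named list of [tissue_spec()] objects.
#' @export
default_tissues <- function() {
  list(
    CSF   = tissue_spec("CSF",   t1 = 4000, t2 = 2000),
    GM    = tissue_spec("GM",    t1 = 1300, t2 = 110),
    WM    = tissue_spec("WM",    t1 = 830,  t2 = 80),
    tumor = tissue_spec("tumor", t1 = 1600, t2 = 150)
  )
}

#' Acquisition specification
#'
#' Spin-echo acquisition parameters: repetition time, echo time and voxel
#' size.  Defaults are a short-TE 3T T1-weighted protocol (TR 1980 ms,
#' TE 2.28 ms, 1 mm isotropic voxels).
#'
#' @param tr Repetition time, ms (`> 0`).
#' @param te Echo time, ms (`>= 0`).
#' @param voxel_size Voxel extent per axis, mm.
#' @return An `acquisition_spec` object.
#' @export
acquisition_spec <- function(tr = 1980, te = 2.28, voxel_size = c(1, 1, 1)) {
  if (tr <= 0 || te < 0 || any(voxel_size <= 0)) {
    ik_stop("acquisition must satisfy tr > 0, te >= 0, voxel_size > 0",
            "data")
  }
  structure(list(tr = tr, te = te, voxel_size = as.numeric(voxel_size)),
            class = "acquisition_spec")
}

#' Spin-echo signal model
#'
#' The spin-echo signal of a tissue under an acquisition:
#' `S = density * (1 - exp(-TR/T1)) * exp(-TE/T2)`.
#' For a list of tissues the per-voxel mixture signal (the sum over
#' tissues) is returned.  S increases with TR and decreases with TE.
#'
#' @param tissue A [tissue_spec()], or a list of them.
#' @param acq An [acquisition_spec()].
#' @return Non-negative signal intensity (arbitrary units).
#' @examples
#' spin_echo_signal(tissue_spec("WM", 830, 80), acquisition_spec())
#' @export
spin_echo_signal <- function(tissue, acq = acquisition_spec()) {
  if (inherits(tissue, "tissue_spec")) tissue <- list(tissue)
  sum(vapply(tissue, function(ts) {
    ts$density * (1 - exp(-acq$tr / ts$t1)) * exp(-acq$te / ts$t2)
  }, numeric(1)))
}

#' Geometric region of a phantom
#'
#' One painted region, in coordinates relative to the image extent
#' (voxel centers mapped to `[0, 1]` per axis).  Regions are painted in
#' list order, later regions overwriting earlier ones, which is how the
#' nested brain / gray-matter ribbon / white-matter core / tumor geometry
#' is built.
#'
#' @param tissue Name of the tissue filling the region (must exist in the
#'   phantom's tissue table).
#' @param shape `"ellipsoid"` or `"box"`.
#' @param center Region center, fractions of the image extent.
#' @param semiaxes Semi-axis lengths (ellipsoid) or half-widths (box),
#'   fractions of the image extent.
#' @return A `phantom_region` object.
#' @export
region <- function(tissue, shape = c("ellipsoid", "box"), center = 0.5,
                   semiaxes = 0.4) {
  shape <- match.arg(shape)
  if (any(semiaxes <= 0)) ik_stop("region semiaxes must be > 0", "data")
  structure(list(tissue = as.character(tissue), shape = shape,
                 center = as.numeric(center),
                 semiaxes = as.numeric(semiaxes)),
            class = "phantom_region")
}

#' Default nested brain geometry
#'
#' Concentric ellipsoids — CSF envelope, gray-matter ribbon, white-matter
#' core — plus an off-center tumor blob inside the white matter.
#'
#' @return List of [region()] objects.
#' @export
default_geometry <- function() {
  list(
    region("CSF",   center = 0.5, semiaxes = 0.45),
    region("GM",    center = 0.5, semiaxes = 0.36),
    region("WM",    center = 0.5, semiaxes = 0.26),
    region("tumor", center = c(0.42, 0.58, 0.5), semiaxes = 0.09)
  )
}

#' Generate a spin-echo brain phantom with ground truth
#'
#' Paints the geometry's regions with their tissues' spin-echo signals,
#' adds seeded noise, and returns the image together with the ground-truth
#' label map (labels `1..K` in tissue-table order, 0 = background), the
#' brain mask (all painted voxels), the tissue table and the noise
#' description.  Deterministic given `seed`.
#'
#' @param shape Integer image shape (2- or 3-D).
#' @param geometry List of [region()] objects (painted in order).
#' @param tissues Named list of [tissue_spec()] objects.
#' @param acq An [acquisition_spec()].
#' @param noise Noise model for [corrupt()].
#' @param sigma Noise level (absolute intensity units for
#'   gaussian/rician, corrupted fraction for salt_pepper); 0 = noiseless.
#' @param seed Integer seed.
#' @return A `phantom_truth` object with fields `image` ([gray_image]),
#'   `labels`, `tissues`, `signals`, `noise`.
#' @examples
#' ph <- make_phantom(shape = c(32, 32), sigma = 0)
#' table(ph$labels)
#' @export
make_phantom <- function(shape = c(64, 64, 64), geometry = default_geometry(),
                         tissues = default_tissues(),
                         acq = acquisition_spec(),
                         noise = c("gaussian", "rician", "salt_pepper"),
                         sigma = 0, seed = 1) {
  noise <- match.arg(noise)
  shape <- as.integer(shape)
  if (length(shape) < 2 || length(shape) > 3) {
    ik_stop("phantom shape must be 2- or 3-D", "usage")
  }
  if (length(tissues) < 2) ik_stop("need at least 2 tissues", "data")
  tnames <- vapply(tissues, function(t) t$name, character(1))
  names(tissues) <- tnames
  for (rg in geometry) {
    if (!rg$tissue %in% tnames) {
      ik_stop(paste0("geometry region references unknown tissue '",
                     rg$tissue, "'"), "data")
    }
  }

  nd <- length(shape)
  # voxel-center coordinates as fractions of the extent, per axis
  coords <- lapply(shape, function(n) (seq_len(n) - 0.5) / n)
  labels <- array(0L, shape)
  for (rg in geometry) {
    ctr <- rep_len(rg$center, nd)
    sem <- rep_len(rg$semiaxes, nd)
    dist_axes <- mapply(function(u, c0, s) (u - c0) / s, coords, ctr, sem,
                        SIMPLIFY = FALSE)
    inside <- if (rg$shape == "ellipsoid") {
      q <- array(0, shape)
      for (k in seq_len(nd)) {
        rep_dims <- shape
        ax <- dist_axes[[k]]^2
        perm <- seq_len(nd)
        arr <- array(rep(ax, prod(shape) / shape[k]),
                     dim = c(shape[k], shape[-k]))
        if (k > 1) arr <- aperm(arr, order(c(k, seq_len(nd)[-k])))
        q <- q + arr
      }
      q <= 1
    } else {
      ok <- array(TRUE, shape)
      for (k in seq_len(nd)) {
        ax <- abs(dist_axes[[k]]) <= 1
        arr <- array(rep(ax, prod(shape) / shape[k]),
                     dim = c(shape[k], shape[-k]))
        if (k > 1) arr <- aperm(arr, order(c(k, seq_len(nd)[-k])))
        ok <- ok & arr
      }
      ok
    }
    labels[inside] <- match(rg$tissue, tnames)
  }
  if (!any(labels > 0)) ik_stop("geometry paints no voxel", "data")

  signals <- vapply(tissues, spin_echo_signal, numeric(1), acq = acq)
  intens <- array(0, shape)
  intens[labels > 0] <- signals[labels[labels > 0]]
  mask <- labels > 0
  vox <- rep_len(acq$voxel_size, nd)
  img <- gray_image(intens, vox, mask)
  if (sigma > 0) img <- corrupt(img, noise, sigma, seed)

  structure(
    list(image = img,
         labels = labels,
         tissues = tissues,
         signals = signals,
         geometry = geometry,
         acquisition = acq,
         noise = list(model = noise, sigma = sigma, seed = seed)),
    class = "phantom_truth"
  )
}

#' Inject noise into an image
#'
#' Seeded noise on the in-mask voxels.  `gaussian` adds `N(0, level^2)`;
#' `rician` replaces each intensity by the magnitude of the complex signal
#' with independent `N(0, level^2)` noise on both channels (the
#' distribution of magnitude MR noise); `salt_pepper` sets a `level`
#' fraction of in-mask voxels to the in-mask minimum or maximum with equal
#' probability.  `level = 0` returns the input unchanged.
#'
#' @param image A [gray_image].
#' @param model `"gaussian"`, `"rician"` or `"salt_pepper"`.
#' @param level Noise level (`>= 0`).
#' @param seed Integer seed.
#' @return The corrupted [gray_image].
#' @export
corrupt <- function(image, model = c("gaussian", "rician", "salt_pepper"),
                    level, seed = 1) {
  model <- match.arg(model)
  image <- as_gray_image(image)
  if (level < 0) ik_stop("noise level must be >= 0", "usage")
  if (level == 0) return(image)
  msk <- image_mask(image)
  x <- image$intensities
  v <- x[msk]
  n <- length(v)
  v_new <- with_seed(seed, {
    switch(model,
      gaussian = v + stats::rnorm(n, 0, level),
      rician = sqrt((v + stats::rnorm(n, 0, level))^2 +
                      stats::rnorm(n, 0, level)^2),
      salt_pepper = {
        hit <- stats::runif(n) < level
        lo <- min(v); hi <- max(v)
        v[hit] <- ifelse(stats::runif(sum(hit)) < 0.5, lo, hi)
        v
      })
  })
  x[msk] <- v_new
  gray_image(x, image$voxel_size, image$mask)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> ", paste(dim(x$labels), collapse = " x "),
      " voxels, ", length(x$tissues), " tissues (",
      paste(names(x$tissues), collapse = ", "), ")\n", sep = "")
  cat("  noise: ", x$noise$model, " level ", x$noise$sigma,
      " seed ", x$noise$seed, "\n", sep = "")
  invisible(x)
}
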