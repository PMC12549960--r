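#' Image stack container
#'
#' An `ImageStack` is a single-channel 3D voxel grid with anisotropic voxel
#' spacing, the carrier for all image arithmetic in the package. Arrays are
#' indexed `(z, y, x)` and spacing is given in micrometres per voxel in the
#' same order.
#'
#' @param voxels numeric 3D array of non-negative intensities, dim `(z, y, x)`.
#' @param spacing numeric length-3 voxel spacing in micrometres `(z, y, x)`.
#' @param name channel label, e.g. `"DAPI"`, `"EdU"`.
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(voxels, spacing = c(0.2, 0.04, 0.04), name = "channel") {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (z, y, x) in um")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 name = as.character(name)),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ImageStack '%s': %d x %d x %d (z,y,x), spacing %s um, range [%g, %g]\n",
              x$name, d[1], d[2], d[3],
              paste(signif(x$spacing, 3), collapse = " x "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

as_stack_like <- function(voxels, template, name = NULL) {
  image_stack(voxels, template$spacing, if (is.null(name)) template$name else name)
}

#' Read a 3D stack from a multipage TIFF
#'
#' Pages are z-slices; interleaved multichannel files are de-interleaved via
#' `n_channels`/`channel`. Voxel spacing is recovered from the TIFF
#' description written by [write_stack()] or must be supplied.
#'
#' @param path TIFF file path.
#' @param channel 1-based channel index for interleaved multichannel files.
#' @param n_channels number of interleaved channels in the file.
#' @param spacing voxel spacing (z, y, x) in um; overrides the metadata
#'   sidecar written by [write_stack()].
#' @param name channel label for the returned stack.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel = 1L, n_channels = 1L, spacing = NULL,
                       name = "channel") {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) %% n_channels != 0L)
    stop("page count ", length(pages), " not divisible by n_channels ", n_channels)
  if (channel < 1L || channel > n_channels) stop("invalid channel index")
  sel <- pages[seq(channel, length(pages), by = n_channels)]
  if (length(dim(sel[[1]])) != 2L) stop("expected single-sample (grayscale) pages")
  vox <- array(0, dim = c(length(sel), dim(sel[[1]])))
  for (i in seq_along(sel)) vox[i, , ] <- sel[[i]]
  if (is.null(spacing)) {
    meta_path <- paste0(path, ".meta.yaml")
    if (file.exists(meta_path)) {
      meta <- yaml::read_yaml(meta_path)
      spacing <- as.numeric(meta$spacing_um)
    }
  }
  if (is.null(spacing) || length(spacing) != 3L || any(is.na(spacing)))
    stop("voxel spacing not present in metadata; pass spacing = c(z, y, x)")
  image_stack(vox, spacing, name)
}

#' Write a 3D stack to a multipage 16-bit TIFF
#'
#' Integer data in 0..65535 round-trips losslessly. Voxel spacing and the
#' channel name are stored in a `<path>.meta.yaml` sidecar so
#' [read_stack()] can recover them.
#'
#' @param stack an [image_stack()] or an integer-valued array.
#' @param path output file path.
#' @param bits bits per sample (16 default).
#' @export
write_stack <- function(stack, path, bits = 16L) {
  if (!inherits(stack, "ImageStack")) stack <- image_stack(stack)
  v <- stack$voxels
  maxval <- 2^bits - 1
  if (min(v) < 0 || max(v) > maxval)
    stop("intensities outside the representable ", bits, "-bit range")
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
  yaml::write_yaml(list(spacing_um = as.numeric(stack$spacing),
                        channel = stack$name),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Write a label map as 16-bit TIFF
#' @param labels integer 3D array (0 = background).
#' @param path output path.
#' @param spacing voxel spacing (z, y, x) um.
#' @export
write_label_map <- function(labels, path, spacing = c(0.2, 0.04, 0.04)) {
  write_stack(image_stack(labels, spacing, "labels"), path)
}

#' Gaussian smoothing of a stack
#'
#' Separable sampled-Gaussian filtering with reflective borders; the default
#' sigma of 1 voxel matches the blur applied to the DNA channel before
#' chromocenter segmentation.
#'
#' @param stack an [image_stack()].
#' @param sigma standard deviation in voxels; either a scalar (applied to all
#'   axes) or a length-3 vector (z, y, x). `sigma = 0` is the identity.
#' @return the filtered [image_stack()].
#' @export
gaussian_smooth <- function(stack, sigma = 1) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  v <- stack$voxels
  for (ax in 1:3) {
    if (sigma[ax] > 0) v <- conv_axis(v, gaussian_kernel1d(sigma[ax]), ax)
  }
  as_stack_like(v, stack)
}

#' Box-mean smoothing of a stack
#'
#' Cubic-neighbourhood mean of half-width `radius` (radius 1 = the 3x3x3
#' mean used before spot seed detection).
#'
#' @param stack an [image_stack()].
#' @param radius non-negative integer half-width in voxels.
#' @return the filtered [image_stack()].
#' @export
mean_smooth <- function(stack, radius = 1L) {
  radius <- as.integer(radius)
  if (radius < 0L) stop("radius must be >= 0")
  if (radius == 0L) return(stack)
  k <- rep(1 / (2 * radius + 1), 2 * radius + 1)
  v <- stack$voxels
  for (ax in 1:3) v <- conv_axis(v, k, ax)
  as_stack_like(v, stack)
}

#' Min-max contrast normalization to [0, 1]
#'
#' Linear rescale with 0% saturation; a constant input yields an all-zero
#' stack carrying attribute `constant_input = TRUE` and a warning.
#'
#' @param stack an [image_stack()].
#' @return the rescaled [image_stack()].
#' @export
normalize_contrast <- function(stack) {
  v <- stack$voxels
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("constant input: normalized stack is all zeros")
    out <- as_stack_like(array(0, dim(v)), stack)
    attr(out, "constant_input") <- TRUE
    return(out)
  }
  as_stack_like((v - rng[1]) / diff(rng), stack)
}

#' Convert a length in micrometres to per-axis voxels
#' @param um length in micrometres.
#' @param spacing voxel spacing (z, y, x) um.
#' @return length-3 vector of voxel counts per axis.
#' @export
um_to_voxels <- function(um, spacing) um / spacing
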