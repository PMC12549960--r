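#' Mander's 3D colocalization coefficients
#'
#' Between two channels inside a nuclear region of interest, with
#' above-threshold masks TA and TB: `M1` is the fraction of channel-A
#' intensity over TA that lies inside TB, and `M2` the symmetric quantity
#' for channel B. Thresholds are Otsu within the ROI per channel by
#' default (quantile or fixed thresholds are accepted for
#' reproducibility).
#'
#' @param chanA,chanB [image_stack()]s of identical shape.
#' @param roi a [label_map()] or logical array (the nucleus mask).
#' @param threshold `"otsu"`, `"quantile"`, or a length-2 numeric vector
#'   of fixed thresholds (A, B) on the raw intensity scales.
#' @param quantile_prob probability for the quantile rule.
#' @return list of class `ManderResult`: `M1`, `M2`, `threshold_a`,
#'   `threshold_b`, `undefined` (TRUE when a channel has no
#'   supra-threshold intensity, in which case its coefficient is NA).
#' @export
manders_coefficients <- function(chanA, chanB, roi,
                                 threshold = "otsu", quantile_prob = 0.9) {
  if (!identical(dim(chanA$voxels), dim(chanB$voxels)))
    stop("channel shapes differ")
  m <- if (inherits(roi, "LabelMap")) roi$labels > 0L else roi
  if (!any(m)) stop("empty ROI")
  a <- chanA$voxels[m]
  b <- chanB$voxels[m]
  thr <- if (is.numeric(threshold)) {
    if (length(threshold) != 2L) stop("fixed threshold must be length 2 (A, B)")
    threshold
  } else if (identical(threshold, "otsu")) {
    c(otsu_threshold(a), otsu_threshold(b))
  } else {
    c(quantile_threshold(a, quantile_prob), quantile_threshold(b, quantile_prob))
  }
  ta <- a > thr[1]
  tb <- b > thr[2]
  sa <- sum(a[ta]); sb <- sum(b[tb])
  undefined <- sa <= 0 || sb <= 0
  M1 <- if (sa > 0) sum(a[ta & tb]) / sa else NA_real_
  M2 <- if (sb > 0) sum(b[ta & tb]) / sb else NA_real_
  structure(list(M1 = M1, M2 = M2, threshold_a = thr[1], threshold_b = thr[2],
                 undefined = undefined),
            class = "ManderResult")
}

#' @export
print.ManderResult <- function(x, ...) {
  cat(sprintf("Mander's coefficients: M1 = %.4f, M2 = %.4f%s\n", x$M1, x$M2,
              if (x$undefined) " (undefined: empty threshold mask)" else ""))
  invisible(x)
}
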