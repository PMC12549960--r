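# High-content cell-cycle gating, PTM normalization, PCH enrichment,
# replication-foci pattern classification and pulse-chase substage scoring.

#' Gate a cell population into G1 / S / G2 by DAPI and EdU
#'
#' EdU-positive cells are called S; EdU-negative cells are split by total
#' DNA content into G1 (low, ~2C) and G2 (high, ~4C). Thresholds come from
#' the data by default: Otsu on log EdU intensities for EdU positivity, and
#' the midpoint of a deterministic 2-means split of log DNA among
#' EdU-negative cells for the 2C/4C boundary. Both can be fixed via `model`
#' (e.g. thresholds derived from negative-control wells).
#'
#' @param cells data.frame with columns `total_dna` and `mean_edu` (e.g.
#'   from [simulate_population_table()] or a high-content export).
#' @param model optional list: `edu_threshold` (a.u.), `dna_boundary`
#'   (a.u., 2C/4C split), `edu_background` (a.u., subtracted before
#'   thresholding).
#' @return the input data.frame with a `stage` column in {G1, S, G2}, with
#'   the fitted `GateModel` in attribute `"gate_model"`.
#' @export
gate_population <- function(cells, model = NULL) {
  stopifnot(all(c("total_dna", "mean_edu") %in% names(cells)))
  edu <- cells$mean_edu
  if (!is.null(model$edu_background)) edu <- pmax(edu - model$edu_background, 0)
  edu_thr <- model$edu_threshold
  if (is.null(edu_thr)) {
    le <- log1p(edu)
    edu_thr <- expm1(otsu_threshold(le))
  }
  is_s <- edu > edu_thr
  neg <- which(!is_s)
  if (length(neg) < 2L)
    stop("GateFailure: no EdU-negative cells to split into G1/G2")
  dna_bound <- model$dna_boundary
  if (is.null(dna_bound)) {
    ld <- log(pmax(cells$total_dna[neg], .Machine$double.eps))
    # deterministic 2-means on log DNA, initialized at the lower/upper quartiles
    cen <- stats::quantile(ld, c(0.25, 0.75), names = FALSE)
    if (diff(cen) < 1e-8)
      stop("GateFailure: DAPI histogram of EdU-negative cells is unimodal ",
           "(quartile spread ", signif(diff(cen), 3), ")")
    for (it in 1:100) {
      assign2 <- abs(ld - cen[1]) > abs(ld - cen[2])
      new_cen <- c(mean(ld[!assign2]), mean(ld[assign2]))
      if (any(!is.finite(new_cen)))
        stop("GateFailure: could not separate 2C and 4C modes")
      if (max(abs(new_cen - cen)) < 1e-10) break
      cen <- new_cen
    }
    if (exp(max(cen)) / exp(min(cen)) < 1.2)
      stop("GateFailure: 2C and 4C DAPI modes not separable ",
           "(mode ratio ", signif(exp(max(cen)) / exp(min(cen)), 3), ")")
    dna_bound <- exp(mean(cen))
  }
  stage <- ifelse(is_s, "S", ifelse(cells$total_dna <= dna_bound, "G1", "G2"))
  cells$stage <- stage
  attr(cells, "gate_model") <- list(edu_threshold = edu_thr,
                                    dna_boundary = dna_bound,
                                    method = if (is.null(model)) "mixture"
                                    else "manual")
  cells
}

#' Per-stage PTM fold change, DNA-normalized and G1-referenced
#'
#' For each cell the PTM sum is divided by the DNA sum; per stage the fold
#' change is the median of this ratio divided by the G1 median, so the G1
#' fold is 1 by construction.
#'
#' @param cells gated data.frame (a `stage` column present).
#' @param ptm name of the PTM sum column (default `"ptm"`).
#' @param dna name of the DNA sum column (default `"total_dna"`).
#' @param stages stage order for the output.
#' @return named numeric vector of fold changes per stage.
#' @export
ptm_fold_change <- function(cells, ptm = "ptm", dna = "total_dna",
                            stages = c("G1", "S", "G2")) {
  stopifnot("stage" %in% names(cells))
  if (!any(cells$stage == "G1")) stop("empty G1 group")
  r <- cells[[ptm]] / cells[[dna]]
  med <- vapply(stages, function(st) stats::median(r[cells$stage == st]),
                numeric(1))
  med / med[["G1"]]
}

#' Signal enrichment inside a region of interest
#'
#' Sum of the channel over the ROI divided by the sum of DNA over the ROI
#' (`statistic = "sum_ratio"`, the PCH-enrichment measure), or the plain
#' mean of the channel in the ROI (`statistic = "mean"`, used for mean EdU
#' in PCH).
#'
#' @param channel an [image_stack()] (e.g. a histone PTM or RNA-FISH
#'   channel).
#' @param dna an [image_stack()] of the DNA channel (ignored for
#'   `statistic = "mean"`).
#' @param roi a [label_map()] (e.g. segmented chromocenters) or logical
#'   array.
#' @param statistic `"sum_ratio"` or `"mean"`.
#' @return a single ratio or mean.
#' @export
measure_enrichment_in_roi <- function(channel, dna = NULL, roi,
                                      statistic = c("sum_ratio", "mean")) {
  statistic <- match.arg(statistic)
  m <- if (inherits(roi, "LabelMap")) roi$labels > 0L else roi
  if (!any(m)) stop("empty ROI")
  if (statistic == "mean") return(mean(channel$voxels[m]))
  if (is.null(dna)) stop("dna channel required for sum_ratio")
  if (!identical(dim(channel$voxels), dim(dna$voxels)))
    stop("channel and dna shapes differ")
  sum(channel$voxels[m]) / sum(dna$voxels[m])
}

#' Classify the spatial pattern of replication foci
#'
#' Computes the fraction of total foci intensity lying in chromocenters
#' (`f_cc`) and in the peripheral nuclear shell (`f_rim`, the outer 15% of
#' the normalized nuclear radius by default). Decision: `f_cc >= cc_frac`
#' gives S II (chromocenter-associated), otherwise `f_rim >= rim_frac`
#' gives S III (peripheral/perinucleolar), otherwise S I (dispersed
#' euchromatic).
#'
#' @param foci a `SpotSet` of replication foci (EdU or PCNA).
#' @param nucleus a [label_map()] of the nucleus.
#' @param chromocenters a [label_map()] of segmented PCH.
#' @param min_foci minimum spot count; fewer raises an `Unclassifiable`
#'   error.
#' @param cc_frac,rim_frac decision thresholds on the intensity fractions.
#' @param rim_depth_frac rim shell thickness as a fraction of the
#'   normalized nuclear radius (0.15 = the outer 15%).
#' @param dilate_cc voxels by which the chromocenter mask is dilated before
#'   measuring `f_cc` (captures surface-associated foci).
#' @return character `"SI"`, `"SII"` or `"SIII"`, with attributes `f_cc`
#'   and `f_rim`.
#' @export
classify_rfi_pattern <- function(foci, nucleus, chromocenters, min_foci = 5L,
                                 cc_frac = 0.4, rim_frac = 0.4,
                                 rim_depth_frac = 0.15, dilate_cc = 2L) {
  if (nrow(foci$spots) < min_foci)
    stop("Unclassifiable: fewer than ", min_foci, " foci")
  nmask <- nucleus$labels > 0L
  ccm <- chromocenters$labels > 0L
  if (dilate_cc > 0) ccm <- dilate6(ccm, dilate_cc) & nmask
  # normalized nuclear radius from a second-moment ellipsoid fit of the
  # mask (for a solid ellipsoid the coordinate variance is semiaxis^2 / 5),
  # so the rim shell keeps its relative thickness in every direction even
  # for anisotropic nuclei
  idx <- which(nmask)
  co <- coords_from_index(idx, dim(nmask))
  ctr <- colMeans(co)
  semi <- sqrt(5 * apply(co, 2, stats::var))
  rho <- ellipsoid_rho(dim(nmask), semi, ctr)
  rim <- nmask & rho >= (1 - rim_depth_frac)
  # intensity-weighted fractions: each focus contributes its integrated
  # intensity to the compartment holding its centroid
  d <- dim(nmask)
  cz <- pmin(pmax(round(foci$spots$z), 1), d[1])
  cy <- pmin(pmax(round(foci$spots$y), 1), d[2])
  cx <- pmin(pmax(round(foci$spots$x), 1), d[3])
  at <- cbind(cz, cy, cx)
  w <- foci$spots$integrated_intensity
  f_cc <- sum(w[ccm[at]]) / sum(w)
  f_rim <- sum(w[rim[at] & !ccm[at]]) / sum(w)
  out <- if (f_cc >= cc_frac) "SII" else if (f_rim >= rim_frac) "SIII" else "SI"
  attr(out, "f_cc") <- f_cc
  attr(out, "f_rim") <- f_rim
  out
}

#' Score S-phase progression from an EdU/PCNA pulse-chase pair
#'
#' Deterministic truth table over the pulse (EdU, past synthesis) and chase
#' (PCNA, ongoing synthesis) readouts: a negative EdU but positive PCNA
#' signal indicates S I at the chase end; EdU positive with an S I pattern
#' and punctate PCNA indicates S II (pattern read from the PCNA channel);
#' EdU positive with no punctate PCNA means the cell was in S III at the
#' pulse and has exited S; neither signal means non-S.
#'
#' @param edu_present logical, EdU signal detected.
#' @param pcna_punctate logical, punctate PCNA foci detected.
#' @param edu_pattern optional pattern label (`"SI"`, `"SII"`, `"SIII"`)
#'   from [classify_rfi_pattern()] on the EdU channel; required to be
#'   absent/NA when `edu_present` is FALSE.
#' @param pcna_pattern optional pattern label for the PCNA channel;
#'   required to be absent/NA when `pcna_punctate` is FALSE.
#' @return character progression call: `"SI"`, `"SII"`, `"SIII_exited"`,
#'   or `"nonS"`.
#' @export
assign_pulse_chase_stage <- function(edu_present, pcna_punctate,
                                     edu_pattern = NA_character_,
                                     pcna_pattern = NA_character_) {
  if (!edu_present && !is.na(edu_pattern))
    stop("input error: EdU pattern supplied for a cell flagged EdU-negative")
  if (!pcna_punctate && !is.na(pcna_pattern))
    stop("input error: PCNA pattern supplied for a cell without punctate PCNA")
  if (!edu_present && pcna_punctate) return("SI")
  if (edu_present && pcna_punctate) return("SII")
  if (edu_present && !pcna_punctate) return("SIII_exited")
  "nonS"
}

#' Cliff's delta effect size
#'
#' Non-parametric effect size: the probability that a value of `a` exceeds
#' a value of `b` minus the reverse, over all pairs;
#' `delta = (#[a > b] - #[a < b]) / (n m)`, in `[-1, 1]`.
#'
#' @param a,b numeric samples (non-empty).
#' @return delta.
#' @export
cliffs_delta <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  n <- length(a); m <- length(b)
  if (as.double(n) * m <= 4e6) {
    d <- sign(outer(a, b, `-`))
    return(sum(d) / (n * m))
  }
  # rank-based O((n+m) log(n+m)) path for large samples
  sb <- sort(b)
  gt <- findInterval(a, sb, left.open = TRUE)          # b values < a
  ge <- findInterval(a, sb)                             # b values <= a
  (sum(gt) - sum(m - ge)) / (as.double(n) * m)
}

#' Classical 2D nucleus segmentation for high-content fields
#'
#' A weight-free fallback segmenter for 2D projections: Gaussian blur, Otsu
#' threshold, hole filling and distance-map watershed separation of
#' touching nuclei (via EBImage). Any external segmenter's per-cell table
#' can be used instead.
#'
#' @param img 2D numeric matrix (a projection or single plane).
#' @param sigma Gaussian blur sigma, pixels.
#' @param min_size minimum object area, pixels.
#' @return integer matrix of nucleus labels.
#' @export
segment_nuclei_2d <- function(img, sigma = 2, min_size = 50) {
  sm <- EBImage::gblur(EBImage::Image(img / max(img)), sigma = sigma)
  thr <- otsu_threshold(as.vector(sm))
  mask <- EBImage::fillHull(sm > thr)
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm)
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0L])
  bad <- which(sizes < min_size)
  if (length(bad)) lab[lab %in% bad] <- 0L
  u <- setdiff(sort(unique(as.vector(lab))), 0L)
  out <- array(0L, dim(lab))
  out[lab > 0L] <- match(lab[lab > 0L], u)
  out
}
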