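# HMRF chromatin-compaction classification and intensity-weighted mapping
# of signals to compaction classes.

#' HMRF classification parameters
#'
#' Parameters of the hidden Markov random field used to partition nuclear
#' voxels into chromatin compaction classes by DNA intensity: a Gaussian
#' emission per class plus a Potts smoothness prior of strength `beta` over
#' face neighbours, optimized by iterated conditional modes (ICM) with
#' EM-style parameter updates.
#'
#' @param n_classes number of compaction classes (7: classes 1-4 form the
#'   active nuclear compartment, 5-7 the inactive compartment).
#' @param beta Potts interaction strength; `beta = 0` reduces to per-voxel
#'   maximum-likelihood Gaussian classification.
#' @param neighborhood `"6"` face connectivity (the only one implemented;
#'   per-axis weights handle anisotropy).
#' @param axis_weights optional length-3 neighbour weights (z, y, x);
#'   default scales by inverse voxel spacing so that z-anisotropy weakens
#'   the axial coupling.
#' @param max_iter maximum ICM sweeps.
#' @param tol stop when fewer than this fraction of labels change.
#' @return list of class `HmrfParams`.
#' @export
hmrf_params <- function(n_classes = 7L, beta = 0.3, neighborhood = "6",
                        axis_weights = NULL, max_iter = 50L, tol = 0.001) {
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (beta < 0) stop("beta must be >= 0")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  structure(list(n_classes = as.integer(n_classes), beta = beta,
                 neighborhood = neighborhood, axis_weights = axis_weights,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "HmrfParams")
}

#' Classify nuclear voxels into chromatin compaction classes (HMRF)
#'
#' Labels are initialized by quantile binning of the nuclear DNA intensities
#' into equal-count classes, then iterated: Gaussian emission means and
#' variances are re-estimated from the current labels, and every voxel takes
#' the class minimizing negative log emission minus `beta` times the
#' (weighted) count of agreeing face neighbours. On return classes are
#' relabelled by ascending mean DNA intensity, so class 1 is the least and
#' class `n_classes` the most compacted chromatin.
#'
#' @param dna an [image_stack()] of the DNA channel.
#' @param nucleus a [label_map()]; classification is restricted to its mask.
#' @param params a [hmrf_params()].
#' @return object of class `CompactionMap`: `labels` (class ids, 0 outside
#'   the nucleus), `class_means`, `class_vars` (the Gaussian emission
#'   parameters of the final sweep, ordered by class, so that with
#'   `beta = 0` the labels are exactly the per-voxel ML assignment under
#'   them), `anc_classes`, `inc_classes`, `converged`, `n_iter`, `spacing`.
#' @export
classify_compaction_hmrf <- function(dna, nucleus, params = hmrf_params()) {
  nmask <- nucleus$labels > 0L
  if (!any(nmask)) stop("empty nucleus mask")
  x <- dna$voxels
  K <- params$n_classes
  inside <- x[nmask]
  if (length(unique(inside)) < K)
    stop("DegenerateHistogram: fewer distinct intensities than classes")
  w <- params$axis_weights
  if (is.null(w)) w <- min(dna$spacing) / dna$spacing
  # deterministic initialization: equal-count quantile bins
  q <- stats::quantile(inside, probs = seq(0, 1, length.out = K + 1))
  q <- unique(q)
  lab_in <- findInterval(inside, q, rightmost.closed = TRUE, all.inside = TRUE)
  if (length(q) - 1L < K)  # heavily tied histogram: spread bins evenly
    lab_in <- as.integer(cut(rank(inside, ties.method = "first"), K,
                             labels = FALSE))
  labels <- array(0L, dim(x))
  labels[nmask] <- lab_in
  n_in <- length(inside)
  converged <- FALSE
  iter <- 0L
  var_floor <- max(1e-12, stats::var(inside) * 1e-8)
  for (iter in seq_len(params$max_iter)) {
    # M-step: Gaussian emission parameters from current labels
    mu <- as.vector(tapply(inside, factor(lab_in, levels = 1:K), mean))
    va <- as.vector(tapply(inside, factor(lab_in, levels = 1:K), stats::var))
    va[!is.finite(va) | va < var_floor] <- var_floor
    empty <- !is.finite(mu)
    if (any(empty)) { # re-seed empty classes at intensity extremes
      mu[empty] <- stats::quantile(inside, probs = seq(0.01, 0.99,
                                                       length.out = K))[empty]
      va[empty] <- stats::var(inside)
    }
    # ICM sweep (synchronous): energy per class over all nuclear voxels
    E <- matrix(0, nrow = n_in, ncol = K)
    for (k in 1:K) {
      ek <- 0.5 * log(2 * pi * va[k]) + (inside - mu[k])^2 / (2 * va[k])
      if (params$beta > 0) {
        same <- neighbor_sum6((labels == k) * 1, weights = w)
        ek <- ek - params$beta * same[nmask]
      }
      E[, k] <- ek
    }
    new_in <- max.col(-E, ties.method = "first")
    changed <- mean(new_in != lab_in)
    lab_in <- new_in
    labels[nmask] <- lab_in
    mu_final <- mu; va_final <- va   # emission parameters of this sweep
    if (changed < params$tol) { converged <- TRUE; break }
  }
  # relabel ascending by emission mean, keeping the parameters of the final
  # sweep so labels remain the exact energy minimizers under them
  mu <- mu_final; va <- va_final
  ord <- order(mu)
  remap <- integer(K); remap[ord] <- 1:K
  lab_in <- remap[lab_in]
  labels[nmask] <- lab_in
  anc <- seq_len(ceiling(K * 4 / 7))
  structure(list(labels = labels, class_means = mu[ord], class_vars = va[ord],
                 anc_classes = anc, inc_classes = setdiff(1:K, anc),
                 converged = converged, n_iter = iter, params = params,
                 spacing = dna$spacing),
            class = "CompactionMap")
}

#' @export
print.CompactionMap <- function(x, ...) {
  cat(sprintf("CompactionMap: %d classes, means %s, converged=%s (%d sweeps)\n",
              length(x$class_means),
              paste(signif(x$class_means, 4), collapse = ", "),
              x$converged, x$n_iter))
  invisible(x)
}

#' Intensity-weighted mapping of a signal to compaction classes
#'
#' Signal voxels above a threshold contribute their intensity to the
#' compaction class of their voxel; the profile entry for class k is the
#' fraction of total supra-threshold intensity in class k, so brighter
#' signals have a larger impact than dim ones.
#'
#' @param signal an [image_stack()] (e.g. EdU replication foci or a PTM).
#' @param cmap a `CompactionMap` from [classify_compaction_hmrf()].
#' @param threshold `"otsu"` (computed within the nucleus), or a fixed
#'   numeric value on the signal intensity scale.
#' @return numeric vector of class fractions (class `ClassFractionProfile`),
#'   summing to 1.
#' @export
map_signal_to_classes <- function(signal, cmap, threshold = "otsu") {
  lab <- cmap$labels
  if (!identical(dim(signal$voxels), dim(lab)))
    stop("signal and compaction map shapes differ")
  v <- signal$voxels
  inside <- lab > 0L
  thr <- if (is.numeric(threshold)) threshold
  else otsu_threshold(v[inside])
  sel <- inside & (v > thr)
  if (!any(sel)) stop("EmptySignal: no signal above threshold inside nucleus")
  K <- length(cmap$class_means)
  tot <- as.vector(tapply(v[sel], factor(lab[sel], levels = 1:K), sum))
  tot[is.na(tot)] <- 0
  profile <- tot / sum(tot)
  structure(profile, class = "ClassFractionProfile", threshold = thr)
}

#' Active/inactive nuclear compartment summary of a class profile
#'
#' @param profile a `ClassFractionProfile` (classes ascending in density).
#' @param anc_classes indices of the active nuclear compartment classes
#'   (1-4 of 7 by default); the rest form the inactive compartment.
#' @return named numeric: `anc_fraction`, `inc_fraction` (summing to 1).
#' @export
summarize_anc_inc <- function(profile, anc_classes = 1:4) {
  p <- as.numeric(profile)
  anc <- sum(p[anc_classes])
  c(anc_fraction = anc, inc_fraction = sum(p) - anc)
}
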