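# 3D spot segmentation: local-maxima seeds, Gaussian-fit stop thresholds,
# seeded region growth and watershed splitting of clustered spots.

#' Find spot seeds as local intensity maxima
#'
#' The stack is preprocessed with a box-mean filter (radius 1 by default)
#' and min-max normalized, then strict 26-neighbourhood local maxima inside
#' the nucleus are kept if they rise more than `noise_tolerance` above the
#' nuclear background (median); maxima closer than `merge_radius` are
#' collapsed to the brightest.
#'
#' @param stack an [image_stack()] of the spot channel.
#' @param nucleus a [label_map()] or logical array restricting the search.
#' @param mean_radius preprocessing box-mean radius, voxels (0 disables).
#' @param normalize min-max normalize after smoothing.
#' @param noise_tolerance minimum prominence above the nuclear median, on
#'   the preprocessed intensity scale; default 3x the median absolute
#'   deviation of nuclear voxels.
#' @param merge_radius collapse radius in voxels (scaled by spacing
#'   anisotropy).
#' @return data.frame of seeds: `z`, `y`, `x`, `value` (preprocessed),
#'   ordered by decreasing value, with the preprocessed stack in attribute
#'   `"processed"`.
#' @export
find_seeds <- function(stack, nucleus, mean_radius = 1L, normalize = TRUE,
                       noise_tolerance = NULL, merge_radius = 2) {
  nmask <- if (inherits(nucleus, "LabelMap")) nucleus$labels > 0L else nucleus
  if (!any(nmask)) stop("empty nucleus mask")
  proc <- stack
  if (mean_radius > 0) proc <- mean_smooth(proc, mean_radius)
  if (normalize) proc <- suppressWarnings(normalize_contrast(proc))
  v <- proc$voxels
  inside <- v[nmask]
  med <- stats::median(inside)
  if (is.null(noise_tolerance)) noise_tolerance <- 3 * stats::mad(inside)
  # strict local maxima over the 26-neighbourhood
  is_max <- array(TRUE, dim(v))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    s <- v
    if (dz != 0) s <- axis_shift(s, 1, dz, fill = -Inf)
    if (dy != 0) s <- axis_shift(s, 2, dy, fill = -Inf)
    if (dx != 0) s <- axis_shift(s, 3, dx, fill = -Inf)
    is_max <- is_max & (v >= s)
  }
  # array faces are excluded: reflective smoothing leaves noise there
  # under-averaged and every face voxel trivially beats its missing neighbours
  interior <- array(TRUE, dim(v))
  d <- dim(v)
  interior[c(1, d[1]), , ] <- FALSE
  interior[, c(1, d[2]), ] <- FALSE
  interior[, , c(1, d[3])] <- FALSE
  cand <- which(is_max & nmask & interior & (v - med >= noise_tolerance))
  if (length(cand) == 0L) {
    out <- data.frame(z = integer(0), y = integer(0), x = integer(0),
                      value = numeric(0))
    attr(out, "processed") <- proc
    return(out)
  }
  co <- coords_from_index(cand, dim(v))
  val <- v[cand]
  ord <- order(val, decreasing = TRUE)
  co <- co[ord, , drop = FALSE]; val <- val[ord]
  # greedy non-maximum suppression within merge_radius (um-scaled)
  sc <- stack$spacing / min(stack$spacing)
  keep <- rep(TRUE, length(val))
  for (i in seq_along(val)) {
    if (!keep[i]) next
    if (i < length(val)) {
      j <- (i + 1):length(val)
      d2 <- ((co[j, 1] - co[i, 1]) * sc[1])^2 +
        ((co[j, 2] - co[i, 2]) * sc[2])^2 +
        ((co[j, 3] - co[i, 3]) * sc[3])^2
      keep[j][d2 <= merge_radius^2] <- FALSE
    }
  }
  out <- data.frame(z = co[keep, 1], y = co[keep, 2], x = co[keep, 3],
                    value = val[keep])
  attr(out, "processed") <- proc
  out
}

# radially averaged intensity profile around a seed (shells of 1 voxel,
# anisotropy scaled); returns data.frame(r, mean)
radial_profile <- function(v, seed, fit_radius, sc) {
  d <- dim(v)
  rr <- ceiling(fit_radius / sc)
  zr <- max(1, seed[1] - rr[1]):min(d[1], seed[1] + rr[1])
  yr <- max(1, seed[2] - rr[2]):min(d[2], seed[2] + rr[2])
  xr <- max(1, seed[3] - rr[3]):min(d[3], seed[3] + rr[3])
  dist <- sqrt(outer(outer(((zr - seed[1]) * sc[1])^2,
                           ((yr - seed[2]) * sc[2])^2, `+`),
                     ((xr - seed[3]) * sc[3])^2, `+`))
  sub <- v[zr, yr, xr]
  shell <- round(dist)
  sel <- shell <= fit_radius
  m <- tapply(sub[sel], shell[sel], mean)
  data.frame(r = as.numeric(names(m)), mean = as.numeric(m))
}

# fit m(r) = B + A exp(-r^2 / (2 sigma^2)); NULL on degenerate profile
fit_radial_gaussian <- function(prof) {
  if (nrow(prof) < 3) return(NULL)
  B0 <- min(prof$mean); A0 <- max(prof$mean) - B0
  if (A0 <= 0) return(NULL)
  fit <- tryCatch(
    minpack.lm::nlsLM(mean ~ B + A * exp(-r^2 / (2 * sigma^2)), data = prof,
                      start = list(A = A0, B = B0, sigma = 1.5),
                      lower = c(A = 0, B = -Inf, sigma = 0.3),
                      upper = c(A = Inf, B = Inf, sigma = max(prof$r)),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  if (!is.finite(p[["A"]]) || p[["A"]] <= 0) return(NULL)
  p
}

#' Grow spots from seeds with a Gaussian-fit stop threshold
#'
#' For each seed a 1D Gaussian (amplitude A, offset B, width sigma) is
#' fitted to the radially averaged intensity profile; voxel clustering then
#' flood-fills (6-connectivity) from the seed over voxels at or above the
#' stop threshold `B + stop_fraction * A`. Regions claimed by several seeds
#' are merged into multi-seed spots, to be separated by [watershed_split()].
#' Integrated intensities are sums of the input stack over spot voxels.
#'
#' @param stack an [image_stack()]; growth and fitting use this stack as
#'   given (apply the same preprocessing as used for [find_seeds()] when
#'   following the standard pipeline).
#' @param seeds data.frame with columns z, y, x (from [find_seeds()]).
#' @param nucleus optional [label_map()]/logical array restricting growth.
#' @param stop_fraction stop threshold as a fraction of the fitted
#'   amplitude above the fitted offset (0.5 = half maximum).
#' @param fit_radius radial-profile extent, voxels.
#' @param grow_radius maximum growth half-width around the seed, voxels.
#' @return object of class `SpotSet`: `spots` data.frame (label, z, y, x
#'   centroid, voxel_count, integrated_intensity, seed_value, n_seeds,
#'   threshold), `label_map`, `seed_table`, `discarded` (seed rows whose
#'   radial fit was degenerate, with reasons).
#' @export
grow_spots <- function(stack, seeds, nucleus = NULL, stop_fraction = 0.5,
                       fit_radius = 7, grow_radius = 10) {
  v <- stack$voxels
  d <- dim(v)
  nmask <- if (is.null(nucleus)) NULL
  else if (inherits(nucleus, "LabelMap")) nucleus$labels > 0L else nucleus
  sc <- stack$spacing / min(stack$spacing)
  if (!"value" %in% names(seeds))
    seeds$value <- v[as.matrix(round(seeds[, c("z", "y", "x")]))]
  n <- nrow(seeds)
  lab_arr <- array(0L, d)
  spot_of_seed <- integer(n)     # spot id each seed ended in
  thresholds <- rep(NA_real_, n)
  discarded <- integer(0)
  reasons <- character(0)
  next_id <- 0L
  merge_into <- function(ids) min(ids)  # union-find lite via relabel
  for (i in seq_len(n)) {
    seed <- as.integer(round(unlist(seeds[i, c("z", "y", "x")])))
    prof <- radial_profile(v, seed, fit_radius, sc)
    p <- fit_radial_gaussian(prof)
    if (is.null(p)) {
      # degenerate fit: fall back to half-range threshold in the window;
      # a flat window discards the seed
      rng <- range(prof$mean)
      if (diff(rng) <= 0) {
        discarded <- c(discarded, i)
        reasons <- c(reasons, "flat radial profile")
        next
      }
      thr <- mean(rng)
    } else {
      thr <- p[["B"]] + stop_fraction * p[["A"]]
    }
    thr <- min(thr, v[seed[1], seed[2], seed[3]])
    thresholds[i] <- thr
    # local window flood fill from the seed over voxels >= thr
    rr <- pmin(ceiling(grow_radius / sc), grow_radius)
    zr <- max(1, seed[1] - rr[1]):min(d[1], seed[1] + rr[1])
    yr <- max(1, seed[2] - rr[2]):min(d[2], seed[2] + rr[2])
    xr <- max(1, seed[3] - rr[3]):min(d[3], seed[3] + rr[3])
    sub <- v[zr, yr, xr, drop = FALSE]
    ok <- sub >= thr
    if (!is.null(nmask)) ok <- ok & nmask[zr, yr, xr]
    grown <- array(FALSE, dim(ok))
    grown[seed[1] - zr[1] + 1L, seed[2] - yr[1] + 1L, seed[3] - xr[1] + 1L] <- TRUE
    repeat {
      nxt <- (grown | dilate6(grown)) & ok
      if (identical(nxt, grown)) break
      grown <- nxt
    }
    gidx <- which(grown)
    co <- coords_from_index(gidx, dim(grown))
    co[, 1] <- co[, 1] + zr[1] - 1L
    co[, 2] <- co[, 2] + yr[1] - 1L
    co[, 3] <- co[, 3] + xr[1] - 1L
    glob <- index_from_coords(co, d)
    hit <- unique(lab_arr[glob])
    hit <- hit[hit > 0L]
    if (length(hit) == 0L) {
      next_id <- next_id + 1L
      id <- next_id
    } else {
      id <- merge_into(hit)
      for (h in setdiff(hit, id)) {
        lab_arr[lab_arr == h] <- id
        spot_of_seed[spot_of_seed == h] <- id
      }
    }
    lab_arr[glob] <- id
    spot_of_seed[i] <- id
  }
  seed_table <- cbind(seeds, spot = spot_of_seed)
  build_spotset(lab_arr, v, seed_table[spot_of_seed > 0L, , drop = FALSE],
                stack, thresholds,
                discarded = cbind(seeds[discarded, , drop = FALSE],
                                  reason = reasons))
}

# assemble a SpotSet from a label array, compacting labels to 1..K
build_spotset <- function(lab_arr, v, seed_table, stack, thresholds = NULL,
                          discarded = NULL) {
  idx <- which(lab_arr > 0L)
  u <- sort(unique(lab_arr[idx]))
  out <- array(0L, dim(lab_arr))
  if (length(u)) {
    out[idx] <- match(lab_arr[idx], u)
    seed_table$spot <- match(seed_table$spot, u)
  }
  ids <- out[idx]
  spots <- if (length(u)) {
    co <- coords_from_index(idx, dim(out))
    f <- factor(ids, levels = seq_along(u))
    data.frame(
      label = seq_along(u),
      z = as.vector(tapply(co[, 1] * v[idx], f, sum) / tapply(v[idx], f, sum)),
      y = as.vector(tapply(co[, 2] * v[idx], f, sum) / tapply(v[idx], f, sum)),
      x = as.vector(tapply(co[, 3] * v[idx], f, sum) / tapply(v[idx], f, sum)),
      voxel_count = as.vector(table(f)),
      integrated_intensity = as.vector(tapply(v[idx], f, sum)),
      seed_value = as.vector(tapply(seed_table$value,
                                    factor(seed_table$spot,
                                           levels = seq_along(u)), max)),
      n_seeds = as.vector(table(factor(seed_table$spot,
                                       levels = seq_along(u)))))
  } else {
    data.frame(label = integer(0), z = numeric(0), y = numeric(0),
               x = numeric(0), voxel_count = integer(0),
               integrated_intensity = numeric(0), seed_value = numeric(0),
               n_seeds = integer(0))
  }
  structure(list(spots = spots, label_map = out, seed_table = seed_table,
                 channel = stack$name, spacing = stack$spacing,
                 thresholds = thresholds, discarded = discarded),
            class = "SpotSet")
}

#' @export
print.SpotSet <- function(x, ...) {
  cat(sprintf("SpotSet '%s': %d spot(s), %d voxel(s)\n", x$channel,
              nrow(x$spots), sum(x$spots$voxel_count)))
  invisible(x)
}

#' Split multi-seed spots by seeded 3D watershed
#'
#' Spots containing more than one seed are partitioned by descending-
#' intensity immersion from their seeds (6-connectivity): region voxels are
#' visited from bright to dim and each joins the labelled neighbour with
#' the brightest intensity. Single-seed spots are returned unchanged and
#' the union of spot voxels is preserved exactly.
#'
#' @param spotset a `SpotSet` from [grow_spots()].
#' @param stack the [image_stack()] used for growth (intensity landscape).
#' @return a `SpotSet` in which every spot contains exactly one seed.
#' @export
watershed_split <- function(spotset, stack) {
  v <- stack$voxels
  d <- dim(v)
  lab_arr <- spotset$label_map
  st <- spotset$seed_table
  multi <- spotset$spots$label[spotset$spots$n_seeds > 1L]
  if (length(multi) == 0L) return(spotset)
  next_id <- max(lab_arr) + 1L
  strides <- c(1L, -1L, d[1], -d[1], d[1] * d[2], -d[1] * d[2])
  for (m in multi) {
    idx <- which(lab_arr == m)
    srows <- which(st$spot == m)
    sidx <- index_from_coords(as.matrix(st[srows, c("z", "y", "x")]), d)
    new_ids <- c(m, next_id + seq_len(length(srows) - 1L) - 1L)
    next_id <- next_id + length(srows) - 1L
    # local assignment by descending-intensity flooding
    loc <- match(idx, idx)
    assign_loc <- integer(length(idx))
    assign_loc[match(sidx, idx)] <- new_ids
    # neighbour lookup (6-connectivity) restricted to the region, guarding
    # against wrap-around across array faces
    co <- coords_from_index(idx, d)
    nb <- matrix(NA_integer_, nrow = length(idx), ncol = 6L)
    for (k in 1:6) {
      ax <- c(1, 1, 2, 2, 3, 3)[k]
      dir <- c(1, -1, 1, -1, 1, -1)[k]
      valid <- co[, ax] + dir >= 1 & co[, ax] + dir <= d[ax]
      nb[valid, k] <- match(idx[valid] + strides[k], idx)
    }
    ord <- order(v[idx], decreasing = TRUE)
    repeat {
      changed <- FALSE
      for (i in ord) {
        if (assign_loc[i] > 0L) next
        nn <- nb[i, ]
        nn <- nn[!is.na(nn)]
        nn <- nn[assign_loc[nn] > 0L]
        if (length(nn)) {
          assign_loc[i] <- assign_loc[nn[which.max(v[idx[nn]])]]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    # isolated voxels unreachable from any seed keep the original label
    assign_loc[assign_loc == 0L] <- m
    lab_arr[idx] <- assign_loc
    st$spot[srows] <- new_ids
  }
  out <- build_spotset(lab_arr, v, st, stack,
                       thresholds = spotset$thresholds,
                       discarded = spotset$discarded)
  out$channel <- spotset$channel
  out
}

#' Count spots per region of interest
#'
#' A spot is counted in an ROI if its (rounded) centroid voxel carries that
#' ROI label (default), or if any of its voxels overlap the ROI
#' (`rule = "overlap"`).
#'
#' @param spotset a `SpotSet`.
#' @param roi a [label_map()] (e.g. segmented chromocenters).
#' @param rule `"centroid"` or `"overlap"`.
#' @return list: `per_roi` (named integer vector over ROI labels) and
#'   `total` (spots assigned to any ROI).
#' @export
count_spots_in_roi <- function(spotset, roi, rule = c("centroid", "overlap")) {
  rule <- match.arg(rule)
  rl <- roi$labels
  ids <- setdiff(sort(unique(as.vector(rl))), 0L)
  per <- stats::setNames(integer(length(ids)), ids)
  if (nrow(spotset$spots) == 0L)
    return(list(per_roi = per, total = 0L))
  if (rule == "centroid") {
    cz <- pmin(pmax(round(spotset$spots$z), 1), dim(rl)[1])
    cy <- pmin(pmax(round(spotset$spots$y), 1), dim(rl)[2])
    cx <- pmin(pmax(round(spotset$spots$x), 1), dim(rl)[3])
    hit <- rl[cbind(cz, cy, cx)]
  } else {
    hit <- vapply(spotset$spots$label, function(l) {
      r <- rl[spotset$label_map == l]
      r <- r[r > 0L]
      if (length(r)) as.integer(names(sort(table(r), decreasing = TRUE))[1]) else 0L
    }, integer(1))
  }
  tab <- table(factor(hit[hit > 0L], levels = ids))
  per[] <- as.integer(tab)
  list(per_roi = per, total = sum(hit > 0L))
}

#' Match detected spots to planted centers
#'
#' Greedy one-to-one matching within `radius` (voxels, anisotropy scaled);
#' reports precision, recall and the matched pairs. Used to benchmark
#' detection against simulated ground truth.
#'
#' @param detected matrix/data.frame of detected centers (z, y, x).
#' @param truth matrix of planted centers (z, y, x).
#' @param radius match radius, voxels.
#' @param spacing voxel spacing for anisotropy scaling.
#' @return list: precision, recall, n_matched.
#' @export
spot_match_stats <- function(detected, truth, radius = 2,
                             spacing = c(1, 1, 1)) {
  det <- as.matrix(as.data.frame(detected)[, c("z", "y", "x")])
  tru <- as.matrix(as.data.frame(truth)[, c("z", "y", "x")])
  sc <- spacing / min(spacing)
  used <- rep(FALSE, nrow(tru))
  n_match <- 0L
  for (i in seq_len(nrow(det))) {
    d2 <- ((tru[, 1] - det[i, 1]) * sc[1])^2 +
      ((tru[, 2] - det[i, 2]) * sc[2])^2 +
      ((tru[, 3] - det[i, 3]) * sc[3])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= radius^2) {
      used[j] <- TRUE
      n_match <- n_match + 1L
    }
  }
  list(precision = if (nrow(det)) n_match / nrow(det) else NA_real_,
       recall = if (nrow(tru)) n_match / nrow(tru) else NA_real_,
       n_matched = n_match)
}
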