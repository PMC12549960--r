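# Synthetic-data generators: 3D nuclei with chromocenters and replication
# foci, high-content cell populations, compaction textures, spot fields and
# FRAP traces -- all with exact ground truth, so every downstream stage can
# be validated without raw microscopy data.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Configuration for a simulated nucleus stack
#'
#' Describes an ellipsoidal nucleus with spherical DAPI-dense chromocenters
#' (1-voxel Gaussian-blurred edges emulating optics), an optional
#' replication-foci channel laid out in one of the three S-substage spatial
#' patterns, and an optional histone-PTM channel enriched at chromocenters.
#'
#' @param shape stack dimensions (z, y, x) in voxels.
#' @param voxel_size voxel spacing (z, y, x) in micrometres.
#' @param nucleus_semiaxes ellipsoid semiaxes (z, y, x) in voxels.
#' @param n_chromocenters number of chromocenters to plant.
#' @param cc_radius chromocenter radius mean and sd, voxels.
#' @param nucleoplasm_level,cc_level intensity levels (a.u.);
#'   `cc_level > nucleoplasm_level`.
#' @param s_pattern replication-foci spatial pattern: `"none"`, `"SI"`
#'   (dispersed nucleoplasmic, excluding chromocenters), `"SII"` (on
#'   chromocenter surfaces) or `"SIII"` (peripheral rim shell, the outer 15%
#'   of normalized ellipsoidal radius).
#' @param n_foci number of replication foci.
#' @param focus_sigma Gaussian width of each focus, voxels.
#' @param focus_level peak amplitude of each focus (a.u.).
#' @param ptm_cc_enrichment PTM channel intensity ratio inside chromocenters
#'   relative to the DNA-proportional baseline (1 = no enrichment).
#' @param noise list with `gaussian_sd` (additive read noise, a.u.; default
#'   2% of `cc_level`) and `poisson_scale` (0 disables shot noise).
#' @param seed integer; identical configurations and seeds give identical
#'   output.
#' @return a list of class `SimNucleusConfig`.
#' @export
sim_nucleus_config <- function(shape = c(40, 80, 80),
                               voxel_size = c(0.2, 0.04, 0.04),
                               nucleus_semiaxes = c(15, 30, 30),
                               n_chromocenters = 12,
                               cc_radius = c(mean = 4, sd = 0.5),
                               nucleoplasm_level = 1000,
                               cc_level = 3000,
                               s_pattern = c("none", "SI", "SII", "SIII"),
                               n_foci = 80,
                               focus_sigma = 1.5,
                               focus_level = 2000,
                               ptm_cc_enrichment = 1,
                               noise = list(gaussian_sd = NULL, poisson_scale = 0),
                               seed = 1L) {
  s_pattern <- match.arg(s_pattern)
  if (is.null(noise$gaussian_sd)) noise$gaussian_sd <- 0.02 * cc_level
  if (is.null(noise$poisson_scale)) noise$poisson_scale <- 0
  cfg <- list(shape = as.integer(shape), voxel_size = voxel_size,
              nucleus_semiaxes = nucleus_semiaxes,
              n_chromocenters = as.integer(n_chromocenters),
              cc_radius = cc_radius,
              nucleoplasm_level = nucleoplasm_level, cc_level = cc_level,
              s_pattern = s_pattern, n_foci = as.integer(n_foci),
              focus_sigma = focus_sigma, focus_level = focus_level,
              ptm_cc_enrichment = ptm_cc_enrichment, noise = noise,
              seed = as.integer(seed))
  class(cfg) <- "SimNucleusConfig"
  validate_sim_nucleus_config(cfg)
  cfg
}

validate_sim_nucleus_config <- function(cfg) {
  if (any(cfg$nucleus_semiaxes >= (cfg$shape - 1) / 2))
    stop("geometry error: nucleus semiaxes do not fit inside the stack shape")
  if (cfg$cc_level <= cfg$nucleoplasm_level)
    stop("cc_level must exceed nucleoplasm_level")
  if (cfg$n_chromocenters < 0 || cfg$n_foci < 0)
    stop("counts must be >= 0")
  invisible(cfg)
}

# normalized ellipsoidal radius of every voxel (1 on the nucleus surface)
ellipsoid_rho <- function(shape, semiaxes, center = (shape + 1) / 2) {
  z <- ((seq_len(shape[1]) - center[1]) / semiaxes[1])^2
  y <- ((seq_len(shape[2]) - center[2]) / semiaxes[2])^2
  x <- ((seq_len(shape[3]) - center[3]) / semiaxes[3])^2
  sqrt(outer(outer(z, y, `+`), x, `+`))
}

add_gaussian_blob <- function(v, center, sigma, amplitude) {
  d <- dim(v)
  r <- ceiling(4 * sigma)
  zr <- max(1, round(center[1]) - r):min(d[1], round(center[1]) + r)
  yr <- max(1, round(center[2]) - r):min(d[2], round(center[2]) + r)
  xr <- max(1, round(center[3]) - r):min(d[3], round(center[3]) + r)
  g <- amplitude * exp(-(
    outer(outer((zr - center[1])^2, (yr - center[2])^2, `+`),
          (xr - center[3])^2, `+`)) / (2 * sigma^2))
  v[zr, yr, xr] <- v[zr, yr, xr] + g
  v
}

#' Simulate a multichannel nucleus stack with ground truth
#'
#' Generates a DNA channel (ellipsoidal nucleus plus chromocenter blobs),
#' optionally an EdU-like foci channel following the configured S-substage
#' pattern, and optionally a PTM channel proportional to DNA and enriched
#' `ptm_cc_enrichment`-fold inside chromocenters. Noise is applied last.
#'
#' @param cfg a [sim_nucleus_config()].
#' @return list with `channels` (named list of [image_stack()]: `DNA`, and
#'   where applicable `EdU`, `PTM`) and `truth` (nucleus_mask, cc_label_map,
#'   cc_centers, cc_radii, focus_centers, rim_mask, stage_label).
#' @export
simulate_nucleus_stack <- function(cfg) {
  validate_sim_nucleus_config(cfg)
  with_seed(cfg$seed, {
    d <- cfg$shape
    center <- (d + 1) / 2
    rho <- ellipsoid_rho(d, cfg$nucleus_semiaxes, center)
    nucleus <- rho <= 1
    rim_mask <- nucleus & rho >= 0.85

    # --- chromocenters: non-overlapping spheres well inside the nucleus
    cc_label <- array(0L, dim = d)
    cc_centers <- matrix(numeric(0), ncol = 3,
                         dimnames = list(NULL, c("z", "y", "x")))
    cc_radii <- numeric(0)
    if (cfg$n_chromocenters > 0) {
      n_try <- 0L
      while (nrow(cc_centers) < cfg$n_chromocenters && n_try < 20000L) {
        n_try <- n_try + 1L
        r <- max(1.5, stats::rnorm(1, cfg$cc_radius[["mean"]],
                                   cfg$cc_radius[["sd"]]))
        p <- center + stats::runif(3, -1, 1) * (cfg$nucleus_semiaxes - r - 2)
        # keep the whole sphere clearly inside the nucleus: the center must
        # lie within the ellipsoid shrunk by the radius plus a margin
        inner <- pmax(cfg$nucleus_semiaxes - (r + 2), 1)
        if (sqrt(sum(((p - center) / inner)^2)) > 1) next
        if (nrow(cc_centers) > 0) {
          dist2 <- rowSums(sweep(cc_centers, 2, p)^2)
          # optical blur adds a dim halo of ~1.5 voxels per object; a 4-voxel
          # surface gap keeps segmented objects from fusing
          if (any(sqrt(dist2) < cc_radii + r + 4)) next
        }
        cc_centers <- rbind(cc_centers, p)
        cc_radii <- c(cc_radii, r)
      }
      if (nrow(cc_centers) < cfg$n_chromocenters)
        stop("geometry error: could not place ", cfg$n_chromocenters,
             " non-overlapping chromocenters")
      for (i in seq_len(nrow(cc_centers))) {
        r <- cc_radii[i]; p <- cc_centers[i, ]
        zr <- max(1, floor(p[1] - r)):min(d[1], ceiling(p[1] + r))
        yr <- max(1, floor(p[2] - r)):min(d[2], ceiling(p[2] + r))
        xr <- max(1, floor(p[3] - r)):min(d[3], ceiling(p[3] + r))
        dist2 <- outer(outer((zr - p[1])^2, (yr - p[2])^2, `+`), (xr - p[3])^2, `+`)
        sub <- cc_label[zr, yr, xr]
        sub[dist2 <= r^2 & sub == 0L] <- i
        cc_label[zr, yr, xr] <- sub
      }
    }
    cc_mask <- cc_label > 0L

    # --- DNA channel: nucleoplasm plateau + blurred-edge chromocenters
    dna <- array(0, dim = d)
    dna[nucleus] <- cfg$nucleoplasm_level
    if (any(cc_mask)) {
      cc_soft <- conv_axis(conv_axis(conv_axis(cc_mask * 1,
        gaussian_kernel1d(1), 1), gaussian_kernel1d(1), 2),
        gaussian_kernel1d(1), 3)
      dna <- dna + (cfg$cc_level - cfg$nucleoplasm_level) * cc_soft * nucleus
    }

    channels <- list(DNA = dna)

    # --- replication foci channel
    focus_centers <- matrix(numeric(0), ncol = 3,
                            dimnames = list(NULL, c("z", "y", "x")))
    if (cfg$s_pattern != "none" && cfg$n_foci > 0) {
      focus_centers <- place_foci(cfg, d, center, rho, nucleus, cc_mask,
                                  cc_centers, cc_radii)
      edu <- array(0, dim = d)
      for (i in seq_len(nrow(focus_centers)))
        edu <- add_gaussian_blob(edu, focus_centers[i, ], cfg$focus_sigma,
                                 cfg$focus_level)
      channels$EdU <- edu * (rho <= 1.02)
    }

    # --- PTM channel: DNA-proportional, enriched inside chromocenters
    channels$PTM <- dna * (1 + (cfg$ptm_cc_enrichment - 1) * cc_mask)

    # --- noise last
    for (nm in names(channels)) {
      v <- channels[[nm]]
      if (cfg$noise$poisson_scale > 0) {
        sc <- cfg$noise$poisson_scale
        v <- stats::rpois(length(v), pmax(v, 0) / sc) * sc
        dim(v) <- d
      }
      if (cfg$noise$gaussian_sd > 0)
        v <- v + array(stats::rnorm(prod(d), 0, cfg$noise$gaussian_sd), d)
      channels[[nm]] <- image_stack(pmax(v, 0), cfg$voxel_size, nm)
    }

    truth <- list(nucleus_mask = nucleus, cc_label_map = cc_label,
                  cc_centers = cc_centers, cc_radii = cc_radii,
                  focus_centers = focus_centers, rim_mask = rim_mask,
                  stage_label = cfg$s_pattern)
    list(channels = channels, truth = truth)
  })
}

# sample focus centers according to the S-substage spatial pattern
place_foci <- function(cfg, d, center, rho, nucleus, cc_mask,
                       cc_centers, cc_radii) {
  n <- cfg$n_foci
  if (cfg$s_pattern == "SII") {
    if (nrow(cc_centers) == 0)
      stop("SII pattern requires chromocenters")
    idx <- rep_len(seq_len(nrow(cc_centers)), n)
    pts <- t(vapply(idx, function(i) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      cc_centers[i, ] + cc_radii[i] * u
    }, numeric(3)))
    colnames(pts) <- c("z", "y", "x")
    return(pts)
  }
  margin <- ceiling(2 * cfg$focus_sigma)
  ok <- if (cfg$s_pattern == "SI") {
    nucleus & rho <= 0.8 & !dilate6(cc_mask, 2L)
  } else { # SIII: peripheral rim shell, kept off the very surface so the
    # blob stays inside the nucleus
    nucleus & rho >= 0.85 & rho <= 0.96
  }
  cand <- which(ok)
  if (length(cand) < n) stop("not enough room to place ", n, " foci")
  sel <- sample(cand, n)
  pts <- coords_from_index(sel, d)
  storage.mode(pts) <- "double"
  pts
}

#' Configuration for a simulated cell population
#'
#' Emulates the DAPI/EdU population structure of an asynchronously cycling
#' culture: G1 cells at 2C DNA content, S cells uniformly between 2C and 4C
#' with elevated EdU, G2 cells at 4C. Stage allocation is deterministic
#' (largest-remainder rounding of the proportions); only the per-cell
#' feature draws are stochastic. Defaults place ~70% of cells in S phase,
#' the regime typical of mouse embryonic stem cells.
#'
#' @param n_cells number of cells.
#' @param stage_proportions named proportions for G1, S, G2; must sum to 1.
#' @param dapi_mean named means of total DAPI per stage (a.u.; S ignores the
#'   mean and draws uniformly between the G1 and G2 means).
#' @param dapi_cv coefficient of variation of DAPI per stage.
#' @param edu_mean,edu_cv mean EdU intensity and CV per stage; only S is
#'   elevated above background.
#' @param ptm_enrichment per-stage PTM level relative to DNA content
#'   (G1 = 1 is the reference).
#' @param ptm_cv lognormal CV of the per-cell PTM/DNA ratio.
#' @param pch_fraction fraction of nuclear DNA residing in PCH (used for the
#'   per-channel PCH sum columns).
#' @param seed integer seed.
#' @return a list of class `SimPopulationConfig`.
#' @export
sim_population_config <- function(n_cells = 2000,
                                  stage_proportions = c(G1 = 0.15, S = 0.70, G2 = 0.15),
                                  dapi_mean = c(G1 = 2, S = 3, G2 = 4),
                                  dapi_cv = c(G1 = 0.05, S = 0, G2 = 0.05),
                                  edu_mean = c(G1 = 100, S = 1000, G2 = 100),
                                  edu_cv = c(G1 = 0.2, S = 0.25, G2 = 0.2),
                                  ptm_enrichment = c(G1 = 1, S = 1, G2 = 1),
                                  ptm_cv = 0.1,
                                  pch_fraction = 0.1,
                                  seed = 1L) {
  if (abs(sum(stage_proportions) - 1) > 1e-9)
    stop("config error: stage_proportions must sum to 1")
  if (any(dapi_cv < 0) || any(edu_cv < 0) || ptm_cv < 0)
    stop("config error: CVs must be >= 0")
  cfg <- list(n_cells = as.integer(n_cells),
              stage_proportions = stage_proportions,
              dapi_mean = dapi_mean, dapi_cv = dapi_cv,
              edu_mean = edu_mean, edu_cv = edu_cv,
              ptm_enrichment = ptm_enrichment, ptm_cv = ptm_cv,
              pch_fraction = pch_fraction, seed = as.integer(seed))
  class(cfg) <- "SimPopulationConfig"
  cfg
}

#' Simulate a high-content per-cell feature table
#'
#' @param cfg a [sim_population_config()].
#' @return data.frame with columns `cell_id`, `stage_true`, `total_dna`,
#'   `mean_edu`, `ptm` (nuclear PTM sum), `ptm_pch`, `dna_pch`.
#' @export
simulate_population_table <- function(cfg) {
  stopifnot(inherits(cfg, "SimPopulationConfig"))
  with_seed(cfg$seed, {
    p <- cfg$stage_proportions[c("G1", "S", "G2")]
    n <- cfg$n_cells
    counts <- floor(n * p)
    rem <- n - sum(counts)
    if (rem > 0) {
      frac <- n * p - counts
      add <- order(frac, decreasing = TRUE)[seq_len(rem)]
      counts[add] <- counts[add] + 1L
    }
    stage <- rep(c("G1", "S", "G2"), times = counts)
    dna <- numeric(n); edu <- numeric(n)
    for (st in c("G1", "S", "G2")) {
      i <- which(stage == st)
      if (st == "S") {
        dna[i] <- stats::runif(length(i), cfg$dapi_mean[["G1"]],
                               cfg$dapi_mean[["G2"]])
        if (cfg$dapi_cv[["S"]] > 0)
          dna[i] <- dna[i] * exp(stats::rnorm(length(i), 0, cfg$dapi_cv[["S"]]))
      } else {
        dna[i] <- stats::rnorm(length(i), cfg$dapi_mean[[st]],
                               cfg$dapi_cv[[st]] * cfg$dapi_mean[[st]])
      }
      edu[i] <- pmax(stats::rnorm(length(i), cfg$edu_mean[[st]],
                                  cfg$edu_cv[[st]] * cfg$edu_mean[[st]]), 0)
    }
    dna <- pmax(dna, 0)
    fac <- cfg$ptm_enrichment[stage]
    ratio_noise <- if (cfg$ptm_cv > 0)
      exp(stats::rnorm(n, 0, sqrt(log(1 + cfg$ptm_cv^2)))) else rep(1, n)
    ptm <- fac * dna * ratio_noise
    data.frame(cell_id = seq_len(n), stage_true = stage,
               total_dna = dna, mean_edu = edu, ptm = ptm,
               ptm_pch = cfg$pch_fraction * ptm,
               dna_pch = cfg$pch_fraction * dna,
               stringsAsFactors = FALSE)
  })
}

#' Configuration for a simulated FRAP trace
#'
#' The default sampling (6 pre-bleach frames, 60 post-bleach frames at 10 s
#' intervals) mirrors a typical confocal bleaching protocol: 1 min before
#' and 10 min after the bleach.
#'
#' @param pre_frames,post_frames frame counts before/after the bleach.
#' @param dt frame interval, seconds.
#' @param tau recovery time constant, seconds.
#' @param mobile_fraction fraction of the bleached deficit that recovers,
#'   in `[0, 1]`.
#' @param bleach_depth normalized intensity immediately after the bleach.
#' @param background camera background level, a.u.
#' @param roi_scale,nucleus_scale pre-bleach raw amplitudes above background.
#' @param acquisition_bleach_rate per-frame fractional loss applied to both
#'   the ROI and the whole-nucleus trace.
#' @param noise_sd Gaussian noise sd on the normalized scale.
#' @param seed integer seed.
#' @return a list of class `SimFrapConfig`.
#' @export
sim_frap_config <- function(pre_frames = 6L, post_frames = 60L, dt = 10,
                            tau = 50, mobile_fraction = 0.6,
                            bleach_depth = 0.2, background = 10,
                            roi_scale = 100, nucleus_scale = 120,
                            acquisition_bleach_rate = 0.001,
                            noise_sd = 0, seed = 1L) {
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("config error: mobile_fraction must be in [0, 1]")
  if (dt <= 0) stop("config error: dt must be > 0")
  cfg <- list(pre_frames = as.integer(pre_frames),
              post_frames = as.integer(post_frames), dt = dt, tau = tau,
              mobile_fraction = mobile_fraction, bleach_depth = bleach_depth,
              background = background, roi_scale = roi_scale,
              nucleus_scale = nucleus_scale,
              acquisition_bleach_rate = acquisition_bleach_rate,
              noise_sd = noise_sd, seed = as.integer(seed))
  class(cfg) <- "SimFrapConfig"
  cfg
}

#' Simulate a raw FRAP trace with known kinetics
#'
#' The bleach occurs at t = 0; pre-bleach frames sit at negative times and
#' the first post-bleach frame at `t = dt`. The underlying normalized ROI
#' signal is `bleach_depth + mobile_fraction * (1 - bleach_depth) *
#' (1 - exp(-t / tau))`; acquisition bleaching multiplies both raw traces,
#' a constant background is added, then noise.
#'
#' @param cfg a [sim_frap_config()].
#' @return list with `curve` (a [frap_curve()]) and `truth`
#'   (tau, mobile_fraction, bleach_depth, plateau).
#' @export
simulate_frap_curve <- function(cfg) {
  stopifnot(inherits(cfg, "SimFrapConfig"))
  with_seed(cfg$seed, {
    t_pre <- -rev(seq_len(cfg$pre_frames)) * cfg$dt
    t_post <- seq_len(cfg$post_frames) * cfg$dt
    tt <- c(t_pre, t_post)
    s <- c(rep(1, cfg$pre_frames),
           cfg$bleach_depth + cfg$mobile_fraction * (1 - cfg$bleach_depth) *
             (1 - exp(-t_post / cfg$tau)))
    decay <- (1 - cfg$acquisition_bleach_rate)^(seq_along(tt) - 1L)
    roi <- cfg$background + cfg$roi_scale * decay * s
    nuc <- cfg$background + cfg$nucleus_scale * decay
    if (cfg$noise_sd > 0)
      roi <- roi + stats::rnorm(length(roi), 0, cfg$noise_sd * cfg$roi_scale)
    curve <- frap_curve(time = tt, roi_mean = roi, nucleus_mean = nuc,
                        background = rep(cfg$background, length(tt)),
                        n_pre = cfg$pre_frames)
    plateau <- cfg$bleach_depth + cfg$mobile_fraction * (1 - cfg$bleach_depth)
    list(curve = curve,
         truth = list(tau = cfg$tau, mobile_fraction = cfg$mobile_fraction,
                      bleach_depth = cfg$bleach_depth, plateau = plateau))
  })
}

#' Simulate a spatially coherent multi-class compaction texture
#'
#' A Gaussian random field is smoothed and quantile-binned into `n_classes`
#' equal-count classes inside an ellipsoidal nucleus, giving a Potts-like
#' label texture; voxel intensities are the class means plus Gaussian noise.
#' Used to benchmark the HMRF compaction classifier against planted labels.
#'
#' @param shape stack dimensions (z, y, x).
#' @param semiaxes nucleus ellipsoid semiaxes, voxels.
#' @param n_classes number of compaction classes.
#' @param class_means intensity means per class, ascending.
#' @param noise_sd Gaussian noise sd (default 10% of the class spacing).
#' @param smooth_sigma correlation length of the label field, voxels.
#' @param spacing voxel spacing (z, y, x) um.
#' @param seed integer seed.
#' @return list: `dna` ([image_stack()]), `labels` (planted class per voxel,
#'   0 outside), `nucleus_mask`, `class_means`.
#' @export
simulate_compaction_texture <- function(shape = c(64, 64, 64),
                                        semiaxes = c(28, 28, 28),
                                        n_classes = 7,
                                        class_means = seq(1000, 4000,
                                                          length.out = n_classes),
                                        noise_sd = NULL,
                                        smooth_sigma = 2.5,
                                        spacing = c(0.1, 0.1, 0.1),
                                        seed = 1L) {
  spacing_cls <- diff(class_means[1:2])
  if (is.null(noise_sd)) noise_sd <- 0.1 * spacing_cls
  with_seed(seed, {
    rho <- ellipsoid_rho(shape, semiaxes)
    nucleus <- rho <= 1
    field <- array(stats::rnorm(prod(shape)), shape)
    k <- gaussian_kernel1d(smooth_sigma)
    for (ax in 1:3) field <- conv_axis(field, k, ax)
    inside <- field[nucleus]
    q <- stats::quantile(inside, probs = seq(0, 1, length.out = n_classes + 1))
    lab_in <- findInterval(inside, q, rightmost.closed = TRUE, all.inside = TRUE)
    labels <- array(0L, shape)
    labels[nucleus] <- lab_in
    dna <- array(0, shape)
    dna[nucleus] <- class_means[lab_in] + stats::rnorm(length(lab_in), 0, noise_sd)
    list(dna = image_stack(dna, spacing, "DNA"), labels = labels,
         nucleus_mask = nucleus, class_means = class_means)
  })
}

#' Simulate a field of isolated 3D Gaussian spots
#'
#' Spots are placed on a jittered grid with a guaranteed minimum spacing,
#' on a flat background with Gaussian noise; used to benchmark spot
#' detection precision/recall against the planted centers.
#'
#' @param n_spots number of spots.
#' @param spacing_vox minimum center-to-center spacing, voxels.
#' @param amplitude spot peak amplitude above background, a.u.
#' @param sigma spot Gaussian width, voxels.
#' @param background flat background level, a.u.
#' @param noise_sd additive Gaussian noise sd (amplitude / noise_sd is the
#'   spot SNR).
#' @param spacing voxel spacing (z, y, x) um.
#' @param seed integer seed.
#' @return list: `stack` ([image_stack()]), `centers` (matrix z,y,x),
#'   `mask` (all-TRUE region of interest).
#' @export
simulate_spot_field <- function(n_spots = 200, spacing_vox = 8,
                                amplitude = 500, sigma = 1.5,
                                background = 100, noise_sd = 100,
                                spacing = c(0.2, 0.1, 0.1), seed = 1L) {
  with_seed(seed, {
    margin <- ceiling(3 * sigma) + 2L
    per_axis <- ceiling(n_spots^(1 / 3))
    # grid large enough for n_spots sites
    while (per_axis^3 < n_spots) per_axis <- per_axis + 1L
    d <- rep(per_axis * spacing_vox + 2L * margin, 3L)
    sites <- as.matrix(expand.grid(z = seq_len(per_axis), y = seq_len(per_axis),
                                   x = seq_len(per_axis)))
    sites <- sites[sample(nrow(sites), n_spots), , drop = FALSE]
    centers <- margin + (sites - 0.5) * spacing_vox +
      matrix(stats::runif(3 * n_spots, -1, 1), ncol = 3)
    v <- array(background, dim = d)
    for (i in seq_len(n_spots))
      v <- add_gaussian_blob(v, centers[i, ], sigma, amplitude)
    if (noise_sd > 0)
      v <- pmax(v + array(stats::rnorm(prod(d), 0, noise_sd), d), 0)
    colnames(centers) <- c("z", "y", "x")
    list(stack = image_stack(v, spacing, "spots"), centers = centers,
         mask = array(TRUE, dim = d))
  })
}
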