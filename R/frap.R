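# FRAP trace normalization, replicate averaging and single-exponential
# recovery fitting.

#' FRAP trace container
#'
#' Time-resolved mean intensities of the bleached region, the whole
#' nucleus and the background, with the bleach at t = 0 (pre-bleach frames
#' at negative times).
#'
#' @param time frame times in seconds, strictly increasing.
#' @param roi_mean,nucleus_mean,background per-frame mean intensities
#'   (a.u.); `background` may be a scalar (constant) or per-frame vector.
#' @param n_pre number of pre-bleach frames (>= 1).
#' @param normalized optional precomputed normalized trace.
#' @return object of class `FrapCurve`.
#' @export
frap_curve <- function(time, roi_mean, nucleus_mean, background = 0,
                       n_pre = sum(time < 0), normalized = NULL) {
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (n_pre < 1L) stop("at least one pre-bleach frame required")
  n <- length(time)
  if (length(background) == 1L) background <- rep(background, n)
  stopifnot(length(roi_mean) == n, length(nucleus_mean) == n,
            length(background) == n)
  structure(list(time = time, roi_mean = roi_mean,
                 nucleus_mean = nucleus_mean, background = background,
                 n_pre = as.integer(n_pre), normalized = normalized),
            class = "FrapCurve")
}

#' Read FRAP traces from CSV
#'
#' Expected columns: `time_s`, `roi_mean`, `nucleus_mean`, and optionally
#' `background` (constant 0 assumed otherwise).
#'
#' @param path CSV file.
#' @return a [frap_curve()].
#' @export
read_frap_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "roi_mean", "nucleus_mean") %in% names(d)))
  bg <- if ("background" %in% names(d)) d$background else 0
  frap_curve(d$time_s, d$roi_mean, d$nucleus_mean, bg)
}

#' Double-normalize a FRAP trace
#'
#' The background-corrected ROI mean is divided by the background-corrected
#' whole-nucleus mean (correcting acquisition bleaching), and the result is
#' divided by its pre-bleach mean so that the pre-bleach level is 1.
#' Normalizing an already-normalized curve is the identity.
#'
#' @param curve a [frap_curve()].
#' @return the curve with `normalized` filled.
#' @export
normalize_frap <- function(curve) {
  nuc <- curve$nucleus_mean - curve$background
  if (any(nuc <= 0))
    stop("whole-nucleus intensity does not exceed background at every frame")
  r <- (curve$roi_mean - curve$background) / nuc
  pre <- mean(r[seq_len(curve$n_pre)])
  if (pre <= 0) stop("non-positive pre-bleach level")
  curve$normalized <- r / pre
  curve
}

#' Average normalized FRAP curves across replicates
#'
#' Curves are aligned on the first curve's time grid (linear interpolation
#' where grids differ) and averaged pointwise; the SEM is reported per time
#' point. Fits are meant to be performed on this averaged curve.
#'
#' @param curves list of normalized [frap_curve()]s.
#' @return a [frap_curve()] whose `normalized` is the pointwise mean, with
#'   attributes `sem` (per-frame standard error; NA with a warning for a
#'   single curve) and `n_curves`.
#' @export
average_curves <- function(curves) {
  if (length(curves) == 0L) stop("no curves")
  curves <- lapply(curves, function(cv)
    if (is.null(cv$normalized)) normalize_frap(cv) else cv)
  ref <- curves[[1]]
  mat <- vapply(curves, function(cv) {
    if (isTRUE(all.equal(cv$time, ref$time))) cv$normalized
    else stats::approx(cv$time, cv$normalized, xout = ref$time, rule = 2)$y
  }, numeric(length(ref$time)))
  mat <- matrix(mat, nrow = length(ref$time))
  out <- ref
  out$normalized <- rowMeans(mat)
  if (ncol(mat) < 2L) {
    warning("SEM undefined for fewer than 2 curves")
    sem <- rep(NA_real_, nrow(mat))
  } else {
    sem <- apply(mat, 1, stats::sd) / sqrt(ncol(mat))
  }
  attr(out, "sem") <- sem
  attr(out, "n_curves") <- ncol(mat)
  out
}

#' Fit a single-exponential recovery to a normalized FRAP curve
#'
#' Model: `I(t) = Iinf - (Iinf - I0) * exp(-t / tau)` for post-bleach
#' times t > 0 (the bleach frame itself is excluded; t is measured from
#' the bleach). Nonlinear least squares with data-driven starting values:
#' I0 from the first post-bleach point, Iinf from the mean of the last 10%
#' of frames, tau from the time to half recovery.
#'
#' @param curve a normalized [frap_curve()] (normalization is applied if
#'   missing).
#' @return object of class `FrapFit`: `bleach_depth` (I0), `plateau`
#'   (Iinf), `tau` (s), `mobile_fraction` `(Iinf - I0) / (1 - I0)`,
#'   `halftime` `tau * log(2)`, `converged`, `fit` (the nls object).
#' @export
fit_exponential_recovery <- function(curve) {
  if (is.null(curve$normalized)) curve <- normalize_frap(curve)
  post <- curve$time > 0
  tt <- curve$time[post]
  yy <- curve$normalized[post]
  if (length(tt) < 4L) stop("too few post-bleach frames to fit")
  I0_start <- yy[1]
  Iinf_start <- mean(utils::tail(yy, max(2L, ceiling(0.1 * length(yy)))))
  half_level <- (I0_start + Iinf_start) / 2
  t_half <- tt[which(yy >= half_level)[1]]
  if (is.na(t_half) || t_half <= 0) t_half <- stats::median(tt) / 4
  tau_start <- max(t_half / log(2), min(diff(tt)) / 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ Iinf - (Iinf - I0) * exp(-tt / tau),
                      start = list(I0 = I0_start, Iinf = Iinf_start,
                                   tau = tau_start),
                      lower = c(I0 = -Inf, Iinf = -Inf, tau = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(bleach_depth = NA_real_, plateau = NA_real_,
                          tau = NA_real_, mobile_fraction = NA_real_,
                          halftime = NA_real_, converged = FALSE, fit = NULL),
                     class = "FrapFit"))
  }
  p <- stats::coef(fit)
  conv <- isTRUE(fit$convInfo$isConv) && p[["tau"]] > 2e-6 &&
    p[["tau"]] < 100 * max(tt)
  structure(list(bleach_depth = p[["I0"]], plateau = p[["Iinf"]],
                 tau = p[["tau"]],
                 mobile_fraction = (p[["Iinf"]] - p[["I0"]]) / (1 - p[["I0"]]),
                 halftime = p[["tau"]] * log(2),
                 converged = conv, fit = fit),
            class = "FrapFit")
}

#' @export
print.FrapFit <- function(x, ...) {
  cat(sprintf(paste0("FRAP fit: I0 = %.3f, plateau = %.3f, tau = %.1f s, ",
                     "mobile fraction = %.3f, t1/2 = %.1f s%s\n"),
              x$bleach_depth, x$plateau, x$tau, x$mobile_fraction, x$halftime,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}
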