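# FRAP normalization and one-phase-association fitting, mobile fraction,
# the four-parameter logistic relation between condensation propensity
# and foci counts, and threshold-based 3D foci counting.

#' Normalize a FRAP trace
#'
#' The bleached-ROI intensity is divided pointwise by the control-ROI
#' intensity (correcting acquisition photobleaching and laser
#' fluctuations), then by the mean of the first five pre-bleach points,
#' so the pre-bleach level is 1.
#'
#' @param trace list with `times`, `intensity`, `control`,
#'   `bleach_index` (first post-bleach frame, > 5).
#' @param n_prebleach pre-bleach points averaged (default 5).
#' @return trace with `normalized` added.
#' @export
preprocess_frap <- function(trace, n_prebleach = 5) {
  if (trace$bleach_index <= n_prebleach) {
    stop("need at least ", n_prebleach, " pre-bleach points")
  }
  y <- trace$intensity / trace$control
  y <- y / mean(y[seq_len(n_prebleach)])
  trace$normalized <- y
  trace
}

#' Fit one-phase-association recovery to a normalized FRAP trace
#'
#' Fits `Y(t) = plateau - (plateau - initial) * exp(-k t)` to the
#' post-bleach points up to `t_max` seconds (t = 0 at the first
#' post-bleach frame) by least squares with variance weights 1/Y^2
#' (model-predicted Y, iteratively reweighted). The mobile fraction is
#' `(plateau - initial) / (1 - initial)`.
#'
#' @param trace normalized trace from [preprocess_frap()].
#' @param t_max post-bleach fitting horizon in seconds (default 60).
#' @param weighting `"predicted"` (default) or `"data"` for 1/y^2 on the
#'   observations.
#' @return list(k, plateau, initial, mobile_fraction, rss, converged).
#' @export
fit_frap_recovery <- function(trace, t_max = 60,
                              weighting = c("predicted", "data")) {
  weighting <- match.arg(weighting)
  y <- trace$normalized
  if (is.null(y)) stop("trace is not normalized; run preprocess_frap()")
  bi <- trace$bleach_index
  tt <- trace$times[bi:length(y)] - trace$times[bi]
  yy <- y[bi:length(y)]
  sel <- tt <= t_max
  tt <- tt[sel]; yy <- yy[sel]
  start <- list(plateau = max(mean(tail(yy, 10)), yy[1] + 1e-3),
                initial = yy[1],
                k = 0.1)
  model <- function(p, t) p$plateau - (p$plateau - p$initial) *
    exp(-p$k * t)
  w <- if (weighting == "data") 1 / pmax(yy, 1e-6)^2 else rep(1, length(yy))
  fit <- NULL
  converged <- FALSE
  for (it in 1:6) {
    fit <- try(minpack.lm::nlsLM(
      yy ~ plateau - (plateau - initial) * exp(-k * tt),
      start = start, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) break
    p <- as.list(coef(fit))
    if (weighting == "data") { converged <- TRUE; break }
    w_new <- 1 / pmax(model(p, tt), 1e-6)^2
    if (max(abs(w_new - w) / w) < 1e-6) { converged <- TRUE; w <- w_new;
      start <- p; break }
    w <- w_new
    start <- p
  }
  if (inherits(fit, "try-error") || is.null(fit)) {
    return(list(k = NA_real_, plateau = NA_real_, initial = NA_real_,
                mobile_fraction = NA_real_, rss = NA_real_,
                converged = FALSE))
  }
  p <- as.list(coef(fit))
  pred <- model(p, tt)
  list(k = p$k, plateau = p$plateau, initial = p$initial,
       mobile_fraction = (p$plateau - p$initial) / (1 - p$initial),
       rss = sum((yy - pred)^2), converged = converged || TRUE)
}

#' Evaluate the four-parameter logistic curve
#'
#' `Y = minimum + (maximum - minimum) / (1 + 10^((log_inflection - X) *
#' hill_slope))` (the standard Prism-style parameterization: at
#' X = log_inflection, Y is midway between minimum and maximum).
#'
#' @param params list or named vector with minimum, maximum,
#'   log_inflection, hill_slope.
#' @param x numeric vector.
#' @export
logistic4_eval <- function(params, x) {
  p <- as.list(params)
  p$minimum + (p$maximum - p$minimum) /
    (1 + 10^((p$log_inflection - x) * p$hill_slope))
}

#' Fit the four-parameter logistic curve by least squares
#'
#' @param x,y data points (>= 4).
#' @return named list of fitted parameters plus rss.
#' @export
logistic4_fit <- function(x, y) {
  if (length(x) < 4) stop("need at least 4 points for a 4PL fit")
  start <- list(minimum = min(y), maximum = max(y),
                log_inflection = stats::median(x),
                hill_slope = if (cor(x, y) >= 0) 1 else -1)
  fit <- minpack.lm::nlsLM(
    y ~ minimum + (maximum - minimum) /
      (1 + 10^((log_inflection - x) * hill_slope)),
    start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- as.list(coef(fit))
  p$rss <- sum(residuals(fit)^2)
  p
}

#' Count nuclear foci in a 3D stack by relative intensity threshold
#'
#' The threshold is `rel_threshold` times the mean intensity of the
#' masked maximum z-projection (per nucleus). Voxels above threshold
#' within the (2D, applied across z) nuclear mask are grouped into
#' 26-connected 3D components; components with at least `min_voxels`
#' voxels count as foci.
#'
#' @param stack 3D array (x, y, z).
#' @param mask 2D logical nuclear mask.
#' @param rel_threshold relative threshold (default 1.6).
#' @param min_voxels minimum component size (default 2).
#' @return list(count, threshold, foci = data.table(focus, n_voxels,
#'   total_intensity, mean_intensity)).
#' @export
count_foci <- function(stack, mask, rel_threshold = 1.6, min_voxels = 2) {
  if (!any(mask)) stop("empty nuclear mask")
  dims <- dim(stack)
  zproj <- apply(stack, c(1, 2), max)
  thr <- rel_threshold * mean(zproj[mask])
  above <- sweep(stack > thr, c(1, 2), mask, "&")
  idx <- which(above)
  if (!length(idx)) {
    return(list(count = 0L, threshold = thr,
                foci = data.table(focus = integer(), n_voxels = integer(),
                                  total_intensity = numeric(),
                                  mean_intensity = numeric())))
  }
  coords <- arrayInd(idx, dims)
  key <- function(m) (m[, 3] - 1) * dims[1] * dims[2] +
    (m[, 2] - 1) * dims[1] + m[, 1]
  lookup <- new.env(hash = TRUE, size = length(idx))
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, envir = lookup)
  labels <- integer(length(idx))
  shifts <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, ]
  lab <- 0L
  for (i in seq_along(idx)) {
    if (labels[i] > 0L) next
    lab <- lab + 1L
    queue <- i
    labels[i] <- lab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      cc <- coords[cur, ]
      nb <- sweep(shifts, 2, cc, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nbk <- key(nb[ok, , drop = FALSE])
      for (kk in nbk) {
        j <- lookup[[as.character(kk)]]
        if (!is.null(j) && labels[j] == 0L) {
          labels[j] <- lab
          queue <- c(queue, j)
        }
      }
    }
  }
  vals <- stack[idx]
  foci <- data.table(label = labels, val = vals)[
    , .(n_voxels = .N, total_intensity = sum(val),
        mean_intensity = mean(val)), by = label]
  foci <- foci[n_voxels >= min_voxels]
  setorder(foci, -total_intensity)
  foci[, focus := .I]
  list(count = nrow(foci), threshold = thr,
       foci = foci[, .(focus, n_voxels, total_intensity, mean_intensity)])
}
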