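#' Detect candidate spots in a frame
#'
#' Applies a difference-of-Gaussians bandpass (sd `band_low_px` minus sd
#' `band_high_px`), then keeps local maxima of the bandpassed image above a
#' fixed intensity threshold, with a minimum separation of 2 px (the brighter
#' of two closer candidates is kept).
#'
#' @param frame Numeric matrix of camera counts (rows = y, columns = x).
#' @param band_low_px Small Gaussian sd in pixels (default 1).
#' @param band_high_px Large Gaussian sd in pixels (default 3).
#' @param intensity_threshold Fixed threshold on the bandpassed image, in
#'   counts. `NULL` picks median + 5 MAD of the bandpassed frame.
#' @return Data frame `x_px, y_px, value` of candidate pixel positions
#'   (0-based pixel coordinates, x = column), brightest first. A flat frame
#'   yields zero rows.
#' @export
detect_candidates <- function(frame, band_low_px = 1, band_high_px = 3,
                              intensity_threshold = NULL) {
  if (band_low_px >= band_high_px)
    stop("band_low_px must be < band_high_px", call. = FALSE)
  frame <- as.matrix(frame)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0), value = numeric(0))
  if (max(frame) == min(frame)) return(empty)

  bp <- gaussian_blur(frame, band_low_px) - gaussian_blur(frame, band_high_px)
  if (is.null(intensity_threshold))
    intensity_threshold <- stats::median(bp) + 5 * stats::mad(bp)
  if (!is.finite(intensity_threshold)) return(empty)

  mx <- local_maxima(bp)
  keep <- which(mx & bp > intensity_threshold, arr.ind = TRUE)
  if (nrow(keep) == 0) return(empty)
  cand <- data.frame(x_px = keep[, 2] - 1, y_px = keep[, 1] - 1,
                     value = bp[keep])
  cand <- cand[order(-cand$value), , drop = FALSE]
  # merge candidates closer than 2 px into the brighter one
  sel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { sel[1] <- TRUE; next }
    prev <- cand[sel, , drop = FALSE]
    d2 <- (prev$x_px - cand$x_px[i])^2 + (prev$y_px - cand$y_px[i])^2
    sel[i] <- all(d2 >= 4)
  }
  out <- cand[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

gaussian_blur <- function(m, sigma) {
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  brush <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
  EBImage::filter2(m, brush, boundary = "replicate")
}

# TRUE where a pixel is the strict maximum of its 3x3 neighbourhood
# (ties resolved toward the top-left for determinism)
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  res <- matrix(TRUE, nr, nc)
  first <- TRUE
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
    # strict on later neighbours, non-strict on earlier ones breaks plateaus
    if (di < 0 || (di == 0 && dj < 0)) res <- res & (m > nb) else res <- res & (m >= nb)
  }
  res
}

#' Fit a 2D elliptical Gaussian to a candidate spot
#'
#' Least-squares fit of an elliptical Gaussian plus constant background on a
#' square window around the initial guess. Free parameters: x/y position,
#' x/y width, elliptical rotation angle, amplitude, background. Positions and
#' widths are converted to um via the pixel size; the photon estimate is
#' `2*pi*amplitude*width_x*width_y / (pixel_size^2 * em_gain)`.
#'
#' @param frame Numeric matrix of counts.
#' @param guess Length-2 numeric, 0-based pixel position (x = column, y = row).
#' @param window_px Odd window size in pixels (default 9, i.e. >= 6 PSF sd).
#' @param config An [imaging_config()] (pixel size, EM gain).
#' @return One-row data.frame: `x_um, y_um, wx_um, wy_um, theta_rad,
#'   amplitude, background, photons, fit_ok`. `fit_ok = FALSE` flags
#'   non-convergence, degenerate data, non-finite pixels, or a center outside
#'   the window.
#' @export
fit_spot <- function(frame, guess, window_px = 9, config = imaging_config()) {
  px <- config$pixel_size
  half <- window_px %/% 2
  cx <- as.integer(round(guess[1])); cy <- as.integer(round(guess[2]))
  bad <- data.frame(x_um = NA_real_, y_um = NA_real_, wx_um = NA_real_,
                    wy_um = NA_real_, theta_rad = NA_real_,
                    amplitude = NA_real_, background = NA_real_,
                    photons = NA_real_, fit_ok = FALSE)
  if (cx - half < 0 || cy - half < 0 ||
      cx + half > ncol(frame) - 1 || cy + half > nrow(frame) - 1)
    stop("fit window not fully inside frame", call. = FALSE)
  w <- frame[(cy - half):(cy + half) + 1, (cx - half):(cx + half) + 1]
  if (any(!is.finite(w))) return(bad)
  if (max(w) == min(w)) return(bad)

  xs <- (cx - half):(cx + half)     # 0-based pixel coords of window columns
  ys <- (cy - half):(cy + half)
  gx <- matrix(rep(xs, each = length(ys)), length(ys))
  gy <- matrix(rep(ys, times = length(xs)), length(ys))

  bg0 <- min(w); a0 <- max(w) - bg0
  wt <- pmax(w - bg0, 0)
  x0 <- sum(gx * wt) / sum(wt); y0 <- sum(gy * wt) / sum(wt)
  s0 <- max(config$psf_sigma / px, 0.8)

  model <- function(p) {
    th <- p[5]
    u <- cos(th) * (gx - p[1]) + sin(th) * (gy - p[2])
    v <- -sin(th) * (gx - p[1]) + cos(th) * (gy - p[2])
    p[6] * exp(-0.5 * (u^2 / p[3]^2 + v^2 / p[4]^2)) + p[7]
  }
  res_fn <- function(p) as.vector(w - model(p))
  fit <- try(minpack.lm::nls.lm(
    par = c(x0, y0, s0, s0, 0, a0, bg0), fn = res_fn,
    lower = c(min(xs) - 1, min(ys) - 1, 0.3, 0.3, -pi, 0, -Inf),
    upper = c(max(xs) + 1, max(ys) + 1, window_px, window_px, pi, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(bad)
  p <- fit$par
  ok <- fit$info %in% 1:4 && p[6] > 0 &&
    p[1] >= min(xs) && p[1] <= max(xs) && p[2] >= min(ys) && p[2] <= max(ys)

  # canonicalize: symmetric spots report angle 0; wrap to (-pi/2, pi/2]
  th <- atan2(sin(p[5]), cos(p[5]))
  if (th > pi / 2) th <- th - pi
  if (th <= -pi / 2) th <- th + pi
  if (abs(p[3] - p[4]) < 1e-3 * max(p[3], p[4])) th <- 0

  photons <- 2 * pi * p[6] * (p[3] * px) * (p[4] * px) /
    (px^2 * config$em_gain)
  data.frame(x_um = p[1] * px, y_um = p[2] * px,
             wx_um = p[3] * px, wy_um = p[4] * px, theta_rad = th,
             amplitude = p[6], background = p[7],
             photons = max(photons, 0), fit_ok = ok)
}

#' Localize all spots in a movie
#'
#' Runs [detect_candidates()] and [fit_spot()] on every frame and collects a
#' localization table. The first `skip_frames` frames can be discarded
#' (pre-bleaching of the field of view before acquisition).
#'
#' @param movie An `spt_movie`, or a list of count matrices.
#' @param config An [imaging_config()].
#' @param window_px Fit window (default 9 px).
#' @param skip_frames Frames to discard at the start (default 0).
#' @param keep_failed Keep rows with `fit_ok = FALSE` (default FALSE).
#' @param ... Passed to [detect_candidates()].
#' @return Localization table: `frame, x_um, y_um, wx_um, wy_um, theta_rad,
#'   amplitude, background, photons, fit_ok`.
#' @export
localize_movie <- function(movie, config = imaging_config(), window_px = 9,
                           skip_frames = 0, keep_failed = FALSE, ...) {
  frames <- if (inherits(movie, "spt_movie")) movie$frames else movie
  half <- window_px %/% 2
  out <- list()
  for (f in seq_along(frames)) {
    if (f <= skip_frames) next
    fr <- frames[[f]]
    cand <- detect_candidates(fr, ...)
    if (nrow(cand) == 0) next
    for (i in seq_len(nrow(cand))) {
      # clamp the window inside the frame
      gx <- min(max(cand$x_px[i], half), ncol(fr) - 1 - half)
      gy <- min(max(cand$y_px[i], half), nrow(fr) - 1 - half)
      loc <- fit_spot(fr, c(gx, gy), window_px, config)
      loc$frame <- f
      out[[length(out) + 1L]] <- loc
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                      wx_um = numeric(), wy_um = numeric(),
                      theta_rad = numeric(), amplitude = numeric(),
                      background = numeric(), photons = numeric(),
                      fit_ok = logical()))
  tab <- do.call(rbind, out)
  if (!keep_failed) tab <- tab[tab$fit_ok, , drop = FALSE]
  rownames(tab) <- NULL
  tab[, c("frame", "x_um", "y_um", "wx_um", "wy_um", "theta_rad",
          "amplitude", "background", "photons", "fit_ok")]
}
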