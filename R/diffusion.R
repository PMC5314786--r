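#' Time-averaged mean-squared displacement of a trajectory
#'
#' MSD at lag k is averaged over all pairs of localizations whose frame
#' indices differ by exactly k; pairs spanning a missing frame at other lags
#' are simply absent, so gaps are excluded naturally.
#'
#' @param trajectory Data frame with columns `frame`, `x_um`, `y_um`.
#' @param max_lag Maximum lag in frames (default 10). Lags beyond the
#'   trajectory span are dropped with a warning.
#' @param dt Frame interval in seconds.
#' @return An `msd_curve` data.frame: `lag_s`, `msd`, `se`, `n_pairs`.
#' @export
msd <- function(trajectory, max_lag = 10, dt = 0.005) {
  if (nrow(trajectory) < 2)
    stop("trajectory needs at least 2 localizations", call. = FALSE)
  fr <- trajectory$frame
  span <- max(fr) - min(fr)
  if (max_lag > span) {
    warning("max_lag exceeds trajectory span; truncated", call. = FALSE)
    max_lag <- span
  }
  out <- lapply(seq_len(max_lag), function(k) {
    i <- match(fr + k, fr)
    ok <- !is.na(i)
    if (!any(ok)) return(NULL)
    sq <- (trajectory$x_um[i[ok]] - trajectory$x_um[ok])^2 +
      (trajectory$y_um[i[ok]] - trajectory$y_um[ok])^2
    data.frame(lag_s = k * dt, msd = mean(sq),
               se = stats::sd(sq) / sqrt(length(sq)), n_pairs = length(sq))
  })
  res <- do.call(rbind, out)
  class(res) <- c("msd_curve", "data.frame")
  res
}

#' Apparent diffusion coefficient from truncated trajectory MSD
#'
#' For each trajectory, the apparent diffusion coefficient is estimated from
#' the first `n_steps` single-frame steps:
#' `D_app = sum(dx_k^2 + dy_k^2) / (4 * n_steps * dt)`.
#' Steps bridging a gap are excluded from both the sum and the count, and
#' trajectories with fewer than `n_steps` valid steps are excluded (their ids
#' are reported in the `excluded` attribute).
#'
#' @param tracks An `spt_tracks` data frame (or any data frame with
#'   `traj_id`, `frame`, `x_um`, `y_um`).
#' @param n_steps Number of single-frame steps used (default 4).
#' @param dt Frame interval in seconds.
#' @param mobility_threshold Slow/fast boundary in um^2/s (default 1):
#'   trajectories with `D_app < mobility_threshold` are labelled `"slow"`.
#' @return Data frame `traj_id, D_app, n_steps, class` with attribute
#'   `excluded` (trajectory ids with too few steps).
#' @examples
#' tr <- data.frame(traj_id = 1, frame = 1:5,
#'                  x_um = c(0, .1264911, 0, .1264911, 0) ,
#'                  y_um = 0)
#' apparent_D(tr, dt = 0.005)  # each squared step 0.016 -> D_app = 0.8
#' @export
apparent_D <- function(tracks, n_steps = 4, dt = 0.005, mobility_threshold = 1) {
  parts <- split(as.data.frame(tracks), tracks$traj_id)
  res <- vector("list", length(parts)); excl <- c()
  for (nm in names(parts)) {
    tr <- parts[[nm]]
    tr <- tr[order(tr$frame), , drop = FALSE]
    dfr <- diff(tr$frame)
    ok <- which(dfr == 1L)
    if (length(ok) < n_steps) { excl <- c(excl, nm); next }
    use <- ok[seq_len(n_steps)]
    sq <- (tr$x_um[use + 1L] - tr$x_um[use])^2 +
      (tr$y_um[use + 1L] - tr$y_um[use])^2
    res[[nm]] <- data.frame(traj_id = tr$traj_id[1],
                            D_app = sum(sq) / (4 * n_steps * dt),
                            n_steps = n_steps)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(traj_id = integer(), D_app = numeric(),
                                      n_steps = integer())
  out$class <- ifelse(out$D_app < mobility_threshold, "slow", "fast")
  rownames(out) <- NULL
  attr(out, "excluded") <- excl
  out
}

#' Localization precision from the fixed-cell apparent diffusion coefficient
#'
#' In a fixed-cell control all apparent motion is localization noise, so the
#' mean apparent diffusion coefficient obeys `D_fixed = sigma^2 / (4*dt)`,
#' giving `sigma = sqrt(4 * D_fixed * dt)`. Under this convention the
#' per-axis single-localization error is `s = sigma / 2`.
#'
#' @param D_fixed Mean apparent D of the fixed-cell control, um^2/s (>= 0).
#' @param dt Frame interval, s.
#' @return Named list with `sigma` (um) and `s_axis = sigma/2` (um).
#' @examples
#' precision_from_fixed(0.32, 0.005)$sigma  # 0.08 um
#' @export
precision_from_fixed <- function(D_fixed, dt) {
  if (D_fixed < 0 || dt < 0) stop("inputs must be >= 0", call. = FALSE)
  sigma <- sqrt(4 * D_fixed * dt)
  list(sigma = sigma, s_axis = sigma / 2)
}

#' Extract single-frame squared displacements from tracks
#'
#' Helper feeding [fit_cdf()]: squared displacements of all steps between
#' consecutive frames (gap-bridging steps excluded).
#'
#' @param tracks An `spt_tracks` data frame.
#' @return Numeric vector of squared displacements in um^2.
#' @export
squared_displacements <- function(tracks) {
  parts <- split(as.data.frame(tracks), tracks$traj_id)
  unlist(lapply(parts, function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    i <- which(diff(tr$frame) == 1L)
    (tr$x_um[i + 1L] - tr$x_um[i])^2 + (tr$y_um[i + 1L] - tr$y_um[i])^2
  }), use.names = FALSE)
}
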