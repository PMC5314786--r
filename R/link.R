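#' Link localizations into trajectories
#'
#' Frame-to-frame linking with a fixed displacement window and short memory:
#' localizations in consecutive frames within `max_link_distance` are linked
#' by the optimal bipartite assignment (maximum number of links, then minimum
#' total squared displacement, ties broken by lower localization index); a
#' track whose spot disappears persists for `memory_frames` frames, and a
#' displacement bridging a one-frame gap must satisfy
#' `max_link_distance * gap_distance_factor`.
#'
#' If a `cell_id` column is present, linking is performed independently per
#' cell.
#'
#' @param localizations Data frame with columns `frame`, `x_um`, `y_um` and
#'   optionally `cell_id`.
#' @param config A [tracking_config()].
#' @return Data frame of class `spt_tracks` with columns `traj_id, frame,
#'   x_um, y_um, gap_flag, cell_id`; every input localization appears in
#'   exactly one trajectory.
#' @export
link <- function(localizations, config = tracking_config()) {
  cols <- c("frame", "x_um", "y_um")
  empty <- data.frame(traj_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric(),
                      gap_flag = logical(), cell_id = integer())
  class(empty) <- c("spt_tracks", "data.frame")
  if (is.null(localizations) || nrow(localizations) == 0) return(empty)
  stopifnot(all(cols %in% names(localizations)))

  if (!is.null(localizations$cell_id)) {
    parts <- split(localizations, localizations$cell_id)
    offset <- 0L
    out <- lapply(parts, function(p) {
      tr <- link_one_field(p, config)
      if (nrow(tr)) {
        tr$traj_id <- tr$traj_id + offset
        tr$cell_id <- p$cell_id[1]
        offset <<- max(tr$traj_id)
      }
      tr
    })
    res <- do.call(rbind, out)
  } else {
    res <- link_one_field(localizations, config)
    res$cell_id <- NA_integer_
  }
  rownames(res) <- NULL
  class(res) <- c("spt_tracks", "data.frame")
  res
}

link_one_field <- function(loc, config) {
  loc <- loc[order(loc$frame), , drop = FALSE]
  frames <- sort(unique(loc$frame))
  # active track state
  track_last_x <- numeric(0); track_last_y <- numeric(0)
  track_last_frame <- integer(0); track_id <- integer(0)
  next_id <- 1L
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    det <- loc[loc$frame == f, , drop = FALSE]
    nd <- nrow(det)
    active <- which(track_last_frame >= f - 1L - config$memory_frames &
                      track_last_frame < f)
    # admissible (track, detection) pairs
    edges <- NULL
    if (length(active) && nd) {
      lag <- f - track_last_frame[active]
      lim <- ifelse(lag > 1, config$max_link_distance * config$gap_distance_factor,
                    config$max_link_distance)
      d2 <- matrix(0, length(active), nd)
      for (i in seq_along(active)) {
        d2[i, ] <- (track_last_x[active[i]] - det$x_um)^2 +
          (track_last_y[active[i]] - det$y_um)^2
      }
      adm <- d2 <= (lim^2)
      if (any(adm)) edges <- list(d2 = d2, adm = adm)
    }
    assign_det <- rep(NA_integer_, nd)   # detection -> active-track index
    if (!is.null(edges)) {
      m <- match_bipartite(edges$d2, edges$adm)
      assign_det <- m
    }
    for (j in seq_len(nd)) {
      if (!is.na(assign_det[j])) {
        ti <- active[assign_det[j]]
        gap <- (f - track_last_frame[ti]) > 1L
        rows[[fi]] <- rbind(rows[[fi]], data.frame(
          traj_id = track_id[ti], frame = f, x_um = det$x_um[j],
          y_um = det$y_um[j], gap_flag = gap))
        track_last_x[ti] <- det$x_um[j]; track_last_y[ti] <- det$y_um[j]
        track_last_frame[ti] <- f
      } else {
        track_last_x <- c(track_last_x, det$x_um[j])
        track_last_y <- c(track_last_y, det$y_um[j])
        track_last_frame <- c(track_last_frame, f)
        track_id <- c(track_id, next_id)
        rows[[fi]] <- rbind(rows[[fi]], data.frame(
          traj_id = next_id, frame = f, x_um = det$x_um[j],
          y_um = det$y_um[j], gap_flag = FALSE))
        next_id <- next_id + 1L
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(traj_id = integer(), frame = integer(),
                                      x_um = numeric(), y_um = numeric(),
                                      gap_flag = logical())
  out <- out[order(out$traj_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Optimal assignment of detections (columns) to tracks (rows) over the
# admissible edges: maximum number of links, then minimum total squared
# displacement, ties broken toward lower indices. Solved exactly by
# enumeration within connected components (fields are sparse); components
# with too many edges fall back to greedy nearest-neighbour.
match_bipartite <- function(d2, adm, max_edges = 24L) {
  nt <- nrow(d2); nd <- ncol(d2)
  assign_det <- rep(NA_integer_, nd)
  # connected components over the bipartite admissibility graph
  comp_t <- rep(0L, nt); comp_d <- rep(0L, nd); nc <- 0L
  for (i in seq_len(nt)) {
    if (comp_t[i] || !any(adm[i, ])) next
    nc <- nc + 1L
    qt <- i
    while (length(qt)) {
      ti <- qt[1]; qt <- qt[-1]
      if (comp_t[ti]) next
      comp_t[ti] <- nc
      for (j in which(adm[ti, ])) {
        if (!comp_d[j]) {
          comp_d[j] <- nc
          qt <- c(qt, which(adm[, j] & comp_t == 0L))
        }
      }
    }
  }
  for (cc in seq_len(nc)) {
    ts <- which(comp_t == cc); ds <- which(comp_d == cc)
    sub_adm <- adm[ts, ds, drop = FALSE]
    if (sum(sub_adm) > max_edges) {
      # greedy fallback: repeatedly take the globally smallest admissible d2
      sub_d2 <- d2[ts, ds, drop = FALSE]
      repeat {
        sub_d2[!sub_adm] <- Inf
        if (all(!is.finite(sub_d2))) break
        k <- which(sub_d2 == min(sub_d2), arr.ind = TRUE)[1, , drop = TRUE]
        assign_det[ds[k[2]]] <- ts[k[1]]
        sub_adm[k[1], ] <- FALSE; sub_adm[, k[2]] <- FALSE
      }
    } else {
      best <- best_matching(d2[ts, ds, drop = FALSE], sub_adm)
      for (j in seq_along(ds)) if (!is.na(best[j])) assign_det[ds[j]] <- ts[best[j]]
    }
  }
  assign_det
}

# exact search over matchings in a small component
best_matching <- function(d2, adm) {
  nt <- nrow(d2); nd <- ncol(d2)
  best <- list(size = -1L, cost = Inf, m = rep(NA_integer_, nd))
  recurse <- function(j, used_t, m, size, cost) {
    if (j > nd) {
      if (size > best$size || (size == best$size && cost < best$cost - 1e-12))
        best <<- list(size = size, cost = cost, m = m)
      return(invisible())
    }
    # option: leave detection j unmatched
    recurse(j + 1L, used_t, m, size, cost)
    for (i in seq_len(nt)) {
      if (adm[i, j] && !used_t[i]) {
        used_t[i] <- TRUE; m[j] <- i
        recurse(j + 1L, used_t, m, size + 1L, cost + d2[i, j])
        used_t[i] <- FALSE; m[j] <- NA_integer_
      }
    }
  }
  recurse(1L, logical(nt), rep(NA_integer_, nd), 0L, 0)
  best$m
}

#' Closed-form probability that a diffusive step stays inside the linking window
#'
#' For a 2D Gaussian step with per-axis variance `2*D_app*dt + 2*s_axis^2`,
#' the step magnitude is Rayleigh and the probability of falling within the
#' window W is `1 - exp(-W^2 / (4*D_app*dt + 4*s_axis^2))`.
#'
#' @param D_app Apparent diffusion coefficient, um^2/s.
#' @param dt Frame interval, s.
#' @param s_axis Per-axis localization error, um.
#' @param window Linking window, um.
#' @return Probability in `[0, 1]`.
#' @examples
#' link_correctness(4, 0.005, 0, 0.67)  # 0.9963
#' @export
link_correctness <- function(D_app, dt, s_axis, window) {
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  if (any(c(D_app, dt, s_axis) < 0)) stop("arguments must be >= 0", call. = FALSE)
  v <- 4 * D_app * dt + 4 * s_axis^2
  if (v == 0) return(1)
  1 - exp(-window^2 / v)
}

#' Monte-Carlo fraction of steps inside the linking window
#'
#' Draws `n` 2D Gaussian displacements with per-axis variance
#' `2*D_app*dt + 2*s_axis^2` and returns the fraction whose magnitude is at
#' most `window`; the simulation counterpart of [link_correctness()].
#'
#' @inheritParams link_correctness
#' @param n Number of simulated steps.
#' @param seed Optional integer seed.
#' @return List with `fraction`, `se` (binomial standard error) and `n`.
#' @export
link_fraction_mc <- function(D_app, dt, s_axis, window, n = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sd_axis <- sqrt(2 * D_app * dt + 2 * s_axis^2)
  dx <- stats::rnorm(n, sd = sd_axis); dy <- stats::rnorm(n, sd = sd_axis)
  inside <- (dx^2 + dy^2) <= window^2
  p <- mean(inside)
  list(fraction = p, se = sqrt(p * (1 - p) / n), n = n)
}

#' Split a track table into a list of per-trajectory data frames
#' @param tracks An `spt_tracks` data frame.
#' @return Named list of data frames.
#' @export
split_tracks <- function(tracks) split(as.data.frame(tracks), tracks$traj_id)
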