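#' Subtract the post-bleach baseline of a photobleaching trace
#'
#' Cell autofluorescence is estimated from the post-bleach plateau (the last
#' `plateau_frac` of the frames) and subtracted.
#'
#' @param trace Numeric vector, single-cell intensity per area over time.
#' @param plateau_frac Fraction of trailing frames defining the plateau
#'   (default 0.1).
#' @return The baseline-subtracted trace with attributes `baseline` and
#'   `baseline_subtracted = TRUE`.
#' @export
subtract_baseline <- function(trace, plateau_frac = 0.1) {
  n <- length(trace)
  k <- max(1L, floor(plateau_frac * n))
  if (n < 2L || k >= n)
    stop("trace too short for the plateau window", call. = FALSE)
  base <- mean(trace[(n - k + 1L):n])
  out <- trace - base
  attr(out, "baseline") <- base
  attr(out, "baseline_subtracted") <- TRUE
  out
}

#' Photobleaching lifetime from an exponential decay fit
#'
#' Nonlinear least squares of `A * exp(-t / tau) + c` to a fluorescence
#' time-trace; sufficient to obtain the photobleaching lifetime of a
#' fluorophore from ensemble (many-molecule) traces.
#'
#' @param time Time vector, s.
#' @param trace Intensity vector.
#' @return List `tau` (s), `tau_ci` (95% interval, NA if unavailable), `A`,
#'   `offset`, `failed` (TRUE when the trace does not decay).
#' @export
fit_lifetime <- function(time, trace) {
  n <- length(trace)
  head_m <- mean(trace[seq_len(max(2, n %/% 10))])
  tail_m <- mean(trace[(n - max(2, n %/% 10) + 1):n])
  if (!(head_m > tail_m) || stats::sd(trace) == 0)
    return(list(tau = NA_real_, tau_ci = c(NA_real_, NA_real_),
                A = NA_real_, offset = NA_real_, failed = TRUE))
  a0 <- head_m - tail_m
  # crude tau: time to fall to 1/e of the head-tail span
  below <- which(trace - tail_m < a0 / exp(1))
  t0 <- if (length(below)) time[below[1]] else time[n] / 2
  t0 <- max(t0, diff(range(time)) / 100)
  resfn <- function(p) trace - (p[1] * exp(-time / p[2]) + p[3])
  fit <- try(minpack.lm::nls.lm(
    par = c(a0, t0, tail_m), fn = resfn,
    lower = c(0, 1e-9, -Inf), upper = c(Inf, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(tau = NA_real_, tau_ci = c(NA_real_, NA_real_),
                A = NA_real_, offset = NA_real_, failed = TRUE))
  p <- fit$par
  dof <- max(n - 3, 1)
  se <- tryCatch(sqrt(diag(solve(fit$hessian)) * fit$deviance / dof)[2],
                 error = function(e) NA_real_)
  list(tau = p[2], tau_ci = p[2] + c(-1.96, 1.96) * se,
       A = p[1], offset = p[3],
       failed = p[1] <= 0 || p[2] <= 0)
}

#' HMM step fitting of a photobleaching trace
#'
#' Hidden Markov model over molecule counts k = 0..`max_molecules` with
#' Gaussian emissions `N(k * u, noise_sd)` and transitions allowing only
#' `k -> k` and `k -> k-1` (photobleaching is irreversible). Transitions are
#' parameterized by a single per-frame, per-molecule bleaching probability
#' `p`, so `P(k -> k-1) = k * p` (independent bleaching). The unitary
#' intensity `u`, the noise sd and `p` are fitted by maximizing the forward
#' likelihood over a deterministic grid, and the state path is decoded by
#' Viterbi.
#'
#' @param trace Baseline-subtracted intensity trace.
#' @param max_molecules Largest admissible start count (default 6).
#' @param u_grid_size Number of candidate unitary intensities (default 40,
#'   log-spaced around a robust initial guess).
#' @return A `step_fit` object: `states` (decoded molecule count per frame,
#'   non-increasing), `n_steps`, `step_heights`, `step_frames`, `u`,
#'   `noise_sd`, `bleach_prob`, `logLik`, `failed` (all-zero trace).
#' @export
hmm_steps <- function(trace, max_molecules = 6, u_grid_size = 40) {
  y <- as.numeric(trace)
  n <- length(y)
  if (max(abs(y)) == 0 || stats::sd(y) == 0) {
    return(structure(list(states = rep(0L, n), n_steps = 0L,
                          step_heights = numeric(0), step_frames = integer(0),
                          u = NA_real_, noise_sd = NA_real_,
                          bleach_prob = NA_real_, logLik = NA_real_,
                          failed = TRUE, trace = y),
                     class = "step_fit"))
  }
  # robust u guess: smallest sustained drop clearly above the noise
  sd0 <- stats::mad(diff(y)) / sqrt(2)
  drops <- -diff(stats::runmed(y, min(5, n - (1 - n %% 2))))
  real_drops <- drops[drops > 3 * sd0 & drops > 0]
  u0 <- if (length(real_drops)) min(real_drops) else max(y) / max_molecules
  u0 <- max(u0, 1e-6 * max(abs(y)))
  # 40 log-spaced candidates around the guess, including the guess itself
  u_cands <- unique(c(u0, u0 * exp(seq(log(0.25), log(2.5),
                                       length.out = u_grid_size - 1))))
  sd0 <- max(sd0, 0.005 * u0)
  sd_cands <- sd0 * c(0.7, 1, 1.5, 2.5)
  p_cands <- c(0.005, 0.02, 0.05, 0.12)

  ks <- 0:max_molecules
  cand <- expand.grid(u = u_cands, sd = sd_cands, p = p_cands)
  ll <- hmm_forward_grid(y, ks, cand)
  bi <- which.max(ll)
  best <- list(ll = ll[bi], u = cand$u[bi], sd = cand$sd[bi], p = cand$p[bi])
  em <- vapply(ks * best$u, function(m) stats::dnorm(y, m, best$sd), numeric(n))
  em <- pmax(matrix(em, ncol = length(ks)), 1e-300)
  states <- hmm_viterbi(em, ks, best$p)
  drops_at <- which(diff(states) < 0)
  heights <- -diff(states)[drops_at] * best$u  # single-step drops: = u
  structure(list(states = states, n_steps = length(drops_at),
                 step_heights = rep(best$u, sum(-diff(states)[drops_at])),
                 step_frames = drops_at + 1L,
                 u = best$u, noise_sd = best$sd, bleach_prob = best$p,
                 logLik = best$ll, failed = FALSE, trace = y),
            class = "step_fit")
}

# Forward log-likelihood for every candidate (u, sd, p) at once.
# States ks = 0..K-1; transition k -> k-1 with prob min(k*p, 0.9), else stay.
# Works on a K x C matrix of forward variables, so the time loop is the only
# scalar loop.
hmm_forward_grid <- function(y, ks, cand) {
  n <- length(y); K <- length(ks); C <- nrow(cand)
  mu <- outer(ks, cand$u)                       # K x C state means
  sdm <- matrix(cand$sd, K, C, byrow = TRUE)
  down <- pmin(outer(ks, cand$p), 0.9)          # K x C
  stay <- 1 - down
  emis <- function(t) pmax(stats::dnorm(y[t], mu, sdm), 1e-300)
  alpha <- emis(1) / K
  s <- colSums(alpha)
  ll <- log(s)                                  # frame 1 contribution
  alpha <- sweep(alpha, 2, s, `/`)
  for (t in 2:n) {
    a_new <- alpha * stay
    a_new[seq_len(K - 1), ] <- a_new[seq_len(K - 1), , drop = FALSE] +
      alpha[2:K, , drop = FALSE] * down[2:K, , drop = FALSE]
    a_new <- a_new * emis(t)
    s <- colSums(a_new)
    bad <- !is.finite(s) | s <= 0
    s[bad] <- .Machine$double.xmin              # hopeless candidate, keep going
    ll <- ll + log(s)
    alpha <- sweep(a_new, 2, s, `/`)
    if (any(bad)) alpha[, bad] <- 1 / K
  }
  ll
}

hmm_viterbi <- function(em, ks, p) {
  n <- nrow(em); K <- length(ks)
  down <- pmin(ks * p, 0.9); stay <- 1 - down
  logem <- log(em)
  delta <- log(rep(1 / K, K)) + logem[1, ]
  psi <- matrix(0L, n, K)
  for (t in 2:n) {
    d_new <- numeric(K)
    for (k in seq_len(K)) {
      # predecessors of state k: k (stay) and k+1 (bleach)
      cand <- delta[k] + log(stay[k])
      from <- k
      if (k < K) {
        alt <- delta[k + 1] + log(down[k + 1])
        if (alt > cand) { cand <- alt; from <- k + 1L }
      }
      d_new[k] <- cand + logem[t, k]
      psi[t, k] <- from
    }
    delta <- d_new
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  ks[path]
}

#' @export
print.step_fit <- function(x, ...) {
  if (x$failed) {
    cat("Photobleaching step fit: flat/zero trace, no steps\n")
    return(invisible(x))
  }
  cat(sprintf("Photobleaching step fit: %d step(s), u = %.3g, noise sd %.3g\n",
              x$n_steps, x$u, x$noise_sd))
  cat(sprintf("  initial molecule count %d, logLik %.1f\n",
              x$states[1], x$logLik))
  invisible(x)
}

#' @export
plot.step_fit <- function(x, xlab = "frame", ylab = "intensity", ...) {
  graphics::plot(x$trace, type = "l", col = "steelblue", xlab = xlab,
                 ylab = ylab, ...)
  graphics::lines(x$states * x$u, col = "red", lwd = 2)
  invisible(x)
}

#' Unitary fluorophore intensity from pooled step heights
#'
#' Fits a single 1D Gaussian (free position, width, amplitude) to the
#' histogram of photobleaching step heights pooled over many traces; the
#' center is the fluorophore unitary intensity.
#'
#' @param step_heights Numeric vector of step heights (>= 30 values).
#' @param breaks Histogram breaks (default "FD").
#' @return List `u` (center), `sd` (width), `amplitude`, `se_u`,
#'   `poor_fit` (TRUE when the histogram is badly described by one Gaussian,
#'   e.g. bimodal input), `residual_rms`.
#' @export
unitary_intensity <- function(step_heights, breaks = "FD") {
  h <- step_heights[is.finite(step_heights)]
  if (length(h) < 30) stop("need at least 30 step heights", call. = FALSE)
  if (stats::sd(h) == 0)
    return(list(u = h[1], sd = 0, amplitude = length(h), se_u = 0,
                poor_fit = FALSE, residual_rms = 0))
  hs <- graphics::hist(h, breaks = breaks, plot = FALSE)
  x <- hs$mids; y <- hs$counts
  df <- data.frame(x = x, y = y)
  fit <- try(minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)), data = df,
    start = list(A = max(y), mu = stats::median(h), sigma = stats::sd(h)),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("Gaussian fit of the step-height histogram failed", call. = FALSE)
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  rel <- sqrt(mean(res^2)) / max(y)
  se_mu <- tryCatch(summary(fit)$coefficients["mu", "Std. Error"],
                    error = function(e) NA_real_)
  list(u = unname(cf["mu"]), sd = abs(unname(cf["sigma"])),
       amplitude = unname(cf["A"]), se_u = se_mu,
       poor_fit = rel > 0.18, residual_rms = sqrt(mean(res^2)))
}

#' Molecules per cell from total fluorescence and unitary intensity
#'
#' @param total_cell_fluorescence Overall cellular fluorescence (counts),
#'   scalar or vector.
#' @param u Fluorophore unitary intensity (> 0).
#' @return Real-valued molecule count(s) (`total / u`).
#' @examples count_molecules(87, 8.7)  # 10
#' @export
count_molecules <- function(total_cell_fluorescence, u) {
  if (u <= 0) stop("unitary intensity must be > 0", call. = FALSE)
  total_cell_fluorescence / u
}

#' Classify cells as loaded by the control mean + 3 sd rule
#'
#' A cell is loaded when its fluorescence per cell area exceeds the mean plus
#' three standard deviations of a non-electroporated control population.
#'
#' @param cell_values Fluorescence per cell area of the cells to classify.
#' @param control_values Control population (>= 10 cells).
#' @return Data frame `value, loaded` with attributes `threshold` and
#'   `zero_variance` (TRUE when the control has no spread; the threshold then
#'   degenerates to the control mean).
#' @export
classify_loaded <- function(cell_values, control_values) {
  if (length(control_values) < 10)
    stop("need at least 10 control cells", call. = FALSE)
  m <- mean(control_values); s <- stats::sd(control_values)
  zero_var <- s == 0
  thr <- m + 3 * s
  out <- data.frame(value = cell_values, loaded = cell_values > thr)
  attr(out, "threshold") <- thr
  attr(out, "zero_variance") <- zero_var
  out
}
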