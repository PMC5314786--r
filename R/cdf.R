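#' Fit the cumulative distribution of squared displacements to m species
#'
#' The single-frame squared displacement of species j (free 2D diffusion plus
#' per-axis localization error `s_axis`) is exponential with mean
#' `tau_j = 4*D_j*dt + 4*s_axis^2`, so the CDF of a mixture is
#' `CDF(u) = 1 - sum_j A_j * exp(-u / tau_j)`. The empirical CDF is fitted
#' by least squares with deterministic multi-start; species are reported in
#' ascending order of D.
#'
#' @param sq_disp Numeric vector of single-frame squared displacements
#'   (um^2); at least 200 values.
#' @param m Number of species (default 2).
#' @param s_axis Per-axis localization error in um (its `4*s^2` offset is
#'   removed from the fitted means).
#' @param dt Frame interval in seconds.
#' @return A `cdf_fit` object: `D` (um^2/s, ascending), `weights`, `s_axis`,
#'   `dt`, `resid_norm` (RMS CDF residual), `failed`.
#' @export
fit_cdf <- function(sq_disp, m = 2, s_axis = 0, dt = 0.005) {
  u <- sort(as.numeric(sq_disp))
  u <- u[is.finite(u) & u >= 0]
  if (length(u) < 200) stop("need at least 200 squared displacements", call. = FALSE)
  if (stats::sd(u) == 0) {
    out <- list(D = rep(NA_real_, m), weights = rep(NA_real_, m),
                s_axis = s_axis, dt = dt, resid_norm = NA_real_, failed = TRUE)
    class(out) <- "cdf_fit"
    return(out)
  }
  ec <- (seq_along(u) - 0.5) / length(u)
  offset <- 4 * s_axis^2

  # parameters: log(tau_j) and (m-1) logits for the weights
  model_cdf <- function(par) {
    tau <- exp(par[seq_len(m)])
    w <- softmax_weights(par[-seq_len(m)], m)
    1 - rowSums(vapply(seq_len(m), function(j) w[j] * exp(-u / tau[j]),
                       numeric(length(u))))
  }
  obj <- function(par) sum((model_cdf(par) - ec)^2)

  mu <- mean(u)
  starts <- list(
    c(log(mu * c(0.2, 1, 5)[seq_len(m)]), rep(0, m - 1)),
    c(log(mu * c(0.02, 1.5, 8)[seq_len(m)]), rep(0, m - 1)),
    c(log(stats::quantile(u, seq(0.2, 0.9, length.out = m))), rep(0, m - 1)))
  best <- NULL
  for (st in starts) {
    fit <- try(stats::optim(st, obj, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("CDF fit failed from all starts", call. = FALSE)
  tau <- exp(best$par[seq_len(m)])
  w <- softmax_weights(best$par[-seq_len(m)], m)
  D <- pmax((tau - offset) / (4 * dt), 0)
  ord <- order(D)
  out <- list(D = D[ord], weights = w[ord], s_axis = s_axis, dt = dt,
              resid_norm = sqrt(best$value / length(u)), failed = FALSE)
  class(out) <- "cdf_fit"
  out
}

softmax_weights <- function(logits, m) {
  z <- exp(c(logits, 0))
  z / sum(z)
}

#' @export
print.cdf_fit <- function(x, digits = 3, ...) {
  if (x$failed) {
    cat("CDF fit: FAILED (degenerate data)\n")
    return(invisible(x))
  }
  cat(sprintf("CDF fit, %d diffusive species (offset 4s^2 = %.4g um^2):\n",
              length(x$D), 4 * x$s_axis^2))
  for (j in seq_along(x$D))
    cat(sprintf("  D_%d = %s um^2/s, weight %s\n", j,
                signif(x$D[j], digits), signif(x$weights[j], digits)))
  cat(sprintf("  RMS CDF residual %.3g\n", x$resid_norm))
  invisible(x)
}

#' @export
coef.cdf_fit <- function(object, ...) {
  c(stats::setNames(object$D, paste0("D", seq_along(object$D))),
    stats::setNames(object$weights, paste0("A", seq_along(object$D))))
}

#' @export
plot.cdf_fit <- function(x, sq_disp, main = "Squared-displacement CDF fit",
                         xlab = expression(u ~ (mu * m^2)), ...) {
  u <- sort(sq_disp)
  ec <- (seq_along(u) - 0.5) / length(u)
  graphics::plot(u, ec, type = "s", main = main, xlab = xlab,
                 ylab = "CDF", col = "grey50", ...)
  tau <- 4 * x$D * x$dt + 4 * x$s_axis^2
  fit <- 1 - rowSums(vapply(seq_along(tau), function(j)
    x$weights[j] * exp(-u / tau[j]), numeric(length(u))))
  graphics::lines(u, fit, lwd = 2, col = 2)
  invisible(x)
}
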