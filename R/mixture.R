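#' Fit a gamma mixture to apparent diffusion coefficients
#'
#' The apparent diffusion coefficient of a trajectory truncated to `shape`
#' single-frame steps of one free diffusive species is gamma distributed with
#' shape `shape` and mean equal to the species' apparent D. A population with
#' several diffusive species therefore follows a mixture
#' `sum_j A_j * Gamma(shape, mean = Dbar_j)`, which is fitted here by
#' maximum likelihood (EM with deterministic multi-start). Species means can
#' be constrained to known values, e.g. the apparent D of ribosome-bound
#' complexes (0.5 um^2/s) or of a fixed-cell control (0.32 um^2/s).
#'
#' @param D_values Numeric vector of apparent diffusion coefficients
#'   (um^2/s); at least 50 values.
#' @param m Number of species, 1 to 3 (default 2).
#' @param shape Gamma shape = number of averaged steps (default 4).
#' @param constraints Optional numeric vector of length `m`; entry j fixes
#'   species j's mean apparent D, `NA` leaves it free. Species are in
#'   ascending order of mean.
#' @param n_restarts Deterministic EM restarts (default 10).
#' @param max_iter,tol EM iteration control.
#' @return An object of class `gamma_mix` with components `means`, `weights`,
#'   `constrained`, `shape`, `logLik`, `converged`, `m`, `data`.
#' @seealso [ternary_complex_Dapp] for the 2.4 um^2/s three-species constraint.
#' @export
fit_gamma_mixture <- function(D_values, m = 2, shape = 4, constraints = NULL,
                              n_restarts = 10, max_iter = 500, tol = 1e-8) {
  x <- as.numeric(D_values)
  x <- x[is.finite(x) & x >= 0]
  if (length(x) < 50) stop("need at least 50 D values", call. = FALSE)
  if (!m %in% 1:3) stop("m must be 1, 2 or 3", call. = FALSE)
  if (is.null(constraints)) constraints <- rep(NA_real_, m)
  if (length(constraints) != m) stop("constraints must have length m", call. = FALSE)
  x <- pmax(x, 1e-9)  # gamma density vanishes at exactly 0

  fixed <- !is.na(constraints)
  qs <- stats::quantile(x, probs = seq(0.15, 0.85, length.out = m))
  cands <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    # deterministic spread of starting means around the data quantiles
    f <- 0.4 + 1.6 * (r - 1) / max(n_restarts - 1, 1)
    mu <- qs * f
    mu[fixed] <- constraints[fixed]
    w <- rep(1 / m, m)
    ll_old <- -Inf; conv <- FALSE
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(m), function(j)
        w[j] * stats::dgamma(x, shape = shape, rate = shape / mu[j]),
        numeric(length(x)))
      dens <- matrix(dens, ncol = m)
      tot <- rowSums(dens)
      tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
      ll <- sum(log(tot))
      resp <- dens / tot
      w <- colMeans(resp)
      for (j in seq_len(m)) {
        if (!fixed[j] && w[j] > 0)
          mu[j] <- sum(resp[, j] * x) / sum(resp[, j])
      }
      mu <- pmax(mu, 1e-8)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
        conv <- TRUE; break
      }
      ll_old <- ll
    }
    cands[[r]] <- list(means = unname(mu), weights = unname(w), logLik = ll,
                       converged = conv)
  }
  # among restarts whose log-likelihoods are statistically indistinguishable
  # (within 2 units of the best), prefer the most parsimonious solution
  # (largest dominant weight): close means make the weight split
  # unidentifiable, and this tie-break keeps single-species data from
  # presenting as two separated species
  lls <- vapply(cands, `[[`, numeric(1), "logLik")
  near <- which(lls > max(lls) - 2)
  dom <- vapply(cands[near], function(cc) max(cc$weights), numeric(1))
  best <- cands[[near[which.max(dom)]]]
  # merge indistinguishable free components: with two means this close the
  # weight split is unidentifiable and the likelihood is flat
  free <- which(!fixed)
  if (length(free) > 1) {
    for (i in free) for (j in free) {
      if (i < j && best$weights[j] > 0 &&
          abs(best$means[i] - best$means[j]) <
            0.02 * max(best$means[i], best$means[j])) {
        pooled <- (best$weights[i] * best$means[i] +
                     best$weights[j] * best$means[j]) /
          (best$weights[i] + best$weights[j])
        best$means[c(i, j)] <- pooled
        best$weights[i] <- best$weights[i] + best$weights[j]
        best$weights[j] <- 0
      }
    }
  }
  ord <- order(best$means)
  structure(list(means = best$means[ord], weights = best$weights[ord],
                 constrained = fixed[ord],
                 constraints = constraints[ord],
                 shape = shape, m = m,
                 logLik = best$logLik, converged = best$converged,
                 n = length(x), data = x),
            class = "gamma_mix")
}

#' Apparent diffusion coefficient of the ternary complex
#'
#' Named constant (um^2/s) used to constrain the intermediate species in
#' three-species decompositions: aminoacyl-tRNA bound to EF-Tu and GTP.
#' @export
ternary_complex_Dapp <- 2.4

#' @export
print.gamma_mix <- function(x, digits = 3, ...) {
  cat(sprintf("Gamma mixture (shape %g) of %d diffusive species, n = %d\n",
              x$shape, x$m, x$n))
  tab <- data.frame(mean_Dapp = signif(x$means, digits),
                    weight = signif(x$weights, digits),
                    constrained = x$constrained)
  print(tab, row.names = paste0("  species ", seq_len(x$m)))
  cat(sprintf("logLik %.2f, converged: %s\n", x$logLik, x$converged))
  invisible(x)
}

#' @export
coef.gamma_mix <- function(object, ...) {
  c(stats::setNames(object$means, paste0("Dbar", seq_len(object$m))),
    stats::setNames(object$weights, paste0("A", seq_len(object$m))))
}

#' @export
logLik.gamma_mix <- function(object, ...) {
  free <- sum(!object$constrained) + (object$m - 1)
  structure(object$logLik, df = free, nobs = object$n, class = "logLik")
}

#' @export
summary.gamma_mix <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Mixture density of a fitted gamma mixture
#' @param object A `gamma_mix` fit.
#' @param x Points at which to evaluate, um^2/s.
#' @param ... Unused.
#' @return Numeric density values.
#' @export
density_gamma_mix <- function(object, x, ...) {
  rowSums(vapply(seq_len(object$m), function(j)
    object$weights[j] * stats::dgamma(x, shape = object$shape,
                                      rate = object$shape / object$means[j]),
    numeric(length(x))))
}

#' @export
simulate.gamma_mix <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  j <- sample.int(object$m, nsim, replace = TRUE, prob = object$weights)
  stats::rgamma(nsim, shape = object$shape,
                rate = object$shape / object$means[j])
}

#' @export
plot.gamma_mix <- function(x, breaks = 40, main = "Apparent D mixture fit",
                           xlab = expression(D[app] ~ (mu * m^2 / s)), ...) {
  h <- graphics::hist(x$data, breaks = breaks, freq = FALSE, main = main,
                      xlab = xlab, col = "grey90", border = "grey60", ...)
  xs <- seq(0, max(x$data), length.out = 400)
  graphics::lines(xs, density_gamma_mix(x, xs), lwd = 2)
  for (j in seq_len(x$m)) {
    graphics::lines(xs, x$weights[j] * stats::dgamma(
      xs, shape = x$shape, rate = x$shape / x$means[j]), lty = 2)
  }
  invisible(h)
}
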