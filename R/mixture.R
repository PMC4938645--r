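#' Logit (log-odds) transform of methylation values
#'
#' Methylation histograms pile up near 0 and 1; the logit transform
#' spreads both tails so that Gaussian components become resolvable.
#' Boundary values are clamped into `[epsilon, 1 - epsilon]` before
#' transforming so the result is always finite.
#'
#' @param m Methylation values in \[0,1\] (vectorised).
#' @param epsilon Probability floor in (0, 0.5).
#' @return Log-odds values `log(m' / (1 - m'))`.
#' @export
logit <- function(m, epsilon = 0.005) {
  if (epsilon <= 0 || epsilon >= 0.5) {
    stop("`epsilon` must lie in (0, 0.5)")
  }
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("methylation values must lie in [0, 1]")
  }
  qlogis(pmin(pmax(m, epsilon), 1 - epsilon))
}

#' Inverse logit
#'
#' @param x Log-odds values.
#' @return Methylation values `1 / (1 + exp(-x))`.
#' @export
inverse_logit <- function(x) {
  plogis(x)
}

#' Fit a univariate Gaussian mixture by EM
#'
#' Expectation-maximisation for a k-component Gaussian mixture on the
#' logit scale.  Responsibilities are computed from normalised component
#' densities (in log space for stability); weights, means and variances
#' are then updated in closed form.  Convergence is declared when the
#' log-likelihood gain drops below `tol` (default 1e-8) or after
#' `max_iter` iterations.  The fit is repeated from `n_restarts` seeded
#' starts (the first uses quantile-spaced initial means, the rest jitter
#' them) and the best log-likelihood wins.  A restart whose component
#' standard deviation collapses below 1e-6 is discarded; if every
#' restart degenerates an error is raised.
#'
#' Components are reported in increasing order of mean.
#'
#' @param values Numeric vector on the logit scale (length >= 10 * k).
#' @param k Number of components.
#' @param seed Integer seed controlling the restarts.
#' @param n_restarts Number of seeded restarts.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Absolute log-likelihood gain below which EM stops.
#' @return An object of class `"mixture_fit"`: list with `k`, `weights`,
#'   `means`, `sds` (logit scale), `means_prob` (inverse-logit of the
#'   means), `log_likelihood`, `bic`, `converged`, `n_iterations`, `n`.
#' @export
fit_mixture <- function(values, k, seed = 1L, n_restarts = 10L,
                        max_iter = 1000L, tol = 1e-8) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 10L * k) {
    stop("need at least 10 * k = ", 10L * k, " values, got ", n)
  }
  if (!all(is.finite(x))) {
    stop("logit values must be finite; clamp with logit() first")
  }
  best <- NULL
  sdx <- sd(x)
  base_means <- as.numeric(quantile(x, probs = (seq_len(k) - 0.5) / k))
  for (r in seq_len(n_restarts)) {
    if (r == 1L) {
      mu0 <- base_means
    } else {
      set.seed((seed * 1000L + r) %% .Machine$integer.max)
      mu0 <- base_means + rnorm(k, 0, sdx / 2)
    }
    fit <- .em_gaussian(x, k, mu0, sd0 = rep(max(sdx / k, 0.1), k),
                        max_iter = max_iter, tol = tol)
    if (is.null(fit)) next  # degenerate restart
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("all EM restarts degenerated (component sd collapsed)")
  }
  ord <- order(best$means)
  structure(
    list(
      k = k,
      weights = best$weights[ord],
      means = best$means[ord],
      sds = best$sds[ord],
      means_prob = plogis(best$means[ord]),
      log_likelihood = best$log_likelihood,
      bic = -2 * best$log_likelihood + (3 * k - 1) * log(n),
      converged = best$converged,
      n_iterations = best$n_iterations,
      ll_trace = best$ll_trace,
      n = n
    ),
    class = "mixture_fit"
  )
}

# One EM run; returns NULL when a component degenerates.
.em_gaussian <- function(x, k, mu, sd0, max_iter, tol) {
  n <- length(x)
  w <- rep(1 / k, k)
  s <- sd0
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  ll <- -Inf
  trace <- numeric(0)
  repeat {
    iter <- iter + 1L
    # E step: log responsibilities with log-sum-exp
    lp <- matrix(0, n, k)
    for (j in seq_len(k)) {
      lp[, j] <- log(w[j]) + dnorm(x, mu[j], s[j], log = TRUE)
    }
    mx <- lp[, 1L]
    if (k > 1L) for (j in 2:k) mx <- pmax(mx, lp[, j])
    lse <- mx + log(rowSums(exp(lp - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(lp - lse)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    # M step
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    s <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    if (any(!is.finite(s)) || any(s < 1e-6)) {
      return(NULL)
    }
  }
  list(weights = w, means = mu, sds = s, log_likelihood = ll,
       converged = converged, n_iterations = iter, ll_trace = trace)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture, k = %d (n = %d, BIC = %.1f%s)\n",
              x$k, x$n, x$bic,
              if (x$converged) "" else ", NOT converged"))
  for (j in seq_len(x$k)) {
    cat(sprintf(
      "  comp %d: weight %.3f, mean %.2f (methylation %.3f), sd %.2f\n",
      j, x$weights[j], x$means[j], x$means_prob[j], x$sds[j]
    ))
  }
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits every candidate k and returns the fit minimising
#' `BIC = -2 logL + (3k - 1) log n`.
#'
#' @inheritParams fit_mixture
#' @param k_candidates Candidate component counts.
#' @return The best `"mixture_fit"`, with an attribute `bic_table`
#'   (data.frame of k, log_likelihood, bic, converged).
#' @export
select_k <- function(values, k_candidates = 1:3, seed = 1L, ...) {
  fits <- lapply(k_candidates, function(k) {
    fit_mixture(values, k, seed = seed, ...)
  })
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bics)]]
  attr(best, "bic_table") <- data.frame(
    k = k_candidates,
    log_likelihood = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    bic = bics,
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
  best
}

#' Density curves of a fitted mixture
#'
#' Evaluates the total mixture density and each weighted component
#' density over a grid, for histogram overlays.
#'
#' @param fit A `"mixture_fit"`.
#' @param from,to Grid range (defaults: means +/- 4 max sd).
#' @param n Grid size.
#' @return data.frame with columns `x`, `total`, `comp_1` ... `comp_k`.
#' @export
mixture_density_curves <- function(fit, from = NULL, to = NULL, n = 512L) {
  if (is.null(from)) from <- min(fit$means) - 4 * max(fit$sds)
  if (is.null(to)) to <- max(fit$means) + 4 * max(fit$sds)
  x <- seq(from, to, length.out = n)
  comps <- vapply(seq_len(fit$k), function(j) {
    fit$weights[j] * dnorm(x, fit$means[j], fit$sds[j])
  }, numeric(n))
  out <- data.frame(x = x, total = rowSums(comps))
  colnames(comps) <- paste0("comp_", seq_len(fit$k))
  cbind(out, comps)
}
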