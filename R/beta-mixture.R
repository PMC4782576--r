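# Per-sample three-state beta-mixture model of 450k beta values, and the
# lower/upper state thresholds derived from it.  The EM uses exact
# component-wise M-steps (Newton on the beta log-likelihood reduced to
# its sufficient statistics), accepting only likelihood-improving steps,
# so the observed log-likelihood is non-decreasing.

# Weighted beta log-likelihood reduced to sufficient statistics:
#   g(a,b) = (a-1)*S1 + (b-1)*S2 - W*lbeta(a,b)
beta_suff_obj <- function(a, b, S1, S2, W) {
  (a - 1) * S1 + (b - 1) * S2 - W * lbeta(a, b)
}

# Maximise g(a,b) from a starting point by damped Newton steps on
# (a, b); cost is O(1) per step (the data enter only through S1,S2,W).
beta_weighted_mle <- function(a, b, S1, S2, W, steps = 25) {
  obj <- beta_suff_obj(a, b, S1, S2, W)
  for (it in seq_len(steps)) {
    dg_ab <- digamma(a + b)
    ga <- S1 - W * (digamma(a) - dg_ab)
    gb <- S2 - W * (digamma(b) - dg_ab)
    tg_ab <- trigamma(a + b)
    haa <- -W * (trigamma(a) - tg_ab)
    hbb <- -W * (trigamma(b) - tg_ab)
    hab <- W * tg_ab
    det <- haa * hbb - hab^2
    if (!is.finite(det) || det == 0) break
    da <- -(hbb * ga - hab * gb) / det
    db <- -(haa * gb - hab * ga) / det
    step <- 1
    improved <- FALSE
    for (h in 1:20) {
      a2 <- a + step * da
      b2 <- b + step * db
      if (a2 > 1e-3 && b2 > 1e-3) {
        o2 <- beta_suff_obj(a2, b2, S1, S2, W)
        if (is.finite(o2) && o2 >= obj) {
          a <- a2; b <- b2
          improved <- o2 > obj + 1e-12 * abs(obj)
          obj <- o2
          break
        }
      }
      step <- step / 2
    }
    if (!improved) break
  }
  c(a = a, b = b)
}

#' Fit a three-state beta mixture to one sample's beta values
#'
#' EM fit of a K-component beta mixture (default K = 3: unmethylated,
#' half-methylated, fully methylated).  Components are initialised at
#' the 10th/50th/90th percentiles (quantile spacing for general K) and
#' reported sorted by mean.  Values at exactly 0 or 1 are nudged by
#' `eps`.  The log-likelihood is non-decreasing across iterations.
#'
#' @param x Numeric vector of beta values in `[0,1]` (>= 100 finite
#'   values required).
#' @param K Number of components.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations (non-convergence returns the
#'   best fit with `converged = FALSE` and a warning).
#' @param seed Seed for the fitting subsample (see `n_max`).
#' @param n_max Fit on a seeded subsample of at most this many values
#'   (threshold estimates are stable well below the default 5000).
#' @param eps Nudge applied to values at exactly 0 or 1.
#' @return Object of class `beta_mixture_fit`: `pi`, `shape1`, `shape2`,
#'   `means`, `loglik` (trace), `converged`, `flags`, `n`.
#' @export
fit_beta_mixture <- function(x, K = 3, tol = 1e-6, max_iter = 100,
                             seed = 1, n_max = 5000, eps = 1e-6) {
  x <- x[is.finite(x)]
  if (length(x) < 100) stopf("need >= 100 finite beta values, got %d", length(x))
  if (any(x < 0 | x > 1)) stopf("beta values outside [0,1]")
  x[x == 0] <- eps
  x[x == 1] <- 1 - eps
  n_all <- length(x)
  if (n_all > n_max) {
    x <- with_seed(seed, sample(x, n_max))
  }
  n <- length(x)
  lx <- log(x); l1x <- log1p(-x)

  init <- function(jitter = 0) {
    qs <- seq(0.1, 0.9, length.out = K)
    m <- stats::quantile(x, qs, names = FALSE)
    if (jitter > 0) {
      m <- pmin(pmax(m + stats::runif(K, -jitter, jitter), 0.02), 0.98)
    }
    m <- sort(m)
    kap <- 10
    list(pi = rep(1 / K, K), a = m * kap, b = (1 - m) * kap)
  }

  run_em <- function(par) {
    ll_trace <- numeric(0)
    flags <- character(0)
    for (iter in seq_len(max_iter)) {
      # component log-densities via sufficient statistics (single pass
      # over lx/l1x; avoids K dbeta calls)
      lk <- outer(lx, par$a - 1) + outer(l1x, par$b - 1)
      lk <- sweep(lk, 2, log(par$pi) - lbeta(par$a, par$b), "+")
      mx <- lk[, 1]
      for (k in 2:K) mx <- pmax(mx, lk[, k])
      lse <- mx + log(rowSums(exp(lk - mx)))
      ll <- sum(lse)
      ll_trace <- c(ll_trace, ll)
      r <- exp(lk - lse)
      W <- colSums(r)
      if (any(W / n < 1e-4)) {
        flags <- c(flags, "degenerate")
        break
      }
      for (k in seq_len(K)) {
        ab <- beta_weighted_mle(par$a[k], par$b[k],
                                sum(r[, k] * lx), sum(r[, k] * l1x), W[k])
        par$a[k] <- ab[["a"]]; par$b[k] <- ab[["b"]]
      }
      par$pi <- W / n
      if (iter > 1) {
        prev <- ll_trace[iter - 1]
        if (abs(ll - prev) <= tol * (abs(prev) + 1e-8)) {
          return(list(par = par, ll = ll_trace, converged = TRUE,
                      flags = flags))
        }
      }
    }
    list(par = par, ll = ll_trace,
         converged = FALSE, flags = flags)
  }

  fit <- run_em(init())
  if ("degenerate" %in% fit$flags) {
    # one re-initialisation with jittered component means, then flag
    fit2 <- with_seed(seed + 1L, run_em(init(jitter = 0.1)))
    if (!"degenerate" %in% fit2$flags) {
      fit <- fit2
      fit$flags <- c(fit$flags, "reinitialized")
    } else {
      fit <- if (max(fit2$ll) > max(fit$ll)) fit2 else fit
      fit$flags <- unique(c(fit$flags, "degenerate"))
    }
  }
  if (!fit$converged && !"degenerate" %in% fit$flags) {
    warnf("beta-mixture EM did not converge in %d iterations", max_iter)
  }
  ord <- order(fit$par$a / (fit$par$a + fit$par$b))
  out <- list(
    pi = fit$par$pi[ord],
    shape1 = fit$par$a[ord],
    shape2 = fit$par$b[ord],
    means = (fit$par$a / (fit$par$a + fit$par$b))[ord],
    loglik = fit$ll,
    converged = fit$converged,
    flags = fit$flags,
    n = n_all
  )
  class(out) <- "beta_mixture_fit"
  out
}

#' @export
print.beta_mixture_fit <- function(x, ...) {
  cat(sprintf("beta mixture fit: %d components, n = %d, logLik = %.2f%s\n",
              length(x$pi), x$n, x$loglik[length(x$loglik)],
              if (x$converged) "" else " (not converged)"))
  print(data.frame(pi = x$pi, shape1 = x$shape1, shape2 = x$shape2,
                   mean = x$means))
  invisible(x)
}

#' Lower and upper methylation-state thresholds from a mixture fit
#'
#' `L` is the smallest beta in `(mean1, mean2)` where the posterior of
#' the half-methylated component reaches that of the unmethylated one;
#' `U` is the analogue between the half- and fully methylated
#' components.  Found by grid search.
#'
#' @param fit A [fit_beta_mixture()] result with 3 ordered components.
#' @param resolution Grid resolution (default 1e-4).
#' @return Named vector `c(L = , U = )` with `0 < L < U < 1`.
#' @export
state_thresholds <- function(fit, resolution = 1e-4) {
  stopifnot(inherits(fit, "beta_mixture_fit"), length(fit$pi) == 3)
  crossing <- function(k1, k2) {
    lo <- fit$means[k1]; hi <- fit$means[k2]
    grid <- seq(lo, hi, by = resolution)
    upper <- log(fit$pi[k2]) +
      stats::dbeta(grid, fit$shape1[k2], fit$shape2[k2], log = TRUE)
    lower <- log(fit$pi[k1]) +
      stats::dbeta(grid, fit$shape1[k1], fit$shape2[k1], log = TRUE)
    hit <- which(upper >= lower)
    if (!length(hit)) {
      stopf("no posterior crossing between components %d and %d", k1, k2)
    }
    grid[hit[1]]
  }
  L <- crossing(1, 2)
  U <- crossing(2, 3)
  c(L = L, U = U)
}
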