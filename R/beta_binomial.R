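#' Beta-binomial log-likelihood
#'
#' Log of the beta-binomial pmf in the mean/overdispersion
#' parameterization used throughout the caller: with shape parameters
#' `a = mu * (1/rho - 1)` and `b = (1 - mu) * (1/rho - 1)`, the pmf is
#' `choose(n, x) * beta(x + a, n - x + b) / beta(a, b)`, evaluated via
#' log-gamma identities. As `rho -> 0` the distribution converges
#' continuously to the binomial with success probability `mu`; `rho = 0`
#' is accepted and evaluated as the binomial. An empty observation
#' (`n = 0`) has log-probability 0.
#'
#' @param x Alt-read count(s), `0 <= x <= n`.
#' @param n Depth(s).
#' @param mu Mean error rate, in (0, 1).
#' @param rho Overdispersion, in `[0, 1)`.
#' @return Numeric vector of log-probabilities, one per observation.
#' @examples
#' beta_binomial_loglik(1, 10, 0.1, 1e-12)  # ~ dbinom(1, 10, 0.1, log = TRUE)
#' @export
beta_binomial_loglik <- function(x, n, mu, rho) {
  stopifnot(length(mu) == 1L, length(rho) == 1L)
  if (!is.finite(mu) || mu <= 0 || mu >= 1)
    stop("'mu' must be in (0, 1)", call. = FALSE)
  if (!is.finite(rho) || rho < 0 || rho >= 1)
    stop("'rho' must be in [0, 1)", call. = FALSE)
  if (length(x) != length(n))
    stop("'x' and 'n' must have equal length", call. = FALSE)
  if (any(x < 0) || any(x > n))
    stop("need 0 <= x <= n", call. = FALSE)
  .bb_loglik_cpp(as.numeric(x), as.numeric(n), mu, rho)
}

.mu_floor <- 1e-8
.rho_floor <- 1e-8

#' Fit a site-specific beta-binomial error model
#'
#' Maximum-likelihood estimation of the background error mean `mu` and
#' between-sample overdispersion `rho` at one site, from alt counts and
#' depths across the background ("normal") panel. The optimizer is a
#' bounded quasi-Newton (L-BFGS-B) on the logit scale, started from a
#' method-of-moments estimate. Boundary fits (e.g. all counts zero) land
#' on the floors `1e-8`.
#'
#' @param xs Alt-read counts per background sample.
#' @param ns Depths per background sample (same length, `xs <= ns`).
#' @return A list of class `error_model_fit` with elements `mu`, `rho`,
#'   `loglik`, `n_background` and `converged`.
#' @export
fit_beta_binomial <- function(xs, ns) {
  if (length(xs) != length(ns) || length(xs) < 2L)
    stop("need >= 2 background samples with matching counts", call. = FALSE)
  if (any(xs < 0) || any(xs > ns))
    stop("need 0 <= xs <= ns", call. = FALSE)
  if (all(ns == 0))
    stop("degenerate input: all depths are zero", call. = FALSE)
  xs <- as.numeric(xs); ns <- as.numeric(ns)

  out <- function(mu, rho, ll, conv) {
    structure(list(mu = mu, rho = rho, loglik = ll,
                   n_background = length(xs), converged = conv),
              class = "error_model_fit")
  }
  if (sum(xs) == 0) {
    ll <- sum(.bb_loglik_cpp(xs, ns, .mu_floor, .rho_floor))
    return(out(.mu_floor, .rho_floor, ll, TRUE))
  }

  # method-of-moments start
  mu0 <- min(max(sum(xs) / sum(ns), .mu_floor), 1 - .mu_floor)
  ok <- ns > 0
  ph <- xs[ok] / ns[ok]
  inv_n <- mean(1 / ns[ok])
  rho0 <- if (length(ph) > 1L && mu0 > 0 && mu0 < 1) {
    (stats::var(ph) / (mu0 * (1 - mu0)) - inv_n) / (1 - inv_n)
  } else .rho_floor
  rho0 <- min(max(rho0, 1e-6), 0.5)

  logit <- function(p) log(p / (1 - p))
  expit <- function(z) 1 / (1 + exp(-z))
  nll <- function(par) {
    mu <- expit(par[1]); rho <- expit(par[2])
    mu <- min(max(mu, .mu_floor), 1 - .mu_floor)
    rho <- min(max(rho, .rho_floor), 1 - .rho_floor)
    -sum(.bb_loglik_cpp(xs, ns, mu, rho))
  }
  fit <- tryCatch(
    stats::optim(c(logit(mu0), logit(rho0)), nll, method = "L-BFGS-B",
                 lower = logit(.mu_floor), upper = logit(1 - .mu_floor),
                 control = list(maxit = 200L)),
    error = function(e) NULL)
  if (is.null(fit)) {
    ll <- sum(.bb_loglik_cpp(xs, ns, mu0, max(rho0, .rho_floor)))
    return(out(mu0, max(rho0, .rho_floor), ll, FALSE))
  }
  mu <- min(max(expit(fit$par[1]), .mu_floor), 1 - .mu_floor)
  rho <- min(max(expit(fit$par[2]), .rho_floor), 1 - .rho_floor)
  out(mu, rho, -fit$value, fit$convergence == 0L)
}

#' One-sample likelihood-ratio test against a background error model
#'
#' Full maximum-likelihood version of the site test: the null model fits
#' one shared (mu, rho) on background plus test sample; the alternative
#' adds a separate rate for the test sample while sharing rho, giving one
#' extra free parameter. `lambda = 2 * (loglik_alt - loglik_null)`,
#' clipped at 0. The one-sided p-value is `0.5 * P(chisq_1 >= lambda)`
#' when the test rate exceeds the background rate, and 1 otherwise (the
#' test targets excess variant reads only). A test sample with zero depth
#' yields `p = 1` with `degenerate_coverage = TRUE` rather than an error.
#'
#' This routine is exact but iterative; [call_variants()] uses a faster
#' batch path with plug-in rate estimates (see its documentation).
#'
#' @param x_test,n_test Alt count and depth in the sample of interest.
#' @param xs_bg,ns_bg Alt counts and depths across the background pool
#'   (at least 2 samples with positive depth).
#' @return A list of class `lrt_result`: `mu_hat_test`, `mu_hat_background`,
#'   `lambda`, `p`, `degenerate_coverage`.
#' @export
lrt_one_sample <- function(x_test, n_test, xs_bg, ns_bg) {
  if (sum(ns_bg > 0) < 2L)
    stop("background needs >= 2 samples with positive depth", call. = FALSE)
  res <- function(mut, mub, lam, p, degen = FALSE) {
    structure(list(mu_hat_test = mut, mu_hat_background = mub,
                   lambda = lam, p = p, degenerate_coverage = degen),
              class = "lrt_result")
  }
  mub_plug <- sum(xs_bg) / sum(ns_bg)
  if (n_test == 0)
    return(res(NA_real_, mub_plug, 0, 1, degen = TRUE))

  null_fit <- fit_beta_binomial(c(xs_bg, x_test), c(ns_bg, n_test))

  # alternative: (mu_bg, mu_test, rho), maximized jointly; started both
  # from the null solution (guaranteeing lambda >= 0 up to optimizer
  # tolerance) and from plug-in proportions
  logit <- function(p) log(p / (1 - p))
  expit <- function(z) 1 / (1 + exp(-z))
  clamp <- function(p) min(max(p, .mu_floor), 1 - .mu_floor)
  nll <- function(par) {
    mb <- clamp(expit(par[1])); mt <- clamp(expit(par[2]))
    rho <- min(max(expit(par[3]), .rho_floor), 1 - .rho_floor)
    -(sum(.bb_loglik_cpp(as.numeric(xs_bg), as.numeric(ns_bg), mb, rho)) +
        .bb_loglik_cpp(as.numeric(x_test), as.numeric(n_test), mt, rho))
  }
  starts <- list(
    c(logit(clamp(null_fit$mu)), logit(clamp(null_fit$mu)),
      logit(max(null_fit$rho, .rho_floor))),
    c(logit(clamp(mub_plug)), logit(clamp(x_test / n_test)),
      logit(max(null_fit$rho, .rho_floor))))
  best <- NULL
  for (s in starts) {
    f <- tryCatch(stats::optim(s, nll, method = "L-BFGS-B",
                               lower = logit(.mu_floor),
                               upper = logit(1 - .mu_floor),
                               control = list(maxit = 200L)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best))
    return(res(x_test / n_test, mub_plug, 0, 1))
  mub <- clamp(expit(best$par[1])); mut <- clamp(expit(best$par[2]))
  lambda <- max(0, 2 * (-best$value - null_fit$loglik))
  p <- if (mut > mub) max(0.5 * stats::pchisq(lambda, 1, lower.tail = FALSE),
                          1e-300) else 1
  res(mut, mub, lambda, min(p, 1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted values ("q-values"): sort p ascending, take
#' `p_(i) * m / i`, enforce monotonicity from the largest rank down, cap
#' at 1, and return in the original order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  o <- order(pvalues)
  q <- pvalues[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}
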