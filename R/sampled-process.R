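#' Probability of the number of sampled extant descendants
#'
#' For a single lineage evolving under a birth-death process with rates
#' \eqn{(\lambda, \mu)} for time `t`, each individual alive at the end is
#' sampled independently with probability \eqn{\rho}. This returns the
#' probability \eqn{p_n(t | \lambda, \mu, \rho)} of observing exactly `n`
#' sampled (extant) descendants.
#'
#' For \eqn{\lambda \neq \mu} the law is
#' \deqn{p_0(t) = 1 - \frac{\rho(\lambda-\mu)}
#'   {\rho\lambda + (\lambda(1-\rho)-\mu)e^{-(\lambda-\mu)t}}, \quad
#'   p_1(t) = \frac{\rho(\lambda-\mu)^2 e^{-(\lambda-\mu)t}}
#'   {(\rho\lambda + (\lambda(1-\rho)-\mu)e^{-(\lambda-\mu)t})^2},}
#' and \eqn{p_n(t) = p_1(t)\,(\lambda q(t))^{n-1}} for \eqn{n > 1}; the
#' critical case \eqn{\lambda = \mu} uses the corresponding limits (see
#' [q_function()]).
#'
#' @param n Number of sampled descendants (integer \eqn{\ge 0}).
#' @param t Elapsed time \eqn{\ge 0}. May be a vector.
#' @param params A [bd_params()] triplet.
#' @param log Return the log probability?
#' @return Numeric vector, one probability per `t`.
#' @export
sampled_count_probability <- function(n, t, params, log = FALSE) {
  stopifnot(inherits(params, "bd_params"))
  check_count(n, "n", min = 0L)
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be non-negative", call. = FALSE)
  cp <- to_canonical(params)
  rho <- params$sampling_prob
  if (n == 0L) {
    p <- 1 - rho * canonical_p0(t, cp)
    p <- pmin(pmax(p, 0), 1)
    if (log) base::log(p) else p
  } else {
    lp <- base::log(rho) + canonical_pn(n, t, cp, log = TRUE)
    if (log) lp else exp(lp)
  }
}

#' Auxiliary q(t) of the sampled birth-death process
#'
#' The function \eqn{q(t | \lambda, \mu, \rho)} appearing in the sampled
#' descendant distribution and in the conditioned tree densities:
#' \deqn{q(t) = \frac{\rho(1 - e^{-(\lambda-\mu)t})}
#'   {\lambda\rho + (\lambda(1-\rho)-\mu)e^{-(\lambda-\mu)t}},}
#' with critical-case limit \eqn{\rho t / (1 + \rho\lambda t)}. It satisfies
#' \eqn{q(0) = 0}, \eqn{\lambda q(t) < 1} for finite `t`, and
#' \eqn{dq/dt = p_1(t)}, so \eqn{\int_0^{t_0} p_1(s)\,ds = q(t_0)}.
#'
#' @inheritParams sampled_count_probability
#' @return Numeric vector, one value per `t`.
#' @export
q_function <- function(t, params, log = FALSE) {
  stopifnot(inherits(params, "bd_params"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be non-negative", call. = FALSE)
  lq <- base::log(params$sampling_prob) +
    canonical_q(t, to_canonical(params), log = TRUE)
  if (log) lq else exp(lq)
}

#' Canonical tilde functions of the two-parameter birth-death process
#'
#' The sampled-process quantities rescaled by \eqn{1/\rho} depend only on the
#' canonical pair \eqn{(\lambda', \mu')}:
#' \eqn{\tilde p_0 = (1 - p_0)/\rho}, \eqn{\tilde p_1 = p_1/\rho},
#' \eqn{\tilde p_n = \tilde p_1 (\lambda'\tilde q)^{n-1}},
#' \eqn{\tilde q = q/\rho}. For \eqn{\lambda' \neq \mu'} (with
#' \eqn{r = \lambda' - \mu'}):
#' \deqn{\tilde p_0(t) = \frac{r}{\lambda' - \mu' e^{-rt}}, \quad
#'   \tilde p_1(t) = \frac{r^2 e^{-rt}}{(\lambda' - \mu' e^{-rt})^2}, \quad
#'   \tilde q(t) = \frac{1 - e^{-rt}}{\lambda' - \mu' e^{-rt}},}
#' and in the critical case \eqn{\lambda' = \mu'}:
#' \eqn{\tilde p_0 = 1/(1+\lambda' t)}, \eqn{\tilde p_1 = 1/(1+\lambda' t)^2},
#' \eqn{\tilde q = t/(1+\lambda' t)}. A negative \eqn{\mu'} is a first-class
#' input: the closed forms are evaluated as written and remain finite and
#' positive.
#'
#' Note \eqn{\tilde p_1(t | \lambda', \mu') =
#' p_{1,1}(t | \lambda = \lambda', \mu = \mu', \rho = 1)} whenever
#' \eqn{\mu' \ge 0}.
#'
#' @param t Elapsed time \eqn{\ge 0}; vectorized.
#' @param cp A [canonical_params()] pair.
#' @param n Number of descendants (\eqn{\ge 1}) for `canonical_pn`.
#' @param log Return the natural logarithm?
#' @return Numeric vector, one value per `t`.
#' @name canonical_functions
NULL

#' @rdname canonical_functions
#' @export
canonical_p0 <- function(t, cp, log = FALSE) {
  v <- canon_eval(t, cp, "p0")
  if (log) v else exp(v)
}

#' @rdname canonical_functions
#' @export
canonical_p1 <- function(t, cp, log = FALSE) {
  v <- canon_eval(t, cp, "p1")
  if (log) v else exp(v)
}

#' @rdname canonical_functions
#' @export
canonical_pn <- function(n, t, cp, log = FALSE) {
  check_count(n, "n", min = 1L)
  v <- canon_eval(t, cp, "p1")
  if (n > 1L)
    v <- v + (n - 1) * (base::log(cp$lambda_prime) + canon_eval(t, cp, "q"))
  if (log) v else exp(v)
}

#' @rdname canonical_functions
#' @export
canonical_q <- function(t, cp, log = FALSE) {
  v <- canon_eval(t, cp, "q")
  if (log) v else exp(v)
}

# ---- internal --------------------------------------------------------------

# Log-scale evaluation of the tilde functions, stable for either sign of
# r = lambda' - mu' (and for mu' < 0). which is one of "p0", "p1", "q".
canon_eval <- function(t, cp, which) {
  stopifnot(inherits(cp, "canonical_params"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be non-negative", call. = FALSE)
  lam <- cp$lambda_prime
  mu <- cp$mu_prime
  r <- lam - mu
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    if (is_critical(lam, mu, ti)) {
      l1 <- log1p(lam * ti)
      out[i] <- switch(which,
                       p0 = -l1,
                       p1 = -2 * l1,
                       q = if (ti == 0) -Inf else base::log(ti) - l1)
    } else if (r > 0) {
      ld <- base::log(lam - mu * exp(-r * ti))   # > log(r) > -Inf
      out[i] <- switch(which,
                       p0 = base::log(r) - ld,
                       p1 = 2 * base::log(r) - r * ti - 2 * ld,
                       q = base::log(-expm1(-r * ti)) - ld)
    } else {
      ld <- base::log(mu - lam * exp(r * ti))    # mu > lam > 0 here
      out[i] <- switch(which,
                       p0 = base::log(-r) + r * ti - ld,
                       p1 = 2 * base::log(-r) + r * ti - 2 * ld,
                       q = base::log(-expm1(r * ti)) - ld)
    }
  }
  out
}
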