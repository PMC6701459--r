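#' Maximum-likelihood fit in canonical coordinates
#'
#' Maximizes the conditioned tree log-density over the identifiable pair
#' \eqn{\lambda' \in (0, \infty)}, \eqn{\mu' \in (-\infty, \infty)}. The
#' three-parameter surface over \eqn{(\lambda, \mu, \rho)} has a ridge (every
#' triplet mapping to the same canonical pair has the same likelihood), so
#' optimization is carried out in \eqn{(\log\lambda', \mu')} with a
#' derivative-free simplex and four starts seeded from a pure-birth (Yule)
#' estimate. The two unconditioned rows are rejected: they are not a
#' likelihood for data observed through sampling.
#'
#' @param tree A [reconstructed_tree()].
#' @param conditioning One of the five conditioned rows of [conditionings].
#' @param init Optional [canonical_params()] starting point (replaces the
#'   Yule-based starts).
#' @param max_evaluations Total objective-evaluation budget across starts.
#' @return An object of class `"bd_fit"` with fields `estimate`
#'   ([canonical_params()]), `log_likelihood`, `converged`, `n_evaluations`,
#'   `feasible_rho` ([feasible_rho_interval()] at the estimate),
#'   `standard_errors` (in \eqn{(\log\lambda', \mu')}; `NULL` unless the
#'   numerical Hessian is negative-definite), and `ridge_degenerate` (`TRUE`
#'   for data too small to identify two parameters, e.g. a single branching
#'   time).
#' @export
fit_canonical_mle <- function(tree, conditioning, init = NULL,
                              max_evaluations = 2000L) {
  stopifnot(inherits(tree, "reconstructed_tree"))
  conditioning <- match.arg(conditioning, conditionings)
  if (conditioning %in% c("uncond_stem", "uncond_crown"))
    stop("unconditioned densities are not a likelihood for sampled data; ",
         "use a conditioned row", call. = FALSE)
  check_conditioning_inputs(tree, conditioning)
  negll <- function(par) {
    v <- try(tree_log_density_canonical(
      tree, canonical_params(exp(par[1]), par[2]), conditioning), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) 1e10 else -v
  }
  starts <- if (!is.null(init)) {
    stopifnot(inherits(init, "canonical_params"))
    list(c(base::log(init$lambda_prime), init$mu_prime))
  } else {
    times <- c(tree$branching_times, tree$stem_age)
    lam0 <- max((tree$n - 2) / max(sum(times), .Machine$double.eps), 0.1)
    list(c(base::log(lam0), lam0 / 2),
         c(base::log(lam0), -lam0 / 2),
         c(base::log(2 * lam0), lam0 / 2),
         c(base::log(lam0 / 2), -lam0 / 2))
  }
  budget <- ceiling(max_evaluations / length(starts))
  best <- NULL
  nev <- 0L
  conv <- FALSE
  for (s in starts) {
    fit <- stats::optim(s, negll, method = "Nelder-Mead",
                        control = list(maxit = budget, reltol = 1e-10))
    nev <- nev + fit$counts[["function"]]
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) conv <- TRUE
  }
  est <- canonical_params(exp(best$par[1]), best$par[2])
  # curvature in (log lambda', mu'); flat or indefinite => ridge-degenerate
  hess <- try(stats::optimHess(best$par, negll), silent = TRUE)
  se <- NULL
  degenerate <- tree$n <= 2L
  if (!inherits(hess, "try-error") && all(is.finite(hess))) {
    ev <- eigen(hess, symmetric = TRUE, only.values = TRUE)$values
    if (all(ev > 0) && min(ev) > 1e-8 * max(abs(ev))) {
      se <- sqrt(diag(solve(hess)))
      names(se) <- c("log_lambda_prime", "mu_prime")
    } else {
      degenerate <- TRUE
    }
  } else {
    degenerate <- TRUE
  }
  structure(list(estimate = est,
                 log_likelihood = -best$value,
                 converged = conv,
                 n_evaluations = nev,
                 feasible_rho = feasible_rho_interval(est),
                 standard_errors = se,
                 ridge_degenerate = degenerate,
                 conditioning = conditioning),
            class = "bd_fit")
}

#' @export
print.bd_fit <- function(x, ...) {
  cat(sprintf("Birth-death fit (%s): lambda' = %.6g, mu' = %.6g\n",
              x$conditioning, x$estimate$lambda_prime, x$estimate$mu_prime))
  cat(sprintf("  log-likelihood %.6f after %d evaluations (%s)\n",
              x$log_likelihood, x$n_evaluations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  back-transformable for rho in (0, %g]\n", x$feasible_rho$upper))
  if (x$ridge_degenerate)
    cat("  warning: curvature is flat/degenerate; the two parameters are not\n",
        "  jointly identified by these data\n", sep = "")
  invisible(x)
}

#' Likelihood ridge over the sampling probability
#'
#' For each `rho` on a grid, back-transforms a canonical fit to the triplet
#' \eqn{(\lambda'/\rho,\ \mu'-\lambda'+\lambda'/\rho,\ \rho)} and re-evaluates
#' the triplet log-likelihood of the tree. All feasible rows have the same
#' log-likelihood - the ridge that makes the three-parameter fit
#' ill-posed - while rows beyond the feasibility bound are flagged rather
#' than evaluated. This is also why a likelihood comparison of
#' "complete sampling" against "incomplete sampling" is meaningless: every
#' \eqn{\rho = 1} model has equal-likelihood counterparts at smaller
#' \eqn{\rho}, and some \eqn{\rho < 1} models have no \eqn{\rho = 1}
#' counterpart at all.
#'
#' @param tree A [reconstructed_tree()].
#' @param fit A `"bd_fit"` from [fit_canonical_mle()] (or any
#'   [canonical_params()]).
#' @param rho_grid Values in (0, 1] to profile over.
#' @param conditioning Conditioned row to evaluate; defaults to the fit's.
#' @return A data frame with columns `rho`, `lambda`, `mu`, `log_likelihood`,
#'   `feasible`; `lambda`/`mu`/`log_likelihood` are `NA` on infeasible rows.
#' @export
ridge_profile <- function(tree, fit, rho_grid, conditioning = NULL) {
  cp <- if (inherits(fit, "bd_fit")) fit$estimate else fit
  stopifnot(inherits(cp, "canonical_params"))
  if (is.null(conditioning)) {
    if (!inherits(fit, "bd_fit"))
      stop("supply a conditioning when profiling bare canonical parameters",
           call. = FALSE)
    conditioning <- fit$conditioning
  }
  conditioning <- match.arg(conditioning, conditionings)
  upper <- feasible_rho_interval(cp)$upper
  rows <- lapply(rho_grid, function(rho) {
    if (rho <= 0 || rho > upper + 1e-12) {
      data.frame(rho = rho, lambda = NA_real_, mu = NA_real_,
                 log_likelihood = NA_real_, feasible = FALSE)
    } else {
      p <- from_canonical(cp, rho)
      data.frame(rho = rho, lambda = p$birth_rate, mu = p$death_rate,
                 log_likelihood = tree_log_density(tree, p, conditioning),
                 feasible = TRUE)
    }
  })
  do.call(rbind, rows)
}

#' Prior distribution specification
#'
#' Small helper describing a univariate prior for
#' [effective_prior_pushforward()]. Supported families: `"uniform"`
#' (`min`, `max`), `"exponential"` (`rate`), `"normal"` (`mean`, `sd`), and
#' `"point"` (`value`).
#'
#' @param family One of `"uniform"`, `"exponential"`, `"normal"`, `"point"`.
#' @param ... Family parameters, see above.
#' @return An object of class `"dist_spec"`.
#' @export
dist_spec <- function(family = c("uniform", "exponential", "normal", "point"),
                      ...) {
  family <- match.arg(family)
  pars <- list(...)
  needed <- switch(family,
                   uniform = c("min", "max"),
                   exponential = "rate",
                   normal = c("mean", "sd"),
                   point = "value")
  if (!all(needed %in% names(pars)))
    stop("missing parameters: ", paste(setdiff(needed, names(pars)),
                                       collapse = ", "), call. = FALSE)
  structure(list(family = family, pars = pars[needed]), class = "dist_spec")
}

draw_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$pars
  switch(spec$family,
         uniform = stats::runif(n, p$min, p$max),
         exponential = stats::rexp(n, p$rate),
         normal = stats::rnorm(n, p$mean, p$sd),
         point = rep.int(p$value, n))
}

#' Effective prior on (lambda, mu, rho) induced by canonical priors
#'
#' Demonstrates how priors placed on the canonical pair propagate to the
#' redundant triplet: \eqn{(\lambda', \mu')} is drawn from the given priors,
#' \eqn{\rho} uniformly on its feasible interval, and the triplet obtained by
#' back-transformation. When the \eqn{\mu'} prior has mass on negative
#' values, the feasible interval shrinks below (0, 1] for part of the draws
#' and the induced \eqn{\rho} marginal is pushed towards small values - it is
#' no longer uniform. Draws with \eqn{\lambda' \le 0} are rejected and
#' counted.
#'
#' @param prior_lambda_prime,prior_mu_prime [dist_spec()] priors.
#' @param n_samples Number of accepted draws to return.
#' @param seed Optional integer seed.
#' @return A data frame with columns `lambda_prime`, `mu_prime`, `rho`,
#'   `lambda`, `mu`; the attribute `"rejected"` counts discarded
#'   \eqn{\lambda' \le 0} draws.
#' @export
effective_prior_pushforward <- function(prior_lambda_prime, prior_mu_prime,
                                        n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out_lp <- numeric(0)
  out_mp <- numeric(0)
  rejected <- 0L
  while (length(out_lp) < n_samples) {
    need <- n_samples - length(out_lp)
    lp <- draw_dist(prior_lambda_prime, need)
    mp <- draw_dist(prior_mu_prime, need)
    keep <- lp > 0
    rejected <- rejected + sum(!keep)
    out_lp <- c(out_lp, lp[keep])
    out_mp <- c(out_mp, mp[keep])
    if (rejected > 1e3 * (n_samples + 1))
      stop("prior places essentially no mass on lambda' > 0", call. = FALSE)
  }
  upper <- ifelse(out_mp >= 0, 1, pmin(1, 1 / (1 - out_mp / out_lp)))
  rho <- stats::runif(n_samples, 0, upper)
  lambda <- out_lp / rho
  mu <- out_mp - out_lp + lambda
  res <- data.frame(lambda_prime = out_lp, mu_prime = out_mp, rho = rho,
                    lambda = lambda, mu = pmax(mu, 0))
  attr(res, "rejected") <- rejected
  res
}
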