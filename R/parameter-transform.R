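#' Map a sampled birth-death triplet to canonical coordinates
#'
#' The transformation \eqn{\lambda' = \rho\lambda},
#' \eqn{\mu' = \mu - \lambda(1-\rho)}. It preserves the net diversification
#' rate exactly: \eqn{\lambda' - \mu' = \lambda - \mu}. With \eqn{\rho = 1} it
#' is the identity; \eqn{\mu'} may be negative (e.g. \eqn{\lambda = 4\mu},
#' \eqn{\rho = 0.5} yields \eqn{\mu' = -\mu}).
#'
#' @param params A [bd_params()] triplet with \eqn{\lambda > 0}.
#' @return A [canonical_params()] pair.
#' @export
to_canonical <- function(params) {
  stopifnot(inherits(params, "bd_params"))
  if (params$birth_rate <= 0)
    stop("lambda must be strictly positive to generate trees", call. = FALSE)
  canonical_params(params$sampling_prob * params$birth_rate,
                   params$death_rate -
                     params$birth_rate * (1 - params$sampling_prob))
}

#' Back-transform canonical coordinates to a birth-death triplet
#'
#' For a chosen sampling probability \eqn{\rho} inside
#' [feasible_rho_interval()], returns the triplet
#' \eqn{\lambda = \lambda'/\rho}, \eqn{\mu = \mu' - \lambda' + \lambda'/\rho},
#' which yields the same conditioned tree probability density as `cp`. At the
#' upper feasibility boundary \eqn{\rho = 1/(1 - \mu'/\lambda')} (relevant
#' when \eqn{\mu' < 0}) the implied \eqn{\mu} is exactly 0; tiny negative
#' values from float rounding (\eqn{\ge -10^{-12}}) are clamped to 0.
#'
#' @param cp A [canonical_params()] pair.
#' @param rho Sampling probability in the feasible interval.
#' @return A [bd_params()] triplet; `to_canonical(from_canonical(cp, rho))`
#'   recovers `cp` exactly.
#' @export
from_canonical <- function(cp, rho) {
  stopifnot(inherits(cp, "canonical_params"),
            is.numeric(rho), length(rho) == 1L, is.finite(rho))
  iv <- feasible_rho_interval(cp)
  if (rho <= 0 || rho > iv$upper + 1e-12)
    stop(sprintf("rho = %g outside the feasible interval (0, %g]", rho, iv$upper),
         call. = FALSE)
  lambda <- cp$lambda_prime / rho
  mu <- cp$mu_prime - cp$lambda_prime + lambda
  if (mu < -1e-12 * max(1, lambda))
    stop(sprintf("rho = %g implies a negative death rate %g", rho, mu),
         call. = FALSE)
  # float dust at the feasibility boundary collapses to an exact zero
  if (abs(mu) < 1e-12 * max(1, lambda)) mu <- 0
  bd_params(lambda, mu, min(rho, 1))
}

#' Feasible sampling probabilities for a canonical pair
#'
#' The set of \eqn{\rho} for which `cp` back-transforms to a proper triplet
#' \eqn{(\lambda > 0, \mu \ge 0, \rho \in (0,1])}: all of \eqn{(0, 1]} when
#' \eqn{\mu' \ge 0}, and \eqn{(0, \min(1, 1/(1-\mu'/\lambda'))]} when
#' \eqn{\mu' < 0}.
#'
#' @param cp A [canonical_params()] pair.
#' @return An object of class `"rho_interval"` with fields `lower` (always 0,
#'   exclusive) and `upper` (inclusive).
#' @export
feasible_rho_interval <- function(cp) {
  stopifnot(inherits(cp, "canonical_params"))
  upper <- if (cp$mu_prime >= 0) 1
           else min(1, 1 / (1 - cp$mu_prime / cp$lambda_prime))
  structure(list(lower = 0, upper = upper), class = "rho_interval")
}

#' @export
print.rho_interval <- function(x, ...) {
  cat(sprintf("Feasible sampling probabilities: (0, %g]\n", x$upper))
  invisible(x)
}

#' Equivalent birth-death triplet at another sampling probability
#'
#' Given a triplet \eqn{(\lambda, \mu, \rho)} and a target sampling
#' probability `rho_hat`, returns the triplet
#' \eqn{(\hat\lambda, \hat\mu, \hat\rho)} with
#' \eqn{\lambda\rho = \hat\lambda\hat\rho} and
#' \eqn{\mu - \lambda(1-\rho) = \hat\mu - \hat\lambda(1-\hat\rho)}; the two
#' triplets give identical conditioned tree probability densities. The target
#' is feasible for every \eqn{\hat\rho \in (0,1]} when \eqn{\mu/\lambda \ge 1},
#' and for \eqn{\hat\rho \le \rho/(1 - \mu/\lambda)} when
#' \eqn{\mu/\lambda < 1}. Infeasibility is returned as a value (class
#' `"bd_infeasible"` carrying the violated bound), not as an error.
#'
#' @param params A [bd_params()] triplet.
#' @param rho_hat Target sampling probability in (0, 1].
#' @return A [bd_params()] triplet, or a `"bd_infeasible"` object whose
#'   `rho_max` field is the largest feasible target.
#' @seealso [complete_sampling_equivalent()], [is_feasible()]
#' @export
equivalent_triplet <- function(params, rho_hat) {
  stopifnot(inherits(params, "bd_params"),
            is.numeric(rho_hat), length(rho_hat) == 1L,
            is.finite(rho_hat), rho_hat > 0, rho_hat <= 1)
  cp <- to_canonical(params)
  iv <- feasible_rho_interval(cp)
  if (rho_hat > iv$upper + 1e-12) {
    return(structure(list(rho_hat = rho_hat, rho_max = iv$upper),
                     class = "bd_infeasible"))
  }
  from_canonical(cp, rho_hat)
}

#' @export
print.bd_infeasible <- function(x, ...) {
  cat(sprintf(
    "Infeasible transformation: rho_hat = %g exceeds the feasible bound %g\n",
    x$rho_hat, x$rho_max))
  invisible(x)
}

#' Is a transformation result feasible?
#'
#' @param x Result of [equivalent_triplet()] or
#'   [complete_sampling_equivalent()].
#' @return `TRUE` for a [bd_params()] triplet, `FALSE` for a
#'   `"bd_infeasible"` marker.
#' @export
is_feasible <- function(x) !inherits(x, "bd_infeasible")

#' Complete-sampling equivalent of a sampled triplet
#'
#' Convenience wrapper of [equivalent_triplet()] with \eqn{\hat\rho = 1}: the
#' completely sampled process with the same conditioned tree density. It
#' exists iff \eqn{\mu/\lambda \ge 1 - \rho} (always when
#' \eqn{\mu/\lambda \ge 1}); for \eqn{0 \le \mu/\lambda < 1 - \rho} no such
#' process exists because the implied death rate \eqn{\mu'} is negative.
#'
#' @param params A [bd_params()] triplet.
#' @return A [bd_params()] with `sampling_prob = 1`, or a `"bd_infeasible"`
#'   marker.
#' @export
complete_sampling_equivalent <- function(params) {
  equivalent_triplet(params, 1)
}
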