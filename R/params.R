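#' Birth-death rate pair
#'
#' Container for the per-lineage birth rate \eqn{\lambda} and death rate
#' \eqn{\mu} of a linear (constant-rate) birth-death process. Both rates are
#' per unit time; at least one must be strictly positive for nontrivial
#' dynamics.
#'
#' @param birth_rate Birth (speciation) rate \eqn{\lambda \ge 0}.
#' @param death_rate Death (extinction) rate \eqn{\mu \ge 0}.
#' @return An object of class `"rate_pair"`.
#' @examples
#' rate_pair(1, 0.5)
#' @export
rate_pair <- function(birth_rate, death_rate) {
  stopifnot(is.numeric(birth_rate), length(birth_rate) == 1L,
            is.numeric(death_rate), length(death_rate) == 1L)
  if (!is.finite(birth_rate) || !is.finite(death_rate))
    stop("rates must be finite", call. = FALSE)
  if (birth_rate < 0 || death_rate < 0)
    stop("rates must be non-negative", call. = FALSE)
  structure(list(birth_rate = as.numeric(birth_rate),
                 death_rate = as.numeric(death_rate)),
            class = "rate_pair")
}

#' @export
print.rate_pair <- function(x, ...) {
  cat(sprintf("Birth-death rates: lambda = %g, mu = %g\n",
              x$birth_rate, x$death_rate))
  invisible(x)
}

#' Birth-death parameters with sampling probability
#'
#' The biological parameter triplet of the sampled birth-death process: birth
#' rate \eqn{\lambda}, death rate \eqn{\mu}, and the probability
#' \eqn{\rho \in (0, 1]} that each individual alive at the present is sampled
#' (independently).
#'
#' @param birth_rate Birth rate \eqn{\lambda \ge 0}.
#' @param death_rate Death rate \eqn{\mu \ge 0}.
#' @param sampling_prob Sampling probability \eqn{\rho \in (0, 1]}.
#' @return An object of class `"bd_params"` (also inheriting `"rate_pair"`).
#' @seealso [to_canonical()] for the identifiable two-parameter form.
#' @examples
#' bd_params(1, 0.5, 0.8)
#' @export
bd_params <- function(birth_rate, death_rate, sampling_prob = 1) {
  rp <- rate_pair(birth_rate, death_rate)
  stopifnot(is.numeric(sampling_prob), length(sampling_prob) == 1L)
  if (!is.finite(sampling_prob) || sampling_prob <= 0 || sampling_prob > 1)
    stop("sampling_prob must lie in (0, 1]", call. = FALSE)
  structure(c(rp, list(sampling_prob = as.numeric(sampling_prob))),
            class = c("bd_params", "rate_pair"))
}

#' @export
print.bd_params <- function(x, ...) {
  cat(sprintf("Sampled birth-death parameters: lambda = %g, mu = %g, rho = %g\n",
              x$birth_rate, x$death_rate, x$sampling_prob))
  invisible(x)
}

#' Canonical (identifiable) birth-death parameters
#'
#' The identifiable pair \eqn{(\lambda', \mu')} with
#' \eqn{\lambda' = \rho\lambda} and \eqn{\mu' = \mu - \lambda(1 - \rho)}.
#' \eqn{\mu'} may be negative, in which case it cannot be interpreted as a
#' death rate of any completely sampled process; \eqn{\lambda'} must be
#' strictly positive. The difference \eqn{\lambda' - \mu'} always equals
#' \eqn{\lambda - \mu} of any generating triplet.
#'
#' @param lambda_prime Canonical birth rate \eqn{\lambda' > 0}.
#' @param mu_prime Canonical death rate \eqn{\mu'}, any real value.
#' @return An object of class `"canonical_params"`.
#' @seealso [to_canonical()], [from_canonical()], [feasible_rho_interval()]
#' @examples
#' canonical_params(2, -1)
#' @export
canonical_params <- function(lambda_prime, mu_prime) {
  stopifnot(is.numeric(lambda_prime), length(lambda_prime) == 1L,
            is.numeric(mu_prime), length(mu_prime) == 1L)
  if (!is.finite(lambda_prime) || !is.finite(mu_prime))
    stop("canonical parameters must be finite", call. = FALSE)
  if (lambda_prime <= 0)
    stop("lambda_prime must be strictly positive", call. = FALSE)
  structure(list(lambda_prime = as.numeric(lambda_prime),
                 mu_prime = as.numeric(mu_prime)),
            class = "canonical_params")
}

#' @export
print.canonical_params <- function(x, ...) {
  cat(sprintf("Canonical birth-death parameters: lambda' = %g, mu' = %g\n",
              x$lambda_prime, x$mu_prime))
  invisible(x)
}

# Internal: accept either a bare (lambda, mu) pair or a rate_pair/bd_params.
as_rate_pair <- function(rates) {
  if (inherits(rates, "rate_pair")) return(rates)
  if (is.numeric(rates) && length(rates) == 2L) return(rate_pair(rates[1], rates[2]))
  stop("expected a rate_pair or a numeric vector c(lambda, mu)", call. = FALSE)
}

# Critical-case switch: lambda ~= mu relative to the elapsed time, chosen so
# alpha/beta stay continuous across the boundary without catastrophic
# cancellation.
is_critical <- function(lambda, mu, t) {
  abs(lambda - mu) * t < 1e-9 * (1 + lambda * t)
}
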