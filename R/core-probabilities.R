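#' Classical birth-death transition probabilities
#'
#' Probability \eqn{p_{n,m}(t | \lambda, \mu)} that a linear birth-death
#' process starting with `n` individuals has `m` individuals a time `t` later,
#' with no sampling involved.
#'
#' The single-lineage law is geometric:
#' \eqn{p_{1,0} = \alpha}, \eqn{p_{1,m} = (1-\alpha)(1-\beta)\beta^{m-1}}
#' with \eqn{\alpha = \mu(e^{rt}-1)/(\lambda e^{rt}-\mu)},
#' \eqn{\beta = \lambda(e^{rt}-1)/(\lambda e^{rt}-\mu)}, \eqn{r = \lambda-\mu};
#' in the critical case \eqn{\lambda = \mu} both reduce to
#' \eqn{\lambda t/(1+\lambda t)}. A start of `n` independent lineages composes
#' the law n-fold:
#' \deqn{p_{n,m} = \sum_{j=1}^{\min(n,m)} \binom{n}{j} \alpha^{n-j}
#'   \left[(1-\alpha)(1-\beta)\right]^j \binom{m-1}{j-1} \beta^{m-j},}
#' and \eqn{p_{n,0} = \alpha^n}. Evaluation uses the numerically stable branch
#' for the sign of \eqn{r}, so rates up to order 100 are safe.
#'
#' @param n Starting number of individuals (integer, \eqn{\ge 1}).
#' @param m Number of individuals after time `t` (integer, \eqn{\ge 0}).
#' @param t Elapsed time, \eqn{\ge 0}. May be a vector.
#' @param rates A [rate_pair()] (or numeric `c(lambda, mu)`).
#' @param log Return the log probability?
#' @return Numeric vector of probabilities (or log probabilities), one per `t`.
#' @seealso [tilde_transition()] for the interchange-symmetric scaled form,
#'   [transition_oracle()] for an independent generator-exponential check.
#' @examples
#' transition_probability(1, 1, 1, rate_pair(1, 0))  # exp(-1)
#' @export
transition_probability <- function(n, m, t, rates, log = FALSE) {
  rates <- as_rate_pair(rates)
  check_count(n, "n", min = 1L)
  check_count(m, "m", min = 0L)
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be non-negative", call. = FALSE)
  ab <- alpha_beta(rates$birth_rate, rates$death_rate, t)
  lp <- log_pnm(n, m, ab$log_alpha, ab$log_beta, ab$log_1ma, ab$log_1mb)
  if (log) lp else exp(lp)
}

#' Tilde-scaled transition probability
#'
#' The scaled form \eqn{\tilde p_{n,m}(t|\lambda,\mu) = \lambda^n \mu^m
#' p_{n,m}(t|\lambda,\mu)}, which is invariant under interchanging the birth
#' and death rates: \eqn{\tilde p_{n,m}(t|\lambda,\mu) =
#' \tilde p_{n,m}(t|\mu,\lambda)} for all \eqn{n \ge 1}, \eqn{m \ge 0}. The
#' diagonal case \eqn{m = n} gives the bare symmetry
#' \eqn{p_{n,n}(t|\lambda,\mu) = p_{n,n}(t|\mu,\lambda)}.
#'
#' @inheritParams transition_probability
#' @return Non-negative numeric vector, one value per `t`.
#' @examples
#' tilde_transition(1, 1, 0.5, rate_pair(100, 1))
#' tilde_transition(1, 1, 0.5, rate_pair(1, 100))  # identical
#' @export
tilde_transition <- function(n, m, t, rates) {
  rates <- as_rate_pair(rates)
  check_count(n, "n", min = 1L)
  check_count(m, "m", min = 0L)
  rates$birth_rate^n * rates$death_rate^m *
    transition_probability(n, m, t, rates)
}

#' Generator-exponential oracle for transition probabilities
#'
#' Computes the full distribution of the population size after time `t` by
#' exponentiating the birth-death generator truncated to states
#' `0..truncation` (birth rate \eqn{k\lambda}, death rate \eqn{k\mu} from
#' state `k`). This is an independent numerical route used to validate the
#' closed-form [transition_probability()]; the truncation must be generous
#' enough that the probability mass escaping above it is below `tail_tol`.
#' Small state spaces use dense Pade exponentiation ([Matrix::expm()]);
#' truncations above 400 evaluate the same exponential by the uniformized
#' Poisson series, which only touches the required row.
#'
#' @param n Starting population size (\eqn{\ge 1}).
#' @param t Elapsed time (scalar, \eqn{\ge 0}).
#' @param rates A [rate_pair()].
#' @param truncation Highest state retained; must be at least `10 * n`.
#' @param tail_tol Maximum tolerated probability deficit (mass lost above the
#'   truncation).
#' @return Numeric vector of length `truncation + 1`: probabilities of
#'   population sizes `0..truncation`; sums to 1 within `tail_tol`.
#' @export
transition_oracle <- function(n, t, rates, truncation, tail_tol = 1e-12) {
  rates <- as_rate_pair(rates)
  check_count(n, "n", min = 1L)
  stopifnot(length(t) == 1L, is.finite(t), t >= 0)
  truncation <- as.integer(truncation)
  if (truncation < 10L * n)
    stop("truncation must be at least 10 * n", call. = FALSE)
  k <- 0:truncation
  lam <- rates$birth_rate
  mu <- rates$death_rate
  Q <- Matrix::bandSparse(truncation + 1L, truncation + 1L, k = c(-1L, 0L, 1L),
                          diagonals = list(k[-1L] * mu,
                                           -k * (lam + mu),
                                           k[-(truncation + 1L)] * lam))
  p <- if (truncation <= 400L) {
    as.numeric(Matrix::expm(Q * t)[n + 1L, ])
  } else {
    # uniformized evaluation of the same matrix exponential: with
    # Lambda = max exit rate, exp(tQ) = sum_k dpois(k, Lambda t) P^k,
    # P = I + Q/Lambda; only the row e_n^T exp(tQ) is accumulated.
    Lambda <- truncation * (lam + mu)
    if (Lambda * t == 0) {
      as.numeric(seq_along(k) == n + 1L)
    } else {
      P <- Matrix::Diagonal(truncation + 1L) + Q / Lambda
      kmax <- stats::qpois(1e-14, Lambda * t, lower.tail = FALSE) + 10L
      v <- as.numeric(seq_along(k) == n + 1L)
      acc <- stats::dpois(0, Lambda * t) * v
      for (j in seq_len(kmax)) {
        v <- as.numeric(v %*% P)
        acc <- acc + stats::dpois(j, Lambda * t) * v
      }
      acc
    }
  }
  p <- pmax(p, 0)
  deficit <- 1 - sum(p)
  if (deficit > tail_tol)
    stop(sprintf("truncation too small: tail mass %.3e exceeds %.1e",
                 deficit, tail_tol), call. = FALSE)
  p
}

# ---- internal machinery ----------------------------------------------------

check_count <- function(x, name, min) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("%s must be a single integer >= %d", name, min), call. = FALSE)
  invisible(TRUE)
}

# log(alpha), log(beta), log(1-alpha), log(1-beta) of the single-lineage
# geometric law, on the branch that avoids overflow for either sign of
# r = lambda - mu:
#   r >= 0, x = exp(-rt): alpha = mu(1-x)/(lambda - mu x)
#                         1-alpha = r/(lambda - mu x)
#                         beta  = lambda(1-x)/(lambda - mu x)
#                         1-beta = r x/(lambda - mu x)
#   r < 0,  y = exp(rt):  alpha = mu(1-y)/(mu - lambda y)
#                         1-alpha = -r y/(mu - lambda y)
#                         beta  = lambda(1-y)/(mu - lambda y)
#                         1-beta = -r/(mu - lambda y)
alpha_beta <- function(lambda, mu, t) {
  nt <- length(t)
  la <- lb <- l1a <- l1b <- numeric(nt)
  for (i in seq_len(nt)) {
    ti <- t[i]
    if (is_critical(lambda, mu, ti)) {
      # alpha = beta = lambda t / (1 + lambda t)
      lab <- log(lambda * ti) - log1p(lambda * ti)
      la[i] <- lb[i] <- lab
      l1a[i] <- l1b[i] <- -log1p(lambda * ti)
      next
    }
    r <- lambda - mu
    if (r > 0) {
      lx1 <- log(-expm1(-r * ti))                  # log(1 - e^{-rt})
      ld <- log(lambda - mu * exp(-r * ti))        # log(lambda - mu x) > log(r) > -Inf
      la[i] <- log(mu) + lx1 - ld
      lb[i] <- log(lambda) + lx1 - ld
      l1a[i] <- log(r) - ld
      l1b[i] <- log(r) - r * ti - ld
    } else {
      lx1 <- log(-expm1(r * ti))                   # log(1 - e^{rt})
      ld <- log(mu - lambda * exp(r * ti))
      la[i] <- log(mu) + lx1 - ld
      lb[i] <- log(lambda) + lx1 - ld
      l1a[i] <- log(-r) + r * ti - ld
      l1b[i] <- log(-r) - ld
    }
  }
  list(log_alpha = la, log_beta = lb, log_1ma = l1a, log_1mb = l1b)
}

# k * l with the convention 0 * (-Inf) = 0 (empty factor).
xmul <- function(k, l) ifelse(k == 0, 0, k * l)

# log p_{n,m} from log alpha/beta pieces; handles the degenerate pure-birth
# (alpha = 0, log_alpha = -Inf) and pure-death (beta = 0) cases because
# impossible terms carry -Inf and drop out of the log-sum-exp.
log_pnm <- function(n, m, log_alpha, log_beta, log_1ma, log_1mb) {
  nt <- length(log_alpha)
  out <- numeric(nt)
  for (i in seq_len(nt)) {
    la <- log_alpha[i]; lb <- log_beta[i]
    l1a <- log_1ma[i]; l1b <- log_1mb[i]
    if (m == 0L) {
      out[i] <- n * la
      next
    }
    j <- seq_len(min(n, m))
    terms <- lchoose(n, j) + xmul(n - j, la) + j * (l1a + l1b) +
      lchoose(m - 1, j - 1) + xmul(m - j, lb)
    mx <- max(terms)
    out[i] <- if (is.finite(mx)) mx + log(sum(exp(terms - mx))) else -Inf
  }
  out
}
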