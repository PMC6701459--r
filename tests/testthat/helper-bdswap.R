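# Shared grids and small utilities for the suite.

# Rate/time grid over which the interchange symmetry and oracle agreement
# are asserted.
sym_grid <- expand.grid(lambda = c(0.3, 1, 2.5), mu = c(0.3, 1, 2.5),
                        t = c(0.1, 0.5, 1, 2))

# Canonical-parameter grid for the tilde-function symmetries (mu' >= 0).
tilde_grid <- expand.grid(lambda_prime = c(0.5, 1, 2),
                          mu_prime = c(0, 0.3, 1, 1.7),
                          t = c(0.1, 0.5, 1, 2))

# Oracle with adaptive truncation: size the state space from the geometric
# tail rate of the single-lineage law, then escalate if the tail-mass check
# still fails.
oracle_adaptive <- function(n, t, rates) {
  p11 <- transition_probability(1, 1, t, rates)
  beta <- transition_probability(1, 2, t, rates) / p11
  M <- max(20L * n, 200L,
           if (beta > 0 && beta < 1) ceiling(log(1e-14) / log(beta)) + 100L)
  repeat {
    p <- try(transition_oracle(n, t, rates, truncation = M), silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
    M <- ceiling(M * 1.6)
    if (M > 20000L) stop("oracle truncation insufficient even at 20000")
  }
}

# Limiting tilde forms at a zero first argument (lambda' -> 0+), used to
# check the swap identities at mu' = 0 where the swapped pair (0, lambda')
# is outside the constructor's domain.
limit_p0_zero_first <- function(t, other) exp(-other * t)
limit_q_zero_first <- function(t, other) (1 - exp(-other * t)) / other
limit_pn_zero_first <- function(n, t, other) {
  if (n == 1) exp(-other * t) else 0
}

# Random valid triplet.
random_bd_params <- function() {
  bd_params(runif(1, 0.1, 3), runif(1, 0, 3), runif(1, 0.05, 1))
}

# Draw crown age by forward first-passage of the population size to n
# (count-level Gillespie from two individuals; extinct runs are redrawn).
draw_crown_age_first_passage <- function(n, lambda, mu) {
  total <- lambda + mu
  repeat {
    size <- 2L
    now <- 0
    while (size > 0L && size < n) {
      now <- now + rexp(1L, size * total)
      size <- size + (if (runif(1L) < lambda / total) 1L else -1L)
    }
    if (size >= n) return(now)
  }
}

# Simulate a crown-and-n tree: crown age by first passage, interior
# branching times from the exact conditioned density.
simulate_crown_n_tree <- function(n, cp) {
  t1 <- draw_crown_age_first_passage(n, cp$lambda_prime,
                                     max(cp$mu_prime, 0))
  inner <- sample_branching_times(n - 2L, t1, cp)
  reconstructed_tree(c(t1, sort(inner, decreasing = TRUE)))
}
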