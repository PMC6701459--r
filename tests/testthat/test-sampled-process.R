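test_that("sampled-descendant probabilities reduce correctly at the edges", {
  p <- bd_params(1.4, 0.6, 0.7)
  # at t = 0 the lineage itself is the only candidate descendant
  expect_equal(sampled_count_probability(0, 0, p), 0.3, tolerance = 1e-12)
  expect_equal(sampled_count_probability(1, 0, p), 0.7, tolerance = 1e-12)
  expect_equal(sampled_count_probability(2, 0, p), 0, tolerance = 1e-12)
  # long-run extinction probability mu/lambda, independent of rho
  expect_equal(sampled_count_probability(0, 80, bd_params(2, 1, 0.5)), 0.5,
               tolerance = 1e-10)
  expect_equal(sampled_count_probability(0, 80, bd_params(2, 1, 0.9)), 0.5,
               tolerance = 1e-10)
  # subcritical: extinction is certain
  expect_equal(sampled_count_probability(0, 200, bd_params(0.5, 1, 0.8)), 1,
               tolerance = 1e-10)
  expect_error(sampled_count_probability(-1, 1, p), "n must be")
  expect_error(sampled_count_probability(1, -1, p), "non-negative")
})

test_that("q(t) satisfies its boundary values and quadrature identity", {
  expect_equal(q_function(0, bd_params(1, 0.5, 0.8)), 0)
  expect_equal(q_function(1, bd_params(1, 0, 1)), 1 - exp(-1),
               tolerance = 1e-12)
  # dq/dt = p_1 so q(t) is the integral of the one-descendant probability
  set.seed(42)
  for (rep in 1:6) {
    p <- random_bd_params()
    t_up <- runif(1, 0.5, 3)
    val <- stats::integrate(function(s) sampled_count_probability(1, s, p),
                            0, t_up, rel.tol = 1e-10)$value
    expect_equal(val, q_function(t_up, p), tolerance = 1e-8)
  }
  # lambda * q < 1 for finite t (approaching 1 from below as t grows)
  p <- bd_params(2, 0.3, 0.6)
  for (t in c(0.1, 1, 10)) expect_lt(p$birth_rate * q_function(t, p), 1)
  expect_lte(p$birth_rate * q_function(100, p), 1)
})

test_that("the sampled-count distribution is normalized in closed form", {
  params <- list(bd_params(1, 0.5, 1), bd_params(1, 0.5, 0.6),
                 bd_params(1, 1, 0.8), bd_params(0.5, 1, 0.9),
                 bd_params(2.5, 2.5, 0.3))
  for (p in params) for (t in c(0.2, 1, 3)) {
    p0 <- sampled_count_probability(0, t, p)
    p1 <- sampled_count_probability(1, t, p)
    lq <- p$birth_rate * q_function(t, p)
    expect_lt(abs(p0 + p1 / (1 - lq) - 1), 1e-12)
  }
})

test_that("canonical tilde functions are consistent with the triplet forms", {
  set.seed(7)
  for (rep in 1:10) {
    p <- random_bd_params()
    cp <- to_canonical(p)
    rho <- p$sampling_prob
    for (t in c(0.3, 1.2, 2.5)) {
      expect_equal(rho * canonical_p1(t, cp),
                   sampled_count_probability(1, t, p), tolerance = 1e-12)
      expect_equal(rho * canonical_pn(4, t, cp),
                   sampled_count_probability(4, t, p), tolerance = 1e-12)
      expect_equal(rho * canonical_q(t, cp), q_function(t, p),
                   tolerance = 1e-12)
      expect_equal(rho * canonical_p0(t, cp),
                   1 - sampled_count_probability(0, t, p), tolerance = 1e-12)
    }
  }
  # at t = 0: p~0 = 1
  expect_equal(canonical_p0(0, canonical_params(1.3, 0.2)), 1)
  # complete sampling: p~1 is the bare p_{1,1}
  expect_equal(canonical_p1(0.8, canonical_params(1.5, 0.4)),
               transition_probability(1, 1, 0.8, rate_pair(1.5, 0.4)),
               tolerance = 1e-12)
  # negative mu': cross-parameterization against the generating triplet
  cp <- canonical_params(2, -1)
  p <- bd_params(4, 1, 0.5)
  v <- canonical_pn(3, 1, cp)
  expect_true(is.finite(v) && v > 0)
  expect_equal(v, sampled_count_probability(3, 1, p) / 0.5, tolerance = 1e-12)
  expect_error(canonical_params(0, 1), "strictly positive")
})

test_that("swap identities of the tilde functions hold for mu' >= 0", {
  for (i in seq_len(nrow(tilde_grid))) {
    lp <- tilde_grid$lambda_prime[i]
    mp <- tilde_grid$mu_prime[i]
    t <- tilde_grid$t[i]
    cp <- canonical_params(lp, mp)
    if (mp > 0) {
      sw <- canonical_params(mp, lp)
      expect_lt(abs(lp * (1 - canonical_p0(t, cp)) -
                    mp * (1 - canonical_p0(t, sw))), 1e-10)
      expect_lt(abs(canonical_p0(t, cp) -
                    canonical_p0(t, sw) * exp((lp - mp) * t)), 1e-10)
      expect_lt(abs(canonical_q(t, cp) - canonical_q(t, sw)), 1e-10)
      for (n in 1:5) {
        expect_lt(abs(mp^(n - 1) * canonical_pn(n, t, cp) -
                      lp^(n - 1) * canonical_pn(n, t, sw)), 1e-10)
      }
    } else {
      # mu' = 0: the swapped pair (0, lambda') lies outside the constructor
      # domain; compare against its limiting closed forms
      expect_lt(abs(lp * (1 - canonical_p0(t, cp)) - 0), 1e-10)
      expect_lt(abs(canonical_p0(t, cp) -
                    limit_p0_zero_first(t, lp) * exp(lp * t)), 1e-10)
      expect_lt(abs(canonical_q(t, cp) - limit_q_zero_first(t, lp)), 1e-10)
      for (n in 1:5) {
        lhs <- if (n == 1) canonical_pn(1, t, cp) else 0
        expect_lt(abs(lhs - lp^(n - 1) * limit_pn_zero_first(n, t, lp)),
                  1e-10)
      }
    }
  }
})

test_that("the critical switch is continuous", {
  eps <- 1e-7
  for (lam in c(0.5, 1, 2)) for (t in c(0.5, 1, 2)) for (n in 0:3) {
    base_ <- sampled_count_probability(n, t, bd_params(lam, lam, 0.8))
    up <- sampled_count_probability(n, t, bd_params(lam, lam + eps, 0.8))
    dn <- sampled_count_probability(n, t, bd_params(lam, lam - eps, 0.8))
    expect_lt(abs(up - base_), 1e-5)
    expect_lt(abs(dn - base_), 1e-5)
  }
})

test_that("sampled-count law matches Monte-Carlo frequencies", {
  set.seed(101)
  nrep <- 20000
  for (p in list(bd_params(1, 0.5, 0.6), bd_params(1, 1, 0.8))) {
    final <- simulate_final_counts(nrep, rate_pair(p$birth_rate, p$death_rate), 1)
    sampled <- rbinom(nrep, size = final, prob = p$sampling_prob)
    for (n in 0:5) {
      theo <- sampled_count_probability(n, 1, p)
      emp <- mean(sampled == n)
      se <- sqrt(theo * (1 - theo) / nrep)
      expect_lt(abs(emp - theo), 4 * se + 1e-12)
    }
  }
})
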