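test_that("Newick parsing extracts tip count, ages and stem age", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(tr$n, 3L)
  expect_equal(tr$branching_times, c(2, 1))
  expect_null(tr$stem_age)
  tr <- read_newick("((A:1,B:1):1,C:2):0.5;")
  expect_equal(tr$stem_age, 2.5)
  expect_equal(tr$branching_times[1], 2)
  expect_error(read_newick("(A:1,B:2);"), "ultrametric")
  expect_error(read_newick("(A,B);"), "branch lengths")
  # single-tip degenerate tree: branch length is the stem age
  tr <- read_newick("t1:2;")
  expect_equal(tr$n, 1L)
  expect_equal(tr$stem_age, 2)
})

test_that("Newick writing round-trips times, stem age and tip count", {
  tr <- reconstructed_tree(c(2, 1), stem_age = 2.5)
  back <- read_newick(write_newick(tr, seed = 4))
  expect_equal(back$n, 3L)
  expect_equal(back$branching_times, c(2, 1), tolerance = 1e-9)
  expect_equal(back$stem_age, 2.5, tolerance = 1e-9)
  # larger random tree
  set.seed(99)
  bt <- sort(runif(9, 0.1, 4), decreasing = TRUE)
  back <- read_newick(write_newick(reconstructed_tree(bt), seed = 2))
  expect_equal(back$branching_times, bt, tolerance = 1e-9)
  # single tip with stem age
  expect_match(write_newick(reconstructed_tree(numeric(0), stem_age = 3)),
               "^t1:3;$")
  # a stored topology is reused verbatim
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(sort(read_newick(write_newick(tr))$branching_times), c(1, 2))
})

test_that("conditioned densities hit frozen closed-form values", {
  # n = 2, pure birth, complete sampling: p11 = e^-t, q = 1 - e^-t
  tr <- reconstructed_tree(1, stem_age = 2)
  expect_equal(tree_log_density(tr, bd_params(1, 0, 1), "stem_and_n"),
               log(exp(-1) / (1 - exp(-2))), tolerance = 1e-12)
  # n = 1 tree: unconditioned stem density is just p11(t0)
  tr1 <- reconstructed_tree(numeric(0), stem_age = 1.5)
  expect_equal(tree_log_density(tr1, bd_params(1, 0, 1), "uncond_stem"),
               -1.5, tolerance = 1e-12)
  # stem_and_n with n = 1 has an empty product: log density 0
  expect_equal(tree_log_density(tr1, bd_params(1, 0.4, 1), "stem_and_n"), 0)
})

test_that("triplet and canonical evaluations agree row by row", {
  set.seed(31)
  for (rep in 1:15) {
    p <- random_bd_params()
    cp <- to_canonical(p)
    bt <- sort(runif(5, 0.05, 1.8), decreasing = TRUE)
    tree <- reconstructed_tree(bt, stem_age = 2)
    for (cond in c("stem_survival", "crown_survival", "n_uniform_t0",
                   "stem_and_n", "crown_and_n")) {
      a <- tree_log_density(tree, p, cond)
      b <- tree_log_density_canonical(tree, cp, cond)
      expect_lt(abs(a - b), 1e-12 * max(1, abs(a)))
    }
    for (cond in c("uncond_stem", "uncond_crown")) {
      a <- tree_log_density(tree, p, cond)
      b <- tree_log_density_canonical(tree, cp, cond,
                                      rho = p$sampling_prob)
      expect_lt(abs(a - b), 1e-12 * max(1, abs(a)))
    }
  }
  # rho = 1: canonical unconditioned density equals the bare triplet one
  tree <- reconstructed_tree(c(1.2, 0.4), stem_age = 2)
  expect_equal(tree_log_density_canonical(tree, canonical_params(1.3, 0.6),
                                          "uncond_stem", rho = 1),
               tree_log_density(tree, bd_params(1.3, 0.6, 1), "uncond_stem"),
               tolerance = 1e-12)
})

test_that("identifiability misuse and missing inputs are rejected", {
  tree <- reconstructed_tree(c(1.2, 0.4), stem_age = 2)
  cp <- canonical_params(1, 0.5)
  expect_error(tree_log_density_canonical(tree, cp, "stem_and_n", rho = 0.5),
               "not identifiable")
  expect_error(tree_log_density_canonical(tree, cp, "uncond_stem"),
               "supply")
  no_stem <- reconstructed_tree(c(1.2, 0.4))
  expect_error(tree_log_density(no_stem, bd_params(1, 0.5, 1), "stem_and_n"),
               "stem age")
  tip1 <- reconstructed_tree(numeric(0), stem_age = 1)
  expect_error(tree_log_density(tip1, bd_params(1, 0.5, 1), "crown_and_n"),
               "n >= 2")
})

test_that("survival and exact-n conditionings differ by the stated ratio", {
  set.seed(57)
  for (rep in 1:10) {
    p <- random_bd_params()
    n <- sample(2:7, 1)
    bt <- sort(runif(n - 1, 0.05, 1.9), decreasing = TRUE)
    tree <- reconstructed_tree(bt, stem_age = 2)
    # f(T | stem) = f(T | stem, n) * p_n(t0) / (1 - p_0(t0))
    lhs <- tree_log_density(tree, p, "stem_survival") -
      tree_log_density(tree, p, "stem_and_n")
    rhs <- sampled_count_probability(n, 2, p, log = TRUE) -
      log(1 - sampled_count_probability(0, 2, p))
    expect_lt(abs(lhs - rhs), 1e-12 * max(1, abs(lhs)))
    # crown analogue: ratio p_n-like mass from two surviving lineages at t1
    t1 <- bt[1]
    lhs <- tree_log_density(tree, p, "crown_survival") -
      tree_log_density(tree, p, "crown_and_n")
    cp <- to_canonical(p)
    # both crown lineages jointly produce n sampled tips; under the density
    # table this ratio reduces to log((n-1) * p1(t1)^2 (lam q(t1))^{n-2})
    # minus 2 log(1 - p0(t1))
    rhs <- log(n - 1) +
      2 * sampled_count_probability(1, t1, p, log = TRUE) +
      (n - 2) * (log(p$birth_rate) + q_function(t1, p, log = TRUE)) -
      2 * log(1 - sampled_count_probability(0, t1, p))
    expect_lt(abs(lhs - rhs), 1e-11 * max(1, abs(lhs)))
  }
})

test_that("exact-n conditioned densities are swap-symmetric for mu' > 0", {
  set.seed(71)
  for (rep in 1:10) {
    lp <- runif(1, 0.3, 2.5)
    mp <- runif(1, 0.05, 2.5)
    cp <- canonical_params(lp, mp)
    sw <- canonical_params(mp, lp)
    bt <- sort(runif(5, 0.05, 1.8), decreasing = TRUE)
    tree <- reconstructed_tree(bt, stem_age = 2)
    for (cond in c("stem_and_n", "crown_and_n")) {
      a <- tree_log_density_canonical(tree, cp, cond)
      b <- tree_log_density_canonical(tree, sw, cond)
      expect_lt(abs(a - b), 1e-10 * max(1, abs(a)))
    }
    # survival rows are NOT swap symmetric in general
    a <- tree_log_density_canonical(tree, cp, "stem_survival")
    b <- tree_log_density_canonical(tree, sw, "stem_survival")
    if (abs(lp - mp) > 0.1) expect_gt(abs(a - b), 1e-8)
  }
})

test_that("q equals the integral of p1 and the n = 2 origin-prior density is normalized", {
  set.seed(13)
  for (rep in 1:20) {
    p <- random_bd_params()
    t0 <- runif(1, 0.5, 3)
    val <- stats::integrate(function(s) sampled_count_probability(1, s, p),
                            0, t0, rel.tol = 1e-10)$value
    expect_lt(abs(val - q_function(t0, p)), 1e-8)
  }
  # integral over the crown age of exp(n_uniform_t0 density) at n = 2
  for (cp in list(canonical_params(1, 0.5), canonical_params(0.8, 0.8),
                  canonical_params(2, -0.7))) {
    dens <- function(t1) vapply(t1, function(u) {
      exp(tree_log_density_canonical(reconstructed_tree(u), cp,
                                     "n_uniform_t0"))
    }, numeric(1))
    total <- stats::integrate(dens, 0, Inf, rel.tol = 1e-9)$value
    expect_lt(abs(total - 1), 1e-6)
  }
})

test_that("densities stay finite for negative mu' inputs", {
  bt <- sort(runif(6, 0.05, 2.5), decreasing = TRUE)
  tree <- reconstructed_tree(bt, stem_age = 3)
  for (lp in c(0.5, 1, 2)) for (mp in c(-0.2, -1, -5)) {
    cp <- canonical_params(lp, mp)
    for (cond in c("stem_survival", "crown_survival", "n_uniform_t0",
                   "stem_and_n", "crown_and_n")) {
      v <- tree_log_density_canonical(tree, cp, cond)
      expect_true(is.finite(v))
    }
  }
})
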