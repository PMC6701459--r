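#' Population-size trajectory of a birth-death process
#'
#' Constructs (and validates) a population-size path: a start count, ordered
#' event times in `(0, t_total)`, and event types (+1 birth, -1 death). The
#' implied sizes before each event are computed and checked to stay
#' non-negative, with no events after absorption at zero.
#'
#' @param times Strictly increasing event times in `(0, t_total)`.
#' @param types Integer vector of the same length; `+1` birth, `-1` death
#'   (the characters `"birth"`/`"death"` are also accepted).
#' @param t_total Total duration of the observation window.
#' @param start_count Initial population size (\eqn{\ge 1}).
#' @return An object of class `"bd_trajectory"` with fields `times`, `types`,
#'   `sizes` (population immediately before each event), `start_count`,
#'   `end_count`, `t_total`.
#' @export
bd_trajectory <- function(times, types, t_total, start_count = 1L) {
  if (is.character(types))
    types <- ifelse(types == "birth", 1L, -1L)
  types <- as.integer(types)
  stopifnot(length(times) == length(types),
            all(types %in% c(-1L, 1L)),
            is.numeric(t_total), length(t_total) == 1L, t_total > 0,
            start_count >= 1L)
  if (length(times)) {
    if (any(diff(times) <= 0) || times[1] <= 0 || times[length(times)] >= t_total)
      stop("event times must be strictly increasing within (0, t_total)",
           call. = FALSE)
  }
  sizes <- start_count + c(0L, cumsum(types))[seq_along(types)]
  after <- sizes + types
  if (any(after < 0L) || any(sizes == 0L))
    stop("inconsistent trajectory: population would go negative or revive",
         call. = FALSE)
  structure(list(times = as.numeric(times), types = types, sizes = sizes,
                 start_count = as.integer(start_count),
                 end_count = as.integer(start_count + sum(types)),
                 t_total = as.numeric(t_total)),
            class = "bd_trajectory")
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf(
    "Birth-death trajectory: %d -> %d individuals, %d event(s) over %g time units\n",
    x$start_count, x$end_count, length(x$times), x$t_total))
  invisible(x)
}

#' Simulate a birth-death population trajectory (Gillespie)
#'
#' Forward stochastic simulation of the population size: waiting times are
#' exponential with total rate \eqn{n(\lambda+\mu)} at population size `n`,
#' and each event is a birth with probability
#' \eqn{p = \lambda/(\lambda+\mu)}. The run stops at `t_total` or on
#' absorption at zero.
#'
#' @param rates A [rate_pair()].
#' @param t_total Duration.
#' @param start_count Initial population size.
#' @param seed Optional integer seed (`set.seed`); omit to use the current
#'   RNG stream.
#' @param max_population Guard against runaway supercritical growth.
#' @return A [bd_trajectory()].
#' @export
simulate_trajectory <- function(rates, t_total, start_count = 1L, seed = NULL,
                                max_population = 1e6) {
  rates <- as_rate_pair(rates)
  stopifnot(t_total > 0, start_count >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lam <- rates$birth_rate
  mu <- rates$death_rate
  total <- lam + mu
  times <- numeric(0)
  types <- integer(0)
  size <- as.integer(start_count)
  now <- 0
  while (size > 0L && total > 0) {
    now <- now + stats::rexp(1L, rate = size * total)
    if (now >= t_total) break
    type <- if (stats::runif(1L) < lam / total) 1L else -1L
    size <- size + type
    times <- c(times, now)
    types <- c(types, type)
    if (size > max_population)
      stop("population exceeded max_population; raise the cap to simulate ",
           "supercritical runs this long", call. = FALSE)
  }
  bd_trajectory(times, types, t_total, start_count)
}

#' Time-reverse a trajectory with birth/death interchanged
#'
#' Maps event times \eqn{t \mapsto t_{total} - t}, reverses their order, and
#' swaps birth and death labels; the start count becomes the original end
#' count. `reverse_trajectory` is an involution. For a trajectory with equal
#' start and end size, its probability density under \eqn{(\lambda, \mu)}
#' equals the density of the reversal under the swapped rates
#' \eqn{(\mu, \lambda)} - the pathwise identity behind the transition-
#' probability interchange symmetry.
#'
#' @param traj A [bd_trajectory()].
#' @return A [bd_trajectory()].
#' @seealso [trajectory_log_density()]
#' @export
reverse_trajectory <- function(traj) {
  stopifnot(inherits(traj, "bd_trajectory"))
  if (traj$end_count == 0L)
    stop("cannot reverse a trajectory absorbed at zero: the reversal would ",
         "have to start from an empty population", call. = FALSE)
  bd_trajectory(times = rev(traj$t_total - traj$times),
                types = -rev(traj$types),
                t_total = traj$t_total,
                start_count = traj$end_count)
}

#' Log probability density of a population trajectory
#'
#' The density of a fully observed path: per event, a rate factor
#' \eqn{\lambda n_i} (birth) or \eqn{\mu n_i} (death) with \eqn{n_i} the size
#' just before the event; exponential waiting-time terms
#' \eqn{-(\lambda+\mu) n_i \Delta t_i} over every inter-event interval; and
#' the no-further-event tail \eqn{-(\lambda+\mu) n_{end} (t_{total} - t_k)}.
#' For an event-free path of one individual this reduces to
#' \eqn{e^{-(\lambda+\mu) t}}.
#'
#' @param traj A [bd_trajectory()].
#' @param rates A [rate_pair()].
#' @return The log density (scalar); `-Inf` if the path contains an event
#'   whose rate is zero.
#' @export
trajectory_log_density <- function(traj, rates) {
  stopifnot(inherits(traj, "bd_trajectory"))
  rates <- as_rate_pair(rates)
  lam <- rates$birth_rate
  mu <- rates$death_rate
  total <- lam + mu
  times <- traj$times
  sizes <- traj$sizes
  k <- length(times)
  last <- if (k) times[k] else 0
  dts <- diff(c(0, times))
  event_rates <- ifelse(traj$types == 1L, lam, mu) * sizes
  sum(base::log(event_rates)) -
    total * (sum(sizes * dts) + traj$end_count * (traj$t_total - last))
}

#' Vectorized final population sizes
#'
#' Simulates `nrep` independent birth-death runs and returns only the
#' population size at `t_total`. All replicates advance in lock-step
#' (one exponential draw per replicate per round), which makes large
#' Monte-Carlo checks of the transition law cheap in pure R. Uses the current
#' RNG stream.
#'
#' @param nrep Number of replicates.
#' @param rates A [rate_pair()].
#' @param t_total Duration.
#' @param start_count Initial size of every replicate.
#' @param max_population Cap on any replicate's size.
#' @return Integer vector of length `nrep`.
#' @export
simulate_final_counts <- function(nrep, rates, t_total, start_count = 1L,
                                  max_population = 1e6) {
  rates <- as_rate_pair(rates)
  lam <- rates$birth_rate
  mu <- rates$death_rate
  total <- lam + mu
  size <- rep.int(as.integer(start_count), nrep)
  if (total == 0) return(size)
  now <- numeric(nrep)
  active <- size > 0L
  while (any(active)) {
    idx <- which(active)
    now[idx] <- now[idx] + stats::rexp(length(idx), rate = size[idx] * total)
    ended <- now[idx] >= t_total
    ev <- idx[!ended]
    if (length(ev)) {
      step <- ifelse(stats::runif(length(ev)) < lam / total, 1L, -1L)
      size[ev] <- size[ev] + step
      if (any(size[ev] > max_population))
        stop("a replicate exceeded max_population", call. = FALSE)
    }
    active[idx[ended]] <- FALSE
    active[ev[size[ev] == 0L]] <- FALSE
  }
  size
}

#' Simulate a full genealogy
#'
#' Forward Gillespie simulation retaining the tree structure: at a birth the
#' chosen lineage splits into two daughters, at a death it terminates. Used
#' by [sample_present()] and [simulate_reconstructed_tree()].
#'
#' @inheritParams simulate_trajectory
#' @return A list with per-node vectors `parent`, `t_start`, `t_end`
#'   (forward times; `t_end = t_total` for extant lineages), the logical
#'   `extant`, root ids `roots`, and `t_total`.
#' @export
simulate_genealogy <- function(rates, t_total, start_count = 1L, seed = NULL,
                               max_population = 1e6) {
  rates <- as_rate_pair(rates)
  stopifnot(t_total > 0, start_count >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lam <- rates$birth_rate
  mu <- rates$death_rate
  total <- lam + mu
  cap <- 64L
  parent <- integer(cap)
  t_start <- numeric(cap)
  t_end <- rep(NA_real_, cap)
  nnode <- as.integer(start_count)
  alive <- seq_len(start_count)
  now <- 0
  while (length(alive) > 0L && total > 0) {
    now <- now + stats::rexp(1L, rate = length(alive) * total)
    if (now >= t_total) break
    pick <- alive[sample.int(length(alive), 1L)]
    if (stats::runif(1L) < lam / total) {
      if (nnode + 2L > cap) {
        cap <- cap * 2L
        parent <- c(parent, integer(cap))
        t_start <- c(t_start, numeric(cap))
        t_end <- c(t_end, rep(NA_real_, cap))
        cap <- length(parent)
      }
      t_end[pick] <- now
      kids <- nnode + 1:2
      parent[kids] <- pick
      t_start[kids] <- now
      nnode <- nnode + 2L
      alive <- c(alive[alive != pick], kids)
      if (length(alive) > max_population)
        stop("population exceeded max_population", call. = FALSE)
    } else {
      t_end[pick] <- now
      alive <- alive[alive != pick]
    }
  }
  idx <- seq_len(nnode)
  extant <- idx %in% alive
  t_end[alive] <- t_total
  list(parent = parent[idx], t_start = t_start[idx], t_end = t_end[idx],
       extant = extant, roots = seq_len(start_count), t_total = t_total)
}

#' Sample extant tips and prune to the reconstructed tree
#'
#' Each extant lineage of a simulated genealogy is retained independently
#' with probability `rho`; extinct and unsampled lineages are pruned. The
#' branching times of the reconstructed tree are the ages of the genealogy
#' nodes whose two daughter subtrees both contain a sampled tip.
#'
#' @param genealogy Output of [simulate_genealogy()].
#' @param rho Sampling probability in (0, 1].
#' @param seed Optional integer seed.
#' @return A [reconstructed_tree()] (with attributes `root_counts`, the
#'   sampled-tip count under each starting lineage), or `NULL` when no tip is
#'   sampled. For a single starting lineage the stem age is set to the run
#'   duration.
#' @export
sample_present <- function(genealogy, rho, seed = NULL) {
  stopifnot(rho > 0, rho <= 1)
  if (!is.null(seed)) set.seed(seed)
  nn <- length(genealogy$parent)
  sampled <- genealogy$extant & stats::runif(nn) < rho
  if (!any(sampled)) return(NULL)
  cnt <- as.integer(sampled)
  for (id in nn:1) {                      # children always have larger ids
    p <- genealogy$parent[id]
    if (p > 0L) cnt[p] <- cnt[p] + cnt[id]
  }
  # daughters are created as consecutive id pairs, so non-root ids pair up
  kid_ids <- which(genealogy$parent > 0L)
  retained <- if (length(kid_ids)) {
    k1 <- kid_ids[seq(1L, length(kid_ids), by = 2L)]
    k2 <- kid_ids[seq(2L, length(kid_ids), by = 2L)]
    genealogy$parent[k1][cnt[k1] >= 1L & cnt[k2] >= 1L]
  } else integer(0)
  ages <- genealogy$t_total - genealogy$t_end[retained]
  ages <- resolve_age_ties(ages)
  stem <- if (length(genealogy$roots) == 1L) genealogy$t_total else NULL
  tree <- reconstructed_tree(ages, stem_age = stem)
  attr(tree, "root_counts") <- cnt[genealogy$roots]
  tree
}

#' Simulate a reconstructed tree under a conditioning
#'
#' Rejection sampler: genealogies are simulated with [simulate_genealogy()]
#' and sampled with [sample_present()] until the conditioning event holds -
#' at least one sampled tip for `"stem_survival"` (at least one from each
#' initial lineage for `"crown_survival"`), exactly `n` sampled tips for
#' `"stem_and_n"`/`"crown_and_n"` (crown rows additionally require both
#' initial lineages represented, so that `age` is the crown age). Crown rows
#' start from two lineages at `age`; stem rows from one. The unconditioned
#' labels perform a single draw and may return `NULL`;
#' `"n_uniform_t0"` has an improper origin prior and cannot be simulated
#' directly.
#'
#' @param params A [bd_params()] triplet.
#' @param conditioning One of [conditionings] except `"n_uniform_t0"`.
#' @param age Stem age (stem rows) or crown age (crown rows).
#' @param n Required number of sampled tips (for the `*_and_n` rows).
#' @param seed Optional integer seed.
#' @param max_retries Rejection budget.
#' @param max_population Population cap per run.
#' @return A [reconstructed_tree()]; crown trees carry `age` as their oldest
#'   branching time, stem trees carry it as `stem_age`. The attribute
#'   `"rejections"` records the number of rejected genealogies.
#' @export
simulate_reconstructed_tree <- function(params, conditioning, age, n = NULL,
                                        seed = NULL, max_retries = 1e5,
                                        max_population = 1e6) {
  stopifnot(inherits(params, "bd_params"), age > 0)
  conditioning <- match.arg(conditioning, conditionings)
  if (conditioning == "n_uniform_t0")
    stop("'n_uniform_t0' places an improper uniform prior on the origin; ",
         "it cannot be simulated by this sampler", call. = FALSE)
  crown <- conditioning %in% c("uncond_crown", "crown_survival", "crown_and_n")
  need_n <- conditioning %in% c("stem_and_n", "crown_and_n")
  if (need_n) {
    stopifnot(!is.null(n), n >= 1L)
    if (crown && n < 2L) stop("crown trees need n >= 2", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rates <- rate_pair(params$birth_rate, params$death_rate)
  rejections <- 0L
  repeat {
    gen <- simulate_genealogy(rates, age, start_count = if (crown) 2L else 1L,
                              max_population = max_population)
    tree <- sample_present(gen, params$sampling_prob)
    ok <- !is.null(tree)
    if (ok) {
      rc <- attr(tree, "root_counts")
      if (crown && any(rc < 1L)) ok <- FALSE
      if (ok && need_n && sum(rc) != n) ok <- FALSE
    }
    if (ok || conditioning %in% c("uncond_stem", "uncond_crown")) break
    rejections <- rejections + 1L
    if (rejections >= max_retries)
      stop(sprintf(
        "max_retries exhausted (acceptance rate below %.2e); widen the budget",
        1 / max_retries), call. = FALSE)
  }
  if (!ok) return(NULL)   # unconditioned draw with no sampled tip
  if (crown) {
    tree <- reconstructed_tree(c(age, tree$branching_times), stem_age = NULL)
  }
  attr(tree, "rejections") <- rejections
  tree
}

#' Exact sampler for conditioned branching times
#'
#' Under the `*_and_n` conditionings the branching times other than the
#' conditioning age are independent draws from the density
#' \eqn{\tilde p_1(t) / \tilde q(age)} on `(0, age)` (the derivative identity
#' \eqn{d\tilde q/dt = \tilde p_1} makes \eqn{\tilde q(t)/\tilde q(age)} the
#' exact CDF). This inverse-CDF sampler draws such times directly, which is
#' what makes large-`n` parameter-recovery experiments affordable; it is
#' cross-checked against the rejection sampler
#' [simulate_reconstructed_tree()] in the test suite.
#'
#' @param k Number of times to draw.
#' @param age Upper end of the support (stem or crown age).
#' @param cp A [canonical_params()] pair.
#' @return Numeric vector of `k` iid branching times in `(0, age)`. Uses the
#'   current RNG stream.
#' @export
sample_branching_times <- function(k, age, cp) {
  stopifnot(inherits(cp, "canonical_params"), age > 0, k >= 0)
  if (k == 0) return(numeric(0))
  u <- stats::runif(k)
  lam <- cp$lambda_prime
  mu <- cp$mu_prime
  y <- u * canonical_q(age, cp)
  if (is_critical(lam, mu, age)) {
    y / (1 - lam * y)
  } else {
    r <- lam - mu
    -base::log((1 - y * lam) / (1 - y * mu)) / r
  }
}

# Break exact float ties among simulated node ages (measure-zero events).
resolve_age_ties <- function(ages) {
  if (!anyDuplicated(ages)) return(ages)
  warning("simultaneous event times; jittering by one ulp")
  while (anyDuplicated(ages)) {
    d <- duplicated(ages)
    ages[d] <- ages[d] * (1 + .Machine$double.eps)
  }
  ages
}
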