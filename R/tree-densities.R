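#' Conditionings of the reconstructed-tree density
#'
#' The seven events a reconstructed-tree probability density can be normalized
#' by:
#' \describe{
#'   \item{`"uncond_stem"`}{process starts from one lineage at the stem age
#'     \eqn{t_0}; no conditioning on sampling.}
#'   \item{`"uncond_crown"`}{process starts from two lineages at the crown age
#'     \eqn{t_1}; no conditioning on sampling.}
#'   \item{`"stem_survival"`}{stem start, conditioned on at least one sampled
#'     tip.}
#'   \item{`"crown_survival"`}{crown start, conditioned on at least one
#'     sampled tip from each initial lineage.}
#'   \item{`"n_uniform_t0"`}{conditioned on exactly `n` sampled tips with the
#'     stem age drawn uniformly on \eqn{(0, \infty)} and integrated out.}
#'   \item{`"stem_and_n"`}{stem start, conditioned on exactly `n` sampled
#'     tips.}
#'   \item{`"crown_and_n"`}{crown start, conditioned on exactly `n` sampled
#'     tips.}
#' }
#' Stem-family labels require a known stem age; crown-family labels and
#' `"n_uniform_t0"` require \eqn{n \ge 2}.
#'
#' @format Character vector of the seven labels.
#' @export
conditionings <- c("uncond_stem", "uncond_crown", "stem_survival",
                   "crown_survival", "n_uniform_t0", "stem_and_n",
                   "crown_and_n")

#' Reconstructed tree (tip count and branching times)
#'
#' The sufficient statistics of a reconstructed ultrametric tree for the
#' birth-death densities in this package: the number of sampled tips `n` and
#' the ordered branching times \eqn{t_1 > t_2 > \dots > t_{n-1} > 0} measured
#' backwards from the present (time 0), plus an optional stem age
#' \eqn{t_0 > t_1} and an optional topology (an `ape` `"phylo"` object
#' retained from input).
#'
#' @param branching_times Numeric vector of node ages, any order; must be
#'   positive and distinct. May be empty for a single-tip tree.
#' @param stem_age Optional stem age, strictly older than the oldest
#'   branching time.
#' @param topology Optional `"phylo"` object.
#' @return An object of class `"reconstructed_tree"` with fields `n`,
#'   `branching_times` (sorted decreasing), `stem_age`, `topology`.
#' @export
reconstructed_tree <- function(branching_times, stem_age = NULL,
                               topology = NULL) {
  branching_times <- as.numeric(branching_times)
  if (any(!is.finite(branching_times)) || any(branching_times <= 0))
    stop("branching times must be finite and positive", call. = FALSE)
  bt <- sort(branching_times, decreasing = TRUE)
  if (anyDuplicated(bt))
    stop("branching times must be distinct", call. = FALSE)
  if (!is.null(stem_age)) {
    stopifnot(is.numeric(stem_age), length(stem_age) == 1L, is.finite(stem_age))
    if (length(bt) && stem_age <= bt[1])
      stop("stem_age must exceed the oldest branching time", call. = FALSE)
    if (stem_age <= 0) stop("stem_age must be positive", call. = FALSE)
  }
  structure(list(n = length(bt) + 1L, branching_times = bt,
                 stem_age = stem_age, topology = topology),
            class = "reconstructed_tree")
}

#' @export
print.reconstructed_tree <- function(x, ...) {
  cat(sprintf("Reconstructed tree: %d tip(s)", x$n))
  if (x$n > 1L)
    cat(sprintf(", crown age %g", x$branching_times[1]))
  if (!is.null(x$stem_age))
    cat(sprintf(", stem age %g", x$stem_age))
  cat("\n")
  invisible(x)
}

#' Read a reconstructed tree from Newick
#'
#' Parses a rooted ultrametric Newick tree (branch lengths required, in time
#' units) and extracts the tip count and internal-node ages. A root edge, if
#' present, sets the stem age to crown age plus root-edge length.
#'
#' @param x A Newick string, or the path of a file whose first line is one.
#' @param tol Relative ultrametricity tolerance (fraction of tree height).
#' @return A [reconstructed_tree()]; the parsed `"phylo"` topology is kept.
#' @examples
#' read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(x, tol = 1e-6) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!grepl("[();]", x)) {
    if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
    x <- readLines(x, n = 1L, warn = FALSE)
  }
  # single-tip tree, optionally with nothing but a label and length
  if (!grepl("\\(", x)) {
    mt <- regmatches(x, regexec("^\\s*([^:;,()]*):([0-9.eE+-]+)\\s*;", x))[[1]]
    if (length(mt) != 3L)
      stop("cannot parse single-tip Newick: ", x, call. = FALSE)
    len <- as.numeric(mt[3])
    return(reconstructed_tree(numeric(0),
                              stem_age = if (len > 0) len else NULL))
  }
  tr <- ape::read.tree(text = x)
  if (is.null(tr)) stop("malformed Newick string", call. = FALSE)
  if (is.null(tr$edge.length))
    stop("Newick tree must have branch lengths", call. = FALSE)
  ntip <- length(tr$tip.label)
  depth <- ape::node.depth.edgelength(tr)
  height <- max(depth[seq_len(ntip)])
  dev <- max(height - depth[seq_len(ntip)])
  if (dev > tol * max(height, .Machine$double.eps))
    stop(sprintf("tree is not ultrametric: max tip-depth deviation %g", dev),
         call. = FALSE)
  ages <- height - depth[(ntip + 1L):(ntip + tr$Nnode)]
  ages <- pmax(ages, 0)
  if (anyDuplicated(ages)) {
    warning("tied branching times; breaking ties by an infinitesimal jitter")
    eps <- max(height, 1) * 1e-12
    ages <- ages + seq_along(ages) * eps * duplicated(ages)
    while (anyDuplicated(ages)) ages[duplicated(ages)] <- ages[duplicated(ages)] + eps
  }
  stem <- if (!is.null(tr$root.edge) && tr$root.edge > 0)
    max(ages) + tr$root.edge else NULL
  reconstructed_tree(ages, stem_age = stem, topology = tr)
}

#' Write a reconstructed tree as Newick
#'
#' If the tree carries a topology it is written directly; otherwise a random
#' ranked topology consistent with the branching times is generated from
#' `seed` (coalescing two uniformly chosen lineages at each branching time,
#' youngest first). A stem age is emitted as a root edge.
#'
#' @param tree A [reconstructed_tree()].
#' @param seed Integer seed for the random topology (ignored when a topology
#'   is stored).
#' @return A Newick string; [read_newick()] round-trips `n`, the branching
#'   times (to 1e-9), and the stem age.
#' @export
write_newick <- function(tree, seed = 1L) {
  stopifnot(inherits(tree, "reconstructed_tree"))
  root_edge <- function(s) {
    if (!is.null(tree$stem_age) && tree$n > 1L)
      sprintf("%s:%.12g", s, tree$stem_age - tree$branching_times[1])
    else s
  }
  if (tree$n == 1L) {
    len <- if (is.null(tree$stem_age)) 0 else tree$stem_age
    return(sprintf("t1:%.12g;", len))
  }
  if (!is.null(tree$topology))
    return(ape::write.tree(tree$topology))
  set.seed(seed)
  labs <- sprintf("t%d:", seq_len(tree$n))
  node <- labs                      # growing newick fragments, ":" pending
  height <- numeric(tree$n)         # age of each fragment's root
  for (a in sort(tree$branching_times)) {
    pick <- sample.int(length(node), 2L)
    merged <- sprintf("(%s%.12g,%s%.12g):",
                      node[pick[1]], a - height[pick[1]],
                      node[pick[2]], a - height[pick[2]])
    node <- c(node[-pick], merged)
    height <- c(height[-pick], a)
  }
  s <- sub(":$", "", node[1])
  paste0(root_edge(s), ";")
}

#' Log probability density of a reconstructed tree
#'
#' Evaluates the reconstructed-tree probability density under a sampled
#' birth-death process \eqn{(\lambda, \mu, \rho)} for one of the seven
#' [conditionings], in log scale. Writing \eqn{p_{1,1}(t)} for the
#' probability of exactly one sampled descendant, \eqn{p_0(t)} for no sampled
#' descendant, and \eqn{q(t)} as in [q_function()], the seven densities are
#' \deqn{f(T | L(t_0)=1) = p_{1,1}(t_0)\prod_{i=1}^{n-1}\lambda p_{1,1}(t_i)}
#' \deqn{f(T | L(t_1)=2) = p_{1,1}(t_1)^2\prod_{i=2}^{n-1}\lambda p_{1,1}(t_i)}
#' \deqn{f(T | t_0 = t_{stem}) = \frac{p_{1,1}(t_0)}{1-p_0(t_0)}
#'   \prod_{i=1}^{n-1}\lambda p_{1,1}(t_i)}
#' \deqn{f(T | t_1 = t_{crown}) = \Big(\frac{p_{1,1}(t_1)}{1-p_0(t_1)}\Big)^2
#'   \prod_{i=2}^{n-1}\lambda p_{1,1}(t_i)}
#' \deqn{f(T | L_s(0)=n) = n\frac{p_{1,1}(t_1)}{1-p_0(t_1)}
#'   \prod_{i=1}^{n-1}\lambda p_{1,1}(t_i)}
#' \deqn{f(T | t_0 = t_{stem}, L_s(0)=n) = \prod_{i=1}^{n-1}
#'   \frac{p_{1,1}(t_i)}{q(t_0)}}
#' \deqn{f(T | t_1 = t_{crown}, L_s(0)=n) = \frac{1}{n-1}\prod_{i=2}^{n-1}
#'   \frac{p_{1,1}(t_i)}{q(t_1)}}
#' Densities are over the ordered branching-time vector; no labelled-topology
#' factors are introduced. Only the two unconditioned rows depend on all
#' three parameters; the five conditioned rows depend on the data only
#' through the canonical pair (see [tree_log_density_canonical()]).
#'
#' @param tree A [reconstructed_tree()].
#' @param params A [bd_params()] triplet with \eqn{\lambda > 0}.
#' @param conditioning One of [conditionings].
#' @return The log density (scalar).
#' @export
tree_log_density <- function(tree, params, conditioning) {
  stopifnot(inherits(tree, "reconstructed_tree"),
            inherits(params, "bd_params"))
  conditioning <- match.arg(conditioning, conditionings)
  check_conditioning_inputs(tree, conditioning)
  lp1 <- function(t) sampled_count_probability(1L, t, params, log = TRUE)
  l1mp0 <- function(t) base::log(params$sampling_prob) +
    canonical_p0(t, to_canonical(params), log = TRUE)
  lq <- function(t) q_function(t, params, log = TRUE)
  assemble_log_density(tree, conditioning,
                       log_lambda = base::log(params$birth_rate),
                       lp1 = lp1, lsurv = l1mp0, lq = lq)
}

#' Log tree density in canonical coordinates
#'
#' Evaluates the same seven densities as [tree_log_density()] but from the
#' canonical pair \eqn{(\lambda', \mu')}, using
#' \eqn{p_{1,1} = \rho\tilde p_1}, \eqn{1 - p_0 = \rho\tilde p_0},
#' \eqn{q = \rho\tilde q} and \eqn{\lambda p_{1,1} = \lambda'\tilde p_1}. All
#' \eqn{\rho} factors cancel in the five conditioned rows, so those must be
#' called without a `rho`; the two unconditioned rows retain leading
#' \eqn{\rho} factors and require one. Supplying `rho` for a conditioned row
#' is an error: it would suggest a third identifiable parameter where there
#' is none.
#'
#' @param tree A [reconstructed_tree()].
#' @param cp A [canonical_params()] pair.
#' @param conditioning One of [conditionings].
#' @param rho Sampling probability; required by (and only by) the two
#'   unconditioned rows.
#' @return The log density (scalar). For any triplet mapping to `cp` the
#'   conditioned rows agree with [tree_log_density()] to close to machine
#'   precision.
#' @export
tree_log_density_canonical <- function(tree, cp, conditioning, rho = NULL) {
  stopifnot(inherits(tree, "reconstructed_tree"),
            inherits(cp, "canonical_params"))
  conditioning <- match.arg(conditioning, conditionings)
  check_conditioning_inputs(tree, conditioning)
  uncond <- conditioning %in% c("uncond_stem", "uncond_crown")
  if (uncond && is.null(rho))
    stop("the unconditioned densities depend on rho; supply one", call. = FALSE)
  if (!uncond && !is.null(rho))
    stop("rho is not identifiable under a conditioned density; do not supply it",
         call. = FALSE)
  extra <- 0
  if (uncond) {
    stopifnot(is.numeric(rho), length(rho) == 1L, rho > 0, rho <= 1)
    extra <- if (conditioning == "uncond_stem") base::log(rho) else 2 * base::log(rho)
  }
  extra + assemble_log_density(
    tree, conditioning,
    log_lambda = base::log(cp$lambda_prime),
    lp1 = function(t) canonical_p1(t, cp, log = TRUE),
    lsurv = function(t) canonical_p0(t, cp, log = TRUE),
    lq = function(t) canonical_q(t, cp, log = TRUE))
}

# ---- internal --------------------------------------------------------------

check_conditioning_inputs <- function(tree, conditioning) {
  stem_rows <- c("uncond_stem", "stem_survival", "stem_and_n")
  if (conditioning %in% stem_rows && is.null(tree$stem_age))
    stop(sprintf("conditioning '%s' requires a stem age", conditioning),
         call. = FALSE)
  if (!(conditioning %in% stem_rows) && tree$n < 2L)
    stop(sprintf("conditioning '%s' requires n >= 2 tips", conditioning),
         call. = FALSE)
  invisible(TRUE)
}

# Shared row-by-row assembly. lp1/lsurv/lq are log p11, log(1-p0) (or their
# canonical analogues, whose rho factors cancel), log q. Sums over empty
# index sets are 0 (n = 1 stem rows, n = 2 crown rows).
assemble_log_density <- function(tree, conditioning, log_lambda, lp1, lsurv, lq) {
  bt <- tree$branching_times            # t_1 > ... > t_{n-1}
  n <- tree$n
  t0 <- tree$stem_age
  t1 <- if (n > 1L) bt[1] else NULL
  inner <- bt[-1]                       # t_2 ... t_{n-1}
  sum_all <- sum(log_lambda + lp1(bt))          # i = 1..n-1
  sum_inner <- sum(log_lambda + lp1(inner))     # i = 2..n-1
  switch(conditioning,
    uncond_stem = lp1(t0) + sum_all,
    uncond_crown = 2 * lp1(t1) + sum_inner,
    stem_survival = lp1(t0) - lsurv(t0) + sum_all,
    crown_survival = 2 * (lp1(t1) - lsurv(t1)) + sum_inner,
    n_uniform_t0 = base::log(n) + lp1(t1) - lsurv(t1) + sum_all,
    stem_and_n = sum(lp1(bt) - lq(t0)),
    crown_and_n = -base::log(n - 1) + sum(lp1(inner) - lq(t1)))
}
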