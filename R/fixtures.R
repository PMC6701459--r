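#' Generate deterministic test fixtures
#'
#' Writes (a) five tiny hand-constructed ultrametric Newick trees with 1 to 5
#' tips and documented branching times, (b) simulated reconstructed trees
#' (one Newick per line per conditioning) at \eqn{\lambda = 1},
#' \eqn{\mu = 0.5}, \eqn{\rho = 0.8}, stem/crown age 3, and (c) a CSV
#' parameter grid for symmetry checks. Identical seeds give bit-identical
#' files; the returned manifest records an MD5 hash per file.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param n_trees Simulated trees per conditioning.
#' @return Invisibly, a data frame with columns `file` and `md5`.
#' @export
generate_fixtures <- function(out_dir, seed = 1L, n_trees = 50L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2L) != 0L)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  files <- character(0)

  hand <- c(
    n1 = "t1:2;",                                        # stem age 2
    n2 = "(A:1,B:1):0.5;",                               # t1=1, stem 1.5
    n3 = "((A:1,B:1):1,C:2);",                           # t1=2, t2=1
    n4 = "(((A:1,B:1):0.5,C:1.5):1,D:2.5);",             # t1=2.5, t2=1.5, t3=1
    n5 = "((((A:1,B:1):0.5,C:1.5):0.5,D:2):1,E:3);"      # 3,2,1.5,1
  )
  for (nm in names(hand)) {
    f <- file.path(out_dir, paste0("hand_", nm, ".nwk"))
    writeLines(hand[[nm]], f)
    files <- c(files, f)
  }

  params <- bd_params(1, 0.5, 0.8)
  set.seed(seed)
  for (cond in c("stem_survival", "crown_survival", "stem_and_n",
                 "crown_and_n")) {
    n_req <- if (grepl("and_n", cond)) 4L else NULL
    trees <- vapply(seq_len(n_trees), function(i) {
      tr <- simulate_reconstructed_tree(params, cond, age = 3, n = n_req)
      write_newick(tr, seed = i)
    }, character(1))
    f <- file.path(out_dir, paste0("sim_", cond, ".nwk"))
    writeLines(trees, f)
    files <- c(files, f)
  }

  grid <- expand.grid(lambda = c(0.3, 1, 2.5), mu = c(0.3, 1, 2.5),
                      t = c(0.1, 0.5, 1, 2))
  f <- file.path(out_dir, "symmetry_grid.csv")
  utils::write.csv(grid, f, row.names = FALSE)
  files <- c(files, f)

  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         row.names = NULL)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
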