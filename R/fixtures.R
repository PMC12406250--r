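# Test fixtures: a brute-force enumeration oracle, toy group sets with known
# fragment counts, and synthetic descriptor/property data with a known sparse
# linear signal.

#' Brute-force fragment-graph enumeration (oracle)
#'
#' Independently enumerates every feasible fragment graph of a node set by
#' full grid expansion: all symmetric non-negative integer matrices with zero
#' diagonal within the pairwise bond-multiplicity bounds are generated
#' outright, then filtered by exact valence saturation, by the literal
#' subset-sum form of the anti-cycle constraints, and by graph connectivity
#' (via igraph components, deliberately not the package's own
#' breadth-first-search code path). This is the reference implementation that
#' [enumerate_fragments()] is tested against; it refuses node sets larger
#' than `max_nodes` because the grid grows combinatorially.
#'
#' @param nodes A `node_set` (see [expand_instances()]).
#' @param max_nodes Refusal threshold (default 7).
#' @return List of `fragment_graph` objects.
#' @export
brute_force_enumerate <- function(nodes, max_nodes = 7L) {
  n <- nrow(nodes)
  if (n > max_nodes)
    stop("brute-force oracle refuses node sets larger than ", max_nodes,
         " nodes", call. = FALSE)
  if (n < 2L) return(list())
  v <- as.integer(nodes$valence)
  mv <- nodes$multi
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  ub <- apply(pairs, 1, function(pr) {
    i <- pr[1]; j <- pr[2]
    if (mv[i] && mv[j]) 1L
    else if (mv[i]) min(v[i] - 1L, v[j])
    else if (mv[j]) min(v[j] - 1L, v[i])
    else min(v[i], v[j])
  })
  if (prod(ub + 1) > 5e6)
    stop("brute-force grid too large (", prod(ub + 1), " matrices)",
         call. = FALSE)
  grid <- as.matrix(do.call(expand.grid, c(lapply(ub, function(u) 0:u),
                                           KEEP.OUT.ATTRS = FALSE)))
  jm <- max_subset_size(sum(mv))
  subsets <- list()
  if (sum(mv) >= 1L) {
    for (sz in seq_len(min(jm, sum(mv))))
      subsets <- c(subsets, utils::combn(which(mv), sz, simplify = FALSE))
  }
  out <- list()
  for (r in seq_len(nrow(grid))) {
    A <- matrix(0L, n, n)
    A[cbind(pairs[, 1], pairs[, 2])] <- grid[r, ]
    A <- A + t(A)
    if (!identical(as.integer(rowSums(A)), v)) next
    ok <- TRUE
    for (s in subsets) {
      if (sum(A[s, s]) > 2L * length(s) - 1L) { ok <- FALSE; break }
    }
    if (!ok) next
    g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
    if (igraph::count_components(g) != 1L) next
    out[[length(out) + 1L]] <- new_fragment_graph(nodes, A)
  }
  out
}

#' Toy group sets with oracle-verified fragment counts
#'
#' Small, fully enumerable generation problems for testing. Each entry
#' carries a `group_set` and the number of unique fragments its enumeration
#' must produce (`expected_count`, established with the brute-force oracle
#' and hand enumeration).
#'
#' @return Named list of `list(groupset =, expected_count =)` fixtures.
#' @export
toy_group_sets <- function() {
  dummy <- group_spec("dummy", "*", 1L)
  list(
    hydroxyl_only = list(
      # single possible fragment: *-OH
      groupset = group_set(list(dummy, group_spec("hydroxyl", "O", 1L)),
                           role = "head", min_groups = 1L, max_groups = 1L),
      expected_count = 1L),
    methylene_chain = list(
      # chains *-CH2-CH3 and *-CH2-CH2-CH3
      groupset = group_set(
        list(dummy,
             group_spec("methylidene", "C", 2L, max_occurrences = 2L),
             group_spec("methyl", "C", 1L, max_occurrences = 2L)),
        role = "tail", min_groups = 2L, max_groups = 4L),
      expected_count = 2L),
    branched = list(
      # *-CH3 (collapsed methyl) and the isopropyl attachment *-CH(CH3)2
      groupset = group_set(
        list(dummy,
             group_spec("methyllidyne", "C", 3L),
             group_spec("methyl", "C", 1L, max_occurrences = 3L)),
        role = "tail", min_groups = 1L, max_groups = 4L),
      expected_count = 2L),
    asymmetric_ester = list(
      # one selection, one graph: *-C(=O)-O-CH3
      groupset = group_set(
        list(dummy,
             group_spec("ester", "C(=O)O", 2L,
                        connections = list(list(atom = 1L, cap = 1L),
                                           list(atom = "final", cap = 1L))),
             group_spec("methyl", "C", 1L)),
        role = "head", min_groups = 2L, max_groups = 2L),
      expected_count = 1L)
  )
}

#' Generate a synthetic QSPR data set with known sparse linear structure
#'
#' Descriptors are independent standard normal draws; the response is a
#' sparse linear combination of the first `k` descriptors plus Gaussian
#' noise: `y = X beta + eps`, `eps ~ N(0, sigma^2)`. Used to test the
#' descriptor-filtering and model-training protocol with a known ground
#' truth.
#'
#' @param n Number of molecules (rows).
#' @param p Number of descriptors.
#' @param k Number of true predictors (`k <= p`).
#' @param beta Coefficients of the true predictors (recycled to length `k`);
#'   default alternates +2 and -3.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return List with `x` (a `descriptor_table`-classed data frame), `y`,
#'   `beta` (full-length named coefficient vector) and the generating `spec`.
#' @export
synthetic_qspr_dataset <- function(n = 200L, p = 50L, k = 5L,
                                   beta = c(2, -3), sigma = 0.1, seed = 0L) {
  stopifnot(k <= p, sigma >= 0)
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("d%02d", seq_len(p))))
  b <- stats::setNames(numeric(p), colnames(x))
  b[seq_len(k)] <- rep_len(beta, k)
  y <- as.numeric(x %*% b + stats::rnorm(n, sd = sigma))
  xd <- as.data.frame(x)
  class(xd) <- c("descriptor_table", "data.frame")
  list(x = xd, y = y, beta = b,
       spec = list(n = n, p = p, k = k, sigma = sigma, seed = seed))
}
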