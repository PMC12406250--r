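# Exhaustive enumeration of fragment graphs over a node set.
#
# The feasibility model: symmetric non-negative integer adjacency y[j,j']
# over nodes with fixed valences v_j, where
#   (i)   sum_{j'} y[j,j'] = v_j                      (valence saturation)
#   (ii)  y[j,j'] = y[j',j], y[j,j] = 0               (symmetry, no self-bond)
#   (iii) y[j,j'] <= 1 if both j, j' are multivalence
#   (iv)  y[j,j'] <= v_j - 1 if j multivalence, j' single-valence
#   (v)   sum_{j,j' in S} y[j,j'] <= 2|S| - 1 for every nonempty subset S of
#         multivalence nodes with |S| <= Jm = ceil((m+1)/2)  (anti-cycle)
#   (vi)  sum y >= 2(n - 1)                           (edge-count lower bound)
# All solutions are enumerated; previously found solutions are excluded by
# integer cuts on the support pattern of the adjacency, and a breadth-first
# search connectivity check is the final authority on connectedness.

#' Maximum subset size for the anti-cycle connectivity constraints
#'
#' For `m` multivalence nodes the subset constraints are generated for all
#' nonempty subsets up to size \eqn{\lceil (m+1)/2 \rceil}.
#'
#' @param m Non-negative integer count of multivalence nodes.
#' @return Integer subset-size bound.
#' @export
max_subset_size <- function(m) {
  m <- as.integer(m)
  if (is.na(m) || m < 0L) stop("m must be a non-negative integer", call. = FALSE)
  as.integer(ceiling((m + 1) / 2))
}

#' Number of connectivity constraints generated by the powerset rule
#'
#' Counts the nonempty subsets of the multivalence node set up to the
#' [max_subset_size()] bound: \eqn{\sum_{i=1}^{J_m} \binom{m}{i}}.
#'
#' @param m Positive integer count of multivalence nodes.
#' @return Integer constraint count.
#' @export
connectivity_constraint_count <- function(m) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be a positive integer", call. = FALSE)
  jm <- max_subset_size(m)
  as.integer(sum(choose(m, seq_len(jm))))
}

#' Breadth-first search connectivity of a fragment graph
#'
#' @param graph A `fragment_graph`, or a symmetric adjacency matrix.
#' @return `TRUE` iff a breadth-first traversal from node 1 reaches every node.
#' @export
is_connected <- function(graph) {
  A <- if (inherits(graph, "fragment_graph")) graph$adjacency else graph
  n <- nrow(A)
  if (is.null(n) || n == 0L) stop("empty graph", call. = FALSE)
  if (n == 1L) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    u <- queue[1L]
    queue <- queue[-1L]
    nb <- which(A[u, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

new_fragment_graph <- function(nodes, A) {
  dimnames(A) <- list(nodes$label, nodes$label)
  structure(list(nodes = nodes, adjacency = A), class = "fragment_graph")
}

#' @export
print.fragment_graph <- function(x, ...) {
  cat(sprintf("<fragment_graph> %d nodes, %d bonds\n",
              nrow(x$adjacency), sum(x$adjacency) / 2))
  print(x$adjacency)
  invisible(x)
}

# Pairwise upper bound on y[i,j] from constraints (iii)/(iv) and valences.
.edge_upper_bounds <- function(nodes) {
  n <- nrow(nodes)
  v <- nodes$valence
  mv <- nodes$multi
  ub <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ub[i, j] <- if (mv[i] && mv[j]) 1L
    else if (mv[i] && !mv[j]) min(v[i] - 1L, v[j])
    else if (!mv[i] && mv[j]) min(v[j] - 1L, v[i])
    else min(v[i], v[j])
  }
  ub
}

# Anti-cycle subset constraints, checked through their graph-theoretic
# equivalent: a violated subset exists iff the subgraph induced by the
# multivalence nodes contains a cycle of length <= Jm. (A minimal subset with
# >= |S| internal edges is exactly a cycle; the symmetric sum over S counts
# each internal edge twice, so sum <= 2|S| - 1 is sum/2 <= |S| - 1.)
.violates_subset_constraints <- function(A, nodes) {
  mv <- which(nodes$multi)
  m <- length(mv)
  if (m < 3L) return(FALSE)  # subsets of size <= 2 are already edge-bounded
  jm <- max_subset_size(m)
  sub <- A[mv, mv, drop = FALSE]
  if (sum(sub) / 2 < 3) return(FALSE)
  g <- igraph::graph_from_adjacency_matrix(sub > 0, mode = "undirected")
  girth <- suppressWarnings(igraph::girth(g)$girth)
  is.finite(girth) && girth > 0 && girth <= jm
}

# Integer cut: a solution is excluded iff it coincides with a recorded
# solution in every bond variable. (With binary bond variables this is the
# classical support cut; with bounded-integer multiplicities the support
# alone can nest across distinct solutions, so the exact value pattern is
# what "differs in at least one variable" must compare.)
.violates_cut <- function(A, cuts) {
  if (!length(cuts)) return(FALSE)
  vals <- A[upper.tri(A)]
  for (ck in cuts) if (identical(ck, vals)) return(TRUE)
  FALSE
}

#' Enumerate all feasible fragment graphs for one node set
#'
#' Performs exhaustive feasibility enumeration of the graph-generation model:
#' every symmetric integer adjacency matrix satisfying the valence-saturation,
#' bond-multiplicity, anti-cycle and edge-count constraints is generated by a
#' depth-first search with constraint propagation; each accepted solution is
#' recorded as an integer cut on its support so that enumeration provably
#' never repeats a solution, and solutions failing the breadth-first-search
#' connectivity check are discarded (but still cut) so that enumeration
#' progresses.
#'
#' @param nodes A `node_set` from [expand_instances()], or a data frame with
#'   columns `label`, `valence`, `multi`.
#' @param max_solutions Safety cap on the number of accepted solutions.
#' @return List of `fragment_graph` objects (empty when infeasible), with an
#'   `enumeration_state` attribute recording the integer cuts and the counts
#'   of raw and disconnected solutions.
#' @export
enumerate_fragments <- function(nodes, max_solutions = 10000L) {
  if (nrow(nodes) < 2L)
    stop("fragment enumeration needs at least 2 nodes", call. = FALSE)
  n <- nrow(nodes)
  v <- as.integer(nodes$valence)
  if (sum(v) %% 2L == 1L) {
    out <- list()
    attr(out, "enumeration_state") <-
      list(cuts = list(), n_sol = 0L, n_raw = 0L, n_disconnected = 0L)
    return(out)
  }
  ub <- .edge_upper_bounds(nodes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  np <- nrow(pairs)
  A <- matrix(0L, n, n)
  deg <- integer(n)
  sols <- list()
  cuts <- list()
  n_raw <- 0L
  n_disc <- 0L
  accept <- function(A) {
    # valence saturation (i): rows 1..n-1 are pruned during the search; the
    # last row must still be verified here
    if (!all(deg == v)) return(invisible(NULL))
    # edge-count lower bound (vi): redundant under saturation, kept as printed.
    if (sum(A) < 2L * (n - 1L)) return(invisible(NULL))
    if (.violates_subset_constraints(A, nodes)) return(invisible(NULL))
    if (.violates_cut(A, cuts)) return(invisible(NULL))
    n_raw <<- n_raw + 1L
    cuts[[length(cuts) + 1L]] <<- A[upper.tri(A)]
    if (!is_connected(A)) {
      n_disc <<- n_disc + 1L
      return(invisible(NULL))
    }
    sols[[length(sols) + 1L]] <<- new_fragment_graph(nodes, A)
    invisible(NULL)
  }
  rec <- function(k) {
    if (length(sols) >= max_solutions)
      stop("enumeration cap of ", max_solutions, " solutions exceeded",
           call. = FALSE)
    if (k > np) {
      accept(A)
      return(invisible(NULL))
    }
    i <- pairs[k, 1]; j <- pairs[k, 2]
    hi <- min(ub[i, j], v[i] - deg[i], v[j] - deg[j])
    for (y in 0:hi) {
      A[i, j] <<- A[j, i] <<- y
      deg[i] <<- deg[i] + y; deg[j] <<- deg[j] + y
      # row i is fully assigned once its last pair (i, n) is set
      if (!(j == n && deg[i] != v[i])) rec(k + 1L)
      deg[i] <<- deg[i] - y; deg[j] <<- deg[j] - y
      A[i, j] <<- A[j, i] <<- 0L
    }
    invisible(NULL)
  }
  rec(1L)
  attr(sols, "enumeration_state") <-
    list(cuts = cuts, n_sol = length(sols), n_raw = n_raw,
         n_disconnected = n_disc)
  sols
}

#' Size of the unconstrained group-combination space
#'
#' Number of subsets of the chemical groups (dummy excluded) available to a
#' generation problem with no size or occurrence constraints: `2^n` for `n`
#' chemical groups. This is the combinatorial space that the size bounds and
#' structural constraints prune.
#'
#' @param groupset A [group_set()], or an integer count of chemical groups.
#' @return Numeric count (may exceed integer range).
#' @export
combination_space_size <- function(groupset) {
  n <- if (inherits(groupset, "group_set"))
    sum(!vapply(groupset$groups, `[[`, logical(1), "is_dummy"))
  else as.integer(groupset)
  2^n
}

# Enumerate admissible selections (instance-count vectors) of a group set:
# dummy exactly once, core groups at least once, per-group counts within
# occurrence limits, total chemical instances within the size bounds.
.admissible_selections <- function(groupset) {
  gs <- groupset$groups
  nm <- names(gs)
  dummy <- vapply(gs, `[[`, logical(1), "is_dummy")
  core <- vapply(gs, `[[`, logical(1), "is_core")
  maxo <- vapply(gs, `[[`, integer(1), "max_occurrences")
  rng <- lapply(seq_along(gs), function(i) {
    if (dummy[i]) 1L else if (core[i]) seq.int(1L, maxo[i]) else seq.int(0L, maxo[i])
  })
  grid <- do.call(expand.grid, c(rng, KEEP.OUT.ATTRS = FALSE))
  names(grid) <- nm
  tot <- rowSums(grid[, !dummy, drop = FALSE])
  grid <- grid[tot >= groupset$min_groups & tot <= groupset$max_groups, ,
               drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Generate every unique fragment for a group set
#'
#' Iterates over all admissible group selections (size bounds on chemical
#' group instances, per-group occurrence limits, the dummy exactly once, core
#' groups always included), enumerates the feasible connected graphs of each
#' selection with [enumerate_fragments()], assembles each graph into an
#' atom-level fragment and deduplicates across selections by canonical
#' assembled SMILES (asymmetric groups can make distinct graphs coincide, and
#' permuted instances of one group always do).
#'
#' @param groupset A [group_set()].
#' @param max_solutions Per-selection enumeration cap.
#' @param progress Emit a message every 200 selections.
#' @return A data frame of class `fragment_library` with columns `id`,
#'   `smiles` (one `*` attachment point), `selection`, `n_nodes`; the
#'   corresponding `fragment_graph` objects are kept in the `graphs`
#'   attribute, and per-run counts in the `summary` attribute.
#' @export
generate_all <- function(groupset, max_solutions = 10000L, progress = FALSE) {
  stopifnot(inherits(groupset, "group_set"))
  sel <- .admissible_selections(groupset)
  graphs <- list()
  sel_lab <- character()
  n_feasible_sel <- 0L
  for (r in seq_len(nrow(sel))) {
    if (progress && r %% 200L == 0L)
      message("selection ", r, "/", nrow(sel), " (", length(graphs),
              " graphs so far)")
    counts <- unlist(sel[r, , drop = TRUE])
    counts <- counts[counts > 0]
    if (sum(counts * vapply(names(counts), function(g)
      groupset$groups[[g]]$valence, integer(1))) %% 2L == 1L) next
    ns <- expand_instances(groupset, counts)
    if (nrow(ns) < 2L) next
    found <- enumerate_fragments(ns, max_solutions = max_solutions)
    if (length(found)) n_feasible_sel <- n_feasible_sel + 1L
    lab <- paste(paste0(names(counts), "x", counts), collapse = "+")
    for (g in found) {
      graphs[[length(graphs) + 1L]] <- g
      sel_lab <- c(sel_lab, lab)
    }
  }
  if (!length(graphs)) {
    out <- data.frame(id = character(), smiles = character(),
                      selection = character(), n_nodes = integer())
    attr(out, "graphs") <- list()
    class(out) <- c("fragment_library", "data.frame")
    return(out)
  }
  bms <- lapply(graphs, fragment_to_bond_matrix, groupset = groupset)
  smi <- bond_matrices_to_smiles(bms, allow_attachment = TRUE)
  ok <- !is.na(smi) & !grepl(".", smi, fixed = TRUE)
  keep <- ok & !duplicated(smi)
  out <- data.frame(
    id = paste0(substr(groupset$role, 1, 1), seq_len(sum(keep))),
    smiles = smi[keep],
    selection = sel_lab[keep],
    n_nodes = vapply(graphs[keep], function(g) nrow(g$adjacency), integer(1)),
    stringsAsFactors = FALSE)
  attr(out, "graphs") <- graphs[keep]
  attr(out, "summary") <- list(
    n_selections = nrow(sel), n_feasible_selections = n_feasible_sel,
    n_graphs = length(graphs), n_assembly_failed = sum(!ok),
    n_unique = sum(keep))
  class(out) <- c("fragment_library", "data.frame")
  out
}

#' @export
print.fragment_library <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<fragment_library> %d unique fragments", nrow(x)))
  if (!is.null(s))
    cat(sprintf(" (from %d graphs over %d feasible of %d selections)",
                s$n_graphs, s$n_feasible_selections, s$n_selections))
  cat("\n")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Export fragments as a .smi file and adjacency CSVs
#'
#' Writes one SMILES (with its `*` attachment point) plus identifier per line
#' to `<stem>.smi`, and optionally each fragment's labeled adjacency matrix to
#' `<stem>_adjacency.csv` (stacked blocks with a leading id column).
#'
#' @param lib A `fragment_library` from [generate_all()].
#' @param stem Output path stem.
#' @param adjacency Also write the adjacency CSV.
#' @return Invisibly, the paths written.
#' @export
write_fragments <- function(lib, stem, adjacency = FALSE) {
  smi_path <- paste0(stem, ".smi")
  writeLines(paste(lib$smiles, lib$id), smi_path)
  paths <- smi_path
  if (adjacency) {
    gpath <- paste0(stem, "_adjacency.csv")
    blocks <- lapply(seq_len(nrow(lib)), function(i) {
      g <- attr(lib, "graphs")[[i]]
      A <- g$adjacency
      df <- data.frame(id = lib$id[i], node = rownames(A), A,
                       check.names = FALSE)
      df
    })
    utils::write.csv(do.call(rbind, blocks), gpath, row.names = FALSE)
    paths <- c(paths, gpath)
  }
  invisible(paths)
}
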