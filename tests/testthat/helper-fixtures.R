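# Shared fixtures: small group sets and node sets built in code, plus a
# canonical serialization for comparing sets of fragment graphs.

dummy_spec <- function() group_spec("dummy", "*", 1L)

# a compact chemistry for assembly tests
spec_hydroxyl <- function() group_spec("hydroxyl", "O", 1L)
spec_methyl <- function(max = 1L) group_spec("methyl", "C", 1L, max_occurrences = max)
spec_methylidene <- function(max = 1L)
  group_spec("methylidene", "C", 2L, max_occurrences = max)
spec_methyllidyne <- function() group_spec("methyllidyne", "C", 3L)
spec_ester <- function() group_spec(
  "ester", "C(=O)O", 2L,
  connections = list(list(atom = 1L, cap = 1L), list(atom = "final", cap = 1L)))
spec_sulfate <- function() group_spec("sulfate", "OS(=O)(=O)[O-]", 1L)
spec_phenyl_para <- function() group_spec(
  "phenyl", "c1ccccc1", 2L,
  connections = list(list(atom = 1L, cap = 1L), list(atom = 4L, cap = 1L)))
spec_butylene <- function(max = 1L) group_spec(
  "c4h8", "CCCC", 2L,
  connections = list(list(atom = 1L, cap = 1L), list(atom = "final", cap = 1L)),
  max_occurrences = max)

# node set built directly (bypassing selection machinery) for enumeration
# tests; groups must exist in some group_set for atom-level assembly only.
make_nodes <- function(labels, valences, multi) {
  structure(
    data.frame(label = labels, group = labels, valence = as.integer(valences),
               multi = multi, count = 1L, stringsAsFactors = FALSE),
    class = c("node_set", "data.frame"))
}

# serialize a fragment-graph list into a sortable character set
graph_signatures <- function(graphs) {
  sort(vapply(graphs, function(g)
    paste(as.integer(g$adjacency), collapse = ","), character(1)))
}

# node sets (<= 6 nodes) spanning collapsed nodes, multivalence nodes,
# multi-edges and potential cycles, used for oracle-equivalence checks
oracle_node_sets <- function() {
  list(
    two_singles = make_nodes(c("a", "b"), c(1, 1), c(FALSE, FALSE)),
    single_vs_tri = make_nodes(c("a", "b"), c(1, 3), c(FALSE, TRUE)),
    collapsed_pair = make_nodes(c("a", "m"), c(2, 2), c(TRUE, FALSE)),
    iso_branch = make_nodes(c("ch", "m", "d"), c(3, 2, 1),
                            c(TRUE, FALSE, FALSE)),
    chain4 = make_nodes(c("d", "a", "b", "m"), c(1, 2, 2, 1),
                        c(FALSE, TRUE, TRUE, FALSE)),
    cyclic5 = make_nodes(c("a", "b", "c", "d2", "m"), c(2, 2, 3, 2, 1),
                         c(TRUE, TRUE, TRUE, TRUE, FALSE)),
    dense6 = make_nodes(c("a", "b", "c", "d2", "e", "m"),
                        c(3, 2, 2, 2, 2, 1),
                        c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
    multi_edge6 = make_nodes(c("ch1", "ch2", "m1", "m2", "d", "e"),
                             c(3, 3, 2, 2, 1, 1),
                             c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)))
}

shipped_head_set <- function()
  read_group_table(system.file("extdata", "head_groups.csv",
                               package = "surfcamd"),
                   role = "head", size_bounds = c(2L, 4L))

shipped_tail_set <- function()
  read_group_table(system.file("extdata", "tail_groups.csv",
                               package = "surfcamd"),
                   role = "tail", size_bounds = c(3L, 7L),
                   core_groups = "hexylene")
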