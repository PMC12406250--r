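test_that("groups convert to bond matrices with implicit-hydrogen bookkeeping", {
  bm <- group_to_bond_matrix(spec_methyl())
  expect_length(bm$atoms, 1L)
  expect_equal(sum(bm$bond), 0)
  expect_equal(surfcamd:::implicit_hydrogens(bm), 4L)

  su <- group_to_bond_matrix(spec_sulfate())
  expect_length(su$atoms, 5L)
  expect_equal(sum(su$charge), -1L)
  expect_equal(sum(su$bond > 0) / 2, 4)          # O-S plus three S-O bonds

  du <- group_to_bond_matrix(dummy_spec())
  expect_identical(du$atoms, "*")

  expect_error(group_to_bond_matrix(
    group_spec("bad", "C=O", 2L,
               connections = list(list(atom = 2L, cap = 2L)))),
    "replaceable hydrogen")
})

test_that("fragment assembly places bonds at declared connection atoms", {
  toys <- toy_group_sets()
  lib <- generate_all(toys$hydroxyl_only$groupset)
  expect_identical(lib$smiles, canonical_smiles("*O"))

  # para-substituted phenyl: neighbors land on ring atoms 1 and 4
  gs <- group_set(list(dummy_spec(), spec_phenyl_para(), spec_methyl()),
                  role = "tail", min_groups = 2L, max_groups = 2L)
  lib <- generate_all(gs)
  expect_identical(lib$smiles, canonical_smiles("Cc1ccc(*)cc1"))
  expect_false(identical(lib$smiles, canonical_smiles("Cc1ccccc1*")))
})

test_that("head-tail fusion removes the dummies and conserves atoms", {
  h <- surfcamd:::ob_parse_smiles("*O")[[1]]
  t <- surfcamd:::ob_parse_smiles("*C")[[1]]
  m <- combine_head_tail(h, t)
  expect_length(m$atoms, length(h$atoms) + length(t$atoms) - 2L)
  expect_false(any(m$atoms == "*"))
  expect_identical(to_smiles(m), canonical_smiles("CO"))

  # sodium-dodecyl-sulfate skeleton from sulfate head + dodecyl tail
  hd <- surfcamd:::ob_parse_smiles("*OS(=O)(=O)[O-]")[[1]]
  tl <- surfcamd:::ob_parse_smiles("*CCCCCCCCCCCC")[[1]]
  sds <- combine_head_tail(hd, tl)
  expect_identical(to_smiles(sds),
                   canonical_smiles("CCCCCCCCCCCCOS(=O)(=O)[O-]"))

  expect_error(combine_head_tail(m, t), "exactly one dummy")
})

test_that("to_smiles sanitizes and refuses disconnected or dummy-bearing matrices", {
  single_c <- surfcamd:::new_bond_matrix("C", 0L, matrix(0L, 1, 1))
  expect_identical(to_smiles(single_c), "C")

  two_frag <- surfcamd:::new_bond_matrix(c("C", "O"), c(0L, 0L),
                                         matrix(0L, 2, 2))
  expect_error(to_smiles(two_frag), "[Dd]isconnected")

  with_dummy <- surfcamd:::ob_parse_smiles("*C")[[1]]
  expect_error(to_smiles(with_dummy), "dummy")
  expect_identical(to_smiles(with_dummy, allow_attachment = TRUE),
                   canonical_smiles("*C"))

  penta <- surfcamd:::new_bond_matrix(
    rep("C", 6), integer(6),
    {
      b <- matrix(0L, 6, 6); b[1, 2:6] <- 1L; b[2:6, 1] <- 1L; b
    })
  expect_error(to_smiles(penta), "valence violation")
})

test_that("the dipentyl sulfosuccinate node set reproduces its printed graph and molecule", {
  # 1,4-dioxo-1,4-dipentoxybutane-2-sulfonate: CH(SO3-) backbone carrying two
  # pentyl ester arms, with the two CH3 groups collapsed into one node
  gset <- group_set(list(
    dummy_spec(),
    group_spec("sulfonate", "S(=O)(=O)[O-]", 1L),
    group_spec("methine", "C", 3L),
    group_spec("coo", "C(=O)O", 2L,
               connections = list(list(atom = 1L, cap = 1L),
                                  list(atom = "final", cap = 1L))),
    group_spec("ch2coo", "CC(=O)O", 2L,
               connections = list(list(atom = 1L, cap = 1L),
                                  list(atom = "final", cap = 1L))),
    spec_butylene(max = 2L),
    spec_methyl(max = 2L)), role = "tail", min_groups = 1L, max_groups = 8L)
  ns <- expand_instances(gset, c(sulfonate = 1, methine = 1, coo = 1,
                                 ch2coo = 1, c4h8 = 2, methyl = 2))
  expect_equal(nrow(ns), 7L)
  expect_equal(sum(ns$multi), 5L)   # the worked Jm = 3 / Nc = 25 case
  sols <- enumerate_fragments(ns)
  # hand-built adjacency in node order: sulfonate, methine, coo, ch2coo,
  # c4h8#1, c4h8#2, collapsed methyl
  A <- matrix(0L, 7, 7)
  edges <- rbind(c(1, 2), c(2, 3), c(2, 4), c(3, 5), c(4, 6), c(5, 7), c(6, 7))
  A[edges] <- 1L
  A <- A + t(A)
  hits <- vapply(sols, function(g) identical(unname(g$adjacency), A),
                 logical(1))
  expect_true(any(hits))
  # the oracle agrees on the full solution set at 7 nodes
  expect_identical(graph_signatures(sols),
                   graph_signatures(brute_force_enumerate(ns)))
  # assembly reproduces the hand-built reference SMILES
  bm <- fragment_to_bond_matrix(sols[[which(hits)[1]]], gset)
  ref <- canonical_smiles("CCCCCOC(=O)C(S(=O)(=O)[O-])CC(=O)OCCCCC")
  expect_identical(to_smiles(bm), ref)
})

test_that("assembly is invariant to swapping instances of the same group", {
  gset <- group_set(list(dummy_spec(), spec_butylene(max = 2L),
                         spec_methyllidyne(), spec_methyl(max = 2L)),
                    role = "tail", min_groups = 1L, max_groups = 6L)
  ns <- expand_instances(gset, c(dummy = 1, c4h8 = 2, methyllidyne = 1,
                                 methyl = 2))
  sols <- enumerate_fragments(ns)
  expect_gt(length(sols), 0L)
  emit <- function(g) tryCatch(
    to_smiles(fragment_to_bond_matrix(g, gset), allow_attachment = TRUE),
    error = function(e) paste("rejected:", conditionMessage(e)))
  n_ok <- 0L
  for (g in sols) {
    # swap the two c4h8 instance nodes (an automorphism of the node set)
    perm <- seq_len(nrow(ns))
    i <- which(ns$group == "c4h8")
    perm[i] <- rev(perm[i])
    g2 <- surfcamd:::new_fragment_graph(ns, g$adjacency[perm, perm])
    s1 <- emit(g)
    s2 <- emit(g2)
    expect_identical(s1, s2)
    if (!startsWith(s1, "rejected:")) n_ok <- n_ok + 1L
  }
  expect_gt(n_ok, 0L)
})

test_that("assemble_library crosses all pairs and records per-candidate failures", {
  h1 <- data.frame(id = "h1", smiles = "*O")
  t1 <- data.frame(id = "t1", smiles = "*C")
  one <- assemble_library(h1, t1)
  expect_equal(nrow(one), 1L)
  expect_true(one$valid)

  heads <- data.frame(id = paste0("h", 1:3),
                      smiles = c("*O", "*OS(=O)(=O)[O-]", "*C(=O)OC"))
  tails <- data.frame(id = paste0("t", 1:2),
                      smiles = c("*C", "*CCCCCC"))
  lib <- assemble_library(heads, tails,
                          extra = c("CCO", "CC.O", "CCCCCCCCCCCCOS(=O)(=O)[O-]"))
  expect_equal(nrow(lib), 3 * 2 + 3)
  s <- attr(lib, "summary")
  expect_equal(s$n_heads, 3L)
  expect_equal(s$n_tails, 2L)
  # the multi-fragment extra is rejected with a reason, the rest pass
  expect_equal(sum(!lib$valid), 1L)
  expect_match(lib$rejection_reason[!lib$valid], "disconnected")
  # every valid SMILES re-parses to one connected molecule, identically
  re <- canonical_smiles(lib$smiles[lib$valid])
  expect_false(any(grepl(".", re, fixed = TRUE)))
  expect_identical(re, lib$smiles[lib$valid])
})
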