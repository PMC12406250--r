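test_that("epsilon grids span the observed range with q+1 points", {
  g <- build_grid(c(0, 2, 5, 10), q = 10)
  expect_length(g$eps, 11L)
  expect_equal(g$eps[1], 10)
  expect_equal(g$eps[11], 0)
  expect_equal(diff(g$eps), rep(-1, 10))
  expect_warning(g0 <- build_grid(c(3, 3, 3), q = 10), "degenerate")
  expect_length(g0$eps, 1L)
  expect_error(build_grid(1:3, q = 0), "q must be")
  expect_error(build_grid(numeric()), "no finite")
})

test_that("a candidate dominating every objective wins every feasible cell", {
  cand <- data.frame(id = c("A", "B"), f1 = c(5, 1), f2 = c(4, 2),
                     f3 = c(9, 3))
  obj <- data.frame(property = c("f1", "f2", "f3"), role = "objective",
                    direction = "max", lower = -Inf, upper = Inf)
  sol <- epsilon_constraint_enumerate(cand, obj, q = 4)
  expect_identical(sol$id, "A")
  expect_equal(sol$n_cells_won, attr(sol, "n_subproblems"))
})

test_that("single-objective degenerate case returns the global optimum", {
  cand <- data.frame(id = c("A", "B", "C"), f1 = c(1, 3, 2))
  obj <- data.frame(property = "f1", role = "objective", direction = "max",
                    lower = -Inf, upper = Inf)
  expect_identical(epsilon_constraint_enumerate(cand, obj)$id, "B")
})

test_that("cell winners match an independently coded exhaustive evaluation", {
  set.seed(11)
  cand <- data.frame(id = sprintf("c%02d", 1:5),
                     f1 = c(3, 1, 4, 2, 5), f2 = c(10, 40, 20, 50, 5))
  obj <- data.frame(property = c("f1", "f2"), role = "objective",
                    direction = c("max", "max"), lower = -Inf, upper = Inf)
  q <- 5L
  sol <- epsilon_constraint_enumerate(cand, obj, q = q)
  # oracle: direct loop over the grid of Eq-14 epsilon values
  r <- max(cand$f2) - min(cand$f2)
  oracle <- character()
  for (k in 0:q) {
    eps <- max(cand$f2) - k * r / q
    feas <- cand[cand$f2 >= eps, ]
    if (!nrow(feas)) next
    best <- feas[feas$f1 == max(feas$f1), ]
    if (nrow(best) > 1) best <- best[order(-best$f2, best$id), ][1, ]
    oracle <- c(oracle, best$id)
  }
  expect_setequal(sol$id, unique(oracle))
  # enumeration is invariant to candidate ordering
  perm <- cand[sample(nrow(cand)), ]
  expect_setequal(epsilon_constraint_enumerate(perm, obj, q = q)$id, sol$id)
})

test_that("pareto filtering keeps exactly the nondominated points", {
  d <- data.frame(f1 = c(1, 0), f2 = c(1, 0))
  kept <- pareto_filter(d, c("max", "max"))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$f1, 1)
  # identical duplicates are retained and flagged as ties
  dup <- data.frame(f1 = c(1, 1, 0), f2 = c(2, 2, 5))
  keptd <- pareto_filter(dup, c("max", "max"))
  expect_equal(nrow(keptd), 3L)
  expect_equal(sum(attr(keptd, "tie")), 2L)
  # random 50-point cloud versus the O(n^2) pairwise oracle
  set.seed(19)
  cloud <- data.frame(f1 = runif(50), f2 = runif(50), f3 = runif(50))
  dirs <- c("max", "min", "max")
  kept50 <- pareto_filter(cloud, dirs)
  ov <- sweep(as.matrix(cloud), 2, ifelse(dirs == "max", 1, -1), `*`)
  dominated <- vapply(seq_len(50), function(i) {
    for (j in seq_len(50)) {
      if (j != i && all(ov[j, ] >= ov[i, ]) && any(ov[j, ] > ov[i, ]))
        return(TRUE)
    }
    FALSE
  }, logical(1))
  expect_identical(sort(as.integer(rownames(kept50))),
                   sort(which(!dominated)))
})

test_that("every epsilon-constraint solution survives the pareto filter up to ties", {
  set.seed(23)
  cand <- data.frame(id = sprintf("c%02d", 1:30),
                     f1 = rnorm(30), f2 = rnorm(30))
  obj <- data.frame(property = c("f1", "f2"), role = "objective",
                    direction = c("max", "min"), lower = -Inf, upper = Inf)
  sol <- epsilon_constraint_enumerate(cand, obj, q = 10)
  kept <- pareto_filter(sol[, c("id", "f1", "f2")], obj$direction)
  expect_setequal(kept$id, sol$id)
})

test_that("TOPSIS closeness is 1 at the ideal, 0 at the negative-ideal, and matches hand arithmetic", {
  front <- data.frame(id = c("ideal", "mid", "worst"),
                      f1 = c(1, 0.8, 0.2), f2 = c(1, 0.5, 0.1))
  r <- topsis_rank(front, c("max", "max"))
  expect_equal(r$closeness[r$id == "ideal"], 1)
  expect_equal(r$closeness[r$id == "worst"], 0)
  # hand computation for the middle candidate: normalized (0.75, 4/9)
  n1 <- (0.8 - 0.2) / 0.8
  n2 <- (0.5 - 0.1) / 0.9
  dpos <- sqrt((1 - n1)^2 + (1 - n2)^2)
  dneg <- sqrt(n1^2 + n2^2)
  expect_equal(r$closeness[r$id == "mid"], dneg / (dpos + dneg),
               tolerance = 1e-12)
  expect_identical(r$id, c("ideal", "mid", "worst"))  # descending order
  # affine rescaling of one objective is absorbed by the normalization
  resc <- front
  resc$f2 <- 100 * resc$f2 - 7
  expect_equal(topsis_rank(resc, c("max", "max"))$closeness, r$closeness,
               tolerance = 1e-12)
  # min-direction orientation flips the ranking
  rmin <- topsis_rank(front, c("min", "min"))
  expect_equal(rmin$closeness[rmin$id == "ideal"], 0)
  # all-constant front degenerates to 0.5 with a warning
  flat <- data.frame(f1 = c(1, 1), f2 = c(2, 2))
  expect_warning(rf <- topsis_rank(flat, c("max", "max")), "zero range")
  expect_equal(rf$closeness, c(0.5, 0.5))
})

test_that("objective tables parse constraints, directions and infinite cutoffs", {
  p <- system.file("extdata", "objectives_case1.csv", package = "surfcamd")
  obj <- read_objective_table(p)
  expect_equal(sum(obj$role == "objective"), 3L)
  expect_equal(obj$direction[obj$property == "biodegradability"], "max")
  expect_equal(obj$upper[obj$property == "krafft_point"], Inf)
  expect_equal(obj$lower[obj$property == "surface_tension"], 20)
  p2 <- system.file("extdata", "objectives_case2.csv", package = "surfcamd")
  obj2 <- read_objective_table(p2)
  expect_equal(sum(obj2$role == "objective"), 2L)
  expect_equal(obj2$upper[obj2$property == "SAscore"], 4.5)
})

test_that("rank_candidates applies cutoffs, flags the front and orders by closeness", {
  set.seed(31)
  pred <- data.frame(id = sprintf("c%02d", 1:40),
                     SAscore = runif(40, 1, 8),
                     logCMC = rnorm(40, 2),
                     biodegradability = runif(40),
                     krafft_point = runif(40, -20, 90),
                     surface_tension = runif(40, 10, 50),
                     logLC50 = rnorm(40, 0.5))
  obj <- read_objective_table(system.file("extdata", "objectives_case1.csv",
                                          package = "surfcamd"))
  out <- rank_candidates(pred, obj, q = 6, top_k = 3)
  expect_true(all(c("feasible", "on_front", "closeness") %in% names(out)))
  expect_true(all(out$on_front[!is.na(out$closeness)]))
  # cutoffs respected
  infeas <- !out$feasible
  expect_true(all(out$krafft_point[infeas] < 0 |
                    out$surface_tension[infeas] < 20 |
                    out$surface_tension[infeas] > 40 |
                    out$logLC50[infeas] < 0))
  expect_false(any(out$on_front & !out$feasible))
  top <- attr(out, "top")
  expect_lte(nrow(top), 3L)
  expect_equal(top$closeness, sort(top$closeness, decreasing = TRUE))
})
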