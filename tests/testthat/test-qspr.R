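test_that("descriptor computation is per-molecule fault tolerant and deterministic", {
  d <- compute_descriptors(c("CCO", "CCO", "not a molecule ((", "c1ccccc1O"))
  expect_s3_class(d, "descriptor_table")
  expect_equal(nrow(d), 4L)
  fails <- attr(d, "failures")
  expect_true(is.na(fails[1]) && is.na(fails[2]) && is.na(fails[4]))
  expect_false(is.na(fails[3]))
  expect_true(all(is.na(as.numeric(d[3, ]))))
  # duplicate molecules get identical rows; computable values are finite
  expect_equal(as.numeric(d[1, ]), as.numeric(d[2, ]))
  expect_true(all(is.finite(as.numeric(d[1, ]))))
  # empty input -> empty table
  expect_equal(nrow(compute_descriptors(character())), 0L)
})

test_that("descriptor filtering drops constants, duplicates and hubs, and is idempotent", {
  set.seed(42)
  base <- matrix(rnorm(60 * 6), 60, 6,
                 dimnames = list(NULL, paste0("v", 1:6)))
  tbl <- as.data.frame(base)
  tbl$const <- 1
  tbl$copy_of_v1 <- tbl$v1                  # identical pair: later member goes
  tbl$with_na <- c(NA, rnorm(59))
  # a hub correlated with three others
  tbl$hub <- tbl$v2 + tbl$v3 * 0            # placeholder, replaced below
  tbl$h1 <- tbl$v4 + rnorm(60, sd = 0.01)
  tbl$hub <- NULL
  tbl$hub <- (tbl$v4 + rnorm(60, sd = 0.005))
  tbl$h2 <- tbl$hub + rnorm(60, sd = 0.01)
  tbl$h3 <- tbl$hub + rnorm(60, sd = 0.01)
  f <- filter_descriptors(tbl, threshold = 0.9)
  dropped <- attr(f, "dropped")
  expect_false("const" %in% names(f))
  expect_false("with_na" %in% names(f))
  expect_false("copy_of_v1" %in% names(f))
  expect_true("v1" %in% names(f))           # earlier member survives
  expect_equal(unname(dropped["const"]), "constant")
  expect_equal(unname(dropped["with_na"]), "missing_or_nonnumeric")
  # hub correlates with h1, h2, h3 (degree > 2) and is removed outright
  expect_equal(unname(dropped["hub"]), "degree_gt_2")
  # no high-correlation pair remains
  cm <- abs(cor(as.matrix(as.data.frame(f))))
  diag(cm) <- 0
  expect_lt(max(cm), 0.9 + 1e-12)
  # idempotence
  f2 <- filter_descriptors(f, threshold = 0.9)
  expect_identical(names(f2), names(f))
  expect_error(filter_descriptors(tbl[1, ]), "at least 2")
})

test_that("model training recovers a noiseless sparse signal", {
  d <- synthetic_qspr_dataset(n = 200, p = 30, k = 2, beta = c(2, -3),
                              sigma = 0, seed = 7)
  m <- train_qspr(d$x, d$y, family = "lasso", seed = 0)
  supp <- names(which(abs(m$coef) > 1e-6))
  expect_setequal(supp, names(which(d$beta != 0)))
  expect_gt(m$metrics$test["r2"], 0.99)
  # against closed-form least squares on the true support
  ls <- coef(lm(d$y ~ d$x$d01 + d$x$d02))
  expect_equal(unname(ls[2:3]), c(2, -3), tolerance = 1e-8)
  expect_equal(unname(m$coef[c("d01", "d02")]), c(2, -3), tolerance = 0.05)

  mp <- train_qspr(d$x, d$y, family = "pls", ncomp = 4, seed = 0)
  expect_gt(mp$metrics$test["r2"], 0.99)
})

test_that("degenerate and malformed training inputs are handled", {
  d <- synthetic_qspr_dataset(n = 40, p = 5, seed = 1)
  m <- train_qspr(d$x, rep(2.5, 40), family = "lasso", seed = 0)
  expect_true(m$constant_y)
  expect_equal(unname(predict(m, d$x)), rep(2.5, 40))
  expect_equal(unname(m$metrics$train["r2_defined"]), 0)
  expect_error(train_qspr(d$x, d$y[-1]), "rows")
  expect_error(train_qspr(d$x[1:5, ], d$y[1:5]), "at least 10")
})

test_that("evaluation uses the standard R2 and RMSE definitions", {
  d <- synthetic_qspr_dataset(n = 50, p = 5, k = 2, sigma = 0.3, seed = 3)
  m <- train_qspr(d$x, d$y, family = "lasso", seed = 0)
  # perfect predictions
  pred <- predict(m, d$x)
  ev <- evaluate_qspr(m, d$x, pred)            # y := model predictions
  expect_equal(unname(ev["r2"]), 1, tolerance = 1e-12)
  expect_equal(unname(ev["rmse"]), 0, tolerance = 1e-12)
  # mean-only predictions give R2 = 0: brute-force recomputation
  const <- m; const$coef[] <- 0; const$intercept <- mean(d$y)
  ev0 <- evaluate_qspr(const, d$x, d$y)
  expect_equal(unname(ev0["r2"]), 0, tolerance = 1e-12)
  expect_equal(unname(ev0["rmse"]),
               sqrt(mean((d$y - mean(d$y))^2)), tolerance = 1e-12)
  # arbitrary affine mismatch matches direct recomputation
  ev1 <- evaluate_qspr(m, d$x, d$y + 0.5)
  expect_equal(unname(ev1["rmse"]),
               sqrt(mean((d$y + 0.5 - pred)^2)), tolerance = 1e-12)
  expect_error(evaluate_qspr(m, d$x[, 1:2], d$y), "missing descriptor")
})

test_that("prediction is affine, column-order invariant and artifact-stable", {
  d <- synthetic_qspr_dataset(n = 60, p = 8, k = 3, sigma = 0.1, seed = 5)
  m <- train_qspr(d$x, d$y, family = "lasso", seed = 0)
  p1 <- predict(m, d$x)
  # column order must not matter
  p2 <- predict(m, d$x[, rev(names(d$x))])
  expect_equal(p1, p2)
  # all-zero model predicts its intercept everywhere
  z <- m; z$coef[] <- 0; z$intercept <- 1.25
  expect_equal(unname(predict(z, d$x)), rep(1.25, 60))
  # identical refit under the same seed gives identical predictions
  m2 <- train_qspr(d$x, d$y, family = "lasso", seed = 0)
  expect_identical(predict(m2, d$x), p1)
  # two-file artifact round trip
  stem <- tempfile()
  write_qspr(m, stem)
  expect_true(all(file.exists(paste0(stem, ".json"),
                              paste0(stem, "_descriptors.txt"))))
  m3 <- read_qspr(stem)
  expect_equal(predict(m3, d$x), p1, tolerance = 1e-12)
  # log-scale round trip
  ml <- train_qspr(d$x, 10^(d$y / 5), family = "lasso",
                   transform = "log10", seed = 0)
  pm <- predict(ml, d$x)
  pn <- predict(ml, d$x, scale = "natural")
  expect_equal(pn, 10^pm)
})

test_that("lasso support recovery holds at the stated synthetic design", {
  # n = 200, p = 50, k = 5, sigma = 0.1; recovery across fixed seeds
  hits <- vapply(1:12, function(s) {
    d <- synthetic_qspr_dataset(n = 200, p = 50, k = 5, sigma = 0.1, seed = s)
    m <- train_qspr(d$x, d$y, family = "lasso", seed = s)
    truth <- names(which(d$beta != 0))
    sel <- names(which(abs(m$coef) > 1e-6))
    all(truth %in% sel)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
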