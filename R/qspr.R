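# QSPR: 2D descriptors, correlation-based filtering, linear model training
# (PLS or cross-validated lasso) and property prediction.

#' Compute 2D molecular descriptors from SMILES
#'
#' Builds a numeric descriptor block per molecule from the atom-level bond
#' matrix: atom and bond composition, ring and branching counts, degree
#' distribution, topological indices (Wiener, Zagreb, Randic, eccentricity)
#' on the heavy-atom graph, and Open Babel physicochemical properties (MW,
#' logP, TPSA, molar refractivity, hydrogen-bond acceptor/donor counts).
#' Failures are recorded per molecule (rows of `NA`), never globally fatal.
#'
#' @param smiles Character vector of SMILES.
#' @return A data frame of class `descriptor_table` (rows = molecules,
#'   columns = descriptors, all numeric) with attributes `smiles` and
#'   `failures` (character reasons, `NA` where fine).
#' @export
compute_descriptors <- function(smiles) {
  p_names <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD")
  if (!length(smiles)) {
    out <- as.data.frame(matrix(numeric(), 0, 0))
    attr(out, "smiles") <- character()
    attr(out, "failures") <- character()
    class(out) <- c("descriptor_table", "data.frame")
    return(out)
  }
  parsed <- ob_parse_smiles(smiles)
  failures <- rep(NA_character_, length(smiles))
  rows <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    bm <- parsed[[i]]
    if (is.null(bm)) {
      failures[i] <- "SMILES parse failed"
      next
    }
    if (any(bm$atoms == "*")) {
      failures[i] <- "attachment point in molecule"
      next
    }
    rows[[i]] <- .graph_descriptors(bm)
  }
  # Open Babel property block, one batched call on the parseable molecules
  okp <- which(!vapply(rows, is.null, logical(1)))
  props <- matrix(NA_real_, length(smiles), length(p_names),
                  dimnames = list(NULL, p_names))
  if (length(okp)) {
    pv <- tryCatch(.ob_properties(smiles[okp]), error = function(e) NULL)
    if (!is.null(pv)) props[okp, ] <- as.matrix(pv[, p_names])
  }
  g_names <- names(.graph_descriptors(ob_parse_smiles("C")[[1]]))
  mat <- matrix(NA_real_, length(smiles), length(g_names),
                dimnames = list(NULL, g_names))
  for (i in okp) mat[i, ] <- rows[[i]]
  out <- as.data.frame(cbind(mat, props))
  attr(out, "smiles") <- smiles
  attr(out, "failures") <- failures
  class(out) <- c("descriptor_table", "data.frame")
  out
}

.ob_properties <- function(smiles) {
  sdf <- ChemmineOB::convertFormat("SMI", "SDF",
                                   paste0(paste(smiles, collapse = "\n"), "\n"))
  sset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(textConnection(sdf)))
  ChemmineR::propOB(sset)
}

.graph_descriptors <- function(bm) {
  atoms <- bm$atoms
  n <- length(atoms)
  bond <- bm$bond
  deg <- rowSums(bond > 0)
  nb <- sum(bond > 0) / 2
  ncomp <- if (n == 1L) 1L else {
    g <- igraph::graph_from_adjacency_matrix(bond > 0, mode = "undirected")
    igraph::count_components(g)
  }
  halo <- c("F", "Cl", "Br", "I")
  ih <- implicit_hydrogens(bm)
  d <- c(
    n_heavy = n,
    n_C = sum(atoms == "C"), n_N = sum(atoms == "N"), n_O = sum(atoms == "O"),
    n_S = sum(atoms == "S"), n_P = sum(atoms == "P"),
    n_halogen = sum(atoms %in% halo),
    frac_hetero = mean(!(atoms == "C")),
    n_bonds = nb,
    n_double = sum(bond == 2) / 2, n_triple = sum(bond == 3) / 2,
    n_rings = nb - n + ncomp,
    total_charge = sum(bm$charge), n_charged = sum(bm$charge != 0),
    n_implicit_h = sum(ih, na.rm = TRUE),
    n_deg1 = sum(deg == 1), n_deg2 = sum(deg == 2),
    n_deg3 = sum(deg == 3), n_deg4 = sum(deg >= 4),
    branch_points = sum(deg >= 3))
  if (n > 1L) {
    g <- igraph::graph_from_adjacency_matrix(bond > 0, mode = "undirected")
    dist <- igraph::distances(g)
    fin <- is.finite(dist)
    ecc <- apply(ifelse(fin, dist, 0), 1, max)
    ij <- which(upper.tri(bond) & bond > 0, arr.ind = TRUE)
    d <- c(d,
           wiener = sum(dist[upper.tri(dist)][is.finite(dist[upper.tri(dist)])]),
           diameter = max(ecc), radius = min(ecc), mean_ecc = mean(ecc),
           zagreb_m1 = sum(deg^2),
           zagreb_m2 = sum(deg[ij[, 1]] * deg[ij[, 2]]),
           randic = sum(1 / sqrt(deg[ij[, 1]] * deg[ij[, 2]])))
  } else {
    d <- c(d, wiener = 0, diameter = 0, radius = 0, mean_ecc = 0,
           zagreb_m1 = 0, zagreb_m2 = 0, randic = 0)
  }
  d
}

#' Filter a descriptor table by the pairwise-correlation protocol
#'
#' Drops columns with missing or non-numeric entries and constant columns,
#' then builds the graph of descriptor pairs whose absolute Pearson
#' correlation exceeds `threshold`. Descriptors correlated with more than two
#' other descriptors are removed outright; among the surviving correlated
#' pairs the later-ordered member is discarded (ordering = the descriptor
#' generator's canonical column order), so that no high-correlation pair
#' remains. The operation is idempotent.
#'
#' @param table A `descriptor_table` or numeric data frame.
#' @param threshold Absolute-correlation threshold (default 0.9).
#' @return The filtered table (same class), with a `dropped` attribute naming
#'   removed columns and the removal stage.
#' @export
filter_descriptors <- function(table, threshold = 0.9) {
  if (nrow(table) < 2L)
    stop("descriptor filtering needs at least 2 molecules", call. = FALSE)
  x <- as.data.frame(table)
  dropped <- character()
  numeric_ok <- vapply(x, function(col) is.numeric(col) && !anyNA(col),
                       logical(1))
  dropped <- c(dropped, stats::setNames(rep("missing_or_nonnumeric",
                                            sum(!numeric_ok)),
                                        names(x)[!numeric_ok]))
  x <- x[numeric_ok]
  constant <- vapply(x, function(col) max(col) == min(col), logical(1))
  dropped <- c(dropped, stats::setNames(rep("constant", sum(constant)),
                                        names(x)[constant]))
  x <- x[!constant]
  if (ncol(x) > 1L) {
    cm <- abs(stats::cor(as.matrix(x)))
    diag(cm) <- 0
    high <- cm > threshold
    degree <- rowSums(high)
    hub <- degree > 2
    dropped <- c(dropped, stats::setNames(rep("degree_gt_2", sum(hub)),
                                          colnames(cm)[hub]))
    x <- x[!hub]
    if (ncol(x) > 1L) {
      cm <- abs(stats::cor(as.matrix(x)))
      diag(cm) <- 0
      keep <- rep(TRUE, ncol(x))
      for (i in seq_len(ncol(x) - 1L)) {
        if (!keep[i]) next
        partners <- which(cm[i, ] > threshold)
        partners <- partners[partners > i & keep[partners]]
        if (length(partners)) {
          keep[partners] <- FALSE
          dropped <- c(dropped,
                       stats::setNames(rep("correlated_pair",
                                           length(partners)),
                                       colnames(cm)[partners]))
        }
      }
      x <- x[keep]
    }
  }
  attr(x, "smiles") <- attr(table, "smiles")
  attr(x, "failures") <- attr(table, "failures")
  attr(x, "dropped") <- dropped
  class(x) <- class(table)
  x
}

#' Train a linear QSPR model
#'
#' Splits the data randomly into 80% training and 20% testing rows, fits
#' either a partial-least-squares regression (`family = "pls"`, with `ncomp`
#' latent components) or a lasso regression with 5-fold cross-validated
#' penalty selection (`family = "lasso"`), and reports the coefficient of
#' determination and root-mean-square error on both splits. The fitted
#' predictor is stored as an explicit affine function of the selected
#' descriptors, so predictions are exactly reproducible from the artifact.
#'
#' @param x Descriptor table (rows = molecules).
#' @param y Numeric property values, one per row of `x`.
#' @param family `"pls"` or `"lasso"`.
#' @param ncomp Number of PLS components (ignored for lasso).
#' @param transform `"identity"` or `"log10"` applied to `y` before fitting
#'   (log10 is the convention for CMC and LC50).
#' @param property Property name stored on the model.
#' @param seed Integer seed controlling the split and the CV folds.
#' @param cv_folds Folds for the lasso cross-validation.
#' @return An object of class `qspr_model`.
#' @export
train_qspr <- function(x, y, family = c("pls", "lasso"), ncomp = 2L,
                       transform = c("identity", "log10"),
                       property = "property", seed = 0L, cv_folds = 5L) {
  family <- match.arg(family)
  transform <- match.arg(transform)
  x <- as.data.frame(x)
  if (nrow(x) != length(y))
    stop("x has ", nrow(x), " rows but y has length ", length(y), call. = FALSE)
  if (nrow(x) < 10L)
    stop("need at least 10 molecules to fit a model", call. = FALSE)
  if (ncol(x) == 0L)
    stop("no descriptor columns left to fit on", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("x and y must be complete", call. = FALSE)
  yt <- if (transform == "log10") log10(y) else y
  xm <- as.matrix(x)
  n <- nrow(xm)
  set.seed(seed)
  test_idx <- sort(sample.int(n, size = max(1L, round(0.2 * n))))
  train_idx <- setdiff(seq_len(n), test_idx)
  xtr <- xm[train_idx, , drop = FALSE]
  ytr <- yt[train_idx]
  constant_y <- stats::sd(ytr) == 0
  p <- ncol(xm)
  if (constant_y) {
    coefs <- stats::setNames(rep(0, p), colnames(xm))
    intercept <- ytr[1]
    hyper <- list()
    nonzero <- 0L
  } else if (family == "pls") {
    ncomp <- min(as.integer(ncomp), p, length(train_idx) - 1L)
    fit <- mixOmics::pls(xtr, ytr, ncomp = ncomp, mode = "regression")
    nd <- function(m) { colnames(m) <- colnames(xm); m }
    intercept <- as.numeric(stats::predict(fit,
                                           nd(matrix(0, 1, p)))$predict[, , ncomp])
    coefs <- as.numeric(stats::predict(fit, nd(diag(p)))$predict[, , ncomp]) -
      intercept
    names(coefs) <- colnames(xm)
    hyper <- list(ncomp = ncomp)
    nonzero <- sum(coefs != 0)
  } else {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(cv_folds), length(train_idx)))
    fit <- glmnet::cv.glmnet(xtr, ytr, foldid = foldid)
    cf <- as.numeric(stats::coef(fit, s = "lambda.min"))
    intercept <- cf[1]
    coefs <- stats::setNames(cf[-1], colnames(xm))
    hyper <- list(lambda = fit$lambda.min)
    nonzero <- sum(coefs != 0)
  }
  model <- structure(
    list(property = property, family = family, transform = transform,
         descriptors = colnames(xm), coef = coefs, intercept = intercept,
         hyper = hyper, nonzero = nonzero, seed = as.integer(seed),
         n_train = length(train_idx), n_test = length(test_idx),
         constant_y = constant_y),
    class = "qspr_model")
  model$metrics <- list(
    train = .qspr_metrics(yt[train_idx], .affine_predict(model, xm[train_idx, , drop = FALSE])),
    test = .qspr_metrics(yt[test_idx], .affine_predict(model, xm[test_idx, , drop = FALSE])))
  model
}

.affine_predict <- function(model, xm) {
  miss <- setdiff(model$descriptors, colnames(xm))
  if (length(miss))
    stop("missing descriptor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  as.numeric(xm[, model$descriptors, drop = FALSE] %*% model$coef +
               model$intercept)
}

.qspr_metrics <- function(obs, pred) {
  rmse <- sqrt(mean((obs - pred)^2))
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum((obs - pred)^2) / ss_tot
  c(r2 = r2, rmse = rmse, r2_defined = as.numeric(ss_tot > 0))
}

#' Evaluate a QSPR model on a labeled set
#'
#' @param model A `qspr_model`.
#' @param x Descriptor table containing the model's descriptor columns.
#' @param y Property values on the natural scale (the model's transform is
#'   applied before scoring, matching how the model was fitted).
#' @return Named numeric vector `r2`, `rmse` (and an `r2_defined` flag).
#' @export
evaluate_qspr <- function(model, x, y) {
  stopifnot(inherits(model, "qspr_model"))
  yt <- if (model$transform == "log10") log10(y) else y
  .qspr_metrics(yt, .affine_predict(model, as.matrix(as.data.frame(x))))
}

#' Predict properties for molecules
#'
#' @param object A `qspr_model`.
#' @param newdata A descriptor table, or a character vector of SMILES (the
#'   descriptors are computed first; molecules that fail descriptor
#'   computation get `NA` with the reason in the `failures` attribute).
#' @param scale `"model"` returns values on the fitted scale (log10 for
#'   log-transformed properties, the convention used throughout);
#'   `"natural"` back-transforms.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.qspr_model <- function(object, newdata, scale = c("model", "natural"),
                               ...) {
  scale <- match.arg(scale)
  failures <- NULL
  if (is.character(newdata)) {
    newdata <- compute_descriptors(newdata)
    failures <- attr(newdata, "failures")
  }
  xm <- as.matrix(as.data.frame(newdata))
  bad <- rowSums(is.na(xm)) > 0
  xm[is.na(xm)] <- 0
  pred <- .affine_predict(object, xm)
  pred[bad] <- NA_real_
  if (scale == "natural" && object$transform == "log10") pred <- 10^pred
  if (!is.null(failures)) attr(pred, "failures") <- failures
  pred
}

#' @export
print.qspr_model <- function(x, ...) {
  cat(sprintf("<qspr_model> %s  family=%s  transform=%s  nonzero=%d/%d\n",
              x$property, x$family, x$transform, x$nonzero,
              length(x$coef)))
  cat(sprintf("  train: R2=%.3f RMSE=%.3g   test: R2=%.3f RMSE=%.3g\n",
              x$metrics$train["r2"], x$metrics$train["rmse"],
              x$metrics$test["r2"], x$metrics$test["rmse"]))
  invisible(x)
}

#' Write / read a QSPR model artifact
#'
#' The artifact is a pair of files mirroring the two-file convention of model
#' + descriptor list: `<stem>.json` holds the parameters and metrics,
#' `<stem>_descriptors.txt` the ordered descriptor names the model needs.
#'
#' @param model A `qspr_model`.
#' @param stem Path stem for the two files.
#' @return Invisibly, the paths written.
#' @export
write_qspr <- function(model, stem) {
  stopifnot(inherits(model, "qspr_model"))
  jp <- paste0(stem, ".json")
  dp <- paste0(stem, "_descriptors.txt")
  jsonlite::write_json(
    list(property = model$property, family = model$family,
         transform = model$transform, intercept = model$intercept,
         coef = as.list(model$coef), hyper = model$hyper,
         nonzero = model$nonzero, seed = model$seed,
         n_train = model$n_train, n_test = model$n_test,
         constant_y = model$constant_y,
         metrics = lapply(model$metrics, as.list)),
    jp, auto_unbox = TRUE, digits = NA)
  writeLines(model$descriptors, dp)
  invisible(c(jp, dp))
}

#' @rdname write_qspr
#' @param stem Path stem used by [write_qspr()].
#' @export
read_qspr <- function(stem) {
  j <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  descriptors <- readLines(paste0(stem, "_descriptors.txt"))
  structure(
    list(property = j$property, family = j$family, transform = j$transform,
         descriptors = descriptors,
         coef = stats::setNames(as.numeric(j$coef[descriptors]), descriptors),
         intercept = j$intercept, hyper = as.list(j$hyper),
         nonzero = j$nonzero, seed = j$seed, n_train = j$n_train,
         n_test = j$n_test, constant_y = isTRUE(j$constant_y),
         metrics = lapply(j$metrics, unlist)),
    class = "qspr_model")
}
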