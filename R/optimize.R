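# Epsilon-constraint multiobjective ranking, Pareto filtering and TOPSIS.

#' Read an optimization configuration table
#'
#' Layout: one row per property model with columns `model`,
#' `objective function/constraint`, `max/min`, `min`, `max`, `unit`. `inf`
#' (any case) and empty cells are accepted for unbounded cutoffs.
#'
#' @param path CSV file path.
#' @return A data frame of class `objective_spec` with columns `property`,
#'   `role` (objective/constraint), `direction` (max/min or `NA`), `lower`,
#'   `upper`, `unit`.
#' @export
read_objective_table <- function(path) {
  if (!file.exists(path)) stop("objective table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         strip.white = TRUE)
  hdr <- .norm_header(names(tab))
  pick <- function(keys) {
    hit <- which(hdr %in% keys)
    if (!length(hit)) NA_integer_ else hit[1]
  }
  ci <- c(property = pick(c("model", "property")),
          role = pick(c("objectivefunctionconstraint", "role", "type")),
          dir = pick(c("maxmin", "direction")),
          lower = pick("min"), upper = pick("max"),
          unit = pick(c("unit", "units")))
  if (anyNA(ci[c("property", "role")]))
    stop("objective table must have 'model' and 'objective function/constraint' columns",
         call. = FALSE)
  num <- function(v, default) {
    v <- tolower(trimws(as.character(v)))
    out <- suppressWarnings(as.numeric(v))
    out[v %in% c("inf", "+inf")] <- Inf
    out[v == "-inf"] <- -Inf
    out[is.na(out) & !v %in% c("inf", "+inf", "-inf")] <- default
    out
  }
  role <- ifelse(grepl("objective", tolower(tab[[ci["role"]]])),
                 "objective", "constraint")
  dir <- if (!is.na(ci["dir"])) tolower(trimws(tab[[ci["dir"]]])) else
    rep("", nrow(tab))
  dir[!dir %in% c("max", "min")] <- NA_character_
  if (any(role == "objective" & is.na(dir)))
    stop("every objective row needs a max/min direction", call. = FALSE)
  out <- data.frame(
    property = as.character(tab[[ci["property"]]]),
    role = role, direction = dir,
    lower = if (!is.na(ci["lower"])) num(tab[[ci["lower"]]], -Inf) else -Inf,
    upper = if (!is.na(ci["upper"])) num(tab[[ci["upper"]]], Inf) else Inf,
    unit = if (!is.na(ci["unit"])) as.character(tab[[ci["unit"]]]) else NA_character_,
    stringsAsFactors = FALSE)
  if (any(out$lower > out$upper))
    stop("constraint with lower cutoff above upper cutoff", call. = FALSE)
  class(out) <- c("objective_spec", "data.frame")
  out
}

#' Build an epsilon grid over one objective's observed range
#'
#' The range `r = max - min` is divided into `q` equal intervals, giving
#' `q + 1` grid values from the observed maximum down to the observed minimum
#' (`eps_k = max - k * r / q`). A degenerate range collapses to a single grid
#' point with a warning.
#'
#' @param values Observed objective values over the candidate pool.
#' @param q Number of intervals (>= 1).
#' @return An object of class `epsilon_grid`: list with `eps`, `q`, `r`,
#'   `min`, `max`.
#' @export
build_grid <- function(values, q = 10L) {
  q <- as.integer(q)
  if (is.na(q) || q < 1L) stop("q must be >= 1", call. = FALSE)
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite objective values", call. = FALSE)
  fmax <- max(values); fmin <- min(values)
  r <- fmax - fmin
  if (r == 0) {
    warning("degenerate objective range; single-point grid")
    eps <- fmax
  } else {
    eps <- fmax - seq.int(0L, q) * r / q
  }
  structure(list(eps = eps, q = q, r = r, min = fmin, max = fmax),
            class = "epsilon_grid")
}

#' Enumerate epsilon-constraint subproblems over a candidate pool
#'
#' The first objective is optimized by enumeration while every other
#' objective is bounded by a grid value (at or above `eps` for maximized
#' secondaries, at or below the mirrored grid value for minimized ones). One
#' winner is picked per feasible grid cell (ties broken lexicographically on
#' the oriented secondary objectives, then by candidate id) and the union of
#' winners is returned.
#'
#' @param candidates Data frame with an `id` column (or rownames) and one
#'   numeric column per objective property.
#' @param objectives An `objective_spec` (only rows with `role ==
#'   "objective"` are used; order defines which objective is optimized).
#' @param q Intervals per secondary objective (scalar or one per secondary).
#' @return Data frame of distinct winners (id, objective values,
#'   `n_cells_won`), with attributes `n_subproblems`, `n_infeasible` and
#'   `grids`.
#' @export
epsilon_constraint_enumerate <- function(candidates, objectives, q = 10L) {
  obj <- objectives[objectives$role == "objective", , drop = FALSE]
  if (nrow(obj) < 1L) stop("no objectives defined", call. = FALSE)
  ids <- if (!is.null(candidates$id)) as.character(candidates$id) else
    rownames(candidates)
  miss <- setdiff(obj$property, names(candidates))
  if (length(miss))
    stop("candidate pool lacks objective column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  vals <- as.matrix(candidates[, obj$property, drop = FALSE])
  if (!nrow(vals)) stop("empty candidate pool", call. = FALSE)
  sgn <- ifelse(obj$direction == "max", 1, -1)
  ov <- sweep(vals, 2, sgn, `*`)  # oriented: larger is always better
  p <- nrow(obj)
  if (p == 1L) {
    best <- which(ov[, 1] == max(ov[, 1]))[1]
    out <- data.frame(id = ids[best], vals[best, , drop = FALSE],
                      n_cells_won = 1L, check.names = FALSE)
    attr(out, "n_subproblems") <- 1L
    attr(out, "n_infeasible") <- 0L
    return(out)
  }
  qv <- rep_len(as.integer(q), p - 1L)
  grids <- lapply(seq_len(p - 1L), function(i) build_grid(ov[, i + 1L], qv[i]))
  cells <- do.call(expand.grid,
                   c(lapply(grids, function(g) seq_along(g$eps)),
                     KEEP.OUT.ATTRS = FALSE))
  win <- integer(nrow(cells))
  for (r in seq_len(nrow(cells))) {
    feas <- rep(TRUE, nrow(ov))
    for (i in seq_len(p - 1L))
      feas <- feas & ov[, i + 1L] >= grids[[i]]$eps[cells[r, i]]
    if (!any(feas)) next
    cand <- which(feas)
    f1 <- ov[cand, 1L]
    cand <- cand[f1 == max(f1)]
    if (length(cand) > 1L) {
      # lexicographic on oriented secondaries, then id
      ord <- do.call(order, c(lapply(seq_len(p - 1L) + 1L,
                                     function(j) -ov[cand, j]),
                              list(ids[cand])))
      cand <- cand[ord[1L]]
    }
    win[r] <- cand
  }
  n_inf <- sum(win == 0L)
  win <- win[win > 0L]
  if (!length(win)) {
    warning("all epsilon cells infeasible")
    out <- data.frame(id = character(),
                      matrix(numeric(), 0, p,
                             dimnames = list(NULL, obj$property)),
                      n_cells_won = integer(), check.names = FALSE)
  } else {
    tab <- table(win)
    sel <- as.integer(names(tab))
    out <- data.frame(id = ids[sel], vals[sel, , drop = FALSE],
                      n_cells_won = as.integer(tab), check.names = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_subproblems") <- nrow(cells)
  attr(out, "n_infeasible") <- n_inf
  attr(out, "grids") <- grids
  out
}

#' Pareto (nondominated) filter
#'
#' Keeps the solutions not weakly dominated by a distinct strictly-better
#' solution: a row is dropped iff some other row is at least as good in every
#' objective and strictly better in at least one. Exact duplicates are all
#' retained and flagged as ties.
#'
#' @param solutions Data frame or matrix of objective values (plus optional
#'   non-numeric id columns, which are carried through).
#' @param directions Character vector, `"max"`/`"min"` per objective column.
#' @return The nondominated subset with a logical `tie` attribute.
#' @export
pareto_filter <- function(solutions, directions) {
  df <- as.data.frame(solutions)
  num <- vapply(df, is.numeric, logical(1))
  objcols <- names(df)[num]
  if (length(directions) != length(objcols))
    stop("need one direction per numeric objective column", call. = FALSE)
  ov <- as.matrix(df[objcols])
  ov <- sweep(ov, 2, ifelse(directions == "max", 1, -1), `*`)
  n <- nrow(ov)
  keep <- rep(TRUE, n)
  # vectorized pairwise dominance: j dominates i if ov[j,] >= ov[i,] with one >
  for (i in seq_len(n)) {
    ge <- colSums(t(ov) >= ov[i, ]) == ncol(ov)
    gt <- colSums(t(ov) > ov[i, ]) > 0
    if (any(ge & gt)) keep[i] <- FALSE
  }
  out <- df[keep, , drop = FALSE]
  dup <- duplicated(ov[keep, , drop = FALSE]) |
    duplicated(ov[keep, , drop = FALSE], fromLast = TRUE)
  attr(out, "tie") <- dup
  out
}

#' TOPSIS closeness ranking of a Pareto front
#'
#' Objective values are oriented so that larger is better, normalized per
#' objective by the maximum-minimum method, and each candidate is scored by
#' its Euclidean distances to the ideal point (all ones) and the
#' negative-ideal point (all zeros): closeness = d- / (d+ + d-), with equal
#' objective weights. If every objective has zero range the closeness is 0.5
#' for all candidates, with a warning.
#'
#' @param front Data frame or matrix of objective values (non-numeric columns
#'   carried through).
#' @param directions `"max"`/`"min"` per numeric objective column.
#' @return `front` with a `closeness` column, sorted by decreasing closeness.
#' @export
topsis_rank <- function(front, directions) {
  df <- as.data.frame(front)
  num <- vapply(df, is.numeric, logical(1))
  objcols <- names(df)[num]
  if (length(directions) != length(objcols))
    stop("need one direction per numeric objective column", call. = FALSE)
  ov <- as.matrix(df[objcols])
  if (!nrow(ov)) stop("empty front", call. = FALSE)
  ov <- sweep(ov, 2, ifelse(directions == "max", 1, -1), `*`)
  rng <- apply(ov, 2, function(cl) diff(range(cl)))
  if (all(rng == 0)) {
    warning("zero range on every objective; closeness set to 0.5")
    df$closeness <- 0.5
    return(df)
  }
  norm <- ov
  for (j in seq_len(ncol(ov))) {
    norm[, j] <- if (rng[j] == 0) 0.5 else
      (ov[, j] - min(ov[, j])) / rng[j]
  }
  dpos <- sqrt(rowSums((1 - norm)^2))
  dneg <- sqrt(rowSums(norm^2))
  df$closeness <- dneg / (dpos + dneg)
  df[order(-df$closeness), , drop = FALSE]
}

#' Rank a candidate pool by constrained multiobjective optimization
#'
#' Applies the hard property cutoffs, runs the epsilon-constraint enumeration
#' over the objectives, extracts the Pareto-efficient set from the solution
#' union and scores it with TOPSIS.
#'
#' @param predictions Data frame with `id`, `smiles` (optional) and one
#'   numeric column per property named in `objectives`.
#' @param objectives An `objective_spec` from [read_objective_table()].
#' @param q Epsilon intervals per secondary objective.
#' @param top_k How many top solutions to report in the `top` attribute.
#' @return `predictions` augmented with `feasible`, `on_front` and
#'   `closeness` columns, sorted front-first by closeness; attributes `front`
#'   and `top`.
#' @export
rank_candidates <- function(predictions, objectives, q = 10L, top_k = 4L) {
  stopifnot(is.data.frame(predictions))
  if (!nrow(predictions)) stop("no candidates", call. = FALSE)
  cons <- objectives[objectives$role == "constraint", , drop = FALSE]
  feas <- rep(TRUE, nrow(predictions))
  for (r in seq_len(nrow(cons))) {
    pv <- predictions[[cons$property[r]]]
    if (is.null(pv))
      stop("predictions lack constraint column '", cons$property[r], "'",
           call. = FALSE)
    feas <- feas & pv >= cons$lower[r] & pv <= cons$upper[r]
  }
  obj <- objectives[objectives$role == "objective", , drop = FALSE]
  pool <- predictions[feas, , drop = FALSE]
  if (!nrow(pool)) {
    warning("no candidate satisfies the property cutoffs")
    out <- predictions
    out$feasible <- feas
    out$on_front <- FALSE
    out$closeness <- NA_real_
    return(out)
  }
  if (is.null(pool$id)) pool$id <- as.character(seq_len(nrow(predictions)))[feas]
  sols <- epsilon_constraint_enumerate(pool, obj, q = q)
  front <- pareto_filter(sols[, c("id", obj$property)], obj$direction)
  ranked <- topsis_rank(front, obj$direction)
  out <- predictions
  out$feasible <- feas
  pid <- if (!is.null(predictions$id)) as.character(predictions$id) else
    as.character(seq_len(nrow(predictions)))
  out$on_front <- pid %in% ranked$id
  out$closeness <- ranked$closeness[match(pid, ranked$id)]
  out <- out[order(-out$on_front, -ifelse(is.na(out$closeness), -Inf,
                                          out$closeness)), , drop = FALSE]
  attr(out, "front") <- ranked
  attr(out, "top") <- utils::head(ranked, top_k)
  out
}
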