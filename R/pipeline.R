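# End-to-end pipeline: config-driven subcommands mirroring the two
# generation problems (P1 heads, P2 tails) and the assembly / training /
# prediction / optimization stage (P3).

.default_config <- list(
  head_min = 1L, head_max = 4L, tail_min = 1L, tail_max = 4L,
  head_core = "", tail_core = "", q = 10L, top_k = 4L, seed = 0L,
  corr_threshold = 0.9, max_iter = 10000L, outdir = ".")

#' Read a pipeline configuration
#'
#' A configuration is a named list, or a two-column `key,value` CSV file.
#' Recognized keys: `head_table`, `tail_table`, `head_min`, `head_max`,
#' `tail_min`, `tail_max`, `head_core`, `tail_core` (comma-separated group
#' names), `objective_table`, `train_files` (semicolon-separated
#' `property=path[:family[:ncomp]]` entries), `extra_smiles` (path to a .smi
#' file), `models_dir`, `q`, `top_k`, `seed`, `corr_threshold`, `max_iter`,
#' `outdir`.
#'
#' @param config Named list or CSV path.
#' @return Normalized configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    tab <- utils::read.csv(config, header = TRUE, stringsAsFactors = FALSE,
                           strip.white = TRUE)
    if (!all(c("key", "value") %in% names(tab)))
      stop("config CSV needs 'key' and 'value' columns", call. = FALSE)
    config <- stats::setNames(as.list(tab$value), tab$key)
  }
  out <- utils::modifyList(.default_config, as.list(config))
  for (k in c("head_min", "head_max", "tail_min", "tail_max", "q", "top_k",
              "seed", "max_iter"))
    out[[k]] <- as.integer(out[[k]])
  out$corr_threshold <- as.numeric(out$corr_threshold)
  if (out$q < 1L) stop("q must be >= 1", call. = FALSE)
  out
}

.split_names <- function(s) {
  s <- trimws(strsplit(as.character(s), ",", fixed = TRUE)[[1]])
  s[nzchar(s)]
}

.log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

.write_summary <- function(outdir, stage, counts) {
  path <- file.path(outdir, "run_summary.json")
  prev <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else list()
  prev[[stage]] <- counts
  jsonlite::write_json(prev, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run a pipeline stage
#'
#' Subcommands: `generate-heads` and `generate-tails` enumerate fragment
#' libraries from the configured group tables and write `.smi` and `.csv`
#' outputs; `assemble` builds and sanitizes the full head-by-tail candidate
#' library (`candidates.csv`, `candidates.smi`); `train-qspr` trains property
#' models from `(smiles,value)` CSV training files and writes model
#' artifacts; `predict` scores the candidate library with the trained models
#' (`predictions.csv`); `optimize` runs the constrained epsilon-constraint
#' ranking (`pareto.csv`). Every stage appends its counts to
#' `run_summary.json` in the output directory.
#'
#' @param subcommand One of `"generate-heads"`, `"generate-tails"`,
#'   `"assemble"`, `"train-qspr"`, `"predict"`, `"optimize"`.
#' @param config Named list or CSV path (see [read_run_config()]).
#' @return Invisibly, the stage's main result object.
#' @export
surf_run <- function(subcommand = c("generate-heads", "generate-tails",
                                    "assemble", "train-qspr", "predict",
                                    "optimize"),
                     config) {
  subcommand <- match.arg(subcommand)
  cfg <- read_run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  switch(subcommand,
         "generate-heads" = .run_generate(cfg, "head"),
         "generate-tails" = .run_generate(cfg, "tail"),
         "assemble" = .run_assemble(cfg),
         "train-qspr" = .run_train(cfg),
         "predict" = .run_predict(cfg),
         "optimize" = .run_optimize(cfg))
}

.run_generate <- function(cfg, role) {
  tab <- cfg[[paste0(role, "_table")]]
  if (is.null(tab)) stop("config lacks ", role, "_table", call. = FALSE)
  gs <- read_group_table(tab, role = role,
                         size_bounds = c(cfg[[paste0(role, "_min")]],
                                         cfg[[paste0(role, "_max")]]),
                         core_groups = .split_names(cfg[[paste0(role, "_core")]]))
  t0 <- Sys.time()
  lib <- generate_all(gs, max_solutions = cfg$max_iter)
  el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  stem <- file.path(cfg$outdir, paste0(role, "s"))
  write_fragments(lib, stem)
  utils::write.csv(as.data.frame(lib), paste0(stem, ".csv"), row.names = FALSE)
  s <- attr(lib, "summary")
  .log_msg(role, " generation: ", nrow(lib), " unique fragments from ",
           s$n_feasible_selections, "/", s$n_selections,
           " feasible selections (", round(el, 1), " s)")
  .write_summary(cfg$outdir, paste0("generate_", role, "s"),
                 c(s, elapsed_s = round(el, 2)))
  invisible(lib)
}

.read_smi <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  parts <- strsplit(ln, "[ \t]+")
  data.frame(id = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                         character(1)),
             smiles = vapply(parts, `[[`, character(1), 1),
             stringsAsFactors = FALSE)
}

.run_assemble <- function(cfg) {
  heads <- .read_smi(file.path(cfg$outdir, "heads.smi"))
  tails <- .read_smi(file.path(cfg$outdir, "tails.smi"))
  if (!nrow(heads) || !nrow(tails))
    stop("no head or tail fragments; run generate-heads / generate-tails first",
         call. = FALSE)
  extra <- NULL
  if (!is.null(cfg$extra_smiles) && nzchar(cfg$extra_smiles))
    extra <- .read_smi(cfg$extra_smiles)$smiles
  t0 <- Sys.time()
  cand <- assemble_library(heads, tails, extra = extra)
  el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  utils::write.csv(as.data.frame(cand), file.path(cfg$outdir, "candidates.csv"),
                   row.names = FALSE)
  writeLines(cand$smiles[cand$valid], file.path(cfg$outdir, "candidates.smi"))
  s <- attr(cand, "summary")
  .log_msg("assembly: ", s$n_candidates, " candidates, ",
           sprintf("%.2f%% valid", 100 * s$validity_rate),
           " (", round(el, 1), " s)")
  .write_summary(cfg$outdir, "assemble", c(s, elapsed_s = round(el, 2)))
  invisible(cand)
}

.parse_train_files <- function(s) {
  entries <- trimws(strsplit(as.character(s), ";", fixed = TRUE)[[1]])
  entries <- entries[nzchar(entries)]
  lapply(entries, function(e) {
    kv <- strsplit(e, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad train_files entry: ", e, call. = FALSE)
    opt <- strsplit(kv[2], ":", fixed = TRUE)[[1]]
    list(property = trimws(kv[1]), path = opt[1],
         family = if (length(opt) > 1) opt[2] else "lasso",
         ncomp = if (length(opt) > 2) as.integer(opt[3]) else 2L)
  })
}

.run_train <- function(cfg) {
  if (is.null(cfg$train_files)) stop("config lacks train_files", call. = FALSE)
  specs <- .parse_train_files(cfg$train_files)
  mdir <- file.path(cfg$outdir, "models")
  dir.create(mdir, showWarnings = FALSE)
  models <- list()
  for (sp in specs) {
    tab <- utils::read.csv(sp$path, stringsAsFactors = FALSE)
    if (!all(c("smiles", "value") %in% names(tab)))
      stop("training CSV ", sp$path, " needs smiles,value columns", call. = FALSE)
    desc <- compute_descriptors(tab$smiles)
    ok <- is.na(attr(desc, "failures"))
    flt <- filter_descriptors(desc[ok, , drop = FALSE],
                              threshold = cfg$corr_threshold)
    # training values for log-scale properties (logCMC, logLC50) are expected
    # already on the log10 scale, as tabulated in the literature sources
    m <- train_qspr(flt, tab$value[ok], family = sp$family, ncomp = sp$ncomp,
                    transform = "identity", property = sp$property,
                    seed = cfg$seed)
    write_qspr(m, file.path(mdir, sp$property))
    models[[sp$property]] <- m
    .log_msg("trained ", sp$property, ": test R2=",
             round(m$metrics$test["r2"], 3))
  }
  .write_summary(cfg$outdir, "train_qspr",
                 list(properties = names(models)))
  invisible(models)
}

.load_models <- function(cfg) {
  mdir <- if (!is.null(cfg$models_dir) && nzchar(cfg$models_dir))
    cfg$models_dir else file.path(cfg$outdir, "models")
  stems <- sub("\\.json$", "", list.files(mdir, pattern = "\\.json$",
                                          full.names = TRUE))
  if (!length(stems)) stop("no model artifacts in ", mdir, call. = FALSE)
  models <- lapply(stems, read_qspr)
  stats::setNames(models, vapply(models, `[[`, character(1), "property"))
}

.run_predict <- function(cfg) {
  cand_path <- file.path(cfg$outdir, "candidates.csv")
  if (!file.exists(cand_path)) stop("no candidates.csv; run assemble first",
                                    call. = FALSE)
  cand <- utils::read.csv(cand_path, stringsAsFactors = FALSE)
  cand <- cand[cand$valid & !is.na(cand$smiles), , drop = FALSE]
  if (!nrow(cand)) stop("no valid candidates", call. = FALSE)
  models <- .load_models(cfg)
  desc <- compute_descriptors(cand$smiles)
  pred <- data.frame(id = paste(cand$head_id, cand$tail_id, sep = "_"),
                     smiles = cand$smiles, stringsAsFactors = FALSE)
  for (m in models) pred[[m$property]] <- predict(m, desc)
  utils::write.csv(pred, file.path(cfg$outdir, "predictions.csv"),
                   row.names = FALSE)
  .log_msg("predicted ", length(models), " properties for ", nrow(pred),
           " candidates")
  .write_summary(cfg$outdir, "predict",
                 list(n_candidates = nrow(pred),
                      properties = names(models)))
  invisible(pred)
}

.run_optimize <- function(cfg) {
  if (is.null(cfg$objective_table)) stop("config lacks objective_table",
                                         call. = FALSE)
  pred_path <- file.path(cfg$outdir, "predictions.csv")
  if (!file.exists(pred_path)) stop("no predictions.csv; run predict first",
                                    call. = FALSE)
  pred <- utils::read.csv(pred_path, stringsAsFactors = FALSE)
  if (!nrow(pred)) stop("no candidates in predictions.csv", call. = FALSE)
  objectives <- read_objective_table(cfg$objective_table)
  ranked <- rank_candidates(pred, objectives, q = cfg$q, top_k = cfg$top_k)
  utils::write.csv(ranked, file.path(cfg$outdir, "pareto.csv"),
                   row.names = FALSE)
  front <- attr(ranked, "front")
  .log_msg("optimization: ", sum(ranked$feasible), " feasible, ",
           nrow(front), " on the Pareto front")
  .write_summary(cfg$outdir, "optimize",
                 list(n_candidates = nrow(ranked),
                      n_feasible = sum(ranked$feasible),
                      n_front = nrow(front),
                      top = as.list(utils::head(front$id, cfg$top_k))))
  invisible(ranked)
}
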