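# Building-block groups: parsing, validation and expansion into graph nodes.

#' Define a molecular building-block group
#'
#' A group is a molecular fragment (given as SMILES) with a declared number of
#' free attachment points (its *group valence*) and a list of connection slots
#' stating at which atom, and how many times, external single bonds may replace
#' implicit hydrogens. Groups are the nodes of the fragment-generation graph
#' model.
#'
#' @param name Group name (unique within a [group_set()]).
#' @param smiles Fragment SMILES. The dummy placeholder group uses `"*"`.
#' @param valence Positive integer; number of external single bonds the group
#'   must form within a fragment.
#' @param connections List of connection slots, each `list(atom =, cap =)`
#'   where `atom` is a 1-based heavy-atom index into the SMILES atom order (or
#'   the sentinel `"final"`, resolved to the last atom) and `cap` is the number
#'   of external bonds that atom accepts. Slot capacities must sum to
#'   `valence`. Defaults to a single slot on atom 1.
#' @param max_occurrences Positive integer; maximum number of instances of this
#'   group in one fragment (the occurrence limit \eqn{n_j}).
#' @param is_core If `TRUE` the group is mandatory in every fragment.
#' @return An object of class `group_spec`.
#' @seealso [group_set()], [read_group_table()], [expand_instances()]
#' @export
group_spec <- function(name, smiles, valence,
                       connections = list(list(atom = 1L, cap = valence)),
                       max_occurrences = 1L, is_core = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  valence <- as.integer(valence)
  max_occurrences <- as.integer(max_occurrences)
  if (is.na(valence) || valence < 1L)
    stop("group '", name, "': valence must be a positive integer", call. = FALSE)
  if (is.na(max_occurrences) || max_occurrences < 1L)
    stop("group '", name, "': max_occurrences must be a positive integer", call. = FALSE)
  is_dummy <- identical(smiles, "*")
  if (is_dummy && valence != 1L)
    stop("the dummy group must have valence 1", call. = FALSE)
  natoms <- smiles_atom_count(smiles)
  if (is.na(natoms) || natoms < 1L)
    stop("group '", name, "': SMILES '", smiles, "' could not be parsed",
         call. = FALSE)
  conns <- lapply(connections, function(cn) {
    atom <- cn$atom
    cap <- as.integer(cn$cap)
    if (!identical(atom, "final")) {
      atom <- as.integer(atom)
      if (is.na(atom) || atom < 1L || atom > natoms)
        stop("group '", name, "': connection atom index ", cn$atom,
             " does not resolve to an atom of '", smiles, "'", call. = FALSE)
    } else {
      atom <- natoms  # "final" sentinel: last heavy atom in SMILES order
    }
    if (is.na(cap) || cap < 1L)
      stop("group '", name, "': connection capacity must be positive", call. = FALSE)
    list(atom = atom, cap = cap)
  })
  if (sum(vapply(conns, `[[`, integer(1), "cap")) != valence)
    stop("group '", name, "': connection capacities must sum to the group valence (",
         valence, ")", call. = FALSE)
  structure(
    list(name = name, smiles = smiles, valence = valence, connections = conns,
         max_occurrences = max_occurrences, is_dummy = is_dummy,
         is_core = isTRUE(is_core), n_atoms = natoms),
    class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("<group_spec> %s  smiles=%s  v=%d  max=%d%s%s\n", x$name,
              x$smiles, x$valence, x$max_occurrences,
              if (x$is_dummy) "  [dummy]" else "",
              if (x$is_core) "  [core]" else ""))
  invisible(x)
}

#' Bundle groups into a head or tail generation problem
#'
#' @param groups List of [group_spec()] objects, exactly one of which must be
#'   the dummy attachment group (`smiles == "*"`).
#' @param role `"head"` or `"tail"`.
#' @param min_groups,max_groups Bounds on the number of chemical group
#'   *instances* per fragment (a group selected twice counts twice; the dummy
#'   is excluded from the count).
#' @param core_groups Character vector of group names that must be present in
#'   every fragment.
#' @return An object of class `group_set`.
#' @export
group_set <- function(groups, role = c("head", "tail"),
                      min_groups = 1L, max_groups = 4L,
                      core_groups = character()) {
  role <- match.arg(role)
  if (length(groups) == 0L)
    stop("group set is empty", call. = FALSE)
  stopifnot(all(vapply(groups, inherits, logical(1), "group_spec")))
  nm <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicated group names: ", paste(nm[duplicated(nm)], collapse = ", "),
         call. = FALSE)
  names(groups) <- nm
  ndum <- sum(vapply(groups, `[[`, logical(1), "is_dummy"))
  if (ndum != 1L)
    stop("a group set must contain exactly one dummy group (smiles \"*\"), found ",
         ndum, call. = FALSE)
  min_groups <- as.integer(min_groups); max_groups <- as.integer(max_groups)
  if (min_groups < 1L || max_groups < min_groups)
    stop("size bounds must satisfy 1 <= min_groups <= max_groups", call. = FALSE)
  bad <- setdiff(core_groups, nm)
  if (length(bad))
    stop("core group(s) not in table: ", paste(bad, collapse = ", "), call. = FALSE)
  for (g in core_groups) groups[[g]]$is_core <- TRUE
  structure(list(role = role, groups = groups, min_groups = min_groups,
                 max_groups = max_groups),
            class = "group_set")
}

#' @export
print.group_set <- function(x, ...) {
  cat(sprintf("<group_set> role=%s  %d groups  size bounds %d-%d\n",
              x$role, length(x$groups), x$min_groups, x$max_groups))
  for (g in x$groups) print(g)
  invisible(x)
}

# Canonical column names and accepted header aliases for group tables.
# Headers are normalized (lowercase, non-alphanumerics stripped) before lookup.
.group_table_aliases <- list(
  name = c("group", "groups", "name", "groupname"),
  smiles = c("smiles", "smile", "smilesnotation"),
  valence = c("groupvalence", "valence", "freevalence"),
  cap1 = c("valencefirstconnectionatom", "valencesfor1stconnection",
           "valencesfor1stconnectionindex1", "valencefirstconnection",
           "valence1stconnection"),
  smiles_verbatim = c("smilesverbatim", "smilesaspublished"),
  max_occ = c("maximumnumberofgroups", "maxgroups", "maxoccurrences",
              "maximumoccurrences")
)

.norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

# map normalized headers of higher-order connection columns:
#  <ord> connection atom index / valence <ord> connection [atom]
.conn_index_re <- "^(second|third|fourth|fifth|2nd|3rd|4th|5th)connectionatomindex$"
.conn_cap_re <- "^(valence|vlence)(second|third|fourth|fifth|2nd|3rd|4th|5th)connection(atom)?$"
.conn_ord <- c(second = 2L, third = 3L, fourth = 4L, fifth = 5L,
               "2nd" = 2L, "3rd" = 3L, "4th" = 4L, "5th" = 5L)

#' Read a group table (head or tail inputs) from CSV
#'
#' The expected layout is one row per group with columns for the group name,
#' SMILES, group valence, the capacity of the first connection atom (always
#' atom 1), then pairs of columns `second connection atom index` /
#' `valence second connection atom` (and third, fourth, ... as needed; an
#' index of `0` or an empty cell means "no such connection"), and the
#' `maximum number of groups` occurrence limit. The special index `"final"`
#' resolves to the last atom of the group's SMILES. The dummy row is detected
#' by SMILES `"*"`. Header matching is case- and punctuation-insensitive via
#' a documented alias map.
#'
#' @param path CSV file path.
#' @param role `"head"` or `"tail"`.
#' @param size_bounds Length-2 integer vector: minimum and maximum number of
#'   group instances per fragment (dummy excluded).
#' @param core_groups Names of groups mandatory in every fragment.
#' @return A [group_set()].
#' @export
read_group_table <- function(path, role = c("head", "tail"),
                             size_bounds = c(1L, 4L),
                             core_groups = character()) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("group table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         strip.white = TRUE)
  if (nrow(tab) == 0L) stop("group table is empty: ", path, call. = FALSE)
  hdr <- .norm_header(names(tab))
  find_col <- function(key) {
    hit <- which(hdr %in% .group_table_aliases[[key]])
    if (length(hit)) hit[1] else NA_integer_
  }
  req <- c("name", "smiles", "valence", "cap1", "max_occ")
  idx <- vapply(req, find_col, integer(1))
  if (anyNA(idx))
    stop("group table ", path, " is missing required column(s): ",
         paste(req[is.na(idx)], collapse = ", "), call. = FALSE)
  # higher-order connection column pairs, by ordinal
  ord_idx <- regmatches(hdr, regexec(.conn_index_re, hdr))
  ord_cap <- regmatches(hdr, regexec(.conn_cap_re, hdr))
  conn_cols <- list()
  for (i in seq_along(hdr)) {
    if (length(ord_idx[[i]]) > 0) {
      k <- .conn_ord[[ord_idx[[i]][2]]]
      conn_cols[[as.character(k)]] <- c(index = i,
                                        conn_cols[[as.character(k)]]["cap"])
    }
    if (length(ord_cap[[i]]) > 0) {
      k <- .conn_ord[[ord_cap[[i]][3]]]
      conn_cols[[as.character(k)]] <- c(conn_cols[[as.character(k)]]["index"],
                                        cap = i)
    }
  }
  ords <- sort(as.integer(names(conn_cols)))
  groups <- vector("list", nrow(tab))
  for (r in seq_len(nrow(tab))) {
    row_id <- paste0("row ", r, " ('", tab[r, idx[["name"]]], "')")
    val <- suppressWarnings(as.integer(tab[r, idx[["valence"]]]))
    if (is.na(val) || val < 1L)
      stop("group table ", path, ", ", row_id, ": non-positive or missing valence",
           call. = FALSE)
    conns <- list()
    cap1 <- suppressWarnings(as.integer(tab[r, idx[["cap1"]]]))
    if (!is.na(cap1) && cap1 > 0L)
      conns[[length(conns) + 1L]] <- list(atom = 1L, cap = cap1)
    for (k in ords) {
      cc <- conn_cols[[as.character(k)]]
      a_raw <- trimws(as.character(tab[r, cc[["index"]]]))
      cp <- suppressWarnings(as.integer(tab[r, cc[["cap"]]]))
      if (is.na(a_raw) || a_raw %in% c("", "0", "NA") || is.na(cp) || cp < 1L)
        next
      atom <- if (identical(tolower(a_raw), "final")) "final" else
        suppressWarnings(as.integer(a_raw))
      if (!identical(atom, "final") && is.na(atom))
        stop("group table ", path, ", ", row_id,
             ": unparseable connection atom index '", a_raw, "'", call. = FALSE)
      conns[[length(conns) + 1L]] <- list(atom = atom, cap = cp)
    }
    groups[[r]] <- tryCatch(
      group_spec(name = as.character(tab[r, idx[["name"]]]),
                 smiles = as.character(tab[r, idx[["smiles"]]]),
                 valence = val, connections = conns,
                 max_occurrences = suppressWarnings(
                   as.integer(tab[r, idx[["max_occ"]]]))),
      error = function(e) stop("group table ", path, ", ", row_id, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  group_set(groups, role = role, min_groups = size_bounds[1],
            max_groups = size_bounds[2], core_groups = core_groups)
}

#' Expand a group selection into the node set of the graph model
#'
#' Each selected group with valence greater than one contributes one node per
#' instance; all instances of a single-valence group of one type are collapsed
#' into a single node whose valence equals the instance count. This collapsing
#' removes redundant permutation-equivalent solutions from the enumeration.
#'
#' @param groupset A [group_set()].
#' @param counts Named integer vector of instance counts (names must be group
#'   names in `groupset`; groups absent from `counts` get count 0).
#' @return An object of class `node_set`: a data frame with one row per node
#'   (`label`, `group`, `valence`, `multi`) carrying the originating
#'   `group_set` as an attribute. `multi` flags nodes whose *group* valence
#'   exceeds one (the set \eqn{J \setminus J_0}).
#' @export
expand_instances <- function(groupset, counts) {
  stopifnot(inherits(groupset, "group_set"))
  counts <- counts[counts > 0]
  bad <- setdiff(names(counts), names(groupset$groups))
  if (length(bad))
    stop("unknown group(s) in selection: ", paste(bad, collapse = ", "),
         call. = FALSE)
  rows <- list()
  for (g in names(counts)) {
    spec <- groupset$groups[[g]]
    cnt <- as.integer(counts[[g]])
    if (cnt > spec$max_occurrences)
      stop("group '", g, "' selected ", cnt,
           " times but max_occurrences is ", spec$max_occurrences,
           call. = FALSE)
    if (spec$valence == 1L) {
      # collapse: one node, valence = instance count
      rows[[length(rows) + 1L]] <-
        data.frame(label = g, group = g, valence = cnt, multi = FALSE,
                   count = cnt, stringsAsFactors = FALSE)
    } else {
      for (b in seq_len(cnt)) {
        rows[[length(rows) + 1L]] <-
          data.frame(label = if (cnt > 1L) paste0(g, "#", b) else g,
                     group = g, valence = spec$valence, multi = TRUE,
                     count = 1L, stringsAsFactors = FALSE)
      }
    }
  }
  ns <- do.call(rbind, rows)
  rownames(ns) <- NULL
  structure(ns, class = c("node_set", "data.frame"), groupset = groupset)
}

#' @export
print.node_set <- function(x, ...) {
  cat(sprintf("<node_set> %d nodes, total valence %d (%d multivalence)\n",
              nrow(x), sum(x$valence), sum(x$multi)))
  print.data.frame(x)
  invisible(x)
}

# Count heavy atoms in a SMILES string without a toolkit round trip: atoms are
# bracket expressions or organic-subset symbols. Sufficient for the small
# group fragments handled here; full parsing happens in the assembly module.
smiles_atom_count <- function(smiles) {
  if (identical(smiles, "*")) return(1L)
  s <- smiles
  n <- 0L
  i <- 1L
  two <- c("Cl", "Br")
  one <- c("B", "C", "N", "O", "P", "S", "F", "I", "c", "n", "o", "p", "s", "*")
  while (i <= nchar(s)) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, nchar(s)), fixed = TRUE)
      if (j < 0) return(NA_integer_)
      n <- n + 1L
      i <- i + j
    } else if (i < nchar(s) && substr(s, i, i + 1L) %in% two) {
      n <- n + 1L; i <- i + 2L
    } else if (ch %in% one) {
      n <- n + 1L; i <- i + 1L
    } else if (ch %in% c("(", ")", "=", "#", "-", "+", "/", "\\", "@", ".",
                         as.character(0:9), "%")) {
      i <- i + 1L
    } else {
      return(NA_integer_)
    }
  }
  n
}
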