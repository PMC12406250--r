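# Atom-level assembly: groups -> bond matrices -> fused surfactants -> SMILES.
#
# SMILES parsing and canonicalization go through Open Babel (ChemmineOB);
# bond-matrix bookkeeping, implicit-hydrogen accounting and valence
# sanitization are handled here. Open Babel preserves the SMILES atom order
# when converting to SDF, which is what connection atom indices refer to.

# standard valence sets per element; charge shifts the effective set
.std_valences <- list(
  "*" = 1L, H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L)

new_bond_matrix <- function(atoms, charge, bond) {
  stopifnot(length(atoms) == length(charge), nrow(bond) == length(atoms),
            ncol(bond) == length(atoms))
  structure(list(atoms = atoms, charge = as.integer(charge),
                 bond = bond), class = "bond_matrix")
}

#' @export
print.bond_matrix <- function(x, ...) {
  cat(sprintf("<bond_matrix> %d atoms, %d bonds%s\n", length(x$atoms),
              sum(x$bond > 0) / 2,
              if (any(x$atoms == "*")) " (has attachment point)" else ""))
  invisible(x)
}

# ---- Open Babel bridge -----------------------------------------------------

# Batched SMILES -> canonical SMILES. Returns NA for entries Open Babel could
# not convert. Input order is preserved via per-line tags.
ob_canonical_smiles <- function(smiles, .retry = TRUE) {
  if (!length(smiles)) return(character())
  tag <- paste0("m", seq_along(smiles))
  txt <- paste0(paste(smiles, tag, collapse = "\n"), "\n")
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", txt),
                  error = function(e) "")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  res <- rep(NA_character_, length(smiles))
  for (p in parts) {
    if (length(p) >= 2) {
      i <- match(trimws(p[2]), tag)
      if (!is.na(i)) res[i] <- trimws(p[1])
    }
  }
  res[res == ""] <- NA_character_
  # an unparseable entry can abort the rest of the batch: retry singly
  if (.retry && anyNA(res) && length(smiles) > 1L) {
    for (i in which(is.na(res)))
      res[i] <- ob_canonical_smiles(smiles[i], .retry = FALSE)
  }
  res
}

#' Canonicalize SMILES strings
#'
#' Vectorized canonicalization through Open Babel; unparseable entries are
#' returned as `NA`.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) ob_canonical_smiles(smiles)

# Batched SMILES -> V2000 molblocks, parsed into bond matrices. Returns a
# list with NULL for failed entries.
ob_parse_smiles <- function(smiles, .retry = TRUE) {
  if (!length(smiles)) return(list())
  tag <- paste0("m", seq_along(smiles))
  txt <- paste0(paste(smiles, tag, collapse = "\n"), "\n")
  sdf <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", txt),
                  error = function(e) "")
  res <- rep(list(NULL), length(smiles))
  if (nzchar(sdf)) {
    blocks <- strsplit(sdf, "$$$$\n", fixed = TRUE)[[1]]
    for (bl in blocks) {
      if (!nzchar(trimws(bl))) next
      bm <- tryCatch(parse_molblock(bl), error = function(e) NULL)
      if (is.null(bm)) next
      i <- match(attr(bm, "title"), tag)
      if (!is.na(i)) res[[i]] <- bm
    }
  }
  # an unparseable entry can abort the rest of the batch: retry singly
  miss <- vapply(res, is.null, logical(1))
  if (.retry && any(miss) && length(smiles) > 1L) {
    for (i in which(miss))
      res[[i]] <- ob_parse_smiles(smiles[i], .retry = FALSE)[[1]]
  }
  res
}

# Minimal V2000 molblock reader: element symbols, bond orders, M CHG charges.
parse_molblock <- function(text) {
  ln <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(ln) < 4) stop("molblock too short")
  counts <- ln[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1) stop("bad molblock counts line")
  atoms <- character(na)
  for (i in seq_len(na)) {
    atoms[i] <- trimws(substr(ln[4 + i], 32, 34))
  }
  bond <- matrix(0L, na, na)
  for (i in seq_len(nb)) {
    bl <- ln[4 + na + i]
    a <- as.integer(substr(bl, 1, 3))
    b <- as.integer(substr(bl, 4, 6))
    o <- as.integer(substr(bl, 7, 9))
    if (o == 4L) o <- 1L  # aromatic flag: order handled after kekulization
    bond[a, b] <- bond[b, a] <- o
  }
  charge <- integer(na)
  for (l in grep("^M  CHG", ln, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(substr(l, 7, nchar(l))), "\\s+")[[1]])
    k <- flds[1]
    for (p in seq_len(k)) charge[flds[2 * p]] <- flds[2 * p + 1]
  }
  out <- new_bond_matrix(atoms, charge, bond)
  attr(out, "title") <- trimws(ln[1])
  out
}

# Bond matrix -> V2000 molblock text (2D placeholder coordinates).
write_molblock <- function(bm, title = "mol") {
  na <- length(bm$atoms)
  ij <- which(upper.tri(bm$bond) & bm$bond > 0, arr.ind = TRUE)
  nb <- nrow(ij)
  hdr <- c(title, "  surfcamd", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  at <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                bm$atoms)
  bd <- if (nb) sprintf("%3d%3d%3d  0  0  0  0", ij[, 1], ij[, 2],
                        bm$bond[ij]) else character()
  chg <- character()
  ci <- which(bm$charge != 0L)
  if (length(ci)) {
    # M CHG lines carry at most 8 atom/charge pairs each
    for (s in split(ci, ceiling(seq_along(ci) / 8))) {
      chg <- c(chg, paste0("M  CHG", sprintf("%3d", length(s)),
                           paste0(sprintf("%4d%4d", s, bm$charge[s]),
                                  collapse = "")))
    }
  }
  paste(c(hdr, at, bd, chg, "M  END", "$$$$"), collapse = "\n")
}

# Batched bond matrices -> canonical SMILES via Open Babel (NA on failure).
bond_matrices_to_smiles <- function(bms, allow_attachment = FALSE) {
  if (!length(bms)) return(character())
  tags <- paste0("m", seq_along(bms))
  txt <- paste0(paste(vapply(seq_along(bms), function(i)
    write_molblock(bms[[i]], tags[i]), character(1)), collapse = "\n"), "\n")
  out <- tryCatch(ChemmineOB::convertFormat("SDF", "CAN", txt),
                  error = function(e) "")
  res <- rep(NA_character_, length(bms))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  for (p in strsplit(lines, "\t", fixed = TRUE)) {
    if (length(p) >= 2) {
      i <- match(trimws(p[2]), tags)
      if (!is.na(i)) res[i] <- trimws(p[1])
    }
  }
  ok <- vapply(bms, function(b) sanitize_bond_matrix(b)$valid, logical(1))
  res[!ok] <- NA_character_
  if (!allow_attachment) res[grepl("*", res, fixed = TRUE)] <- NA_character_
  res
}

# ---- implicit hydrogens and sanitization -----------------------------------

# implicit hydrogen count per atom: difference between the smallest standard
# valence (charge-adjusted) that accommodates the heavy-bond order sum and
# that sum; negative gap = valence violation.
implicit_hydrogens <- function(bm) {
  bsum <- rowSums(bm$bond)
  vapply(seq_along(bm$atoms), function(i) {
    allowed <- .std_valences[[bm$atoms[i]]]
    if (is.null(allowed)) return(NA_integer_)
    # charge adjustment: cations gain a bond (e.g. N+), anions lose one (O-)
    allowed <- allowed + bm$charge[i]
    fit <- allowed[allowed >= bsum[i]]
    if (!length(fit)) return(NA_integer_)
    as.integer(min(fit) - bsum[i])
  }, integer(1))
}

# Valence / element sanitization on a bond matrix. Dummies are allowed at
# most their single bond. Returns validity plus a reason for rejects.
sanitize_bond_matrix <- function(bm) {
  if (!length(bm$atoms)) return(list(valid = FALSE, reason = "empty molecule"))
  unknown <- setdiff(unique(bm$atoms), names(.std_valences))
  if (length(unknown))
    return(list(valid = FALSE,
                reason = paste("invalid atom(s):", paste(unknown, collapse = ","))))
  ih <- implicit_hydrogens(bm)
  if (anyNA(ih)) {
    bad <- which(is.na(ih))[1]
    return(list(valid = FALSE,
                reason = sprintf("valence violation at atom %d (%s, bond order %d%s)",
                                 bad, bm$atoms[bad], sum(bm$bond[bad, ]),
                                 if (bm$charge[bad] != 0)
                                   sprintf(", charge %+d", bm$charge[bad]) else "")))
  }
  list(valid = TRUE, reason = NA_character_)
}

# ---- group / fragment / surfactant assembly --------------------------------

#' Convert a group's SMILES into its atom-level bond matrix
#'
#' Atoms are ordered as in the SMILES; hydrogens stay implicit and are
#' accounted for by valence bookkeeping, so forming an external bond at a
#' connection atom silently consumes one implicit hydrogen.
#'
#' @param spec A [group_spec()].
#' @return A `bond_matrix` with the group's connection slots attached as the
#'   `slots` attribute (one atom index per unit of connection capacity, in
#'   declared order).
#' @export
group_to_bond_matrix <- function(spec) {
  stopifnot(inherits(spec, "group_spec"))
  bm <- ob_parse_smiles(spec$smiles)[[1]]
  if (is.null(bm))
    stop("group '", spec$name, "': SMILES '", spec$smiles,
         "' could not be parsed", call. = FALSE)
  if (length(bm$atoms) != spec$n_atoms)
    stop("group '", spec$name, "': parsed atom count differs from SMILES",
         call. = FALSE)
  slots <- unlist(lapply(spec$connections, function(cn) rep(cn$atom, cn$cap)))
  ih <- implicit_hydrogens(bm)
  for (a in unique(slots)) {
    need <- sum(slots == a)
    if (bm$atoms[a] != "*" && (is.na(ih[a]) || ih[a] < need))
      stop("group '", spec$name, "': atom ", a, " (", bm$atoms[a],
           ") lacks ", need, " replaceable hydrogen(s)", call. = FALSE)
  }
  attr(bm, "slots") <- as.integer(slots)
  bm
}

#' Expand a fragment graph into an atom-level bond matrix
#'
#' Every unit of adjacency multiplicity becomes one single bond placed at the
#' next unused declared connection atom of each group (slots consumed in
#' declared order; neighbors processed in node-index order), consuming one
#' implicit hydrogen per endpoint. Collapsed single-valence nodes are expanded
#' back into one fragment copy per instance.
#'
#' @param graph A `fragment_graph`.
#' @param groupset The [group_set()] the graph was generated from (defaults to
#'   the one recorded on the graph's node set).
#' @return A `bond_matrix` for the whole fragment.
#' @export
fragment_to_bond_matrix <- function(graph, groupset = NULL) {
  stopifnot(inherits(graph, "fragment_graph"))
  nodes <- graph$nodes
  if (is.null(groupset)) groupset <- attr(nodes, "groupset")
  if (is.null(groupset))
    stop("no group_set available for atom-level expansion", call. = FALSE)
  n <- nrow(nodes)
  atoms <- character(); charge <- integer()
  bonds <- list()
  node_slots <- vector("list", n)
  base_cache <- list()
  off <- 0L
  for (i in seq_len(n)) {
    g <- nodes$group[i]
    spec <- groupset$groups[[g]]
    if (is.null(spec)) stop("node group '", g, "' not in group set", call. = FALSE)
    if (is.null(base_cache[[g]])) base_cache[[g]] <- group_to_bond_matrix(spec)
    base <- base_cache[[g]]
    copies <- if (spec$valence == 1L) nodes$valence[i] else 1L
    slots <- integer()
    for (cp in seq_len(copies)) {
      atoms <- c(atoms, base$atoms)
      charge <- c(charge, base$charge)
      bonds[[length(bonds) + 1L]] <- list(off = off, bond = base$bond)
      slots <- c(slots, attr(base, "slots") + off)
      off <- off + length(base$atoms)
    }
    node_slots[[i]] <- slots
  }
  bond <- matrix(0L, off, off)
  for (b in bonds) {
    idx <- seq_len(nrow(b$bond)) + b$off
    bond[idx, idx] <- b$bond
  }
  ptr <- rep(1L, n)
  A <- graph$adjacency
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    mult <- A[i, j]
    if (mult == 0L) next
    for (k in seq_len(mult)) {
      if (ptr[i] > length(node_slots[[i]]) || ptr[j] > length(node_slots[[j]]))
        stop("connection-atom exhaustion at nodes ", nodes$label[i], " / ",
             nodes$label[j], call. = FALSE)
      ai <- node_slots[[i]][ptr[i]]; ptr[i] <- ptr[i] + 1L
      aj <- node_slots[[j]][ptr[j]]; ptr[j] <- ptr[j] + 1L
      if (bond[ai, aj] != 0L)
        stop("duplicate atom-level bond between nodes ", nodes$label[i],
             " and ", nodes$label[j], call. = FALSE)
      bond[ai, aj] <- bond[aj, ai] <- 1L
    }
  }
  new_bond_matrix(atoms, charge, bond)
}

#' Fuse a head and a tail at their dummy atoms
#'
#' Each input must contain exactly one dummy atom (`*`). The two dummies are
#' removed and replaced by a single bond between their former neighbors.
#'
#' @param head,tail `bond_matrix` objects with one dummy atom each.
#' @return A `bond_matrix` with `n_head + n_tail - 2` atoms and no dummy.
#' @export
combine_head_tail <- function(head, tail) {
  stopifnot(inherits(head, "bond_matrix"), inherits(tail, "bond_matrix"))
  dh <- which(head$atoms == "*"); dt <- which(tail$atoms == "*")
  if (length(dh) != 1L || length(dt) != 1L)
    stop("head and tail must each carry exactly one dummy atom (found ",
         length(dh), " and ", length(dt), ")", call. = FALSE)
  nh_nb <- which(head$bond[dh, ] > 0)
  nt_nb <- which(tail$bond[dt, ] > 0)
  if (length(nh_nb) != 1L || length(nt_nb) != 1L)
    stop("dummy atoms must have exactly one neighbor", call. = FALSE)
  hk <- setdiff(seq_along(head$atoms), dh)
  tk <- setdiff(seq_along(tail$atoms), dt)
  atoms <- c(head$atoms[hk], tail$atoms[tk])
  charge <- c(head$charge[hk], tail$charge[tk])
  nh <- length(hk)
  bond <- matrix(0L, nh + length(tk), nh + length(tk))
  bond[seq_len(nh), seq_len(nh)] <- head$bond[hk, hk]
  bond[nh + seq_along(tk), nh + seq_along(tk)] <- tail$bond[tk, tk]
  a <- match(nh_nb, hk)
  b <- nh + match(nt_nb, tk)
  bond[a, b] <- bond[b, a] <- 1L
  new_bond_matrix(atoms, charge, bond)
}

#' Emit the canonical SMILES of a bond matrix
#'
#' The matrix is sanitized (element and valence checks against standard
#' valences with formal-charge adjustment), converted through Open Babel and
#' canonicalized. Multi-fragment results (a `.` in the SMILES) and sanitation
#' failures raise an error rather than returning an invalid string.
#'
#' @param matrix A `bond_matrix`.
#' @param allow_attachment Permit a `*` attachment atom (for fragments).
#' @return Canonical SMILES string.
#' @export
to_smiles <- function(matrix, allow_attachment = FALSE) {
  stopifnot(inherits(matrix, "bond_matrix"))
  if (!allow_attachment && any(matrix$atoms == "*"))
    stop("bond matrix still contains a dummy atom", call. = FALSE)
  san <- sanitize_bond_matrix(matrix)
  if (!san$valid) stop("sanitization failed: ", san$reason, call. = FALSE)
  smi <- bond_matrices_to_smiles(list(matrix), allow_attachment = TRUE)[[1]]
  if (is.na(smi)) stop("SMILES conversion failed", call. = FALSE)
  if (grepl(".", smi, fixed = TRUE))
    stop("disconnected structure (multi-fragment SMILES)", call. = FALSE)
  smi
}

#' Assemble the full head x tail candidate library
#'
#' Every combination of a head and a tail fragment is fused at the dummy
#' atoms and sanitized; optional extra SMILES (e.g. known surfactants from an
#' external database) are appended after the same sanitization. Per-candidate
#' failures are recorded, never fatal.
#'
#' @param heads,tails `fragment_library` objects from [generate_all()], or
#'   data frames with `id` and `smiles` (one `*` each) columns.
#' @param extra Optional character vector of complete surfactant SMILES to
#'   merge into the pool.
#' @return A data frame of class `candidate_set` with columns `head_id`,
#'   `tail_id`, `smiles`, `valid`, `rejection_reason`, plus a `summary`
#'   attribute with counts and the validity rate.
#' @export
assemble_library <- function(heads, tails, extra = NULL) {
  hb <- .library_bond_matrices(heads)
  tb <- .library_bond_matrices(tails)
  nh <- length(hb); nt <- length(tb)
  if (!nh || !nt) stop("need at least one head and one tail", call. = FALSE)
  combos <- expand.grid(h = seq_len(nh), t = seq_len(nt),
                        KEEP.OUT.ATTRS = FALSE)
  bms <- vector("list", nrow(combos))
  reason <- rep(NA_character_, nrow(combos))
  for (r in seq_len(nrow(combos))) {
    bms[[r]] <- tryCatch(combine_head_tail(hb[[combos$h[r]]], tb[[combos$t[r]]]),
                         error = function(e) {
                           reason[r] <<- conditionMessage(e)
                           NULL
                         })
  }
  built <- !vapply(bms, is.null, logical(1))
  smi <- rep(NA_character_, nrow(combos))
  san_reason <- rep(NA_character_, nrow(combos))
  if (any(built)) {
    sm <- bond_matrices_to_smiles(bms[built], allow_attachment = FALSE)
    smi[built] <- sm
    for (r in which(built)) {
      if (is.na(smi[r])) {
        san_reason[r] <- sanitize_bond_matrix(bms[[r]])$reason
        if (is.na(san_reason[r])) san_reason[r] <- "SMILES conversion failed"
      } else if (grepl(".", smi[r], fixed = TRUE)) {
        san_reason[r] <- "disconnected structure"
        smi[r] <- NA_character_
      }
    }
  }
  reason[is.na(reason)] <- san_reason[is.na(reason)]
  out <- data.frame(
    head_id = .library_ids(heads)[combos$h],
    tail_id = .library_ids(tails)[combos$t],
    smiles = smi,
    valid = !is.na(smi),
    rejection_reason = reason,
    stringsAsFactors = FALSE)
  if (length(extra)) {
    can <- ob_canonical_smiles(extra)
    bad_dot <- grepl(".", can, fixed = TRUE)
    can[bad_dot] <- NA_character_
    out <- rbind(out, data.frame(
      head_id = NA_character_, tail_id = NA_character_,
      smiles = can, valid = !is.na(can),
      rejection_reason = ifelse(is.na(can),
                                ifelse(bad_dot, "disconnected structure",
                                       "SMILES parse failed"),
                                NA_character_),
      stringsAsFactors = FALSE))
  }
  attr(out, "summary") <- list(
    n_heads = nh, n_tails = nt, n_candidates = nrow(out),
    n_valid = sum(out$valid),
    validity_rate = mean(out$valid))
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<candidate_set> %d candidates (%d heads x %d tails), %.1f%% valid\n",
              s$n_candidates, s$n_heads, s$n_tails, 100 * s$validity_rate))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

.library_bond_matrices <- function(lib) {
  if (inherits(lib, "fragment_library") && length(attr(lib, "graphs"))) {
    gs <- attr(attr(lib, "graphs")[[1]]$nodes, "groupset")
    return(lapply(attr(lib, "graphs"), fragment_to_bond_matrix, groupset = gs))
  }
  parsed <- ob_parse_smiles(lib$smiles)
  if (any(vapply(parsed, is.null, logical(1))))
    stop("unparseable fragment SMILES at row(s): ",
         paste(which(vapply(parsed, is.null, logical(1))), collapse = ", "),
         call. = FALSE)
  parsed
}

.library_ids <- function(lib) {
  if (!is.null(lib$id)) as.character(lib$id) else as.character(seq_len(nrow(lib)))
}
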