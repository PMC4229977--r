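#' Search options for motif matching
#'
#' @param precision Positive multiplier applied to each tolerance-augmented
#'   template distance: a query atom pair satisfies a constraint iff its
#'   distance is at most `(template distance + tolerance) * precision`.
#'   1.0 (the default) reproduces the tolerance-only rule; values below 1
#'   tighten the search, above 1 relax it.
#' @param max_unmatched Maximum number of motif slots allowed to go
#'   unmatched (default 0, a perfect match; 1 allows the classic
#'   one-missing-residue imperfect match).
#' @param substitution_groups `NULL` (default; residue types must match the
#'   motif exactly), `TRUE` for the shipped groups of chemically
#'   interchangeable types (see [default_substitution_groups()]), or a list
#'   of character vectors of three-letter codes.
#' @return A list of class `sitemotif_options`.
#' @export
search_options <- function(precision = 1.0, max_unmatched = 0L,
                           substitution_groups = NULL) {
  if (!is.numeric(precision) || length(precision) != 1 || precision <= 0) {
    abort("precision must be a single positive number")
  }
  if (max_unmatched < 0) abort("max_unmatched must be >= 0")
  if (isTRUE(substitution_groups)) {
    substitution_groups <- default_substitution_groups()
  }
  structure(list(precision = precision,
                 max_unmatched = as.integer(max_unmatched),
                 substitution_groups = substitution_groups),
            class = "sitemotif_options")
}

#' Residue types treated as interchangeable when substitutions are on
#'
#' Conservative chemistry-based groups: nucleophilic hydroxyl/thiol
#' (SER/CYS/THR), acidic (ASP/GLU), amide (ASN/GLN), aliphatic
#' (VAL/ILE/LEU), basic (LYS/ARG), aromatic (PHE/TYR). A residue matched
#' through a group counts as one substitution toward the Levenshtein
#' distance of the hit.
#'
#' @return A list of character vectors.
#' @export
default_substitution_groups <- function() {
  list(c("SER", "CYS", "THR"), c("ASP", "GLU"), c("ASN", "GLN"),
       c("VAL", "ILE", "LEU"), c("LYS", "ARG"), c("PHE", "TYR"))
}

#' Effective distance cutoff for one constraint
#'
#' The tolerance is an addition to the template distance; the precision
#' factor then multiplies the result. A query atom pair satisfies the
#' constraint iff its distance is `<= (distance + tolerance) * precision`.
#'
#' @param distance Template inter-atom distance, Angstrom (> 0).
#' @param tolerance Motif tolerance, Angstrom (>= 0).
#' @param precision Search-time multiplier (> 0).
#' @return Cutoff in Angstrom.
#' @examples
#' effective_cutoff(5.0, 2.0, 1.0)  # 7.0
#' @export
effective_cutoff <- function(distance, tolerance, precision = 1.0) {
  if (any(precision <= 0)) abort("precision must be positive")
  stopifnot(all(distance > 0), all(tolerance >= 0))
  (distance + tolerance) * precision
}

# ---- internal search machinery ---------------------------------------

# candidate residue types for a slot under the configured substitutions
slot_candidate_types <- function(res_name, groups) {
  types <- res_name
  for (g in groups %||% list()) {
    if (res_name %in% g) types <- union(types, g)
  }
  types
}

# precompute everything the DFS and the brute-force oracle share
search_context <- function(motif, query, options) {
  res <- residues(query)
  ctx <- list(
    motif = motif,
    query_id = struct_id(query),
    res = res,
    res_name_by_key = setNames(res$res_name, res$key),
    coords = residue_coord_index(query),
    n_slots = nrow(motif$slots)
  )
  ctx$candidates <- map(seq_len(ctx$n_slots), function(i) {
    types <- slot_candidate_types(motif$slots$res_name[i],
                                  options$substitution_groups)
    res$key[res$res_name %in% types]
  })
  by_pair <- split(motif$constraints,
                   paste(motif$constraints$slot_i,
                         motif$constraints$slot_j))
  ctx$pair_constraints <- map(by_pair, function(cc) {
    list(slot_i = cc$slot_i[1], slot_j = cc$slot_j[1],
         atom_i = cc$atom_i, atom_j = cc$atom_j,
         cutoff = effective_cutoff(cc$distance, motif$tolerance,
                                   options$precision))
  })
  ctx
}

# check every constraint between two assigned slots (0-based indices);
# constraints whose atom name is absent from the assigned residue (only
# possible for substituted types) are skipped
pair_satisfied <- function(ctx, slot_a, key_a, slot_b, key_b) {
  if (slot_a > slot_b) {
    tmp <- slot_a; slot_a <- slot_b; slot_b <- tmp
    tmp <- key_a; key_a <- key_b; key_b <- tmp
  }
  cc <- ctx$pair_constraints[[paste(slot_a, slot_b)]]
  if (is.null(cc)) return(TRUE)
  ma <- get(key_a, envir = ctx$coords)
  mb <- get(key_b, envir = ctx$coords)
  ia <- match(cc$atom_i, rownames(ma))
  ib <- match(cc$atom_j, rownames(mb))
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) return(TRUE)
  da <- ma[ia[ok], , drop = FALSE]
  db <- mb[ib[ok], , drop = FALSE]
  d2 <- (da[, 1] - db[, 1])^2 + (da[, 2] - db[, 2])^2 +
    (da[, 3] - db[, 3])^2
  all(d2 <= cc$cutoff[ok]^2)
}

# depth-first search over the given active slots (0-based), rarest
# candidate list first; returns a list of named key vectors (names =
# slot index as character)
dfs_assignments <- function(ctx, active_slots) {
  ord <- active_slots[order(map_int(active_slots,
                                    ~ length(ctx$candidates[[.x + 1]])))]
  n <- length(ord)
  found <- list()
  keys <- character(n)
  recurse <- function(pos) {
    slot <- ord[pos]
    for (cand in ctx$candidates[[slot + 1]]) {
      if (pos > 1 && cand %in% keys[seq_len(pos - 1)]) next
      ok <- TRUE
      if (pos > 1) {
        for (q in seq_len(pos - 1)) {
          if (!pair_satisfied(ctx, slot, cand, ord[q], keys[q])) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) next
      keys[pos] <<- cand
      if (pos == n) {
        found[[length(found) + 1]] <<- setNames(keys, as.character(ord))
      } else {
        recurse(pos + 1)
      }
    }
  }
  if (n > 0) recurse(1)
  found
}

# assemble a match tibble row from a named slot->key vector
assemble_match <- function(ctx, keys_by_slot) {
  all_slots <- seq_len(ctx$n_slots) - 1L
  key <- unname(keys_by_slot[as.character(all_slots)])
  unmatched <- is.na(key)
  res_name <- ifelse(unmatched, NA_character_, ctx$res_name_by_key[key])
  a <- tibble(
    slot = all_slots,
    key = ifelse(unmatched, NA_character_, key),
    res_name = res_name,
    unmatched = unmatched
  )
  a <- a |>
    tidyr::separate_wider_delim("key", ":",
                                names = c("chain", "seq_id", "icode"),
                                cols_remove = FALSE) |>
    mutate(seq_id = suppressWarnings(as.integer(.data$seq_id))) |>
    select("slot", "key", "chain", "seq_id", "icode", "res_name",
           "unmatched")
  n_sub <- sum(!a$unmatched &
                 a$res_name != ctx$motif$slots$res_name, na.rm = TRUE)
  tibble(
    motif_id = ctx$motif$motif_id,
    query_id = ctx$query_id,
    n_substitutions = as.integer(n_sub),
    n_unmatched = as.integer(sum(unmatched)),
    residue_set = paste(sort(key[!unmatched]), collapse = "|"),
    .assign_key = paste(ifelse(unmatched, "-", key), collapse = "|"),
    assignment = list(a)
  )
}

# shared post-processing: maximality filter + dedup + deterministic order
finalize_matches <- function(ctx, rows) {
  if (length(rows) == 0) return(empty_matches())
  m <- bind_rows(rows)
  # a match with unmatched slots is dropped when its residues are all
  # contained in a stricter match (fewer unmatched slots)
  if (any(m$n_unmatched > 0)) {
    sets <- map(m$residue_set, ~ strsplit(.x, "|", fixed = TRUE)[[1]])
    keep <- map_lgl(seq_len(nrow(m)), function(i) {
      if (m$n_unmatched[i] == 0) return(TRUE)
      for (j in seq_len(nrow(m))) {
        if (m$n_unmatched[j] < m$n_unmatched[i] &&
            all(sets[[i]] %in% sets[[j]])) {
          return(FALSE)
        }
      }
      TRUE
    })
    m <- m[keep, , drop = FALSE]
  }
  # dedup by unordered residue set: fewest unmatched, then fewest
  # substitutions, then smallest assignment tuple
  m |>
    arrange(.data$residue_set, .data$n_unmatched, .data$n_substitutions,
            .data$.assign_key) |>
    distinct(.data$residue_set, .keep_all = TRUE) |>
    arrange(.data$residue_set) |>
    select(-".assign_key")
}

empty_matches <- function() {
  tibble(motif_id = character(), query_id = character(),
         n_substitutions = integer(), n_unmatched = integer(),
         residue_set = character(), assignment = list())
}

#' Find all residue constellations matching a motif
#'
#' Searches a query structure for sets of residues that satisfy every
#' distance constraint of the motif under the effective cutoff
#' `(distance + tolerance) * precision`. The search is a progressive
#' candidate filter: slots are ordered rarest residue type first, partial
#' assignments are extended one slot at a time, and any candidate that
#' violates a constraint against an already-assigned slot is pruned --- the
#' within-distance cascade a structure viewer would perform with nested
#' selections, made exhaustive. Matches may span chains. With
#' `max_unmatched > 0`, the search is repeated with slots left out to
#' admit imperfect matches, which are reported only when not contained in
#' a stricter match. Results are deduplicated by the unordered set of
#' assigned residues and returned in a deterministic order.
#'
#' @param motif A `sitemotif_motif`.
#' @param query A structure tibble.
#' @param options A [search_options()] list.
#' @return A tibble with one row per match: `motif_id`, `query_id`,
#'   `n_substitutions`, `n_unmatched`, `residue_set` (the dedup key), and
#'   list-column `assignment` (per-slot tibble with `slot`, `key`,
#'   `chain`, `seq_id`, `icode`, `res_name`, `unmatched`).
#' @examples
#' fx <- synth_structure(n_decoys = 10, seed = 3)
#' s <- read_pdb(fx$pdb)
#' m <- build_motif(s, fx$site_specs)
#' find_matches(m, s)
#' @seealso [brute_force_matches()] for the exhaustive verification
#'   oracle, [score_matches()] to add Levenshtein and RMSD scores.
#' @export
find_matches <- function(motif, query, options = search_options()) {
  v <- validate_motif(motif)
  if (length(v) > 0) abort(c("invalid motif:", v))
  ctx <- search_context(motif, query, options)
  rows <- list()
  for (k in 0:options$max_unmatched) {
    if (k >= ctx$n_slots) break
    excl_sets <- if (k == 0) list(integer(0)) else {
      apply(utils::combn(seq_len(ctx$n_slots) - 1L, k), 2, identity,
            simplify = FALSE)
    }
    for (excl in excl_sets) {
      active <- setdiff(seq_len(ctx$n_slots) - 1L, excl)
      for (keys in dfs_assignments(ctx, active)) {
        rows[[length(rows) + 1]] <- assemble_match(ctx, keys)
      }
    }
  }
  finalize_matches(ctx, rows)
}

#' Exhaustive brute-force motif search (verification oracle)
#'
#' Enumerates every tuple of distinct residues with slot-compatible types
#' and checks every constraint directly, with none of the progressive
#' pruning used by [find_matches()]. Definitionally equivalent output
#' (same deduplication and ordering), exponentially slower: guarded to
#' queries of at most 80 residues.
#'
#' @inheritParams find_matches
#' @return Same shape as [find_matches()].
#' @export
brute_force_matches <- function(motif, query,
                                options = search_options()) {
  v <- validate_motif(motif)
  if (length(v) > 0) abort(c("invalid motif:", v))
  ctx <- search_context(motif, query, options)
  if (nrow(ctx$res) > 80) {
    abort(sprintf(
      "brute-force search is limited to 80 residues (query has %d)",
      nrow(ctx$res)))
  }
  rows <- list()
  for (k in 0:options$max_unmatched) {
    if (k >= ctx$n_slots) break
    excl_sets <- if (k == 0) list(integer(0)) else {
      apply(utils::combn(seq_len(ctx$n_slots) - 1L, k), 2, identity,
            simplify = FALSE)
    }
    for (excl in excl_sets) {
      active <- setdiff(seq_len(ctx$n_slots) - 1L, excl)
      cand_lists <- map(active, ~ ctx$candidates[[.x + 1]])
      if (any(lengths(cand_lists) == 0)) next
      grid <- do.call(tidyr::expand_grid,
                      setNames(cand_lists, paste0("s", active)))
      for (r in seq_len(nrow(grid))) {
        keys <- as.character(grid[r, ])
        if (anyDuplicated(keys)) next
        ok <- TRUE
        for (a in seq_along(active)) {
          for (b in seq_len(a - 1)) {
            if (!pair_satisfied(ctx, active[a], keys[a],
                                active[b], keys[b])) {
              ok <- FALSE
              break
            }
          }
          if (!ok) break
        }
        if (ok) {
          rows[[length(rows) + 1]] <-
            assemble_match(ctx, setNames(keys, as.character(active)))
        }
      }
    }
  }
  finalize_matches(ctx, rows)
}
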