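#' Levenshtein edit distance between two strings
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions converting one string into the other, by the standard
#' dynamic program with unit costs. Identical strings are at distance 0;
#' one residue difference between a motif string and a match string gives
#' distance 1, and so on.
#'
#' @param a,b Character scalars (may be empty).
#' @return Non-negative integer.
#' @examples
#' levenshtein("HSE", "HSE")  # 0
#' levenshtein("HSE", "HCE")  # 1: His-Cys-Glu matching a His-Ser-Glu motif
#' @export
levenshtein <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1, length(b) == 1)
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  na <- length(sa)
  nb <- length(sb)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- integer(nb + 1)
    cur[1] <- i
    for (j in seq_len(nb)) {
      cost <- if (sa[i] == sb[j]) 0L else 1L
      cur[j + 1] <- min(prev[j + 1] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  as.integer(prev[nb + 1])
}

#' One-letter residue string of a match, in motif slot order
#'
#' Assigned query residues are transcribed to one-letter codes in slot
#' order; unmatched slots are omitted, so each shows up as a deletion in
#' the Levenshtein distance against [motif_string()].
#'
#' @param motif The motif the match belongs to.
#' @param assignment One `assignment` tibble from a [find_matches()] row.
#' @return Single string.
#' @export
match_string <- function(motif, assignment) {
  a <- assignment[!assignment$unmatched, , drop = FALSE]
  if (nrow(a) == 0) return("")
  paste(one_letter(a$res_name), collapse = "")
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid superposition of one point set onto another:
#' centroids are aligned, the optimal rotation comes from the SVD of the
#' covariance matrix with the determinant sign corrected so the result is
#' a proper rotation (no reflection), and the RMSD is reported over the
#' superposed pairs. Unweighted.
#'
#' @param ref_coords,mov_coords Numeric matrices, N x 3, N >= 1, row i of
#'   one corresponding to row i of the other. `mov_coords` is moved onto
#'   `ref_coords`.
#' @return List with `rotation` (3x3), `translation` (length 3; the fit
#'   is `ref ~ mov %*% t(rotation) + translation`), and `rmsd`
#'   (Angstrom).
#' @export
superpose <- function(ref_coords, mov_coords) {
  ref <- as.matrix(ref_coords)
  mov <- as.matrix(mov_coords)
  if (!all(dim(ref) == dim(mov)) || ncol(ref) != 3) {
    abort("coordinate sets must be N x 3 matrices of equal size")
  }
  n <- nrow(ref)
  if (n == 0) abort("cannot superpose empty coordinate sets")
  cr <- colMeans(ref)
  cm <- colMeans(mov)
  a <- sweep(ref, 2, cr)
  b <- sweep(mov, 2, cm)
  h <- t(b) %*% a
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- b %*% t(rot)
  rmsd <- sqrt(sum((a - fitted)^2) / n)
  list(rotation = rot, translation = as.numeric(cr - cm %*% t(rot)),
       rmsd = rmsd)
}

# side chains with chemically equivalent atom pairs whose labels can be
# swapped; each entry is a list of pairs swapped together
symmetric_sidechains <- list(
  ASP = list(c("OD1", "OD2")),
  GLU = list(c("OE1", "OE2")),
  ASN = NULL, # O/N are distinguishable; no swap
  PHE = list(c("CD1", "CD2"), c("CE1", "CE2")),
  TYR = list(c("CD1", "CD2"), c("CE1", "CE2")),
  ARG = list(c("NH1", "NH2"))
)

# atom correspondence (motif template atoms vs query atoms) for a match,
# as a tibble: slot, atom (motif name), query atom name, coordinates
match_correspondence <- function(motif, assignment, coords_env, mode) {
  rows <- list()
  for (i in seq_len(nrow(assignment))) {
    if (assignment$unmatched[i]) next
    slot_atoms <- motif$slots$atoms[[which(motif$slots$slot ==
                                             assignment$slot[i])]]
    qm <- get(assignment$key[i], envir = coords_env)
    wanted <- switch(mode,
      all = slot_atoms$atom,
      ca = intersect("CA", slot_atoms$atom),
      ca_cb = intersect(c("CA", "CB"), slot_atoms$atom)
    )
    wanted <- wanted[wanted %in% rownames(qm)]
    if (length(wanted) == 0) next
    ti <- match(wanted, slot_atoms$atom)
    rows[[length(rows) + 1]] <- tibble(
      slot = assignment$slot[i],
      res_name = assignment$res_name[i],
      atom = wanted,
      tx = slot_atoms$x[ti], ty = slot_atoms$y[ti], tz = slot_atoms$z[ti],
      qx = qm[wanted, 1], qy = qm[wanted, 2], qz = qm[wanted, 3]
    )
  }
  bind_rows(rows)
}

#' RMSD between a motif template and a match, in a given atom mode
#'
#' Builds the atom correspondence for the mode --- `"ca"`: CA against CA
#' per matched slot; `"ca_cb"`: CA and CB, skipping CB where absent on
#' either side (glycine contributes one pair); `"all"`: atoms sharing the
#' same name within each matched slot, so substituted residue types
#' contribute their shared names only --- then superposes the motif's
#' template coordinates onto the query with [superpose()] and returns the
#' RMSD. For side chains whose terminal atoms are chemically equivalent
#' (ASP, GLU, PHE, TYR, ARG), both labelings are tried per residue and
#' the lower RMSD kept, so an arbitrary OD1/OD2-style naming flip cannot
#' inflate the score. Returns `NA` when the mode yields no atom pairs
#' (for example `"ca"` against a motif that stored no backbone).
#'
#' @param motif The motif.
#' @param assignment One `assignment` tibble from a [find_matches()] row.
#' @param query The query structure.
#' @param mode `"all"`, `"ca"`, or `"ca_cb"`.
#' @return RMSD in Angstrom, or `NA_real_` when undefined.
#' @export
match_rmsd <- function(motif, assignment, query, mode = "all") {
  mode <- match.arg(mode, c("all", "ca", "ca_cb"))
  coords_env <- residue_coord_index(query)
  corr <- match_correspondence(motif, assignment, coords_env, mode)
  if (nrow(corr) == 0) return(NA_real_)
  ref <- cbind(corr$qx, corr$qy, corr$qz)
  mov <- cbind(corr$tx, corr$ty, corr$tz)

  # enumerate label swaps for symmetric side chains present in the
  # correspondence (query side), keep the lowest RMSD
  swap_sets <- list()
  if (mode == "all") {
    for (s in unique(corr$slot)) {
      rn <- corr$res_name[corr$slot == s][1]
      for (pair in symmetric_sidechains[[rn]] %||% list()) {
        i1 <- which(corr$slot == s & corr$atom == pair[1])
        i2 <- which(corr$slot == s & corr$atom == pair[2])
        if (length(i1) == 1 && length(i2) == 1) {
          swap_sets[[length(swap_sets) + 1]] <- c(i1, i2)
        }
      }
    }
  }
  # swaps within one residue are applied together (ring flips move both
  # CD and CE pairs); group swap sets by slot
  if (length(swap_sets) > 0 && length(swap_sets) <= 8) {
    slot_of <- map_int(swap_sets, ~ as.integer(corr$slot[.x[1]]))
    groups <- split(swap_sets, slot_of)
    best <- Inf
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(groups)))
    for (r in seq_len(nrow(combos))) {
      refr <- ref
      for (g in seq_along(groups)) {
        if (combos[r, g]) {
          for (sw in groups[[g]]) {
            refr[sw, ] <- refr[rev(sw), ]
          }
        }
      }
      best <- min(best, superpose(refr, mov)$rmsd)
    }
    return(best)
  }
  superpose(ref, mov)$rmsd
}

#' Score matches by Levenshtein distance and RMSD
#'
#' Annotates each match with the Levenshtein distance between the motif's
#' residue string and the match's residue string (substituted residues
#' appear as substitutions, unmatched slots as deletions) and, optionally,
#' the superposition RMSD in three atom modes: all atoms, C-alpha only,
#' and C-alpha plus C-beta.
#'
#' @param matches Output of [find_matches()] (or
#'   [brute_force_matches()]).
#' @param motif The motif searched.
#' @param query The query structure.
#' @param compute_rmsd Set `FALSE` to skip the RMSD columns (left `NA`).
#' @return Tibble of class `sitemotif_scores`: the match columns plus
#'   `levenshtein`, `rmsd_all`, `rmsd_ca`, `rmsd_ca_cb`, ranked with
#'   [rank_matches()].
#' @export
score_matches <- function(matches, motif, query, compute_rmsd = TRUE) {
  ms <- motif_string(motif)
  out <- matches
  out$levenshtein <- map_int(matches$assignment,
                             ~ levenshtein(ms, match_string(motif, .x)))
  if (compute_rmsd && nrow(matches) > 0) {
    out$rmsd_all <- map_dbl(matches$assignment,
                            ~ match_rmsd(motif, .x, query, "all"))
    out$rmsd_ca <- map_dbl(matches$assignment,
                           ~ match_rmsd(motif, .x, query, "ca"))
    out$rmsd_ca_cb <- map_dbl(matches$assignment,
                              ~ match_rmsd(motif, .x, query, "ca_cb"))
  } else {
    out$rmsd_all <- rep(NA_real_, nrow(out))
    out$rmsd_ca <- rep(NA_real_, nrow(out))
    out$rmsd_ca_cb <- rep(NA_real_, nrow(out))
  }
  out <- rank_matches(out)
  class(out) <- c("sitemotif_scores", class(tibble()))
  out
}

#' Rank scored matches
#'
#' Ascending by Levenshtein distance first (the first-level screen), then
#' by all-atom RMSD (lower is a better match), with ties broken by the
#' assigned residue tuple for determinism. `NA` RMSDs sort last within a
#' Levenshtein level.
#'
#' @param scored Output of [score_matches()].
#' @return The same tibble, reordered.
#' @export
rank_matches <- function(scored) {
  if (nrow(scored) == 0) return(scored)
  # arrange() sorts NA RMSDs last within a Levenshtein level
  scored |>
    arrange(.data$levenshtein, .data$rmsd_all, .data$residue_set)
}

#' Plot scored matches
#'
#' Levenshtein distance against all-atom RMSD, one point per match,
#' colored by motif. The best hits sit in the lower-left corner.
#'
#' @param object A `sitemotif_scores` (or batch results) tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sitemotif_scores <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rmsd_all,
                                   y = factor(.data$levenshtein),
                                   colour = .data$motif_id)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "all-atom RMSD (Å)",
                  y = "Levenshtein distance", colour = "motif") +
    ggplot2::theme_minimal()
}
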