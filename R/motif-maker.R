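#' Specify a catalytic residue for motif building
#'
#' Builds the residue-specification tibble consumed by [build_motif()]:
#' residue type, author residue number and chain, plus an optional flag to
#' add the backbone atoms (N, CA, C, O) of that residue to the template.
#'
#' @param res_name Three-letter residue code (must be a standard amino
#'   acid).
#' @param seq_id Author residue number.
#' @param chain Chain identifier.
#' @param icode Insertion code ("" for none).
#' @param include_backbone Add the residue's backbone atoms to its slot.
#' @return A one-row tibble; bind rows to specify several residues.
#' @examples
#' dplyr::bind_rows(
#'   residue_spec("SER", 1, "A"),
#'   residue_spec("HIS", 2, "A"),
#'   residue_spec("ASP", 3, "A")
#' )
#' @export
residue_spec <- function(res_name, seq_id, chain, icode = "",
                         include_backbone = FALSE) {
  res_name <- toupper(res_name)
  if (!res_name %in% standard_aa) {
    abort(paste0("residue must be a standard amino acid, got: ", res_name))
  }
  tibble(res_name = res_name, seq_id = as.integer(seq_id),
         chain = as.character(chain), icode = icode,
         include_backbone = isTRUE(include_backbone))
}

#' Build a motif template from a structure
#'
#' Creates an orientation-independent motif from the catalytic residues of
#' a source structure. Each specified residue becomes a slot whose atom
#' list is its side-chain heavy atoms (plus backbone atoms when requested
#' for that residue); the template then records the distance between every
#' atom pair across every slot pair. Matching a query later requires each
#' of those distances to be reproduced within `tolerance` (times the
#' search-time precision factor), which captures the site's geometry
#' without reference to any coordinate frame.
#'
#' @param structure A structure tibble (see [read_pdb()]).
#' @param specs Residue specification tibble from [residue_spec()] rows;
#'   at least three residues. Spec order defines slot order (and hence the
#'   motif's residue string for Levenshtein scoring); matching itself is
#'   order-independent.
#' @param tolerance Angstrom allowance added to template distances at
#'   search time; default 2.00.
#' @param ec_number EC classification of the source enzyme (dotted string).
#' @param motif_id Identifier; defaults to `<struct_id>_site`.
#' @param set_label Motif set label, default `"U"` (user-built).
#' @return A validated `sitemotif_motif`.
#' @examples
#' fx <- synth_structure(n_decoys = 10, seed = 3)
#' s <- read_pdb(fx$pdb)
#' m <- build_motif(s, fx$site_specs, ec_number = "3.4.21.4")
#' glance(m)
#' @export
build_motif <- function(structure, specs, tolerance = 2.00,
                        ec_number = "", motif_id = NULL,
                        set_label = "U") {
  if (nrow(specs) < 3) {
    abort(sprintf(
      "active site must contain at least 3 residues (%d specified)",
      nrow(specs)))
  }
  if (!"icode" %in% names(specs)) specs$icode <- ""
  if (!"include_backbone" %in% names(specs)) specs$include_backbone <- FALSE
  motif_id <- motif_id %||% paste0(struct_id(structure), "_site")

  atoms_tbl <- as_tibble(structure)
  slot_rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    res <- atoms_tbl |>
      filter(.data$chain == sp$chain, .data$seq_id == sp$seq_id,
             .data$icode == sp$icode)
    if (nrow(res) == 0) {
      abort(sprintf("residue not found in structure: chain %s, number %d%s",
                    sp$chain, sp$seq_id, sp$icode))
    }
    found_name <- unique(res$res_name)
    if (!identical(found_name, sp$res_name)) {
      abort(sprintf(
        "residue %s:%d is %s in the structure, but the spec says %s",
        sp$chain, sp$seq_id, paste(found_name, collapse = "/"),
        sp$res_name))
    }
    sel <- atom_subset(res, "sidechain")
    if (sp$include_backbone) {
      sel <- bind_rows(atom_subset(res, "backbone"), sel)
    }
    if (nrow(sel) == 0) {
      abort(sprintf(
        "residue %s:%d (%s) has no side-chain heavy atoms; set include_backbone for it",
        sp$chain, sp$seq_id, sp$res_name))
    }
    slot_rows[[i]] <- tibble(
      slot = i - 1L, res_name = sp$res_name, seq_id = sp$seq_id,
      chain = sp$chain,
      atoms = list(tibble(atom = sel$atom, x = sel$x, y = sel$y,
                          z = sel$z)))
  }
  slots <- bind_rows(slot_rows)

  cons <- list()
  for (i in seq_len(nrow(slots) - 1)) {
    ai <- slots$atoms[[i]]
    for (j in seq(i + 1, nrow(slots))) {
      aj <- slots$atoms[[j]]
      grid <- tidyr::expand_grid(ii = seq_len(nrow(ai)),
                                 jj = seq_len(nrow(aj)))
      d <- sqrt((ai$x[grid$ii] - aj$x[grid$jj])^2 +
                (ai$y[grid$ii] - aj$y[grid$jj])^2 +
                (ai$z[grid$ii] - aj$z[grid$jj])^2)
      cons[[length(cons) + 1]] <- tibble(
        slot_i = slots$slot[i], atom_i = ai$atom[grid$ii],
        slot_j = slots$slot[j], atom_j = aj$atom[grid$jj],
        distance = d)
    }
  }

  m <- new_motif(motif_id = motif_id, source_pdb = struct_id(structure),
                 ec_number = ec_number, set_label = set_label,
                 slots = slots, constraints = bind_rows(cons),
                 tolerance = tolerance)
  v <- validate_motif(m)
  if (length(v) > 0) abort(c("built motif failed validation:", v))
  m
}

#' Self-test a motif against its source structure
#'
#' Acceptance check for a freshly built motif: the template must be found
#' in the very structure it came from, with Levenshtein distance 0 and
#' all-atom RMSD ~0 after superposition. Runs [find_matches()] at
#' precision 1.0 and looks for a match covering exactly the motif's source
#' residues. Because distance constraints and superposition RMSD are both
#' rigid-motion invariant, the test also passes when the source has been
#' rotated and translated.
#'
#' @param motif A motif.
#' @param source The structure the motif was built from (possibly rigidly
#'   moved).
#' @return One-row tibble: `found` (logical), `levenshtein` (integer, NA
#'   when not found), `rmsd_all` (Angstrom, NA when not found).
#' @export
self_test <- function(motif, source) {
  target <- sort(residue_key(motif$slots$chain, motif$slots$seq_id))
  matches <- find_matches(motif, source, search_options(precision = 1.0))
  hit <- NULL
  for (i in seq_len(nrow(matches))) {
    a <- matches$assignment[[i]]
    if (identical(sort(a$key[!a$unmatched]), target)) {
      hit <- matches[i, ]
      break
    }
  }
  if (is.null(hit)) {
    return(tibble(found = FALSE, levenshtein = NA_integer_,
                  rmsd_all = NA_real_))
  }
  scored <- score_matches(hit, motif, source)
  tibble(found = TRUE, levenshtein = scored$levenshtein[1],
         rmsd_all = scored$rmsd_all[1])
}

#' Apply a rigid motion to a structure
#'
#' Rotates and translates every atom; useful for testing the engine's
#' rigid-motion invariance.
#'
#' @param structure A structure tibble.
#' @param rotation 3x3 rotation matrix (default: identity).
#' @param translation Length-3 numeric offset (default: zero).
#' @return The transformed structure.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- cbind(structure$x, structure$y, structure$z) %*% t(rotation)
  out <- as_tibble(structure)
  out$x <- xyz[, 1] + translation[1]
  out$y <- xyz[, 2] + translation[2]
  out$z <- xyz[, 3] + translation[3]
  new_structure(out, struct_id = struct_id(structure),
                model = attr(structure, "model") %||% 1L)
}

#' Draw a uniformly random rotation matrix
#'
#' @param seed Optional RNG seed (local to this call).
#' @return A 3x3 proper rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  # QR of a Gaussian matrix, sign-corrected to a proper rotation
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  q <- q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}
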