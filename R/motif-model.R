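#' Motif template objects
#'
#' A motif is an orientation-independent description of a catalytic site:
#' an ordered list of residue slots (residue type, source residue identity,
#' atom names with their template coordinates) plus the template distances
#' between every atom pair across every slot pair, and a tolerance in
#' Angstrom that is added to each template distance when testing a
#' candidate site. The default tolerance is 2.00 Angstrom.
#'
#' @param motif_id Unique identifier for the motif.
#' @param source_pdb Identifier of the structure the template was taken
#'   from.
#' @param ec_number Dotted Enzyme Commission string, 1-4 levels (may be
#'   empty).
#' @param set_label Motif set: `"P"` (packaged), `"U"` (user), `"J"`, `"N"`.
#' @param slots Tibble with columns `slot` (0-based), `res_name`, `seq_id`,
#'   `chain`, and list-column `atoms` (each a tibble `atom`, `x`, `y`, `z`).
#' @param constraints Tibble with columns `slot_i`, `atom_i`, `slot_j`,
#'   `atom_j`, `distance` covering every unordered slot pair.
#' @param tolerance Angstrom allowance added to template distances.
#' @return An object of class `sitemotif_motif`.
#' @seealso [build_motif()], [parse_motif()], [validate_motif()]
#' @export
new_motif <- function(motif_id, source_pdb = "", ec_number = "",
                      set_label = "U", slots, constraints,
                      tolerance = 2.00) {
  m <- structure(
    list(motif_id = motif_id, source_pdb = source_pdb,
         ec_number = ec_number, set_label = set_label,
         slots = as_tibble(slots), constraints = as_tibble(constraints),
         tolerance = tolerance),
    class = "sitemotif_motif"
  )
  m
}

#' Validate a motif template
#'
#' Checks every structural invariant of a motif and returns the violations
#' as a character vector (empty when the motif is valid). Pure; never
#' raises.
#'
#' Invariants: at least three residue slots; standard amino-acid slot
#' types; non-empty atom lists with one finite coordinate triple per atom;
#' every unordered slot pair covered by at least one distance constraint;
#' constraint endpoints present in their slots' atom lists; positive
#' constraint distances with `slot_i < slot_j`; non-negative tolerance.
#'
#' @param motif A `sitemotif_motif`.
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_motif <- function(motif) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!is.list(motif) || is.null(motif$slots) || is.null(motif$constraints)) {
    return("not a motif object (missing slots or constraints)")
  }
  sl <- motif$slots
  cs <- motif$constraints
  if (nrow(sl) < 3) {
    add(sprintf("active site must contain at least 3 residues (has %d)",
                nrow(sl)))
  }
  if (!identical(sl$slot, seq_len(nrow(sl)) - 1L) &&
      !identical(as.integer(sl$slot), seq_len(nrow(sl)) - 1L)) {
    add("slot indices must be 0..n-1 in order")
  }
  bad_aa <- setdiff(unique(sl$res_name), standard_aa)
  if (length(bad_aa) > 0) {
    add(paste0("slot residue type(s) not standard amino acids: ",
               paste(bad_aa, collapse = ", ")))
  }
  for (i in seq_len(nrow(sl))) {
    at <- sl$atoms[[i]]
    if (is.null(at) || nrow(at) == 0) {
      add(sprintf("slot %d has an empty atom list", sl$slot[i]))
      next
    }
    if (any(!nzchar(trimws(at$atom)))) {
      add(sprintf("slot %d has a blank atom name", sl$slot[i]))
    }
    if (anyDuplicated(at$atom)) {
      add(sprintf("slot %d has duplicate atom names", sl$slot[i]))
    }
    if (!all(is.finite(c(at$x, at$y, at$z)))) {
      add(sprintf("slot %d has non-finite template coordinates", sl$slot[i]))
    }
  }
  if (is.null(motif$tolerance) || !is.finite(motif$tolerance) ||
      motif$tolerance < 0) {
    add("tolerance must be a non-negative number")
  }
  if (nrow(cs) > 0) {
    if (any(cs$slot_i >= cs$slot_j)) {
      add("constraints must have slot_i < slot_j")
    }
    if (any(!is.finite(cs$distance) | cs$distance <= 0)) {
      add("constraint distances must be positive")
    }
    slot_atoms <- setNames(map(sl$atoms, ~ .x$atom), as.character(sl$slot))
    for (r in seq_len(nrow(cs))) {
      for (side in c("i", "j")) {
        s <- cs[[paste0("slot_", side)]][r]
        a <- cs[[paste0("atom_", side)]][r]
        if (!as.character(s) %in% names(slot_atoms)) {
          add(sprintf("constraint %d references missing slot %d", r, s))
        } else if (!a %in% slot_atoms[[as.character(s)]]) {
          add(sprintf("constraint %d references atom %s absent from slot %d",
                      r, a, s))
        }
      }
    }
  }
  n <- nrow(sl)
  if (n >= 2) {
    want <- utils::combn(sort(sl$slot), 2)
    have <- unique(paste(cs$slot_i, cs$slot_j))
    missing_pairs <- setdiff(paste(want[1, ], want[2, ]), have)
    if (length(missing_pairs) > 0) {
      add(paste0("slot pair(s) without any distance constraint: ",
                 paste(missing_pairs, collapse = "; ")))
    }
  }
  v
}

#' Serialize a motif to YAML text
#'
#' Writes the complete motif -- identity, slots with template coordinates,
#' all pairwise distance constraints and the tolerance -- as deterministic,
#' human-readable YAML. Template coordinates are included so RMSD against
#' the motif is computable without the source structure. Numbers are
#' written with 17 significant digits, so `parse_motif(serialize_motif(m))`
#' reproduces every double exactly and repeated calls are byte-identical.
#'
#' @param motif A valid `sitemotif_motif`.
#' @return A single YAML string.
#' @export
serialize_motif <- function(motif) {
  v <- validate_motif(motif)
  if (length(v) > 0) {
    abort(c("cannot serialize an invalid motif:", v))
  }
  doc <- list(
    motif_id = motif$motif_id,
    source_pdb = motif$source_pdb,
    ec_number = motif$ec_number,
    set_label = motif$set_label,
    tolerance = motif$tolerance,
    slots = pmap(motif$slots, function(slot, res_name, seq_id, chain,
                                       atoms) {
      list(slot = as.integer(slot), res_name = res_name,
           seq_id = as.integer(seq_id), chain = chain,
           atoms = pmap(atoms, function(atom, x, y, z) {
             list(name = atom, x = x, y = y, z = z)
           }))
    }),
    constraints = pmap(motif$constraints,
                       function(slot_i, atom_i, slot_j, atom_j, distance) {
      list(slot_i = as.integer(slot_i), atom_i = atom_i,
           slot_j = as.integer(slot_j), atom_j = atom_j,
           distance = distance)
    })
  )
  yaml::as.yaml(doc, precision = 17L)
}

#' Parse a motif from YAML text or a file
#'
#' Reads the declarative motif format written by [serialize_motif()] (or
#' hand-written to the same schema) and returns a fully validated motif. A
#' missing `tolerance` field defaults to 2.00 Angstrom.
#'
#' @param text YAML text, or a path to a motif file.
#' @return A `sitemotif_motif`.
#' @export
parse_motif <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text), collapse = "\n")
  }
  doc <- tryCatch(yaml::yaml.load(text), error = function(e) {
    abort(paste0("motif YAML parse error: ", conditionMessage(e)))
  })
  for (f in c("motif_id", "slots", "constraints")) {
    if (is.null(doc[[f]])) {
      abort(paste0("motif file missing required field: ", f))
    }
  }
  slots <- bind_rows(map(doc$slots, function(s) {
    for (f in c("slot", "res_name", "seq_id", "chain", "atoms")) {
      if (is.null(s[[f]])) {
        abort(paste0("motif slot missing field: slots/", f))
      }
    }
    tibble(slot = as.integer(s$slot), res_name = s$res_name,
           seq_id = as.integer(s$seq_id), chain = as.character(s$chain),
           atoms = list(bind_rows(map(s$atoms, function(a) {
             tibble(atom = a$name, x = as.numeric(a$x),
                    y = as.numeric(a$y), z = as.numeric(a$z))
           }))))
  }))
  constraints <- bind_rows(map(doc$constraints, function(cc) {
    tibble(slot_i = as.integer(cc$slot_i), atom_i = cc$atom_i,
           slot_j = as.integer(cc$slot_j), atom_j = cc$atom_j,
           distance = as.numeric(cc$distance))
  }))
  m <- new_motif(
    motif_id = doc$motif_id,
    source_pdb = doc$source_pdb %||% "",
    ec_number = doc$ec_number %||% "",
    set_label = doc$set_label %||% "U",
    slots = slots, constraints = constraints,
    tolerance = doc$tolerance %||% 2.00
  )
  v <- validate_motif(m)
  if (length(v) > 0) {
    abort(c(paste0("invalid motif '", m$motif_id, "':"), v))
  }
  m
}

#' Write a motif to a file
#'
#' @param motif A valid motif.
#' @param path Output path (conventionally `<set>_<motif_id>.motif.yaml`).
#' @return `path`, invisibly.
#' @export
write_motif <- function(motif, path) {
  writeLines(sub("\n$", "", serialize_motif(motif)), path)
  invisible(path)
}

#' One-letter residue string of a motif, in slot order
#'
#' @param motif A motif.
#' @return Single string, one character per slot.
#' @export
motif_string <- function(motif) {
  paste(one_letter(motif$slots$res_name), collapse = "")
}

#' @export
print.sitemotif_motif <- function(x, ...) {
  cat("# motif '", x$motif_id, "' (set ", x$set_label,
      if (nzchar(x$ec_number)) paste0(", EC ", x$ec_number), "): ",
      nrow(x$slots), " slots [",
      paste(x$slots$res_name, collapse = "-"), "], ",
      nrow(x$constraints), " distance constraints, tolerance ",
      format(x$tolerance), " A\n", sep = "")
  invisible(x)
}

#' @describeIn new_motif `tidy()` returns the constraint table (one row per
#'   atom-pair distance constraint).
#' @param x A motif.
#' @param ... Unused.
#' @export
tidy.sitemotif_motif <- function(x, ...) {
  x$constraints
}

#' @describeIn new_motif `glance()` returns a one-row summary.
#' @export
glance.sitemotif_motif <- function(x, ...) {
  tibble(motif_id = x$motif_id, set_label = x$set_label,
         ec_number = x$ec_number, n_slots = nrow(x$slots),
         residues = paste(x$slots$res_name, collapse = "-"),
         n_constraints = nrow(x$constraints), tolerance = x$tolerance)
}
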