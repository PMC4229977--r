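#' Read a PDB-format structure into an atom tibble
#'
#' Parses PDB coordinate records into a flat tibble with one row per heavy
#' atom, keeping the first model of multi-model files. Hydrogens (and
#' deuteriums), waters and all HETATM residues other than selenomethionine
#' are dropped; MSE is normalized to MET (its SE atom renamed SD). When a
#' file carries alternate locations, the conformer with the highest
#' occupancy is kept per atom, ties broken by altloc character order.
#'
#' Parsing itself is delegated to [bio3d::read.pdb()]; this function applies
#' the selection and normalization rules above and reshapes the result.
#'
#' @param source Path to a PDB file, or a character scalar containing
#'   PDB-format text (recognized by the presence of a newline).
#' @param struct_id Identifier for the structure. Defaults to the file name
#'   stem, or `"structure"` for literal text input.
#'
#' @return A tibble of class `sitemotif_structure` with columns `chain`,
#'   `seq_id`, `icode`, `res_name`, `atom`, `element`, `x`, `y`, `z`,
#'   `occupancy`, and attributes `struct_id` and `model` (the model index
#'   kept, always 1).
#'
#' @examples
#' pdb <- synth_structure(n_decoys = 5, seed = 1)$pdb
#' s <- read_pdb(pdb)
#' dplyr::count(s, res_name)
#' @export
read_pdb <- function(source, struct_id = NULL) {
  stopifnot(is.character(source), length(source) == 1)
  if (grepl("\n", source)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(sub("\n$", "", source), path)
    struct_id <- struct_id %||% "structure"
  } else {
    if (!file.exists(source)) {
      abort(paste0("PDB file not found: ", source))
    }
    path <- source
    struct_id <- struct_id %||% sub("\\.(pdb|ent)$", "", basename(source))
  }

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      abort(paste0("cannot parse PDB input '", struct_id, "': ",
                   conditionMessage(e)))
    }
  )
  at <- as_tibble(pdb$atom)
  if (nrow(at) == 0) {
    abort(paste0("no ATOM records in PDB input '", struct_id, "'"))
  }

  at <- at |>
    mutate(
      alt = ifelse(is.na(.data$alt), "", .data$alt),
      insert = ifelse(is.na(.data$insert), "", .data$insert),
      chain = ifelse(is.na(.data$chain), "A", .data$chain),
      o = ifelse(is.na(.data$o), 1, .data$o),
      elesy = ifelse(is.na(.data$elesy), guess_element(.data$elety),
                     .data$elesy)
    ) |>
    # heavy atoms of amino-acid residues only: no hydrogens, no waters,
    # no HETATM except selenomethionine
    filter(!(toupper(.data$elesy) %in% c("H", "D")),
           .data$type == "ATOM" | .data$resid == "MSE",
           !(.data$resid %in% c("HOH", "WAT", "DOD")))
  if (nrow(at) == 0) {
    abort(paste0("no heavy protein atoms in PDB input '", struct_id, "'"))
  }

  at <- at |>
    mutate(
      elety = ifelse(.data$resid == "MSE" & .data$elety == "SE", "SD",
                     .data$elety),
      elesy = ifelse(.data$resid == "MSE" & toupper(.data$elesy) == "SE",
                     "S", .data$elesy),
      resid = ifelse(.data$resid == "MSE", "MET", .data$resid)
    )

  # altloc: keep highest occupancy per atom, ties by altloc character
  at <- at |>
    mutate(.ord = row_number()) |>
    arrange(.data$chain, .data$resno, .data$insert, .data$elety,
            dplyr::desc(.data$o), .data$alt) |>
    distinct(.data$chain, .data$resno, .data$insert, .data$elety,
             .keep_all = TRUE) |>
    arrange(.data$.ord)

  out <- tibble(
    chain = at$chain,
    seq_id = as.integer(at$resno),
    icode = at$insert,
    res_name = at$resid,
    atom = trimws(at$elety),
    element = toupper(at$elesy),
    x = at$x, y = at$y, z = at$z,
    occupancy = at$o
  )
  new_structure(out, struct_id = struct_id)
}

guess_element <- function(name) {
  stripped <- sub("^[0-9']*", "", trimws(name))
  substr(stripped, 1, 1)
}

#' Construct a structure tibble
#'
#' Low-level constructor used by [read_pdb()] and the fixture generator.
#'
#' @param atoms Tibble with columns `chain`, `seq_id`, `icode`, `res_name`,
#'   `atom`, `element`, `x`, `y`, `z`, `occupancy`.
#' @param struct_id Structure identifier.
#' @param model Model index retained (PDB files with several models keep the
#'   first).
#' @return The atom tibble with class `sitemotif_structure`.
#' @export
new_structure <- function(atoms, struct_id = "structure", model = 1L) {
  req <- c("chain", "seq_id", "icode", "res_name", "atom", "element",
           "x", "y", "z", "occupancy")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("structure tibble lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  out <- as_tibble(atoms)
  class(out) <- c("sitemotif_structure", class(tibble()))
  attr(out, "struct_id") <- struct_id
  attr(out, "model") <- as.integer(model)
  out
}

#' @export
print.sitemotif_structure <- function(x, ...) {
  cat("# structure '", struct_id(x), "': ",
      nrow(distinct(as_tibble(x), .data$chain, .data$seq_id, .data$icode)),
      " residues, ", nrow(x), " atoms\n", sep = "")
  NextMethod()
}

#' Structure identifier
#'
#' @param structure A structure tibble.
#' @return The `struct_id` attribute, or `"structure"` when absent (for
#'   example after dplyr operations that drop attributes).
#' @export
struct_id <- function(structure) {
  attr(structure, "struct_id") %||% "structure"
}

#' Write a structure to PDB format
#'
#' Formats the atom tibble back into PDB ATOM records via
#' [bio3d::write.pdb()]. Coordinates are written at the format's fixed
#' precision (3 decimals), so a round trip agrees to 1e-3 Angstrom.
#'
#' @param structure A structure tibble.
#' @param path Output file path, or `NULL` to return the PDB text as a
#'   single string.
#' @return `path` invisibly, or the PDB text when `path` is `NULL`.
#' @export
write_pdb <- function(structure, path = NULL) {
  as_text <- is.null(path)
  if (as_text) path <- tempfile(fileext = ".pdb")
  n <- nrow(structure)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(cbind(structure$x, structure$y, structure$z))),
    type = rep("ATOM", n),
    resno = structure$seq_id,
    resid = structure$res_name,
    eleno = seq_len(n),
    elety = structure$atom,
    chain = structure$chain,
    insert = ifelse(structure$icode == "", NA, structure$icode),
    o = structure$occupancy,
    b = rep(0, n),
    elesy = structure$element
  )
  if (as_text) {
    txt <- paste0(paste(readLines(path), collapse = "\n"), "\n")
    unlink(path)
    return(txt)
  }
  invisible(path)
}

#' Select atoms of a residue (or structure) by mode
#'
#' Atom selection used throughout motif building and RMSD scoring. Modes:
#' `"sidechain"` (atoms not in N, CA, C, O), `"backbone"` (N, CA, C, O),
#' `"ca"` (CA only), `"ca_cb"` (CA and CB; glycine contributes CA only),
#' `"all"` (everything). Selection is applied row-wise, so the function
#' works on a single residue's atoms or on a whole structure; input row
#' order (file order) is preserved.
#'
#' @param atoms Atom tibble (a structure, or a subset of its rows).
#' @param mode One of `"sidechain"`, `"backbone"`, `"all"`, `"ca"`,
#'   `"ca_cb"`.
#' @return The filtered atom tibble.
#' @examples
#' s <- read_pdb(synth_structure(n_decoys = 0, seed = 1)$pdb)
#' ser <- dplyr::filter(s, res_name == "SER")
#' atom_subset(ser, "sidechain")$atom  # CB, OG
#' @export
atom_subset <- function(atoms, mode) {
  mode <- match.arg(mode, c("sidechain", "backbone", "all", "ca", "ca_cb"))
  keep <- switch(mode,
    sidechain = !(atoms$atom %in% backbone_atoms),
    backbone = atoms$atom %in% backbone_atoms,
    ca = atoms$atom == "CA",
    ca_cb = atoms$atom %in% c("CA", "CB"),
    all = rep(TRUE, nrow(atoms))
  )
  atoms[keep, , drop = FALSE]
}

#' Convert a three-letter residue code to one letter
#'
#' Standard IUPAC mapping; MSE (selenomethionine) maps to M. Vectorized.
#'
#' @param res_name Character vector of three-letter codes.
#' @return Character vector of one-letter codes.
#' @export
one_letter <- function(res_name) {
  out <- unname(aa_three_to_one[toupper(res_name)])
  if (anyNA(out)) {
    abort(paste0("unknown residue code(s): ",
                 paste(unique(res_name[is.na(out)]), collapse = ", ")))
  }
  out
}

# residue identity key within a structure: chain + author number + icode
residue_key <- function(chain, seq_id, icode = "") {
  paste(chain, seq_id, icode, sep = ":")
}

#' List the residues of a structure
#'
#' One row per residue, in file order, with its identity key.
#'
#' @param structure A structure tibble.
#' @return Tibble with columns `key`, `chain`, `seq_id`, `icode`,
#'   `res_name`, `n_atoms`.
#' @export
residues <- function(structure) {
  as_tibble(structure) |>
    mutate(key = residue_key(.data$chain, .data$seq_id, .data$icode)) |>
    group_by(.data$key, .data$chain, .data$seq_id, .data$icode,
             .data$res_name) |>
    dplyr::summarise(n_atoms = dplyr::n(), .groups = "drop") |>
    arrange(match(.data$key, unique(residue_key(structure$chain,
                                                structure$seq_id,
                                                structure$icode))))
}

# per-residue coordinate matrices (rownames = atom names), in an
# environment keyed by residue key; shared by finder and scoring
residue_coord_index <- function(structure) {
  keys <- residue_key(structure$chain, structure$seq_id, structure$icode)
  xyz <- cbind(structure$x, structure$y, structure$z)
  idx <- split(seq_len(nrow(structure)), keys)
  env <- new.env(parent = emptyenv())
  for (k in names(idx)) {
    m <- xyz[idx[[k]], , drop = FALSE]
    rownames(m) <- structure$atom[idx[[k]]]
    assign(k, m, envir = env)
  }
  env
}
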