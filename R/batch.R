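#' Load a motif library from directories
#'
#' Reads every motif file (`*.yaml` / `*.motif.yaml`) under the given
#' directories, validates each, and keeps those whose set label is in
#' `sets`. Invalid or unparseable files are skipped with a warning (one
#' bad file must not take down a library); duplicate motif ids across
#' files are an error naming both files.
#'
#' @param directories Character vector of directories to scan.
#' @param sets Set labels to keep, a subset of `c("P","U","J","N")`.
#' @return List of class `sitemotif_library` with elements `motifs`
#'   (named list of motifs), `files` (named character of source paths),
#'   `sets`.
#' @export
load_library <- function(directories, sets = c("P", "U", "J", "N")) {
  missing_dirs <- directories[!dir.exists(directories)]
  if (length(missing_dirs) > 0) {
    abort(paste0("motif director(ies) not found: ",
                 paste(missing_dirs, collapse = ", ")))
  }
  files <- unlist(map(directories, ~ list.files(
    .x, pattern = "\\.ya?ml$", full.names = TRUE)))
  files <- sort(files)
  motifs <- list()
  sources <- character()
  for (f in files) {
    m <- tryCatch(parse_motif(f), error = function(e) {
      warn(paste0("skipping unreadable motif file ", f, ": ",
                  conditionMessage(e)))
      NULL
    })
    if (is.null(m)) next
    if (!m$set_label %in% sets) next
    if (m$motif_id %in% names(motifs)) {
      abort(paste0("duplicate motif_id '", m$motif_id, "' in files ",
                   sources[[m$motif_id]], " and ", f))
    }
    motifs[[m$motif_id]] <- m
    sources[[m$motif_id]] <- f
  }
  if (length(motifs) == 0) {
    abort(paste0("no readable motif files with set label in {",
                 paste(sets, collapse = ","), "} under: ",
                 paste(directories, collapse = ", ")))
  }
  structure(list(motifs = motifs, files = sources, sets = sets),
            class = "sitemotif_library")
}

#' @export
print.sitemotif_library <- function(x, ...) {
  cat("# motif library: ", length(x$motifs), " motifs (sets ",
      paste(sort(unique(map_chr(x$motifs, "set_label"))), collapse = ","),
      ")\n", sep = "")
  invisible(x)
}

#' @describeIn load_library `tidy()` gives one row per motif in the
#'   library.
#' @param x A `sitemotif_library`.
#' @param ... Unused.
#' @export
tidy.sitemotif_library <- function(x, ...) {
  bind_rows(map(x$motifs, glance))
}

# flatten one assignment tibble to "chain:seq_id:res_name" per slot
# ("-" for unmatched), pipe-separated
assignment_label <- function(assignment) {
  paste(ifelse(assignment$unmatched, "-",
               paste(assignment$chain, assignment$seq_id,
                     assignment$res_name, sep = ":")),
        collapse = "|")
}

#' Search many structures against a motif library
#'
#' Runs [find_matches()] plus [score_matches()] for the full cross
#' product of structures and motifs and flattens every scored match into
#' one result record. A failure on one structure is caught, logged, and
#' does not affect the others.
#'
#' @param structures A structure tibble or a list of them.
#' @param library A `sitemotif_library` (or a list of motifs).
#' @param options A [search_options()] list.
#' @param compute_rmsd Compute the three RMSD columns (RMSD is optional;
#'   `FALSE` leaves them `NA` and skips the superpositions).
#' @return Tibble of class `sitemotif_results`, ordered by `query_id`,
#'   `motif_id`, then rank: columns `query_id`, `motif_id`, `motif_ec`,
#'   `levenshtein`, `rmsd_all`, `rmsd_ca`, `rmsd_ca_cb`,
#'   `n_substitutions`, `n_unmatched`, `residues`
#'   (`chain:seq_id:res_name` per slot). A per-structure run log is
#'   attached as attribute `"run_log"`.
#' @export
batch_search <- function(structures, library,
                         options = search_options(),
                         compute_rmsd = TRUE) {
  if (is.data.frame(structures)) structures <- list(structures)
  if (length(structures) == 0) abort("no structures to search")
  motifs <- if (inherits(library, "sitemotif_library")) {
    library$motifs
  } else if (inherits(library, "sitemotif_motif")) {
    setNames(list(library), library$motif_id)
  } else {
    setNames(library, map_chr(library, "motif_id"))
  }
  if (length(motifs) == 0) abort("no motifs to search")

  records <- list()
  log_rows <- list()
  for (s in structures) {
    qid <- struct_id(s)
    t0 <- Sys.time()
    res <- tryCatch({
      rows <- list()
      for (m in motifs) {
        scored <- score_matches(find_matches(m, s, options), m, s,
                                compute_rmsd = compute_rmsd)
        if (nrow(scored) == 0) next
        rows[[length(rows) + 1]] <- tibble(
          query_id = qid,
          motif_id = m$motif_id,
          motif_ec = m$ec_number,
          levenshtein = scored$levenshtein,
          rmsd_all = scored$rmsd_all,
          rmsd_ca = scored$rmsd_ca,
          rmsd_ca_cb = scored$rmsd_ca_cb,
          n_substitutions = scored$n_substitutions,
          n_unmatched = scored$n_unmatched,
          residues = map_chr(scored$assignment, assignment_label)
        )
      }
      bind_rows(rows)
    }, error = function(e) e)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      warn(paste0("batch: structure '", qid, "' failed: ",
                  conditionMessage(res)))
      log_rows[[length(log_rows) + 1]] <- tibble(
        query_id = qid, status = "error", n_matches = NA_integer_,
        seconds = elapsed, message = conditionMessage(res))
    } else {
      records[[length(records) + 1]] <- res
      log_rows[[length(log_rows) + 1]] <- tibble(
        query_id = qid, status = "ok", n_matches = nrow(res),
        seconds = elapsed, message = "")
    }
  }
  out <- bind_rows(records)
  if (nrow(out) == 0) {
    out <- tibble(query_id = character(), motif_id = character(),
                  motif_ec = character(), levenshtein = integer(),
                  rmsd_all = double(), rmsd_ca = double(),
                  rmsd_ca_cb = double(), n_substitutions = integer(),
                  n_unmatched = integer(), residues = character())
  }
  out <- arrange(out, .data$query_id, .data$motif_id)
  class(out) <- c("sitemotif_results", "sitemotif_scores",
                  class(tibble()))
  attr(out, "run_log") <- bind_rows(log_rows)
  out
}

results_header <- c("query_id", "motif_id", "motif_ec", "levenshtein",
                    "rmsd_all", "rmsd_ca", "rmsd_ca_cb",
                    "n_substitutions", "n_unmatched", "residues")

#' Write batch results to CSV
#'
#' Fixed column order (`query_id, motif_id, motif_ec, levenshtein,
#' rmsd_all, rmsd_ca, rmsd_ca_cb, n_substitutions, n_unmatched,
#' residues`), RMSDs printed with 3 decimals (empty when not computed),
#' deterministic row order: identical inputs give byte-identical files.
#'
#' @param records A `sitemotif_results` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.3f", x))
  out <- tibble(
    query_id = records$query_id,
    motif_id = records$motif_id,
    motif_ec = records$motif_ec,
    levenshtein = as.character(records$levenshtein),
    rmsd_all = fmt(records$rmsd_all),
    rmsd_ca = fmt(records$rmsd_ca),
    rmsd_ca_cb = fmt(records$rmsd_ca_cb),
    n_substitutions = as.character(records$n_substitutions),
    n_unmatched = as.character(records$n_unmatched),
    residues = records$residues
  )
  lines <- c(paste(results_header, collapse = ","),
             do.call(paste, c(unname(as.list(out)), sep = ",")))
  if (nrow(out) == 0) lines <- lines[1]
  writeLines(lines, path)
  invisible(path)
}

#' Read a batch results CSV back into a tibble
#'
#' @param path CSV written by [write_results()].
#' @return A `sitemotif_results` tibble (RMSDs at the file's 3-decimal
#'   precision).
#' @export
read_results <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    query_id = readr::col_character(), motif_id = readr::col_character(),
    motif_ec = readr::col_character(), levenshtein = readr::col_integer(),
    rmsd_all = readr::col_double(), rmsd_ca = readr::col_double(),
    rmsd_ca_cb = readr::col_double(),
    n_substitutions = readr::col_integer(),
    n_unmatched = readr::col_integer(),
    residues = readr::col_character()))
  out$motif_ec[is.na(out$motif_ec)] <- ""
  class(out) <- c("sitemotif_results", "sitemotif_scores",
                  class(tibble()))
  out
}

#' Depth of agreement between two EC numbers
#'
#' Counts the leading Enzyme Commission components equal level-wise; a
#' wildcard component (`-` or `*`) or the end of either string stops the
#' count. Used to reproduce true-positive accounting where a hit counts
#' when the query shares the motif's full EC number (level 4) or only its
#' first three levels.
#'
#' @param motif_ec,query_ec Dotted EC strings (1-4 levels; may be empty).
#' @return Integer 0-4.
#' @examples
#' ec_match_level("3.4.21.4", "3.4.21.4")  # 4
#' ec_match_level("3.4.21.4", "3.4.21.5")  # 3
#' @export
ec_match_level <- function(motif_ec, query_ec) {
  split_ec <- function(x) {
    if (is.na(x) || !nzchar(x)) return(character(0))
    strsplit(x, ".", fixed = TRUE)[[1]]
  }
  a <- split_ec(motif_ec)
  b <- split_ec(query_ec)
  level <- 0L
  for (i in seq_len(min(length(a), length(b), 4L))) {
    if (a[i] %in% c("-", "*") || b[i] %in% c("-", "*")) break
    if (a[i] != b[i]) break
    level <- level + 1L
  }
  level
}
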