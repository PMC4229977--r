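# small library on disk: two P motifs from distinct fixtures + one U motif
make_demo_library <- function(dir) {
  fx1 <- synth_structure(n_decoys = 8, seed = 101, struct_id = "qa")
  fx2 <- synth_structure(n_decoys = 8, seed = 102, struct_id = "qb")
  m1 <- build_motif(fx1$structure, fx1$site_specs, motif_id = "p_one",
                    ec_number = "3.4.21.4", set_label = "P")
  m2 <- build_motif(fx2$structure, fx2$site_specs, motif_id = "p_two",
                    ec_number = "3.4.21.26", set_label = "P")
  mu <- build_motif(fx1$structure, fx1$site_specs, motif_id = "u_one",
                    ec_number = "", set_label = "U")
  write_motif(m1, file.path(dir, "P_p_one.motif.yaml"))
  write_motif(m2, file.path(dir, "P_p_two.motif.yaml"))
  write_motif(mu, file.path(dir, "U_u_one.motif.yaml"))
  list(fx1 = fx1, fx2 = fx2)
}

test_that("library loading filters by set and survives corrupt files", {
  dir <- withr::local_tempdir()
  make_demo_library(dir)
  writeLines("this is: [not, a, motif", file.path(dir, "broken.yaml"))

  expect_warning(lib_p <- load_library(dir, sets = "P"), "skipping")
  expect_length(lib_p$motifs, 2)
  expect_setequal(names(lib_p$motifs), c("p_one", "p_two"))

  lib_all <- suppressWarnings(load_library(dir))
  expect_length(lib_all$motifs, 3)
  td <- tidy(lib_all)
  expect_equal(nrow(td), 3)

  expect_error(suppressWarnings(load_library(dir, sets = "J")),
               "no readable motif files")
  expect_error(load_library(file.path(dir, "missing")), "not found")
})

test_that("duplicate motif ids across files are fatal and name both files", {
  dir <- withr::local_tempdir()
  fx <- synth_structure(n_decoys = 5, seed = 103)
  m <- build_motif(fx$structure, fx$site_specs, motif_id = "dup",
                   set_label = "P")
  write_motif(m, file.path(dir, "a.motif.yaml"))
  write_motif(m, file.path(dir, "b.motif.yaml"))
  expect_error(load_library(dir), "dup.*a\\.motif\\.yaml.*b\\.motif\\.yaml")
})

test_that("batch search crosses structures with motifs and flattens records", {
  dir <- withr::local_tempdir()
  fxs <- make_demo_library(dir)
  lib <- suppressWarnings(load_library(dir, sets = "P"))
  res <- batch_search(list(fxs$fx1$structure, fxs$fx2$structure), lib)
  # each structure's planted site matches its own motif; the two sites
  # have independent random geometry, so cross matches are possible only
  # within tolerance -- require at least the two self hits, and check
  # the record set against per-pair searches
  expected <- 0
  for (s in list(fxs$fx1$structure, fxs$fx2$structure)) {
    for (m in lib$motifs) {
      expected <- expected + nrow(find_matches(m, s))
    }
  }
  expect_equal(nrow(res), expected)
  expect_gte(nrow(res), 2)
  expect_true(all(c("qa p_one", "qb p_two") %in%
                    paste(res$query_id, res$motif_id)))
  log <- attr(res, "run_log")
  expect_equal(log$status, c("ok", "ok"))
  expect_equal(res$query_id, sort(res$query_id))
})

test_that("RMSD columns are optional and empty when switched off", {
  fx <- synth_structure(n_decoys = 6, seed = 104, struct_id = "q1")
  m <- build_motif(fx$structure, fx$site_specs, motif_id = "m1")
  res <- batch_search(fx$structure, m, compute_rmsd = FALSE)
  expect_equal(nrow(res), 1)
  expect_true(is.na(res$rmsd_all) && is.na(res$rmsd_ca))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(res, path)
  row <- strsplit(readLines(path)[2], ",")[[1]]
  expect_equal(row[5:7], c("", "", ""))
})

test_that("a structure with no matches yields no records but a log entry", {
  fx <- synth_structure(n_decoys = 6, seed = 105, struct_id = "qhit")
  m <- build_motif(fx$structure, fx$site_specs, motif_id = "m1")
  empty <- synth_structure(n_decoys = 6, sites = character(0),
                           decoy_types = c("GLY", "ALA"), seed = 106,
                           struct_id = "qmiss")
  res <- batch_search(list(fx$structure, empty$structure), m)
  expect_equal(unique(res$query_id), "qhit")
  log <- attr(res, "run_log")
  expect_equal(log$n_matches[log$query_id == "qmiss"], 0L)
})

test_that("results CSV round-trips at its printed precision", {
  fx <- synth_structure(n_decoys = 6, seed = 107, struct_id = "q1")
  m <- build_motif(fx$structure, fx$site_specs, motif_id = "m1",
                   ec_number = "1.1.1.1")
  res <- batch_search(fx$structure, m)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(res, path)
  lines <- readLines(path)
  expect_length(lines, nrow(res) + 1)
  expect_equal(lines[1], paste("query_id,motif_id,motif_ec,levenshtein",
                               "rmsd_all,rmsd_ca,rmsd_ca_cb",
                               "n_substitutions,n_unmatched,residues",
                               sep = ","))
  back <- read_results(path)
  expect_equal(back$query_id, res$query_id)
  expect_equal(back$levenshtein, res$levenshtein)
  expect_equal(back$rmsd_all, round(res$rmsd_all, 3))
  expect_equal(back$residues, res$residues)

  # empty record set -> header-only file
  write_results(res[0, ], path)
  expect_length(readLines(path), 1)
})

test_that("identical batch runs write byte-identical CSVs", {
  dir <- withr::local_tempdir()
  fxs <- make_demo_library(dir)
  lib <- suppressWarnings(load_library(dir, sets = "P"))
  p1 <- file.path(dir, "r1.csv")
  p2 <- file.path(dir, "r2.csv")
  write_results(batch_search(list(fxs$fx1$structure, fxs$fx2$structure),
                             lib), p1)
  write_results(batch_search(list(fxs$fx1$structure, fxs$fx2$structure),
                             lib), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("EC agreement depth is counted level-wise with wildcards", {
  expect_equal(ec_match_level("3.4.21.4", "3.4.21.4"), 4L)
  expect_equal(ec_match_level("3.4.21.4", "3.4.21.5"), 3L)
  expect_equal(ec_match_level("1.1.1.8", "2.1.1.8"), 0L)
  expect_equal(ec_match_level("3.4.21.-", "3.4.21.4"), 3L)
  expect_equal(ec_match_level("3.4", "3.4.21.4"), 2L)
  expect_equal(ec_match_level("", "3.4.21.4"), 0L)
})
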