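test_that("effective cutoff adds tolerance then applies precision", {
  expect_equal(effective_cutoff(5.0, 2.0, 1.0), 7.0)
  expect_equal(effective_cutoff(5.0, 0.0, 1.0), 5.0)
  expect_equal(effective_cutoff(5.0, 2.0, 0.5), 3.5)
  expect_error(effective_cutoff(5.0, 2.0, 0), "positive")
  expect_error(effective_cutoff(5.0, 2.0, -1), "positive")
})

test_that("a clean planted triad yields exactly one perfect match", {
  fx <- synth_structure(n_decoys = 40, seed = 1)
  m <- triad_motif_from(fx)
  q <- read_pdb(fx$pdb)
  hits <- find_matches(m, q)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$n_substitutions, 0L)
  expect_equal(hits$n_unmatched, 0L)
  a <- hits$assignment[[1]]
  expect_equal(sort(a$seq_id), sort(fx$site_specs$seq_id))
  expect_equal(match_sets(brute_force_matches(m, q)), match_sets(hits))
})

test_that("displacing the aspartate far beyond tolerance kills the match", {
  fx <- synth_structure(n_decoys = 20, seed = 2)
  m <- triad_motif_from(fx)
  asp_seq <- fx$site_specs$seq_id[fx$site_specs$res_name == "ASP"]
  his_seq <- fx$site_specs$seq_id[fx$site_specs$res_name == "HIS"]
  atoms <- tibble::as_tibble(fx$structure)
  # push the whole aspartate 3x tolerance straight away from the
  # histidine, so its hydrogen-bond-range constraints cannot survive
  asp <- atoms$seq_id == asp_seq
  his <- atoms$seq_id == his_seq
  u <- c(mean(atoms$x[asp]) - mean(atoms$x[his]),
         mean(atoms$y[asp]) - mean(atoms$y[his]),
         mean(atoms$z[asp]) - mean(atoms$z[his]))
  u <- u / sqrt(sum(u^2)) * 3 * m$tolerance
  atoms$x[asp] <- atoms$x[asp] + u[1]
  atoms$y[asp] <- atoms$y[asp] + u[2]
  atoms$z[asp] <- atoms$z[asp] + u[3]
  broken <- new_structure(atoms, struct_id = "broken")
  expect_equal(nrow(find_matches(m, broken)), 0)
  expect_equal(nrow(brute_force_matches(m, broken)), 0)
})

test_that("two independently planted triads give two matches", {
  fx <- synth_structure(sites = c("triad", "triad"), n_decoys = 20,
                        seed = 3)
  m <- build_motif(fx$structure, fx$all_site_specs[[1]])
  hits <- find_matches(m, fx$structure)
  expect_equal(nrow(hits), 2)
  expect_equal(match_sets(brute_force_matches(m, fx$structure)),
               match_sets(hits))
})

test_that("search equals the brute-force oracle across fixtures and options", {
  for (seed in 0:24) {
    fx <- oracle_fixture(seed)
    m <- triad_motif_from(fx)
    for (p in c(0.8, 1.0, 1.2)) {
      for (mu in 0:1) {
        opt <- search_options(precision = p, max_unmatched = mu)
        expect_equal(
          match_sets(find_matches(m, fx$structure, opt)),
          match_sets(brute_force_matches(m, fx$structure, opt)),
          info = sprintf("seed=%d precision=%.1f max_unmatched=%d",
                         seed, p, mu))
      }
    }
  }
})

test_that("match sets grow monotonically with precision and tolerance", {
  for (seed in c(0, 5, 9, 13, 17)) {
    fx <- oracle_fixture(seed)
    m <- triad_motif_from(fx)
    sets_by_p <- purrr::map(c(0.8, 1.0, 1.2), function(p) {
      match_sets(find_matches(m, fx$structure,
                              search_options(precision = p)))
    })
    expect_true(all(sets_by_p[[1]] %in% sets_by_p[[2]]))
    expect_true(all(sets_by_p[[2]] %in% sets_by_p[[3]]))
    sets_by_t <- purrr::map(c(1.0, 2.0, 3.0), function(tol) {
      mt <- triad_motif_from(fx, tolerance = tol)
      match_sets(find_matches(mt, fx$structure))
    })
    expect_true(all(sets_by_t[[1]] %in% sets_by_t[[2]]))
    expect_true(all(sets_by_t[[2]] %in% sets_by_t[[3]]))
  }
})

test_that("the match set is invariant under rigid motion of the query", {
  fx <- oracle_fixture(7)
  m <- triad_motif_from(fx)
  before <- find_matches(m, fx$structure)
  moved <- transform_structure(fx$structure, random_rotation(41),
                               c(-30, 8, 55))
  after <- find_matches(m, moved)
  expect_equal(match_sets(before), match_sets(after))
  expect_gt(nrow(before), 0)
})

test_that("substitution groups admit cysteine in a serine slot", {
  fx <- synth_structure(n_decoys = 15, seed = 6)
  m <- triad_motif_from(fx)
  # mutate the planted serine to cysteine in place (OG -> SG)
  atoms <- tibble::as_tibble(fx$structure)
  ser_seq <- fx$site_specs$seq_id[fx$site_specs$res_name == "SER"]
  sel <- atoms$seq_id == ser_seq
  atoms$res_name[sel] <- "CYS"
  atoms$atom[sel & atoms$atom == "OG"] <- "SG"
  mutant <- new_structure(atoms, struct_id = "mutant")

  expect_equal(nrow(find_matches(m, mutant)), 0)  # strict typing
  hits <- find_matches(m, mutant,
                       search_options(substitution_groups = TRUE))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$n_substitutions, 1L)
  expect_equal(match_string(m, hits$assignment[[1]]), "CHD")
  expect_equal(levenshtein(motif_string(m),
                           match_string(m, hits$assignment[[1]])), 1L)
  # oracle agrees under substitutions as well
  expect_equal(match_sets(brute_force_matches(
    m, mutant, search_options(substitution_groups = TRUE))),
    match_sets(hits))
})

test_that("one unmatched slot recovers a site with a deleted residue", {
  fx <- synth_structure(n_decoys = 15, seed = 8)
  m <- triad_motif_from(fx)
  asp_seq <- fx$site_specs$seq_id[fx$site_specs$res_name == "ASP"]
  pruned <- new_structure(
    dplyr::filter(tibble::as_tibble(fx$structure), seq_id != asp_seq),
    struct_id = "pruned")
  expect_equal(nrow(find_matches(m, pruned)), 0)
  hits <- find_matches(m, pruned, search_options(max_unmatched = 1))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$n_unmatched, 1L)
  a <- hits$assignment[[1]]
  expect_true(a$unmatched[a$slot == 2])
  expect_equal(levenshtein(motif_string(m), match_string(m, a)), 1L)
})

test_that("imperfect matches contained in a perfect match are suppressed", {
  fx <- synth_structure(n_decoys = 10, seed = 9)
  m <- triad_motif_from(fx)
  hits <- find_matches(m, fx$structure, search_options(max_unmatched = 1))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$n_unmatched, 0L)
})

test_that("slot permutation leaves the match set unchanged", {
  fx <- oracle_fixture(12)
  m <- triad_motif_from(fx)
  m_perm <- build_motif(fx$structure, fx$site_specs[c(2, 3, 1), ])
  expect_equal(match_sets(find_matches(m, fx$structure)),
               match_sets(find_matches(m_perm, fx$structure)))
})

test_that("the brute-force oracle refuses oversized queries", {
  fx <- synth_structure(n_decoys = 90, seed = 10)
  m <- triad_motif_from(fx)
  expect_error(brute_force_matches(m, fx$structure), "80 residues")
})
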