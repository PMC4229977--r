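test_that("edit distance matches the worked catalytic-site examples", {
  expect_equal(levenshtein("HSE", "HSE"), 0L)
  expect_equal(levenshtein("HSE", "HCE"), 1L)  # Cys replacing Ser
  expect_equal(levenshtein("", "HSE"), 3L)
  expect_equal(levenshtein("HSE", ""), 3L)
  expect_equal(levenshtein("", ""), 0L)
})

test_that("edit distance agrees with independent oracles and is a metric", {
  alphabet <- c("H", "S", "D", "E", "C", "K")
  rand_str <- function() {
    paste(sample(alphabet, sample(0:7, 1), replace = TRUE),
          collapse = "")
  }
  withr::with_seed(42, {
    for (i in 1:40) {
      a <- rand_str(); b <- rand_str(); c <- rand_str()
      d_ab <- levenshtein(a, b)
      expect_equal(d_ab, lev_naive(a, b), info = paste(a, b))
      expect_equal(d_ab,
                   as.integer(utils::adist(a, b)), info = paste(a, b))
      expect_equal(d_ab, levenshtein(b, a))                  # symmetry
      expect_equal(levenshtein(a, a), 0L)                    # identity
      expect_lte(d_ab, levenshtein(a, c) + levenshtein(c, b))# triangle
    }
  })
})

test_that("match strings transcribe assignments in slot order", {
  fx <- synth_structure(n_decoys = 8, seed = 14)
  m <- triad_motif_from(fx)
  hits <- find_matches(m, fx$structure)
  expect_equal(motif_string(m), "SHD")
  expect_equal(match_string(m, hits$assignment[[1]]), "SHD")
  # an unmatched slot is simply omitted -> one deletion
  a <- hits$assignment[[1]]
  a$unmatched[2] <- TRUE
  expect_equal(match_string(m, a), "SD")
  expect_equal(levenshtein(motif_string(m), match_string(m, a)), 1L)
})

test_that("Kabsch superposition recovers rigid motions exactly", {
  withr::with_seed(2, {
    p <- matrix(rnorm(24), 8, 3)
  })
  expect_equal(superpose(p, p)$rmsd, 0)
  moved <- p %*% t(random_rotation(5)) +
    matrix(rep(c(4, -2, 9), each = 8), 8, 3)
  fit <- superpose(p, moved)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # fitted coordinates land on the reference
  back <- moved %*% t(fit$rotation) +
    matrix(rep(fit$translation, each = 8), 8, 3)
  expect_lt(max(abs(back - p)), 1e-8)
  expect_error(superpose(p, p[1:3, ]), "equal size")
})

test_that("SVD superposition agrees with the quaternion closed form", {
  for (seed in 0:9) {
    withr::with_seed(seed, {
      ref <- matrix(rnorm(15), 5, 3)
      mov <- matrix(rnorm(15), 5, 3)
    })
    expect_equal(superpose(ref, mov)$rmsd, horn_rmsd(ref, mov),
                 tolerance = 1e-6, info = paste("seed", seed))
  }
})

test_that("a self-match scores zero in every mode; RMSD survives rigid motion", {
  fx <- synth_structure(n_decoys = 8, seed = 15)
  specs <- fx$site_specs
  specs$include_backbone <- TRUE  # so the CA mode is defined
  m <- build_motif(fx$structure, specs)
  hits <- find_matches(m, fx$structure)
  expect_equal(nrow(hits), 1)
  a <- hits$assignment[[1]]
  for (mode in c("all", "ca", "ca_cb")) {
    expect_lt(match_rmsd(m, a, fx$structure, mode), 1e-6)
  }
  moved <- transform_structure(fx$structure, random_rotation(33),
                               c(7, 7, -7))
  for (mode in c("all", "ca", "ca_cb")) {
    expect_lt(match_rmsd(m, a, moved, mode), 1e-6)
  }
})

test_that("the CA mode is undefined for side-chain-only motifs", {
  fx <- synth_structure(n_decoys = 5, seed = 16)
  m <- triad_motif_from(fx)
  hits <- find_matches(m, fx$structure)
  a <- hits$assignment[[1]]
  expect_true(is.na(match_rmsd(m, a, fx$structure, "ca")))
  expect_false(is.na(match_rmsd(m, a, fx$structure, "ca_cb")))  # CB only
})

test_that("all-atom RMSD under 0.1 A coordinate noise stays in the expected band", {
  fx <- synth_structure(n_decoys = 0, seed = 17)
  m <- triad_motif_from(fx)
  hits <- find_matches(m, fx$structure)
  a <- hits$assignment[[1]]
  rmsds <- purrr::map_dbl(1:100, function(s) {
    noisy <- perturb_structure(fx$structure, 0.1, seed = 9000 + s)
    match_rmsd(m, a, noisy, "all")
  })
  expect_true(all(rmsds >= 0.05 & rmsds <= 0.35))
})

test_that("chemically equivalent atom labelings cannot inflate the RMSD", {
  fx <- synth_structure(n_decoys = 5, seed = 18)
  m <- triad_motif_from(fx)
  # swap the OD1/OD2 labels on the planted aspartate in the query
  atoms <- tibble::as_tibble(fx$structure)
  asp_seq <- fx$site_specs$seq_id[fx$site_specs$res_name == "ASP"]
  i1 <- which(atoms$seq_id == asp_seq & atoms$atom == "OD1")
  i2 <- which(atoms$seq_id == asp_seq & atoms$atom == "OD2")
  atoms$atom[c(i1, i2)] <- c("OD2", "OD1")
  swapped <- new_structure(atoms, struct_id = "swapped")
  hits <- find_matches(m, swapped)
  expect_equal(nrow(hits), 1)
  expect_lt(match_rmsd(m, hits$assignment[[1]], swapped, "all"), 1e-6)
})

test_that("glycine contributes a single pair in the CA+CB mode", {
  gfx <- synth_structure(n_decoys = 6,
                         decoy_types = c("GLY", "ALA", "LEU"), seed = 19)
  res <- residues(gfx$structure)
  gly <- res[res$res_name == "GLY", ][1, ]
  specs <- dplyr::bind_rows(gfx$site_specs[1:2, ],
                            residue_spec("GLY", gly$seq_id, gly$chain,
                                         include_backbone = TRUE))
  specs$include_backbone <- TRUE
  m <- build_motif(gfx$structure, specs)
  hits <- find_matches(m, gfx$structure)
  expect_gte(nrow(hits), 1)
  a <- hits$assignment[[1]]
  corr <- sitemotif:::match_correspondence(
    m, a, sitemotif:::residue_coord_index(gfx$structure), "ca_cb")
  expect_equal(sum(corr$slot == 2), 1)  # CA only for glycine
  expect_equal(sum(corr$slot == 0), 2)  # CA + CB for serine
})

test_that("ranking sorts by Levenshtein, then all-atom RMSD, deterministically", {
  scored <- tibble::tibble(
    levenshtein = c(1L, 0L, 0L, 1L),
    rmsd_all = c(0.2, 1.5, 0.9, NA),
    residue_set = c("d", "b", "a", "c"),
    motif_id = "m", query_id = "q")
  ranked <- rank_matches(scored)
  expect_equal(ranked$residue_set, c("a", "b", "d", "c"))
  expect_equal(nrow(rank_matches(scored[0, ])), 0)
})

test_that("scored matches carry all three RMSD modes and plot", {
  fx <- synth_structure(n_decoys = 8, seed = 20)
  m <- triad_motif_from(fx)
  sc <- score_matches(find_matches(m, fx$structure), m, fx$structure)
  expect_s3_class(sc, "sitemotif_scores")
  expect_equal(sc$levenshtein, 0L)
  expect_lt(sc$rmsd_all, 1e-6)
  expect_lt(sc$rmsd_ca_cb, 1e-6)
  p <- ggplot2::autoplot(sc)
  expect_s3_class(p, "ggplot")
  sc2 <- score_matches(find_matches(m, fx$structure), m, fx$structure,
                       compute_rmsd = FALSE)
  expect_true(is.na(sc2$rmsd_all))
})
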