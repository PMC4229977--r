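# shared fixture builders and independent oracles

# fixture whose decoy pool includes the planted residue types, so search
# candidates are non-trivial (used for oracle-equivalence properties)
oracle_fixture <- function(seed) {
  nd <- withr::with_seed(seed, sample(15L:30L, 1))
  synth_structure(
    n_decoys = nd,
    decoy_types = c("SER", "HIS", "ASP", "GLY", "ALA", "LEU", "GLU",
                    "ASN"),
    seed = seed + 100000L
  )
}

triad_motif_from <- function(fx, tolerance = 2.0, ...) {
  build_motif(fx$structure, fx$site_specs, tolerance = tolerance, ...)
}

# minimal hand-written PDB records
pdb_line <- function(serial, name, res, chain, resno, x, y, z,
                     occ = 1, elem = substr(name, 1, 1), alt = " ",
                     record = "ATOM") {
  sprintf("%-6s%5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, ifelse(nchar(name) < 4, paste0(" ", name),
                                 name),
          alt, res, chain, resno, x, y, z, occ, 0, elem)
}

# naive exponential-time edit distance (independent oracle, lengths <= 7)
lev_naive <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  min(lev_naive(substr(a, 2, nchar(a)), b) + 1L,
      lev_naive(a, substr(b, 2, nchar(b))) + 1L,
      lev_naive(substr(a, 2, nchar(a)), substr(b, 2, nchar(b))) + cost)
}

# Horn's closed-form quaternion solution for the optimal superposition
# RMSD (independent of the SVD route used by superpose())
horn_rmsd <- function(ref, mov) {
  a <- scale(as.matrix(ref), scale = FALSE)
  b <- scale(as.matrix(mov), scale = FALSE)
  s <- t(b) %*% a
  nm <- matrix(0, 4, 4)
  nm[1, ] <- c(s[1, 1] + s[2, 2] + s[3, 3], s[2, 3] - s[3, 2],
               s[3, 1] - s[1, 3], s[1, 2] - s[2, 1])
  nm[2, ] <- c(s[2, 3] - s[3, 2], s[1, 1] - s[2, 2] - s[3, 3],
               s[1, 2] + s[2, 1], s[3, 1] + s[1, 3])
  nm[3, ] <- c(s[3, 1] - s[1, 3], s[1, 2] + s[2, 1],
               -s[1, 1] + s[2, 2] - s[3, 3], s[2, 3] + s[3, 2])
  nm[4, ] <- c(s[1, 2] - s[2, 1], s[3, 1] + s[1, 3],
               s[2, 3] + s[3, 2], -s[1, 1] - s[2, 2] + s[3, 3])
  lambda <- max(eigen(nm, symmetric = TRUE)$values)
  sqrt(max(0, (sum(a^2) + sum(b^2) - 2 * lambda) / nrow(a)))
}

# residue-set representation of a match table, for set comparisons
match_sets <- function(matches) sort(matches$residue_set)
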