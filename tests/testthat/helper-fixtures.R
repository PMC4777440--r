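# Shared builders for the test suite. Toy structures are constructed
# in-memory (no file round-trip) unless the reader path itself is under
# test, in which case makeFixture() PDB files are used.

toy_structure <- function(xyz, chain = rep("A", nrow(xyz)),
                          resid = rep("ALA", nrow(xyz))) {
  n <- nrow(xyz)
  resno <- as.integer(stats::ave(seq_len(n), chain, FUN = seq_along))
  residues <- data.frame(
    chain = chain, resno = resno, insert = "",
    resid = resid, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    key = paste0(chain, ":", resno), stringsAsFactors = FALSE)
  new("CalphaStructure", residues = residues,
      atoms = data.frame(key = character(), elety = character(),
                         x = numeric(), y = numeric(), z = numeric(),
                         stringsAsFactors = FALSE),
      ligands = list(), nModels = 1L)
}

# deterministic compact blob (independent of makeFixture's sampler);
# compact enough that every residue has neighbours within the 11 A
# intensity cutoff
toy_globule <- function(n, seed = 1, spread = 1.8) {
  set.seed(seed)
  xyz <- matrix(stats::rnorm(3 * n, sd = spread * n^(1 / 3)), ncol = 3)
  # push apart any close pairs to avoid coincident residues
  repeat {
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    if (min(d) > 2.5) break
    i <- which(d == min(d), arr.ind = TRUE)[1, ]
    xyz[i[1], ] <- xyz[i[1], ] + stats::rnorm(3, sd = 1)
  }
  xyz
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# full pipeline on a structure + site: returns profile and both mode sets
run_transition <- function(s, site, alpha = 100, nModes = 10, kT = 0.5961,
                           k0 = 1, cutoff = 25, dc = 11) {
  m <- buildHarmonicModel(s, cutoff = cutoff, k0 = k0)
  mb <- applyRestraints(m, site, alpha = alpha)
  free <- computeModes(hessianMatrix(m), nModes = nModes)
  bound <- computeModes(hessianMatrix(mb), nModes = nModes)
  ef <- residueIntensities(free, s, dc = dc)
  eb <- residueIntensities(bound, s, dc = dc)
  list(profile = allostericFreeEnergy(ef, eb, kT = kT),
       free = free, bound = bound, epsFree = ef, epsBound = eb,
       model = m, modelBound = mb)
}

# site made of the first k residues of a structure
head_site <- function(s, k, name = "SITE") {
  bindingSite(name, residueKeys(s)[seq_len(k)], s)
}

write_pdb_text <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(lines, file)
  file
}

pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          occ = 1, b = 0, type = "ATOM", alt = " ",
                          elesy = "C") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, paste0(" ", elety), alt, resid, chain, resno,
          x, y, z, occ, b, elesy)
}
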