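test_that("PDB read-back preserves residues, order and coordinates", {
  lines <- c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 1.25, -2.5, 0.125),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 4.75, 0.0, 1.5),
    pdb_atom_line(3, "CA", "VAL", "A", 3, 8.0, 2.25, -1.0),
    "END")
  f <- write_pdb_text(lines)
  s <- readCalphaStructure(f)
  expect_equal(nResidues(s), 3L)
  expect_equal(residueTable(s)$resid, c("ALA", "GLY", "VAL"))
  expect_equal(unname(coordMatrix(s)[, 1]), c(1.25, 4.75, 8.0))
  expect_equal(unname(coordMatrix(s)[2, ]), c(4.75, 0.0, 1.5))
  # reading the same file twice is bitwise identical
  expect_identical(s, readCalphaStructure(f))
})

test_that("multi-model policies select or average NMR bundle conformers", {
  lines <- c(
    "MODEL        1",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 3.8, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 2, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 5.8, 2, 0),
    "ENDMDL", "END")
  f <- write_pdb_text(lines)
  s_first <- readCalphaStructure(f, modelPolicy = "first")
  s_mean <- readCalphaStructure(f, modelPolicy = "mean")
  s_2 <- readCalphaStructure(f, modelPolicy = 2)
  expect_equal(s_mean@nModels, 2L)
  expect_equal(unname(coordMatrix(s_first)[1, ]), c(0, 0, 0))
  expect_equal(unname(coordMatrix(s_2)[1, ]), c(2, 0, 0))
  # mean conformer is the per-atom arithmetic mean
  expect_equal(unname(coordMatrix(s_mean)[1, ]), c(1, 0, 0),
               tolerance = 1e-9)
  expect_equal(unname(coordMatrix(s_mean)[2, ]), c(4.8, 1, 0),
               tolerance = 1e-9)
  expect_error(readCalphaStructure(f, modelPolicy = 3), "out of range")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  lines <- c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
    pdb_atom_line(3, "CA", "ALA", "A", 2, 3.8, 0, 0),
    "END")
  s <- readCalphaStructure(write_pdb_text(lines))
  expect_equal(nResidues(s), 2L)
  expect_equal(unname(coordMatrix(s)[1, ]), c(9, 9, 9))
})

test_that("ligand-contact detection follows the distance rule and is monotone in cutoff", {
  # C-alpha-only record: effective cutoff is contactCutoff + 3 A
  lines <- c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 3, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 20, 0, 0),
    pdb_atom_line(3, "C1", "LIG", "X", 901, 0, 0, 0, type = "HETATM"),
    "END")
  s <- readCalphaStructure(write_pdb_text(lines))
  expect_equal(ligandIds(s), "X:LIG:901")
  site <- detectBindingSite(s, "X:LIG:901", contactCutoff = 4.5)
  expect_equal(siteMembers(site), "A:1")
  expect_equal(site@source, "ligand-contact")
  expect_error(detectBindingSite(s, "Y:FOO:1"), "ligand not found")

  # degenerate cutoff with nothing that close -> empty-site error
  far <- c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 20, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 25, 0, 0),
    pdb_atom_line(3, "C1", "LIG", "X", 901, 0, 0, 0, type = "HETATM"),
    "END")
  s_far <- readCalphaStructure(write_pdb_text(far))
  expect_error(detectBindingSite(s_far, "X:LIG:901", contactCutoff = 0.1),
               "empty site")

  # monotone membership on a realistic fixture
  fx <- makeFixture("random_globule", nResidues = 30, seed = 7,
                    dir = tempdir(), plantLigand = TRUE)
  sg <- readCalphaStructure(fx$structureFile)
  cuts <- c(2, 4.5, 8, 15)
  members <- lapply(cuts, function(cc)
    siteMembers(detectBindingSite(sg, fx$manifest$ligandId,
                                  contactCutoff = cc)))
  for (i in seq_len(length(cuts) - 1))
    expect_true(all(members[[i]] %in% members[[i + 1]]))
})

test_that("fixture round-trip matches the generator manifest", {
  for (kind in c("random_globule", "two_domain_hinge")) {
    fx <- makeFixture(kind, nResidues = 40, seed = 3, dir = tempdir(),
                      plantLigand = TRUE)
    s <- readCalphaStructure(fx$structureFile)
    expect_equal(nResidues(s), fx$manifest$nResidues)
    expect_equal(residueKeys(s), unlist(fx$manifest$residueKeys))
    site <- detectBindingSite(s, fx$manifest$ligandId)
    expect_setequal(siteMembers(site),
                    unlist(fx$manifest$plantedContacts))
  }
})

test_that("homologous chains are grouped and put in correspondence", {
  # identical homodimer -> one group, identity correspondence
  fx <- makeFixture("symmetric_dimer", nResidues = 40, seed = 2,
                    dir = tempdir())
  s <- readCalphaStructure(fx$structureFile)
  g <- groupHomologousChains(s)
  expect_length(chainGroupList(g), 1L)
  expect_setequal(chainGroupList(g)[[1]], c("A", "B"))
  corr <- g@correspondence[[1]]
  expect_equal(nrow(corr), 20L)
  expect_equal(corr[, "A"], paste0("A:", 1:20))
  expect_equal(corr[, "B"], paste0("B:", 1:20))

  # hetero assembly: A=B and C=D with different sequences -> two groups
  seqs <- strsplit(c("MKVLAAGHTRWE", "AQNNFDYCEPLI"), "")
  xyz <- toy_globule(48, seed = 5)
  chains <- rep(c("A", "B", "C", "D"), each = 12)
  resid <- bio3d::aa123(c(seqs[[1]], seqs[[1]], seqs[[2]], seqs[[2]]))
  sh <- toy_structure(xyz, chain = chains, resid = resid)
  gh <- groupHomologousChains(sh)
  grp <- chainGroupList(gh)
  expect_length(grp, 2L)
  expect_setequal(grp[[which(vapply(grp, function(g) "A" %in% g, TRUE))]],
                  c("A", "B"))
  expect_setequal(grp[[which(vapply(grp, function(g) "C" %in% g, TRUE))]],
                  c("C", "D"))
})

test_that("correspondence skips an internal deletion", {
  seqA <- strsplit("MKVLAAGHTRWEDPQSFYIN", "")[[1]]  # 20 residues
  seqB <- seqA[-10]                                  # internal deletion
  xyz <- toy_globule(39, seed = 11)
  sh <- toy_structure(xyz, chain = rep(c("A", "B"), c(20, 19)),
                      resid = bio3d::aa123(c(seqA, seqB)))
  g <- groupHomologousChains(sh, identityThreshold = 90)
  expect_length(chainGroupList(g), 1L)
  corr <- g@correspondence[[1]]
  expect_equal(nrow(corr), 19L)   # aligned length = |A| - 1
  # matched positions carry the same residue type in both chains
  rt <- residueTable(sh)
  nameof <- function(k) rt$resid[match(k, rt$key)]
  expect_equal(nameof(corr[, "A"]), nameof(corr[, "B"]))
  # position 10 of chain A (the deleted one) is absent from the mapping
  expect_false("A:10" %in% corr[, "A"])
})
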