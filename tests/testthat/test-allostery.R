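fake_modeset <- function(vectors, keys) {
  v <- as.matrix(vectors)
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  new("ModeSet", values = seq_len(ncol(v)), vectors = v,
      nRigidRemoved = 6L, residueKeys = keys)
}

fake_intensity <- function(eps, keys, c = 1, dc = 11) {
  new("IntensityTable", eps = matrix(eps, ncol = length(keys),
                                     dimnames = list(NULL, keys)),
      residueKeys = keys, zeroNeighbor = rep(FALSE, length(keys)),
      c = c, dc = dc, nModes = as.integer(length(eps) / length(keys)))
}

test_that("residue intensities measure relative neighbour motion", {
  # a pure translation deforms nothing: eps = 0 everywhere
  s <- toy_structure(toy_globule(10, seed = 13))
  tv <- rep(c(1, 0, 0), 10)
  ms <- fake_modeset(tv, residueKeys(s))
  eps <- intensityMatrix(residueIntensities(ms, s))
  expect_equal(max(abs(eps)), 0)

  # two residues 5 A apart, opposite unit displacements: eps = 2c each
  s2 <- toy_structure(rbind(c(0, 0, 0), c(5, 0, 0)))
  v <- c(1, 0, 0, -1, 0, 0) / sqrt(2)
  ms2 <- fake_modeset(v, residueKeys(s2))
  for (cc in c(1, 3.5)) {
    eps2 <- intensityMatrix(residueIntensities(ms2, s2, c = cc))
    expect_equal(unname(eps2[1, ]), c(2 * cc, 2 * cc), tolerance = 1e-12)
  }

  # residues beyond dc from everyone are flagged zero-neighbour
  s3 <- toy_structure(rbind(c(0, 0, 0), c(5, 0, 0), c(100, 0, 0)))
  ms3 <- fake_modeset(stats::rnorm(9), residueKeys(s3))
  it3 <- residueIntensities(ms3, s3, dc = 11)
  expect_equal(it3@zeroNeighbor, c(FALSE, FALSE, TRUE))
  expect_equal(unname(intensityMatrix(it3)[, 3]), 0)

  # vectorized result equals the naive double-loop oracle
  s20 <- toy_structure(toy_globule(20, seed = 14))
  H <- hessianMatrix(buildHarmonicModel(s20))
  md <- computeModes(H, nModes = 5)
  expect_lt(max(abs(intensityMatrix(residueIntensities(md, s20)) -
                      oracleIntensity(md, s20))), 1e-10)
})

test_that("the displacement normalisation in the two-residue example is consistent", {
  # |e_1 - e_2|^2 = (2/sqrt(2))^2 = 2 for the antisymmetric unit mode
  v <- c(1, 0, 0, -1, 0, 0) / sqrt(2)
  expect_equal(sum((v[1:3] - v[4:6])^2), 2)
})

test_that("allosteric free energy is the log-ratio of intensities", {
  keys <- c("A:1", "A:2")
  # bound == free -> dg identically zero
  f <- fake_intensity(c(0.3, 0.7), keys)
  expect_equal(unname(profileValues(allostericFreeEnergy(f, f))),
               c(0, 0))
  # single mode with eps_bound = e^2 * eps_free -> dg = kT
  b <- fake_intensity(exp(2) * c(0.3, 0.7), keys)
  p <- allostericFreeEnergy(f, b, kT = 0.5961)
  expect_equal(unname(profileValues(p)), c(0.5961, 0.5961),
               tolerance = 1e-12)
  expect_error(allostericFreeEnergy(f, fake_intensity(1, "A:9")),
               "residue set")
})

test_that("per-residue free energies match the partition-function oracle", {
  s <- toy_structure(toy_globule(12, seed = 15))
  tr <- run_transition(s, head_site(s, 3), alpha = 100, nModes = 4)
  kT <- 0.5961
  ef <- intensityMatrix(tr$epsFree)
  eb <- intensityMatrix(tr$epsBound)
  dg_oracle <- vapply(seq_len(ncol(ef)), function(i) {
    zf <- oraclePartition(ef[, i], kT)
    zb <- oraclePartition(eb[, i], kT)
    -kT * log(zb / zf)
  }, numeric(1))
  expect_equal(unname(profileValues(tr$profile)), dg_oracle,
               tolerance = 1e-6)
  # quadrature agrees with the closed Gaussian form per mode
  expect_equal(oraclePartition(2 * pi * kT, kT), 1, tolerance = 1e-6)
  eps_row <- ef[, 1]
  expect_equal(oraclePartition(eps_row, kT),
               prod(sqrt(2 * pi * kT / eps_row)), tolerance = 1e-6)
})

test_that("alpha = 0 gives an identically zero profile through the pipeline", {
  s <- toy_structure(toy_globule(15, seed = 16))
  tr <- run_transition(s, head_site(s, 4), alpha = 0)
  expect_equal(max(abs(profileValues(tr$profile))), 0, tolerance = 1e-10)
  expect_equal(globalFreeEnergy(tr$free, tr$bound), 0, tolerance = 1e-10)
})

test_that("modulation free energy distinguishes its two formulas", {
  s <- toy_structure(toy_globule(16, seed = 17))
  sA <- bindingSite("A", residueKeys(s)[1:3], s)
  sB <- bindingSite("B", residueKeys(s)[12:14], s)
  m <- buildHarmonicModel(s)
  mk <- function(sites) {
    md <- computeModes(hessianMatrix(
      if (length(sites)) applyRestraints(m, sites, alpha = 100) else m),
      nModes = 10)
    residueIntensities(md, s)
  }
  e0 <- mk(list()); eA <- mk(list(sA)); eAB <- mk(list(sA, sB))

  # m-system == n-system -> zero
  z <- modulationFreeEnergy(e0, eA, eA)
  expect_equal(max(abs(profileValues(z))), 0, tolerance = 1e-12)

  # difference formula is exactly dg(0->n) - dg(0->m)
  dd <- modulationFreeEnergy(e0, eA, eAB)
  dgA <- profileValues(allostericFreeEnergy(e0, eA))
  dgAB <- profileValues(allostericFreeEnergy(e0, eAB))
  expect_equal(profileValues(dd), dgAB - dgA, tolerance = 1e-12)

  # literal log-ratio formula differs by a second free->m term
  dd_lr <- modulationFreeEnergy(e0, eA, eAB, formula = "logratio")
  expect_equal(profileValues(dd_lr), dgAB - 2 * dgA, tolerance = 1e-10)

  # site-level sign agrees with brute-force recomputed profiles
  ddB <- mean(profileValues(dd)[siteMembers(sB)])
  brute <- mean((dgAB - dgA)[siteMembers(sB)])
  expect_equal(sign(ddB), sign(brute))
})

test_that("site and protein averages behave as arithmetic means", {
  keys <- paste0("A:", 1:4)
  p <- new("AllostericProfile",
           dg = stats::setNames(c(1, -1, 2, 4), keys),
           label = "t", kT = 0.5961, nModes = 10L, flags = character())
  site <- new("BindingSite", name = "s", members = keys[1:2],
              source = "explicit", detectionMode = "")
  expect_equal(siteFreeEnergy(p, site), 0)
  all_site <- new("BindingSite", name = "all", members = keys,
                  source = "explicit", detectionMode = "")
  expect_equal(siteFreeEnergy(p, all_site), proteinFreeEnergy(p),
               tolerance = 1e-12)
  p@dg[1] <- NA_real_
  expect_error(siteFreeEnergy(p, site), "undefined")
  expect_equal(proteinFreeEnergy(p), mean(c(-1, 2, 4)))
})

test_that("global free energy follows the eigenvalue spectra", {
  s <- toy_structure(toy_globule(14, seed = 18))
  tr <- run_transition(s, head_site(s, 4), alpha = 100, nModes = 8)
  expect_equal(globalFreeEnergy(tr$free, tr$free), 0)
  gd <- globalFreeEnergy(tr$free, tr$bound, kT = 0.5961)
  expect_gte(gd, 0)
  # equals a direct dense-eigenvalue computation
  lf <- rev(eigen(hessianMatrix(tr$model), symmetric = TRUE,
                  only.values = TRUE)$values)[7:14]
  lb <- rev(eigen(hessianMatrix(tr$modelBound), symmetric = TRUE,
                  only.values = TRUE)$values)[7:14]
  expect_equal(gd, 0.5961 / 2 * sum(log(lb / lf)), tolerance = 1e-10)
  # log-ratio modulation formula reduces to dG when m-state is free
  expect_equal(globalModulation(tr$free, tr$free, tr$bound), gd,
               tolerance = 1e-12)
  expect_equal(globalModulation(tr$free, tr$free, tr$bound,
                                formula = "difference"), gd,
               tolerance = 1e-12)
})

test_that("monomer averaging reports per-position means and standard errors", {
  # planted offsets {0, +0.3, -0.3} at every position: SEM = 0.3/sqrt(3)
  keys <- c(paste0("A:", 1:5), paste0("B:", 1:5), paste0("C:", 1:5))
  base <- c(-1, 0.5, 2, 0, -0.25)
  dg <- stats::setNames(c(base, base + 0.3, base - 0.3), keys)
  p <- new("AllostericProfile", dg = dg, label = "t", kT = 0.5961,
           nModes = 10L, flags = character())
  corr <- cbind(A = paste0("A:", 1:5), B = paste0("B:", 1:5),
                C = paste0("C:", 1:5))
  g <- new("ChainGroups", groups = list(c("A", "B", "C")),
           correspondence = list(corr), identityThreshold = 95)
  ma <- monomerAverage(p, g)
  expect_equal(ma$mean, base)
  expect_equal(ma$sem, rep(stats::sd(c(0, 0.3, -0.3)) / sqrt(3), 5),
               tolerance = 1e-12)
  expect_equal(ma$sem[1], 0.1732051, tolerance = 1e-6)

  # a C2-symmetric dimer has numerically zero error band
  fx <- makeFixture("symmetric_dimer", nResidues = 32, seed = 6,
                    dir = tempdir(), plantLigand = TRUE)
  s <- readCalphaStructure(fx$structureFile)
  site <- detectBindingSite(s, fx$manifest$ligandId)
  # symmetrize the site across both chains so the profile stays symmetric
  mirror <- sub("^A", "B", siteMembers(site))
  site2 <- bindingSite("sym", c(siteMembers(site), mirror), s)
  tr <- run_transition(s, site2)
  ma2 <- monomerAverage(tr$profile, groupHomologousChains(s))
  expect_lt(max(ma2$sem), 1e-8)
})

test_that("tube radii rescale profiles into [0, 1]", {
  mk <- function(v) new("AllostericProfile",
                        dg = stats::setNames(v, paste0("A:", seq_along(v))),
                        label = "t", kT = 0.5961, nModes = 10L,
                        flags = character())
  expect_equal(unname(tubeRadii(mk(c(-1, 0, 3)))), c(0, 0.25, 1))
  expect_equal(unname(tubeRadii(mk(rep(2, 4)))), rep(0.5, 4))
  v <- stats::rnorm(20)
  expect_equal(tubeRadii(mk(3.7 * v + 11)), tubeRadii(mk(v)),
               tolerance = 1e-12)
})

test_that("profiles are invariant under force-constant scaling and rigid motion", {
  s <- toy_structure(toy_globule(15, seed = 19))
  site <- head_site(s, 4)
  p1 <- profileValues(run_transition(s, site, k0 = 1)$profile)
  p2 <- profileValues(run_transition(s, site, k0 = 7.3)$profile)
  expect_lt(max(abs(p1 - p2)), 1e-9)

  R <- random_rotation(seed = 42)
  xyz_r <- sweep(coordMatrix(s) %*% t(R), 2, c(5, -3, 11), "+")
  sr <- toy_structure(xyz_r)
  pr <- profileValues(run_transition(sr, head_site(sr, 4))$profile)
  expect_lt(max(abs(unname(p1) - unname(pr))), 1e-6)
})

test_that("free energies are additive over disjoint mode sets", {
  s <- toy_structure(toy_globule(15, seed = 20))
  site <- head_site(s, 4)
  m <- buildHarmonicModel(s)
  mb <- applyRestraints(m, site, alpha = 100)
  free <- computeModes(hessianMatrix(m), nModes = 10)
  bound <- computeModes(hessianMatrix(mb), nModes = 10)
  dg_of <- function(f, b) profileValues(allostericFreeEnergy(
    residueIntensities(f, s), residueIntensities(b, s)))
  whole <- dg_of(free, bound)
  parts <- dg_of(free[1:5], bound[1:5]) + dg_of(free[6:10], bound[6:10])
  expect_equal(whole, parts, tolerance = 1e-14)
})

test_that("|dg| grows with alpha and the restrained site is stabilized", {
  fx <- makeFixture("two_domain_hinge", nResidues = 60, seed = 1,
                    dir = tempdir(), plantLigand = TRUE)
  s <- readCalphaStructure(fx$structureFile)
  site <- detectBindingSite(s, fx$manifest$ligandId)
  means <- vapply(c(1, 10, 100), function(a)
    siteFreeEnergy(run_transition(s, site, alpha = a)$profile, site),
    numeric(1))
  expect_true(all(means <= 0))                 # restrained site stabilized
  expect_true(all(diff(abs(means)) > 0))       # monotone in alpha
})

test_that("multiplet-summed profiles are invariant to the eigenbasis", {
  fx <- makeFixture("symmetric_dimer", nResidues = 32, seed = 6,
                    dir = tempdir(), plantLigand = TRUE)
  s <- readCalphaStructure(fx$structureFile)
  site <- detectBindingSite(s, fx$manifest$ligandId)
  tr <- run_transition(s, site, nModes = 10)

  mix_within_multiplets <- function(ms, seed) {
    set.seed(seed)
    lam <- eigenvalues(ms)
    V <- modeVectors(ms)
    grp <- cumsum(c(1, diff(lam) > 1e-10 * max(lam)))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (length(idx) == 1) {
        V[, idx] <- V[, idx] * sample(c(-1, 1), 1)
      } else {
        Q <- qr.Q(qr(matrix(stats::rnorm(length(idx)^2), length(idx))))
        V[, idx] <- V[, idx] %*% Q
      }
    }
    new("ModeSet", values = lam, vectors = V,
        nRigidRemoved = nRigidRemoved(ms), residueKeys = residueKeys(ms))
  }
  dg_ref <- profileValues(tr$profile)
  for (sd_ in 1:3) {
    f2 <- mix_within_multiplets(tr$free, sd_)
    b2 <- mix_within_multiplets(tr$bound, sd_ + 100)
    dg2 <- profileValues(allostericFreeEnergy(
      residueIntensities(f2, s), residueIntensities(b2, s)))
    expect_equal(dg2, dg_ref, tolerance = 1e-9)
  }
})
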