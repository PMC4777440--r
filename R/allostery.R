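#' @include AllClasses.R
NULL

#' Residue intensity parameters of a mode set
#'
#' For every retained mode `mu` and residue `i`, the intensity
#' `eps[mu,i] = sum over j of c * |e_mu,i - e_mu,j|^2`, where `j` runs over
#' the neighbours of `i` at reference distance below `dc` and `e_mu,i` is
#' the 3-vector of mode `mu` at residue `i`. The intensity is the stiffness
#' of the per-residue allosteric potential: it measures the elastic work
#' that mode `mu` exerts on the neighbourhood of residue `i`. Neighbour
#' lists are always built on the reference structure, so free and bound
#' tables differ only through their mode vectors.
#'
#' @param modes a [ModeSet].
#' @param s the [CalphaStructure] the modes were computed on (same residue
#'   order).
#' @param c intensity scale, kcal/mol/A^2 (cancels in free-energy
#'   differences; kept for unit fidelity).
#' @param dc neighbourhood distance cutoff, Angstrom (default 11, roughly
#'   the second coordination shell of a C-alpha trace).
#' @return an [IntensityTable].
#' @export
residueIntensities <- function(modes, s, c = 1, dc = 11) {
  stopifnot(is(modes, "ModeSet"), is(s, "CalphaStructure"))
  if (dc <= 0) stop("dc must be > 0")
  keys <- residueKeys(s)
  if (!identical(residueKeys(modes), keys))
    stop("modes and structure disagree on residue ordering")
  n_modes <- length(eigenvalues(modes))
  if (n_modes == 0L) stop("empty mode set")
  n <- length(keys)
  xyz <- coordMatrix(s)
  adj <- as.matrix(stats::dist(xyz)) < dc
  diag(adj) <- FALSE
  eps <- matrix(0, nrow = n_modes, ncol = n,
                dimnames = list(NULL, keys))
  V <- modeVectors(modes)
  for (mu in seq_len(n_modes)) {
    E <- matrix(V[, mu], ncol = 3, byrow = TRUE)
    D2 <- as.matrix(stats::dist(E))^2
    eps[mu, ] <- c * rowSums(D2 * adj)
  }
  new("IntensityTable", eps = eps, residueKeys = keys,
      zeroNeighbor = unname(rowSums(adj) == 0), c = c, dc = dc,
      nModes = as.integer(n_modes))
}

## floor tiny intensities so log-ratios stay finite; returns list(eps, floored)
.floor_eps <- function(eps, zero_neighbor) {
  pos <- eps[eps > 0]
  if (length(pos) == 0L) return(list(eps = eps, floored = logical(ncol(eps))))
  flr <- 1e-12 * stats::median(pos)
  hit <- eps < flr
  hit[, zero_neighbor] <- FALSE   # excluded residues, not floored ones
  eps[eps < flr] <- flr
  list(eps = eps, floored = apply(hit, 2, any))
}

.check_tables <- function(a, b) {
  if (!identical(a@residueKeys, b@residueKeys))
    stop("intensity tables disagree on the residue set")
  if (a@nModes != b@nModes)
    stop("intensity tables use different numbers of modes")
  if (a@c != b@c || a@dc != b@dc)
    stop("intensity tables were built with different (c, dc) parameters")
}

#' Per-residue allosteric free energy of a free -> bound transition
#'
#' From the per-residue partition function of the harmonic allosteric
#' potential (a product of Gaussian integrals, one per mode), the
#' configurational free-energy change of residue `i` caused by restraining
#' the binding site(s) is
#' `dg_i = kT/2 * sum over modes of log(eps_bound / eps_free)`.
#' Negative values mean local stabilization (the residue's neighbourhood
#' moves less in the bound system), positive values increased local
#' dynamics. Residues without any neighbour inside `dc` in either table are
#' reported as `NA` and excluded from site/protein averages; residues whose
#' intensity had to be floored (quasi-rigid neighbourhood in some mode) are
#' flagged.
#'
#' @param free,bound [IntensityTable]s of the ligand-free and site-restrained
#'   systems (same residues, modes and parameters).
#' @param kT thermal energy, kcal/mol (default 0.5961, i.e. T = 300 K).
#' @param label transition descriptor stored with the profile.
#' @return an [AllostericProfile].
#' @export
allostericFreeEnergy <- function(free, bound, kT = 0.5961,
                                 label = "0 -> bound") {
  stopifnot(is(free, "IntensityTable"), is(bound, "IntensityTable"))
  .check_tables(free, bound)
  if (kT <= 0) stop("kT must be positive")
  undef <- free@zeroNeighbor | bound@zeroNeighbor
  f <- .floor_eps(free@eps, undef)
  b <- .floor_eps(bound@eps, undef)
  dg <- (kT / 2) * colSums(log(b$eps / f$eps))
  dg[undef] <- NA_real_
  names(dg) <- free@residueKeys
  flags <- unique(free@residueKeys[undef | f$floored | b$floored])
  new("AllostericProfile", dg = dg, label = label, kT = kT,
      nModes = free@nModes, flags = flags)
}

#' Modulation free energy of sequential binding
#'
#' Quantifies cooperativity: the change in the per-residue allosteric free
#' energy when going from `m` restrained sites to `n > m` restrained sites.
#' The default (`formula = "difference"`) is the difference of the two
#' transitions from the free state,
#' `ddg_i = dg_i(0 -> n) - dg_i(0 -> m)`;
#' negative values indicate that the later binding event stabilizes the
#' residue further (positive cooperativity at that residue when evaluated
#' over the second site). `formula = "logratio"` instead evaluates the literal
#' log-ratio `kT/2 * sum log(eps_n * eps_0 / eps_m^2)`, which differs from
#' the difference form by a second free-to-m term.
#'
#' @param free [IntensityTable] of the ligand-free system.
#' @param mBound,nBound [IntensityTable]s of the systems with `m` and `n`
#'   sites restrained (both sharing the free reference).
#' @param kT thermal energy, kcal/mol.
#' @param formula `"difference"` (default) or `"logratio"`.
#' @param label transition descriptor.
#' @return an [AllostericProfile] holding `ddg_i`.
#' @export
modulationFreeEnergy <- function(free, mBound, nBound, kT = 0.5961,
                                 formula = c("difference", "logratio"),
                                 label = "m -> n") {
  formula <- match.arg(formula)
  .check_tables(free, mBound)
  .check_tables(free, nBound)
  if (formula == "difference") {
    p_n <- allostericFreeEnergy(free, nBound, kT = kT, label = label)
    p_m <- allostericFreeEnergy(free, mBound, kT = kT, label = label)
    dg <- profileValues(p_n) - profileValues(p_m)
    flags <- unique(c(p_n@flags, p_m@flags))
  } else {
    undef <- free@zeroNeighbor | mBound@zeroNeighbor | nBound@zeroNeighbor
    f0 <- .floor_eps(free@eps, undef)
    fm <- .floor_eps(mBound@eps, undef)
    fn <- .floor_eps(nBound@eps, undef)
    dg <- (kT / 2) * colSums(log(fn$eps * f0$eps / fm$eps^2))
    dg[undef] <- NA_real_
    names(dg) <- free@residueKeys
    flags <- unique(free@residueKeys[undef | f0$floored | fm$floored |
                                       fn$floored])
  }
  new("AllostericProfile", dg = dg, label = label, kT = kT,
      nModes = free@nModes, flags = flags)
}

#' Site-averaged allosteric free energy
#'
#' Arithmetic mean of the per-residue free energy over the members of a
#' binding site — the site-level descriptor reported for ligated and
#' regulated sites.
#'
#' @param p an [AllostericProfile].
#' @param site a [BindingSite] whose members all have defined values.
#' @return numeric scalar, kcal/mol.
#' @export
siteFreeEnergy <- function(p, site) {
  stopifnot(is(p, "AllostericProfile"), is(site, "BindingSite"))
  v <- profileValues(p)[siteMembers(site)]
  if (anyNA(v))
    stop("site '", siteName(site), "' contains residue(s) with undefined ",
         "free energy: ",
         paste(siteMembers(site)[is.na(v)], collapse = ", "))
  mean(v)
}

#' Protein-averaged allosteric free energy
#'
#' Mean over all residues with defined values — the baseline against which
#' site means are judged.
#'
#' @param p an [AllostericProfile].
#' @return numeric scalar, kcal/mol.
#' @export
proteinFreeEnergy <- function(p) {
  stopifnot(is(p, "AllostericProfile"))
  mean(profileValues(p), na.rm = TRUE)
}

#' Global allosteric free energy from eigenvalue spectra
#'
#' Whole-structure configurational free-energy change of the free -> bound
#' transition, `dG = kT/2 * sum over modes of log(lambda_bound /
#' lambda_free)`, from the retained eigenvalues of the two systems (each
#' system summed over its own lowest modes). Stiffening is a positive
#' semi-definite perturbation, so `dG >= 0` whenever `alpha > 0`.
#'
#' @param free,bound [ModeSet]s with equal numbers of retained modes.
#' @param kT thermal energy, kcal/mol.
#' @return numeric scalar, kcal/mol.
#' @export
globalFreeEnergy <- function(free, bound, kT = 0.5961) {
  stopifnot(is(free, "ModeSet"), is(bound, "ModeSet"))
  lf <- eigenvalues(free); lb <- eigenvalues(bound)
  if (length(lf) != length(lb))
    stop("mode sets have different sizes")
  (kT / 2) * sum(log(lb / lf))
}

#' Global modulation free energy
#'
#' Spectrum-level analogue of the per-residue modulation free energy for
#' the sequence free -> m sites -> n sites. `formula = "logratio"` evaluates
#' `kT/2 * sum log(lambda_0 * lambda_n / lambda_m^2)`;
#' `formula = "difference"` evaluates `dG(0->n) - dG(0->m)`.
#'
#' @param free,mBound,nBound [ModeSet]s with equal numbers of modes.
#' @param kT thermal energy, kcal/mol.
#' @param formula `"logratio"` (default) or `"difference"`.
#' @return numeric scalar, kcal/mol.
#' @export
globalModulation <- function(free, mBound, nBound, kT = 0.5961,
                             formula = c("logratio", "difference")) {
  formula <- match.arg(formula)
  l0 <- eigenvalues(free); lm <- eigenvalues(mBound); ln <- eigenvalues(nBound)
  if (length(unique(c(length(l0), length(lm), length(ln)))) != 1L)
    stop("mode sets have different sizes")
  if (formula == "logratio")
    (kT / 2) * sum(log(l0 * ln / lm^2))
  else
    (kT / 2) * sum(log(ln / lm))
}

#' Monomer-averaged profile with standard errors
#'
#' Averages a per-residue profile over the homologous chains of each chain
#' group, position by aligned position, and reports the standard error of
#' the mean across chains — the error band that reflects structural
#' differences between homologous monomers. Singleton groups get a zero
#' error band.
#'
#' @param p an [AllostericProfile].
#' @param g a [ChainGroups] object for the same structure.
#' @return data.frame with columns `group`, `position`, `key` (residue key
#'   in the group's first chain), `mean`, `sem`, `n_chains`.
#' @export
monomerAverage <- function(p, g) {
  stopifnot(is(p, "AllostericProfile"), is(g, "ChainGroups"))
  dg <- profileValues(p)
  out <- lapply(seq_along(g@groups), function(gi) {
    corr <- g@correspondence[[gi]]
    if (nrow(corr) == 0L) return(NULL)
    vals <- matrix(dg[corr], nrow = nrow(corr))
    m <- rowMeans(vals, na.rm = TRUE)
    nc <- ncol(vals)
    sem <- if (nc > 1)
      apply(vals, 1, function(r) {
        r <- r[!is.na(r)]
        if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else 0
      })
    else rep(0, nrow(vals))
    data.frame(group = gi, position = seq_len(nrow(corr)),
               key = corr[, 1], mean = m, sem = sem, n_chains = nc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tube radii for backbone-thickness rendering
#'
#' Affine rescaling of a profile to `[0, 1]`:
#' `rho_i = (dg_i - min dg) / (max dg - min dg)`, so the most stabilized
#' residue maps to 0 and the most destabilized to 1. A constant profile
#' maps to 0.5 everywhere (degenerate-range convention). `NA` values stay
#' `NA`.
#'
#' @param p an [AllostericProfile].
#' @return named numeric vector in `[0, 1]`.
#' @export
tubeRadii <- function(p) {
  stopifnot(is(p, "AllostericProfile"))
  dg <- profileValues(p)
  ok <- !is.na(dg)
  rng <- range(dg[ok])
  rho <- dg
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2])))
    rho[ok] <- 0.5
  else
    rho[ok] <- (dg[ok] - rng[1]) / (rng[2] - rng[1])
  rho
}
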