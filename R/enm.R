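#' @include AllClasses.R
NULL

#' Build the C-alpha harmonic model of the ligand-free system
#'
#' Every residue pair within `cutoff` of each other in the reference
#' structure is connected by a distance spring contributing
#' `k_ij * (d_ij - d0_ij)^2` to the energy, with the distance-dependent
#' force constant `k_ij = k0 / d0_ij^exponent`. The default decay exponent 6
#' and 25 Angstrom cutoff give the long-ranged, smoothly decaying network
#' appropriate for low-frequency collective motions. The amplitude `k0`
#' only sets the global energy scale: per-residue free energy differences
#' depend on mode shapes and eigenvalue ratios and are invariant under it.
#'
#' @param s a [CalphaStructure] with at least 2 residues.
#' @param cutoff network distance cutoff, Angstrom.
#' @param exponent decay exponent of the force-constant law.
#' @param k0 force-constant amplitude (energy/A^2 at 1 A).
#' @return a [HarmonicModel] with no site terms.
#' @export
buildHarmonicModel <- function(s, cutoff = 25, exponent = 6, k0 = 1) {
  stopifnot(is(s, "CalphaStructure"))
  n <- nResidues(s)
  if (n < 2L) stop("harmonic model needs at least 2 residues")
  xyz <- coordMatrix(s)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (any(d[idx] == 0))
    stop("coincident residue pair(s) at zero distance")
  pairs <- data.frame(i = idx[, 1], j = idx[, 2], d0 = d[idx])
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs$k <- k0 * pairs$d0^(-exponent)
  new("HarmonicModel", reference = s, pairs = pairs, siteTerms = list(),
      cutoff = cutoff, exponent = exponent, k0 = k0, siteTermHalf = TRUE)
}

#' Restrain binding sites to model ligand binding
#'
#' The bound system is the free system plus, for every restrained site, a
#' stiffening term `alpha * 1/2 * sum over intra-site pairs of
#' k_ij (d_ij - d0_ij)^2`, over all pairs of site residues regardless of
#' the network cutoff (binding sites are compact, so this rarely matters).
#' The force constants follow the same distance law as the base network.
#' With `alpha = 0` the bound Hessian equals the free one exactly.
#'
#' @param m a [HarmonicModel].
#' @param sites a [BindingSite] or list of them; each needs >= 2 members.
#' @param alpha dimensionless stiffening factor (default 100, strong enough
#'   that the restrained site moves quasi-rigidly in the low modes).
#' @param siteTermHalf keep the literal 1/2 inside the site term (default
#'   TRUE, so a site pair's total spring constant is `k_ij * (1 + alpha/2)`).
#' @return a [HarmonicModel] with the site terms appended.
#' @export
applyRestraints <- function(m, sites, alpha = 100, siteTermHalf = m@siteTermHalf) {
  stopifnot(is(m, "HarmonicModel"))
  if (is(sites, "BindingSite")) sites <- list(sites)
  if (alpha < 0) stop("alpha must be >= 0")
  keys <- residueKeys(m@reference)
  xyz <- coordMatrix(m@reference)
  terms <- m@siteTerms
  for (site in sites) {
    mem <- match(siteMembers(site), keys)
    if (anyNA(mem))
      stop("site '", siteName(site), "' references residue(s) absent from ",
           "the model: ",
           paste(siteMembers(site)[is.na(mem)], collapse = ", "))
    if (length(mem) < 2L)
      stop("site '", siteName(site), "' has fewer than 2 residues; ",
           "nothing to restrain")
    cmb <- utils::combn(sort(mem), 2)
    d0 <- sqrt(rowSums((xyz[cmb[1, ], , drop = FALSE] -
                          xyz[cmb[2, ], , drop = FALSE])^2))
    if (any(d0 == 0)) stop("coincident residues within site '",
                           siteName(site), "'")
    sp <- data.frame(i = cmb[1, ], j = cmb[2, ], d0 = d0,
                     k = m@k0 * d0^(-m@exponent))
    terms[[length(terms) + 1L]] <- list(site = site, pairs = sp,
                                        alpha = alpha)
  }
  new("HarmonicModel", reference = m@reference, pairs = m@pairs,
      siteTerms = terms, cutoff = m@cutoff, exponent = m@exponent,
      k0 = m@k0, siteTermHalf = siteTermHalf)
}

## effective (d - d0)^2 spring amplitudes of all terms of a model:
## data.frame(i, j, a) with possible repeats across base/site terms
.spring_terms <- function(m) {
  base <- data.frame(i = m@pairs$i, j = m@pairs$j, d0 = m@pairs$d0,
                     a = m@pairs$k)
  half <- if (m@siteTermHalf) 0.5 else 1.0
  extra <- lapply(m@siteTerms, function(st)
    data.frame(i = st$pairs$i, j = st$pairs$j, d0 = st$pairs$d0,
               a = st$alpha * half * st$pairs$k))
  do.call(rbind, c(list(base), extra))
}

#' Hessian of a harmonic model at its reference coordinates
#'
#' Analytic second derivative of the total energy at the reference
#' structure. Each `a * (d - d0)^2` spring contributes the 3x3 block
#' `2a * u %o% u` (with `u` the unit bond vector) to its two diagonal
#' blocks and `-2a * u %o% u` to the off-diagonal blocks; the curvature
#' perpendicular to the bond vanishes at the minimum. The result is
#' symmetric and every 3x3 block row sums to zero (translational
#' invariance).
#'
#' @param m a [HarmonicModel] (site terms, if present, are included).
#' @return a 3N x 3N numeric matrix with `residueKeys` attribute.
#' @export
hessianMatrix <- function(m) {
  stopifnot(is(m, "HarmonicModel"))
  xyz <- coordMatrix(m@reference)
  n <- nrow(xyz)
  terms <- .spring_terms(m)
  H <- matrix(0, 3 * n, 3 * n)
  for (t in seq_len(nrow(terms))) {
    i <- terms$i[t]; j <- terms$j[t]
    u <- xyz[j, ] - xyz[i, ]
    u <- u / sqrt(sum(u^2))
    B <- (2 * terms$a[t]) * tcrossprod(u)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- H[ii, ii] + B
    H[jj, jj] <- H[jj, jj] + B
    H[ii, jj] <- H[ii, jj] - B
    H[jj, ii] <- H[jj, ii] - B
  }
  attr(H, "residueKeys") <- residueKeys(m@reference)
  attr(H, "coords") <- unname(xyz)
  H
}
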