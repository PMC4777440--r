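#' @include AllClasses.R
NULL

## Brute-force reference implementations used by the test suite. These are
## deliberately written as naive loops, independent of the vectorized
## production code paths (they share only the data containers).

## total scalar energy of a model at flat coordinate vector x (length 3N)
.oracle_energy <- function(m, x) {
  xyz <- matrix(x, ncol = 3, byrow = TRUE)
  e <- 0
  p <- m@pairs
  for (t in seq_len(nrow(p))) {
    d <- sqrt(sum((xyz[p$i[t], ] - xyz[p$j[t], ])^2))
    e <- e + p$k[t] * (d - p$d0[t])^2
  }
  half <- if (m@siteTermHalf) 0.5 else 1.0
  for (st in m@siteTerms) {
    sp <- st$pairs
    for (t in seq_len(nrow(sp))) {
      d <- sqrt(sum((xyz[sp$i[t], ] - xyz[sp$j[t], ])^2))
      e <- e + st$alpha * half * sp$k[t] * (d - sp$d0[t])^2
    }
  }
  e
}

#' Finite-difference Hessian oracle
#'
#' Central second differences of the scalar model energy around the
#' reference coordinates — an implementation-independent check of the
#' analytic Hessian assembly.
#'
#' @param m a [HarmonicModel].
#' @param step finite-difference step, Angstrom.
#' @return 3N x 3N numeric matrix.
#' @export
oracleHessianFD <- function(m, step = 1e-5) {
  x0 <- as.vector(t(coordMatrix(m@reference)))
  n <- length(x0)
  H <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in a:n) {
      xpp <- x0; xpm <- x0; xmp <- x0; xmm <- x0
      xpp[a] <- xpp[a] + step; xpp[b] <- xpp[b] + step
      xpm[a] <- xpm[a] + step; xpm[b] <- xpm[b] - step
      xmp[a] <- xmp[a] - step; xmp[b] <- xmp[b] + step
      xmm[a] <- xmm[a] - step; xmm[b] <- xmm[b] - step
      H[a, b] <- (.oracle_energy(m, xpp) - .oracle_energy(m, xpm) -
                    .oracle_energy(m, xmp) + .oracle_energy(m, xmm)) /
        (4 * step^2)
      H[b, a] <- H[a, b]
    }
  }
  H
}

#' Double-loop residue-intensity oracle
#'
#' Naive per-mode, per-residue, per-neighbour summation of
#' `c * |e_mu,i - e_mu,j|^2` — the reference for the vectorized
#' [residueIntensities()].
#'
#' @param modes a [ModeSet].
#' @param s the matching [CalphaStructure].
#' @param c,dc intensity scale and neighbourhood cutoff.
#' @return numeric matrix (modes x residues).
#' @export
oracleIntensity <- function(modes, s, c = 1, dc = 11) {
  xyz <- coordMatrix(s)
  n <- nrow(xyz)
  V <- modeVectors(modes)
  nm <- ncol(V)
  eps <- matrix(0, nm, n, dimnames = list(NULL, residueKeys(s)))
  for (mu in seq_len(nm)) {
    for (i in seq_len(n)) {
      ei <- V[(3 * i - 2):(3 * i), mu]
      acc <- 0
      for (j in seq_len(n)) {
        if (j == i) next
        if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < dc) {
          ej <- V[(3 * j - 2):(3 * j), mu]
          acc <- acc + c * sum((ei - ej)^2)
        }
      }
      eps[mu, i] <- acc
    }
  }
  eps
}

#' Quadrature partition-function oracle
#'
#' Numerically integrates the per-residue partition function
#' `prod over modes of integral of exp(-eps_mu sigma^2 / (2 kT)) dsigma`,
#' to be compared with the closed Gaussian form
#' `prod(sqrt(2 pi kT / eps_mu))`.
#'
#' @param epsRow numeric vector of intensities (one per mode), all > 0.
#' @param kT thermal energy, kcal/mol.
#' @return numeric scalar.
#' @export
oraclePartition <- function(epsRow, kT = 0.5961) {
  stopifnot(all(epsRow > 0), kT > 0)
  prod(vapply(epsRow, function(e)
    stats::integrate(function(s) exp(-e * s^2 / (2 * kT)),
                     -Inf, Inf, rel.tol = 1e-10)$value,
    numeric(1)))
}
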