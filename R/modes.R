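#' @include AllClasses.R
NULL

## connected components of the residue interaction graph encoded by the
## off-diagonal 3x3 blocks of a Hessian
.hessian_components <- function(H) {
  n <- nrow(H) / 3L
  comp <- rep(0L, n)
  cur <- 0L
  for (s0 in seq_len(n)) {
    if (comp[s0] != 0L) next
    cur <- cur + 1L
    queue <- s0
    comp[s0] <- cur
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      ii <- (3 * i - 2):(3 * i)
      for (j in seq_len(n)) {
        if (comp[j] != 0L || j == i) next
        jj <- (3 * j - 2):(3 * j)
        if (any(abs(H[ii, jj]) > 1e-14)) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

## orthonormal basis of the rigid-body space (3 translations + 3 rotations
## about the centroid) for reference coordinates xyz
.rigid_basis <- function(xyz) {
  n <- nrow(xyz)
  ctr <- sweep(xyz, 2, colMeans(xyz))
  B <- matrix(0, 3 * n, 6)
  for (ax in 1:3) B[seq(ax, 3 * n, 3), ax] <- 1
  gens <- list(rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0)),
               rbind(c(0, 0, 1), c(0, 0, 0), c(-1, 0, 0)),
               rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0)))
  for (g in 1:3) B[, 3 + g] <- as.vector(t(ctr %*% t(gens[[g]])))
  qr.Q(qr(B))
}

#' Diagonalize a Hessian and select the low-frequency modes
#'
#' Full symmetric eigendecomposition of the 3N x 3N Hessian. Eigenvalues
#' below `rigidTol` times the largest eigenvalue are candidate rigid-body
#' modes; a connected 3-D structure has exactly six (three translations,
#' three rotations). Because strong site stiffening inflates the largest
#' eigenvalue, a genuinely soft internal mode (e.g. a hinge torsion) can
#' fall under the relative threshold; candidates are therefore classified
#' by their overlap with the analytic rigid-body subspace of the reference
#' coordinates, and only true rigid modes are removed. The `nModes` lowest
#' remaining eigenpairs are returned in ascending order. Mode vectors carry a
#' deterministic sign: the component of largest absolute value is made
#' positive. Note that inside a degenerate eigenvalue multiplet the
#' individual vectors remain basis-dependent; only multiplet-summed
#' quantities are well defined downstream.
#'
#' @param h Hessian matrix from [hessianMatrix()].
#' @param nModes number of internal modes to retain (default 10, the
#'   low-frequency set that carries the collective motions relevant for
#'   allosteric communication).
#' @param rigidTol relative eigenvalue threshold for rigid-mode removal.
#' @return a [ModeSet].
#' @export
computeModes <- function(h, nModes = 10, rigidTol = 1e-8) {
  stopifnot(is.matrix(h), nrow(h) == ncol(h), nrow(h) %% 3 == 0)
  if (nModes < 1) stop("nModes must be >= 1")
  keys <- attr(h, "residueKeys")
  if (is.null(keys)) keys <- as.character(seq_len(nrow(h) / 3L))
  if (nrow(h) < 3 * 2) stop("Hessian too small")

  eig <- eigen(h, symmetric = TRUE)
  vals <- rev(eig$values)
  vecs <- eig$vectors[, rev(seq_len(ncol(eig$vectors))), drop = FALSE]
  lam_max <- max(vals)
  if (lam_max <= 0) stop("Hessian has no positive eigenvalue")
  cand <- which(vals < rigidTol * lam_max)
  coords <- attr(h, "coords")
  if (length(cand) > 6L) {
    comp <- .hessian_components(h)
    k <- max(comp)
    if (k > 1)
      stop(length(cand), " near-zero modes found (expected 6): the ",
           "structure is disconnected into ", k, " components of sizes ",
           paste(tabulate(comp), collapse = ", "),
           "; each rigid body contributes 6 zero modes")
    if (!is.null(coords)) {
      ## connected: separate true rigid modes from soft internal modes
      ## caught by the relative threshold (the stiffened system raises
      ## lam_max)
      Q <- .rigid_basis(coords)
      ov <- colSums(crossprod(Q, vecs[, cand, drop = FALSE])^2)
      cand <- cand[ov > 0.5]
    }
  }
  n_rigid <- length(cand)
  if (n_rigid > 6L)
    stop(n_rigid, " near-zero modes found (expected 6): the structure is ",
         "geometrically degenerate (e.g. collinear)")
  if (n_rigid < 6L)
    stop("only ", n_rigid, " near-zero modes found (expected 6): ",
         "over-restrained or ill-conditioned Hessian")
  n_internal <- length(vals) - n_rigid
  if (n_internal < nModes)
    stop("only ", n_internal, " internal modes available, ", nModes,
         " requested")
  sel <- setdiff(seq_along(vals), cand)[seq_len(nModes)]
  vals <- vals[sel]
  vecs <- vecs[, sel, drop = FALSE]
  ## deterministic sign: largest-|component| entry positive
  for (c_i in seq_len(ncol(vecs))) {
    p <- which.max(abs(vecs[, c_i]))
    if (vecs[p, c_i] < 0) vecs[, c_i] <- -vecs[, c_i]
  }
  new("ModeSet", values = vals, vectors = vecs,
      nRigidRemoved = as.integer(n_rigid), residueKeys = keys)
}
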