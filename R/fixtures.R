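#' @include AllClasses.R
NULL

## run code under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

## hard-sphere rejection sampling of n points in a sphere of radius R
.globule_coords <- function(n, min_sep = 3.5) {
  R <- max(6, 3.3 * n^(1 / 3))
  pts <- matrix(NA_real_, n, 3)
  got <- 0L
  tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > 20000L * n) stop("globule sampling failed to converge")
    p <- stats::runif(3, -R, R)
    if (sum(p^2) > R^2) next
    if (got > 0) {
      d2 <- colSums((t(pts[seq_len(got), , drop = FALSE]) - p)^2)
      if (min(d2) < min_sep^2) next
    }
    got <- got + 1L
    pts[got, ] <- p
  }
  list(xyz = pts, radius = R)
}

.random_sequence <- function(n) {
  aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  sample(aa1, n, replace = TRUE)
}

## residues with C-alpha within `cut` of any ligand atom (generator's own
## contact rule, independent of detectBindingSite)
.planted_contacts <- function(xyz, keys, lig, cut) {
  hit <- logical(nrow(xyz))
  for (i in seq_len(nrow(xyz)))
    for (a in seq_len(nrow(lig)))
      if (sum((xyz[i, ] - lig[a, ])^2) <= cut^2) hit[i] <- TRUE
  keys[hit]
}

#' Generate a deterministic toy structure with a manifest
#'
#' Writes a standard PDB file (C-alpha records only, plus an optional
#' planted 3-atom ligand) so the full reader path is exercised, together
#' with a JSON manifest recording the planted truth: residue keys, chain
#' equivalences, expected rigid-mode count, domain memberships, ligand
#' contact set. The same `seed` and parameters always reproduce the same
#' file and manifest.
#'
#' Kinds:
#' \describe{
#'   \item{helix}{ideal alpha-helix geometry (rise 1.5 A, 100 degree turn,
#'     radius 2.3 A), consecutive C-alpha spacing about 3.8 A.}
#'   \item{random_globule}{residues rejection-sampled into a sphere with a
#'     3.5 A minimum separation — a compact connected blob.}
#'   \item{symmetric_dimer}{a globule (chain A) plus its exact C2 image
#'     about the z axis (chain B), identical sequences.}
#'   \item{two_domain_hinge}{two globules joined by a 3-residue linker — a
#'     minimal allosteric caricature in which restraining a patch on one
#'     domain measurably perturbs the other.}
#'   \item{disconnected}{two globules separated by well over the network
#'     cutoff (12 near-zero modes; used for error-path tests).}
#' }
#'
#' @param kind one of `"helix"`, `"random_globule"`, `"symmetric_dimer"`,
#'   `"two_domain_hinge"`, `"disconnected"`.
#' @param nResidues total residue count.
#' @param seed integer RNG seed recorded in the manifest.
#' @param dir output directory.
#' @param plantLigand place a 3-atom ligand (`X:LIG:901`) near a reference
#'   residue and record its contact set (not available for `"helix"` and
#'   `"disconnected"`).
#' @return list with `structureFile`, `manifestFile` and the `manifest`
#'   itself.
#' @export
makeFixture <- function(kind = c("helix", "random_globule", "symmetric_dimer",
                                 "two_domain_hinge", "disconnected"),
                        nResidues, seed = 1, dir = tempdir(),
                        plantLigand = FALSE) {
  kind <- match.arg(kind)
  n <- as.integer(nResidues)
  if (n < 4L) stop("nResidues must be >= 4")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  res <- .with_seed(seed, {
    chain <- rep("A", n)
    params <- list()
    domains <- NULL
    c2 <- NULL
    if (kind == "helix") {
      i <- seq_len(n) - 1
      xyz <- cbind(2.3 * cos(i * 100 * pi / 180),
                   2.3 * sin(i * 100 * pi / 180),
                   1.5 * i)
      seq1 <- .random_sequence(n)
      params <- list(rise = 1.5, turn_deg = 100, radius = 2.3)
    } else if (kind == "random_globule") {
      g <- .globule_coords(n)
      xyz <- g$xyz
      seq1 <- .random_sequence(n)
      params <- list(radius = g$radius, min_sep = 3.5)
    } else if (kind == "symmetric_dimer") {
      na <- n %/% 2L
      g <- .globule_coords(na)
      shift <- g$radius + 2.0
      A <- sweep(g$xyz, 2, c(shift, 0, 0), "+")
      B <- A %*% diag(c(-1, -1, 1))      # C2 about z
      ## guarantee no inter-chain clash (C2 image cannot overlap for x>0
      ## points but check anyway)
      dmin <- min(as.matrix(stats::dist(rbind(A, B)))[seq_len(na),
                                                      na + seq_len(na)])
      xyz <- rbind(A, B)
      chain <- rep(c("A", "B"), each = na)
      n <- 2L * na
      sa <- .random_sequence(na)
      seq1 <- c(sa, sa)
      c2 <- diag(c(-1, -1, 1))
      params <- list(radius = g$radius, shift = shift,
                     min_interchain = dmin)
    } else if (kind == "two_domain_hinge") {
      nd <- (n - 3L) %/% 2L
      gA <- .globule_coords(nd)
      gB <- .globule_coords(nd + (n - 3L - 2L * nd))
      off <- max(gA$radius, gB$radius) + 7.6
      A <- sweep(gA$xyz, 2, c(-off, 0, 0), "+")
      B <- sweep(gB$xyz, 2, c(+off, 0, 0), "+")
      L <- cbind(c(-3.8, 0, 3.8), 0, 0)
      xyz <- rbind(A, L, B)
      n <- nrow(xyz)
      chain <- rep("A", n)
      seq1 <- .random_sequence(n)
      domains <- list(A = seq_len(nrow(A)),
                      linker = nrow(A) + 1:3,
                      B = nrow(A) + 3L + seq_len(nrow(B)))
      params <- list(radiusA = gA$radius, radiusB = gB$radius, offset = off)
    } else { # disconnected
      na <- n %/% 2L
      gA <- .globule_coords(na)
      gB <- .globule_coords(n - na)
      sep <- gA$radius + gB$radius + 30
      A <- sweep(gA$xyz, 2, c(-sep / 2, 0, 0), "+")
      B <- sweep(gB$xyz, 2, c(+sep / 2, 0, 0), "+")
      xyz <- rbind(A, B)
      chain <- rep(c("A", "B"), c(na, n - na))
      seq1 <- .random_sequence(n)
      params <- list(separation = sep)
    }

    resno <- stats::ave(seq_len(n), chain, FUN = seq_along)
    keys <- paste0(chain, ":", resno)
    resid3 <- bio3d::aa123(seq1)

    lig <- NULL
    planted <- NULL
    lig_id <- NULL
    if (plantLigand) {
      if (kind %in% c("helix", "disconnected"))
        stop("plantLigand not supported for kind '", kind, "'")
      target <- if (kind == "two_domain_hinge") {
        ## surface residue of domain A: farthest from the linker
        dA <- domains$A
        dA[which.max(abs(xyz[dA, 1] - 0))]
      } else 1L
      base <- xyz[target, ]
      lig <- rbind(base + c(2.5, 0, 0), base + c(0, 2.5, 0),
                   base + c(0, 0, 2.5))
      lig_id <- "X:LIG:901"
      planted <- .planted_contacts(xyz, keys, lig, cut = 4.5 + 3.0)
    }
    list(xyz = xyz, chain = chain, resno = resno, keys = keys,
         resid3 = resid3, seq1 = seq1, params = params, domains = domains,
         c2 = c2, lig = lig, planted = planted, lig_id = lig_id, n = n)
  })

  stem <- sprintf("%s_n%d_s%d", kind, res$n, as.integer(seed))
  pdb_file <- file.path(dir, paste0(stem, ".pdb"))
  man_file <- file.path(dir, paste0(stem, "_manifest.json"))

  xyz_all <- res$xyz
  type <- rep("ATOM", res$n)
  resno <- res$resno
  resid <- res$resid3
  chain <- res$chain
  elety <- rep("CA", res$n)
  if (!is.null(res$lig)) {
    xyz_all <- rbind(xyz_all, res$lig)
    type <- c(type, rep("HETATM", 3))
    resno <- c(resno, rep(901L, 3))
    resid <- c(resid, rep("LIG", 3))
    chain <- c(chain, rep("X", 3))
    elety <- c(elety, c("C1", "C2", "C3"))
  }
  bio3d::write.pdb(file = pdb_file, xyz = as.vector(t(xyz_all)),
                   type = type, resno = resno, resid = resid,
                   chain = chain, elety = elety,
                   o = rep(1, length(type)), b = rep(0, length(type)))

  manifest <- list(
    generator = "makeFixture", kind = kind, nResidues = res$n,
    seed = as.integer(seed), parameters = res$params,
    chains = unique(res$chain), residueKeys = res$keys,
    sequence = paste(res$seq1, collapse = ""),
    expectedRigidModes = if (kind == "disconnected") 12L else 6L,
    c2Operator = res$c2,
    domains = lapply(res$domains, as.integer),
    ligandId = res$lig_id, plantedContacts = res$planted)
  jsonlite::write_json(manifest, man_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(structureFile = pdb_file, manifestFile = man_file,
       manifest = manifest)
}
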