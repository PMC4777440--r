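#' @import methods
NULL

#' CalphaStructure: coarse-grained protein structure
#'
#' Ordered C-alpha records of a protein assembly, together with any
#' heavy-atom records retained for ligand-contact detection. Residues are
#' identified by the key `"chain:resno"` or `"chain:resno:icode"` when an
#' insertion code is present; the order of residues is the file order and is
#' stable across reads of the same file.
#'
#' @slot residues data.frame with columns `chain`, `resno` (integer),
#'   `insert` (character, `""` if none), `resid` (3-letter residue name),
#'   `x`, `y`, `z` (Angstrom) and `key` (unique residue identifier).
#' @slot atoms data.frame of protein heavy atoms (columns `key`, `elety`,
#'   `x`, `y`, `z`); may have zero rows when only C-alpha records exist
#'   (e.g. coarse-grained fixture files).
#' @slot ligands named list; each element a numeric matrix (n_atoms x 3) of
#'   ligand heavy-atom coordinates, named `"chain:resname:resno"`.
#' @slot nModels integer, number of models in the source file.
#'
#' @exportClass CalphaStructure
setClass("CalphaStructure",
  representation(
    residues = "data.frame",
    atoms    = "data.frame",
    ligands  = "list",
    nModels  = "integer"
  ),
  prototype(
    residues = data.frame(),
    atoms    = data.frame(),
    ligands  = list(),
    nModels  = 1L
  )
)

setValidity("CalphaStructure", function(object) {
  r <- object@residues
  msgs <- character()
  need <- c("chain", "resno", "insert", "resid", "x", "y", "z", "key")
  if (!all(need %in% names(r)))
    return(paste("residues must have columns:", paste(need, collapse = ", ")))
  if (nrow(r) > 0) {
    if (anyDuplicated(r$key))
      msgs <- c(msgs, "residue keys must be unique")
    if (!all(is.finite(as.matrix(r[, c("x", "y", "z")]))))
      msgs <- c(msgs, "all C-alpha coordinates must be finite")
  }
  if (object@nModels < 1L) msgs <- c(msgs, "nModels must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' BindingSite: a set of residues forming one binding site
#'
#' @slot name site label, e.g. `"ATP-CTP"`.
#' @slot members character vector of residue keys (see [CalphaStructure]).
#' @slot source `"explicit"` or `"ligand-contact"`; ligand-contact sites
#'   carry the detection mode used (`"heavy-atom"` or `"calpha"`) in
#'   `detectionMode`.
#' @slot detectionMode character, `""` for explicit sites.
#'
#' @exportClass BindingSite
setClass("BindingSite",
  representation(
    name = "character",
    members = "character",
    source = "character",
    detectionMode = "character"
  ),
  prototype(source = "explicit", detectionMode = "")
)

setValidity("BindingSite", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "site needs a non-empty name")
  if (length(object@members) < 1L)
    msgs <- c(msgs, "a binding site needs at least 1 residue")
  if (anyDuplicated(object@members))
    msgs <- c(msgs, "site members must be unique")
  if (!object@source %in% c("explicit", "ligand-contact"))
    msgs <- c(msgs, "source must be 'explicit' or 'ligand-contact'")
  if (length(msgs)) msgs else TRUE
})

#' ChainGroups: homologous-chain grouping of an assembly
#'
#' Chains are grouped when their pairwise global sequence identity is at
#' least the grouping threshold (default 95%). For every group an aligned
#' residue correspondence is stored: a character matrix with one row per
#' aligned position and one column per chain, holding residue keys (only
#' positions present in every chain of the group are kept).
#'
#' @slot groups list of character vectors of chain ids.
#' @slot correspondence list (parallel to `groups`) of character matrices.
#' @slot identityThreshold numeric, percent identity used for grouping.
#'
#' @exportClass ChainGroups
setClass("ChainGroups",
  representation(
    groups = "list",
    correspondence = "list",
    identityThreshold = "numeric"
  ),
  prototype(identityThreshold = 95)
)

setValidity("ChainGroups", function(object) {
  if (length(object@groups) != length(object@correspondence))
    return("groups and correspondence must be parallel lists")
  ch <- unlist(object@groups)
  if (anyDuplicated(ch)) return("every chain must belong to exactly one group")
  TRUE
})

#' HarmonicModel: C-alpha elastic network with optional site restraints
#'
#' The free-system energy is `sum over pairs k_ij (d_ij - d0_ij)^2` over all
#' residue pairs within the network cutoff, with the distance-dependent
#' force constant `k_ij = k0 / d0_ij^exponent`. Site restraint terms add,
#' for each restrained site, `alpha * 1/2 * k_ij (d_ij - d0_ij)^2` over all
#' intra-site pairs (no cutoff applied inside a site). With
#' `siteTermHalf = FALSE` the 1/2 inside the site term is dropped.
#'
#' @slot reference the [CalphaStructure] whose coordinates are the energy
#'   minimum.
#' @slot pairs data.frame with columns `i`, `j` (residue indices, i < j),
#'   `d0` (reference distance, Angstrom) and `k` (force constant).
#' @slot siteTerms list; each element `list(site, pairs, alpha)` where
#'   `pairs` has the same columns as the base pair list.
#' @slot cutoff,exponent,k0 network parameters.
#' @slot siteTermHalf logical, literal-reading flag for the site 1/2 factor.
#'
#' @exportClass HarmonicModel
setClass("HarmonicModel",
  representation(
    reference = "CalphaStructure",
    pairs = "data.frame",
    siteTerms = "list",
    cutoff = "numeric",
    exponent = "numeric",
    k0 = "numeric",
    siteTermHalf = "logical"
  ),
  prototype(siteTerms = list(), cutoff = 25, exponent = 6, k0 = 1,
            siteTermHalf = TRUE)
)

setValidity("HarmonicModel", function(object) {
  p <- object@pairs
  msgs <- character()
  if (!all(c("i", "j", "d0", "k") %in% names(p)))
    return("pairs must have columns i, j, d0, k")
  if (nrow(p) > 0) {
    if (any(p$i >= p$j)) msgs <- c(msgs, "pairs must have i < j")
    if (anyDuplicated(p[, c("i", "j")])) msgs <- c(msgs, "duplicate pairs")
    if (any(p$d0 <= 0)) msgs <- c(msgs, "all reference distances must be > 0")
    if (any(p$d0 > object@cutoff + 1e-9))
      msgs <- c(msgs, "base pairs must respect the network cutoff")
  }
  if (object@k0 <= 0) msgs <- c(msgs, "k0 must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' ModeSet: selected normal modes of one system
#'
#' Eigenpairs of a 3N x 3N Hessian after removal of the rigid-body modes,
#' sorted by ascending eigenvalue. Vectors follow a deterministic sign
#' convention: the component of largest absolute value is positive.
#'
#' @slot values numeric vector of eigenvalues (ascending, all > 0).
#' @slot vectors 3N x n_modes matrix of orthonormal mode vectors (columns).
#' @slot nRigidRemoved integer, number of near-zero modes removed (6 for a
#'   connected 3-D structure).
#' @slot residueKeys character, residue keys in Hessian order.
#'
#' @exportClass ModeSet
setClass("ModeSet",
  representation(
    values = "numeric",
    vectors = "matrix",
    nRigidRemoved = "integer",
    residueKeys = "character"
  )
)

setValidity("ModeSet", function(object) {
  msgs <- character()
  if (length(object@values) != ncol(object@vectors))
    msgs <- c(msgs, "one eigenvalue per mode vector required")
  if (is.unsorted(object@values)) msgs <- c(msgs, "eigenvalues must be ascending")
  if (length(object@values) && any(object@values < 0))
    msgs <- c(msgs, "eigenvalues must be non-negative after rigid-mode removal")
  if (nrow(object@vectors) != 3L * length(object@residueKeys))
    msgs <- c(msgs, "vectors must have 3N rows")
  if (length(msgs)) msgs else TRUE
})

#' IntensityTable: residue intensity parameters of one system
#'
#' The intensity `eps[mu, i]` measures how strongly mode `mu` deforms the
#' neighbourhood of residue `i`:
#' `eps[mu,i] = sum over neighbours j of c * |e_mu,i - e_mu,j|^2`,
#' with neighbours `j != i` at reference distance `< dc` from `i`.
#'
#' @slot eps numeric matrix, n_modes x N residues.
#' @slot residueKeys character, column order of `eps`.
#' @slot zeroNeighbor logical vector, TRUE for residues with no neighbour
#'   within `dc` (their intensities are identically zero and excluded from
#'   free-energy profiles).
#' @slot c,dc intensity scale (kcal/mol/A^2) and neighbourhood cutoff (A).
#' @slot nModes integer.
#'
#' @exportClass IntensityTable
setClass("IntensityTable",
  representation(
    eps = "matrix",
    residueKeys = "character",
    zeroNeighbor = "logical",
    c = "numeric",
    dc = "numeric",
    nModes = "integer"
  )
)

setValidity("IntensityTable", function(object) {
  msgs <- character()
  if (ncol(object@eps) != length(object@residueKeys))
    msgs <- c(msgs, "eps needs one column per residue")
  if (nrow(object@eps) != object@nModes)
    msgs <- c(msgs, "eps needs one row per mode")
  if (length(object@eps) && any(object@eps < -1e-12))
    msgs <- c(msgs, "intensities must be non-negative")
  if (length(object@zeroNeighbor) != length(object@residueKeys))
    msgs <- c(msgs, "zeroNeighbor flag needed per residue")
  if (length(msgs)) msgs else TRUE
})

#' AllostericProfile: per-residue allosteric (or modulation) free energy
#'
#' @slot dg named numeric vector, kcal/mol, indexed by residue key; `NA` for
#'   residues excluded because their neighbourhood is empty.
#' @slot label transition descriptor, e.g. `"0 -> 1xSITE"`.
#' @slot kT thermal energy used, kcal/mol.
#' @slot nModes number of modes summed.
#' @slot flags character vector of keys of flagged (excluded or floored)
#'   residues.
#'
#' @exportClass AllostericProfile
setClass("AllostericProfile",
  representation(
    dg = "numeric",
    label = "character",
    kT = "numeric",
    nModes = "integer",
    flags = "character"
  ),
  prototype(label = "", flags = character())
)

setValidity("AllostericProfile", function(object) {
  if (is.null(names(object@dg))) return("dg must be named by residue key")
  if (object@kT <= 0) return("kT must be positive")
  TRUE
})
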