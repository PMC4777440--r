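#' @include AllClasses.R
NULL

#' Number of residues
#' @param x a CalphaStructure, HarmonicModel or IntensityTable
#' @return integer
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Residue identifier keys, in model order
#' @param x object carrying a residue ordering
#' @return character vector of `"chain:resno[:icode]"` keys
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))

#' Residue table (chain, resno, insert, resid, x, y, z, key)
#' @param x a CalphaStructure
#' @return data.frame
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' C-alpha coordinate matrix (N x 3)
#' @param x a CalphaStructure
#' @return numeric matrix
#' @export
setGeneric("coordMatrix", function(x) standardGeneric("coordMatrix"))

#' Ligand identifiers present in a structure
#' @param x a CalphaStructure
#' @return character vector of `"chain:resname:resno"` ids
#' @export
setGeneric("ligandIds", function(x) standardGeneric("ligandIds"))

#' Eigenvalues of a mode set
#' @param x a ModeSet
#' @return numeric vector, ascending
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' Mode vector matrix (3N x n_modes)
#' @param x a ModeSet
#' @return numeric matrix with orthonormal columns
#' @export
setGeneric("modeVectors", function(x) standardGeneric("modeVectors"))

#' Number of rigid-body modes removed during diagonalization
#' @param x a ModeSet
#' @return integer
#' @export
setGeneric("nRigidRemoved", function(x) standardGeneric("nRigidRemoved"))

#' Residue intensity matrix (modes x residues)
#' @param x an IntensityTable
#' @return numeric matrix
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' Per-residue free energy values of a profile
#' @param x an AllostericProfile
#' @return named numeric vector (kcal/mol)
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' Members of a binding site
#' @param x a BindingSite
#' @return character vector of residue keys
#' @export
setGeneric("siteMembers", function(x) standardGeneric("siteMembers"))

#' Name of a binding site
#' @param x a BindingSite
#' @return character scalar
#' @export
setGeneric("siteName", function(x) standardGeneric("siteName"))

#' Chain groups of an assembly
#' @param x a ChainGroups object
#' @return list of character vectors of chain ids
#' @export
setGeneric("chainGroupList", function(x) standardGeneric("chainGroupList"))

## ---- methods ----

#' @rdname nResidues
setMethod("nResidues", "CalphaStructure", function(x) nrow(x@residues))
#' @rdname nResidues
setMethod("nResidues", "HarmonicModel", function(x) nResidues(x@reference))
#' @rdname nResidues
setMethod("nResidues", "IntensityTable", function(x) length(x@residueKeys))

#' @rdname residueKeys
setMethod("residueKeys", "CalphaStructure", function(x) x@residues$key)
#' @rdname residueKeys
setMethod("residueKeys", "ModeSet", function(x) x@residueKeys)
#' @rdname residueKeys
setMethod("residueKeys", "IntensityTable", function(x) x@residueKeys)
#' @rdname residueKeys
setMethod("residueKeys", "AllostericProfile", function(x) names(x@dg))

#' @rdname residueTable
setMethod("residueTable", "CalphaStructure", function(x) x@residues)

#' @rdname coordMatrix
setMethod("coordMatrix", "CalphaStructure", function(x) {
  m <- as.matrix(x@residues[, c("x", "y", "z")])
  rownames(m) <- x@residues$key
  m
})

#' @rdname ligandIds
setMethod("ligandIds", "CalphaStructure", function(x) names(x@ligands))

#' @rdname eigenvalues
setMethod("eigenvalues", "ModeSet", function(x) x@values)
#' @rdname modeVectors
setMethod("modeVectors", "ModeSet", function(x) x@vectors)
#' @rdname nRigidRemoved
setMethod("nRigidRemoved", "ModeSet", function(x) x@nRigidRemoved)

#' Subset a ModeSet by mode index
#'
#' @param x a ModeSet
#' @param i integer mode indices (1 = lowest-frequency retained mode)
#' @param j,...,drop ignored
#' @return a ModeSet with the selected modes
#' @export
setMethod("[", "ModeSet", function(x, i, j, ..., drop = FALSE) {
  new("ModeSet",
      values = x@values[i],
      vectors = x@vectors[, i, drop = FALSE],
      nRigidRemoved = x@nRigidRemoved,
      residueKeys = x@residueKeys)
})

#' @rdname intensityMatrix
setMethod("intensityMatrix", "IntensityTable", function(x) x@eps)

#' @rdname profileValues
setMethod("profileValues", "AllostericProfile", function(x) x@dg)

#' @rdname siteMembers
setMethod("siteMembers", "BindingSite", function(x) x@members)
#' @rdname siteName
setMethod("siteName", "BindingSite", function(x) x@name)

#' @rdname chainGroupList
setMethod("chainGroupList", "ChainGroups", function(x) x@groups)

## ---- show ----

setMethod("show", "CalphaStructure", function(object) {
  r <- object@residues
  cat("CalphaStructure:", nrow(r), "residues,",
      length(unique(r$chain)), "chain(s)")
  if (length(object@ligands)) cat(",", length(object@ligands), "ligand(s)")
  if (object@nModels > 1L) cat(",", object@nModels, "models")
  cat("\n")
  if (length(object@ligands))
    cat("  ligands:", paste(names(object@ligands), collapse = " "), "\n")
})

setMethod("show", "BindingSite", function(object) {
  cat("BindingSite '", object@name, "' (", object@source,
      if (nzchar(object@detectionMode)) paste0("/", object@detectionMode),
      "): ", length(object@members), " residues\n", sep = "")
})

setMethod("show", "ChainGroups", function(object) {
  cat("ChainGroups:", length(object@groups), "group(s) at >=",
      object@identityThreshold, "% identity\n")
  for (g in seq_along(object@groups))
    cat("  group", g, ":", paste(object@groups[[g]], collapse = ","),
        "(", nrow(object@correspondence[[g]]), "aligned positions )\n")
})

setMethod("show", "HarmonicModel", function(object) {
  cat("HarmonicModel:", nResidues(object), "residues,",
      nrow(object@pairs), "network pairs (cutoff", object@cutoff, "A, k0 =",
      object@k0, ", 1/d^", object@exponent, ")\n")
  for (st in object@siteTerms)
    cat("  restrained site '", siteName(st$site), "': ",
        nrow(st$pairs), " pairs, alpha = ", st$alpha, "\n", sep = "")
})

setMethod("show", "ModeSet", function(object) {
  cat("ModeSet:", length(object@values), "modes (",
      object@nRigidRemoved, "rigid removed ), eigenvalues [",
      format(min(object@values), digits = 4), ",",
      format(max(object@values), digits = 4), "]\n")
})

setMethod("show", "IntensityTable", function(object) {
  cat("IntensityTable:", object@nModes, "modes x",
      length(object@residueKeys), "residues (c =", object@c,
      "kcal/mol/A^2, dc =", object@dc, "A );",
      sum(object@zeroNeighbor), "zero-neighbour residue(s)\n")
})

setMethod("show", "AllostericProfile", function(object) {
  ok <- !is.na(object@dg)
  cat("AllostericProfile '", object@label, "': ", length(object@dg),
      " residues (", sum(!ok), " undefined), kT = ", object@kT,
      " kcal/mol, ", object@nModes, " modes\n", sep = "")
  if (any(ok))
    cat("  dg range [", format(min(object@dg[ok]), digits = 4), ",",
        format(max(object@dg[ok]), digits = 4), "] kcal/mol\n")
})
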