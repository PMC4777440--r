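#' @include AllClasses.R
NULL

#' Write a per-residue profile as a tab-separated table
#'
#' Columns: `chain`, `resno`, `icode`, `resname`, `dg_kcal_mol`, `flags`
#' (`excluded` for residues without neighbours, `floored` for residues with
#' a floored intensity, empty otherwise).
#'
#' @param p an [AllostericProfile].
#' @param s the matching [CalphaStructure].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeProfileTable <- function(p, s, file) {
  r <- residueTable(s)
  dg <- profileValues(p)[r$key]
  flags <- ifelse(is.na(dg), "excluded",
                  ifelse(r$key %in% p@flags, "floored", ""))
  tab <- data.frame(chain = r$chain, resno = r$resno, icode = r$insert,
                    resname = r$resid,
                    dg_kcal_mol = ifelse(is.na(dg), "NA",
                                         sprintf("%.6f", dg)),
                    flags = flags, stringsAsFactors = FALSE)
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a structure with profile values in the B-factor column
#'
#' Copies the C-alpha records of the input structure with the per-residue
#' value written into the B-factor column (clamped to the PDB-representable
#' range \[-99.99, 999.99\]; undefined residues get 0), the standard
#' hand-off to molecular viewers.
#'
#' @param s a [CalphaStructure].
#' @param values named numeric vector indexed by residue key (a profile or
#'   tube-radius vector).
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeBfactorPdb <- function(s, values, file) {
  r <- residueTable(s)
  b <- values[r$key]
  b[is.na(b)] <- 0
  b <- pmin(pmax(b, -99.99), 999.99)
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(as.matrix(r[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(r)),
                   resno = r$resno, resid = r$resid, chain = r$chain,
                   insert = r$insert,
                   elety = rep("CA", nrow(r)),
                   o = rep(1, nrow(r)), b = as.numeric(b))
  invisible(file)
}

#' Write the monomer-averaged profile with standard errors
#'
#' @param ma data.frame from [monomerAverage()].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeMonomerTable <- function(ma, file) {
  tab <- data.frame(group = ma$group, position = ma$position, key = ma$key,
                    mean_dg = sprintf("%.6f", ma$mean),
                    sem = sprintf("%.6f", ma$sem),
                    n_chains = ma$n_chains, stringsAsFactors = FALSE)
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
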