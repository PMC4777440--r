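#' @include AllClasses.R
NULL

## Standard water residue names never treated as ligands.
.WATER <- c("HOH", "WAT", "DOD", "H2O")

.residue_key <- function(chain, resno, insert) {
  ic <- ifelse(is.na(insert) | insert == "", "", paste0(":", insert))
  paste0(chain, ":", resno, ic)
}

## Keep, within each (chain, resno, insert, elety) group, the single record
## of highest occupancy; ties broken by altloc letter order.
.filter_altloc <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  occ <- atom$o
  occ[is.na(occ)] <- 1
  grp <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "\r")
  ord <- order(grp, -occ, alt)
  keep_first <- !duplicated(grp[ord])
  sort(ord[keep_first])
}

#' Read the C-alpha representation of a protein structure
#'
#' Parses a PDB (or mmCIF) file and extracts one C-alpha record per residue,
#' protein heavy atoms (kept for ligand-contact site detection) and
#' non-water HETATM groups as candidate ligands. Alternate locations are
#' resolved to the highest-occupancy conformer. Multi-model files (NMR
#' bundles) are reduced according to `modelPolicy`: the first model, the
#' arithmetic mean conformer over all models, or a specific model index.
#'
#' Non-standard amino acids that carry a carbon C-alpha atom (e.g. MSE) are
#' treated as residues; every other non-water HETATM group is a candidate
#' ligand identified as `"chain:resname:resno"`.
#'
#' @param path path to a `.pdb` (or `.cif`/`.mmcif`) file.
#' @param modelPolicy `"first"`, `"mean"`, or an integer model index.
#' @return a [CalphaStructure].
#' @examples
#' fx <- makeFixture("helix", nResidues = 12, seed = 1, dir = tempdir())
#' s <- readCalphaStructure(fx$structureFile)
#' nResidues(s)
#' @export
readCalphaStructure <- function(path, modelPolicy = "first") {
  if (!file.exists(path)) stop("structure file not found: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("unparseable structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  atom <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)

  keep <- .filter_altloc(atom)
  atom <- atom[keep, , drop = FALSE]
  xyz_cols <- as.vector(vapply(keep, function(i) (3L * i - 2L):(3L * i),
                               integer(3)))
  xyz <- xyz[, xyz_cols, drop = FALSE]

  coords <- switch(as.character(modelPolicy[1]),
    first = xyz[1, ],
    mean  = colMeans(xyz),
    {
      k <- suppressWarnings(as.integer(modelPolicy[1]))
      if (is.na(k) || k < 1L || k > n_models)
        stop("model index out of range: ", modelPolicy[1],
             " (file has ", n_models, " model(s))")
      xyz[k, ]
    })
  atom$x <- coords[seq(1, length(coords), 3)]
  atom$y <- coords[seq(2, length(coords), 3)]
  atom$z <- coords[seq(3, length(coords), 3)]

  atom$insert[is.na(atom$insert)] <- ""
  elesy <- if ("elesy" %in% names(atom)) atom$elesy else
    substr(trimws(atom$elety), 1, 1)
  elesy[is.na(elesy)] <- ""

  ## a carbon atom named CA marks a residue (excludes calcium ions)
  is_ca <- trimws(atom$elety) == "CA" & toupper(trimws(elesy)) %in% c("C", "")
  grp_id <- paste(atom$chain, atom$resno, atom$insert, sep = "\r")

  ## residues = groups possessing a (carbon) CA; includes CA-bearing HETATM
  ## groups such as MSE
  ca_rows <- which(is_ca & !atom$resid %in% .WATER)
  if (length(ca_rows) == 0L) stop("no C-alpha atoms found in ", path)
  ca <- atom[ca_rows, , drop = FALSE]
  residues <- data.frame(
    chain = ca$chain, resno = ca$resno, insert = ca$insert,
    resid = ca$resid, x = ca$x, y = ca$y, z = ca$z,
    key = .residue_key(ca$chain, ca$resno, ca$insert),
    stringsAsFactors = FALSE)
  if (anyDuplicated(residues$key))
    stop("duplicate residue identifiers after altloc filtering in ", path)

  chains_with_ca <- unique(residues$chain)
  all_protein_chains <- unique(atom$chain[atom$type == "ATOM"])
  empty <- setdiff(all_protein_chains, chains_with_ca)
  if (length(empty))
    stop("chain(s) without any C-alpha atom: ", paste(empty, collapse = ", "))

  ## protein heavy atoms: all non-H atoms of residue groups
  res_grp_ids <- grp_id[ca_rows]
  prot_rows <- which(grp_id %in% res_grp_ids & !toupper(elesy) %in% "H")
  pa <- atom[prot_rows, , drop = FALSE]
  atoms <- data.frame(
    key = .residue_key(pa$chain, pa$resno, pa$insert),
    elety = trimws(pa$elety), x = pa$x, y = pa$y, z = pa$z,
    stringsAsFactors = FALSE)

  ## ligands: non-water HETATM groups that are not residues
  het_rows <- which(atom$type == "HETATM" & !atom$resid %in% .WATER &
                      !grp_id %in% res_grp_ids & !toupper(elesy) %in% "H")
  ligands <- list()
  if (length(het_rows)) {
    ha <- atom[het_rows, , drop = FALSE]
    lig_id <- paste(ha$chain, ha$resid, ha$resno, sep = ":")
    for (id in unique(lig_id)) {
      sel <- lig_id == id
      ligands[[id]] <- cbind(x = ha$x[sel], y = ha$y[sel], z = ha$z[sel])
    }
  }

  new("CalphaStructure", residues = residues, atoms = atoms,
      ligands = ligands, nModels = as.integer(n_models))
}
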