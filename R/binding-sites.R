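#' @include AllClasses.R
NULL

#' Construct a binding site from an explicit residue list
#'
#' @param name site label.
#' @param members character vector of residue keys (`"chain:resno[:icode]"`).
#' @param structure optional [CalphaStructure]; when given, membership is
#'   validated against it.
#' @return a [BindingSite]
#' @export
bindingSite <- function(name, members, structure = NULL) {
  members <- unique(as.character(members))
  if (!is.null(structure)) {
    unknown <- setdiff(members, residueKeys(structure))
    if (length(unknown))
      stop("site '", name, "' references unknown residue(s): ",
           paste(unknown, collapse = ", "))
  }
  new("BindingSite", name = name, members = members, source = "explicit")
}

#' Detect a binding site from ligand contacts
#'
#' Residues in contact with the heavy atoms of a bound ligand. When protein
#' heavy atoms were retained at parse time, a residue is a member if any of
#' its heavy atoms lies within `contactCutoff` of any ligand heavy atom.
#' When only C-alpha records exist, the C-alpha is used with the cutoff
#' widened by 3 Angstrom (an allowance for the typical C-alpha-to-side-chain
#' reach); the mode used is recorded in the site's `detectionMode`.
#'
#' @param s a [CalphaStructure] whose ligand list contains `ligandId`.
#' @param ligandId ligand identifier `"chain:resname:resno"`.
#' @param contactCutoff heavy-atom contact distance, Angstrom (default 4.5).
#' @param name optional site name (default: the ligand id).
#' @return a [BindingSite] with `source = "ligand-contact"`.
#' @export
detectBindingSite <- function(s, ligandId, contactCutoff = 4.5, name = NULL) {
  stopifnot(is(s, "CalphaStructure"))
  if (contactCutoff <= 0) stop("contactCutoff must be > 0")
  if (!ligandId %in% names(s@ligands))
    stop("ligand not found: '", ligandId, "' (available: ",
         paste(names(s@ligands), collapse = ", "), ")")
  lig <- s@ligands[[ligandId]]

  ## full-atom contacts need more than the C-alpha trace itself
  has_full_atom <- nrow(s@atoms) > 0 && any(s@atoms$elety != "CA")
  if (has_full_atom) {
    mode <- "heavy-atom"
    pts <- as.matrix(s@atoms[, c("x", "y", "z")])
    keys <- s@atoms$key
    cut <- contactCutoff
  } else {
    mode <- "calpha"
    pts <- coordMatrix(s)
    keys <- residueKeys(s)
    cut <- contactCutoff + 3.0
  }
  ## min distance from each protein atom to any ligand atom
  d2min <- rep(Inf, nrow(pts))
  for (a in seq_len(nrow(lig))) {
    d2 <- (pts[, 1] - lig[a, 1])^2 + (pts[, 2] - lig[a, 2])^2 +
      (pts[, 3] - lig[a, 3])^2
    d2min <- pmin(d2min, d2)
  }
  members <- unique(keys[d2min <= cut^2])
  if (length(members) == 0L)
    stop("empty site: no residue within ", cut, " A of ligand '",
         ligandId, "'")
  members <- members[order(match(members, residueKeys(s)))]
  new("BindingSite", name = if (is.null(name)) ligandId else name,
      members = members, source = "ligand-contact", detectionMode = mode)
}

#' Read binding-site definitions from a plain-text site file
#'
#' One site per line, two forms:
#' \preformatted{
#' SITE <name> <chain>:<resnum>[<icode>] <chain>:<resnum> ...
#' SITE <name> LIGAND <chain>:<resname>:<resnum> CUTOFF <Angstrom>
#' }
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path site file.
#' @param structure the [CalphaStructure] the sites refer to.
#' @return named list of [BindingSite] objects.
#' @export
readSiteFile <- function(path, structure) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sites <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) < 3L || toupper(tok[1]) != "SITE")
      stop("malformed site line: '", ln, "'")
    nm <- tok[2]
    if (toupper(tok[3]) == "LIGAND") {
      if (length(tok) != 6L || toupper(tok[5]) != "CUTOFF")
        stop("malformed LIGAND site line: '", ln, "'")
      sites[[nm]] <- detectBindingSite(structure, tok[4],
                                       contactCutoff = as.numeric(tok[6]),
                                       name = nm)
    } else {
      members <- vapply(tok[-(1:2)], function(t) {
        p <- strsplit(t, ":", fixed = TRUE)[[1]]
        if (length(p) < 2L) stop("malformed residue spec '", t, "' in: ", ln)
        ## split trailing icode letters off the residue number
        num <- sub("^(-?[0-9]+).*$", "\\1", p[2])
        ic <- sub("^-?[0-9]+", "", p[2])
        .residue_key(p[1], as.integer(num), ic)
      }, character(1), USE.NAMES = FALSE)
      sites[[nm]] <- bindingSite(nm, members, structure)
    }
  }
  sites
}
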