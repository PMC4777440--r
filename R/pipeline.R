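#' @include AllClasses.R
NULL

#' Run the full allosteric free-energy pipeline
#'
#' Orchestrates the analysis for one structure: build the ligand-free
#' elastic network, then for every declared transition restrain the listed
#' binding sites, diagonalize both systems, and derive the per-residue,
#' per-site and whole-protein free energy changes. A transition restrains
#' `nSites` in the end state and (optionally) `mSites` in the start state;
#' with `mSites` empty the profile is the plain free -> bound allosteric
#' free energy, otherwise the modulation free energy of sequential binding.
#'
#' When `outDir` is given, each transition writes: the per-residue profile
#' table, the monomer-averaged profile with standard errors, a JSON
#' site/protein summary, and two PDB copies with the profile and its tube
#' radii in the B-factor column; a machine-readable run log (all
#' parameters, eigenvalue spectrum heads, flags raised) covers the run.
#' Rerunning the same configuration reproduces the output files
#' byte-for-byte.
#'
#' @param structure a [CalphaStructure] or path to a structure file.
#' @param sites named list of [BindingSite]s, or path to a site file (see
#'   [readSiteFile()]).
#' @param transitions list of `list(label =, nSites = <site names>,
#'   mSites = <site names or NULL>)`. Restraining n copies of a site across
#'   monomers is expressed by listing the n site instances.
#' @param alpha stiffening factor of restrained sites.
#' @param cutoff,exponent,k0 elastic-network parameters (see
#'   [buildHarmonicModel()]).
#' @param c,dc intensity parameters (see [residueIntensities()]).
#' @param nModes number of low-frequency modes.
#' @param kT thermal energy, kcal/mol (0.5961 = 300 K).
#' @param modelPolicy model selection for multi-model files.
#' @param siteTermHalf literal 1/2 inside site restraint terms.
#' @param modulationFormula `"difference"` or `"logratio"` (see
#'   [modulationFreeEnergy()]).
#' @param outDir optional output directory for the report bundle.
#' @return (invisibly) a list with the structure, chain groups, free-system
#'   mode set, and per-transition results (`profile`, `globalDG`,
#'   `summary`, `monomer`, `boundModes`).
#' @export
runAllostery <- function(structure, sites, transitions,
                         alpha = 100, cutoff = 25, exponent = 6, k0 = 1,
                         c = 1, dc = 11, nModes = 10, kT = 0.5961,
                         modelPolicy = "first", siteTermHalf = TRUE,
                         modulationFormula = "difference", outDir = NULL) {
  s <- if (is.character(structure)) {
    readCalphaStructure(structure, modelPolicy = modelPolicy)
  } else structure
  stopifnot(is(s, "CalphaStructure"))
  if (is.character(sites)) sites <- readSiteFile(sites, s)
  if (is(sites, "BindingSite")) sites <- list(sites)
  if (is.null(names(sites)) || any(!nzchar(names(sites))))
    names(sites) <- vapply(sites, siteName, character(1))

  labels <- vapply(transitions, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("transition labels must be unique")
  for (tr in transitions) {
    miss <- setdiff(c(tr$nSites, tr$mSites), names(sites))
    if (length(miss))
      stop("transition '", tr$label, "' references undefined site(s): ",
           paste(miss, collapse = ", "))
  }

  model <- buildHarmonicModel(s, cutoff = cutoff, exponent = exponent,
                              k0 = k0)
  free_h <- hessianMatrix(model)
  free_modes <- computeModes(free_h, nModes = nModes)
  free_eps <- residueIntensities(free_modes, s, c = c, dc = dc)
  groups <- groupHomologousChains(s)

  bound_system <- function(site_names) {
    bm <- applyRestraints(model, sites[site_names], alpha = alpha,
                          siteTermHalf = siteTermHalf)
    md <- computeModes(hessianMatrix(bm), nModes = nModes)
    list(modes = md, eps = residueIntensities(md, s, c = c, dc = dc))
  }

  results <- list()
  for (tr in transitions) {
    nb <- bound_system(tr$nSites)
    if (is.null(tr$mSites) || length(tr$mSites) == 0L) {
      profile <- allostericFreeEnergy(free_eps, nb$eps, kT = kT,
                                      label = tr$label)
      gdg <- globalFreeEnergy(free_modes, nb$modes, kT = kT)
    } else {
      mb <- bound_system(tr$mSites)
      profile <- modulationFreeEnergy(free_eps, mb$eps, nb$eps, kT = kT,
                                      formula = modulationFormula,
                                      label = tr$label)
      gdg <- globalModulation(free_modes, mb$modes, nb$modes, kT = kT)
    }
    site_means <- lapply(sites, function(st)
      tryCatch(siteFreeEnergy(profile, st), error = function(e) NA_real_))
    summary <- list(
      label = tr$label,
      restrained_sites = tr$nSites,
      start_sites = tr$mSites,
      site_mean_dg = site_means,
      protein_mean_dg = proteinFreeEnergy(profile),
      global_dG = gdg,
      kT = kT, n_modes = nModes, alpha = alpha)
    results[[tr$label]] <- list(profile = profile, globalDG = gdg,
                                summary = summary,
                                monomer = monomerAverage(profile, groups),
                                boundModes = nb$modes)
  }

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    safe <- function(x) gsub("[^A-Za-z0-9_.-]+", "_", x)
    for (lb in names(results)) {
      rr <- results[[lb]]
      stem <- file.path(outDir, safe(lb))
      writeProfileTable(rr$profile, s, paste0(stem, "_profile.tsv"))
      writeMonomerTable(rr$monomer, paste0(stem, "_monomer.tsv"))
      jsonlite::write_json(rr$summary, paste0(stem, "_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      writeBfactorPdb(s, profileValues(rr$profile),
                      paste0(stem, "_dg_bfactor.pdb"))
      writeBfactorPdb(s, tubeRadii(rr$profile),
                      paste0(stem, "_tube_bfactor.pdb"))
    }
    runlog <- list(
      parameters = list(alpha = alpha, cutoff = cutoff,
                        exponent = exponent, k0 = k0, c = c, dc = dc,
                        n_modes = nModes, kT = kT,
                        model_policy = as.character(modelPolicy),
                        site_term_half = siteTermHalf,
                        modulation_formula = modulationFormula),
      structure = list(n_residues = nResidues(s),
                       chains = unique(residueTable(s)$chain),
                       n_models = s@nModels),
      sites = lapply(sites, function(st)
        list(name = siteName(st), n_members = length(siteMembers(st)),
             source = st@source, members = siteMembers(st))),
      transitions = lapply(results, function(rr) rr$summary),
      eigenvalue_head_free = utils::head(eigenvalues(free_modes), 12),
      eigenvalue_head_bound = lapply(results, function(rr)
        utils::head(eigenvalues(rr$boundModes), 12)),
      rigid_modes_removed = nRigidRemoved(free_modes),
      flags = lapply(results, function(rr) rr$profile@flags))
    jsonlite::write_json(runlog, file.path(outDir, "runlog.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(structure = s, sites = sites, groups = groups,
                 freeModes = free_modes, results = results))
}
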