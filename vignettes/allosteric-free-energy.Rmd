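---
title: "Allosteric free energy from a single structure: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allosteric free energy from a single structure: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allofep)
```

## The model

`allofep` estimates, from one protein structure, how ligand binding at a
site redistributes configurational (entropic) free energy across the
protein — the thermodynamic signature of allosteric communication. The
model has three layers.

**1. Harmonic description of the free and bound systems.** The protein is
reduced to its C$\alpha$ trace and described by an elastic network: every
residue pair $(i,j)$ within 25 Å contributes a distance spring

$$E^{(0)} = \sum_{\text{pairs } i,j} k_{ij}\,(d_{ij} - d^0_{ij})^2,
\qquad k_{ij} = k_0 / (d^0_{ij})^6,$$

minimized at the input coordinates $d^0_{ij}$. The steep $1/d^6$ decay
concentrates stiffness in the first coordination shells while the long
25 Å cutoff retains the weak couplings that shape the low-frequency,
collective motions. Ligand binding is modeled *without the ligand*: all
residue pairs of the binding site $s$ are stiffened,

$$E^{(n)} = E^{(0)} + \alpha \sum_k V_{s_k}, \qquad
V_s = \tfrac12 \sum_{i<j \in s} k_{ij}(d_{ij}-d^0_{ij})^2,$$

with stiffening factor $\alpha = 100$ by default. Both systems share the
same reference coordinates, so every downstream difference is caused by
the restraint alone.

**2. Normal modes and the allosteric potential.** Both Hessians are
diagonalized exactly; the six rigid-body modes are removed and the ten
lowest internal modes retained per system (each system is summed over its
own mode set — no mode matching is attempted). For residue $i$ and mode
$\mu$ the *residue intensity*

$$\varepsilon_{\mu,i} = \sum_{j:\,d^0_{ij} < d_c} c\,
\lVert \mathbf{e}_{\mu,i} - \mathbf{e}_{\mu,j} \rVert^2$$

measures how strongly the mode deforms the residue's neighbourhood
($d_c = 11$ Å, $c = 1$ kcal/mol/Å²). It is the stiffness of a per-residue
harmonic "allosteric potential" in the mode amplitudes $\sigma_\mu$.

**3. Statistical mechanics per residue.** Treating the $\sigma_\mu$ as
Gaussian degrees of freedom gives a closed-form per-residue partition
function $z_i = \prod_\mu (2\pi k_BT / \varepsilon_{\mu,i})^{1/2}$, whence
the allosteric free energy of the free → bound transition

$$\Delta g_i = \frac{k_BT}{2} \sum_\mu
\ln \frac{\varepsilon^{\text{bound}}_{\mu,i}}{\varepsilon^{\text{free}}_{\mu,i}}.$$

Negative $\Delta g_i$ means the residue's neighbourhood moves less after
binding (stabilization), positive means increased local dynamics. Site
and protein averages, the sequential-binding modulation free energy
$\Delta\Delta g_i = \Delta g_i(0\!\to\!n) - \Delta g_i(0\!\to\!m)$ (whose
sign distinguishes positive from negative cooperativity), and the global
spectrum-level $\Delta G = \frac{k_BT}{2}\sum_\mu \ln
(\lambda^{\text{bound}}_\mu/\lambda^{\text{free}}_\mu)$ complete the
picture.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 25 | Å | elastic-network pair cutoff |
| `exponent` | 6 | — | force-constant decay $1/d^6$ |
| `k0` | 1 | energy·Å⁴ | global stiffness scale — cancels in all $\Delta g$, $\Delta G$ (eigenvalue ratios and mode shapes are scale-invariant) |
| `alpha` | 100 | — | site stiffening; $\Delta g$ magnitudes grow monotonically with it, profiles saturate at large values |
| `dc` | 11 | Å | intensity neighbourhood (about two coordination shells) |
| `c` | 1 | kcal/mol/Å² | intensity scale — cancels in $\Delta g$ |
| `nModes` | 10 | — | low-frequency modes per system |
| `kT` | 0.5961 | kcal/mol | thermal energy at 300 K |

The temperature is not dictated by the model; we adopt the room-
temperature convention $k_BT = 0.5961$ kcal/mol (300 K), which puts site
averages for real assemblies on the kcal/mol scale. Intra-site restraint
pairs are *not* subjected to the 25 Å cutoff: binding sites are compact,
and the restraint's meaning (an overwhelming ligand contact network) is
independent of the background network's range. The literal factor ½
inside the site term is kept (`siteTermHalf = TRUE`), so a site pair's
total spring constant is $k_{ij}(1 + \alpha/2)$; at $\alpha = 100$ the
distinction from $k_{ij}(1+\alpha)$ is a 2% rescaling of the restraint
with no qualitative effect, and the flag exposes the alternative.

## Numerical choices

* **Eigensolver.** Dense symmetric `eigen()`; exact eigenmodes rather
  than any truncated approximation. Mode vectors carry a deterministic
  sign (largest-magnitude component positive), making reruns
  byte-identical.
* **Rigid-mode removal.** Eigenvalues below $10^{-8}\lambda_{\max}$ are
  candidate rigid modes. Because site stiffening inflates
  $\lambda_{\max}$, a genuinely soft internal mode (a hinge torsion) can
  dip under the relative threshold; candidates are therefore classified
  by overlap with the analytic rigid-body subspace and only true rigid
  modes are removed. More than six zero modes on a connected structure,
  or a disconnected network, is an error (with the component sizes
  reported), not a warning.
* **Degenerate multiplets.** Symmetric oligomers produce (near-)
  degenerate eigenvalues whose individual eigenvectors are
  basis-dependent. Per-mode quantities inside a multiplet are therefore
  not individually meaningful; multiplet-summed $\Delta g$ contributions
  are, and the test suite checks that invariance explicitly.
* **Vanishing intensities.** A residue whose whole neighbourhood moves
  rigidly in a mode has $\varepsilon \approx 0$ and an unstable
  log-ratio. Intensities are floored at $10^{-12}\times$ the median
  positive intensity and the affected residues flagged; residues with no
  neighbour within $d_c$ at all are excluded (`NA`) rather than
  extrapolated.
* **Altloc / models.** Alternate locations resolve to the
  highest-occupancy conformer (ties by altloc letter); NMR bundles reduce
  by `modelPolicy` — first model, a specific model, or the arithmetic
  mean conformer.

## Design choices that were genuinely open

* **Two modulation formulas.** The sequential-binding free energy can be
  written as the difference of two free→bound profiles, or as the literal
  log-ratio $\frac{k_BT}{2}\sum_\mu \ln(\varepsilon^{(n)}
  \varepsilon^{(0)}/(\varepsilon^{(m)})^2)$. The two are not
  algebraically equal (the latter adds a second free→$m$ term). The
  difference form is the default — it is the quantity whose sign directly
  encodes cooperativity between the two binding events — and the
  log-ratio form is available via `formula = "logratio"`
  (the same name selects the spectrum-level analogue in `globalModulation`).
* **Site definitions.** Binding sites are either explicit residue lists
  or detected from ligand contacts: heavy-atom distance ≤ 4.5 Å when the
  full-atom record is available, C$\alpha$ distance ≤ cutoff + 3 Å when only
  the trace exists (the 3 Å allowance approximates side-chain reach).
  Published per-site free energies depend strongly on the exact residue
  membership, which literature descriptions rarely pin down; the contact
  rule here is a documented convention, and site membership should be
  inspected (it is written to the run log) before comparing numbers
  across studies.
* **Chain grouping.** "Homologous monomers" are operationalized as
  chains with ≥ 95% global sequence identity (Needleman–Wunsch via
  Biostrings, BLOSUM62); profiles are averaged per aligned position with
  the standard error across chains as the error band.
* **No mass weighting.** All C$\alpha$ get unit mass; modes are plain
  Hessian eigenvectors. Mass-weighting with a uniform residue mass would
  rescale all eigenvalues equally and leave every $\Delta g$ unchanged.

## What the synthetic fixtures do and do not show

The generators (`makeFixture`) produce an ideal helix, hard-sphere
globules, an exact C2 dimer, a two-domain hinge with a 3-residue linker,
and a deliberately disconnected pair. The hinge is the minimal allosteric
caricature: restraining a surface patch on one domain produces a
measurable, reproducible free-energy response in the other domain —
sign-correct (restrained site stabilized, $\Delta G \ge 0$) and
monotone in $\alpha$. Problem sizes in the tests are 8–60 residues with
10–50 modes, where dense diagonalization and the brute-force oracles
(finite-difference Hessians, double-loop intensities, quadrature
partition functions) are exact enough to pin every pipeline stage.

What toys cannot show: real proteins have native contact topologies,
secondary-structure stiffness anisotropy and oligomeric interfaces that
shape the low-mode spectrum; mode-count robustness of the profile is
noticeably higher for real folds than for random globules, whose spectra
lack a clean low-frequency gap. Passing the fixture suite therefore
validates the mathematics and the implementation, not the biological
accuracy of any particular site definition. Validation against published
whole-assembly site averages requires the original PDB assemblies, which
are not redistributed with the package; the relevant test activates when
the files are placed under `tests/testthat/structures/`.

## Known limitations

* Binding is modeled purely as site stiffening: no ligand chemistry, no
  distinction between agonists and antagonists sharing a site, no
  binding-affinity component (the $\Delta g$ is configurational work
  only).
* The harmonic approximation ignores anharmonicity and conformational
  change; results describe the basin around the input structure.
* Assemblies are taken as given — no symmetry expansion or assembly
  reconstruction; the biological unit must be the input file.
* Per-residue values inside degenerate multiplets of highly symmetric
  oligomers depend on the eigenbasis; compare multiplet sums or
  site/monomer averages.

## A worked example

```{r example, eval = FALSE}
fx <- makeFixture("two_domain_hinge", nResidues = 60, seed = 1,
                  dir = tempdir(), plantLigand = TRUE)
s <- readCalphaStructure(fx$structureFile)
site <- detectBindingSite(s, fx$manifest$ligandId, name = "SITEA")
res <- runAllostery(s, list(SITEA = site),
                    transitions = list(list(label = "0 -> 1xSITEA",
                                            nSites = "SITEA")),
                    outDir = tempfile("hinge_run"))
p <- res$results[["0 -> 1xSITEA"]]$profile
siteFreeEnergy(p, site)     # < 0: the restrained site is stabilized
proteinFreeEnergy(p)        # small: work is redistributed, not created
```
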