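---
title: "Methods: reactivity and trajectory analysis of flavoenzyme-nitroaromatic complexes"
author: "flavoreact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flavoenzyme-nitroaromatic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavoreact)
```

## The scientific question

Flavoenzymes of the Old Yellow Enzyme family, such as xenobiotic reductase B
(XenB), transfer a hydride from the N5 atom of their FMN cofactor to a bound
substrate. XenB is strikingly selective among chemically similar
nitroaromatics: it reduces 2,4,6-trinitrotoluene (TNT), 2,4-dinitrotoluene,
4-amino-2,6-dinitrotoluene and 1,3,5-trinitrobenzene, but not
2,6-dinitrotoluene, 2-amino-4,6-dinitrotoluene or nitrobenzene. Two families
of factors can explain this: *binding* factors (does the enzyme hold the
ligand in a stable, reactive pose near the cofactor?) and *reactivity*
factors (is the ligand intrinsically a good hydride acceptor?). `flavoreact`
implements the quantitative analysis for both, leaving the expensive
upstream computations — molecular dynamics and electronic structure — to
dedicated engines whose scalar or structural outputs this package consumes.

## Global reactivity descriptors

Given frontier orbital energies in eV, Koopmans' theorem supplies the
ionization potential $I = -\epsilon_H$ and electron affinity
$A = -\epsilon_L$, from which `reactivity_profile()` derives:

$$\Delta\epsilon = \epsilon_L - \epsilon_H, \qquad
\chi = \tfrac{I+A}{2}, \qquad \eta = \tfrac{I-A}{2}, \qquad
\omega = \frac{\chi^2}{2\eta},$$
$$\omega^- = \frac{(3I+A)^2}{16(I-A)}, \qquad
\omega^+ = \frac{(I+3A)^2}{16(I-A)}, \qquad
\Delta\omega^\pm = \omega^+ + \omega^-.$$

The electrodonating ($\omega^-$) and electroaccepting ($\omega^+$) powers are
the standard quadratic-interpolation forms; they satisfy the exact identity
$\omega^- - \omega^+ = \chi$, which the test suite asserts to $10^{-9}$ eV
along with $2\eta\omega = \chi^2$ and first-order homogeneity in the
energies. A degenerate gap is a hard error because $\omega$, $\omega^\pm$
divide by the hardness.

Two presentation details matter in practice and are explicit options rather
than silent behavior:

* **Truncation vs rounding.** `format_profile()` defaults to truncation
  toward zero because published one-decimal descriptor tables in this area
  reproduce cell-for-cell from the stated orbital energies under truncation
  (e.g. $\omega^- = 10.571 \to$ "10.5"), not under round-half-even. Both
  modes are available; a $10^{-9}$ guard treats values a few ulp below an
  exact decimal (such as $-3.7 - (-9.6) = 5.8999\ldots95$) as exact.
* **Tie-tolerant ranking.** `rank_compounds()` orders compounds by a chosen
  descriptor and merges values within `tie_tolerance` into tie groups, so a
  published ordering with explicit ties ("DN6 == DN4") is a testable object.
  Ranking the gap is done on the one-decimal published gap column: the
  printed gaps were evidently computed from unrounded energies, and
  recomputing them from the rounded $\epsilon$ columns would collapse
  near-ties that the published ordering distinguishes.

## HAD distances and complex stability

`had_series()` measures per-frame Euclidean distances from a single donor
atom (FMN N5) to named acceptor atoms — nitro nitrogens or reducible ring
carbons, supplied as selection expressions; the package deliberately does
*no* bond perception or automatic nitro-group detection.
`distance_distribution()` bins a series into a normalized histogram
(default bin 0.1 Å, enough to resolve the ~0.2 Å spreads of a bound state
without noise domination; histograms only, no kernel density estimates).

"Stable complex" is usually an ocular judgment on distance traces. Here it
is an explicit, reported criterion: `classify_stability()` calls a complex
stable when the fraction of frames with distance at or below `cutoff`
(default 6.0 Å) reaches `occupancy` (default 0.8). Both defaults are design
choices, not measurements: 6 Å comfortably contains the bound-state
distributions (3–5 Å) while excluding a ligand that has left the pocket, and
0.8 tolerates transient excursions without calling a dissociated ligand
bound. Both are parameters of every output.

## Pose clustering

`ligand_rmsd_matrix()` computes entry $(i,j)$ as the ligand heavy-atom RMSD
between frames $i$ and $j$ after superposing frame $j$ onto frame $i$ by a
*fit* selection (typically protein heavy atoms). The ligand is not
re-fitted: pose changes relative to the binding site are exactly what the
matrix should measure. Because the fit makes raw entries slightly
asymmetric, the matrix is symmetrized by averaging. Hydrogens are rejected
from the ligand selection outright.

`dbscan_poses()` is classic DBSCAN on the precomputed matrix with the
field-standard defaults ε = 1.5 Å and minPts = 5. Three details differ among
published implementations and are fixed here deliberately:

* neighbor counts *include the point itself*, so minPts = 5 means "at least
  4 others within ε";
* "at least five points per cluster" is implemented as the minPts density
  parameter, not as post-hoc filtering;
* a border point reachable from several clusters joins the cluster of its
  *lowest-labeled* core neighbor, making the classic order-dependence
  deterministic. Cluster labels use the R convention 0 = noise, 1..k.

Representative structures are medoids — the member minimizing summed RMSD to
its cluster, ties broken by lowest frame id — the standard deterministic
choice when only a distance matrix is available. `contact_residues()`
reports residues with any atom (hydrogens included) within 3 Å of any ligand
atom, the shell conventionally highlighted around bound nitroaromatics.

The whole stack is verified against a brute-force restatement of the DBSCAN
definition (core points via neighborhood counts, clusters via connected
components of the core graph) on random distance matrices, and by parameter
recovery on synthetic trajectories with 1–3 planted pose modes.

## Promolecular NCI grids

The NCI index locates weak interactions where the reduced density gradient

$$s = \frac{|\nabla\rho|}{2(3\pi^2)^{1/3}\rho^{4/3}}$$

is small, and classifies them by the sign of $\lambda_2$ (the middle
eigenvalue of the density Hessian) times $\rho$: attractive
($\mathrm{sign}(\lambda_2)\rho < -t$), van der Waals ($|\cdot| \le t$),
repulsive ($> t$). `flavoreact` evaluates these fields on promolecular
densities — sums of spherical free-atom densities — with *analytic*
gradients and Hessians accumulated from the same exponential terms; finite
differences appear only as a test oracle.

The packaged proatom set (`default_proatom_model()`) represents each atom as
exponential shells $c\,e^{-r/\zeta}$ normalized to their electron counts.
Core shells take Slater-rule screened decay lengths; the valence shell takes
its decay from the exact asymptotic law $\rho \sim e^{-2\sqrt{2 I_p}\,r}$
with $I_p$ the first ionization energy. The tail choice matters: overly
steep valence shells (e.g. raw Slater valence exponents) shrink the low-$s$
basin between non-bonded atoms to a sliver that a 0.15 Å grid can miss,
whereas ionization-scaled tails reproduce the familiar picture — a contiguous
van der Waals band between two rings stacked at 3.4 Å. Hydrogen is the exact
ground-state density $e^{-2r}/\pi$. The set covers H, C, N, O, P, S and is
plain data: any per-element table of $(c, \zeta)$ pairs can be swapped in.

Numerical choices: all NCI internals are atomic units with conversion at the
interface (coordinates Å everywhere else; cube files are written in Bohr per
the format's convention); default grid spacing 0.15 Å balances resolution
against cost at desk scale; $\lambda_2$ comes from a vectorized closed-form
symmetric-3×3 eigenvalue solver (cross-checked against `eigen()`); the
retention and category thresholds $s_{\max} = 0.5$ and $t = 0.01$ a.u.
follow common promolecular-NCI practice and are arguments everywhere.
Structures without hydrogens (common for heavy-atom trajectory frames) are
accepted with a message, since the promolecular sum remains well defined.

## Electrostatic potential maps and ring currents

`point_charge_esp()` evaluates $V(\mathbf r) = \sum_a q_a/|\mathbf r -
\mathbf R_a|$ from user-supplied partial charges (e.g. RESP): a monopole
approximation that reproduces the qualitative map — negative potential
pooled at nitro oxygens, positive over the electron-poor ring — without any
wavefunction. `esp_extrema()` restricts to a van der Waals shell band
(Bondi-type radii, default 1.2–2.0× the radius) and reports the extrema with
their nearest atoms. No multipoles beyond the monopole are attempted.

Ring-current bookkeeping is scalar arithmetic on externally computed
integrated current strengths: net RCS = diatropic (≥ 0) + paratropic (≤ 0)
components in nA/T, classified aromatic / antiaromatic / non-aromatic with
an explicit near-zero band of half-width $z$ = 1 nA/T (strict inequalities
at the boundary). The benzene reference components 17.60 and −4.95 nA/T give
a net 12.65, displayed as 12.7 under half-up rounding — the display
convention is half-up (with the same $10^{-9}$ float guard) because that is
how the reference value is conventionally quoted.

## The synthetic-data generator

`make_complex_trajectory()` emulates the *geometry* of a flavoenzyme binding
pocket, not its physics. A static scaffold holds an FMN-like plane (donor N5
at the origin) and four named pocket residues; a rigid, planar TNT-like
ligand (16 heavy atoms + 5 hydrogens, ring C1–C6, nitro groups named by
carbon) stacks parallel to the cofactor plane. Per frame a pose mode is
drawn by weight, the target direction from N5 is jittered with isotropic
Gaussian noise, and the acceptor nitrogen is placed at a distance drawn from
$N(\mu_{HAD}, \sigma_{HAD})$ along that direction. This construction makes
the realized HAD distribution carry exactly the requested moments while the
lateral mode structure drives pose clustering; an escape option grows the
distance linearly after a chosen frame to model a dissociating ligand.

Defaults encode the study conditions: frames every 0.02 ns (50 per ns), HAD
mean 3.5 Å and sd 0.2 Å for a bound complex;
`recipe_full_production()` provides the full 200 ns / 10,000-frame sampling
plan, while tests run 500-frame recipes (and 40 frames per planted mode for
cluster recovery) so the whole suite completes in seconds.
`separated_pose_modes(k)` places 1–3 modes by rotating the nominal acceptor
direction about the donor, keeping targets on the nominal-distance sphere so
mode separations are true chord lengths (≥ 4 Å) regardless of the HAD
distribution. Generation is bitwise deterministic under the recipe seed and
leaves the global RNG stream untouched.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: there is no force field, no solvent, no protein
flexibility and no dynamics (poses are sampled independently, not
propagated); the ligand moves by rigid translation only; real trajectories
have correlated frames, anisotropic pose basins and conformational exchange.
The generator demonstrates that the *analysis* recovers planted truth, not
that any particular enzyme behaves this way.

## Orchestration

`run_pipeline()` reads a YAML run configuration, checks every referenced
input before any computation, runs only the requested stages, and writes
delimited tables, cube files and a plain-text report in which every number
is accompanied by the parameters that produced it (ε, minPts, cutoffs,
thresholds, bin widths, seeds). Given the same config and inputs the report
body is byte-identical across runs. The package is an R library first: the
exported functions and this vignette are its interface, and the pipeline
function is the single entry point scripts should call.

## Known limitations

* The published per-compound trajectory figures and NCI isosurfaces from the
  original 200 ns simulations are not reproducible here: those trajectories
  and wavefunctions are not distributed, so the corresponding claims are
  covered by property-based tests and the in-table numeric targets instead.
* Promolecular densities are a superposition approximation: they support the
  topological NCI analysis but not energetics, and the packaged proatom set
  is a deliberately simple two-to-three-shell model.
* The PDB dialect is minimal (ATOM/HETATM/MODEL/ENDMDL; no altloc, insertion
  codes, or mmCIF; no binary trajectory formats), and the selection grammar
  is conjunctions of simple predicates only — enough to express every
  selection the analyses need, small enough to test exhaustively.
* Table cells that depend on unrounded upstream energies (e.g. a published
  net electrophilicity of 14.7 where the rounded orbital energies give
  14.89) cannot be reproduced from rounded inputs; the package documents the
  discrepancy rather than fitting to it.
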