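# flavoreact

Why does a flavoenzyme such as xenobiotic reductase B (XenB) reduce some
nitroaromatic substrates and ignore chemically similar ones? Answering that
question combines four strands of computational evidence, and `flavoreact`
implements the analysis layer for all of them:

1. **Conceptual-DFT reactivity descriptors.** From frontier orbital energies
   (ϵ<sub>HOMO</sub>, ϵ<sub>LUMO</sub>) and Koopmans' theorem (I = −ϵ<sub>H</sub>,
   A = −ϵ<sub>L</sub>) the package computes the HOMO–LUMO gap, electronegativity
   χ = (I+A)/2, global hardness η = (I−A)/2, electrophilicity ω = χ²/2η, the
   electrodonating and electroaccepting powers ω⁻ = (3I+A)²/16(I−A) and
   ω⁺ = (I+3A)²/16(I−A), and the net electrophilicity Δω± = ω⁺+ω⁻ (all eV).
2. **Hydride acceptor–donor (HAD) distances.** Per-frame distances from the
   FMN cofactor's N5 atom to reducible acceptor atoms of the ligand, their
   normalized distributions, and an explicit stable/unstable complex
   classification (bound fraction at a distance cutoff).
3. **Pose clustering.** Pairwise ligand heavy-atom RMSD over trajectory frames
   (after superposing each frame on the binding site), DBSCAN at ε = 1.5 Å /
   minPts = 5 on the precomputed matrix, medoid representative structures, and
   residues within 3 Å of the ligand.
4. **Non-covalent interaction (NCI) grids.** Promolecular densities as sums of
   exponential proatom shells, the reduced density gradient
   s = |∇ρ| / (2(3π²)^{1/3} ρ^{4/3}), and sign(λ₂)ρ classification of
   low-gradient points into attractive / van der Waals / repulsive contacts,
   exported as cube files. Point-charge electrostatic potential maps and net
   ring-current-strength (RCS) aromaticity bookkeeping round out the evidence.

A synthetic-data module generates enzyme–ligand trajectories with planted pose
modes and exact HAD-distance statistics, so the entire pipeline is testable
without any simulation output.

## Worked example

```r
library(flavoreact)

# 1. reactivity descriptors for the seven packaged nitroaromatics (eV)
prof <- reactivity_profile(nitroaromatic_orbitals())
format_profile(prof, decimals = 1, mode = "truncate")
#>  compound eps_homo eps_lumo gap chi eta omega omega_minus omega_plus net_electrophilicity
#>       TNT     -9.0     -3.5 5.5 6.2 2.7   7.1        10.5        4.3                 14.8
#>       DN6     -8.5     -3.0 5.5 5.7 2.7   6.0         9.2        3.4                 12.7
#>       DN4     -8.3     -2.8 5.5 5.5 2.7   5.6         8.7        3.1                 11.8
#>       4AD     -7.0     -2.6 4.4 4.8 2.2   5.2         7.9        3.1                 11.0
#>       2AD     -7.1     -2.8 4.3 4.9 2.1   5.6         8.4        3.4                 11.9
#>       TNB     -9.6     -3.7 5.9 6.6 2.9   7.4        11.1        4.5                 15.7
#>       NBZ     -8.1     -2.5 5.6 5.3 2.8   5.0         8.0        2.7                 10.7

# 2. benzene reference ring current: diatropic + paratropic components
net_ring_current(17.60, -4.95, label = "benzene")
#> benzene: net RCS 12.7 nA/T (diatropic +17.60, paratropic -4.95): aromatic

# 3. synthetic trajectory with two planted pose modes; cluster and classify
traj <- make_complex_trajectory(
  complex_recipe(n_frames = 80, pose_modes = separated_pose_modes(2), seed = 11))
m  <- ligand_rmsd_matrix(traj, "resname TNT and not element H",
                         "not resname TNT and not element H")
dbscan_poses(m)
#> DBSCAN (eps 1.50 A, minPts 5): 2 clusters, 0 noise / 80 frames
#> medoid frames: 5, 75

hs <- had_series(traj, "resname FMN and name N5",
                 list(N2 = "resname TNT and name N2"))
classify_stability(hs$N2)
#> stable (bound fraction 1.000 at cutoff 6.0 A, occupancy >= 0.80)

# 4. contact residues of the deterministic pocket fixture
contact_residues(make_pocket_complex(), "resname TNT")
#>   chain resid resname min_dist
#> 1     A    65     TYR     2.80
#> 2     A   129     LEU     2.90
#> 3     A   335     TYR     2.85
```

The descriptor table reads exactly as a practitioner would publish it: one
decimal, truncated, with the electron-poor trinitro compounds (TNB, TNT)
showing the largest electrophilicity and net electrophilicity — the compounds
against which the enzyme is most active. The clustering output recovers the
two planted binding poses with their medoid frames, and the stability call
reports the parameters that produced it.

`run_pipeline("run.yaml", "out/")` chains any subset of these stages from a
single YAML config and writes delimited tables, cube files and a parameter-
stamped plain-text report.

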