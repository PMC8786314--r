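# lipsite

Quantitative analysis of fatty-acid binding to pentameric ligand-gated ion
channels (pLGICs), built around the kind of data that established DHA
(docosahexaenoic acid, 22:6) as a state-dependent inhibitor of the model
channel ELIC while palmitic acid (PA, 16:0) is not: coarse-grained
membrane-protein trajectories, patch-clamp dose–response and decay tables,
and photoaffinity-labeling chromatogram areas.

The package is for computational membrane biophysicists and ion-channel
labs who want the full quantification chain as tested, reusable functions
rather than one-off scripts. The study's own microsecond trajectories and
recordings are not required: a seeded synthetic-data module generates every
input with known ground truth, which is also how the package validates its
estimators.

## What it computes

**Boundary lipid metric.** For lipid species *i*,

        B_i = ⟨ b_i / b_tot ⟩ / χ_i

where *b_i* counts molecules of species *i* whose minimum bead–protein
distance is within a 6 Å shell, *b_tot* all molecules in the shell, χ_i the
species mol fraction, and ⟨·⟩ a time average. B > 1 means enrichment at the
protein boundary, B < 1 depletion.

**Leaflet-resolved polar density and enhancement maps.** On a protein-
centered polar grid (Δr = 5 Å, Δθ = π/15, r ≤ 70 Å),

        ρ_B(r_i, θ_j) = ⟨ n_B(r_i, θ_j) ⟩ / (r_i Δr Δθ),
        ρ̃_B = ρ_B / (x_B s_B N_L ⟨A⟩⁻¹)

with *s_B* beads per molecule, *N_L* the (per-leaflet) lipid count and ⟨A⟩
the mean projected box area; ρ̃ = 1 is bulk density.

**Per-residue contact probabilities.** Fraction of frames in which any
species bead lies within 5 Å of any bead of a residue, per subunit and
averaged over the five subunits, with per-helix mean and cumulative
summaries.

**Density threshold affinity.** Annular-sector binding sites ("M1" and "M3"
sites, 10 < r < 40 Å, angular bounds from the M4 helix to the midpoint
between adjacent M1/M3 helices, ×5 subunits ×2 leaflets) are scored against
an area-matched bulk reference by

        ΔG = −k_B T ln[ P_site(n ≥ n*) / P_bulk(n ≥ n*) ]   (threshold)
        ΔG = −k_B T ln( ⟨n⟩_site / ⟨n⟩_bulk )               (mean ratio)

in kcal/mol at 323 K; negative is favorable.

**Markov gating simulations.** Fixed-step RK4 integration of dP/dt = PQ for
ligand-dependent gating schemes (resting / agonist-bound / pre-active /
open / desensitized states with inhibitor-bound copies), under inhibitor
pre-application protocols (pre-equilibrated initial state, 25 s agonist
step), reporting peak and steady-state current, decay kinetics, and class
occupancies.

**Ephys fitting.** Biexponential current decay with the amplitude-weighted
time constant (A1·τ1 + A2·τ2)/(A1 + A2), Hill EC50 with n = 2, and
sigmoidal IC50 fits.

**Photolabel quantification.** Molecular formula masses, diazirine
photoadduct masses (parent − N2), the labeled-peptide acceptance filter
(later retention time and < 10 ppm mass error), apparent labeling
efficiency AUC_labeled/(AUC_labeled + AUC_unlabeled), and replicate-wise
competition normalization.

## Worked example

Generate a membrane with a 3× DHA enrichment planted in the subunit-A M3
sector of both leaflets, then quantify it:

```r
library(lipsite)
spec <- membraneSpec(
  nFrames = 400, seed = 42, proteinClearance = 0, dynamics = "independent",
  enhancements = list(list(site = "M3", subunit = "A", leaflet = "both",
                           species = "DHA", factor = 3)))
gen  <- genMembraneTraj(spec)
traj <- gen$trajectory
lf   <- assignLeaflets(traj)
comp <- compositionTable(traj, lf)

boundaryMetric(traj, comp)
#> BoundaryResult: shell 6.0 A, 400 frames
#>  species         B        sem
#>      DHA 1.0624739 0.03335573
#>     POPC 1.0091426 0.00619660
#>     POPE 0.9874944 0.01186883
#>     POPG 0.9835714 0.01546627
```

The planted sector is at r 10–40 Å, which barely overlaps the 6 Å boundary
shell, so B stays near 1 for every species. The maps and site affinities
see it clearly:

```r
em <- enhancementMap(radialDensityMap(traj, lf, "DHA", "outer"), comp)
s  <- gen$groundTruth$plantedSectors[1, ]
sectorMeanEnhancement(em, s$rMin, s$rMax, s$thetaMin, s$thetaMax)
#> [1] 2.73

geo  <- defineSiteSectors(traj, list(M1 = 199:222, M3 = 256:280, M4 = 300:320))
st   <- siteTable(geo)
site <- st[st$site == "M3" & st$subunit == "A" & st$leaflet == "outer", ]
hS <- occupancyHistogram(traj, lf, site, "DHA")
hB <- bulkReferenceHistogram(traj, lf, "DHA", site$area, leaflet = "outer", seed = 7)
thresholdAffinity(hS, hB, estimator = "mean_ratio")
#> AffinityResult (mean_ratio): dG = -0.6794 kcal/mol at 323 K
```

The sector-mean enhancement reads ≈ 2.7–2.9 rather than exactly 3 because
the planted molecules come out of a finite lipid reservoir (the expected
value at these settings is 2.89); the mean-ratio ΔG estimates
−k_B·323·ln 3 = −0.705 kcal/mol. A gating simulation of inhibitor
pre-application with the shipped pre-active-stabilizing example scheme:

```r
sch <- buildScheme(exampleScheme("preactive"))
obs <- currentObservables(integrateProtocol(sch,
         gatingProtocol(agonist = 0.03, inhibitor = 1e-4, duration = 25, dt = 1e-5)))
obs[, c("peak", "steady_state", "weighted_tau", "preactive_final")]
#>    peak steady_state weighted_tau preactive_final
#> 1 0.107        0.051        6.764           0.507
```

100 µM inhibitor cuts the peak open probability to ~0.11 (0.55 without
inhibitor) and leaves half the channels in the pre-active state at the end
of the agonist step.

Configuration-driven runs (`runPipeline("config.yaml")`) chain these stages
with a provenance manifest; `inst/scripts/lipsite-run.R` is a thin
command-line wrapper around it.

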