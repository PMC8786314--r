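---
title: "Quantifying fatty-acid binding sites in a pentameric channel: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fatty-acid binding sites in a pentameric channel: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipsite)
```

## The scientific problem

Free fatty acids modulate pentameric ligand-gated ion channels (pLGICs):
polyunsaturated species such as docosahexaenoic acid (DHA, 22:6) inhibit
agonist-evoked currents far more strongly than saturated species such as
palmitic acid (PA, 16:0). Whether that difference reflects selective
binding to protein sites — and which sites — is a quantitative question
that gets attacked from three sides: lipid–protein spatial statistics in
coarse-grained molecular dynamics (CGMD) of the channel in a model
membrane, macroscopic gating simulations that ask which non-conducting
state an inhibitor must stabilize to reproduce the electrophysiology, and
photoaffinity-labeling mass spectrometry that locates binding residues and
measures competition by the natural fatty acids. `lipsite` implements that
quantification chain for a pentameric channel such as ELIC in a
2:1:1 POPC:POPE:POPG membrane with 4 mol% free fatty acid.

This vignette explains each model, its assumptions, the tunable parameters,
and the numerical and design choices, in the package's own terms.

## Trajectory canonicalization

All spatial estimators assume a protein-centered frame with the membrane
normal along z. Because upstream simulation packages do not agree on how
frames are fitted, `alignFrames()` defines the convention explicitly:

* the origin is the centroid of the *transmembrane* protein beads, i.e.
  those within 25 Å of the bilayer midplane (the mean z of all lipid
  headgroup beads). Centering on the TM slab rather than the whole protein
  keeps the large extracellular domain from pulling the origin off the
  pore axis;
* each frame is rotated about z by the least-squares in-plane rotation
  superposing the protein beads onto a reference frame. The membrane
  normal is taken as z throughout, which is how coarse-grained membrane
  systems are built and barostatted;
* lipids are re-imaged into the protein-centered cell *after* the
  rotation, so that undoing a rigid in-plane rotation is exact; all
  distances downstream use minimum-image conventions under the per-frame
  box.

Leaflet assignment is per frame: a lipid whose mean headgroup-bead z lies
above the midplane is "outer", else "inner". Re-evaluating every frame
means flip-flop shows up as a label change rather than an error. Beads are
always binned by their own (x, y) while leaflet membership follows the
parent molecule, so a tail bead sagging past the midplane still counts
with its leaflet.

## Enrichment statistics

The **boundary lipid metric** `B_i = ⟨b_i/b_tot⟩/χ_i` counts lipid
*molecules* whose minimum bead–protein distance is within the shell cutoff
(default 6 Å, the coarse-grained first-shell distance). χ_i defaults to the
whole-membrane mol fraction; a per-leaflet variant exists because
single-tail fatty acids can distribute asymmetrically. Frames with an
empty shell are excluded from the average.

The **polar density map** counts *beads*: `ρ = ⟨n(r_i, θ_j)⟩/(r_i Δr Δθ)`
with Δr = 5 Å, Δθ = π/15 and r ≤ 70 Å by default. The bin-center
normalization `r_i Δr Δθ` equals the exact annular-sector area, so
`Σ ρ·area` reproduces the mean within-range bead count to machine
precision — a conservation identity the tests assert at 1e-6 relative
error. The θ = 0 axis is fixed to the subunit-A M4 azimuth so maps are
comparable across runs. Protein-occupied bins are reported as-is; masking
is a plotting concern.

The **enhancement map** divides ρ by the expected bulk density
`x_B s_B N_L/⟨A⟩`. For leaflet-resolved maps the default normalization is
per leaflet (x and N of that leaflet), so ρ̃ = 1 means "bulk of this
leaflet"; the whole-membrane variant is selectable. ⟨A⟩ is the raw
projected box area, not the lipid-accessible area — the simplest reading
of the normalization — which means a system with a protein of appreciable
cross-section shows bulk ρ̃ slightly above 1; the calibration tests
therefore run against the uniform-placement null described below, where
the identity ρ̃ = 1 is exact.

The two granularities — molecules for B, beads for ρ — are kept distinct
deliberately; they answer different questions (who is in the shell vs how
much lipid mass sits where).

## Contact probabilities

A residue–species contact exists in a frame when any species bead lies
within the cutoff (default 5 Å) of *any* bead of the residue, backbone or
sidechain. Probabilities are reported per subunit and as the five-subunit
mean; helix-level summaries give both the residue-mean ("averaged") and
the residue-sum ("cumulative") of the mean profile. Residue-mean is the
assumed meaning of a per-helix "average"; both are exported so the choice
is visible. Helix membership (M1–M4 residue ranges) is supplied by the
caller, never hard-coded.

## Binding sites and the density threshold affinity

The M1 and M3 intrasubunit sites are annular sectors in the protein-fixed
frame: radial bounds 10 < r < 40 Å; one angular boundary at the M4 helix
azimuth and the other midway between the same subunit's M1 (respectively
M3) helix and the adjacent subunit's M3 (respectively M1) helix. Helix
azimuths are time-averaged circular means of each helix's bead centroid
direction. The construction is five-fold symmetric and duplicated per
leaflet: 20 site instances, pairwise non-overlapping within a leaflet
(verified exhaustively in the tests).

Site occupancy histograms `P_site(n)` count species beads (of molecules in
the site's leaflet) inside the sector per frame. The bulk reference
`P_bulk(n)` must be area-matched; rather than requiring a separate
control simulation, the default estimator counts beads in randomly placed
area-matched annular sectors spanning a far annulus (50–70 Å) of the same
trajectory, pooled over frames and seeded placements. The sampling sectors
span the annulus radially with the angular width set by the area match
(a congruent 10–40 Å sector cannot fit inside a 50–70 Å annulus). When a
dedicated control trajectory is available, the same functions run on it
unchanged.

Two affinity estimators are first-class, because the exact
density-threshold convention is a modeling choice:

* threshold: `ΔG = −k_B T ln[P_site(n ≥ n*)/P_bulk(n ≥ n*)]` with
  `n* = floor(⟨n⟩_bulk) + 1` by default (the smallest integer strictly
  above the bulk mean);
* mean ratio: `ΔG = −k_B T ln(⟨n⟩_site/⟨n⟩_bulk)`, which has the clean
  closed form `−k_B T ln f` when the site density is f× bulk.

Units are kcal/mol with k_B = 0.0019872 kcal·mol⁻¹·K⁻¹ and T = 323 K by
default (the coarse-grained production temperature); negative ΔG is
favorable. A vanishing tail or mean yields a signed infinite-affinity
flag (`finite = FALSE`), never a silent number. Uncertainty across
replicate trajectories is mean ± SEM with n the replicate count;
within-trajectory standard errors use batch means (below).

## Gating simulations

Schemes are ligand-dependent continuous-time Markov models declared in
YAML: states with class tags (resting, agonist-bound, pre-active, open,
desensitized; inhibitor-bound copies flagged), transitions with rates in
s⁻¹ (or s⁻¹M⁻¹ when agonist- or inhibitor-dependent). The generator
matrix at given concentrations has nonnegative off-diagonals and zero row
sums; validation rejects duplicate or undeclared states, negative rates
and disconnected graphs by name.

Protocols are piecewise-constant concentration steps (default: a 25 s
agonist application) integrated by fixed-step fourth-order Runge-Kutta,
with the initial condition the pre-equilibration steady state obtained by
a null-space solve (the long-integration oracle in the tests confirms the
equivalence). A stepsize guard requires `dt·max|Q| < 0.1` and suggests a
compliant dt. Matrix-exponential propagation (`propagateExpm()`) is an
exact cross-check for stiff schemes, labeled as an extension — RK4 is the
production integrator. Current is `−ΣP(open states)` (inward negative);
observables include the peak, the steady state (mean of the last 10% of
the step), their ratio, a biexponential decay fit with weighted tau, and
the final pre-active (AF+AFI) and desensitized (AD+ADI …) occupancies.

The two shipped schemes are *placeholders with a documented phenotype*,
not fits: rates were chosen so that, with inhibitor pre-application, peak
current decreases monotonically with inhibitor concentration, current
decay accelerates and deepens, and near-complete peak inhibition coincides
with the stabilized class dominating at steady state — the qualitative
signature that either a pre-active-stabilizing or a
desensitized-stabilizing inhibitor can produce. Microscopic reversibility
is enforced on every binding/gating cycle (a 100× affinity gain for a
state is paid by 100× shifts in the inhibitor-layer gating equilibria).
The desensitized variant additionally includes a slow unliganded
desensitization pathway (R ⇌ D), because without some resting-accessible
desensitized state a desensitization-stabilizing inhibitor cannot reduce
the *peak* of a subsequent agonist response — pre-application must be able
to park channels somewhere non-conducting. Users reproducing a specific
published scheme supply their own rate file.

## Curve fitting

Exponential decay fits use multi-start Levenberg–Marquardt
(`minpack.lm`): time constants initialized on a log-spaced grid spanning
the window, lowest residual kept, components ordered by τ. The
single-exponential fallback is selected when the biexponential fails to
improve the residual sum of squares by a configurable factor (default
1.5×) or when the single fit is already at numerical zero — without the
second criterion a noiseless single exponential would be "improved" by
meaningless ratios of near-zero residuals. Constant traces are flagged
non-convergent with best-effort parameters rather than erroring. The
weighted time constant is `(A1τ1 + A2τ2)/(A1 + A2)`, scale-invariant in
the amplitudes.

Hill activation fits fix n = 2 (the convention for this channel's agonist
responses); inhibition fits use `y = 1/(1 + ([I]/IC50)^h)` with the floor
fixed at 0 and the top at 1 — normalized peaks start at 1 by construction,
and with no printed evidence of a non-zero floor the 0-floor model is the
parsimonious default (h free unless fixed).

## Photolabel quantification

Element masses are pinned in code: monoisotopic masses of the principal
isotopes, and conventional standard atomic weights for average masses
(S = 32.06, which is what makes the hexadecylthio adduct shift round to
257.5 Da). Diazirine photoadduct masses follow the N2-loss convention —
photolysis expels N2 and the carbene inserts — so the adduct mass is the
parent's monoisotopic mass minus 28.0061 Da; for the KK-242 reagent
(C17H21F3N2O3) this reproduces the 330.14 Da search modification without
any proton/charge adjustment, which is why that convention is the
package's documented choice. The labeled-peptide filter requires a later
retention time than the unlabeled partner (a hydrophobic adduct must
elute later on reverse phase) and < 10 ppm mass error. Apparent labeling
efficiency is AUC_labeled/(AUC_labeled+AUC_unlabeled) from extracted-ion
chromatograms — spectral processing upstream of the AUC table is out of
scope — and competition normalization divides by the same replicate's
control before any pooling, so replicate-scale differences (columns,
emitter tips, ionization) cancel exactly.

## The synthetic-data generator

`genMembraneTraj()` emulates the study system: a 160 × 160 Å bilayer with
176 POPC + 88 POPE + 88 POPG molecules per leaflet (2:1:1) plus 15 fatty
acids per leaflet (≈ 4 mol%), around a static five-fold scaffold of 20 TM
helix axes carrying subunit labels A–E and a configurable residue
numbering (defaults place M1 at 199–222, M2 at 228–250, M3 at 256–280,
M4 at 300–320, so residues like 264, 313, 318 are addressable). Diacyl
lipids carry 12 beads, fatty acids 3 (headgroup flagged); only the ratios
matter to the estimators.

Lipid anchors follow a target density field: uniform over the leaflet,
multiplied by the planted factor *f* inside enhancement sectors, zero
within a steric clearance radius around each helix axis (default 4 Å).
Dynamics are either independent redraws per frame (an exact uniform/
Poisson placement oracle) or a Metropolis random walk (step SD 10 Å per
1 ns frame, matching coarse-grained lipid diffusion of roughly
10⁻⁶ cm²/s) whose acceptance ratio `w(new)/w(old)` makes the stationary
density exactly proportional to the target — planting by reweighting
rather than by confining a whole number of molecules avoids quantizing
the planted density. Beads jitter around their anchor with SD 0.5 Å; the
jitter is kept small so molecule-level ground truth transfers to
bead-level estimands (a larger, more realistic intramolecular spread
would only blur sector edges by a few percent). The motion is a bounded
random walk, not physical diffusion — sufficient for time-average
estimators, and documented as non-physical.

Every generator output carries a ground-truth record: per-planted-sector
factor, the expected Eq.-style enhancement `f·κ` (κ < 1 accounts for the
finite lipid reservoir: planting enrichment somewhere depletes the same
leaflet's bulk, κ = A/(A + (f−1)·ΣA_sectors)), expected mean occupancies,
per-molecule leaflet labels, and the seed.

**What the calibration runs show — and what they do not.** The null and
planted-recovery tests run with clearance 0 ("no protein preference") and
independent frames, because that is the regime where the estimands are
exact: uniform placement gives B = 1 and bulk ρ̃ = 1 identically, and a
planted sector's mean-ratio ΔG is exactly −k_B T ln f. Passing them shows
the estimator chain is unbiased and correctly normalized at the study's
bin sizes and sample counts. It does not show that a real membrane's
correlations (protein-excluded area, lipid–lipid structure, slow
diffusion) are captured — they are deliberately not. The random-walk mode
exists so the qualitative tests (leaflet ordering of site affinities, M3
contact ranking, batch-SEM behaviour) run under temporal correlation.

## Statistical choices

Per-frame series from diffusing lipids are autocorrelated, so standard
errors use the batch-means method (default 20 contiguous batches), which
is consistent under correlation without estimating an autocorrelation
time. The uniform-null acceptance check compares every bulk bin's ρ̃ to 1
at 3 SEM using 10 Å × 36° calibration bins over the 50–70 Å annulus: at
500 frames these bins hold enough fatty-acid counts for a per-bin
three-sigma comparison to be meaningful, while production-resolution
(5 Å × 12°) bins are checked through their pooled bulk mean. Planted
recovery uses factors 0.5, 2 and 3 at 1500 frames, planting one M3 sector
in both leaflets — enough statistics for the 10% recovery tolerance
without making the planted area so large that the reservoir correction κ
dominates.

## Degenerate inputs and failure modes

Species absent from the membrane are undefined-metric errors; zero bulk
density is an undefined-normalization error; both-zero AUC pairs and
A1 + A2 = 0 weighted taus are undefined; empty tails in the threshold
affinity produce signed infinity flags; constant traces and flat dose–
response tables are flagged or rejected as unidentifiable; bin widths that
do not divide their range evenly are configuration errors, and a map
radius beyond half the box logs a warning. Pipeline configurations are
validated before any stage runs (missing inputs, unknown stages, missing
seeds on stochastic stages).

## Problem sizes used in validation

The shipped test suite and calibration runs use the full membrane
composition at 30–500 frames for structural checks, 1500 frames for
planted-factor recovery, 50–150 fitting replicates for noise-recovery
statistics, and 25 s gating protocols at dt = 10 µs — sizes chosen so the
whole suite characterizes the estimators well while running in about a
minute on a laptop core.

## Known limitations

* The generator's protein is static and its helices are straight vertical
  axes; tilt, kinks and conformational flexibility are absent.
* Lipid dynamics are diffusive only in the mean; no inter-lipid
  interactions, no flip-flop unless constructed explicitly.
* The enhancement normalization uses the raw box area (see above); with
  steric exclusion enabled, bulk ρ̃ sits a few percent above 1 by
  construction.
* Gating schemes integrate deterministic macroscopic occupancies; there
  is no stochastic single-channel simulation and no rate fitting to
  experimental traces.
* MS quantification starts from extracted-ion-chromatogram areas;
  peptide-spectrum matching, deconvolution and fragment annotation are
  upstream tools' territory.
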