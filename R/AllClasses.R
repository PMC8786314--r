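## S4 container classes for the package.

#' Coarse-grained membrane trajectory
#'
#' Holds a bead metadata table, per-frame coordinates (in Angstrom), per-frame
#' orthorhombic box lengths, and the canonicalization state. Coordinates are
#' stored as an `n_beads x 3 x n_frames` array. When `aligned` is `TRUE` the
#' centroid of the transmembrane protein beads sits at the origin in every
#' frame and the membrane normal is the z axis.
#'
#' The bead table carries one row per bead with columns `bead_index`,
#' `molecule_id`, `species`, `residue_id`, `residue_name`, `subunit`,
#' `bead_name`, `is_protein`, `is_headgroup`.
#'
#' @slot beads data.frame of per-bead metadata (see Details).
#' @slot coords numeric array `n_beads x 3 x n_frames`, Angstrom.
#' @slot box numeric matrix `n_frames x 3`, box lengths in Angstrom.
#' @slot frameInterval numeric, time between stored frames in ns.
#' @slot aligned logical, whether frames are protein-centered and z-normal.
#' @exportClass CGTrajectory
setClass("CGTrajectory",
  representation(beads = "data.frame", coords = "array", box = "matrix",
                 frameInterval = "numeric", aligned = "logical"))

setValidity("CGTrajectory", function(object) {
  b <- object@beads
  need <- c("bead_index", "molecule_id", "species", "residue_id",
            "residue_name", "subunit", "bead_name", "is_protein",
            "is_headgroup")
  miss <- setdiff(need, names(b))
  if (length(miss))
    return(paste("bead table missing columns:", paste(miss, collapse = ", ")))
  if (!identical(as.integer(b$bead_index), seq_len(nrow(b))))
    return("bead_index must be unique and contiguous starting at 1")
  d <- dim(object@coords)
  if (length(d) != 3L || d[1] != nrow(b) || d[2] != 3L)
    return("coords must be an n_beads x 3 x n_frames array")
  if (nrow(object@box) != d[3] || ncol(object@box) != 3L)
    return("box must be an n_frames x 3 matrix")
  if (any(object@box <= 0)) return("box lengths must be positive")
  if (any(b$is_protein)) {
    su <- unique(b$subunit[b$is_protein])
    if (length(su) != 5L)
      return(sprintf("pentamer inputs need 5 protein subunits, found %d",
                     length(su)))
  }
  TRUE
})

#' Per-frame leaflet assignment of lipid molecules
#'
#' @slot moleculeId integer vector of lipid molecule ids (one per row).
#' @slot leaflet character matrix `n_molecules x n_frames` of
#'   `"outer"`/`"inner"` labels.
#' @exportClass LeafletAssignment
setClass("LeafletAssignment",
  representation(moleculeId = "integer", leaflet = "matrix"))

setValidity("LeafletAssignment", function(object) {
  if (length(object@moleculeId) != nrow(object@leaflet))
    return("one leaflet row per molecule required")
  if (!all(object@leaflet %in% c("outer", "inner")))
    return("leaflet labels must be 'outer' or 'inner'")
  TRUE
})

#' Membrane composition summary
#'
#' Per-species mol fractions, beads per molecule, and lipid counts (whole
#' membrane and per leaflet), plus the time-averaged projected box area used
#' for bulk-density normalization.
#'
#' @slot table data.frame with columns `species`, `nMol`, `molFraction`,
#'   `beadsPerMol`, `nMolOuter`, `nMolInner`.
#' @slot nLipids integer, total lipid molecule count.
#' @slot meanArea numeric, time-averaged projected box area (Angstrom^2).
#' @exportClass CompositionTable
setClass("CompositionTable",
  representation(table = "data.frame", nLipids = "integer",
                 meanArea = "numeric"))

setValidity("CompositionTable", function(object) {
  tb <- object@table
  if (abs(sum(tb$molFraction) - 1) > 1e-8)
    return("mol fractions must sum to 1")
  if (any(tb$beadsPerMol < 1)) return("beadsPerMol must be >= 1")
  if (sum(tb$nMolOuter + tb$nMolInner) != object@nLipids)
    return("per-leaflet counts must sum to the whole-membrane count")
  TRUE
})

#' Boundary lipid metric result
#'
#' @slot table data.frame with per-species `B` and its standard error.
#' @slot series numeric matrix `n_frames x n_species` of per-frame boundary
#'   fractions b_i/b_tot.
#' @slot shellCutoff numeric, boundary shell cutoff in Angstrom.
#' @slot nFrames integer, frames entering the average.
#' @exportClass BoundaryResult
setClass("BoundaryResult",
  representation(table = "data.frame", series = "matrix",
                 shellCutoff = "numeric", nFrames = "integer"))

#' Leaflet-resolved polar density map
#'
#' Time-averaged bead density rho (beads Angstrom^-2) of one lipid species in
#' one leaflet, on a polar grid centered on the channel pore.
#'
#' @slot species character, lipid species token.
#' @slot leaflet character, `"outer"` or `"inner"`.
#' @slot rEdges numeric radial bin edges (Angstrom).
#' @slot thetaEdges numeric angular bin edges (radians).
#' @slot rho numeric matrix `n_r x n_theta` of densities.
#' @slot nFrames integer.
#' @slot perFrame matrix of per-frame bin counts (`n_frames x n_bins`,
#'   bins in column-major grid order) or a 0x0 matrix when not retained.
#' @exportClass DensityMap
setClass("DensityMap",
  representation(species = "character", leaflet = "character",
                 rEdges = "numeric", thetaEdges = "numeric", rho = "matrix",
                 nFrames = "integer", perFrame = "matrix"))

setValidity("DensityMap", function(object) {
  if (any(object@rho < 0)) return("rho must be nonnegative")
  dr <- diff(object@rEdges); dt <- diff(object@thetaEdges)
  if (max(abs(dr - dr[1])) > 1e-9 || max(abs(dt - dt[1])) > 1e-9)
    return("bin widths must be uniform")
  if (!identical(dim(object@rho),
                 c(length(object@rEdges) - 1L, length(object@thetaEdges) - 1L)))
    return("rho dimensions must match bin edges")
  TRUE
})

#' Bulk-normalized polar enhancement map
#'
#' Same grid as [DensityMap-class]; values are the dimensionless enhancement
#' rho~ (1 = bulk density, >1 enrichment, <1 depletion).
#'
#' @slot rhoTilde numeric matrix of enhancement values.
#' @slot bulkDensity numeric, expected bulk bead density used for
#'   normalization (beads Angstrom^-2).
#' @exportClass EnhancementMap
setClass("EnhancementMap", contains = "DensityMap",
  representation(rhoTilde = "matrix", bulkDensity = "numeric"))

#' Per-residue lipid contact probabilities
#'
#' @slot profile data.frame with one row per residue x subunit:
#'   `residue_id`, `residue_name`, `subunit`, `probability`.
#' @slot meanProfile data.frame with the cross-subunit mean per residue.
#' @slot species character, lipid species analyzed.
#' @slot cutoff numeric, contact cutoff in Angstrom.
#' @slot nFrames integer.
#' @exportClass ContactProfile
setClass("ContactProfile",
  representation(profile = "data.frame", meanProfile = "data.frame",
                 species = "character", cutoff = "numeric",
                 nFrames = "integer"))

setValidity("ContactProfile", function(object) {
  p <- object@profile$probability
  if (any(p < 0 | p > 1)) return("probabilities must lie in [0,1]")
  TRUE
})

#' Annular-sector binding-site geometry
#'
#' One row per site instance (site x subunit x leaflet). Angular bounds are
#' in the protein-fixed frame; `thetaMin` -> `thetaMax` is counter-clockwise.
#'
#' @slot sites data.frame with columns `site`, `subunit`, `leaflet`, `rMin`,
#'   `rMax`, `thetaMin`, `thetaMax`, `area`.
#' @exportClass SiteGeometry
setClass("SiteGeometry", representation(sites = "data.frame"))

setValidity("SiteGeometry", function(object) {
  s <- object@sites
  if (any(s$rMin >= s$rMax)) return("rMin must be < rMax")
  TRUE
})

#' Bead-count occupancy histogram
#'
#' Distribution over frames of the number of species beads found inside a
#' region (a binding-site sector or an area-matched bulk reference region).
#'
#' @slot counts numeric vector; element k is the number of frames (or frame x
#'   placement samples) with exactly k-1 beads in the region.
#' @slot nFrames integer, number of samples pooled.
#' @slot region character description of the counting region.
#' @slot species character.
#' @slot area numeric region area (Angstrom^2).
#' @exportClass OccupancyHistogram
setClass("OccupancyHistogram",
  representation(counts = "numeric", nFrames = "integer", region = "character",
                 species = "character", area = "numeric"))

setValidity("OccupancyHistogram", function(object) {
  if (abs(sum(object@counts) - object@nFrames) > 1e-6)
    return("counts must sum to nFrames")
  if (any(object@counts < 0)) return("counts must be nonnegative")
  TRUE
})

#' Density threshold affinity result
#'
#' @slot deltaG numeric, kcal/mol (negative = favorable); `Inf`/`-Inf` when a
#'   tail probability vanishes (see `finite`).
#' @slot estimator character, `"threshold"` or `"mean_ratio"`.
#' @slot nStar integer threshold used (NA for the mean-ratio estimator).
#' @slot temperature numeric, K.
#' @slot finite logical, FALSE when the estimate is an infinite-affinity flag.
#' @exportClass AffinityResult
setClass("AffinityResult",
  representation(deltaG = "numeric", estimator = "character",
                 nStar = "integer", temperature = "numeric",
                 finite = "logical"))

#' Ligand-dependent Markov gating scheme
#'
#' @slot states data.frame with columns `name`, `conducting`, `class`,
#'   `inhibitorBound`.
#' @slot transitions data.frame with columns `from`, `to`, `rate`, `ligand`
#'   (`"none"`, `"agonist"` or `"inhibitor"`); ligand-dependent rates are in
#'   s^-1 M^-1, others in s^-1.
#' @exportClass KineticScheme
setClass("KineticScheme",
  representation(states = "data.frame", transitions = "data.frame"))

#' Concentration-step protocol for gating simulations
#'
#' @slot preAgonist numeric, agonist concentration (M) during pre-equilibration.
#' @slot preInhibitor numeric, inhibitor concentration (M) during
#'   pre-equilibration.
#' @slot steps data.frame with columns `duration` (s), `agonist` (M),
#'   `inhibitor` (M).
#' @slot dt numeric integration step (s).
#' @exportClass GatingProtocol
setClass("GatingProtocol",
  representation(preAgonist = "numeric", preInhibitor = "numeric",
                 steps = "data.frame", dt = "numeric"))

setValidity("GatingProtocol", function(object) {
  if (any(object@steps$duration <= 0)) return("step durations must be > 0")
  if (object@dt <= 0) return("dt must be > 0")
  TRUE
})

#' Integrated state-occupancy trajectory
#'
#' @slot time numeric time grid (s).
#' @slot prob numeric matrix `n_time x n_states` of state probabilities.
#' @slot scheme the [KineticScheme-class] integrated.
#' @slot stepIndex integer protocol-step index per time point.
#' @exportClass StateTrajectory
setClass("StateTrajectory",
  representation(time = "numeric", prob = "matrix", scheme = "KineticScheme",
                 stepIndex = "integer"))

#' Biexponential decay fit
#'
#' @slot A1,A2 numeric amplitudes (normalized current units).
#' @slot tau1,tau2 numeric time constants (s); `A2 = 0, tau2 = NA` when the
#'   single-exponential fallback was selected.
#' @slot offset numeric baseline offset.
#' @slot weightedTau numeric amplitude-weighted time constant (s).
#' @slot rss numeric residual sum of squares.
#' @slot converged logical.
#' @slot model character, `"biexponential"` or `"single"`.
#' @exportClass DecayFit
setClass("DecayFit",
  representation(A1 = "numeric", tau1 = "numeric", A2 = "numeric",
                 tau2 = "numeric", offset = "numeric", weightedTau = "numeric",
                 rss = "numeric", converged = "logical", model = "character"))

#' Dose-response fit (Hill EC50 or inhibition IC50)
#'
#' @slot ec50 numeric half-maximal concentration (M).
#' @slot ec50SE numeric standard error of `ec50`.
#' @slot hill numeric Hill slope (fixed 2 for agonist activation by default).
#' @slot rmax numeric fitted maximal response (1 for normalized inhibition
#'   curves with the floor fixed at 0).
#' @slot kind character, `"EC50"` or `"IC50"`.
#' @slot rss numeric residual sum of squares.
#' @slot data data.frame of the fitted points (`conc`, `response`).
#' @exportClass DoseResponseFit
setClass("DoseResponseFit",
  representation(ec50 = "numeric", ec50SE = "numeric", hill = "numeric",
                 rmax = "numeric", kind = "character", rss = "numeric",
                 data = "data.frame"))
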