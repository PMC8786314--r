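## Generics and accessors.

#' Number of frames in an object
#' @param x a trajectory, map or histogram object.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @describeIn nFrames frames stored in a trajectory.
#' @export
setMethod("nFrames", "CGTrajectory", function(x) dim(x@coords)[3])

#' @describeIn nFrames frames averaged into a density map.
#' @export
setMethod("nFrames", "DensityMap", function(x) x@nFrames)

#' @describeIn nFrames samples pooled into an occupancy histogram.
#' @export
setMethod("nFrames", "OccupancyHistogram", function(x) x@nFrames)

#' Bead metadata table of a trajectory
#' @param x a [CGTrajectory-class].
#' @return data.frame with one row per bead.
#' @export
setGeneric("beadTable", function(x) standardGeneric("beadTable"))

#' @rdname beadTable
#' @export
setMethod("beadTable", "CGTrajectory", function(x) x@beads)

#' Per-frame coordinates of a trajectory
#' @param x a [CGTrajectory-class].
#' @param frame optional frame index; when given, returns an `n_beads x 3`
#'   matrix for that frame.
#' @return coordinate array or single-frame matrix (Angstrom).
#' @export
setGeneric("trajCoords", function(x, frame = NULL) standardGeneric("trajCoords"))

#' @rdname trajCoords
#' @export
setMethod("trajCoords", "CGTrajectory", function(x, frame = NULL) {
  if (is.null(frame)) x@coords else x@coords[, , frame, drop = TRUE]
})

#' Whether a trajectory is protein-centered and z-aligned
#' @param x a [CGTrajectory-class].
#' @return logical.
#' @export
setGeneric("isAligned", function(x) standardGeneric("isAligned"))

#' @rdname isAligned
#' @export
setMethod("isAligned", "CGTrajectory", function(x) x@aligned)

#' Site-instance table of a sector geometry
#' @param x a [SiteGeometry-class].
#' @return data.frame with one row per site instance.
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @rdname siteTable
#' @export
setMethod("siteTable", "SiteGeometry", function(x) x@sites)

#' Free-energy value of an affinity result
#' @param x an [AffinityResult-class].
#' @return numeric, kcal/mol (can be `Inf`/`-Inf`, see the `finite` slot).
#' @export
setGeneric("deltaG", function(x) standardGeneric("deltaG"))

#' @rdname deltaG
#' @export
setMethod("deltaG", "AffinityResult", function(x) x@deltaG)

#' Amplitude-weighted time constant of a decay fit
#' @param x a [DecayFit-class].
#' @return numeric, seconds.
#' @export
setGeneric("fittedWeightedTau", function(x) standardGeneric("fittedWeightedTau"))

#' @rdname fittedWeightedTau
#' @export
setMethod("fittedWeightedTau", "DecayFit", function(x) x@weightedTau)

## ---- show methods ----

setMethod("show", "CGTrajectory", function(object) {
  b <- object@beads
  cat(sprintf("CGTrajectory: %d beads (%d protein), %d frames, %s\n",
              nrow(b), sum(b$is_protein), dim(object@coords)[3],
              if (object@aligned) "aligned" else "unaligned"))
  sp <- table(b$species[!b$is_protein])
  if (length(sp))
    cat("  lipid beads:", paste(sprintf("%s=%d", names(sp), sp),
                                collapse = ", "), "\n")
  cat(sprintf("  box (frame 1): %.1f x %.1f x %.1f A, frame interval %g ns\n",
              object@box[1, 1], object@box[1, 2], object@box[1, 3],
              object@frameInterval))
})

setMethod("show", "BoundaryResult", function(object) {
  cat(sprintf("BoundaryResult: shell %.1f A, %d frames\n",
              object@shellCutoff, object@nFrames))
  print(object@table, row.names = FALSE)
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("%s: species %s, %s leaflet, %d x %d bins (r <= %.0f A), %d frames\n",
              class(object), object@species, object@leaflet,
              nrow(object@rho), ncol(object@rho), max(object@rEdges),
              object@nFrames))
})

setMethod("show", "ContactProfile", function(object) {
  cat(sprintf("ContactProfile: species %s, cutoff %.1f A, %d residues x %d subunits, %d frames\n",
              object@species, object@cutoff, nrow(object@meanProfile),
              length(unique(object@profile$subunit)), object@nFrames))
})

setMethod("show", "SiteGeometry", function(object) {
  s <- object@sites
  cat(sprintf("SiteGeometry: %d site instances (%s), r in [%.0f, %.0f] A\n",
              nrow(s), paste(unique(s$site), collapse = ", "),
              min(s$rMin), max(s$rMax)))
})

setMethod("show", "OccupancyHistogram", function(object) {
  m <- sum((seq_along(object@counts) - 1) * object@counts) / object@nFrames
  cat(sprintf("OccupancyHistogram: %s in %s, %d samples, <n> = %.3f\n",
              object@species, object@region, object@nFrames, m))
})

setMethod("show", "AffinityResult", function(object) {
  cat(sprintf("AffinityResult (%s): dG = %s kcal/mol at %g K%s\n",
              object@estimator,
              if (object@finite) sprintf("%.4f", object@deltaG)
              else sprintf("%sInf (flagged)", if (object@deltaG > 0) "+" else "-"),
              object@temperature,
              if (!is.na(object@nStar)) sprintf(", n* = %d", object@nStar) else ""))
})

setMethod("show", "KineticScheme", function(object) {
  cat(sprintf("KineticScheme: %d states (%d conducting), %d transitions\n",
              nrow(object@states), sum(object@states$conducting),
              nrow(object@transitions)))
})

setMethod("show", "StateTrajectory", function(object) {
  cat(sprintf("StateTrajectory: %d states over %.3g s (%d points)\n",
              ncol(object@prob), max(object@time), length(object@time)))
})

setMethod("show", "DecayFit", function(object) {
  if (!object@converged) cat("DecayFit: not converged (best-effort values)\n")
  cat(sprintf("DecayFit (%s): A1=%.4g tau1=%.4g s", object@model,
              object@A1, object@tau1))
  if (object@model == "biexponential")
    cat(sprintf(" A2=%.4g tau2=%.4g s", object@A2, object@tau2))
  cat(sprintf(" C=%.4g; weighted tau %.4g s\n", object@offset, object@weightedTau))
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf("%s fit: %.4g M (SE %.2g), Hill slope %.3g, Rmax %.3g\n",
              object@kind, object@ec50, object@ec50SE, object@hill,
              object@rmax))
})
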