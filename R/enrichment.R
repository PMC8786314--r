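## Boundary lipid metric and leaflet-resolved polar density/enhancement maps.

#' Boundary lipid metric B
#'
#' For each lipid species i, `B_i = <b_i/b_tot> / chi_i`, where `b_i` is the
#' number of molecules of species i whose minimum bead-to-protein-bead
#' distance is within `shellCutoff`, `b_tot` the total molecules in that
#' boundary shell, `chi_i` the species' mol fraction, and `< >` the average
#' over frames (frames with an empty shell are excluded). `B > 1` indicates
#' enrichment around the protein, `B < 1` depletion.
#'
#' @param traj an aligned [CGTrajectory-class].
#' @param composition optional [CompositionTable-class] (computed from `traj`
#'   when missing).
#' @param shellCutoff boundary shell cutoff, Angstrom (default 6).
#' @param species optional subset of species to report (all by default); the
#'   shell composition always uses all lipids.
#' @return a [BoundaryResult-class]; the per-species standard error is a
#'   batch-means SEM over the per-frame series.
#' @export
boundaryMetric <- function(traj, composition = NULL, shellCutoff = 6,
                           species = NULL) {
  if (!isAligned(traj)) .stopf("trajectory must be aligned first")
  if (is.null(composition)) composition <- compositionTable(traj)
  tb <- composition@table
  if (is.null(species)) species <- tb$species
  chi <- stats::setNames(tb$molFraction, tb$species)[species]
  if (any(is.na(chi) | chi == 0))
    .stopf("undefined metric: species absent from the membrane: %s",
           paste(species[is.na(chi) | chi == 0], collapse = ", "))

  b <- traj@beads
  lip <- which(!b$is_protein)
  prot <- which(b$is_protein)
  if (!length(prot)) .stopf("input error: no protein beads")
  molId <- b$molecule_id[lip]
  molF <- match(molId, sort(unique(molId)))          # 1..nMol
  molSpecies <- b$species[lip][!duplicated(molF)]
  nMol <- max(molF)

  nf <- dim(traj@coords)[3]
  allSpecies <- tb$species
  frac <- matrix(NA_real_, nf, length(allSpecies),
                 dimnames = list(NULL, allSpecies))
  protM <- traj@coords[prot, , , drop = FALSE]
  lipM <- traj@coords[lip, , , drop = FALSE]
  ## candidate prefilter: only beads inside the protein's bounding cylinder
  ## (inflated by the cutoff) can be in the shell
  lr2 <- lipM[, 1, ]^2 + lipM[, 2, ]^2
  lr2 <- matrix(lr2, length(lip), nf)
  lz <- matrix(lipM[, 3, ], length(lip), nf)
  for (f in seq_len(nf)) {
    pf <- matrix(protM[, , f], ncol = 3)
    rCyl <- sqrt(max(pf[, 1]^2 + pf[, 2]^2)) + shellCutoff
    zRange <- range(pf[, 3]) + c(-1, 1) * shellCutoff
    cand <- which(lr2[, f] <= rCyl^2 & lz[, f] >= zRange[1] &
                  lz[, f] <= zRange[2])
    inShell <- logical(nMol)
    if (length(cand)) {
      d2 <- .cpp_mol_min_dist2(matrix(lipM[cand, , f], ncol = 3),
                               molF[cand], nMol, pf,
                               traj@box[f, ], shellCutoff)
      inShell <- d2 <= shellCutoff^2
    }
    btot <- sum(inShell)
    if (btot == 0) next
    cnt <- table(factor(molSpecies[inShell], levels = allSpecies))
    frac[f, ] <- as.numeric(cnt) / btot
  }
  used <- stats::complete.cases(frac)
  if (!any(used)) .stopf("boundary shell empty in every frame")
  Bi <- colMeans(frac[used, , drop = FALSE])[species] / chi
  sem <- vapply(species, function(s)
    batchSEM(frac[used, s]) / chi[[s]], 1)
  methods::new("BoundaryResult",
               table = data.frame(species = species, B = as.numeric(Bi),
                                  sem = as.numeric(sem),
                                  stringsAsFactors = FALSE, row.names = NULL),
               series = frac[used, species, drop = FALSE],
               shellCutoff = shellCutoff, nFrames = sum(used))
}

## Shared polar binning: per-frame counts of selected beads on the grid.
## Returns a matrix n_frames x (nr * ntheta), column-major over (r, theta).
#' @noRd
.polarBinCounts <- function(traj, beadSel, leaflets, leaflet, dr, dtheta,
                            rMax) {
  nr <- rMax / dr
  nt <- 2 * pi / dtheta
  if (abs(nr - round(nr)) > 1e-9)
    .stopf("configuration error: dr = %g does not divide r_max = %g evenly",
           dr, rMax)
  if (abs(nt - round(nt)) > 1e-9)
    .stopf("configuration error: dtheta = %g does not divide 2*pi evenly",
           dtheta)
  nr <- round(nr); nt <- round(nt)
  if (rMax > min(traj@box[, 1:2]) / 2)
    .warnf("r_max = %g exceeds half the smallest box dimension", rMax)

  b <- traj@beads
  nf <- dim(traj@coords)[3]
  counts <- matrix(0L, nf, nr * nt)
  if (!any(beadSel)) return(list(counts = counts, nr = nr, nt = nt))
  beadMol <- b$molecule_id[beadSel]
  molRow <- match(beadMol, leaflets@moleculeId)
  if (anyNA(molRow)) .stopf("selected beads include non-lipid molecules")
  sub <- traj@coords[beadSel, , , drop = FALSE]
  for (f in seq_len(nf)) {
    keep <- leaflets@leaflet[molRow, f] == leaflet
    if (!any(keep)) next
    xy <- matrix(sub[keep, 1:2, f], ncol = 2)
    p <- .polar(xy)
    ok <- p$r < rMax
    if (!any(ok)) next
    ri <- pmin(floor(p$r[ok] / dr), nr - 1L)
    ti <- pmin(floor(p$theta[ok] / dtheta), nt - 1L)
    idx <- ri + nr * ti + 1L
    tab <- tabulate(idx, nbins = nr * nt)
    counts[f, ] <- tab
  }
  list(counts = counts, nr = nr, nt = nt)
}

#' Leaflet-resolved polar density map
#'
#' Time-averaged bead density of one species in one leaflet on a polar grid
#' centered on the pore axis:
#' `rho(r_i, theta_j) = <n(r_i, theta_j)> / (r_i * dr * dtheta)`, with `r_i`
#' the bin center radius (note `r_i*dr*dtheta` is the exact annular-sector
#' bin area). Beads are binned by their own (x, y); leaflet membership is the
#' parent molecule's.
#'
#' @param traj an aligned [CGTrajectory-class].
#' @param leaflets a [LeafletAssignment-class] for `traj`.
#' @param species lipid species token.
#' @param leaflet `"outer"` or `"inner"`.
#' @param dr radial bin width, Angstrom (default 5).
#' @param dtheta angular bin width, radians (default pi/15).
#' @param rMax map extent, Angstrom (default 70).
#' @param keepFrames retain the per-frame bin-count matrix (needed for
#'   per-bin standard errors).
#' @return a [DensityMap-class].
#' @export
radialDensityMap <- function(traj, leaflets, species, leaflet = "outer",
                             dr = 5, dtheta = pi / 15, rMax = 70,
                             keepFrames = FALSE) {
  if (!isAligned(traj)) .stopf("trajectory must be aligned first")
  leaflet <- match.arg(leaflet, c("outer", "inner"))
  b <- traj@beads
  sel <- !b$is_protein & b$species == species
  pb <- .polarBinCounts(traj, sel, leaflets, leaflet, dr, dtheta, rMax)
  rEdges <- seq(0, rMax, by = dr)
  tEdges <- seq(0, 2 * pi, length.out = pb$nt + 1L)
  rCenter <- rEdges[-1] - dr / 2
  binArea <- matrix(rCenter * dr * dtheta, pb$nr, pb$nt)
  rho <- matrix(colMeans(pb$counts), pb$nr, pb$nt) / binArea
  methods::new("DensityMap", species = species, leaflet = leaflet,
               rEdges = rEdges, thetaEdges = tEdges, rho = rho,
               nFrames = nrow(pb$counts),
               perFrame = if (keepFrames) pb$counts else
                 matrix(0, 0, 0))
}

#' Bulk-normalized enhancement map
#'
#' Divides a density map by the expected bulk bead density
#' `x_B * s_B * N_L / <A>` (Eq.-style normalization), where `x_B` is the
#' species mol fraction, `s_B` beads per molecule, `N_L` the lipid count and
#' `<A>` the time-averaged projected box area. With
#' `leafletNormalization = "per_leaflet"` (the default for leaflet-resolved
#' maps) `x_B` and `N_L` refer to the map's leaflet, so 1 means "bulk of
#' that leaflet".
#'
#' @param density a [DensityMap-class].
#' @param composition a [CompositionTable-class].
#' @param leafletNormalization `"per_leaflet"` or `"whole"`.
#' @return an [EnhancementMap-class].
#' @export
enhancementMap <- function(density, composition,
                           leafletNormalization = c("per_leaflet", "whole")) {
  leafletNormalization <- match.arg(leafletNormalization)
  tb <- composition@table
  row <- tb[tb$species == density@species, ]
  if (nrow(row) != 1L)
    .stopf("species %s not in composition table", density@species)
  A <- composition@meanArea
  if (leafletNormalization == "per_leaflet") {
    nLeaf <- if (density@leaflet == "outer") sum(tb$nMolOuter)
             else sum(tb$nMolInner)
    nSp <- if (density@leaflet == "outer") row$nMolOuter else row$nMolInner
    xB <- if (nLeaf > 0) nSp / nLeaf else 0
    NL <- nLeaf
  } else {
    xB <- row$molFraction
    NL <- composition@nLipids
  }
  bulk <- xB * row$beadsPerMol * NL / A
  if (bulk <= 0) .stopf("undefined normalization: zero bulk density for %s",
                        density@species)
  methods::new("EnhancementMap", density, rhoTilde = density@rho / bulk,
               bulkDensity = bulk)
}

#' Area-weighted mean enhancement over an annular sector
#'
#' Averages `rho~` over the part of the map inside a sector, weighting each
#' bin by its overlap area with the sector (exact for polar-rectangle bins).
#'
#' @param map an [EnhancementMap-class].
#' @param rMin,rMax radial bounds, Angstrom.
#' @param thetaMin,thetaMax angular bounds, radians (counter-clockwise from
#'   `thetaMin`).
#' @return numeric sector-mean enhancement.
#' @export
sectorMeanEnhancement <- function(map, rMin, rMax, thetaMin, thetaMax) {
  rE <- map@rEdges; tE <- map@thetaEdges
  nr <- length(rE) - 1L; nt <- length(tE) - 1L
  width <- .arcWidth(thetaMin, thetaMax)
  W <- matrix(0, nr, nt)
  for (i in seq_len(nr)) {
    rlo <- max(rE[i], rMin); rhi <- min(rE[i + 1L], rMax)
    if (rhi <= rlo) next
    rw <- (rhi^2 - rlo^2) / 2
    for (j in seq_len(nt)) {
      ## angular overlap of bin arc with sector arc (both CCW intervals)
      a0 <- .wrapAngle(tE[j] - thetaMin)
      a1 <- a0 + (tE[j + 1L] - tE[j])
      ov <- max(0, min(a1, width) - min(a0, width)) +
        max(0, min(a1 - 2 * pi, width) - max(a0 - 2 * pi, 0))
      if (ov > 0) W[i, j] <- rw * ov
    }
  }
  if (sum(W) == 0) .stopf("sector does not overlap the map")
  sum(W * map@rhoTilde) / sum(W)
}

#' Export a density or enhancement map as a long-format table
#'
#' @param map a [DensityMap-class] or [EnhancementMap-class].
#' @return data.frame with `leaflet`, `species`, `r_center`, `theta_center`,
#'   `rho` and (for enhancement maps) `rho_tilde`.
#' @export
mapAsTable <- function(map) {
  rC <- map@rEdges[-1] - diff(map@rEdges) / 2
  tC <- map@thetaEdges[-1] - diff(map@thetaEdges) / 2
  out <- data.frame(leaflet = map@leaflet, species = map@species,
                    r_center = rep(rC, times = length(tC)),
                    theta_center = rep(tC, each = length(rC)),
                    rho = as.vector(map@rho))
  if (methods::is(map, "EnhancementMap"))
    out$rho_tilde <- as.vector(map@rhoTilde)
  out
}
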