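## M1/M3 annular-sector binding sites, occupancy histograms, and the density
## threshold affinity.

## Construct M1/M3 sector angular bounds from per-subunit helix azimuths.
## For each subunit, the M1 site runs from the M4 azimuth to midway between
## the same subunit's M1 and the adjacent subunit's M3; the M3 site runs from
## the M4 azimuth to midway between the same subunit's M3 and the adjacent
## subunit's M1 (adjacency resolved by angular proximity on each side of M4).
#' @noRd
.sectorBoundsFromAzimuths <- function(aziM1, aziM3, aziM4, subunits) {
  n <- length(aziM4)
  out <- list()
  signedArc <- function(from, to) {
    d <- .wrapAngle(to - from)
    if (d > pi) d - 2 * pi else d
  }
  for (k in seq_len(n)) {
    for (site in c("M1", "M3")) {
      own <- if (site == "M1") aziM1[k] else aziM3[k]
      othPool <- if (site == "M1") aziM3 else aziM1
      d <- signedArc(aziM4[k], own)
      if (abs(d) < 1e-9 || abs(d) > 2 * pi / 5)
        .stopf("geometry error: helix azimuths contradict a pentameric arrangement")
      dir <- sign(d)
      ## nearest other-helix azimuth strictly beyond `own` in direction `dir`
      w <- .wrapAngle((othPool - own) * dir)
      w[w < 1e-9] <- Inf
      j <- which.min(w)
      if (!is.finite(w[j]) || w[j] > 2 * pi / 5)
        .stopf("geometry error: no adjacent helix found within one subunit turn")
      boundary <- .wrapAngle(own + dir * w[j] / 2)
      lo <- if (dir > 0) aziM4[k] else boundary
      hi <- if (dir > 0) boundary else aziM4[k]
      out[[length(out) + 1L]] <- data.frame(
        site = site, subunit = subunits[k],
        thetaMin = .wrapAngle(lo), thetaMax = .wrapAngle(hi),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## time-averaged azimuth of a set of beads (circular mean of per-frame
## centroid directions)
#' @noRd
.meanAzimuth <- function(coords, sel) {
  xs <- colMeans(coords[sel, 1, , drop = FALSE][, 1, , drop = FALSE])
  ys <- colMeans(coords[sel, 2, , drop = FALSE][, 1, , drop = FALSE])
  a <- atan2(ys, xs)
  .wrapAngle(atan2(mean(sin(a)), mean(cos(a))))
}

#' Define the M1/M3 annular-sector binding sites
#'
#' Helix azimuths are the time-averaged azimuthal angles of each
#' transmembrane helix's bead centroid; sector angular bounds follow the
#' M4-to-midpoint construction (see the package vignette), radial bounds
#' default to 10-40 Angstrom, and each sector is duplicated for both
#' leaflets, giving 20 site instances for a pentamer.
#'
#' @param traj an aligned [CGTrajectory-class].
#' @param helixGroups named list mapping helix names (must include M1, M3,
#'   M4) to residue-id vectors.
#' @param rMin,rMax radial site bounds, Angstrom.
#' @return a [SiteGeometry-class].
#' @export
defineSiteSectors <- function(traj, helixGroups, rMin = 10, rMax = 40) {
  if (!isAligned(traj)) .stopf("trajectory must be aligned first")
  need <- c("M1", "M3", "M4")
  if (!all(need %in% names(helixGroups)))
    .stopf("helixGroups must define M1, M3 and M4 residue ranges")
  b <- traj@beads
  subunits <- sort(unique(b$subunit[b$is_protein]))
  azi <- sapply(need, function(h) vapply(subunits, function(su) {
    sel <- which(b$is_protein & b$subunit == su &
                 b$residue_id %in% helixGroups[[h]])
    if (!length(sel)) .stopf("no beads for helix %s subunit %s", h, su)
    .meanAzimuth(traj@coords, sel)
  }, 1))
  sect <- .sectorBoundsFromAzimuths(azi[, "M1"], azi[, "M3"], azi[, "M4"],
                                    subunits)
  sect <- merge(sect, data.frame(leaflet = c("outer", "inner")))
  sect$rMin <- rMin
  sect$rMax <- rMax
  sect$area <- (rMax^2 - rMin^2) / 2 * .arcWidth(sect$thetaMin, sect$thetaMax)
  ## verify per-leaflet non-overlap: CCW arcs [a, a+w) overlap iff either
  ## start falls strictly inside the other arc
  for (lf in c("outer", "inner")) {
    s <- sect[sect$leaflet == lf, ]
    for (i in seq_len(nrow(s) - 1L)) for (j in (i + 1L):nrow(s)) {
      wI <- .arcWidth(s$thetaMin[i], s$thetaMax[i])
      wJ <- .arcWidth(s$thetaMin[j], s$thetaMax[j])
      if (.wrapAngle(s$thetaMin[j] - s$thetaMin[i]) < wI - 1e-9 ||
          .wrapAngle(s$thetaMin[i] - s$thetaMin[j]) < wJ - 1e-9)
        .stopf("geometry error: sectors %s-%s and %s-%s overlap",
               s$site[i], s$subunit[i], s$site[j], s$subunit[j])
    }
  }
  methods::new("SiteGeometry", sites = sect[order(sect$leaflet, sect$subunit,
                                                  sect$site), ])
}

#' Test points for membership in an annular sector
#'
#' @param xy two-column matrix of in-plane coordinates (Angstrom).
#' @param sector one-row data.frame with `rMin`, `rMax`, `thetaMin`,
#'   `thetaMax` (e.g. one row of [siteTable()]).
#' @return logical vector.
#' @export
inSector <- function(xy, sector) {
  p <- .polar(xy)
  p$r >= sector$rMin & p$r < sector$rMax &
    .inArc(p$theta, sector$thetaMin, sector$thetaMax)
}

#' Site occupancy histogram P_site(n)
#'
#' Per frame, counts the beads of the species (restricted to molecules in
#' the site's leaflet) whose (r, theta) falls inside the sector, and returns
#' the distribution of that count over frames.
#'
#' @param traj an aligned [CGTrajectory-class].
#' @param leaflets a [LeafletAssignment-class].
#' @param site one-row data.frame from [siteTable()] (needs `site`,
#'   `subunit`, `leaflet`, bounds), or a SiteGeometry subset with one row.
#' @param species lipid species token.
#' @return an [OccupancyHistogram-class].
#' @export
occupancyHistogram <- function(traj, leaflets, site, species) {
  if (methods::is(site, "SiteGeometry")) site <- siteTable(site)
  if (nrow(site) != 1L) .stopf("supply exactly one site instance")
  counts <- .regionCounts(traj, leaflets, species, site$leaflet,
                          function(xy) inSector(xy, site))
  .histFromCounts(counts, sprintf("%s site, subunit %s, %s leaflet",
                                  site$site, site$subunit, site$leaflet),
                  species, site$area)
}

#' @noRd
.regionCounts <- function(traj, leaflets, species, leaflet, predicate) {
  b <- traj@beads
  sel <- which(!b$is_protein & b$species == species)
  nf <- dim(traj@coords)[3]
  if (!length(sel)) return(integer(nf) * 0L)
  molRow <- match(b$molecule_id[sel], leaflets@moleculeId)
  counts <- integer(nf)
  for (f in seq_len(nf)) {
    keep <- leaflets@leaflet[molRow, f] == leaflet
    if (!any(keep)) next
    xy <- matrix(traj@coords[sel[keep], 1:2, f], ncol = 2)
    counts[f] <- sum(predicate(xy))
  }
  counts
}

#' @noRd
.histFromCounts <- function(counts, region, species, area) {
  tab <- tabulate(counts + 1L, nbins = max(counts) + 1L)
  methods::new("OccupancyHistogram", counts = as.numeric(tab),
               nFrames = length(counts), region = region, species = species,
               area = area)
}

#' Mean occupancy of a histogram
#' @param h an [OccupancyHistogram-class].
#' @return numeric `<n>`.
#' @export
meanOccupancy <- function(h) {
  sum((seq_along(h@counts) - 1) * h@counts) / h@nFrames
}

#' Bulk reference occupancy histogram P_bulk(n)
#'
#' Estimates the bead-count distribution expected in a bulk-membrane region
#' of the same area as a binding site, by counting species beads inside
#' randomly placed area-matched annular sectors spanning a far annulus
#' (default 50-70 Angstrom from the pore axis), pooled over frames and
#' placements. The sampling sectors span the annulus radially with the
#' angular width adjusted to match `siteArea`.
#'
#' @param traj an aligned [CGTrajectory-class].
#' @param leaflets a [LeafletAssignment-class].
#' @param species lipid species token.
#' @param siteArea target region area, Angstrom^2.
#' @param leaflet leaflet to sample.
#' @param rAnnulus length-2 numeric, bulk annulus radial bounds (Angstrom).
#' @param nPlacements random sector placements per frame (default 8).
#' @param seed integer seed for the placements.
#' @return an [OccupancyHistogram-class].
#' @export
bulkReferenceHistogram <- function(traj, leaflets, species, siteArea,
                                   leaflet = "outer",
                                   rAnnulus = c(50, 70), nPlacements = 8L,
                                   seed = 1L) {
  annArea <- (rAnnulus[2]^2 - rAnnulus[1]^2) * pi
  if (siteArea > annArea)
    .stopf("site area %.0f exceeds bulk annulus area %.0f", siteArea, annArea)
  if (rAnnulus[2] > min(traj@box[, 1:2]) / 2)
    .warnf("bulk annulus extends beyond half the box")
  b <- traj@beads
  prot <- which(b$is_protein)
  if (length(prot)) {
    pr <- sqrt(traj@coords[prot, 1, 1]^2 + traj@coords[prot, 2, 1]^2)
    if (any(pr >= rAnnulus[1] & pr <= rAnnulus[2]))
      .warnf("bulk annulus contains protein beads")
  }
  width <- 2 * siteArea / (rAnnulus[2]^2 - rAnnulus[1]^2)
  set.seed(seed)
  sel <- which(!b$is_protein & b$species == species)
  nf <- dim(traj@coords)[3]
  molRow <- match(b$molecule_id[sel], leaflets@moleculeId)
  counts <- integer(nf * nPlacements)
  k <- 0L
  for (f in seq_len(nf)) {
    keep <- leaflets@leaflet[molRow, f] == leaflet
    xy <- matrix(traj@coords[sel[keep], 1:2, f], ncol = 2)
    p <- .polar(xy)
    inAnn <- p$r >= rAnnulus[1] & p$r < rAnnulus[2]
    th <- p$theta[inAnn]
    th0 <- stats::runif(nPlacements, 0, 2 * pi)
    for (j in seq_len(nPlacements)) {
      k <- k + 1L
      counts[k] <- sum(.inArc(th, th0[j], th0[j] + width))
    }
  }
  .histFromCounts(counts,
                  sprintf("bulk annulus %.0f-%.0f A, %s leaflet",
                          rAnnulus[1], rAnnulus[2], leaflet),
                  species, siteArea)
}

#' Pool occupancy histograms
#'
#' @param ... [OccupancyHistogram-class] objects over the same species and
#'   (nominally) area-matched regions.
#' @return pooled [OccupancyHistogram-class].
#' @export
poolHistograms <- function(...) {
  hs <- list(...)
  if (length(hs) == 1L && is.list(hs[[1]])) hs <- hs[[1]]
  nmax <- max(vapply(hs, function(h) length(h@counts), 1L))
  cnt <- rowSums(vapply(hs, function(h)
    c(h@counts, rep(0, nmax - length(h@counts))), numeric(nmax)))
  methods::new("OccupancyHistogram", counts = cnt,
               nFrames = sum(vapply(hs, function(h) h@nFrames, 1L)),
               region = paste("pooled:", hs[[1]]@region),
               species = hs[[1]]@species, area = hs[[1]]@area)
}

#' Density threshold affinity
#'
#' Free-energy-like score comparing a site occupancy distribution with an
#' area-matched bulk reference. Two estimators are provided:
#' `"threshold"`: `dG = -kB*T*ln( P_site(n >= n*) / P_bulk(n >= n*) )` with
#' `n*` defaulting to the smallest integer strictly greater than the bulk
#' mean occupancy; `"mean_ratio"`: `dG = -kB*T*ln( <n>_site / <n>_bulk )`.
#' Negative values mean favorable (enriched) sites. When a required tail
#' probability or mean is zero the result is an infinite-affinity flag
#' (`deltaG = +/-Inf`, `finite = FALSE`) rather than a number.
#'
#' @param pSite,pBulk [OccupancyHistogram-class] objects (area-matched).
#' @param temperature Kelvin (default 323, the production temperature).
#' @param estimator `"threshold"` or `"mean_ratio"`.
#' @param nStar integer threshold or `"auto"`.
#' @return an [AffinityResult-class].
#' @export
thresholdAffinity <- function(pSite, pBulk, temperature = 323,
                              estimator = c("threshold", "mean_ratio"),
                              nStar = "auto") {
  estimator <- match.arg(estimator)
  if (pSite@nFrames == 0L || pBulk@nFrames == 0L)
    .stopf("histograms must be nonempty")
  kT <- .kB * temperature
  if (estimator == "mean_ratio") {
    mS <- meanOccupancy(pSite); mB <- meanOccupancy(pBulk)
    if (mS == 0 && mB == 0) .stopf("both histograms have zero mean occupancy")
    if (mS == 0 || mB == 0) {
      return(methods::new("AffinityResult",
                          deltaG = if (mS == 0) Inf else -Inf,
                          estimator = estimator, nStar = NA_integer_,
                          temperature = temperature, finite = FALSE))
    }
    dG <- -kT * log(mS / mB)
    return(methods::new("AffinityResult", deltaG = dG, estimator = estimator,
                        nStar = NA_integer_, temperature = temperature,
                        finite = TRUE))
  }
  if (identical(nStar, "auto"))
    nStar <- floor(meanOccupancy(pBulk)) + 1L
  nStar <- as.integer(nStar)
  tail <- function(h) {
    p <- h@counts / h@nFrames
    n <- seq_along(p) - 1L
    sum(p[n >= nStar])
  }
  tS <- tail(pSite); tB <- tail(pBulk)
  if (tS == 0 && tB == 0)
    .stopf("threshold n* = %d exceeded in neither histogram", nStar)
  if (tS == 0 || tB == 0) {
    return(methods::new("AffinityResult",
                        deltaG = if (tS == 0) Inf else -Inf,
                        estimator = estimator, nStar = nStar,
                        temperature = temperature, finite = FALSE))
  }
  methods::new("AffinityResult", deltaG = -kT * log(tS / tB),
               estimator = estimator, nStar = nStar,
               temperature = temperature, finite = TRUE)
}
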