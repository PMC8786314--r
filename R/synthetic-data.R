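## Synthetic-data generators: membrane trajectories with planted site
## enrichment, current traces, and labeling AUC tables — every output comes
## with a machine-readable ground truth.

#' Specification for a synthetic coarse-grained membrane system
#'
#' Defaults emulate the simulated study system: a pentameric transmembrane
#' scaffold (four helices M1-M4 per subunit) in a 160 x 160 Angstrom bilayer
#' of 2:1:1 POPC:POPE:POPG with 4 mol% free fatty acid (15 molecules per
#' leaflet). Lipid in-plane motion is a bounded random walk (Metropolis steps
#' with reflection-by-rejection, which keeps the stationary distribution
#' uniform over each molecule's home region); `dynamics = "independent"`
#' redraws positions every frame, giving the independent uniform/Poisson
#' placement used as a Monte-Carlo oracle by the calibration tests.
#'
#' @param boxLength lateral box edge, Angstrom.
#' @param boxHeight box height (z), Angstrom.
#' @param nLipidsPerLeaflet named integer vector of diacyl lipid counts per
#'   leaflet.
#' @param fattyAcid fatty-acid species token (e.g. "DHA" or "PA").
#' @param nFattyAcidPerLeaflet fatty-acid molecules per leaflet.
#' @param beadsPerLipid beads per diacyl lipid molecule.
#' @param beadsPerFattyAcid beads per fatty-acid molecule.
#' @param enhancements list of plants, each a list with fields `site` ("M1"
#'   or "M3"), `subunit` ("A".."E" or "all"), `leaflet` ("outer", "inner" or
#'   "both"), `species`, `factor` (> 0). Within planted sectors the named
#'   species' density is `factor` times its same-leaflet bulk density.
#' @param nFrames number of frames.
#' @param frameInterval ns between frames.
#' @param stepSd random-walk step standard deviation per frame per axis,
#'   Angstrom (matched to coarse-grained lipid diffusion at a 1 ns save
#'   interval).
#' @param jitterSd intramolecular bead jitter, Angstrom.
#' @param proteinClearance steric clearance radius around each helix axis
#'   from which lipid anchors are excluded, Angstrom; 0 gives the "no protein
#'   preference" uniform placement mode.
#' @param dynamics `"walk"` (default) or `"independent"`.
#' @param helixRadii,helixAzimuthsDeg named numeric vectors (M1..M4): scaffold
#'   helix axis radii (Angstrom) and subunit-A azimuths (degrees); other
#'   subunits are 72-degree rotations.
#' @param helixResidues named list of residue-id ranges for M1..M4.
#' @param seed mandatory integer seed.
#' @return a validated `membraneSpec` list.
#' @export
membraneSpec <- function(boxLength = 160, boxHeight = 100,
                         nLipidsPerLeaflet = c(POPC = 176L, POPE = 88L,
                                               POPG = 88L),
                         fattyAcid = "DHA", nFattyAcidPerLeaflet = 15L,
                         beadsPerLipid = 12L, beadsPerFattyAcid = 3L,
                         enhancements = list(), nFrames = 100L,
                         frameInterval = 1, stepSd = 10, jitterSd = 0.5,
                         proteinClearance = 4, dynamics = c("walk",
                                                            "independent"),
                         helixRadii = c(M1 = 15, M2 = 8, M3 = 15, M4 = 20),
                         helixAzimuthsDeg = c(M1 = 24, M2 = 0, M3 = -24,
                                              M4 = 0),
                         helixResidues = list(M1 = 199:222, M2 = 228:250,
                                              M3 = 256:280, M4 = 300:320),
                         seed) {
  if (missing(seed)) .stopf("membraneSpec: a seed is mandatory")
  dynamics <- match.arg(dynamics)
  for (e in enhancements) {
    if (!is.numeric(e$factor) || e$factor <= 0)
      .stopf("enhancement factors must be > 0")
    if (!e$site %in% c("M1", "M3")) .stopf("unknown site '%s'", e$site)
  }
  ## feasibility: total anchor density must stay well below close packing
  area <- boxLength^2
  nMol <- sum(nLipidsPerLeaflet) + nFattyAcidPerLeaflet
  if (nMol / area > 0.05)
    .stopf("overfilled box: %d molecules per leaflet in %.0f A^2", nMol, area)
  structure(list(boxLength = boxLength, boxHeight = boxHeight,
                 nLipidsPerLeaflet = nLipidsPerLeaflet,
                 fattyAcid = fattyAcid,
                 nFattyAcidPerLeaflet = as.integer(nFattyAcidPerLeaflet),
                 beadsPerLipid = as.integer(beadsPerLipid),
                 beadsPerFattyAcid = as.integer(beadsPerFattyAcid),
                 enhancements = enhancements, nFrames = as.integer(nFrames),
                 frameInterval = frameInterval, stepSd = stepSd,
                 jitterSd = jitterSd, proteinClearance = proteinClearance,
                 dynamics = dynamics, helixRadii = helixRadii,
                 helixAzimuthsDeg = helixAzimuthsDeg,
                 helixResidues = helixResidues, seed = as.integer(seed)),
            class = "membraneSpec")
}

## Scaffold helix axis table: site, subunit, helix, azimuth (rad), radius.
#' @noRd
.scaffoldHelices <- function(spec) {
  hx <- expand.grid(helix = c("M1", "M2", "M3", "M4"), subunit = LETTERS[1:5],
                    stringsAsFactors = FALSE)
  hx$azimuth <- .wrapAngle((spec$helixAzimuthsDeg[hx$helix] +
                            72 * (match(hx$subunit, LETTERS[1:5]) - 1)) *
                           pi / 180)
  hx$radius <- spec$helixRadii[hx$helix]
  hx
}

## Protein bead table + static coordinates from the scaffold.
#' @noRd
.scaffoldProtein <- function(spec) {
  hx <- .scaffoldHelices(spec)
  rows <- list()
  for (i in seq_len(nrow(hx))) {
    res <- spec$helixResidues[[hx$helix[i]]]
    n <- length(res)
    z <- seq(-16, 16, length.out = n)
    if (hx$helix[i] %in% c("M2", "M4")) z <- rev(z)  # antiparallel bundle
    rows[[i]] <- data.frame(
      residue_id = res, subunit = hx$subunit[i], helix = hx$helix[i],
      x = hx$radius[i] * cos(hx$azimuth[i]),
      y = hx$radius[i] * sin(hx$azimuth[i]), z = z,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## z templates (headgroup first); mirrored for the inner leaflet.
#' @noRd
.zTemplate <- function(nBeads) {
  if (nBeads == 1L) return(18)
  seq(18, 3, length.out = nBeads)
}

#' Generate a synthetic membrane trajectory with known ground truth
#'
#' Lipid anchors are placed uniformly over each leaflet (outside the
#' scaffold's steric clearance), except that species named in planted
#' enhancements occupy each planted sector with probability proportional to
#' `factor` times the sector area, which makes the stationary anchor density
#' inside the sector exactly `factor` times the same-leaflet bulk density.
#' Each molecule carries its beads at fixed depth templates with small
#' intramolecular jitter. The trajectory is generated directly in the
#' canonical protein-centered frame.
#'
#' @param spec a [membraneSpec()].
#' @return list with elements `trajectory` (a [CGTrajectory-class], aligned)
#'   and `groundTruth` (list: planted sectors with expected occupancies and
#'   enhancement values, per-molecule leaflet labels, densities, seed).
#' @export
genMembraneTraj <- function(spec) {
  stopifnot(inherits(spec, "membraneSpec"))
  set.seed(spec$seed)
  L <- spec$boxLength
  prot <- .scaffoldProtein(spec)
  hx <- .scaffoldHelices(spec)
  sect <- .sectorBoundsFromAzimuths(
    aziM1 = hx$azimuth[hx$helix == "M1"],
    aziM3 = hx$azimuth[hx$helix == "M3"],
    aziM4 = hx$azimuth[hx$helix == "M4"],
    subunits = hx$subunit[hx$helix == "M1"])
  sect$rMin <- 10; sect$rMax <- 40
  sect$area <- (sect$rMax^2 - sect$rMin^2) / 2 * .arcWidth(sect$thetaMin,
                                                           sect$thetaMax)

  ## resolve plants into per-(species, leaflet) sector tables
  plants <- list()
  for (e in spec$enhancements) {
    subs <- if (identical(e$subunit %||% "all", "all")) LETTERS[1:5]
            else e$subunit
    leaf <- if (identical(e$leaflet %||% "both", "both"))
              c("outer", "inner") else e$leaflet
    for (lf in leaf) {
      rows <- sect[sect$site == e$site & sect$subunit %in% subs, ]
      rows$leaflet <- lf; rows$factor <- e$factor; rows$species <- e$species
      plants[[length(plants) + 1L]] <- rows
    }
  }
  plants <- if (length(plants)) do.call(rbind, plants) else NULL

  clearance <- spec$proteinClearance
  helixXY <- cbind(hx$radius * cos(hx$azimuth), hx$radius * sin(hx$azimuth))
  inClearance <- function(xy) {
    if (clearance <= 0) return(rep(FALSE, nrow(xy)))
    ok <- rep(FALSE, nrow(xy))
    for (j in seq_len(nrow(helixXY))) {
      d2 <- (xy[, 1] - helixXY[j, 1])^2 + (xy[, 2] - helixXY[j, 2])^2
      ok <- ok | d2 < clearance^2
    }
    ok
  }
  drawUniformBox <- function(n) cbind(stats::runif(n, -L / 2, L / 2),
                                      stats::runif(n, -L / 2, L / 2))

  ## molecule bookkeeping -----------------------------------------------
  mols <- list()
  for (lf in c("outer", "inner")) {
    counts <- c(spec$nLipidsPerLeaflet,
                stats::setNames(spec$nFattyAcidPerLeaflet, spec$fattyAcid))
    for (s in names(counts)) {
      n <- counts[[s]]
      if (n == 0) next
      mols[[length(mols) + 1L]] <-
        data.frame(species = s, leaflet = lf, idx = seq_len(n),
                   stringsAsFactors = FALSE)
    }
  }
  mols <- do.call(rbind, mols)
  nMol <- nrow(mols)
  leafArea <- L^2

  ## Anchor placement targets, per (species, leaflet), the unnormalized
  ## density w(x) = factor inside that species' planted sectors, 1 in bulk,
  ## 0 inside the steric clearance. Initial positions are drawn from w by
  ## rejection; the random walk uses Metropolis acceptance w(new)/w(old), so
  ## the stationary anchor density is exactly proportional to w in both
  ## dynamics modes (no per-molecule confinement, hence no quantization of
  ## the planted density by integer molecule counts).
  weightFns <- list()
  weightKey <- paste(mols$species, mols$leaflet)
  for (k in unique(weightKey)) {
    s <- mols$species[weightKey == k][1]
    lf <- mols$leaflet[weightKey == k][1]
    st <- if (is.null(plants)) NULL else
      plants[plants$leaflet == lf & plants$species == s, , drop = FALSE]
    weightFns[[k]] <- local({
      st <- st
      function(xy) {
        w <- rep(1, nrow(xy))
        if (!is.null(st) && nrow(st)) {
          p <- .polar(xy)
          for (j in seq_len(nrow(st))) {
            hit <- p$r >= st$rMin[j] & p$r < st$rMax[j] &
              .inArc(p$theta, st$thetaMin[j], st$thetaMax[j])
            w[hit] <- st$factor[j]
          }
        }
        w[inClearance(xy)] <- 0
        w
      }
    })
  }
  drawFromWeight <- function(n, wfn, wmax) {
    out <- matrix(0, n, 2)
    need <- seq_len(n)
    while (length(need)) {
      cand <- drawUniformBox(length(need))
      acc <- stats::runif(length(need)) < wfn(cand) / wmax
      out[need[acc], ] <- cand[acc, , drop = FALSE]
      need <- need[!acc]
    }
    out
  }
  wmaxFor <- stats::setNames(vapply(unique(weightKey), function(k) {
    s <- mols$species[weightKey == k][1]
    lf <- mols$leaflet[weightKey == k][1]
    if (is.null(plants)) return(1)
    st <- plants[plants$leaflet == lf & plants$species == s, , drop = FALSE]
    max(1, st$factor)
  }, 1), unique(weightKey))

  anchors <- matrix(0, nMol, 2)
  for (k in unique(weightKey)) {
    sel <- which(weightKey == k)
    anchors[sel, ] <- drawFromWeight(length(sel), weightFns[[k]],
                                     wmaxFor[[k]])
  }

  ## bead tables ---------------------------------------------------------
  lipidRows <- list()
  beadsPer <- ifelse(mols$species == spec$fattyAcid, spec$beadsPerFattyAcid,
                     spec$beadsPerLipid)
  headName <- ifelse(mols$species == spec$fattyAcid, "COO", "PO4")
  for (i in seq_len(nMol)) {
    nb <- beadsPer[i]
    lipidRows[[i]] <- data.frame(
      molecule = i, species = mols$species[i], leaflet = mols$leaflet[i],
      bead = seq_len(nb),
      bead_name = c(headName[i], sprintf("C%d", seq_len(nb - 1L))),
      stringsAsFactors = FALSE)
  }
  lipidBeads <- do.call(rbind, lipidRows)
  zsign <- ifelse(lipidBeads$leaflet == "outer", 1, -1)
  zTemplates <- lapply(unique(beadsPer), .zTemplate)
  names(zTemplates) <- as.character(unique(beadsPer))
  zBase <- unlist(lapply(seq_len(nMol), function(i)
    zTemplates[[as.character(beadsPer[i])]]))
  zBase <- zBase * zsign

  nProtBeads <- nrow(prot)
  nLipBeads <- nrow(lipidBeads)
  beadMol <- lipidBeads$molecule

  beads <- data.frame(
    bead_index = seq_len(nProtBeads + nLipBeads),
    molecule_id = c(rep(1L, nProtBeads), lipidBeads$molecule + 1L),
    species = c(rep("PROT", nProtBeads), lipidBeads$species),
    residue_id = c(prot$residue_id, lipidBeads$molecule),
    residue_name = c(rep("GLY", nProtBeads), lipidBeads$species),
    subunit = c(prot$subunit, rep("", nLipBeads)),
    bead_name = c(rep("BB", nProtBeads), lipidBeads$bead_name),
    is_protein = rep(c(TRUE, FALSE), c(nProtBeads, nLipBeads)),
    is_headgroup = c(rep(FALSE, nProtBeads), lipidBeads$bead == 1L),
    stringsAsFactors = FALSE)

  ## frames --------------------------------------------------------------
  nf <- spec$nFrames
  coords <- array(0, c(nProtBeads + nLipBeads, 3L, nf))
  protXYZ <- cbind(prot$x, prot$y, prot$z)
  independent <- spec$dynamics == "independent"
  for (f in seq_len(nf)) {
    if (independent && f > 1L) {
      for (k in unique(weightKey)) {
        sel <- which(weightKey == k)
        anchors[sel, ] <- drawFromWeight(length(sel), weightFns[[k]],
                                         wmaxFor[[k]])
      }
    } else if (!independent && f > 1L) {
      prop <- anchors + matrix(stats::rnorm(2L * nMol, 0, spec$stepSd),
                               nMol, 2)
      prop[, 1] <- .wrapCoords(prop[, 1], L)
      prop[, 2] <- .wrapCoords(prop[, 2], L)
      u <- stats::runif(nMol)
      for (k in unique(weightKey)) {
        sel <- which(weightKey == k)
        wNew <- weightFns[[k]](prop[sel, , drop = FALSE])
        wOld <- weightFns[[k]](anchors[sel, , drop = FALSE])
        acc <- sel[u[sel] < wNew / pmax(wOld, .Machine$double.eps)]
        anchors[acc, ] <- prop[acc, , drop = FALSE]
      }
    }
    xy <- anchors[beadMol, ] +
      matrix(stats::rnorm(2L * nLipBeads, 0, spec$jitterSd), nLipBeads, 2)
    xy[, 1] <- .wrapCoords(xy[, 1], L)
    xy[, 2] <- .wrapCoords(xy[, 2], L)
    z <- zBase + stats::rnorm(nLipBeads, 0, spec$jitterSd)
    coords[, , f] <- rbind(protXYZ, cbind(xy, z))
  }

  traj <- newCGTrajectory(beads, coords,
                          box = c(L, L, spec$boxHeight),
                          frameInterval = spec$frameInterval, aligned = TRUE)

  gt <- list(
    seed = spec$seed, dynamics = spec$dynamics,
    fattyAcid = spec$fattyAcid,
    leaflet = stats::setNames(mols$leaflet, seq_len(nMol) + 1L),
    sectors = sect,
    plantedSectors = plants,
    perLeafletBeadDensity = vapply(c(outer = "outer", inner = "inner"),
      function(lf) {
        sel <- mols$leaflet == lf
        sum(beadsPer[sel]) / L^2
      }, 1))
  if (!is.null(plants)) {
    gt$plantedSectors$kappa <- NA_real_
    for (j in seq_len(nrow(plants))) {
      lf <- plants$leaflet[j]; s <- plants$species[j]
      pl <- which(plants$leaflet == lf & plants$species == s)
      aBulk <- leafArea - sum(plants$area[pl])
      kappa <- leafArea / (aBulk + sum(plants$factor[pl] * plants$area[pl]))
      gt$plantedSectors$kappa[j] <- kappa
    }
    ## expected Eq.4-style enhancement in each planted sector and the
    ## expected mean bead occupancy
    nLeafBeads <- vapply(seq_len(nrow(plants)), function(j) {
      sel <- mols$leaflet == plants$leaflet[j] &
        mols$species == plants$species[j]
      sum(beadsPer[sel])
    }, 1)
    gt$plantedSectors$expectedRhoTilde <-
      plants$factor * gt$plantedSectors$kappa
    gt$plantedSectors$expectedMeanOccupancy <-
      gt$plantedSectors$expectedRhoTilde * nLeafBeads / L^2 * plants$area
  }
  list(trajectory = traj, groundTruth = gt)
}

#' Write the ground truth sidecar beside a generated dataset
#'
#' @param groundTruth the `groundTruth` element returned by a generator.
#' @param path output file (YAML).
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(groundTruth, path) {
  gt <- rapply(groundTruth, function(x)
    if (is.data.frame(x)) as.list(x) else x, how = "replace")
  yaml::write_yaml(gt, path)
  invisible(path)
}

#' Generate a synthetic current trace
#'
#' @param kind `"biexp"` (sum of two exponentials plus offset) or `"scheme"`
#'   (integrate a gating scheme under a protocol, see [integrateProtocol]).
#' @param params for `"biexp"`: list with `A1`, `tau1`, `A2`, `tau2`, `C`
#'   (default 0), `tEnd` (s), `dt` (s). For `"scheme"`: list with `scheme`
#'   (a [KineticScheme-class]) and `protocol` (a [GatingProtocol-class]).
#' @param noiseSd additive Gaussian noise SD (normalized current units).
#' @param seed integer seed.
#' @return list with `trace` (data.frame `time_s`, `current`) and
#'   `groundTruth`.
#' @export
genCurrentTrace <- function(kind = c("biexp", "scheme"), params,
                            noiseSd = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (noiseSd < 0) .stopf("noiseSd must be >= 0")
  set.seed(seed)
  if (kind == "biexp") {
    p <- params
    C <- p$C %||% 0
    t <- seq(0, p$tEnd, by = p$dt)
    y <- p$A1 * exp(-t / p$tau1) + p$A2 * exp(-t / p$tau2) + C
    trace <- data.frame(time_s = t, current = y)
    gt <- list(kind = "biexp", A1 = p$A1, tau1 = p$tau1, A2 = p$A2,
               tau2 = p$tau2, C = C,
               weightedTau = weightedTau(p$A1, p$tau1, p$A2, p$tau2),
               noiseSd = noiseSd, seed = seed)
  } else {
    st <- integrateProtocol(params$scheme, params$protocol)
    trace <- data.frame(time_s = st@time, current = currentOf(st))
    gt <- list(kind = "scheme", noiseSd = noiseSd, seed = seed)
  }
  if (noiseSd > 0)
    trace$current <- trace$current + stats::rnorm(nrow(trace), 0, noiseSd)
  list(trace = trace, groundTruth = gt)
}

#' Generate a synthetic labeled/unlabeled AUC table
#'
#' Emulates the structure of a photolabeling competition dataset: per
#' replicate and condition, one labeled and one unlabeled chromatogram AUC
#' whose ratio encodes a known apparent labeling efficiency. Replicates carry
#' multiplicative scale differences (ionization/column effects) and
#' log-normal noise.
#'
#' @param trueEfficiencies named numeric vector (condition -> efficiency in
#'   \[0,1\]); must include a `"control"` condition for normalization tests.
#' @param replicateScales numeric vector of per-replicate abundance scales.
#' @param noiseCV coefficient of variation of the log-normal AUC noise.
#' @param seed integer seed.
#' @param peptide peptide span label (default "M4").
#' @return list with `table` (data.frame: replicate, condition, peptide,
#'   labeled_flag, rt_min, auc, observed_mass, theoretical_mass) and
#'   `groundTruth`.
#' @export
genAUCTable <- function(trueEfficiencies, replicateScales = c(1, 1, 1),
                        noiseCV = 0, seed = 1L, peptide = "M4") {
  if (any(trueEfficiencies < 0 | trueEfficiencies > 1))
    .stopf("efficiencies must lie in [0,1]")
  set.seed(seed)
  sdlog <- sqrt(log(1 + noiseCV^2))
  rows <- list()
  baseAUC <- 1e6
  massU <- 2311.30   # unlabeled peptide monoisotopic mass, synthetic value
  for (r in seq_along(replicateScales)) {
    for (cn in names(trueEfficiencies)) {
      e <- trueEfficiencies[[cn]]
      scale <- replicateScales[r]
      noise <- function() if (noiseCV > 0)
        stats::rlnorm(1, -sdlog^2 / 2, sdlog) else 1
      aucL <- baseAUC * scale * e * noise()
      aucU <- baseAUC * scale * (1 - e) * noise()
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, condition = cn, peptide = peptide,
        labeled_flag = c(FALSE, TRUE), rt_min = c(38.5, 42.1),
        auc = c(aucU, aucL),
        observed_mass = c(massU * (1 + 2e-6), (massU + 330.14) * (1 - 3e-6)),
        theoretical_mass = c(massU, massU + 330.14),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  row.names(tab) <- NULL
  list(table = tab,
       groundTruth = list(trueEfficiencies = as.list(trueEfficiencies),
                          replicateScales = replicateScales,
                          noiseCV = noiseCV, seed = seed))
}
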