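## Shared fixtures, all built in code.

## Default helix residue ranges of the synthetic scaffold.
helixGroupsDefault <- function() {
  list(M1 = 199:222, M2 = 228:250, M3 = 256:280, M4 = 300:320)
}

## Small default-composition membrane for structural tests.
smallMembrane <- function(nFrames = 20L, seed = 42L, ...) {
  genMembraneTraj(membraneSpec(nFrames = nFrames, seed = seed, ...))
}

## Hand-built minimal trajectory: a 5-subunit protein stub (one bead per
## subunit) plus arbitrary lipid molecules at given xy positions.
## lipids: data.frame with species, x, y, leaflet ("outer"/"inner").
tinyTrajectory <- function(lipids, nFrames = 1L, box = c(200, 200, 60),
                           protZ = 0) {
  nP <- 5L
  protXY <- cbind(3 * cos(2 * pi * (0:4) / 5), 3 * sin(2 * pi * (0:4) / 5))
  nL <- nrow(lipids)
  beads <- data.frame(
    bead_index = seq_len(nP + nL),
    molecule_id = c(rep(1L, nP), seq_len(nL) + 1L),
    species = c(rep("PROT", nP), lipids$species),
    residue_id = c(1:nP, seq_len(nL)),
    residue_name = c(rep("GLY", nP), lipids$species),
    subunit = c(LETTERS[1:5], rep("", nL)),
    bead_name = c(rep("BB", nP), rep("HD", nL)),
    is_protein = rep(c(TRUE, FALSE), c(nP, nL)),
    is_headgroup = c(rep(FALSE, nP), rep(TRUE, nL)),
    stringsAsFactors = FALSE)
  z <- ifelse(lipids$leaflet == "outer", 18, -18)
  frame <- rbind(cbind(protXY, protZ), cbind(lipids$x, lipids$y, z))
  coords <- array(rep(frame, nFrames), c(nP + nL, 3L, nFrames))
  newCGTrajectory(beads, coords, box, aligned = TRUE)
}

## Leaflet assignment straight from a tinyTrajectory's construction.
tinyLeaflets <- function(lipids, nFrames = 1L) {
  new("LeafletAssignment",
      moleculeId = seq_len(nrow(lipids)) + 1L,
      leaflet = matrix(lipids$leaflet, nrow(lipids), nFrames))
}

kB <- 0.0019872

## Brute-force oracle: per residue x subunit, any species bead within cutoff
## of any residue bead, straight double loop over beads.
bruteContacts <- function(traj, species, cutoff) {
  b <- beadTable(traj)
  fa <- which(!b$is_protein & b$species == species)
  prot <- which(b$is_protein)
  key <- unique(paste(b$residue_id[prot], b$subunit[prot], sep = "|"))
  nf <- nFrames(traj)
  out <- matrix(0, length(key), nf, dimnames = list(key, NULL))
  for (f in seq_len(nf)) {
    box <- traj@box[f, ]
    for (g in key) {
      parts <- strsplit(g, "|", fixed = TRUE)[[1]]
      rb <- prot[b$residue_id[prot] == as.integer(parts[1]) &
                 b$subunit[prot] == parts[2]]
      hit <- FALSE
      for (i in rb) {
        for (j in fa) {
          d <- traj@coords[j, , f] - traj@coords[i, , f]
          d <- d - box * round(d / box)
          if (sum(d^2) <= cutoff^2) { hit <- TRUE; break }
        }
        if (hit) break
      }
      out[g, f] <- hit
    }
  }
  rowMeans(out)
}

## Minimal pentamer with one residue bead per subunit and controllable
## fatty-acid bead positions per frame.
contactFixture <- function(faXYZ) {
  ## faXYZ: list of per-frame matrices (n_fa x 3)
  nP <- 5L
  protXY <- cbind(10 * cos(2 * pi * (0:4) / 5), 10 * sin(2 * pi * (0:4) / 5))
  nFA <- nrow(faXYZ[[1]])
  nf <- length(faXYZ)
  beads <- data.frame(
    bead_index = seq_len(nP + nFA),
    molecule_id = c(rep(1L, nP), seq_len(nFA) + 1L),
    species = c(rep("PROT", nP), rep("DHA", nFA)),
    residue_id = c(rep(264L, nP), seq_len(nFA)),
    residue_name = c(rep("GLY", nP), rep("DHA", nFA)),
    subunit = c(LETTERS[1:5], rep("", nFA)),
    bead_name = c(rep("BB", nP), rep("COO", nFA)),
    is_protein = rep(c(TRUE, FALSE), c(nP, nFA)),
    is_headgroup = c(rep(FALSE, nP), rep(TRUE, nFA)),
    stringsAsFactors = FALSE)
  co <- array(0, c(nP + nFA, 3, nf))
  for (f in seq_len(nf))
    co[, , f] <- rbind(cbind(protXY, 0), faXYZ[[f]])
  newCGTrajectory(beads, co, c(200, 200, 100), aligned = TRUE)
}

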