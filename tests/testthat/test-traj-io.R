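test_that("toy GRO topology loads with complete bead metadata", {
  gro <- c("toy system", "    3",
           "    1DHA   COO    1   0.500   0.500   1.700",
           "    2POPC  PO4    2   1.000   2.000   1.800",
           "    2POPC  C1     3   1.050   2.050   1.500",
           "  10.00000  10.00000   6.00000")
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro, path)
  cfg <- list(POPC = list(headgroup_beads = "PO4"),
              DHA = list(headgroup_beads = "COO"))
  traj <- loadTrajectory(path, speciesConfig = cfg)
  expect_s4_class(traj, "CGTrajectory")
  b <- beadTable(traj)
  expect_identical(nrow(b), 3L)
  expect_identical(nFrames(traj), 1L)
  expect_identical(b$species, c("DHA", "POPC", "POPC"))
  expect_identical(b$molecule_id, c(1L, 2L, 2L))
  expect_identical(b$is_headgroup, c(TRUE, TRUE, FALSE))
  expect_equal(trajCoords(traj, 1)[2, ], c(10, 20, 18))
  expect_equal(traj@box[1, ], c(100, 100, 60))
  expect_false(isAligned(traj))
})

test_that("unknown residue names give a configuration error naming them", {
  gro <- c("t", "    1",
           "    1DHPC  PO4    1   1.000   1.000   1.000",
           "  10.0  10.0  6.0")
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro, path)
  expect_error(loadTrajectory(path, speciesConfig = list(POPC = list())),
               "DHPC")
})

test_that("generated trajectories round-trip through GRO within format precision", {
  gen <- smallMembrane(nFrames = 3L, seed = 5L)
  traj <- gen$trajectory
  path <- withr::local_tempfile(fileext = ".gro")
  writeGRO(traj, path)
  cfg <- yaml::read_yaml(system.file("extdata", "species_default.yaml",
                                     package = "lipsite"))
  back <- loadTrajectory(path, speciesConfig = cfg)
  expect_identical(dim(back@coords), dim(traj@coords))
  ## GRO stores nm to 3 decimals -> 0.005 A worst case per coordinate
  expect_lt(max(abs(back@coords - traj@coords)), 0.0051)
  expect_identical(back@beads$species, traj@beads$species)
  expect_identical(back@beads$is_protein, traj@beads$is_protein)
  expect_identical(back@beads$is_headgroup, traj@beads$is_headgroup)
  expect_identical(back@beads$subunit, traj@beads$subunit)
  expect_identical(back@beads$residue_id[back@beads$is_protein],
                   traj@beads$residue_id[traj@beads$is_protein])
})

test_that("columnar container round-trips bit-exactly", {
  gen <- smallMembrane(nFrames = 2L, seed = 9L)
  dir <- withr::local_tempdir()
  writeTrajectoryContainer(gen$trajectory, dir)
  back <- readTrajectoryContainer(dir)
  expect_identical(back@coords, gen$trajectory@coords)
  expect_identical(back@beads$molecule_id, gen$trajectory@beads$molecule_id)
  expect_identical(back@aligned, gen$trajectory@aligned)
})

test_that("alignment recovers planted rigid transforms and is idempotent", {
  gen <- smallMembrane(nFrames = 4L, seed = 21L)
  traj <- gen$trajectory
  a1 <- alignFrames(traj)
  ## generator output is already canonical: alignment must be ~identity
  expect_lt(max(abs(a1@coords - traj@coords)), 1e-6)

  ## rotate frame 3 by +30 degrees about z; alignment must undo it
  rot <- traj
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot@coords[, , 3] <- rot@coords[, , 3] %*% R
  a2 <- alignFrames(rot, referenceFrame = 1L)
  expect_lt(max(abs(a2@coords[, , 3] - a1@coords[, , 3])), 1e-6)

  ## translate all beads of frame 2; protein centroid must return to origin
  sh <- traj
  sh@coords[, 1, 2] <- sh@coords[, 1, 2] + 5
  sh@coords[, 2, 2] <- sh@coords[, 2, 2] + 5
  a3 <- alignFrames(sh)
  prot <- a3@beads$is_protein
  expect_lt(max(abs(colMeans(a3@coords[prot, 1:2, 2]))), 1e-9)

  ## idempotence and rigidity
  a4 <- alignFrames(a1)
  expect_lt(max(abs(a4@coords - a1@coords)), 1e-9)
  d0 <- dist(traj@coords[1:40, , 1])
  d1 <- dist(a1@coords[1:40, , 1])
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("alignment requires protein beads", {
  lip <- data.frame(species = "POPC", x = 1, y = 1, leaflet = "outer")
  traj <- tinyTrajectory(lip)
  traj@beads$is_protein <- FALSE
  traj@beads$subunit <- ""
  expect_error(alignFrames(traj), "no protein beads")
})

test_that("leaflet assignment follows headgroup z, per frame", {
  lip <- data.frame(species = c("POPC", "POPC"), x = c(10, -10),
                    y = 0, leaflet = c("outer", "inner"))
  traj <- tinyTrajectory(lip)
  lf <- assignLeaflets(traj)
  expect_identical(as.vector(lf@leaflet[, 1]), c("outer", "inner"))

  ## generator ground truth: 100% agreement with planted labels
  gen <- smallMembrane(nFrames = 10L, seed = 13L)
  lf2 <- assignLeaflets(gen$trajectory)
  truth <- gen$groundTruth$leaflet[as.character(lf2@moleculeId)]
  expect_true(all(lf2@leaflet == matrix(truth, nrow(lf2@leaflet), 10L)))

  ## a lipid crossing the midplane changes label between frames
  traj2 <- tinyTrajectory(lip, nFrames = 2L)
  hd <- which(traj2@beads$molecule_id == 2L)
  traj2@coords[hd, 3, 2] <- -18
  lf3 <- assignLeaflets(traj2)
  expect_identical(as.vector(lf3@leaflet[1, ]), c("outer", "inner"))

  ## lipid without headgroup bead is a configuration error
  traj3 <- tinyTrajectory(lip)
  traj3@beads$is_headgroup[traj3@beads$molecule_id == 2L] <- FALSE
  expect_error(assignLeaflets(traj3), "headgroup")
})

test_that("leaflet counts per frame sum to the lipid molecule count", {
  gen <- smallMembrane(nFrames = 6L, seed = 31L)
  lf <- assignLeaflets(gen$trajectory)
  b <- beadTable(gen$trajectory)
  nLip <- length(unique(b$molecule_id[!b$is_protein]))
  perFrame <- colSums(lf@leaflet == "outer") + colSums(lf@leaflet == "inner")
  expect_true(all(perFrame == nLip))
})

test_that("composition table reports fractions, bead counts and leaflets", {
  gen <- smallMembrane(nFrames = 4L, seed = 2L)
  lf <- assignLeaflets(gen$trajectory)
  comp <- compositionTable(gen$trajectory, lf)
  tb <- comp@table
  expect_equal(sum(tb$molFraction), 1)
  expect_equal(tb$beadsPerMol[tb$species == "DHA"], 3)
  expect_equal(tb$beadsPerMol[tb$species == "POPC"], 12)
  expect_equal(tb$nMolOuter[tb$species == "DHA"], 15)
  expect_equal(comp@meanArea, 160^2)
})
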