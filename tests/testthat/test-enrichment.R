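test_that("boundary metric matches direct arithmetic on a built frame", {
  ## 4 lipids inside the 6 A shell around the protein stub, all species X;
  ## 4 more species-Y lipids far away: chi_X = 0.5, b_X/b_tot = 1 -> B_X = 2
  lip <- data.frame(
    species = rep(c("X", "Y"), each = 4),
    x = c(6, -6, 0, 0, 40, -40, 40, -40),
    y = c(0, 0, 6, -6, 40, 40, -40, -40),
    leaflet = "outer")
  traj <- tinyTrajectory(lip, protZ = 18)   # protein beads near lipid z
  br <- boundaryMetric(traj, shellCutoff = 6)
  tb <- br@table
  expect_equal(tb$B[tb$species == "X"], 2)
  expect_equal(tb$B[tb$species == "Y"], 0)
  ## species absent from the membrane is an undefined-metric error
  expect_error(boundaryMetric(traj, species = "Z"), "absent")
})

test_that("boundary fractions sum to one over species", {
  gen <- smallMembrane(nFrames = 15L, seed = 8L)
  br <- boundaryMetric(gen$trajectory)
  expect_true(all(abs(rowSums(br@series) - 1) < 1e-12))
})

test_that("B is invariant under frame relabeling and rigid rotation", {
  gen <- smallMembrane(nFrames = 12L, seed = 77L)
  traj <- gen$trajectory
  b0 <- boundaryMetric(traj)@table$B
  ## reverse frame order
  rev <- traj
  rev@coords <- traj@coords[, , rev(seq_len(12))]
  expect_equal(boundaryMetric(rev)@table$B, b0)
  ## rigid in-plane rotation of every frame
  th <- 0.7; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0,
                           0, 0, 1), 3, 3)
  rot <- traj
  for (f in 1:12) rot@coords[, , f] <- rot@coords[, , f] %*% R
  expect_equal(boundaryMetric(rot)@table$B, b0, tolerance = 1e-12)
})

test_that("density map bin arithmetic matches the closed form", {
  ## one bead fixed in the bin centered at r = 12.5 A
  lip <- data.frame(species = "X", x = 12.5, y = 0.01, leaflet = "outer")
  traj <- tinyTrajectory(lip, nFrames = 5L)
  lf <- tinyLeaflets(lip, 5L)
  dm <- radialDensityMap(traj, lf, "X", "outer", dr = 5, dtheta = pi / 15,
                         rMax = 70)
  expect_equal(dm@rho[3, 1], 1 / (12.5 * 5 * pi / 15))
  ## all other bins empty
  expect_equal(sum(dm@rho > 0), 1L)
  ## inner leaflet map is empty
  dmI <- radialDensityMap(traj, lf, "X", "inner")
  expect_true(all(dmI@rho == 0))
})

test_that("bin-width configuration errors are raised", {
  lip <- data.frame(species = "X", x = 10, y = 0, leaflet = "outer")
  traj <- tinyTrajectory(lip)
  lf <- tinyLeaflets(lip)
  expect_error(radialDensityMap(traj, lf, "X", dr = 3), "does not divide")
  expect_error(radialDensityMap(traj, lf, "X", dtheta = 1), "does not divide")
  small <- tinyTrajectory(lip, box = c(100, 100, 60))
  expect_warning(radialDensityMap(small, lf, "X", rMax = 60,
                                  dr = 5, dtheta = pi / 15), "half")
})

test_that("mass conservation: sum(rho * bin area) equals mean bead count", {
  gen <- smallMembrane(nFrames = 25L, seed = 4L)
  traj <- gen$trajectory
  lf <- assignLeaflets(traj)
  for (sp in c("DHA", "POPC")) {
    dm <- radialDensityMap(traj, lf, sp, "outer")
    rC <- dm@rEdges[-1] - diff(dm@rEdges) / 2
    binArea <- matrix(rC * 5 * pi / 15, nrow(dm@rho), ncol(dm@rho))
    total <- sum(dm@rho * binArea)
    ## independent count of within-r_max beads of outer-leaflet molecules
    b <- beadTable(traj)
    sel <- which(!b$is_protein & b$species == sp)
    molRow <- match(b$molecule_id[sel], lf@moleculeId)
    cnt <- vapply(seq_len(nFrames(traj)), function(f) {
      keep <- lf@leaflet[molRow, f] == "outer"
      xy <- traj@coords[sel[keep], 1:2, f]
      sum(sqrt(xy[, 1]^2 + xy[, 2]^2) < 70)
    }, 1)
    expect_equal(total, mean(cnt), tolerance = 1e-9)
  }
})

test_that("enhancement normalization identities hold", {
  lip <- data.frame(species = "X", x = 12.5, y = 0.01, leaflet = "outer")
  traj <- tinyTrajectory(lip)
  lf <- tinyLeaflets(lip)
  comp <- compositionTable(traj, lf)
  dm <- radialDensityMap(traj, lf, "X", "outer")
  em <- enhancementMap(dm, comp)
  ## rho~ = rho / bulk, so the occupied bin is rho/bulk and empty bins 0
  bulk <- 1 * 1 * 1 / (200 * 200)   # x_B * s_B * N_L / A (per leaflet)
  expect_equal(em@bulkDensity, bulk)
  expect_equal(em@rhoTilde, dm@rho / bulk)
  ## all-zero density map -> rho~ = 0 everywhere (whole-membrane bulk)
  emI <- enhancementMap(radialDensityMap(traj, lf, "X", "inner"), comp,
                        leafletNormalization = "whole")
  expect_true(all(emI@rhoTilde == 0))
  ## per-leaflet normalization with an empty leaflet is undefined
  expect_error(enhancementMap(radialDensityMap(traj, lf, "X", "inner"),
                              comp), "undefined normalization")
})

test_that("a sector planted at 3x bulk reads ~3 in rho~, ~1 elsewhere", {
  plant <- list(list(site = "M3", subunit = "A", leaflet = "outer",
                     species = "DHA", factor = 3))
  gen <- genMembraneTraj(membraneSpec(nFrames = 400L, seed = 19L,
                                      proteinClearance = 0,
                                      dynamics = "independent",
                                      enhancements = plant))
  traj <- gen$trajectory
  lf <- assignLeaflets(traj)
  em <- enhancementMap(radialDensityMap(traj, lf, "DHA", "outer"),
                       compositionTable(traj, lf))
  ps <- gen$groundTruth$plantedSectors
  s <- ps[ps$leaflet == "outer", ][1, ]
  inside <- sectorMeanEnhancement(em, s$rMin, s$rMax, s$thetaMin, s$thetaMax)
  expect_equal(inside, 3, tolerance = 0.15)
  ## far bulk annulus reads ~1 (vs kappa-adjusted expectation)
  outside <- mean(em@rhoTilde[11:14, ])
  expect_equal(outside, 1, tolerance = 0.1)
})

test_that("uniform membrane gives B and bulk rho~ consistent with 1", {
  gen <- genMembraneTraj(membraneSpec(nFrames = 120L, seed = 23L,
                                      proteinClearance = 0,
                                      dynamics = "independent"))
  traj <- gen$trajectory
  lf <- assignLeaflets(traj)
  br <- boundaryMetric(traj)
  z <- abs(br@table$B - 1) / br@table$sem
  expect_true(all(z < 4))
  em <- enhancementMap(radialDensityMap(traj, lf, "POPC", "outer"),
                       compositionTable(traj, lf))
  expect_equal(mean(em@rhoTilde[11:14, ]), 1, tolerance = 0.03)
})
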