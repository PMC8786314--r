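test_that("the pentamer yields 20 non-overlapping sectors with exact areas", {
  gen <- smallMembrane(nFrames = 5L, seed = 15L)
  geo <- defineSiteSectors(gen$trajectory, helixGroupsDefault())
  st <- siteTable(geo)
  expect_identical(nrow(st), 20L)
  expect_identical(sort(unique(st$site)), c("M1", "M3"))
  expect_identical(sort(unique(st$leaflet)), c("inner", "outer"))
  ## closed-form annular-sector area
  width <- (st$thetaMax - st$thetaMin) %% (2 * pi)
  expect_equal(st$area, (40^2 - 10^2) / 2 * width, tolerance = 1e-9)
  ## exhaustive pairwise non-overlap within each leaflet on a fine angular grid
  for (lf in c("outer", "inner")) {
    s <- st[st$leaflet == lf, ]
    th <- seq(0, 2 * pi, length.out = 3600)
    membership <- sapply(seq_len(nrow(s)), function(j)
      inSector(cbind(25 * cos(th), 25 * sin(th)), s[j, ]))
    expect_true(all(rowSums(membership) <= 1))
  }
})

test_that("sector membership agrees with brute-force point-in-sector", {
  gen <- smallMembrane(nFrames = 2L, seed = 25L)
  st <- siteTable(defineSiteSectors(gen$trajectory, helixGroupsDefault()))
  set.seed(123)
  pts <- cbind(runif(1e4, -60, 60), runif(1e4, -60, 60))
  r <- sqrt(rowSums(pts^2))
  th <- atan2(pts[, 2], pts[, 1]) %% (2 * pi)
  for (j in c(1, 7, 14, 20)) {
    s <- st[j, ]
    w <- (s$thetaMax - s$thetaMin) %% (2 * pi)
    brute <- r >= s$rMin & r < s$rMax & ((th - s$thetaMin) %% (2 * pi)) < w
    expect_identical(inSector(pts, s), brute)
  }
})

test_that("rotating the system by 72 degrees leaves the sector set invariant", {
  gen <- smallMembrane(nFrames = 3L, seed = 33L)
  traj <- gen$trajectory
  st1 <- siteTable(defineSiteSectors(traj, helixGroupsDefault()))
  th <- 2 * pi / 5
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- traj
  for (f in 1:3) rot@coords[, , f] <- rot@coords[, , f] %*% R
  st2 <- siteTable(defineSiteSectors(rot, helixGroupsDefault()))
  ## 72 deg is the pentamer period: the sector set is invariant up to
  ## subunit relabeling
  key <- function(s) {
    k <- s[order(s$site, s$leaflet, round(s$thetaMin, 9)),
           c("site", "leaflet", "thetaMin", "thetaMax")]
    row.names(k) <- NULL
    k
  }
  expect_equal(key(st2), key(st1), tolerance = 1e-9)
})

test_that("geometry errors are raised for non-pentameric azimuths", {
  expect_error(
    lipsite:::.sectorBoundsFromAzimuths(
      aziM1 = rep(0.1, 5), aziM3 = rep(0.1, 5), aziM4 = rep(0.1, 5),
      subunits = LETTERS[1:5]),
    "geometry error")
})

test_that("occupancy histograms behave on degenerate and planted inputs", {
  gen <- smallMembrane(nFrames = 10L, seed = 3L,
                       nFattyAcidPerLeaflet = 0L)
  st <- siteTable(defineSiteSectors(gen$trajectory, helixGroupsDefault()))
  lf <- assignLeaflets(gen$trajectory)
  ## no fatty acids in the system -> all mass at n = 0
  h0 <- occupancyHistogram(gen$trajectory, lf, st[1, ], "DHA")
  expect_equal(h0@counts, 10)
  expect_equal(meanOccupancy(h0), 0)

  ## one bead pinned inside the sector every frame -> all mass at n = 1
  s <- st[st$site == "M1" & st$subunit == "A" & st$leaflet == "outer", ]
  mid <- (s$thetaMin + ((s$thetaMax - s$thetaMin) %% (2 * pi)) / 2) %% (2 * pi)
  lip <- data.frame(species = "DHA", x = 25 * cos(mid), y = 25 * sin(mid),
                    leaflet = "outer")
  traj <- tinyTrajectory(lip, nFrames = 7L)
  lf2 <- tinyLeaflets(lip, 7L)
  h1 <- occupancyHistogram(traj, lf2, s, "DHA")
  expect_equal(h1@counts, c(0, 7))
  expect_equal(meanOccupancy(h1), 1)
})

test_that("site occupancy matches a Poisson oracle under uniform placement", {
  ## single-bead fatty acids so bead counts are molecule counts (Poisson)
  gen <- genMembraneTraj(membraneSpec(nFrames = 400L, seed = 55L,
                                      proteinClearance = 0,
                                      dynamics = "independent",
                                      beadsPerFattyAcid = 1L))
  traj <- gen$trajectory
  lf <- assignLeaflets(traj)
  st <- siteTable(defineSiteSectors(traj, helixGroupsDefault()))
  s <- st[st$site == "M3" & st$subunit == "B" & st$leaflet == "outer", ]
  h <- occupancyHistogram(traj, lf, s, "DHA")
  lambda <- 15 / 160^2 * s$area
  ## mean within sampling error of the Poisson mean
  sem <- sqrt(lambda / 400)
  expect_lt(abs(meanOccupancy(h) - lambda), 4 * sem)
  ## cell probabilities within multinomial sampling error of Poisson(lambda)
  p <- h@counts / h@nFrames
  pois <- dpois(seq_along(p) - 1, lambda)
  tol <- 4 * sqrt(pmax(pois * (1 - pois), 0.01) / 400)
  expect_true(all(abs(p - pois) < tol))
})

test_that("bulk reference histogram is calibrated and area-linear", {
  gen <- genMembraneTraj(membraneSpec(nFrames = 300L, seed = 61L,
                                      proteinClearance = 0,
                                      dynamics = "independent"))
  traj <- gen$trajectory
  lf <- assignLeaflets(traj)
  d <- 15 * 3 / 160^2               # outer-leaflet fatty-acid bead density
  area <- 471.2389
  hB <- bulkReferenceHistogram(traj, lf, "DHA", area, leaflet = "outer",
                               seed = 2)
  expect_lt(abs(meanOccupancy(hB) - d * area), 3 * sqrt(d * area / 2000))
  ## doubling the area doubles the mean within sampling error
  hB2 <- bulkReferenceHistogram(traj, lf, "DHA", 2 * area, leaflet = "outer",
                                seed = 3)
  expect_equal(meanOccupancy(hB2) / meanOccupancy(hB), 2, tolerance = 0.15)
  ## zero species -> all mass at n = 0
  genEmpty <- smallMembrane(nFrames = 5L, seed = 4L, nFattyAcidPerLeaflet = 0L)
  lfE <- assignLeaflets(genEmpty$trajectory)
  hE <- bulkReferenceHistogram(genEmpty$trajectory, lfE, "DHA", area,
                               seed = 2)
  expect_equal(meanOccupancy(hE), 0)
  ## area larger than the annulus is an error
  expect_error(bulkReferenceHistogram(traj, lf, "DHA", 1e5, seed = 2),
               "exceeds")
})

test_that("threshold affinity identities: zero, antisymmetry, infinities", {
  mkHist <- function(counts, area = 471) {
    new("OccupancyHistogram", counts = as.numeric(counts),
        nFrames = as.integer(sum(counts)),
        region = "test", species = "DHA", area = area)
  }
  hA <- mkHist(c(40, 30, 20, 10))
  hB <- mkHist(c(10, 20, 30, 40))
  ## identical distributions -> dG = 0 for both estimators
  for (est in c("threshold", "mean_ratio"))
    expect_equal(deltaG(thresholdAffinity(hA, hA, estimator = est)), 0)
  ## antisymmetry of the mean-ratio estimator
  a1 <- thresholdAffinity(hA, hB, estimator = "mean_ratio")
  a2 <- thresholdAffinity(hB, hA, estimator = "mean_ratio")
  expect_equal(deltaG(a1), -deltaG(a2))
  ## site never reaching n* while bulk does -> +Inf flag
  hZ <- mkHist(c(100))
  res <- thresholdAffinity(hZ, hB, estimator = "threshold", nStar = 2)
  expect_false(res@finite)
  expect_identical(deltaG(res), Inf)
  ## favorable = negative: enriched site
  expect_lt(deltaG(a2), 0)
})

test_that("mean-ratio dG recovers -kT ln f on planted Poisson histograms", {
  set.seed(11)
  T <- 323
  for (f in c(1 / 3, 1 / 2, 2, 3)) {
    lam <- 0.8
    siteCounts <- tabulate(rpois(4000, f * lam) + 1L)
    bulkCounts <- tabulate(rpois(4000, lam) + 1L)
    mk <- function(cn) new("OccupancyHistogram", counts = as.numeric(cn),
                           nFrames = sum(cn), region = "x", species = "DHA",
                           area = 471)
    a <- thresholdAffinity(mk(siteCounts), mk(bulkCounts),
                           estimator = "mean_ratio", temperature = T)
    expect_equal(deltaG(a), -kB * T * log(f), tolerance = 0.12)
  }
})

test_that("outer-leaflet-only enrichment orders site affinities by leaflet", {
  plant <- list(list(site = "M3", subunit = "all", leaflet = "outer",
                     species = "DHA", factor = 3))
  gen <- genMembraneTraj(membraneSpec(nFrames = 500L, seed = 71L,
                                      proteinClearance = 0,
                                      dynamics = "independent",
                                      enhancements = plant))
  traj <- gen$trajectory
  lf <- assignLeaflets(traj)
  st <- siteTable(defineSiteSectors(traj, helixGroupsDefault()))
  dgFor <- function(leaflet) {
    sites <- st[st$site == "M3" & st$leaflet == leaflet, ]
    hS <- poolHistograms(lapply(seq_len(nrow(sites)), function(j)
      occupancyHistogram(traj, lf, sites[j, ], "DHA")))
    hB <- bulkReferenceHistogram(traj, lf, "DHA", sites$area[1],
                                 leaflet = leaflet, seed = 5)
    deltaG(thresholdAffinity(hS, hB, estimator = "mean_ratio"))
  }
  expect_lt(dgFor("outer"), dgFor("inner"))
})
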