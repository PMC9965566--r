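test_that("dark binarization uses a strict grey-value threshold", {
  expect_false(any(binarizeDark(makeImage(50L))))
  expect_true(all(binarizeDark(makeImage(49L))))
  img <- makeImage(180L, 30, 30)
  g <- greyValues(img); g[10:12, 10:12] <- 30L
  img <- EnFaceImage(g)
  expect_equal(sum(binarizeDark(img)), 9)
  expect_error(binarizeDark(makeImage(10L), greyThreshold = 256),
               "greyThreshold")
})

test_that("component labeling matches the definition of 4- and 8-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(max(labelComponents(m, 8)), 1)
  expect_equal(max(labelComponents(m, 4)), 2)
  expect_equal(max(labelComponents(matrix(FALSE, 5, 5), 8)), 0)
  expect_error(labelComponents(m, 6), "connectivity")
})

test_that("component labeling agrees with a flood-fill oracle on random grids", {
  set.seed(11)
  for (rep in 1:12) {
    dens <- runif(1, 0.15, 0.6)
    m <- matrix(runif(2500) < dens, 50, 50)
    for (conn in c(4, 8)) {
      got <- labelComponents(m, conn)
      want <- floodLabelOracle(m, conn)
      # same partition: identical component count and identical pixel sets
      expect_equal(max(got), max(want))
      expect_true(all((got > 0) == (want > 0)))
      key <- paste(got[m], want[m])
      expect_equal(length(unique(key)), max(got))
    }
  }
})

test_that("4-connectivity labeling agrees with EBImage::bwlabel", {
  set.seed(21)
  for (rep in 1:5) {
    m <- matrix(runif(1600) < 0.4, 40, 40)
    got <- labelComponents(m, 4)
    ref <- EBImage::bwlabel(m * 1)
    expect_equal(max(got), max(ref))
    key <- paste(got[m], ref[m])
    expect_equal(length(unique(key)), max(got))
  }
})

test_that("detection applies the strict grey and area rules", {
  nr <- 60; nc <- 60
  zones <- makeZones(nr, nc, beta = c(5, 55, 5, 55))

  expect_equal(nRegions(detectMvd(makeImage(200L, nr, nc), zones)), 0)

  # 15 px is not 'exceeding 20 pixels'
  g <- matrix(200L, nr, nc); g[20:22, 20:24] <- 30L
  expect_equal(nRegions(detectMvd(EnFaceImage(g), zones)), 0)

  # exactly 20 px still fails the strict rule
  g <- matrix(200L, nr, nc); g[20:23, 20:24] <- 30L
  expect_equal(nRegions(detectMvd(EnFaceImage(g), zones)), 0)

  # 25 px passes; area in mm2 is the pixel count times 126.5625 um2
  g <- matrix(200L, nr, nc); g[20:24, 20:24] <- 30L
  out <- detectMvd(EnFaceImage(g), zones)
  expect_equal(nRegions(out), 1)
  tab <- regionTable(out)
  expect_equal(tab$area_px, 25)
  expect_equal(tab$area_mm2, 25 * 126.5625 / 1e6)
  expect_equal(tab$zone, "beta")
  expect_equal(tab$min_grey, 30)
})

test_that("regions are sorted by area then centroid and ids are dense", {
  nr <- 60; nc <- 60
  g <- matrix(200L, nr, nc)
  g[5:10, 5:10] <- 20L      # 36 px
  g[40:44, 40:49] <- 20L    # 50 px
  g[30:35, 20:25] <- 20L    # 36 px, centroid below/right of first
  out <- detectMvd(EnFaceImage(g), fullBetaZones(nr, nc))
  tab <- regionTable(out)
  expect_equal(tab$region_id, 1:3)
  expect_equal(tab$area_px, c(50, 36, 36))
  expect_lt(tab$centroid_row[2], tab$centroid_row[3])
})

test_that("zone assignment is by majority with ties going to beta", {
  nr <- 30; nc <- 30
  zones <- makeZones(nr, nc, beta = c(1, 30, 1, 15), alpha = c(1, 30, 16, 30))
  fully <- cbind(row = rep(5:9, 3), col = rep(3:5, each = 5))
  expect_equal(assignZone(fully, zones), "beta")
  # 60% alpha / 40% beta
  px <- cbind(row = rep(10, 10), col = 12:21)
  expect_equal(assignZone(px, zones), "alpha")
  # exact 50/50 tie -> beta
  px <- cbind(row = rep(10, 10), col = 11:20)
  expect_equal(assignZone(px, zones), "beta")
  out <- matrix(c(1L, 1L), 1, 2)
  expect_error(assignZone(out, makeZones(nr, nc)), "outside both")
})

test_that("detection equals the brute-force oracle on random images", {
  set.seed(31)
  for (rep in 1:20) {
    nr <- 64; nc <- 64
    g <- matrix(sample(0:255, nr * nc, TRUE), nr, nc)
    img <- EnFaceImage(g)
    zones <- if (rep %% 2) fullBetaZones(nr, nc) else
      makeZones(nr, nc, beta = c(5, 60, 5, 40), alpha = c(5, 60, 45, 62))
    vessels <- if (rep %% 3 == 0)
      VesselMask(matrix(runif(nr * nc) < 0.05, nr, nc)) else NULL
    for (conn in c(4, 8)) {
      got <- detectMvd(img, zones, vessels, connectivity = conn)
      want <- bruteForceDetect(img, zones, vessels, connectivity = conn)
      expect_equal(regionTable(got)$area_px, want$areas)
      union <- matrix(FALSE, nr, nc)
      for (p in regionPixels(got)) union[p] <- TRUE
      expect_identical(union, want$union)
    }
  }
})

test_that("detected totals are monotone in the thresholds", {
  set.seed(41)
  g <- matrix(sample(30:80, 3600, TRUE), 60, 60)
  img <- EnFaceImage(g)
  zones <- fullBetaZones(60, 60)
  area <- function(thr, minA) {
    tab <- regionTable(detectMvd(img, zones, greyThreshold = thr,
                                 minAreaPx = minA))
    c(n = nrow(tab), a = sum(tab$area_px))
  }
  base <- area(50, 20)
  higher <- area(60, 20)
  lowerMin <- area(50, 10)
  expect_gte(higher["a"], base["a"])
  expect_gte(lowerMin["a"], base["a"])
  expect_gte(lowerMin["n"], base["n"])
})

test_that("region areas are additive and regions disjoint", {
  set.seed(51)
  g <- matrix(sample(c(20L, 200L), 3600, TRUE, prob = c(0.3, 0.7)), 60, 60)
  img <- EnFaceImage(g)
  out <- detectMvd(img, fullBetaZones(60, 60))
  tab <- regionTable(out)
  union <- matrix(FALSE, 60, 60)
  total <- 0L
  for (p in regionPixels(out)) {
    expect_false(any(union[p]))     # disjoint
    union[p] <- TRUE
    total <- total + nrow(p)
  }
  expect_equal(sum(tab$area_px), total)
  expect_equal(sum(tab$area_mm2), sum(union) * pixelAreaUm2(img) / 1e6)
})

test_that("vessel exclusion can split a region, each part filtered on its own", {
  nr <- 40; nc <- 40
  g <- matrix(200L, nr, nc)
  g[10:14, 6:15] <- 30L                 # 5 x 10 = 50-px blob
  img <- EnFaceImage(g)
  zones <- fullBetaZones(nr, nc)
  v <- matrix(FALSE, nr, nc); v[10:14, 10] <- TRUE   # cut into 20 + 25
  out <- detectMvd(img, zones, VesselMask(v))
  tab <- regionTable(out)
  expect_equal(tab$area_px, 25)          # the 20-px half fails 'exceeding 20'
  # covering half exactly: area equals the uncovered half only
  v2 <- matrix(FALSE, nr, nc); v2[10:14, 6:10] <- TRUE
  out2 <- detectMvd(img, zones, VesselMask(v2))
  expect_equal(regionTable(out2)$area_px, 25)
})

test_that("zone clipping before vs after labeling behaves as documented", {
  nr <- 40; nc <- 40
  g <- matrix(200L, nr, nc)
  g[10:14, 8:17] <- 30L                  # 50-px blob straddling zone edge
  img <- EnFaceImage(g)
  zones <- makeZones(nr, nc, beta = c(1, 40, 12, 40))
  # clip first: only the 5 x 6 = 30 px inside beta are labeled
  a <- regionTable(detectMvd(img, zones, clipZonesFirst = TRUE))
  expect_equal(a$area_px, 30)
  # label first: the full component is found, then restricted to the zone
  b <- regionTable(detectMvd(img, zones, clipZonesFirst = FALSE))
  expect_equal(b$area_px, 30)
})
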