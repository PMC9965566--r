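test_that("profile validation enforces the generator invariants", {
  p <- generatorProfile("high_myopia")
  expect_s3_class(p, "mvdGeneratorProfile")
  expect_error(generatorProfile("high_myopia",
                                overrides = list(mvd = list(presence_prob = 1.2))),
               "probabilities")
  expect_error(generatorProfile("high_myopia",
                                overrides = list(mvd = list(grey = list(max = 60)))),
               "grey support")
  expect_error(generatorProfile("high_myopia",
                                overrides = list(background = list(mean_grey = 60))),
               "background mean grey")
  expect_error(generatorProfile("no_such_profile"), "not found")
})

test_that("eye truth sampling respects the presence gate and group bounds", {
  p0 <- generatorProfile("mild_moderate",
                         overrides = list(mvd = list(presence_prob = 0)))
  t0 <- sampleEyeTruth(p0, 1, seed = 4)
  expect_false(t0$mvd_present)
  expect_length(t0$region_sizes_px, 0)

  p <- generatorProfile("high_myopia")
  for (i in 1:20) {
    t <- sampleEyeTruth(p, i, seed = 100 + i)
    expect_true(t$record$SE >= -10 && t$record$SE <= -6)
    expect_true(t$record$quality_score >= 6)
    if (t$mvd_present) {
      expect_true(all(t$region_sizes_px >= 21))
      expect_lte(sum(t$region_sizes_px), 0.6 * t$beta_px)
    }
  }
})

test_that("sampled SE matches the profile's truncated-normal moments", {
  p <- generatorProfile("high_myopia")
  set.seed(7)
  se <- replicate(4000, sampleEyeTruth(p)$record$SE)
  m <- p$se_trunc
  expect_lt(abs(mean(se) - m$mean), 3 * m$sd / sqrt(4000))
  expect_equal(sd(se), m$sd, tolerance = 0.08)
  # the realized distribution emulates the reported arm moments
  expect_equal(m$mean, -7.14, tolerance = 1e-3)
  expect_equal(m$sd, 0.927, tolerance = 1e-3)
})

test_that("same seed gives identical eyes, different seeds differ", {
  p <- generatorProfile("mild_moderate")
  a <- simulateEye(p, 3, 9)
  b <- simulateEye(p, 3, 9)
  expect_identical(greyValues(a$image), greyValues(b$image))
  expect_identical(a$truth$record, b$truth$record)
  c <- simulateEye(p, 3, 10)
  expect_false(identical(greyValues(a$image), greyValues(c$image)))
})

test_that("rendering honors the zero-noise limit and dropout grey bound", {
  p <- generatorProfile("high_myopia",
                        overrides = list(background = list(speckle_sd = 0),
                                         vessels = list(n_trees = 0),
                                         disc_render = list(grey_sd = 0)))
  eye <- simulateEye(p, 1, 5)
  g <- greyValues(eye$image)
  structures <- eye$mvdMask | zoneMask(eye$zones, "disc")
  expect_true(all(g[!structures] == p$background$mean_grey))
  expect_true(all(g[eye$mvdMask] < 50))
  expect_true(all(g[eye$mvdMask] >= 0))
})

test_that("zone geometry: beta adjacent to disc, alpha peripheral to beta", {
  p <- generatorProfile("high_myopia")
  for (s in 1:4) {
    eye <- simulateEye(p, s, 20 + s)
    disc <- zoneMask(eye$zones, "disc")
    beta <- zoneMask(eye$zones, "beta")
    alpha <- zoneMask(eye$zones, "alpha")
    expect_false(any(disc & beta) || any(disc & alpha) || any(beta & alpha))
    # 4-connected adjacency between beta and the disc boundary
    discDil <- mvdquant:::dilateMask(disc, 1L)
    expect_true(any(discDil & beta))
    if (sum(alpha)) {
      # alpha pixels lie farther from the disc centroid than the nearest
      # beta pixel at the same angle
      ctr <- c(mean(which(disc, arr.ind = TRUE)[, 1]),
               mean(which(disc, arr.ind = TRUE)[, 2]))
      pol <- function(m) {
        rc <- which(m, arr.ind = TRUE)
        list(r = sqrt((rc[, 1] - ctr[1])^2 + (rc[, 2] - ctr[2])^2),
             a = atan2(rc[, 2] - ctr[2], rc[, 1] - ctr[1]))
      }
      pb <- pol(beta); pa <- pol(alpha)
      bins <- seq(-pi, pi, length.out = 73)
      bb <- cut(pb$a, bins); ba <- cut(pa$a, bins)
      minBeta <- tapply(pb$r, bb, min)
      for (lev in levels(ba)[table(ba) > 0]) {
        if (!is.na(minBeta[lev]))
          expect_gte(min(pa$r[ba == lev]), minBeta[lev])
      }
    }
    # every planted dropout pixel lies inside a PPA mask
    expect_true(all(!eye$mvdMask | (beta | alpha)))
  }
})

test_that("a planted 30-px region is recovered exactly in a vessel-free eye", {
  p <- generatorProfile("mild_moderate", overrides = vesselFree)
  truth <- sampleEyeTruth(p, 1, seed = 33)
  truth$mvd_present <- TRUE
  truth$region_sizes_px <- 30L
  truth$alpha_region_sizes_px <- integer(0)
  eye <- renderEye(truth, p, seed = 34)
  out <- detectMvd(eye$image, eye$zones)
  tab <- regionTable(out)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$area_px, 30)
  expect_equal(tab$zone, "beta")
  expect_equal(eye$truth$true_total_mvd_beta_px, 30)
})

test_that("cohorts written to disk round trip and are deterministic", {
  p <- generatorProfile("mild_moderate", overrides = list(n_eyes = 3))
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generateCohort(p, d1, seed = 2)
  m2 <- generateCohort(p, d2, seed = 2)
  expect_identical(readBin(file.path(d1, "manifest.csv"), "raw", 1e6),
                   readBin(file.path(d2, "manifest.csv"), "raw", 1e6))
  rec <- readManifest(file.path(d1, "manifest.csv"))
  expect_equal(nrow(rec), 3)
  expect_equal(rec$group, rep("mild_moderate", 3))

  eid <- rec$eye_id[1]
  img <- readEnFaceImage(file.path(d1, paste0(eid, "_octa.png")))
  zones <- readZoneSet(file.path(d1, paste0(eid, "_disc.png")),
                       file.path(d1, paste0(eid, "_alpha.png")),
                       file.path(d1, paste0(eid, "_beta.png")), img)
  expect_s4_class(zones, "ZoneSet")
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(truth$seed, 2)
  expect_length(truth$eyes, 3)

  # the files reproduce the in-memory eye exactly
  eye <- simulateEye(p, 1, 2)
  expect_identical(greyValues(img), greyValues(eye$image))

  # an empty cohort writes an empty manifest and nothing else
  d0 <- file.path(tempdir(), "coh0")
  unlink(d0, recursive = TRUE)
  m0 <- generateCohort(p, d0, seed = 2, nEyes = 0)
  expect_equal(nrow(m0), 0)
  expect_equal(length(list.files(d0, pattern = "png$")), 0)
})
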