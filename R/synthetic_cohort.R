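# Synthetic peripapillary cohort generator.
#
# Each eye is sampled in two stages. sampleEyeTruth draws the clinical
# covariates and the ground-truth areas: SE from a truncated normal on the
# group's inclusion interval; AL linearly coupled to SE with residual noise;
# PPA-beta area lognormal around the group mean with an SE term; total
# dropout area log-linear in PPA-beta area with AL and age terms (the
# coupling that induces the cohort-level correlations) behind a Bernoulli
# presence gate. renderEye realizes the eye as an image: correlated speckle
# background, a wobbled disc with the PPA-beta annulus adjacent to it and
# the PPA-alpha annulus peripheral to beta, bright vessel trees, and planted
# dark dropout regions grown as random connected blobs of exactly the
# planned pixel counts.

#' Sample the ground truth for one synthetic eye
#'
#' Uses the current RNG state unless \code{seed} is given. The total dropout
#' pixel budget is coupled to the true PPA-beta area on the log scale (plus
#' AL and age terms), floored at one minimal detectable region and capped at
#' 60\% of the beta zone, then split into connected-region pixel counts of
#' at least \code{min_region_px} each.
#'
#' @param profile a \code{\link{generatorProfile}}.
#' @param index eye index within the cohort (used for identifiers).
#' @param seed optional integer seed.
#' @return a list ("eye truth"): \code{record} (one manifest row),
#'   target zone areas, dropout presence, and the per-region pixel plan.
#' @export
sampleEyeTruth <- function(profile, index = 1L, seed = NULL) {
  if (!is.null(seed)) return(withSeed(seed, sampleEyeTruth(profile, index)))
  cv <- profile$covariates
  pitch <- profile$grid$pixel_pitch_um
  apx <- pitch^2 / 1e6                       # pixel area in mm^2

  se <- rtruncnorm(1, cv$se$mean, cv$se$sd, cv$se$lower, cv$se$upper)
  zse <- if (profile$se_trunc$sd > 0)
    (se - profile$se_trunc$mean) / profile$se_trunc$sd else 0
  al <- cv$al$mean + cv$al$se_corr * cv$al$sd * zse +
    cv$al$sd * sqrt(max(0, 1 - cv$al$se_corr^2)) * stats::rnorm(1)
  age <- rtruncnorm(1, cv$age$mean, cv$age$sd, cv$age$lower, cv$age$upper)
  sex <- if (stats::runif(1) < cv$female_prob) "F" else "M"
  quality <- sample(6:10, 1, prob = profile$quality$score_probs)

  # PPA-beta area: lognormal with exact mean at the profile target
  zb <- profile$zones$ppa_beta_area
  vlog <- zb$se_coef^2 + zb$sdlog^2
  logBeta <- log(zb$mean_mm2) - vlog / 2 + zb$se_coef * (-zse) +
    zb$sdlog * stats::rnorm(1)
  betaArea <- max(zb$min_mm2, exp(logBeta))
  betaPx <- max(1L, as.integer(round(betaArea / apx)))

  za <- profile$zones$ppa_alpha
  alphaPresent <- stats::runif(1) < za$presence_prob
  alphaPx <- 0L
  if (alphaPresent) {
    la <- log(za$area$mean_mm2) - za$area$sdlog^2 / 2 +
      za$area$sdlog * stats::rnorm(1)
    alphaPx <- max(1L, as.integer(round(max(za$area$min_mm2, exp(la)) / apx)))
  }

  mv <- profile$mvd
  present <- stats::runif(1) < mv$presence_prob
  sizes <- integer(0)
  if (present) {
    cp <- mv$coupling
    meanLogBeta <- log(zb$mean_mm2) - vlog / 2
    logM <- cp$intercept_log + cp$log_beta_coef * (log(betaArea) - meanLogBeta) +
      cp$al_coef * (al - cv$al$mean) +
      cp$age_coef * (age - profile$age_trunc$mean) +
      cp$sigma_log * stats::rnorm(1)
    totalPx <- as.integer(round(exp(logM) / apx))
    totalPx <- max(mv$min_region_px, min(totalPx, as.integer(0.6 * betaPx)))
    sizes <- planRegionSizes(totalPx, mv$min_region_px,
                             mv$regions_per_700px, mv$max_regions)
  }

  alphaSizes <- integer(0)
  if (present && alphaPresent &&
      stats::runif(1) < mv$alpha$presence_prob_given_alpha) {
    la <- log(mv$alpha$area$mean_mm2) - mv$alpha$area$sdlog^2 / 2 +
      mv$alpha$area$sdlog * stats::rnorm(1)
    apxN <- as.integer(round(exp(la) / apx))
    apxN <- max(mv$min_region_px, min(apxN, as.integer(0.5 * alphaPx)))
    if (apxN >= mv$min_region_px)
      alphaSizes <- planRegionSizes(apxN, mv$min_region_px,
                                    mv$regions_per_700px, 2L)
  }

  eid <- sprintf("%s_%03d", profile$name, index)
  record <- data.frame(eye_id = eid, subject_id = eid, age = age, sex = sex,
                       SE = se, AL = al, quality_score = quality,
                       artifact_flags = "", group = profile$group,
                       stringsAsFactors = FALSE)
  list(record = record,
       beta_area_mm2 = betaArea, beta_px = betaPx,
       alpha_present = alphaPresent, alpha_px = alphaPx,
       mvd_present = present,
       region_sizes_px = sizes,
       alpha_region_sizes_px = alphaSizes)
}

# Split a pixel budget into region sizes, each >= minPx, summing exactly to
# the budget.
planRegionSizes <- function(totalPx, minPx, regionsPer700, maxRegions) {
  if (totalPx < minPx) return(integer(0))
  kMax <- min(maxRegions, totalPx %/% minPx)
  k <- 1L + stats::rpois(1, totalPx * regionsPer700 / 700)
  k <- max(1L, min(k, kMax))
  w <- stats::rgamma(k, shape = 1.5)
  sizes <- floor(totalPx * w / sum(w))
  sizes[1] <- sizes[1] + (totalPx - sum(sizes))
  while (any(sizes < minPx) && length(sizes) > 1) {
    i <- which.min(sizes)
    j <- which.max(sizes)
    deficit <- minPx - sizes[i]
    if (sizes[j] - deficit >= minPx) {
      sizes[j] <- sizes[j] - deficit
      sizes[i] <- minPx
    } else {
      sizes[j] <- sizes[j] + sizes[i]
      sizes <- sizes[-i]
    }
  }
  as.integer(sizes)
}

# Smooth 2*pi-periodic wobble in [-1, 1] evaluated at angles theta.
wobbleFun <- function(harmonics) {
  a <- stats::rnorm(harmonics) / seq_len(harmonics)
  phi <- stats::runif(harmonics, 0, 2 * pi)
  function(theta) {
    w <- 0
    for (k in seq_len(harmonics)) w <- w + a[k] * cos(k * theta + phi[k])
    m <- max(abs(w), 1e-9)
    w / m
  }
}

# Grow one connected blob of exactly `size` pixels inside `allowed`
# (4-neighbour growth, so the blob is connected under both connectivities).
growBlob <- function(allowed, size, maxTries = 8L) {
  nr <- nrow(allowed); nc <- ncol(allowed)
  avail <- which(allowed)
  if (length(avail) < size) return(NULL)
  for (try in seq_len(maxTries)) {
    seedPx <- avail[sample.int(length(avail), 1)]
    inRegion <- matrix(FALSE, nr, nc)
    inRegion[seedPx] <- TRUE
    region <- integer(size); region[1] <- seedPx; nReg <- 1L
    cand <- blobNeighbours(seedPx, nr, nc)
    while (nReg < size && length(cand)) {
      i <- sample.int(length(cand), 1)
      p <- cand[i]
      cand <- cand[-i]
      if (!allowed[p] || inRegion[p]) next
      inRegion[p] <- TRUE
      nReg <- nReg + 1L
      region[nReg] <- p
      cand <- c(cand, blobNeighbours(p, nr, nc))
    }
    if (nReg == size) return(region)
  }
  NULL
}

blobNeighbours <- function(p, nr, nc) {
  r <- (p - 1L) %% nr + 1L
  cc <- (p - 1L) %/% nr + 1L
  out <- integer(0)
  if (r > 1L) out <- c(out, p - 1L)
  if (r < nr) out <- c(out, p + 1L)
  if (cc > 1L) out <- c(out, p - nr)
  if (cc < nc) out <- c(out, p + nr)
  out
}

# Stamp offsets for a filled disc of the given radius (pixels).
discOffsets <- function(radius, nr) {
  r <- ceiling(radius)
  dr <- rep(-r:r, times = 2 * r + 1)
  dc <- rep(-r:r, each = 2 * r + 1)
  keep <- dr^2 + dc^2 <= radius^2
  list(dr = dr[keep], dc = dc[keep])
}

#' Render one synthetic eye
#'
#' Realizes an eye truth as an en-face image plus zone masks and the
#' ground-truth dropout mask. The image is correlated speckle background
#' plus a textured disc, bright vessel trees radiating from the disc, and
#' planted dark dropout regions (grey value below 50 by construction). Zone
#' geometry: the PPA-beta annulus is grown outward from the disc boundary in
#' perturbed-distance order, so beta is adjacent to the disc and alpha
#' (grown next in the same ordering) is peripheral to beta at every angle.
#'
#' @param truth an eye truth from \code{\link{sampleEyeTruth}}.
#' @param profile the \code{\link{generatorProfile}} used to sample it.
#' @param seed optional integer seed.
#' @return list with \code{image} (\code{\linkS4class{EnFaceImage}}),
#'   \code{zones} (\code{\linkS4class{ZoneSet}}), \code{mvdMask} (logical
#'   ground-truth dropout mask), \code{vesselTruth} (logical mask of
#'   rendered vessel pixels), and \code{truth} augmented with the achieved
#'   region pixel sets and per-zone true totals.
#' @export
renderEye <- function(truth, profile, seed = NULL) {
  if (!is.null(seed)) return(withSeed(seed, renderEye(truth, profile)))
  nr <- profile$grid$height_px; nc <- profile$grid$width_px
  pitch <- profile$grid$pixel_pitch_um
  apx <- pitch^2 / 1e6
  zcfg <- profile$zones

  centerR <- nr / 2 + stats::runif(1, -6, 6)
  centerC <- nc / 2 + stats::runif(1, -6, 6)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- sqrt((rows - centerR)^2 + (cols - centerC)^2)
  theta <- atan2(cols - centerC, rows - centerR)

  wDisc <- wobbleFun(zcfg$wobble$harmonics)
  discR <- zcfg$disc_radius_px * (1 + 0.04 * wDisc(theta))
  disc <- d <= discR

  nBeta <- truth$beta_px
  nAlpha <- if (truth$alpha_present) truth$alpha_px else 0L
  ringR <- zcfg$disc_radius_px
  thickness <- nBeta / (2 * pi * (ringR + 3))
  amp <- min(zcfg$wobble$amplitude_px, thickness / 3)
  wRing <- wobbleFun(zcfg$wobble$harmonics)
  key <- d + amp * wRing(theta)
  outside <- which(!disc)
  ord <- outside[order(key[outside])]
  if (nBeta + nAlpha > length(ord))
    stop("zone areas exceed the image grid", call. = FALSE)
  beta <- matrix(FALSE, nr, nc); beta[ord[seq_len(nBeta)]] <- TRUE
  # alpha zone as a crescent peripheral to beta: an angular window wide
  # enough to give the crescent a workable radial thickness (PPA-alpha in
  # fundus images is typically a crescent, not a closed ring)
  alpha <- matrix(FALSE, nr, nc)
  if (nAlpha > 0) {
    rBetaOut <- sqrt((sum(disc) + nBeta) / pi)
    tAlpha <- max(8, min(16, nAlpha / 150))
    dTheta <- min(2 * pi, nAlpha / (tAlpha * rBetaOut))
    ang0 <- stats::runif(1, -pi, pi)
    dAng <- abs(((theta - ang0 + pi) %% (2 * pi)) - pi)
    repeat {
      inWindow <- !disc & !beta & dAng <= dTheta / 2
      if (sum(inWindow) >= nAlpha || dTheta >= 2 * pi) break
      dTheta <- min(2 * pi, dTheta * 1.5)
    }
    wIdx <- which(inWindow)
    wOrd <- wIdx[order(key[wIdx])]
    alpha[wOrd[seq_len(nAlpha)]] <- TRUE
  }

  # plant dropout regions (beta first, then alpha), keeping regions
  # non-adjacent to each other so each is one detected component
  plant <- function(allowedZone, sizes, allowedBase) {
    out <- list()
    allowedCur <- allowedBase & allowedZone
    for (s in sizes) {
      reg <- growBlob(allowedCur, s)
      if (is.null(reg))
        stop("dropout region does not fit inside the sampled zone",
             call. = FALSE)
      m <- matrix(FALSE, nr, nc); m[reg] <- TRUE
      allowedCur <- allowedCur & !dilateMask(m, 1L)
      out[[length(out) + 1L]] <- reg
    }
    out
  }
  base <- matrix(TRUE, nr, nc)
  betaRegions <- plant(beta, truth$region_sizes_px, base)
  for (reg in betaRegions) base[reg] <- FALSE
  base <- !dilateMask(!base, 1L)
  alphaRegions <- plant(alpha, truth$alpha_region_sizes_px, base)

  # background speckle
  bg <- profile$background
  if (bg$speckle_sd > 0) {
    z <- gaussianBlurMatrix(matrix(stats::rnorm(nr * nc), nr, nc),
                            bg$correlation_px)
    z <- (z - mean(z)) / stats::sd(z)
    g <- bg$mean_grey + bg$speckle_sd * z
  } else {
    g <- matrix(bg$mean_grey, nr, nc)
  }

  dr <- profile$disc_render
  nDisc <- sum(disc)
  if (nDisc)
    g[disc] <- dr$grey_mean + dr$grey_sd * stats::rnorm(nDisc)

  # vessel trees radiating outward from the disc margin
  vesselTruth <- matrix(FALSE, nr, nc)
  vs <- profile$vessels
  if (vs$n_trees > 0) {
    for (tree in seq_len(vs$n_trees)) {
      ang <- stats::runif(1, 0, 2 * pi)
      walkers <- list(list(
        r = centerR + (zcfg$disc_radius_px + 2) * cos(ang),
        c = centerC + (zcfg$disc_radius_px + 2) * sin(ang),
        dir = ang,
        w = stats::runif(1, vs$width_px[1], vs$width_px[2]),
        steps = sample(vs$steps[1]:vs$steps[2], 1)))
      nBranch <- 0L
      while (length(walkers)) {
        wk <- walkers[[1]]; walkers <- walkers[-1]
        offs <- discOffsets(wk$w / 2, nr)
        for (s in seq_len(wk$steps)) {
          wk$dir <- wk$dir + stats::rnorm(1, 0, 0.05)
          wk$r <- wk$r + cos(wk$dir)
          wk$c <- wk$c + sin(wk$dir)
          if (wk$r < 2 || wk$r > nr - 1 || wk$c < 2 || wk$c > nc - 1) break
          rr <- round(wk$r) + offs$dr
          cc <- round(wk$c) + offs$dc
          ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
          vesselTruth[cbind(rr[ok], cc[ok])] <- TRUE
          if (nBranch < 3L && stats::runif(1) < 0.015) {
            nBranch <- nBranch + 1L
            walkers[[length(walkers) + 1L]] <- list(
              r = wk$r, c = wk$c,
              dir = wk$dir + sample(c(-1, 1), 1) * stats::runif(1, 0.3, 0.7),
              w = max(vs$width_px[1], wk$w * 0.8),
              steps = ceiling(wk$steps * 0.6))
          }
        }
      }
    }
    vesselTruth[disc] <- FALSE
    nv <- sum(vesselTruth)
    if (nv) g[vesselTruth] <- stats::runif(nv, vs$grey[1], vs$grey[2])
  }

  # dark dropout regions last, so every planted pixel keeps grey < 50
  mvdMask <- matrix(FALSE, nr, nc)
  gcfg <- profile$mvd$grey
  allRegions <- c(lapply(betaRegions, function(r) list(px = r, zone = "beta")),
                  lapply(alphaRegions, function(r) list(px = r, zone = "alpha")))
  for (reg in allRegions) {
    base_grey <- stats::runif(1, gcfg$min, gcfg$max)
    vals <- round(base_grey + stats::rnorm(length(reg$px), 0, gcfg$pixel_sd))
    g[reg$px] <- pmin(49, pmax(2, vals))
    mvdMask[reg$px] <- TRUE
  }
  vesselTruth <- vesselTruth & !mvdMask

  g <- matrix(as.integer(pmin(255, pmax(0, round(g)))), nr, nc)
  image <- EnFaceImage(g, eyeId = truth$record$eye_id, pixelPitchUm = pitch)
  zones <- ZoneSet(discMask = disc, alphaMask = alpha, betaMask = beta)

  truth$true_regions <- lapply(allRegions, function(reg) {
    list(pixels = cbind(row = (reg$px - 1L) %% nr + 1L,
                        col = (reg$px - 1L) %/% nr + 1L),
         zone = reg$zone, area_px = length(reg$px))
  })
  truth$true_total_mvd_beta_px <- sum(vapply(betaRegions, length, integer(1)))
  truth$true_total_mvd_alpha_px <- sum(vapply(alphaRegions, length, integer(1)))
  truth$true_total_mvd_beta_mm2 <- truth$true_total_mvd_beta_px * apx
  truth$true_total_mvd_alpha_mm2 <- truth$true_total_mvd_alpha_px * apx
  list(image = image, zones = zones, mvdMask = mvdMask,
       vesselTruth = vesselTruth, truth = truth)
}

#' Simulate one eye (truth + rendering)
#'
#' @param profile a \code{\link{generatorProfile}}.
#' @param index eye index within the cohort.
#' @param seed cohort-level integer seed; the per-eye stream is derived from
#'   it and the eye index, so eyes are reproducible individually.
#' @return the \code{\link{renderEye}} result.
#' @export
simulateEye <- function(profile, index = 1L, seed = 1L) {
  eyeSeed <- deriveSeed(seed, profile$seed_offset + index)
  withSeed(eyeSeed, {
    truth <- sampleEyeTruth(profile, index)
    renderEye(truth, profile)
  })
}

#' Generate a synthetic cohort on disk
#'
#' Writes, per eye, the en-face image (\code{<eye>_octa.png}), the three zone
#' masks (\code{<eye>_disc.png}, \code{<eye>_alpha.png}, \code{<eye>_beta.png})
#' and the ground-truth dropout mask (\code{<eye>_mvdtruth.png}); plus a
#' cohort manifest (\code{manifest.csv}, readable by
#' \code{\link{readManifest}}) and a truth file (\code{truth.json}) recording
#' per-eye true totals, region sizes and run metadata.
#'
#' @param profile a \code{\link{generatorProfile}}.
#' @param outDir output directory (created if needed).
#' @param seed integer seed; output is byte-identical across runs for a
#'   fixed (profile, seed).
#' @param nEyes number of eyes, defaulting to the profile's \code{n_eyes}.
#' @return invisibly, the manifest data.frame.
#' @export
generateCohort <- function(profile, outDir, seed = 1L,
                           nEyes = profile$n_eyes) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  records <- list(); truthList <- list()
  for (i in seq_len(nEyes)) {
    eye <- tryCatch(simulateEye(profile, i, seed),
                    error = function(e)
                      stop(sprintf("eye %d: %s", i, conditionMessage(e)),
                           call. = FALSE))
    eid <- eye$truth$record$eye_id
    writeEnFaceImage(eye$image, file.path(outDir, paste0(eid, "_octa.png")))
    writeZoneSet(eye$zones,
                 file.path(outDir, paste0(eid, "_disc.png")),
                 file.path(outDir, paste0(eid, "_alpha.png")),
                 file.path(outDir, paste0(eid, "_beta.png")))
    png::writePNG(eye$mvdMask * 1,
                  file.path(outDir, paste0(eid, "_mvdtruth.png")))
    records[[i]] <- eye$truth$record
    truthList[[i]] <- list(
      eye_id = eid,
      beta_area_mm2 = eye$truth$beta_px * profile$grid$pixel_pitch_um^2 / 1e6,
      alpha_present = eye$truth$alpha_present,
      mvd_present = eye$truth$mvd_present,
      true_total_mvd_beta_px = eye$truth$true_total_mvd_beta_px,
      true_total_mvd_alpha_px = eye$truth$true_total_mvd_alpha_px,
      region_sizes_px = eye$truth$region_sizes_px,
      alpha_region_sizes_px = eye$truth$alpha_region_sizes_px)
  }
  manifest <- if (nEyes > 0) do.call(rbind, records) else
    stats::setNames(data.frame(matrix(ncol = 9, nrow = 0)),
                    c(manifestColumns, "group"))
  writeManifest(manifest, file.path(outDir, "manifest.csv"))
  jsonlite::write_json(
    list(profile = profile$name, seed = seed,
         package_version = as.character(utils::packageVersion("mvdquant")),
         eyes = truthList),
    file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
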