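# Shared fixtures and independent oracles for the test suite.

# Build an image from a grey value (scalar or matrix).
makeImage <- function(grey, nr = 40, nc = 40, pitch = 11.25, eyeId = "t") {
  g <- if (is.matrix(grey)) grey else matrix(as.integer(grey), nr, nc)
  EnFaceImage(g, eyeId = eyeId, pixelPitchUm = pitch)
}

# ZoneSet with a rectangular beta zone (and optional alpha rectangle).
makeZones <- function(nr, nc, beta = NULL, alpha = NULL, disc = NULL) {
  rect <- function(spec) {
    m <- matrix(FALSE, nr, nc)
    if (!is.null(spec)) m[spec[1]:spec[2], spec[3]:spec[4]] <- TRUE
    m
  }
  ZoneSet(discMask = rect(disc), alphaMask = rect(alpha), betaMask = rect(beta))
}

fullBetaZones <- function(nr, nc) {
  ZoneSet(discMask = matrix(FALSE, nr, nc), alphaMask = matrix(FALSE, nr, nc),
          betaMask = matrix(TRUE, nr, nc))
}

# Independent connected-component oracle: plain stack-based flood fill over
# individual pixels, no vectorization shared with the implementation.
floodLabelOracle <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      deltas <- if (connectivity == 4)
        list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
      else
        list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
             c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
      for (d in deltas) {
        r <- p[1] + d[1]; cc <- p[2] + d[2]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- cur
          stack[[length(stack) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# Independent end-to-end dropout oracle: threshold, flood fill, area filter.
# Returns per-region pixel-count table (sorted) and the union mask.
bruteForceDetect <- function(image, zones, vessels = NULL, greyThreshold = 50,
                             minAreaPx = 20, connectivity = 8) {
  grid <- greyValues(image)
  valid <- validMask(image)
  if (!is.null(vessels)) valid <- valid & !vessels@mask
  zone <- zoneMask(zones, "beta") | zoneMask(zones, "alpha")
  dark <- valid & zone & grid < greyThreshold
  lab <- floodLabelOracle(dark, connectivity)
  sizes <- tabulate(lab)
  keepLabs <- which(sizes > minAreaPx)
  union <- matrix(FALSE, nrow(grid), ncol(grid))
  for (l in keepLabs) union[lab == l] <- TRUE
  list(areas = sort(sizes[keepLabs], decreasing = TRUE), union = union)
}

# Tiny profile overrides used to keep test cohorts fast.
vesselFree <- list(vessels = list(n_trees = 0))
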