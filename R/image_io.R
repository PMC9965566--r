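# Reading and writing images, masks, manifests and run configuration.
# All grids are 8-bit PNG at the boundary; other bit depths are rejected
# rather than rescaled, because rescaling would silently shift the
# grey-value-50 detection rule.

# Parse bit depth and colour type from a PNG's IHDR chunk.
pngHeaderInfo <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readBin(con, "raw", 8)
  pngSig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(sig) < 8 || !identical(sig, pngSig))
    stop(sprintf("'%s' is not a PNG file", path), call. = FALSE)
  readBin(con, "raw", 8)            # IHDR length + type
  readBin(con, "raw", 8)            # width + height
  depth <- as.integer(readBin(con, "raw", 1))
  colourType <- as.integer(readBin(con, "raw", 1))
  list(bitDepth = depth, colourType = colourType)
}

#' Read an en-face OCTA image from an 8-bit grayscale PNG
#'
#' Accepts single-channel PNGs, or multi-channel PNGs whose colour channels
#' are identical (a grayscale image saved as RGB). Bit depths other than 8
#' are an error: rescaling other depths would shift the absolute grey-value
#' threshold used for dropout detection.
#'
#' @param path path to the PNG file.
#' @param pixelPitchUm physical pixel side length in micrometres
#'   (default 11.25, the 4.5 mm field at 400 pixels).
#' @param eyeId identifier; defaults to the file name without extension.
#' @return an \code{\linkS4class{EnFaceImage}} with an all-\code{TRUE} valid
#'   mask.
#' @seealso \code{\link{writeEnFaceImage}}
#' @export
readEnFaceImage <- function(path, pixelPitchUm = 11.25,
                            eyeId = sub("\\.png$", "", basename(path))) {
  if (!file.exists(path))
    stop(sprintf("image file '%s' does not exist", path), call. = FALSE)
  info <- pngHeaderInfo(path)
  if (info$bitDepth != 8)
    stop(sprintf("'%s' has bit depth %d; expected 8-bit PNG",
                 path, info$bitDepth), call. = FALSE)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    ncol_chan <- if (nch %in% c(2L, 4L)) nch - 1L else nch
    chans <- lapply(seq_len(ncol_chan), function(k) arr[, , k])
    if (ncol_chan > 1) {
      same <- all(vapply(chans[-1], function(ch)
        identical(ch, chans[[1]]), logical(1)))
      if (!same)
        stop(sprintf("'%s' has unequal colour channels; expected grayscale",
                     path), call. = FALSE)
    }
    if (nch %in% c(2L, 4L) && any(arr[, , nch] != 1))
      stop(sprintf("'%s' has a non-trivial alpha channel", path),
           call. = FALSE)
    arr <- chans[[1]]
  }
  grid <- round(arr * 255)
  EnFaceImage(grid, eyeId = eyeId, pixelPitchUm = pixelPitchUm)
}

#' Write an en-face image as an 8-bit grayscale PNG
#'
#' Round-trips losslessly with \code{\link{readEnFaceImage}}.
#'
#' @param image an \code{\linkS4class{EnFaceImage}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEnFaceImage <- function(image, path) {
  png::writePNG(greyValues(image) / 255, path)
  invisible(path)
}

readBinaryMaskPNG <- function(path, what = "mask") {
  info <- pngHeaderInfo(path)
  if (info$bitDepth != 8)
    stop(sprintf("%s '%s' has bit depth %d; expected 8-bit PNG",
                 what, path, info$bitDepth), call. = FALSE)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  vals <- round(arr * 255)
  if (!all(vals %in% c(0, 255)))
    stop(sprintf("%s '%s' contains values other than {0, 255}", what, path),
         call. = FALSE)
  vals == 255
}

#' Read disc and PPA zone masks
#'
#' Each mask is an 8-bit PNG with value 0 outside and 255 inside; any other
#' value is an error (semi-transparent exports are ambiguous). Masks must
#' match the image dimensions and be pairwise disjoint; overlap is an error,
#' never silently resolved.
#'
#' @param discPath,alphaPath,betaPath paths to the disc, PPA-alpha and
#'   PPA-beta mask PNGs.
#' @param image the \code{\linkS4class{EnFaceImage}} the masks belong to.
#' @return a \code{\linkS4class{ZoneSet}}.
#' @export
readZoneSet <- function(discPath, alphaPath, betaPath, image) {
  d <- readBinaryMaskPNG(discPath, "disc mask")
  a <- readBinaryMaskPNG(alphaPath, "PPA-alpha mask")
  b <- readBinaryMaskPNG(betaPath, "PPA-beta mask")
  for (m in list(d, a, b))
    if (!identical(dim(m), dim(image)))
      stop("zone mask dimensions do not match the image", call. = FALSE)
  ZoneSet(discMask = d, alphaMask = a, betaMask = b)
}

#' Write a ZoneSet as three binary PNG masks
#'
#' @param zones a \code{\linkS4class{ZoneSet}}.
#' @param discPath,alphaPath,betaPath output paths.
#' @return invisibly, the three paths.
#' @export
writeZoneSet <- function(zones, discPath, alphaPath, betaPath) {
  png::writePNG(zoneMask(zones, "disc") * 1, discPath)
  png::writePNG(zoneMask(zones, "alpha") * 1, alphaPath)
  png::writePNG(zoneMask(zones, "beta") * 1, betaPath)
  invisible(c(discPath, alphaPath, betaPath))
}

manifestColumns <- c("eye_id", "subject_id", "age", "sex", "SE", "AL",
                     "quality_score", "artifact_flags")

#' Read a per-eye manifest
#'
#' The manifest is a CSV with one row per eye and columns \code{eye_id,
#' subject_id, age, sex, SE, AL, quality_score, artifact_flags} (flags
#' separated by \code{";"}, empty when none). A \code{group} column is
#' derived from SE with \code{\link{classifyGroup}} when absent. Eyes whose
#' spherical equivalent falls outside the study inclusion interval
#' [-10.0, -0.5] D are retained in the returned table but flagged
#' \code{included = FALSE} with reason \code{"se_out_of_range"}, with a
#' warning.
#'
#' @param path CSV path.
#' @return data.frame of eye records with added columns \code{group},
#'   \code{included} and \code{exclusion_reason}.
#' @export
readManifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(artifact_flags = "character"))
  missing <- setdiff(manifestColumns, names(df))
  if (length(missing))
    stop(sprintf("manifest is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  df$artifact_flags[is.na(df$artifact_flags)] <- ""
  inRange <- df$SE >= -10.0 & df$SE <= -0.5
  df$included <- inRange
  df$exclusion_reason <- ifelse(inRange, "", "se_out_of_range")
  if (any(!inRange))
    warning(sprintf(
      "%d eye(s) have SE outside the inclusion interval [-10.0, -0.5] D and were flagged excluded",
      sum(!inRange)))
  if (is.null(df$group)) {
    df$group <- NA_character_
    df$group[inRange] <- classifyGroup(df$SE[inRange])
  }
  if (any(df$quality_score < 0 | df$quality_score > 10, na.rm = TRUE))
    stop("quality_score must lie in [0, 10]", call. = FALSE)
  df
}

#' Write a per-eye manifest CSV
#'
#' @param records data.frame of eye records.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeManifest <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects the tunable constants of the pipeline. Defaults implement the
#' standard rule set: pixels of 11.25 um pitch, dropout = connected regions
#' of grey value < 50 covering > 20 pixels under 8-connectivity, flow signal
#' = grey >= 50, and large vessels = bright (>= 180) elongated components.
#'
#' @param pixel_pitch_um pixel side length, micrometres.
#' @param grey_threshold dropout grey-value threshold (strict \code{<}).
#' @param min_area_px dropout area threshold in pixels (strict \code{>}).
#' @param connectivity 4 or 8.
#' @param signal_threshold flow-signal threshold (\code{>=}).
#' @param vessel_bright_threshold,vessel_min_width_px,vessel_min_length_px,
#'   vessel_elongation_min large-vessel segmentation parameters, see
#'   \code{\link{segmentLargeVessels}}.
#' @param clip_zones_first logical; restrict to zone pixels before labeling
#'   components (default) rather than after.
#' @param seed integer seed for simulation modes.
#' @return a validated named list of class \code{"mvdRunConfig"}.
#' @export
runConfig <- function(pixel_pitch_um = 11.25,
                      grey_threshold = 50,
                      min_area_px = 20,
                      connectivity = 8,
                      signal_threshold = 50,
                      vessel_bright_threshold = 180,
                      vessel_min_width_px = 4,
                      vessel_min_length_px = 30,
                      vessel_elongation_min = 3,
                      clip_zones_first = TRUE,
                      seed = 1L) {
  cfg <- list(pixel_pitch_um = pixel_pitch_um,
              grey_threshold = grey_threshold,
              min_area_px = min_area_px,
              connectivity = as.integer(connectivity),
              signal_threshold = signal_threshold,
              vessel_bright_threshold = vessel_bright_threshold,
              vessel_min_width_px = vessel_min_width_px,
              vessel_min_length_px = vessel_min_length_px,
              vessel_elongation_min = vessel_elongation_min,
              clip_zones_first = isTRUE(clip_zones_first),
              seed = as.integer(seed))
  if (cfg$pixel_pitch_um <= 0) stop("pixel_pitch_um must be positive")
  assertScalarInRange(cfg$grey_threshold, 0, 255, "grey_threshold")
  assertScalarInRange(cfg$signal_threshold, 0, 255, "signal_threshold")
  assertScalarInRange(cfg$vessel_bright_threshold, 0, 255,
                      "vessel_bright_threshold")
  if (cfg$min_area_px < 0) stop("min_area_px must be >= 0")
  if (!cfg$connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8")
  class(cfg) <- "mvdRunConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' Recognized keys are the arguments of \code{\link{runConfig}}; unknown keys
#' are an error.
#'
#' @param path YAML file path.
#' @return a validated configuration list.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  do.call(runConfig, vals)
}
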