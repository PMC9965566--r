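# Generator profiles: parameter sets describing one study arm of the
# synthetic cohort. The two packaged profiles ("high_myopia",
# "mild_moderate") carry calibration constants, stored in versioned YAML
# under inst/extdata/profiles, chosen so that the full pipeline reproduces
# the study-arm statistics (group means of PPA-beta and dropout area,
# dropout prevalence, and the pooled correlations of dropout area with SE,
# AL and PPA-beta area).

packagedProfiles <- c("high_myopia", "mild_moderate")

#' Load a generator profile
#'
#' @param name one of the packaged profile names (\code{"high_myopia"},
#'   \code{"mild_moderate"}) or a path to a profile YAML.
#' @param overrides named list merged over the loaded profile (nested lists
#'   are merged recursively); useful for e.g. disabling vessels
#'   (\code{list(vessels = list(n_trees = 0))}) or shrinking cohorts in
#'   examples.
#' @return a validated profile (list of class \code{"mvdGeneratorProfile"}).
#' @examples
#' p <- generatorProfile("high_myopia", overrides = list(n_eyes = 3))
#' p$covariates$se$mean
#' @export
generatorProfile <- function(name, overrides = list()) {
  path <- if (name %in% packagedProfiles) {
    system.file("extdata", "profiles", paste0(name, ".yaml"),
                package = "mvdquant", mustWork = TRUE)
  } else name
  if (!file.exists(path))
    stop(sprintf("profile '%s' not found", name), call. = FALSE)
  p <- yaml::read_yaml(path)
  if (length(overrides)) p <- utils::modifyList(p, overrides)
  validateProfile(p)
  # truncated-normal moments of the realized SE distribution, used to
  # standardize SE inside the coupling models
  p$se_trunc <- truncnormMoments(p$covariates$se$mean, p$covariates$se$sd,
                                 p$covariates$se$lower, p$covariates$se$upper)
  p$age_trunc <- truncnormMoments(p$covariates$age$mean, p$covariates$age$sd,
                                  p$covariates$age$lower,
                                  p$covariates$age$upper)
  class(p) <- "mvdGeneratorProfile"
  p
}

validateProfile <- function(p) {
  need <- c("name", "group", "n_eyes", "seed_offset", "grid", "covariates",
            "zones", "mvd", "background", "vessels", "disc_render")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop(sprintf("profile missing section(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  probs <- c(p$mvd$presence_prob, p$zones$ppa_alpha$presence_prob,
             p$mvd$alpha$presence_prob_given_alpha, p$covariates$female_prob)
  if (any(probs < 0 | probs > 1))
    stop("profile probabilities must lie in [0, 1]", call. = FALSE)
  sds <- c(p$covariates$se$sd, p$covariates$al$sd, p$covariates$age$sd,
           p$zones$ppa_beta_area$sdlog, p$mvd$coupling$sigma_log,
           p$background$speckle_sd)
  if (any(sds < 0)) stop("profile SDs must be >= 0", call. = FALSE)
  if (p$mvd$grey$min < 0 || p$mvd$grey$max > 49)
    stop("dropout grey support must lie within [0, 49]", call. = FALSE)
  if (p$background$mean_grey <= 50 + 3 * p$background$speckle_sd)
    stop("background mean grey must exceed 50 + 3 * speckle SD", call. = FALSE)
  if (p$n_eyes < 0) stop("n_eyes must be >= 0", call. = FALSE)
  invisible(TRUE)
}
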