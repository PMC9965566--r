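# Cohort layer: QC filtering, SE-based grouping, group comparisons,
# prevalence, correlations and regression of dropout area on covariates.
# Standard tests are delegated to base R (t.test, cor.test, lm).

#' Classify an eye by spherical equivalent
#'
#' Eyes with SE <= -6.0 D form the high myopia group; eyes with
#' -6.0 < SE <= -0.5 D the mild-to-moderate group. The shared endpoint
#' -6.0 D is assigned to the high group (high myopia is conventionally
#' SE <= -6 D). SE outside the inclusion interval [-10.0, -0.5] is an error.
#'
#' @param SE numeric vector of spherical equivalents in diopters (signed).
#' @return character vector, \code{"high"} or \code{"mild_moderate"}.
#' @export
classifyGroup <- function(SE) {
  if (any(is.na(SE)) || any(SE < -10.0) || any(SE > -0.5))
    stop("SE outside the inclusion interval [-10.0, -0.5] D", call. = FALSE)
  ifelse(SE <= -6.0, "high", "mild_moderate")
}

#' Quality-control filter
#'
#' Retains eyes with scan quality score >= \code{minQuality} (default 6/10)
#' and no artifact flags (double-vessel pattern, motion, segmentation errors
#' over more than three lines). Records previously flagged excluded (e.g. SE
#' out of range at manifest load) are also dropped. Every exclusion carries
#' its reason.
#'
#' @param records data.frame of eye records (see \code{\link{readManifest}}).
#' @param minQuality minimum acceptable quality score, default 6.
#' @return list with \code{retained} and \code{excluded} data.frames; the
#'   latter has an \code{exclusion_reason} column.
#' @export
qcFilter <- function(records, minQuality = 6) {
  reason <- rep("", nrow(records))
  if (!is.null(records$exclusion_reason))
    reason <- records$exclusion_reason
  lowq <- records$quality_score < minQuality
  reason[lowq & reason == ""] <- "low_quality"
  flagged <- !is.na(records$artifact_flags) & records$artifact_flags != ""
  reason[flagged & reason == ""] <-
    records$artifact_flags[flagged & reason == ""]
  out <- records
  out$exclusion_reason <- reason
  list(retained = out[reason == "", , drop = FALSE],
       excluded = out[reason != "", , drop = FALSE])
}

#' Compare a variable between two groups
#'
#' Two-sided independent two-sample t-test; equal-variance (Student) by
#' default with a Welch option, per the study's analysis plan.
#'
#' @param values numeric vector, one value per eye.
#' @param groups character/factor vector of group labels (exactly two
#'   levels), parallel to \code{values}.
#' @param varEqual use the pooled-variance Student test (default) or Welch.
#' @return list with \code{t}, \code{df}, \code{p}, and per-group \code{n},
#'   \code{mean}, \code{sd}.
#' @export
compareGroups <- function(values, groups, varEqual = TRUE) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2)
    stop("exactly two groups are required", call. = FALSE)
  split_ <- split(values, factor(groups, levels = lev))
  if (any(vapply(split_, length, integer(1)) < 2))
    stop("each group needs at least 2 eyes", call. = FALSE)
  tt <- stats::t.test(split_[[1]], split_[[2]], var.equal = varEqual)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       n = vapply(split_, length, integer(1)),
       mean = vapply(split_, mean, numeric(1)),
       sd = vapply(split_, stats::sd, numeric(1)))
}

#' Correlation between two variables
#'
#' Spearman (default, as in the study's analysis plan) or Pearson. Spearman
#' uses average ranks for ties. Constant input is an undefined-coefficient
#' error, never a silent 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method \code{"spearman"} or \code{"pearson"}.
#' @return list with \code{estimate} and \code{p}.
#' @export
correlateVars <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = NULL))
  list(estimate = unname(ct$estimate), p = ct$p.value)
}

#' Regression of dropout area on covariates
#'
#' Two views, mirroring how such analyses are reported: (a) per-predictor
#' simple linear fits, each summarized by the signed correlation coefficient
#' r (the Pearson correlation, identical to the standardized simple-fit
#' slope) and its p-value; (b) a joint ordinary-least-squares fit of the
#' response on all predictors with the full coefficient table. A
#' near-collinear design (condition number of the scaled model matrix above
#' \code{kappaBound}) attaches a warning.
#'
#' @param data data.frame holding the response and predictors, at least 10
#'   complete rows.
#' @param response response column name (default total dropout area in the
#'   PPA-beta zone).
#' @param predictors predictor column names.
#' @param kappaBound condition-number bound, default \code{1e8}.
#' @return list with \code{simple} (data.frame predictor, r, p), \code{joint}
#'   (OLS coefficient table as data.frame), \code{kappa}, and the fitted
#'   \code{model}.
#' @export
regressMvd <- function(data, response = "mvd_total_area_beta_mm2",
                       predictors = c("age", "SE", "AL",
                                      "ppa_beta_area_mm2"),
                       kappaBound = 1e8) {
  cols <- c(response, predictors)
  missing <- setdiff(cols, names(data))
  if (length(missing))
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  data <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  if (nrow(data) < 10)
    stop("at least 10 complete eyes are required", call. = FALSE)
  y <- data[[response]]
  simple <- do.call(rbind, lapply(predictors, function(pr) {
    ct <- correlateVars(data[[pr]], y, method = "pearson")
    data.frame(predictor = pr, r = ct$estimate, p = ct$p,
               stringsAsFactors = FALSE)
  }))
  fml <- stats::as.formula(paste(response, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = data)
  X <- scale(stats::model.matrix(fit)[, -1, drop = FALSE])
  kp <- kappa(X, exact = TRUE)
  if (kp > kappaBound)
    warning(sprintf("near-collinear design: condition number %.3g", kp))
  co <- summary(fit)$coefficients
  joint <- data.frame(term = rownames(co), estimate = co[, 1],
                      std_error = co[, 2], t = co[, 3], p = co[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  list(simple = simple, joint = joint, kappa = kp, model = fit)
}

#' Prevalence of detected dropout
#'
#' @param metrics data.frame of per-eye metrics with logical column
#'   \code{mvd_present}.
#' @return fraction of eyes with at least one detected region.
#' @export
mvdPrevalence <- function(metrics) {
  if (!nrow(metrics)) stop("empty cohort", call. = FALSE)
  mean(metrics$mvd_present)
}

#' Summarize a cohort
#'
#' Joins per-eye metrics with covariate records and computes the cohort
#' statistics: per-group descriptive statistics and Student t-tests for the
#' clinical and image variables, dropout prevalence (pooled and by group),
#' Spearman correlations of PPA-beta dropout area with age, SE, AL and
#' PPA-beta area, and the simple/joint linear fits of
#' \code{\link{regressMvd}}.
#'
#' @param metrics per-eye metrics (\code{\link{summarizeEye}} rows).
#' @param records eye records with \code{eye_id}, covariates and
#'   \code{group}.
#' @return a \code{\linkS4class{CohortSummary}}.
#' @export
summarizeCohort <- function(metrics, records) {
  df <- merge(metrics, records, by = "eye_id")
  if (!nrow(df)) stop("metrics and records share no eyes", call. = FALSE)
  if (is.null(df$group)) df$group <- classifyGroup(df$SE)
  vars <- c("age", "SE", "AL", "ppa_beta_area_mm2", "ppa_alpha_area_mm2",
            "mvd_total_area_beta_mm2", "mvd_total_area_alpha_mm2",
            "density_beta", "density_alpha")
  vars <- intersect(vars, names(df))
  gs <- list(); ts <- list()
  for (v in vars) {
    cg <- tryCatch(compareGroups(df[[v]], df$group), error = function(e) NULL)
    if (is.null(cg)) {   # degenerate (constant) variable: descriptives only
      sp <- split(df[[v]], df$group)
      gs[[v]] <- data.frame(variable = v, group = names(sp),
                            n = vapply(sp, length, integer(1)),
                            mean = vapply(sp, mean, numeric(1)),
                            sd = vapply(sp, stats::sd, numeric(1)),
                            row.names = NULL, stringsAsFactors = FALSE)
      ts[[v]] <- data.frame(variable = v, t = NA_real_, df = NA_real_,
                            p = NA_real_, stringsAsFactors = FALSE)
      next
    }
    gs[[v]] <- data.frame(variable = v, group = names(cg$n), n = cg$n,
                          mean = cg$mean, sd = cg$sd,
                          row.names = NULL, stringsAsFactors = FALSE)
    ts[[v]] <- data.frame(variable = v, t = cg$t, df = cg$df, p = cg$p,
                          stringsAsFactors = FALSE)
  }
  preds <- c("age", "SE", "AL", "ppa_beta_area_mm2")
  cors <- do.call(rbind, lapply(preds, function(pr) {
    ct <- correlateVars(df[[pr]], df$mvd_total_area_beta_mm2, "spearman")
    data.frame(predictor = pr, rho = ct$estimate, p = ct$p,
               stringsAsFactors = FALSE)
  }))
  reg <- regressMvd(df)
  prevBy <- vapply(split(df$mvd_present, df$group), mean, numeric(1))
  new("CohortSummary",
      groupStats = do.call(rbind, c(gs, list(make.row.names = FALSE))),
      tests = do.call(rbind, c(ts, list(make.row.names = FALSE))),
      correlations = cors,
      simpleFits = reg$simple,
      jointModel = reg$joint,
      prevalence = mvdPrevalence(df),
      prevalenceByGroup = prevBy,
      nByGroup = vapply(split(df$eye_id, df$group), length, integer(1)))
}
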