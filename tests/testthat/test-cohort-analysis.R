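test_that("grouping by spherical equivalent uses the -6 D boundary", {
  expect_equal(classifyGroup(-7.14), "high")
  expect_equal(classifyGroup(-2.51), "mild_moderate")
  expect_equal(classifyGroup(-6.0), "high")
  expect_equal(classifyGroup(c(-9.9, -0.5)), c("high", "mild_moderate"))
  expect_error(classifyGroup(0.5), "inclusion interval")
  expect_error(classifyGroup(-11), "inclusion interval")
})

test_that("quality filtering keeps score >= 6 with no artifact flags", {
  rec <- data.frame(
    eye_id = paste0("e", 1:5),
    quality_score = c(6, 9, 5, 10, 8),
    artifact_flags = c("", "motion", "", "", "double_vessel;motion"),
    stringsAsFactors = FALSE)
  out <- qcFilter(rec)
  expect_equal(out$retained$eye_id, c("e1", "e4"))
  expect_equal(out$excluded$exclusion_reason,
               c("motion", "low_quality", "double_vessel;motion"))

  # a 220-eye cohort with 15 artifact-flagged eyes retains 205
  set.seed(81)
  big <- data.frame(eye_id = paste0("e", 1:220), quality_score = 10,
                    artifact_flags = "", stringsAsFactors = FALSE)
  big$artifact_flags[sample(220, 15)] <- "motion"
  out <- qcFilter(big)
  expect_equal(nrow(out$retained), 205)
  expect_equal(nrow(out$excluded), 15)
})

test_that("group comparison reproduces hand-computed t statistics", {
  cg <- compareGroups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(cg$t, 0)
  expect_equal(cg$p, 1)

  # {1,2,3} vs {11,12,13}: pooled sd 1, t = -10 / sqrt(2/3)
  cg2 <- compareGroups(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  expect_equal(cg2$t, -10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_lt(cg2$p, 0.01)
  expect_equal(unname(cg2$mean), c(2, 12))

  # label swap flips the sign only
  cg3 <- compareGroups(c(1, 2, 3, 11, 12, 13), rep(c("b", "a"), each = 3))
  expect_equal(cg3$t, -cg2$t)
  expect_equal(cg3$p, cg2$p)

  expect_error(compareGroups(1:3, c("a", "a", "b")), "at least 2")
})

test_that("correlation handles the worked rank example and degenerate input", {
  x <- 1:5
  expect_equal(correlateVars(x, x, "spearman")$estimate, 1)
  expect_equal(correlateVars(x, x, "pearson")$estimate, 1)
  expect_equal(correlateVars(x, -x, "spearman")$estimate, -1)

  # rank-difference arithmetic: d = (-2, 1, 1, 0, 0), sum d^2 = 6,
  # rho = 1 - 6*6/(5*24) = 0.7
  y <- c(3, 1, 2, 4, 5)
  expect_equal(correlateVars(x, y, "spearman")$estimate, 0.7)

  expect_error(correlateVars(rep(1, 5), 1:5), "constant")
  expect_error(correlateVars(1:2, 1:2), "length >= 3")
})

test_that("Spearman correlation is invariant under monotone transforms", {
  set.seed(91)
  for (rep in 1:10) {
    x <- rnorm(40)
    y <- x + rnorm(40)
    base <- correlateVars(x, y, "spearman")$estimate
    expect_equal(correlateVars(exp(x), y, "spearman")$estimate, base)
    expect_equal(correlateVars(x, y^3 + 5, "spearman")$estimate, base)
    expect_equal(correlateVars(qlogis(plogis(x)), 2 * y, "spearman")$estimate,
                 base, tolerance = 1e-8)
  }
})

test_that("regression reports per-predictor r and a joint OLS fit", {
  set.seed(101)
  n <- 60
  df <- data.frame(age = runif(n, 18, 40), SE = runif(n, -10, -0.5),
                   AL = rnorm(n, 25, 1))
  df$ppa_beta_area_mm2 <- runif(n, 0.2, 2)
  df$mvd_total_area_beta_mm2 <- 2 + 3 * df$AL
  out <- suppressWarnings(regressMvd(df))  # exact fit: lm warns
  expect_equal(out$simple$r[out$simple$predictor == "AL"], 1)
  co <- out$joint
  expect_equal(co$estimate[co$term == "AL"], 3, tolerance = 1e-8)
  others <- co$estimate[!co$term %in% c("(Intercept)", "AL")]
  expect_true(all(abs(others) < 1e-8))

  # permuted response: no predictor should correlate strongly
  set.seed(102)
  rs <- replicate(100, {
    df$mvd_total_area_beta_mm2 <- sample(2 + 3 * df$AL)
    regressMvd(df)$simple$r[4]
  })
  expect_lt(max(abs(rs)), 0.5)
  expect_gt(mean(abs(rs) < 2 / sqrt(n)), 0.8)

  expect_error(regressMvd(df[1:5, ]), "at least 10")
})

test_that("prevalence is the fraction of eyes with detected dropout", {
  m <- data.frame(mvd_present = rep(TRUE, 10))
  expect_equal(mvdPrevalence(m), 1)
  m$mvd_present <- FALSE
  expect_equal(mvdPrevalence(m), 0)
  m2 <- data.frame(mvd_present = c(rep(TRUE, 195), rep(FALSE, 10)))
  expect_equal(mvdPrevalence(m2), 0.951, tolerance = 5e-4)
  expect_error(mvdPrevalence(m2[0, , drop = FALSE]), "empty")
})

test_that("cohort summary assembles group statistics and correlations", {
  set.seed(111)
  n <- 40
  rec <- data.frame(
    eye_id = paste0("e", 1:n),
    age = runif(n, 18, 40), sex = "F",
    SE = c(runif(n / 2, -10, -6), runif(n / 2, -5.9, -0.5)),
    AL = rnorm(n, 25, 1), quality_score = 10, artifact_flags = "",
    stringsAsFactors = FALSE)
  rec$group <- classifyGroup(rec$SE)
  met <- data.frame(
    eye_id = rec$eye_id,
    ppa_beta_area_mm2 = ifelse(rec$group == "high", 1.2, 0.6) + runif(n, 0, 0.1),
    ppa_alpha_area_mm2 = 0.3,
    mvd_total_area_beta_mm2 = NA,
    mvd_total_area_alpha_mm2 = 0,
    mvd_present = TRUE, mvd_present_alpha = FALSE,
    density_beta = 100, density_alpha = 50,
    stringsAsFactors = FALSE)
  met$mvd_total_area_beta_mm2 <- 0.2 * met$ppa_beta_area_mm2 + rnorm(n, 0, 0.01)
  cs <- summarizeCohort(met, rec)
  expect_s4_class(cs, "CohortSummary")
  expect_equal(sum(cs@nByGroup), n)
  expect_equal(cs@prevalence, 1)
  expect_gt(cs@simpleFits$r[cs@simpleFits$predictor == "ppa_beta_area_mm2"],
            0.9)
  expect_true(all(c("age", "SE", "AL") %in% cs@correlations$predictor))
  bt <- cs@tests[cs@tests$variable == "ppa_beta_area_mm2", ]
  expect_lt(bt$p, 0.001)
})
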