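mkMaps <- function(M, g) apply(M, 2, function(v) array(v, g@dim),
                               simplify = FALSE)

test_that("voxelwise Welch tests match stats::t.test voxel by voxel", {
  set.seed(41)
  g <- unitGrid(c(3L, 3L, 2L))
  A <- matrix(rnorm(18 * 6, 1), 18)
  B <- matrix(rnorm(18 * 5, 0.5), 18)
  mask <- array(c(rep(TRUE, 15), rep(FALSE, 3)), g@dim)
  res <- voxelwiseTTest(mkMaps(A, g), mkMaps(B, g), mask)
  for (v in which(mask)) {
    tt <- t.test(A[v, ], B[v, ])
    expect_equal(res$stat[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[v], tt$p.value, tolerance = 1e-10)
    expect_equal(res$df[v], unname(tt$parameter), tolerance = 1e-10)
  }
  expect_true(all(is.na(res$stat[!mask])))
  pooled <- voxelwiseTTest(mkMaps(A, g), mkMaps(B, g), mask, varEqual = TRUE)
  v <- which(mask)[1]
  tt <- t.test(A[v, ], B[v, ], var.equal = TRUE)
  expect_equal(pooled$stat[v], unname(tt$statistic), tolerance = 1e-10)
})

test_that("ANCOVA without covariates reproduces the pooled t-test", {
  set.seed(42)
  for (i in 1:10) {
    y <- rnorm(20)
    grp <- factor(rep(c("a", "b"), 10))
    row <- ancova(y, grp)
    tt <- t.test(y[grp == "b"], y[grp == "a"], var.equal = TRUE)
    expect_equal(row$stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p, tt$p.value, tolerance = 1e-10)
    expect_equal(row$estimate, unname(diff(rev(tt$estimate))),
                 tolerance = 1e-10)
  }
})

test_that("ANCOVA adjusts for covariates and reports the group coefficient", {
  set.seed(43)
  n <- 60
  age <- rnorm(n, 50, 10)
  grp <- factor(rep(c("ctrl", "pat"), each = n / 2))
  y <- 0.05 * age + 0.8 * (grp == "pat") + rnorm(n, 0, 0.5)
  row <- ancova(y, grp, data.frame(age = age))
  fit <- lm(y ~ grp + age)
  expect_equal(row$estimate, unname(coef(fit)["grppat"]), tolerance = 1e-10)
  expect_equal(row$p, summary(fit)$coefficients["grppat", 4],
               tolerance = 1e-10)
  expect_lt(row$p, 0.001)
})

test_that("ANCOVA rejects degenerate designs with clear messages", {
  y <- rnorm(10)
  expect_error(ancova(y, rep("a", 10)), "constant")
  expect_error(ancova(y, rep(c("a", "b", "c"), length.out = 10)), "2 levels")
  expect_error(ancova(c(y[-1], NA), rep(c("a", "b"), 5)), "missing")
  x <- rnorm(10)
  expect_error(ancova(y, rep(c("a", "b"), 5),
                      data.frame(x1 = x, x2 = 2 * x)), "collinear")
})

test_that("paired tests match t.test on the differences", {
  set.seed(44)
  x <- rnorm(12, 1); y <- rnorm(12)
  row <- pairedTTest(x, y)
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(row$stat, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(row$p, tt$p.value, tolerance = 1e-10)
})

test_that("degenerate paired differences are handled explicitly", {
  z <- rep(2, 5)
  same <- pairedTTest(z, z)
  expect_equal(same$stat, 0)
  expect_equal(same$p, 1)
  shifted <- pairedTTest(z + 1, z)
  expect_true(is.na(shifted$p))
  expect_match(shifted$note, "degenerate")
  expect_error(pairedTTest(1:2, 2:3), "3 complete pairs")
})

test_that("EDSS models recover a planted disability association", {
  set.seed(45)
  n <- 80
  subj <- data.frame(edss = sample(seq(0, 8, 0.5), n, TRUE),
                     age = rnorm(n, 45, 10),
                     sex = sample(c("F", "M"), n, TRUE),
                     ms_type = sample(c("RR", "SP"), n, TRUE))
  y <- 0.3 * subj$edss + 0.02 * subj$age + rnorm(n, 0, 0.4)
  row <- edssAssociation(y, subj)
  expect_equal(row$term, "edss")
  expect_equal(row$estimate, 0.3, tolerance = 0.1)
  expect_lt(row$p, 1e-6)
  # null association
  row0 <- edssAssociation(rnorm(n), subj)
  expect_gt(row0$p, 1e-4)
})

test_that("EDSS models drop constant factors and demand enough subjects", {
  set.seed(46)
  subj <- data.frame(edss = c(1, 2, 3, 4, 5, 6), age = rnorm(6),
                     sex = rep("F", 6), ms_type = rep("RR", 6))
  row <- edssAssociation(rnorm(6), subj)
  expect_true(is.finite(row$p))
  expect_error(edssAssociation(rnorm(2), subj[1:2, ]), "too few")
})

test_that("Benjamini-Hochberg adjustment matches the textbook example", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Benjamini-Hochberg adjustment matches brute force", {
  set.seed(47)
  for (i in 1:25) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    expect_equal(bhAdjust(p), oracleBH(p), tolerance = 1e-12)
  }
})

test_that("the analysis battery annotates unfittable models instead of failing", {
  subj <- data.frame(
    id = sprintf("S%02d", 1:6),
    group = c("HC", "HC", "MS", "MS", "MS", "MS"),
    prl_positive = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    age = c(50, 52, 40, 41, 55, 54), sex = c("F", "M", "F", "F", "M", "F"),
    edss = c(NA, NA, 2, 3, 4, 2.5), ms_type = c(NA, NA, "RR", "RR", "SP", "RR"),
    stringsAsFactors = FALSE)
  strata <- expand.grid(subject_id = subj$id[3:6],
                        mask_type = c("all", "prl", "non_prl"),
                        stratum = c("none", "low", "mid", "high"),
                        stringsAsFactors = FALSE)
  set.seed(48)
  strata$mean_z <- rnorm(nrow(strata))
  strata$n_voxels <- 10L
  global <- data.frame(subject_id = subj$id, mean_dvr = rnorm(6, 1.2, 0.05))
  res <- runGroupAnalysis(strata, subj, globalSummaries = global)
  expect_s3_class(res, "data.frame")
  expect_true(all(c("analysis", "stratum", "p", "p_adj", "family",
                    "rejected", "note") %in% names(res)))
  # with 2 subjects per PRL group and 4 covariates, models must be skipped
  skipped <- res[res$analysis == "prl_status_ancova", ]
  expect_true(all(grepl("skipped", skipped$note)))
  expect_true(all(is.na(skipped$p)))
  # annotated rows are never counted as rejections
  expect_false(any(res$rejected[is.na(res$p_adj)]))
})

test_that("adjustment families are corrected separately", {
  subj <- data.frame(
    id = sprintf("S%02d", 1:14), group = rep("MS", 14),
    prl_positive = rep(c(TRUE, FALSE), 7),
    age = rnorm(14, 45, 8), sex = rep(c("F", "M"), 7),
    edss = rep(2, 14), ms_type = rep("RR", 14), stringsAsFactors = FALSE)
  strata <- expand.grid(subject_id = subj$id,
                        mask_type = c("all", "prl", "non_prl"),
                        stratum = c("none", "low", "mid", "high"),
                        stringsAsFactors = FALSE)
  set.seed(49)
  strata$mean_z <- rnorm(nrow(strata))
  strata$n_voxels <- 10L
  res <- runGroupAnalysis(strata, subj)
  for (fam in unique(res$family)) {
    sel <- res$family == fam & !is.na(res$p)
    if (!any(sel)) next
    expect_equal(res$p_adj[sel], bhAdjust(res$p[sel]), tolerance = 1e-12)
  }
})
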