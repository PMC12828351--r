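# one tidy result row; p_adj is filled in per correction family later
statRow <- function(analysis, mask_type, stratum, term, estimate = NA_real_,
                    se = NA_real_, stat = NA_real_, p = NA_real_,
                    n = NA_integer_, family = NA_character_, note = "") {
  data.frame(analysis = analysis, mask_type = mask_type, stratum = stratum,
             term = term, estimate = estimate, se = se, stat = stat, p = p,
             p_adj = NA_real_, n = as.integer(n), family = family,
             note = note, stringsAsFactors = FALSE)
}

#' Voxelwise two-sample t-test between groups of maps
#'
#' Welch's t by default (pooled-variance optional) at every in-mask voxel.
#' Positive statistics indicate higher values in group A, so calling with the
#' patient maps first matches the convention that positive values mean higher
#' DVR in patients. Voxels with fewer than 2 defined values in either group,
#' or zero variance in both, are undefined.
#'
#' @param groupA,groupB lists of numeric arrays (or \linkS4class{DVRMap}s).
#' @param mask logical array of voxels to test.
#' @param varEqual pooled-variance (classical) t instead of Welch.
#' @return list of arrays: \code{stat}, \code{p}, \code{df}.
#' @export
voxelwiseTTest <- function(groupA, groupB, mask, varEqual = FALSE) {
  toMat <- function(g) vapply(g, function(x) {
    v <- if (is(x, "DVRMap")) x@values else x
    as.numeric(v)[as.logical(mask)]
  }, numeric(sum(mask)))
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("need at least 2 subjects per group", call. = FALSE)
  A <- toMat(groupA); B <- toMat(groupB)
  nA <- rowSums(!is.na(A)); nB <- rowSums(!is.na(B))
  mA <- rowMeans(A, na.rm = TRUE); mB <- rowMeans(B, na.rm = TRUE)
  vA <- apply(A, 1, var, na.rm = TRUE); vB <- apply(B, 1, var, na.rm = TRUE)
  ok <- nA >= 2 & nB >= 2 & (vA + vB) > 0
  if (varEqual) {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- nA + nB - 2
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  tt <- (mA - mB) / se
  tt[!ok] <- NA_real_
  pp <- 2 * pt(-abs(tt), df)
  dims <- dim(if (is(groupA[[1]], "DVRMap")) groupA[[1]]@values else groupA[[1]])
  put <- function(v) { a <- array(NA_real_, dims); a[as.logical(mask)] <- v; a }
  list(stat = put(tt), p = put(pp), df = put(ifelse(ok, df, NA_real_)))
}

#' Group comparison adjusted for covariates (ANCOVA)
#'
#' Ordinary least squares of the outcome on a two-level group factor plus
#' covariates (factors dummy-coded against their first level); returns the
#' test of the group coefficient, whose sign is second level minus first.
#' With no covariates this reproduces the pooled-variance two-sample t-test
#' exactly.
#'
#' @param outcome numeric, one value per subject, no missing values.
#' @param group factor (or coercible) with exactly 2 observed levels.
#' @param covariates optional data.frame of covariate columns.
#' @return a one-row data.frame (term, estimate, se, stat, p, n).
#' @export
ancova <- function(outcome, group, covariates = NULL) {
  if (anyNA(outcome)) stop("missing outcome values", call. = FALSE)
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L)
    stop("group is constant: no contrast to test", call. = FALSE)
  if (nlevels(group) > 2L) stop("group must have 2 levels", call. = FALSE)
  if (min(table(group)) < 2L)
    stop("need at least 2 subjects per group level", call. = FALSE)
  df <- data.frame(.outcome = outcome, .group = group)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    if (anyNA(covariates)) stop("missing covariate values", call. = FALSE)
    covariates[] <- lapply(covariates, function(x)
      if (is.character(x) || is.logical(x)) droplevels(as.factor(x)) else x)
    keep <- vapply(covariates, function(x)
      !is.factor(x) || nlevels(x) >= 2L, logical(1))
    df <- cbind(df, covariates[, keep, drop = FALSE])
  }
  fit <- lm(.outcome ~ ., data = df)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  rn <- paste0(".group", levels(group)[2])
  statRow("ancova", NA_character_, NA_character_,
          term = paste0("group:", levels(group)[2], "-", levels(group)[1]),
          estimate = sm[rn, 1], se = sm[rn, 2], stat = sm[rn, 3],
          p = sm[rn, 4], n = nrow(df))
}

#' Paired t-test on per-subject paired values
#'
#' One-sample t on the differences \code{x - y}. If every difference is zero
#' the result is stat 0, p 1; a non-zero constant difference (zero variance)
#' is flagged as degenerate rather than reported as infinitely significant.
#'
#' @param x,y numeric vectors paired by subject; NA pairs are dropped.
#' @return a one-row data.frame (term, estimate, se, stat, p, n, note).
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  if (length(d) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (all(d == 0))
    return(statRow("paired_t", NA, NA, "mean_difference", estimate = 0,
                   se = 0, stat = 0, p = 1, n = length(d)))
  if (sd(d) == 0)
    return(statRow("paired_t", NA, NA, "mean_difference", estimate = mean(d),
                   se = 0, n = length(d),
                   note = "degenerate: zero variance of differences"))
  tt <- t.test(d)
  statRow("paired_t", NA, NA, "mean_difference",
          estimate = unname(tt$estimate), se = sd(d) / sqrt(length(d)),
          stat = unname(tt$statistic), p = tt$p.value, n = length(d))
}

#' Association between disability (EDSS) and an outcome
#'
#' OLS of the outcome on EDSS plus covariates (age, sex, MS subtype by
#' default; factor covariates that are constant in the supplied subjects are
#' dropped). Returns the EDSS coefficient's test. EDSS is treated as numeric.
#'
#' @param outcome numeric, one value per row of \code{subjects}.
#' @param subjects data.frame with columns \code{edss}, \code{age},
#'   \code{sex}, \code{ms_type}.
#' @param covariates character, covariate column names.
#' @return a one-row data.frame (term, estimate, se, stat, p, n).
#' @export
edssAssociation <- function(outcome, subjects,
                            covariates = c("age", "sex", "ms_type")) {
  ok <- !is.na(outcome) & !is.na(subjects$edss)
  outcome <- outcome[ok]
  subjects <- subjects[ok, , drop = FALSE]
  if (length(outcome) < 3L)
    stop("too few subjects for the EDSS model", call. = FALSE)
  df <- data.frame(.outcome = outcome, edss = as.numeric(subjects$edss))
  for (cv in covariates) {
    x <- subjects[[cv]]
    if (is.character(x) || is.logical(x)) x <- droplevels(as.factor(x))
    if (is.factor(x) && nlevels(x) < 2L) next
    df[[cv]] <- x
  }
  if (nrow(df) < ncol(model.matrix(.outcome ~ ., df)) + 1L)
    stop("too few subjects for the EDSS model", call. = FALSE)
  fit <- lm(.outcome ~ ., data = df)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  statRow("edss_lm", NA, NA, "edss", estimate = sm["edss", 1],
          se = sm["edss", 2], stat = sm["edss", 3], p = sm["edss", 4],
          n = nrow(df))
}

#' Benjamini-Hochberg adjustment of a p-value family
#'
#' Step-up false-discovery-rate adjustment, clipped at 1, returned in the
#' input order (stable under permutation of the inputs).
#'
#' @param p p-values in [0, 1]; NAs pass through.
#' @param family optional family label (unused, for audit trails).
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p, family = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}
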