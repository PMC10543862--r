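#' Paired per-electrode differences between two methods
#'
#' Joins two measurement tables on `(array_id, electrode)` and returns one
#' row per pair with the two values, their mean and the difference A - B,
#' pooled across arrays. Both tables must cover exactly the same
#' (array, electrode) pairs.
#'
#' @param setA,setB Measurement tables (schema of [read_measurements()]),
#'   one method each.
#' @param parameter `"emd"` or `"adoi"`.
#' @return Data frame with columns `array_id`, `electrode`, `a`, `b`,
#'   `mean`, `diff`.
#' @export
paired_differences <- function(setA, setB, parameter = c("emd", "adoi")) {
  parameter <- match.arg(parameter)
  col <- if (parameter == "emd") "emd_mm" else "adoi_deg"
  a <- setA[, c("array_id", "electrode", col)]
  b <- setB[, c("array_id", "electrode", col)]
  names(a)[3] <- "a"
  names(b)[3] <- "b"
  keyA <- paste(a$array_id, a$electrode)
  keyB <- paste(b$array_id, b$electrode)
  if (anyDuplicated(keyA) || anyDuplicated(keyB))
    cochloc_error("duplicate (array, electrode) rows within one method",
                  "cochloc_pairing_error")
  offenders <- c(setdiff(keyA, keyB), setdiff(keyB, keyA))
  if (length(offenders))
    cochloc_error(paste("unmatched (array, electrode) pairs:",
                        paste(utils::head(offenders, 10), collapse = "; ")),
                  "cochloc_pairing_error")
  m <- merge(a, b, by = c("array_id", "electrode"))
  m <- m[order(m$array_id, m$electrode), ]
  m$mean <- (m$a + m$b) / 2
  m$diff <- m$a - m$b
  rownames(m) <- NULL
  m
}

#' Bland-Altman bias and limits of agreement
#'
#' Bias is the mean of the paired differences; the limits of agreement are
#' `bias +/- 1.96 * SD` with the sample (n-1) standard deviation.
#'
#' @param differences Numeric vector of paired differences, `n >= 2`.
#' @return List with `bias`, `sd`, `loa_low`, `loa_high`, `n`.
#' @export
#' @examples
#' bland_altman(c(-1, 1))  # bias 0, limits +/- 1.96 * sqrt(2)
bland_altman <- function(differences) {
  differences <- as.numeric(differences)
  if (length(differences) < 2 || any(!is.finite(differences)))
    cochloc_error("need >= 2 finite differences", "cochloc_insufficient_data")
  bias <- mean(differences)
  s <- stats::sd(differences)
  list(bias = bias, sd = s, loa_low = bias - 1.96 * s,
       loa_high = bias + 1.96 * s, n = length(differences))
}

#' Percentage error of the limits of agreement
#'
#' The width of the limits of agreement (upper minus lower) divided by the
#' mean of the measurements obtained with the established (reference)
#' method, in percent. It expresses the agreement band relative to the
#' magnitude of what is being measured; scale-invariant.
#'
#' @param loa_low,loa_high Limits of agreement, reference-method units.
#' @param reference_mean Grand mean of the reference method's measurements,
#'   must be > 0.
#' @return Percentage error (percent).
#' @export
percentage_error <- function(loa_low, loa_high, reference_mean) {
  if (!is.finite(reference_mean) || reference_mean <= 0)
    cochloc_error("reference mean must be finite and > 0",
                  "cochloc_invalid_reference")
  100 * (loa_high - loa_low) / reference_mean
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Product-moment correlation of two paired sequences with the confidence
#' interval obtained from the Fisher z-transform (via [stats::cor.test()]).
#'
#' @param x,y Paired numeric vectors, `n >= 4`, neither constant.
#' @param confidence Confidence level, default 0.95.
#' @return List with `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
pearson_with_ci <- function(x, y, confidence = 0.95) {
  if (length(x) != length(y) || length(x) < 4)
    cochloc_error("need paired vectors of length >= 4",
                  "cochloc_insufficient_data")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    cochloc_error("constant input: correlation undefined",
                  "cochloc_undefined_correlation")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = confidence)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1],
       ci_high = ct$conf.int[2], p = ct$p.value, n = length(x))
}

# Two-way ANOVA mean squares of a complete subjects x raters matrix,
# computed from sums of squares directly (no model fit).
two_way_mean_squares <- function(ratings) {
  n <- nrow(ratings)
  k <- ncol(ratings)
  grand <- mean(ratings)
  row_means <- rowMeans(ratings)
  col_means <- colMeans(ratings)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((ratings - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  list(msr = ss_rows / (n - 1), msc = ss_cols / (k - 1),
       mse = ss_err / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Intraclass correlation, two-way mixed effects, absolute agreement
#'
#' ICC from the two-way ANOVA decomposition of a complete subjects x raters
#' matrix (McGraw & Wong convention). The default is the multiple-raters
#' form ICC(A,k) — agreement of the mean of the k raters — matching the
#' "multiple raters/measurements, absolute agreement" model; the
#' single-measure form ICC(A,1) is also available.
#'
#' @param ratings Numeric matrix, subjects in rows (>= 5), raters in
#'   columns (>= 2), no missing cells.
#' @param type `"A,k"` (default) or `"A,1"`.
#' @return ICC value (dimensionless, <= 1).
#' @export
icc_two_way_mixed_absolute <- function(ratings, type = c("A,k", "A,1")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings))
    cochloc_error("ratings matrix has missing cells",
                  "cochloc_incomplete_matrix")
  if (nrow(ratings) < 5 || ncol(ratings) < 2)
    cochloc_error("need >= 5 subjects and >= 2 raters",
                  "cochloc_insufficient_data")
  ms <- two_way_mean_squares(ratings)
  if (type == "A,k") {
    (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / ms$n)
  } else {
    (ms$msr - ms$mse) /
      (ms$msr + (ms$k - 1) * ms$mse + ms$k * (ms$msc - ms$mse) / ms$n)
  }
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality check
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the data, using the Lilliefors correction for the
#' estimated parameters ([nortest::lillie.test()]). `normal` is the
#' alpha = 0.05 decision. Constant data (zero SD) is flagged degenerate
#' rather than tested.
#'
#' @param differences Numeric vector, `n >= 5`.
#' @param alpha Significance level for the decision, default 0.05.
#' @return List with `statistic`, `p`, `normal`, `degenerate`, `n`.
#' @export
ks_normality <- function(differences, alpha = 0.05) {
  differences <- as.numeric(differences)
  if (length(differences) < 5 || any(!is.finite(differences)))
    cochloc_error("need >= 5 finite values", "cochloc_insufficient_data")
  if (stats::sd(differences) == 0)
    return(list(statistic = 0, p = NA_real_, normal = FALSE,
                degenerate = TRUE, n = length(differences)))
  lt <- nortest::lillie.test(differences)
  list(statistic = unname(lt$statistic), p = lt$p.value,
       normal = lt$p.value > alpha, degenerate = FALSE,
       n = length(differences))
}

#' Subgroup tests of per-array bias against potential confounders
#'
#' Compares the central tendency of per-array bias between the levels of a
#' grouping covariate (e.g. voxel size, image-quality score): two groups
#' are compared with the Wilcoxon rank-sum test, more than two with a
#' one-way ANOVA. A flag reports whether the spread of the group means
#' exceeds the interrater-precision criterion for the parameter, i.e.
#' whether the group differences would matter at the scale of manual
#' measurement uncertainty.
#'
#' @param per_array_bias Numeric vector of per-array mean differences.
#' @param groups Factor (or coercible) of the same length; every level must
#'   have `n >= 3`.
#' @param precision_criterion Interrater precision (half-width of the
#'   interrater limits of agreement) in the parameter's units; `NA` skips
#'   the flag.
#' @return List with `test` (`"wilcoxon"` or `"anova"`), `statistic`, `p`,
#'   `group_means`, `exceeds_criterion`.
#' @export
group_bias_tests <- function(per_array_bias, groups,
                             precision_criterion = NA_real_) {
  groups <- droplevels(as.factor(groups))
  if (length(per_array_bias) != length(groups))
    cochloc_error("bias and groups must have equal length",
                  "cochloc_pairing_error")
  sizes <- table(groups)
  if (nlevels(groups) < 2 || any(sizes < 3))
    cochloc_error("need >= 2 groups with >= 3 observations each",
                  "cochloc_insufficient_group")
  group_means <- tapply(per_array_bias, groups, mean)
  if (nlevels(groups) == 2) {
    lv <- levels(groups)
    wt <- stats::wilcox.test(per_array_bias[groups == lv[1]],
                             per_array_bias[groups == lv[2]], exact = FALSE)
    test <- "wilcoxon"
    statistic <- unname(wt$statistic)
    p <- wt$p.value
  } else {
    fit <- stats::aov(per_array_bias ~ groups)
    tab <- summary(fit)[[1]]
    test <- "anova"
    statistic <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
  }
  exceeds <- if (is.na(precision_criterion)) NA else
    (max(group_means) - min(group_means)) > precision_criterion
  list(test = test, statistic = statistic, p = p,
       group_means = group_means, exceeds_criterion = exceeds)
}

#' Full agreement report for one spatial parameter
#'
#' Bundles the whole method-comparison battery for one parameter: paired
#' differences pooled across arrays, Bland-Altman bias and limits of
#' agreement, percentage error relative to the reference method's grand
#' mean, Pearson correlation with Fisher-z CI, ICC(A,k) of the
#' (array, electrode) x method matrix, and the Lilliefors normality check
#' of the differences.
#'
#' @param setA,setB Measurement tables; `setB` is the reference
#'   (established) method used for the percentage-error denominator.
#' @param parameter `"emd"` or `"adoi"`.
#' @param confidence Confidence level for the correlation CI.
#' @return An object of class `agreement_report` (a list).
#' @export
agreement_report <- function(setA, setB, parameter = c("emd", "adoi"),
                             confidence = 0.95) {
  parameter <- match.arg(parameter)
  pd <- paired_differences(setA, setB, parameter)
  ba <- bland_altman(pd$diff)
  pe <- percentage_error(ba$loa_low, ba$loa_high, mean(pd$b))
  pr <- pearson_with_ci(pd$a, pd$b, confidence)
  icc <- icc_two_way_mixed_absolute(cbind(pd$a, pd$b))
  ks <- ks_normality(pd$diff)
  structure(
    list(parameter = parameter, n_pairs = nrow(pd), bias = ba$bias,
         sd = ba$sd, loa_low = ba$loa_low, loa_high = ba$loa_high,
         percentage_error = pe, pearson_r = pr$r, r_ci_low = pr$ci_low,
         r_ci_high = pr$ci_high, r_p = pr$p, icc = icc,
         ks_statistic = ks$statistic, ks_p = ks$p, ks_normal = ks$normal,
         differences = pd),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  unit <- if (x$parameter == "emd") "mm" else "deg"
  cat(sprintf("<agreement_report> %s (%d pairs)\n", toupper(x$parameter),
              x$n_pairs))
  cat(sprintf("  bias %.3f %s, LoA [%.3f, %.3f] %s\n", x$bias, unit,
              x$loa_low, x$loa_high, unit))
  cat(sprintf("  percentage error %.1f%%, r = %.3f [%.3f, %.3f], ICC(A,k) = %.3f\n",
              x$percentage_error, x$pearson_r, x$r_ci_low, x$r_ci_high,
              x$icc))
  cat(sprintf("  Lilliefors D = %.3f, p = %.3g, normal: %s\n",
              x$ks_statistic, x$ks_p, x$ks_normal))
  invisible(x)
}
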