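#' Pooled two-sample t-test from summary statistics
#'
#' Student's t with pooled variance, computed from group means, standard
#' deviations and sizes only -- exactly the arithmetic needed to recompute
#' the t-values printed in a report table (df = n1 + n2 - 2).
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return Object of class `ms_test`: list with `statistic`, `df`, `p`
#'   (two-tailed), `estimate` (mean difference), `method`.
#' @examples
#' ttest_from_summary(37.42, 2.56, 55, 39.54, 4.37, 27)  # t = -2.77, df 80
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  structure(list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 estimate = mean1 - mean2,
                 method = "pooled two-sample t (summary statistics)"),
            class = "ms_test")
}

#' Pooled two-sample t-test from raw samples
#'
#' Identical to [ttest_from_summary()] applied to the samples' own means
#' and standard deviations.
#'
#' @param x,y Numeric sample vectors.
#' @return An `ms_test` (see [ttest_from_summary()]).
#' @export
ttest_from_data <- function(x, y) {
  res <- ttest_from_summary(mean(x), stats::sd(x), length(x),
                            mean(y), stats::sd(y), length(y))
  res$method <- "pooled two-sample t"
  res
}

#' @export
print.ms_test <- function(x, ...) {
  df <- if (length(x$df) == 2) paste(x$df, collapse = ", ") else x$df
  cat(sprintf("%s: statistic = %.3f, df = %s, p = %.4g%s\n",
              x$method, x$statistic, df, x$p,
              if (!is.null(x$corrected_p))
                sprintf(", corrected p = %.4g", x$corrected_p) else ""))
  invisible(x)
}

#' Bonferroni correction
#'
#' `min(1, m * p)`. With the default `m = 4` (one test per microstate
#' class) the corrected alpha 0.05 corresponds to a per-test 0.0125.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param m Number of tests (default 4).
#' @return Corrected p-value(s), capped at 1.
#' @export
bonferroni <- function(p, m = 4) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Mixed (split-plot) repeated-measures ANOVA
#'
#' Two-way ANOVA with microstate class as the within-subject factor and
#' group as the between-subject factor: between-subject F for group against
#' the subject stratum, within-subject F for class and the group x class
#' interaction against the residual stratum. Requires a complete balanced
#' design (every subject measured in every class). Fitted via
#' [stats::aov()] with an `Error(subject)` term.
#'
#' @param values Numeric matrix, subjects x classes (columns named by
#'   class), or a long data frame with columns `subject`, `class`, `value`,
#'   `group`.
#' @param group Group labels per subject (ignored when `values` is long).
#' @param sphericity `"none"` (default) or `"greenhouse-geisser"`: with the
#'   latter, the within-subject and interaction p-values are recomputed
#'   with both degrees of freedom multiplied by the Greenhouse--Geisser
#'   epsilon estimated from the pooled within-group covariance of the
#'   repeated measures (the F statistics are unchanged; `epsilon` is
#'   attached to the returned tests).
#' @return List of three `ms_test` objects: `group`, `class`,
#'   `interaction`, each with an F statistic and a df pair.
#' @export
mixed_anova <- function(values, group = NULL,
                        sphericity = c("none", "greenhouse-geisser")) {
  sphericity <- match.arg(sphericity)
  if (is.data.frame(values) && all(c("subject", "class", "value", "group")
                                   %in% names(values))) {
    long <- values
  } else {
    values <- as.matrix(values)
    if (is.null(group) || length(group) != nrow(values))
      stop("'group' must give one label per subject (row)")
    cls <- colnames(values)
    if (is.null(cls)) cls <- LETTERS[seq_len(ncol(values))]
    long <- data.frame(
      subject = rep(seq_len(nrow(values)), times = ncol(values)),
      class = rep(cls, each = nrow(values)),
      group = rep(as.character(group), times = ncol(values)),
      value = as.vector(values))
  }
  if (anyNA(long$value)) stop("missing cells in the within-subject design")
  tab <- table(long$subject, long$class)
  if (any(tab != 1)) stop("missing cells in the within-subject design")
  long$subject <- factor(long$subject)
  long$class <- factor(long$class)
  long$group <- factor(long$group)
  fit <- stats::aov(value ~ group * class + Error(subject), data = long)
  s <- summary(fit)
  bet <- s[["Error: subject"]][[1]]
  wit <- s[["Error: Within"]][[1]]
  mk <- function(tabrow, resrow, label) {
    structure(list(statistic = tabrow[["F value"]],
                   df = c(tabrow[["Df"]], resrow[["Df"]]),
                   p = tabrow[["Pr(>F)"]],
                   method = paste0("mixed ANOVA ", label, " effect (F)")),
              class = "ms_test")
  }
  rn <- function(tab, name) tab[trimws(rownames(tab)) == name, , drop = FALSE]
  out <- list(group = mk(rn(bet, "group"), rn(bet, "Residuals"), "group"),
              class = mk(rn(wit, "class"), rn(wit, "Residuals"), "class"),
              interaction = mk(rn(wit, "group:class"), rn(wit, "Residuals"),
                               "group x class"))
  if (sphericity == "greenhouse-geisser") {
    wide <- stats::reshape(long[, c("subject", "class", "value")],
                           idvar = "subject", timevar = "class",
                           direction = "wide")[, -1]
    grp_of <- long$group[match(unique(long$subject), long$subject)]
    centred <- do.call(rbind, lapply(split(as.data.frame(wide), grp_of),
                                     function(m) scale(m, scale = FALSE)))
    S <- stats::cov(centred)
    k <- ncol(S)
    D <- S - outer(rowMeans(S), rep(1, k)) -
      outer(rep(1, k), colMeans(S)) + mean(S)
    eps <- sum(diag(D))^2 / ((k - 1) * sum(D^2))
    eps <- min(1, max(eps, 1 / (k - 1)))
    for (term in c("class", "interaction")) {
      tst <- out[[term]]
      tst$p <- stats::pf(tst$statistic, eps * tst$df[1], eps * tst$df[2],
                         lower.tail = FALSE)
      tst$epsilon <- eps
      tst$method <- paste0(tst$method, ", Greenhouse-Geisser corrected")
      out[[term]] <- tst
    }
  }
  out
}

#' Gaussian-identity generalized linear model with Wald inference
#'
#' Fits `response ~ covariates` by maximum likelihood ([stats::glm()]) and
#' reports per-predictor coefficients with Wald 95 percent confidence
#' intervals and p-values. Collinear predictors raise an error naming them.
#'
#' @param response Numeric response vector (one value per subject).
#' @param covariates Data frame of predictors (numeric columns).
#' @param family A [stats::family] object (default gaussian identity).
#' @return Object of class `ms_glm`: data frame with one row per term:
#'   `term`, `beta`, `ci_low`, `ci_high`, `p`.
#' @export
glm_fit <- function(response, covariates, family = stats::gaussian()) {
  covariates <- as.data.frame(covariates)
  n <- length(response)
  if (n != nrow(covariates)) stop("response and covariates lengths differ")
  if (n <= ncol(covariates) + 1)
    stop("need n > number of predictors + 1")
  if (anyNA(response) || anyNA(covariates)) stop("missing values present")
  if (ncol(covariates) > 0) {
    mm <- stats::model.matrix(~ ., data = covariates)
    qr_ <- qr(mm)
    if (qr_$rank < ncol(mm)) {
      aliased <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
      stop("collinear predictors: ", paste(aliased, collapse = ", "))
    }
    dat <- cbind(.response = response, covariates)
    fit <- stats::glm(.response ~ ., data = dat, family = family)
  } else {
    fit <- stats::glm(response ~ 1, family = family)
  }
  sm <- summary(fit)$coefficients
  zq <- stats::qnorm(0.975)
  out <- data.frame(term = rownames(sm),
                    beta = sm[, 1],
                    ci_low = sm[, 1] - zq * sm[, 2],
                    ci_high = sm[, 1] + zq * sm[, 2],
                    p = sm[, 4],
                    row.names = NULL)
  structure(out, class = c("ms_glm", "data.frame"))
}

#' Pearson chi-square test for a 2 x 2 table
#'
#' Without continuity correction, df = 1 -- the form whose value matches a
#' report table's printed chi-square for group proportions.
#'
#' @param counts 2 x 2 matrix of nonnegative counts.
#' @return An `ms_test` with the chi-square statistic, df = 1, and p.
#' @export
chisq_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2))
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in the 2 x 2 table")
  ct <- stats::chisq.test(counts, correct = FALSE)
  structure(list(statistic = unname(ct$statistic), df = 1,
                 p = ct$p.value,
                 method = "Pearson chi-square (2 x 2, uncorrected)"),
            class = "ms_test")
}

#' Post-hoc power of the pooled two-sample t-test
#'
#' Power of a two-tailed pooled-variance t-test at the observed
#' standardized mean difference, via the noncentral t distribution.
#'
#' @inheritParams ttest_from_summary
#' @param alpha Two-tailed significance level (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
posthoc_power <- function(mean1, sd1, n1, mean2, sd2, n2, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  ncp <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + 1 - stats::pt(tcrit, df, ncp)
}

#' Mann-Whitney U test (non-parametric fallback)
#'
#' Provided for data failing normality or variance-homogeneity screening;
#' only ever used when requested explicitly.
#'
#' @param x,y Numeric sample vectors.
#' @return An `ms_test` wrapping [stats::wilcox.test()] (W statistic).
#' @export
mann_whitney <- function(x, y) {
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  structure(list(statistic = unname(wt$statistic), df = NA_real_,
                 p = wt$p.value, method = "Mann-Whitney U"),
            class = "ms_test")
}

#' Group comparison table for microstate parameters
#'
#' For each class and parameter: group means and SDs, pooled t, df,
#' two-tailed p, and the Bonferroni-corrected p (default m = 4, one test
#' per class) -- the structure of a microstate parameter report table.
#'
#' @param params Tidy data frame with columns `subject`, `group`, `class`,
#'   and parameter columns (e.g. `mmd_ms`, `rtt`, `gev`, `occurrence`).
#' @param parameters Which parameter columns to test.
#' @param bonferroni_m Number of tests per parameter family (default 4).
#' @param nonparametric Use [mann_whitney()] instead of the t-test.
#' @return Data frame: class, parameter, per-group mean/sd, statistic, df,
#'   p, corrected_p.
#' @export
parameter_table <- function(params,
                            parameters = intersect(c("mmd_ms", "rtt", "gev",
                                                     "occurrence"),
                                                   names(params)),
                            bonferroni_m = 4, nonparametric = FALSE) {
  stopifnot(all(c("group", "class") %in% names(params)))
  grp <- levels(factor(params$group))
  if (length(grp) != 2) stop("exactly two groups are required")
  out <- NULL
  for (cl in unique(params$class)) for (pm in parameters) {
    x <- params[params$class == cl & params$group == grp[2], pm]
    y <- params[params$class == cl & params$group == grp[1], pm]
    tt <- if (nonparametric) mann_whitney(x, y) else ttest_from_data(x, y)
    out <- rbind(out, data.frame(
      class = cl, parameter = pm,
      mean_g2 = mean(x), sd_g2 = stats::sd(x),
      mean_g1 = mean(y), sd_g1 = stats::sd(y),
      statistic = tt$statistic, df = tt$df[1], p = tt$p,
      corrected_p = bonferroni(tt$p, bonferroni_m)))
  }
  names(out)[names(out) == "mean_g2"] <- paste0("mean_", grp[2])
  names(out)[names(out) == "sd_g2"] <- paste0("sd_", grp[2])
  names(out)[names(out) == "mean_g1"] <- paste0("mean_", grp[1])
  names(out)[names(out) == "sd_g1"] <- paste0("sd_", grp[1])
  out
}
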