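# Cohort statistical layer: per-diet linear regression of each metric over
# age, two-way ANOVA (age x diet) per diet pair, exact Mann-Whitney tests at
# each time point with Bonferroni correction, and Spearman correlation of
# repertoire metrics with morbidity outcomes.

#' Linear regression of a metric over age within one diet
#'
#' @param values Metric values.
#' @param ages Ages in months (same length; at least 3 points spanning at
#'   least 2 distinct ages).
#' @return List: `slope`, `intercept`, `p` (two-sided slope p-value),
#'   `r_squared`, `n`.
#' @export
age_regression <- function(values, ages) {
  keep <- is.finite(values) & is.finite(ages)
  values <- values[keep]; ages <- ages[keep]
  if (length(values) < 3) stop("need >= 3 points for an age regression")
  if (length(unique(ages)) < 2) stop("ages must span >= 2 distinct values")
  fit <- lm(values ~ ages)
  coefs <- summary(fit)$coefficients
  list(slope = unname(coefs["ages", "Estimate"]),
       intercept = unname(coefs["(Intercept)", "Estimate"]),
       p = unname(coefs["ages", "Pr(>|t|)"]),
       r_squared = summary(fit)$r.squared,
       n = length(values))
}

#' Two-way fixed-effects ANOVA (age x diet) for one diet pair
#'
#' @param values Metric values.
#' @param ages Ages (coerced to factor).
#' @param diets Diet labels (exactly two levels).
#' @return List: `p_age`, `p_diet`, `p_interaction`, plus F statistics.
#' @export
two_way_anova <- function(values, ages, diets) {
  keep <- is.finite(values)
  values <- values[keep]
  age_f <- factor(ages[keep])
  diet_f <- factor(diets[keep])
  if (nlevels(diet_f) != 2) stop("two_way_anova compares exactly two diets")
  if (nlevels(age_f) < 2) stop("need >= 2 ages")
  cell_n <- table(age_f, diet_f)
  if (any(cell_n == 0)) {
    bad <- which(cell_n == 0, arr.ind = TRUE)
    stop("empty cell(s): ",
         paste(sprintf("%s x %s", rownames(cell_n)[bad[, 1]],
                       colnames(cell_n)[bad[, 2]]), collapse = ", "))
  }
  if (all(cell_n == 1)) stop("need >= 2 replicates per cell")
  fit <- aov(values ~ age_f * diet_f)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  get <- function(term, col) unname(tab[rn == term, col])
  list(p_age = get("age_f", "Pr(>F)"),
       p_diet = get("diet_f", "Pr(>F)"),
       p_interaction = get("age_f:diet_f", "Pr(>F)"),
       f_age = get("age_f", "F value"),
       f_diet = get("diet_f", "F value"),
       f_interaction = get("age_f:diet_f", "F value"))
}

#' Mann-Whitney U test between two groups at one time point
#'
#' Exact two-sided test when both groups have at most `exact_max` values
#' (n = 5 per group in this design makes the exact test the norm), normal
#' approximation otherwise.
#'
#' @param x,y Metric values of the two groups.
#' @param exact_max Largest per-group n for the exact test (default 8).
#' @return List: `U`, `p`, `n_x`, `n_y`, `exact`.
#' @export
timepoint_test <- function(x, y, exact_max = 8L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  use_exact <- length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = !use_exact)
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       n_x = length(x), n_y = length(y), exact = use_exact)
}

#' Bonferroni adjustment over a test family
#'
#' @param p Raw p-values of the simultaneous family.
#' @return Adjusted p-values, `min(1, p * length(family))` (undefined
#'   entries are excluded from the family size).
#' @export
bonferroni <- function(p) {
  m <- sum(!is.na(p))
  out <- pmin(1, p * m)
  out
}

#' Spearman correlation of repertoire metrics with morbidity outcomes
#'
#' For each metric, Spearman's rho (mid-rank ties) against macromorbidity,
#' neoplasia grade and non-neoplastic burden separately. Metrics or outcomes
#' that are constant are flagged undefined and excluded from the Bonferroni
#' family (one family per outcome panel). Both rho-squared and the linear
#' regression R-squared are emitted as variance-explained candidates.
#'
#' @param metric_table `data.frame` with one row per sample, joined with the
#'   morbidity columns.
#' @param metrics Character vector of metric column names.
#' @param outcomes Outcome column names (default the three morbidity
#'   outcomes).
#' @param min_n Minimum paired observations per correlation (default 5).
#' @return `data.frame`: metric, outcome, rho, p, p_bonferroni, rho_squared,
#'   lm_r_squared, n, defined.
#' @export
morbidity_correlation <- function(metric_table, metrics,
                                  outcomes = c("macromorbidity",
                                               "neoplasia_grade",
                                               "non_neoplastic_burden"),
                                  min_n = 5L) {
  rows <- list()
  for (outcome in outcomes) {
    for (metric in metrics) {
      x <- metric_table[[metric]]
      y <- metric_table[[outcome]]
      keep <- is.finite(x) & is.finite(y)
      x <- x[keep]; y <- y[keep]
      if (length(x) < min_n) {
        stop(sprintf("fewer than %d paired observations for %s vs %s",
                     min_n, metric, outcome))
      }
      defined <- sd(x) > 0 && sd(y) > 0
      if (defined) {
        ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                        exact = FALSE))
        rho <- unname(ct$estimate)
        p <- ct$p.value
        r2 <- summary(lm(y ~ x))$r.squared
      } else {
        rho <- NA_real_; p <- NA_real_; r2 <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, outcome = outcome, rho = rho, p = p,
        rho_squared = rho^2, lm_r_squared = r2, n = length(x),
        defined = defined, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- NA_real_
  for (outcome in outcomes) {
    idx <- out$outcome == outcome & out$defined
    out$p_bonferroni[idx] <- bonferroni(out$p[idx])
  }
  out[, c("metric", "outcome", "rho", "p", "p_bonferroni", "rho_squared",
          "lm_r_squared", "n", "defined")]
}
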