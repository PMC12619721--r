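# Univariate screens: Pearson correlation with t-based p-values, age
# correction by OLS residuals, per-metabolite MLR with Benjamini-Hochberg
# FDR control, and per-metabolite age-adjusted logistic regression.

#' Pearson correlation with parametric p-value
#'
#' Sample Pearson correlation and the two-sided p-value from the exact t
#' transform `t = r sqrt(n-2) / sqrt(1-r^2)` on n-2 degrees of freedom.
#'
#' @param x,y numeric vectors, `n >= 3`, both with positive SD.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input to pearson()")
  r <- cor(x, y)
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p_value = 2 * pt(-abs(tval), n - 2), n = n)
}

#' Age-correct a concentration vector
#'
#' Residuals of the OLS regression of concentration on (intercept, age);
#' the standard display transform before correlating a metabolite with PMI.
#' Constant age degenerates to plain centering, with a warning.
#'
#' @param concentration,age numeric vectors, `n >= 3`.
#' @return residual vector (mean 0).
#' @export
age_correct <- function(concentration, age) {
  if (length(concentration) != length(age)) stop("length mismatch")
  if (length(age) < 3L) stop("need at least 3 observations")
  if (sd(age) == 0) {
    warning("constant age; returning centred concentrations")
    return(concentration - mean(concentration))
  }
  unname(stats::residuals(lm(concentration ~ age)))
}

#' Per-metabolite multiple linear regression screen
#'
#' For each metabolite fits `concentration ~ intercept + age + PMI` by least
#' squares, takes the two-sided t-test p-value of the PMI coefficient, and
#' controls the FDR across metabolites with Benjamini-Hochberg. The reported
#' `r` is the Pearson correlation between the age-corrected concentration and
#' PMI (the quantity drawn in the predictor plots).
#'
#' @param ds a `pmi_dataset`.
#' @param alpha_fdr FDR level (default 0.05).
#' @return data frame with `metabolite`, `coefficient` (PMI slope), `r`,
#'   `p_value`, `q_value`, `direction`, `significant`.
#' @export
mlr_screen <- function(ds, alpha_fdr = 0.05) {
  stopifnot(inherits(ds, "pmi_dataset"))
  n <- nrow(ds$concentrations)
  if (n < 5L) stop("need at least 5 samples")
  age <- ds$samples$age_years
  pmi <- ds$samples$pmi_hours
  if (sd(age) == 0 || sd(pmi) == 0 || abs(cor(age, pmi)) > 1 - 1e-12) {
    stop("singular design: age and PMI must be non-constant and not collinear")
  }
  rows <- lapply(colnames(ds$concentrations), function(met) {
    conc <- ds$concentrations[, met]
    fit <- summary(lm(conc ~ age + pmi))$coefficients
    beta <- fit["pmi", "Estimate"]
    data.frame(metabolite = met, coefficient = beta,
               r = cor(age_correct(conc, age), pmi),
               p_value = fit["pmi", "Pr(>|t|)"])
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$direction <- ifelse(out$coefficient >= 0, "+", "-")
  out$significant <- out$q_value < alpha_fdr
  rownames(out) <- NULL
  out
}

#' Per-metabolite age-adjusted logistic screen
#'
#' For each metabolite fits a maximum-likelihood logistic regression
#' `class ~ intercept + age + concentration` (concentration standardised so
#' the separation guard has a scale) and reports the Wald two-sided p-value
#' of the concentration coefficient. No multiplicity adjustment is applied -
#' this screen is read at plain `p < alpha`, unlike [mlr_screen()]. Fits
#' showing quasi-separation (standardised coefficient beyond 50, or
#' non-convergence) are flagged and their p-value reported as `NA`.
#'
#' @param ds a `pmi_dataset`.
#' @param classes two-level factor (second level is coded 1).
#' @param alpha significance level (default 0.05).
#' @return data frame with `metabolite`, `coefficient` (standardised
#'   concentration effect), `p_value`, `direction`, `separation`,
#'   `significant`.
#' @export
logistic_screen <- function(ds, classes, alpha = 0.05) {
  stopifnot(inherits(ds, "pmi_dataset"))
  classes <- droplevels(as.factor(classes))
  if (nlevels(classes) != 2L) stop("classes must have exactly two levels present")
  if (nrow(ds$concentrations) < 10L) stop("need at least 10 samples")
  y <- as.integer(classes == levels(classes)[2L])
  age <- ds$samples$age_years
  rows <- lapply(colnames(ds$concentrations), function(met) {
    conc <- ds$concentrations[, met]
    s <- sd(conc)
    if (s == 0) {
      return(data.frame(metabolite = met, coefficient = 0, p_value = NA_real_,
                        direction = "+", separation = TRUE))
    }
    z <- (conc - mean(conc)) / s
    boundary <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ age + z, family = binomial(),
          control = list(maxit = 100L, epsilon = 1e-10)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) boundary <<- TRUE
        invokeRestart("muffleWarning")
      })
    beta <- coef(fit)[["z"]]
    sep <- !fit$converged || boundary || abs(beta) > 50
    p <- if (sep) NA_real_ else {
      se <- summary(fit)$coefficients["z", "Std. Error"]
      2 * pnorm(-abs(beta / se))
    }
    data.frame(metabolite = met, coefficient = beta, p_value = p,
               direction = ifelse(beta >= 0, "+", "-"), separation = sep)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  rownames(out) <- NULL
  out
}
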