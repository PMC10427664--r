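## Exploitation-trait association statistics: two-sample KS comparisons of
## trait distributions, Clopper-Pearson binomial intervals for per-category
## exploitation proportions, Wilcoxon rank-sum comparisons, and a
## maximum-likelihood logistic regression of exploitation on standardized
## traits with a family-level random intercept.

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of the (signed, for one-sided alternatives) difference
#' between the two empirical CDFs; the p-value uses the asymptotic KS
#' distribution at the effective sample size `n1*n2/(n1+n2)`. Direction is
#' an explicit argument and is never inferred from the data:
#' `alternative = "greater"` tests whether the ECDF of `a` lies above that
#' of `b` (i.e. `a` stochastically smaller).
#'
#' @param a,b numeric samples.
#' @param alternative `"two_sided"`, `"less"` or `"greater"`.
#' @return list with `statistic` (D), `p.value`, `alternative`.
#' @export
ks_two_sample <- function(a, b, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  alt <- sub("two_sided", "two.sided", alternative)
  kt <- suppressWarnings(ks.test(a, b, alternative = alt, exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       alternative = alternative)
}

#' Clopper-Pearson binomial confidence interval
#'
#' Exact interval via the beta-quantile identity: lower limit
#' `qbeta(alpha/2, k, n-k+1)` (0 when k = 0), upper limit
#' `qbeta(1-alpha/2, k+1, n-k)` (1 when k = n).
#'
#' @param k successes; @param n trials; @param level confidence level.
#' @return named vector `c(lower, upper)`.
#' @export
binomial_ci <- function(k, n, level = 0.95) {
  if (n <= 0 || k < 0 || k > n || k != round(k) || n != round(n))
    stop("need integer 0 <= k <= n, n > 0")
  alpha <- 1 - level
  c(lower = if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1),
    upper = if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k))
}

#' Wilcoxon rank-sum test
#'
#' Midrank ties; exact enumeration for small samples (both n <= 20, no
#' ties), otherwise the normal approximation with continuity and tie
#' correction.
#'
#' @param a,b numeric samples.
#' @param alternative `"two.sided"` (default), `"less"`, `"greater"`.
#' @return list with `statistic` (Mann-Whitney U of `a`), `p.value`,
#'   `alternative`.
#' @export
rank_sum <- function(a, b, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  exact <- length(a) <= 20 && length(b) <= 20 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                     exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       alternative = alternative)
}

.predictor_map <- c(size = "size_mm", min_bathymetry = "min_bathy_m",
                    geographic_range = "gra_km2", thermal_range = "tr_c",
                    feeding = "feeding", attachment = "attachment",
                    mobility = "mobility", position = "position")

#' Logistic regression of exploitation on traits with a family random intercept
#'
#' Fits `exploited ~ traits + (1 | family)` by maximum likelihood
#' (Laplace-approximated integral over the family intercepts, via
#' [lme4::glmer()]). Continuous traits are standardized internally so
#' coefficients are log-odds per standard deviation; by default shell size
#' and geographic range area are log10-transformed and minimum bathymetry
#' log10(x+1)-transformed first, since these traits span orders of
#' magnitude. Categorical traits enter as factors with reference levels
#' unattached / mobile / epifaunal / suspension.
#'
#' @param data species data.frame with `exploited`, `family` and the trait
#'   columns (`size_mm`, `min_bathy_m`, `gra_km2`, `tr_c`, `feeding`,
#'   `attachment`, `mobility`, `position`).
#' @param predictors subset of `c("size", "min_bathymetry",
#'   "geographic_range", "thermal_range", "feeding", "attachment",
#'   "mobility", "position")`.
#' @param transform `"log10"` (default) or `"none"`.
#' @param random_intercept include the family random intercept (`FALSE`
#'   fits a plain logistic regression by IRLS, for comparison).
#' @return object of class `"exploitation_fit"`: list with `coefficients`
#'   (fixed effects, standardized scale), `ranef_sd` (family intercept SD;
#'   0 when `random_intercept = FALSE`), `converged`, `separation` flag,
#'   `n_obs`, `n_families`, `transform`, and the underlying `fit`.
#' @export
fit_exploitation_model <- function(data,
                                   predictors = c("size", "min_bathymetry",
                                                  "geographic_range", "thermal_range"),
                                   transform = c("log10", "none"),
                                   random_intercept = TRUE) {
  transform <- match.arg(transform)
  bad <- setdiff(predictors, names(.predictor_map))
  if (length(bad)) stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  cols <- .predictor_map[predictors]
  need <- c("exploited", "family", unname(cols))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))

  d <- data[need]
  d <- d[complete.cases(d), , drop = FALSE]
  if (length(unique(d$family)) < 2) stop("need at least 2 families")
  if (length(unique(d$exploited)) < 2) stop("outcome has a single class")

  z <- function(v) (v - mean(v)) / sd(v)
  for (p in intersect(predictors, c("size", "min_bathymetry",
                                    "geographic_range", "thermal_range"))) {
    col <- .predictor_map[[p]]
    v <- d[[col]]
    if (transform == "log10") {
      v <- switch(p, size = log10(v), geographic_range = log10(v),
                  min_bathymetry = log10(v + 1), thermal_range = v)
    }
    d[[col]] <- z(v)
  }
  refs <- list(feeding = "suspension", attachment = "unattached",
               mobility = "mobile", position = "epifaunal")
  for (p in intersect(predictors, names(refs))) {
    col <- .predictor_map[[p]]
    d[[col]] <- stats::relevel(factor(d[[col]]), ref = refs[[p]])
  }
  d$exploited <- as.integer(d$exploited)

  rhs <- paste(unname(cols), collapse = " + ")
  if (random_intercept) {
    fml <- stats::as.formula(paste("exploited ~", rhs, "+ (1 | family)"))
    fit <- lme4::glmer(fml, data = d, family = binomial)
    fx <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    ranef_sd <- vc$sdcor[1]
    converged <- length(fit@optinfo$conv$lme4$messages) == 0
  } else {
    fml <- stats::as.formula(paste("exploited ~", rhs))
    fit <- stats::glm(fml, data = d, family = binomial)
    fx <- coef(fit)
    ranef_sd <- 0
    converged <- fit$converged
  }
  separation <- any(abs(fx) > 15)

  structure(list(coefficients = fx[-1], intercept = unname(fx[1]),
                 ranef_sd = ranef_sd, converged = converged,
                 separation = separation, n_obs = nrow(d),
                 n_families = length(unique(d$family)),
                 transform = transform, predictors = predictors, fit = fit),
            class = "exploitation_fit")
}

#' @export
coef.exploitation_fit <- function(object, ...) object$coefficients

#' @export
print.exploitation_fit <- function(x, ...) {
  cat("Exploitation ~ traits",
      if (x$ranef_sd > 0 || inherits(x$fit, "glmerMod")) "+ (1 | family)",
      "\n")
  cat(sprintf("  n = %d species, %d families; transform = %s; converged: %s\n",
              x$n_obs, x$n_families, x$transform, x$converged))
  if (x$separation) cat("  WARNING: possible complete separation\n")
  cat(sprintf("  intercept %.3f; family intercept SD %.3f\n",
              x$intercept, x$ranef_sd))
  print(round(x$coefficients, 3))
  invisible(x)
}

#' @export
summary.exploitation_fit <- function(object, ...) summary(object$fit, ...)
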