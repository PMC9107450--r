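## Cohort association statistics: variable transforms, percentile
## ordinalization of RT-QuIC outcomes, covariate-adjusted linear and
## proportional-odds models, Bonferroni families and the small-sample
## group-comparison dispatcher.

#' Apply (and invert) a skewness-reducing transform
#'
#' Analyte levels and assay outcomes enter the association models on the
#' untransformed, square-root or natural-log scale, chosen per variable to
#' tame skewness.
#'
#' @param values numeric vector.
#' @param kind \code{"identity"}, \code{"sqrt"} or \code{"log"}.
#' @param inverse apply the inverse transform instead.
#' @param ids optional case ids used in domain-error messages.
#' @return transformed numeric vector.
#' @export
applyTransform <- function(values, kind = c("identity", "sqrt", "log"),
                           inverse = FALSE, ids = NULL) {
  kind <- match.arg(kind)
  if (is.null(ids)) ids <- seq_along(values)
  bad <- switch(kind,
                identity = rep(FALSE, length(values)),
                sqrt = !inverse & values < 0,
                log = !inverse & values <= 0)
  if (any(bad, na.rm = TRUE))
    stop(kind, " transform undefined for case(s): ",
         paste(ids[which(bad)], collapse = ", "))
  if (!inverse)
    switch(kind, identity = values, sqrt = sqrt(values), log = log(values))
  else
    switch(kind, identity = values, sqrt = values^2, log = exp(values))
}

#' Ordinalize a continuous outcome at percentile cutpoints
#'
#' Converts a continuous assay outcome into an ordered categorical
#' variable using quantiles of the analysis set itself: PAR uses the 50th
#' and 75th percentiles (3 levels), MaxFL the 25th/50th/75th (4 levels).
#' Quantiles use linear interpolation between order statistics
#' (\code{type = 7}); a value tied exactly with a cutpoint goes to the
#' lower level.
#'
#' @param values numeric vector.
#' @param probs strictly increasing quantile probabilities in (0, 1);
#'   K = length(probs) + 1 levels result.
#' @return integer vector of levels in 1..K, with the cutpoint values in
#'   \code{attr(, "cutpoints")}.
#' @examples
#' table(ordinalize(1:100, c(0.5, 0.75)))   # 50 / 25 / 25
#' @export
ordinalize <- function(values, probs = c(0.5, 0.75)) {
  if (any(probs <= 0 | probs >= 1) || any(diff(probs) <= 0))
    stop("'probs' must be strictly increasing within (0, 1)")
  q <- quantile(values, probs, type = 7, names = FALSE)
  if (length(unique(values)) == 1L)
    warning("all values equal: a single ordinal level results")
  lev <- 1L + rowSums(outer(values, q, ">"))
  attr(lev, "cutpoints") <- q
  lev
}

newModelFit <- function(kind, term, estimate, se, n, status = "ok",
                        diagnostic = NULL) {
  z <- qnorm(0.975)
  fit <- list(kind = kind, term = term, estimate = estimate, se = se,
              ci = c(lower = estimate - z * se, upper = estimate + z * se),
              p = 2 * pnorm(-abs(estimate / se)),
              n = n, status = status, diagnostic = diagnostic)
  if (kind == "cumulative-logit") {
    fit$or <- exp(estimate)
    fit$or_ci <- exp(fit$ci)
  }
  class(fit) <- "modelFit"
  fit
}

#' @export
print.modelFit <- function(x, ...) {
  cat(sprintf("%s model fit (n = %d): %s\n", x$kind, x$n, x$status))
  if (x$status == "ok") {
    cat(sprintf("  %s: beta = %.4f (95%% CI %.4f, %.4f), p = %.3g\n",
                x$term, x$estimate, x$ci[1], x$ci[2], x$p))
    if (!is.null(x$or))
      cat(sprintf("  OR = %.3f (95%% CI %.3f, %.3f)\n",
                  x$or, x$or_ci[1], x$or_ci[2]))
  } else if (!is.null(x$diagnostic)) cat("  ", x$diagnostic, "\n")
  invisible(x)
}

#' Covariate-adjusted linear association model
#'
#' Ordinary least squares of a (possibly transformed) outcome on a
#' predictor of interest plus adjustment covariates (the usual set: age at
#' death, sex, CAA score, APOE4 allele count, Braak stage, Thal phase).
#' The reported coefficient is the change in mean outcome per 1-unit
#' increase in the predictor on its analysis scale, with a Wald 95% CI.
#'
#' @param data data.frame of cases.
#' @param outcome,predictor column names.
#' @param covariates character vector of adjustment column names.
#' @param transforms optional named list/vector mapping column names to
#'   transform kinds (see [applyTransform()]), applied before fitting.
#' @return a \code{modelFit} (see [fitPropOdds()] for the ordinal
#'   counterpart).
#' @export
fitLinear <- function(data, outcome, predictor, covariates = character(),
                      transforms = NULL) {
  vars <- c(outcome, predictor, covariates)
  d <- data[, vars, drop = FALSE]
  for (v in names(transforms))
    if (v %in% vars) d[[v]] <- applyTransform(d[[v]], transforms[[v]],
                                              ids = data$id)
  d <- d[complete.cases(d), , drop = FALSE]
  X <- as.matrix(cbind(1, d[, c(predictor, covariates), drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "))
  f <- stats::as.formula(paste(outcome, "~",
                               paste(c(predictor, covariates), collapse = "+")))
  fit <- lm(f, data = d)
  est <- coef(fit)[[predictor]]
  se <- sqrt(diag(vcov(fit)))[[predictor]]
  newModelFit("linear", predictor, est, se, nrow(d))
}

#' Covariate-adjusted proportional-odds (cumulative-logit) model
#'
#' Fits \deqn{P(Y \le j \mid x) = \mathrm{logistic}(\alpha_j - \beta^T x)}
#' by maximum likelihood over strictly increasing cutpoints
#' \eqn{\alpha_j}, reporting the predictor's log-odds coefficient, its
#' Wald 95% CI from the observed information, and the odds ratio
#' \eqn{e^\beta} - a multiplicative increase in the odds of a higher
#' outcome category per 1-unit predictor increase.  Separation or
#' non-convergence is reported as a failed fit, never silently.
#'
#' @param data data.frame; \code{outcome} must have at least 3 populated
#'   ordered levels.
#' @param outcome,predictor,covariates as in [fitLinear()].
#' @param transforms as in [fitLinear()] (applied to predictors).
#' @return a \code{modelFit} with elements \code{estimate} (log OR),
#'   \code{se}, \code{ci}, \code{p}, \code{or}, \code{or_ci}, \code{n},
#'   \code{status}, plus \code{zeta} (fitted cutpoints).
#' @export
fitPropOdds <- function(data, outcome, predictor, covariates = character(),
                        transforms = NULL) {
  vars <- c(outcome, predictor, covariates)
  d <- data[, vars, drop = FALSE]
  for (v in names(transforms))
    if (v %in% c(predictor, covariates))
      d[[v]] <- applyTransform(d[[v]], transforms[[v]], ids = data$id)
  d <- d[complete.cases(d), , drop = FALSE]
  y <- d[[outcome]]
  if (!is.factor(y)) y <- factor(y, ordered = TRUE)
  d[[outcome]] <- y
  if (nlevels(droplevels(y)) < 3L)
    stop("ordinal outcome needs at least 3 populated levels")
  f <- stats::as.formula(paste(outcome, "~",
                               paste(c(predictor, covariates), collapse = "+")))
  fit <- tryCatch(suppressWarnings(MASS::polr(f, data = d, Hess = TRUE)),
                  error = function(e) e)
  if (inherits(fit, "condition")) {
    out <- newModelFit("cumulative-logit", predictor, NA_real_, NA_real_,
                       nrow(d), status = "failed",
                       diagnostic = conditionMessage(fit))
    return(out)
  }
  est <- coef(fit)[[predictor]]
  se <- sqrt(diag(vcov(fit)))[[predictor]]
  if (!is.finite(se) || se > 1e3) {
    return(newModelFit("cumulative-logit", predictor, est, se, nrow(d),
                       status = "failed",
                       diagnostic = "unstable standard error (separation?)"))
  }
  out <- newModelFit("cumulative-logit", predictor, est, se, nrow(d))
  out$zeta <- fit$zeta
  out
}

#' Negative log-likelihood of the cumulative-logit model
#'
#' The written-out likelihood behind [fitPropOdds()], exposed so the fit
#' can be verified against any generic optimizer:
#' \eqn{P(Y = j) = \mathrm{logistic}(\alpha_j - \eta) -
#' \mathrm{logistic}(\alpha_{j-1} - \eta)} with \eqn{\alpha_0 = -\infty},
#' \eqn{\alpha_K = \infty}.
#'
#' @param theta parameter vector: K-1 increasing cutpoints followed by the
#'   predictor coefficients.
#' @param y integer outcome in 1..K.
#' @param X numeric predictor matrix (no intercept).
#' @param K number of outcome levels.
#' @return negative log-likelihood (Inf for non-increasing cutpoints).
#' @export
cumulativeLogitNLL <- function(theta, y, X, K) {
  alpha <- theta[seq_len(K - 1)]
  if (any(diff(alpha) <= 0)) return(Inf)
  beta <- theta[-seq_len(K - 1)]
  eta <- drop(X %*% beta)
  upper <- c(alpha, Inf)[y]
  lower <- c(-Inf, alpha)[y]
  -sum(log(plogis(upper - eta) - plogis(lower - eta)))
}

#' Bonferroni-corrected significance threshold for a test family
#'
#' Per-family threshold alpha / m, reported rounded to 4 decimals as used
#' for table annotation (12 tests -> 0.0042, 16 tests -> 0.0031); the
#' exact value is kept in \code{attr(, "exact")}.
#'
#' @param alpha family-wise level.
#' @param mTests number of tests in the family.
#' @return threshold (4-decimal), with attribute \code{exact}.
#' @export
bonferroniThreshold <- function(alpha = 0.05, mTests) {
  stopifnot(mTests >= 1)
  exact <- alpha / mTests
  out <- round(exact, 4)
  attr(out, "exact") <- exact
  out
}

#' Group comparison with small-sample test dispatch
#'
#' Applies the rule used for the functional experiments: nonparametric
#' tests (Mann-Whitney U for two groups, Kruskal-Wallis beyond) when every
#' group has more than 8 observations; with any group of size <= 8, where
#' rank tests have very low power, a Student t test (two groups) or
#' one-way ANOVA instead.  All tests two-sided.
#'
#' @param values numeric vector.
#' @param groups grouping factor/vector (every group needs >= 2 values).
#' @param smallN group size at or below which the parametric branch is
#'   taken.
#' @param mComparisons if given, a Bonferroni-adjusted p
#'   (\code{min(1, p * m)}) is reported alongside.
#' @return list: \code{test} (label of the dispatched test), \code{p},
#'   \code{p_adjusted}, \code{statistic}, \code{n_per_group}.
#' @export
groupCompare <- function(values, groups, smallN = 8L, mComparisons = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  ns <- table(groups)
  if (any(ns < 2L))
    stop("group(s) with fewer than 2 values: ",
         paste(names(ns)[ns < 2], collapse = ", "))
  two <- nlevels(groups) == 2L
  small <- any(ns <= smallN)
  if (small) {
    if (two) {
      ht <- t.test(values ~ groups, var.equal = TRUE)
      test <- "t"; p <- ht$p.value; stat <- unname(ht$statistic)
    } else {
      ht <- anova(aov(values ~ groups))
      test <- "anova"; p <- ht$`Pr(>F)`[1]; stat <- ht$`F value`[1]
    }
  } else {
    if (two) {
      ht <- wilcox.test(values ~ groups, exact = FALSE)
      test <- "wilcoxon"; p <- ht$p.value; stat <- unname(ht$statistic)
    } else {
      ht <- kruskal.test(values, groups)
      test <- "kruskal"; p <- ht$p.value; stat <- unname(ht$statistic)
    }
  }
  list(test = test, p = p,
       p_adjusted = if (is.null(mComparisons)) NULL else
         min(1, p * mComparisons),
       statistic = stat, n_per_group = as.vector(ns))
}

#' Association table for one outcome across predictors
#'
#' Convenience driver that fits one model per predictor against a common
#' outcome (linear or proportional odds), with and without a given extra
#' adjustment covariate, and flags significance at the family's
#' Bonferroni threshold - the shape of the published association tables.
#'
#' @param data data.frame.
#' @param outcome outcome column.
#' @param predictors character vector of predictor columns (the test
#'   family; its length sets the Bonferroni divisor unless
#'   \code{mTests} is given).
#' @param covariates base adjustment set.
#' @param kind \code{"linear"} or \code{"propodds"}.
#' @param transforms as in [fitLinear()].
#' @param alpha family-wise level.
#' @param mTests Bonferroni divisor override.
#' @return data.frame: predictor, estimate, CI, p, (OR, OR CI), and
#'   \code{significant} at the family threshold.
#' @export
associationTable <- function(data, outcome, predictors,
                             covariates = character(),
                             kind = c("linear", "propodds"),
                             transforms = NULL, alpha = 0.05,
                             mTests = NULL) {
  kind <- match.arg(kind)
  if (is.null(mTests)) mTests <- length(predictors)
  thr <- bonferroniThreshold(alpha, mTests)
  rows <- lapply(predictors, function(p) {
    fit <- if (kind == "linear")
      fitLinear(data, outcome, p, covariates, transforms)
    else fitPropOdds(data, outcome, p, covariates, transforms)
    row <- data.frame(predictor = p, estimate = fit$estimate,
                      ci_lower = fit$ci[1], ci_upper = fit$ci[2],
                      p = fit$p, status = fit$status,
                      stringsAsFactors = FALSE)
    if (kind == "propodds") {
      row$or <- fit$or; row$or_lower <- fit$or_ci[1]
      row$or_upper <- fit$or_ci[2]
    }
    row
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p <= as.numeric(thr)
  attr(out, "bonferroni_threshold") <- thr
  rownames(out) <- NULL
  out
}
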