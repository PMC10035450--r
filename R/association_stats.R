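#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value, computed directly from the formulas:
#' t = (mean(x) - mean(y)) / sqrt(vx/nx + vy/ny),
#' df = (vx/nx + vy/ny)^2 / ((vx/nx)^2/(nx-1) + (vy/ny)^2/(ny-1)).
#'
#' @param x,y Numeric vectors; missing values dropped; each group needs >= 2
#'   observations and at least one group nonzero variance.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs >= 2 non-missing values")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx + vy == 0)
    stop("zero variance in both groups; Welch statistic undefined")
  se2x <- vx / length(x); se2y <- vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df <- (se2x + se2y)^2 /
    (se2x^2 / (length(x) - 1) + se2y^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Relative frequency differences via identity-link binomial GLM
#'
#' Fits `outcome ~ exposure + covariates` with a binomial family and identity
#' link, so the exposure coefficients are directly interpretable as
#' percentage-point differences in outcome frequency between each index
#' level and the referent (RFD = 100 x coefficient), with Wald 95% CIs.
#' Convergence is tracked explicitly: IWLS failure, fitted probabilities
#' escaping the unit interval, or non-finite standard errors yield a `converged = FALSE`
#' record with reason `"DNC"` — the link is never silently swapped. A
#' constant outcome yields reason `"degenerate outcome"`.
#'
#' @param outcome Binary (0/1 or logical) vector.
#' @param exposure Factor (or coercible); `referent` names the reference
#'   level (default: first level).
#' @param covariates Optional data.frame of adjusters (e.g. age, race).
#' @param referent Referent exposure level.
#' @param outcome_name Label carried into the result.
#' @return data.frame with one row per non-referent exposure level:
#'   `outcome`, `level`, `referent`, `rfd`, `ci_low`, `ci_high` (percentage
#'   points), `converged`, `reason`, `n_index`, `n_referent`, `covariates`.
#' @export
estimate_rfd <- function(outcome, exposure, covariates = NULL,
                         referent = NULL, outcome_name = "outcome") {
  if (is.logical(outcome)) outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0, 1, NA)))
    stop("outcome must be binary (0/1)")
  exposure <- if (is.factor(exposure)) droplevels(exposure) else
    factor(exposure)
  if (!is.null(referent)) {
    if (!referent %in% levels(exposure))
      stop(sprintf("referent '%s' absent from exposure levels (%s)", referent,
                   paste(levels(exposure), collapse = ", ")))
    exposure <- stats::relevel(exposure, referent)
  }
  referent <- levels(exposure)[1]

  df <- data.frame(.y = outcome, .exp = exposure)
  cov_names <- character()
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_names <- colnames(covariates)
    df <- cbind(df, covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  idx_levels <- levels(exposure)[-1]
  counts <- table(df$.exp)

  base <- data.frame(outcome = outcome_name, level = idx_levels,
                     referent = referent, rfd = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, converged = FALSE, reason = "DNC",
                     n_index = as.integer(counts[idx_levels]),
                     n_referent = as.integer(counts[referent]),
                     covariates = paste(cov_names, collapse = "+"),
                     stringsAsFactors = FALSE)
  if (length(unique(df$.y)) < 2) {
    base$reason <- "degenerate outcome"
    return(base)
  }

  fml <- stats::as.formula(paste(".y ~ .exp",
                                 if (length(cov_names))
                                   paste("+", paste(cov_names, collapse = " + "))
                                 else ""))
  mm <- stats::model.matrix(fml, df)
  start <- c(mean(df$.y), rep(0, ncol(mm) - 1))
  fit <- tryCatch(
    suppressWarnings(stats::glm(fml, family = stats::binomial(link = "identity"),
                                data = df, start = start)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(base)
  # fitted probabilities outside, or degenerately at, the unit interval
  # boundary leave the Wald information singular: report DNC, never refit
  eps <- 1e-10
  if (any(fit$fitted.values < eps | fit$fitted.values > 1 - eps))
    return(base)
  sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(sm)) return(base)

  terms <- paste0(".exp", idx_levels)
  for (i in seq_along(idx_levels)) {
    tn <- terms[i]
    if (!tn %in% rownames(sm) || !all(is.finite(sm[tn, 1:2]))) next
    est <- sm[tn, "Estimate"]; se <- sm[tn, "Std. Error"]
    base$rfd[i] <- 100 * est
    base$ci_low[i] <- 100 * (est - 1.96 * se)
    base$ci_high[i] <- 100 * (est + 1.96 * se)
    base$converged[i] <- TRUE
    base$reason[i] <- ""
  }
  base
}

#' Differential immune-score analysis with BH correction
#'
#' Per score, fits the linear model `score ~ group + covariates`; `beta` is
#' the group coefficient (adjusted mean difference in expression units).
#' Benjamini-Hochberg correction is applied across the score family of the
#' contrast (all scores tested in one call).
#'
#' @param score_table data.frame from [compute_scores()] (`sample_id` plus
#'   score columns), or any data.frame of numeric score columns.
#' @param group Binary contrast: factor/character/logical, index level vs
#'   referent; the first factor level is the referent.
#' @param covariates Optional data.frame of adjusters.
#' @param scores Character vector of score columns to test (default: all
#'   numeric columns except `sample_id`).
#' @return data.frame: `score`, `beta`, `se`, `p`, `q` (BH-adjusted).
#' @export
differential_scores <- function(score_table, group, covariates = NULL,
                                scores = NULL) {
  if (is.null(scores))
    scores <- setdiff(colnames(score_table)[vapply(score_table, is.numeric,
                                                   logical(1))],
                      "sample_id")
  if (!length(scores)) stop("no score columns to test")
  g <- if (is.factor(group)) droplevels(group) else factor(group)
  if (nlevels(g) != 2) stop("group must be a two-level contrast")
  if (min(table(g)) < 2) stop("need >= 2 samples per group")

  base <- data.frame(.g = g)
  cov_names <- character()
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_names <- colnames(covariates)
    base <- cbind(base, covariates)
    mm <- stats::model.matrix(~ ., base)
    if (qr(mm)$rank < ncol(mm))
      stop("collinear covariate set: ", paste(cov_names, collapse = ", "))
  }

  res <- data.frame(score = scores, beta = NA_real_, se = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  term <- paste0(".g", levels(g)[2])
  for (i in seq_along(scores)) {
    d <- cbind(base, .s = score_table[[scores[i]]])
    fit <- stats::lm(.s ~ ., data = d)
    sm <- summary(fit)$coefficients
    res$beta[i] <- sm[term, "Estimate"]
    res$se[i] <- sm[term, "Std. Error"]
    res$p[i] <- sm[term, "Pr(>|t|)"]
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}
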