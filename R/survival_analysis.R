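#' Kaplan-Meier curves with a log-rank comparison
#'
#' Product-limit estimation per group via [survival::survfit()] and, when at
#' least two groups have subjects, the k-sample log-rank test via
#' [survival::survdiff()]. Group levels with zero subjects are dropped with a
#' warning.
#'
#' @param time Follow-up times (>= 0).
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Grouping vector (factor or coercible).
#' @return Object of class `km_fit`: list with `curves` (data.frame: group,
#'   time, n_risk, n_event, n_censor, surv), `logrank` (list chi2, df, p; or
#'   NULL with `logrank_skipped` reason when < 2 groups) and `n`, `events`
#'   per group.
#' @export
km_fit <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time < 0, na.rm = TRUE)) stop("times must be >= 0")
  g <- if (is.factor(group)) group else factor(group)
  empty <- levels(g)[table(g) == 0]
  if (length(empty)) {
    warning("dropping empty group(s): ", paste(empty, collapse = ", "))
    g <- droplevels(g)
  }
  df <- data.frame(time = time, event = event, g = g)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  sf <- survival::survfit(survival::Surv(time, event) ~ g, data = df)
  if (nlevels(df$g) > 1) {
    strata_grp <- rep(sub("^g=", "", names(sf$strata)), sf$strata)
  } else {
    strata_grp <- rep(levels(df$g), length(sf$time))
  }
  curves <- data.frame(group = strata_grp, time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       n_censor = sf$n.censor, surv = sf$surv,
                       stringsAsFactors = FALSE)
  out <- list(curves = curves,
              n = table(df$g),
              events = tapply(df$event, df$g, sum),
              logrank = NULL, logrank_skipped = NULL)
  if (nlevels(df$g) >= 2) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
    k <- nlevels(df$g)
    out$logrank <- list(chi2 = unname(sd$chisq), df = k - 1,
                        p = stats::pchisq(sd$chisq, k - 1, lower.tail = FALSE))
  } else {
    out$logrank_skipped <- "fewer than 2 groups represented"
  }
  class(out) <- "km_fit"
  out
}

#' @export
print.km_fit <- function(x, ...) {
  cat("km_fit:", paste(sprintf("%s %d/%d", names(x$n), x$events, x$n),
                       collapse = ", "), "\n")
  if (!is.null(x$logrank))
    cat(sprintf("log-rank chi2 = %.3f (df %d), p = %.4g\n",
                x$logrank$chi2, x$logrank$df, x$logrank$p))
  invisible(x)
}

#' Cox proportional hazards fit with a proportionality check
#'
#' Partial-likelihood estimation via [survival::coxph()] with Efron tie
#' handling. Hazard ratios are exp(coef) with Wald 95% CIs. The
#' proportional-hazards assumption is checked per covariate column by
#' refitting with a covariate x log(time) (or linear-time) interaction as a
#' time-transform term and reporting the interaction's Wald p. Monotone
#' likelihood (a level with no events driving a coefficient to infinity) is
#' flagged per term as `unstable`.
#'
#' @param time,event Follow-up times and event indicators.
#' @param covariates data.frame of covariates; factors are expanded with
#'   their first level as referent (relevel beforehand to choose referents).
#' @param timescale `"log"` (default) or `"linear"` time in the
#'   proportionality interaction.
#' @param proportionality Logical; set `FALSE` to skip the refits.
#' @return Object of class `cox_fit`: list with `table` (term, coef, hr,
#'   ci_low, ci_high, se, z, p, prop_p, unstable), `sctest` (score test:
#'   chi2, df, p), `loglik`, `n`, `n_event`.
#' @export
cox_fit <- function(time, event, covariates, timescale = c("log", "linear"),
                    proportionality = TRUE) {
  timescale <- match.arg(timescale)
  covariates <- as.data.frame(covariates)
  df <- cbind(data.frame(.time = time, .event = event), covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (sum(df$.event) < 1) stop("no events; Cox model cannot be fit")
  mm <- stats::model.matrix(~ ., df[, -(1:2), drop = FALSE])[, -1, drop = FALSE]
  if (qr(mm)$rank < ncol(mm))
    stop("covariate matrix is rank deficient: ",
         paste(colnames(covariates), collapse = ", "))

  warn <- character()
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ mm, data = df,
                    ties = "efron"),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- sub("^mm", "", rownames(co))
  unstable <- grepl("infinite|did not converge|Loglik converged",
                    paste(warn, collapse = "; ")) &
    (abs(co[, "coef"]) > 10 | co[, "se(coef)"] > 100)
  tab <- data.frame(term = terms,
                    coef = co[, "coef"],
                    hr = exp(co[, "coef"]),
                    ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    se = co[, "se(coef)"],
                    z = co[, "z"],
                    p = co[, "Pr(>|z|)"],
                    prop_p = NA_real_,
                    unstable = unname(unstable),
                    row.names = NULL, stringsAsFactors = FALSE)

  if (proportionality) {
    tt_fun <- if (timescale == "log") function(x, t, ...) x * log(t)
              else function(x, t, ...) x * t
    for (j in seq_len(ncol(mm))) {
      pj <- tryCatch({
        dj <- data.frame(.time = df$.time, .event = df$.event)
        fj <- survival::coxph(
          survival::Surv(.time, .event) ~ mm + tt(mm[, j]), data = dj,
          ties = "efron", tt = tt_fun)
        cj <- summary(fj)$coefficients
        cj[nrow(cj), "Pr(>|z|)"]
      }, error = function(e) NA_real_, warning = function(w) NA_real_)
      tab$prop_p[j] <- pj
    }
  }
  structure(list(table = tab,
                 sctest = list(chi2 = unname(sm$sctest["test"]),
                               df = unname(sm$sctest["df"]),
                               p = unname(sm$sctest["pvalue"])),
                 loglik = fit$loglik, n = nrow(df), n_event = sum(df$.event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: n = %d, events = %d\n", x$n, x$n_event))
  print(x$table, digits = 3)
  invisible(x)
}

#' AGI-stratified recurrence analysis of global immune classes
#'
#' Reproduces the recurrence-analysis design on any sample table: excludes
#' stage IV at diagnosis and AGI-indeterminate samples (each exclusion
#' logged with a reason), applies administrative censoring at
#' `admin_censor` years, and within each AGI stratum (AGI, NGI) fits
#' Kaplan-Meier curves with a log-rank test plus crude and adjusted Cox
#' models of immune class with the Adaptive-Enriched referent. The adjusted
#' model adds age (linear, years), race, stage (indicators, I referent) and
#' ER status.
#'
#' @param data data.frame with columns `sample_id`, `recurrence_time`,
#'   `recurrence_event`, `agi`, `immune_class`, `age`, `race`, `stage`,
#'   `er_status`.
#' @param admin_censor Administrative censoring horizon in years (default 5).
#' @param referent Referent immune class (default `"Adaptive-Enriched"`).
#' @param adjust Covariates of the adjusted model.
#' @return Object of class `survival_report`: list with per-stratum entries
#'   (`km`, `cox_crude`, `cox_adjusted`, `events_by_class`, `n_by_class`)
#'   and an `exclusions` data.frame (sample_id, reason).
#' @export
recurrence_analysis <- function(data, admin_censor = 5,
                                referent = "Adaptive-Enriched",
                                adjust = c("age", "race", "stage",
                                           "er_status")) {
  need <- c("sample_id", "recurrence_time", "recurrence_event", "agi",
            "immune_class")
  miss <- setdiff(c(need, adjust), colnames(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))

  excl <- data.frame(sample_id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  note <- function(ids, why) {
    if (length(ids))
      excl <<- rbind(excl, data.frame(sample_id = ids, reason = why,
                                      stringsAsFactors = FALSE))
  }
  keep <- rep(TRUE, nrow(data))
  drop_now <- keep & data$stage %in% "IV"
  note(data$sample_id[drop_now], "stage IV at diagnosis")
  keep <- keep & !drop_now
  drop_now <- keep & (!data$agi %in% c("AGI", "NGI"))
  note(data$sample_id[drop_now], "AGI indeterminate")
  keep <- keep & !drop_now
  drop_now <- keep & (is.na(data$recurrence_time) |
                        is.na(data$recurrence_event))
  note(data$sample_id[drop_now], "missing follow-up")
  keep <- keep & !drop_now
  drop_now <- keep & (is.na(data$immune_class) |
                        data$immune_class %in% c("missing", "indeterminate"))
  note(data$sample_id[drop_now], "immune class not called")
  keep <- keep & !drop_now
  d <- data[keep, , drop = FALSE]

  # administrative censoring: follow-up truncated at the horizon
  over <- d$recurrence_time > admin_censor
  d$recurrence_event[over] <- 0
  d$recurrence_time[over] <- admin_censor

  classes <- unique(c(referent,
                      setdiff(sort(unique(as.character(d$immune_class))),
                              referent)))
  report <- list(exclusions = excl, admin_censor = admin_censor,
                 referent = referent, strata = list())
  for (st in c("AGI", "NGI")) {
    s <- d[d$agi == st, , drop = FALSE]
    if (!nrow(s)) {
      report$strata[[st]] <- list(skipped = "no samples in stratum")
      next
    }
    cls <- factor(as.character(s$immune_class),
                  levels = classes[classes %in% s$immune_class])
    entry <- list(
      n_by_class = table(cls),
      events_by_class = tapply(s$recurrence_event, cls, sum),
      km = km_fit(s$recurrence_time, s$recurrence_event, cls))
    entry$cox_crude <- tryCatch(
      cox_fit(s$recurrence_time, s$recurrence_event,
              data.frame(immune_class = cls)),
      error = function(e) conditionMessage(e))
    adj_cov <- data.frame(immune_class = cls)
    for (v in adjust) {
      col <- s[[v]]
      adj_cov[[v]] <- if (v == "stage")
        factor(as.character(col), levels = c("I", "II", "III"))
      else if (is.character(col)) factor(col) else col
    }
    # drop adjusters that are constant within the stratum (e.g. ER in an
    # ER-stratified run) to keep the model full rank
    for (v in adjust)
      if (length(unique(stats::na.omit(adj_cov[[v]]))) < 2)
        adj_cov[[v]] <- NULL
    entry$cox_adjusted <- tryCatch(
      cox_fit(s$recurrence_time, s$recurrence_event, adj_cov),
      error = function(e) conditionMessage(e))
    report$strata[[st]] <- entry
  }
  class(report) <- "survival_report"
  report
}

#' @export
print.survival_report <- function(x, ...) {
  cat(sprintf("survival_report (admin censor %g y, referent %s); %d excluded\n",
              x$admin_censor, x$referent, nrow(x$exclusions)))
  for (st in names(x$strata)) {
    e <- x$strata[[st]]
    if (!is.null(e$skipped)) { cat(st, ": ", e$skipped, "\n"); next }
    cat("--", st, "stratum --\n")
    print(e$km)
  }
  invisible(x)
}
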