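test_that("KM matches the hand product-limit calculation on the 5-subject set", {
  k <- km_fit(time = 1:5, event = c(1, 0, 1, 0, 1), group = rep("all", 5))
  cv <- k$curves
  # hand product-limit: S(1) = 4/5; S(3) = 4/5 * 2/3; S(5) = 0
  expect_equal(cv$surv[cv$time == 1], 0.8)
  expect_equal(cv$surv[cv$time == 3], 0.8 * 2 / 3, tolerance = 1e-12)
  expect_equal(cv$surv[cv$time == 5], 0)
  expect_true(all(diff(cv$surv) <= 1e-12))
  # survival at the last event time equals prod(1 - d_i/n_i), recomputed
  expect_equal(cv$surv[cv$time == 5],
               prod(1 - c(1 / 5, 1 / 3, 1 / 1)), tolerance = 1e-12)
})

test_that("KM curves are valid step functions and no-event groups stay at 1", {
  set.seed(10)
  time <- c(rexp(30, 0.2), runif(10, 0, 5))
  event <- c(rep(1, 30), rep(0, 10))
  grp <- rep(c("events", "censored-only"), c(30, 10))
  expect_warning(k <- km_fit(c(time, 1), c(event, 0),
                             factor(c(grp, "censored-only"),
                                    levels = c("events", "censored-only",
                                               "ghost"))),
                 "ghost")
  co <- k$curves[k$curves$group == "censored-only", ]
  expect_true(all(co$surv == 1))
  ev <- k$curves[k$curves$group == "events", ]
  expect_true(all(diff(ev$surv) <= 1e-12))
  expect_lte(max(ev$surv), 1)
})

test_that("log-rank holds its nominal size under the null", {
  set.seed(808)
  reject <- vapply(seq_len(500), function(i) {
    time <- rexp(120, 0.3)
    cens <- runif(120, 0, 6)
    obs <- pmin(time, cens)
    k <- km_fit(obs, as.integer(time <= cens),
                rep(c("a", "b"), each = 60))
    k$logrank$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(reject) - 0.05), 0.02)
})

test_that("Cox score test equals the log-rank chi-square on tie-free data", {
  set.seed(19)
  for (i in 1:5) {
    n <- 60
    time <- rexp(n, 0.2) + cumsum(rep(1e-7, n))  # jitter guarantees no ties
    event <- rbinom(n, 1, 0.8)
    g <- factor(rep(c("a", "b"), each = n / 2))
    cf <- cox_fit(time, event, data.frame(g = g), proportionality = FALSE)
    k <- km_fit(time, event, g)
    expect_equal(cf$sctest$chi2, k$logrank$chi2, tolerance = 1e-6)
  }
})

test_that("Efron partial likelihood optimum matches a brute-force oracle", {
  # 10-subject dataset with ties so the Efron correction is exercised
  time <- c(1, 1, 2, 3, 3, 3, 4, 5, 6, 7)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1, 0, 1)
  x <- c(0, 1, 1, 0, 1, 0, 1, 0, 1, 0)
  cf <- cox_fit(time, event, data.frame(x = x), proportionality = FALSE)

  efron_loglik <- function(beta) {
    ll <- 0
    for (t in unique(time[event == 1])) {
      D <- which(time == t & event == 1)
      R <- which(time >= t)
      d <- length(D)
      ll <- ll + beta * sum(x[D])
      sR <- sum(exp(beta * x[R]))
      sD <- sum(exp(beta * x[D]))
      for (l in seq_len(d) - 1) ll <- ll - log(sR - (l / d) * sD)
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-4)
  beta_star <- grid[which.max(vapply(grid, efron_loglik, numeric(1)))]
  expect_equal(cf$table$coef[1], beta_star, tolerance = 1e-3)
  expect_equal(cf$loglik[2], efron_loglik(cf$table$coef[1]),
               tolerance = 1e-8)
})

test_that("Cox recovers a true hazard ratio of 2 under 30% censoring", {
  set.seed(2024)
  n <- 4000
  g <- rep(c(0, 1), each = n / 2)
  time <- rexp(n, 0.2 * ifelse(g == 1, 2, 1))
  cens <- runif(n, 0, 12)
  obs <- pmin(time, cens)
  cf <- cox_fit(obs, as.integer(time <= cens), data.frame(g = factor(g)),
                proportionality = FALSE)
  expect_gt(cf$table$ci_high[1], 2)
  expect_lt(cf$table$ci_low[1], 2)
  expect_equal(cf$table$hr[1], 2, tolerance = 0.15)
})

test_that("null covariates give HR ~ 1 and uniform Wald p across seeds", {
  set.seed(3)
  ps <- vapply(1:60, function(i) {
    n <- 150
    time <- rexp(n, 0.3)
    x <- rnorm(n)
    cf <- cox_fit(time, rep(1, n), data.frame(x = x),
                  proportionality = FALSE)
    cf$table$p[1]
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.1)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("cox_fit declares its error modes", {
  expect_error(cox_fit(c(1, 2, 3), c(0, 0, 0), data.frame(x = 1:3)),
               "no events")
  expect_error(cox_fit(c(1, 2, 3, 4), c(1, 1, 0, 1),
                       data.frame(x = 1:4, y = 2 * (1:4))),
               "rank deficient")
})

test_that("proportionality Wald p is well-behaved under proportional hazards", {
  set.seed(12)
  n <- 400
  g <- factor(rep(c("a", "b"), each = n / 2))
  time <- rexp(n, 0.3 * ifelse(g == "b", 1.8, 1))
  cf <- cox_fit(time, rep(1, n), data.frame(g = g))
  expect_true(is.finite(cf$table$prop_p[1]))
  expect_gt(cf$table$prop_p[1], 0.001)  # PH truly holds here
})

test_that("recurrence_analysis excludes, censors and counts as declared", {
  cfg <- default_config(n_samples = 900, seed = 42, baseline_hazard = 0.08)
  co <- generate_cohort(cfg)
  st <- data.frame(co$annotations, agi = co$truth$agi,
                   immune_class = co$truth$immune_class)
  # force some follow-up beyond 5 y to exercise administrative censoring
  st$recurrence_time[1:10] <- 6.5
  st$recurrence_event[1:10] <- 1
  rep <- recurrence_analysis(st)

  stage4 <- sum(st$stage == "IV")
  expect_identical(sum(rep$exclusions$reason == "stage IV at diagnosis"),
                   stage4)
  analyzed <- sum(vapply(rep$strata, function(e)
    if (is.null(e$skipped)) sum(e$n_by_class) else 0L, numeric(1)))
  expect_identical(analyzed + nrow(rep$exclusions), as.numeric(nrow(st)))

  for (nm in names(rep$strata)) {
    e <- rep$strata[[nm]]
    expect_true(all(e$km$curves$time <= 5))
    # events/N bookkeeping equals direct counting of the filtered table
    s <- st[st$agi == nm & st$stage != "IV", ]
    s$recurrence_event[s$recurrence_time > 5] <- 0
    direct <- tapply(s$recurrence_event, s$immune_class, sum)
    expect_equal(as.vector(e$events_by_class[names(direct)]),
                 as.vector(direct))
  }
  expect_identical(rep$strata$AGI$cox_adjusted$table$term[1:2],
                   c("immune_classImmune-Quiet", "immune_classInnate-Enriched"))
})

test_that("recurrence_analysis on an all-stage-IV table reports only exclusions", {
  st <- data.frame(sample_id = paste0("s", 1:6), age = 50,
                   race = "Black", er_status = "negative", stage = "IV",
                   recurrence_time = 1:6, recurrence_event = 1,
                   agi = "AGI", immune_class = "Adaptive-Enriched")
  rep <- recurrence_analysis(st)
  expect_identical(nrow(rep$exclusions), 6L)
  expect_identical(rep$strata$AGI$skipped, "no samples in stratum")
})

test_that("the AGI/NGI contrast shows class-dependent recurrence only within AGI", {
  co <- generate_cohort(default_config(n_samples = 4000, seed = 314))
  st <- data.frame(co$annotations, agi = co$truth$agi,
                   immune_class = co$truth$immune_class)
  rep <- recurrence_analysis(st)
  expect_lt(rep$strata$AGI$km$logrank$p, 0.05)
  hr_tab <- rep$strata$AGI$cox_adjusted$table
  innate_hr <- hr_tab$hr[hr_tab$term == "immune_classInnate-Enriched"]
  expect_gt(innate_hr, 1.1)
  ngi_tab <- rep$strata$NGI$cox_crude$table
  expect_true(all(abs(log(ngi_tab$hr[grepl("immune_class", ngi_tab$term)]))
                  < log(2.5)))
})
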