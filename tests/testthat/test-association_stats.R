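test_that("welch_t matches the independent stats::t.test implementation", {
  cases <- list(list(x = c(1, 2, 3, 4), y = c(2, 3, 4, 5)),
                list(x = rnorm(20), y = rnorm(35, 0.4, 2)),
                list(x = c(0.1, 0.2, 0.15), y = c(5, 6, 7, 8, 9)))
  set.seed(55)
  for (cs in cases) {
    got <- welch_t(cs$x, cs$y)
    ref <- stats::t.test(cs$x, cs$y, var.equal = FALSE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("welch_t degenerate inputs behave as declared", {
  x <- c(1, 2, 3, 4)
  got <- welch_t(x, x)  # identical samples
  expect_equal(got$t, 0)
  expect_equal(got$p, 1)
  expect_error(welch_t(c(1), c(1, 2, 3)), ">= 2")
  expect_error(welch_t(c(2, 2, 2), c(2, 2, 2)), "zero variance")
})

test_that("welch_t holds its nominal type-I error under the null", {
  set.seed(321)
  reject <- vapply(seq_len(1000), function(i) {
    welch_t(rnorm(15), rnorm(20, 0, 3))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(reject) - 0.05), 0.02)
})

test_that("unadjusted RFD equals the raw difference of proportions", {
  # constructed 2x2: index 60% vs referent 40%
  outcome <- c(rep(1, 60), rep(0, 40), rep(1, 40), rep(0, 60))
  exposure <- factor(rep(c("index", "ref"), each = 100),
                     levels = c("ref", "index"))
  r <- estimate_rfd(outcome, exposure)
  expect_true(r$converged)
  expect_equal(r$rfd, 20, tolerance = 1e-8)
  expect_identical(r$referent, "ref")
  expect_identical(r$n_index, 100L)

  # property over simulated datasets: oracle equivalence to <= 1e-8
  set.seed(77)
  for (i in 1:20) {
    n <- sample(40:120, 1)
    y <- rbinom(n, 1, 0.5)
    g <- factor(sample(c("a", "b"), n, replace = TRUE), levels = c("a", "b"))
    if (length(unique(y)) < 2 || length(unique(g)) < 2) next
    r <- estimate_rfd(y, g)
    oracle <- 100 * (mean(y[g == "b"]) - mean(y[g == "a"]))
    expect_equal(r$rfd, oracle, tolerance = 1e-8)
    expect_true(r$ci_low <= r$rfd && r$rfd <= r$ci_high)
  }
})

test_that("RFD handles multi-level exposures, one row per index level", {
  set.seed(11)
  g <- factor(sample(c("quiet", "innate", "adaptive"), 300, replace = TRUE),
              levels = c("quiet", "innate", "adaptive"))
  p <- c(quiet = 0.2, innate = 0.4, adaptive = 0.6)
  y <- rbinom(300, 1, p[as.character(g)])
  r <- estimate_rfd(y, g, referent = "quiet")
  expect_identical(r$level, c("innate", "adaptive"))
  for (i in 1:2) {
    oracle <- 100 * (mean(y[g == r$level[i]]) - mean(y[g == "quiet"]))
    expect_equal(r$rfd[i], oracle, tolerance = 1e-8)
  }
})

test_that("degenerate and separated outcomes are reported as DNC, never refit", {
  y0 <- rep(0, 50)
  g <- factor(rep(c("a", "b"), 25))
  r <- estimate_rfd(y0, g)
  expect_false(r$converged)
  expect_identical(r$reason, "degenerate outcome")
  expect_true(is.na(r$rfd))

  # complete separation: outcome identical to exposure
  y <- rep(c(0, 1), each = 30)
  g2 <- factor(rep(c("ref", "idx"), each = 30), levels = c("ref", "idx"))
  r2 <- estimate_rfd(y, g2, covariates = data.frame(age = rnorm(60, 50, 8)))
  expect_false(r2$converged)
  expect_identical(r2$reason, "DNC")
})

test_that("adjusted and crude RFDs agree without confounding, diverge with it", {
  cfg <- default_config(n_samples = 2500, seed = 909)
  co <- generate_cohort(cfg)
  t <- co$truth; ann <- co$annotations
  y <- as.integer(t$immune_class == "Adaptive-Enriched")
  g <- factor(t$agi, levels = c("NGI", "AGI"))
  crude <- estimate_rfd(y, g)
  adj <- estimate_rfd(y, g, covariates = ann[, c("age", "race")])
  expect_true(crude$converged && adj$converged)
  expect_equal(adj$rfd, crude$rfd, tolerance = 3)  # Monte-Carlo agreement, pp

  cfg2 <- default_config(n_samples = 2500, seed = 910,
                         confound_race_adaptive_or = 3, confound_race_hr = 2)
  co2 <- generate_cohort(cfg2)
  t2 <- co2$truth; ann2 <- co2$annotations
  # race now predicts adaptive-enriched membership; contrast race groups
  y2 <- as.integer(t2$immune_class == "Adaptive-Enriched")
  g2 <- factor(ann2$race, levels = c("non-Black", "Black"))
  crude2 <- estimate_rfd(y2, g2)
  expect_gt(crude2$rfd, 5)  # the knob tilts adaptive odds for Black samples
})

test_that("differential scores: beta equals the group mean difference without covariates", {
  set.seed(31)
  n <- 80
  g <- factor(rep(c("WT", "Mut"), each = n / 2), levels = c("WT", "Mut"))
  st <- data.frame(sample_id = paste0("s", 1:n),
                   s1 = rnorm(n) + (g == "Mut") * 1.5,
                   s2 = rnorm(n),
                   s3 = rnorm(n) - (g == "Mut") * 0.5)
  r <- differential_scores(st, g)
  for (i in 1:3) {
    sc <- st[[r$score[i]]]
    expect_equal(r$beta[i], mean(sc[g == "Mut"]) - mean(sc[g == "WT"]),
                 tolerance = 1e-10)
  }
  expect_true(all(r$q >= r$p - 1e-15))
})

test_that("BH adjustment matches the step-up procedure by hand", {
  st <- data.frame(s1 = 1, s2 = 1, s3 = 1, s4 = 1)
  # bypass the model: check p.adjust semantics through the result contract
  # using a constructed fit is brittle; instead check our q on known p via
  # the documented family rule
  p <- c(0.01, 0.02, 0.03, 0.04)
  q <- stats::p.adjust(p, "BH")
  expect_equal(q, rep(0.04, 4))  # hand step-up: min over j>=i of p_j * 4/j

  # q is invariant to score ordering within a family
  set.seed(5)
  n <- 60
  g <- factor(rep(c("a", "b"), each = 30))
  st <- data.frame(sapply(1:6, function(i) rnorm(n) + (g == "b") * i / 10))
  names(st) <- paste0("sc", 1:6)
  r1 <- differential_scores(st, g, scores = paste0("sc", 1:6))
  r2 <- differential_scores(st, g, scores = paste0("sc", 6:1))
  expect_equal(r1$q[match(r2$score, r1$score)], r2$q, tolerance = 1e-12)

  # BH never yields more discoveries than unadjusted p at the same threshold
  expect_lte(sum(r1$q < 0.05), sum(r1$p < 0.05))
})

test_that("differential scores flag collinear covariates and recover planted effects", {
  set.seed(66)
  n <- 50
  g <- factor(rep(c("a", "b"), each = n / 2))
  st <- data.frame(s1 = rnorm(n))
  cov_bad <- data.frame(x1 = 1:n, x2 = 2 * (1:n))
  expect_error(differential_scores(st, g, covariates = cov_bad),
               "collinear")

  cfg <- default_config(n_samples = 600, seed = 404)
  co <- generate_cohort(cfg)
  sc <- compute_scores(co$expression, default_marker_panel())
  g2 <- factor(co$truth$tp53, levels = c("WT-like", "Mut-like"))
  # adaptive markers are elevated with immune class, which is independent of
  # TP53 given AGI; contrast by immune class instead for the planted signal
  g3 <- factor(ifelse(co$truth$immune_class == "Adaptive-Enriched",
                      "adaptive", "other"), levels = c("other", "adaptive"))
  r <- differential_scores(sc, g3,
                           covariates = co$annotations[, c("age", "race")],
                           scores = c("B-cell", "T-cell", "NK", "adaptive"))
  expect_gt(r$beta[r$score == "adaptive"], 0.3)
  expect_lt(r$q[r$score == "adaptive"], 0.05)
})
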