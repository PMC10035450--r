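#' Default marker panel for the synthetic genome
#'
#' 48 immune marker genes organised as 10 cell-type panels (6 adaptive:
#' B-cell, T-cell, CD8 T cell, Th, Treg, Tfh; 4 innate: NK, macrophage,
#' neutrophil, eosinophil) plus the checkpoint gene CD274, with adaptive /
#' innate / overall-immune composites and the two single-gene scores
#' (PD-L1 = CD274, CD8 = CD8A). The same gene universe is used by
#' [generate_cohort()], so scores computed on synthetic cohorts line up with
#' this panel by construction.
#'
#' @return `marker_panel` object whose overall-immune panel has 48 genes.
#' @export
default_marker_panel <- function() {
  cell <- list(
    `B-cell`     = paste0("BCELL_", 1:5),
    `T-cell`     = paste0("TCELL_", 1:5),
    `CD8 T cell` = c("CD8A", paste0("CD8T_", 1:3)),
    `Th`         = paste0("TH_", 1:4),
    `Treg`       = paste0("TREG_", 1:4),
    `Tfh`        = paste0("TFH_", 1:4),
    `NK`         = paste0("NK_", 1:5),
    `Macrophage` = paste0("MACRO_", 1:5),
    `Neutrophil` = paste0("NEUTRO_", 1:6),
    `Eosinophil` = paste0("EOSIN_", 1:5))
  adaptive <- unlist(cell[c("B-cell", "T-cell", "CD8 T cell", "Th",
                            "Treg", "Tfh")], use.names = FALSE)
  innate <- unlist(cell[c("NK", "Macrophage", "Neutrophil", "Eosinophil")],
                   use.names = FALSE)
  cell$adaptive <- adaptive
  cell$innate <- innate
  cell$`overall-immune` <- c(adaptive, innate, "CD274")
  marker_panel("synthetic-48", cell,
               single_genes = list(`PD-L1` = "CD274", CD8 = "CD8A"))
}

#' Paper-calibrated default configuration for the synthetic cohort generator
#'
#' Defaults emulate the CBCS analysis population: ER-negative fraction
#' 714/1942; ER-conditional prevalences of TP53 Mut-like (0.857 / 0.236) and
#' HRD-high (0.835 / 0.224); TP53-HRD dependence pinned for ER-negatives so
#' that P(AGI | ER-) = 0.926, and left at independence for ER-positives
#' (`p_neither = NA`); immune-class mixing within AGI from the AGI-stratum
#' class sizes (328/219/157 of 704); exponential recurrence with baseline
#' hazard 0.026/yr (adaptive-enriched AGI risk, 40/328 events over 5 years)
#' and class hazard ratios 1.79 (innate) and 1.65 (immune-quiet) applied only
#' within the AGI stratum; administrative censoring at 5 years.
#'
#' @param n_samples Cohort size (default 1942).
#' @param seed Integer seed stored in the config; same seed, same cohort.
#' @param ... Named overrides for any config field.
#' @return Object of class `synth_config`.
#' @export
default_config <- function(n_samples = 1942, seed = NULL, ...) {
  cfg <- list(
    n_samples = n_samples,
    p_er_negative = 714 / 1942,
    p_er_missing = 0.005,
    # P(TP53 Mut-like | ER), P(HRD-high | ER)
    p_tp53 = c(er_negative = 0.857, er_positive = 0.236),
    p_hrd = c(er_negative = 0.835, er_positive = 0.224),
    # P(neither signature | ER); NA = assume TP53/HRD independence
    p_neither = c(er_negative = 0.074, er_positive = NA),
    # P(immune class | AGI status); rows must sum to 1
    immune_mix = matrix(c(328, 219, 157, 0.233, 0.416, 0.351) /
                          c(704, 704, 704, 1, 1, 1),
                        nrow = 2, byrow = TRUE,
                        dimnames = list(c("AGI", "NGI"),
                                        c("Adaptive-Enriched",
                                          "Innate-Enriched",
                                          "Immune-Quiet"))),
    n_tp53_genes = 25,
    n_hrd_genes = 25,
    n_noise_genes = 402,
    baseline_expression = 8,
    centroid_shift = 1,
    noise_sd = 1,
    marker_elevation = 1,
    baseline_hazard = 0.026,
    weibull_shape = 1,
    hr_by_class = c(`Adaptive-Enriched` = 1, `Innate-Enriched` = 1.79,
                    `Immune-Quiet` = 1.65),
    censor_uniform_max = Inf,
    admin_censor = 5,
    stage_probs = c(I = 0.40, II = 0.38, III = 0.18, IV = 0.04),
    p_black = 0.52,
    age_mean = 50,
    age_sd = 11,
    # confounding knobs (off by default): make race predict both immune
    # class and hazard so crude and adjusted estimates diverge in tests
    confound_race_hr = 1,
    confound_race_adaptive_or = 1,
    seed = seed)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "synth_config")
}

validate_config <- function(cfg) {
  probs <- c(cfg$p_er_negative, cfg$p_er_missing, cfg$p_tp53, cfg$p_hrd,
             cfg$p_neither[!is.na(cfg$p_neither)], cfg$stage_probs,
             cfg$p_black)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(abs(rowSums(cfg$immune_mix) - 1) > 1e-9))
    stop("immune_mix rows must sum to 1 (tolerance 1e-9)")
  if (any(cfg$immune_mix < 0)) stop("immune_mix entries must be >= 0")
  if (abs(sum(cfg$stage_probs) - 1) > 1e-9)
    stop("stage_probs must sum to 1")
  if (any(cfg$hr_by_class <= 0)) stop("hazard ratios must be > 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$baseline_hazard <= 0 || cfg$weibull_shape <= 0)
    stop("baseline_hazard and weibull_shape must be > 0")
  for (er in names(cfg$p_tp53)) {
    jt <- .joint_instability(cfg$p_tp53[[er]], cfg$p_hrd[[er]],
                             cfg$p_neither[[er]])
    if (any(jt < -1e-12))
      stop(sprintf("p_neither[%s] incompatible with the TP53/HRD marginals",
                   er))
  }
  invisible(cfg)
}

# Joint law of (TP53 Mut-like, HRD-high) from the two marginals plus
# P(neither); p00 = NA means independence. Returns c(p11, p10, p01, p00).
.joint_instability <- function(p_t, p_h, p00 = NA) {
  if (is.na(p00)) p00 <- (1 - p_t) * (1 - p_h)
  p11 <- p_t + p_h + p00 - 1
  c(p11 = p11, p10 = p_t - p11, p01 = p_h - p11, p00 = p00)
}

# Signature gene universe and class profile patterns. Mut-like/WT-like (and
# HRD+/HRD-) centroids are opposite +/- shift patterns over their gene block,
# so rank correlation separates them cleanly.
.synthetic_genes <- function(cfg) {
  panel <- default_marker_panel()
  list(tp53 = paste0("TP53SIG_", seq_len(cfg$n_tp53_genes)),
       hrd = paste0("HRDSIG_", seq_len(cfg$n_hrd_genes)),
       immune = panel$cell_types$`overall-immune`,
       noise = paste0("NOISE_", sprintf("%03d", seq_len(cfg$n_noise_genes))),
       panel = panel)
}

.sig_pattern <- function(n) rep(c(1, -1), length.out = n)

# Per-immune-class additive elevation over the 48 marker genes.
.immune_profiles <- function(cfg, genes) {
  panel <- genes$panel
  adaptive <- panel$cell_types$adaptive
  innate <- panel$cell_types$innate
  prof <- matrix(0, nrow = 3, ncol = length(genes$immune),
                 dimnames = list(colnames(cfg$immune_mix), genes$immune))
  e <- cfg$marker_elevation
  prof["Adaptive-Enriched", adaptive] <- e
  prof["Adaptive-Enriched", innate] <- 0.3 * e
  prof["Adaptive-Enriched", "CD274"] <- 0.7 * e
  prof["Innate-Enriched", innate] <- e
  prof["Innate-Enriched", adaptive] <- 0.3 * e
  prof["Innate-Enriched", "CD274"] <- 0.4 * e
  prof
}

#' Generate a synthetic cohort
#'
#' Draws, per sample: ER status (Bernoulli, with a small masked-ER fraction);
#' latent TP53/HRD statuses from the ER-conditional joint law; AGI as their
#' OR; an immune class from the AGI-conditional mixing table; expression as
#' gene baseline + class-specific centroid shifts on the signature blocks +
#' immune-class marker elevation + Gaussian noise; and a recurrence time from
#' a Weibull (default exponential) proportional-hazards law whose class
#' hazard ratios act only within the AGI stratum, censored by an optional
#' uniform censoring time and administrative censoring.
#'
#' @param config `synth_config`, see [default_config()].
#' @return Object of class `synthetic_cohort`: list with `expression`
#'   (genes x samples matrix), `annotations` (data.frame), `truth`
#'   (data.frame of latent labels) and `config`.
#' @export
generate_cohort <- function(config = default_config()) {
  cfg <- validate_config(config)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  genes <- .synthetic_genes(cfg)

  er_neg <- stats::rbinom(n, 1, cfg$p_er_negative) == 1
  er_masked <- stats::rbinom(n, 1, cfg$p_er_missing) == 1

  tp53 <- character(n); hrd <- character(n)
  for (er in c(TRUE, FALSE)) {
    idx <- which(er_neg == er)
    key <- if (er) "er_negative" else "er_positive"
    jt <- pmax(.joint_instability(cfg$p_tp53[[key]], cfg$p_hrd[[key]],
                                  cfg$p_neither[[key]]), 0)
    cell <- sample(c("11", "10", "01", "00"), length(idx), replace = TRUE,
                   prob = jt)
    tp53[idx] <- ifelse(substr(cell, 1, 1) == "1", "Mut-like", "WT-like")
    hrd[idx] <- ifelse(substr(cell, 2, 2) == "1", "HRD+", "HRD-")
  }
  agi <- ifelse(tp53 == "Mut-like" | hrd == "HRD+", "AGI", "NGI")

  race <- ifelse(stats::rbinom(n, 1, cfg$p_black) == 1, "Black", "non-Black")
  age <- round(pmin(pmax(stats::rnorm(n, cfg$age_mean, cfg$age_sd), 20), 74))
  stage <- sample(names(cfg$stage_probs), n, replace = TRUE,
                  prob = cfg$stage_probs)

  classes <- colnames(cfg$immune_mix)
  immune <- character(n)
  for (i in seq_len(n)) {
    p <- cfg$immune_mix[agi[i], ]
    if (cfg$confound_race_adaptive_or != 1 && race[i] == "Black") {
      # tilt the adaptive-enriched odds for Black samples, renormalize
      odds <- p / (1 - p + 1e-12)
      odds["Adaptive-Enriched"] <-
        odds["Adaptive-Enriched"] * cfg$confound_race_adaptive_or
      p <- odds / (1 + odds)
      p <- p / sum(p)
    }
    immune[i] <- sample(classes, 1, prob = p)
  }

  all_genes <- c(genes$tp53, genes$hrd, genes$immune, genes$noise)
  expr <- matrix(cfg$baseline_expression, nrow = length(all_genes), ncol = n,
                 dimnames = list(all_genes, ids))
  pat_t <- .sig_pattern(cfg$n_tp53_genes) * cfg$centroid_shift
  pat_h <- .sig_pattern(cfg$n_hrd_genes) * cfg$centroid_shift
  expr[genes$tp53, ] <- expr[genes$tp53, ] +
    outer(pat_t, ifelse(tp53 == "Mut-like", 1, -1))
  expr[genes$hrd, ] <- expr[genes$hrd, ] +
    outer(pat_h, ifelse(hrd == "HRD+", 1, -1))
  prof <- .immune_profiles(cfg, genes)
  expr[genes$immune, ] <- expr[genes$immune, ] + t(prof[immune, , drop = FALSE])
  if (cfg$noise_sd > 0)
    expr <- expr + stats::rnorm(length(expr), 0, cfg$noise_sd)

  hr <- ifelse(agi == "AGI", cfg$hr_by_class[immune], 1)
  if (cfg$confound_race_hr != 1)
    hr <- hr * ifelse(race == "Black", cfg$confound_race_hr, 1)
  rate <- cfg$baseline_hazard * hr
  # Weibull PH: S(t) = exp(-rate * t^shape); shape 1 = exponential
  ev_time <- (stats::rexp(n, 1) / rate)^(1 / cfg$weibull_shape)
  cens <- if (is.finite(cfg$censor_uniform_max))
    stats::runif(n, 0, cfg$censor_uniform_max) else rep(Inf, n)
  cens <- pmin(cens, cfg$admin_censor)
  obs_time <- pmin(ev_time, cens)
  event <- as.integer(ev_time <= cens)

  annotations <- data.frame(
    sample_id = ids, age = age, race = race,
    er_status = ifelse(er_masked, NA_character_,
                       ifelse(er_neg, "negative", "positive")),
    stage = stage,
    recurrence_time = round(obs_time, 6),
    recurrence_event = event,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    sample_id = ids,
    er_true = ifelse(er_neg, "negative", "positive"),
    tp53 = tp53, hrd = hrd, agi = agi, immune_class = immune,
    stringsAsFactors = FALSE)
  structure(list(expression = expr, annotations = annotations, truth = truth,
                 config = cfg),
            class = "synthetic_cohort")
}

#' Noiseless class centroids implied by a generator configuration
#'
#' Returns, for one signature, the expected (noise-free) expression profile
#' of each class over that signature's gene block, packaged as a
#' [centroid_set()]. Useful for classifying synthetic cohorts without a
#' training split, and as the ground-truth classifier in tests.
#'
#' The TP53 and HRD sets default to the rank-based Spearman metric; the
#' immune-class set defaults to Euclidean distance because the Immune-Quiet
#' class is defined by uniformly low marker expression, a difference in level
#' that shift-invariant correlation metrics cannot see.
#'
#' @param config `synth_config`.
#' @param signature `"tp53"`, `"hrd"` or `"immune"`.
#' @param metric Similarity metric for the returned set; `NULL` picks the
#'   per-signature default above.
#' @return `centroid_set`.
#' @export
expected_centroids <- function(config, signature = c("tp53", "hrd", "immune"),
                               metric = NULL) {
  signature <- match.arg(signature)
  if (is.null(metric))
    metric <- if (signature == "immune") "euclidean" else "spearman"
  cfg <- validate_config(config)
  genes <- .synthetic_genes(cfg)
  b <- cfg$baseline_expression
  if (signature == "tp53") {
    pat <- .sig_pattern(cfg$n_tp53_genes) * cfg$centroid_shift
    centroid_set("TP53", c("Mut-like", "WT-like"), genes$tp53,
                 rbind(b + pat, b - pat), metric = metric)
  } else if (signature == "hrd") {
    pat <- .sig_pattern(cfg$n_hrd_genes) * cfg$centroid_shift
    centroid_set("HRD", c("HRD+", "HRD-"), genes$hrd,
                 rbind(b + pat, b - pat), metric = metric)
  } else {
    prof <- .immune_profiles(cfg, genes)
    centroid_set("immune_class", rownames(prof), genes$immune, b + prof,
                 metric = metric)
  }
}

#' Write a synthetic cohort to disk
#'
#' Writes `expression.tsv`, `annotations.csv` and `truth.csv` under `dir`.
#'
#' @param cohort `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             annotations = file.path(dir, "annotations.csv"),
             truth = file.path(dir, "truth.csv"))
  write_expression(cohort$expression, paths["expression"])
  write_annotations(cohort$annotations, paths["annotations"])
  utils::write.csv(cohort$truth, paths["truth"], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples x %d genes; AGI %d / NGI %d\n",
              ncol(x$expression), nrow(x$expression),
              sum(x$truth$agi == "AGI"), sum(x$truth$agi == "NGI")))
  invisible(x)
}
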