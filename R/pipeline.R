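#' Cross-tabulate two categorical variables with column percentages
#'
#' Counts of `row_var` within each level of `col_var`, with percentages over
#' an explicit per-call denominator policy: `"column"` divides by the full
#' column total including rows where `row_var` is missing (the convention for
#' a classifier applied to every sample), `"observed"` divides by the column
#' total of non-missing rows only (the convention when a classifier is
#' unavailable for part of the cohort). The two conventions coexist in
#' published cross-tabs, so the policy is an argument, never inferred.
#'
#' @param data data.frame.
#' @param row_var,col_var Column names of the two categorical variables.
#' @param denominator `"column"` or `"observed"`.
#' @return data.frame: `row` (including `"Missing"` when present), `col`,
#'   `n`, `pct`.
#' @export
cross_tabulate <- function(data, row_var, col_var,
                           denominator = c("column", "observed")) {
  denominator <- match.arg(denominator)
  if (!nrow(data)) stop("empty table")
  r <- as.character(data[[row_var]])
  c_ <- as.character(data[[col_var]])
  if (any(is.na(c_))) {
    r <- r[!is.na(c_)]; c_ <- c_[!is.na(c_)]
  }
  r[is.na(r)] <- "Missing"
  tab <- table(row = r, col = c_)
  denom <- if (denominator == "column") colSums(tab)
           else colSums(tab[rownames(tab) != "Missing", , drop = FALSE])
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  colnames(out) <- c("row", "col", "n")
  out$pct <- 100 * out$n / denom[out$col]
  out$pct[out$row == "Missing"] <- NA_real_
  out[order(out$col, out$row), , drop = FALSE]
}

#' Assemble a pipeline configuration
#'
#' Exactly one of `simulate` (a [default_config()] object) or `input` (named
#' list of file paths: `expression`, `annotations`) must be given. Centroids
#' may be file paths per signature, `"expected"` (noiseless generator
#' centroids; simulated input only) or `"train"` (trained on the cohort's
#' truth labels; simulated input only).
#'
#' @param simulate Optional `synth_config`.
#' @param input Optional list of input paths.
#' @param centroids `"expected"`, `"train"`, or named list of TSV paths with
#'   entries `tp53`, `hrd`, `immune`.
#' @param panel `marker_panel`, JSON path, or `NULL` for the default panel.
#' @param covariates Adjusters for the association models.
#' @param survival_adjust Adjusters for the adjusted Cox model.
#' @param out_dir Output directory.
#' @param seed Seed recorded into a simulated config lacking one.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, input = NULL,
                            centroids = "expected", panel = NULL,
                            covariates = c("age", "race"),
                            survival_adjust = c("age", "race", "stage",
                                                "er_status"),
                            out_dir = tempfile("gipipe_run_"), seed = NULL) {
  if (is.null(simulate) == is.null(input))
    stop("exactly one of 'simulate' or 'input' must be given")
  if (!is.null(input)) {
    need <- c("expression", "annotations")
    miss <- setdiff(need, names(input))
    if (length(miss)) stop("input lacks path(s): ", paste(miss, collapse = ", "))
    for (p in unlist(input)) if (!file.exists(p)) stop("missing file: ", p)
    if (!is.list(centroids))
      stop("file-based input requires centroid paths per signature")
  }
  if (!is.null(simulate) && !is.null(seed) && is.null(simulate$seed))
    simulate$seed <- seed
  structure(list(simulate = simulate, input = input, centroids = centroids,
                 panel = panel, covariates = covariates,
                 survival_adjust = survival_adjust, out_dir = out_dir,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full genomic-instability / immunogenicity pipeline
#'
#' Stages: acquire cohort (simulate or load) -> classify TP53, HRD and
#' immune class by nearest centroid -> compute immune scores, overall
#' immune expression and Q3 dichotomizations (PD-L1, CD8) -> AGI composite
#' -> ER-stratified cross-tabs -> RFDs of immune classes by instability
#' status -> differential immune scores -> AGI-stratified recurrence
#' analysis. All outputs are written as CSV under `config$out_dir`, plus a
#' JSON `manifest.json` recording stage order, exclusion counts and the
#' seed; the manifest is written even when a stage fails.
#'
#' @param config `pipeline_config`.
#' @return Invisibly, a list with `manifest` and the in-memory `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "gipipe",
                   version = as.character(utils::packageVersion("gipipe")),
                   seed = config$seed %||% config$simulate$seed,
                   stages = list(), outputs = character(),
                   exclusions = list(), status = "failed")
  finalize <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  on.exit(finalize())
  stage <- function(name) manifest$stages[[length(manifest$stages) + 1]] <<- name
  emit <- function(df, file) {
    path <- file.path(config$out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, file)
    path
  }
  results <- list()

  stage("acquire")
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate)
    expr <- cohort$expression
    ann <- cohort$annotations
    results$truth <- cohort$truth
  } else {
    expr <- read_expression(config$input$expression)
    ann <- read_annotations(config$input$annotations)
    cohort <- NULL
  }
  panel <- if (is.null(config$panel)) default_marker_panel()
           else if (inherits(config$panel, "marker_panel")) config$panel
           else read_panel(config$panel)

  stage("centroids")
  cents <- .resolve_centroids(config, cohort)

  stage("classify")
  tp53 <- call_signature(expr, cents$tp53)
  hrd <- call_signature(expr, cents$hrd)
  immune <- call_signature(expr, cents$immune)
  calls <- data.frame(sample_id = tp53$sample_id, tp53 = tp53$label,
                      hrd = hrd$label, immune_class = immune$label,
                      stringsAsFactors = FALSE)

  stage("score")
  scores <- compute_scores(expr, panel)
  scores[["overall-immune"]] <- unname(overall_immune(expr, panel))
  scores$pdl1_class <- as.character(dichotomize_q3(scores[["PD-L1"]]))
  scores$cd8_class <- as.character(dichotomize_q3(scores[["CD8"]]))
  results$scores <- scores
  emit(scores, "scores.csv")

  stage("agi")
  calls$agi <- as.character(call_agi(calls$tp53, calls$hrd))
  tab <- merge(merge(ann, calls, by = "sample_id"),
               scores[, c("sample_id", "PD-L1", "CD8", "overall-immune",
                          "pdl1_class", "cd8_class")],
               by = "sample_id")
  tab <- tab[match(ann$sample_id, tab$sample_id), , drop = FALSE]
  results$sample_table <- tab
  emit(tab, "sample_table.csv")
  er_missing <- sum(is.na(tab$er_status))
  manifest$exclusions$missing_er <- er_missing

  stage("cross_tabulate")
  xt <- list()
  for (v in c("tp53", "hrd", "agi", "immune_class", "pdl1_class",
              "cd8_class")) {
    denom <- if (v %in% c("hrd", "agi")) "observed" else "column"
    dat <- tab
    dat[[v]][dat[[v]] %in% c("missing", "indeterminate")] <- NA_character_
    xt[[v]] <- cbind(variable = v,
                     cross_tabulate(dat, v, "er_status", denominator = denom))
  }
  results$cross_tabs <- do.call(rbind, xt)
  emit(results$cross_tabs, "cross_tabs.csv")

  stage("associate")
  results$rfd <- .pipeline_rfds(tab, config$covariates)
  emit(results$rfd, "rfd.csv")
  results$differential <- .pipeline_differential(tab, scores,
                                                 config$covariates)
  emit(results$differential, "differential_scores.csv")

  stage("survive")
  rep <- recurrence_analysis(tab, adjust = config$survival_adjust)
  results$survival <- rep
  manifest$exclusions$recurrence <-
    as.list(table(rep$exclusions$reason))
  for (st in names(rep$strata)) {
    e <- rep$strata[[st]]
    if (!is.null(e$skipped)) next
    emit(e$km$curves, sprintf("km_%s.csv", st))
    if (inherits(e$cox_adjusted, "cox_fit")) {
      tab2 <- cbind(stratum = st, e$cox_adjusted$table)
      emit(tab2, sprintf("cox_%s.csv", st))
    }
  }

  manifest$status <- "ok"
  manifest$n_samples <- ncol(expr)
  results$manifest <- manifest
  invisible(list(manifest = manifest, results = results))
}

.resolve_centroids <- function(config, cohort) {
  cs <- config$centroids
  if (is.list(cs)) {
    return(list(tp53 = read_centroids(cs$tp53),
                hrd = read_centroids(cs$hrd),
                immune = read_centroids(cs$immune)))
  }
  if (is.null(cohort))
    stop("centroid mode '", cs, "' requires simulated input")
  if (identical(cs, "expected")) {
    list(tp53 = expected_centroids(cohort$config, "tp53"),
         hrd = expected_centroids(cohort$config, "hrd"),
         immune = expected_centroids(cohort$config, "immune"))
  } else if (identical(cs, "train")) {
    genes <- .synthetic_genes(cohort$config)
    lab <- function(x) stats::setNames(x, cohort$truth$sample_id)
    list(tp53 = train_centroids(cohort$expression[genes$tp53, ],
                                lab(cohort$truth$tp53), signature = "TP53"),
         hrd = train_centroids(cohort$expression[genes$hrd, ],
                               lab(cohort$truth$hrd), signature = "HRD"),
         immune = train_centroids(cohort$expression[genes$immune, ],
                                  lab(cohort$truth$immune_class),
                                  metric = "euclidean",
                                  signature = "immune_class"))
  } else stop("unknown centroid mode: ", cs)
}

# Fig-1-shaped RFDs: immune class membership (vs Immune-Quiet referent) as
# outcome, instability/PD-L1 status as exposure, per ER stratum.
.pipeline_rfds <- function(tab, covariates) {
  out <- list()
  exposures <- list(tp53 = c("WT-like", "Mut-like"),
                    hrd = c("HRD-", "HRD+"),
                    pdl1_class = c("Low", "High"))
  for (er in c("negative", "positive")) {
    sub <- tab[tab$er_status %in% er, , drop = FALSE]
    for (ex in names(exposures)) {
      lev <- exposures[[ex]]
      for (cls in c("Adaptive-Enriched", "Innate-Enriched")) {
        keep <- sub$immune_class %in% c(cls, "Immune-Quiet") &
          sub[[ex]] %in% lev
        d <- sub[keep, , drop = FALSE]
        if (nrow(d) < 8 || length(unique(d[[ex]])) < 2) next
        r <- estimate_rfd(as.integer(d$immune_class == cls),
                          factor(d[[ex]], levels = lev),
                          covariates = d[, covariates, drop = FALSE],
                          outcome_name = cls)
        out[[length(out) + 1]] <- cbind(er_status = er, exposure = ex, r)
      }
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

.pipeline_differential <- function(tab, scores, covariates) {
  cell_scores <- setdiff(colnames(scores),
                         c("sample_id", "pdl1_class", "cd8_class"))
  out <- list()
  for (ex in c("tp53", "hrd")) {
    lev <- if (ex == "tp53") c("WT-like", "Mut-like") else c("HRD-", "HRD+")
    keep <- tab[[ex]] %in% lev
    if (sum(keep) < 8) next
    d <- tab[keep, , drop = FALSE]
    sc <- scores[match(d$sample_id, scores$sample_id), , drop = FALSE]
    r <- differential_scores(sc, factor(d[[ex]], levels = lev),
                             covariates = d[, covariates, drop = FALSE],
                             scores = cell_scores)
    out[[length(out) + 1]] <- cbind(exposure = ex, r)
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}
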