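#' Compute immune cell scores from a marker panel
#'
#' Each cell-type score is the per-sample median expression of the panel's
#' genes; single-gene scores pass the gene's value through. Panel genes
#' absent from the matrix are dropped per score; a sample's score is missing
#' when fewer than `min_fraction` of the score's panel genes are observed. A
#' score whose panel has no gene in the matrix at all is an error.
#'
#' @param expr Expression matrix (genes x samples).
#' @param panel `marker_panel`.
#' @param min_fraction Minimum observed fraction of panel genes per sample
#'   (default 0.5).
#' @return data.frame: `sample_id` plus one column per score.
#' @export
compute_scores <- function(expr, panel, min_fraction = 0.5) {
  stopifnot(inherits(panel, "marker_panel"))
  out <- data.frame(sample_id = colnames(expr), stringsAsFactors = FALSE)
  for (nm in names(panel$cell_types)) {
    genes <- panel$cell_types[[nm]]
    present <- intersect(genes, rownames(expr))
    if (!length(present))
      stop(sprintf("no gene of score '%s' (panel '%s') is in the matrix",
                   nm, panel$name))
    block <- expr[present, , drop = FALSE]
    obs_frac <- colMeans(!is.na(block)) * length(present) / length(genes)
    med <- apply(block, 2, stats::median, na.rm = TRUE)
    med[obs_frac < min_fraction] <- NA_real_
    out[[nm]] <- unname(med)
  }
  for (nm in names(panel$single_genes)) {
    g <- panel$single_genes[[nm]]
    if (!g %in% rownames(expr))
      stop(sprintf("single-gene score '%s': gene %s not in the matrix (panel '%s')",
                   nm, g, panel$name))
    out[[nm]] <- unname(expr[g, ])
  }
  out
}

#' Overall immune expression
#'
#' Median expression of the overall-immune panel (48 genes in the default
#' panel) per sample.
#'
#' @param expr Expression matrix.
#' @param overall_panel Character vector of genes, or a `marker_panel` whose
#'   `overall-immune` entry is used.
#' @param min_fraction See [compute_scores()].
#' @return Named numeric vector, one value per sample.
#' @export
overall_immune <- function(expr, overall_panel, min_fraction = 0.5) {
  genes <- if (inherits(overall_panel, "marker_panel"))
    overall_panel$cell_types[["overall-immune"]] else as.character(overall_panel)
  if (!length(genes)) stop("overall-immune panel is empty")
  p <- marker_panel("overall", list(`overall-immune` = genes))
  s <- compute_scores(expr, p, min_fraction)
  stats::setNames(s[["overall-immune"]], s$sample_id)
}

#' Dichotomize a score at the cohort third quartile
#'
#' `High` iff the value strictly exceeds the cohort Q3; ties at Q3 are `Low`.
#' Q3 is the 0.75 quantile under the linear-interpolation convention
#' (`stats::quantile` type 7), computed over the non-missing values of the
#' analysis cohort, so the split depends only on the cohort's value multiset.
#'
#' @param values Numeric vector (>= 4 non-missing values required).
#' @return Factor with levels `Low`, `High`; `NA` where the input is missing.
#' @export
dichotomize_q3 <- function(values) {
  ok <- !is.na(values)
  if (!any(ok)) stop("all values missing")
  if (sum(ok) < 4) stop("need >= 4 non-missing values to place a quartile cut")
  q3 <- stats::quantile(values[ok], 0.75, type = 7, names = FALSE)
  factor(ifelse(values > q3, "High", "Low"), levels = c("Low", "High"))
}

#' Combine TP53 and HRD calls into the AGI composite
#'
#' Any genomic instability (AGI) = TP53 Mut-like OR HRD-high; NGI = neither
#' (both observed negative). OR-with-missingness semantics: one positive
#' disjunct suffices for AGI even if the other call is missing, but NGI
#' requires both calls observed; otherwise the sample is `indeterminate`.
#'
#' @param tp53 Character/factor vector over `{"Mut-like", "WT-like"}`,
#'   `"missing"`/`NA` allowed.
#' @param hrd Character/factor vector over `{"HRD+", "HRD-"}`,
#'   `"missing"`/`NA` allowed.
#' @return Factor with levels `AGI`, `NGI`, `indeterminate`.
#' @export
call_agi <- function(tp53, hrd) {
  tp53 <- as.character(tp53); hrd <- as.character(hrd)
  if (length(tp53) != length(hrd)) stop("tp53 and hrd must have equal length")
  tp53[tp53 %in% c("missing", "indeterminate")] <- NA_character_
  hrd[hrd %in% c("missing", "indeterminate")] <- NA_character_
  bad <- setdiff(unique(stats::na.omit(tp53)), c("Mut-like", "WT-like"))
  if (length(bad)) stop("unknown TP53 call(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(stats::na.omit(hrd)), c("HRD+", "HRD-"))
  if (length(bad)) stop("unknown HRD call(s): ", paste(bad, collapse = ", "))
  out <- ifelse(tp53 %in% "Mut-like" | hrd %in% "HRD+", "AGI",
         ifelse(tp53 %in% "WT-like" & hrd %in% "HRD-", "NGI",
                "indeterminate"))
  factor(out, levels = c("AGI", "NGI", "indeterminate"))
}
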