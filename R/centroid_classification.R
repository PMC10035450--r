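#' Train a nearest-centroid classifier
#'
#' Centroid values are per-class, per-gene means over the training samples.
#' When `genes_per_class` is finite, genes are first ranked by a per-gene
#' one-way ANOVA F statistic across classes and the top-ranked genes are
#' retained (with a single cross-class ranking the per-class top lists
#' coincide, so the union is the top of the ranking).
#'
#' @param expr Expression matrix (genes x samples), see [expression_matrix()].
#' @param labels Class label per sample: either named by sample id or in
#'   column order. Factor level order (or order of first appearance) defines
#'   the class order of the resulting set.
#' @param genes_per_class `"all"` or a positive integer.
#' @param metric Similarity metric stored in the set (default `"spearman"`).
#' @param signature Signature name stored in the set.
#' @return `centroid_set`.
#' @export
train_centroids <- function(expr, labels, genes_per_class = "all",
                            metric = "spearman", signature = "custom") {
  if (!is.null(names(labels))) {
    missing_samp <- setdiff(names(labels), colnames(expr))
    if (length(missing_samp))
      stop("labels reference unknown sample(s): ",
           paste(utils::head(missing_samp, 5), collapse = ", "))
    expr <- expr[, names(labels), drop = FALSE]
  } else if (length(labels) != ncol(expr)) {
    stop("need one label per sample")
  }
  f <- if (is.factor(labels)) droplevels(labels) else
    factor(labels, levels = unique(as.character(labels)))
  if (any(is.na(f))) stop("labels must not be missing")
  counts <- table(f)
  if (any(counts == 0))
    stop("class with zero samples: ", paste(names(counts)[counts == 0],
                                            collapse = ", "))

  cls <- levels(f)
  cent <- vapply(cls, function(k)
    rowMeans(expr[, f == k, drop = FALSE], na.rm = TRUE),
    numeric(nrow(expr)))
  cent <- t(cent)  # classes x genes

  genes <- rownames(expr)
  if (!identical(genes_per_class, "all")) {
    genes_per_class <- as.integer(genes_per_class)
    if (genes_per_class < 1) stop("genes_per_class must be >= 1")
    if (genes_per_class > nrow(expr)) {
      warning("genes_per_class exceeds available genes; clamping to ",
              nrow(expr))
      genes_per_class <- nrow(expr)
    }
    fstat <- .anova_f(expr, f)
    keep <- order(fstat, decreasing = TRUE)[seq_len(genes_per_class)]
    keep <- sort(keep)  # preserve input gene order
    genes <- genes[keep]
    cent <- cent[, keep, drop = FALSE]
  }
  centroid_set(signature, cls, genes, cent, metric = metric)
}

# Vectorized one-way ANOVA F across classes, per gene. Genes with zero
# within-class variance get +Inf (perfect separators) unless also zero
# between, in which case 0.
.anova_f <- function(expr, f) {
  n <- ncol(expr)
  k <- nlevels(f)
  grand <- rowMeans(expr, na.rm = TRUE)
  ssb <- rep(0, nrow(expr)); ssw <- rep(0, nrow(expr))
  for (lev in levels(f)) {
    block <- expr[, f == lev, drop = FALSE]
    m <- rowMeans(block, na.rm = TRUE)
    ssb <- ssb + ncol(block) * (m - grand)^2
    ssw <- ssw + rowSums((block - m)^2, na.rm = TRUE)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
}

#' Classify samples against a centroid set
#'
#' Similarity between each sample and each class centroid is computed on the
#' intersection of the sample's observed genes with the centroid genes, using
#' the set's metric: Spearman or Pearson correlation (label = argmax), or
#' Euclidean distance (reported as negative root-mean-square distance so that
#' argmax still selects the nearest class). Samples with fewer than
#' `min_gene_fraction` of the centroid genes observed are labelled
#' `"missing"` with no similarities reported. Exact similarity ties go to the
#' first tied class in the set's declared class order, with `tie_flag` set.
#'
#' @param expr Expression matrix (genes x samples).
#' @param centroids `centroid_set`.
#' @param min_gene_fraction Minimum observed fraction of centroid genes
#'   required to call a sample (default 0.5).
#' @return data.frame with one row per sample: `sample_id`, `label`,
#'   `tie_flag`, `n_genes_used`, and one `sim.<class>` column per class.
#' @export
classify_samples <- function(expr, centroids, min_gene_fraction = 0.5) {
  common <- intersect(rownames(expr), centroids$genes)
  if (!length(common))
    stop(sprintf(
      "no overlap between expression genes (%d: %s, ...) and centroid genes (%d: %s, ...)",
      nrow(expr), paste(utils::head(rownames(expr), 3), collapse = ", "),
      length(centroids$genes),
      paste(utils::head(centroids$genes, 3), collapse = ", ")))
  cls <- centroids$classes
  cent <- centroids$centroids[, common, drop = FALSE]
  sub <- expr[common, , drop = FALSE]
  n_cgenes <- length(centroids$genes)

  res <- data.frame(sample_id = colnames(expr),
                    label = NA_character_,
                    tie_flag = FALSE,
                    n_genes_used = 0L,
                    stringsAsFactors = FALSE)
  sims <- matrix(NA_real_, nrow = ncol(expr), ncol = length(cls),
                 dimnames = list(colnames(expr), cls))
  for (j in seq_len(ncol(sub))) {
    x <- sub[, j]
    obs <- !is.na(x)
    res$n_genes_used[j] <- sum(obs)
    if (sum(obs) / n_cgenes < min_gene_fraction || sum(obs) < 2) {
      res$label[j] <- "missing"
      next
    }
    s <- vapply(cls, function(k)
      .similarity(x[obs], cent[k, obs], centroids$metric), numeric(1))
    if (all(is.na(s))) {
      res$label[j] <- "indeterminate"
      next
    }
    sims[j, ] <- s
    top <- which(s == max(s, na.rm = TRUE))
    res$label[j] <- cls[top[1]]
    res$tie_flag[j] <- length(top) > 1
  }
  colnames(sims) <- paste0("sim.", cls)
  cbind(res, as.data.frame(sims, optional = TRUE))
}

.similarity <- function(x, cent, metric) {
  switch(metric,
    spearman = {
      if (stats::sd(x) == 0 || stats::sd(cent) == 0) return(NA_real_)
      stats::cor(x, cent, method = "spearman")
    },
    pearson = {
      if (stats::sd(x) == 0 || stats::sd(cent) == 0) return(NA_real_)
      stats::cor(x, cent, method = "pearson")
    },
    euclidean = -sqrt(mean((x - cent)^2)))
}

#' Apply a centroid classifier with an output vocabulary
#'
#' Binds a centroid set to the vocabulary its calls should be reported in
#' (e.g. TP53 centroids to Mut-like/WT-like, HRD centroids to HRD+/HRD-,
#' immune centroids to the three global immune classes) and classifies.
#' `"missing"` and `"indeterminate"` pass through unmapped.
#'
#' @param expr Expression matrix.
#' @param centroids `centroid_set`.
#' @param vocabulary Named character vector mapping each centroid class to an
#'   output label; must cover every class exactly once. `NULL` keeps the
#'   centroid class labels.
#' @param min_gene_fraction See [classify_samples()].
#' @return As [classify_samples()], with `label` in the output vocabulary.
#' @export
call_signature <- function(expr, centroids, vocabulary = NULL,
                           min_gene_fraction = 0.5) {
  if (!is.null(vocabulary)) {
    if (length(vocabulary) != length(centroids$classes) ||
        !setequal(names(vocabulary), centroids$classes))
      stop(sprintf(
        "vocabulary must map each of the %d centroid classes (%s) exactly once",
        length(centroids$classes),
        paste(centroids$classes, collapse = ", ")))
  }
  out <- classify_samples(expr, centroids, min_gene_fraction)
  if (!is.null(vocabulary)) {
    mapped <- out$label %in% names(vocabulary)
    out$label[mapped] <- unname(vocabulary[out$label[mapped]])
  }
  out
}
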