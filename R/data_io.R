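#' Construct and validate a gene-by-sample expression matrix
#'
#' Expression data are held as a plain numeric matrix with genes in rows
#' (rownames = gene identifiers) and samples in columns (colnames = sample
#' identifiers), holding already-normalized log-scale values. The constructor
#' enforces the container invariants: unique identifiers, numeric values with
#' missingness allowed, and a per-gene missingness ceiling. Genes whose
#' missing fraction exceeds `max_missing` are excluded with a logged reason
#' (attribute `"exclusions"`), never silently.
#'
#' @param values Numeric matrix, genes x samples.
#' @param gene_ids,sample_ids Identifier vectors; default to the dimnames of
#'   `values`.
#' @param max_missing Maximum tolerated fraction of missing values per gene
#'   before the gene is excluded at load (default 0.5).
#' @return A numeric matrix with validated dimnames and, when genes were
#'   excluded, an `"exclusions"` attribute (data.frame of gene_id, reason).
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              max_missing = 0.5) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  .check_unique(gene_ids, "gene")
  .check_unique(sample_ids, "sample")
  if (!is.numeric(values))
    stop("expression values must be numeric")
  values[!is.finite(values)] <- NA_real_
  dimnames(values) <- list(gene_ids, sample_ids)

  miss_frac <- rowMeans(is.na(values))
  drop <- miss_frac > max_missing
  exclusions <- data.frame(gene_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  if (any(drop)) {
    exclusions <- data.frame(
      gene_id = gene_ids[drop],
      reason = sprintf("missing fraction %.2f exceeds %.2f",
                       miss_frac[drop], max_missing),
      stringsAsFactors = FALSE)
    message(sum(drop), " gene(s) excluded for excess missingness: ",
            paste(utils::head(gene_ids[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ..." else "")
    values <- values[!drop, , drop = FALSE]
  }
  attr(values, "exclusions") <- exclusions
  values
}

.check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate %s identifier(s): %s", what,
                 paste(utils::head(dup, 5), collapse = ", ")))
  invisible(TRUE)
}

#' Read an expression matrix from TSV
#'
#' Expects genes in rows and samples in columns: a header row of sample
#' identifiers and a first column of gene identifiers. Cells equal to one of
#' `missing_codes` are recorded as missing; any other non-numeric cell is a
#' parse error reported with its row/column coordinates.
#'
#' @param path Path to a tab-separated file.
#' @param missing_codes Strings interpreted as missing (default `""`, `"NA"`).
#' @param max_missing Per-gene missingness ceiling, see [expression_matrix()].
#' @return Validated expression matrix.
#' @export
read_expression <- function(path, missing_codes = c("", "NA"),
                            max_missing = 0.5) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression TSV needs a gene column plus >=1 sample")
  gene_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[cells %in% missing_codes] <- NA_character_
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(values) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad)) {
    hint <- .transpose_hint(length(gene_ids), length(sample_ids))
    stop(sprintf("non-numeric cell '%s' at gene row %d (%s), sample column %s%s",
                 cells[bad[1, 1], bad[1, 2]], bad[1, 1], gene_ids[bad[1, 1]],
                 sample_ids[bad[1, 2]], hint))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  tryCatch(
    expression_matrix(values, max_missing = max_missing),
    error = function(e) stop(conditionMessage(e),
                             .transpose_hint(length(gene_ids),
                                             length(sample_ids)),
                             call. = FALSE))
}

# Heuristic used only to sharpen error messages: signature panels have many
# more genes than a typical header row has samples, so a very wide matrix
# suggests a transposed file. Never used to silently flip the data.
.transpose_hint <- function(n_genes, n_samples) {
  if (n_samples > 20 * max(n_genes, 1))
    " (matrix is much wider than tall; is the file transposed? genes must be rows)"
  else ""
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]; `read_expression(write_expression(x))`
#' reproduces `x`.
#'
#' @param x Expression matrix (genes x samples).
#' @param path Output path.
#' @param gene_column Name of the first (gene identifier) column.
#' @export
write_expression <- function(x, path, gene_column = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- gene_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default categorical vocabularies for sample annotations
#'
#' Declared here rather than hard-coded in the reader so cohorts with other
#' race categories (or additional stages) can be loaded by passing a modified
#' vocabulary.
#'
#' @return Named list of allowed levels for `race`, `er_status` and `stage`.
#' @export
annotation_vocab <- function() {
  list(race = c("Black", "non-Black"),
       er_status = c("positive", "negative"),
       stage = c("I", "II", "III", "IV"))
}

#' Read per-sample clinical annotations from CSV
#'
#' Expected columns: `sample_id`, `age` (years), `race`, `er_status`,
#' `stage`, `recurrence_time` (years from diagnosis), `recurrence_event`
#' (1 = recurrence, 0 = censored). Empty strings and `NA` are missing.
#' Categorical values are validated against `vocab`; an unknown level is an
#' error listing the allowed levels. Missing ER status is retained at load
#' (exclusion from ER-stratified analyses happens downstream), as is stage IV
#' (excluded only by the recurrence analysis).
#'
#' @param path CSV path.
#' @param vocab Vocabulary list, see [annotation_vocab()].
#' @return data.frame of annotations, one row per sample.
#' @export
read_annotations <- function(path, vocab = annotation_vocab()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- c("sample_id", "age", "race", "er_status", "stage",
            "recurrence_time", "recurrence_event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("annotation file lacks column(s): ",
                         paste(miss, collapse = ", "))
  .check_unique(df$sample_id, "sample")
  for (col in c("race", "er_status", "stage")) {
    bad <- setdiff(unique(stats::na.omit(df[[col]])), vocab[[col]])
    if (length(bad))
      stop(sprintf("unknown %s level(s) %s; allowed: %s", col,
                   paste(bad, collapse = ", "),
                   paste(vocab[[col]], collapse = ", ")))
  }
  if (any(df$recurrence_time < 0, na.rm = TRUE))
    stop("recurrence_time must be >= 0")
  if (any(!df$recurrence_event %in% c(0, 1, NA)))
    stop("recurrence_event must be 0/1")
  if (any(df$recurrence_event %in% 1 & is.na(df$recurrence_time)))
    stop("a recurrence event requires a recurrence time")
  df
}

#' Write sample annotations to CSV
#' @param annotations data.frame as returned by [read_annotations()].
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Construct a marker panel
#'
#' A marker panel maps immune score names to gene lists (scores are per-sample
#' medians over the listed genes) plus optional single-gene scores whose value
#' is the gene's expression itself (e.g. PD-L1 = CD274, CD8 = CD8A).
#'
#' @param name Panel name.
#' @param cell_types Named list: score name -> non-empty character vector of
#'   gene identifiers.
#' @param single_genes Named list or character vector: score name -> one gene.
#' @return Object of class `marker_panel`.
#' @export
marker_panel <- function(name, cell_types, single_genes = list()) {
  if (!length(cell_types) || is.null(names(cell_types)))
    stop("cell_types must be a named list of gene vectors")
  for (nm in names(cell_types)) {
    g <- cell_types[[nm]]
    if (!length(g) || !all(nzchar(g)))
      stop(sprintf("gene list for score '%s' is empty", nm))
  }
  single_genes <- as.list(single_genes)
  for (nm in names(single_genes))
    if (length(single_genes[[nm]]) != 1 || !nzchar(single_genes[[nm]]))
      stop(sprintf("single-gene score '%s' must name exactly one gene", nm))
  structure(list(name = name,
                 cell_types = lapply(cell_types, as.character),
                 single_genes = lapply(single_genes, as.character)),
            class = "marker_panel")
}

#' Read a marker panel from JSON
#' @param path JSON file with fields `name`, `cell_types`, `single_genes`.
#' @return `marker_panel` object.
#' @export
read_panel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  marker_panel(x$name, as.list(x$cell_types),
               as.list(x$single_genes %||% list()))
}

#' Write a marker panel to JSON
#' @param panel `marker_panel` object.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(unclass(panel), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a centroid set
#'
#' A centroid set is the trained state of a nearest-centroid classifier:
#' ordered class labels (the order is part of the object identity and defines
#' tie-breaking), a gene universe, a classes-by-genes matrix of centroid
#' values, and the similarity metric the classifier uses.
#'
#' @param signature Signature name (e.g. "TP53", "HRD", "immune_class").
#' @param classes Ordered character vector of class labels (>= 2).
#' @param genes Character vector of gene identifiers.
#' @param centroids Numeric matrix, classes x genes.
#' @param metric One of `"spearman"`, `"pearson"`, `"euclidean"`.
#' @return Object of class `centroid_set`.
#' @export
centroid_set <- function(signature, classes, genes, centroids,
                         metric = c("spearman", "pearson", "euclidean")) {
  metric <- match.arg(metric)
  classes <- as.character(classes)
  genes <- as.character(genes)
  if (length(classes) < 2) stop("a centroid set needs >= 2 classes")
  .check_unique(classes, "class")
  .check_unique(genes, "gene")
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != length(classes) || ncol(centroids) != length(genes))
    stop("centroid matrix must be classes x genes")
  dimnames(centroids) <- list(classes, genes)
  structure(list(signature = signature, classes = classes, genes = genes,
                 centroids = centroids, metric = metric),
            class = "centroid_set")
}

#' Read a centroid set from TSV
#'
#' Format: comment header lines `#signature=<name>` and `#metric=<metric>`,
#' then a tab-separated table with genes in rows and one column per class.
#' Column order defines class order and round-trips through
#' [write_centroids()].
#'
#' @param path TSV path.
#' @return `centroid_set` object.
#' @export
read_centroids <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (!length(m)) stop(sprintf("centroid file lacks '#%s=' header", key))
    sub(paste0("^#", key, "="), "", m[1])
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  centroid_set(signature = get_field("signature"),
               classes = colnames(tab)[-1],
               genes = tab[[1]],
               centroids = t(as.matrix(tab[, -1, drop = FALSE])),
               metric = get_field("metric"))
}

#' Write a centroid set to TSV
#' @param cs `centroid_set` object.
#' @param path Output path.
#' @export
write_centroids <- function(cs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#signature=%s", cs$signature),
               sprintf("#metric=%s", cs$metric)), con)
  df <- data.frame(gene_id = cs$genes, t(cs$centroids), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("centroid_set '%s': %d classes (%s), %d genes, metric %s\n",
              x$signature, length(x$classes),
              paste(x$classes, collapse = ", "), length(x$genes), x$metric))
  invisible(x)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel '%s': %d cell-type scores, %d single-gene scores\n",
              x$name, length(x$cell_types), length(x$single_genes)))
  invisible(x)
}
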