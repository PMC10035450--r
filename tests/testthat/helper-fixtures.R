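# Small fixtures built in code, shared across test files.

tiny_expr <- function() {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  expression_matrix(m)
}

# brute-force spearman: pearson correlation of hand-computed ranks,
# independent of stats::cor(method = "spearman")
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# a well-separated two-class matrix with labelled samples
two_class_expr <- function(n_per = 5, n_genes = 10, shift = 3, sd = 0.2,
                           seed = 42) {
  set.seed(seed)
  pat <- rep(c(1, -1), length.out = n_genes)
  a <- matrix(8 + pat * shift, n_genes, n_per) + rnorm(n_genes * n_per, 0, sd)
  b <- matrix(8 - pat * shift, n_genes, n_per) + rnorm(n_genes * n_per, 0, sd)
  m <- cbind(a, b)
  dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                      paste0("s", seq_len(2 * n_per)))
  list(expr = expression_matrix(m),
       labels = setNames(rep(c("A", "B"), each = n_per), colnames(m)))
}
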