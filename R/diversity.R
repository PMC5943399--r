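# Alpha (inverse Simpson), beta (Bray-Curtis) and gamma (group richness)
# diversity on abundance tables.

#' Inverse Simpson index
#'
#' `1 / sum(p_i^2)` over relative abundances. Counts are accepted and
#' normalised internally, so the index is scale-free.
#'
#' @param p non-negative abundance vector with at least one positive entry
#' @return the index (>= 1; equals the number of taxa for a uniform
#'   community)
#' @export
inverse_simpson <- function(p) {
  if (any(p < 0) || any(!is.finite(p))) stopf("abundances must be finite and non-negative")
  tot <- sum(p)
  if (tot <= 0) stopf("diversity undefined for an all-zero abundance vector")
  p <- p / tot
  1 / sum(p^2)
}

#' Bray-Curtis dissimilarity
#'
#' `sum(|x_i - y_i|) / sum(x_i + y_i)`, in [0, 1]; 0 for identical
#' compositions, 1 for disjoint supports.
#'
#' @param x,y non-negative abundance vectors on the same taxon axis
#' @return dissimilarity in [0, 1]
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must share one taxon axis")
  if (any(x < 0) || any(y < 0)) stopf("abundances must be non-negative")
  denom <- sum(x + y)
  if (denom == 0) stopf("Bray-Curtis undefined when both vectors are all-zero")
  sum(abs(x - y)) / denom
}

new_dist_matrix <- function(m, metric) {
  stopifnot(isSymmetric(unname(m)))
  structure(list(matrix = m, ids = rownames(m), metric = metric),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d samples, metric = %s\n",
              nrow(x$matrix), x$metric))
  invisible(x)
}

#' Pairwise Bray-Curtis distance matrix
#'
#' Computed on relative abundances, so post-subsampling depth differences
#' do not leak into beta diversity.
#'
#' @param table an [abundance_table()] with >= 2 samples
#' @return an object of class `dist_matrix` (symmetric, zero diagonal)
#' @export
beta_matrix <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  rel <- table$rel
  n <- nrow(rel)
  if (n < 2) stopf("need >= 2 samples")
  m <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  for (i in seq_len(n - 1)) {
    xi <- rel[i, ]
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- bray_curtis(xi, rel[j, ])
    }
  }
  new_dist_matrix(m, "bray_curtis")
}

#' Gamma diversity (per-group richness)
#'
#' Number of taxa with positive abundance in at least one sample of each
#' group.
#'
#' @param table an [abundance_table()]
#' @param groups group label per sample (aligned with the table's rows)
#' @return named integer vector of per-group taxon counts
#' @export
gamma_richness <- function(table, groups) {
  stopifnot(inherits(table, "abundance_table"))
  m <- table$counts %||% table$rel
  if (length(groups) != nrow(m)) stopf("one group label per sample required")
  if (anyNA(groups)) stopf("sample(s) without group label")
  vapply(split(seq_len(nrow(m)), groups), function(idx)
    sum(colSums(m[idx, , drop = FALSE] > 0) > 0), integer(1))
}

#' Alpha diversity of every sample in a table
#'
#' Inverse Simpson on relative abundances over assigned reads; samples
#' with fewer than `min_assigned` assigned reads are flagged
#' low-confidence (attribute `low_confidence`) but not excluded.
#'
#' @param table an [abundance_table()]
#' @param min_assigned low-confidence flag threshold (default 10)
#' @return named numeric vector of per-sample alpha values
#' @export
alpha_diversity <- function(table, min_assigned = 10) {
  stopifnot(inherits(table, "abundance_table"))
  a <- apply(table$rel, 1, inverse_simpson)
  if (!is.null(table$assigned))
    attr(a, "low_confidence") <- names(a)[table$assigned < min_assigned]
  a
}

#' Write diversity results as tab-separated text
#'
#' @param alpha named alpha vector
#' @param path output path
#' @return the path, invisibly
#' @export
write_alpha <- function(alpha, path) {
  write_tsv(data.frame(sample = names(alpha), alpha = as.numeric(alpha)), path)
}

#' @rdname write_alpha
#' @param d a `dist_matrix`
#' @export
write_dist_matrix <- function(d, path) {
  df <- data.frame(sample = d$ids, d$matrix, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_alpha
#' @param metric metric tag to attach
#' @export
read_dist_matrix <- function(path, metric = "bray_curtis") {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  new_dist_matrix(m, metric)
}

#' @rdname write_alpha
#' @param gamma named per-group richness
#' @export
write_gamma <- function(gamma, path) {
  write_tsv(data.frame(group = names(gamma), gamma = as.integer(gamma)), path)
}
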