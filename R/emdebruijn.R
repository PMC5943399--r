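# Reference-free sample dissimilarity: earth mover's distance between
# per-sample k-mer mass distributions with a de Bruijn-graph ground
# metric, plus principal-coordinate ordination of the resulting matrix.

#' K-mer mass distribution of a read set
#'
#' Counts every length-k window containing only A/C/G/T (windows touching
#' other characters are skipped) and normalises to total mass 1.
#'
#' @param reads read-set data.frame or character vector of sequences
#' @param k k-mer size (2-13; default 6)
#' @param canonical merge reverse complements (default FALSE: stranded
#'   RNA-seq)
#' @return an object of class `kmer_distribution`: list with `k`, `mass`
#'   (named, sums to 1), `canonical`
#' @export
kmer_distribution <- function(reads, k = 6, canonical = FALSE) {
  k <- check_count(k, "k", min = 2)
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  if (length(seqs) == 0) stopf("no reads")
  ct <- kmer_count_cpp(seqs, k, canonical)
  if (ct$total == 0)
    stopf("no valid length-%d window in any read (empty distribution)", k)
  mass <- sort(ct$counts / ct$total, decreasing = TRUE)
  structure(list(k = k, mass = mass, canonical = canonical),
            class = "kmer_distribution")
}

#' @export
print.kmer_distribution <- function(x, ...) {
  cat(sprintf("<kmer_distribution> k = %d, support %d\n", x$k, length(x$mass)))
  invisible(x)
}

#' Ground distance between two k-mers on the de Bruijn graph
#'
#' Shortest-path hop count in the undirected order-k de Bruijn graph over
#' \{A,C,G,T\} (edges join a word to its single-shift successors in either
#' direction). On the complete graph the distance is at most k; in
#' `observed` mode the graph is restricted to a supplied node set and
#' unreachable pairs score k + 1.
#'
#' @param u,v k-mers of equal length
#' @param k k-mer size (defaults to `nchar(u)`)
#' @return non-negative integer distance
#' @export
ground_distance <- function(u, v, k = nchar(u)) {
  if (nchar(u) != nchar(v)) stopf("k-mer length mismatch")
  as.integer(debruijn_dist_cpp(u, v, as.integer(k), TRUE, character(0))[1, 1])
}

# cost matrix between two k-mer support sets
ground_cost_matrix <- function(sup_a, sup_b, k,
                               mode = c("complete", "observed"),
                               observed = NULL) {
  mode <- match.arg(mode)
  debruijn_dist_cpp(sup_a, sup_b, as.integer(k), mode == "complete",
                    observed %||% character(0))
}

# deterministic orientation so emd(a, b) is bitwise equal to emd(b, a)
emd_orient <- function(a, b) {
  ka <- paste(c(names(a$mass), format(a$mass, digits = 17)), collapse = ",")
  kb <- paste(c(names(b$mass), format(b$mass, digits = 17)), collapse = ",")
  if (ka <= kb) list(a, b) else list(b, a)
}

#' Earth mover's distance between two k-mer distributions
#'
#' Optimal transportation cost with the de Bruijn ground metric, solved to
#' optimality by successive shortest paths on the joint support. Mass
#' shared between the two distributions is cancelled first (valid because
#' the ground cost is a metric with zero diagonal).
#'
#' @param a,b [kmer_distribution()]s with equal k
#' @param mode ground metric mode: `"complete"` (full de Bruijn graph) or
#'   `"observed"` (graph restricted to the joint support; unreachable
#'   pairs cost k + 1)
#' @return non-negative real distance
#' @export
emd <- function(a, b, mode = c("complete", "observed")) {
  stopifnot(inherits(a, "kmer_distribution"), inherits(b, "kmer_distribution"))
  if (a$k != b$k) stopf("k mismatch: %d vs %d", a$k, b$k)
  mode <- match.arg(mode)
  o <- emd_orient(a, b)
  support <- sort(unique(c(names(o[[1]]$mass), names(o[[2]]$mass))))
  x <- setNames(numeric(length(support)), support)
  y <- x
  x[names(o[[1]]$mass)] <- o[[1]]$mass
  y[names(o[[2]]$mass)] <- o[[2]]$mass
  shared <- pmin(x, y)
  x <- x - shared
  y <- y - shared
  ix <- which(x > 0)
  iy <- which(y > 0)
  if (length(ix) == 0 || length(iy) == 0) return(0)
  cost <- ground_cost_matrix(support[ix], support[iy], a$k, mode,
                             observed = support)
  emd_ssp_cpp(x[ix], y[iy], cost)
}

#' Pairwise EMD distance matrix
#'
#' Ground distances over the joint support are computed once and reused
#' for every pair.
#'
#' @param samples named list of [kmer_distribution()]s with equal k
#' @param mode see [emd()]
#' @return a `dist_matrix` with metric tag `"emdebruijn"`
#' @export
pairwise_emd <- function(samples, mode = c("complete", "observed")) {
  mode <- match.arg(mode)
  ks <- vapply(samples, `[[`, numeric(1), "k")
  if (length(unique(ks)) != 1) stopf("all samples must share one k")
  k <- ks[[1]]
  ids <- names(samples) %||% sprintf("s%03d", seq_along(samples))
  support <- sort(unique(unlist(lapply(samples, function(s) names(s$mass)))))
  cost_all <- ground_cost_matrix(support, support, k, mode, observed = support)
  dimnames(cost_all) <- list(support, support)
  n <- length(samples)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      o <- emd_orient(samples[[i]], samples[[j]])
      x <- setNames(numeric(length(support)), support)
      y <- x
      x[names(o[[1]]$mass)] <- o[[1]]$mass
      y[names(o[[2]]$mass)] <- o[[2]]$mass
      shared <- pmin(x, y)
      x <- x - shared
      y <- y - shared
      ix <- which(x > 0); iy <- which(y > 0)
      d <- if (length(ix) == 0 || length(iy) == 0) 0
           else emd_ssp_cpp(x[ix], y[iy],
                            cost_all[ix, iy, drop = FALSE])
      m[i, j] <- m[j, i] <- d
    }
  }
  new_dist_matrix(m, "emdebruijn")
}

#' Principal-coordinate ordination of a distance matrix
#'
#' Classical multidimensional scaling of the double-centred squared
#' distances; axes are ordered by eigenvalue, with the sign convention
#' that each axis's first non-zero loading is positive. If fewer than
#' `n_axes` positive-eigenvalue axes exist the result is truncated with a
#' warning.
#'
#' @param d a `dist_matrix`
#' @param n_axes number of axes requested (>= 1)
#' @return matrix of per-sample coordinates (samples x axes), with
#'   attribute `eig` carrying the eigenvalues
#' @export
ordinate <- function(d, n_axes = 3) {
  stopifnot(inherits(d, "dist_matrix"))
  n_axes <- check_count(n_axes, "n_axes")
  n <- nrow(d$matrix)
  if (all(d$matrix == 0)) {
    out <- matrix(0, n, n_axes, dimnames = list(d$ids, paste0("PC", seq_len(n_axes))))
    attr(out, "eig") <- rep(0, n_axes)
    return(out)
  }
  fit <- cmdscale(as.dist(d$matrix), k = min(n_axes, n - 1), eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < n_axes) {
    warning(sprintf("only %d axes available (requested %d)", ncol(pts), n_axes))
  }
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) && pts[nz[1], j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("PC", seq_len(ncol(pts)))
  rownames(pts) <- d$ids
  attr(pts, "eig") <- fit$eig
  pts
}

#' Spearman rank correlation between ordinations or distance matrices
#'
#' With coordinate matrices, correlates axis pairs; with two distance
#' matrices, correlates their vectorised upper triangles.
#'
#' @param a,b coordinate matrices (samples x axes) or `dist_matrix`
#'   objects over the same samples
#' @return data.frame with `axis` (or `"upper_triangle"`), `rho`, `p`
#' @export
correlate_ordinations <- function(a, b) {
  if (inherits(a, "dist_matrix") && inherits(b, "dist_matrix")) {
    if (!identical(dim(a$matrix), dim(b$matrix)))
      stopf("distance matrices must share the sample set")
    ut <- upper.tri(a$matrix)
    ct <- suppressWarnings(
      cor.test(a$matrix[ut], b$matrix[ut], method = "spearman", exact = FALSE))
    return(data.frame(axis = "upper_triangle",
                      rho = unname(ct$estimate), p = ct$p.value))
  }
  if (nrow(a) != nrow(b)) stopf("coordinate matrices must share the sample set")
  n_ax <- min(ncol(a), ncol(b))
  out <- lapply(seq_len(n_ax), function(j) {
    ct <- suppressWarnings(
      cor.test(a[, j], b[, j], method = "spearman", exact = FALSE))
    data.frame(axis = sprintf("PC%d", j), rho = unname(ct$estimate),
               p = ct$p.value)
  })
  do.call(rbind, out)
}
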