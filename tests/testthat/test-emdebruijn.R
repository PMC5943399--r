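test_that("kmer_distribution counts valid windows and normalises", {
  d <- kmer_distribution("ACGTA", k = 4)
  expect_equal(sort(names(d$mass)), c("ACGT", "CGTA"))
  expect_equal(unname(d$mass[c("ACGT", "CGTA")]), c(0.5, 0.5))
  expect_error(kmer_distribution("ACGNA", k = 4), "no valid")
  set.seed(1)
  d2 <- kmer_distribution(random_dna_strings(10, 50), k = 6)
  expect_equal(sum(d2$mass), 1, tolerance = 1e-12)
  # canonical merging folds reverse complements
  dc <- kmer_distribution(c("ACGT", "ACGT"), k = 4, canonical = TRUE)
  dr <- kmer_distribution(c("ACGT", "TACG"), k = 4, canonical = FALSE)
  expect_equal(length(dc$mass), 1)
  expect_equal(length(dr$mass), 2)
})

test_that("ground distance matches an exhaustive BFS on the full 4-mer graph", {
  expect_equal(ground_distance("ACGT", "ACGT"), 0)
  expect_equal(ground_distance("ACGT", "CGTA"), 1)
  expect_lte(ground_distance("AAAA", "TTTT"), 4)
  expect_error(ground_distance("ACG", "ACGT"), "mismatch")
  # independent oracle: build the order-4 de Bruijn graph in igraph and
  # compare shortest paths for a sample of pairs
  skip_if_not_installed("igraph")
  bases <- c("A", "C", "G", "T")
  all4 <- apply(expand.grid(bases, bases, bases, bases), 1, paste,
                collapse = "")
  edges <- character(0)
  for (w in all4) for (b in bases) {
    edges <- c(edges, w, paste0(substr(w, 2, 4), b))
  }
  g <- igraph::simplify(igraph::graph_from_edgelist(
    matrix(edges, ncol = 2, byrow = TRUE), directed = FALSE))
  dm <- igraph::distances(g)
  set.seed(2)
  for (i in 1:40) {
    u <- sample(all4, 1); v <- sample(all4, 1)
    expect_equal(ground_distance(u, v),
                 unname(dm[u, v]))
  }
})

test_that("emd matches closed forms and the dense LP oracle", {
  a <- kdist(c(ACGT = 1))
  b <- kdist(c(CGTA = 1))
  expect_equal(emd(a, a), 0)
  expect_equal(emd(a, b), 1)  # mass 1 moved one shift
  set.seed(3)
  problems <- list()
  ours <- numeric(0)
  for (i in 1:30) {
    x <- random_kdist(4, 8); y <- random_kdist(4, 8)
    ours[i] <- emd(x, y)
    cost <- bloodbiome:::debruijn_dist_cpp(names(x$mass), names(y$mass),
                                           4L, TRUE, character(0))
    problems[[i]] <- list(a = unname(x$mass), b = unname(y$mass),
                          cost = cost)
  }
  oracle <- emd_lp_oracle(problems)
  expect_equal(ours, oracle, tolerance = 1e-6)
})

test_that("emd satisfies the metric axioms on random distributions", {
  set.seed(4)
  ds <- replicate(12, random_kdist(4, 6), simplify = FALSE)
  for (i in 1:12) expect_equal(emd(ds[[i]], ds[[i]]), 0)
  for (t in 1:15) {
    idx <- sample(12, 3)
    dab <- emd(ds[[idx[1]]], ds[[idx[2]]])
    dba <- emd(ds[[idx[2]]], ds[[idx[1]]])
    expect_identical(dab, dba)
    dac <- emd(ds[[idx[1]]], ds[[idx[3]]])
    dbc <- emd(ds[[idx[2]]], ds[[idx[3]]])
    expect_lte(dac, dab + dbc + 1e-9)
    expect_gte(dab, 0)
  }
})

test_that("disjoint supports at uniform ground distance D give emd = D", {
  # AAAA vs CCCC: every pairwise ground distance is 4
  a <- kdist(c(AAAA = 0.5, AAAC = 0.5))
  gd <- bloodbiome:::debruijn_dist_cpp(names(a$mass), c("GGGG", "GGGT"),
                                       4L, TRUE, character(0))
  skip_if(!all(gd == gd[1, 1]))
  b <- kdist(c(GGGG = 0.5, GGGT = 0.5))
  expect_equal(emd(a, b), gd[1, 1])
})

test_that("emd is invariant to read multiplicity scaling", {
  reads <- c("ACGTACGTAA", "TTGCACGGTA")
  d1 <- kmer_distribution(reads, 4)
  d2 <- kmer_distribution(rep(reads, 5), 4)
  expect_equal(d1$mass[sort(names(d1$mass))], d2$mass[sort(names(d2$mass))])
  other <- kmer_distribution("GGGCCCGGGC", 4)
  expect_equal(emd(d1, other), emd(d2, other))
})

test_that("pairwise_emd equals per-pair calls, symmetric with zero diagonal", {
  set.seed(5)
  ds <- replicate(5, random_kdist(4, 6), simplify = FALSE)
  names(ds) <- paste0("s", 1:5)
  ds$s5 <- ds$s1  # duplicate sample
  dm <- pairwise_emd(ds)
  expect_equal(dm$matrix["s1", "s5"], 0)
  expect_true(all(abs(dm$matrix - t(dm$matrix)) < 1e-9))
  expect_true(all(diag(dm$matrix) == 0))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(dm$matrix[i, j], emd(ds[[i]], ds[[j]]), tolerance = 1e-9)
  }
})

test_that("observed-subgraph mode penalises unreachable pairs", {
  a <- kdist(c(AAAA = 1))
  b <- kdist(c(TTTT = 1))
  # joint support {AAAA, TTTT} has no connecting path: penalty k + 1
  expect_equal(emd(a, b, mode = "observed"), 5)
  expect_lte(emd(a, b, mode = "complete"), 4)
})

test_that("ordinate recovers classical MDS geometry", {
  # three collinear points at distances 1, 1, 2
  m <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d <- bloodbiome:::new_dist_matrix(m, "test")
  expect_warning(xy <- ordinate(d, 3), "axes")  # rank 1-2 < 3 requested
  expect_equal(unname(xy[, 1]), c(1, 0, -1) * sign(xy[1, 1]),
               tolerance = 1e-9)
  # zero matrix -> all-zero coordinates
  z <- bloodbiome:::new_dist_matrix(matrix(0, 3, 3,
                                           dimnames = list(letters[1:3],
                                                           letters[1:3])),
                                    "test")
  expect_true(all(ordinate(z, 2) == 0))
  # Euclidean-embeddable fixture: recovered distances approximate d
  set.seed(6)
  pts <- matrix(rnorm(20), 10, 2)
  dm <- as.matrix(dist(pts))
  rownames(dm) <- colnames(dm) <- paste0("s", 1:10)
  fit <- ordinate(bloodbiome:::new_dist_matrix(dm, "euclid"), 2)
  expect_equal(as.matrix(dist(fit)), dm, ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("correlate_ordinations is a rank statistic", {
  set.seed(7)
  m <- as.matrix(dist(matrix(rnorm(30), 15)))
  rownames(m) <- colnames(m) <- paste0("s", 1:15)
  da <- bloodbiome:::new_dist_matrix(m, "a")
  r <- correlate_ordinations(da, da)
  expect_equal(r$rho, 1)
  # monotone transform leaves rho unchanged
  db <- bloodbiome:::new_dist_matrix(m^2, "b")
  expect_equal(correlate_ordinations(da, db)$rho, 1)
  # independent matrices decorrelate
  hits <- 0
  for (i in 1:20) {
    m2 <- as.matrix(dist(matrix(rnorm(100), 50)))
    m3 <- as.matrix(dist(matrix(rnorm(100), 50)))
    rr <- correlate_ordinations(bloodbiome:::new_dist_matrix(m2, "x"),
                                bloodbiome:::new_dist_matrix(m3, "y"))
    if (abs(rr$rho) < 0.2) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("samples from different marker pools separate on axis 1", {
  tax <- build_taxonomy(4, 2)
  mkA <- simulate_markers(tax, 1, length_range = c(300, 400), seed = 61)
  mkB <- simulate_markers(tax, 1, length_range = c(300, 400), seed = 62)
  sep <- 0
  for (s in 1:5) {
    set.seed(s)
    reads_of <- function(mk) {
      idx <- sample(nrow(mk), 60, replace = TRUE)
      start <- sample(200, 60, replace = TRUE)
      substr(mk$seq[idx], start, start + 99)
    }
    ds <- c(lapply(1:4, function(i) kmer_distribution(reads_of(mkA), 4)),
            lapply(1:4, function(i) kmer_distribution(reads_of(mkB), 4)))
    names(ds) <- paste0("s", 1:8)
    xy <- ordinate(pairwise_emd(ds), 1)
    # full separation of the two pools along axis 1
    ok <- (max(xy[1:4, 1]) < min(xy[5:8, 1])) ||
      (min(xy[1:4, 1]) > max(xy[5:8, 1]))
    if (ok) sep <- sep + 1
  }
  expect_gte(sep, 4)
})
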