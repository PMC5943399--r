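test_that("normalize_alpha is the rankit transform", {
  x <- c(3.2, 1.1, 9.9, 2.4, 5.0)
  got <- normalize_alpha(x)
  expect_equal(sort(got), qnorm(c(0.1, 0.3, 0.5, 0.7, 0.9)), tolerance = 1e-9)
  expect_equal(mean(got), 0, tolerance = 1e-9)
  # rank invariance under monotone transform
  expect_equal(normalize_alpha(exp(x)), got)
  expect_error(normalize_alpha(c(1, 2)), "n >= 3")
  # z-score alternative
  expect_equal(normalize_alpha(x, "zscore"), as.vector(scale(x)))
})

test_that("alpha_group_contrasts is calibrated under the null", {
  design <- simulate_design(c(20, 20), groups = c("A", "B"), seed = 1)
  rejections <- 0
  n_sim <- 150
  set.seed(2)
  for (i in seq_len(n_sim)) {
    alpha <- exp(rnorm(40, 0.5, 0.3)) + 1  # no group effect
    res <- alpha_group_contrasts(alpha, design, "A")
    if (res$contrasts$p[1] < 0.05) rejections <- rejections + 1
  }
  ci <- qbinom(c(0.025, 0.975), n_sim, 0.05)
  expect_gte(rejections, ci[1])
  expect_lte(rejections, ci[2])
})

test_that("alpha_group_contrasts recovers planted group shifts and errors on aliasing", {
  design <- simulate_design(c(40, 40, 40), groups = c("A", "B", "C"), seed = 3)
  set.seed(4)
  alpha <- rnorm(120, 2, 0.5) + ifelse(design$group == "A", 1, 0)
  res <- alpha_group_contrasts(alpha, design, "A")
  expect_equal(nrow(res$contrasts), 2)
  expect_true(all(res$contrasts$p < 0.001))
  expect_true(all(res$contrasts$p_adj >= res$contrasts$p))
  expect_true(all(res$contrasts$estimate > 0))  # reference minus others
  # aliased covariate named in the error
  design$dup <- design$age
  expect_error(
    alpha_group_contrasts(alpha, design, "A",
                          covariates = c("age", "dup")), "dup")
})

test_that("Nagelkerke delta-R2 behaves at the null and under nesting", {
  design <- simulate_design(c(150, 150), groups = c("case", "ctrl"), seed = 5)
  set.seed(6)
  alpha <- rnorm(300)
  res <- logistic_delta_r2(design$group == "case", alpha, design)
  expect_lt(abs(res$delta_r2), 0.03)
  expect_gte(res$r2_full + 1e-12, res$r2_reduced)
  # intercept-only model has R2 = 0
  f0 <- glm(y ~ 1, family = binomial(),
            data = data.frame(y = rep(0:1, each = 20)))
  expect_equal(nagelkerke_r2(f0), 0, tolerance = 1e-12)
})

test_that("delta-R2 calibration recovers a 5% planted effect", {
  sdv <- 0.77
  shift <- calibrate_logistic_shift(0.05, sd = sdv, prevalence = 48 / 97,
                                    n = 97)
  deltas <- numeric(20)
  set.seed(7)
  for (i in 1:20) {
    y <- rep(c(TRUE, FALSE), c(48, 49))
    alpha <- rnorm(97, ifelse(y, shift, 0), sdv)
    deltas[i] <- logistic_delta_r2(y, alpha, NULL, covariates = character(0))$delta_r2
  }
  expect_lt(abs(mean(deltas) - 0.05), 0.015)
})

test_that("beta_pair_groups partitions pairs and detects block structure", {
  nA <- 10; nB <- 8; n <- nA + nB
  lab <- rep(c("A", "B"), c(nA, nB))
  m <- matrix(0.9, n, n); diag(m) <- 0
  m[1:nA, 1:nA] <- 0.1; m[(nA + 1):n, (nA + 1):n] <- 0.1; diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("s", 1:n)
  d <- bloodbiome:::new_dist_matrix(m, "test")
  res <- beta_pair_groups(d, lab, n_perm = 999, seed = 1)
  expect_equal(unname(res$means),
               c(0.1, 0.1, 0.9))
  expect_lte(res$perm_p[["wa_vs_between"]], 0.005)
  # category sizes
  expect_equal(choose(nA, 2) + choose(nB, 2) + nA * nB, choose(n, 2))
  # identical groups: all three means equal within Monte-Carlo error
  set.seed(8)
  pts <- matrix(rnorm(40), 20, 2)
  m2 <- as.matrix(dist(pts)); rownames(m2) <- colnames(m2) <- paste0("x", 1:20)
  res2 <- beta_pair_groups(bloodbiome:::new_dist_matrix(m2, "t"),
                           rep(c("A", "B"), 10), n_perm = 99, seed = 2)
  expect_true(all(res2$perm_p > 0.05))
})

test_that("permanova pseudo-F matches an explicit two-loop oracle", {
  set.seed(9)
  pts <- matrix(rnorm(16), 8, 2)
  m <- as.matrix(dist(pts)); rownames(m) <- colnames(m) <- paste0("s", 1:8)
  lab <- rep(c("A", "B"), each = 4)
  res <- permanova(bloodbiome:::new_dist_matrix(m, "t"), lab, n_perm = 99,
                   seed = 3)
  # oracle: direct sums of squares over explicit index loops
  n <- 8; a <- 2
  sst <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) sst <- sst + m[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (g in unique(lab)) {
    idx <- which(lab == g)
    for (i in idx) for (j in idx) if (i < j) ssw <- ssw + m[i, j]^2
  }
  ssw <- ssw / 4
  f_oracle <- ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  expect_equal(res$pseudo_F, f_oracle, tolerance = 1e-12)
  # determinism and permutation invariance of the observed F
  res2 <- permanova(bloodbiome:::new_dist_matrix(m, "t"), lab, n_perm = 99,
                    seed = 3)
  expect_identical(res$p, res2$p)
  perm <- c(5, 1, 7, 3, 2, 8, 4, 6)
  res3 <- permanova(bloodbiome:::new_dist_matrix(m[perm, perm], "t"),
                    lab[perm], n_perm = 99, seed = 3)
  expect_equal(res3$pseudo_F, res$pseudo_F, tolerance = 1e-12)
})

test_that("permanova agrees with vegan::adonis2 on the observed F", {
  skip_if_not_installed("vegan")
  set.seed(10)
  pts <- matrix(rnorm(60), 20, 3)
  m <- as.matrix(dist(pts)); rownames(m) <- colnames(m) <- paste0("s", 1:20)
  lab <- rep(c("A", "B", "C", "D"), each = 5)
  res <- permanova(bloodbiome:::new_dist_matrix(m, "t"), lab, n_perm = 49,
                   seed = 1)
  av <- vegan::adonis2(as.dist(m) ~ g, data = data.frame(g = lab),
                       permutations = 49)
  expect_equal(res$pseudo_F, av$F[1], tolerance = 1e-10)
})

test_that("permanova attains its minimal p on separated clusters", {
  set.seed(11)
  pts <- rbind(matrix(rnorm(48, 0, 0.05), 24), matrix(rnorm(48, 10, 0.05), 24))
  m <- as.matrix(dist(pts)); rownames(m) <- colnames(m) <- paste0("s", 1:48)
  res <- permanova(bloodbiome:::new_dist_matrix(m, "t"),
                   rep(c("A", "B"), each = 24), n_perm = 999, seed = 4)
  expect_equal(res$p, 1 / 1000)
  m12 <- m[1:12, 1:12]
  expect_error(permanova(bloodbiome:::new_dist_matrix(m12, "t"),
                         c(rep("A", 11), "B"), 99, 1), "size >= 2")
})

test_that("exact 2xK presence test matches enumeration and fisher.test", {
  # exhaustive 2x2 example: present (1,1) of totals (2,2) -> p = 1
  expect_equal(fisher_exact_2xk(c(1, 1), c(2, 2)), 1)
  # agreement with the classical two-sided test on random tables
  set.seed(12)
  for (i in 1:100) {
    K <- sample(2:4, 1)
    tot <- sample(3:12, K, replace = TRUE)
    pres <- vapply(tot, function(t) sample.int(t + 1, 1) - 1L, integer(1))
    if (sum(pres) == 0 || sum(pres) == sum(tot)) next
    ours <- fisher_exact_2xk(pres, tot)
    ref <- fisher.test(rbind(pres, tot - pres))$p.value
    expect_equal(ours, ref, tolerance = 1e-7)
  }
  expect_error(fisher_exact_2xk(c(3, 1), c(2, 2)), "\\[0, total\\]")
})

test_that("bonferroni caps at one", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 23), 1)
  expect_error(bonferroni(1.2, 3), "p-values")
})

test_that("ordination_association finds a planted axis signal", {
  design <- simulate_design(c(60, 60), groups = c("case", "ctrl"), seed = 13)
  set.seed(14)
  n <- nrow(design)
  coords <- matrix(rnorm(3 * n), n, 3,
                   dimnames = list(design$sample_id, paste0("PC", 1:3)))
  y <- design$group == "case"
  coords[, 1] <- ifelse(y, 0.6, -0.6) + rnorm(n, 0, 1)
  res <- ordination_association(coords, y, design, n_axes = 3,
                                covariates = c("age", "sex", "RIN"))
  expect_lt(res$axis_p[["PC1"]], 0.001)
  expect_gte(res$delta_r2, 0)
  # null coordinates: no systematic signal
  set.seed(15)
  res0 <- ordination_association(matrix(rnorm(3 * n), n, 3), y, design, 3,
                                 covariates = c("age", "sex", "RIN"))
  expect_true(all(res0$axis_p > 1e-4))
})

test_that("cell-proportion association recovers the designated correlation", {
  design <- simulate_design(c(65), groups = "Controls", seed = 16)
  hits <- 0
  for (s in 1:20) {
    alpha <- bloodbiome:::with_seed(s, exp(rnorm(65, 0.6, 0.4)) + 1)
    cp <- simulate_cell_proportions(alpha, -0.41, n_celltypes = 6, seed = s)
    res <- cell_proportion_association(alpha, cp, design)
    r1 <- res$correlation[res$cell_type == "cell01"]
    if (r1 > -0.55 && r1 < -0.25) hits <- hits + 1
  }
  expect_gte(hits, 18)
  # independent cell type stays near zero
  alpha <- exp(rnorm(65, 0.6, 0.4)) + 1
  cp0 <- simulate_cell_proportions(alpha, 0, n_celltypes = 4, seed = 99)
  res0 <- cell_proportion_association(alpha, cp0, design)
  expect_lt(abs(res0$correlation[res0$cell_type == "cell01"]), 0.25)
  # empty covariate set reduces to adjustment over other cells only
  res_nocov <- cell_proportion_association(alpha, cp0, NULL,
                                           covariates = character(0))
  expect_equal(nrow(res_nocov), 4)
})
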