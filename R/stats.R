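# Hypothesis tests and effect sizes: covariate-adjusted alpha contrasts,
# Nagelkerke delta-R2 from logistic regression, beta pair-group
# comparison, PERMANOVA, exact 2xK presence tests, ordination-axis
# association and cell-proportion association.

DEFAULT_COVARIATES <- c("age", "sex", "RIN", "batch", "lane", "rna_conc")

#' Rank-based inverse-normal (rankit) transform
#'
#' `qnorm((rank - 0.5) / n)` with average ranks for ties; the default
#' normalisation applied to alpha diversity before linear modelling. A
#' plain z-score is available via `method = "zscore"`.
#'
#' @param alpha numeric vector (n >= 3)
#' @param method `"rankit"` (default) or `"zscore"`
#' @return transformed vector
#' @export
normalize_alpha <- function(alpha, method = c("rankit", "zscore")) {
  method <- match.arg(method)
  if (length(alpha) < 3) stopf("need n >= 3")
  if (any(!is.finite(alpha))) stopf("alpha values must be finite")
  if (method == "zscore") return(as.vector(scale(alpha)))
  qnorm((rank(alpha, ties.method = "average") - 0.5) / length(alpha))
}

prepare_design <- function(design, covariates) {
  d <- as.data.frame(design)
  for (v in covariates) {
    if (!v %in% names(d)) stopf("covariate `%s` missing from design", v)
    if (v %in% c("sex", "batch", "lane") || is.character(d[[v]]))
      d[[v]] <- factor(d[[v]])
  }
  d
}

# error naming aliased columns on rank-deficient fits
check_aliased <- function(fit) {
  co <- coef(fit)
  if (anyNA(co))
    stopf("rank-deficient design; aliased terms: %s",
          paste(names(co)[is.na(co)], collapse = ", "))
  invisible(fit)
}

new_model_result <- function(...) structure(list(...), class = "model_result")

#' @export
print.model_result <- function(x, ...) {
  cat("<model_result>\n")
  if (!is.null(x$contrasts)) { cat("contrasts:\n"); print(x$contrasts) }
  for (nm in c("r2_full", "r2_reduced", "delta_r2", "pseudo_F", "p")) {
    if (!is.null(x[[nm]])) cat(sprintf("  %s = %.4g\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Covariate-adjusted group contrasts on normalised alpha diversity
#'
#' Fits a linear model (ANCOVA) of normalised alpha on group plus
#' biological (age, sex) and technical (RIN, batch, lane, RNA
#' concentration) covariates, and reports the contrast of the reference
#' group against every other group with Bonferroni adjustment over the
#' number of contrasts.
#'
#' @param alpha per-sample alpha values, aligned with `design`
#' @param design a [simulate_design()]-style data.frame
#' @param reference_group group contrasted against all others
#' @param covariates covariate column names (batch/lane/sex treated as
#'   categorical)
#' @param normalize normalisation applied to alpha (see
#'   [normalize_alpha()]); `"none"` disables
#' @return a `model_result` with a `contrasts` data.frame (estimate, se,
#'   p, p_adj per contrast) and the fitted `model`
#' @export
alpha_group_contrasts <- function(alpha, design,
                                  reference_group,
                                  covariates = DEFAULT_COVARIATES,
                                  normalize = "rankit") {
  d <- prepare_design(design, covariates)
  if (length(alpha) != nrow(d)) stopf("alpha and design are misaligned")
  if (!reference_group %in% d$group) stopf("unknown reference group")
  d$group <- stats::relevel(factor(d$group), ref = reference_group)
  d$.y <- if (identical(normalize, "none")) alpha
          else normalize_alpha(alpha, normalize)
  fml <- stats::as.formula(paste(".y ~ group +",
                                 paste(covariates, collapse = " + ")))
  fit <- lm(fml, data = d)
  check_aliased(fit)
  sm <- summary(fit)$coefficients
  rows <- grep("^group", rownames(sm))
  contrasts <- data.frame(
    contrast = paste(reference_group, "vs",
                     sub("^group", "", rownames(sm)[rows])),
    estimate = -sm[rows, 1], se = sm[rows, 2], p = sm[rows, 4])
  contrasts$p_adj <- bonferroni(contrasts$p, nrow(contrasts))
  new_model_result(contrasts = contrasts, model = fit,
                   reference_group = reference_group)
}

nagelkerke_from_loglik <- function(ll_full, ll_null, n) {
  cs <- 1 - exp((2 / n) * (ll_null - ll_full))
  cs_max <- 1 - exp((2 / n) * ll_null)
  cs / cs_max
}

#' Nagelkerke pseudo-R-squared of a fitted logistic model
#'
#' @param fit a binomial [glm()]
#' @return Nagelkerke R2 in [0, 1]
#' @export
nagelkerke_r2 <- function(fit) {
  y <- fit$y
  n <- length(y)
  phat <- mean(y)
  ll_null <- sum(y * log(phat) + (1 - y) * log(1 - phat))
  nagelkerke_from_loglik(as.numeric(logLik(fit)), ll_null, n)
}

fit_logistic <- function(fml, data) {
  w <- NULL
  fit <- withCallingHandlers(
    glm(fml, data = data, family = binomial()),
    warning = function(cond) {
      w <<- conditionMessage(cond)
      invokeRestart("muffleWarning")
    })
  separated <- !is.null(w) &&
    grepl("fitted probabilities numerically 0 or 1", w)
  list(fit = fit, separated = separated)
}

#' Effect of alpha diversity on case status: Nagelkerke delta-R2
#'
#' Fits logistic regressions of case status on covariates with and
#' without alpha and reports the reduction in Nagelkerke R2 when alpha is
#' removed. Perfect separation is flagged; if the glmnet package is
#' available a ridge-penalised delta is reported instead in that case.
#'
#' @param case_labels logical or two-level vector of case status
#' @param alpha per-sample alpha values
#' @param design design data.frame
#' @param covariates covariate columns (empty vector allowed)
#' @return a `model_result` with `r2_full`, `r2_reduced`, `delta_r2`,
#'   `separation_flag`
#' @export
logistic_delta_r2 <- function(case_labels, alpha, design,
                              covariates = DEFAULT_COVARIATES) {
  d <- if (length(covariates)) prepare_design(design, covariates)
       else data.frame(row.names = seq_along(alpha))
  y <- if (is.logical(case_labels)) case_labels
       else {
         lv <- sort(unique(as.character(case_labels)))
         if (length(lv) != 2) stopf("case labels must have exactly two levels")
         as.character(case_labels) == lv[2]
       }
  if (length(unique(y)) != 2) stopf("both outcome classes must be present")
  d$.y <- as.integer(y)
  d$.alpha <- alpha
  rhs_cov <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  full <- fit_logistic(stats::as.formula(paste(".y ~ .alpha +", rhs_cov)), d)
  red <- fit_logistic(stats::as.formula(paste(".y ~", rhs_cov)), d)
  separated <- full$separated || red$separated
  if (separated && requireNamespace("glmnet", quietly = TRUE)) {
    X <- stats::model.matrix(stats::as.formula(paste("~ .alpha +", rhs_cov)), d)[, -1, drop = FALSE]
    n <- nrow(d)
    lam <- 1e-3
    f_full <- glmnet::glmnet(X, d$.y, family = "binomial", alpha = 0, lambda = lam)
    f_red <- glmnet::glmnet(X[, -1, drop = FALSE], d$.y, family = "binomial",
                            alpha = 0, lambda = lam)
    dev_null <- f_full$nulldev
    ll_null <- -dev_null / 2
    r2f <- nagelkerke_from_loglik(-(1 - f_full$dev.ratio) * dev_null / 2, ll_null, n)
    r2r <- nagelkerke_from_loglik(-(1 - f_red$dev.ratio) * dev_null / 2, ll_null, n)
    return(new_model_result(r2_full = r2f, r2_reduced = r2r,
                            delta_r2 = r2f - r2r, separation_flag = TRUE,
                            penalized = TRUE))
  }
  r2f <- nagelkerke_r2(full$fit)
  r2r <- nagelkerke_r2(red$fit)
  new_model_result(r2_full = r2f, r2_reduced = r2r, delta_r2 = r2f - r2r,
                   separation_flag = separated, penalized = FALSE,
                   model = full$fit)
}

#' Beta-diversity pair-group comparison
#'
#' Partitions the off-diagonal entries of a distance matrix into
#' within-group-A, within-group-B and between-group pairs, reports the
#' three means, and tests the pairwise mean differences by label
#' permutation (labels are permuted and pair categories recomputed, which
#' respects the dependence between pairs sharing a sample).
#'
#' @param d a `dist_matrix`
#' @param labels two-level group label per sample
#' @param n_perm permutations (default 999)
#' @param seed RNG seed
#' @return a `model_result` with `means` and `perm_p` (two-sided,
#'   add-one) per comparison
#' @export
beta_pair_groups <- function(d, labels, n_perm = 999, seed = 1) {
  stopifnot(inherits(d, "dist_matrix"))
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2) stopf("exactly two label values required")
  m <- d$matrix
  if (length(labels) != nrow(m)) stopf("one label per sample required")
  small <- table(labels)
  flagged <- names(small)[small < 2]

  cat_means <- function(lab) {
    ia <- which(lab == lv[1]); ib <- which(lab == lv[2])
    wa <- if (length(ia) >= 2) mean(m[ia, ia][upper.tri(m[ia, ia])]) else NA_real_
    wb <- if (length(ib) >= 2) mean(m[ib, ib][upper.tri(m[ib, ib])]) else NA_real_
    bt <- mean(m[ia, ib])
    c(within_a = wa, within_b = wb, between = bt)
  }
  obs <- cat_means(labels)
  dif <- function(v) {
    v <- unname(v)
    c(wa_vs_wb = v[1] - v[2], wa_vs_between = v[1] - v[3],
      wb_vs_between = v[2] - v[3])
  }
  obs_d <- dif(obs)
  exceed <- rep(0L, 3)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pd <- dif(cat_means(sample(labels)))
      exceed <- exceed + (abs(pd) >= abs(obs_d) - 1e-12)
    }
  })
  perm_p <- (1 + exceed) / (1 + n_perm)
  names(perm_p) <- names(obs_d)
  new_model_result(means = setNames(obs, c(paste0("within_", lv[1]),
                                           paste0("within_", lv[2]),
                                           "between")),
                   perm_p = perm_p, n_perm = n_perm, seed = seed,
                   undefined_groups = flagged)
}

permanova_F <- function(d2, idx_by_group, n, a, ss_total) {
  ss_within <- 0
  for (idx in idx_by_group) {
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

#' PERMANOVA on a distance matrix
#'
#' One-factor permutational multivariate analysis of variance: pseudo-F
#' from sums of squared distances (total from all pairs, within from
#' same-group pairs), permutation p-value with the add-one estimator
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`, deterministic per seed.
#'
#' @param d a `dist_matrix`
#' @param labels group label per sample (>= 2 groups, each of size >= 2)
#' @param n_perm permutations (default 1000)
#' @param seed RNG seed
#' @return a `model_result` with `pseudo_F`, `p`, `n_perm`, `seed`
#' @export
permanova <- function(d, labels, n_perm = 1000, seed = 1) {
  stopifnot(inherits(d, "dist_matrix"))
  labels <- as.character(labels)
  m <- d$matrix
  n <- nrow(m)
  if (length(labels) != n) stopf("one label per sample required")
  sizes <- table(labels)
  if (length(sizes) < 2 || any(sizes < 2))
    stopf("need >= 2 groups of size >= 2")
  a <- length(sizes)
  d2 <- m^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  groups <- split(seq_len(n), labels)
  f_obs <- permanova_F(d2, groups, n, a, ss_total)
  exceed <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      f_b <- permanova_F(d2, lapply(groups, function(i) perm[i]), n, a, ss_total)
      if (f_b >= f_obs - 1e-12) exceed <- exceed + 1L
    }
  })
  new_model_result(pseudo_F = f_obs, p = (1 + exceed) / (1 + n_perm),
                   n_perm = n_perm, seed = seed)
}

#' Exact two-sided 2xK presence/absence test
#'
#' Exact test of equal presence probability across K groups, conditioning
#' on all margins: enumerates every K-column table with the observed
#' margins over the K-1 free cells and sums the multivariate
#' hypergeometric probabilities of tables no more probable than the
#' observed one (probability-ordering two-sidedness, the convention of
#' the classical exact test).
#'
#' @param present per-group counts of samples in which the taxon is
#'   present
#' @param totals per-group sample totals
#' @return the exact two-sided p-value
#' @export
fisher_exact_2xk <- function(present, totals) {
  if (length(present) != length(totals) || length(present) < 2)
    stopf("need K >= 2 groups with matching totals")
  if (any(present < 0) || any(present > totals))
    stopf("present counts must lie in [0, total] for every group")
  if (any(totals <= 0)) stopf("all group totals must be positive")
  K <- length(present)
  M <- sum(present)
  logp_obs <- sum(lchoose(totals, present))
  # enumerate free cells x_1..x_{K-1}; x_K is determined by the margin
  logp_sum <- -Inf
  tol <- 1e-7
  rec <- function(g, remaining, logp_acc) {
    if (g == K) {
      xk <- remaining
      if (xk < 0 || xk > totals[K]) return()
      lp <- logp_acc + lchoose(totals[K], xk)
      if (lp <= logp_obs + tol) {
        logp_sum <<- if (is.infinite(logp_sum)) lp
                     else max(logp_sum, lp) + log1p(exp(-abs(logp_sum - lp)))
      }
      return()
    }
    lo <- max(0L, remaining - sum(totals[(g + 1):K]))
    hi <- min(totals[g], remaining)
    if (lo > hi) return()
    for (x in lo:hi) rec(g + 1, remaining - x, logp_acc + lchoose(totals[g], x))
  }
  rec(1L, M, 0)
  denom <- lchoose(sum(totals), M)
  min(1, exp(logp_sum - denom))
}

#' Bonferroni adjustment
#'
#' @param p p-value(s)
#' @param m number of tests
#' @return `min(1, p * m)`
#' @export
bonferroni <- function(p, m) {
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  m <- check_count(m, "m")
  pmin(1, p * m)
}

#' Association of ordination axes with case status
#'
#' Logistic regression of case status on the first `n_axes` ordination
#' coordinates plus covariates; reports per-axis Wald p-values and the
#' joint Nagelkerke delta-R2 of the axis block (full model versus
#' covariates only).
#'
#' @param coords coordinate matrix from [ordinate()]
#' @param case_labels logical or two-level case status per sample
#' @param design design data.frame
#' @param n_axes axes entering the model (default 3)
#' @param covariates covariate columns (empty vector allowed)
#' @return a `model_result` with `axis_p` and `delta_r2`
#' @export
ordination_association <- function(coords, case_labels, design,
                                   n_axes = 3,
                                   covariates = DEFAULT_COVARIATES) {
  n_axes <- min(check_count(n_axes, "n_axes"), ncol(coords))
  d <- prepare_design(design, covariates)
  if (nrow(coords) != nrow(d)) stopf("coords and design are misaligned")
  y <- if (is.logical(case_labels)) case_labels
       else as.character(case_labels) == sort(unique(as.character(case_labels)))[2]
  d$.y <- as.integer(y)
  ax <- sprintf(".ax%d", seq_len(n_axes))
  for (j in seq_len(n_axes)) d[[ax[j]]] <- coords[, j]
  rhs_cov <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  full <- fit_logistic(stats::as.formula(
    paste(".y ~", paste(c(ax, rhs_cov), collapse = " + "))), d)
  red <- fit_logistic(stats::as.formula(paste(".y ~", rhs_cov)), d)
  sm <- summary(full$fit)$coefficients
  axis_p <- sm[ax, 4]
  names(axis_p) <- sprintf("PC%d", seq_len(n_axes))
  new_model_result(axis_p = axis_p,
                   delta_r2 = nagelkerke_r2(full$fit) - nagelkerke_r2(red$fit),
                   separation_flag = full$separated || red$separated,
                   model = full$fit)
}

#' Partial correlation of cell-type proportions with alpha diversity
#'
#' For each cell type, residualises both alpha and that cell type's
#' proportion on the covariates plus all other cell types (one other cell
#' type is dropped because proportions sum to 1), and reports the Pearson
#' correlation of the residuals with its t-test p-value, Bonferroni
#' adjusted over cell types.
#'
#' @param alpha per-sample alpha values
#' @param cell_table samples x cell types proportion matrix
#' @param design design data.frame
#' @param covariates covariate columns (empty vector reduces to plain
#'   correlation adjustment over the other cell types only)
#' @return data.frame with `cell_type`, `correlation`, `p`, `p_adj`
#' @export
cell_proportion_association <- function(alpha, cell_table, design,
                                        covariates = c("age", "sex", "RIN",
                                                       "batch", "lane",
                                                       "rna_conc")) {
  cell_table <- as.matrix(cell_table)
  if (nrow(cell_table) != length(alpha)) stopf("tables are misaligned")
  if (ncol(cell_table) < 2) stopf("need >= 2 cell types")
  d <- if (length(covariates)) prepare_design(design, covariates)
       else data.frame(row.names = seq_along(alpha))
  res <- lapply(seq_len(ncol(cell_table)), function(j) {
    others <- cell_table[, -j, drop = FALSE]
    # drop one other cell type: with the row-sum constraint the full set
    # of others is collinear
    if (ncol(others) > 1) others <- others[, -ncol(others), drop = FALSE]
    Z <- if (length(covariates))
      stats::model.matrix(stats::as.formula(
        paste("~", paste(covariates, collapse = " + "))), d)[, -1, drop = FALSE]
    else NULL
    Z <- cbind(Z, others)
    ra <- resid(lm(alpha ~ Z))
    rc <- resid(lm(cell_table[, j] ~ Z))
    r <- cor(ra, rc)
    df <- length(alpha) - ncol(Z) - 2
    t <- r * sqrt(df / (1 - r^2))
    data.frame(cell_type = colnames(cell_table)[j], correlation = r,
               p = 2 * pt(-abs(t), df))
  })
  out <- do.call(rbind, res)
  out$p_adj <- bonferroni(out$p, nrow(out))
  out
}

#' Calibrate the group shift that yields a target Nagelkerke delta-R2
#'
#' Solves, by numerical integration of the population log-likelihoods,
#' for the mean shift `delta` of a normal predictor (common SD `sd`)
#' between cases and controls such that the Nagelkerke R2 of the
#' single-predictor logistic model equals `target`. When a sample size
#' `n` is supplied, the calibration targets the expectation of the
#' maximum-likelihood estimator at that n (which sits above the
#' population value because the fitted model overstates its own fit),
#' via a short Monte-Carlo bias correction - the reported R2 of a study
#' of size n is that estimator.
#'
#' @param target target Nagelkerke R2 (default 0.05)
#' @param sd common within-group SD of the predictor
#' @param prevalence case fraction
#' @param n optional study size for finite-sample calibration
#' @param B Monte-Carlo replicates per bias-correction step
#' @return the shift (same units as the predictor)
#' @export
calibrate_logistic_shift <- function(target = 0.05, sd = 1,
                                     prevalence = 0.5, n = NULL, B = 300) {
  pop_r2 <- function(delta) {
    s2 <- sd^2
    b0 <- log(prevalence / (1 - prevalence)) - delta^2 / (2 * s2)
    b1 <- delta / s2
    lo <- min(0, delta) - 10 * sd
    hi <- max(0, delta) + 10 * sd
    e1 <- stats::integrate(function(x)
      stats::plogis(b0 + b1 * x, log.p = TRUE) * stats::dnorm(x, delta, sd),
      lo, hi)$value
    e0 <- stats::integrate(function(x)
      stats::plogis(b0 + b1 * x, lower.tail = FALSE, log.p = TRUE) *
        stats::dnorm(x, 0, sd), lo, hi)$value
    l1 <- prevalence * e1 + (1 - prevalence) * e0
    l0 <- prevalence * log(prevalence) + (1 - prevalence) * log(1 - prevalence)
    nagelkerke_from_loglik(l1, l0, 1)
  }
  solve_pop <- function(t)
    stats::uniroot(function(d) pop_r2(d) - t, c(1e-5, 6 * sd),
                   tol = 1e-6)$root
  delta <- solve_pop(target)
  if (is.null(n)) return(delta)
  n1 <- round(prevalence * n)
  sim_mean <- function(d, seed) with_seed(seed, {
    mean(replicate(B, {
      y <- rep(c(TRUE, FALSE), c(n1, n - n1))
      x <- rnorm(n, ifelse(y, d, 0), sd)
      logistic_delta_r2(y, x, NULL, covariates = character(0))$delta_r2
    }))
  })
  t_adj <- target
  for (it in 1:3) {
    mhat <- sim_mean(delta, 1000003 + it)
    t_adj <- max(1e-4, t_adj - (mhat - target))
    delta <- solve_pop(t_adj)
  }
  delta
}
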