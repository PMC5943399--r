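# End-to-end orchestration: simulate -> filter -> profile -> diversity ->
# emd -> stats, with per-stage derived seeds, resumable outputs and a run
# manifest.

default_run_config <- function() {
  list(
    outdir = "bloodbiome_run",
    seed = 1,
    groups = c("Controls", "SCZ", "BPD", "ALS"),
    n_per_group = 12,
    n_phyla = 23, genera_per_phylum = 4,
    markers_per_genus = 2,
    n_reads = 20000,
    microbial_fraction = 0.0124,
    host_leak_fraction = 0.55,
    low_quality_fraction = 0.05,
    low_complexity_fraction = 0.05,
    error_rate = 0,
    depth = 100000, min_q = 20, min_frac = 0.8,
    complexity_threshold = 7, host_k = 21, max_shared = 2,
    profile_k = 21, min_hits = 2,
    rank = "phylum",
    k_emd = 4, emd_mode = "complete", emd_canonical = FALSE,
    target_group = "SCZ", control_group = "Controls",
    covariates = c("age", "sex", "RIN", "batch", "lane", "rna_conc"),
    n_perm = 1000)
}

#' Validate a run configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, and reports every
#' validation problem at once.
#'
#' @param config path to a YAML file, or a named list of overrides
#' @return a resolved config list of class `run_config`
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  cfg <- modifyList(defaults, config[setdiff(names(config), unknown)])
  errs <- character(0)
  if (length(unknown))
    errs <- c(errs, sprintf("unknown config key(s): %s",
                            paste(unknown, collapse = ", ")))
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(is.numeric(cfg$depth) && cfg$depth >= 1, "`depth` must be >= 1")
  chk(is.numeric(cfg$n_reads) && cfg$n_reads >= 1, "`n_reads` must be >= 1")
  chk(is.numeric(cfg$n_per_group) && all(cfg$n_per_group >= 2),
      "`n_per_group` must be >= 2")
  chk(cfg$rank %in% TAX_RANKS, sprintf("`rank` must be one of: %s",
                                       paste(TAX_RANKS, collapse = ", ")))
  chk(cfg$k_emd >= 2 && cfg$k_emd <= 13, "`k_emd` must lie in [2, 13]")
  chk(cfg$emd_mode %in% c("complete", "observed"),
      "`emd_mode` must be 'complete' or 'observed'")
  fracs <- c(cfg$microbial_fraction, cfg$host_leak_fraction,
             cfg$low_quality_fraction, cfg$low_complexity_fraction)
  chk(all(fracs >= 0) && sum(fracs) <= 1,
      "category fractions must be >= 0 and sum to <= 1")
  chk(cfg$target_group %in% cfg$groups, "`target_group` not among `groups`")
  chk(cfg$control_group %in% cfg$groups, "`control_group` not among `groups`")
  if (length(errs)) stopf("invalid config:\n- %s", paste(errs, collapse = "\n- "))
  class(cfg) <- "run_config"
  cfg
}

#' Write a resolved configuration back to YAML
#'
#' @param config a `run_config`
#' @param path output path
#' @return the path, invisibly
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_done <- function(paths) all(file.exists(paths))

manifest_add <- function(manifest, stage, seed, outputs) {
  manifest$stages[[stage]] <- list(
    seed = seed,
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])))
  manifest
}

#' Run the full pipeline on a synthetic study
#'
#' Executes simulate, filter, profile, diversity, emd and stats in order
#' under `config$outdir`. Each stage is resumable: when its declared
#' outputs already exist it is skipped, so deleting only downstream
#' outputs re-runs only the downstream stages. All randomness derives
#' from `config$seed` via stage-name-hashed seeds.
#'
#' @param config a [validate_config()] result (or a list/path accepted by
#'   it)
#' @param quiet suppress progress messages
#' @return the run manifest (invisibly), written as
#'   `manifest.json` alongside a `report.json` summary
#' @export
run_all <- function(config = list(), quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out <- cfg$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(config = unclass(cfg), stages = list())
  groups <- cfg$groups
  design_path <- file.path(out, "design.tsv")
  tax_path <- file.path(out, "taxonomy.tsv")
  markers_path <- file.path(out, "markers.fasta")
  host_path <- file.path(out, "host.fasta")
  sample_dir <- file.path(out, "reads")
  cand_dir <- file.path(out, "candidates")
  dir.create(sample_dir, showWarnings = FALSE)
  dir.create(cand_dir, showWarnings = FALSE)

  ## stage: simulate -------------------------------------------------------
  seed_sim <- derive_seed(cfg$seed, "simulate")
  design <- NULL
  sim_outputs <- c(design_path, tax_path, markers_path, host_path)
  if (!stage_done(sim_outputs)) {
    say("[simulate] generating study (seed %d)", seed_sim)
    tax <- build_taxonomy(cfg$n_phyla, cfg$genera_per_phylum, seed = seed_sim)
    markers <- simulate_markers(tax, cfg$markers_per_genus,
                                k = cfg$profile_k, seed = seed_sim + 1)
    host <- simulate_host_reference(seed = seed_sim + 2)
    design <- simulate_design(cfg$n_per_group, groups, seed = seed_sim + 3)
    profiles <- default_group_profiles(tax, groups,
                                       microbial_fraction = cfg$microbial_fraction)
    knobs <- list(n_reads = cfg$n_reads,
                  microbial_fraction = cfg$microbial_fraction,
                  host_leak_fraction = cfg$host_leak_fraction,
                  low_quality_fraction = cfg$low_quality_fraction,
                  low_complexity_fraction = cfg$low_complexity_fraction,
                  error_rate = cfg$error_rate)
    truth <- list()
    for (i in seq_len(nrow(design))) {
      sid <- design$sample_id[i]
      ab <- draw_sample_abundances(profiles[[design$group[i]]],
                                   seed = seed_sim + 10 + i)
      sim <- simulate_sample_reads(design[i, ], ab, markers, host, knobs,
                                   seed = seed_sim + 5000 + i)
      write_fastq(sim$reads, file.path(sample_dir, paste0(sid, ".fastq")))
      write_tsv(sim$origin, file.path(sample_dir, paste0(sid, ".origin.tsv")))
      truth[[sid]] <- ab
    }
    write_tsv(as.data.frame(design), design_path)
    write_taxonomy(tax, tax_path)
    write_fasta(setNames(markers$seq, markers$marker_id), markers_path)
    write_fasta(host, host_path)
    saveRDS_safe <- function(x, p) write_tsv(
      data.frame(sample = rep(names(x), each = length(x[[1]])),
                 taxon = unlist(lapply(x, names), use.names = FALSE),
                 abundance = unlist(x, use.names = FALSE)), p)
    saveRDS_safe(truth, file.path(out, "true_abundances.tsv"))
  } else say("[simulate] outputs present, skipping")
  manifest <- manifest_add(manifest, "simulate", seed_sim, sim_outputs)
  design <- design %||% {
    d <- read_tsv(design_path); class(d) <- c("sample_design", "data.frame"); d
  }
  tax <- read_taxonomy(tax_path)
  sample_ids <- design$sample_id

  ## stage: filter ---------------------------------------------------------
  seed_flt <- derive_seed(cfg$seed, "filter")
  cand_paths <- file.path(cand_dir, paste0(sample_ids, ".fasta"))
  report_paths <- file.path(cand_dir, paste0(sample_ids, ".report.tsv"))
  if (!stage_done(c(cand_paths, report_paths))) {
    say("[filter] %d samples (seed %d)", length(sample_ids), seed_flt)
    host_idx <- build_host_index(read_fasta(host_path), cfg$host_k)
    fc <- filter_config(depth = cfg$depth, seed = seed_flt,
                        min_q = cfg$min_q, min_frac = cfg$min_frac,
                        complexity_threshold = cfg$complexity_threshold,
                        host_k = cfg$host_k, max_shared = cfg$max_shared)
    for (i in seq_along(sample_ids)) {
      sid <- sample_ids[i]
      reads <- read_fastq(file.path(sample_dir, paste0(sid, ".fastq")))
      res <- suppressWarnings(run_filter(reads, host_idx, fc,
                                         host_is_index = TRUE))
      write_fasta(res$candidates[, c("id", "seq")], cand_paths[i])
      write_filter_report(res$report, report_paths[i])
    }
  } else say("[filter] outputs present, skipping")
  manifest <- manifest_add(manifest, "filter", seed_flt, cand_paths)

  ## stage: profile --------------------------------------------------------
  abund_path <- file.path(out, sprintf("abundance_%s.tsv", cfg$rank))
  if (!stage_done(abund_path)) {
    say("[profile] building index and assigning reads")
    marker_seqs <- read_fasta(markers_path)
    markers <- data.frame(marker_id = names(marker_seqs),
                          taxon_id = sub("\\.m[0-9]+$", "", names(marker_seqs)),
                          seq = unname(marker_seqs), stringsAsFactors = FALSE)
    idx <- build_index(markers, k = cfg$profile_k)
    profs <- lapply(seq_along(sample_ids), function(i) {
      seqs <- read_fasta(cand_paths[i])
      profile_sample(unname(seqs), idx, tax, cfg$min_hits)
    })
    names(profs) <- sample_ids
    tab <- abundance_table(profs, tax, cfg$rank)
    write_abundance_table(tab, abund_path)
  } else say("[profile] outputs present, skipping")
  manifest <- manifest_add(manifest, "profile", NA, abund_path)
  tab <- read_abundance_table(abund_path, rank = cfg$rank)
  tab$taxonomy <- tax

  ## stage: diversity ------------------------------------------------------
  alpha_path <- file.path(out, "alpha.tsv")
  beta_path <- file.path(out, "beta.tsv")
  gamma_path <- file.path(out, "gamma.tsv")
  if (!stage_done(c(alpha_path, beta_path, gamma_path))) {
    say("[diversity] alpha/beta/gamma at rank %s", cfg$rank)
    alpha <- alpha_diversity(tab)
    write_alpha(alpha, alpha_path)
    write_dist_matrix(beta_matrix(tab), beta_path)
    write_gamma(gamma_richness(tab, design$group), gamma_path)
  } else say("[diversity] outputs present, skipping")
  manifest <- manifest_add(manifest, "diversity", NA,
                           c(alpha_path, beta_path, gamma_path))

  ## stage: emd ------------------------------------------------------------
  seed_emd <- derive_seed(cfg$seed, "emd")
  emd_path <- file.path(out, "emd.tsv")
  pcs_path <- file.path(out, "emd_pcs.tsv")
  if (!stage_done(c(emd_path, pcs_path))) {
    say("[emd] k = %d, mode = %s", cfg$k_emd, cfg$emd_mode)
    dists <- lapply(cand_paths, function(p) {
      kmer_distribution(unname(read_fasta(p)), cfg$k_emd, cfg$emd_canonical)
    })
    names(dists) <- sample_ids
    dm <- pairwise_emd(dists, mode = cfg$emd_mode)
    write_dist_matrix(dm, emd_path)
    pcs <- ordinate(dm, 3)
    write_tsv(data.frame(sample = rownames(pcs), pcs), pcs_path)
  } else say("[emd] outputs present, skipping")
  manifest <- manifest_add(manifest, "emd", seed_emd, c(emd_path, pcs_path))

  ## stage: stats ----------------------------------------------------------
  seed_sts <- derive_seed(cfg$seed, "stats")
  stats_path <- file.path(out, "stats.json")
  if (!stage_done(stats_path)) {
    say("[stats] group contrasts, PERMANOVA (%d perms), presence tests",
        cfg$n_perm)
    alpha_df <- read_tsv(alpha_path)
    alpha <- setNames(alpha_df$alpha, alpha_df$sample)[sample_ids]
    contrasts <- alpha_group_contrasts(alpha, design, cfg$target_group,
                                       covariates = cfg$covariates)
    is_pair <- design$group %in% c(cfg$target_group, cfg$control_group)
    dr2 <- logistic_delta_r2(design$group[is_pair] == cfg$target_group,
                             alpha[is_pair], design[is_pair, ],
                             covariates = cfg$covariates)
    beta <- read_dist_matrix(beta_path)
    perma <- permanova(beta, design$group, cfg$n_perm, seed_sts)
    beta_pair <- {
      sub <- beta
      sub$matrix <- beta$matrix[is_pair, is_pair]
      sub$ids <- beta$ids[is_pair]
      beta_pair_groups(sub, design$group[is_pair], n_perm = 999,
                       seed = seed_sts + 1)
    }
    # per-phylum presence outlier scan
    m <- tab$counts %||% tab$rel
    presence <- lapply(colnames(m), function(tx) {
      pres <- tapply(m[, tx] > 0, design$group, sum)[unique(design$group)]
      tot <- table(design$group)[unique(design$group)]
      p <- fisher_exact_2xk(as.integer(pres), as.integer(tot))
      list(taxon = tx, present = as.list(pres), p = p)
    })
    praw <- vapply(presence, function(x) x$p, numeric(1))
    padj <- bonferroni(praw, ncol(m))
    for (i in seq_along(presence)) presence[[i]]$p_adj <- padj[i]
    pcs <- as.matrix(read_tsv(pcs_path)[, -1, drop = FALSE])
    ord <- ordination_association(pcs[is_pair, , drop = FALSE],
                                  design$group[is_pair] == cfg$target_group,
                                  design[is_pair, ],
                                  n_axes = min(3, ncol(pcs)),
                                  covariates = cfg$covariates)
    emd_dm <- read_dist_matrix(emd_path, "emdebruijn")
    rho <- correlate_ordinations(emd_dm, beta)
    summary <- list(
      alpha_group_means = lapply(split(alpha, design$group), mean),
      contrasts = contrasts$contrasts,
      delta_r2 = dr2$delta_r2,
      permanova = list(pseudo_F = perma$pseudo_F, p = perma$p,
                       n_perm = perma$n_perm, seed = perma$seed),
      beta_pair = list(means = as.list(beta_pair$means),
                       perm_p = as.list(beta_pair$perm_p)),
      presence_tests = presence,
      ordination = list(axis_p = as.list(ord$axis_p),
                        delta_r2 = ord$delta_r2),
      emd_beta_spearman = list(rho = rho$rho, p = rho$p),
      seeds = list(global = cfg$seed, stats = seed_sts))
    jsonlite::write_json(summary, stats_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  } else say("[stats] outputs present, skipping")
  manifest <- manifest_add(manifest, "stats", seed_sts, stats_path)

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(manifest)
}
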