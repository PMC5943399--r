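# Synthetic study generator: taxonomy, marker genes, group compositional
# profiles, sample design tables, read sets with a true-origin table, and
# cell-type proportion tables. All generators are deterministic per seed.

#' Group compositional profile
#'
#' Bundles the Dirichlet concentration vector over genus-level taxa that
#' generates per-sample compositions for one subject group, together with
#' the expected microbial read fraction of that group's samples.
#'
#' @param label group label
#' @param concentrations positive Dirichlet concentrations, named by genus
#'   taxon id
#' @param microbial_fraction expected fraction of reads that originate from
#'   marker genes (in (0,1))
#' @param expected_marker_hits expected per-sample marker-hit count
#'   (informational; `microbial_fraction * n_reads`)
#' @return an object of class `group_profile`
#' @export
group_profile <- function(label, concentrations, microbial_fraction = 0.0124,
                          expected_marker_hits = NULL) {
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stopf("all concentrations must be positive and finite")
  check_fraction(microbial_fraction, "microbial_fraction")
  if (microbial_fraction <= 0 || microbial_fraction >= 1)
    stopf("`microbial_fraction` must lie strictly in (0,1)")
  structure(list(label = label, concentrations = concentrations,
                 microbial_fraction = microbial_fraction,
                 expected_marker_hits = expected_marker_hits),
            class = "group_profile")
}

# Calibration of the default four-group study, frozen from a one-off
# Monte-Carlo grid search. Each group differs from the shared
# dominant-phylum composition in two ways: an evenness exponent tau and
# Dirichlet scale theta tuned so phylum-level inverse Simpson means land
# near 2.50 (SCZ) / 1.77 (Controls) / 1.55 (BPD) / 1.65 (ALS) with
# SD ~ 0.6-0.9, and a phylum support fraction (share of phyla with
# non-negligible concentration) reproducing the group richness ordering
# (gamma 23 / 20 / 18 / 16 at 23 phyla).
.group_calibration <- data.frame(
  group = c("Controls", "SCZ", "BPD", "ALS"),
  tau   = c(0.15, 0.65, 0.20, 0.35),
  theta = c(0.60, 5.60, 0.40, 0.60),
  support = c(20 / 23, 1.0, 18 / 23, 16 / 23),
  floor = c(0, 0.005, 0, 0),
  stringsAsFactors = FALSE)

# Dominant-phylum mean composition: the three leading phyla carry ~73/15/11
# percent of the mass, the remaining phyla share a small geometric tail.
base_phylum_profile <- function(n_phyla) {
  head_mass <- c(0.734, 0.149, 0.110)
  if (n_phyla <= 3) return(head_mass[seq_len(n_phyla)] /
                             sum(head_mass[seq_len(n_phyla)]))
  tail <- 0.004 * 0.75^(seq_len(n_phyla - 3) - 1)
  m <- c(head_mass, tail)
  m / sum(m)
}

#' Default calibrated group profiles for the four-group synthetic study
#'
#' Builds one [group_profile] per group over the genus leaves of `taxonomy`.
#' Group differences are pure evenness shifts of a shared dominant-phylum
#' composition (one elevated-diversity group), plus optional presence
#' spiking of two designated phyla in the elevated group.
#'
#' @param taxonomy a [build_taxonomy()] tree
#' @param groups group labels (default the four-group study design)
#' @param elevated label of the elevated-evenness group
#' @param spike_phyla number of designated rare phyla whose presence is
#'   boosted in the elevated group (0 disables)
#' @param microbial_fraction expected microbial read fraction per sample
#' @return named list of `group_profile` objects
#' @export
default_group_profiles <- function(taxonomy,
                                   groups = c("Controls", "SCZ", "BPD", "ALS"),
                                   elevated = "SCZ", spike_phyla = 2,
                                   microbial_fraction = 0.0124) {
  phyla <- taxonomy$id[taxonomy$rank == "phylum"]
  genera <- tax_genera(taxonomy)
  genus_phylum <- vapply(genera, function(g)
    tax_ancestor_at(taxonomy, g, "phylum"), character(1))
  m0 <- setNames(base_phylum_profile(length(phyla)), phyla)
  out <- list()
  for (g in groups) {
    cal <- .group_calibration[.group_calibration$group == g, ]
    if (nrow(cal) == 0) cal <- data.frame(tau = 0.15, theta = 0.60,
                                          support = 20 / 23, floor = 0)
    m <- m0^cal$tau
    if (g == elevated && spike_phyla > 0) {
      designated <- utils::tail(phyla, spike_phyla)
      m[designated] <- pmax(m[designated], 0.015)
    }
    # a small in-support floor keeps the elevated group's rarest phyla
    # detectable at realistic read depths, reproducing its full richness
    if (cal$floor > 0) m <- pmax(m, cal$floor)
    # phyla beyond the group's support carry vanishing mass: per-group
    # richness (gamma) tracks the support size while alpha is shaped by
    # the in-support evenness
    n_support <- max(3, round(cal$support * length(phyla)))
    if (n_support < length(phyla)) {
      dropped <- order(m0)[seq_len(length(phyla) - n_support)]
      if (g == elevated) dropped <- setdiff(dropped, match(utils::tail(phyla, spike_phyla), phyla))
      m[dropped] <- 1e-6
    }
    m <- m / sum(m)
    conc_phylum <- cal$theta * m
    # split each phylum's concentration evenly over its genera: aggregating
    # the genus-level Dirichlet back to phylum level recovers
    # Dirichlet(conc_phylum) exactly
    conc <- conc_phylum[genus_phylum] / as.vector(table(genus_phylum)[genus_phylum])
    names(conc) <- genera
    out[[g]] <- group_profile(g, conc, microbial_fraction)
  }
  out
}

#' Draw one sample's genus-level relative abundances
#'
#' @param profile a [group_profile]
#' @param seed RNG seed
#' @return non-negative named vector over genera summing to 1
#' @export
draw_sample_abundances <- function(profile, seed) {
  stopifnot(inherits(profile, "group_profile"))
  with_seed(seed, {
    p <- rdirichlet1(profile$concentrations)
    names(p) <- names(profile$concentrations)
    p
  })
}

#' Simulate marker genes with cross-genus k-mer uniqueness
#'
#' Every genus leaf receives `markers_per_genus` random sequences in the
#' requested length range. Any candidate sharing a canonical k-mer (at the
#' pipeline's profiling k) with a marker of a different genus is rejected
#' and resampled, so the profiler's k-mer index maps each marker's k-mers
#' to a single genus.
#'
#' @param taxonomy a [build_taxonomy()] tree
#' @param markers_per_genus sequences per genus
#' @param length_range length range (bases), default 300-1500
#' @param k k-mer size whose uniqueness is enforced (default 21)
#' @param seed RNG seed
#' @param max_retries resampling attempts per marker before failing
#' @return an object of class `marker_set`: data.frame with `marker_id`,
#'   `taxon_id`, `seq`
#' @export
simulate_markers <- function(taxonomy, markers_per_genus = 2,
                             length_range = c(300, 1500), k = 21, seed = 1,
                             max_retries = 50) {
  genera <- tax_genera(taxonomy)
  if (length(genera) == 0) stopf("taxonomy has no genus leaves")
  markers_per_genus <- check_count(markers_per_genus, "markers_per_genus")
  with_seed(seed, {
    owner <- new.env(hash = TRUE, parent = emptyenv())
    rows <- vector("list", length(genera) * markers_per_genus)
    n <- 0L
    for (g in genera) {
      for (m in seq_len(markers_per_genus)) {
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          len <- sample(length_range[1]:length_range[2], 1)
          s <- random_dna_cpp(len)
          kms <- kmer_set_cpp(s, k, TRUE)
          clash <- FALSE
          for (km in kms) {
            o <- owner[[km]]
            if (!is.null(o) && o != g) { clash <- TRUE; break }
          }
          if (!clash) {
            for (km in kms) owner[[km]] <- g
            n <- n + 1L
            rows[[n]] <- data.frame(
              marker_id = sprintf("%s.m%02d", g, m),
              taxon_id = g, seq = s, stringsAsFactors = FALSE)
            ok <- TRUE
            break
          }
        }
        if (!ok) stopf("could not generate a genus-unique marker for %s after %d tries",
                       g, max_retries)
      }
    }
    out <- do.call(rbind, rows[seq_len(n)])
    class(out) <- c("marker_set", "data.frame")
    out
  })
}

#' Simulate a sample design table
#'
#' Emulates a four-group blood RNA-seq cohort: group-specific age
#' distributions and sex ratios, plus technical covariates (RIN, batch,
#' flow-cell lane, RNA concentration).
#'
#' @param n_per_group samples per group (scalar or one per group)
#' @param groups group labels
#' @param seed RNG seed
#' @return data.frame of class `sample_design` with columns `sample_id`,
#'   `group`, `age`, `sex`, `RIN`, `batch`, `lane`, `rna_conc`
#' @export
simulate_design <- function(n_per_group = c(49, 48, 48, 47),
                            groups = c("Controls", "SCZ", "BPD", "ALS"),
                            seed = 1) {
  n_per_group <- rep_len(n_per_group, length(groups))
  age_mean <- c(Controls = 41.1, SCZ = 29.9, BPD = 46.5, ALS = 56.4)
  age_sd   <- c(Controls = 10.7, SCZ = 5.8, BPD = 9.9, ALS = 10.3)
  p_male   <- c(Controls = 38 / 49, SCZ = 39 / 48, BPD = 20 / 48, ALS = 29 / 47)
  with_seed(seed, {
    rows <- lapply(seq_along(groups), function(i) {
      g <- groups[i]; n <- n_per_group[i]
      mu <- if (g %in% names(age_mean)) age_mean[[g]] else 45
      sdv <- if (g %in% names(age_sd)) age_sd[[g]] else 12
      pm <- if (g %in% names(p_male)) p_male[[g]] else 0.5
      data.frame(
        sample_id = sprintf("%s_%03d", g, seq_len(n)),
        group = g,
        age = round(pmax(18, rnorm(n, mu, sdv)), 1),
        sex = ifelse(runif(n) < pm, "M", "F"),
        RIN = round(pmin(10, pmax(4, rnorm(n, 7.5, 0.8))), 1),
        batch = sprintf("b%d", sample.int(4, n, replace = TRUE)),
        lane = sprintf("L%d", sample.int(8, n, replace = TRUE)),
        rna_conc = round(exp(rnorm(n, log(150), 0.4)), 1),
        stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    class(d) <- c("sample_design", "data.frame")
    d
  })
}

#' Simulate a host reference as random contigs
#'
#' @param n_seqs number of contigs
#' @param total_length summed contig length (bases)
#' @param seed RNG seed
#' @return named character vector of sequences
#' @export
simulate_host_reference <- function(n_seqs = 5, total_length = 10000, seed = 1) {
  with_seed(seed, {
    len <- rep(total_length %/% n_seqs, n_seqs)
    len[1] <- len[1] + total_length - sum(len)
    setNames(random_dna_cpp(as.integer(len)), sprintf("host_%d", seq_len(n_seqs)))
  })
}

default_read_knobs <- function() {
  list(n_reads = 100000L, microbial_fraction = 0.0124,
       host_leak_fraction = 0.55, low_quality_fraction = 0.05,
       low_complexity_fraction = 0.05, error_rate = 0,
       read_length = 100L, paired = FALSE)
}

# flat high-quality string (Phred 35) of a given length
good_qual <- function(len, n) strrep(intToUtf8(35L + 33L), rep(len, n))

# low-quality strings: a random 40% of positions drop to Phred U[2,15]
low_quality_strings <- function(n, len) {
  n_bad <- ceiling(0.4 * len)
  vapply(seq_len(n), function(i) {
    q <- rep(35L, len)
    pos <- sample.int(len, n_bad)
    q[pos] <- sample(2:15, n_bad, replace = TRUE)
    intToUtf8(q + 33L)
  }, character(1))
}

# homopolymer / dinucleotide repeat sequences
low_complexity_seqs <- function(n, len) {
  vapply(seq_len(n), function(i) {
    if (runif(1) < 0.5) {
      strrep(sample(c("A", "C", "G", "T"), 1), len)
    } else {
      b <- sample(c("A", "C", "G", "T"), 2)
      substr(strrep(paste0(b, collapse = ""), ceiling(len / 2) + 1), 1, len)
    }
  }, character(1))
}

# random substrings of a set of source sequences, weighted by length
source_substrings <- function(sources, n, len) {
  if (n == 0) return(list(seq = character(0), src = integer(0)))
  slen <- nchar(sources)
  usable <- slen >= len
  if (!any(usable)) stopf("all source sequences shorter than the read length")
  w <- ifelse(usable, slen - len + 1, 0)
  src <- sample.int(length(sources), n, replace = TRUE, prob = w)
  start <- floor(runif(n) * (slen[src] - len + 1)) + 1
  list(seq = substr(sources[src], start, start + len - 1), src = src)
}

#' Simulate one sample's read set with a true-origin table
#'
#' Emits `n_reads` reads of five categories: microbial reads are substrings
#' of marker genes of taxa drawn proportionally to `abundances` (with
#' per-base substitution errors at `error_rate`); host-leak reads are
#' substrings of the host reference; low-quality reads have >20% of bases
#' below Phred 20; low-complexity reads are homopolymer/dinucleotide
#' repeats; the remainder is uniform-random sequence. The origin table
#' labels every read id with its category and source taxon, so filter and
#' profiler stages can be checked exactly.
#'
#' @param design one row of a [simulate_design()] table (or a sample id
#'   string), used to prefix read ids
#' @param abundances genus-level relative abundances (named)
#' @param markers a [simulate_markers()] set
#' @param host_ref named character vector of host sequences
#' @param knobs list overriding [default_read_knobs()]
#' @param seed RNG seed
#' @return list with `reads` (read-set data.frame) and `origin`
#'   (data.frame `read_id`, `category`, `taxon_id`)
#' @export
simulate_sample_reads <- function(design, abundances, markers, host_ref,
                                  knobs = list(), seed = 1) {
  kb <- modifyList(default_read_knobs(), knobs)
  n <- check_count(kb$n_reads, "n_reads")
  len <- check_count(kb$read_length, "read_length")
  fr <- c(microbial = kb$microbial_fraction, host = kb$host_leak_fraction,
          low_quality = kb$low_quality_fraction,
          low_complexity = kb$low_complexity_fraction)
  if (any(fr < 0) || sum(fr) > 1) stopf("category fractions must be >= 0 and sum to <= 1")
  if (fr[["microbial"]] > 0 && (is.null(markers) || nrow(markers) == 0))
    stopf("microbial_fraction > 0 requires a non-empty marker set")
  sid <- if (is.data.frame(design)) design$sample_id[1] else as.character(design)

  with_seed(seed, {
    cats <- c(names(fr), "unknown")
    prob <- c(fr, unknown = 1 - sum(fr))
    category <- sample(cats, n, replace = TRUE, prob = prob)
    seqs <- character(n)
    quals <- character(n)
    taxon <- rep(NA_character_, n)

    i_mic <- which(category == "microbial")
    if (length(i_mic)) {
      ab <- abundances[abundances > 0]
      genus <- sample(names(ab), length(i_mic), replace = TRUE, prob = ab)
      # uniform marker within genus
      midx <- vapply(genus, function(g) {
        cand <- which(markers$taxon_id == g)
        cand[sample.int(length(cand), 1)]
      }, integer(1))
      usable <- nchar(markers$seq[midx]) >= len
      if (!all(usable)) stopf("marker shorter than read length")
      start <- floor(runif(length(i_mic)) *
                       (nchar(markers$seq[midx]) - len + 1)) + 1
      s <- substr(markers$seq[midx], start, start + len - 1)
      if (kb$error_rate > 0) s <- mutate_seqs_cpp(s, kb$error_rate)
      seqs[i_mic] <- s
      quals[i_mic] <- good_qual(len, length(i_mic))
      taxon[i_mic] <- genus
    }
    i_host <- which(category == "host")
    if (length(i_host)) {
      ss <- source_substrings(host_ref, length(i_host), len)
      seqs[i_host] <- ss$seq
      quals[i_host] <- good_qual(len, length(i_host))
    }
    i_lq <- which(category == "low_quality")
    if (length(i_lq)) {
      seqs[i_lq] <- random_dna_cpp(rep(len, length(i_lq)))
      quals[i_lq] <- low_quality_strings(length(i_lq), len)
    }
    i_lc <- which(category == "low_complexity")
    if (length(i_lc)) {
      seqs[i_lc] <- low_complexity_seqs(length(i_lc), len)
      quals[i_lc] <- good_qual(len, length(i_lc))
    }
    i_un <- which(category == "unknown")
    if (length(i_un)) {
      seqs[i_un] <- random_dna_cpp(rep(len, length(i_un)))
      quals[i_un] <- good_qual(len, length(i_un))
    }
    ids <- sprintf("%s_r%06d", sid, seq_len(n))
    if (isTRUE(kb$paired)) ids <- paste0(ids, ifelse(seq_len(n) %% 2 == 1, "/1", "/2"))
    list(reads = data.frame(id = ids, seq = seqs, qual = quals,
                            stringsAsFactors = FALSE),
         origin = data.frame(read_id = ids, category = category,
                             taxon_id = taxon, stringsAsFactors = FALSE))
  })
}

#' Simulate a per-sample cell-type proportion table
#'
#' Cell proportions arise from independent positive latent abundances
#' closed to sum 1; the first ("designated") cell type's latent abundance
#' is log-normal with a latent correlation to alpha that is iteratively
#' tuned until the designated cell's empirical correlation with alpha
#' lands within 0.05 of the target (the closure to proportions attenuates
#' latent correlations, so the latent value is solved for, not assumed).
#' Rows sum to 1 exactly.
#'
#' @param alpha_values per-sample alpha diversity
#' @param target_correlation target empirical correlation of the designated
#'   cell type with alpha, in (-1, 1)
#' @param n_celltypes number of cell types (>= 2)
#' @param seed RNG seed
#' @param max_retries attempts before failing
#' @return matrix (samples x cell types) with rows summing to 1; the
#'   designated type is column `cell01`
#' @export
simulate_cell_proportions <- function(alpha_values, target_correlation,
                                      n_celltypes = 6, seed = 1,
                                      max_retries = 20) {
  n <- length(alpha_values)
  if (n < 3) stopf("need at least 3 samples")
  if (any(!is.finite(alpha_values))) stopf("alpha values must be finite")
  check_fraction(target_correlation, "target_correlation", -1, 1)
  if (abs(target_correlation) >= 1)
    stopf("`target_correlation` must lie strictly in (-1, 1)")
  n_celltypes <- check_count(n_celltypes, "n_celltypes", min = 2)
  if (sd(alpha_values) == 0)
    stopf("alpha values are constant; correlation target unattainable")
  with_seed(seed, {
    za <- as.vector(scale(alpha_values))
    r_lat <- max(-0.95, min(0.95, target_correlation * 1.4))
    for (try in seq_len(max_retries)) {
      e <- rnorm(n)
      ze <- resid(lm(e ~ za))
      if (sd(ze) == 0) next
      ze <- as.vector(scale(ze))
      lat <- r_lat * za + sqrt(max(0, 1 - r_lat^2)) * ze
      g1 <- exp(log(2) + 0.30 * lat)
      others <- matrix(rgamma(n * (n_celltypes - 1), shape = 2, rate = 1),
                       nrow = n)
      gm <- cbind(g1, others)
      out <- gm / rowSums(gm)
      achieved <- cor(out[, 1], alpha_values)
      # closure couples the designated cell to the others, attenuating its
      # correlation once the other cells are conditioned on; calibrate the
      # cell-conditioned (partial) correlation to the target while keeping
      # the plain correlation within its band
      oth <- out[, -c(1, n_celltypes), drop = FALSE]
      part <- if (ncol(oth) == 0) achieved
              else cor(resid(lm(alpha_values ~ oth)),
                       resid(lm(out[, 1] ~ oth)))
      if (abs(part - target_correlation) <= 0.05 &&
          abs(achieved - target_correlation) <= 0.1) {
        colnames(out) <- sprintf("cell%02d", seq_len(n_celltypes))
        rownames(out) <- names(alpha_values) %||% sprintf("s%03d", seq_len(n))
        return(out)
      }
      if (target_correlation != 0 && is.finite(part) && part != 0)
        r_lat <- max(-0.97, min(0.97, r_lat * target_correlation / part))
    }
    stopf("could not attain target correlation %.2f after %d tries",
          target_correlation, max_retries)
  })
}
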