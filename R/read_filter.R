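# Filtering cascade reducing host-unmapped reads to candidate microbial
# reads: fixed-depth subsampling, base-quality filter, DUST-style
# low-complexity filter, exact k-mer residual-host screen.

#' Filter configuration
#'
#' @param depth subsampling depth (reads per sample), default 100000
#' @param seed subsampling seed
#' @param min_q minimum Phred quality counted as a good base
#' @param min_frac minimum fraction of good bases for a read to survive
#' @param complexity_threshold DUST-style score above which a read is
#'   removed
#' @param host_k k-mer size of the residual-host screen
#' @param max_shared maximum canonical k-mers a read may share with the
#'   host index before removal
#' @param dedup optional exact-sequence deduplication stage (off by
#'   default)
#' @param stages stage order; removing a stage skips it
#' @return an object of class `filter_config`
#' @export
filter_config <- function(depth = 100000, seed = 0, min_q = 20,
                          min_frac = 0.8, complexity_threshold = 7,
                          host_k = 21, max_shared = 2, dedup = FALSE,
                          stages = c("subsample", "quality", "complexity",
                                     "host")) {
  depth <- check_count(depth, "depth")
  check_fraction(min_frac, "min_frac")
  if (min_frac <= 0) stopf("`min_frac` must be in (0, 1]")
  if (complexity_threshold < 0 || max_shared < 0 || min_q < 0)
    stopf("thresholds must be non-negative")
  structure(list(depth = depth, seed = seed, min_q = min_q,
                 min_frac = min_frac,
                 complexity_threshold = complexity_threshold,
                 host_k = host_k, max_shared = max_shared, dedup = dedup,
                 stages = stages),
            class = "filter_config")
}

#' Subsample a read set to a fixed depth
#'
#' Uniform sampling without replacement, deterministic per seed. When the
#' input holds fewer reads than `depth`, all reads are returned and the
#' result carries attribute `shortfall = TRUE`.
#'
#' @param reads read-set data.frame
#' @param depth target depth
#' @param seed RNG seed
#' @return the subsampled read set (input order preserved)
#' @export
subsample_reads <- function(reads, depth, seed = 0) {
  depth <- check_count(depth, "depth")
  n <- nrow(reads)
  if (n <= depth) {
    attr(reads, "shortfall") <- TRUE
    if (n < depth)
      warning(sprintf("only %d reads available for requested depth %d", n, depth))
    return(reads)
  }
  idx <- with_seed(seed, sort(sample.int(n, depth)))
  out <- reads[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "shortfall") <- FALSE
  out
}

read_qual_fracs <- function(reads, min_q) {
  bad <- nchar(reads$seq) != nchar(reads$qual)
  if (any(bad))
    stopf("sequence/quality length mismatch for read(s): %s",
          paste(head(reads$id[bad], 3), collapse = ", "))
  vapply(reads$qual, function(q) {
    ph <- utf8ToInt(q) - 33L
    mean(ph >= min_q)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Base-quality filter
#'
#' A read is kept iff at least `min_frac` of its bases have Phred quality
#' >= `q`.
#'
#' @param reads read-set data.frame
#' @param q Phred threshold
#' @param min_frac minimum fraction of good bases
#' @return list with `kept` and `removed` read sets
#' @export
quality_filter <- function(reads, q = 20, min_frac = 0.8) {
  ok <- read_qual_fracs(reads, q) >= min_frac
  list(kept = reads[ok, , drop = FALSE],
       removed = reads[!ok, , drop = FALSE])
}

#' DUST-style low-complexity score
#'
#' Counts overlapping 3-mers within 64-base windows (and over the whole
#' sequence), scores each window as sum of c(c-1)/2 over triplet counts c
#' divided by the fixed normaliser 62, and returns the maximum over
#' windows. Homopolymers maximise the score; a sequence whose 3-mers are
#' all distinct scores 0, as does any sequence shorter than 3 bases.
#'
#' @param sequence character vector of sequences over \{A,C,G,T,N\}
#' @return numeric vector of non-negative scores
#' @export
complexity_score <- function(sequence) {
  dust_scores_cpp(as.character(sequence))
}

#' Low-complexity filter
#'
#' Removes reads whose [complexity_score()] exceeds `threshold`.
#'
#' @param reads read-set data.frame
#' @param threshold score threshold (default 7)
#' @return list with `kept` and `removed` read sets
#' @export
complexity_filter <- function(reads, threshold = 7) {
  ok <- complexity_score(reads$seq) <= threshold
  list(kept = reads[ok, , drop = FALSE],
       removed = reads[!ok, , drop = FALSE])
}

#' Build a canonical k-mer index of a host reference
#'
#' @param host_seqs named character vector of host sequences
#' @param k k-mer size (default 21)
#' @return character vector of distinct canonical k-mers
#' @export
build_host_index <- function(host_seqs, k = 21) {
  kmer_set_cpp(as.character(host_seqs), as.integer(k), TRUE)
}

#' Residual-host k-mer screen
#'
#' A read is removed iff it shares more than `max_shared` distinct
#' canonical k-mers with the host index.
#'
#' @param reads read-set data.frame
#' @param host_index canonical k-mer set from [build_host_index()]
#' @param k k-mer size (must match the index)
#' @param max_shared tolerated shared k-mers (default 2)
#' @return list with `kept` and `removed` read sets
#' @export
host_screen <- function(reads, host_index, k = 21, max_shared = 2) {
  if (length(host_index) == 0) {
    warning("empty host index; all reads kept")
    return(list(kept = reads, removed = reads[0, , drop = FALSE]))
  }
  shared <- host_shared_counts_cpp(reads$seq, host_index, as.integer(k), TRUE)
  ok <- shared <= max_shared
  list(kept = reads[ok, , drop = FALSE],
       removed = reads[!ok, , drop = FALSE])
}

#' Run the full filtering cascade
#'
#' Applies, in order: subsampling to fixed depth, base-quality filter,
#' low-complexity filter, residual-host screen (and optional exact
#' deduplication). Returns the candidate reads plus a per-stage count
#' report satisfying input = output + removed at every stage.
#'
#' @param reads read-set data.frame of host-unmapped reads
#' @param host_ref named character vector of host reference sequences
#'   (or a prebuilt [build_host_index()] when `host_is_index = TRUE`)
#' @param config a [filter_config()]
#' @param host_is_index interpret `host_ref` as a prebuilt k-mer index
#' @return list with `candidates` (read set), `report` (class
#'   `filter_report`), and `removed` (per-stage read sets)
#' @export
run_filter <- function(reads, host_ref, config = filter_config(),
                       host_is_index = FALSE) {
  stopifnot(inherits(config, "filter_config"))
  counts <- c(input = nrow(reads))
  removed <- list()
  cur <- reads
  stages <- config$stages
  if (isTRUE(config$dedup)) stages <- c(stages, "dedup")
  for (st in stages) {
    if (st == "subsample") {
      cur <- subsample_reads(cur, config$depth, config$seed)
      counts["after_subsample"] <- nrow(cur)
    } else if (st == "quality") {
      r <- quality_filter(cur, config$min_q, config$min_frac)
      removed$low_quality <- r$removed
      counts["removed_low_quality"] <- nrow(r$removed)
      cur <- r$kept
    } else if (st == "complexity") {
      r <- complexity_filter(cur, config$complexity_threshold)
      removed$low_complexity <- r$removed
      counts["removed_low_complexity"] <- nrow(r$removed)
      cur <- r$kept
    } else if (st == "host") {
      idx <- if (host_is_index) host_ref
             else build_host_index(host_ref, config$host_k)
      r <- host_screen(cur, idx, config$host_k, config$max_shared)
      removed$host <- r$removed
      counts["removed_host_screen"] <- nrow(r$removed)
      cur <- r$kept
    } else if (st == "dedup") {
      dup <- duplicated(cur$seq)
      removed$duplicate <- cur[dup, , drop = FALSE]
      counts["removed_duplicate"] <- sum(dup)
      cur <- cur[!dup, , drop = FALSE]
    } else {
      stopf("unknown filter stage: %s", st)
    }
  }
  counts["candidate_output"] <- nrow(cur)
  report <- structure(list(counts = counts, stages = stages,
                           config = config), class = "filter_report")
  validate_filter_report(report)
  list(candidates = cur, report = report, removed = removed)
}

validate_filter_report <- function(report) {
  ct <- report$counts
  start <- if ("after_subsample" %in% names(ct)) ct[["after_subsample"]]
           else ct[["input"]]
  rem <- sum(ct[grepl("^removed_", names(ct))])
  if (start - rem != ct[["candidate_output"]])
    stopf("filter report violates count conservation")
  if (any(ct < 0)) stopf("negative counts in filter report")
  invisible(report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (nm in names(x$counts)) cat(sprintf("  %-24s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Write a filter report as tab-separated text or JSON
#'
#' @param report a `filter_report`
#' @param path output path; `.json` selects JSON
#' @return the path, invisibly
#' @export
write_filter_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(report$counts), path, auto_unbox = TRUE)
  } else {
    write_tsv(data.frame(stage = names(report$counts),
                         reads = as.integer(report$counts)), path)
  }
  invisible(path)
}
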