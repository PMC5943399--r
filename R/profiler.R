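# Marker-gene profiler: k-mer containment assignment with LCA fallback,
# aggregation of read counts into abundance tables at any rank, and a
# reader for externally produced profiler tables.

#' Build a k-mer marker index
#'
#' Indexes every distinct canonical k-mer of every marker gene against the
#' marker (and its genus-level taxon).
#'
#' @param markers a [simulate_markers()] set, or any data.frame with
#'   `marker_id`, `taxon_id`, `seq`
#' @param k k-mer size (>= 11, default 21)
#' @param canonical merge reverse complements (default TRUE)
#' @return an object of class `marker_index`
#' @export
build_index <- function(markers, k = 21, canonical = TRUE) {
  if (nrow(markers) == 0) stopf("marker set is empty")
  if (k < 11) stopf("k must be >= 11")
  if (anyDuplicated(markers$marker_id))
    stopf("duplicate marker ids: %s",
          paste(unique(markers$marker_id[duplicated(markers$marker_id)]),
                collapse = ", "))
  if (any(nchar(markers$seq) < k))
    stopf("k = %d exceeds the shortest marker length (%d)", k,
          min(nchar(markers$seq)))
  km_per_marker <- lapply(markers$seq, kmer_set_cpp, k = as.integer(k),
                          canonical = canonical)
  structure(list(
    kmers = unlist(km_per_marker, use.names = FALSE),
    marker_of = rep.int(seq_len(nrow(markers)), lengths(km_per_marker)),
    marker_ids = markers$marker_id,
    taxon_ids = markers$taxon_id,
    k = as.integer(k), canonical = canonical), class = "marker_index")
}

#' @export
print.marker_index <- function(x, ...) {
  cat(sprintf("<marker_index> %d markers, %d k-mer entries, k = %d\n",
              length(x$marker_ids), length(x$kmers), x$k))
  invisible(x)
}

#' Assign reads to taxa
#'
#' For each read, collects markers sharing at least `min_hits` distinct
#' k-mers with it. A single hit genus assigns the read at genus rank;
#' several hit genera assign it at their lowest-common-ancestor rank; no
#' hits leave it unassigned (NA). Assignment is independent of read order.
#'
#' @param reads read-set data.frame (or character vector of sequences)
#' @param index a [build_index()]
#' @param taxonomy the taxonomy the markers were simulated from
#' @param min_hits minimum shared k-mers per marker (default 2)
#' @return character vector of taxon ids (NA = unassigned)
#' @export
assign_reads <- function(reads, index, taxonomy, min_hits = 2) {
  stopifnot(inherits(index, "marker_index"))
  min_hits <- check_count(min_hits, "min_hits")
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  hits <- assign_reads_cpp(seqs, index$kmers, index$marker_of,
                           length(index$marker_ids), index$k,
                           index$canonical, min_hits)
  lca_cache <- new.env(hash = TRUE, parent = emptyenv())
  vapply(hits, function(h) {
    if (length(h) == 0) return(NA_character_)
    taxa <- unique(index$taxon_ids[h])
    if (length(taxa) == 1) return(taxa)
    key <- paste(sort(taxa), collapse = "|")
    got <- lca_cache[[key]]
    if (is.null(got)) {
      got <- tax_lca(taxonomy, taxa)
      if (is.na(got)) got <- "NA"
      lca_cache[[key]] <- got
    }
    if (identical(got, "NA")) NA_character_ else got
  }, character(1))
}

#' @rdname assign_reads
#' @param read a single read (sequence string)
#' @return `assign_read` returns one taxon id or NA
#' @export
assign_read <- function(read, index, taxonomy, min_hits = 2) {
  assign_reads(read, index, taxonomy, min_hits)[[1]]
}

#' Profile one sample
#'
#' @inheritParams assign_reads
#' @return list with `counts` (named per-taxon read counts, any rank) and
#'   `unassigned` (count); counts + unassigned = number of reads
#' @export
profile_sample <- function(reads, index, taxonomy, min_hits = 2) {
  n <- if (is.data.frame(reads)) nrow(reads) else length(reads)
  if (n == 0) return(list(counts = setNames(integer(0), character(0)),
                          unassigned = 0L))
  tx <- assign_reads(reads, index, taxonomy, min_hits)
  tab <- table(tx[!is.na(tx)])
  list(counts = setNames(as.integer(tab), names(tab)),
       unassigned = sum(is.na(tx)))
}

#' Assemble an abundance table at a taxonomic rank
#'
#' Collects per-sample profiles into a samples x taxa count matrix at
#' `rank`. Reads assigned at or below `rank` are projected up to their
#' ancestor at `rank`; reads assigned above `rank` (LCA fallback) cannot
#' be placed at that rank and are counted as unassigned there.
#'
#' @param profiles named list of [profile_sample()] results (names =
#'   sample ids)
#' @param taxonomy the taxonomy
#' @param rank target rank
#' @return an object of class `abundance_table`
#' @export
abundance_table <- function(profiles, taxonomy, rank = "phylum") {
  if (!rank %in% TAX_RANKS) stopf("unknown rank: %s", rank)
  ranks <- setNames(taxonomy$rank, taxonomy$id)
  rank_level <- setNames(seq_along(TAX_RANKS), TAX_RANKS)
  samples <- names(profiles) %||% sprintf("s%03d", seq_along(profiles))
  all_taxa <- unique(unlist(lapply(profiles, function(p) names(p$counts))))
  proj <- vapply(all_taxa, function(t) {
    if (rank_level[[ranks[[t]]]] >= rank_level[[rank]])
      tax_ancestor_at(taxonomy, t, rank)
    else NA_character_  # assigned above the target rank
  }, character(1))
  cols <- sort(unique(proj[!is.na(proj)]))
  counts <- matrix(0L, length(profiles), length(cols),
                   dimnames = list(samples, cols))
  unassigned <- integer(length(profiles))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    tgt <- proj[names(p$counts)]
    ok <- !is.na(tgt)
    if (any(ok)) {
      agg <- tapply(p$counts[ok], tgt[ok], sum)
      counts[i, names(agg)] <- as.integer(agg)
    }
    unassigned[i] <- p$unassigned + sum(p$counts[!ok])
  }
  new_abundance_table(counts = counts, rank = rank, taxonomy = taxonomy,
                      unassigned = setNames(unassigned, samples))
}

new_abundance_table <- function(counts = NULL, rel = NULL, rank, taxonomy = NULL,
                                unassigned = NULL) {
  if (is.null(rel)) {
    tot <- rowSums(counts)
    rel <- counts / ifelse(tot == 0, 1, tot)
  }
  structure(list(counts = counts, rel = rel, rank = rank,
                 taxonomy = taxonomy,
                 assigned = if (!is.null(counts)) rowSums(counts) else NULL,
                 unassigned = unassigned),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  m <- x$counts %||% x$rel
  cat(sprintf("<abundance_table> rank = %s, %d samples x %d taxa%s\n",
              x$rank, nrow(m), ncol(m),
              if (is.null(x$counts)) " (relative abundances only)" else ""))
  invisible(x)
}

#' Aggregate an abundance table to a higher rank
#'
#' Descendant taxon counts sum into each ancestor; per-sample totals are
#' preserved.
#'
#' @param table an [abundance_table()]
#' @param rank ancestor rank of the table's current rank
#' @return an `abundance_table` at `rank`
#' @export
aggregate_rank <- function(table, rank) {
  stopifnot(inherits(table, "abundance_table"))
  if (!rank %in% TAX_RANKS) stopf("unknown rank: %s", rank)
  rank_level <- setNames(seq_along(TAX_RANKS), TAX_RANKS)
  if (rank_level[[rank]] > rank_level[[table$rank]])
    stopf("target rank %s is below the table's rank %s", rank, table$rank)
  if (rank == table$rank) return(table)
  if (is.null(table$taxonomy)) stopf("table carries no taxonomy")
  m <- table$counts %||% table$rel
  anc <- vapply(colnames(m), function(t)
    tax_ancestor_at(table$taxonomy, t, rank), character(1))
  if (anyNA(anc)) stopf("taxa without ancestor at rank %s", rank)
  cols <- sort(unique(anc))
  agg <- matrix(0, nrow(m), length(cols), dimnames = list(rownames(m), cols))
  for (j in seq_along(anc)) agg[, anc[[j]]] <- agg[, anc[[j]]] + m[, j]
  if (is.null(table$counts)) {
    new_abundance_table(rel = agg / rowSums(agg), counts = NULL, rank = rank,
                        taxonomy = table$taxonomy,
                        unassigned = table$unassigned)
  } else {
    storage.mode(agg) <- "integer"
    new_abundance_table(counts = agg, rank = rank, taxonomy = table$taxonomy,
                        unassigned = table$unassigned)
  }
}

#' Read an external profiler table
#'
#' `rank_prefixed` parses pipe-separated taxon paths with single-letter
#' rank prefixes (`k__...|p__...|...`) and one relative-abundance column
#' per sample; rows whose deepest rank equals `rank` are extracted and
#' renormalised to sum to 1 per sample. `plain` reads a samples x taxa
#' tab-separated matrix (header = taxon ids).
#'
#' @param path input file
#' @param dialect `"rank_prefixed"` or `"plain"`
#' @param rank rank to extract (rank_prefixed only)
#' @return an [abundance_table()] with relative abundances (no counts)
#' @export
read_external_profile <- function(path, dialect = c("rank_prefixed", "plain"),
                                  rank = "phylum") {
  dialect <- match.arg(dialect)
  if (dialect == "plain") {
    df <- read_tsv(path)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    tot <- rowSums(m)
    if (any(tot <= 0)) stopf("sample(s) with zero total abundance")
    return(new_abundance_table(rel = m / tot, counts = NULL, rank = rank))
  }
  prefix_of <- c(p = "phylum", c = "class", o = "order", f = "family",
                 g = "genus")
  df <- read_tsv(path)
  if (ncol(df) < 2) stopf("rank_prefixed file needs a path column and >= 1 sample column")
  paths <- df[[1]]
  deepest <- character(length(paths))
  label <- character(length(paths))
  for (i in seq_along(paths)) {
    segs <- strsplit(paths[i], "|", fixed = TRUE)[[1]]
    if (any(!grepl("^[a-z]__", segs)))
      stopf("line %d: malformed taxon path '%s'", i + 1, paths[i])
    last <- segs[length(segs)]
    pr <- substr(last, 1, 1)
    deepest[i] <- if (pr %in% names(prefix_of)) prefix_of[[pr]] else "kingdom"
    label[i] <- sub("^[a-z]__", "", last)
  }
  keep <- which(deepest == rank)
  if (length(keep) == 0) stopf("no rows at rank %s", rank)
  m <- t(as.matrix(df[keep, -1, drop = FALSE]))
  colnames(m) <- label[keep]
  rownames(m) <- names(df)[-1]
  tot <- rowSums(m)
  if (any(tot <= 0))
    stopf("line %d: abundances sum to 0 for sample %s",
          keep[1] + 1, rownames(m)[which(tot <= 0)[1]])
  new_abundance_table(rel = m / tot, counts = NULL, rank = rank)
}

#' Write an abundance table as tab-separated text
#'
#' Samples x taxa, header = taxon ids; relative abundances are written
#' when counts are absent.
#'
#' @param table an [abundance_table()]
#' @param path output path
#' @param what `"counts"` or `"rel"`
#' @return the path, invisibly
#' @export
write_abundance_table <- function(table, path,
                                  what = if (is.null(table$counts)) "rel" else "counts") {
  m <- table[[what]]
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_abundance_table
#' @param rank rank label to attach on read
#' @export
read_abundance_table <- function(path, rank = "phylum",
                                 what = c("counts", "rel")) {
  what <- match.arg(what)
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (what == "counts") {
    storage.mode(m) <- "integer"
    new_abundance_table(counts = m, rank = rank)
  } else {
    new_abundance_table(rel = m, counts = NULL, rank = rank)
  }
}
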