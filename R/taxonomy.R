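#' Taxonomic ranks used throughout the package, highest to lowest
#' @export
TAX_RANKS <- c("phylum", "class", "order", "family", "genus")

#' Build a synthetic five-rank taxonomy
#'
#' Generates a complete taxonomy tree with ranks phylum > class > order >
#' family > genus. Each phylum carries a single class/order/family chain and
#' `genera_per_phylum` genus leaves, so the tree has
#' `n_phyla * genera_per_phylum` leaves. Node ids are stable, human-readable
#' strings (`p01`, `p01.c`, ..., `p01.g03`).
#'
#' @param n_phyla number of phyla (>= 1)
#' @param genera_per_phylum number of genus leaves per phylum (>= 1)
#' @param seed RNG seed (kept for interface symmetry; construction is
#'   deterministic)
#' @return an object of class `taxonomy`: a data.frame with columns
#'   `id`, `name`, `rank`, `parent_id`; the root sentinel has id `"root"`.
#' @export
build_taxonomy <- function(n_phyla, genera_per_phylum, seed = 0) {
  n_phyla <- check_count(n_phyla, "n_phyla")
  genera_per_phylum <- check_count(genera_per_phylum, "genera_per_phylum")
  rows <- list(data.frame(id = "root", name = "root", rank = "root",
                          parent_id = NA_character_))
  for (p in seq_len(n_phyla)) {
    pid <- sprintf("p%02d", p)
    rows[[length(rows) + 1L]] <- data.frame(
      id = c(pid, paste0(pid, ".c"), paste0(pid, ".o"), paste0(pid, ".f")),
      name = c(sprintf("Phylum%02d", p), sprintf("Class%02d", p),
               sprintf("Order%02d", p), sprintf("Family%02d", p)),
      rank = c("phylum", "class", "order", "family"),
      parent_id = c("root", pid, paste0(pid, ".c"), paste0(pid, ".o")))
    g <- seq_len(genera_per_phylum)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("%s.g%02d", pid, g),
      name = sprintf("Genus%02d_%02d", p, g),
      rank = "genus",
      parent_id = paste0(pid, ".f"))
  }
  tax <- do.call(rbind, rows)
  rownames(tax) <- tax$id
  class(tax) <- c("taxonomy", "data.frame")
  validate_taxonomy(tax)
  tax
}

validate_taxonomy <- function(tax) {
  if (anyDuplicated(tax$id)) stopf("taxonomy ids are not unique")
  non_root <- tax[tax$rank != "root", ]
  if (!all(non_root$parent_id %in% tax$id))
    stopf("taxonomy has dangling parent ids")
  rank_level <- c(root = 0L, setNames(seq_along(TAX_RANKS), TAX_RANKS))
  pr <- rank_level[tax$rank[match(non_root$parent_id, tax$id)]]
  cr <- rank_level[non_root$rank]
  if (any(cr <= pr)) stopf("taxonomy child rank not below parent rank")
  invisible(tax)
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %d nodes, %d genus leaves, %d phyla\n",
              nrow(x), sum(x$rank == "genus"), sum(x$rank == "phylum")))
  invisible(x)
}

#' Genus-level leaf ids of a taxonomy
#'
#' @param tax a `taxonomy` object
#' @return character vector of genus taxon ids
#' @export
tax_genera <- function(tax) tax$id[tax$rank == "genus"]

# path of node ids from a taxon up to (excluding) the root
tax_path <- function(tax, id) {
  parent <- setNames(tax$parent_id, tax$id)
  path <- character(0)
  cur <- id
  while (!is.na(cur) && cur != "root") {
    path <- c(cur, path)
    cur <- parent[[cur]]
  }
  path
}

# ancestor of `id` at `rank` (id itself if already at that rank), or NA
tax_ancestor_at <- function(tax, id, rank) {
  ranks <- setNames(tax$rank, tax$id)
  path <- tax_path(tax, id)
  hit <- path[ranks[path] == rank]
  if (length(hit)) hit[[1]] else NA_character_
}

# lowest common ancestor of a set of taxon ids; NA when only the root is
# shared
tax_lca <- function(tax, ids) {
  ids <- unique(ids)
  if (length(ids) == 1) return(ids)
  paths <- lapply(ids, function(i) tax_path(tax, i))
  depth <- min(lengths(paths))
  lca <- NA_character_
  for (d in seq_len(depth)) {
    level <- vapply(paths, `[[`, character(1), d)
    if (length(unique(level)) == 1) lca <- level[[1]] else break
  }
  lca
}

#' Write / read a taxonomy as tab-separated text
#'
#' @param tax a `taxonomy` object
#' @param path file path
#' @return the path (write) or a `taxonomy` (read)
#' @export
write_taxonomy <- function(tax, path) {
  write_tsv(as.data.frame(tax)[, c("id", "rank", "name", "parent_id")], path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv(path)
  need <- c("id", "rank", "name", "parent_id")
  if (!all(need %in% names(df)))
    stopf("taxonomy file lacks columns: %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  tax <- df[, c("id", "name", "rank", "parent_id")]
  tax$parent_id[tax$parent_id == ""] <- NA_character_
  rownames(tax) <- tax$id
  class(tax) <- c("taxonomy", "data.frame")
  validate_taxonomy(tax)
  tax
}
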