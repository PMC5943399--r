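test_that("build_index enumerates marker k-mers and validates input", {
  tax <- tiny_taxonomy()
  mk <- data.frame(marker_id = "m1", taxon_id = "p01.g01",
                   seq = paste(rep("ACGT", 100), collapse = ""))
  # one marker: L - k + 1 windows minus canonical collisions
  idx <- build_index(mk, k = 21)
  expect_lte(length(idx$kmers), nchar(mk$seq) - 21 + 1)
  expect_gt(length(idx$kmers), 0)
  expect_error(build_index(mk[0, ], 21), "empty")
  expect_error(build_index(rbind(mk, mk), 21), "duplicate")
  short <- data.frame(marker_id = "s", taxon_id = "t", seq = "ACGTACGTACGT")
  expect_error(build_index(short, 21), "shortest marker")
})

test_that("index built from genus-unique markers never crosses genera", {
  tax <- build_taxonomy(6, 3)
  mk <- simulate_markers(tax, 2, length_range = c(300, 500), seed = 13)
  idx <- build_index(mk, 21)
  genus_of <- idx$taxon_ids[idx$marker_of]
  split_genus <- split(genus_of, idx$kmers)
  expect_true(all(vapply(split_genus, function(g)
    length(unique(g)) == 1, logical(1))))
})

test_that("assign_read resolves verbatim, random and chimeric reads", {
  tax <- tiny_taxonomy()
  mk <- tiny_markers(tax)
  idx <- build_index(mk, 21)
  # verbatim substring (>= k + min_hits - 1 bases) -> its genus
  r <- substr(mk$seq[3], 50, 149)
  expect_equal(assign_read(r, idx, tax), mk$taxon_id[3])
  # random reads stay unassigned
  set.seed(1)
  expect_true(all(is.na(assign_reads(random_dna_strings(20, 100), idx, tax))))
  # chimera of two same-phylum genera -> LCA at the shared family
  two <- mk[mk$taxon_id %in% c("p01.g01", "p01.g02"), ]
  chimera <- paste0(substr(two$seq[1], 1, 50), substr(two$seq[2], 1, 50))
  got <- assign_read(chimera, idx, tax)
  expect_equal(got, "p01.f")
  # chimera across phyla shares only the root -> unassigned
  cross <- mk[mk$taxon_id %in% c("p01.g01", "p02.g01"), ]
  chimera2 <- paste0(substr(cross$seq[1], 1, 50), substr(cross$seq[2], 1, 50))
  expect_true(is.na(assign_read(chimera2, idx, tax)))
})

test_that("profile_sample counts are complete and order-invariant", {
  tax <- tiny_taxonomy()
  mk <- tiny_markers(tax)
  idx <- build_index(mk, 21)
  expect_equal(profile_sample(character(0), idx, tax)$unassigned, 0)
  set.seed(2)
  reads <- c(vapply(sample(nrow(mk), 50, replace = TRUE), function(i)
    substr(mk$seq[i], 11, 110), character(1)),
    random_dna_strings(20, 100))
  p1 <- profile_sample(reads, idx, tax)
  expect_equal(sum(p1$counts) + p1$unassigned, length(reads))
  p2 <- profile_sample(rev(reads), idx, tax)
  expect_equal(p1$counts[sort(names(p1$counts))],
               p2$counts[sort(names(p2$counts))])
})

test_that("abundance tables aggregate with count conservation", {
  tax <- build_taxonomy(1, 3)
  profs <- list(
    s1 = list(counts = c(p01.g01 = 5L, p01.g02 = 3L), unassigned = 2L),
    s2 = list(counts = c(p01.g03 = 4L), unassigned = 0L))
  gt <- abundance_table(profs, tax, "genus")
  expect_equal(unname(rowSums(gt$counts)), c(8, 4))
  expect_true(all(abs(rowSums(gt$rel) - 1) < 1e-9))
  pt <- aggregate_rank(gt, "phylum")
  expect_equal(ncol(pt$counts), 1)
  expect_equal(unname(pt$counts[, 1]), unname(rowSums(gt$counts)))
  expect_error(aggregate_rank(pt, "genus"), "below")
})

test_that("reads assigned above the target rank count as unassigned there", {
  tax <- build_taxonomy(2, 2)
  profs <- list(s1 = list(counts = c(p01.g01 = 6L, p01.f = 4L),
                          unassigned = 1L))
  gt <- abundance_table(profs, tax, "genus")
  expect_equal(unname(gt$counts[1, "p01.g01"]), 6)
  expect_equal(unname(gt$unassigned[["s1"]]), 5)  # 1 + the 4 family-level reads
  ft <- abundance_table(profs, tax, "family")
  expect_equal(unname(ft$counts[1, "p01.f"]), 10)
  expect_equal(unname(ft$unassigned[["s1"]]), 1)
})

test_that("phylum recovery on error-free reads correlates with truth", {
  tax <- build_taxonomy(8, 2)
  mk <- simulate_markers(tax, 2, length_range = c(300, 500), seed = 31)
  host <- simulate_host_reference(seed = 32)
  prof <- group_profile("g", setNames(rep(0.8, 16), tax_genera(tax)))
  idx <- build_index(mk, 21)
  for (s in 1:3) {
    ab <- draw_sample_abundances(prof, seed = 40 + s)
    sim <- simulate_sample_reads("s", ab, mk, host,
                                 list(n_reads = 1500, microbial_fraction = 0.8,
                                      host_leak_fraction = 0.05,
                                      low_quality_fraction = 0,
                                      low_complexity_fraction = 0),
                                 seed = 50 + s)
    p <- profile_sample(sim$reads$seq, idx, tax, min_hits = 2)
    tab <- abundance_table(list(s1 = p), tax, "phylum")
    stopifnot(sum(p$counts) >= 500)
    truth_phylum <- tapply(ab, vapply(names(ab), function(g)
      bloodbiome:::tax_ancestor_at(tax, g, "phylum"), character(1)), sum)
    est <- setNames(rep(0, length(truth_phylum)), names(truth_phylum))
    est[colnames(tab$rel)] <- tab$rel[1, ]
    expect_gte(cor(est, truth_phylum[names(est)]), 0.99)
  }
})

test_that("external profiler tables parse, renormalise and round-trip", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("taxon\tsampleA",
               "k__Bacteria|p__Proteobacteria\t60",
               "k__Bacteria|p__Firmicutes\t30",
               "k__Bacteria|p__Cyanobacteria\t10"), f)
  tab <- read_external_profile(f, "rank_prefixed", rank = "phylum")
  expect_equal(unname(tab$rel[1, ]), c(0.6, 0.3, 0.1))

  # dominant-phylum values renormalised over the extracted rank
  writeLines(c("taxon\ts1",
               "k__Bacteria|p__Proteobacteria\t73.4",
               "k__Bacteria|p__Firmicutes\t14.9",
               "k__Bacteria|p__Cyanobacteria\t11.0"), f)
  tab2 <- read_external_profile(f, "rank_prefixed", rank = "phylum")
  expect_equal(unname(tab2$rel[1, ]), c(0.7392, 0.1501, 0.1108),
               tolerance = 1e-4)

  # malformed path errors with its line number
  writeLines(c("taxon\ts1", "k__Bacteria|oops\t5"), f)
  expect_error(read_external_profile(f, "rank_prefixed"), "line 2")

  # plain dialect round-trip
  rt <- tempfile(fileext = ".tsv")
  write_abundance_table(tab2, rt, what = "rel")
  back <- read_abundance_table(rt, rank = "phylum", what = "rel")
  expect_equal(back$rel, tab2$rel)
})
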